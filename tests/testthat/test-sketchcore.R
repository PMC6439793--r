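test_that("residue chunking follows floor(i / w)", {
  expect_equal(encode_element("P12345", 17, 4)$chunk, 4)
  expect_equal(encode_element("P12345", 17, 1)$chunk, 17)
  # residues in the same window collide: the mechanism behind false overlaps
  expect_identical(encode_element("P12345", 3, 64), encode_element("P12345", 63, 64))
  expect_error(encode_element("P1", 0, 4), class = "sketchoverlap_invalid_argument")
  expect_error(encode_element("P1", 5, 0), class = "sketchoverlap_invalid_argument")
})

test_that("token hashing is deterministic, seed-sensitive and collision-free", {
  tok <- encode_element(rep(sprintf("P%05d", 1:100), each = 100), 1:10000, 1)
  p1 <- hash_params(hash_seed = 1)
  h1 <- hash_token(tok, p1)
  expect_identical(h1, hash_token(tok, p1))
  expect_true(any(h1 != hash_token(tok, hash_params(hash_seed = 2))))
  # 10^4 draws from a >= 2^53 space: any collision indicates a defect
  expect_equal(length(unique(h1)), nrow(tok))
  expect_true(all(h1 >= 0 & h1 < 2^53) && all(h1 == floor(h1)))
  expect_error(hash_params(hash_name = "md5"), class = "sketchoverlap_config_error")
})

test_that("hashed sets take the residue union and chunk it", {
  w1 <- hash_params(window = 1)
  expect_equal(build_hashed_set(fam_interval("F", "P1", 1, 10), w1)$cardinality, 10)
  two <- family_regions("F", data.frame(protein_id = c("P1", "P1"),
                                        start = c(1, 3), end = c(5, 8)))
  expect_equal(build_hashed_set(two, w1)$cardinality, 8)
  # chunks of [1,10] at w=4 enumerate to {0,1,2} by brute force
  expect_equal(build_hashed_set(fam_interval("F", "P1", 1, 10),
                                hash_params(window = 4))$cardinality,
               length(unique(floor(1:10 / 4))))
  expect_error(family_regions("BADFAM", data.frame(protein_id = "P9",
                                                   start = 5, end = 2)),
               regexp = "BADFAM.*P9", class = "sketchoverlap_validation_error")
})

test_that("sketches keep the n smallest hashes, all of them when unsaturated", {
  p <- hash_params(window = 1)
  hs <- build_hashed_set(fam_interval("F", "P1", 1, 10), p)
  wide <- sketch_of(hs, 25)
  expect_identical(wide$mins, sort(hs$hashes))
  expect_equal(length(wide$mins), 10)
  narrow <- sketch_of(hs, 4)
  expect_identical(narrow$mins, sort(hs$hashes)[1:4])
  expect_true(all(diff(narrow$mins) > 0))
  expect_error(sketch_of(hs, 0), class = "sketchoverlap_invalid_argument")
})

test_that("merging sketches reproduces the sketch of the union", {
  p <- hash_params(window = 1)
  hs <- build_hashed_set(fam_interval("F", "P1", 1, 30), p)
  s <- sketch_of(hs, 10)
  expect_identical(merge_sketches(s, s)$mins, s$mins)
  set.seed(421)
  for (k in 1:30) {
    pr <- random_planted_pair(paste0("m", k), 120L)
    A <- build_hashed_set(pr$a, p); B <- build_hashed_set(pr$b, p)
    merged <- merge_sketches(sketch_of(A, 50), sketch_of(B, 50))
    expect_identical(merged$mins, sketch_of(union_hashed_sets(A, B), 50)$mins)
  }
  expect_error(merge_sketches(sketch_of(hs, 10), sketch_of(hs, 20)),
               class = "sketchoverlap_incompatible_params")
  other <- build_hashed_set(fam_interval("F", "P1", 1, 30), hash_params(hash_seed = 9))
  expect_error(merge_sketches(sketch_of(hs, 10), sketch_of(other, 10)),
               class = "sketchoverlap_incompatible_params")
})

test_that("estimators reproduce the exact values when the sketch saturates", {
  p <- hash_params(window = 1)
  pr <- planted_pair("t", 100, 100, 50)         # |A u B| = 150, |A n B| = 50
  A <- build_hashed_set(pr$a, p); B <- build_hashed_set(pr$b, p)
  sa <- sketch_of(A, 200); sb <- sketch_of(B, 200)
  expect_identical(estimate_jaccard_index(sa, sb), 1 / 3)
  expect_identical(estimate_jaccard_index(sa, sb), exact_jaccard_index(A, B))
  expect_identical(estimate_jaccard_index(sa, sa), 1)

  cont <- planted_pair("c", 100, 25, 25)        # B subset of A, |A n B| = 25
  CA <- build_hashed_set(cont$a, p); CB <- build_hashed_set(cont$b, p)
  expect_identical(estimate_containment(sketch_of(CA, 200), CB), 0.25)
  expect_identical(exact_containment(CA, CB), 0.25)
  expect_identical(exact_containment(CB, CA), 1)      # subset direction
  expect_identical(estimate_containment(sketch_of(CB, 200), CA), 1)

  dis <- planted_pair("d", 40, 60, 0)
  DA <- build_hashed_set(dis$a, p); DB <- build_hashed_set(dis$b, p)
  expect_identical(exact_jaccard_index(DA, DB), 0)
  expect_identical(estimate_jaccard_index(sketch_of(DA, 200), sketch_of(DB, 200)), 0)
  expect_identical(estimate_containment(sketch_of(DA, 200), DB), 0)
})

test_that("empty inputs raise a typed signal instead of returning a number", {
  p <- hash_params(window = 1)
  empty <- sketchoverlap:::new_hashed_set(numeric(0), p)
  full <- build_hashed_set(fam_interval("F", "P1", 1, 5), p)
  expect_error(exact_jaccard_index(empty, empty), class = "sketchoverlap_empty_input")
  expect_error(exact_containment(empty, full), class = "sketchoverlap_empty_input")
  expect_error(estimate_jaccard_index(sketch_of(empty, 5), sketch_of(empty, 5)),
               class = "sketchoverlap_empty_input")
  expect_error(estimate_containment(sketch_of(empty, 5), full),
               class = "sketchoverlap_empty_input")
  # one-sided cases are well defined
  expect_identical(exact_jaccard_index(empty, full), 0)
  expect_identical(exact_containment(full, empty), 0)
})

test_that("estimates stay in [0,1] and exact JI never exceeds either containment", {
  p <- hash_params(window = 1)
  set.seed(99)
  for (k in 1:25) {
    pr <- random_planted_pair(paste0("r", k), 300L)
    A <- build_hashed_set(pr$a, p); B <- build_hashed_set(pr$b, p)
    for (n in c(10, 50, 200)) {
      ji <- estimate_jaccard_index(sketch_of(A, n), sketch_of(B, n))
      jc <- estimate_containment(sketch_of(A, n), B)
      expect_true(ji >= 0 && ji <= 1)
      expect_true(jc >= 0 && jc <= 1)
    }
    ji <- exact_jaccard_index(A, B)
    expect_lte(ji, exact_containment(A, B))
    expect_lte(ji, exact_containment(B, A))
  }
})

test_that("w = 1 chunking is the identity and wide windows collide only within w", {
  p1 <- hash_params(window = 1)
  set.seed(17)
  for (k in 1:10) {
    pr <- random_planted_pair(paste0("w", k), 200L)
    A <- build_hashed_set(pr$a, p1); B <- build_hashed_set(pr$b, p1)
    expect_equal(exact_jaccard_index(A, B), residue_ji(pr$a, pr$b))
    expect_equal(exact_containment(A, B), residue_jc(pr$a, pr$b))
  }
  # same protein, residues always >= w apart: no shared chunk possible
  w <- 8L; pw <- hash_params(window = w)
  fa <- fam_interval("GA", "P1", 1, 10)
  fb <- fam_interval("GB", "P1", 10 + w, 30 + w)
  expect_identical(exact_jaccard_index(build_hashed_set(fa, pw),
                                       build_hashed_set(fb, pw)), 0)
  # gap < w: disjoint residues, yet a shared chunk (the false-overlap risk)
  fc <- fam_interval("GC", "P1", 1, 2)
  fd <- fam_interval("GD", "P1", 3, 4)
  expect_identical(residue_ji(fc, fd), 0)
  expect_gt(exact_jaccard_index(build_hashed_set(fc, hash_params(window = 4)),
                                build_hashed_set(fd, hash_params(window = 4))), 0)
})
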