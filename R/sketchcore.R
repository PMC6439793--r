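#' Hashing parameters for family set comparison
#'
#' Bundles everything that must match for two hashed sets or sketches to be
#' comparable: the hash function, its seed, and the residue chunking window
#' `w`. A residue at 1-based coordinate `i` is assigned to chunk
#' `floor(i / w)`, so `w = 1` means no chunking and larger `w` shrinks the
#' element sets at the cost of possible false overlaps between domains that
#' lie closer than `w` residues apart.
#'
#' @param hash_name Name of the hash function. Currently `"fnv1a64"`, a
#'   seeded FNV-1a over the canonical token bytes with a splitmix64
#'   finalizer, emitting 53-bit values (exactly representable as R doubles).
#' @param hash_seed Non-negative integer seed; distinct seeds give
#'   effectively independent hash functions.
#' @param window Positive integer chunking window `w`. Defaults to 4;
#'   windows much larger than 16 make false overlaps between nearby domains
#'   of multidomain proteins increasingly likely.
#' @return An object of class `hash_params`.
#' @export
#' @examples
#' hash_params(window = 1)
hash_params <- function(hash_name = "fnv1a64", hash_seed = 42L, window = 4L) {
  if (!identical(hash_name, "fnv1a64")) {
    stop_config("unknown hash_name '%s' (available: 'fnv1a64')", hash_name)
  }
  hash_seed <- as.integer(hash_seed)
  window <- as.integer(window)
  if (length(hash_seed) != 1L || is.na(hash_seed) || hash_seed < 0L) {
    stop_invalid_arg("hash_seed must be a single non-negative integer")
  }
  if (length(window) != 1L || is.na(window) || window < 1L) {
    stop_invalid_arg("window must be a single integer >= 1")
  }
  structure(list(hash_name = hash_name, hash_seed = hash_seed, window = window),
            class = "hash_params")
}

#' @export
print.hash_params <- function(x, ...) {
  cat(sprintf("<hash_params> %s seed=%d w=%d\n", x$hash_name, x$hash_seed, x$window))
  invisible(x)
}

params_equal <- function(a, b) {
  identical(a$hash_name, b$hash_name) &&
    identical(a$hash_seed, b$hash_seed) &&
    identical(a$window, b$window)
}

check_params_compatible <- function(a, b, what = "objects") {
  if (!params_equal(a, b)) {
    stop_incompatible(
      "%s were built with different hash parameters (%s seed=%d w=%d vs %s seed=%d w=%d)",
      what, a$hash_name, a$hash_seed, a$window, b$hash_name, b$hash_seed, b$window)
  }
  invisible(TRUE)
}

#' Encode residues as (protein, chunk) set elements
#'
#' Maps a residue at 1-based coordinate `i` of a protein to the set element
#' `(protein_id, floor(i / window))`. Vectorised over `protein_id` and
#' `residue_position` (recycled against each other).
#'
#' @param protein_id Character vector of protein accessions.
#' @param residue_position Integer vector of 1-based residue coordinates.
#' @param window Positive integer chunking window.
#' @return A data frame with columns `protein_id` and `chunk`.
#' @export
#' @examples
#' encode_element("P12345", 17, 4)   # chunk 4
#' encode_element("P12345", 17, 1)   # chunk 17: w = 1 keeps residue identity
encode_element <- function(protein_id, residue_position, window) {
  residue_position <- as.numeric(residue_position)
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L) {
    stop_invalid_arg("window must be a single integer >= 1")
  }
  if (any(is.na(residue_position)) || any(residue_position < 1)) {
    stop_invalid_arg("residue_position must be >= 1")
  }
  n <- max(length(protein_id), length(residue_position))
  data.frame(protein_id = rep_len(as.character(protein_id), n),
             chunk = floor(rep_len(residue_position, n) / window),
             stringsAsFactors = FALSE)
}

#' Hash encoded set elements
#'
#' Hashes `(protein_id, chunk)` tokens to 53-bit unsigned integer values
#' (held exactly in doubles). The canonical byte serialization is the
#' accession bytes, a single 0x00 separator, then the chunk as an 8-byte
#' big-endian integer, so the encoding is injective and deterministic across
#' runs and platforms.
#'
#' @param token A data frame with columns `protein_id` and `chunk`, as
#'   returned by [encode_element()].
#' @param params A [hash_params()] object supplying the seed.
#' @return Numeric vector of hash values (non-negative integers < 2^53).
#' @export
hash_token <- function(token, params) {
  stopifnot(inherits(params, "hash_params"))
  if (!all(c("protein_id", "chunk") %in% names(token))) {
    stop_invalid_arg("token must have protein_id and chunk columns")
  }
  if (any(token$chunk < 0)) stop_invalid_arg("chunk must be >= 0")
  .hash_tokens_cpp(as.character(token$protein_id), as.numeric(token$chunk),
                   as.numeric(params$hash_seed))
}

new_hashed_set <- function(hashes, params) {
  structure(list(hashes = hashes, cardinality = length(hashes), params = params),
            class = "hashed_set")
}

#' Construct the full hashed element set of a family
#'
#' Takes the residue-level union of a family's regions (overlapping or
#' abutting intervals on the same protein contribute each residue once),
#' chunks the covered residues with the window in `params`, hashes every
#' distinct `(protein, chunk)` token, and returns the distinct hash values.
#'
#' @param regions A [family_regions()] object.
#' @param params A [hash_params()] object.
#' @return A `hashed_set`: sorted distinct hash values with their parameters.
#' @export
#' @examples
#' fr <- family_regions("FAM1", data.frame(protein_id = "P1", start = 1, end = 10))
#' build_hashed_set(fr, hash_params(window = 4))$cardinality  # chunks 0,1,2
build_hashed_set <- function(regions, params) {
  stopifnot(inherits(regions, "family_regions"), inherits(params, "hash_params"))
  w <- params$window
  reg <- regions$regions
  parts <- split(reg, reg$protein_id)
  tokens <- lapply(names(parts), function(pid) {
    p <- parts[[pid]]
    # Residues covered by an interval [s, e] cover chunks floor(s/w)..floor(e/w)
    # contiguously, so the chunk set is a union of integer ranges.
    cr <- IRanges::reduce(IRanges::IRanges(start = floor(p$start / w),
                                           end = floor(p$end / w)))
    chunks <- unlist(mapply(seq.int, IRanges::start(cr), IRanges::end(cr),
                            SIMPLIFY = FALSE), use.names = FALSE)
    data.frame(protein_id = rep(pid, length(chunks)), chunk = chunks,
               stringsAsFactors = FALSE)
  })
  tok <- do.call(rbind, tokens)
  if (is.null(tok) || nrow(tok) == 0L) {
    stop_validation("family '%s' covers no residues", regions$family_id)
  }
  h <- sort(unique(hash_token(tok, params)))
  new_hashed_set(h, params)
}

#' @export
print.hashed_set <- function(x, ...) {
  cat(sprintf("<hashed_set> %d distinct hashes (%s seed=%d w=%d)\n",
              x$cardinality, x$params$hash_name, x$params$hash_seed, x$params$window))
  invisible(x)
}

#' Union of hashed sets
#'
#' Exact union of full hashed sets sharing the same parameters. Used by the
#' oracles and by tests of the sketch merge identity.
#'
#' @param a,b `hashed_set` objects with identical parameters.
#' @return A `hashed_set` holding the distinct union of hash values.
#' @export
union_hashed_sets <- function(a, b) {
  stopifnot(inherits(a, "hashed_set"), inherits(b, "hashed_set"))
  check_params_compatible(a$params, b$params, "hashed sets")
  new_hashed_set(sort(unique(c(a$hashes, b$hashes))), a$params)
}

# Membership of x in a sorted ascending table, by binary search.
# O(|x| log |table|): never scans the table, which is what keeps query cost
# bounded by the sketch capacity rather than the family cardinality.
sorted_member <- function(x, table) {
  if (length(table) == 0L) return(rep(FALSE, length(x)))
  i <- findInterval(x, table)
  i > 0L & table[pmax(i, 1L)] == x
}

#' Bottom-n MinHash sketch of a hashed set
#'
#' Keeps the `capacity` smallest distinct hash values of the set (all of
#' them when the set is smaller than `capacity`). Because the hash values
#' are a uniform pseudo-random permutation of the elements, the bottom-n
#' values are a uniform sample of the set, which is what makes Jaccard
#' estimation from sketches possible.
#'
#' @param hs A `hashed_set`.
#' @param capacity Positive integer sketch size n.
#' @return An object of class `minhash_sketch` with fields `capacity`,
#'   `mins` (ascending), `source_cardinality`, and `params`.
#' @export
sketch_of <- function(hs, capacity) {
  stopifnot(inherits(hs, "hashed_set"))
  capacity <- as.integer(capacity)
  if (length(capacity) != 1L || is.na(capacity) || capacity < 1L) {
    stop_invalid_arg("capacity must be a single integer >= 1")
  }
  mins <- hs$hashes[seq_len(min(capacity, hs$cardinality))]
  structure(list(capacity = capacity, mins = mins,
                 source_cardinality = hs$cardinality, params = hs$params),
            class = "minhash_sketch")
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat(sprintf("<minhash_sketch> n=%d |mins|=%d of %s elements (%s seed=%d w=%d)\n",
              x$capacity, length(x$mins),
              ifelse(is.na(x$source_cardinality), "?", x$source_cardinality),
              x$params$hash_name, x$params$hash_seed, x$params$window))
  invisible(x)
}

check_sketch_compatible <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  if (a$capacity != b$capacity) {
    stop_incompatible("sketches have different capacities (%d vs %d)",
                      a$capacity, b$capacity)
  }
  check_params_compatible(a$params, b$params, "sketches")
}

#' Merge two sketches into the sketch of the union
#'
#' The bottom-n values of a union are always among the bottom-n values of
#' the parts, so the sketch of `A union B` is computable from the two
#' sketches alone. The source cardinality of the result is known exactly
#' only when both inputs are unsaturated (their sketches hold the whole
#' sets); otherwise it is `NA`.
#'
#' @param a,b `minhash_sketch` objects with equal capacity and parameters.
#' @return A `minhash_sketch` of the union.
#' @export
merge_sketches <- function(a, b) {
  check_sketch_compatible(a, b)
  u <- sort(unique(c(a$mins, b$mins)))
  mins <- u[seq_len(min(a$capacity, length(u)))]
  complete <- length(a$mins) < a$capacity && length(b$mins) < b$capacity
  structure(list(capacity = a$capacity, mins = mins,
                 source_cardinality = if (complete) length(u) else NA_integer_,
                 params = a$params),
            class = "minhash_sketch")
}

#' Estimate the Jaccard index from two sketches
#'
#' Computes `|MIN_n(A' u B') n MIN_n(A') n MIN_n(B')| / |MIN_n(A' u B')|`.
#' The union sketch is a uniform sample of the union, and the numerator
#' counts how many sampled elements belong to both sets, so the ratio is an
#' unbiased proportion estimate of `JI = |A n B| / |A u B|`. When the
#' capacity reaches `|A' u B'|` the sample is the whole union and the
#' estimate equals the exact Jaccard index.
#'
#' @param a,b Compatible `minhash_sketch` objects.
#' @return A number in \[0, 1\].
#' @export
estimate_jaccard_index <- function(a, b) {
  check_sketch_compatible(a, b)
  if (length(a$mins) == 0L && length(b$mins) == 0L) {
    stop_empty_input("Jaccard index is undefined for two empty sets")
  }
  u <- merge_sketches(a, b)$mins
  num <- sum(sorted_member(u, a$mins) & sorted_member(u, b$mins))
  num / length(u)
}

#' Estimate the Jaccard containment of a sketched set in a full set
#'
#' Computes `|MIN_n(A') n B'| / |MIN_n(A')|`: the fraction of the uniform
#' sample of A found in B, an unbiased estimate of `JC(A, B) = |A n B| / |A|`.
#' Containment needs full membership in B, so `b_full` is a complete hashed
#' set, not a sketch; each probe is a binary search, so the cost is
#' `O(n log |B|)`.
#'
#' @param a A non-empty `minhash_sketch` of the contained candidate A.
#' @param b_full The `hashed_set` of the containing candidate B.
#' @return A number in \[0, 1\].
#' @export
estimate_containment <- function(a, b_full) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b_full, "hashed_set"))
  check_params_compatible(a$params, b_full$params, "sketch and hashed set")
  if (length(a$mins) == 0L) {
    stop_empty_input("containment is undefined for an empty query set")
  }
  sum(sorted_member(a$mins, b_full$hashes)) / length(a$mins)
}

#' Exact Jaccard index of two hashed sets
#'
#' `JI(A, B) = |A n B| / |A u B|` by direct set arithmetic on the full hash
#' sets. Cost is linear in the set sizes; serves as the oracle the sketch
#' estimator is checked against.
#'
#' @param a,b `hashed_set` objects with identical parameters, not both empty.
#' @return A number in \[0, 1\].
#' @export
exact_jaccard_index <- function(a, b) {
  stopifnot(inherits(a, "hashed_set"), inherits(b, "hashed_set"))
  check_params_compatible(a$params, b$params, "hashed sets")
  if (a$cardinality == 0L && b$cardinality == 0L) {
    stop_empty_input("Jaccard index is undefined for two empty sets")
  }
  # hash-map membership: O(|A| + |B|), linear in the set sizes
  inter <- sum(!is.na(match(a$hashes, b$hashes)))
  inter / (a$cardinality + b$cardinality - inter)
}

#' Exact Jaccard containment of one hashed set in another
#'
#' `JC(A, B) = |A n B| / |A|`: the fraction of A inside B. Equals 1 exactly
#' when A is a subset of B, which is the statistic of interest when asking
#' whether a query family is a superset of an existing one.
#'
#' @param a A non-empty `hashed_set` (the contained candidate).
#' @param b A `hashed_set` with identical parameters.
#' @return A number in \[0, 1\].
#' @export
exact_containment <- function(a, b) {
  stopifnot(inherits(a, "hashed_set"), inherits(b, "hashed_set"))
  check_params_compatible(a$params, b$params, "hashed sets")
  if (a$cardinality == 0L) {
    stop_empty_input("containment is undefined for an empty set A")
  }
  sum(!is.na(match(a$hashes, b$hashes))) / a$cardinality
}
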