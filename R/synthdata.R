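# Seeded generator of synthetic family region tables with planted,
# exactly-known Jaccard relationships. Planted pairs are realized on
# dedicated proteins (shared residues on pair-shared proteins, private
# residues on family-private proteins), so the residue-level intersection
# is exactly the planted shared block and the truth table is computed by
# direct set arithmetic, not estimated.

local_seed <- function(seed) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  parent <- parent.frame()
  expr <- if (has_seed) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = parent)
  invisible(NULL)
}

#' Planted relation between two synthetic families
#'
#' @param family_a,family_b Family ids (must be among the generated ids).
#' @param fraction For `rel_overlap`, the planted containment
#'   `JC(A, B) = |A n B| / |A|`, strictly between 0 and 1.
#' @return A relation descriptor for [synth_config()].
#' @export
rel_disjoint <- function(family_a, family_b) {
  list(type = "disjoint", a = family_a, b = family_b)
}

#' @rdname rel_disjoint
#' @export
rel_subset <- function(family_a, family_b) {
  list(type = "subset", a = family_a, b = family_b)
}

#' @rdname rel_disjoint
#' @export
rel_overlap <- function(family_a, family_b, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop_config("overlap fraction must lie strictly between 0 and 1")
  }
  list(type = "overlap", a = family_a, b = family_b, fraction = fraction)
}

#' Configuration for the synthetic family generator
#'
#' @param seed Integer seed; the same seed and configuration always produce
#'   identical output files.
#' @param n_families Number of families to generate (ids `SF00001`, ...).
#' @param protein_count Size of the shared protein pool used by families
#'   not involved in any planted relation.
#' @param protein_length Length in residues of every synthetic protein.
#' @param family_size_range Min/max residues per family; sizes are sampled
#'   log-uniformly, mimicking the orders-of-magnitude spread of real
#'   family sizes.
#' @param planted_relations List of [rel_disjoint()], [rel_subset()],
#'   [rel_overlap()] descriptors. A family may take part in at most one.
#' @param clans Optional named character vector assigning clan ids.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed, n_families = 20L, protein_count = 50L,
                         protein_length = 1000L,
                         family_size_range = c(50L, 500L),
                         planted_relations = list(),
                         clans = NULL) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop_config("seed must be an integer")
  n_families <- as.integer(n_families)
  ids <- sprintf("SF%05d", seq_len(n_families))
  if (length(family_size_range) != 2L || family_size_range[1] < 2 ||
      family_size_range[1] > family_size_range[2]) {
    stop_config("family_size_range must be (min, max) with 2 <= min <= max")
  }
  mentioned <- unlist(lapply(planted_relations, function(r) c(r$a, r$b)))
  unknown <- setdiff(mentioned, ids)
  if (length(unknown)) {
    stop_config("planted relations mention unknown families: %s",
                paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(mentioned)) {
    stop_config("a family may take part in at most one planted relation")
  }
  structure(list(seed = seed, n_families = n_families, family_ids = ids,
                 protein_count = as.integer(protein_count),
                 protein_length = as.integer(protein_length),
                 family_size_range = as.integer(family_size_range),
                 planted_relations = planted_relations,
                 clans = clans),
            class = "synth_config")
}

sample_size <- function(range) {
  round(exp(stats::runif(1, log(range[1]), log(range[2]))))
}

# Split `total` residues into 1..5 interval lengths, each within
# protein_length, placed on fresh private proteins at random offsets.
alloc_regions <- function(prefix, total, protein_length) {
  k <- sample.int(min(5L, total), 1L)
  cuts <- if (k > 1L) sort(sample.int(total - 1L, k - 1L)) else integer(0)
  lens <- diff(c(0L, cuts, total))
  lens <- unlist(lapply(lens, function(l) {
    c(rep(protein_length, l %/% protein_length)[seq_len(l %/% protein_length)],
      if (l %% protein_length) l %% protein_length)
  }))
  starts <- vapply(lens, function(l) sample.int(protein_length - l + 1L, 1L),
                   integer(1))
  data.frame(protein_id = sprintf("%s_%02d", prefix, seq_along(lens)),
             start = starts, end = starts + lens - 1L,
             stringsAsFactors = FALSE)
}

# First `n` residues of a region set, walking rows in order.
take_prefix <- function(reg, n) {
  lens <- reg$end - reg$start + 1
  keep <- which(cumsum(lens) < n)
  k <- length(keep) + 1L
  out <- reg[seq_len(k), , drop = FALSE]
  used <- if (k > 1L) sum(lens[keep]) else 0
  out$end[k] <- out$start[k] + (n - used) - 1
  out
}

#' Generate synthetic families with planted overlap relationships
#'
#' Produces a list of families realized as 1-5 contiguous intervals per
#' protein, a truth table giving the exact residue-level sizes,
#' intersection, Jaccard index and both containments for every planted
#' pair, and (optionally) the corresponding `regions.tsv`, `clans.tsv` and
#' `truth.json` files.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory for the TSV/JSON files.
#' @return A list with `families` (named list of [family_regions()]),
#'   `clans` (named character vector) and `truth` (data frame).
#' @export
generate_families <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(config$seed)
  plen <- config$protein_length
  rng <- config$family_size_range
  fams <- list()
  truth <- list()

  for (rel in config$planted_relations) {
    sa <- sample_size(rng)
    sb <- sample_size(rng)
    if (rel$type == "disjoint") {
      fams[[rel$a]] <- alloc_regions(paste0("PRIV_", rel$a), sa, plen)
      fams[[rel$b]] <- alloc_regions(paste0("PRIV_", rel$b), sb, plen)
      inter <- 0L
    } else if (rel$type == "subset") {
      lo <- min(sa, sb); hi <- max(sa, sb)
      if (lo == hi) lo <- hi - 1L
      regs_b <- alloc_regions(paste0("PRIV_", rel$b), hi, plen)
      fams[[rel$b]] <- regs_b
      fams[[rel$a]] <- take_prefix(regs_b, lo)
      sa <- lo; sb <- hi; inter <- lo
    } else { # overlap(fraction)
      inter <- max(1L, round(rel$fraction * sa))
      if (inter >= sa) inter <- sa - 1L
      shared <- alloc_regions(paste0("SHARED_", rel$a, "_", rel$b), inter, plen)
      own_a <- alloc_regions(paste0("PRIV_", rel$a), sa - inter, plen)
      own_b_n <- max(sb - inter, 1L)
      own_b <- alloc_regions(paste0("PRIV_", rel$b), own_b_n, plen)
      fams[[rel$a]] <- rbind(shared, own_a)
      fams[[rel$b]] <- rbind(shared, own_b)
      sb <- inter + own_b_n
    }
    truth[[length(truth) + 1L]] <- data.frame(
      family_a = rel$a, family_b = rel$b, relation = rel$type,
      size_a = sa, size_b = sb, intersection = inter,
      ji = inter / (sa + sb - inter), jc_ab = inter / sa, jc_ba = inter / sb,
      stringsAsFactors = FALSE)
  }

  pool <- sprintf("POOL_P%04d", seq_len(config$protein_count))
  for (fid in setdiff(config$family_ids, names(fams))) {
    size <- sample_size(rng)
    k <- sample.int(min(5L, size), 1L)
    cuts <- if (k > 1L) sort(sample.int(size - 1L, k - 1L)) else integer(0)
    lens <- pmin(diff(c(0L, cuts, size)), plen)
    prot <- sample(pool, length(lens), replace = length(lens) > length(pool))
    starts <- vapply(lens, function(l) sample.int(plen - l + 1L, 1L), integer(1))
    fams[[fid]] <- data.frame(protein_id = prot, start = starts,
                              end = starts + lens - 1L, stringsAsFactors = FALSE)
  }

  families <- lapply(config$family_ids, function(fid) family_regions(fid, fams[[fid]]))
  names(families) <- config$family_ids
  clans <- config$clans
  if (is.null(clans)) clans <- structure(character(0), names = character(0))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(family_a = character(0), family_b = character(0),
               relation = character(0), size_a = numeric(0), size_b = numeric(0),
               intersection = numeric(0), ji = numeric(0), jc_ab = numeric(0),
               jc_ba = numeric(0))

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_regions(families, file.path(dir, "regions.tsv"))
    write_clans(clans, file.path(dir, "clans.tsv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
  }
  list(families = families, clans = clans, truth = truth)
}

#' Fixtures exercising the three overlap scenarios
#'
#' Builds a small family database plus three query families with known
#' classifications: a query on entirely fresh proteins (`novel`), a strict
#' superset of one database family (`single_family` with the superiority
#' flag — increased residue coverage of an existing family), and a query
#' straddling two families of one clan (`multi_family_same_clan`). Family
#' sizes are kept below the default sketch capacity so classifications are
#' exact, not estimates.
#'
#' @param seed Integer seed controlling interval placement.
#' @return A list with `families`, `clans`, `queries` (named list of
#'   [family_regions()]) and `expected` (the recorded expectations).
#' @export
scenario_fixtures <- function(seed = 1L) {
  local_seed(seed)
  plen <- 400L
  db <- list(
    FAM_A   = alloc_regions("PRIV_FAM_A", 100L, plen),
    FAM_B   = alloc_regions("PRIV_FAM_B", 120L, plen),
    CLAN_X1 = alloc_regions("PRIV_CLAN_X1", 100L, plen),
    CLAN_X2 = alloc_regions("PRIV_CLAN_X2", 100L, plen))
  families <- lapply(names(db), function(fid) family_regions(fid, db[[fid]]))
  names(families) <- names(db)
  clans <- c(CLAN_X1 = "CL001", CLAN_X2 = "CL001")

  q_novel <- family_regions("Q_NOVEL", alloc_regions("NOV", 80L, plen))
  q_super <- family_regions("Q_SUPER",
                            rbind(db$FAM_A, alloc_regions("EXTRA_Q_SUPER", 60L, plen)))
  q_clan <- family_regions("Q_CLAN",
                           rbind(take_prefix(db$CLAN_X1, 60L),
                                 take_prefix(db$CLAN_X2, 60L)))
  list(families = families, clans = clans,
       queries = list(novel = q_novel, superset = q_super, clan = q_clan),
       expected = list(
         novel = list(scenario = "novel"),
         superset = list(scenario = "single_family", family = "FAM_A",
                         superior = TRUE, jc_family_in_query = 1.0),
         clan = list(scenario = "multi_family_same_clan",
                     families = c("CLAN_X1", "CLAN_X2"), clan = "CL001")))
}
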