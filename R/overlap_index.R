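SKETCH_FORMAT_VERSION <- 1L

#' Build a searchable index over a database of families
#'
#' Hashes every family once, ahead of time, and stores per family both its
#' bottom-n sketch (for Jaccard index estimation between sketches) and its
#' full hashed set (for containment membership probes). With chunking
#' window `w > 1` the full sets shrink by roughly a factor of `w`, which is
#' the intended mitigation for the memory cost of keeping them.
#'
#' @param families List of [family_regions()] with unique family ids.
#' @param params A [hash_params()] object.
#' @param capacity Sketch size n (default 200).
#' @param clans Optional named character vector mapping family id to clan id.
#' @return An object of class `family_index`.
#' @export
build_index <- function(families, params = hash_params(), capacity = 200L,
                        clans = NULL) {
  if (inherits(families, "family_regions")) families <- list(families)
  if (length(families) == 0L) stop_validation("no families to index")
  ids <- vapply(families, function(f) f$family_id, character(1))
  dup <- duplicated(ids)
  if (any(dup)) {
    stop_validation("duplicate family_id in index input: %s",
                    paste(unique(ids[dup]), collapse = ", "))
  }
  if (is.null(clans)) clans <- structure(character(0), names = character(0))
  entries <- lapply(families, function(f) {
    hs <- build_hashed_set(f, params)
    list(hashed_set = hs, sketch = sketch_of(hs, capacity))
  })
  names(entries) <- ids
  structure(list(params = params, capacity = as.integer(capacity),
                 entries = entries, clans = clans),
            class = "family_index")
}

#' @export
print.family_index <- function(x, ...) {
  cat(sprintf("<family_index> %d families, n=%d, %s seed=%d w=%d, %d clan assignments\n",
              length(x$entries), x$capacity, x$params$hash_name,
              x$params$hash_seed, x$params$window, length(x$clans)))
  invisible(x)
}

#' Compare a query family against every indexed family
#'
#' Hashes and sketches the query with the index parameters, then scores it
#' against each database family: the Jaccard index estimate from the two
#' sketches, the containment of the query in the family
#' (`JC(Q, F)`, query sketch probed against the family's full set), and
#' the containment of the family in the query (`JC(F, Q)`, family sketch
#' probed against the query's full set). Per family the work touches only
#' sketches plus at most n membership probes in each direction, so the cost
#' is governed by n, not by family size.
#'
#' @param query A [family_regions()] object.
#' @param index A `family_index`.
#' @return A data frame of class `comparison_results` with one row per
#'   indexed family: `family_id`, `ji_estimate`, `jc_query_in_family`,
#'   `jc_family_in_query`, `clan_id` (`NA` when unassigned), plus
#'   `query_cardinality` and `family_cardinality` (distinct hashed
#'   elements, used by the superiority rule).
#' @export
compare_query <- function(query, index) {
  stopifnot(inherits(query, "family_regions"), inherits(index, "family_index"))
  if (length(index$entries) == 0L) stop_validation("index is empty")
  qhs <- build_hashed_set(query, index$params)
  qsk <- sketch_of(qhs, index$capacity)
  ids <- names(index$entries)
  ji <- jq <- jf <- fcard <- numeric(length(ids))
  for (k in seq_along(ids)) {
    e <- index$entries[[k]]
    ji[k] <- estimate_jaccard_index(qsk, e$sketch)
    jq[k] <- estimate_containment(qsk, e$hashed_set)
    jf[k] <- estimate_containment(e$sketch, qhs)
    fcard[k] <- e$hashed_set$cardinality
  }
  clan <- unname(index$clans[ids])
  res <- data.frame(family_id = ids, ji_estimate = ji,
                    jc_query_in_family = jq, jc_family_in_query = jf,
                    clan_id = as.character(clan),
                    query_cardinality = qhs$cardinality,
                    family_cardinality = fcard,
                    stringsAsFactors = FALSE)
  class(res) <- c("comparison_results", class(res))
  res
}

#' Classify a query into the overlap scenarios
#'
#' A database family "overlaps" the query when either containment direction
#' reaches `jc_threshold`. The query is then classified as:
#' `novel` (no overlapping family — entirely new residue coverage),
#' `single_family` (exactly one), `multi_family_same_clan` (several, all
#' assigned to one common clan — suggesting a novel clan member or a
#' superior model for a clan member), or `multi_family_mixed` otherwise.
#' An overlapping family is additionally flagged `superior` when the query
#' looks like a strict superset of it: `jc_family_in_query >=
#' superiority_threshold` and the query has more distinct elements, i.e.
#' the candidate offers increased residue coverage of an existing family.
#'
#' @param results A `comparison_results` data frame from [compare_query()].
#' @param clans Optional named clan map; defaults to the `clan_id` column.
#' @param jc_threshold Overlap threshold in (0, 1], default 0.5, applied to
#'   `max(jc_query_in_family, jc_family_in_query)`.
#' @param superiority_threshold Containment level treated as "family fully
#'   inside query" given estimator noise; default 0.95.
#' @return An object of class `overlap_report`: `scenario`, `jc_threshold`,
#'   and `overlapping` (rows above threshold, sorted by
#'   `jc_family_in_query` descending then `family_id`, with a logical
#'   `superior` column).
#' @export
classify <- function(results, clans = NULL, jc_threshold = 0.5,
                     superiority_threshold = 0.95) {
  if (!is.numeric(jc_threshold) || length(jc_threshold) != 1L ||
      jc_threshold <= 0 || jc_threshold > 1) {
    stop_invalid_arg("jc_threshold must lie in (0, 1]")
  }
  if (!is.null(clans) && nrow(results) > 0L) {
    results$clan_id <- as.character(unname(clans[results$family_id]))
  }
  hit <- results[pmax(results$jc_query_in_family, results$jc_family_in_query) >=
                   jc_threshold, , drop = FALSE]
  ord <- order(-hit$jc_family_in_query, hit$family_id)
  hit <- hit[ord, , drop = FALSE]
  rownames(hit) <- NULL
  hit$superior <- hit$jc_family_in_query >= superiority_threshold &
    hit$query_cardinality > hit$family_cardinality
  scenario <- if (nrow(hit) == 0L) {
    "novel"
  } else if (nrow(hit) == 1L) {
    "single_family"
  } else if (!anyNA(hit$clan_id) && length(unique(hit$clan_id)) == 1L) {
    "multi_family_same_clan"
  } else {
    "multi_family_mixed"
  }
  structure(list(scenario = scenario, jc_threshold = jc_threshold,
                 superiority_threshold = superiority_threshold,
                 overlapping = hit),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> scenario: %s (jc_threshold=%.2f)\n",
              x$scenario, x$jc_threshold))
  if (nrow(x$overlapping)) {
    print(x$overlapping[, c("family_id", "ji_estimate", "jc_query_in_family",
                            "jc_family_in_query", "clan_id", "superior")])
  }
  invisible(x)
}

# ---- persistence -----------------------------------------------------------

fmt_u64 <- function(x) sprintf("%.0f", x)

sketch_to_json <- function(family_id, sk) {
  paste0('{"format_version":', SKETCH_FORMAT_VERSION,
         ',"family_id":', jsonlite::toJSON(family_id, auto_unbox = TRUE),
         ',"n":', sk$capacity,
         ',"window":', sk$params$window,
         ',"hash_name":"', sk$params$hash_name, '"',
         ',"hash_seed":', sk$params$hash_seed,
         ',"source_cardinality":', sk$source_cardinality,
         ',"mins":[', paste(fmt_u64(sk$mins), collapse = ","), "]}")
}

sketch_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  params <- hash_params(doc$hash_name, doc$hash_seed, doc$window)
  mins <- as.numeric(doc$mins)
  sk <- structure(list(capacity = as.integer(doc$n), mins = mins,
                       source_cardinality = as.integer(doc$source_cardinality),
                       params = params),
                  class = "minhash_sketch")
  list(family_id = doc$family_id, sketch = sk)
}

#' Persist a family index to a directory
#'
#' Writes `manifest.json` (parameters, capacity, family and clan lists),
#' one `sketches/<family_id>.json` per family, and one
#' `hashsets/<family_id>.txt` per family (the full hashed set as sorted
#' newline-delimited decimal integers). The layout is diff-able and
#' partially loadable; hash values round-trip bit-exactly.
#'
#' @param index A `family_index`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_index <- function(index, dir) {
  stopifnot(inherits(index, "family_index"))
  dir.create(file.path(dir, "sketches"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "hashsets"), recursive = TRUE, showWarnings = FALSE)
  ids <- names(index$entries)
  manifest <- list(format_version = SKETCH_FORMAT_VERSION,
                   hash_name = index$params$hash_name,
                   hash_seed = index$params$hash_seed,
                   window = index$params$window,
                   n = index$capacity,
                   families = as.list(ids),
                   clans = as.list(index$clans))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (fid in ids) {
    e <- index$entries[[fid]]
    writeLines(sketch_to_json(fid, e$sketch),
               file.path(dir, "sketches", paste0(fid, ".json")))
    writeLines(fmt_u64(e$hashed_set$hashes),
               file.path(dir, "hashsets", paste0(fid, ".txt")))
  }
  invisible(dir)
}

#' Load a family index from a directory
#'
#' @param dir Directory written by [write_index()].
#' @return A `family_index`.
#' @export
read_index <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop_validation("no manifest.json in %s", dir)
  man <- jsonlite::fromJSON(man_path)
  params <- hash_params(man$hash_name, man$hash_seed, man$window)
  ids <- unlist(man$families)
  clans <- unlist(man$clans)
  if (is.null(clans)) clans <- structure(character(0), names = character(0))
  entries <- lapply(ids, function(fid) {
    sk <- sketch_from_json(file.path(dir, "sketches", paste0(fid, ".json")))$sketch
    check_params_compatible(sk$params, params, "stored sketch and manifest")
    hashes <- as.numeric(readLines(file.path(dir, "hashsets", paste0(fid, ".txt"))))
    list(hashed_set = new_hashed_set(hashes, params), sketch = sk)
  })
  names(entries) <- ids
  structure(list(params = params, capacity = as.integer(man$n),
                 entries = entries, clans = clans),
            class = "family_index")
}

#' Write an overlap report as JSON and TSV
#'
#' @param report An `overlap_report`.
#' @param json_path Path for the JSON form, or `NULL` to skip.
#' @param tsv_path Path for the per-family TSV table, or `NULL` to skip.
#' @return The report, invisibly.
#' @export
write_report <- function(report, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(report, "overlap_report"))
  ov <- report$overlapping
  if (!is.null(json_path)) {
    doc <- list(scenario = report$scenario,
                jc_threshold = report$jc_threshold,
                superiority_threshold = report$superiority_threshold,
                overlapping = lapply(seq_len(nrow(ov)), function(i) {
                  list(family_id = ov$family_id[i],
                       ji_estimate = ov$ji_estimate[i],
                       jc_query_in_family = ov$jc_query_in_family[i],
                       jc_family_in_query = ov$jc_family_in_query[i],
                       clan_id = if (is.na(ov$clan_id[i])) NULL else ov$clan_id[i],
                       superior = ov$superior[i])
                }))
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(ov, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
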