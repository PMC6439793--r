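#' A named protein family as a set of residue regions
#'
#' A family is a collection of matched regions: `(protein accession,
#' 1-based inclusive start, end)` triples. Overlapping or duplicate
#' intervals are legal (real region tables can abut); the residue-level
#' union is applied at hashing time, not here, so row order and overlaps
#' are preserved exactly as given.
#'
#' @param family_id Non-empty accession string.
#' @param regions Data frame with columns `protein_id`, `start`, `end`.
#' @return An object of class `family_regions`.
#' @export
#' @examples
#' family_regions("FAM1", data.frame(protein_id = "P1", start = 1, end = 50))
family_regions <- function(family_id, regions) {
  family_id <- as.character(family_id)
  if (length(family_id) != 1L || is.na(family_id) || !nzchar(family_id)) {
    stop_validation("family_id must be a non-empty string")
  }
  if (!all(c("protein_id", "start", "end") %in% names(regions))) {
    stop_validation("regions must have protein_id, start and end columns")
  }
  regions <- data.frame(protein_id = as.character(regions$protein_id),
                        start = as.numeric(regions$start),
                        end = as.numeric(regions$end),
                        stringsAsFactors = FALSE)
  if (nrow(regions) == 0L) {
    stop_validation("family '%s' has no regions", family_id)
  }
  bad_acc <- !nzchar(regions$protein_id) | grepl("[\t\n\r]", regions$protein_id)
  if (any(bad_acc)) {
    stop_validation("family '%s': protein accessions must be non-empty and free of tabs/newlines",
                    family_id)
  }
  if (any(is.na(regions$start)) || any(is.na(regions$end)) ||
      any(regions$start != floor(regions$start)) || any(regions$end != floor(regions$end))) {
    stop_validation("family '%s': coordinates must be integers", family_id)
  }
  if (any(regions$start < 1)) {
    stop_validation("family '%s': start coordinates are 1-based and must be >= 1", family_id)
  }
  bad <- regions$start > regions$end
  if (any(bad)) {
    i <- which(bad)[1L]
    stop_validation("family '%s', protein '%s': start %d > end %d",
                    family_id, regions$protein_id[i], regions$start[i], regions$end[i])
  }
  structure(list(family_id = family_id, regions = regions), class = "family_regions")
}

#' @export
print.family_regions <- function(x, ...) {
  cat(sprintf("<family_regions> %s: %d regions on %d proteins, %d residues\n",
              x$family_id, nrow(x$regions), length(unique(x$regions$protein_id)),
              residue_count(x)))
  invisible(x)
}

#' Residue-level size of a family
#'
#' Number of distinct residues covered after the per-protein union of the
#' family's intervals.
#'
#' @param fr A `family_regions` object.
#' @return Integer residue count.
#' @export
residue_count <- function(fr) {
  stopifnot(inherits(fr, "family_regions"))
  parts <- split(fr$regions, fr$regions$protein_id)
  sum(vapply(parts, function(p) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(p$start, p$end))))
  }, numeric(1)))
}

#' Read a family region table
#'
#' Parses a UTF-8 TSV with header columns `family_id`, `protein_id`,
#' `start`, `end` (1-based inclusive residue coordinates) into a list of
#' [family_regions()], grouped by `family_id` in order of first appearance,
#' with row order preserved within each family.
#'
#' @param path Path to the TSV file.
#' @return Named list of `family_regions` objects.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop_validation("regions file not found: %s", path)
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  required <- c("family_id", "protein_id", "start", "end")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop_validation("%s: missing required column(s): %s", path,
                    paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0L) return(structure(list(), names = character(0)))
  line <- seq_len(nrow(tab)) + 1L  # header is line 1
  for (col in c("start", "end")) {
    bad <- !grepl("^[0-9]+$", tab[[col]])
    if (any(bad)) {
      stop_validation("%s line %d: %s '%s' is not a non-negative integer",
                      path, line[which(bad)[1L]], col, tab[[col]][which(bad)[1L]])
    }
  }
  start <- as.numeric(tab$start)
  end <- as.numeric(tab$end)
  bad <- start > end
  if (any(bad)) {
    i <- which(bad)[1L]
    stop_validation("%s line %d: start %d > end %d (family '%s', protein '%s')",
                    path, line[i], start[i], end[i], tab$family_id[i], tab$protein_id[i])
  }
  if (any(start < 1)) {
    i <- which(start < 1)[1L]
    stop_validation("%s line %d: coordinates are 1-based; start must be >= 1",
                    path, line[i])
  }
  ids <- unique(tab$family_id)
  fams <- lapply(ids, function(fid) {
    rows <- tab$family_id == fid
    family_regions(fid, data.frame(protein_id = tab$protein_id[rows],
                                   start = start[rows], end = end[rows],
                                   stringsAsFactors = FALSE))
  })
  names(fams) <- ids
  fams
}

#' Write a family region table
#'
#' Inverse of [read_regions()]: writes the 4-column TSV dialect. A
#' write-then-read round trip reproduces the input exactly.
#'
#' @param families A `family_regions` object or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(families, path) {
  if (inherits(families, "family_regions")) families <- list(families)
  rows <- do.call(rbind, lapply(families, function(f) {
    data.frame(family_id = f$family_id, protein_id = f$regions$protein_id,
               start = f$regions$start, end = f$regions$end,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(family_id = character(0), protein_id = character(0),
                       start = numeric(0), end = numeric(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a family-to-clan mapping
#'
#' Parses a TSV with columns `family_id`, `clan_id`. Families without a
#' clan are simply absent from the file. Duplicate rows for a family are
#' tolerated when consistent and rejected when they conflict.
#'
#' @param path Path to the TSV, or `NULL` for an empty map (clan logic
#'   disabled).
#' @return Named character vector mapping `family_id` to `clan_id`.
#' @export
read_clans <- function(path = NULL) {
  if (is.null(path)) return(structure(character(0), names = character(0)))
  if (!file.exists(path)) stop_validation("clans file not found: %s", path)
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(c("family_id", "clan_id"), names(tab))
  if (length(missing)) {
    stop_validation("%s: missing required column(s): %s", path,
                    paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0L) return(structure(character(0), names = character(0)))
  agg <- tapply(tab$clan_id, tab$family_id, function(x) unique(x), simplify = FALSE)
  conflict <- vapply(agg, length, integer(1)) > 1L
  if (any(conflict)) {
    fid <- names(agg)[conflict][1L]
    stop_validation("%s: family '%s' is mapped to multiple clans: %s",
                    path, fid, paste(agg[[fid]], collapse = ", "))
  }
  # keep first-appearance order
  ids <- unique(tab$family_id)
  structure(vapply(agg[ids], `[`, character(1), 1L), names = ids)
}

#' Write a family-to-clan mapping
#'
#' @param clans Named character vector (names are family ids, values clans).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clans <- function(clans, path) {
  utils::write.table(data.frame(family_id = names(clans),
                                clan_id = unname(clans),
                                stringsAsFactors = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
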