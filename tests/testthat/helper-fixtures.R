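# Shared fixture builders. All constructions are residue-exact at w = 1:
# a planted pair places its shared residues on one protein and each
# family's private residues on family-private proteins, so |A|, |B| and
# |A n B| are known by construction.

fam_interval <- function(id, pid, start, end) {
  family_regions(id, data.frame(protein_id = pid, start = start, end = end,
                                stringsAsFactors = FALSE))
}

# Pair of families with exact sizes and intersection (w = 1 semantics).
planted_pair <- function(tag, size_a, size_b, inter) {
  stopifnot(inter <= size_a, inter <= size_b)
  mk <- function(id, own_pid, own_n) {
    rows <- list()
    if (inter > 0) {
      rows[[1]] <- data.frame(protein_id = paste0("SH_", tag),
                              start = 1, end = inter, stringsAsFactors = FALSE)
    }
    if (own_n > 0) {
      rows[[length(rows) + 1L]] <- data.frame(protein_id = own_pid,
                                              start = 1, end = own_n,
                                              stringsAsFactors = FALSE)
    }
    family_regions(id, do.call(rbind, rows))
  }
  list(a = mk(paste0(tag, "_A"), paste0("OA_", tag), size_a - inter),
       b = mk(paste0(tag, "_B"), paste0("OB_", tag), size_b - inter),
       size_a = size_a, size_b = size_b, inter = inter)
}

# Independent residue-level oracle: enumerates (protein, residue) strings
# from the raw regions with base set operations, no hashing involved.
residue_set <- function(fr) {
  unique(unlist(lapply(seq_len(nrow(fr$regions)), function(i) {
    r <- fr$regions[i, ]
    paste0(r$protein_id, "::", seq.int(r$start, r$end))
  })))
}

residue_ji <- function(fa, fb) {
  a <- residue_set(fa); b <- residue_set(fb)
  length(intersect(a, b)) / length(union(a, b))
}

residue_jc <- function(fa, fb) {
  a <- residue_set(fa); b <- residue_set(fb)
  length(intersect(a, b)) / length(a)
}

# Random residue-exact pair under the current RNG state.
random_planted_pair <- function(tag, max_size = 500L) {
  sa <- sample(10:max_size, 1L)
  sb <- sample(10:max_size, 1L)
  inter <- sample(0:min(sa, sb), 1L)
  planted_pair(tag, sa, sb, inter)
}
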