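# In-code fixture builders shared across test files.

# Minimal scheme with explicit barcode/spacer/priming choices.
toy_scheme <- function(fwd_bc, rev_bc,
                       fwd_sp = rep("", length(fwd_bc)),
                       rev_sp = rep("", length(rev_bc)),
                       priming_fwd = "GTGYCAGCMGCCGCGGTAA",
                       priming_rev = "GGACTACNVGGGTWTCTAAT") {
  structure(list(
    parts = primer_parts("ACACGACGCT", "GACGTGTGCT",
                         priming_fwd = priming_fwd,
                         priming_rev = priming_rev),
    fwd = barcode_set(paste0("f", seq_along(fwd_bc)), fwd_bc, fwd_sp, "forward"),
    rev = barcode_set(paste0("r", seq_along(rev_bc)), rev_bc, rev_sp, "reverse")),
    class = "scheme_spec")
}

# Deterministic random DNA string.
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force single-factor PERMANOVA R2 from the pairwise-sum partition:
# SS_total = sum_{i<j} d_ij^2 / n, SS_within = sum over groups of the
# within-group pairwise sums each divided by the group size.
permanova_r2_bruteforce <- function(D, g) {
  n <- nrow(D)
  ss_total <- sum(D[lower.tri(D)]^2) / n
  ss_within <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    if (length(idx) > 1) {
      sub <- D[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]^2) / length(idx)
    }
  }
  (ss_total - ss_within) / ss_total
}
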