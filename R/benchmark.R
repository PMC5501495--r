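## Mock-community benchmarking: exact-identity read assignment against a
## reference of V4 fragments, OTU-table construction, common scaling,
## rare-OTU filtering, deviation / GC-bias / chimera statistics, and
## Bray-Curtis variance partitioning (PERMANOVA, ANOSIM) via vegan.
##
## Community matrices follow the vegan convention: plain numeric
## matrices, samples in rows, species in columns.

#' Construct a reference database of V4 fragments
#'
#' @param id species identifiers
#' @param sequence fragment sequences (must be unique)
#' @return data.frame of class `reference_db` with columns id, sequence,
#'   gc
#' @export
reference_db <- function(id, sequence) {
  if (anyDuplicated(sequence)) {
    stop("duplicate fragments in reference", call. = FALSE)
  }
  if (anyDuplicated(id)) stop("duplicate reference ids", call. = FALSE)
  out <- data.frame(id = as.character(id), sequence = toupper(sequence),
                    gc = gc_fraction(sequence), stringsAsFactors = FALSE)
  class(out) <- c("reference_db", "data.frame")
  out
}

#' Load a reference database from FASTA
#' @param path FASTA of fragments, one record per species
#' @export
read_reference_fasta <- function(path) {
  seqs <- read_fasta(path)
  reference_db(names(seqs), unname(seqs))
}

#' @rdname reference_db
#' @param templates a [template_set()]
#' @export
ref_from_templates <- function(templates) {
  reference_db(templates$id, templates$sequence)
}

#' Assign fragments to reference species by exact identity
#'
#' A fragment counts for a species iff it equals that species' reference
#' fragment exactly, in either orientation (hash lookup; equivalent to
#' requiring a full-length alignment at 100% identity). Everything else
#' is unassigned.
#'
#' @param fragments character vector of primer-trimmed merged fragments
#' @param ref a [reference_db()]
#' @return list with `counts` (named integer vector per species),
#'   `assigned` (per-fragment species id or NA), `n_unassigned`
#' @export
assign_reads <- function(fragments, ref) {
  hit <- match(fragments, ref$sequence)
  miss <- is.na(hit)
  if (any(miss)) {
    hit[miss] <- match(revcomp(fragments[miss]), ref$sequence)
  }
  species <- ref$id[hit]
  counts <- table(factor(species, levels = ref$id))
  list(counts = stats::setNames(as.integer(counts), ref$id),
       assigned = species,
       n_unassigned = sum(is.na(species)))
}

#' Build an OTU count matrix from demultiplexed, merged fragments
#'
#' @param sample_id per-fragment sample assignment
#' @param fragment per-fragment sequence
#' @param ref a [reference_db()]
#' @return list with `counts` (samples x species matrix) and
#'   `unassigned` (per-sample count of fragments matching no reference)
#' @export
build_otu_table <- function(sample_id, fragment, ref) {
  keep <- !is.na(sample_id) & !is.na(fragment)
  sample_id <- sample_id[keep]; fragment <- fragment[keep]
  asg <- assign_reads(fragment, ref)
  samples <- sort(unique(sample_id))
  counts <- table(factor(sample_id, levels = samples),
                  factor(asg$assigned, levels = ref$id))
  counts <- matrix(as.integer(counts), nrow = length(samples),
                   dimnames = list(samples, ref$id))
  unassigned <- tapply(is.na(asg$assigned), factor(sample_id, levels = samples), sum)
  list(counts = counts, unassigned = stats::setNames(as.integer(unassigned), samples))
}

#' Ground-truth OTU table from a simulator truth table
#'
#' @param truth a truth data.frame from [sample_reads()] /
#'   [simulate_experiment()]
#' @param species reference species ids defining the column order
#' @param include_chimeras count chimeric reads (under their first
#'   parent)? Default FALSE, matching an exact-identity assignment in
#'   which chimeras match nothing.
#' @return samples x species count matrix
#' @export
truth_otu <- function(truth, species, include_chimeras = FALSE) {
  if (!include_chimeras) truth <- truth[!truth$is_chimera, , drop = FALSE]
  samples <- sort(unique(truth$sample_id))
  counts <- table(factor(truth$sample_id, levels = samples),
                  factor(truth$parent1, levels = species))
  matrix(as.integer(counts), nrow = length(samples),
         dimnames = list(samples, species))
}

#' Common scaling of library sizes
#'
#' Multiplies each library's counts by (smallest library size / own
#' size); the library-scaling equivalent of averaging infinitely many
#' rarefactions. No rounding is applied.
#'
#' @param counts samples x species count matrix
#' @return scaled matrix; every row sums to the smallest library size
#' @export
common_scale <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) == 0) {
    stop("counts must be a non-empty matrix", call. = FALSE)
  }
  sizes <- rowSums(counts)
  if (any(sizes <= 0)) stop("all library sizes must be positive", call. = FALSE)
  counts * (min(sizes) / sizes)
}

#' Convert counts to relative abundances
#' @param counts samples x species matrix
#' @return matrix with rows summing to 1
#' @export
relative_abundance <- function(counts) {
  sizes <- rowSums(counts)
  if (any(sizes <= 0)) stop("all library sizes must be positive", call. = FALSE)
  counts / sizes
}

#' Drop OTUs of low average relative abundance
#'
#' @param rel samples x species relative-abundance matrix (rows sum
#'   to 1)
#' @param threshold minimum column mean to keep (default 1e-4, i.e.
#'   0.01%)
#' @param renormalize rescale rows to sum to 1 afterwards? Default FALSE.
#' @return filtered matrix
#' @export
filter_rare <- function(rel, threshold = 1e-4, renormalize = FALSE) {
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  keep <- colMeans(rel) >= threshold
  out <- rel[, keep, drop = FALSE]
  if (renormalize) out <- out / rowSums(out)
  out
}

#' Mean absolute deviation from expected species proportions
#'
#' For each species, the absolute difference between its mean observed
#' relative abundance and its expected proportion, in percentage points;
#' `overall` averages these over species. Per-species means and standard
#' deviations of the observed abundances (in percentage points) are also
#' returned.
#'
#' @param rel samples x species relative-abundance matrix
#' @param expected vector of expected proportions, one per species
#'   (default equal proportions; a subset of a community may be assessed
#'   against its nominal per-species expectation, so the vector need not
#'   sum to 1)
#' @return list with `overall` (scalar, percentage points),
#'   `per_species` (data.frame species, mean_pct, sd_pct, expected_pct,
#'   abs_dev_pct)
#' @export
mean_abs_deviation_from_expected <- function(rel,
                                             expected = rep(1 / ncol(rel), ncol(rel))) {
  if (length(expected) != ncol(rel)) {
    stop("expected proportions do not match the species columns", call. = FALSE)
  }
  mean_obs <- colMeans(rel)
  sd_obs <- apply(rel, 2, stats::sd)
  dev <- abs(mean_obs - expected) * 100
  list(overall = mean(dev),
       per_species = data.frame(species = colnames(rel),
                                mean_pct = mean_obs * 100,
                                sd_pct = sd_obs * 100,
                                expected_pct = expected * 100,
                                abs_dev_pct = dev,
                                row.names = NULL,
                                stringsAsFactors = FALSE))
}

#' Regression of mean relative abundance on GC content
#'
#' Ordinary least squares of per-species mean relative abundance (in %)
#' on fragment GC content (in %); the slope is the abundance change in
#' percentage points per 1% GC.
#'
#' @param mean_rel_pct per-species mean relative abundance, percent
#' @param gc_pct per-species GC content, percent
#' @return list with `slope`, `intercept`, `p_value`, `r_squared`, `fit`
#' @export
gc_bias_slope <- function(mean_rel_pct, gc_pct) {
  if (length(mean_rel_pct) < 3) stop("need at least 3 species", call. = FALSE)
  if (stats::sd(gc_pct) == 0) stop("GC content is constant", call. = FALSE)
  fit <- stats::lm(mean_rel_pct ~ gc_pct)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = unname(sm$coefficients[2, 4]),
       r_squared = sm$r.squared,
       fit = fit)
}

#' Chimera rate statistics from a simulator truth table
#'
#' @param truth truth data.frame (with `is_chimera` and `chimera_seq`);
#'   may span several samples
#' @return data.frame per sample: `sample_id`, `n_reads`,
#'   `chimera_fraction` (chimeric reads / reads) and `singleton_fraction`
#'   (distinct chimeric sequences seen exactly once / distinct chimeric
#'   sequences; NA when a sample has no chimeras)
#' @export
chimera_stats <- function(truth) {
  samples <- sort(unique(truth$sample_id))
  out <- lapply(samples, function(s) {
    tt <- truth[truth$sample_id == s, , drop = FALSE]
    n <- nrow(tt)
    n_chim <- sum(tt$is_chimera)
    singleton <- NA_real_
    if (n_chim > 0) {
      occ <- table(tt$chimera_seq[tt$is_chimera])
      singleton <- sum(occ == 1) / length(occ)
    }
    data.frame(sample_id = s, n_reads = n,
               chimera_fraction = n_chim / n,
               singleton_fraction = singleton,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Regression of chimera fraction on PCR cycle number
#'
#' @param cycles per-sample cycle counts (first-stage or total)
#' @param chimera_fraction per-sample chimera fractions
#' @return list with `slope` (per cycle), `r_squared`, `p_value`, `fit`
#' @export
chimera_cycle_regression <- function(cycles, chimera_fraction) {
  if (length(unique(cycles)) < 2) {
    stop("cycle counts are constant", call. = FALSE)
  }
  if (length(cycles) < 3) stop("need at least 3 samples", call. = FALSE)
  fit <- stats::lm(chimera_fraction ~ cycles)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       fit = fit)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(i, j) = 1 - 2 sum_k min(x_ik, x_jk) / sum_k (x_ik + x_jk), computed
#' with vegan. Symmetric with zero diagonal; values in [0, 1] for
#' non-negative data.
#'
#' @param x samples x species abundance matrix (counts or relative)
#' @return full symmetric matrix with sample labels
#' @export
bray_curtis_matrix <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (any(rowSums(x) == 0)) stop("all-zero sample row", call. = FALSE)
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' PERMANOVA variance partitioning of a distance matrix
#'
#' Partitions the (Gower-centered) sums of squares of a distance matrix
#' by one or more factors with sequential (order-dependent) sums of
#' squares, reporting R-squared per factor; significance by permutation
#' of sample labels (vegan's adonis2).
#'
#' @param d distance matrix (full symmetric matrix or `dist`)
#' @param grouping a factor, or a data.frame of factors; with several
#'   columns terms enter the model in column order
#' @param n_perm number of permutations (default 10000)
#' @param seed RNG seed for the permutations
#' @return data.frame with one row per term plus Residual/Total: `term`,
#'   `df`, `ss`, `r2`, `f`, `p_value`
#' @export
permanova_r2 <- function(d, grouping, n_perm = 10000L, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  d <- stats::as.dist(d)
  if (attr(d, "Size") < 2) stop("need at least 2 samples", call. = FALSE)
  if (!is.data.frame(grouping)) grouping <- data.frame(group = grouping)
  grouping[] <- lapply(grouping, function(col) factor(col))
  if (any(vapply(grouping, nlevels, integer(1)) < 1)) {
    stop("grouping factors need at least one level", call. = FALSE)
  }
  set.seed(seed)
  form <- stats::as.formula(paste("d ~", paste(names(grouping), collapse = " + ")))
  fit <- vegan::adonis2(form, data = grouping, permutations = n_perm,
                        by = "terms")
  data.frame(term = rownames(fit), df = fit$Df, ss = fit$SumOfSqs,
             r2 = fit$R2, f = fit$F, p_value = fit$`Pr(>F)`,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' ANOSIM on a distance matrix
#'
#' R = (mean between-group rank - mean within-group rank) / (M/2) with M
#' = n(n-1)/2 and mid-ranked ties; significance by permutation (vegan).
#'
#' @inheritParams permanova_r2
#' @param grouping a factor with at least 2 groups
#' @return list with `R` and `p_value`
#' @export
anosim_r <- function(d, grouping, n_perm = 10000L, seed = 1L) {
  d <- stats::as.dist(d)
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2) stop("need at least 2 groups", call. = FALSE)
  set.seed(seed)
  fit <- vegan::anosim(d, grouping, permutations = n_perm)
  list(R = unname(fit$statistic), p_value = fit$signif)
}

#' Pairwise Spearman correlations between samples
#'
#' Spearman rank correlation between every pair of samples'
#' species-abundance vectors; a constant vector yields NA against all
#' others.
#'
#' @param rel samples x species abundance matrix (>= 2 species)
#' @return samples x samples correlation matrix, unit diagonal
#' @export
spearman_matrix <- function(rel) {
  if (ncol(rel) < 2) stop("need at least 2 species", call. = FALSE)
  out <- suppressWarnings(stats::cor(t(rel), method = "spearman"))
  diag(out) <- 1
  out
}
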