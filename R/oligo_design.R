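## Oligo assembly, plate layout generation and the multiplexing cost
## arithmetic of the triple-indexing scheme.

#' Assemble a complete PCR1 primer from its four parts
#'
#' The PCR1 primer is, 5' to 3': partial Illumina adapter, 12-nt internal
#' barcode, heterogeneity spacer (0-7 nt), gene-priming sequence.
#'
#' @param parts a [primer_parts()] object
#' @param barcode one row of a [barcode_set()] (data.frame with `sequence`,
#'   `spacer`, `direction`)
#' @param direction which primer to assemble; must agree with the
#'   barcode's direction
#' @return the full oligo as a character string
#' @export
assemble_pcr1_primer <- function(parts, barcode,
                                 direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (nrow(barcode) != 1) stop("expected a single barcode row", call. = FALSE)
  if (barcode$direction != direction) {
    stop("barcode '", barcode$name, "' is a ", barcode$direction,
         " barcode; cannot assemble a ", direction, " primer", call. = FALSE)
  }
  adapter <- if (direction == "forward") parts$partial_adapter_fwd else parts$partial_adapter_rev
  priming <- if (direction == "forward") parts$priming_fwd else parts$priming_rev
  if (!nzchar(priming)) stop("empty priming sequence", call. = FALSE)
  paste0(adapter, barcode$sequence, barcode$spacer, priming)
}

#' Generate a plate layout from forward and reverse barcode sets
#'
#' Takes the Cartesian product of forward and reverse PCR1 barcodes in
#' forward-major order, optionally excluding pairs whose barcode
#' sequences are identical (such pairs form high-melting-temperature
#' hairpins and yield roughly tenfold fewer reads), and fills wells
#' row-major A1..H12 up to the plate size.
#'
#' @param fwd,rev [barcode_set()] objects
#' @param exclude_identical drop pairs with identical barcode sequences?
#' @param plate_size maximum number of wells (default 96)
#' @param pool_index name of the PCR2 (pool) index attached to this plate
#' @return object of class `plate_layout`: list with `wells` (data.frame
#'   well/fwd/rev), `excluded` (data.frame fwd/rev/reason), `pool_index`
#' @export
build_plate_layout <- function(fwd, rev, exclude_identical = FALSE,
                               plate_size = 96L, pool_index = "p1") {
  stopifnot(inherits(fwd, "barcode_set"), inherits(rev, "barcode_set"))
  if (nrow(fwd) == 0 || nrow(rev) == 0) {
    stop("barcode sets must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(c(fwd$name, rev$name))) {
    stop("duplicate barcode names across forward and reverse sets",
         call. = FALSE)
  }
  combos <- expand.grid(rev_i = seq_len(nrow(rev)), fwd_i = seq_len(nrow(fwd)),
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[order(combos$fwd_i, combos$rev_i), , drop = FALSE]
  fwd_name <- fwd$name[combos$fwd_i]
  rev_name <- rev$name[combos$rev_i]
  identical_pair <- fwd$sequence[combos$fwd_i] == rev$sequence[combos$rev_i]

  excluded <- data.frame(fwd = character(0), rev = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(combos))
  if (exclude_identical && any(identical_pair)) {
    excluded <- data.frame(fwd = fwd_name[identical_pair],
                           rev = rev_name[identical_pair],
                           reason = "identical-index hairpin risk",
                           stringsAsFactors = FALSE)
    keep <- !identical_pair
  }
  fwd_name <- fwd_name[keep]
  rev_name <- rev_name[keep]
  n_wells <- min(plate_size, length(fwd_name))
  well_ids <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
  if (n_wells > length(well_ids)) {
    well_ids <- paste0("W", seq_len(n_wells))  # oversized "plate"
  }
  wells <- data.frame(well = well_ids[seq_len(n_wells)],
                      fwd = fwd_name[seq_len(n_wells)],
                      rev = rev_name[seq_len(n_wells)],
                      stringsAsFactors = FALSE)
  structure(list(wells = wells, excluded = excluded,
                 pool_index = pool_index,
                 identical_pairs = sum(identical_pair)),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %d wells (pool %s), %d pair(s) excluded\n",
              nrow(x$wells), x$pool_index, nrow(x$excluded)))
  invisible(x)
}

#' Oligo cost of the triple-indexing scheme
#'
#' Triple indexing reuses one fixed plate's worth of PCR1 primers
#' (default 12 forward + 8 reverse) for every plate and distinguishes
#' plates by the PCR2 reverse index, so the oligo count grows by one per
#' additional 96 samples: 12 + 8 + 1 universal PCR2 forward +
#' ceiling(n / plate_size) indexed PCR2 reverse primers.
#'
#' @param n_samples number of samples to multiplex
#' @param plate_size samples per plate (default 96)
#' @param n_fwd,n_rev sizes of the PCR1 barcode sets (defaults 12 and 8)
#' @param max_pcr2_indices number of distinct PCR2 indices available;
#'   exceeding it is an error reporting the shortfall
#' @return object of class `scheme_cost`
#' @export
count_oligos_triple <- function(n_samples, plate_size = 96L,
                                n_fwd = 12L, n_rev = 8L,
                                max_pcr2_indices = Inf) {
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  n_plates <- ceiling(n_samples / plate_size)
  if (n_plates > max_pcr2_indices) {
    stop(sprintf(
      "need %d PCR2 indices for %d samples but only %d available (shortfall %d)",
      n_plates, n_samples, max_pcr2_indices, n_plates - max_pcr2_indices),
      call. = FALSE)
  }
  breakdown <- c(pcr1_fwd = as.integer(n_fwd), pcr1_rev = as.integer(n_rev),
                 pcr2_fwd = 1L, pcr2_rev = as.integer(n_plates))
  structure(list(scheme = "triple", n_samples = as.integer(n_samples),
                 plate_size = as.integer(plate_size),
                 breakdown = breakdown,
                 n_oligos = sum(breakdown)),
            class = "scheme_cost")
}

#' Oligo cost of the two-step dual-indexing alternative
#'
#' With dual indexing the sample identity is carried entirely by the
#' indexed PCR2 forward x reverse pair, so i forward and j reverse
#' indexed oligos cover i*j samples; the count minimises i + j subject to
#' i*j >= n (plus the 2 universal PCR1 oligos), which scales with the
#' square root of n per index set, i.e. quadratically in samples for a
#' fixed set.
#'
#' @param n_samples number of samples
#' @return object of class `scheme_cost`
#' @export
count_oligos_dual_alternative <- function(n_samples) {
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  best_i <- 1L
  best_j <- as.integer(ceiling(n_samples))
  best <- best_i + best_j
  for (i in seq_len(ceiling(sqrt(n_samples)) + 1)) {
    j <- as.integer(ceiling(n_samples / i))
    if (i + j < best) {
      best <- i + j
      best_i <- as.integer(i)
      best_j <- j
    }
  }
  breakdown <- c(pcr1_fwd = 1L, pcr1_rev = 1L,
                 pcr2_fwd = best_i, pcr2_rev = best_j)
  structure(list(scheme = "dual", n_samples = as.integer(n_samples),
                 plate_size = NA_integer_,
                 breakdown = breakdown,
                 n_oligos = sum(breakdown)),
            class = "scheme_cost")
}

#' @export
print.scheme_cost <- function(x, ...) {
  cat(sprintf("<scheme_cost> %s indexing, %d samples: %d oligos\n",
              x$scheme, x$n_samples, x$n_oligos))
  cat("  ", paste(names(x$breakdown), x$breakdown, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-position base composition over a plate's read-start constructs
#'
#' Illumina cluster calling needs balanced A/C/G/T fractions over the
#' first sequencing cycles; the heterogeneity spacers stagger the shared
#' priming sequence across read positions to restore that balance. This
#' diagnostic computes, for each of the first `prefix_len` read
#' positions, the base fractions over all wells (equally weighted).
#' Degenerate IUPAC positions in the priming sequence contribute
#' fractionally to each base they allow; positions beyond a well's
#' construct contribute nothing for that well.
#'
#' @param layout a [build_plate_layout()] result
#' @param scheme a `scheme_spec` resolving barcode names to sequences
#' @param prefix_len number of read positions to tabulate
#' @param direction which mate's construct to analyse
#' @return matrix `prefix_len` x 4 (columns A, C, G, T); rows sum to 1
#' @export
positional_base_composition <- function(layout, scheme, prefix_len = 31L,
                                        direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (prefix_len <= 0) stop("prefix_len must be positive", call. = FALSE)
  set <- if (direction == "forward") scheme$fwd else scheme$rev
  priming <- if (direction == "forward") scheme$parts$priming_fwd else scheme$parts$priming_rev
  key <- if (direction == "forward") "fwd" else "rev"
  idx <- match(layout$wells[[key]], set$name)
  if (anyNA(idx)) stop("layout references unknown barcode names", call. = FALSE)
  constructs <- paste0(set$sequence[idx], set$spacer[idx], priming)

  counts <- matrix(0, nrow = prefix_len, ncol = 4,
                   dimnames = list(NULL, DNA_BASES))
  for (s in constructs) {
    L <- min(nchar(s), prefix_len)
    if (L == 0) next
    chars <- strsplit(substr(s, 1, L), "")[[1]]
    for (p in seq_len(L)) {
      bases <- iupac_expand(chars[p])
      counts[p, bases] <- counts[p, bases] + 1 / length(bases)
    }
  }
  sums <- rowSums(counts)
  if (any(sums == 0)) {
    stop("no construct reaches position ", which(sums == 0)[1], call. = FALSE)
  }
  counts / sums
}
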