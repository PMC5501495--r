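## Primer/barcode table I/O and the scheme container.
##
## The on-disk format is a TSV with columns
##   name, direction, adapter, barcode, spacer, priming, full_oligo
## where direction is one of "forward", "reverse" (PCR1 primers with
## 12-nt internal barcodes and 0-7 nt heterogeneity spacers),
## "pcr2_forward" (single universal oligo) or "pcr2_reverse" (one row per
## 6-nt pool index). full_oligo must equal the concatenation
## adapter + barcode + spacer + priming and is validated on load.

PCR1_BARCODE_LEN <- 12L
SPACER_MAX <- 7L
PCR2_INDEX_LEN <- 6L

#' Construct a barcode set
#'
#' A barcode set holds the internal (PCR1) barcodes for one primer
#' direction, together with each barcode's heterogeneity spacer.
#'
#' @param name character vector of barcode names (e.g. "f1", "r10")
#' @param sequence character vector of barcode sequences (equal length,
#'   A/C/G/T only)
#' @param spacer character vector of spacer sequences (0-7 nt)
#' @param direction "forward" or "reverse"
#' @return object of class `barcode_set` (a data.frame)
#' @export
barcode_set <- function(name, sequence, spacer, direction) {
  direction <- match.arg(direction, c("forward", "reverse"))
  sequence <- toupper(sequence)
  spacer <- toupper(spacer)
  if (anyDuplicated(name)) {
    stop("duplicate barcode names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "), call. = FALSE)
  }
  assert_dna(sequence, "barcode")
  if (any(nzchar(spacer))) assert_dna(spacer[nzchar(spacer)], "spacer")
  if (length(unique(nchar(sequence))) > 1) {
    stop("all ", direction, " barcodes must have the same length", call. = FALSE)
  }
  if (any(nchar(spacer) > SPACER_MAX)) {
    stop("spacer length exceeds ", SPACER_MAX, " nt", call. = FALSE)
  }
  out <- data.frame(name = name, sequence = sequence, spacer = spacer,
                    direction = direction, stringsAsFactors = FALSE)
  class(out) <- c("barcode_set", "data.frame")
  out
}

#' @export
print.barcode_set <- function(x, ...) {
  cat(sprintf("<barcode_set> %d %s barcodes (%d nt), spacers %d-%d nt, min Hamming %s\n",
              nrow(x), x$direction[1], nchar(x$sequence[1]),
              min(nchar(x$spacer)), max(nchar(x$spacer)),
              format(min_pairwise_hamming(x$sequence))))
  invisible(x)
}

#' Construct the fixed primer parts of the two-stage design
#'
#' @param partial_adapter_fwd,partial_adapter_rev 5' partial Illumina
#'   adapters on the PCR1 forward/reverse primers
#' @param priming_fwd,priming_rev 3' gene-priming sequences (IUPAC codes
#'   allowed; defaults are the V4 515f/806r pair)
#' @param pcr2_adapter_fwd,pcr2_adapter_rev remaining Illumina adapters
#'   added during PCR2
#' @param pcr2_indices character vector of 6-nt pool indices carried by
#'   the PCR2 reverse primers
#' @return object of class `primer_parts`
#' @export
primer_parts <- function(partial_adapter_fwd, partial_adapter_rev,
                         priming_fwd = "GTGYCAGCMGCCGCGGTAA",
                         priming_rev = "GGACTACNVGGGTWTCTAAT",
                         pcr2_adapter_fwd = "",
                         pcr2_adapter_rev = "",
                         pcr2_indices = character(0)) {
  if (!nzchar(priming_fwd) || !nzchar(priming_rev)) {
    stop("priming sequences must be non-empty", call. = FALSE)
  }
  assert_dna(c(priming_fwd, priming_rev), "priming sequence", iupac = TRUE)
  assert_dna(c(partial_adapter_fwd, partial_adapter_rev), "adapter")
  if (length(pcr2_indices) && any(nchar(pcr2_indices) != PCR2_INDEX_LEN)) {
    stop("PCR2 indices must all be ", PCR2_INDEX_LEN, " nt", call. = FALSE)
  }
  structure(list(partial_adapter_fwd = toupper(partial_adapter_fwd),
                 partial_adapter_rev = toupper(partial_adapter_rev),
                 priming_fwd = toupper(priming_fwd),
                 priming_rev = toupper(priming_rev),
                 pcr2_adapter_fwd = toupper(pcr2_adapter_fwd),
                 pcr2_adapter_rev = toupper(pcr2_adapter_rev),
                 pcr2_indices = toupper(pcr2_indices)),
            class = "primer_parts")
}

#' Read a primer table and assemble the indexing scheme
#'
#' Validates that the `full_oligo` column equals the concatenation of the
#' part columns, that barcodes are uniquely decodable at the requested
#' mismatch tolerance, and partitions rows into PCR1 barcode sets and the
#' fixed primer parts.
#'
#' @param path TSV file (see package vignette for the column contract)
#' @param barcode_mismatch_max mismatch tolerance the barcode sets must
#'   support; each direction's minimum pairwise Hamming distance must
#'   exceed twice this value
#' @return object of class `scheme_spec`: list with elements `parts`
#'   (primer_parts), `fwd` and `rev` (barcode_set)
#' @export
read_primer_table <- function(path, barcode_mismatch_max = 0L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  required <- c("name", "direction", "adapter", "barcode", "spacer",
                "priming", "full_oligo")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("primer table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  scheme_from_table(tab, barcode_mismatch_max = barcode_mismatch_max)
}

#' @rdname read_primer_table
#' @param tab a data.frame with the primer-table columns
#' @export
scheme_from_table <- function(tab, barcode_mismatch_max = 0L) {
  for (col in c("adapter", "barcode", "spacer", "priming", "full_oligo")) {
    tab[[col]] <- toupper(tab[[col]])
  }
  recon <- paste0(tab$adapter, tab$barcode, tab$spacer, tab$priming)
  bad <- recon != tab$full_oligo
  if (any(bad)) {
    stop("full_oligo does not equal adapter+barcode+spacer+priming for: ",
         paste(tab$name[bad], collapse = ", "), call. = FALSE)
  }

  pick <- function(d) tab[tab$direction == d, , drop = FALSE]
  fwd_rows <- pick("forward"); rev_rows <- pick("reverse")
  p2f <- pick("pcr2_forward"); p2r <- pick("pcr2_reverse")
  if (nrow(fwd_rows) == 0 || nrow(rev_rows) == 0) {
    stop("primer table must contain forward and reverse PCR1 rows",
         call. = FALSE)
  }
  one <- function(x, what) {
    u <- unique(x)
    if (length(u) != 1) stop("expected a single ", what, call. = FALSE)
    u
  }
  fwd <- barcode_set(fwd_rows$name, fwd_rows$barcode, fwd_rows$spacer, "forward")
  rev <- barcode_set(rev_rows$name, rev_rows$barcode, rev_rows$spacer, "reverse")
  for (set in list(fwd, rev)) {
    dmin <- min_pairwise_hamming(set$sequence)
    if (!(barcode_mismatch_max < dmin / 2)) {
      stop(set$direction[1], " barcode set is not uniquely decodable at ",
           barcode_mismatch_max, " mismatches (min pairwise Hamming distance ",
           dmin, ")", call. = FALSE)
    }
  }
  parts <- primer_parts(
    partial_adapter_fwd = one(fwd_rows$adapter, "forward partial adapter"),
    partial_adapter_rev = one(rev_rows$adapter, "reverse partial adapter"),
    priming_fwd = one(fwd_rows$priming, "forward priming sequence"),
    priming_rev = one(rev_rows$priming, "reverse priming sequence"),
    pcr2_adapter_fwd = if (nrow(p2f)) one(p2f$adapter, "PCR2 forward adapter") else "",
    pcr2_adapter_rev = if (nrow(p2r)) one(p2r$adapter, "PCR2 reverse adapter") else "",
    pcr2_indices = if (nrow(p2r)) stats::setNames(p2r$barcode, p2r$name) else character(0))
  structure(list(parts = parts, fwd = fwd, rev = rev),
            class = "scheme_spec")
}

#' @export
print.scheme_spec <- function(x, ...) {
  cat(sprintf("<scheme_spec> %d forward x %d reverse PCR1 barcodes, %d PCR2 indices\n",
              nrow(x$fwd), nrow(x$rev), length(x$parts$pcr2_indices)))
  cat("  priming: ", x$parts$priming_fwd, " / ", x$parts$priming_rev, "\n", sep = "")
  invisible(x)
}

#' Load the packaged default primer scheme
#'
#' A structurally faithful default table: 12 forward and 8 reverse PCR1
#' primers with 12-nt internal barcodes and 0-7 nt heterogeneity spacers,
#' one universal PCR2 forward primer and 12 indexed PCR2 reverse primers.
#' The barcode sequences themselves are synthetic (designed for large
#' pairwise Hamming separation), not a published oligo set.
#'
#' @param barcode_mismatch_max see [read_primer_table()]
#' @return a `scheme_spec`
#' @export
default_scheme <- function(barcode_mismatch_max = 0L) {
  path <- system.file("extdata", "primers_default.tsv", package = "trindex",
                      mustWork = TRUE)
  read_primer_table(path, barcode_mismatch_max = barcode_mismatch_max)
}
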