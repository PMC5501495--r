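## Small shared helpers: DNA alphabet checks, IUPAC expansion, GC content,
## reverse complement and FASTQ/FASTA I/O thin wrappers around Biostrings.

DNA_BASES <- c("A", "C", "G", "T")

#' Expand an IUPAC code to its concrete bases
#' @param code single IUPAC character (e.g. "M")
#' @return character vector of bases in {A,C,G,T}
#' @keywords internal
iupac_expand <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  code <- toupper(code)
  if (!code %in% names(map)) {
    stop("not an IUPAC nucleotide code: '", code, "'", call. = FALSE)
  }
  strsplit(map[[code]], "")[[1]]
}

#' @keywords internal
is_dna <- function(x, iupac = FALSE) {
  alphabet <- if (iupac) names(Biostrings::IUPAC_CODE_MAP) else DNA_BASES
  chars <- strsplit(toupper(x), "")
  vapply(chars, function(ch) all(ch %in% alphabet), logical(1))
}

#' @keywords internal
assert_dna <- function(x, what = "sequence", iupac = FALSE) {
  bad <- !is_dna(x, iupac = iupac)
  if (any(bad)) {
    stop(what, " contains non-", if (iupac) "IUPAC" else "ACGT",
         " characters: ", paste(utils::head(x[bad], 3), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' GC fraction of DNA strings
#' @param x character vector of DNA sequences
#' @return numeric vector of GC fractions in [0, 1]
#' @export
gc_fraction <- function(x) {
  assert_dna(x, "sequence", iupac = TRUE)
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  ifelse(n > 0, gc / n, NA_real_)
}

#' Reverse complement of DNA strings
#' @param x character vector (IUPAC codes allowed)
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Per-position Hamming distance between equal-length strings
#' @keywords internal
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("unequal lengths in hamming()", call. = FALSE)
  sum(charToRaw(a) != charToRaw(b))
}

#' Minimum pairwise Hamming distance within a set of equal-length strings
#' @keywords internal
min_pairwise_hamming <- function(x) {
  if (length(x) < 2) return(Inf)
  dmin <- Inf
  for (i in seq_len(length(x) - 1)) {
    for (j in seq(i + 1, length(x))) {
      dmin <- min(dmin, hamming(x[i], x[j]))
    }
  }
  dmin
}

## --- FASTQ / FASTA I/O -----------------------------------------------------

#' Read a paired or single FASTQ file
#'
#' @param path path to a .fastq or .fastq.gz file
#' @return list with character vectors `id`, `seq`, `qual`
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own internal metadata columns here
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  list(id = names(qs),
       seq = as.character(qs),
       qual = as.character(Biostrings::quality(qs)))
}

#' Write reads to FASTQ
#'
#' @param id,seq,qual parallel character vectors
#' @param path output path (plain text)
#' @export
write_fastq <- function(id, seq, qual, path) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (length(seq) == 0) {
    file.create(path)
    return(invisible(path))
  }
  s <- Biostrings::DNAStringSet(seq)
  names(s) <- id
  qs <- Biostrings::QualityScaledDNAStringSet(s, Biostrings::PhredQuality(qual))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Write sequences to FASTA
#' @param id,seq parallel character vectors
#' @param path output path
#' @export
write_fasta <- function(id, seq, path) {
  if (length(seq) == 0) {
    file.create(path)
    return(invisible(path))
  }
  s <- Biostrings::DNAStringSet(seq)
  names(s) <- id
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path input path
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}
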