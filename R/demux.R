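## Paired-read demultiplexing on dual internal barcodes.
##
## Reads start at the internal barcode (the partial adapter is upstream of
## the sequencing primer and is not sequenced), so each mate's layout is
## barcode (12 nt) + heterogeneity spacer (0-7 nt) + gene-priming sequence
## + insert. Assignment requires the pool (PCR2) index plus both internal
## barcodes to resolve in the sample sheet.

#' Demultiplexing configuration
#'
#' @param barcode_mismatch_max allowed substitutions in each internal
#'   barcode (default 0). Must stay below half the minimum pairwise
#'   Hamming distance of the barcode sets (unique decodability; enforced
#'   at scheme load time).
#' @param primer_mismatch_frac allowed mismatch fraction when verifying
#'   the gene-priming sequence (default 0.1, the usual adapter-trimming
#'   convention)
#' @param spacer_mode "lookup" takes the spacer length from the barcode
#'   table; "scan" tries lengths 0-7 until the priming sequence matches
#' @param min_overlap minimum read-pair overlap for merging (default 10)
#' @param merge_mismatch_frac maximum mismatch fraction in the overlap
#'   (default 0.25)
#' @param spacer_before_barcode set TRUE if the read-start element order
#'   is spacer then barcode (the converse of the default layout)
#' @param swap_mates set TRUE when mate 1 carries the reverse barcode
#' @return a list of class `demux_config`
#' @export
demux_config <- function(barcode_mismatch_max = 0L,
                         primer_mismatch_frac = 0.1,
                         spacer_mode = c("lookup", "scan"),
                         min_overlap = 10L,
                         merge_mismatch_frac = 0.25,
                         spacer_before_barcode = FALSE,
                         swap_mates = FALSE) {
  spacer_mode <- match.arg(spacer_mode)
  stopifnot(primer_mismatch_frac >= 0, primer_mismatch_frac <= 1,
            merge_mismatch_frac >= 0, merge_mismatch_frac <= 1,
            barcode_mismatch_max >= 0, min_overlap >= 1)
  structure(list(barcode_mismatch_max = as.integer(barcode_mismatch_max),
                 primer_mismatch_frac = primer_mismatch_frac,
                 spacer_mode = spacer_mode,
                 min_overlap = as.integer(min_overlap),
                 merge_mismatch_frac = merge_mismatch_frac,
                 spacer_before_barcode = isTRUE(spacer_before_barcode),
                 swap_mates = isTRUE(swap_mates)),
            class = "demux_config")
}

#' Match a DNA sequence against an IUPAC pattern
#'
#' A position matches when the sequence base belongs to the expansion of
#' the pattern's IUPAC code at that position.
#'
#' @param pattern IUPAC DNA string
#' @param seq DNA string (or character vector) of the same length
#' @param max_mismatch mismatches tolerated for `matches` to be TRUE
#' @return list with `matches` (logical) and `n_mismatch` (integer),
#'   vectorized over `seq`
#' @export
iupac_match <- function(pattern, seq, max_mismatch = 0L) {
  assert_dna(pattern, "pattern", iupac = TRUE)
  assert_dna(seq, "sequence", iupac = TRUE)
  if (any(nchar(seq) != nchar(pattern))) {
    stop("pattern and sequence lengths differ", call. = FALSE)
  }
  n_mismatch <- iupac_mismatch_counts(pattern, seq)
  list(matches = n_mismatch <= max_mismatch, n_mismatch = n_mismatch)
}

## Vectorized mismatch counting of many equal-length strings against one
## IUPAC pattern: loop over pattern positions, not over reads.
#' @keywords internal
iupac_mismatch_counts <- function(pattern, seqs) {
  L <- nchar(pattern)
  pat <- strsplit(toupper(pattern), "")[[1]]
  allowed <- lapply(pat, iupac_expand)
  mm <- integer(length(seqs))
  up <- toupper(seqs)
  for (p in seq_len(L)) {
    ch <- substr(up, p, p)
    ok <- ch %in% allowed[[p]]
    mm <- mm + !ok
  }
  mm
}

#' Parse the start of a read into barcode, spacer and insert offset
#'
#' @param read character vector of read sequences
#' @param direction "forward" or "reverse": which barcode set/priming
#'   sequence the mate carries
#' @param scheme a `scheme_spec`
#' @param cfg a [demux_config()]
#' @return data.frame with columns `barcode` (name or NA), `spacer_len`,
#'   `insert_offset` and `reason` (NA when parsed, else "bad_barcode" or
#'   "bad_primer")
#' @export
parse_read_start <- function(read, direction = c("forward", "reverse"),
                             scheme, cfg = demux_config()) {
  direction <- match.arg(direction)
  set <- if (direction == "forward") scheme$fwd else scheme$rev
  priming <- if (direction == "forward") scheme$parts$priming_fwd else scheme$parts$priming_rev
  bc_len <- nchar(set$sequence[1])
  pr_len <- nchar(priming)
  pr_mm_max <- floor(cfg$primer_mismatch_frac * pr_len)
  n <- length(read)
  read <- toupper(read)

  barcode <- rep(NA_character_, n)
  spacer_len <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)

  too_short <- nchar(read) < bc_len + SPACER_MAX + pr_len
  reason[too_short] <- "bad_barcode"
  todo <- which(!too_short)

  match_barcode_at <- function(idx, offset) {
    # returns barcode row index (or NA) for reads in `idx`, barcode
    # starting at position offset+1
    prefix <- substr(read[idx], offset + 1, offset + bc_len)
    hit <- match(prefix, set$sequence)
    if (cfg$barcode_mismatch_max > 0 && anyNA(hit)) {
      miss <- which(is.na(hit))
      upre <- unique(prefix[miss])
      near <- vapply(upre, function(p) {
        if (!all(strsplit(p, "")[[1]] %in% DNA_BASES)) return(NA_integer_)
        d <- vapply(set$sequence, function(b) hamming(b, p), integer(1))
        within <- which(d <= cfg$barcode_mismatch_max)
        if (length(within) == 1) within else NA_integer_
      }, integer(1))
      hit[miss] <- near[match(prefix[miss], upre)]
    }
    hit
  }

  if (!cfg$spacer_before_barcode) {
    hit <- match_barcode_at(todo, 0L)
    bad <- is.na(hit)
    reason[todo[bad]] <- "bad_barcode"
    ok <- todo[!bad]
    hit <- hit[!bad]
    if (length(ok)) {
      if (cfg$spacer_mode == "lookup") {
        sl <- nchar(set$spacer[hit])
        pr_sub <- substr(read[ok], bc_len + sl + 1, bc_len + sl + pr_len)
        mm <- iupac_mismatch_counts(priming, pr_sub)
        good <- mm <= pr_mm_max
        barcode[ok[good]] <- set$name[hit[good]]
        spacer_len[ok[good]] <- sl[good]
        reason[ok[!good]] <- "bad_primer"
      } else {
        remaining <- ok; rem_hit <- hit
        for (sl in 0:SPACER_MAX) {
          if (!length(remaining)) break
          pr_sub <- substr(read[remaining], bc_len + sl + 1, bc_len + sl + pr_len)
          mm <- iupac_mismatch_counts(priming, pr_sub)
          good <- mm <= pr_mm_max
          barcode[remaining[good]] <- set$name[rem_hit[good]]
          spacer_len[remaining[good]] <- sl
          remaining <- remaining[!good]; rem_hit <- rem_hit[!good]
        }
        reason[remaining] <- "bad_primer"
      }
    }
  } else {
    # spacer precedes the barcode: scan spacer lengths, then verify
    # barcode and priming at the shifted offsets
    remaining <- todo
    for (sl in 0:SPACER_MAX) {
      if (!length(remaining)) break
      hit <- match_barcode_at(remaining, sl)
      cand <- which(!is.na(hit))
      if (length(cand)) {
        ci <- remaining[cand]
        pr_sub <- substr(read[ci], sl + bc_len + 1, sl + bc_len + pr_len)
        mm <- iupac_mismatch_counts(priming, pr_sub)
        good <- mm <= pr_mm_max
        barcode[ci[good]] <- set$name[hit[cand][good]]
        spacer_len[ci[good]] <- sl
        remaining <- setdiff(remaining, ci[good])
      }
    }
    reason[setdiff(remaining, which(!is.na(barcode)))] <- "bad_barcode"
  }

  data.frame(barcode = barcode, spacer_len = spacer_len,
             insert_offset = ifelse(is.na(barcode), NA_integer_,
                                    bc_len + spacer_len + pr_len),
             reason = reason, stringsAsFactors = FALSE)
}

## --- sample sheets ---------------------------------------------------------

#' Construct a sample sheet
#'
#' Maps the triple key (pool index, forward barcode, reverse barcode) to
#' a sample identifier.
#'
#' @param pool_index,fwd_barcode,rev_barcode,sample_id parallel vectors
#' @param scheme optional `scheme_spec`; when given, barcode names are
#'   checked against it
#' @return data.frame of class `sample_sheet`
#' @export
sample_sheet <- function(pool_index, fwd_barcode, rev_barcode, sample_id,
                         scheme = NULL) {
  sh <- data.frame(pool_index = as.character(pool_index),
                   fwd_barcode = as.character(fwd_barcode),
                   rev_barcode = as.character(rev_barcode),
                   sample_id = as.character(sample_id),
                   stringsAsFactors = FALSE)
  key <- paste(sh$pool_index, sh$fwd_barcode, sh$rev_barcode, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (pool, fwd, rev) keys in sample sheet", call. = FALSE)
  }
  if (anyDuplicated(sh$sample_id)) {
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  }
  if (!is.null(scheme)) {
    if (!all(sh$fwd_barcode %in% scheme$fwd$name)) {
      stop("sample sheet references unknown forward barcodes", call. = FALSE)
    }
    if (!all(sh$rev_barcode %in% scheme$rev$name)) {
      stop("sample sheet references unknown reverse barcodes", call. = FALSE)
    }
  }
  class(sh) <- c("sample_sheet", "data.frame")
  sh
}

#' Read / write a sample sheet TSV
#' @param path TSV with columns pool_index, fwd_barcode, rev_barcode,
#'   sample_id
#' @inheritParams sample_sheet
#' @export
read_sample_sheet <- function(path, scheme = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  sample_sheet(tab$pool_index, tab$fwd_barcode, tab$rev_barcode,
               tab$sample_id, scheme = scheme)
}

#' @rdname read_sample_sheet
#' @param sheet a `sample_sheet`
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a sample sheet from a plate layout
#'
#' One sample per well, named `<prefix><i>` in well order.
#'
#' @param layout a [build_plate_layout()] result
#' @param sample_ids optional explicit ids (default "S1", "S2", ...)
#' @param prefix id prefix used when `sample_ids` is NULL
#' @export
sheet_from_layout <- function(layout, sample_ids = NULL, prefix = "S") {
  n <- nrow(layout$wells)
  if (is.null(sample_ids)) sample_ids <- paste0(prefix, seq_len(n))
  sample_sheet(rep(layout$pool_index, n), layout$wells$fwd,
               layout$wells$rev, sample_ids)
}

## --- pair merging ----------------------------------------------------------

## Merge one read pair given mate-2 already reverse-complemented.
## Returns list(seq, qual, overlap) or NULL.
#' @keywords internal
merge_one <- function(s1, q1, rc2, q2r, min_overlap, max_frac) {
  l1 <- nchar(s1); l2 <- nchar(rc2)
  max_o <- min(l1, l2)
  if (max_o < min_overlap) return(NULL)

  best_o <- NA_integer_; best_mm <- NA_integer_; best_frac <- Inf
  # anchored fast path: locate mate-2's leading k-mer inside mate 1
  k <- min(16L, l2)
  pos <- regexpr(substr(rc2, 1, k), s1, fixed = TRUE)
  if (pos > 0) {
    o <- l1 - as.integer(pos) + 1L
    if (o >= min_overlap && o <= max_o) {
      mm <- hamming(substr(s1, l1 - o + 1, l1), substr(rc2, 1, o))
      if (mm / o <= max_frac) { best_o <- o; best_mm <- mm; best_frac <- mm / o }
    }
  }
  if (is.na(best_o)) {
    for (o in seq(max_o, min_overlap)) {
      mm <- hamming(substr(s1, l1 - o + 1, l1), substr(rc2, 1, o))
      f <- mm / o
      if (f <= max_frac && f < best_frac) { best_o <- o; best_mm <- mm; best_frac <- f }
    }
  }
  if (is.na(best_o)) return(NULL)
  o <- best_o
  if (best_mm == 0) {
    seq <- paste0(s1, substr(rc2, o + 1, l2))
    qual <- paste0(substr(q1, 1, l1 - o),
                   overlap_qual_max(substr(q1, l1 - o + 1, l1), substr(q2r, 1, o)),
                   substr(q2r, o + 1, l2))
  } else {
    a <- strsplit(substr(s1, l1 - o + 1, l1), "")[[1]]
    b <- strsplit(substr(rc2, 1, o), "")[[1]]
    qa <- utf8ToInt(substr(q1, l1 - o + 1, l1))
    qb <- utf8ToInt(substr(q2r, 1, o))
    take_b <- (a != b) & (qb > qa)
    cons <- ifelse(take_b, b, a)
    consq <- intToUtf8(pmax(qa, qb), multiple = FALSE)
    seq <- paste0(substr(s1, 1, l1 - o), paste(cons, collapse = ""),
                  substr(rc2, o + 1, l2))
    qual <- paste0(substr(q1, 1, l1 - o), consq, substr(q2r, o + 1, l2))
  }
  list(seq = seq, qual = qual, overlap = o)
}

#' @keywords internal
overlap_qual_max <- function(qa, qb) {
  intToUtf8(pmax(utf8ToInt(qa), utf8ToInt(qb)), multiple = FALSE)
}

#' Merge a read pair over its 3' overlap
#'
#' Mate 2 is reverse-complemented, the best overlap of at least
#' `min_overlap` bases with mismatch fraction at most
#' `merge_mismatch_frac` is located (lowest mismatch fraction wins, ties
#' to the longer overlap), and disagreements in the overlap are resolved
#' toward the higher-quality base (agreements keep the max quality).
#'
#' @param r1_insert,r2_insert insert sequences (barcode/spacer/priming
#'   already removed); `r2_insert` in raw (reverse-strand) orientation
#' @param q1,q2 Phred quality strings (defaults: constant high quality)
#' @param cfg a [demux_config()]
#' @return list with `merged` (character or NA), `qual`, `overlap`,
#'   `ok` (logical); vectorized over pairs
#' @export
merge_pair <- function(r1_insert, r2_insert, q1 = NULL, q2 = NULL,
                       cfg = demux_config()) {
  n <- length(r1_insert)
  stopifnot(length(r2_insert) == n)
  if (is.null(q1)) q1 <- strrep("I", nchar(r1_insert))
  if (is.null(q2)) q2 <- strrep("I", nchar(r2_insert))
  if (any(!nzchar(r1_insert)) || any(!nzchar(r2_insert))) {
    stop("empty insert", call. = FALSE)
  }
  rc2 <- revcomp(r2_insert)
  q2r <- vapply(strsplit(q2, ""), function(x) paste(rev(x), collapse = ""),
                character(1))
  merged <- rep(NA_character_, n); qual <- rep(NA_character_, n)
  overlap <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    m <- merge_one(r1_insert[i], q1[i], rc2[i], q2r[i],
                   cfg$min_overlap, cfg$merge_mismatch_frac)
    if (!is.null(m)) {
      merged[i] <- m$seq; qual[i] <- m$qual; overlap[i] <- m$overlap
    }
  }
  list(merged = merged, qual = qual, overlap = overlap, ok = !is.na(merged))
}

#' Trim the reverse-priming site from the 3' end of merged fragments
#'
#' When a merged fragment still carries the reverse primer (as its
#' reverse complement) at the 3' end, remove it. Absent sites leave the
#' fragment unchanged and are flagged. Idempotent.
#'
#' @param merged character vector of merged fragments
#' @param rev_priming the reverse gene-priming sequence (IUPAC)
#' @param cfg a [demux_config()] (uses `primer_mismatch_frac`)
#' @return data.frame with `fragment` and `primer_found`
#' @export
trim_trailing_primer <- function(merged, rev_priming, cfg = demux_config()) {
  site <- revcomp(rev_priming)          # IUPAC complement of the primer
  L <- nchar(site)
  mm_max <- floor(cfg$primer_mismatch_frac * L)
  n <- length(merged)
  found <- rep(FALSE, n)
  long_enough <- nchar(merged) > L
  idx <- which(long_enough)
  if (length(idx)) {
    tail_sub <- substr(merged[idx], nchar(merged[idx]) - L + 1, nchar(merged[idx]))
    mm <- iupac_mismatch_counts(site, tail_sub)
    hit <- mm <= mm_max
    found[idx[hit]] <- TRUE
    merged[idx[hit]] <- substr(merged[idx[hit]], 1,
                               nchar(merged[idx[hit]]) - L)
  }
  data.frame(fragment = merged, primer_found = found,
             stringsAsFactors = FALSE)
}

## --- pair-level demultiplexing ---------------------------------------------

#' Demultiplex paired reads on dual internal barcodes
#'
#' @param r1,r2 read lists with elements `id`, `seq`, `qual` (as from
#'   [read_fastq()]), or plain character vectors of sequences
#' @param pool_index the pool (PCR2) index of this file pair
#' @param sheet a [sample_sheet()]
#' @param scheme a `scheme_spec`
#' @param cfg a [demux_config()]
#' @param merge merge assigned pairs into fragments?
#' @return object of class `demux_result`: list with
#'   \itemize{
#'     \item `assignments`: per-pair data.frame (id, sample_id, reason,
#'       fwd_barcode, rev_barcode, insert1, insert2, merged)
#'     \item `stats`: a `demux_stats` list (totals, per-sample counts,
#'       per-reason unassigned counts, merged / merge_failed)
#'   }
#' @export
demultiplex_pairs <- function(r1, r2, pool_index, sheet, scheme,
                              cfg = demux_config(), merge = TRUE) {
  as_reads <- function(x) {
    if (is.character(x)) {
      list(id = paste0("read", seq_along(x)), seq = x,
           qual = strrep("I", nchar(x)))
    } else x
  }
  r1 <- as_reads(r1); r2 <- as_reads(r2)
  n <- length(r1$seq)
  if (length(r2$seq) != n) stop("mate files differ in read count", call. = FALSE)
  if (cfg$swap_mates) { tmp <- r1; r1 <- r2; r2 <- tmp }

  p1 <- parse_read_start(r1$seq, "forward", scheme, cfg)
  p2 <- parse_read_start(r2$seq, "reverse", scheme, cfg)

  reason <- rep(NA_character_, n)
  reason[!is.na(p1$reason) & p1$reason == "bad_barcode"] <- "bad_fwd_barcode"
  reason[is.na(reason) & !is.na(p2$reason) & p2$reason == "bad_barcode"] <- "bad_rev_barcode"
  reason[is.na(reason) & (!is.na(p1$reason) | !is.na(p2$reason))] <- "bad_primer"

  key <- paste(pool_index, p1$barcode, p2$barcode, sep = "\r")
  skey <- paste(sheet$pool_index, sheet$fwd_barcode, sheet$rev_barcode, sep = "\r")
  srow <- match(key, skey)
  no_entry <- is.na(reason) & is.na(srow)
  reason[no_entry] <- "no_samplesheet_entry"
  sample_id <- ifelse(is.na(reason), sheet$sample_id[srow], NA_character_)

  assigned <- which(is.na(reason))
  insert1 <- rep(NA_character_, n); insert2 <- rep(NA_character_, n)
  iq1 <- rep(NA_character_, n); iq2 <- rep(NA_character_, n)
  insert1[assigned] <- substr(r1$seq[assigned], p1$insert_offset[assigned] + 1,
                              nchar(r1$seq[assigned]))
  insert2[assigned] <- substr(r2$seq[assigned], p2$insert_offset[assigned] + 1,
                              nchar(r2$seq[assigned]))
  iq1[assigned] <- substr(r1$qual[assigned], p1$insert_offset[assigned] + 1,
                          nchar(r1$qual[assigned]))
  iq2[assigned] <- substr(r2$qual[assigned], p2$insert_offset[assigned] + 1,
                          nchar(r2$qual[assigned]))

  merged <- rep(NA_character_, n)
  merged_qual <- rep(NA_character_, n)
  if (merge && length(assigned)) {
    m <- merge_pair(insert1[assigned], insert2[assigned],
                    iq1[assigned], iq2[assigned], cfg)
    merged[assigned] <- m$merged
    merged_qual[assigned] <- m$qual
  }

  assignments <- data.frame(id = r1$id, sample_id = sample_id,
                            reason = reason,
                            fwd_barcode = p1$barcode, rev_barcode = p2$barcode,
                            insert1 = insert1, insert2 = insert2,
                            insert1_qual = iq1, insert2_qual = iq2,
                            merged = merged, merged_qual = merged_qual,
                            stringsAsFactors = FALSE)

  stats <- demux_stats(assignments, merging = merge)
  structure(list(assignments = assignments, stats = stats,
                 pool_index = pool_index),
            class = "demux_result")
}

#' @keywords internal
demux_stats <- function(assignments, merging) {
  n <- nrow(assignments)
  assigned <- !is.na(assignments$sample_id)
  per_sample <- table(assignments$sample_id[assigned])
  reasons <- c("bad_fwd_barcode", "bad_rev_barcode", "bad_primer",
               "no_samplesheet_entry")
  unassigned <- vapply(reasons, function(r)
    sum(!is.na(assignments$reason) & assignments$reason == r), integer(1))
  merged <- if (merging) sum(assigned & !is.na(assignments$merged)) else NA_integer_
  merge_failed <- if (merging) sum(assigned & is.na(assignments$merged)) else NA_integer_
  st <- structure(list(total_pairs = n,
                       assigned_pairs = as.integer(sum(assigned)),
                       per_sample = per_sample,
                       unassigned = unassigned,
                       merged = merged, merge_failed = merge_failed),
                  class = "demux_stats")
  # conservation invariant; a violation is a programming error
  stopifnot(st$total_pairs == st$assigned_pairs + sum(st$unassigned))
  if (merging) stopifnot(st$merged + st$merge_failed == st$assigned_pairs)
  st
}

#' @export
print.demux_stats <- function(x, ...) {
  cat(sprintf("<demux_stats> %d pairs: %d assigned (%d samples), %d unassigned\n",
              x$total_pairs, x$assigned_pairs, length(x$per_sample),
              sum(x$unassigned)))
  cat("  unassigned by reason: ",
      paste(names(x$unassigned), x$unassigned, sep = "=", collapse = ", "), "\n")
  if (!is.na(x$merged)) {
    cat(sprintf("  merged %d, merge_failed %d\n", x$merged, x$merge_failed))
  }
  invisible(x)
}

#' @export
print.demux_result <- function(x, ...) {
  cat("<demux_result> pool ", x$pool_index, "\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' Demultiplex a pair of FASTQ files to per-sample outputs
#'
#' Thin file-level wrapper around [demultiplex_pairs()]: writes per-sample
#' paired FASTQ, per-sample FASTA of merged fragments, and the
#' demultiplexing statistics as TSV.
#'
#' @param r1_path,r2_path paired FASTQ files (.fastq or .fastq.gz)
#' @param pool_index pool (PCR2) index of this file pair
#' @param sheet,scheme,cfg,merge see [demultiplex_pairs()]
#' @param out_dir output directory (created if absent)
#' @return the `demux_result`, invisibly
#' @export
demux_files <- function(r1_path, r2_path, pool_index, sheet, scheme,
                        out_dir, cfg = demux_config(), merge = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- demultiplex_pairs(read_fastq(r1_path), read_fastq(r2_path),
                           pool_index, sheet, scheme, cfg, merge)
  a <- res$assignments
  for (s in unique(stats::na.omit(a$sample_id))) {
    rows <- which(!is.na(a$sample_id) & a$sample_id == s)
    write_fastq(a$id[rows], a$insert1[rows], a$insert1_qual[rows],
                file.path(out_dir, paste0(s, "_R1.fastq")))
    write_fastq(a$id[rows], a$insert2[rows], a$insert2_qual[rows],
                file.path(out_dir, paste0(s, "_R2.fastq")))
    if (merge) {
      ok <- rows[!is.na(a$merged[rows])]
      write_fasta(a$id[ok], a$merged[ok],
                  file.path(out_dir, paste0(s, "_merged.fasta")))
    }
  }
  st <- res$stats
  stats_tab <- data.frame(
    metric = c("total_pairs", "assigned_pairs", names(st$unassigned),
               "merged", "merge_failed"),
    value = c(st$total_pairs, st$assigned_pairs, unname(st$unassigned),
              st$merged, st$merge_failed))
  utils::write.table(stats_tab, file.path(out_dir, "demux_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  per_sample <- data.frame(sample_id = names(st$per_sample),
                           pairs = as.integer(st$per_sample))
  utils::write.table(per_sample, file.path(out_dir, "sample_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}
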