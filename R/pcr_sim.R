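## Generative PCR model: a per-molecule Bernoulli branching process in
## which duplication probability declines with template GC content above
## a reference point, and each duplication yields, with a small
## probability, a chimera joining the duplicating molecule's prefix to
## another pool molecule's suffix at the homologous coordinate.
##
## Molecules are tracked as counts per distinct sequence (33 template
## groups plus one row per distinct chimeric product), so pool sizes in
## the millions remain tractable; uniform down-sampling caps the tracked
## pool at `capacity` molecules.

#' Construct a template set
#'
#' @param id character vector of species ids (unique)
#' @param sequence DNA fragments, unique, typically 250-300 nt
#' @param initial_copies per-template starting copy number
#' @return data.frame of class `template_set` with columns id, sequence,
#'   gc, and attribute `initial_copies`
#' @export
template_set <- function(id, sequence, initial_copies = 1000) {
  if (anyDuplicated(id)) stop("template ids must be unique", call. = FALSE)
  if (anyDuplicated(sequence)) stop("template sequences must be unique", call. = FALSE)
  assert_dna(sequence, "template")
  out <- data.frame(id = as.character(id), sequence = toupper(sequence),
                    gc = gc_fraction(sequence), stringsAsFactors = FALSE)
  attr(out, "initial_copies") <- initial_copies
  class(out) <- c("template_set", "data.frame")
  out
}

#' Generate a mock-community template set along a GC gradient
#'
#' Emulates a defined mock community of cloned V4 fragments blended to
#' equal proportions: `n_species` random fragments whose GC contents are
#' evenly spaced over `[gc_min, gc_max]` (realized GC exact to within one
#' base by construction).
#'
#' @param n_species number of species (default 33)
#' @param length fragment length in nt (default 253)
#' @param gc_min,gc_max GC-content range (defaults 0.30-0.69; the top end
#'   matches the most extreme species a defined community typically
#'   carries)
#' @param initial_copies starting copies per template
#' @param seed RNG seed (same seed, same set)
#' @return a [template_set()]
#' @export
make_mock_templates <- function(n_species = 33L, length = 253L,
                                gc_min = 0.30, gc_max = 0.69,
                                initial_copies = 1000, seed = 1L) {
  if (n_species < 2) stop("need at least 2 species", call. = FALSE)
  if (gc_min > gc_max || gc_min < 0 || gc_max > 1) {
    stop("invalid GC range", call. = FALSE)
  }
  set.seed(seed)
  gc_target <- seq(gc_min, gc_max, length.out = n_species)
  n_gc <- round(gc_target * length)
  if (any(n_gc < 0 | n_gc > length)) {
    stop("fragment length too short for the requested GC targets", call. = FALSE)
  }
  seqs <- character(n_species)
  for (i in seq_len(n_species)) {
    repeat {
      pos_gc <- sample.int(length, n_gc[i])
      chars <- character(length)
      chars[pos_gc] <- sample(c("G", "C"), n_gc[i], replace = TRUE)
      chars[-pos_gc] <- sample(c("A", "T"), length - n_gc[i], replace = TRUE)
      cand <- paste(chars, collapse = "")
      if (!cand %in% seqs[seq_len(i - 1)]) break
    }
    seqs[i] <- cand
  }
  ids <- sprintf("sp%02d", seq_len(n_species))
  template_set(ids, seqs, initial_copies = initial_copies)
}

#' PCR simulation parameters
#'
#' @param cycles1,cycles2 first- and second-stage cycle counts (defaults
#'   35 and 10, the high-multiplexing regime)
#' @param e0 baseline per-cycle duplication probability at or below the
#'   reference GC (default 0.9)
#' @param gc_penalty efficiency loss per unit GC fraction above
#'   `gc_ref` (default 0.5)
#' @param gc_ref GC fraction below which efficiency is unpenalized
#'   (default 0.5)
#' @param chimera_prob probability that a duplication event produces a
#'   chimera rather than a faithful copy, first-stage PCR (default 0.01)
#' @param chimera_prob2 same for the second-stage PCR; defaults to 0
#'   because chimera formation is dominated by the degenerate-primer
#'   first stage
#' @param capacity maximum tracked pool size; larger pools are uniformly
#'   down-sampled and the dilution recorded (default 2e6)
#' @param denaturation_boost divisor applied to the GC penalty, modelling
#'   longer melting steps that rescue high-GC templates (1 = short melt)
#' @return list of class `pcr_params`
#' @export
pcr_params <- function(cycles1 = 35L, cycles2 = 10L, e0 = 0.9,
                       gc_penalty = 0.5, gc_ref = 0.5,
                       chimera_prob = 0.01, chimera_prob2 = 0,
                       capacity = 2e6, denaturation_boost = 1) {
  stopifnot(e0 > 0, e0 <= 1,
            chimera_prob >= 0, chimera_prob < 1,
            chimera_prob2 >= 0, chimera_prob2 < 1,
            gc_penalty >= 0, denaturation_boost >= 1,
            cycles1 >= 0, cycles2 >= 0, capacity > 0)
  structure(list(cycles1 = as.integer(cycles1), cycles2 = as.integer(cycles2),
                 e0 = e0, gc_penalty = gc_penalty, gc_ref = gc_ref,
                 chimera_prob = chimera_prob, chimera_prob2 = chimera_prob2,
                 capacity = capacity, denaturation_boost = denaturation_boost),
            class = "pcr_params")
}

#' GC-dependent amplification efficiency
#'
#' e(gc) = clamp(e0 - gc_penalty * max(0, gc - gc_ref) /
#' denaturation_boost, 0, 1): monotone non-increasing in GC, equal to
#' `e0` at or below the reference GC. High-GC templates melt less
#' completely during short denaturation steps and are outcompeted; a
#' longer melt (denaturation_boost > 1) shrinks the penalty.
#'
#' @param gc GC fraction(s) in [0, 1]
#' @param p a [pcr_params()]
#' @return duplication probability per cycle
#' @export
amplification_efficiency <- function(gc, p) {
  if (any(gc < 0 | gc > 1)) stop("gc must lie in [0, 1]", call. = FALSE)
  pen <- p$gc_penalty * pmax(0, gc - p$gc_ref) / p$denaturation_boost
  pmin(pmax(p$e0 - pen, 0), 1)
}

#' Simulate two-stage PCR on a template set
#'
#' Runs `cycles1 + cycles2` cycles of the branching process. Every cycle,
#' each molecule duplicates with probability given by
#' [amplification_efficiency()] of its GC content; each new copy is, with
#' probability `chimera_prob` (stage 1) or `chimera_prob2` (stage 2), a
#' chimera: the prefix of the duplicating molecule up to a uniform
#' interior breakpoint joined to the suffix of another pool molecule
#' (chosen proportionally to copy number) at the same coordinate.
#' Provenance (parent species, breakpoint, cycle of origin) is recorded
#' for every distinct chimeric product.
#'
#' @param templates a [template_set()]
#' @param p a [pcr_params()]
#' @param seed RNG seed; identical seeds give identical pools
#' @return object of class `pcr_pool`: list with `templates`, `counts`
#'   (per-template copy numbers), `chimeras` (data.frame sequence,
#'   parent1, parent2, breakpoint, born_cycle, gc, count), `dilution`
#'   (cumulative down-sampling factor), `params`
#' @export
simulate_pcr <- function(templates, p = pcr_params(), seed = 1L) {
  if (nrow(templates) == 0) stop("empty template set", call. = FALSE)
  set.seed(seed)
  L <- nchar(templates$sequence[1])
  if (any(nchar(templates$sequence) != L)) {
    stop("templates must share a common length for homologous-coordinate joining",
         call. = FALSE)
  }
  counts <- rep(attr(templates, "initial_copies"),
                length.out = nrow(templates))
  counts <- as.numeric(counts)
  e_t <- amplification_efficiency(templates$gc, p)
  chim <- data.frame(sequence = character(0), parent1 = character(0),
                     parent2 = character(0), breakpoint = integer(0),
                     born_cycle = integer(0), gc = numeric(0),
                     count = numeric(0), stringsAsFactors = FALSE)
  dilution <- 1
  total_cycles <- p$cycles1 + p$cycles2

  for (cyc in seq_len(total_cycles)) {
    q <- if (cyc <= p$cycles1) p$chimera_prob else p$chimera_prob2

    new_t <- stats::rbinom(length(counts), counts, e_t)
    n_chim_t <- if (q > 0) stats::rbinom(length(counts), new_t, q) else integer(length(counts))
    counts <- counts + new_t - n_chim_t

    new_c <- n_cc <- integer(0)
    if (nrow(chim)) {
      e_c <- amplification_efficiency(chim$gc, p)
      new_c <- stats::rbinom(nrow(chim), chim$count, e_c)
      n_cc <- if (q > 0) stats::rbinom(nrow(chim), new_c, q) else integer(nrow(chim))
      chim$count <- chim$count + new_c - n_cc
    }

    k <- sum(n_chim_t) + sum(n_cc)
    if (k > 0) {
      src_is_t <- rep(c(TRUE, FALSE), c(sum(n_chim_t), sum(n_cc)))
      src_idx <- c(rep(seq_along(n_chim_t), n_chim_t),
                   rep(seq_along(n_cc), n_cc))
      pool_counts <- c(counts, if (nrow(chim)) chim$count else numeric(0))
      partner <- sample.int(length(pool_counts), k, replace = TRUE,
                            prob = pool_counts)
      bp <- sample.int(L - 1L, k, replace = TRUE)

      src_seq <- ifelse(src_is_t, templates$sequence[src_idx],
                        chim$sequence[ifelse(src_is_t, NA, src_idx)])
      src_p1 <- ifelse(src_is_t, templates$id[src_idx],
                       chim$parent1[ifelse(src_is_t, NA, src_idx)])
      p_is_t <- partner <= length(counts)
      p_idx <- ifelse(p_is_t, partner, partner - length(counts))
      p_seq <- ifelse(p_is_t, templates$sequence[p_idx],
                      chim$sequence[ifelse(p_is_t, NA, p_idx)])
      p_p2 <- ifelse(p_is_t, templates$id[p_idx],
                     chim$parent2[ifelse(p_is_t, NA, p_idx)])

      new_seq <- paste0(substr(src_seq, 1, bp), substr(p_seq, bp + 1, L))
      add <- data.frame(sequence = new_seq, parent1 = src_p1, parent2 = p_p2,
                        breakpoint = bp, born_cycle = cyc,
                        gc = gc_fraction(new_seq), count = 1,
                        stringsAsFactors = FALSE)
      chim <- rbind(chim, add)
    }

    total <- sum(counts) + sum(chim$count)
    if (total > p$capacity) {
      keep <- p$capacity / total
      counts <- stats::rbinom(length(counts), counts, keep)
      if (nrow(chim)) {
        chim$count <- stats::rbinom(nrow(chim), chim$count, keep)
        chim <- chim[chim$count > 0, , drop = FALSE]
      }
      dilution <- dilution * keep
    }
  }

  structure(list(templates = templates, counts = counts, chimeras = chim,
                 dilution = dilution, params = p, seed = seed),
            class = "pcr_pool")
}

#' @export
print.pcr_pool <- function(x, ...) {
  cat(sprintf("<pcr_pool> %d templates, %.3g molecules (%.2f%% chimeric), dilution %.3g\n",
              nrow(x$templates), sum(x$counts) + sum(x$chimeras$count),
              100 * chimera_fraction(x), x$dilution))
  invisible(x)
}

#' Chimeric fraction of a simulated pool
#' @param pool a `pcr_pool`
#' @return fraction of pool molecules that are chimeric
#' @export
chimera_fraction <- function(pool) {
  tot <- sum(pool$counts) + sum(pool$chimeras$count)
  if (tot == 0) return(NA_real_)
  sum(pool$chimeras$count) / tot
}

## realize degenerate IUPAC positions of a priming sequence, one random
## expansion per read (vectorized over reads)
#' @keywords internal
realize_priming <- function(priming, n) {
  chars <- strsplit(priming, "")[[1]]
  cols <- lapply(chars, function(ch) {
    opts <- iupac_expand(ch)
    if (length(opts) == 1) rep(opts, n) else sample(opts, n, replace = TRUE)
  })
  do.call(paste0, cols)
}

#' @keywords internal
add_substitution_errors <- function(seqs, err_rate) {
  if (err_rate <= 0) return(seqs)
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    hits <- which(stats::runif(L) < err_rate)
    if (length(hits)) {
      ch <- strsplit(seqs[i], "")[[1]]
      for (h in hits) {
        ch[h] <- sample(setdiff(DNA_BASES, ch[h]), 1)
      }
      seqs[i] <- paste(ch, collapse = "")
    }
  }
  seqs
}

#' Emit paired reads from a simulated pool in the triple-index layout
#'
#' Draws molecules with replacement proportionally to copy number and
#' writes each as a read pair: mate 1 = forward barcode + spacer +
#' (realized) forward priming + fragment; mate 2 = reverse barcode +
#' spacer + (realized) reverse priming + reverse-complemented fragment;
#' both truncated to `read_len`. Substitution errors are i.i.d. per base
#' at `err_rate`. A ground-truth row is recorded per pair.
#'
#' @param pool a `pcr_pool`
#' @param n_reads number of pairs to emit
#' @param well list or data.frame row with `fwd` and `rev` barcode names
#' @param scheme a `scheme_spec`
#' @param sample_id sample identifier written into the truth table
#' @param read_len read length in nt (default 250)
#' @param err_rate substitution error rate per base (default 0)
#' @param seed RNG seed
#' @return list with `r1`, `r2` (lists of id/seq/qual) and `truth`
#'   (data.frame id, sample_id, parent1, parent2, is_chimera, breakpoint,
#'   fwd_barcode, rev_barcode, fwd_spacer_len, rev_spacer_len)
#' @export
sample_reads <- function(pool, n_reads, well, scheme, sample_id = "S1",
                         read_len = 250L, err_rate = 0, seed = 1L) {
  set.seed(seed)
  fwd_row <- scheme$fwd[match(well$fwd, scheme$fwd$name), , drop = FALSE]
  rev_row <- scheme$rev[match(well$rev, scheme$rev$name), , drop = FALSE]
  if (nrow(fwd_row) != 1 || anyNA(fwd_row$sequence) ||
      nrow(rev_row) != 1 || anyNA(rev_row$sequence)) {
    stop("well barcodes not found in scheme", call. = FALSE)
  }
  empty_reads <- list(id = character(0), seq = character(0), qual = character(0))
  if (n_reads == 0) {
    return(list(r1 = empty_reads, r2 = empty_reads,
                truth = truth_frame(character(0), sample_id, character(0),
                                    character(0), logical(0), integer(0),
                                    character(0), fwd_row, rev_row)))
  }
  n_cat <- nrow(pool$templates) + nrow(pool$chimeras)
  weights <- c(pool$counts, pool$chimeras$count)
  if (sum(weights) == 0) stop("pool is empty", call. = FALSE)
  pick <- sample.int(n_cat, n_reads, replace = TRUE, prob = weights)
  is_chim <- pick > nrow(pool$templates)
  ti <- ifelse(is_chim, NA_integer_, pick)
  ci <- ifelse(is_chim, pick - nrow(pool$templates), NA_integer_)
  frag <- ifelse(is_chim, pool$chimeras$sequence[ci],
                 pool$templates$sequence[ti])
  parent1 <- ifelse(is_chim, pool$chimeras$parent1[ci], pool$templates$id[ti])
  parent2 <- ifelse(is_chim, pool$chimeras$parent2[ci], NA_character_)
  breakpoint <- ifelse(is_chim, pool$chimeras$breakpoint[ci], NA_integer_)

  ids <- sprintf("%s_read%06d", sample_id, seq_len(n_reads))
  pr1 <- realize_priming(scheme$parts$priming_fwd, n_reads)
  pr2 <- realize_priming(scheme$parts$priming_rev, n_reads)
  s1 <- substr(paste0(fwd_row$sequence, fwd_row$spacer, pr1, frag), 1, read_len)
  s2 <- substr(paste0(rev_row$sequence, rev_row$spacer, pr2, revcomp(frag)),
               1, read_len)
  s1 <- add_substitution_errors(s1, err_rate)
  s2 <- add_substitution_errors(s2, err_rate)
  q1 <- strrep("I", nchar(s1))
  q2 <- strrep("I", nchar(s2))

  list(r1 = list(id = ids, seq = s1, qual = q1),
       r2 = list(id = ids, seq = s2, qual = q2),
       truth = truth_frame(ids, sample_id, parent1, parent2, is_chim,
                           breakpoint, ifelse(is_chim, frag, NA_character_),
                           fwd_row, rev_row))
}

#' @keywords internal
truth_frame <- function(ids, sample_id, parent1, parent2, is_chim,
                        breakpoint, chimera_seq, fwd_row, rev_row) {
  n <- length(ids)
  data.frame(id = ids, sample_id = rep(sample_id, n),
             parent1 = parent1, parent2 = parent2,
             is_chimera = is_chim, breakpoint = breakpoint,
             chimera_seq = chimera_seq,
             fwd_barcode = rep(fwd_row$name, n),
             rev_barcode = rep(rev_row$name, n),
             fwd_spacer_len = rep(nchar(fwd_row$spacer), n),
             rev_spacer_len = rep(nchar(rev_row$spacer), n),
             stringsAsFactors = FALSE)
}

#' Simulate a multi-sample experiment
#'
#' One [simulate_pcr()] + [sample_reads()] per design row; reads are
#' pooled per pool index, truth tables concatenated, and a manifest of
#' the factorial structure returned.
#'
#' @param design data.frame with columns `sample_id`, `fwd`, `rev`,
#'   `pool_index` and optionally `cycles1`, `cycles2`, `template_amount`
#'   (total starting molecules across templates), `n_reads` (defaults
#'   from `params` / `n_reads`)
#' @param templates a [template_set()]
#' @param scheme a `scheme_spec`
#' @param params baseline [pcr_params()]; per-row columns override
#'   `cycles1`/`cycles2`
#' @param n_reads default read pairs per sample (default 20000)
#' @param read_len,err_rate see [sample_reads()]
#' @param same_index_collapse when TRUE, wells whose forward and reverse
#'   barcode sequences are identical yield tenfold fewer reads (hairpin
#'   interference)
#' @param seed global seed; per-sample seeds are derived deterministically
#' @return list of class `sim_experiment` with `pools` (per pool index:
#'   merged `r1`, `r2` read lists), `truth`, `manifest`, `templates`,
#'   `scheme`
#' @export
simulate_experiment <- function(design, templates, scheme,
                                params = pcr_params(), n_reads = 20000L,
                                read_len = 250L, err_rate = 0,
                                same_index_collapse = FALSE, seed = 1L) {
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample ids in design", call. = FALSE)
  }
  key <- paste(design$pool_index, design$fwd, design$rev)
  if (anyDuplicated(key)) {
    stop("wells must be distinct within a pool", call. = FALSE)
  }
  n <- nrow(design)
  col_or <- function(col, default) {
    if (col %in% names(design)) design[[col]] else rep(default, n)
  }
  cycles1 <- col_or("cycles1", params$cycles1)
  cycles2 <- col_or("cycles2", params$cycles2)
  template_amount <- col_or("template_amount",
                            attr(templates, "initial_copies") * nrow(templates))
  reads_per <- col_or("n_reads", n_reads)

  fwd_seq <- scheme$fwd$sequence[match(design$fwd, scheme$fwd$name)]
  rev_seq <- scheme$rev$sequence[match(design$rev, scheme$rev$name)]
  if (same_index_collapse) {
    collapsed <- !is.na(fwd_seq) & fwd_seq == rev_seq
    reads_per[collapsed] <- pmax(1L, round(reads_per[collapsed] / 10))
  }

  pools <- list()
  truths <- vector("list", n)
  chim_frac <- numeric(n)
  for (i in seq_len(n)) {
    p_i <- params
    p_i$cycles1 <- as.integer(cycles1[i])
    p_i$cycles2 <- as.integer(cycles2[i])
    t_i <- templates
    attr(t_i, "initial_copies") <- pmax(1, round(template_amount[i] / nrow(templates)))
    seed_i <- (seed * 1000L + i) %% .Machine$integer.max
    pool <- simulate_pcr(t_i, p_i, seed = seed_i)
    chim_frac[i] <- chimera_fraction(pool)
    rd <- sample_reads(pool, reads_per[i],
                       well = list(fwd = design$fwd[i], rev = design$rev[i]),
                       scheme = scheme, sample_id = design$sample_id[i],
                       read_len = read_len, err_rate = err_rate,
                       seed = seed_i + 500000L)
    truths[[i]] <- rd$truth
    px <- as.character(design$pool_index[i])
    if (is.null(pools[[px]])) {
      pools[[px]] <- list(r1 = rd$r1, r2 = rd$r2)
    } else {
      for (m in c("r1", "r2")) {
        pools[[px]][[m]] <- list(id = c(pools[[px]][[m]]$id, rd[[m]]$id),
                                 seq = c(pools[[px]][[m]]$seq, rd[[m]]$seq),
                                 qual = c(pools[[px]][[m]]$qual, rd[[m]]$qual))
      }
    }
  }
  manifest <- data.frame(sample_id = design$sample_id,
                         pool_index = design$pool_index,
                         fwd = design$fwd, rev = design$rev,
                         cycles1 = cycles1, cycles2 = cycles2,
                         template_amount = template_amount,
                         n_reads = reads_per,
                         pool_chimera_fraction = chim_frac,
                         stringsAsFactors = FALSE)
  structure(list(pools = pools, truth = do.call(rbind, truths),
                 manifest = manifest, templates = templates, scheme = scheme),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("<sim_experiment> %d samples in %d pool(s), %d read pairs\n",
              nrow(x$manifest), length(x$pools), nrow(x$truth)))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Pooled paired FASTQ per pool index, truth table TSV and manifest TSV.
#'
#' @param sim a `sim_experiment`
#' @param out_dir output directory
#' @return `out_dir`, invisibly
#' @export
write_experiment <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (px in names(sim$pools)) {
    write_fastq(sim$pools[[px]]$r1$id, sim$pools[[px]]$r1$seq,
                sim$pools[[px]]$r1$qual,
                file.path(out_dir, paste0(px, "_R1.fastq")))
    write_fastq(sim$pools[[px]]$r2$id, sim$pools[[px]]$r2$seq,
                sim$pools[[px]]$r2$qual,
                file.path(out_dir, paste0(px, "_R2.fastq")))
  }
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
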