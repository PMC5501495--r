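test_that("IUPAC matching expands degenerate codes", {
  expect_true(iupac_match("M", "A")$matches)
  expect_equal(iupac_match("M", "A")$n_mismatch, 0L)
  expect_true(iupac_match("GTGY", "GTGT")$matches)
  m <- iupac_match("AAAA", "AAAT", max_mismatch = 0)
  expect_false(m$matches)
  expect_equal(m$n_mismatch, 1L)
  expect_error(iupac_match("AAA", "AAAA"), "length")
  expect_error(iupac_match("AZAA", "AAAA"), "IUPAC")
})

test_that("read-start parsing inverts oligo assembly", {
  scheme <- default_scheme()
  cfg <- demux_config()
  # assembly round-trip: every forward and reverse barcode, exact reads
  for (dir in c("forward", "reverse")) {
    set <- if (dir == "forward") scheme$fwd else scheme$rev
    priming <- if (dir == "forward") scheme$parts$priming_fwd else scheme$parts$priming_rev
    priming_concrete <- gsub("Y", "C", gsub("M", "A", gsub("N", "G",
                        gsub("V", "C", gsub("W", "T", priming)))))
    reads <- paste0(set$sequence, set$spacer, priming_concrete,
                    strrep("A", 60))
    p <- parse_read_start(reads, dir, scheme, cfg)
    expect_identical(p$barcode, set$name)
    expect_identical(p$spacer_len, nchar(set$spacer))
    expect_identical(p$insert_offset,
                     nchar(set$sequence) + nchar(set$spacer) + nchar(priming))
  }
  # scan mode finds the same spacer lengths without the lookup table
  reads <- paste0(scheme$fwd$sequence, scheme$fwd$spacer,
                  "GTGTCAGCAGCCGCGGTAA", strrep("A", 60))
  p_scan <- parse_read_start(reads, "forward", scheme,
                             demux_config(spacer_mode = "scan"))
  expect_identical(p_scan$spacer_len, nchar(scheme$fwd$spacer))

  # unmatchable prefix fails as bad_barcode
  bad <- parse_read_start(strrep("N", 80), "forward", scheme, cfg)
  expect_identical(bad$reason, "bad_barcode")
  # matching barcode but corrupted priming fails as bad_primer
  corrupt <- paste0(scheme$fwd$sequence[1], scheme$fwd$spacer[1],
                    strrep("T", 19), strrep("A", 60))
  expect_identical(parse_read_start(corrupt, "forward", scheme, cfg)$reason,
                   "bad_primer")
})

test_that("single-substitution barcodes decode uniquely at mismatch 1", {
  scheme <- default_scheme(barcode_mismatch_max = 1L)
  cfg <- demux_config(barcode_mismatch_max = 1L)
  # enumerate all single-substitution variants of every forward barcode
  reads <- character(0); truth <- character(0)
  for (i in seq_len(nrow(scheme$fwd))) {
    bc <- scheme$fwd$sequence[i]
    for (pos in 1:12) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(bc, pos, pos))) {
        var <- bc
        substr(var, pos, pos) <- b
        reads <- c(reads, paste0(var, scheme$fwd$spacer[i],
                                 "GTGTCAGCAGCCGCGGTAA", strrep("A", 60)))
        truth <- c(truth, scheme$fwd$name[i])
      }
    }
  }
  p <- parse_read_start(reads, "forward", scheme, cfg)
  expect_identical(p$barcode, truth)
})

test_that("barcode sets failing unique decodability are rejected at load", {
  tab <- read.delim(system.file("extdata", "primers_default.tsv",
                                package = "trindex"),
                    colClasses = "character")
  # two forward barcodes one substitution apart: min Hamming distance 1
  i <- which(tab$direction == "forward")[1:2]
  close_bc <- tab$barcode[i[1]]
  substr(close_bc, 1, 1) <- setdiff(c("A", "C"), substr(close_bc, 1, 1))[1]
  tab$barcode[i[2]] <- close_bc
  tab$full_oligo[i[2]] <- paste0(tab$adapter[i[2]], close_bc,
                                 tab$spacer[i[2]], tab$priming[i[2]])
  # distance-1 barcodes remain decodable for exact matching but cannot
  # support any mismatch tolerance
  expect_silent(scheme_from_table(tab, barcode_mismatch_max = 0L))
  expect_error(scheme_from_table(tab, barcode_mismatch_max = 1L),
               "uniquely decodable")
  # outright duplicated sequences fail even at zero tolerance
  tab$barcode[i[2]] <- tab$barcode[i[1]]
  tab$full_oligo[i[2]] <- paste0(tab$adapter[i[2]], tab$barcode[i[2]],
                                 tab$spacer[i[2]], tab$priming[i[2]])
  expect_error(scheme_from_table(tab, barcode_mismatch_max = 0L),
               "uniquely decodable")
})

test_that("read-pair merging reconstructs fragments and rejects non-overlaps", {
  cfg <- demux_config()
  frag <- rand_dna(253, seed = 31)
  r1 <- substr(frag, 1, 180)
  r2 <- revcomp(substr(frag, 74, 253))
  m <- merge_pair(r1, r2, cfg = cfg)
  expect_true(m$ok)
  expect_identical(m$merged, frag)
  expect_equal(m$overlap, 180L + 180L - 253L)

  # unrelated sequences with no qualifying overlap fail
  set.seed(77)
  a <- rand_dna(120); b <- rand_dna(120)
  m2 <- merge_pair(a, b, cfg = demux_config(min_overlap = 10,
                                            merge_mismatch_frac = 0))
  expect_false(m2$ok)

  # one mismatch inside a 107-nt overlap passes the 0.25 threshold and
  # conserves merged length
  r1m <- substr(frag, 1, 180)
  substr(r1m, 150, 150) <- setdiff(c("A", "C"), substr(r1m, 150, 150))[1]
  m3 <- merge_pair(r1m, r2, cfg = cfg)
  expect_true(m3$ok)
  expect_equal(nchar(m3$merged), 253L)

  # the disagreement resolves toward the higher-quality base
  q1 <- strrep("#", 180)          # low quality mate 1
  q2 <- strrep("I", 180)
  m4 <- merge_pair(r1m, r2, q1 = q1, q2 = q2, cfg = cfg)
  expect_identical(m4$merged, frag)
  expect_error(merge_pair("", "ACGT"), "empty insert")
})

test_that("trailing reverse-primer removal is tolerant and idempotent", {
  cfg <- demux_config()
  rev_priming <- "GGACTACNVGGGTWTCTAAT"
  frag <- rand_dna(200, seed = 5)
  with_primer <- paste0(frag, revcomp("GGACTACAGGGGTATCTAAT"))  # one expansion
  tr <- trim_trailing_primer(with_primer, rev_priming, cfg)
  expect_identical(tr$fragment, frag)
  expect_true(tr$primer_found)
  # idempotent and flags absence
  tr2 <- trim_trailing_primer(tr$fragment, rev_priming, cfg)
  expect_identical(tr2$fragment, frag)
  expect_false(tr2$primer_found)
  # every wobble realization of the primer is removed
  real <- expand.grid(Y = c("C", "T"), N = c("A", "C", "G", "T"),
                      V = c("A", "C", "G"), W = c("A", "T"),
                      stringsAsFactors = FALSE)
  for (k in seq_len(nrow(real))) {
    p <- sub("Y", real$Y[k], sub("N", real$N[k],
           sub("V", real$V[k], sub("W", real$W[k], rev_priming))))
    out <- trim_trailing_primer(paste0(frag, revcomp(p)), rev_priming, cfg)
    expect_true(out$primer_found)
    expect_identical(out$fragment, frag)
  }
})

test_that("paired demultiplexing recovers simulated samples exactly", {
  scheme <- default_scheme()
  tpl <- make_mock_templates(n_species = 10, seed = 3, initial_copies = 500)
  lay <- build_plate_layout(scheme$fwd, scheme$rev)
  wells <- lay$wells[1:8, ]
  sheet <- sheet_from_layout(lay)[1:8, ]
  design <- data.frame(sample_id = sheet$sample_id, fwd = wells$fwd,
                       rev = wells$rev, pool_index = "p1")
  sim <- simulate_experiment(design, tpl, scheme,
                             params = pcr_params(cycles1 = 10, cycles2 = 0,
                                                 chimera_prob = 0,
                                                 capacity = 1e5),
                             n_reads = 125, seed = 8)
  res <- demultiplex_pairs(sim$pools$p1$r1, sim$pools$p1$r2, "p1",
                           sheet, scheme)
  a <- res$assignments
  # 100% correct assignment against simulator ground truth
  expect_identical(a$sample_id, sim$truth$sample_id[match(a$id, sim$truth$id)])
  expect_equal(res$stats$assigned_pairs, 1000L)
  expect_equal(sum(res$stats$unassigned), 0L)
  # conservation
  expect_equal(res$stats$total_pairs,
               res$stats$assigned_pairs + sum(res$stats$unassigned))
  # per-sample counts equal the simulator's sampling counts
  expect_equal(as.integer(res$stats$per_sample[sheet$sample_id]),
               rep(125L, 8))
  # merging correctness: every merged fragment is a source molecule
  expect_true(all(a$merged %in% tpl$sequence))

  # a valid barcode pair absent from the sheet is reported as such
  res2 <- demultiplex_pairs(sim$pools$p1$r1, sim$pools$p1$r2, "p1",
                            sheet[-1, ], scheme)
  expect_equal(unname(res2$stats$unassigned["no_samplesheet_entry"]), 125L)
  expect_equal(res2$stats$assigned_pairs, 875L)
})

test_that("file-level demultiplexing writes per-sample outputs and stats", {
  scheme <- default_scheme()
  tpl <- make_mock_templates(n_species = 5, seed = 11, initial_copies = 200)
  lay <- build_plate_layout(scheme$fwd, scheme$rev)
  sheet <- sheet_from_layout(lay)[1:2, ]
  design <- data.frame(sample_id = sheet$sample_id,
                       fwd = sheet$fwd_barcode, rev = sheet$rev_barcode,
                       pool_index = "p1")
  sim <- simulate_experiment(design, tpl, scheme,
                             params = pcr_params(cycles1 = 5, cycles2 = 0,
                                                 chimera_prob = 0,
                                                 capacity = 1e4),
                             n_reads = 50, seed = 2)
  simdir <- withr::local_tempdir()
  outdir <- withr::local_tempdir()
  write_experiment(sim, simdir)
  res <- demux_files(file.path(simdir, "p1_R1.fastq"),
                     file.path(simdir, "p1_R2.fastq"),
                     "p1", sheet, scheme, outdir)
  expect_equal(res$stats$assigned_pairs, 100L)
  for (s in sheet$sample_id) {
    expect_true(file.exists(file.path(outdir, paste0(s, "_R1.fastq"))))
    fr <- read_fasta(file.path(outdir, paste0(s, "_merged.fasta")))
    expect_length(fr, 50L)
    expect_true(all(fr %in% tpl$sequence))
  }
  stats <- read.delim(file.path(outdir, "demux_stats.tsv"))
  expect_equal(stats$value[stats$metric == "total_pairs"], 100L)
})
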