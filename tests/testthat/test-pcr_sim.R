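test_that("mock template generation hits its GC targets deterministically", {
  tpl <- make_mock_templates(n_species = 33, gc_min = 0.30, gc_max = 0.69,
                             seed = 12)
  expect_equal(nrow(tpl), 33L)
  expect_equal(anyDuplicated(tpl$sequence), 0L)
  targets <- seq(0.30, 0.69, length.out = 33)
  # realized GC within one base of the evenly spaced targets
  expect_true(all(abs(tpl$gc - targets) <= 1 / 253 + 1e-12))
  expect_equal(max(tpl$gc), 0.69, tolerance = 1 / 253)
  # gc column equals recomputed GC
  expect_equal(tpl$gc, gc_fraction(tpl$sequence))

  # degenerate range
  tpl2 <- make_mock_templates(n_species = 2, gc_min = 0.5, gc_max = 0.5,
                              length = 100, seed = 1)
  expect_true(all(abs(tpl2$gc - 0.5) <= 1 / 100 + 1e-12))

  # determinism
  expect_identical(make_mock_templates(seed = 42),
                   make_mock_templates(seed = 42))
  expect_error(make_mock_templates(n_species = 1), "at least 2")
})

test_that("amplification efficiency is the clamped GC-penalty law", {
  p0 <- pcr_params(e0 = 0.95, gc_penalty = 0, gc_ref = 0.5)
  expect_equal(amplification_efficiency(c(0, 0.5, 1), p0), rep(0.95, 3))
  p <- pcr_params(e0 = 0.95, gc_penalty = 0.5, gc_ref = 0.5)
  expect_equal(amplification_efficiency(0.5, p), 0.95)
  expect_equal(amplification_efficiency(0.69, p), 0.855)
  expect_equal(amplification_efficiency(0.3, p), 0.95)
  # monotone non-increasing; longer denaturation shrinks the penalty
  gc <- seq(0, 1, 0.01)
  expect_true(all(diff(amplification_efficiency(gc, p)) <= 0))
  pboost <- pcr_params(e0 = 0.95, gc_penalty = 0.5, gc_ref = 0.5,
                       denaturation_boost = 3)
  expect_true(amplification_efficiency(0.69, pboost) >
                amplification_efficiency(0.69, p))
  expect_error(amplification_efficiency(1.2, p), "\\[0, 1\\]")
})

test_that("the branching process obeys its degenerate and mean laws", {
  tpl <- make_mock_templates(n_species = 3, length = 100, gc_min = 0.3,
                             gc_max = 0.4, initial_copies = 50, seed = 2)
  # no chimera channel -> no chimeras
  pool <- simulate_pcr(tpl, pcr_params(cycles1 = 8, cycles2 = 2,
                                       chimera_prob = 0, capacity = 1e6),
                       seed = 4)
  expect_equal(nrow(pool$chimeras), 0L)
  # zero cycles -> pool is exactly the initial templates
  pool0 <- simulate_pcr(tpl, pcr_params(cycles1 = 0, cycles2 = 0), seed = 4)
  expect_equal(pool0$counts, rep(50, 3))
  expect_equal(pool0$dilution, 1)

  # mean pool size matches the closed-form branching expectation
  # N0 (1+e)^n for uniform efficiency e (GC below gc_ref), q = 0
  one <- template_set("t1", rand_dna(100, seed = 9), initial_copies = 50)
  p <- pcr_params(cycles1 = 6, cycles2 = 0, e0 = 0.5, gc_penalty = 0,
                  chimera_prob = 0, capacity = 1e9)
  sizes <- vapply(1:200, function(s)
    sum(simulate_pcr(one, p, seed = s)$counts), numeric(1))
  expected <- 50 * 1.5^6
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - expected), 3 * se)
})

test_that("chimeras carry consistent provenance back to the templates", {
  tpl <- make_mock_templates(n_species = 5, length = 120, initial_copies = 400,
                             seed = 6)
  pool <- simulate_pcr(tpl, pcr_params(cycles1 = 12, cycles2 = 0,
                                       chimera_prob = 0.05, capacity = 5e4),
                       seed = 10)
  ch <- pool$chimeras
  expect_gt(nrow(ch), 0)
  expect_true(all(ch$parent1 %in% tpl$id))
  expect_true(all(ch$parent2 %in% tpl$id))
  expect_true(all(ch$breakpoint >= 1 & ch$breakpoint <= 119))
  expect_true(all(nchar(ch$sequence) == 120))
  expect_true(all(ch$born_cycle >= 1 & ch$born_cycle <= 12))
  # the chimeric sequence really is prefix + suffix at the homologous
  # coordinate: in the first cycle both source and partner are still
  # pure templates, so the identity is checkable directly
  first_gen <- ch[ch$born_cycle == 1, ]
  expect_gt(nrow(first_gen), 0)
  p1seq <- tpl$sequence[match(first_gen$parent1, tpl$id)]
  p2seq <- tpl$sequence[match(first_gen$parent2, tpl$id)]
  expect_true(all(substr(first_gen$sequence, 1, first_gen$breakpoint) ==
                    substr(p1seq, 1, first_gen$breakpoint)))
  expect_true(all(substr(first_gen$sequence, first_gen$breakpoint + 1, 120) ==
                    substr(p2seq, first_gen$breakpoint + 1, 120)))
  # deterministic under seed
  pool2 <- simulate_pcr(tpl, pcr_params(cycles1 = 12, cycles2 = 0,
                                        chimera_prob = 0.05, capacity = 5e4),
                        seed = 10)
  expect_identical(pool$counts, pool2$counts)
  expect_identical(pool$chimeras, pool2$chimeras)
})

test_that("read sampling emits the triple-index layout with exact truth", {
  scheme <- default_scheme()
  tpl <- make_mock_templates(n_species = 4, initial_copies = 300, seed = 21)
  pool <- simulate_pcr(tpl, pcr_params(cycles1 = 6, cycles2 = 0,
                                       chimera_prob = 0, capacity = 1e5),
                       seed = 3)
  rd <- sample_reads(pool, 200, well = list(fwd = "f3", rev = "r5"),
                     scheme = scheme, sample_id = "SX", seed = 14)
  expect_length(rd$r1$seq, 200L)
  expect_true(all(nchar(rd$r1$seq) == 250))
  # error-free reads parse back to the generating well
  p1 <- parse_read_start(rd$r1$seq, "forward", scheme, demux_config())
  p2 <- parse_read_start(rd$r2$seq, "reverse", scheme, demux_config())
  expect_true(all(p1$barcode == "f3"))
  expect_true(all(p2$barcode == "r5"))
  expect_true(all(rd$truth$parent1 %in% tpl$id))
  expect_true(all(!rd$truth$is_chimera))
  # chimera flag <-> two recorded parents
  expect_true(all(is.na(rd$truth$parent2)))

  # zero reads -> empty outputs and empty truth
  rd0 <- sample_reads(pool, 0, well = list(fwd = "f3", rev = "r5"),
                      scheme = scheme, seed = 1)
  expect_length(rd0$r1$seq, 0L)
  expect_equal(nrow(rd0$truth), 0L)

  # one-species pool propagates to a one-species truth table
  single <- template_set("only", tpl$sequence[1], initial_copies = 100)
  pool1 <- simulate_pcr(single, pcr_params(cycles1 = 4, cycles2 = 0,
                                           chimera_prob = 0), seed = 2)
  rd1 <- sample_reads(pool1, 50, well = list(fwd = "f1", rev = "r1"),
                      scheme = scheme, seed = 5)
  expect_true(all(rd1$truth$parent1 == "only"))
})

test_that("experiment simulation books a factorial design and is reproducible", {
  scheme <- default_scheme()
  tpl <- make_mock_templates(n_species = 4, initial_copies = 200, seed = 2)
  lay <- build_plate_layout(scheme$fwd, scheme$rev)
  w <- lay$wells[1:16, ]
  design <- data.frame(sample_id = paste0("S", 1:16), fwd = w$fwd, rev = w$rev,
                       pool_index = "p1",
                       cycles1 = rep(c(25, 35), each = 8),
                       template_amount = rep(c(2.5e6, 2.5e7), times = 8))
  sim <- simulate_experiment(design, tpl, scheme,
                             params = pcr_params(cycles2 = 5,
                                                 chimera_prob = 0,
                                                 capacity = 2e4),
                             n_reads = 20, seed = 31)
  expect_equal(nrow(sim$manifest), 16L)
  expect_equal(nrow(sim$truth), 16L * 20L)
  expect_setequal(unique(sim$truth$sample_id), design$sample_id)
  expect_equal(sim$manifest$cycles1, design$cycles1)
  expect_equal(sim$manifest$template_amount, design$template_amount)

  # byte-identical FASTQ under the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_experiment(sim, d1)
  sim2 <- simulate_experiment(design, tpl, scheme,
                              params = pcr_params(cycles2 = 5,
                                                  chimera_prob = 0,
                                                  capacity = 2e4),
                              n_reads = 20, seed = 31)
  write_experiment(sim2, d2)
  for (f in c("p1_R1.fastq", "p1_R2.fastq", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  expect_error(simulate_experiment(design[c(1, 1), ], tpl, scheme),
               "duplicate sample ids")
  dup_well <- design[1:2, ]; dup_well$fwd <- "f1"; dup_well$rev <- "r1"
  expect_error(simulate_experiment(dup_well, tpl, scheme), "distinct")
})

test_that("same-index wells yield tenfold fewer reads when collapse is on", {
  scheme <- default_scheme()
  # reverse set reusing a forward sequence creates one same-index well
  rev2 <- barcode_set(c("rA", "rB"),
                      c(scheme$fwd$sequence[1], scheme$rev$sequence[1]),
                      c("", "C"), "reverse")
  sch <- structure(list(parts = scheme$parts, fwd = scheme$fwd, rev = rev2),
                   class = "scheme_spec")
  tpl <- make_mock_templates(n_species = 3, initial_copies = 100, seed = 4)
  design <- data.frame(sample_id = c("same", "diff"), fwd = c("f1", "f1"),
                       rev = c("rA", "rB"), pool_index = "p1")
  sim <- simulate_experiment(design, tpl, sch,
                             params = pcr_params(cycles1 = 5, cycles2 = 0,
                                                 chimera_prob = 0,
                                                 capacity = 1e4),
                             n_reads = 1000, same_index_collapse = TRUE,
                             seed = 7)
  expect_equal(sim$manifest$n_reads[sim$manifest$sample_id == "same"], 100)
  expect_equal(sim$manifest$n_reads[sim$manifest$sample_id == "diff"], 1000)
})
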