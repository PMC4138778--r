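test_that("generate_reference: determinism, GC control, homopolymer control", {
  g1 <- generate_reference(300, seed = 42)
  g2 <- generate_reference(300, seed = 42)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(g1$ref, f1); write_fasta(g2$ref, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
  expect_false(identical(
    generate_reference(300, seed = 43)$ref$seqs, g1$ref$seqs))

  # flat gradient at 0.5 -> mean site GC ~ 0.5
  gf <- generate_reference(2000, gc_gradient = c(0.5, 0.5), seed = 7)
  gcs <- vapply(seq_len(2000), function(i)
    gc_content(gf$ref, gf$panel$chrom[i], gf$panel$pos[i]), numeric(1))
  expect_equal(mean(gcs), 0.5, tolerance = 0.04)

  # no planted homopolymers: lengths stay at the iid background
  g0 <- generate_reference(500, homopolymer_rate = 0, seed = 9,
                           gc_gradient = c(0.5, 0.5))
  hp0 <- vapply(seq_len(500), function(i)
    homopolymer_length(g0$ref, g0$panel$chrom[i], g0$panel$pos[i]), integer(1))
  gp <- generate_reference(500, homopolymer_rate = 1, seed = 9,
                           gc_gradient = c(0.5, 0.5))
  hpp <- vapply(seq_len(500), function(i)
    homopolymer_length(gp$ref, gp$panel$chrom[i], gp$panel$pos[i]), integer(1))
  expect_lt(mean(hp0), 3)
  expect_gt(mean(hpp), mean(hp0) + 1)

  expect_error(generate_reference(10, spacing = 80, seed = 1), "infeasible")
})

test_that("simulate_truth: HWE genotypes and frequency extremes", {
  panel <- toy_panel(50)
  t0 <- simulate_truth(panel, 4, freq_range = c(0, 0), seed = 1)
  expect_true(all(t0$geno == 0L))
  t1 <- simulate_truth(panel, 4, freq_range = c(1, 1), seed = 1)
  expect_true(all(t1$geno == 2L))

  big <- toy_panel(5000)
  th <- simulate_truth(big, 12, freq_range = c(0.5, 0.5), seed = 2)
  expect_equal(mean(th$geno == 1L), 0.5, tolerance = 0.02)   # 2pq at p = 0.5
  expect_equal(mean(th$geno) / 2, 0.5, tolerance = 0.02)     # allele freq
})

test_that("simulate_platform: zero error is the identity; events log is exact", {
  gen <- generate_reference(200, seed = 3)
  feats <- annotate_features(gen$panel, gen$ref)
  truth <- simulate_truth(gen$panel, 4, seed = 4)

  z <- simulate_platform(truth, feats, zero_error(error_model("exome")), seed = 5)
  expect_identical(unname(z$states), unname(truth$geno))
  expect_equal(nrow(z$events), 0L)

  m <- simulate_platform(truth, feats, error_model("exome", b0 = -2), seed = 6)
  # every call that differs from truth is exactly one logged event
  diff_idx <- which(m$states != truth$geno | is.na(m$states), arr.ind = TRUE)
  got <- data.table::data.table(site = diff_idx[, 1],
                                sample = truth$samples[diff_idx[, 2]])
  data.table::setorder(got, site, sample)
  ev <- unique(m$events[, .(site, sample)])
  data.table::setorder(ev, site, sample)
  # events with no visible effect (miscall landing on a missed hom-ref) are
  # allowed; every visible difference must be logged
  expect_true(nrow(got) <= nrow(ev))
  expect_equal(nrow(data.table::fsetdiff(got, ev)), 0L)

  m2 <- simulate_platform(truth, feats, error_model("exome", b0 = -2), seed = 6)
  expect_identical(m$states, m2$states)            # same seed, same calls
})

test_that("GC-sensitive platform under-calls high-GC sites", {
  gen <- generate_reference(2000, gc_gradient = c(0.1, 0.9), seed = 11)
  feats <- annotate_features(gen$panel, gen$ref)
  truth <- simulate_truth(gen$panel, 6, seed = 12)
  sim <- simulate_platform(truth, feats,
                           error_model("exome", b0 = -3, b_gc = 4, b_homo = 0,
                                       b_depth = 0),
                           seed = 13)
  missed <- rowSums(sim$states != truth$geno)
  hi <- feats$gc > stats::median(feats$gc)
  expect_gt(mean(missed[hi]), mean(missed[!hi]) * 1.5)
})

test_that("emit_fixtures: determinism and configured no-call rates", {
  cfg <- sim_config(n_sites = 150, n_samples = 3, seed = 21)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- emit_fixtures(simulate_dataset(cfg), d1)
  f2 <- emit_fixtures(simulate_dataset(cfg), d2)
  for (nm in names(f1))
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                     info = nm)                    # byte-identical fixture set

  # flat 5% exome miss rate: alt-positive call count ~ 0.95 x truth
  cfg5 <- sim_config(n_sites = 2000, n_samples = 6, seed = 22,
                     wgs = zero_error(error_model("wgs")),
                     exome = error_model("exome", b0 = qlogis(0.05),
                                         b_depth = 0, b_gc = 0, b_homo = 0,
                                         miscall = 0),
                     array = zero_error(error_model("array")),
                     n_manifest_flip_probes = 0)
  sim5 <- simulate_dataset(cfg5)
  truth_alt <- sum(sim5$truth$geno >= 1L)
  called_alt <- sum(alt_positive(sim5$tensor$state[, , "exome"]))
  expect_equal(called_alt / truth_alt, 0.95, tolerance = 0.01)
})

test_that("exome target fraction halves the harmonized panel", {
  cfg <- zero_error_config(n_sites = 200, n_samples = 2, seed = 31,
                           exome_target_fraction = 0.5)
  d <- tempfile()
  run_simulation(cfg, d)
  suppressMessages(b <- run_full_analysis(file.path(d, "analysis.config")))
  expect_equal(b$panel_counters$n_final, 100L)
})

test_that("sim_config validates its stated world", {
  expect_error(sim_config(n_sites = 100), "seed is mandatory")
  expect_error(sim_config(n_sites = 0, seed = 1), "n_sites")
  expect_error(sim_config(n_sites = 10, n_samples = 1, seed = 1), "n_samples")
  expect_error(error_model("wgs", nonsense = 1), "unknown")
})
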