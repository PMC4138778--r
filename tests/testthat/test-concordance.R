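test_that("alt_positive and Venn classification", {
  expect_true(alt_positive(1L))
  expect_true(alt_positive(2L))
  expect_false(alt_positive(0L))
  expect_false(alt_positive(NA_integer_))

  # one sample, 8 sites spanning all combinations of (array, wgs, exome)
  g <- expand.grid(o = c(0L, 1L), h = c(0L, 1L), p = c(0L, 1L))
  tn <- toy_tensor(cbind(g$o), cbind(g$h), cbind(g$p))
  cls <- classify_venn(tn, "S01")
  expect_equal(cls$class[g$o == 1 & g$h == 1 & g$p == 1], "OHP")
  expect_equal(cls$class[g$o == 1 & g$h == 1 & g$p == 0], "OH")
  expect_equal(cls$class[g$o == 0 & g$h == 0 & g$p == 0], "NONE")
  expect_false(any(cls$missing_involved))

  vc <- venn_counts(tn, "S01")
  expect_equal(sum(vc), 8L)           # partition covers the panel
  expect_true(all(vc == 1L))

  tn2 <- toy_tensor(cbind(NA_integer_), cbind(1L), cbind(1L))
  expect_true(classify_venn(tn2, "S01")$missing_involved)
})

test_that("sample_summary equals a naive triple-loop recount on random tensors", {
  naive <- function(tensor, sample) {
    pos <- function(p) {
      s <- tensor$state[, sample, p]
      !is.na(s) & s >= 1L
    }
    o <- pos("array"); h <- pos("wgs"); p <- pos("exome")
    cnt <- c(total = 0, o = 0, h = 0, p = 0, all = 0, ho = 0, hp = 0, op = 0)
    for (i in seq_len(nrow(tensor$panel))) {
      if (o[i] || h[i] || p[i]) cnt["total"] <- cnt["total"] + 1
      if (o[i]) cnt["o"] <- cnt["o"] + 1
      if (h[i]) cnt["h"] <- cnt["h"] + 1
      if (p[i]) cnt["p"] <- cnt["p"] + 1
      if (o[i] && h[i] && p[i]) cnt["all"] <- cnt["all"] + 1
      if (h[i] && o[i]) cnt["ho"] <- cnt["ho"] + 1
      if (h[i] && p[i]) cnt["hp"] <- cnt["hp"] + 1
      if (o[i] && p[i]) cnt["op"] <- cnt["op"] + 1
    }
    cnt
  }
  for (seed in 1:6) {
    tn <- random_tensor(sample(10:50, 1), 4, seed = seed)
    for (s in tn$samples) {
      sm <- sample_summary(tn, s)
      nv <- naive(tn, s)
      expect_equal(sm$total_calls, unname(nv["total"]))
      expect_equal(sm$n_omni, unname(nv["o"]))
      expect_equal(sm$n_hiseq, unname(nv["h"]))
      expect_equal(sm$n_proton, unname(nv["p"]))
      expect_equal(sm$all_concordant, unname(nv["all"]))
      expect_equal(sm$ho_concordant, unname(nv["ho"]))
      expect_equal(sm$hp_concordant, unname(nv["hp"]))
      expect_equal(sm$op_concordant, unname(nv["op"]))
      # inclusion-exclusion identity
      expect_equal(sm$total_calls,
                   sm$n_omni + sm$n_hiseq + sm$n_proton - sm$ho_concordant -
                     sm$op_concordant - sm$hp_concordant + sm$all_concordant)
      # Venn partition
      expect_equal(sum(venn_counts(tn, s)), nrow(tn$panel))
    }
  }
})

test_that("identical platforms collapse all summary counts", {
  set.seed(4)
  m <- matrix(sample(0:2, 60, replace = TRUE), 20, 3)
  tn <- toy_tensor(m, m, m)
  sm <- sample_summary(tn, "S02")
  npos <- sum(m[, 2] >= 1)
  expect_true(all(unlist(
    sm[, .(total_calls, n_omni, n_hiseq, n_proton, all_concordant,
           ho_concordant, hp_concordant, op_concordant)]) == npos))
  expect_equal(sm$proton_support, 1)
})

test_that("overall_concordance: extremes, a derived toy, symmetry, missing policy", {
  n <- 10L
  same <- matrix(rep(c(0L, 1L), 5), n, 1)
  tn_same <- toy_tensor(same, same, same)
  expect_equal(as.numeric(overall_concordance(tn_same, "wgs", "array")), 1.0)

  flip <- 1L - same
  tn_flip <- toy_tensor(same, flip, same)
  expect_equal(as.numeric(overall_concordance(tn_flip, "wgs", "array")), 0.0)

  # 4 sites x 1 sample, 3 agreements out of 4 pairs (enumerated by hand)
  a <- cbind(c(1L, 0L, 1L, 0L)); b <- cbind(c(1L, 0L, 0L, 0L))
  tn <- toy_tensor(a, b, a)
  expect_equal(as.numeric(overall_concordance(tn, "wgs", "array",
                                              include_negatives = TRUE)), 0.75)
  # alt-positive universe: sites {1, 3}; both positive only at site 1
  expect_equal(as.numeric(overall_concordance(tn, "wgs", "array",
                                              include_negatives = FALSE)), 0.5)

  for (seed in 1:4) {
    tn <- random_tensor(30, 3, seed = seed + 50)
    for (neg in c(TRUE, FALSE))
      expect_equal(
        as.numeric(overall_concordance(tn, "wgs", "exome", neg)),
        as.numeric(overall_concordance(tn, "exome", "wgs", neg)))
  }

  # MISSING pairs: excluded from the denominator vs counted discordant
  a <- cbind(c(1L, NA, 1L)); b <- cbind(c(1L, 1L, 0L))
  tnm <- toy_tensor(a, b, a)
  ex <- overall_concordance(tnm, "wgs", "array", missing_policy = "exclude")
  expect_equal(as.numeric(ex), 1 / 2)
  expect_equal(attr(ex, "n_missing_pairs"), 1L)
  expect_equal(as.numeric(overall_concordance(tnm, "wgs", "array",
                                              missing_policy = "discordant")),
               1 / 3)
})

test_that("adding a discordant site never increases concordance", {
  set.seed(77)
  base <- matrix(sample(0:2, 40, replace = TRUE), 20, 2)
  tn <- toy_tensor(base, base, base)
  f0 <- as.numeric(overall_concordance(tn, "wgs", "array"))
  withdisc <- function(m, v) rbind(m, v)
  tn2 <- toy_tensor(withdisc(base, c(1L, 1L)), withdisc(base, c(0L, 0L)),
                    withdisc(base, c(1L, 1L)))
  expect_lt(as.numeric(overall_concordance(tn2, "wgs", "array")), f0 + 1e-12)
  expect_lt(as.numeric(overall_concordance(tn2, "wgs", "array",
                                           include_negatives = FALSE)),
            f0 + 1e-12)
})

test_that("allele_count_matrix: corners, diagonal, marginals, transpose", {
  ns <- 12L
  hom <- matrix(2L, 1, ns)
  tn <- toy_tensor(hom, hom, hom)
  m <- allele_count_matrix(tn, "wgs", "array")
  expect_equal(dim(m), c(25L, 25L))
  expect_equal(m["24", "24"], 1L)
  expect_equal(sum(m), 1L)

  set.seed(5)
  g <- matrix(sample(0:2, 30 * ns, replace = TRUE), 30, ns)
  tn2 <- toy_tensor(g, g, g)
  m2 <- allele_count_matrix(tn2, "wgs", "array")
  expect_equal(sum(m2), 30L)                       # total = panel size
  expect_equal(sum(diag(m2)), 30L)                 # perfect agreement: diagonal
  # marginals equal the per-platform allele-count histograms
  ac <- rowSums(matrix(pmin(g, 2), 30, ns))
  expect_equal(unname(rowSums(m2)),
               unname(as.integer(table(factor(ac, levels = 0:24)))))

  tn3 <- random_tensor(40, 12, seed = 8)
  expect_equal(allele_count_matrix(tn3, "array", "exome"),
               t(allele_count_matrix(tn3, "exome", "array")))
})

test_that("common_discordant_sites requires discordance in every sample", {
  ns <- 12L
  o <- matrix(1L, 5, ns)
  h <- o
  h[2, ] <- 0L                        # discordant everywhere
  h[3, 1:11] <- 0L                    # discordant in 11/12 samples only
  h[5, ] <- 0L                        # discordant everywhere
  tn <- toy_tensor(o, h, o)
  expect_equal(common_discordant_sites(tn, "wgs", "array"), c(2L, 5L))
  expect_length(common_discordant_sites(tn, "array", "array"), 0L)
  expect_length(common_discordant_sites(tn, "exome", "array"), 0L)
})

test_that("discordance_summary classes partition per-sample discordance", {
  tn <- random_tensor(40, 4, seed = 12)
  ds <- discordance_summary(tn)
  per <- ds[seq_along(tn$samples)]
  expect_equal(per$total_discordant,
               per$proton_conc_hiseq_disc + per$hiseq_conc_proton_disc +
                 per$both_discordant)
  expect_equal(per$both_discordant,
               per$ngs_agree_both_disc + per$all_discordant)
})
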