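test_that("blebbing tables tally frequencies per group in order", {
  rec <- data.frame(group = rep(c("ctrl", "ko"), c(10, 8)),
                    blebbing = c(rep(c(TRUE, FALSE), c(3, 7)),
                                 rep(c(TRUE, FALSE), c(5, 3))))
  tb <- blebbing_table(rec)
  expect_equal(tb$group, c("ctrl", "ko"))
  expect_equal(tb$frequency[1], 0.30)
  expect_equal(tb$blebbing, c(3L, 5L))
  expect_equal(tb$non_blebbing, c(7L, 3L))
  # explicit factor ordering is preserved
  rec$group <- factor(rec$group, levels = c("ko", "ctrl"))
  expect_equal(blebbing_table(rec)$group, c("ko", "ctrl"))
  # empty group errors by name
  rec2 <- rec; rec2$group <- factor(rec2$group, levels = c("ko", "ctrl", "wt"))
  expect_error(blebbing_table(rec2), "wt")
})

test_that("group tallies from a simulated experiment match ground truth", {
  groups <- list(a = scene_params(n_cells = 5, blebbing_fraction = 0.2),
                 b = scene_params(n_cells = 5, blebbing_fraction = 0.8))
  rec <- suppressMessages(simulate_experiment(groups, scenes_per_group = 1, seed = 2))
  tb <- blebbing_table(rec)
  truth_tally <- tapply(rec$true_blebbing, rec$group, sum)
  expect_equal(tb$blebbing, as.integer(truth_tally[tb$group]))
})

test_that("two-sided Fisher p-values match exhaustive enumeration", {
  expect_equal(fisher_exact_p(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_p(matrix(c(5, 5, 5, 5), 2)), 1.0)
  set.seed(33)
  for (i in 1:200) {
    m <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (sum(m) == 0 || sum(m) > 40) next
    expect_equal(fisher_exact_p(m), fisher_oracle(m), tolerance = 1e-12)
    # and agrees with the standard implementation's convention
    if (sum(m[1, ]) > 0 && sum(m[2, ]) > 0)
      expect_equal(fisher_exact_p(m), fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("BH adjustment equals the step-up formula and is monotone", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  set.seed(34)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    tb <- data.frame(group = letters[1:2], blebbing = c(3, 9),
                     non_blebbing = c(17, 11))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("pairwise Fisher results are symmetric, adjusted, and bounded", {
  tb <- data.frame(group = c("g1", "g2", "g3", "g4"),
                   blebbing = c(3, 12, 7, 20),
                   non_blebbing = c(47, 38, 43, 30))
  out <- fisher_pairwise_fdr(tb)
  expect_equal(nrow(out$results), 6L)
  expect_true(all(out$results$p_adjusted >= out$results$p_raw - 1e-12))
  expect_true(all(out$results$p_adjusted <= 1))
  expect_equal(out$results$p_adjusted,
               bh_oracle(out$results$p_raw), tolerance = 1e-12)
  expect_identical(out$p_adjusted_matrix, t(out$p_adjusted_matrix))
  expect_equal(unname(diag(out$p_adjusted_matrix)), rep(1, 4))
  expect_error(fisher_pairwise_fdr(tb[1, , drop = FALSE]), "at least 2")
  tb0 <- tb; tb0$blebbing[2] <- 0; tb0$non_blebbing[2] <- 0
  expect_error(fisher_pairwise_fdr(tb0), "zero total")
})

test_that("two-way ANOVA on log counts detects a shifted group", {
  set.seed(35)
  hits <- 0L
  for (i in 1:100) {
    n <- 100
    counts <- pmax(5, round(10^rnorm(4 * n, log10(30), 0.25)))
    rec <- data.frame(fa_count = counts,
                      genotype = rep(c("wt", "ko"), each = 2 * n),
                      treatment = rep(rep(c("veh", "drug"), each = n), 2))
    shift <- rec$genotype == "ko" & rec$treatment == "drug"
    rec$fa_count[shift] <- pmax(5, round(rec$fa_count[shift] * 2))
    out <- fa_group_test(rec, c("genotype", "treatment"))
    sig <- out$tukey[grepl("ko:drug", out$tukey$group_a) |
                     grepl("ko:drug", out$tukey$group_b), ]
    if (all(sig$p_adjusted < 0.05)) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("the interaction test holds its nominal size under the null", {
  set.seed(36)
  rej <- 0L
  n_sim <- 200L
  for (i in seq_len(n_sim)) {
    n <- 100
    rec <- data.frame(fa_count = pmax(5, round(10^rnorm(4 * n, log10(30), 0.25))),
                      genotype = rep(c("wt", "ko"), each = 2 * n),
                      treatment = rep(rep(c("veh", "drug"), each = n), 2))
    out <- fa_group_test(rec, c("genotype", "treatment"))
    p_int <- out$anova$p[out$anova$term == "A:B"]
    if (p_int < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_sim, 0.03)
  expect_lte(rej / n_sim, 0.07)
})

test_that("degenerate all-equal responses report a no-variance condition", {
  rec <- data.frame(fa_count = rep(10, 40),
                    genotype = rep(c("wt", "ko"), each = 20),
                    treatment = rep(rep(c("a", "b"), each = 10), 2))
  out <- fa_group_test(rec, c("genotype", "treatment"))
  expect_true(out$no_variance)
  expect_true(all(out$tukey$p_adjusted == 1))
  expect_true(all(out$rank$p_adjusted == 1))
  # structural errors
  expect_error(fa_group_test(rec[rec$treatment == "a" | rec$genotype == "wt", ],
                             c("genotype", "treatment")), "empty design cell")
  rec0 <- rec; rec0$fa_count[1] <- 0
  expect_error(fa_group_test(rec0, c("genotype", "treatment")), "log-defined")
})

test_that("ANOVA main-effect p agrees with a permutation oracle", {
  set.seed(37)
  n <- 12
  rec <- data.frame(
    fa_count = pmax(2, round(10^rnorm(4 * n, log10(30), 0.2))),
    genotype = rep(c("wt", "ko"), each = 2 * n),
    treatment = rep(rep(c("veh", "drug"), each = n), 2))
  rec$fa_count[rec$genotype == "ko"] <-
    pmax(2, round(rec$fa_count[rec$genotype == "ko"] * 1.12))
  out <- fa_group_test(rec, c("genotype", "treatment"))
  p_aov <- out$anova$p[out$anova$term == "A"]
  y <- log10(rec$fa_count)
  f_obs <- balanced_f_a(y, rec$genotype, rec$treatment)
  f_perm <- replicate(10000, balanced_f_a(sample(y), rec$genotype, rec$treatment))
  p_perm <- mean(f_perm >= f_obs)
  expect_lt(abs(p_aov - p_perm), 0.02)
})

test_that("spreading sample arithmetic matches the nested protocol", {
  expect_equal(spreading_sample_size(8, 3, 3), 72L)
  expect_equal(spreading_sample_size(1, 1, 1), 1L)
  set.seed(38)
  for (i in 1:10) {
    abc <- sample(1:6, 3, replace = TRUE)
    # brute-force enumeration of the sampling grid
    cnt <- 0L
    for (p in seq_len(abc[3])) for (f in seq_len(abc[2]))
      for (ce in seq_len(abc[1])) cnt <- cnt + 1L
    expect_equal(spreading_sample_size(abc[1], abc[2], abc[3]), cnt)
  }
})
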