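test_that("Clopper-Pearson limits match the beta-quantile closed form", {
  # boundary closed form
  ci <- proportion_ci(0, 10)
  expect_equal(ci[["estimate"]], 0)
  expect_equal(ci[["lower"]], 0)
  expect_equal(ci[["upper"]], 1 - 0.025^(1 / 10), tolerance = 1e-12)
  # symmetry at the midpoint
  ci5 <- proportion_ci(5, 10)
  expect_equal(ci5[["lower"]], 1 - ci5[["upper"]], tolerance = 1e-12)
  # independent beta-quantile oracle
  for (xn in list(c(76, 100), c(3, 20), c(59, 60))) {
    x <- xn[1]; n <- xn[2]
    ci <- proportion_ci(x, n)
    expect_equal(ci[["lower"]], qbeta(0.025, x, n - x + 1),
                 tolerance = 1e-10)
    expect_equal(ci[["upper"]], qbeta(0.975, x + 1, n - x),
                 tolerance = 1e-10)
  }
  expect_error(proportion_ci(11, 10), "n_responded")
})

test_that("omnibus chi-square equals the direct Pearson sum", {
  tab <- data.frame(group = c("a", "b"), n_tested = c(100, 100),
                    n_responded = c(35, 76))
  res <- omnibus_chisq(tab)
  m <- cbind(c(35, 76), c(65, 24))
  expect_equal(res$statistic, pearson_chisq_direct(m), tolerance = 1e-12)
  expect_identical(res$df, 1L)
  expect_equal(res$p_raw, pchisq(res$statistic, 1, lower.tail = FALSE))
})

test_that("identical groups give statistic 0 and p 1 for any k", {
  for (k in c(2, 4, 6)) {
    tab <- data.frame(group = letters[1:k], n_tested = 80, n_responded = 40)
    res <- omnibus_chisq(tab)
    expect_equal(res$statistic, 0, tolerance = 1e-12)
    expect_equal(res$p_raw, 1)
    expect_equal(res$df, k - 1)
  }
})

test_that("zero expected counts advise an exact test", {
  tab <- data.frame(group = c("a", "b"), n_tested = c(10, 10),
                    n_responded = c(0, 0))
  expect_error(omnibus_chisq(tab), "exact test")
})

test_that("post-hoc pairs are BH-adjusted exactly as the step-up oracle", {
  tab <- data.frame(group = c("w", "x", "y", "z"),
                    n_tested = c(120, 100, 90, 110),
                    n_responded = c(90, 40, 50, 80))
  ph <- posthoc_chisq(tab, adjust = "fdr")
  expect_identical(nrow(ph), 6L)
  # raw p oracle per pair, then independent BH
  raw <- mapply(function(i, j)
    chisq_p_2x2(tab$n_responded[i], tab$n_tested[i],
                tab$n_responded[j], tab$n_tested[j]),
    combn(4, 2)[1, ], combn(4, 2)[2, ])
  expect_equal(ph$p_raw, unname(raw), tolerance = 1e-12)
  expect_equal(ph$p_adjusted, bh_stepup(ph$p_raw), tolerance = 1e-12)
  expect_true(all(ph$p_adjusted >= ph$p_raw))
})

test_that("post-hoc on identical groups returns all-1 adjusted p", {
  tab <- data.frame(group = c("a", "b", "c"), n_tested = 50,
                    n_responded = 20)
  ph <- posthoc_chisq(tab)
  expect_true(all(ph$p_adjusted == 1))
})

test_that("two-group post-hoc reproduces the omnibus p exactly", {
  tab <- data.frame(group = c("a", "b"), n_tested = c(100, 130),
                    n_responded = c(76, 45))
  expect_equal(posthoc_chisq(tab)$p_raw, omnibus_chisq(tab)$p_raw,
               tolerance = 1e-15)
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(11)
  a <- rnorm(15, 0.3, 0.1); b <- rnorm(20, 0.5, 0.1)
  res <- anova_tukey(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(res$p_raw, tt$p.value, tolerance = 1e-8)
})

test_that("Tukey HSD matches the studentized-range computation", {
  set.seed(12)
  g <- list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10))
  res <- anova_tukey(g)
  expect_identical(nrow(res$tukey), 3L)
  # reference: ptukey on the pairwise mean difference
  mse <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1)) / 27
  dab <- abs(mean(g$b) - mean(g$a)) / sqrt(mse / 10)
  p_ref <- ptukey(dab, 3, 27, lower.tail = FALSE)
  row <- res$tukey[res$tukey$contrast == "b-a", ]
  expect_equal(row$p_adjusted, p_ref, tolerance = 1e-8)
  expect_true(all(res$tukey$lwr <= res$tukey$diff &
                  res$tukey$diff <= res$tukey$upr))
})

test_that("degenerate constant groups are guarded", {
  expect_error(anova_tukey(list(a = c(1, 1), b = c(1, 1))),
               "zero variance")
  res <- anova_tukey(list(a = c(1, 1), b = c(2, 2)))
  expect_true(res$degenerate)
  expect_identical(res$p_raw, 0)
})

test_that("ANOVA type-I error is calibrated at the nominal level", {
  set.seed(101)
  F <- simulate_anova_F(1000, k = 3, n_per = 26, means = c(0, 0, 0))
  rate <- mean(F > qf(0.95, 2, 75))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("Tukey familywise error is controlled in an all-null design", {
  set.seed(55)
  hits <- vapply(1:2000, function(i) {
    g <- split(rnorm(4 * 26), rep(1:4, each = 26))
    names(g) <- letters[1:4]
    any(anova_tukey(g)$tukey$p_adjusted < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 0.02)
})

test_that("power functions return alpha exactly at zero effect", {
  expect_equal(power_chisq(0, N = 500, df = 16, alpha = 0.01), 0.01,
               tolerance = 1e-9)
  expect_equal(power_anova(0, k = 3, n_per_group = 26, alpha = 0.05),
               0.05, tolerance = 1e-9)
})

test_that("power is monotone in effect size and sample size", {
  pw <- vapply(seq(0, 0.6, 0.1), power_chisq, 1, N = 200, df = 4)
  expect_true(all(diff(pw) > 0))
  pn <- vapply(c(50, 100, 200, 400, 800), function(n)
    power_chisq(0.2, N = n, df = 4), numeric(1))
  expect_true(all(diff(pn) > 0))
  pa <- vapply(seq(0, 0.5, 0.1), power_anova, 1, k = 3, n_per_group = 26)
  expect_true(all(diff(pa) > 0))
  pan <- vapply(c(10, 20, 40, 80), function(n)
    power_anova(0.25, k = 3, n_per_group = n), numeric(1))
  expect_true(all(diff(pan) > 0))
})

test_that("effect-size conventions resolve to Cohen's values", {
  expect_equal(power_chisq("medium", N = 500, df = 16, alpha = 0.01),
               power_chisq(0.3, N = 500, df = 16, alpha = 0.01))
  expect_equal(power_anova("medium", k = 3, n_per_group = 26),
               power_anova(0.25, k = 3, n_per_group = 26))
})

test_that("Clopper-Pearson coverage is at least nominal (exact check)", {
  for (n in c(20, 60)) for (p in c(0.1, 0.5, 0.9)) {
    expect_gte(cp_coverage_exact(p, n), 0.95)
  }
})

test_that("assay analysis composes proportions, omnibus and post-hoc", {
  probs <- assay_panel("kinase_panel")
  rows <- lapply(seq_along(probs), function(i)
    simulate_population(list(name = names(probs)[i],
                             response_prob = probs[[i]]),
                        500, seed = 400 + i)$assay_row)
  tab <- do.call(rbind, rows)
  rep <- analyze_assay(tab, reference = "TH/+")
  expect_s3_class(rep, "per_assay_report")
  pr <- rep$proportions
  ratio <- pr$proportion[pr$group == "TH>G2019S"] /
    pr$proportion[pr$group == "TH/+"]
  expect_lt(abs(ratio - 0.35 / 0.76), 0.1)
  expect_lt(rep$vs_reference$p_adjusted[1], 0.001)
  expect_error(analyze_assay(tab, reference = "absent"), "reference")
})

test_that("a same-probability panel rarely reports adjusted significance", {
  clean <- vapply(1:100, function(r) {
    rows <- lapply(1:3, function(i)
      simulate_population(list(name = letters[i], response_prob = 0.6),
                          60, seed = 7000 + 10 * r + i)$assay_row)
    all(posthoc_chisq(do.call(rbind, rows))$p_adjusted >= 0.05)
  }, logical(1))
  expect_gte(mean(clean), 0.95)
})

test_that("a single-group table reports proportions only", {
  tab <- data.frame(group = "only", n_tested = 40, n_responded = 30)
  rep <- analyze_assay(tab)
  expect_identical(nrow(rep$proportions), 1L)
  expect_null(rep$omnibus)
  expect_null(rep$pairwise)
})

test_that("stratified tables yield within-group rescue comparisons", {
  tab <- data.frame(group = rep(c("TH>G2019S", "TH/+"), each = 2),
                    stratum = rep(c("vehicle", "drug"), 2),
                    n_tested = 130,
                    n_responded = c(42, 57, 95, 93))
  rep <- analyze_assay(tab, reference = "TH/+")
  expect_identical(nrow(rep$rescue), 2L)
  expect_true(all(sub(":.*", "", rep$rescue$group1) ==
                  sub(":.*", "", rep$rescue$group2)))
})
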