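#' Exact (Clopper-Pearson) binomial confidence interval for a proportion
#'
#' @param n_responded Number of responders.
#' @param n_tested Number of flies tested.
#' @param conf Confidence level.
#' @return Named numeric vector: `estimate`, `lower`, `upper`.
#' @examples
#' proportion_ci(76, 100)
#' @export
proportion_ci <- function(n_responded, n_tested, conf = 0.95) {
  if (n_tested < 1 || n_responded < 0 || n_responded > n_tested)
    stop("need 0 <= n_responded <= n_tested with n_tested >= 1")
  if (conf <= 0 || conf >= 1) stop("'conf' must be in (0, 1)")
  bt <- binom.test(n_responded, n_tested, conf.level = conf)
  c(estimate = n_responded / n_tested,
    lower = bt$conf.int[1], upper = bt$conf.int[2])
}

as_contingency <- function(table) {
  need <- c("group", "n_tested", "n_responded")
  if (!all(need %in% names(table)))
    stop("assay table needs columns: ", paste(need, collapse = ", "))
  if (any(table$n_tested < 1) ||
      any(table$n_responded < 0 | table$n_responded > table$n_tested))
    stop("need 0 <= n_responded <= n_tested with n_tested >= 1")
  m <- cbind(responded = table$n_responded,
             not = table$n_tested - table$n_responded)
  rownames(m) <- as.character(table$group)
  m
}

#' Omnibus Pearson chi-square test on an assay table
#'
#' Tests homogeneity of response proportions across all groups of a
#' `groups x (responded, not)` contingency table. No continuity
#' correction by default (set `correct = TRUE` for Yates' correction on
#' 2x2 tables).
#'
#' @param table Data frame with columns `group`, `n_tested`,
#'   `n_responded` (>= 2 rows).
#' @param correct Apply Yates' continuity correction (2x2 only).
#' @return List of class `per_test`: `statistic`, `df`, `p_raw`,
#'   `method`.
#' @examples
#' tab <- data.frame(group = c("ctrl", "mut"), n_tested = c(100, 100),
#'                   n_responded = c(76, 35))
#' omnibus_chisq(tab)
#' @export
omnibus_chisq <- function(table, correct = FALSE) {
  m <- as_contingency(table)
  if (nrow(m) < 2L) stop("need at least 2 groups")
  exp_counts <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(exp_counts == 0))
    stop("a cell has expected count 0; use an exact test instead")
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_raw = ct$p.value,
                 method = if (correct)
                   "Pearson chi-square (Yates-corrected)"
                 else "Pearson chi-square"),
            class = "per_test")
}

#' @export
print.per_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  X-squared = %.4g, df = %s, p = %.4g\n",
              x$statistic, paste(x$df, collapse = ", "), x$p_raw))
  invisible(x)
}

map_adjust <- function(adjust) {
  a <- match.arg(adjust, c("fdr", "BH", "bonferroni", "holm", "none"))
  if (a == "fdr") "BH" else a
}

#' Pairwise post-hoc chi-square tests with multiplicity adjustment
#'
#' Runs a 2x2 Pearson chi-square test on every pair of groups and adjusts
#' the p-values for multiple comparisons (Benjamini-Hochberg by default).
#' Pairs are reported in the (deterministic) row order of the table.
#'
#' @inheritParams omnibus_chisq
#' @param adjust Adjustment method: `"fdr"` (Benjamini-Hochberg, default),
#'   `"bonferroni"`, `"holm"` or `"none"`.
#' @return Data frame with one row per pair: `group1`, `group2`,
#'   `statistic`, `df`, `p_raw`, `p_adjusted`, plus attributes `method`
#'   and `adjustment`.
#' @examples
#' tab <- data.frame(group = c("a", "b", "c"),
#'                   n_tested = c(100, 100, 100),
#'                   n_responded = c(76, 35, 40))
#' posthoc_chisq(tab)
#' @export
posthoc_chisq <- function(table, adjust = "fdr", correct = FALSE) {
  m <- as_contingency(table)
  if (nrow(m) < 2L) stop("need at least 2 groups")
  adj <- map_adjust(adjust)
  pairs <- utils::combn(nrow(m), 2)
  rows <- apply(pairs, 2, function(ij) {
    sub <- m[ij, , drop = FALSE]
    exp_counts <- outer(rowSums(sub), colSums(sub)) / sum(sub)
    if (any(exp_counts == 0))
      stop("pair (", rownames(m)[ij[1]], ", ", rownames(m)[ij[2]],
           ") has an expected count of 0; use an exact test instead")
    ct <- suppressWarnings(chisq.test(sub, correct = correct))
    data.frame(group1 = rownames(m)[ij[1]], group2 = rownames(m)[ij[2]],
               statistic = unname(ct$statistic),
               df = unname(ct$parameter), p_raw = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_raw, method = adj)
  rownames(out) <- NULL
  attr(out, "method") <- if (correct)
    "pairwise Pearson chi-square (Yates-corrected)"
  else "pairwise Pearson chi-square"
  attr(out, "adjustment") <- adj
  out
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Fixed-effects one-way ANOVA of a continuous kinematic readout
#' (typically episode duration) across groups, followed by Tukey honest
#' significant difference pairwise comparisons via the studentized-range
#' distribution.
#'
#' If every group is internally constant the F statistic is degenerate:
#' with distinct means the result is reported as `statistic = Inf`,
#' `p_raw = 0` with `degenerate = TRUE`; with identical means it is an
#' error.
#'
#' @param groups Either a named list of numeric vectors, or a data frame
#'   with columns `group` and `value`.
#' @param conf Confidence level for the Tukey intervals.
#' @return List of class `per_anova`: `statistic` (F), `df` (c(df1,
#'   df2)), `p_raw`, `degenerate`, `tukey` (data frame `contrast`,
#'   `diff`, `lwr`, `upr`, `p_adjusted`), `method`.
#' @examples
#' set.seed(1)
#' anova_tukey(list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10)))
#' @export
anova_tukey <- function(groups, conf = 0.95) {
  if (is.data.frame(groups)) {
    if (!all(c("group", "value") %in% names(groups)))
      stop("data frame input needs columns 'group' and 'value'")
    df <- data.frame(group = as.character(groups$group),
                     value = groups$value)
  } else if (is.list(groups)) {
    if (is.null(names(groups))) stop("list input must be named by group")
    df <- data.frame(
      group = rep(names(groups), lengths(groups)),
      value = unlist(groups, use.names = FALSE))
  } else stop("'groups' must be a named list or a data frame")
  df <- df[complete.cases(df), ]
  sizes <- table(df$group)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) stop("every group needs at least 2 values")
  within_var <- tapply(df$value, df$group, var)
  if (all(within_var == 0)) {
    means <- tapply(df$value, df$group, mean)
    if (max(means) - min(means) == 0)
      stop("zero variance within and between groups; ANOVA undefined")
    k <- length(sizes); N <- nrow(df)
    return(structure(list(statistic = Inf, df = c(k - 1, N - k),
                          p_raw = 0, degenerate = TRUE, tukey = NULL,
                          method = "one-way ANOVA (degenerate: zero within-group variance)"),
                     class = "per_anova"))
  }
  df$group <- factor(df$group)
  fit <- aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = conf)$group
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adjusted = tk[, "p adj"], row.names = NULL)
  structure(list(statistic = tab[1, "F value"],
                 df = c(tab[1, "Df"], tab[2, "Df"]),
                 p_raw = tab[1, "Pr(>F)"], degenerate = FALSE,
                 tukey = tukey, method = "one-way ANOVA + Tukey HSD"),
            class = "per_anova")
}

#' @export
print.per_anova <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n", x$df[1], x$df[2],
              x$statistic, x$p_raw))
  if (!is.null(x$tukey)) {
    cat("  Tukey HSD:\n")
    print(x$tukey, row.names = FALSE)
  }
  invisible(x)
}

resolve_effect <- function(effect, kind) {
  if (is.character(effect)) {
    conv <- if (kind == "w") c(small = 0.1, medium = 0.3, large = 0.5)
            else c(small = 0.1, medium = 0.25, large = 0.4)
    effect <- unname(conv[match.arg(effect, names(conv))])
  }
  if (!is.numeric(effect) || length(effect) != 1L || effect < 0)
    stop("effect size must be a non-negative scalar (or small/medium/large)")
  effect
}

#' Power of the chi-square test of association
#'
#' Computes `P[chi2_noncentral(df, lambda) > chi2_crit(df, alpha)]` with
#' noncentrality `lambda = w^2 * N`, where `w` is Cohen's effect size for
#' contingency tables.
#'
#' @param w Cohen's w, or one of `"small"`, `"medium"`, `"large"`
#'   (0.1 / 0.3 / 0.5).
#' @param N Total sample size.
#' @param df Degrees of freedom of the test.
#' @param alpha Significance level.
#' @return Power (scalar in `[alpha, 1]` for `w >= 0`).
#' @examples
#' power_chisq(w = 0.3, N = 500, df = 16, alpha = 0.01)
#' @export
power_chisq <- function(w, N, df, alpha = 0.05) {
  w <- resolve_effect(w, "w")
  if (N < 2 || df < 1) stop("need N >= 2 and df >= 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  crit <- qchisq(1 - alpha, df)
  pchisq(crit, df, ncp = w^2 * N, lower.tail = FALSE)
}

#' Power of the one-way ANOVA F test
#'
#' Computes `P[F_noncentral(k-1, N-k, lambda) > F_crit(k-1, N-k, alpha)]`
#' with noncentrality `lambda = f^2 * N`, `N = k * n_per_group`, where
#' `f` is Cohen's effect size for the ratio of the between-group SD of
#' the means to the within-group SD.
#'
#' @param f Cohen's f, or one of `"small"`, `"medium"`, `"large"`
#'   (0.1 / 0.25 / 0.4).
#' @param k Number of groups.
#' @param n_per_group Flies per group.
#' @param alpha Significance level.
#' @return Power (scalar in `[alpha, 1]` for `f >= 0`).
#' @examples
#' power_anova(f = 0.25, k = 3, n_per_group = 26)
#' @export
power_anova <- function(f, k, n_per_group, alpha = 0.05) {
  f <- resolve_effect(f, "f")
  if (k < 2) stop("need k >= 2 groups")
  if (n_per_group < 2) stop("need n_per_group >= 2")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  N <- k * n_per_group
  crit <- qf(1 - alpha, k - 1, N - k)
  pf(crit, k - 1, N - k, ncp = f^2 * N, lower.tail = FALSE)
}

#' Analyze a population assay table
#'
#' Full statistical report for an assay table: per-group response
#' proportions with exact binomial confidence limits; the omnibus
#' chi-square test; pairwise post-hoc chi-square tests with multiplicity
#' adjustment; the subset of pairs involving a declared reference group;
#' and, when the table carries a `stratum` column (e.g. drug vs vehicle),
#' the within-group across-stratum "rescue" comparisons.
#'
#' With a single row only the proportion and its confidence interval are
#' reported.
#'
#' @param table Data frame with columns `group`, `n_tested`,
#'   `n_responded` and optionally `stratum`.
#' @param reference Optional reference group label (must be present).
#' @param adjust Multiplicity adjustment (see [posthoc_chisq()]).
#' @param conf Confidence level for the proportion intervals.
#' @param correct Yates' continuity correction for the pairwise tests.
#' @return List of class `per_assay_report` with elements `proportions`,
#'   `omnibus`, `pairwise`, `vs_reference`, `rescue`, `config`,
#'   `config_hash`, `package_version`.
#' @examples
#' tab <- data.frame(group = c("TH/+", "TH>G2019S"),
#'                   n_tested = c(100, 100), n_responded = c(76, 35))
#' analyze_assay(tab, reference = "TH/+")
#' @export
analyze_assay <- function(table, reference = NULL, adjust = "fdr",
                          conf = 0.95, correct = FALSE) {
  if (!all(c("group", "n_tested", "n_responded") %in% names(table)))
    stop("assay table needs columns group, n_tested, n_responded")
  tab <- as.data.frame(table)
  has_strata <- "stratum" %in% names(tab) &&
    length(unique(tab$stratum)) > 1L
  cell <- if (has_strata) paste(tab$group, tab$stratum, sep = ":")
          else as.character(tab$group)
  if (anyDuplicated(cell)) stop("group (x stratum) labels must be unique")
  work <- data.frame(group = cell, n_tested = tab$n_tested,
                     n_responded = tab$n_responded)
  props <- do.call(rbind, lapply(seq_len(nrow(work)), function(i) {
    ci <- proportion_ci(work$n_responded[i], work$n_tested[i], conf)
    data.frame(group = work$group[i], n_tested = work$n_tested[i],
               n_responded = work$n_responded[i],
               proportion = ci[["estimate"]], lower = ci[["lower"]],
               upper = ci[["upper"]])
  }))
  if (!is.null(reference) && !reference %in% c(work$group, tab$group))
    stop("reference group '", reference, "' is not in the table")
  omnibus <- pairwise <- vs_ref <- rescue <- NULL
  if (nrow(work) >= 2L) {
    omnibus <- omnibus_chisq(work, correct = correct)
    pairwise <- posthoc_chisq(work, adjust = adjust, correct = correct)
    if (!is.null(reference)) {
      is_ref <- function(lab) lab == reference |
        (has_strata & sub(":[^:]*$", "", lab) == reference)
      vs_ref <- pairwise[is_ref(pairwise$group1) |
                         is_ref(pairwise$group2), , drop = FALSE]
      rownames(vs_ref) <- NULL
    }
    if (has_strata) {
      base <- function(lab) sub(":[^:]*$", "", lab)
      keep <- base(pairwise$group1) == base(pairwise$group2)
      rescue <- pairwise[keep, , drop = FALSE]
      rownames(rescue) <- NULL
    }
  }
  config <- list(reference = reference, adjust = map_adjust(adjust),
                 conf = conf, correct = correct)
  structure(list(proportions = props, omnibus = omnibus,
                 pairwise = pairwise, vs_reference = vs_ref,
                 rescue = rescue, config = config,
                 config_hash = config_hash(config),
                 package_version = as.character(packageVersion("perkin"))),
            class = "per_assay_report")
}

#' @export
print.per_assay_report <- function(x, ...) {
  cat("PER assay report (perkin ", x$package_version, ", hash ",
      x$config_hash, ")\n", sep = "")
  cat("Proportions (", x$config$conf * 100, "% exact CI):\n", sep = "")
  pr <- x$proportions
  for (i in seq_len(nrow(pr)))
    cat(sprintf("  %-24s %3d/%3d  %.3f [%.3f, %.3f]\n", pr$group[i],
                pr$n_responded[i], pr$n_tested[i], pr$proportion[i],
                pr$lower[i], pr$upper[i]))
  if (!is.null(x$omnibus)) { cat("Omnibus: "); print(x$omnibus) }
  if (!is.null(x$vs_reference) && nrow(x$vs_reference)) {
    cat("Versus reference '", x$config$reference, "' (",
        attr(x$pairwise, "adjustment"), "-adjusted):\n", sep = "")
    print(x$vs_reference, row.names = FALSE)
  }
  invisible(x)
}
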