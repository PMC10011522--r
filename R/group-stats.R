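#' Paired t-test
#'
#' Thin, validated wrapper around the paired Student t-test on differences
#' `x - y`, with an explicit one- or two-tailed alternative.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @param tail `"two"` (default), `"less"` (alternative: mean of x - y < 0)
#'   or `"greater"`.
#' @return List of class `paired_test`: `t`, `df`, `p`, `tail`,
#'   `mean_difference`.
#' @export
paired_t <- function(x, y, tail = c("two", "less", "greater")) {
  tail <- match.arg(tail)
  if (length(x) != length(y)) stop_invalid("x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop_invalid("need at least 2 complete pairs (got %d)", n)
  d <- x - y
  if (sd(d) == 0)
    stop_invalid("zero-variance differences: paired t-test undefined")
  alt <- switch(tail, two = "two.sided", less = "less", greater = "greater")
  tt <- t.test(x, y, paired = TRUE, alternative = alt)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, tail = tail, n = n,
                 mean_difference = unname(tt$estimate)),
            class = "paired_test")
}

#' One-way between-groups ANOVA
#'
#' Classical fixed-effects one-way ANOVA (equal variances assumed), with
#' df = (k - 1, N - k).
#'
#' @param groups Named list of numeric vectors, one per group (each n >= 2).
#' @return List of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, `design = "between"`.
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ow <- oneway.test(values ~ g, var.equal = TRUE)
  structure(list(F = unname(ow$statistic),
                 df_between = unname(ow$parameter[1]),
                 df_within = unname(ow$parameter[2]),
                 p = ow$p.value, design = "between"),
            class = "anova_result")
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA on a complete subjects-by-conditions matrix;
#' df = (k - 1, (k - 1)(n - 1)). No sphericity correction is applied by
#' default (matching the conventional unannotated F report);
#' `gg_correction = TRUE` applies the Greenhouse-Geisser epsilon to the
#' degrees of freedom used for the p-value.
#'
#' @param mat Numeric matrix, subjects in rows, conditions in columns,
#'   no missing cells (no imputation is attempted).
#' @param gg_correction Apply Greenhouse-Geisser correction to the p-value.
#' @return List of class `anova_result`: `F`, `df_between` (conditions),
#'   `df_within` (error), `p`, `design = "within"` (plus `epsilon` when
#'   corrected).
#' @export
rm_anova <- function(mat, gg_correction = FALSE) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat)))
    stop_invalid("missing or non-finite cells: complete matrix required")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop_invalid("need >= 2 subjects and >= 2 conditions")
  df <- data.frame(y = as.vector(mat),
                   subj = factor(rep(seq_len(n), times = k)),
                   cond = factor(rep(seq_len(k), each = n)))
  a <- aov(y ~ cond + Error(subj), data = df)
  s <- summary(a)[["Error: Within"]][[1]]
  Fv <- s["cond", "F value"]
  df1 <- s["cond", "Df"]; df2 <- s["Residuals", "Df"]
  eps <- NULL
  # a condition effect that is negligible against the data's total variation
  # is zero (guards against 0/0 noise in condition-constant designs)
  ss_tot <- sum((mat - mean(mat))^2)
  if (s["cond", "Sum Sq"] <= 1e-10 * max(ss_tot, 1e-300)) Fv <- 0
  else if (!is.finite(Fv)) Fv <- Inf   # real effect with error-free residuals
  p <- pf(Fv, df1, df2, lower.tail = FALSE)
  if (gg_correction) {
    eps <- gg_epsilon(mat)
    p <- pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
  }
  structure(list(F = unname(Fv), df_between = df1, df_within = df2,
                 p = unname(p), design = "within", epsilon = eps),
            class = "anova_result")
}

# Greenhouse-Geisser epsilon from the double-centred covariance of conditions
gg_epsilon <- function(mat) {
  S <- stats::cov(mat)
  k <- ncol(S)
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

#' Tukey-Kramer post-hoc comparisons
#'
#' All pairwise group contrasts using the studentized-range distribution;
#' under unequal group sizes the Tukey-Kramer harmonic correction applies,
#' and with equal n this reduces exactly to Tukey's HSD.
#'
#' @param groups Named list of numeric vectors (as for [one_way_anova()]).
#' @return Tibble of class contrasts: `pair`, `estimate` (difference in
#'   means), `p_adjusted`, `method = "tukey_kramer"`.
#' @export
tukey_kramer <- function(groups) {
  check_groups(groups)
  labs <- group_labels(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labs, lengths(groups)), levels = labs)
  tk <- TukeyHSD(aov(values ~ g))$g
  tibble::tibble(pair = rownames(tk), estimate = tk[, "diff"],
                 p_adjusted = tk[, "p adj"], method = "tukey_kramer")
}

#' Fisher's least-significant-difference pairwise tests
#'
#' Pairwise t-tests sharing the pooled within-group standard deviation
#' (error df = N - k), optionally Bonferroni-adjusted.
#'
#' @param groups Named list of numeric vectors.
#' @param adjust `"none"` (classic LSD) or `"bonferroni"`.
#' @return Tibble: `pair`, `estimate`, `p_adjusted`, `method`.
#' @export
lsd_pairwise <- function(groups, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  check_groups(groups)
  labs <- group_labels(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labs, lengths(groups)), levels = labs)
  pt <- pairwise.t.test(values, g, p.adjust.method = adjust, pool.sd = TRUE)
  means <- vapply(groups, mean, numeric(1))
  pairs <- which(!is.na(pt$p.value), arr.ind = TRUE)
  tibble::tibble(
    pair = paste(rownames(pt$p.value)[pairs[, 1]],
                 colnames(pt$p.value)[pairs[, 2]], sep = "-"),
    estimate = means[rownames(pt$p.value)[pairs[, 1]]] -
      means[colnames(pt$p.value)[pairs[, 2]]],
    p_adjusted = pt$p.value[pairs],
    method = if (adjust == "none") "lsd" else "lsd_bonferroni")
}

#' Bonferroni adjustment
#'
#' @param p Vector of raw p-values.
#' @param m Number of comparisons (default `length(p)`).
#' @return `min(1, p * m)` per element.
#' @examples
#' bonferroni_adjust(0.02, m = 3) # 0.06
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_invalid("p-values must be in [0,1]")
  if (m < 1) stop_invalid("m must be >= 1")
  pmin(1, p * m)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop_invalid("need a list of >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop_invalid("every group needs >= 2 observations")
  if (any(!vapply(groups, function(x) all(is.finite(x)), TRUE)))
    stop_invalid("groups must be finite numeric")
}

group_labels <- function(groups) {
  if (is.null(names(groups))) paste0("g", seq_along(groups)) else names(groups)
}

#' Cohort-level statistical report
#'
#' The full between/within battery on a cohort's seizure indices:
#' per-group mean and SD of the three normalized index changes; within-group
#' paired t-tests of raw post vs pre indices (one-tailed post < pre for
#' count and duration -- the suppression hypothesis is directional -- and
#' two-tailed for amplitude); and between-group one-way ANOVA with
#' Tukey-Kramer contrasts on the normalized changes. Animals with undefined
#' normalized indices are dropped listwise per index (counts reported).
#'
#' @param normalized Tibble from [normalize_indices()] including `group`.
#' @param indices Tibble from [compute_indices()] including `group` (raw
#'   per-period indices, used for the paired tests).
#' @return List of class `cohort_report`: `group_summary` (tibble),
#'   `paired_tests`, `anova`, `posthoc` per index, `n_dropped`.
#' @export
analyze_cohort <- function(normalized, indices) {
  stopifnot("group" %in% names(normalized), "group" %in% names(indices))
  groups <- unique(normalized$group)
  fields <- c(count = "count_change_pct", duration = "duration_change_pct",
              amplitude = "amplitude_change_pct")
  raw_fields <- c(count = "ictal_count",
                  duration = "ictal_duration_per_event_s",
                  amplitude = "ictal_amplitude_per_event_uv")
  summ <- list(); anovas <- list(); posthocs <- list(); paired <- list()
  n_dropped <- integer(0)
  for (f in names(fields)) {
    by_group <- lapply(setNames(groups, groups), function(g) {
      v <- normalized[[fields[[f]]]][normalized$group == g]
      v[is.finite(v)]
    })
    n_dropped[[f]] <- sum(normalized$group %in% groups) -
      sum(lengths(by_group))
    summ[[f]] <- tibble::tibble(
      index = f, group = groups,
      n = lengths(by_group)[groups],
      mean_change_pct = vapply(by_group, mean, 1)[groups],
      sd_change_pct = vapply(by_group, sd, 1)[groups])
    if (length(groups) >= 2 && all(lengths(by_group) >= 2)) {
      anovas[[f]] <- one_way_anova(by_group)
      posthocs[[f]] <- tukey_kramer(by_group)
    } else {
      warning(sprintf("between-group tests skipped for %s (degenerate design)", f))
    }
    paired[[f]] <- lapply(setNames(groups, groups), function(g) {
      sub <- indices[indices$group == g, ]
      pre <- sub[sub$period == "pre", ]
      post <- sub[sub$period == "post", ]
      ids <- intersect(pre$animal_id, post$animal_id)
      x <- post[[raw_fields[[f]]]][match(ids, post$animal_id)]
      y <- pre[[raw_fields[[f]]]][match(ids, pre$animal_id)]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 2) return(NULL)
      tail <- if (f %in% c("count", "duration")) "less" else "two"
      tryCatch(paired_t(x[ok], y[ok], tail = tail), error = function(e) NULL)
    })
  }
  structure(list(group_summary = dplyr::bind_rows(summ),
                 paired_tests = paired, anova = anovas, posthoc = posthocs,
                 n_dropped = n_dropped),
            class = "cohort_report")
}

#' Dialysis-arm statistical report
#'
#' Repeated-measures comparison of unbound-drug concentrations: RM-ANOVA
#' across the focal-cassette (FF) pulsing parameter sets; RM-ANOVA across
#' the three cassette conditions (Ctrl, FO, FF averaged over sets per run);
#' Bonferroni-adjusted pairwise paired t contrasts; a paired comparison of
#' the 25% vs 50% duty-cycle sets; and relative concentration increases of
#' every condition over Ctrl.
#'
#' @param samples Tibble from [generate_dialysis_samples()] (or measured
#'   data) with columns `run`, `condition`, `concentration_ug_ml`.
#' @return List of class `dialysis_report`.
#' @export
analyze_dialysis <- function(samples) {
  stopifnot(all(c("run", "condition", "concentration_ug_ml") %in%
                  names(samples)))
  conds <- unique(samples$condition)
  wide <- condition_matrix(samples, conds)
  ff <- grep("^FF", conds, value = TRUE)
  out <- list()
  safe_paired_p <- function(x, y)
    tryCatch(paired_t(x, y)$p, error = function(e) NA_real_)
  if (length(ff) >= 2) {
    out$rm_anova_ff_sets <- rm_anova(wide[, ff, drop = FALSE])
    pairs <- utils::combn(ff, 2)
    praw <- apply(pairs, 2, function(pr)
      safe_paired_p(wide[, pr[1]], wide[, pr[2]]))
    out$pairwise_ff <- tibble::tibble(
      pair = apply(pairs, 2, paste, collapse = "-"),
      estimate = apply(pairs, 2, function(pr)
        mean(wide[, pr[1]]) - mean(wide[, pr[2]])),
      p_adjusted = bonferroni_adjust(praw),
      method = "paired_t_bonferroni")
  }
  if (all(c("Ctrl", "FO") %in% conds) && length(ff) >= 1) {
    cond3 <- cbind(Ctrl = wide[, "Ctrl"], FO = wide[, "FO"],
                   FF = rowMeans(wide[, ff, drop = FALSE]))
    out$rm_anova_conditions <- rm_anova(cond3)
    praw <- c(`FF-Ctrl` = safe_paired_p(cond3[, "FF"], cond3[, "Ctrl"]),
              `FF-FO` = safe_paired_p(cond3[, "FF"], cond3[, "FO"]),
              `FO-Ctrl` = safe_paired_p(cond3[, "FO"], cond3[, "Ctrl"]))
    out$pairwise_conditions <- tibble::tibble(
      pair = names(praw), p_adjusted = bonferroni_adjust(unname(praw)),
      method = "paired_t_bonferroni")
  }
  if ("Ctrl" %in% conds) {
    ctrl_mean <- mean(wide[, "Ctrl"])
    out$relative_increase_vs_ctrl_pct <- setNames(
      100 * (colMeans(wide) / ctrl_mean - 1), colnames(wide))
  }
  out$condition_means <- colMeans(wide)
  structure(out, class = "dialysis_report")
}

condition_matrix <- function(samples, conds) {
  runs <- sort(unique(samples$run))
  wide <- matrix(NA_real_, length(runs), length(conds),
                 dimnames = list(runs, conds))
  for (r in seq_len(nrow(samples)))
    wide[as.character(samples$run[r]), samples$condition[r]] <-
      samples$concentration_ug_ml[r]
  if (any(is.na(wide)))
    stop_invalid("incomplete paired design: every run needs every condition")
  wide
}
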