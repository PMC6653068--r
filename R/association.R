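#' Odds ratio of a 2x2 exposure/outcome table
#'
#' Cell convention: `a` = exposed with outcome, `b` = exposed without,
#' `c` = unexposed with, `d` = unexposed without ("exposed" being the
#' comparison group, e.g. the discordant subgroup). The point estimate is the
#' cross-product ratio `(a*d)/(b*c)`, identical to the single-binary-covariate
#' logistic-regression odds ratio, with a Wald confidence interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. A zero cell yields
#' `Inf`/`0` sentinels (no continuity correction by default, optionally
#' Haldane-Anscombe +0.5 via `haldane`), a degenerate flag, and an exact
#' conditional p-value in place of the Wald one.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @param conf_level confidence level for the Wald interval (default 0.95).
#' @param haldane add 0.5 to every cell before estimation (default FALSE).
#' @return A list of class `association_result`: `or`, `ci_low`, `ci_high`,
#'   `p_wald`, `p_exact` (computed for degenerate tables, otherwise `NA`),
#'   `method`, `degenerate`.
#' @export
#' @examples
#' odds_ratio(12, 20, 5, 64)$or  # 7.68
odds_ratio <- function(a, b, c, d, conf_level = 0.95, haldane = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0), sum(cells) >= 1)
  if (haldane) cells <- cells + 0.5
  degenerate <- any(cells == 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (!degenerate) {
    or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
    se <- sqrt(sum(1 / cells))
    ci <- exp(log(or) + c(-1, 1) * z * se)
    p_wald <- 2 * stats::pnorm(-abs(log(or)) / se)
    res <- list(or = unname(or), ci_low = ci[1], ci_high = ci[2],
                p_wald = unname(p_wald), p_exact = NA_real_,
                method = "wald_logistic", degenerate = FALSE)
  } else {
    num <- cells["a"] * cells["d"]
    den <- cells["b"] * cells["c"]
    or <- if (den > 0) unname(num / den) else if (num > 0) Inf else NaN
    ex <- exact_test(a, b, c, d)
    res <- list(or = or, ci_low = NA_real_, ci_high = NA_real_,
                p_wald = NA_real_, p_exact = ex$p,
                method = "exact", degenerate = TRUE)
  }
  class(res) <- "association_result"
  res
}

#' Conditional exact test of a 2x2 table
#'
#' Conditional exact inference given the table margins: the two-sided
#' Fisher-type p-value sums the noncentral (here central, under the null)
#' hypergeometric probabilities of all tables no more probable than the one
#' observed, and the odds ratio is the conditional maximum-likelihood
#' estimate (infinite when a zero cell forces separation). This is the
#' small-sample analogue of exact logistic regression for a single binary
#' covariate.
#'
#' @inheritParams odds_ratio
#' @return A list with `p` (two-sided exact p) and `or_cond` (conditional
#'   MLE odds ratio).
#' @export
exact_test <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab)
  list(p = ft$p.value, or_cond = unname(ft$estimate))
}

#' Rare-event flag for a characteristic
#'
#' A binary characteristic is "rare" when fewer than 5% of the cohort carry
#' it; rare characteristics are analysed with the exact conditional test
#' instead of the Wald interval.
#'
#' @param a,c outcome-positive counts in the exposed and unexposed groups.
#' @param cohort_n total number of patients.
#' @return Logical scalar.
#' @export
rare_flag <- function(a, c, cohort_n) {
  stopifnot(cohort_n > 0)
  (a + c) / cohort_n < 0.05
}

#' Associate cluster labels with every binary characteristic
#'
#' Builds the 2x2 table of each characteristic against a two-group label
#' vector and reports the odds ratio of the exposed (comparison) group,
#' choosing the Wald logistic method or the exact conditional test by the
#' rare-event rule. Patients with a missing flag are excluded from that
#' characteristic's table; an all-missing characteristic is skipped with a
#' warning.
#'
#' @param labels named two-group label vector (names = patient ids).
#' @param characteristics data.frame with `patient_id` and 0/1 flag columns.
#' @param exposed the label value treated as the exposed/comparison group
#'   (default: the less frequent group).
#' @param conf_level Wald confidence level.
#' @return data.frame with one row per characteristic: counts, odds ratio,
#'   Wald CI, p-value and method tag.
#' @export
associate_all <- function(labels, characteristics, exposed = NULL,
                          conf_level = 0.95) {
  stopifnot(!is.null(names(labels)), is.data.frame(characteristics))
  groups <- unique(labels)
  if (length(groups) != 2) stop("labels must define exactly two groups")
  if (is.null(exposed)) {
    exposed <- names(which.min(table(labels)))
    if (is.numeric(labels)) exposed <- as.numeric(exposed)
  }
  if (!exposed %in% groups) stop("exposed group not present in labels")
  flags <- setdiff(names(characteristics), "patient_id")
  ch <- characteristics[match(names(labels), characteristics$patient_id), ,
                        drop = FALSE]
  cohort_n <- length(labels)
  rows <- list()
  for (flag in flags) {
    x <- ch[[flag]]
    ok <- !is.na(x)
    if (!any(ok)) {
      warning(sprintf("characteristic %s has no observed values; skipped", flag))
      next
    }
    exp_grp <- labels[ok] == exposed
    a <- sum(x[ok] == 1 & exp_grp)
    b <- sum(x[ok] == 0 & exp_grp)
    cc <- sum(x[ok] == 1 & !exp_grp)
    dd <- sum(x[ok] == 0 & !exp_grp)
    res <- odds_ratio(a, b, cc, dd, conf_level = conf_level)
    use_exact <- rare_flag(a, cc, cohort_n) || res$degenerate
    if (use_exact && !res$degenerate) {
      res$p_exact <- exact_test(a, b, cc, dd)$p
      res$method <- "exact"
    }
    rows[[flag]] <- data.frame(
      characteristic = flag,
      n_exposed_with = a, n_exposed_without = b,
      n_ref_with = cc, n_ref_without = dd,
      or = res$or, ci_low = res$ci_low, ci_high = res$ci_high,
      p = if (res$method == "exact") res$p_exact else res$p_wald,
      method = res$method)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Biomarker / disease-activity concordance profile of one patient
#'
#' Flags each consecutive-visit interval as synchronized when the biomarker
#' and the activity score move in the same direction (equal signs of the
#' consecutive differences, with sign in {-1, 0, +1}), and reports the
#' percentage of synchronized intervals together with the Pearson correlation
#' of the two raw series.
#'
#' @param biomarker,activity equal-length numeric vectors (>= 2 visits).
#' @return A list of class `concordance_profile`: `interval_flags` (logical),
#'   `percent_sync` in \[0, 100\] and `pearson_r`.
#' @export
concordance_profile <- function(biomarker, activity) {
  if (length(biomarker) != length(activity)) {
    stop("series must have equal length")
  }
  if (length(biomarker) < 2) stop("need at least 2 visits")
  flags <- sign(diff(biomarker)) == sign(diff(activity))
  r <- if (stats::sd(biomarker) == 0 || stats::sd(activity) == 0) {
    NA_real_
  } else {
    stats::cor(biomarker, activity)
  }
  structure(list(interval_flags = flags,
                 percent_sync = 100 * mean(flags),
                 pearson_r = r),
            class = "concordance_profile")
}
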