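#' Worked-example subgroup characteristic counts
#'
#' Loads the bundled per-characteristic counts of binary clinical flags in
#' two patient subgroups of a 101-patient lupus cohort (a concordant
#' subgroup of 69 and a discordant subgroup of 32 patients), used as
#' worked-example input for the odds-ratio association analysis. Columns:
#' `characteristic`, `n_1A_with`, `n_1A_total`, `n_1B_with`, `n_1B_total`.
#' Three rows are degenerate for a cross-product odds ratio (a zero cell or
#' a full column): `serositis`, `prednisolone`, `immunosuppressants`.
#'
#' @return data.frame of counts.
#' @export
#' @examples
#' counts <- subgroup_count_table()
#' row <- counts[counts$characteristic == "musculoskeletal", ]
#' odds_ratio(row$n_1B_with, row$n_1B_total - row$n_1B_with,
#'            row$n_1A_with, row$n_1A_total - row$n_1A_with)$or
subgroup_count_table <- function() {
  path <- system.file("extdata", "subgroup_counts.csv", package = "lupustraj")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Odds ratios from a subgroup count table
#'
#' Computes, for every characteristic in a count table shaped like
#' [subgroup_count_table()], the odds ratio of the discordant ("1B",
#' exposed) subgroup versus the concordant ("1A") subgroup, with Wald
#' confidence limits or exact sentinels for degenerate tables.
#'
#' @param counts data.frame as returned by [subgroup_count_table()].
#' @return data.frame with `characteristic`, `or`, `ci_low`, `ci_high`,
#'   `p`, `method`, `degenerate`.
#' @export
subgroup_odds_ratios <- function(counts = subgroup_count_table()) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    res <- odds_ratio(r$n_1B_with, r$n_1B_total - r$n_1B_with,
                      r$n_1A_with, r$n_1A_total - r$n_1A_with)
    data.frame(characteristic = r$characteristic, or = res$or,
               ci_low = res$ci_low, ci_high = res$ci_high,
               p = if (res$degenerate) res$p_exact else res$p_wald,
               method = res$method, degenerate = res$degenerate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
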