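#' Percentage change
#'
#' `PC = 100 * (after - before) / before`, the effect-size currency used
#' for all before/after comparisons.
#'
#' @param before,after parameter values before and after conditioning.
#' @return percentage change.
#' @export
percent_change <- function(before, after) {
  if (any(before == 0))
    sp_stop("percentage change undefined for before = 0",
            "stimplast_undefined_error")
  100 * (after - before) / before
}

#' Session-level paired test on percentage changes
#'
#' Wilcoxon signed-rank test on paired before/after values across
#' sessions, reporting the percentage change of the means.
#'
#' @param before,after equal-length paired session values.
#' @param metric metric label carried into the result.
#' @param alpha significance level.
#' @return data.frame of class `session_comparison`: `metric`, `before`,
#'   `after`, `pc`, `test`, `p_value`, `significant`, `n`.
#' @export
session_level_tests <- function(before, after, metric = "metric",
                                alpha = 0.05) {
  if (length(before) != length(after) || length(before) < 2)
    sp_stop("need >= 2 paired sessions", "stimplast_argument_error")
  p <- if (all(after == before)) 1
       else suppressWarnings(wilcox.test(after, before, paired = TRUE)$p.value)
  out <- data.frame(metric = metric, before = mean(before),
                    after = mean(after),
                    pc = percent_change(mean(before), mean(after)),
                    test = "wilcoxon_signed_rank", p_value = p,
                    significant = p < alpha, n = length(before),
                    stringsAsFactors = FALSE)
  class(out) <- c("session_comparison", "data.frame")
  out
}

#' Two-sample KS test on pooled before/after distributions
#'
#' @param before_values,after_values non-empty pooled samples.
#' @return list: `statistic`, `p_value`.
#' @export
pooled_distribution_test <- function(before_values, after_values) {
  if (!length(before_values) || !length(after_values))
    sp_stop("both samples must be non-empty", "stimplast_argument_error")
  kt <- suppressWarnings(ks.test(before_values, after_values))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Bootstrap test for a before-to-after increase
#'
#' Bootstrap confidence interval of the mean paired difference; the change
#' is significant when the interval excludes zero.
#'
#' @param before,after matched pair values (e.g. per-pair MI).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed RNG seed.
#' @return list: `mean_diff`, `ci` (length 2), `significant`.
#' @export
bootstrap_increase_test <- function(before, after, n_boot = 100,
                                    conf = 0.95, seed = 1) {
  if (n_boot < 1)
    sp_stop("n_boot must be >= 1", "stimplast_argument_error")
  stopifnot(length(before) == length(after))
  d <- after - before
  old <- set.seed_scoped(seed)
  on.exit(restore_seed(old))
  boots <- vapply(seq_len(n_boot), function(b)
    mean(d[sample.int(length(d), replace = TRUE)]), numeric(1))
  ci <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2))
  list(mean_diff = mean(d), ci = unname(ci),
       significant = ci[1] > 0 || ci[2] < 0)
}

#' Before/after session report
#'
#' Assembles the summary table over all analyzed metrics: before value,
#' after value, percentage change, and (when per-session vectors are
#' supplied) the Wilcoxon signed-rank p-value.
#'
#' @param pre,post named lists of metric values (scalars, or equal-length
#'   per-session vectors).
#' @param alpha significance level.
#' @return data.frame: `metric`, `before`, `after`, `pc`, `p_value`,
#'   `significant`.
#' @export
build_report <- function(pre, post, alpha = 0.05) {
  if (!setequal(names(pre), names(post)))
    sp_stop("pre and post metric sets differ", "stimplast_argument_error")
  rows <- lapply(names(pre), function(nm) {
    b <- pre[[nm]]; a <- post[[nm]]
    if (length(b) > 1 && length(b) == length(a)) {
      r <- session_level_tests(b, a, metric = nm, alpha = alpha)
      data.frame(metric = nm, before = r$before, after = r$after, pc = r$pc,
                 p_value = r$p_value, significant = r$significant,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(metric = nm, before = mean(b), after = mean(a),
                 pc = percent_change(mean(b), mean(a)),
                 p_value = NA_real_, significant = NA,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
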