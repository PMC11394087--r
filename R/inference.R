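#' Bootstrap chi-square goodness of fit on pooled prey counts
#'
#' Tests whether prey individuals are spread unevenly over the observed
#' categories. Expected counts default to uniform over the `S` observed
#' categories, `E_i = T / S` with `T = sum(counts)`; the chi-square statistic
#' is `sum((O - E)^2 / E)`. Rather than the asymptotic reference, the null
#' distribution is built by resampling: each iteration draws `T` prey with
#' replacement from the null category distribution and recomputes the
#' statistic. The p value uses the add-one convention
#' `p = (1 + #(chi2_rep >= chi2_obs)) / (1 + iterations)`, so it is never
#' exactly zero. Standardized residuals `(O_i - E_i) / sqrt(E_i)` localize the
#' departure per category; `|r| > 1.96` is conventionally significant at the
#' 0.05 level.
#'
#' @param counts named vector of non-negative per-category pooled prey
#'   counts, positive sum, at least two categories. Include only the
#'   categories of the observed set: the statistic is not invariant under
#'   padding with never-observed categories (each extra category changes `S`
#'   and hence every `E_i`).
#' @param iterations bootstrap iterations, at least 100 (default 1000).
#' @param seed optional integer seed, recorded in the result.
#' @param expected optional null proportions (positive, recycled to sum 1)
#'   replacing the uniform null.
#' @return An object of class `"gof_boot"`: list with `chi2`, `p`,
#'   `observed`, `expected`, `residuals`, `iterations`, `seed`, `null_prob`.
#' @seealso [residual_flags()]
#' @export
#' @examples
#' gof <- bootstrap_gof(c(A = 40, B = 5, C = 5, D = 5), seed = 1)
#' gof$p
bootstrap_gof <- function(counts, iterations = 1000, seed = NULL, expected = NULL) {
  if (any(!is_count(counts)) || sum(counts) <= 0)
    stopf("counts must be non-negative integers with a positive sum")
  S <- length(counts)
  if (S < 2) stopf("goodness of fit is degenerate with a single category")
  if (iterations < 100) stopf("iterations must be at least 100")
  tot <- sum(counts)
  prob <- if (is.null(expected)) rep(1 / S, S) else {
    if (length(expected) != S || any(expected <= 0))
      stopf("expected must give a positive proportion per category")
    expected / sum(expected)
  }
  E <- tot * prob
  chi2_obs <- sum((counts - E)^2 / E)
  if (!is.null(seed)) set.seed(seed)
  reps <- stats::rmultinom(iterations, tot, prob)
  chi2_rep <- colSums((reps - E)^2 / E)
  p <- (1 + sum(chi2_rep >= chi2_obs - 1e-12)) / (1 + iterations)
  structure(list(chi2 = chi2_obs, p = p,
                 observed = counts, expected = stats::setNames(E, names(counts)),
                 residuals = stats::setNames((counts - E) / sqrt(E), names(counts)),
                 iterations = iterations, seed = seed, null_prob = prob),
            class = "gof_boot")
}

#' @export
print.gof_boot <- function(x, ...) {
  cat(sprintf("Bootstrap chi-square goodness of fit (%d categories, %d prey)\n",
              length(x$observed), sum(x$observed)))
  cat(sprintf("  chi2 = %.2f, p = %.4g (%d iterations%s)\n", x$chi2, x$p,
              x$iterations, if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  flg <- residual_flags(x)
  tab <- data.frame(observed = x$observed, expected = round(x$expected, 2),
                    residual = round(x$residuals, 2), flag = as.character(flg))
  print(tab)
  invisible(x)
}

#' Flag categories by standardized residual
#'
#' Classifies each category of a goodness-of-fit result as consumed more
#' (`over`), less (`under`) or as expected (`none`), by comparing its
#' standardized residual with a threshold (1.96 corresponds to the 0.05
#' level).
#'
#' @param gof a `"gof_boot"` result.
#' @param threshold positive residual cutoff (default 1.96).
#' @return Named factor with levels `under`, `none`, `over`.
#' @export
#' @examples
#' residual_flags(bootstrap_gof(c(A = 40, B = 5, C = 5, D = 5), seed = 1))
residual_flags <- function(gof, threshold = 1.96) {
  stopifnot(inherits(gof, "gof_boot"))
  r <- gof$residuals
  factor(ifelse(r > threshold, "over", ifelse(r < -threshold, "under", "none")),
         levels = c("under", "none", "over"))
}

#' Select diet items by relative importance
#'
#' Returns the categories whose RII reaches a threshold in at least one size
#' class (inclusive comparison) — the usual screen before per-item modelling,
#' with the conventional cutoff RII >= 1.0.
#'
#' @param metrics a `"diet_metrics"` table.
#' @param threshold minimum RII (default 1.0).
#' @return Character vector of category names, in first-appearance order.
#' @export
#' @examples
#' d <- table1_fixture()
#' m <- diet_metrics(diet_table(d, size_classes(300, 509, 3),
#'                              vtd_total = c(10, 7, 14)))
#' rii_filter(m)
rii_filter <- function(metrics, threshold = 1.0) {
  stopifnot(inherits(metrics, "diet_metrics"))
  keep <- metrics$category[metrics$rii >= threshold]
  unique(metrics$category)[unique(metrics$category) %in% keep]
}
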