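#' Full diet-composition analysis of a stomach-content dataset
#'
#' The package's central entry point: aggregates stomach-level records into
#' per-size-class diet tables and computes the deterministic composition
#' summaries in one call — the four diet indices with RII classification
#' ([diet_metrics()]), pooled frequency of occurrence ([pooled_occurrence()]),
#' Simpson diversity per class ([simpson_index()]) and pairwise Pianka niche
#' overlap ([niche_overlap()]). Resampling-based analyses (diversity
#' comparison, bootstrap goodness of fit, per-item logistic fits) are
#' separate, seed-taking functions; see [simpson_test()], [bootstrap_gof()]
#' and [presence_logit()].
#'
#' @param x a `"diet_data"` object (see [diet_data()], [read_diet()],
#'   [simulate_stomachs()], [table1_fixture()]).
#' @param scheme a [size_classes()] scheme; default: `k` equal-width classes
#'   spanning the observed TL range.
#' @param k number of size classes when `scheme` is `NULL` (default 3).
#' @param vtd_total optional explicit per-class total displaced volume (mL);
#'   see [diet_table()].
#' @param overlap_basis proportion basis for the Pianka overlap (default
#'   `"numeric"`).
#' @return An object of class `"diet_analysis"`: list with `scheme`, `table`
#'   (`"diet_table"`), `metrics` (`"diet_metrics"`), `pooled`, `diversity`
#'   (per-class Simpson `D`, `NA` for empty classes) and `overlap`
#'   (`"niche_overlap"`).
#' @export
#' @examples
#' d <- table1_fixture()
#' an <- diet_analysis(d, scheme = attr(d, "scheme"),
#'                     vtd_total = attr(d, "vtd_total"))
#' an
diet_analysis <- function(x, scheme = NULL, k = 3, vtd_total = NULL,
                          overlap_basis = "numeric") {
  stopifnot(inherits(x, "diet_data"))
  if (is.null(scheme))
    scheme <- size_classes(min(x$stomachs$tl_mm), max(x$stomachs$tl_mm), k)
  dt <- diet_table(x, scheme, vtd_total = vtd_total)
  metrics <- diet_metrics(dt)
  div <- vapply(seq_len(scheme$k), function(j) {
    cnt <- dt$n_i[dt$size_class == j]
    if (sum(cnt) > 0) simpson_index(cnt) else NA_real_
  }, numeric(1))
  structure(list(data = x, scheme = scheme, table = dt, metrics = metrics,
                 pooled = pooled_occurrence(dt),
                 diversity = stats::setNames(div, seq_len(scheme$k)),
                 overlap = niche_overlap(dt, basis = overlap_basis)),
            class = "diet_analysis")
}

#' @export
print.diet_analysis <- function(x, ...) {
  cat(sprintf("Diet-composition analysis: %d stomachs, %d categories, %d size classes\n",
              nrow(x$data$stomachs), nrow(x$data$categories), x$scheme$k))
  cat("Simpson diversity by class:",
      paste(sprintf("%s = %.4f", names(x$diversity), x$diversity), collapse = ", "), "\n")
  if (!is.null(x$overlap$pairs)) {
    cat("Pianka overlap:",
        paste(sprintf("%d-%d = %.4f (%s)", x$overlap$pairs$class_a,
                      x$overlap$pairs$class_b, x$overlap$pairs$overlap,
                      x$overlap$pairs$label), collapse = ", "), "\n")
  }
  cat("Top categories by pooled occurrence:\n")
  print(utils::head(x$pooled, 3), row.names = FALSE)
  invisible(x)
}

#' @export
summary.diet_analysis <- function(object, digits = 1, ...) {
  m <- object$metrics
  m$pct_n <- round_half_up(m$pct_n, digits)
  m$pct_v <- round_half_up(m$pct_v, digits)
  m$pct_fo <- round_half_up(m$pct_fo, digits)
  m$rii <- round_half_up(m$rii, digits)
  m$vd_ml <- round_half_up(m$vd_ml, digits)
  structure(list(metrics = m, analysis = object), class = "summary.diet_analysis")
}

#' @export
print.summary.diet_analysis <- function(x, ...) {
  print.diet_analysis(x$analysis)
  cat("\nPer-class diet metrics (display-rounded):\n")
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

#' Plot per-class relative importance
#'
#' Grouped bar plot of RII per category and size class, with the
#' low/secondary/high thresholds (10 and 40) as dashed reference lines.
#'
#' @param x a `"diet_analysis"` object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.diet_analysis <- function(x, ...) {
  m <- x$metrics
  cats <- unique(m$category)
  mat <- matrix(m$rii, nrow = x$scheme$k, byrow = TRUE,
                dimnames = list(paste("class", seq_len(x$scheme$k)), cats))
  graphics::barplot(mat, beside = TRUE, las = 2, ylab = "RII",
                    legend.text = rownames(mat), ...)
  graphics::abline(h = c(10, 40), lty = 2, col = "grey40")
  invisible(x)
}
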