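#' Numeric percentage of prey categories
#'
#' The share of all prey individuals in a class that belong to each category:
#' `%N_i = 100 * N_i / N_t` with `N_t = sum(N_i)`.
#'
#' @param counts non-negative per-category prey counts with positive sum.
#' @return Numeric vector of percentages summing to 100.
#' @export
#' @examples
#' numeric_percentage(c(1, 1, 2))
numeric_percentage <- function(counts) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  nt <- sum(counts)
  if (nt <= 0) stopf("numeric percentage undefined: total prey count is zero")
  100 * counts / nt
}

#' Volumetric percentage of prey categories
#'
#' The share of total displaced volume contributed by each category:
#' `%V_i = 100 * vd_i / vTd`. When `vTd` exceeds the sum of the per-category
#' volumes (a measured total including unidentified material), the percentages
#' sum to less than 100.
#'
#' @param vd non-negative per-category displaced volumes, mL.
#' @param vTd total displaced volume, mL, positive.
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' volumetric_percentage(2.5, vTd = 5)
volumetric_percentage <- function(vd, vTd) {
  if (any(vd < 0)) stopf("vd must be non-negative")
  if (length(vTd) != 1 || vTd <= 0) stopf("volumetric percentage undefined: vTd must be positive")
  100 * vd / vTd
}

#' Percentage frequency of occurrence
#'
#' The share of examined stomachs in which a category appears:
#' `%FO = 100 * n / N`.
#'
#' @param n incidence: number of stomachs containing the category.
#' @param N number of stomachs examined, positive; `n <= N`.
#' @return Numeric percentage (vectorized over `n`).
#' @export
#' @examples
#' frequency_occurrence(27, 31)
frequency_occurrence <- function(n, N) {
  if (length(N) != 1 || N <= 0) stopf("N must be a positive stomach count")
  if (any(n < 0) || any(n > N)) stopf("incidence n must satisfy 0 <= n <= N")
  100 * n / N
}

#' Relative importance index (RII)
#'
#' Combines occurrence and volume into a single importance score on the 0-100
#' scale: `RII = %FO * %V / 100`.
#'
#' @param pct_fo,pct_v percentages in `[0, 100]` (vectorized).
#' @return RII values in `[0, 100]`.
#' @seealso [classify_rii()]
#' @export
#' @examples
#' relative_importance(85.7, 77.4)
relative_importance <- function(pct_fo, pct_v) {
  if (any(pct_fo < 0 | pct_fo > 100) || any(pct_v < 0 | pct_v > 100))
    stopf("percentages must lie in [0, 100]")
  pct_fo * pct_v / 100
}

#' Classify RII into importance groups
#'
#' Trophic groups by relative importance: `low` for RII in `[0, 10)`,
#' `secondary` for `[10, 40)`, `high` for `[40, 100]`. Boundaries belong to
#' the upper group (an RII of exactly 10 is secondary).
#'
#' @param rii RII values in `[0, 100]`.
#' @return Factor with levels `low`, `secondary`, `high`.
#' @export
#' @examples
#' classify_rii(c(0, 9.9, 10, 39.9, 40, 100))
classify_rii <- function(rii) {
  if (any(rii < 0 | rii > 100)) stopf("RII must lie in [0, 100]")
  cut(rii, breaks = c(0, 10, 40, 100), labels = c("low", "secondary", "high"),
      right = FALSE, include.lowest = TRUE)
}

#' Per-class diet metrics table
#'
#' Computes, for every (size class, category) cell of a [diet_table()], the
#' four diet indices — numeric percentage, volumetric percentage, frequency
#' of occurrence and RII — plus the RII importance class. Classes with no
#' prey (or zero total volume) get all-zero metrics rather than an error, so
#' empty strata flow through.
#'
#' All values are computed at full precision; round for display with
#' `round_half_up` semantics if matching printed tables (see the package
#' vignette).
#'
#' @param dt a `"diet_table"`.
#' @return A data frame of class `"diet_metrics"`: columns `size_class`,
#'   `category`, `n_i`, `vd_ml`, `pct_n`, `pct_v`, `pct_fo`, `rii`,
#'   `rii_class`.
#' @export
#' @examples
#' d <- table1_fixture()
#' m <- diet_metrics(diet_table(d, size_classes(300, 509, 3),
#'                              vtd_total = c(10, 7, 14)))
#' head(m)
diet_metrics <- function(dt) {
  stopifnot(inherits(dt, "diet_table"))
  pct_n <- ifelse(dt$N_t > 0, 100 * dt$n_i / pmax(dt$N_t, 1), 0)
  pct_v <- ifelse(dt$vTd > 0, 100 * dt$vd / pmax(dt$vTd, 1e-300), 0)
  pct_fo <- ifelse(dt$N > 0, 100 * dt$n / pmax(dt$N, 1), 0)
  out <- data.frame(size_class = dt$size_class, category = dt$category,
                    n_i = dt$n_i, vd_ml = dt$vd,
                    pct_n = pct_n, pct_v = pct_v, pct_fo = pct_fo,
                    stringsAsFactors = FALSE)
  out$rii <- relative_importance(out$pct_fo, out$pct_v)
  out$rii_class <- classify_rii(out$rii)
  attr(out, "scheme") <- attr(dt, "scheme")
  class(out) <- c("diet_metrics", "data.frame")
  out
}

#' Pooled frequency of occurrence across size classes
#'
#' Pools incidence over all examined stomachs (summing per-class incidences,
#' valid because every stomach belongs to exactly one class) and reports the
#' overall %FO per category — the basis for statements like "occurrence was
#' highest for Coleoptera".
#'
#' @param dt a `"diet_table"`.
#' @return Data frame with columns `category`, `n` (pooled incidence),
#'   `N` (total stomachs) and `pct_fo`.
#' @export
#' @examples
#' d <- table1_fixture()
#' pooled_occurrence(diet_table(d, size_classes(300, 509, 3)))
pooled_occurrence <- function(dt) {
  stopifnot(inherits(dt, "diet_table"))
  N <- sum(unique(dt[, c("size_class", "N")])$N)
  n <- as.vector(rowsum(dt$n, dt$category)[unique(dt$category), ])
  out <- data.frame(category = unique(dt$category), n = n, N = N,
                    pct_fo = frequency_occurrence(n, N),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$pct_fo), ]
}
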