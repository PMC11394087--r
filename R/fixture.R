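# The hatchling Morelet's crocodile study summary table and its stomach-level
# reconstruction. The published study reports only class-level percentages for
# 31 stomachs in three TL classes (10/7/14); the reconstruction recovers
# integer incidences and prey counts consistent with the printed columns.

t1_categories <- function() {
  data.frame(
    name = c("Coleoptera", "Hemiptera", "Araneae", "Blattodea", "Hymenoptera",
             "Fish", "Birds", "Diptera", "Odonata", "Scorpiones", "Gastropods"),
    rank = c("order", "order", "order", "order", "order",
             "class", "class", "order", "order", "order", "class"),
    group = c(rep("invertebrate", 5), "vertebrate", "vertebrate",
              rep("invertebrate", 3), "invertebrate"),
    stringsAsFactors = FALSE)
}

#' Published per-class diet metrics of the hatchling crocodile study
#'
#' The printed summary table of the study the package reconstructs: per size
#' class (1 initial, 2 medium, 3 final; 10/7/14 stomachs) and prey category,
#' the numeric percentage, displaced volume (mL), volumetric percentage,
#' frequency of occurrence, RII and its printed importance class. Values are
#' exactly as printed (one-decimal, half-up rounding); use them as reference
#' inputs, e.g. to check [relative_importance()] arithmetic or to drive
#' [infer_counts()].
#'
#' @return Data frame with columns `size_class`, `category`, `pct_n`,
#'   `vd_ml`, `pct_v`, `pct_fo`, `rii`, `rii_class`, plus per-class `N`.
#' @seealso [table1_fixture()] for the stomach-level reconstruction.
#' @export
#' @examples
#' t1 <- table1_printed()
#' subset(t1, size_class == 2 & category == "Coleoptera")
table1_printed <- function() {
  cats <- t1_categories()$name
  out <- data.frame(
    size_class = rep(1:3, each = 11),
    category = rep(cats, 3),
    pct_n = c(26.6, 29.4, 23.5, 2.9, 5.9, 0, 0, 2.9, 2.9, 5.9, 0,
              25, 16.7, 25, 4.2, 12.5, 4.2, 0, 4.2, 4.2, 4.2, 0,
              22.2, 16.7, 16.7, 7.4, 11.1, 7.4, 1.9, 3.7, 1.9, 3.7, 7.4),
    vd_ml = c(3.5, 2.1, 1.3, 0.5, 0.2, 0, 0, 0.9, 0.3, 0.2, 0,
              5.4, 2.3, 2.1, 1.3, 1.3, 0.3, 0, 0.1, 0.5, 0.2, 0,
              4.9, 2.8, 3.7, 2.1, 1.4, 2, 1.3, 0.3, 0.1, 0.3, 0.2),
    pct_v = c(34.5, 21, 12.5, 5, 2, 0, 0, 9, 3, 1.5, 0,
              77.4, 32.9, 30, 18.6, 17.9, 4.3, 0, 0.7, 7.1, 2.9, 0,
              34.6, 20, 26.1, 15, 10, 13.9, 9.3, 1.8, 0.7, 1.8, 1.4),
    pct_fo = c(90, 100, 80, 10, 20, 0, 0, 10, 10, 20, 0,
               85.7, 57.1, 85.7, 14.3, 42.9, 14.3, 0, 14.3, 14.3, 14.3, 0,
               85.7, 64.3, 64.3, 28.6, 42.9, 28.6, 7.1, 14.3, 7.1, 14.3, 28.6),
    rii = c(31.1, 21, 10, 0.5, 0.4, 0, 0, 0.9, 0.3, 0.3, 0,
            66.3, 18.8, 25.7, 2.7, 7.7, 0.6, 0, 0.1, 1, 0.4, 0,
            29.7, 12.9, 16.8, 4.3, 4.3, 4, 0.7, 0.3, 0.1, 0.3, 0.4),
    rii_class = c("secondary", "secondary", "secondary", rep("low", 8),
                  "high", "secondary", "secondary", rep("low", 8),
                  "secondary", "secondary", "secondary", rep("low", 8)),
    stringsAsFactors = FALSE)
  out$N <- c(10L, 7L, 14L)[out$size_class]
  out
}

# Per-class reconstructed incidences (= printed %FO x N / 100, integral in all
# 33 cells). Prey counts from the integer reconstruction of the %N columns
# coincide with the incidences in every class: one prey per incident stomach
# (totals N_t = 34, 24, 54).
t1_incidence <- function() {
  matrix(c(9, 10, 8, 1, 2, 0, 0, 1, 1, 2, 0,
           6, 4, 6, 1, 3, 1, 0, 1, 1, 1, 0,
           12, 9, 9, 4, 6, 4, 1, 2, 1, 2, 4),
         nrow = 3, byrow = TRUE, dimnames = list(NULL, t1_categories()$name))
}

#' Reconstructed stomach-level dataset of the hatchling crocodile study
#'
#' A synthetic stomach-level reconstruction of the study dataset: 31 stomachs
#' in three TL size classes (10, 7, 14), 11 prey categories. Per class, each
#' category's incidence equals the printed %FO times the class size (an
#' integer in every cell), each incident stomach holds exactly one prey
#' individual of the category (the integer-count reconstruction of the %N
#' columns gives counts equal to the incidences), and the class's printed
#' displaced volume is split equally over its incident stomachs.
#'
#' Two conventions, fixed because the study publishes no per-stomach rows:
#' TL values are an even lattice within each class interval, and incidences
#' are placed round-robin over the class's stomachs (categories in table
#' order, with a running offset), which spreads items so that no stomach is
#' empty. Statistics that depend on within-stomach co-occurrence (e.g.
#' stomach-bootstrap variances) are convention-dependent.
#'
#' The matching explicit volumetric denominators are 10, 7 and 14 mL per
#' class (attribute `"vtd_total"`): the study's measured total displaced
#' volume exceeded the sum over identified items, so the printed %V columns
#' do not sum to 100.
#'
#' @return A `"diet_data"` object with attributes `"scheme"`
#'   (`size_classes(300, 509, 3)`) and `"vtd_total"` (`c(10, 7, 14)`).
#' @seealso [table1_printed()]; the same dataset ships as CSVs in
#'   `inst/extdata/` (`table1_stomachs.csv`, `table1_prey.csv`).
#' @export
#' @examples
#' d <- table1_fixture()
#' dt <- diet_table(d, attr(d, "scheme"), vtd_total = attr(d, "vtd_total"))
#' pooled_occurrence(dt)
table1_fixture <- function() {
  scheme <- size_classes(300, 509, 3)
  cats <- t1_categories()
  inc <- t1_incidence()
  vd <- matrix(table1_printed()$vd_ml, nrow = 3, byrow = TRUE,
               dimnames = list(NULL, cats$name))
  Ncls <- c(10L, 7L, 14L)
  stomachs <- NULL
  prey <- NULL
  sid <- 0
  for (cl in 1:3) {
    N <- Ncls[cl]
    tl <- scheme$breaks[cl] + scheme$width * (seq_len(N) - 0.5) / N
    ids <- sprintf("S%02d", sid + seq_len(N))
    sid <- sid + N
    stomachs <- rbind(stomachs, data.frame(stomach_id = ids, tl_mm = tl,
                                           stringsAsFactors = FALSE,
                                           row.names = NULL))
    off <- 0
    for (j in seq_len(nrow(cats))) {
      nc <- inc[cl, j]
      if (nc == 0) next
      pos <- ((off + seq_len(nc) - 1) %% N) + 1
      off <- off + nc
      prey <- rbind(prey, data.frame(
        stomach_id = ids[pos], category = cats$name[j], rank = cats$rank[j],
        group = cats$group[j], count = 1L,
        volume_ml = unname(vd[cl, j]) / nc,
        stringsAsFactors = FALSE, row.names = NULL))
    }
  }
  out <- diet_data(stomachs, prey, categories = cats)
  attr(out, "scheme") <- scheme
  attr(out, "vtd_total") <- c(10, 7, 14)
  out
}

#' Estimate a simulation scenario from a dataset
#'
#' Fits the simple generative model of [sim_scenario()] to an observed (or
#' reconstructed) dataset: per-category constant prevalence from incidence /
#' stomachs, zero-truncated Poisson rate from the mean count per occurrence,
#' and log-normal volume location from the mean per-item volume (given
#' `sdlog`). Useful to simulate datasets "like the study" at arbitrary size.
#'
#' @param x a `"diet_data"` object.
#' @param scheme optional [size_classes()] scheme; with `class`, restricts
#'   estimation to the stomachs of one size class.
#' @param class optional size-class index; a class with no stomachs or no
#'   prey yields zero prevalences.
#' @param n_stomachs stomachs for the returned scenario (default: as in `x`).
#' @param sdlog assumed log-normal volume spread (default 0.5).
#' @param seed optional seed stored in the scenario.
#' @return A `"sim_scenario"`.
#' @export
#' @examples
#' sc <- scenario_from_data(table1_fixture(), n_stomachs = 1000)
#' sc$presence[[1]]$pi  # Coleoptera prevalence 27/31
scenario_from_data <- function(x, scheme = NULL, class = NULL,
                               n_stomachs = NULL, sdlog = 0.5, seed = NULL) {
  stopifnot(inherits(x, "diet_data"))
  st <- x$stomachs
  pr <- x$prey
  if (!is.null(class)) {
    if (is.null(scheme)) stopf("class requires a size-class scheme")
    keep <- assign_size_class(st$tl_mm, scheme) == class
    st <- st[keep, ]
    pr <- pr[pr$stomach_id %in% st$stomach_id, ]
  }
  ns <- nrow(st)
  cats <- x$categories
  prev <- lambda <- meanlog <- numeric(nrow(cats))
  for (j in seq_len(nrow(cats))) {
    pj <- pr[pr$category == cats$name[j] & pr$count > 0, ]
    prev[j] <- if (ns > 0) nrow(pj) / ns else 0
    if (nrow(pj) == 0) { lambda[j] <- 1e-6; meanlog[j] <- log(0.3) - sdlog^2 / 2; next }
    mbar <- sum(pj$count) / nrow(pj)
    lambda[j] <- if (mbar <= 1 + 1e-9) 1e-6 else
      stats::uniroot(function(l) l / (1 - exp(-l)) - mbar,
                     c(1e-8, 10 * mbar))$root
    vbar <- sum(pj$volume_ml) / sum(pj$count)
    meanlog[j] <- log(max(vbar, 1e-12)) - sdlog^2 / 2
  }
  tlr <- if (!is.null(scheme)) c(scheme$lower_mm, scheme$upper_mm) else
    range(x$stomachs$tl_mm)
  sim_scenario(cats, n_stomachs = n_stomachs %||% max(ns, 1), tl_range = tlr,
               presence = as.list(prev), lambda = lambda, meanlog = meanlog,
               sdlog = sdlog, seed = seed)
}
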