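#' Define a stomach-content simulation scenario
#'
#' Describes the generative model used by [simulate_stomachs()]: each
#' stomach's total length is drawn uniformly on `tl_range`; independently per
#' category, the category is present with a probability given by the presence
#' model (a constant prevalence, or a logistic function of TL); given
#' presence, the prey count is zero-truncated Poisson with mean parameter
#' `lambda`, and each prey individual contributes an independent log-normal
#' displaced volume.
#'
#' @param categories character vector of category names, or a data frame with
#'   columns `name`, `rank`, `group` (defaults: rank `"order"`, group
#'   `"invertebrate"`).
#' @param n_stomachs number of stomachs to generate (default 31, the size of
#'   the study the package is built around).
#' @param tl_range TL sampling range in mm (default `c(300, 509)`).
#' @param presence per-category presence model: either a numeric vector of
#'   constant prevalences in `[0, 1]`, or a list whose elements are a single
#'   prevalence or a length-2 vector `c(b0, b1)` of logistic coefficients on
#'   the log-odds scale (slope per mm TL). Recycled if length 1.
#' @param lambda per-category zero-truncated Poisson rate (positive);
#'   recycled. The mean count given presence is `lambda / (1 - exp(-lambda))`.
#' @param meanlog,sdlog per-prey-item log-normal volume parameters (mL);
#'   recycled. `sdlog = 0` gives fixed item volumes.
#' @param seed optional default seed stored in the scenario.
#' @return An object of class `"sim_scenario"`.
#' @export
#' @examples
#' sc <- sim_scenario(c("Coleoptera", "Fish"), n_stomachs = 50,
#'                    presence = list(0.9, c(-12, 0.02)), lambda = 1.5)
#' sim <- simulate_stomachs(sc, seed = 1)
sim_scenario <- function(categories, n_stomachs = 31, tl_range = c(300, 509),
                         presence = 0.5, lambda = 1, meanlog = log(0.3),
                         sdlog = 0.5, seed = NULL) {
  if (is.character(categories))
    categories <- data.frame(name = categories, rank = "order",
                             group = "invertebrate", stringsAsFactors = FALSE)
  categories <- as.data.frame(categories)
  if (!all(c("name", "rank", "group") %in% names(categories)))
    stopf("categories must be names or a data frame with name, rank, group")
  if (anyDuplicated(categories$name)) stopf("categories must be distinct")
  S <- nrow(categories)
  if (n_stomachs < 1) stopf("n_stomachs must be positive")
  if (length(tl_range) != 2 || tl_range[2] <= tl_range[1] || tl_range[1] <= 0)
    stopf("tl_range must be increasing and positive")
  if (!is.list(presence)) presence <- as.list(presence)
  presence <- rep_len(presence, S)
  presence <- lapply(presence, function(p) {
    if (length(p) == 1) {
      if (p < 0 || p > 1) stopf("constant prevalence must lie in [0, 1]")
      list(type = "constant", pi = as.numeric(p))
    } else if (length(p) == 2) {
      list(type = "logistic", b0 = p[1], b1 = p[2])
    } else stopf("each presence model is a prevalence or c(b0, b1)")
  })
  lambda <- rep_len(lambda, S); meanlog <- rep_len(meanlog, S)
  sdlog <- rep_len(sdlog, S)
  if (any(lambda <= 0)) stopf("lambda must be positive")
  if (any(sdlog < 0)) stopf("sdlog must be non-negative")
  structure(list(categories = categories, n_stomachs = as.integer(n_stomachs),
                 tl_range = tl_range, presence = presence, lambda = lambda,
                 meanlog = meanlog, sdlog = sdlog, seed = seed),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario: %d stomachs, TL ~ U(%g, %g) mm, %d categories\n",
              x$n_stomachs, x$tl_range[1], x$tl_range[2], nrow(x$categories)))
  invisible(x)
}

# Zero-truncated Poisson sampler via inverse-CDF restriction to {1, 2, ...}.
rztpois <- function(n, lambda) {
  if (n == 0) return(integer(0))
  p0 <- stats::dpois(0, lambda)
  u <- stats::runif(n, p0, 1)
  pmax(stats::qpois(u, lambda), 1L)
}

#' Simulate a stomach-content dataset
#'
#' Draws a dataset from a [sim_scenario()]: per stomach a uniform TL; per
#' category a Bernoulli presence (constant or logistic in TL); given
#' presence, a zero-truncated Poisson prey count and a displaced volume equal
#' to the sum of per-item log-normal draws. Fully reproducible given the
#' seed.
#'
#' @param scenario a `"sim_scenario"`.
#' @param seed integer seed; defaults to the seed stored in the scenario
#'   (an unseeded call uses the current RNG state).
#' @return A validated `"diet_data"` object (all scenario categories are
#'   declared even if absent from the draw).
#' @export
simulate_stomachs <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_stomachs
  tl <- stats::runif(n, scenario$tl_range[1], scenario$tl_range[2])
  ids <- sprintf("sim%04d", seq_len(n))
  stomachs <- data.frame(stomach_id = ids, tl_mm = tl, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(scenario$categories))
  for (j in seq_len(nrow(scenario$categories))) {
    pm <- scenario$presence[[j]]
    prob <- if (pm$type == "constant") rep(pm$pi, n) else
      stats::plogis(pm$b0 + pm$b1 * tl)
    pres <- stats::rbinom(n, 1, prob) == 1
    if (!any(pres)) next
    cnt <- rztpois(sum(pres), scenario$lambda[j])
    vol <- vapply(cnt, function(k)
      sum(stats::rlnorm(k, scenario$meanlog[j], scenario$sdlog[j])), numeric(1))
    rows[[j]] <- data.frame(stomach_id = ids[pres],
                            category = scenario$categories$name[j],
                            rank = scenario$categories$rank[j],
                            group = scenario$categories$group[j],
                            count = cnt, volume_ml = vol,
                            stringsAsFactors = FALSE)
  }
  prey <- do.call(rbind, rows)
  if (is.null(prey))
    prey <- data.frame(stomach_id = character(0), category = character(0),
                       rank = character(0), group = character(0),
                       count = integer(0), volume_ml = numeric(0))
  diet_data(stomachs, prey, categories = scenario$categories)
}
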