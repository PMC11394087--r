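#' Simpson diversity index
#'
#' The complement form `D = 1 - sum(p_i^2)` on raw proportions
#' `p_i = n_i / sum(n)`: the probability that two prey individuals drawn at
#' random belong to different categories. Bounded by `1 - 1/S` for `S`
#' categories, with equality at even abundances, and invariant under
#' proportional scaling of the counts.
#'
#' @param counts non-negative per-category counts (or abundances) with
#'   positive sum.
#' @return `D` in `[0, 1)`.
#' @export
#' @examples
#' simpson_index(c(6, 4, 6, 1, 3, 1, 1, 1, 1))
simpson_index <- function(counts) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stopf("Simpson diversity undefined: all counts are zero")
  1 - sum((counts / tot)^2)
}

#' Per-stomach count matrix for one size class
#'
#' Builds the stomachs-by-categories count matrix for the stomachs of one
#' size class — the resampling unit for [simpson_test()].
#'
#' @param x a `"diet_data"` object.
#' @param scheme a [size_classes()] scheme.
#' @param class size-class index in `1..k`.
#' @return Integer matrix, one row per stomach in the class (row names are
#'   stomach ids), one column per declared category.
#' @export
stomach_matrix <- function(x, scheme, class) {
  stopifnot(inherits(x, "diet_data"), inherits(scheme, "size_classes"))
  cls <- assign_size_class(x$stomachs$tl_mm, scheme)
  ids <- x$stomachs$stomach_id[cls == class]
  cats <- x$categories$name
  m <- matrix(0L, length(ids), length(cats), dimnames = list(ids, cats))
  pr <- x$prey[x$prey$stomach_id %in% ids, ]
  if (nrow(pr)) m[cbind(match(pr$stomach_id, ids), match(pr$category, cats))] <- as.integer(pr$count)
  m
}

#' Bootstrap comparison of Simpson diversity between two groups
#'
#' Tests whether dietary diversity differs between two sets of stomachs
#' (e.g. two size classes). Within each group, stomachs are resampled with
#' replacement `replicates` times; Simpson `D` is recomputed on the pooled
#' counts of each replicate, giving a bootstrap standard error per group.
#' The statistic is `t = (D_a - D_b) / sqrt(se_a^2 + se_b^2)`, referred to a
#' t distribution with Welch-Satterthwaite degrees of freedom for a two-sided
#' p value.
#'
#' @param counts_a,counts_b per-stomach count matrices (stomachs x
#'   categories), e.g. from [stomach_matrix()]; each must have at least two
#'   stomachs (a single stomach has no resampling variance).
#' @param replicates number of bootstrap replicates, at least 100.
#' @param seed optional integer seed, recorded in the result.
#' @return An object of class `"simpson_test"`: list with `t`, `p`,
#'   `D` (the two observed diversities), `se`, `df`, `replicates`, `seed`
#'   and `method`.
#' @export
#' @examples
#' d <- table1_fixture(); sc <- size_classes(300, 509, 3)
#' simpson_test(stomach_matrix(d, sc, 1), stomach_matrix(d, sc, 3),
#'              replicates = 500, seed = 1)
simpson_test <- function(counts_a, counts_b, replicates = 1000, seed = NULL) {
  if (replicates < 100) stopf("replicates must be at least 100")
  for (m in list(counts_a, counts_b)) {
    if (!is.matrix(m) || nrow(m) < 2)
      stopf("each group needs a count matrix with at least 2 stomachs")
    if (sum(m) <= 0) stopf("each group must contain prey")
  }
  if (!is.null(seed)) set.seed(seed)
  boot_D <- function(m) {
    n <- nrow(m)
    w <- stats::rmultinom(replicates, n, rep(1 / n, n))  # stomach resampling weights
    cnt <- crossprod(m, w)                               # categories x replicates
    tot <- colSums(cnt)
    keep <- tot > 0
    if (sum(keep) < 2) stopf("too many empty bootstrap replicates")
    1 - colSums((cnt[, keep, drop = FALSE] / rep(tot[keep], each = nrow(cnt)))^2)
  }
  Da <- simpson_index(colSums(counts_a)); Db <- simpson_index(colSums(counts_b))
  ra <- boot_D(counts_a); rb <- boot_D(counts_b)
  va <- stats::var(ra); vb <- stats::var(rb)
  if (va + vb <= 0) {
    tstat <- 0; df <- Inf; p <- 1
  } else {
    tstat <- (Da - Db) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(ra) - 1) + vb^2 / (length(rb) - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  structure(list(t = tstat, p = p, D = c(a = Da, b = Db),
                 se = c(a = sqrt(va), b = sqrt(vb)), df = df,
                 replicates = replicates, seed = seed,
                 method = "stomach bootstrap, Welch t reference"),
            class = "simpson_test")
}

#' @export
print.simpson_test <- function(x, ...) {
  cat("Bootstrap comparison of Simpson diversity\n")
  cat(sprintf("  D = %.4f vs %.4f   t = %.4f, df = %.1f, p = %.4f\n",
              x$D[1], x$D[2], x$t, x$df, x$p))
  cat(sprintf("  %s (%d replicates%s)\n", x$method, x$replicates,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Pianka niche overlap between two proportion vectors
#'
#' The symmetric overlap `O_jk = sum(p_i q_i) / sqrt(sum(p_i^2) sum(q_i^2))`
#' between two resource-use proportion vectors over a common category
#' ordering: 0 for disjoint diets, 1 for identical ones (Cauchy-Schwarz).
#'
#' @param p,q non-negative proportion vectors of equal length, each summing
#'   to 1 (tolerance 1e-9).
#' @return Overlap in `[0, 1]`.
#' @export
#' @examples
#' pianka_overlap(c(0.5, 0.5, 0), c(0.5, 0, 0.5))
pianka_overlap <- function(p, q) {
  if (length(p) != length(q))
    stopf("proportion vectors must align on the same categories")
  if (any(p < 0) || any(q < 0)) stopf("proportions must be non-negative")
  if (sum(p) <= 0 || sum(q) <= 0) stopf("overlap undefined for a zero vector")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stopf("proportions must sum to 1")
  sum(p * q) / sqrt(sum(p^2) * sum(q^2))
}

#' Pairwise niche overlap between size classes
#'
#' Computes Pianka overlap for every pair of size classes in a diet table.
#' The resource-use proportions can be numeric (prey-count shares, the
#' default), volumetric (displaced-volume shares) or occurrence
#' (incidence shares). A verbal annotation labels overlaps `>= 0.6` "high",
#' `[0.4, 0.6)` "moderate" and `< 0.4` "low".
#'
#' @param dt a `"diet_table"`.
#' @param basis `"numeric"`, `"volumetric"` or `"occurrence"`.
#' @return Object of class `"niche_overlap"`: list with the symmetric
#'   `overlap` matrix (1 on the diagonal for non-empty classes), `basis`, and
#'   a `pairs` data frame (`class_a`, `class_b`, `overlap`, `label`).
#' @export
#' @examples
#' d <- table1_fixture()
#' niche_overlap(diet_table(d, size_classes(300, 509, 3)))
niche_overlap <- function(dt, basis = c("numeric", "volumetric", "occurrence")) {
  stopifnot(inherits(dt, "diet_table"))
  basis <- match.arg(basis)
  col <- switch(basis, numeric = "n_i", volumetric = "vd", occurrence = "n")
  cls <- sort(unique(dt$size_class))
  props <- lapply(cls, function(j) {
    v <- dt[dt$size_class == j, ]
    v <- v[order(v$category), ]
    s <- sum(v[[col]])
    if (s > 0) v[[col]] / s else rep(NA_real_, nrow(v))
  })
  k <- length(cls)
  O <- diag(1, k); dimnames(O) <- list(cls, cls)
  pairs <- NULL
  for (j in seq_len(k)) for (l in seq_len(k)) {
    if (anyNA(props[[j]]) || anyNA(props[[l]])) { O[j, l] <- NA_real_; next }
    if (l > j) {
      O[j, l] <- O[l, j] <- pianka_overlap(props[[j]], props[[l]])
      pairs <- rbind(pairs, data.frame(class_a = cls[j], class_b = cls[l],
                                       overlap = O[j, l]))
    }
  }
  if (!is.null(pairs))
    pairs$label <- ifelse(pairs$overlap >= 0.6, "high",
                          ifelse(pairs$overlap >= 0.4, "moderate", "low"))
  structure(list(overlap = O, basis = basis, pairs = pairs),
            class = "niche_overlap")
}

#' @export
print.niche_overlap <- function(x, digits = 4, ...) {
  cat(sprintf("Pianka niche overlap (%s basis)\n", x$basis))
  print(round(x$overlap, digits))
  invisible(x)
}
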