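#' Construct a validated stomach-content dataset
#'
#' Bundles stomach records and prey records into a single validated object,
#' the input container for all downstream analyses. One stomach corresponds to
#' one flushed individual; prey records attribute counts and displaced volumes
#' of prey categories to stomachs. Duplicate (stomach, category) prey rows are
#' summed on construction.
#'
#' @param stomachs data frame with columns `stomach_id` (unique) and `tl_mm`
#'   (total length, millimetres, positive); optional `site` and `date` columns
#'   are carried along.
#' @param prey data frame with columns `stomach_id`, `category`, `rank`
#'   (`"order"` or `"class"`), `group` (`"invertebrate"` or `"vertebrate"`),
#'   `count` (non-negative integer prey individuals) and `volume_ml`
#'   (non-negative displaced volume, mL). May have zero rows.
#' @param categories optional data frame (`name`, `rank`, `group`) declaring
#'   the full category set, so categories absent from `prey` (e.g. in a
#'   simulated dataset) are retained with zero entries downstream. Defaults to
#'   the categories present in `prey`.
#'
#' @return An object of class `"diet_data"`: a list with elements `stomachs`,
#'   `prey` (duplicates summed) and `categories`.
#' @seealso [read_diet()], [diet_table()], [simulate_stomachs()]
#' @export
#' @examples
#' st <- data.frame(stomach_id = c("a", "b"), tl_mm = c(320, 480))
#' pr <- data.frame(stomach_id = c("a", "a", "b"),
#'                  category = c("Coleoptera", "Coleoptera", "Fish"),
#'                  rank = c("order", "order", "class"),
#'                  group = c("invertebrate", "invertebrate", "vertebrate"),
#'                  count = c(2, 1, 1), volume_ml = c(0.4, 0.2, 1.5))
#' d <- diet_data(st, pr)
#' d$prey  # the two Coleoptera rows are summed
diet_data <- function(stomachs, prey, categories = NULL) {
  need_st <- c("stomach_id", "tl_mm")
  miss <- setdiff(need_st, names(stomachs))
  if (length(miss)) stopf("stomach table is missing column(s): %s", paste(miss, collapse = ", "))
  need_pr <- c("stomach_id", "category", "rank", "group", "count", "volume_ml")
  miss <- setdiff(need_pr, names(prey))
  if (length(miss)) stopf("prey table is missing column(s): %s", paste(miss, collapse = ", "))

  stomachs$stomach_id <- as.character(stomachs$stomach_id)
  if (anyDuplicated(stomachs$stomach_id))
    stopf("duplicate stomach_id: %s",
          paste(unique(stomachs$stomach_id[duplicated(stomachs$stomach_id)]), collapse = ", "))
  if (!is.numeric(stomachs$tl_mm) || any(!is.finite(stomachs$tl_mm)) || any(stomachs$tl_mm <= 0))
    stopf("tl_mm must be finite and positive for every stomach")

  prey$stomach_id <- as.character(prey$stomach_id)
  prey$category <- as.character(prey$category)
  if (nrow(prey)) {
    bad <- which(!is_count(prey$count))
    if (length(bad)) stopf("prey row %d: count must be a non-negative integer", bad[1])
    bad <- which(!(is.numeric(prey$volume_ml) & is.finite(prey$volume_ml) & prey$volume_ml >= 0))
    if (length(bad)) stopf("prey row %d: volume_ml must be non-negative", bad[1])
    unknown <- setdiff(prey$stomach_id, stomachs$stomach_id)
    if (length(unknown))
      stopf("prey rows reference unknown stomach_id: %s", paste(unknown, collapse = ", "))
    bad <- which(!prey$rank %in% c("order", "class"))
    if (length(bad)) stopf("prey row %d: rank must be 'order' or 'class'", bad[1])
    bad <- which(!prey$group %in% c("invertebrate", "vertebrate"))
    if (length(bad)) stopf("prey row %d: group must be 'invertebrate' or 'vertebrate'", bad[1])
  }

  cat_tab <- unique(prey[nrow(prey) > 0, c("category", "rank", "group"), drop = FALSE])
  names(cat_tab)[1] <- "name"
  rownames(cat_tab) <- NULL
  if (anyDuplicated(cat_tab$name))
    stopf("category '%s' has inconsistent rank/group annotations",
          cat_tab$name[duplicated(cat_tab$name)][1])
  if (!is.null(categories)) {
    categories <- as.data.frame(categories)
    if (!all(c("name", "rank", "group") %in% names(categories)))
      stopf("categories must have columns name, rank, group")
    extra <- setdiff(cat_tab$name, categories$name)
    if (length(extra)) stopf("prey uses undeclared categories: %s", paste(extra, collapse = ", "))
    cat_tab <- categories[, c("name", "rank", "group")]
    cat_tab$name <- as.character(cat_tab$name)
  }
  if (anyDuplicated(cat_tab$name)) stopf("duplicate category names in categories")

  # sum duplicate (stomach, category) rows
  if (nrow(prey)) {
    key <- paste(prey$stomach_id, prey$category, sep = "\r")
    agg <- rowsum(prey[, c("count", "volume_ml")], key, reorder = FALSE)
    first <- !duplicated(key)
    prey <- data.frame(stomach_id = prey$stomach_id[first],
                       category = prey$category[first],
                       rank = prey$rank[first], group = prey$group[first],
                       count = agg$count, volume_ml = agg$volume_ml,
                       stringsAsFactors = FALSE, row.names = NULL)
  }

  structure(list(stomachs = as.data.frame(stomachs, stringsAsFactors = FALSE),
                 prey = prey, categories = cat_tab),
            class = "diet_data")
}

#' @export
print.diet_data <- function(x, ...) {
  cat(sprintf("Stomach-content dataset: %d stomachs, %d prey categories, %d prey records\n",
              nrow(x$stomachs), nrow(x$categories), nrow(x$prey)))
  cat(sprintf("TL range: %.0f-%.0f mm\n", min(x$stomachs$tl_mm), max(x$stomachs$tl_mm)))
  invisible(x)
}

#' Read a stomach-content dataset from CSV files
#'
#' Reads the two standard comma-separated tables (UTF-8, header row, decimal
#' point): a stomach table (`stomach_id`, `tl_mm`, optional `site`, `date`)
#' and a prey table (`stomach_id`, `category`, `rank`, `group`, `count`,
#' `volume_ml`), validating both (see [diet_data()]).
#'
#' @param stomachs_file,prey_file paths to the CSV files.
#' @return A `"diet_data"` object.
#' @seealso [write_diet()]; a reconstructed example dataset ships with the
#'   package, see [table1_fixture()].
#' @export
#' @examples
#' d <- read_diet(system.file("extdata", "table1_stomachs.csv", package = "crocdiet"),
#'                system.file("extdata", "table1_prey.csv", package = "crocdiet"))
#' d
read_diet <- function(stomachs_file, prey_file) {
  for (f in c(stomachs_file, prey_file))
    if (!file.exists(f)) stopf("file not found: %s", f)
  st <- utils::read.csv(stomachs_file, stringsAsFactors = FALSE)
  pr <- utils::read.csv(prey_file, stringsAsFactors = FALSE)
  diet_data(st, pr)
}

#' Write a stomach-content dataset to CSV files
#'
#' Inverse of [read_diet()]: writes the stomach and prey tables in the standard
#' CSV schema, at full numeric precision so that a read/write round trip
#' reproduces the dataset exactly.
#'
#' @param x a `"diet_data"` object.
#' @param stomachs_file,prey_file output paths.
#' @return `x`, invisibly.
#' @export
write_diet <- function(x, stomachs_file, prey_file) {
  stopifnot(inherits(x, "diet_data"))
  utils::write.csv(x$stomachs, stomachs_file, row.names = FALSE, quote = TRUE)
  utils::write.csv(x$prey, prey_file, row.names = FALSE, quote = TRUE)
  invisible(x)
}

#' Equal-width total-length size classes
#'
#' Divides a total-length (TL) range into `k` equal-width intervals, width
#' `(upper - lower) / k`. Intervals are half-open, left-closed
#' `[b_j, b_{j+1})`, except the last which is closed at `upper` so the largest
#' animal is assignable. The study design behind the package uses
#' `size_classes(300, 509, 3)`: initial, medium and final hatchling intervals
#' of width 69.67 mm.
#'
#' @param lower_mm,upper_mm range limits in mm, `upper_mm > lower_mm`.
#' @param k number of classes, a positive integer.
#' @return An object of class `"size_classes"`: list with `lower_mm`,
#'   `upper_mm`, `k`, `width`, `breaks` (length `k + 1`) and display `labels`.
#' @seealso [assign_size_class()]
#' @export
#' @examples
#' size_classes(300, 509, 3)$breaks
size_classes <- function(lower_mm, upper_mm, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stopf("k must be a positive integer")
  if (!is.numeric(lower_mm) || !is.numeric(upper_mm) || upper_mm <= lower_mm)
    stopf("upper_mm must exceed lower_mm")
  breaks <- lower_mm + (0:k) * (upper_mm - lower_mm) / k
  labels <- sprintf("%.1f-%.1f mm", breaks[-(k + 1)], breaks[-1])
  structure(list(lower_mm = lower_mm, upper_mm = upper_mm, k = as.integer(k),
                 width = (upper_mm - lower_mm) / k, breaks = breaks, labels = labels),
            class = "size_classes")
}

#' @export
print.size_classes <- function(x, ...) {
  cat(sprintf("%d size classes of width %.2f mm on [%g, %g]:\n",
              x$k, x$width, x$lower_mm, x$upper_mm))
  cat(paste(sprintf("  %d: %s", seq_len(x$k), x$labels), collapse = "\n"), "\n")
  invisible(x)
}

#' Assign total lengths to size classes
#'
#' Returns, for each TL, the index `j` of the interval
#' `[breaks[j], breaks[j+1])` containing it; the last interval is closed on
#' the right. TL values outside `[lower_mm, upper_mm]` are an error (widen the
#' scheme if the data exceed the design range).
#'
#' @param tl_mm numeric vector of total lengths, mm.
#' @param scheme a [size_classes()] scheme.
#' @return Integer vector of class indices in `1..k`.
#' @export
#' @examples
#' assign_size_class(c(300, 415, 509), size_classes(300, 509, 3))
assign_size_class <- function(tl_mm, scheme) {
  stopifnot(inherits(scheme, "size_classes"))
  if (any(tl_mm < scheme$lower_mm | tl_mm > scheme$upper_mm))
    stopf("TL outside [%g, %g] mm; widen the size-class scheme",
          scheme$lower_mm, scheme$upper_mm)
  findInterval(tl_mm, scheme$breaks, rightmost.closed = TRUE)
}

#' Aggregate stomach records into a per-class diet table
#'
#' Collapses stomach-level prey records to the per-(size class, category)
#' quantities that feed the diet indices: prey counts `n_i`, incidence `n`
#' (number of stomachs in which the category appears with count > 0) and
#' displaced volume `vd` (mL), together with the per-class denominators:
#' `N` (stomachs examined), `N_t` (total prey individuals) and `vTd` (total
#' displaced volume).
#'
#' Every declared category appears in every class, with zeros where absent.
#' `vTd` defaults to the per-class sum of `vd` over identified items; studies
#' sometimes measure a total displaced volume that exceeds that sum (e.g.
#' unidentifiable material), in which case supply it via `vtd_total`.
#'
#' @param x a `"diet_data"` object.
#' @param scheme a [size_classes()] scheme covering all TLs in `x`.
#' @param vtd_total optional numeric vector, length `k`: explicit per-class
#'   total displaced volume (mL) used as the volumetric-percentage
#'   denominator. `NULL` (default) uses the per-class sum of `vd`.
#' @return A data frame of class `"diet_table"` with one row per
#'   (size class, category): columns `size_class`, `category`, `n_i`, `n`,
#'   `vd`, `N`, `N_t`, `vTd`. The scheme is attached as attribute `"scheme"`.
#' @seealso [diet_metrics()], [pooled_occurrence()]
#' @export
#' @examples
#' d <- table1_fixture()
#' dt <- diet_table(d, size_classes(300, 509, 3), vtd_total = c(10, 7, 14))
#' unique(dt[, c("size_class", "N", "N_t")])
diet_table <- function(x, scheme, vtd_total = NULL) {
  stopifnot(inherits(x, "diet_data"), inherits(scheme, "size_classes"))
  k <- scheme$k
  if (!is.null(vtd_total)) {
    if (length(vtd_total) != k || any(vtd_total < 0))
      stopf("vtd_total must be a non-negative vector of length k = %d", k)
  }
  cats <- x$categories$name
  cls <- assign_size_class(x$stomachs$tl_mm, scheme)
  names(cls) <- x$stomachs$stomach_id

  out <- expand.grid(category = cats, size_class = seq_len(k),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("size_class", "category")]
  out$n_i <- 0; out$n <- 0L; out$vd <- 0

  if (nrow(x$prey)) {
    pcls <- cls[x$prey$stomach_id]
    idx <- match(paste(pcls, x$prey$category), paste(out$size_class, out$category))
    out$n_i <- as.vector(rowsum(c(x$prey$count, numeric(nrow(out))),
                                c(idx, seq_len(nrow(out)))))
    out$vd <- as.vector(rowsum(c(x$prey$volume_ml, numeric(nrow(out))),
                               c(idx, seq_len(nrow(out)))))
    inc <- x$prey$count > 0
    out$n <- as.integer(rowsum(c(as.numeric(inc), numeric(nrow(out))),
                               c(idx, seq_len(nrow(out)))))
  }
  Ncls <- tabulate(cls, nbins = k)
  out$N <- Ncls[out$size_class]
  Nt <- as.vector(rowsum(out$n_i, out$size_class))
  out$N_t <- Nt[out$size_class]
  sum_vd <- as.vector(rowsum(out$vd, out$size_class))
  out$vTd <- if (is.null(vtd_total)) sum_vd[out$size_class] else vtd_total[out$size_class]
  stopifnot(all(out$n <= out$N))

  attr(out, "scheme") <- scheme
  class(out) <- c("diet_table", "data.frame")
  out
}

#' Reconstruct integer counts from rounded percentages
#'
#' Published diet tables often print only percentage columns. This utility
#' recovers the smallest total `T` and non-negative integer counts `n_i`
#' summing to `T` such that each `100 * n_i / T`, rounded half-up to `digits`
#' decimals, reproduces the printed percentages exactly. The search is
#' exhaustive over `T = 1..t_max` with, for each `T`, a subset-sum dynamic
#' program over the per-category candidate counts.
#'
#' @param pct numeric vector of printed percentages, each in `[0, 100]`.
#' @param t_max upper bound for the exhaustive total search (default 100).
#' @param digits decimal places of the printed percentages (default 1).
#' @return A list with `found` (logical), `total` (`T`, or `NA`) and `counts`
#'   (integer vector, or `NULL`). `found = FALSE` signals explicitly that no
#'   integer composition up to `t_max` reproduces the input.
#' @export
#' @examples
#' infer_counts(c(25, 16.7, 25, 4.2, 12.5, 4.2, 4.2, 4.2, 4.2))
#' infer_counts(c(33.3, 50))  # inconsistent: found = FALSE
infer_counts <- function(pct, t_max = 100, digits = 1) {
  if (!is.numeric(pct) || !length(pct) || any(!is.finite(pct)) || any(pct < 0 | pct > 100))
    stopf("pct must be percentages in [0, 100]")
  if (t_max < 1) stopf("t_max must be at least 1")
  for (T in seq_len(t_max)) {
    cand <- lapply(pct, function(p) {
      n <- 0:T
      n[abs(round_half_up(100 * n / T, digits) - round_half_up(p, digits)) < 1e-9]
    })
    if (any(lengths(cand) == 0)) next
    # reach[[i]][s+1]: can categories 1..i-1 sum to s
    reach <- vector("list", length(pct))
    prev <- c(TRUE, rep(FALSE, T))
    ok <- TRUE
    for (i in seq_along(cand)) {
      reach[[i]] <- prev
      cur <- rep(FALSE, T + 1)
      for (n in cand[[i]]) {
        from <- which(prev)
        to <- from + n
        cur[to[to <= T + 1]] <- TRUE
      }
      prev <- cur
      if (!any(prev)) { ok <- FALSE; break }
    }
    if (!ok || !prev[T + 1]) next
    counts <- integer(length(pct))
    target <- T
    for (i in rev(seq_along(cand))) {
      for (n in sort(cand[[i]])) {
        if (target - n >= 0 && reach[[i]][target - n + 1]) {
          counts[i] <- n
          target <- target - n
          break
        }
      }
    }
    return(list(found = TRUE, total = T, counts = counts))
  }
  list(found = FALSE, total = NA_integer_, counts = NULL)
}
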