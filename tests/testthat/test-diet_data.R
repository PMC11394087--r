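test_that("reading the shipped study CSVs yields 31 stomachs and 11 categories", {
  d <- read_diet(system.file("extdata", "table1_stomachs.csv", package = "crocdiet"),
                 system.file("extdata", "table1_prey.csv", package = "crocdiet"))
  expect_s3_class(d, "diet_data")
  expect_equal(nrow(d$stomachs), 31)
  expect_equal(sort(d$categories$name), sort(table1_fixture()$categories$name))
  expect_length(unique(d$prey$category), 11)
})

test_that("dataset validation rejects malformed input with informative errors", {
  st <- data.frame(stomach_id = c("a", "b"), tl_mm = c(320, 480))
  pr <- data.frame(stomach_id = "a", category = "Coleoptera", rank = "order",
                   group = "invertebrate", count = 1L, volume_ml = 0.2)
  expect_error(diet_data(st[, "stomach_id", drop = FALSE], pr), "tl_mm")
  expect_error(diet_data(st, pr[, -5]), "count")
  expect_error(diet_data(st, transform(pr, stomach_id = "zz")), "unknown stomach")
  expect_error(diet_data(st, transform(pr, count = -1)), "row 1")
  expect_error(diet_data(st, transform(pr, volume_ml = -0.5)), "row 1")
  expect_error(diet_data(rbind(st, st[1, ]), pr), "duplicate")
})

test_that("duplicate (stomach, category) prey rows are summed on load", {
  st <- data.frame(stomach_id = "a", tl_mm = 400)
  pr <- data.frame(stomach_id = "a", category = "Coleoptera", rank = "order",
                   group = "invertebrate", count = c(2L, 3L), volume_ml = c(0.1, 0.4))
  d <- diet_data(st, pr)
  expect_equal(nrow(d$prey), 1)
  expect_equal(d$prey$count, 5)
  expect_equal(d$prey$volume_ml, 0.5)
})

test_that("an empty prey table is a valid dataset with an all-zero diet table", {
  st <- data.frame(stomach_id = c("a", "b"), tl_mm = c(320, 480))
  pr <- data.frame(stomach_id = character(0), category = character(0),
                   rank = character(0), group = character(0),
                   count = integer(0), volume_ml = numeric(0))
  cats <- data.frame(name = "Coleoptera", rank = "order", group = "invertebrate")
  d <- diet_data(st, pr, categories = cats)
  dt <- diet_table(d, size_classes(300, 509, 2))
  expect_true(all(dt$n_i == 0) && all(dt$n == 0) && all(dt$vd == 0))
  expect_equal(unique(dt$N_t), 0)
})

test_that("size classes are equal-width with exact breaks, last interval closed", {
  sc <- size_classes(300, 509, 3)
  expect_equal(sc$breaks, c(300, 300 + 209 / 3, 300 + 2 * 209 / 3, 509))
  expect_equal(sc$width, 209 / 3)
  expect_equal(size_classes(0, 10, 1)$breaks, c(0, 10))
  expect_error(size_classes(300, 300, 3), "exceed")
  expect_error(size_classes(300, 509, 0), "positive integer")
})

test_that("TL assignment is left-closed with the upper limit in the last class", {
  sc <- size_classes(300, 509, 3)
  expect_equal(assign_size_class(415, sc), 2)      # the study's mean TL
  expect_equal(assign_size_class(300, sc), 1)
  expect_equal(assign_size_class(sc$breaks[2], sc), 2)
  expect_equal(assign_size_class(509, sc), 3)
  expect_error(assign_size_class(250, sc), "outside")
})

test_that("aggregation reproduces class sizes and incidence semantics", {
  d <- table1_fixture()
  dt <- diet_table(d, study_scheme())
  expect_equal(unique(dt[, c("size_class", "N")])$N, c(10, 7, 14))

  one <- diet_data(data.frame(stomach_id = "a", tl_mm = 400),
                   data.frame(stomach_id = "a", category = "X", rank = "order",
                              group = "invertebrate", count = 3L, volume_ml = 0.2))
  dt1 <- diet_table(one, size_classes(300, 509, 1))
  expect_equal(dt1$n_i, 3); expect_equal(dt1$n, 1L); expect_equal(dt1$N, 1L)

  # a zero-count row does not create incidence
  two <- diet_data(data.frame(stomach_id = c("a", "b"), tl_mm = c(400, 401)),
                   data.frame(stomach_id = c("a", "b"), category = "X",
                              rank = "order", group = "invertebrate",
                              count = c(2L, 0L), volume_ml = c(0.2, 0)))
  expect_equal(diet_table(two, size_classes(300, 509, 1))$n, 1L)
})

test_that("stomach and prey totals are conserved under aggregation", {
  for (seed in 1:5) {
    d <- simulate_stomachs(random_scenario(seed), seed = seed)
    sc <- size_classes(300, 509, 3)
    dt <- diet_table(d, sc)
    expect_equal(sum(unique(dt[, c("size_class", "N")])$N), nrow(d$stomachs))
    expect_equal(sum(dt$n_i), sum(d$prey$count))
    expect_equal(sum(dt$vd), sum(d$prey$volume_ml))
  }
})

test_that("write/read round trip reproduces the records exactly", {
  d <- simulate_stomachs(random_scenario(3), seed = 3)
  fs <- tempfile(fileext = ".csv"); fp <- tempfile(fileext = ".csv")
  write_diet(d, fs, fp)
  d2 <- read_diet(fs, fp)
  expect_equal(d2$stomachs$stomach_id, d$stomachs$stomach_id)
  expect_equal(d2$stomachs$tl_mm, d$stomachs$tl_mm)
  expect_equal(d2$prey[order(d2$prey$stomach_id, d2$prey$category), ],
               d$prey[order(d$prey$stomach_id, d$prey$category), ],
               ignore_attr = TRUE)
})

# Independent oracle for the count reconstruction: recursive search over the
# per-category candidate sets defined directly by the rounding property.
oracle_infer <- function(pct, t_max = 100, d = 1) {
  for (T in seq_len(t_max)) {
    cand <- lapply(pct, function(p) {
      n <- 0:T
      n[abs(rhu(100 * n / T, d) - rhu(p, d)) < 1e-9]
    })
    if (any(lengths(cand) == 0)) next
    pick <- function(i, left) {
      if (i > length(cand)) return(if (left == 0) integer(0) else NULL)
      for (n in cand[[i]]) {
        if (n > left) next
        rest <- pick(i + 1, left - n)
        if (!is.null(rest)) return(c(n, rest))
      }
      NULL
    }
    sol <- pick(1, T)
    if (!is.null(sol)) return(list(total = T, counts = sol))
  }
  NULL
}

test_that("count reconstruction finds the smallest consistent total", {
  medium <- c(25, 16.7, 25, 4.2, 12.5, 4.2, 4.2, 4.2, 4.2)
  res <- infer_counts(medium)
  orc <- oracle_infer(medium)
  expect_true(res$found)
  expect_equal(res$total, 24)
  expect_equal(res$counts, c(6L, 4L, 6L, 1L, 3L, 1L, 1L, 1L, 1L))
  expect_equal(res$total, orc$total)
  expect_equal(sum(res$counts), res$total)

  expect_equal(infer_counts(c(50, 50))$counts, c(1L, 1L))
  expect_equal(infer_counts(c(50, 50))$total, 2)

  bad <- infer_counts(c(33.3, 50))
  expect_false(bad$found)
  expect_true(is.na(bad$total))
  expect_error(infer_counts(c(-1, 50)), "\\[0, 100\\]")
})

test_that("reconstructed counts re-percentage to their input (self-inverse)", {
  set.seed(11)
  for (i in 1:20) {
    counts <- rmultinom(1, sample(5:40, 1), rep(1 / 4, 4))[, 1]
    counts <- counts[counts >= 0]
    pct <- rhu(100 * counts / sum(counts), 1)
    res <- infer_counts(pct)
    expect_true(res$found)
    expect_equal(rhu(100 * res$counts / res$total, 1), pct)
    expect_true(res$total <= sum(counts))
  }
})

test_that("reconstructed study incidences pool to the published occurrences", {
  d <- table1_fixture()
  dt <- diet_table(d, study_scheme())
  inc <- sapply(c("Coleoptera", "Hemiptera", "Araneae"),
                function(cc) sum(dt$n[dt$category == cc]))
  expect_equal(unname(inc), c(27, 23, 23))
  expect_equal(rhu(frequency_occurrence(27, 31)), 87.1)
  expect_equal(rhu(frequency_occurrence(23, 31)), 74.2)
})
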