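test_that("bootstrap GOF is exact-null on perfectly uniform counts", {
  g <- bootstrap_gof(c(10, 10, 10, 10), iterations = 200, seed = 1)
  expect_equal(g$chi2, 0)
  expect_equal(g$p, 1)
  expect_true(all(residual_flags(g) == "none"))
})

test_that("bootstrap GOF p follows the add-one convention and its floor", {
  # one dominant category: no uniform replicate can match chi2_obs
  for (seed in c(2, 17, 33)) {
    g <- bootstrap_gof(c(40, 0, 0, 0), iterations = 1000, seed = seed)
    expect_equal(g$chi2, 120)  # (30^2 + 3*10^2)/10
    expect_equal(g$p, 1 / 1001)
  }
  g <- bootstrap_gof(c(12, 9), iterations = 500, seed = 4)
  expect_gte(g$p, 1 / 501)
  expect_lte(g$p, 1)
})

test_that("bootstrap GOF is reproducible and relabel-invariant", {
  cnt <- c(A = 20, B = 9, C = 4, D = 11)
  g1 <- bootstrap_gof(cnt, iterations = 400, seed = 12)
  g2 <- bootstrap_gof(cnt, iterations = 400, seed = 12)
  expect_identical(g1$p, g2$p)
  perm <- c(3, 1, 4, 2)
  g3 <- bootstrap_gof(cnt[perm], iterations = 400, seed = 12)
  expect_equal(g3$chi2, g1$chi2)
  expect_equal(unname(g3$residuals), unname(g1$residuals[perm]))
})

test_that("bootstrap GOF accepts a non-uniform null and rejects bad input", {
  g <- bootstrap_gof(c(30, 10), iterations = 200, seed = 1, expected = c(3, 1))
  expect_equal(g$chi2, 0)
  expect_error(bootstrap_gof(c(5), iterations = 200), "single category")
  expect_error(bootstrap_gof(c(0, 0), iterations = 200), "positive sum")
  expect_error(bootstrap_gof(c(5, 5), iterations = 10), "100")
  expect_error(bootstrap_gof(c(5, 5), iterations = 200, expected = c(1, 0)), "positive proportion")
})

test_that("standardized residuals flag the study's dominant prey", {
  d <- table1_fixture()
  dt <- diet_table(d, study_scheme())
  cnt <- tapply(dt$n_i, dt$category, sum)
  g <- bootstrap_gof(cnt[cnt > 0], iterations = 1000, seed = 8)
  fl <- residual_flags(g)
  expect_true(all(fl[c("Coleoptera", "Hemiptera", "Araneae")] == "over"))
  expect_lt(g$p, 0.01)
  # degenerate threshold: every nonzero residual is flagged
  fl0 <- residual_flags(g, threshold = 0)
  expect_true(all(fl0[abs(g$residuals) > 0] != "none"))
})

test_that("RII filter keeps categories reaching the threshold in any class", {
  d <- table1_fixture()
  m <- diet_metrics(diet_table(d, study_scheme(), vtd_total = attr(d, "vtd_total")))
  expect_setequal(rii_filter(m),
                  c("Coleoptera", "Hemiptera", "Araneae", "Blattodea",
                    "Hymenoptera", "Odonata", "Fish"))
  expect_setequal(rii_filter(m, threshold = 0), unique(m$category))
  expect_length(rii_filter(m, threshold = 100), 0)
})

test_that("IRLS maximum agrees with a brute-force likelihood grid", {
  set.seed(31)
  for (i in 1:4) {
    n <- sample(15:30, 1)
    tl <- runif(n, 300, 509)
    y <- rbinom(n, 1, plogis(-4 + 0.01 * tl))
    if (length(unique(y)) < 2) next
    fit <- presence_logit(y, tl)
    if (!fit$estimable) next
    ref <- grid_logit(y, tl)
    expect_equal(unname(fit$coefficients_centred[1]), unname(ref["b0"]), tolerance = 5e-4)
    expect_equal(unname(fit$coefficients_centred[2]), unname(ref["b1"]), tolerance = 5e-4)
  }
})

test_that("presence fit matches glm and the likelihood-ratio test", {
  d <- table1_fixture()
  pm <- presence_matrix(d)
  tl <- attr(pm, "tl_mm")
  for (cc in c("Hemiptera", "Fish", "Blattodea")) {
    fit <- presence_logit(pm[, cc], tl, category = cc)
    ref <- suppressWarnings(glm(pm[, cc] ~ tl, family = binomial()))
    expect_true(fit$estimable)
    expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-5)
    expect_equal(fit$chi2, unname(ref$null.deviance - ref$deviance), tolerance = 1e-6)
    expect_equal(unname(diag(vcov(fit))), unname(diag(vcov(ref))), tolerance = 1e-4)
  }
})

test_that("IRLS deviance is non-increasing across iterations", {
  set.seed(41)
  for (i in 1:5) {
    tl <- runif(40, 300, 509)
    y <- rbinom(40, 1, plogis(-8 + 0.02 * tl))
    if (length(unique(y)) < 2) next
    fit <- presence_logit(y, tl)
    expect_true(all(diff(fit$deviance_trace) <= 1e-10))
  }
})

test_that("degenerate outcomes are flagged non-estimable, not forced", {
  tl <- seq(310, 500, length.out = 20)
  all1 <- presence_logit(rep(1, 20), tl)
  expect_false(all1$estimable)
  expect_match(all1$reason, "single level")
  expect_true(is.na(all1$coefficients[2]))
  # complete separation along TL
  sep <- presence_logit(as.numeric(tl > 400), tl)
  expect_false(sep$estimable)
  expect_error(predict(sep), "non-estimable")
  expect_error(residuals(sep), "non-estimable")
})

test_that("null simulations give unbiased slopes and calibrated p values", {
  set.seed(51)
  cover <- pvals <- numeric(0)
  for (s in 1:60) {
    tl <- runif(200, 300, 509)
    y <- rbinom(200, 1, 0.4)  # presence independent of TL
    fit <- presence_logit(y, tl)
    if (!fit$estimable) next
    se <- sqrt(diag(vcov(fit)))[2]
    cover <- c(cover, abs(coef(fit)[2]) <= 3 * se)
    pvals <- c(pvals, fit$p)
  }
  expect_gte(mean(cover), 0.95)
  expect_gte(mean(pvals <= 0.05), 0.0)
  expect_lte(mean(pvals <= 0.05), 0.15)
  expect_gt(mean(pvals), 0.3)  # roughly uniform, not piled at 0
})

test_that("predictions carry a monotone curve with a valid Wald band", {
  set.seed(61)
  tl <- runif(150, 300, 509)
  y <- rbinom(150, 1, plogis(-10 + 0.025 * tl))
  fit <- presence_logit(y, tl)
  pr <- predict(fit, interval = TRUE)
  expect_true(all(pr$fit > 0 & pr$fit < 1))
  expect_true(all(pr$lower <= pr$fit & pr$fit <= pr$upper))
  expect_true(all(diff(pr$fit) > 0) || all(diff(pr$fit) < 0))
  eta <- predict(fit, newdata = c(350, 450), type = "link")
  expect_equal(plogis(eta), predict(fit, newdata = c(350, 450)))
  sim <- simulate(fit, nsim = 3, seed = 2)
  expect_true(all(unlist(sim) %in% 0:1))
})
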