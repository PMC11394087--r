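# Shared builders for small in-code fixtures.

tiny_dataset <- function() {
  st <- data.frame(stomach_id = c("a", "b", "c"), tl_mm = c(320, 410, 500),
                   stringsAsFactors = FALSE)
  pr <- data.frame(
    stomach_id = c("a", "a", "b", "c"),
    category = c("Coleoptera", "Fish", "Coleoptera", "Araneae"),
    rank = c("order", "class", "order", "order"),
    group = c("invertebrate", "vertebrate", "invertebrate", "invertebrate"),
    count = c(3L, 1L, 2L, 4L), volume_ml = c(0.6, 1.5, 0.4, 0.8),
    stringsAsFactors = FALSE)
  diet_data(st, pr)
}

study_scheme <- function() size_classes(300, 509, 3)

# half-up rounding used by the printed reference table
rhu <- function(x, d = 1) sign(x) * floor(abs(x) * 10^d + 0.5 + 1e-9) / 10^d

# Independent oracle: brute-force grid maximization of the two-parameter
# Bernoulli log-likelihood on the centred-TL scale, iteratively refined.
# Deliberately shares no code path with the package's IRLS fitter.
grid_logit <- function(y, tl, refinements = 6) {
  x <- tl - mean(tl)
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30)))))
  }
  c0 <- 0; c1 <- 0; h0 <- 10; h1 <- 0.5
  for (r in seq_len(refinements)) {
    g0 <- seq(c0 - h0, c0 + h0, length.out = 41)
    g1 <- seq(c1 - h1, c1 + h1, length.out = 41)
    val <- outer(g0, g1, Vectorize(ll))
    ix <- which(val == max(val), arr.ind = TRUE)[1, ]
    c0 <- g0[ix[1]]; c1 <- g1[ix[2]]
    h0 <- h0 / 10; h1 <- h1 / 10
  }
  c(b0 = c0, b1 = c1)
}

random_scenario <- function(seed, n = 40, S = 5) {
  set.seed(seed)
  sim_scenario(paste0("cat", seq_len(S)), n_stomachs = n,
               presence = as.list(runif(S, 0.2, 0.9)),
               lambda = runif(S, 0.5, 3), meanlog = log(0.3), sdlog = 0.4)
}
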