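#' Logistic regression of prey presence against total length
#'
#' Fits `logit P(present) = b0 + b1 * TL` by maximum likelihood for one prey
#' category, the standard model for an ontogenetic shift in a prey item's
#' occurrence. The fit uses iteratively reweighted least squares (IRLS) with
#' step-halving, on TL centred at its sample mean for numerical conditioning
#' (coefficients are reported on the raw TL scale). Convergence is declared
#' when the relative change in log-likelihood falls below `1e-8` (at most 100
#' iterations). The model is compared against the intercept-only fit with a
#' 1-d.f. likelihood-ratio chi-square.
#'
#' Degenerate data — a single outcome level, or complete separation of
#' presences and absences along TL — have no finite maximum-likelihood
#' estimate; such fits are returned flagged `estimable = FALSE` rather than
#' forced to a finite answer.
#'
#' @param presence 0/1 (or logical) vector: category present in each stomach.
#' @param tl_mm total length per stomach, mm; same length as `presence`,
#'   at least 2 stomachs.
#' @param category optional label carried into the result.
#' @param level confidence level for bands (default 0.95).
#' @return An object of class `"presence_logit"` with components
#'   `coefficients` (`(Intercept)`, `tl_mm`; log-odds scale, slope per mm),
#'   `chi2` and `p` (likelihood-ratio test vs intercept-only), `logLik`,
#'   `null_logLik`, `deviance_trace` (per-IRLS-iteration deviance),
#'   `estimable`, `converged`, `n`, and the data. Methods: `print`,
#'   `summary`, `coef`, `vcov`, `logLik`, `fitted`, `residuals` (deviance),
#'   `predict` (with Wald confidence bands through the inverse link),
#'   `simulate`, `plot`.
#' @export
#' @examples
#' set.seed(1)
#' tl <- runif(200, 300, 509)
#' y <- rbinom(200, 1, plogis(-12 + 0.03 * tl))
#' fit <- presence_logit(y, tl)
#' fit
presence_logit <- function(presence, tl_mm, category = NULL, level = 0.95) {
  y <- as.numeric(presence)
  if (!all(y %in% c(0, 1))) stopf("presence must be 0/1 or logical")
  if (length(y) != length(tl_mm)) stopf("presence and tl_mm lengths differ")
  if (length(y) < 2) stopf("need at least 2 stomachs")
  if (any(!is.finite(tl_mm)) || any(tl_mm <= 0)) stopf("tl_mm must be positive")

  n <- length(y)
  ybar <- mean(y)
  null_ll <- if (ybar %in% c(0, 1)) 0 else
    sum(y * log(ybar) + (1 - y) * log(1 - ybar))
  base <- list(category = category, n = n, tl_mm = tl_mm, presence = y,
               level = level, null_logLik = null_ll)

  if (ybar %in% c(0, 1)) {
    return(structure(c(base, list(
      estimable = FALSE, converged = FALSE,
      reason = "outcome has a single level",
      coefficients = c(`(Intercept)` = NA_real_, tl_mm = NA_real_),
      chi2 = NA_real_, p = NA_real_, logLik = NA_real_,
      deviance_trace = numeric(0))), class = "presence_logit"))
  }

  m <- mean(tl_mm)
  X <- cbind(1, tl_mm - m)
  loglik <- function(b) {
    eta <- drop(X %*% b)
    # numerically stable log(1 + e^eta)
    sum(y * eta - ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30)))))
  }
  beta <- c(stats::qlogis(ybar), 0)
  ll <- loglik(beta)
  trace <- -2 * ll
  converged <- FALSE
  for (it in seq_len(100)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    ll_new <- loglik(beta_new)
    step <- beta_new - beta
    h <- 0
    while (!is.finite(ll_new) || ll_new < ll) {      # step-halving guard
      h <- h + 1
      if (h > 30) break
      beta_new <- beta + step / 2^h
      ll_new <- loglik(beta_new)
    }
    if (!is.finite(ll_new) || ll_new < ll) break
    trace <- c(trace, -2 * ll_new)
    done <- abs(ll_new - ll) < 1e-8 * (abs(ll_new) + 0.1)
    beta <- beta_new
    ll <- ll_new
    if (done) { converged <- TRUE; break }
  }

  mu <- stats::plogis(drop(X %*% beta))
  separated <- all(mu[y == 1] > 1 - 1e-6) && all(mu[y == 0] < 1e-6)
  estimable <- converged && !separated && all(abs(beta) < 1e6)

  w <- pmax(mu * (1 - mu), 1e-12)
  vc_c <- tryCatch(solve(t(X * w) %*% X), error = function(e) matrix(NA_real_, 2, 2))
  A <- matrix(c(1, 0, -m, 1), 2, 2)                  # centred -> raw transform
  vc <- A %*% vc_c %*% t(A)
  dimnames(vc) <- list(c("(Intercept)", "tl_mm"), c("(Intercept)", "tl_mm"))
  coefs <- c(`(Intercept)` = beta[1] - beta[2] * m, tl_mm = beta[2])
  chi2 <- 2 * (ll - null_ll)
  structure(c(base, list(
    estimable = estimable, converged = converged,
    reason = if (separated) "complete separation" else if (!converged) "IRLS did not converge" else NULL,
    coefficients = coefs, coefficients_centred = beta, center = m,
    vcov = vc, vcov_centred = vc_c,
    chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    logLik = ll, deviance_trace = trace, fitted = mu)),
    class = "presence_logit")
}

#' @export
print.presence_logit <- function(x, ...) {
  cat(sprintf("Logistic presence model%s (n = %d stomachs)\n",
              if (is.null(x$category)) "" else paste0(": ", x$category), x$n))
  if (!x$estimable) {
    cat(sprintf("  not estimable: %s\n", x$reason))
    return(invisible(x))
  }
  cat(sprintf("  logit P = %.4g + %.4g * TL(mm)\n",
              x$coefficients[1], x$coefficients[2]))
  cat(sprintf("  LR chi2 = %.4g on 1 df, p = %.4g\n", x$chi2, x$p))
  invisible(x)
}

#' @export
coef.presence_logit <- function(object, ...) object$coefficients

#' @export
vcov.presence_logit <- function(object, ...) object$vcov

#' @export
logLik.presence_logit <- function(object, ...) {
  structure(object$logLik, df = 2, nobs = object$n, class = "logLik")
}

#' @export
fitted.presence_logit <- function(object, ...) object$fitted

#' @export
residuals.presence_logit <- function(object, type = c("deviance", "pearson", "response"), ...) {
  type <- match.arg(type)
  if (!object$estimable) stopf("no residuals for a non-estimable fit")
  y <- object$presence; mu <- object$fitted
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu * (1 - mu)),
         deviance = sign(y - mu) *
           sqrt(-2 * (y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))))
}

#' Predicted presence probability over total length
#'
#' @param object a `"presence_logit"` fit.
#' @param newdata optional numeric vector of TL values (mm); defaults to a
#'   100-point grid over the observed TL range.
#' @param type `"response"` (probability) or `"link"` (log-odds).
#' @param interval logical: include a pointwise Wald confidence band,
#'   computed on the linear predictor and mapped through the inverse link.
#' @param level confidence level; defaults to the level stored in the fit.
#' @param ... unused.
#' @return If `interval = FALSE`, a numeric vector; otherwise a data frame
#'   with `tl_mm`, `fit`, `lower`, `upper`.
#' @export
predict.presence_logit <- function(object, newdata = NULL,
                                   type = c("response", "link"),
                                   interval = FALSE, level = NULL, ...) {
  type <- match.arg(type)
  if (!object$estimable) stopf("cannot predict from a non-estimable fit")
  tl <- newdata %||% seq(min(object$tl_mm), max(object$tl_mm), length.out = 100)
  X <- cbind(1, tl - object$center)
  eta <- drop(X %*% object$coefficients_centred)
  if (!interval) return(if (type == "link") eta else stats::plogis(eta))
  level <- level %||% object$level
  se <- sqrt(rowSums((X %*% object$vcov_centred) * X))
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- eta - z * se; hi <- eta + z * se
  if (type == "response") { eta <- stats::plogis(eta); lo <- stats::plogis(lo); hi <- stats::plogis(hi) }
  data.frame(tl_mm = tl, fit = eta, lower = lo, upper = hi)
}

#' @export
simulate.presence_logit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$estimable) stopf("cannot simulate from a non-estimable fit")
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim, stats::rbinom(object$n, 1, object$fitted)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.presence_logit <- function(object, ...) {
  out <- object
  if (object$estimable) {
    se <- sqrt(diag(object$vcov))
    out$coef_table <- cbind(Estimate = object$coefficients, `Std. Error` = se,
                            `z value` = object$coefficients / se,
                            `Pr(>|z|)` = 2 * stats::pnorm(-abs(object$coefficients / se)))
  }
  class(out) <- c("summary.presence_logit", class(object))
  out
}

#' @export
print.summary.presence_logit <- function(x, ...) {
  print.presence_logit(x)
  if (!is.null(x$coef_table)) {
    cat("\nCoefficients (Wald):\n")
    stats::printCoefmat(x$coef_table)
  }
  invisible(x)
}

#' Plot a fitted presence-probability curve
#'
#' Observed presences/absences against TL with the fitted logistic curve and
#' its pointwise confidence band (dotted).
#'
#' @param x a `"presence_logit"` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.presence_logit <- function(x, ...) {
  if (!x$estimable) stopf("cannot plot a non-estimable fit")
  pr <- predict(x, interval = TRUE)
  graphics::plot(x$tl_mm, x$presence, pch = ifelse(x$presence == 1, 8, 1),
                 xlab = "Total length (mm)", ylab = "P(present)",
                 ylim = c(0, 1),
                 main = x$category %||% "Prey presence vs total length", ...)
  graphics::lines(pr$tl_mm, pr$fit, col = "red", lwd = 2)
  graphics::lines(pr$tl_mm, pr$lower, lty = 3)
  graphics::lines(pr$tl_mm, pr$upper, lty = 3)
  invisible(x)
}

#' Per-stomach presence matrix
#'
#' Presence/absence (0/1) of each category in each stomach, the response
#' matrix for per-item [presence_logit()] fits.
#'
#' @param x a `"diet_data"` object.
#' @return Integer matrix stomachs x categories, with stomach ids as row
#'   names; `attr(, "tl_mm")` carries the matching TL vector.
#' @export
presence_matrix <- function(x) {
  stopifnot(inherits(x, "diet_data"))
  ids <- x$stomachs$stomach_id
  cats <- x$categories$name
  m <- matrix(0L, length(ids), length(cats), dimnames = list(ids, cats))
  pr <- x$prey[x$prey$count > 0, ]
  if (nrow(pr)) m[cbind(match(pr$stomach_id, ids), match(pr$category, cats))] <- 1L
  attr(m, "tl_mm") <- x$stomachs$tl_mm
  m
}
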