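#' Logistic (logit) model fitting and log-likelihood scoring
#'
#' The probability that a sample is a tumor is modelled as
#' \deqn{p = \frac{e^{\beta_0+\beta_1 x_1+\dots+\beta_n x_n}}
#'             {1+e^{\beta_0+\beta_1 x_1+\dots+\beta_n x_n}}}
#' with the \eqn{x_j} selected probe intensities.  Coefficients are
#' estimated by maximum likelihood with Newton-Raphson/IRLS; the fitted
#' model is scored by its natural log-likelihood value (LLV)
#' \deqn{LLV(\hat\beta) = \sum_i \left[y_i\log\hat\pi(x_i) +
#'   (1-y_i)\log(1-\hat\pi(x_i))\right] \le 0,}
#' larger (closer to zero) being better.
#'
#' Predictors are standardized internally; when any standardized
#' coefficient escapes beyond \code{beta_cap} in absolute value the data
#' are (quasi-)separated, the coefficients are clamped at the cap, the fit
#' is flagged \code{separated}, and the LLV is evaluated at the clamped
#' coefficients.  This keeps panel scores finite while still ranking
#' separating panels at the top.
#'
#' @name logit-model
NULL

.PROB_EPS <- 1e-12
.BETA_CAP <- 30

# log-likelihood of coefficients on the standardized design (with intercept
# column); probabilities clipped away from 0/1 so the value stays finite.
.loglik <- function(Xa, y, b) {
  p <- stats::plogis(drop(Xa %*% b))
  p <- pmin(pmax(p, .PROB_EPS), 1 - .PROB_EPS)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit a logit model by maximum likelihood
#'
#' Newton-Raphson on standardized predictors with step-halving (so the
#' log-likelihood never decreases across iterations) and a pseudo-inverse
#' fallback for rank-deficient designs (e.g. duplicated predictor columns
#' arising from identifier resolution).  See \link{logit-model} for the
#' separation policy.
#'
#' @param X Numeric matrix, samples x predictors (0 predictor columns give
#'   an intercept-only fit).
#' @param y Binary response (1 = tumor, 0 = normal), one per row of
#'   \code{X}; both classes must be present.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence threshold on the maximum absolute score.
#' @param beta_cap Clamp for standardized coefficients (separation guard).
#' @return An object of class \code{ab_logit_fit}: list with \code{beta0},
#'   \code{betas} (original scale), \code{beta0_std}, \code{betas_std}
#'   (standardized scale, used for the small-coefficient replacement move
#'   of the genetic algorithm), \code{llv}, \code{converged},
#'   \code{separated}, \code{rank_deficient}, \code{n_samples},
#'   \code{n_predictors}.
#' @export
fit_lm <- function(X, y, max_iter = 100L, tol = 1e-8,
                   beta_cap = .BETA_CAP) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  y <- as.integer(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("at least two samples required")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(0L, 1L))) stop("y must be binary (0/1)")
  if (length(unique(y)) < 2L)
    stop("both classes must be present to fit a logit model")
  if (any(!is.finite(X))) stop("non-finite predictor values")

  mu <- if (p) colMeans(X) else numeric(0)
  sigma <- if (p) apply(X, 2L, stats::sd) else numeric(0)
  sigma[!is.finite(sigma) | sigma == 0] <- 1
  Xs <- if (p) sweep(sweep(X, 2L, mu), 2L, sigma, "/") else
    matrix(0, n, 0L)
  Xa <- cbind(1, Xs)

  b <- numeric(p + 1L)
  ll <- .loglik(Xa, y, b)
  converged <- FALSE
  separated <- FALSE
  rank_deficient <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xa %*% b)
    pr <- stats::plogis(eta)
    score <- drop(crossprod(Xa, y - pr))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    w <- pmax(pr * (1 - pr), 1e-10)
    H <- crossprod(Xa * w, Xa)
    qh <- qr(H)
    if (qh$rank < ncol(Xa)) {
      rank_deficient <- TRUE
      step <- drop(MASS::ginv(H) %*% score)
    } else {
      step <- solve(qh, score)
    }
    # step-halving: accept the Newton step only where it improves the fit
    for (h in 0:30) {
      b_new <- b + step / 2^h
      ll_new <- .loglik(Xa, y, b_new)
      if (ll_new >= ll - 1e-12) break
    }
    b <- b_new; ll <- ll_new
    if (any(abs(b) > beta_cap)) {
      separated <- TRUE
      b <- pmin(pmax(b, -beta_cap), beta_cap)
      ll <- .loglik(Xa, y, b)
      break
    }
  }
  # complete-separation diagnostic: every fitted probability sits on its
  # label, so the unconstrained MLE is at infinity even if the score
  # converged before any coefficient reached the cap
  if (!separated &&
      all(abs(y - stats::plogis(drop(Xa %*% b))) < 1e-6))
    separated <- TRUE
  beta0_std <- b[1L]
  betas_std <- b[-1L]
  betas <- if (p) betas_std / sigma else numeric(0)
  beta0 <- beta0_std - if (p) sum(betas_std * mu / sigma) else 0
  structure(
    list(beta0 = beta0, betas = betas,
         beta0_std = beta0_std, betas_std = betas_std,
         center = mu, scale = sigma,
         llv = ll, converged = converged, separated = separated,
         rank_deficient = rank_deficient,
         n_samples = n, n_predictors = p),
    class = "ab_logit_fit")
}

#' @export
print.ab_logit_fit <- function(x, ...) {
  cat("<logit fit> ", x$n_predictors, " predictor(s), ", x$n_samples,
      " samples, LLV = ", format(x$llv, digits = 6),
      if (x$separated) " [separated]" else "",
      if (x$rank_deficient) " [rank-deficient]" else "", "\n", sep = "")
  invisible(x)
}

#' Predicted tumor probabilities
#'
#' Logistic transform of the fitted linear predictor, clipped into
#' \code{(0, 1)} so downstream log-likelihoods stay finite.
#'
#' @param fit An \code{ab_logit_fit}.
#' @param X Predictor matrix with the same columns the fit was trained on.
#' @return Numeric vector of probabilities, one per row of \code{X}.
#' @export
predict_prob <- function(fit, X) {
  stopifnot(inherits(fit, "ab_logit_fit"))
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  if (ncol(X) != fit$n_predictors)
    stop("X has ", ncol(X), " columns but the fit expects ",
         fit$n_predictors)
  eta <- fit$beta0 + if (ncol(X)) drop(X %*% fit$betas) else
    rep(0, nrow(X))
  pmin(pmax(stats::plogis(eta), .PROB_EPS), 1 - .PROB_EPS)
}

#' Natural log-likelihood value of a fit on given data
#'
#' Evaluated in log space (sum of Bernoulli log terms, never the
#' product) with probabilities clipped to \code{[1e-12, 1 - 1e-12]}.
#'
#' @inheritParams predict_prob
#' @param y Binary response vector.
#' @return The LLV, a number <= 0.
#' @export
llv <- function(fit, X, y) {
  p <- predict_prob(fit, X)
  y <- as.integer(y)
  if (length(y) != length(p)) stop("length(y) must match nrow(X)")
  sum(y * log(p) + (1 - y) * log(1 - p))
}
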