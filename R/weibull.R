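#' Fit a two-parameter Weibull model to measured hair lengths
#'
#' Maximum-likelihood fit of the Weibull shape (`alpha`) and scale (`beta`,
#' um) with the location fixed at 0. The shape equation is solved by
#' root-finding on the profile score; the scale then has the closed form
#' `beta = (mean(x^alpha))^(1/alpha)`. Hair length populations are
#' unimodal and normal-like, which the Weibull family covers.
#'
#' @param lengths numeric vector of measured lengths, um (at least 3,
#'   all positive).
#' @return Object of class `weibull_model` with fields `alpha`, `beta`,
#'   `loglik`, `n`.
#' @export
fit_weibull <- function(lengths) {
  x <- as.numeric(lengths)
  if (length(x) < 3) stop("need at least 3 lengths")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all lengths must be positive and finite")
  if (max(x) - min(x) < .Machine$double.eps * max(x) * 10)
    stop("degenerate fit: lengths are constant (shape tends to infinity)")
  lx <- log(x)
  score <- function(a) {
    xa <- x^a
    sum(xa * lx) / sum(xa) - 1 / a - mean(lx)
  }
  lo <- 1e-3; hi <- 1
  while (score(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (score(hi) < 0)
    stop("degenerate fit: shape estimate diverges")
  a <- uniroot(score, c(lo, hi), tol = 1e-10)$root
  b <- mean(x^a)^(1 / a)
  ll <- sum(stats::dweibull(x, shape = a, scale = b, log = TRUE))
  structure(list(alpha = a, beta = b, loglik = ll, n = length(x)),
            class = "weibull_model")
}

#' Construct a Weibull model from known parameters
#' @param alpha shape (> 0, dimensionless).
#' @param beta scale (> 0, um).
#' @return Object of class `weibull_model`.
#' @export
weibull_model <- function(alpha, beta) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  structure(list(alpha = alpha, beta = beta, loglik = NA_real_, n = 0L),
            class = "weibull_model")
}

#' @export
print.weibull_model <- function(x, ...) {
  cat(sprintf("<weibull_model> alpha = %.4g, beta = %.4g um\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Weibull cumulative distribution function
#'
#' `g(x) = 1 - exp(-(x/beta)^alpha)`.
#'
#' @param x lengths, um (>= 0).
#' @param model a `weibull_model`.
#' @return Probabilities in `[0, 1]`.
#' @export
weibull_cdf <- function(x, model) {
  if (any(x < 0)) stop("x must be non-negative")
  1 - exp(-(x / model$beta)^model$alpha)
}

#' Sample virtual growth lengths by survival analysis
#'
#' A partially visible hair is taken to have "survived" to its visible
#' length `l_r`; the remaining (virtual) length `l_v` follows the future
#' lifetime law of the fitted Weibull: density
#' `p(l) = f(l + l_r) / (1 - g(l_r))`. Inversion of its CDF has the closed
#' form
#' `l_v = beta * ((l_r/beta)^alpha - log(1 - u))^(1/alpha) - l_r`,
#' with `u ~ Uniform(0, 1)` drawn from the open interval (avoiding
#' infinite lengths at u = 1). With `l_r = 0` this reduces to a plain
#' Weibull draw; for `alpha = 1` the law is memoryless.
#'
#' @param l_r visible length, um (>= 0; scalar).
#' @param model a `weibull_model`.
#' @param n number of draws.
#' @param u optional uniform variates (for deterministic evaluation).
#' @return Numeric vector of `l_v` draws, um.
#' @export
sample_future_length <- function(l_r, model, n = 1, u = NULL) {
  if (l_r < 0) stop("l_r must be non-negative")
  if (is.null(u)) {
    u <- runif(n)
    u[u == 0] <- .Machine$double.eps     # open interval (0, 1)
    u[u == 1] <- 1 - .Machine$double.eps
  }
  a <- model$alpha; b <- model$beta
  pmax(b * ((l_r / b)^a - log1p(-u))^(1 / a) - l_r, 0)
}
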