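#' @keywords internal
"_PACKAGE"

FAMILIES <- c("weibull", "gamma", "lognormal", "gaussian")

check_params <- function(family, params) {
  params <- as.numeric(params)
  if (length(params) != 2 || any(!is.finite(params))) {
    stop("params must be two finite numbers")
  }
  ok <- switch(family,
    weibull   = params[1] > 0 && params[2] > 0,
    gamma     = params[1] > 0 && params[2] > 0,
    lognormal = params[2] > 0,
    gaussian  = params[2] > 0
  )
  if (!ok) stop(sprintf("invalid parameters for %s: (%g, %g)",
                        family, params[1], params[2]))
  params
}

#' Evaluate a candidate probability density
#'
#' The three candidate families for heavy-tailed receptor populations are
#' Weibull (shape `a`, scale `b`), Gamma (shape `a`, scale `b`) and lognormal
#' (mean `mu` and SD `sigma` of log-counts); the Gaussian (`mu`, `sigma` of
#' counts) is carried only as a comparison baseline. Values outside the
#' support (x <= 0 for the three positive families) get density 0.
#'
#' @param family One of `"weibull"`, `"gamma"`, `"lognormal"`, `"gaussian"`.
#' @param params Numeric length-2 vector of family parameters, in the order
#'   above.
#' @param x Receptor levels (receptors/cell) at which to evaluate.
#' @return Densities (per receptors/cell), same length as `x`.
#' @examples
#' eval_pdf("lognormal", c(0, 1), 1)   # standard normal peak: 0.3989
#' eval_pdf("weibull", c(1, 1), 1)     # unit exponential: exp(-1)
#' @export
eval_pdf <- function(family, params, x) {
  family <- match.arg(family, FAMILIES)
  params <- check_params(family, params)
  switch(family,
    weibull   = stats::dweibull(x, shape = params[1], scale = params[2]),
    gamma     = stats::dgamma(x, shape = params[1], scale = params[2]),
    lognormal = stats::dlnorm(x, meanlog = params[1], sdlog = params[2]),
    gaussian  = stats::dnorm(x, mean = params[1], sd = params[2])
  )
}

neg_loglik <- function(family, logp, x) {
  p <- exp(logp)
  d <- suppressWarnings(switch(family,
    weibull = stats::dweibull(x, shape = p[1], scale = p[2], log = TRUE),
    gamma   = stats::dgamma(x, shape = p[1], scale = p[2], log = TRUE)
  ))
  if (any(!is.finite(d))) return(1e300)
  -sum(d)
}

# Profile MLEs. For the gamma, the scale profiles out as b = mean(x)/a and
# the shape solves log(a) - digamma(a) = log(mean x) - mean(log x) (Newton).
# For the Weibull, the scale profiles out as b = (mean x^a)^(1/a) and the
# shape solves sum(x^a log x)/sum(x^a) - 1/a - mean(log x) = 0 (monotone in
# a; bracketing + uniroot). Both return NULL on failure so the caller can
# fall back to a 2-parameter optimizer.
gamma_mle_profile <- function(x, tol = 1e-12) {
  s <- log(mean(x)) - mean(log(x))
  if (!is.finite(s) || s <= 0) return(NULL)
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:100) {
    g <- log(a) - digamma(a) - s
    step <- g / (1 / a - trigamma(a))
    a_new <- a - step
    if (a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < tol * a) { a <- a_new; break }
    a <- a_new
  }
  if (!is.finite(a) || a <= 0) return(NULL)
  c(a, mean(x) / a)
}

weibull_mle_profile <- function(x) {
  z <- x / max(x)  # rescaled to avoid overflow in z^a
  lx <- log(x)
  ml <- mean(lx)
  g <- function(a) {
    za <- z^a
    sum(za * lx) / sum(za) - 1 / a - ml
  }
  lo <- 0.05; hi <- 1
  while (g(hi) < 0 && hi < 1024) hi <- hi * 2
  while (g(lo) > 0 && lo > 1e-6) lo <- lo / 2
  if (g(lo) > 0 || g(hi) < 0) return(NULL)
  a <- tryCatch(stats::uniroot(g, c(lo, hi), tol = 1e-10)$root,
                error = function(e) NULL)
  if (is.null(a) || !is.finite(a) || a <= 0) return(NULL)
  b <- max(x) * mean(z^a)^(1 / a)
  c(a, b)
}

# Three deterministic starting points for the 2-parameter positive families:
# method of moments, a quantile-based start, and unit shape with mean scale.
mle_starts <- function(family, x) {
  m <- mean(x); v <- stats::var(x); cv <- sqrt(v) / m
  if (family == "gamma") {
    list(c(m^2 / v, v / m),
         c(1 / cv^2, m * cv^2),
         c(1, m))
  } else { # weibull: shape from the CV approximation a ~ cv^-1.086
    a0 <- max(cv^-1.086, 0.1)
    list(c(a0, m / gamma(1 + 1 / a0)),
         c(1.5, stats::quantile(x, 0.63, names = FALSE)),
         c(1, m))
  }
}

#' Fit a distribution by maximum likelihood
#'
#' Parameters are estimated by MLE on the raw (unbinned) values; the binned
#' SSE is reserved for model selection and bin-number optimization, so that
#' the fitted parameters do not depend on the bin count. Lognormal and
#' Gaussian MLEs are closed-form; gamma and Weibull are maximized
#' numerically in log-parameter space from three deterministic starting
#' points (method of moments, quantile matching, unit shape).
#'
#' @param sample A [receptor_sample()] or numeric vector (n >= 10).
#' @param family One of `"weibull"`, `"gamma"`, `"lognormal"`, `"gaussian"`.
#' @return An object of class `distribution_fit`: list with `family`,
#'   `params` (named), `loglik`, `converged`, `n`, and `sse` (`NA` until
#'   scored against a histogram).
#' @export
fit_mle <- function(sample, family = c("weibull", "gamma", "lognormal", "gaussian")) {
  family <- match.arg(family)
  # a raw numeric vector is taken at face value: nonpositive values are a
  # support violation for the three positive families, reported not dropped
  if (!inherits(sample, "receptor_sample") && is.numeric(sample) &&
      family != "gaussian" && any(sample <= 0, na.rm = TRUE)) {
    stop(sprintf("%d nonpositive values: %s requires strictly positive data",
                 sum(sample <= 0, na.rm = TRUE), family))
  }
  x <- as_receptor_sample(sample)$values
  if (length(x) < 10) stop("need at least 10 values to fit")
  if (max(x) == min(x)) stop("degenerate sample: all values equal")
  converged <- TRUE
  if (family == "lognormal") {
    lx <- log(x)
    mu <- mean(lx)
    sigma <- sqrt(mean((lx - mu)^2))
    params <- c(mu = mu, sigma = sigma)
    ll <- sum(stats::dlnorm(x, mu, sigma, log = TRUE))
  } else if (family == "gaussian") {
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    params <- c(mu = mu, sigma = sigma)
    ll <- sum(stats::dnorm(x, mu, sigma, log = TRUE))
  } else {
    # fast path: profile likelihood reduces both families to one dimension
    params <- switch(family,
      gamma = gamma_mle_profile(x),
      weibull = weibull_mle_profile(x)
    )
    if (is.null(params)) {
      # fallback: 2-parameter search from three deterministic starts
      best <- NULL
      for (start in mle_starts(family, x)) {
        fit <- tryCatch(
          stats::optim(log(start), neg_loglik, family = family, x = x,
                       method = "BFGS", control = list(maxit = 500)),
          error = function(e) NULL
        )
        if (is.null(fit) || !is.finite(fit$value)) next
        if (is.null(best) || fit$value < best$value) best <- fit
      }
      if (is.null(best)) stop(sprintf("MLE failed for %s from all starts", family))
      params <- exp(best$par)
      converged <- best$convergence == 0
    }
    names(params) <- c("shape", "scale")
    ll <- -neg_loglik(family, log(params), x)
    if (!is.finite(ll)) stop(sprintf("MLE for %s yielded non-finite likelihood", family))
  }
  structure(
    list(family = family, params = params, loglik = ll,
         converged = converged, n = length(x), sse = NA_real_),
    class = "distribution_fit"
  )
}

#' @export
print.distribution_fit <- function(x, ...) {
  cat(sprintf("distribution_fit: %s(%s = %.4g, %s = %.4g), n = %d, logLik = %.4g%s\n",
              x$family, names(x$params)[1], x$params[1],
              names(x$params)[2], x$params[2], x$n, x$loglik,
              if (is.finite(x$sse)) sprintf(", SSE = %.4g", x$sse) else ""))
  invisible(x)
}

#' Sum of squared errors of a fitted density against a histogram
#'
#' The observed bin heights are density-normalized, `d_i = n_i / (N * w)`,
#' and compared with the fitted density evaluated at the bin centers:
#' `SSE = sum_i (d_i - f(c_i))^2`. Density normalization makes the observed
#' and expected values commensurable and the SSE comparable across bin
#' numbers, which the bin-number search requires.
#'
#' @param hist A histogram from [build_histogram()].
#' @param fit A `distribution_fit` (or list with `family` and `params`).
#' @return Nonnegative scalar SSE.
#' @export
compute_sse <- function(hist, fit) {
  stopifnot(inherits(hist, "receptor_histogram"))
  if (length(hist$counts) == 0) stop("empty histogram")
  d <- hist$counts / (hist$total * hist$width)
  f <- eval_pdf(fit$family, fit$params, hist$centers)
  sum((d - f)^2)
}

#' Select the best-fitting family by SSE
#'
#' Fits Weibull, Gamma and lognormal to the sample by MLE and returns the
#' family whose fitted density has the lowest SSE against the k-bin
#' histogram. The Gaussian is deliberately excluded: it serves only as a
#' baseline to illustrate how poorly a symmetric distribution represents
#' heavy-tailed receptor data. A family that cannot be fitted (e.g. support
#' violation) is skipped with a warning; if all three fail, an error is
#' raised.
#'
#' @param sample A [receptor_sample()] or numeric vector.
#' @param k Bin count for the comparison histogram (>= 2; default 20, see
#'   [low_bin_config()] for why very coarse histograms are avoided here).
#' @return List with `family` (best), `fits` (named list of
#'   `distribution_fit`s with `sse` filled in) and `sse` (named vector).
#' @export
select_best_family <- function(sample, k = 20) {
  if (k < 2) stop("k must be >= 2")
  sample <- as_receptor_sample(sample)
  hist <- build_histogram(sample, k)
  fits <- list(); sse <- c()
  for (fam in c("weibull", "gamma", "lognormal")) {
    fit <- tryCatch(fit_mle(sample, fam), error = function(e) {
      warning(sprintf("skipping %s: %s", fam, conditionMessage(e)))
      NULL
    })
    if (is.null(fit)) next
    fit$sse <- compute_sse(hist, fit)
    fits[[fam]] <- fit
    sse[fam] <- fit$sse
  }
  if (length(fits) == 0) stop("no candidate family could be fitted")
  list(family = names(which.min(sse)), fits = fits, sse = sse)
}
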