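#' Representative statistics of a receptor population
#'
#' The four single-value representations of a heterogeneous population:
#' geometric mean `exp(mean(log x))`, arithmetic mean, mode and median. The
#' mode and median favor frequently repeated values, the arithmetic mean is
#' biased toward the heavy tail, and the geometric mean balances frequency
#' against range — which is why it is usually the preferred representation
#' for lognormal-like receptor data. All four are computed on the raw
#' (unbinned) values, so the mode need not fall in the largest histogram
#' bin. The mode of continuous data is defined as the most frequent value
#' after rounding to the nearest integer receptor count (the data's physical
#' resolution), ties broken toward the smaller value.
#'
#' @param sample A [receptor_sample()] or numeric vector of positive values.
#' @return Object of class `representative_stats`: list with
#'   `geometric_mean`, `arithmetic_mean`, `mode`, `median` (receptors/cell).
#' @examples
#' s <- representative_stats(c(1, 2, 4, 8))
#' s$geometric_mean  # 64^(1/4) = 2.8284
#' @export
representative_stats <- function(sample) {
  if (!inherits(sample, "receptor_sample") && is.numeric(sample) &&
      any(sample <= 0, na.rm = TRUE)) {
    stop(sprintf("%d nonpositive values: the geometric mean requires strictly positive data",
                 sum(sample <= 0, na.rm = TRUE)))
  }
  x <- as_receptor_sample(sample)$values
  rounded <- round(x)
  tab <- table(rounded)
  mode_val <- as.numeric(names(tab)[which.max(tab)])  # ties: smallest (table is sorted)
  structure(
    list(geometric_mean = exp(mean(log(x))),
         arithmetic_mean = mean(x),
         mode = mode_val,
         median = stats::median(x)),
    class = "representative_stats"
  )
}

#' @export
print.representative_stats <- function(x, ...) {
  cat(sprintf("geometric mean %.4g | arithmetic mean %.4g | mode %.4g | median %.4g receptors/cell\n",
              x$geometric_mean, x$arithmetic_mean, x$mode, x$median))
  invisible(x)
}

gaussian_mixture_loglik <- function(x, weights, means, sds) {
  dens <- vapply(seq_along(weights),
                 function(m) weights[m] * stats::dnorm(x, means[m], sds[m]),
                 numeric(length(x)))
  sum(log(rowSums(dens)))
}

em_once <- function(x, m, centers, max_iter, tol, sd_floor) {
  n <- length(x)
  means <- sort(centers)
  sds <- rep(stats::sd(x) / m, m)
  weights <- rep(1 / m, m)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(m),
                   function(j) weights[j] * stats::dnorm(x, means[j], sds[j]),
                   numeric(n))
    rowsum_d <- rowSums(dens)
    if (any(rowsum_d <= 0) || any(!is.finite(rowsum_d))) return(NULL)
    resp <- dens / rowsum_d
    ll <- sum(log(rowsum_d))
    ll_trace <- c(ll_trace, ll)
    nk <- colSums(resp)
    weights <- nk / n
    means <- colSums(resp * x) / nk
    sds <- sqrt(colSums(resp * (outer(x, means, "-"))^2) / nk)
    if (any(sds < sd_floor)) return(NULL)  # component collapse
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(weights = weights, means = means, sds = sds, loglik = ll,
       ll_trace = ll_trace, iterations = iter,
       converged = iter < max_iter)
}

#' Fit a tri-modal Gaussian mixture by EM
#'
#' Multimodal tumor-cell and tumor-endothelial receptor populations are
#' decomposed into `m` Gaussian subpopulations by expectation-maximization.
#' The best of `restarts` seeded k-means initializations (by log-likelihood)
#' is kept; components are then sorted by descending weight so that
#' component 1 is "Density 1" (the most frequent subpopulation). Cells are
#' hard-assigned to the component with maximum posterior responsibility.
#'
#' @param sample A [receptor_sample()] or numeric vector (n >= 10 m).
#' @param m Number of components (default 3).
#' @param seed Master RNG seed for the restarts.
#' @param restarts Number of seeded initializations (default 10).
#' @param max_iter,tol EM iteration cap (500) and relative log-likelihood
#'   convergence tolerance (1e-8).
#' @return Object of class `mixture_fit`: `weights`, `means`, `sds` (sorted
#'   by descending weight), `assignment` (1-based component per cell),
#'   `loglik`, `ll_trace` (per-iteration log-likelihood of the winning run),
#'   `converged`.
#' @export
fit_mixture <- function(sample, m = 3, seed = 1, restarts = 10,
                        max_iter = 500, tol = 1e-8) {
  sample <- as_receptor_sample(sample)
  x <- sample$values
  if (length(x) < 10 * m) stop(sprintf("need at least %d values for m = %d", 10 * m, m))
  sd_floor <- 1e-6 * stats::sd(x)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    km <- tryCatch(stats::kmeans(x, centers = m, nstart = 1),
                   error = function(e) NULL)
    centers <- if (is.null(km)) stats::quantile(x, stats::runif(m), names = FALSE)
               else as.numeric(km$centers)
    fit <- em_once(x, m, centers, max_iter, tol, sd_floor)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("EM failed to converge in all restarts (component collapse or degenerate data)")
  ord <- order(best$weights, decreasing = TRUE)
  weights <- best$weights[ord]; means <- best$means[ord]; sds <- best$sds[ord]
  resp <- vapply(seq_len(m),
                 function(j) weights[j] * stats::dnorm(x, means[j], sds[j]),
                 numeric(length(x)))
  assignment <- max.col(resp, ties.method = "first")
  structure(
    list(m = m, weights = weights, means = means, sds = sds,
         assignment = assignment, loglik = best$loglik,
         ll_trace = best$ll_trace, converged = best$converged,
         n = length(x)),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: %d Gaussian components, n = %d, logLik = %.6g\n",
              x$m, x$n, x$loglik))
  for (j in seq_len(x$m)) {
    cat(sprintf("  Density %d: weight %.3f, mean %.4g, sd %.4g\n",
                j, x$weights[j], x$means[j], x$sds[j]))
  }
  invisible(x)
}

#' Density-weighted mixture-level statistic
#'
#' The mixture-level value of a representative statistic is the sum of the
#' per-component values weighted by the component densities (mixture
#' weights). Being a convex combination, it always lies within the range of
#' the component values.
#'
#' @param weights Mixture weights (nonnegative, summing to 1).
#' @param stats Per-component statistic values, same length.
#' @return Scalar weighted value.
#' @examples
#' mixture_weighted_stat(c(0.5, 0.3, 0.2), c(10, 20, 30))  # 17
#' @export
mixture_weighted_stat <- function(weights, stats) {
  if (length(weights) != length(stats)) stop("length mismatch between weights and stats")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be nonnegative and sum to 1")
  }
  sum(weights * stats)
}

#' Per-component and mixture-level representative statistics
#'
#' Computes [representative_stats()] on the cells hard-assigned to each
#' mixture component ("Density 1/2/3"), then combines them into
#' mixture-level values with [mixture_weighted_stat()]. Component statistics
#' are computed on assigned cells rather than from the fitted Gaussian
#' parameters because a Gaussian's support includes nonpositive values,
#' where the geometric mean is undefined.
#'
#' @param sample The sample the mixture was fitted to.
#' @param fit A [fit_mixture()] result.
#' @return Object of class `mixture_summary`: `components` (list of
#'   `representative_stats` per component), `weights` and `mixture` (a
#'   `representative_stats`-like list of weighted values).
#' @export
mixture_summary <- function(sample, fit) {
  sample <- as_receptor_sample(sample)
  stopifnot(inherits(fit, "mixture_fit"), length(fit$assignment) == sample$n)
  comps <- lapply(seq_len(fit$m), function(j) {
    representative_stats(sample$values[fit$assignment == j])
  })
  stat_names <- c("geometric_mean", "arithmetic_mean", "mode", "median")
  mixture <- lapply(stat_names, function(s) {
    mixture_weighted_stat(fit$weights, vapply(comps, `[[`, numeric(1), s))
  })
  names(mixture) <- stat_names
  structure(list(components = comps, weights = fit$weights, mixture = mixture),
            class = "mixture_summary")
}

#' @export
print.mixture_summary <- function(x, ...) {
  for (j in seq_along(x$components)) {
    cat(sprintf("Density %d (weight %.3f): ", j, x$weights[j]))
    print(x$components[[j]])
  }
  cat("Mixture: ")
  cat(sprintf("geometric mean %.4g | arithmetic mean %.4g | mode %.4g | median %.4g\n",
              x$mixture$geometric_mean, x$mixture$arithmetic_mean,
              x$mixture$mode, x$mixture$median))
  invisible(x)
}
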