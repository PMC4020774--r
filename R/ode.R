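# Stiff-capable ODE integration: a 2(3)-order Rosenbrock method with
# adaptive step size (the scheme behind MATLAB's ode23s), with the Jacobian
# evaluated by forward differences at every step. Adequate for the model's
# ~40 species; no compiled code needed.

num_jacobian <- function(f, y, fy = f(y)) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- max(1e-8, 1e-8 * abs(y[j]))
    yp <- y
    yp[j] <- yp[j] + h
    J[, j] <- (f(yp) - fy) / h
  }
  J
}

#' Integrate an autonomous ODE system with a stiff Rosenbrock method
#'
#' Second-order Rosenbrock integration with an embedded third-order error
#' estimate and adaptive steps. Intended for the compartment model but usable
#' for any autonomous system.
#'
#' @param f Derivative function `f(y) -> dy/dt` (autonomous).
#' @param y0 Named initial state.
#' @param times Ascending output times; the first is the initial time.
#' @param rtol,atol Relative and absolute error tolerances.
#' @param max_steps Step-count guard.
#' @return Matrix with one row per output time (attribute `times`), columns
#'   named as `y0`.
#' @export
ode_rosenbrock <- function(f, y0, times, rtol = 1e-8, atol = 1e-8,
                           max_steps = 200000L) {
  stopifnot(length(times) >= 2, !is.unsorted(times))
  n <- length(y0)
  d <- 1 / (2 + sqrt(2))
  e32 <- 6 + sqrt(2)
  out <- matrix(NA_real_, length(times), n,
                dimnames = list(NULL, names(y0)))
  out[1, ] <- y0
  y <- y0
  t <- times[1]
  h <- (times[2] - times[1]) / 100
  next_out <- 2L
  steps <- 0L
  while (next_out <= length(times)) {
    if (steps >= max_steps) stop("ode_rosenbrock: step limit exceeded (stiffness or tolerance problem)")
    h <- min(h, times[next_out] - t)
    F0 <- f(y)
    J <- num_jacobian(f, y, F0)
    repeat {
      steps <- steps + 1L
      W <- diag(n) - h * d * J
      lu <- tryCatch(solve(W), error = function(e) NULL)
      if (is.null(lu)) { h <- h / 2; next }
      k1 <- lu %*% F0
      F1 <- f(y + 0.5 * h * as.numeric(k1))
      k2 <- lu %*% (F1 - as.numeric(k1)) + k1
      ynew <- y + h * as.numeric(k2)
      F2 <- f(ynew)
      k3 <- lu %*% (F2 - e32 * (as.numeric(k2) - F1) - 2 * (as.numeric(k1) - F0))
      err <- (h / 6) * (as.numeric(k1) - 2 * as.numeric(k2) + as.numeric(k3))
      sc <- atol + rtol * pmax(abs(y), abs(ynew))
      errnorm <- sqrt(mean((err / sc)^2))
      if (is.finite(errnorm) && errnorm <= 1) {
        t <- t + h
        y <- ynew
        h <- h * min(5, max(0.2, 0.9 * errnorm^(-1 / 3)))
        break
      }
      h <- h * max(0.1, 0.9 * errnorm^(-1 / 3))
      if (h < 1e-12 * max(abs(times))) stop("ode_rosenbrock: step size underflow")
    }
    while (next_out <= length(times) && t >= times[next_out] - 1e-9 * max(1, abs(t))) {
      out[next_out, ] <- y
      next_out <- next_out + 1L
    }
  }
  attr(out, "times") <- times
  out
}

# Newton refinement of a steady state f(y) = 0, with simple damping.
newton_steady_state <- function(f, y, max_iter = 50, tol = 1e-12) {
  for (i in seq_len(max_iter)) {
    fy <- f(y)
    if (max(abs(fy) / pmax(abs(y), 1)) < tol) break
    J <- num_jacobian(f, y, fy)
    step <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      ynew <- y + lambda * step
      if (max(abs(f(ynew))) <= max(abs(fy)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    y <- ynew
  }
  y
}
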