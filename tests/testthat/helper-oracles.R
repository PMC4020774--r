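# Independent oracles used across the suite. These deliberately re-derive
# quantities with the dumbest correct method available so they cannot share
# a bug with the implementation under test.

# Per-value bin assignment: right-open bins, last bin closed.
oracle_bin_counts <- function(x, k) {
  lo <- min(x); hi <- max(x)
  edges <- seq(lo, hi, length.out = k + 1)
  counts <- integer(k)
  for (v in x) {
    j <- k
    for (b in seq_len(k - 1)) {
      if (v >= edges[b] && v < edges[b + 1]) { j <- b; break }
    }
    counts[j] <- counts[j] + 1L
  }
  counts
}

# Exhaustive condition scan for the cutoff bin (1-based; NA if none).
oracle_cutoff <- function(counts, fraction) {
  thr <- fraction * max(counts)
  i_max <- which.max(counts)
  k <- length(counts)
  for (j in seq_len(k)) {
    if (j <= i_max) next
    left <- counts[j - 1]
    right <- if (j == k) 0 else counts[j + 1]
    if (counts[j] < thr && left < thr && right < thr) return(j)
  }
  NA_integer_
}

# Brute-force SSE summation against a fitted density.
oracle_sse <- function(hist, fit) {
  total <- 0
  for (i in seq_along(hist$counts)) {
    d <- hist$counts[i] / (hist$total * hist$width)
    f <- eval_pdf(fit$family, fit$params, hist$centers[i])
    total <- total + (d - f)^2
  }
  total
}

# Asymptotic standard errors from the observed information (central-
# difference Hessian of the negative log-likelihood at the MLE).
oracle_asymp_se <- function(family, params, x) {
  nll <- function(p) {
    -sum(log(pmax(eval_pdf(family, p, x), 1e-300)))
  }
  p <- as.numeric(params)
  h <- pmax(1e-5 * abs(p), 1e-8)
  H <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- (nll(p + ei + ej) - nll(p + ei - ej) -
                nll(p - ei + ej) + nll(p - ei - ej)) / (4 * h[i] * h[j])
  }
  sqrt(diag(solve(H)))
}

# Free-ligand equilibrium of L + R <=> C in a closed volume.
oracle_binding_equilibrium <- function(L_total, R_total, Kd) {
  b <- L_total - R_total - Kd
  (b + sqrt(b^2 + 4 * L_total * Kd)) / 2
}

# A random histogram object for oracle-equivalence sweeps.
random_histogram <- function(k, max_count = 500) {
  counts <- as.integer(stats::rpois(k, stats::runif(1, 0.5, 50)))
  counts[sample.int(k, 1)] <- max_count
  w <- stats::runif(1, 0.5, 100)
  lo <- stats::runif(1, 0, 1000)
  edges <- lo + w * (0:k)
  structure(
    list(edges = edges, centers = (edges[-1] + edges[-(k + 1)]) / 2,
         counts = counts, width = w, total = sum(counts)),
    class = "receptor_histogram"
  )
}
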