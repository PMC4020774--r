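#' Configuration for the low bin search
#'
#' @param k_min Minimum bin number scanned (default 5: fewer bins cannot
#'   usefully represent the data).
#' @param k_max Maximum bin number scanned (default 200).
#' @param eligibility_fraction Occupancy fraction of the largest bin below
#'   which a bin (and both neighbors) must fall to qualify as the cutoff bin.
#'   Default 0.01 (the "1% of the largest bin" criterion); 0.02 is sometimes
#'   appropriate for very heavy tails.
#' @param reference_k Bin number used once, before the k-scan, to select the
#'   best-fitting family (default 20). The best family is insensitive to the
#'   bin number over a wide range, but very coarse histograms (around the
#'   minimum of 5 bins) are unreliable for selection: the density evaluated
#'   at the center of a wide bin is a poor stand-in for the average density
#'   within it.
#' @return An object of class `low_bin_config`.
#' @export
low_bin_config <- function(k_min = 5L, k_max = 200L, eligibility_fraction = 0.01,
                           reference_k = 20L) {
  stopifnot(k_min >= 2, k_min <= k_max, reference_k >= 2,
            eligibility_fraction > 0, eligibility_fraction < 1)
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 eligibility_fraction = eligibility_fraction,
                 reference_k = as.integer(reference_k)),
            class = "low_bin_config")
}

#' Build an equal-width histogram
#'
#' `k` equal-width bins spanning `[min(values), max(values)]`. Intervals are
#' right-open except the last, which is closed, so every value lands in
#' exactly one bin and the counts sum to n.
#'
#' @param sample A [receptor_sample()] or numeric vector.
#' @param k Number of bins (>= 2).
#' @return Object of class `receptor_histogram` with `edges` (length k+1),
#'   `centers`, `counts`, `width` and `total`.
#' @examples
#' h <- build_histogram(c(1, 1, 1, 9, 9), k = 2)
#' h$counts  # 3 2
#' @export
build_histogram <- function(sample, k) {
  x <- as_receptor_sample(sample)$values
  if (k < 2) stop("k must be >= 2")
  lo <- min(x); hi <- max(x)
  if (hi == lo) stop("zero range: all values identical")
  k <- as.integer(k)
  w <- (hi - lo) / k
  edges <- lo + w * (0:k)
  edges[k + 1] <- hi  # guard rounding on the last edge
  idx <- pmin(floor((x - lo) / w) + 1L, k)  # last bin closed on the right
  counts <- tabulate(idx, nbins = k)
  structure(
    list(edges = edges, centers = (edges[-1] + edges[-(k + 1)]) / 2,
         counts = counts, width = w, total = length(x)),
    class = "receptor_histogram"
  )
}

#' @export
print.receptor_histogram <- function(x, ...) {
  cat(sprintf("receptor_histogram: %d bins of width %.4g over [%.4g, %.4g], N = %d\n",
              length(x$counts), x$width, x$edges[1],
              x$edges[length(x$edges)], x$total))
  invisible(x)
}

#' Find the SSE-optimal bin number
#'
#' Scans `k` from `k_min` to `k_max`, computing the SSE of the given family's
#' raw-data MLE density against each k-bin histogram, and returns the
#' minimizer. Parameters are held fixed at the raw-data MLE while `k` varies
#' (re-estimating per k would couple the parameters to the bin count and
#' break comparability of the SSE across k). Ties break toward smaller k.
#'
#' @param sample A [receptor_sample()] or numeric vector.
#' @param family Distribution family already selected for this sample.
#' @param config A [low_bin_config()].
#' @param fit Optional precomputed `distribution_fit` for `family` (avoids
#'   refitting).
#' @return List with `k_star`, `sse_by_k` (named vector over the scanned
#'   grid) and the `fit` used.
#' @export
optimal_bin_number <- function(sample, family, config = low_bin_config(),
                               fit = NULL) {
  sample <- as_receptor_sample(sample)
  if (is.null(fit)) fit <- fit_mle(sample, family)
  ks <- config$k_min:config$k_max
  sse <- vapply(ks, function(k) compute_sse(build_histogram(sample, k), fit),
                numeric(1))
  names(sse) <- ks
  list(k_star = ks[which.min(sse)], sse_by_k = sse, fit = fit)
}

#' Locate the outlier cutoff bin
#'
#' The cutoff bin is the leftmost bin strictly to the right of the largest
#' bin whose own count and both neighbors' counts are all below
#' `eligibility_fraction` times the largest bin's count (e.g. with the 1%
#' criterion and a largest bin of 500 cells, the threshold is "fewer than 5
#' cells"). The low-occupancy condition gives the cutoff bin low occurrence
#' probability; requiring the same of both neighbors ensures it is not an
#' isolated dip. The missing right neighbor of the last bin counts as 0
#' cells; the leftmost maximal bin is "the largest bin" if tied. Only
#' right-of-maximum bins are candidates: left-tail low expression is a real
#' biological state, not an artifact.
#'
#' @param hist A [build_histogram()] result.
#' @param config A [low_bin_config()].
#' @return 1-based bin index of the cutoff bin, or `NA_integer_` if no bin
#'   qualifies.
#' @export
find_cutoff_bin <- function(hist, config = low_bin_config()) {
  stopifnot(inherits(hist, "receptor_histogram"))
  counts <- hist$counts
  k <- length(counts)
  threshold <- config$eligibility_fraction * max(counts)
  i_max <- which.max(counts)  # leftmost maximal bin
  padded <- c(counts, 0)      # missing right neighbor of last bin = 0 cells
  for (j in seq_len(k)) {
    if (j <= i_max) next
    if (counts[j] < threshold &&
        padded[j - 1] < threshold &&
        padded[j + 1] < threshold) {
      return(j)
    }
  }
  NA_integer_
}

#' Low bin search: family selection, optimal binning and outlier removal
#'
#' The full three-step procedure for characterizing a heterogeneous
#' receptor population: (1) select the best-fitting family (lowest SSE among
#' Weibull, Gamma, lognormal at the reference bin number
#' `config$reference_k`; the best family is insensitive to the bin number,
#' so one reference k suffices);
#' (2) find the SSE-optimal bin number for that family; (3) find the cutoff
#' bin on the optimal histogram and remove it and every bin to its right,
#' then refit the family on the kept cells.
#'
#' @param sample A [receptor_sample()] or numeric vector of n >= 100 cells.
#' @param config A [low_bin_config()].
#' @return Object of class `low_bin_result`: list with `best_family`,
#'   `k_star`, `sse_by_k`, `histogram` (at `k_star`), `cutoff_bin`
#'   (index or `NA`), `cutoff_value` (left edge of the cutoff bin, or `NA`),
#'   `kept_mask`, `removed_count`, `fit` (pre-removal) and `refit`
#'   (post-removal).
#' @export
low_bin_search <- function(sample, config = low_bin_config()) {
  sample <- as_receptor_sample(sample)
  if (sample$n < 100) {
    stop("low_bin_search needs at least 100 cells; binning is not meaningful below this")
  }
  sel <- select_best_family(sample, k = config$reference_k)
  fam <- sel$family
  opt <- optimal_bin_number(sample, fam, config, fit = sel$fits[[fam]])
  hist <- build_histogram(sample, opt$k_star)
  j <- find_cutoff_bin(hist, config)
  if (is.na(j)) {
    cutoff_value <- NA_real_
    kept_mask <- rep(TRUE, sample$n)
  } else {
    cutoff_value <- hist$edges[j]
    kept_mask <- sample$values < cutoff_value
  }
  kept <- receptor_sample(sample$values[kept_mask],
                          label = paste(sample$label, "(outliers removed)"))
  structure(
    list(best_family = fam, k_star = opt$k_star, sse_by_k = opt$sse_by_k,
         histogram = hist, cutoff_bin = j, cutoff_value = cutoff_value,
         kept_mask = kept_mask, removed_count = sum(!kept_mask),
         fit = opt$fit, refit = fit_mle(kept, fam), kept = kept,
         config = config),
    class = "low_bin_result"
  )
}

#' @export
print.low_bin_result <- function(x, ...) {
  cat(sprintf("low_bin_result: best family %s, k* = %d\n", x$best_family, x$k_star))
  if (is.na(x$cutoff_bin)) {
    cat("  no cutoff bin qualified; 0 cells removed\n")
  } else {
    cat(sprintf("  cutoff bin %d (>= %.4g receptors/cell): %d cells removed\n",
                x$cutoff_bin, x$cutoff_value, x$removed_count))
  }
  invisible(x)
}

#' Baseline outlier rule: three standard deviations above the mean
#'
#' Single-pass rule removing every value above `mean + 3 * SD`, the common
#' default this package's cutoff method is benchmarked against.
#'
#' @param sample A [receptor_sample()] or numeric vector (n >= 2).
#' @return Logical kept-mask, `TRUE` for retained cells.
#' @export
three_sd_outliers <- function(sample) {
  x <- as_receptor_sample(sample)$values
  if (length(x) < 2) stop("need at least 2 values")
  x <= mean(x) + 3 * stats::sd(x)
}

#' Baseline bin-count rules
#'
#' Conventional size-only bin-count rules used by common software packages,
#' implemented as configurable approximations: `matlab_sqrt` is
#' `ceiling(sqrt(n))`, `palisade` is `floor(n^exponent)` with exponent 1/3 by
#' default. Both depend only on n, not on the data shape — the contrast the
#' SSE-optimal search is designed to expose.
#'
#' @param n Sample size (>= 1).
#' @param rule `"matlab_sqrt"` or `"palisade"`.
#' @param exponent Power for the `palisade` rule.
#' @return Integer bin count.
#' @examples
#' baseline_bin_rules(29584, "matlab_sqrt")  # 172
#' @export
baseline_bin_rules <- function(n, rule = c("matlab_sqrt", "palisade"),
                               exponent = 1 / 3) {
  stopifnot(n >= 1)
  rule <- match.arg(rule)
  switch(rule,
    matlab_sqrt = as.integer(ceiling(sqrt(n))),
    palisade    = as.integer(floor(n^exponent))
  )
}

run_bootstrap_trials <- function(sample, sizes, trials, seed, config, protocol) {
  sample <- as_receptor_sample(sample)
  stopifnot(trials >= 1)
  if (any(sizes > sample$n)) stop("requested size exceeds sample size")
  set.seed(seed)
  rows <- list()
  for (size in sizes) {
    for (tr in seq_len(trials)) {
      if (protocol == "subsample") {
        values <- sample$values[sample.int(sample$n, size)]
      } else { # perturb20: inflate `size` distinct cells by 20%, keep all cells
        values <- sample$values
        if (size > 0) {
          idx <- sample.int(sample$n, size)
          values[idx] <- values[idx] * 1.2
        }
      }
      res <- low_bin_search(values, config)
      rows[[length(rows) + 1]] <- data.frame(
        protocol = protocol, size = size, trial = tr,
        cutoff_value = res$cutoff_value,
        geometric_mean = exp(mean(log(res$kept$values)))
      )
    }
  }
  trials_df <- do.call(rbind, rows)
  ranges <- do.call(rbind, lapply(split(trials_df, trials_df$size), function(d) {
    data.frame(size = d$size[1],
               cutoff_range = if (all(is.na(d$cutoff_value))) NA_real_
                              else diff(range(d$cutoff_value, na.rm = TRUE)),
               gm_range = diff(range(d$geometric_mean)))
  }))
  rownames(ranges) <- NULL
  structure(list(protocol = protocol, sizes = sizes, trials = trials_df,
                 ranges = ranges, seed = seed),
            class = "bootstrap_result")
}

#' Bootstrap robustness: random subsampling
#'
#' For each requested size, draws `trials` independent without-replacement
#' subsamples, runs the full low bin search on each and records the cutoff
#' value and the post-removal geometric mean. The spread of these quantities
#' across trials measures how sensitive the procedure is to acquisition
#' size.
#'
#' @param sample A [receptor_sample()] or numeric vector.
#' @param sizes Subsample sizes (each <= n), e.g. `c(1000, 5000, 10000)`.
#' @param trials Trials per size (100 in a full robustness study).
#' @param seed Integer RNG seed.
#' @param config A [low_bin_config()].
#' @return Object of class `bootstrap_result` with per-trial records and
#'   per-size max-minus-min ranges.
#' @export
bootstrap_subsample <- function(sample, sizes, trials = 100, seed = 1,
                                config = low_bin_config()) {
  run_bootstrap_trials(sample, sizes, trials, seed, config, "subsample")
}

#' Bootstrap robustness: 20% value perturbation
#'
#' For each trial, `size` distinct cells are chosen uniformly and their
#' values increased by 20%; low bin search then runs on the perturbed full
#' data set. This emulates calibration error concentrated in a random subset
#' of events.
#'
#' @inheritParams bootstrap_subsample
#' @export
bootstrap_perturb <- function(sample, sizes, trials = 100, seed = 1,
                              config = low_bin_config()) {
  run_bootstrap_trials(sample, sizes, trials, seed, config, "perturb20")
}
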