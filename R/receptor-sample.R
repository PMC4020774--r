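#' Construct a receptor sample
#'
#' A `receptor_sample` holds calibrated per-cell surface receptor counts
#' (receptors/cell) for one channel of one cell population, plus a free-text
#' provenance label. Non-finite and nonpositive values are dropped at
#' construction time and the number of dropped values is recorded: receptor
#' counts are physical (nonnegative) quantities and the geometric mean,
#' lognormal fits and log-scale diagnostics all require strictly positive
#' values.
#'
#' @param values Numeric vector of per-cell receptor counts (receptors/cell).
#' @param label Free-text provenance label (e.g. `"HUVEC VEGFR1"`).
#' @param component Optional integer vector of ground-truth component labels
#'   (same length as `values`), carried by the synthetic mixture generator.
#' @return An object of class `receptor_sample`: a list with elements
#'   `values`, `label`, `n`, `n_dropped` and optionally `component`.
#' @examples
#' s <- receptor_sample(c(100, 250, 980), label = "example")
#' s$n
#' @export
receptor_sample <- function(values, label = "", component = NULL) {
  if (!is.numeric(values)) stop("`values` must be numeric")
  values <- as.numeric(values)
  keep <- is.finite(values) & values > 0
  n_dropped <- sum(!keep)
  if (!is.null(component)) {
    if (length(component) != length(values)) {
      stop("`component` must have the same length as `values`")
    }
    component <- component[keep]
  }
  values <- values[keep]
  if (length(values) == 0L) stop("no positive finite values in `values`")
  out <- list(
    values = values,
    label = as.character(label)[1],
    n = length(values),
    n_dropped = n_dropped,
    component = component
  )
  class(out) <- "receptor_sample"
  out
}

#' @export
print.receptor_sample <- function(x, ...) {
  cat(sprintf(
    "receptor_sample: %d cells%s%s\n",
    x$n,
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    if (x$n_dropped > 0) sprintf(" (%d nonpositive/non-finite dropped)", x$n_dropped) else ""
  ))
  q <- stats::quantile(x$values, c(0, 0.5, 1))
  cat(sprintf("  min %.4g | median %.4g | max %.4g receptors/cell\n",
              q[1], q[2], q[3]))
  invisible(x)
}

as_receptor_sample <- function(x, label = "") {
  if (inherits(x, "receptor_sample")) return(x)
  receptor_sample(x, label = label)
}
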