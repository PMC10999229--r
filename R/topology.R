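# Persistent-homology core: edge-density (or correlation-step) filtration of a
# connectivity matrix, Betti-0 curve via union-find, trapezoidal AUC.
#
# At density epsilon the retained graph consists of the top ceiling(eps * E)
# edges of the descending weight ranking (E = n(n-1)/2 unique pairs; ties are
# broken by node-index order, which matters only on degenerate inputs). The
# cutoff weight W reported for each threshold is the weight of the lowest-
# ranked retained edge; density 0 retains no edges and reports W = +Inf.

# Edge rank retained at a density fraction: ceiling(density * E), guarded
# against floating-point overshoot when density * E is mathematically
# integral (e.g. 0.4 * 15).
rank_at_density <- function(density, n_edges) {
  max(1L, min(n_edges, as.integer(ceiling(density * n_edges - 1e-9))))
}

#' Cutoff weight at an edge-density threshold
#'
#' Returns the edge weight `W` attained at a given edge density: the weight of
#' rank `ceiling(density * E)` when the `E = n(n-1)/2` unique edges are sorted
#' in descending order. Density 0 returns `Inf` (no edges retained).
#'
#' @param m symmetric connectivity matrix.
#' @param density edge-density fraction in `[0, 1]`.
#' @return The cutoff weight on the Fisher-z scale.
#' @export
cutoff_weight <- function(m, density) {
  check_square_symmetric(m)
  if (!is.numeric(density) || length(density) != 1L || is.na(density) ||
      density < 0 || density > 1)
    stop("invalid parameter: density must be a single value in [0, 1]")
  if (density == 0) return(Inf)
  se <- sorted_edges(m)
  se$w[rank_at_density(density, length(se$w))]
}

#' Betti-0 number at an edge-density threshold
#'
#' Counts the connected components of the graph retaining the top
#' `ceiling(density * E)` edges of the descending weight ranking; isolated
#' nodes count as components. Uses union-find with path compression.
#'
#' @inheritParams cutoff_weight
#' @return Integer component count.
#' @export
betti0_at <- function(m, density) {
  check_square_symmetric(m)
  if (!is.numeric(density) || length(density) != 1L || is.na(density) ||
      density < 0 || density > 1)
    stop("invalid parameter: density must be a single value in [0, 1]")
  se <- sorted_edges(m)
  k <- if (density == 0) 0L else rank_at_density(density, length(se$w))
  uf_component_counts(se$i, se$j, se$n, k)
}

#' Betti-0 curve under edge-density (or correlation) filtration
#'
#' Sweeps the filtration from the empty graph to the first threshold at which
#' a single connected component forms, recording the component count at each
#' step. In `"density"` mode thresholds are edge-density fractions on the grid
#' `0, step, 2*step, ...`; negative-weight edges enter the retained set only
#' if a single component has not yet formed by the time their rank is reached.
#' In `"correlation"` mode thresholds are descending correlation cutoffs
#' (1, 1 - step, ...) stored against `1 - r` so thresholds ascend; edges with
#' Fisher-z weight above `atanh(r)` are retained.
#'
#' If a single component never forms the curve ends at the last grid point and
#' the `truncated` flag is set.
#'
#' @inheritParams cutoff_weight
#' @param step filtration step in `(0, 1]` (default 0.01, i.e. one percentile
#'   of the edge-weight distribution per step).
#' @param mode `"density"` (primary) or `"correlation"` (variant).
#' @return An object of class `betti_curve`: a list with `thresholds`,
#'   `cutoff_weights`, `b0`, `mode`, `n_nodes`, `truncated`.
#' @examples
#' set.seed(1)
#' z <- correlation_matrix(matrix(rnorm(20 * 80), nrow = 20))
#' bc <- betti0_curve(z)
#' auc(bc)
#' @export
betti0_curve <- function(m, step = 0.01, mode = c("density", "correlation")) {
  check_square_symmetric(m)
  mode <- match.arg(mode)
  if (!is.numeric(step) || length(step) != 1L || is.na(step) ||
      step <= 0 || step > 1)
    stop("invalid parameter: step must be in (0, 1]")
  se <- sorted_edges(m)
  E <- length(se$w)
  n <- se$n

  if (mode == "density") {
    grid <- seq(0, 1, by = step)
    if (grid[length(grid)] < 1) grid <- c(grid, 1)
    ks <- vapply(grid, rank_at_density, integer(1), n_edges = E)
    ks[grid == 0] <- 0L
    cutoffs <- c(Inf, se$w[ks[-1L]])
  } else {
    # descending r-cutoffs 1, 1-step, ..., mapped to ascending 1-r
    r_grid <- seq(1, -1, by = -step)
    if (r_grid[length(r_grid)] > -1) r_grid <- c(r_grid, -1)
    grid <- 1 - r_grid
    cutoffs <- atanh(pmin(pmax(r_grid, -(1 - 1e-7)), 1 - 1e-7))
    ks <- vapply(cutoffs, function(w) sum(se$w > w), integer(1L))
    ks[1L] <- 0L
  }

  b0 <- uf_component_counts(se$i, se$j, n, ks)
  stop_at <- match(1L, b0)
  truncated <- is.na(stop_at)
  if (truncated) stop_at <- length(b0)

  structure(list(
    thresholds = grid[seq_len(stop_at)],
    cutoff_weights = cutoffs[seq_len(stop_at)],
    b0 = b0[seq_len(stop_at)],
    mode = mode,
    step = step,
    n_nodes = n,
    truncated = truncated
  ), class = "betti_curve")
}

#' Area under a Betti-0 curve
#'
#' Trapezoidal integral of the component count against the filtration value,
#' from the first threshold to the threshold at which the count first reaches
#' 1 (the whole stored curve, since [betti0_curve()] stops there). Lower
#' values mean the network merges into a single component faster.
#'
#' @param curve a `betti_curve` object, or any list with numeric `thresholds`
#'   and `b0` of equal length.
#' @return The AUC in component-count-times-threshold units.
#' @export
auc <- function(curve) {
  x <- curve$thresholds
  y <- curve$b0
  if (length(x) < 2L)
    stop("degenerate curve: need at least 2 points to integrate")
  if (length(x) != length(y))
    stop("thresholds and b0 differ in length")
  sum(diff(x) * (head(y, -1L) + y[-1L]) / 2)
}

#' @export
print.betti_curve <- function(x, ...) {
  cat("Betti-0 curve (", x$mode, " filtration, step ", x$step, ")\n", sep = "")
  cat("  nodes:", x$n_nodes, "\n")
  cat("  thresholds:", length(x$thresholds),
      sprintf("(%.3g .. %.3g)", x$thresholds[1L],
              x$thresholds[length(x$thresholds)]), "\n")
  cat("  B0:", x$b0[1L], "->", x$b0[length(x$b0)],
      if (x$truncated) "(truncated: single component never formed)" else "",
      "\n")
  cat("  AUC:", format(auc(x), digits = 6), "\n")
  invisible(x)
}

#' @export
plot.betti_curve <- function(x, ...) {
  plot(x$thresholds, x$b0, type = "s",
       xlab = if (x$mode == "density") "edge density" else "1 - r",
       ylab = expression(B[0]), ...)
  invisible(x)
}

#' @export
as.data.frame.betti_curve <- function(x, ...) {
  data.frame(mode = x$mode, threshold = x$thresholds,
             cutoff_weight = x$cutoff_weights, b0 = x$b0)
}
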