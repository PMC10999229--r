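# Fisher-z connectivity matrices from node time series, plus the edge-sign
# conventions used downstream (positive-part for segregation/modularity) and
# the split-sample helper for time-series halves.

#' Build a Fisher-z connectivity matrix from node time series
#'
#' Computes Pearson correlations between all node pairs of a node-by-time
#' matrix and applies the Fisher z-transformation `z = atanh(r)`. Correlations
#' are clipped to `1 - clip_eps` in absolute value before the transform so the
#' result is always finite. The diagonal is set to zero and is excluded from
#' all downstream computations (filtration, segregation, modularity).
#'
#' @param ts numeric node-by-time matrix; rownames, if present, are kept as
#'   node ids.
#' @param clip_eps positive clipping margin applied to `|r|` before `atanh`.
#' @return A symmetric numeric matrix of Fisher-z weights with zero diagonal.
#' @examples
#' ts <- matrix(rnorm(5 * 100), nrow = 5)
#' z <- correlation_matrix(ts)
#' n_pairs(z)  # 10
#' @export
correlation_matrix <- function(ts, clip_eps = 1e-7) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3L)
    stop("insufficient data: need at least 3 time samples, got ", ncol(ts))
  sds <- apply(ts, 1L, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    ids <- if (!is.null(rownames(ts))) rownames(ts)[bad] else bad
    stop("degenerate input: constant time series for node(s) ",
         paste(ids, collapse = ", "))
  }
  r <- cor(t(ts))
  r <- pmin(pmax(r, -(1 - clip_eps)), 1 - clip_eps)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2   # enforce exact symmetry
  if (is.null(rownames(ts))) {
    dimnames(z) <- list(paste0("n", seq_len(nrow(ts))),
                        paste0("n", seq_len(nrow(ts))))
  } else {
    dimnames(z) <- list(rownames(ts), rownames(ts))
  }
  z
}

#' Zero the negative edges of a connectivity matrix
#'
#' Sets all negative weights to 0, the convention used before computing
#' system segregation and modularity Q. Idempotent; symmetry is preserved.
#'
#' @param m symmetric connectivity matrix.
#' @return The matrix with negative entries replaced by 0.
#' @export
positive_part <- function(m) {
  check_square_symmetric(m)
  m[m < 0] <- 0
  m
}

#' Split a time series into contiguous segments
#'
#' Divides a node-by-time matrix into `n_segments` contiguous, non-overlapping
#' segments covering all samples in order. When the length is not divisible,
#' earlier segments receive the extra samples.
#'
#' @param ts node-by-time matrix.
#' @param n_segments number of segments (default 2, the split-sample check).
#' @return A list of node-by-time matrices.
#' @export
split_timeseries <- function(ts, n_segments = 2L) {
  ts <- as.matrix(ts)
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) stop("invalid parameter: n_segments must be >= 1")
  L <- ncol(ts)
  if (L < 3L * n_segments)
    stop("insufficient data: series of length ", L,
         " cannot be split into ", n_segments, " segments of >= 3 samples")
  base <- L %/% n_segments
  rem <- L %% n_segments
  sizes <- base + as.integer(seq_len(n_segments) <= rem)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(n_segments), function(s) ts[, starts[s]:ends[s], drop = FALSE])
}

# -- internal helpers ---------------------------------------------------------

check_square_symmetric <- function(m, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("expected a square matrix")
  if (max(abs(m - t(m))) > tol)
    stop("matrix is not symmetric within tolerance ", tol)
  invisible(m)
}

#' Number of unique off-diagonal node pairs
#'
#' @param m square connectivity matrix.
#' @return `n * (n - 1) / 2` for an n-node matrix.
#' @export
n_pairs <- function(m) {
  n <- nrow(m)
  n * (n - 1L) / 2L
}

# Upper-triangle edge list sorted by descending weight; ties broken by node
# index order (i, then j) for determinism.
sorted_edges <- function(m) {
  n <- nrow(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[upper.tri(m)]
  o <- order(-w, idx[, 1L], idx[, 2L])
  list(i = idx[o, 1L], j = idx[o, 2L], w = w[o], n = n)
}
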