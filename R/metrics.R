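# Graph-theoretic comparators for the topological AUC: whole-brain system
# segregation on a node-to-network partition, and Newman modularity Q from a
# deterministic maximization (leading-eigenvector bisection with
# Kernighan-Lin-style refinement), both on the positive-edge matrix.

#' Whole-brain system segregation
#'
#' Computes `(mean within-network connectivity - mean between-network
#' connectivity) / mean within-network connectivity` over the Fisher-z matrix
#' with negative edges set to zero (apply [positive_part()] first). By default
#' the zeroed edges stay in the means, i.e. the means run over all `W`
#' within-network and `B` between-network node pairs; `include_zeros = FALSE`
#' restricts the means to strictly positive edges.
#'
#' @param m symmetric connectivity matrix with no negative entries.
#' @param partition node-to-network assignment: a vector of network labels,
#'   one per node, optionally named by node id (names must then match the
#'   matrix dimnames).
#' @param include_zeros logical; keep zeroed edges in the means (default TRUE).
#' @return A list of class `segregation_result` with `mean_within`,
#'   `mean_between`, `segregation`, `n_within`, `n_between`.
#' @examples
#' m <- matrix(0.2, 6, 6); m[1:3, 1:3] <- 0.6; m[4:6, 4:6] <- 0.6; diag(m) <- 0
#' system_segregation(m, rep(c("A", "B"), each = 3))$segregation  # 0.6667
#' @export
system_segregation <- function(m, partition, include_zeros = TRUE) {
  check_square_symmetric(m)
  if (any(m < 0))
    stop("matrix has negative entries; apply positive_part() first")
  partition <- align_partition(partition, m)
  if (length(unique(partition)) < 2L)
    stop("partition must contain at least 2 networks")
  ut <- upper.tri(m)
  same <- outer(partition, partition, "==")[ut]
  w <- m[ut]
  keep <- if (include_zeros) rep(TRUE, length(w)) else w > 0
  win <- w[same & keep]
  btw <- w[!same & keep]
  mean_within <- mean(win)
  mean_between <- mean(btw)
  if (!is.finite(mean_within) || mean_within <= 0)
    stop("undefined segregation: mean within-network connectivity is not positive")
  structure(list(
    mean_within = mean_within,
    mean_between = mean_between,
    segregation = (mean_within - mean_between) / mean_within,
    n_within = length(win),
    n_between = length(btw)
  ), class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf(
    "System segregation: %.4f (mean within %.4f over %d edges, mean between %.4f over %d edges)\n",
    x$segregation, x$mean_within, x$n_within, x$mean_between, x$n_between))
  invisible(x)
}

align_partition <- function(partition, m) {
  n <- nrow(m)
  if (length(partition) != n) {
    if (!is.null(names(partition)) && !is.null(rownames(m)) &&
        all(rownames(m) %in% names(partition))) {
      partition <- partition[rownames(m)]
    } else {
      stop("partition covers ", length(partition), " nodes but matrix has ", n)
    }
  } else if (!is.null(names(partition)) && !is.null(rownames(m))) {
    if (!all(rownames(m) %in% names(partition)))
      stop("partition is missing node(s): ",
           paste(setdiff(rownames(m), names(partition)), collapse = ", "))
    partition <- partition[rownames(m)]
  }
  as.character(partition)
}

#' Modularity Q of a given partition
#'
#' Newman's weighted modularity
#' `Q = sum_c [ w_c / m2 - (d_c / m2)^2 ]` where `w_c` is twice the total
#' within-community weight (counting both matrix triangles), `d_c` the total
#' degree (strength) of community `c`, and `m2` the total weight over both
#' triangles. Q is 0 for the trivial single-community partition.
#'
#' @param m symmetric non-negative weight matrix (zero diagonal).
#' @param membership community label per node.
#' @return Numeric Q.
#' @export
modularity_value <- function(m, membership) {
  check_square_symmetric(m)
  membership <- as.character(membership)
  if (length(membership) != nrow(m))
    stop("membership length does not match matrix size")
  A <- m
  diag(A) <- 0
  m2 <- sum(A)
  if (m2 <= 0) stop("undefined modularity: matrix has no positive edges")
  k <- rowSums(A)
  q <- 0
  for (cc in unique(membership)) {
    idx <- membership == cc
    q <- q + sum(A[idx, idx]) / m2 - (sum(k[idx]) / m2)^2
  }
  q
}

#' Deterministic modularity maximization
#'
#' Maximizes Newman's weighted modularity by recursive leading-eigenvector
#' bisection of the (generalized) modularity matrix, with Kernighan-Lin-style
#' fine tuning after each split and a final greedy refinement pass (single-node
#' moves and community merges) with fixed node-order tie-breaking. Every step
#' is deterministic, so repeated calls on the same matrix return an identical
#' `(q, membership)` pair. The detected communities are agnostic to any a
#' priori network partition.
#'
#' @param m symmetric connectivity matrix with negative edges already zeroed
#'   (apply [positive_part()] first) and at least one positive edge.
#' @return A list of class `modularity_result` with `q`, `membership`
#'   (integer labels 1..k in order of first appearance), `n_communities`.
#' @examples
#' m <- matrix(0, 8, 8); m[1:4, 1:4] <- 1; m[5:8, 5:8] <- 1; diag(m) <- 0
#' modularity_q(m)$q  # 0.5
#' @export
modularity_q <- function(m) {
  check_square_symmetric(m)
  if (any(m < 0))
    stop("matrix has negative entries; apply positive_part() first")
  A <- m
  diag(A) <- 0
  n <- nrow(A)
  m2 <- sum(A)
  if (m2 <= 0) stop("undefined modularity: matrix has no positive edges")
  k <- rowSums(A)
  B <- A - outer(k, k) / m2   # modularity matrix

  spectral <- local({
    membership <- integer(n)
    next_label <- 1L
    divide <- function(nodes) {
      s <- bisect_group(B, nodes)
      if (is.null(s)) {
        membership[nodes] <<- next_label
        next_label <<- next_label + 1L
        return(invisible(NULL))
      }
      divide(nodes[s > 0])
      divide(nodes[s < 0])
    }
    divide(seq_len(n))
    membership
  })

  # two deterministic starting partitions -- recursive spectral bisection and
  # greedy agglomerative merging -- each polished by the same refinement; the
  # better final Q wins (ties go to the spectral start)
  polish <- function(membership) {
    repeat {
      membership <- refine_membership(A, k, m2, membership)
      q_now <- modularity_value(m, membership)
      changed <- FALSE
      for (lab in unique(membership)) {
        nodes <- which(membership == lab)
        s <- bisect_group(B, nodes)
        if (is.null(s)) next
        cand <- membership
        cand[nodes[s < 0]] <- max(membership) + 1L
        if (modularity_value(m, cand) > q_now + 1e-12) {
          membership <- cand
          q_now <- modularity_value(m, cand)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    membership
  }
  # vector-partition starts: sign patterns of the leading eigenvectors of B
  ev <- eigen(B, symmetric = TRUE)
  eig_start <- function(nv) {
    U <- ev$vectors[, seq_len(min(nv, n)), drop = FALSE]
    key <- apply(U >= 0, 1L, paste, collapse = "")
    match(key, unique(key))
  }
  starts <- list(spectral, agglomerate(A, k, m2), eig_start(2L), eig_start(3L))
  cands <- lapply(starts, polish)
  qvals <- vapply(cands, function(mm) modularity_value(m, mm), numeric(1))
  membership <- cands[[which.max(qvals)]]   # ties -> earliest start
  membership <- match(membership, unique(membership))
  structure(list(
    q = modularity_value(m, membership),
    membership = membership,
    n_communities = length(unique(membership))
  ), class = "modularity_result")
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf("Modularity Q = %.4f over %d communities\n",
              x$q, x$n_communities))
  invisible(x)
}

# Attempt to split `nodes` in two using the leading eigenvector of the
# generalized modularity matrix, followed by KL-style fine tuning. Returns a
# +/-1 vector over `nodes`, or NULL if the group is indivisible.
bisect_group <- function(B, nodes) {
  ng <- length(nodes)
  if (ng < 2L) return(NULL)
  Bg <- B[nodes, nodes, drop = FALSE]
  diag(Bg) <- diag(Bg) - rowSums(Bg)
  ev <- eigen((Bg + t(Bg)) / 2, symmetric = TRUE)
  u <- ev$vectors[, 1L]
  if (ev$values[1L] <= 1e-12) return(NULL)
  s <- ifelse(u >= 0, 1, -1)

  # Kernighan-Lin fine tuning: full passes flipping each node once, keeping
  # the best configuration seen; repeat while the pass improves dQ. Flip
  # gains are maintained incrementally: flipping v changes s'Bs by
  # -4 s_v (Bs)_v + 4 B_vv.
  Bg <- (Bg + t(Bg)) / 2
  best <- s
  best_val <- drop(s %*% Bg %*% s)
  repeat {
    sv <- best
    val <- best_val
    Bs <- drop(Bg %*% sv)
    moved <- rep(FALSE, ng)
    pass_best <- best_val; pass_best_sv <- best
    for (step in seq_len(ng)) {
      gains <- -4 * sv * Bs + 4 * diag(Bg)
      gains[moved] <- -Inf
      v <- which.max(gains)
      val <- val + gains[v]
      Bs <- Bs - 2 * sv[v] * Bg[, v]
      sv[v] <- -sv[v]; moved[v] <- TRUE
      if (val > pass_best + 1e-12) {
        pass_best <- val; pass_best_sv <- sv
      }
    }
    if (pass_best > best_val + 1e-12) {
      best <- pass_best_sv; best_val <- pass_best
    } else break
  }
  if (best_val <= 1e-12 || all(best > 0) || all(best < 0)) return(NULL)
  best
}

# Deterministic Kernighan-Lin-style refinement of a full partition. Each
# pass tentatively moves every node exactly once to its best alternative
# community (or a new singleton), allowing downhill moves, and keeps the best
# prefix of the move sequence; passes repeat while they improve Q. A merge
# pass over community pairs follows. All gains are on the scale 2/m2 * Q, so
# comparisons are equivalent to comparing Q; ties break to the lowest node
# and community index via which.max.
refine_membership <- function(A, k, m2, membership) {
  n <- nrow(A)
  q_of <- function(mem) {
    q <- 0
    for (cc in unique(mem)) {
      idx <- mem == cc
      q <- q + sum(A[idx, idx]) / m2 - (sum(k[idx]) / m2)^2
    }
    q
  }
  repeat {
    improved <- FALSE
    # KL passes; acceptance is anchored to the recomputed Q, not the
    # incrementally accumulated gains, so floating-point drift cannot loop
    repeat {
      q_before <- q_of(membership)
      labs <- sort(unique(membership))
      cur <- match(membership, labs)
      K <- length(labs)
      ind <- matrix(0, n, K); ind[cbind(seq_len(n), cur)] <- 1
      s_to <- A %*% ind                       # strength of v to each community
      d_com <- as.numeric(crossprod(ind, k))  # community total strengths
      moved <- rep(FALSE, n)
      gain_cum <- 0
      best_gain <- 0
      best_state <- cur
      for (step in seq_len(n)) {
        # vectorized best-move search over all unmoved nodes
        base <- s_to[cbind(seq_len(n), cur)] -
          k * (d_com[cur] - k) / m2
        P <- s_to - outer(k, d_com) / m2
        P[cbind(seq_len(n), cur)] <- -Inf
        tg <- max.col(P, ties.method = "first")
        gv <- P[cbind(seq_len(n), tg)] - base
        single <- -base > gv          # moving to a new singleton is better
        gv[single] <- -base[single]
        tg[single] <- 0L
        gv[moved] <- -Inf
        v <- which.max(gv)
        best_g <- gv[v]; best_t <- tg[v]
        ci <- cur[v]
        if (best_t == 0L) {                   # open a new community column
          s_to <- cbind(s_to, A[, v])
          d_com <- c(d_com, 0)
          best_t <- ncol(s_to)
        }
        s_to[, ci] <- s_to[, ci] - A[, v]
        s_to[, best_t] <- s_to[, best_t] + A[, v]
        d_com[ci] <- d_com[ci] - k[v]
        d_com[best_t] <- d_com[best_t] + k[v]
        cur[v] <- as.integer(best_t)
        moved[v] <- TRUE
        gain_cum <- gain_cum + best_g
        if (gain_cum > best_gain + 1e-12) {
          best_gain <- gain_cum
          best_state <- cur
        }
      }
      if (best_gain > 1e-12 && q_of(best_state) > q_before + 1e-12) {
        membership <- best_state
        improved <- TRUE
      } else break
    }
    # merge pass
    labs <- sort(unique(membership))
    if (length(labs) > 1L) {
      for (a in seq_along(labs)) {
        for (b in seq_along(labs)) {
          if (b <= a) next
          ia <- membership == labs[a]; ib <- membership == labs[b]
          if (!any(ia) || !any(ib)) next
          gain <- 2 * sum(A[ia, ib]) / m2 -
            2 * sum(k[ia]) * sum(k[ib]) / m2^2
          if (gain > 1e-12) {
            membership[ib] <- labs[a]
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  membership
}

# Greedy agglomerative start: from the all-singletons partition, repeatedly
# merge the community pair with the largest modularity gain while any gain is
# positive. Deterministic (which.max tie-breaks to the first index).
agglomerate <- function(A, k, m2) {
  n <- nrow(A)
  W <- A            # community-pair total weights (both triangles)
  diag(W) <- 0
  d <- k
  alive <- rep(TRUE, n)
  membership <- seq_len(n)
  repeat {
    G <- 2 * W / m2 - 2 * outer(d, d) / m2^2
    G[!alive, ] <- -Inf
    G[, !alive] <- -Inf
    diag(G) <- -Inf
    best <- which.max(G)
    if (G[best] <= 1e-12) break
    b <- (best - 1L) %/% n + 1L
    a <- (best - 1L) %% n + 1L
    membership[membership == b] <- a
    W[a, ] <- W[a, ] + W[b, ]
    W[, a] <- W[, a] + W[, b]
    W[a, a] <- W[a, a] + 2 * W[b, b]
    d[a] <- d[a] + d[b]
    alive[b] <- FALSE
  }
  membership
}
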