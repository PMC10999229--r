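# Edge-density filtration, Betti-0 curves and trapezoidal AUC.

test_that("cutoff_weight follows the descending edge ranking", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- c(0.9, 0.7, 0.5, 0.3, 0.2, 0.1)
  m <- m + t(m)
  E <- 6
  expect_equal(cutoff_weight(m, 1), 0.1)            # minimum off-diagonal
  expect_equal(cutoff_weight(m, 2 / E), 0.7)        # rank-2 weight
  expect_equal(cutoff_weight(m, 0.25), 0.7)         # ceiling(0.25 * 6) = 2
  expect_identical(cutoff_weight(m, 0), Inf)        # no edges retained
  expect_error(cutoff_weight(m, 1.2), "invalid parameter")
  expect_error(cutoff_weight(m, -0.1), "invalid parameter")
})

test_that("betti0_at equals BFS component counts on random matrices", {
  for (trial in 1:25) {
    n <- sample(20:40, 1)
    z <- random_z_matrix(n, seed = 7000 + trial)
    E <- n * (n - 1) / 2
    for (d in c(0, 0.02, 0.05, 0.1, 0.3, 0.7, 1)) {
      k <- if (d == 0) 0L else max(1, ceiling(d * E - 1e-9))
      expect_equal(betti0_at(z, d), bfs_components_topk(z, k),
                   info = sprintf("trial %d density %.2f", trial, d))
    }
  }
})

test_that("the full graph at density 0 has one component per node", {
  z <- random_z_matrix(264, seed = 77, len = 30)
  expect_equal(betti0_at(z, 0), 264)
})

test_that("a weak bridge between two triangles produces the expected plateau", {
  # two triangles of strong edges joined by one weak bridge: the curve stays
  # at 2 components until the bridge's density rank (7th of 15), then drops
  m <- matrix(0, 6, 6)
  strong <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  for (r in seq_len(nrow(strong))) {
    m[strong[r, 1], strong[r, 2]] <- 1 - 0.01 * r
    m[strong[r, 2], strong[r, 1]] <- 1 - 0.01 * r
  }
  m[3, 4] <- m[4, 3] <- 0.5   # bridge, rank 7
  bc <- betti0_curve(m, step = 1 / 15)   # one edge per step
  expect_equal(bc$b0[1], 6)
  expect_equal(bc$b0[length(bc$b0)], 1)
  # after 6 edges both triangles are complete: exactly 2 components
  expect_equal(betti0_at(m, 6 / 15), 2)
  expect_equal(betti0_at(m, 7 / 15), 1)
  # BFS oracle agrees along the whole grid
  for (k in 1:15)
    expect_equal(betti0_at(m, k / 15), bfs_components_topk(m, k))
})

test_that("curves are non-increasing, start at n, and end at 1", {
  for (trial in 1:20) {
    n <- sample(15:30, 1)
    z <- random_z_matrix(n, seed = 7100 + trial)
    bc <- betti0_curve(z)
    expect_equal(bc$b0[1], n)
    expect_true(all(diff(bc$b0) <= 0))
    expect_false(bc$truncated)
    expect_equal(bc$b0[length(bc$b0)], 1)
    expect_equal(length(bc$thresholds), length(bc$b0))
    expect_equal(length(bc$cutoff_weights), length(bc$b0))
    expect_true(all(diff(bc$thresholds) > 0))
  }
})

test_that("density-mode curves are invariant to rank-preserving weight transforms", {
  z <- random_z_matrix(25, seed = 7201)
  r <- tanh(z)                    # raw correlations: same ranking
  shifted <- z + 5                # constant shift: same ranking
  bc_z <- betti0_curve(z)
  expect_equal(bc_z$b0, betti0_curve(r)$b0)
  expect_equal(bc_z$b0, betti0_curve(shifted)$b0)
  expect_equal(auc(bc_z), auc(betti0_curve(r)))
  # correlation mode is not shift invariant (documented asymmetry)
  cc1 <- betti0_curve(tanh(z) * 0.5, mode = "correlation")
  cc2 <- betti0_curve(tanh(z) * 0.9, mode = "correlation")
  expect_false(identical(cc1$b0, cc2$b0))
})

test_that("AUC matches hand trapezoids and degenerate curves error", {
  fix <- list(thresholds = c(0, 0.01, 0.02), b0 = c(5, 3, 1))
  expect_equal(auc(fix), 0.06)
  n <- 40
  two <- list(thresholds = c(0, 0.01), b0 = c(n, 1))
  expect_equal(auc(two), 0.01 * (n + 1) / 2)
  # constant height c over width d integrates to c * d
  flat <- list(thresholds = seq(0, 0.1, by = 0.02), b0 = rep(3, 6))
  expect_equal(auc(flat), 3 * 0.1)
  expect_error(auc(list(thresholds = 0, b0 = 5)), "degenerate curve")
})

test_that("raising one edge weight cannot increase AUC under correlation filtration", {
  # under a correlation cutoff the retained edge set can only gain the
  # promoted edge, so the component count is pointwise dominated and the AUC
  # cannot grow (under density filtration the promoted edge displaces the
  # previous rank-k edge and no such dominance holds)
  for (trial in 1:10) {
    z <- random_z_matrix(15, seed = 7300 + trial)
    r <- tanh(z)
    base_auc <- auc(betti0_curve(r, mode = "correlation"))
    ut <- which(upper.tri(r), arr.ind = TRUE)
    w <- r[upper.tri(r)]
    pick <- ut[which.min(w), ]
    r2 <- r
    r2[pick[1], pick[2]] <- r2[pick[2], pick[1]] <- max(w) + 0.05
    expect_lte(auc(betti0_curve(r2, mode = "correlation")), base_auc + 1e-12)
  }
})

test_that("stronger within-community coupling yields higher mean AUC", {
  part <- simulate_partition(20, 4)
  mean_auc <- function(w, seeds) {
    cfg <- sim_config(n_participants = 2, n_nodes = 20, n_networks = 4,
                      series_length = 150, within_coupling = w,
                      between_coupling = 0.1, domains = "fluid")
    mean(vapply(seeds, function(s) {
      ts <- simulate_timeseries(part, cfg, "bl", seed = s)
      auc(betti0_curve(correlation_matrix(ts)))
    }, numeric(1)))
  }
  seeds <- 1:12
  expect_gt(mean_auc(0.8, seeds), mean_auc(0.3, seeds))
})
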