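# Behavior standardization, residualization, OLS reporting, FDR, permutation,
# mediation, BIC search.

test_that("standardize_behavior anchors to baseline statistics and inverts speed", {
  set.seed(201)
  bl <- rnorm(50, 100, 15)
  z_bl <- standardize_behavior(bl, mean(bl), sd(bl))
  expect_equal(mean(z_bl), 0, tolerance = 1e-12)
  expect_equal(sd(z_bl), 1, tolerance = 1e-12)
  # speed: a reaction time below the baseline mean is a positive z
  expect_gt(standardize_behavior(90, 100, 15, is_speed = TRUE), 0)
  # follow-up standardized with baseline stats keeps its shift
  fu <- bl + 5
  z_fu <- standardize_behavior(fu, mean(bl), sd(bl))
  expect_equal(mean(z_fu), 5 / sd(bl), tolerance = 1e-12)
  expect_error(standardize_behavior(bl, 0, 0), "degenerate scale")
})

test_that("residualize_on_baseline reproduces hand OLS and its limits", {
  # 3-point fixture by hand: baseline (1,2,3), change (2,2,5)
  expect_equal(residualize_on_baseline(c(2, 2, 5), c(1, 2, 3)),
               c(0.5, -1, 0.5), tolerance = 1e-12)
  # perfect linear dependence leaves nothing
  b <- c(1, 4, 2, 7)
  expect_equal(residualize_on_baseline(2 * b, b), rep(0, 4),
               tolerance = 1e-12)
  # orthogonal change is just centered
  set.seed(202)
  base <- rnorm(40)
  ch <- rnorm(40)
  ch_orth <- resid(lm(ch ~ base)) + 3      # orthogonal to base by design
  expect_equal(residualize_on_baseline(ch_orth, base),
               unname(ch_orth - mean(ch_orth)), tolerance = 1e-10)
  expect_warning(out <- residualize_on_baseline(c(1, 2, 3), c(5, 5, 5)),
                 "constant baseline")
  expect_equal(out, c(-1, 0, 1))
  # NA propagation with listwise fitting
  with_na <- residualize_on_baseline(c(2, NA, 5, 3), c(1, 2, 3, 1.5))
  expect_true(is.na(with_na[2]) && !anyNA(with_na[-2]))
})

test_that("remove_scrubbing fully removes planted linear contamination", {
  set.seed(203)
  scrub <- runif(80, 0.02, 0.3)
  clean <- rnorm(80)
  contaminated <- clean + 4 * scrub
  adj <- remove_scrubbing(contaminated, scrub)
  expect_lt(abs(cor(adj, scrub)), 1e-10)
})

test_that("fit_model matches the normal-equations oracle on a fixed fixture", {
  # 10-row fixture; expected values from the closed-form OLS solution
  x1 <- c(0.2, 1.5, -0.3, 0.8, 2.1, -1.2, 0.5, 1.9, -0.7, 0.1)
  x2 <- c(1.0, 0.4, -0.9, 1.3, 0.2, -0.5, 2.0, -1.1, 0.6, 0.9)
  y <- c(1.1, 2.4, -1.5, 2.2, 3.0, -2.6, 2.3, 1.8, -0.9, 0.8)
  X <- cbind(1, x1, x2)
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)      # independent oracle
  fm <- fit_model(y, data.frame(x1 = x1, x2 = x2))
  expect_equal(fm$coefficients$estimate, beta_hat[2:3], tolerance = 1e-10)
  expect_equal(fm$coefficients$beta_std,
               beta_hat[2:3] * c(sd(x1), sd(x2)) / sd(y), tolerance = 1e-10)
  # partial eta-squared from the t statistics
  rss <- sum((y - X %*% beta_hat)^2)
  sigma2 <- rss / (10 - 3)
  se <- sqrt(diag(solve(t(X) %*% X)) * sigma2)[2:3]
  tv <- beta_hat[2:3] / se
  expect_equal(fm$coefficients$eta_p2, unname(tv^2 / (tv^2 + 7)),
               tolerance = 1e-10)
  expect_equal(fm$coefficients$ci_low,
               unname(beta_hat[2:3] - qt(0.975, 7) * se), tolerance = 1e-10)
  expect_true(all(fm$coefficients$eta_p2 >= 0 & fm$coefficients$eta_p2 <= 1))
})

test_that("fit_model limits: near-perfect fit and collinearity", {
  set.seed(204)
  x <- rnorm(100)
  y <- x + rnorm(100, 0, 1e-4)
  fm <- fit_model(y, data.frame(x = x))
  expect_equal(fm$coefficients$beta_std, 1, tolerance = 1e-3)
  expect_gt(fm$coefficients$eta_p2, 0.999)
  expect_error(fit_model(y, data.frame(a = x, b = 2 * x)), "collinearity.*b")
  expect_error(fit_model(y[1:3], data.frame(a = x[1:3], b = rnorm(3), c = rnorm(3))),
               "insufficient data")
})

test_that("fdr_family reproduces the BH step-up and its invariants", {
  expect_equal(fdr_family(0.03)$adjusted, 0.03)
  expect_equal(fdr_family(c(0.01, 0.02, 0.03, 0.04))$adjusted, rep(0.04, 4))
  expect_error(fdr_family(c(0.5, 1.2)), "invalid input")
  set.seed(205)
  p <- runif(78)
  fam <- fdr_family(p, q = 0.05)
  expect_true(all(fam$adjusted >= p))
  # adjusted values are monotone in the raw ranks
  o <- order(p)
  expect_true(all(diff(fam$adjusted[o]) >= -1e-15))
  # corrected rejections never exceed uncorrected ones
  expect_lte(sum(fam$reject), sum(p < 0.05))
})

test_that("permutation test separates planted effects, is seeded, and supports +1 correction", {
  set.seed(206)
  n <- 150
  x <- rnorm(n)
  covs <- data.frame(x = x, z = rnorm(n))
  y <- 0.8 * x + rnorm(n, 0, sqrt(1 - 0.8^2))
  pt1 <- permutation_test(y, covs, "x", n_perm = 1000, seed = 3)
  expect_equal(pt1$p, 0)
  pt2 <- permutation_test(y, covs, "x", n_perm = 1000, seed = 3)
  expect_identical(pt1$p, pt2$p)
  expect_identical(pt1$null, pt2$null)
  pt3 <- permutation_test(y, covs, "x", n_perm = 1000, seed = 3,
                          plus_one = TRUE)
  expect_equal(pt3$p, 1 / 1001)
  expect_error(permutation_test(y, covs, "x", n_perm = 0), "invalid parameter")
  expect_error(permutation_test(y, covs, "nope"), "not found")
})

test_that("null permutation p-values are approximately uniform", {
  ps <- vapply(1:60, function(s) {
    set.seed(900 + s)
    n <- 40
    preds <- data.frame(a = rnorm(n), b = rnorm(n))
    y <- rnorm(n)
    permutation_test(y, preds, "a", n_perm = 200, seed = s)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("mediation recovers the product-of-coefficients truth and its identity", {
  set.seed(207)
  n <- 2000
  x <- rnorm(n)
  m <- -0.5 * x + rnorm(n)
  y <- -0.1 * x + 0.4 * m + rnorm(n)
  med <- mediation_bootstrap(x, m, y, n_boot = 400, seed = 8)
  expect_lt(abs(med$acme - (-0.2)), 0.03)
  # exact OLS identity on the point estimates
  expect_equal(med$total, med$direct + med$acme, tolerance = 1e-10)
  expect_equal(med$prop_mediated, med$acme / med$total, tolerance = 1e-12)
  # full mediation: proportion mediated near 1
  y2 <- 0.4 * m + rnorm(n)
  med2 <- mediation_bootstrap(x, m, y2, n_boot = 400, seed = 9)
  expect_lt(abs(med2$prop_mediated - 1), 0.1)
  # determinism and guards
  med_b <- mediation_bootstrap(x, m, y, n_boot = 400, seed = 8)
  expect_identical(med$ci, med_b$ci)
  expect_error(mediation_bootstrap(x, rep(1, n), y), "degenerate mediator")
  expect_error(mediation_bootstrap(x[1:10], m[1:10], y[1:10]),
               "insufficient data")
})

test_that("null-mediator ACME intervals cover zero at roughly nominal rate", {
  covered <- vapply(1:30, function(s) {
    set.seed(1200 + s)
    n <- 120
    x <- rnorm(n)
    m <- rnorm(n)                  # mediator unrelated to x and y
    y <- 0.3 * x + rnorm(n)
    med <- mediation_bootstrap(x, m, y, n_boot = 300, seed = s)
    med$ci[1, "acme"] <= 0 && med$ci[2, "acme"] >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("bic_search enumerates subsets and recovers planted predictors", {
  set.seed(208)
  n <- 500
  cands <- as.data.frame(matrix(rnorm(n * 7), n,
                                dimnames = list(NULL, paste0("v", 1:7))))
  y <- 0.6 * cands$v1 + 0.5 * cands$v4 + rnorm(n)
  bs <- bic_search(y, cands)
  expect_equal(nrow(bs$ranking), 127L)
  expect_setequal(bs$winner$terms, c("v1", "v4"))
  expect_true(all(diff(bs$ranking$bic) >= 0))
  one <- bic_search(y, cands["v1"])
  expect_equal(nrow(one$ranking), 1L)
  expect_error(bic_search(y[1:5], cands[1:5, ]), "insufficient data")
})
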