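# Cohort generator: partition, factor-model time series, cohort bookkeeping,
# determinism, and the programmed behavioral change model.

test_that("simulate_partition splits nodes as evenly as divisibility allows", {
  p <- simulate_partition(264, 14)
  sizes <- as.vector(table(p)[unique(p)])
  expect_equal(sort(unique(sizes)), c(18L, 19L))
  expect_equal(sum(sizes == 19L), 12L)   # 264 = 14 * 18 + 12
  expect_equal(sum(sizes == 18L), 2L)
  expect_equal(length(p), 264L)

  p4 <- simulate_partition(4, 2)
  expect_equal(unname(p4), c("N01", "N01", "N02", "N02"))
  expect_error(simulate_partition(3, 4), "invalid config")
})

test_that("factor-model correlations follow the closed form", {
  part <- simulate_partition(12, 3)
  # pure noise: no structure
  cfg0 <- sim_config(n_nodes = 12, n_networks = 3, series_length = 400,
                     within_coupling = 0, between_coupling = 0,
                     domains = "fluid")
  ts0 <- simulate_timeseries(part, cfg0, "bl", seed = 21)
  r0 <- cor(t(ts0))
  expect_lt(mean(abs(r0[upper.tri(r0)])), 3 / sqrt(400))

  # within_coupling = lambda, between = 0: within-community r -> l^2/(l^2+1)
  lambda <- 0.6
  cfgl <- sim_config(n_nodes = 12, n_networks = 3, series_length = 1e5,
                     within_coupling = lambda, between_coupling = 0,
                     domains = "fluid")
  tsl <- simulate_timeseries(part, cfgl, "bl", seed = 22)
  r <- cor(t(tsl))
  same <- outer(part, part, "==")
  ut <- upper.tri(r)
  expect_equal(mean(r[ut & same]), lambda^2 / (lambda^2 + 1),
               tolerance = 0.02)
  expect_lt(abs(mean(r[ut & !same])), 0.02)

  # determinism
  expect_identical(simulate_timeseries(part, cfg0, "bl", seed = 5),
                   simulate_timeseries(part, cfg0, "bl", seed = 5))
})

test_that("within-community correlations exceed between on nearly all seeds", {
  part <- simulate_partition(20, 4)
  cfg <- sim_config(n_nodes = 20, n_networks = 4, series_length = 200,
                    domains = "fluid")
  same <- outer(part, part, "==")
  ut <- upper.tri(same)
  wins <- vapply(1:40, function(s) {
    r <- cor(t(simulate_timeseries(part, cfg, "bl", seed = s)))
    mean(r[ut & same]) > mean(r[ut & !same])
  }, logical(1))
  expect_true(all(wins))
})

test_that("cohort bookkeeping: rows, timepoints, behavior change follows the programmed model", {
  cfg <- small_config(seed = 9)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$covariates), 24L)
  expect_equal(sort(unique(co$behavior$timepoint)), c("bl", "fu"))
  expect_equal(nrow(co$behavior), 24L * 2L * length(cfg$domains))
  # every participant appears at both timepoints in every domain
  counts <- table(co$behavior$id, co$behavior$timepoint)
  expect_true(all(counts == length(cfg$domains)))
  # raw follow-up minus baseline equals the programmed change mapped through
  # the domain's raw scale, exactly
  beh <- co$behavior[co$behavior$domain == "fluid", ]
  bl <- beh[beh$timepoint == "bl", ]
  fu <- beh[beh$timepoint == "fu", ]
  fu <- fu[match(bl$id, fu$id), ]
  programmed <- co$truth$delta_behavior[bl$id, "fluid"]
  expect_equal((fu$score - bl$score) / bl$scale_sd[1], unname(programmed),
               tolerance = 1e-12)
})

test_that("a fixed seed reproduces the cohort byte for byte", {
  co1 <- simulate_cohort(small_config(seed = 4))
  co2 <- simulate_cohort(small_config(seed = 4))
  expect_identical(co1, co2)
  d1 <- file.path(tempdir(), "coh_a")
  d2 <- file.path(tempdir(), "coh_b")
  unlink(c(d1, d2), recursive = TRUE)
  write_cohort(co1, d1)
  write_cohort(co2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_participants = 0), "invalid config")
  expect_error(sim_config(n_nodes = 3, n_networks = 4), "invalid config")
  expect_error(sim_config(series_length = 5), "invalid config")
  expect_error(sim_config(within_coupling = 0.1, between_coupling = 0.2),
               "invalid config")
  expect_error(sim_config(age_range = c(80, 20)), "invalid config")
})

test_that("null cohorts keep the downstream age coefficient inside its CI most of the time", {
  hits <- vapply(1:25, function(s) {
    co <- simulate_cohort(null_config(seed = 400 + s))
    tab <- compute_cohort_measures(co)
    vars <- phconnect:::domain_variables(tab, "fluid")
    fm <- fit_model(vars$d_beh, vars$pred_d)
    cf <- fm$coefficients[fm$coefficients$term == "age", ]
    cf$ci_low <= 0 && cf$ci_high >= 0
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
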