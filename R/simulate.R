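# Seeded generator of synthetic longitudinal cohorts with the statistical
# structure the analysis chain assumes: block-modular correlation structure
# over functional communities, an age-graded reduction of within-community
# coupling at follow-up, and behavioral change linearly coupled to age and to
# the latent topology change. Ground truth is stored for recovery tests.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' Defaults emulate a lifespan cohort measured at baseline and a five-year
#' follow-up on a 264-node, 14-network parcellation.
#'
#' @param n_participants cohort size (default 163).
#' @param n_nodes number of functional nodes (default 264).
#' @param n_networks number of functional networks / communities (default 14).
#' @param series_length samples per task time series (default 430, the length
#'   of the fluid-reasoning tasks at TR = 2 s).
#' @param within_coupling loading of the shared community factor, on the
#'   correlation scale (within-community correlation tends to
#'   `(w^2 + b^2) / (w^2 + b^2 + 1)` for long series).
#' @param between_coupling loading of the global factor shared by all nodes.
#' @param age_range baseline age range in years (uniform; default 20-80).
#' @param seg_decline_slope per-year change of within-community coupling at
#'   follow-up, applied as `slope * (age - midpoint(age_range))`; negative
#'   values program disproportionate decline in older participants.
#' @param coupling_sd SD of participant-level heterogeneity added to the
#'   programmed coupling change (individual differences in decline; without
#'   it the latent change is collinear with age).
#' @param beta_age_behavior per-year effect of (centered) age on behavioral
#'   change, in baseline-SD units.
#' @param beta_auc_behavior effect of the latent coupling change on behavioral
#'   change, in baseline-SD units per unit coupling.
#' @param beta_nart_behavior effect of (centered) NART IQ on behavioral
#'   change, in baseline-SD units per IQ point.
#' @param noise_sd residual SD of behavioral change (baseline-SD units).
#' @param domains character vector of cognitive domains; `"speed"` is treated
#'   as a reaction-time domain (lower raw score is better).
#' @param seed integer random seed; a fixed seed gives a bit-identical cohort.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 163L,
                       n_nodes = 264L,
                       n_networks = 14L,
                       series_length = 430L,
                       within_coupling = 0.5,
                       between_coupling = 0.15,
                       age_range = c(20, 80),
                       seg_decline_slope = -0.004,
                       coupling_sd = 0.08,
                       beta_age_behavior = -0.01,
                       beta_auc_behavior = 4,
                       beta_nart_behavior = 0.015,
                       noise_sd = 0.5,
                       domains = c("mem", "fluid", "speed", "vocab"),
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_nodes = as.integer(n_nodes),
    n_networks = as.integer(n_networks),
    series_length = as.integer(series_length),
    within_coupling = within_coupling,
    between_coupling = between_coupling,
    age_range = as.numeric(age_range),
    seg_decline_slope = seg_decline_slope,
    coupling_sd = coupling_sd,
    beta_age_behavior = beta_age_behavior,
    beta_auc_behavior = beta_auc_behavior,
    beta_nart_behavior = beta_nart_behavior,
    noise_sd = noise_sd,
    domains = as.character(domains),
    seed = as.integer(seed)
  )
  if (cfg$n_participants < 1L)
    stop("invalid config: n_participants must be >= 1")
  if (cfg$n_networks < 2L || cfg$n_nodes < cfg$n_networks)
    stop("invalid config: need n_nodes >= n_networks >= 2")
  if (cfg$series_length < 10L)
    stop("invalid config: series_length must be >= 10")
  if (cfg$within_coupling < 0 || cfg$between_coupling < 0 ||
      cfg$within_coupling <= cfg$between_coupling &&
      !(cfg$within_coupling == 0 && cfg$between_coupling == 0))
    stop("invalid config: need within_coupling > between_coupling >= 0 (or both 0)")
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) <= 0)
    stop("invalid config: age_range must be an increasing pair of years")
  if (cfg$noise_sd < 0 || cfg$coupling_sd < 0)
    stop("invalid config: standard deviations must be non-negative")
  if (length(cfg$domains) < 1L || anyDuplicated(cfg$domains))
    stop("invalid config: domains must be a non-empty set of unique labels")
  structure(cfg, class = "sim_config")
}

#' Simulate a node-to-network partition
#'
#' Assigns `n_nodes` to `n_networks` labels with sizes as equal as
#' divisibility allows; the remainder is given to the first networks in label
#' order, deterministically.
#'
#' @param n_nodes number of nodes.
#' @param n_networks number of networks (>= 2, <= `n_nodes`).
#' @param seed unused for the assignment itself (it is deterministic); kept
#'   for interface uniformity.
#' @return A character vector of network labels (`"N01"`, ...) named by node
#'   id (`"n001"`, ...).
#' @export
simulate_partition <- function(n_nodes, n_networks, seed = NULL) {
  n_nodes <- as.integer(n_nodes)
  n_networks <- as.integer(n_networks)
  if (n_networks < 2L || n_networks > n_nodes)
    stop("invalid config: need n_nodes >= n_networks >= 2")
  base <- n_nodes %/% n_networks
  rem <- n_nodes %% n_networks
  sizes <- base + as.integer(seq_len(n_networks) <= rem)
  labels <- rep(sprintf("N%02d", seq_len(n_networks)), times = sizes)
  names(labels) <- sprintf("n%03d", seq_len(n_nodes))
  labels
}

#' Simulate a node-by-time series with block-modular correlation structure
#'
#' Factor model: each node's signal is `w * community factor +
#' b * global factor + unit-variance noise`, where `w` is the within-community
#' coupling and `b` the global coupling. At follow-up the within-coupling is
#' shifted by `seg_decline_slope * (age - midpoint(age_range))` (plus an
#' optional participant-specific offset `coupling_shift` carrying the latent
#' heterogeneity). For long series, within-community correlations tend to
#' `(w^2 + b^2) / (w^2 + b^2 + 1)` and between-community correlations to
#' `b^2 / (w^2 + b^2 + 1)` (loadings equal across nodes).
#'
#' @param partition node-to-network labels as from [simulate_partition()].
#' @param config a [sim_config()].
#' @param timepoint `"bl"` or `"fu"`.
#' @param age participant age in years (drives the follow-up decline).
#' @param seed integer seed for this series.
#' @param coupling_shift extra additive shift of the within-coupling at
#'   follow-up (participant heterogeneity; default 0).
#' @return A node-by-time numeric matrix with node ids as rownames.
#' @export
simulate_timeseries <- function(partition, config, timepoint = c("bl", "fu"),
                                age = mean(config$age_range), seed = 1L,
                                coupling_shift = 0) {
  timepoint <- match.arg(timepoint)
  if (config$series_length < 10L)
    stop("invalid config: series_length must be >= 10")
  w <- config$within_coupling
  if (timepoint == "fu") {
    mid <- mean(config$age_range)
    w <- w + config$seg_decline_slope * (age - mid) + coupling_shift
  }
  w <- max(w, 0.02 * (config$within_coupling > 0))
  b <- config$between_coupling
  L <- config$series_length
  n <- length(partition)
  comms <- unique(partition)
  set.seed(as.integer(seed))
  g <- rnorm(L)
  f <- matrix(rnorm(length(comms) * L), nrow = length(comms),
              dimnames = list(comms, NULL))
  eps <- matrix(rnorm(n * L), nrow = n)
  x <- w * f[partition, , drop = FALSE] + rep(b * g, each = n) + eps
  rownames(x) <- names(partition)
  x
}

#' Simulate a longitudinal synthetic cohort
#'
#' Generates covariates, two-timepoint connectivity data, and behavioral
#' scores with a programmed linear change model, and stores the ground truth.
#' Ages are uniform over `age_range`; covariates (sex, education, NART IQ,
#' per-domain scrubbing, cortical thickness, WMH volume) are drawn
#' independently with realistic ranges. For each domain the latent coupling
#' change is `seg_decline_slope * (age - midpoint) + coupling_sd * eta`, and
#' the behavioral change (in baseline-SD units) is
#' `beta_age_behavior * (age - midpoint) + beta_auc_behavior * coupling change
#' + beta_nart_behavior * (NART - 117) + noise`.
#'
#' @param config a [sim_config()].
#' @param store `"matrix"` (default) keeps per-participant Fisher-z
#'   connectivity matrices; `"timeseries"` keeps the raw node-by-time series
#'   (needed for split-sample analyses; larger).
#' @return An object of class `ph_cohort`: a list with `config`, `partition`,
#'   `covariates` (one row per participant), `behavior` (long table of raw
#'   scores), `data` (nested list `[[domain]][[timepoint]][[participant]]`),
#'   and `truth` (latent coupling changes and programmed behavioral changes).
#' @export
simulate_cohort <- function(config, store = c("matrix", "timeseries")) {
  stopifnot(inherits(config, "sim_config"))
  store <- match.arg(store)
  set.seed(config$seed)
  n <- config$n_participants
  mid <- mean(config$age_range)
  doms <- config$domains

  id <- sprintf("p%04d", seq_len(n))
  age <- runif(n, config$age_range[1L], config$age_range[2L])
  sex <- rbinom(n, 1L, 0.5)
  edu <- pmin(pmax(round(rnorm(n, 16.3, 2.4)), 8), 22)
  nart <- pmin(pmax(rnorm(n, 117, 7.7), 85), 135)
  ct_bl <- rnorm(n, 2.5, 0.12)
  ct_fu <- ct_bl + rnorm(n, -0.03, 0.02)
  wmh_bl <- rlnorm(n, log(2) + 0.03 * (age - mid), 0.9)
  wmh_fu <- wmh_bl * rlnorm(n, 0.15, 0.2)
  scrub <- matrix(runif(n * length(doms), 0.02, 0.28), nrow = n,
                  dimnames = list(NULL, paste0("scrub_", doms)))

  covariates <- data.frame(id = id, age = age, sex = sex, edu = edu,
                           nart = nart, ct_bl = ct_bl, ct_fu = ct_fu,
                           wmh_bl = wmh_bl, wmh_fu = wmh_fu,
                           stringsAsFactors = FALSE)
  covariates <- cbind(covariates, as.data.frame(scrub))

  partition <- simulate_partition(config$n_nodes, config$n_networks)

  # latent coupling change and programmed behavioral change, per domain
  delta_coupling <- matrix(NA_real_, n, length(doms),
                           dimnames = list(id, doms))
  delta_behavior <- matrix(NA_real_, n, length(doms),
                           dimnames = list(id, doms))
  for (d in seq_along(doms)) {
    eta <- rnorm(n)
    delta_coupling[, d] <- config$seg_decline_slope * (age - mid) +
      config$coupling_sd * eta
    delta_behavior[, d] <- config$beta_age_behavior * (age - mid) +
      config$beta_auc_behavior * delta_coupling[, d] +
      config$beta_nart_behavior * (nart - 117) +
      rnorm(n, 0, config$noise_sd)
  }

  # raw behavioral scores: accuracy-like (percent correct) except for speed,
  # which is reaction-time-like (lower is better); follow-up raw change is
  # the programmed z change mapped through the domain's raw scale
  behavior <- do.call(rbind, lapply(seq_along(doms), function(d) {
    dom <- doms[d]
    is_speed <- dom == "speed"
    if (is_speed) {
      raw_bl <- 1500 + 5 * (age - mid) + rnorm(n, 0, 150)
      raw_fu <- raw_bl - delta_behavior[, d] * 150
      scale_sd <- 150
    } else {
      raw_bl <- 75 - 0.2 * (age - mid) + rnorm(n, 0, 8)
      raw_fu <- raw_bl + delta_behavior[, d] * 8
      scale_sd <- 8
    }
    data.frame(id = rep(id, 2L), domain = dom,
               timepoint = rep(c("bl", "fu"), each = n),
               score = c(raw_bl, raw_fu), is_speed = is_speed,
               scale_sd = scale_sd, stringsAsFactors = FALSE)
  }))
  rownames(behavior) <- NULL

  # connectivity data: per-participant seeds drawn from the main stream so
  # the whole cohort is reproducible from config$seed alone
  series_seeds <- array(sample.int(.Machine$integer.max,
                                   n * 2L * length(doms)),
                        dim = c(n, 2L, length(doms)))
  data <- setNames(vector("list", length(doms)), doms)
  for (d in seq_along(doms)) {
    data[[d]] <- list(bl = vector("list", n), fu = vector("list", n))
    for (p in seq_len(n)) {
      for (tp in c("bl", "fu")) {
        ti <- if (tp == "bl") 1L else 2L
        shift <- if (tp == "fu")
          delta_coupling[p, d] -
            config$seg_decline_slope * (age[p] - mid) else 0
        ts <- simulate_timeseries(partition, config, timepoint = tp,
                                  age = age[p],
                                  seed = series_seeds[p, ti, d],
                                  coupling_shift = shift)
        data[[d]][[tp]][[p]] <-
          if (store == "matrix") correlation_matrix(ts) else ts
      }
      names(data[[d]]$bl) <- id
      names(data[[d]]$fu) <- id
    }
  }

  structure(list(
    config = config,
    partition = partition,
    covariates = covariates,
    behavior = behavior,
    data = data,
    store = store,
    truth = list(config = config,
                 delta_coupling = delta_coupling,
                 delta_behavior = delta_behavior)
  ), class = "ph_cohort")
}

#' @export
print.ph_cohort <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic longitudinal cohort\n")
  cat(sprintf("  %d participants, 2 timepoints, %d domain(s): %s\n",
              cfg$n_participants, length(cfg$domains),
              paste(cfg$domains, collapse = ", ")))
  cat(sprintf("  %d nodes in %d networks; series length %d; stored as %s\n",
              cfg$n_nodes, cfg$n_networks, cfg$series_length, x$store))
  cat(sprintf("  age %.1f-%.1f; seg_decline_slope %.4g; beta_auc_behavior %.3g\n",
              min(x$covariates$age), max(x$covariates$age),
              cfg$seg_decline_slope, cfg$beta_auc_behavior))
  invisible(x)
}
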