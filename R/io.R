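# Plain-text readers and writers: square connectivity matrices as CSV with a
# node-id header, partitions as two-column CSV, cohorts as a directory of
# covariates + behavior + manifest-driven matrix files + ground truth.

#' Write / read a connectivity matrix as square CSV
#'
#' The CSV has a header row of node ids and one row per node (first column
#' the node id), human-auditable at parcellation scale.
#'
#' @param m symmetric connectivity matrix with dimnames.
#' @param path file path.
#' @return `read_matrix_csv()` returns the matrix; writers return the path
#'   invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(node = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop("validation error in ", path, ": matrix is not square")
  m
}

#' Write / read a node-to-network partition as CSV
#'
#' Two columns: `node_id`, `network_label`.
#'
#' @param partition labels named by node id, as from [simulate_partition()].
#' @param path file path.
#' @export
write_partition_csv <- function(partition, path) {
  write.csv(data.frame(node_id = names(partition),
                       network_label = unname(partition)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_csv
#' @export
read_partition_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("node_id", "network_label") %in% names(df)))
    stop("validation error in ", path,
         ": expected columns node_id, network_label")
  setNames(as.character(df$network_label), df$node_id)
}

#' Serialize a synthetic cohort to a directory
#'
#' Writes `covariates.csv`, `behavior.csv`, `partition.csv`, a
#' `manifest.csv` (participant, timepoint, domain, path) pointing at one
#' square matrix CSV per participant/timepoint/domain under `matrices/`,
#' ground truth (`truth_delta_coupling.csv`, `truth_delta_behavior.csv`) and
#' the resolved configuration as `config.yaml`.
#'
#' @param cohort a `ph_cohort` with `store = "matrix"`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ph_cohort"))
  if (cohort$store != "matrix")
    stop("write_cohort() serializes matrix-form cohorts; convert first")
  dir.create(file.path(dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  write.csv(cohort$behavior, file.path(dir, "behavior.csv"),
            row.names = FALSE)
  write_partition_csv(cohort$partition, file.path(dir, "partition.csv"))
  man <- list()
  for (d in cohort$config$domains) {
    for (tp in c("bl", "fu")) {
      for (id in names(cohort$data[[d]][[tp]])) {
        rel <- file.path("matrices", paste(d, tp, id, "csv", sep = "."))
        write_matrix_csv(cohort$data[[d]][[tp]][[id]], file.path(dir, rel))
        man[[length(man) + 1L]] <- data.frame(
          participant = id, timepoint = tp, domain = d, path = rel,
          stringsAsFactors = FALSE)
      }
    }
  }
  write.csv(do.call(rbind, man), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  tr <- cohort$truth
  write.csv(data.frame(id = rownames(tr$delta_coupling),
                       tr$delta_coupling, check.names = FALSE),
            file.path(dir, "truth_delta_coupling.csv"), row.names = FALSE)
  write.csv(data.frame(id = rownames(tr$delta_behavior),
                       tr$delta_behavior, check.names = FALSE),
            file.path(dir, "truth_delta_behavior.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a serialized cohort directory back
#'
#' Inverse of [write_cohort()]; validates the manifest and reconstructs a
#' `ph_cohort` object (numeric round trip is exact up to CSV float
#' formatting, about 1e-15 relative).
#'
#' @param dir directory written by [write_cohort()].
#' @return A `ph_cohort` object.
#' @export
read_cohort <- function(dir) {
  need <- c("covariates.csv", "behavior.csv", "partition.csv",
            "manifest.csv", "config.yaml")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("validation error: missing ", f, " in ", dir)
  cfg_raw <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- do.call(sim_config, cfg_raw[setdiff(names(cfg_raw), character())])
  covariates <- read.csv(file.path(dir, "covariates.csv"),
                         stringsAsFactors = FALSE)
  behavior <- read.csv(file.path(dir, "behavior.csv"),
                       stringsAsFactors = FALSE)
  partition <- read_partition_csv(file.path(dir, "partition.csv"))
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  data <- list()
  for (r in seq_len(nrow(man))) {
    d <- man$domain[r]; tp <- man$timepoint[r]; id <- man$participant[r]
    fp <- file.path(dir, man$path[r])
    if (!file.exists(fp))
      stop("validation error: manifest entry points at missing file ", fp)
    data[[d]][[tp]][[id]] <- read_matrix_csv(fp)
  }
  tdc <- read.csv(file.path(dir, "truth_delta_coupling.csv"),
                  check.names = FALSE)
  tdb <- read.csv(file.path(dir, "truth_delta_behavior.csv"),
                  check.names = FALSE)
  dc <- as.matrix(tdc[, -1L, drop = FALSE]); rownames(dc) <- tdc$id
  db <- as.matrix(tdb[, -1L, drop = FALSE]); rownames(db) <- tdb$id
  structure(list(config = config, partition = partition,
                 covariates = covariates, behavior = behavior,
                 data = data, store = "matrix",
                 truth = list(config = config, delta_coupling = dc,
                              delta_behavior = db)),
            class = "ph_cohort")
}

#' Read a wide time-series CSV
#'
#' First column node id, remaining columns samples.
#'
#' @param path file path.
#' @return Node-by-time numeric matrix with node-id rownames.
#' @export
read_timeseries_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
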