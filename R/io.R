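#' Read a simulation configuration from JSON or YAML
#'
#' Flat keys mirror [sim_config()] and [growth_params()]:
#' `a, r, M, C0, m0, dt, m_death, S, p, q, width, height, cell_area,
#' n_plants, pattern, n_steps, record_every, seed, clusters, cluster_sd`.
#' Missing keys fall back to the package defaults; `p`/`q` accept the
#' string `"Inf"`.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else stop("config must be .json, .yaml or .yml")
  as_inf <- function(v) if (is.character(v)) as.numeric(v) else v
  gp_args <- cfg[intersect(names(cfg),
                           c("a", "r", "M", "C0", "m0", "dt", "m_death"))]
  gp <- do.call(growth_params, gp_args)
  ar_args <- cfg[intersect(names(cfg), c("width", "height", "cell_area"))]
  ar <- do.call(arena, ar_args)
  sc_args <- cfg[intersect(names(cfg),
                           c("S", "p", "q", "n_plants", "pattern", "n_steps",
                             "record_every", "seed", "clusters",
                             "cluster_sd"))]
  sc_args$p <- as_inf(sc_args$p); sc_args$q <- as_inf(sc_args$q)
  sc_args <- sc_args[!vapply(sc_args, is.null, logical(1))]
  do.call(sim_config, c(sc_args, list(params = gp, arena = ar)))
}

#' Write a simulation configuration as JSON
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  flat <- c(config$params[c("a", "r", "M", "C0", "m0", "dt", "m_death")],
            config$arena[c("width", "height", "cell_area")],
            config[c("S", "p", "q", "n_plants", "pattern", "n_steps",
                     "record_every", "seed", "clusters", "cluster_sd")])
  flat$p <- if (is.infinite(flat$p)) "Inf" else flat$p
  flat$q <- if (is.infinite(flat$q)) "Inf" else flat$q
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

rii_schema <- c("stress", "density", "replicate", "P_w", "P_s", "RII")

#' Write RII records as tidy CSV
#'
#' @param records Data frame from [run_factorial()] (or compatible).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rii_csv <- function(records, path) {
  cols <- intersect(c(rii_schema, "n_plants", "n_alive"), names(records))
  write.csv(records[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read an RII table (simulated or experimental)
#'
#' The reader contract for per-replicate performance tables: columns
#' `stress`, `density`, `replicate` plus either `RII` directly or the
#' performance pair `P_w`, `P_s` from which RII is computed. Greenhouse
#' source-data tables (salinity level, pot density, per-pot mean
#' performance with neighbours and the no-neighbour baseline) coerce into
#' this schema.
#'
#' @param path CSV path.
#' @return Data frame with at least `stress`, `density`, `replicate`,
#'   `RII`.
#' @export
read_rii_csv <- function(path) {
  d <- read.csv(path)
  need <- c("stress", "density", "replicate")
  if (!all(need %in% names(d)))
    stop("RII table must have columns: ", paste(need, collapse = ", "))
  if (!"RII" %in% names(d)) {
    if (!all(c("P_w", "P_s") %in% names(d)))
      stop("RII table needs either an RII column or both P_w and P_s")
    d$RII <- compute_rii(d$P_w, d$P_s)
  }
  d
}

#' Write the per-plant trajectory of a simulation as tidy CSV
#'
#' @param sim A [run_simulation()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(sim, path) {
  write.csv(sim$trajectory[, c("step", "id", "x", "y", "m", "alive")],
            path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Records what produced a set of outputs: a digest of the configuration,
#' the master seed, package version, timings and output paths, written as
#' JSON next to the outputs.
#'
#' @param config A [sim_config()] (or any list of parameters).
#' @param seed Master seed used.
#' @param outputs Character vector of output paths.
#' @param timings Named numeric vector of stage timings (seconds).
#' @param path Manifest path (JSON).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, seed, outputs, timings = NULL,
                           path = "manifest.json") {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, force = TRUE)
  man <- list(config_hash = sum(utf8ToInt(as.character(cfg_json)) *
                                  seq_along(utf8ToInt(as.character(cfg_json)))) %%
                2147483647,
              seed = seed,
              package_version = as.character(utils::packageVersion("zoifacil")),
              timestamp = format(Sys.time(), tz = "UTC"),
              timings = as.list(timings),
              outputs = outputs)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}
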