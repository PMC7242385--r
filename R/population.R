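#' Simulation configuration
#'
#' Bundles every model and protocol parameter for one run: growth
#' parameters, stress, sharing modes, arena, number of plants, spatial
#' pattern, duration and seed.
#'
#' @param params A [growth_params()].
#' @param S Stress intensity in `[0, 1]`.
#' @param p,q Modes of competition and facilitation (sharing exponents).
#' @param arena A [arena()].
#' @param n_plants Number of plants placed at step 0 (initial density; the
#'   arena area is fixed, so a count is a density).
#' @param pattern Spatial pattern: `"random"` (uniform), `"regular"`
#'   (centred near-square lattice) or `"aggregated"` (Gaussian clusters).
#' @param n_steps Number of time steps (default 50).
#' @param record_every Record cadence in steps (default 10); the final
#'   step is always recorded.
#' @param seed Integer seed; every random draw in the run flows from it.
#' @param clusters Number of cluster centres for the aggregated pattern.
#'   The default (60) is a fixed count, so that the within-patch density
#'   scales with the density treatment; tying the count to `n_plants`
#'   would hold local density constant and erase the treatment.
#' @param cluster_sd Gaussian scatter of cluster members (cells,
#'   default 20).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(params = growth_params(), S = 0, p = 1, q = 1,
                       arena = zoifacil::arena(), n_plants = 300L,
                       pattern = c("random", "regular", "aggregated"),
                       n_steps = 50L, record_every = 10L, seed = 1L,
                       clusters = 60L, cluster_sd = 20) {
  pattern <- match.arg(pattern)
  check_stress(S)
  if (is.na(p) || p < 0 || is.na(q) || q < 0) stop("p and q must be >= 0 or Inf")
  n_plants <- as.integer(n_plants)
  if (n_plants < 1L) stop("n_plants must be >= 1")
  n_steps <- as.integer(n_steps); record_every <- as.integer(record_every)
  if (n_steps < 1L || record_every < 1L)
    stop("n_steps and record_every must be >= 1")
  if (is.null(clusters)) clusters <- 60L
  structure(list(params = params, S = S, p = p, q = q, arena = arena,
                 n_plants = n_plants, pattern = pattern, n_steps = n_steps,
                 record_every = record_every, seed = as.integer(seed),
                 clusters = as.integer(clusters), cluster_sd = cluster_sd),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d plants (%s), S = %g, p = %g, q = %g, ",
                     "%d steps, seed = %d\n"),
              x$n_plants, x$pattern, x$S, x$p, x$q, x$n_steps, x$seed))
  invisible(x)
}

#' Place the initial population
#'
#' Positions `n_plants` plants of mass `m0` on the arena under the
#' configured spatial pattern. Random: i.i.d. uniform. Regular: a centred
#' near-square lattice (maximally even). Aggregated: cluster centres drawn
#' uniformly, members scattered around them with Gaussian noise and
#' wrapped. Reproducible under the configuration seed.
#'
#' @param config A [sim_config()].
#' @return Data frame `id`, `x`, `y`, `m`, `alive`, `birth_step`.
#' @export
init_population <- function(config) {
  n <- config$n_plants
  W <- config$arena$width; H <- config$arena$height
  set.seed(config$seed)
  pos <- switch(config$pattern,
    random = cbind(runif(n, 0, W), runif(n, 0, H)),
    regular = {
      ncol_ <- max(1L, ceiling(sqrt(n * W / H)))
      nrow_ <- ceiling(n / ncol_)
      sx <- W / ncol_; sy <- H / nrow_
      g <- expand.grid(i = seq_len(ncol_) - 1L, j = seq_len(nrow_) - 1L)
      g <- g[seq_len(n), , drop = FALSE]
      cbind(sx * (g$i + 0.5), sy * (g$j + 0.5))
    },
    aggregated = {
      k <- config$clusters
      cx <- runif(k, 0, W); cy <- runif(k, 0, H)
      idx <- rep_len(seq_len(k), n)
      cbind(wrap_coord(cx[idx] + rnorm(n, 0, config$cluster_sd), W),
            wrap_coord(cy[idx] + rnorm(n, 0, config$cluster_sd), H))
    })
  data.frame(id = seq_len(n), x = pos[, 1], y = pos[, 2],
             m = rep(config$params$m0, n), alive = rep(TRUE, n),
             birth_step = 0L)
}

#' Advance the population one time step
#'
#' Synchronous forward-Euler update: the interaction field is computed
#' once over all live plants, then every mass is updated from that same
#' snapshot, so the result does not depend on plant order. Masses are
#' capped at `M`; plants whose mass falls to `m_death` or below are marked
#' dead and never re-enter the field.
#'
#' @param pop Population data frame (as from [init_population()]).
#' @param config A [sim_config()].
#' @return Updated population data frame.
#' @export
sim_step <- function(pop, config) {
  gp <- config$params
  live <- which(pop$alive)
  if (!length(live)) return(pop)
  plants <- data.frame(id = pop$id[live], x = pop$x[live], y = pop$y[live],
                       A = gp$C0 * pop$m[live]^(3 / 4))
  fld <- compute_field(plants, config$arena, config$p, config$q)
  rate <- realized_growth_rate(pop$m[live], fld$I_c, fld$I_f, gp, config$S)
  m_new <- pmin(pop$m[live] + gp$dt * rate, gp$M)
  dead <- m_new <= gp$m_death
  pop$m[live] <- pmax(m_new, 0)
  pop$alive[live][dead] <- FALSE
  pop
}

#' Run one simulation
#'
#' Runs `n_steps` synchronous updates, recording the population every
#' `record_every` steps (plus steps 0 and `n_steps`).
#'
#' @param config A [sim_config()].
#' @param full_trajectory Record every step regardless of `record_every`
#'   (used for the time-resolved analyses).
#' @return A list of class `zoi_sim` with elements `trajectory` (long data
#'   frame: `step`, `id`, `x`, `y`, `m`, `alive`), `summary` (`step`,
#'   `n_alive`, `mean_mass` — mean over survivors, `NA` when none) and
#'   `final` (the population at the last step), plus the `config`.
#' @export
run_simulation <- function(config, full_trajectory = FALSE) {
  pop <- init_population(config)
  steps <- 0:config$n_steps
  rec <- if (full_trajectory) steps else
    unique(c(0L, steps[steps %% config$record_every == 0L], config$n_steps))
  traj <- vector("list", length(rec))
  summ <- vector("list", length(rec))
  snap <- function(step, pop) {
    list(traj = cbind(step = step, pop),
         summ = data.frame(step = step, n_alive = sum(pop$alive),
                           mean_mass = if (any(pop$alive))
                             mean(pop$m[pop$alive]) else NA_real_))
  }
  ri <- 1L
  if (0L %in% rec) { s <- snap(0L, pop); traj[[ri]] <- s$traj; summ[[ri]] <- s$summ; ri <- ri + 1L }
  for (t in seq_len(config$n_steps)) {
    pop <- sim_step(pop, config)
    if (t %in% rec) {
      s <- snap(t, pop); traj[[ri]] <- s$traj; summ[[ri]] <- s$summ; ri <- ri + 1L
    }
  }
  structure(list(trajectory = do.call(rbind, traj),
                 summary = do.call(rbind, summ),
                 final = pop, config = config),
            class = "zoi_sim")
}

#' @export
print.zoi_sim <- function(x, ...) {
  fin <- x$summary[nrow(x$summary), ]
  cat(sprintf(paste0("<zoi_sim> %d plants, S = %g, %d steps: %d alive, ",
                     "mean mass %.4g\n"),
              x$config$n_plants, x$config$S, x$config$n_steps,
              fin$n_alive, fin$mean_mass))
  invisible(x)
}
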