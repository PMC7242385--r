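#' Relative interaction index
#'
#' `RII = (P_w - P_s) / (P_w + P_s)` where `P_w` is mean performance with
#' neighbours and `P_s` the lone-plant baseline. RII lies in `[-1, 1]`:
#' negative values indicate net competition, positive values net
#' facilitation.
#'
#' @param P_w,P_s Non-negative performances (vectors recycle).
#' @return RII values; `NA` with a warning where `P_w + P_s = 0`.
#' @examples
#' compute_rii(1, 3)   # -0.5
#' compute_rii(2, 0)   # 1: no surviving lone plant
#' @export
compute_rii <- function(P_w, P_s) {
  if (any(P_w < 0 | P_s < 0, na.rm = TRUE)) stop("performances must be >= 0")
  tot <- P_w + P_s
  out <- ifelse(tot > 0, (P_w - P_s) / tot, NA_real_)
  if (any(tot == 0, na.rm = TRUE))
    warning("P_w + P_s = 0: RII undefined (both performances zero)")
  out
}

#' Lone-plant performance baseline
#'
#' Mass of an isolated plant after `n_steps`, from the same forward-Euler
#' integration of the no-neighbour growth equation that the simulator
#' uses, so a plant that never interacts has RII exactly 0.
#'
#' @param S Stress in `[0, 1]`.
#' @param params A [growth_params()].
#' @param n_steps Measurement step (default 50).
#' @return Final mass (scalar).
#' @export
lone_baseline <- function(S, params = growth_params(), n_steps = 50L) {
  m <- integrate_lone(params, S, n_steps)
  m[length(m)]
}

#' Factorial stress-by-density design
#'
#' The default design is the study protocol: stress levels none (0), low
#' (0.45), high (0.75) and extreme (0.85); seven density levels 2 to 8;
#' five replicates; measurement after 50 steps.
#'
#' @param stress Stress levels.
#' @param density Density levels (the covariate used in all analyses).
#' @param replicates Replicates per cell.
#' @param n_steps Measurement step.
#' @return An object of class `factorial_design`.
#' @export
factorial_design <- function(stress = c(0, 0.45, 0.75, 0.85), density = 2:8,
                             replicates = 5L, n_steps = 50L) {
  check_stress(stress)
  if (length(density) < 1 || any(density <= 0)) stop("invalid density levels")
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1")
  structure(list(stress = stress, density = density,
                 replicates = replicates, n_steps = as.integer(n_steps)),
            class = "factorial_design")
}

# Deterministic seed expansion: fold design coordinates through an LCG so
# any (stress, density, replicate) cell is reproducible in isolation.
derive_seed <- function(master, ...) {
  x <- as.numeric(master) %% 2^31
  for (v in c(...)) {
    x <- (1103515245 * ((x + as.numeric(v) * 1000) %% 2^31) + 12345) %% 2^31
  }
  as.integer(x %% 2147483646) + 1L
}

#' Run the full factorial experiment
#'
#' For every (stress, density, replicate) cell a simulation is run with a
#' seed derived deterministically from the master seed and the cell
#' coordinates. Performance with neighbours `P_w` is the mean biomass of
#' survivors at the measurement step; the baseline `P_s` comes from
#' [lone_baseline()] at the same step.
#'
#' Density levels are mapped to plant counts as
#' `n_plants = density * plants_per_level`; the level itself (the paper
#' axis value) is the covariate carried through all downstream analyses.
#'
#' @param design A [factorial_design()].
#' @param config Template [sim_config()]; its `S` and `n_plants` are
#'   overwritten per cell, everything else (pattern, p, q, arena,
#'   growth parameters) is taken as-is.
#' @param seed Master seed.
#' @param plants_per_level Plants per density level (calibration
#'   constant, default 150; see the methods vignette).
#' @param time_resolved Also record mean mass and RII at every recorded
#'   step (for the growth-dynamics analyses); adds a `trajectory`
#'   attribute with columns `stress`, `density`, `replicate`, `step`,
#'   `n_alive`, `P_w`, `P_s`, `RII`.
#' @return Data frame of replicate-level records: `stress`, `density`,
#'   `replicate`, `n_plants`, `n_alive`, `P_w`, `P_s`, `RII`.
#' @export
run_factorial <- function(design = factorial_design(),
                          config = sim_config(), seed = 1L,
                          plants_per_level = 150L, time_resolved = FALSE) {
  gp <- config$params
  base <- vapply(design$stress, lone_baseline, numeric(1),
                 params = gp, n_steps = design$n_steps)
  base_traj <- if (time_resolved)
    lapply(design$stress, function(S) integrate_lone(gp, S, design$n_steps))
  rows <- list(); trows <- list(); k <- 0L
  for (si in seq_along(design$stress)) {
    for (dl in design$density) {
      for (rep_i in seq_len(design$replicates)) {
        k <- k + 1L
        cfg <- config
        cfg$S <- design$stress[si]
        cfg$n_plants <- as.integer(round(dl * plants_per_level))
        cfg$n_steps <- design$n_steps
        cfg$seed <- derive_seed(seed, si, dl, rep_i)
        sim <- run_simulation(cfg, full_trajectory = isTRUE(time_resolved))
        fin <- sim$summary[nrow(sim$summary), ]
        P_w <- if (fin$n_alive > 0) fin$mean_mass else 0
        rii <- if (P_w + base[si] > 0)
          (P_w - base[si]) / (P_w + base[si]) else NA_real_
        rows[[k]] <- data.frame(stress = cfg$S, density = dl,
                                replicate = rep_i, n_plants = cfg$n_plants,
                                n_alive = fin$n_alive,
                                P_w = P_w, P_s = base[si], RII = rii)
        if (time_resolved) {
          sm <- sim$summary
          ps <- base_traj[[si]][sm$step + 1]
          pw <- ifelse(sm$n_alive > 0, sm$mean_mass, 0)
          trows[[k]] <- data.frame(stress = cfg$S, density = dl,
                                   replicate = rep_i, step = sm$step,
                                   n_alive = sm$n_alive, P_w = pw, P_s = ps,
                                   RII = ifelse(pw + ps > 0,
                                                (pw - ps) / (pw + ps),
                                                NA_real_))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$n_alive == 0))
    warning(sum(out$n_alive == 0), " replicate(s) ended with no survivors")
  if (time_resolved) attr(out, "trajectory") <- do.call(rbind, trows)
  out
}

#' Summarize RII records per stress-by-density cell
#'
#' @param records Output of [run_factorial()] (or any data frame with
#'   `stress`, `density`, `RII`).
#' @return Data frame `stress`, `density`, `mean_rii`, `sem`, `n`.
#' @export
summarize_rii <- function(records) {
  sp <- split(records, list(records$stress, records$density), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    v <- d$RII[!is.na(d$RII)]
    data.frame(stress = d$stress[1], density = d$density[1],
               mean_rii = mean(v), sem = sd(v) / sqrt(length(v)),
               n = length(v))
  }))
  out <- out[order(out$stress, out$density), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Density level at which mean RII peaks
#'
#' @param mean_rii Mean RII per density level.
#' @param density Density levels (same order).
#' @return The density attaining the maximum; ties break towards the
#'   lower density (conservative for rightward-shift comparisons).
#' @export
peak_density <- function(mean_rii, density) {
  keep <- !is.na(mean_rii)
  if (!any(keep)) stop("all mean RII values missing")
  mean_rii <- mean_rii[keep]; density <- density[keep]
  if (length(density) < 2) stop("need at least 2 density levels")
  density[which.max(mean_rii)] # which.max returns the first (lowest) maximum
}

#' Classify the shape of an RII-density curve
#'
#' Distinguishes the two regimes of the facilitation-density relationship:
#' `"hump-shaped"` (an interior maximum with a significant rise from the
#' lowest density, non-decreasing before the peak and non-increasing
#' after, within tolerance) and `"monotone-decreasing"` (every successive
#' difference within tolerance of non-positive); anything else is
#' `"other"`. The hump test comes first so a genuine interior peak is not
#' swallowed by the monotone tolerance.
#'
#' All tolerances are expressed in units of the replicate standard error,
#' since the absolute RII scale depends on calibration: a successive
#' difference of two cell means is compared against `tol_mult` times its
#' own standard error `sqrt(sem_i^2 + sem_(i+1)^2)`, and the rise to the
#' peak must exceed one standard error of that difference to count as a
#' hump.
#'
#' @param mean_rii Mean RII per density level (ordered by density).
#' @param sem Replicate standard errors per level (same order); a scalar
#'   recycles.
#' @param tol_mult Tolerance multiplier on the standard error of each
#'   successive difference (default 2, a conventional two-sigma band).
#' @return One of `"monotone-decreasing"`, `"hump-shaped"`, `"other"`.
#' @examples
#' classify_shape(c(0, -0.1, -0.2, -0.3), sem = 0.01)
#' classify_shape(c(-0.1, 0.2, 0.4, 0.1), sem = 0.01)
#' @export
classify_shape <- function(mean_rii, sem = 0, tol_mult = 2) {
  n <- length(mean_rii)
  if (n < 3) stop("need at least 3 density levels")
  sem <- rep_len(sem, n)
  d <- diff(mean_rii)
  se_d <- sqrt(sem[-n]^2 + sem[-1]^2)
  tol <- tol_mult * se_d
  pk <- which.max(mean_rii)
  rise <- mean_rii[pk] - mean_rii[1]
  if (pk > 1 && pk < n && rise > sqrt(sem[1]^2 + sem[pk]^2) &&
      all(d[seq_len(pk - 1)] >= -tol[seq_len(pk - 1)]) &&
      all(d[pk:(n - 1)] <= tol[pk:(n - 1)]))
    return("hump-shaped")
  if (all(d <= tol)) return("monotone-decreasing")
  "other"
}
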