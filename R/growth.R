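#' Allometric constant from a target maximum ZOI radius
#'
#' The ZOI area is tied to biomass by `A = C0 * m^(3/4)`. This helper
#' returns the `C0` for which a plant at the maximum mass `M` has a ZOI of
#' radius `r_max` (cell units), which is the natural way to calibrate the
#' spatial footprint of the model on a given arena.
#'
#' @param r_max Target ZOI radius at mass `M`.
#' @param M Maximum mass.
#' @return The allometric constant `C0` (area per mass^(3/4)).
#' @export
zoi_c0 <- function(r_max, M) pi * r_max^2 / M^(3 / 4)

#' Growth parameters
#'
#' Parameters of the metabolic-scaling growth model. An isolated plant
#' grows as `dm/dt = a * m^(3/4) * (1 - S - (m/M)^(1/4))`; with neighbours
#' the rate is expressed per unit ZOI area through the intrinsic rate `r`
#' (mass / area / time), and the two forms coincide exactly when
#' `a = r * C0` (the default).
#'
#' The defaults are the package's calibration for the 200 x 200 arena (the
#' methods vignette documents the choice): `M = 20000`; `C0` such that the
#' ZOI radius at `M` is 40 cells; `a = 1.5`, so the characteristic growth
#' time `4 * M^(1/4) / a` is about 32 steps and plants are still growing
#' when measured after 50 steps (an annual harvested mid-growth, and the
#' regime in which the facilitation-density relationship is
#' time-dependent); and `m0 = M * (1 - 0.85)^4`, the equilibrium mass at
#' the extreme stress level — a seedling for which extreme stress exactly
#' cancels net growth without neighbours.
#'
#' @param a Intrinsic mass-growth constant (mass^(1/4) / time).
#' @param M Theoretical maximum mass.
#' @param C0 Allometric constant, `A = C0 * m^(3/4)`.
#' @param r Intrinsic growth rate (mass / area / time); defaults to
#'   `a / C0` so the isolated-plant and neighbourhood forms agree.
#' @param m0 Initial mass of a plant.
#' @param dt Time-step length for the forward-Euler update.
#' @param m_death Mass at or below which a plant dies (default 0).
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(a = 1.5, M = 20000, C0 = zoi_c0(40, M), r = a / C0,
                          m0 = M * (1 - 0.85)^4, dt = 1, m_death = 0) {
  if (any(c(a, r, M, C0, m0, dt) <= 0)) stop("a, r, M, C0, m0, dt must be > 0")
  if (m0 >= M) stop("m0 must be below M")
  structure(list(a = a, r = r, M = M, C0 = C0, m0 = m0, dt = dt,
                 m_death = m_death),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(paste0("<growth_params> a = %g, r = %g, M = %g, C0 = %g, ",
                     "m0 = %g, dt = %g\n"),
              x$a, x$r, x$M, x$C0, x$m0, x$dt))
  invisible(x)
}

check_stress <- function(S) {
  if (any(S < 0 | S > 1)) stop("stress S must lie in [0, 1]")
  S
}

#' Potential growth rate of an isolated plant
#'
#' `dm/dt = a * m^(3/4) * (1 - S - (m/M)^(1/4))`. `S` is the stress
#' intensity, the proportional reduction in incoming energy: 0 means no
#' stress, 1 extreme stress with no resources. The rate vanishes at the
#' stress-dependent equilibrium `m* = M * (1 - S)^4`.
#'
#' @param m Mass (> 0), possibly a vector.
#' @param params A [growth_params()].
#' @param S Stress in `[0, 1]`.
#' @return Growth rate (mass / time).
#' @export
potential_growth_rate <- function(m, params, S) {
  if (any(m <= 0)) stop("mass must be > 0")
  check_stress(S)
  params$a * m^(3 / 4) * (1 - S - (m / params$M)^(1 / 4))
}

#' Realized growth rate with neighbours
#'
#' `dm/dt = r * A * ((1 - S * I_f) * I_c - (m/M)^(1/4))` with
#' `A = C0 * m^(3/4)`. Competition enters through `I_c` (share of
#' potential resources actually obtained) and facilitation through the
#' realized-stress index `I_f = 1 - A_f / A`: the same amount of
#' amelioration `A_f` reduces stress more for a small beneficiary than for
#' a large one, which makes the facilitative response size-dependent. With
#' `I_c = I_f = 1` and `a = r * C0` this reduces exactly to
#' [potential_growth_rate()].
#'
#' @inheritParams potential_growth_rate
#' @param I_c,I_f Competition and realized-stress indices in `[0, 1]`.
#' @return Growth rate (mass / time).
#' @export
realized_growth_rate <- function(m, I_c, I_f, params, S) {
  if (any(m <= 0)) stop("mass must be > 0")
  check_stress(S)
  if (any(I_c < 0 | I_c > 1) || any(I_f < 0 | I_f > 1))
    stop("I_c and I_f must lie in [0, 1]")
  A <- params$C0 * m^(3 / 4)
  params$r * A * ((1 - S * I_f) * I_c - (m / params$M)^(1 / 4))
}

#' Growth rate of a plant without neighbours (lone-plant baseline)
#'
#' `dm/dt = r * A * (1 - S - (m/M)^(1/4))`; identical to
#' [realized_growth_rate()] at `I_c = I_f = 1` and used to integrate the
#' no-neighbour performance baseline for the RII.
#'
#' @inheritParams potential_growth_rate
#' @return Growth rate (mass / time).
#' @export
lone_growth_rate <- function(m, params, S) {
  if (any(m <= 0)) stop("mass must be > 0")
  check_stress(S)
  A <- params$C0 * m^(3 / 4)
  params$r * A * (1 - S - (m / params$M)^(1 / 4))
}

#' Integrate the lone-plant trajectory
#'
#' Forward-Euler integration of the no-neighbour growth equation with the
#' same step length as the simulator, so an isolated simulated plant and
#' this baseline agree step-by-step.
#'
#' @inheritParams potential_growth_rate
#' @param n_steps Number of steps.
#' @param m0 Starting mass (default `params$m0`).
#' @return Numeric vector of masses at steps `0..n_steps`.
#' @export
integrate_lone <- function(params, S, n_steps, m0 = params$m0) {
  check_stress(S)
  m <- numeric(n_steps + 1)
  m[1] <- m0
  for (t in seq_len(n_steps)) {
    mt <- m[t] + params$dt * lone_growth_rate(m[t], params, S)
    m[t + 1] <- min(max(mt, 0), params$M)
    if (m[t + 1] <= params$m_death) {
      m[(t + 1):(n_steps + 1)] <- m[t + 1]
      break
    }
  }
  m
}
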