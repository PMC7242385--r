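#' Deterministic toy plant configurations
#'
#' Small fixed geometries used as oracles for the interaction-field
#' machinery:
#' \describe{
#'   \item{isolated}{one plant, no neighbours.}
#'   \item{coincident-pair}{two identical, fully coincident circles.}
#'   \item{fig5-triplet}{a benefactor X with two beneficiaries: A, small
#'     and fully inside X's ZOI; B, larger, overlapping X partially with
#'     the same overlap area as A (solved from the analytic lens
#'     formula). Equal amelioration, different size — the size-dependent
#'     facilitative response makes `I_f(A) < I_f(B)`.}
#'   \item{disjoint}{three well-separated circles, no overlap.}
#'   \item{lattice}{a 3 x 3 grid of equal circles with slight overlap
#'     between orthogonal neighbours.}
#' }
#'
#' @param case Configuration name.
#' @return Data frame with columns `id`, `label`, `x`, `y`, `A`.
#' @export
generate_toy_geometry <- function(case = c("isolated", "coincident-pair",
                                           "fig5-triplet", "disjoint",
                                           "lattice")) {
  case <- match.arg(case)
  out <- switch(case,
    "isolated" = data.frame(label = "X", x = 100, y = 100, A = pi * 100),
    "coincident-pair" = data.frame(label = c("X1", "X2"),
                                   x = c(100, 100), y = c(100, 100),
                                   A = c(pi * 64, pi * 64)),
    "fig5-triplet" = {
      rX <- 20; rA <- 4; rB <- 12
      # A sits fully inside X => overlap(A, X) = area of A
      target <- pi * rA^2
      # place B so that lens(B, X) equals that same overlap area
      dB <- uniroot(function(d) lens_overlap_area(rB, rX, d) - target,
                    interval = c(rX - rB + 1e-9, rX + rB - 1e-9))$root
      data.frame(label = c("X", "A", "B"),
                 x = c(100, 100 + (rX - rA) / 2, 100 - dB),
                 y = c(100, 100, 100),
                 A = pi * c(rX^2, rA^2, rB^2))
    },
    "disjoint" = data.frame(label = c("X1", "X2", "X3"),
                            x = c(40, 120, 160), y = c(40, 120, 40),
                            A = pi * c(100, 64, 36)),
    "lattice" = {
      g <- expand.grid(i = 0:2, j = 0:2)
      data.frame(label = paste0("L", seq_len(9)),
                 x = 70 + 30 * g$i, y = 70 + 30 * g$j, A = pi * 16^2)
    })
  cbind(id = seq_len(nrow(out)), out)
}

#' Generate synthetic RII records from a known linear model
#'
#' RII is drawn as a Gaussian linear model on standardized stress,
#' density and their product, then clipped to `[-1, 1]` (clip events are
#' reported via a message). Used to exercise the Bayesian machinery with
#' known ground truth.
#'
#' @param coefficients Named vector; any of `(Intercept)`, `S`, `D`,
#'   `SxD` (missing names default to 0).
#' @param design A [factorial_design()].
#' @param noise Residual standard deviation (> 0).
#' @param seed Integer seed.
#' @return Data frame `stress`, `density`, `replicate`, `RII` with
#'   attribute `truth` (the generating coefficients and noise).
#' @export
generate_synthetic_rii <- function(coefficients = c("(Intercept)" = -0.1,
                                                    S = 0.15, D = -0.2,
                                                    SxD = 0.25),
                                   design = factorial_design(),
                                   noise = 0.1, seed = 1L) {
  if (noise <= 0) stop("noise scale must be > 0")
  full <- c("(Intercept)" = 0, S = 0, D = 0, SxD = 0)
  unknown <- setdiff(names(coefficients), names(full))
  if (length(unknown)) stop("unknown coefficient(s): ",
                            paste(unknown, collapse = ", "))
  full[names(coefficients)] <- coefficients
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      density = design$density, stress = design$stress)
  X <- build_design("S+D+SxD", grid$stress, grid$density)
  set.seed(seed)
  rii <- as.numeric(X %*% full) + rnorm(nrow(grid), 0, noise)
  n_clip <- sum(rii < -1 | rii > 1)
  if (n_clip > 0) message(n_clip, " RII value(s) clipped to [-1, 1]")
  out <- data.frame(stress = grid$stress, density = grid$density,
                    replicate = grid$replicate,
                    RII = pmin(pmax(rii, -1), 1))
  attr(out, "truth") <- list(coefficients = full, noise = noise,
                             scaling = attr(X, "scaling"))
  out
}
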