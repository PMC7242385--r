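#' Define a wrap-around simulation arena
#'
#' The arena is a rectangular grid of homogeneous square patches whose
#' opposite edges are identified (a torus), so there are no edge effects.
#' All plant coordinates live in `[0, width) x [0, height)` (cell units).
#'
#' @param width,height Number of patches along each axis (default 200 x 200).
#' @param cell_area Area represented by one patch, in the model's area units.
#' @param torus Logical; the geometry engine assumes wrap-around and only
#'   `TRUE` is supported. The flag is kept so configurations are explicit.
#' @return An object of class `zoi_arena`.
#' @examples
#' arena()           # the default 200 x 200 torus
#' arena(40, 40)     # a small arena for cell-wise reference checks
#' @export
arena <- function(width = 200L, height = 200L, cell_area = 1, torus = TRUE) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stop("arena dimensions must be >= 1")
  if (!is.numeric(cell_area) || cell_area <= 0) stop("cell_area must be > 0")
  if (!isTRUE(torus)) stop("only the wrap-around (torus) topology is supported")
  structure(list(width = width, height = height, cell_area = cell_area,
                 torus = TRUE),
            class = "zoi_arena")
}

#' @export
print.zoi_arena <- function(x, ...) {
  cat(sprintf("<zoi_arena> %d x %d patches, cell_area = %g (torus)\n",
              x$width, x$height, x$cell_area))
  invisible(x)
}

#' ZOI radius from area
#'
#' @param A ZOI area (area units).
#' @return Radius in the same length units as the arena coordinates,
#'   assuming unit cell area corresponds to unit side length.
#' @keywords internal
zoi_radius <- function(A) sqrt(A / pi)

#' Minimum-image (torus) distance between points
#'
#' @param x1,y1,x2,y2 Coordinates.
#' @param arena A [arena()].
#' @return Vector of distances under the wrap-around metric.
#' @export
torus_dist <- function(x1, y1, x2, y2, arena) {
  dx <- abs(x1 - x2); dy <- abs(y1 - y2)
  dx <- pmin(dx, arena$width - dx)
  dy <- pmin(dy, arena$height - dy)
  sqrt(dx^2 + dy^2)
}

wrap_coord <- function(v, n) {
  w <- v %% n
  # guard against w == n from floating roundoff of tiny negatives
  w[w >= n] <- 0
  w
}

#' Rasterize one ZOI circle onto the arena grid
#'
#' A cell is covered iff its centre lies strictly inside the circle, with
#' the minimum-image convention so circles wrap across the arena edges.
#'
#' @param x,y Circle centre (cell units, wrapped into the arena).
#' @param A Circle area (area units).
#' @param arena A [arena()].
#' @return Data frame with 0-based integer columns `cell_x`, `cell_y`.
#' @examples
#' nrow(rasterize_zoi(100, 100, 100 * pi, arena()))  # close to 100 * pi
#' @export
rasterize_zoi <- function(x, y, A, arena) {
  side <- sqrt(arena$cell_area)
  r <- zoi_radius(A) / side
  if (r >= min(arena$width, arena$height) / 2)
    stop("ZOI radius reaches half the arena span; self-overlap on the torus is ill-defined")
  if (A <= 0) return(data.frame(cell_x = integer(0), cell_y = integer(0)))
  cx <- x / side; cy <- y / side
  i <- seq.int(ceiling(cx - r - 0.5), floor(cx + r - 0.5))
  j <- seq.int(ceiling(cy - r - 0.5), floor(cy + r - 0.5))
  if (!length(i) || !length(j))
    return(data.frame(cell_x = integer(0), cell_y = integer(0)))
  g <- expand.grid(i = i, j = j)
  inside <- (g$i + 0.5 - cx)^2 + (g$j + 0.5 - cy)^2 < r^2
  data.frame(cell_x = as.integer(g$i[inside] %% arena$width),
             cell_y = as.integer(g$j[inside] %% arena$height))
}

#' Relative shares of a contested quantity
#'
#' Weight of plant i is `size_i^exponent / sum_j size_j^exponent`. The
#' exponent is the mode of sharing: 0 gives equal shares regardless of
#' size (complete symmetry), 1 gives shares proportional to size, and
#' `Inf` gives everything to the largest plant (complete asymmetry; exact
#' ties split equally).
#'
#' @param sizes Positive sizes (ZOI areas) of the plants covering a cell.
#' @param exponent Sharing exponent `>= 0`, or `Inf`.
#' @return Numeric vector of fractions summing to 1.
#' @examples
#' share_weights(c(1, 3), 0)    # 0.5 0.5
#' share_weights(c(1, 3), 1)    # 0.25 0.75
#' share_weights(c(1, 3), Inf)  # 0 1
#' @export
share_weights <- function(sizes, exponent) {
  if (!length(sizes)) stop("empty size vector")
  if (any(sizes <= 0)) stop("all sizes must be > 0")
  if (is.na(exponent) || exponent < 0) stop("exponent must be >= 0 or Inf")
  if (is.infinite(exponent)) {
    w <- as.numeric(sizes == max(sizes))
    return(w / sum(w))
  }
  if (exponent == 0) return(rep(1 / length(sizes), length(sizes)))
  w <- (sizes / max(sizes))^exponent
  if (sum(w) == 0) return(rep(1 / length(sizes), length(sizes)))
  w / sum(w)
}

check_plants_df <- function(plants) {
  need <- c("x", "y", "A")
  if (!all(need %in% names(plants)))
    stop("plants must have columns x, y, A")
  if (is.null(plants$id)) plants$id <- seq_len(nrow(plants))
  plants
}

#' Compute the per-plant interaction field
#'
#' Rasterizes every ZOI onto the arena and divides each contested cell
#' among its coverers. Resources: one `cell_area` is split with p-weights
#' (competition), plant i obtaining `w_p_i * cell_area` towards `A_c`.
#' Stress: the cell's stress burden is shared with q-weights — coverer i
#' bears `w_q_i` of it and neighbours shield it from the rest, so its
#' amelioration gains `(1 - w_q_i) * cell_area` towards `A_f`. A small
#' plant overlapped by a large benefactor therefore sheds almost all
#' stress in the shared zone (nurse-plant shielding), and per-capita
#' relief grows with local crowding — the reason more neighbours help
#' under more severe stress. At `q = Inf` the largest coverer bears the
#' entire shared stress and receives no relief. Cells covered by a single
#' plant count fully towards that plant's obtained resources `A_c` and
#' contribute nothing to its amelioration `A_f`. All areas entering the
#' indices are measured in rasterized cells, so the bounds `I_c, I_f` in
#' `[0, 1]` hold exactly:
#' \deqn{I_c = A_c / A, \qquad I_f = 1 - A_f / A.}
#' `I_c` is the proportion of its potential resources a plant actually
#' obtains under competition; `I_f` is the proportion of ambient stress it
#' still experiences after neighbours' amelioration. Plants whose circle
#' rasterizes to zero cells take `I_c = I_f = 1` by convention.
#'
#' @param plants Data frame with columns `x`, `y`, `A` (and optionally `id`).
#' @param arena A [arena()].
#' @param p,q Sharing exponents for competition and facilitation
#'   (see [share_weights()]).
#' @param engine `"cpp"` (fast path) or `"r"` (cell-wise reference
#'   enumeration; small arenas only). Both are observationally equivalent.
#' @return Data frame with columns `id`, `A` (continuous input area),
#'   `A_rast`, `A_c`, `A_f`, `I_c`, `I_f`.
#' @examples
#' pl <- data.frame(x = c(50, 50), y = c(50, 50), A = c(200, 200))
#' compute_field(pl, arena(), p = 1, q = 1)  # coincident pair: 0.5 each
#' @export
compute_field <- function(plants, arena, p = 1, q = 1,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  plants <- check_plants_df(plants)
  n <- nrow(plants)
  if (n == 0L)
    return(data.frame(id = integer(0), A = numeric(0), A_rast = numeric(0),
                      A_c = numeric(0), A_f = numeric(0),
                      I_c = numeric(0), I_f = numeric(0)))
  if (engine == "cpp") {
    fld <- zoi_field_cpp(wrap_coord(plants$x, arena$width),
                         wrap_coord(plants$y, arena$height),
                         plants$A, arena$width, arena$height,
                         arena$cell_area, p, q)
  } else {
    fld <- field_cellwise(plants, arena, p, q)
  }
  A_rast <- fld$A_rast
  I_c <- ifelse(A_rast > 0, fld$A_c / A_rast, 1)
  I_f <- ifelse(A_rast > 0, 1 - fld$A_f / A_rast, 1)
  data.frame(id = plants$id, A = plants$A, A_rast = A_rast,
             A_c = fld$A_c, A_f = fld$A_f, I_c = I_c, I_f = I_f)
}

# Cell-wise reference enumeration: loop over every arena cell, find its
# coverers by the torus metric, and apply share_weights() directly. The
# fast engine must match this on any input (tested on small arenas).
field_cellwise <- function(plants, arena, p, q) {
  side <- sqrt(arena$cell_area)
  r <- zoi_radius(plants$A) / side
  if (any(r >= min(arena$width, arena$height) / 2))
    stop("ZOI radius reaches half the arena span; self-overlap on the torus is ill-defined")
  n <- nrow(plants)
  A_rast <- A_c <- A_f <- numeric(n)
  cx <- wrap_coord(plants$x, arena$width) / side
  cy <- wrap_coord(plants$y, arena$height) / side
  for (j in seq_len(arena$height) - 1L) {
    for (i in seq_len(arena$width) - 1L) {
      dx <- abs(i + 0.5 - cx); dx <- pmin(dx, arena$width - dx)
      dy <- abs(j + 0.5 - cy); dy <- pmin(dy, arena$height - dy)
      cov <- which(dx^2 + dy^2 < r^2)
      k <- length(cov)
      if (k == 0L) next
      A_rast[cov] <- A_rast[cov] + arena$cell_area
      if (k == 1L) {
        A_c[cov] <- A_c[cov] + arena$cell_area
      } else {
        A_c[cov] <- A_c[cov] +
          arena$cell_area * share_weights(plants$A[cov], p)
        A_f[cov] <- A_f[cov] +
          arena$cell_area * (1 - share_weights(plants$A[cov], q))
      }
    }
  }
  list(A_rast = A_rast, A_c = A_c, A_f = A_f)
}

#' Exact two-circle overlap (lens) area
#'
#' Closed-form area of intersection of two circles on the plane (no
#' wrapping); used as the analytic oracle for the rasterized geometry.
#'
#' @param r1,r2 Radii.
#' @param d Centre distance.
#' @return Overlap area; 0 when disjoint, the smaller circle's area under
#'   containment.
#' @export
lens_overlap_area <- function(r1, r2, d) {
  stopifnot(r1 >= 0, r2 >= 0, d >= 0)
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  d1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  d2 <- d - d1
  seg <- function(r, h) r^2 * acos(pmin(pmax(h / r, -1), 1)) -
    h * sqrt(pmax(r^2 - h^2, 0))
  seg(r1, d1) + seg(r2, d2)
}

#' Per-cell coverage table (debug dump)
#'
#' Enumerates every covered cell with the ids of the plants covering it;
#' intended for inspecting small configurations.
#'
#' @inheritParams compute_field
#' @param file Optional path; when given the table is written as CSV.
#' @return Data frame `cell_x`, `cell_y`, `plant_ids` (ids separated by
#'   `;`), invisibly when written to file.
#' @export
coverage_table <- function(plants, arena, file = NULL) {
  plants <- check_plants_df(plants)
  cells <- do.call(rbind, lapply(seq_len(nrow(plants)), function(k) {
    cc <- rasterize_zoi(plants$x[k], plants$y[k], plants$A[k], arena)
    if (nrow(cc)) cc$plant_id <- plants$id[k]
    cc
  }))
  if (is.null(cells) || nrow(cells) == 0L)
    return(data.frame(cell_x = integer(0), cell_y = integer(0),
                      plant_ids = character(0)))
  key <- paste(cells$cell_x, cells$cell_y)
  ids <- vapply(split(cells$plant_id, key),
                function(v) paste(sort(v), collapse = ";"), character(1))
  xy <- do.call(rbind, strsplit(names(ids), " "))
  out <- data.frame(cell_x = as.integer(xy[, 1]), cell_y = as.integer(xy[, 2]),
                    plant_ids = unname(ids), stringsAsFactors = FALSE)
  out <- out[order(out$cell_y, out$cell_x), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(file)) {
    write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
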