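test_that("rasterization covers the analytic area and respects the torus", {
  ar <- arena()
  expect_equal(nrow(rasterize_zoi(50, 50, 0, ar)), 0)

  # translation invariance across the wrap-around edge
  n_origin <- nrow(rasterize_zoi(0, 0, pi * 9, ar))
  n_centre <- nrow(rasterize_zoi(100, 100, pi * 9, ar))
  expect_identical(n_origin, n_centre)

  # covered-cell count approximates the circle area, converging as the
  # radius grows relative to the (unit) cells
  for (r in c(5.5, 10.2, 40.7)) {
    n <- nrow(rasterize_zoi(77.3, 41.9, pi * r^2, ar))
    expect_lt(abs(n - pi * r^2) / (pi * r^2), 10 / r) # perimeter-bound error
  }
  n <- nrow(rasterize_zoi(100, 100, 100 * pi, ar))
  expect_lt(abs(n - 100 * pi) / (100 * pi), 0.1)

  # a circle reaching half the arena span is rejected
  expect_error(rasterize_zoi(100, 100, pi * 100^2, ar), "half the arena")
})

test_that("share weights cover symmetric, proportional and winner-takes-all modes", {
  expect_equal(share_weights(c(1, 3), 0), c(0.5, 0.5))
  expect_equal(share_weights(c(1, 3), 1), c(0.25, 0.75))
  expect_equal(share_weights(c(1, 3), Inf), c(0, 1))
  expect_equal(share_weights(c(2, 2, 2), Inf), rep(1 / 3, 3)) # tied maxima
  expect_equal(sum(share_weights(runif(7, 0.1, 9), 2.3)), 1)
  expect_error(share_weights(numeric(0), 1))
  expect_error(share_weights(c(1, -1), 1))
  expect_error(share_weights(c(1, 2), -0.5))
})

test_that("interaction field matches the frozen oracles", {
  ar <- arena()
  # a single plant competes and is stressed in full
  f1 <- compute_field(data.frame(x = 30, y = 40, A = 200), ar)
  expect_equal(f1$I_c, 1)
  expect_equal(f1$I_f, 1)
  expect_equal(f1$A_c, f1$A_rast)
  expect_equal(f1$A_f, 0)

  # two coincident equal circles split every cell 50/50
  f2 <- compute_field(data.frame(x = c(50, 50), y = c(50, 50),
                                 A = c(200, 200)), ar)
  expect_equal(f2$I_c, c(0.5, 0.5))
  expect_equal(f2$I_f, c(0.5, 0.5))

  # zero-area plant: no interaction by convention
  f3 <- compute_field(data.frame(x = c(10, 10), y = c(10, 10),
                                 A = c(0, 50)), ar)
  expect_equal(f3$I_c, c(1, 1))
  expect_equal(f3$I_f, c(1, 1))
})

test_that("fast engine is observationally equivalent to cell-wise enumeration", {
  set.seed(42)
  ar <- arena(32, 24)
  for (i in 1:6) {
    n <- sample(2:6, 1)
    pl <- data.frame(x = runif(n, 0, 32), y = runif(n, 0, 24),
                     A = runif(n, 0.5, 120))
    for (ex in list(c(1, 1), c(0, 0), c(2.5, 0.7), c(Inf, 1), c(1, Inf))) {
      fc <- compute_field(pl, ar, p = ex[1], q = ex[2])
      fr <- compute_field(pl, ar, p = ex[1], q = ex[2], engine = "r")
      expect_equal(fc, fr, tolerance = 1e-12)
    }
  }
})

test_that("field invariants hold on random configurations", {
  set.seed(99)
  ar <- arena(60, 60)
  for (i in 1:40) {
    n <- sample(2:7, 1)
    pl <- data.frame(id = seq_len(n), x = runif(n, 0, 60),
                     y = runif(n, 0, 60), A = runif(n, 1, 500))
    p <- sample(c(0, 0.5, 1, 2, Inf), 1)
    q <- sample(c(0, 0.5, 1, 2), 1)
    f <- compute_field(pl, ar, p, q)
    # bounds
    expect_true(all(f$I_c >= 0 & f$I_c <= 1))
    expect_true(all(f$I_f >= 0 & f$I_f <= 1))
    expect_true(all(f$A_c <= f$A_rast + 1e-9))
    expect_true(all(f$A_f <= f$A_rast + 1e-9))
    # conservation: obtained resources sum to the union's rasterized area
    cells <- unlist(lapply(seq_len(n), function(k)
      rasterized_cells(pl$x[k], pl$y[k], pl$A[k], ar)))
    expect_equal(sum(f$A_c), length(unique(cells)) * ar$cell_area,
                 tolerance = 1e-9)
    # permuting plants leaves per-plant indices unchanged
    perm <- sample(n)
    fp <- compute_field(pl[perm, ], ar, p, q)
    expect_equal(fp[order(fp$id), ]$I_c, f$I_c, tolerance = 1e-12)
    expect_equal(fp[order(fp$id), ]$I_f, f$I_f, tolerance = 1e-12)
    # facilitation requires a shared cell (finite q)
    shared <- vapply(seq_len(n), function(k) {
      own <- rasterized_cells(pl$x[k], pl$y[k], pl$A[k], ar)
      other <- unlist(lapply(setdiff(seq_len(n), k), function(j)
        rasterized_cells(pl$x[j], pl$y[j], pl$A[j], ar)))
      length(intersect(own, other)) > 0
    }, logical(1))
    expect_equal(f$A_f > 0, shared)
  }
})

test_that("the larger plant's resource share is non-decreasing in p", {
  ar <- arena(60, 60)
  pl <- data.frame(x = c(25, 32), y = c(30, 30), A = c(150, 450))
  shares <- vapply(c(0, 0.5, 1, 2, 5, Inf), function(p)
    compute_field(pl, ar, p = p)$A_c[2], numeric(1))
  expect_true(all(diff(shares) >= -1e-9))
})

test_that("closed-form lens area matches geometry limits and brute force", {
  expect_equal(lens_overlap_area(2, 5, 1), 4 * pi)        # containment
  expect_equal(lens_overlap_area(3, 3, 10), 0)            # disjoint
  d <- 3; r <- 3
  expect_equal(lens_overlap_area(r, r, d),
               2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2))
  # Monte Carlo cross-check on an asymmetric pair
  set.seed(3)
  r1 <- 4; r2 <- 2.5; d <- 3.2
  pts <- cbind(runif(2e5, -r1, r1), runif(2e5, -r1, r1))
  inside <- pts[, 1]^2 + pts[, 2]^2 < r1^2 &
    (pts[, 1] - d)^2 + pts[, 2]^2 < r2^2
  expect_equal(lens_overlap_area(r1, r2, d), mean(inside) * (2 * r1)^2,
               tolerance = 0.02)
})

test_that("rasterized pairwise overlap converges to the analytic lens area", {
  ar <- arena()
  # same shape at growing scale: finer effective resolution
  rel_err <- vapply(c(4, 8, 16), function(r) {
    d <- 1.2 * r
    a <- rasterized_cells(60, 60, pi * r^2, ar)
    b <- rasterized_cells(60 + d, 60, pi * r^2, ar)
    exact <- lens_overlap_area(r, r, d)
    abs(length(intersect(a, b)) - exact) / exact
  }, numeric(1))
  expect_lt(rel_err[2], rel_err[1] + 0.02)
  expect_lt(rel_err[3], 0.05)
})

test_that("coverage table lists covering plants per cell", {
  ar <- arena(20, 20)
  pl <- data.frame(id = c(1, 2), x = c(5, 5), y = c(5, 5), A = c(10, 10))
  ct <- coverage_table(pl, ar)
  expect_true(all(ct$plant_ids == "1;2"))
  expect_equal(nrow(ct), compute_field(pl, ar)$A_rast[1])
  f <- tempfile(fileext = ".csv")
  coverage_table(pl, ar, file = f)
  expect_equal(read.csv(f, colClasses = c(plant_ids = "character")), ct)
})
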