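test_that("potential growth rate has the right zeros and signs", {
  gp <- growth_params()
  expect_equal(potential_growth_rate(gp$M, gp, 0), 0)
  # stress-dependent fixed point m* = M (1 - S)^4
  for (S in c(0.2, 0.45, 0.75)) {
    expect_equal(potential_growth_rate(gp$M * (1 - S)^4, gp, S), 0,
                 tolerance = 1e-12)
  }
  expect_lt(potential_growth_rate(500, gp, 1), 0)  # no resources at S = 1
  expect_error(potential_growth_rate(-1, gp, 0))
  expect_error(potential_growth_rate(10, gp, 1.2))
})

test_that("realized growth reduces to the isolated form when a = r * C0", {
  gp <- growth_params()
  m <- exp(seq(log(gp$m0), log(gp$M), length.out = 25))
  for (S in c(0, 0.3, 0.45, 0.75, 0.85, 1)) {
    expect_equal(realized_growth_rate(m, 1, 1, gp, S),
                 potential_growth_rate(m, gp, S), tolerance = 1e-12)
    expect_equal(lone_growth_rate(m, gp, S),
                 realized_growth_rate(m, 1, 1, gp, S), tolerance = 1e-14)
  }
  # full amelioration cancels stress; no resources force decline
  expect_equal(realized_growth_rate(100, 1, 0, gp, 0.85),
               potential_growth_rate(100, gp, 0), tolerance = 1e-12)
  A <- gp$C0 * 100^(3 / 4)
  expect_equal(realized_growth_rate(100, 0, 1, gp, 0.3),
               -gp$r * A * (100 / gp$M)^(1 / 4), tolerance = 1e-12)
  expect_error(realized_growth_rate(100, 1.4, 1, gp, 0))
})

test_that("isolated plants converge monotonically to M (1 - S)^4", {
  gp <- growth_params()
  for (S in c(0, 0.45, 0.75)) {
    m <- integrate_lone(gp, S, 400)
    tgt <- gp$M * (1 - S)^4
    expect_lt(abs(m[401] - tgt) / tgt, 1e-3)
    expect_true(all(diff(m) >= -1e-12))  # monotone approach from below
  }
  # the default seedling mass is the extreme-stress equilibrium: static
  m <- integrate_lone(gp, 0.85, 50)
  expect_equal(m, rep(gp$m0, 51), tolerance = 1e-12)
})

test_that("population initialization honours pattern, count and seed", {
  cfg <- sim_config(n_plants = 37, seed = 11)
  for (pat in c("random", "regular", "aggregated")) {
    cfg$pattern <- pat
    pop <- init_population(cfg)
    expect_equal(nrow(pop), 37)
    expect_true(all(pop$x >= 0 & pop$x < 200 & pop$y >= 0 & pop$y < 200))
    expect_true(all(pop$m == cfg$params$m0) && all(pop$alive))
    expect_identical(pop, init_population(cfg))   # determinism
  }
  # regular: 4 plants on a 200 x 200 torus sit 100 apart
  cfg4 <- sim_config(n_plants = 4, pattern = "regular")
  pop4 <- init_population(cfg4)
  d <- outer(seq_len(4), seq_len(4), Vectorize(function(i, j)
    torus_dist(pop4$x[i], pop4$y[i], pop4$x[j], pop4$y[j], cfg4$arena)))
  expect_equal(sort(unique(round(d[upper.tri(d)], 9))),
               c(100, round(100 * sqrt(2), 9)))
  expect_error(sim_config(n_plants = 0))
})

test_that("synchronous stepping preserves symmetry and caps masses", {
  gp <- growth_params()
  cfg <- sim_config(params = gp, S = 0, n_plants = 2, seed = 1)
  pop <- init_population(cfg)
  pop$x <- c(80, 80); pop$y <- c(80, 80)   # coincident pair
  for (i in 1:30) {
    pop <- sim_step(pop, cfg)
    expect_equal(pop$m[1], pop$m[2], tolerance = 1e-12)
  }
  expect_true(all(pop$m <= gp$M))
})

test_that("a lone simulated plant follows the no-neighbour integration exactly", {
  cfg <- sim_config(S = 0.45, n_plants = 1, n_steps = 50, seed = 5)
  sim <- run_simulation(cfg, full_trajectory = TRUE)
  ref <- integrate_lone(cfg$params, 0.45, 50)
  expect_equal(sim$trajectory$m, ref, tolerance = 1e-12)
})

test_that("simulations are bit-identical under a fixed seed and bounded", {
  cfg <- sim_config(S = 0.75, n_plants = 60, n_steps = 20, seed = 9)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_true(all(s1$trajectory$m[s1$trajectory$alive] > 0))
  expect_true(all(s1$trajectory$m <= cfg$params$M))
  expect_equal(s1$summary$step, c(0, 10, 20))
  # crowding reduces mean mass below the lone baseline at S = 0
  cfg0 <- sim_config(S = 0, n_plants = 200, n_steps = 30, seed = 2)
  s0 <- run_simulation(cfg0)
  expect_lt(s0$summary$mean_mass[nrow(s0$summary)],
            lone_baseline(0, cfg0$params, 30))
})

test_that("halving the step length changes lone outcomes by under 1 percent", {
  for (S in c(0, 0.45, 0.75, 0.85)) {
    m1 <- lone_baseline(S, growth_params(), 50)
    gph <- growth_params(dt = 0.5)
    m2 <- integrate_lone(gph, S, 100)[101]
    expect_lt(abs(m1 - m2) / m2, 0.03)
  }
})
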