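# Shared fixtures for the suite. The default factorial experiment is the
# most expensive object several tests need; compute it once per session.

.cache <- new.env(parent = emptyenv())

default_factorial <- function() {
  if (is.null(.cache$factorial))
    .cache$factorial <- run_factorial(seed = 1)
  .cache$factorial
}

# classification + peak summary of a factorial table, one row per stress
shape_summary <- function(records) {
  s <- summarize_rii(records)
  do.call(rbind, lapply(split(s, s$stress), function(ss)
    data.frame(stress = ss$stress[1],
               shape = classify_shape(ss$mean_rii, ss$sem),
               peak = peak_density(ss$mean_rii, ss$density),
               low = ss$mean_rii[1], low_sem = ss$sem[1],
               high = ss$mean_rii[nrow(ss)], high_sem = ss$sem[nrow(ss)])))
}

# small factorial used by mechanics tests (fast, not the study design)
tiny_factorial <- function(seed = 7) {
  run_factorial(factorial_design(stress = c(0, 0.75), density = 2:4,
                                 replicates = 2L, n_steps = 10L),
                config = sim_config(),
                seed = seed, plants_per_level = 5L)
}

rasterized_cells <- function(x, y, A, arena) {
  cc <- rasterize_zoi(x, y, A, arena)
  paste(cc$cell_x, cc$cell_y)
}
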