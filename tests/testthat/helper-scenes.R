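# Shared small-scale simulation conditions for fast unit tests: a hexagonal
# toy crystal an order of magnitude smaller than the PSI-like reference, so
# enumeration boxes stay tiny. Scenes are cached per (seed, noise) within a
# test run.

toy_conditions <- function() {
  list(cell = unit_cell(40, 40, 30, 90, 90, 120),
       symmetry = "hexagonal_622",
       beam = beam(1.5),
       det = detector(50, 0.1, 1400L, 1400L),
       envelope = mosaic_envelope(0.3, 1500),
       d_range = c(8, 2))
}

toy_scene_cache <- new.env(parent = emptyenv())

toy_scene <- function(seed = 1L, noise_sigma_mm = 0) {
  key <- paste0("s", seed, "_", noise_sigma_mm)
  if (!is.null(toy_scene_cache[[key]])) return(toy_scene_cache[[key]])
  tc <- toy_conditions()
  sc <- simulate_still(cell = tc$cell, symmetry = tc$symmetry,
                       envelope = tc$envelope, beam = tc$beam, det = tc$det,
                       d_range = tc$d_range,
                       noise_sigma_mm = noise_sigma_mm, seed = seed)
  toy_scene_cache[[key]] <- sc
  sc
}

# random unit vector from the current RNG stream
runit3 <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}
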