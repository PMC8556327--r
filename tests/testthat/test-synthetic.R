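test_that("generators are deterministic given a seed", {
  r1 <- build_ring(ring_spec(n = 3, jitter_sigma = 0.3, seed = 7))
  r2 <- build_ring(ring_spec(n = 3, jitter_sigma = 0.3, seed = 7))
  r3 <- build_ring(ring_spec(n = 3, jitter_sigma = 0.3, seed = 8))
  expect_identical(r1$assembly$atoms, r2$assembly$atoms)
  expect_false(isTRUE(all.equal(r1$assembly$atoms$x, r3$assembly$atoms$x)))
  # jitter does not leak into the global RNG stream
  set.seed(123); x1 <- rnorm(1)
  set.seed(123); invisible(build_ring(ring_spec(n = 3, jitter_sigma = 0.2)))
  expect_identical(rnorm(1), x1)
})

test_that("simulated experiments reproduce their noise model", {
  buf <- cpc_buffer
  spec0 <- auc_spec(species = data.frame(s = numeric(0), f_ratio = numeric(0),
                                         loading = numeric(0)),
                    noise_sigma = 0.005, times = c(300, 600), seed = 1)
  ds <- simulate_auc(spec0, buffer = buf, ncell = 200)
  expect_equal(mean(ds$scans), 0, tolerance = 3 * 0.005 / sqrt(length(ds$scans)))
  expect_equal(stats::sd(as.numeric(ds$scans)), 0.005, tolerance = 0.2)
  # seeded reproducibility
  sp <- auc_spec(times = seq(600, 3000, by = 600), seed = 4)
  d1 <- simulate_auc(sp, buffer = buf, ncell = 200)
  d2 <- simulate_auc(sp, buffer = buf, ncell = 200)
  expect_identical(d1$scans, d2$scans)
})

test_that("peak recovery is stable across noise seeds", {
  buf <- cpc_buffer
  base <- list(species = data.frame(s = c(3.15, 5.24, 7.97, 11.32),
                                    f_ratio = 1.195,
                                    loading = c(0.15, 0.6, 0.1, 0.15)),
               times = seq(600, 9000, by = 600))
  peaks_for_seed <- function(seed) {
    sp <- auc_spec(species = base$species, noise_sigma = 0.005,
                   times = base$times, seed = seed)
    ds <- simulate_auc(sp, buffer = buf, ncell = 250)
    fit <- fit_cs(ds, s_grid = seq(1, 15, length.out = 75), f_ratio = 1.195,
                  buffer = buf, thin = 2)
    sort(peaks_to_species(fit)$s_obs)
  }
  p1 <- peaks_for_seed(1)
  p2 <- peaks_for_seed(2)
  expect_equal(length(p1), 4)
  expect_equal(length(p2), 4)
  expect_lt(max(abs(p1 - p2)), 0.2)
})

test_that("fixtures written by the generator round-trip", {
  path <- tempfile(fileext = ".cif")
  write_fixture(ring_c4, path, format = "mmcif")
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(ring_c4$assembly$atoms))
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(ring_c4$assembly$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})
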