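faxen_midpoint <- function(radii, scan) {
  plat <- stats::median(scan[radii > 6.6 & radii < 7.0])
  i <- which(scan > plat / 2)[1]
  stats::approx(scan[(i - 1):i], radii[(i - 1):i], xout = plat / 2)$y
}

test_that("closed-cell Lamm solutions conserve mass", {
  buf <- cpc_buffer
  sp <- data.frame(s = c(3.15, 11.32),
                   D = diffusion_coefficient(c(3.15, 11.32), 1.195, buf),
                   loading = c(0.4, 0.6))
  ds <- lamm_simulate(sp, times = seq(0, 8000, by = 1000), buffer = buf)
  m <- cell_mass(ds)
  expect_lt(max(abs(m - m[1])) / m[1], 0.001)
})

test_that("zero rotor speed gives pure diffusion towards a uniform profile", {
  still <- hydro_params(rotor_rpm = 0)
  sp <- data.frame(s = 5, D = 5e-6, loading = 1)
  ds <- lamm_simulate(sp, times = c(0, 2e4, 2e5), buffer = still, ncell = 200)
  m <- cell_mass(ds)
  expect_lt(max(abs(m - m[1])) / m[1], 1e-10)
  # long-time profile is flat
  final <- ds$scans[3, ]
  expect_lt(max(final) - min(final), 0.02 * mean(final))
})

test_that("zero loading and empty species give zero scans", {
  buf <- cpc_buffer
  ds <- lamm_simulate(data.frame(s = 5, D = 5e-7, loading = 0),
                      times = c(0, 1000), buffer = buf, ncell = 100)
  expect_true(all(ds$scans == 0))
  ds2 <- lamm_simulate(data.frame(s = numeric(0), D = numeric(0),
                                  loading = numeric(0)),
                       times = c(0, 1000), buffer = buf, ncell = 100,
                       baseline = 0.1)
  expect_true(all(ds2$scans == 0.1))
})

test_that("non-diffusing boundary follows the exponential boundary law", {
  buf <- cpc_buffer
  sp <- data.frame(s = 5.24, D = 3e-8, loading = 1)
  ds <- lamm_simulate(sp, times = c(1500, 3000), buffer = buf)
  for (k in 1:2) {
    mid <- faxen_midpoint(ds$radii, ds$scans[k, ])
    pred <- 6.0 * exp(5.24e-13 * buf$omega2 * ds$times[k])
    expect_lt(abs(mid - pred) / pred, 0.01)
  }
})

test_that("under-resolved grids are rejected with a Peclet error", {
  buf <- cpc_buffer
  sp <- data.frame(s = 5.24, D = 1e-10, loading = 1)
  expect_error(lamm_simulate(sp, times = c(0, 100), buffer = buf),
               "Peclet")
  expect_error(lamm_simulate(data.frame(s = 5, D = 5e-7, loading = 1),
                             times = c(100, 50), buffer = buf),
               "nondecreasing")
})

test_that("scan CSV round-trip preserves the dataset", {
  buf <- cpc_buffer
  sp <- data.frame(s = 5.24, D = diffusion_coefficient(5.24, 1.195, buf),
                   loading = 0.8)
  ds <- lamm_simulate(sp, times = c(600, 1200), buffer = buf, ncell = 150)
  path <- tempfile(fileext = ".csv")
  write_scans(ds, path)
  back <- read_scans(path, buffer = buf)
  expect_equal(back$times, ds$times)
  expect_equal(back$radii, ds$radii, tolerance = 1e-9)
  expect_equal(back$scans, ds$scans, tolerance = 1e-6, ignore_attr = TRUE)
})
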