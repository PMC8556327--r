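one_atom <- function(el, x = 0, y = 0, z = 0, hetero = FALSE)
  data.frame(element = el, name = el, resid = "LIG", resno = 1L, chain = "X",
             x = x, y = y, z = z, hetero = hetero, occ = 1, b = 0)

test_that("single-sphere and far-apart SASA match the closed form", {
  a <- shrake_rupley_sasa(one_atom("C"), probe = 1.4, n_points = 960)
  expect_equal(a$total, 4 * pi * 3.10^2, tolerance = 0.005)
  two <- rbind(one_atom("C"), one_atom("C", x = 100))
  expect_equal(shrake_rupley_sasa(two)$total, 2 * 4 * pi * 3.10^2,
               tolerance = 1e-9)
  expect_error(shrake_rupley_sasa(one_atom("XX")), "XX")
})

test_that("two overlapping spheres match the analytic cap area", {
  R <- 1.70 + 1.4
  for (d in c(2.0, 3.5, 5.0)) {
    two <- rbind(one_atom("C"), one_atom("C", x = d))
    got <- shrake_rupley_sasa(two)$total
    want <- 2 * (4 * pi * R^2 - two_sphere_cap_area(R, d))
    expect_equal(got, want, tolerance = 0.01)
    expect_lt(got, 2 * 4 * pi * R^2)
  }
})

test_that("interface burial matches the cap oracle and is symmetric", {
  d <- 3.5
  A <- one_atom("C")
  B <- one_atom("C", x = d)
  B$chain <- "Y"
  rep_ab <- interface_report(A, B)
  rep_ba <- interface_report(B, A)
  R <- 1.70 + 1.4
  expect_equal(rep_ab$buried, two_sphere_cap_area(R, d), tolerance = 0.01)
  expect_equal(rep_ab$buried, rep_ba$buried, tolerance = 1e-9)
  expect_gte(rep_ab$buried, -0.1)
  # far-apart parts bury nothing
  Bfar <- B; Bfar$x <- 100
  rep0 <- interface_report(A, Bfar)
  expect_equal(rep0$buried, 0, tolerance = 1e-9)
  expect_equal(contact_percent(rep0$buried, rep0$asa_a - rep0$buried), 0)
  # overlapping atom identities across parts are refused
  expect_error(interface_report(A, A), "both parts")
})

test_that("SASA converges under point-count doubling", {
  at <- subset_atoms(ring_c4$assembly)
  t1 <- shrake_rupley_sasa(at, n_points = 960)$total
  t2 <- shrake_rupley_sasa(at, n_points = 1920)$total
  expect_lt(abs(t2 - t1) / t2, 0.003)
})

test_that("contact percentage formula and errors", {
  expect_equal(contact_percent(0, 100), 0)
  expect_equal(contact_percent(50, 50), 50)
  expect_equal(contact_percent(26, 74), 26)
  expect_error(contact_percent(0, 0), "zero")
  expect_error(contact_percent(-1, 5), "non-negative")
})

test_that("solvation estimate: zero burial, linearity, analytic oracle", {
  A <- one_atom("C")
  Bfar <- one_atom("C", x = 100); Bfar$chain <- "Y"
  expect_equal(solvation_energy_estimate(A, Bfar), 0, tolerance = 1e-9)
  # two overlapping carbons: estimate = -2 * asp_C * cap area
  d <- 3.5
  B <- one_atom("C", x = d); B$chain <- "Y"
  R <- 1.70 + 1.4
  asp <- c(C = 0.016)
  got <- solvation_energy_estimate(A, B, asp = asp)
  want <- -2 * 0.016 * two_sphere_cap_area(R, d)
  expect_equal(got, want, tolerance = 0.01)
  # doubling the solvation parameter doubles the estimate
  expect_equal(solvation_energy_estimate(A, B, asp = c(C = 0.032)), 2 * got,
               tolerance = 1e-9)
  expect_error(solvation_energy_estimate(A, within(B, element <- "FE")),
               "FE")
})
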