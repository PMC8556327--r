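test_that("vertex angles: basic values, invariances, degenerate input", {
  expect_equal(vertex_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(vertex_angle(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0)), 180)
  expect_error(vertex_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "coincident")
  # swap and rigid-motion invariance
  set.seed(3)
  for (k in 1:5) {
    p <- matrix(rnorm(9, sd = 5), 3, 3)
    a0 <- vertex_angle(p[1, ], p[2, ], p[3, ])
    expect_equal(vertex_angle(p[3, ], p[2, ], p[1, ]), a0)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    q <- p %*% t(R) + matrix(rnorm(3), 3, 3, byrow = TRUE)
    expect_equal(vertex_angle(q[1, ], q[2, ], q[3, ]), a0, tolerance = 1e-9)
  }
})

test_that("ideal rings give exact interface rotations and detected orders", {
  for (n in c(3, 4, 6, 8)) {
    ring <- build_ring(ring_spec(n = n, layers = 1))
    asm <- ring$assembly
    for (i in seq_len(n) - 1L)
      expect_equal(interface_rotation(asm, i, (i + 1) %% n), 360 / n,
                   tolerance = 1e-6 / (360 / n))
    expect_lt(interface_rotation(asm, 0, 0), 1e-4)
    sym <- detect_symmetry(asm)
    expect_equal(sym$order_n, n)
    expect_equal(sym$sym_type, "Cn")
    expect_equal(mean(sym$per_interface_angle), 360 / n, tolerance = 1e-9)
  }
  for (n in c(3, 4)) {
    sym <- detect_symmetry(build_ring(ring_spec(n = n, layers = 2))$assembly)
    expect_equal(sym$order_n, n)
    expect_equal(sym$sym_type, "Dn")
    expect_equal(sym$layers, 2)
  }
})

test_that("construction bend and adjacent angles are recovered", {
  for (ang in c(100, 110, 123)) {
    ring <- build_ring(ring_spec(n = 4, bend_angle = ang, adjacent_angle = 52))
    expect_equal(attr(monomer_bend_angle(ring$assembly), "mean"), ang,
                 tolerance = 0.5 / ang)
  }
  for (ang in c(52, 90)) {
    ring <- build_ring(ring_spec(n = 4, bend_angle = 110, adjacent_angle = ang))
    expect_equal(attr(adjacent_monomer_angle(ring$assembly), "mean"), ang,
                 tolerance = 0.5 / ang)
  }
  # missing anchor residue is named in the error
  expect_error(monomer_bend_angle(ring_c4$assembly,
                                  anchors = list(c("alpha", 70),
                                                 c("alpha", 999),
                                                 c("beta", 70))),
               "alpha999")
})

test_that("symmetry detection is invariant under global rigid motion", {
  moved <- random_rigid(ring_d3$assembly, seed = 11)
  s0 <- detect_symmetry(ring_d3$assembly)
  s1 <- detect_symmetry(moved)
  expect_equal(s1$order_n, s0$order_n)
  expect_equal(s1$sym_type, s0$sym_type)
  expect_equal(s1$mean_angle_residual, s0$mean_angle_residual,
               tolerance = 1e-6)
  expect_equal(attr(monomer_bend_angle(moved), "mean"),
               attr(monomer_bend_angle(ring_d3$assembly), "mean"),
               tolerance = 1e-6)
  expect_equal(attr(adjacent_monomer_angle(moved), "mean"),
               attr(adjacent_monomer_angle(ring_d3$assembly), "mean"),
               tolerance = 1e-6)
})

test_that("jittered rings keep their detected order and approximate angles", {
  ring <- build_ring(ring_spec(n = 4, layers = 1, jitter_sigma = 0.3,
                               seed = 5))
  sym <- detect_symmetry(ring$assembly)
  expect_equal(sym$order_n, 4)
  # 0.3 A jitter on anchors 6-8 A from the vertex propagates to about
  # 0.3/7 rad ~ 2.5 deg per copy; the 4-copy mean stays within ~2 deg
  expect_equal(attr(monomer_bend_angle(ring$assembly), "mean"),
               ring$truth$bend_angle, tolerance = 2 / 110)
  expect_equal(attr(adjacent_monomer_angle(ring$assembly), "mean"),
               ring$truth$adjacent_angle, tolerance = 2 / 52)
})

test_that("delta-theta identities", {
  expect_identical(delta_theta(3, 4), 30)
  expect_identical(delta_theta(6, 8), 15)
  expect_identical(delta_theta(5, 5), 0)
  expect_equal(delta_theta(4, 3), -delta_theta(3, 4))
  expect_error(delta_theta(1, 4), ">= 2")
})

test_that("pore diameter: constructed value and non-ring flag", {
  # ring of single carbon atoms at radius 30 from the z axis
  k <- 12
  ph <- 2 * pi * (seq_len(k) - 1) / k
  at <- data.frame(element = "C", name = "C1", resid = "LIG",
                   resno = seq_len(k), chain = "X",
                   x = 30 * cos(ph), y = 30 * sin(ph), z = 0,
                   hetero = TRUE, occ = 1, b = 0)
  asm <- assembly(at)
  pd <- pore_diameter(asm, axis = c(0, 0, 1), center = c(0, 0, 0))
  expect_equal(pd$pore_diameter, 2 * (30 - 1.70), tolerance = 1e-9)
  expect_equal(pd$raw_diameter, 60, tolerance = 1e-9)
  expect_false(pd$is_ring)  # no protomers assigned: nothing encloses a pore
  expect_true(pore_diameter(ring_c4$assembly)$is_ring)
  # hydrogens are ignored
  ath <- rbind(at, within(at[1, ], { element <- "H"; x <- 5 }))
  expect_equal(pore_diameter(assembly(ath), axis = c(0, 0, 1),
                             center = c(0, 0, 0))$pore_diameter,
               2 * (30 - 1.70), tolerance = 1e-9)
})
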