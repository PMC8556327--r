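test_that("PDB and mmCIF round-trips preserve atoms, coordinates and flags", {
  asm <- ring_d3$assembly
  for (fmt in c("pdb", "mmcif")) {
    path <- tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
    write_structure(asm, path, fmt)
    back <- read_structure(path)
    expect_equal(nrow(back$atoms), nrow(asm$atoms))
    expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
                 as.matrix(asm$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
    expect_identical(back$atoms$chain, asm$atoms$chain)
    expect_equal(back$atoms$resno, asm$atoms$resno)
    expect_identical(back$atoms$hetero, asm$atoms$hetero)
    # the pseudo-chromophore hetero residues survive with their flag set
    expect_true(all(back$atoms$resid[back$atoms$hetero] == "CYC"))
  }
})

test_that("format auto-detection and degenerate inputs give clear errors", {
  empty <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), empty)
  expect_error(read_structure(empty), "no atoms")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
  odd <- tempfile(fileext = ".xyz")
  file.create(odd)
  expect_error(read_structure(odd), "format")
  cifbad <- tempfile(fileext = ".cif")
  writeLines("data_x", cifbad)
  expect_error(read_structure(cifbad), "atom_site")
})

test_that("alternate locations other than blank/A are dropped on read", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.50 10.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.50 10.00           C",
    "ATOM      3  CA  ALA A   2       3.800   0.000   0.000  1.00 10.00           C",
    "END"), path)
  asm <- read_structure(path)
  expect_equal(nrow(asm$atoms), 2L)
  expect_equal(asm$atoms$x, c(0, 3.8))
})

test_that("Kabsch superposition recovers constructed transforms, reflection-free", {
  set.seed(7)
  X <- matrix(rnorm(45), 15, 3)
  th <- 37 * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  Y <- X %*% t(Rz) + matrix(c(1, 2, 3), 15, 3, byrow = TRUE)
  tr <- superpose(X, Y)
  expect_lt(tr$rmsd, 1e-8)
  expect_equal(rotation_angle(tr), 37, tolerance = 1e-8)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-8)
  # rmsd is symmetric and matches the explicit residual of the transform
  trb <- superpose(Y, X)
  expect_equal(tr$rmsd, trb$rmsd, tolerance = 1e-8)
  set.seed(8)
  Z <- Y + matrix(rnorm(45, sd = 0.3), 15, 3)
  trz <- superpose(X, Z)
  resid <- Z - apply_transform(trz, X)
  expect_equal(trz$rmsd, sqrt(sum(resid^2) / nrow(X)), tolerance = 1e-10)
  # applying the fit twice is a fixed point
  Xfit <- apply_transform(trz, X)
  expect_equal(superpose(Xfit, Z)$rmsd, trz$rmsd, tolerance = 1e-10)
  # a mirrored cloud still yields a proper rotation
  trm <- superpose(X, X %*% diag(c(-1, 1, 1)))
  expect_equal(det(trm$rotation), 1, tolerance = 1e-8)
  expect_gt(trm$rmsd, 0.1)
  # identical sets: identity
  tri <- superpose(X, X)
  expect_lt(tri$rmsd, 1e-10)
  expect_equal(tri$rotation, diag(3), tolerance = 1e-8)
  expect_error(superpose(X[1:4, ], X), "length")
  expect_error(superpose(X[1:2, ], X[1:2, ]), "3")
  lin <- cbind(1:5, 0, 0)
  expect_error(superpose(lin, lin), "collinear")
})

test_that("C-alpha matching pairs residues by number and by alignment", {
  asm <- toy_two_chain(1:100, 51:150)
  m <- match_ca(asm, "A", "B", mode = "by_resnum")
  expect_length(m$resno_a, 50)
  expect_equal(m$resno_a, 51:100)
  same <- match_ca(asm, "A", "A")
  expect_length(same$resno_a, 100)
  expect_error(match_ca(toy_two_chain(1:10, 11:20), "A", "B"), "no shared")

  # alignment mode: one internal deletion is excluded from the pairing
  seq_a <- c("ALA", "GLY", "SER", "THR", "VAL", "LEU", "ILE", "PHE")
  seq_b <- seq_a[-4]  # THR deleted
  asm2 <- toy_two_chain(1:8, 101:107, seq_a = seq_a, seq_b = seq_b)
  ma <- match_ca(asm2, "A", "B", mode = "by_alignment")
  expect_length(ma$resno_a, 7)
  expect_false(4 %in% ma$resno_a)
  # achieved score equals the brute-force optimum
  a1 <- c("A", "G", "S", "T", "V", "L", "I", "F")
  b1 <- a1[-4]
  matches <- sum(a1[ma$resno_a] == b1[ma$resno_b - 100])
  gaps <- (length(a1) - length(ma$resno_a)) + (length(b1) - length(ma$resno_b))
  expect_equal(matches - gaps, brute_align_score(a1, b1))
})

test_that("contact-based protomer grouping recovers the construction pairing", {
  asm <- ring_c4$assembly
  regrouped <- group_protomers(assembly(asm$atoms), pairing = "by_contact")
  key <- function(pt) paste(sort(paste(pt$alpha, pt$beta)), collapse = ";")
  expect_identical(key(regrouped$protomers), key(asm$protomers))
  expect_equal(n_protomers(regrouped), 4L)
  expect_setequal(regrouped$protomers$index, 0:3)
  # D3 ring: 12 chains -> 6 protomers
  expect_equal(n_protomers(ring_d3$assembly), 6L)
  # odd chain count is refused
  sub <- assembly(asm$atoms[asm$atoms$chain %in% c("A", "B", "C"), ])
  expect_error(group_protomers(sub), "odd")
})
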