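test_that("chromophore sites are located with correct ids and anchors", {
  asm <- ring_d3$assembly
  sites <- locate_chromophores(asm)
  expect_equal(nrow(sites), 12)  # 2 per protomer x 6
  expect_setequal(unique(sites$id), c("a84PCB", "b82PCB"))
  expect_true(all(!is.na(sites$anchor_chain)))
  expect_setequal(sites$anchor_resno[sites$id == "a84PCB"], 84)
  # centroids match the generator's ground truth
  tr <- ring_d3$truth$chromophores
  for (k in seq_len(nrow(sites))) {
    d <- sqrt((tr$x - sites$x[k])^2 + (tr$y - sites$y[k])^2 +
                (tr$z - sites$z[k])^2)
    expect_lt(min(d), 1e-6)
  }
  # no hetero residues -> empty site list
  bare <- assembly(subset_atoms(asm, hetero = FALSE))
  expect_equal(nrow(locate_chromophores(bare)), 0)
  # chromophore too far from any cysteine keeps the site, anchor unset
  at <- asm$atoms
  far <- at$hetero & at$chain == at$chain[at$hetero][1]
  at$x[far] <- at$x[far] + 500
  expect_warning(s2 <- locate_chromophores(assembly(at)), "no cysteine")
  expect_equal(nrow(s2), 12)
  expect_equal(sum(is.na(s2$anchor_chain)), 1)
})

test_that("distance networks: metric properties and invariance", {
  sites <- locate_chromophores(ring_d3$assembly)
  net <- pair_distances(sites)
  n <- nrow(sites)
  expect_equal(nrow(net$edges), n * (n - 1) / 2)  # no self edges
  expect_true(all(net$edges$dist > 0))
  expect_true(all(net$edges$class == "intraprotein"))  # one assembly id
  # triangle inequality over sampled triples
  D <- as.matrix(dist(sites[, c("x", "y", "z")]))
  set.seed(2)
  for (k in 1:25) {
    ijk <- sample(n, 3)
    expect_lte(D[ijk[1], ijk[2]],
               D[ijk[1], ijk[3]] + D[ijk[3], ijk[2]] + 1e-9)
  }
  # invariance of named minimum distances under rigid motion
  moved <- random_rigid(ring_d3$assembly, seed = 99)
  net2 <- pair_distances(locate_chromophores(moved))
  expect_equal(net2$named_pairs$min_dist, net$named_pairs$min_dist,
               tolerance = 1e-9)
  # cutoff is honoured
  cut <- pair_distances(sites, cutoff = 30)
  expect_true(all(cut$edges$dist <= 30))
  # construction spacing reproduced exactly
  expect_equal(named_pair_distance(net, "a84PCB", "b82PCB"), 20,
               tolerance = 1e-9)
})

test_that("simple distances and degenerate inputs", {
  s <- data.frame(id = c("x", "y"), resid = "CYC", chain = c("A", "B"),
                  resno = 1:2, anchor_chain = NA, anchor_resno = NA,
                  protomer = 0:1, assembly_id = c("A1", "A2"),
                  x = c(0, 3), y = c(0, 4), z = c(0, 0))
  net <- pair_distances(s)
  expect_equal(net$edges$dist, 5)
  expect_equal(net$edges$class, "interprotein")
  expect_error(pair_distances(s[1, ]), "at least 2")
})

test_that("stacked-layer networks keep only cross-layer pairs", {
  a <- ring_c4$assembly
  b <- a
  b$atoms$z <- b$atoms$z + 30
  net <- stacked_layer_distances(a, b)
  expect_true(all(net$edges$class == "interprotein"))
  expect_false(is.unsorted(net$edges$dist))
  # a site directly above its own copy is exactly 30 apart
  expect_equal(net$named_pairs$min_dist[net$named_pairs$pair ==
                                          "a84PCB-a84PCB"], 30,
               tolerance = 1e-9)
  expect_lte(min(net$edges$dist), 30 + 1e-9)
  # identical layers: minimum distance 0
  net0 <- stacked_layer_distances(a, a)
  expect_equal(min(net0$edges$dist), 0, tolerance = 1e-12)
})
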