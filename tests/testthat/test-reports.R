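test_that("geometry report matches the underlying library calls", {
  out <- file.path(tempdir(), "rep-geom")
  cfg <- run_config(out_dir = out)
  res <- report_geometry(ring_c4, config = cfg, compare_order = 3)
  expect_true(file.exists(file.path(out, "geometry.json")))
  expect_true(file.exists(file.path(out, "geometry.csv")))
  expect_equal(res$symmetry$order_n, 4)
  expect_equal(res$bend_angle_mean,
               attr(monomer_bend_angle(ring_c4$assembly), "mean"))
  expect_equal(res$delta_theta, 30)
  js <- jsonlite::read_json(file.path(out, "geometry.json"),
                            simplifyVector = TRUE)
  expect_equal(js$symmetry$order_n, 4)
})

test_that("reports are byte-identical on identical inputs", {
  out1 <- file.path(tempdir(), "idem1"); out2 <- file.path(tempdir(), "idem2")
  report_geometry(ring_c4, config = run_config(out_dir = out1))
  report_geometry(ring_c4, config = run_config(out_dir = out2))
  for (f in c("geometry.json", "geometry.csv"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
})

test_that("chromophore and energetics reports run and flag the octamer step", {
  out <- file.path(tempdir(), "rep-misc")
  cfg <- run_config(out_dir = out)
  rc <- report_chromophores(ring_d3, config = cfg)
  expect_equal(rc$n_sites, 12)
  expect_true(all(c("a84PCB", "b82PCB") %in% rc$ids))

  re <- report_energetics(config = cfg)
  expect_equal(nrow(re$unfavorable_steps), 1)
  expect_equal(re$unfavorable_steps$dG_f, 11.1, tolerance = 1e-9)
  # overriding the dissociation table changes the computed steps
  cfg2 <- run_config(out_dir = out,
                     dG_diss = c(`2` = 1, `3` = 2, `4` = 3, `6` = 10, `8` = 40))
  re2 <- report_energetics(config = cfg2)
  expect_equal(re2$steps$dG_f[re2$steps$parts == "4+4"], -(40 - 6))
  expect_equal(nrow(re2$unfavorable_steps), 0)
  # empty route list gives a header-only table
  re3 <- report_energetics(config = cfg, routes = list())
  expect_equal(nrow(re3$steps), 0)
})

test_that("auc report simulates and fits", {
  out <- file.path(tempdir(), "rep-auc")
  buf <- cpc_buffer
  cfg <- run_config(out_dir = out, s_grid_points = 60, f_ratio = 1.195,
                    buffer = buf)
  spec <- auc_spec(species = data.frame(s = 5.24, f_ratio = 1.195,
                                        loading = 0.8),
                   noise_sigma = 0.003, times = seq(600, 4800, by = 600),
                   seed = 2)
  rs <- report_auc(spec, mode = "simulate", config = cfg, ncell = 250)
  expect_true(file.exists(file.path(out, "scans.csv")))
  expect_equal(rs$n_scans, 8)

  rf <- report_auc(file.path(out, "scans.csv"), mode = "fit", config = cfg,
                   thin = 2)
  expect_lt(rf$fit_rmsd, 0.01)
  expect_equal(rf$species$s_obs[which.max(rf$species$loading)], 5.24,
               tolerance = 0.05)
})

test_that("configuration validation and file round-trip", {
  expect_error(run_config(bogus_key = 1), "unknown config key")
  p <- tempfile(fileext = ".yaml")
  writeLines(c("s_grid_points: 42", "f_ratio: 1.3"), p)
  cfg <- read_run_config(p)
  expect_equal(cfg$s_grid_points, 42)
  expect_equal(cfg$f_ratio, 1.3)
  expect_equal(cfg$sasa_probe, 1.4)  # defaults preserved
})
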