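#' Validated run configuration
#'
#' A light container for the parameters shared by the reporting helpers.
#' Unknown keys are rejected so that typos surface immediately; every value
#' actually used (explicit or defaulted) is echoed into each report's log.
#'
#' @param ... named settings. Known keys: `input`, `format`, `out_dir`,
#'   `seed`, `anchors_bend`, `anchors_adjacent`, `chromophore_residues`,
#'   `sasa_probe`, `sasa_points`, `dG_diss`, `s_grid_min`, `s_grid_max`,
#'   `s_grid_points`, `f_ratio`, `lambda`, `buffer`, `vbar`, `verbose`.
#' @return a `run_config` list with defaults filled in.
#' @export
run_config <- function(...) {
  defaults <- list(
    input = NULL, format = "auto", out_dir = ".", seed = 0,
    anchors_bend = .default_bend_anchors,
    anchors_adjacent = .default_adjacent_anchors,
    chromophore_residues = c("CYC", "PCB", "BLA"),
    sasa_probe = 1.4, sasa_points = 960,
    dG_diss = c(`2` = 4.8, `3` = 20.9, `4` = 16.0, `6` = 54.6, `8` = 20.9),
    s_grid_min = 1, s_grid_max = 15, s_grid_points = 100,
    f_ratio = 1.2, lambda = 0.05,
    buffer = NULL, vbar = NULL, verbose = FALSE)
  user <- list(...)
  if (length(user) == 1L && is.list(user[[1]]) && is.null(names(user)))
    user <- user[[1]]
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("config must be YAML or JSON"))
  run_config(lst)
}

report_paths <- function(out_dir, stem) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  list(json = file.path(out_dir, paste0(stem, ".json")),
       csv = file.path(out_dir, paste0(stem, ".csv")),
       log = file.path(out_dir, paste0(stem, ".log")))
}

write_report <- function(result, table, paths, cfg, used) {
  jsonlite::write_json(result, paths$json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  tab <- table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 4)
  write.csv(tab, paths$csv, row.names = FALSE)
  writeLines(c(format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
               paste0(names(used), " = ",
                      vapply(used, function(v) paste(format(v), collapse = " "),
                             character(1)))),
             paths$log)
  invisible(result)
}

resolve_assembly <- function(x, cfg) {
  if (inherits(x, "assembly")) return(x)
  if (is.list(x) && inherits(x$assembly, "assembly")) return(x$assembly)
  if (is.character(x)) {
    asm <- read_structure(x, format = cfg$format)
    return(group_protomers(asm, pairing = "by_contact"))
  }
  stop("pass an assembly, a build_ring() result, or a structure file path")
}

#' Geometry report
#'
#' Runs symmetry detection, the monomer bend and adjacent-monomer angle
#' measurements, inter-protomer rotations between azimuthal neighbours, the
#' ideal-angle difference to a comparison ring order, and the pore diameter;
#' writes `geometry.json`, a per-protomer `geometry.csv` and a parameter log.
#'
#' @param x an [assembly()] (protomers assigned), a [build_ring()] result,
#'   or a structure file path.
#' @param config a [run_config()].
#' @param compare_order optional second ring order m for the delta-theta
#'   entry.
#' @return the report list, invisibly.
#' @export
report_geometry <- function(x, config = run_config(), compare_order = NULL) {
  asm <- resolve_assembly(x, config)
  sym <- detect_symmetry(asm)
  bend <- monomer_bend_angle(asm, anchors = config$anchors_bend)
  adj <- adjacent_monomer_angle(asm, anchors = config$anchors_adjacent)
  pore <- pore_diameter(asm, axis = sym$axis, center = sym$center)
  rots <- vapply(seq_len(nrow(adj)), function(k)
    interface_rotation(asm, adj$protomer[k], adj$neighbor[k]), numeric(1))
  res <- list(
    symmetry = list(order_n = sym$order_n, sym_type = sym$sym_type,
                    layers = sym$layers, axis = as.numeric(sym$axis),
                    mean_angle_residual = sym$mean_angle_residual),
    bend_angle_mean = attr(bend, "mean"),
    adjacent_angle_mean = attr(adj, "mean"),
    interface_rotation_mean = mean(rots),
    delta_theta = if (!is.null(compare_order))
      delta_theta(min(sym$order_n, compare_order),
                  max(sym$order_n, compare_order)) else NULL,
    pore = pore)
  tab <- data.frame(protomer = bend$protomer, bend_angle = bend$value,
                    adjacent_angle = adj$value[match(bend$protomer, adj$protomer)],
                    interface_rotation = rots[match(bend$protomer, adj$protomer)])
  paths <- report_paths(config$out_dir, "geometry")
  write_report(res, tab, paths, config,
               used = list(anchors_bend = unlist(config$anchors_bend),
                           anchors_adjacent = unlist(config$anchors_adjacent),
                           seed = config$seed))
  invisible(res)
}

#' Chromophore network report
#'
#' Site detection plus the pairwise distance network; writes
#' `chromophores.json`, the edge table `chromophores.csv` and a log.
#'
#' @inheritParams report_geometry
#' @param cutoff optional edge cutoff in angstrom.
#' @return the report list, invisibly.
#' @export
report_chromophores <- function(x, config = run_config(), cutoff = Inf) {
  asm <- resolve_assembly(x, config)
  sites <- locate_chromophores(asm, residue_names = config$chromophore_residues)
  if (nrow(sites) < 2) stop("fewer than two chromophore sites found")
  net <- pair_distances(sites, cutoff = cutoff)
  res <- list(n_sites = nrow(sites), ids = sort(unique(sites$id)),
              named_pairs = net$named_pairs,
              shortest = head(net$edges, 10))
  paths <- report_paths(config$out_dir, "chromophores")
  write_report(res, net$edges, paths, config,
               used = list(chromophore_residues = config$chromophore_residues,
                           cutoff = cutoff, seed = config$seed))
  invisible(res)
}

#' Assembly energetics report
#'
#' The oligomer formation-energy pathway table from the configured
#' dissociation free energies, with unfavourable steps flagged, plus the
#' stability ranking; optionally an interface burial report between two
#' protomers of a supplied assembly. Writes `energetics.json`,
#' `energetics.csv` and a log.
#'
#' @param config a [run_config()] (`dG_diss` supplies the model).
#' @param routes route definitions as in [pathway_graph()].
#' @param x optional assembly for an adjacent-protomer interface report.
#' @return the report list, invisibly.
#' @export
report_energetics <- function(config = run_config(), routes = .default_routes,
                              x = NULL) {
  model <- assembly_energy_model(config$dG_diss)
  pg <- pathway_graph(model, routes)
  res <- list(dG_diss = as.list(model$dG_diss),
              ranking = stability_ranking(model),
              steps = as.data.frame(pg),
              unfavorable_steps = as.data.frame(pg)[!pg$favorable, ,
                                                    drop = FALSE])
  if (!is.null(x)) {
    asm <- resolve_assembly(x, config)
    adj <- adjacent_index(asm)
    ir <- interface_report(subset_atoms(asm, protomers = adj$index[1]),
                           subset_atoms(asm, protomers = adj$next_index[1]),
                           probe = config$sasa_probe,
                           n_points = config$sasa_points)
    res$interface <- list(asa_a = ir$asa_a, asa_b = ir$asa_b,
                          asa_complex = ir$asa_complex, buried = ir$buried,
                          contact_percent_a = ir$contact_percent_a)
  }
  paths <- report_paths(config$out_dir, "energetics")
  write_report(res, as.data.frame(pg), paths, config,
               used = list(dG_diss = config$dG_diss,
                           sasa_probe = config$sasa_probe,
                           sasa_points = config$sasa_points,
                           seed = config$seed))
  invisible(res)
}

#' Sedimentation-velocity report
#'
#' Either simulates an experiment from an [auc_spec()] or fits a c(s)
#' distribution to scans; emits the c(s) table and the per-peak species
#' table. Writes `auc.json`, `auc.csv` (the c(s) table) and a log.
#'
#' @param x for `mode = "simulate"` an [auc_spec()]; for `mode = "fit"` a
#'   `sedimentation_dataset` or a scan CSV path (see [read_scans()]).
#' @param mode `"fit"` or `"simulate"`.
#' @param config a [run_config()] (buffer, s grid, f_ratio, lambda, seed).
#' @param ... passed on to [simulate_auc()] or [fit_cs()].
#' @return the report list, invisibly.
#' @export
report_auc <- function(x, mode = c("fit", "simulate"),
                       config = run_config(), ...) {
  mode <- match.arg(mode)
  buffer <- config$buffer %||% hydro_params()
  if (mode == "simulate") {
    stopifnot(inherits(x, "auc_spec"))
    ds <- simulate_auc(x, buffer = buffer, ...)
    paths <- report_paths(config$out_dir, "auc")
    write_scans(ds, file.path(config$out_dir, "scans.csv"))
    res <- list(mode = "simulate", n_scans = length(ds$times),
                species = ds$truth, noise_sigma = ds$noise_sigma)
    write_report(res, data.frame(time = ds$times,
                                 mass = cell_mass(ds)),
                 paths, config, used = list(seed = x$seed))
    return(invisible(res))
  }
  ds <- if (is.character(x)) read_scans(x, buffer = buffer) else x
  fit <- fit_cs(ds,
                s_grid = seq(config$s_grid_min, config$s_grid_max,
                             length.out = config$s_grid_points),
                f_ratio = config$f_ratio, lambda = config$lambda,
                buffer = buffer, vbar = config$vbar %||% buffer$vbar, ...)
  sp <- peaks_to_species(fit)
  res <- list(mode = "fit", f_ratio = fit$f_ratio, fit_rmsd = fit$fit_rmsd,
              species = sp)
  paths <- report_paths(config$out_dir, "auc")
  write_report(res, data.frame(s = fit$s_grid, c = fit$c), paths, config,
               used = list(f_ratio = config$f_ratio, lambda = config$lambda,
                           s_grid = c(config$s_grid_min, config$s_grid_max,
                                      config$s_grid_points),
                           seed = config$seed))
  invisible(res)
}
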