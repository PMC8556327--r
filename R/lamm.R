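#' Simulate sedimentation-velocity scans (Lamm equation)
#'
#' Solves the Lamm equation
#' `dc/dt = (1/r) d/dr [ r (D dc/dr - s w^2 r c) ]`
#' per species on a uniform radial finite-volume grid with zero total flux at
#' the meniscus and cell bottom (a closed cell), Crank-Nicolson in time with
#' exponentially fitted face fluxes. The scheme conserves mass to machine
#' precision; a cell-Peclet guard rejects grids too coarse for the requested
#' diffusion coefficient.
#'
#' @param species data frame with columns `s` (Svedberg), `D` (cm^2/s) and
#'   `loading` (signal units; initial uniform concentration).
#' @param times scan times in seconds (nondecreasing).
#' @param buffer a [hydro_params()] (supplies the rotor speed).
#' @param geometry `c(r_meniscus, r_bottom)` in cm.
#' @param ncell radial cells (default 400).
#' @param dt internal time step in seconds; default resolves the fastest
#'   species to about one cell per step.
#' @param baseline constant absorbance offset added to every scan.
#' @param pe_max maximum allowed cell Peclet number `s*w^2*r*h/D`.
#' @return a `sedimentation_dataset`: list with `radii` (cell centres, cm),
#'   `times` (s), `scans` (time x radius matrix), `geometry`, `buffer`,
#'   `species`.
#' @export
lamm_simulate <- function(species, times, buffer = hydro_params(),
                          geometry = c(6.0, 7.2), ncell = 400, dt = NULL,
                          baseline = 0, pe_max = 20) {
  stopifnot(is.data.frame(species), all(c("s", "D", "loading") %in% names(species)))
  if (nrow(species) && (any(species$s <= 0) || any(species$D <= 0)))
    stop("species s and D must be > 0")
  if (any(species$loading < 0)) stop("loadings must be >= 0")
  rm <- geometry[1]; rb <- geometry[2]
  if (!(rm > 0 && rb > rm)) stop("need 0 < r_meniscus < r_bottom")
  times <- as.numeric(times)
  if (any(diff(times) < 0) || any(times < 0)) stop("times must be nondecreasing and >= 0")
  h <- (rb - rm) / ncell
  omega2 <- buffer$omega2
  if (nrow(species)) {
    pe <- species$s * .S_unit * omega2 * rb * h / species$D
    if (any(pe > pe_max))
      stop(sprintf(paste0("cell Peclet number %.1f exceeds %g: the %d-cell grid ",
                          "is too coarse for D = %.2e cm^2/s; use a finer grid"),
                   max(pe), pe_max, ncell, species$D[which.max(pe)]))
  }
  if (is.null(dt)) {
    vmax <- if (nrow(species)) max(species$s) * .S_unit * omega2 * rb else 0
    dt <- if (vmax > 0) max(1, min(30, h / vmax)) else 30
  }
  radii <- rm + (seq_len(ncell) - 0.5) * h
  scans <- matrix(baseline, nrow = length(times), ncol = ncell)
  for (k in seq_len(nrow(species))) {
    if (species$loading[k] == 0) next
    scans <- scans + .lamm_core(as.integer(ncell), rm, rb,
                                species$s[k] * .S_unit, species$D[k],
                                omega2, times, dt, species$loading[k])
  }
  structure(list(radii = radii, times = times, scans = scans,
                 geometry = c(r_meniscus = rm, r_bottom = rb),
                 buffer = buffer, species = species, baseline = baseline),
            class = "sedimentation_dataset")
}

#' @export
print.sedimentation_dataset <- function(x, ...) {
  cat(sprintf("<sedimentation_dataset> %d scans x %d radii, r %.2f-%.2f cm, t %g-%g s\n",
              nrow(x$scans), ncol(x$scans), x$geometry[1], x$geometry[2],
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
plot.sedimentation_dataset <- function(x, every = 1, ...) {
  sel <- seq(1, nrow(x$scans), by = every)
  graphics::matplot(x$radii, t(x$scans[sel, , drop = FALSE]), type = "l",
                    lty = 1, col = grDevices::hcl.colors(length(sel), "Blues", rev = TRUE),
                    xlab = "radius (cm)", ylab = "signal", ...)
  invisible(x)
}

#' Total mass in a sector-shaped cell
#'
#' The conserved quantity of the closed-cell Lamm problem,
#' `integral of c(r) r dr` per scan (sector geometry).
#'
#' @param dataset a `sedimentation_dataset`.
#' @return numeric vector, one value per scan.
#' @export
cell_mass <- function(dataset) {
  h <- diff(dataset$geometry)[[1]] / ncol(dataset$scans)
  as.numeric((dataset$scans - dataset$baseline) %*% (dataset$radii * h))
}

#' Write / read sedimentation scans as CSV
#'
#' One `radius` column plus one column per scan; the header row carries the
#' scan times in seconds (as `t<seconds>`).
#'
#' @param dataset a `sedimentation_dataset`.
#' @param path CSV file path.
#' @return `write_scans` returns `path` invisibly; `read_scans` returns a
#'   `sedimentation_dataset` (with `buffer`/`species` unset unless supplied).
#' @export
write_scans <- function(dataset, path) {
  df <- data.frame(radius = dataset$radii, t(dataset$scans))
  names(df)[-1] <- paste0("t", format(dataset$times, trim = TRUE,
                                      scientific = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scans
#' @param buffer optional [hydro_params()] attached to the returned dataset.
#' @export
read_scans <- function(path, buffer = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (!("radius" %in% names(df))) stop("scan CSV needs a 'radius' column")
  tcols <- setdiff(names(df), "radius")
  times <- as.numeric(sub("^t", "", tcols))
  if (anyNA(times)) stop("scan column names must encode times as t<seconds>")
  radii <- df$radius
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  scans <- t(as.matrix(df[, tcols, drop = FALSE]))
  if (!all(is.finite(scans))) stop("non-finite scan values")
  o <- order(times)
  structure(list(radii = radii, times = times[o],
                 scans = scans[o, , drop = FALSE],
                 geometry = c(r_meniscus = min(radii), r_bottom = max(radii)),
                 buffer = buffer, species = NULL, baseline = 0),
            class = "sedimentation_dataset")
}
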