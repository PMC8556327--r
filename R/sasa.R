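#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom accessible area by deterministic sphere-point sampling: each atom
#' is probed at radius r_vdw + probe with a Fibonacci point set, counting
#' points not inside any neighbour's expanded sphere. Neighbour search uses
#' spatial binning. Hydrogens are excluded (deposited models are heavy-atom).
#'
#' @param atoms an [assembly()] or an atom data frame (see [assembly()]).
#' @param probe probe radius in angstrom (default 1.4, water).
#' @param n_points sphere points per atom (default 960).
#' @param radii_set radius table name; `"bondi"` is the only built-in.
#' @return a `sasa_result`: list with `per_atom_area` (angstrom^2, one entry
#'   per non-hydrogen atom), `total`, `atoms` (the atom subset used),
#'   `probe_radius`, `n_sphere_points`, `radii_set`.
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 960,
                               radii_set = "bondi") {
  at <- if (inherits(atoms, "assembly")) atoms$atoms else atoms
  if (!identical(radii_set, "bondi")) stop("unknown radii set: ", radii_set)
  if (probe <= 0) stop("probe radius must be > 0")
  at <- at[toupper(at$element) != "H", , drop = FALSE]
  if (!nrow(at)) stop("no (heavy) atoms")
  rad <- vdw_radius(at$element) + probe
  area <- .sasa_core(atom_xyz(at), rad, as.integer(n_points))
  structure(list(per_atom_area = as.numeric(area), total = sum(area),
                 atoms = at, probe_radius = probe,
                 n_sphere_points = as.integer(n_points),
                 radii_set = radii_set),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$per_atom_area), x$probe_radius,
              x$n_sphere_points))
  invisible(x)
}

#' Interface burial between two atom sets
#'
#' Computes the accessible surface area of each part in isolation and of
#' their union, the buried area per part, and the contact statistic
#' contact% = buried / (accessible + buried) of each part (the part's
#' isolated area is its accessible-plus-buried area).
#'
#' @param part_a,part_b disjoint atom data frames (e.g. from
#'   [subset_atoms()]).
#' @param probe,n_points,radii_set passed to [shrake_rupley_sasa()].
#' @return an `interface_report`: list with `asa_a`, `asa_b`, `asa_complex`
#'   (angstrom^2), `buried` per part `= (asa_a + asa_b - asa_complex)/2`,
#'   `contact_percent_a`, `contact_percent_b`, and the per-part SASA results.
#' @export
interface_report <- function(part_a, part_b, probe = 1.4, n_points = 960,
                             radii_set = "bondi") {
  if (inherits(part_a, "assembly")) part_a <- part_a$atoms
  if (inherits(part_b, "assembly")) part_b <- part_b$atoms
  ka <- paste(part_a$chain, part_a$resno, part_a$name)
  kb <- paste(part_b$chain, part_b$resno, part_b$name)
  dup <- intersect(ka, kb)
  if (length(dup)) stop("atom identities present in both parts: ",
                        paste(head(dup, 3), collapse = "; "),
                        if (length(dup) > 3) " ...")
  sa <- shrake_rupley_sasa(part_a, probe, n_points, radii_set)
  sb <- shrake_rupley_sasa(part_b, probe, n_points, radii_set)
  sc <- shrake_rupley_sasa(rbind(part_a, part_b), probe, n_points, radii_set)
  buried <- (sa$total + sb$total - sc$total) / 2
  structure(list(asa_a = sa$total, asa_b = sb$total, asa_complex = sc$total,
                 buried = buried,
                 contact_percent_a = 100 * buried / sa$total,
                 contact_percent_b = 100 * buried / sb$total,
                 sasa_a = sa, sasa_b = sb, sasa_complex = sc),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("<interface_report> ASA A %.1f, B %.1f, complex %.1f A^2\n",
              x$asa_a, x$asa_b, x$asa_complex))
  cat(sprintf("  buried per part %.1f A^2; contact%% %.1f (A) / %.1f (B)\n",
              x$buried, x$contact_percent_a, x$contact_percent_b))
  invisible(x)
}

#' Contact percentage of a subunit interface
#'
#' `contact% = 100 * buried / (accessible + buried)`, where `accessible` is
#' the area remaining accessible in the complex and `buried` the area lost
#' on complexation.
#'
#' @param buried,accessible areas in angstrom^2 (non-negative, not both 0).
#' @return percentage in `[0, 100]`.
#' @export
contact_percent <- function(buried, accessible) {
  if (any(buried < 0) || any(accessible < 0)) stop("areas must be non-negative")
  if (any(buried + accessible == 0)) stop("buried and accessible both zero")
  100 * buried / (accessible + buried)
}

# atomic solvation parameters, kcal/mol/A^2 (element-level approximation:
# carbon and sulfur burial favourable, polar burial unfavourable)
.default_asp <- c(C = 0.016, S = 0.021, N = -0.006, O = -0.006, P = -0.006)

#' Solvation free-energy estimate of complexation
#'
#' A buried-area-weighted atomic solvation estimate:
#' `sum over atoms of ASP(element) * buried area on complexation`, with the
#' per-atom buried area taken as isolated minus in-complex accessible area.
#' This is a simple atomic-solvation-parameter model of the interface
#' solvation term; it is an order-of-magnitude estimate, not a calibrated
#' reproduction of any particular interface-analysis program's energies.
#'
#' @param part_a,part_b disjoint atom data frames.
#' @param asp named vector of atomic solvation parameters (kcal/mol/A^2) per
#'   element.
#' @param probe,n_points passed to [shrake_rupley_sasa()].
#' @return estimated solvation free-energy gain in kcal/mol (negative =
#'   favourable burial).
#' @export
solvation_energy_estimate <- function(part_a, part_b, asp = .default_asp,
                                      probe = 1.4, n_points = 960) {
  rep <- interface_report(part_a, part_b, probe = probe, n_points = n_points)
  per_iso <- c(rep$sasa_a$per_atom_area, rep$sasa_b$per_atom_area)
  per_cpx <- rep$sasa_complex$per_atom_area
  el <- toupper(rep$sasa_complex$atoms$element)
  a <- asp[el]
  if (anyNA(a)) stop("no atomic solvation parameter for element(s): ",
                     paste(unique(el[is.na(a)]), collapse = ", "))
  buried_per_atom <- pmax(0, per_iso - per_cpx)
  -sum(a * buried_per_atom)
}
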