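#' Specification of a synthetic ring assembly
#'
#' Describes an idealized Cn (one layer) or Dn (two layers) protein ring
#' built from a toy two-chain protomer: a C-alpha trace with the anchor
#' residues used by the angle measurements at the conventional author
#' numbers (alpha-Gln70, alpha-Arg30, beta-Gly70, beta-Pro69) and one
#' pseudo-chromophore per chain, thioether-anchored at a cysteine
#' (alpha-Cys84, beta-Cys82).
#'
#' @param n protomers per layer (>= 2).
#' @param layers 1 (Cn) or 2 (Dn; the second ring is related to the first by
#'   a 2-fold axis perpendicular to the ring axis).
#' @param ring_radius ring radius in angstrom.
#' @param bend_angle monomer-internal anchor angle, degrees.
#' @param adjacent_angle inter-monomer anchor angle, degrees.
#' @param layer_offset half-spacing of the two layers along the axis,
#'   angstrom.
#' @param jitter_sigma coordinate noise sd, angstrom.
#' @param seed RNG seed for the jitter.
#' @return a `ring_spec` list.
#' @export
ring_spec <- function(n, layers = 1, ring_radius = 45, bend_angle = 110,
                      adjacent_angle = 52, layer_offset = 15,
                      jitter_sigma = 0, seed = 0) {
  stopifnot(n >= 2, layers %in% c(1, 2), ring_radius > 0, jitter_sigma >= 0)
  structure(list(n = as.integer(n), layers = as.integer(layers),
                 ring_radius = ring_radius, bend_angle = bend_angle,
                 adjacent_angle = adjacent_angle, layer_offset = layer_offset,
                 jitter_sigma = jitter_sigma, seed = as.integer(seed)),
            class = "ring_spec")
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

unitv <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Build a synthetic ring assembly with known ground truth
#'
#' Constructs the anchor geometry exactly: the adjacent-monomer anchor angle
#' (vertex beta-Pro69, rays to alpha-Gln70 and to the next protomer's
#' beta-Pro69) equals `spec$adjacent_angle`, and the monomer bend angle
#' (vertex alpha-Arg30, rays to alpha-Gln70 and beta-Gly70) equals
#' `spec$bend_angle`, for every protomer of an unjittered ring. Filler
#' residues give each chain a compact C-alpha body so contact-based chain
#' pairing and surface-area calculations have something to work with; one
#' pseudo-chromophore (hetero residue `CYC`, five heavy atoms) is bonded
#' 1.81 angstrom from each chain's cysteine S-gamma.
#'
#' @param spec a [ring_spec()].
#' @return list with `assembly` (protomers assigned, indices in construction
#'   order) and `truth`: the axis, center, construction angles, the ideal
#'   inter-protomer rotation `360/n`, and the unjittered chromophore site
#'   table.
#' @export
build_ring <- function(spec) {
  stopifnot(inherits(spec, "ring_spec"))
  n <- spec$n; R <- spec$ring_radius
  ga <- spec$adjacent_angle * pi / 180
  gb <- spec$bend_angle * pi / 180

  # anchor construction in the layer plane (z = 0 before stacking)
  P <- c(R, 0, 0)                                  # beta-Pro69 CA
  Pn <- as.numeric(rot_z(360 / n) %*% P)           # same atom, next protomer
  u <- unitv(Pn - P)                               # chord direction
  zax <- c(0, 0, 1)
  A <- P + 6 * (cos(ga) * u + sin(ga) * zax)       # alpha-Gln70 CA
  w1 <- unitv(c(-1, 0, 0) + 0.35 * zax)            # inward and slightly up
  V <- A + 8 * w1                                  # alpha-Arg30 CA (vertex)
  e1 <- unitv(A - V)
  m2 <- unitv(cross3(e1, u))
  B <- V + 8 * (cos(gb) * e1 + sin(gb) * m2)       # beta-Gly70 CA

  O <- (A + V + P) / 3                             # protomer local origin

  # helical C-alpha filler around a local centre, radius ~4 A
  filler <- function(center, resnos, skip, phase) {
    keep <- setdiff(resnos, skip)
    k <- seq_along(keep)
    t(vapply(k, function(i) center + c(4 * cos(phase + 0.6 * i),
                                       4 * sin(phase + 0.6 * i),
                                       1.4 * (i - length(k) / 2) * 0.45),
             numeric(3)))
  }

  atom_row <- function(xyz, name, resid, resno, chain, element, hetero = FALSE)
    data.frame(element = element, name = name, resid = resid, resno = resno,
               chain = chain, x = xyz[1], y = xyz[2], z = xyz[3],
               hetero = hetero, occ = 1, b = 0, stringsAsFactors = FALSE)

  # chromophore: SG already placed; 5 heavy atoms starting 1.81 A from SG
  chromophore <- function(sg, dir, chain, resno) {
    d1 <- unitv(dir)
    d2 <- unitv(cross3(d1, c(0, 0, 1)) + 0.2)
    pos <- rbind(sg + 1.81 * d1,
                 sg + 3.2 * d1 + 0.8 * d2,
                 sg + 4.5 * d1,
                 sg + 4.0 * d1 - 1.2 * d2,
                 sg + 5.6 * d1 + 0.5 * d2)
    el <- c("C", "C", "N", "C", "C")
    do.call(rbind, lapply(seq_len(5), function(i)
      atom_row(pos[i, ], paste0(el[i], i), "CYC", resno, chain, el[i],
               hetero = TRUE)))
  }

  # ---- protomer 0, alpha chain: residues 30..85, anchors 30 and 70,
  #      CYS 84 with SG and chromophore
  build_protomer <- function(chain_a, chain_b) {
    a_res <- 30:85
    a_core <- O + c(-3, 2, 1)
    fa <- filler(a_core, a_res, skip = c(30, 70, 84), phase = 0.3)
    rows <- list(atom_row(V, "CA", "ARG", 30, chain_a, "C"),
                 atom_row(A, "CA", "GLN", 70, chain_a, "C"))
    keep <- setdiff(a_res, c(30, 70, 84))
    for (i in seq_along(keep))
      rows[[length(rows) + 1L]] <- atom_row(fa[i, ], "CA", "ALA", keep[i],
                                            chain_a, "C")
    cys_a <- a_core + c(5, -2, 2)
    sg_a <- cys_a + c(1.2, 0.8, 0.6)
    rows[[length(rows) + 1L]] <- atom_row(cys_a, "CA", "CYS", 84, chain_a, "C")
    rows[[length(rows) + 1L]] <- atom_row(sg_a, "SG", "CYS", 84, chain_a, "S")
    rows[[length(rows) + 1L]] <- chromophore(sg_a, c(0.7, 0.5, 0.5), chain_a, 201)

    # beta chain: residues 60..90, anchors 69 and 70, CYS 82
    b_res <- 60:90
    b_core <- O + c(3, -2, -1)
    fb <- filler(b_core, b_res, skip = c(69, 70, 82), phase = 2.1)
    rows[[length(rows) + 1L]] <- atom_row(P, "CA", "PRO", 69, chain_b, "C")
    rows[[length(rows) + 1L]] <- atom_row(B, "CA", "GLY", 70, chain_b, "C")
    keepb <- setdiff(b_res, c(69, 70, 82))
    for (i in seq_along(keepb))
      rows[[length(rows) + 1L]] <- atom_row(fb[i, ], "CA", "ALA", keepb[i],
                                            chain_b, "C")
    # place the beta chromophore so the intra-protomer a84PCB-b82PCB
    # centroid spacing matches the ~20 angstrom PCB pair spacing seen in
    # phycocyanin rings
    cys_b <- b_core + c(-4, 3, -2)
    sg_b <- cys_b + c(-1.0, 1.0, 0.5)
    chrom_a <- chromophore(sg_a, c(0.7, 0.5, 0.5), chain_a, 201)
    chrom_b <- chromophore(sg_b, c(-0.6, 0.6, 0.4), chain_b, 202)
    cen_a <- colMeans(atom_xyz(chrom_a))
    cen_b <- colMeans(atom_xyz(chrom_b))
    shift <- (20.0 - sqrt(sum((cen_b - cen_a)^2))) * unitv(cen_b - cen_a)
    chrom_b$x <- chrom_b$x + shift[1]
    chrom_b$y <- chrom_b$y + shift[2]
    chrom_b$z <- chrom_b$z + shift[3]
    cys_b <- cys_b + shift; sg_b <- sg_b + shift
    rows[[length(rows) + 1L]] <- atom_row(cys_b, "CA", "CYS", 82, chain_b, "C")
    rows[[length(rows) + 1L]] <- atom_row(sg_b, "SG", "CYS", 82, chain_b, "S")
    rows[[length(rows) + 1L]] <- chrom_b
    do.call(rbind, rows)
  }

  chain_pool <- c(LETTERS, letters, as.character(0:9))
  total <- n * spec$layers
  if (2 * total > length(chain_pool)) stop("too many chains for the id pool")

  proto0 <- build_protomer("?", "!")  # placeholder chain ids
  layers_atoms <- list()
  truth_sites <- list()
  pidx <- 0L
  for (ly in seq_len(spec$layers)) {
    for (i in seq_len(n) - 1L) {
      at <- proto0
      ca <- chain_pool[2 * pidx + 1]; cb <- chain_pool[2 * pidx + 2]
      at$chain[at$chain == "?"] <- ca
      at$chain[at$chain == "!"] <- cb
      xyz <- atom_xyz(at)
      Rz <- rot_z(360 * i / n)
      xyz <- xyz %*% t(Rz)
      xyz[, 3] <- xyz[, 3] + spec$layer_offset
      if (ly == 2) {  # 2-fold about the x axis: (x, y, z) -> (x, -y, -z)
        xyz[, 2] <- -xyz[, 2]
        xyz[, 3] <- -xyz[, 3]
      }
      at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
      layers_atoms[[length(layers_atoms) + 1L]] <- at
      for (ch in c(ca, cb)) {
        hm <- at[at$hetero & at$chain == ch, , drop = FALSE]
        cen <- colMeans(atom_xyz(hm))
        role <- if (ch == ca) "a" else "b"
        anch <- if (ch == ca) 84L else 82L
        truth_sites[[length(truth_sites) + 1L]] <-
          data.frame(id = paste0(role, anch, "PCB"), protomer = pidx,
                     layer = ly, x = cen[1], y = cen[2], z = cen[3],
                     stringsAsFactors = FALSE)
      }
      pidx <- pidx + 1L
    }
  }
  atoms <- do.call(rbind, layers_atoms)
  if (spec$jitter_sigma > 0) {
    noise <- with_seed(spec$seed,
                       matrix(rnorm(3L * nrow(atoms), sd = spec$jitter_sigma),
                              ncol = 3))
    atoms$x <- atoms$x + noise[, 1]
    atoms$y <- atoms$y + noise[, 2]
    atoms$z <- atoms$z + noise[, 3]
  }
  asm <- assembly(atoms)
  asm <- group_protomers(asm, pairing = "by_order")
  list(assembly = asm,
       truth = list(axis = c(0, 0, 1), center = c(0, 0, 0),
                    n = n, layers = spec$layers,
                    sym_type = if (spec$layers == 2) "Dn" else "Cn",
                    bend_angle = spec$bend_angle,
                    adjacent_angle = spec$adjacent_angle,
                    interface_rotation = 360 / n,
                    chromophores = do.call(rbind, truth_sites),
                    spec = spec))
}

#' Write a synthetic assembly fixture
#'
#' Thin wrapper over [write_structure()] for generated assemblies; the file
#' round-trips through [read_structure()] with coordinates preserved to the
#' format precision (1e-3 angstrom).
#'
#' @param assembly an [assembly()] (or the list returned by [build_ring()]).
#' @param path output path.
#' @param format `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(assembly, path, format = c("pdb", "mmcif")) {
  if (!inherits(assembly, "assembly") && !is.null(assembly$assembly))
    assembly <- assembly$assembly
  write_structure(assembly, path, format)
}

#' Specification of a synthetic sedimentation-velocity experiment
#'
#' The default species mixture emulates a dilute phycocyanin solution whose
#' dominant species is the dimer: monomer, dimer, tetramer and hexamer at
#' 3.15, 5.24, 7.97 and 11.32 S, a shared frictional ratio of 1.195, and
#' i.i.d. Gaussian scan noise of sd 0.005 absorbance — the regime in which a
#' well-converged c(s) fit has rmsd below 0.01.
#'
#' @param species data frame with columns `s` (Svedberg), `f_ratio` and
#'   `loading` (absorbance units).
#' @param noise_sigma Gaussian noise sd, absorbance units.
#' @param times scan times, seconds.
#' @param seed RNG seed.
#' @return an `auc_spec` list.
#' @export
auc_spec <- function(species = data.frame(s = c(3.15, 5.24, 7.97, 11.32),
                                          f_ratio = 1.195,
                                          loading = c(0.15, 0.60, 0.10, 0.15)),
                     noise_sigma = 0.005,
                     times = seq(300, 9000, by = 300),
                     seed = 0) {
  stopifnot(all(species$loading >= 0), noise_sigma >= 0)
  structure(list(species = species, noise_sigma = noise_sigma,
                 times = as.numeric(times), seed = as.integer(seed)),
            class = "auc_spec")
}

#' Simulate a sedimentation-velocity experiment
#'
#' Per-species diffusion coefficients from the frictional-ratio scaling law,
#' forward Lamm simulation of each species, summed scans plus seeded i.i.d.
#' Gaussian noise.
#'
#' @param spec an [auc_spec()].
#' @param buffer a [hydro_params()].
#' @param vbar partial specific volume, mL/g.
#' @param ... further arguments to [lamm_simulate()] (geometry, ncell, ...).
#' @return a `sedimentation_dataset`; the generating species table (with D)
#'   is attached as `$species` and the noise level as `$noise_sigma`.
#' @export
simulate_auc <- function(spec, buffer = hydro_params(), vbar = buffer$vbar,
                         ...) {
  stopifnot(inherits(spec, "auc_spec"))
  sp <- spec$species
  species <- if (nrow(sp))
    data.frame(s = sp$s,
               D = diffusion_coefficient(sp$s, sp$f_ratio, buffer, vbar),
               loading = sp$loading)
  else data.frame(s = numeric(0), D = numeric(0), loading = numeric(0))
  ds <- lamm_simulate(species, times = spec$times, buffer = buffer, ...)
  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed,
                       matrix(rnorm(length(ds$scans), sd = spec$noise_sigma),
                              nrow = nrow(ds$scans)))
    ds$scans <- ds$scans + noise
  }
  ds$noise_sigma <- spec$noise_sigma
  ds$truth <- sp
  ds
}
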