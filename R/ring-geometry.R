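#' Angle at a vertex between three points
#'
#' The planar angle at `p2` between the rays `p2 -> p1` and `p2 -> p3`.
#'
#' @param p1,p2,p3 3-vectors (angstrom). `p2` is the vertex.
#' @return angle in degrees, in `[0, 180]`.
#' @export
vertex_angle <- function(p1, p2, p3) {
  u <- as.numeric(p1) - as.numeric(p2)
  v <- as.numeric(p3) - as.numeric(p2)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-9 || nv < 1e-9) stop("coincident points: angle undefined")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

# default anchor residues (author numbering): the monomer bend angle is
# measured at alpha-Arg30 between alpha-Gln70 and beta-Gly70; the
# adjacent-monomer angle at beta-Pro69 between alpha-Gln70 of the same
# protomer and beta-Pro69 of the next protomer around the ring.
.default_bend_anchors <- list(c("alpha", 70), c("alpha", 30), c("beta", 70))
.default_adjacent_anchors <- list(c("alpha", 70), c("beta", 69), c("beta", 69))

anchor_ca <- function(assembly, protomer_index, role, resno) {
  pt <- assembly$protomers
  if (is.null(pt)) stop("assembly has no protomer assignment; call group_protomers()")
  row <- pt[pt$index == protomer_index, , drop = FALSE]
  if (!nrow(row)) stop("no protomer with index ", protomer_index)
  chain <- if (role == "alpha") row$alpha else row$beta
  at <- assembly$atoms
  hit <- at[at$chain == chain & !at$hetero & at$name == "CA" &
              at$resno == as.integer(resno), , drop = FALSE]
  if (!nrow(hit)) stop("anchor residue ", role, resno,
                       " (chain ", chain, ") has no C-alpha atom")
  as.numeric(hit[1, c("x", "y", "z")])
}

parse_anchor <- function(a) list(role = match.arg(a[[1]], c("alpha", "beta")),
                                 resno = as.integer(a[[2]]))

#' Bend angle of an (alpha-beta) protomer
#'
#' The internal bend of one protomer, measured as the planar angle between
#' three anchor C-alpha atoms, vertex at the middle anchor (defaults:
#' alpha-Gln70, alpha-Arg30 vertex, beta-Gly70). Three points define no
#' torsion, so the measurement is the planar vertex angle.
#'
#' @param assembly an [assembly()] with protomers assigned.
#' @param protomer 0-based protomer index, or `NULL` for all protomers.
#' @param anchors list of three `c(role, resno)` anchors (role `"alpha"` or
#'   `"beta"`); the second entry is the vertex.
#' @return data frame with columns `protomer`, `value` (degrees) and `label`;
#'   the mean over the symmetry-equivalent copies is in attribute `"mean"`.
#' @export
monomer_bend_angle <- function(assembly, protomer = NULL,
                               anchors = .default_bend_anchors) {
  an <- lapply(anchors, parse_anchor)
  idx <- if (is.null(protomer)) assembly$protomers$index else protomer
  vals <- vapply(idx, function(i) {
    vertex_angle(anchor_ca(assembly, i, an[[1]]$role, an[[1]]$resno),
                 anchor_ca(assembly, i, an[[2]]$role, an[[2]]$resno),
                 anchor_ca(assembly, i, an[[3]]$role, an[[3]]$resno))
  }, numeric(1))
  lab <- paste0(vapply(an, function(a) paste0(a$role, a$resno), character(1)),
                collapse = "-")
  out <- data.frame(protomer = idx, value = vals, label = lab,
                    stringsAsFactors = FALSE)
  attr(out, "mean") <- mean(vals)
  out
}

# protomer adjacency: both azimuthal neighbours within the same layer
adjacent_index <- function(assembly) {
  pt <- assembly$protomers
  nxt <- integer(nrow(pt)); prv <- integer(nrow(pt))
  for (ly in unique(pt$layer)) {
    rows <- which(pt$layer == ly)
    ord <- rows[order(pt$azimuth[rows])]
    nxt[ord] <- c(ord[-1], ord[1])
    prv[ord] <- c(ord[length(ord)], ord[-length(ord)])
  }
  data.frame(index = pt$index, next_index = pt$index[nxt],
             prev_index = pt$index[prv])
}

#' Angle between adjacent protomers
#'
#' The planar angle spanning two neighbouring protomers in the same ring
#' layer: vertex at the middle anchor of protomer `i` (default beta-Pro69),
#' rays to the first anchor of protomer `i` (default alpha-Gln70) and to the
#' third anchor of the adjacent protomer (default its beta-Pro69). Of the two
#' azimuthal neighbours in the layer, the structurally adjacent one is taken
#' as the protomer whose third-anchor atom lies nearer the first anchor of
#' protomer `i` — this makes the measurement independent of the azimuthal
#' orientation of the layer (the two layers of a Dn assembly wind in
#' opposite senses).
#'
#' @inheritParams monomer_bend_angle
#' @param i 0-based protomer index, or `NULL` for all protomers.
#' @return data frame as in [monomer_bend_angle()], with a `neighbor` column.
#' @export
adjacent_monomer_angle <- function(assembly, i = NULL,
                                   anchors = .default_adjacent_anchors) {
  an <- lapply(anchors, parse_anchor)
  adj <- adjacent_index(assembly)
  idx <- if (is.null(i)) adj$index else i
  rowsel <- match(idx, adj$index)
  pick <- function(ii, jn, jp) {
    p1 <- anchor_ca(assembly, ii, an[[1]]$role, an[[1]]$resno)
    dn <- sum((anchor_ca(assembly, jn, an[[3]]$role, an[[3]]$resno) - p1)^2)
    dp <- sum((anchor_ca(assembly, jp, an[[3]]$role, an[[3]]$resno) - p1)^2)
    if (dn <= dp) jn else jp
  }
  nb <- mapply(pick, idx, adj$next_index[rowsel], adj$prev_index[rowsel])
  vals <- mapply(function(ii, jj) {
    vertex_angle(anchor_ca(assembly, ii, an[[1]]$role, an[[1]]$resno),
                 anchor_ca(assembly, ii, an[[2]]$role, an[[2]]$resno),
                 anchor_ca(assembly, jj, an[[3]]$role, an[[3]]$resno))
  }, idx, nb)
  lab <- paste0(vapply(an, function(a) paste0(a$role, a$resno), character(1)),
                collapse = "-")
  out <- data.frame(protomer = idx, neighbor = nb, value = vals, label = lab,
                    stringsAsFactors = FALSE)
  attr(out, "mean") <- mean(vals)
  out
}

#' Rotation angle between two protomers
#'
#' Superposes protomer `i` onto protomer `j` (C-alpha atoms matched by
#' residue number within the alpha and beta chains) and returns the rotation
#' angle of the optimal rigid transform. For an ideal n-fold ring, adjacent
#' protomers give exactly 360/n degrees.
#'
#' @param assembly an [assembly()] with protomers assigned.
#' @param i,j 0-based protomer indices.
#' @return angle in degrees.
#' @export
interface_rotation <- function(assembly, i, j) {
  pt <- assembly$protomers
  ri <- pt[pt$index == i, , drop = FALSE]
  rj <- pt[pt$index == j, , drop = FALSE]
  if (!nrow(ri) || !nrow(rj)) stop("unknown protomer index")
  ma <- match_ca(assembly, ri$alpha, rj$alpha)
  mb <- match_ca(assembly, ri$beta, rj$beta)
  tr <- superpose(rbind(ma$xyz_a, mb$xyz_a), rbind(ma$xyz_b, mb$xyz_b))
  rotation_angle(tr)
}

#' Detect the cyclic/dihedral symmetry of a ring assembly
#'
#' Scores, for each candidate ring order n, the hypothesis that the protomer
#' centroids of each layer lie at 360/n spacing about a principal axis. Both
#' extreme eigenvectors of the centroid covariance are tried as the axis
#' (oblate rings put the axis along the smallest-eigenvalue direction,
#' prolate stacks along the largest) and the one with the lower angular
#' residual is kept. The symmetry type is Dn when two layers related by a
#' perpendicular 2-fold axis are found, otherwise Cn.
#'
#' @param assembly an [assembly()] with at least 2 protomers assigned.
#' @param candidate_orders integer vector of ring orders to score.
#' @param two_fold_tol tolerance (degrees) for matching the two layers under
#'   a perpendicular 2-fold rotation.
#' @return a `symmetry_report`: list with `order_n`, `sym_type`, `axis`,
#'   `center`, `per_interface_angle` (consecutive azimuth gaps, degrees),
#'   `mean_angle_residual`, `layers` and the per-protomer `frame`.
#' @export
detect_symmetry <- function(assembly, candidate_orders = 2:12,
                            two_fold_tol = 10) {
  pt <- assembly$protomers
  if (is.null(pt) || nrow(pt) < 2) stop("need at least 2 assigned protomers")
  if (nrow(pt) < min(candidate_orders))
    stop("fewer protomers (", nrow(pt), ") than the smallest candidate order (",
         min(candidate_orders), ")")
  prot <- assembly$atoms[!assembly$atoms$hetero, , drop = FALSE]
  cen <- t(vapply(seq_len(nrow(pt)), function(k)
    colMeans(atom_xyz(prot[prot$chain %in% c(pt$alpha[k], pt$beta[k]), ,
                           drop = FALSE])), numeric(3)))
  X <- sweep(cen, 2, colMeans(cen))
  axes <- if (nrow(cen) >= 3) {
    ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
    list(ev$vectors[, 3], ev$vectors[, 1])
  } else list(c(0, 0, 1))

  best <- NULL
  for (ax in axes) {
    fr <- ring_frame(cen, axis = ax)
    for (n in sort(candidate_orders)) {
      res <- order_residual(fr, n)
      if (!is.finite(res)) next
      # tie-break: prefer the larger n when residuals agree within 1e-3 deg
      if (is.null(best) || res < best$res - 1e-3 ||
          (abs(res - best$res) <= 1e-3 && n > best$n)) {
        best <- list(n = n, res = res, frame = fr)
      }
    }
  }
  if (is.null(best)) stop("no candidate order matches the protomer layout ",
                          "(layer sizes ", paste(table(ring_frame(cen)$layer),
                                                 collapse = "/"), ")")
  fr <- best$frame
  nlayer <- length(unique(fr$layer))
  sym_type <- if (nlayer == 2 && has_two_fold(fr, tol = two_fold_tol))
    "Dn" else "Cn"
  gaps <- unlist(lapply(unique(fr$layer), function(ly) {
    az <- sort(fr$azimuth[fr$layer == ly])
    diff(c(az, az[1] + 360))
  }))
  structure(list(order_n = best$n, sym_type = sym_type, axis = fr$axis,
                 center = fr$center, per_interface_angle = as.numeric(gaps),
                 mean_angle_residual = best$res, layers = nlayer,
                 frame = fr, centroids = cen),
            class = "symmetry_report")
}

# score of the "n protomers per layer at 360/n spacing" hypothesis: the mean
# angular gap deviation plus a radial-consistency penalty (a true ring axis
# sees all centroids at a common radius; a spurious in-plane axis does not),
# expressed in degrees so the two terms are commensurate
order_residual <- function(frame, n) {
  layers <- unique(frame$layer)
  res <- vapply(layers, function(ly) {
    sel <- frame$layer == ly
    az <- sort(frame$azimuth[sel])
    if (length(az) != n) return(Inf)
    gaps <- diff(c(az, az[1] + 360))
    rad <- frame$radial[sel]
    pen <- if (mean(rad) > 0) stats::sd(rad) / mean(rad) * 180 / pi else 0
    mean(abs(gaps - 360 / n)) + pen
  }, numeric(1))
  mean(res)
}

# do the two layers map onto each other under some 2-fold axis perpendicular
# to the principal axis?
has_two_fold <- function(frame, tol = 10) {
  a <- which(frame$layer == 1L); b <- which(frame$layer == 2L)
  if (length(a) != length(b)) return(FALSE)
  azA <- frame$azimuth[a]; azB <- frame$azimuth[b]
  for (k in seq_along(b)) {
    psi <- (azA[1] + azB[k]) / 2
    mapped <- (2 * psi - azA) %% 360
    d <- vapply(mapped, function(m) min(abs(((azB - m + 180) %% 360) - 180)),
                numeric(1))
    if (all(d < tol)) return(TRUE)
  }
  FALSE
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat(sprintf("<symmetry_report> order n = %d, type %s (%d layer%s)\n",
              x$order_n, sub("n$", as.character(x$order_n), x$sym_type),
              x$layers, if (x$layers > 1) "s" else ""))
  cat(sprintf("  axis (%.3f, %.3f, %.3f), mean angular residual %.3f deg\n",
              x$axis[1], x$axis[2], x$axis[3], x$mean_angle_residual))
  invisible(x)
}

#' Ideal rotation-angle difference between two ring orders
#'
#' For rings of order n and m built from the same subunit, the inter-subunit
#' rotation angles differ by (360/n - 360/m) degrees; positive when n < m.
#'
#' @param n,m ring orders (>= 2).
#' @return degrees.
#' @export
delta_theta <- function(n, m) {
  if (any(c(n, m) < 2)) stop("ring orders must be >= 2")
  360 / n - 360 / m
}

#' Inner pore diameter of a ring assembly
#'
#' Twice the minimum over heavy atoms of the radial distance to the symmetry
#' axis minus that atom's van der Waals radius; the raw centre-to-nearest-atom
#' diameter is reported alongside.
#'
#' @param assembly an [assembly()].
#' @param axis,center symmetry axis and centre; taken from
#'   [detect_symmetry()] when `NULL`.
#' @return list with `pore_diameter`, `raw_diameter` (angstrom) and
#'   `is_ring` (FALSE when fewer than 3 protomers enclose no pore).
#' @export
pore_diameter <- function(assembly, axis = NULL, center = NULL) {
  if (is.null(axis) || is.null(center)) {
    sym <- detect_symmetry(assembly)
    axis <- sym$axis; center <- sym$center
  }
  axis <- axis / sqrt(sum(axis^2))
  at <- assembly$atoms[toupper(assembly$atoms$element) != "H", , drop = FALSE]
  X <- sweep(atom_xyz(at), 2, center)
  axial <- X %*% axis
  radial <- sqrt(pmax(0, rowSums(X^2) - axial^2))
  rv <- vdw_radius(at$element)
  list(pore_diameter = 2 * min(radial - rv),
       raw_diameter = 2 * min(radial),
       is_ring = n_protomers(assembly) >= 3)
}
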