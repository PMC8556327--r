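#' Group chains into (alpha-beta) protomers
#'
#' Pairs the protein chains of an assembly into alpha/beta protomers — the
#' repeating heterodimer unit of the ring — and assigns protomer indices by
#' angular position about the assembly's centroid axis.
#'
#' `by_contact` pairs each putative alpha chain (taken in file order) with
#' the unpaired protein chain sharing the largest inter-chain contact count
#' within 5 angstrom; pairing is refused as ambiguous when the two best
#' candidates are within 5% of each other's contact count. `by_order` pairs
#' chains in file order (1st+2nd, 3rd+4th, ...).
#'
#' @param assembly an [assembly()] with an even number of protein chains.
#' @param pairing `"by_contact"` or `"by_order"`.
#' @param contact_cutoff contact distance in angstrom (default 5).
#' @return the assembly with `$protomers` assigned (columns `alpha`, `beta`,
#'   `index`, `layer`).
#' @export
group_protomers <- function(assembly, pairing = c("by_contact", "by_order"),
                            contact_cutoff = 5) {
  pairing <- match.arg(pairing)
  at <- assembly$atoms
  prot <- at[!at$hetero, , drop = FALSE]
  chains <- unique(prot$chain)  # file order
  if (length(chains) < 2L) stop("need at least two protein chains")
  if (length(chains) %% 2L != 0L)
    stop("odd number of protein chains (", length(chains),
         "); cannot pair into (alpha-beta) protomers")

  if (pairing == "by_order") {
    pairs <- matrix(chains, ncol = 2, byrow = TRUE)
  } else {
    xyz_by_chain <- lapply(chains, function(ch)
      atom_xyz(prot[prot$chain == ch, , drop = FALSE]))
    names(xyz_by_chain) <- chains
    contacts <- function(a, b) {
      A <- xyz_by_chain[[a]]; B <- xyz_by_chain[[b]]
      # chunked pairwise count within cutoff
      cut2 <- contact_cutoff^2
      n <- 0L
      step <- 500L
      for (i0 in seq(1, nrow(A), by = step)) {
        Ai <- A[i0:min(i0 + step - 1L, nrow(A)), , drop = FALSE]
        d2 <- outer(rowSums(Ai^2), rowSums(B^2), "+") - 2 * Ai %*% t(B)
        n <- n + sum(d2 < cut2)
      }
      n
    }
    unpaired <- chains
    pairs <- matrix(character(0), 0, 2)
    while (length(unpaired) > 1L) {
      a <- unpaired[1]
      cand <- unpaired[-1]
      cc <- vapply(cand, function(b) as.numeric(contacts(a, b)), numeric(1))
      ord <- order(cc, decreasing = TRUE)
      best <- cand[ord[1]]
      if (length(cand) > 1L) {
        c1 <- cc[ord[1]]; c2 <- cc[ord[2]]
        if (c1 == 0 || c2 >= 0.95 * c1)
          stop("ambiguous contact pairing for chain ", a, ": candidates ",
               cand[ord[1]], " (", c1, " contacts) and ", cand[ord[2]],
               " (", c2, " contacts)")
      }
      pairs <- rbind(pairs, c(a, best))
      unpaired <- setdiff(unpaired, c(a, best))
    }
  }

  # centroid of each protomer's protein atoms
  cen <- t(apply(pairs, 1, function(p)
    colMeans(atom_xyz(prot[prot$chain %in% p, , drop = FALSE]))))
  fr <- ring_frame(cen)
  pt <- data.frame(alpha = pairs[, 1], beta = pairs[, 2],
                   layer = fr$layer, azimuth = fr$azimuth,
                   stringsAsFactors = FALSE)
  ord <- order(pt$layer, pt$azimuth)
  pt <- pt[ord, , drop = FALSE]
  pt$index <- seq_len(nrow(pt)) - 1L
  rownames(pt) <- NULL
  assembly$protomers <- pt[, c("alpha", "beta", "index", "layer", "azimuth")]
  assembly
}

# geometric frame of a set of protomer centroids: principal axis, center,
# axial coordinate, azimuth (degrees, [0, 360)), and layer split
ring_frame <- function(centroids, axis = NULL) {
  centroids <- as.matrix(centroids)
  center <- colMeans(centroids)
  X <- sweep(centroids, 2, center)
  if (is.null(axis)) {
    if (nrow(centroids) >= 3) {
      ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
      # oblate ring: centroids spread in the plane normal to the axis, so the
      # axis is the smallest-eigenvalue direction; prolate stacks the largest.
      # detect_symmetry disambiguates by residual; default to smallest here.
      axis <- ev$vectors[, 3]
    } else axis <- c(0, 0, 1)
  }
  axis <- axis / sqrt(sum(axis^2))
  axial <- as.numeric(X %*% axis)
  # in-plane basis
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  az <- atan2(as.numeric(X %*% e2), as.numeric(X %*% e1)) * 180 / pi
  az <- (az + 360) %% 360
  radial <- sqrt(pmax(0, rowSums(X^2) - axial^2))
  list(center = center, axis = axis, axial = axial, azimuth = az,
       radial = radial, layer = split_layers(axial))
}

# split axial coordinates into 1 or 2 layers by the largest gap
split_layers <- function(axial) {
  n <- length(axial)
  if (n < 2) return(rep(1L, n))
  o <- order(axial)
  s <- axial[o]
  gaps <- diff(s)
  if (!length(gaps) || max(gaps) < max(5, 0.6 * (max(s) - min(s))))
    return(rep(1L, n))
  cutpos <- which.max(gaps)
  layer <- integer(n)
  layer[o] <- ifelse(seq_len(n) <= cutpos, 1L, 2L)
  layer
}
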