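#' Locate covalently bound chromophores
#'
#' Every hetero residue whose name is in `residue_names` becomes a
#' chromophore site. Phycocyanobilin (PCB) chromophores are thioether-linked
#' to conserved cysteines, so the anchor cysteine is found as the nearest
#' cysteine S-gamma within `max_thioether` angstrom of any chromophore
#' carbon; the site id is formed from the anchor chain's role and residue
#' number (e.g. `a84PCB` for the chromophore on alpha-Cys84). A site whose
#' anchor cannot be found within the cutoff is kept with the anchor unset,
#' with a warning.
#'
#' @param assembly an [assembly()] parsed with hetero residues (protomers
#'   should be assigned so chain roles are known).
#' @param residue_names hetero residue names treated as chromophores.
#' @param max_thioether maximum S-gamma-to-carbon bond distance (angstrom).
#' @param assembly_id label distinguishing assemblies in multi-assembly
#'   networks.
#' @return data frame of sites: `id`, `resid`, `chain`, `resno`,
#'   `anchor_chain`, `anchor_resno`, `protomer`, `assembly_id`, centroid
#'   `x`, `y`, `z` (unweighted mean of the chromophore's heavy atoms).
#' @export
locate_chromophores <- function(assembly,
                                residue_names = c("CYC", "PCB", "BLA"),
                                max_thioether = 2.5,
                                assembly_id = "A1") {
  at <- assembly$atoms
  chrom <- at[at$hetero & at$resid %in% residue_names &
                toupper(at$element) != "H", , drop = FALSE]
  empty <- data.frame(id = character(0), resid = character(0),
                      chain = character(0), resno = integer(0),
                      anchor_chain = character(0), anchor_resno = integer(0),
                      protomer = integer(0), assembly_id = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(chrom)) return(empty)
  sg <- at[!at$hetero & at$resid == "CYS" & at$name == "SG", , drop = FALSE]
  pt <- assembly$protomers
  role_of <- function(chain) {
    if (is.null(pt)) return(NA_character_)
    if (chain %in% pt$alpha) "a" else if (chain %in% pt$beta) "b"
    else NA_character_
  }
  protomer_of <- function(chain) {
    if (is.null(pt)) return(NA_integer_)
    hit <- pt$index[pt$alpha == chain | pt$beta == chain]
    if (length(hit)) hit[1] else NA_integer_
  }
  key <- paste(chrom$chain, chrom$resno, chrom$resid)
  sites <- lapply(unique(key), function(k) {
    g <- chrom[key == k, , drop = FALSE]
    cen <- colMeans(atom_xyz(g))
    carb <- g[toupper(g$element) == "C", , drop = FALSE]
    anchor_chain <- NA_character_; anchor_resno <- NA_integer_
    if (nrow(sg) && nrow(carb)) {
      d2 <- outer(rowSums(atom_xyz(sg)^2), rowSums(atom_xyz(carb)^2), "+") -
        2 * atom_xyz(sg) %*% t(atom_xyz(carb))
      dmin <- sqrt(pmax(0, apply(d2, 1, min)))
      if (min(dmin) <= max_thioether) {
        w <- which.min(dmin)
        anchor_chain <- sg$chain[w]; anchor_resno <- sg$resno[w]
      }
    }
    if (is.na(anchor_chain))
      warning("chromophore ", g$resid[1], " ", g$chain[1], g$resno[1],
              " has no cysteine S-gamma within ", max_thioether,
              " A; anchor unset", call. = FALSE)
    role <- if (is.na(anchor_chain)) NA_character_ else role_of(anchor_chain)
    id <- if (is.na(anchor_chain) || is.na(role))
      paste0(g$chain[1], g$resno[1], "PCB")
    else paste0(role, anchor_resno, "PCB")
    data.frame(id = id, resid = g$resid[1], chain = g$chain[1],
               resno = g$resno[1], anchor_chain = anchor_chain,
               anchor_resno = anchor_resno,
               protomer = if (is.na(anchor_chain)) protomer_of(g$chain[1])
                          else protomer_of(anchor_chain),
               assembly_id = assembly_id,
               x = cen[1], y = cen[2], z = cen[3], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, sites)
  rownames(out) <- NULL
  out
}

#' Pairwise chromophore distance network
#'
#' All pairwise centroid-to-centroid distances between chromophore sites.
#' Edges between sites of the same `assembly_id` are classed
#' `"intraprotein"`, others `"interprotein"`. For each named pair label the
#' minimum distance over symmetry-equivalent copies is summarised, matching
#' how representative distances are reported for symmetric assemblies.
#'
#' @param sites site table from [locate_chromophores()] (>= 2 sites; rbind
#'   tables from several assemblies for inter-assembly networks).
#' @param cutoff optional maximum edge distance (angstrom).
#' @return a `distance_network`: list with `nodes`, `edges` (data frame
#'   `id_a`, `id_b`, `dist`, `class`) and `named_pairs` (minimum distance per
#'   unordered id pair).
#' @export
pair_distances <- function(sites, cutoff = Inf) {
  if (nrow(sites) < 2) stop("need at least 2 chromophore sites")
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  n <- nrow(sites)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt(rowSums((xyz[ij[, 1], , drop = FALSE] -
                       xyz[ij[, 2], , drop = FALSE])^2))
  cls <- ifelse(sites$assembly_id[ij[, 1]] == sites$assembly_id[ij[, 2]],
                "intraprotein", "interprotein")
  edges <- data.frame(id_a = sites$id[ij[, 1]], id_b = sites$id[ij[, 2]],
                      dist = d, class = cls, stringsAsFactors = FALSE)
  edges <- edges[edges$dist <= cutoff, , drop = FALSE]
  edges <- edges[order(edges$dist), , drop = FALSE]
  rownames(edges) <- NULL
  pairlab <- apply(cbind(edges$id_a, edges$id_b), 1, function(p)
    paste(sort(p), collapse = "-"))
  named <- if (nrow(edges)) {
    agg <- tapply(edges$dist, pairlab, min)
    data.frame(pair = names(agg), min_dist = as.numeric(agg),
               stringsAsFactors = FALSE)
  } else data.frame(pair = character(0), min_dist = numeric(0))
  rownames(named) <- NULL
  structure(list(nodes = sites, edges = edges, named_pairs = named,
                 cutoff = cutoff),
            class = "distance_network")
}

#' @export
print.distance_network <- function(x, ...) {
  cat("<distance_network> ", nrow(x$nodes), " sites, ", nrow(x$edges),
      " edges", if (is.finite(x$cutoff)) paste0(" (cutoff ", x$cutoff, " A)"),
      "\n", sep = "")
  if (nrow(x$edges)) {
    cat("  shortest edges:\n")
    print(head(x$edges, 5), row.names = FALSE)
  }
  invisible(x)
}

#' Minimum distance for a named chromophore pair
#'
#' @param network a `distance_network` from [pair_distances()].
#' @param id_a,id_b site id labels (e.g. `"a84PCB"`, `"b82PCB"`).
#' @param class optionally restrict to `"intraprotein"` or `"interprotein"`
#'   edges.
#' @return minimum distance in angstrom (NA when the pair is absent).
#' @export
named_pair_distance <- function(network, id_a, id_b, class = NULL) {
  e <- network$edges
  if (!is.null(class)) e <- e[e$class == class, , drop = FALSE]
  sel <- (e$id_a == id_a & e$id_b == id_b) | (e$id_a == id_b & e$id_b == id_a)
  if (!any(sel)) return(NA_real_)
  min(e$dist[sel])
}

#' Cross-layer chromophore distances between two stacked assemblies
#'
#' Restricts the chromophore network to pairs spanning two assemblies (for
#' example the two rings of a stacked crystal-packing unit), sorted by
#' ascending distance.
#'
#' @param layer_a,layer_b two [assembly()] objects sharing an axis.
#' @param ... passed to [locate_chromophores()].
#' @return a `distance_network` containing only cross-layer edges.
#' @export
stacked_layer_distances <- function(layer_a, layer_b, ...) {
  sa <- locate_chromophores(layer_a, assembly_id = "layerA", ...)
  sb <- locate_chromophores(layer_b, assembly_id = "layerB", ...)
  net <- pair_distances(rbind(sa, sb))
  net$edges <- net$edges[net$edges$class == "interprotein", , drop = FALSE]
  rownames(net$edges) <- NULL
  pairlab <- apply(cbind(net$edges$id_a, net$edges$id_b), 1, function(p)
    paste(sort(p), collapse = "-"))
  net$named_pairs <- if (nrow(net$edges)) {
    agg <- tapply(net$edges$dist, pairlab, min)
    data.frame(pair = names(agg), min_dist = as.numeric(agg),
               stringsAsFactors = FALSE)
  } else data.frame(pair = character(0), min_dist = numeric(0))
  net
}
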