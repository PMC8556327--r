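#' Oligomer assembly free-energy model
#'
#' Holds the standard dissociation free energies (dG0_diss, kcal/mol) of the
#' oligomeric states into monomers and derives formation free energies
#' between oligomers. The shipped defaults are the dissociation energies of
#' the dimer, trimer, tetramer, hexamer and octamer of the thermophilic
#' C-phycocyanin studied with this package (4.8, 20.9, 16.0, 54.6 and
#' 20.9 kcal/mol); they are treated as input data — interface-analysis
#' entropy parameterizations are not recomputed here.
#'
#' @param dG_diss named numeric vector: oligomer order n -> dG0_diss into
#'   monomers (kcal/mol). The monomer (n = 1) is implicitly 0.
#' @return an `assembly_energy_model`.
#' @export
assembly_energy_model <- function(dG_diss = c(`2` = 4.8, `3` = 20.9,
                                              `4` = 16.0, `6` = 54.6,
                                              `8` = 20.9)) {
  if (is.null(names(dG_diss)) || any(!nzchar(names(dG_diss))))
    stop("dG_diss must be named by oligomer order")
  tab <- c(`1` = 0, dG_diss)
  tab <- tab[!duplicated(names(tab))]
  structure(list(dG_diss = tab), class = "assembly_energy_model")
}

#' @export
print.assembly_energy_model <- function(x, ...) {
  cat("<assembly_energy_model> dG0_diss into monomers (kcal/mol):\n")
  ord <- names(x$dG_diss)[order(as.integer(names(x$dG_diss)))]
  for (n in ord) cat(sprintf("  n = %s: %6.1f\n", n, x$dG_diss[[n]]))
  rk <- stability_ranking(x)
  cat("  stability ranking (most stable first): ",
      paste(rk$n, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Oligomer stability ranking
#' @param model an [assembly_energy_model()].
#' @return data frame of oligomer orders sorted by decreasing dG0_diss.
#' @export
stability_ranking <- function(model) {
  n <- as.integer(names(model$dG_diss))
  keep <- n > 1
  out <- data.frame(n = n[keep], dG_diss = as.numeric(model$dG_diss[keep]))
  out <- out[order(-out$dG_diss), , drop = FALSE]
  rownames(out) <- NULL
  out
}

dG_of <- function(model, n) {
  key <- as.character(n)
  miss <- setdiff(unique(key), names(model$dG_diss))
  if (length(miss)) stop("no dG0_diss entry for oligomer order ",
                         paste(miss, collapse = ", "))
  as.numeric(model$dG_diss[key])
}

#' Formation free energy between oligomers
#'
#' The free energy of assembling `product` from `parts`:
#' `dG0_f = -(dG0_diss(product) - sum dG0_diss(parts))`. Negative values are
#' favourable formation. Monomer counts must balance.
#'
#' @param model an [assembly_energy_model()].
#' @param parts integer vector of part oligomer orders (e.g. `c(4, 4)`).
#' @param product product oligomer order (e.g. `8`).
#' @return dG0_f in kcal/mol.
#' @export
formation_energy <- function(model, parts, product) {
  if (sum(parts) != product)
    stop("unbalanced stoichiometry: parts supply ", sum(parts),
         " monomers but the product needs ", product)
  -(dG_of(model, product) - sum(dG_of(model, parts)))
}

# default assembly routes: each step is parts -> product
.default_routes <- list(
  "monomer-dimer-octamer" = list(list(parts = c(1, 1), product = 2),
                                 list(parts = c(2, 2, 2, 2), product = 8)),
  "monomer-trimer-hexamer" = list(list(parts = c(1, 1, 1), product = 3),
                                  list(parts = c(3, 3), product = 6)),
  "monomer-dimer-tetramer-octamer" = list(list(parts = c(1, 1), product = 2),
                                          list(parts = c(2, 2), product = 4),
                                          list(parts = c(4, 4), product = 8))
)

#' Assembly pathway table
#'
#' Per-step formation free energies along candidate assembly routes, with
#' unfavourable (positive dG0_f) steps flagged. Route totals telescope: the
#' summed step energies from monomers to the product equal
#' `-dG0_diss(product)` exactly.
#'
#' @param model an [assembly_energy_model()].
#' @param routes named list of routes; each route is a list of steps
#'   `list(parts = <orders>, product = <order>)`. Defaults cover
#'   monomer-dimer-octamer, monomer-trimer-hexamer and
#'   monomer-dimer-tetramer-octamer.
#' @return a `pathway_graph`: data frame with columns `route`, `step`,
#'   `parts`, `product`, `dG_f` (per single step event), `count` (how many
#'   times the step runs to build one final product) and `favorable`.
#' @export
pathway_graph <- function(model, routes = .default_routes) {
  rows <- list()
  for (rn in names(routes)) {
    steps <- routes[[rn]]
    K <- length(steps)
    # step multiplicities, walking back from one copy of the final product
    count <- rep(1, K)
    if (K > 1) for (k in (K - 1):1)
      count[k] <- sum(vapply((k + 1):K, function(j)
        count[j] * sum(steps[[j]]$parts == steps[[k]]$product), numeric(1)))
    for (k in seq_along(steps)) {
      st <- steps[[k]]
      dg <- formation_energy(model, st$parts, st$product)
      rows[[length(rows) + 1L]] <- data.frame(
        route = rn, step = k,
        parts = paste(st$parts, collapse = "+"),
        product = st$product, dG_f = dg, count = count[k],
        favorable = dg <= 0, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(route = character(0), step = integer(0), parts = character(0),
               product = integer(0), dG_f = numeric(0), count = numeric(0),
               favorable = logical(0))
  class(out) <- c("pathway_graph", "data.frame")
  out
}

#' Total formation energy of each route
#'
#' Sums `count * dG_f` over the steps of each route; for a route starting
#' from monomers this telescopes to `-dG0_diss(final product)` exactly.
#'
#' @param graph a [pathway_graph()].
#' @return data frame with `route`, `product` and `total_dG_f`.
#' @export
route_totals <- function(graph) {
  df <- as.data.frame(graph)
  out <- do.call(rbind, lapply(split(df, df$route), function(g)
    data.frame(route = g$route[1], product = g$product[nrow(g)],
               total_dG_f = sum(g$count * g$dG_f), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> step formation energies (kcal/mol; '!' = unfavourable)\n")
  df <- as.data.frame(x)
  if (nrow(df)) {
    df$flag <- ifelse(df$favorable, "", "!")
    print(df[, c("route", "step", "parts", "product", "dG_f", "count", "flag")],
          row.names = FALSE)
  }
  invisible(x)
}
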