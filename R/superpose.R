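#' Rigid-body superposition (Kabsch)
#'
#' Least-squares optimal rotation and translation mapping `moving` onto
#' `fixed`. The rotation is constrained to be a proper rotation
#' (determinant +1): biological assemblies are chiral, so a reflection is
#' never returned even when it would fit better.
#'
#' @param moving,fixed n x 3 coordinate matrices with paired rows (n >= 3,
#'   not all collinear).
#' @return a `rigid_transform`: list with `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd` (angstrom, residual after the transform) and
#'   `n_atoms`. The transform maps x to `rotation %*% x + translation`.
#' @export
superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stop("coordinate sets differ in length (",
                                        nrow(moving), " vs ", nrow(fixed), ")")
  if (ncol(moving) != 3 || ncol(fixed) != 3) stop("coordinates must be n x 3")
  n <- nrow(moving)
  if (n < 3) stop("need at least 3 paired points")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  X <- sweep(moving, 2, cm); Y <- sweep(fixed, 2, cf)
  sv0 <- svd(X)
  if (sv0$d[2] <= 1e-8 * max(sv0$d[1], 1e-12)) stop("points are collinear")
  H <- crossprod(X, Y)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- as.numeric(cf - R %*% cm)
  res <- Y - X %*% t(R)
  rmsd <- sqrt(sum(res^2) / n)
  structure(list(rotation = R, translation = tvec, rmsd = rmsd, n_atoms = n),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rmsd %.4f A over %d atoms, rotation angle %.3f deg\n",
              x$rmsd, x$n_atoms, rotation_angle(x)))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param transform a `rigid_transform` from [superpose()].
#' @param xyz n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, xyz) {
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Rotation angle of a rigid transform
#'
#' The angle theta = acos((trace(R) - 1) / 2) of the rotation component,
#' in degrees.
#'
#' @param transform a `rigid_transform` or a 3 x 3 rotation matrix.
#' @return angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(transform) {
  R <- if (inherits(transform, "rigid_transform")) transform$rotation else transform
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Pair the C-alpha atoms of two chains
#'
#' Builds matched coordinate sets for superposition. `by_resnum` pairs
#' residues sharing author residue numbers; `by_alignment` pairs residues by
#' global sequence alignment of the one-letter sequences (match +1,
#' mismatch 0, gap -1), keeping aligned non-gap columns.
#'
#' @param assembly an [assembly()] (or two assemblies via `assembly_b`).
#' @param chain_a,chain_b chain ids.
#' @param mode `"by_resnum"` or `"by_alignment"`.
#' @param assembly_b optional second assembly holding `chain_b`.
#' @return list with matrices `xyz_a`, `xyz_b` and vectors `resno_a`,
#'   `resno_b`.
#' @export
match_ca <- function(assembly, chain_a, chain_b,
                     mode = c("by_resnum", "by_alignment"), assembly_b = NULL) {
  mode <- match.arg(mode)
  ca_a <- chain_ca(assembly, chain_a)
  ca_b <- chain_ca(assembly_b %||% assembly, chain_b)
  if (mode == "by_resnum") {
    common <- intersect(ca_a$resno, ca_b$resno)
    if (!length(common)) stop("no shared residue numbers between chains ",
                              chain_a, " and ", chain_b)
    ia <- match(common, ca_a$resno); ib <- match(common, ca_b$resno)
  } else {
    s1 <- one_letter(ca_a$resid); s2 <- one_letter(ca_b$resid)
    mp <- align_pairs(s1, s2)
    if (!nrow(mp)) stop("alignment of chains ", chain_a, " and ", chain_b,
                        " has no aligned columns")
    ia <- mp[, 1]; ib <- mp[, 2]
  }
  list(xyz_a = atom_xyz(ca_a)[ia, , drop = FALSE],
       xyz_b = atom_xyz(ca_b)[ib, , drop = FALSE],
       resno_a = ca_a$resno[ia], resno_b = ca_b$resno[ib])
}

chain_ca <- function(assembly, chain) {
  at <- assembly$atoms
  ca <- at[at$chain == chain & !at$hetero & at$name == "CA", , drop = FALSE]
  if (!nrow(ca)) stop("chain ", chain, " has no C-alpha atoms")
  ca <- ca[order(ca$resno), , drop = FALSE]
  ca[!duplicated(ca$resno), , drop = FALSE]
}

one_letter <- function(resid) {
  aa <- suppressWarnings(bio3d::aa321(resid))
  aa[is.na(aa) | aa == "X" | !nzchar(aa)] <- "X"
  aa
}

# global alignment of two one-letter sequences; returns matrix of paired
# positions (index into seq1, index into seq2)
align_pairs <- function(s1, s2) {
  mat <- diag(1, 26)
  dimnames(mat) <- list(LETTERS, LETTERS)
  aln <- Biostrings::pairwiseAlignment(paste(s1, collapse = ""),
                                       paste(s2, collapse = ""),
                                       type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  i <- 0L; j <- 0L
  out <- matrix(0L, 0, 2)
  for (k in seq_along(p)) {
    if (p[k] != "-") i <- i + 1L
    if (s[k] != "-") j <- j + 1L
    if (p[k] != "-" && s[k] != "-") out <- rbind(out, c(i, j))
  }
  out
}
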