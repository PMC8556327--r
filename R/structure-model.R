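#' Assembly objects
#'
#' An `assembly` holds the atoms of a (possibly multi-chain) macromolecular
#' model together with an optional grouping of its chains into alpha/beta
#' protomers — the repeating heterodimer unit of a phycobiliprotein ring.
#'
#' The atom table has one row per atom with columns `element`, `name`,
#' `resid` (residue name), `resno` (author residue number), `chain` (author
#' chain id), `x`, `y`, `z` (angstrom), `hetero` (logical), `occ`, `b`.
#'
#' @param atoms data frame of atoms (see Details).
#' @param protomers optional data frame with columns `alpha`, `beta`
#'   (chain ids) and `index` (0-based position around the ring).
#' @return an object of class `assembly`.
#' @export
assembly <- function(atoms, protomers = NULL) {
  req <- c("element", "name", "resid", "resno", "chain", "x", "y", "z", "hetero")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$element))) stop("empty element symbol")
  if (!("occ" %in% names(atoms))) atoms$occ <- 1
  if (!("b" %in% names(atoms))) atoms$b <- 0
  rownames(atoms) <- NULL
  obj <- structure(list(atoms = atoms, protomers = protomers),
                   class = "assembly")
  obj
}

#' @export
print.assembly <- function(x, ...) {
  np <- n_protomers(x)
  cat("<assembly> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain)), " chains",
      if (np > 0) paste0(", ", np, " (alpha-beta) protomers") else
        " (protomers unassigned)",
      "\n", sep = "")
  nh <- sum(x$atoms$hetero)
  if (nh > 0) cat("  hetero atoms: ", nh, " (residues: ",
                  paste(unique(x$atoms$resid[x$atoms$hetero]), collapse = ", "),
                  ")\n", sep = "")
  invisible(x)
}

#' Number of protomers in an assembly
#' @param assembly an [assembly()].
#' @return integer count (0 when protomers are unassigned).
#' @export
n_protomers <- function(assembly) {
  if (is.null(assembly$protomers)) 0L else nrow(assembly$protomers)
}

# coordinate matrix for a subset of atoms
atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])

#' Subset the atoms of an assembly
#'
#' @param assembly an [assembly()].
#' @param chains chain ids to keep (NULL = all).
#' @param protomers protomer indices (0-based) to keep; requires assigned
#'   protomers.
#' @param hetero `NA` to keep all atoms, `TRUE`/`FALSE` to keep only
#'   hetero / only polymer atoms.
#' @param element optionally restrict to these element symbols.
#' @return atom data frame.
#' @export
subset_atoms <- function(assembly, chains = NULL, protomers = NULL,
                         hetero = NA, element = NULL) {
  at <- assembly$atoms
  if (!is.null(protomers)) {
    pt <- assembly$protomers
    if (is.null(pt)) stop("assembly has no protomer assignment")
    keep <- pt$index %in% protomers
    chains <- unique(c(chains, pt$alpha[keep], pt$beta[keep]))
  }
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (!is.na(hetero)) at <- at[at$hetero == hetero, , drop = FALSE]
  if (!is.null(element)) at <- at[toupper(at$element) %in% toupper(element), , drop = FALSE]
  rownames(at) <- NULL
  at
}

# ---------------------------------------------------------------------------
# readers

#' Read a macromolecular structure
#'
#' Reads PDB or PDBx/mmCIF coordinate files into an [assembly()]. All ATOM
#' and HETATM records are kept; hetero residues are flagged; author chain ids
#' and residue numbers are preserved. Alternate locations other than blank or
#' 'A' are dropped. Protomers are left unassigned until [group_protomers()]
#' is called.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return an [assembly()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif", mmcif = "mmcif",
                     stop("cannot infer structure format from extension '.", ext,
                          "'; pass format explicitly"))
  }
  at <- switch(format, pdb = read_pdb_atoms(path), mmcif = read_mmcif_atoms(path))
  if (nrow(at) == 0L) stop("no atoms in ", path)
  at <- at[at$altloc %in% c("", "A"), , drop = FALSE]
  at$altloc <- NULL
  assembly(at)
}

read_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("cannot parse PDB file ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("no atoms in ", path)
  el <- trimws(a$elesy)
  blank <- is.na(el) | !nzchar(el)
  el[blank] <- element_from_name(a$elety[blank])
  data.frame(
    element = toupper(el),
    name = trimws(a$elety),
    resid = trimws(a$resid),
    resno = as.integer(a$resno),
    chain = ifelse(is.na(a$chain), "", a$chain),
    x = a$x, y = a$y, z = a$z,
    hetero = a$type == "HETATM",
    occ = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE
  )
}

# guess the element from a PDB atom name (first alphabetic run, two-letter
# elements only when the name starts in column 13, which bio3d strips; use
# the common-case heuristic: leading digit removed, first letter)
element_from_name <- function(name) {
  nm <- gsub("^[0-9']+", "", trimws(name))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "SE", "NA"), two, one)
}

# minimal PDBx/mmCIF reader: the atom_site loop only
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tagline <- grep("^_atom_site\\.", lines)
  if (!length(tagline)) stop("cannot parse mmCIF file ", path,
                             ": no _atom_site category")
  start <- tagline[1]
  tags <- character(0)
  i <- start
  while (i <= length(lines) && grepl("^_atom_site\\.", lines[i])) {
    tags <- c(tags, sub("^_atom_site\\.(\\S+).*$", "\\1", lines[i]))
    i <- i + 1
  }
  rows <- list()
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*(#|loop_|_\\S|data_)", ln) || !nzchar(trimws(ln))) break
    tok <- cif_tokens(ln)
    if (length(tok) != length(tags))
      stop("cannot parse mmCIF file ", path, ": line ", i,
           " has ", length(tok), " values for ", length(tags), " atom_site fields")
    rows[[length(rows) + 1L]] <- tok
    i <- i + 1
  }
  if (!length(rows)) stop("no atoms in ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  col <- function(primary, fallback = NULL, default = NA_character_) {
    if (primary %in% tags) m[, primary]
    else if (!is.null(fallback) && fallback %in% tags) m[, fallback]
    else rep(default, nrow(m))
  }
  grp <- col("group_PDB", default = "ATOM")
  data.frame(
    element = toupper(col("type_symbol")),
    name = col("label_atom_id", "auth_atom_id"),
    resid = col("auth_comp_id", "label_comp_id"),
    resno = as.integer(col("auth_seq_id", "label_seq_id")),
    chain = col("auth_asym_id", "label_asym_id", default = ""),
    x = as.numeric(col("Cartn_x")),
    y = as.numeric(col("Cartn_y")),
    z = as.numeric(col("Cartn_z")),
    hetero = grp == "HETATM",
    occ = suppressWarnings(as.numeric(col("occupancy", default = "1"))),
    b = suppressWarnings(as.numeric(col("B_iso_or_equiv", default = "0"))),
    altloc = sub("^[.?]$", "", col("label_alt_id", default = "")),
    stringsAsFactors = FALSE
  )
}

# split a CIF data line into tokens, honouring single/double quotes
cif_tokens <- function(line) {
  out <- character(0)
  s <- trimws(line)
  while (nzchar(s)) {
    first <- substr(s, 1, 1)
    if (first %in% c("'", '"')) {
      # quote ends at matching quote followed by whitespace or end of line
      rest <- substr(s, 2, nchar(s))
      pos <- regexpr(paste0(first, "(\\s|$)"), rest)
      if (pos < 0) stop("unterminated quote in CIF line: ", line)
      out <- c(out, substr(rest, 1, pos - 1))
      s <- trimws(substr(rest, pos + 1, nchar(rest)))
    } else {
      pos <- regexpr("\\s", s)
      if (pos < 0) {
        out <- c(out, s)
        s <- ""
      } else {
        out <- c(out, substr(s, 1, pos - 1))
        s <- trimws(substr(s, pos, nchar(s)))
      }
    }
  }
  out
}

# ---------------------------------------------------------------------------
# writers

#' Write a structure to PDB or mmCIF
#'
#' Emits a minimal valid coordinate file. Round-tripping through
#' [read_structure()] preserves atom count, chain ids, residue numbers and
#' coordinates to 1e-3 angstrom (the format's precision).
#'
#' @param assembly an [assembly()].
#' @param path output file path.
#' @param format `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(assembly, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  at <- assembly$atoms
  lines <- if (format == "pdb") {
    rec <- ifelse(at$hetero, "HETATM", "ATOM  ")
    name4 <- ifelse(nchar(at$name) >= 4, substr(at$name, 1, 4),
                    sprintf(" %-3s", at$name))
    c(sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              rec, seq_len(nrow(at)) %% 100000L, name4,
              substr(at$resid, 1, 3), substr(at$chain, 1, 1), at$resno,
              at$x, at$y, at$z, at$occ, at$b, at$element),
      "END")
  } else {
    c("data_oligoring",
      "#", "loop_",
      paste0("_atom_site.", c("group_PDB", "id", "type_symbol", "label_atom_id",
                              "label_alt_id", "auth_comp_id", "auth_asym_id",
                              "auth_seq_id", "Cartn_x", "Cartn_y", "Cartn_z",
                              "occupancy", "B_iso_or_equiv")),
      sprintf("%s %d %s %s . %s %s %d %.3f %.3f %.3f %.2f %.2f",
              ifelse(at$hetero, "HETATM", "ATOM"), seq_len(nrow(at)),
              at$element, cif_quote(at$name), at$resid, at$chain, at$resno,
              at$x, at$y, at$z, at$occ, at$b),
      "#")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

cif_quote <- function(x) ifelse(grepl("['\"\\s]", x), paste0('"', x, '"'), x)
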