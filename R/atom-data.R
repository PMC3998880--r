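# Atom-type classification and per-element radii.
#
# The eight heavy-atom classes follow the Sobolev-style contact scheme:
# hydrophilic (donates and accepts hydrogen bonds), acceptor, donor,
# hydrophobic (aliphatic carbon), aromatic (ring carbon), neutral (carbon or
# sulfur bound to polar atoms), and the two context-dependent ring-nitrogen
# classes neutral_donor / neutral_acceptor.  The per-(residue, atom) table
# below is a reconstruction from the published class definitions: the source
# article cites the classification but does not print the table.

#' Atom-type class labels
#'
#' The eight heavy-atom interaction classes used by the contact model, plus
#' the `"unassigned"` marker for unknown (residue, atom) pairs.  Unassigned
#' atoms are treated as the neutral class when interaction weights are looked
#' up.
#'
#' @return Character vector of the eight class labels (without
#'   `"unassigned"`), in the order used by interaction matrices.
#' @export
atom_type_classes <- function() {
  c("hydrophilic", "acceptor", "donor", "hydrophobic",
    "aromatic", "neutral", "neutral_donor", "neutral_acceptor")
}

# Fixed van der Waals radii (Angstrom) per element, used when deciding and
# apportioning surfaces in contact.
.element_radii <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)
.default_radius <- 1.7

.radius_for_element <- function(element) {
  r <- .element_radii[toupper(element)]
  unname(ifelse(is.na(r), .default_radius, r))
}

# Build the (residue, atom) -> class lookup.  Backbone atoms are shared by
# all residues; side chains are listed explicitly.
.build_type_table <- function() {
  res20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")
  rows <- list()
  add <- function(res, atom, cls) {
    rows[[length(rows) + 1L]] <<- data.frame(resid = res, name = atom,
                                             class = cls)
  }
  for (r in res20) {
    # Proline's backbone nitrogen has no amide hydrogen to donate.
    add(r, "N", if (r == "PRO") "acceptor" else "donor")
    add(r, "CA", "neutral")
    add(r, "C", "neutral")
    add(r, "O", "acceptor")
    add(r, "OXT", "acceptor")
  }
  sc <- list(
    ALA = c(CB = "hydrophobic"),
    ARG = c(CB = "hydrophobic", CG = "hydrophobic", CD = "neutral",
            NE = "donor", CZ = "neutral", NH1 = "donor", NH2 = "donor"),
    ASN = c(CB = "hydrophobic", CG = "neutral", OD1 = "acceptor",
            ND2 = "donor"),
    ASP = c(CB = "hydrophobic", CG = "neutral", OD1 = "acceptor",
            OD2 = "acceptor"),
    CYS = c(CB = "hydrophobic", SG = "neutral"),
    GLN = c(CB = "hydrophobic", CG = "hydrophobic", CD = "neutral",
            OE1 = "acceptor", NE2 = "donor"),
    GLU = c(CB = "hydrophobic", CG = "hydrophobic", CD = "neutral",
            OE1 = "acceptor", OE2 = "acceptor"),
    GLY = character(0),
    HIS = c(CB = "hydrophobic", CG = "aromatic", ND1 = "neutral_donor",
            CD2 = "aromatic", CE1 = "aromatic", NE2 = "neutral_acceptor"),
    ILE = c(CB = "hydrophobic", CG1 = "hydrophobic", CG2 = "hydrophobic",
            CD1 = "hydrophobic"),
    LEU = c(CB = "hydrophobic", CG = "hydrophobic", CD1 = "hydrophobic",
            CD2 = "hydrophobic"),
    LYS = c(CB = "hydrophobic", CG = "hydrophobic", CD = "hydrophobic",
            CE = "neutral", NZ = "donor"),
    MET = c(CB = "hydrophobic", CG = "hydrophobic", SD = "hydrophobic",
            CE = "hydrophobic"),
    PHE = c(CB = "hydrophobic", CG = "aromatic", CD1 = "aromatic",
            CD2 = "aromatic", CE1 = "aromatic", CE2 = "aromatic",
            CZ = "aromatic"),
    PRO = c(CB = "hydrophobic", CG = "hydrophobic", CD = "neutral"),
    SER = c(CB = "neutral", OG = "hydrophilic"),
    THR = c(CB = "neutral", OG1 = "hydrophilic", CG2 = "hydrophobic"),
    TRP = c(CB = "hydrophobic", CG = "aromatic", CD1 = "aromatic",
            CD2 = "aromatic", NE1 = "donor", CE2 = "aromatic",
            CE3 = "aromatic", CZ2 = "aromatic", CZ3 = "aromatic",
            CH2 = "aromatic"),
    TYR = c(CB = "hydrophobic", CG = "aromatic", CD1 = "aromatic",
            CD2 = "aromatic", CE1 = "aromatic", CE2 = "aromatic",
            CZ = "aromatic", OH = "hydrophilic"),
    VAL = c(CB = "hydrophobic", CG1 = "hydrophobic", CG2 = "hydrophobic")
  )
  for (r in names(sc)) {
    v <- sc[[r]]
    for (a in names(v)) add(r, a, v[[a]])
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

.type_table_env <- new.env(parent = emptyenv())

.type_table <- function() {
  if (is.null(.type_table_env$tab)) {
    tab <- .build_type_table()
    key <- paste(tab$resid, tab$name, sep = "|")
    .type_table_env$tab <- tab
    .type_table_env$map <- stats::setNames(tab$class, key)
  }
  .type_table_env
}

#' Look up the atom-type class of a single atom
#'
#' @param resid Three-letter residue name (e.g. `"LYS"`).
#' @param name PDB atom name (e.g. `"NZ"`).
#' @return One of the eight class labels, or `"unassigned"` when the
#'   (residue, atom) pair is not in the lookup table.
#' @examples
#' atom_type("LYS", "NZ")   # "donor"
#' atom_type("ALA", "CB")   # "hydrophobic"
#' @export
atom_type <- function(resid, name) {
  env <- .type_table()
  cls <- unname(env$map[paste(toupper(resid), toupper(name), sep = "|")])
  ifelse(is.na(cls), "unassigned", cls)
}

#' Interaction matrices between atom-type classes
#'
#' `eps_matrix_ones()` returns the non-specific matrix (every entry exactly 1)
#' that defines the ENCoM_ns variant.  `eps_matrix_default()` returns the
#' bundled default matrix.  The default is a chemistry-motivated
#' *reconstruction* (complementary pairs such as donor/acceptor or
#' hydrophobic/hydrophobic weighted up, clashing pairs weighted down): the
#' source method never published its numeric matrix, so the default must not
#' be read as ground truth and can be overridden with [read_eps_matrix()].
#'
#' @return Symmetric 8 x 8 numeric matrix with dimnames
#'   [atom_type_classes()].
#' @export
eps_matrix_ones <- function() {
  cls <- atom_type_classes()
  matrix(1, 8, 8, dimnames = list(cls, cls))
}

#' @rdname eps_matrix_ones
#' @export
eps_matrix_default <- function() {
  cls <- atom_type_classes()
  m <- matrix(1, 8, 8, dimnames = list(cls, cls))
  set <- function(a, b, v) {
    m[a, b] <<- v
    m[b, a] <<- v
  }
  fav <- 2
  unf <- 0.5
  set("hydrophilic", "hydrophilic", fav)
  set("hydrophilic", "acceptor", fav)
  set("hydrophilic", "donor", fav)
  set("hydrophilic", "neutral_donor", fav)
  set("hydrophilic", "neutral_acceptor", fav)
  set("hydrophilic", "hydrophobic", unf)
  set("acceptor", "donor", fav)
  set("acceptor", "acceptor", unf)
  set("acceptor", "neutral_donor", fav)
  set("acceptor", "neutral_acceptor", unf)
  set("acceptor", "hydrophobic", unf)
  set("donor", "donor", unf)
  set("donor", "neutral_acceptor", fav)
  set("donor", "neutral_donor", unf)
  set("donor", "hydrophobic", unf)
  set("hydrophobic", "hydrophobic", fav)
  set("hydrophobic", "aromatic", fav)
  set("hydrophobic", "neutral_donor", unf)
  set("hydrophobic", "neutral_acceptor", unf)
  set("aromatic", "aromatic", fav)
  set("neutral_donor", "neutral_donor", unf)
  set("neutral_acceptor", "neutral_acceptor", unf)
  set("neutral_donor", "neutral_acceptor", fav)
  m
}

#' Read an atom-type interaction matrix from a TSV file
#'
#' The file must be tab-separated with a header row and first column holding
#' the eight class labels of [atom_type_classes()] (any order); the body is
#' the symmetric matrix of positive interaction weights.
#'
#' @param path Path to the TSV file.
#' @return Symmetric 8 x 8 numeric matrix ordered as [atom_type_classes()].
#' @export
read_eps_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  validate_eps_matrix(m)
}

#' Write an interaction matrix to TSV
#'
#' @param eps Matrix as returned by [eps_matrix_default()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eps_matrix <- function(eps, path) {
  eps <- validate_eps_matrix(eps)
  df <- data.frame(class = rownames(eps), eps, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an interaction matrix
#'
#' Checks that `eps` is a symmetric 8 x 8 matrix over the class labels with
#' finite, strictly positive entries, and reorders it to the canonical class
#' order.
#'
#' @param eps Candidate matrix.
#' @return The validated, canonically ordered matrix.
#' @export
validate_eps_matrix <- function(eps) {
  cls <- atom_type_classes()
  if (!is.matrix(eps) || !all(dim(eps) == c(8L, 8L)))
    stop("interaction matrix must be 8 x 8")
  if (is.null(rownames(eps)) || is.null(colnames(eps)) ||
      !setequal(rownames(eps), cls) || !setequal(colnames(eps), cls))
    stop("interaction matrix must be labelled with the eight atom-type classes")
  eps <- eps[cls, cls]
  if (!all(is.finite(eps)) || any(eps <= 0))
    stop("interaction matrix entries must be finite and > 0")
  if (max(abs(eps - t(eps))) > 1e-12 * max(abs(eps)))
    stop("interaction matrix must be symmetric")
  eps
}
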