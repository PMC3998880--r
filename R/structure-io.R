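# Structure input/output.  PDB record parsing and writing are delegated to
# bio3d; the filtering policy (single model, highest-occupancy alternate
# location, heavy atoms of standard residues only, MSE treated as MET, one
# CA required per residue) is applied here.

.standard_residues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                        "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                        "PRO", "SER", "THR", "TRP", "TYR", "VAL")

# Internal constructor.  `atoms` must carry serial, name, element, chain,
# resid, resno, insert, x, y, z, b in file order; residues are partitioned by
# (chain, resno, insert) runs and indexed contiguously from 1.
.new_structure <- function(atoms, source_id = "unknown", model = 1L) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  res_index <- cumsum(!duplicated(key) & !c(FALSE, key[-1L] == key[-length(key)]))
  # simpler and order-safe: index by first appearance of each key
  res_index <- match(key, unique(key))
  atoms$res_index <- res_index
  if (is.null(atoms$atom_type)) atoms$atom_type <- NA_character_
  if (is.null(atoms$radius)) atoms$radius <- .radius_for_element(atoms$element)
  if (is.null(atoms$b)) atoms$b <- 0
  n_res <- max(res_index)
  ca_idx <- integer(n_res)
  for (i in seq_len(n_res)) {
    w <- which(res_index == i & atoms$name == "CA")
    if (length(w) != 1L)
      stop("residue ", i, " must have exactly one CA atom (found ",
           length(w), ")")
    ca_idx[i] <- w
  }
  first <- match(seq_len(n_res), res_index)
  res_info <- data.frame(res_index = seq_len(n_res),
                         chain = atoms$chain[first],
                         resno = atoms$resno[first],
                         insert = atoms$insert[first],
                         resid = atoms$resid[first],
                         stringsAsFactors = FALSE)
  structure(list(atoms = atoms, n_res = n_res, ca_idx = ca_idx,
                 res_info = res_info, source_id = source_id,
                 model = as.integer(model)),
            class = "enc_structure")
}

#' Read a PDB file into a coarse-grained-ready structure
#'
#' Parses ATOM records (plus selenomethionine HETATM records, remapped to
#' MET), keeps heavy atoms of the twenty standard residues, resolves
#' alternate locations by highest occupancy, and drops waters, other
#' heteroatoms, hydrogens, non-standard residues and any residue lacking a
#' CA atom (with a warning).  Multi-model (NMR-style) files use model 1 by
#' default.
#'
#' @param path Path to a PDB file.
#' @param model Model number to use for multi-model files (default 1).
#' @param chains Optional character vector of chain identifiers to keep.
#' @return An object of class `enc_structure`: a residue-partitioned heavy
#'   atom table with per-atom coordinates (Angstrom), experimental B column,
#'   contact radii and (after [assign_atom_types()]) atom-type classes.
#' @examples
#' pdb <- write_structure_pdb(make_structure("ideal_helix", 8), tempfile(fileext = ".pdb"))
#' s <- read_pdb(pdb)
#' s$n_res
#' @export
read_pdb <- function(path, model = 1L, chains = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model < 1L || model > n_models)
    stop("requested model ", model, " but file has ", n_models, " model(s)")
  if (model > 1L) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    at$x <- xyz[, 1L]
    at$y <- xyz[, 2L]
    at$z <- xyz[, 3L]
  }
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0

  # Selenomethionine is a routine crystallographic substitution: map to MET.
  mse <- at$resid == "MSE"
  if (any(mse)) {
    at$resid[mse] <- "MET"
    at$elety[mse & at$elety == "SE"] <- "SD"
    at$elesy[mse & at$elesy == "SE"] <- "S"
    at$type[mse] <- "ATOM"
  }
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]

  nonstd <- !(at$resid %in% .standard_residues)
  if (any(nonstd)) {
    warning("dropping ", sum(nonstd), " atom(s) in non-standard residue(s): ",
            paste(unique(at$resid[nonstd]), collapse = ", "))
    at <- at[!nonstd, , drop = FALSE]
  }

  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- substr(gsub("[0-9]", "", at$elety[bad]), 1L, 1L)
  hyd <- toupper(elem) %in% c("H", "D")
  at <- at[!hyd, , drop = FALSE]
  elem <- elem[!hyd]
  if (nrow(at) == 0L) stop("no atoms left after filtering: ", path)
  at$element <- toupper(elem)

  # Alternate locations: per (chain, residue, atom name) keep the
  # highest-occupancy record, ties resolving to the first altloc label,
  # then restore file order.
  at$.row <- seq_len(nrow(at))
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(akey, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(akey[ord]), , drop = FALSE]
  at <- at[order(at$.row), , drop = FALSE]

  # Residues without a CA cannot host a network node.
  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  has_ca <- rkey %in% rkey[at$elety == "CA"]
  if (any(!has_ca)) {
    warning("dropping ", length(unique(rkey[!has_ca])),
            " residue(s) lacking a CA atom")
    at <- at[has_ca, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("empty structure after filtering: ", path)

  atoms <- data.frame(serial = at$eleno, name = at$elety,
                      element = at$element, chain = at$chain,
                      resid = at$resid, resno = at$resno, insert = at$insert,
                      x = at$x, y = at$y, z = at$z, b = at$b,
                      stringsAsFactors = FALSE)
  .new_structure(atoms,
                 source_id = sub("\\.(pdb|ent)$", "", basename(path)),
                 model = model)
}

#' Assign atom-type classes to every heavy atom
#'
#' Looks up each (residue name, atom name) pair in the bundled eight-class
#' table.  Unknown pairs are labelled `"unassigned"` with a warning and are
#' treated as the neutral class when interaction weights are applied.
#'
#' @param struct An `enc_structure`.
#' @return The structure with the `atom_type` column filled in.
#' @export
assign_atom_types <- function(struct) {
  stopifnot(inherits(struct, "enc_structure"))
  cls <- atom_type(struct$atoms$resid, struct$atoms$name)
  n_un <- sum(cls == "unassigned")
  if (n_un > 0L)
    warning(n_un, " atom(s) with no atom-type entry left unassigned ",
            "(treated as neutral in contact weights)")
  struct$atoms$atom_type <- cls
  struct
}

#' CA coordinates of a structure
#'
#' @param struct An `enc_structure`.
#' @return Numeric N x 3 matrix of alpha-carbon coordinates (Angstrom).
#' @export
ca_xyz <- function(struct) {
  stopifnot(inherits(struct, "enc_structure"))
  as.matrix(struct$atoms[struct$ca_idx, c("x", "y", "z")])
}

#' @export
print.enc_structure <- function(x, ...) {
  cat("enc_structure '", x$source_id, "': ", x$n_res, " residues, ",
      nrow(x$atoms), " heavy atoms", sep = "")
  if (all(is.na(x$atoms$atom_type))) cat(" (atom types unassigned)")
  cat("\n")
  invisible(x)
}

#' Write a structure back to PDB format
#'
#' @param struct An `enc_structure`.
#' @param path Output path.
#' @return `path`, invisibly (so the call nests inside [read_pdb()]).
#' @export
write_structure_pdb <- function(struct, path) {
  stopifnot(inherits(struct, "enc_structure"))
  a <- struct$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, eleno = a$serial,
                   elety = a$name, chain = a$chain, insert = a$insert,
                   o = rep(1, nrow(a)), b = a$b, elesy = a$element)
  invisible(path)
}

#' Write and read normal modes in a plain-text NMD-style format
#'
#' `write_modes()` stores a spectral decomposition as a documented text
#' format: a header with the model kind and system size, one `eigenvalue`
#' line and one `mode` line (3N components, or N for the Gaussian network
#' model) per mode, at 12 significant digits.  `read_modes()` restores the
#' decomposition losslessly to that precision.
#'
#' @param decomp An `enc_modes` spectral decomposition (see [diagonalize()]).
#' @param struct The `enc_structure` the decomposition was computed from;
#'   residue counts must match.
#' @param path Output (input) path.
#' @return `write_modes()` returns `path` invisibly; `read_modes()` returns
#'   an `enc_modes` object.
#' @export
write_modes <- function(decomp, struct, path) {
  stopifnot(inherits(decomp, "enc_modes"), inherits(struct, "enc_structure"))
  if (decomp$n_res != struct$n_res)
    stop("dimension mismatch: decomposition has ", decomp$n_res,
         " residues, structure has ", struct$n_res)
  if (length(decomp$values) == 0L) stop("empty mode set")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("encomr_modes 1",
               paste("model", decomp$model),
               paste("n_residues", decomp$n_res),
               paste("n_rigid", decomp$n_rigid),
               paste("source", struct$source_id)), con)
  for (k in seq_along(decomp$values)) {
    writeLines(sprintf("eigenvalue %d %.12e", k, decomp$values[k]), con)
    writeLines(paste("mode", k,
                     paste(sprintf("%.12e", decomp$vectors[, k]),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_modes
#' @export
read_modes <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6L || !startsWith(lines[1L], "encomr_modes"))
    stop("not an encomr mode file: ", path)
  field <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))][1L]
    sub(paste0("^", key, " "), "", ln)
  }
  model <- field("model")
  n_res <- as.integer(field("n_residues"))
  n_rigid <- as.integer(field("n_rigid"))
  ev_lines <- lines[startsWith(lines, "eigenvalue ")]
  md_lines <- lines[startsWith(lines, "mode ")]
  values <- vapply(strsplit(ev_lines, " "), function(p) as.numeric(p[3L]), 0)
  vectors <- vapply(strsplit(md_lines, " "),
                    function(p) as.numeric(p[-(1:2)]),
                    numeric(length(strsplit(md_lines[1L], " ")[[1L]]) - 2L))
  structure(list(values = values, vectors = vectors, n_rigid = n_rigid,
                 model = model, n_res = n_res),
            class = "enc_modes")
}
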