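# Shared fixtures: hand-written PDB text and small cached structures.

# One fixed-width ATOM record (PDB columns).
pdb_atom_line <- function(serial, name, alt, resn, chain, resno, x, y, z,
                          occ = 1, b = 0, elem = substr(name, 1L, 1L),
                          record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), alt, resn, chain, resno, "",
          x, y, z, occ, b, elem)
}

# Minimal hand-written tripeptide ALA-GLY-ALA, optionally with an altloc
# pair on the first CB and a hydrogen.
write_tripeptide_pdb <- function(path, altloc_cb = FALSE, drop_ca2 = FALSE,
                                 with_h = FALSE, with_water = FALSE) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, pdb_atom_line(...))
  s <- 0L
  nxt <- function() {
    s <<- s + 1L
    s
  }
  add(nxt(), "N", "", "ALA", "A", 1, 0.0, 0.0, 0.0, elem = "N")
  add(nxt(), "CA", "", "ALA", "A", 1, 1.46, 0.0, 0.0)
  add(nxt(), "C", "", "ALA", "A", 1, 2.0, 1.4, 0.0)
  add(nxt(), "O", "", "ALA", "A", 1, 1.3, 2.4, 0.0, elem = "O")
  if (altloc_cb) {
    add(nxt(), "CB", "A", "ALA", "A", 1, 1.9, -0.8, 1.2, occ = 0.6)
    add(nxt(), "CB", "B", "ALA", "A", 1, 2.1, -0.9, 1.3, occ = 0.4)
  } else {
    add(nxt(), "CB", "", "ALA", "A", 1, 1.9, -0.8, 1.2)
  }
  if (with_h) add(nxt(), "HA", "", "ALA", "A", 1, 1.6, 0.5, 0.9, elem = "H")
  add(nxt(), "N", "", "GLY", "A", 2, 3.3, 1.5, 0.0, elem = "N")
  if (!drop_ca2) add(nxt(), "CA", "", "GLY", "A", 2, 4.0, 2.8, 0.0)
  add(nxt(), "C", "", "GLY", "A", 2, 5.5, 2.6, 0.1)
  add(nxt(), "O", "", "GLY", "A", 2, 6.1, 1.55, 0.2, elem = "O")
  add(nxt(), "N", "", "ALA", "A", 3, 6.1, 3.8, 0.0, elem = "N")
  add(nxt(), "CA", "", "ALA", "A", 3, 7.55, 3.85, 0.1)
  add(nxt(), "C", "", "ALA", "A", 3, 8.1, 5.25, 0.0)
  add(nxt(), "O", "", "ALA", "A", 3, 7.4, 6.26, 0.1, elem = "O")
  add(nxt(), "CB", "", "ALA", "A", 3, 8.2, 3.0, -1.0)
  if (with_water)
    add(nxt(), "O", "", "HOH", "A", 90, 12.0, 12.0, 12.0, elem = "O",
        record = "HETATM")
  writeLines(c(ln, "END"), path)
  path
}

# Cached small structures used across files.
fx_helix5 <- make_structure("ideal_helix", 5, side_chain = "single_sphere")
fx_helix8 <- make_structure("ideal_helix", 8, side_chain = "single_sphere")
fx_helix10 <- make_structure("ideal_helix", 10, side_chain = "single_sphere",
                             sc_type = rep(c("hydrophobic", "donor"),
                                           length.out = 10))
fx_contacts5 <- build_contacts(fx_helix5)
fx_contacts8 <- build_contacts(fx_helix8)

# Central finite-difference Hessian of the potential (independent oracle).
fd_hessian <- function(struct, params, contacts, dd = 1e-4) {
  x0 <- as.vector(t(ca_xyz(struct)))
  n <- length(x0)
  V <- function(x) potential_energy(struct, x, params, contacts)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    ei <- ej <- rep(0, n)
    ei[i] <- dd
    ej[j] <- dd
    v <- (V(x0 + ei + ej) - V(x0 + ei - ej) - V(x0 - ei + ej) +
            V(x0 - ei - ej)) / (4 * dd^2)
    H[i, j] <- H[j, i] <- v
  }
  H
}

# Rigidly rotate + translate every atom of a structure.
rotate_structure <- function(struct, seed = 42, shift = c(5, -3, 2)) {
  R <- encomr:::.random_rotation(seed)
  a <- struct$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2L, shift, FUN = "+")
  a$x <- xyz[, 1L]
  a$y <- xyz[, 2L]
  a$z <- xyz[, 3L]
  out <- struct
  out$atoms <- a
  out
}
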