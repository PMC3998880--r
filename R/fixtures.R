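# Deterministic synthetic structures and task bundles.  Toy geometries
# (bead chains, ideal helices, hinged two-domain shapes) with optional
# single-sphere pseudo side chains keep contact areas near closed form and
# make every downstream module testable without structure downloads.

#' Generate a synthetic structure
#'
#' Builds a deterministic toy protein: a straight bead chain (3.8 Angstrom
#' CA spacing), an ideal alpha-helix (rise 1.5 Angstrom, 100 degree twist,
#' 2.3 Angstrom radius; consecutive CA distance ~3.8 Angstrom), or a hinged
#' two-domain helix (second half rotated about the hinge residue).  With
#' `side_chain = "single_sphere"` each residue gets one pseudo side-chain
#' sphere ("CB") at a fixed offset, with an assignable atom-type class and
#' radius.
#'
#' @param kind `"linear_chain"`, `"ideal_helix"` or `"two_domain_hinge"`.
#' @param n_residues Number of residues (>= 3).
#' @param side_chain `"none"` or `"single_sphere"`.
#' @param seed Integer seed (coordinates are deterministic; the seed is
#'   recorded for provenance and used by stochastic downstream helpers).
#' @param sc_type Atom-type class(es) of the side-chain spheres, recycled
#'   over residues (default `"hydrophobic"`).
#' @param sc_radius Side-chain sphere radius (Angstrom, default 1.7).
#' @param spacing CA spacing of the linear chain (Angstrom).
#' @param hinge_angle Bend angle (degrees) of the two-domain hinge.
#' @return An `enc_structure` with atom types already assigned.
#' @examples
#' make_structure("ideal_helix", 10, side_chain = "single_sphere")
#' @export
make_structure <- function(kind = c("linear_chain", "ideal_helix",
                                    "two_domain_hinge"),
                           n_residues, side_chain = c("none",
                                                      "single_sphere"),
                           seed = 1L, sc_type = "hydrophobic",
                           sc_radius = 1.7, spacing = 3.8,
                           hinge_angle = 60) {
  kind <- match.arg(kind)
  side_chain <- match.arg(side_chain)
  n <- as.integer(n_residues)
  if (n < 3L) stop("n_residues must be >= 3")
  bad <- setdiff(sc_type, atom_type_classes())
  if (length(bad) > 0L)
    stop("unknown side-chain atom type(s): ", paste(bad, collapse = ", "))
  sc_type <- rep_len(sc_type, n)

  helix_coords <- function(idx) {
    om <- 100 * pi / 180
    cbind(2.3 * cos(idx * om), 2.3 * sin(idx * om), 1.5 * idx)
  }
  golden <- pi * (3 - sqrt(5))
  if (kind == "linear_chain") {
    ca <- cbind(0, 0, spacing * seq_len(n))
    out_dir <- cbind(cos(golden * seq_len(n)), sin(golden * seq_len(n)), 0)
  } else {
    ca <- helix_coords(seq_len(n))
    out_dir <- cbind(cos(seq_len(n) * 100 * pi / 180),
                     sin(seq_len(n) * 100 * pi / 180), 0)
    if (kind == "two_domain_hinge") {
      pivot <- n %/% 2L
      th <- hinge_angle * pi / 180
      Rx <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
      sel <- (pivot + 1L):n
      ca[sel, ] <- sweep(sweep(ca[sel, , drop = FALSE], 2L, ca[pivot, ]) %*%
                           t(Rx), 2L, ca[pivot, ], FUN = "+")
      out_dir[sel, ] <- out_dir[sel, , drop = FALSE] %*% t(Rx)
    }
  }

  rows <- list()
  serial <- 0L
  for (i in seq_len(n)) {
    serial <- serial + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      serial = serial, name = "CA", element = "C", chain = "A",
      resid = "ALA", resno = i, insert = "", x = ca[i, 1L], y = ca[i, 2L],
      z = ca[i, 3L], b = 0, atom_type = "neutral", radius = 1.7,
      stringsAsFactors = FALSE)
    if (side_chain == "single_sphere") {
      serial <- serial + 1L
      cb <- ca[i, ] + 1.53 * out_dir[i, ]
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = "CB", element = "C", chain = "A",
        resid = "ALA", resno = i, insert = "", x = cb[1L], y = cb[2L],
        z = cb[3L], b = 0, atom_type = sc_type[i], radius = sc_radius,
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  s <- .new_structure(atoms, source_id = paste0("toy_", kind, "_n", n),
                      model = 1L)
  attr(s, "seed") <- as.integer(seed)
  s
}

# Apply a per-residue CA displacement (N x 3) to all atoms of a structure
# (side-chain atoms follow their residue rigidly by translation).
.displace_structure <- function(struct, disp) {
  a <- struct$atoms
  a$x <- a$x + disp[a$res_index, 1L]
  a$y <- a$y + disp[a$res_index, 2L]
  a$z <- a$z + disp[a$res_index, 3L]
  out <- struct
  out$atoms <- a
  out$source_id <- paste0(struct$source_id, "_displaced")
  out
}

#' Generate a start/target conformer pair
#'
#' Displaces a synthetic structure to produce a target conformation with a
#' known relationship to the start: along the 7th (slowest internal) mode
#' of the chosen model (so the best overlap is 1 by construction), by a
#' rigid hinge bend of the second half, or by a seeded random displacement.
#'
#' @param struct An `enc_structure` (see [make_structure()]).
#' @param displacement `"along_mode_7"`, `"hinge_bend"` or `"random"`.
#' @param magnitude Displacement size: total CA displacement norm in
#'   Angstrom (`along_mode_7`, `random`) or bend angle in degrees
#'   (`hinge_bend`).  Must be nonzero.
#' @param seed Seed for the random displacement.
#' @param params Model used to compute mode 7 for `"along_mode_7"`.
#' @return A list with `start` and `target` structures.
#' @export
make_conformer_pair <- function(struct,
                                displacement = c("along_mode_7",
                                                 "hinge_bend", "random"),
                                magnitude = 0.1, seed = 1L,
                                params = enc_params()) {
  stopifnot(inherits(struct, "enc_structure"))
  displacement <- match.arg(displacement)
  if (magnitude == 0) stop("magnitude must be nonzero (degenerate overlap)")
  n <- struct$n_res
  if (displacement == "along_mode_7") {
    decomp <- build_modes(struct, params)
    v <- decomp$vectors[, decomp$n_rigid + 1L]
    disp <- matrix(v, ncol = 3L, byrow = TRUE) * (magnitude / .vnorm(v))
  } else if (displacement == "hinge_bend") {
    xyz <- ca_xyz(struct)
    pivot <- n %/% 2L
    th <- magnitude * pi / 180
    Rx <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
    new_xyz <- xyz
    sel <- (pivot + 1L):n
    new_xyz[sel, ] <- sweep(sweep(xyz[sel, , drop = FALSE], 2L,
                                  xyz[pivot, ]) %*% t(Rx), 2L,
                            xyz[pivot, ], FUN = "+")
    disp <- new_xyz - xyz
  } else {
    disp <- .with_seed(seed, matrix(stats::rnorm(3L * n), ncol = 3L))
    disp <- disp * (magnitude / sqrt(sum(disp^2)))
  }
  list(start = struct, target = .displace_structure(struct, disp))
}

#' Generate a wild-type/mutant pair with an injected experimental ddG
#'
#' The mutant differs from the wild type only in one residue's side-chain
#' sphere: its atom-type class and/or its radius.  An "experimental" ddG is
#' injected by the stated generative rule `ddg_exp = c_true * score +
#' N(0, noise_sd)`, where `score` is the entropic prediction under `params`
#' for the pair, so that regression slope and RMSE recovery are checkable
#' by construction.
#'
#' @param struct Wild-type `enc_structure` with single-sphere side chains.
#' @param position Residue index to mutate (1..N).
#' @param new_type New atom-type class of the side-chain sphere (`NULL` to
#'   keep).
#' @param radius_scale Multiplier on the side-chain sphere radius.
#' @param params,eps Model and interaction matrix used for the generative
#'   score.
#' @param c_true Generative slope linking the entropic score to the
#'   injected ddG.
#' @param noise_sd Gaussian noise standard deviation (kcal/mol-like units).
#' @param seed Seed for the noise.
#' @return A list: `wt`, `mut`, `position`, `score_true` (entropic score
#'   under `params`), `ddg_exp`, `c_true`, `noise_sd`.
#' @export
make_mutation_pair <- function(struct, position, new_type = NULL,
                               radius_scale = 1, params = enc_params(),
                               eps = eps_matrix_default(), c_true = 1,
                               noise_sd = 0, seed = 1L) {
  stopifnot(inherits(struct, "enc_structure"))
  if (position < 1L || position > struct$n_res)
    stop("invalid position: ", position)
  sel <- struct$atoms$res_index == position & struct$atoms$name == "CB"
  if (!any(sel))
    stop("residue ", position, " has no side-chain sphere to mutate")
  mut <- struct
  if (!is.null(new_type)) {
    if (!new_type %in% atom_type_classes())
      stop("unknown atom type: ", new_type)
    mut$atoms$atom_type[sel] <- new_type
  }
  mut$atoms$radius[sel] <- mut$atoms$radius[sel] * radius_scale
  mut$source_id <- paste0(struct$source_id, "_mut", position)
  score <- predict_ddg(struct, mut, params, eps = eps)$score
  ddg <- c_true * score +
    if (noise_sd > 0) .with_seed(seed, stats::rnorm(1L, 0, noise_sd)) else 0
  list(wt = struct, mut = mut, position = as.integer(position),
       score_true = score, ddg_exp = ddg, c_true = c_true,
       noise_sd = noise_sd)
}

#' Benchmark bundle of synthetic mutation and overlap tasks
#'
#' Assembles the inputs of [parameter_search()]: a set of single-sphere
#' mutation tasks with injected experimental ddG values spanning the
#' stabilizing/neutral/destabilizing classes, and a set of conformational
#' change tasks of `"domain"` (hinge bend of a two-domain toy) and
#' `"loop"` (localized random displacement of a helix) kinds.  Contact
#' models are precomputed per structure since they do not depend on the
#' alpha weights being searched.
#'
#' @param seed Master seed.
#' @param model Contact model kind (`"encom"` or `"encom_ns"`).
#' @param n_mut Number of mutation tasks.
#' @param n_overlap Number of overlap tasks per kind.
#' @param n_res Residues per toy structure.
#' @param noise_sd Noise on the injected ddG values.
#' @param eps Interaction matrix.
#' @return A list of class `enc_bundle` with `mutation_tasks`,
#'   `overlap_tasks`, `model`, and the generative constant
#'   `c_true` used for the injected ddG values.
#' @export
make_benchmark_bundle <- function(seed = 1L, model = "encom", n_mut = 10L,
                                  n_overlap = 3L, n_res = 10L,
                                  noise_sd = 0.25,
                                  eps = eps_matrix_default()) {
  wt <- make_structure("ideal_helix", n_res, side_chain = "single_sphere",
                       sc_type = rep(c("hydrophobic", "donor"),
                                     length.out = n_res))
  params0 <- enc_params(model)
  wt_contacts <- build_contacts(wt, eps = eps)

  scales <- rep_len(c(1.6, 0.55, 1.25, 0.75, 1.05), n_mut)
  types <- rep_len(list(NULL, "acceptor", NULL, "aromatic", NULL), n_mut)
  positions <- rep_len(seq(2L, n_res - 1L), n_mut)
  raw <- lapply(seq_len(n_mut), function(k) {
    mp <- make_mutation_pair(wt, positions[k], new_type = types[[k]],
                             radius_scale = scales[k], params = params0,
                             eps = eps, c_true = 1, noise_sd = 0)
    mp$mut_contacts <- build_contacts(mp$mut, eps = eps)
    mp
  })
  # Scale the generative slope so injected ddG values span the +-0.5
  # class thresholds, then add seeded noise.
  med <- stats::median(abs(vapply(raw, function(t) t$score_true, 0)))
  c_true <- if (med > 0) 1.5 / med else 1
  noise <- .with_seed(seed, stats::rnorm(n_mut, 0, noise_sd))
  mutation_tasks <- lapply(seq_len(n_mut), function(k) {
    t <- raw[[k]]
    list(wt = t$wt, mut = t$mut, wt_contacts = wt_contacts,
         mut_contacts = t$mut_contacts, position = t$position,
         score_true = t$score_true,
         ddg_exp = c_true * t$score_true + noise[k])
  })

  hinge <- make_structure("two_domain_hinge", n_res,
                          side_chain = "single_sphere")
  hinge_contacts <- build_contacts(hinge, eps = eps)
  helix_contacts <- wt_contacts
  overlap_tasks <- list()
  for (k in seq_len(n_overlap)) {
    cp <- make_conformer_pair(hinge, "hinge_bend", magnitude = 4 + 2 * k)
    overlap_tasks[[length(overlap_tasks) + 1L]] <-
      list(start = cp$start, target = cp$target,
           start_contacts = hinge_contacts, kind = "domain")
    cp <- make_conformer_pair(wt, "random", magnitude = 0.6,
                              seed = seed + 100L + k)
    overlap_tasks[[length(overlap_tasks) + 1L]] <-
      list(start = cp$start, target = cp$target,
           start_contacts = helix_contacts, kind = "loop")
  }
  structure(list(mutation_tasks = mutation_tasks,
                 overlap_tasks = overlap_tasks, model = model,
                 c_true = c_true, seed = as.integer(seed)),
            class = "enc_bundle")
}

#' @export
print.enc_bundle <- function(x, ...) {
  cat("enc_bundle: ", length(x$mutation_tasks), " mutation tasks, ",
      length(x$overlap_tasks), " overlap tasks (model ", x$model, ")\n",
      sep = "")
  invisible(x)
}
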