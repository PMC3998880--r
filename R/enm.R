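# Stiffness matrices and spectral decomposition for the five network models.
#
# The ENCoM / STeM potential is the four-term Go-like form (energies in
# model units, reference geometry at the minimum):
#
#   V = a1 * sum_bonds     (r - r0)^2
#     + a2 * sum_angles    (th - th0)^2
#     + a3 * sum_dihedrals [ (1 - cos(phi - phi0)) + 1/2 (1 - cos 3(phi - phi0)) ]
#     + a4 * sum_{|i-j|>=2} w_ij [ 5 (r0/r)^12 - 6 (r0/r)^10 + 1 ]
#
# with w_ij = beta_ij (surfaces in contact weighted by atom-type
# interactions) for ENCoM/ENCoM_ns and w_ij = 1 for STeM.  The +1 shift
# makes V(reference) = 0 without touching any derivative.  Every term is a
# function f(c(x)) of one internal coordinate with f'(c0) = 0 at the
# reference, so the exact Hessian at the reference is
# sum_terms f''(c0) grad(c) grad(c)^T -- positive semidefinite by
# construction.  Second derivatives at the reference: bonds 2*a1, angles
# 2*a2, dihedrals (1 + 9/2)*a3, long-range 120*a4*w_ij/r0^2.

#' Model parameter set
#'
#' Bundles the four force-constant weights of the Go-like potential with the
#' model kind and the network cutoffs.  The shipped ENCoM default
#' `(1e3, 1e4, 1e4, 1e-2)` is a documented *reconstruction*: the source
#' method reports its optimum only graphically, stating that high
#' bond/angle weights and a long-range weight below 1 favour conformational
#' overlap and mutation prediction.  The `"bfactor"` profile `(1e2, 1e3,
#' 1e3, 1e1)` (long-range weight above 1) follows the reported opposite
#' trend for b-factor accuracy, and the STeM alphas `(100, 20, 1, 1)` are
#' the classical Go-potential constants the model inherits.
#'
#' @param model One of `"encom"`, `"encom_ns"`, `"stem"`, `"anm"`, `"gnm"`.
#' @param alpha Numeric 4-vector of positive weights (bond stretch, angle
#'   bend, dihedral torsion, long-range); ignored by ANM/GNM.  `NULL` picks
#'   the profile default.
#' @param anm_cutoff ANM interaction cutoff in Angstrom (default 18).
#' @param gnm_cutoff GNM (Kirchhoff) cutoff in Angstrom (default 10).
#' @param profile Which default alpha set to use when `alpha` is `NULL`:
#'   `"overlap"` (the main reconstruction) or `"bfactor"`.
#' @return An object of class `enc_params`.
#' @export
enc_params <- function(model = "encom", alpha = NULL, anm_cutoff = 18,
                       gnm_cutoff = 10, profile = c("overlap", "bfactor")) {
  model <- match.arg(tolower(model), .model_kinds)
  profile <- match.arg(profile)
  if (is.null(alpha)) {
    alpha <- if (model == "stem") {
      c(100, 20, 1, 1)
    } else if (profile == "bfactor") {
      c(1e2, 1e3, 1e3, 1e1)
    } else {
      c(1e3, 1e4, 1e4, 1e-2)
    }
  }
  alpha <- as.numeric(alpha)
  if (length(alpha) != 4L || any(!is.finite(alpha)) || any(alpha <= 0))
    stop("alpha must be 4 positive finite weights")
  if (anm_cutoff <= 0 || gnm_cutoff <= 0) stop("cutoffs must be > 0")
  structure(list(model = model, alpha = alpha, anm_cutoff = anm_cutoff,
                 gnm_cutoff = gnm_cutoff, profile = profile),
            class = "enc_params")
}

#' @export
print.enc_params <- function(x, ...) {
  cat("enc_params: model=", x$model, " alpha=(",
      paste(format(x$alpha), collapse = ", "), ")", sep = "")
  if (x$model == "anm") cat(" cutoff=", x$anm_cutoff, " A", sep = "")
  if (x$model == "gnm") cat(" cutoff=", x$gnm_cutoff, " A", sep = "")
  cat("\n")
  invisible(x)
}

# Long-range pair weights for the fourth term: beta_ij for the contact
# models (pairs with positive beta only), 1 for every |i-j| >= 2 pair for
# STeM.  Bonded neighbours |i-j| <= 1 are always excluded.
.longrange_pairs <- function(n, model, contacts) {
  if (model %in% c("encom", "encom_ns")) {
    if (is.null(contacts))
      stop("ENCoM models require a ContactModel (see build_contacts())")
    if (nrow(contacts$beta) != n)
      stop("contact model has ", nrow(contacts$beta),
           " residues, structure has ", n)
    idx <- which(upper.tri(contacts$beta) & contacts$beta > 0, arr.ind = TRUE)
    idx <- idx[idx[, 2L] - idx[, 1L] >= 2L, , drop = FALSE]
    list(i = idx[, 1L], j = idx[, 2L],
         w = contacts$beta[idx])
  } else {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    idx <- idx[idx[, 2L] - idx[, 1L] >= 2L, , drop = FALSE]
    list(i = idx[, 1L], j = idx[, 2L], w = rep(1, nrow(idx)))
  }
}

#' Potential energy of a displaced conformation
#'
#' Evaluates the four-term Go-like potential of the STeM-family models
#' relative to the reference (equilibrium) geometry stored in `struct`.  By
#' construction `V(reference) = 0` and the potential is invariant under
#' rigid motions of the conformation.
#'
#' @param struct Reference `enc_structure` (defines equilibrium internal
#'   coordinates).
#' @param conformation Numeric 3N vector (or N x 3 matrix) of displaced CA
#'   coordinates.
#' @param params An `enc_params` for a 3D model (`"gnm"` has no Cartesian
#'   potential; `"anm"` uses the Hookean pair term only).
#' @param contacts `enc_contacts`, required for `"encom"`/`"encom_ns"`.
#' @return Scalar energy in model units.
#' @export
potential_energy <- function(struct, conformation, params,
                             contacts = NULL) {
  stopifnot(inherits(struct, "enc_structure"), inherits(params, "enc_params"))
  n <- struct$n_res
  ref <- ca_xyz(struct)
  x <- if (is.matrix(conformation)) conformation else
    matrix(conformation, ncol = 3L, byrow = TRUE)
  if (!all(dim(x) == c(n, 3L)))
    stop("conformation must hold 3N coordinates for N = ", n, " residues")
  if (params$model == "gnm")
    stop("the Gaussian network model has no Cartesian potential")

  if (params$model == "anm") {
    D0 <- as.matrix(stats::dist(ref))
    D1 <- as.matrix(stats::dist(x))
    sel <- upper.tri(D0) & D0 < params$anm_cutoff
    return(sum((D1[sel] - D0[sel])^2))
  }

  a <- params$alpha
  V <- 0
  # bonds
  for (i in seq_len(n - 1L)) {
    r0 <- .vnorm(ref[i, ] - ref[i + 1L, ])
    r1 <- .vnorm(x[i, ] - x[i + 1L, ])
    V <- V + a[1L] * (r1 - r0)^2
  }
  # angles
  if (n >= 3L) for (i in seq_len(n - 2L)) {
    g0 <- .angle_geom(ref[i, ], ref[i + 1L, ], ref[i + 2L, ])
    g1 <- .angle_geom(x[i, ], x[i + 1L, ], x[i + 2L, ])
    if (!g0$degenerate) V <- V + a[2L] * (g1$value - g0$value)^2
  }
  # dihedrals
  if (n >= 4L) for (i in seq_len(n - 3L)) {
    g0 <- .dihedral_geom(ref[i, ], ref[i + 1L, ], ref[i + 2L, ], ref[i + 3L, ])
    g1 <- .dihedral_geom(x[i, ], x[i + 1L, ], x[i + 2L, ], x[i + 3L, ])
    if (!g0$degenerate) {
      d <- g1$value - g0$value
      V <- V + a[3L] * ((1 - cos(d)) + 0.5 * (1 - cos(3 * d)))
    }
  }
  # long-range
  lr <- .longrange_pairs(n, params$model, contacts)
  if (length(lr$i) > 0L) for (k in seq_along(lr$i)) {
    i <- lr$i[k]
    j <- lr$j[k]
    r0 <- .vnorm(ref[i, ] - ref[j, ])
    r1 <- .vnorm(x[i, ] - x[j, ])
    s <- r0 / r1
    V <- V + a[4L] * lr$w[k] * (5 * s^12 - 6 * s^10 + 1)
  }
  V
}

#' Build the stiffness matrix of a network model
#'
#' Returns the analytic second-derivative (Hessian) matrix of the chosen
#' model at the reference geometry: 3N x 3N for the 3D models, the N x N
#' Kirchhoff matrix for GNM.  The STeM-family Hessian is assembled as a sum
#' of rank-one contributions `k * g g^T` over internal-coordinate terms and
#' is therefore symmetric positive semidefinite by construction.
#'
#' @inheritParams potential_energy
#' @param contacts `enc_contacts`; required for `"encom"`/`"encom_ns"`,
#'   ignored otherwise.
#' @return Symmetric stiffness matrix.
#' @export
build_hessian <- function(struct, params, contacts = NULL) {
  stopifnot(inherits(struct, "enc_structure"), inherits(params, "enc_params"))
  n <- struct$n_res
  if (n < 3L) stop("network build requires at least 3 residues")
  xyz <- ca_xyz(struct)

  if (params$model == "gnm") {
    D <- as.matrix(stats::dist(xyz))
    A <- (D < params$gnm_cutoff) & upper.tri(D)
    K <- matrix(0, n, n)
    K[A] <- -1
    K <- K + t(K)
    diag(K) <- -rowSums(K)
    .check_connectivity(K != 0)
    return(K)
  }

  H <- matrix(0, 3L * n, 3L * n)
  add_rank1 <- function(k, nodes, grads) {
    idx <- unlist(lapply(nodes, function(i) (3L * (i - 1L) + 1L):(3L * i)))
    g <- unlist(grads)
    H[idx, idx] <<- H[idx, idx] + k * tcrossprod(g)
  }

  if (params$model == "anm") {
    D <- as.matrix(stats::dist(xyz))
    sel <- which(upper.tri(D) & D < params$anm_cutoff, arr.ind = TRUE)
    for (p in seq_len(nrow(sel))) {
      i <- sel[p, 1L]
      j <- sel[p, 2L]
      bg <- .bond_geom(xyz[i, ], xyz[j, ])
      add_rank1(2, list(i, j), list(bg$gi, bg$gj))
    }
    adj <- D < params$anm_cutoff
    diag(adj) <- FALSE
    .check_connectivity(adj)
    return(H)
  }

  a <- params$alpha
  for (i in seq_len(n - 1L)) {
    bg <- .bond_geom(xyz[i, ], xyz[i + 1L, ])
    add_rank1(2 * a[1L], list(i, i + 1L), list(bg$gi, bg$gj))
  }
  if (n >= 3L) for (i in seq_len(n - 2L)) {
    ag <- .angle_geom(xyz[i, ], xyz[i + 1L, ], xyz[i + 2L, ])
    if (!ag$degenerate)
      add_rank1(2 * a[2L], list(i, i + 1L, i + 2L),
                list(ag$gi, ag$gj, ag$gk))
  }
  if (n >= 4L) for (i in seq_len(n - 3L)) {
    dg <- .dihedral_geom(xyz[i, ], xyz[i + 1L, ], xyz[i + 2L, ],
                         xyz[i + 3L, ])
    if (!dg$degenerate)
      add_rank1(5.5 * a[3L], list(i, i + 1L, i + 2L, i + 3L),
                list(dg$gi, dg$gj, dg$gk, dg$gl))
  }
  lr <- .longrange_pairs(n, params$model, contacts)
  adj <- matrix(FALSE, n, n)
  if (length(lr$i) > 0L) for (k in seq_along(lr$i)) {
    i <- lr$i[k]
    j <- lr$j[k]
    r0 <- .vnorm(xyz[i, ] - xyz[j, ])
    bg <- .bond_geom(xyz[i, ], xyz[j, ])
    add_rank1(120 * a[4L] * lr$w[k] / r0^2, list(i, j), list(bg$gi, bg$gj))
    adj[i, j] <- adj[j, i] <- TRUE
  }
  for (i in seq_len(n - 1L)) adj[i, i + 1L] <- adj[i + 1L, i] <- TRUE
  .check_connectivity(adj)
  H
}

# Warn when the bonded + long-range interaction graph is disconnected
# (extra zero modes are then expected).
.check_connectivity <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    i <- queue[1L]
    queue <- queue[-1L]
    nb <- which(adj[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen))
    warning("interaction network is disconnected; extra zero modes expected")
  invisible(all(seen))
}

#' Diagonalize a stiffness matrix
#'
#' Full symmetric eigendecomposition with eigenvalues in ascending order.
#' Rigid modes are identified by count (the 6 smallest for 3D models, 1 for
#' GNM), not by thresholding.  Eigenvalues below `-1e-8 * max(lambda)`
#' raise an error: a valid stiffness matrix is positive semidefinite.
#'
#' @param H Symmetric stiffness matrix from [build_hessian()].
#' @param model Model kind string (determines the rigid-mode count).
#' @return An object of class `enc_modes` with ascending `values`, matching
#'   orthonormal `vectors` (columns), `n_rigid`, `model` and `n_res`.
#' @export
diagonalize <- function(H, model = "encom") {
  model <- match.arg(tolower(model), .model_kinds)
  if (!is.matrix(H) || nrow(H) != ncol(H)) stop("H must be square")
  if (max(abs(H - t(H))) > 1e-8 * max(abs(H), 1e-300))
    stop("H must be symmetric")
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  lam_max <- max(abs(values))
  if (any(values < -1e-8 * lam_max))
    stop("stiffness matrix is not positive semidefinite")
  n_rigid <- if (.is_3d_model(model)) 6L else 1L
  n_res <- if (.is_3d_model(model)) nrow(H) / 3L else nrow(H)
  structure(list(values = values, vectors = vectors,
                 n_rigid = n_rigid, model = model, n_res = as.integer(n_res)),
            class = "enc_modes")
}

#' @export
print.enc_modes <- function(x, ...) {
  ni <- length(x$values) - x$n_rigid
  cat("enc_modes (", x$model, "): ", x$n_res, " residues, ", ni,
      " internal modes, slowest internal eigenvalue ",
      format(x$values[x$n_rigid + 1L], digits = 4), "\n", sep = "")
  invisible(x)
}

# Internal mode indices of a decomposition.
.internal_idx <- function(decomp) {
  (decomp$n_rigid + 1L):length(decomp$values)
}

#' Build and decompose a model in one call
#'
#' Convenience pipeline: (for the contact models) compute surfaces in
#' contact and beta weights, assemble the stiffness matrix, diagonalize.
#'
#' @inheritParams build_hessian
#' @param eps Interaction matrix used when `contacts` must be computed;
#'   `"encom_ns"` always uses the all-ones matrix.
#' @param method Contact surface method (see [contact_surfaces()]).
#' @return An `enc_modes` object.
#' @export
build_modes <- function(struct, params = enc_params(), contacts = NULL,
                        eps = eps_matrix_default(), method = "analytic") {
  if (params$model %in% c("encom", "encom_ns") && is.null(contacts)) {
    if (params$model == "encom_ns") eps <- eps_matrix_ones()
    contacts <- build_contacts(struct, eps = eps, method = method)
  }
  diagonalize(build_hessian(struct, params, contacts), params$model)
}
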