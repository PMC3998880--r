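# Observables computed from spectral decompositions: predicted b-factors,
# conformational overlap against a target structure, vibrational entropy
# differences (the entropic mutation score), and normalized b-factor
# difference profiles.

#' Predicted b-factors from internal modes
#'
#' For 3D models, the per-residue mean-square fluctuation summed over the
#' internal modes (7..3N): `b_i = sum_n (v_nix^2 + v_niy^2 + v_niz^2) /
#' lambda_n`.  For the Gaussian network model, the diagonal of the
#' pseudoinverse of the Kirchhoff matrix (internal modes 2..N).  Values are
#' shape-only (arbitrary units); correlation with experimental B columns is
#' the meaningful comparison.
#'
#' @param decomp An `enc_modes` decomposition.
#' @return Numeric length-N vector of nonnegative predicted b-factors.
#' @export
predict_bfactors <- function(decomp) {
  stopifnot(inherits(decomp, "enc_modes"))
  idx <- .internal_idx(decomp)
  lam <- decomp$values[idx]
  if (any(lam <= 0))
    stop("internal eigenvalues must be positive to predict b-factors")
  V <- decomp$vectors[, idx, drop = FALSE]
  W <- V %*% diag(1 / sqrt(lam), length(lam))
  msf <- rowSums(W * W)
  if (.is_3d_model(decomp$model)) {
    n <- decomp$n_res
    msf <- msf[seq(1L, 3L * n, by = 3L)] + msf[seq(2L, 3L * n, by = 3L)] +
      msf[seq(3L, 3L * n, by = 3L)]
  }
  msf
}

# Match residues of two structures by (chain, author residue number,
# insertion code); returns index pairs in each structure's residue order.
.match_residues <- function(a, b) {
  ka <- paste(a$res_info$chain, a$res_info$resno, a$res_info$insert,
              sep = "|")
  kb <- paste(b$res_info$chain, b$res_info$resno, b$res_info$insert,
              sep = "|")
  m <- match(ka, kb)
  keep <- !is.na(m)
  list(ia = which(keep), ib = m[keep])
}

#' Overlap between normal modes and an observed conformational change
#'
#' Superposes `target` onto `start` by least-squares rigid fit over matched
#' CA atoms (match by chain + residue number + insertion code), forms the
#' displacement vector, optionally projects out any residual rigid-body
#' component using the decomposition's rigid modes, and computes for every
#' internal mode `O_n = |v_n . dr| / (||v_n|| ||dr||)`.  The summary value
#' is the best overlap within the 10 slowest internal modes.
#'
#' @param decomp An `enc_modes` decomposition built from `start` (3D models
#'   only); residue counts must match the common residue set.
#' @param start,target `enc_structure` conformations sharing at least 3
#'   residues.
#' @param project_rigid Remove rigid-body components of the displacement
#'   before normalizing (default `TRUE`), so that squared overlaps over the
#'   full internal basis sum to 1.
#' @return A list of class `enc_overlap`: per-mode `overlaps` (named by mode
#'   number, internal modes only), `best_overlap`, `best_mode`, and the
#'   displacement norm `dr_norm` (Angstrom).
#' @export
overlap <- function(decomp, start, target, project_rigid = TRUE) {
  stopifnot(inherits(decomp, "enc_modes"),
            inherits(start, "enc_structure"),
            inherits(target, "enc_structure"))
  if (!.is_3d_model(decomp$model))
    stop("overlap requires a 3D model decomposition")
  m <- .match_residues(start, target)
  if (length(m$ia) < 3L)
    stop("start and target share fewer than 3 residues")
  if (length(m$ia) != decomp$n_res || !all(m$ia == seq_len(decomp$n_res)))
    stop("decomposition does not cover the common residue set; rebuild on ",
         "the matched subset (see conformational_overlap())")
  xs <- ca_xyz(start)[m$ia, , drop = FALSE]
  xt <- ca_xyz(target)[m$ib, , drop = FALSE]
  xt_fit <- .kabsch_fit(xs, xt)
  dr <- as.vector(t(xt_fit - xs))
  if (project_rigid) {
    B <- decomp$vectors[, seq_len(decomp$n_rigid), drop = FALSE]
    dr <- dr - B %*% crossprod(B, dr)
  }
  nrm <- .vnorm(dr)
  if (nrm < 1e-9)
    stop("identical conformations: overlap undefined (zero displacement)")
  idx <- .internal_idx(decomp)
  ov <- abs(as.vector(crossprod(decomp$vectors[, idx, drop = FALSE], dr))) / nrm
  names(ov) <- idx
  first10 <- seq_len(min(10L, length(ov)))
  structure(list(overlaps = ov,
                 best_overlap = max(ov[first10]),
                 best_mode = idx[first10][which.max(ov[first10])],
                 dr_norm = nrm),
            class = "enc_overlap")
}

#' @export
print.enc_overlap <- function(x, ...) {
  cat("enc_overlap: best of 10 slowest internal modes = ",
      format(x$best_overlap, digits = 4), " (mode ", x$best_mode,
      "), |dr| = ", format(x$dr_norm, digits = 4), " A\n", sep = "")
  invisible(x)
}

#' Overlap with automatic rebuilding on the common residue subset
#'
#' High-level wrapper: matches residues between the two conformations,
#' restricts both structures to the common set, rebuilds the network and
#' decomposition from `start`, and calls [overlap()].
#'
#' @inheritParams overlap
#' @param params An `enc_params`.
#' @param ... Passed to [build_modes()].
#' @return An `enc_overlap` object.
#' @export
conformational_overlap <- function(start, target, params = enc_params(),
                                   ...) {
  m <- .match_residues(start, target)
  if (length(m$ia) < 3L)
    stop("start and target share fewer than 3 residues")
  s <- .subset_structure(start, m$ia)
  t2 <- .subset_structure(target, m$ib)
  decomp <- build_modes(s, params, ...)
  overlap(decomp, s, t2)
}

# Restrict a structure to a residue-index subset (kept in order).
.subset_structure <- function(struct, res_idx) {
  keep <- struct$atoms$res_index %in% res_idx
  atoms <- struct$atoms[keep, , drop = FALSE]
  atoms$res_index <- NULL
  .new_structure(atoms, source_id = struct$source_id, model = struct$model)
}

#' Vibrational entropy difference between two decompositions
#'
#' Classical harmonic vibrational entropy difference over paired, sorted
#' internal eigenvalues in units where `k_B = 1`:
#' `DS(a -> b) = 1/2 * sum_n [ln lambda_a,n - ln lambda_b,n]`.
#' Positive when `b`'s spectrum is softer (lower frequencies, more
#' accessible microstates) than `a`'s.  Exactly antisymmetric and additive
#' over chained comparisons.
#'
#' @param decomp_a,decomp_b `enc_modes` decompositions of the same model
#'   kind and size.
#' @return Scalar entropy difference (model units, `k_B = 1`).
#' @export
entropy_difference <- function(decomp_a, decomp_b) {
  stopifnot(inherits(decomp_a, "enc_modes"), inherits(decomp_b, "enc_modes"))
  if (decomp_a$model != decomp_b$model)
    stop("decompositions come from different model kinds")
  if (decomp_a$n_res != decomp_b$n_res)
    stop("size mismatch: ", decomp_a$n_res, " vs ", decomp_b$n_res,
         " residues")
  la <- decomp_a$values[.internal_idx(decomp_a)]
  lb <- decomp_b$values[.internal_idx(decomp_b)]
  if (any(la <= 0) || any(lb <= 0))
    stop("internal eigenvalues must be positive")
  0.5 * sum(log(la) - log(lb))
}

#' Entropic prediction of the effect of a mutation
#'
#' Runs the full pipeline (contacts, stiffness matrix, spectrum) for a
#' wild-type structure and a pre-built mutant model with near-identical
#' backbone, and scores the mutation by the vibrational entropy change of
#' the folded state, oriented so that a destabilizing mutation (stiffer
#' mutant, lower folded-state entropy) tends to a positive score:
#' `score = 1/2 * sum_n [ln lambda_mut,n - ln lambda_wt,n]`.
#' For the purely geometric models (ANM, STeM) a side-chain-only mutation
#' leaves the spectrum unchanged and the score is zero.
#'
#' @param wt,mutant `enc_structure` objects with equal residue counts.
#' @param params An `enc_params`.
#' @param eps Interaction matrix for the contact models.
#' @param method Contact surface method.
#' @return A list of class `enc_ddg`: `score` (model entropy units; the raw
#'   predicted stability change), `model`, and the two decompositions.
#' @export
predict_ddg <- function(wt, mutant, params = enc_params(),
                        eps = eps_matrix_default(), method = "analytic") {
  stopifnot(inherits(wt, "enc_structure"), inherits(mutant, "enc_structure"))
  if (wt$n_res != mutant$n_res)
    stop("wild type and mutant have different residue counts (",
         wt$n_res, " vs ", mutant$n_res, ")")
  d_wt <- build_modes(wt, params, eps = eps, method = method)
  d_mut <- build_modes(mutant, params, eps = eps, method = method)
  score <- entropy_difference(d_mut, d_wt)
  structure(list(score = score, model = params$model,
                 wt_modes = d_wt, mut_modes = d_mut),
            class = "enc_ddg")
}

#' @export
print.enc_ddg <- function(x, ...) {
  cat("enc_ddg (", x$model, "): entropic score ",
      format(x$score, digits = 5),
      " (positive = predicted destabilizing)\n", sep = "")
  invisible(x)
}

#' Normalized b-factor difference profile
#'
#' Per-residue difference of z-scored predicted b-factors between a
#' wild-type and a mutant decomposition, with an inverted sign so that the
#' profile tracks NMR order-parameter (S^2) differences: a residue made
#' *more* flexible by the mutation (b-factor up, S^2 down) gets a negative
#' value.  `dB_i = -( z(b_mut)_i - z(b_wt)_i )`.
#'
#' @param wt_decomp,mut_decomp `enc_modes` decompositions of equal size.
#' @return Numeric length-N profile.
#' @export
delta_b_profile <- function(wt_decomp, mut_decomp) {
  b_wt <- predict_bfactors(wt_decomp)
  b_mut <- predict_bfactors(mut_decomp)
  if (length(b_wt) != length(b_mut))
    stop("size mismatch between the two decompositions")
  z <- function(v) {
    s <- stats::sd(v)
    if (s == 0) return(v * 0)
    (v - mean(v)) / s
  }
  -(z(b_mut) - z(b_wt))
}
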