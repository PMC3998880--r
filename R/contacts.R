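# Surfaces in contact between atoms and the residue-pair modulation weights
# beta_ij built from them.
#
# Definition of the contact surface (documented package construction; the
# source method cites an analytic algorithm without formulas): every atom is
# a sphere of radius r + probe.  The surface of atom a is partitioned among
# the neighbouring spheres that overlap it: a surface point belongs to the
# neighbour with the smallest power distance (|p - c|^2 - R^2), provided that
# power is negative (the point is inside that neighbour).  The surface in
# contact S(a,b) is the average of the area b wins on a's sphere and the
# area a wins on b's sphere.  The analytic method evaluates the areas exactly
# via Gauss-Bonnet on the circular-arc arrangement cut on each sphere (every
# constraint -- membership of a neighbour sphere, or a radical-plane power
# comparison -- is a spherical cap); the numeric method estimates the same
# partition with a deterministic Fibonacci point lattice and serves as an
# independent oracle and fallback.

# Deterministic Fibonacci lattice of M unit directions.
.fib_points <- function(M) {
  i <- seq_len(M) - 0.5
  phi <- pi * (sqrt(5) + 1) * i
  z <- 1 - 2 * i / M
  r <- sqrt(pmax(0, 1 - z * z))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Intersect a union of circular arcs (list of c(start, length), radians) with
# the single arc [s, s + l] on the circle.
.arc_clip <- function(arcs, s, l) {
  out <- list()
  two_pi <- 2 * pi
  for (a in arcs) {
    d <- (a[1L] - s) %% two_pi
    lo <- d
    hi <- d + a[2L]
    for (off in c(0, -two_pi)) {
      l2 <- max(lo + off, 0)
      h2 <- min(hi + off, l)
      if (h2 > l2 + 1e-12)
        out[[length(out) + 1L]] <- c((s + l2) %% two_pi, h2 - l2)
    }
  }
  out
}

# Area of the spherical region {|q| = R, q . n_k >= h_k for all k}.
# `nrm` is K x 3 (unit rows), `h` length K.  Exact via Gauss-Bonnet over the
# arc arrangement; falls back to lattice sampling if the arrangement is
# numerically degenerate.
.caps_area <- function(nrm, h, R, fallback_points = 20000L) {
  eps <- 1e-9 * R
  keep <- h > -R + eps
  nrm <- nrm[keep, , drop = FALSE]
  h <- h[keep]
  K <- length(h)
  if (K == 0L) return(4 * pi * R^2)
  if (any(h >= R - eps)) return(0)

  sample_area <- function() {
    P <- .fib_points(fallback_points) * R
    ok <- rep(TRUE, fallback_points)
    for (k in seq_len(K)) ok <- ok & (P %*% nrm[k, ] >= h[k])
    4 * pi * R^2 * mean(ok)
  }

  two_pi <- 2 * pi
  arcs_k <- vector("list", K)
  basis_k <- vector("list", K)
  rho <- sqrt(R^2 - h^2)
  for (k in seq_len(K)) {
    n <- nrm[k, ]
    ref <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- .unit(.cross(ref, n))
    v <- .cross(n, u)
    basis_k[[k]] <- list(n = n, u = u, v = v)
    arcs <- list(c(0, two_pi))
    for (j in seq_len(K)) {
      if (j == k) next
      a <- rho[k] * sum(u * nrm[j, ])
      b <- rho[k] * sum(v * nrm[j, ])
      cc <- h[j] - h[k] * sum(n * nrm[j, ])
      Rm <- sqrt(a * a + b * b)
      if (Rm < 1e-12 * R) {
        if (cc > 0) {
          arcs <- list()
          break
        }
        next
      }
      x <- cc / Rm
      if (x <= -1) next
      if (x >= 1) {
        arcs <- list()
        break
      }
      w <- acos(x)
      arcs <- .arc_clip(arcs, atan2(b, a) - w, 2 * w)
      if (length(arcs) == 0L) break
    }
    arcs_k[[k]] <- arcs
  }

  full_circles <- integer(0)
  seg <- list()  # arcs with vertices: list(k, t0, len)
  for (k in seq_len(K)) {
    for (a in arcs_k[[k]]) {
      if (a[2L] >= two_pi - 1e-9) {
        full_circles <- c(full_circles, k)
      } else {
        seg[[length(seg) + 1L]] <- list(k = k, t0 = a[1L], len = a[2L])
      }
    }
  }

  if (length(seg) == 0L && length(full_circles) == 0L) return(0)

  circ_point <- function(k, t) {
    bk <- basis_k[[k]]
    h[k] * bk$n + rho[k] * (bk$u * cos(t) + bk$v * sin(t))
  }
  circ_tan <- function(k, t) {
    bk <- basis_k[[k]]
    -bk$u * sin(t) + bk$v * cos(t)
  }

  kg_sum <- sum(h[full_circles] / R * two_pi)
  n_loops <- length(full_circles)
  eps_sum <- 0

  if (length(seg) > 0L) {
    ns <- length(seg)
    starts <- t(vapply(seg, function(s) circ_point(s$k, s$t0), numeric(3L)))
    ends <- t(vapply(seg, function(s) circ_point(s$k, s$t0 + s$len),
                     numeric(3L)))
    kg_sum <- kg_sum + sum(vapply(seg, function(s) s$len * h[s$k] / R, 0))
    # successor of arc i: the arc starting where arc i ends
    succ <- integer(ns)
    tol <- 1e-6 * R
    for (i in seq_len(ns)) {
      d2 <- rowSums(sweep(starts, 2L, ends[i, ])^2)
      j <- which.min(d2)
      if (sqrt(d2[j]) > tol) return(sample_area())
      succ[i] <- j
      p <- ends[i, ]
      t_in <- circ_tan(seg[[i]]$k, seg[[i]]$t0 + seg[[i]]$len)
      t_out <- circ_tan(seg[[j]]$k, seg[[j]]$t0)
      phat <- p / R
      eps_sum <- eps_sum +
        atan2(sum(.cross(t_in, t_out) * phat), sum(t_in * t_out))
    }
    if (anyDuplicated(succ)) return(sample_area())
    visited <- rep(FALSE, ns)
    for (i in seq_len(ns)) {
      if (visited[i]) next
      n_loops <- n_loops + 1L
      j <- i
      while (!visited[j]) {
        visited[j] <- TRUE
        j <- succ[j]
      }
    }
  }

  chi <- 2L - n_loops
  A <- R^2 * (two_pi * chi - kg_sum - eps_sum)
  if (!is.finite(A) || A < -1e-6 * R^2 || A > 4 * pi * R^2 + 1e-6 * R^2)
    return(sample_area())
  max(A, 0)
}

#' Surfaces in contact between atoms
#'
#' Computes, for every pair of atoms in *different* residues whose
#' solvent-extended spheres overlap, the surface area in contact (Angstrom^2)
#' under the power-diagram partition described in the package vignette.
#' Atoms of the same residue still compete for surface but no intra-residue
#' area is reported.
#'
#' @param struct An `enc_structure` with radii (always present after
#'   [read_pdb()] or [make_structure()]).
#' @param method `"analytic"` (exact Gauss-Bonnet arrangement areas, the
#'   default) or `"numeric"` (deterministic sphere-point sampling; the
#'   oracle).
#' @param probe Probe radius in Angstrom added to every atomic radius before
#'   deciding and apportioning contact (default 1.4, a water probe).
#' @param n_points Number of lattice points per sphere for the numeric
#'   method.
#' @return An object of class `enc_surfaces`: a table of atom-index pairs
#'   with positive contact areas plus the settings used.
#' @export
contact_surfaces <- function(struct, method = c("analytic", "numeric"),
                             probe = 1.4, n_points = 4096L) {
  stopifnot(inherits(struct, "enc_structure"))
  method <- match.arg(method)
  a <- struct$atoms
  n <- nrow(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  R <- a$radius + probe
  res <- a$res_index

  D <- as.matrix(stats::dist(xyz))
  dup <- which(D < 1e-9 & upper.tri(D), arr.ind = TRUE)
  if (nrow(dup) > 0L)
    stop("degenerate geometry: atoms ", a$serial[dup[1L, 1L]], " and ",
         a$serial[dup[1L, 2L]], " share identical coordinates")

  contact <- D < outer(R, R, "+") & upper.tri(D)
  nbrs <- lapply(seq_len(n), function(i)
    which((D[i, ] < R[i] + R) & seq_len(n) != i))

  pair_idx <- which(contact, arr.ind = TRUE)
  res_pairs <- pair_idx[res[pair_idx[, 1L]] != res[pair_idx[, 2L]], ,
                        drop = FALSE]

  area_on <- function(ai, bj) {
    # area of atom ai's sphere won by neighbour bj
    nb <- nbrs[[ai]]
    d_b <- xyz[bj, ] - xyz[ai, ]
    Db <- .vnorm(d_b)
    cons_n <- matrix(d_b / Db, nrow = 1L)
    cons_h <- (R[ai]^2 + Db^2 - R[bj]^2) / (2 * Db)
    pw_b <- Db^2 - R[bj]^2
    for (cj in nb) {
      if (cj == bj) next
      d_c <- xyz[cj, ] - xyz[ai, ]
      m <- d_b - d_c
      nm <- .vnorm(m)
      pw_c <- sum(d_c * d_c) - R[cj]^2
      if (nm < 1e-9) {
        if (pw_b > pw_c || (pw_b == pw_c && bj > cj)) return(0)
        next
      }
      cons_n <- rbind(cons_n, m / nm)
      cons_h <- c(cons_h, (pw_b - pw_c) / (2 * nm))
    }
    .caps_area(cons_n, cons_h, R[ai])
  }

  area_on_numeric <- function(ai, dirs) {
    # winner index (0 = unassigned) per lattice point of atom ai's sphere
    nb <- nbrs[[ai]]
    P <- sweep(dirs * R[ai], 2L, xyz[ai, ], FUN = "+")
    best <- rep(0, nrow(P))
    winner <- integer(nrow(P))
    for (bj in nb) {
      pw <- rowSums(sweep(P, 2L, xyz[bj, ])^2) - R[bj]^2
      upd <- pw < best
      best[upd] <- pw[upd]
      winner[upd] <- bj
    }
    winner
  }

  areas <- numeric(nrow(res_pairs))
  if (nrow(res_pairs) > 0L) {
    if (method == "numeric") {
      dirs <- .fib_points(n_points)
      winners <- lapply(seq_len(n), function(i)
        if (length(nbrs[[i]]) > 0L) area_on_numeric(i, dirs) else integer(0))
      for (p in seq_len(nrow(res_pairs))) {
        i <- res_pairs[p, 1L]
        j <- res_pairs[p, 2L]
        si <- 4 * pi * R[i]^2 * mean(winners[[i]] == j)
        sj <- 4 * pi * R[j]^2 * mean(winners[[j]] == i)
        areas[p] <- (si + sj) / 2
      }
    } else {
      for (p in seq_len(nrow(res_pairs))) {
        i <- res_pairs[p, 1L]
        j <- res_pairs[p, 2L]
        areas[p] <- (area_on(i, j) + area_on(j, i)) / 2
      }
    }
  }

  keep <- areas > 0
  pairs <- data.frame(ai = res_pairs[keep, 1L], aj = res_pairs[keep, 2L],
                      area = areas[keep])
  structure(list(pairs = pairs, method = method, probe = probe,
                 n_points = if (method == "numeric") as.integer(n_points) else NA_integer_,
                 n_atoms = n),
            class = "enc_surfaces")
}

#' @export
print.enc_surfaces <- function(x, ...) {
  cat("enc_surfaces: ", nrow(x$pairs), " inter-residue atom contacts (",
      x$method, " method, probe ", x$probe, " A)\n", sep = "")
  invisible(x)
}

#' Residue-pair modulation weights beta_ij
#'
#' Aggregates atom-pair surfaces in contact into the symmetric N x N matrix
#' of residue-pair weights: `beta[i, j]` is the sum over atom pairs (a in
#' residue i, b in residue j) of `eps[T(a), T(b)] * S(a, b)`, where `T` is
#' the atom-type class and `S` the surface in contact.  Atoms with an
#' `"unassigned"` type use the neutral row of `eps`.  With the all-ones
#' matrix the weights reduce to plain summed contact areas (the non-specific
#' ENCoM_ns model).
#'
#' @param struct An `enc_structure` with atom types assigned.
#' @param surfaces An `enc_surfaces` object from [contact_surfaces()]
#'   computed on the same structure.
#' @param eps 8 x 8 interaction matrix (see [eps_matrix_default()]).
#' @return An object of class `enc_contacts` holding `beta` (N x N,
#'   symmetric, nonnegative) and the underlying atom-pair surfaces.
#' @export
compute_beta <- function(struct, surfaces, eps = eps_matrix_default()) {
  stopifnot(inherits(struct, "enc_structure"),
            inherits(surfaces, "enc_surfaces"))
  if (surfaces$n_atoms != nrow(struct$atoms))
    stop("surfaces were computed on a different structure")
  eps <- validate_eps_matrix(eps)
  types <- struct$atoms$atom_type
  if (all(is.na(types)))
    stop("atom types are unassigned; run assign_atom_types() first")
  types[is.na(types) | types == "unassigned"] <- "neutral"
  ti <- match(types, atom_type_classes())
  n <- struct$n_res
  beta <- matrix(0, n, n)
  p <- surfaces$pairs
  if (nrow(p) > 0L) {
    ri <- struct$atoms$res_index[p$ai]
    rj <- struct$atoms$res_index[p$aj]
    w <- eps[cbind(ti[p$ai], ti[p$aj])] * p$area
    for (k in seq_len(nrow(p))) {
      beta[ri[k], rj[k]] <- beta[ri[k], rj[k]] + w[k]
      beta[rj[k], ri[k]] <- beta[rj[k], ri[k]] + w[k]
    }
  }
  structure(list(beta = beta, atom_surfaces = p, method = surfaces$method,
                 probe = surfaces$probe),
            class = "enc_contacts")
}

#' @export
print.enc_contacts <- function(x, ...) {
  nz <- sum(x$beta[upper.tri(x$beta)] > 0)
  cat("enc_contacts: ", nrow(x$beta), " residues, ", nz,
      " residue pairs in contact\n", sep = "")
  invisible(x)
}

#' One-call contact model
#'
#' Convenience wrapper running [contact_surfaces()] then [compute_beta()].
#'
#' @inheritParams compute_beta
#' @inheritParams contact_surfaces
#' @return An `enc_contacts` object.
#' @export
build_contacts <- function(struct, eps = eps_matrix_default(),
                           method = "analytic", probe = 1.4,
                           n_points = 4096L) {
  compute_beta(struct,
               contact_surfaces(struct, method = method, probe = probe,
                                n_points = n_points),
               eps = eps)
}
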