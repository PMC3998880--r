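test_that("the potential vanishes at the reference and under rigid motion", {
  s <- fx_helix5
  p <- enc_params("encom")
  x0 <- ca_xyz(s)
  expect_identical(potential_energy(s, x0, p, fx_contacts5), 0)
  xr <- sweep(x0 %*% t(encomr:::.random_rotation(3)), 2L, c(2, -1, 4),
              FUN = "+")
  expect_lt(abs(potential_energy(s, xr, p, fx_contacts5)), 1e-9)
  expect_error(potential_energy(s, x0[1:4, ], p, fx_contacts5), "3N")
})

test_that("small bond stretches cost quadratic energy", {
  s <- fx_helix5
  p <- enc_params("encom")
  x0 <- ca_xyz(s)
  stretch <- function(delta) {
    x <- x0
    u <- (x0[1L, ] - x0[2L, ]) / sqrt(sum((x0[1L, ] - x0[2L, ])^2))
    x[1L, ] <- x[1L, ] + delta * u
    potential_energy(s, x, p, fx_contacts5)
  }
  d <- 1e-4
  ratio <- stretch(d) / stretch(d / 2)
  expect_equal(ratio, 4, tolerance = 0.01)
})

test_that("the analytic Hessian matches finite differences of the potential", {
  for (model in c("encom", "stem")) {
    p <- enc_params(model)
    H <- build_hessian(fx_helix5, p, fx_contacts5)
    expect_lt(max(abs(H - t(H))), 1e-10 * max(abs(H)))
    Hfd <- fd_hessian(fx_helix5, p, fx_contacts5)
    expect_lt(max(abs(H - Hfd)) / max(abs(H)), 1e-5)
  }
})

test_that("every 3D model has exactly six rigid modes and a positive internal spectrum", {
  for (model in c("encom", "encom_ns", "stem", "anm")) {
    p <- enc_params(model)
    con <- if (model == "encom") fx_contacts8 else
      if (model == "encom_ns") build_contacts(fx_helix8,
                                              eps = eps_matrix_ones()) else
        NULL
    d <- diagonalize(build_hessian(fx_helix8, p, con), model)
    expect_length(d$values, 3L * fx_helix8$n_res)
    lam_max <- max(d$values)
    expect_lt(max(abs(d$values[1:6])), 1e-8 * lam_max)
    expect_true(all(d$values[7:length(d$values)] > 0))
    # orthonormality of the eigenbasis
    G <- crossprod(d$vectors)
    expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)
  }
  # GNM: one rigid mode of an N x N Kirchhoff matrix
  dg <- diagonalize(build_hessian(fx_helix8, enc_params("gnm")), "gnm")
  expect_length(dg$values, fx_helix8$n_res)
  expect_equal(dg$n_rigid, 1L)
  expect_lt(abs(dg$values[1L]), 1e-8 * max(dg$values))
})

test_that("rigid-body displacement vectors lie in the null space", {
  H <- build_hessian(fx_helix8, enc_params("encom"), fx_contacts8)
  B <- encomr:::.rigid_basis(ca_xyz(fx_helix8))
  expect_lt(max(abs(H %*% B)), 1e-8 * norm(H, "2"))
})

test_that("the internal spectrum is invariant under rigid rotation", {
  p <- enc_params("encom")
  d1 <- diagonalize(build_hessian(fx_helix8, p, fx_contacts8), "encom")
  sr <- rotate_structure(fx_helix8, seed = 9)
  d2 <- diagonalize(build_hessian(sr, p, build_contacts(sr)), "encom")
  i1 <- d1$values[7:length(d1$values)]
  i2 <- d2$values[7:length(d2$values)]
  expect_lt(max(abs(i1 - i2) / i1), 1e-6)
})

test_that("a collinear triatomic with bond springs only shows the classic frequencies", {
  # straight 3-bead chain: angle terms are degenerate, no dihedrals exist
  # and no long-range pair is in contact, so only the two bond springs of
  # stiffness k = 2*a1 act.  The 1D spring chain has nonzero eigenvalues
  # k and 3k; transverse/rigid directions all fall in the null space.
  chain <- make_structure("linear_chain", 3)
  a1 <- 7.5
  p <- enc_params("encom", alpha = c(a1, 1e-12, 1e-12, 1e-12))
  H <- build_hessian(chain, p, build_contacts(chain))
  lam <- sort(eigen(H, symmetric = TRUE)$values)
  k <- 2 * a1
  expect_equal(lam[8:9], c(k, 3 * k), tolerance = 1e-9)
  expect_lt(max(abs(lam[1:7])), 1e-9 * k)
})

test_that("ENCoM with the all-ones matrix reproduces the non-specific variant exactly", {
  con_ones <- build_contacts(fx_helix8, eps = eps_matrix_ones())
  H1 <- build_hessian(fx_helix8, enc_params("encom"), con_ones)
  H2 <- build_hessian(fx_helix8, enc_params("encom_ns"), con_ones)
  expect_identical(H1, H2)
})

test_that("scaling all four weights scales the spectrum and nothing else", {
  c_fac <- 3.7
  p1 <- enc_params("encom", alpha = c(10, 100, 100, 0.1))
  p2 <- enc_params("encom", alpha = c_fac * p1$alpha)
  H1 <- build_hessian(fx_helix8, p1, fx_contacts8)
  H2 <- build_hessian(fx_helix8, p2, fx_contacts8)
  expect_equal(H2, c_fac * H1, tolerance = 1e-12)
  d1 <- diagonalize(H1, "encom")
  d2 <- diagonalize(H2, "encom")
  expect_equal(d2$values, c_fac * d1$values, tolerance = 1e-9)
  # b-factors scale by 1/c, so their correlation structure is unchanged
  expect_equal(stats::cor(predict_bfactors(d1), predict_bfactors(d2)), 1,
               tolerance = 1e-9)
  # entropy differences between two structures are scale-invariant
  sm <- make_mutation_pair(fx_helix10, 4L, radius_scale = 1.4, params = p1)
  s1 <- predict_ddg(sm$wt, sm$mut, p1)$score
  s2 <- predict_ddg(sm$wt, sm$mut, p2)$score
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("ANM agrees with an independent reference implementation", {
  s <- make_structure("ideal_helix", 12)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(s, path)
  ours <- diagonalize(build_hessian(read_pdb(path), enc_params("anm")),
                      "anm")
  ref <- bio3d::nma(bio3d::read.pdb(path), ff = "anm", cutoff = 18,
                    mass = FALSE, temp = NULL)
  # eigenvalue ratio must be a constant (force-constant convention) ...
  i_ours <- ours$values[7:length(ours$values)]
  i_ref <- ref$L[7:length(ref$L)]
  ratio <- i_ours / i_ref
  expect_lt(stats::sd(ratio) / mean(ratio), 1e-3)
  # ... and fluctuation profiles must coincide
  expect_gt(stats::cor(predict_bfactors(ours), ref$fluctuations), 0.9999)
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(diagonalize(matrix(c(1, 2, 0, 1), 2, 2), "anm"), "symmetric")
  expect_error(diagonalize(-diag(4), "anm"), "semidefinite")
  # a GNM whose cutoff is shorter than the bead spacing splits the network
  wide <- make_structure("linear_chain", 5, spacing = 12)
  expect_warning(build_hessian(wide, enc_params("gnm")), "disconnected")
  tiny <- make_structure("linear_chain", 3)
  tiny2 <- encomr:::.subset_structure(tiny, 1:2)
  expect_error(build_hessian(tiny2, enc_params("anm")), "at least 3")
})
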