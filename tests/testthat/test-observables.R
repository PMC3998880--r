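fx_modes8 <- diagonalize(build_hessian(fx_helix8, enc_params("encom"),
                                       fx_contacts8), "encom")

test_that("predicted b-factors equal pseudoinverse block traces", {
  for (model in c("encom", "stem", "anm")) {
    p <- enc_params(model)
    H <- build_hessian(fx_helix5, p,
                       if (model == "encom") fx_contacts5 else NULL)
    d <- diagonalize(H, model)
    b <- predict_bfactors(d)
    G <- MASS::ginv(H)
    oracle <- vapply(seq_len(fx_helix5$n_res), function(i)
      sum(diag(G)[(3L * i - 2L):(3L * i)]), 0)
    expect_lt(max(abs(b - oracle) / oracle), 1e-8)
    expect_true(all(b >= 0))
  }
  # GNM variant: diagonal of the Kirchhoff pseudoinverse
  K <- build_hessian(fx_helix5, enc_params("gnm"))
  dg <- diagonalize(K, "gnm")
  expect_lt(max(abs(predict_bfactors(dg) - diag(MASS::ginv(K))) /
                  diag(MASS::ginv(K))), 1e-8)
})

test_that("b-factors are homogeneous of degree -1 in the eigenvalues", {
  d <- fx_modes8
  d_scaled <- d
  d_scaled$values <- 2.5 * d$values
  expect_equal(predict_bfactors(d_scaled), predict_bfactors(d) / 2.5,
               tolerance = 1e-12)
})

test_that("a dominant single mode dominates the fluctuation profile", {
  d <- fx_modes8
  idx <- 7:length(d$values)
  d$values[idx[-1L]] <- 1e12
  b <- predict_bfactors(d)
  v7 <- matrix(d$vectors[, 7L], ncol = 3L, byrow = TRUE)
  expect_equal(b, rowSums(v7^2) / d$values[7L], tolerance = 1e-6)
})

test_that("overlap is 1 for a displacement along one eigenvector and 0 off the first ten", {
  s <- fx_helix8
  d <- fx_modes8
  along <- function(mode_col, mag = 0.3) {
    disp <- matrix(d$vectors[, mode_col], ncol = 3L, byrow = TRUE) * mag
    encomr:::.displace_structure(s, disp)
  }
  ov7 <- overlap(d, s, along(7L))
  expect_equal(ov7$best_overlap, 1, tolerance = 1e-6)
  expect_equal(ov7$best_mode, 7L)
  expect_true(all(ov7$overlaps[-1L] <= 1e-6))
  # displacement along the 17th internal basis vector: none of the 10
  # slowest modes see it
  ov_hi <- overlap(d, s, along(23L))
  expect_lt(ov_hi$best_overlap, 1e-6)
  expect_equal(unname(ov_hi$overlaps[["23"]]), 1, tolerance = 1e-6)
})

test_that("squared overlaps over the internal basis sum to one for any displacement", {
  s <- fx_helix8
  d <- fx_modes8
  set.seed(21)
  for (rep in 1:3) {
    disp <- matrix(rnorm(3L * s$n_res, sd = 0.05), ncol = 3L)
    ov <- overlap(d, s, encomr:::.displace_structure(s, disp))
    expect_equal(sum(ov$overlaps^2), 1, tolerance = 1e-8)
    expect_true(all(ov$overlaps >= 0 & ov$overlaps <= 1 + 1e-12))
  }
})

test_that("identical conformations make the overlap undefined", {
  expect_error(overlap(fx_modes8, fx_helix8, fx_helix8), "undefined|zero")
})

test_that("overlap rebuilds on the common residue subset when sets differ", {
  s <- fx_helix10
  cp <- make_conformer_pair(s, "random", magnitude = 0.5, seed = 4)
  target <- encomr:::.subset_structure(cp$target, 2:9)
  expect_error(overlap(fx_modes8, s, target), "common residue")
  ov <- conformational_overlap(s, target, enc_params("encom"))
  expect_true(is.finite(ov$best_overlap))
  expect_true(ov$best_overlap >= 0 && ov$best_overlap <= 1)
})

test_that("entropy differences are zero on identity, antisymmetric and additive", {
  p <- enc_params("encom")
  d_a <- fx_modes8
  sm <- make_mutation_pair(fx_helix8, 4L, radius_scale = 1.5, params = p)
  d_b <- build_modes(sm$mut, p)
  sm2 <- make_mutation_pair(fx_helix8, 5L, new_type = "acceptor",
                            radius_scale = 0.7, params = p)
  d_c <- build_modes(sm2$mut, p)
  expect_identical(entropy_difference(d_a, d_a), 0)
  expect_equal(entropy_difference(d_a, d_b), -entropy_difference(d_b, d_a))
  expect_equal(entropy_difference(d_a, d_b) + entropy_difference(d_b, d_c),
               entropy_difference(d_a, d_c), tolerance = 1e-12)
  # stiffening b monotonically lowers its relative entropy
  prev <- Inf
  for (c_fac in c(1.5, 2, 4)) {
    d_stiff <- d_b
    d_stiff$values <- c_fac * d_b$values
    cur <- entropy_difference(d_a, d_stiff)
    expect_lt(cur, prev)
    prev <- cur
  }
  d_gnm <- diagonalize(build_hessian(fx_helix8, enc_params("gnm")), "gnm")
  expect_error(entropy_difference(d_a, d_gnm), "model")
})

test_that("the entropic mutation score behaves physically", {
  p <- enc_params("encom")
  # self-comparison scores exactly zero
  expect_identical(predict_ddg(fx_helix8, fx_helix8, p)$score, 0)
  # a contact-enlarging mutation scores nonzero, stably under rotation
  sm <- make_mutation_pair(fx_helix10, 5L, radius_scale = 1.6, params = p)
  s1 <- predict_ddg(sm$wt, sm$mut, p)$score
  expect_gt(abs(s1), 1e-8)
  s2 <- predict_ddg(sm$wt, rotate_structure(sm$mut, seed = 13), p)$score
  expect_equal(s2, s1, tolerance = 1e-6)
  # geometry-only models are blind to side-chain-only changes
  expect_lt(abs(predict_ddg(sm$wt, sm$mut, enc_params("anm"))$score), 1e-8)
  expect_lt(abs(predict_ddg(sm$wt, sm$mut, enc_params("stem"))$score), 1e-8)
  # mismatched sizes are rejected
  expect_error(predict_ddg(fx_helix8, fx_helix10, p), "residue counts")
})

test_that("delta-B profiles are normalized, signed and localized", {
  p <- enc_params("encom")
  expect_equal(delta_b_profile(fx_modes8, fx_modes8),
               rep(0, fx_helix8$n_res))
  # uniform eigenvalue scaling only rescales b, which the z-score removes
  d_scaled <- fx_modes8
  d_scaled$values <- 3 * fx_modes8$values
  expect_equal(delta_b_profile(fx_modes8, d_scaled),
               rep(0, fx_helix8$n_res), tolerance = 1e-10)
  # weakening one residue's long-range springs softens it: extremum of the
  # profile at that residue, negative sign (more flexible tracks a lower
  # order parameter).  The b-factor-optimal weight profile is used since
  # delta-B is a fluctuation observable.
  pb <- enc_params("encom", profile = "bfactor")
  con <- build_contacts(fx_helix10)
  d_wt <- diagonalize(build_hessian(fx_helix10, pb, con), "encom")
  for (pos in c(4L, 6L)) {
    soft <- con
    soft$beta[pos, ] <- soft$beta[pos, ] * 0.1
    soft$beta[, pos] <- con$beta[, pos] * 0.1
    d_mut <- diagonalize(build_hessian(fx_helix10, pb, soft), "encom")
    db <- delta_b_profile(d_wt, d_mut)
    expect_equal(which.max(abs(db)), pos)
    expect_lt(db[pos], 0)
  }
})
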