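test_that("through-origin regression matches hand-computed cases", {
  r <- rmse_through_origin(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$slope, 2)
  expect_equal(r$rmse, 0)
  # orthogonal case: sum(xy) = 0 so the slope collapses to zero
  r2 <- rmse_through_origin(c(1, -1), c(1, 1))
  expect_equal(r2$slope, 0)
  expect_equal(r2$rmse, 1)
  # permutation invariance
  set.seed(8)
  x <- rnorm(40)
  y <- 1.3 * x + rnorm(40, 0, 0.2)
  perm <- sample.int(40)
  r3 <- rmse_through_origin(x, y)
  r4 <- rmse_through_origin(x[perm], y[perm])
  expect_equal(r3$slope, r4$slope)
  expect_equal(r3$rmse, r4$rmse)
  # exact proportionality has zero error for any slope
  for (k in c(-3, 0.01, 12)) {
    expect_equal(rmse_through_origin(x, k * x)$rmse, 0, tolerance = 1e-12)
    expect_equal(rmse_through_origin(x, k * x)$slope, k, tolerance = 1e-12)
  }
  expect_error(rmse_through_origin(rep(0, 5), rnorm(5)), "degenerate")
  expect_error(rmse_through_origin(1, 1), "at least 2")
  expect_error(rmse_through_origin(1:3, 1:4), "equal length")
})

test_that("bootstrap is deterministic, unbiased on constants and well calibrated", {
  b1 <- bootstrap(1:100, "mean", n_iter = 2000L, seed = 7L)
  b2 <- bootstrap(1:100, "mean", n_iter = 2000L, seed = 7L)
  expect_identical(b1$estimate, b2$estimate)
  expect_identical(b1$quantiles, b2$quantiles)
  # constant sample: the statistic is the constant with zero spread
  bc <- bootstrap(rep(4.2, 30), "median", n_iter = 500L, seed = 1L)
  expect_equal(bc$estimate, 4.2)
  expect_equal(bc$stderr, 0)
  # bootstrap standard error of the mean tracks sigma/sqrt(n)
  expect_lt(abs(b1$stderr - sd(1:100) / 10) / (sd(1:100) / 10), 0.15)
  # paired statistics work on two-column input
  xy <- cbind(1:20, 2 * (1:20) + rnorm(20, 0, 0.1))
  br <- bootstrap(xy, "rmse_through_origin", n_iter = 300L, seed = 2L)
  expect_true(is.finite(br$estimate))
  expect_error(bootstrap(numeric(0), "mean"), "empty")
})

test_that("mutation classification uses the closed neutral interval", {
  cl <- classify_mutations(c(-0.5, 0.5, -0.51, 0.51, 0))
  expect_equal(as.character(cl$class),
               c("neutral", "neutral", "stabilizing", "destabilizing",
                 "neutral"))
  expect_equal(sum(cl$counts), 5L)
  empty <- classify_mutations(numeric(0))
  expect_equal(unname(empty$counts), c(0L, 0L, 0L))
  expect_error(classify_mutations(c(1, NA)), "finite")
  # data-frame input via the ddg_exp column
  df <- data.frame(ddg_exp = c(-2, 2))
  expect_equal(unname(classify_mutations(df)$counts), c(1L, 0L, 1L))
})

test_that("self-consistency bias and error measure distance to y = -x", {
  sc0 <- self_consistency(c(1.2, -0.4, 2), -c(1.2, -0.4, 2))
  expect_equal(sc0$bias, 0)
  expect_equal(sc0$error, 0)
  # constant offset: every point sits sqrt(2) away from the line
  sc1 <- self_consistency(rep(1, 8), rep(1, 8))
  expect_equal(sc1$bias, sqrt(2))
  expect_equal(sc1$error, sqrt(2))
  # sign flip flips the bias and preserves the error
  set.seed(5)
  fwd <- rnorm(30)
  rev <- -fwd + rnorm(30, 0.3, 0.4)
  sa <- self_consistency(fwd, rev)
  sb <- self_consistency(-fwd, -rev)
  expect_equal(sb$bias, -sa$bias)
  expect_equal(sb$error, sa$error)
  # error >= |bias| on arbitrary inputs
  for (rep in 1:5) {
    f <- rnorm(12)
    r <- rnorm(12)
    sc <- self_consistency(f, r)
    expect_gte(sc$error, abs(sc$bias) - 1e-12)
  }
  expect_error(self_consistency(1:3, 1:4), "equal length")
  # bootstrap spreads attach on request and are deterministic
  sc_b <- self_consistency(fwd, rev, n_iter = 200L, seed = 3L)
  sc_b2 <- self_consistency(fwd, rev, n_iter = 200L, seed = 3L)
  expect_identical(sc_b$bias_boot$estimate, sc_b2$bias_boot$estimate)
})

test_that("model combination is never worse than the better single model", {
  set.seed(31)
  y <- rnorm(60)
  pe <- y + rnorm(60, 0, 0.5)
  po <- 0.8 * y + rnorm(60, 0, 0.9)
  cm <- combine_models(pe, po, y, n_iter = 200L, seed = 1L)
  single <- function(p) {
    k <- sum(p * y) / sum(p * p)
    sqrt(mean((y - k * p)^2))
  }
  expect_lte(cm$rmse_combined, min(single(pe), single(po)) + 1e-10)
  expect_true(is.finite(cm$delta_rmse))
  # a redundant partner adds nothing: combined rmse equals the single fit
  cm_dup <- suppressWarnings(combine_models(pe, pe, y, n_iter = 50L,
                                            seed = 1L))
  expect_equal(cm_dup$rmse_combined, single(pe), tolerance = 1e-8)
  # a perfect partner leaves no role for the entropic model
  cm_perf <- combine_models(pe, y, y, n_iter = 100L, seed = 1L)
  expect_lt(cm_perf$ratio, 1e-6)
})

test_that("the parameter grid search is deterministic and scale-degenerate", {
  bun <- make_benchmark_bundle(seed = 2L, n_mut = 6L, n_overlap = 2L,
                               n_res = 8L)
  res1 <- parameter_search(bun, grid_log10 = c(0, 2), seed = 1L,
                           n_boot = 50L)
  res2 <- parameter_search(bun, grid_log10 = c(0, 2), seed = 1L,
                           n_boot = 50L)
  expect_identical(res1, res2)
  expect_equal(nrow(res1), 16L)
  expect_equal(res1$rank[1L], 1L)
  # a single-point grid ranks that point first
  one <- parameter_search(bun, grid_log10 = matrix(c(1, 2, 2, -1), 1L),
                          seed = 1L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$rank, 1L)
  # uniformly scaled alpha sets give identical scale-invariant metrics
  two <- parameter_search(bun,
                          grid_log10 = rbind(c(0, 1, 1, -1),
                                             c(2, 3, 3, 1)),
                          seed = 1L, n_boot = 50L)
  expect_equal(two$rmse_stab[1L], two$rmse_stab[2L], tolerance = 1e-6)
  expect_equal(two$rmse_destab[1L], two$rmse_destab[2L], tolerance = 1e-6)
  expect_equal(two$overlap_domain[1L], two$overlap_domain[2L],
               tolerance = 1e-6)
  expect_equal(two$overlap_loop[1L], two$overlap_loop[2L],
               tolerance = 1e-6)
  expect_error(parameter_search(bun, grid_log10 = numeric(0)), "empty")
})
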