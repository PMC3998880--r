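# Evaluation machinery: through-origin regression, bootstrap, mutation
# classification, self-consistency bias/error, linear model combination and
# the force-constant grid search.

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Zero-intercept linear regression and its RMSE
#'
#' Fits `y ~ k x` through the origin (`k = sum(xy) / sum(x^2)`) and reports
#' the root-mean-square error of the fit.  The through-origin constraint
#' encodes the physical requirement that a null mutation must predict a
#' null experimental change.
#'
#' @param x Predicted values.
#' @param y Experimental values (same length, >= 2).
#' @return A list of class `enc_regression`: `slope`, `rmse`, `n`.
#' @examples
#' rmse_through_origin(c(1, 2, 3), c(2, 4, 6))  # slope 2, rmse 0
#' @export
rmse_through_origin <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 points")
  if (all(x == 0)) stop("degenerate fit: all predictions are zero")
  k <- sum(x * y) / sum(x * x)
  structure(list(slope = k, rmse = sqrt(mean((y - k * x)^2)),
                 n = length(x)),
            class = "enc_regression")
}

#' @export
print.enc_regression <- function(x, ...) {
  cat("through-origin fit: slope ", format(x$slope, digits = 5), ", RMSE ",
      format(x$rmse, digits = 5), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

.boot_statistics <- c("mean", "median", "rmse_through_origin", "correlation")

.eval_statistic <- function(statistic, values, idx = seq_len(NROW(values))) {
  switch(statistic,
         mean = mean(values[idx]),
         median = stats::median(values[idx]),
         rmse_through_origin =
           rmse_through_origin(values[idx, 1L], values[idx, 2L])$rmse,
         correlation = stats::cor(values[idx, 1L], values[idx, 2L]))
}

#' Bootstrap a statistic
#'
#' Resamples the input with replacement `n_iter` times (default 10000, the
#' benchmark protocol) and reports the bootstrapped average of the chosen
#' statistic together with its spread.  Fully deterministic given `seed`.
#'
#' @param values Numeric vector (for `"mean"`/`"median"`) or two-column
#'   matrix/data frame of (predicted, experimental) pairs (for
#'   `"rmse_through_origin"`/`"correlation"`).
#' @param statistic One of `"mean"`, `"median"`, `"rmse_through_origin"`,
#'   `"correlation"`.
#' @param n_iter Number of bootstrap replicates.
#' @param seed Integer RNG seed (required: all statistics in this package
#'   are reproducible by contract).
#' @return A list of class `enc_boot`: `estimate` (bootstrapped average),
#'   `stderr` (bootstrap standard deviation), `quantiles` (2.5/50/97.5%),
#'   `observed` (statistic on the full sample), `n`, `n_iter`, `seed`.
#' @export
bootstrap <- function(values, statistic = c("mean", "median",
                                            "rmse_through_origin",
                                            "correlation"),
                      n_iter = 10000L, seed = 1L) {
  statistic <- match.arg(statistic)
  if (statistic %in% c("rmse_through_origin", "correlation")) {
    values <- as.matrix(values)
    if (ncol(values) != 2L)
      stop("statistic '", statistic, "' needs two-column input")
  } else {
    values <- as.numeric(values)
  }
  n <- NROW(values)
  if (n == 0L) stop("empty input")
  reps <- .with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      idx <- sample.int(n, n, replace = TRUE)
      .eval_statistic(statistic, values, idx)
    }, 0)
  })
  reps_ok <- reps[is.finite(reps)]
  structure(list(estimate = mean(reps_ok),
                 stderr = if (length(reps_ok) > 1L) stats::sd(reps_ok) else 0,
                 quantiles = stats::quantile(reps_ok,
                                             c(0.025, 0.5, 0.975),
                                             names = TRUE),
                 observed = .eval_statistic(statistic, values),
                 n = n, n_iter = as.integer(n_iter),
                 seed = as.integer(seed), statistic = statistic),
            class = "enc_boot")
}

#' @export
print.enc_boot <- function(x, ...) {
  cat("bootstrap ", x$statistic, " (", x$n_iter, " replicates, seed ",
      x$seed, "): ", format(x$estimate, digits = 5), " +/- ",
      format(x$stderr, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Classify mutations by experimental stability change
#'
#' Applies the standard thermodynamic thresholds: stabilizing
#' `ddG < -0.5` kcal/mol, neutral `ddG` in the *closed* interval
#' `[-0.5, 0.5]`, destabilizing `ddG > 0.5`.
#'
#' @param ddg Numeric vector of experimental ddG values (kcal/mol), or a
#'   data frame with a `ddg_exp` column.
#' @return A list with `class` (factor per mutation) and `counts` (named
#'   vector stabilizing/neutral/destabilizing; sums to the input size).
#' @export
classify_mutations <- function(ddg) {
  if (is.data.frame(ddg)) {
    if (is.null(ddg$ddg_exp)) stop("data frame input needs a ddg_exp column")
    ddg <- ddg$ddg_exp
  }
  ddg <- as.numeric(ddg)
  if (any(!is.finite(ddg))) stop("ddG values must be finite")
  cls <- factor(ifelse(ddg < -0.5, "stabilizing",
                       ifelse(ddg > 0.5, "destabilizing", "neutral")),
                levels = c("stabilizing", "neutral", "destabilizing"))
  counts <- table(cls)
  list(class = cls,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Self-consistency of forward and back mutation predictions
#'
#' A thermodynamically consistent predictor satisfies
#' `ddG(A->B) = -ddG(B->A)`; plotted against each other, perfect pairs fall
#' on the line `y = -x`.  The bias is the signed mean distance of the pairs
#' from that line, `mean(fwd + rev) / sqrt(2)`, and the error is the RMS
#' distance `sqrt(mean((fwd + rev)^2)) / sqrt(2)`.  Error >= |bias| always.
#'
#' @param fwd,rev Equal-length vectors of forward and back predictions.
#' @param n_iter,seed If `n_iter > 0`, bootstrap spreads for bias and error
#'   are attached.
#' @return A list of class `enc_selfconsistency`: `bias`, `error`,
#'   `n_pairs`, and optional `bias_boot`/`error_boot`.
#' @export
self_consistency <- function(fwd, rev, n_iter = 0L, seed = 1L) {
  fwd <- as.numeric(fwd)
  rev <- as.numeric(rev)
  if (length(fwd) != length(rev)) stop("fwd and rev must have equal length")
  d <- fwd + rev
  out <- list(bias = mean(d) / sqrt(2),
              error = sqrt(mean(d^2)) / sqrt(2),
              n_pairs = length(d))
  if (n_iter > 0L) {
    out$bias_boot <- bootstrap(d / sqrt(2), "mean", n_iter, seed)
    rms <- .with_seed(seed + 1L, {
      vapply(seq_len(n_iter), function(it) {
        idx <- sample.int(length(d), length(d), replace = TRUE)
        sqrt(mean(d[idx]^2)) / sqrt(2)
      }, 0)
    })
    out$error_boot <- list(estimate = mean(rms), stderr = stats::sd(rms))
  }
  structure(out, class = "enc_selfconsistency")
}

#' @export
print.enc_selfconsistency <- function(x, ...) {
  cat("self-consistency over ", x$n_pairs, " pairs: bias ",
      format(x$bias, digits = 4), ", error ", format(x$error, digits = 4),
      "\n", sep = "")
  invisible(x)
}

# Through-origin rescaling of predictions onto the experimental scale.
.rescale_on <- function(pred, y) {
  k <- sum(pred * y) / sum(pred * pred)
  if (!is.finite(k)) k <- 0
  k * pred
}

# Minimum-norm least squares of y on the columns of X (SVD), flagging
# collinearity.
.svd_lsq <- function(X, y, tol = 1e-10) {
  s <- svd(X)
  pos <- s$d > tol * max(s$d)
  if (!all(pos))
    warning("collinear predictors: using minimum-norm combination")
  co <- s$v[, pos, drop = FALSE] %*%
    ((crossprod(s$u[, pos, drop = FALSE], y)) / s$d[pos])
  as.vector(co)
}

#' Linear combination of two mutation predictors
#'
#' Per bootstrap replicate: rescale the entropic-model predictions, the
#' partner predictions and a seeded reshuffled-random baseline onto the
#' experimental scale by their through-origin slopes, fit the two-parameter
#' combination `y ~ c1 p_encom + c2 p_other` by SVD least squares, and
#' record the RMSE difference of the combination against the random
#' baseline and the coefficient ratio `c1/c2` (the relative contribution of
#' the entropic model).
#'
#' @param pred_encom,pred_other,y_exp Aligned prediction and experiment
#'   vectors.
#' @param n_iter Number of bootstrap replicates.
#' @param seed RNG seed (drives both the reshuffled baseline and the
#'   bootstrap).
#' @return A list of class `enc_combination`: `coefficients` (full-sample
#'   fit), `delta_rmse` (bootstrapped mean RMSE difference combination -
#'   random; negative is better than random), `delta_rmse_sd`, `ratio`
#'   (bootstrapped mean |c1/c2|), `rmse_combined`, `rmse_random`.
#' @export
combine_models <- function(pred_encom, pred_other, y_exp,
                           n_iter = 1000L, seed = 1L) {
  pred_encom <- as.numeric(pred_encom)
  pred_other <- as.numeric(pred_other)
  y_exp <- as.numeric(y_exp)
  n <- length(y_exp)
  stopifnot(length(pred_encom) == n, length(pred_other) == n, n >= 3L)
  pred_rand <- .with_seed(seed, y_exp[sample.int(n, n)])

  fit_once <- function(idx) {
    y <- y_exp[idx]
    pe <- .rescale_on(pred_encom[idx], y)
    po <- .rescale_on(pred_other[idx], y)
    pr <- .rescale_on(pred_rand[idx], y)
    co <- suppressWarnings(.svd_lsq(cbind(pe, po), y))
    rc <- sqrt(mean((y - cbind(pe, po) %*% co)^2))
    rr <- sqrt(mean((y - pr)^2))
    c(co, rc, rr)
  }

  full <- fit_once(seq_len(n))
  reps <- .with_seed(seed + 1L, {
    vapply(seq_len(n_iter), function(it) {
      fit_once(sample.int(n, n, replace = TRUE))
    }, numeric(4L))
  })
  ratio <- abs(reps[1L, ]) / pmax(abs(reps[2L, ]), 1e-12)
  drmse <- reps[3L, ] - reps[4L, ]
  structure(list(coefficients = full[1:2],
                 delta_rmse = mean(drmse),
                 delta_rmse_sd = stats::sd(drmse),
                 ratio = mean(ratio),
                 ratio_sd = stats::sd(ratio),
                 rmse_combined = full[3L],
                 rmse_random = full[4L],
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "enc_combination")
}

#' @export
print.enc_combination <- function(x, ...) {
  cat("model combination: dRMSE vs random ",
      format(x$delta_rmse, digits = 4), " +/- ",
      format(x$delta_rmse_sd, digits = 3), ", contribution ratio ",
      format(x$ratio, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Grid search over the four force-constant weights
#'
#' Sparse exhaustive search over integer exponents: every combination of
#' `10^grid_log10` for the four alpha weights is scored on a benchmark
#' bundle (see [make_benchmark_bundle()]).  Stage 1 computes, per grid
#' point, the bootstrapped-median through-origin RMSE for the stabilizing
#' and destabilizing mutation tasks and ranks by the summed Z-scores (over
#' the grid population; lower RMSE is better).  The `keep_frac` best sets
#' advance to stage 2, where mean best-of-10 overlaps for domain and loop
#' tasks add their Z-scores; the final ranking maximizes the combined
#' Z-score.  At published scale the grid is 13^4 = 28561 combinations; the
#' grid here is caller-sized.
#'
#' @param bundle Benchmark bundle from [make_benchmark_bundle()].
#' @param grid_log10 Integer (or numeric) exponents searched for each
#'   alpha; the grid is their 4-fold Cartesian product.  Alternatively a
#'   4-column matrix of explicit log10 values.
#' @param seed RNG seed for the bootstraps.
#' @param keep_frac Fraction of stage-1 grid points advanced to the overlap
#'   stage (the published description is ambiguous between two values, so
#'   it is exposed as a parameter; default 0.25).
#' @param n_boot Bootstrap replicates per RMSE estimate.
#' @return A data frame of class `enc_search`, one row per grid point,
#'   sorted by final rank: log10 alphas, stage-1 RMSEs and Z-scores,
#'   stage-2 overlaps and Z-scores, total score and rank (NA for points
#'   eliminated at stage 1).
#' @export
parameter_search <- function(bundle, grid_log10 = -1:1, seed = 1L,
                             keep_frac = 0.25, n_boot = 200L) {
  stopifnot(inherits(bundle, "enc_bundle"))
  if (is.matrix(grid_log10)) {
    grid <- as.data.frame(grid_log10)
    names(grid) <- paste0("log_a", 1:4)
  } else {
    if (length(grid_log10) == 0L) stop("empty grid")
    grid <- expand.grid(log_a1 = grid_log10, log_a2 = grid_log10,
                        log_a3 = grid_log10, log_a4 = grid_log10)
  }
  ng <- nrow(grid)
  if (ng == 0L) stop("empty grid")

  score_point <- function(g) {
    alpha <- 10^as.numeric(g)
    params <- enc_params(bundle$model, alpha = alpha)
    sc <- vapply(bundle$mutation_tasks, function(task) {
      d_wt <- diagonalize(build_hessian(task$wt, params, task$wt_contacts),
                          params$model)
      d_mut <- diagonalize(build_hessian(task$mut, params,
                                         task$mut_contacts),
                           params$model)
      entropy_difference(d_mut, d_wt)
    }, 0)
    ddg <- vapply(bundle$mutation_tasks, function(t) t$ddg_exp, 0)
    cls <- classify_mutations(ddg)$class
    med_rmse <- function(sel) {
      if (sum(sel) < 2L || all(sc[sel] == 0)) return(NA_real_)
      bootstrap(cbind(sc[sel], ddg[sel]), "rmse_through_origin",
                n_iter = n_boot, seed = seed)$quantiles[["50%"]]
    }
    ovl <- vapply(bundle$overlap_tasks, function(task) {
      d <- diagonalize(build_hessian(task$start, params,
                                     task$start_contacts),
                       params$model)
      overlap(d, task$start, task$target)$best_overlap
    }, 0)
    kinds <- vapply(bundle$overlap_tasks, function(t) t$kind, "")
    c(rmse_stab = med_rmse(cls == "stabilizing"),
      rmse_destab = med_rmse(cls == "destabilizing"),
      overlap_domain = mean(ovl[kinds == "domain"]),
      overlap_loop = mean(ovl[kinds == "loop"]))
  }

  metrics <- t(vapply(seq_len(ng), function(i) score_point(grid[i, ]),
                      numeric(4L)))
  res <- cbind(grid, as.data.frame(metrics))

  zscore <- function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(v * 0)
    (v - mean(v, na.rm = TRUE)) / s
  }
  # lower RMSE is better: negate so that higher Z is better throughout
  res$z_rmse <- -(zscore(res$rmse_stab) + zscore(res$rmse_destab))
  n_keep <- max(1L, ceiling(keep_frac * ng))
  stage1_rank <- rank(-res$z_rmse, ties.method = "first")
  kept <- stage1_rank <= n_keep
  z_dom <- zscore(res$overlap_domain[kept])
  z_loop <- zscore(res$overlap_loop[kept])
  res$z_overlap <- NA_real_
  res$z_overlap[kept] <- z_dom + z_loop
  res$total_z <- ifelse(kept, res$z_rmse + res$z_overlap, NA_real_)
  res$rank <- NA_integer_
  res$rank[kept] <- rank(-res$total_z[kept], ties.method = "first")
  res <- res[order(res$rank, -res$z_rmse, na.last = TRUE), ]
  rownames(res) <- NULL
  class(res) <- c("enc_search", "data.frame")
  res
}
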