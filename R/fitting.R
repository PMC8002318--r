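#' Root mean square error
#'
#' `sqrt(mean((observed - predicted)^2))` over paired observations.
#'
#' @param observed,predicted Numeric vectors of equal nonzero length.
#' @return Scalar RMSE in the units of the inputs.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0) {
    stop("rmse requires two equal-length, nonempty vectors", call. = FALSE)
  }
  sqrt(mean((observed - predicted)^2))
}

#' Seeded train/test split
#'
#' Shuffles the runs with a seeded generator and assigns the first
#' `ceiling(train_fraction * n)` of each stratum to the training set. When
#' the table carries more than one `dataset_tag`, the split is stratified so
#' every tag keeps (as nearly as possible) its proportion in both subsets.
#' Deterministic for a fixed seed.
#'
#' @param table An [experiment_table()] with at least 5 runs.
#' @param train_fraction Fraction of runs assigned to training, in (0, 1).
#' @param seed Integer seed for the shuffle.
#' @return A list with `train` and `test` experiment tables.
#' @export
split_train_test <- function(table, train_fraction = 0.75, seed = 1) {
  if (nrow(table) < 5) {
    stop("insufficient data: need at least 5 runs to split", call. = FALSE)
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  tags <- unique(table$dataset_tag)
  train_idx <- integer(0)
  withr::with_seed(seed, {
    for (tag in tags) {
      idx <- which(table$dataset_tag == tag)
      idx <- idx[sample.int(length(idx))]
      n_train <- ceiling(train_fraction * length(idx))
      train_idx <- c(train_idx, idx[seq_len(n_train)])
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(table)), train_idx)
  list(train = experiment_table(table[train_idx, , drop = FALSE]),
       test = experiment_table(table[test_idx, , drop = FALSE]))
}

#' Seeded k-fold partition
#'
#' Shuffles `1..n` with the seeded generator and partitions the shuffled
#' indices into `k` disjoint validation folds whose sizes differ by at most
#' one (the first `n %% k` folds take the extra element).
#'
#' @param n Number of items.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed.
#' @return A list of `k` integer vectors partitioning `1..n`.
#' @export
kfold_indices <- function(n, k, seed = 1) {
  if (k < 2 || k > n) {
    stop("k must satisfy 2 <= k <= n", call. = FALSE)
  }
  perm <- withr::with_seed(seed, sample.int(n))
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  split(perm, rep(seq_len(k), times = sizes))
}

# ---- internal optimization machinery ----------------------------------------

# MRT objective in theta = (log b1, b2, b3); b4 = 1 + b2 - b3 by elimination,
# so the seconds constraint holds exactly at every iterate. Internally the
# mean *squared* error is minimized (same argmin as the RMSE, but smooth at
# a perfect fit); a quadratic penalty keeps the derived b4 inside the
# search bounds. Reported objective values are RMSEs.
mrt_objective <- function(theta, design, obs, bounds) {
  b2 <- theta[2]; b3 <- theta[3]
  b4 <- 1 + b2 - b3
  pred <- exp(theta[1] + (b2 - b3) * log(design$frv) + log(design$avail) -
                b4 * log(design$disp))
  pen <- 1e6 * (max(0, bounds[1] - b4)^2 + max(0, b4 - bounds[2])^2)
  mean((obs - pred)^2) + pen
}

mrt_gradient <- function(theta, design, obs, bounds) {
  b2 <- theta[2]; b3 <- theta[3]
  b4 <- 1 + b2 - b3
  l <- log(design$frv) - log(design$disp)
  pred <- exp(theta[1] + (b2 - b3) * log(design$frv) + log(design$avail) -
                b4 * log(design$disp))
  r <- obs - pred
  g1 <- mean(-2 * r * pred)
  g2 <- mean(-2 * r * pred * l)
  dpen <- 1e6 * 2 * (-max(0, bounds[1] - b4) + max(0, b4 - bounds[2]))
  c(g1, g2 + dpen, -g2 - dpen)
}

# One bounded quasi-Newton descent from a given start (PORT routines).
# Returns the optimum, start/end RMSE, and whether the run terminated with
# a convergence diagnostic (anything but an iteration/evaluation limit).
mrt_descent <- function(theta0, design, obs, bounds) {
  lower <- c(log(bounds[1]), bounds[1], bounds[1])
  upper <- c(log(bounds[2]), bounds[2], bounds[2])
  f0 <- mrt_objective(theta0, design, obs, bounds)
  fit <- stats::nlminb(theta0, mrt_objective, gradient = mrt_gradient,
                       design = design, obs = obs, bounds = bounds,
                       lower = lower, upper = upper,
                       control = list(iter.max = 500, eval.max = 1000))
  list(theta = fit$par, start_obj = sqrt(f0), end_obj = sqrt(fit$objective),
       convergence = !grepl("limit", fit$message))
}

params_from_theta <- function(theta, b5 = NA_real_, b6 = NA_real_) {
  b2 <- theta[2]; b3 <- theta[3]
  model_parameters(exp(theta[1]), b2, b3, 1 + b2 - b3, b5, b6)
}

new_rtd_fit <- function(metric, params, fold_rmse, train_rmse, seed,
                        n_multistarts, converged, trace, fitted = TRUE) {
  structure(list(metric = metric, params = params, fold_rmse = fold_rmse,
                 train_rmse = train_rmse, seed = seed,
                 n_multistarts = n_multistarts, converged = converged,
                 trace = trace, fitted = fitted),
            class = "rtd_fit")
}

#' @export
print.rtd_fit <- function(x, ...) {
  if (!x$fitted) {
    cat("RTD model fit (", x$metric, "): not fitted\n", sep = "")
    return(invisible(x))
  }
  cat("RTD model fit (", x$metric, ")\n", sep = "")
  print(x$params)
  cat("  training RMSE:", signif(x$train_rmse, 6), "\n")
  if (length(x$fold_rmse) > 0) {
    cat("  fold validation RMSE:", paste(signif(x$fold_rmse, 4), collapse = ", "), "\n")
  }
  cat("  seed:", x$seed, "| multistarts:", x$n_multistarts,
      "| converged:", x$converged, "\n")
  invisible(x)
}

#' Fit the mean-residence-time model
#'
#' Minimizes the RMSE between observed and predicted mean residence time
#' over `(b1, b2, b3)`, with `b4 = 1 + b2 - b3` eliminated so the seconds
#' constraint holds exactly by construction. The search is a bounded
#' quasi-Newton descent (`b1` on the log scale), restarted from
#' `n_multistarts` seeded initial points. Each start runs a k-fold
#' cross-validation chain: the optimum of one fold's training subset
#' warm-starts the next fold, validation RMSE is recorded on each held-out
#' fold, and the chain finishes with a descent on the full training set.
#' The chain with the least mean validation RMSE supplies the reported
#' parameters.
#'
#' Note that the mean-residence-time data constrain `b2` and `b3` only
#' through their difference (the prediction depends on `b2 - b3` once `b4`
#' is eliminated); the returned `b2`, `b3` are one point on that ridge, and
#' `b3` is pinned individually only by a subsequent variance fit with
#' `refit_shape = TRUE` (see [fit_variance()]).
#'
#' @param train An [experiment_table()] with `mrt_s` observed on every run.
#' @param k Number of cross-validation folds.
#' @param n_multistarts Number of seeded restarts.
#' @param seed Integer seed controlling starts and fold assignment.
#' @param bounds Length-2 search bounds applied to every parameter.
#' @return An object of class `rtd_fit` with elements `params`
#'   ([model_parameters()]), `fold_rmse`, `train_rmse`, `seed`,
#'   `n_multistarts`, `converged` and an objective `trace`.
#' @export
fit_mrt <- function(train, k = 5, n_multistarts = 8, seed = 1,
                    bounds = c(1e-3, 10)) {
  if (nrow(train) == 0 || any(is.na(train$mrt_s))) {
    stop("fit_mrt requires a nonempty table with mrt_s observed on every run",
         call. = FALSE)
  }
  n <- nrow(train)
  if (k > n) stop("k exceeds the number of training runs", call. = FALSE)
  design <- model_design(train)
  obs <- train$mrt_s
  folds <- kfold_indices(n, k, seed = seed + 1L)

  # seeded multistart draws: b1 log-uniform across its bounds, exponents
  # uniform over a plausible start window (the search bounds stay wider)
  exp_lo <- max(bounds[1], 0.1); exp_hi <- min(bounds[2], 2.5)
  starts <- withr::with_seed(seed, {
    t(replicate(n_multistarts, c(
      stats::runif(1, log(bounds[1]), log(bounds[2])),
      stats::runif(2, exp_lo, exp_hi)
    )))
  })

  best <- NULL
  for (m in seq_len(n_multistarts)) {
    theta <- starts[m, ]
    val_rmse <- numeric(k)
    trace <- vector("list", k + 1)
    codes <- logical(k + 1)
    for (j in seq_len(k)) {
      hold <- folds[[j]]
      res <- mrt_descent(theta, design[-hold, , drop = FALSE], obs[-hold], bounds)
      theta <- res$theta
      codes[j] <- res$convergence
      trace[[j]] <- c(start_obj = res$start_obj, end_obj = res$end_obj)
      p <- params_from_theta(theta)
      val_rmse[j] <- rmse(obs[hold],
                          predict_mrt_design(design[hold, , drop = FALSE], p))
    }
    res <- mrt_descent(theta, design, obs, bounds)
    codes[k + 1] <- res$convergence
    trace[[k + 1]] <- c(start_obj = res$start_obj, end_obj = res$end_obj)
    score <- mean(val_rmse)
    if (is.null(best) || score < best$score) {
      best <- list(score = score, theta = res$theta, val_rmse = val_rmse,
                   train_rmse = res$end_obj, codes = codes,
                   trace = do.call(rbind, trace))
    }
  }
  params <- params_from_theta(best$theta)
  new_rtd_fit("mrt_s", params, best$val_rmse, best$train_rmse, seed,
              n_multistarts, all(best$codes),
              as.data.frame(best$trace))
}

# Variance objective (mean squared error; same argmin as the RMSE). When
# shape is refit, theta = (log b5, b3) with d = b2 - b3 and b4 = 1 + d
# frozen at the MRT-fit values (so the MRT predictions are untouched) and
# b6 = b3 + b4; both constraints stay exact.
varnorm_objective <- function(theta, design, obs, d, b4, bounds,
                              denominator, form) {
  b5 <- exp(theta[1]); b3 <- theta[2]
  p <- list(b3 = b3, b4 = b4, b5 = b5, b6 = b3 + b4)
  pe <- predict_peclet_design(design, p, denominator)
  pred <- variance_from_peclet(pe, form = form)
  pen <- 1e6 * (max(0, bounds[1] - (b3 + b4))^2 + max(0, (b3 + b4) - bounds[2])^2)
  mean((obs - pred)^2) + pen
}

#' Fit the variance (Peclet-number) model
#'
#' Fits the normalized-variance model on runs where the normalized variance
#' was observed and a kneading section exists. By default the exponents
#' `b3`, `b4` are taken from the mean-residence-time fit, `b6 = b3 + b4` is
#' set exactly (the dimensionless constraint), and only the scale `b5` is
#' optimized. With `refit_shape = TRUE`, `b5` and `b3` are fitted jointly
#' while `b2 - b3` and `b4` are held at the mean-residence-time values — the
#' mean-residence-time predictions are unchanged, both constraints remain
#' exact, and the variance data pin down `b3` individually (`b2` is updated
#' to `b3 + (b2 - b3)`).
#'
#' If no usable variance observations exist, an unfitted result is returned
#' rather than an error.
#'
#' @param train An [experiment_table()].
#' @param mrt_fit The `rtd_fit` from [fit_mrt()] (or its
#'   [model_parameters()]).
#' @param refit_shape Jointly refit `b3` with `b5` (default `FALSE`).
#' @param n_multistarts Seeded restarts for the joint fit.
#' @param seed Integer seed.
#' @param bounds Length-2 search bounds.
#' @param denominator Mixing-factor denominator, see [predict_peclet()].
#' @param form Variance form, see [variance_from_peclet()].
#' @return An object of class `rtd_fit` (metric `"varnorm"`); `fitted` is
#'   `FALSE` when no variance observations were available.
#' @export
fit_variance <- function(train, mrt_fit, refit_shape = FALSE,
                         n_multistarts = 4, seed = 1, bounds = c(1e-3, 10),
                         denominator = c("per_block", "total"),
                         form = c("printed", "open_open")) {
  denominator <- match.arg(denominator)
  form <- match.arg(form)
  mp <- if (inherits(mrt_fit, "rtd_fit")) mrt_fit$params else mrt_fit
  usable <- !is.na(train$varnorm) & train$nk > 0 & train$sa_deg > 0
  if (!any(usable)) {
    return(new_rtd_fit("varnorm",
                       model_parameters(mp$b1, mp$b2, mp$b3, mp$b4),
                       numeric(0), NA_real_, seed, 0L, NA, NULL,
                       fitted = FALSE))
  }
  sub <- experiment_table(train[usable, , drop = FALSE])
  design <- model_design(sub)
  obs <- sub$varnorm
  d <- mp$b2 - mp$b3

  if (!refit_shape) {
    b3 <- mp$b3; b4 <- mp$b4; b6 <- b3 + b4
    obj1 <- function(lb5) {
      varnorm_objective(c(lb5, b3), design, obs, d, b4, bounds, denominator, form)
    }
    opt <- stats::optimize(obj1, interval = log(bounds), tol = 1e-12)
    params <- model_parameters(mp$b1, mp$b2, b3, b4, exp(opt$minimum), b6)
    trace <- data.frame(start_obj = sqrt(obj1(0)), end_obj = sqrt(opt$objective))
    return(new_rtd_fit("varnorm", params, numeric(0), sqrt(opt$objective), seed,
                       1L, TRUE, trace))
  }

  b4 <- mp$b4
  lower <- c(log(bounds[1]), bounds[1])
  upper <- c(log(bounds[2]), bounds[2])
  exp_lo <- max(bounds[1], 0.1); exp_hi <- min(bounds[2], 2.5)
  starts <- withr::with_seed(seed, {
    t(replicate(n_multistarts, c(stats::runif(1, log(bounds[1]), log(bounds[2])),
                                 stats::runif(1, exp_lo, exp_hi))))
  })
  b5_start <- if (is.null(mp$b5) || is.na(mp$b5)) 1 else min(bounds[2], max(bounds[1], mp$b5))
  starts <- rbind(c(log(b5_start), mp$b3), starts)
  best <- NULL
  codes <- logical(0)
  trace <- list()
  for (m in seq_len(nrow(starts))) {
    f0 <- varnorm_objective(starts[m, ], design, obs, d, b4, bounds,
                            denominator, form)
    fit <- stats::nlminb(starts[m, ], varnorm_objective, design = design,
                         obs = obs, d = d, b4 = b4, bounds = bounds,
                         denominator = denominator, form = form,
                         lower = lower, upper = upper,
                         control = list(iter.max = 500, eval.max = 1000))
    codes <- c(codes, !grepl("limit", fit$message))
    trace[[m]] <- c(start_obj = sqrt(f0), end_obj = sqrt(fit$objective))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  b5 <- exp(best$par[1]); b3 <- best$par[2]
  params <- model_parameters(mp$b1, b3 + d, b3, b4, b5, b3 + b4)
  new_rtd_fit("varnorm", params, numeric(0), sqrt(best$objective), seed,
              nrow(starts), all(codes),
              as.data.frame(do.call(rbind, trace)))
}

#' Evaluate fitted parameters on a held-out test set
#'
#' Predicts the mean residence time (and, when variance parameters are
#' supplied, the normalized variance) for each test run, and reports the
#' test RMSE, per-run parity records and the fraction of predictions inside
#' a confidence band around the observed value. Band membership uses closed
#' intervals: a prediction exactly at the band edge counts as in-band.
#' Default bands are ±1 s for the mean residence time and ±0.1 for the
#' normalized variance; long-residence-time equipment warrants a wider band
#' (e.g. ±20 s).
#'
#' @param test An [experiment_table()]; must be disjoint from the training
#'   runs (the caller's responsibility).
#' @param mrt_params [model_parameters()] for the mean residence time.
#' @param var_params Optional [model_parameters()] carrying b5/b6; `NULL`
#'   (or an unfitted variance result) skips the variance evaluation.
#' @param bands Named list of half-widths, `list(mrt_s = 1, varnorm = 0.1)`.
#' @param partition Label stored with the parity records.
#' @param denominator,form Passed to [predict_table()].
#' @return A list of class `rtd_evaluation`: `mrt_rmse`, `varnorm_rmse`,
#'   `parity` (data.frame: run_id, metric, observed, predicted, band,
#'   in_band, partition) and `in_band` (named fractions).
#' @export
evaluate_fit <- function(test, mrt_params, var_params = NULL,
                         bands = list(mrt_s = 1, varnorm = 0.1),
                         partition = "test",
                         denominator = c("per_block", "total"),
                         form = c("printed", "open_open")) {
  if (nrow(test) == 0) stop("empty test set", call. = FALSE)
  denominator <- match.arg(denominator)
  form <- match.arg(form)
  if (inherits(var_params, "rtd_fit")) {
    var_params <- if (var_params$fitted) var_params$params else NULL
  }
  if (inherits(mrt_params, "rtd_fit")) mrt_params <- mrt_params$params
  use_params <- if (!is.null(var_params) && !is.na(var_params$b5)) var_params else mrt_params
  pred <- predict_table(test, use_params, denominator = denominator, form = form)

  parity <- data.frame(run_id = test$run_id, metric = "mrt_s",
                       observed = test$mrt_s, predicted = pred$mrt_pred_s,
                       band = bands$mrt_s, stringsAsFactors = FALSE)
  if (!is.null(var_params) && any(!is.na(test$varnorm) & !is.na(pred$varnorm_pred))) {
    keep <- !is.na(test$varnorm) & !is.na(pred$varnorm_pred)
    parity <- rbind(parity, data.frame(
      run_id = test$run_id[keep], metric = "varnorm",
      observed = test$varnorm[keep], predicted = pred$varnorm_pred[keep],
      band = bands$varnorm, stringsAsFactors = FALSE))
  }
  parity$in_band <- abs(parity$observed - parity$predicted) <= parity$band
  parity$partition <- partition

  mrt_rows <- parity$metric == "mrt_s" & !is.na(parity$observed)
  var_rows <- parity$metric == "varnorm"
  out <- list(
    mrt_rmse = if (any(mrt_rows)) rmse(parity$observed[mrt_rows], parity$predicted[mrt_rows]) else NA_real_,
    varnorm_rmse = if (any(var_rows)) rmse(parity$observed[var_rows], parity$predicted[var_rows]) else NA_real_,
    parity = parity,
    in_band = c(mrt_s = if (any(mrt_rows)) mean(parity$in_band[mrt_rows]) else NA_real_,
                varnorm = if (any(var_rows)) mean(parity$in_band[var_rows]) else NA_real_)
  )
  class(out) <- "rtd_evaluation"
  out
}

#' @export
print.rtd_evaluation <- function(x, ...) {
  cat("RTD evaluation:\n")
  cat("  MRT RMSE:", signif(x$mrt_rmse, 6), "s | in band:",
      signif(x$in_band[["mrt_s"]], 4), "\n")
  if (!is.na(x$varnorm_rmse)) {
    cat("  varnorm RMSE:", signif(x$varnorm_rmse, 6), "| in band:",
        signif(x$in_band[["varnorm"]], 4), "\n")
  }
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' Writes parameters, constraint residuals, fold RMSEs, seed and options in
#' a fixed field order with full precision, so identical fits produce
#' byte-identical files.
#'
#' @param fit An `rtd_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  chk <- validate_constraints(fit$params)
  payload <- list(
    metric = fit$metric,
    fitted = fit$fitted,
    parameters = fit$params[c("b1", "b2", "b3", "b4", "b5", "b6")],
    constraint_residuals = list(r1 = chk$r1, r2 = chk$r2),
    fold_rmse = fit$fold_rmse,
    train_rmse = fit$train_rmse,
    seed = fit$seed,
    n_multistarts = fit$n_multistarts,
    converged = fit$converged
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a serialized fit result
#'
#' Inverse of [write_fit_json()] for the fields needed to reuse a fit:
#' returns an `rtd_fit` whose parameters round-trip exactly.
#'
#' @param path Path written by [write_fit_json()].
#' @return An `rtd_fit`.
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pars <- x$parameters
  params <- model_parameters(pars$b1, pars$b2, pars$b3, pars$b4,
                             ifelse(is.null(pars$b5), NA_real_, pars$b5),
                             ifelse(is.null(pars$b6), NA_real_, pars$b6),
                             tol = 1e-6)
  new_rtd_fit(x$metric, params, as.numeric(x$fold_rmse), x$train_rmse,
              x$seed, x$n_multistarts, x$converged, NULL,
              fitted = x$fitted)
}

#' Full split / fit / evaluate pipeline
#'
#' Convenience wrapper running the whole workflow: a seeded stratified
#' train/test split, the k-fold cross-validated mean-residence-time fit,
#' the variance fit (when variance observations exist), and evaluation on
#' the held-out test set. Fully deterministic for fixed inputs and seed.
#'
#' @param table An [experiment_table()].
#' @param train_fraction Training fraction for [split_train_test()].
#' @param k,n_multistarts,bounds Passed to [fit_mrt()].
#' @param refit_shape Passed to [fit_variance()].
#' @param bands Passed to [evaluate_fit()].
#' @param seed Integer seed for every random step.
#' @return A list of class `rtd_pipeline`: `mrt_fit`, `var_fit`,
#'   `evaluation`, `train_ids`, `test_ids`, `seed`.
#' @export
crossval_pipeline <- function(table, train_fraction = 0.75, k = 5,
                              n_multistarts = 8, refit_shape = FALSE,
                              bands = list(mrt_s = 1, varnorm = 0.1),
                              bounds = c(1e-3, 10), seed = 1) {
  split <- split_train_test(table, train_fraction = train_fraction, seed = seed)
  mrt_fit <- fit_mrt(split$train, k = k, n_multistarts = n_multistarts,
                     seed = seed, bounds = bounds)
  var_fit <- fit_variance(split$train, mrt_fit, refit_shape = refit_shape,
                          seed = seed, bounds = bounds)
  evaluation <- evaluate_fit(split$test, mrt_fit$params,
                             var_params = var_fit, bands = bands)
  structure(list(mrt_fit = mrt_fit, var_fit = var_fit,
                 evaluation = evaluation,
                 train_ids = split$train$run_id, test_ids = split$test$run_id,
                 seed = seed),
            class = "rtd_pipeline")
}

#' @export
print.rtd_pipeline <- function(x, ...) {
  cat("RTD pipeline (seed ", x$seed, "): ", length(x$train_ids), " train / ",
      length(x$test_ids), " test runs\n", sep = "")
  print(x$mrt_fit)
  if (x$var_fit$fitted) print(x$var_fit)
  print(x$evaluation)
  invisible(x)
}
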