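test_that("rmse matches hand arithmetic and is permutation invariant", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rmse(c(1, 5, 9), c(2, 4, 8)), rmse(c(9, 1, 5), c(8, 2, 4)))
  expect_error(rmse(1:3, 1:2), "equal-length")
})

test_that("train/test split is disjoint, seeded and stratified", {
  tab <- make_synthetic_table(n = 10, seed = 2)
  sp <- split_train_test(tab, train_fraction = 0.8, seed = 7)
  expect_identical(nrow(sp$train), 8L)
  expect_identical(nrow(sp$test), 2L)
  expect_length(intersect(sp$train$run_id, sp$test$run_id), 0)
  expect_setequal(c(sp$train$run_id, sp$test$run_id), tab$run_id)
  sp2 <- split_train_test(tab, train_fraction = 0.8, seed = 7)
  expect_identical(sp$train$run_id, sp2$train$run_id)
  # stratification: 40 A + 20 B at 0.75 -> 30 A + 15 B in training
  tab2 <- make_synthetic_table(n = 60, seed = 2)
  tab2$dataset_tag <- rep(c("A", "B"), c(40, 20))
  sp3 <- split_train_test(tab2, train_fraction = 0.75, seed = 1)
  expect_identical(as.vector(table(sp3$train$dataset_tag)[c("A", "B")]),
                   c(30L, 15L))
  expect_error(split_train_test(tab[1:3, ], seed = 1), "insufficient")
})

test_that("k-fold partition is balanced and exhaustive", {
  f <- kfold_indices(10, 5, seed = 3)
  expect_length(f, 5)
  expect_true(all(lengths(f) == 2))
  expect_setequal(unlist(f), 1:10)
  f2 <- kfold_indices(11, 5, seed = 3)
  expect_identical(unname(sort(lengths(f2), decreasing = TRUE)),
                   c(3L, 2L, 2L, 2L, 2L))
  expect_setequal(unlist(f2), 1:11)
  expect_error(kfold_indices(4, 5), "k must satisfy")
})

test_that("noise-free parameter recovery through the constrained fit", {
  truth <- kumar2015_truth()
  tab <- make_synthetic_table(n = 40, seed = 11, cv = 0)
  fit <- fit_mrt(tab, seed = 5)
  expect_lt(fit$train_rmse, 1e-6)
  # identifiable MRT quantities: scale b1, difference b2 - b3, and b4
  expect_equal(fit$params$b1, truth$b1, tolerance = 1e-6)
  expect_equal(fit$params$b2 - fit$params$b3, truth$b2 - truth$b3,
               tolerance = 1e-6)
  expect_equal(fit$params$b4, truth$b4, tolerance = 1e-6)
  # the seconds constraint holds exactly by construction
  expect_equal(validate_constraints(fit$params, tol = 1e-12)$r1, 0,
               tolerance = 1e-12)
  # the variance fit pins b3 (and hence b2, b5, b6) individually
  vfit <- fit_variance(tab, fit, refit_shape = TRUE, seed = 5)
  expect_equal(vfit$params$b5, truth$b5, tolerance = 1e-4)
  expect_equal(vfit$params$b3, truth$b3, tolerance = 1e-4)
  expect_identical(vfit$params$b6, vfit$params$b3 + vfit$params$b4)
})

test_that("default variance fit adjusts only the scale b5", {
  truth <- kumar2015_truth()
  tab <- make_synthetic_table(n = 30, seed = 13, cv = 0)
  fit <- fit_mrt(tab, seed = 4)
  vfit <- fit_variance(tab, fit, refit_shape = FALSE, seed = 4)
  expect_identical(vfit$params$b3, fit$params$b3)
  expect_identical(vfit$params$b4, fit$params$b4)
  expect_identical(vfit$params$b6, vfit$params$b3 + vfit$params$b4)
  expect_true(vfit$fitted)
})

test_that("variance fit reports not-fitted when variance is unobserved", {
  tab <- make_synthetic_table(n = 20, seed = 9)
  tab$varnorm <- NA_real_
  fit <- fit_mrt(tab, seed = 2)
  vfit <- fit_variance(tab, fit, seed = 2)
  expect_false(vfit$fitted)
  expect_true(is.na(vfit$params$b5))
})

test_that("optimizer beats a coarse grid-search oracle", {
  tab <- make_synthetic_table(n = 20, seed = 17, cv = 0.05)
  design <- tsgrtd:::model_design(tab)
  obs <- tab$mrt_s
  fit <- fit_mrt(tab, k = 4, n_multistarts = 4, seed = 3)
  # brute-force oracle: 5 points per parameter over the same bounds
  grid <- expand.grid(b1 = exp(seq(log(1e-3), log(10), length.out = 5)),
                      b2 = seq(0.1, 2.5, length.out = 5),
                      b3 = seq(0.1, 2.5, length.out = 5))
  grid_rmse <- vapply(seq_len(nrow(grid)), function(i) {
    p <- list(b1 = grid$b1[i], b2 = grid$b2[i], b3 = grid$b3[i],
              b4 = 1 + grid$b2[i] - grid$b3[i])
    rmse(obs, tsgrtd:::predict_mrt_design(design, p))
  }, numeric(1))
  expect_lte(fit$train_rmse, min(grid_rmse))
})

test_that("penalized-constraint optimization agrees with elimination", {
  tab <- make_synthetic_table(n = 20, seed = 19, cv = 0.03)
  design <- tsgrtd:::model_design(tab)
  obs <- tab$mrt_s
  fit <- fit_mrt(tab, k = 4, n_multistarts = 4, seed = 6)
  # oracle: optimize all four parameters with a heavy penalty on the
  # seconds-constraint residual instead of eliminating b4
  pen_obj <- function(th) {
    p <- list(b1 = exp(th[1]), b2 = th[2], b3 = th[3], b4 = th[4])
    r1 <- -p$b2 + p$b3 + p$b4 - 1
    mean((obs - tsgrtd:::predict_mrt_design(design, p))^2) + 1e8 * r1^2
  }
  best <- Inf
  set.seed(31)
  for (i in 1:6) {
    th0 <- c(runif(1, log(0.01), log(5)), runif(3, 0.1, 2.5))
    o <- nlminb(th0, pen_obj, lower = c(log(1e-3), 1e-3, 1e-3, 1e-3),
                upper = c(log(10), 10, 10, 10))
    if (o$objective < best) { best <- o$objective; th_best <- o$par }
  }
  p_pen <- list(b1 = exp(th_best[1]), b2 = th_best[2], b3 = th_best[3],
                b4 = th_best[4])
  rmse_pen <- rmse(obs, tsgrtd:::predict_mrt_design(design, p_pen))
  expect_equal(fit$train_rmse, rmse_pen, tolerance = 1e-3)
  expect_equal(fit$params$b1, p_pen$b1, tolerance = 0.01)
  expect_equal(fit$params$b2 - fit$params$b3, p_pen$b2 - p_pen$b3,
               tolerance = 0.01)
})

test_that("accepted descents never increase the objective", {
  tab <- make_synthetic_table(n = 30, seed = 23, cv = 0.05)
  fit <- fit_mrt(tab, seed = 8)
  expect_true(all(fit$trace$end_obj <= fit$trace$start_obj + 1e-12))
})

test_that("fitting is deterministic for a fixed seed", {
  tab <- make_synthetic_table(n = 30, seed = 29, cv = 0.05)
  f1 <- fit_mrt(tab, seed = 12)
  f2 <- fit_mrt(tab, seed = 12)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$fold_rmse, f2$fold_rmse)
  f3 <- fit_mrt(tab, seed = 13)
  expect_false(identical(f3$params, f1$params))
})

test_that("evaluation bands use closed intervals and report parity records", {
  tab <- make_synthetic_table(n = 12, seed = 31, cv = 0)
  truth <- kumar2015_truth()
  ev <- evaluate_fit(tab, truth, var_params = truth)
  expect_equal(ev$mrt_rmse, 0, tolerance = 1e-12)
  expect_equal(unname(ev$in_band["mrt_s"]), 1)
  expect_equal(unname(ev$in_band["varnorm"]), 1)
  # offset exactly by the band half-width: boundary counts as in-band
  tab2 <- tab
  tab2$mrt_s <- tab$mrt_s + 1
  ev2 <- evaluate_fit(experiment_table(tab2), truth,
                      bands = list(mrt_s = 1, varnorm = 0.1))
  expect_equal(unname(ev2$in_band["mrt_s"]), 1)
  tab3 <- tab
  tab3$mrt_s <- tab$mrt_s + 2
  ev3 <- evaluate_fit(experiment_table(tab3), truth,
                      bands = list(mrt_s = 1, varnorm = 0.1))
  expect_equal(unname(ev3$in_band["mrt_s"]), 0)
  expect_error(evaluate_fit(tab[0, ], truth), "empty test set")
})

test_that("fit results round-trip through the JSON writer", {
  tab <- make_synthetic_table(n = 24, seed = 37, cv = 0.05)
  fit <- fit_mrt(tab, k = 4, n_multistarts = 4, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- read_fit_json(path)
  expect_equal(back$params$b1, fit$params$b1, tolerance = 1e-12)
  expect_equal(back$params$b4, fit$params$b4, tolerance = 1e-12)
  expect_equal(back$fold_rmse, fit$fold_rmse, tolerance = 1e-12)
  expect_equal(back$seed, fit$seed)
})
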