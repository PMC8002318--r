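test_that("net volumetric feed rate combines powder and liquid streams", {
  cond <- process_condition(10, 600, 0.115, 600, 1000)
  # hand arithmetic: (10/600 + 10*0.115/1000) kg-basis m3/h, over 3600 s/h
  expect_equal(net_volumetric_feed_rate(cond),
               (10 / 600 + 10 * 0.115 / 1000) / 3600, tolerance = 1e-12)
  expect_equal(net_volumetric_feed_rate(cond), 4.949074e-6, tolerance = 1e-6)
  dry <- process_condition(10, 600, 0, 600, 1000)
  expect_equal(net_volumetric_feed_rate(dry), 10 / 600 / 3600)
  doubled <- process_condition(20, 600, 0.115, 600, 1000)
  expect_equal(net_volumetric_feed_rate(doubled), 2 * net_volumetric_feed_rate(cond))
})

test_that("surrogate factors reduce correctly and match a log-domain oracle", {
  expect_equal(holdup_factor(2, 3, 0), 3)
  expect_equal(holdup_factor(2, 3, 1), 6)
  expect_equal(flow_factor(2, 3, 0, 0), 1)
  expect_equal(flow_factor(2, 3, 1, 1), 6)
  expect_equal(mixing_factor(180, 1, 0, 1, 1), pi)
  expect_equal(mixing_factor(60, 2, 1, 4, 2), 2 * mixing_factor(60, 2, 1, 2, 2))
  expect_equal(mixing_factor(60, 2, 1, 2, 4), mixing_factor(60, 2, 1, 2, 2) / 2)
  # log-domain oracle across a grid of inputs
  set.seed(42)
  for (i in 1:20) {
    frv <- 10^runif(1, -7, -4); disp <- 10^runif(1, -6, -3)
    avail <- 10^runif(1, -6, -3); b <- runif(4, 0.1, 2)
    expect_equal(holdup_factor(frv, avail, b[1]),
                 exp(b[1] * log(frv) + log(avail)), tolerance = 1e-12)
    expect_equal(flow_factor(frv, disp, b[2], b[3]),
                 exp(b[2] * log(frv) + b[3] * log(disp)), tolerance = 1e-12)
    expect_equal(mixing_factor(60, disp, b[4], 3, 2),
                 exp(log(60) + b[4] * log(disp) + log(3) + log(pi) -
                       log(2) - log(180)), tolerance = 1e-12)
  }
})

test_that("constraint residuals and published parameter sets", {
  p <- model_parameters(1, 0, 0, 1, 1, 1)
  chk <- validate_constraints(p)
  expect_equal(chk$r1, 0)
  expect_equal(chk$r2, 0)
  expect_true(chk$pass)
  # pooled-fit column closes both constraints exactly at printed precision
  pooled <- list(b1 = 0.46, b2 = 1.24, b3 = 1.09, b4 = 1.15, b5 = 2.29, b6 = 2.24)
  chk <- validate_constraints(pooled, tol = 1e-9)
  expect_equal(chk$r1, 0, tolerance = 1e-12)
  expect_equal(chk$r2, 0, tolerance = 1e-12)
  # constructing parameters that break the seconds constraint fails
  expect_error(model_parameters(1, 1, 1, 2), "constraint violation")
})

test_that("MRT prediction follows the holdup-over-flow form", {
  geom <- default_geom(); cfg <- default_config(); cond <- default_cond()
  p <- kumar2015_truth()
  mrt <- predict_mrt(cond, geom, cfg, p)
  frv <- net_volumetric_feed_rate(cond)
  expect_equal(mrt, p$b1 * holdup_factor(frv, total_available_volume(geom, cfg), p$b2) /
                 flow_factor(frv, displacement_rate(geom, cond$rpm), p$b3, p$b4))
  # linear in the scale constant
  p2 <- model_parameters(2 * p$b1, p$b2, p$b3, p$b4)
  expect_equal(predict_mrt(cond, geom, cfg, p2), 2 * mrt)
  # faster screws shorten the residence time (b4 > 0)
  slow <- process_condition(10, 500, 0.115, 600, 1000)
  fast <- process_condition(10, 900, 0.115, 600, 1000)
  expect_gt(predict_mrt(slow, geom, cfg, p), predict_mrt(fast, geom, cfg, p))
})

test_that("predictions are invariant to volume-unit rescaling when constraints hold", {
  cfg <- default_config(); p <- kumar2015_truth()
  for (scale in c(1e1, 1e3)) {
    # lengths x s scales volumes by s^3; densities / s^3 scales frv by s^3
    geom_a <- default_geom()
    geom_b <- screw_geometry(0.0125 * scale, 0.00625 * scale, 0.025 * scale,
                             0.3 * scale, 0.001 * scale)
    s3 <- scale^3
    cond_a <- default_cond()
    cond_b <- process_condition(10, 600, 0.115, 600 / s3, 1000 / s3)
    expect_equal(predict_mrt(cond_b, geom_b, cfg, p),
                 predict_mrt(cond_a, geom_a, cfg, p), tolerance = 1e-10)
    expect_equal(predict_peclet(cond_b, geom_b, cfg, p),
                 predict_peclet(cond_a, geom_a, cfg, p), tolerance = 1e-10)
  }
})

test_that("sign of the MRT partial derivatives matches finite differences", {
  cfg <- default_config(); p <- kumar2015_truth()
  geom <- default_geom()
  base <- predict_mrt(default_cond(), geom, cfg, p)
  # analytic: d log MRT / d log avail = +1
  geom_big <- screw_geometry(0.0125, 0.00625, 0.025, 0.33, 0.001)
  expect_gt(predict_mrt(default_cond(), geom_big, cfg, p), base)
  # analytic: d log MRT / d log FR carries the sign of (b2 - b3) > 0 here
  more_feed <- process_condition(11, 600, 0.115, 600, 1000)
  fd_sign <- sign(predict_mrt(more_feed, geom, cfg, p) - base)
  expect_identical(fd_sign, sign(p$b2 - p$b3))
})

test_that("Peclet responds to stagger angle and scales with b5", {
  geom <- default_geom(); cond <- default_cond(); p <- kumar2015_truth()
  pe60 <- predict_peclet(cond, geom, default_config(), p)
  pe90 <- predict_peclet(cond, geom, screw_configuration(6, 3, 2, 90), p)
  expect_gt(pe60, pe90)  # wider stagger -> more local mixing -> lower Pe
  expect_gt(variance_from_peclet(pe90), variance_from_peclet(pe60))
  p2 <- model_parameters(p$b1, p$b2, p$b3, p$b4, 2 * p$b5, p$b6)
  expect_equal(predict_peclet(cond, geom, default_config(), p2), 2 * pe60)
  # more elements per block -> weaker mixing -> higher Pe -> lower variance
  pe_npb4 <- predict_peclet(cond, geom, screw_configuration(8, 2, 4, 60), p)
  pe_npb2 <- predict_peclet(cond, geom, screw_configuration(8, 4, 2, 60), p)
  expect_gt(pe_npb4, pe_npb2)
  # no kneading section: the variance model is undefined
  expect_error(predict_peclet(cond, geom, screw_configuration(0, 0, 0, 0), p),
               "undefined mixing")
})

test_that("variance-from-Peclet formula and its limits", {
  expect_equal(variance_from_peclet(2), 1.5)
  expect_lt(variance_from_peclet(1e9), 1e-8)
  # strictly decreasing on a log-spaced grid
  grid <- 10^seq(-2, 4, length.out = 50)
  v <- variance_from_peclet(grid)
  expect_true(all(diff(v) < 0))
  # classical open-open form differs but shares the limits
  v2 <- variance_from_peclet(grid, form = "open_open")
  expect_true(all(diff(v2) < 0))
  expect_equal(variance_from_peclet(2, form = "open_open"), 1 + 2)
  expect_error(variance_from_peclet(-1), "domain")
})

test_that("table predictions agree with the scalar interface", {
  tab <- make_synthetic_table(n = 8, seed = 3)
  p <- kumar2015_truth()
  pred <- predict_table(tab, p)
  for (i in c(1, 4, 8)) {
    row <- tab[i, ]
    geom <- screw_geometry(row$screw_radius_mm / 1000, row$knead_thickness_mm / 1000,
                           row$lead_mm / 1000, row$convey_len_mm / 1000,
                           row$fe_disc_mm / 1000)
    cfg <- screw_configuration(row$nk, row$kb, row$nk_per_block, row$sa_deg)
    cond <- process_condition(row$fr_kg_h, row$rpm, row$ls_pct / 100,
                              row$powder_density_kg_m3, row$liquid_density_kg_m3)
    expect_equal(pred$mrt_pred_s[i], predict_mrt(cond, geom, cfg, p))
    expect_equal(pred$pe_pred[i], predict_peclet(cond, geom, cfg, p))
    expect_equal(pred$varnorm_pred[i], variance_from_peclet(pred$pe_pred[i]))
  }
})
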