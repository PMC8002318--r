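#' Operating point of a granulation run
#'
#' One steady-state operating condition: powder feed rate, screw speed, the
#' liquid-to-solid mass ratio, and the densities used to convert mass feed
#' rates to volumetric ones. The bulk density of the loose powder is the
#' intended `powder_density_kg_m3` (conveying of un-compacted powder is
#' governed by bulk density); a true density can be supplied instead if a
#' study calls for it.
#'
#' @param fr_kg_h Powder mass feed rate (kg/h).
#' @param rpm Screw speed (revolutions per minute).
#' @param ls_ratio Liquid-to-solid mass ratio (liquid mass feed rate divided
#'   by powder mass feed rate; LS% / 100). Non-negative, sanity-bounded
#'   below 2.
#' @param powder_density_kg_m3 Powder (bulk) density (kg/m^3).
#' @param liquid_density_kg_m3 Granulation-liquid density (kg/m^3).
#' @return An object of class `process_condition`.
#' @export
process_condition <- function(fr_kg_h, rpm, ls_ratio,
                              powder_density_kg_m3, liquid_density_kg_m3 = 1000) {
  pos <- c(fr_kg_h = fr_kg_h, rpm = rpm,
           powder_density_kg_m3 = powder_density_kg_m3,
           liquid_density_kg_m3 = liquid_density_kg_m3)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("invalid condition: feed rate, rpm and densities must be finite and > 0",
         call. = FALSE)
  }
  if (!is.finite(ls_ratio) || ls_ratio < 0 || ls_ratio >= 2) {
    stop("invalid condition: ls_ratio must be in [0, 2)", call. = FALSE)
  }
  structure(list(fr_kg_h = fr_kg_h, rpm = rpm, ls_ratio = ls_ratio,
                 powder_density_kg_m3 = powder_density_kg_m3,
                 liquid_density_kg_m3 = liquid_density_kg_m3),
            class = "process_condition")
}

#' Model tuning constants
#'
#' The residence-time model carries six tuning constants: a scale `b1` and
#' exponents `b2`, `b3`, `b4` for the mean residence time, and a scale `b5`
#' with exponent `b6` for the Peclet number. Dimensional consistency imposes
#' two constraints: `-b2 + b3 + b4 = 1` (so the predicted mean residence
#' time is in seconds) and `b3 + b4 = b6` (so the Peclet number is
#' dimensionless). `b5` and `b6` may be `NA` when only the mean residence
#' time is modeled.
#'
#' @param b1,b2,b3,b4 Mean-residence-time scale and exponents.
#' @param b5,b6 Peclet-number scale and exponent (`NA` if not fitted).
#' @param tol Constraint tolerance; use the default `1e-9` for internally
#'   produced parameters and `0.015` when validating externally supplied
#'   values printed at two decimals.
#' @return An object of class `model_parameters`.
#' @examples
#' model_parameters(0.33, 0.99, 0.65, 1.33, 5.35, 1.99, tol = 0.015)
#' @export
model_parameters <- function(b1, b2, b3, b4, b5 = NA_real_, b6 = NA_real_,
                             tol = 1e-9) {
  core <- c(b1 = b1, b2 = b2, b3 = b3, b4 = b4)
  if (any(!is.finite(core))) {
    stop("invalid parameters: b1..b4 must be finite", call. = FALSE)
  }
  if (is.na(b5) != is.na(b6)) {
    stop("invalid parameters: b5 and b6 must be supplied together", call. = FALSE)
  }
  p <- structure(list(b1 = b1, b2 = b2, b3 = b3, b4 = b4, b5 = b5, b6 = b6),
                 class = "model_parameters")
  chk <- validate_constraints(p, tol = tol)
  if (!chk$pass) {
    stop(sprintf("constraint violation: residuals r1 = %.3g (want -b2+b3+b4 = 1), r2 = %.3g (want b3+b4 = b6) exceed tol %.3g",
                 chk$r1, ifelse(is.na(chk$r2), 0, chk$r2), tol), call. = FALSE)
  }
  p
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Model parameters: b1 =", x$b1, "b2 =", x$b2, "b3 =", x$b3, "b4 =", x$b4)
  if (!is.na(x$b5)) cat(" b5 =", x$b5, "b6 =", x$b6)
  cat("\n")
  invisible(x)
}

#' Check the dimensional-consistency constraints
#'
#' Computes the residuals of the two exponent constraints,
#' `r1 = -b2 + b3 + b4 - 1` (seconds constraint on the mean residence time)
#' and `r2 = b3 + b4 - b6` (dimensionless constraint on the Peclet number),
#' and reports whether both are within tolerance. `r2` is `NA`, and not
#' counted against the check, when `b6` is absent.
#'
#' @param params A `model_parameters` object or a list with fields b1..b6.
#' @param tol Tolerance on the absolute residuals.
#' @return A list with `r1`, `r2`, and logical `pass`.
#' @export
validate_constraints <- function(params, tol = 1e-9) {
  r1 <- -params$b2 + params$b3 + params$b4 - 1
  r2 <- if (is.null(params$b6) || is.na(params$b6)) NA_real_ else params$b3 + params$b4 - params$b6
  pass <- abs(r1) <= tol && (is.na(r2) || abs(r2) <= tol)
  list(r1 = r1, r2 = r2, pass = pass)
}

#' Net volumetric material feed rate
#'
#' Converts the powder mass feed rate (kg/h) and the liquid-to-solid ratio
#' to a total volumetric feed rate in m^3/s:
#' powder volume flow plus liquid volume flow, where the liquid mass rate is
#' the powder mass rate times the liquid-to-solid ratio.
#'
#' @param cond A [process_condition()].
#' @return Volumetric feed rate (m^3/s), strictly positive.
#' @export
net_volumetric_feed_rate <- function(cond) {
  stopifnot(inherits(cond, "process_condition"))
  fr_kg_s <- cond$fr_kg_h / 3600
  fr_kg_s / cond$powder_density_kg_m3 +
    fr_kg_s * cond$ls_ratio / cond$liquid_density_kg_m3
}

#' Surrogate holdup factor
#'
#' `frv^b2 * avail_total`: the reduced-order expression standing in for the
#' material holdup, combining the net volumetric feed rate and the total
#' available screw volume.
#'
#' @param frv Net volumetric feed rate (m^3/s), > 0.
#' @param avail_total Total available volume (m^3), > 0.
#' @param b2 Holdup exponent.
#' @return Surrogate holdup quantity.
#' @export
holdup_factor <- function(frv, avail_total, b2) {
  if (any(frv <= 0) || any(avail_total <= 0)) {
    stop("holdup factor requires frv > 0 and avail_total > 0", call. = FALSE)
  }
  frv^b2 * avail_total
}

#' Surrogate flow factor
#'
#' `frv^b3 * disp_rate^b4`: the reduced-order expression for convective
#' axial transport, combining the net volumetric feed rate and the
#' conveying-screw displacement rate.
#'
#' @param frv Net volumetric feed rate (m^3/s), > 0.
#' @param disp_rate Displacement rate (m^3/s), > 0.
#' @param b3,b4 Flow exponents.
#' @return Surrogate flow quantity.
#' @export
flow_factor <- function(frv, disp_rate, b3, b4) {
  if (any(frv <= 0) || any(disp_rate <= 0)) {
    stop("flow factor requires frv > 0 and disp_rate > 0", call. = FALSE)
  }
  frv^b3 * disp_rate^b4
}

#' Surrogate mixing factor
#'
#' `sa_deg * disp_rate^b6 * kb * pi / (nk_per_block * 180)`: the
#' reduced-order expression for local axial mixing in the kneading section.
#' Local mixing strengthens with the stagger angle and weakens with the
#' number of kneading elements per block.
#'
#' @param sa_deg Stagger angle (degrees), > 0.
#' @param disp_rate Displacement rate (m^3/s), > 0.
#' @param b6 Mixing exponent.
#' @param kb Number of kneading blocks, >= 1.
#' @param nk_per_block Kneading elements per block, >= 1.
#' @return Surrogate mixing quantity.
#' @export
mixing_factor <- function(sa_deg, disp_rate, b6, kb, nk_per_block) {
  if (any(nk_per_block <= 0)) {
    stop("invalid configuration: nk_per_block must be >= 1 for the mixing factor",
         call. = FALSE)
  }
  if (any(sa_deg <= 0) || any(disp_rate <= 0) || any(kb <= 0)) {
    stop("mixing factor requires sa_deg > 0, disp_rate > 0 and kb >= 1", call. = FALSE)
  }
  sa_deg * disp_rate^b6 * kb * pi / (nk_per_block * 180)
}

#' Predicted mean residence time
#'
#' The semi-mechanistic mean residence time,
#' `b1 * holdup / flow = b1 * frv^(b2 - b3) * avail_total * disp^(-b4)`,
#' in seconds. Requires the seconds constraint `-b2 + b3 + b4 = 1` to hold
#' within `tol`; when it does, the prediction is invariant to a common
#' rescaling of all volumetric quantities.
#'
#' @param cond A [process_condition()].
#' @param geom A [screw_geometry()].
#' @param config A [screw_configuration()].
#' @param params A [model_parameters()].
#' @param tol Constraint tolerance.
#' @return Mean residence time (s), strictly positive.
#' @export
predict_mrt <- function(cond, geom, config, params, tol = 1e-9) {
  chk <- validate_constraints(params, tol = tol)
  if (abs(chk$r1) > tol) {
    stop(sprintf("constraint violation: -b2+b3+b4 - 1 = %.3g exceeds tol %.3g", chk$r1, tol),
         call. = FALSE)
  }
  frv <- net_volumetric_feed_rate(cond)
  avail <- total_available_volume(geom, config)
  disp <- displacement_rate(geom, cond$rpm)
  params$b1 * holdup_factor(frv, avail, params$b2) /
    flow_factor(frv, disp, params$b3, params$b4)
}

#' Predicted Peclet number
#'
#' The semi-mechanistic Peclet number, `b5 * flow / mixing`, characterizing
#' the ratio of convective to dispersive axial transport. Requires the
#' dimensionless constraint `b3 + b4 = b6` within `tol` and a kneading
#' section (the mixing factor is undefined without one). The mixing-factor
#' denominator uses the number of kneading elements per block by default;
#' `denominator = "total"` divides by the total element count instead.
#'
#' @inheritParams predict_mrt
#' @param denominator Either `"per_block"` (default) or `"total"`.
#' @return Peclet number (dimensionless), strictly positive.
#' @export
predict_peclet <- function(cond, geom, config, params,
                           denominator = c("per_block", "total"), tol = 1e-9) {
  denominator <- match.arg(denominator)
  if (is.na(params$b5) || is.na(params$b6)) {
    stop("Peclet prediction requires b5 and b6", call. = FALSE)
  }
  chk <- validate_constraints(params, tol = tol)
  if (is.na(chk$r2) || abs(chk$r2) > tol) {
    stop(sprintf("constraint violation: b3+b4-b6 = %.3g exceeds tol %.3g", chk$r2, tol),
         call. = FALSE)
  }
  if (config$n_kneading == 0 || config$stagger_deg <= 0) {
    stop("undefined mixing: the variance model requires a kneading section (NK > 0, SA > 0)",
         call. = FALSE)
  }
  frv <- net_volumetric_feed_rate(cond)
  disp <- displacement_rate(geom, cond$rpm)
  nk_den <- if (denominator == "per_block") config$n_per_block else config$n_kneading
  params$b5 * flow_factor(frv, disp, params$b3, params$b4) /
    mixing_factor(config$stagger_deg, disp, params$b6, config$n_blocks, nk_den)
}

#' Normalized RTD variance from the Peclet number
#'
#' Maps a Peclet number to the normalized (dimensionless) variance of the
#' residence time distribution under the open-open dispersion boundary
#' condition. The default form is `2/Pe + 8/(Pe + 2)^2`; the classical
#' open-open relation `2/Pe + 8/Pe^2` is available for comparison via
#' `form = "open_open"`. Both are strictly decreasing in Pe and vanish in
#' the plug-flow limit.
#'
#' @param pe Peclet number(s), > 0.
#' @param form `"printed"` (default) or `"open_open"`.
#' @return Normalized variance (dimensionless).
#' @export
variance_from_peclet <- function(pe, form = c("printed", "open_open")) {
  form <- match.arg(form)
  if (any(!is.finite(pe)) || any(pe <= 0)) {
    stop("domain error: Peclet number must be finite and > 0", call. = FALSE)
  }
  if (form == "printed") 2 / pe + 8 / (pe + 2)^2 else 2 / pe + 8 / pe^2
}

# ---- vectorized table interface ---------------------------------------------

# Precompute per-row model inputs (feed rate, volumes, displacement rate) from
# an experiment table. Returns a data.frame; used by prediction and fitting.
model_design <- function(table) {
  n <- nrow(table)
  frv <- avail <- disp <- numeric(n)
  for (i in seq_len(n)) {
    row <- table[i, ]
    geom <- screw_geometry(row$screw_radius_mm / 1000,
                           row$knead_thickness_mm / 1000,
                           row$lead_mm / 1000,
                           row$convey_len_mm / 1000,
                           row$fe_disc_mm / 1000)
    config <- screw_configuration(row$nk, row$kb, row$nk_per_block, row$sa_deg)
    cond <- process_condition(row$fr_kg_h, row$rpm, row$ls_pct / 100,
                              row$powder_density_kg_m3, row$liquid_density_kg_m3)
    frv[i] <- net_volumetric_feed_rate(cond)
    avail[i] <- total_available_volume(geom, config)
    disp[i] <- displacement_rate(geom, row$rpm)
  }
  data.frame(frv = frv, avail = avail, disp = disp,
             sa_deg = table$sa_deg, kb = table$kb,
             nk_per_block = table$nk_per_block, nk = table$nk)
}

# MRT predictions from a precomputed design; b4 is taken from params as-is.
predict_mrt_design <- function(design, params) {
  params$b1 * design$frv^(params$b2 - params$b3) * design$avail *
    design$disp^(-params$b4)
}

# Peclet predictions from a precomputed design; rows without a kneading
# section get NA.
predict_peclet_design <- function(design, params,
                                  denominator = c("per_block", "total")) {
  denominator <- match.arg(denominator)
  nk_den <- if (denominator == "per_block") design$nk_per_block else design$nk
  pe <- rep(NA_real_, nrow(design))
  ok <- design$nk > 0 & design$sa_deg > 0
  pe[ok] <- params$b5 * design$frv[ok]^params$b3 *
    design$disp[ok]^(params$b4 - params$b6) * nk_den[ok] * 180 /
    (design$sa_deg[ok] * design$kb[ok] * pi)
  pe
}

#' Predict residence-time moments for a table of runs
#'
#' Evaluates the mean residence time, Peclet number and normalized variance
#' for every run in an experiment table. Runs without a kneading section get
#' `NA` for the Peclet number and variance (the mixing factor is undefined
#' there).
#'
#' @param table An [experiment_table()] (observed-response columns are not
#'   required).
#' @param params A [model_parameters()]; b5/b6 may be `NA`, in which case
#'   only the mean residence time is predicted.
#' @param denominator Mixing-factor denominator, see [predict_peclet()].
#' @param form Variance form, see [variance_from_peclet()].
#' @param tol Constraint tolerance.
#' @return A data.frame with `run_id`, `mrt_pred_s`, `pe_pred`,
#'   `varnorm_pred`.
#' @export
predict_table <- function(table, params, denominator = c("per_block", "total"),
                          form = c("printed", "open_open"), tol = 1e-9) {
  denominator <- match.arg(denominator)
  form <- match.arg(form)
  chk <- validate_constraints(params, tol = tol)
  if (abs(chk$r1) > tol) {
    stop("constraint violation: -b2+b3+b4 must equal 1 for MRT prediction", call. = FALSE)
  }
  design <- model_design(table)
  mrt <- predict_mrt_design(design, params)
  if (!is.na(params$b5)) {
    if (is.na(chk$r2) || abs(chk$r2) > tol) {
      stop("constraint violation: b3+b4 must equal b6 for Peclet prediction", call. = FALSE)
    }
    pe <- predict_peclet_design(design, params, denominator)
    varnorm <- rep(NA_real_, length(pe))
    varnorm[!is.na(pe)] <- variance_from_peclet(pe[!is.na(pe)], form = form)
  } else {
    pe <- rep(NA_real_, nrow(table))
    varnorm <- pe
  }
  data.frame(run_id = table$run_id, mrt_pred_s = mrt, pe_pred = pe,
             varnorm_pred = varnorm)
}
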