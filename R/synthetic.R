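#' Geometry presets for synthetic datasets
#'
#' Plausible default screw dimensions for two equipment classes: a 25 mm
#' pilot-scale granulator (`"consigma25"`: 12.5 mm screw radius, element
#' thickness half the radius, lead equal to the screw diameter, 300 mm of
#' conveying length) and a small lab-scale extruder (`"threetec"`: 6 mm
#' radius, 150 mm conveying length). These are stated defaults for synthetic
#' studies, not measured dimensions of any particular machine; every value
#' can be overridden by editing the returned row.
#'
#' @param label `"consigma25"` or `"threetec"`.
#' @return A one-row data.frame of geometry and density columns in the
#'   canonical schema units (mm, kg/m^3).
#' @export
geometry_preset <- function(label = c("consigma25", "threetec")) {
  label <- match.arg(label)
  if (label == "consigma25") {
    data.frame(screw_radius_mm = 12.5, knead_thickness_mm = 6.25,
               lead_mm = 25, convey_len_mm = 300, fe_disc_mm = 1,
               powder_density_kg_m3 = 600, liquid_density_kg_m3 = 1000)
  } else {
    data.frame(screw_radius_mm = 6, knead_thickness_mm = 3,
               lead_mm = 12, convey_len_mm = 150, fe_disc_mm = 1,
               powder_density_kg_m3 = 320, liquid_density_kg_m3 = 1000)
  }
}

#' Specification of a synthetic designed experiment
#'
#' Describes how to generate a design table: per-factor levels (for the
#' full-factorial design) or ranges (for random-uniform sampling) of powder
#' feed rate, screw speed, liquid-to-solid percentage, kneading element
#' count and stagger angle, the geometry preset, the number of runs and the
#' seed.
#'
#' @param fr_kg_h,rpm,ls_pct,nk,sa_deg Numeric vectors: the factor levels
#'   (full-factorial) or a range whose min/max bound the sampling
#'   (random-uniform). A single value fixes the factor.
#' @param n_runs Number of runs; `NULL` (full-factorial only) keeps the full
#'   grid. A full-factorial grid is cycled or truncated to `n_runs`.
#' @param design `"full-factorial"` or `"random-uniform"`.
#' @param geometry A one-row geometry data.frame, see [geometry_preset()].
#' @param seed Integer seed (used by the random-uniform design).
#' @param label `dataset_tag` stamped on generated rows.
#' @return An object of class `doe_spec`.
#' @export
doe_spec <- function(fr_kg_h, rpm, ls_pct, nk, sa_deg, n_runs = NULL,
                     design = c("full-factorial", "random-uniform"),
                     geometry = geometry_preset("consigma25"),
                     seed = 1, label = "synthetic") {
  design <- match.arg(design)
  for (nm in c("fr_kg_h", "rpm", "ls_pct", "nk", "sa_deg")) {
    v <- get(nm)
    if (length(v) == 0 || any(!is.finite(v))) {
      stop("empty or non-finite level set for factor ", nm, call. = FALSE)
    }
  }
  if (any(fr_kg_h <= 0) || any(rpm <= 0)) {
    stop("feed rate and rpm levels must be > 0", call. = FALSE)
  }
  if (any(ls_pct < 0) || any(ls_pct > 100)) {
    stop("ls_pct levels must be within [0, 100]", call. = FALSE)
  }
  if (any(sa_deg <= 0) || any(sa_deg > 90)) {
    stop("sa_deg levels must be within (0, 90]", call. = FALSE)
  }
  if (!is.null(n_runs) && n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  structure(list(fr_kg_h = fr_kg_h, rpm = rpm, ls_pct = ls_pct, nk = nk,
                 sa_deg = sa_deg, n_runs = n_runs, design = design,
                 geometry = geometry, seed = seed, label = label),
            class = "doe_spec")
}

# Kneading elements are mounted in pairs: snap NK to an even count >= 2 and
# factor it as (NK/2) blocks of 2 elements.
snap_nk <- function(nk) {
  nk <- pmax(2, 2 * round(nk / 2))
  data.frame(nk = nk, kb = nk %/% 2, nk_per_block = 2)
}

#' Generate a designed experiment table
#'
#' Expands a [doe_spec()] into per-run rows. The full-factorial design
#' enumerates the level grid (cycling or truncating to `n_runs` when
#' requested); the random-uniform design samples each factor independently
#' and uniformly between its range bounds with the seeded generator.
#' Kneading counts are snapped to even values and factored into blocks of
#' two elements.
#'
#' @param spec A [doe_spec()].
#' @return A data.frame of design rows in the canonical schema (without
#'   observed-response columns), with `run_id` of the form `label-001`.
#' @export
generate_doe <- function(spec) {
  stopifnot(inherits(spec, "doe_spec"))
  if (spec$design == "full-factorial") {
    grid <- expand.grid(fr_kg_h = spec$fr_kg_h, rpm = spec$rpm,
                        ls_pct = spec$ls_pct, nk = spec$nk,
                        sa_deg = spec$sa_deg, KEEP.OUT.ATTRS = FALSE)
    if (!is.null(spec$n_runs)) {
      idx <- rep_len(seq_len(nrow(grid)), spec$n_runs)
      grid <- grid[idx, , drop = FALSE]
    }
  } else {
    n <- spec$n_runs
    if (is.null(n)) stop("random-uniform design requires n_runs", call. = FALSE)
    rng <- function(v, n) {
      if (length(v) == 1) rep(v, n) else stats::runif(n, min(v), max(v))
    }
    grid <- withr::with_seed(spec$seed, data.frame(
      fr_kg_h = rng(spec$fr_kg_h, n),
      rpm = rng(spec$rpm, n),
      ls_pct = rng(spec$ls_pct, n),
      nk = rng(spec$nk, n),
      sa_deg = rng(spec$sa_deg, n)
    ))
  }
  nk <- snap_nk(grid$nk)
  n <- nrow(grid)
  out <- data.frame(
    run_id = sprintf("%s-%03d", spec$label, seq_len(n)),
    dataset_tag = spec$label,
    fr_kg_h = grid$fr_kg_h, rpm = grid$rpm, ls_pct = grid$ls_pct,
    nk = nk$nk, kb = nk$kb, nk_per_block = nk$nk_per_block,
    sa_deg = grid$sa_deg,
    spec$geometry[rep(1, n), , drop = FALSE],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Measurement-noise specification
#'
#' Multiplicative lognormal noise for the simulated responses: residence
#' times are positive and their measurement error scales with magnitude, so
#' each observation is the model value times a lognormal factor with unit
#' mean and the given coefficient of variation.
#'
#' @param mrt_cv Coefficient of variation of the mean-residence-time noise.
#' @param var_cv Coefficient of variation of the variance noise.
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(mrt_cv = 0, var_cv = 0, seed = 1) {
  if (mrt_cv < 0 || var_cv < 0) stop("noise cv must be >= 0", call. = FALSE)
  structure(list(mrt_cv = mrt_cv, var_cv = var_cv, seed = seed),
            class = "noise_spec")
}

# Unit-mean lognormal factors at coefficient of variation cv.
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

#' Simulate observed responses on a design
#'
#' Evaluates the residence-time model at the true parameters for every
#' design row and perturbs the predictions with seeded multiplicative
#' lognormal noise (unit-mean, so the observations are unbiased on the
#' ratio scale). With `cv = 0` the observations equal the model predictions
#' exactly, which makes this generator the parameter-recovery oracle for
#' the fitting pipeline. Runs without a kneading section get `NA` variance.
#'
#' @param design Design rows from [generate_doe()] (or a full experiment
#'   table whose response columns will be overwritten).
#' @param true_params A [model_parameters()] satisfying both constraints;
#'   when b5/b6 are `NA` only the mean residence time is simulated.
#' @param noise A [noise_spec()].
#' @param drop_sa90_fraction Optionally drop this fraction of runs at a
#'   90-degree stagger angle (emulating missing runs from equipment jamming
#'   at high stagger angles).
#' @return An [experiment_table()].
#' @export
simulate_observations <- function(design, true_params, noise = noise_spec(),
                                  drop_sa90_fraction = 0) {
  stopifnot(inherits(noise, "noise_spec"))
  chk <- validate_constraints(true_params)
  if (!chk$pass) {
    stop("true_params must satisfy both constraints exactly", call. = FALSE)
  }
  design <- as.data.frame(design)
  design$mrt_s <- NA_real_
  design$varnorm <- NA_real_
  tab <- experiment_table(design)
  md <- model_design(tab)
  mrt <- predict_mrt_design(md, true_params)
  varnorm <- rep(NA_real_, nrow(tab))
  if (!is.na(true_params$b5)) {
    pe <- predict_peclet_design(md, true_params)
    ok <- !is.na(pe)
    varnorm[ok] <- variance_from_peclet(pe[ok])
  }
  withr::with_seed(noise$seed, {
    tab$mrt_s <- mrt * lognormal_factor(nrow(tab), noise$mrt_cv)
    ok <- !is.na(varnorm)
    tab$varnorm[ok] <- varnorm[ok] * lognormal_factor(sum(ok), noise$var_cv)
    if (drop_sa90_fraction > 0) {
      at90 <- which(tab$sa_deg == 90)
      n_drop <- floor(drop_sa90_fraction * length(at90))
      if (n_drop > 0) {
        drop <- at90[sample.int(length(at90), n_drop)]
        tab <- tab[-drop, , drop = FALSE]
      }
    }
  })
  experiment_table(tab)
}

#' Synthetic dataset presets mirroring the collated literature studies
#'
#' Returns a [doe_spec()] whose factor ranges, fixed factors, equipment
#' class and run count mirror the three published twin-screw granulation
#' RTD datasets: `"kumar2015-like"` (66 runs on a 25 mm-class granulator;
#' feed rate 10–25 kg/h, screw speed 500–900 RPM, 2–12 kneading elements,
#' stagger angle 30–90 degrees, liquid-to-solid percentage fixed at 11.5),
#' `"kumar2016-like"` (51 runs, same equipment, LS varied 6–8), and
#' `"ismail2019-like"` (24 runs on a lab-scale extruder with low feed rates
#' and high liquid-to-solid percentages). Factor sampling is random-uniform
#' within the ranges; the true equipment dimensions of the source studies
#' are not public here, so the geometry presets are stated defaults.
#'
#' @param label One of `"kumar2015-like"`, `"kumar2016-like"`,
#'   `"ismail2019-like"`.
#' @param n_runs Override the preset run count.
#' @param seed Integer seed for the sampling.
#' @return A [doe_spec()].
#' @export
preset_dataset <- function(label = c("kumar2015-like", "kumar2016-like",
                                     "ismail2019-like"),
                           n_runs = NULL, seed = 1) {
  label <- match.arg(label)
  spec <- switch(label,
    "kumar2015-like" = doe_spec(
      fr_kg_h = c(10, 25), rpm = c(500, 900), ls_pct = 11.5,
      nk = c(2, 12), sa_deg = c(30, 90), n_runs = 66,
      design = "random-uniform", geometry = geometry_preset("consigma25"),
      seed = seed, label = label),
    "kumar2016-like" = doe_spec(
      fr_kg_h = c(10, 25), rpm = c(500, 900), ls_pct = c(6, 8),
      nk = c(2, 12), sa_deg = c(30, 60), n_runs = 51,
      design = "random-uniform", geometry = geometry_preset("consigma25"),
      seed = seed, label = label),
    "ismail2019-like" = doe_spec(
      fr_kg_h = c(0.5, 2), rpm = c(200, 500), ls_pct = c(70, 100),
      nk = c(4, 8), sa_deg = 60, n_runs = 24,
      design = "random-uniform", geometry = geometry_preset("threetec"),
      seed = seed, label = label)
  )
  if (!is.null(n_runs)) spec$n_runs <- n_runs
  spec
}
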