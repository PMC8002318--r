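#' Screw geometry of a twin-screw granulator
#'
#' Describes the physical dimensions of the screw that the available-volume
#' and displacement-rate calculations need: the outer radius of the screw
#' elements, the thickness of a single kneading disc, the lead length (axial
#' length of one full 360-degree turn of the conveying flight), the total
#' axial length of the conveying sections, and the disc thickness used to
#' discretize the conveying screw into a stack of thin pseudo-kneading discs.
#'
#' All lengths are in metres. The discretization step `fe_disc_m` rescales
#' the conveying volume (the discretized volume does not converge as the
#' step shrinks); its value is absorbed by the fitted scale constants, so it
#' should be held fixed across a dataset. The default of 1 mm matches a
#' unit-thickness disc on lab/pilot-scale equipment.
#'
#' @param radius_m Outer radius of the screw elements (m).
#' @param knead_thickness_m Thickness of one kneading element (m).
#' @param lead_m Lead length of the conveying flight (m).
#' @param convey_length_m Total axial length of conveying sections (m);
#'   zero is allowed and denotes a screw with no conveying section.
#' @param fe_disc_m Disc thickness for the conveying-screw discretization (m).
#' @return An object of class `screw_geometry`.
#' @examples
#' geom <- screw_geometry(0.0125, 0.00625, 0.025, 0.3)
#' @export
screw_geometry <- function(radius_m, knead_thickness_m, lead_m,
                           convey_length_m, fe_disc_m = 1e-3) {
  vals <- c(radius_m = radius_m, knead_thickness_m = knead_thickness_m,
            lead_m = lead_m, fe_disc_m = fe_disc_m)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("invalid geometry: radius, kneading thickness, lead and disc thickness must be finite and > 0",
         call. = FALSE)
  }
  if (!is.finite(convey_length_m) || convey_length_m < 0) {
    stop("invalid geometry: conveying length must be finite and >= 0", call. = FALSE)
  }
  if (fe_disc_m > lead_m) {
    stop("invalid geometry: fe_disc_m must not exceed the lead length", call. = FALSE)
  }
  if (convey_length_m > 0 && fe_disc_m > convey_length_m) {
    stop("invalid geometry: fe_disc_m must not exceed the conveying length", call. = FALSE)
  }
  structure(list(radius_m = radius_m,
                 knead_thickness_m = knead_thickness_m,
                 lead_m = lead_m,
                 convey_length_m = convey_length_m,
                 fe_disc_m = fe_disc_m),
            class = "screw_geometry")
}

#' @export
print.screw_geometry <- function(x, ...) {
  cat("Screw geometry (m): R =", x$radius_m,
      "| knead t =", x$knead_thickness_m,
      "| lead =", x$lead_m,
      "| convey L =", x$convey_length_m,
      "| FE disc =", x$fe_disc_m, "\n")
  invisible(x)
}

#' Kneading-block layout of a screw configuration
#'
#' The kneading section is described by the total number of kneading
#' elements, how they are grouped into blocks, and the stagger angle between
#' adjacent elements. A pure-conveying screw is encoded with all counts zero
#' and a zero stagger angle.
#'
#' @param n_kneading Total number of kneading elements (NK).
#' @param n_blocks Number of kneading blocks (KB).
#' @param n_per_block Number of kneading elements per block.
#' @param stagger_deg Stagger angle between adjacent kneading elements
#'   (degrees, in (0, 90]).
#' @return An object of class `screw_configuration`.
#' @examples
#' cfg <- screw_configuration(6, 3, 2, 60)
#' @export
screw_configuration <- function(n_kneading, n_blocks, n_per_block, stagger_deg) {
  counts <- c(n_kneading, n_blocks, n_per_block)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("invalid configuration: counts must be non-negative integers", call. = FALSE)
  }
  if (n_kneading == 0) {
    if (n_blocks != 0 || n_per_block != 0 || stagger_deg != 0) {
      stop("invalid configuration: a screw without kneading elements must have zero blocks and zero stagger angle",
           call. = FALSE)
    }
  } else {
    if (n_blocks < 1 || n_per_block < 1 || n_kneading != n_blocks * n_per_block) {
      stop("invalid configuration: n_kneading must equal n_blocks * n_per_block (all >= 1)",
           call. = FALSE)
    }
    if (!is.finite(stagger_deg) || stagger_deg <= 0 || stagger_deg > 90) {
      stop("invalid configuration: stagger angle must be in (0, 90] degrees", call. = FALSE)
    }
  }
  structure(list(n_kneading = n_kneading,
                 n_blocks = n_blocks,
                 n_per_block = n_per_block,
                 stagger_deg = stagger_deg),
            class = "screw_configuration")
}

#' @export
print.screw_configuration <- function(x, ...) {
  cat("Screw configuration: NK =", x$n_kneading,
      "| blocks =", x$n_blocks, "x", x$n_per_block,
      "| stagger =", x$stagger_deg, "deg\n")
  invisible(x)
}

# Sector volume of a stack of staggered discs: 4 * 1/2 * R^2 * n * t * SA * pi/180.
sector_stack_volume <- function(radius_m, n, thickness_m, stagger_deg) {
  4 * 0.5 * radius_m^2 * n * thickness_m * stagger_deg * pi / 180
}

# Discretization of a conveying section of given axial length into thin discs:
# n discs of equal thickness, with the total twist spread over the n - 1 gaps.
convey_discretization <- function(length_m, lead_m, fe_disc_m) {
  n <- round(length_m / fe_disc_m)
  if (n < 2) {
    stop("discretization too coarse: the conveying section must resolve into at least 2 discs",
         call. = FALSE)
  }
  theta_total <- 360 * length_m / lead_m
  list(n = n,
       thickness_m = length_m / n,
       stagger_deg = theta_total / (n - 1))
}

#' Available volume of the kneading blocks
#'
#' Volume available to material in the kneading section, computed as the
#' stagger-angle sector volume summed over all kneading elements:
#' \eqn{4 \times \tfrac12 R^2 \, NK \, t \, SA_{deg} \, \pi/180}.
#' Returns zero for a screw without kneading elements.
#'
#' @param geom A [screw_geometry()].
#' @param config A [screw_configuration()].
#' @return Volume in m^3.
#' @export
available_volume_kneading <- function(geom, config) {
  stopifnot(inherits(geom, "screw_geometry"), inherits(config, "screw_configuration"))
  if (config$n_kneading == 0) return(0)
  sector_stack_volume(geom$radius_m, config$n_kneading,
                      geom$knead_thickness_m, config$stagger_deg)
}

#' Available volume of the conveying sections
#'
#' The helical conveying screw is approximated as a stack of many thin
#' kneading discs spanning the same axial length: `n` discs of thickness
#' `convey_length / n` with the section's total twist (360 degrees per lead
#' length) spread over the `n - 1` gaps between discs. The stack's sector
#' volume is then evaluated with the same formula as for a kneading block.
#'
#' The result scales with the chosen disc thickness (halving `fe_disc_m`
#' roughly halves the volume), so the discretization step is part of the
#' model configuration and is absorbed by the fitted scale constants.
#'
#' @inheritParams available_volume_kneading
#' @return Volume in m^3.
#' @export
available_volume_conveying <- function(geom) {
  stopifnot(inherits(geom, "screw_geometry"))
  if (geom$convey_length_m <= 0) {
    stop("no conveying section: conveying length is zero", call. = FALSE)
  }
  fe <- convey_discretization(geom$convey_length_m, geom$lead_m, geom$fe_disc_m)
  sector_stack_volume(geom$radius_m, fe$n, fe$thickness_m, fe$stagger_deg)
}

#' Total available volume of the screw
#'
#' Sum of the kneading-block and conveying-section available volumes. A
#' screw with no conveying section contributes only the kneading term, and
#' vice versa.
#'
#' @inheritParams available_volume_kneading
#' @return Volume in m^3, strictly positive.
#' @export
total_available_volume <- function(geom, config) {
  v_knead <- available_volume_kneading(geom, config)
  v_convey <- if (geom$convey_length_m > 0) available_volume_conveying(geom) else 0
  total <- v_knead + v_convey
  if (total <= 0) {
    stop("invalid screw: total available volume is zero (no kneading and no conveying section)",
         call. = FALSE)
  }
  total
}

#' Volumetric displacement rate of the conveying screw
#'
#' Rate at which one final lead of conveying screw displaces material:
#' revolutions per second times the available volume of a single lead
#' (axial length = lead length, full 360-degree twist), discretized the same
#' way as [available_volume_conveying()].
#'
#' @param geom A [screw_geometry()].
#' @param rpm Screw speed in revolutions per minute (>= 0).
#' @return Volumetric rate in m^3/s.
#' @export
displacement_rate <- function(geom, rpm) {
  stopifnot(inherits(geom, "screw_geometry"))
  if (!is.finite(rpm) || rpm < 0) {
    stop("invalid input: rpm must be finite and >= 0", call. = FALSE)
  }
  fe <- convey_discretization(geom$lead_m, geom$lead_m, geom$fe_disc_m)
  one_lead <- sector_stack_volume(geom$radius_m, fe$n, fe$thickness_m, fe$stagger_deg)
  rpm / 60 * one_lead
}
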