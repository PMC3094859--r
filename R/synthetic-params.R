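#' Biexponential clearance parameters
#'
#' Parameters of the washout model f(t) = a exp(-b t) + c exp(-d t), with
#' amplitudes expressed as percentages of the initially retained activity.
#' The short component (rate \code{b}) captures early mechanical loss after
#' injection; the long component (rate \code{d}) captures slow leakage from
#' viable tissue. Amplitudes are normalized so that a + c = 100.
#'
#' @param a short-component amplitude (percent, >= 0; 0 for monoexponential).
#' @param b short rate constant (1/hour, > 0; ignored when \code{a} is 0).
#' @param c long-component amplitude (percent, > 0).
#' @param d long rate constant (1/hour, > 0, < b when both present).
#' @param injected_activity injected activity in MBq.
#' @return object of class \code{clearance_params}.
#' @examples
#' clearance_params(a = 37.9, b = 0.3712, c = 62.1, d = 0.0012930)
#' @export
clearance_params <- function(a, b, c, d, injected_activity = 50) {
  if (a < 0) stop("a must be >= 0")
  if (c <= 0) stop("c must be > 0")
  if (d <= 0) stop("d must be > 0")
  if (a > 0) {
    if (is.na(b) || b <= 0) stop("b must be > 0 when a > 0")
    if (b <= d) stop("rate ordering violated: need b > d")
  } else {
    b <- NA_real_
  }
  if (injected_activity <= 0) stop("injected_activity must be > 0")
  tot <- a + c
  structure(list(a = 100 * a / tot, b = b, c = 100 * c / tot, d = d,
                 injected_activity = injected_activity),
            class = "clearance_params")
}

#' @export
print.clearance_params <- function(x, ...) {
  cat(sprintf("Clearance parameters: a=%.1f%% b=%.4g/h c=%.1f%% d=%.4g/h (%.1f MBq)\n",
              x$a, x$b, x$c, x$d, x$injected_activity))
  invisible(x)
}

#' Phantom geometry for the dynamic image simulator
#'
#' A rectangular voxel grid with a spherical hot focus (the injection site)
#' over a uniform background, the simplest configuration exercising the
#' threshold-based VOI mask.
#'
#' @param dim integer vector of 3 grid dimensions (voxels).
#' @param center focus center (voxel coordinates); defaults to grid middle.
#' @param radius focus radius in voxels (> 0).
#' @param focus_background_ratio focus:background intensity ratio at t = 0
#'   (> 1).
#' @param voxel_size_mm voxel edge length, metadata only.
#' @export
phantom_geometry <- function(dim = c(32L, 32L, 32L), center = (dim + 1) / 2,
                             radius = 4, focus_background_ratio = 20,
                             voxel_size_mm = 4) {
  dim <- as.integer(dim)
  if (length(dim) != 3 || any(dim < 1)) stop("dim must be 3 positive integers")
  if (radius <= 0) stop("focus radius must be > 0")
  if (focus_background_ratio <= 1) stop("focus:background ratio must be > 1")
  if (any(center - radius < 1) || any(center + radius > dim))
    stop("focus must lie entirely inside the grid")
  structure(list(dim = dim, center = center, radius = radius,
                 focus_background_ratio = focus_background_ratio,
                 voxel_size_mm = voxel_size_mm),
            class = "phantom_geometry")
}

#' Wholebody biodistribution specification
#'
#' Fractions of total body activity in the heart and the major clearance
#' organs visible on planar scans (liver, kidneys, bladder, remainder),
#' plus per-organ redistribution rates at which activity leaves the heart
#' for each organ. Fractions must sum to 1.
#'
#' @param heart_fraction fraction of activity in the heart at t = 0.
#' @param organ_fractions named numeric vector (liver, kidneys, bladder,
#'   remainder); together with heart_fraction must sum to 1.
#' @param redistribution_rates named numeric vector (same names), 1/hour,
#'   >= 0: rate at which heart activity transfers to each organ.
#' @export
biodistribution_spec <- function(heart_fraction = 0.48,
                                 organ_fractions = c(liver = 0.25,
                                                     kidneys = 0.12,
                                                     bladder = 0.05,
                                                     remainder = 0.10),
                                 redistribution_rates = c(liver = 0.015,
                                                          kidneys = 0.008,
                                                          bladder = 0.004,
                                                          remainder = 0.005)) {
  if (heart_fraction < 0 || heart_fraction > 1)
    stop("heart_fraction must be in [0, 1]")
  if (any(organ_fractions < 0)) stop("organ fractions must be non-negative")
  tot <- heart_fraction + sum(organ_fractions)
  if (abs(tot - 1) > 1e-9)
    stop(sprintf("fractions must sum to 1 (got %.6f)", tot))
  if (is.null(names(organ_fractions)) ||
      !setequal(names(organ_fractions), names(redistribution_rates)))
    stop("organ_fractions and redistribution_rates must share names")
  if (any(redistribution_rates < 0)) stop("redistribution rates must be >= 0")
  structure(list(heart_fraction = heart_fraction,
                 organ_fractions = organ_fractions,
                 redistribution_rates = redistribution_rates[names(organ_fractions)]),
            class = "biodistribution_spec")
}
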