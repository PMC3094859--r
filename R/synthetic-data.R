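#' Imaging schedule used by the simulators
#'
#' Serial acquisitions over the first hours on injection day followed by
#' weekly follow-up sessions, mirroring a typical small-cohort myocardial
#' retention protocol (continuous scanning for 5 h, then three weekly
#' sessions).
#'
#' @param serial_hours times (hours) of the injection-day frames.
#' @param followup_days days of the follow-up sessions.
#' @return numeric vector of hours post first acquisition, starting at 0.
#' @export
acquisition_schedule <- function(serial_hours = seq(0, 5, by = 0.5),
                                 followup_days = c(7, 14, 21)) {
  sort(unique(c(serial_hours, followup_days * 24)))
}

# biexponential envelope, percent of initially retained activity
envelope_pct <- function(params, t) {
  a <- params$a
  long <- params$c * exp(-params$d * t)
  if (a > 0) a * exp(-params$b * t) + long else long
}

check_timepoints <- function(timepoints) {
  if (length(timepoints) < 1) stop("need at least one timepoint")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (timepoints[1] < 0) stop("timepoints must start at or after 0")
}

add_counting_noise <- function(values, noise, peak_counts, seed) {
  if (noise == "none") return(values)
  scale <- peak_counts / max(values)
  counts <- values * scale
  noisy <- withr::with_seed(seed, {
    switch(noise,
      poisson = stats::rpois(length(counts), counts),
      gaussian = counts + stats::rnorm(length(counts), sd = sqrt(pmax(counts, 0)))
    )
  })
  pmax(noisy, 0) / scale
}

#' Simulate a decaying time-activity curve
#'
#' Forward model of what the washout fit assumes: a biexponential
#' biological envelope modulated by physical decay of the nuclide,
#' optionally degraded by counting noise. With \code{noise = "none"} the
#' output is exact:
#' \deqn{A(t) = A_0 \frac{a e^{-bt} + c e^{-dt}}{100} \, 2^{-t/T_{phys}}.}
#'
#' @param params a \code{\link{clearance_params}} object.
#' @param timepoints hours post first acquisition, strictly increasing
#'   starting at 0 (see \code{\link{acquisition_schedule}}).
#' @param physical_half_life nuclide half-life in hours; \code{Inf}
#'   disables physical decay.
#' @param noise one of "none", "poisson", "gaussian". Poisson acts on
#'   counts after scaling the peak value to \code{peak_counts}; Gaussian
#'   uses the matching sqrt(counts) standard deviation.
#' @param peak_counts counts assigned to the curve maximum for the noise
#'   model.
#' @param seed integer seed; required when noise is not "none".
#' @param subject,group identifiers stored on the returned TAC.
#' @return a \code{\link{tac}} with raw (decaying) activity in MBq;
#'   decay-correct it with \code{\link{decay_correct}}.
#' @export
simulate_tac <- function(params, timepoints,
                         physical_half_life = in111_half_life_hours,
                         noise = c("none", "poisson", "gaussian"),
                         peak_counts = 1e4, seed = NULL,
                         subject = NA_character_, group = NA_character_) {
  stopifnot(inherits(params, "clearance_params"))
  noise <- match.arg(noise)
  check_timepoints(timepoints)
  if (physical_half_life <= 0) stop("physical_half_life must be > 0")
  if (noise != "none" && is.null(seed)) stop("seed required for noisy simulation")
  act <- params$injected_activity * envelope_pct(params, timepoints) / 100 *
    2^(-timepoints / physical_half_life)
  act <- add_counting_noise(act, noise, peak_counts, seed)
  tac(timepoints, act, units = "MBq", subject = subject, group = group)
}

#' Simulate a dynamic SPECT-like image series
#'
#' Post-reconstruction surrogate: a uniform background with a spherical
#' injection focus whose intensity follows the biexponential-with-decay
#' curve of \code{\link{simulate_tac}}. Per-voxel Poisson noise is applied
#' frame by frame under the given seed. No projection or reconstruction
#' physics is modeled.
#'
#' @param geometry a \code{\link{phantom_geometry}}.
#' @param params a \code{\link{clearance_params}}.
#' @param timepoints frame times in hours, increasing from 0.
#' @param physical_half_life hours; Inf disables decay.
#' @param background_counts mean background voxel intensity (counts).
#' @param noise "poisson" or "none".
#' @param seed integer seed (required for noise).
#' @return object of class \code{dynamic_image_series}: list with a 4-D
#'   array \code{data} (x, y, z, frame), \code{time_hours}, and the
#'   geometry.
#' @export
simulate_dynamic_spect <- function(geometry, params, timepoints,
                                   physical_half_life = in111_half_life_hours,
                                   background_counts = 10,
                                   noise = c("poisson", "none"), seed = NULL) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  noise <- match.arg(noise)
  check_timepoints(timepoints)
  if (noise == "poisson" && is.null(seed)) stop("seed required for noisy simulation")
  ref <- simulate_tac(params, timepoints, physical_half_life, noise = "none")
  rel <- ref$activity / ref$activity[1]
  dm <- geometry$dim
  idx <- expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]), z = seq_len(dm[3]))
  dist2 <- (idx$x - geometry$center[1])^2 + (idx$y - geometry$center[2])^2 +
    (idx$z - geometry$center[3])^2
  focus <- array(dist2 <= geometry$radius^2, dim = dm)
  frames <- array(background_counts, dim = c(dm, length(timepoints)))
  # focus signal sits on top of the background, so subtracting the flat
  # background downstream recovers the injected activity exactly
  focus_level <- background_counts * (geometry$focus_background_ratio - 1)
  for (k in seq_along(timepoints)) {
    fr <- array(background_counts, dim = dm)
    fr[focus] <- background_counts + focus_level * rel[k]
    frames[, , , k] <- fr
  }
  if (noise == "poisson") {
    frames <- withr::with_seed(seed, {
      array(stats::rpois(length(frames), frames), dim = dim(frames))
    })
  }
  structure(list(data = frames, time_hours = timepoints, geometry = geometry,
                 noise = noise),
            class = "dynamic_image_series")
}

#' @export
print.dynamic_image_series <- function(x, ...) {
  cat(sprintf("Dynamic image series: %s voxels x %d frames (%s noise)\n",
              paste(x$geometry$dim, collapse = "x"), length(x$time_hours),
              x$noise))
  invisible(x)
}

#' Simulate paired heart/wholebody planar scans
#'
#' Activity starts distributed per the biodistribution spec and
#' redistributes from the heart to the clearance organs: the heart
#' effluxes first-order with total rate equal to the sum of the per-organ
#' redistribution rates, and each organ receives its rate's share of the
#' efflux. Decay-corrected total counts are conserved exactly; the
#' heart:wholebody ratio is strictly decreasing whenever any rate is
#' positive.
#'
#' @param spec a \code{\link{biodistribution_spec}}.
#' @param timepoints scan times in hours, increasing from 0.
#' @param injected_activity MBq.
#' @param physical_half_life hours; Inf disables decay.
#' @param counts_per_mbq planar sensitivity converting activity to counts.
#' @param heart_area,bg_area ROI areas in pixels (background ROI counts are
#'   zero in the noiseless phantom; the area fields exercise the
#'   per-area correction downstream).
#' @param noise "none" or "poisson" (applied to every counts column).
#' @param seed integer seed (required for noise).
#' @param subject,group identifiers.
#' @return data frame of class \code{wholebody_scans}: one row per scan
#'   with heart, organ, background and total counts.
#' @export
simulate_wholebody_pair <- function(spec, timepoints, injected_activity = 50,
                                    physical_half_life = in111_half_life_hours,
                                    counts_per_mbq = 2e4,
                                    heart_area = 400, bg_area = 400,
                                    noise = c("none", "poisson"), seed = NULL,
                                    subject = NA_character_,
                                    group = NA_character_) {
  stopifnot(inherits(spec, "biodistribution_spec"))
  noise <- match.arg(noise)
  check_timepoints(timepoints)
  if (noise == "poisson" && is.null(seed)) stop("seed required for noisy simulation")
  rates <- spec$redistribution_rates
  k <- sum(rates)
  h0 <- spec$heart_fraction
  heart <- h0 * exp(-k * timepoints)
  organs <- vapply(names(rates), function(o) {
    gained <- if (k > 0) (rates[[o]] / k) * h0 * (1 - exp(-k * timepoints))
              else rep(0, length(timepoints))
    spec$organ_fractions[[o]] + gained
  }, numeric(length(timepoints)))
  organs <- matrix(organs, nrow = length(timepoints),
                   dimnames = list(NULL, names(rates)))
  decay <- 2^(-timepoints / physical_half_life)
  scale <- injected_activity * counts_per_mbq
  heart_counts <- heart * decay * scale
  organ_counts <- organs * decay * scale
  total_counts <- heart_counts + rowSums(organ_counts)
  if (noise == "poisson") {
    noisy <- withr::with_seed(seed, {
      list(h = stats::rpois(length(heart_counts), heart_counts),
           o = matrix(stats::rpois(length(organ_counts), organ_counts),
                      nrow = nrow(organ_counts),
                      dimnames = dimnames(organ_counts)))
    })
    heart_counts <- noisy$h
    organ_counts <- noisy$o
    total_counts <- heart_counts + rowSums(organ_counts)
  }
  out <- data.frame(subject = subject, group = group,
                    time_hours = timepoints,
                    heart_counts = heart_counts,
                    bg_counts = 0, bg_area = bg_area,
                    heart_area = heart_area,
                    total_counts = total_counts)
  out <- cbind(out, as.data.frame(organ_counts))
  structure(out, class = c("wholebody_scans", "data.frame"))
}

#' Generate a synthetic injection cohort
#'
#' Draws per-subject clearance parameters from log-normal distributions
#' (rates and amplitudes are positive and right-skewed) centered by
#' default on the group means of the packaged canine reference fits, and
#' per-subject biodistributions with heart fractions spread around the
#' group's early retention mean. Identical seed and specs yield an
#' identical cohort.
#'
#' @param group "epicardial" or "endocardial".
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed.
#' @param centers optional list with elements \code{a}, \code{b}, \code{d}
#'   (amplitude percent and rates 1/h) overriding the fixture-derived
#'   group means; an element \code{sdlog = 0} makes the cohort degenerate
#'   at the centers.
#' @param sdlog log-scale spread of the parameter distributions.
#' @param heart_fraction_mean,heart_fraction_sd normal spread (truncated to
#'   [0.15, 0.80]) of the per-subject heart fraction; defaults reflect
#'   early post-injection retention near 50\% with wide inter-subject
#'   variation.
#' @return object of class \code{synthetic_cohort}: list with the group
#'   label, the seed, and one \code{$subjects} entry per subject holding
#'   \code{params} and \code{biodist}.
#' @export
make_cohort <- function(group = c("epicardial", "endocardial"), n_subjects,
                        seed = 1L, centers = NULL, sdlog = 0.25,
                        heart_fraction_mean = NULL,
                        heart_fraction_sd = 0.13) {
  group <- match.arg(group)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  fits <- canine_fit_table()
  g <- fits[fits$group == group, ]
  def <- list(a = mean(g$a_pct, na.rm = TRUE),
              b = mean(g$b_per_hour, na.rm = TRUE),
              d = mean(g$d_per_hour))
  if (!is.null(centers)) def[names(centers)] <- centers
  sdl <- if (!is.null(centers) && !is.null(centers$sdlog)) centers$sdlog else sdlog
  if (is.null(heart_fraction_mean))
    heart_fraction_mean <- if (group == "epicardial") 0.48 else 0.50
  draw_ln <- function(n, center) center * exp(stats::rnorm(n, 0, sdl))
  subjects <- withr::with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      a <- min(max(draw_ln(1, def$a), 1), 90)
      b <- draw_ln(1, def$b)
      d <- draw_ln(1, def$d)
      if (b <= d) b <- d * 10   # keep components resolvable
      hf <- min(max(stats::rnorm(1, heart_fraction_mean, heart_fraction_sd),
                    0.15), 0.80)
      base <- biodistribution_spec()
      rest <- base$organ_fractions / sum(base$organ_fractions) * (1 - hf)
      list(params = clearance_params(a, b, 100 - a, d),
           biodist = biodistribution_spec(hf, rest,
                                          base$redistribution_rates))
    })
  })
  structure(list(group = group, seed = seed, subjects = subjects),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic %s cohort: %d subjects (seed %d)\n",
              x$group, length(x$subjects), x$seed))
  invisible(x)
}
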