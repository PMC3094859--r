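#' Heart-to-wholebody activity ratio for one planar scan
#'
#' Background correction is per-area: the background ROI gives a
#' counts-per-pixel estimate which is scaled to the heart ROI area (and to
#' the full image area when \code{total_area} is known) before the heart
#' counts are normalized to total image counts. The result is a
#' percentage, clamped to [0, 100]; a negative corrected heart count
#' clamps to 0 with a warning.
#'
#' @param heart_counts,total_counts ROI and whole-image counts.
#' @param bg_counts,bg_area background-ROI counts and area (pixels).
#' @param heart_area heart-ROI area (pixels).
#' @param total_area full image area (pixels); NA (default) applies no
#'   background correction to the total.
#' @return percentage in [0, 100].
#' @export
compute_hwb <- function(heart_counts, total_counts, bg_counts = 0,
                        bg_area = 1, heart_area = bg_area,
                        total_area = NA_real_) {
  if (any(c(heart_counts, total_counts, bg_counts) < 0))
    stop("counts must be >= 0")
  if (total_counts <= 0) stop("total counts must be > 0")
  if (heart_counts > total_counts) stop("heart counts exceed total counts")
  bg_per_px <- if (bg_area > 0) bg_counts / bg_area else 0
  heart_corr <- heart_counts - bg_per_px * heart_area
  if (heart_corr < 0) {
    warning("background exceeds heart counts; clamping to 0")
    heart_corr <- 0
  }
  total_corr <- total_counts -
    if (is.na(total_area)) 0 else bg_per_px * total_area
  if (total_corr <= 0) stop("background-corrected total is not positive")
  min(max(100 * heart_corr / total_corr, 0), 100)
}

#' Heart:wholebody ratio time series for a cohort of scans
#'
#' @param scans data frame in the wholebody dialect (columns subject,
#'   group, time_hours, heart_counts, bg_counts, bg_area, heart_area,
#'   total_counts), e.g. from \code{\link{simulate_wholebody_pair}}.
#' @param total_area optional full image area for total background
#'   correction.
#' @return data frame ordered by subject and time with columns subject,
#'   group, time_hours, hwb_pct. Missing sessions stay absent (gaps are
#'   preserved, not interpolated).
#' @export
hwb_timeseries <- function(scans, total_area = NA_real_) {
  need <- c("subject", "time_hours", "heart_counts", "total_counts")
  miss <- setdiff(need, names(scans))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"group" %in% names(scans)) scans$group <- NA_character_
  if (!"bg_counts" %in% names(scans)) scans$bg_counts <- 0
  if (!"bg_area" %in% names(scans)) scans$bg_area <- 1
  if (!"heart_area" %in% names(scans)) scans$heart_area <- scans$bg_area
  key <- paste(scans$subject, scans$time_hours)
  if (anyDuplicated(key))
    stop("duplicate timestamps for subject(s): ",
         paste(unique(scans$subject[duplicated(key)]), collapse = ", "))
  scans <- scans[order(scans$subject, scans$time_hours), ]
  pct <- vapply(seq_len(nrow(scans)), function(i) {
    compute_hwb(scans$heart_counts[i], scans$total_counts[i],
                scans$bg_counts[i], scans$bg_area[i], scans$heart_area[i],
                total_area)
  }, numeric(1))
  data.frame(subject = scans$subject, group = scans$group,
             time_hours = scans$time_hours, hwb_pct = pct)
}
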