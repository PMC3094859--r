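#' Build a threshold VOI mask from the first frame
#'
#' The volume of interest is defined on the first acquired frame as all
#' voxels at or above a fraction of that frame's maximum intensity
#' (inclusive comparison). The mask is frozen and reused verbatim for
#' every later frame and session; cross-session alignment is assumed
#' given.
#'
#' @param frame0 numeric 3-D (or 2-D) array, the t = 0 frame.
#' @param threshold_fraction fraction of the frame maximum (default 0.30).
#' @param connected_only if TRUE, keep only the connected component
#'   containing the maximum voxel (6-connectivity); off by default.
#' @return object of class \code{voi_mask}: logical array with attributes
#'   \code{threshold_fraction} and \code{source_frame}.
#' @export
build_mask <- function(frame0, threshold_fraction = 0.30,
                       connected_only = FALSE) {
  if (!is.array(frame0) && !is.matrix(frame0)) frame0 <- as.array(frame0)
  mx <- max(frame0)
  if (mx <= 0) stop("frame has no positive voxels")
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    stop("threshold_fraction must be in (0, 1]")
  mask <- frame0 >= threshold_fraction * mx
  if (connected_only) mask <- keep_component(mask, which.max(frame0))
  structure(mask, threshold_fraction = threshold_fraction,
            source_frame = 1L, class = c("voi_mask", class(mask)))
}

# flood fill (6-connectivity) from linear index `start`
keep_component <- function(mask, start) {
  dm <- dim(mask)
  keep <- array(FALSE, dm)
  stack <- start
  offs <- rbind(diag(length(dm)), -diag(length(dm)))
  while (length(stack)) {
    i <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (keep[i] || !mask[i]) next
    keep[i] <- TRUE
    pos <- arrayInd(i, dm)
    for (r in seq_len(nrow(offs))) {
      nb <- pos + offs[r, ]
      if (all(nb >= 1) && all(nb <= dm)) {
        j <- sum((nb - 1) * cumprod(c(1, dm[-length(dm)]))) + 1
        if (mask[j] && !keep[j]) stack <- c(stack, j)
      }
    }
  }
  keep
}

#' Extract a time-activity curve through a VOI mask
#'
#' Multiplies the mask into each frame and takes the mean intensity of the
#' in-mask voxels, subtracting a per-frame background estimate (scalar or
#' one value per frame); negative corrected means are clamped to zero.
#'
#' @param series a \code{\link{simulate_dynamic_spect}} result or any list
#'   with \code{data} (4-D array) and \code{time_hours}.
#' @param mask a \code{\link{build_mask}} result congruent with the grid.
#' @param background scalar or per-frame background intensity to subtract.
#' @return a \code{\link{tac}} (raw values; decay-correct separately).
#' @export
extract_tac <- function(series, mask, background = 0) {
  dm <- dim(series$data)
  nt <- length(series$time_hours)
  if (length(dm) != 4 || dm[4] != nt) stop("series must be x,y,z,frame")
  if (!all(dim(mask) == dm[1:3])) stop("mask grid does not match series grid")
  if (!any(mask)) stop("mask is empty")
  bg <- rep_len(background, nt)
  vals <- vapply(seq_len(nt), function(k) {
    fr <- series$data[, , , k]
    max(mean(fr[mask]) - bg[k], 0)
  }, numeric(1))
  tac(series$time_hours, vals, units = "mean voxel counts")
}

#' Correct a TAC for physical decay
#'
#' Multiplies measured activity by 2^(t / physical half-life), removing
#' radioactive decay of the nuclide so the remaining time dependence is
#' biological clearance. The t = 0 sample is unchanged.
#'
#' @param x a \code{\link{tac}}.
#' @param physical_half_life hours (> 0).
#' @return the TAC with \code{activity_dc} filled in.
#' @export
decay_correct <- function(x, physical_half_life = in111_half_life_hours) {
  stopifnot(inherits(x, "tac"))
  if (physical_half_life <= 0) stop("physical_half_life must be > 0")
  x$activity_dc <- x$activity * 2^(x$time_hours / physical_half_life)
  x
}
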