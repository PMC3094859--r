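#' Construct a time-activity curve
#'
#' A TAC holds activity samples at increasing times post-injection, with
#' optional decay-corrected values alongside the raw (physically decaying)
#' measurements.
#'
#' @param time_hours numeric vector, strictly increasing, first value >= 0.
#' @param activity raw (or background-corrected) activity per timepoint.
#' @param activity_dc decay-corrected activity, or NULL if not yet corrected.
#' @param units character label for the activity units.
#' @param subject,group optional identifiers carried into tabular output.
#' @return An object of class \code{tac}: a data frame with columns
#'   \code{time_hours}, \code{activity}, \code{activity_dc} and attributes
#'   \code{units}, \code{subject}, \code{group}.
#' @export
tac <- function(time_hours, activity, activity_dc = NULL,
                units = "arbitrary", subject = NA_character_,
                group = NA_character_) {
  time_hours <- as.numeric(time_hours)
  activity <- as.numeric(activity)
  if (length(time_hours) != length(activity))
    stop("time_hours and activity must have equal length")
  if (length(time_hours) == 0) stop("empty TAC")
  if (any(diff(time_hours) <= 0))
    stop("timepoints must be strictly increasing")
  if (time_hours[1] < 0) stop("timepoints must start at or after 0")
  if (!is.null(activity_dc) && length(activity_dc) != length(activity))
    stop("activity_dc length mismatch")
  out <- data.frame(
    time_hours = time_hours,
    activity = activity,
    activity_dc = if (is.null(activity_dc)) NA_real_ else as.numeric(activity_dc)
  )
  structure(out, units = units, subject = subject, group = group,
            class = c("tac", "data.frame"))
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("Time-activity curve: %d timepoints, %.3g-%.3g h",
              nrow(x), min(x$time_hours), max(x$time_hours)))
  subj <- attr(x, "subject")
  if (!is.na(subj)) cat(sprintf(" [%s/%s]", attr(x, "group"), subj))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' @export
plot.tac <- function(x, which = c("activity", "activity_dc"), log = "y", ...) {
  which <- match.arg(which)
  y <- x[[which]]
  graphics::plot(x$time_hours, y, xlab = "Time post-injection (h)",
                 ylab = paste0(which, " (", attr(x, "units"), ")"),
                 log = if (all(y > 0)) log else "", type = "b", ...)
  invisible(x)
}

# values used downstream for fitting: decay-corrected if present, else raw
tac_values <- function(x) {
  if (all(is.na(x$activity_dc))) x$activity else x$activity_dc
}
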