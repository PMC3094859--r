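#' Convert a clearance rate constant to a half-life
#'
#' @param rate rate constant in 1/hour (> 0), vectorized.
#' @return half-life in hours, ln(2) / rate.
#' @examples
#' half_life(0.0012930)   # ~536 h
#' @export
half_life <- function(rate) {
  if (any(!is.na(rate) & rate <= 0)) stop("rate must be > 0")
  log(2) / rate
}

#' Normalize biexponential amplitudes to percent fractions
#'
#' @param a_raw short-component amplitude (>= 0).
#' @param c_raw long-component amplitude (> 0, or >= 0 if a_raw > 0).
#' @return named numeric vector c(a_pct, c_pct) summing to 100.
#' @export
normalize_fractions <- function(a_raw, c_raw) {
  if (a_raw < 0 || c_raw < 0) stop("amplitudes must be non-negative")
  tot <- a_raw + c_raw
  if (tot == 0) stop("both amplitudes are zero")
  a_pct <- 100 * a_raw / tot
  c(a_pct = a_pct, c_pct = 100 - a_pct)   # complement keeps the sum exact
}

# curve-peeling starting values: fit the tail for the long component, then
# the early-time residual for the short component
peel_start <- function(t, y, tail_start) {
  late <- t >= tail_start
  if (sum(late) < 2) late <- t >= stats::median(t)
  fl <- stats::lm(log(y[late]) ~ t[late])
  c0 <- exp(stats::coef(fl)[[1]])
  d0 <- max(-stats::coef(fl)[[2]], 1e-8)
  resid <- y - c0 * exp(-d0 * t)
  early <- !late & resid > 0.01 * max(y)
  if (sum(early) >= 2) {
    fe <- stats::lm(log(resid[early]) ~ t[early])
    a0 <- exp(stats::coef(fe)[[1]])
    b0 <- max(-stats::coef(fe)[[2]], 10 * d0)
  } else {
    a0 <- 0.2 * c0
    b0 <- 100 * d0
  }
  list(a = a0, b = b0, c = c0, d = d0)
}

#' Fit a biexponential washout curve to a TAC
#'
#' Constrained nonlinear least squares of
#' f(t) = a exp(-b t) + c exp(-d t) on a decay-corrected TAC.
#' Positivity is enforced by optimizing log-amplitudes and log-rates
#' (Levenberg-Marquardt via \pkg{minpack.lm}), initialized by classic
#' curve peeling: the tail beyond \code{tail_start} sets the long
#' component, the early residual sets the short one. Returned rates always
#' satisfy b > d. The fit falls back to a single exponential when the
#' short component is unsupported: too few early/late points, short
#' amplitude fraction below 1\%, rate ratio b/d below \code{min_ratio}
#' (components unresolvable), or the short-amplitude confidence interval
#' including zero.
#'
#' @param x a \code{\link{tac}}; decay-corrected values are used when
#'   present.
#' @param weights "none" (default) or "poisson": inverse counting
#'   variance, raw/dc^2 when the TAC carries both raw and decay-corrected
#'   columns (decay correction inflates late-time variance), else
#'   1/value.
#' @param tail_start hours after which points are treated as pure long
#'   component for initialization.
#' @param min_ratio minimum resolvable b/d ratio.
#' @param early_cutoff,late_cutoff hours defining the early/late coverage
#'   required for a biexponential fit (at least two points at or before
#'   \code{early_cutoff} and one at or after \code{late_cutoff}).
#' @return object of class \code{biexp_fit}: amplitudes \code{a}, \code{c}
#'   (data units), rates \code{b}, \code{d} (1/h), percent fractions
#'   \code{a_pct}, \code{c_pct}, half-lives \code{t_half_short},
#'   \code{t_half_long} (hours), \code{model} ("biexponential" or
#'   "monoexponential"), \code{rss}, \code{converged}, \code{status}.
#' @export
fit_biexponential <- function(x, weights = c("none", "poisson"),
                              tail_start = 100, min_ratio = 5,
                              early_cutoff = 5, late_cutoff = 168) {
  stopifnot(inherits(x, "tac"))
  weights <- match.arg(weights)
  t <- x$time_hours
  y <- tac_values(x)
  if (length(t) < 3) stop("need at least 3 points")
  if (any(y < 0)) stop("negative activity values")
  w <- if (weights == "poisson") {
    # Poisson counting variance: var(y_dc) ~ y_dc^2 / raw counts, so the
    # inverse-variance weight is raw / dc^2; without raw counts (already
    # corrected data) it reduces to 1 / value
    raw <- x$activity
    if (!all(is.na(x$activity_dc)) && all(raw > 0)) {
      raw / pmax(y, 1e-12)^2
    } else {
      1 / pmax(y, 1e-12)
    }
  } else {
    rep(1, length(y))
  }
  spans <- sum(t <= early_cutoff) >= 2 && sum(t >= late_cutoff) >= 1
  status <- character(0)

  fit_mono <- function(why) {
    pos <- y > 0
    if (sum(pos) < 3) stop("need at least 3 positive points")
    fl <- stats::lm(log(y[pos]) ~ t[pos])
    c0 <- exp(stats::coef(fl)[[1]])
    d0 <- -stats::coef(fl)[[2]]
    boundary <- FALSE
    if (d0 <= 1e-10) { d0 <- 1e-10; boundary <- TRUE }
    df <- data.frame(t = t, y = y, w = w)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ exp(lc - exp(ld) * t), data = df,
                        start = list(lc = log(c0), ld = log(d0)),
                        weights = df$w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      cc <- c0; dd <- d0
      status <- c(why, "log_linear_fallback")
    } else {
      cf <- stats::coef(fit)
      cc <- exp(cf[["lc"]]); dd <- exp(cf[["ld"]])
      status <- why
    }
    if (dd <= 1e-9 || boundary) status <- c(status, "rate_at_zero_boundary")
    rss <- sum(w * (y - cc * exp(-dd * t))^2)
    structure(list(a = NA_real_, b = NA_real_, c = cc, d = dd,
                   a_pct = NA_real_, c_pct = 100,
                   t_half_short = NA_real_,
                   t_half_long = if (dd > 1e-9) half_life(dd) else Inf,
                   model = "monoexponential", rss = rss,
                   converged = TRUE, status = status),
              class = "biexp_fit")
  }

  if (!spans) return(fit_mono("insufficient_early_late_coverage"))
  if (length(t) < 5) return(fit_mono("fewer_than_5_points"))

  st <- tryCatch(peel_start(t, y, tail_start), error = function(e) NULL)
  if (is.null(st) || st$a <= 0) return(fit_mono("peeling_failed"))
  df <- data.frame(t = t, y = y, w = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ exp(la - exp(lb) * t) + exp(lc - exp(ld) * t),
                      data = df,
                      start = list(la = log(st$a), lb = log(st$b),
                                   lc = log(st$c), ld = log(st$d)),
                      weights = df$w,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(fit_mono("biexponential_did_not_converge"))
  cf <- stats::coef(fit)
  a <- exp(cf[["la"]]); b <- exp(cf[["lb"]])
  cc <- exp(cf[["lc"]]); d <- exp(cf[["ld"]])
  swapped <- b < d
  if (swapped) { tmp <- a; a <- cc; cc <- tmp; tmp <- b; b <- d; d <- tmp }
  fr <- normalize_fractions(a, cc)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(la = NA, lb = NA, lc = NA, ld = NA))
  se_la <- if (swapped) se[["lc"]] else se[["la"]]
  # delta method on a = exp(la): CI includes 0 iff la CI is unbounded below
  a_ci_zero <- !is.na(se_la) && se_la >= 1 / stats::qnorm(0.975)
  if (fr[["a_pct"]] < 1 || b / d < min_ratio || a_ci_zero) {
    why <- if (fr[["a_pct"]] < 1) "short_fraction_below_1pct"
           else if (b / d < min_ratio) "components_unresolvable"
           else "short_amplitude_ci_includes_zero"
    return(fit_mono(why))
  }
  rss <- sum(w * stats::residuals(fit)^2)
  structure(list(a = a, b = b, c = cc, d = d,
                 a_pct = fr[["a_pct"]], c_pct = fr[["c_pct"]],
                 t_half_short = half_life(b), t_half_long = half_life(d),
                 model = "biexponential", rss = rss,
                 converged = TRUE, status = "ok"),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  if (x$model == "biexponential") {
    # report half-lives at conventional precision; full precision is kept
    cat(sprintf("Biexponential fit: a%%=%.1f b=%.4g/h c%%=%.1f d=%.4g/h\n",
                x$a_pct, x$b, x$c_pct, x$d))
    cat(sprintf("  T1/2 short = %.2f h, T1/2 long = %.0f h (rss %.3g)\n",
                x$t_half_short, x$t_half_long, x$rss))
  } else {
    cat(sprintf("Monoexponential fit: d=%.4g/h, T1/2 long = %.0f h (rss %.3g)\n",
                x$d, x$t_half_long, x$rss))
    cat("  status:", paste(x$status, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tabulate fits in the reference-table layout
#'
#' @param fits named list of \code{biexp_fit} objects (names = subject
#'   ids).
#' @param group optional group label(s), recycled.
#' @return data frame with columns subject, group, a, b, c, d, a_pct,
#'   c_pct, t12s_hours, t12l_hours, model, rss.
#' @export
fits_to_table <- function(fits, group = NA_character_) {
  stopifnot(length(fits) >= 1)
  subj <- if (is.null(names(fits))) as.character(seq_along(fits)) else names(fits)
  group <- rep_len(group, length(fits))
  do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(subject = subj[i], group = group[i],
               a = f$a, b = f$b, c = f$c, d = f$d,
               a_pct = f$a_pct, c_pct = f$c_pct,
               t12s_hours = f$t_half_short, t12l_hours = f$t_half_long,
               model = f$model, rss = f$rss)
  }))
}
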