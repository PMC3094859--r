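#' Build the cohort analysis report
#'
#' Combines a fit table (\code{\link{fits_to_table}} layout or the
#' packaged reference table) and an H:WB table into group summaries
#' (mean +/- SEM), between-group Mann-Whitney comparisons with Bonferroni
#' correction, paired within-group short-vs-long comparisons, and
#' kinetic-model validity flags for each long half-life.
#'
#' Following the reference-table convention, subjects fit
#' monoexponentially (no resolvable short component) are excluded from
#' the fractional-washout and short-half-life averages but kept in the
#' long-half-life averages.
#'
#' @param fits data frame with columns group, and either
#'   \code{t12s_hours}/\code{t12l_hours} or \code{b_per_hour}/
#'   \code{d_per_hour} (half-lives then derived), plus \code{a_pct},
#'   \code{c_pct}.
#' @param hwb data frame with columns group and \code{hwb_pct} plus
#'   \code{session} or \code{time_hours}; only the earliest session per
#'   subject enters the retention summary.
#' @param params a \code{\link{kinetic_model_params}} supplying validity
#'   bounds (and the DIRF half-life for the clearance-ratio line).
#' @param paired_test "wilcoxon" (signed rank, paired by subject,
#'   default) or "mann_whitney" for the within-group short-vs-long
#'   comparison.
#' @return object of class \code{spectac_report}: list with
#'   \code{summaries} (data frame), \code{comparisons} (data frame),
#'   \code{validity} (data frame), \code{clearance_ratio}, and
#'   \code{markdown} (character).
#' @export
build_report <- function(fits, hwb = NULL, params = kinetic_model_params(),
                         paired_test = c("wilcoxon", "mann_whitney")) {
  paired_test <- match.arg(paired_test)
  stopifnot(is.data.frame(fits), "group" %in% names(fits))
  if (!"t12l_hours" %in% names(fits)) {
    if (!"d_per_hour" %in% names(fits))
      stop("fits must carry t12l_hours or d_per_hour")
    fits$t12l_hours <- half_life(fits$d_per_hour)
    fits$t12s_hours <- ifelse(is.na(fits$b_per_hour), NA,
                              half_life(fits$b_per_hour))
  }
  mono <- is.na(fits$t12s_hours)
  groups <- unique(fits$group)

  sum_rows <- list()
  for (g in groups) {
    gi <- fits$group == g
    add <- function(var, vals) {
      s <- summarize_group(vals, g, var)
      data.frame(group = g, variable = var, n = s$n, mean = s$mean,
                 sem = s$sem)
    }
    sum_rows[[length(sum_rows) + 1]] <- add("t_half_long_hours",
                                            fits$t12l_hours[gi])
    sum_rows[[length(sum_rows) + 1]] <- add("t_half_short_hours",
                                            fits$t12s_hours[gi & !mono])
    if ("c_pct" %in% names(fits))
      sum_rows[[length(sum_rows) + 1]] <- add("long_fraction_pct",
                                              fits$c_pct[gi & !mono])
  }

  hwb0 <- NULL
  if (!is.null(hwb)) {
    stopifnot("group" %in% names(hwb), "hwb_pct" %in% names(hwb))
    ord <- if ("session" %in% names(hwb)) hwb$session else hwb$time_hours
    first <- ord == min(ord)
    hwb0 <- hwb[first & !is.na(hwb$hwb_pct), ]
    for (g in unique(hwb0$group)) {
      s <- summarize_group(hwb0$hwb_pct[hwb0$group == g], g, "hwb_0h_pct")
      sum_rows[[length(sum_rows) + 1]] <-
        data.frame(group = g, variable = "hwb_0h_pct", n = s$n,
                   mean = s$mean, sem = s$sem)
    }
  }
  summaries <- do.call(rbind, sum_rows)

  comparisons <- NULL
  notes <- character(0)
  if (length(groups) == 2) {
    g1 <- groups[1]; g2 <- groups[2]
    specs <- list(
      list(var = "t_half_long_hours",
           x = fits$t12l_hours[fits$group == g1],
           y = fits$t12l_hours[fits$group == g2]),
      list(var = "t_half_short_hours",
           x = fits$t12s_hours[fits$group == g1 & !mono],
           y = fits$t12s_hours[fits$group == g2 & !mono]))
    if (!is.null(hwb0))
      specs[[3]] <- list(var = "hwb_0h_pct",
                         x = hwb0$hwb_pct[hwb0$group == g1],
                         y = hwb0$hwb_pct[hwb0$group == g2])
    fam <- length(specs)
    comp_rows <- lapply(specs, function(s) {
      r <- mann_whitney(s$x, s$y, s$var, family = fam)
      data.frame(variable = s$var, comparison = paste(g1, "vs", g2),
                 test = r$test, statistic = r$statistic, p_raw = r$p_raw,
                 p_adjusted = r$p_adjusted, family = fam,
                 method = r$method)
    })
    # within-group short vs long component (paired by subject)
    for (g in groups) {
      gi <- fits$group == g & !mono
      if (sum(gi) >= 2) {
        pr <- if (paired_test == "wilcoxon") {
          suppressWarnings(stats::wilcox.test(fits$t12s_hours[gi],
                                              fits$t12l_hours[gi],
                                              paired = TRUE))
        } else {
          suppressWarnings(stats::wilcox.test(fits$t12s_hours[gi],
                                              fits$t12l_hours[gi]))
        }
        comp_rows[[length(comp_rows) + 1]] <-
          data.frame(variable = "t_half_short_vs_long",
                     comparison = g,
                     test = if (paired_test == "wilcoxon")
                       "Wilcoxon signed rank" else "Mann-Whitney U",
                     statistic = unname(pr$statistic), p_raw = pr$p.value,
                     p_adjusted = bonferroni(pr$p.value, 2), family = 2,
                     method = "as computed")
      }
    }
    comparisons <- do.call(rbind, comp_rows)
  } else {
    notes <- c(notes, sprintf(
      "only group(s) %s present; between-group comparisons skipped",
      paste(groups, collapse = ", ")))
  }

  validity <- data.frame(
    subject = if ("subject" %in% names(fits)) fits$subject else
      if ("dog" %in% names(fits)) fits$dog else seq_len(nrow(fits)),
    group = fits$group,
    t12l_hours = fits$t12l_hours,
    model_valid = fits$t12l_hours >= params$lower_bound &
      fits$t12l_hours <= params$upper_bound)

  ratio <- leakage_to_dirf_ratio(mean(fits$t12l_hours), params$dirf_half_life)

  md <- c("# Radiolabel clearance report", "",
          "## Group summaries (mean +/- SEM)", "",
          sprintf("- %s %s: %.2f +/- %.2f (n = %d)",
                  summaries$group, summaries$variable, summaries$mean,
                  summaries$sem, summaries$n), "")
  if (!is.null(comparisons))
    md <- c(md, "## Comparisons (raw and Bonferroni-adjusted p)", "",
            sprintf("- %s [%s]: %s p_raw = %.4g, p_adj = %.4g",
                    comparisons$variable, comparisons$comparison,
                    comparisons$test, comparisons$p_raw,
                    comparisons$p_adjusted), "")
  md <- c(md,
          sprintf("Mean long half-life / DIRF half-life = %.1f (DIRF %.3g h)",
                  ratio, params$dirf_half_life),
          sprintf("Validity window: %g-%g h; %d/%d long half-lives inside",
                  params$lower_bound, params$upper_bound,
                  sum(validity$model_valid), nrow(validity)),
          if (length(notes)) paste("Note:", notes) else NULL)

  structure(list(summaries = summaries, comparisons = comparisons,
                 validity = validity, clearance_ratio = ratio,
                 markdown = paste(md, collapse = "\n")),
            class = "spectac_report")
}

#' @export
print.spectac_report <- function(x, ...) {
  cat(x$markdown, "\n")
  invisible(x)
}
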