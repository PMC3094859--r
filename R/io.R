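#' Read and write TAC CSV files
#'
#' The TAC dialect is comma-separated UTF-8 with columns
#' \code{time_hours, activity, activity_dc, subject, group}; one file may
#' hold several subjects.
#'
#' @param tacs a single \code{\link{tac}} or a list of them.
#' @param path file path.
#' @return \code{write_tac_csv} returns the path invisibly;
#'   \code{read_tac_csv} returns a named list of \code{tac} objects keyed
#'   by subject.
#' @name tac_csv
NULL

#' @rdname tac_csv
#' @export
write_tac_csv <- function(tacs, path) {
  if (inherits(tacs, "tac")) tacs <- list(tacs)
  rows <- do.call(rbind, lapply(tacs, function(x) {
    data.frame(time_hours = x$time_hours, activity = x$activity,
               activity_dc = x$activity_dc,
               subject = attr(x, "subject"), group = attr(x, "group"))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname tac_csv
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_hours", "activity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed TAC CSV, missing column(s): ", paste(miss, collapse = ", "))
  if (!"subject" %in% names(df)) df$subject <- "1"
  if (!"group" %in% names(df)) df$group <- NA_character_
  out <- lapply(split(df, df$subject), function(s) {
    s <- s[order(s$time_hours), ]
    tac(s$time_hours, s$activity,
        activity_dc = if ("activity_dc" %in% names(s)) s$activity_dc else NULL,
        subject = s$subject[1], group = s$group[1])
  })
  out
}

#' Write / read a dynamic image series as NIfTI
#'
#' The voxel data go to a single 4-D NIfTI file; frame times (hours) and
#' the noise tag go to a JSON sidecar next to it.
#'
#' @param series a \code{dynamic_image_series}.
#' @param path output path ending in .nii or .nii.gz.
#' @return \code{write_image_series} returns \code{path} invisibly;
#'   \code{read_image_series} returns a \code{dynamic_image_series}
#'   (geometry reduced to grid dimensions and voxel size).
#' @name image_series_io
NULL

#' @rdname image_series_io
#' @export
write_image_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_image_series"))
  vox <- series$geometry$voxel_size_mm
  img <- RNifti::asNifti(series$data, pixdim = c(rep(vox, 3), 1))
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(time_hours = series$time_hours,
                            noise = series$noise,
                            voxel_size_mm = vox),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname image_series_io
#' @export
read_image_series <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  data <- array(as.numeric(img), dim = dim(img))
  dm <- dim(data)[1:3]
  geom <- phantom_geometry(dim = dm, radius = 1,
                           voxel_size_mm = meta$voxel_size_mm)
  structure(list(data = data, time_hours = meta$time_hours,
                 geometry = geom, noise = meta$noise),
            class = "dynamic_image_series")
}

#' Pipeline configuration
#'
#' One JSON-serializable object holding every tunable the pipeline uses;
#' round-trips losslessly through \code{\link{write_config}} /
#' \code{\link{read_config}} so a run can be reproduced from its logged
#' config.
#'
#' @param physical_half_life nuclide half-life, hours.
#' @param voi_threshold VOI threshold fraction of the frame maximum.
#' @param C,dirf_half_life,bounds_preset kinetic-model inputs (see
#'   \code{\link{kinetic_model_params}}).
#' @param fit_weights,fit_tail_start,fit_min_ratio fitting options (see
#'   \code{\link{fit_biexponential}}).
#' @param injection_offset_hours lag between injection and the first
#'   acquisition; used only by the synthetic generator's bookkeeping.
#' @param seed integer seed for all simulation randomness.
#' @param n_subjects named list/vector: subjects per group.
#' @return object of class \code{pipeline_config} (a named list).
#' @export
pipeline_config <- function(physical_half_life = in111_half_life_hours,
                            voi_threshold = 0.30,
                            C = log(2) / 1434, dirf_half_life = 18,
                            bounds_preset = "60d",
                            fit_weights = "none", fit_tail_start = 100,
                            fit_min_ratio = 5,
                            injection_offset_hours = 0.6,
                            seed = 1L,
                            n_subjects = c(epicardial = 9L,
                                           endocardial = 10L)) {
  structure(list(physical_half_life = physical_half_life,
                 voi_threshold = voi_threshold,
                 C = C, dirf_half_life = dirf_half_life,
                 bounds_preset = bounds_preset,
                 fit_weights = fit_weights,
                 fit_tail_start = fit_tail_start,
                 fit_min_ratio = fit_min_ratio,
                 injection_offset_hours = injection_offset_hours,
                 seed = as.integer(seed),
                 n_subjects = as.list(n_subjects)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  cfg[names(lst)] <- lst
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
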