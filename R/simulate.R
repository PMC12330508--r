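#' Simulate a vertex-wise BOLD run
#'
#' Forward model: `signal = baseline * (1 + sum_c amp_c(vertex)/100 *
#' regressor_c(volume)) + noise`, where `amp_c` is the subject's
#' ground-truth percent-signal-change field for category `c` under the
#' run's task (patch profile plus the non-selective VOTC response; the
#' one-back task multiplies amplitudes by the attention gain), and the
#' regressors are the same HRF-convolved boxcars the GLM uses. Noise is
#' Gaussian per vertex-volume, optionally AR(1) along time.
#'
#' @param mesh A `votc_mesh`.
#' @param mask A `votc_mask`.
#' @param layout A `subject_layout` (carries amplitudes, baseline,
#'   noise SD, AR(1) coefficient).
#' @param design A `localizer_design` (its `task` selects the amplitudes).
#' @param params HRF parameters.
#' @param noise_sd Noise SD in signal units; defaults to the layout's.
#' @param seed Integer RNG seed.
#' @return An object of class `bold_timeseries`: list with `subject_id`,
#'   `data` (vertex x volume matrix), `design`, `noise_sd`.
#' @export
simulate_timeseries <- function(mesh, mask, layout, design,
                                params = hrf_params(),
                                noise_sd = NULL, seed = 1L) {
  stopifnot(inherits(mesh, "votc_mesh"), inherits(mask, "votc_mask"),
            inherits(layout, "subject_layout"),
            inherits(design, "localizer_design"))
  if (is.null(noise_sd)) noise_sd <- layout$noise_sd
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)

  cats <- intersect(setdiff(localizer_categories(), "blank"),
                    unique(design$trials$category))
  nv <- design$n_volumes
  signal <- matrix(layout$baseline, mesh$n_vertices, nv)
  if (length(cats)) {
    A <- vapply(cats, function(cc) {
      amplitude_field(mesh, mask, layout, cc, task = design$task)
    }, numeric(mesh$n_vertices))                      # vertex x category
    R <- t(vapply(cats, function(cc) {
      convolve_regressor(design, cc, params)
    }, numeric(nv)))                                  # category x volume
    signal <- signal + (layout$baseline / 100) * (A %*% R)
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, {
      e <- matrix(stats::rnorm(mesh$n_vertices * nv), mesh$n_vertices, nv)
      if (layout$ar1 != 0) {
        e <- t(apply(e, 1L, function(z) {
          as.numeric(stats::filter(z, layout$ar1, method = "recursive"))
        })) * sqrt(1 - layout$ar1^2)
      }
      e * noise_sd
    })
    signal <- signal + noise
  }
  structure(
    list(subject_id = layout$subject_id, data = signal, design = design,
         noise_sd = noise_sd),
    class = "bold_timeseries"
  )
}

#' @export
print.bold_timeseries <- function(x, ...) {
  cat(sprintf("<bold_timeseries: %s, %d vertices x %d volumes, noise sd %.3g>\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$noise_sd))
  invisible(x)
}

#' Write / read a time series as a flat binary array with JSON sidecar
#'
#' The data matrix is stored as little-endian doubles (vertex-major) in
#' `<path>.dat`; dimensions, tr, task and subject are stored in
#' `<path>.json`.
#'
#' @param ts A `bold_timeseries`.
#' @param path Path stem (without extension).
#' @return `write_timeseries` returns the stem invisibly;
#'   `read_timeseries` returns a `bold_timeseries` (with a minimal design
#'   stub carrying `tr`, `n_volumes`, `task`).
#' @export
write_timeseries <- function(ts, path) {
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(ts$data), con, size = 8L, endian = "little")
  jsonlite::write_json(
    list(subject_id = ts$subject_id, n_vertices = nrow(ts$data),
         n_volumes = ncol(ts$data), tr = ts$design$tr,
         task = ts$design$task, noise_sd = ts$noise_sd),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n_vertices * meta$n_volumes
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  dat <- matrix(readBin(con, "double", n, size = 8L, endian = "little"),
                meta$n_vertices, meta$n_volumes)
  design <- structure(
    list(trials = data.frame(onset = numeric(0), duration = numeric(0),
                             category = character(0)),
         tr = meta$tr, n_volumes = meta$n_volumes, task = meta$task,
         run_id = NA),
    class = "localizer_design"
  )
  structure(
    list(subject_id = meta$subject_id, data = dat, design = design,
         noise_sd = meta$noise_sd),
    class = "bold_timeseries"
  )
}
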