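#' Stimulus categories of the localizer
#'
#' Five stimulus categories plus the unmodeled blank baseline.
#' @export
localizer_categories <- function() {
  c("text", "pseudofont", "face", "object", "limb", "blank")
}

#' Build a randomized localizer run design
#'
#' One run consists of `n_trials` back-to-back 4-second trials (each trial
#' is a sequence of four 800 ms images with 200 ms gaps; at this level of
#' description a trial is a 4 s boxcar of its category). Category counts
#' are balanced to within one trial and the order is randomized. "blank"
#' trials carry no regressor and serve as the baseline.
#'
#' @param n_trials Number of trials (>= 6, at least one per category).
#' @param tr Repetition time in seconds.
#' @param seed Integer RNG seed; the design is a pure function of
#'   `(n_trials, tr, seed, task, run_id)`.
#' @param task `"one_back"` or `"fixation"`.
#' @param run_id Run identifier.
#'
#' @return An object of class `localizer_design`: list with `trials`
#'   (data.frame: onset, duration, category), `tr`, `n_volumes`, `task`,
#'   `run_id`. `n_volumes` covers the stimulus time plus a 16 s tail for
#'   the haemodynamic response.
#' @examples
#' d <- make_design(65, tr = 1.19, seed = 1)
#' sum(d$trials$duration)  # 260 s of stimulus time
#' @export
make_design <- function(n_trials, tr, seed = 1L,
                        task = c("one_back", "fixation"), run_id = 1L) {
  task <- match.arg(task)
  cats <- localizer_categories()
  if (n_trials < length(cats)) {
    stop("`n_trials` must be >= ", length(cats),
         " (one trial per category)", call. = FALSE)
  }
  trial_dur <- 4
  with_seed(seed, {
    base <- n_trials %/% length(cats)
    extra <- n_trials %% length(cats)
    counts <- rep(base, length(cats)) +
      as.integer(seq_along(cats) %in% sample(seq_along(cats), extra))
    order <- sample(rep(cats, counts))
    trials <- data.frame(
      onset = (seq_len(n_trials) - 1) * trial_dur,
      duration = trial_dur,
      category = order,
      stringsAsFactors = FALSE
    )
    structure(
      list(trials = trials, tr = tr,
           n_volumes = as.integer(ceiling((n_trials * trial_dur + 16) / tr)),
           task = task, run_id = run_id),
      class = "localizer_design"
    )
  })
}

#' @export
print.localizer_design <- function(x, ...) {
  cat(sprintf("<localizer_design: %d trials, tr %.3g s, %d volumes, %s task, run %s>\n",
              nrow(x$trials), x$tr, x$n_volumes, x$task, x$run_id))
  invisible(x)
}

#' Write / read a design as a BIDS-style events table
#'
#' Tab-separated file with columns `onset`, `duration`, `trial_type`.
#'
#' @param design A `localizer_design`.
#' @param path File path.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns the events as a data.frame.
#' @export
write_events_tsv <- function(design, path) {
  ev <- data.frame(onset = design$trials$onset,
                   duration = design$trials$duration,
                   trial_type = design$trials$category)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
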