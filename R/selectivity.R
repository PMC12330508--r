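#' Extract a response profile from PSC maps within an ROI
#'
#' One record per stimulus category: the mean percent signal change over
#' the ROI's vertices.
#'
#' @param psc_maps Named list of `vertex_map`s (kind `"psc"`), one per
#'   stimulus category.
#' @param roi A non-empty `votc_roi`.
#' @param participant Participant id (defaults to the ROI's subject tag).
#' @param roi_task Task whose data defined the ROI (`"one_back"`,
#'   `"fixation"`, `"all_runs"`, or `"n/a"` for group/template ROIs).
#' @param map_task Task whose data produced the PSC maps.
#' @return A data.frame with columns `participant`, `roi_name`,
#'   `roi_task`, `map_task`, `category`, `psc` (the long response-record
#'   layout).
#' @export
extract_profile <- function(psc_maps, roi,
                            participant = roi$subject_id,
                            roi_task = "all_runs", map_task = "fixation") {
  stopifnot(inherits(roi, "votc_roi"))
  if (length(roi$vertices) == 0L) {
    stop("empty ROI: response profile undefined (region not identifiable)",
         call. = FALSE)
  }
  cats <- setdiff(localizer_categories(), "blank")
  missing <- setdiff(cats, names(psc_maps))
  if (length(missing)) {
    stop("missing category maps: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  psc <- vapply(cats, function(cc) {
    mean(psc_maps[[cc]]$values[roi$vertices], na.rm = TRUE)
  }, numeric(1))
  data.frame(participant = participant, roi_name = roi$name,
             roi_task = roi_task, map_task = map_task,
             category = cats, psc = unname(psc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Text-selectivity index of a response profile
#'
#' `index = (T - O) / (|T| + |O|)` with `T` the text PSC and `O` the mean
#' PSC of the other stimulus categories (pseudofonts included, blank
#' excluded). Bounded in `[-1, 1]`, positive iff the text response
#' exceeds the mean other response; the degenerate `0/0` case is defined
#' as 0 and flagged.
#'
#' @param profile A profile data.frame from [extract_profile()] (one
#'   participant/ROI/map-task cell).
#' @return A one-row data.frame: `participant`, `roi_name`, `roi_task`,
#'   `map_task`, `index`, `degenerate`.
#' @export
selectivity_index <- function(profile) {
  stopifnot(is.data.frame(profile), "category" %in% names(profile))
  if (!"text" %in% profile$category || nrow(profile) < 2L) {
    stop("profile must contain text and at least one other category",
         call. = FALSE)
  }
  T_ <- profile$psc[profile$category == "text"]
  O_ <- mean(profile$psc[profile$category != "text"])
  denom <- abs(T_) + abs(O_)
  degenerate <- denom == 0
  idx <- if (degenerate) 0 else (T_ - O_) / denom
  data.frame(participant = profile$participant[1],
             roi_name = profile$roi_name[1],
             roi_task = profile$roi_task[1],
             map_task = profile$map_task[1],
             index = idx, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-task cross-validation of ROI tuning
#'
#' For every subject and every held-out cell (ROI defined on one task,
#' responses measured with the other task's data), asks whether text has
#' the maximum mean PSC among the stimulus categories, and aggregates the
#' fraction of subjects for which it does in all their held-out cells.
#' Subjects missing a task ROI (empty) are excluded and logged.
#'
#' @param task_rois Named list `list(one_back = , fixation = )` of
#'   per-subject ROI lists.
#' @param task_psc_maps Named list `list(one_back = , fixation = )`; each
#'   element is a per-subject list of named per-category PSC maps.
#' @return List with `table` (data.frame: participant, roi_task,
#'   map_task, text_psc, max_other_psc, text_is_max), `fraction`
#'   (subjects where text wins every held-out cell), `excluded`
#'   (participant ids).
#' @export
crossval_tuning <- function(task_rois, task_psc_maps) {
  tasks <- c("one_back", "fixation")
  stopifnot(all(tasks %in% names(task_rois)),
            all(tasks %in% names(task_psc_maps)))
  n_sub <- length(task_rois[[1]])
  rows <- list()
  excluded <- character(0)
  for (i in seq_len(n_sub)) {
    rois <- lapply(tasks, function(tk) task_rois[[tk]][[i]])
    names(rois) <- tasks
    is_empty <- vapply(rois, function(r) length(r$vertices) == 0L, TRUE)
    if (any(is_empty)) {
      id <- rois[[which(is_empty)[1]]]$subject_id
      excluded <- c(excluded, id)
      message("crossval_tuning: excluding ", id, " (empty task ROI)")
      next
    }
    for (roi_task in tasks) {
      map_task <- setdiff(tasks, roi_task)
      prof <- extract_profile(task_psc_maps[[map_task]][[i]],
                              rois[[roi_task]],
                              roi_task = roi_task, map_task = map_task)
      text_psc <- prof$psc[prof$category == "text"]
      max_other <- max(prof$psc[prof$category != "text"])
      rows[[length(rows) + 1L]] <- data.frame(
        participant = prof$participant[1], roi_task = roi_task,
        map_task = map_task, text_psc = text_psc,
        max_other_psc = max_other,
        text_is_max = text_psc > max_other,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  frac <- if (is.null(tab)) NA_real_ else {
    mean(tapply(tab$text_is_max, tab$participant, all))
  }
  list(table = tab, fraction = frac, excluded = excluded)
}

#' Compare native, group, and template ROI families
#'
#' For each ROI family, extracts per-subject response profiles and
#' selectivity indices, then contrasts each non-native family against the
#' native one by within-subject differencing (native minus family) with a
#' paired t-test on the selectivity index and on the text response.
#' The subject is the unit of analysis (the paired differencing is the
#' exact balanced-design surrogate for a subject random intercept).
#'
#' Native ROIs are paired with each subject's native-space maps;
#' group/template ROIs (fixed vertex sets in template space) are applied
#' to every subject's template-space maps. Subjects with an empty native
#' ROI are dropped from all families.
#'
#' @param native_rois Per-subject list of native `votc_roi`.
#' @param family_rois Named list of fixed template-space `votc_roi`
#'   objects (group and/or imported template ROIs).
#' @param native_psc_maps Per-subject list of named per-category
#'   native-space PSC maps.
#' @param template_psc_maps Per-subject list of named per-category
#'   template-space PSC maps.
#' @param map_task Label recorded for the maps' task provenance.
#' @return List with `profiles` (long data.frame of mean PSC per family x
#'   category), `selectivity` (per subject x family), `paired`
#'   (per family: estimate, se, t, dof for native-minus-family
#'   differences in selectivity index and text PSC).
#' @export
compare_roi_families <- function(native_rois, family_rois,
                                 native_psc_maps, template_psc_maps,
                                 map_task = "fixation") {
  usable <- which(vapply(native_rois,
                         function(r) length(r$vertices) > 0L, TRUE))
  if (length(usable) == 0L) {
    stop("no subjects with a usable native ROI", call. = FALSE)
  }
  profiles <- list()
  sel <- list()
  for (i in usable) {
    p_nat <- extract_profile(native_psc_maps[[i]], native_rois[[i]],
                             roi_task = "all_runs", map_task = map_task)
    p_nat$family <- "native"
    profiles[[length(profiles) + 1L]] <- p_nat
    s <- selectivity_index(p_nat)
    s$family <- "native"
    sel[[length(sel) + 1L]] <- s
    for (fam in names(family_rois)) {
      roi <- family_rois[[fam]]
      if (length(roi$vertices) == 0L) next
      p <- extract_profile(template_psc_maps[[i]], roi,
                           participant = native_rois[[i]]$subject_id,
                           roi_task = "n/a", map_task = map_task)
      p$family <- fam
      profiles[[length(profiles) + 1L]] <- p
      s <- selectivity_index(p)
      s$participant <- native_rois[[i]]$subject_id
      s$family <- fam
      sel[[length(sel) + 1L]] <- s
    }
  }
  profiles <- do.call(rbind, profiles)
  sel <- do.call(rbind, sel)
  fams <- setdiff(unique(sel$family), "native")
  if (length(fams) == 0L) {
    stop("no usable comparison family", call. = FALSE)
  }
  paired <- do.call(rbind, lapply(fams, function(fam) {
    rbind(
      paired_stats(sel, profiles, fam, "index"),
      paired_stats(sel, profiles, fam, "text_psc")
    )
  }))
  list(profiles = profiles, selectivity = sel, paired = paired)
}

# Within-subject native-minus-family paired t statistic for one measure.
paired_stats <- function(sel, profiles, fam, measure) {
  if (measure == "index") {
    x <- sel$index[sel$family == "native"]
    y <- sel$index[sel$family == fam]
  } else {
    p_n <- profiles[profiles$family == "native" &
                      profiles$category == "text", ]
    p_f <- profiles[profiles$family == fam &
                      profiles$category == "text", ]
    x <- p_n$psc
    y <- p_f$psc
  }
  d <- x - y
  n <- length(d)
  se <- stats::sd(d) / sqrt(n)
  data.frame(family = fam, measure = measure,
             estimate = mean(d), se = se,
             t = mean(d) / se, dof = n - 1,
             stringsAsFactors = FALSE)
}

#' Paired comparison of task-specific ROI sizes
#'
#' Paired t statistic of one-back minus fixation ROI sizes across
#' subjects (positive when attention enlarges the region).
#'
#' @param oneback_rois,fixation_rois Per-subject lists of `votc_roi`.
#' @return List with `mean_oneback`, `mean_fixation`, `t`, `dof`,
#'   `sizes` (data.frame).
#' @export
task_size_test <- function(oneback_rois, fixation_rois) {
  stopifnot(length(oneback_rois) == length(fixation_rois))
  a <- vapply(oneback_rois, function(r) length(r$vertices), integer(1))
  b <- vapply(fixation_rois, function(r) length(r$vertices), integer(1))
  d <- a - b
  se <- stats::sd(d) / sqrt(length(d))
  list(mean_oneback = mean(a), mean_fixation = mean(b),
       t = mean(d) / se, dof = length(d) - 1,
       sizes = data.frame(participant = vapply(oneback_rois,
                                               `[[`, "", "subject_id"),
                          one_back = a, fixation = b))
}

#' Write response or selectivity records as long-format CSV
#'
#' Columns exactly: `participant`, `roi_name`, `roi_task`, `map_task`,
#' `category`, `value`. Selectivity records get category `"selectivity"`.
#'
#' @param records A profiles or selectivity data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  if ("psc" %in% names(records)) {
    out <- data.frame(participant = records$participant,
                      roi_name = records$roi_name,
                      roi_task = records$roi_task,
                      map_task = records$map_task,
                      category = records$category,
                      value = records$psc)
  } else {
    out <- data.frame(participant = records$participant,
                      roi_name = records$roi_name,
                      roi_task = records$roi_task,
                      map_task = records$map_task,
                      category = "selectivity",
                      value = records$index)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
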