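#' Default end-to-end run configuration
#'
#' A single configuration object drives the whole pipeline: mesh, mask,
#' cohorts, localizer design, analysis thresholds, and the master seed.
#'
#' @param mesh_size Grid side length (vertices).
#' @param spacing Grid spacing, mm.
#' @param cohorts Named list of [cohort_config()] objects.
#' @param n_trials Trials per run.
#' @param tr Repetition time, s.
#' @param runs_per_task Localizer runs per task.
#' @param t_threshold ROI-defining t threshold.
#' @param prob_threshold Group-ROI probability threshold (strict).
#' @param drift_order Polynomial drift order per run.
#' @param seed Master seed; all per-subject seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mesh_size = 48, spacing = 1,
                       cohorts = list(children = cohort_config("children"),
                                      adults = cohort_config("adults")),
                       n_trials = 65, tr = 1.19, runs_per_task = 2,
                       t_threshold = 3, prob_threshold = 0.2,
                       drift_order = 1, seed = 1L) {
  cfg <- list(mesh = list(kind = "grid", size = mesh_size, spacing = spacing),
              cohorts = cohorts,
              design = list(n_trials = n_trials, tr = tr,
                            runs_per_task = runs_per_task),
              thresholds = list(t = t_threshold, prob = prob_threshold),
              drift_order = drift_order,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' Checks thresholds, seeds, and that every patch's subregion exists in
#' the mask geometry, before any compute happens.
#'
#' @param cfg A `run_config`.
#' @return `cfg`, invisibly usable (returned on success).
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$seed) || is.na(cfg$seed)) {
    stop("config error: seed must be set", call. = FALSE)
  }
  if (cfg$thresholds$t <= 0 || cfg$thresholds$prob < 0) {
    stop("config error: thresholds must be positive", call. = FALSE)
  }
  mesh <- make_mesh(cfg$mesh$kind, cfg$mesh$size, spacing = cfg$mesh$spacing)
  mask <- make_votc_mask(mesh)
  for (co in names(cfg$cohorts)) {
    for (nm in names(cfg$cohorts[[co]]$patches)) {
      sr <- cfg$cohorts[[co]]$patches[[nm]]$subregion
      if (!sr %in% names(mask$subregions)) {
        stop(sprintf("config error: cohort '%s' patch '%s' uses unknown subregion '%s'",
                     co, nm, sr), call. = FALSE)
      }
    }
  }
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly;
#'   `read_run_config` returns a validated `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass_deep(cfg), path)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cohorts <- lapply(raw$cohorts, function(co) {
    cfg <- cohort_config(co$cohort, n_subjects = co$n_subjects,
                         noise_sd = co$noise_sd,
                         oneback_gain = co$oneback_gain,
                         registration_sd = co$registration_sd,
                         amp_cv = co$amp_cv, falloff_sd = co$falloff_sd,
                         common_response = co$common_response,
                         ar1 = co$ar1)
    cfg$patches <- co$patches
    cfg
  })
  run_config(mesh_size = raw$mesh$size, spacing = raw$mesh$spacing,
             cohorts = cohorts,
             n_trials = raw$design$n_trials, tr = raw$design$tr,
             runs_per_task = raw$design$runs_per_task,
             t_threshold = raw$thresholds$t,
             prob_threshold = raw$thresholds$prob,
             drift_order = raw$drift_order, seed = raw$seed)
}

#' Import a template ROI from a FreeSurfer label file
#'
#' @param path Label file.
#' @param mesh The template `votc_mesh` (out-of-range vertex indices are
#'   rejected).
#' @param name ROI name.
#' @return A template-space `votc_roi`.
#' @export
import_template_roi <- function(path, mesh, name = basename(path)) {
  roi <- read_label(path, mesh, name = name, subject_id = "template")
  roi$source$space <- "template"
  roi
}

# Per-subject localizer simulation + GLM analysis. Returns t-maps, PSC
# maps (joint fit and per task), native ROIs (joint and per task), and
# template-space transported maps/ROIs.
analyze_subject <- function(mesh, mask, layout, cfg, subject_seed) {
  tasks <- c("one_back", "fixation")
  designs <- list()
  ts <- list()
  k <- 0L
  for (tk in tasks) {
    for (r in seq_len(cfg$design$runs_per_task)) {
      k <- k + 1L
      d <- make_design(cfg$design$n_trials, cfg$design$tr,
                       seed = subject_seed + 101L * k, task = tk,
                       run_id = k)
      designs[[k]] <- d
      ts[[k]] <- simulate_timeseries(mesh, mask, layout, d,
                                     seed = subject_seed + 101L * k + 50L)
    }
  }
  task_of <- vapply(designs, function(d) d$task, "")

  fit_for <- function(idx) {
    dm <- build_design_matrix(designs[idx], drift_order = cfg$drift_order)
    fit_glm(ts[idx], dm)
  }
  fit_all <- fit_for(seq_along(designs))
  fits_task <- lapply(tasks, function(tk) fit_for(which(task_of == tk)))
  names(fits_task) <- tasks

  cats <- setdiff(localizer_categories(), "blank")
  tmaps <- lapply(cats, function(cc) {
    suppressWarnings(contrast_t(fit_all, vs_other_weights(cc)))
  })
  names(tmaps) <- cats
  psc_all <- lapply(cats, function(cc) suppressWarnings(psc_map(fit_all, cc)))
  names(psc_all) <- cats
  psc_task <- lapply(fits_task, function(f) {
    maps <- lapply(cats, function(cc) suppressWarnings(psc_map(f, cc)))
    names(maps) <- cats
    maps
  })

  thr <- cfg$thresholds$t
  vwfa <- define_roi(tmaps$text, mesh, mask, "vwfa", threshold = thr,
                     name = "VWFA", subject_id = layout$subject_id)
  ffa <- define_roi(tmaps$face, mesh, mask, "ffa", threshold = thr,
                    name = "FFA", subject_id = layout$subject_id)
  task_vwfa <- lapply(tasks, function(tk) {
    tm <- suppressWarnings(contrast_t(fits_task[[tk]],
                                      vs_other_weights("text")))
    define_roi(tm, mesh, mask, "vwfa", threshold = thr,
               name = paste0("tVWFA-", tk), subject_id = layout$subject_id)
  })
  names(task_vwfa) <- tasks

  shift <- layout$registration_shift
  list(
    layout = layout,
    tmaps = tmaps, psc = psc_all, psc_task = psc_task,
    vwfa = vwfa, ffa = ffa, task_vwfa = task_vwfa,
    tmaps_template = lapply(tmaps, to_template, shift = shift, mesh = mesh),
    psc_template = lapply(psc_all, to_template, shift = shift, mesh = mesh),
    vwfa_template = to_template(vwfa, shift, mesh),
    ffa_template = to_template(ffa, shift, mesh)
  )
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes simulate -> GLM -> ROI -> group -> selectivity for every
#' cohort in the configuration, writes the standard output tables, and
#' returns the results with a run manifest. Identical config + seed gives
#' byte-identical outputs.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed). `NULL` skips all
#'   file output.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with per-cohort results (`subjects`, group
#'   maps and ROIs, Dice table, cross-validation and comparison tables)
#'   and `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  validate_run_config(cfg)
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  mesh <- make_mesh(cfg$mesh$kind, cfg$mesh$size, spacing = cfg$mesh$spacing)
  mask <- make_votc_mask(mesh)

  results <- list()
  stage_times <- c()
  files <- character(0)
  for (co in names(cfg$cohorts)) {
    ccfg <- cfg$cohorts[[co]]
    cohort_seed <- cfg$seed + 100000L * match(co, names(cfg$cohorts))
    say("[%s] sampling %d subjects", co, ccfg$n_subjects)
    layouts <- sample_population(mesh, mask, config = ccfg,
                                 seed = cohort_seed)
    t_stage <- Sys.time()
    subjects <- lapply(seq_along(layouts), function(i) {
      say("[%s] subject %d/%d", co, i, length(layouts))
      analyze_subject(mesh, mask, layouts[[i]], cfg,
                      subject_seed = cohort_seed + i)
    })
    stage_times[paste0(co, "_subjects")] <-
      as.numeric(difftime(Sys.time(), t_stage, units = "secs"))

    empty_vwfa <- vapply(subjects, function(s) {
      length(s$vwfa$vertices) == 0L
    }, TRUE)
    if (any(empty_vwfa)) {
      say("[%s] warning: %d subjects with empty VWFA", co, sum(empty_vwfa))
    }

    dice_tab <- do.call(rbind, lapply(subjects, function(s) {
      dr <- dice(s$task_vwfa$one_back, s$task_vwfa$fixation)
      data.frame(participant = s$layout$subject_id, dsc = dr$dsc,
                 intersection = dr$intersection_size,
                 size_oneback = dr$size_a, size_fixation = dr$size_b,
                 both_empty = dr$both_empty)
    }))

    vwfa_pmap <- probabilistic_map(lapply(subjects, `[[`, "vwfa_template"),
                                   mesh)
    ffa_pmap <- probabilistic_map(lapply(subjects, `[[`, "ffa_template"),
                                  mesh)
    g_vwfa <- group_roi(vwfa_pmap, cfg$thresholds$prob,
                        name = paste0(co, "-gVWFA"))
    g_ffa <- group_roi(ffa_pmap, cfg$thresholds$prob,
                       name = paste0(co, "-gFFA"))
    group_t <- lapply(names(subjects[[1]]$tmaps_template), function(cc) {
      group_t_map(lapply(subjects, function(s) s$tmaps_template[[cc]]))
    })
    names(group_t) <- names(subjects[[1]]$tmaps_template)
    indicator <- overlap_indicator(
      lapply(subjects, `[[`, "vwfa_template"),
      lapply(subjects, `[[`, "ffa_template"), mesh
    )
    crossval <- crossval_tuning(
      list(one_back = lapply(subjects, function(s) s$task_vwfa$one_back),
           fixation = lapply(subjects, function(s) s$task_vwfa$fixation)),
      list(one_back = lapply(subjects, function(s) s$psc_task$one_back),
           fixation = lapply(subjects, function(s) s$psc_task$fixation))
    )
    size_test <- task_size_test(
      lapply(subjects, function(s) s$task_vwfa$one_back),
      lapply(subjects, function(s) s$task_vwfa$fixation)
    )
    results[[co]] <- list(
      layouts = layouts, subjects = subjects, dice = dice_tab,
      vwfa_pmap = vwfa_pmap, ffa_pmap = ffa_pmap,
      group_vwfa = g_vwfa, group_ffa = g_ffa,
      group_t = group_t, indicator = indicator,
      crossval = crossval, size_test = size_test
    )
  }

  # Cross-cohort selectivity comparison: every cohort's native VWFAs
  # against every cohort-level group VWFA (template ROIs can be added by
  # the caller via compare_roi_families directly).
  family_rois <- lapply(results, `[[`, "group_vwfa")
  names(family_rois) <- paste0(names(results), "_gVWFA")
  family_rois <- Filter(function(r) length(r$vertices) > 0L, family_rois)
  comparisons <- lapply(results, function(res) {
    usable_fams <- family_rois
    if (length(usable_fams) == 0L) return(NULL)
    tryCatch(
      compare_roi_families(
        lapply(res$subjects, `[[`, "vwfa"), usable_fams,
        lapply(res$subjects, `[[`, "psc"),
        lapply(res$subjects, `[[`, "psc_template")
      ),
      error = function(e) NULL
    )
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_path <- file.path(out_dir, "config.yaml")
    write_run_config(cfg, cfg_path)
    files <- c(files, cfg_path)
    for (co in names(results)) {
      res <- results[[co]]
      p <- function(nm) file.path(out_dir, paste0(co, "_", nm))
      utils::write.csv(res$dice, p("dice.csv"), row.names = FALSE)
      write_vertex_map_csv(res$vwfa_pmap, p("vwfa_probmap.csv"))
      write_vertex_map_csv(res$group_t$text, p("group_t_text.csv"))
      write_vertex_map_csv(res$group_t$face, p("group_t_face.csv"))
      write_indicator_csv(res$indicator, p("indicator.csv"))
      if (length(res$group_vwfa$vertices)) {
        write_label(res$group_vwfa, mesh, p("gVWFA.label"))
        files <- c(files, p("gVWFA.label"))
      }
      if (!is.null(comparisons[[co]])) {
        write_records_csv(comparisons[[co]]$selectivity,
                          p("selectivity.csv"))
        utils::write.csv(comparisons[[co]]$paired, p("paired_stats.csv"),
                         row.names = FALSE)
        files <- c(files, p("selectivity.csv"), p("paired_stats.csv"))
      }
      files <- c(files, p("dice.csv"), p("vwfa_probmap.csv"),
                 p("group_t_text.csv"), p("group_t_face.csv"),
                 p("indicator.csv"))
    }
  }

  manifest <- list(
    config_hash = if (!is.null(out_dir)) {
      unname(tools::md5sum(file.path(out_dir, "config.yaml")))
    } else NA_character_,
    package_version = as.character(utils::packageVersion("votcsim")),
    seed = cfg$seed,
    files = files,
    stage_seconds = as.list(stage_times),
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(results, list(comparisons = comparisons,
                            manifest = manifest,
                            mesh = mesh, mask = mask)))
}
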