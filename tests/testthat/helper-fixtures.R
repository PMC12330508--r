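# Shared fixtures: the standard simulation surface and a per-subject
# localizer + GLM runner used across test files. Heavy cohort analyses
# used by several acceptance checks are computed lazily and cached for
# the test session.

std_mesh <- function() make_mesh("grid", 48)
std_mask <- function(mesh = std_mesh()) make_votc_mask(mesh)

# Simulate a subject's four localizer runs (2 per task) and return
# designs + time series.
simulate_subject_runs <- function(mesh, mask, layout, seed,
                                  runs_per_task = 2, n_trials = 65,
                                  tr = 1.19) {
  designs <- list()
  ts <- list()
  k <- 0L
  for (tk in c("one_back", "fixation")) {
    for (r in seq_len(runs_per_task)) {
      k <- k + 1L
      d <- make_design(n_trials, tr, seed = seed + 101L * k, task = tk,
                       run_id = k)
      designs[[k]] <- d
      ts[[k]] <- simulate_timeseries(mesh, mask, layout, d,
                                     seed = seed + 101L * k + 50L)
    }
  }
  list(designs = designs, ts = ts)
}

# Joint-fit analysis for one subject: t-maps, PSC maps, native text ROI.
fit_subject <- function(mesh, mask, layout, seed) {
  runs <- simulate_subject_runs(mesh, mask, layout, seed)
  fit <- fit_glm(runs$ts, build_design_matrix(runs$designs))
  cats <- setdiff(localizer_categories(), "blank")
  tmaps <- lapply(cats, function(cc) {
    suppressWarnings(contrast_t(fit, vs_other_weights(cc)))
  })
  names(tmaps) <- cats
  psc <- lapply(cats, function(cc) suppressWarnings(psc_map(fit, cc)))
  names(psc) <- cats
  vwfa <- define_roi(tmaps$text, mesh, mask, "vwfa",
                     subject_id = layout$subject_id)
  list(fit = fit, tmaps = tmaps, psc = psc, vwfa = vwfa)
}

roi_from_vertices <- function(vertices, mesh, name = "roi",
                              subject_id = "test") {
  votcsim:::new_roi(vertices, name = name, subject_id = subject_id,
                    mesh_n = mesh$n_vertices)
}

# ---- cached heavy scenario runs (shared across acceptance checks) ----

.scenario_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.scenario_cache[[key]])) .scenario_cache[[key]] <- force(expr)
  .scenario_cache[[key]]
}

# Washout scenario: children-like cohort (text jitter 2.5x the 4 mm patch
# radius), noise-free forward model so that spatial topography is the only
# between-subject variance source; adult-like cohort at standard SNR
# supplies the group VWFA.
washout_run <- function() {
  cached("washout", {
    cfg <- run_config(
      cohorts = list(children = cohort_config("children", noise_sd = 0),
                     adults = cohort_config("adults")),
      seed = 1L
    )
    suppressMessages(run_pipeline(cfg, out_dir = NULL, quiet = TRUE))
  })
}

# Task-modulation scenario: standard SNR, soft patch edges (Gaussian
# falloff) so the suprathreshold extent responds to the attentional gain.
task_run <- function() {
  cached("task", {
    cfg <- run_config(
      cohorts = list(children = cohort_config("children",
                                              falloff_sd = 1.5)),
      seed = 1L
    )
    suppressMessages(run_pipeline(cfg, out_dir = NULL, quiet = TRUE))
  })
}
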