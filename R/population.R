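# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All samplers are pure functions of (config, seed).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Cohort configuration for the synthetic population
#'
#' Returns the generator settings for one simulated cohort. Two presets
#' mirror the study design: a larger `"children"` cohort whose
#' text-selective patch is highly variable in position, and a smaller
#' `"adults"` cohort with modest text variability. In both, the
#' face-selective patch is large and spatially stable, and the OTS band
#' also hosts a limb-selective patch (as the occipitotemporal sulcus does),
#' so that the same template territory can be text-selective in one person
#' and limb-selective in another.
#'
#' Patch amplitudes are percent signal change over the blank baseline
#' during the fixation task; the one-back task multiplies all stimulus
#' responses by `oneback_gain` (attentional enhancement). Patches are
#' discs with a flat core of the stated radius and a Gaussian amplitude
#' falloff (`falloff_sd` mm) beyond it. Per-subject response amplitudes
#' are heterogeneous (log-normal, coefficient of variation `amp_cv`).
#'
#' @param cohort `"children"` or `"adults"`.
#' @param n_subjects Cohort size (defaults: 30 children, 15 adults).
#' @param noise_sd Gaussian measurement noise SD per vertex-volume, in
#'   baseline signal units (baseline = 100). The default is calibrated so
#'   that a four-run localizer yields an in-patch text t-statistic of
#'   about 8.
#' @param oneback_gain Multiplicative attentional gain of the one-back
#'   task over fixation.
#' @param registration_sd SD (mm) of the per-subject rigid shift standing
#'   in for template-registration error.
#' @param amp_cv Between-subject coefficient of variation of patch
#'   amplitudes.
#' @param falloff_sd Gaussian edge falloff SD (mm). Default 0: patches
#'   are hard-edged geodesic discs; a positive value adds a soft
#'   amplitude skirt beyond the core radius.
#' @param common_response Percent signal change evoked by every stimulus
#'   category at every VOTC vertex (non-selective visual response).
#' @param ar1 AR(1) coefficient of the measurement noise (0 = iid).
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(cohort = c("children", "adults"),
                          n_subjects = NULL,
                          noise_sd = 1.4,
                          oneback_gain = 1.3,
                          registration_sd = 2,
                          amp_cv = 0.35,
                          falloff_sd = 0,
                          common_response = 0.5,
                          ar1 = 0) {
  cohort <- match.arg(cohort)
  text_jitter <- if (cohort == "children") 10 else 3
  if (is.null(n_subjects)) n_subjects <- if (cohort == "children") 30L else 15L
  patches <- list(
    text = list(subregion = "ots", center = c(16, 32), radius = 4,
                jitter = text_jitter, amp = 1.2),
    pseudofont = list(subregion = "ots", attach_to = "text",
                      offset = c(3, 0), radius = 3.5, jitter = 0, amp = 1.0),
    face = list(subregion = "fusiform", center = c(26, 14), radius = 8,
                jitter = 2, amp = 1.5),
    limb = list(subregion = "ots", center = c(18, 32), radius = 6,
                jitter = 3, amp = 1.2),
    object = list(subregion = "fusiform", center = c(10, 14), radius = 5,
                  jitter = 3, amp = 1.0)
  )
  structure(
    list(cohort = cohort, n_subjects = as.integer(n_subjects),
         patches = patches, noise_sd = noise_sd,
         oneback_gain = oneback_gain, registration_sd = registration_sd,
         amp_cv = amp_cv, falloff_sd = falloff_sd,
         common_response = common_response, baseline = 100, ar1 = ar1),
    class = "cohort_config"
  )
}

#' Sample a population of subject layouts
#'
#' Draws per-subject ground-truth geometry: each category patch center is
#' the group center plus an isotropic Gaussian jitter (clipped to the
#' patch's anatomical subregion), the pseudofont patch rides on the
#' realized text center at a fixed offset (partial overlap), per-subject
#' amplitudes are log-normal around the configured means, and each subject
#' receives a rigid registration shift used when projecting to template
#' space.
#'
#' @param mesh A `votc_mesh`.
#' @param mask A `votc_mask`.
#' @param n_subjects Number of subjects (default from `config`).
#' @param config A [cohort_config()].
#' @param variability Optional named numeric vector of per-category
#'   center-jitter SDs (mm) overriding the config.
#' @param sizes Optional named numeric vector of per-category patch radii
#'   (mm) overriding the config.
#' @param gains Optional length-1 one-back gain overriding the config.
#' @param seed Integer RNG seed; identical seeds give identical
#'   populations.
#'
#' @return A list of `subject_layout` objects. Each has `subject_id`,
#'   `patches` (per category: `center`, `radius`, `amp` named by task,
#'   `jitter_draw`), and `registration_shift` (mm).
#' @export
sample_population <- function(mesh, mask, n_subjects = NULL,
                              config = cohort_config(),
                              variability = NULL, sizes = NULL,
                              gains = NULL, seed = 1L) {
  stopifnot(inherits(mesh, "votc_mesh"), inherits(mask, "votc_mask"))
  validate_mask(mask)
  if (is.null(n_subjects)) n_subjects <- config$n_subjects
  for (nm in names(variability)) {
    if (variability[[nm]] < 0) stop("jitter sds must be >= 0", call. = FALSE)
    config$patches[[nm]]$jitter <- variability[[nm]]
  }
  for (nm in names(sizes)) config$patches[[nm]]$radius <- sizes[[nm]]
  if (!is.null(gains)) config$oneback_gain <- gains[[1]]
  for (nm in names(config$patches)) {
    p <- config$patches[[nm]]
    sub <- mask$subregions[[p$subregion]]
    if (is.null(sub)) {
      stop(sprintf("patch '%s' references unknown subregion '%s'",
                   nm, p$subregion), call. = FALSE)
    }
    ext <- max(stats::dist(mesh$coords[sub, , drop = FALSE]))
    if (p$radius > ext) {
      stop(sprintf("patch '%s' radius (%.1f mm) exceeds its subregion extent",
                   nm, p$radius), call. = FALSE)
    }
  }
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      sample_subject(mesh, mask, config, sprintf("sub-%03d", i))
    })
  })
}

sample_subject <- function(mesh, mask, config, subject_id) {
  d <- ncol(mesh$coords)
  patches <- list()
  sdlog <- sqrt(log(1 + config$amp_cv^2))
  # one overall responsiveness scale per subject, shared across categories:
  # between-subject gain heterogeneity without reordering category tuning
  scale <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  # category patches tile the cortex within a subject: cores of distinct
  # patches must not overlap. The text patch is placed first (its location
  # is the free variable); later patches are redrawn, or pushed to
  # tangency, to respect the mosaic. The attached pseudofont patch is
  # exempt (partial overlap with text is intended).
  placed <- list()
  for (nm in names(config$patches)) {
    p <- config$patches[[nm]]
    if (!is.null(p$attach_to)) {
      base_center <- patches[[p$attach_to]]$center
      jitter <- rep(0, d)
      center <- base_center + c(p$offset, rep(0, d - length(p$offset)))
      center <- clip_to_subregion(mesh, mask, center, p$subregion)
    } else {
      for (try in 1:60) {
        jitter <- stats::rnorm(d, 0, p$jitter)
        center <- c(p$center, rep(0, d - length(p$center))) + jitter
        center <- clip_to_subregion(mesh, mask, center, p$subregion)
        if (mosaic_ok(center, p$radius, placed)) break
      }
      if (!mosaic_ok(center, p$radius, placed)) {
        center <- mosaic_push(center, p$radius, placed)
        center <- clip_to_subregion(mesh, mask, center, p$subregion)
      }
      placed[[nm]] <- list(center = center, radius = p$radius)
    }
    amp <- p$amp * scale * c(one_back = config$oneback_gain, fixation = 1)
    patches[[nm]] <- list(center = center, radius = p$radius, amp = amp,
                          jitter_draw = jitter)
  }
  structure(
    list(subject_id = subject_id, patches = patches,
         registration_shift = stats::rnorm(d, 0, config$registration_sd),
         oneback_gain = config$oneback_gain,
         falloff_sd = config$falloff_sd,
         common_response = config$common_response,
         baseline = config$baseline, noise_sd = config$noise_sd,
         ar1 = config$ar1),
    class = "subject_layout"
  )
}

# Core non-overlap test against already-placed patches.
mosaic_ok <- function(center, radius, placed) {
  all(vapply(placed, function(q) {
    sqrt(sum((center - q$center)^2)) >= radius + q$radius
  }, TRUE))
}

# Fallback when rejection sampling cannot satisfy the mosaic: move the
# candidate center radially away from each violating patch to tangency.
mosaic_push <- function(center, radius, placed) {
  for (q in placed) {
    delta <- center - q$center
    dist <- sqrt(sum(delta^2))
    need <- radius + q$radius
    if (dist < need) {
      dir <- if (dist > 1e-9) delta / dist else c(1, rep(0, length(delta) - 1))
      center <- q$center + dir * need
    }
  }
  center
}

# Clip a candidate patch center to its allowed subregion: if the nearest
# mesh vertex is outside the subregion, snap to the nearest subregion vertex.
clip_to_subregion <- function(mesh, mask, center, subregion) {
  sub <- mask$subregions[[subregion]]
  v <- nearest_vertex(mesh, center)
  if (!is.na(v) && v %in% sub) return(center)
  d2 <- colSums((t(mesh$coords[sub, , drop = FALSE]) - center)^2)
  mesh$coords[sub[which.min(d2)], ]
}

# Relative amplitude profile of a patch: 1 inside the core radius, Gaussian
# falloff beyond, truncated at 3 falloff SDs.
patch_profile <- function(dist, radius, falloff_sd) {
  f <- numeric(length(dist))
  f[dist <= radius] <- 1
  if (falloff_sd > 0) {
    ring <- dist > radius & dist <= radius + 3 * falloff_sd
    f[ring] <- exp(-(dist[ring] - radius)^2 / (2 * falloff_sd^2))
  }
  f
}

#' True per-vertex response amplitude for one category
#'
#' The forward-model ground truth: the category's patch profile times its
#' per-subject, per-task amplitude, plus the non-selective common visual
#' response, all restricted to the VOTC mask. Units: percent signal change
#' over baseline.
#'
#' @param mesh A `votc_mesh`.
#' @param mask A `votc_mask`.
#' @param layout A `subject_layout`.
#' @param category One of `"text"`, `"pseudofont"`, `"face"`, `"object"`,
#'   `"limb"`.
#' @param task `"one_back"` or `"fixation"`.
#' @return Numeric vector of length `n_vertices` (percent signal change).
#' @export
amplitude_field <- function(mesh, mask, layout, category,
                            task = c("fixation", "one_back")) {
  task <- match.arg(task)
  a <- numeric(mesh$n_vertices)
  p <- layout$patches[[category]]
  if (!is.null(p)) {
    f <- patch_profile(vertex_distances(mesh, p$center), p$radius,
                       layout$falloff_sd)
    a <- f * p$amp[[task]]
  }
  gain <- if (task == "one_back") layout$oneback_gain else 1
  common <- layout$common_response * gain
  out <- numeric(mesh$n_vertices)
  out[mask$votc] <- a[mask$votc] + common
  out
}

#' Ground-truth patch vertex set
#'
#' The simulator-truth region for parameter-recovery checks: vertices
#' whose relative amplitude profile is at least `level` (default:
#' full-width-half-maximum support), restricted to the VOTC mask.
#'
#' @inheritParams amplitude_field
#' @param level Relative profile cutoff in (0, 1].
#' @param subregion Anatomical restriction: `"votc"` (default) or a
#'   subregion name, so the truth set can be limited to the same
#'   anatomical territory an ROI rule allows.
#' @return Integer vector of vertex indices.
#' @export
true_patch <- function(mesh, mask, layout, category, level = 0.5,
                       subregion = "votc") {
  p <- layout$patches[[category]]
  if (is.null(p)) stop("unknown category: ", category, call. = FALSE)
  f <- patch_profile(vertex_distances(mesh, p$center), p$radius,
                     layout$falloff_sd)
  allowed <- if (subregion == "votc") mask$votc else mask$subregions[[subregion]]
  if (is.null(allowed)) stop("unknown subregion: ", subregion, call. = FALSE)
  intersect(which(f >= level), allowed)
}
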