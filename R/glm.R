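# HRF-convolved category regressor for one run, sampled at volume times.
# The HRF is evaluated on an oversampled timeline (tr/oversample), convolved
# with the category boxcar, and normalized so that one isolated 4 s trial
# peaks at 1: a beta of b then means "b signal units at the single-trial
# peak", and percent signal change inherits that meaning.
convolve_regressor <- function(design, category, params = hrf_params(),
                               oversample = 10L) {
  dt <- design$tr / oversample
  n_fine <- design$n_volumes * oversample
  tfine <- (seq_len(n_fine) - 1) * dt
  box <- numeric(n_fine)
  tr_rows <- design$trials[design$trials$category == category, , drop = FALSE]
  for (i in seq_len(nrow(tr_rows))) {
    on <- tr_rows$onset[i]
    box[tfine >= on & tfine < on + tr_rows$duration[i]] <- 1
  }
  h <- canonical_hrf(seq(0, 30, by = dt), params)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_len(n_fine)]
  ref_box <- c(rep(1, round(4 / dt)), numeric(length(h)))
  ref_peak <- max(stats::convolve(ref_box, rev(h),
                                  type = "open")[seq_along(ref_box)])
  reg <- conv / ref_peak
  reg[seq(1, n_fine, by = oversample)]
}

#' Build the GLM design matrix
#'
#' One HRF-convolved boxcar column per non-blank stimulus category
#' (shared across runs, so a single set of category betas is estimated),
#' plus per-run polynomial drift columns up to `drift_order` (order 0 is
#' the run intercept). Blank trials are the unmodeled baseline.
#'
#' @param designs A `localizer_design` or a list of them (runs are
#'   concatenated; drift columns are block-diagonal by run).
#' @param params HRF parameters, see [hrf_params()].
#' @param drift_order Maximum polynomial drift order per run.
#' @return An object of class `design_matrix`: list with `X` (volume x
#'   regressor matrix), `categories`, `drift_cols`, `run_lengths`,
#'   `designs`.
#' @export
build_design_matrix <- function(designs, params = hrf_params(),
                                drift_order = 1L) {
  if (inherits(designs, "localizer_design")) designs <- list(designs)
  stopifnot(all(vapply(designs, inherits, TRUE, "localizer_design")))
  cats <- setdiff(localizer_categories(), "blank")
  present <- cats[vapply(cats, function(cc) {
    any(vapply(designs, function(d) cc %in% d$trials$category, TRUE))
  }, TRUE)]
  run_lengths <- vapply(designs, function(d) d$n_volumes, integer(1))
  n_total <- sum(run_lengths)

  X_cat <- matrix(0, n_total, length(present),
                  dimnames = list(NULL, present))
  offset <- 0L
  for (d in designs) {
    rows <- offset + seq_len(d$n_volumes)
    for (cc in present) {
      X_cat[rows, cc] <- convolve_regressor(d, cc, params)
    }
    offset <- offset + d$n_volumes
  }

  drift_list <- list()
  offset <- 0L
  for (r in seq_along(designs)) {
    nv <- run_lengths[r]
    tt <- seq(-1, 1, length.out = nv)
    D <- stats::poly(tt, degree = max(drift_order, 1), raw = FALSE)
    D <- cbind(1, D[, seq_len(drift_order), drop = FALSE])
    colnames(D) <- sprintf("run%d_drift%d", r, 0:drift_order)
    block <- matrix(0, n_total, ncol(D), dimnames = list(NULL, colnames(D)))
    block[offset + seq_len(nv), ] <- D
    drift_list[[r]] <- block
    offset <- offset + nv
  }
  drift <- do.call(cbind, drift_list)
  X <- cbind(X_cat, drift)
  if (qr(X)$rank < ncol(X)) {
    stop("degenerate design: rank-deficient design matrix", call. = FALSE)
  }
  structure(
    list(X = X, categories = present, drift_cols = colnames(drift),
         intercept_cols = grep("_drift0$", colnames(drift), value = TRUE),
         run_lengths = run_lengths, designs = designs,
         hrf = params, drift_order = drift_order),
    class = "design_matrix"
  )
}

#' Per-vertex ordinary-least-squares GLM fit
#'
#' Fits all vertices jointly against the shared design matrix, returning
#' category betas, residual variance, and residual degrees of freedom.
#'
#' @param ts A `bold_timeseries` or a list of them (runs, concatenated in
#'   the order of the design matrix).
#' @param dm A `design_matrix` from [build_design_matrix()].
#' @return An object of class `glm_fit`: list with `betas` (regressor x
#'   vertex), `sigma2`, `dof`, `baseline` (mean run intercept per
#'   vertex), `xtx_inv`, `dm`.
#' @export
fit_glm <- function(ts, dm) {
  stopifnot(inherits(dm, "design_matrix"))
  if (inherits(ts, "bold_timeseries")) ts <- list(ts)
  Y <- t(do.call(cbind, lapply(ts, function(r) r$data)))  # volumes x vertices
  if (nrow(Y) != nrow(dm$X)) {
    stop("time series and design matrix volume counts differ", call. = FALSE)
  }
  qx <- qr(dm$X)
  if (qx$rank < ncol(dm$X)) {
    stop("degenerate design: rank-deficient design matrix", call. = FALSE)
  }
  betas <- qr.coef(qx, Y)
  res <- Y - dm$X %*% betas
  dof <- nrow(Y) - qx$rank
  sigma2 <- colSums(res^2) / dof
  baseline <- colMeans(betas[dm$intercept_cols, , drop = FALSE])
  structure(
    list(betas = betas, sigma2 = sigma2, dof = dof, baseline = baseline,
         xtx_inv = chol2inv(qr.R(qx)), dm = dm,
         n_vertices = ncol(Y)),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit: %d vertices, %d regressors, dof %d>\n",
              x$n_vertices, nrow(x$betas), x$dof))
  invisible(x)
}

# Lightweight per-vertex scalar map container.
new_vertex_map <- function(values, kind, meta = list()) {
  structure(list(values = as.numeric(values), kind = kind, meta = meta),
            class = "vertex_map")
}

#' @export
print.vertex_map <- function(x, ...) {
  fin <- x$values[is.finite(x$values)]
  cat(sprintf("<vertex_map: kind '%s', %d vertices, range [%.3g, %.3g]>\n",
              x$kind, length(x$values),
              if (length(fin)) min(fin) else NA, if (length(fin)) max(fin) else NA))
  invisible(x)
}

#' Category-versus-others contrast weights
#'
#' `+1` on the target category and `-1/(k-1)` on each of the other
#' stimulus categories (blank excluded), so the contrast compares the
#' target with the equal-weighted average of the others and is invariant
#' to adding a constant to all stimulus betas.
#'
#' @param category Target category.
#' @param categories Stimulus categories in the model.
#' @return Named numeric weight vector.
#' @export
vs_other_weights <- function(category,
                             categories = setdiff(localizer_categories(),
                                                  "blank")) {
  if (!category %in% categories) {
    stop("unknown category: ", category, call. = FALSE)
  }
  w <- stats::setNames(rep(-1 / (length(categories) - 1), length(categories)),
                       categories)
  w[category] <- 1
  w
}

#' Contrast t-statistic map
#'
#' Computes `t = c'b / sqrt(sigma2 * c'(X'X)^-1 c)` per vertex. Vertices
#' with (numerically) zero residual variance get a sentinel: signed
#' infinity when the contrast itself is non-zero, 0 otherwise, with a
#' warning.
#'
#' @param fit A `glm_fit`.
#' @param weights Named per-category contrast weights (e.g.
#'   [vs_other_weights()]). Unnamed regressors get weight 0.
#' @param var_tol Residual-variance floor below which a vertex is treated
#'   as noise-free.
#' @return A `vertex_map` of kind `"t"`.
#' @export
contrast_t <- function(fit, weights, var_tol = 1e-10) {
  stopifnot(inherits(fit, "glm_fit"))
  w <- numeric(nrow(fit$betas))
  names(w) <- rownames(fit$betas)
  bad <- setdiff(names(weights), names(w))
  if (length(bad)) stop("unknown regressors in weights: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  w[names(weights)] <- weights
  est <- drop(crossprod(w, fit$betas))
  cvar <- drop(crossprod(w, fit$xtx_inv %*% w))
  tval <- est / sqrt(fit$sigma2 * cvar)
  zero_var <- fit$sigma2 <= var_tol
  if (any(zero_var)) {
    warning(sum(zero_var),
            " zero-variance vertices; t set to signed infinity sentinel",
            call. = FALSE)
    tval[zero_var] <- ifelse(abs(est[zero_var]) > sqrt(var_tol),
                             sign(est[zero_var]) * Inf, 0)
  }
  new_vertex_map(tval, "t",
                 meta = list(weights = weights, dof = fit$dof))
}

#' Percent-signal-change map for one category
#'
#' `100 * beta / baseline`, where the baseline is the mean run intercept
#' (the blank-implicit baseline). The blank category maps to identically
#' zero. Vertices with non-positive baseline become `NA` with a warning.
#'
#' @param fit A `glm_fit`.
#' @param category Stimulus category, or `"blank"`.
#' @return A `vertex_map` of kind `"psc"`.
#' @export
psc_map <- function(fit, category) {
  stopifnot(inherits(fit, "glm_fit"))
  if (category == "blank") {
    return(new_vertex_map(numeric(fit$n_vertices), "psc",
                          meta = list(category = "blank")))
  }
  if (!category %in% fit$dm$categories) {
    stop("category not in model: ", category, call. = FALSE)
  }
  psc <- 100 * fit$betas[category, ] / fit$baseline
  bad <- fit$baseline <= 0
  if (any(bad)) {
    warning(sum(bad), " vertices with non-positive baseline set to NA",
            call. = FALSE)
    psc[bad] <- NA_real_
  }
  new_vertex_map(psc, "psc", meta = list(category = category))
}

#' Write a vertex map as per-vertex CSV
#'
#' Columns `vertex_id` (1-based) and `value`.
#' @param map A `vertex_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vertex_map_csv <- function(map, path) {
  utils::write.csv(
    data.frame(vertex_id = seq_along(map$values), value = map$values),
    path, row.names = FALSE
  )
  invisible(path)
}
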