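# Transport per-vertex values along the mesh by a rigid shift (nearest-
# vertex resampling): output(v) = input(nearest vertex to coords(v) - shift).
# Positions falling outside the mesh contribute 0.
transport_values <- function(values, shift, mesh) {
  stopifnot(length(values) == mesh$n_vertices)
  if (all(shift == 0)) return(values)
  if (mesh$kind == "grid") {
    s <- mesh$side
    d <- round(shift / mesh$spacing)
    col <- (seq_len(mesh$n_vertices) - 1L) %/% s + 1L
    row <- (seq_len(mesh$n_vertices) - 1L) %% s + 1L
    src_col <- col - d[1]
    src_row <- row - d[2]
    ok <- src_col >= 1 & src_col <= s & src_row >= 1 & src_row <= s
    out <- numeric(mesh$n_vertices)
    out[ok] <- values[(src_col[ok] - 1L) * s + src_row[ok]]
    out
  } else {
    src <- t(t(mesh$coords) - shift)
    idx <- apply(src, 1L, function(p) which.min(vertex_distances(mesh, p)))
    values[idx]
  }
}

#' Apply a subject's registration error to a vertex map
#'
#' Stand-in for projecting a native-surface map to the template: the map
#' is transported along the mesh by the subject's rigid registration
#' shift with nearest-vertex resampling. A zero shift is the identity.
#'
#' @param map A `vertex_map`.
#' @param shift Numeric shift in mm (e.g. `layout$registration_shift`).
#' @param mesh The `votc_mesh`.
#' @return A `vertex_map` of the same kind in template space.
#' @export
apply_registration_error <- function(map, shift, mesh) {
  stopifnot(inherits(map, "vertex_map"), all(is.finite(shift)))
  out <- new_vertex_map(transport_values(map$values, shift, mesh),
                        map$kind, map$meta)
  out$meta$space <- "template"
  out
}

#' Project a map or ROI to template space
#'
#' Dispatches on class: vertex maps are resampled with
#' [apply_registration_error()]; ROI vertex sets are moved by the shift
#' (nearest-vertex), with vertices shifted off the mesh dropped (boundary
#' clipping).
#'
#' @param x A `vertex_map` or `votc_roi`.
#' @param shift Numeric registration shift (mm).
#' @param mesh The `votc_mesh`.
#' @return The transported object.
#' @export
to_template <- function(x, shift, mesh) {
  stopifnot(all(is.finite(shift)))
  if (inherits(x, "vertex_map")) {
    return(apply_registration_error(x, shift, mesh))
  }
  stopifnot(inherits(x, "votc_roi"))
  if (all(shift == 0)) return(x)
  moved <- vapply(x$vertices, function(v) {
    nearest_vertex(mesh, mesh$coords[v, ] + shift, clamp = FALSE)
  }, integer(1))
  out <- new_roi(moved[!is.na(moved)], name = x$name,
                 subject_id = x$subject_id, mesh_n = mesh$n_vertices,
                 source = c(x$source, list(space = "template")))
  out
}

#' Probabilistic map from template-space ROIs
#'
#' Per-vertex proportion of subjects whose ROI covers the vertex.
#'
#' @param rois Non-empty list of template-space `votc_roi` (one per
#'   subject; empty ROIs contribute zeros).
#' @param mesh The template `votc_mesh`.
#' @return A `vertex_map` of kind `"probability"` with `meta$n_subjects`.
#' @export
probabilistic_map <- function(rois, mesh) {
  if (length(rois) == 0L) stop("`rois` must be non-empty", call. = FALSE)
  stopifnot(all(vapply(rois, inherits, TRUE, "votc_roi")))
  counts <- numeric(mesh$n_vertices)
  for (r in rois) counts[r$vertices] <- counts[r$vertices] + 1
  new_vertex_map(counts / length(rois), "probability",
                 meta = list(n_subjects = length(rois),
                             region = rois[[1]]$name))
}

#' Group ROI from a probabilistic map
#'
#' Takes vertices whose coverage probability is strictly above
#' `prob_threshold` (default 0.2: more than 20% of participants had a
#' native ROI there).
#'
#' @param pmap A probability `vertex_map` from [probabilistic_map()].
#' @param prob_threshold Strict lower probability bound.
#' @param name Group ROI name.
#' @return A `votc_roi` tagged as a group ROI.
#' @export
group_roi <- function(pmap, prob_threshold = 0.2, name = "group") {
  stopifnot(inherits(pmap, "vertex_map"), pmap$kind == "probability")
  new_roi(which(pmap$values > prob_threshold), name = name,
          subject_id = "group", mesh_n = length(pmap$values),
          source = list(prob_threshold = prob_threshold,
                        n_subjects = pmap$meta$n_subjects))
}

#' Percent of template vertices, at printed precision
#'
#' `100 * count / total` rounded to one decimal place, the precision used
#' when reporting vertex counts as a share of the 163,842-vertex
#' template.
#'
#' @param count Vertex count(s).
#' @param total Template vertex total.
#' @return Numeric percentage(s), one decimal place.
#' @export
percent_of_template <- function(count, total) {
  round(100 * count / total, 1)
}

#' Text/face overlap-indicator map
#'
#' Labels every template vertex by which categories' native ROIs touch it
#' across subjects: `text_only` (at least one subject's text ROI, no
#' face), `face_only`, `both` (text-selective in at least one subject and
#' face-selective in at least one other -- the territory where averaging
#' mixes categories), or `neither`.
#'
#' @param text_rois,face_rois Lists of template-space `votc_roi`.
#' @param mesh The template `votc_mesh`.
#' @param template_total Total vertex count used as the percentage
#'   denominator (defaults to the mesh size; pass 163842 to express
#'   counts against the full surface template).
#' @return An object of class `indicator_map`: list with `labels`
#'   (factor per mesh vertex), `counts` and `percent` (named, the four
#'   labels; counts sum to `template_total`), `template_total`.
#' @export
overlap_indicator <- function(text_rois, face_rois, mesh,
                              template_total = mesh$n_vertices) {
  text_cov <- logical(mesh$n_vertices)
  face_cov <- logical(mesh$n_vertices)
  for (r in text_rois) text_cov[r$vertices] <- TRUE
  for (r in face_rois) face_cov[r$vertices] <- TRUE
  lab <- rep("neither", mesh$n_vertices)
  lab[text_cov & !face_cov] <- "text_only"
  lab[!text_cov & face_cov] <- "face_only"
  lab[text_cov & face_cov] <- "both"
  levels <- c("text_only", "face_only", "both", "neither")
  counts <- stats::setNames(as.integer(table(factor(lab, levels))), levels)
  counts["neither"] <- counts["neither"] +
    as.integer(template_total - mesh$n_vertices)
  structure(
    list(labels = factor(lab, levels), counts = counts,
         percent = percent_of_template(counts, template_total),
         template_total = as.integer(template_total)),
    class = "indicator_map"
  )
}

#' @export
print.indicator_map <- function(x, ...) {
  cat(sprintf("<indicator_map: %s of %d template vertices>\n",
              paste(sprintf("%s=%d (%.1f%%)", names(x$counts), x$counts,
                            x$percent), collapse = ", "),
              x$template_total))
  invisible(x)
}

#' Write the overlap-indicator summary as CSV
#'
#' Columns: `label`, `n_vertices`, `percent_of_template`.
#' @param ind An `indicator_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_indicator_csv <- function(ind, path) {
  utils::write.csv(
    data.frame(label = names(ind$counts), n_vertices = ind$counts,
               percent_of_template = ind$percent),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Vertex-wise group one-sample t-map
#'
#' Per-vertex one-sample t of subjects' template-space contrast values
#' against zero (dof = n - 1). Vertices where the between-subject
#' variance is numerically zero get a sentinel: signed infinity if the
#' common value is non-zero, 0 otherwise.
#'
#' @param maps List (length >= 2) of template-space contrast
#'   `vertex_map`s, one per subject.
#' @param var_tol Between-subject variance floor treated as zero.
#' @return A `vertex_map` of kind `"t"` with `meta$dof = n - 1`.
#' @export
group_t_map <- function(maps, var_tol = 1e-10) {
  if (length(maps) < 2L) stop("need at least 2 subjects", call. = FALSE)
  stopifnot(all(vapply(maps, inherits, TRUE, "vertex_map")))
  M <- do.call(rbind, lapply(maps, function(m) m$values))
  n <- nrow(M)
  mu <- colMeans(M)
  v <- colSums((t(t(M) - mu))^2) / (n - 1)
  tval <- mu / sqrt(v / n)
  zero_var <- v <= var_tol
  tval[zero_var] <- ifelse(abs(mu[zero_var]) > sqrt(var_tol),
                           sign(mu[zero_var]) * Inf, 0)
  new_vertex_map(tval, "t", meta = list(dof = n - 1, n_subjects = n))
}
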