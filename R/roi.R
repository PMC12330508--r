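#' Category-to-subregion ROI rules
#'
#' Named rules binding each functional region to the anatomical subregion
#' it may occupy: text- (VWFA-like), pseudofont- and limb-selective
#' clusters live on the OTS band; face- (FFA-like) and object-selective
#' clusters on the fusiform band.
#' @return Named character vector mapping rule name to subregion.
#' @export
roi_rules <- function() {
  c(vwfa = "ots", pseudofont = "ots", limb = "ots",
    ffa = "fusiform", object = "fusiform", votc = "votc")
}

new_roi <- function(vertices, name, subject_id = NA_character_,
                    mesh_n = NA_integer_, source = list()) {
  structure(
    list(name = name, subject_id = subject_id,
         vertices = sort(unique(as.integer(vertices))),
         mesh_n = as.integer(mesh_n), source = source),
    class = "votc_roi"
  )
}

#' Construct an ROI from a vertex index set
#'
#' @param vertices Integer vertex indices (1-based; deduplicated and
#'   sorted).
#' @param mesh The `votc_mesh` the ROI lives on.
#' @param name ROI name.
#' @param subject_id Subject or group tag.
#' @return A `votc_roi`.
#' @export
as_roi <- function(vertices, mesh, name = "roi",
                   subject_id = NA_character_) {
  stopifnot(inherits(mesh, "votc_mesh"))
  vertices <- as.integer(vertices)
  if (length(vertices) && (min(vertices) < 1L ||
                           max(vertices) > mesh$n_vertices)) {
    stop("vertex indices outside the mesh", call. = FALSE)
  }
  new_roi(vertices, name = name, subject_id = subject_id,
          mesh_n = mesh$n_vertices)
}

#' @export
print.votc_roi <- function(x, ...) {
  cat(sprintf("<votc_roi '%s' (%s): %d vertices>\n", x$name,
              x$subject_id, length(x$vertices)))
  invisible(x)
}

#' Define a functional ROI from a thresholded t-map
#'
#' Automated stand-in for manual ROI drawing: takes every vertex with
#' `t > threshold` that falls inside the anatomical subregion named by
#' `subregion_rule`; supra-threshold clusters extending beyond the
#' anatomical boundary are clipped at it. Clusters (after clipping)
#' smaller than `min_cluster` vertices are discarded as speckle a human
#' rater would ignore. The result may be empty (the region is then "not
#' identifiable" in this subject).
#'
#' @param tmap A `vertex_map` of kind `"t"`.
#' @param mesh The `votc_mesh` the map lives on.
#' @param mask A `votc_mask`.
#' @param subregion_rule A rule name from [roi_rules()] or a subregion
#'   name in `mask$subregions` (or `"votc"` for the whole mask).
#' @param threshold t threshold (default 3; vertices strictly above are
#'   taken).
#' @param min_cluster Minimum cluster size in vertices (default 1).
#' @param name,subject_id ROI provenance labels.
#' @return A `votc_roi`.
#' @export
define_roi <- function(tmap, mesh, mask, subregion_rule, threshold = 3,
                       min_cluster = 1L, name = subregion_rule,
                       subject_id = NA_character_) {
  stopifnot(inherits(tmap, "vertex_map"), inherits(mesh, "votc_mesh"),
            inherits(mask, "votc_mask"))
  if (length(tmap$values) != mesh$n_vertices) {
    stop("t-map and mesh sizes differ", call. = FALSE)
  }
  rule <- subregion_rule
  if (rule %in% names(roi_rules())) rule <- roi_rules()[[rule]]
  allowed <- if (rule == "votc") mask$votc else mask$subregions[[rule]]
  if (is.null(allowed)) {
    stop("unknown subregion rule: ", subregion_rule, call. = FALSE)
  }
  supra <- which(!is.na(tmap$values) & tmap$values > threshold)
  verts <- intersect(supra, allowed)
  if (min_cluster > 1L && length(verts)) {
    comps <- vertex_components(mesh, verts)
    verts <- unlist(comps[lengths(comps) >= min_cluster], use.names = FALSE)
    if (is.null(verts)) verts <- integer(0)
  }
  new_roi(verts, name = name, subject_id = subject_id,
          mesh_n = mesh$n_vertices,
          source = list(rule = subregion_rule, threshold = threshold,
                        min_cluster = min_cluster,
                        map_meta = tmap$meta))
}

#' Dice similarity coefficient between two ROIs
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`. If both ROIs are empty the
#' coefficient is defined as 0 and flagged, so population summaries stay
#' computable.
#'
#' @param a,b `votc_roi` objects on the same mesh.
#' @return An object of class `dice_result`: list with `dsc`,
#'   `intersection_size`, `size_a`, `size_b`, `both_empty`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "votc_roi"), inherits(b, "votc_roi"))
  if (!is.na(a$mesh_n) && !is.na(b$mesh_n) && a$mesh_n != b$mesh_n) {
    stop("ROIs live on different meshes", call. = FALSE)
  }
  ia <- length(a$vertices); ib <- length(b$vertices)
  ov <- length(intersect(a$vertices, b$vertices))
  both_empty <- ia == 0L && ib == 0L
  structure(
    list(dsc = if (both_empty) 0 else 2 * ov / (ia + ib),
         intersection_size = ov, size_a = ia, size_b = ib,
         both_empty = both_empty,
         roi_a = a$name, roi_b = b$name),
    class = "dice_result"
  )
}

#' @export
print.dice_result <- function(x, ...) {
  cat(sprintf("<dice: %.3f (|A|=%d, |B|=%d, |A&B|=%d)%s>\n", x$dsc,
              x$size_a, x$size_b, x$intersection_size,
              if (x$both_empty) " [both empty]" else ""))
  invisible(x)
}

#' ROI size in vertices and surface area
#'
#' @param roi A `votc_roi`.
#' @param mesh The mesh the ROI lives on.
#' @return List with `n_vertices` and `area` (mm^2, summed per-vertex
#'   tessellation area).
#' @export
roi_size <- function(roi, mesh) {
  stopifnot(inherits(roi, "votc_roi"), inherits(mesh, "votc_mesh"))
  list(n_vertices = length(roi$vertices),
       area = sum(vertex_area(mesh)[roi$vertices]))
}

#' Write / read an ROI in FreeSurfer label format
#'
#' Plain-text label files: a comment header, a vertex-count line, then
#' one line per vertex: `vertex_id x y z value` with 0-based vertex ids.
#' The write-read round trip is lossless for vertex sets.
#'
#' @param roi A `votc_roi`.
#' @param mesh The mesh supplying coordinates (z padded with 0 for 2-D
#'   meshes).
#' @param path Label file path.
#' @return `write_label` returns `path` invisibly; `read_label` returns a
#'   `votc_roi`.
#' @export
write_label <- function(roi, mesh, path) {
  stopifnot(inherits(roi, "votc_roi"), inherits(mesh, "votc_mesh"))
  v <- roi$vertices
  co <- mesh$coords[v, , drop = FALSE]
  if (ncol(co) == 2L) co <- cbind(co, 0)
  lines <- c(
    sprintf("#!ascii label, votcsim ROI '%s' subject %s", roi$name,
            roi$subject_id),
    as.character(length(v)),
    sprintf("%d  %.6f  %.6f  %.6f  %.10f", v - 1L, co[, 1], co[, 2],
            co[, 3], rep(1, length(v)))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_label
#' @param name ROI name to assign on read.
#' @param subject_id Subject tag to assign on read.
#' @export
read_label <- function(path, mesh, name = basename(path),
                       subject_id = NA_character_) {
  stopifnot(inherits(mesh, "votc_mesh"))
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1], "#")) {
    stop("malformed label file (line 1): missing comment header",
         call. = FALSE)
  }
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed label file (line 2): bad vertex count",
                     call. = FALSE)
  if (length(lines) < 2L + n) {
    stop(sprintf("malformed label file (line %d): expected %d vertex lines",
                 length(lines) + 1L, n), call. = FALSE)
  }
  verts <- integer(n)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[2L + i]), "\\s+")[[1]]
    id <- suppressWarnings(as.integer(fields[1]))
    if (length(fields) < 5L || is.na(id)) {
      stop(sprintf("malformed label file (line %d)", 2L + i), call. = FALSE)
    }
    verts[i] <- id + 1L
  }
  if (any(verts < 1L | verts > mesh$n_vertices)) {
    stop("label file contains vertex indices outside the mesh",
         call. = FALSE)
  }
  new_roi(verts, name = name, subject_id = subject_id,
          mesh_n = mesh$n_vertices, source = list(file = path))
}
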