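#' Build an anatomical VOTC mask with named subregions
#'
#' Defines a ventral-occipitotemporal-cortex-like territory on a grid mesh
#' and partitions it into two anatomically motivated bands: an "ots" band
#' (occipitotemporal-sulcus-like, hosting text-, pseudofont-, and
#' limb-selective patches) and a "fusiform" band (hosting face- and
#' object-selective patches). ROI definition later constrains
#' category-selective clusters to these subregions, emulating the practice
#' of drawing functional ROIs only within anatomical limits.
#'
#' @param mesh A grid `votc_mesh`.
#' @param x_range,y_range Numeric length-2 vectors, mm: the VOTC bounding
#'   box in mesh coordinates. Defaults place a centered box covering most
#'   of the default 48 mm mesh (the mesh is essentially a VOTC flat patch
#'   with a signal-free frame).
#' @param split_y The y coordinate (mm) separating the fusiform band
#'   (below) from the OTS band (above). Default: midline of `y_range`.
#'
#' @return An object of class `votc_mask`: list with `votc` (integer
#'   vertex indices), `subregions` (named list of disjoint integer vectors
#'   partitioning `votc`), and the geometry parameters.
#' @export
make_votc_mask <- function(mesh,
                           x_range = c(4, 44),
                           y_range = c(4, 44),
                           split_y = mean(y_range)) {
  stopifnot(inherits(mesh, "votc_mesh"))
  x <- mesh$coords[, 1]
  y <- mesh$coords[, 2]
  in_votc <- x >= x_range[1] & x < x_range[2] & y >= y_range[1] & y < y_range[2]
  votc <- which(in_votc)
  if (length(votc) == 0L) stop("VOTC box contains no vertices", call. = FALSE)
  ots <- votc[y[votc] >= split_y]
  fusiform <- votc[y[votc] < split_y]
  structure(
    list(votc = votc,
         subregions = list(ots = ots, fusiform = fusiform),
         x_range = x_range, y_range = y_range, split_y = split_y),
    class = "votc_mask"
  )
}

#' @export
print.votc_mask <- function(x, ...) {
  cat(sprintf("<votc_mask: %d vertices (%s)>\n", length(x$votc),
              paste(sprintf("%s=%d", names(x$subregions),
                            lengths(x$subregions)), collapse = ", ")))
  invisible(x)
}

# Validate the mask invariants (subregions disjoint and within votc).
validate_mask <- function(mask) {
  stopifnot(inherits(mask, "votc_mask"))
  all_sub <- unlist(mask$subregions, use.names = FALSE)
  if (anyDuplicated(all_sub)) stop("mask subregions overlap", call. = FALSE)
  if (!all(all_sub %in% mask$votc)) {
    stop("mask subregions extend beyond the VOTC", call. = FALSE)
  }
  invisible(mask)
}
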