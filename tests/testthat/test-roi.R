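tmap_from <- function(values, mesh) votcsim:::new_vertex_map(values, "t")

test_that("ROI definition thresholds, clips, and may come up empty", {
  mesh <- std_mesh()
  mask <- std_mask(mesh)
  # all sub-threshold: empty ROI, not an error
  tm <- tmap_from(rep(1, mesh$n_vertices), mesh)
  expect_length(define_roi(tm, mesh, mask, "vwfa")$vertices, 0)

  # single supra-threshold vertex inside the mask: singleton
  v0 <- mask$subregions$ots[100]
  vals <- rep(0, mesh$n_vertices)
  vals[v0] <- 5
  roi <- define_roi(tmap_from(vals, mesh), mesh, mask, "vwfa")
  expect_identical(roi$vertices, v0)
  expect_equal(roi$source$threshold, 3)

  # a cluster straddling the OTS/fusiform boundary is clipped to OTS
  center <- c(20, mask$split_y)
  d <- vertex_distances(mesh, center)
  vals <- ifelse(d < 5, 6, 0)
  roi <- define_roi(tmap_from(vals, mesh), mesh, mask, "vwfa")
  expect_true(all(roi$vertices %in% mask$subregions$ots))
  expect_true(length(roi$vertices) > 0)
  # same map under the FFA rule keeps only the fusiform half
  roi_f <- define_roi(tmap_from(vals, mesh), mesh, mask, "ffa")
  expect_true(all(roi_f$vertices %in% mask$subregions$fusiform))
  expect_setequal(c(roi$vertices, roi_f$vertices),
                  intersect(which(vals > 3), mask$votc))

  expect_error(define_roi(tm, mesh, mask, "cerebellum"), "unknown subregion")
})

test_that("minimum-cluster-size filtering removes speckle", {
  mesh <- std_mesh()
  mask <- std_mask(mesh)
  ots <- mask$subregions$ots
  vals <- rep(0, mesh$n_vertices)
  blob <- intersect(which(vertex_distances(mesh, c(16, 32)) <= 3), ots)
  vals[blob] <- 6
  lone <- intersect(which(vertex_distances(mesh, c(36, 38)) < 0.5), ots)
  vals[lone] <- 6
  roi <- define_roi(tmap_from(vals, mesh), mesh, mask, "vwfa",
                    min_cluster = 5)
  expect_setequal(roi$vertices, blob)
})

test_that("thresholding is monotone: lower thresholds give supersets", {
  mesh <- std_mesh()
  mask <- std_mask(mesh)
  set.seed(1)
  vals <- stats::rnorm(mesh$n_vertices, 2, 2)
  r2 <- define_roi(tmap_from(vals, mesh), mesh, mask, "vwfa", threshold = 2)
  r3 <- define_roi(tmap_from(vals, mesh), mesh, mask, "vwfa", threshold = 3)
  r4 <- define_roi(tmap_from(vals, mesh), mesh, mask, "vwfa", threshold = 4)
  expect_true(all(r3$vertices %in% r2$vertices))
  expect_true(all(r4$vertices %in% r3$vertices))
})

test_that("dice matches its definition on hand-built cases", {
  mesh <- make_mesh("grid", 16)
  a <- roi_from_vertices(1:50, mesh, "a")
  expect_equal(dice(a, a)$dsc, 1)
  b <- roi_from_vertices(51:60, mesh, "b")
  expect_equal(dice(a, b)$dsc, 0)
  c1 <- roi_from_vertices(1:10, mesh)
  c2 <- roi_from_vertices(6:15, mesh)
  dr <- dice(c1, c2)
  expect_equal(dr$dsc, 0.5)
  expect_equal(dr$intersection_size, 5)
  # both empty: defined 0 with flag
  e <- roi_from_vertices(integer(0), mesh)
  expect_equal(dice(e, e)$dsc, 0)
  expect_true(dice(e, e)$both_empty)
  # mismatched meshes rejected
  other <- roi_from_vertices(1:5, make_mesh("grid", 8))
  expect_error(dice(a, other), "different meshes")
})

test_that("dice is symmetric and equals 1 only for identical nonempty sets", {
  mesh <- make_mesh("grid", 20)
  set.seed(3)
  for (i in 1:30) {
    a <- roi_from_vertices(sample(400, sample(0:60, 1)), mesh)
    b <- roi_from_vertices(sample(400, sample(1:60, 1)), mesh)
    expect_identical(dice(a, b)$dsc, dice(b, a)$dsc)
    if (dice(a, b)$dsc == 1) expect_setequal(a$vertices, b$vertices)
  }
})

test_that("roi_size counts vertices and tessellation area", {
  mesh <- make_mesh("grid", 2)
  full <- roi_from_vertices(1:4, mesh)
  expect_equal(roi_size(full, mesh), list(n_vertices = 4, area = 4))
  empty <- roi_from_vertices(integer(0), mesh)
  expect_equal(roi_size(empty, mesh), list(n_vertices = 0, area = 0))
  single <- roi_from_vertices(2, make_mesh("grid", 4, spacing = 2))
  expect_equal(roi_size(single, make_mesh("grid", 4, spacing = 2)),
               list(n_vertices = 1, area = 4))
})

test_that("FreeSurfer label files round-trip vertex sets exactly", {
  mesh <- std_mesh()
  roi <- roi_from_vertices(c(5, 90, 777, 2301), mesh, "VWFA", "sub-001")
  path <- withr::local_tempfile(fileext = ".label")
  write_label(roi, mesh, path)
  back <- read_label(path, mesh, name = "VWFA", subject_id = "sub-001")
  expect_identical(back$vertices, roi$vertices)

  # malformed inputs fail with a line reference
  writeLines(c("#!ascii label", "2", "0 0 0 0 1"), path)
  expect_error(read_label(path, mesh), "line")
  writeLines(c("no header", "1", "0 0 0 0 1"), path)
  expect_error(read_label(path, mesh), "header")
  writeLines(c("#!ascii label", "1",
               sprintf("%d 0 0 0 1", mesh$n_vertices)), path)
  expect_error(read_label(path, mesh), "outside the mesh")
})
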