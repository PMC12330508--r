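vmap <- function(values, kind = "contrast") votcsim:::new_vertex_map(values, kind)

test_that("registration transport is exact index arithmetic on grids", {
  mesh <- make_mesh("grid", 10)
  vals <- seq_len(100)
  m <- vmap(vals)
  # zero shift is the identity
  expect_identical(apply_registration_error(m, c(0, 0), mesh)$values,
                   as.numeric(vals))
  # one grid spacing in +x translates the map by one column
  shifted <- apply_registration_error(m, c(1, 0), mesh)$values
  expect_equal(shifted[11:100], vals[1:90])
  expect_true(all(shifted[1:10] == 0))
})

test_that("opposite shifts lower the averaged peak below either individual peak", {
  mesh <- make_mesh("grid", 20)
  center <- c(10, 10)
  peak <- exp(-vertex_distances(mesh, center)^2 / 4)
  m1 <- apply_registration_error(vmap(peak), c(3, 0), mesh)
  m2 <- apply_registration_error(vmap(peak), c(-3, 0), mesh)
  avg <- (m1$values + m2$values) / 2
  # brute-force check against direct averaging of the transported fields
  expect_lt(max(avg), max(m1$values))
  expect_lt(max(avg), max(m2$values))
})

test_that("ROI transport preserves size away from the boundary and drops at it", {
  mesh <- make_mesh("grid", 16)
  inner <- which(vertex_distances(mesh, c(7, 7)) <= 2)
  roi <- roi_from_vertices(inner, mesh)
  moved <- to_template(roi, c(2, 0), mesh)
  expect_length(moved$vertices, length(inner))
  expect_identical(to_template(roi, c(0, 0), mesh)$vertices, roi$vertices)
  # shifting far off the mesh clips vertices away
  clipped <- to_template(roi, c(14, 0), mesh)
  expect_lt(length(clipped$vertices), length(inner))

  # opposite registration shifts reduce template-space overlap
  a <- to_template(roi, c(2, 0), mesh)
  b <- to_template(roi, c(-2, 0), mesh)
  expect_lt(dice(a, b)$dsc, dice(roi, roi)$dsc)
})

test_that("probabilistic maps count coverage and keep integrality", {
  mesh <- make_mesh("grid", 8)
  rois <- list(roi_from_vertices(1:10, mesh),
               roi_from_vertices(6:12, mesh),
               roi_from_vertices(integer(0), mesh),
               roi_from_vertices(10, mesh))
  pm <- probabilistic_map(rois, mesh)
  expect_equal(pm$values[1], 0.25)
  expect_equal(pm$values[6], 0.5)
  expect_equal(pm$values[10], 0.75)
  expect_true(all(abs(pm$values * 4 - round(pm$values * 4)) < 1e-12))
  expect_error(probabilistic_map(list(), mesh), "non-empty")
  # unanimous coverage reaches 1
  pm1 <- probabilistic_map(rois[c(1, 1)], mesh)
  expect_equal(pm1$values[1], 1)
})

test_that("group ROIs use a strict probability threshold", {
  mesh <- make_mesh("grid", 8)
  rois <- lapply(1:5, function(i) {
    roi_from_vertices(if (i == 1) 1:4 else 2:4, mesh)
  })
  pm <- probabilistic_map(rois, mesh)   # vertex 1 at exactly 0.2
  g <- group_roi(pm, 0.2)
  expect_false(1 %in% g$vertices)
  expect_true(all(2:4 %in% g$vertices))
  # threshold 0 returns the union of the ROIs; threshold 1 is empty
  expect_setequal(group_roi(pm, 0)$vertices,
                  sort(unique(unlist(lapply(rois, `[[`, "vertices")))))
  expect_length(group_roi(pm, 1)$vertices, 0)
})

test_that("overlap indicator partitions the template and rounds percentages", {
  mesh <- make_mesh("grid", 8)
  text <- list(roi_from_vertices(1:5, mesh))
  face <- list(roi_from_vertices(4:9, mesh))
  ind <- overlap_indicator(text, face, mesh)
  expect_equal(sum(ind$counts), 64)
  expect_equal(unname(ind$counts["both"]), 2)
  expect_equal(unname(ind$counts["text_only"]), 3)
  # a larger template denominator swells "neither" only
  ind2 <- overlap_indicator(text, face, mesh, template_total = 1000)
  expect_equal(sum(ind2$counts), 1000)
  expect_equal(ind2$counts[c("text_only", "face_only", "both")],
               ind$counts[c("text_only", "face_only", "both")])
  # no face ROIs: both-count is zero
  ind3 <- overlap_indicator(text, list(), mesh)
  expect_equal(unname(ind3$counts["both"]), 0)
  # identical text and face ROI labels those vertices as both
  ind4 <- overlap_indicator(text, text, mesh)
  expect_equal(unname(ind4$counts["both"]), 5)
  expect_equal(unname(ind4$counts["text_only"]), 0)
})

test_that("group t-maps implement the one-sample t with sentinels", {
  mesh <- make_mesh("grid", 4)
  zeros <- lapply(1:3, function(i) vmap(rep(0, 16)))
  expect_true(all(group_t_map(zeros)$values == 0))

  vals <- list(vmap(rep(1, 16)), vmap(rep(2, 16)), vmap(rep(3, 16)))
  gt <- group_t_map(vals)
  expect_equal(gt$values[1], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(gt$meta$dof, 2)

  # zero-variance, non-zero mean: signed infinity
  same <- lapply(1:3, function(i) vmap(rep(c(2, -2), 8)))
  expect_true(all(group_t_map(same)$values == rep(c(Inf, -Inf), 8)))
  expect_error(group_t_map(vals[1]), "at least 2")
})

test_that("group-level text t decays as spatial jitter grows", {
  # geometry-only ladder: per-subject truth text fields transported to
  # template, no measurement noise, common seeds across jitter levels;
  # a single-patch configuration isolates jitter as the only mechanism
  mesh <- std_mesh()
  mask <- std_mask(mesh)
  max_t <- vapply(c(0, 4, 12), function(jit) {
    cfg <- cohort_config("children", noise_sd = 0, registration_sd = 0)
    cfg$patches <- cfg$patches["text"]
    lays <- sample_population(mesh, mask, n_subjects = 30, config = cfg,
                              variability = c(text = jit), seed = 77)
    maps <- lapply(lays, function(l) {
      con <- amplitude_field(mesh, mask, l, "text", "fixation") -
        l$common_response
      to_template(vmap(con), l$registration_shift, mesh)
    })
    gt <- group_t_map(maps)
    max(gt$values[is.finite(gt$values)])
  }, numeric(1))
  expect_true(all(diff(max_t) <= 0))
})
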