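# model_geometry: readers, domain measures, outline projection.

test_that("JSON contour models round-trip through the writer and reader", {
  model <- contour_model(list(
    list(class = "BM", contours = lapply(0:50, function(k)
      circle_pts(1000, 1000, k * 10, 400, 60L))),
    list(class = "ILV", contours = list(circle_pts(900, 1000, 250, 40, 24L))),
    list(class = "ILV", contours = list(circle_pts(1100, 950, 260, 35, 24L))),
    list(class = "RT", contours = list(circle_pts(1500, 1000, 250, 25, 24L)))),
    z_step_nm = 10, endosome_id = "rt1")
  path <- withr::local_tempfile(fileext = ".json")
  write_contour_model(model, path)
  back <- read_contour_model(path, "json")
  expect_identical(back$endosome_id, "rt1")
  expect_identical(class_counts(back), c(BM = 1L, ILV = 2L, RT = 1L))
  expect_true(is_analysable(back))
  expect_equal(back$objects[[1]]$contours[[5]],
               unname(model$objects[[1]]$contours[[5]]),
               ignore_attr = TRUE)
})

test_that("imod point lists parse to the same contours as the JSON dialect", {
  model <- flat_model()
  dir <- withr::local_tempdir()
  pj <- file.path(dir, "m.json"); pi <- file.path(dir, "m.pts")
  write_contour_model(model, pj, "json")
  write_contour_model(model, pi, "imod_points")
  a <- read_contour_model(pj, "json")
  b <- read_contour_model(pi, "imod_points",
                          class_map = list("1" = "BM", "2" = "ILV",
                                           "3" = "RT"),
                          z_step_nm = 10)
  for (i in seq_along(a$objects)) {
    expect_identical(a$objects[[i]]$class, b$objects[[i]]$class)
    for (j in seq_along(a$objects[[i]]$contours))
      expect_equal(unname(a$objects[[i]]$contours[[j]]),
                   unname(b$objects[[i]]$contours[[j]]), tolerance = 1e-8)
  }
})

test_that("invalid models are rejected with informative errors", {
  two_pt <- list(list(class = "BM",
                      contours = list(cbind(c(0, 1), c(0, 1), c(0, 0)))))
  expect_error(contour_model(two_pt, 10), "fewer than 3 points")
  mixed_z <- list(list(class = "BM",
                       contours = list(cbind(c(0, 1, 2), c(0, 1, 0),
                                             c(0, 0, 5)))))
  expect_error(contour_model(mixed_z, 10), "share one z")
  expect_error(contour_model(list(list(class = "XX", contours =
    list(circle_pts(5, 5, 0, 2)))), 10), "unknown compartment class")
  expect_error(contour_model(list(list(class = "BM", contours = list())), 10),
               "empty object")
  off_grid <- list(list(class = "BM",
                        contours = list(circle_pts(50, 50, 7, 20))))
  expect_error(contour_model(off_grid, 10), "not a multiple of z_step")
})

test_that("length2d measures closed-polygon perimeter", {
  r <- 100
  m <- contour_model(list(list(class = "BM",
                               contours = list(circle_pts(500, 500, 0, r,
                                                          360L)))),
                     z_step_nm = 10)
  dm <- compute_domain_measure(m, "length2d")
  expect_equal(dm$per_class[["BM"]], 2 * pi * r, tolerance = 1e-3)
  expect_identical(dm$unit, "nm")
  expect_error(compute_domain_measure(sphere_model(), "length2d"),
               "single-plane")
})

test_that("area3d reproduces cylinder and sphere analytics", {
  r <- 50; h <- 200
  dm <- compute_domain_measure(cylinder_model(r, h, 11L), "area3d")
  expect_equal(dm$per_class[["ILV"]], 2 * pi * r * h + 2 * pi * r^2,
               tolerance = 0.05)
  R <- 200
  dms <- compute_domain_measure(sphere_model(R, 41L), "area3d")
  expect_equal(dms$per_class[["ILV"]], 4 * pi * R^2, tolerance = 0.05)
})

test_that("mesh sphere area error is monotone non-increasing in slice count", {
  R <- 200
  errs <- vapply(c(11L, 21L, 41L), function(n) {
    a <- compute_domain_measure(sphere_model(R, n), "area3d")$per_class[["ILV"]]
    abs(a - 4 * pi * R^2) / (4 * pi * R^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("domain measure total is the exact per-class sum", {
  dm <- compute_domain_measure(flat_model(), "length2d")
  expect_identical(dm$total, sum(dm$per_class))
  gen <- generate_endosome_scene("fig5_sm", seed = 7)
  dm3 <- compute_domain_measure(gen$model, "area3d")
  expect_identical(dm3$total, sum(dm3$per_class))
})

test_that("single-slice 3D objects become flat discs with a warning", {
  m <- contour_model(list(list(class = "ILV",
                               contours = list(circle_pts(200, 200, 0, 50,
                                                          180L)))),
                     z_step_nm = 10)
  expect_warning(dm <- compute_domain_measure(m, "area3d"), "single slice")
  expect_equal(dm$per_class[["ILV"]], 2 * pi * 50^2, tolerance = 0.01)
})

test_that("projection rasterizes outlines and clips with a warning", {
  m <- contour_model(list(list(class = "BM",
                               contours = list(circle_pts(30, 30, 0, 12,
                                                          180L)))),
                     z_step_nm = 10)
  ras <- project_outlines(m, diag(3), c(64, 64))$BM
  # brute-force pixel set from transforming every (densified) contour point
  expect_gt(sum(ras), 0)
  pts <- m$objects[[1]]$contours[[1]][, 1:2]
  on_circle <- abs(sqrt((which(ras == 1L, arr.ind = TRUE)[, 2] - 1 - 30)^2 +
                          (which(ras == 1L, arr.ind = TRUE)[, 1] - 1 - 30)^2) -
                     12)
  expect_lt(max(on_circle), 1)   # 1-px wide ring on the circle
  # equivariance under integer translation
  tr <- diag(3); tr[1, 3] <- 5; tr[2, 3] <- 3
  shifted <- project_outlines(m, tr, c(64, 64))$BM
  expect_identical(shifted[(1:40) + 3, (1:40) + 5], ras[1:40, 1:40])
  # all points outside -> error; partial clip -> warning
  far <- diag(3); far[1, 3] <- 500
  expect_error(project_outlines(m, far, c(64, 64)), "field of view")
  part <- diag(3); part[1, 3] <- 28
  expect_warning(project_outlines(m, part, c(64, 64)), "clipped")
  expect_error(project_outlines(m, matrix(0, 3, 3), c(64, 64)), "singular")
})

test_that("sphere-stack projection covers the silhouette band densely", {
  m <- sphere_model(R = 200, n_slices = 41L)
  tm <- diag(c(0.1, 0.1, 1))  # 10 nm/px
  ras <- project_outlines(m, tm, c(220, 220))$ILV
  idx <- which(ras == 1L, arr.ind = TRUE)
  rad <- sqrt((idx[, 2] - 1 - 100)^2 + (idx[, 1] - 1 - 100)^2)
  expect_lt(max(rad), 21)       # inside the silhouette
  expect_gt(max(rad), 19.0)       # reaches the limb
  n11 <- sum(project_outlines(sphere_model(200, 11L), tm, c(220, 220))$ILV)
  expect_gt(sum(ras), n11)        # support grows with slice count
})
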