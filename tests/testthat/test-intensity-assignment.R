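# intensity_assignment: background, value PDFs, fractional assignment.

test_that("background estimation recovers constant and blob-on-constant fields", {
  masks <- random_masks(seed = 2)
  part <- partition_masks(masks)
  img <- matrix(7, 48, 48)
  cfg <- assign_config()
  expect_equal(estimate_background(img, part, cfg), 7)
  img2 <- matrix(10, 48, 48)
  img2[masks$BM] <- 200
  expect_equal(estimate_background(img2, part, cfg), 10)
  # explicit ROI median
  roi <- matrix(FALSE, 48, 48); roi[1:5, 1:5] <- TRUE
  cfg_roi <- assign_config(background = background_rule("roi_median",
                                                        roi = roi))
  expect_equal(estimate_background(img2, part, cfg_roi), 10)
  # union covering everything -> error
  allm <- list(BM = matrix(TRUE, 4, 4))
  expect_error(estimate_background(matrix(1, 4, 4), partition_masks(allm),
                                   cfg), "outside the union")
})

test_that("value PDFs match Gaussian-kernel closed forms", {
  cfg <- assign_config(kde_bandwidth = 1)
  f1 <- fit_value_pdf(5, cfg)
  expect_equal(pdf_eval(f1, 5), 1 / sqrt(2 * pi))
  f2 <- fit_value_pdf(c(0, 10), cfg)
  expect_equal(pdf_eval(f2, 0), pdf_eval(f2, 10))
  expect_equal(pdf_eval(f2, 0),
               (stats::dnorm(0) + stats::dnorm(10)) / 2)
  expect_s3_class(fit_value_pdf(numeric(0), cfg), "value_pdf_unavailable")
})

test_that("the KDE is consistent against the true density at large n", {
  set.seed(42)
  x <- rnorm(1e4, mean = 50, sd = 4)
  f <- fit_value_pdf(x, assign_config(kde_bandwidth = 1))
  grid <- seq(30, 70, by = 0.25)
  # kernel-smoothed truth: N(50, sqrt(16 + 1))
  expect_lt(max(abs(pdf_eval(f, grid) -
                      stats::dnorm(grid, 50, sqrt(17)))), 0.01)
})

test_that("symmetric PDFs halve an overlap pixel; separated PDFs capture it", {
  a <- matrix(FALSE, 20, 40); a[5:15, 5:20] <- TRUE
  b <- matrix(FALSE, 20, 40); b[5:15, 14:29] <- TRUE  # same exclusive size
  part <- partition_masks(list(BM = a, ILV = b))
  img <- matrix(0, 20, 40)
  img[a & !b] <- 3   # identical exclusive value distributions
  img[b & !a] <- 3
  img[a & b] <- 8
  cfg <- assign_config(background = background_rule("roi_median"))
  it <- assign_intensities(list(ch = img), part, cfg)
  expect_equal(it$intensity[it$class == "BM"],
               it$intensity[it$class == "ILV"])
  # strongly separated value distributions: overlap value near A's support
  img2 <- matrix(0, 20, 40)
  set.seed(1)
  img2[a & !b] <- rnorm(sum(a & !b), 10, 1)
  img2[b & !a] <- rnorm(sum(b & !a), 100, 1)
  img2[a & b] <- 10
  it2 <- assign_intensities(list(ch = img2), part, cfg)
  va <- fit_value_pdf(pmax(img2[a & !b], 0), cfg)
  vb <- fit_value_pdf(pmax(img2[b & !a], 0), cfg)
  frac_a <- pdf_eval(va, 10) / (pdf_eval(va, 10) + pdf_eval(vb, 10))
  expect_gte(frac_a, 0.99)
  overlap_total <- sum(img2[a & b])
  expect_equal(it2$intensity[it2$class == "BM"],
               sum(img2[a & !b]) + frac_a * overlap_total, tolerance = 1e-9)
})

test_that("missing PDFs trigger the configured fallback, conserving totals", {
  a <- matrix(FALSE, 12, 12); a[4:9, 4:9] <- TRUE
  b <- a  # identical masks: no exclusive pixels at all
  part <- partition_masks(list(BM = a, ILV = b))
  img <- matrix(0, 12, 12); img[a] <- 6
  cfg <- assign_config(background = background_rule("roi_median"))
  it <- assign_intensities(list(ch = img), part, cfg)
  expect_equal(it$intensity, rep(sum(img[a]) / 2, 2))
  expect_equal(sum(it$intensity), unname(attr(it, "total")["ch"]))
  # area_split weights by exclusive pixel counts
  b2 <- matrix(FALSE, 12, 12); b2[4:9, 4:11] <- TRUE  # B has exclusive px
  part2 <- partition_masks(list(BM = a, ILV = b2))
  img2 <- matrix(0, 12, 12); img2[b2] <- 3; img2[a] <- 6
  it_eq <- assign_intensities(list(ch = img2), part2, cfg)
  # A has no exclusive pixels -> fallback splits the overlap equally
  expect_equal(it_eq$intensity[it_eq$class == "BM"], sum(img2[a]) / 2)
})

test_that("fractional assignment matches the brute-force oracle to 1e-10", {
  set.seed(11)
  masks <- random_masks(seed = 5)
  img <- matrix(rpois(48 * 48, 8), 48, 48)
  img[masks$BM] <- img[masks$BM] + rpois(sum(masks$BM), 30)
  img[masks$ILV] <- img[masks$ILV] + rpois(sum(masks$ILV), 60)
  part <- partition_masks(masks)
  it <- assign_intensities(list(ch = img), part, assign_config())
  want <- oracle_assign(list(ch = img), masks)$ch
  expect_equal(stats::setNames(it$intensity, it$class), want,
               tolerance = 1e-10)
})

test_that("assignment is deterministic and conserves on every input", {
  gen <- generate_endosome_scene("fig5_sm", seed = 4)
  ren <- render_channels(gen$model, gen$scene)
  outl <- project_outlines(gen$model, ren$transform,
                           dim(ren$images$lipid))
  part <- partition_masks(build_class_masks(outl, synthetic_mask_cfg()))
  cfg <- synthetic_assign_cfg()
  it1 <- assign_intensities(ren$images, part, cfg)
  it2 <- assign_intensities(ren$images, part, cfg)
  expect_identical(it1, it2)
  tot <- attr(it1, "total")
  for (ch in names(ren$images)) {
    s <- sum(it1$intensity[it1$channel == ch])
    expect_lt(abs(s - tot[ch]) / tot[ch], 1e-6)
  }
  expect_error(run_quantify(gen$model, ren$images[c("Tf", "LDL")],
                            ren$transform, channels = CLEM_CHANNELS),
               "missing channel.*lipid")
})
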