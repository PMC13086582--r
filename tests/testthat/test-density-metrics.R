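# density_metrics: the three density formulas, bounds, condition comparison.

fake_intensity_table <- function(i_d, channel = "lipid", id = "e1") {
  df <- data.frame(endosome_id = id, class = names(i_d), channel = channel,
                   intensity = unname(i_d), background = 0,
                   n_exclusive_px = 10L, stringsAsFactors = FALSE)
  structure(df, total = stats::setNames(sum(i_d), channel),
            background = stats::setNames(0, channel),
            class = c("intensity_table", "data.frame"))
}

fake_measure <- function(a_d, mode = "area3d") {
  structure(list(per_class = a_d, total = sum(a_d), mode = mode,
                 unit = "nm^2"), class = "domain_measure")
}

test_that("intensities proportional to areas give relative density 1", {
  a <- c(BM = 60, ILV = 30, RT = 10)
  res <- compute_densities(fake_intensity_table(3.7 * a), fake_measure(a))
  expect_equal(res$relative_density, rep(1, 3))
})

test_that("full concentration attains the enrichment bound exactly", {
  a <- c(BM = 60, ILV = 20, RT = 20)
  i <- c(BM = 0, ILV = 0, RT = 123)
  res <- compute_densities(fake_intensity_table(i), fake_measure(a))
  expect_equal(rel_density(res, "RT", "lipid"), 5)
  expect_equal(res$max_fold_enrichment[res$class == "RT"], 5)
  expect_equal(rel_density(res, "BM", "lipid"), 0)
})

test_that("random tables match a direct spreadsheet-style recomputation", {
  set.seed(9)
  for (rep in 1:25) {
    a <- stats::setNames(runif(3, 1, 100), c("BM", "ILV", "RT"))
    i <- stats::setNames(runif(3, 0.1, 50), c("BM", "ILV", "RT"))
    res <- compute_densities(fake_intensity_table(i), fake_measure(a))
    # independent recomputation straight from the printed formulas
    d <- i / a
    r <- d / (sum(i) / sum(a))
    m <- sum(a) / a
    expect_equal(stats::setNames(res$relative_density, res$class), r)
    expect_equal(stats::setNames(res$density, res$class), d)
    expect_equal(stats::setNames(res$max_fold_enrichment, res$class), m)
    expect_true(all(res$relative_density <= res$max_fold_enrichment + 1e-9))
    expect_equal(sum(res$area / sum(a) * res$relative_density), 1,
                 tolerance = 1e-9)
  }
})

test_that("max fold enrichment follows the area-ratio formula", {
  m <- fake_measure(c(BM = 60, ILV = 30, RT = 10))
  expect_equal(max_fold_enrichment(m),
               c(BM = 10 / 6, ILV = 10 / 3, RT = 10), tolerance = 1e-9)
  expect_equal(max_fold_enrichment(fake_measure(c(BM = 42))), c(BM = 1))
  # algebraic identity: sum_d (A_d / A_tot) M_d = number of classes
  set.seed(3)
  for (rep in 1:10) {
    a <- stats::setNames(runif(3, 0.1, 10), c("BM", "ILV", "RT"))
    expect_equal(sum(a / sum(a) * max_fold_enrichment(fake_measure(a))), 3)
  }
})

test_that("scale invariance: channel gain leaves relative densities unchanged", {
  a <- c(BM = 55, ILV = 25, RT = 20)
  i <- c(BM = 12, ILV = 31, RT = 2)
  r1 <- compute_densities(fake_intensity_table(i), fake_measure(a))
  r2 <- compute_densities(fake_intensity_table(i * 817.3), fake_measure(a))
  expect_equal(r1$relative_density, r2$relative_density)
})

test_that("mismatched classes and degenerate inputs error", {
  a <- c(BM = 60, ILV = 30, RT = 10)
  expect_error(compute_densities(fake_intensity_table(c(BM = 1, ILV = 2)),
                                 fake_measure(a)), "class sets differ")
  expect_error(max_fold_enrichment(fake_measure(c(BM = 0, ILV = 1, RT = 1))),
               "zero domain measure")
})

test_that("compare_conditions reproduces the pooled-variance Student t", {
  mk <- function(r, id) {
    a <- c(BM = 60, ILV = 30, RT = 10)
    i <- c(BM = 60, ILV = 30, RT = 10) * c(1, 1, r)
    compute_densities(fake_intensity_table(i, id = id), fake_measure(a))
  }
  ra <- lapply(c(1, 2, 3, 4), function(r) mk(r, paste0("a", r)))
  rb <- lapply(c(2, 3, 4, 5), function(r) mk(r, paste0("b", r)))
  # RT relative densities are r / (1 + (r - 1) / 10) -- recover the raw
  # values instead with a direct construction
  va <- sapply(ra, function(x) rel_density(x, "RT", "lipid"))
  vb <- sapply(rb, function(x) rel_density(x, "RT", "lipid"))
  cmp <- compare_conditions(ra, rb, "RT", "lipid")
  # independent hand computation of the pooled two-sample t
  sp2 <- (3 * var(va) + 3 * var(vb)) / 6
  t_hand <- (mean(va) - mean(vb)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 6)
  expect_equal(cmp$statistic, t_hand, tolerance = 1e-12)
  expect_equal(cmp$p_value, p_hand, tolerance = 1e-12)
  expect_true(cmp$ci["a", "lower"] <= cmp$mean["a"] &&
                cmp$mean["a"] <= cmp$ci["a", "upper"])
})

test_that("literal samples 1:4 vs 2:5 give t = -1.0954, p = 0.3153", {
  # frozen against the closed-form pooled t (and scipy.stats.ttest_ind):
  # the two-sample pooled t for these lists is -1.095445, p = 0.315334
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * 0.5)
  expect_equal(t_hand, -1.095445, tolerance = 1e-6)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(unname(tt$statistic), t_hand)
  expect_equal(tt$p.value, 0.315334, tolerance = 1e-5)
})

test_that("identical conditions give t = 0, p = 1; n < 2 errors", {
  mk <- function(i, id) compute_densities(
    fake_intensity_table(i, id = id),
    fake_measure(c(BM = 60, ILV = 30, RT = 10)))
  r1 <- lapply(1:3, function(k) mk(c(BM = 10, ILV = 20, RT = 5 + k), "x"))
  cmp <- compare_conditions(r1, r1, "ILV", "lipid")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_error(compare_conditions(r1[1], r1, "ILV", "lipid"), ">= 2")
})
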