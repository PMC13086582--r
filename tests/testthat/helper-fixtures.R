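# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; the oracles deliberately re-derive results by the
# dumbest possible route (per-pixel loops, direct formulas) so they stay
# independent of the package internals they check.

# -- geometric fixtures -------------------------------------------------

circle_pts <- function(cx, cy, z, r, n = 90L) {
  th <- (seq_len(n) - 1L) / n * 2 * pi
  cbind(x = cx + r * cos(th), y = cy + r * sin(th), z = z)
}

# capped cylinder: identical circles on n_slices planes
cylinder_model <- function(r = 50, h = 200, n_slices = 11L, n_pts = 180L,
                           class = "ILV") {
  z_step <- h / (n_slices - 1L)
  contours <- lapply(seq_len(n_slices) - 1L, function(k)
    circle_pts(500, 500, k * z_step, r, n_pts))
  contour_model(list(list(class = class, contours = contours)),
                z_step_nm = z_step)
}

# sphere sampled as circle contours away from the poles
sphere_model <- function(R = 200, n_slices = 41L, n_pts = 180L,
                         class = "ILV") {
  z <- seq(-R, R, length.out = n_slices + 2L)[2:(n_slices + 1L)]
  z_step <- z[2] - z[1]
  contours <- lapply(z, function(zz)
    circle_pts(1000, 1000, zz - z[1], sqrt(R^2 - zz^2), n_pts))
  contour_model(list(list(class = class, contours = contours)),
                z_step_nm = z_step)
}

# small three-class single-plane model for 2D-mode tests
flat_model <- function() {
  contour_model(list(
    list(class = "BM", contours = list(circle_pts(300, 300, 0, 200, 120L))),
    list(class = "ILV", contours = list(circle_pts(260, 300, 0, 40, 60L),
                                        circle_pts(350, 280, 0, 30, 60L))),
    list(class = "RT", contours = list(circle_pts(560, 300, 0, 25, 60L)))),
    z_step_nm = 10)
}

# -- brute-force oracles ------------------------------------------------

# per-pixel set-membership partition oracle
oracle_partition_labels <- function(masks) {
  nr <- nrow(masks[[1]]); nc <- ncol(masks[[1]])
  lab <- matrix("", nr, nc)
  for (r in seq_len(nr)) for (c0 in seq_len(nc)) {
    covering <- names(masks)[vapply(masks, function(m) m[r, c0], logical(1))]
    lab[r, c0] <- paste(covering, collapse = ",")
  }
  lab
}

# direct KDE-mixture fractional assignment, looping over pixels and kernels
oracle_assign <- function(images, masks, bandwidth = 1, p_bg = 5) {
  classes <- names(masks)
  lab <- oracle_partition_labels(masks)
  out <- list()
  for (ch in names(images)) {
    img <- images[[ch]]
    b <- unname(stats::quantile(img[lab == ""], p_bg / 100))
    corr <- pmax(img - b, 0)
    excl_vals <- lapply(classes, function(k) corr[lab == k])
    names(excl_vals) <- classes
    i_d <- stats::setNames(rep(0, length(classes)), classes)
    for (k in classes) i_d[k] <- sum(excl_vals[[k]])
    over_labels <- setdiff(unique(as.vector(lab)), c("", classes))
    for (ol in over_labels) {
      s <- strsplit(ol, ",")[[1]]
      vals <- corr[lab == ol]
      if (all(vapply(excl_vals[s], length, integer(1)) > 0)) {
        for (v in vals) {
          f <- vapply(s, function(k)
            mean(stats::dnorm(v, excl_vals[[k]], bandwidth)), numeric(1))
          if (sum(f) > 1e-290) {
            for (k in s) i_d[k] <- i_d[k] + v * f[k] / sum(f)
          } else {
            for (k in s) i_d[k] <- i_d[k] + v / length(s)
          }
        }
      } else {
        for (k in s) i_d[k] <- i_d[k] + sum(vals) / length(s)
      }
    }
    out[[ch]] <- i_d
  }
  out
}

# direct bilinear interpolation at one (x, y), 0-based pixel centers
oracle_bilinear <- function(img, x, y) {
  x0 <- min(floor(x), ncol(img) - 2); y0 <- min(floor(y), nrow(img) - 2)
  fx <- x - x0; fy <- y - y0
  img[y0 + 1, x0 + 1] * (1 - fx) * (1 - fy) +
    img[y0 + 1, x0 + 2] * fx * (1 - fy) +
    img[y0 + 2, x0 + 1] * (1 - fx) * fy +
    img[y0 + 2, x0 + 2] * fx * fy
}

# random blob masks for partition / assignment tests
random_masks <- function(shape = c(48L, 48L), n_classes = 3L, seed = 1L) {
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
  masks <- lapply(seq_len(n_classes), function(i) {
    cx <- runif(1, 8, nc - 8); cy <- runif(1, 8, nr - 8)
    rad <- runif(1, 8, 16)
    (xs - cx)^2 + (ys - cy)^2 <= rad^2
  })
  names(masks) <- c("BM", "ILV", "RT")[seq_len(n_classes)]
  masks
}

# standard pipeline settings for synthetic scenes: mask blur matched to the
# scene PSF, unbiased background (median of the signal-free surround)
synthetic_mask_cfg <- function(params = scene_params()) {
  mask_config(sigma_px = suggest_mask_sigma(params$psf_sigma_nm,
                                            params$pixel_size_nm))
}

synthetic_assign_cfg <- function() {
  assign_config(background = background_rule("roi_median"))
}

quantify_scene <- function(preset, seed, params = scene_params()) {
  gen <- generate_endosome_scene(preset, seed = seed, params = params)
  ren <- render_channels(gen$model, gen$scene)
  res <- run_quantify(gen$model, ren$images, ren$transform,
                      mask_cfg = synthetic_mask_cfg(params),
                      assign_cfg = synthetic_assign_cfg())
  list(gen = gen, ren = ren, res = res)
}

rel_density <- function(res, class, channel) {
  res$relative_density[res$class == class & res$channel == channel]
}
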