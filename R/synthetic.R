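# Synthetic endosome scenes and section stacks with known ground truth.
#
# The generator emulates what the quantification assumes about real data:
# an endosome whose membranes lie inside a resin section of finite
# thickness (the tomographic slab), membrane-area-proportional fluorophore
# emission with compartment-specific densities, widefield PSF blur,
# uniform background, and shot noise. Geometry is a boundary-membrane (BM)
# sphere truncated by the slab, intraluminal vesicles (ILVs) inside it,
# and one recycling tubule (RT) protruding radially outward in the slab.

scene_presets <- function() {
  # relative membrane densities (a.u.), class x channel; the lipid column of
  # fig5_sm follows the published SM pattern (BM 0.9, ILV 3.6, RT 0.5),
  # fig5_fa the bulk fatty-acid pattern (0.73 / 2.52 / 1.23); Tf is enriched
  # in RTs and LDL in ILVs in both, mirroring the cargo internal standards.
  lip_sm <- c(BM = 0.9, ILV = 3.6, RT = 0.5)
  lip_fa <- c(BM = 0.73, ILV = 2.52, RT = 1.23)
  tf <- c(BM = 0.9, ILV = 0.5, RT = 2.07)
  ldl <- c(BM = 0.6, ILV = 5.73, RT = 0.4)
  list(
    fig5_sm = cbind(lipid = lip_sm, Tf = tf, LDL = ldl),
    fig5_fa = cbind(lipid = lip_fa, Tf = tf, LDL = ldl),
    uniform = cbind(lipid = c(BM = 1, ILV = 1, RT = 1),
                    Tf = c(BM = 1, ILV = 1, RT = 1),
                    LDL = c(BM = 1, ILV = 1, RT = 1)))
}

#' Default synthetic scene parameters
#'
#' The stated world of the recovery tests. Geometry: BM sphere radius 800 nm
#' truncated by a 500 nm section (the tomography section thickness), three
#' to six ILVs of 40 nm radius, one RT of 25 nm radius and 1100 nm length;
#' chosen so that the class area shares give relative-density ground truth
#' close to the published enrichment pattern. Imaging: 65 nm camera pixels,
#' 150 nm PSF sigma, background 20 counts, Poisson noise,
#' 0.05 expected photons per nm^2 of membrane at relative density 1.
#'
#' @param ... overrides for any listed parameter.
#' @return list of parameters.
#' @export
scene_params <- function(...) {
  p <- list(
    bm_radius_nm = 800,
    section_thickness_nm = 500,
    z_step_nm = 10,
    n_ilv = 6L,
    ilv_radius_nm = 40,
    ilv_max_radial_nm = 450,
    ilv_min_gap_nm = 15,
    rt_radius_nm = 25,
    rt_length_nm = 1100,
    contour_spacing_nm = 20,
    pixel_size_nm = 65,
    psf_sigma_nm = 150,
    image_size_px = 128L,
    background = 20,
    mean_density_photons_nm2 = 0.05,
    noise = "poisson",        # "poisson", "gaussian", or "none"
    read_noise_sd = 0)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  assert_that(length(unknown) == 0, "unknown scene parameter(s): ",
              paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

circle_contour <- function(cx, cy, z, r, spacing) {
  n <- max(12L, ceiling(2 * pi * r / spacing))
  th <- (seq_len(n) - 1L) / n * 2 * pi
  cbind(x = cx + r * cos(th), y = cy + r * sin(th), z = z)
}

#' Generate a synthetic endosome scene
#'
#' Draws a randomized geometry (ILV placements, RT attachment azimuth and
#' height) under the preset's membrane densities, samples the membranes as
#' classified closed contours on the z-step grid inside the section slab,
#' and computes the ground-truth per-class relative densities from the
#' realized mesh areas.
#'
#' @param preset `"fig5_sm"`, `"fig5_fa"` or `"uniform"`.
#' @param seed RNG seed (recorded in the scene).
#' @param params parameter list from [scene_params()].
#' @return list with `model` (a `contour_model`) and `scene` (parameters,
#'   density matrix `rho`, ground-truth `relative_density` matrix,
#'   `measures`, `seed`, `preset`).
#' @export
generate_endosome_scene <- function(preset = c("fig5_sm", "fig5_fa", "uniform"),
                                    seed = 1L, params = scene_params()) {
  preset <- match.arg(preset)
  p <- params
  seed <- as.integer(seed)
  set.seed(seed)
  ctr_px <- (p$image_size_px - 1) / 2
  cx <- ctr_px * p$pixel_size_nm
  cy <- cx
  half <- p$section_thickness_nm / 2
  zc <- ceiling((half + p$z_step_nm) / p$z_step_nm) * p$z_step_nm +
    p$z_step_nm  # slab centre, keeps all plane z >= 0 on the step grid
  r_bm <- p$bm_radius_nm
  assert_that(half < r_bm, "section must be thinner than the BM diameter")

  planes <- seq(zc - half, zc + half, by = p$z_step_nm)
  # BM: truncated sphere, one ring per plane
  bm_contours <- lapply(planes, function(z)
    circle_contour(cx, cy, z, sqrt(r_bm^2 - (z - zc)^2),
                   p$contour_spacing_nm))

  # ILVs: spheres fully inside both the BM and the slab, non-overlapping
  r_i <- p$ilv_radius_nm
  max_zoff <- half - r_i - p$z_step_nm
  assert_that(max_zoff > 0, "ILVs do not fit inside the section")
  centers <- matrix(numeric(0), 0, 3)
  guard <- 0L
  while (nrow(centers) < p$n_ilv && guard < 5000L) {
    guard <- guard + 1L
    rad <- sqrt(stats::runif(1)) * p$ilv_max_radial_nm
    th <- stats::runif(1, 0, 2 * pi)
    cand <- c(cx + rad * cos(th), cy + rad * sin(th),
              zc + stats::runif(1, -max_zoff, max_zoff))
    assert_that(sqrt(sum((cand - c(cx, cy, zc))^2)) + r_i < r_bm,
                "ILV outside the boundary membrane")
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >
              2 * r_i + p$ilv_min_gap_nm))
      centers <- rbind(centers, cand)
  }
  assert_that(nrow(centers) == p$n_ilv,
              "could not place ", p$n_ilv, " non-overlapping ILVs")
  ilv_objects <- lapply(seq_len(p$n_ilv), function(i) {
    cc <- centers[i, ]
    zs <- planes[abs(planes - cc[3]) < r_i - 1e-9]
    contours <- lapply(zs, function(z)
      circle_contour(cc[1], cc[2], z, sqrt(r_i^2 - (z - cc[3])^2),
                     p$contour_spacing_nm / 4))
    contours <- contours[vapply(contours, function(ct)
      polygon_perimeter(ct) > 0, logical(1))]
    list(class = "ILV", contours = contours)
  })

  # RT: radial tube in the slab, attached at the BM surface pointing outward
  r_t <- p$rt_radius_nm
  z_rt <- zc + stats::runif(1, -(half - r_t - 2 * p$z_step_nm),
                            half - r_t - 2 * p$z_step_nm)
  th_rt <- stats::runif(1, 0, 2 * pi)
  u <- c(cos(th_rt), sin(th_rt))
  nv <- c(-u[2], u[1])
  s0 <- sqrt(r_bm^2 - (z_rt - zc)^2) - 2  # tiny inset into the BM surface
  s1 <- s0 + p$rt_length_nm
  zs <- planes[abs(planes - z_rt) < r_t - 1e-9]
  rt_contours <- lapply(zs, function(z) {
    w <- sqrt(r_t^2 - (z - z_rt)^2)
    s_seq <- seq(s0, s1, length.out =
                   max(8L, ceiling((s1 - s0) / p$contour_spacing_nm)))
    t_seq <- seq(-w, w, length.out = max(3L, ceiling(2 * w / 8) + 1L))
    ring <- rbind(
      cbind(s_seq, -w),
      cbind(s1, t_seq[-c(1, length(t_seq))]),
      cbind(rev(s_seq), w),
      cbind(s0, rev(t_seq[-c(1, length(t_seq))])))
    cbind(x = cx + ring[, 1] * u[1] + ring[, 2] * nv[1],
          y = cy + ring[, 1] * u[2] + ring[, 2] * nv[2], z = z)
  })

  objects <- c(list(list(class = "BM", contours = bm_contours)),
               ilv_objects,
               list(list(class = "RT", contours = rt_contours)))
  model <- contour_model(objects, z_step_nm = p$z_step_nm,
                         endosome_id = sprintf("synthetic_%s_seed%d",
                                               preset, seed))
  measures <- compute_domain_measure(model, "area3d")
  rho_rel <- scene_presets()[[preset]]
  rho <- rho_rel * p$mean_density_photons_nm2
  a <- measures$per_class[rownames(rho)] / measures$total
  truth <- sweep(rho_rel, 2, colSums(rho_rel * a), "/")
  scene <- list(params = p, preset = preset, seed = seed, rho = rho,
                relative_density = truth, measures = measures,
                rt_geometry = list(z = z_rt, azimuth = th_rt),
                ilv_centers = centers)
  list(model = model, scene = scene)
}

#' Render the fluorescence channels of a synthetic scene
#'
#' Forward model: every mesh triangle of the model emits
#' `rho[class, channel] * area` expected photons at its centroid, z-projected
#' onto the camera grid, convolved with the Gaussian PSF, plus uniform
#' background; shot noise is Poisson on the expected counts (read noise
#' optional). The noise-free expectation images are returned alongside for
#' oracle tests.
#'
#' @param model the `contour_model` of the scene.
#' @param scene the scene description from [generate_endosome_scene()].
#' @return list with `images` (named list of noisy channel matrices),
#'   `expected` (noise-free), `transform` (the identity nm-to-px
#'   `registration_transform`), `background`, `seed`.
#' @export
render_channels <- function(model, scene) {
  p <- scene$params
  npx <- p$image_size_px
  sig_px <- p$psf_sigma_nm / p$pixel_size_nm
  cls <- vapply(model$objects, function(o) o$class, character(1))
  # per-class z-projected membrane-area maps (nm^2 per pixel)
  area_maps <- list()
  for (k in unique(cls)) {
    amap <- matrix(0, npx, npx)
    for (ob in model$objects[cls == k]) {
      msh <- mesh_object(ob$contours, cap = k != "BM")
      cen <- (msh$a + msh$b + msh$c) / 3
      col0 <- round(cen[, 1] / p$pixel_size_nm)
      row0 <- round(cen[, 2] / p$pixel_size_nm)
      keep <- col0 >= 0 & col0 < npx & row0 >= 0 & row0 < npx
      idx <- row0[keep] + 1L + col0[keep] * npx
      acc <- rowsum(msh$tri_areas[keep], group = idx)
      amap[as.integer(rownames(acc))] <- amap[as.integer(rownames(acc))] +
        acc[, 1]
    }
    area_maps[[k]] <- amap
  }
  channels <- colnames(scene$rho)
  expected <- list()
  for (ch in channels) {
    photons <- matrix(0, npx, npx)
    for (k in names(area_maps))
      photons <- photons + scene$rho[k, ch] * area_maps[[k]]
    expected[[ch]] <- gaussian_blur_2d(photons, sig_px) + p$background
  }
  set.seed(scene$seed + 1000003L)
  images <- lapply(expected, function(lam) {
    img <- switch(p$noise,
      poisson = matrix(stats::rpois(length(lam), lam), nrow(lam)),
      gaussian = lam + matrix(stats::rnorm(length(lam),
                                           sd = p$read_noise_sd), nrow(lam)),
      none = lam,
      stop_clem("unknown noise model: ", p$noise))
    if (p$noise == "poisson" && p$read_noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), sd = p$read_noise_sd),
                          nrow(img))
    pmax(img, 0)
  })
  tm <- diag(c(1 / p$pixel_size_nm, 1 / p$pixel_size_nm, 1))
  list(images = images, expected = expected,
       transform = registration_transform(tm, type = "identity"),
       background = p$background, seed = scene$seed)
}

#' Generate a vertically cut section-edge image
#'
#' Emulates the resin-penetration test: a stained block cut perpendicular to
#' its surface. With `labelling = "surface"` the fluorophores sit in a thin
#' slab at the block edge (much thinner than the PSF, so the observed edge
#' profile is PSF-limited); with `"volume"` they extend uniformly to
#' `depth_nm`, widening the profile.
#'
#' @param labelling `"surface"` or `"volume"`.
#' @param depth_nm labelled depth; default 20 nm for surface, 800 nm for
#'   volume.
#' @param psf_sigma_nm PSF sigma (nm).
#' @param pixel_size_nm pixel size (nm).
#' @param shape image `c(rows, cols)`.
#' @param edge_px column (0-based) of the block edge.
#' @param peak_photons expected in-band signal level (counts above
#'   background).
#' @param background background counts.
#' @param seed RNG seed.
#' @return list with `image`, `expected`, `pixel_size_um`, `depth_nm`,
#'   `psf_sigma_nm`, `seed`.
#' @export
generate_edge_stack <- function(labelling = c("surface", "volume"),
                                depth_nm = NULL, psf_sigma_nm = 150,
                                pixel_size_nm = 65, shape = c(80L, 160L),
                                edge_px = 60, peak_photons = 400,
                                background = 20, seed = 1L) {
  labelling <- match.arg(labelling)
  if (is.null(depth_nm))
    depth_nm <- if (labelling == "surface") 20 else 800
  assert_that(depth_nm > 0 && psf_sigma_nm > 0, "positive dimensions required")
  nr <- shape[1]; nc <- shape[2]
  x_nm <- (0:(nc - 1)) * pixel_size_nm
  edge_nm <- edge_px * pixel_size_nm
  band <- as.numeric(x_nm >= edge_nm & x_nm < edge_nm + depth_nm)
  # thin-band case: guarantee at least one lit column at the edge
  if (all(band == 0)) band[edge_px + 1L] <- depth_nm / pixel_size_nm
  profile_row <- band * peak_photons
  ideal <- matrix(profile_row, nr, nc, byrow = TRUE)
  expected <- gaussian_blur_2d(ideal, psf_sigma_nm / pixel_size_nm) +
    background
  set.seed(seed)
  image <- matrix(stats::rpois(length(expected), expected), nr, nc)
  list(image = image, expected = expected,
       pixel_size_um = pixel_size_nm / 1000,
       depth_nm = depth_nm, psf_sigma_nm = psf_sigma_nm,
       labelling = labelling, seed = seed)
}

#' Generate registered serial-section images
#'
#' Emulates the horizontal serial-section test. The specimen structure is a
#' smooth random blob field. With `labelling = "volume"` every section
#' carries the same structure signal (plus independent shot noise), so
#' consecutive sections correlate strongly; with `"surface"` each section's
#' label placement is an independent realization (mutually exclusive
#' signal), so consecutive sections are uncorrelated.
#'
#' @param labelling `"surface"` or `"volume"`.
#' @param n_sections number of sections (>= 2).
#' @param shape image shape `c(rows, cols)`.
#' @param n_blobs blobs in the structure field.
#' @param blob_sigma_px structure smoothness (px).
#' @param peak_photons approximate expected blob amplitude (counts).
#' @param background background counts.
#' @param noise `"poisson"` (default) or `"none"` (noise-free expectation).
#' @param seed RNG seed.
#' @return list with `sections` (list of matrices), `background`,
#'   `labelling`, `seed`.
#' @export
generate_serial_sections <- function(labelling = c("surface", "volume"),
                                     n_sections = 6L, shape = c(100L, 100L),
                                     n_blobs = 40L, blob_sigma_px = 3,
                                     peak_photons = 120, background = 20,
                                     noise = c("poisson", "none"),
                                     seed = 1L) {
  noise <- match.arg(noise)
  labelling <- match.arg(labelling)
  assert_that(n_sections >= 2, "need n_sections >= 2")
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  structure_field <- function() {
    f <- matrix(0, nr, nc)
    r <- sample.int(nr, n_blobs, replace = TRUE)
    cidx <- sample.int(nc, n_blobs, replace = TRUE)
    amp <- stats::runif(n_blobs, 0.5, 1)
    acc <- rowsum(amp, group = r + (cidx - 1L) * nr)
    f[as.integer(rownames(acc))] <- acc[, 1]
    g <- gaussian_blur_2d(f, blob_sigma_px)
    g / max(g) * peak_photons
  }
  shared <- structure_field()
  sections <- lapply(seq_len(n_sections), function(i) {
    s <- if (labelling == "volume") shared else structure_field()
    lam <- s + background
    if (noise == "none") lam
    else matrix(stats::rpois(length(lam), lam), nr, nc)
  })
  list(sections = sections, background = background, labelling = labelling,
       seed = seed)
}
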