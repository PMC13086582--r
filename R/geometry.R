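# Geometry: surface areas / outline lengths of contour models, and the
# z-projection of model outlines into the fluorescence image plane.
#
# Mesh construction follows the convention of slice-wise manual segmentation:
# each object is a stack of closed contours, one per z-plane; adjacent
# contours are joined by a triangle band after arc-length resampling to a
# common vertex count and cyclic nearest-point alignment; terminal contours
# of closed organelles (ILVs, RTs, and optionally the BM) are closed by a
# centroid triangle fan ("meshed with cap").

closed_segments <- function(ct) {
  # returns list(p, q) of consecutive point pairs including the closing edge
  n <- nrow(ct)
  list(p = ct, q = ct[c(2:n, 1L), , drop = FALSE])
}

polygon_perimeter <- function(ct) {
  s <- closed_segments(ct[, 1:2, drop = FALSE])
  sum(row_norms(s$q - s$p))
}

polygon_area_xy <- function(ct) {
  # shoelace, absolute value
  x <- ct[, 1]; y <- ct[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_signed_area <- function(ct) {
  x <- ct[, 1]; y <- ct[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Resample a closed contour to a fixed vertex count
#'
#' Arc-length uniform resampling along the closed polygon (the closing edge
#' is included). Used to put adjacent contours of a mesh band into
#' one-to-one vertex correspondence.
#' @param ct n x 3 (or n x 2) point matrix.
#' @param m target vertex count.
#' @return m x ncol(ct) matrix.
#' @keywords internal
resample_contour <- function(ct, m) {
  n <- nrow(ct)
  pts <- rbind(ct, ct[1, , drop = FALSE])
  seg <- row_norms(pts[-1, , drop = FALSE] - pts[-(n + 1), , drop = FALSE])
  cum <- c(0, cumsum(seg))
  total <- cum[n + 1]
  if (total <= 0) return(ct[rep(1L, m), , drop = FALSE])
  target <- seq(0, total, length.out = m + 1L)[1:m]
  out <- matrix(0, m, ncol(ct))
  for (k in seq_len(ncol(ct))) {
    out[, k] <- stats::approx(cum, pts[, k], xout = target)$y
  }
  out
}

tri_area3 <- function(a, b, c) {
  # rows of a,b,c are triangle vertices; vectorized over rows
  u <- b - a; v <- c - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

orient_ccw <- function(ct) {
  if (polygon_signed_area(ct) < 0) ct[rev(seq_len(nrow(ct))), , drop = FALSE]
  else ct
}

align_offset <- function(a, b) {
  # cyclic shift s of b minimizing sum |a_i - b_{i+s}|; both m x k
  m <- nrow(a)
  best_s <- 0L; best <- Inf
  for (s in 0L:(m - 1L)) {
    idx <- ((seq_len(m) - 1L + s) %% m) + 1L
    d <- sum(row_norms(a - b[idx, , drop = FALSE]))
    if (d < best) { best <- d; best_s <- s }
  }
  ((seq_len(m) - 1L + best_s) %% m) + 1L
}

band_triangles <- function(c1, c2, m = NULL) {
  # triangle strip between two closed contours (n1 x 3, n2 x 3, same object)
  if (is.null(m)) m <- max(nrow(c1), nrow(c2), 32L)
  a <- orient_ccw(resample_contour(c1, m))
  b <- orient_ccw(resample_contour(c2, m))
  b <- b[align_offset(a, b), , drop = FALSE]
  j <- c(2:m, 1L)
  # two triangles per quad: (a_i, a_j, b_i), (b_i, a_j, b_j)
  list(a1 = rbind(a, b), b1 = rbind(a[j, , drop = FALSE], a[j, , drop = FALSE]),
       c1 = rbind(b, b[j, , drop = FALSE]))
}

fan_triangles <- function(ct) {
  # centroid fan over a closed contour (cap face)
  n <- nrow(ct)
  ctr <- matrix(colMeans(ct), n, 3, byrow = TRUE)
  j <- c(2:n, 1L)
  list(a1 = ctr, b1 = ct, c1 = ct[j, , drop = FALSE])
}

#' Triangulate one object of a contour model
#'
#' @param contours list of closed contour matrices (n x 3, nm), one per
#'   z-plane; they are sorted by z internally.
#' @param cap logical: close the terminal contours with centroid fans.
#' @return list with `vertices` components `a`, `b`, `c` (matrices of
#'   triangle corners) and `area` (total mesh area, nm^2).
#' @keywords internal
mesh_object <- function(contours, cap = TRUE) {
  z <- vapply(contours, function(ct) ct[1, 3], numeric(1))
  contours <- contours[order(z)]
  nslice <- length(contours)
  A <- list(); B <- list(); C <- list()
  if (nslice == 1L) {
    # single-slice object: flat disc, both faces
    f <- fan_triangles(contours[[1]])
    A <- list(f$a1, f$a1); B <- list(f$b1, f$b1); C <- list(f$c1, f$c1)
  } else {
    for (k in seq_len(nslice - 1L)) {
      tb <- band_triangles(contours[[k]], contours[[k + 1L]])
      A[[length(A) + 1L]] <- tb$a1
      B[[length(B) + 1L]] <- tb$b1
      C[[length(C) + 1L]] <- tb$c1
    }
    if (cap) {
      for (ct in contours[c(1L, nslice)]) {
        f <- fan_triangles(ct)
        A[[length(A) + 1L]] <- f$a1
        B[[length(B) + 1L]] <- f$b1
        C[[length(C) + 1L]] <- f$c1
      }
    }
  }
  a <- do.call(rbind, A); b <- do.call(rbind, B); cc <- do.call(rbind, C)
  areas <- tri_area3(a, b, cc)
  list(a = a, b = b, c = cc, tri_areas = areas, area = sum(areas))
}

#' Measure compartment membrane domains
#'
#' In `area3d` mode, per-class triangulated mesh surface area (nm^2): ILV and
#' RT objects are always capped at their terminal contours; capping of the BM
#' (whose top/bottom contours usually mark where the physical section
#' truncates the organelle, not real membrane) is controlled by `cap_bm` and
#' defaults to `FALSE`. Objects spanning a single plane are treated as flat
#' discs (both faces) with a warning. In `length2d` mode (single-plane
#' models), per-class summed closed-polygon perimeter (nm).
#'
#' @param model a `contour_model`.
#' @param mode `"area3d"` or `"length2d"`.
#' @param cap_bm cap the terminal BM contours in `area3d` mode.
#' @return a `domain_measure`: list with `per_class` (named numeric over the
#'   classes present), `total`, `mode` and `unit`.
#' @export
compute_domain_measure <- function(model, mode = c("area3d", "length2d"),
                                   cap_bm = FALSE) {
  mode <- match.arg(mode)
  validate_contour_model(model)
  cls <- vapply(model$objects, function(o) o$class, character(1))
  vals <- numeric(length(model$objects))
  if (mode == "length2d") {
    zall <- unlist(lapply(model$objects, function(o)
      vapply(o$contours, function(ct) ct[1, 3], numeric(1))))
    assert_that(max(zall) - min(zall) <= 1e-6 * model$z_step_nm,
                "length2d mode requires a single-plane model")
    for (i in seq_along(model$objects)) {
      per <- vapply(model$objects[[i]]$contours, polygon_perimeter, numeric(1))
      assert_that(all(per > 0), "degenerate contour (zero perimeter) in object ", i)
      vals[i] <- sum(per)
    }
  } else {
    for (i in seq_along(model$objects)) {
      per <- vapply(model$objects[[i]]$contours, polygon_perimeter, numeric(1))
      assert_that(all(per > 0), "degenerate contour (zero perimeter) in object ", i)
      if (length(model$objects[[i]]$contours) == 1L)
        warning("object ", i, " (", cls[i],
                ") spans a single slice; treated as a flat disc", call. = FALSE)
      cap <- if (cls[i] == "BM") cap_bm else TRUE
      vals[i] <- mesh_object(model$objects[[i]]$contours, cap = cap)$area
    }
  }
  present <- unique(cls)
  per_class <- vapply(present, function(k) sum(vals[cls == k]), numeric(1))
  assert_that(all(per_class > 0), "non-positive class measure")
  structure(list(per_class = per_class, total = sum(per_class), mode = mode,
                 unit = if (mode == "area3d") "nm^2" else "nm"),
            class = "domain_measure")
}

#' @export
print.domain_measure <- function(x, ...) {
  cat("<domain_measure> mode=", x$mode, " [", x$unit, "]\n", sep = "")
  print(round(c(x$per_class, total = x$total), 1))
  invisible(x)
}

#' Project model outlines into the image plane
#'
#' Collapses all contours of all z-planes onto one 2D raster per class:
#' every pixel traversed by a transformed contour segment is set to 1.
#' Pixel centers sit at integer coordinates, origin at the image top-left,
#' x = column, y = row (both 0-based in transform space).
#'
#' @param model a `contour_model`.
#' @param transform a `registration_transform` (or plain 3x3 homogeneous
#'   matrix) mapping model (x, y) in nm to image pixel coordinates.
#' @param image_shape integer vector `c(rows, cols)`.
#' @return named list of 0/1 integer matrices, one per class present.
#' @export
project_outlines <- function(model, transform, image_shape) {
  validate_contour_model(model)
  tm <- transform_matrix(transform)
  det2 <- tm[1, 1] * tm[2, 2] - tm[1, 2] * tm[2, 1]
  assert_that(is.finite(det2) && abs(det2) > 1e-12, "singular transform")
  assert_that(length(image_shape) == 2 && all(image_shape >= 1),
              "image_shape must be positive c(rows, cols)")
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  cls <- vapply(model$objects, function(o) o$class, character(1))
  out <- list()
  n_clip <- 0L; n_tot <- 0L
  for (k in unique(cls)) {
    ras <- matrix(0L, nr, nc)
    for (ob in model$objects[cls == k]) {
      for (ct in ob$contours) {
        px <- apply_transform(tm, ct[, 1:2, drop = FALSE])
        pts <- densify_closed(px, step = 0.4)
        r <- round(pts[, 2]); c0 <- round(pts[, 1])
        n_tot <- n_tot + nrow(pts)
        keep <- r >= 0 & r <= nr - 1L & c0 >= 0 & c0 <= nc - 1L
        n_clip <- n_clip + sum(!keep)
        if (any(keep)) ras[cbind(r[keep] + 1L, c0[keep] + 1L)] <- 1L
      }
    }
    out[[k]] <- ras
  }
  assert_that(n_clip < n_tot, "model outside field of view")
  if (n_clip > 0)
    warning(n_clip, " of ", n_tot,
            " projected contour samples fell outside the image and were clipped",
            call. = FALSE)
  out
}

densify_closed <- function(px, step = 0.4) {
  # sample a closed polyline at <= `step` px spacing (8-connected raster)
  n <- nrow(px)
  p <- px; q <- px[c(2:n, 1L), , drop = FALSE]
  len <- row_norms(q - p)
  ns <- pmax(1L, ceiling(len / step))
  total <- sum(ns)
  t_all <- numeric(total); seg_idx <- integer(total)
  pos <- 1L
  for (i in seq_len(n)) {
    kk <- ns[i]
    t_all[pos:(pos + kk - 1L)] <- (seq_len(kk) - 1L) / kk
    seg_idx[pos:(pos + kk - 1L)] <- i
    pos <- pos + kk
  }
  p[seg_idx, , drop = FALSE] * (1 - t_all) + q[seg_idx, , drop = FALSE] * t_all
}
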