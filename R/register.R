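# Fiducial landmark registration: least-squares affine / similarity fits
# and the leave-one-out correlation error map.

#' Construct / extract a transform matrix
#' @param transform a `registration_transform`, a 3x3 homogeneous matrix, or
#'   `"identity"`.
#' @return 3x3 homogeneous matrix.
#' @keywords internal
transform_matrix <- function(transform) {
  if (inherits(transform, "registration_transform")) return(transform$matrix)
  if (identical(transform, "identity")) return(diag(3))
  assert_that(is.matrix(transform) && all(dim(transform) == c(3, 3)),
              "transform must be a registration_transform or 3x3 matrix")
  transform
}

#' Apply a 2D transform to points
#' @param transform see [transform_matrix()].
#' @param pts n x 2 matrix.
#' @return n x 2 matrix of mapped points.
#' @export
apply_transform <- function(transform, pts) {
  tm <- transform_matrix(transform)
  pts <- matrix(as.numeric(pts), ncol = 2)
  out <- cbind(pts, 1) %*% t(tm)
  out[, 1:2, drop = FALSE] / out[, 3]
}

#' Build a registration transform from a matrix
#' @param matrix 3x3 homogeneous matrix.
#' @param type transform type label.
#' @param residuals optional per-landmark fit residuals (px).
#' @export
registration_transform <- function(matrix = diag(3),
                                   type = c("affine", "similarity", "identity"),
                                   residuals = numeric(0)) {
  type <- match.arg(type)
  assert_that(abs(det(matrix)) > 1e-12, "transform matrix is singular")
  structure(list(matrix = matrix, type = type, residuals = residuals),
            class = "registration_transform")
}

#' @export
print.registration_transform <- function(x, ...) {
  cat("<registration_transform> type=", x$type, "\n", sep = "")
  print(signif(x$matrix, 6))
  if (length(x$residuals))
    cat("  residuals (px): ", paste(signif(x$residuals, 3), collapse = " "),
        "\n", sep = "")
  invisible(x)
}

#' Fit a landmark transform by least squares
#'
#' Minimizes the summed squared distances between transformed source
#' landmarks and destination landmarks. The affine fit solves two linear
#' least-squares systems on the design `[x y 1]`; the similarity fit
#' (rotation + isotropic scale + translation) uses the closed-form complex
#' least-squares solution.
#'
#' @param points_src,points_dst n x 2 matrices of corresponding landmarks
#'   (>= 3 pairs for affine, >= 2 for similarity; no duplicate source
#'   points; source not collinear for affine).
#' @param type `"affine"` or `"similarity"`.
#' @return a `registration_transform` with per-landmark residuals.
#' @export
fit_landmark_affine <- function(points_src, points_dst,
                                type = c("affine", "similarity")) {
  type <- match.arg(type)
  src <- matrix(as.numeric(points_src), ncol = 2)
  dst <- matrix(as.numeric(points_dst), ncol = 2)
  assert_that(nrow(src) == nrow(dst), "landmark counts differ")
  assert_that(!anyDuplicated(src), "duplicate source landmarks")
  if (type == "affine") {
    assert_that(nrow(src) >= 3, "affine fit needs >= 3 landmark pairs")
    X <- cbind(src, 1)
    qr_x <- qr(X)
    assert_that(qr_x$rank == 3, "degenerate (collinear) source landmarks")
    coef <- qr.coef(qr_x, dst)   # 3 x 2
    tm <- rbind(cbind(t(coef[1:2, , drop = FALSE]), coef[3, ]), c(0, 0, 1))
  } else {
    assert_that(nrow(src) >= 2, "similarity fit needs >= 2 landmark pairs")
    zs <- complex(real = src[, 1], imaginary = src[, 2])
    zd <- complex(real = dst[, 1], imaginary = dst[, 2])
    ms <- mean(zs); md <- mean(zd)
    denom <- sum(Mod(zs - ms)^2)
    assert_that(denom > 0, "degenerate source landmarks")
    alpha <- sum(Conj(zs - ms) * (zd - md)) / denom
    beta <- md - alpha * ms
    tm <- rbind(c(Re(alpha), -Im(alpha), Re(beta)),
                c(Im(alpha),  Re(alpha), Im(beta)),
                c(0, 0, 1))
  }
  res <- row_norms(apply_transform(tm, src) - dst)
  registration_transform(tm, type = type, residuals = res)
}

#' Leave-one-out correlation error map
#'
#' For each landmark, refits the transform without it and records the
#' prediction error at the held-out landmark; the per-landmark errors are
#' then interpolated over the image grid by inverse-distance weighting
#' (exponent 2) from the destination landmark positions. A pixel closer
#' than half a pixel to a landmark takes that landmark's error exactly.
#'
#' @param points_src,points_dst n x 2 landmark matrices (n >= 4).
#' @param grid_shape `c(rows, cols)` of the error field.
#' @param type transform type passed to [fit_landmark_affine()].
#' @return list with `field` (rows x cols matrix, predicted error in px) and
#'   `loo_residuals` (per landmark).
#' @export
correlation_error_map <- function(points_src, points_dst, grid_shape,
                                  type = c("affine", "similarity")) {
  type <- match.arg(type)
  src <- matrix(as.numeric(points_src), ncol = 2)
  dst <- matrix(as.numeric(points_dst), ncol = 2)
  n <- nrow(src)
  assert_that(n >= 4, "leave-one-out error map needs >= 4 landmark pairs")
  loo <- vapply(seq_len(n), function(i) {
    tf <- fit_landmark_affine(src[-i, , drop = FALSE],
                              dst[-i, , drop = FALSE], type = type)
    sqrt(sum((apply_transform(tf, src[i, , drop = FALSE]) -
                dst[i, , drop = FALSE])^2))
  }, numeric(1))
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  near <- matrix(Inf, nr, nc); near_val <- matrix(0, nr, nc)
  for (i in seq_len(n)) {
    d2 <- (xs - dst[i, 1])^2 + (ys - dst[i, 2])^2
    num <- num + loo[i] / pmax(d2, 1e-12)
    den <- den + 1 / pmax(d2, 1e-12)
    upd <- d2 < near
    near[upd] <- d2[upd]; near_val[upd] <- loo[i]
  }
  field <- num / den
  snap <- near < 0.25
  field[snap] <- near_val[snap]
  list(field = field, loo_residuals = loo)
}
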