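# Plain-text image and transform I/O.
#
# The pipeline's imaging environment has no binary-image dependency, so
# channel images and audit masks travel as ASCII matrices: plain PGM ("P2")
# for integer images and CSV for arbitrary numeric matrices. Registration
# transforms are stored as a small JSON document.

#' Read / write an ASCII PGM (P2) image
#'
#' @param path file path.
#' @return numeric matrix (rows x cols).
#' @export
read_pgm <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  assert_that(length(tok) >= 4 && tok[1] == "P2",
              path, ": not an ASCII PGM (P2) file")
  nc <- as.integer(tok[2]); nr <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  assert_that(length(vals) == nr * nc, path, ": pixel count mismatch")
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}

#' @rdname read_pgm
#' @param image numeric matrix; values are rounded and clamped to
#'   `[0, maxval]`.
#' @param maxval maximum grey value written to the header.
#' @export
write_pgm <- function(image, path, maxval = max(1, ceiling(max(image)))) {
  m <- pmin(pmax(round(image), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a numeric matrix as CSV (no header)
#' @param path file path.
#' @return numeric matrix.
#' @export
read_image_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' @rdname read_image_csv
#' @param image numeric matrix.
#' @export
write_image_csv <- function(image, path) {
  utils::write.table(image, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a channel image by extension
#'
#' Dispatches on the file extension: `.pgm` (ASCII P2) or `.csv`.
#' @param path file path.
#' @return numeric matrix.
#' @export
read_channel_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pgm = read_pgm(path),
         csv = read_image_csv(path),
         stop_clem("unsupported image format '.", ext,
                   "' (use ASCII .pgm or .csv): ", path))
}

#' Write / read a registration transform as JSON
#' @param transform a `registration_transform`.
#' @param path file path.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(
    list(type = transform$type,
         matrix = unname(transform$matrix),
         residuals_px = transform$residuals),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  registration_transform(matrix(unlist(obj$matrix), 3, 3, byrow =
                                  is.null(dim(obj$matrix))),
                         type = obj$type,
                         residuals = obj$residuals_px %||% numeric(0))
}

#' Write mask partition audit files
#'
#' Per-class masks as 8-bit PGM label images plus the region table as CSV
#' (`code, classes, type, n_pixels`).
#' @param partition a `class_mask_partition`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @export
write_partition <- function(partition, dir, prefix = "mask") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in names(partition$masks))
    write_pgm(partition$masks[[k]] * 255,
              file.path(dir, paste0(prefix, "_", k, ".pgm")), maxval = 255)
  utils::write.csv(partition$regions,
                   file.path(dir, paste0(prefix, "_regions.csv")),
                   row.names = FALSE)
  invisible(dir)
}
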