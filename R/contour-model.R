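# Classified membrane contour models: constructor, validation, file I/O.
#
# A contour model is the geometric ground truth of the quantification: an
# ordered set of closed 3D point contours per compartment class (BM = globular
# boundary membrane, ILV = intraluminal vesicle, RT = recycling tubule),
# one contour per z-plane and object, all coordinates in nanometres.

#' Construct a classified contour model
#'
#' @param objects list of objects; each object is a list with elements
#'   `class` (one of `"BM"`, `"ILV"`, `"RT"`) and `contours` (a list of
#'   numeric matrices with columns x, y, z in nm; every contour is treated
#'   as a closed polygon and must contain at least 3 points, all sharing
#'   one z value).
#' @param z_step_nm spacing between successive contour planes (nm).
#' @param endosome_id identifier carried through to all results.
#' @param pixel_size_model_nm optional model voxel size metadata (nm).
#' @param validate run invariant checks (default `TRUE`).
#' @return an object of class `contour_model`.
#' @export
contour_model <- function(objects, z_step_nm, endosome_id = "endosome",
                          pixel_size_model_nm = NA_real_, validate = TRUE) {
  m <- structure(
    list(objects = objects, z_step_nm = as.numeric(z_step_nm),
         endosome_id = as.character(endosome_id),
         pixel_size_model_nm = as.numeric(pixel_size_model_nm)),
    class = "contour_model")
  if (validate) validate_contour_model(m)
  m
}

#' Validate a contour model
#'
#' Checks the structural invariants: >= 3 points per contour, one shared z
#' value per contour, z values on the z-step grid (within 1e-6 of a step),
#' all coordinates finite and non-negative, known class labels, and no
#' object without contours.
#'
#' @param model a `contour_model`.
#' @return the model, invisibly; errors describe the offending object.
#' @export
validate_contour_model <- function(model) {
  assert_that(inherits(model, "contour_model"), "not a contour_model")
  assert_that(is_scalar_number(model$z_step_nm) && model$z_step_nm > 0,
              "z_step_nm must be a positive number")
  assert_that(length(model$objects) > 0, "model has no objects")
  for (i in seq_along(model$objects)) {
    ob <- model$objects[[i]]
    check_class_labels(ob$class)
    assert_that(length(ob$class) == 1L, "object ", i, ": class must be scalar")
    assert_that(length(ob$contours) > 0, "object ", i, " (", ob$class,
                "): empty object (no contours)")
    for (j in seq_along(ob$contours)) {
      ct <- ob$contours[[j]]
      where <- paste0("object ", i, " (", ob$class, "), contour ", j)
      assert_that(is.matrix(ct) && ncol(ct) == 3 && is.numeric(ct),
                  where, ": contour must be a numeric n x 3 matrix")
      assert_that(nrow(ct) >= 3, where, ": contour has fewer than 3 points")
      assert_that(all(is.finite(ct)), where, ": non-finite coordinate")
      assert_that(all(ct >= 0), where, ": negative coordinate")
      zz <- ct[, 3]
      assert_that(max(zz) - min(zz) <= 1e-6 * model$z_step_nm,
                  where, ": points do not share one z value")
      k <- zz[1] / model$z_step_nm
      assert_that(abs(k - round(k)) <= 1e-6,
                  where, ": z = ", zz[1], " is not a multiple of z_step (",
                  model$z_step_nm, ")")
    }
  }
  invisible(model)
}

#' Count objects per compartment class
#' @param model a `contour_model`.
#' @return named integer vector over BM, ILV, RT.
#' @export
class_counts <- function(model) {
  cls <- vapply(model$objects, function(o) o$class, character(1))
  vapply(COMPARTMENT_CLASSES, function(k) sum(cls == k), integer(1))
}

#' Is a model analysable for compartment quantification?
#'
#' The selection rule of the density analysis: an endosome enters the
#' quantification only if its model contains at least one object of every
#' class (BM, ILV and RT).
#' @param model a `contour_model`.
#' @return logical scalar.
#' @export
is_analysable <- function(model) all(class_counts(model) >= 1L)

#' @export
print.contour_model <- function(x, ...) {
  cc <- class_counts(x)
  cat("<contour_model> ", x$endosome_id, "\n",
      "  objects: ", paste(names(cc), cc, sep = ":", collapse = " "), "\n",
      "  z step : ", x$z_step_nm, " nm\n", sep = "")
  invisible(x)
}

#' Read a classified contour model from file
#'
#' Two dialects are supported:
#' \describe{
#'   \item{json}{the documented JSON schema: top-level fields `endosome_id`,
#'     `z_step_nm`, optional `pixel_size_model_nm`, and `objects`, a list of
#'     `{class, contours}` entries where `contours` is a list of point lists
#'     `[[x, y, z], ...]` in nm.}
#'   \item{imod_points}{whitespace-separated ASCII in the layout produced by
#'     IMOD's `model2point -object`: one record per point,
#'     `object contour x y z` with 1-based object and contour indices.
#'     Because the point file does not carry class labels, a mapping from
#'     object index to class must be supplied via `class_map`.}
#' }
#'
#' @param path file path.
#' @param dialect `"json"` or `"imod_points"`.
#' @param class_map for `imod_points`: named character vector or list mapping
#'   object index (as character) to class label, e.g. `c("1" = "BM")`.
#' @param z_step_nm for `imod_points`: the contour plane spacing (nm).
#' @param endosome_id for `imod_points`: identifier (default: file name).
#' @return a validated `contour_model`.
#' @export
read_contour_model <- function(path, dialect = c("json", "imod_points"),
                               class_map = NULL, z_step_nm = NULL,
                               endosome_id = NULL) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "file not found: ", path)
  if (dialect == "json") read_contour_json(path) else
    read_imod_points(path, class_map, z_step_nm, endosome_id)
}

read_contour_json <- function(path) {
  parsed <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                     error = function(e)
                       stop_clem("JSON parse failure in ", path, ": ",
                                 conditionMessage(e)))
  for (f in c("endosome_id", "z_step_nm", "objects"))
    assert_that(!is.null(parsed[[f]]), path, ": missing field '", f, "'")
  objects <- lapply(parsed$objects, function(ob) {
    assert_that(!is.null(ob$class) && !is.null(ob$contours),
                path, ": object missing 'class' or 'contours'")
    contours <- lapply(ob$contours, function(ct) {
      pts <- vapply(ct, function(p) {
        assert_that(length(p) == 3, path, ": contour point is not [x, y, z]")
        as.numeric(unlist(p))
      }, numeric(3))
      ct <- t(pts)
      colnames(ct) <- c("x", "y", "z")
      ct
    })
    list(class = ob$class, contours = contours)
  })
  px <- parsed$pixel_size_model_nm
  px <- if (is.null(px) || !is.numeric(px)) NA_real_ else px
  contour_model(objects, z_step_nm = parsed$z_step_nm,
                endosome_id = parsed$endosome_id,
                pixel_size_model_nm = px)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_imod_points <- function(path, class_map, z_step_nm, endosome_id) {
  assert_that(!is.null(class_map), "imod_points dialect needs a class_map")
  assert_that(!is.null(z_step_nm), "imod_points dialect needs z_step_nm")
  tab <- tryCatch(utils::read.table(path, col.names =
                    c("object", "contour", "x", "y", "z")),
                  error = function(e)
                    stop_clem("imod_points parse failure in ", path, ": ",
                              conditionMessage(e)))
  assert_that(nrow(tab) > 0, path, ": empty point file")
  objects <- lapply(sort(unique(tab$object)), function(oi) {
    cls <- class_map[[as.character(oi)]]
    assert_that(!is.null(cls) && !is.na(cls),
                path, ": no class mapping for object ", oi)
    sub <- tab[tab$object == oi, , drop = FALSE]
    contours <- lapply(sort(unique(sub$contour)), function(ci) {
      pts <- as.matrix(sub[sub$contour == ci, c("x", "y", "z"), drop = FALSE])
      dimnames(pts) <- list(NULL, c("x", "y", "z"))
      pts
    })
    list(class = cls, contours = contours)
  })
  contour_model(objects, z_step_nm = z_step_nm,
                endosome_id = endosome_id %||% basename(path))
}

#' Write a contour model
#'
#' Writes either the JSON dialect (lossless round-trip of
#' [read_contour_model()]) or the `imod_points` ASCII layout.
#' @param model a `contour_model`.
#' @param path output file.
#' @param dialect `"json"` or `"imod_points"`.
#' @return `path`, invisibly.
#' @export
write_contour_model <- function(model, path,
                                dialect = c("json", "imod_points")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    payload <- list(
      endosome_id = model$endosome_id,
      z_step_nm = model$z_step_nm,
      objects = lapply(model$objects, function(ob)
        list(class = ob$class,
             contours = lapply(ob$contours, function(ct)
               unname(ct))))
    )
    if (!is.na(model$pixel_size_model_nm))
      payload$pixel_size_model_nm <- model$pixel_size_model_nm
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    rows <- list()
    for (i in seq_along(model$objects)) {
      ob <- model$objects[[i]]
      for (j in seq_along(ob$contours)) {
        ct <- ob$contours[[j]]
        rows[[length(rows) + 1L]] <-
          cbind(object = i, contour = j, ct)
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.table(format(as.data.frame(tab), trim = TRUE, digits = 15),
                       path, quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
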