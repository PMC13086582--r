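#' @keywords internal
"_PACKAGE"

# Compartment classes accepted throughout the package.
COMPARTMENT_CLASSES <- c("BM", "ILV", "RT")

#' Default channel names
#'
#' The three fluorescence channels of the standard experiment: the clicked
#' lipid probe, transferrin (recycling cargo) and LDL (degradative cargo).
#' All channel-indexed functions accept arbitrary channel names; these are
#' only the defaults used by the synthetic generator.
#' @export
CLEM_CHANNELS <- c("lipid", "Tf", "LDL")

stop_clem <- function(..., call. = FALSE) stop(..., call. = call.)

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_clem(...)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Check a compartment class label
#' @param label character vector of labels.
#' @return `label`, invisibly, if all labels are valid; otherwise an error.
#' @keywords internal
check_class_labels <- function(label) {
  bad <- setdiff(unique(label), COMPARTMENT_CLASSES)
  assert_that(length(bad) == 0,
              "unknown compartment class label(s): ",
              paste(bad, collapse = ", "),
              " (accepted: ", paste(COMPARTMENT_CLASSES, collapse = ", "), ")")
  invisible(label)
}

# row-wise euclidean norms
row_norms <- function(m) sqrt(rowSums(m * m))
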