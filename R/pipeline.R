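# End-to-end quantification: contour model + channel images + registration
# -> per-compartment densities and enrichments.

#' Quantify compartment densities for one endosome
#'
#' Runs the full chain: domain measures, outline projection, blurred class
#' masks, exclusive/overlap partition, background-corrected KDE intensity
#' assignment, and the density/enrichment calculations.
#'
#' @param model a `contour_model` containing at least one object of each
#'   class (set `require_all_classes = FALSE` to lift the selection rule).
#' @param images named list of channel matrices (equal shapes).
#' @param transform `registration_transform` (or 3x3 matrix) mapping model
#'   nm coordinates to image pixels.
#' @param mode `"area3d"` (surface areas, nm^2) or `"length2d"`
#'   (outline lengths, nm; single-plane models).
#' @param mask_cfg a [mask_config()].
#' @param assign_cfg an [assign_config()].
#' @param channels channels that must be present; defaults to the names of
#'   `images`. A listed channel missing from `images` is an error naming it.
#' @param cap_bm passed to [compute_domain_measure()].
#' @param require_all_classes enforce the BM+ILV+RT selection rule.
#' @param out_dir if non-NULL, results are written there (density CSV,
#'   region table, audit masks, JSON bundle).
#' @return a `density_result`.
#' @export
run_quantify <- function(model, images, transform, mode = "area3d",
                         mask_cfg = mask_config(),
                         assign_cfg = assign_config(),
                         channels = names(images), cap_bm = FALSE,
                         require_all_classes = TRUE, out_dir = NULL) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop_clem("[", what, " | ", model$endosome_id, "] ",
                conditionMessage(e)))
  }
  missing_ch <- setdiff(channels, names(images))
  assert_that(length(missing_ch) == 0, "missing channel(s): ",
              paste(missing_ch, collapse = ", "))
  images <- images[channels]
  if (require_all_classes)
    assert_that(is_analysable(model),
                "model is not analysable: needs >= 1 object of each class (",
                paste(names(class_counts(model)), class_counts(model),
                      sep = "=", collapse = ", "), ")")
  shape <- dim(images[[1]])
  measures <- stage("model_geometry",
                    compute_domain_measure(model, mode, cap_bm = cap_bm))
  outlines <- stage("model_geometry",
                    project_outlines(model, transform, shape))
  masks <- stage("mask_builder", build_class_masks(outlines, mask_cfg))
  partition <- stage("mask_builder", partition_masks(masks))
  intens <- stage("intensity_assignment",
                  assign_intensities(images, partition, assign_cfg,
                                     endosome_id = model$endosome_id))
  result <- stage("density_metrics", compute_densities(intens, measures))
  if (!is.null(out_dir)) write_quantify_outputs(result, partition, out_dir)
  result
}

write_quantify_outputs <- function(result, partition, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  id <- result$endosome_id[1]
  utils::write.csv(as.data.frame(result),
                   file.path(out_dir, paste0(id, "_densities.csv")),
                   row.names = FALSE)
  write_partition(partition, out_dir, prefix = paste0(id, "_mask"))
  bundle <- list(
    endosome_id = id, mode = attr(result, "mode"), unit = attr(result, "unit"),
    total_area = attr(result, "total_area"),
    total_intensity = as.list(attr(result, "total_intensity")),
    rows = as.data.frame(result))
  jsonlite::write_json(bundle, file.path(out_dir, paste0(id, "_result.json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Summarize relative densities across endosomes
#'
#' @param results list of `density_result` objects.
#' @return data.frame with per (class, channel) mean relative density,
#'   s.e.m., 95 percent confidence interval of the mean, and n.
#' @export
summarize_relative_densities <- function(results) {
  all <- do.call(rbind, lapply(results, as.data.frame))
  out <- do.call(rbind, lapply(split(all, list(all$class, all$channel),
                                     drop = TRUE), function(g) {
    x <- g$relative_density
    ci <- if (length(x) >= 2) mean_ci(x) else c(lower = NA_real_,
                                                upper = NA_real_)
    data.frame(class = g$class[1], channel = g$channel[1],
               mean_relative_density = mean(x),
               sem = if (length(x) >= 2) stats::sd(x) / sqrt(length(x))
                     else NA_real_,
               ci95_lower = ci[["lower"]], ci95_upper = ci[["upper"]],
               n = length(x), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
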