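# Densities, relative densities, enrichment bounds and condition comparison.
#
# For a membrane domain d with assigned intensity I_d and measure A_d
# (surface area in nm^2, or outline length in nm in the single-plane mode):
#   density            D_d = I_d / A_d
#   relative density   R_d = D_d / (I_tot / A_tot)
#   max fold enrichment M_d = A_tot / A_d   (upper bound on R_d, attained
#                                            when all signal sits in d)

#' Maximum possible fold enrichment per class
#'
#' `M_d = A_tot / A_d`: the relative density a domain would attain if the
#' entire signal of a channel were concentrated on it.
#' @param measures a `domain_measure`.
#' @return named numeric vector over the classes present.
#' @export
max_fold_enrichment <- function(measures) {
  assert_that(inherits(measures, "domain_measure"), "need a domain_measure")
  assert_that(all(measures$per_class > 0), "zero domain measure")
  measures$total / measures$per_class
}

#' Compute per-compartment densities and enrichments
#'
#' @param intensities an `intensity_table` from [assign_intensities()].
#' @param measures a `domain_measure` from [compute_domain_measure()]; its
#'   class set must match the intensity table's.
#' @return a `density_result`: data.frame with one row per (class, channel)
#'   and columns `endosome_id`, `class`, `channel`, `intensity`, `area`,
#'   `density`, `relative_density`, `max_fold_enrichment`; attributes `mode`,
#'   `unit`, `total_intensity`, `total_area`.
#' @export
compute_densities <- function(intensities, measures) {
  assert_that(inherits(measures, "domain_measure"), "need a domain_measure")
  cls_i <- sort(unique(intensities$class))
  cls_m <- sort(names(measures$per_class))
  assert_that(identical(cls_i, cls_m),
              "class sets differ between intensities (",
              paste(cls_i, collapse = ","), ") and measures (",
              paste(cls_m, collapse = ","), ")")
  assert_that(all(measures$per_class > 0), "zero domain measure")
  totals <- attr(intensities, "total")
  a_tot <- measures$total
  res <- intensities[, c("endosome_id", "class", "channel", "intensity")]
  res$area <- unname(measures$per_class[res$class])
  res$density <- res$intensity / res$area
  i_tot <- totals[res$channel]
  assert_that(all(i_tot > 0), "zero total intensity for channel(s): ",
              paste(unique(res$channel[i_tot <= 0]), collapse = ","))
  res$relative_density <- res$density / (i_tot / a_tot)
  res$max_fold_enrichment <- a_tot / res$area
  # invariants: bound and area-weighted-mean conservation, per channel
  assert_that(all(res$relative_density <= res$max_fold_enrichment + 1e-9),
              "relative density exceeds its enrichment bound")
  for (ch in unique(res$channel)) {
    sub <- res[res$channel == ch, ]
    s <- sum(sub$area / a_tot * sub$relative_density)
    assert_that(abs(s - 1) <= 1e-6,
                "area-weighted relative densities do not average to 1 (",
                ch, ")")
  }
  structure(res, mode = measures$mode, unit = measures$unit,
            total_intensity = totals, total_area = a_tot,
            class = c("density_result", "data.frame"))
}

#' Compare relative densities between two conditions
#'
#' Pools the per-endosome relative densities of one (class, channel) cell
#' per condition and reports the mean, the t-based 95 percent confidence
#' interval of the mean, the s.e.m., and a two-sided two-sample Student
#' t-test (pooled variance by default; Welch via `var_equal = FALSE`).
#'
#' @param results_a,results_b lists of `density_result` objects (one per
#'   endosome), at least 2 per condition.
#' @param class compartment class label.
#' @param channel channel name.
#' @param var_equal pooled-variance Student form (default `TRUE`).
#' @param conf_level confidence level (default 0.95).
#' @return a `condition_comparison` list.
#' @export
compare_conditions <- function(results_a, results_b, class, channel,
                               var_equal = TRUE, conf_level = 0.95) {
  check_class_labels(class)
  xa <- pull_relative_density(results_a, class, channel)
  xb <- pull_relative_density(results_b, class, channel)
  assert_that(length(xa) >= 2 && length(xb) >= 2,
              "need >= 2 endosomes per condition")
  tt <- stats::t.test(xa, xb, var.equal = var_equal,
                      conf.level = conf_level)
  structure(list(
    class = class, channel = channel,
    mean = c(a = mean(xa), b = mean(xb)),
    sem = c(a = stats::sd(xa) / sqrt(length(xa)),
            b = stats::sd(xb) / sqrt(length(xb))),
    ci = rbind(a = mean_ci(xa, conf_level), b = mean_ci(xb, conf_level)),
    n = c(a = length(xa), b = length(xb)),
    statistic = unname(tt$statistic), p_value = tt$p.value,
    var_equal = var_equal, conf_level = conf_level),
    class = "condition_comparison")
}

mean_ci <- function(x, conf_level = 0.95) {
  n <- length(x)
  half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) *
    stats::sd(x) / sqrt(n)
  c(lower = mean(x) - half, upper = mean(x) + half)
}

pull_relative_density <- function(results, class, channel) {
  vapply(results, function(r) {
    hit <- r$class == class & r$channel == channel
    assert_that(sum(hit) == 1, "no unique (", class, ", ", channel,
                ") row in a density_result")
    r$relative_density[hit]
  }, numeric(1))
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison> ", x$class, "/", x$channel, "\n",
      sprintf("  a: mean %.3f [%.3f, %.3f] (n=%d)\n", x$mean["a"],
              x$ci["a", 1], x$ci["a", 2], x$n["a"]),
      sprintf("  b: mean %.3f [%.3f, %.3f] (n=%d)\n", x$mean["b"],
              x$ci["b", 1], x$ci["b", 2], x$n["b"]),
      sprintf("  t = %.4f, p = %.4g (%s)\n", x$statistic, x$p_value,
              if (x$var_equal) "Student" else "Welch"), sep = "")
  invisible(x)
}
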