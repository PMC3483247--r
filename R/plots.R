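#' Plot the BIC curve of a supertype model
#'
#' BIC against cluster count, with the chosen elbow marked.
#'
#' @param model A `supertype_model`.
#' @return A ggplot object.
#' @export
plot_bic_curve <- function(model) {
  stopifnot(inherits(model, "supertype_model"))
  ggplot2::ggplot(model$bic, ggplot2::aes(x = .data$k, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = model$k, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters (k)", y = "BIC",
                  title = sprintf("BIC elbow at k = %d", model$k)) +
    ggplot2::theme_minimal()
}

#' DAPC scatterplot of supertypes
#'
#' Alleles on the first two discriminant axes, coloured by supertype.
#'
#' @param model A `supertype_model` with `k >= 2`.
#' @return A ggplot object.
#' @export
plot_dapc <- function(model) {
  stopifnot(inherits(model, "supertype_model"), !is.null(model$coords))
  d <- tidy(model)
  ycol <- if ("LD2" %in% names(d)) "LD2" else "LD1"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$LD1, y = .data[[ycol]],
                                  colour = factor(.data$supertype))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::stat_ellipse(level = 0.67, na.rm = TRUE) +
    ggplot2::labs(colour = "supertype",
                  title = sprintf("DAPC of %d supertypes (%d PCs retained)",
                                  model$k, model$n_pcs)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_dapc
#' @param object A `supertype_model`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.supertype_model <- function(object, ...) plot_dapc(object)

#' Plot the validation funnel
#'
#' Reads retained after each validation step.
#'
#' @param result A `validation_result` (or `pipeline_result`).
#' @return A ggplot object.
#' @export
plot_funnel <- function(result) {
  if (inherits(result, "pipeline_result")) result <- result$validation
  f <- result$funnel
  f$step <- factor(f$step, levels = f$step)
  ggplot2::ggplot(f, ggplot2::aes(x = .data$step, y = .data$reads)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "reads retained") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Read depth versus allele count
#'
#' QC scatter of per-individual allele number against read number; above the
#' coverage floor the regression should be flat.
#'
#' @param result A `pipeline_result`.
#' @return A ggplot object.
#' @export
plot_depth_vs_alleles <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  d <- result$genotypes |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(reads = sum(.data$copies),
                     n_alleles = dplyr::n_distinct(.data$allele_id),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$reads, y = .data$n_alleles)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "reads per individual", y = "alleles per individual") +
    ggplot2::theme_minimal()
}
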