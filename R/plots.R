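## ggplot2 displays for the main result types.

#' Plot a genome scan profile
#'
#' `-log10(p)` along the genome, faceted by chromosome, with the detection
#' threshold drawn as a horizontal line. M2 profiles are coloured by
#' environment.
#'
#' @param object A `scan_profile`.
#' @param threshold Threshold line on the `-log10(p)` scale.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scan_profile <- function(object, threshold = 4, ...) {
  aes_ <- if ("env" %in% names(object)) {
    ggplot2::aes(x = .data$pos_cM, y = .data$neglog10p,
                 colour = factor(.data$env))
  } else {
    ggplot2::aes(x = .data$pos_cM, y = .data$neglog10p)
  }
  ggplot2::ggplot(as_tibble(object), aes_) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chr),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(
      x = "position (cM)", y = expression(-log[10](italic(p))),
      colour = "environment",
      title = paste0(attr(object, "method"), " scan (",
                     attr(object, "allele_model"), " model)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot the allelic effect series of a fitted QTL model
#'
#' Allelic substitution effects (deviations from the reference allele) per
#' QTL, coloured by sign and sized by |effect|/SE, split by environment
#' when effects are environment specific.
#'
#' @param object A `qtl_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qtl_model <- function(object, ...) {
  eff <- object$effects |>
    dplyr::mutate(env = ifelse(is.na(.data$env), "all", .data$env),
                  z = .data$estimate / .data$std.error)
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$marker, y = .data$allele)) +
    ggplot2::geom_point(ggplot2::aes(size = abs(.data$z),
                                     colour = .data$estimate)) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey90",
                                    high = "red") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$env)) +
    ggplot2::labs(x = "QTL position", y = "allele",
                  colour = "effect", size = "|effect| / SE",
                  title = paste0(object$method, " allelic substitution effects")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot allele contrasts against the environmental covariate
#'
#' Homozygous reference-vs-allele contrasts `-2 (beta_a + Z gamma_a)` as
#' lines over the covariate range, one line per allele, with the observed
#' environments marked.
#'
#' @param object A `sensitivity_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensitivity_fit <- function(object, ...) {
  zr <- range(object$covariate$Z)
  grid <- seq(zr[1], zr[2], length.out = 50)
  lines <- purrr::map_dfr(object$alleles, function(a) {
    allele_contrast(object, a, grid)
  })
  ggplot2::ggplot(lines, ggplot2::aes(x = .data$Z, y = .data$contrast,
                                      colour = .data$allele)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$covariate$Z,
                        linetype = 3, colour = "grey60") +
    ggplot2::labs(
      x = "environmental covariate (centred on reference)",
      y = "homozygous contrast vs reference allele",
      title = paste0("QTL ", object$marker, ": covariate sensitivity")
    ) +
    ggplot2::theme_minimal()
}
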