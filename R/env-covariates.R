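## QTL-by-environment sensitivity to an environmental covariate.
## The environment-specific allelic effect beta_ae is decomposed as
## beta_a + Z_e * gamma_a (+ delta_ae), where Z_e is the covariate expressed
## relative to a reference environment, beta_a the allelic effect at the
## reference level and gamma_a the change in effect per covariate unit.

#' Centre an environmental covariate on a reference environment
#'
#' @param covariate Tibble `env`, `Z` (raw covariate values, e.g. mm of
#'   precipitation).
#' @param reference Reference environment; default the environment with the
#'   smallest raw value (e.g. the driest location), which then sits at
#'   `Z = 0`.
#' @return Tibble `env`, `Z` (centred), `Z_raw`, with the reference recorded
#'   as an attribute.
#' @export
center_covariate <- function(covariate, reference = NULL) {
  stopifnot(all(c("env", "Z") %in% names(covariate)))
  if (is.null(reference)) reference <- covariate$env[which.min(covariate$Z)]
  if (!reference %in% covariate$env) abort("reference environment not found")
  out <- covariate |>
    dplyr::mutate(Z_raw = .data$Z,
                  Z = .data$Z - .data$Z[.data$env == reference])
  attr(out, "reference") <- reference
  out
}

#' Decompose a QTL's environment-specific effects into main effect and
#' covariate sensitivity
#'
#' Refits the two-stage multi-environment QTL model at a focal position,
#' replacing its environment-specific allelic term by a main-effect column
#' per allele (`x_ia`) and a sensitivity column per allele (`x_ia * Z_e`),
#' plus (with three or more environments) a residual QTL-by-environment
#' random term `delta_ae` absorbing effect variation the covariate does not
#' explain; with two environments `delta` is inestimable next to `beta` and
#' `gamma` and is dropped. Cofactor positions keep their usual
#' environment-specific fixed terms. Per-coefficient Wald tests (df = 1)
#' are returned alongside the estimates.
#'
#' @param blues Stacked within-environment BLUEs (`genotype`, `cross`,
#'   `env`, `blue`) covering the environments of `covariate`.
#' @param designs Allele designs from [qtl_designs()].
#' @param marker Focal QTL position (marker id).
#' @param covariate Tibble `env`, `Z`; centred with [center_covariate()]
#'   unless already carrying a `Z_raw` column.
#' @param cofactors Optional cofactor markers (character or tibble with
#'   `marker`).
#' @param reference Reference environment passed to [center_covariate()].
#' @param min_carriers Alleles carried by fewer genotypes are flagged (their
#'   effects tend to have large standard errors).
#' @param ... Passed to [reml_fit()].
#' @return Object of class `sensitivity_fit`: a coefficient table (one row
#'   per allele: `beta`, `gamma`, standard errors, Wald statistics; the
#'   reference allele is identically zero), the centred covariate, the
#'   joint coefficient covariance, and the underlying `mixed_fit`.
#' @export
fit_sensitivity <- function(blues, designs, marker, covariate,
                            cofactors = NULL, reference = NULL,
                            min_carriers = 5, ...) {
  data <- scan_data(blues, "M3")
  if (!"Z_raw" %in% names(covariate)) {
    covariate <- center_covariate(covariate, reference)
  }
  envs <- sort(unique(data$env))
  miss <- setdiff(envs, covariate$env)
  if (length(miss)) abort(paste("covariate missing for:", paste(miss, collapse = ", ")))
  covariate <- dplyr::filter(covariate, .data$env %in% envs)
  if (length(unique(covariate$Z)) < 2) {
    abort("environmental covariate takes a single value; sensitivity inestimable")
  }
  Ze <- setNames(covariate$Z, covariate$env)

  parts <- method_parts(data, "M3")
  design <- designs[[marker]]
  if (is.null(design)) abort(paste("no design at marker", marker))
  Xq <- qtl_columns(design, data$genotype)          # main-effect columns
  colnames(Xq) <- paste0("beta:", design$alleles)
  Xs <- Xq * Ze[data$env]
  colnames(Xs) <- paste0("gamma:", design$alleles)
  cof_mk <- if (is.null(cofactors)) character()
            else if (is.character(cofactors)) cofactors else cofactors$marker
  cof_mk <- setdiff(cof_mk, marker)
  Xc <- lapply(cof_mk, function(mk) {
    qtl_columns(designs[[mk]], data$genotype, env = data$env)
  })
  X <- do.call(cbind, c(list(parts$X, Xq, Xs), Xc))

  random <- list()
  if (length(envs) >= 3) {
    delta <- do.call(cbind, lapply(envs, function(e) Xq * (data$env == e)))
    colnames(delta) <- paste0("delta:", rep(design$alleles, length(envs)),
                              ":", rep(envs, each = ncol(Xq)))
    random <- list(delta = Matrix::Matrix(delta, sparse = TRUE))
  }

  fit <- reml_fit(data$blue, X, parts$spec, random = random, ...)

  alleles <- design$alleles
  geno_x <- design$X[unique(rownames(design$X)), , drop = FALSE]
  carriers <- colSums(geno_x > 1e-6)
  row_of <- function(kind, a) {
    nm <- paste0(kind, ":", a)
    if (!nm %in% names(fit$beta)) {
      return(c(est = NA_real_, se = NA_real_))
    }
    c(est = unname(fit$beta[nm]),
      se = sqrt(fit$vcov_beta[nm, nm]))
  }
  tab <- purrr::map_dfr(alleles, function(a) {
    bb <- row_of("beta", a); gg <- row_of("gamma", a)
    tibble(allele = a,
           beta = unname(bb["est"]), beta_se = unname(bb["se"]),
           gamma = unname(gg["est"]), gamma_se = unname(gg["se"]),
           carriers = unname(carriers[a]))
  }) |>
    dplyr::mutate(
      beta_W = (.data$beta / .data$beta_se)^2,
      beta_p = pchisq(.data$beta_W, 1, lower.tail = FALSE),
      gamma_W = (.data$gamma / .data$gamma_se)^2,
      gamma_p = pchisq(.data$gamma_W, 1, lower.tail = FALSE),
      flagged = .data$carriers < min_carriers
    )
  ref_row <- tibble(allele = design$reference, beta = 0, beta_se = 0,
                    gamma = 0, gamma_se = 0, carriers = NA_integer_,
                    beta_W = NA_real_, beta_p = NA_real_,
                    gamma_W = NA_real_, gamma_p = NA_real_, flagged = FALSE)
  structure(list(
    table = dplyr::bind_rows(ref_row, tab),
    marker = marker, reference_allele = design$reference,
    covariate = covariate, reference_env = attr(covariate, "reference"),
    fit = fit, alleles = alleles
  ), class = "sensitivity_fit")
}

#' @exportS3Method print sensitivity_fit
#' @keywords internal
print.sensitivity_fit <- function(x, ...) {
  cat("sensitivity_fit at ", x$marker, " (reference allele ",
      x$reference_allele, ", reference environment ",
      x$reference_env %||% "first", ")\n", sep = "")
  print(as.data.frame(x$table), digits = 3)
  invisible(x)
}

#' @export
tidy.sensitivity_fit <- function(x, ...) {
  x$table |>
    tidyr::pivot_longer(c("beta", "gamma"), names_to = "term",
                        values_to = "estimate") |>
    dplyr::mutate(
      std.error = ifelse(.data$term == "beta", .data$beta_se, .data$gamma_se),
      statistic = ifelse(.data$term == "beta", .data$beta_W, .data$gamma_W),
      p.value = ifelse(.data$term == "beta", .data$beta_p, .data$gamma_p)
    ) |>
    dplyr::select("allele", "term", "estimate", "std.error", "statistic",
                  "p.value", "flagged")
}

#' @export
glance.sensitivity_fit <- function(x, ...) {
  tibble(marker = x$marker, n.alleles = length(x$alleles) + 1,
         n.env = nrow(x$covariate), logLik = x$fit$loglik,
         converged = x$fit$converged)
}

#' Homozygous allele contrast at a covariate level
#'
#' Difference in trait value between a genotype homozygous for the
#' reference allele and one homozygous for allele `a` at covariate level
#' `Z` (centred scale): `-2 * (beta_a + Z * gamma_a)`, positive when the
#' reference allele confers the larger trait value. Standard errors come
#' from the delta method on the joint `(beta_a, gamma_a)` covariance.
#'
#' @param fit A `sensitivity_fit`, or a data frame of published-style
#'   coefficients with columns `allele`, `beta`, `gamma` (then no standard
#'   errors are computed: the joint coefficient covariance is unknown).
#' @param allele Allele label present in the fit.
#' @param Z Covariate value(s), on the centred scale (reference = 0).
#' @return Tibble `allele`, `Z`, `contrast`, `se`.
#' @export
allele_contrast <- function(fit, allele, Z) {
  if (is.data.frame(fit)) {
    row <- fit[fit$allele == allele, ]
    if (nrow(row) != 1) abort(paste("unknown allele", allele))
    return(tibble(allele = allele, Z = Z,
                  contrast = -2 * (row$beta + Z * row$gamma),
                  se = NA_real_))
  }
  if (allele == fit$reference_allele) {
    return(tibble(allele = allele, Z = Z, contrast = 0, se = 0))
  }
  if (!allele %in% fit$alleles) abort(paste("unknown allele", allele))
  bn <- paste0("beta:", allele)
  gn <- paste0("gamma:", allele)
  b <- unname(fit$fit$beta[bn])
  g <- unname(fit$fit$beta[gn])
  V <- fit$fit$vcov_beta[c(bn, gn), c(bn, gn)]
  se <- 2 * sqrt(V[1, 1] + Z^2 * V[2, 2] + 2 * Z * V[1, 2])
  tibble(allele = allele, Z = Z, contrast = -2 * (b + Z * g), se = se)
}
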