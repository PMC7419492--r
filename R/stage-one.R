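## Stage one: genotype BLUEs from plot data.
## y = mu + E_e + D_(e) + G_ic + GE_ice + eps, with the environment and the
## genotype (partitioned into checks and entries) fixed, the design terms
## (replicate, block nested in replicate; one variance each) and the
## genotype-by-environment term random, and a homogeneous plot error.

check_plot_table <- function(plots) {
  need <- c("genotype", "cross", "env", "rep", "block", "check", "trait")
  miss <- setdiff(need, names(plots))
  if (length(miss)) abort(paste("plot table missing columns:",
                                paste(miss, collapse = ", ")))
  invisible(plots)
}

stage_one_random <- function(plots, with_ge = TRUE) {
  fac_z <- function(f) {
    f <- factor(f)
    z <- Matrix::t(Matrix::fac2sparse(f))
    colnames(z) <- levels(f)
    z
  }
  zs <- list(
    rep = fac_z(paste(plots$env, plots$rep, sep = ":")),
    block = fac_z(paste(plots$env, plots$rep, plots$block, sep = ":"))
  )
  if (with_ge) {
    zs$ge <- fac_z(paste(plots$genotype, plots$env, sep = ":"))
  }
  zs
}

blues_from_fit <- function(fit, plots, envs) {
  entries <- plots |>
    dplyr::filter(!.data$check) |>
    dplyr::distinct(.data$genotype, .data$cross)
  nm <- names(fit$beta)
  b <- fit$beta
  env_cols <- paste0("env", envs)
  env_part <- mean(c(0, unname(b[intersect(env_cols, nm)])))
  # the baseline genotype has no coefficient; any other absent coefficient
  # was dropped as collinear and its BLUE is not estimable
  base_geno <- levels(factor(plots$genotype))[1]
  gcoef <- vapply(seq_len(nrow(entries)), function(i) {
    g <- entries$genotype[i]
    if (g == base_geno) 0
    else if (paste0("genotype", g) %in% nm) unname(b[paste0("genotype", g)])
    else NA_real_
  }, 1)
  if (anyNA(gcoef)) warn("some genotype effects not estimable; BLUE set to NA")
  entries |>
    dplyr::mutate(blue = unname(b["(Intercept)"]) + env_part + gcoef) |>
    dplyr::arrange(.data$genotype)
}

#' Genotype BLUEs across environments
#'
#' Fits the plot-data model jointly over all environments, with environment
#' and genotype fixed, replicate and block random (one variance each), a
#' homogeneous random genotype-by-environment term, and a homogeneous plot
#' error; check genotypes are part of the fit but excluded from the returned
#' entry BLUEs. The BLUE of a genotype is its estimated expected value
#' averaged over the environment main effects, i.e. the genetic main effect
#' across environments.
#'
#' @param plots Plot table (`genotype`, `cross`, `env`, `rep`, `block`,
#'   `check`, `trait`).
#' @param ... Passed to [reml_fit()].
#' @return Tibble `genotype`, `cross`, `env = "ALL"`, `blue`.
#' @export
fit_blues_joint <- function(plots, ...) {
  check_plot_table(plots)
  envs <- sort(unique(plots$env))
  if (length(envs) < 2) abort("joint BLUEs require at least two environments")
  df <- plots |>
    dplyr::mutate(env = factor(.data$env, levels = envs),
                  genotype = factor(.data$genotype))
  X <- model.matrix(~ env + genotype, df)
  spec <- vcov_spec("iid", genotype = df$genotype)
  fit <- reml_fit(df$trait, X, spec, random = stage_one_random(df, TRUE), ...)
  blues_from_fit(fit, plots, envs) |>
    dplyr::mutate(env = "ALL", .after = "cross")
}

#' Genotype BLUEs within environments
#'
#' Single-environment version of the plot-data model: the environment and
#' genotype-by-environment terms are dropped, replicate and block stay
#' random, genotype (checks and entries) stays fixed.
#'
#' @param plots Plot table.
#' @param env Environment id(s) to fit; default all environments, returning
#'   the stacked per-environment BLUEs used by the joint multi-environment
#'   QTL models.
#' @param ... Passed to [reml_fit()].
#' @return Tibble `genotype`, `cross`, `env`, `blue`.
#' @export
fit_blues_within <- function(plots, env = NULL, ...) {
  check_plot_table(plots)
  envs <- env %||% sort(unique(plots$env))
  missing_env <- setdiff(envs, plots$env)
  if (length(missing_env)) {
    abort(paste("environment(s) absent from plot table:",
                paste(missing_env, collapse = ", ")))
  }
  purrr::map_dfr(envs, function(e) {
    df <- plots |>
      dplyr::filter(.data$env == e) |>
      dplyr::mutate(genotype = factor(.data$genotype))
    X <- model.matrix(~genotype, df)
    spec <- vcov_spec("iid", genotype = df$genotype)
    fit <- reml_fit(df$trait, X, spec,
                    random = stage_one_random(df, FALSE), ...)
    blues_from_fit(fit, df, character()) |>
      dplyr::mutate(env = e, .after = "cross")
  })
}
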