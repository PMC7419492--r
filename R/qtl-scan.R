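## Genome scans for the four detection methods.
##
## M1: QTL model on across-environment BLUEs, cross-specific residual
##     variances, one substitution effect per allele.
## M2: the same model fitted separately on each environment's BLUEs.
## M3: joint model on the stacked within-environment BLUEs with
##     environment-specific cross and QTL effects under CS + ECSE.
## M4: the one-stage version of M3 on plot data, with replicate and block
##     as extra random terms.

method_choices <- c("M1", "M2", "M3", "M4")

qtl_col_prefix <- function(marker) paste0("QTL:", marker, ":")

# QTL fixed-effect columns at one position for a data slice
qtl_columns <- function(design, genotype, env = NULL) {
  if (ncol(design$X) == 0) {
    return(matrix(0, length(genotype), 0))      # monomorphic position
  }
  X <- design$X[match(genotype, rownames(design$X)), , drop = FALSE]
  X[is.na(X)] <- 0                      # checks and foreign ids carry 0
  colnames(X) <- paste0(qtl_col_prefix(design$marker), design$alleles)
  if (is.null(env)) return(X)
  envs <- sort(unique(env))
  out <- do.call(cbind, lapply(envs, function(e) {
    Xe <- X * (env == e)
    colnames(Xe) <- paste0(colnames(X), ":", e)
    Xe
  }))
  out
}

# base fixed design, covariance spec and extra random terms per method
method_parts <- function(data, method) {
  if (method %in% c("M1", "M2")) {
    df <- data.frame(cross = factor(data$cross))
    X <- model.matrix(~cross, df)
    list(X = X, spec = vcov_spec("cross_specific", cross = data$cross),
         random = list(), per_env = FALSE)
  } else if (method == "M3") {
    df <- data.frame(env = factor(data$env), cross = factor(data$cross))
    X <- if (nlevels(df$env) > 1) {
      model.matrix(~ env + env:cross, df)
    } else {
      model.matrix(~cross, df)
    }
    list(X = X,
         spec = vcov_spec("cs_ecse", genotype = data$genotype,
                          cross = data$cross, env = data$env),
         random = list(), per_env = TRUE)
  } else {
    chk <- factor(ifelse(data$check, data$genotype, ".entry"),
                  levels = c(".entry", sort(unique(data$genotype[data$check]))))
    df <- data.frame(env = factor(data$env), cross = factor(data$cross),
                     chk = chk)
    rhs <- if (nlevels(df$env) > 1) "env + env:cross" else "cross"
    if (nlevels(chk) > 1) rhs <- paste(rhs, "+ chk")
    X <- model.matrix(stats::as.formula(paste("~", rhs)), df)
    list(X = X,
         spec = vcov_spec("cs_ecse", genotype = data$genotype,
                          cross = data$cross, env = data$env),
         random = stage_one_random(data, with_ge = FALSE), per_env = TRUE)
  }
}

# fit the method's model with QTL terms at `markers`; returns the mixed fit
fit_qtl_model <- function(data, designs, method, markers, start = NULL, ...) {
  parts <- method_parts(data, method)
  y <- if (method == "M4") data$trait else data$blue
  qtl_X <- lapply(markers, function(mk) {
    qtl_columns(designs[[mk]], data$genotype,
                env = if (parts$per_env) data$env)
  })
  X <- do.call(cbind, c(list(parts$X), qtl_X))
  reml_fit(y, X, parts$spec, random = parts$random, start = start, ...)
}

scan_data <- function(data, method) {
  if (method == "M4") {
    check_plot_table(data)
    data
  } else {
    need <- c("genotype", "cross", "env", "blue")
    miss <- setdiff(need, names(data))
    if (length(miss)) abort(paste("BLUE table missing columns:",
                                  paste(miss, collapse = ", ")))
    data
  }
}

new_scan_profile <- function(df, method, model) {
  structure(df, class = c("scan_profile", class(tibble())),
            method = method, allele_model = model)
}

scan_core <- function(data, designs, method, cofactors = NULL,
                      exclusion = 50, ...) {
  map <- attr(designs, "map")
  markers <- intersect(map$marker, names(designs))
  pos <- map[match(markers, map$marker), ]
  cof <- cofactors
  start <- NULL
  last_err <- "unknown"
  vals <- rep(NA_real_, length(markers))
  for (i in seq_along(markers)) {
    mk <- markers[i]
    cond <- character()
    if (!is.null(cof) && nrow(cof)) {
      same_chr <- cof$chr == pos$chr[i]
      excl <- same_chr & abs(cof$pos_cM - pos$pos_cM[i]) < exclusion
      cond <- cof$marker[!excl]
    }
    res <- tryCatch({
      # after the first position the previous optimum warm-starts the next
      fit <- fit_qtl_model(data, designs, method, c(mk, cond),
                           start = start,
                           n_starts = if (is.null(start)) 2 else 1, ...)
      wt <- wald_test(fit, paste0("^", escape_regex(qtl_col_prefix(mk))),
                      regex = TRUE)
      list(fit = fit, wt = wt)
    }, error = function(e) e)
    if (!rlang::is_condition(res)) {
      start <- res$fit$theta
      vals[i] <- res$wt$neglog10p
    } else {
      last_err <- conditionMessage(res)
    }
  }
  if (all(is.na(vals))) {
    abort(paste("every scan position failed; last error:", last_err))
  }
  tibble(marker = markers, chr = pos$chr, pos_cM = pos$pos_cM,
         neglog10p = vals)
}

#' Simple interval mapping scan
#'
#' Fits the chosen method's QTL model at every map position and returns the
#' Wald `-log10(p)` of the position's QTL term. For M2 the scan is run
#' separately in each environment present in the data and the profiles are
#' stacked with an `env` column. Positions whose fit fails to converge are
#' reported as `NA`.
#'
#' @param data Across-environment BLUEs (M1), stacked within-environment
#'   BLUEs (M2, M3) or a plot table (M4).
#' @param designs Allele designs from [qtl_designs()].
#' @param method `"M1"`, `"M2"`, `"M3"` or `"M4"`.
#' @param ... Passed to [reml_fit()].
#' @return A `scan_profile` tibble: `marker`, `chr`, `pos_cM`,
#'   `neglog10p` (and `env` for M2).
#' @export
sim_scan <- function(data, designs, method = method_choices, ...) {
  method <- match.arg(method)
  cim_scan(data, designs, method, cofactors = NULL, ...)
}

#' Composite interval mapping scan
#'
#' As [sim_scan()], but each position's model also includes the QTL terms of
#' the cofactor positions, except cofactors lying within `exclusion` cM of
#' the tested position on the same chromosome. With no cofactors this is
#' exactly the simple interval mapping scan.
#'
#' @inheritParams sim_scan
#' @param cofactors Cofactor positions as returned by [select_cofactors()]
#'   (a tibble with `marker`, `chr`, `pos_cM`, and `env` for M2), or a
#'   character vector of marker ids.
#' @param exclusion Exclusion window around the tested position, cM.
#' @export
cim_scan <- function(data, designs, method = method_choices,
                     cofactors = NULL, exclusion = 50, ...) {
  method <- match.arg(method)
  data <- scan_data(data, method)
  map <- attr(designs, "map")
  if (is.character(cofactors)) {
    cofactors <- map |>
      dplyr::filter(.data$marker %in% cofactors) |>
      dplyr::select("marker", "chr", "pos_cM")
  }
  if (method == "M2") {
    envs <- sort(unique(data$env))
    prof <- purrr::map_dfr(envs, function(e) {
      cof_e <- cofactors
      if (!is.null(cof_e) && "env" %in% names(cof_e)) {
        cof_e <- dplyr::filter(cof_e, .data$env == e)
      }
      scan_core(dplyr::filter(data, .data$env == e), designs, "M2",
                cofactors = cof_e, exclusion = exclusion, ...) |>
        dplyr::mutate(env = e)
    })
    return(new_scan_profile(prof, "M2", attr(designs, "model")))
  }
  prof <- scan_core(data, designs, method, cofactors = cofactors,
                    exclusion = exclusion, ...)
  new_scan_profile(prof, method, attr(designs, "model"))
}

## ---- greedy peak selection ----

greedy_peaks <- function(profile, threshold, min_dist) {
  cand <- profile |>
    dplyr::filter(!is.na(.data$neglog10p), .data$neglog10p >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$neglog10p), .data$chr, .data$pos_cM)
  picked <- cand[0, ]
  while (nrow(cand) > 0) {
    top <- cand[1, ]
    picked <- dplyr::bind_rows(picked, top)
    cand <- cand |>
      dplyr::filter(!(.data$chr == top$chr &
                        abs(.data$pos_cM - top$pos_cM) < min_dist))
  }
  dplyr::arrange(picked, .data$chr, .data$pos_cM)
}

#' Select cofactor positions from a scan profile
#'
#' Greedy rule: repeatedly take the highest remaining `-log10(p)` at or
#' above the threshold and discard every position within `min_dist` cM on
#' the same chromosome; ties go to the smallest chromosome then smallest
#' position. Profiles carrying an `env` column (M2) are processed per
#' environment.
#'
#' @param profile A `scan_profile`.
#' @param threshold Detection threshold on the `-log10(p)` scale.
#' @param min_dist Minimum distance between selected positions, cM.
#' @return Tibble of selected positions (possibly empty), in map order.
#' @export
select_cofactors <- function(profile, threshold = 4, min_dist = 50) {
  stopifnot(threshold > 0)
  if ("env" %in% names(profile)) {
    profile |>
      dplyr::group_by(.data$env) |>
      dplyr::group_modify(~greedy_peaks(.x, threshold, min_dist)) |>
      dplyr::ungroup() |>
      dplyr::relocate("env", .after = dplyr::last_col())
  } else {
    greedy_peaks(profile, threshold, min_dist)
  }
}

#' Select QTL positions from a CIM profile
#'
#' Same greedy contract as [select_cofactors()] with a tighter default
#' spacing of 20 cM.
#'
#' @inheritParams select_cofactors
#' @export
select_qtls <- function(profile, threshold = 4, min_dist = 20) {
  select_cofactors(profile, threshold, min_dist)
}

## ---- multi-QTL model / backward elimination ----

new_qtl_model <- function(qtl, effects, fit, method, model) {
  structure(list(qtl = qtl, effects = effects, fit = fit,
                 method = method, allele_model = model),
            class = "qtl_model")
}

#' Backward elimination of candidate QTLs
#'
#' Fits the multi-QTL model containing all candidates, then iteratively
#' removes the QTL with the smallest Wald `-log10(p)` while that value is
#' below the threshold, refitting after each removal. Every QTL retained in
#' the returned model is significant in the final joint fit. For M2 the
#' data must be a single environment's BLUEs.
#'
#' @param data See [sim_scan()].
#' @param designs Allele designs from [qtl_designs()].
#' @param candidates Candidate positions: marker ids or a tibble with a
#'   `marker` column (e.g. from [select_qtls()]).
#' @param method Detection method.
#' @param threshold Retention threshold on the `-log10(p)` scale.
#' @param ... Passed to [reml_fit()].
#' @return A `qtl_model`: per-QTL Wald results, per-allele (by environment
#'   for M2-M4) substitution effects with standard errors, and the final
#'   joint `mixed_fit`. An empty model (with a warning) if no candidate
#'   survives.
#' @export
backward_elimination <- function(data, designs, candidates,
                                 method = method_choices, threshold = 4,
                                 ...) {
  method <- match.arg(method)
  data <- scan_data(data, method)
  if (method == "M2" && length(unique(data$env)) > 1) {
    abort("M2 backward elimination runs on one environment at a time")
  }
  markers <- if (is.character(candidates)) candidates else candidates$marker
  if (length(markers) == 0) abort("no candidate QTLs supplied")
  testable <- vapply(markers, function(mk) ncol(designs[[mk]]$X) > 0, TRUE)
  if (!all(testable)) {
    warn(paste("dropping monomorphic candidate(s):",
               paste(markers[!testable], collapse = ", ")))
    markers <- markers[testable]
  }
  map <- attr(designs, "map")
  repeat {
    if (length(markers) == 0) {
      warn("all candidate QTLs eliminated; returning empty model")
      return(new_qtl_model(
        qtl = tibble(marker = character(), chr = integer(),
                     pos_cM = double(), W = double(), df = integer(),
                     p = double(), neglog10p = double()),
        effects = tibble(marker = character(), allele = character(),
                         env = character(), estimate = double(),
                         std.error = double()),
        fit = NULL, method = method, model = attr(designs, "model")))
    }
    fit <- fit_qtl_model(data, designs, method, markers, ...)
    wt <- purrr::map_dfr(markers, function(mk) {
      dplyr::mutate(wald_test(fit, paste0("^", escape_regex(qtl_col_prefix(mk))),
                              regex = TRUE),
                    marker = mk, .before = 1)
    })
    worst <- which.min(wt$neglog10p)
    if (wt$neglog10p[worst] >= threshold) break
    markers <- markers[-worst]
  }
  qtl <- wt |>
    dplyr::left_join(map, by = "marker") |>
    dplyr::select("marker", "chr", "pos_cM", "W", "df", "p", "neglog10p") |>
    dplyr::arrange(.data$chr, .data$pos_cM)
  effects <- extract_qtl_effects(fit, markers)
  new_qtl_model(qtl, effects, fit, method, attr(designs, "model"))
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

extract_qtl_effects <- function(fit, markers) {
  nm <- names(fit$beta)
  purrr::map_dfr(markers, function(mk) {
    pre <- qtl_col_prefix(mk)
    cols <- nm[startsWith(nm, pre)]
    if (length(cols) == 0) return(NULL)
    parts <- strsplit(sub(escape_regex(pre), "", cols), ":", fixed = TRUE)
    tibble(
      marker = mk,
      allele = vapply(parts, `[`, "", 1),
      env = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""),
      estimate = unname(fit$beta[cols]),
      std.error = sqrt(diag(fit$vcov_beta)[cols])
    )
  })
}

#' @exportS3Method print qtl_model
#' @keywords internal
print.qtl_model <- function(x, ...) {
  cat("qtl_model (", x$method, ", ", x$allele_model, "): ",
      nrow(x$qtl), " QTL(s)\n", sep = "")
  if (nrow(x$qtl)) print(as.data.frame(x$qtl), digits = 4)
  invisible(x)
}

#' @export
tidy.qtl_model <- function(x, ...) x$effects

#' @export
glance.qtl_model <- function(x, ...) {
  tibble(n.qtl = nrow(x$qtl), method = x$method,
         allele.model = x$allele_model,
         logLik = if (is.null(x$fit)) NA_real_ else x$fit$loglik,
         converged = if (is.null(x$fit)) NA else x$fit$converged)
}

#' Consolidate QTL positions across methods
#'
#' Clusters the positions detected by several methods (or models) by
#' single-linkage on each chromosome: two positions belong to the same
#' unique QTL when they are separated by less than `merge_dist` cM, and
#' clusters chain through intermediate positions. This yields the count of
#' unique QTL positions across methods.
#'
#' @param positions A tibble with columns `method`, `chr`, `pos_cM` (extra
#'   columns kept), or a named list of `qtl_model` objects.
#' @param merge_dist Merge distance in cM.
#' @return Input positions augmented with a `qtl_id` cluster label.
#' @export
consolidate_qtls <- function(positions, merge_dist = 10) {
  if (is.list(positions) && !is.data.frame(positions)) {
    positions <- purrr::imap_dfr(positions, function(m, nm) {
      dplyr::mutate(m$qtl, method = nm, .before = 1)
    })
  }
  positions |>
    dplyr::group_by(.data$chr) |>
    dplyr::arrange(.data$pos_cM, .by_group = TRUE) |>
    dplyr::mutate(
      .new = c(TRUE, diff(.data$pos_cM) >= merge_dist),
      .cl = cumsum(.data$.new)
    ) |>
    dplyr::group_by(.data$chr, .data$.cl) |>
    dplyr::mutate(qtl_id = sprintf("chr%s@%.1f", .data$chr[1],
                                   mean(.data$pos_cM))) |>
    dplyr::ungroup() |>
    dplyr::select(-".new", -".cl")
}
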