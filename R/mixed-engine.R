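#' Declare a residual/genetic covariance structure
#'
#' The multi-environment QTL models use a compound-symmetry (CS) genotypic
#' covariance combined with environment-cross-specific error (ECSE)
#' variances: observations on the same genotype share a covariance
#' `sigma2_g` across environments, and each (environment, cross) stratum has
#' its own residual variance. Simpler structures are available for the
#' single-environment models.
#'
#' @param kind One of `"iid"` (one residual variance), `"cross_specific"`
#'   (one residual variance per cross), `"cs_homogeneous"` (CS genotype term
#'   plus one residual variance), `"cs_ecse"` (CS genotype term plus one
#'   residual variance per environment-by-cross stratum).
#' @param genotype,cross,env Factors (or vectors) aligned with the
#'   observation vector; which are required depends on `kind`.
#' @return Object of class `vcov_spec`.
#' @export
vcov_spec <- function(kind = c("iid", "cross_specific", "cs_homogeneous",
                               "cs_ecse"),
                      genotype = NULL, cross = NULL, env = NULL) {
  kind <- match.arg(kind)
  need <- switch(kind,
                 iid = character(),
                 cross_specific = "cross",
                 cs_homogeneous = "genotype",
                 cs_ecse = c("genotype", "cross", "env"))
  got <- list(genotype = genotype, cross = cross, env = env)
  for (nm in need) {
    if (is.null(got[[nm]])) abort(paste0("vcov_spec '", kind, "' needs ", nm))
  }
  n <- max(lengths(got))
  for (nm in names(got)) {
    if (is.null(got[[nm]])) next
    if (length(got[[nm]]) == 1) got[[nm]] <- rep(got[[nm]], n)
    if (length(got[[nm]]) != n) {
      abort("genotype/cross/env must have equal lengths")
    }
  }
  genotype <- got$genotype
  cross <- got$cross
  env <- got$env
  strata <- switch(kind,
                   iid = ,
                   cs_homogeneous = factor(rep("resid", n)),
                   cross_specific = factor(cross),
                   cs_ecse = factor(paste(env, cross, sep = ":")))
  structure(list(kind = kind, n = n,
                 genotype = if (!is.null(genotype)) factor(genotype),
                 strata = strata),
            class = "vcov_spec")
}

#' @exportS3Method print vcov_spec
#' @keywords internal
print.vcov_spec <- function(x, ...) {
  cat("vcov_spec:", x$kind, "-", n_params(x), "variance parameter(s) for",
      x$n, "observations\n")
  invisible(x)
}

n_params <- function(spec) {
  nlevels(spec$strata) + as.integer(spec$kind %in% c("cs_homogeneous", "cs_ecse"))
}

#' Materialise the observation covariance matrix
#'
#' Builds the dense `n x n` covariance implied by a [vcov_spec()] and a
#' parameter vector. Under `cs_ecse`, entry `(o, o')` equals
#' `sigma2_g * [same genotype] + sigma2_(e,c) * [o == o']`: the same
#' genotype observed in two environments is linked by `sigma2_g`, and
#' observations from different crosses are independent.
#'
#' @param spec A [vcov_spec()].
#' @param params Named list with `sigma2_g` (CS kinds only) and `sigma2`
#'   (one value per residual stratum, in `levels(spec$strata)` order), or a
#'   bare numeric vector `c(sigma2_g, sigma2...)` in the same order.
#' @return Dense covariance matrix.
#' @export
build_vcov <- function(spec, params) {
  has_cs <- spec$kind %in% c("cs_homogeneous", "cs_ecse")
  if (!is.list(params)) {
    params <- if (has_cs) {
      list(sigma2_g = params[1], sigma2 = params[-1])
    } else {
      list(sigma2 = params)
    }
  }
  s2 <- rep_len(params$sigma2, nlevels(spec$strata))
  if (any(s2 < 0) || (has_cs && params$sigma2_g < 0)) {
    abort("variance parameters must be non-negative")
  }
  V <- diag(s2[as.integer(spec$strata)], spec$n)
  if (has_cs) {
    same <- outer(spec$genotype, spec$genotype, "==") * 1
    V <- V + params$sigma2_g * same
  }
  dimnames(V) <- NULL
  V
}

## ---- REML machinery ----

# Drop collinear columns of X by pivoted QR; returns X and dropped names.
drop_collinear <- function(X, tol = 1e-9) {
  qr_ <- qr(X, tol = tol)
  r <- qr_$rank
  keep <- sort(qr_$pivot[seq_len(r)])
  list(X = X[, keep, drop = FALSE],
       dropped = colnames(X)[setdiff(seq_len(ncol(X)), keep)])
}

# Builds the REML objective. Random terms are iid-variance design matrices;
# the residual is diagonal with one variance per stratum. V^{-1} uses the
# Woodbury identity with a sparse Cholesky of G^{-1} + Z'R^{-1}Z; when the
# single random term is an indicator matrix (one level per observation, as
# for the CS genotype term) that matrix is diagonal and handled in closed
# form.
make_reml_obj <- function(y, X, Zs, stratum) {
  n <- length(y)
  p <- ncol(X)
  si <- as.integer(stratum)
  ns <- nlevels(stratum)
  K <- length(Zs)
  indicator <- NULL
  if (K == 1) {
    Z1 <- as(Zs[[1]], "matrix")
    if (all(Z1 %in% c(0, 1)) && all(rowSums(Z1) == 1)) {
      indicator <- max.col(Z1, ties.method = "first")
      qk <- ncol(Z1)
    }
  }
  if (K > 0 && is.null(indicator)) {
    Zl <- lapply(Zs, function(z) as(as(z, "CsparseMatrix"), "generalMatrix"))
    Z <- Reduce(Matrix::cbind2, Zl)
    qks <- vapply(Zs, ncol, 1L)
    ch_cache <- NULL                 # symbolic factorisation reused
  }
  const <- (n - p) * log(2 * pi)

  # theta holds log-variances; the overall scale is profiled out
  # analytically (V = s * V0, s_hat = y'P0y / (n - p)), so the objective is
  # invariant to adding a constant to theta and one dimension less needs
  # searching.
  function(theta, want_fit = FALSE, profile = TRUE) {
    if (profile) {
      # theta is on the variance-ratio scale (overall level profiled out);
      # bound the ratios so degenerate fits cannot drive the Woodbury
      # algebra into catastrophic cancellation
      theta <- pmin(pmax(theta, -18), 18)
    }
    v <- exp(theta)
    s2 <- v[K + seq_len(ns)]
    rinv <- 1 / s2[si]
    logdetR <- sum(log(s2[si]))
    if (K == 0) {
      ViX <- X * rinv
      Viy <- y * rinv
      logdetV <- logdetR
    } else if (!is.null(indicator)) {
      g <- v[1]
      d <- as.vector(rowsum(rinv, indicator))           # Z'R^{-1}Z diagonal
      m <- 1 / g + d
      logdetV <- logdetR + qk * log(g) + sum(log(m))
      RX <- X * rinv
      Ry <- y * rinv
      ZtRX <- rowsum(RX, indicator)
      ZtRy <- as.vector(rowsum(Ry, indicator))
      ViX <- RX - rinv * (ZtRX / m)[indicator, , drop = FALSE]
      Viy <- Ry - rinv * (ZtRy / m)[indicator]
    } else {
      g <- rep(v[seq_len(K)], qks)
      A <- Z * sqrt(rinv)
      M <- Matrix::forceSymmetric(Matrix::Diagonal(x = 1 / g) +
                                    Matrix::crossprod(A))
      if (is.null(ch_cache)) {
        ch_cache <<- Matrix::Cholesky(M, LDL = FALSE)
      }
      ch <- Matrix::update(ch_cache, M)
      logdetM <- 2 * Matrix::determinant(ch, sqrt = TRUE)$modulus
      logdetV <- logdetR + sum(log(g)) + as.numeric(logdetM)
      RX <- X * rinv
      Ry <- y * rinv
      ZtRX <- Matrix::crossprod(Z, RX)
      ZtRy <- Matrix::crossprod(Z, Ry)
      ViX <- RX - rinv * as.matrix(Z %*% Matrix::solve(ch, ZtRX))
      Viy <- Ry - rinv * as.vector(Z %*% Matrix::solve(ch, ZtRy))
    }
    XtViX <- crossprod(X, ViX)
    XtViy <- crossprod(X, Viy)
    R <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(R)) return(if (want_fit) NULL else Inf)
    logdetXtViX <- 2 * sum(log(diag(R)))
    beta <- backsolve(R, backsolve(R, XtViy, transpose = TRUE))
    yPy <- sum(y * Viy) - sum(XtViy * beta)
    if (profile) {
      s <- max(yPy / (n - p), 1e-300)             # profiled scale
      neg2ll <- (n - p) * log(s) + logdetV + logdetXtViX + (n - p) + const
    } else {
      s <- 1
      neg2ll <- logdetV + logdetXtViX + yPy + const
    }
    if (!want_fit) return(neg2ll / 2)             # negative REML loglik
    vb <- s * chol2inv(R)
    dimnames(vb) <- list(colnames(X), colnames(X))
    list(loglik = -neg2ll / 2, beta = setNames(as.vector(beta), colnames(X)),
         vcov_beta = vb, scale = s)
  }
}

#' REML fit of a linear mixed model with structured covariance
#'
#' Maximises the restricted log-likelihood over the variance parameters of a
#' [vcov_spec()] (optionally augmented with extra iid random terms such as
#' replicate, block, or a residual QTL-by-environment term), then estimates
#' the fixed effects by generalised least squares at the optimum.
#' Optimisation is Nelder-Mead on the log-variance scale with multiple
#' starts; variances are therefore bounded away from negative values, and
#' components driven to the boundary are reported as 0.
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix (column names kept; collinear
#'   columns are dropped automatically and recorded).
#' @param spec A [vcov_spec()] describing the genotype covariance and the
#'   residual strata.
#' @param random Named list of additional random-term design matrices
#'   (each with a single iid variance).
#' @param start Optional warm-start vector of log-variances (as returned in
#'   `fit$theta`), used as the first optimisation start.
#' @param n_starts Number of deterministic starts (>= 1).
#' @param maxit Nelder-Mead iteration cap.
#' @param reltol Relative convergence tolerance on the REML criterion.
#' @return Object of class `mixed_fit`: fixed estimates and their
#'   covariance, variance components, REML log-likelihood (including the
#'   `(n - p) log(2 pi)` constant), optimiser state and bookkeeping.
#' @export
reml_fit <- function(y, X, spec, random = list(), start = NULL,
                     n_starts = 2, maxit = 1500, reltol = 1e-9) {
  stopifnot(length(y) == nrow(X), spec$n == length(y))
  dc <- drop_collinear(X)
  X <- dc$X
  Zs <- random
  if (spec$kind %in% c("cs_homogeneous", "cs_ecse")) {
    Zg <- Matrix::t(Matrix::fac2sparse(spec$genotype))
    colnames(Zg) <- levels(spec$genotype)
    Zs <- c(list(genotype = Zg), Zs)
  }
  K <- length(Zs)
  ns <- nlevels(spec$strata)

  if (length(y) - ncol(X) < 1) {
    # saturated fixed design (e.g. noise-free toys): exact solve, nothing
    # left to estimate variances from
    beta <- qr.solve(X, y)
    vb <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
    vc <- rep(0, K + ns)
    names(vc) <- c(names(Zs), paste0("resid(", levels(spec$strata), ")"))
    return(structure(list(
      beta = setNames(as.vector(beta), colnames(X)), vcov_beta = vb,
      varcomp = vc, loglik = NA_real_, theta = rep(-Inf, K + ns),
      n_obs = length(y), n_fixed = ncol(X), dropped = dc$dropped,
      spec_kind = spec$kind, converged = TRUE
    ), class = "mixed_fit"))
  }

  obj <- make_reml_obj(y, X, Zs, spec$strata)

  vy <- var(stats::lm.fit(X, y)$residuals)
  if (!is.finite(vy) || vy <= 0) vy <- var(y) + 1e-8

  # optimise over variance ratios: the first residual stratum is pinned at
  # log-variance 0 and the overall scale comes from the analytic profile
  pin <- K + 1L
  expand <- function(tr) append(tr, 0, after = K)
  reduce <- function(tf) (tf - tf[pin])[-pin]
  full_starts <- list(
    log(c(rep(vy / (2 * max(K, 1)), K), rep(vy / 2, ns))),
    log(c(rep(vy / 10, K), rep(vy, ns)))
  )
  starts <- lapply(full_starts[seq_len(max(1, n_starts))], reduce)
  if (!is.null(start) && length(start) == K + ns) {
    starts <- c(list(reduce(start)), head(starts, n_starts - 1))
  }

  if (K + ns == 1) {
    best <- list(par = numeric(0), value = obj(0), convergence = 0)
  } else {
    best <- NULL
    for (s0 in starts) {
      if (length(s0) == 1) {
        op <- stats::optimize(function(tr) obj(expand(tr)),
                              interval = c(s0 - 25, s0 + 25), tol = 1e-9)
        cand <- list(par = op$minimum, value = op$objective, convergence = 0)
      } else {
        cand <- optim(s0, function(tr) obj(expand(tr)),
                      method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
      }
      if (is.null(best) || cand$value < best$value) best <- cand
    }
  }
  theta0 <- pmin(pmax(expand(best$par), -18), 18)
  fit <- obj(theta0, want_fit = TRUE)
  if (is.null(fit)) abort("singular fixed-effect design at the REML optimum")
  theta <- theta0 + log(fit$scale)              # absolute log-variances
  vc <- exp(theta)
  vc[vc < 1e-8 * vy] <- 0                       # boundary components
  names(vc) <- c(names(Zs), paste0("resid(", levels(spec$strata), ")"))
  structure(list(
    beta = fit$beta, vcov_beta = fit$vcov_beta,
    varcomp = vc, loglik = fit$loglik, theta = theta,
    n_obs = length(y), n_fixed = ncol(X),
    dropped = dc$dropped, spec_kind = spec$kind,
    converged = best$convergence == 0
  ), class = "mixed_fit")
}

#' Restricted log-likelihood at fixed variance components
#'
#' Evaluates the REML criterion of the model [reml_fit()] fits, at a given
#' set of variances instead of the optimum. Useful to verify that a fit's
#' optimum dominates any grid of candidate variance values.
#'
#' @inheritParams reml_fit
#' @param varcomp Vector of variances (> 0) in the fit's component order:
#'   random-term variances first (genotype CS term first when the spec has
#'   one), then one residual variance per stratum.
#' @return The restricted log-likelihood (same constant as `fit$loglik`).
#' @export
reml_loglik <- function(y, X, spec, random = list(), varcomp) {
  dc <- drop_collinear(X)
  Zs <- random
  if (spec$kind %in% c("cs_homogeneous", "cs_ecse")) {
    Zg <- Matrix::t(Matrix::fac2sparse(spec$genotype))
    Zs <- c(list(genotype = Zg), Zs)
  }
  stopifnot(length(varcomp) == length(Zs) + nlevels(spec$strata),
            all(varcomp > 0))
  obj <- make_reml_obj(y, dc$X, Zs, spec$strata)
  -obj(log(varcomp), profile = FALSE)
}

#' @exportS3Method print mixed_fit
#' @keywords internal
print.mixed_fit <- function(x, ...) {
  cat("mixed_fit (", x$spec_kind, "): ", x$n_fixed, " fixed effects, ",
      length(x$varcomp), " variance component(s), REML logLik = ",
      format(x$loglik, digits = 6),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mixed_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov_beta))
  tibble(term = names(x$beta), estimate = unname(x$beta),
         std.error = unname(se),
         statistic = unname(x$beta / se),
         p.value = 2 * pchisq((x$beta / se)^2, 1, lower.tail = FALSE))
}

#' @export
glance.mixed_fit <- function(x, ...) {
  tibble(logLik = x$loglik, nobs = x$n_obs, n.fixed = x$n_fixed,
         n.varcomp = length(x$varcomp), converged = x$converged)
}

#' Wald test of a block of fixed effects
#'
#' Tests the null hypothesis that all listed coefficients are zero with
#' `W = beta' V(beta)^{-1} beta`, referred to a chi-square distribution with
#' degrees of freedom equal to the number of coefficients tested (`n_a - 1`
#' for a main-effect QTL term; `N_e * (n_a - 1)` for environment-specific
#' terms). A singular sub-covariance falls back to a generalised inverse
#' with the degrees of freedom reduced to its rank, with a warning.
#'
#' @param fit A `mixed_fit`.
#' @param terms Character vector of coefficient names (or a regular
#'   expression when `regex = TRUE`).
#' @param regex Interpret `terms` as a regular expression.
#' @return One-row tibble `W`, `df`, `p`, `neglog10p`.
#' @export
wald_test <- function(fit, terms, regex = FALSE) {
  nm <- names(fit$beta)
  sel <- if (regex) grep(terms, nm, value = TRUE) else intersect(terms, nm)
  if (length(sel) == 0) abort("no tested coefficients present in fit")
  b <- fit$beta[sel]
  V <- fit$vcov_beta[sel, sel, drop = FALSE]
  W <- tryCatch({
    R <- chol(V)
    u <- backsolve(R, b, transpose = TRUE)
    sum(u^2)
  }, error = function(e) NA_real_)
  df <- length(sel)
  if (is.na(W)) {
    warn("singular coefficient covariance; using generalised inverse")
    eg <- eigen(V, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-10
    df <- sum(pos)
    u <- crossprod(eg$vectors[, pos, drop = FALSE], b)
    W <- sum(u^2 / eg$values[pos])
  }
  W <- max(W, 0)
  tibble(W = W, df = df,
         p = pchisq(W, df, lower.tail = FALSE),
         neglog10p = neglog10p_chi2(W, df))
}

#' Convert a Wald statistic to -log10(p)
#'
#' Chi-square upper-tail probability on the log scale, numerically stable
#' for p-values far below double precision underflow of the plain survival
#' function.
#'
#' @param W Wald statistic(s), >= 0.
#' @param df Degrees of freedom, >= 1.
#' @return `-log10` of the chi-square survival probability.
#' @export
#' @examples
#' neglog10p_chi2(44.3, 4)
neglog10p_chi2 <- function(W, df) {
  stopifnot(all(W >= 0), all(df >= 1))
  -pchisq(W, df, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Bonferroni genome-wide threshold on the -log10(p) scale
#'
#' @param n_tests Number of tested positions.
#' @param alpha Family-wise error rate.
#' @return `-log10(alpha / n_tests)`.
#' @export
#' @examples
#' bonferroni_threshold(5949)
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  -log10(alpha / n_tests)
}
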