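#' Haldane map function
#'
#' Converts a genetic distance in centimorgan into a recombination fraction
#' under Haldane's no-interference model, `r = (1 - exp(-2 d / 100)) / 2`.
#' The same mapping function is used consistently by the simulator and by the
#' identity-by-descent machinery.
#'
#' @param d_cM Numeric vector of distances in centimorgan (>= 0).
#' @return Recombination fractions in `[0, 0.5)`.
#' @export
#' @examples
#' haldane_r(c(0, 1, 20, 1e6))
haldane_r <- function(d_cM) {
  stopifnot(all(d_cM >= 0))
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' Simulate a genetic map
#'
#' Markers are evenly spaced along each chromosome (first marker at 0 cM,
#' last at `length_cM`), optionally jittered. With `jitter = 0` the map is
#' fully deterministic.
#'
#' @param n_chr Number of chromosomes.
#' @param length_cM Chromosome length in centimorgan (recycled over
#'   chromosomes).
#' @param n_markers Markers per chromosome (>= 2; recycled).
#' @param jitter Standard deviation (cM) of Gaussian jitter applied to the
#'   interior marker positions; positions are re-sorted and clamped to
#'   `[0, length_cM]`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `marker`, `chr`, `pos_cM` (the genetic map
#'   contract used throughout the package).
#' @export
sim_map <- function(n_chr = 2, length_cM = 100, n_markers = 15, jitter = 0,
                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  length_cM <- rep_len(length_cM, n_chr)
  n_markers <- rep_len(n_markers, n_chr)
  stopifnot(all(n_markers >= 2), all(length_cM > 0))
  purrr::map_dfr(seq_len(n_chr), function(ch) {
    pos <- seq(0, length_cM[ch], length.out = n_markers[ch])
    if (jitter > 0) {
      mid <- seq_along(pos)[-c(1, length(pos))]
      pos[mid] <- pos[mid] + rnorm(length(mid), 0, jitter)
      pos <- sort(pmin(pmax(pos, 0), length_cM[ch]))
    }
    tibble(
      marker = sprintf("c%d_m%02d", ch, seq_len(n_markers[ch])),
      chr = ch,
      pos_cM = pos
    )
  })
}

#' Simulate NAM genotypes of doubled-haploid progeny
#'
#' Emulates a nested association mapping design: one central parent crossed
#' to `n_peripheral` peripheral parents, each cross producing doubled-haploid
#' (DH) progeny. Each DH line is a single recombinant gamete (crossovers from
#' a Markov chain whose transition probabilities between adjacent markers are
#' Haldane recombination fractions, i.e. a Poisson crossover process with no
#' interference), then doubled, so SNP dosages are 0 or 2.
#'
#' Peripheral parents are drawn from a small set of founder haplotypes
#' (`n_ancestral_groups`) with per-marker mutations, so that local
#' identity-by-state clustering recovers ancestral groups, mimicking real
#' panels where several parents descend from common ancestors.
#'
#' @param map Genetic map tibble from [sim_map()].
#' @param n_peripheral Number of peripheral parents (= number of crosses).
#' @param n_per_cross DH progeny per cross (recycled over crosses).
#' @param n_ancestral_groups Number of founder haplotypes behind the
#'   peripheral parents; default `max(2, ceiling(n_peripheral / 2))`.
#' @param mutation Per-marker probability that a parent deviates from its
#'   founder haplotype.
#' @param maf Allele frequency used to draw founder haplotypes.
#' @param central_parent Identifier of the central parent.
#' @param seed Optional integer seed.
#' @return A list of class `nam_sim` with elements `geno` (a [marker_data]
#'   object holding progeny and parent dosages plus the map), `crosses`
#'   (tibble `genotype`, `cross`, `parent1` = central, `parent2`), `origin`
#'   (integer matrix, 1 = central-parent origin, 2 = peripheral), and
#'   `parent_groups` (founder group of each peripheral parent).
#' @export
sim_nam_genotypes <- function(map, n_peripheral = 4, n_per_cross = 80,
                              n_ancestral_groups = NULL, mutation = 0.02,
                              maf = 0.5, central_parent = "P0", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(map)
  n_per_cross <- rep_len(n_per_cross, n_peripheral)
  if (is.null(n_ancestral_groups)) {
    n_ancestral_groups <- max(2, ceiling(n_peripheral / 2))
  }
  periph_ids <- sprintf("P%d", seq_len(n_peripheral))

  central_hap <- rbinom(m, 1, maf)
  founders <- matrix(rbinom(m * n_ancestral_groups, 1, maf),
                     nrow = n_ancestral_groups, byrow = TRUE)
  groups <- rep_len(seq_len(n_ancestral_groups), n_peripheral)
  parent_haps <- vapply(seq_len(n_peripheral), function(p) {
    hap <- founders[groups[p], ]
    flip <- runif(m) < mutation
    hap[flip] <- 1L - hap[flip]
    hap
  }, integer(m))
  parent_haps <- t(parent_haps)            # parents x markers
  rownames(parent_haps) <- periph_ids

  # switch probabilities between adjacent markers, per chromosome
  chr <- map$chr
  d_next <- pmax(c(diff(map$pos_cM), 0), 0)
  r_next <- haldane_r(d_next)
  r_next[c(diff(chr) != 0, TRUE)] <- 0.5   # chromosome breaks: independent

  sim_gamete_origins <- function(n) {
    # n gametes; returns n x m matrix of origins in {1, 2}
    o <- matrix(0L, n, m)
    o[, 1] <- rbinom(n, 1, 0.5) + 1L
    for (j in seq_len(m - 1)) {
      switch_ <- runif(n) < r_next[j]
      o[, j + 1] <- ifelse(switch_, 3L - o[, j], o[, j])
    }
    o
  }

  geno_list <- vector("list", n_peripheral)
  origin_list <- vector("list", n_peripheral)
  cross_list <- vector("list", n_peripheral)
  for (p in seq_len(n_peripheral)) {
    n <- n_per_cross[p]
    ori <- sim_gamete_origins(n)
    hap <- ifelse(ori == 1L,
                  matrix(central_hap, n, m, byrow = TRUE),
                  matrix(parent_haps[p, ], n, m, byrow = TRUE))
    ids <- sprintf("C%02d_%03d", p, seq_len(n))
    rownames(hap) <- rownames(ori) <- ids
    geno_list[[p]] <- 2L * hap
    origin_list[[p]] <- ori
    cross_list[[p]] <- tibble(
      genotype = ids, cross = sprintf("C%02d", p),
      parent1 = central_parent, parent2 = periph_ids[p]
    )
  }
  progeny <- do.call(rbind, geno_list)
  origin <- do.call(rbind, origin_list)
  colnames(progeny) <- colnames(origin) <- map$marker
  parents <- 2L * rbind(central_hap, parent_haps)
  rownames(parents) <- c(central_parent, periph_ids)
  colnames(parents) <- map$marker

  crosses <- dplyr::bind_rows(cross_list)
  attr(crosses, "central_parent") <- central_parent
  structure(
    list(
      geno = marker_data(progeny, parents, map),
      crosses = crosses,
      origin = origin,
      parent_groups = setNames(groups, periph_ids)
    ),
    class = "nam_sim"
  )
}

#' @exportS3Method print nam_sim
#' @keywords internal
print.nam_sim <- function(x, ...) {
  cat("NAM simulation:", nrow(x$geno$progeny), "DH lines,",
      length(unique(x$crosses$cross)), "crosses,",
      ncol(x$geno$progeny), "markers\n")
  invisible(x)
}

#' Simulate plot-level phenotypes for a NAM experiment
#'
#' Generates an augmented p-rep trial in each environment and phenotypes from
#' the generative model
#' `y = mu + E_e + rep + block + C_ce + sum_q x * beta_ae(q) + GE_ice + eps`,
#' where `GE_ice ~ N(0, sigma2_g)` is drawn once per genotype and shared
#' across environments (compound symmetry) and the plot error has an
#' environment-by-cross-specific variance. A configurable fraction of the
#' entries is replicated twice (default one third, the p-rep convention);
#' check genotypes are fixed extra entries repeated in every incomplete
#' block.
#'
#' QTL truth is a tibble with columns `marker`, `parent` (peripheral parent
#' carrying the non-reference allele), and either per-environment effects
#' (`env`, `beta`) or a main effect plus covariate sensitivity (`beta`,
#' `gamma`, combined with `covariate` as `beta + Z_e * gamma`). Effects are
#' allelic substitution effects relative to the central-parent allele, in
#' trait units per allele copy.
#'
#' @param sim A `nam_sim` object from [sim_nam_genotypes()].
#' @param qtl QTL truth tibble (see Details); `NULL` for a null trait.
#' @param n_env Number of environments (ignored if `covariate` given).
#' @param covariate Optional tibble `env`, `Z` defining environments and an
#'   environmental covariate used with `gamma`-style truth.
#' @param mu Intercept, trait units.
#' @param env_effect Fixed environment main effects (default 0, 5, 10, ...).
#' @param sigma2_g Genotypic (compound-symmetry) variance.
#' @param sigma2_e Plot error variance; scalar, or an `n_env x n_cross`
#'   matrix for environment-cross-specific errors.
#' @param sigma2_rep,sigma2_block Variances of the replicate and incomplete
#'   block effects.
#' @param cross_env_sd SD of the fixed cross-by-environment shifts `C_ce`.
#' @param p_rep Fraction of entries with two replicates.
#' @param block_size Entry plots per incomplete block.
#' @param n_checks Number of check genotypes (one plot per block each).
#' @param check_effect_sd SD of the fixed check genotype effects.
#' @param seed Optional integer seed.
#' @return List with `plots` (tibble `genotype`, `cross`, `env`, `rep`,
#'   `block`, `check`, `trait`) and `truth` (QTL table with realised
#'   `beta_ae`, genetic values, fixed effects and variance components).
#' @export
sim_phenotypes <- function(sim, qtl = NULL, n_env = 2, covariate = NULL,
                           mu = 100, env_effect = NULL,
                           sigma2_g = 4, sigma2_e = 8,
                           sigma2_rep = 1, sigma2_block = 1,
                           cross_env_sd = 1,
                           p_rep = 1 / 3, block_size = 8,
                           n_checks = 2, check_effect_sd = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(covariate)) {
    envs <- covariate$env
    n_env <- length(envs)
  } else {
    envs <- sprintf("E%d", seq_len(n_env))
  }
  if (is.null(env_effect)) env_effect <- seq(0, by = 5, length.out = n_env)
  env_effect <- setNames(rep_len(env_effect, n_env), envs)

  crosses <- sim$crosses
  cross_ids <- unique(crosses$cross)
  n_cross <- length(cross_ids)
  geno_ids <- crosses$genotype
  n_geno <- length(geno_ids)
  if (is.matrix(sigma2_e)) {
    stopifnot(nrow(sigma2_e) == n_env, ncol(sigma2_e) == n_cross)
    s2e <- sigma2_e
  } else {
    s2e <- matrix(sigma2_e, n_env, n_cross)
  }
  dimnames(s2e) <- list(envs, cross_ids)

  # realised per-environment allelic effects
  qtl_truth <- NULL
  gvalue <- matrix(0, n_geno, n_env, dimnames = list(geno_ids, envs))
  if (!is.null(qtl)) {
    qtl <- as_tibble(qtl)
    if ("gamma" %in% names(qtl)) {
      stopifnot(!is.null(covariate))
      qtl_truth <- tidyr::crossing(qtl, covariate) |>
        dplyr::mutate(beta_ae = .data$beta + .data$Z * .data$gamma)
    } else if ("env" %in% names(qtl)) {
      qtl_truth <- dplyr::mutate(qtl, beta_ae = .data$beta)
    } else {
      qtl_truth <- tidyr::crossing(qtl, env = envs) |>
        dplyr::mutate(beta_ae = .data$beta)
    }
    per_parent <- setNames(crosses$parent2, crosses$genotype)
    for (k in seq_len(nrow(qtl_truth))) {
      row <- qtl_truth[k, ]
      x <- 2 * (sim$origin[, row$marker] == 2L) *
        (per_parent[geno_ids] == row$parent)
      gvalue[, row$env] <- gvalue[, row$env] + x * row$beta_ae
    }
  }

  ge <- rnorm(n_geno, 0, sqrt(sigma2_g))                  # CS genotype term
  names(ge) <- geno_ids
  c_ce <- matrix(rnorm(n_env * n_cross, 0, cross_env_sd), n_env, n_cross,
                 dimnames = list(envs, cross_ids))
  check_ids <- if (n_checks > 0) sprintf("CHK%d", seq_len(n_checks)) else character()
  check_eff <- setNames(rnorm(n_checks, 0, check_effect_sd), check_ids)
  check_ge <- setNames(rnorm(n_checks, 0, sqrt(sigma2_g)), check_ids)

  n_rep2 <- ceiling(p_rep * n_geno)
  cross_of <- setNames(crosses$cross, crosses$genotype)

  plots <- purrr::map_dfr(envs, function(e) {
    rep2 <- sample(geno_ids, n_rep2)
    purrr::map_dfr(1:2, function(r) {
      ids <- if (r == 1) sample(geno_ids) else sample(rep2)
      if (length(ids) == 0) return(NULL)
      blk <- ceiling(seq_along(ids) / block_size)
      entries <- tibble(genotype = ids, block = blk, check = FALSE)
      chk <- tidyr::crossing(block = unique(blk), genotype = check_ids) |>
        dplyr::mutate(check = TRUE)
      dplyr::bind_rows(entries, chk) |>
        dplyr::mutate(env = e, rep = r)
    })
  })

  rep_key <- paste(plots$env, plots$rep)
  blk_key <- paste(plots$env, plots$rep, plots$block)
  rep_eff <- setNames(rnorm(length(unique(rep_key)), 0, sqrt(sigma2_rep)),
                      unique(rep_key))
  blk_eff <- setNames(rnorm(length(unique(blk_key)), 0, sqrt(sigma2_block)),
                      unique(blk_key))

  is_chk <- plots$check
  cross <- ifelse(is_chk, "CHK", cross_of[plots$genotype])
  g_part <- ifelse(is_chk,
                   check_eff[plots$genotype] + check_ge[plots$genotype],
                   gvalue[cbind(match(plots$genotype, geno_ids),
                                match(plots$env, envs))] +
                     ge[plots$genotype])
  cce <- ifelse(is_chk, 0,
                c_ce[cbind(match(plots$env, envs), match(cross, cross_ids))])
  s2 <- ifelse(is_chk, mean(s2e),
               s2e[cbind(match(plots$env, envs), match(cross, cross_ids))])
  y <- mu + env_effect[plots$env] + rep_eff[rep_key] + blk_eff[blk_key] +
    cce + g_part + rnorm(nrow(plots), 0, sqrt(s2))

  plots <- plots |>
    dplyr::mutate(cross = cross, trait = unname(y)) |>
    dplyr::select("genotype", "cross", "env", "rep", "block", "check", "trait")

  list(
    plots = plots,
    truth = list(
      qtl = qtl_truth,
      gvalue = gvalue,
      ge = ge,
      env_effect = env_effect,
      cross_env = c_ce,
      varcomp = list(sigma2_g = sigma2_g, sigma2_e = s2e,
                     sigma2_rep = sigma2_rep, sigma2_block = sigma2_block)
    )
  )
}
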