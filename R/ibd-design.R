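#' Marker data container
#'
#' Bundles the progeny dosage matrix, the parent dosage matrix and the
#' genetic map, the three inputs every marker-level operation needs. Dosages
#' are minor-allele counts in `{0, 1, 2}` or `NA`; doubled-haploid progeny
#' are expected to carry only 0/2 (residual heterozygous calls are treated
#' as missing where origin matters).
#'
#' @param progeny Numeric matrix, individuals x markers, with dimnames.
#' @param parents Numeric matrix, parents x markers, same marker columns.
#' @param map Tibble with columns `marker`, `chr`, `pos_cM` covering all
#'   marker columns.
#' @return An object of class `marker_data`.
#' @export
marker_data <- function(progeny, parents, map) {
  stopifnot(is.matrix(progeny), is.matrix(parents),
            !is.null(rownames(progeny)), !is.null(colnames(progeny)))
  map <- as_tibble(map)
  if (!all(c("marker", "chr", "pos_cM") %in% names(map))) {
    abort("map must have columns marker, chr, pos_cM")
  }
  if (anyDuplicated(map$marker)) abort("duplicated marker ids in map")
  missing_in_map <- setdiff(colnames(progeny), map$marker)
  if (length(missing_in_map)) {
    abort(paste0("markers absent from map: ",
                 paste(head(missing_in_map, 5), collapse = ", ")))
  }
  if (!identical(colnames(progeny), colnames(parents))) {
    abort("progeny and parents must share identical marker columns")
  }
  map <- map |>
    dplyr::filter(.data$marker %in% colnames(progeny)) |>
    dplyr::arrange(.data$chr, .data$pos_cM)
  # store columns in map order so positional logic is monotone
  progeny <- progeny[, map$marker, drop = FALSE]
  parents <- parents[, map$marker, drop = FALSE]
  ok <- progeny %in% c(0, 1, 2) | is.na(progeny)
  if (!all(ok)) abort("progeny dosages must be 0, 1, 2 or NA")
  structure(list(progeny = progeny, parents = parents, map = map),
            class = "marker_data")
}

#' @exportS3Method print marker_data
#' @keywords internal
print.marker_data <- function(x, ...) {
  cat("marker_data:", nrow(x$progeny), "individuals x", ncol(x$progeny),
      "markers;", nrow(x$parents), "parents;",
      length(unique(x$map$chr)), "chromosomes\n")
  invisible(x)
}

#' Per-marker summary statistics
#'
#' Minor-allele frequency and missing fraction computed over progeny calls.
#'
#' @param geno A [marker_data] object.
#' @return Tibble `marker`, `chr`, `pos_cM`, `maf`, `miss`.
#' @export
marker_stats <- function(geno) {
  g <- geno$progeny
  miss <- colMeans(is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  maf <- pmin(p, 1 - p)
  geno$map |>
    dplyr::mutate(maf = unname(maf[.data$marker]),
                  miss = unname(miss[.data$marker]))
}

subset_markers <- function(geno, keep) {
  marker_data(geno$progeny[, keep, drop = FALSE],
              geno$parents[, keep, drop = FALSE],
              dplyr::filter(geno$map, .data$marker %in% keep))
}

#' Marker quality control
#'
#' Drops markers with minor-allele frequency below `maf_min` or missing
#' fraction above `miss_max`, keeping the original map order.
#'
#' @param geno A [marker_data] object.
#' @param maf_min Minimum minor-allele frequency kept (exclusive lower
#'   bound on dropped markers: markers with `maf >= maf_min` survive).
#' @param miss_max Maximum missing fraction kept.
#' @return Filtered [marker_data].
#' @export
qc_markers <- function(geno, maf_min = 0.05, miss_max = 0.10) {
  stopifnot(maf_min > 0, maf_min < 0.5, miss_max > 0, miss_max < 1)
  st <- marker_stats(geno)
  keep <- st$marker[!is.na(st$maf) & st$maf >= maf_min & st$miss <= miss_max]
  if (length(keep) == 0) abort("no markers survive QC")
  subset_markers(geno, keep)
}

#' Deduplicate co-located markers
#'
#' At each (chromosome, position) keeps the most polymorphic marker (highest
#' minor-allele frequency); ties keep the first in map order.
#'
#' @param geno A [marker_data] object.
#' @return [marker_data] with at most one marker per map position.
#' @export
dedupe_positions <- function(geno) {
  st <- marker_stats(geno) |>
    dplyr::mutate(.ord = dplyr::row_number())
  keep <- st |>
    dplyr::group_by(.data$chr, .data$pos_cM) |>
    dplyr::arrange(dplyr::desc(.data$maf), .data$.ord, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord) |>
    dplyr::pull(.data$marker)
  subset_markers(geno, keep)
}

#' Random imputation of missing bi-allelic dosages
#'
#' Missing progeny calls are drawn from the marker's allele frequency within
#' the individual's cross (doubled haploids: dosage 2 with probability equal
#' to the within-cross allele-2 frequency). Markers entirely missing within
#' a cross fall back to the population frequency with a warning.
#'
#' @param geno A [marker_data] object.
#' @param crosses Cross table (`genotype`, `cross`).
#' @param seed Optional integer seed (same seed, same imputation).
#' @return [marker_data] without missing progeny values.
#' @export
impute_biallelic <- function(geno, crosses, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- geno$progeny
  if (!anyNA(g)) return(geno)
  cross <- crosses$cross[match(rownames(g), crosses$genotype)]
  if (anyNA(cross)) abort("individuals missing from cross table")
  pop_p <- colMeans(g, na.rm = TRUE) / 2
  fell_back <- FALSE
  for (cr in unique(cross)) {
    rows <- which(cross == cr)
    sub <- g[rows, , drop = FALSE]
    na_idx <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(na_idx) == 0) next
    p_cr <- colMeans(sub, na.rm = TRUE) / 2
    bad <- is.nan(p_cr)
    if (any(bad[unique(na_idx[, 2])])) fell_back <- TRUE
    p_cr[bad] <- pop_p[bad]
    p_draw <- p_cr[na_idx[, 2]]
    sub[na_idx] <- 2 * rbinom(nrow(na_idx), 1, p_draw)
    g[rows, ] <- sub
  }
  if (fell_back) {
    warn("markers entirely missing within a cross imputed from population frequency")
  }
  marker_data(g, geno$parents, geno$map)
}

## ---- identity by descent for doubled haploids ----

# forward-backward posteriors of a 2-state origin chain on one chromosome
# emit: n_markers x 2 matrix of emission likelihoods; r: switch prob to next
ibd_fb <- function(emit, r) {
  m <- nrow(emit)
  alpha <- matrix(0, m, 2)
  beta <- matrix(0, m, 2)
  alpha[1, ] <- 0.5 * emit[1, ]
  sa <- sum(alpha[1, ])
  alpha[1, ] <- alpha[1, ] / sa
  for (j in seq_len(m - 1)) {
    a <- alpha[j, ]
    pred <- c(a[1] * (1 - r[j]) + a[2] * r[j],
              a[1] * r[j] + a[2] * (1 - r[j]))
    v <- pred * emit[j + 1, ]
    alpha[j + 1, ] <- v / sum(v)
  }
  beta[m, ] <- c(1, 1)
  for (j in rev(seq_len(m - 1))) {
    b <- beta[j + 1, ] * emit[j + 1, ]
    beta[j, ] <- c(b[1] * (1 - r[j]) + b[2] * r[j],
                   b[1] * r[j] + b[2] * (1 - r[j]))
    beta[j, ] <- beta[j, ] / sum(beta[j, ])
  }
  post <- alpha * beta
  post / rowSums(post)
}

#' Expected parental allele copies for doubled-haploid progeny
#'
#' For each DH individual and each marker position, computes the expected
#' number of allele copies inherited from each of its two parents via a
#' two-state hidden Markov chain along every chromosome. Transition
#' probabilities between adjacent markers are Haldane recombination
#' fractions of the map distance; markers where the two parents share the
#' same score (or where the progeny call is missing or heterozygous) emit no
#' information. Chromosomes on which the parents are identical everywhere
#' yield flat posteriors (one expected copy from each parent) with a
#' warning.
#'
#' @param geno A [marker_data] object (progeny dosages 0/2; heterozygous
#'   calls are treated as missing for origin inference).
#' @param crosses Cross table (`genotype`, `cross`, `parent1`, `parent2`).
#' @return Object of class `ibd_dh`: list with `p1_copies` (individuals x
#'   markers matrix of expected copies of the `parent1` allele; copies of
#'   `parent2` are `2 - p1_copies`), plus the `map` and `crosses` used.
#' @export
compute_ibd_dh <- function(geno, crosses) {
  map <- geno$map
  g <- geno$progeny
  res <- matrix(NA_real_, nrow(g), ncol(g), dimnames = dimnames(g))
  chr_idx <- split(seq_len(nrow(map)), map$chr)
  flat_warned <- FALSE
  for (cr in unique(crosses$cross)) {
    info <- crosses[crosses$cross == cr, ]
    p1 <- geno$parents[info$parent1[1], ]
    p2 <- geno$parents[info$parent2[1], ]
    ids <- intersect(rownames(g), info$genotype)
    informative_marker <- p1 != p2 & !is.na(p1) & !is.na(p2) &
      p1 %in% c(0, 2) & p2 %in% c(0, 2)
    for (idx in chr_idx) {
      d <- diff(map$pos_cM[idx])
      r <- haldane_r(d)
      if (!any(informative_marker[idx])) {
        res[ids, idx] <- 1
        if (!flat_warned) {
          warn("parents identical along a whole chromosome; flat IBD (one copy each) returned")
          flat_warned <- TRUE
        }
        next
      }
      for (id in ids) {
        obs <- g[id, idx]
        obs[obs == 1] <- NA                       # residual hets: missing
        emit <- matrix(1, length(idx), 2)
        inf_j <- informative_marker[idx] & !is.na(obs)
        emit[inf_j, 1] <- as.numeric(obs[inf_j] == p1[idx][inf_j])
        emit[inf_j, 2] <- as.numeric(obs[inf_j] == p2[idx][inf_j])
        conflict <- inf_j & emit[, 1] == 0 & emit[, 2] == 0
        emit[conflict, ] <- 1                     # matches neither: ignore
        if (length(idx) == 1) {
          post <- matrix(emit[1, ] * 0.5, 1, 2)
          post <- post / sum(post)
        } else {
          post <- ibd_fb(emit, r)
        }
        res[id, idx] <- 2 * post[, 1]
      }
    }
  }
  structure(list(p1_copies = res, map = map, crosses = crosses),
            class = "ibd_dh")
}

#' @exportS3Method print ibd_dh
#' @keywords internal
print.ibd_dh <- function(x, ...) {
  cat("ibd_dh: expected parent-1 allele copies,",
      nrow(x$p1_copies), "individuals x", ncol(x$p1_copies), "positions\n")
  invisible(x)
}

#' Ancestral clustering of parents by local identity by state
#'
#' At each marker position, pairwise parent similarity is the fraction of
#' identical scores over the markers lying within `window` cM of the
#' position (the position's own marker included; an empty window falls back
#' to the nearest marker). Parents are then grouped by single-linkage
#' clustering, merging chains whose similarity is at least `threshold`.
#' This is a deliberately simple windowed-IBS stand-in for kernel-based
#' haplotype clustering: adequate to define ancestral allele classes, not a
#' reimplementation of clusthaplo.
#'
#' @param geno A [marker_data] object (parent scores are used).
#' @param window Half-width of the similarity window, cM (> 0; default 2).
#' @param threshold Similarity at or above which parents join a class.
#' @return Object of class `ancestral_classes`: integer matrix parents x
#'   markers of class ids (renumbered by first appearance), with the
#'   window/threshold recorded as attributes.
#' @export
cluster_ancestral <- function(geno, window = 2, threshold = 0.8) {
  stopifnot(window > 0, threshold > 0, threshold <= 1)
  par <- geno$parents
  np <- nrow(par)
  map <- geno$map
  cls <- matrix(NA_integer_, np, nrow(map),
                dimnames = list(rownames(par), map$marker))
  for (j in seq_len(nrow(map))) {
    same_chr <- which(map$chr == map$chr[j])
    idx <- same_chr[abs(map$pos_cM[same_chr] - map$pos_cM[j]) <= window]
    if (length(idx) == 0) {
      idx <- same_chr[which.min(abs(map$pos_cM[same_chr] - map$pos_cM[j]))]
      warn("empty clustering window; using nearest marker")
    }
    sub <- par[, idx, drop = FALSE]
    S <- matrix(1, np, np)
    for (a in seq_len(np - 1)) for (b in (a + 1):np) {
      ok <- !is.na(sub[a, ]) & !is.na(sub[b, ])
      S[a, b] <- S[b, a] <- if (any(ok)) mean(sub[a, ok] == sub[b, ok]) else 0
    }
    if (np == 1) {
      cls[, j] <- 1L
    } else {
      hc <- stats::hclust(stats::as.dist(1 - S), method = "single")
      k <- stats::cutree(hc, h = 1 - threshold + 1e-12)
      cls[, j] <- as.integer(match(k, unique(k)))   # renumber by appearance
    }
  }
  structure(cls, class = "ancestral_classes",
            window = window, threshold = threshold)
}

## ---- allele design matrices ----

#' QTL allele design matrix at one position
#'
#' Builds the matrix of expected allele dosages `x_ia` used as the QTL term
#' of the detection models, under one of three allele codings:
#' * `parental`: one column of expected allele copies per non-reference
#'   parent (from IBD probabilities); the central parent is the reference.
#' * `ancestral`: parental columns summed within local ancestral classes;
#'   the class containing the central parent is the reference.
#' * `biallelic`: a single column of SNP minor-allele dosage; the major
#'   allele is the reference.
#' Effects estimated on these designs are allelic substitution effects,
#' i.e. deviations from the reference allele. Columns that are all zero
#' (allele absent from the data) are dropped with a warning.
#'
#' @param marker Marker id (a map position).
#' @param model `"parental"`, `"ancestral"` or `"biallelic"`.
#' @param geno A [marker_data] object.
#' @param crosses Cross table; its `central_parent` attribute (or the
#'   `central` argument) names the reference parent.
#' @param ibd An `ibd_dh` object (required for parental/ancestral).
#' @param classes An `ancestral_classes` object (required for ancestral).
#' @param central Central parent id; defaults to the cross table attribute.
#' @return Object of class `allele_design`: list with `marker`, `model`,
#'   `alleles` (non-reference labels), `X` (individuals x alleles dosage
#'   matrix), `reference`, and for the ancestral model the class membership.
#' @export
build_design <- function(marker, model = c("parental", "ancestral", "biallelic"),
                         geno, crosses, ibd = NULL, classes = NULL,
                         central = attr(crosses, "central_parent")) {
  model <- match.arg(model)
  ids <- intersect(rownames(geno$progeny), crosses$genotype)
  out <- switch(
    model,
    biallelic = {
      x <- geno$progeny[ids, marker]
      if (anyNA(x)) abort("biallelic design requires imputed genotypes")
      p <- mean(x) / 2
      ref <- "major"
      if (p > 0.5) x <- 2 - x                    # code the minor allele
      list(alleles = "minor", X = matrix(x, ncol = 1,
                                         dimnames = list(ids, "minor")),
           reference = "major")
    },
    parental = {
      if (is.null(ibd)) abort("parental design requires ibd")
      if (is.null(central)) abort("central parent undefined")
      Xfull <- parental_dosage(marker, ids, ibd, crosses, central)
      keep <- setdiff(colnames(Xfull), central)
      list(alleles = keep, X = Xfull[, keep, drop = FALSE],
           reference = central)
    },
    ancestral = {
      if (is.null(ibd) || is.null(classes)) {
        abort("ancestral design requires ibd and classes")
      }
      if (is.null(central)) abort("central parent undefined")
      Xfull <- parental_dosage(marker, ids, ibd, crosses, central)
      cl <- classes[colnames(Xfull), marker]
      M <- outer(cl, sort(unique(cl)), "==") * 1   # parents x classes
      labels <- paste0("anc", sort(unique(cl)))
      colnames(M) <- labels
      Xanc <- Xfull %*% M
      ref <- labels[match(cl[central], sort(unique(cl)))]
      keep <- setdiff(labels, ref)
      list(alleles = keep, X = Xanc[, keep, drop = FALSE],
           reference = ref, membership = cl)
    }
  )
  nz <- colSums(abs(out$X)) > 0
  if (!all(nz)) {
    warn(paste0("dropping absent allele column(s) at ", marker, ": ",
                paste(out$alleles[!nz], collapse = ", ")))
    out$X <- out$X[, nz, drop = FALSE]
    out$alleles <- out$alleles[nz]
  }
  structure(c(list(marker = marker, model = model), out),
            class = "allele_design")
}

# full parents x individuals dosage block at one marker (all parents,
# central included), from IBD expected copies
parental_dosage <- function(marker, ids, ibd, crosses, central) {
  parents <- unique(c(central, crosses$parent1, crosses$parent2))
  X <- matrix(0, length(ids), length(parents),
              dimnames = list(ids, parents))
  info <- crosses[match(ids, crosses$genotype), ]
  x1 <- ibd$p1_copies[ids, marker]
  X[cbind(seq_along(ids), match(info$parent1, parents))] <- x1
  X[cbind(seq_along(ids), match(info$parent2, parents))] <-
    X[cbind(seq_along(ids), match(info$parent2, parents))] + (2 - x1)
  X
}

#' @exportS3Method print allele_design
#' @keywords internal
print.allele_design <- function(x, ...) {
  cat("allele_design (", x$model, ") at ", x$marker, ": ",
      ncol(x$X), " allele column(s), reference = ", x$reference, "\n",
      sep = "")
  invisible(x)
}

#' Allele designs at every map position
#'
#' Convenience wrapper building the [build_design()] matrix at each marker,
#' the per-position inputs of a genome scan.
#'
#' @inheritParams build_design
#' @param markers Markers to build (default: all markers in the map).
#' @return Named list of `allele_design` objects, plus the map as an
#'   attribute.
#' @export
qtl_designs <- function(geno, crosses,
                        model = c("parental", "ancestral", "biallelic"),
                        ibd = NULL, classes = NULL, markers = NULL,
                        central = attr(crosses, "central_parent")) {
  model <- match.arg(model)
  markers <- markers %||% geno$map$marker
  out <- lapply(markers, function(mk) {
    build_design(mk, model, geno, crosses, ibd = ibd, classes = classes,
                 central = central)
  })
  names(out) <- markers
  attr(out, "map") <- geno$map
  attr(out, "model") <- model
  out
}
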