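## Readers and writers for the package's plain-CSV input schemas and its
## result files. The schemas are bespoke tabular files (comma separated,
## header row, NA for missing):
##   map:       marker, chromosome, position_cM
##   genotype:  id, parent (TRUE/FALSE), one column per marker (dosage 0/1/2)
##   cross:     individual, cross, parent1, parent2
##   phenotype: genotype, cross, env, rep, block, check, trait
##   covariate: env, covariate, value

#' Read and validate a full set of experiment inputs
#'
#' Loads the map, genotype, cross, phenotype and (optionally) covariate
#' files and enforces cross-file consistency: the map must cover every
#' marker, every phenotyped entry must have genotypes and a cross, parents
#' must be genotyped, and plots must be unique within (genotype,
#' environment, replicate, block). Violations raise an error naming the
#' offending ids.
#'
#' @param map_file,geno_file,cross_file,pheno_file,covariate_file File
#'   paths (covariate optional).
#' @param central_parent Id of the NAM central parent.
#' @return List with `geno` (a [marker_data]), `crosses`, `plots`,
#'   `covariate` (or `NULL`) and `central_parent`.
#' @export
read_mpp_inputs <- function(map_file, geno_file, cross_file, pheno_file,
                            covariate_file = NULL, central_parent) {
  map <- readr::read_csv(map_file, show_col_types = FALSE)
  need_cols(map, c("marker", "chromosome", "position_cM"), "map")
  map <- map |>
    dplyr::transmute(marker = as.character(.data$marker),
                     chr = as.integer(.data$chromosome),
                     pos_cM = as.numeric(.data$position_cM))

  gtab <- readr::read_csv(geno_file, show_col_types = FALSE)
  need_cols(gtab, c("id", "parent"), "genotype")
  markers <- setdiff(names(gtab), c("id", "parent"))
  not_mapped <- setdiff(markers, map$marker)
  if (length(not_mapped)) {
    abort(paste("markers absent from map:",
                paste(head(not_mapped, 10), collapse = ", ")))
  }
  gm <- as.matrix(gtab[markers])
  rownames(gm) <- gtab$id
  progeny <- gm[!gtab$parent, , drop = FALSE]
  parents <- gm[gtab$parent, , drop = FALSE]
  if (!central_parent %in% rownames(parents)) {
    abort(paste("central parent", central_parent, "not among genotyped parents"))
  }
  geno <- marker_data(progeny, parents, map)

  crosses <- readr::read_csv(cross_file, show_col_types = FALSE)
  need_cols(crosses, c("individual", "cross", "parent1", "parent2"), "cross")
  crosses <- dplyr::rename(crosses, genotype = "individual")
  unknown_parent <- setdiff(unique(c(crosses$parent1, crosses$parent2)),
                            rownames(parents))
  if (length(unknown_parent)) {
    abort(paste("cross parents without genotypes:",
                paste(unknown_parent, collapse = ", ")))
  }
  if (anyDuplicated(crosses$genotype)) {
    abort("individuals assigned to more than one cross")
  }
  attr(crosses, "central_parent") <- central_parent

  plots <- readr::read_csv(pheno_file, show_col_types = FALSE)
  need_cols(plots, c("genotype", "cross", "env", "rep", "block", "check",
                     "trait"), "phenotype")
  plots$check <- as.logical(plots$check)
  entries <- unique(plots$genotype[!plots$check])
  no_geno <- setdiff(entries, rownames(progeny))
  if (length(no_geno)) {
    abort(paste("phenotyped entries without genotypes:",
                paste(head(no_geno, 10), collapse = ", ")))
  }
  no_cross <- setdiff(entries, crosses$genotype)
  if (length(no_cross)) {
    abort(paste("phenotyped entries without a cross:",
                paste(head(no_cross, 10), collapse = ", ")))
  }
  key <- paste(plots$genotype, plots$env, plots$rep, plots$block)
  if (anyDuplicated(key)) {
    abort(paste("duplicated plots:",
                paste(head(unique(key[duplicated(key)]), 5), collapse = "; ")))
  }

  covariate <- NULL
  if (!is.null(covariate_file)) {
    covariate <- readr::read_csv(covariate_file, show_col_types = FALSE)
    need_cols(covariate, c("env", "value"), "covariate")
    covariate <- dplyr::transmute(covariate, env = .data$env,
                                  Z = as.numeric(.data$value))
  }
  list(geno = geno, crosses = crosses, plots = plots, covariate = covariate,
       central_parent = central_parent)
}

need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(paste0(what, " file missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  invisible(df)
}

#' Write simulated inputs to the package's CSV schemas
#'
#' Companion to the simulator: dumps a [sim_nam_genotypes()] /
#' [sim_phenotypes()] pair as the map/genotype/cross/phenotype (and
#' optional covariate) files that [read_mpp_inputs()] reads back.
#'
#' @param sim A `nam_sim` object.
#' @param plots Plot table from [sim_phenotypes()].
#' @param dir Output directory (created if needed).
#' @param covariate Optional covariate tibble `env`, `Z`.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_mpp_inputs <- function(sim, plots, dir, covariate = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(map = file.path(dir, "map.csv"),
             geno = file.path(dir, "geno.csv"),
             cross = file.path(dir, "cross.csv"),
             pheno = file.path(dir, "pheno.csv"))
  readr::write_csv(
    dplyr::transmute(sim$geno$map, marker = .data$marker,
                     chromosome = .data$chr, position_cM = .data$pos_cM),
    paths["map"])
  gtab <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(sim$geno$progeny, rownames = "id"),
                  parent = FALSE, .after = "id"),
    dplyr::mutate(as_tibble(sim$geno$parents, rownames = "id"),
                  parent = TRUE, .after = "id"))
  readr::write_csv(gtab, paths["geno"])
  readr::write_csv(dplyr::rename(sim$crosses, individual = "genotype"),
                   paths["cross"])
  readr::write_csv(plots, paths["pheno"])
  if (!is.null(covariate)) {
    paths["covariate"] <- file.path(dir, "covariate.csv")
    readr::write_csv(
      dplyr::transmute(covariate, env = .data$env, covariate = "index",
                       value = .data$Z),
      paths["covariate"])
  }
  invisible(paths)
}

#' Write / read a scan profile
#'
#' Profiles round-trip through CSV with the method and allele model stored
#' as columns, so `read_scan_profile(write_scan_profile(x))` reproduces the
#' profile exactly.
#'
#' @param profile A `scan_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan_profile <- function(profile, path) {
  out <- as_tibble(profile) |>
    dplyr::mutate(method = attr(profile, "method"),
                  allele_model = attr(profile, "allele_model"))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_scan_profile
#' @export
read_scan_profile <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  method <- df$method[1]
  model <- df$allele_model[1]
  new_scan_profile(dplyr::select(df, -"method", -"allele_model"),
                   method, model)
}

#' Serialise a fitted QTL model to JSON
#'
#' @param model A `qtl_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qtl_model <- function(model, path) {
  jsonlite::write_json(list(
    method = model$method, allele_model = model$allele_model,
    qtl = model$qtl, effects = model$effects,
    varcomp = if (!is.null(model$fit)) as.list(model$fit$varcomp),
    loglik = if (!is.null(model$fit)) model$fit$loglik
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration, seed and package version needed to reproduce
#' a run exactly.
#'
#' @param path Output path.
#' @param config Named list of run settings (must include `seed` when the
#'   run used randomness).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config) {
  jsonlite::write_json(list(
    package = "mppme",
    version = as.character(utils::packageVersion("mppme")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
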