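# Marker QC, imputation, IBD probabilities and allele design matrices.

test_that("qc_markers applies the MAF and missingness thresholds", {
  # marker A: MAF 1/16 = 0.0625 from 8 calls, 2/10 missing
  # marker B: MAF 0.04, complete; marker C: MAF 0.5, complete
  gA <- c(0, 0, 0, 0, 0, 0, 0, 1, NA, NA)
  gB <- c(rep(0, 46), rep(2, 2), 2, 1)[1:10]        # hand-set below instead
  gB <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1)             # MAF 1/20 = 0.05
  gC <- c(rep(0, 5), rep(2, 5))                     # MAF 0.5
  gD <- c(rep(0, 9), 1)                             # MAF 1/20 = 0.05
  progeny <- cbind(mA = gA, mB = gB, mC = gC, mD = gD)
  rownames(progeny) <- sprintf("i%02d", 1:10)
  parents <- rbind(P0 = c(0, 0, 0, 0), P1 = c(2, 2, 2, 2))
  colnames(parents) <- colnames(progeny)
  md <- toy_marker_data(progeny, parents)

  st <- marker_stats(md)
  expect_equal(st$maf, c(1 / 16, 0.05, 0.5, 0.05))
  expect_equal(st$miss, c(0.2, 0, 0, 0))

  kept <- qc_markers(md, maf_min = 0.05, miss_max = 0.10)
  expect_equal(kept$map$marker, c("mB", "mC", "mD"))  # mA: too much missing
  # mA survives once the missingness cap is relaxed (MAF 0.0625 >= 0.05)
  expect_true("mA" %in% qc_markers(md, 0.05, 0.25)$map$marker)
  # below-threshold MAF is dropped
  expect_false("mB" %in% qc_markers(md, 0.051, 0.25)$map$marker)
  low <- toy_marker_data(progeny[, c("mB", "mD")],
                         parents[, c("mB", "mD")])
  expect_error(qc_markers(low, 0.10, 0.5), "no markers survive")
})

test_that("qc_markers is idempotent and monotone in the MAF threshold", {
  set.seed(7)
  progeny <- matrix(sample(c(0, 2, NA), 400, replace = TRUE,
                           prob = c(0.6, 0.3, 0.1)), 20, 20)
  rownames(progeny) <- sprintf("i%02d", 1:20)
  parents <- matrix(0, 2, 20, dimnames = list(c("P0", "P1"), NULL))
  md <- toy_marker_data(progeny, parents)
  once <- qc_markers(md, 0.1, 0.2)
  twice <- qc_markers(once, 0.1, 0.2)
  expect_identical(once$map, twice$map)
  expect_identical(once$progeny, twice$progeny)
  counts <- vapply(c(0.05, 0.1, 0.2, 0.3), function(m) {
    ncol(tryCatch(qc_markers(md, m, 0.2)$progeny,
                  error = function(e) matrix(nrow = 0, ncol = 0)))
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("dedupe_positions keeps the most polymorphic co-located marker", {
  progeny <- cbind(
    a1 = c(rep(0, 9), 2),                 # MAF 0.1
    a2 = c(rep(0, 7), rep(2, 3)),         # MAF 0.3
    b1 = c(rep(0, 8), 2, 2),              # MAF 0.2
    b2 = c(rep(0, 8), 2, 2),              # MAF 0.2 (tie, later in map)
    b3 = c(rep(0, 6), rep(2, 4)),         # MAF 0.4
    c1 = c(rep(0, 5), rep(2, 5))
  )
  rownames(progeny) <- sprintf("i%02d", 1:10)
  parents <- matrix(0, 2, 6, dimnames = list(c("P0", "P1"), NULL))
  md <- toy_marker_data(progeny, parents,
                        chr = c(1, 1, 1, 1, 1, 2),
                        pos = c(10, 10, 30, 30, 30, 5))
  dd <- dedupe_positions(md)
  expect_equal(dd$map$marker, c("a2", "b3", "c1"))
  # no co-location: unchanged
  md2 <- toy_marker_data(progeny[, c(1, 3)],
                         parents[, c(1, 3)], chr = c(1, 1), pos = c(0, 10))
  expect_identical(dedupe_positions(md2)$map$marker, c("a1", "b1"))
  # equal MAF ties keep the first in map order
  md3 <- toy_marker_data(progeny[, c(3, 4)], parents[, c(3, 4)],
                         chr = c(1, 1), pos = c(30, 30))
  expect_equal(dedupe_positions(md3)$map$marker, "b1")
})

test_that("random imputation is seed-reproducible and frequency-matched", {
  crosses <- tibble::tibble(genotype = sprintf("i%05d", 1:10100),
                            cross = "C01")
  obs <- c(rep(0, 50), rep(2, 50))                 # 50/50 within the cross
  progeny <- matrix(c(obs, rep(NA_real_, 10000)), ncol = 1)
  rownames(progeny) <- crosses$genotype
  colnames(progeny) <- "m01"
  parents <- matrix(c(0, 2), 2, 1, dimnames = list(c("P0", "P1"), "m01"))
  md <- toy_marker_data(progeny, parents)

  a <- impute_biallelic(md, crosses, seed = 11)
  b <- impute_biallelic(md, crosses, seed = 11)
  expect_identical(a$progeny, b$progeny)
  expect_false(anyNA(a$progeny))
  frac <- mean(a$progeny[101:10100, 1]) / 2
  expect_lt(abs(frac - 0.5), 0.02)                 # law of large numbers
  # complete data returned unchanged
  expect_identical(impute_biallelic(a, crosses, seed = 1)$progeny, a$progeny)
})

test_that("DH identity-by-descent posteriors match brute-force enumeration", {
  # 6 markers: informative at 1, 3, 4, 6; parents identical at 2 and 5
  pos <- c(0, 5, 20, 40, 41, 60)
  p0 <- c(0, 0, 0, 0, 2, 0)
  p1 <- c(2, 0, 2, 2, 2, 2)
  obs_sets <- list(
    c(0, 0, 2, 0, 2, 2),       # switches origin twice
    c(0, 0, 0, 0, 2, 0),       # all parent-1 origin where informative
    c(2, NA, 2, NA, 2, 0),     # missing calls at two markers
    c(1, 0, 2, 2, 2, 2)        # residual het treated as missing
  )
  progeny <- do.call(rbind, obs_sets)
  rownames(progeny) <- sprintf("i%02d", seq_along(obs_sets))
  parents <- rbind(P0 = p0, P1 = p1)
  colnames(parents) <- sprintf("m%02d", 1:6)
  md <- toy_marker_data(progeny, parents, pos = pos)
  crosses <- tibble::tibble(genotype = rownames(progeny), cross = "C01",
                            parent1 = "P0", parent2 = "P1")
  ibd <- compute_ibd_dh(md, crosses)

  r <- haldane_r(diff(pos))
  informative <- p0 != p1
  for (k in seq_along(obs_sets)) {
    obs <- obs_sets[[k]]
    obs[!is.na(obs) & obs == 1] <- NA
    emit <- matrix(1, 6, 2)
    use <- informative & !is.na(obs)
    emit[use, 1] <- as.numeric(obs[use] == p0[use])
    emit[use, 2] <- as.numeric(obs[use] == p1[use])
    expected <- 2 * bf_origin_posterior(emit, r)[, 1]
    expect_equal(unname(ibd$p1_copies[k, ]), expected, tolerance = 1e-10)
  }
})

test_that("IBD handles fully informative, mid-interval and flat cases", {
  # fully informative flanking markers 1 cM apart, progeny matches parent 1
  md <- toy_marker_data(
    progeny = matrix(c(0, 0), 1, 2, dimnames = list("i01", NULL)),
    parents = rbind(P0 = c(0, 0), P1 = c(2, 2)), pos = c(0, 1))
  crosses <- tibble::tibble(genotype = "i01", cross = "C01",
                            parent1 = "P0", parent2 = "P1")
  expect_equal(unname(compute_ibd_dh(md, crosses)$p1_copies[1, ]), c(2, 2))

  # uninformative chromosome: flat posterior, one copy from each parent
  md2 <- toy_marker_data(
    progeny = matrix(c(0, 0), 1, 2, dimnames = list("i01", NULL)),
    parents = rbind(P0 = c(0, 0), P1 = c(0, 0)), pos = c(0, 10))
  expect_warning(ibd2 <- compute_ibd_dh(md2, crosses), "flat")
  expect_equal(unname(ibd2$p1_copies[1, ]), c(1, 1))

  # position midway between discordant informative markers 20 cM apart:
  # symmetric, posterior 1/2 each, checked against the enumeration oracle
  pos <- c(0, 10, 20)
  md3 <- toy_marker_data(
    progeny = matrix(c(0, 0, 2), 1, 3, dimnames = list("i01", NULL)),
    parents = rbind(P0 = c(0, 0, 0), P1 = c(2, 0, 2)), pos = pos)
  x <- compute_ibd_dh(md3, crosses)$p1_copies[1, ]
  emit <- rbind(c(1, 0), c(1, 1), c(0, 1))
  oracle <- 2 * bf_origin_posterior(emit, haldane_r(diff(pos)))[, 1]
  expect_equal(unname(x), oracle, tolerance = 1e-10)
  expect_equal(unname(x[2]), 1)                  # symmetry
})

test_that("IBD dosages of the two parents always sum to two", {
  fx <- toy_nam(seed = 5, n_markers = 6, n_per_cross = 20)
  ibd <- compute_ibd_dh(fx$sim$geno, fx$sim$crosses)
  x1 <- ibd$p1_copies
  expect_true(all(abs((x1 + (2 - x1)) - 2) < 1e-8))
  expect_true(all(x1 >= 0 & x1 <= 2))
})

test_that("ancestral clustering reproduces hand single-linkage partitions", {
  # 5 markers within a +/-25 cM window; similarities by hand:
  # P1~P2 = 1, P1~P3 = 0.8, P4 far from everyone
  scores <- rbind(
    P0 = c(0, 0, 0, 0, 0),
    P1 = c(0, 0, 0, 0, 0),
    P2 = c(0, 0, 0, 0, 2),
    P3 = c(2, 2, 2, 2, 2)
  )
  colnames(scores) <- sprintf("m%02d", 1:5)
  md <- toy_marker_data(matrix(0, 1, 5, dimnames = list("i01", NULL)),
                        scores, pos = seq(0, 40, by = 10))
  cl <- cluster_ancestral(md, window = 50, threshold = 0.8)
  k <- cl[, 3]
  expect_equal(unname(k[c("P0", "P1")]), c(1L, 1L))
  expect_equal(unname(k["P2"]), 1L)              # joins via similarity 0.8
  expect_equal(unname(k["P3"]), 2L)
  # threshold 1 keeps only exact duplicates together
  k1 <- cluster_ancestral(md, window = 50, threshold = 1)[, 3]
  expect_equal(length(unique(k1)), 3)
  expect_equal(unname(k1["P0"]), unname(k1["P1"]))
  # identical parents share a class everywhere at any window
  expect_true(all(cluster_ancestral(md, window = 2)[c("P0", "P1"), 1] == 1L))
})

test_that("allele designs satisfy the coding contracts", {
  fx <- toy_nam(seed = 9, n_markers = 6, n_peripheral = 3, n_per_cross = 25)
  geno <- fx$sim$geno
  crosses <- fx$sim$crosses
  ibd <- compute_ibd_dh(geno, crosses)
  st <- marker_stats(geno)
  mk <- st$marker[which(st$maf > 0.2)[1]]       # a clearly polymorphic marker

  # biallelic: single column equal to the minor-allele dosage
  db <- build_design(mk, "biallelic", geno, crosses)
  x <- geno$progeny[rownames(db$X), mk]
  if (mean(x) / 2 > 0.5) x <- 2 - x
  expect_equal(unname(db$X[, 1]), unname(x))
  expect_equal(db$reference, "major")

  # parental: one column per peripheral parent; rows sum to 2 minus the
  # central-parent copies
  dp <- build_design(mk, "parental", geno, crosses, ibd = ibd)
  expect_setequal(dp$alleles, c("P1", "P2", "P3"))
  expect_equal(unname(rowSums(dp$X)),
               unname(2 - ibd$p1_copies[rownames(dp$X), mk]),
               tolerance = 1e-8)

  # ancestral equals parental post-multiplied by class membership
  cls <- cluster_ancestral(geno, window = 30, threshold = 0.8)
  da <- build_design(mk, "ancestral", geno, crosses, ibd = ibd,
                     classes = cls)
  membership <- da$membership
  parents <- c("P0", dp$alleles)
  full <- matrix(0, nrow(dp$X), length(parents),
                 dimnames = list(rownames(dp$X), parents))
  full[, "P0"] <- ibd$p1_copies[rownames(dp$X), mk]
  full[, dp$alleles] <- dp$X
  for (cl_lab in da$alleles) {
    cl_id <- as.integer(sub("anc", "", cl_lab))
    members <- names(membership)[membership == cl_id]
    expect_equal(unname(da$X[, cl_lab]),
                 unname(rowSums(full[, members, drop = FALSE])),
                 tolerance = 1e-10)
  }
  # reference class contains the central parent and is excluded
  ref_id <- as.integer(sub("anc", "", da$reference))
  expect_equal(unname(membership["P0"]), ref_id)
  expect_false(da$reference %in% colnames(da$X))

  # degenerate merge: all peripheral parents in one non-central class
  nm <- ncol(geno$progeny)
  scores <- rbind(P0 = rep(0, nm), P1 = rep(2, nm), P2 = rep(2, nm),
                  P3 = rep(2, nm))
  colnames(scores) <- geno$map$marker
  geno2 <- marker_data(geno$progeny, scores, geno$map)
  cls2 <- cluster_ancestral(geno2, window = 30, threshold = 0.8)
  da2 <- build_design(mk, "ancestral", geno2, crosses, ibd = ibd,
                      classes = cls2)
  expect_equal(ncol(da2$X), 1)
})
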