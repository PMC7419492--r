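# Genome-scan orchestration: greedy selections, CIM conditioning, backward
# elimination and cross-method consolidation.

mk_profile <- function(chr, pos, v, env = NULL) {
  df <- tibble::tibble(marker = sprintf("x%02d", seq_along(pos)),
                       chr = chr, pos_cM = pos, neglog10p = v)
  if (!is.null(env)) df$env <- env
  mppme:::new_scan_profile(df, "M1", "biallelic")
}

test_that("greedy peak selection follows the hand-traced rule", {
  # all below threshold: empty
  p0 <- mk_profile(1, c(10, 30, 90), c(1, 2, 3.9))
  expect_equal(nrow(select_cofactors(p0, threshold = 4, min_dist = 50)), 0)

  # highest first, then exclusion within 50 cM on the chromosome
  p1 <- mk_profile(1, c(10, 30, 90), c(5, 6, 4.5))
  sel <- select_cofactors(p1, threshold = 4, min_dist = 50)
  expect_equal(sel$pos_cM, c(30, 90))

  # exclusion is per chromosome: same positions on another chromosome stay
  p2 <- mk_profile(c(1, 1, 2), c(10, 30, 35), c(5, 6, 4.5))
  expect_equal(select_cofactors(p2, 4, 50)$pos_cM, c(30, 35))

  # NA positions are ignored
  p3 <- mk_profile(1, c(10, 60), c(NA, 5))
  expect_equal(select_cofactors(p3, 4, 50)$pos_cM, 60)

  # ties go to the smallest chromosome, then the smallest position: a
  # 30 cM plateau of equal values keeps only its leftmost point at 20 cM
  p4 <- mk_profile(1, c(0, 10, 20, 30), c(2, 5, 5, 5))
  expect_equal(select_qtls(p4, 4, 20)$pos_cM, c(10, 30))
  p5 <- mk_profile(c(2, 1), c(5, 80), c(5, 5))
  first <- select_qtls(p5, 4, 20)
  expect_equal(first$chr, c(1, 2))              # both kept, chr 1 first
})

test_that("three admissible peaks match the hand trace at 20 cM spacing", {
  p <- mk_profile(1, c(0, 15, 40, 55, 90), c(4.2, 6, 5, 4.5, 4.1))
  # greedy: take 15 (6.0), drop 0; take 40 (5.0), drop 55; take 90
  expect_equal(select_qtls(p, 4, 20)$pos_cM, c(15, 40, 90))
})

test_that("per-environment profiles are selected separately", {
  p <- mk_profile(c(1, 1, 1, 1), c(10, 30, 10, 30), c(5, 4.5, 2, 6),
                  env = c("E1", "E1", "E2", "E2"))
  sel <- select_cofactors(p, 4, 50)
  expect_equal(sel$env, c("E1", "E2"))
  expect_equal(sel$pos_cM, c(10, 30))
})

test_that("consolidation clusters positions by single linkage", {
  pos <- tibble::tibble(method = c("M1", "M3", "M1", "M4", "M2"),
                        chr = c(10, 10, 10, 2, 2),
                        pos_cM = c(45.0, 45.2, 60, 5, 17))
  cc <- consolidate_qtls(pos, merge_dist = 10)
  ids <- cc$qtl_id[order(cc$method, cc$pos_cM)]
  expect_equal(cc$qtl_id[cc$pos_cM == 45.0], cc$qtl_id[cc$pos_cM == 45.2])
  expect_false(cc$qtl_id[cc$pos_cM == 60] %in%
                 cc$qtl_id[cc$pos_cM %in% c(45, 45.2)])
  # 12 cM apart: two clusters
  expect_equal(length(unique(cc$qtl_id[cc$chr == 2])), 2)
  # chaining: 0, 8, 16 collapses into one cluster under single linkage
  chain <- tibble::tibble(method = "M1", chr = 1, pos_cM = c(0, 8, 16))
  expect_equal(length(unique(consolidate_qtls(chain, 10)$qtl_id)), 1)
})

test_that("M2 scans return one profile per environment and M3 reduces to M2
           with a single environment", {
  fx <- toy_nam(seed = 101, n_chr = 1, n_markers = 5, n_peripheral = 2,
                n_per_cross = 40,
                qtl = env2_qtl("c1_m03", c("P1", "P2"), beta = -2.5))
  geno <- impute_biallelic(fx$sim$geno, fx$sim$crosses, seed = 1)
  designs <- qtl_designs(geno, fx$sim$crosses, "biallelic")
  bl <- fit_blues_within(fx$ph$plots)

  p2 <- sim_scan(bl, designs, "M2", reltol = 1e-12)
  expect_setequal(unique(p2$env), c("E1", "E2"))
  expect_equal(nrow(p2), 10)

  one_env <- dplyr::filter(bl, env == "E1")
  p2a <- sim_scan(one_env, designs, "M2", reltol = 1e-12)
  p3a <- sim_scan(one_env, designs, "M3", reltol = 1e-12)
  expect_equal(p3a$neglog10p, p2a$neglog10p, tolerance = 1e-6)
})

test_that("CIM conditions on cofactors outside the exclusion window", {
  fx <- toy_nam(seed = 103, n_chr = 2, n_markers = 5, n_peripheral = 2,
                n_per_cross = 50,
                qtl = tibble::tibble(marker = "c1_m02",
                                     parent = c("P1", "P2"),
                                     beta = -2))
  geno <- impute_biallelic(fx$sim$geno, fx$sim$crosses, seed = 1)
  designs <- qtl_designs(geno, fx$sim$crosses, "biallelic")
  bl <- fit_blues_joint(fx$ph$plots)
  simp <- sim_scan(bl, designs, "M1")
  cof <- simp[simp$marker == "c1_m02", ]
  cimp <- cim_scan(bl, designs, "M1", cofactors = cof, exclusion = 50)
  # within the exclusion window the cofactor drops out: SIM values return
  near <- abs(simp$pos_cM - cof$pos_cM) < 50 & simp$chr == cof$chr
  expect_equal(cimp$neglog10p[near], simp$neglog10p[near], tolerance = 1e-4)
  # outside the window the model conditions on the cofactor, changing the
  # profile (here: the other chromosome loses the QTL's confounding signal)
  expect_false(isTRUE(all.equal(cimp$neglog10p[!near],
                                simp$neglog10p[!near], tolerance = 1e-4)))
})

test_that("backward elimination keeps significant QTLs and drops noise", {
  fx <- toy_nam(seed = 105, n_chr = 2, n_markers = 5, n_peripheral = 3,
                n_per_cross = 50,
                qtl = tibble::tibble(marker = "c1_m03",
                                     parent = c("P1", "P2", "P3"),
                                     beta = -2))
  geno <- impute_biallelic(fx$sim$geno, fx$sim$crosses, seed = 1)
  ibd <- compute_ibd_dh(geno, fx$sim$crosses)
  designs <- qtl_designs(geno, fx$sim$crosses, "parental", ibd = ibd)
  bl <- fit_blues_joint(fx$ph$plots)

  qm <- backward_elimination(bl, designs, c("c1_m03", "c2_m03"), "M1",
                             threshold = 4)
  expect_s3_class(qm, "qtl_model")
  expect_equal(qm$qtl$marker, "c1_m03")          # noise candidate dropped
  expect_true(all(qm$qtl$neglog10p >= 4))
  eff <- tidy(qm)
  expect_setequal(eff$allele, c("P1", "P2", "P3"))
  expect_true(all(is.na(eff$env)))               # M1: main effects only
  # estimates consistent with the planted -2 given their standard errors
  expect_lt(max(abs(eff$estimate + 2) / eff$std.error), 4)

  # single candidate below threshold: empty model with a warning
  expect_warning(
    empty <- backward_elimination(bl, designs, "c2_m05", "M1", threshold = 4),
    "empty")
  expect_equal(nrow(empty$qtl), 0)
  expect_equal(nrow(glance(empty)), 1)
})

test_that("noise candidates are eliminated before a real QTL", {
  drops <- vapply(1:8, function(i) {
    fx <- toy_nam(seed = 200 + i, n_chr = 2, n_markers = 8,
                  n_peripheral = 2, n_per_cross = 50,
                  qtl = tibble::tibble(marker = "c1_m04",
                                       parent = c("P1", "P2"), beta = -3))
    ibd <- compute_ibd_dh(fx$sim$geno, fx$sim$crosses)
    designs <- qtl_designs(fx$sim$geno, fx$sim$crosses, "parental",
                           ibd = ibd)
    bl <- fit_blues_joint(fx$ph$plots)
    qm <- backward_elimination(bl, designs, c("c1_m04", "c2_m05"), "M1",
                               threshold = 4)
    identical(qm$qtl$marker, "c1_m04")
  }, TRUE)
  expect_gte(sum(drops), 7)
})

test_that("null scans rarely exceed the detection threshold", {
  hits <- 0L; total <- 0L
  for (i in 1:4) {
    fx <- toy_nam(seed = 300 + i, n_chr = 2, n_markers = 10,
                  n_peripheral = 2, n_per_cross = 60, qtl = NULL)
    geno <- impute_biallelic(fx$sim$geno, fx$sim$crosses, seed = 1)
    designs <- qtl_designs(geno, fx$sim$crosses, "biallelic")
    bl <- fit_blues_joint(fx$ph$plots)
    prof <- sim_scan(bl, designs, "M1")
    hits <- hits + sum(prof$neglog10p >= 4, na.rm = TRUE)
    total <- total + sum(!is.na(prof$neglog10p))
  }
  expect_gte(total, 55)      # monomorphic positions come back as NA
  expect_lte(hits, 2)        # nominal rate 1e-4 per position under the null
})

test_that("the scan peak localises a strong simulated QTL", {
  found <- vapply(1:6, function(i) {
    fx <- toy_nam(seed = 400 + i, n_chr = 1, n_markers = 11, length_cM = 90,
                  n_peripheral = 3, n_per_cross = 60,
                  qtl = tibble::tibble(marker = "c1_m06",
                                       parent = c("P1", "P2", "P3"),
                                       beta = -1.6))
    ibd <- compute_ibd_dh(fx$sim$geno, fx$sim$crosses)
    designs <- qtl_designs(fx$sim$geno, fx$sim$crosses, "parental", ibd = ibd)
    bl <- fit_blues_joint(fx$ph$plots)
    prof <- sim_scan(bl, designs, "M1")
    peak <- prof[which.max(prof$neglog10p), ]
    abs(peak$pos_cM - fx$map$pos_cM[fx$map$marker == "c1_m06"]) <= 10
  }, TRUE)
  expect_gte(sum(found), 5)
})

test_that("one-stage and two-stage joint scans agree on a balanced toy", {
  fx <- toy_nam(seed = 501, n_chr = 1, n_markers = 6, n_peripheral = 2,
                n_per_cross = 50,
                qtl = env2_qtl("c1_m03", c("P1", "P2"), beta = -3),
                sigma2_rep = 0, sigma2_block = 0, p_rep = 1, n_checks = 0)
  ibd <- compute_ibd_dh(fx$sim$geno, fx$sim$crosses)
  designs <- qtl_designs(fx$sim$geno, fx$sim$crosses, "parental", ibd = ibd)
  bl <- fit_blues_within(fx$ph$plots)
  p3 <- sim_scan(bl, designs, "M3")
  p4 <- sim_scan(fx$ph$plots, designs, "M4")
  expect_gt(cor(p3$neglog10p, p4$neglog10p), 0.99)
  expect_equal(which.max(p3$neglog10p), which.max(p4$neglog10p))
})
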