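# Shared fixtures, built in code at test time.

# marker_data from explicit matrices and positions
toy_marker_data <- function(progeny, parents, chr = NULL, pos = NULL) {
  m <- ncol(progeny)
  if (is.null(colnames(progeny))) {
    colnames(progeny) <- sprintf("m%02d", seq_len(m))
  }
  colnames(parents) <- colnames(progeny)
  if (is.null(rownames(progeny))) {
    rownames(progeny) <- sprintf("i%02d", seq_len(nrow(progeny)))
  }
  if (is.null(rownames(parents))) {
    rownames(parents) <- sprintf("P%d", seq_len(nrow(parents)) - 1)
  }
  map <- tibble::tibble(
    marker = colnames(progeny),
    chr = chr %||% rep(1L, m),
    pos_cM = pos %||% seq(0, by = 10, length.out = m)
  )
  marker_data(progeny, parents, map)
}

# a small simulated NAM experiment reused by several suites
toy_nam <- function(seed = 42, n_chr = 2, n_markers = 8, length_cM = 100,
                    n_peripheral = 3, n_per_cross = 60, qtl = NULL,
                    n_env = 2, ...) {
  set.seed(seed)
  map <- sim_map(n_chr = n_chr, length_cM = length_cM, n_markers = n_markers)
  sim <- sim_nam_genotypes(map, n_peripheral = n_peripheral,
                           n_per_cross = n_per_cross)
  ph <- sim_phenotypes(sim, qtl = qtl, n_env = n_env, ...)
  list(map = map, sim = sim, ph = ph)
}

# env-specific QTL truth: effect `beta` for every peripheral allele in env2
env2_qtl <- function(marker, parents, beta = -3, envs = c("E1", "E2")) {
  tibble::tibble(
    marker = marker,
    parent = rep(parents, length(envs)),
    env = rep(envs, each = length(parents)),
    beta = rep(c(0, beta), each = length(parents))
  )
}

# brute-force posterior of the 2-state origin chain: enumerate every origin
# path, weight by 1/2 * prod(transitions) * prod(emissions)
bf_origin_posterior <- function(emit, r) {
  m <- nrow(emit)
  paths <- as.matrix(expand.grid(rep(list(1:2), m)))
  w <- apply(paths, 1, function(s) {
    pr <- 0.5 * emit[1, s[1]]
    for (j in seq_len(m - 1)) {
      stay <- s[j] == s[j + 1]
      pr <- pr * (if (stay) 1 - r[j] else r[j]) * emit[j + 1, s[j + 1]]
    }
    pr
  })
  post <- matrix(0, m, 2)
  for (j in seq_len(m)) {
    for (s in 1:2) post[j, s] <- sum(w[paths[, j] == s])
  }
  post / rowSums(post)
}
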