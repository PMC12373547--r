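# Shared fixtures, built in code.

# Small genotype matrix of homozygous codes with given dimensions.
random_geno <- function(n, m, seed = 1, miss = 0) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  M <- sapply(p, function(pp) rbinom(n, 1, pp) * 2)
  dimnames(M) <- list(sprintf("L%03d", seq_len(n)),
                      sprintf("M%03d", seq_len(m)))
  if (miss > 0) M[runif(length(M)) < miss] <- NA
  geno_matrix(M)
}

# Map covering the markers of random_geno(), spread over `n_chrom`
# chromosomes round-robin.
map_for <- function(G, n_chrom = 6) {
  m <- colnames(unclass(G))
  chroms <- paste0(rep(1:7, length.out = n_chrom),
                   rep(c("A", "B", "D"), length.out = n_chrom))
  data.frame(marker_id = m,
             chromosome = rep(chroms, length.out = length(m)),
             subgenome = substring(rep(chroms, length.out = length(m)), 2),
             position = seq_along(m),
             stringsAsFactors = FALSE)
}

# Discrete-generation Wright-Fisher population of diploids with free
# recombination between loci: the independent oracle for the LD-based Ne
# estimator. Returns a dosage geno_matrix after `n_gen` generations.
simulate_wf_population <- function(ne = 50, n_loci = 300, n_gen = 100,
                                   seed = 1) {
  set.seed(seed)
  h1 <- matrix(rbinom(ne * n_loci, 1, 0.5), ne)
  h2 <- matrix(rbinom(ne * n_loci, 1, 0.5), ne)
  for (g in seq_len(n_gen)) {
    p1 <- sample.int(ne, ne, replace = TRUE)
    p2 <- sample.int(ne, ne, replace = TRUE)
    pick1 <- matrix(runif(ne * n_loci) < 0.5, ne)
    pick2 <- matrix(runif(ne * n_loci) < 0.5, ne)
    nh1 <- ifelse(pick1, h1[p1, ], h2[p1, ])
    nh2 <- ifelse(pick2, h1[p2, ], h2[p2, ])
    h1 <- nh1
    h2 <- nh2
  }
  M <- h1 + h2
  dimnames(M) <- list(sprintf("I%03d", seq_len(ne)),
                      sprintf("W%03d", seq_len(n_loci)))
  geno_matrix(M)
}

# Closed-form ridge regression on centered markers: the independent oracle
# for the GBLUP / RR-BLUP equivalence. Markers are centered with the
# all-line frequencies (as the VanRaden kernel is); `resid` is y minus the
# model intercept on the training rows. Returns genetic values for all
# lines.
ridge_genetic_values <- function(M, resid, train, lambda) {
  Z <- sweep(M, 2, colMeans(M))
  Zt <- Z[train, , drop = FALSE]
  beta <- solve(crossprod(Zt) + diag(lambda, ncol(Z)), crossprod(Zt, resid))
  drop(Z %*% beta)
}
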