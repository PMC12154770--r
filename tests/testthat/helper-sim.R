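# shared fixture builders (all generated in code; no stored data)

small_panel <- function(n_acc = 30, n_snps = 400, seed = 42, ...) {
  generate_founder_panel(n_acc, n_snps, n_chroms = 2, seed = seed, ...)
}

# panel with an exactly known genotype matrix (no randomness)
toy_panel <- function() {
  G <- rbind(acc1 = c(0, 0, 1, 1, 0, 1),
             acc2 = c(1, 0, 0, 1, 1, 0),
             acc3 = c(0, 1, 1, 0, 1, 1))
  founder_panel(G, snp_chrom = rep("chr1", 6), snp_pos = 1:6 * 10,
                z_origin = cbind(bio1 = c(5, 10, 15)))
}

# two-garden local-adaptation experiment used by several modules
run_two_garden_sim <- function(panel, v_s_inv = 0.08, capacity = 200,
                               n_reps = 3, n_gen = 1, seed = 7) {
  params <- sim_params(W_max = 1, V_s_inv = v_s_inv,
                       carrying_capacity = capacity, seed = seed)
  gardens <- list(garden_design("hot", c(bio1 = 16), n_replicates = n_reps,
                                n_generations = n_gen),
                  garden_design("cold", c(bio1 = -1), n_replicates = n_reps,
                                n_generations = n_gen))
  simulate_experiment(panel, gardens, params, seed = seed)
}

# exhaustive Kendall permutation p for small n (independent oracle)
kendall_perm_oracle <- function(x, y) {
  taus <- apply(gtools_permutations(length(y)), 1,
                function(ix) stats::cor(x, y[ix], method = "kendall"))
  t_obs <- stats::cor(x, y, method = "kendall")
  list(tau = t_obs, p = mean(abs(taus) >= abs(t_obs) - 1e-12))
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

# Dirichlet draw for test mixtures
rdirichlet_test <- function(alpha) {
  g <- rgamma(length(alpha), alpha, 1)
  g / sum(g)
}

clip_test <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# multi-garden local-adaptation experiment summarised the way the
# forecasting module consumes it
loo_sim_fixture <- function(n_acc = 30, n_snps = 300, n_gardens = 8,
                            n_reps = 3, v_s_inv = 0.1, capacity = 200,
                            seed = 1, z_range = c(0, 16)) {
  panel <- generate_founder_panel(n_acc, n_snps, n_chroms = 2,
                                  climate_span = list(bio1 = z_range),
                                  seed = seed)
  climates <- seq(z_range[1], z_range[2], length.out = n_gardens)
  gardens <- lapply(seq_len(n_gardens), function(i)
    garden_design(paste0("g", i), c(bio1 = climates[i]),
                  n_replicates = n_reps, n_generations = 1))
  params <- sim_params(W_max = 1, V_s_inv = v_s_inv,
                       carrying_capacity = capacity, seed = seed)
  traj <- simulate_experiment(panel, gardens, params, seed = seed + 1)
  acc_f0 <- lapply(traj$acc_freq, function(g)
    do.call(rbind, lapply(g, function(m) m[1, ])))
  acc_f1 <- lapply(traj$acc_freq, function(g)
    do.call(rbind, lapply(g, function(m) m[2, ])))
  p1_garden <- do.call(rbind, lapply(traj$allele_freq, function(g)
    colMeans(do.call(rbind, lapply(g, function(m) m[2, ])))))
  list(panel = panel, climates = climates, acc_f0 = unname(acc_f0),
       acc_f1 = unname(acc_f1), p1_garden = unname(p1_garden),
       traj = traj)
}

# one self-null draw of observed frequency change, independent per SNP:
# each SNP gets its own multinomial founding of N plants and its own
# without-replacement thinning of the seed pool (uniform seed set)
selfnull_observed_delta <- function(panel, N, fecundity = 10) {
  G <- panel$genotypes
  n_snp <- ncol(G)
  C <- rmultinom(n_snp, N, panel$start_freq)      # accessions x SNP
  C2 <- apply(C, 2, function(cnt) {
    pool <- rep(seq_along(cnt), cnt * fecundity)
    tabulate(pool[sample.int(length(pool), N)], nbins = length(cnt))
  })
  p0 <- as.numeric(crossprod(panel$start_freq, G))
  colSums(C2 * G) / N - p0
}
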