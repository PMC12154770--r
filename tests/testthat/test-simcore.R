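test_that("generated founder panels satisfy their invariants", {
  panel <- generate_founder_panel(231, 300, n_chroms = 3, seed = 11)
  # near-equal seed mix targeting 1/231 per accession
  expect_equal(sum(panel$start_freq), 1, tolerance = 1e-12)
  expect_true(all(abs(panel$start_freq - 1 / 231) < 0.005))
  expect_true(all(panel$genotypes %in% c(0, 1)))
  for (ch in unique(panel$snp_chrom)) {
    expect_true(all(diff(panel$snp_pos[panel$snp_chrom == ch]) > 0))
  }
  expect_error(generate_founder_panel(0, 10), "positive")
  expect_error(generate_founder_panel(10, 2, n_chroms = 5), "n_chroms")
})

test_that("ld_decay controls adjacent-SNP founder correlation", {
  indep <- generate_founder_panel(80, 600, ld_decay = 0, seed = 3)
  linked <- generate_founder_panel(80, 600, ld_decay = 30, seed = 3)
  adj_r2 <- function(p) {
    G <- p$genotypes
    r <- vapply(seq_len(ncol(G) - 1), function(j)
      suppressWarnings(stats::cor(G[, j], G[, j + 1]))^2, numeric(1))
    mean(r, na.rm = TRUE)
  }
  # genotypes share an ancestry gradient, so "independent" SNPs retain a
  # small background correlation; linkage must add far more
  expect_lt(adj_r2(indep), 0.12)
  expect_gt(adj_r2(linked), adj_r2(indep) + 0.3)
})

test_that("seeded panel generation is bit-reproducible", {
  p1 <- generate_founder_panel(50, 500, n_chroms = 2, seed = 99)
  p2 <- generate_founder_panel(50, 500, n_chroms = 2, seed = 99)
  expect_identical(p1, p2)
})

test_that("accession fitness follows the Gaussian stabilizing form", {
  panel <- toy_panel()
  params <- sim_params(W_max = c(1, 2, 3), V_s_inv = 0.1)
  # zero distance gives W_max
  w <- accession_fitness(panel, params, c(bio1 = 10))
  expect_equal(w[2], 2)
  # flat niche: V_s_inv = 0 ignores distance
  flat <- sim_params(W_max = c(1, 2, 3), V_s_inv = 0)
  expect_equal(accession_fitness(panel, flat, c(bio1 = -40)), c(1, 2, 3))
  # closed form: W_max = 1, V_s_inv = 0.1, distance 2 -> exp(-0.4)
  one <- sim_params(W_max = 1, V_s_inv = 0.1)
  expect_equal(accession_fitness(panel, one, c(bio1 = 7))[1], exp(-0.4))
  expect_error(accession_fitness(panel, params, c(bio7 = 3)), "z_garden")
  expect_error(accession_fitness(panel, params, c(bio1 = 3), "bio9"), "z_origin")
})

test_that("a lethal accession is eliminated in one generation", {
  panel <- toy_panel()
  params <- sim_params(W_max = c(0, 1, 1), V_s_inv = 0,
                       carrying_capacity = 300)
  st <- list(generation = 0L, acc = rep(1:3, each = 100),
             geno = vector("list", 300), census_size = 300L, extinct = FALSE)
  w <- accession_fitness(panel, params, c(bio1 = 10))
  set.seed(1)
  st1 <- simulate_generation(st, w, params, panel)
  expect_false(1 %in% st1$acc)
  expect_false(st1$extinct)
  # all-lethal population goes extinct with a flag, not an error
  dead <- simulate_generation(st, c(0, 0, 0), params, panel)
  expect_true(dead$extinct)
  expect_equal(dead$census_size, 0L)
})

test_that("neutral uniform reproduction preserves expected frequencies", {
  panel <- toy_panel()
  params <- sim_params(W_max = 1, V_s_inv = 0, carrying_capacity = 3000,
                       fecundity = 10)
  st <- list(generation = 0L, acc = rep(1:3, c(1500, 900, 600)),
             geno = vector("list", 3000), census_size = 3000L,
             extinct = FALSE)
  set.seed(5)
  f1 <- replicate(50, {
    s <- simulate_generation(st, c(1, 1, 1), params, panel)
    tabulate(s$acc, 3) / length(s$acc)
  })
  expect_equal(rowMeans(f1), c(0.5, 0.3, 0.2), tolerance = 0.01)
})

test_that("outcrossing produces recombinants at the requested rate", {
  panel <- small_panel(10, 100, seed = 2)
  params <- sim_params(W_max = 1, V_s_inv = 0, carrying_capacity = 200,
                       outcross_rate = 0.1)
  st <- list(generation = 0L, acc = rep(1:10, each = 20),
             geno = vector("list", 200), census_size = 200L, extinct = FALSE)
  set.seed(8)
  st1 <- simulate_generation(st, rep(1, 10), params, panel)
  n_rec <- sum(!vapply(st1$geno, is.null, logical(1)))
  ci <- qbinom(c(0.0005, 0.9995), 200, 0.1)
  expect_gte(n_rec, ci[1])
  expect_lte(n_rec, ci[2])
})

test_that("neutral experiment means recover the seed mix", {
  panel <- small_panel(20, 10, seed = 4)
  params <- sim_params(W_max = 1, V_s_inv = 0, carrying_capacity = 100)
  g <- garden_design("g", c(bio1 = 10), n_replicates = 200, n_generations = 1)
  traj <- simulate_experiment(panel, list(g), params, seed = 21)
  f1 <- do.call(rbind, lapply(traj$acc_freq$g, function(m) m[2, ]))
  # Monte-Carlo mean across 200 replicates matches the founder mix
  expect_lt(max(abs(colMeans(f1) - panel$start_freq)), 0.02)
  expect_equal(rowSums(f1), rep(1, 200), tolerance = 1e-9)
})

test_that("strong divergent selection picks different winners per garden", {
  panel <- small_panel(25, 10, seed = 6)
  params <- sim_params(W_max = 1, V_s_inv = 0.3, carrying_capacity = 400,
                       offspring_model = "uniform")
  traj <- run_two_garden_sim(panel, v_s_inv = 0.3, capacity = 400,
                             n_reps = 8, seed = 31)
  top <- function(g) {
    f1 <- colMeans(do.call(rbind, lapply(traj$acc_freq[[g]],
                                         function(m) m[2, ])))
    which.max(f1 - panel$start_freq)
  }
  w_hot <- accession_fitness(panel, params, c(bio1 = 16))
  w_cold <- accession_fitness(panel, params, c(bio1 = -1))
  expect_false(top("hot") == top("cold"))
  # winners agree with the generative fitness ranking
  expect_gt(w_hot[top("hot")], stats::quantile(w_hot, 0.8))
  expect_gt(w_cold[top("cold")], stats::quantile(w_cold, 0.8))
})

test_that("12 replicates per garden is the default design", {
  g <- garden_design("g", c(bio1 = 5), n_generations = 1)
  expect_equal(g$n_replicates, 12L)
})

test_that("neutral drift variance matches the seed-pool sampling variance", {
  # uniform seed set of size fecundity per plant, then K of S seeds kept
  # without replacement: Var(f1 | f0) = f0 (1 - f0) / K * (S - K)/(S - 1)
  panel <- small_panel(30, 10, seed = 9)
  K <- 100; fec <- 10; S <- K * fec
  params <- sim_params(W_max = 1, V_s_inv = 0, carrying_capacity = K,
                       fecundity = fec)
  g <- garden_design("g", c(bio1 = 10), n_replicates = 500, n_generations = 1)
  traj <- simulate_experiment(panel, list(g), params, seed = 77)
  f0 <- do.call(rbind, lapply(traj$acc_freq$g, function(m) m[1, ]))
  f1 <- do.call(rbind, lapply(traj$acc_freq$g, function(m) m[2, ]))
  obs_var <- sum(apply(f1 - f0, 2, stats::var))
  exp_var <- sum(colMeans(f0 * (1 - f0)) / K * (S - K) / (S - 1))
  expect_equal(obs_var, exp_var, tolerance = 0.15)
})

test_that("stronger selection never helps a maladapted accession", {
  panel <- small_panel(20, 10, seed = 13)
  target <- which.max(abs(panel$z_origin[, "bio1"] - 14))  # most maladapted
  mean_freq <- function(vsi) {
    v <- rep(0.05, 20); v[target] <- vsi
    params <- sim_params(W_max = 1, V_s_inv = v, carrying_capacity = 150)
    g <- garden_design("g", c(bio1 = 14), n_replicates = 200,
                       n_generations = 1)
    traj <- simulate_experiment(panel, list(g), params, seed = 55)
    mean(vapply(traj$acc_freq$g, function(m) m[2, target], numeric(1)))
  }
  expect_gte(mean_freq(0.02) + 0.005, mean_freq(0.2))
})

test_that("pool-seq observation is consistent and flags missing data", {
  panel <- small_panel(20, 300, seed = 15)
  f <- rep(1 / 20, 20)
  # near-infinite flowers and depth recover the true pool frequency
  s <- sample_poolseq(f, panel, n_flowers = 1e4, mean_depth = 1e4,
                      seq_error = 0, seed = 3)
  est <- estimate_allele_freq(s)
  expect_lt(mean(abs(est$freq - s$true_pool_freq), na.rm = TRUE), 0.01)
  # and the pool itself approaches the mixture-implied frequency
  p_mix <- as.numeric(crossprod(f, panel$genotypes))
  expect_lt(mean(abs(est$freq - p_mix), na.rm = TRUE), 0.01)
  # zero depth: all counts zero, frequencies missing
  s0 <- sample_poolseq(f, panel, n_flowers = 10, mean_depth = 0, seed = 3)
  expect_true(all(s0$alt_count == 0 & s0$ref_count == 0))
  expect_true(all(is.na(estimate_allele_freq(s0)$freq)))
  # empty population cannot be sampled
  empty <- list(generation = 1L, acc = integer(0), geno = list(),
                census_size = 0L, extinct = TRUE)
  expect_error(sample_poolseq(empty, panel, 10, 10), "no reproductive")
})

test_that("deconvolution error decreases with sequencing depth", {
  panel <- small_panel(25, 600, seed = 17)
  f <- rep(1 / 25, 25)
  mae_at <- function(depth) {
    maes <- vapply(1:4, function(i) {
      s <- sample_poolseq(f, panel, n_flowers = 5000, mean_depth = depth,
                          seq_error = 0, seed = 100 + depth + i)
      af <- deconvolve_accessions(estimate_allele_freq(s), panel)
      mean(abs(af$freq - f))
    }, numeric(1))
    mean(maes)
  }
  maes <- c(mae_at(10), mae_at(50), mae_at(250))
  expect_true(all(diff(maes) < 0))
})

test_that("seeded experiments are bit-reproducible", {
  panel <- small_panel(15, 50, seed = 23)
  params <- sim_params(W_max = 1, V_s_inv = 0.1, carrying_capacity = 80,
                       outcross_rate = 0.05)
  g <- garden_design("g", c(bio1 = 8), n_replicates = 2, n_generations = 2)
  t1 <- simulate_experiment(panel, list(g), params, seed = 41)
  t2 <- simulate_experiment(panel, list(g), params, seed = 41)
  expect_identical(t1, t2)
})
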