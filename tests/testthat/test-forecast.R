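test_that("logistic trajectory fits are exact on logistic data", {
  yrs <- 0:4
  # constant frequency: beta = 0
  flat <- fit_logistic_trajectory(matrix(0.3, 5, 1), yrs)
  expect_equal(flat$snp$beta, 0)
  # exact logistic with slope 0.3/year
  p <- plogis(-1 + 0.3 * yrs)
  ex <- fit_logistic_trajectory(matrix(p, 5, 1), yrs)
  expect_equal(ex$snp$beta, 0.3, tolerance = 1e-8)
  expect_equal(ex$snp$intercept, -1, tolerance = 1e-8)
  expect_error(fit_logistic_trajectory(matrix(0.5, 2, 1), 0:1), "3 observations")
  # block averaging
  part <- list(block_of = c(1L, 1L, 2L))
  P <- cbind(p, plogis(-1 + 0.1 * yrs), plogis(0.2 * yrs))
  fb <- fit_logistic_trajectory(P, yrs, partition = part)
  expect_equal(fb$block_beta$beta, c(mean(c(0.3, 0.1)), 0.2), tolerance = 1e-8)
})

test_that("trajectory slope CI covers the truth under binomial sampling", {
  yrs <- 0:5
  hits <- vapply(1:100, function(i) {
    set.seed(500 + i)
    p <- plogis(-0.5 + 0.3 * yrs)
    obs <- rbinom(6, 100, p) / 100
    fit <- fit_logistic_trajectory(matrix(obs, 6, 1), yrs)
    lo <- fit$snp$beta - qt(0.975, 4) * fit$snp$se
    hi <- fit$snp$beta + qt(0.975, 4) * fit$snp$se
    lo <= 0.3 && 0.3 <= hi
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("selection coefficients follow the odds-ratio model", {
  # 0.5 -> 0.6 in one generation: odds 1 -> 1.5, s = 0.5
  s1 <- estimate_selection_coefficient(c(0.5, 0.6))
  expect_equal(s1$s, 0.5, tolerance = 1e-12)
  expect_true(all(is.na(s1$ci)))
  # flat trajectory: s = 0
  s0 <- estimate_selection_coefficient(rep(0.4, 5))
  expect_equal(s0$s, 0)
  expect_error(estimate_selection_coefficient(0.5), "2 timepoints")
})

test_that("selection estimation recovers a generative s over a trajectory", {
  s_true <- 0.3
  hits <- 0; signs <- 0
  n_run <- 120
  for (i in 1:n_run) {
    set.seed(700 + i)
    odds <- 1 * (1 + s_true)^(0:4)
    p <- odds / (1 + odds)
    obs <- rbinom(5, 100, p) / 100
    est <- estimate_selection_coefficient(obs, 0:4)
    if (!any(is.na(est$ci)) && est$ci[1] <= s_true && s_true <= est$ci[2])
      hits <- hits + 1
    if (est$s > 0) signs <- signs + 1
  }
  expect_gte(hits / n_run, 0.85)
  expect_gte(signs / n_run, 0.95)   # sign-correct at s = 0.3, depth 100
})

test_that("genomic offset clines reproduce generating logistics and score genotypes", {
  z <- seq(-2, 2, length.out = 8)
  a <- c(-1, 0.5); b <- c(0.8, -0.4)
  P <- sapply(1:2, function(j) plogis(a[j] + b[j] * z))
  om <- fit_genomic_offset(P, z)
  expect_equal(om$intercept, a, tolerance = 1e-8)
  expect_equal(om$slope, b, tolerance = 1e-8)
  # constant frequencies: flat clines, p_adapt independent of z
  om0 <- fit_genomic_offset(matrix(0.4, 8, 3), z)
  expect_equal(om0$slope, rep(0, 3), tolerance = 1e-10)
  expect_equal(predict_adaptive_freq(om0, -2), predict_adaptive_freq(om0, 2))
  expect_error(fit_genomic_offset(P[1:2, ], z[1:2]), "3 training gardens")
  # GO score extremes
  panel <- toy_panel()
  X <- panel$genotypes
  mock <- structure(list(intercept = qlogis(clip_test(X[2, ])), slope = rep(0, 6),
                         snp_subset = 1:6), class = "offset_model")
  go <- go_score(mock, 0, panel)
  expect_lt(go[["acc2"]], 0.01)
  anti <- structure(list(intercept = qlogis(clip_test(1 - X[2, ])),
                         slope = rep(0, 6), snp_subset = 1:6),
                    class = "offset_model")
  expect_gt(go_score(anti, 0, panel)[["acc2"]], 0.99)
  # bounded in [0,1] and invariant to duplicating every SNP
  expect_true(all(go >= 0 & go <= 1))
  pan2 <- founder_panel(cbind(X, X), snp_chrom = rep("chr1", 12),
                        snp_pos = 1:12, z_origin = panel$z_origin)
  dup <- structure(list(intercept = rep(mock$intercept, 2),
                        slope = rep(0, 12), snp_subset = 1:12),
                   class = "offset_model")
  expect_equal(unname(go_score(dup, 0, pan2)), unname(go), tolerance = 1e-12)
})

test_that("offset predictions agree with in-sample evolved frequencies", {
  # moderate selection: the logit-linear cline is a good description of
  # accession sorting along the gradient (strong sorting makes mid-garden
  # winner composition non-interpolable and degrades the cline fit)
  sim <- loo_sim_fixture(n_acc = 60, n_snps = 400, n_gardens = 6,
                         n_reps = 6, v_s_inv = 0.03, capacity = 800,
                         seed = 31)
  om <- fit_genomic_offset(sim$p1_garden, sim$climates)
  r <- vapply(seq_along(sim$climates), function(g) {
    stats::cor(predict_adaptive_freq(om, sim$climates[g]), sim$p1_garden[g, ])
  }, numeric(1))
  expect_gte(min(r), 0.9)
})

test_that("leave-one-out predictability is positive under local adaptation and null under drift", {
  sim <- loo_sim_fixture(n_acc = 30, n_snps = 300, n_gardens = 10,
                         n_reps = 6, v_s_inv = 0.1, capacity = 400,
                         seed = 33)
  expect_error(loo_predictability(sim$p1_garden[1, , drop = FALSE],
                                  sim$acc_f0[1], sim$acc_f1[1],
                                  sim$climates[1], sim$panel), "3 gardens")
  sel <- loo_predictability(sim$p1_garden, sim$acc_f0, sim$acc_f1,
                            sim$climates, sim$panel, scorer = "go")
  tt <- stats::t.test(sel$r, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  neu <- loo_sim_fixture(n_acc = 30, n_snps = 300, n_gardens = 8,
                         n_reps = 4, v_s_inv = 0, capacity = 300, seed = 34)
  nl <- loo_predictability(neu$p1_garden, neu$acc_f0, neu$acc_f1,
                           neu$climates, neu$panel, scorer = "go")
  ci <- stats::t.test(nl$r)$conf.int
  expect_true(ci[1] <= 0 && 0 <= ci[2])
  # adding stabilizing-selection information does not hurt on average
  sel2 <- loo_predictability(sim$p1_garden, sim$acc_f0, sim$acc_f1,
                             sim$climates, sim$panel,
                             scorer = "go_plus_stabsel")
  expect_gte(mean(sel2$r), mean(sel$r) - 0.05)
})

test_that("survival model recovers coefficients and flags degenerate data", {
  # null: survival independent of predictors
  set.seed(35)
  rec0 <- data.frame(r2 = runif(120), temp = runif(120, 0, 20),
                     survived = rbinom(120, 1, 0.5))
  m0 <- survival_model(rec0)
  expect_true(all(abs(m0$coef[-1] / m0$se[-1]) < 3.5))
  # generative interaction recovered within CI most of the time
  hits <- vapply(1:60, function(i) {
    set.seed(900 + i)
    n <- 150
    r2 <- runif(n); temp <- runif(n, -1, 1)
    eta <- -0.5 + 0.5 * r2 + 0.3 * temp + 2 * r2 * temp
    y <- rbinom(n, 1, plogis(eta))
    m <- survival_model(data.frame(r2 = r2, temp = temp, survived = y))
    lo <- m$coef[4] - 1.96 * m$se[4]; hi <- m$coef[4] + 1.96 * m$se[4]
    lo <= 2 && 2 <= hi
  }, logical(1))
  expect_gte(mean(hits), 0.85)
  # all survive: degenerate, flagged, no exception
  recall <- data.frame(r2 = runif(30), temp = runif(30, 0, 20),
                       survived = 1)
  mall <- survival_model(recall)
  expect_true(mall$flagged)
  # isoline solves the fitted model at the requested probability
  iso <- m0$isoline
  ok <- is.finite(iso$r2_required)
  pred <- plogis(m0$coef[1] + m0$coef[2] * iso$r2_required[ok] +
                   m0$coef[3] * iso$temp[ok] +
                   m0$coef[4] * iso$r2_required[ok] * iso$temp[ok])
  expect_equal(pred, rep(0.5, sum(ok)), tolerance = 1e-8)
})

test_that("census fits detect rescue-like rebounds and straight declines", {
  # exact parabola through (0,100), (1,20), (2,60): quadratic = 60
  cs <- data.frame(generation = c(0, 1, 2), census = c(100, 20, 60))
  fit <- census_trajectory(cs)
  expect_equal(fit$quadratic, 60)
  expect_true(fit$rebound)
  expect_equal(fit$minimum_at, 140 / 120, tolerance = 1e-8)
  # monotone straight decline: no rebound
  lin <- data.frame(generation = c(0, 1, 2), census = c(100, 60, 20))
  fl <- census_trajectory(lin)
  expect_equal(fl$quadratic, 0)
  expect_false(fl$rebound)
  # constant counts: all coefficients zero
  cc <- census_trajectory(data.frame(generation = 0:3, census = 50))
  expect_equal(cc$linear, 0)
  expect_equal(cc$quadratic, 0)
  expect_false(cc$rebound)
  # too few timepoints: skipped with NA
  sk <- census_trajectory(data.frame(generation = c(0, 1), census = c(5, 4)))
  expect_true(is.na(sk$quadratic))
  # replicate-pooled noisy rebound still detected
  set.seed(36)
  g <- rep(0:4, each = 6)
  mu <- 100 - 80 * g + 22 * g^2
  noisy <- data.frame(generation = g,
                      census = pmax(0, round(mu + rnorm(length(g), 0, 10))))
  fn <- census_trajectory(noisy)
  expect_true(fn$rebound)
  expect_lt(fn$p_quad, 0.05)
})

test_that("per-block trajectory slopes track carrier origin temperature", {
  # alleles carried by warm-origin accessions rise in a warm garden:
  # regression of per-block beta on mean carrier origin temperature is
  # positive
  sim <- loo_sim_fixture(n_acc = 40, n_snps = 400, n_gardens = 6,
                         n_reps = 4, v_s_inv = 0.1, seed = 37,
                         z_range = c(6, 16))
  panel <- sim$panel
  warm <- which.max(sim$climates)
  p0 <- as.numeric(crossprod(panel$start_freq, panel$genotypes))
  p1 <- sim$p1_garden[warm, ]
  # slope over two timepoints on the logit scale per SNP
  beta <- qlogis(pmin(pmax(p1, 1e-4), 1 - 1e-4)) -
    qlogis(pmin(pmax(p0, 1e-4), 1 - 1e-4))
  carrier_t <- vapply(seq_len(ncol(panel$genotypes)), function(j) {
    w <- panel$genotypes[, j]
    if (sum(w) == 0) return(NA_real_)
    sum(w * panel$z_origin[, "bio1"]) / sum(w)
  }, numeric(1))
  ok <- !is.na(carrier_t)
  fit <- stats::lm(beta[ok] ~ carrier_t[ok])
  expect_gt(stats::coef(fit)[2], 0)
  expect_lt(summary(fit)$coefficients[2, 4], 0.01)
})
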