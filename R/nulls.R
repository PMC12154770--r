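#' Wright-Fisher sampling variance of allele frequency change
#'
#' Classic one-generation Wright-Fisher expectation
#' \code{Var(dp) = p0 (1 - p0) / (2N)} for a diploid population of size N.
#'
#' @param p0 starting allele frequency in [0, 1].
#' @param N population size (>= 1); a conservative choice is the number
#'   of individuals sequenced.
#'
#' @return The drift variance (vectorized over \code{p0} and \code{N}).
#' @export
wf_variance <- function(p0, N) {
  if (any(N < 1)) stop("N must be >= 1")
  if (any(p0 < 0 | p0 > 1)) stop("p0 must be in [0, 1]")
  p0 * (1 - p0) / (2 * N)
}

#' Analytic accession-sorting variance of allele frequency change
#'
#' Closed-form one-generation null variance for the uniform seed-set
#' sorting model: N selfing plants founded multinomially from the seed
#' mix each set \code{fecundity} seeds, and N seeds are kept without
#' replacement from the pool of \code{S = N * fecundity}. By the law of
#' total variance on the 0/1 allele value per seed,
#' \code{Var(dp) = p0 (1 - p0)/N * [1 + (1 - 1/N)(S - N)/(S - 1)]}.
#'
#' @param p0 founder allele frequency in [0, 1].
#' @param N population size per tray.
#' @param fecundity seeds per plant before regulation.
#' @param generations compounding generations (variance accumulated by
#'   iterating the per-generation factor on p0(1-p0); exact for one
#'   generation, first-order beyond).
#'
#' @return per-SNP null variance (vectorized over p0).
#' @export
sorting_variance <- function(p0, N, fecundity = 10, generations = 1) {
  if (any(N < 1)) stop("N must be >= 1")
  S <- N * fecundity
  fac <- (1 + (1 - 1 / N) * (S - N) / (S - 1)) / N
  v <- p0 * (1 - p0) * (1 - (1 - fac)^generations)
  v
}

# one round of neutral accession sorting on a count vector:
# uniform  - every individual sets exactly `fecundity` seeds, then the
#            next generation is drawn without replacement (hypergeometric)
# poisson  - Poisson seed set, then sampled down to N
sort_counts_once <- function(counts, N, fecundity, offspring_model) {
  pool <- switch(offspring_model,
                 uniform = counts * fecundity,
                 poisson = rpois(length(counts), counts * fecundity))
  tot <- sum(pool)
  if (tot == 0) return(counts * 0L)
  if (tot <= N) return(as.integer(pool))
  # sample N seeds without replacement from the pool
  picks <- sample.int(tot, N)
  cum <- cumsum(pool)
  acc <- findInterval(picks - 1L, c(0L, cum), rightmost.closed = TRUE)
  tabulate(acc, nbins = length(counts))
}

#' Neutral accession-sorting null for allele-frequency change
#'
#' Non-Wright-Fisher neutral expectation: replicate populations of N
#' selfing individuals are resampled from the founder mix and undergo
#' neutral reproduction (uniform or Poisson seed set, no outcrossing);
#' allele-frequency changes are implied through the founder genotype
#' matrix. Returns the per-SNP null variance of frequency change and a
#' per starting-frequency-bin summary.
#'
#' @param start_freq founder-mix simplex over accessions.
#' @param panel a \code{\link{founder_panel}}.
#' @param N population size per replicate.
#' @param offspring_model \code{"uniform"} or \code{"poisson"}.
#' @param generations number of sorting rounds (0 gives zero variance).
#' @param reps number of null replicates (>= 100 recommended).
#' @param fecundity seeds per individual before down-sampling.
#' @param seed optional RNG seed.
#'
#' @return list with \code{delta} (reps x SNP matrix of null frequency
#'   changes), \code{var_snp} (per-SNP null variance), \code{p0}
#'   (expected starting allele frequency) and \code{bins} (per-decile
#'   summary; bins with < 50 SNPs merged upward).
#' @export
simulate_neutral_sorting <- function(start_freq, panel, N,
                                     offspring_model = c("uniform", "poisson"),
                                     generations = 1, reps = 200,
                                     fecundity = 10, seed = NULL) {
  offspring_model <- match.arg(offspring_model)
  if (!is.null(seed)) set.seed(seed)
  G <- impute_genotypes(panel$genotypes)
  p0 <- as.numeric(crossprod(start_freq, G))
  n_acc <- length(start_freq)
  delta <- matrix(0, reps, ncol(G))
  if (generations > 0) {
    cnt0 <- rmultinom(reps, N, start_freq)        # founding of each tray
    for (r in seq_len(reps)) {
      cnt <- cnt0[, r]
      for (g in seq_len(generations))
        cnt <- sort_counts_once(cnt, N, fecundity, offspring_model)
      tot <- sum(cnt)
      pt <- if (tot == 0) p0 else as.numeric(crossprod(cnt, G)) / tot
      delta[r, ] <- pt - p0
    }
  }
  var_snp <- colMeans(delta^2)
  list(delta = delta, var_snp = var_snp, p0 = p0,
       bins = bin_by_p0(p0, var_snp))
}

# decile bins of p0; bins with < 50 SNPs merged into the neighbour above
bin_by_p0 <- function(p0, v, min_snps = 50) {
  br <- unique(stats::quantile(p0, seq(0, 1, 0.1), na.rm = TRUE))
  if (length(br) < 2) br <- c(min(p0) - 1e-9, max(p0) + 1e-9)
  bin <- cut(p0, br, include.lowest = TRUE)
  tab <- table(bin)
  lev <- levels(bin)
  grp <- seq_along(lev)
  for (i in seq_along(lev)) {
    if (tab[i] < min_snps && i < length(lev)) grp[grp == i] <- i + 1
  }
  bin2 <- factor(grp[as.integer(bin)])
  data.frame(bin = names(tapply(v, bin2, mean)),
             mean_var = as.numeric(tapply(v, bin2, mean)),
             n_snps = as.integer(table(bin2)))
}

#' Excess-variance test of observed against neutral frequency change
#'
#' Compares the observed variance of allele-frequency change,
#' \code{mean((p1 - p0)^2)}, with a neutral expectation (analytic
#' Wright-Fisher or simulated accession sorting): reports the variance
#' ratio, a bootstrap CI over SNPs, a Mann-Whitney U test of the two
#' squared-change distributions, and a per starting-frequency-bin
#' breakdown. A ratio well above 1 indicates frequency shifts beyond
#' drift.
#'
#' @param delta_obs observed per-SNP frequency change (vector, or matrix
#'   samples x SNP whose squared values are averaged over rows).
#' @param p0 per-SNP starting frequency (for WF null and binning).
#' @param N population size for the analytic WF null (typically the
#'   number of individuals sequenced; conservative).
#' @param null_var optional per-SNP null variance from
#'   \code{\link{simulate_neutral_sorting}} (overrides the WF null).
#' @param null_delta optional matrix of null frequency-change draws used
#'   for the Mann-Whitney comparison.
#' @param n_boot bootstrap replicates for the CI (default 200).
#' @param seed optional RNG seed for the bootstrap.
#'
#' @return An object of class \code{drift_test}: \code{ratio},
#'   \code{ci}, \code{mwu_p}, \code{bins}, \code{n_snps}.
#' @export
variance_ratio_test <- function(delta_obs, p0, N = NULL, null_var = NULL,
                                null_delta = NULL, n_boot = 200, seed = NULL) {
  if (is.matrix(delta_obs)) {
    obs_sq <- colMeans(delta_obs^2, na.rm = TRUE)
  } else obs_sq <- as.numeric(delta_obs)^2
  keep <- !is.na(obs_sq)
  if (!any(keep)) stop("all observed frequency changes missing")
  obs_sq <- obs_sq[keep]; p0 <- p0[keep]
  if (length(obs_sq) < 100)
    warning("fewer than 100 SNPs; variance ratio will be unstable")
  if (is.null(null_var)) {
    if (is.null(N)) stop("supply either null_var or N for the WF null")
    null_var <- wf_variance(p0, N)
  } else null_var <- null_var[keep]
  pos <- null_var > 0
  ratio <- mean(obs_sq[pos]) / mean(null_var[pos])
  if (!is.null(seed)) set.seed(seed)
  n <- sum(pos)
  bs <- replicate(n_boot, {
    ix <- sample.int(n, n, replace = TRUE)
    mean(obs_sq[pos][ix]) / mean(null_var[pos][ix])
  })
  ci <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
  mwu_p <- if (!is.null(null_delta)) {
    stats::wilcox.test(obs_sq, as.numeric(null_delta)^2)$p.value
  } else NA_real_
  bins <- bin_by_p0(p0[pos], obs_sq[pos] / null_var[pos])
  names(bins)[2] <- "mean_ratio"
  structure(list(ratio = ratio, ci = ci, mwu_p = mwu_p, bins = bins,
                 n_snps = n),
            class = "drift_test")
}

#' @export
print.drift_test <- function(x, ...) {
  cat(sprintf("variance ratio obs/null = %.3f [95%% CI %.3f-%.3f], %d SNPs\n",
              x$ratio, x$ci[1], x$ci[2], x$n_snps))
  invisible(x)
}

#' Hudson F_ST between two pooled samples
#'
#' Genome-wide Hudson estimator computed as a ratio of averages (sums of
#' per-SNP numerators over sums of denominators), which avoids the
#' instability of averaging per-SNP ratios. With pool depths supplied,
#' the numerator subtracts the binomial sampling correction
#' \code{p(1-p)/(n-1)} per sample.
#'
#' @param p_a,p_b per-SNP allele frequencies of the two samples.
#' @param n_a,n_b per-SNP sample sizes (pool depths) for the sampling
#'   correction; omit for the uncorrected estimator.
#'
#' @return list with \code{fst}, \code{n_snps}.
#' @export
compute_fst <- function(p_a, p_b, n_a = NULL, n_b = NULL) {
  keep <- !is.na(p_a) & !is.na(p_b)
  if (!is.null(n_a)) keep <- keep & n_a > 1 & n_b > 1
  if (sum(keep) < 1) stop("no shared non-missing SNPs")
  if (sum(keep) < 100)
    warning("fewer than 100 shared SNPs; F_ST will be noisy")
  pa <- p_a[keep]; pb <- p_b[keep]
  num <- (pa - pb)^2
  if (!is.null(n_a)) {
    num <- num - pa * (1 - pa) / (n_a[keep] - 1) - pb * (1 - pb) / (n_b[keep] - 1)
  }
  den <- pa * (1 - pb) + pb * (1 - pa)
  if (sum(den) == 0) return(list(fst = 0, n_snps = sum(keep)))
  list(fst = sum(num) / sum(den), n_snps = sum(keep))
}

#' PCA of allele-frequency change
#'
#' Principal components of the samples x SNPs matrix of frequency change
#' relative to the founder, \code{p_t - p_0}. The matrix is already
#' centred on the founder state, so no re-centering is applied and the
#' founder (zero change) projects to the origin by construction.
#'
#' @param delta samples x SNPs matrix of \code{p_t - p_0}.
#'
#' @return list with \code{scores} (samples x PCs), \code{var_explained}
#'   and the \code{rotation}.
#' @export
pca_frequency_change <- function(delta) {
  delta <- as.matrix(delta)
  if (nrow(delta) < 3) stop("need at least 3 samples for a PCA")
  pc <- stats::prcomp(delta, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / max(sum(pc$sdev^2), .Machine$double.eps)
  list(scores = pc$x, var_explained = ve, rotation = pc$rotation)
}

#' Evolutionary repeatability across replicates
#'
#' Mean pairwise Spearman rank correlation of frequency change between
#' replicate populations of the same garden, at the allele or accession
#' level, with a bootstrap CI over replicate pairs.
#'
#' @param deltas replicates x features matrix of frequency change
#'   (alleles or accessions as columns).
#' @param n_boot bootstrap replicates for the CI.
#' @param seed optional RNG seed for the bootstrap.
#'
#' @return list with \code{r_rho} (mean pairwise Spearman), \code{ci},
#'   \code{pairs} (per-pair correlations).
#' @export
repeatability <- function(deltas, n_boot = 200, seed = NULL) {
  deltas <- as.matrix(deltas)
  R <- nrow(deltas)
  if (R < 2) stop("need at least 2 replicates")
  cm <- stats::cor(t(deltas), method = "spearman", use = "pairwise.complete.obs")
  prs <- cm[upper.tri(cm)]
  if (!is.null(seed)) set.seed(seed)
  bs <- replicate(n_boot, mean(sample(prs, length(prs), replace = TRUE)))
  list(r_rho = mean(prs),
       ci = stats::quantile(bs, c(0.025, 0.975), names = FALSE),
       pairs = prs)
}

#' Heritability of accession frequency change
#'
#' Variance-components estimate of the repeatable (accession-attributable)
#' fraction of frequency change across replicate populations: one-way
#' random-effects ANOVA by method of moments, with the accession as the
#' random group, truncated into [0, 1].
#'
#' @param delta_acc accessions x replicates matrix of accession frequency
#'   change within one garden.
#'
#' @return list with \code{H2}, variance components
#'   \code{sigma2_accession} and \code{sigma2_residual}, and a
#'   \code{degenerate} flag (TRUE when total variance is zero, H2
#'   undefined/NA).
#' @export
heritability_freq_change <- function(delta_acc) {
  delta_acc <- as.matrix(delta_acc)
  a <- nrow(delta_acc); r <- ncol(delta_acc)
  if (r < 2) stop("need at least 2 replicates")
  if (a < 10) stop("need at least 10 accessions")
  if (stats::var(as.numeric(delta_acc)) == 0)
    return(list(H2 = NA_real_, sigma2_accession = 0, sigma2_residual = 0,
                degenerate = TRUE))
  gm <- rowMeans(delta_acc)
  msb <- r * stats::var(gm)                       # between-accession MS
  msw <- mean(apply(delta_acc, 1, stats::var))    # within (residual) MS
  s2a <- max(0, (msb - msw) / r)
  h2 <- s2a / (s2a + msw)
  list(H2 = min(1, max(0, h2)), sigma2_accession = s2a,
       sigma2_residual = msw, degenerate = FALSE)
}
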