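#' Partition the founder panel into LD blocks
#'
#' Greedy chaining along each chromosome: the current block is extended
#' while the next SNP's squared correlation (r^2 across founder
#' genotypes) with any of the last \code{max_gap} SNPs of the block
#' reaches \code{r2_threshold}; otherwise a new block starts. Blocks are
#' contiguous, non-overlapping and cover every SNP. Deterministic.
#'
#' @param panel a \code{\link{founder_panel}} (>= 2 SNPs).
#' @param r2_threshold r^2 needed to chain a SNP into the current block
#'   (default 0.5).
#' @param max_gap how many trailing block SNPs are checked (default 10).
#'
#' @return An \code{ld_blocks} object: \code{block_of} (per-SNP block
#'   id) and \code{blocks} (data.frame: block, chrom, start_snp,
#'   end_snp, start_pos, end_pos, n_snps, mean_maf).
#' @export
build_ld_blocks <- function(panel, r2_threshold = 0.5, max_gap = 10) {
  G <- impute_genotypes(panel$genotypes)
  n_snp <- ncol(G)
  if (n_snp < 2) stop("need at least 2 SNPs")
  block_of <- integer(n_snp)
  bid <- 0L
  for (ch in unique(panel$snp_chrom)) {
    ix <- which(panel$snp_chrom == ch)
    bid <- bid + 1L
    block_of[ix[1]] <- bid
    cur <- ix[1]                      # SNP indices of the current block
    for (k in ix[-1]) {
      tail_ix <- cur[max(1, length(cur) - max_gap + 1):length(cur)]
      r2 <- suppressWarnings(stats::cor(G[, k], G[, tail_ix]))^2
      r2[is.na(r2)] <- 0              # monomorphic SNPs carry no linkage
      if (max(r2) >= r2_threshold) {
        cur <- c(cur, k)
      } else {
        bid <- bid + 1L
        cur <- k
      }
      block_of[k] <- bid
    }
  }
  maf <- pmin(colMeans(G), 1 - colMeans(G))
  blocks <- do.call(rbind, lapply(seq_len(bid), function(b) {
    ix <- which(block_of == b)
    data.frame(block = b, chrom = panel$snp_chrom[ix[1]],
               start_snp = ix[1], end_snp = ix[length(ix)],
               start_pos = panel$snp_pos[ix[1]],
               end_pos = panel$snp_pos[ix[length(ix)]],
               n_snps = length(ix), mean_maf = mean(maf[ix]))
  }))
  structure(list(block_of = block_of, blocks = blocks), class = "ld_blocks")
}

# binomial log-likelihood, safe at p in {0,1}
binom_ll <- function(alt, dep, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(alt * log(p) + (dep - alt) * log(1 - p))
}

#' Replicate-consistent selection LRT at one SNP
#'
#' Likelihood-ratio test for a consistent allele-frequency shift across
#' replicate populations. Null: all replicates sit at one shared
#' frequency at both timepoints. Alternative: replicates share the
#' founder frequency at t0 and one common post-selection frequency at t1
#' (one extra parameter). Statistic 2(l_alt - l_null) is referred to
#' chi-square with 1 df.
#'
#' @param alt0,dep0 per-replicate alt counts and depths at t0.
#' @param alt1,dep1 per-replicate alt counts and depths at t1.
#'
#' @return list with \code{stat}, \code{p}, and the MLE frequencies
#'   \code{p0_hat}, \code{p1_hat}. NA when every replicate has zero
#'   depth.
#' @export
lrt_parallel_selection <- function(alt0, dep0, alt1, dep1) {
  if (length(alt0) < 2) stop("need >= 2 replicates")
  if (sum(dep0) + sum(dep1) == 0)
    return(list(stat = NA_real_, p = NA_real_,
                p0_hat = NA_real_, p1_hat = NA_real_))
  p_null <- (sum(alt0) + sum(alt1)) / (sum(dep0) + sum(dep1))
  p0 <- if (sum(dep0) > 0) sum(alt0) / sum(dep0) else p_null
  p1 <- if (sum(dep1) > 0) sum(alt1) / sum(dep1) else p_null
  ll_null <- binom_ll(c(alt0, alt1), c(dep0, dep1), p_null)
  ll_alt <- binom_ll(alt0, dep0, p0) + binom_ll(alt1, dep1, p1)
  stat <- max(0, 2 * (ll_alt - ll_null))
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       p0_hat = p0, p1_hat = p1)
}

#' Genome-wide replicate-consistent selection scan
#'
#' Applies \code{\link{lrt_parallel_selection}} at every SNP, adjusts
#' p-values (Bonferroni or BH), summarizes LD blocks by their minimum p
#' with a within-block Bonferroni correction, and reports the genomic
#' inflation factor lambda_GC (median statistic over the chi-square(1)
#' median).
#'
#' @param alt0,dep0,alt1,dep1 replicates x SNP matrices of counts at the
#'   two timepoints.
#' @param partition an \code{ld_blocks} partition (optional; without it
#'   only per-SNP results are returned).
#' @param correction \code{"bonferroni"} or \code{"bh"}.
#' @param alpha significance level on adjusted p-values (default 0.05).
#'
#' @return A \code{scan_result}: per-SNP data.frame (\code{stat},
#'   \code{p}, \code{p_adj}, \code{significant}), optional per-block
#'   data.frame (min p, within-block Bonferroni, significance), and
#'   \code{lambda_gc}.
#' @export
scan_genome <- function(alt0, dep0, alt1, dep1, partition = NULL,
                        correction = c("bonferroni", "bh"), alpha = 0.05) {
  correction <- match.arg(correction)
  n_snp <- ncol(alt0)
  stat <- p <- numeric(n_snp)
  for (j in seq_len(n_snp)) {
    r <- lrt_parallel_selection(alt0[, j], dep0[, j], alt1[, j], dep1[, j])
    stat[j] <- r$stat; p[j] <- r$p
  }
  meth <- if (correction == "bh") "BH" else "bonferroni"
  p_adj <- stats::p.adjust(p, method = meth)
  snp <- data.frame(stat = stat, p = p, p_adj = p_adj,
                    significant = !is.na(p_adj) & p_adj < alpha)
  lambda <- stats::median(stat, na.rm = TRUE) / stats::qchisq(0.5, 1)
  blocks <- NULL
  if (!is.null(partition)) {
    bo <- partition$block_of
    minp <- tapply(p, bo, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
    nsn <- tapply(p, bo, function(x) sum(!is.na(x)))
    p_block <- pmin(1, as.numeric(minp) * as.numeric(nsn))   # within-block Bonferroni
    p_block_adj <- stats::p.adjust(p_block, method = meth)
    blocks <- data.frame(block = as.integer(names(minp)),
                         p_block = p_block, p_adj = p_block_adj,
                         significant = !is.na(p_block_adj) & p_block_adj < alpha)
  }
  structure(list(snp = snp, blocks = blocks, lambda_gc = lambda,
                 correction = correction),
            class = "scan_result")
}

#' Cross-garden block-overlap permutation test
#'
#' Tests whether significant LD blocks recur across more gardens than
#' expected by chance. Observed statistic: number of blocks significant
#' in at least \code{k_gardens} gardens. Null: each garden's significant
#' set is resampled uniformly over the block universe preserving its
#' size. p = (1 + #(null >= observed)) / (n_perm + 1), so the smallest
#' attainable p is 1/(n_perm+1).
#'
#' @param sig_sets list (one per garden) of significant block ids.
#' @param n_blocks size of the common block universe.
#' @param k_gardens minimum number of gardens a block must recur in.
#' @param n_perm number of permutations (>= 1).
#' @param seed optional RNG seed.
#'
#' @return list with \code{observed}, \code{p}, and the null counts.
#' @export
block_overlap_permutation <- function(sig_sets, n_blocks, k_gardens,
                                      n_perm = 1000, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  count_overlap <- function(sets) {
    tab <- table(unlist(sets))
    sum(tab >= k_gardens)
  }
  obs <- count_overlap(sig_sets)
  sizes <- lengths(sig_sets)
  null_counts <- replicate(n_perm, {
    count_overlap(lapply(sizes, function(s) sample.int(n_blocks, s)))
  })
  list(observed = obs,
       p = (1 + sum(null_counts >= obs)) / (n_perm + 1),
       null_counts = null_counts)
}
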