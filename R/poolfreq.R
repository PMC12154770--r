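#' Allele frequencies from pooled counts
#'
#' Raw pool-seq allele-frequency estimate per SNP: alt/(ref+alt) where
#' depth reaches \code{min_depth}, missing otherwise.
#'
#' @param sample a \code{pool_sample} (or any list with \code{ref_count}
#'   and \code{alt_count}).
#' @param min_depth minimum depth below which the frequency is set
#'   missing (default 1).
#'
#' @return A \code{freq_table}: list with \code{freq}, \code{depth} and a
#'   \code{smoothed} flag (FALSE for raw estimates).
#' @export
estimate_allele_freq <- function(sample, min_depth = 1) {
  ref <- sample$ref_count; alt <- sample$alt_count
  if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE))
    stop("negative read counts")
  depth <- ref + alt
  p <- ifelse(depth >= min_depth, alt / depth, NA_real_)
  structure(list(freq = p, depth = depth, smoothed = FALSE,
                 meta = sample$meta),
            class = "freq_table")
}

# founder dosage matrix prepared for deconvolution: residual heterozygous
# calls coded 0.5 (already allowed), missing calls mean-imputed per SNP
impute_genotypes <- function(G) {
  if (!anyNA(G)) return(G)
  cm <- colMeans(G, na.rm = TRUE)
  cm[is.nan(cm)] <- 0.5
  ix <- which(is.na(G), arr.ind = TRUE)
  G[ix] <- cm[ix[, 2]]
  G
}

# min ||G' f - p||^2 + ridge ||f||^2  s.t.  f >= 0, sum(f) = 1.
# Solved as NNLS on the Cholesky-compressed normal equations with the
# sum-to-one constraint imposed as a heavily weighted row, then
# renormalized onto the simplex.
solve_simplex_nnls <- function(G, p, ridge = 1e-4) {
  n_acc <- nrow(G)
  M <- tcrossprod(G) / ncol(G)              # scale by n_snps for conditioning
  v <- as.numeric(G %*% p) / ncol(G)
  diag(M) <- diag(M) + ridge / ncol(G)
  w_eq <- mean(diag(M))   # moderate weight; simplex enforced by renormalization
  M <- M + w_eq
  v <- v + w_eq
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) {
    warning("rank-deficient founder panel; increasing ridge for solve")
    diag(M) <- diag(M) + 1e-6 * max(diag(M))
    R <- chol(M)
  }
  b <- backsolve(R, v, transpose = TRUE)
  f <- pracma::lsqnonneg(R, b)$x
  s <- sum(f)
  if (s <= 0) rep(1 / n_acc, n_acc) else f / s
}

#' Deconvolve founder-accession frequencies from pooled allele frequencies
#'
#' Reconstructs the relative abundance of the founder accessions in a
#' pooled sample by simplex-constrained ridge least squares: the pool
#' allele-frequency vector is modelled as a mixture of the founder
#' genotype rows, \code{f = argmin ||G'f - p||^2 + ridge ||f||^2} subject
#' to \code{f >= 0, sum(f) = 1}. Deterministic given its inputs.
#'
#' @param freqs a \code{freq_table} (one sample) or numeric vector of
#'   pool allele frequencies (NA = missing SNP).
#' @param panel a \code{\link{founder_panel}}; missing founder calls are
#'   mean-imputed per SNP for the solve.
#' @param ridge ridge regularization weight (default 1e-4, for rank
#'   safety on near-duplicated accessions).
#'
#' @return An \code{acc_freq} object: \code{freq} (simplex over
#'   accessions), \code{residual_rms} (RMS of \code{p - G'f} over used
#'   SNPs) and the SNPs used.
#' @export
deconvolve_accessions <- function(freqs, panel, ridge = 1e-4) {
  p <- if (inherits(freqs, "freq_table")) freqs$freq else as.numeric(freqs)
  use <- !is.na(p)
  if (!any(use)) stop("all SNPs missing; cannot deconvolve")
  G <- impute_genotypes(panel$genotypes)[, use, drop = FALSE]
  if (sum(use) < nrow(G))
    warning("fewer non-missing SNPs than accessions; solution is regularized")
  f <- solve_simplex_nnls(G, p[use], ridge = ridge)
  fitted <- as.numeric(crossprod(G, f))
  structure(list(freq = stats::setNames(f, panel$accession_ids),
                 residual_rms = sqrt(mean((p[use] - fitted)^2)),
                 snps_used = which(use),
                 meta = if (inherits(freqs, "freq_table")) freqs$meta else list()),
            class = "acc_freq")
}

#' Linkage-based smoothing of pool allele frequencies
#'
#' Error-reduction step exploiting linkage in the founder panel: noisy
#' per-SNP frequencies are replaced by their projection through the
#' reconstructed accession mixture, \code{p_smooth = G' f_hat}. Because
#' every founder genome constrains millions of linked sites jointly, the
#' projection shrinks independent per-SNP sampling noise. Idempotent:
#' smoothing already-smoothed frequencies returns them unchanged (up to
#' the ridge perturbation).
#'
#' @param freqs a \code{freq_table} with raw estimates.
#' @param accfreq the matching \code{acc_freq} from
#'   \code{\link{deconvolve_accessions}}.
#' @param panel the \code{\link{founder_panel}}.
#'
#' @return A \code{freq_table} with smoothed frequencies at every panel
#'   SNP and \code{smoothed = TRUE}.
#' @export
smooth_frequencies <- function(freqs, accfreq, panel) {
  G <- impute_genotypes(panel$genotypes)
  p_smooth <- as.numeric(crossprod(G, accfreq$freq))
  structure(list(freq = p_smooth,
                 depth = if (inherits(freqs, "freq_table")) freqs$depth else NULL,
                 smoothed = TRUE,
                 meta = if (inherits(freqs, "freq_table")) freqs$meta else list()),
            class = "freq_table")
}

#' Merge pool samples from the same tray and growing season
#'
#' Sums read counts and flowers across multiple samplings of the same
#' garden x replicate x generation; the merged frequency is therefore the
#' depth-weighted mean of the parts.
#'
#' @param samples list of \code{pool_sample} objects with identical
#'   garden, replicate and generation metadata.
#'
#' @return A merged \code{pool_sample}.
#' @export
merge_samples <- function(samples) {
  if (length(samples) < 1) stop("no samples to merge")
  key <- function(s) paste(s$meta$garden, s$meta$replicate, s$meta$generation)
  if (length(unique(vapply(samples, key, character(1)))) != 1)
    stop("samples have mixed garden/replicate/generation metadata")
  ref <- Reduce(`+`, lapply(samples, `[[`, "ref_count"))
  alt <- Reduce(`+`, lapply(samples, `[[`, "alt_count"))
  fl <- sum(vapply(samples, function(s) as.integer(s$n_flowers), integer(1)))
  structure(list(ref_count = ref, alt_count = alt, n_flowers = fl,
                 meta = samples[[1]]$meta),
            class = "pool_sample")
}

#' Reconstruction error summary
#'
#' Compares estimated frequencies (allele-level or accession-level) to a
#' known truth, as used on simulated data and on founder seed-mix
#' validation sequencing.
#'
#' @param estimated numeric vector/matrix, or \code{freq_table} /
#'   \code{acc_freq}.
#' @param truth same shape as \code{estimated}.
#'
#' @return list with \code{mae}, \code{rmse} and error \code{quantiles}
#'   (absolute error at 50/90/95/99 percent).
#' @export
estimate_error <- function(estimated, truth) {
  est <- if (is.list(estimated)) estimated$freq else estimated
  tru <- if (is.list(truth)) truth$freq else truth
  if (length(est) != length(tru)) stop("shape mismatch between estimate and truth")
  err <- abs(as.numeric(est) - as.numeric(tru))
  err <- err[!is.na(err)]
  list(mae = mean(err), rmse = sqrt(mean(err^2)),
       quantiles = stats::quantile(err, c(0.5, 0.9, 0.95, 0.99)))
}
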