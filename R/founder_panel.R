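#' Founder accession panel
#'
#' Container for a panel of inbred (homozygous) founder accessions: a
#' dosage matrix over biallelic SNPs, the climates of origin of each
#' accession, and the relative frequency of each accession in the founder
#' seed mix.
#'
#' @param genotypes numeric matrix, accessions x SNPs, entries in
#'   \{0, 1\} (homozygous dosages; \code{NA} allowed for missing calls,
#'   0.5 for rare residual heterozygotes).
#' @param accession_ids character vector of accession labels (rows).
#' @param snp_chrom chromosome label per SNP.
#' @param snp_pos 1-based position per SNP; strictly increasing within
#'   each chromosome.
#' @param z_origin numeric matrix, accessions x climate variables, the
#'   climate at each accession's geographic origin (e.g. BIOCLIM-style
#'   variables in degrees C or mm).
#' @param start_freq founder seed-mix frequency per accession; must be a
#'   simplex (non-negative, summing to 1).
#'
#' @return An object of class \code{founder_panel}.
#' @export
founder_panel <- function(genotypes, accession_ids = rownames(genotypes),
                          snp_chrom, snp_pos, z_origin,
                          start_freq = rep(1 / nrow(genotypes), nrow(genotypes))) {
  genotypes <- as.matrix(genotypes)
  n_acc <- nrow(genotypes)
  n_snp <- ncol(genotypes)
  if (is.null(accession_ids)) accession_ids <- paste0("acc", seq_len(n_acc))
  stopifnot(length(accession_ids) == n_acc,
            length(snp_chrom) == n_snp, length(snp_pos) == n_snp)
  ok <- is.na(genotypes) | genotypes %in% c(0, 0.5, 1)
  if (!all(ok))
    stop("genotype entries must be 0, 1, 0.5 (het) or NA")
  if (any(start_freq < 0) || abs(sum(start_freq) - 1) > 1e-9)
    stop("start_freq must be a simplex (non-negative, sum 1 within 1e-9)")
  for (ch in unique(snp_chrom)) {
    pos <- snp_pos[snp_chrom == ch]
    if (any(diff(pos) <= 0))
      stop("snp_pos must be strictly increasing within chromosome ", ch)
  }
  z_origin <- as.matrix(z_origin)
  if (nrow(z_origin) != n_acc) stop("z_origin must have one row per accession")
  rownames(genotypes) <- accession_ids
  rownames(z_origin) <- accession_ids
  structure(list(genotypes = genotypes,
                 accession_ids = as.character(accession_ids),
                 snp_chrom = as.character(snp_chrom),
                 snp_pos = as.integer(snp_pos),
                 z_origin = z_origin,
                 start_freq = as.numeric(start_freq)),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("founder_panel:", length(x$accession_ids), "accessions x",
      length(x$snp_pos), "SNPs on", length(unique(x$snp_chrom)),
      "chromosome(s);", ncol(x$z_origin), "climate variable(s)\n")
  invisible(x)
}

#' Generate a synthetic founder panel
#'
#' Draws a panel of homozygous founder accessions with spatially
#' autocorrelated allele sharing along the genome (so LD blocks exist), a
#' latent ancestry gradient that couples genotypes to climate of origin
#' (emulating past local adaptation), and a near-equal founder seed mix
#' with small Dirichlet jitter.
#'
#' Genotypes are generated by a per-accession copy process along each
#' chromosome: SNP j copies SNP j-1 with probability exp(-1/ld_decay) and
#' otherwise draws a fresh Bernoulli whose probability depends on the
#' accession's latent ancestry coordinate. \code{ld_decay = 0} gives
#' independent SNPs.
#'
#' @param n_accessions number of founder accessions (>= 2).
#' @param n_snps total number of SNPs (>= n_chroms).
#' @param n_chroms number of chromosomes (SNPs split evenly).
#' @param climate_span named list of length-2 numeric ranges, one per
#'   climate variable (default a single annual-temperature-like variable
#'   spanning -3 to 18 degrees C).
#' @param ld_decay correlation length of the genotype copy process in SNP
#'   index units; 0 disables linkage.
#' @param climate_ancestry_cor target correlation between the latent
#'   ancestry gradient and climate of origin (0..1).
#' @param dirichlet_conc concentration of the Dirichlet jitter on the
#'   founder seed mix; large values give a near-exact 1/n mix.
#' @param seed optional RNG seed for reproducibility.
#'
#' @return A \code{\link{founder_panel}}.
#' @export
generate_founder_panel <- function(n_accessions, n_snps, n_chroms = 1,
                                   climate_span = list(bio1 = c(-3, 18)),
                                   ld_decay = 20,
                                   climate_ancestry_cor = 0.8,
                                   dirichlet_conc = 5000,
                                   seed = NULL) {
  if (n_accessions < 2 || n_snps < 1 || n_chroms < 1)
    stop("n_accessions, n_snps and n_chroms must be positive (>= 2 accessions)")
  if (n_snps < n_chroms) stop("n_snps must be >= n_chroms")
  if (!is.null(seed)) set.seed(seed)
  rho <- if (ld_decay <= 0) 0 else exp(-1 / ld_decay)

  # latent ancestry coordinate per accession drives both allele
  # probabilities and climate of origin
  u <- runif(n_accessions, -0.5, 0.5)
  alpha <- rnorm(n_snps, 0, 0.8)         # per-SNP baseline logit-frequency
  beta <- rnorm(n_snps, 0, 2.5)          # per-SNP ancestry cline strength
  pmat <- plogis(outer(u, beta) + rep(alpha, each = n_accessions))

  chrom_of <- sort(rep_len(seq_len(n_chroms), n_snps))
  G <- matrix(0L, n_accessions, n_snps)
  fresh <- matrix(runif(n_accessions * n_snps) < pmat, n_accessions, n_snps)
  copy <- matrix(runif(n_accessions * n_snps) < rho, n_accessions, n_snps)
  for (j in seq_len(n_snps)) {
    if (j == 1 || chrom_of[j] != chrom_of[j - 1]) {
      G[, j] <- fresh[, j]
    } else {
      G[, j] <- ifelse(copy[, j], G[, j - 1], fresh[, j])
    }
  }
  storage.mode(G) <- "double"

  # climate of origin: blend of ancestry gradient and independent noise,
  # rescaled onto each requested span
  w <- climate_ancestry_cor
  z_origin <- sapply(names(climate_span), function(v) {
    raw <- w * scale(u)[, 1] + sqrt(max(0, 1 - w^2)) * rnorm(n_accessions)
    sp <- climate_span[[v]]
    sp[1] + (raw - min(raw)) / (max(raw) - min(raw)) * diff(sp)
  })
  z_origin <- matrix(z_origin, nrow = n_accessions,
                     dimnames = list(NULL, names(climate_span)))

  start_freq <- rdirichlet1(rep(dirichlet_conc / n_accessions, n_accessions))

  pos <- unlist(lapply(split(seq_len(n_snps), chrom_of),
                       function(ix) seq_along(ix) * 100L), use.names = FALSE)
  founder_panel(G,
                accession_ids = sprintf("acc%03d", seq_len(n_accessions)),
                snp_chrom = paste0("chr", chrom_of),
                snp_pos = pos,
                z_origin = z_origin,
                start_freq = start_freq)
}

# one Dirichlet draw via independent gammas
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Expected accession fitness under Gaussian stabilizing selection
#'
#' Computes per-accession expected relative fitness in a garden as
#' \code{w_a = W_max_a * exp(-V_s_inv_a * (z_origin_a - z_garden)^2)}:
#' fitness is maximal at the accession's climate of origin and decays as a
#' Gaussian function of climate distance, at accession-specific rate
#' \code{V_s_inv}.
#'
#' @param panel a \code{\link{founder_panel}}.
#' @param params a \code{\link{sim_params}} object carrying per-accession
#'   \code{W_max} and \code{V_s_inv}.
#' @param z_garden named numeric vector of garden climate values.
#' @param climate_var which climate variable to use (must be present in
#'   both the panel's \code{z_origin} and \code{z_garden}).
#'
#' @return numeric vector of non-negative expected fitnesses, one per
#'   accession; equals \code{W_max} where \code{z_origin == z_garden}.
#' @export
accession_fitness <- function(panel, params, z_garden, climate_var = "bio1") {
  if (!climate_var %in% colnames(panel$z_origin))
    stop("climate variable '", climate_var, "' not in panel z_origin")
  if (!climate_var %in% names(z_garden))
    stop("climate variable '", climate_var, "' not in z_garden")
  n <- length(panel$accession_ids)
  Wm <- rep_len(params$W_max, n)
  Vi <- rep_len(params$V_s_inv, n)
  d <- panel$z_origin[, climate_var] - z_garden[[climate_var]]
  as.numeric(Wm * exp(-Vi * d^2))
}
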