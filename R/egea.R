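#' Per-garden response matrix for eGEA
#'
#' Default eGEA response: per-garden mean logit frequency change between
#' founder and evolved populations, averaged over replicates, one row
#' per garden, one column per SNP. Raw frequency change is available as
#' an option.
#'
#' @param p1 list (one per garden) of replicates x SNP matrices of
#'   evolved frequencies, or a gardens x SNP matrix of replicate means.
#' @param p0 per-SNP founder frequency.
#' @param type \code{"logit"} (default) or \code{"delta"} (raw p1 - p0).
#' @param clip frequencies are clipped into [clip, 1 - clip] before the
#'   logit (default 1e-4).
#'
#' @return gardens x SNP response matrix.
#' @export
egea_response <- function(p1, p0, type = c("logit", "delta"), clip = 1e-4) {
  type <- match.arg(type)
  if (is.list(p1)) p1 <- do.call(rbind, lapply(p1, colMeans))
  p1 <- as.matrix(p1)
  cl <- function(x) pmin(pmax(x, clip), 1 - clip)
  switch(type,
         logit = sweep(stats::qlogis(cl(p1)), 2, stats::qlogis(cl(p0))),
         delta = sweep(p1, 2, p0))
}

#' Kendall rank association of frequency change with climate
#'
#' Per-SNP Kendall tau between the per-garden response (mean frequency
#' change) and a garden climate variable; robust to nonlinear but
#' monotone climate responses. Exact p-values for small garden numbers
#' (no ties), normal approximation otherwise.
#'
#' @param response gardens x SNP matrix (see \code{\link{egea_response}}).
#' @param climate numeric climate value per garden.
#'
#' @return data.frame with per-SNP \code{tau} and \code{p}.
#' @export
egea_kendall <- function(response, climate) {
  response <- as.matrix(response)
  if (nrow(response) < 5) stop("need >= 5 gardens")
  if (stats::sd(climate) == 0) stop("climate is constant across gardens")
  res <- apply(response, 2, function(y) {
    if (stats::sd(y) == 0) return(c(tau = 0, p = 1))
    ct <- suppressWarnings(stats::cor.test(y, climate, method = "kendall"))
    c(tau = unname(ct$estimate), p = ct$p.value)
  })
  data.frame(tau = res["tau", ], p = res["p", ])
}

#' Binomial GLM association of allele counts with climate
#'
#' Per-SNP quasi-binomial regression of alt/depth on garden climate with
#' depth weights, accounting for variable pool sizes; overdispersion is
#' estimated by Pearson chi-square / df, Wald p on the climate slope.
#' Complete separation is flagged and the p-value taken from a
#' ridge-penalized refit.
#'
#' @param alt,dep observations x SNP matrices of alt counts and depths
#'   (one row per garden or garden-replicate).
#' @param climate climate value per observation (row).
#'
#' @return data.frame with per-SNP \code{slope}, \code{p},
#'   \code{dispersion} and \code{separated} flag.
#' @export
egea_glm <- function(alt, dep, climate) {
  alt <- as.matrix(alt); dep <- as.matrix(dep)
  n_snp <- ncol(alt)
  slope <- p <- disp <- numeric(n_snp)
  sep <- logical(n_snp)
  for (j in seq_len(n_snp)) {
    ok <- dep[, j] > 0
    if (sum(ok) < 3) { slope[j] <- NA; p[j] <- NA; next }
    y <- alt[ok, j] / dep[ok, j]
    fit <- suppressWarnings(
      stats::glm(y ~ climate[ok], family = stats::quasibinomial(),
                 weights = dep[ok, j]))
    mu <- stats::fitted(fit)
    separated <- !fit$converged || any(mu < 1e-8) || any(mu > 1 - 1e-8)
    sep[j] <- separated
    if (!separated) {
      sm <- summary(fit)$coefficients
      slope[j] <- sm[2, 1]; p[j] <- sm[2, 4]
      disp[j] <- summary(fit)$dispersion
    } else {
      rf <- ridge_logistic(cbind(1, climate[ok]), y, dep[ok, j], lambda = 0.5)
      slope[j] <- rf$beta[2]
      p[j] <- 2 * stats::pnorm(-abs(rf$beta[2] / rf$se[2]))
      disp[j] <- NA_real_
    }
  }
  data.frame(slope = slope, p = p, dispersion = disp, separated = sep)
}

# minimal ridge-penalized binomial IRLS; se from the penalized Fisher
# information. Used only as a fallback under complete separation.
ridge_logistic <- function(X, y, w, lambda = 0.5, maxit = 50) {
  beta <- rep(0, ncol(X))
  # intercept nearly unpenalized; the tiny ridge keeps the Hessian
  # nonsingular when the weights collapse (e.g. all-one outcomes)
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- lambda * 1e-3
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    W <- w * mu * (1 - mu)
    H <- crossprod(X, X * W) + 2 * pen
    g <- crossprod(X, w * (y - mu)) - 2 * pen %*% beta
    step <- solve(H, g)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < 1e-8) break
  }
  eta <- as.numeric(X %*% beta); mu <- stats::plogis(eta)
  H <- crossprod(X, X * (w * mu * (1 - mu))) + 2 * pen
  list(beta = beta, se = sqrt(diag(solve(H))))
}

#' Latent-factor-corrected linear association
#'
#' Light-weight latent-factor correction for shared structure in the
#' garden x SNP response: the top k principal factors of the response
#' matrix are regressed out of both the response and the climate
#' variable, and the association p comes from the residual linear model
#' (df = n_gardens - 2 - k). With k = 0 this is the plain per-SNP linear
#' regression. This is a PC-residualization stand-in for a full latent
#' factor mixed model.
#'
#' @param response gardens x SNP matrix.
#' @param climate climate value per garden.
#' @param k_factors number of latent factors to remove (0 <=
#'   k < n_gardens - 1).
#'
#' @return data.frame with per-SNP \code{slope}, \code{t} and \code{p}.
#' @export
egea_latent_factor <- function(response, climate, k_factors = 1) {
  Y <- as.matrix(response)
  n <- nrow(Y)
  if (n < k_factors + 2) stop("need >= k_factors + 2 gardens")
  if (k_factors >= n - 1) stop("k_factors must be < n_gardens - 1")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  x <- as.numeric(scale(climate, center = TRUE, scale = FALSE))
  if (k_factors > 0) {
    U <- stats::prcomp(Yc, center = FALSE)$x[, seq_len(k_factors), drop = FALSE]
    P <- diag(n) - U %*% solve(crossprod(U), t(U))
    Yc <- P %*% Yc
    x <- as.numeric(P %*% x)
  }
  sxx <- sum(x^2)
  if (sxx < .Machine$double.eps) stop("climate has no residual variance after factor removal")
  slope <- as.numeric(crossprod(Yc, x)) / sxx
  df <- n - 2 - k_factors
  rss <- colSums(Yc^2) - slope^2 * sxx
  se <- sqrt(pmax(rss, 0) / pmax(df, 1) / sxx)
  tt <- slope / se
  p <- 2 * stats::pt(-abs(tt), df = df)
  p[!is.finite(p)] <- 1
  data.frame(slope = slope, t = tt, p = p)
}

#' Weighted-Z pooling of per-SNP p-values into LD blocks
#'
#' WZA: per-SNP p-values are converted to z-scores z = qnorm(1 - p),
#' pooled within each LD block as sum(w z) / sqrt(sum(w^2)) with
#' founder-heterozygosity weights w = p(1-p) (uniform weights
#' available), and the block z-scores are inflation-corrected by a
#' median-based lambda on z^2 before computing one-sided block p-values.
#'
#' @param p per-SNP p-values (p = 0 clipped to machine minimum with a
#'   warning).
#' @param partition an \code{ld_blocks} partition covering every SNP.
#' @param weights per-SNP weights; default founder heterozygosity
#'   p(1-p) from \code{panel}, or uniform when neither is given.
#' @param panel optional \code{\link{founder_panel}} used to compute
#'   heterozygosity weights.
#' @param inflation_correct apply the median-lambda correction
#'   (default TRUE).
#'
#' @return data.frame per block: \code{block, z, z_corrected, p,
#'   n_snps}; attribute \code{lambda} carries the inflation factor.
#' @export
wza_pool <- function(p, partition, weights = NULL, panel = NULL,
                     inflation_correct = TRUE) {
  if (any(p <= 0, na.rm = TRUE)) {
    warning("p-values of 0 clipped to machine minimum")
    p[p <= 0] <- .Machine$double.xmin
  }
  bo <- partition$block_of
  if (length(p) != length(bo)) stop("p-values not aligned to the SNP partition")
  if (is.null(weights)) {
    if (!is.null(panel)) {
      q <- colMeans(impute_genotypes(panel$genotypes))
      weights <- q * (1 - q)
      weights[weights == 0] <- 1e-6
    } else weights <- rep(1, length(p))
  }
  z <- stats::qnorm(1 - pmin(p, 1 - 1e-16))
  ok <- !is.na(z)
  zb <- vapply(split(seq_along(z)[ok], bo[ok]), function(ix) {
    w <- weights[ix]
    sum(w * z[ix]) / sqrt(sum(w^2))
  }, numeric(1))
  lambda <- 1
  zc <- zb
  if (inflation_correct && length(zb) > 1) {
    lambda <- stats::median(zb^2, na.rm = TRUE) / stats::qchisq(0.5, 1)
    if (is.finite(lambda) && lambda > 0) zc <- zb / sqrt(lambda)
  }
  out <- data.frame(block = as.integer(names(zb)), z = as.numeric(zb),
                    z_corrected = as.numeric(zc),
                    p = stats::pnorm(as.numeric(zc), lower.tail = FALSE),
                    n_snps = as.integer(table(bo[ok])))
  out <- out[order(out$block), ]
  rownames(out) <- NULL
  attr(out, "lambda") <- lambda
  out
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up BH q-values (monotone) for block-level p-values.
#'
#' @param p vector of p-values in (0, 1].
#'
#' @return q-values, same length and order as \code{p}.
#' @export
fdr_correct <- function(p) {
  stats::p.adjust(p, method = "BH")
}
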