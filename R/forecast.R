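clip01 <- function(p, eps = 1e-4) pmin(pmax(p, eps), 1 - eps)

#' Logistic allele-frequency trajectories
#'
#' Fits logit(p) linearly against a predictor (year/generation, or
#' garden climate), giving the logistic rate parameter beta =
#' d logit(p) / d predictor per allele; betas can be averaged within LD
#' blocks.
#'
#' @param p observations x SNP matrix (or vector) of allele frequencies,
#'   clipped into [1e-4, 1 - 1e-4].
#' @param predictor numeric predictor per observation (>= 3 values).
#' @param partition optional \code{ld_blocks}; when given, per-block
#'   mean betas are returned as well.
#'
#' @return list with per-SNP data.frame (\code{beta, intercept, se, p})
#'   and optional \code{block_beta}.
#' @export
fit_logistic_trajectory <- function(p, predictor, partition = NULL) {
  P <- as.matrix(p)
  if (nrow(P) == 1) P <- t(P)
  if (nrow(P) < 3) stop("need >= 3 observations; trajectory skipped")
  Y <- stats::qlogis(clip01(P))
  x <- as.numeric(predictor)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  beta <- as.numeric(crossprod(Y, xc)) / sxx
  intercept <- colMeans(Y) - beta * mean(x)
  df <- nrow(P) - 2
  fittedY <- outer(xc, beta) + rep(colMeans(Y), each = nrow(P))
  rss <- colSums((Y - fittedY)^2)
  se <- sqrt(rss / pmax(df, 1) / sxx)
  tt <- ifelse(se > 0, beta / se, 0)
  pv <- 2 * stats::pt(-abs(tt), df = pmax(df, 1))
  snp <- data.frame(beta = beta, intercept = intercept, se = se, p = pv)
  block_beta <- NULL
  if (!is.null(partition)) {
    bb <- tapply(beta, partition$block_of, mean)
    block_beta <- data.frame(block = as.integer(names(bb)),
                             beta = as.numeric(bb))
    block_beta <- block_beta[order(block_beta$block), ]
    rownames(block_beta) <- NULL
  }
  list(snp = snp, block_beta = block_beta)
}

#' Selection coefficient from an allele-frequency trajectory
#'
#' Haploid-lineage (selfing) competition model: the carrier lineage's
#' odds multiply by (1 + s) each generation, so s_hat =
#' exp(per-generation logit slope) - 1. CI is transformed from the
#' slope's 95 percent CI; with exactly two timepoints the estimate is
#' exact and the CI is NA (no residual df).
#'
#' @param p allele frequency per timepoint (clipped away from 0/1).
#' @param generations generation index per timepoint (default
#'   0..length(p)-1).
#'
#' @return A \code{selection_estimate}: \code{s}, \code{ci},
#'   \code{slope}, \code{n_generations}.
#' @export
estimate_selection_coefficient <- function(p, generations = seq_along(p) - 1) {
  if (length(p) < 2) stop("need >= 2 timepoints")
  y <- stats::qlogis(clip01(as.numeric(p)))
  x <- as.numeric(generations)
  if (length(p) == 2) {
    slope <- diff(y) / diff(x)
    return(structure(list(s = exp(slope) - 1, ci = c(NA_real_, NA_real_),
                          slope = slope, n_generations = diff(range(x))),
                     class = "selection_estimate"))
  }
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[[2]]
  ci <- tryCatch(suppressWarnings(suppressMessages(stats::confint(fit)))[2, ],
                 error = function(e) c(NA_real_, NA_real_))
  structure(list(s = exp(slope) - 1, ci = exp(as.numeric(ci)) - 1,
                 slope = slope, n_generations = diff(range(x))),
            class = "selection_estimate")
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat(sprintf("s = %+.3f per generation [95%% CI %.3f, %.3f] over %g generations\n",
              x$s, x$ci[1], x$ci[2], x$n_generations))
  invisible(x)
}

#' Fit per-SNP climate clines for genomic offset
#'
#' Trains the genomic-offset model: for each SNP, the evolved allele
#' frequency across training gardens is regressed on garden climate on
#' the logit scale, giving a logistic cline p_adapt(z) = plogis(a + b z)
#' that maps any query climate to the locally adaptive allele frequency.
#'
#' @param p1 training gardens x SNP matrix of evolved allele frequencies
#'   (replicate means).
#' @param climate climate value per training garden (>= 3 gardens).
#' @param snp_subset integer indices of SNPs to use (default all;
#'   typically the significant eGEA blocks of the training gardens).
#'
#' @return An \code{offset_model}: \code{intercept}, \code{slope} per
#'   SNP, \code{snp_subset}, \code{climate_range}.
#' @export
fit_genomic_offset <- function(p1, climate, snp_subset = NULL) {
  P <- as.matrix(p1)
  if (nrow(P) < 3) stop("need >= 3 training gardens")
  if (length(climate) != nrow(P)) stop("one climate value per training garden")
  if (is.null(snp_subset)) snp_subset <- seq_len(ncol(P))
  if (length(snp_subset) == 0) stop("empty SNP subset")
  Y <- stats::qlogis(clip01(P[, snp_subset, drop = FALSE]))
  x <- as.numeric(climate)
  xc <- x - mean(x)
  b <- as.numeric(crossprod(Y, xc)) / sum(xc^2)
  a <- colMeans(Y) - b * mean(x)
  structure(list(intercept = a, slope = b, snp_subset = snp_subset,
                 climate_range = range(x)),
            class = "offset_model")
}

#' Adaptive allele frequencies predicted at a query climate
#'
#' @param model an \code{offset_model}.
#' @param z_query climate value.
#'
#' @return per-SNP p_adapt in (0, 1), over the model's SNP subset.
#' @export
predict_adaptive_freq <- function(model, z_query) {
  clip01(stats::plogis(model$intercept + model$slope * z_query), 1e-6)
}

#' Genomic offset score per accession
#'
#' Mismatch between the climate-predicted adaptive allele frequencies
#' and an accession's genome: GO = (1/n) sum_i |p_adapt,i - X_i| over
#' the model's SNP subset (X the accession dosage). Lower scores mean
#' the genotype is predicted to fit the query climate better.
#'
#' @param model an \code{offset_model}.
#' @param z_query climate of the garden to score against.
#' @param panel a \code{\link{founder_panel}}.
#'
#' @return named numeric vector of offsets in [0, 1], one per accession.
#' @export
go_score <- function(model, z_query, panel) {
  p_adapt <- predict_adaptive_freq(model, z_query)
  X <- impute_genotypes(panel$genotypes)[, model$snp_subset, drop = FALSE]
  out <- rowMeans(abs(sweep(X, 2, p_adapt)))
  stats::setNames(as.numeric(out), panel$accession_ids)
}

# stabilizing-selection predicted log fitness per accession at climate z
stabsel_predicted_logw <- function(fit, panel, z_query, climate_var) {
  acc <- fit$accessions
  lw <- acc$log_W_max - acc$V_s_inv *
    (panel$z_origin[match(acc$accession, panel$accession_ids), climate_var] - z_query)^2
  lw[acc$skipped] <- NA
  stats::setNames(lw, acc$accession)
}

#' Leave-one-out predictability of evolutionary trajectories
#'
#' For each garden in turn, a genomic-offset model (and optionally
#' stabilizing-selection parameters) is trained on the remaining gardens
#' and used to rank the founder accessions by predicted performance at
#' the held-out garden's climate; predictability is the Spearman
#' correlation between that ranking and the observed per-accession
#' log(p1/p0) in each held-out replicate.
#'
#' Scorers: \code{"go"} ranks by -GO; \code{"go_plus_stabsel"} adds the
#' z-scored stabilizing-selection predicted log-fitness to the z-scored
#' -GO; \code{"climate_distance"} ranks by -(z_origin - z_garden)^2 and
#' uses no genomic training.
#'
#' @param p1_garden gardens x SNP matrix of evolved allele frequencies
#'   (replicate means), for offset training.
#' @param acc_f0,acc_f1 lists (one per garden) of replicates x accession
#'   matrices of founder-accession frequencies at t0 and t1.
#' @param climates climate value per garden (>= 3 gardens).
#' @param panel the \code{\link{founder_panel}}.
#' @param scorer prediction rule (see above).
#' @param climate_var climate variable name for the stabsel/climate
#'   scorers.
#' @param snp_subset optional SNP indices for the offset model (default
#'   all SNPs).
#' @param epsilon pseudo-frequency for the observed log ratios.
#'
#' @return data.frame: garden, replicate, r (Spearman), r2.
#' @export
loo_predictability <- function(p1_garden, acc_f0, acc_f1, climates, panel,
                               scorer = c("go", "go_plus_stabsel",
                                          "climate_distance"),
                               climate_var = "bio1", snp_subset = NULL,
                               epsilon = 1e-4) {
  scorer <- match.arg(scorer)
  n_g <- length(climates)
  if (n_g < 3) stop("need >= 3 gardens for leave-one-out")
  zsc <- function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) return(v * 0)
    (v - mean(v, na.rm = TRUE)) / s
  }
  out <- list()
  for (g in seq_len(n_g)) {
    train <- setdiff(seq_len(n_g), g)
    score <- NULL
    if (scorer == "climate_distance") {
      d2 <- (panel$z_origin[, climate_var] - climates[g])^2
      score <- -d2
    } else {
      om <- fit_genomic_offset(p1_garden[train, , drop = FALSE],
                               climates[train], snp_subset = snp_subset)
      score <- -go_score(om, climates[g], panel)
      if (scorer == "go_plus_stabsel") {
        lr <- do.call(rbind, lapply(train, function(tg) {
          f0m <- colMeans(acc_f0[[tg]]); f1m <- colMeans(acc_f1[[tg]])
          data.frame(accession = panel$accession_ids, garden = tg,
                     f0 = f0m, f1 = f1m,
                     log_ratio = log((f1m + epsilon) / (f0m + epsilon)),
                     excluded = f0m < 1e-5)
        }))
        d2 <- (panel$z_origin[match(lr$accession, panel$accession_ids),
                              climate_var] - climates[lr$garden])^2
        sfit <- fit_per_accession(lr, d2, min_gardens = 3)
        lw <- stabsel_predicted_logw(sfit, panel, climates[g], climate_var)
        score <- zsc(score) + zsc(lw[panel$accession_ids])
      }
    }
    reps <- nrow(acc_f1[[g]])
    for (r in seq_len(reps)) {
      obs <- log((acc_f1[[g]][r, ] + epsilon) / (acc_f0[[g]][r, ] + epsilon))
      rho <- suppressWarnings(
        stats::cor(score, obs, method = "spearman",
                   use = "pairwise.complete.obs"))
      out[[length(out) + 1]] <- data.frame(garden = g, replicate = r,
                                           r = rho, r2 = rho^2,
                                           scorer = scorer)
    }
  }
  do.call(rbind, out)
}

#' Survival model on evolutionary predictability and climate
#'
#' Logistic regression of replicate survival on leave-one-out
#' predictability (r^2), garden temperature, and their interaction.
#' Complete separation or degenerate outcomes (all survived/died)
#' trigger a flagged ridge-penalized refit instead of an error.
#' Survival-probability isolines are obtained by solving the fitted
#' model for a given survival probability as a function of temperature.
#'
#' @param records data.frame with columns \code{r2}, \code{temp} and
#'   logical/0-1 \code{survived} (>= 20 records recommended).
#' @param prob isoline survival probability (default 0.5).
#' @param temp_grid temperatures at which to evaluate the isoline.
#'
#' @return list with \code{coef}, \code{se}, \code{p}, \code{flagged}
#'   (degenerate or separated fit), and \code{isoline} data.frame
#'   (temp, r2_required).
#' @export
survival_model <- function(records, prob = 0.5, temp_grid = NULL) {
  if (nrow(records) < 20)
    warning("fewer than 20 records; survival model will be unstable")
  y <- as.numeric(records$survived)
  flagged <- FALSE
  if (length(unique(y)) < 2) {
    flagged <- TRUE
    X <- cbind(1, records$r2, records$temp, records$r2 * records$temp)
    rf <- ridge_logistic(X, y, rep(1, length(y)), lambda = 1)
    cf <- rf$beta; se <- rf$se
  } else {
    fit <- suppressWarnings(
      stats::glm(y ~ r2 * temp, data = records, family = stats::binomial()))
    mu <- stats::fitted(fit)
    if (!fit$converged || any(mu < 1e-8) || any(mu > 1 - 1e-8)) {
      flagged <- TRUE
      X <- stats::model.matrix(~ r2 * temp, records)
      rf <- ridge_logistic(X, y, rep(1, length(y)), lambda = 1)
      cf <- rf$beta; se <- rf$se
    } else {
      sm <- summary(fit)$coefficients
      cf <- sm[, 1]; se <- sm[, 2]
    }
  }
  names(cf) <- names(se) <- c("(Intercept)", "r2", "temp", "r2:temp")
  pv <- 2 * stats::pnorm(-abs(cf / se))
  if (is.null(temp_grid))
    temp_grid <- seq(min(records$temp), max(records$temp), length.out = 25)
  # solve plogis(b0 + b1 r2 + b2 T + b3 r2 T) = prob for r2
  lo <- stats::qlogis(prob)
  denom <- cf["r2"] + cf["r2:temp"] * temp_grid
  r2_req <- ifelse(abs(denom) > 1e-12,
                   (lo - cf["(Intercept)"] - cf["temp"] * temp_grid) / denom,
                   NA_real_)
  list(coef = cf, se = se, p = pv, flagged = flagged,
       isoline = data.frame(temp = temp_grid, r2_required = r2_req))
}

#' Census trajectory (evolutionary rescue) fit
#'
#' Pools replicate census counts per garden and fits a second-degree
#' polynomial of census size on generation. A rebound (U-shaped,
#' rescue-like) trajectory is flagged when the quadratic coefficient is
#' positive with an interior minimum inside the observed generation
#' range and the coefficient is significant (p < 0.05) or the fit is
#' exact (saturated, zero residual df).
#'
#' @param census data.frame with columns \code{generation} and
#'   \code{census} (one row per replicate x generation; a \code{garden}
#'   column is respected, fitting each garden separately).
#'
#' @return data.frame per garden: intercept, linear, quadratic, p_quad,
#'   minimum_at, rebound, n_points; gardens with < 3 distinct
#'   timepoints are skipped (NA row).
#' @export
census_trajectory <- function(census) {
  if (is.null(census$garden)) census$garden <- "garden1"
  out <- lapply(split(census, census$garden), function(d) {
    base <- data.frame(garden = d$garden[1], intercept = NA_real_,
                       linear = NA_real_, quadratic = NA_real_,
                       p_quad = NA_real_, minimum_at = NA_real_,
                       rebound = NA, n_points = nrow(d))
    if (length(unique(d$generation)) < 3) return(base)
    fit <- stats::lm(census ~ generation + I(generation^2), data = d)
    cf <- stats::coef(fit)
    sm <- suppressWarnings(summary(fit))$coefficients
    saturated <- fit$df.residual == 0 ||
      (nrow(sm) == 3 && all(abs(stats::residuals(fit)) < 1e-8))
    p_quad <- if (nrow(sm) >= 3 && !saturated) sm[3, 4] else NA_real_
    quad <- unname(cf[3])
    if (is.na(quad)) quad <- 0                       # collinear: straight line
    min_at <- if (quad > 0) -unname(cf[2]) / (2 * quad) else NA_real_
    interior <- !is.na(min_at) &&
      min_at > min(d$generation) && min_at < max(d$generation)
    rebound <- quad > 0 && interior &&
      (saturated || (!is.na(p_quad) && p_quad < 0.05))
    base$intercept <- unname(cf[1]); base$linear <- unname(cf[2])
    base$quadratic <- quad; base$p_quad <- p_quad
    base$minimum_at <- if (interior) min_at else NA_real_
    base$rebound <- rebound
    base
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
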