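#' Log fitness ratios from accession frequency trajectories
#'
#' In a selfing founder mix, the ratio of an accession's relative
#' frequency across one generation is a proxy of its relative fitness
#' (p_t+1 / p_t = w / w_bar). This computes log((p_t1 + eps)/(p_t0 +
#' eps)) per accession x garden x replicate, flagging records whose
#' starting frequency is below the exclusion threshold.
#'
#' @param f0,f1 accession frequencies at the two timepoints; either
#'   numeric vectors (one replicate) or long data.frames with columns
#'   \code{accession, garden, replicate, freq}.
#' @param epsilon pseudo-frequency added to numerator and denominator
#'   (default 1e-4, about half a flower in a 5,000-seed pool).
#' @param exclude_below records with \code{f0} under this threshold are
#'   flagged \code{excluded} (default 1e-5).
#'
#' @return data.frame with \code{log_ratio}, \code{boundary} (f0 or f1
#'   was 0) and \code{excluded} flags, plus any id columns supplied.
#' @export
log_fitness_ratios <- function(f0, f1, epsilon = 1e-4, exclude_below = 1e-5) {
  if (is.data.frame(f0)) {
    ids <- f0[setdiff(names(f0), "freq")]
    v0 <- f0$freq; v1 <- f1$freq
  } else {
    ids <- data.frame(accession = seq_along(f0))
    v0 <- as.numeric(f0); v1 <- as.numeric(f1)
  }
  lr <- log((v1 + epsilon) / (v0 + epsilon))
  cbind(ids, data.frame(f0 = v0, f1 = v1, log_ratio = lr,
                        boundary = v0 == 0 | v1 == 0,
                        excluded = v0 < exclude_below))
}

#' Global Gaussian stabilizing-selection fit
#'
#' Fits log(p_t+1/p_t) = log(W_max / w_bar_g) - V_s_inv * (z_origin -
#' z_garden)^2 jointly over accessions and gardens: a linear model of
#' the log fitness ratio on the negative squared climate distance with
#' garden fixed offsets (one garden anchored at zero; soft-selection
#' normalization). The slope is the species-wide strength of stabilizing
#' selection V_s_inv.
#'
#' @param ratios data.frame from \code{\link{log_fitness_ratios}} with
#'   columns \code{log_ratio, garden} (excluded records are dropped).
#' @param dist2 squared climate distance per row of \code{ratios}.
#'
#' @return list with \code{V_s_inv}, \code{se}, \code{ci} (95 percent),
#'   \code{r_squared}, \code{p}, \code{offsets} (per-garden log mean
#'   fitness, first garden = 0), \code{n}.
#' @export
fit_global_stabilizing <- function(ratios, dist2) {
  df <- data.frame(log_ratio = ratios$log_ratio, garden = ratios$garden,
                   dist2 = dist2)
  if (!is.null(ratios$excluded)) df <- df[!ratios$excluded, ]
  df <- df[is.finite(df$log_ratio) & is.finite(df$dist2), ]
  if (stats::var(df$dist2) == 0) stop("no variance in squared climate distance")
  df$garden <- factor(df$garden)
  fit <- stats::lm(log_ratio ~ garden + I(-dist2), data = df)
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  slope_row <- rownames(cf) == "I(-dist2)"
  est <- cf[slope_row, 1]; se <- cf[slope_row, 2]
  ci <- est + c(-1, 1) * stats::qt(0.975, fit$df.residual) * se
  offs <- c(0, stats::coef(fit)[grep("^garden", names(stats::coef(fit)))])
  names(offs) <- levels(df$garden)
  list(V_s_inv = unname(est), se = unname(se), ci = ci,
       r_squared = sm$r.squared, p = cf[slope_row, 4],
       offsets = offs, n = nrow(df))
}

#' Per-accession stabilizing-selection fits
#'
#' Accession-specific niches: one joint linear model with an intercept
#' (log W_max) and a negative-squared-distance slope (V_s_inv) per
#' accession plus shared garden offsets (first garden anchored at zero,
#' so the offsets are identified only up to a constant). Joint
#' estimation keeps the offsets consistent when niche widths vary
#' between accessions, so noiseless model data are recovered exactly.
#' Negative slopes are truncated at 0 with a flag; accessions observed
#' in fewer than \code{min_gardens} gardens are skipped with a reason.
#'
#' @param ratios data.frame from \code{\link{log_fitness_ratios}} with
#'   \code{accession, garden, log_ratio}.
#' @param dist2 squared climate distance per row.
#' @param min_gardens minimum distinct gardens per fitted accession
#'   (default 3).
#'
#' @return A \code{stabilizing_fit}: data.frame \code{accessions}
#'   (accession, log_W_max, W_max, V_s_inv, se, truncated, n_gardens,
#'   skipped, reason), shared \code{offsets}, and the global fit.
#' @export
fit_per_accession <- function(ratios, dist2, min_gardens = 3) {
  glob <- fit_global_stabilizing(ratios, dist2)
  df <- data.frame(accession = as.character(ratios$accession),
                   garden = as.character(ratios$garden),
                   log_ratio = ratios$log_ratio, dist2 = dist2,
                   excluded = if (is.null(ratios$excluded)) FALSE else ratios$excluded)
  df <- df[!df$excluded & is.finite(df$log_ratio), ]
  ord <- unique(df$accession)          # preserve input accession order
  ng_of <- tapply(df$garden, df$accession, function(g) length(unique(g)))[ord]
  dvar <- tapply(df$dist2, df$accession, stats::var)[ord]
  all_acc <- ord
  fit_ok <- ng_of >= min_gardens & dvar > 0
  sub <- df[df$accession %in% all_acc[fit_ok], ]
  sub$acc <- factor(sub$accession)
  sub$gard <- factor(sub$garden)
  sub$nd2 <- -sub$dist2
  fit <- suppressWarnings(
    stats::lm(log_ratio ~ 0 + acc + acc:nd2 + gard, data = sub))
  cf <- stats::coef(fit)
  se_all <- tryCatch(suppressWarnings(summary(fit))$coefficients[, 2],
                     error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                                         names(cf)))
  lev <- levels(sub$acc)
  ic <- cf[paste0("acc", lev)]
  sl <- cf[paste0("acc", lev, ":nd2")]
  sl_se <- se_all[paste0("acc", lev, ":nd2")]
  offs <- c(0, cf[grep("^gard", names(cf))])
  names(offs) <- levels(sub$gard)
  acc <- data.frame(accession = all_acc,
                    log_W_max = NA_real_, W_max = NA_real_,
                    V_s_inv = NA_real_, se = NA_real_, truncated = FALSE,
                    n_gardens = as.integer(ng_of),
                    skipped = !fit_ok,
                    reason = ifelse(ng_of < min_gardens,
                                    sprintf("seen in %d < %d gardens",
                                            ng_of, min_gardens),
                                    ifelse(dvar <= 0,
                                           "no variance in climate distance", "")))
  m <- match(lev, acc$accession)
  acc$log_W_max[m] <- unname(ic)
  acc$W_max[m] <- exp(unname(ic))
  acc$V_s_inv[m] <- pmax(0, unname(sl))
  acc$se[m] <- unname(sl_se)
  acc$truncated[m] <- !is.na(sl) & sl < 0
  rownames(acc) <- NULL
  structure(list(accessions = acc, offsets = offs, global = glob),
            class = "stabilizing_fit")
}

#' @export
print.stabilizing_fit <- function(x, ...) {
  ok <- !x$accessions$skipped
  cat(sprintf("stabilizing_fit: %d accessions fitted (%d skipped); global V_s_inv = %.4g (R2 = %.3f)\n",
              sum(ok), sum(!ok), x$global$V_s_inv, x$global$r_squared))
  invisible(x)
}

#' Specialist-generalist trade-off
#'
#' Spearman correlation between fitted maximum fitness W_max and niche
#' narrowness V_s_inv across accessions: a positive correlation means
#' high-peak accessions pay with faster fitness decay away from their
#' climate of origin (specialists), while flat-niche generalists have
#' lower peaks.
#'
#' @param fit a \code{stabilizing_fit}.
#'
#' @return list with \code{rho}, \code{p}, \code{n}, and
#'   \code{degenerate} flag (constant V_s_inv or W_max; correlation
#'   undefined).
#' @export
niche_tradeoff <- function(fit) {
  acc <- fit$accessions[!fit$accessions$skipped, ]
  if (nrow(acc) < 10) stop("need >= 10 fitted accessions")
  if (stats::sd(acc$V_s_inv) < 1e-10 || stats::sd(acc$log_W_max) < 1e-10)
    return(list(rho = NA_real_, p = NA_real_, n = nrow(acc), degenerate = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(acc$log_W_max, acc$V_s_inv, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(acc),
       degenerate = FALSE)
}

#' Realized climatic optimum and adaptation lag per accession
#'
#' Estimates where along the garden climate gradient each accession
#' performed best: the frequency-weighted mean garden climate, with
#' weights either the fitness proxy p1/p0 or the evolved frequency p1.
#' The adaptation lag is the realized optimum minus the climate at the
#' accession's origin; negative values mean the accession now performs
#' best in climates colder than its home.
#'
#' @param acc_freq long data.frame with \code{accession, garden, f0, f1}
#'   (replicates already averaged, or one row per replicate).
#' @param garden_climate named vector: climate value per garden.
#' @param z_origin named vector: climate of origin per accession.
#' @param weight \code{"ratio"} (p1/p0, default) or \code{"p1"}.
#'
#' @return data.frame: accession, z_opt, lag, n_gardens, undefined flag
#'   (all-zero weights).
#' @export
realized_optimum <- function(acc_freq, garden_climate, z_origin,
                             weight = c("ratio", "p1")) {
  weight <- match.arg(weight)
  out <- lapply(split(acc_freq, acc_freq$accession), function(d) {
    ag <- stats::aggregate(d[c("f0", "f1")], by = list(garden = d$garden), mean)
    if (nrow(ag) < 2)
      return(data.frame(accession = d$accession[1], z_opt = NA_real_,
                        lag = NA_real_, n_gardens = nrow(ag), undefined = TRUE))
    w <- switch(weight, ratio = ag$f1 / pmax(ag$f0, 1e-12), p1 = ag$f1)
    z <- garden_climate[as.character(ag$garden)]
    if (sum(w) <= 0 || all(!is.finite(w)))
      return(data.frame(accession = d$accession[1], z_opt = NA_real_,
                        lag = NA_real_, n_gardens = nrow(ag), undefined = TRUE))
    zo <- sum(w * z) / sum(w)
    data.frame(accession = d$accession[1], z_opt = zo,
               lag = zo - z_origin[[as.character(d$accession[1])]],
               n_gardens = nrow(ag), undefined = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
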