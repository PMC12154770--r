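#' Simulation parameters
#'
#' Parameters of the forward simulator: per-accession fitness peaks and
#' niche widths, tray carrying capacity, the seed-set (offspring number)
#' model, and the per-offspring outcrossing probability.
#'
#' @param W_max per-accession maximum fitness (recycled; relative units,
#'   >= 0).
#' @param V_s_inv per-accession strength of stabilizing selection, the
#'   rate of fitness decay per squared climate unit (recycled; >= 0).
#' @param carrying_capacity individuals retained per tray after density
#'   regulation.
#' @param fecundity mean seed set per individual before regulation; sets
#'   the size of the seed pool from which the next generation is drawn.
#' @param offspring_model \code{"uniform"} (seed set proportional to
#'   fitness, no extra stochasticity) or \code{"poisson"} (Poisson seed
#'   set with mean proportional to fitness).
#' @param outcross_rate probability that an offspring is an outcrossed
#'   recombinant rather than a selfed copy of its mother.
#' @param seed base RNG seed used by \code{\link{simulate_experiment}}.
#'
#' @return An object of class \code{sim_params}.
#' @export
sim_params <- function(W_max = 1, V_s_inv = 0, carrying_capacity = 100,
                       fecundity = 10,
                       offspring_model = c("uniform", "poisson"),
                       outcross_rate = 0, seed = NULL) {
  offspring_model <- match.arg(offspring_model)
  if (any(W_max < 0)) stop("W_max must be >= 0")
  if (any(V_s_inv < 0)) stop("V_s_inv must be >= 0")
  if (outcross_rate < 0 || outcross_rate > 1)
    stop("outcross_rate must be in [0, 1]")
  if (carrying_capacity < 1) stop("carrying_capacity must be >= 1")
  structure(list(W_max = W_max, V_s_inv = V_s_inv,
                 carrying_capacity = as.integer(carrying_capacity),
                 fecundity = fecundity,
                 offspring_model = offspring_model,
                 outcross_rate = outcross_rate, seed = seed),
            class = "sim_params")
}

#' Garden design
#'
#' @param garden_id garden label.
#' @param z_garden named numeric vector of garden climate values; names
#'   must match the founder panel's climate variables.
#' @param n_replicates number of independent replicate trays (default 12).
#' @param n_generations number of generations to simulate.
#' @param census_schedule generation indices at which a census is taken
#'   (default all generations).
#'
#' @return An object of class \code{garden_design}.
#' @export
garden_design <- function(garden_id, z_garden, n_replicates = 12,
                          n_generations = 1,
                          census_schedule = seq_len(n_generations)) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(garden_id = as.character(garden_id),
                 z_garden = z_garden,
                 n_replicates = as.integer(n_replicates),
                 n_generations = as.integer(n_generations),
                 census_schedule = as.integer(census_schedule)),
            class = "garden_design")
}

# initial population: capacity individuals drawn multinomially from the
# founder seed mix. Individuals are stored columnwise: mom accession index,
# and an optional recombinant genotype row (NULL = pure founder line).
init_population <- function(panel, params) {
  cnt <- as.vector(rmultinom(1, params$carrying_capacity, panel$start_freq))
  acc <- rep(seq_along(cnt), cnt)
  list(generation = 0L, acc = acc,
       geno = vector("list", length(acc)),
       census_size = length(acc), extinct = FALSE)
}

#' Advance one generation of accession sorting
#'
#' One generation of the life cycle: seed set proportional to relative
#' fitness (deterministic under \code{"uniform"}, Poisson under
#' \code{"poisson"}), selfed offspring copying the maternal genotype,
#' outcrossed offspring (probability \code{outcross_rate}) taking a
#' one-crossover-per-chromosome recombinant of two parents, then density
#' regulation by sampling without replacement down to the carrying
#' capacity (soft selection: mean fitness is an implicit normalizer).
#'
#' @param state population state as produced by
#'   \code{\link{simulate_experiment}} internals (fields: generation, acc,
#'   geno, census_size, extinct).
#' @param fitness per-accession expected fitness vector (from
#'   \code{\link{accession_fitness}}).
#' @param params a \code{\link{sim_params}}.
#' @param panel the \code{\link{founder_panel}} (needed for recombinant
#'   genotypes when \code{outcross_rate > 0}).
#'
#' @return The next population state. If every individual has fitness 0
#'   the returned state is empty with \code{extinct = TRUE} (no error).
#' @export
simulate_generation <- function(state, fitness, params, panel = NULL) {
  if (state$extinct || length(state$acc) == 0)
    return(modifyList(state, list(generation = state$generation + 1L,
                                  census_size = 0L, extinct = TRUE)))
  w <- fitness[state$acc]
  # recombinants: mid-parent fitness
  rec <- !vapply(state$geno, is.null, logical(1))
  if (any(rec)) {
    dad <- vapply(state$geno[rec], function(g) g$dad, integer(1))
    w[rec] <- (fitness[state$acc[rec]] + fitness[dad]) / 2
  }
  if (all(w <= 0))
    return(list(generation = state$generation + 1L, acc = integer(0),
                geno = list(), census_size = 0L, extinct = TRUE))
  n <- length(w)
  target <- params$fecundity * n * w / sum(w)   # expected seeds per parent
  n_seeds <- switch(params$offspring_model,
                    uniform = largest_remainder(target),
                    poisson = rpois(n, target))
  if (sum(n_seeds) == 0)
    return(list(generation = state$generation + 1L, acc = integer(0),
                geno = list(), census_size = 0L, extinct = TRUE))
  mother <- rep(seq_len(n), n_seeds)
  # density regulation: sample seeds without replacement down to capacity
  if (length(mother) > params$carrying_capacity)
    mother <- mother[sort(sample.int(length(mother), params$carrying_capacity))]
  acc2 <- state$acc[mother]
  geno2 <- state$geno[mother]
  if (params$outcross_rate > 0) {
    oc <- runif(length(mother)) < params$outcross_rate
    if (any(oc)) {
      fathers <- sample.int(n, sum(oc), replace = TRUE, prob = w / sum(w))
      oc_idx <- which(oc)
      for (k in seq_along(oc_idx)) {
        i <- oc_idx[k]
        geno2[[i]] <- recombine_individual(state, mother[i], fathers[k], panel)
      }
    }
  }
  list(generation = state$generation + 1L, acc = acc2, geno = geno2,
       census_size = length(acc2), extinct = FALSE)
}

# deterministic rounding of expected counts preserving the total
largest_remainder <- function(target) {
  fl <- floor(target)
  rem <- round(sum(target)) - sum(fl)
  if (rem > 0) {
    extra <- order(target - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

# genotype row of an individual (founder row or stored recombinant row)
individual_genotype <- function(state, i, panel) {
  g <- state$geno[[i]]
  if (is.null(g)) panel$genotypes[state$acc[i], ] else g$row
}

# one crossover uniformly placed per chromosome; offspring assumed
# immediately homozygous (instant inbred-line approximation for a selfer)
recombine_individual <- function(state, mom_i, dad_i, panel) {
  if (is.null(panel)) stop("panel required for outcrossing")
  gm <- individual_genotype(state, mom_i, panel)
  gd <- individual_genotype(state, dad_i, panel)
  out <- gm
  for (ch in unique(panel$snp_chrom)) {
    ix <- which(panel$snp_chrom == ch)
    bp <- sample.int(length(ix), 1)   # crossover after this SNP
    if (bp < length(ix)) {
      tail_ix <- ix[(bp + 1):length(ix)]
      out[tail_ix] <- gd[tail_ix]
    }
  }
  list(row = out, dad = state$acc[[dad_i]], recombinant = TRUE)
}

# accession (maternal-lineage) frequencies and mean allele frequencies of
# a population state
state_frequencies <- function(state, panel) {
  n_acc <- length(panel$accession_ids)
  if (length(state$acc) == 0)
    return(list(acc_freq = rep(NA_real_, n_acc),
                allele_freq = rep(NA_real_, length(panel$snp_pos))))
  acc_freq <- tabulate(state$acc, nbins = n_acc) / length(state$acc)
  rec <- !vapply(state$geno, is.null, logical(1))
  if (!any(rec)) {
    allele_freq <- as.numeric(crossprod(acc_freq, panel$genotypes))
  } else {
    pure_cnt <- tabulate(state$acc[!rec], nbins = n_acc)
    tot <- as.numeric(crossprod(pure_cnt, panel$genotypes))
    for (i in which(rec)) tot <- tot + state$geno[[i]]$row
    allele_freq <- tot / length(state$acc)
  }
  list(acc_freq = acc_freq, allele_freq = allele_freq)
}

#' Simulate a replicated multi-garden evolution experiment
#'
#' Runs the forward simulator for every garden x replicate over the
#' requested number of generations, recording true accession frequencies
#' (maternal lineages), true allele frequencies, census sizes and
#' extinction flags. Replicates within a garden differ only by their
#' random seed.
#'
#' @param panel a \code{\link{founder_panel}}.
#' @param gardens list of \code{\link{garden_design}} objects.
#' @param params a \code{\link{sim_params}}.
#' @param climate_var climate variable used for the fitness model.
#' @param seed optional seed overriding \code{params$seed}.
#'
#' @return An object of class \code{true_trajectories}: a list with
#'   \code{acc_freq[[garden]][[replicate]]} (generations+1 x accessions),
#'   \code{allele_freq[[garden]][[replicate]]} (generations+1 x SNPs),
#'   \code{census} (long data.frame) and \code{gardens}.
#' @export
simulate_experiment <- function(panel, gardens, params,
                                climate_var = "bio1", seed = NULL) {
  if (length(gardens) < 1) stop("need at least one garden")
  if (inherits(gardens, "garden_design")) gardens <- list(gardens)
  seed <- if (!is.null(seed)) seed else params$seed
  acc_out <- list(); frq_out <- list()
  census <- list()
  for (gi in seq_along(gardens)) {
    gd <- gardens[[gi]]
    fit <- accession_fitness(panel, params, gd$z_garden, climate_var)
    acc_out[[gd$garden_id]] <- list()
    frq_out[[gd$garden_id]] <- list()
    for (r in seq_len(gd$n_replicates)) {
      if (!is.null(seed)) set.seed((seed + 7919L * gi + 104729L * r) %% 2147483647L)
      st <- init_population(panel, params)
      A <- matrix(NA_real_, gd$n_generations + 1, length(panel$accession_ids))
      P <- matrix(NA_real_, gd$n_generations + 1, length(panel$snp_pos))
      fr <- state_frequencies(st, panel)
      A[1, ] <- fr$acc_freq; P[1, ] <- fr$allele_freq
      census[[length(census) + 1]] <-
        data.frame(garden = gd$garden_id, replicate = r, generation = 0L,
                   census = st$census_size, extinct = st$extinct)
      for (g in seq_len(gd$n_generations)) {
        st <- simulate_generation(st, fit, params, panel)
        fr <- state_frequencies(st, panel)
        A[g + 1, ] <- fr$acc_freq; P[g + 1, ] <- fr$allele_freq
        census[[length(census) + 1]] <-
          data.frame(garden = gd$garden_id, replicate = r, generation = g,
                     census = st$census_size, extinct = st$extinct)
      }
      acc_out[[gd$garden_id]][[r]] <- A
      frq_out[[gd$garden_id]][[r]] <- P
    }
  }
  structure(list(acc_freq = acc_out, allele_freq = frq_out,
                 census = do.call(rbind, census),
                 gardens = gardens, climate_var = climate_var),
            class = "true_trajectories")
}

#' Pool-seq observation of a population
#'
#' Emulates pooled sequencing of flowers sampled from a tray: flowers are
#' drawn multinomially over individuals (or directly from true accession
#' frequencies), per-SNP depth is Poisson, and alternate-read counts are
#' binomial around the pool allele frequency with a symmetric
#' substitution error.
#'
#' @param x either a population state (individual level) or a numeric
#'   vector of true accession frequencies (then \code{panel} supplies
#'   genotypes).
#' @param panel the \code{\link{founder_panel}}.
#' @param n_flowers number of flowers pooled (>= 1).
#' @param mean_depth mean sequencing depth per SNP (reads; >= 0).
#' @param seq_error symmetric ref<->alt substitution error rate
#'   (default 0.007).
#' @param meta optional named list of sample metadata (sample_id, garden,
#'   replicate, generation, date).
#' @param seed optional RNG seed.
#'
#' @return A \code{pool_sample}: list with per-SNP \code{ref_count},
#'   \code{alt_count}, \code{n_flowers}, the (sampled) pool allele
#'   frequency used, and metadata.
#' @export
sample_poolseq <- function(x, panel, n_flowers, mean_depth,
                           seq_error = 0.007, meta = list(), seed = NULL) {
  if (n_flowers < 1) stop("n_flowers must be >= 1")
  if (mean_depth < 0) stop("mean_depth must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.list(x) && !is.null(x$acc)) {             # population state
    if (length(x$acc) == 0) stop("no reproductive individuals to sample")
    picks <- sample.int(length(x$acc), n_flowers, replace = TRUE)
    cnt_acc <- tabulate(x$acc[picks], nbins = length(panel$accession_ids))
    rec <- which(!vapply(x$geno[picks], is.null, logical(1)))
    if (length(rec)) {
      cnt_pure <- tabulate(x$acc[picks][-rec], nbins = length(panel$accession_ids))
      tot <- as.numeric(crossprod(cnt_pure, panel$genotypes))
      for (i in picks[rec]) tot <- tot + x$geno[[i]]$row
      pool_p <- tot / n_flowers
    } else {
      pool_p <- as.numeric(crossprod(cnt_acc, panel$genotypes)) / n_flowers
    }
  } else {                                          # true accession freqs
    f <- as.numeric(x)
    if (any(is.na(f)) || length(f) != length(panel$accession_ids))
      stop("no reproductive individuals to sample")
    cnt <- as.vector(rmultinom(1, n_flowers, f))
    pool_p <- as.numeric(crossprod(cnt, panel$genotypes)) / n_flowers
  }
  G_imp <- impute_genotypes(panel$genotypes)
  # missing founder calls enter pool_p via imputation above only when the
  # panel has NAs; pool_p from crossprod would be NA there
  if (anyNA(pool_p)) {
    cntv <- if (exists("cnt", inherits = FALSE)) cnt else cnt_acc
    pool_p <- as.numeric(crossprod(cntv, G_imp)) / sum(cntv)
  }
  n_snp <- length(panel$snp_pos)
  depth <- rpois(n_snp, mean_depth)
  p_err <- pool_p * (1 - seq_error) + (1 - pool_p) * seq_error
  alt <- rbinom(n_snp, depth, pmin(pmax(p_err, 0), 1))
  structure(list(ref_count = depth - alt, alt_count = alt,
                 n_flowers = as.integer(n_flowers),
                 true_pool_freq = pool_p,
                 meta = meta),
            class = "pool_sample")
}

#' @export
print.pool_sample <- function(x, ...) {
  cat("pool_sample:", length(x$alt_count), "SNPs, mean depth",
      round(mean(x$ref_count + x$alt_count), 2), "from", x$n_flowers,
      "flowers\n")
  invisible(x)
}
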