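#' Species x strain occurrence matrix
#'
#' @param counts Integer matrix of specimen counts (rows = species, columns =
#'   strains), all >= 0, with dimnames.
#' @param n_specimens Named vector of total specimens screened per species;
#'   defaults to the row sums (i.e. every specimen infected).
#' @return Object of class `occurrence_matrix`.
#' @export
occurrence_matrix <- function(counts, n_specimens = NULL) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            all(counts >= 0))
  storage.mode(counts) <- "integer"
  if (is.null(n_specimens))
    n_specimens <- setNames(rowSums(counts), rownames(counts))
  n_specimens <- n_specimens[rownames(counts)]
  structure(list(counts = counts, n_specimens = n_specimens),
            class = "occurrence_matrix")
}

#' Species with at least one infected specimen
#'
#' @param occ An [occurrence_matrix()].
#' @return Character vector of infected species.
#' @export
infected_species <- function(occ) {
  stopifnot(inherits(occ, "occurrence_matrix"))
  rownames(occ$counts)[rowSums(occ$counts) > 0]
}

species_strains <- function(occ, species) {
  if (!species %in% rownames(occ$counts))
    stop("unknown species: ", species)
  colnames(occ$counts)[occ$counts[species, ] > 0]
}

#' Number of strains shared by two species
#'
#' @param occ An [occurrence_matrix()].
#' @param pair Character vector of two species names.
#' @return Size of the intersection of the two species' strain sets.
#' @export
shared_strain_count <- function(occ, pair) {
  stopifnot(length(pair) == 2)
  length(intersect(species_strains(occ, pair[1]),
                   species_strains(occ, pair[2])))
}

#' Mean cross-species ANI between the strain occurrences of two species
#'
#' Every occurrence (specimen-strain instance) of one species is compared
#' with every occurrence of the other, in both ANI directions. Shared
#' strains (the same strain on both sides) contribute 100 when
#' `include_shared` is TRUE and are skipped otherwise; with no cross pairs
#' left after exclusion the value is undefined (NA), not 0.
#'
#' @param occ An [occurrence_matrix()].
#' @param ani_matrix Square ANI matrix (percent) over the strain ids.
#' @param pair Character vector of two species names (both infected).
#' @param include_shared Include same-strain pairs as ANI 100?
#' @return Mean percent ANI, or NA when undefined.
#' @export
mean_cross_ani <- function(occ, ani_matrix, pair, include_shared = TRUE) {
  stopifnot(length(pair) == 2)
  ca <- occ$counts[pair[1], ]
  cb <- occ$counts[pair[2], ]
  if (sum(ca) == 0 || sum(cb) == 0)
    stop("mean_cross_ani requires both species infected")
  occ_a <- rep(colnames(occ$counts), ca)
  occ_b <- rep(colnames(occ$counts), cb)
  vals <- numeric(0)
  for (sa in occ_a) for (sb in occ_b) {
    if (sa == sb) {
      if (include_shared) vals <- c(vals, 100, 100)
    } else {
      vals <- c(vals, ani_matrix[sa, sb], ani_matrix[sb, sa])
    }
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

# Precompute the per-species-pair statistic matrix used by the permutation
# test so each null replicate is a single indexing operation.
pair_stat_matrix <- function(occ, species, statistic, ani_matrix) {
  n <- length(species)
  P <- matrix(NA_real_, n, n, dimnames = list(species, species))
  if (statistic == "shared_count") {
    Z <- occ$counts[species, , drop = FALSE] > 0
    S <- tcrossprod(Z * 1)
    return(S)
  }
  include <- statistic == "mean_ani_incl"
  inf <- rowSums(occ$counts[species, , drop = FALSE]) > 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (inf[i] && inf[j]) {
      v <- mean_cross_ani(occ, ani_matrix, c(species[i], species[j]),
                          include_shared = include)
      P[i, j] <- P[j, i] <- v
    }
  }
  P
}

#' Permutation test of strain sharing between sister-species pairs
#'
#' The observed statistic is the mean over the (filtered) true pairs; the
#' null distribution re-pairs the same species uniformly at random into
#' disjoint pairs (shuffle-then-chunk, a uniform random perfect matching)
#' and recomputes the mean. The empirical p-value counts null values greater
#' than or equal to the observed one, with the observed value itself
#' included as one of the `n_reps` replicates, so p is never below
#' `1/n_reps`.
#'
#' Filters: `"all"` keeps every pair; `"any_infected"` keeps pairs with at
#' least one infected member; `"both_infected"` keeps pairs where both
#' members are infected (the headline variant).
#'
#' @param occ An [occurrence_matrix()].
#' @param pairs data.frame with columns species_a, species_b (true pairs).
#' @param statistic One of "shared_count", "mean_ani_incl", "mean_ani_excl".
#' @param filter One of "both_infected", "any_infected", "all".
#' @param ani_matrix Strain ANI matrix, required for the mean-ANI statistics.
#' @param n_reps Total replicates including the observed value.
#' @param seed Integer RNG seed.
#' @return Object of class `sharing_test`: statistic_name, observed,
#'   null_values, n_reps, p_emp, filter, seed, n_species.
#' @export
sharing_permutation_test <- function(occ, pairs,
                                     statistic = c("shared_count",
                                                   "mean_ani_incl",
                                                   "mean_ani_excl"),
                                     filter = c("both_infected",
                                                "any_infected", "all"),
                                     ani_matrix = NULL, n_reps = 30000L,
                                     seed = 1L) {
  statistic <- match.arg(statistic)
  filter <- match.arg(filter)
  if (statistic != "shared_count" && is.null(ani_matrix))
    stop("ani_matrix is required for the mean-ANI statistics")
  inf <- infected_species(occ)
  keep <- switch(filter,
    all = rep(TRUE, nrow(pairs)),
    any_infected = pairs$species_a %in% inf | pairs$species_b %in% inf,
    both_infected = pairs$species_a %in% inf & pairs$species_b %in% inf)
  kept <- pairs[keep, , drop = FALSE]
  species <- unique(c(kept$species_a, kept$species_b))
  if (length(species) %% 2 != 0)
    stop("cannot form disjoint pairs: odd number of filtered species")
  if (length(species) < 4)
    stop("need at least 4 filtered species")
  P <- pair_stat_matrix(occ, species, statistic, ani_matrix)
  ia <- match(kept$species_a, species)
  ib <- match(kept$species_b, species)
  observed <- mean(P[cbind(ia, ib)], na.rm = TRUE)
  if (is.nan(observed)) stop("observed statistic undefined for every pair")
  set.seed(as.integer(seed))
  n <- length(species)
  odd <- seq(1, n, by = 2)
  even <- odd + 1
  null_values <- numeric(n_reps - 1L)
  for (r in seq_len(n_reps - 1L)) {
    p <- sample.int(n)
    null_values[r] <- mean(P[cbind(p[odd], p[even])], na.rm = TRUE)
  }
  p_emp <- (1 + sum(null_values >= observed, na.rm = TRUE)) / n_reps
  structure(list(statistic_name = statistic, observed = observed,
                 null_values = null_values, n_reps = as.integer(n_reps),
                 p_emp = p_emp, filter = filter, seed = as.integer(seed),
                 n_species = n),
            class = "sharing_test")
}

#' @export
print.sharing_test <- function(x, ...) {
  cat("Strain-sharing permutation test (", x$statistic_name, ", filter ",
      x$filter, ", N = ", x$n_species, " species)\n", sep = "")
  cat("  observed =", signif(x$observed, 5), " p_emp =", signif(x$p_emp, 4),
      "over", x$n_reps, "replicates (observed included)\n")
  invisible(x)
}

#' Sample incidence of infection across species
#'
#' @param status Logical (or 0/1) vector: one entry per screened species,
#'   TRUE when at least one specimen is infected.
#' @return Incidence as an integer percent (rounded for reporting).
#' @export
incidence <- function(status) {
  stopifnot(length(status) >= 1)
  round(100 * sum(as.logical(status)) / length(status))
}

#' Within-species prevalence with a Wilson 95% interval
#'
#' @param n_infected Number of infected specimens.
#' @param n_total Number of specimens screened (>= 1).
#' @param species Optional species label.
#' @param conf Confidence level (default 0.95).
#' @return One-row data.frame: species, n_infected, n_total, prevalence,
#'   ci_lo, ci_hi.
#' @export
prevalence_ci <- function(n_infected, n_total, species = NA_character_,
                          conf = 0.95) {
  stopifnot(n_total >= 1, n_infected >= 0, n_infected <= n_total)
  p <- n_infected / n_total
  z <- qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n_total
  center <- (p + z^2 / (2 * n_total)) / denom
  half <- z * sqrt(p * (1 - p) / n_total + z^2 / (4 * n_total^2)) / denom
  data.frame(species = species, n_infected = n_infected, n_total = n_total,
             prevalence = p,
             ci_lo = min(max(center - half, 0), p),
             ci_hi = max(min(center + half, 1), p),
             stringsAsFactors = FALSE)
}

#' Bayesian logistic model of strain sharing (random-walk Metropolis)
#'
#' Fits `logit P(share) = b0 + b1 time + b2 sympatry + b3 time x sympatry`
#' with weakly informative Normal(0, prior_sd^2) priors on the standardized
#' coefficients, by random-walk Metropolis with proposal scales adapted
#' during burn-in only. Predictors are standardized internally; draws are
#' reported on both the standardized and the raw scale.
#'
#' @param pairs data.frame with columns `shares` (0/1 or logical),
#'   `sympatry`, and `split_gen` / `split_my` (whichever `time_unit` needs);
#'   at least 6 rows.
#' @param time_unit "generations" (uses split_gen) or "My" (uses split_my).
#' @param n_iter,burn_in,thin Sampler settings (defaults 60000 / 10000 / 10).
#' @param prior_sd Prior standard deviation on standardized coefficients.
#' @param seed Integer RNG seed.
#' @return Object of class `posterior_draws`: `draws` (standardized scale,
#'   columns b0..b3), `draws_raw`, `n_kept`, `acceptance_rate`, `scaling`.
#' @export
fit_share_model <- function(pairs, time_unit = c("generations", "My"),
                            n_iter = 60000L, burn_in = 10000L, thin = 10L,
                            prior_sd = 5, seed = 1L) {
  time_unit <- match.arg(time_unit)
  stopifnot(nrow(pairs) >= 6)
  y <- as.numeric(pairs$shares)
  stopifnot(all(y %in% c(0, 1)))
  t_raw <- if (time_unit == "generations") pairs$split_gen else pairs$split_my
  s_raw <- pairs$sympatry
  mt <- mean(t_raw); st <- sd(t_raw)
  ms <- mean(s_raw); ss <- sd(s_raw)
  if (st == 0 || ss == 0) stop("a predictor is constant")
  zt <- (t_raw - mt) / st
  zs <- (s_raw - ms) / ss
  X <- cbind(1, zt, zs, zt * zs)
  # separation heuristic: warn when an unpenalized fit degenerates
  withCallingHandlers(
    glm(y ~ zt + zs + zt:zs, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warning("possible separation in the sharing model; ",
                "the priors regularize the posterior", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  log_post <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - log1p(exp(eta))) + sum(dnorm(beta, 0, prior_sd, log = TRUE))
  }
  set.seed(as.integer(seed))
  beta <- rep(0, 4)
  lp <- log_post(beta)
  prop_sd <- rep(0.5, 4)
  kept <- matrix(NA_real_, (n_iter - burn_in) %/% thin, 4)
  colnames(kept) <- c("b0", "b1", "b2", "b3")
  n_acc <- 0L; acc_window <- 0L; k <- 0L
  for (it in seq_len(n_iter)) {
    cand <- beta + rnorm(4, 0, prop_sd)
    lp_cand <- log_post(cand)
    if (log(runif(1)) < lp_cand - lp) {
      beta <- cand; lp <- lp_cand
      n_acc <- n_acc + 1L; acc_window <- acc_window + 1L
    }
    if (it <= burn_in && it %% 500 == 0) {
      rate <- acc_window / 500
      prop_sd <- prop_sd * exp(rate - 0.25)
      acc_window <- 0L
    }
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      k <- k + 1L
      kept[k, ] <- beta
    }
  }
  if (k < 1000) warning("fewer than 1000 kept draws; increase n_iter")
  # back-transform to raw scale: logit = a0 + a1 t + a2 s + a3 t s
  a3 <- kept[, "b3"] / (st * ss)
  a1 <- kept[, "b1"] / st - kept[, "b3"] * ms / (st * ss)
  a2 <- kept[, "b2"] / ss - kept[, "b3"] * mt / (st * ss)
  a0 <- kept[, "b0"] - kept[, "b1"] * mt / st - kept[, "b2"] * ms / ss +
    kept[, "b3"] * mt * ms / (st * ss)
  raw <- cbind(b0 = a0, b1 = a1, b2 = a2, b3 = a3)
  structure(list(draws = kept, draws_raw = raw, n_kept = k,
                 acceptance_rate = n_acc / n_iter,
                 scaling = list(time_mean = mt, time_sd = st,
                                sympatry_mean = ms, sympatry_sd = ss,
                                time_unit = time_unit)),
            class = "posterior_draws")
}

#' pMCMC of a posterior coefficient
#'
#' Twice the smaller of the posterior probabilities that the coefficient is
#' above or below zero: 0 when every draw has the same sign, 1 for a
#' posterior balanced around zero.
#'
#' @param draws Numeric vector of posterior draws for one coefficient.
#' @return pMCMC in [0, 1].
#' @export
pmcmc <- function(draws) {
  stopifnot(length(draws) >= 1)
  min(1, 2 * min(mean(draws > 0), mean(draws < 0)))
}
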