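# Synthetic individual-level trait tables --------------------------------
#
# The generator emulates the statistical structure the analysis assumes
# for database extracts of individual trait records: lognormal
# between-species variation of trait means, lognormal within-species
# (intraspecific) variation, variable per-species sample sizes, and
# optionally disjoint individual sets per trait or independent
# multiplicative measurement noise. The default scale -- 368 species,
# 1920 individuals -- matches the fine-root dataset the demonstration is
# modelled on. Values are strictly positive by construction, so the log
# transform is always valid.

#' Specify one simulated trait
#'
#' @param name Trait name, e.g. `"RTD"`.
#' @param log_mean Mean of the species-level log trait means.
#' @param log_sd Between-species SD of log trait means (`>= 0`).
#' @param within_log_sd Within-species SD on the log scale: either a
#'   single number (homogeneous) or a length-2 range `c(lo, hi)` for the
#'   heterogeneous mode, in which per-species SDs span the range
#'   monotonically in the species' log mean (species with larger means
#'   get larger within-species spread, the coupling that inflates the
#'   between-species variation of the Jensen gap).
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(name, log_mean, log_sd, within_log_sd) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(log_mean), length(log_mean) == 1L,
            is.numeric(log_sd), length(log_sd) == 1L, log_sd >= 0,
            is.numeric(within_log_sd),
            length(within_log_sd) %in% c(1L, 2L),
            all(within_log_sd >= 0))
  if (length(within_log_sd) == 2L && within_log_sd[1] > within_log_sd[2]) {
    stop("within_log_sd range must be c(lo, hi) with lo <= hi",
         call. = FALSE)
  }
  structure(list(name = name, log_mean = log_mean, log_sd = log_sd,
                 within_log_sd = within_log_sd), class = "trait_spec")
}

#' Configuration of a synthetic trait-table simulation
#'
#' Defaults describe the study conditions the package's demonstration
#' targets: 368 species, 1920 individuals, two root traits (root tissue
#' density RTD in g cm^-3 and fine-root diameter D in mm) with lognormal
#' between- and within-species variation, all traits measured on the
#' same individuals, and no extra measurement noise.
#'
#' @param n_species Number of species.
#' @param total_individuals Total number of individuals across species
#'   (allocated exactly; see Details).
#' @param traits List of [trait_spec()]s.
#' @param n_per_species Length-2 integer range `c(min, max)`, `min >= 1`:
#'   per-species individual counts are drawn uniformly from this range,
#'   then rescaled by largest-remainder rounding so they sum exactly to
#'   `total_individuals`.
#' @param shared_individuals If `TRUE` (default) every trait is measured
#'   on every individual; if `FALSE`, each species' individuals are
#'   split in half, the first half (plus any odd one) measured for the
#'   first trait only and the second half for the remaining traits, so
#'   per-trait sample sizes differ.
#' @param measurement_noise_log_sd SD of independent multiplicative
#'   (log-scale additive) measurement noise added per record
#'   (default 0).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A list of class `simulation_config`.
#' @details Infeasible combinations (e.g. `total_individuals` below
#'   `n_species * min` or above `n_species * max`) are rejected.
#' @export
simulation_config <- function(n_species = 368L,
                              total_individuals = 1920L,
                              traits = list(
                                trait_spec("RTD", log_mean = log(0.25),
                                           log_sd = 0.45,
                                           within_log_sd = 0.30),
                                trait_spec("D", log_mean = log(0.35),
                                           log_sd = 0.40,
                                           within_log_sd = 0.30)),
                              n_per_species = c(1L, 10L),
                              shared_individuals = TRUE,
                              measurement_noise_log_sd = 0,
                              seed = 1L) {
  stopifnot(n_species >= 1, total_individuals >= 1,
            length(n_per_species) == 2L, n_per_species[1] >= 1,
            n_per_species[1] <= n_per_species[2],
            measurement_noise_log_sd >= 0,
            is.list(traits), length(traits) >= 1L)
  for (tr in traits) {
    if (!inherits(tr, "trait_spec")) {
      stop("every element of `traits` must be a trait_spec()",
           call. = FALSE)
    }
  }
  if (total_individuals < n_species * n_per_species[1] ||
      total_individuals > n_species * n_per_species[2]) {
    stop(sprintf(
      "total_individuals = %d is infeasible for %d species with %d..%d individuals each",
      total_individuals, n_species, n_per_species[1], n_per_species[2]),
      call. = FALSE)
  }
  structure(
    list(n_species = as.integer(n_species),
         total_individuals = as.integer(total_individuals),
         traits = traits,
         n_per_species = as.integer(n_per_species),
         shared_individuals = isTRUE(shared_individuals),
         measurement_noise_log_sd = measurement_noise_log_sd,
         seed = as.integer(seed)),
    class = "simulation_config")
}

# Allocate per-species counts: uniform draws rescaled to the exact total
# by largest-remainder rounding, clamped to the configured range.
.allocate_counts <- function(n_species, total, rng) {
  raw <- sample(seq(rng[1], rng[2]), n_species, replace = TRUE)
  target <- raw * total / sum(raw)
  counts <- pmax(floor(target), rng[1])
  rem <- total - sum(counts)
  if (rem > 0) {
    ord <- order(target - floor(target), decreasing = TRUE)
    i <- 0L
    while (rem > 0) {
      k <- ord[(i %% n_species) + 1L]
      if (counts[k] < rng[2]) {
        counts[k] <- counts[k] + 1L
        rem <- rem - 1L
      }
      i <- i + 1L
    }
  } else if (rem < 0) {
    ord <- order(counts, decreasing = TRUE)
    i <- 0L
    while (rem < 0) {
      k <- ord[(i %% n_species) + 1L]
      if (counts[k] > rng[1]) {
        counts[k] <- counts[k] - 1L
        rem <- rem + 1L
      }
      i <- i + 1L
    }
  }
  as.integer(counts)
}

# per-species within-SD: constant, or range mapped monotonically onto
# the rank of the species log-mean
.within_sd_per_species <- function(spec, log_means) {
  w <- spec$within_log_sd
  if (length(w) == 1L) return(rep(w, length(log_means)))
  r <- rank(log_means, ties.method = "first")
  w[1] + (w[2] - w[1]) * (r - 1) / max(length(log_means) - 1, 1)
}

#' Simulate an individual-level trait table
#'
#' Draws, for each species and trait, a log-scale species mean from
#' `Normal(log_mean, log_sd)`; each individual record is
#' `exp(species log mean + Normal(0, within_log_sd) +
#' Normal(0, measurement_noise_log_sd))`. The random stream is seeded
#' once and consumed in a fixed order (species counts, species means per
#' trait, then records trait by trait), so a given config is fully
#' reproducible.
#'
#' @param config A [simulation_config()].
#' @return A [trait_table()] with species identifiers `S0001`... and
#'   individual identifiers `S0001_I01`...
#' @export
simulate_trait_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ns <- config$n_species
  sp_ids <- sprintf("S%04d", seq_len(ns))
  counts <- .allocate_counts(ns, config$total_individuals,
                             config$n_per_species)
  sp_means <- lapply(config$traits, function(spec) {
    stats::rnorm(ns, spec$log_mean, spec$log_sd)
  })
  rows <- vector("list", length(config$traits))
  for (ti in seq_along(config$traits)) {
    spec <- config$traits[[ti]]
    mu <- sp_means[[ti]]
    wsd <- .within_sd_per_species(spec, mu)
    per_species <- vector("list", ns)
    for (s in seq_len(ns)) {
      n_s <- counts[s]
      ind <- sprintf("%s_I%02d", sp_ids[s], seq_len(n_s))
      measured <- .measured_subset(n_s, ti, length(config$traits),
                                   config$shared_individuals)
      if (!length(measured)) next
      lv <- mu[s] + stats::rnorm(length(measured), 0, wsd[s])
      if (config$measurement_noise_log_sd > 0) {
        lv <- lv + stats::rnorm(length(measured), 0,
                                config$measurement_noise_log_sd)
      }
      per_species[[s]] <- data.frame(
        species = sp_ids[s], individual = ind[measured],
        trait = spec$name, value = exp(lv), stringsAsFactors = FALSE)
    }
    rows[[ti]] <- do.call(rbind, per_species)
  }
  trait_table(do.call(rbind, rows))
}

# which of a species' individuals are measured for trait ti
.measured_subset <- function(n_s, ti, n_traits, shared) {
  if (shared || n_traits == 1L) return(seq_len(n_s))
  half <- ceiling(n_s / 2)          # odd individual goes to the first trait
  if (ti == 1L) seq_len(half) else setdiff(seq_len(n_s), seq_len(half))
}

#' Simulate two traits coupled by a power law at the individual level
#'
#' The first trait in `config` is simulated as in
#' [simulate_trait_table()]; the second trait is derived per individual
#' as `y = a * x^b`, optionally perturbed by lognormal noise. With zero
#' noise the individual-level log-log relationship
#' `log(y) = log(a) + b log(x)` is exact, so averaging the transformed
#' values preserves it exactly at the species level, while transforming
#' the averages does not.
#'
#' @param config A [simulation_config()] whose `traits` list has exactly
#'   two entries; the second entry's distribution parameters are ignored
#'   (only its name is used), and both traits are measured on the same
#'   individuals.
#' @param a Multiplicative constant, `> 0`.
#' @param b Exponent.
#' @param noise_log_sd SD of log-scale noise added to y (default 0).
#' @return A [trait_table()] holding both traits.
#' @export
simulate_coupled_traits <- function(config, a, b, noise_log_sd = 0) {
  stopifnot(inherits(config, "simulation_config"),
            length(config$traits) == 2L,
            is.numeric(a), length(a) == 1L,
            is.numeric(b), length(b) == 1L, noise_log_sd >= 0)
  if (!is.finite(a) || a <= 0) stop("`a` must be positive", call. = FALSE)
  if (!is.finite(b)) stop("`b` must be finite", call. = FALSE)
  cfg_x <- config
  cfg_x$traits <- config$traits[1]
  tab_x <- simulate_trait_table(cfg_x)
  y <- a * tab_x$value^b
  if (noise_log_sd > 0) {
    y <- y * exp(stats::rnorm(length(y), 0, noise_log_sd))
  }
  tab_y <- tab_x
  tab_y$trait <- config$traits[[2]]$name
  tab_y$value <- y
  trait_table(rbind(as.data.frame(tab_x), as.data.frame(tab_y)))
}
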