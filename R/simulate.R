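#' Simulation configuration for mixed-mating genotype datasets
#'
#' Builds the parameter set for [simulate_dataset()]. The generative model
#' is: regional allele frequencies per locus from a symmetric
#' Dirichlet(`regional_alpha`); local population frequencies drifted around
#' the regional ones with a Balding-Nichols parameterisation governed by
#' `theta` (larger `theta`, stronger differentiation); adult genotypes drawn
#' with inbreeding coefficient `inbreeding_F`; seeds produced from one
#' maternal plant per population through a hierarchical mating cascade:
#' apomixis (prob `apomixis_rate`, clonal copy of the mother), else a
#' Mendelian maternal gamete plus a paternal gamete from the mother
#' (`selfing_rate`), from a migrant drawn from the regional pool
#' (`migrant_pollen_rate`), or from a uniformly chosen other adult of the
#' same population. Missing data is masked per call at `missing_rate`.
#'
#' @param n_loci Number of loci.
#' @param alleles_per_locus Number of possible alleles per locus (k >= 2).
#' @param regional_alpha Symmetric Dirichlet concentration for regional
#'   frequencies (> 0; small values give skewed frequency spectra with many
#'   rare alleles).
#' @param n_populations Number of local populations.
#' @param theta Differentiation parameter in (0, 1); local frequencies are
#'   Dirichlet with mean = regional and concentration `(1 - theta)/theta`,
#'   so E\[Fst\] is approximately `theta`.
#' @param n_adults_per_pop Adult plants genotyped per population.
#' @param inbreeding_F Inbreeding coefficient used when drawing adult
#'   genotypes, in \[0, 1\].
#' @param selfing_rate Probability a non-apomictic seed is selfed.
#' @param apomixis_rate Probability a seed is an exact clonal copy of the
#'   mother (checked first in the cascade).
#' @param migrant_pollen_rate Probability the paternal gamete of an
#'   outcrossed seed comes from outside the sampled population (drawn from
#'   regional frequencies).
#' @param seeds_per_bunch Seeds genotyped from the single bunch collected
#'   per population.
#' @param missing_rate Per-call missing-data masking probability, in
#'   \[0, 1).
#' @param spatial_gradient If TRUE, local allele-frequency means are
#'   interpolated along a one-dimensional transect between two drifted
#'   endpoint frequency profiles, inducing isolation by distance.
#' @param rng_seed Integer seed making the whole dataset reproducible.
#' @param label Free-text scenario label stored with the config.
#' @return A list of class `"sim_config"`.
#' @seealso [sim_preset()] for the three species-like scenarios.
#' @export
sim_config <- function(n_loci = 16,
                       alleles_per_locus = 8,
                       regional_alpha = 0.8,
                       n_populations = 5,
                       theta = 0.2,
                       n_adults_per_pop = 15,
                       inbreeding_F = 0,
                       selfing_rate = 0,
                       apomixis_rate = 0,
                       migrant_pollen_rate = 0.05,
                       seeds_per_bunch = 16,
                       missing_rate = 0.05,
                       spatial_gradient = FALSE,
                       rng_seed = NULL,
                       label = "custom") {
  cfg <- list(n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              regional_alpha = regional_alpha,
              n_populations = as.integer(n_populations),
              theta = theta,
              n_adults_per_pop = as.integer(n_adults_per_pop),
              inbreeding_F = inbreeding_F,
              selfing_rate = selfing_rate,
              apomixis_rate = apomixis_rate,
              migrant_pollen_rate = migrant_pollen_rate,
              seeds_per_bunch = as.integer(seeds_per_bunch),
              missing_rate = missing_rate,
              spatial_gradient = isTRUE(spatial_gradient),
              rng_seed = rng_seed,
              label = label)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_loci >= 1, cfg$alleles_per_locus >= 2,
            cfg$regional_alpha > 0,
            cfg$n_populations >= 1, cfg$n_adults_per_pop >= 1,
            cfg$seeds_per_bunch >= 1)
  if (!(cfg$theta > 0 && cfg$theta < 1)) {
    rlang::abort("theta must be in (0, 1)")
  }
  props <- c(inbreeding_F = cfg$inbreeding_F, selfing_rate = cfg$selfing_rate,
             apomixis_rate = cfg$apomixis_rate,
             migrant_pollen_rate = cfg$migrant_pollen_rate)
  bad <- names(props)[props < 0 | props > 1]
  if (length(bad) > 0) rlang::abort(paste0("proportion out of [0,1]: ",
                                           paste(bad, collapse = ", ")))
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    rlang::abort("missing_rate must be in [0, 1)")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$label, "\n")
  flds <- setdiff(names(x), "label")
  for (f in flds) cat(sprintf("  %-20s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Species-like simulation presets
#'
#' Three scenarios emulating the contrasting mating systems of wild banana
#' relatives as reflected in their population and seed genetics:
#'
#' * `acuminata_like` — a near-obligate selfer with occasional apomixis:
#'   few alleles per locus, strong inbreeding in adults (F = 0.8), selfing
#'   rate 0.99, apomixis rate 0.1, almost no migrant pollen; seeds are
#'   near-clonal with Ho close to 0 and bunches carry little beyond their
#'   mother's alleles.
#' * `balbisiana_like` — a low-diversity mixed mater: outbred adults but
#'   partial selfing (0.4) and some apomixis in the seed crop.
#' * `maclayi_like` — a diverse obligate outcrosser: many alleles per locus,
#'   no selfing, random-mating adults, isolation by distance along the
#'   transect.
#'
#' Loci counts (19/10/14), allele numbers, missing rates and differentiation
#' levels mirror the filtered marker panels and summary statistics reported
#' for the three species (mean locus polymorphism 3.8/6.2/18.6; missing data
#' 3.9/8.1/4.7%; among-population phi roughly 0.29/0.25/0.18).
#'
#' @param name Preset name.
#' @param ... Named overrides passed to [sim_config()].
#' @return A `"sim_config"`.
#' @export
#' @examples
#' sim_preset("maclayi_like", rng_seed = 1)
sim_preset <- function(name = c("acuminata_like", "balbisiana_like",
                                "maclayi_like"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    acuminata_like = list(n_loci = 19, alleles_per_locus = 24,
                          regional_alpha = 0.035, theta = 0.29,
                          inbreeding_F = 0.8, selfing_rate = 0.99,
                          apomixis_rate = 0.1, migrant_pollen_rate = 0.005,
                          missing_rate = 0.039, spatial_gradient = FALSE),
    balbisiana_like = list(n_loci = 10, alleles_per_locus = 8,
                           regional_alpha = 0.15, theta = 0.25,
                           inbreeding_F = 0, selfing_rate = 0.4,
                           apomixis_rate = 0.05, migrant_pollen_rate = 0.05,
                           missing_rate = 0.081, spatial_gradient = FALSE),
    maclayi_like = list(n_loci = 14, alleles_per_locus = 20,
                        regional_alpha = 0.5, theta = 0.2,
                        inbreeding_F = 0, selfing_rate = 0,
                        apomixis_rate = 0, migrant_pollen_rate = 0.05,
                        missing_rate = 0.047, spatial_gradient = TRUE))
  args <- utils::modifyList(c(base, list(label = name)), list(...))
  do.call(sim_config, args)
}

# Dirichlet draws via normalised gammas
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  sweep(x, 1, rowSums(x), "/")
}

locus_names <- function(n) sprintf("L%02d", seq_len(n))
allele_codes <- function(k) 100L + 2L * seq_len(k)

#' Draw regional allele frequencies
#'
#' One frequency vector per locus from a symmetric
#' Dirichlet(`regional_alpha`). Uses the current RNG state; seed once (or
#' call through [simulate_dataset()]) for reproducibility.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `locus`, `allele`, `freq`; frequencies sum
#'   to 1 within each locus.
#' @export
simulate_regional_frequencies <- function(config) {
  validate_sim_config(config)
  k <- config$alleles_per_locus
  loci <- locus_names(config$n_loci)
  mat <- rdirichlet(config$n_loci, rep(config$regional_alpha, k))
  tibble::tibble(locus = rep(loci, each = k),
                 allele = rep(allele_codes(k), times = config$n_loci),
                 freq = as.vector(t(mat)))
}

freq_list <- function(freq_tbl) {
  split(stats::setNames(freq_tbl$freq, freq_tbl$allele), freq_tbl$locus)
}

# one diploid genotype per locus given local frequency list and inbreeding F
draw_genotypes <- function(freqs, n, inbreeding_F) {
  loci <- names(freqs)
  out <- matrix(NA_integer_, nrow = n, ncol = 2 * length(loci))
  for (j in seq_along(loci)) {
    p <- freqs[[j]]
    codes <- as.integer(names(p))
    ibd <- stats::runif(n) < inbreeding_F
    a1 <- sample(codes, n, replace = TRUE, prob = p)
    a2 <- sample(codes, n, replace = TRUE, prob = p)
    a2[ibd] <- a1[ibd]
    out[, 2 * j - 1] <- a1
    out[, 2 * j] <- a2
  }
  colnames(out) <- allele_cols(loci)
  out
}

#' Simulate one local population of adult plants
#'
#' Local allele frequencies are drawn per locus from a Dirichlet with mean
#' equal to the regional frequencies and concentration `(1 - theta)/theta`
#' (Balding-Nichols drift); adult genotypes are then drawn with
#' `P(homozygote i) = p_i^2 + F p_i (1 - p_i)` and
#' `P(heterozygote ij) = 2 p_i p_j (1 - F)`. When gradient endpoints are
#' supplied (by [simulate_dataset()] under `spatial_gradient = TRUE`) the
#' local mean is first interpolated between the two endpoint profiles at the
#' population's transect position.
#'
#' @param regional Tibble from [simulate_regional_frequencies()].
#' @param config A [sim_config()].
#' @param pop_index Population number (1-based), used for ids.
#' @param endpoints Optional list `(start, end, x)` of two frequency tables
#'   and the transect position in \[0, 1\].
#' @return A list with `adults` (genotype tibble rows, role "population")
#'   and `local_freqs` (tibble `locus`, `allele`, `freq`).
#' @export
simulate_population <- function(regional, config, pop_index, endpoints = NULL) {
  validate_sim_config(config)
  conc <- (1 - config$theta) / config$theta
  reg <- freq_list(regional)
  if (!is.null(endpoints)) {
    e1 <- freq_list(endpoints$start)
    e2 <- freq_list(endpoints$end)
    x <- endpoints$x
    # interpolated mean, then mild extra drift around it
    mean_f <- purrr::map2(e1, e2, function(a, b) (1 - x) * a + x * b)
    local <- purrr::map(mean_f, function(p) {
      q <- drop(rdirichlet(1, pmax(p, 1e-8) * 3 * conc))
      stats::setNames(q, names(p))
    })
  } else {
    local <- purrr::map(reg, function(p) {
      q <- drop(rdirichlet(1, pmax(p, 1e-8) * conc))
      stats::setNames(q, names(p))
    })
  }
  pop <- sprintf("P%d", pop_index)
  geno <- draw_genotypes(local, config$n_adults_per_pop, config$inbreeding_F)
  adults <- tibble::tibble(
    sample_id = sprintf("%s_A%02d", pop, seq_len(config$n_adults_per_pop)),
    population = pop, role = "population",
    bunch = NA_character_, lat = NA_real_, lon = NA_real_)
  adults <- dplyr::bind_cols(adults, tibble::as_tibble(geno))
  local_tbl <- tibble::tibble(
    locus = rep(names(local), each = config$alleles_per_locus),
    allele = rep(allele_codes(config$alleles_per_locus),
                 times = length(local)),
    freq = unlist(local, use.names = FALSE))
  list(adults = adults, local_freqs = local_tbl)
}

gamete <- function(individual, loci) {
  pick <- stats::runif(length(loci)) < 0.5
  a1 <- as.integer(unlist(individual[paste0(loci, "_1")]))
  a2 <- as.integer(unlist(individual[paste0(loci, "_2")]))
  ifelse(pick, a1, a2)
}

#' Simulate one seed bunch from a maternal plant
#'
#' Per seed the mating cascade is: apomixis (exact multilocus copy of the
#' mother), else a Mendelian maternal gamete combined with a paternal gamete
#' from the mother (selfing), from a migrant genotype drawn at regional
#' frequencies, or from a uniformly chosen other adult of the same
#' population. Missing-data masking is applied by [simulate_dataset()], not
#' here, so parentage stays verifiable.
#'
#' @param mother One row of the adults tibble.
#' @param adults Adults tibble of the mother's population.
#' @param regional Regional frequency tibble (migrant pollen pool).
#' @param config A [sim_config()].
#' @param bunch_id Bunch label (default derived from the mother).
#' @return A list with `seeds` (genotype tibble rows, role "seed") and
#'   `parentage` (tibble `seed_id`, `mother_id`, `father`; `father` is an
#'   adult id or one of `"SELF"`, `"APOMICT"`, `"MIGRANT"`).
#' @export
simulate_bunch <- function(mother, adults, regional, config,
                           bunch_id = NULL) {
  validate_sim_config(config)
  if (!mother$sample_id %in% adults$sample_id) {
    rlang::abort("mother must be one of the population's adults")
  }
  loci <- genotype_loci(adults)
  others <- adults[adults$sample_id != mother$sample_id, ]
  if (nrow(others) == 0 && config$selfing_rate < 1 &&
      config$migrant_pollen_rate < 1 && config$apomixis_rate < 1) {
    rlang::abort("no pollen source: single-adult population without full selfing/apomixis")
  }
  reg <- freq_list(regional)
  bunch_id <- bunch_id %||% paste0("B_", mother$population)
  n <- config$seeds_per_bunch
  mom_row <- as.integer(unlist(mother[allele_cols(loci)]))

  geno <- matrix(NA_integer_, nrow = n, ncol = 2 * length(loci))
  father <- character(n)
  for (i in seq_len(n)) {
    if (stats::runif(1) < config$apomixis_rate) {
      geno[i, ] <- mom_row
      father[i] <- "APOMICT"
      next
    }
    mat <- gamete(mother, loci)
    u <- stats::runif(1)
    if (u < config$selfing_rate) {
      pat <- gamete(mother, loci)
      father[i] <- "SELF"
    } else if (u < config$selfing_rate + config$migrant_pollen_rate) {
      pat <- purrr::map_int(reg, function(p) {
        sample(as.integer(names(p)), 1, prob = p)
      })
      father[i] <- "MIGRANT"
    } else {
      sire <- others[sample.int(nrow(others), 1), ]
      pat <- gamete(sire, loci)
      father[i] <- sire$sample_id
    }
    geno[i, seq(1, 2 * length(loci), by = 2)] <- mat
    geno[i, seq(2, 2 * length(loci), by = 2)] <- pat
  }
  colnames(geno) <- allele_cols(loci)
  seeds <- tibble::tibble(
    sample_id = sprintf("%s_S%02d", bunch_id, seq_len(n)),
    population = mother$population, role = "seed",
    bunch = bunch_id, lat = mother$lat, lon = mother$lon)
  seeds <- dplyr::bind_cols(seeds, tibble::as_tibble(geno))
  parentage <- tibble::tibble(seed_id = seeds$sample_id,
                              mother_id = mother$sample_id,
                              father = father)
  list(seeds = seeds, parentage = parentage)
}

mask_missing <- function(gt, rate) {
  if (rate <= 0) return(gt)
  loci <- genotype_loci(gt)
  for (loc in loci) {
    hit <- stats::runif(nrow(gt)) < rate
    gt[[paste0(loc, "_1")]][hit] <- NA_integer_
    gt[[paste0(loc, "_2")]][hit] <- NA_integer_
  }
  gt
}

#' Simulate a complete population-and-seed genotype dataset
#'
#' Builds `n_populations` local populations of adults on a one-dimensional
#' transect, each contributing one seed bunch from a uniformly chosen
#' maternal plant, then masks calls at `missing_rate`. Fully reproducible
#' from the seed.
#'
#' @param config A [sim_config()] or [sim_preset()].
#' @param seed Integer RNG seed; defaults to `config$rng_seed`, one of the
#'   two must be given.
#' @return A list of class `"sim_dataset"` with:
#'   * `data` — validated genotype tibble (adults and seeds);
#'   * `truth` — list of `regional` and `local` frequency tables, seed
#'     `parentage`, chosen `mothers`, and the echoed `config`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_preset("maclayi_like"), seed = 1)
#' dplyr::count(sim$data, population, role)
simulate_dataset <- function(config, seed = NULL) {
  validate_sim_config(config)
  seed <- seed %||% config$rng_seed
  if (is.null(seed)) rlang::abort("an rng seed is required (config$rng_seed or seed=)")
  withr::with_seed(as.integer(seed), {
    regional <- simulate_regional_frequencies(config)
    endpoints <- NULL
    ends <- NULL
    if (config$spatial_gradient) {
      conc <- (1 - config$theta) / config$theta
      drift_once <- function() {
        tbl <- regional
        tbl$freq <- unlist(purrr::map(freq_list(regional), function(p) {
          drop(rdirichlet(1, pmax(p, 1e-8) * conc))
        }), use.names = FALSE)
        tbl
      }
      ends <- list(start = drift_once(), end = drift_once())
    }
    xs <- if (config$n_populations == 1) 0.5 else
      (seq_len(config$n_populations) - 1) / (config$n_populations - 1)
    pieces <- purrr::map(seq_len(config$n_populations), function(i) {
      ep <- if (config$spatial_gradient)
        list(start = ends$start, end = ends$end, x = xs[i]) else NULL
      pop <- simulate_population(regional, config, i, endpoints = ep)
      pop$adults$lat <- 10
      pop$adults$lon <- 100 + xs[i] * 2
      mother <- pop$adults[sample.int(nrow(pop$adults), 1), ]
      bunch <- simulate_bunch(mother, pop$adults, regional, config)
      list(adults = pop$adults, seeds = bunch$seeds,
           parentage = bunch$parentage,
           mother = tibble::tibble(population = mother$population,
                                   mother_id = mother$sample_id),
           local = dplyr::mutate(pop$local_freqs,
                                 population = sprintf("P%d", i),
                                 .before = 1))
    })
    data <- dplyr::bind_rows(purrr::map(pieces, "adults"),
                             purrr::map(pieces, "seeds"))
    data <- mask_missing(data, config$missing_rate)
    data <- validate_genotypes(data)
    truth <- list(regional = regional,
                  local = dplyr::bind_rows(purrr::map(pieces, "local")),
                  parentage = dplyr::bind_rows(purrr::map(pieces, "parentage")),
                  mothers = dplyr::bind_rows(purrr::map(pieces, "mother")),
                  config = config)
    structure(list(data = data, truth = truth), class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cfg <- x$truth$config
  cat("<sim_dataset>", cfg$label, "—",
      cfg$n_populations, "populations x", cfg$n_adults_per_pop, "adults +",
      cfg$seeds_per_bunch, "seeds/bunch,", cfg$n_loci, "loci\n")
  invisible(x)
}

#' Small example dataset for documentation
#'
#' A quick outcrossing-scenario dataset (3 populations, 6 adults, 6 seeds
#' per bunch, 6 loci) used in function examples.
#'
#' @return A genotype tibble.
#' @export
sim_dataset_example <- function() {
  cfg <- sim_preset("maclayi_like", n_loci = 6, alleles_per_locus = 6,
                    n_populations = 3, n_adults_per_pop = 6,
                    seeds_per_bunch = 6, missing_rate = 0.02, rng_seed = 42)
  simulate_dataset(cfg)$data
}
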