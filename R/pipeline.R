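#' Pipeline configuration
#'
#' Assembles and validates the settings of [run_full_analysis()]. Exactly
#' one of `input` (a genotype table path) or `preset` (a simulation
#' scenario, see [sim_preset()]) must be given, and `rng_seed` is
#' mandatory: every stochastic stage (simulation, accumulation resampling,
#' permutation tests) derives its own deterministic child seed from it.
#'
#' @param input Path to a delimited genotype table, or `NULL`.
#' @param preset Simulation preset name, or `NULL`.
#' @param preset_overrides Named list of [sim_config()] overrides applied to
#'   the preset.
#' @param rng_seed Integer seed (required).
#' @param max_missing Missing-data threshold for [filter_missing()].
#' @param g Rarefaction depth or `"auto"`.
#' @param regional_estimator Richness extrapolator for population/bunch
#'   curves (default `"bootstrap"`).
#' @param within_bunch_estimator Extrapolator for seed-within-bunch curves
#'   (default `"chao2"`, robust at ~16 units).
#' @param n_resamples Orderings per accumulation curve.
#' @param n_permutations Permutations for AMOVA and Mantel tests.
#' @param thresholds Capture target percentages, each in (0, 100].
#' @param distance Inter-individual distance for AMOVA.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, preset = NULL,
                            preset_overrides = list(),
                            rng_seed = NULL,
                            max_missing = 0.25, g = "auto",
                            regional_estimator = "bootstrap",
                            within_bunch_estimator = "chao2",
                            n_resamples = 999, n_permutations = 999,
                            thresholds = c(70, 90),
                            distance = "mismatch") {
  if (is.null(rng_seed)) abort("rng_seed is required")
  if (is.null(input) == is.null(preset)) {
    abort("give exactly one of 'input' (genotype table path) or 'preset'")
  }
  if (any(thresholds <= 0 | thresholds > 100)) {
    abort("thresholds must be in (0, 100]")
  }
  estimators <- c("bootstrap", "chao2", "jackknife1")
  stopifnot(regional_estimator %in% estimators,
            within_bunch_estimator %in% estimators,
            distance %in% c("mismatch", "euclidean"),
            n_resamples >= 1, n_permutations >= 1)
  structure(list(input = input, preset = preset,
                 preset_overrides = preset_overrides,
                 rng_seed = as.integer(rng_seed),
                 max_missing = max_missing, g = g,
                 regional_estimator = regional_estimator,
                 within_bunch_estimator = within_bunch_estimator,
                 n_resamples = as.integer(n_resamples),
                 n_permutations = as.integer(n_permutations),
                 thresholds = as.numeric(thresholds),
                 distance = distance),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a key-value config file, rejects unknown keys, applies the
#' documented defaults and validates the result. The effective config is
#' echoed in the run manifest; [save_config()] writes it back so that
#' dump-and-reload round-trips.
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration as YAML
#'
#' @param config A `"pipeline_config"`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  lst <- unclass(config)
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (length(lst$preset_overrides) == 0) lst$preset_overrides <- NULL
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

stage_seed <- function(config, k) {
  (config$rng_seed + 97L * k) %% .Machine$integer.max
}

#' Run the full genetic-capture analysis
#'
#' Orchestrates the whole pipeline on one dataset: missing-data filter;
#' regional diversity summary for populations vs seeds with the capture
#' proportion; local (per population / per bunch) diversity summaries with
#' Welch comparisons of seed vs population index values; AMOVA with
#' permutation test; accumulation curves with capture thresholds over
#' local populations, over bunches (both normalised against the
#' extrapolated total regional population richness), and over seeds within
#' each bunch (normalised against that bunch's extrapolated total); allele
#' membership across bunches and the pooled populations; Nei distances
#' with a complete-linkage dendrogram; and Mantel isolation-by-distance
#' tests when coordinates are present. Stages that the dataset cannot
#' support (a single population, missing coordinates, infinite distances)
#' are skipped and logged, not fatal.
#'
#' @param config A [pipeline_config()] or [load_config()] result.
#' @param out_dir Optional directory; when given, every table is written as
#'   CSV/Newick/JSON plus a run manifest, and reruns with the same config
#'   and seed are byte-identical (timestamps live only in the manifest).
#' @param quiet Suppress progress messages.
#' @return A list bundle of class `"capture_report"` with elements
#'   `data`, `filter_report`, `regional`, `capture`, `local`,
#'   `comparisons`, `amova`, `accumulation` (population/bunch/seed curves
#'   and thresholds), `membership`, `nei`, `newick`, `mantel`, `skipped`,
#'   `manifest`.
#' @export
#' @examples
#' cfg <- pipeline_config(preset = "maclayi_like", rng_seed = 1,
#'                        preset_overrides = list(n_loci = 6,
#'                                                n_adults_per_pop = 8,
#'                                                seeds_per_bunch = 6),
#'                        n_resamples = 49, n_permutations = 49)
#' rep <- run_full_analysis(cfg, quiet = TRUE)
#' rep$capture
run_full_analysis <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) inform(paste0(...))
  skipped <- list()
  skip <- function(stage, reason) {
    say("skipping ", stage, ": ", reason)
    skipped[[length(skipped) + 1]] <<- tibble(stage = stage, reason = reason)
  }

  # --- input ---------------------------------------------------------------
  if (!is.null(config$input)) {
    say("reading ", config$input)
    gt <- read_genotype_table(config$input)
  } else {
    say("simulating preset ", config$preset)
    cfg <- do.call(sim_preset, c(list(name = config$preset),
                                 config$preset_overrides))
    gt <- simulate_dataset(cfg, seed = stage_seed(config, 1L))$data
  }

  gt <- filter_missing(gt, config$max_missing)
  filt <- removal_report(gt)
  say(sprintf("filter: %d/%d loci, %d/%d samples kept; %.1f%% missing",
              sum(!filt$loci$dropped), nrow(filt$loci),
              sum(!filt$samples$dropped), nrow(filt$samples),
              filt$overall_missing_pct))

  # --- diversity -----------------------------------------------------------
  regional <- diversity_summary(gt, by = "role", g = config$g)
  ar <- stats::setNames(regional$AR, regional$role)
  capture <- tibble(
    AR_population = ar[["population"]], AR_seeds = ar[["seed"]],
    capture_pct = capture_proportion(ar[["seed"]], ar[["population"]]),
    capture_pct_rounded = capture_proportion(ar[["seed"]], ar[["population"]],
                                             digits = 0))
  local <- diversity_summary(gt, by = c("role", "population"), g = config$g)

  comparisons <- NULL
  pops <- filter(local, .data$role == "population")
  seeds <- filter(local, .data$role == "seed")
  if (nrow(pops) >= 2 && nrow(seeds) >= 2) {
    comparisons <- list_rbind(purrr::map(
      c("AR", "Hprime", "lambda", "E5", "Ho", "Hexp"),
      function(idx) {
        mutate(welch_t_test(seeds[[idx]], pops[[idx]]), index = idx,
               .before = 1)
      }))
  } else {
    skip("welch comparisons", "fewer than 2 localities per role")
  }

  # --- structure -----------------------------------------------------------
  amv <- NULL
  n_pops <- dplyr::n_distinct(pool_genotypes(gt, "population")$population)
  if (n_pops >= 2) {
    amv <- tryCatch(
      amova_permutation_test(gt, distance = config$distance,
                             n_permutations = config$n_permutations,
                             seed = stage_seed(config, 2L)),
      error = function(e) { skip("amova", conditionMessage(e)); NULL })
  } else {
    skip("amova", "fewer than 2 populations")
  }

  nei <- tryCatch(nei_distance(gt, by = c("role", "population")),
                  error = function(e) { skip("nei", conditionMessage(e)); NULL })
  newick <- NULL
  if (!is.null(nei)) {
    if (isTRUE(attr(nei, "has_infinite"))) {
      skip("dendrogram", "infinite Nei distance (disjoint allele sets)")
    } else if (attr(nei, "Size") >= 2) {
      newick <- as_newick(hierarchical_clustering(nei))
    }
  }

  mantel <- NULL
  if (all(is.na(gt$lat)) || all(is.na(gt$lon))) {
    skip("mantel", "no coordinates")
  } else if (n_pops < 3) {
    skip("mantel", "fewer than 3 populations")
  } else {
    mantel <- list_rbind(purrr::map(c("population", "seed"), function(r) {
      sub <- pool_genotypes(gt, r)
      dg <- geo_distance(sub, by = "population")
      dn <- nei_distance(sub, by = "population")
      if (isTRUE(attr(dn, "has_infinite"))) {
        skip(paste0("mantel (", r, ")"), "infinite Nei distance")
        return(NULL)
      }
      mutate(mantel_test(dg, dn, n_permutations = config$n_permutations,
                         seed = stage_seed(config, 3L)),
             role = r, .before = 1)
    }))
  }

  # --- accumulation --------------------------------------------------------
  inc_pop <- tryCatch(build_incidence(gt, unit = "population"),
                      error = function(e) {
                        skip("population accumulation", conditionMessage(e))
                        NULL
                      })
  total <- NULL
  curve_pop <- NULL
  if (!is.null(inc_pop)) {
    total <- extrapolate_total_richness(inc_pop, config$regional_estimator)
    curve_pop <- accumulation_curve(inc_pop, n_resamples = config$n_resamples,
                                    estimator = config$regional_estimator,
                                    seed = stage_seed(config, 4L))
  }
  curve_bunch <- NULL
  seed_curves <- NULL
  has_seeds <- any(gt$role == "seed")
  if (has_seeds && dplyr::n_distinct(gt$bunch[gt$role == "seed"]) >= 2) {
    inc_bunch <- build_incidence(gt, unit = "bunch")
    curve_bunch <- accumulation_curve(inc_bunch,
                                      n_resamples = config$n_resamples,
                                      estimator = config$regional_estimator,
                                      total = total$S_hat,
                                      seed = stage_seed(config, 5L))
  } else {
    skip("bunch accumulation", "fewer than 2 bunches")
  }
  if (has_seeds) {
    bunches <- unique(gt$bunch[gt$role == "seed"])
    seed_curves <- purrr::map(stats::setNames(bunches, bunches), function(b) {
      inc <- build_incidence(gt, unit = "seed", bunch = b)
      accumulation_curve(inc, n_resamples = config$n_resamples,
                         estimator = config$within_bunch_estimator,
                         seed = stage_seed(config, 6L))
    })
  } else {
    skip("seed accumulation", "no seed samples")
  }
  thresholds <- list(
    population = if (!is.null(curve_pop))
      units_to_threshold(curve_pop, config$thresholds),
    bunch = if (!is.null(curve_bunch))
      units_to_threshold(curve_bunch, config$thresholds),
    seed = if (!is.null(seed_curves))
      list_rbind(purrr::imap(seed_curves, function(cv, b) {
        mutate(units_to_threshold(cv, config$thresholds), bunch = b,
               .before = 1)
      })))

  membership <- NULL
  if (has_seeds) {
    groups <- split(pool_genotypes(gt, "seed"),
                    pool_genotypes(gt, "seed")$bunch)
    groups$regional_population <- pool_genotypes(gt, "population")
    if (length(groups) >= 2) membership <- allele_membership(groups)
  }

  manifest <- list(
    package = "seedcapture",
    version = as.character(utils::packageVersion("seedcapture")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(config))

  bundle <- structure(list(
    data = gt, filter_report = filt, regional = regional, capture = capture,
    local = local, comparisons = comparisons, amova = amv,
    accumulation = list(population = curve_pop, bunch = curve_bunch,
                        seed = seed_curves, total_regional = total,
                        thresholds = thresholds),
    membership = membership, nei = nei, newick = newick, mantel = mantel,
    skipped = if (length(skipped)) list_rbind(skipped) else
      tibble(stage = character(), reason = character()),
    manifest = manifest), class = "capture_report")

  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' @export
print.capture_report <- function(x, ...) {
  cat("<capture_report>\n")
  cat("  regional capture: ", round(x$capture$capture_pct, 1), "%\n", sep = "")
  if (!is.null(x$amova)) {
    cat(sprintf("  AMOVA phi = %.3f (p = %.3g)\n", x$amova$phi, x$amova$p))
  }
  cat("  stages skipped:", nrow(x$skipped), "\n")
  invisible(x)
}

#' Write a capture report bundle to disk
#'
#' Emits every table of a [run_full_analysis()] bundle as CSV, the
#' dendrogram as Newick, and the manifest as JSON. Apart from the manifest
#' timestamp the files are byte-identical across reruns with the same
#' config and seed.
#'
#' @param bundle A `"capture_report"`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    if (!is.null(df)) readr::write_csv(df, file.path(out_dir, name))
  }
  w(bundle$regional, "regional_diversity.csv")
  w(bundle$capture, "capture.csv")
  w(bundle$local, "local_diversity.csv")
  w(bundle$comparisons, "welch_comparisons.csv")
  w(bundle$filter_report$loci, "filter_loci.csv")
  w(bundle$filter_report$samples, "filter_samples.csv")
  if (!is.null(bundle$amova)) {
    w(tidy(bundle$amova), "amova_components.csv")
    w(glance(bundle$amova), "amova_summary.csv")
  }
  if (!is.null(bundle$accumulation$population)) {
    w(tidy(bundle$accumulation$population), "accumulation_population.csv")
  }
  if (!is.null(bundle$accumulation$bunch)) {
    w(tidy(bundle$accumulation$bunch), "accumulation_bunch.csv")
  }
  if (!is.null(bundle$accumulation$seed)) {
    w(list_rbind(purrr::imap(bundle$accumulation$seed, function(cv, b) {
      mutate(tidy(cv), bunch = b, .before = 1)
    })), "accumulation_seeds.csv")
  }
  thr <- bundle$accumulation$thresholds
  w(list_rbind(list(
    if (!is.null(thr$population))
      mutate(thr$population, unit = "population", .before = 1),
    if (!is.null(thr$bunch)) mutate(thr$bunch, unit = "bunch", .before = 1),
    if (!is.null(thr$seed)) mutate(thr$seed, unit = "seed", .before = 1))),
    "capture_thresholds.csv")
  if (!is.null(bundle$membership)) {
    w(bundle$membership, "allele_membership.csv")
    w(attr(bundle$membership, "pairwise"), "allele_membership_pairwise.csv")
  }
  if (!is.null(bundle$nei)) {
    m <- as.matrix(bundle$nei)
    w(mutate(as_tibble(m), label = rownames(m), .before = 1),
      "nei_distances.csv")
  }
  if (!is.null(bundle$newick)) {
    writeLines(bundle$newick, file.path(out_dir, "dendrogram.nwk"))
  }
  w(bundle$mantel, "mantel.csv")
  w(bundle$skipped, "skipped_stages.csv")
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
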