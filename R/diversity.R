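#' Rarefied allelic richness
#'
#' Standardises allele counts to a common number of gene copies by
#' hypergeometric rarefaction (El Mousadik & Petit style). Per locus and
#' group, with `N` non-missing gene copies of which `N_i` carry allele `i`,
#' the expected number of distinct alleles in a subsample of `g` copies is
#' `sum_i (1 - choose(N - N_i, g)/choose(N, g))`; group AR is the sum over
#' loci, so a dataset's AR scales with the number of loci retained.
#'
#' @param gt A genotype tibble.
#' @param by Grouping metadata columns (groups being compared share the
#'   rarefaction depth).
#' @param g Rarefaction depth in gene copies (>= 2), or `"auto"`: per locus,
#'   the minimum non-missing copy count across the groups; loci absent from
#'   some group are then excluded (and flagged in the `"dropped_loci"`
#'   attribute).
#' @return A tibble with the grouping columns and `AR`; per-locus values
#'   (`locus`, `g`, `AR_locus`) are in the `"per_locus"` attribute.
#' @export
#' @examples
#' gt <- sim_dataset_example()
#' allelic_richness(gt, by = "role")
allelic_richness <- function(gt, by = "role", g = "auto") {
  counts <- allele_counts(gt, by)
  groups <- distinct(counts, across(all_of(by)))
  depth <- counts |>
    distinct(across(all_of(by)), .data$locus, .data$n_copies) |>
    tidyr::complete(tidyr::nesting(!!!rlang::syms(by)), !!rlang::sym("locus"),
                    fill = list(n_copies = 0L)) |>
    group_by(.data$locus) |>
    summarise(g = min(.data$n_copies), .groups = "drop")
  if (identical(g, "auto")) {
    dropped <- filter(depth, .data$g < 2)
    depth <- filter(depth, .data$g >= 2)
    if (nrow(depth) == 0) abort("no locus has >= 2 gene copies in every group")
  } else {
    stopifnot(is.numeric(g), g >= 2)
    short <- filter(depth, .data$g < !!g)
    if (nrow(short) > 0) {
      abort(paste0("rarefaction depth ", g, " exceeds gene copies at: ",
                   paste(short$locus, collapse = ", ")))
    }
    depth$g <- as.integer(g)
    dropped <- depth[0, ]
  }
  per_locus <- counts |>
    dplyr::inner_join(depth, by = "locus") |>
    group_by(across(all_of(by)), .data$locus, .data$g) |>
    summarise(AR_locus = sum(1 - exp(lchoose(.data$n_copies - .data$n_allele,
                                             .data$g) -
                                     lchoose(.data$n_copies, .data$g))),
              .groups = "drop")
  out <- per_locus |>
    group_by(across(all_of(by))) |>
    summarise(AR = sum(.data$AR_locus), n_loci = dplyr::n(),
              .groups = "drop")
  attr(out, "per_locus") <- per_locus
  attr(out, "dropped_loci") <- dropped$locus
  out
}

# integer allele counts per group x locus x allele, with gene-copy totals
allele_counts <- function(gt, by) {
  stopifnot(all(by %in% GT_META))
  long <- alleles_long(gt)
  if (nrow(long) == 0) abort("no non-missing genotype calls")
  long |>
    count(across(all_of(by)), .data$locus, .data$allele, name = "n_allele") |>
    group_by(across(all_of(by)), .data$locus) |>
    mutate(n_copies = sum(.data$n_allele)) |>
    ungroup()
}

#' Private alleles between two groupings
#'
#' Counts alleles observed in one group and not the other, per locus and
#' summed over loci (set differences of non-zero-frequency alleles).
#'
#' @param gt A genotype tibble whose `by` grouping yields exactly two
#'   groups.
#' @param by Grouping metadata column(s).
#' @return A two-row tibble with the grouping columns and `n_private`; the
#'   private allele lists are in the `"alleles"` attribute.
#' @export
private_alleles <- function(gt, by = "role") {
  counts <- allele_counts(gt, by)
  counts$group <- interaction(counts[by], drop = TRUE)
  grps <- levels(counts$group)
  if (length(grps) != 2) {
    abort("private_alleles needs a grouping with exactly two groups")
  }
  a <- filter(counts, .data$group == grps[1])
  b <- filter(counts, .data$group == grps[2])
  if (length(intersect(unique(a$locus), unique(b$locus))) == 0) {
    abort("groups share no locus with data")
  }
  key <- function(x) paste(x$locus, x$allele)
  priv_a <- a[!key(a) %in% key(b), ]
  priv_b <- b[!key(b) %in% key(a), ]
  out <- bind_rows(
    mutate(distinct(a, across(all_of(by))), n_private = nrow(priv_a)),
    mutate(distinct(b, across(all_of(by))), n_private = nrow(priv_b)))
  attr(out, "alleles") <- bind_rows(priv_a, priv_b)[, c(by, "locus", "allele")]
  out
}

#' Multilocus genotypes
#'
#' Assigns each sample its multilocus genotype (MLG): the tuple of unordered
#' allele pairs across loci. By default a missing call is a distinct state,
#' so two samples differing only in missingness are distinct MLGs;
#' `missing = "wildcard"` instead lets a missing call match anything
#' (greedy assignment in sample order, documented tie-break).
#'
#' @param gt A genotype tibble.
#' @param by Optional grouping metadata columns; MLG identity is always
#'   computed dataset-wide, counts are per group.
#' @param missing `"state"` (default) or `"wildcard"`.
#' @return A tibble with the grouping columns (if any), `N` and `MLG`;
#'   per-sample assignments (`sample_id`, `mlg`) in the `"assignments"`
#'   attribute.
#' @export
count_mlg <- function(gt, by = NULL, missing = c("state", "wildcard")) {
  missing <- match.arg(missing)
  loci <- genotype_loci(gt)
  keymat <- sapply(loci, function(loc) {
    a <- gt[[paste0(loc, "_1")]]
    b <- gt[[paste0(loc, "_2")]]
    k <- paste0(pmin(a, b), "/", pmax(a, b))
    k[is.na(a) | is.na(b)] <- "."
    k
  })
  keymat <- matrix(keymat, nrow = nrow(gt))
  if (missing == "state") {
    key <- apply(keymat, 1, paste, collapse = "|")
    mlg <- match(key, unique(key))
  } else {
    mlg <- integer(nrow(gt))
    reps <- list() # representative key rows per MLG class
    for (i in seq_len(nrow(gt))) {
      row <- keymat[i, ]
      hit <- 0L
      for (m in seq_along(reps)) {
        r <- reps[[m]]
        ok <- all(row == r | row == "." | r == ".")
        if (ok) { hit <- m; break }
      }
      if (hit == 0L) {
        reps[[length(reps) + 1L]] <- row
        hit <- length(reps)
      } else {
        # refine representative where it was missing
        r <- reps[[hit]]
        r[r == "."] <- row[r == "."]
        reps[[hit]] <- r
      }
      mlg[i] <- hit
    }
  }
  assignments <- tibble(sample_id = gt$sample_id, mlg = mlg)
  if (is.null(by)) {
    out <- tibble(N = nrow(gt), MLG = dplyr::n_distinct(mlg))
  } else {
    out <- gt |>
      mutate(mlg = mlg) |>
      group_by(across(all_of(by))) |>
      summarise(N = dplyr::n(), MLG = dplyr::n_distinct(.data$mlg),
                .groups = "drop")
  }
  attr(out, "assignments") <- assignments
  out
}

#' Genotypic diversity indices from MLG abundances
#'
#' Shannon-Wiener `H' = -sum p_i log(p_i)` (natural log), Simpson
#' `lambda = 1 - sum p_i^2`, and evenness
#' `E5 = ((1/sum p_i^2) - 1)/(exp(H') - 1)`, with `E5 = 1` for a single
#' MLG.
#'
#' @param abundances Positive integer vector of MLG abundances.
#' @return A one-row tibble with `Hprime`, `lambda`, `E5`.
#' @export
#' @examples
#' genotypic_diversity(c(2, 1, 1))
genotypic_diversity <- function(abundances) {
  if (length(abundances) == 0) abort("empty abundance vector")
  stopifnot(all(abundances > 0))
  p <- abundances / sum(abundances)
  hprime <- -sum(p * log(p))
  sumsq <- sum(p^2)
  lambda <- 1 - sumsq
  # uniform abundances give E5 = 1 exactly (avoids rounding past the bound)
  e5 <- if (length(p) == 1 || length(unique(abundances)) == 1) 1 else
    ((1 / sumsq) - 1) / (exp(hprime) - 1)
  tibble(Hprime = hprime, lambda = lambda, E5 = e5)
}

#' Observed and expected heterozygosity
#'
#' Per locus, `Ho` is the fraction of heterozygous non-missing calls and
#' `Hexp` is Nei's gene diversity `1 - sum p_i^2`, by default with the
#' small-sample correction `n_c/(n_c - 1)` (`n_c` = non-missing gene
#' copies). Group values are unweighted means over loci with at least two
#' gene copies; excluded loci are flagged.
#'
#' @param gt A genotype tibble.
#' @param by Grouping metadata columns.
#' @param unbiased Apply the `n_c/(n_c - 1)` correction (default TRUE).
#' @return A tibble with the grouping columns, `Ho`, `Hexp` and `n_loci`;
#'   per-locus values in the `"per_locus"` attribute.
#' @export
heterozygosity <- function(gt, by = "role", unbiased = TRUE) {
  long <- filter(tidy_genotypes(gt), !.data$missing)
  ho <- long |>
    group_by(across(all_of(by)), .data$locus) |>
    summarise(n_calls = dplyr::n(),
              Ho_locus = mean(.data$allele_1 != .data$allele_2),
              .groups = "drop")
  hexp <- allele_counts(gt, by) |>
    group_by(across(all_of(by)), .data$locus, .data$n_copies) |>
    summarise(sumsq = sum((.data$n_allele / .data$n_copies)^2),
              .groups = "drop") |>
    mutate(Hexp_locus = (1 - .data$sumsq) *
             if (unbiased) .data$n_copies / (.data$n_copies - 1) else 1)
  per_locus <- dplyr::inner_join(ho, hexp, by = c(by, "locus"))
  excluded <- filter(per_locus, .data$n_copies < 2)
  per_locus <- filter(per_locus, .data$n_copies >= 2)
  out <- per_locus |>
    group_by(across(all_of(by))) |>
    summarise(Ho = mean(.data$Ho_locus), Hexp = mean(.data$Hexp_locus),
              n_loci = dplyr::n(), .groups = "drop")
  attr(out, "per_locus") <- per_locus
  attr(out, "excluded_loci") <- excluded
  out
}

#' Inbreeding coefficient Fis
#'
#' Ratio-of-averages estimator `Fis = 1 - mean(Ho_l)/mean(Hexp_l)` over
#' loci with `Hexp_l > 0`. Negative values indicate heterozygote excess.
#' Groups whose loci are all monomorphic get `NA` with a warning.
#'
#' @inheritParams heterozygosity
#' @return A tibble with the grouping columns and `Fis`; per-locus Fis in
#'   the `"per_locus"` attribute.
#' @export
inbreeding_coefficient <- function(gt, by = "population", unbiased = TRUE) {
  het <- heterozygosity(gt, by = by, unbiased = unbiased)
  per_locus <- attr(het, "per_locus") |>
    filter(.data$Hexp_locus > 0) |>
    mutate(Fis_locus = 1 - .data$Ho_locus / .data$Hexp_locus)
  out <- per_locus |>
    group_by(across(all_of(by))) |>
    summarise(Fis = 1 - mean(.data$Ho_locus) / mean(.data$Hexp_locus),
              .groups = "drop")
  all_groups <- distinct(het, across(all_of(by)))
  out <- left_join(all_groups, out, by = by)
  if (anyNA(out$Fis)) {
    warn("Fis undefined for group(s) with no polymorphic locus (NA returned)")
  }
  attr(out, "per_locus") <- per_locus
  out
}

#' Genetic capture proportion
#'
#' Allelic richness of a seed collection as a percentage of its source
#' population's allelic richness.
#'
#' @param ar_seeds,ar_population Allelic richness values on the same locus
#'   panel and rarefaction depth.
#' @param digits Optional rounding (use 0 for headline integer percent).
#' @return Percentage (vectorised).
#' @export
#' @examples
#' capture_proportion(37, 73, digits = 0) # 51
capture_proportion <- function(ar_seeds, ar_population, digits = NULL) {
  if (any(ar_population == 0)) abort("population allelic richness is zero")
  pct <- 100 * ar_seeds / ar_population
  if (!is.null(digits)) pct <- round(pct, digits)
  pct
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite fractional degrees
#' of freedom and a two-sided p-value, for comparing per-locality index
#' values between seeds and populations. Degenerate zero-variance input is
#' handled without error (t = 0, p = 1 for equal means).
#'
#' @param a,b Numeric vectors of index values (length >= 2 each).
#' @return A one-row tibble with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) + stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    return(tibble(t = sign(mean(a) - mean(b)) * Inf,
                  df = length(a) + length(b) - 2, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
}

#' Allele frequency spectrum
#'
#' Flat list of allele relative frequencies across loci per group, the
#' numeric input of frequency-density summaries, with a rare-allele count
#' at a given threshold.
#'
#' @param gt A genotype tibble.
#' @param by Grouping metadata columns.
#' @param rare_threshold Frequencies strictly below this are "rare".
#' @return A tibble (grouping columns, `locus`, `allele`, `freq`, `rare`);
#'   per-group rare/total counts in the `"rare_counts"` attribute.
#' @export
allele_frequency_spectrum <- function(gt, by = "role", rare_threshold = 0.05) {
  freq <- allele_frequencies(gt, by = by)
  out <- mutate(freq, rare = .data$freq < rare_threshold)
  counts <- out |>
    group_by(across(all_of(by))) |>
    summarise(n_rare = sum(.data$rare), n_alleles = dplyr::n(),
              .groups = "drop")
  attr(out, "rare_counts") <- counts
  out
}

#' Diversity summary table
#'
#' One row per group with the standard description of a codominant dataset:
#' sample count `N`, rarefied allelic richness `AR` (summed over loci),
#' private alleles `PA` (only when the grouping yields exactly two groups,
#' each counted against the other), multilocus genotype count `MLG`,
#' genotypic diversity `Hprime`, `lambda`, `E5` on MLG abundances, and
#' `Hexp`, `Ho`, `Fis` averaged over loci.
#'
#' @inheritParams allelic_richness
#' @param unbiased Small-sample correction for `Hexp` (default TRUE).
#' @return A tibble, one row per group.
#' @export
#' @examples
#' gt <- sim_dataset_example()
#' diversity_summary(gt, by = "role")
diversity_summary <- function(gt, by = "role", g = "auto", unbiased = TRUE) {
  ar <- allelic_richness(gt, by = by, g = g)
  mlg <- count_mlg(gt, by = by)
  assignments <- attr(mlg, "assignments")
  gd <- gt |>
    mutate(mlg = assignments$mlg[match(.data$sample_id,
                                       assignments$sample_id)]) |>
    group_by(across(all_of(by))) |>
    summarise(gdiv = list(genotypic_diversity(as.integer(table(.data$mlg)))),
              .groups = "drop") |>
    tidyr::unnest("gdiv")
  het <- heterozygosity(gt, by = by, unbiased = unbiased)
  fis <- suppressWarnings(inbreeding_coefficient(gt, by = by,
                                                 unbiased = unbiased))
  out <- mlg |>
    left_join(select(ar, all_of(by), "AR"), by = by) |>
    left_join(gd, by = by) |>
    left_join(select(het, all_of(by), "Hexp", "Ho"), by = by) |>
    left_join(fis, by = by)
  grp_tbl <- distinct(out, across(all_of(by)))
  if (nrow(grp_tbl) == 2) {
    pa <- private_alleles(gt, by = by)
    out <- left_join(out, rename(pa, PA = "n_private"), by = by)
  } else {
    out$PA <- NA_integer_
  }
  out <- select(out, all_of(by), "N", "AR", "PA", "MLG", "Hprime", "lambda",
                "E5", "Hexp", "Ho", "Fis")
  attr(out, "assignments") <- NULL
  out
}
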