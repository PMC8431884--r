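#' Allele incidence matrix over collection units
#'
#' Reduces a genotype table to presence/absence of each (locus, allele) pair
#' across collection units: local populations (adult plants), seed bunches,
#' or individual seeds within one bunch. This is the input of the richness
#' extrapolators and accumulation curves.
#'
#' @param gt A genotype tibble.
#' @param unit `"population"` (adult plants grouped by population),
#'   `"bunch"` (seeds grouped by bunch) or `"seed"` (individual seeds of a
#'   single bunch).
#' @param bunch For `unit = "seed"`: which bunch to use; may be omitted when
#'   the table holds exactly one bunch.
#' @return An object of class `"incidence_matrix"`: a list with `units`
#'   (ordered labels), `alleles` (tibble `locus`, `allele`), `presence`
#'   (logical units x alleles matrix) and `unit_type`.
#' @export
#' @examples
#' gt <- sim_dataset_example()
#' build_incidence(gt, unit = "population")
build_incidence <- function(gt, unit = c("population", "bunch", "seed"),
                            bunch = NULL) {
  unit <- match.arg(unit)
  if (unit == "population") {
    sub <- pool_genotypes(gt, "population")
    sub$unit <- sub$population
  } else {
    sub <- pool_genotypes(gt, "seed")
    if (unit == "seed") {
      bunches <- unique(sub$bunch)
      if (is.null(bunch)) {
        if (length(bunches) > 1) {
          abort("several bunches present; pick one with bunch =")
        }
        bunch <- bunches
      }
      sub <- filter(sub, .data$bunch == !!bunch)
      if (nrow(sub) == 0) abort(paste0("no seeds in bunch '", bunch, "'"))
      sub$unit <- sub$sample_id
    } else {
      sub$unit <- sub$bunch
    }
  }
  units <- unique(sub$unit)
  if (unit != "seed" && length(units) < 2) {
    abort(paste0("need at least 2 ", unit, " units"))
  }
  long <- alleles_long(sub)
  empty <- setdiff(units, unique(long$unit))
  if (length(empty) > 0) {
    abort(paste0("unit(s) without any non-missing call: ",
                 paste(empty, collapse = ", ")))
  }
  alleles <- long |>
    distinct(.data$locus, .data$allele) |>
    arrange(.data$locus, .data$allele)
  akey <- paste(alleles$locus, alleles$allele)
  presence <- matrix(FALSE, nrow = length(units), ncol = nrow(alleles),
                     dimnames = list(units, akey))
  seen <- distinct(long, .data$unit, .data$locus, .data$allele)
  presence[cbind(match(seen$unit, units),
                 match(paste(seen$locus, seen$allele), akey))] <- TRUE
  structure(list(units = units, alleles = alleles, presence = presence,
                 unit_type = unit),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat("<incidence_matrix>", length(x$units), x$unit_type, "units x",
      nrow(x$alleles), "alleles\n")
  invisible(x)
}

#' Extrapolate total allelic richness from incidence data
#'
#' Incidence-based estimators of the total (observed + unobserved) number
#' of alleles in the region or bunch the units were sampled from:
#'
#' * `bootstrap`: `S_obs + sum_i (1 - p_i)^n`, `p_i` the fraction of units
#'   containing allele `i`;
#' * `chao2` (classic): `S_obs + q1^2/(2 q2)` when `q2 > 0`, else the
#'   bias-corrected `S_obs + q1 (q1 - 1)/2`;
#' * `jackknife1`: `S_obs + q1 (n - 1)/n`;
#'
#' with `q1`/`q2` the numbers of alleles occurring in exactly 1/2 units.
#'
#' @param incidence An [build_incidence()] object.
#' @param estimator Estimator name.
#' @return A one-row tibble: `estimator`, `n_units`, `S_obs`, `q1`, `q2`,
#'   `S_hat`, `se` (Chao2 only, `NA` otherwise).
#' @export
extrapolate_total_richness <- function(incidence,
                                       estimator = c("bootstrap", "chao2",
                                                     "jackknife1")) {
  estimator <- match.arg(estimator)
  f <- colSums(incidence$presence)
  n <- nrow(incidence$presence)
  s_obs <- length(f)
  q1 <- sum(f == 1)
  q2 <- sum(f == 2)
  se <- NA_real_
  if (estimator == "bootstrap") {
    p <- f / n
    s_hat <- s_obs + sum((1 - p)^n)
  } else if (estimator == "chao2") {
    if (n < 2) abort("chao2 needs at least 2 units")
    if (q2 > 0) {
      s_hat <- s_obs + q1^2 / (2 * q2)
      r <- q1 / q2
      se <- sqrt(q2 * (r^2 / 2 + r^3 + r^4 / 4))
    } else {
      s_hat <- s_obs + q1 * (q1 - 1) / 2
    }
  } else {
    if (n < 2) abort("jackknife1 needs at least 2 units")
    s_hat <- s_obs + q1 * (n - 1) / n
  }
  tibble(estimator = estimator, n_units = n, S_obs = s_obs,
         q1 = q1, q2 = q2, S_hat = s_hat, se = se)
}

# analytic mean accumulation: E[S_k] = sum_i 1 - C(n-f_i, k)/C(n, k)
exact_accumulation <- function(f, n) {
  sapply(seq_len(n), function(k) {
    sum(1 - exp(lchoose(n - f, k) - lchoose(n, k)))
  })
}

#' Allele accumulation curve over collection units
#'
#' Expected cumulative number of distinct alleles as collection units are
#' added, either analytically (`method = "exact"`, the mean over all unit
#' orderings) or by resampling unit orderings (`method = "random"`,
#' permutations without replacement by default, giving a per-step standard
#' deviation as well). The curve is normalised as a percentage of an
#' extrapolated total richness, by default estimated from the same
#' incidence matrix; pass `total` to normalise against an external
#' reference (e.g. bunch curves against the extrapolated total regional
#' richness of the populations).
#'
#' @param incidence An [build_incidence()] object.
#' @param n_resamples Number of resampled orderings (`method = "random"`).
#' @param method `"random"` or `"exact"`.
#' @param estimator Estimator used for the normalising total when `total`
#'   is not given (see [extrapolate_total_richness()]).
#' @param total Optional external total richness to normalise against.
#' @param seed Optional RNG seed for the resampling.
#' @param replace Resample units with replacement (strict bootstrap
#'   semantics) instead of permuting them.
#' @return A tibble of class `"accumulation_curve"` with columns `k`,
#'   `mean`, `sd`, `pct` and attributes `unit_type`, `n_units`, `S_obs`,
#'   `S_hat`, `estimator`, `method`, `n_resamples`, `replace`.
#' @export
#' @examples
#' gt <- sim_dataset_example()
#' inc <- build_incidence(gt, unit = "population")
#' accumulation_curve(inc, method = "exact")
accumulation_curve <- function(incidence, n_resamples = 999,
                               method = c("random", "exact"),
                               estimator = "bootstrap", total = NULL,
                               seed = NULL, replace = FALSE) {
  method <- match.arg(method)
  pres <- incidence$presence
  n <- nrow(pres)
  f <- colSums(pres)
  s_obs <- ncol(pres)
  if (is.null(total)) {
    total <- extrapolate_total_richness(incidence, estimator)$S_hat
  } else {
    estimator <- "external"
  }
  if (method == "exact") {
    if (replace) abort("replace = TRUE requires method = 'random'")
    means <- exact_accumulation(f, n)
    sds <- rep(NA_real_, n)
  } else {
    if (n_resamples < 1) abort("n_resamples must be >= 1")
    run <- function() {
      acc <- matrix(0, nrow = n_resamples, ncol = n)
      for (r in seq_len(n_resamples)) {
        ord <- if (replace) sample.int(n, n, replace = TRUE) else sample.int(n)
        m <- pres[ord, , drop = FALSE]
        first <- apply(m, 2, which.max)       # first unit containing allele
        first[colSums(m) == 0] <- NA          # possible under replacement
        acc[r, ] <- cumsum(tabulate(first[!is.na(first)], nbins = n))
      }
      acc
    }
    acc <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
    means <- colMeans(acc)
    sds <- apply(acc, 2, stats::sd)
  }
  out <- tibble(k = seq_len(n), mean = means, sd = sds,
                pct = 100 * means / total)
  structure(out,
            class = c("accumulation_curve", class(out)),
            unit_type = incidence$unit_type, n_units = n, S_obs = s_obs,
            S_hat = total, estimator = estimator, method = method,
            n_resamples = if (method == "random") n_resamples else NA_integer_,
            replace = replace)
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat("<accumulation_curve>", attr(x, "n_units"), attr(x, "unit_type"),
      "units; S_obs =", attr(x, "S_obs"),
      "| S_hat =", round(attr(x, "S_hat"), 2),
      paste0("(", attr(x, "estimator"), "); method = ", attr(x, "method")),
      "\n")
  NextMethod()
}

#' Collection units needed to reach capture targets
#'
#' Smallest number of units whose expected cumulative allele count reaches
#' each target percentage of the extrapolated total. When even all observed
#' units fall short, a two-parameter saturating (Michaelis-Menten) curve
#' `S(k) = V k/(K + k)` is least-squares fitted to the mean curve (starting
#' values `V = S_hat`, `K = n/2`) and the extrapolated unit count is
#' reported, flagged `"extrapolated"`.
#'
#' @param curve An [accumulation_curve()].
#' @param targets Target percentages in `(0, 100]`.
#' @param extrapolate Fit the saturating curve for unreached targets.
#' @return A tibble with `target`, `k` (units; `NA` when unreachable) and
#'   `source` (`"observed"`, `"extrapolated"` or `"not_reached"`).
#' @export
units_to_threshold <- function(curve, targets = c(70, 90),
                               extrapolate = TRUE) {
  if (any(targets <= 0 | targets > 100)) {
    abort("targets must be in (0, 100]")
  }
  s_hat <- attr(curve, "S_hat")
  n <- attr(curve, "n_units")
  fit <- NULL
  if (extrapolate && any(100 * curve$mean / s_hat < max(targets))) {
    df <- data.frame(k = curve$k, y = curve$mean)
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(y ~ V * k / (K + k), data = df,
                   start = list(V = s_hat, K = n / 2),
                   control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
  }
  rows <- purrr::map(sort(targets), function(t) {
    hit <- which(curve$pct >= t)
    if (length(hit) > 0) {
      return(tibble(target = t, k = min(hit), source = "observed"))
    }
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      want <- t / 100 * s_hat
      if (cf[["V"]] > want && cf[["K"]] > 0) {
        k_ext <- ceiling(cf[["K"]] * want / (cf[["V"]] - want))
        return(tibble(target = t, k = as.numeric(k_ext),
                      source = "extrapolated"))
      }
    }
    tibble(target = t, k = NA_real_, source = "not_reached")
  })
  list_rbind(rows)
}

#' Allele membership across groupings
#'
#' Which alleles occur in which grouping — the numeric content of
#' Euler/Venn summaries of shared and private alleles.
#'
#' @param x Either a genotype tibble (then split by `by`) or a named list
#'   of genotype tibbles, one per grouping (at least two).
#' @param by Grouping metadata column(s) when `x` is a single tibble.
#' @return A wide tibble (`locus`, `allele`, one logical column per group)
#'   with attributes `"pairwise"` (tibble `group_a`, `group_b`, `shared`,
#'   `only_a`, `only_b`) and `"shared_by_all"` (count).
#' @export
#' @examples
#' gt <- sim_dataset_example()
#' m <- allele_membership(gt, by = "role")
#' attr(m, "pairwise")
allele_membership <- function(x, by = "role") {
  if (is.data.frame(x)) {
    x$group <- interaction(x[by], drop = TRUE, sep = "/")
    groups <- split(x, x$group)
  } else {
    groups <- x
  }
  if (length(groups) < 2) abort("need at least two groupings")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("groupings must be named")
  }
  sets <- purrr::map(groups, function(g) {
    distinct(alleles_long(as_tibble(g)), .data$locus, .data$allele)
  })
  all_alleles <- distinct(bind_rows(sets), .data$locus, .data$allele) |>
    arrange(.data$locus, .data$allele)
  out <- all_alleles
  for (nm in names(sets)) {
    key <- paste(all_alleles$locus, all_alleles$allele)
    out[[nm]] <- key %in% paste(sets[[nm]]$locus, sets[[nm]]$allele)
  }
  memb <- as.matrix(out[names(sets)])
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  pairwise <- list_rbind(purrr::map(pairs, function(p) {
    a <- memb[, p[1]]
    b <- memb[, p[2]]
    tibble(group_a = p[1], group_b = p[2],
           shared = sum(a & b), only_a = sum(a & !b), only_b = sum(!a & b))
  }))
  attr(out, "pairwise") <- pairwise
  attr(out, "shared_by_all") <- sum(rowSums(memb) == ncol(memb))
  out
}
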