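suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# Build a genotype tibble from a list of per-sample metadata + allele pairs.
# calls: named list locus -> c(a1, a2) (NA for missing)
gt_row <- function(id, pop, role, calls, bunch = NA, lat = NA, lon = NA) {
  row <- tibble(sample_id = id, population = pop, role = role,
                bunch = as.character(bunch), lat = as.numeric(lat),
                lon = as.numeric(lon))
  for (loc in names(calls)) {
    row[[paste0(loc, "_1")]] <- as.integer(calls[[loc]][1])
    row[[paste0(loc, "_2")]] <- as.integer(calls[[loc]][2])
  }
  row
}

# small two-population fixture: 4 adults + 2 seeds, 2 loci
gt_tiny <- function() {
  bind_rows(
    gt_row("a1", "p1", "population", list(L1 = c(101, 103), L2 = c(200, 200)),
           lat = 0, lon = 0),
    gt_row("a2", "p1", "population", list(L1 = c(101, 101), L2 = c(200, 202)),
           lat = 0, lon = 0),
    gt_row("b1", "p2", "population", list(L1 = c(103, 105), L2 = c(202, 202)),
           lat = 0, lon = 1),
    gt_row("b2", "p2", "population", list(L1 = c(105, 105), L2 = c(200, 202)),
           lat = 0, lon = 1),
    gt_row("s1", "p1", "seed", list(L1 = c(101, 103), L2 = c(200, 200)),
           bunch = "B1", lat = 0, lon = 0),
    gt_row("s2", "p2", "seed", list(L1 = c(103, 103), L2 = c(202, 202)),
           bunch = "B2", lat = 0, lon = 1))
}

# random small genotype tibble (single group) for oracle tests
random_gt <- function(seed, n_samples = 5, n_loci = 3, k = 4,
                      missing_rate = 0.15) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_samples), function(i) {
      calls <- lapply(seq_len(n_loci), function(l) {
        if (runif(1) < missing_rate) return(c(NA, NA))
        100 + 2 * sort(sample.int(k, 2, replace = TRUE))
      })
      names(calls) <- sprintf("L%02d", seq_len(n_loci))
      gt_row(sprintf("s%02d", i), "p1", "population", calls)
    })
    bind_rows(rows)
  })
}

# Exhaustive rarefaction oracle: mean number of distinct alleles over all
# C(N, g) subsamples of the gene copies.
enum_rarefaction <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(idx) length(unique(copies[idx]))))
}

# Exhaustive accumulation oracle: mean cumulative distinct alleles over all
# n! unit orderings of a presence matrix.
enum_accumulation <- function(presence) {
  n <- nrow(presence)
  perms <- perm_all(n)
  acc <- sapply(perms, function(ord) {
    m <- presence[ord, , drop = FALSE]
    first <- apply(m, 2, which.max)
    cumsum(tabulate(first, nbins = n))
  })
  rowMeans(acc)
}

perm_all <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perm_all(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# Definitional AMOVA oracle: explicit pair loops over squared distances.
amova_oracle <- function(d2, grouping) {
  n <- nrow(d2)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    s <- 0
    if (length(idx) > 1) {
      for (a in seq_along(idx)[-length(idx)]) {
        for (b in (a + 1):length(idx)) s <- s + d2[idx[a], idx[b]]
      }
    }
    ss_within <- ss_within + s / length(idx)
  }
  sizes <- table(grouping)
  G <- length(sizes)
  ss_among <- ss_total - ss_within
  ms_among <- ss_among / (G - 1)
  ms_within <- ss_within / (n - G)
  n0 <- (n - sum(sizes^2) / n) / (G - 1)
  s2w <- ms_within
  s2a <- max(0, (ms_among - ms_within) / n0)
  list(ssd_among = ss_among, ssd_within = ss_within,
       sigma2 = c(among = s2a, within = s2w),
       phi = s2a / (s2a + s2w))
}

# incidence_matrix built directly from a list of unit allele sets
incidence_from_sets <- function(sets) {
  alleles <- sort(unique(unlist(sets)))
  presence <- t(sapply(sets, function(s) alleles %in% s))
  rownames(presence) <- names(sets) %||% paste0("u", seq_along(sets))
  colnames(presence) <- paste("L1", alleles)
  structure(list(units = rownames(presence),
                 alleles = tibble(locus = "L1", allele = alleles),
                 presence = presence, unit_type = "population"),
            class = "incidence_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
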