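#' Inter-individual genetic distance matrix
#'
#' Pairwise distances between diploid individuals used by [amova()]. The
#' default `"mismatch"` distance counts allele differences per locus (0 for
#' identical unordered pairs, 1 when sharing exactly one allele, 2 when
#' sharing none) and sums over loci; `"euclidean"` is the squared Euclidean
#' distance on per-allele dosage (0/1/2) vectors. Loci with a missing call
#' in either sample are skipped pairwise and the distance rescaled by
#' `L/L_compared`; pairs compared on fewer than half the loci are flagged.
#'
#' @param gt A genotype tibble.
#' @param distance `"mismatch"` or `"euclidean"`.
#' @return A symmetric numeric matrix with sample ids as dimnames and a
#'   logical `"low_overlap"` attribute marking rescaled pairs with
#'   `L_compared < L/2`.
#' @export
individual_distances <- function(gt, distance = c("mismatch", "euclidean")) {
  distance <- match.arg(distance)
  loci <- genotype_loci(gt)
  n <- nrow(gt)
  total <- matrix(0, n, n)
  compared <- matrix(0L, n, n)
  for (loc in loci) {
    a <- pmin(gt[[paste0(loc, "_1")]], gt[[paste0(loc, "_2")]])
    b <- pmax(gt[[paste0(loc, "_1")]], gt[[paste0(loc, "_2")]])
    ok <- !is.na(a)
    if (distance == "mismatch") {
      eq2 <- outer(a, a, "==") & outer(b, b, "==")
      share <- outer(a, a, "==") | outer(a, b, "==") |
        outer(b, a, "==") | outer(b, b, "==")
      d <- 2 - share - eq2          # 0 if identical, 1 if one shared, 2 else
    } else {
      codes <- sort(unique(c(a[ok], b[ok])))
      dose <- sapply(codes, function(cd) (a == cd) + (b == cd))
      dose <- matrix(dose, nrow = n)
      d <- as.matrix(stats::dist(dose))^2
    }
    d[!ok, ] <- 0
    d[, !ok] <- 0
    total <- total + ifelse(is.na(d), 0, d)
    compared <- compared + as.integer(outer(ok, ok, "&"))
  }
  if (any(compared[upper.tri(compared)] == 0)) {
    abort("sample pair(s) share no scored locus")
  }
  scaled <- total * length(loci) / pmax(compared, 1)
  diag(scaled) <- 0
  dimnames(scaled) <- list(gt$sample_id, gt$sample_id)
  attr(scaled, "low_overlap") <- compared < length(loci) / 2 & compared > 0
  scaled
}

phi_from_d2 <- function(d2, grouping) {
  n <- nrow(d2)
  groups <- split(seq_len(n), grouping)
  sizes <- lengths(groups)
  g <- length(groups)
  ssd_total <- sum(d2) / (2 * n)
  ssd_within <- sum(purrr::map_dbl(groups, function(idx) {
    sum(d2[idx, idx]) / (2 * length(idx))
  }))
  ssd_among <- ssd_total - ssd_within
  df_among <- g - 1
  df_within <- n - g
  ms_among <- ssd_among / df_among
  ms_within <- ssd_within / df_within
  n0 <- (n - sum(sizes^2) / n) / (g - 1)
  sigma_w <- ms_within
  sigma_a <- (ms_among - ms_within) / n0
  truncated <- sigma_a < 0
  if (truncated) sigma_a <- 0
  list(ssd = c(among = ssd_among, within = ssd_within, total = ssd_total),
       df = c(among = df_among, within = df_within, total = n - 1),
       ms = c(among = ms_among, within = ms_within),
       sigma2 = c(among = sigma_a, within = sigma_w),
       phi = if (sigma_a + sigma_w > 0) sigma_a / (sigma_a + sigma_w) else NA,
       truncated = truncated)
}

#' Analysis of molecular variance (AMOVA)
#'
#' Distance-based two-level AMOVA partitioning molecular variance among and
#' within local populations from squared inter-individual distances
#' (Excoffier-style sums of squares with unequal group sizes). The
#' phi-statistic `sigma2_among/(sigma2_among + sigma2_within)` measures
#' among-population differentiation; negative among-group components are
#' truncated to zero and flagged.
#'
#' @param gt A genotype tibble; only samples with `role = role` enter.
#' @param by Metadata column defining the groups (default `"population"`).
#' @param role Which samples to analyse (default adult population plants).
#' @param distance Inter-individual distance, see [individual_distances()].
#' @return An object of class `"capture_amova"`; see [tidy.capture_amova()]
#'   and [glance.capture_amova()].
#' @export
#' @examples
#' gt <- sim_dataset_example()
#' amova(gt)
amova <- function(gt, by = "population", role = "population",
                  distance = c("mismatch", "euclidean")) {
  distance <- match.arg(distance)
  sub <- pool_genotypes(gt, role)
  grouping <- interaction(sub[by], drop = TRUE)
  sizes <- table(grouping)
  if (length(sizes) < 2) abort("AMOVA needs at least 2 groups")
  if (any(sizes < 2)) {
    abort(paste0("group(s) with a single sample: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  d <- individual_distances(sub, distance)
  d2 <- d^2
  res <- phi_from_d2(d2, grouping)
  if (is.na(res$phi)) {
    warn("all samples identical: phi undefined")
  }
  structure(c(res, list(
    percent_within = 100 * res$sigma2[["within"]] /
      sum(res$sigma2),
    distance = distance, by = by, n = nrow(sub),
    n_groups = length(sizes), p = NA_real_,
    n_permutations = NA_integer_)),
    class = "capture_amova")
}

#' Permutation test for AMOVA differentiation
#'
#' Permutes individuals among groups (group sizes fixed), recomputes phi,
#' and reports the one-sided plus-one-corrected p-value
#' `(count(phi_perm >= phi_obs) + 1)/(n_permutations + 1)`.
#'
#' @inheritParams amova
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Optional RNG seed.
#' @return The `"capture_amova"` object with `p`, `n_permutations` filled
#'   and the permuted phi values in the `"phi_perm"` attribute.
#' @export
amova_permutation_test <- function(gt, by = "population",
                                   role = "population",
                                   distance = c("mismatch", "euclidean"),
                                   n_permutations = 999, seed = NULL) {
  distance <- match.arg(distance)
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  obs <- amova(gt, by = by, role = role, distance = distance)
  sub <- pool_genotypes(gt, role)
  grouping <- interaction(sub[by], drop = TRUE)
  d2 <- individual_distances(sub, distance)^2
  run <- function() {
    purrr::map_dbl(seq_len(n_permutations), function(i) {
      phi_from_d2(d2, sample(grouping))$phi
    })
  }
  phi_perm <- if (is.null(seed)) run() else
    withr::with_seed(as.integer(seed), run())
  obs$p <- (sum(phi_perm >= obs$phi, na.rm = TRUE) + 1) /
    (n_permutations + 1)
  obs$n_permutations <- as.integer(n_permutations)
  attr(obs, "phi_perm") <- phi_perm
  obs
}

#' @export
print.capture_amova <- function(x, ...) {
  cat("AMOVA (", x$distance, " distance, ", x$n, " samples in ",
      x$n_groups, " groups)\n", sep = "")
  print(tidy.capture_amova(x))
  cat(sprintf("phi = %.4f; %% within = %.1f", x$phi, x$percent_within))
  if (!is.na(x$p)) {
    cat(sprintf("; p = %.4g (%d permutations)", x$p, x$n_permutations))
  }
  cat("\n")
  if (isTRUE(x$truncated)) cat("note: negative among-group variance truncated to 0\n")
  invisible(x)
}

#' @describeIn amova Tidy the variance decomposition (one row per stratum).
#' @param x A `"capture_amova"` object.
#' @param ... Unused.
#' @export
tidy.capture_amova <- function(x, ...) {
  tibble(source = c("among", "within", "total"),
         df = as.numeric(x$df[c("among", "within", "total")]),
         SSD = as.numeric(x$ssd[c("among", "within", "total")]),
         MS = c(as.numeric(x$ms), NA),
         sigma2 = c(as.numeric(x$sigma2), NA))
}

#' @describeIn amova One-row summary (phi, percent within, p).
#' @export
glance.capture_amova <- function(x, ...) {
  tibble(phi = x$phi, percent_within = x$percent_within,
         percent_among = 100 - x$percent_within,
         p = x$p, n_permutations = x$n_permutations,
         n = x$n, n_groups = x$n_groups)
}

#' Nei (1972) standard genetic distance between groupings
#'
#' For each pair of groups with allele frequency profiles `x`, `y`:
#' identity `I = Jxy/sqrt(Jx Jy)` where `Jxy = sum_l sum_i x_li y_li`,
#' `Jx = sum_l sum_i x_li^2` (sums over loci taken before the ratio), and
#' distance `D = -log(I)`. Loci without data in either group of a pair are
#' skipped for that pair. `I = 0` yields `D = Inf`, which is kept and
#' flagged rather than capped.
#'
#' @param gt A genotype tibble.
#' @param by Grouping metadata column(s) (default population x role, the
#'   local populations and local seed lots).
#' @return A `stats::dist` object with a `"has_infinite"` attribute.
#' @export
nei_distance <- function(gt, by = c("role", "population")) {
  freq <- allele_frequencies(gt, by = by)
  freq$group <- interaction(freq[by], drop = TRUE, sep = "/")
  groups <- levels(freq$group)
  if (length(groups) < 2) abort("need at least 2 groups")
  parts <- split(freq, freq$group)
  m <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_along(groups)) {
    for (j in seq_len(i - 1)) {
      x <- parts[[groups[i]]]
      y <- parts[[groups[j]]]
      shared <- intersect(unique(x$locus), unique(y$locus))
      if (length(shared) == 0) {
        abort(paste0("no shared locus with data: ", groups[i], " vs ",
                     groups[j]))
      }
      x <- x[x$locus %in% shared, ]
      y <- y[y$locus %in% shared, ]
      key_x <- paste(x$locus, x$allele)
      key_y <- paste(y$locus, y$allele)
      common <- intersect(key_x, key_y)
      jxy <- sum(x$freq[match(common, key_x)] * y$freq[match(common, key_y)])
      jx <- sum(x$freq^2)
      jy <- sum(y$freq^2)
      ident <- jxy / sqrt(jx * jy)
      m[i, j] <- m[j, i] <- if (ident <= 0) Inf else -log(ident)
    }
  }
  d <- stats::as.dist(m)
  attr(d, "method") <- "nei1972"
  attr(d, "has_infinite") <- any(is.infinite(m))
  d
}

#' Complete-linkage hierarchical clustering of groupings
#'
#' Agglomerative clustering of a genetic distance matrix (complete linkage
#' by default: cluster distance = maximum pairwise distance). Ties are
#' broken deterministically by input label order. Infinite distances are
#' refused with advice to cap them explicitly.
#'
#' @param d A `dist` or symmetric matrix.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return An `hclust` object.
#' @seealso [as_newick()] for Newick export.
#' @export
hierarchical_clustering <- function(d, linkage = "complete") {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) abort("distance matrix is not symmetric")
    d <- stats::as.dist(d)
  }
  if (any(is.infinite(d))) {
    abort("infinite distances; cap them explicitly before clustering")
  }
  stats::hclust(d, method = linkage)
}

#' Export a dendrogram as a Newick string
#'
#' @param hc An `hclust` object.
#' @return A single Newick string with branch lengths from merge heights.
#' @export
as_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries of two distance matrices
#' over the same labels (typically geographic vs genetic distances, testing
#' isolation by distance), with a one-sided (greater) permutation p-value
#' under simultaneous row/column permutations of one matrix, plus-one
#' corrected.
#'
#' @param d_a,d_b `dist` objects or symmetric matrices with identical label
#'   order.
#' @param n_permutations Number of permutations (default 999).
#' @param seed Optional RNG seed.
#' @return A one-row tibble: `r`, `p`, `n_permutations`, `n_labels`.
#' @export
mantel_test <- function(d_a, d_b, n_permutations = 999, seed = NULL) {
  a <- as.matrix(d_a)
  b <- as.matrix(d_b)
  n <- nrow(a)
  if (n < 3) abort("Mantel test needs at least 3 labels")
  if (!all(dim(a) == dim(b))) abort("distance matrices differ in size")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    abort("distance matrices must share the same labels in the same order")
  }
  lower <- lower.tri(a)
  r_obs <- stats::cor(a[lower], b[lower])
  run <- function() {
    purrr::map_dbl(seq_len(n_permutations), function(i) {
      p <- sample.int(n)
      stats::cor(a[lower], b[p, p][lower])
    })
  }
  r_perm <- if (is.null(seed)) run() else
    withr::with_seed(as.integer(seed), run())
  p_val <- (sum(r_perm >= r_obs) + 1) / (n_permutations + 1)
  tibble(r = r_obs, p = p_val, n_permutations = n_permutations,
         n_labels = n)
}

#' Euclidean geographic distances between groupings
#'
#' Plain Euclidean distance on raw latitude/longitude coordinates of group
#' centroids (decimal degrees), the conventional companion matrix of a
#' Mantel isolation-by-distance test at local scales.
#'
#' @param gt A genotype tibble with coordinates.
#' @param by Grouping metadata column(s).
#' @return A `stats::dist` object over the group labels.
#' @export
geo_distance <- function(gt, by = c("role", "population")) {
  cent <- gt |>
    group_by(across(all_of(by))) |>
    summarise(lat = mean(.data$lat, na.rm = TRUE),
              lon = mean(.data$lon, na.rm = TRUE), .groups = "drop")
  if (anyNA(cent$lat) || anyNA(cent$lon)) {
    abort("group(s) without coordinates")
  }
  labs <- as.character(interaction(cent[by], drop = TRUE, sep = "/"))
  m <- as.matrix(stats::dist(cent[, c("lon", "lat")]))
  dimnames(m) <- list(labs, labs)
  stats::as.dist(m)
}
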