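#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across all_of any_of n count left_join distinct pull bind_rows rename
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_chr map_lgl map2 pmap imap list_rbind
NULL

# Metadata columns every genotype table carries, in canonical order.
GT_META <- c("sample_id", "population", "role", "bunch", "lat", "lon")

#' Locus names of a genotype table
#'
#' Genotype tables are plain tibbles with the metadata columns `sample_id`,
#' `population`, `role` (`"population"` or `"seed"`), `bunch`, `lat`, `lon`,
#' followed by two integer allele columns per locus named `<locus>_1` and
#' `<locus>_2` (missing allele = `NA`). This helper recovers the ordered
#' locus list from the column names.
#'
#' @param gt A genotype tibble.
#' @return Character vector of locus names, in column order.
#' @export
#' @examples
#' gt <- sim_dataset_example()
#' genotype_loci(gt)[1:4]
genotype_loci <- function(gt) {
  cols <- setdiff(names(gt), GT_META)
  a1 <- stringr::str_subset(cols, "_1$")
  stringr::str_remove(a1, "_1$")
}

allele_cols <- function(loci) {
  as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
}

#' Validate a genotype table
#'
#' Checks the structural invariants of the genotype data model: required
#' metadata columns, paired allele columns, unique sample ids, positive
#' integer allele codes, every seed carrying a bunch id. Half-called
#' genotypes (one allele present, the partner missing) are normalised to
#' fully missing with a warning, since a single scored allele cannot be
#' interpreted as a diploid call.
#'
#' @param gt A genotype tibble (see [genotype_loci()] for the layout).
#' @return The validated (possibly normalised) tibble, invisibly usable in
#'   a pipe.
#' @export
validate_genotypes <- function(gt) {
  gt <- as_tibble(gt)
  miss_meta <- setdiff(c("sample_id", "population", "role"), names(gt))
  if (length(miss_meta) > 0) {
    abort(paste0("genotype table lacks required column(s): ",
                 paste(miss_meta, collapse = ", ")))
  }
  for (col in c("bunch", "lat", "lon")) {
    if (!col %in% names(gt)) gt[[col]] <- NA
  }
  gt$bunch <- as.character(gt$bunch)
  gt$lat <- as.numeric(gt$lat)
  gt$lon <- as.numeric(gt$lon)
  gt$sample_id <- as.character(gt$sample_id)
  gt$population <- as.character(gt$population)
  gt$role <- tolower(as.character(gt$role))

  cols <- setdiff(names(gt), GT_META)
  bad <- stringr::str_subset(cols, "_[12]$", negate = TRUE)
  if (length(bad) > 0) {
    abort(paste0("column(s) not recognised as metadata or <locus>_1/<locus>_2 pairs: ",
                 paste(bad, collapse = ", ")))
  }
  loci1 <- stringr::str_remove(stringr::str_subset(cols, "_1$"), "_1$")
  loci2 <- stringr::str_remove(stringr::str_subset(cols, "_2$"), "_2$")
  orphan <- c(setdiff(loci1, loci2), setdiff(loci2, loci1))
  if (length(orphan) > 0) {
    abort(paste0("unpaired allele column for locus: ",
                 paste(orphan, collapse = ", ")))
  }
  if (length(loci1) < 1) abort("genotype table contains no locus columns")
  if (nrow(gt) < 1) abort("genotype table contains no samples")
  if (anyDuplicated(gt$sample_id) > 0) {
    abort(paste0("duplicate sample_id: ",
                 paste(unique(gt$sample_id[duplicated(gt$sample_id)]), collapse = ", ")))
  }
  if (!all(gt$role %in% c("population", "seed"))) {
    abort("role must be 'population' or 'seed'")
  }
  no_bunch <- gt$role == "seed" & (is.na(gt$bunch) | gt$bunch == "")
  if (any(no_bunch)) {
    abort(paste0("seed sample(s) without bunch id: ",
                 paste(gt$sample_id[no_bunch], collapse = ", ")))
  }

  acols <- allele_cols(loci1)
  for (col in acols) {
    v <- gt[[col]]
    v[!is.na(v) & v == 0] <- NA
    if (any(!is.na(v) & (v < 0 | v != round(v)))) {
      abort(paste0("allele codes must be positive integers (column ", col, ")"))
    }
    gt[[col]] <- as.integer(v)
  }
  # half-calls: one allele scored, partner missing -> treat call as missing
  n_half <- 0L
  for (loc in loci1) {
    a <- gt[[paste0(loc, "_1")]]
    b <- gt[[paste0(loc, "_2")]]
    half <- xor(is.na(a), is.na(b))
    if (any(half)) {
      n_half <- n_half + sum(half)
      gt[[paste0(loc, "_1")]][half] <- NA_integer_
      gt[[paste0(loc, "_2")]][half] <- NA_integer_
    }
  }
  if (n_half > 0) {
    warn(paste0(n_half, " half-called genotype(s) set to missing"))
  }
  gt[, c(GT_META, acols)]
}

#' Read a genotype table from delimited text
#'
#' Reads the package's tabular genotype exchange format: one row per sample,
#' columns `sample_id`, `population`, `role`, `bunch`, `lat`, `lon`, then two
#' columns per locus named `<locus>_1`/`<locus>_2` holding integer allele
#' codes (typically fragment lengths in bp). Missing alleles may be coded
#' `0` or left empty. Allele order within a call carries no meaning.
#'
#' @param file Path or connection, passed to [readr::read_delim()].
#' @param delim Field delimiter (default comma).
#' @return A validated genotype tibble.
#' @seealso [write_genotype_table()], [validate_genotypes()]
#' @export
read_genotype_table <- function(file, delim = ",") {
  raw <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_genotypes(raw)
}

#' Write a genotype table as delimited text
#'
#' Emits the dialect accepted by [read_genotype_table()]; missing alleles are
#' coded `0`, absent coordinates are left empty.
#'
#' @param gt A genotype tibble.
#' @param file Destination path or connection.
#' @param delim Field delimiter (default comma).
#' @return `file`, invisibly.
#' @export
write_genotype_table <- function(gt, file, delim = ",") {
  gt <- validate_genotypes(gt)
  acols <- allele_cols(genotype_loci(gt))
  out <- gt
  for (col in acols) {
    v <- out[[col]]
    v[is.na(v)] <- 0L
    out[[col]] <- v
  }
  readr::write_delim(out, file, delim = delim, na = "")
  invisible(file)
}

#' Write a GenAlEx-style two-column-per-locus CSV
#'
#' Export-only writer for the spreadsheet layout commonly exchanged for SSR
#' data: three header rows (counts; title and population names; column
#' labels), then one row per sample with `Sample`, `Pop` and two allele
#' columns per locus, missing coded 0.
#'
#' @param gt A genotype tibble.
#' @param file Destination path.
#' @param title Dataset title placed in the second header row.
#' @return `file`, invisibly.
#' @export
write_genalex <- function(gt, file, title = "seedcapture export") {
  gt <- validate_genotypes(gt)
  loci <- genotype_loci(gt)
  gt <- arrange(gt, .data$population)
  pops <- unique(gt$population)
  sizes <- as.integer(table(factor(gt$population, levels = pops)))
  ncols <- 2 + 2 * length(loci)
  pad <- function(x) c(x, rep("", max(0, ncols - length(x))))
  l1 <- pad(c(length(loci), nrow(gt), length(pops), sizes))
  l2 <- pad(c(title, "", "", pops))
  l3 <- pad(c("Sample", "Pop", as.vector(rbind(loci, rep("", length(loci))))))
  body <- cbind(gt$sample_id, gt$population,
                as.matrix(sapply(allele_cols(loci), function(col) {
                  v <- gt[[col]]
                  v[is.na(v)] <- 0L
                  v
                })))
  lines <- apply(rbind(l1, l2, l3, body), 1, paste, collapse = ",")
  writeLines(lines, file)
  invisible(file)
}

#' Long (tidy) view of genotype calls
#'
#' @param gt A genotype tibble.
#' @return A tibble with one row per sample x locus: the metadata columns,
#'   `locus`, `allele_1`, `allele_2` and `missing` (TRUE when the call is
#'   missing, i.e. either allele unscored).
#' @export
tidy_genotypes <- function(gt) {
  loci <- genotype_loci(gt)
  long <- tidyr::pivot_longer(gt, cols = all_of(allele_cols(loci)),
                              names_to = c("locus", ".value"),
                              names_pattern = "^(.*)_([12])$")
  long <- rename(long, allele_1 = "1", allele_2 = "2")
  mutate(long, missing = is.na(.data$allele_1) | is.na(.data$allele_2),
         locus = factor(.data$locus, levels = loci))
}

# one row per gene copy (non-missing calls only)
alleles_long <- function(gt) {
  long <- tidy_genotypes(gt)
  long <- filter(long, !.data$missing)
  tidyr::pivot_longer(long, cols = c("allele_1", "allele_2"),
                      values_to = "allele", names_to = NULL)
}

#' Drop loci and samples with excessive missing data
#'
#' Applies the quality filter used before any diversity analysis: loci whose
#' missing-call fraction across samples strictly exceeds `max_missing` are
#' removed first, then samples whose missing fraction across the remaining
#' loci strictly exceeds it. A call is missing when either allele is
#' unscored. The default threshold of 0.25 keeps loci/samples with exactly
#' 25% missing ("more than 25%" are excluded).
#'
#' @param gt A genotype tibble.
#' @param max_missing Maximum tolerated missing fraction, in `[0, 1)`.
#' @return The filtered genotype tibble, with a removal report attached as
#'   attribute `"removal"` (see [removal_report()]).
#' @export
filter_missing <- function(gt, max_missing = 0.25) {
  gt <- validate_genotypes(gt)
  stopifnot(is.numeric(max_missing), max_missing >= 0, max_missing < 1)
  loci <- genotype_loci(gt)

  loc_frac <- map_dbl(loci, function(loc) {
    mean(is.na(gt[[paste0(loc, "_1")]]) | is.na(gt[[paste0(loc, "_2")]]))
  })
  drop_loc <- loc_frac > max_missing
  if (all(drop_loc)) abort("all loci exceed the missing-data threshold")
  kept_loci <- loci[!drop_loc]
  gt2 <- gt[, c(GT_META, allele_cols(kept_loci))]

  m1 <- as.matrix(gt2[, paste0(kept_loci, "_1")])
  m2 <- as.matrix(gt2[, paste0(kept_loci, "_2")])
  miss <- is.na(m1) | is.na(m2)
  samp_frac <- rowMeans(miss)
  drop_samp <- samp_frac > max_missing
  if (all(drop_samp)) abort("all samples exceed the missing-data threshold")
  out <- gt2[!drop_samp, ]

  overall <- mean(miss[!drop_samp, , drop = FALSE]) * 100
  report <- list(
    loci = tibble(locus = loci, missing_frac = loc_frac,
                  dropped = drop_loc),
    samples = tibble(sample_id = gt2$sample_id, missing_frac = samp_frac,
                     dropped = drop_samp),
    max_missing = max_missing,
    overall_missing_pct = overall
  )
  attr(out, "removal") <- report
  out
}

#' Removal report of a filtered genotype table
#'
#' @param gt A genotype tibble returned by [filter_missing()].
#' @return A list with elements `loci` and `samples` (tibbles of missing
#'   fractions and drop flags), the threshold used, and the dataset-wide
#'   missing percentage after filtering.
#' @export
removal_report <- function(gt) {
  rep <- attr(gt, "removal")
  if (is.null(rep)) abort("no removal report: was the table filtered with filter_missing()?")
  rep
}

#' Restrict a genotype table to one role
#'
#' Regional pooling: all population plants, or all seeds, across local
#' populations. Local groupings are expressed through the `by` argument of
#' the index functions instead.
#'
#' @param gt A genotype tibble.
#' @param role `"population"` or `"seed"`.
#' @return The sub-tibble of samples with that role.
#' @export
pool_genotypes <- function(gt, role = c("population", "seed")) {
  role <- match.arg(role)
  out <- filter(gt, .data$role == !!role)
  if (nrow(out) == 0) abort(paste0("no samples with role '", role, "'"))
  out
}

#' Allele relative frequencies by grouping
#'
#' For every group (any combination of metadata columns) and locus, the
#' relative frequency of each allele among the non-missing gene copies of
#' that group, together with the gene-copy count the estimate is based on.
#'
#' @param gt A genotype tibble.
#' @param by Character vector of metadata columns defining the grouping
#'   (e.g. `"role"`, `c("role", "population")`, `"bunch"`).
#' @return A tibble with the grouping columns, `locus`, `allele`, `freq`,
#'   and `n_copies`. Group x locus combinations with zero non-missing
#'   copies are absent from the table and listed in the `"empty_loci"`
#'   attribute.
#' @export
#' @examples
#' gt <- sim_dataset_example()
#' allele_frequencies(gt, by = "role")
allele_frequencies <- function(gt, by = "role") {
  stopifnot(all(by %in% GT_META))
  long <- alleles_long(gt)
  freq <- long |>
    count(across(all_of(by)), .data$locus, .data$allele, name = "n_allele") |>
    group_by(across(all_of(by)), .data$locus) |>
    mutate(n_copies = sum(.data$n_allele),
           freq = .data$n_allele / .data$n_copies) |>
    ungroup() |>
    select(all_of(by), "locus", "allele", "freq", "n_copies")

  groups <- distinct(gt, across(all_of(by)))
  full <- tidyr::crossing(groups, locus = factor(genotype_loci(gt),
                                                 levels = genotype_loci(gt)))
  empty <- dplyr::anti_join(full, distinct(freq, across(all_of(by)), .data$locus),
                            by = c(by, "locus"))
  attr(freq, "empty_loci") <- empty
  freq
}
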