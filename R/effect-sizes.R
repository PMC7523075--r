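#' Paired within-plant effect sizes between two compartments
#'
#' For each of the `top_n` most abundant OTUs (dataset-wide totals) and each
#' plant possessing both compartments, computes
#' `ES = (relA - relB) / (relA + relB)` on per-sample relative abundances,
#' so `+1` means the OTU occurs only in compartment A of that plant and `-1`
#' only in compartment B. Plants where the OTU is absent from both samples
#' are excluded from that OTU's ES set. Reports the quintiles (min, 25%,
#' median, 75%, max) and a two-sided paired Wilcoxon signed-rank test per
#' OTU.
#'
#' @param x An [otu_table()] with design metadata.
#' @param pair Length-2 character vector: compartments (A, B).
#' @param top_n Number of most-abundant OTUs to analyse.
#' @return A tibble, one row per OTU: `otu_id`, `compartment_a/b`, quintile
#'   columns, `n_pairs`, `wilcoxon_statistic`, `p_value`, and a list-column
#'   `es` of per-plant values.
#' @export
paired_effect_size <- function(x, pair = c("nodule", "root"), top_n = 20) {
  stopifnot(inherits(x, "otu_table"), length(pair) == 2)
  meta <- x$metadata
  a_samples <- meta$sample_id[meta$compartment == pair[1]]
  b_samples <- meta$sample_id[meta$compartment == pair[2]]
  plants <- intersect(meta$plant_id[meta$sample_id %in% a_samples],
                      meta$plant_id[meta$sample_id %in% b_samples])
  if (length(plants) == 0) {
    abort(sprintf("no plant has both '%s' and '%s' samples.", pair[1], pair[2]))
  }
  rel <- to_relative_abundance(x)
  top <- names(sort(rowSums(x$counts), decreasing = TRUE))[
    seq_len(min(top_n, nrow(x$counts)))]
  # per-plant sample lookup
  lookup <- function(plant, comp) {
    meta$sample_id[meta$plant_id == plant & meta$compartment == comp][1]
  }
  purrr::map_dfr(top, function(otu) {
    es <- vapply(plants, function(pl) {
      ra <- rel[otu, lookup(pl, pair[1])]
      rb <- rel[otu, lookup(pl, pair[2])]
      if (ra == 0 && rb == 0) return(NA_real_)
      (ra - rb) / (ra + rb)
    }, 0)
    es <- es[!is.na(es)]
    wt <- if (length(es) > 0 && any(es != 0)) {
      wilcoxon_signed_rank(es)
    } else {
      list(statistic = NA_real_, p_value = NA_real_)
    }
    q <- if (length(es)) quintiles(es) else rep(NA_real_, 5)
    tibble(
      otu_id = otu, compartment_a = pair[1], compartment_b = pair[2],
      es_min = q[[1]], es_q25 = q[[2]], es_median = q[[3]],
      es_q75 = q[[4]], es_max = q[[5]], n_pairs = length(es),
      wilcoxon_statistic = wt$statistic, p_value = wt$p_value,
      es = list(es)
    )
  })
}

#' Paired Wilcoxon signed-rank test on a vector of differences
#'
#' Two-sided; exact null distribution when `n <= 25` and there are no ties
#' among absolute differences, otherwise the normal approximation with tie
#' correction (the behaviour of `stats::wilcox.test`). Zero differences are
#' dropped; all-zero input is an error.
#'
#' @param differences Numeric vector of paired differences.
#' @return A list with `statistic` (V) and `p_value`.
#' @export
wilcoxon_signed_rank <- function(differences) {
  nz <- differences[differences != 0]
  if (length(nz) == 0) abort("all differences are zero: test undefined.")
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  res <- suppressWarnings(
    stats::wilcox.test(differences, mu = 0, exact = exact, correct = TRUE)
  )
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Core taxa of a compartment by prevalence
#'
#' OTUs present (>= 1 read) in strictly more than `prevalence_threshold` of
#' the compartment's samples.
#'
#' @param x An [otu_table()].
#' @param compartment Compartment level to examine.
#' @param prevalence_threshold Proportion in `[0, 1]`; strict inequality.
#' @return A tibble `otu_id`, `n_present`, `n_samples`, `prevalence`,
#'   sorted by decreasing prevalence.
#' @export
core_taxa <- function(x, compartment = "nodule", prevalence_threshold = 0.5) {
  stopifnot(inherits(x, "otu_table"))
  samples <- x$metadata$sample_id[x$metadata$compartment == compartment]
  if (length(samples) == 0) abort(paste0("no samples in compartment: ", compartment))
  sub <- x$counts[, samples, drop = FALSE]
  n_present <- rowSums(sub >= 1)
  prev <- n_present / length(samples)
  out <- tibble(otu_id = rownames(sub), n_present = as.integer(unname(n_present)),
                n_samples = length(samples), prevalence = unname(prev))
  out <- dplyr::filter(out, .data$prevalence > prevalence_threshold)
  dplyr::arrange(out, dplyr::desc(.data$prevalence))
}

#' Per-compartment OTU presence sets and Venn-region counts
#'
#' An OTU counts as present in a compartment iff its summed reads there are
#' strictly greater than `min_reads`. Returns the per-compartment sets and
#' the cardinality of every intersection region (each OTU assigned to the
#' exact subset of compartments containing it).
#'
#' @param x An [otu_table()].
#' @param min_reads Presence threshold (strict: a compartment sum of exactly
#'   `min_reads` does not count).
#' @return A list with `sets` (named list of OTU id vectors) and `regions`
#'   (tibble `region` (e.g. `"root+nodule"`), `n_compartments`, `count`).
#' @export
compartment_presence_sets <- function(x, min_reads = 10) {
  stopifnot(inherits(x, "otu_table"))
  comps <- unique(x$metadata$compartment)
  comps <- comps[!is.na(comps)]
  if (length(comps) < 2) abort("need >= 2 compartments.")
  sets <- lapply(stats::setNames(comps, comps), function(comp) {
    samples <- x$metadata$sample_id[x$metadata$compartment == comp]
    sums <- rowSums(x$counts[, samples, drop = FALSE])
    rownames(x$counts)[sums > min_reads]
  })
  membership <- vapply(sets, function(s) rownames(x$counts) %in% s,
                       logical(nrow(x$counts)))
  present_any <- rowSums(membership) > 0
  region_key <- apply(membership[present_any, , drop = FALSE], 1, function(r) {
    paste(comps[r], collapse = "+")
  })
  counted <- table(region_key)
  all_regions <- unlist(lapply(seq_along(comps), function(sz) {
    apply(utils::combn(comps, sz), 2, paste, collapse = "+")
  }))
  regions <- tibble(
    region = all_regions,
    n_compartments = lengths(strsplit(all_regions, "\\+")),
    count = as.integer(counted[all_regions]) %>% tidyr::replace_na(0L)
  )
  list(sets = sets, regions = regions)
}

#' Pearson chi-square test with Monte-Carlo p-value
#'
#' Pearson's `X^2 = sum (O - E)^2 / E` with the p-value simulated from
#' tables sampled with both margins fixed (Patefield's algorithm, via
#' `stats::chisq.test(simulate.p.value = TRUE)`), using the `(b+1)/(m+1)`
#' estimator.
#'
#' @param contingency Non-negative integer matrix with positive margins.
#' @param replications Number of Monte-Carlo tables.
#' @param seed Optional integer seed.
#' @return A tibble `chi_square`, `p_value`, `replications`.
#' @export
monte_carlo_chi_square <- function(contingency, replications = 10000,
                                   seed = NULL) {
  m <- as.matrix(contingency)
  if (any(m < 0) || any(m != round(m))) {
    abort("contingency table must hold non-negative integers.")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("zero row/column margin in contingency table.")
  }
  res <- with_seed(seed, {
    stats::chisq.test(m, simulate.p.value = TRUE, B = replications)
  })
  tibble(chi_square = unname(res$statistic), p_value = res$p.value,
         replications = as.integer(replications))
}
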