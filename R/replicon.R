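#' Plasmid:chromosome reads-per-megabase ratios
#'
#' For each sample, divides each plasmid's reads per megabase by the
#' chromosome's reads per megabase; the ratio estimates the fraction of
#' (symbiont) cells carrying that plasmid. Samples with fewer than
#' `min_rpob_reads` reads on the single-copy chromosomal marker rpoB are
#' flagged excluded (low signal-to-noise) and get `NA` ratios.
#'
#' @param data Tidy tibble with columns `sample_id`, `compartment`,
#'   `replicon`, `length_bp`, `reads`, `rpob_reads` (as produced by
#'   [generate_replicon_counts()] or read from TSV).
#' @param chromosome_id Replicon id of the chromosome.
#' @param min_rpob_reads rpoB read-count floor (samples strictly below it
#'   are excluded).
#' @return A tibble, one row per sample x plasmid: `sample_id`,
#'   `compartment`, `plasmid`, `ratio`, `rpob_reads`, `excluded`.
#' @export
replicon_ratio <- function(data, chromosome_id = "chromosome",
                           min_rpob_reads = 20) {
  data <- as_tibble(data)
  required <- c("sample_id", "compartment", "replicon", "length_bp", "reads",
                "rpob_reads")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(data$length_bp <= 0)) abort("replicon lengths must be > 0.")
  if (any(data$reads < 0)) abort("read counts must be >= 0.")
  if (!chromosome_id %in% data$replicon) {
    abort(paste0("unknown chromosome replicon id: ", chromosome_id))
  }
  per_mb <- data %>%
    dplyr::mutate(reads_per_mb = .data$reads / (.data$length_bp / 1e6))
  chrom <- per_mb %>%
    dplyr::filter(.data$replicon == chromosome_id) %>%
    dplyr::select("sample_id", chrom_per_mb = "reads_per_mb")
  if (any(chrom$chrom_per_mb == 0)) {
    abort(paste0("zero chromosome reads in sample(s): ",
                 paste(chrom$sample_id[chrom$chrom_per_mb == 0], collapse = ", ")))
  }
  per_mb %>%
    dplyr::filter(.data$replicon != chromosome_id) %>%
    dplyr::left_join(chrom, by = "sample_id") %>%
    dplyr::mutate(
      excluded = .data$rpob_reads < min_rpob_reads,
      ratio = dplyr::if_else(.data$excluded, NA_real_,
                             .data$reads_per_mb / .data$chrom_per_mb)
    ) %>%
    dplyr::select("sample_id", "compartment", plasmid = "replicon", "ratio",
                  "rpob_reads", "excluded")
}

#' Aggregate per-feature counts to per-replicon counts
#'
#' Sums per-feature (e.g. coding-sequence) read counts within replicons
#' using a feature-to-replicon map, producing the tidy input of
#' [replicon_ratio()]. rpoB reads are taken from the feature named by
#' `rpob_feature`.
#'
#' @param features Tibble with `sample_id`, `compartment`, `feature_id`,
#'   `reads`.
#' @param feature_map Tibble with `feature_id`, `replicon`.
#' @param replicon_lengths Named vector of replicon lengths (bases).
#' @param rpob_feature Feature id of the rpoB gene.
#' @return Tidy per-replicon tibble.
#' @export
aggregate_replicon_counts <- function(features, feature_map, replicon_lengths,
                                      rpob_feature = "rpoB") {
  features <- as_tibble(features)
  joined <- dplyr::left_join(features, as_tibble(feature_map), by = "feature_id")
  if (anyNA(joined$replicon)) abort("feature(s) missing from `feature_map`.")
  rpob <- features %>%
    dplyr::filter(.data$feature_id == rpob_feature) %>%
    dplyr::select("sample_id", rpob_reads = "reads")
  joined %>%
    dplyr::group_by(.data$sample_id, .data$compartment, .data$replicon) %>%
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop") %>%
    dplyr::mutate(length_bp = unname(replicon_lengths[.data$replicon])) %>%
    dplyr::left_join(rpob, by = "sample_id") %>%
    dplyr::mutate(rpob_reads = tidyr::replace_na(.data$rpob_reads, 0L))
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided; exact for small tie-free samples, normal approximation with
#' tie correction otherwise (`stats::wilcox.test` semantics).
#'
#' @param group_a,group_b Numeric vectors.
#' @return A list with `statistic` (W, the Mann-Whitney U of `group_a`) and
#'   `p_value`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be non-empty.")
  }
  exact <- length(group_a) + length(group_b) <= 50 &&
    !any(duplicated(c(group_a, group_b)))
  res <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Compare plasmid ratios between two compartments
#'
#' Median (with quartiles) plasmid:chromosome ratio per compartment and
#' plasmid, plus a Wilcoxon-Mann-Whitney test between the two compartments
#' for each plasmid. Excluded samples (rpoB filter) are dropped first.
#'
#' @param ratios Output of [replicon_ratio()].
#' @param compartments Length-2 character vector.
#' @return A tibble per plasmid: medians/quartiles per compartment, `W`,
#'   `p_value`, group sizes.
#' @export
compare_replicon_ratios <- function(ratios, compartments = c("root", "nodule")) {
  keep <- ratios %>%
    dplyr::filter(!.data$excluded, .data$compartment %in% compartments)
  purrr::map_dfr(unique(keep$plasmid), function(pl) {
    a <- keep$ratio[keep$plasmid == pl & keep$compartment == compartments[1]]
    b <- keep$ratio[keep$plasmid == pl & keep$compartment == compartments[2]]
    test <- mann_whitney_u(a, b)
    tibble(
      plasmid = pl,
      compartment_a = compartments[1], compartment_b = compartments[2],
      n_a = length(a), n_b = length(b),
      median_a = stats::median(a), median_b = stats::median(b),
      q25_a = stats::quantile(a, 0.25, names = FALSE),
      q75_a = stats::quantile(a, 0.75, names = FALSE),
      q25_b = stats::quantile(b, 0.25, names = FALSE),
      q75_b = stats::quantile(b, 0.75, names = FALSE),
      W = test$statistic, p_value = test$p_value
    )
  })
}
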