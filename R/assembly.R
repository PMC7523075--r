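#' Pairwise Raup-Crick beta (null-model community assembly)
#'
#' For each sample pair, compares the observed number of shared OTUs to a
#' null distribution in which each sample's observed richness is preserved
#' and OTUs are drawn without replacement with probability proportional to
#' their occurrence frequency in a reference sample set. With
#' `percentile = (num null sharing > observed + 0.5 x ties) / replicates`,
#' `beta_RC = 2 x percentile - 1`, so `beta_RC < -0.95` means the pair
#' shares more OTUs than expected by chance (deterministic establishment)
#' and `beta_RC > 0.95` fewer; `|beta_RC| > 0.95` is the two-tailed
#' significance rule at alpha = 0.05.
#'
#' @param x An [otu_table()]; presence is >= 1 read.
#' @param pairs Data frame with columns `sample_a`, `sample_b` (and
#'   optionally `plant_id`), or `NULL` to build same-plant pairs from
#'   `compartments`.
#' @param compartments Length-2 character vector used when `pairs` is `NULL`:
#'   pair each plant's sample in `compartments[1]` with its sample in
#'   `compartments[2]`.
#' @param replicates Number of null assemblages per pair.
#' @param seed Optional integer seed.
#' @param pool Reference set defining the species pool and occurrence
#'   frequencies: `"pair_compartments"` (union of samples in the two
#'   compartments involved, the default) or `"all"` (every sample).
#' @return A tibble: `sample_a`, `sample_b`, `plant_id`, `shared_observed`,
#'   `beta_rc`, `significant`, `direction`
#'   (`more_similar`/`less_similar`/`null`), `replicates`.
#' @export
raup_crick <- function(x, pairs = NULL, compartments = c("root", "nodule"),
                       replicates = 1000, seed = NULL,
                       pool = c("pair_compartments", "all")) {
  stopifnot(inherits(x, "otu_table"))
  pool <- match.arg(pool)
  meta <- x$metadata
  if (is.null(pairs)) {
    a_meta <- meta[meta$compartment == compartments[1], ]
    b_meta <- meta[meta$compartment == compartments[2], ]
    plants <- intersect(a_meta$plant_id, b_meta$plant_id)
    if (!length(plants)) abort("no paired plants for the requested compartments.")
    pairs <- tibble(
      plant_id = plants,
      sample_a = a_meta$sample_id[match(plants, a_meta$plant_id)],
      sample_b = b_meta$sample_id[match(plants, b_meta$plant_id)]
    )
  } else {
    pairs <- as_tibble(pairs)
    if (!"plant_id" %in% names(pairs)) pairs$plant_id <- NA_character_
  }
  pa <- x$counts >= 1
  ref_samples <- if (pool == "all") colnames(pa) else {
    meta$sample_id[meta$compartment %in%
                     unique(meta$compartment[meta$sample_id %in%
                                               c(pairs$sample_a, pairs$sample_b)])]
  }
  freq <- rowSums(pa[, ref_samples, drop = FALSE])
  in_pool <- freq > 0
  freq <- freq[in_pool]
  pa <- pa[in_pool, , drop = FALSE]
  pool_size <- sum(in_pool)

  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      va <- pa[, pairs$sample_a[i]]
      vb <- pa[, pairs$sample_b[i]]
      ra <- sum(va); rb <- sum(vb)
      if (ra == 0 || rb == 0) abort("empty sample in a Raup-Crick pair.")
      if (ra > pool_size || rb > pool_size) {
        abort("sample richness exceeds the species pool.")
      }
      observed <- sum(va & vb)
      null_shared <- vapply(seq_len(replicates), function(r) {
        sa <- sample.int(pool_size, ra, prob = freq)
        sb <- sample.int(pool_size, rb, prob = freq)
        length(intersect(sa, sb))
      }, 0L)
      percentile <- (sum(null_shared > observed) +
                       0.5 * sum(null_shared == observed)) / replicates
      beta <- 2 * percentile - 1
      tibble(
        sample_a = pairs$sample_a[i], sample_b = pairs$sample_b[i],
        plant_id = pairs$plant_id[i], shared_observed = observed,
        beta_rc = beta, significant = abs(beta) > 0.95,
        direction = if (abs(beta) <= 0.95) "null" else
          if (beta < 0) "more_similar" else "less_similar",
        replicates = as.integer(replicates)
      )
    })
  })
}

#' Compare deterministic-assembly rates between two pairing types
#'
#' Fractions of significant Raup-Crick pairs in each result set, compared by
#' a two-tailed Fisher's exact test on the 2x2 significant/not x pairing
#' table.
#'
#' @param results_a,results_b Tibbles from [raup_crick()].
#' @return A tibble `rate_a`, `rate_b`, `n_a`, `n_b`, `fisher_p`.
#' @export
deterministic_assembly_rates <- function(results_a, results_b) {
  if (nrow(results_a) == 0 || nrow(results_b) == 0) {
    abort("both result sets must be non-empty.")
  }
  sa <- sum(results_a$significant); sb <- sum(results_b$significant)
  tab <- matrix(c(sa, nrow(results_a) - sa, sb, nrow(results_b) - sb), 2,
                byrow = TRUE)
  tibble(
    rate_a = sa / nrow(results_a), rate_b = sb / nrow(results_b),
    n_a = nrow(results_a), n_b = nrow(results_b),
    fisher_p = fisher_exact(tab)
  )
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' P-value is the total probability, under fixed margins, of all tables at
#' least as extreme (point probability <= the observed table's).
#'
#' @param table_2x2 Non-negative integer 2x2 matrix.
#' @return The two-tailed p-value.
#' @export
fisher_exact <- function(table_2x2) {
  m <- as.matrix(table_2x2)
  if (any(m < 0)) abort("negative entry in contingency table.")
  if (!all(dim(m) == c(2, 2))) abort("expected a 2x2 table.")
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' COMBO metric: number of unique species combinations
#'
#' Counts the distinct presence/absence column vectors (unique species
#' combinations across sites) of a binary OTU x sample matrix.
#'
#' @param presence Binary matrix, OTUs as rows, samples as columns.
#' @return Integer count of distinct columns.
#' @export
combo_metric <- function(presence) {
  m <- as.matrix(presence) > 0
  length(unique(apply(m, 2, paste, collapse = "")))
}

# Null-matrix generator for the SIM-family randomizations. Constraints:
# sim6 preserves total fill (OTUs equiprobable, samples weighted by observed
# richness); sim2/sim4 preserve each OTU's occurrence count (samples
# equiprobable / richness-weighted).
make_null_generator <- function(pa, algorithm) {
  n_otu <- nrow(pa); n_samp <- ncol(pa)
  fill <- sum(pa)
  col_w <- colSums(pa) / sum(pa)
  row_occ <- rowSums(pa)
  switch(algorithm,
    sim6 = function() {
      cellw <- rep(col_w, each = n_otu)
      idx <- sample.int(n_otu * n_samp, fill, prob = cellw)
      m <- matrix(FALSE, n_otu, n_samp)
      m[idx] <- TRUE
      m
    },
    sim2 = function() {
      m <- matrix(FALSE, n_otu, n_samp)
      for (i in seq_len(n_otu)) {
        m[i, sample.int(n_samp, row_occ[i])] <- TRUE
      }
      m
    },
    sim4 = function() {
      m <- matrix(FALSE, n_otu, n_samp)
      for (i in seq_len(n_otu)) {
        m[i, sample.int(n_samp, row_occ[i], prob = col_w)] <- TRUE
      }
      m
    }
  )
}

#' Co-occurrence null-model test (COMBO metric, SIM-family algorithms)
#'
#' Converts counts to presence/absence, generates `iterations` null matrices
#' under the selected randomization, computes [combo_metric()] on each, and
#' returns the standardized effect size `Z = (obs - mean_null)/sd_null` and
#' a two-tailed permutation p-value. Algorithms (rows = OTUs, columns =
#' samples; total fill always preserved):
#' * `sim6` (default): OTU weights equiprobable, sample occurrence
#'   probabilities proportional to observed sample richness.
#' * `sim2`: each OTU keeps its observed number of occurrences, placed in
#'   equiprobable samples.
#' * `sim4`: as `sim2` but samples weighted by observed richness.
#'
#' @param x An [otu_table()] or binary/count matrix.
#' @param algorithm One of `"sim6"`, `"sim2"`, `"sim4"`.
#' @param iterations Number of null matrices.
#' @param exclude_otus OTU ids to drop before testing (e.g. the dominant
#'   symbiont OTU1).
#' @param compartment Optional compartment to subset to (requires metadata).
#' @param seed Optional integer seed.
#' @return A tibble: `metric`, `algorithm`, `observed`, `null_mean`,
#'   `null_sd`, `z_score`, `p_value`, `iterations`.
#' @export
cooccurrence_ses <- function(x, algorithm = c("sim6", "sim2", "sim4"),
                             iterations = 10000, exclude_otus = NULL,
                             compartment = NULL, seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (inherits(x, "otu_table")) {
    counts <- x$counts
    if (!is.null(compartment)) {
      samples <- x$metadata$sample_id[x$metadata$compartment == compartment]
      counts <- counts[, samples, drop = FALSE]
    }
  } else counts <- as.matrix(x)
  if (!is.null(exclude_otus)) {
    counts <- counts[setdiff(rownames(counts), exclude_otus), , drop = FALSE]
  }
  pa <- counts >= 1
  pa <- pa[rowSums(pa) > 0, , drop = FALSE]
  if (nrow(pa) < 2 || ncol(pa) < 2) abort("need >= 2 OTUs and >= 2 samples.")
  observed <- combo_metric(pa)
  null_matrix <- make_null_generator(pa, algorithm)

  with_seed(seed, {
    nulls <- vapply(seq_len(iterations), function(i) combo_metric(null_matrix()),
                    0L)
    sd_null <- stats::sd(nulls)
    if (sd_null == 0) abort("degenerate null: all null matrices give one COMBO value.")
    mean_null <- mean(nulls)
    p_hi <- (sum(nulls >= observed) + 1) / (iterations + 1)
    p_lo <- (sum(nulls <= observed) + 1) / (iterations + 1)
    tibble(
      metric = "combo", algorithm = algorithm, observed = observed,
      null_mean = mean_null, null_sd = sd_null,
      z_score = (observed - mean_null) / sd_null,
      p_value = min(1, 2 * min(p_hi, p_lo)),
      iterations = as.integer(iterations)
    )
  })
}
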