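#' One-way permutational multivariate ANOVA (PerMANOVA)
#'
#' Partitions the total sum of squared dissimilarities among and within
#' groups: `SS_total = (1/N) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, and
#' `pseudo-F = (SS_between/(a-1)) / (SS_within/(N-a))`. Significance is
#' assessed by permuting group labels; the p-value uses the `(b+1)/(m+1)`
#' estimator. For two groups `exhaustive = TRUE` enumerates every distinct
#' assignment instead (exact p-value).
#'
#' @param d A `dissimilarity_matrix` (or symmetric matrix) over samples.
#' @param group Factor (or vector) of group labels, in `d`'s sample order,
#'   or the name of a metadata column when `metadata` is supplied.
#' @param permutations Number of label permutations.
#' @param seed Optional integer seed.
#' @param exhaustive Enumerate all distinct two-group assignments.
#' @param metadata Optional tibble with `sample_id` and the grouping column.
#' @return An `mb_permanova`: tibble with `pseudo_F`, `df_num`, `df_den`,
#'   `p_value`, `n_permutations`, `ss_between`, `ss_within`, `n`.
#' @export
permanova <- function(d, group, permutations = 999, seed = NULL,
                      exhaustive = FALSE, metadata = NULL) {
  m <- as.matrix(d)
  if (!is.null(metadata)) {
    stopifnot(is.character(group), length(group) == 1)
    group <- metadata[[group]][match(rownames(m), metadata$sample_id)]
  }
  g <- factor(group)
  if (length(g) != nrow(m)) abort("`group` must match the samples of `d`.")
  sizes <- table(g)
  if (length(sizes) < 2) abort("need >= 2 groups.")
  if (any(sizes == 0)) abort("empty group level.")
  d2 <- m^2
  n <- nrow(m)
  a <- length(sizes)

  f_stat <- function(gv) {
    ss_t <- sum(d2[lower.tri(d2)]) / n
    ss_w <- 0
    for (lev in levels(gv)) {
      idx <- which(gv == lev)
      if (length(idx) > 1) {
        sub <- d2[idx, idx]
        ss_w <- ss_w + sum(sub[lower.tri(sub)]) / length(idx)
      }
    }
    ss_b <- ss_t - ss_w
    if (ss_w == 0) return(c(Inf, ss_b, ss_w))
    c((ss_b / (a - 1)) / (ss_w / (n - a)), ss_b, ss_w)
  }

  obs <- f_stat(g)
  if (exhaustive) {
    if (a != 2) abort("exhaustive enumeration is implemented for 2 groups.")
    n1 <- sizes[[1]]
    combs <- utils::combn(n, n1)
    fs <- apply(combs, 2, function(idx) {
      gv <- factor(ifelse(seq_len(n) %in% idx, levels(g)[1], levels(g)[2]),
                   levels = levels(g))
      f_stat(gv)[1]
    })
    p <- mean(fs >= obs[1] - 1e-12)
    nperm <- ncol(combs)
  } else {
    fs <- with_seed(seed, {
      vapply(seq_len(permutations), function(i) {
        f_stat(factor(sample(as.character(g)), levels = levels(g)))[1]
      }, 0)
    })
    p <- (sum(fs >= obs[1] - 1e-12) + 1) / (permutations + 1)
    nperm <- permutations
  }
  out <- tibble(
    pseudo_F = obs[1], df_num = a - 1L, df_den = n - a,
    p_value = p, n_permutations = as.integer(nperm),
    ss_between = obs[2], ss_within = obs[3], n = n
  )
  class(out) <- c("mb_permanova", class(out))
  out
}

#' Per-compartment PerMANOVAs for soil origin and genotype
#'
#' Runs [permanova()] within each compartment, once per tested factor, on
#' the subset of the dissimilarity matrix belonging to that compartment.
#'
#' @param d A `dissimilarity_matrix` over all samples.
#' @param metadata Design tibble covering `d`'s samples.
#' @param factors Metadata columns to test (each one-way).
#' @param permutations,seed Passed to [permanova()].
#' @return A tibble with one row per compartment x factor.
#' @export
permanova_by_compartment <- function(d, metadata,
                                     factors = c("soil", "genotype"),
                                     permutations = 999, seed = NULL) {
  m <- as.matrix(d)
  meta <- metadata[match(rownames(m), metadata$sample_id), ]
  comps <- unique(meta$compartment)
  purrr::map_dfr(comps, function(comp) {
    idx <- which(meta$compartment == comp)
    sub <- dissimilarity_matrix(m[idx, idx])
    purrr::map_dfr(factors, function(fac) {
      res <- permanova(sub, meta[[fac]][idx], permutations = permutations,
                       seed = if (is.null(seed)) NULL else
                         derive_seed(seed, paste0(comp, fac)))
      dplyr::bind_cols(tibble(compartment = comp, factor = fac), res)
    })
  })
}

#' One-way test of ordination axis scores across groups
#'
#' ANOVA of the coordinates of a single NMDS axis across group levels, used
#' to interpret which axis separates soils or genotypes.
#'
#' @param ord An `mb_ordination`.
#' @param axis Axis number (1-based, `<= k`).
#' @param group Group labels in the ordination's sample order, or a metadata
#'   column name with `metadata` supplied.
#' @param metadata Optional design tibble.
#' @return An `mb_anova` tibble (see [factorial_anova()]).
#' @export
axis_score_test <- function(ord, axis, group, metadata = NULL) {
  if (axis > ord$k) abort("`axis` exceeds the ordination dimensionality.")
  scores <- ord$coordinates[[paste0("axis", axis)]]
  if (!is.null(metadata)) {
    group <- metadata[[group]][match(ord$coordinates$sample_id,
                                     metadata$sample_id)]
  }
  if (length(unique(group)) < 2) abort("need >= 2 groups.")
  factorial_anova(data.frame(score = scores, group = factor(group)),
                  score ~ group)
}
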