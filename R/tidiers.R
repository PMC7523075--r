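#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the variance-component table of a PVCA fit
#'
#' @param x An `mb_pvca`.
#' @param ... Unused.
#' @return Tibble `term`, `percent`.
#' @exportS3Method
tidy.mb_pvca <- function(x, ...) x$components

#' @exportS3Method
glance.mb_pvca <- function(x, ...) {
  tibble(n_axes = x$n_axes, stress = x$ordination$stress,
         total_axis_r2 = sum(x$ordination$axis_r2[seq_len(x$n_axes)]))
}

#' Tidy ordination coordinates into long format
#'
#' @param x An `mb_ordination`.
#' @param ... Unused.
#' @return Tibble `sample_id`, `axis`, `score`.
#' @exportS3Method
tidy.mb_ordination <- function(x, ...) {
  tidyr::pivot_longer(x$coordinates, -"sample_id", names_to = "axis",
                      values_to = "score")
}

#' @exportS3Method
glance.mb_ordination <- function(x, ...) {
  tibble(k = x$k, stress = x$stress, converged = x$converged)
}

#' @exportS3Method
tidy.mb_permanova <- function(x, ...) {
  tibble(term = "group", statistic = x$pseudo_F, df = x$df_num,
         df.residual = x$df_den, p.value = x$p_value)
}

#' @exportS3Method
glance.mb_permanova <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, p.value = x$p_value, n = x$n,
         n_permutations = x$n_permutations)
}
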