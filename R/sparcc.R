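#' Log-ratio variance matrix
#'
#' The statistic underlying sparse compositional correlation inference:
#' per-sample fractions are estimated with a pseudocount and
#' `t_ij = var over samples of log(x_i / x_j)` (n-1 denominator).
#'
#' @param counts Count matrix, OTUs as rows, samples as columns.
#' @param pseudocount Added to every count before fraction estimation.
#' @return Symmetric matrix with zero diagonal.
#' @export
log_ratio_variance <- function(counts, pseudocount = 1) {
  m <- as.matrix(counts) + pseudocount
  if (nrow(m) < 2) abort("need >= 2 OTUs.")
  if (ncol(m) < 3) abort("need >= 3 samples for stable log-ratio variances.")
  fr <- sweep(m, 2, colSums(m), "/")
  lf <- log(fr)
  v <- apply(lf, 1, stats::var)
  cv <- stats::cov(t(lf))
  t_mat <- outer(v, v, "+") - 2 * cv
  t_mat[t_mat < 0] <- 0
  diag(t_mat) <- 0
  dimnames(t_mat) <- list(rownames(counts), rownames(counts))
  t_mat
}

# Solve for basis variances omega^2 given t and the set of included pairs.
# For each i: sum_{j in inc(i)} t_ij ~= |inc(i)| w_i + sum_{j in inc(i)} w_j.
solve_basis_variances <- function(t_mat, include) {
  p <- nrow(t_mat)
  a <- include
  diag(a) <- 0
  m <- diag(rowSums(a)) + a
  rhs <- rowSums(t_mat * a)
  w <- tryCatch(solve(m, rhs), error = function(e) {
    abort("basis-variance system is singular after exclusions.")
  })
  if (any(w <= 0)) {
    warn("negative basis variance estimate(s) clamped to a small positive value.")
    w[w <= 0] <- 1e-8
  }
  w
}

basis_correlations <- function(t_mat, w) {
  rho <- (outer(w, w, "+") - t_mat) / (2 * outer(sqrt(w), sqrt(w)))
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  rho
}

sparcc_once <- function(t_mat, inference_iterations, exclusion_threshold) {
  p <- nrow(t_mat)
  include <- matrix(TRUE, p, p)
  diag(include) <- FALSE
  w <- solve_basis_variances(t_mat, include)
  rho <- basis_correlations(t_mat, w)
  for (round in seq_len(inference_iterations)) {
    cand <- abs(rho)
    cand[!include] <- -Inf
    diag(cand) <- -Inf
    mx <- max(cand)
    if (!is.finite(mx) || mx <= exclusion_threshold) break
    idx <- which(cand == mx, arr.ind = TRUE)[1, ]
    include[idx[1], idx[2]] <- FALSE
    include[idx[2], idx[1]] <- FALSE
    if (any(rowSums(include) < 2)) break
    w <- solve_basis_variances(t_mat, include)
    rho <- basis_correlations(t_mat, w)
  }
  list(rho = rho, w = w)
}

#' Sparse compositional correlations (SparCC)
#'
#' Estimates correlations between latent ("basis") abundances from
#' compositional count data: per resample, fractions are drawn from a
#' Dirichlet posterior (counts + pseudocount), log-ratio variances `t_ij`
#' computed, basis variances solved from the linear system implied by the
#' sparsity assumption, and `rho_ij = (w_i + w_j - t_ij)/(2 sqrt(w_i w_j))`;
#' the strongest-correlated pair above `exclusion_threshold` is then
#' iteratively removed from the system and it is re-solved, for up to
#' `inference_iterations` exclusion rounds. Estimates are averaged over
#' `n_resamples` fraction draws and clipped to `[-1, 1]`.
#'
#' @param counts Count matrix (OTUs x samples), ideally pre-filtered (see
#'   [sparcc_filter()]).
#' @param inference_iterations Maximum exclusion rounds.
#' @param exclusion_threshold Absolute-correlation threshold above which the
#'   strongest pair is excluded from the basis system; `Inf` disables
#'   exclusions (single closed-form solve).
#' @param n_resamples Number of Dirichlet fraction draws averaged over; `0`
#'   uses the point estimate (counts + pseudocount) only.
#' @param pseudocount Prior count added to all cells.
#' @param seed Optional integer seed.
#' @return An `mb_sparcc`: list with `rho` (correlation matrix),
#'   `basis_variances`, `otu_ids`, and the settings used.
#' @export
sparcc_correlations <- function(counts, inference_iterations = 10,
                                exclusion_threshold = 0.1, n_resamples = 10,
                                pseudocount = 1, seed = NULL) {
  m <- as.matrix(counts)
  if (nrow(m) < 4) abort("SparCC needs >= 4 OTUs for the basis solve.")
  with_seed(seed, {
    draws <- max(1L, as.integer(n_resamples))
    acc_rho <- 0
    acc_w <- 0
    for (b in seq_len(draws)) {
      fr <- if (n_resamples > 0) {
        apply(m + pseudocount, 2, function(col) rdirichlet1(col))
      } else {
        sweep(m + pseudocount, 2, colSums(m + pseudocount), "/")
      }
      lf <- log(fr)
      v <- apply(lf, 1, stats::var)
      cv <- stats::cov(t(lf))
      t_mat <- outer(v, v, "+") - 2 * cv
      t_mat[t_mat < 0] <- 0
      diag(t_mat) <- 0
      est <- sparcc_once(t_mat, inference_iterations, exclusion_threshold)
      acc_rho <- acc_rho + est$rho
      acc_w <- acc_w + est$w
    }
    rho <- acc_rho / draws
    rho[rho > 1] <- 1; rho[rho < -1] <- -1
    diag(rho) <- 1
    dimnames(rho) <- list(rownames(m), rownames(m))
    structure(
      list(rho = rho, basis_variances = acc_w / draws,
           otu_ids = rownames(m),
           settings = list(inference_iterations = inference_iterations,
                           exclusion_threshold = exclusion_threshold,
                           n_resamples = n_resamples,
                           pseudocount = pseudocount)),
      class = "mb_sparcc"
    )
  })
}

#' @export
print.mb_sparcc <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf("<mb_sparcc> %d OTUs; max |rho| = %.3f%s\n", nrow(x$rho),
              max(abs(off)),
              if (!is.null(x$p_values)) sprintf("; %d permutations",
                                                x$n_permutations) else ""))
  invisible(x)
}

#' Permutation p-values for SparCC correlations
#'
#' Null distribution from independently permuting each OTU's counts across
#' samples and recomputing the correlations; two-tailed
#' `p_ij = (count |rho_null| >= |rho_obs| + 1) / (permutations + 1)`.
#' Permutation re-estimates use the point-estimate fractions (no Dirichlet
#' resampling) for speed.
#'
#' @param counts The count matrix used for `result`.
#' @param result An `mb_sparcc` from [sparcc_correlations()].
#' @param permutations Number of permutations (>= 1).
#' @param seed Optional integer seed.
#' @return `result` with `p_values` (symmetric matrix) and `n_permutations`
#'   fields added.
#' @export
sparcc_pvalues <- function(counts, result, permutations = 1000, seed = NULL) {
  stopifnot(inherits(result, "mb_sparcc"))
  if (permutations < 1) abort("`permutations` must be >= 1.")
  m <- as.matrix(counts)
  obs <- abs(result$rho)
  s <- result$settings
  with_seed(seed, {
    exceed <- matrix(0, nrow(m), nrow(m))
    for (b in seq_len(permutations)) {
      perm <- t(apply(m, 1, sample))
      est <- sparcc_correlations(perm,
                                 inference_iterations = s$inference_iterations,
                                 exclusion_threshold = s$exclusion_threshold,
                                 n_resamples = 0,
                                 pseudocount = s$pseudocount, seed = NULL)
      exceed <- exceed + (abs(est$rho) >= obs)
    }
    p <- (exceed + 1) / (permutations + 1)
    diag(p) <- NA_real_
    dimnames(p) <- dimnames(result$rho)
    result$p_values <- p
    result$n_permutations <- as.integer(permutations)
    result
  })
}

#' Filter a count table before SparCC
#'
#' Keeps OTUs with mean count at least `min_mean` and present in at least
#' `min_prevalence` of samples (a conventional compositional-network
#' filtering recipe; record of the filter is attached for provenance).
#'
#' @param counts Count matrix or [otu_table()].
#' @param min_mean Minimum mean count per OTU.
#' @param min_prevalence Minimum fraction of samples with >= 1 read.
#' @return Filtered count matrix with a `filter_spec` attribute.
#' @export
sparcc_filter <- function(counts, min_mean = 1, min_prevalence = 0.2) {
  m <- if (inherits(counts, "otu_table")) counts$counts else as.matrix(counts)
  keep <- rowMeans(m) >= min_mean & rowMeans(m >= 1) >= min_prevalence
  out <- m[keep, , drop = FALSE]
  attr(out, "filter_spec") <- list(min_mean = min_mean,
                                   min_prevalence = min_prevalence,
                                   n_kept = sum(keep), n_total = nrow(m))
  out
}

#' Significant SparCC edges as a tibble
#'
#' @param x An `mb_sparcc` with p-values.
#' @param p_threshold Two-tailed p-value cutoff.
#' @param ... Unused.
#' @return Tibble `otu_a`, `otu_b`, `rho`, `p_value`, sorted by `|rho|`.
#' @exportS3Method
tidy.mb_sparcc <- function(x, p_threshold = 1, ...) {
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  out <- tibble(
    otu_a = x$otu_ids[idx[, 1]], otu_b = x$otu_ids[idx[, 2]],
    rho = x$rho[idx],
    p_value = if (!is.null(x$p_values)) x$p_values[idx] else NA_real_
  )
  out <- dplyr::filter(out, is.na(.data$p_value) | .data$p_value <= p_threshold)
  dplyr::arrange(out, dplyr::desc(abs(.data$rho)))
}
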