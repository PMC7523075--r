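#' Modified principal variance component analysis (PVCA) on NMDS axes
#'
#' Partitions community variation among design terms by (1) ordinating the
#' dissimilarity matrix into `n_axes` NMDS axes, (2) fitting, per axis, a
#' variance-component model with all design terms random --
#' `score ~ (1|soil) + (1|genotype) + (1|compartment) + all interactions` --
#' by REML (variances constrained non-negative), (3) converting each axis's
#' variance components to percentages, and (4) averaging across axes with
#' weights proportional to each axis's share of community variation
#' (per-axis R-squared), rescaled so the final percentages total 100.
#'
#' @param d A `dissimilarity_matrix`.
#' @param metadata Design tibble with `sample_id`, `soil`, `genotype`,
#'   `compartment` covering `d`'s samples.
#' @param n_axes Number of NMDS axes to use (ordination run at `k = n_axes`).
#' @param ord Optional precomputed `mb_ordination` with `k >= n_axes`.
#' @param seed Optional integer seed (NMDS restarts).
#' @param restarts Random starts for the ordination.
#' @return An `mb_pvca`: list with `components` (tibble `term`, `percent`),
#'   `per_axis` (percent per term per axis), `weights`, and the ordination.
#' @export
pvca <- function(d, metadata, n_axes = 10, ord = NULL, seed = NULL,
                 restarts = 16) {
  m <- as.matrix(d)
  meta <- metadata[match(rownames(m), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) abort("`metadata` must cover every sample in `d`.")
  for (v in c("soil", "genotype", "compartment")) {
    if (length(unique(meta[[v]])) < 2) {
      abort(paste0("singular design: factor '", v, "' has < 2 levels."))
    }
  }
  if (is.null(ord)) {
    if (n_axes >= nrow(m)) abort("`n_axes` must be < number of samples.")
    ord <- nmds(d, k = n_axes, restarts = restarts, seed = seed)
  } else if (ord$k < n_axes) {
    abort("supplied ordination has fewer axes than `n_axes`.")
  }
  scores <- as.matrix(ord$coordinates[, paste0("axis", seq_len(n_axes))])
  fit <- pvca_from_scores(scores, meta, weights = ord$axis_r2[seq_len(n_axes)])
  fit$ordination <- ord
  fit
}

#' REML variance-component partition of axis scores
#'
#' The score-level core of [pvca()]: per axis (column of `scores`) fits the
#' all-random variance-component model by REML, converts components to
#' percentages, and averages axes with the given weights (rescaled to sum
#' 100). Axes whose REML fit fails are dropped with a warning and the
#' weights renormalized.
#'
#' @param scores Numeric matrix, samples x axes.
#' @param metadata Design tibble with `soil`, `genotype`, `compartment` in
#'   `scores` row order.
#' @param weights Per-axis weights (e.g. axis R-squared); uniform if `NULL`.
#' @return An `mb_pvca` (without an `ordination` element).
#' @export
pvca_from_scores <- function(scores, metadata, weights = NULL) {
  scores <- as.matrix(scores)
  n_axes <- ncol(scores)
  if (is.null(weights)) weights <- rep(1, n_axes)
  stopifnot(length(weights) == n_axes, all(weights >= 0))
  df <- data.frame(
    soil = factor(metadata$soil), genotype = factor(metadata$genotype),
    compartment = factor(metadata$compartment)
  )
  terms <- c(soil = "soil", genotype = "genotype", compartment = "compartment",
             `soil:genotype` = "soil:genotype",
             `soil:compartment` = "soil:compartment",
             `genotype:compartment` = "genotype:compartment",
             `soil:genotype:compartment` = "soil:genotype:compartment")
  form <- stats::as.formula(paste(
    "score ~ 1 +", paste(sprintf("(1 | %s)", terms), collapse = " + ")))

  per_axis <- matrix(NA_real_, length(terms) + 1L, n_axes,
                     dimnames = list(c(names(terms), "residual"), NULL))
  ok <- logical(n_axes)
  for (a in seq_len(n_axes)) {
    df$score <- scores[, a]
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(form, data = df, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE))
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    vc <- as.data.frame(lme4::VarCorr(fit))
    vars <- stats::setNames(vc$vcov, vc$grp)
    resid_var <- vars[["Residual"]]
    comp_vars <- vapply(names(terms), function(t) {
      v <- vars[names(vars) == t]
      if (length(v)) v[[1]] else 0
    }, 0)
    total <- sum(comp_vars) + resid_var
    per_axis[, a] <- c(comp_vars, resid_var) / total * 100
    ok[a] <- TRUE
  }
  if (!any(ok)) abort("REML failed on every axis.")
  if (any(!ok)) {
    warn(paste0("dropping ", sum(!ok), " axis/axes with failed REML fits; ",
                "weights renormalized."))
  }
  w <- weights * ok
  if (sum(w) == 0) abort("all usable axes have zero weight.")
  w <- w / sum(w)
  percent <- as.numeric(per_axis[, ok, drop = FALSE] %*% w[ok])
  percent <- percent / sum(percent) * 100
  components <- tibble(term = rownames(per_axis), percent = percent)
  structure(
    list(components = components, per_axis = per_axis, weights = w,
         n_axes = n_axes),
    class = "mb_pvca"
  )
}

#' @export
print.mb_pvca <- function(x, ...) {
  cat("<mb_pvca> variance explained (%):\n")
  print(as.data.frame(x$components), row.names = FALSE)
  invisible(x)
}
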