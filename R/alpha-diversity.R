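#' Iterative-subsampling alpha diversity estimators
#'
#' For each sample with at least `depth` reads, repeatedly rarefies to
#' `depth` reads (without replacement) and averages, over iterations:
#' observed OTU richness `S_obs`; the complement of Simpson's diversity
#' `1 - D` with the bias-corrected estimator
#' `D = sum n_i (n_i - 1) / (N (N - 1))`; and Simpson's evenness
#' `E_D = (1 / D) / S_obs`. Samples below `depth` are excluded with a
#' warning. Note `E_D` can exceed 1 on tiny, very even draws (a property of
#' the bias-corrected `D`).
#'
#' @param x An [otu_table()].
#' @param depth Rarefaction depth (reads per iteration); must be >= 2.
#' @param iterations Number of subsampling iterations to average over.
#' @param seed Optional integer seed.
#' @return A tibble with one row per retained sample: `sample_id`, `s_obs`,
#'   `simpson_complement`, `simpson_evenness`, `n_iterations`, `depth`,
#'   joined with the design metadata.
#' @export
iterative_alpha <- function(x, depth = 1500, iterations = 1000, seed = NULL) {
  stopifnot(inherits(x, "otu_table"))
  if (depth < 2) abort("`depth` must be >= 2 (Simpson's D is undefined below).")
  counts <- x$counts
  totals <- colSums(counts)
  keep <- totals >= depth
  if (!any(keep)) abort("no sample has total count >= depth.")
  if (any(!keep)) {
    warn(paste0("excluding ", sum(!keep), " sample(s) with total < depth: ",
                paste(colnames(counts)[!keep], collapse = ", ")))
  }
  counts <- counts[, keep, drop = FALSE]

  with_seed(seed, {
    res <- apply(counts, 2, function(col) {
      exhaustive <- sum(col) == depth
      iters <- if (exhaustive) 1L else iterations
      acc <- c(s = 0, d = 0, e = 0)
      for (it in seq_len(iters)) {
        draw <- if (exhaustive) col else draw_hypergeometric(col, depth)
        nz <- draw[draw > 0]
        s_obs <- length(nz)
        d_hat <- sum(nz * (nz - 1)) / (depth * (depth - 1))
        acc <- acc + c(s_obs, 1 - d_hat,
                       if (d_hat > 0) (1 / d_hat) / s_obs else NA_real_)
      }
      acc / iters
    })
    out <- tibble(
      sample_id = colnames(counts),
      s_obs = unname(res[1, ]),
      simpson_complement = unname(res[2, ]),
      simpson_evenness = unname(res[3, ]),
      n_iterations = iterations,
      depth = as.integer(depth)
    )
    dplyr::left_join(out, x$metadata, by = "sample_id")
  })
}

#' Logit and Box-Cox response transforms
#'
#' `logit(p) = log(p / (1 - p))`; Box-Cox `(x^lambda - 1) / lambda` for
#' `lambda != 0`, `log(x)` for `lambda = 0`. For the logit, values of
#' exactly 0 or 1 (possible for evenness on degenerate draws) are clamped to
#' `[eps, 1 - eps]` with a warning; values outside `[0, 1]` are an error.
#'
#' @param values Numeric vector.
#' @param kind `"logit"` or `"box-cox"`.
#' @param lambda Box-Cox exponent (required for `kind = "box-cox"`).
#' @param eps Clamping bound for logit inputs at 0/1; default `1/(2*1500)`,
#'   half a count at the standard rarefaction depth.
#' @return Transformed numeric vector.
#' @export
transform_response <- function(values, kind = c("logit", "box-cox"),
                               lambda = NULL, eps = 1 / 3000) {
  kind <- match.arg(kind)
  if (kind == "logit") {
    bad <- which(values < 0 | values > 1)
    if (length(bad)) {
      abort(sprintf("logit input outside [0, 1]: value %g at position %d",
                    values[bad[1]], bad[1]))
    }
    clamped <- values <= 0 | values >= 1
    if (any(clamped)) {
      warn(sprintf("clamping %d logit input(s) at 0/1 to [%g, %g]",
                   sum(clamped), eps, 1 - eps))
      values <- pmin(pmax(values, eps), 1 - eps)
    }
    log(values / (1 - values))
  } else {
    if (is.null(lambda)) abort("`lambda` is required for the Box-Cox transform.")
    bad <- which(values <= 0)
    if (length(bad)) {
      abort(sprintf("Box-Cox input must be > 0: value %g at position %d",
                    values[bad[1]], bad[1]))
    }
    if (lambda == 0) log(values) else (values^lambda - 1) / lambda
  }
}

#' Profile-likelihood estimate of the Box-Cox exponent
#'
#' Maximizes the Box-Cox profile log-likelihood of a single sample (no
#' covariates) over `lambda`, for use when analysing new data instead of the
#' fixed per-compartment exponents.
#'
#' @param x Positive numeric vector.
#' @param interval Search interval for `lambda`.
#' @return The maximizing `lambda`.
#' @export
estimate_box_cox_lambda <- function(x, interval = c(-3, 3)) {
  if (any(x <= 0)) abort("Box-Cox requires positive values.")
  n <- length(x)
  ll <- function(lambda) {
    y <- transform_response(x, "box-cox", lambda = lambda)
    -n / 2 * log(stats::var(y) * (n - 1) / n) + (lambda - 1) * sum(log(x))
  }
  stats::optimize(ll, interval, maximum = TRUE)$maximum
}

#' Default per-compartment Box-Cox exponents for richness
#'
#' The exponents used for the observed-richness responses by compartment:
#' rhizosphere 1.6, root 0, leaf -0.2, nodule -0.2.
#'
#' @return Named numeric vector.
#' @export
default_richness_lambdas <- function() {
  c(rhizosphere = 1.6, root = 0, leaf = -0.2, nodule = -0.2)
}

#' Fixed-effects factorial ANOVA
#'
#' Sequential (Type I) sums of squares; on balanced designs the partition is
#' order-invariant. Unbalanced designs are analysed with a warning (SS then
#' depend on term order, as in sequential least-squares projections).
#'
#' @param data A data frame.
#' @param formula Model formula, e.g. `response ~ soil * genotype * compartment`.
#' @return A tibble with class `mb_anova`: `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value` (residual row included).
#' @export
factorial_anova <- function(data, formula) {
  mf <- stats::model.frame(formula, data)
  response <- stats::model.response(mf)
  if (stats::var(response) == 0) abort("constant response: no variance to partition.")
  factors <- mf[-1]
  if (any(vapply(factors, function(f) length(unique(f)), 1L) < 2)) {
    abort("every factor needs >= 2 observed levels.")
  }
  cells <- table(interaction(lapply(factors, as.factor), drop = TRUE))
  if (length(unique(as.integer(cells))) > 1) {
    warn("unbalanced design: sequential (Type I) sums of squares depend on term order.")
  }
  data <- as.data.frame(lapply(mf, function(col) {
    if (is.character(col) || is.logical(col)) factor(col) else col
  }))
  fit <- stats::aov(formula, data = data)
  if (stats::df.residual(fit) == 0) abort("zero residual degrees of freedom.")
  s <- summary(fit)[[1]]
  out <- tibble(
    term = trimws(rownames(s)),
    df = s[["Df"]],
    sumsq = s[["Sum Sq"]],
    meansq = s[["Mean Sq"]],
    statistic = s[["F value"]],
    p.value = s[["Pr(>F)"]]
  )
  class(out) <- c("mb_anova", class(out))
  out
}

#' Tukey HSD with a compact letter display
#'
#' All-pairs studentized-range test at level `alpha` after a one-way ANOVA,
#' plus a compact letter display in which groups sharing a letter do not
#' differ significantly. The q statistic for a pair is
#' `|mean_i - mean_j| / sqrt(MSE/2 (1/n_i + 1/n_j))` (Tukey-Kramer),
#' reducing to `diff / sqrt(MSE/n)` for equal group sizes.
#'
#' @param data A data frame.
#' @param response,group Column names (strings) of the response and grouping
#'   factor.
#' @param alpha Familywise significance level.
#' @return A list with tibbles `pairs` (`group_a`, `group_b`, `diff`, `q`,
#'   `p.value`) and `letters` (`group`, `n`, `mean`, `letter`).
#' @export
tukey_hsd <- function(data, response, group, alpha = 0.05) {
  y <- data[[response]]
  g <- factor(data[[group]])
  ns <- table(g)
  if (length(ns) < 2) abort("need >= 2 groups.")
  if (any(ns < 2)) {
    abort(paste0("every group needs n >= 2; offending: ",
                 paste(names(ns)[ns < 2], collapse = ", ")))
  }
  fit <- stats::aov(y ~ g)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  means <- tapply(y, g, mean)
  k <- length(means)
  df_err <- stats::df.residual(fit)
  combs <- utils::combn(names(means), 2)
  pairs <- purrr::map_dfr(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    se <- sqrt(mse / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
    q <- abs(means[[a]] - means[[b]]) / se
    tibble(group_a = a, group_b = b, diff = means[[b]] - means[[a]],
           q = q, p.value = stats::ptukey(q, k, df_err, lower.tail = FALSE))
  })
  letters_tbl <- tibble(
    group = names(sort(means, decreasing = TRUE)),
    n = as.integer(ns[names(sort(means, decreasing = TRUE))]),
    mean = as.numeric(sort(means, decreasing = TRUE)),
    letter = compact_letters(pairs, names(sort(means, decreasing = TRUE)), alpha)
  )
  list(pairs = pairs, letters = letters_tbl, mse = mse, df = df_err)
}

# Insert-and-absorb compact letter display over a pairwise p-value table.
compact_letters <- function(pairs, groups_ordered, alpha) {
  sig <- function(a, b) {
    row <- pairs[(pairs$group_a == a & pairs$group_b == b) |
                   (pairs$group_a == b & pairs$group_b == a), ]
    nrow(row) > 0 && row$p.value[1] < alpha
  }
  # letter sets: list of character vectors of group names (non-differing)
  sets <- list(groups_ordered[1])
  for (gname in groups_ordered[-1]) {
    placed <- FALSE
    for (i in seq_along(sets)) {
      if (!any(vapply(sets[[i]], sig, TRUE, b = gname))) {
        sets[[i]] <- c(sets[[i]], gname)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- gname
  }
  # absorb redundant sets
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i != j && keep[i] && keep[j] && all(sets[[i]] %in% sets[[j]])) {
      keep[i] <- FALSE
    }
  }
  sets <- sets[keep]
  vapply(groups_ordered, function(gname) {
    paste0(letters[which(vapply(sets, function(s) gname %in% s, TRUE))],
           collapse = "")
  }, "")
}
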