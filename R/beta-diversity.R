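#' Iterative-subsampling Bray-Curtis dissimilarity
#'
#' Per iteration, every eligible sample (total >= `depth`) is rarefied to
#' `depth` reads and all pairwise Bray-Curtis dissimilarities
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` are computed; the returned
#' matrix is the element-wise mean over iterations.
#'
#' @param x An [otu_table()].
#' @param depth Rarefaction depth.
#' @param iterations Number of subsampling iterations.
#' @param seed Optional integer seed.
#' @return A `dissimilarity_matrix`: symmetric numeric matrix in `[0, 1]`
#'   with attributes `depth` and `n_iterations`.
#' @export
iterative_bray_curtis <- function(x, depth = 1500, iterations = 1000,
                                  seed = NULL) {
  stopifnot(inherits(x, "otu_table"))
  counts <- x$counts
  keep <- colSums(counts) >= depth
  if (sum(keep) < 2) abort("need >= 2 samples with total count >= depth.")
  if (any(!keep)) {
    warn(paste0("excluding ", sum(!keep), " sample(s) with total < depth: ",
                paste(colnames(counts)[!keep], collapse = ", ")))
  }
  counts <- counts[, keep, drop = FALSE]
  with_seed(seed, {
    acc <- matrix(0, ncol(counts), ncol(counts))
    for (it in seq_len(iterations)) {
      sub <- apply(counts, 2, draw_hypergeometric, depth = depth)
      acc <- acc + as.matrix(vegan::vegdist(t(sub), method = "bray"))
    }
    m <- acc / iterations
    dimnames(m) <- list(colnames(counts), colnames(counts))
    dissimilarity_matrix(m, depth = depth, n_iterations = iterations)
  })
}

#' Construct a dissimilarity matrix object
#'
#' @param values Symmetric numeric matrix with values in `[0, 1]`, zero
#'   diagonal, and sample ids as dimnames.
#' @param depth,n_iterations Provenance attributes (optional).
#' @return A `dissimilarity_matrix`.
#' @export
dissimilarity_matrix <- function(values, depth = NA_integer_,
                                 n_iterations = NA_integer_) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    dimnames(values) <- list(paste0("s", seq_len(nrow(values))),
                             paste0("s", seq_len(nrow(values))))
  }
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8))) {
    abort("dissimilarity matrix must be symmetric.")
  }
  if (any(diag(values) != 0)) abort("dissimilarity matrix must have zero diagonal.")
  if (any(values < 0 | values > 1 + 1e-12)) {
    abort("dissimilarity values must lie in [0, 1].")
  }
  structure(values, depth = depth, n_iterations = n_iterations,
            class = c("dissimilarity_matrix", "matrix"))
}

#' Write / read a dissimilarity matrix as TSV
#'
#' Square TSV with sample ids (`format = "square"`) or lower-triangle
#' phylip-style (`format = "phylip"`).
#'
#' @param d A `dissimilarity_matrix`.
#' @param path File path.
#' @param format `"square"` or `"phylip"`.
#' @return `path` invisibly (write); a `dissimilarity_matrix` (read).
#' @export
write_dissimilarity <- function(d, path, format = c("square", "phylip")) {
  format <- match.arg(format)
  m <- unclass(d)
  if (format == "square") {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.character(nrow(m)), con)
    for (i in seq_len(nrow(m))) {
      writeLines(paste(c(rownames(m)[i],
                         formatC(m[i, seq_len(i - 1)], format = "g", digits = 10)),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path, format = c("square", "phylip")) {
  format <- match.arg(format)
  if (format == "square") {
    df <- utils::read.delim(path, header = TRUE, row.names = 1,
                            check.names = FALSE)
    m <- as.matrix(df)
  } else {
    lines <- readLines(path)
    n <- as.integer(lines[1])
    ids <- character(n)
    m <- matrix(0, n, n)
    for (i in seq_len(n)) {
      parts <- strsplit(lines[i + 1], "\t")[[1]]
      ids[i] <- parts[1]
      if (i > 1) {
        vals <- as.numeric(parts[-1])
        m[i, seq_len(i - 1)] <- vals
        m[seq_len(i - 1), i] <- vals
      }
    }
    dimnames(m) <- list(ids, ids)
  }
  dissimilarity_matrix(m)
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS via isotonic-regression majorization
#' (vegan's `monoMDS` engine through `metaMDS`), taking the best of
#' `restarts` random starts; the configuration is centred and rotated to
#' principal axes. Per-axis R-squared values (squared Pearson correlation of
#' single-axis distances with the observed dissimilarities) are attached,
#' as used for the PVCA axis weights.
#'
#' @param d A `dissimilarity_matrix` (or symmetric matrix / `dist`).
#' @param k Number of ordination axes.
#' @param restarts Number of random starts.
#' @param max_iter Majorization iterations per start.
#' @param tol Convergence tolerance on stress.
#' @param seed Optional integer seed.
#' @return An `mb_ordination`: list with `coordinates` (tibble `sample_id` +
#'   `axis1..axisk`), `stress`, `axis_r2`, `k`, `converged`.
#' @export
nmds <- function(d, k = 3, restarts = 32, max_iter = 500, tol = 1e-7,
                 seed = NULL) {
  m <- as.matrix(d)
  if (k >= nrow(m)) abort("`k` must be smaller than the number of samples.")
  if (k < 1) abort("`k` must be >= 1.")
  with_seed(seed, {
    fit <- suppressWarnings(suppressMessages(
      vegan::metaMDS(stats::as.dist(m), k = k, try = restarts,
                     trymax = restarts, maxit = max_iter,
                     sfgrmin = 1e-9, sratmax = 1 - tol,
                     autotransform = FALSE, wascores = FALSE, trace = 0)
    ))
    coords <- fit$points
    # centre and rotate to principal axes (metaMDS already pc-rotates via
    # monoMDS pc=TRUE, but make it explicit and deterministic in sign)
    coords <- scale(coords, center = TRUE, scale = FALSE)
    if (k > 1) {
      pc <- stats::prcomp(coords, center = FALSE)
      coords <- coords %*% pc$rotation
    }
    for (a in seq_len(k)) if (coords[1, a] < 0) coords[, a] <- -coords[, a]
    colnames(coords) <- paste0("axis", seq_len(k))
    ord <- structure(
      list(
        coordinates = dplyr::bind_cols(tibble(sample_id = rownames(m)),
                                       as_tibble(as.data.frame(coords))),
        stress = fit$stress,
        k = k,
        converged = isTRUE(fit$converged) || fit$stress < 1e-6
      ),
      class = "mb_ordination"
    )
    ord$axis_r2 <- axis_r_squared(m, ord)
    ord
  })
}

#' @export
print.mb_ordination <- function(x, ...) {
  cat(sprintf("<mb_ordination> k = %d, stress-1 = %.4f%s\n", x$k, x$stress,
              if (!x$converged) " (no convergence flag)" else ""))
  cat("axis R2:", paste(sprintf("%.3f", x$axis_r2), collapse = ", "), "\n")
  invisible(x)
}

#' Per-axis share of community variation
#'
#' For each ordination axis, the squared Pearson correlation between the
#' observed dissimilarities and the inter-sample distances computed from
#' that axis alone. Constant axes get 0 with a warning.
#'
#' @param d Dissimilarity matrix (or object coercible to matrix).
#' @param ord An `mb_ordination` derived from `d`.
#' @return Numeric vector of length `k`.
#' @export
axis_r_squared <- function(d, ord) {
  m <- as.matrix(d)
  obs <- m[lower.tri(m)]
  coords <- as.matrix(ord$coordinates[, -1, drop = FALSE])
  vapply(seq_len(ncol(coords)), function(a) {
    da <- as.matrix(stats::dist(coords[, a, drop = FALSE]))
    da <- da[lower.tri(da)]
    if (stats::sd(da) == 0) {
      warn(sprintf("axis %d has constant coordinates; R2 set to 0", a))
      return(0)
    }
    stats::cor(obs, da)^2
  }, 0)
}
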