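#' OTU count table with experimental design metadata
#'
#' An `otu_table` bundles an OTU x sample matrix of non-negative integer
#' sequence counts with optional per-OTU taxonomy and a per-sample design
#' key (soil origin, plant genotype, replicate, compartment, plant id).
#' All analysis functions in the package take an `otu_table` (or a plain
#' data frame, where noted) as their first argument and return tibbles.
#'
#' @param counts Integer matrix, OTUs as rows and samples as columns, with
#'   unique row and column names.
#' @param taxonomy Optional character vector of lineage strings, one per OTU.
#' @param metadata Optional data frame of per-sample design keys with columns
#'   `sample_id`, `soil`, `genotype`, `replicate`, `compartment`, `plant_id`.
#'   If `NULL`, sample names are parsed with [parse_sample_name()] when they
#'   follow the `<soil><genotype><replicate><compartment>` code (e.g.
#'   `"C96bN"`); otherwise metadata is left empty.
#'
#' @return An object of class `otu_table`.
#' @seealso [read_otu_table()], [parse_sample_name()], [generate_experiment()]
#' @export
otu_table <- function(counts, taxonomy = NULL, metadata = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("Otu", sprintf("%04d", seq_len(nrow(counts))))
  }
  if (is.null(colnames(counts))) {
    abort("`counts` must have sample names as column names.")
  }
  validate_counts(counts)
  if (anyDuplicated(rownames(counts))) abort("duplicate OTU ids in `counts`.")
  if (anyDuplicated(colnames(counts))) abort("duplicate sample ids in `counts`.")
  if (!is.null(taxonomy)) {
    if (length(taxonomy) != nrow(counts)) {
      abort("`taxonomy` must have one entry per OTU.")
    }
    taxonomy <- stats::setNames(as.character(taxonomy), rownames(counts))
  }
  if (is.null(metadata)) {
    metadata <- try_parse_metadata(colnames(counts))
  } else {
    metadata <- as_tibble(metadata)
    required <- c("sample_id", "soil", "genotype", "replicate", "compartment")
    missing <- setdiff(required, names(metadata))
    if (length(missing)) {
      abort(paste0("metadata lacks columns: ", paste(missing, collapse = ", ")))
    }
    if (!all(colnames(counts) %in% metadata$sample_id)) {
      abort("metadata must cover every sample in `counts`.")
    }
    metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
    if (!"plant_id" %in% names(metadata)) {
      metadata$plant_id <- paste0(metadata$soil, metadata$genotype,
                                  metadata$replicate)
    }
  }
  structure(
    list(counts = counts, taxonomy = taxonomy, metadata = metadata),
    class = "otu_table"
  )
}

validate_counts <- function(counts) {
  if (!is.numeric(counts)) abort("counts must be numeric.")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "counts must be non-negative integers; offending cell: OTU '%s', sample '%s' (value %s)",
      rownames(counts)[bad[1, 1]] %||% bad[1, 1],
      colnames(counts)[bad[1, 2]] %||% bad[1, 2],
      format(counts[bad[1, 1], bad[1, 2]])
    ))
  }
  invisible(counts)
}

try_parse_metadata <- function(sample_ids) {
  ok <- grepl("^[CF](1|27|96)[a-e][LNRS]$", sample_ids)
  if (all(ok)) {
    parse_sample_name(sample_ids)
  } else {
    tibble(sample_id = sample_ids, soil = NA_character_,
           genotype = NA_character_, replicate = NA_character_,
           compartment = NA_character_, plant_id = NA_character_)
  }
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d OTUs x %d samples, total %s reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  comp <- x$metadata$compartment
  if (!all(is.na(comp))) {
    cat("compartments:", paste(sprintf("%s (%d)", names(table(comp)),
                                       table(comp)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Design metadata of an OTU table
#'
#' @param x An [otu_table()].
#' @return A tibble with one row per sample.
#' @export
sample_metadata <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  x$metadata
}

#' Subset an OTU table by samples and/or OTUs
#'
#' @param x An [otu_table()].
#' @param samples,otus Character vectors of ids (or logical/integer indices).
#' @return An [otu_table()] restricted to the requested rows/columns.
#' @export
subset_table <- function(x, samples = NULL, otus = NULL) {
  stopifnot(inherits(x, "otu_table"))
  counts <- x$counts
  if (!is.null(otus)) counts <- counts[otus, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  tax <- if (!is.null(x$taxonomy)) x$taxonomy[rownames(counts)]
  otu_table(counts, taxonomy = tax,
            metadata = x$metadata[match(colnames(counts), x$metadata$sample_id), ])
}

#' Long-format view of an OTU table
#'
#' @param x An [otu_table()].
#' @param ... Unused.
#' @return A tibble with columns `otu_id`, `sample_id`, `count` and the
#'   design metadata, one row per (OTU, sample) pair with a nonzero count.
#' @exportS3Method
tidy.otu_table <- function(x, ...) {
  long <- as_tibble(as.data.frame.table(x$counts, stringsAsFactors = FALSE))
  names(long) <- c("otu_id", "sample_id", "count")
  long <- dplyr::filter(long, .data$count > 0)
  dplyr::left_join(long, x$metadata, by = "sample_id")
}

#' Parse study-style sample names into design keys
#'
#' Sample names encode soil origin (`C` Corsica, `F` France), plant genotype
#' (`1`, `27`, `96`), replicate (`a`-`e`) and compartment (`L` leaf, `N`
#' nodule, `R` root endosphere, `S` rhizosphere soil), e.g. `"C96bN"`.
#' `plant_id` is the soil x genotype x replicate key shared by the (up to
#' four) compartment samples of one plant.
#'
#' @param name Character vector of sample names.
#' @return A tibble with columns `sample_id`, `soil`, `genotype`,
#'   `replicate`, `compartment`, `plant_id`.
#' @export
#' @examples
#' parse_sample_name(c("C96bN", "F1aS"))
parse_sample_name <- function(name) {
  m <- regmatches(name, regexec("^([CF])(1|27|96)([a-e])([LNRS])$", name))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) {
    abort(paste0(
      "unrecognized sample name(s): ", paste(name[bad], collapse = ", "),
      ". Valid codes: soil C/F, genotype 1/27/96, replicate a-e, ",
      "compartment L/N/R/S."
    ))
  }
  soil_map <- c(C = "Corsica", F = "France")
  comp_map <- c(L = "leaf", N = "nodule", R = "root", S = "rhizosphere")
  parts <- do.call(rbind, m)
  tibble(
    sample_id = name,
    soil = unname(soil_map[parts[, 2]]),
    genotype = paste0("G", parts[, 3]),
    replicate = parts[, 4],
    compartment = unname(comp_map[parts[, 5]]),
    plant_id = paste0(parts[, 2], parts[, 3], parts[, 4])
  )
}

#' Read an OTU table from disk
#'
#' Supports a plain TSV (OTUs as rows, first column OTU ids, header row of
#' sample names; orientation is auto-detected and normalized to OTUs x
#' samples when sample names follow the design code), the mothur
#' "shared" dialect (`label`/`Group`/`numOtus` leading columns, samples as
#' rows), and BIOM v1 JSON.
#'
#' @param path File path.
#' @param dialect One of `"tsv"`, `"mothur-shared"`, `"biom"`.
#' @param taxonomy Optional path to a two-column TSV (otu_id, lineage).
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, dialect = c("tsv", "mothur-shared", "biom"),
                           taxonomy = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  counts <- switch(dialect,
    "tsv" = read_counts_tsv(path),
    "mothur-shared" = read_counts_shared(path),
    "biom" = read_counts_biom(path)
  )
  tax <- NULL
  if (!is.null(taxonomy)) {
    tt <- utils::read.delim(taxonomy, header = TRUE, stringsAsFactors = FALSE)
    tax <- stats::setNames(tt[[2]], tt[[1]])[rownames(counts)]
  }
  otu_table(counts, taxonomy = tax)
}

read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df)
  storage.mode(mat) <- "double"
  if (anyNA(mat)) abort(paste0("non-numeric cell in ", path))
  # normalize orientation: samples are recognizable by the design code
  rows_look_like_samples <- all(grepl("^[CF](1|27|96)[a-e][LNRS]$", rownames(mat)))
  cols_look_like_samples <- all(grepl("^[CF](1|27|96)[a-e][LNRS]$", colnames(mat)))
  if (rows_look_like_samples && !cols_look_like_samples) mat <- t(mat)
  validate_counts(mat)
  mat
}

read_counts_shared <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  lead <- intersect(c("label", "Group", "numOtus", "numOTUs"), names(df))
  if (!"Group" %in% lead) abort("not a mothur shared file: no 'Group' column")
  samples <- df$Group
  mat <- t(as.matrix(df[, setdiff(names(df), lead), drop = FALSE]))
  colnames(mat) <- samples
  storage.mode(mat) <- "double"
  validate_counts(mat)
  mat
}

read_counts_biom <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  otus <- vapply(b$rows, function(r) r$id, "")
  samples <- vapply(b$columns, function(cc) cc$id, "")
  mat <- matrix(0, length(otus), length(samples),
                dimnames = list(otus, samples))
  if (identical(b$matrix_type, "dense")) {
    for (i in seq_along(b$data)) mat[i, ] <- unlist(b$data[[i]])
  } else {
    for (trip in b$data) {
      mat[trip[[1]] + 1L, trip[[2]] + 1L] <- trip[[3]]
    }
  }
  validate_counts(mat)
  mat
}

#' Write an OTU table as TSV
#'
#' OTUs as rows, first column `otu_id`, one column per sample.
#'
#' @param x An [otu_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(otu_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop rare OTUs by dataset-wide total count
#'
#' Retains OTUs whose total count across all samples is at least
#' `min_total`; the sample set is unchanged. The default of 10 reflects
#' common amplicon practice; the threshold is exposed because published
#' analyses rarely state theirs.
#'
#' @param x An [otu_table()].
#' @param min_total Minimum dataset-wide total count (inclusive).
#' @return A filtered [otu_table()].
#' @export
filter_rare_otus <- function(x, min_total = 10) {
  stopifnot(inherits(x, "otu_table"), min_total >= 0)
  keep <- rowSums(x$counts) >= min_total
  subset_table(x, otus = which(keep))
}

#' Per-sample relative abundances
#'
#' @param x An [otu_table()] or a count matrix (OTUs x samples).
#' @return A matrix of proportions; each column sums to 1.
#' @export
to_relative_abundance <- function(x) {
  counts <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    abort(paste0("sample(s) with zero total count: ",
                 paste(colnames(counts)[zero], collapse = ", ")))
  }
  sweep(counts, 2, totals, "/")
}

#' Rarefy one sample's counts without replacement
#'
#' Draws `depth` reads from a count vector by multivariate hypergeometric
#' sampling (without replacement), the behaviour implied by subsampling a
#' fixed number of sequences from a sample's reads.
#'
#' @param column Non-negative integer count vector.
#' @param depth Number of reads to draw; must not exceed `sum(column)`.
#' @param seed Optional integer seed (local to this draw).
#' @return An integer vector of the same length summing to `depth`.
#' @export
subsample_counts <- function(column, depth, seed = NULL) {
  column <- as.numeric(column)
  if (any(column < 0 | column != round(column))) {
    abort("`column` must be non-negative integer counts.")
  }
  total <- sum(column)
  if (depth > total) {
    abort(sprintf("depth (%d) exceeds sample total (%d); exclude the sample upstream.",
                  as.integer(depth), as.integer(total)))
  }
  with_seed(seed, {
    if (depth == total) return(as.integer(column))
    draw_hypergeometric(column, depth)
  })
}

# Sequential conditional hypergeometric draw; O(n_otus) per call.
draw_hypergeometric <- function(column, depth) {
  out <- integer(length(column))
  remaining <- sum(column)
  need <- depth
  for (i in seq_along(column)) {
    if (need == 0L) break
    ci <- column[i]
    if (ci == 0) next
    k <- stats::rhyper(1, ci, remaining - ci, need)
    out[i] <- k
    need <- need - k
    remaining <- remaining - ci
  }
  out
}

# Rarefy all eligible columns of a count matrix; drops (with a warning)
# samples whose total is below `depth`.
rarefy_matrix <- function(counts, depth) {
  totals <- colSums(counts)
  drop <- totals < depth
  if (any(drop)) {
    warn(paste0("excluding ", sum(drop), " sample(s) with total < depth: ",
                paste(colnames(counts)[drop], collapse = ", ")))
    counts <- counts[, !drop, drop = FALSE]
  }
  apply(counts, 2, draw_hypergeometric, depth = depth)
}
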