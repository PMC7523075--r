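#' Pipeline configuration
#'
#' Defaults follow the study's stated analysis parameters: subsampling depth
#' 1500 with 1000 iterations, NMDS in 3 dimensions with the first 10 axes
#' feeding the PVCA, 999 permutations for PerMANOVA, 1000 Raup-Crick
#' replicates with the `|beta_RC| > 0.95` rule, 10,000 co-occurrence
#' iterations, SparCC with 10 inference iterations and 1000 permutations,
#' core prevalence > 0.5, compartment presence > 10 reads, and an rpoB floor
#' of 20 reads.
#'
#' @param depth,iterations Subsampling depth and iteration count.
#' @param nmds_k NMDS dimensionality for ordination output.
#' @param pvca_axes NMDS axes used by the PVCA.
#' @param permutations PerMANOVA permutations.
#' @param rc_replicates Raup-Crick null replicates.
#' @param cooccur_iterations Co-occurrence null matrices.
#' @param sparcc_iterations,sparcc_permutations SparCC settings.
#' @param core_prevalence Core-taxon prevalence threshold (strict).
#' @param presence_min_reads Compartment presence threshold (strict).
#' @param beta_rc_cut Significance cut on `|beta_RC|`.
#' @param min_rpob_reads rpoB read floor for the replicon stage.
#' @param min_total_otu Rare-OTU dataset-wide total filter.
#' @param nmds_restarts Random starts per ordination.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(depth = 1500, iterations = 1000, nmds_k = 3,
                            pvca_axes = 10, permutations = 999,
                            rc_replicates = 1000, cooccur_iterations = 10000,
                            sparcc_iterations = 10, sparcc_permutations = 1000,
                            core_prevalence = 0.5, presence_min_reads = 10,
                            beta_rc_cut = 0.95, min_rpob_reads = 20,
                            min_total_otu = 10, nmds_restarts = 16,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config, extra = NULL) {
  rlang::hash(list(unclass(config), extra))
}

write_tsv_out <- function(df, path) {
  df <- dplyr::select(as_tibble(df), !dplyr::where(is.list))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full compartment-microbiome analysis pipeline
#'
#' Executes, in order: rare-OTU filtering; iterative alpha diversity with
#' transforms and factorial ANOVA; iterative Bray-Curtis, NMDS, PVCA;
#' per-compartment PerMANOVAs; paired effect sizes; core nodule taxa and
#' compartment presence sets; Raup-Crick for root-nodule and
#' rhizosphere-nodule pairs with the Fisher comparison; nodule co-occurrence
#' (with and without OTU1); SparCC on the filtered nodule table; and, when a
#' replicon table is given, plasmid:chromosome ratios with the
#' root-vs-nodule rank test. Every stage writes a TSV under `out_dir` and a
#' `manifest.json` records parameters, derived per-stage seeds, and excluded
#' samples. Rerunning with an unchanged config and existing outputs skips
#' recomputation (config-hash check); stages can be skipped by name.
#'
#' @param x An [otu_table()] with design metadata.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param replicon_data Optional tidy replicon count table (see
#'   [replicon_ratio()]).
#' @param stages Stage names to run (`NULL` = all applicable; the replicon
#'   stage is included only when `replicon_data` is given). Requesting
#'   `"replicon"` explicitly without `replicon_data` is a pre-flight error.
#'   Stages: `alpha`, `beta`, `pvca`, `permanova`, `effectsize`, `core`,
#'   `presence`, `raupcrick`, `cooccur`, `sparcc`, `replicon`.
#' @param skip Stage names to skip.
#' @return Named list of stage results (invisibly also written to
#'   `out_dir`).
#' @export
run_pipeline <- function(x, out_dir, config = pipeline_config(),
                         replicon_data = NULL, stages = NULL,
                         skip = character()) {
  stopifnot(inherits(x, "otu_table"), inherits(config, "pipeline_config"))
  all_stages <- c("alpha", "beta", "pvca", "permanova", "effectsize", "core",
                  "presence", "raupcrick", "cooccur", "sparcc", "replicon")
  unknown <- setdiff(c(skip, stages), all_stages)
  if (length(unknown)) abort(paste0("unknown stage(s): ",
                                    paste(unknown, collapse = ", ")))
  if (!is.null(stages)) {
    if ("replicon" %in% stages && is.null(replicon_data)) {
      abort("stage 'replicon' requested but `replicon_data` is missing.")
    }
    skip <- union(skip, setdiff(all_stages, stages))
  }
  if (is.null(replicon_data) && !"replicon" %in% skip) {
    skip <- c(skip, "replicon")
  }
  stages <- all_stages
  if (anyNA(x$metadata$compartment)) {
    abort("design metadata is required for the pipeline.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config, extra = list(dim(x), sum(x$counts)))
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list()
  fresh <- !identical(manifest$config_hash, hash)
  if (fresh) {
    manifest <- list(config_hash = hash, master_seed = config$seed,
                     parameters = unclass(config),
                     package_version = as.character(utils::packageVersion("medicomb")),
                     stage_seeds = list(), completed = character())
  }
  results <- list()
  seeds <- lapply(stats::setNames(stages, stages),
                  function(st) derive_seed(config$seed, st))
  manifest$stage_seeds <- seeds

  done <- function(stage) !fresh && stage %in% manifest$completed &&
    file.exists(file.path(out_dir, paste0(stage, ".tsv")))
  mark <- function(stage) {
    manifest$completed <<- union(manifest$completed, stage)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  run_stage <- function(stage, fn) {
    if (stage %in% skip) return(invisible(NULL))
    if (done(stage)) {
      results[[stage]] <<- "cached"
      return(invisible(NULL))
    }
    results[[stage]] <<- fn()
    mark(stage)
  }

  x <- filter_rare_otus(x, config$min_total_otu)
  meta <- x$metadata
  bc <- NULL

  run_stage("alpha", function() {
    alpha <- iterative_alpha(x, depth = config$depth,
                             iterations = config$iterations,
                             seed = seeds$alpha)
    lam <- default_richness_lambdas()
    alpha <- alpha %>%
      dplyr::group_by(.data$compartment) %>%
      dplyr::mutate(
        richness_boxcox = transform_response(
          .data$s_obs, "box-cox",
          lambda = lam[[dplyr::cur_group()$compartment]]),
        diversity_logit = transform_response(.data$simpson_complement, "logit",
                                             eps = 1 / (2 * config$depth)),
        evenness_logit = transform_response(.data$simpson_evenness, "logit",
                                            eps = 1 / (2 * config$depth))
      ) %>% dplyr::ungroup()
    anovas <- purrr::map_dfr(
      c(diversity = "diversity_logit", evenness = "evenness_logit",
        richness = "richness_boxcox"),
      function(resp) {
        factorial_anova(alpha, stats::as.formula(
          paste(resp, "~ soil * genotype * compartment"))) %>%
          dplyr::mutate(response = resp, .before = 1)
      })
    write_tsv_out(alpha, file.path(out_dir, "alpha.tsv"))
    write_tsv_out(anovas, file.path(out_dir, "alpha_anova.tsv"))
    list(alpha = alpha, anova = anovas)
  })

  need_bc <- !all(c("beta", "pvca", "permanova") %in% skip)
  if (need_bc) {
    bc <- iterative_bray_curtis(x, depth = config$depth,
                                iterations = config$iterations,
                                seed = seeds$beta)
  }

  run_stage("beta", function() {
    ord <- nmds(bc, k = config$nmds_k, restarts = config$nmds_restarts,
                seed = seeds$beta)
    write_dissimilarity(bc, file.path(out_dir, "bray_curtis.tsv"))
    write_tsv_out(ord$coordinates, file.path(out_dir, "beta.tsv"))
    list(dissimilarity = bc, ordination = ord)
  })

  run_stage("pvca", function() {
    fit <- pvca(bc, meta, n_axes = min(config$pvca_axes, nrow(as.matrix(bc)) - 1),
                seed = seeds$pvca, restarts = config$nmds_restarts)
    write_tsv_out(fit$components, file.path(out_dir, "pvca.tsv"))
    fit
  })

  run_stage("permanova", function() {
    res <- permanova_by_compartment(bc, meta,
                                    permutations = config$permutations,
                                    seed = seeds$permanova)
    write_tsv_out(res, file.path(out_dir, "permanova.tsv"))
    res
  })

  run_stage("effectsize", function() {
    pairs <- list(c("nodule", "root"), c("rhizosphere", "root"),
                  c("root", "leaf"))
    es <- purrr::map_dfr(pairs, function(p) paired_effect_size(x, p))
    write_tsv_out(es, file.path(out_dir, "effectsize.tsv"))
    es
  })

  run_stage("core", function() {
    core <- core_taxa(x, "nodule", config$core_prevalence)
    write_tsv_out(core, file.path(out_dir, "core.tsv"))
    core
  })

  run_stage("presence", function() {
    sets <- compartment_presence_sets(x, config$presence_min_reads)
    write_tsv_out(sets$regions, file.path(out_dir, "presence.tsv"))
    sets
  })

  run_stage("raupcrick", function() {
    rn <- raup_crick(x, compartments = c("root", "nodule"),
                     replicates = config$rc_replicates, seed = seeds$raupcrick)
    sn <- raup_crick(x, compartments = c("rhizosphere", "nodule"),
                     replicates = config$rc_replicates,
                     seed = derive_seed(seeds$raupcrick, "rhizo"))
    rates <- deterministic_assembly_rates(rn, sn)
    out <- dplyr::bind_rows(
      dplyr::mutate(rn, pairing = "root-nodule", .before = 1),
      dplyr::mutate(sn, pairing = "rhizosphere-nodule", .before = 1)
    )
    write_tsv_out(out, file.path(out_dir, "raupcrick.tsv"))
    write_tsv_out(rates, file.path(out_dir, "raupcrick_rates.tsv"))
    list(pairs = out, rates = rates)
  })

  run_stage("cooccur", function() {
    # restrict to prevalent nodule OTUs: the COMBO null has no spread when
    # hundreds of rare OTUs make every null column vector unique
    nod_samples <- meta$sample_id[meta$compartment == "nodule"]
    prev <- rowMeans(x$counts[, nod_samples, drop = FALSE] >= 1)
    nod <- subset_table(x, samples = nod_samples,
                        otus = which(prev >= 0.25))
    otu1 <- rownames(x$counts)[which.max(rowSums(x$counts))]
    run_one <- function(excl, seed) {
      tryCatch(
        cooccurrence_ses(nod, "sim6", iterations = config$cooccur_iterations,
                         exclude_otus = excl, seed = seed),
        error = function(e) {
          warn(paste0("co-occurrence test not evaluable: ",
                      conditionMessage(e)))
          tibble(metric = "combo", algorithm = "sim6", observed = NA_integer_,
                 null_mean = NA_real_, null_sd = NA_real_,
                 z_score = NA_real_, p_value = NA_real_,
                 iterations = as.integer(config$cooccur_iterations))
        })
    }
    res <- dplyr::bind_rows(
      dplyr::mutate(run_one(NULL, seeds$cooccur), set = "nodule",
                    .before = 1),
      dplyr::mutate(run_one(otu1, derive_seed(seeds$cooccur, "nootu1")),
                    set = "nodule_excl_otu1", .before = 1)
    )
    write_tsv_out(res, file.path(out_dir, "cooccur.tsv"))
    res
  })

  run_stage("sparcc", function() {
    nod <- subset_table(
      x, samples = meta$sample_id[meta$compartment == "nodule"])
    filtered <- sparcc_filter(nod$counts)
    fit <- sparcc_correlations(filtered,
                               inference_iterations = config$sparcc_iterations,
                               seed = seeds$sparcc)
    fit <- sparcc_pvalues(filtered, fit,
                          permutations = config$sparcc_permutations,
                          seed = derive_seed(seeds$sparcc, "perm"))
    edges <- tidy(fit)
    write_tsv_out(edges, file.path(out_dir, "sparcc.tsv"))
    fit
  })

  run_stage("replicon", function() {
    ratios <- replicon_ratio(replicon_data,
                             min_rpob_reads = config$min_rpob_reads)
    test <- compare_replicon_ratios(ratios)
    write_tsv_out(ratios, file.path(out_dir, "replicon.tsv"))
    write_tsv_out(test, file.path(out_dir, "replicon_test.tsv"))
    list(ratios = ratios, test = test)
  })

  invisible(results)
}
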