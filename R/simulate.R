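#' Configuration for the synthetic common-garden experiment
#'
#' The generator emulates a paired two-soil x three-genotype common-garden
#' design with up to five replicate plants per soil x genotype cell and four
#' compartments per plant (rhizosphere, root endosphere, nodule, leaf),
#' dominated in every compartment by a single symbiont-like taxon (OTU1,
#' the Ensifer analogue). Structure built in:
#' a diversity gradient rhizosphere > root/leaf > nodule (via per-compartment
#' Dirichlet concentrations and OTU1 dominance targets), soil effects
#' confined to the rhizosphere, genotype effects confined to the root
#' endosphere, and (optionally) nodule communities subsampled from the same
#' plant's realized root community (deterministic nested colonization).
#'
#' @param n_otus Number of OTUs in the regional pool.
#' @param n_replicates Replicate plants per soil x genotype cell (max 5,
#'   replicate codes `a`-`e`).
#' @param depth_log_mean,depth_log_sd Sequencing depth is drawn per sample
#'   from a lognormal with these log-scale parameters.
#' @param dominance Named vector of target OTU1 relative abundances per
#'   compartment, each in (0, 1).
#' @param concentration Named vector of Dirichlet concentration scalars per
#'   compartment; smaller values give noisier, lower-diversity draws.
#' @param sigma_soil SD of per-OTU soil log-fold effects (rhizosphere only).
#' @param sigma_geno SD of per-OTU genotype log-fold effects (root only).
#' @param sigma_base SD of the lognormal rank-abundance base profile.
#' @param nodule_from_root If `TRUE`, a plant's nodule community is derived
#'   from its realized root community (nested colonization); if `FALSE`,
#'   nodules are drawn independently from the base profile.
#' @param seed Integer seed; identical config + seed gives identical tables.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_otus = 300,
                              n_replicates = 5,
                              depth_log_mean = log(20000),
                              depth_log_sd = 0.3,
                              dominance = c(rhizosphere = 0.10, root = 0.30,
                                            leaf = 0.40, nodule = 0.85),
                              concentration = c(rhizosphere = 150, root = 40,
                                                leaf = 40, nodule = 12),
                              sigma_soil = 1.0,
                              sigma_geno = 0.5,
                              sigma_base = 1.5,
                              nodule_from_root = TRUE,
                              seed = 1L) {
  comps <- c("rhizosphere", "root", "leaf", "nodule")
  dominance <- dominance[comps]
  concentration <- concentration[comps]
  if (anyNA(dominance) || any(dominance <= 0) || any(dominance >= 1)) {
    abort("`dominance` must name all four compartments with values in (0, 1).")
  }
  if (anyNA(concentration) || any(concentration <= 0)) {
    abort("`concentration` must name all four compartments with values > 0.")
  }
  if (sigma_soil < 0 || sigma_geno < 0 || sigma_base < 0) {
    abort("effect SDs must be >= 0.")
  }
  if (n_otus < 2) abort("`n_otus` must be >= 2.")
  if (n_replicates < 1 || n_replicates > 5) {
    abort("`n_replicates` must be in 1..5 (replicate codes a-e).")
  }
  structure(
    list(n_otus = as.integer(n_otus), n_replicates = as.integer(n_replicates),
         depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
         dominance = dominance, concentration = concentration,
         sigma_soil = sigma_soil, sigma_geno = sigma_geno,
         sigma_base = sigma_base,
         nodule_from_root = isTRUE(nodule_from_root),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# Force OTU1 to the target proportion, scaling the remaining mass.
force_dominance <- function(p, target) {
  rest <- p[-1]
  rest <- if (sum(rest) > 0) rest / sum(rest) else
    rep(1 / length(rest), length(rest))
  c(target, (1 - target) * rest)
}

#' Generate a synthetic compartment-structured OTU table
#'
#' Recipe: (1) draw a lognormal rank-abundance base profile; (2) rhizosphere
#' expected proportions = base x soil-specific per-OTU log-fold multipliers;
#' (3) root expected proportions = base x genotype-specific multipliers with
#' OTU1 forced to the root dominance target; (4) nodule expectations derive
#' from the plant's realized root counts with OTU1 raised to the nodule
#' target (when `nodule_from_root`), else from the base profile; (5) leaf
#' expectations are the base profile with the leaf dominance target; (6) each
#' sample draws proportions ~ Dirichlet(concentration x expected), then
#' counts ~ Multinomial(depth) with depth lognormal.
#'
#' @param config A [simulation_config()].
#' @return An [otu_table()] with 2 soils x 3 genotypes x `n_replicates`
#'   plants x 4 compartments; sample names follow the design code parsed by
#'   [parse_sample_name()].
#' @export
generate_experiment <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be a simulation_config().")
  }
  cfg <- config
  soils <- c("C", "F")
  genos <- c("1", "27", "96")
  reps <- letters[seq_len(cfg$n_replicates)]
  comp_code <- c(rhizosphere = "S", root = "R", nodule = "N", leaf = "L")

  with_seed(cfg$seed, {
    n <- cfg$n_otus
    base <- sort(stats::rlnorm(n, 0, cfg$sigma_base), decreasing = TRUE)
    base <- base / sum(base)
    soil_eff <- lapply(stats::setNames(soils, soils),
                       function(s) exp(stats::rnorm(n, 0, cfg$sigma_soil)))
    geno_eff <- lapply(stats::setNames(genos, genos),
                       function(g) exp(stats::rnorm(n, 0, cfg$sigma_geno)))

    cols <- list()
    for (s in soils) for (g in genos) for (r in reps) {
      plant <- paste0(s, g, r)
      rhizo_exp <- force_dominance(base * soil_eff[[s]] / sum(base * soil_eff[[s]]),
                                   cfg$dominance[["rhizosphere"]])
      root_exp <- force_dominance(base * geno_eff[[g]] / sum(base * geno_eff[[g]]),
                                  cfg$dominance[["root"]])
      leaf_exp <- force_dominance(base, cfg$dominance[["leaf"]])

      draw_sample <- function(expected, comp) {
        p <- rdirichlet1(cfg$concentration[[comp]] * expected)
        depth <- max(2L, round(stats::rlnorm(1, cfg$depth_log_mean,
                                             cfg$depth_log_sd)))
        as.integer(stats::rmultinom(1, depth, p))
      }

      rhizo <- draw_sample(rhizo_exp, "rhizosphere")
      root <- draw_sample(root_exp, "root")
      leaf <- draw_sample(leaf_exp, "leaf")
      nod_exp <- if (cfg$nodule_from_root) {
        force_dominance(root / sum(root), cfg$dominance[["nodule"]])
      } else {
        force_dominance(base, cfg$dominance[["nodule"]])
      }
      nodule <- draw_sample(nod_exp, "nodule")

      cols[[paste0(plant, "S")]] <- rhizo
      cols[[paste0(plant, "R")]] <- root
      cols[[paste0(plant, "N")]] <- nodule
      cols[[paste0(plant, "L")]] <- leaf
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- paste0("Otu", sprintf("%04d", seq_len(n)))
    otu_table(counts)
  })
}

#' Generate synthetic per-replicon read-count tables
#'
#' Emulates shotgun read counts mapped per replicon (chromosome plus
#' plasmids) of a dominant symbiont, where only a fraction of cells carry
#' each plasmid: the expected plasmid:chromosome reads-per-megabase ratio in
#' a sample equals that sample's compartment `fraction_with_plasmid`. An
#' rpoB read count (single-copy chromosomal marker, ~4 kb of the chromosome)
#' is included for the low-signal sample filter.
#'
#' @param n_samples Samples per compartment.
#' @param fraction_with_plasmid Named list/vector: per compartment, either a
#'   single fraction applied to all plasmids or a named vector per plasmid.
#' @param depth Expected total chromosome-mapped reads per sample; the
#'   default keeps the rpoB marker (~4 kb) comfortably above the 20-read
#'   exclusion floor for all but genuinely shallow samples.
#' @param replicon_lengths Named vector of replicon lengths in bases; must
#'   include `chromosome`.
#' @param seed Integer seed.
#' @return A tibble with columns `sample_id`, `compartment`, `replicon`,
#'   `length_bp`, `reads`, `rpob_reads`.
#' @export
generate_replicon_counts <- function(n_samples = 15,
                                     fraction_with_plasmid = list(
                                       root = c(pSymA = 0.45, pSymB = 0.9),
                                       nodule = c(pSymA = 0.95, pSymB = 0.95)),
                                     depth = 40000,
                                     replicon_lengths = c(chromosome = 3781904,
                                                          pSymA = 1354226,
                                                          pSymB = 1683301),
                                     seed = 1L) {
  if (!"chromosome" %in% names(replicon_lengths)) {
    abort("`replicon_lengths` must include 'chromosome'.")
  }
  if (any(replicon_lengths <= 0)) abort("replicon lengths must be > 0.")
  plasmids <- setdiff(names(replicon_lengths), "chromosome")
  rpob_len <- 4000
  with_seed(seed, {
    rows <- list()
    for (comp in names(fraction_with_plasmid)) {
      frac <- fraction_with_plasmid[[comp]]
      if (length(frac) == 1 && is.null(names(frac))) {
        frac <- stats::setNames(rep(frac, length(plasmids)), plasmids)
      }
      if (any(frac < 0 | frac > 1)) abort("fractions must be in [0, 1].")
      for (i in seq_len(n_samples)) {
        sid <- sprintf("%s_%02d", comp, i)
        # per-Mb chromosome rate, with sample-level depth noise
        rate_mb <- depth / (replicon_lengths[["chromosome"]] / 1e6) *
          stats::rlnorm(1, 0, 0.2)
        chr_reads <- stats::rpois(1, rate_mb * replicon_lengths[["chromosome"]] / 1e6)
        rpob <- stats::rpois(1, rate_mb * rpob_len / 1e6)
        reads <- c(chromosome = chr_reads)
        for (p in plasmids) {
          lam <- rate_mb * frac[[p]] * replicon_lengths[[p]] / 1e6
          reads[p] <- stats::rpois(1, lam)
        }
        rows[[sid]] <- tibble(
          sample_id = sid, compartment = comp,
          replicon = names(replicon_lengths),
          length_bp = unname(replicon_lengths),
          reads = unname(reads[names(replicon_lengths)]),
          rpob_reads = rpob
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
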