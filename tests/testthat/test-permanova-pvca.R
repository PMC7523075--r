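two_group_toy <- function() {
  # 2 groups of 2: within-pair distance 0.1, between 0.9
  m <- matrix(0.9, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.1
  m[3, 4] <- m[4, 3] <- 0.1
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:4), paste0("s", 1:4))
  dissimilarity_matrix(m)
}

test_that("pseudo-F matches Anderson's formulas on a hand example", {
  d <- two_group_toy()
  res <- permanova(d, c("a", "a", "b", "b"), permutations = 99, seed = 1)
  expect_equal(res$pseudo_F, 161)
  expect_equal(res$df_num, 1L)
  expect_equal(res$df_den, 2L)
})

test_that("exhaustive p equals enumeration over distinct partitions", {
  d <- two_group_toy()
  res <- permanova(d, c("a", "a", "b", "b"), exhaustive = TRUE)
  expect_equal(res$p_value, 1 / 3)
})

test_that("pseudo-F agrees with vegan::adonis2 on random data", {
  set.seed(3)
  x <- matrix(rpois(8 * 20, 12), nrow = 20)
  d <- as.matrix(vegan::vegdist(t(x), "bray"))
  dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  g <- rep(c("u", "v"), each = 4)
  ours <- permanova(dissimilarity_matrix(d), g, permutations = 199, seed = 2)
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 199)
  expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$p_value, ref$`Pr(>F)`[1], tolerance = 0.12)
})

test_that("null p-values are roughly uniform", {
  set.seed(11)
  ps <- replicate(40, {
    x <- matrix(rpois(8 * 15, 10), nrow = 15)
    d <- as.matrix(vegan::vegdist(t(x), "bray"))
    dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
    permanova(dissimilarity_matrix(d), sample(rep(c("u", "v"), each = 4)),
              permutations = 59)$p_value
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.75)
})

test_that("per-compartment PerMANOVA recovers the planted design", {
  t <- generate_experiment(simulation_config(n_otus = 60, n_replicates = 4,
                                             depth_log_mean = log(2500),
                                             seed = 13))
  bc <- suppressWarnings(iterative_bray_curtis(t, depth = 800, iterations = 3,
                                               seed = 1))
  res <- permanova_by_compartment(bc, sample_metadata(t), permutations = 199,
                                  seed = 5)
  rh_soil <- res$p_value[res$compartment == "rhizosphere" & res$factor == "soil"]
  rt_geno <- res$p_value[res$compartment == "root" & res$factor == "genotype"]
  nd_soil <- res$p_value[res$compartment == "nodule" & res$factor == "soil"]
  expect_lt(rh_soil, 0.05)
  expect_lt(rt_geno, 0.05)
  expect_gt(nd_soil, 0.05)
})

test_that("axis-score tests flag separated groups and reject degenerate input", {
  ord <- structure(list(
    coordinates = tibble::tibble(sample_id = paste0("s", 1:12),
                                 axis1 = rnorm(12),
                                 axis2 = c(rnorm(6), rnorm(6, 50))),
    k = 2, stress = 0.05), class = "mb_ordination")
  g <- rep(c("u", "v"), each = 6)
  res <- axis_score_test(ord, 2, g)
  expect_lt(res$p.value[1], 0.001)
  expect_error(axis_score_test(ord, 3, g), "exceeds")
  expect_error(axis_score_test(ord, 1, rep("u", 12)), ">= 2")
})

test_that("PVCA percentages sum to 100 and recover an injected factor", {
  set.seed(42)
  meta <- design_metadata(n_replicates = 3)
  comp_means <- c(leaf = -2, nodule = 4, rhizosphere = 0, root = -1)
  scores <- cbind(comp_means[meta$compartment] + rnorm(nrow(meta), 0, 0.05),
                  rnorm(nrow(meta)), rnorm(nrow(meta)))
  fit <- pvca_from_scores(scores, meta, weights = c(0.9, 0.05, 0.05))
  comp <- fit$components
  expect_equal(sum(comp$percent), 100, tolerance = 1e-6)
  expect_true(all(comp$percent >= 0))
  expect_gt(comp$percent[comp$term == "compartment"], 60)
  expect_equal(comp$term[which.max(comp$percent)], "compartment")
})

test_that("pure-noise axes put nearly all variance in the residual", {
  meta <- design_metadata(n_replicates = 3)
  set.seed(7)
  res_pc <- replicate(25, {
    scores <- matrix(rnorm(nrow(meta) * 3), ncol = 3)
    fit <- pvca_from_scores(scores, meta)
    fit$components$percent[fit$components$term == "residual"]
  })
  expect_gt(mean(res_pc), 88)
})

test_that("PVCA on synthetic data ranks soil x compartment above genotype x compartment", {
  t <- generate_experiment(simulation_config(n_otus = 80, n_replicates = 4,
                                             depth_log_mean = log(2500),
                                             seed = 19))
  bc <- suppressWarnings(iterative_bray_curtis(t, depth = 800, iterations = 3,
                                               seed = 2))
  fit <- pvca(bc, sample_metadata(t), n_axes = 6, seed = 3, restarts = 6)
  comp <- fit$components
  expect_equal(sum(comp$percent), 100, tolerance = 1e-6)
  expect_gt(comp$percent[comp$term == "soil:compartment"],
            comp$percent[comp$term == "genotype:compartment"])
})
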