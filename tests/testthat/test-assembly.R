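test_that("beta_RC stays in [-1, 1] and classifies by the 0.95 rule", {
  t <- generate_experiment(simulation_config(n_otus = 40, n_replicates = 2,
                                             depth_log_mean = log(1500),
                                             seed = 3))
  res <- raup_crick(t, compartments = c("root", "nodule"), replicates = 100,
                    seed = 1)
  expect_true(all(res$beta_rc >= -1 & res$beta_rc <= 1))
  expect_identical(res$significant, abs(res$beta_rc) > 0.95)
  expect_true(all(res$direction[res$significant & res$beta_rc < 0] ==
                    "more_similar"))
  expect_identical(
    res$beta_rc,
    raup_crick(t, compartments = c("root", "nodule"), replicates = 100,
               seed = 1)$beta_rc)
})

test_that("Monte-Carlo beta_RC matches exhaustive enumeration on small pools", {
  # 5-species pool over 4 samples with uneven occurrence frequencies
  counts <- rbind(
    Otu1 = c(1, 1, 1, 1),
    Otu2 = c(1, 1, 0, 0),
    Otu3 = c(0, 1, 1, 0),
    Otu4 = c(1, 0, 0, 0),
    Otu5 = c(0, 0, 1, 1)
  )
  colnames(counts) <- paste0("s", 1:4)
  t <- otu_table(counts, metadata = tibble::tibble(
    sample_id = colnames(counts), soil = "X", genotype = "Y",
    replicate = letters[1:4], compartment = "nodule"))
  pa <- counts >= 1
  freq <- rowSums(pa)
  pairs <- tibble::tibble(sample_a = c("s1", "s2"), sample_b = c("s2", "s3"))
  mc <- raup_crick(t, pairs = pairs, replicates = 40000, seed = 9,
                   pool = "all")
  for (i in 1:2) {
    exact <- oracle_beta_rc(pa, pairs$sample_a[i], pairs$sample_b[i], freq)
    expect_lt(abs(mc$beta_rc[i] - exact), 0.02)
  }
})

test_that("assembly-rate comparison reproduces the Fisher contingency logic", {
  mk <- function(n_sig, n_tot) {
    tibble::tibble(significant = c(rep(TRUE, n_sig),
                                   rep(FALSE, n_tot - n_sig)))
  }
  res <- deterministic_assembly_rates(mk(21, 30), mk(8, 30))
  expect_equal(res$rate_a, 0.7)
  expect_equal(res$rate_b, 8 / 30, tolerance = 1e-12)
  expect_equal(res$fisher_p, 0.0017, tolerance = 0.05)
  expect_equal(res$fisher_p, oracle_fisher(matrix(c(21, 9, 8, 22), 2,
                                                  byrow = TRUE)),
               tolerance = 1e-9)
  expect_equal(deterministic_assembly_rates(mk(5, 10), mk(5, 10))$fisher_p, 1)
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(1, 2, 2)), 1)
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2)), 1 / 3, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 2), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab), oracle_fisher(tab), tolerance = 1e-9)
  }
  tab <- matrix(c(3, 1, 2, 5), 2)
  expect_equal(fisher_exact(tab), fisher_exact(t(tab)))
  expect_equal(fisher_exact(tab), fisher_exact(tab[2:1, ]))
  expect_equal(fisher_exact(tab), fisher_exact(tab[, 2:1]))
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "negative")
})

test_that("COMBO counts distinct presence combinations", {
  expect_equal(combo_metric(matrix(1, 3, 4)), 1)
  m <- cbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(combo_metric(m), 2)
  m2 <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(combo_metric(m2), 3)
})

test_that("null generators preserve their stated constraints", {
  set.seed(2)
  pa <- matrix(runif(60) < 0.4, 6, 10)
  pa[1, ] <- TRUE # keep all rows/cols non-degenerate
  pa[, 1] <- TRUE
  for (alg in c("sim6", "sim2", "sim4")) {
    gen <- medicomb:::make_null_generator(pa, alg)
    for (r in 1:20) {
      nm <- gen()
      expect_equal(sum(nm), sum(pa))
      if (alg %in% c("sim2", "sim4")) {
        expect_equal(rowSums(nm), rowSums(pa))
      }
    }
  }
})

test_that("co-occurrence SES is calibrated on its own null and detects structure", {
  # few species over many sites, so the null COMBO distribution has spread
  set.seed(6)
  pa <- matrix(runif(4 * 25) < 0.4, 4, 25)
  pa[1, colSums(pa) == 0] <- TRUE
  gen <- medicomb:::make_null_generator(pa, "sim6")
  zs <- vapply(1:10, function(i) {
    obs <- gen() * 1L
    obs[1, colSums(obs) == 0] <- 1L
    rownames(obs) <- paste0("Otu", 1:nrow(obs))
    colnames(obs) <- paste0("s", 1:ncol(obs))
    cooccurrence_ses(obs, "sim6", iterations = 400, seed = i)$z_score
  }, 0)
  expect_gte(sum(abs(zs) < 2), 8)

  # two repeated site patterns -> minimal COMBO, strongly negative Z
  seg <- matrix(0L, 5, 25)
  seg[1:2, 1:13] <- 1L
  seg[3:4, 14:25] <- 1L
  dimnames(seg) <- list(paste0("Otu", 1:5), paste0("s", 1:25))
  res <- cooccurrence_ses(seg, "sim6", iterations = 400, seed = 3)
  expect_equal(res$observed, 2)
  expect_lt(res$z_score, -2)

  # fully constrained toy: sim2 with all-full matrix has sd 0
  full <- matrix(1L, 2, 3)
  dimnames(full) <- list(c("Otu1", "Otu2"), c("a", "b", "c"))
  expect_error(cooccurrence_ses(full, "sim2", iterations = 50, seed = 1),
               "degenerate")
})

test_that("excluding the dominant OTU changes the tested matrix", {
  set.seed(9)
  m <- matrix(as.integer(runif(5 * 20) < 0.4), 5, 20)
  m[1, ] <- 1L # dominant OTU present everywhere
  m[2, colSums(m[-1, , drop = FALSE]) == 0] <- 1L
  dimnames(m) <- list(paste0("Otu", 1:5), paste0("s", 1:20))
  with_1 <- cooccurrence_ses(m, "sim6", iterations = 300, seed = 2)
  without <- cooccurrence_ses(m, "sim6", iterations = 300,
                              exclude_otus = "Otu1", seed = 2)
  expect_false(identical(with_1$observed, without$observed) &&
                 identical(with_1$null_mean, without$null_mean))
})
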