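test_that("exhaustive draws reproduce hand-computed Simpson quantities", {
  counts <- cbind(C1aS = c(900, 450, 150), C1aR = c(1500, 0, 0))
  rownames(counts) <- paste0("Otu", 1:3)
  t <- otu_table(counts)
  a <- iterative_alpha(t, depth = 1500, iterations = 5, seed = 1)
  r1 <- a[a$sample_id == "C1aS", ]
  # D = (900*899 + 450*449 + 150*149) / (1500*1499) = 1033500/2248500
  expect_equal(r1$s_obs, 3)
  expect_equal(r1$simpson_complement, 1 - 1033500 / 2248500, tolerance = 1e-12)
  expect_equal(r1$simpson_evenness, (2248500 / 1033500) / 3, tolerance = 1e-12)
  r2 <- a[a$sample_id == "C1aR", ]
  expect_equal(r2$s_obs, 1)
  expect_equal(r2$simpson_complement, 0)
})

test_that("samples below depth are excluded with a warning", {
  counts <- cbind(C1aS = c(900, 700), C1aR = c(10, 5))
  rownames(counts) <- c("Otu1", "Otu2")
  expect_warning(a <- iterative_alpha(otu_table(counts), depth = 1000,
                                      iterations = 3, seed = 1), "C1aR")
  expect_equal(a$sample_id, "C1aS")
  expect_error(iterative_alpha(otu_table(counts), depth = 1), "depth")
})

test_that("alpha estimates are stable in the iteration count", {
  t <- generate_experiment(simulation_config(n_otus = 40, n_replicates = 1,
                                             depth_log_mean = log(3000),
                                             seed = 7))
  a1 <- suppressWarnings(iterative_alpha(t, depth = 1000, iterations = 40,
                                         seed = 1))
  a2 <- suppressWarnings(iterative_alpha(t, depth = 1000, iterations = 80,
                                         seed = 2))
  expect_equal(a1$simpson_complement, a2$simpson_complement, tolerance = 0.02)
  expect_equal(a1$s_obs, a2$s_obs, tolerance = 0.05)
})

test_that("logit and Box-Cox transforms match their closed forms", {
  expect_equal(transform_response(0.5, "logit"), 0)
  expect_equal(transform_response(c(0.25, 0.75), "logit"),
               c(log(1 / 3), log(3)))
  expect_equal(transform_response(9, "box-cox", lambda = 1), 8)
  expect_equal(transform_response(exp(2), "box-cox", lambda = 0), 2)
  expect_equal(transform_response(4, "box-cox", lambda = 1.6),
               (4^1.6 - 1) / 1.6)
  expect_error(transform_response(1.2, "logit"), "outside")
  expect_error(transform_response(-1, "box-cox", lambda = 0.5), "> 0")
  expect_warning(out <- transform_response(c(0, 0.5), "logit", eps = 1e-3),
                 "clamping")
  expect_equal(out[1], log(1e-3 / (1 - 1e-3)))
})

test_that("profile-likelihood lambda recovers a known transform scale", {
  set.seed(42)
  y <- rnorm(400, 10, 1)
  x <- exp(y) # log-normal: lambda ~ 0
  expect_lt(abs(estimate_box_cox_lambda(x)), 0.15)
})

test_that("balanced 2x2 ANOVA matches hand-computed sums of squares", {
  df <- data.frame(
    a = rep(c("a1", "a1", "a2", "a2"), each = 2),
    b = rep(c("b1", "b2", "b1", "b2"), each = 2),
    y = c(1, 3, 2, 4, 5, 7, 6, 8)
  )
  res <- factorial_anova(df, y ~ a * b)
  expect_equal(res$statistic[res$term == "a"], 16)
  expect_equal(res$statistic[res$term == "b"], 1)
  expect_equal(res$statistic[res$term == "a:b"], 0)
  expect_equal(res$meansq[res$term == "Residuals"], 2)
  # SS decomposition
  expect_equal(sum(res$sumsq), sum((df$y - mean(df$y))^2), tolerance = 1e-8)
})

test_that("unbalanced ANOVA matches explicit sequential projections", {
  set.seed(5)
  df <- data.frame(
    a = factor(c("a1", "a1", "a1", "a2", "a2")),
    b = factor(c("b1", "b2", "b2", "b1", "b2")),
    y = rnorm(5)
  )
  expect_warning(res <- factorial_anova(df, y ~ a + b), "unbalanced")
  # oracle: sequential least-squares projections
  x0 <- model.matrix(~1, df)
  x1 <- model.matrix(~a, df)
  x2 <- model.matrix(~a + b, df)
  proj <- function(x) x %*% solve(crossprod(x), t(x))
  ss_a <- sum(((proj(x1) - proj(x0)) %*% df$y)^2)
  ss_b <- sum(((proj(x2) - proj(x1)) %*% df$y)^2)
  expect_equal(res$sumsq[res$term == "a"], ss_a, tolerance = 1e-10)
  expect_equal(res$sumsq[res$term == "b"], ss_b, tolerance = 1e-10)
})

test_that("degenerate ANOVA inputs error", {
  df <- data.frame(a = c("x", "x", "y", "y"), y = rep(1, 4))
  expect_error(factorial_anova(df, y ~ a), "constant")
  df2 <- data.frame(a = c("x", "y"), y = c(1, 2))
  expect_error(factorial_anova(df2, y ~ a), "residual")
})

test_that("Tukey HSD q statistic and letters behave as expected", {
  a <- sqrt(3 - 0.75)
  b <- sqrt(0.75)
  offs <- c(-a, -b, b, a) # SSE per group = 2(a^2+b^2) = 6 -> MSE = 12/6 = 2
  df <- data.frame(g = rep(c("g1", "g2"), each = 4),
                   y = c(2.5 + offs, 6.5 + offs))
  res <- tukey_hsd(df, "y", "g")
  expect_equal(res$mse, 2, tolerance = 1e-10)
  expect_equal(res$pairs$q, 4 / sqrt(2 / 4), tolerance = 1e-10)
  expect_equal(res$pairs$p.value,
               ptukey(4 / sqrt(0.5), 2, 6, lower.tail = FALSE))

  # all groups equal -> one shared letter
  set.seed(1)
  df2 <- data.frame(g = rep(c("g1", "g2", "g3"), each = 5),
                    y = rnorm(15, 0, 1))
  res2 <- tukey_hsd(df2, "y", "g")
  expect_true(all(res2$letters$letter == res2$letters$letter[1]))

  # one far-separated group gets its own letter
  df3 <- data.frame(g = rep(c("g1", "g2", "g3"), each = 5),
                    y = c(rnorm(5), rnorm(5), rnorm(5, 100)))
  res3 <- tukey_hsd(df3, "y", "g")
  far <- res3$letters$letter[res3$letters$group == "g3"]
  others <- res3$letters$letter[res3$letters$group != "g3"]
  expect_false(far %in% others)
  expect_error(tukey_hsd(data.frame(g = c("a", "a", "b"), y = 1:3), "y", "g"),
               "n >= 2")
})

test_that("Tukey p-values agree with stats::TukeyHSD", {
  set.seed(9)
  df <- data.frame(g = rep(c("g1", "g2", "g3"), each = 6),
                   y = rnorm(18) + rep(c(0, 0.8, 2), each = 6))
  ours <- tukey_hsd(df, "y", "g")$pairs
  ref <- TukeyHSD(aov(y ~ g, df))$g
  ref_key <- do.call(rbind, strsplit(rownames(ref), "-"))
  for (i in seq_len(nrow(ref))) {
    row <- ours[(ours$group_a == ref_key[i, 2] & ours$group_b == ref_key[i, 1]) |
                  (ours$group_a == ref_key[i, 1] & ours$group_b == ref_key[i, 2]), ]
    expect_equal(row$p.value, ref[i, "p adj"], tolerance = 1e-8)
  }
})

test_that("compartment is the dominant alpha-diversity effect on synthetic data", {
  t <- generate_experiment(simulation_config(n_otus = 60, n_replicates = 3,
                                             depth_log_mean = log(3000),
                                             seed = 17))
  a <- suppressWarnings(iterative_alpha(t, depth = 1000, iterations = 10,
                                        seed = 3))
  a$div_logit <- transform_response(a$simpson_complement, "logit")
  res <- factorial_anova(a, div_logit ~ soil * genotype * compartment)
  p_comp <- res$p.value[res$term == "compartment"]
  expect_lt(p_comp, 0.001)
  expect_equal(res$term[which.max(res$statistic)], "compartment")
})
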