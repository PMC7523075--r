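# Small fixtures and independent brute-force oracles used across the suite.

# A hand-sized table with design-coded sample names (2 plants x 4 compartments).
tiny_design_table <- function() {
  counts <- rbind(
    Otu1 = c(40, 60, 85, 50, 45, 55, 80, 52),
    Otu2 = c(30, 20, 10, 25, 28, 22, 12, 24),
    Otu3 = c(20, 15, 5, 15, 17, 16, 6, 14),
    Otu4 = c(10, 5, 0, 10, 10, 7, 2, 10)
  )
  colnames(counts) <- c("C1aS", "C1aR", "C1aN", "C1aL",
                        "F27bS", "F27bR", "F27bN", "F27bL")
  otu_table(counts)
}

# Exact two-sided Fisher p by hypergeometric enumeration over fixed margins.
oracle_fisher <- function(tab) {
  r <- rowSums(tab); k <- colSums(tab); n <- sum(tab)
  a_range <- max(0, k[1] - r[2]):min(r[1], k[1])
  probs <- vapply(a_range, function(a) {
    stats::dhyper(a, r[1], r[2], k[1])
  }, 0)
  p_obs <- stats::dhyper(tab[1, 1], r[1], r[2], k[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided signed-rank p by enumerating all sign assignments.
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  p <- 2 * min(mean(vs <= v_obs), mean(vs >= v_obs))
  min(1, p)
}

# Exact two-sided rank-sum p by enumerating group assignments.
oracle_rank_sum <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_obs <- sum(rank(pooled)[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, function(idx) {
    sum(rank(pooled)[idx]) - na * (na + 1) / 2
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Independent one-way pseudo-F from a distance matrix (explicit pair loops).
oracle_pseudo_f <- function(m, g) {
  g <- as.character(g)
  n <- nrow(m)
  ss_t <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + m[i, j]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    if (length(idx) > 1) {
      s <- 0
      for (i in idx) for (j in idx) if (i < j) s <- s + m[i, j]^2
      ss_w <- ss_w + s / length(idx)
    }
  }
  a <- length(unique(g))
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# Exact permutation p for a 2-group PerMANOVA by full enumeration.
oracle_permanova_p <- function(m, g) {
  g <- as.character(g)
  f_obs <- oracle_pseudo_f(m, g)
  lev <- unique(g)
  n1 <- sum(g == lev[1])
  combs <- utils::combn(nrow(m), n1)
  fs <- apply(combs, 2, function(idx) {
    gg <- rep(lev[2], nrow(m)); gg[idx] <- lev[1]
    oracle_pseudo_f(m, gg)
  })
  mean(fs >= f_obs - 1e-12)
}

# Probability of drawing a specific species set under sequential
# weighted sampling without replacement (enumerates orderings).
set_draw_prob <- function(set, w) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  total <- sum(w)
  sum(vapply(perms(set), function(ord) {
    rem <- total
    p <- 1
    for (s in ord) {
      p <- p * w[s] / rem
      rem <- rem - w[s]
    }
    p
  }, 0))
}

# Exact beta_RC for a pair by enumerating all richness-preserving draws.
oracle_beta_rc <- function(pa, sample_a, sample_b, freq) {
  pool <- seq_len(nrow(pa))
  ra <- sum(pa[, sample_a]); rb <- sum(pa[, sample_b])
  obs <- sum(pa[, sample_a] & pa[, sample_b])
  sets_a <- utils::combn(pool, ra, simplify = FALSE)
  sets_b <- utils::combn(pool, rb, simplify = FALSE)
  pa_prob <- vapply(sets_a, set_draw_prob, 0, w = freq)
  pb_prob <- vapply(sets_b, set_draw_prob, 0, w = freq)
  p_gt <- 0; p_eq <- 0
  for (i in seq_along(sets_a)) for (j in seq_along(sets_b)) {
    sh <- length(intersect(sets_a[[i]], sets_b[[j]]))
    pr <- pa_prob[i] * pb_prob[j]
    if (sh > obs) p_gt <- p_gt + pr
    if (sh == obs) p_eq <- p_eq + pr
  }
  2 * (p_gt + 0.5 * p_eq) - 1
}

# Exact Monte-Carlo-free chi-square p over fixed-margin 2x2 tables.
oracle_chisq_p <- function(tab) {
  r <- rowSums(tab); k <- colSums(tab)
  e <- outer(r, k) / sum(tab)
  stat <- function(t) sum((t - e)^2 / e)
  obs <- stat(tab)
  a_range <- max(0, k[1] - r[2]):min(r[1], k[1])
  p <- 0
  for (a in a_range) {
    t <- matrix(c(a, k[1] - a, r[1] - a, r[2] - (k[1] - a)), 2)
    if (stat(t) >= obs - 1e-12) p <- p + stats::dhyper(a, r[1], r[2], k[1])
  }
  p
}

# Full-factorial design metadata without generating counts.
design_metadata <- function(n_replicates = 3) {
  grid <- expand.grid(soil = c("C", "F"), genotype = c("1", "27", "96"),
                      replicate = letters[seq_len(n_replicates)],
                      compartment = c("S", "R", "N", "L"),
                      stringsAsFactors = FALSE)
  parse_sample_name(paste0(grid$soil, grid$genotype, grid$replicate,
                           grid$compartment))
}
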