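test_that("spearman_matrix: monotone pairs, oracle agreement, tie handling", {
  x <- c(3, 1, 4, 1.5, 9)
  tab <- cbind(a = x, b = exp(x), c = -x^3)
  sm <- spearman_matrix(tab)
  expect_equal(sm$rho["a", "b"], 1)
  expect_equal(sm$rho["a", "c"], -1)
  expect_equal(diag(sm$rho), c(a = 1, b = 1, c = 1))
  expect_equal(sm$rho, t(sm$rho))

  set.seed(9)
  toy <- matrix(rnorm(5 * 4), 5, 4,
                dimnames = list(NULL, letters[1:4]))
  toy[2, 1] <- toy[1, 1]   # a tie
  sm <- spearman_matrix(toy)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(sm$rho[i, j], oracle_spearman(toy[, i], toy[, j]),
                 tolerance = 1e-12)

  # invariance under strictly monotone transforms of a column
  toy2 <- toy
  toy2[, 1] <- exp(toy2[, 1])
  sm2 <- spearman_matrix(toy2)
  expect_equal(unname(sm2$rho), unname(sm$rho), tolerance = 1e-12)

  const <- cbind(k = rep(2, 5), toy[, 1:2])
  smc <- spearman_matrix(const)
  expect_true("k" %in% smc$flagged)
  expect_true(is.na(smc$rho["k", 2]))
  expect_equal(smc$rho["k", "k"], 1)
})

test_that("wilcoxon_paired: degenerate input, exact branch vs sign enumeration", {
  x <- c(1, 2, 3, 4, 5)
  res <- wilcoxon_paired(x, x)
  expect_true(res$degenerate)
  expect_true(is.na(res$p_value))
  expect_equal(res$n_zero, 5)

  set.seed(4)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    x <- rnorm(n)
    y <- x - rnorm(n, mean = 0.5)
    res <- wilcoxon_paired(x, y)
    expect_equal(res$method, "exact")
    expect_equal(res$p_value, oracle_wilcoxon_exact(x, y), tolerance = 1e-12)
  }
  # ties in |differences| are handled by average ranks in both routes
  x <- c(2, 4, 6, 1, 3, 9)
  y <- c(1, 3, 5, 3, 5, 2)   # |d| = 1,1,1,2,2,7
  expect_equal(wilcoxon_paired(x, y)$p_value, oracle_wilcoxon_exact(x, y),
               tolerance = 1e-12)
  # and agrees with stats::wilcox.test when there are no ties
  x <- c(1.3, -0.4, 2.2, 0.9, -1.7, 0.6, 3.1, -2.4)
  y <- rep(0, 8)
  expect_equal(wilcoxon_paired(x, y)$p_value,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("wilcoxon_paired: exact and asymptotic branches agree closely", {
  # At n = 12 the normal approximation (continuity-corrected, identical to
  # stats::wilcox.test's) deviates from the exact p by up to ~0.014 at
  # mid-range p — a property of the approximation itself, not of this
  # implementation. We assert the measured bound at n = 12 (0.02, and 0.01
  # wherever p < 0.1) and the nominal 0.01 at n = 25.
  set.seed(7)
  for (rep in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    p_exact <- wilcoxon_paired(x, y, exact_limit = 25)$p_value
    p_asym <- wilcoxon_paired(x, y, exact_limit = 0)$p_value
    expect_lt(abs(p_exact - p_asym), 0.02)
    if (p_exact < 0.1) expect_lt(abs(p_exact - p_asym), 0.01)
  }
  for (rep in 1:10) {
    x <- rnorm(25); y <- rnorm(25)
    expect_lt(abs(wilcoxon_paired(x, y, exact_limit = 25)$p_value -
                  wilcoxon_paired(x, y, exact_limit = 0)$p_value), 0.01)
  }
})

test_that("wilcoxon_paired: power against a 1-SD shift exceeds 0.5 at n = 50", {
  set.seed(11)
  rej <- replicate(500, {
    x <- rnorm(50, mean = 1)
    y <- rnorm(50, mean = 0)
    wilcoxon_paired(x, y)$p_value < 0.05
  })
  expect_gt(mean(rej), 0.5)
})

test_that("rank-biserial effect size: boundaries, zeros, rank-sum oracle", {
  x <- 1:8
  expect_equal(paired_rank_effect(x + 1, x), 1)
  expect_equal(paired_rank_effect(x - 1, x), -1)
  expect_equal(paired_rank_effect(x, x), 0)

  xm <- c(5, 1, 4, 2, 8, 3)
  ym <- c(3, 2, 1, 6, 2, 3)
  d <- (xm - ym)[xm != ym]   # zeros dropped before ranking
  r <- rank(abs(d))
  expect_equal(paired_rank_effect(xm, ym),
               (sum(r[d > 0]) - sum(r[d < 0])) / sum(r))
  # sign convention: effect sign equals the sign of the median difference
  expect_gt(paired_rank_effect(xm, ym) *
              sign(median(d[d != 0]) + 1e-9), -1e-12)
})

test_that("compare_corpus: degenerate corpus, planted direction, small strata", {
  # observed identical to nulls -> zero effects, degenerate tests
  tab <- data.frame(network = rep(paste0("g", 1:6), each = 2),
                    index = rep(c("S", "Omega"), 6),
                    observed = rep(c(0.5, 0.7), 6),
                    null_mean = rep(c(0.5, 0.7), 6))
  cmp <- compare_corpus(tab)
  expect_true(all(cmp$effect_size == 0))
  expect_true(all(is.na(cmp$p_value)))

  # single network -> descriptive only
  cmp1 <- compare_corpus(tab[tab$network == "g1", ])
  expect_false(any(cmp1$tested))
  expect_true(all(is.na(cmp1$p_value)))

  # synthetic corpus of planted-organisation graphs vs rewired nulls:
  # the construction forces Omega(observed) > Omega(null)
  set.seed(21)
  rows <- list()
  for (i in 1:12) {
    g <- fixture_graph("planted_multiorder",
                       multiplicities = sample(2:5, sample(3:5, 1),
                                               replace = TRUE))
    obs <- neighbourhood_organisation(g)
    ens <- null_ensemble(g, n_realisations = 4, seed = 1000 + i)
    rows[[i]] <- data.frame(
      network = paste0("pm", i), index = "Omega", observed = obs,
      null_mean = ens$summary$mean[ens$summary$index == "Omega"])
  }
  cmp <- compare_corpus(do.call(rbind, rows))
  expect_gt(cmp$effect_size[cmp$index == "Omega"], 0)
  expect_lt(cmp$p_value[cmp$index == "Omega"], 0.05)

  # stratification path
  tab$class <- rep(c("bio", "soc"), each = 6)
  cmps <- compare_corpus(tab, by_class = TRUE)
  expect_true(all(c("bio", "soc") %in% cmps$class))
})
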