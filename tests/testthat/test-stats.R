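test_that("K-S screen is calibrated on normal data and rejects uniform data", {
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    if (ks_normality(rnorm(1000))$p_value > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 45)
  set.seed(1)
  expect_lt(ks_normality(runif(1000))$p_value, 0.01)
  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
  expect_error(ks_normality(rep(2, 10)), "constant")
})

test_that("exact Wilcoxon matches full enumeration for all small partitions", {
  expect_equal(wilcoxon_ranksum(c(1, 2), c(3, 4))$p_value, 2 / 6,
               tolerance = 1e-12)
  set.seed(30)
  for (na in 2:5) for (nb in na:5) {
    x <- sample(100, na + nb)          # tie-free
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    res <- wilcoxon_ranksum(a, b)
    expect_true(res$exact)
    expect_equal(res$p_value, wilcoxon_exact_oracle(a, b), tolerance = 1e-12,
                 label = sprintf("exact p (n=%d+%d)", na, nb))
  }
})

test_that("identical samples give p = 1 and modes agree on moderate n", {
  expect_equal(wilcoxon_ranksum(1:4, 1:4)$p_value, 1)
  set.seed(31)
  for (rep in 1:10) {
    x <- sample(1000, 12)
    a <- x[1:6]; b <- x[7:12]
    p_ex <- wilcoxon_ranksum(a, b, exact = TRUE)$p_value
    p_ap <- wilcoxon_ranksum(a, b, exact = FALSE)$p_value
    expect_lt(abs(p_ex - p_ap), 0.02)
  }
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "non-empty")
  expect_warning(wilcoxon_ranksum(c(1, 1, 2), c(2, 3), exact = TRUE), "ties")
})

test_that("Spearman handles monotone transforms, ties and the toy vector", {
  expect_equal(spearman_cor(1:5, c(1, 3, 2, 5, 4))$rho, 0.8)
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  set.seed(32)
  a <- rnorm(20); b <- rnorm(20)
  base <- spearman_cor(a, b)
  mono <- spearman_cor(exp(a), b^3 * 0 + b)   # strictly monotone in x only
  expect_equal(base$rho, mono$rho, tolerance = 1e-12)
  expect_equal(base$p_value, mono$p_value, tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 6), 1:6), "constant")
  expect_error(spearman_cor(1:3, 3:1), "at least 4")
})

test_that("BH adjustment matches the hand step-up rule and its invariances", {
  expect_equal(fdr_bh(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(fdr_bh(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(fdr_bh(0.2), 0.2)
  set.seed(33)
  for (rep in 1:10) {
    p <- runif(20)
    q <- fdr_bh(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))          # monotone in sorted order
    perm <- sample(20)
    expect_equal(fdr_bh(p[perm]), q[perm])           # permutation invariant
    expect_true(all(q <= 1 & q >= p))
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("edgewise comparison flags planted edges and nothing under self-comparison", {
  set.seed(34)
  mk <- function(shift_edges = NULL, delta = 0) {
    lapply(1:15, function(s) {
      m <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
      m[upper.tri(m)] <- runif(15, 0.3, 0.5)
      if (!is.null(shift_edges)) m[shift_edges] <- m[shift_edges] + delta
      m + t(m)
    })
  }
  a <- mk(rbind(c(1, 2), c(3, 4)), 0.3)
  b <- mk()
  res <- edgewise_compare(a, b)
  sig <- res[attr(res, "significant"), ]
  expect_true(all(c("a-b") %in% paste(sig$chan_a, sig$chan_b, sep = "-")))
  expect_true(all(sig$direction == 1))
  expect_equal(nrow(res), 15)

  self <- edgewise_compare(b, b)
  expect_true(all(self$p_raw == 1))
  expect_error(edgewise_compare(a[1], b), "2 subjects")
})

test_that("paired signed-rank option detects consistent within-subject shifts", {
  set.seed(37)
  base <- runif(12, 0.3, 0.6)
  a <- lapply(seq_along(base), function(s) {
    m <- matrix(0, 3, 3); m[upper.tri(m)] <- base[s] + c(0.1, 0, 0); m + t(m)
  })
  b <- lapply(seq_along(base), function(s) {
    m <- matrix(0, 3, 3); m[upper.tri(m)] <- base[s]; m + t(m)
  })
  res <- edgewise_compare(a, b, paired = TRUE)
  expect_lt(res$p_raw[1], 0.01)          # shifted edge
  expect_equal(res$p_raw[2], 1)          # identical pairs
  expect_error(edgewise_compare(a[1:3], b, paired = TRUE), "aligned")
  expect_equal(wilcoxon_signedrank(1:5, 1:5)$p_value, 1)
})

test_that("nodewise comparison and self-comparison behave like the edgewise case", {
  set.seed(35)
  a <- matrix(rnorm(20 * 5, mean = 0), 20, 5,
              dimnames = list(NULL, paste0("n", 1:5)))
  b <- a
  self <- nodewise_compare(a, b)
  expect_true(all(self$p_raw == 1))
  a2 <- a; a2[, 2] <- a2[, 2] + 2
  res <- nodewise_compare(a2, b)
  expect_true(attr(res, "significant")[2])
  expect_equal(res$direction[2], 1)
  expect_error(nodewise_compare(a, b[, 1:3]), "node sets")
})

test_that("performance correlation recovers a planted monotone link", {
  set.seed(36)
  u <- rnorm(30)
  feats <- cbind(f1 = u + rnorm(30, sd = 0.3), f2 = rnorm(30))
  scores <- 8 + 0.8 * u + rnorm(30, sd = 0.4)
  res <- correlate_with_performance(feats, scores)
  expect_gt(res$rho[res$feature == "f1"], 0.5)
  expect_true(attr(res, "significant")[1])
  expect_lt(abs(res$rho[res$feature == "f2"]), 0.4)

  dup <- correlate_with_performance(cbind(s = scores), scores)
  expect_equal(dup$rho, 1)

  expect_error(correlate_with_performance(feats[1:4, ], scores[1:4]),
               "at least 5")
  rownames(feats) <- paste0("s", 1:30)
  names(scores) <- paste0("s", 1:30)
  shuffled <- scores[sample(30)]
  res2 <- correlate_with_performance(feats, shuffled)  # realigned by id
  expect_equal(res2$rho[1], res$rho[1])
  names(scores)[1] <- "zz"
  expect_error(correlate_with_performance(feats, scores), "do not match")
})
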