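test_that("quantile normalization maps columns onto the rank-mean reference", {
  # hand-enumerated rank means: reference = ((1+4)/2, (2+5)/2, (3+6)/2)
  m <- named_matrix(cbind(c(1, 2, 3), c(4, 5, 6)))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))
  expect_identical(dimnames(qn), dimnames(m))

  # identical columns are already normalized
  same <- named_matrix(cbind(c(2, 1, 5), c(2, 1, 5)))
  expect_equal(quantile_normalize(same), same)

  # a single sample is its own reference
  one <- named_matrix(cbind(c(3, 1, 2)))
  expect_equal(quantile_normalize(one), one)

  expect_error(quantile_normalize(named_matrix(cbind(c(1, -2), c(3, 4)))),
               "non-positive")
})

test_that("quantile normalization ties receive the mean reference value of their ranks", {
  # column 1 has a tie occupying ranks 1 and 2; reference = (2, 3, 10)
  m <- named_matrix(cbind(c(1, 1, 9), c(3, 11, 1)))
  qn <- quantile_normalize(m)
  ref <- rowMeans(apply(m, 2, sort))
  expect_equal(unname(qn[, 1]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
  expect_equal(sort(unname(qn[, 2])), unname(ref))
})

test_that("quantile normalization is idempotent, mean-conserving, and matches limma on tie-free data", {
  set.seed(42)
  m <- named_matrix(matrix(2^runif(200, 4, 12), 40, 5))
  qn <- quantile_normalize(m)
  # sorted columns all equal the reference
  sorted <- apply(qn, 2, sort)
  expect_equal(sorted, sorted[, c(1, 1, 1, 1, 1)],
               ignore_attr = TRUE)
  # idempotence and grand-mean conservation
  expect_equal(quantile_normalize(qn), qn)
  expect_equal(mean(qn), mean(m))
  # independent implementation agrees in the absence of ties
  expect_equal(unname(qn), unname(limma::normalizeQuantiles(m)),
               tolerance = 1e-12)
})

test_that("group log2 fold change is the difference of log2 group means", {
  design <- make_design(2, 2)
  m <- matrix(2^c(7, 7, 5, 5,      # probe 1: case mean 7, control mean 5
                  5, 5, 7, 7,      # probe 2: symmetric
                  6, 6, 6, 6),     # probe 3: no change
              3, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), design$sample_id))
  fc <- group_log2fc(m, design)
  expect_equal(fc$log2fc, c(2, -2, 0))
  expect_equal(fc$fc_abs, c(4, 4, 1))
  expect_error(group_log2fc(m, make_design(4, 3)), "match")
})

test_that("welch variant reproduces the hand-computed statistic and t.test", {
  design <- make_design(3, 3)
  m <- matrix(2^c(1, 2, 3, 2, 3, 4), 1, 6,
              dimnames = list("p1", design$sample_id))
  # case (1,2,3) vs control (2,3,4): t = -1.2247 on Welch df 4
  p <- probe_test(m, design, variant = "welch")
  expect_equal(unname(p), 0.2878641, tolerance = 1e-4)
  expect_equal(unname(p),
               t.test(c(1, 2, 3), c(2, 3, 4))$p.value, tolerance = 1e-12)

  # vectorized path agrees with per-probe t.test on random data
  set.seed(1)
  mm <- named_matrix(2^matrix(rnorm(60, 8), 10, 6))
  design <- make_design(3, 3)
  colnames(mm) <- design$sample_id
  pw <- probe_test(mm, design, "welch")
  pp <- probe_test(mm, design, "pooled")
  for (i in 1:10) {
    x <- log2(mm[i, 1:3])
    y <- log2(mm[i, 4:6])
    expect_equal(unname(pw[i]), t.test(x, y)$p.value, tolerance = 1e-12)
    expect_equal(unname(pp[i]),
                 t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate variances follow the stated conventions", {
  design <- make_design(2, 2)
  m <- matrix(2^c(5, 5, 5, 5), 1, 4,
              dimnames = list("p1", design$sample_id))
  expect_equal(unname(probe_test(m, design, "welch")), 1)
  m2 <- matrix(2^c(5, 5, 7, 7), 1, 4,
               dimnames = list("p1", design$sample_id))
  p2 <- probe_test(m2, design, "welch")
  expect_gt(unname(p2), 0)
  expect_lt(unname(p2), 1e-100)
  expect_error(probe_test(m, make_design(1, 3)), "match|2 samples")
})

test_that("moderated t shrinks variances and matches limma's empirical Bayes", {
  sim <- simulate_expression(500, seed = 10)
  # d0 = 0 forces no shrinkage: identical to the pooled t
  expect_equal(probe_test(sim$matrix, sim$design, "moderated", prior_df = 0),
               probe_test(sim$matrix, sim$design, "pooled"))

  # independent oracle: limma's lmFit + eBayes on the same log2 matrix
  p_mod <- probe_test(sim$matrix, sim$design, "moderated")
  dm <- cbind(1, sim$design$group == "case")
  fit <- limma::eBayes(limma::lmFit(log2(sim$matrix), dm))
  expect_equal(unname(p_mod), fit$p.value[, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("call_de applies the dual fold-change/p filter with direction", {
  rec <- data.frame(
    probe_id = c("up_strong", "flat", "p_fail", "down"),
    log2fc = c(log2(66.9668), 0, log2(3), -2),
    p_value = c(0.000005335, 0.5, 0.06, 0.001),
    stringsAsFactors = FALSE)
  de <- call_de(rec)
  expect_equal(de$direction, c("up", "none", "none", "down"))
  expect_equal(de$fc_abs[1], 66.9668, tolerance = 1e-10)
  expect_equal(de$probe_id, rec$probe_id)     # input order preserved
  expect_error(call_de(rec, fc_threshold = 0.5), "fc_threshold")
})

test_that("call_de is monotone in its thresholds and BH gating is valid", {
  set.seed(3)
  rec <- data.frame(probe_id = sprintf("p%03d", 1:200),
                    log2fc = rnorm(200), p_value = runif(200),
                    stringsAsFactors = FALSE)
  de_set <- function(...) {
    d <- call_de(rec, ...)
    d$probe_id[d$direction != "none"]
  }
  base <- de_set()
  expect_true(all(de_set(fc_threshold = 2) %in% base))
  expect_true(all(de_set(p_threshold = 0.01) %in% base))
  # BH never calls more than raw p at the same threshold
  bh <- de_set(adjust = "BH")
  expect_true(all(bh %in% base))
  d <- call_de(rec, adjust = "BH")
  expect_true(all(d$adj_p >= d$p_value))
  ord <- order(d$p_value)
  expect_true(all(diff(d$adj_p[ord]) >= -1e-15))
})

test_that("hierarchical ordering matches a brute-force UPGMA oracle", {
  # two probes: the single possible merge
  m2 <- named_matrix(2^rbind(c(1, 2, 3), c(3, 1, 2)))
  res2 <- hclust_order(m2)
  expect_setequal(res2$order, rownames(m2))
  expect_equal(nrow(res2$tree$merge), 1)

  # perfectly correlated pair merges first at distance 0
  m3 <- 2^rbind(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 2, 1))
  colnames(m3) <- c("s1", "s2", "s3")
  res3 <- hclust_order(m3)
  first_merge <- hclust_merges(res3$tree, res3$tree$labels)[1, ]
  expect_equal(c(first_merge$set_a, first_merge$set_b), c("a", "b"))
  expect_equal(res3$tree$height[1], 0, tolerance = 1e-12)

  # random probes: merge sequence identical to the naive O(n^3) oracle
  set.seed(8)
  m5 <- named_matrix(2^matrix(rnorm(30, 8), 5, 6))
  res5 <- hclust_order(m5)
  prof <- log2(m5)
  d <- 1 - cor(t(prof))
  got <- hclust_merges(res5$tree, res5$tree$labels)
  want <- oracle_upgma(d)
  expect_equal(got$set_a, want$set_a)
  expect_equal(got$set_b, want$set_b)
  expect_equal(got$height, want$height, tolerance = 1e-12)

  # zero-variance profile is at distance 1 from everything
  mz <- named_matrix(2^rbind(c(5, 5, 5), c(1, 2, 3), c(1.1, 2.2, 3.1)))
  resz <- hclust_order(mz)
  expect_setequal(resz$order, rownames(mz))
  # the flat probe (p01) joins last, at height 1
  mz_merges <- hclust_merges(resz$tree, resz$tree$labels)
  expect_true("p01" %in% c(mz_merges$set_a[2], mz_merges$set_b[2]))
  expect_equal(mz_merges$height[2], 1, tolerance = 1e-12)

  one <- named_matrix(2^cbind(c(4)))
  expect_equal(hclust_order(one)$order, "p01")
})
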