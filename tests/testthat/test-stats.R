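test_that("descriptive summary uses interpolated quartiles", {
  d <- tibble::tibble(year = 2013, v = c(1, 2, 3, 4, 5))
  s <- descriptive_summary(d, "v")
  expect_equal(s$min, 1); expect_equal(s$q25, 2); expect_equal(s$mean, 3)
  expect_equal(s$q75, 4); expect_equal(s$max, 5); expect_equal(s$n, 5L)

  const <- descriptive_summary(tibble::tibble(year = 1, v = rep(7, 9)), "v")
  expect_true(all(unlist(const[c("min", "q25", "mean", "q75", "max")]) == 7))

  # frozen evaluation of the inclusive interpolation on an awkward set
  x <- c(0.23, 0.25, 0.43, 0.87, 1.89)
  s2 <- descriptive_summary(tibble::tibble(year = 1, v = x), "v")
  expect_equal(s2$q25, 0.25) # (n-1)*0.25 = 1 lands on the 2nd order stat
  expect_equal(s2$q75, 0.87)
  x6 <- c(x, 2.5)
  s3 <- descriptive_summary(tibble::tibble(year = 1, v = x6), "v")
  expect_equal(s3$q25, 0.25 + 0.25 * (0.43 - 0.25)) # h = 2.25
  expect_equal(s3$q75, 0.87 + 0.75 * (1.89 - 0.87)) # h = 4.75
  expect_error(descriptive_summary(d, "nope"), "nope")
})

test_that("spearman correlation matches the brute-force rank formula", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_rank(x, x)$rho, 1)
  expect_equal(spearman_rank(x, -x)$rho, -1)
  set.seed(55)
  for (i in 1:20) {
    a <- stats::rnorm(9)
    b <- stats::rnorm(9) + a
    expect_equal(spearman_rank(a, b)$rho, oracle_spearman_rho(a, b))
    # invariance under strictly monotone transforms
    expect_equal(spearman_rank(exp(a), b)$rho, spearman_rank(a, b)$rho)
    expect_equal(spearman_rank(a, 3 * b - 100)$rho, spearman_rank(a, b)$rho)
  }
  expect_error(spearman_rank(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rank(1:2, 1:2), "length")
})

test_that("exact permutation p equals full enumeration at n = 6 with ties", {
  x <- c(1, 2, 2, 3, 4, 5)  # one tie
  y <- c(2, 1, 4, 3, 6, 5)
  r <- spearman_rank(x, y, method = "exact")
  perms <- oracle_perms(6)
  rhos <- apply(perms, 1, function(p) oracle_spearman_rho(x, y[p]))
  expect_equal(nrow(perms), 720)
  expect_equal(r$rho, oracle_spearman_rho(x, y))
  expect_equal(r$p_value, mean(abs(rhos) >= abs(r$rho) - 1e-12))
  expect_error(spearman_rank(stats::rnorm(9), stats::rnorm(9),
                             method = "exact"), "n <= 8")
})

test_that("signed-rank statistics follow the reporting convention", {
  pre <- c(10, 12, 9, 14, 11)
  post <- pre - c(1, 2, 0.5, 3, 1.5) # all post < pre
  r <- wilcoxon_signed_rank(pre, post)
  expect_equal(r$w, 0)
  expect_equal(r$w_minus, 15)
  expect_equal(r$p_value, 2 / 32) # enumeration over 2^5 sign patterns
  expect_lt(r$z, 0)               # post lower -> negative Z
  expect_equal(r$method, "exact")

  # antisymmetric differences: W+ = W-, Z = 0, p = 1
  pre2 <- c(0, 0, 0, 0)
  post2 <- c(2, -2, 1, -1)
  r2 <- wilcoxon_signed_rank(pre2, post2)
  expect_equal(r2$z, 0)
  expect_equal(r2$p_value, 1)

  # zero differences are dropped before ranking
  r3 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 9), c(1, 3, 5, 6, 17))
  expect_equal(r3$n_effective, 4)
  expect_gt(r3$z, 0)
  expect_error(wilcoxon_signed_rank(1:3, 1:3), "degenerate")
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "unpaired")
})

test_that("exact branch equals sign-pattern enumeration up to n = 12", {
  set.seed(66)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    pre <- stats::rnorm(n)
    post <- pre + stats::rnorm(n, mean = -0.5)
    # occasional ties in |d|
    if (i %% 3 == 0) post[2] <- pre[2] - abs(post[1] - pre[1])
    r <- wilcoxon_signed_rank(pre, post)
    expect_equal(r$method, "exact")
    expect_equal(r$p_value, oracle_signed_rank_p(post - pre))
  }
})

test_that("normal approximation approaches the exact p at n = 12", {
  set.seed(77)
  diffs <- numeric(0)
  for (i in 1:20) {
    pre <- stats::rnorm(12)
    post <- pre + stats::rnorm(12, mean = -0.6)
    ex <- wilcoxon_signed_rank(pre, post, exact_limit = 15)
    ap <- wilcoxon_signed_rank(pre, post, exact_limit = 0)
    expect_equal(ap$method, "normal-approximation")
    diffs <- c(diffs, abs(ex$p_value - ap$p_value))
  }
  expect_lt(max(diffs), 0.02)
})

test_that("signed-rank agrees with the reference implementation", {
  set.seed(88)
  pre <- stats::rnorm(10)
  post <- pre + stats::rnorm(10, -0.3)
  r <- wilcoxon_signed_rank(pre, post)
  ref <- stats::wilcox.test(post, pre, paired = TRUE, exact = TRUE)
  expect_equal(r$p_value, unname(ref$p.value))
  expect_equal(max(r$w_plus, r$w_minus) + r$w, 10 * 11 / 2)
})

test_that("discriminant analysis separates what is separable", {
  set.seed(99)
  n <- 30
  d <- tibble::tibble(
    f1 = c(stats::rnorm(n, 0), stats::rnorm(n, 10)),
    f2 = c(stats::rnorm(n, 0), stats::rnorm(n, -6)),
    g = rep(c("a", "b"), each = n)
  )
  fit <- lda_two_group(d, c("f1", "f2"), "g")
  expect_equal(fit$accuracy, 100)
  expect_equal(fit$accuracy_loo, 100)
  expect_lt(fit$wilks_lambda, 0.05)
  expect_lt(fit$p_value, 1e-10)
  expect_equal(rowSums(fit$confusion), c(a = n, b = n))
  expect_equal(rowSums(fit$confusion_loo), c(a = n, b = n))
})

test_that("discriminant accuracy hovers at chance on null data", {
  set.seed(111)
  accs <- vapply(1:40, function(i) {
    d <- tibble::tibble(f1 = stats::rnorm(40), f2 = stats::rnorm(40),
                        g = rep(c("a", "b"), each = 20))
    lda_two_group(d, c("f1", "f2"), "g")$accuracy_loo
  }, numeric(1))
  # mean LOO accuracy within 3 standard errors of 50%
  expect_lt(abs(mean(accs) - 50), 3 * stats::sd(accs) / sqrt(40))
})

test_that("classification is invariant under affine feature maps", {
  set.seed(122)
  d <- tibble::tibble(
    f1 = c(stats::rnorm(25, 0), stats::rnorm(25, 1.5)),
    f2 = c(stats::rnorm(25, 0), stats::rnorm(25, -1)),
    g = rep(c("a", "b"), each = 25)
  )
  A <- matrix(c(2, 0.5, -1, 3), 2)   # invertible
  tx <- as.matrix(d[c("f1", "f2")]) %*% A
  d2 <- tibble::tibble(f1 = tx[, 1] + 7, f2 = tx[, 2] - 3, g = d$g)
  fit1 <- lda_two_group(d, c("f1", "f2"), "g")
  fit2 <- lda_two_group(d2, c("f1", "f2"), "g")
  expect_equal(fit1$confusion, fit2$confusion)
  expect_equal(fit1$confusion_loo, fit2$confusion_loo)
  expect_equal(fit1$wilks_lambda, fit2$wilks_lambda)
})

test_that("wilks lambda shrinks as the group separation grows", {
  set.seed(133)
  base <- tibble::tibble(f1 = stats::rnorm(60), f2 = stats::rnorm(60),
                         g = rep(c("a", "b"), each = 30))
  lambdas <- vapply(c(0, 1, 2.5, 5), function(delta) {
    d <- base
    d$f1[d$g == "b"] <- d$f1[d$g == "b"] + delta
    lda_two_group(d, c("f1", "f2"), "g")$wilks_lambda
  }, numeric(1))
  expect_true(all(diff(lambdas) < 0))
})

test_that("discriminant results match the reference LDA", {
  skip_if_not_installed("MASS")
  set.seed(144)
  d <- tibble::tibble(
    f1 = c(stats::rnorm(20, 0), stats::rnorm(20, 1.2)),
    f2 = c(stats::rnorm(20, 0), stats::rnorm(20, 0.8)),
    g = factor(rep(c("a", "b"), each = 20))
  )
  fit <- lda_two_group(d, c("f1", "f2"), "g")
  ref <- MASS::lda(g ~ f1 + f2, data = d, prior = c(0.5, 0.5))
  pred_ref <- stats::predict(ref)$class
  mine <- ifelse(
    (fit$scores >= fit$cut) == (fit$group_means[1] >= fit$group_means[2]),
    "a", "b")
  expect_equal(as.character(pred_ref), mine)
  ref_cv <- MASS::lda(g ~ f1 + f2, data = d, prior = c(0.5, 0.5), CV = TRUE)
  expect_equal(unname(100 * mean(ref_cv$class == d$g)), fit$accuracy_loo)
})

test_that("rank agreement tabulates differences and the within-2 share", {
  same <- tibble::tibble(rank_wqs = c(1L, 3L, 5L), rank_cds = c(1L, 3L, 5L))
  t1 <- rank_agreement(same)
  expect_equal(t1$pct[t1$difference == 0], 100)
  expect_equal(attr(t1, "share_within_2"), 100)

  extreme <- tibble::tibble(rank_wqs = c(1L, 5L), rank_cds = c(5L, 1L))
  t2 <- rank_agreement(extreme)
  expect_equal(t2$n[t2$difference == -4], 1L)
  expect_equal(t2$n[t2$difference == 4], 1L)
  expect_equal(attr(t2, "share_within_2"), 0)

  set.seed(155)
  wq <- sample(1:5, 10, TRUE); cd <- sample(1:5, 10, TRUE)
  t3 <- rank_agreement(tibble::tibble(rank_wqs = wq, rank_cds = cd))
  hand <- table(factor(wq - cd, levels = -4:4))
  expect_equal(t3$n, unname(as.integer(hand)))
  expect_equal(sum(t3$n), 10L)
  expect_equal(sum(t3$pct), 100)
  expect_error(rank_agreement(tibble::tibble()), "no index")
})

test_that("per-year rank counts conserve the sample counts", {
  one <- tibble::tibble(year = 2013, rank_wqs = rep(5L, 7),
                        rank_cds = rep(1L, 7))
  c1 <- count_by_rank(one, "wqs")
  expect_equal(unlist(c1[1, paste0("rank_", 1:5)], use.names = FALSE),
               c(0L, 0L, 0L, 0L, 7L))
  d <- simulate_dataset(synthetic_config(), seed = 17)
  idx <- wq_indices(d)
  counts <- count_by_rank(idx, "cds")
  expect_equal(counts$n, c(40L, 40L, 40L, 40L, 37L, 34L))
})
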