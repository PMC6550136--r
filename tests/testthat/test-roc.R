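brute_auc <- function(scores, labels) {
  cs <- scores[labels == 1]; co <- scores[labels == 0]
  tot <- 0
  for (x in cs) for (y in co)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(cs) * length(co))
}

brute_delong_var <- function(scores, labels) {
  cs <- scores[labels == 1]; co <- scores[labels == 0]
  m <- length(cs); n <- length(co)
  v10 <- vapply(cs, function(x) mean((x > co) + 0.5 * (x == co)), 0)
  v01 <- vapply(co, function(y) mean((cs > y) + 0.5 * (cs == y)), 0)
  var(v10) / m + var(v01) / n
}

test_that("AUC equals the Mann-Whitney statistic on exhaustive small inputs", {
  set.seed(11)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  for (rep in 1:60) {
    n <- sample(4:8, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- sample(grid, n, TRUE)   # heavy ties on purpose
    r <- roc(scores, labels)
    expect_equal(r$auc, brute_auc(scores, labels), tolerance = 1e-12)
    if (sum(labels) >= 2 && sum(1 - labels) >= 2)
      expect_equal(r$var, brute_delong_var(scores, labels),
                   tolerance = 1e-12)
  }
})

test_that("perfect separation gives AUC 1 and a perfect Youden point", {
  r <- roc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$youden$sensitivity, 1)
  expect_equal(r$youden$specificity, 1)
  expect_equal(r$ci, c(1, 1))
  expect_error(roc(1:4, c(1, 1, 1, 1)), "both")
})

test_that("independent scores give chance AUC", {
  set.seed(12)
  r <- roc(rnorm(2000), rbinom(2000, 1, 0.3))
  expect_lt(abs(r$auc - 0.5), 0.05)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
})

test_that("DeLong machinery agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(13)
  y <- rbinom(120, 1, 0.4)
  s1 <- y + rnorm(120)
  s2 <- 0.5 * y + rnorm(120)
  r1 <- roc(s1, y); r2 <- roc(s2, y)
  pr1 <- pROC::roc(y, s1, quiet = TRUE)
  expect_equal(r1$auc, as.numeric(pROC::auc(pr1)), tolerance = 1e-10)
  expect_equal(r1$var, pROC::var(pr1, method = "delong"),
               tolerance = 1e-10)
  expect_equal(unname(r1$ci),
               as.numeric(pROC::ci.auc(pr1, method = "delong"))[c(1, 3)],
               tolerance = 1e-8)
  pt <- pROC::roc.test(pr1, pROC::roc(y, s2, quiet = TRUE),
                       method = "delong", paired = TRUE)
  ours <- delong_test(r1, r2, paired = TRUE)
  expect_equal(ours$p, pt$p.value, tolerance = 1e-8)
  # unpaired across disjoint cohorts
  y2 <- rbinom(80, 1, 0.5); s3 <- y2 + rnorm(80)
  ru <- delong_test(r1, roc(s3, y2), paired = FALSE)
  pu <- pROC::roc.test(pr1, pROC::roc(y2, s3, quiet = TRUE),
                       method = "delong", paired = FALSE)
  # pROC refers the unpaired statistic to a t distribution; the statistic
  # itself (and our normal p) must agree with its z
  expect_equal(ru$z, unname(pu$statistic), tolerance = 1e-8)
  expect_equal(ru$p, 2 * pnorm(-abs(ru$z)), tolerance = 1e-12)
})

test_that("a model compared with itself is a null comparison", {
  set.seed(14)
  y <- rbinom(60, 1, 0.5); s <- y + rnorm(60)
  r <- roc(s, y)
  expect_warning(out <- delong_test(r, r, paired = TRUE), "degenerate")
  expect_equal(out$difference, 0)
  expect_equal(out$p, 1)
})

test_that("rank statistics are invariant to monotone score transforms", {
  set.seed(15)
  y <- rbinom(100, 1, 0.4); s <- rnorm(100) + y
  r <- roc(s, y)
  r_t <- roc(exp(3 * s) + 2, y)
  expect_equal(r_t$auc, r$auc, tolerance = 1e-12)
  expect_equal(r_t$var, r$var, tolerance = 1e-12)
  expect_equal(r_t$youden$sensitivity, r$youden$sensitivity)
  expect_equal(r_t$youden$specificity, r$youden$specificity)
  y2 <- rbinom(100, 1, 0.4); s2 <- rnorm(100) + y2
  p1 <- delong_test(r, roc(s2, y2), paired = FALSE)$p
  p2 <- delong_test(r_t, roc(log(s2 - min(s2) + 1), y2), paired = FALSE)$p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("unpaired z matches hand-computed structural components", {
  sa <- c(3, 1, 4, 1, 5, 9, 2, 6); ya <- c(1, 0, 1, 0, 1, 1, 0, 0)
  sb <- c(2, 7, 1, 8, 2, 8, 1, 8); yb <- c(0, 1, 0, 1, 0, 1, 1, 0)
  ra <- roc(sa, ya); rb <- roc(sb, yb)
  z_hand <- (brute_auc(sa, ya) - brute_auc(sb, yb)) /
    sqrt(brute_delong_var(sa, ya) + brute_delong_var(sb, yb))
  out <- delong_test(ra, rb, paired = FALSE)
  expect_equal(out$z, z_hand, tolerance = 1e-12)
  expect_equal(out$p, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)
})

test_that("bootstrap interval behaves at the boundaries and under seeding", {
  s <- c(1, 2, 3, 11, 12, 13); y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(bootstrap_ci(s, y, B = 200, seed = 1), c(1, 1))
  set.seed(16)
  s2 <- rnorm(100); y2 <- rbinom(100, 1, 0.4)
  a <- bootstrap_ci(s2, y2, B = 300, seed = 7)
  b <- bootstrap_ci(s2, y2, B = 300, seed = 7)
  expect_identical(a, b)
  expect_error(bootstrap_ci(c(1, 2), c(1, 0), B = 10, seed = 1), ">= 2")
})

test_that("bootstrap and DeLong intervals agree at moderate n", {
  set.seed(17)
  y <- rbinom(1000, 1, 0.3); s <- y + rnorm(1000)
  r <- roc(s, y)
  b <- bootstrap_ci(s, y, B = 500, seed = 2)
  expect_lt(abs((b[2] - b[1]) / 2 - (r$ci[2] - r$ci[1]) / 2), 0.02)
  expect_true(b[1] <= r$auc && r$auc <= b[2])
})

test_that("bootstrap interval covers the point AUC across simulations", {
  set.seed(18)
  hits <- vapply(1:40, function(i) {
    y <- rbinom(200, 1, 0.3); s <- y + rnorm(200)
    ci <- bootstrap_ci(s, y, B = 200, seed = i)
    a <- roc(s, y)$auc
    ci[1] <= a && a <= ci[2]
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
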