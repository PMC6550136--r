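test_that("preprocess standardizes and handles degenerate input", {
  img <- matrix(runif(80 * 60), 80, 60)
  out <- preprocess_image(img, size = 96)
  expect_equal(dim(out), c(96, 96))
  expect_lt(abs(mean(out)), 1e-9)
  expect_lt(abs(sd(as.vector(out)) - 1), 1e-9)
  expect_warning(z <- preprocess_image(matrix(1, 10, 10), size = 32),
                 "constant")
  expect_equal(z, matrix(0, 32, 32))
})

test_that("downscale is aspect-preserving with an even pad split", {
  # 400 x 200 at size 299: scale 299/400, new dims 299 x 150 (rounded),
  # then 149 pad columns split 74 left / 75 right
  img <- matrix(runif(400 * 200) + 1, 400, 200)
  out <- preprocess_image(img, size = 299)
  expect_equal(dim(out), c(299, 299))
  pad_val <- out[1, 1]
  col_is_pad <- apply(out, 2, function(cc) all(cc == pad_val))
  expect_true(all(col_is_pad[1:74]))          # floor(149 / 2) on the left
  expect_true(all(col_is_pad[225:299]))       # remaining 75 on the right
  expect_false(col_is_pad[75])
  expect_false(col_is_pad[224])
  expect_false(any(apply(out, 1, function(rr) all(rr == pad_val))))
})

test_that("featurizer is deterministic, order-equivariant and mirror-sensitive", {
  cfg <- tiny_sim(seed = 13)
  co <- simulate_cohort(cfg)[1:12, ]
  imgs <- render_images(co, cfg)
  f1 <- featurize(imgs)
  f2 <- featurize(imgs)
  expect_identical(f1, f2)
  perm <- c(5, 1, 9, 2, 12, 3, 4, 6, 7, 8, 10, 11)
  f3 <- featurize(imgs[perm, ])
  expect_equal(f3, f1[perm, ])
  # identical images give identical features
  expect_equal(f1[1, ], featurize(imgs[c(1, 1), ])[2, ])
  # left-right mirror changes the feature vector
  m <- matrix(imgs[1, ], 96, 96)
  fm <- featurize(rbind(as.vector(m), as.vector(m[, 96:1])))
  expect_false(isTRUE(all.equal(fm[1, ], fm[2, ])))
})

test_that("compiled filter bank matches the reference implementation", {
  set.seed(2)
  X <- matrix(runif(6 * 24 * 24), 6, 24 * 24)
  a <- featurize(X, featurizer_spec(dim = 64))
  Xs <- confaudit:::ca_standardize_rows(X)
  b <- confaudit:::ca_filter_bank_r(Xs, 24, 4)
  expect_equal(unname(a), unname(b), tolerance = 1e-10)
  expect_error(featurizer_spec(dim = 50), "4 \\* g\\^2")
})

test_that("external featurizer adapter is honoured", {
  X <- matrix(runif(4 * 16), 4, 16)
  spec <- featurizer_spec("external", dim = 3,
                          fn = function(x) x[, 1:3] * 0 + 1)
  expect_equal(dim(featurize(X, spec)), c(4, 3))
  expect_error(featurize(X, featurizer_spec("external", fn = function(x) 1)),
               "malformed")
})

test_that("PCA reduction matches an eigendecomposition oracle", {
  set.seed(3)
  X <- matrix(rnorm(20 * 5), 20, 5)
  p <- pca_reduce(X, k = 5)
  # oracle: eigen of the covariance matrix
  ev <- eigen(cov(X))
  scores_oracle <- sweep(X, 2, colMeans(X)) %*% ev$vectors
  for (j in 1:5)
    expect_equal(abs(unname(p$scores[, j])), abs(unname(scores_oracle[, j])),
                 tolerance = 1e-8)
  expect_equal(p$explained, ev$values / sum(ev$values), tolerance = 1e-8)
  # full-rank k: perfect reconstruction
  rec <- p$scores %*% t(p$loadings)
  expect_equal(unname(rec + rep(p$center, each = 20)), unname(X),
               tolerance = 1e-8)
})

test_that("PCA respects rank, train-only fitting and score centering", {
  set.seed(4)
  base <- rnorm(30)
  X1 <- cbind(base, 2 * base, -base)           # rank 1
  p1 <- pca_reduce(X1, k = 1)
  expect_equal(p1$explained[1], 1, tolerance = 1e-12)
  expect_error(pca_reduce(X1, k = 2), "rank")
  X <- matrix(rnorm(40 * 6), 40, 6)
  train <- rep(c(TRUE, FALSE), 20)
  p <- pca_reduce(X, k = 3, train = train)
  expect_equal(colMeans(p$scores[train, ]), rep(0, 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(p$explained) < 1e-12))
  expect_equal(unname(crossprod(p$loadings)), diag(3), tolerance = 1e-10)
  # projection of new rows uses train loadings
  expect_equal(pca_project(p, X[!train, , drop = FALSE]),
               p$scores[!train, ], tolerance = 1e-12)
})

test_that("a PCA reduction round-trips through JSON", {
  set.seed(7)
  X <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  p <- pca_reduce(X, k = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_pca(p, path)
  back <- read_pca(path)
  expect_equal(back$loadings, p$loadings, tolerance = 1e-12)
  expect_equal(back$center, p$center, tolerance = 1e-12)
  expect_equal(pca_project(back, X), p$scores, tolerance = 1e-10)
})

test_that("PC-covariate R2 matches a normal-equations oracle", {
  set.seed(6)
  n <- 120
  g <- factor(sample(c("a", "b", "c"), n, TRUE))
  pc1 <- ifelse(g == "a", 1, ifelse(g == "b", 3, 4)) + rnorm(n, 0, 0.5)
  scores <- cbind(PC1 = pc1, PC2 = rnorm(n))
  out <- pc_covariate_r2(scores, data.frame(g = g, const = 1,
                                            exact = pc1))
  # oracle via explicit least squares
  Xd <- model.matrix(~ g)
  bh <- solve(t(Xd) %*% Xd, t(Xd) %*% pc1)
  r2_oracle <- 1 - sum((pc1 - Xd %*% bh)^2) / sum((pc1 - mean(pc1))^2)
  got <- out$r2[out$pc == "PC1" & out$covariate == "g"]
  expect_equal(got, r2_oracle, tolerance = 1e-10)
  expect_equal(out$r2[out$pc == "PC1" & out$covariate == "exact"], 1,
               tolerance = 1e-10)
  expect_equal(out$r2[out$pc == "PC1" & out$covariate == "const"], 0)
  expect_lt(out$r2[out$pc == "PC2" & out$covariate == "g"], 0.1)
})

test_that("scanner dominates image variation on default cohorts", {
  co <- simulate_cohort(small_sim(seed = 16))
  feats <- featurize(render_images(co))
  pcs <- pca_reduce(feats, 5, train = co$partition == "train")
  r2 <- pc_covariate_r2(pcs$scores,
                        co[, c("scanner_model", "age", "sex", "bmi",
                               "fall", "pain")])
  pc1 <- r2[r2$pc == "PC1", ]
  expect_equal(pc1$covariate[which.max(pc1$r2)], "scanner_model")
  for (v in c("age", "sex", "bmi", "fall", "pain"))
    expect_gt(pc1$r2[pc1$covariate == "scanner_model"],
              pc1$r2[pc1$covariate == v])
})
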