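# Image preprocessing, filter-bank featurization and PCA reduction.
#
# The featurizer is a fixed, deterministic stand-in for a pretrained CNN
# embedding: grid-pooled intensity means and dispersions plus oriented
# gradient energies. Its claims-relevant property is that it captures
# acquisition signatures (borders, grain, markers, brightness) at least as
# strongly as any disease signal, which is what the audit is about. An
# adapter hook accepts an external featurizer (e.g. a real CNN's 2048-d
# penultimate layer exported to CSV).

#' Preprocess one image: downscale, pad, standardize
#'
#' Aspect-preserving bilinear downscale so the longer side equals `size`,
#' symmetric zero-padding of the shorter side to `size` (odd pad pixels go
#' to the bottom/right), then per-image standardization to mean 0 /
#' standard deviation 1. A constant image has no scale and is returned as
#' all zeros with a warning.
#'
#' @param image numeric matrix.
#' @param size output side length (default 299, the classical CNN input).
#' @return `size` x `size` standardized matrix.
#' @export
preprocess_image <- function(image, size = 299) {
  if (!is.matrix(image) || !length(image)) ca_stop("image must be a matrix")
  if (sd(as.vector(image)) < 1e-12) {
    warning("constant image; returning zero array")
    return(matrix(0, size, size))
  }
  d <- dim(image)
  if (max(d) > size) {
    s <- size / max(d)
    nh <- max(1L, round(d[1] * s)); nw <- max(1L, round(d[2] * s))
    image <- EBImage::resize(EBImage::Image(image), w = nh, h = nw)
    image <- matrix(EBImage::imageData(image), nh, nw)
  }
  d <- dim(image)
  padr <- size - d[1]; padc <- size - d[2]
  out <- matrix(0, size, size)
  r0 <- padr %/% 2; c0 <- padc %/% 2
  out[r0 + seq_len(d[1]), c0 + seq_len(d[2])] <- image
  mu <- mean(out); s <- sd(as.vector(out))
  if (s < 1e-12) {
    warning("constant image; returning zero array")
    return(matrix(0, size, size))
  }
  (out - mu) / s
}

# standardize rows of an images-as-rows matrix (size already uniform)
ca_standardize_rows <- function(X) {
  mu <- rowMeans(X)
  s <- sqrt(pmax(rowMeans(X^2) - mu^2, 0))
  zero <- s < 1e-12
  if (any(zero)) {
    warning(sum(zero), " constant image(s); set to zeros")
    s[zero] <- 1
  }
  out <- (X - mu) / s
  out[zero, ] <- 0
  out
}

#' Featurizer specification
#'
#' @param type `"filter_bank"` (built-in) or `"external"`.
#' @param dim feature dimensionality; for the filter bank must be
#'   `4 * g^2` for an integer pooling grid `g` (default 256, g = 8).
#' @param fn for `type = "external"`: a function mapping an images-as-rows
#'   matrix to an n x dim feature matrix (e.g. a CNN embedding adapter).
#' @return object of class `featurizer_spec`.
#' @export
featurizer_spec <- function(type = c("filter_bank", "external"), dim = 256,
                            fn = NULL) {
  type <- match.arg(type)
  if (type == "filter_bank") {
    g <- sqrt(dim / 4)
    if (g != round(g) || g < 1)
      ca_stop("filter_bank dim must be 4 * g^2 for integer g (got %d)", dim)
  } else if (!is.function(fn)) {
    ca_stop("external featurizer needs fn")
  }
  structure(list(type = type, dim = as.integer(dim), fn = fn),
            class = "featurizer_spec")
}

# reference R implementation of the filter bank (test oracle for the
# compiled path; not used in production)
ca_filter_bank_r <- function(X, size, g) {
  M <- ca_pool_matrix(size, g)
  idx <- matrix(seq_len(size * size), size, size)
  dxi <- as.vector(idx[, c(2:size, size)])
  dyi <- as.vector(idx[c(2:size, size), ])
  m1 <- as.matrix(X %*% M)
  sds <- sqrt(pmax(as.matrix(X^2 %*% M) - m1^2, 0))
  gx <- as.matrix(abs(X[, dxi, drop = FALSE] - X) %*% M)
  gy <- as.matrix(abs(X[, dyi, drop = FALSE] - X) %*% M)
  cbind(m1, sds, gx, gy)
}

# pooling matrix: pixels (column-major, size x size) -> g x g block means
ca_pool_matrix <- function(size, g) {
  brk <- ceiling(seq_len(size) / (size / g))
  # column-major: row index varies fastest
  px_block <- (brk[rep(seq_len(size), each = size)] - 1) * g +
    brk[rep(seq_len(size), times = size)]
  M <- Matrix::sparseMatrix(i = seq_len(size * size), j = px_block, x = 1,
                            dims = c(size * size, g * g))
  M %*% Matrix::Diagonal(g * g, 1 / Matrix::colSums(M))
}

#' Featurize images with the fixed filter bank
#'
#' Per image: g x g grid-pooled means, pooled standard deviations, and
#' pooled horizontal / vertical absolute gradient energies (orientation
#' sensitive, so laterality markers and borders are visible to downstream
#' models). Deterministic, and the output row order follows the input.
#'
#' @param images images-as-rows matrix (from [render_images()] /
#'   [ca_standardize_rows()]) or a list of equally-sized matrices.
#' @param spec a [featurizer_spec()].
#' @param standardize standardize each image to mean 0 / sd 1 first
#'   (default TRUE; the preprocessing contract).
#' @return n x dim feature matrix, rownames preserved.
#' @export
featurize <- function(images, spec = featurizer_spec(),
                      standardize = TRUE) {
  if (is.list(images) && !is.matrix(images)) {
    dims <- vapply(images, function(m) dim(m), integer(2))
    if (length(unique(dims[1, ])) > 1 || length(unique(dims[2, ])) > 1 ||
        any(dims[1, ] != dims[2, ]))
      ca_stop("all images must be square and identically sized")
    X <- t(vapply(images, as.vector, numeric(length(images[[1]]))))
    rownames(X) <- names(images)
  } else X <- images
  size <- round(sqrt(ncol(X)))
  if (size * size != ncol(X)) ca_stop("images must be square")
  if (spec$type == "external") {
    if (standardize) X <- ca_standardize_rows(X)
    feats <- spec$fn(X)
    if (!is.matrix(feats) || nrow(feats) != nrow(X))
      ca_stop("external featurizer returned a malformed matrix")
    rownames(feats) <- rownames(X)
    return(feats)
  }
  g <- as.integer(sqrt(spec$dim / 4))
  feats <- ca_filter_bank(X, size, g, standardize = standardize)
  colnames(feats) <- c(paste0("mean_", seq_len(g * g)),
                   paste0("sd_", seq_len(g * g)),
                   paste0("gx_", seq_len(g * g)),
                   paste0("gy_", seq_len(g * g)))
  rownames(feats) <- rownames(X)
  feats
}

#' Reduce a feature matrix to its leading principal components
#'
#' The rotation is fit on the training rows only (exact SVD via
#' [stats::prcomp()]); every row is then projected with the training
#' loadings, so test rows never influence the subspace.
#'
#' @param features n x p feature matrix.
#' @param k number of components (default 10).
#' @param train logical vector of training rows (default: all rows).
#' @return list of class `pca_reduction`: `scores` (n x k, rownames kept),
#'   `loadings` (p x k, orthonormal), `center`, `explained` (fraction of
#'   training variance per component, non-increasing), `k`.
#' @export
pca_reduce <- function(features, k = 10, train = NULL) {
  train <- train %||% rep(TRUE, nrow(features))
  Xtr <- features[train, , drop = FALSE]
  pc <- prcomp(Xtr, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-9)
  if (k > rank)
    ca_stop("k = %d exceeds the rank (%d) of the training features", k, rank)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- sweep(features, 2, pc$center) %*% load
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = load, center = pc$center,
                 explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
                 k = k),
            class = "pca_reduction")
}

#' Project new features onto a fitted PCA reduction
#' @param pca a `pca_reduction`.
#' @param features n x p matrix with the same columns the PCA was fit on.
#' @return n x k score matrix.
#' @export
pca_project <- function(pca, features) {
  s <- sweep(features, 2, pca$center) %*% pca$loadings
  colnames(s) <- paste0("PC", seq_len(pca$k))
  s
}

#' Persist / restore a PCA reduction as JSON
#'
#' Stores the training mean, loadings and explained-variance fractions so
#' new cohorts can be projected without refitting.
#'
#' @param pca a `pca_reduction`.
#' @param path JSON file.
#' @return `path` invisibly; `read_pca()` returns a `pca_reduction`
#'   without scores.
#' @export
write_pca <- function(pca, path) {
  jsonlite::write_json(
    list(center = as.list(setNames(pca$center, names(pca$center))),
         loadings = apply(pca$loadings, 2, identity, simplify = FALSE),
         explained = pca$explained, k = pca$k,
         feature_names = rownames(pca$loadings)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pca
#' @export
read_pca <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  load <- do.call(cbind, x$loadings)
  rownames(load) <- x$feature_names
  colnames(load) <- paste0("PC", seq_len(x$k))
  structure(list(scores = NULL, loadings = load,
                 center = unlist(x$center), explained = x$explained,
                 k = x$k),
            class = "pca_reduction")
}

#' R-squared of each principal component against each covariate
#'
#' Regresses every PC score on every covariate (factors expand to
#' indicator columns) and reports the coefficient of determination --
#' the screen used to name which acquisition variable dominates each
#' component. Constant covariates get R^2 = 0.
#'
#' @param pc_scores n x k matrix of PC scores.
#' @param covariates data.frame of covariates (rows aligned with scores).
#' @return data.frame (pc, covariate, r2), sorted by decreasing r2 within
#'   each PC.
#' @export
pc_covariate_r2 <- function(pc_scores, covariates) {
  out <- list()
  for (v in names(covariates)) {
    x <- covariates[[v]]
    ok <- !is.na(x)
    for (j in seq_len(ncol(pc_scores))) {
      y <- pc_scores[ok, j]
      xi <- x[ok]
      tss <- sum((y - mean(y))^2)
      if (tss < 1e-12 || length(unique(xi)) < 2) {
        r2 <- 0
      } else {
        X <- if (is.numeric(xi)) cbind(1, xi) else
          model.matrix(~ factor(xi))
        fit <- lm.fit(X, y)
        r2 <- max(0, 1 - sum(fit$residuals^2) / tss)
      }
      out[[length(out) + 1L]] <- data.frame(
        pc = colnames(pc_scores)[j] %||% paste0("PC", j),
        covariate = v, r2 = r2, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$pc, -res$r2), ]
}
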