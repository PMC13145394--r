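# In-fold preprocessing: k-NN imputation of MCAR cells, one-hot encoding,
# log transform of right-skewed columns, min-max scaling, and removal of
# zero-variance columns. Every statistic is learned from training rows only;
# transform() is a pure function thereafter.

moment_skewness <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3) return(0)
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# nan-Euclidean distances from each query row to each reference row:
# squared distance over mutually observed columns, rescaled by
# n_cols / n_observed (sklearn convention).
nan_euclidean <- function(Q, R) {
  p <- ncol(Q)
  Qo <- !is.na(Q); Ro <- !is.na(R)
  Q0 <- Q; Q0[!Qo] <- 0
  R0 <- R; R0[!Ro] <- 0
  # sum over shared columns of (q - r)^2, via masked cross products
  sq <- (Q0^2) %*% t(Ro) - 2 * Q0 %*% t(R0) + Qo %*% t(R0^2)
  shared <- Qo %*% t(Ro)
  d2 <- ifelse(shared > 0, p * sq / shared, Inf)
  sqrt(pmax(d2, 0))
}

knn_impute <- function(M, ref, k) {
  need <- which(rowSums(is.na(M)) > 0)
  if (!length(need)) return(M)
  col_means <- colMeans(ref, na.rm = TRUE)
  col_means[!is.finite(col_means)] <- 0
  D <- nan_euclidean(M[need, , drop = FALSE], ref)
  for (qi in seq_along(need)) {
    r <- need[qi]
    miss_cols <- which(is.na(M[r, ]))
    ord <- order(D[qi, ])
    for (j in miss_cols) {
      donors <- ord[!is.na(ref[ord, j]) & is.finite(D[qi, ord])]
      if (length(donors)) {
        M[r, j] <- mean(ref[head(donors, k), j])
      } else {
        M[r, j] <- col_means[j]
      }
    }
  }
  M
}

#' Fit the in-fold preprocessor on training rows
#'
#' Learns, from the training rows only: the k-NN imputer reference (raw
#' numeric training matrix, nan-Euclidean distances, sklearn-style), the
#' set of right-skewed columns to `log1p`-transform (moment skewness >
#' `skew_threshold` and non-negative), one-hot vocabularies for
#' categorical/logical columns, min-max bounds per continuous column, and
#' the zero-variance columns to drop. Apply with `predict(pp, X)`.
#'
#' @param X training feature data.frame (numeric + factor/character/logical
#'   columns; MCAR cells are `NA`).
#' @param k neighbors for imputation (default 5).
#' @param skew_threshold skewness above which a column is log-transformed
#'   (default 1).
#' @return object of class `preprocessor`.
#' @export
fit_preprocessor <- function(X, k = 5, skew_threshold = 1) {
  is_cat <- vapply(X, function(col)
    is.factor(col) || is.character(col) || is.logical(col), logical(1))
  num_cols <- names(X)[!is_cat]
  cat_cols <- names(X)[is_cat]

  M <- as.matrix(X[, num_cols, drop = FALSE])
  storage.mode(M) <- "double"
  ref <- M
  M_imp <- knn_impute(M, ref, k)

  skews <- vapply(num_cols, function(j) moment_skewness(M_imp[, j]),
                  numeric(1))
  mins0 <- suppressWarnings(apply(M_imp, 2, min, na.rm = TRUE))
  log_cols <- num_cols[skews > skew_threshold & mins0 >= 0]
  T_ <- M_imp
  for (j in log_cols) T_[, j] <- log1p(T_[, j])

  mins <- apply(T_, 2, min); maxs <- apply(T_, 2, max)
  rng <- maxs - mins
  rng[rng == 0] <- 1  # constant columns map to 0 and are dropped below

  vocab <- lapply(X[, cat_cols, drop = FALSE], function(col) {
    if (is.logical(col)) c("FALSE", "TRUE") else
      if (is.factor(col)) levels(col) else sort(unique(as.character(col)))
  })

  pp <- list(num_cols = num_cols, cat_cols = cat_cols, vocab = vocab,
             ref = ref, k = k, log_cols = log_cols,
             mins = mins, rng = rng)
  class(pp) <- "preprocessor"
  # determine zero-variance drops from the transformed training matrix
  Z <- predict_preprocessor_raw(pp, X)
  keep <- apply(Z, 2, function(col) var(col) > 1e-10)
  pp$keep_cols <- colnames(Z)[keep]
  pp
}

# transform without the column drop (used once during fitting)
predict_preprocessor_raw <- function(pp, X) {
  M <- as.matrix(X[, pp$num_cols, drop = FALSE])
  storage.mode(M) <- "double"
  M <- knn_impute(M, pp$ref, pp$k)
  for (j in pp$log_cols) M[, j] <- log1p(pmax(M[, j], 0))
  M <- sweep(sweep(M, 2, pp$mins[pp$num_cols]), 2, pp$rng[pp$num_cols], `/`)
  oh <- lapply(pp$cat_cols, function(cn) {
    v <- pp$vocab[[cn]]
    col <- as.character(X[[cn]])
    out <- matrix(0, nrow(X), length(v),
                  dimnames = list(NULL, paste0(cn, "_", v)))
    hit <- match(col, v)
    ok <- !is.na(hit)
    out[cbind(which(ok), hit[ok])] <- 1
    out
  })
  do.call(cbind, c(list(M), oh))
}

#' @param object a `preprocessor`.
#' @param X data.frame with the same columns the preprocessor was fitted
#'   on.
#' @param ... unused.
#' @rdname fit_preprocessor
#' @export
predict.preprocessor <- function(object, X, ...) {
  Z <- predict_preprocessor_raw(object, X)
  Z[, object$keep_cols, drop = FALSE]
}
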