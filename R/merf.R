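#' Fit a mixed-effect random forest (MERF)
#'
#' Combines a random forest, which learns a global nonlinear function
#' `f(x)` by pooling rows across participants, with per-participant random
#' intercepts `b_i ~ N(0, sigma_b^2)` estimated by an EM-style alternation:
#'
#' 1. fit the forest on `(X, y - b[group])`;
#' 2. with `r_i` the residuals `y - f(X)` of participant `i` (out-of-bag
#'    forest predictions, to avoid the forest absorbing the intercepts),
#'    update each intercept by random-intercept shrinkage (BLUP):
#'    `b_i = mean(r_i) * sigma_b^2 / (sigma_b^2 + sigma_eps^2 / n_i)`;
#' 3. update the variance components by the EM moment formulas:
#'    `sigma_b^2 = mean_i(b_i^2 + v_i)` and
#'    `sigma_eps^2 = mean_it((r_it - b_i)^2) + mean_i weighted posterior
#'    variance`, where `v_i = (sigma_eps^2 / n_i) * shrinkage_i` is the
#'    posterior intercept variance.
#'
#' Iteration stops when the relative change of the penalized generalized
#' log-likelihood criterion falls below `tol` or after `max_iter` rounds;
#' the criterion trace is recorded for audit.
#'
#' @param X numeric matrix/data.frame of features (no missing values).
#' @param y numeric outcome.
#' @param groups participant id per row (>= 2 distinct ids; with a single
#'   id the model degenerates to a plain forest, with a warning).
#' @param num.trees,mtry,min.node.size forest hyperparameters (passed to
#'   [ranger::ranger()]).
#' @param max_iter maximum EM iterations (default 10).
#' @param tol relative-change convergence tolerance on the criterion
#'   (default 0.01; bootstrap refit noise keeps the criterion jittering at
#'   the percent level, so a tighter tolerance rarely triggers).
#' @param use_oob use out-of-bag predictions for the in-loop residuals
#'   (default TRUE; rows never out of bag fall back to in-sample).
#' @param sigma2_b_fixed optionally pin the intercept variance (e.g. 0 to
#'   disable the random effects entirely, collapsing MERF onto the plain
#'   forest); `NULL` (default) estimates it.
#' @param seed RNG seed for the forest.
#' @return object of class `merf_model`: `forest`, `intercepts` (named),
#'   `sigma2_b`, `sigma2_eps`, `trace`, `converged`, `n_iter`.
#' @export
fit_merf <- function(X, y, groups, num.trees = 100, mtry = NULL,
                     min.node.size = 5, max_iter = 10, tol = 0.01,
                     use_oob = TRUE, sigma2_b_fixed = NULL, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  stopifnot(nrow(X) == length(y), length(groups) == length(y))
  if (any(!is.finite(X))) stop("non-finite feature values: impute first")
  groups <- as.character(groups)
  uids <- unique(groups)
  if (length(uids) < 2) {
    warning("single participant: MERF degenerates to a plain random forest")
  }
  n_i <- table(groups)[uids]
  b <- setNames(rep(0, length(uids)), uids)
  sigma2_eps <- var(y)
  pm <- tapply(y, groups, mean)[uids]
  sigma2_b <- if (length(uids) >= 2) var(as.numeric(pm)) else 0
  if (!is.finite(sigma2_b)) sigma2_b <- 0
  if (!is.null(sigma2_b_fixed)) sigma2_b <- sigma2_b_fixed

  trace <- numeric(0)
  converged <- FALSE
  forest <- NULL
  dat <- as.data.frame(X)
  names(dat) <- paste0("f", seq_len(ncol(X)))
  for (it in seq_len(max_iter)) {
    dat$.target <- y - b[groups]
    forest <- ranger::ranger(
      dependent.variable.name = ".target", data = dat,
      num.trees = num.trees, mtry = mtry, min.node.size = min.node.size,
      seed = seed, num.threads = 1)
    fhat <- if (use_oob) {
      oob <- forest$predictions
      miss <- !is.finite(oob)
      if (any(miss))
        oob[miss] <- predict(forest, data = dat[miss, , drop = FALSE],
                             num.threads = 1)$predictions
      oob
    } else {
      predict(forest, data = dat, num.threads = 1)$predictions
    }
    r <- y - fhat
    r_bar <- tapply(r, groups, mean)[uids]
    shrink <- if (sigma2_b > 0)
      sigma2_b / (sigma2_b + sigma2_eps / as.numeric(n_i)) else
        rep(0, length(uids))
    b <- setNames(as.numeric(r_bar) * shrink, uids)
    v_i <- shrink * sigma2_eps / as.numeric(n_i)  # posterior variances
    resid <- r - b[groups]
    sigma2_eps <- mean(resid^2) + sum(as.numeric(n_i) * v_i) / length(y)
    sigma2_b <- if (is.null(sigma2_b_fixed)) mean(b^2 + v_i) else
      sigma2_b_fixed
    sigma2_eps <- max(sigma2_eps, 1e-8)

    # penalized criterion (generalized log-likelihood of the mixed part),
    # computed from in-sample forest residuals: the out-of-bag residuals
    # used for the intercept update re-randomize every refit and would put
    # bootstrap noise into the convergence signal
    r_in <- y - predict(forest, data = dat, num.threads = 1)$predictions -
      b[groups]
    gll <- sum(r_in^2) / sigma2_eps +
      (if (sigma2_b > 0) sum(b^2) / sigma2_b else 0) +
      length(y) * log(sigma2_eps) +
      (if (sigma2_b > 0) length(uids) * log(sigma2_b) else 0)
    trace <- c(trace, gll)
    if (it >= 2) {
      rel <- abs(trace[it] - trace[it - 1]) /
        max(abs(trace[it - 1]), .Machine$double.eps)
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  if (!converged && max_iter > 1)
    warning("MERF did not converge in ", max_iter,
            " iterations; returning last iterate")
  out <- list(forest = forest, intercepts = b, sigma2_b = sigma2_b,
              sigma2_eps = sigma2_eps, trace = trace,
              converged = converged, n_iter = length(trace),
              feature_names = names(dat)[names(dat) != ".target"])
  class(out) <- "merf_model"
  out
}

#' Predict from a fitted MERF
#'
#' `yhat = f(X) + b[group]`, with `b = 0` for participants unseen at fit
#' time (cold start: a new user needs an initial stretch of data before
#' their intercept can be estimated).
#'
#' @param object a `merf_model`.
#' @param X feature matrix.
#' @param groups participant ids per row.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.merf_model <- function(object, X, groups, ...) {
  X <- as.matrix(X)
  dat <- as.data.frame(X)
  names(dat) <- object$feature_names
  fhat <- predict(object$forest, data = dat, num.threads = 1)$predictions
  badd <- object$intercepts[as.character(groups)]
  badd[is.na(badd)] <- 0
  as.numeric(fhat) + as.numeric(badd)
}
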