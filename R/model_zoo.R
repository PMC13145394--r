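# Eleven modeling approaches behind one fit/predict contract. Every fit_*
# function takes a numeric feature matrix (post imputation/encoding/scaling),
# the outcome, and per-row participant ids; every predict method is defined
# for any ids, including participants never seen at fit time.

#' Intercept-only benchmark models
#'
#' `fit_global_intercept()` predicts the grand mean of the training outcome
#' for everyone. `fit_person_intercept()` predicts each participant's
#' training mean, falling back to the grand mean for unseen participants
#' (cold start).
#'
#' @param y numeric training outcome (non-empty).
#' @param groups participant ids per row.
#' @return objects of class `intercept_model`.
#' @export
fit_global_intercept <- function(y, groups = NULL) {
  stopifnot(length(y) >= 1)
  out <- list(global_mean = mean(y), person_means = NULL)
  class(out) <- "intercept_model"
  out
}

#' @rdname fit_global_intercept
#' @export
fit_person_intercept <- function(y, groups) {
  stopifnot(length(y) >= 1, length(groups) == length(y))
  pm <- tapply(y, as.character(groups), mean)
  out <- list(global_mean = mean(y),
              person_means = setNames(as.numeric(pm), names(pm)))
  class(out) <- "intercept_model"
  out
}

#' @param object an `intercept_model`.
#' @param X ignored (kept for the shared contract).
#' @param ... unused.
#' @rdname fit_global_intercept
#' @export
predict.intercept_model <- function(object, X = NULL, groups = NULL, ...) {
  n <- if (!is.null(groups)) length(groups) else nrow(X)
  if (is.null(object$person_means)) return(rep(object$global_mean, n))
  p <- object$person_means[as.character(groups)]
  p[is.na(p)] <- object$global_mean
  as.numeric(p)
}

#' Fit a population-based learner
#'
#' One of: ordinary least-squares linear regression, a random forest
#' (ranger), or a feedforward neural network (fully connected ReLU hidden
#' layers, linear output). Person-stable "+PS" variants are the same
#' learners on an augmented feature matrix; the caller controls the columns.
#'
#' @param learner_kind `"linear"`, `"forest"` or `"ffnn"`.
#' @param X numeric feature matrix (no non-finite values).
#' @param y numeric outcome.
#' @param hyper named list of hyperparameters: forest `num.trees`, `mtry`,
#'   `min.node.size`; ffnn `hidden`, `epochs`, `lr`, `l2`; linear none.
#' @param seed RNG seed.
#' @return object of class `population_model`.
#' @export
fit_population <- function(learner_kind = c("linear", "forest", "ffnn"),
                           X, y, hyper = list(), seed = 1L) {
  learner_kind <- match.arg(learner_kind)
  X <- as.matrix(X); storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite feature values: impute first")
  fit <- switch(learner_kind,
    linear = {
      dat <- as.data.frame(X)
      names(dat) <- paste0("f", seq_len(ncol(X)))
      dat$.y <- y
      lm(.y ~ ., data = dat)
    },
    forest = {
      dat <- as.data.frame(X)
      names(dat) <- paste0("f", seq_len(ncol(X)))
      dat$.y <- y
      ranger::ranger(dependent.variable.name = ".y", data = dat,
                     num.trees = hyper$num.trees %||% 200,
                     mtry = hyper$mtry,
                     min.node.size = hyper$min.node.size %||% 5,
                     seed = seed, num.threads = 1)
    },
    ffnn = {
      set.seed(seed)
      par <- mlp_init(ncol(X), hyper$hidden %||% c(32), seed = seed,
                      y_mean = mean(y))
      mlp_train(par, X, y, epochs = hyper$epochs %||% 300,
                lr = hyper$lr %||% 0.01, l2 = hyper$l2 %||% 1e-4)
    })
  out <- list(kind = learner_kind, fit = fit, n_features = ncol(X))
  class(out) <- "population_model"
  out
}

#' @param object a `population_model`.
#' @rdname fit_population
#' @export
predict.population_model <- function(object, X, ...) {
  X <- as.matrix(X)
  switch(object$kind,
    linear = {
      dat <- as.data.frame(X)
      names(dat) <- paste0("f", seq_len(ncol(X)))
      as.numeric(predict(object$fit, newdata = dat))
    },
    forest = {
      dat <- as.data.frame(X)
      names(dat) <- paste0("f", seq_len(ncol(X)))
      as.numeric(predict(object$fit, data = dat,
                         num.threads = 1)$predictions)
    },
    ffnn = mlp_forward(object$fit, X)$yhat)
}

#' Fit the embedding-personalized feedforward network
#'
#' Each participant id is mapped to a dense `d`-dimensional embedding
#' vector, concatenated with the (already scaled) sensor features and fed
#' through the fully connected network; embeddings and network weights are
#' learned jointly by gradient descent on the squared error. At prediction
#' time, unseen participants receive the mean of the learned embedding rows
#' (cold start); [finetune_embeddings()] adapts new users' rows while every
#' other parameter stays frozen.
#'
#' @param X numeric feature matrix.
#' @param y numeric outcome.
#' @param person_ids participant id per row.
#' @param d embedding dimension, 32 or 64 (default 32).
#' @param hyper list: `hidden`, `epochs`, `lr`, `l2`.
#' @param seed RNG seed; a fixed seed reproduces the weights exactly.
#' @return object of class `embed_net_model` with `params` (weights +
#'   embedding table), `id_levels`, `curve` (training loss).
#' @export
fit_embed_net <- function(X, y, person_ids, d = 32, hyper = list(),
                          seed = 1L) {
  if (d <= 0) stop("embedding dimension must be positive")
  if (!d %in% c(32, 64))
    warning("embedding dimension outside the standard {32, 64} set")
  X <- as.matrix(X); storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite feature values: impute first")
  ids <- as.character(person_ids)
  levels <- sort(unique(ids))
  idx <- match(ids, levels)
  set.seed(seed)
  par <- mlp_init(ncol(X), hyper$hidden %||% c(32), n_ids = length(levels),
                  d = d, seed = seed, y_mean = mean(y))
  par <- mlp_train(par, X, y, emb_idx = idx,
                   epochs = hyper$epochs %||% 300,
                   lr = hyper$lr %||% 0.01, l2 = hyper$l2 %||% 1e-4)
  out <- list(params = par, id_levels = levels, d = d,
              curve = par$curve, finetuned_ids = character(0))
  class(out) <- "embed_net_model"
  out
}

#' @param object an `embed_net_model`.
#' @rdname fit_embed_net
#' @export
predict.embed_net_model <- function(object, X, groups, ...) {
  X <- as.matrix(X)
  ids <- as.character(groups)
  par <- object$params
  idx <- match(ids, object$id_levels)
  if (anyNA(idx)) {
    # unseen participants: append one mean-embedding row and point at it
    par$E <- rbind(par$E, colMeans(par$E))
    idx[is.na(idx)] <- nrow(par$E)
  }
  mlp_forward(par, X, emb_idx = idx)$yhat
}

#' Fine-tune only the embedding rows for new users
#'
#' Creates fresh embedding rows for the new participant ids (initialized at
#' the mean of the learned rows) and optimizes them on the adaptation data;
#' all network weights and all existing users' embedding rows are frozen
#' and remain bit-identical to their pre-adaptation values.
#'
#' @param model a fitted `embed_net_model`.
#' @param X_new,y_new adaptation rows for the new users.
#' @param new_ids participant id per adaptation row; must be disjoint from
#'   the training ids.
#' @param epochs,lr fine-tuning budget (defaults 200, 0.05).
#' @return the adapted `embed_net_model`.
#' @export
finetune_embeddings <- function(model, X_new, y_new, new_ids, epochs = 200,
                                lr = 0.05) {
  ids <- as.character(new_ids)
  if (any(ids %in% model$id_levels))
    stop("new_ids must be disjoint from training ids")
  uniq <- sort(unique(ids))
  par <- model$params
  mean_row <- colMeans(par$E)
  new_rows <- matrix(rep(mean_row, each = length(uniq)),
                     nrow = length(uniq), ncol = length(mean_row))
  par$E <- rbind(par$E, new_rows)
  levels <- c(model$id_levels, uniq)
  if (length(y_new) == 0) {
    warning("empty adaptation set: embeddings stay at initialization")
  } else {
    X_new <- as.matrix(X_new)
    idx <- match(ids, levels)
    rows <- length(model$id_levels) + seq_along(uniq)
    par <- mlp_train(par, X_new, y_new, emb_idx = idx, epochs = epochs,
                     lr = lr, l2 = 0, trainable = "embedding",
                     trainable_rows = rows)
  }
  model$params <- par
  model$id_levels <- levels
  model$finetuned_ids <- uniq
  model
}

#' Registry of the eleven modeling approaches
#'
#' Maps model names to fit/predict closures under the shared contract, with
#' flags for whether a model uses the person-stable feature block and
#' whether it is personalized (carries a model-internal representation of
#' the individual). `adapt` is non-NULL only for the two approaches that
#' support holdout adaptation: the per-person intercept (recomputed means)
#' and the embedding network (embedding-only fine-tuning).
#'
#' @param hyper named list of per-model hyperparameter defaults (see
#'   [default_hyper()]).
#' @return named list of model descriptors.
#' @export
model_registry <- function(hyper = default_hyper()) {
  h <- hyper
  reg <- list(
    global_intercept = list(
      label = "Global Intercept", uses_ps = FALSE, personalized = FALSE,
      fit = function(X, y, groups, seed) fit_global_intercept(y),
      predict = function(m, X, groups) predict(m, X, groups = groups)),
    per_person_intercept = list(
      label = "Per Person Intercept", uses_ps = FALSE, personalized = TRUE,
      fit = function(X, y, groups, seed) fit_person_intercept(y, groups),
      predict = function(m, X, groups) predict(m, X, groups = groups),
      adapt = function(m, X, y, groups) fit_person_intercept(y, groups)),
    lr = list(
      label = "LR", uses_ps = FALSE, personalized = FALSE,
      fit = function(X, y, groups, seed)
        fit_population("linear", X, y, seed = seed),
      predict = function(m, X, groups) predict(m, X)),
    rf = list(
      label = "RF", uses_ps = FALSE, personalized = FALSE,
      fit = function(X, y, groups, seed)
        fit_population("forest", X, y, hyper = h$rf, seed = seed),
      fit_hyper = function(X, y, groups, hy, seed)
        fit_population("forest", X, y, hyper = hy, seed = seed),
      predict = function(m, X, groups) predict(m, X)),
    ffnn = list(
      label = "FFNN", uses_ps = FALSE, personalized = FALSE,
      fit = function(X, y, groups, seed)
        fit_population("ffnn", X, y, hyper = h$ffnn, seed = seed),
      fit_hyper = function(X, y, groups, hy, seed)
        fit_population("ffnn", X, y, hyper = hy, seed = seed),
      predict = function(m, X, groups) predict(m, X)),
    lr_ps = list(
      label = "LR + PS", uses_ps = TRUE, personalized = FALSE,
      fit = function(X, y, groups, seed)
        fit_population("linear", X, y, seed = seed),
      predict = function(m, X, groups) predict(m, X)),
    rf_ps = list(
      label = "RF + PS", uses_ps = TRUE, personalized = FALSE,
      fit = function(X, y, groups, seed)
        fit_population("forest", X, y, hyper = h$rf, seed = seed),
      fit_hyper = function(X, y, groups, hy, seed)
        fit_population("forest", X, y, hyper = hy, seed = seed),
      predict = function(m, X, groups) predict(m, X)),
    ffnn_ps = list(
      label = "FFNN + PS", uses_ps = TRUE, personalized = FALSE,
      fit = function(X, y, groups, seed)
        fit_population("ffnn", X, y, hyper = h$ffnn, seed = seed),
      fit_hyper = function(X, y, groups, hy, seed)
        fit_population("ffnn", X, y, hyper = hy, seed = seed),
      predict = function(m, X, groups) predict(m, X)),
    merf = list(
      label = "MERF", uses_ps = FALSE, personalized = TRUE,
      fit = function(X, y, groups, seed)
        fit_merf(X, y, groups, num.trees = h$merf$num.trees,
                 max_iter = h$merf$max_iter, tol = h$merf$tol, seed = seed),
      predict = function(m, X, groups) predict(m, X, groups)),
    merf_ps = list(
      label = "MERF + PS", uses_ps = TRUE, personalized = TRUE,
      fit = function(X, y, groups, seed)
        fit_merf(X, y, groups, num.trees = h$merf$num.trees,
                 max_iter = h$merf$max_iter, tol = h$merf$tol, seed = seed),
      predict = function(m, X, groups) predict(m, X, groups)),
    ffnn_embedding = list(
      label = "FFNN + Embedding", uses_ps = FALSE, personalized = TRUE,
      fit = function(X, y, groups, seed)
        fit_embed_net(X, y, groups, d = h$embed$d, hyper = h$embed,
                      seed = seed),
      predict = function(m, X, groups) predict(m, X, groups),
      adapt = function(m, X, y, groups)
        finetune_embeddings(m, X, y, groups,
                            epochs = h$embed$finetune_epochs,
                            lr = h$embed$finetune_lr))
  )
  reg
}

#' Default hyperparameters for the model zoo
#'
#' Small, desk-scale defaults; the grids explored by [grid_search()] are
#' separate (see [default_grids()]).
#'
#' @return named list of hyperparameter lists.
#' @export
default_hyper <- function() {
  list(rf = list(num.trees = 200, min.node.size = 5),
       ffnn = list(hidden = c(32), epochs = 300, lr = 0.01, l2 = 1e-4),
       merf = list(num.trees = 100, max_iter = 8, tol = 0.01),
       embed = list(d = 32, hidden = c(32), epochs = 300, lr = 0.1,
                    l2 = 1e-4, finetune_epochs = 200, finetune_lr = 0.05))
}
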