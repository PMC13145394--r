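#' Build the outer split plan
#'
#' User-based split: about `holdout_frac` of participants (at least one)
#' form a holdout set, sampled within quantile strata of per-person row
#' count (default 4 bins, largest-remainder allocation) so the holdout
#' mirrors the cohort's sampling intensity. Time-based split: within every
#' user (known and holdout), the chronologically first `train_frac` of rows
#' go to train/adaptation and the rest to test; with fractional 80% the
#' train share is floored.
#'
#' @param ds an `assembled_dataset`.
#' @param holdout_frac fraction of users held out, in (0, 0.5).
#' @param train_frac chronological train share per user (default 0.8).
#' @param n_bins strata for the per-person row count (default 4).
#' @param seed RNG seed for the holdout draw.
#' @return object of class `split_plan` with `holdout_users`, and row index
#'   vectors `train_idx`, `test_idx` (known users) and `adapt_idx`,
#'   `holdout_test_idx` (holdout users).
#' @export
make_split <- function(ds, holdout_frac = 0.1, train_frac = 0.8,
                       n_bins = 4, seed = 1L) {
  if (holdout_frac <= 0 || holdout_frac >= 0.5)
    stop("holdout_frac must lie in (0, 0.5)")
  groups <- as.character(ds$groups)
  users <- sort(unique(groups))
  if (length(users) < 10) stop("need at least 10 participants to split")
  counts <- table(groups)[users]

  set.seed(seed)
  br <- unique(quantile(as.numeric(counts),
                        probs = seq(0, 1, length.out = n_bins + 1)))
  stratum <- cut(as.numeric(counts), breaks = br, include.lowest = TRUE)
  target <- max(1L, round(holdout_frac * length(users)))
  # largest-remainder allocation of the holdout across strata
  sizes <- table(stratum)
  exact <- target * as.numeric(sizes) / length(users)
  alloc <- floor(exact)
  rem <- target - sum(alloc)
  if (rem > 0) {
    ord <- order(exact - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  alloc <- pmin(alloc, as.numeric(sizes))
  holdout <- character(0)
  for (s in seq_along(levels(stratum))) {
    pool <- users[which(as.integer(stratum) == s)]
    if (alloc[s] > 0)
      holdout <- c(holdout, sample(pool, alloc[s]))
  }

  split_user <- function(u) {
    rows <- which(groups == u)
    rows <- rows[order(ds$timestamp[rows])]
    n_tr <- floor(train_frac * length(rows))
    list(train = rows[seq_len(n_tr)],
         test = rows[setdiff(seq_along(rows), seq_len(n_tr))])
  }
  known <- setdiff(users, holdout)
  ktr <- lapply(known, split_user)
  htr <- lapply(holdout, split_user)
  out <- list(holdout_users = holdout,
              train_idx = unlist(lapply(ktr, `[[`, "train")),
              test_idx = unlist(lapply(ktr, `[[`, "test")),
              adapt_idx = unlist(lapply(htr, `[[`, "train")),
              holdout_test_idx = unlist(lapply(htr, `[[`, "test")),
              holdout_frac = holdout_frac, train_frac = train_frac,
              seed = seed)
  class(out) <- "split_plan"
  out
}

#' Expanding-window cross-validation folds
#'
#' Splits each participant's rows (restricted to `rows`) chronologically
#' into `k` near-equal chunks. Fold `i` trains on everyone's chunks
#' `1..i-1` and validates on chunk `i`; the first fold is skipped so the
#' training set is never empty, yielding `k - 1` folds.
#'
#' @param ds an `assembled_dataset`.
#' @param rows row indices to fold (typically the split plan's train rows).
#' @param k number of chunks (default 5, giving 4 folds).
#' @return list of `k - 1` folds, each `list(train =, val =)` of row
#'   indices.
#' @export
make_folds <- function(ds, rows, k = 5) {
  groups <- as.character(ds$groups)[rows]
  chunk <- integer(length(rows))
  for (u in unique(groups)) {
    sel <- which(groups == u)
    sel <- sel[order(ds$timestamp[rows[sel]])]
    chunk[sel] <- as.integer(cut(seq_along(sel), breaks = k, labels = FALSE))
  }
  lapply(2:k, function(i)
    list(train = rows[chunk < i], val = rows[chunk == i]))
}

#' Regression metrics
#'
#' MAE, RMSE and R-squared with the evaluated split's own label mean as the
#' baseline (so a global-mean predictor scores near zero and worse models go
#' negative).
#'
#' @param pred,obs equal-length numeric vectors, length >= 2.
#' @return one-row data.frame `mae`, `rmse`, `r2`, `n`.
#' @export
evaluate_metrics <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  if (length(obs) < 2) stop("need at least 2 rows")
  err <- obs - pred
  data.frame(mae = mean(abs(err)),
             rmse = sqrt(mean(err^2)),
             r2 = 1 - sum(err^2) / sum((obs - mean(obs))^2),
             n = length(obs))
}

# feature columns for a model variant
dataset_matrix <- function(ds, rows, uses_ps = FALSE) {
  cols <- c(ds$feature_info$passive, ds$feature_info$context)
  if (uses_ps) cols <- c(cols, ds$feature_info$ps)
  ds$X[rows, cols, drop = FALSE]
}

#' Exhaustive hyperparameter search over expanding-window folds
#'
#' Evaluates every configuration in `grid` on the fold plan, refitting the
#' preprocessor inside each fold's training rows (no leakage of validation
#' statistics). Best = lowest mean validation MAE; ties are broken toward
#' the configuration with fewest hyperparameters, then grid order.
#'
#' @param ds an `assembled_dataset`.
#' @param fold_plan folds from [make_folds()].
#' @param fit_fun `function(X, y, groups, hyper, seed)` returning a model.
#' @param predict_fun `function(model, X, groups)` returning predictions.
#' @param grid non-empty list of named hyperparameter lists.
#' @param uses_ps include the person-stable block.
#' @param seed seed forwarded to fits.
#' @return list `best` (the winning hyper list), `results` (data.frame of
#'   mean MAE per configuration).
#' @export
grid_search <- function(ds, fold_plan, fit_fun, predict_fun, grid,
                        uses_ps = FALSE, seed = 1L) {
  if (!length(grid)) stop("empty hyperparameter grid")
  mean_mae <- vapply(grid, function(hy) {
    maes <- vapply(fold_plan, function(fold) {
      Xtr_raw <- dataset_matrix(ds, fold$train, uses_ps)
      pp <- fit_preprocessor(Xtr_raw)
      Xtr <- predict(pp, Xtr_raw)
      Xva <- predict(pp, dataset_matrix(ds, fold$val, uses_ps))
      m <- fit_fun(Xtr, ds$y[fold$train],
                   as.character(ds$groups)[fold$train], hy, seed)
      mean(abs(ds$y[fold$val] -
                 predict_fun(m, Xva, as.character(ds$groups)[fold$val])))
    }, numeric(1))
    mean(maes)
  }, numeric(1))
  n_par <- vapply(grid, length, integer(1))
  ord <- order(mean_mae, n_par, seq_along(grid))
  list(best = grid[[ord[1]]],
       results = data.frame(config = seq_along(grid), mean_mae = mean_mae,
                            n_hyper = n_par))
}

#' Run the two evaluation scenarios for every registered model
#'
#' Scenario `"time"` (known users): every model is trained on the known
#' users' chronologically first 80% and evaluated on their last 20%.
#' Scenario `"new_user"`: the same fitted models predict the holdout users'
#' last 20% without any adaptation, except the per-person intercept and the
#' embedding network, which first adapt on the holdout users' first 80%
#' (the embedding model via embedding-only fine-tuning; all other weights
#' frozen). Preprocessor statistics always come from the known users'
#' training rows.
#'
#' @param ds an `assembled_dataset` (use the `with_PS` variant so the +PS
#'   models find their columns).
#' @param registry model registry (default [model_registry()]).
#' @param split a [make_split()] plan (built from `seed` if NULL).
#' @param seed seed for splitting and model fits.
#' @param tune if TRUE, run [grid_search()] per tunable model with
#'   `grids`; default FALSE (registry defaults).
#' @param grids named list of hyperparameter grids (see [default_grids()]).
#' @param r2_baseline `"test"` (default) uses the evaluated split's own
#'   label mean in R-squared; `"train"` uses the training-label mean.
#' @return data.frame: one row per model x scenario with MAE, RMSE, R2 and
#'   row counts.
#' @export
run_scenarios <- function(ds, registry = model_registry(), split = NULL,
                          seed = 1L, tune = FALSE, grids = default_grids(),
                          r2_baseline = c("test", "train")) {
  r2_baseline <- match.arg(r2_baseline)
  if (is.null(split)) split <- make_split(ds, seed = seed)
  groups <- as.character(ds$groups)
  res <- list()
  for (name in names(registry)) {
    spec <- registry[[name]]
    Xtr_raw <- dataset_matrix(ds, split$train_idx, spec$uses_ps)
    pp <- fit_preprocessor(Xtr_raw)
    Xtr <- predict(pp, Xtr_raw)
    ytr <- ds$y[split$train_idx]
    gtr <- groups[split$train_idx]
    if (tune && !is.null(grids[[name]])) {
      folds <- make_folds(ds, split$train_idx)
      gs <- grid_search(ds, folds,
                        fit_fun = function(X, y, g, hy, s)
                          spec$fit_hyper(X, y, g, hy, s),
                        predict_fun = spec$predict,
                        grid = grids[[name]], uses_ps = spec$uses_ps,
                        seed = seed)
      model <- spec$fit_hyper(Xtr, ytr, gtr, gs$best, seed)
    } else {
      model <- spec$fit(Xtr, ytr, gtr, seed)
    }

    score <- function(pred, obs) {
      m <- evaluate_metrics(pred, obs)
      if (r2_baseline == "train")
        m$r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(ytr))^2)
      m
    }

    # scenario A: time-based holdout in known users
    Xte <- predict(pp, dataset_matrix(ds, split$test_idx, spec$uses_ps))
    pA <- spec$predict(model, Xte, groups[split$test_idx])
    mA <- score(pA, ds$y[split$test_idx])

    # scenario B: new users, adaptation only where the contract allows it
    model_b <- model
    if (!is.null(spec$adapt) && length(split$adapt_idx)) {
      Xad <- predict(pp, dataset_matrix(ds, split$adapt_idx, spec$uses_ps))
      model_b <- spec$adapt(model, Xad, ds$y[split$adapt_idx],
                            groups[split$adapt_idx])
    }
    Xho <- predict(pp, dataset_matrix(ds, split$holdout_test_idx,
                                      spec$uses_ps))
    pB <- spec$predict(model_b, Xho, groups[split$holdout_test_idx])
    mB <- score(pB, ds$y[split$holdout_test_idx])

    res[[length(res) + 1]] <- cbind(
      data.frame(model = name, label = spec$label,
                 scenario = c("time", "new_user"),
                 stringsAsFactors = FALSE),
      rbind(mA, mB))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "n_holdout_users") <- length(split$holdout_users)
  out
}

#' Default hyperparameter grids for tuning
#'
#' Deliberately small, desk-scale grids.
#'
#' @return named list of grids (lists of hyperparameter lists).
#' @export
default_grids <- function() {
  list(rf = list(list(num.trees = 200, min.node.size = 5),
                 list(num.trees = 200, min.node.size = 20)),
       ffnn = list(list(hidden = c(16), epochs = 300, lr = 0.01),
                   list(hidden = c(32), epochs = 300, lr = 0.01)))
}

#' Render the results table as Markdown
#'
#' One table per scenario, rows = models in registry order, columns = MAE,
#' R2, RMSE — the shape of the study's report artifact.
#'
#' @param results a [run_scenarios()] data.frame.
#' @return single character string of Markdown.
#' @export
format_report <- function(results) {
  fm <- function(x) formatC(x, digits = 3, format = "f")
  out <- character(0)
  for (sc in unique(results$scenario)) {
    r <- results[results$scenario == sc, ]
    title <- if (sc == "time") "Time-based holdout (known users)" else
      "New-user holdout"
    out <- c(out, paste0("## ", title), "",
             "| Model | MAE | R2 | RMSE |", "|---|---|---|---|",
             sprintf("| %s | %s | %s | %s |", r$label, fm(r$mae), fm(r$r2),
                     fm(r$rmse)),
             "")
  }
  paste(out, collapse = "\n")
}
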