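default_traits <- c("PH", "PeD", "IL1", "IL2")

#' Model configurations matching the study's tuned settings
#'
#' Constructors for the four predictor configurations: stepwise multiple
#' linear regression over PH, PeD, IL1, IL2 with a 0.05 entry level; a
#' feed-forward network with hidden layers 3-9-8, learning rate 0.2,
#' momentum 0.1, 2000 iterations; epsilon-SVR with RBF kernel, gamma
#' 0.004, C 0.1 (epsilon defaults to 0.1); and a 100-tree random forest
#' with 2 candidate features per split and minimum leaf size 4.
#'
#' @param candidates candidate predictor columns (MLR).
#' @param alpha_enter entry significance level for the partial F-test.
#' @param learning_rate,momentum,iterations,hidden_layers network training
#'   settings.
#' @param kernel,gamma,C,epsilon SVR settings.
#' @param n_trees,features_per_split,min_samples_leaf forest settings.
#' @param seed fit seed where the fitter is stochastic.
#' @return a config list with a `kind` field.
#' @name model_configs
NULL

#' @rdname model_configs
#' @export
mlr_config <- function(candidates = default_traits, alpha_enter = 0.05) {
  stopifnot(alpha_enter > 0)
  list(kind = "mlr", candidates = candidates, alpha_enter = alpha_enter)
}

#' @rdname model_configs
#' @export
ann_config <- function(learning_rate = 0.2, momentum = 0.1,
                       iterations = 2000, hidden_layers = c(3, 9, 8),
                       seed = 1) {
  stopifnot(learning_rate > 0, momentum >= 0, iterations > 0,
            all(hidden_layers > 0))
  list(kind = "ann", learning_rate = learning_rate, momentum = momentum,
       iterations = iterations, hidden_layers = hidden_layers, seed = seed)
}

#' @rdname model_configs
#' @export
svr_config <- function(kernel = "rbf", gamma = 0.004, C = 0.1,
                       epsilon = 0.1) {
  stopifnot(gamma > 0, C > 0, epsilon > 0)
  list(kind = "svr", kernel = kernel, gamma = gamma, C = C,
       epsilon = epsilon)
}

#' @rdname model_configs
#' @export
rf_config <- function(n_trees = 100, features_per_split = 2,
                      min_samples_leaf = 4, seed = 1) {
  stopifnot(n_trees > 0, features_per_split > 0, min_samples_leaf > 0)
  list(kind = "rf", n_trees = n_trees,
       features_per_split = features_per_split,
       min_samples_leaf = min_samples_leaf, seed = seed)
}

#' Deterministic train/test split of a trait table
#'
#' Simple random partition: `round(n * train_fraction)` rows to training,
#' the rest to testing. The same seed always yields the same partition.
#'
#' @param table trait data.frame with at least 8 rows.
#' @param train_fraction proportion in (0, 1); default 0.75.
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_train_test <- function(table, train_fraction = 0.75, seed = 1) {
  n <- nrow(table)
  if (n < 8L) stop("need at least 8 rows to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie in (0, 1)", call. = FALSE)
  }
  n_train <- round(n * train_fraction)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = table[sort(idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), idx), , drop = FALSE])
}

check_trait_table <- function(table, columns, response = "LS") {
  need <- c(columns, response)
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("trait table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (cn in need) {
    if (any(!is.finite(table[[cn]]))) {
      stop("missing or non-finite values in modeling column ", cn,
           call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Forward stepwise multiple linear regression with an entry F-test
#'
#' At each step the candidate with the largest partial R-squared (the
#' increment in model R-squared it would produce) enters, provided its
#' partial F-test p-value is below `alpha_enter`; selection stops when no
#' candidate qualifies. The trace records, per step, the entered variable,
#' its partial R-squared, the cumulative model R-squared, and the entered
#' variable's variance inflation factor against the variables already in
#' the model (1 for the first entry). Ties in partial R-squared are broken
#' by candidate column order.
#'
#' @param train trait data.frame.
#' @param config an [mlr_config()].
#' @param response response column (default `"LS"`).
#' @return object of class `lodge_model` with fields `fit` (an `lm`),
#'   `trace` (data.frame `step`, `entered`, `partial_r2`, `model_r2`,
#'   `vif`), `features`.
#' @export
stepwise_mlr <- function(train, config = mlr_config(), response = "LS") {
  check_trait_table(train, config$candidates, response)
  y <- train[[response]]
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("constant response: nothing to regress", call. = FALSE)
  entered <- character()
  remaining <- config$candidates
  rss_old <- tss
  trace <- data.frame(step = integer(), entered = character(),
                      partial_r2 = numeric(), model_r2 = numeric(),
                      vif = numeric(), stringsAsFactors = FALSE)
  repeat {
    if (!length(remaining)) break
    stats_cand <- lapply(remaining, function(cand) {
      xm <- cbind(1, as.matrix(train[c(entered, cand)]))
      qrx <- qr(xm)
      if (qrx$rank < ncol(xm)) {
        stop("degenerate design: ", cand,
             " is collinear with {", paste(entered, collapse = ", "), "}",
             call. = FALSE)
      }
      rss <- sum(qr.resid(qrx, y)^2)
      p <- ncol(xm)
      f <- (rss_old - rss) / (rss / (n - p))
      list(partial_r2 = (rss_old - rss) / tss,
           p_value = stats::pf(f, 1, n - p, lower.tail = FALSE),
           rss = rss)
    })
    pr2 <- vapply(stats_cand, `[[`, numeric(1), "partial_r2")
    best <- which.max(pr2)  # first max wins: column-order tie-break
    if (stats_cand[[best]]$p_value >= config$alpha_enter) break
    cand <- remaining[best]
    v <- if (length(entered)) {
      unname(vif(as.matrix(train[c(entered, cand)]))[length(entered) + 1L])
    } else {
      1.0
    }
    rss_old <- stats_cand[[best]]$rss
    entered <- c(entered, cand)
    remaining <- setdiff(remaining, cand)
    trace <- rbind(trace, data.frame(
      step = length(entered), entered = cand,
      partial_r2 = pr2[best], model_r2 = 1 - rss_old / tss, vif = v,
      stringsAsFactors = FALSE))
  }
  fml <- if (length(entered)) {
    stats::reformulate(entered, response)
  } else {
    stats::reformulate("1", response)
  }
  fit <- stats::lm(fml, data = train)
  structure(list(kind = "mlr", fit = fit, trace = trace,
                 features = entered, response = response),
            class = "lodge_model")
}

minmax_fit <- function(x) {
  list(min = apply(x, 2, min), range = apply(x, 2, function(v) {
    r <- diff(range(v))
    if (r == 0) 1 else r
  }))
}

minmax_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$min), 2, sc$range, "/")
}

#' Fit the feed-forward network predictor
#'
#' Inputs are min-max scaled to \[0, 1\] on the training split (the same
#' affine map is applied at prediction time); the score target is left on
#' its native \[0, 1\] scale. Training is per-pattern (online)
#' backpropagation with momentum for a fixed number of epochs, with
#' seeded weight initialization, so fits are reproducible.
#'
#' @param train trait data.frame.
#' @param config an [ann_config()].
#' @param features predictor columns.
#' @param response response column.
#' @return object of class `lodge_model`.
#' @export
fit_ann <- function(train, config = ann_config(),
                    features = default_traits, response = "LS") {
  check_trait_table(train, features, response)
  x <- as.matrix(train[features])
  sc <- minmax_fit(x)
  xs <- minmax_apply(x, sc)
  layers <- mlp_train(xs, train[[response]],
                      hidden = config$hidden_layers,
                      learning_rate = config$learning_rate,
                      momentum = config$momentum,
                      iterations = config$iterations,
                      seed = config$seed)
  structure(list(kind = "ann", layers = layers, scaling = sc,
                 features = features, response = response),
            class = "lodge_model")
}

#' Fit the epsilon-SVR predictor
#'
#' RBF-kernel epsilon-SVR at the configured gamma, C and epsilon; inputs
#' min-max scaled to \[0, 1\] on the training split.
#'
#' @inheritParams fit_ann
#' @param config an [svr_config()].
#' @return object of class `lodge_model`.
#' @export
fit_svr <- function(train, config = svr_config(),
                    features = default_traits, response = "LS") {
  check_trait_table(train, features, response)
  if (nrow(train) < 2L) {
    stop("SVR needs at least two training rows", call. = FALSE)
  }
  x <- as.matrix(train[features])
  sc <- minmax_fit(x)
  xs <- minmax_apply(x, sc)
  kern <- if (config$kernel == "rbf") "radial" else config$kernel
  fit <- e1071::svm(x = xs, y = train[[response]],
                    type = "eps-regression", kernel = kern,
                    gamma = config$gamma, cost = config$C,
                    epsilon = config$epsilon, scale = FALSE,
                    fitted = FALSE)
  structure(list(kind = "svr", fit = fit, scaling = sc,
                 features = features, response = response),
            class = "lodge_model")
}

#' Fit the random-forest predictor
#'
#' 100 bootstrap regression trees by default, 2 candidate features per
#' split, minimum 4 samples per leaf; seeded, so fits are reproducible.
#' Raw trait units are used (forests are scale-invariant).
#'
#' @inheritParams fit_ann
#' @param config an [rf_config()].
#' @return object of class `lodge_model`.
#' @export
fit_rf <- function(train, config = rf_config(),
                   features = default_traits, response = "LS") {
  check_trait_table(train, features, response)
  if (nrow(train) < 2L * config$min_samples_leaf) {
    stop("too few rows for the configured minimum leaf size", call. = FALSE)
  }
  fit <- with_seed(config$seed, {
    randomForest::randomForest(
      x = as.matrix(train[features]), y = train[[response]],
      ntree = config$n_trees,
      mtry = min(config$features_per_split, length(features)),
      nodesize = config$min_samples_leaf)
  })
  structure(list(kind = "rf", fit = fit, features = features,
                 response = response),
            class = "lodge_model")
}

#' Predict lodging scores from a fitted model
#'
#' @param object a `lodge_model`.
#' @param newdata data.frame with the model's feature columns.
#' @param ... unused.
#' @return numeric vector of predicted scores.
#' @export
predict.lodge_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    stop("newdata is missing feature columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  switch(object$kind,
    mlr = as.vector(stats::predict(object$fit, newdata = newdata)),
    ann = {
      xs <- minmax_apply(as.matrix(newdata[object$features]),
                         object$scaling)
      mlp_predict(object$layers, xs)
    },
    svr = {
      xs <- minmax_apply(as.matrix(newdata[object$features]),
                         object$scaling)
      if (object$fit$tot.nSV == 0L) {
        # every training target inside the epsilon tube: the solution is
        # the bare intercept
        rep(-object$fit$rho, nrow(xs))
      } else {
        as.vector(stats::predict(object$fit, newdata = xs))
      }
    },
    rf = as.vector(stats::predict(object$fit,
                                  newdata = as.matrix(newdata[object$features]))),
    stop("unknown model kind: ", object$kind, call. = FALSE)
  )
}

#' Evaluate a fitted model on a table
#'
#' @param model a `lodge_model`.
#' @param table trait data.frame with the model's schema.
#' @param split_label `"training"` or `"testing"`, carried into the output.
#' @return list with `predictions` (data.frame `observed`, `predicted`,
#'   `split`) and `report` (one-row metric data.frame).
#' @export
evaluate_model <- function(model, table,
                           split_label = c("testing", "training")) {
  split_label <- match.arg(split_label)
  check_trait_table(table, model$features, model$response)
  pred <- predict(model, table)
  obs <- table[[model$response]]
  list(predictions = data.frame(observed = obs, predicted = pred,
                                split = split_label,
                                stringsAsFactors = FALSE),
       report = evaluate_predictions(obs, pred))
}

#' Fit one model from a config
#'
#' @param train training data.frame.
#' @param config one of the [model_configs] lists.
#' @param features predictor columns (ignored by MLR, which uses its own
#'   candidate list).
#' @return a `lodge_model`.
#' @export
fit_model <- function(train, config, features = default_traits) {
  switch(config$kind,
         mlr = stepwise_mlr(train, config),
         ann = fit_ann(train, config, features),
         svr = fit_svr(train, config, features),
         rf = fit_rf(train, config, features),
         stop("unknown model kind: ", config$kind, call. = FALSE))
}

#' Fit and compare several predictors on one shared split
#'
#' All configs are fitted on the same training split and evaluated on both
#' splits. The grid is ranked by testing R-squared (descending), ties by
#' testing RMSE (ascending).
#'
#' @param table trait data.frame.
#' @param configs named list of model configs (>= 2 for a comparison; one
#'   is allowed and yields a single-row grid).
#' @param train_fraction,split_seed split settings shared by all models.
#' @return list of class `lodge_comparison` with `grid` (model x split
#'   metric rows plus `rank`), `scatter` (per-model observed/predicted
#'   with a within-band flag), `split_sizes`, `split_seed`.
#' @export
compare_models <- function(table, configs,
                           train_fraction = 0.75, split_seed = 1) {
  if (!length(configs)) stop("no model configs given", call. = FALSE)
  if (is.null(names(configs)) || any(!nzchar(names(configs)))) {
    names(configs) <- vapply(configs, `[[`, character(1), "kind")
  }
  sp <- split_train_test(table, train_fraction, split_seed)
  grid <- list(); scatter <- list()
  for (nm in names(configs)) {
    model <- fit_model(sp$train, configs[[nm]])
    for (split in c("training", "testing")) {
      tab <- if (split == "training") sp$train else sp$test
      ev <- evaluate_model(model, tab, split)
      grid[[length(grid) + 1L]] <-
        cbind(data.frame(model = nm, split = split,
                         stringsAsFactors = FALSE), ev$report)
      sc <- ev$predictions
      sc$model <- nm
      sc$within_band <- ifelse(
        sc$observed == 0, abs(sc$predicted) <= 0.01,
        abs(sc$predicted - sc$observed) <= 0.25 * sc$observed)
      scatter[[length(scatter) + 1L]] <- sc
    }
  }
  grid <- do.call(rbind, grid)
  test_rows <- grid[grid$split == "testing", ]
  ord <- order(-test_rows$r2, test_rows$rmse)
  rank_map <- stats::setNames(seq_along(ord), test_rows$model[ord])
  grid$rank <- as.integer(rank_map[grid$model])
  grid <- grid[order(grid$rank, grid$split), ]
  rownames(grid) <- NULL
  structure(list(grid = grid, scatter = do.call(rbind, scatter),
                 split_sizes = c(train = nrow(sp$train),
                                 test = nrow(sp$test)),
                 split_seed = split_seed,
                 train_fraction = train_fraction),
            class = "lodge_comparison")
}
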