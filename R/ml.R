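# Supervised learning on feature tables with interpretable attribution:
# activity labeling, train/test splitting (random-rows or grouped),
# gradient-boosted trees and baseline models, standard metrics, exact
# Shapley attributions for tree models (with a seeded sampling fallback),
# mean-|attribution| feature ranking, and the four end-to-end schemes.

#' Binary activity label from an IC50
#'
#' Strictly below the threshold is `strong`, above is `weak`; exactly at
#' the threshold is `weak` (the strict definitions leave the boundary
#' unassigned, and the conservative choice is the weaker class).
#'
#' @param ic50 IC50 in micromolar (> 0); vectorized.
#' @param threshold class boundary in micromolar (default 0.050).
#' @return factor with levels `c("weak", "strong")`.
#' @export
label_activity <- function(ic50, threshold = 0.050) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("invalid-parameter: IC50 must be finite and > 0")
  factor(ifelse(ic50 < threshold, "strong", "weak"),
         levels = c("weak", "strong"))
}

#' Model specification
#'
#' @param task `"classification"` or `"regression"`.
#' @param algorithm one of `"xgboost"`, `"knn"`, `"lr"` (logistic/linear
#'   regression), `"rf"`, `"svm"`, `"dt"`.
#' @param params named list of hyperparameters. For `xgboost` the defaults
#'   are learning rate 0.1, `nrounds` 500, `max_depth` 11,
#'   `min_child_weight` 4 (the full-scale tree count of 10000 is available
#'   by overriding `nrounds`); `knn` takes `k` (default 5).
#' @param split training fraction in (0, 1), default 0.70.
#' @param seed master seed.
#' @param n_replicates replicate count for [run_scheme()] (default 1).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(task = c("classification", "regression"),
                       algorithm = c("xgboost", "knn", "lr", "rf", "svm", "dt"),
                       params = list(), split = 0.70, seed = 1,
                       n_replicates = 1) {
  task <- match.arg(task)
  algorithm <- match.arg(algorithm)
  stopifnot(split > 0, split < 1, n_replicates >= 1)
  defaults <- switch(algorithm,
                     xgboost = list(eta = 0.1, nrounds = 500, max_depth = 11,
                                    min_child_weight = 4),
                     knn = list(k = 5),
                     rf = list(ntree = 200),
                     list())
  defaults[names(params)] <- params
  if (!is.null(defaults$nrounds) && defaults$nrounds < 1)
    stop("invalid-parameter: tree count must be >= 1")
  structure(list(task = task, algorithm = algorithm, params = defaults,
                 split = split, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "model_spec")
}

.feature_cols <- function(table) {
  setdiff(names(table), c("label", "group"))
}

.feature_matrix <- function(table) {
  as.matrix(table[, .feature_cols(table), drop = FALSE])
}

#' Split a feature table into train and test sets
#'
#' `random-rows` splits frames independently of their origin, so frames of
#' one system can land on both sides; `grouped` keeps all frames of a
#' group (one inhibitor/system) on one side, the leakage-safe alternative
#' for frame-correlated data.
#'
#' @param table data frame with a `label` column, optionally `group`.
#' @param fraction training fraction (default 0.70).
#' @param seed RNG seed.
#' @param mode `"random-rows"` (default) or `"grouped"`.
#' @return list with `train` and `test` data frames (disjoint, exhaustive).
#' @export
split_train_test <- function(table, fraction = 0.70, seed = 1,
                             mode = c("random-rows", "grouped")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(table), nrow(table) > 0, "label" %in% names(table))
  set.seed(seed)
  if (mode == "random-rows") {
    n_train <- round(nrow(table) * fraction)
    idx <- sample(nrow(table), n_train)
  } else {
    if (!"group" %in% names(table)) stop("split error: grouped mode needs a group column")
    groups <- unique(table$group)
    if (length(groups) < 2) stop("split error: grouped mode needs >= 2 groups")
    n_g <- max(1, round(length(groups) * fraction))
    g_train <- sample(groups, n_g)
    idx <- which(table$group %in% g_train)
  }
  list(train = table[idx, , drop = FALSE],
       test = table[-idx, , drop = FALSE])
}

#' Train a model on a feature table
#'
#' @param train data frame with `label` (factor for classification, numeric
#'   for regression) and feature columns; a `group` column is ignored.
#' @param spec a [model_spec()].
#' @return a fitted model handle (class `allokin_model`) usable with
#'   [predict_model()], [evaluate()], and [attribute()].
#' @export
train_model <- function(train, spec) {
  stopifnot(inherits(spec, "model_spec"), "label" %in% names(train))
  x <- .feature_matrix(train)
  y <- train$label
  if (spec$task == "classification") {
    y <- factor(y)
    if (nlevels(droplevels(y)) < 2)
      stop("degenerate-label: training set has a single class")
    positive <- if ("strong" %in% levels(y)) "strong" else levels(y)[2]
  } else {
    y <- as.numeric(y)
    if (length(y) < 3) stop("need >= 3 rows for regression")
    positive <- NULL
  }
  set.seed(spec$seed)
  fit <- switch(
    spec$algorithm,
    xgboost = {
      lab <- if (spec$task == "classification")
        as.numeric(y == positive) else y
      obj <- if (spec$task == "classification")
        "binary:logistic" else "reg:squarederror"
      p <- spec$params
      xgboost::xgb.train(
        params = list(objective = obj, eta = p$eta, max_depth = p$max_depth,
                      min_child_weight = p$min_child_weight, nthread = 1,
                      seed = spec$seed),
        data = xgboost::xgb.DMatrix(x, label = lab),
        nrounds = p$nrounds, verbose = 0)
    },
    knn = list(x = x, y = y, k = spec$params$k),
    lr = {
      df <- data.frame(x, check.names = FALSE)
      df$.label <- if (spec$task == "classification")
        as.numeric(y == positive) else y
      if (spec$task == "classification")
        stats::glm(.label ~ ., data = df, family = stats::binomial())
      else stats::lm(.label ~ ., data = df)
    },
    rf = randomForest::randomForest(x, y, ntree = spec$params$ntree),
    svm = e1071::svm(x, y, probability = FALSE),
    dt = {
      df <- data.frame(x, check.names = FALSE)
      df$.label <- y
      rpart::rpart(.label ~ ., data = df,
                   method = if (spec$task == "classification") "class" else "anova")
    })
  structure(list(spec = spec, fit = fit, features = .feature_cols(train),
                 levels = if (spec$task == "classification") levels(y),
                 positive = positive),
            class = "allokin_model")
}

#' Predict with a fitted model handle
#'
#' @param model an `allokin_model`.
#' @param newdata feature table (extra columns `label`/`group` ignored).
#' @param type `"response"` (class label / numeric value) or `"score"`
#'   (numeric score; for classification the probability or margin for the
#'   positive class).
#' @return vector of predictions.
#' @export
predict_model <- function(model, newdata, type = c("response", "score")) {
  type <- match.arg(type)
  if (!all(model$features %in% names(newdata)))
    stop("feature-mismatch: newdata lacks training features")
  x <- as.matrix(newdata[, model$features, drop = FALSE])
  spec <- model$spec
  cls <- spec$task == "classification"
  score <- switch(
    spec$algorithm,
    xgboost = predict(model$fit, xgboost::xgb.DMatrix(x)),
    knn = {
      if (cls) {
        p <- class::knn(model$fit$x, x, model$fit$y, k = model$fit$k,
                        prob = TRUE)
        pr <- attr(p, "prob")
        ifelse(p == model$positive, pr, 1 - pr)
      } else {
        # distance-free regression k-NN: average of k nearest neighbors
        apply(x, 1, function(row) {
          d <- colSums((t(model$fit$x) - row)^2)
          mean(model$fit$y[order(d)[seq_len(model$fit$k)]])
        })
      }
    },
    lr = {
      df <- data.frame(x, check.names = FALSE)
      as.numeric(stats::predict(model$fit, df,
                                type = if (cls) "response" else "response"))
    },
    rf = {
      if (cls) as.numeric(stats::predict(model$fit, x, type = "prob")[, model$positive])
      else as.numeric(stats::predict(model$fit, x))
    },
    svm = {
      p <- stats::predict(model$fit, x)
      if (cls) as.numeric(p == model$positive) else as.numeric(p)
    },
    dt = {
      df <- data.frame(x, check.names = FALSE)
      if (cls) stats::predict(model$fit, df, type = "prob")[, model$positive]
      else as.numeric(stats::predict(model$fit, df))
    })
  if (!cls || type == "score") return(score)
  factor(ifelse(score >= 0.5, model$positive,
                setdiff(model$levels, model$positive)),
         levels = model$levels)
}

#' Evaluate a model on a test table
#'
#' Classification: accuracy, precision, recall, F1 with `strong` as the
#' positive class. Regression: R-squared, MSE, RMSE, MAE.
#'
#' @param model an `allokin_model`.
#' @param test feature table with `label`.
#' @return named list of metrics (`model_metrics`).
#' @export
evaluate <- function(model, test) {
  stopifnot(nrow(test) > 0, "label" %in% names(test))
  pred <- predict_model(model, test)
  if (model$spec$task == "classification") {
    truth <- factor(test$label, levels = model$levels)
    pos <- model$positive
    tp <- sum(pred == pos & truth == pos)
    fp <- sum(pred == pos & truth != pos)
    fn <- sum(pred != pos & truth == pos)
    tn <- sum(pred != pos & truth != pos)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    out <- list(accuracy = (tp + tn) / length(truth), precision = precision,
                recall = recall, f1 = f1)
  } else {
    y <- as.numeric(test$label)
    e <- y - pred
    mse <- mean(e^2)
    vy <- stats::var(y)
    out <- list(r_squared = if (vy > 0) 1 - mse / mean((y - mean(y))^2)
                else NA_real_,
                mse = mse, rmse = sqrt(mse), mae = mean(abs(e)),
                degenerate = vy == 0)
  }
  structure(out, class = "model_metrics")
}

#' Per-sample additive feature attributions
#'
#' For gradient-boosted trees the attributions are the exact tree-path
#' Shapley values (additivity holds to numerical precision in margin
#' space). For other algorithms a seeded permutation-sampling estimate is
#' used, with a warning; additivity then holds only approximately.
#'
#' @param model an `allokin_model`.
#' @param samples feature table of samples to attribute.
#' @param n_permutations permutations per sample for the sampling fallback
#'   (default 128).
#' @return list of class `attribution_matrix`: `values` (samples x
#'   features, signed), `base` (expected model output), `output` (per-sample
#'   model output the attributions sum to, margin scale for classification).
#' @export
attribute <- function(model, samples, n_permutations = 128) {
  x <- as.matrix(samples[, model$features, drop = FALSE])
  if (model$spec$algorithm == "xgboost") {
    contrib <- predict(model$fit, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
    nf <- length(model$features)
    vals <- contrib[, seq_len(nf), drop = FALSE]
    colnames(vals) <- model$features
    base <- contrib[1, nf + 1]
    out <- predict(model$fit, xgboost::xgb.DMatrix(x), outputmargin = TRUE)
  } else {
    warning("exact tree attribution unavailable for algorithm '",
            model$spec$algorithm, "'; using seeded sampling estimate")
    sc <- function(m) {
      colnames(m) <- model$features
      predict_model(model, as.data.frame(m, check.names = FALSE),
                    type = "score")
    }
    set.seed(model$spec$seed)
    base <- mean(sc(x))
    nf <- ncol(x)
    vals <- matrix(0, nrow(x), nf, dimnames = list(NULL, model$features))
    bg <- x[sample(nrow(x), min(32, nrow(x))), , drop = FALSE]
    for (s in seq_len(nrow(x))) {
      acc <- numeric(nf)
      for (p in seq_len(n_permutations)) {
        ord <- sample(nf)
        z <- bg[sample(nrow(bg), 1), ]
        prev <- sc(matrix(z, 1))
        cur <- z
        for (f in ord) {
          cur[f] <- x[s, f]
          now <- sc(matrix(cur, 1))
          acc[f] <- acc[f] + (now - prev)
          prev <- now
        }
      }
      vals[s, ] <- acc / n_permutations
    }
    out <- sc(x)
  }
  structure(list(values = vals, base = base, output = out),
            class = "attribution_matrix")
}

#' Rank features by mean absolute attribution
#'
#' @param attr an `attribution_matrix` from [attribute()].
#' @param k number of top features to keep (default 20); truncated with a
#'   warning when larger than the feature count.
#' @param feature_values optional matrix of the attributed samples'
#'   feature values, used for the directionality summary (fraction of
#'   above-median-value samples with positive attribution).
#' @return data frame with `feature`, `mean_abs_attribution`,
#'   `direction_positive_frac`, ordered descending (name tie-break).
#' @export
rank_features <- function(attr, k = 20, feature_values = NULL) {
  stopifnot(inherits(attr, "attribution_matrix"))
  v <- attr$values
  if (ncol(v) == 0) stop("empty attribution matrix")
  if (k > ncol(v)) {
    warning("k exceeds feature count; truncating")
    k <- ncol(v)
  }
  imp <- colMeans(abs(v))
  dirfrac <- rep(NA_real_, ncol(v))
  if (!is.null(feature_values)) {
    for (j in seq_len(ncol(v))) {
      hi <- feature_values[, j] > stats::median(feature_values[, j])
      if (any(hi)) dirfrac[j] <- mean(v[hi, j] > 0)
    }
  }
  ord <- order(-imp, colnames(v))
  data.frame(feature = colnames(v)[ord],
             mean_abs_attribution = unname(imp[ord]),
             direction_positive_frac = dirfrac[ord])[seq_len(k), ]
}

#' Run one labeling-and-learning scheme end to end
#'
#' Schemes mirror the four feature-family / label pairings: (1) trajectory
#' descriptors vs activity, (2) interaction fingerprints vs activity,
#' (3) residue contacts vs activity, (4) residue contacts vs free energy.
#' Schemes 1-3 take a binary `strong`/`weak` label (classification) or an
#' IC50-derived value (regression); scheme 4 requires a continuous
#' free-energy label and only supports regression.
#'
#' Each replicate draws its own split seed from the master seed, then
#' splits, trains, evaluates, attributes the test samples, and ranks.
#'
#' @param table feature table with `label` (+ optional `group`).
#' @param scheme integer 1-4.
#' @param spec a [model_spec()]; `n_replicates` controls repetition.
#' @param split_mode passed to [split_train_test()].
#' @param k top-k for the ranking (default 20).
#' @return list with `metrics` (one row per replicate), `aggregate`
#'   (mean/sd per metric), and `ranking` (from the first replicate's
#'   model, attributed on its test set).
#' @export
run_scheme <- function(table, scheme, spec, split_mode = "random-rows",
                       k = 20) {
  stopifnot(scheme %in% 1:4, inherits(spec, "model_spec"))
  if (scheme == 4 && spec$task != "regression")
    stop("scheme error: free-energy labels are continuous; use a regression spec")
  if (spec$task == "classification" && !is.factor(table$label) &&
      !is.character(table$label))
    stop("scheme error: classification needs a categorical label")
  rows <- vector("list", spec$n_replicates)
  ranking <- NULL
  for (rep_i in seq_len(spec$n_replicates)) {
    seed_i <- spec$seed + 1000L * (rep_i - 1L)
    sp <- split_train_test(table, fraction = spec$split, seed = seed_i,
                           mode = split_mode)
    spec_i <- spec
    spec_i$seed <- seed_i
    m <- train_model(sp$train, spec_i)
    met <- evaluate(m, sp$test)
    rows[[rep_i]] <- as.data.frame(met[!vapply(met, is.logical, TRUE)])
    if (rep_i == 1L) {
      at <- attribute(m, sp$test)
      ranking <- rank_features(at, k = k,
                               feature_values = as.matrix(
                                 sp$test[, m$features, drop = FALSE]))
    }
  }
  metrics <- do.call(rbind, rows)
  metrics$replicate <- seq_len(nrow(metrics))
  agg <- data.frame(metric = setdiff(names(metrics), "replicate"))
  agg$mean <- vapply(agg$metric, function(m) mean(metrics[[m]]), numeric(1))
  agg$sd <- vapply(agg$metric, function(m) stats::sd(metrics[[m]]), numeric(1))
  list(metrics = metrics, aggregate = agg, ranking = ranking)
}
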