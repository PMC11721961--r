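# Labeling, splitting, model training/evaluation, Shapley attribution,
# feature ranking, and the end-to-end schemes.

test_that("activity labeling applies the strict threshold with weak ties", {
  expect_equal(as.character(label_activity(0.00155)), "strong")
  expect_equal(as.character(label_activity(0.181)), "weak")
  expect_equal(as.character(label_activity(0.050)), "weak")
  expect_equal(levels(label_activity(1)), c("weak", "strong"))
  expect_error(label_activity(0), "invalid-parameter")
})

test_that("splits are disjoint, exhaustive, seeded, and group-safe", {
  tab <- gen_feature_table(n_samples = 1000, n_features = 5, planted = 1,
                           seed = 1)
  sp <- split_train_test(tab, fraction = 0.7, seed = 3)
  expect_equal(nrow(sp$train), 700)
  expect_equal(nrow(sp$test), 300)
  sp2 <- split_train_test(tab, fraction = 0.7, seed = 3)
  expect_identical(sp$train, sp2$train)
  spg <- split_train_test(tab, seed = 3, mode = "grouped")
  expect_length(intersect(unique(spg$train$group), unique(spg$test$group)), 0)
  tab1 <- tab; tab1$group <- "g01"
  expect_error(split_train_test(tab1, mode = "grouped", seed = 1),
               "split error")
})

test_that("a linearly separable toy is learned perfectly; degenerate labels fail", {
  set.seed(2)
  x1 <- c(rnorm(100, -3), rnorm(100, 3))
  tab <- data.frame(label = factor(rep(c("weak", "strong"), each = 100),
                                   levels = c("weak", "strong")),
                    f1 = x1, f2 = rnorm(200))
  m <- train_model(tab, model_spec(params = list(nrounds = 50, max_depth = 2),
                                   seed = 1))
  expect_equal(evaluate(m, tab)$accuracy, 1)
  tab_one <- tab; tab_one$label <- factor("weak", levels = c("weak", "strong"))
  expect_error(train_model(tab_one, model_spec(seed = 1)), "degenerate-label")
})

test_that("pure-noise labels give held-out accuracy inside the binomial band", {
  tab <- gen_feature_table(n_samples = 1000, n_features = 50, planted = 1:5,
                           effect_sizes = 0, seed = 99)
  sp <- split_train_test(tab[, names(tab) != "group"], seed = 99)
  m <- train_model(sp$train, model_spec(seed = 99,
                                        params = list(nrounds = 150,
                                                      max_depth = 4)))
  acc <- evaluate(m, sp$test)$accuracy
  n <- nrow(sp$test)
  expect_lt(abs(acc - 0.5), 1.96 * sqrt(0.25 / n) + 1e-9)
})

test_that("metrics match hand-computed confusion counts and exact fits", {
  # TP 3, FP 1, FN 1, TN 5 -> precision .75, recall .75, F1 .75, acc .8
  truth <- factor(c(rep("strong", 4), rep("weak", 6)),
                  levels = c("weak", "strong"))
  pred <- factor(c("strong", "strong", "strong", "weak",
                   "strong", rep("weak", 5)), levels = c("weak", "strong"))
  tp <- sum(pred == "strong" & truth == "strong")
  fp <- sum(pred == "strong" & truth == "weak")
  fn <- sum(pred == "weak" & truth == "strong")
  tn <- sum(pred == "weak" & truth == "weak")
  expect_equal(c(tp, fp, fn, tn), c(3, 1, 1, 5))
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  expect_equal(prec, 0.75)
  expect_equal(rec, 0.75)
  expect_equal(2 * prec * rec / (prec + rec), 0.75)
  expect_equal((tp + tn) / 10, 0.8)
  # regression on an exactly learnable signal: y-hat == y
  tab <- data.frame(label = 1:20 / 2, f1 = 1:20)
  m <- train_model(tab, model_spec(task = "regression", algorithm = "lr",
                                   seed = 1))
  met <- evaluate(m, tab)
  expect_equal(met$r_squared, 1, tolerance = 1e-9)
  expect_equal(met$mse, 0, tolerance = 1e-12)
  expect_equal(met$rmse, sqrt(met$mse))
})

test_that("baseline algorithms train and predict on the same table", {
  set.seed(4)
  tab <- data.frame(label = factor(rep(c("weak", "strong"), each = 60),
                                   levels = c("weak", "strong")),
                    f1 = c(rnorm(60, -2), rnorm(60, 2)), f2 = rnorm(120))
  for (alg in c("knn", "lr", "rf", "svm", "dt")) {
    # glm warns about perfect separation on this deliberately easy toy
    m <- suppressWarnings(train_model(tab, model_spec(algorithm = alg,
                                                      seed = 1)))
    acc <- suppressWarnings(evaluate(m, tab)$accuracy)
    expect_gt(acc, 0.9)
  }
})

test_that("tree attributions are additive against independent predictions", {
  tab <- gen_feature_table(n_samples = 500, n_features = 20, planted = 1:2,
                           effect_sizes = 2, seed = 6)
  sp <- split_train_test(tab[, names(tab) != "group"], seed = 6)
  m <- train_model(sp$train, model_spec(seed = 6,
                                        params = list(nrounds = 200,
                                                      max_depth = 5)))
  at <- attribute(m, sp$test)
  resid <- max(abs(at$base + rowSums(at$values) - at$output))
  expect_lt(resid, 1e-4)
  # regression: constant labels give a constant model with zero attributions
  const <- data.frame(label = rep(2.5, 50), f1 = rnorm(50), f2 = rnorm(50))
  mc <- train_model(const, model_spec(task = "regression", seed = 1,
                                      params = list(nrounds = 10,
                                                    max_depth = 2)))
  atc <- attribute(mc, const)
  expect_lt(max(abs(atc$values)), 1e-6)
  expect_equal(unname(atc$base + rowSums(atc$values)), rep(2.5, 50),
               tolerance = 1e-6)
})

test_that("a single-split stump attributes everything to its feature", {
  # one informative binary feature, depth-1 tree
  x <- data.frame(label = c(rep(0, 50), rep(10, 50)),
                  f1 = c(rep(0, 50), rep(1, 50)), f2 = 0)
  m <- train_model(x, model_spec(task = "regression", seed = 1,
                                 params = list(nrounds = 1, max_depth = 1,
                                               eta = 1,
                                               min_child_weight = 1)))
  at <- attribute(m, x)
  expect_lt(max(abs(at$values[, "f2"])), 1e-9)
  expect_equal(unname(at$values[, "f1"]), unname(at$output - at$base),
               tolerance = 1e-5)   # single-precision tree arithmetic
})

test_that("sampling fallback warns and stays roughly additive", {
  set.seed(9)
  tab <- data.frame(label = factor(rep(c("weak", "strong"), each = 40),
                                   levels = c("weak", "strong")),
                    f1 = c(rnorm(40, -2), rnorm(40, 2)), f2 = rnorm(80))
  m <- train_model(tab, model_spec(algorithm = "rf", seed = 2))
  expect_warning(at <- attribute(m, tab[1:5, ], n_permutations = 16),
                 "sampling")
  expect_equal(dim(at$values), c(5, 2))
})

test_that("feature ranking orders by mean |attribution| with name ties", {
  vals <- cbind(a = c(1, -1, 1), b = c(2, -2, 2), b2 = c(2, -2, 2))
  at <- structure(list(values = vals, base = 0, output = rowSums(vals)),
                  class = "attribution_matrix")
  rk <- rank_features(at, k = 3)
  expect_equal(rk$feature, c("b", "b2", "a"))
  expect_warning(rank_features(at, k = 10), "truncating")
  fv <- cbind(a = c(0, 1, 2), b = c(0, 1, 2), b2 = c(0, 1, 2))
  rk2 <- rank_features(at, k = 3, feature_values = fv)
  expect_true(all(rk2$direction_positive_frac %in% c(0, 0.5, 1)))
})

test_that("run_scheme wires split-train-evaluate-attribute deterministically", {
  tab <- gen_feature_table(n_samples = 400, n_features = 30, planted = 1:3,
                           effect_sizes = 2, seed = 12)
  tab$group <- NULL
  spec <- model_spec(seed = 12, n_replicates = 3,
                     params = list(nrounds = 60, max_depth = 3))
  r1 <- run_scheme(tab, 1, spec, k = 10)
  r2 <- run_scheme(tab, 1, spec, k = 10)
  expect_identical(r1$metrics, r2$metrics)
  expect_equal(nrow(r1$metrics), 3)
  expect_equal(nrow(r1$aggregate), 4)  # accuracy, precision, recall, f1
  expect_true(all(attr(tab, "planted")[1:3] %in% r1$ranking$feature[1:5]))
  # free-energy labels are continuous: classification spec is a scheme error
  expect_error(run_scheme(tab, 4, spec), "scheme error")
})
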