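# Built-in classifier adapters.
#
# Each adapter wraps one learner from an established R package behind the
# registry contract: fit(x, y, params) with x a numeric matrix (column names
# preserved) and y a factor with sorted levels; predict(model, x) returning a
# probability matrix with class-level column names (or discrete labels, which
# the registry wraps into one-hot vectors). Adapters run under a seeded RNG
# state set by train_classifier(), so learners that draw from R's RNG
# (forests, boosting, neural nets, Platt scaling) are reproducible.
#
# Formula-based learners (rpart) see syntactically safe column names V1..Vp
# internally because post-encoding feature names contain '='; the mapping is
# positional and restored on prediction.

safe_frame <- function(x) {
  df <- as.data.frame(x)
  colnames(df) <- paste0("V", seq_len(ncol(x)))
  df
}

# glmnet requires >= 2 columns; pad single-feature matrices with a constant
# zero column (coefficient 0, harmless) so top-1 feature-count cells work.
pad_two_cols <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, `.pad` = 0)
}

register_builtin_classifiers <- function() {
  register_classifier(
    "rpart/decision_tree",
    fit = function(x, y, params) {
      df <- safe_frame(x)
      df$.class <- y
      rpart::rpart(.class ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     cp = params$cp, maxdepth = params$maxdepth,
                     minsplit = params$minsplit, xval = 0))
    },
    predict = function(model, x) predict(model, newdata = safe_frame(x), type = "prob"),
    default = list(cp = 0.01, maxdepth = 30, minsplit = 20)
  )

  register_classifier(
    "randomForest/random_forest",
    fit = function(x, y, params)
      randomForest::randomForest(x = x, y = y, ntree = params$ntree,
                                 nodesize = params$nodesize),
    predict = function(model, x) predict(model, newdata = x, type = "prob"),
    default = list(ntree = 500, nodesize = 1)
  )

  register_classifier(
    "ranger/random_forest",
    fit = function(x, y, params)
      ranger::ranger(x = x, y = y, num.trees = params$num_trees,
                     min.node.size = params$min_node_size,
                     probability = TRUE, num.threads = 1),
    predict = function(model, x)
      predict(model, data = x, num.threads = 1)$predictions,
    default = list(num_trees = 500, min_node_size = 1)
  )

  register_classifier(
    "xgboost/xgboost",
    fit = function(x, y, params) {
      k <- nlevels(y)
      obj <- if (k == 2) list(objective = "binary:logistic")
             else list(objective = "multi:softprob", num_class = k)
      booster <- xgboost::xgb.train(
        params = c(list(max_depth = params$max_depth, eta = params$eta,
                        nthread = 1, seed = sample.int(10000, 1)), obj),
        data = xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L, nthread = 1),
        nrounds = params$nrounds, verbose = 0)
      list(booster = booster, levels = levels(y))
    },
    predict = function(model, x) {
      p <- predict(model$booster, xgboost::xgb.DMatrix(x, nthread = 1))
      k <- length(model$levels)
      probs <- if (k == 2) cbind(1 - p, p)
               else matrix(as.numeric(p), ncol = k)
      colnames(probs) <- model$levels
      probs
    },
    default = list(nrounds = 50, max_depth = 6, eta = 0.3)
  )

  register_classifier(
    "glmnet/logistic_regression",
    fit = function(x, y, params) {
      x <- pad_two_cols(x)
      fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
      fit <- glmnet::glmnet(x, y, family = fam, alpha = params$alpha,
                            lambda = params$lambda)
      list(fit = fit, lambda = params$lambda, levels = levels(y))
    },
    predict = function(model, x) {
      x <- pad_two_cols(x)
      p <- predict(model$fit, newx = x, s = model$lambda, type = "response")
      if (length(dim(p)) == 3) {
        probs <- p[, , 1, drop = TRUE]
        probs <- matrix(probs, nrow = nrow(x),
                        dimnames = list(NULL, dimnames(p)[[2]]))
      } else {
        probs <- cbind(1 - p[, 1], p[, 1])
        colnames(probs) <- model$levels
      }
      probs
    },
    default = list(alpha = 0, lambda = 1e-3)
  )

  register_classifier(
    "e1071/svm_rbf",
    fit = function(x, y, params)
      e1071::svm(x = x, y = y, kernel = "radial", cost = params$cost,
                 probability = TRUE),
    predict = function(model, x) {
      p <- predict(model, newdata = x, probability = TRUE)
      attr(p, "probabilities")
    },
    default = list(cost = 1)
  )

  register_classifier(
    "e1071/naive_bayes",
    fit = function(x, y, params)
      e1071::naiveBayes(x = as.data.frame(x), y = y, laplace = params$laplace),
    predict = function(model, x)
      predict(model, newdata = as.data.frame(x), type = "raw"),
    default = list(laplace = 0)
  )

  register_classifier(
    "kernlab/svm_linear",
    fit = function(x, y, params)
      kernlab::ksvm(x, y, kernel = "vanilladot", kpar = list(),
                    C = params$C, prob.model = TRUE),
    predict = function(model, x)
      kernlab::predict(model, x, type = "probabilities"),
    default = list(C = 1)
  )

  register_classifier(
    "nnet/mlp",
    fit = function(x, y, params) {
      fit <- nnet::nnet(x, nnet::class.ind(y), size = params$size,
                        decay = params$decay, maxit = params$maxit,
                        softmax = TRUE, trace = FALSE, MaxNWts = 10000)
      list(fit = fit, levels = levels(y))
    },
    predict = function(model, x) {
      probs <- predict(model$fit, x)
      colnames(probs) <- model$levels
      probs
    },
    default = list(size = 3, decay = 0.1, maxit = 150)
  )

  register_classifier(
    "MASS/lda",
    fit = function(x, y, params)
      suppressWarnings(MASS::lda(x, grouping = y)),
    predict = function(model, x) predict(model, x)$posterior,
    default = list()
  )

  register_classifier(
    "caret/knn",
    fit = function(x, y, params) caret::knn3(x, y, k = params$k),
    predict = function(model, x) predict(model, x, type = "prob"),
    default = list(k = 5)
  )
  invisible()
}
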