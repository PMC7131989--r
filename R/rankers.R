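# Built-in feature-ranking adapters.
#
# A ranker returns a named relevance score per feature (higher = more
# relevant); the registry converts scores to an ordered feature list with
# deterministic tie-breaking by feature name. Univariate rankers score each
# feature against the class on its own; the remaining rankers extract
# importances or weights from a fitted multivariate model.

univariate_scores <- function(x, fn) {
  vapply(seq_len(ncol(x)), function(j) {
    s <- tryCatch(fn(x[, j]), error = function(e) NA_real_)
    if (is.na(s) || !is.finite(s)) 0 else s
  }, numeric(1)) -> s
  stats::setNames(s, colnames(x))
}

register_builtin_rankers <- function() {
  register_ranker(
    "univariate/anova_f",
    rank = function(x, y, params)
      univariate_scores(x, function(col)
        stats::oneway.test(col ~ y, var.equal = TRUE)$statistic)
  )

  register_ranker(
    "univariate/kruskal_wallis",
    rank = function(x, y, params)
      univariate_scores(x, function(col) stats::kruskal.test(col, y)$statistic)
  )

  register_ranker(
    "univariate/pearson_cor",
    rank = function(x, y, params)
      univariate_scores(x, function(col) abs(stats::cor(col, as.integer(y))))
  )

  register_ranker(
    "univariate/auroc",
    rank = function(x, y, params) {
      levels <- levels(y)
      univariate_scores(x, function(col) {
        max(vapply(levels, function(l) {
          a <- auroc(col, y == l)
          if (is.na(a)) 0 else abs(a - 0.5)
        }, numeric(1)))
      })
    }
  )

  register_ranker(
    "rpart/importance",
    rank = function(x, y, params) {
      df <- safe_frame(x)
      df$.class <- y
      fit <- rpart::rpart(.class ~ ., data = df, method = "class",
                          control = rpart::rpart.control(xval = 0, cp = 0))
      imp <- fit$variable.importance
      if (is.null(imp)) imp <- numeric(0)
      # map safe names V<j> back to the original feature names
      idx <- as.integer(sub("^V", "", names(imp)))
      stats::setNames(as.numeric(imp), colnames(x)[idx])
    }
  )

  register_ranker(
    "randomForest/gini_importance",
    rank = function(x, y, params) {
      fit <- randomForest::randomForest(x = x, y = y, ntree = params$ntree)
      imp <- fit$importance[, "MeanDecreaseGini"]
      stats::setNames(as.numeric(imp), rownames(fit$importance))
    },
    default = list(ntree = 500)
  )

  register_ranker(
    "ranger/impurity_importance",
    rank = function(x, y, params) {
      fit <- ranger::ranger(x = x, y = y, num.trees = params$num_trees,
                            importance = "impurity", num.threads = 1)
      fit$variable.importance
    },
    default = list(num_trees = 500)
  )

  register_ranker(
    "xgboost/gain",
    rank = function(x, y, params) {
      k <- nlevels(y)
      obj <- if (k == 2) list(objective = "binary:logistic")
             else list(objective = "multi:softprob", num_class = k)
      booster <- xgboost::xgb.train(
        params = c(list(max_depth = 6, eta = 0.3, nthread = 1,
                        seed = sample.int(10000, 1)), obj),
        data = xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L, nthread = 1),
        nrounds = params$nrounds, verbose = 0)
      imp <- xgboost::xgb.importance(model = booster)
      stats::setNames(imp$Gain, imp$Feature)
    },
    default = list(nrounds = 50)
  )

  register_ranker(
    "glmnet/lasso_weights",
    rank = function(x, y, params) {
      xp <- pad_two_cols(x)
      fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
      fit <- glmnet::glmnet(xp, y, family = fam, alpha = 1, lambda = params$lambda)
      co <- glmnet::coef.glmnet(fit, s = params$lambda)
      if (is.list(co)) {
        w <- Reduce(`+`, lapply(co, function(m) abs(as.numeric(m[-1, 1]))))
      } else {
        w <- abs(as.numeric(co[-1, 1]))
      }
      stats::setNames(w, colnames(xp))[colnames(x)]
    },
    default = list(lambda = 0.01)
  )

  register_ranker(
    "e1071/svm_weights",
    rank = function(x, y, params) {
      fit <- e1071::svm(x = x, y = y, kernel = "linear", cost = params$cost)
      w <- crossprod(fit$coefs, fit$SV) # (k*(k-1)/2 binary machines) x features
      stats::setNames(colSums(abs(w)), colnames(fit$SV))
    },
    default = list(cost = 1)
  )
  invisible()
}

.onLoad <- function(libname, pkgname) {
  register_builtin_classifiers()
  register_builtin_rankers()
  load_algorithm_configs()
}
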