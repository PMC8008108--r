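# Classifier registry: 10 binary classifiers behind one fit/predict surface.
# All models are trained on standardized features (training-set statistics)
# and return the predicted probability of the positive class.

#' Available classifiers
#' @return character vector of the 10 classifier identifiers.
#' @export
classifier_registry <- function() {
  c("random_forest", "knn", "logistic", "svm_linear", "svm_rbf",
    "naive_bayes", "decision_tree", "adaboost", "gradient_boosting", "lda")
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  keep <- sdv > 0
  list(mu = mu, sd = ifelse(keep, sdv, 1), keep = keep)
}

standardize_apply <- function(x, st) {
  xs <- sweep(sweep(x, 2, st$mu), 2, st$sd, "/")
  xs[, st$keep, drop = FALSE]
}

# hand-rolled AdaBoost.M1 over depth-1 rpart stumps
fit_adaboost <- function(x, y, n_rounds = 30) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  yy <- ifelse(y == 1, 1, -1)
  df <- data.frame(x, check.names = FALSE)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = cbind(df, y = factor(y)), weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    hp <- ifelse(pred == 1, 1, -1)
    w <- w * exp(-alpha * yy * hp)
    w <- w / sum(w)
    stumps[[m]] <- fit
    alphas[m] <- alpha
    if (err < 1e-8) break
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost <- function(model, x) {
  df <- data.frame(x, check.names = FALSE)
  score <- Reduce(`+`, lapply(seq_along(model$stumps), function(m) {
    pred <- as.integer(as.character(predict(model$stumps[[m]], df,
                                            type = "class")))
    model$alphas[m] * ifelse(pred == 1, 1, -1)
  }))
  1 / (1 + exp(-2 * score))
}

#' Fit a registered classifier
#'
#' @param x numeric feature matrix (training set, columns named).
#' @param y binary labels (0/1), both classes present.
#' @param classifier one of [classifier_registry()].
#' @param seed seed applied before stochastic fits (forests, boosting).
#' @return an object of class `mvb_model`; use [predict_prob()] on new data.
#' @export
fit_classifier <- function(x, y, classifier = "random_forest", seed = 1L) {
  classifier <- match.arg(classifier, classifier_registry())
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  abort_if(length(unique(y)) < 2, "both classes must be present in `y`")
  st <- standardize_fit(x)
  xs <- standardize_apply(x, st)
  yf <- factor(y, levels = c(0, 1))
  set.seed(seed)
  fit <- switch(classifier,
    random_forest = randomForest::randomForest(xs, yf, ntree = 200),
    knn = list(train = xs, y = yf, k = min(5L, nrow(xs) - 1L)),
    logistic = suppressWarnings(
      glm(y ~ ., data = data.frame(xs, y = y, check.names = FALSE),
          family = binomial())),
    svm_linear = e1071::svm(xs, yf, kernel = "linear", probability = TRUE,
                            cost = 1),
    svm_rbf = e1071::svm(xs, yf, kernel = "radial", probability = TRUE,
                         cost = 1),
    naive_bayes = e1071::naiveBayes(xs, yf),
    decision_tree = rpart::rpart(
      y ~ ., data = cbind(data.frame(xs, check.names = FALSE), y = yf),
      method = "class",
      control = rpart::rpart.control(minsplit = 5, cp = 0.01, xval = 0)),
    adaboost = fit_adaboost(xs, y),
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 2, eta = 0.3,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(xs, label = y, nthread = 1),
      nrounds = 40, verbose = 0),
    lda = {
      # lda rejects variables with (near-)zero pooled within-class spread,
      # which small CV folds can produce; restrict it to usable columns
      wsd <- apply(xs, 2, function(v) max(tapply(v, yf, stats::sd)))
      cols <- which(is.finite(wsd) & wsd > 1e-8)
      if (length(cols) == 0) {
        # every column is constant within both classes: break the ties with
        # a deterministic, negligible perturbation so lda can proceed
        xs <- xs + matrix(seq_len(length(xs)) %% 7 - 3, nrow(xs)) * 1e-8
        cols <- seq_len(ncol(xs))
      }
      list(lda = suppressWarnings(MASS::lda(xs[, cols, drop = FALSE],
                                            grouping = yf)),
           cols = cols)
    })
  structure(list(classifier = classifier, fit = fit, standardize = st,
                 features = colnames(x)),
            class = "mvb_model")
}

#' Predict positive-class probabilities
#'
#' @param model an `mvb_model` from [fit_classifier()].
#' @param newdata numeric matrix or data frame with the training features.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, newdata) {
  abort_if(!inherits(model, "mvb_model"), "`model` must be an mvb_model")
  x <- as.matrix(newdata[, model$features, drop = FALSE])
  storage.mode(x) <- "double"
  xs <- standardize_apply(x, model$standardize)
  fit <- model$fit
  p <- switch(model$classifier,
    random_forest = predict(fit, xs, type = "prob")[, "1"],
    knn = {
      pr <- class::knn(fit$train, xs, fit$y, k = fit$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    logistic = predict(fit, data.frame(xs, check.names = FALSE),
                       type = "response"),
    svm_linear = attr(predict(fit, xs, probability = TRUE),
                      "probabilities")[, "1"],
    svm_rbf = attr(predict(fit, xs, probability = TRUE),
                   "probabilities")[, "1"],
    naive_bayes = predict(fit, xs, type = "raw")[, "1"],
    decision_tree = predict(fit, data.frame(xs, check.names = FALSE),
                            type = "prob")[, "1"],
    adaboost = predict_adaboost(fit, xs),
    gradient_boosting = predict(fit, xgboost::xgb.DMatrix(xs, nthread = 1)),
    lda = predict(fit$lda, xs[, fit$cols, drop = FALSE])$posterior[, "1"])
  unname(pmin(pmax(as.numeric(p), 0), 1))
}
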