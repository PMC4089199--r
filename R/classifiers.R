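# Classifier back-ends are plumbing: each is an established implementation
# (e1071, rpart, randomForest, nnet) behind a uniform fit/predict pair.
# x is a dense numeric matrix with descriptor column names, y a factor.

CLASSIFIERS <- c("naive_bayes", "decision_tree", "random_forest",
                 "neural_network", "svm")

fit_classifier <- function(x, y, classifier, params = list()) {
  classifier <- match.arg(classifier, CLASSIFIERS)
  df <- as.data.frame(x, check.names = TRUE)
  # build calls with symbols (not evaluated data) so back-ends that
  # deparse(substitute(y)) for labels see a short name
  call_with <- function(fn, params) {
    eval(as.call(c(list(fn, x = quote(df), y = quote(y)), params)))
  }
  model <- switch(classifier,
    naive_bayes = call_with(quote(e1071::naiveBayes), params),
    decision_tree = {
      df$.class <- y
      do.call(rpart::rpart,
              c(list(formula = .class ~ ., data = df, method = "class"),
                params))
    },
    random_forest = call_with(quote(randomForest::randomForest), params),
    neural_network = {
      defaults <- list(size = 10, maxit = 500, trace = FALSE,
                       MaxNWts = 100000)
      do.call(nnet::nnet,
              c(list(x = x, y = nnet::class.ind(y), softmax = TRUE),
                modifyList(defaults, params)))
    },
    svm = call_with(quote(e1071::svm), params)
  )
  structure(list(classifier = classifier, model = model,
                 features = colnames(df)[colnames(df) != ".class"],
                 levels = levels(y)),
            class = "kmer_classifier")
}

predict_classifier <- function(fit, x) {
  df <- as.data.frame(x, check.names = TRUE)
  pred <- switch(fit$classifier,
    naive_bayes = predict(fit$model, df),
    decision_tree = predict(fit$model, df, type = "class"),
    random_forest = predict(fit$model, df),
    neural_network = {
      p <- predict(fit$model, x)
      factor(colnames(p)[max.col(p, ties.method = "first")],
             levels = fit$levels)
    },
    svm = predict(fit$model, df)
  )
  factor(as.character(pred), levels = fit$levels)
}
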