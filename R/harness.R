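#' Stratified train/test split
#'
#' Splits a labeled dataset class by class so the training fraction is met
#' as closely as floor/ceil allocation allows, with at least one sequence
#' on each side per class.  Deterministic given `seed`.
#'
#' @param data Labeled dataset tibble with a `class` column.
#' @param train_fraction Proportion of each class assigned to training
#'   (default 0.7).
#' @param seed Integer seed for the within-class shuffle.
#' @param method `"stratified"` (random within class, default) or
#'   `"prefix"` (the first rows of each class in input order train — the
#'   literal "first 70%" reading).
#' @return The input tibble with an added `.partition` factor column
#'   (`"train"` / `"test"`).
#' @examples
#' ds <- generate_sequences(synthetic_config(c(A = 10, B = 10),
#'                                           length_range = c(20, 30)))
#' table(stratified_split(ds, 0.7, seed = 1)$.partition)
#' @export
stratified_split <- function(data, train_fraction = 0.7, seed = 1,
                             method = c("stratified", "prefix")) {
  method <- match.arg(method)
  if (!"class" %in% names(data)) abort("`data` must have a `class` column")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1")
  }
  tab <- table(data$class)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    abort(paste0("cannot split class(es) with fewer than 2 sequences: ",
                 paste(small, collapse = ", ")))
  }
  part <- character(nrow(data))
  for (cls in names(tab)) {
    rows <- which(as.character(data$class) == cls)
    n <- length(rows)
    n_train <- min(max(round(n * train_fraction), 1), n - 1)
    train_rows <- if (method == "prefix") rows[seq_len(n_train)]
                  else withr::with_seed(seed, sample(rows, n_train))
    part[rows] <- "test"
    part[train_rows] <- "train"
  }
  out <- data
  out$.partition <- factor(part, levels = c("train", "test"))
  out
}

# stratified fold assignment for the optional cross-validation mode
assign_folds <- function(data, folds, seed) {
  fold <- integer(nrow(data))
  for (cls in class_levels(data$class)) {
    rows <- which(as.character(data$class) == cls)
    fold[rows] <- withr::with_seed(
      seed, sample(rep_len(seq_len(folds), length(rows))))
  }
  fold
}

run_single <- function(encoded, space, data, train_ids, test_ids,
                       classifier, k_features, variant, use_selection,
                       classifier_params, fit_seed) {
  ids <- attr(encoded, "sequence_ids")
  cls <- attr(encoded, "class_labels")
  enc_train <- encoded[encoded$sequence_id %in% train_ids, ]
  attr(enc_train, "sequence_ids") <- train_ids
  if (!is.null(cls)) {
    attr(enc_train, "class_labels") <- cls[match(train_ids, ids)]
  }
  attr(enc_train, "n_total") <- space$size

  selection <- NULL
  if (use_selection) {
    selection <- select_features(enc_train, space, k = k_features,
                                 variant = variant)
    cols <- sort(selection$selected)
  } else {
    cols <- seq_len(space$size)
  }

  m <- feature_matrix(encoded, space)
  y <- factor(as.character(data$class[match(ids, data$sequence_id)]),
              levels = class_levels(data$class))
  x_train <- as.matrix(m[match(train_ids, ids), cols, drop = FALSE])
  x_test <- as.matrix(m[match(test_ids, ids), cols, drop = FALSE])
  y_train <- y[match(train_ids, ids)]
  y_test <- y[match(test_ids, ids)]

  # constant training columns carry no information and break Gaussian
  # class-conditional densities (sd = 0): drop them before fitting
  keep <- apply(x_train, 2, function(v) any(v != v[1]))
  if (!any(keep)) abort("all training feature columns are constant")
  x_train <- x_train[, keep, drop = FALSE]
  x_test <- x_test[, keep, drop = FALSE]

  fit <- withr::with_seed(fit_seed,
    fit_classifier(x_train, y_train, classifier, classifier_params))
  pred <- predict_classifier(fit, x_test)
  cm <- confusion_matrix(y_test, pred, classes = levels(y))
  list(selection = selection,
       selected_features = if (use_selection) selection$selected else NULL,
       train_ids = train_ids, test_ids = test_ids,
       confusion = cm, report = evaluation_report(cm))
}

#' Run a repeated classification experiment
#'
#' The full protocol: for each run, draw a stratified train/test split,
#' fit the per-class statistics and feature selection on the training
#' partition only, restrict both partitions to the selected descriptors,
#' train the chosen classifier and evaluate on the held-out partition.
#' Results are aggregated as mean and standard deviation of every metric
#' over the runs.  Encoding is shared across runs (it does not depend on
#' the split); everything fitted — statistics, selection, classifier —
#' sees only the training rows of its run.
#'
#' @param data Labeled dataset tibble (`sequence_id`, `class`,
#'   `residues`), or a long-form encoding from [encode_sequences()] /
#'   [read_feature_csv()] with a `class` column.
#' @param classifier One of `"naive_bayes"`, `"decision_tree"`,
#'   `"random_forest"`, `"neural_network"` (one hidden layer of 10 units,
#'   softmax output, at most 500 epochs), `"svm"`.
#' @param n_runs Number of repeated splits (default 10).
#' @param train_fraction Training proportion per class (default 0.7).
#' @param k_features Number of descriptors kept by the selector (default
#'   50); ignored when `use_selection = FALSE`.
#' @param variant Separation-statistic variant, see
#'   [pairwise_separation()].
#' @param use_selection If `FALSE`, train on all descriptors (the
#'   no-selection baseline).
#' @param space The [ngram_feature_space()] (default `n_max = 3`).
#' @param seed Base seed; run r uses `seed + r - 1` for its split and
#'   classifier initialisation, so a fixed seed reproduces every run.
#' @param split_method `"stratified"` or `"prefix"`, see
#'   [stratified_split()].
#' @param cv_folds Optional: when set (e.g. 10), runs stratified k-fold
#'   cross-validation instead of repeated splits; `n_runs` and
#'   `train_fraction` are ignored.
#' @param classifier_params Named list of extra arguments for the
#'   back-end.
#' @return An object of class `kmer_experiment`: a list with `runs` (one
#'   entry per run: selected features, train/test ids, `confusion`,
#'   `report`), `aggregate` (tibble: metric, mean, sd), and `config`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' \donttest{
#' ds <- generate_sequences(synthetic_preset("dataset2", seed = 7))
#' ex <- run_experiment(ds, classifier = "naive_bayes", n_runs = 2,
#'                      k_features = 20, seed = 7)
#' glance(ex)
#' }
#' @export
run_experiment <- function(data,
                           classifier = c("naive_bayes", "decision_tree",
                                          "random_forest",
                                          "neural_network", "svm"),
                           n_runs = 10, train_fraction = 0.7,
                           k_features = 50,
                           variant = c("as_printed", "welch"),
                           use_selection = TRUE,
                           space = ngram_feature_space(3),
                           seed = 1,
                           split_method = c("stratified", "prefix"),
                           cv_folds = NULL,
                           classifier_params = list()) {
  classifier <- match.arg(classifier)
  variant <- match.arg(variant)
  split_method <- match.arg(split_method)
  if (n_runs < 1) abort("`n_runs` must be at least 1")

  if ("feature_index" %in% names(data)) {
    encoded <- data
    ids <- attr(encoded, "sequence_ids") %||% unique(encoded$sequence_id)
    info <- distinct(encoded, .data$sequence_id, .data$class)
    data <- info[match(ids, info$sequence_id), ]
  } else {
    validate_dataset(data)
    encoded <- encode_sequences(data, space)
  }

  if (is.null(cv_folds)) {
    splits <- purrr::map(seq_len(n_runs), function(r) {
      sp <- stratified_split(data, train_fraction, seed = seed + r - 1,
                             method = split_method)
      list(train = sp$sequence_id[sp$.partition == "train"],
           test = sp$sequence_id[sp$.partition == "test"])
    })
  } else {
    fold <- assign_folds(data, cv_folds, seed)
    splits <- purrr::map(seq_len(cv_folds), function(f) {
      list(train = data$sequence_id[fold != f],
           test = data$sequence_id[fold == f])
    })
  }

  runs <- purrr::imap(splits, function(sp, r) {
    res <- run_single(encoded, space, data, sp$train, sp$test,
                      classifier, k_features, variant, use_selection,
                      classifier_params, fit_seed = seed + r - 1)
    res$run_index <- r
    res
  })

  per_run <- bind_rows(purrr::map(runs, ~ glance(.x$report)))
  num_cols <- names(per_run)[vapply(per_run, is.numeric, logical(1))]
  aggregate <- tibble(
    metric = num_cols,
    mean = purrr::map_dbl(per_run[num_cols], mean),
    sd = purrr::map_dbl(per_run[num_cols],
                        ~ if (length(.x) > 1) stats::sd(.x) else NA_real_))

  structure(
    list(runs = runs, aggregate = aggregate,
         config = list(classifier = classifier,
                       n_runs = length(runs),
                       train_fraction = train_fraction,
                       k_features = k_features, variant = variant,
                       use_selection = use_selection, seed = seed,
                       split_method = split_method, cv_folds = cv_folds)),
    class = "kmer_experiment"
  )
}

#' @export
print.kmer_experiment <- function(x, ...) {
  acc <- x$aggregate[x$aggregate$metric == "accuracy", ]
  cat("<kmer_experiment>", x$config$classifier, "over",
      x$config$n_runs, "runs\n")
  cat(sprintf("accuracy %.4f +/- %.4f\n", acc$mean, acc$sd))
  invisible(x)
}

#' @describeIn run_experiment Per-run metric rows (run index, accuracy and
#'   the macro panel).
#' @param x A `kmer_experiment` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.kmer_experiment <- function(x, ...) {
  bind_rows(purrr::map(x$runs, function(r) {
    mutate(glance(r$report), run = r$run_index, .before = 1)
  }))
}

#' @describeIn run_experiment One-row summary: classifier, runs, mean and
#'   sd of accuracy and macro F-measure/MCC.
#' @exportS3Method generics::glance
glance.kmer_experiment <- function(x, ...) {
  get <- function(m, col) x$aggregate[[col]][x$aggregate$metric == m]
  tibble(classifier = x$config$classifier,
         n_runs = x$config$n_runs,
         k_features = if (x$config$use_selection) x$config$k_features
                      else NA_integer_,
         accuracy = get("accuracy", "mean"),
         accuracy_sd = get("accuracy", "sd"),
         macro_f_measure = get("macro_f_measure", "mean"),
         macro_mcc = get("macro_mcc", "mean"))
}

#' @describeIn run_experiment Dot-and-error plot of the aggregate metric
#'   panel over runs.
#' @param object A `kmer_experiment` object.
#' @exportS3Method ggplot2::autoplot
autoplot.kmer_experiment <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(cols = -c("run", "total"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::labs(x = NULL, y = "value over runs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
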