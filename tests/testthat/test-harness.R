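small_planted <- function(n_per_class = 20, rate = 0.08, seed = 5,
                          classes = c("A", "B", "C")) {
  generate_sequences(synthetic_config(
    classes = setNames(rep(n_per_class, length(classes)), classes),
    length_range = c(50, 80),
    planted = tibble::tibble(descriptor = c("MKV", "LST", "GAW")[
                               seq_along(classes)],
                             class = classes, rate = rate),
    seed = seed))
}

test_that("stratified_split allocates per class near the requested fraction", {
  one <- tibble::tibble(sequence_id = as.character(1:100),
                        class = rep("c", 100), residues = "MKV")
  sp <- stratified_split(one, 0.7, seed = 1)
  expect_equal(sum(sp$.partition == "train"), 70)
  expect_equal(sum(sp$.partition == "test"), 30)

  three <- tibble::tibble(sequence_id = as.character(1:750),
                          class = rep(c("globin", "trypsin", "ras"),
                                      each = 250),
                          residues = "MKV")
  sp3 <- stratified_split(three, 0.7, seed = 2)
  tab <- table(sp3$class, sp3$.partition)
  expect_equal(unname(tab[, "train"]), rep(175L, 3))
  expect_equal(unname(tab[, "test"]), rep(75L, 3))
})

test_that("splits are deterministic in the seed and exhaustive", {
  ds <- random_dataset(15, classes = c("A", "B"), seed = 9)
  a <- stratified_split(ds, 0.7, seed = 42)
  b <- stratified_split(ds, 0.7, seed = 42)
  expect_equal(a$.partition, b$.partition)
  c <- stratified_split(ds, 0.7, seed = 43)
  expect_false(identical(a$.partition, c$.partition))
  expect_equal(sort(c(a$sequence_id[a$.partition == "train"],
                      a$sequence_id[a$.partition == "test"])),
               sort(ds$sequence_id))
})

test_that("every class keeps at least one row on each side", {
  tiny <- tibble::tibble(sequence_id = as.character(1:4),
                         class = rep(c("A", "B"), each = 2),
                         residues = "MKV")
  sp <- stratified_split(tiny, 0.9, seed = 1)
  tab <- table(sp$class, sp$.partition)
  expect_true(all(tab >= 1))
  expect_error(stratified_split(tiny, 1.2, seed = 1), "between 0 and 1")
  tiny$class <- c("A", "A", "A", "B")
  expect_error(stratified_split(tiny, 0.7, seed = 1), "fewer than 2")
})

test_that("prefix split takes the first rows of each class", {
  ds <- tibble::tibble(sequence_id = as.character(1:10),
                       class = rep(c("A", "B"), each = 5),
                       residues = "MKV")
  sp <- stratified_split(ds, 0.6, seed = 1, method = "prefix")
  expect_equal(sp$sequence_id[sp$.partition == "train"],
               c("1", "2", "3", "6", "7", "8"))
})

test_that("experiments are reproducible run for run", {
  ds <- small_planted(12, seed = 31)
  for (cl in c("naive_bayes", "random_forest")) {
    e1 <- run_experiment(ds, classifier = cl, n_runs = 1, k_features = 15,
                         seed = 99)
    e2 <- run_experiment(ds, classifier = cl, n_runs = 1, k_features = 15,
                         seed = 99)
    expect_equal(unclass(e1$runs[[1]]$confusion),
                 unclass(e2$runs[[1]]$confusion))
    expect_equal(e1$runs[[1]]$selected_features,
                 e2$runs[[1]]$selected_features)
  }
})

test_that("selection is fitted on the training partition only", {
  ds <- small_planted(15, seed = 77)
  ex <- run_experiment(ds, classifier = "decision_tree", n_runs = 1,
                       k_features = 12, seed = 4)
  run <- ex$runs[[1]]
  # recompute selection from the stored training ids alone
  train_data <- ds[ds$sequence_id %in% run$train_ids, ]
  direct <- select_features(train_data, ngram_feature_space(3), k = 12)
  expect_equal(sort(direct$selected), sort(run$selected_features))
  # deleting any test row cannot change the selected set
  for (drop_id in run$test_ids[1:3]) {
    reduced <- ds[ds$sequence_id != drop_id, ]
    again <- select_features(reduced[reduced$sequence_id %in% run$train_ids, ],
                             ngram_feature_space(3), k = 12)
    expect_equal(sort(again$selected), sort(run$selected_features))
  }
})

test_that("planted signal is learnable well above chance", {
  ds <- small_planted(20, rate = 0.08, seed = 55)
  ex <- run_experiment(ds, classifier = "naive_bayes", n_runs = 3,
                       k_features = 20, seed = 7)
  expect_gt(glance(ex)$accuracy, 0.6)     # chance is 1/3
  expect_equal(ex$config$n_runs, 3)
  expect_equal(nrow(tidy(ex)), 3)
})

test_that("run_experiment accepts a pre-encoded matrix equivalently", {
  ds <- small_planted(10, seed = 3, classes = c("A", "B"))
  space <- ngram_feature_space(3)
  enc <- encode_sequences(ds, space)
  e1 <- run_experiment(ds, classifier = "decision_tree", n_runs = 2,
                       k_features = 10, seed = 11, space = space)
  e2 <- run_experiment(enc, classifier = "decision_tree", n_runs = 2,
                       k_features = 10, seed = 11, space = space)
  expect_equal(glance(e1)$accuracy, glance(e2)$accuracy)
  expect_equal(e1$runs[[1]]$selected_features,
               e2$runs[[1]]$selected_features)
})

test_that("cross-validation mode partitions every sequence exactly once", {
  ds <- small_planted(12, seed = 13, classes = c("A", "B"))
  ex <- run_experiment(ds, classifier = "decision_tree", cv_folds = 4,
                       k_features = 10, seed = 2)
  expect_equal(ex$config$n_runs, 4)
  test_ids <- unlist(purrr::map(ex$runs, "test_ids"))
  expect_setequal(test_ids, ds$sequence_id)
  expect_equal(anyDuplicated(test_ids), 0)
})

test_that("confusion row sums equal test-set class counts in every run", {
  ds <- small_planted(14, seed = 21)
  ex <- run_experiment(ds, classifier = "naive_bayes", n_runs = 2,
                       k_features = 15, seed = 8)
  for (run in ex$runs) {
    counts <- table(ds$class[match(run$test_ids, ds$sequence_id)])
    expect_equal(unname(rowSums(run$confusion)), as.vector(counts))
  }
})

test_that("neural network back-end uses the compact one-hidden-layer net", {
  ds <- small_planted(10, seed = 41, classes = c("A", "B"))
  ex <- run_experiment(ds, classifier = "neural_network", n_runs = 1,
                       k_features = 8, seed = 6)
  expect_s3_class(ex$runs[[1]]$report$per_class, "tbl_df")
  expect_gt(glance(ex)$accuracy, 0.5)
})
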