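test_that("class statistics match direct arithmetic on the worked example", {
  ds <- sample_sequences()
  ds <- rbind(ds, ds)                       # two identical classes
  ds$class <- rep(c("p", "q"), each = 5)
  ds$sequence_id <- paste0(ds$class, 1:5)
  enc <- encode_sequences(ds, ngram_feature_space(1))
  st <- class_statistics(enc)
  m_freqs <- c(2 / 9, 2 / 8, 1 / 10, 2 / 8, 2 / 9)   # frequency of "M"
  row <- st[st$class == "p" & st$descriptor == "M", ]
  expect_equal(row$mean, sum(m_freqs) / 5)
  expect_equal(row$variance,
               sum((mean(m_freqs) - m_freqs)^2) / 4)
  expect_equal(row$n_sequences, 5)
  expect_true(all(st$variance >= 0))
})

test_that("a class of identical vectors has zero variance and mean = vector", {
  ds <- tibble::tibble(sequence_id = c("a1", "a2", "b1", "b2"),
                       class = rep(c("A", "B"), each = 2),
                       residues = c("MKMK", "MKMK", "ACAC", "ACAC"))
  st <- class_statistics(encode_sequences(ds, ngram_feature_space(1)))
  a <- st[st$class == "A", ]
  expect_equal(a$variance, rep(0, nrow(a)))
  expect_equal(sort(a$mean), c(0.5, 0.5))
})

test_that("a single-sequence class is a degenerate-class error", {
  ds <- tibble::tibble(sequence_id = c("a1", "a2", "b1"),
                       class = c("A", "A", "B"),
                       residues = c("MKMK", "MKAC", "ACAC"))
  enc <- encode_sequences(ds, ngram_feature_space(1))
  expect_error(class_statistics(enc), "B")
})

test_that("pairwise metric matches a scalar hand calculation in both variants", {
  # two 3-sequence classes over a tiny space; frequencies chosen by hand
  X <- rbind(c(0.2, 0.5), c(0.4, 0.5), c(0.3, 0.5),
             c(0.6, 0.1), c(0.8, 0.3), c(0.7, 0.2))
  labels <- rep(c("p", "q"), each = 3)
  enc <- encoded_from_matrix(X, labels)
  st <- class_statistics(enc)
  n_total <- 2
  mp <- mean(X[1:3, 1]); vp <- var(X[1:3, 1])
  mq <- mean(X[4:6, 1]); vq <- var(X[4:6, 1])
  for (variant in c("as_printed", "welch")) {
    pair <- pairwise_separation(st, n_total, variant)
    want1 <- if (variant == "as_printed") {
      abs(mp - mq) / (vp / n_total + vq / n_total)
    } else {
      abs(mp - mq) / sqrt(vp / 3 + vq / 3)
    }
    expect_equal(pair$vd[pair$feature_index == 1], want1)
  }
})

test_that("zero numerator gives 0 and zero denominator gives +Inf", {
  # feature "A": constant 1 in class p, absent in q -> variances 0,
  # means differ -> infinite separation; feature shared equally -> 0
  ds <- tibble::tibble(sequence_id = c("p1", "p2", "q1", "q2"),
                       class = rep(c("p", "q"), each = 2),
                       residues = c("AA", "AA", "CC", "CC"))
  st <- class_statistics(encode_sequences(ds, ngram_feature_space(1)))
  pair <- pairwise_separation(st, 20, "as_printed")
  expect_equal(pair$vd[pair$descriptor == "A"], Inf)
  expect_equal(pair$vd[pair$descriptor == "C"], Inf)

  same <- tibble::tibble(sequence_id = c("p1", "p2", "q1", "q2"),
                         class = rep(c("p", "q"), each = 2),
                         residues = c("AC", "CA", "AC", "CA"))
  st2 <- class_statistics(encode_sequences(same, ngram_feature_space(1)))
  pair2 <- pairwise_separation(st2, 20, "as_printed")
  expect_equal(pair2$vd, c(0, 0))
})

test_that("final_metric is the columnwise minimum and handles Inf", {
  expect_equal(final_metric(matrix(c(5, 2, 7), ncol = 1)), 2)
  one <- matrix(runif(10), nrow = 1)
  expect_equal(final_metric(one), as.numeric(one))
  set.seed(1)
  m <- matrix(runif(150), nrow = 3)
  m[1, 4] <- Inf
  want <- vapply(seq_len(50), function(j) min(m[, j]), numeric(1))
  expect_equal(final_metric(m), want)
  expect_error(final_metric(matrix(numeric(0), nrow = 0)), "at least one")
})

test_that("vectorized selection agrees with the naive nested-loop oracle", {
  set.seed(7)
  for (i in 1:20) {
    n_classes <- sample(2:4, 1)
    n_feat <- sample(5:25, 1)
    rows_per <- sample(3:8, 1)
    X <- matrix(round(runif(n_classes * rows_per * n_feat), 3),
                ncol = n_feat)
    X[runif(length(X)) < 0.4] <- 0       # sparsity
    labels <- rep(LETTERS[seq_len(n_classes)], each = rows_per)
    variant <- sample(c("as_printed", "welch"), 1)
    enc <- encoded_from_matrix(X, labels)
    st <- class_statistics(enc)
    pair <- pairwise_separation(st, n_feat, variant)
    got <- final_metric(dense_final_from_pairs(pair, n_feat))
    want <- oracle_selection_metric(X, labels, n_feat, variant)
    expect_equal(got, want$final, tolerance = 1e-10)
  }
})

test_that("selection ranks descending with deterministic index tie-breaks", {
  ds <- random_dataset(5, classes = c("A", "B"), len = c(10, 20), seed = 21)
  space <- ngram_feature_space(2)
  sel <- select_features(ds, space, k = 10)
  r <- sel$ranking
  expect_equal(nrow(r), space$size)
  expect_true(all(diff(r$final_metric) <= 0))
  # ties (here: the all-zero tail) are ordered by ascending feature index
  zero <- r$feature_index[r$final_metric == 0]
  expect_equal(zero, sort(zero))
  expect_equal(sel$selected, r$feature_index[1:10])
  expect_true(all(sel$ranking$final_metric[1:10] >=
                  r$final_metric[11]))
  # boundary: k = n_total selects everything in metric order
  all_sel <- select_features(ds, space, k = space$size)
  expect_equal(all_sel$selected, r$feature_index)
  expect_error(select_features(ds, space, k = 0), "k")
  expect_error(select_features(ds, space, k = space$size + 1), "k")
})

test_that("min_metric threshold mode selects by absolute cutoff", {
  ds <- random_dataset(5, classes = c("A", "B"), len = c(10, 20), seed = 22)
  space <- ngram_feature_space(1)
  sel <- select_features(ds, space, variant = "welch", min_metric = 1)
  expect_true(all(sel$ranking$final_metric[
    sel$ranking$feature_index %in% sel$selected] >= 1))
  expect_setequal(sel$selected,
                  sel$ranking$feature_index[sel$ranking$final_metric >= 1])
})

test_that("statistics are invariant to row order and class relabeling", {
  ds <- random_dataset(6, classes = c("A", "B", "C"), seed = 13)
  space <- ngram_feature_space(2)
  sel1 <- select_features(ds, space, k = 15)

  shuffled <- ds[sample(nrow(ds)), ]
  sel2 <- select_features(shuffled, space, k = 15)
  expect_setequal(sel1$selected, sel2$selected)
  expect_equal(sel1$ranking$final_metric, sel2$ranking$final_metric)

  relev <- ds
  relev$class <- factor(as.character(relev$class),
                        levels = c("C", "A", "B"))
  relev <- relev[order(as.integer(relev$class)), ]
  sel3 <- select_features(relev, space, k = 15)
  expect_setequal(sel1$selected, sel3$selected)
})

test_that("pairwise metric is symmetric in the class pair", {
  ds <- random_dataset(5, classes = c("A", "B"), seed = 17)
  enc <- encode_sequences(ds, ngram_feature_space(1))
  st <- class_statistics(enc)
  for (variant in c("as_printed", "welch")) {
    fwd <- pairwise_separation(st, 20, variant)
    st_rev <- st
    st_rev$class <- factor(as.character(st$class), levels = c("B", "A"))
    rev <- pairwise_separation(st_rev, 20, variant)
    merged <- merge(fwd, rev, by = "feature_index")
    expect_equal(merged$vd.x, merged$vd.y)
  }
})

test_that("welch variant is invariant to per-feature positive rescaling", {
  set.seed(31)
  X <- matrix(runif(60), ncol = 6)
  labels <- rep(c("A", "B"), each = 5)
  base <- oracle_dense_vd <- final_metric(dense_final_from_pairs(
    pairwise_separation(class_statistics(encoded_from_matrix(X, labels)),
                        6, "welch"), 6))
  X2 <- X
  X2[, 3] <- X2[, 3] * 7.5
  scaled <- final_metric(dense_final_from_pairs(
    pairwise_separation(class_statistics(encoded_from_matrix(X2, labels)),
                        6, "welch"), 6))
  expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("selection accessors tidy and glance are coherent", {
  ds <- random_dataset(5, classes = c("A", "B"), seed = 19)
  sel <- select_features(ds, ngram_feature_space(2), k = 8)
  td <- tidy(sel)
  expect_equal(sum(td$selected), 8)
  g <- glance(sel)
  expect_equal(g$n_selected, 8)
  expect_equal(g$n_pairs, 1)
  expect_s3_class(autoplot(sel), "ggplot")
})
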