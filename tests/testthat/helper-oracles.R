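# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate the vectorized implementations.

# all overlapping k-windows of a residue string by direct substring scan;
# windows containing characters outside the 20-letter alphabet are invalid
oracle_windows <- function(residues, k) {
  chars <- strsplit(residues, "")[[1]]
  len <- length(chars)
  if (len < k) return(character(0))
  out <- character(0)
  for (p in seq_len(len - k + 1)) {
    w <- chars[p:(p + k - 1)]
    if (all(w %in% kmerselect::AMINO_ACIDS)) {
      out <- c(out, paste0(w, collapse = ""))
    }
  }
  out
}

oracle_count <- function(residues, kgram) {
  sum(oracle_windows(residues, nchar(kgram)) == kgram)
}

# naive per-class mean/variance (two explicit passes, dense)
oracle_stats <- function(X, labels) {
  res <- list()
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    n <- length(rows)
    mu <- numeric(ncol(X))
    v <- numeric(ncol(X))
    for (j in seq_len(ncol(X))) {
      s <- 0
      for (i in rows) s <- s + X[i, j]
      m <- s / n
      ss <- 0
      for (i in rows) ss <- ss + (m - X[i, j])^2
      mu[j] <- m
      v[j] <- ss / (n - 1)
    }
    res[[cl]] <- list(mean = mu, var = v, n = n)
  }
  res
}

# naive pairwise separation + min-over-pairs final metric
oracle_selection_metric <- function(X, labels, n_total, variant) {
  st <- oracle_stats(X, labels)
  classes <- unique(labels)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  pm <- matrix(0, length(pairs), ncol(X))
  for (pi in seq_along(pairs)) {
    p <- st[[pairs[[pi]][1]]]
    q <- st[[pairs[[pi]][2]]]
    for (j in seq_len(ncol(X))) {
      num <- abs(p$mean[j] - q$mean[j])
      den <- if (variant == "as_printed") {
        p$var[j] / n_total + q$var[j] / n_total
      } else {
        sqrt(p$var[j] / p$n + q$var[j] / q$n)
      }
      pm[pi, j] <- if (num == 0) 0 else num / den
    }
  }
  vd <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) vd[j] <- min(pm[, j])
  list(pair = pm, final = vd, pairs = pairs)
}

# turn a dense matrix of frequencies into the package's long encoded form
encoded_from_matrix <- function(X, labels) {
  ids <- paste0("r", seq_len(nrow(X)))
  rows <- which(X != 0, arr.ind = TRUE)
  enc <- tibble::tibble(
    sequence_id = ids[rows[, 1]],
    class = factor(labels[rows[, 1]], levels = unique(labels)),
    feature_index = as.integer(rows[, 2]),
    descriptor = paste0("f", rows[, 2]),
    frequency = X[rows])
  enc <- enc[order(match(enc$sequence_id, ids), enc$feature_index), ]
  attr(enc, "sequence_ids") <- ids
  attr(enc, "class_labels") <- factor(labels, levels = unique(labels))
  attr(enc, "n_total") <- ncol(X)
  enc
}

# package-side dense final metric from the sparse pairwise tibble
dense_final_from_pairs <- function(pair_tbl, n_total) {
  n_pairs <- attr(pair_tbl, "n_pairs")
  key <- paste(pair_tbl$class_p, pair_tbl$class_q)
  pm <- matrix(0, n_pairs, n_total)
  for (pi in seq_along(unique(key))) {
    sub <- pair_tbl[key == unique(key)[pi], ]
    pm[pi, sub$feature_index] <- sub$vd
  }
  pm
}

# small labeled dataset of random clean sequences
random_dataset <- function(n_per_class, classes = c("A", "B"),
                           len = c(20, 40), seed = 1) {
  set.seed(seed)
  rows <- lapply(classes, function(cl) {
    tibble::tibble(
      sequence_id = paste0(cl, seq_len(n_per_class)),
      class = cl,
      residues = vapply(seq_len(n_per_class), function(i) {
        paste0(sample(kmerselect::AMINO_ACIDS, sample(len[1]:len[2], 1),
                      replace = TRUE), collapse = "")
      }, ""))
  })
  out <- do.call(rbind, rows)
  out$class <- factor(out$class, levels = classes)
  out
}

# the five worked-example sequences used throughout the encoder tests
sample_sequences <- function() {
  tibble::tibble(
    sequence_id = paste0("seq", 1:5),
    class = "demo",
    residues = c("MKVLIFACM", "MKLCMKVL", "ACMKVLIFAC", "MKLIFACM",
                 "CMKVIFACM"))
}

# plain labeled matrix accepted by evaluation_report()
new_confusion_for_test <- function(counts, classes) {
  matrix(as.integer(counts), nrow = length(classes),
         dimnames = list(actual = classes, predicted = classes))
}

frequency_of <- function(encoded, id, descriptor) {
  r <- encoded[encoded$sequence_id == id & encoded$descriptor == descriptor, ]
  if (nrow(r) == 0) 0 else r$frequency
}
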