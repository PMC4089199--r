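#' Per-superfamily mean and variance of every feature
#'
#' For each class computes, feature by feature, the arithmetic mean over
#' the class's sequences and the sample variance (divisor \eqn{N_i - 1}).
#' Zero frequencies of absent descriptors are included implicitly, so the
#' result stays sparse: features never seen in a class (mean and variance
#' both zero) are omitted.
#'
#' @param encoded Long-form encoding from [encode_sequences()] with a
#'   `class` column.
#' @return A tibble with columns `class`, `feature_index`, `descriptor`,
#'   `n_sequences`, `mean`, `variance`; the per-class sequence counts are
#'   also kept in attribute `class_sizes`.
#' @examples
#' ds <- tibble::tibble(
#'   sequence_id = c("a1", "a2", "b1", "b2"),
#'   class = factor(rep(c("A", "B"), each = 2)),
#'   residues = c("MKVLIFACM", "ACMKVLIFAC", "MKLCMKVL", "CMKVIFACM"))
#' enc <- encode_sequences(ds, ngram_feature_space(1))
#' class_statistics(enc)
#' @export
class_statistics <- function(encoded) {
  if (!"class" %in% names(encoded)) {
    abort("`encoded` must carry a `class` column")
  }
  ids <- attr(encoded, "sequence_ids")
  cls <- attr(encoded, "class_labels")
  membership <- if (!is.null(ids) && !is.null(cls)) {
    tibble(sequence_id = ids, class = cls)    # robust to all-zero rows
  } else {
    distinct(encoded, .data$sequence_id, .data$class)
  }
  sizes <- count(membership, .data$class, name = "n_sequences")
  sizes <- sizes[sizes$n_sequences > 0, ]
  small <- as.character(sizes$class[sizes$n_sequences < 2])
  if (length(small) > 0) {
    abort(paste0("cannot compute a sample variance for class(es) with ",
                 "fewer than 2 sequences: ", paste(small, collapse = ", ")))
  }
  stats <- encoded |>
    group_by(.data$class, .data$feature_index, .data$descriptor) |>
    summarise(n_nonzero = n(),
              sum_x = sum(.data$frequency),
              x = list(.data$frequency),
              .groups = "drop") |>
    left_join(sizes, by = "class")
  # two-pass variance on sparse columns: implicit zeros contribute
  # (N - m) * mean^2 to the sum of squared deviations
  stats$mean <- stats$sum_x / stats$n_sequences
  stats$variance <- purrr::pmap_dbl(
    list(stats$x, stats$mean, stats$n_sequences, stats$n_nonzero),
    function(x, m, n, nz) (sum((x - m)^2) + (n - nz) * m^2) / (n - 1)
  )
  out <- stats[, c("class", "feature_index", "descriptor",
                   "n_sequences", "mean", "variance")]
  out <- arrange(out, .data$class, .data$feature_index)
  attr(out, "class_sizes") <- sizes
  out
}

# the per-pair separation statistic on aligned mean/variance vectors.
# as_printed: |mp - mq| / (vp/n_total + vq/n_total)   (no square root)
# welch:      |mp - mq| / sqrt(vp/np + vq/nq)
# 0/0 -> 0; positive/0 -> +Inf (the feature separates the pair perfectly)
separation_values <- function(mp, vp, np, mq, vq, nq, n_total, variant) {
  num <- abs(mp - mq)
  den <- switch(variant,
                as_printed = vp / n_total + vq / n_total,
                welch = sqrt(vp / np + vq / nq))
  vd <- num / den
  vd[num == 0] <- 0
  vd
}

#' Pairwise class-separation statistic for every feature
#'
#' For each unordered pair of classes (p, q), scores every feature j by
#' how far apart the class means sit relative to the class variances.
#' Two variants are provided:
#' * `"as_printed"` (default): \eqn{|\bar X_p(j) - \bar X_q(j)| /
#'   (S_p^2(j)/N_{Total} + S_q^2(j)/N_{Total})} — the statistic exactly as
#'   the method defines it, with the pooled variance scaled by the size of
#'   the descriptor universe and no square root.
#' * `"welch"`: \eqn{|\bar X_p(j) - \bar X_q(j)| /
#'   \sqrt{S_p^2(j)/N_p + S_q^2(j)/N_q}} — the standard two-sample
#'   (Welch) statistic the printed form resembles.
#'
#' A zero denominator with zero numerator gives 0; with a positive
#' numerator it gives `+Inf` (a zero-variance feature with different class
#' means separates the pair perfectly and outranks all finite scores).
#'
#' @param stats Per-class statistics from [class_statistics()].
#' @param n_total Size of the descriptor universe (e.g. 8420); required by
#'   the `as_printed` variant.
#' @param variant `"as_printed"` or `"welch"`.
#' @return A tibble with columns `class_p`, `class_q`, `feature_index`,
#'   `descriptor`, `vd`, covering every feature present in at least one
#'   class of the pair (all others score exactly 0).
#' @export
pairwise_separation <- function(stats, n_total,
                                variant = c("as_printed", "welch")) {
  variant <- match.arg(variant)
  classes <- class_levels(stats$class)
  if (length(classes) < 2) abort("need at least 2 classes")
  sizes <- attr(stats, "class_sizes")
  n_of <- setNames(sizes$n_sequences, as.character(sizes$class))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  per_pair <- purrr::map(pairs, function(pq) {
    sp <- stats[as.character(stats$class) == pq[1], ]
    sq <- stats[as.character(stats$class) == pq[2], ]
    j <- dplyr::full_join(
      sp[, c("feature_index", "descriptor", "mean", "variance")],
      sq[, c("feature_index", "descriptor", "mean", "variance")],
      by = c("feature_index", "descriptor"), suffix = c("_p", "_q"))
    j[is.na(j)] <- 0
    tibble(class_p = pq[1], class_q = pq[2],
           feature_index = j$feature_index,
           descriptor = j$descriptor,
           vd = separation_values(j$mean_p, j$variance_p, n_of[pq[1]],
                                  j$mean_q, j$variance_q, n_of[pq[2]],
                                  n_total, variant))
  })
  out <- arrange(bind_rows(per_pair), .data$class_p, .data$class_q,
                 .data$feature_index)
  attr(out, "n_pairs") <- length(pairs)
  out
}

#' Minimum-over-pairs final metric
#'
#' Collapses a pairs-by-features matrix of separation scores to one score
#' per feature: the minimum across all class pairs, so a feature scores
#' high only if it discriminates every pair of superfamilies
#' simultaneously.  `+Inf` entries participate normally in the minimum.
#'
#' @param pair_metrics Numeric matrix, rows = class pairs, columns =
#'   features.
#' @return Numeric vector of per-feature minima.
#' @examples
#' final_metric(rbind(c(5, 1), c(2, 3), c(7, 2)))  # 2 1
#' @export
final_metric <- function(pair_metrics) {
  if (!is.matrix(pair_metrics) || nrow(pair_metrics) < 1) {
    abort("`pair_metrics` must be a matrix with at least one pair row")
  }
  apply(pair_metrics, 2, min)
}

# sparse min-over-pairs: a feature missing from any pair's rows has vd = 0
# there, so only features present in all pairs can score above zero
sparse_final_metric <- function(pair_tbl) {
  n_pairs <- attr(pair_tbl, "n_pairs")
  pair_tbl |>
    group_by(.data$feature_index, .data$descriptor) |>
    summarise(final_metric = if (n() == n_pairs) min(.data$vd) else 0,
              .groups = "drop")
}

#' Select the most discriminative n-gram features
#'
#' The full filter-selection pipeline: per-class means and variances,
#' pairwise separation statistic, min-over-pairs final metric, and top-k
#' selection.  Ranking is by final metric descending with ties broken by
#' ascending feature index, so the selected set is deterministic.
#'
#' @param data Either a labeled dataset tibble (`sequence_id`, `class`,
#'   `residues`) — encoded internally — or a long-form encoding from
#'   [encode_sequences()].
#' @param space The [ngram_feature_space()] to encode in (default
#'   `n_max = 3`, 8420 descriptors).
#' @param k Number of features to keep (default 50, the upper end of the
#'   "a few tens of features" regime the method targets).
#' @param variant Separation-statistic variant, see
#'   [pairwise_separation()].
#' @param min_metric Optional absolute threshold: when given, all features
#'   with final metric `>= min_metric` are selected and `k` is ignored.
#' @return An object of class `kmer_selection`: a list with
#'   `ranking` (tibble: `rank`, `feature_index`, `descriptor`,
#'   `final_metric`), `selected` (integer vector of selected feature
#'   indices, in rank order), `pair_metric` (the sparse pairwise tibble),
#'   `statistics` (per-class stats), `k`, `variant`, `classes`, `n_total`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' ds <- generate_sequences(synthetic_config(
#'   classes = c(A = 20, B = 20), length_range = c(30, 40),
#'   planted = tibble::tibble(descriptor = "MKV", class = "A", rate = 0.1),
#'   seed = 1))
#' sel <- select_features(ds, k = 5)
#' tidy(sel)
#' @export
select_features <- function(data, space = ngram_feature_space(3), k = 50,
                            variant = c("as_printed", "welch"),
                            min_metric = NULL) {
  variant <- match.arg(variant)
  encoded <- if ("feature_index" %in% names(data)) data
             else encode_sequences(data, space)
  n_total <- attr(encoded, "n_total") %||% space$size
  if (is.null(min_metric)) {
    if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n_total) {
      abort(paste0("`k` must be a single integer in [1, ", n_total, "]"))
    }
    k <- as.integer(k)
  }
  stats <- class_statistics(encoded)
  pair_tbl <- pairwise_separation(stats, n_total, variant)
  fm <- sparse_final_metric(pair_tbl)
  metric <- numeric(n_total)
  metric[fm$feature_index] <- fm$final_metric
  ord <- order(-metric, seq_len(n_total))   # ties -> ascending index
  ranking <- tibble(rank = seq_len(n_total),
                    feature_index = ord,
                    descriptor = space$descriptors[ord],
                    final_metric = metric[ord])
  selected <- if (is.null(min_metric)) ranking$feature_index[seq_len(k)]
              else ranking$feature_index[ranking$final_metric >= min_metric]
  structure(
    list(ranking = ranking, selected = selected, pair_metric = pair_tbl,
         statistics = stats, k = if (is.null(min_metric)) k else NA_integer_,
         min_metric = min_metric, variant = variant,
         classes = class_levels(stats$class), n_total = n_total,
         space = space),
    class = "kmer_selection"
  )
}

#' @export
print.kmer_selection <- function(x, ...) {
  cat("<kmer_selection>", length(x$selected), "of", x$n_total,
      "features selected (variant =", paste0(x$variant, ")\n"))
  cat("classes:", paste(x$classes, collapse = ", "), "\n")
  print(head(x$ranking, 5))
  invisible(x)
}

#' @describeIn select_features Tidy the ranking: one row per feature with
#'   `rank`, `feature_index`, `descriptor`, `final_metric` and `selected`.
#' @param x A `kmer_selection` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.kmer_selection <- function(x, ...) {
  mutate(x$ranking, selected = .data$feature_index %in% x$selected)
}

#' @describeIn select_features One-row summary of the selection.
#' @exportS3Method generics::glance
glance.kmer_selection <- function(x, ...) {
  tibble(n_classes = length(x$classes),
         n_pairs = choose(length(x$classes), 2),
         n_total = x$n_total,
         n_selected = length(x$selected),
         variant = x$variant,
         top_metric = x$ranking$final_metric[1],
         cutoff_metric = x$ranking$final_metric[length(x$selected)])
}

#' @describeIn select_features Plot the ranked final metric with the
#'   selected prefix highlighted.
#' @param object A `kmer_selection` object.
#' @param top_n Number of top-ranked features to show (default 200).
#' @exportS3Method ggplot2::autoplot
autoplot.kmer_selection <- function(object, top_n = 200, ...) {
  d <- head(tidy(object), top_n)
  d$final_metric[is.infinite(d$final_metric)] <-
    max(d$final_metric[is.finite(d$final_metric)], 1) * 1.1
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$final_metric,
                                  colour = .data$selected)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "min-over-pairs separation metric",
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' Restrict an encoding to the selected features
#'
#' @param encoded Long-form encoding from [encode_sequences()].
#' @param selection A `kmer_selection` from [select_features()], or an
#'   integer vector of feature indices.
#' @return The encoding filtered to the selected features (attributes
#'   preserved).
#' @export
reduce_features <- function(encoded, selection) {
  idx <- if (inherits(selection, "kmer_selection")) selection$selected
         else as.integer(selection)
  out <- encoded[encoded$feature_index %in% idx, ]
  attr(out, "sequence_ids") <- attr(encoded, "sequence_ids")
  attr(out, "class_labels") <- attr(encoded, "class_labels")
  attr(out, "n_total") <- attr(encoded, "n_total")
  out
}

#' Write a selection table to TSV
#'
#' Writes one row per ranked feature: rank, feature index, descriptor,
#' final metric, and one column of the pairwise metric per class pair.
#'
#' @param selection A `kmer_selection`.
#' @param path Output TSV path.
#' @param top_n How many ranked rows to write (default: the selected set).
#' @return Invisibly, the path.
#' @export
write_selection_tsv <- function(selection, path,
                                top_n = length(selection$selected)) {
  d <- head(selection$ranking, top_n)
  pm <- selection$pair_metric |>
    mutate(pair = paste0("vd_", .data$class_p, "_", .data$class_q)) |>
    select("feature_index", "pair", "vd") |>
    tidyr::pivot_wider(names_from = "pair", values_from = "vd",
                       values_fill = 0)
  d <- left_join(d, pm, by = "feature_index")
  d[is.na(d)] <- 0
  readr::write_tsv(d, path)
  invisible(path)
}
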