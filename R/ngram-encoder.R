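#' Enumerate the fixed n-gram descriptor universe
#'
#' Builds the ordered universe of all amino-acid n-grams of length 1 to
#' `n_max` over the 20-letter alphabet.  Descriptors are ordered by length
#' and then lexicographically, so column indices are stable across runs.
#' The universe has \eqn{\sum_{k=1}^{n_{max}} 20^k} descriptors: 8420 for
#' the default `n_max = 3` (20 + 400 + 8000).
#'
#' @param n_max Maximum descriptor length, between 1 and 5 (lengths above
#'   3 grow the space 20-fold per step and are rarely worth the cost).
#' @return An object of class `ngram_space`: a list with `n_max`,
#'   `descriptors` (character vector), `k` (integer vector of descriptor
#'   lengths), `offsets` (block start offsets per k) and `size`.
#' @examples
#' space <- ngram_feature_space(3)
#' space$size            # 8420
#' head(space$descriptors)
#' @export
ngram_feature_space <- function(n_max = 3) {
  if (!is.numeric(n_max) || length(n_max) != 1 || n_max != round(n_max) ||
      n_max < 1 || n_max > 5) {
    abort("`n_max` must be a single integer between 1 and 5")
  }
  n_max <- as.integer(n_max)
  blocks <- lapply(seq_len(n_max), function(k) {
    g <- do.call(expand.grid,
                 c(rep(list(AMINO_ACIDS), k),
                   list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
    # expand.grid varies the first column fastest; read columns in reverse
    # so the last character of the k-mer varies fastest (lexicographic).
    do.call(paste0, rev(g))
  })
  sizes <- 20^seq_len(n_max)
  structure(
    list(n_max = n_max,
         descriptors = unlist(blocks),
         k = rep(seq_len(n_max), times = sizes),
         offsets = cumsum(c(0, sizes[-n_max])),
         size = sum(sizes)),
    class = "ngram_space"
  )
}

#' @export
print.ngram_space <- function(x, ...) {
  cat("<ngram_space> n_max =", x$n_max, "with", x$size, "descriptors\n")
  invisible(x)
}

#' Map descriptor strings to feature indices
#'
#' @param descriptors Character vector of descriptor strings.
#' @param space An [ngram_feature_space()].
#' @return Integer vector of 1-based feature indices (NA for strings not
#'   in the universe).
#' @export
descriptor_index <- function(descriptors, space) {
  match(descriptors, space$descriptors)
}

# per-position alphabet ranks of one residue string (NA for non-standard)
residue_ranks <- function(residues) {
  match(strsplit(residues, "", fixed = TRUE)[[1]], AMINO_ACIDS)
}

# 1-based indices into the k-block (1..20^k) of all windows of width k;
# NA where the window overlaps a non-standard residue
window_block_indices <- function(ranks, k) {
  len <- length(ranks)
  if (len < k) return(integer(0))
  nw <- len - k + 1
  idx <- rep(0, nw)
  for (j in seq_len(k)) {
    idx <- idx + (ranks[j:(j + nw - 1)] - 1) * 20^(k - j)
  }
  idx + 1
}

#' Count overlapping k-grams of one sequence
#'
#' Counts every window of width `k` (stride 1).  Windows that overlap a
#' non-standard residue are excluded from both the counts and the
#' denominator; a sequence shorter than `k` yields no windows.
#'
#' @param residues A single residue string.
#' @param k Window width (positive integer).
#' @return A tibble with columns `kgram` and `count`, carrying the number
#'   of valid windows in attribute `n_windows`.
#' @examples
#' count_kgrams("MKLCMKVL", 2)                  # MK occurs twice, 7 windows
#' attr(count_kgrams("MKLCMKVL", 2), "n_windows")
#' @export
count_kgrams <- function(residues, k) {
  if (!is.character(residues) || length(residues) != 1) {
    abort("`residues` must be a single string")
  }
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    abort("`k` must be a single positive integer")
  }
  ranks <- residue_ranks(toupper(residues))
  idx <- window_block_indices(ranks, as.integer(k))
  valid <- idx[!is.na(idx)]
  if (length(valid) == 0) {
    out <- tibble(kgram = character(0), count = integer(0))
    attr(out, "n_windows") <- 0L
    return(out)
  }
  tab <- table(valid)
  block <- as.integer(names(tab))
  # reconstruct k-mer strings from block indices (base-20 digits)
  chars <- matrix("", nrow = length(block), ncol = k)
  rem <- block - 1L
  for (j in rev(seq_len(k))) {
    chars[, j] <- AMINO_ACIDS[rem %% 20 + 1]
    rem <- rem %/% 20
  }
  out <- tibble(kgram = apply(chars, 1, paste0, collapse = ""),
                count = as.integer(tab))
  out <- arrange(out, .data$kgram)
  attr(out, "n_windows") <- length(valid)
  out
}

#' Encode sequences as n-gram frequency vectors
#'
#' Converts each sequence into its frequency vector over the descriptor
#' universe, returned in sparse long form (absent descriptors have
#' frequency zero).  For each descriptor length k the frequency of a
#' k-gram is its window count divided by the number of valid k-windows of
#' that sequence, so each k-block of a clean sequence sums to 1.  Windows
#' overlapping non-standard residues are excluded from both numerator and
#' denominator (the `drop_ngrams` policy of [read_fasta()]).
#'
#' @param data A dataset tibble with columns `sequence_id` and `residues`
#'   (and usually `class`), e.g. from [load_labeled_dataset()] or
#'   [generate_sequences()].
#' @param space An [ngram_feature_space()]; default `ngram_feature_space(3)`.
#' @return A tibble with columns `sequence_id`, `class` (if present in
#'   `data`), `feature_index`, `descriptor`, `k`, `count`, `frequency`,
#'   one row per sequence/descriptor with a nonzero count.  Row order is
#'   input sequence order, then feature index.  The input's sequence order
#'   is kept in attribute `sequence_ids`.
#' @examples
#' seqs <- tibble::tibble(sequence_id = "s1", residues = "MKVLIFACM")
#' enc <- encode_sequences(seqs, ngram_feature_space(1))
#' enc[enc$descriptor == "M", "frequency"]   # 2/9
#' @export
encode_sequences <- function(data, space = ngram_feature_space(3)) {
  if (!inherits(space, "ngram_space")) {
    abort("`space` must be an `ngram_space` from ngram_feature_space()")
  }
  validate_dataset(data, require_classes = FALSE)
  has_class <- "class" %in% names(data)
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    ranks <- residue_ranks(data$residues[i])
    per_k <- purrr::map(seq_len(space$n_max), function(k) {
      idx <- window_block_indices(ranks, k)
      valid <- idx[!is.na(idx)]
      if (length(valid) == 0) return(NULL)
      tab <- table(valid)
      tibble(feature_index = space$offsets[k] + as.integer(names(tab)),
             k = k,
             count = as.integer(tab),
             frequency = as.integer(tab) / length(valid))
    })
    out <- bind_rows(per_k)
    if (nrow(out) == 0) return(NULL)
    out$sequence_id <- data$sequence_id[i]
    if (has_class) out$class <- data$class[i]
    out
  })
  enc <- bind_rows(rows)
  enc$descriptor <- space$descriptors[enc$feature_index]
  cols <- c("sequence_id", if (has_class) "class",
            "feature_index", "descriptor", "k", "count", "frequency")
  enc <- arrange(enc[, cols], match(.data$sequence_id, data$sequence_id),
                 .data$feature_index)
  attr(enc, "sequence_ids") <- data$sequence_id
  if (has_class) attr(enc, "class_labels") <- data$class
  attr(enc, "n_total") <- space$size
  enc
}

#' Materialise an encoded dataset as a sparse matrix
#'
#' @param encoded Long-form encoding from [encode_sequences()].
#' @param space The [ngram_feature_space()] used to encode.
#' @return A `dgCMatrix` (rows = sequences in input order, columns = all
#'   descriptors, named).  Row class labels, when present, are kept in
#'   attribute `class_labels`.
#' @export
feature_matrix <- function(encoded, space) {
  ids <- attr(encoded, "sequence_ids") %||% unique(encoded$sequence_id)
  m <- Matrix::sparseMatrix(
    i = match(encoded$sequence_id, ids),
    j = encoded$feature_index,
    x = encoded$frequency,
    dims = c(length(ids), space$size),
    dimnames = list(ids, space$descriptors)
  )
  if ("class" %in% names(encoded)) {
    attr(m, "class_labels") <-
      encoded$class[match(ids, encoded$sequence_id)]
  }
  m
}

#' Write an encoded dataset to disk
#'
#' `write_feature_csv()` writes the dense CSV used by the CLI (columns:
#' `sequence_id`, `class`, then one column per descriptor).
#' `write_feature_mtx()` writes MatrixMarket coordinate format with
#' sidecar descriptor-name and row-label files.
#'
#' @inheritParams feature_matrix
#' @param path Output path (`.csv`, or `.mtx` for the sparse writer).
#' @return Invisibly, the path written.
#' @export
write_feature_csv <- function(encoded, space, path) {
  m <- feature_matrix(encoded, space)
  labels <- attr(m, "class_labels")
  df <- as.data.frame(as.matrix(m), check.names = FALSE)
  df <- cbind(sequence_id = rownames(m),
              class = if (is.null(labels)) NA_character_
                      else as.character(labels),
              df)
  readr::write_csv(as_tibble(df), path)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
write_feature_mtx <- function(encoded, space, path) {
  m <- feature_matrix(encoded, space)
  Matrix::writeMM(m, path)
  writeLines(space$descriptors, paste0(path, ".descriptors"))
  labels <- attr(m, "class_labels")
  readr::write_tsv(
    tibble(sequence_id = rownames(m),
           class = if (is.null(labels)) NA_character_
                   else as.character(labels)),
    paste0(path, ".rows")
  )
  invisible(path)
}

#' Read a dense feature CSV back into long encoded form
#'
#' Inverse of [write_feature_csv()]; used by the CLI to hand matrices
#' between stages.
#'
#' @param path CSV path written by [write_feature_csv()].
#' @param space The matching [ngram_feature_space()].
#' @return A long-form encoding tibble as from [encode_sequences()]
#'   (without `k`/`count` columns).
#' @export
read_feature_csv <- function(path, space) {
  df <- readr::read_csv(path, col_types = readr::cols(
    sequence_id = "c", class = "c", .default = "d"))
  desc <- setdiff(names(df), c("sequence_id", "class"))
  if (!identical(desc, space$descriptors)) {
    abort("feature CSV columns do not match the descriptor universe")
  }
  long <- tidyr::pivot_longer(df, cols = -c("sequence_id", "class"),
                              names_to = "descriptor",
                              values_to = "frequency")
  long <- long[long$frequency != 0, ]
  long$feature_index <- descriptor_index(long$descriptor, space)
  long$class <- factor(long$class, levels = unique(df$class))
  out <- long[, c("sequence_id", "class", "feature_index", "descriptor",
                  "frequency")]
  attr(out, "sequence_ids") <- df$sequence_id
  attr(out, "class_labels") <- factor(df$class, levels = unique(df$class))
  attr(out, "n_total") <- space$size
  out
}
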