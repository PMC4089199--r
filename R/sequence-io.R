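#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file of amino-acid sequences into a tibble, normalising
#' residues to uppercase and applying a policy for non-standard residues
#' (anything outside the 20-letter alphabet in [AMINO_ACIDS]: B, J, O, U,
#' X, Z, `*`, gaps, ...).
#'
#' @param path Path to a FASTA file.
#' @param residue_policy How to treat sequences containing non-standard
#'   residues:
#'   * `"drop_ngrams"` (default): keep the sequence; downstream encoding
#'     skips every n-gram window that overlaps a non-standard position.
#'     UniProt entries occasionally contain B/Z/X and rejecting whole
#'     sequences would bias class counts.
#'   * `"reject"`: abort with an error naming the offending sequence.
#'   * `"skip_sequence"`: drop the record with a warning.
#' @return A tibble with columns `sequence_id` (first whitespace-delimited
#'   token of the header), `residues` (uppercase string) and
#'   `has_nonstandard` (logical).  Rows are in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "MKVLIFACM"), fa)
#' read_fasta(fa)
#' @seealso [load_labeled_dataset()]
#' @export
read_fasta <- function(path,
                       residue_policy = c("drop_ngrams", "reject",
                                          "skip_sequence")) {
  residue_policy <- match.arg(residue_policy)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      abort(paste0("malformed FASTA in ", path, ": ", conditionMessage(e)))
    }
  )
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  residues <- unname(toupper(as.character(set)))
  if (any(!nzchar(residues))) {
    abort(paste0("zero-length sequence(s) in ", path, ": ",
                 paste(ids[!nzchar(residues)], collapse = ", ")))
  }
  nonstd <- !purrr::map_lgl(strsplit(residues, "", fixed = TRUE),
                            ~ all(.x %in% AMINO_ACIDS))
  if (residue_policy == "reject" && any(nonstd)) {
    abort(paste0("non-standard residues in sequence(s): ",
                 paste(ids[nonstd], collapse = ", "),
                 " (residue_policy = \"reject\")"))
  }
  out <- tibble(sequence_id = ids, residues = residues,
                has_nonstandard = nonstd)
  if (residue_policy == "skip_sequence" && any(nonstd)) {
    warn(paste0("skipping ", sum(nonstd),
                " sequence(s) with non-standard residues: ",
                paste(ids[nonstd], collapse = ", ")))
    out <- out[!out$has_nonstandard, ]
  }
  out
}

#' Read a sequence-id to class label map
#'
#' Reads a two-column TSV with header `sequence_id<TAB>class`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sequence_id` and `class`.
#' @export
read_label_map <- function(path) {
  lm <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("sequence_id", "class") %in% names(lm))) {
    abort("label map must have header columns `sequence_id` and `class`")
  }
  lm[, c("sequence_id", "class")]
}

#' Load a labeled multi-class protein sequence dataset
#'
#' Builds the labeled dataset every downstream step consumes, either from
#' one FASTA file per class (a named vector of paths) or from a single
#' FASTA plus a label-map TSV.  Classes are ordered by first appearance;
#' duplicate ids across files are an error (superfamily sets are expected
#' to be non-redundant), as are classes with fewer than 2 sequences
#' (per-class variance needs at least 2).
#'
#' @param fasta Either a named character vector `c(class = path, ...)` with
#'   one FASTA per class, or a single unnamed FASTA path (then `labels` is
#'   required).
#' @param labels Optional path to a label-map TSV (see [read_label_map()]).
#' @inheritParams read_fasta
#' @return A tibble with columns `sequence_id`, `class` (factor, levels in
#'   first-appearance order), `residues`, `has_nonstandard`.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines(c(">g1", "MKVLIFACM", ">g2", "ACMKVLIFAC"),
#'            file.path(dir, "globin.fasta"))
#' writeLines(c(">r1", "MKLCMKVL", ">r2", "CMKVIFACM"),
#'            file.path(dir, "ras.fasta"))
#' load_labeled_dataset(c(globin = file.path(dir, "globin.fasta"),
#'                        ras = file.path(dir, "ras.fasta")))
#' @export
load_labeled_dataset <- function(fasta, labels = NULL,
                                 residue_policy = c("drop_ngrams", "reject",
                                                    "skip_sequence")) {
  residue_policy <- match.arg(residue_policy)
  if (!is.null(names(fasta)) && all(nzchar(names(fasta)))) {
    parts <- purrr::imap(fasta, function(path, cls) {
      mutate(read_fasta(path, residue_policy), class = cls)
    })
    data <- bind_rows(parts)
    lev <- names(fasta)
  } else {
    if (length(fasta) != 1 || is.null(labels)) {
      abort(paste0("`fasta` must be a named vector of per-class paths, ",
                   "or a single path together with `labels`"))
    }
    seqs <- read_fasta(fasta, residue_policy)
    lm <- read_label_map(labels)
    missing_ids <- setdiff(lm$sequence_id, seqs$sequence_id)
    if (length(missing_ids) > 0) {
      abort(paste0("label map refers to ids missing from the FASTA: ",
                   paste(missing_ids, collapse = ", ")))
    }
    unlabeled <- setdiff(seqs$sequence_id, lm$sequence_id)
    if (length(unlabeled) > 0) {
      abort(paste0("sequences without a label: ",
                   paste(unlabeled, collapse = ", ")))
    }
    data <- left_join(seqs, lm, by = "sequence_id")
    lev <- unique(lm$class[match(seqs$sequence_id, lm$sequence_id)])
  }
  data <- data[, c("sequence_id", "class", "residues", "has_nonstandard")]
  data$class <- factor(data$class, levels = lev)
  # class order then within-class input order
  data <- data[order(as.integer(data$class)), ]
  validate_dataset(data)
  as_tibble(data)
}

#' Write a labeled dataset to FASTA files and a label map
#'
#' Inverse of [load_labeled_dataset()]: writes one FASTA per class plus a
#' `labels.tsv` map, so a dataset round-trips identically.
#'
#' @param data Dataset tibble (`sequence_id`, `class`, `residues`).
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the FASTA paths written.
#' @export
write_dataset <- function(data, dir) {
  validate_dataset(data)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (cls in class_levels(data$class)) {
    sub <- data[as.character(data$class) == cls, ]
    path <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", cls), ".fasta"))
    writeLines(paste0(">", sub$sequence_id, "\n", sub$residues), path)
    paths[cls] <- path
  }
  readr::write_tsv(
    tibble(sequence_id = data$sequence_id,
           class = as.character(data$class)),
    file.path(dir, "labels.tsv")
  )
  invisible(paths)
}
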