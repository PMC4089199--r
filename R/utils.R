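#' The twenty standard amino acids
#'
#' The one-letter codes of the 20 standard amino acids, in alphabetical
#' order.  This is the alphabet over which all n-gram descriptors are
#' enumerated; residues outside it (B, J, O, U, X, Z, gaps, stops) are
#' "non-standard" and handled according to the `residue_policy` of
#' [read_fasta()].
#'
#' @format A character vector of length 20.
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Truncate frequencies for display
#'
#' Truncates toward zero at a fixed number of decimals (2/7 displays as
#' 0.28, 1/6 as 0.16).  Display-only: no internal computation ever
#' truncates.
#'
#' @param x Numeric vector of frequencies.
#' @param digits Number of decimal places kept (default 2).
#' @return Numeric vector truncated toward zero.
#' @examples
#' trunc_frequency(c(2 / 7, 1 / 6))
#' @export
trunc_frequency <- function(x, digits = 2) {
  trunc(x * 10^digits) / 10^digits
}

# shared validation for the (sequence_id, class, residues) dataset tibble
validate_dataset <- function(data, require_classes = TRUE) {
  needed <- c("sequence_id", "residues")
  if (require_classes) needed <- c(needed, "class")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` must have columns ",
                 paste0("`", needed, "`", collapse = ", "),
                 "; missing: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) == 0) abort("dataset is empty")
  dup <- data$sequence_id[duplicated(data$sequence_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence ids: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (any(!nzchar(data$residues))) abort("empty residue strings in dataset")
  if (require_classes) {
    tab <- table(data$class)
    if (length(tab) < 2) {
      abort("dataset must contain at least 2 classes")
    }
    small <- names(tab)[tab < 2]
    if (length(small) > 0) {
      abort(paste0("classes with fewer than 2 sequences: ",
                   paste(small, collapse = ", ")))
    }
  }
  invisible(data)
}

# class labels in first-appearance order
class_levels <- function(x) {
  if (is.factor(x)) levels(x) else unique(as.character(x))
}
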