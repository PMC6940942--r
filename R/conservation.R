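# Alignment-column conservation: relative entropy (information content) and
# per-column residue frequency, reported in reference-sequence coordinates.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Count residues in one alignment column
#'
#' Ambiguity letters (B, Z, X, U, J, O) carry no usable composition signal and
#' are counted as gaps, with a warning.
#'
#' @param letters Character vector of single letters, one per aligned sequence
#'   (`-` or `.` for gaps).
#' @return A list with `counts` (named integer over the 20 amino acids) and
#'   `gaps`.
#' @export
column_counts <- function(letters) {
  letters <- toupper(letters)
  is_gap <- letters %in% c("-", ".")
  odd <- !is_gap & !(letters %in% AA20)
  if (any(odd)) {
    warning("non-canonical letters counted as gaps: ",
            paste(unique(letters[odd]), collapse = ", "), call. = FALSE)
    is_gap <- is_gap | odd
  }
  counts <- table(factor(letters[!is_gap], levels = AA20))
  list(counts = stats::setNames(as.integer(counts), AA20),
       gaps = sum(is_gap))
}

#' Relative entropy (information content) of an alignment column
#'
#' `R = log2(20) - (H + e_n)` in bits, where `H` is the Shannon entropy of the
#' non-gap residue frequencies and `e_n = 19 / (2 ln 2 n)` is the small-sample
#' correction (off by default; with hundreds of sequences it is a few
#' hundredths of a bit). Gaps are excluded from the frequency denominator. The
#' result is clamped at zero.
#'
#' @param counts Named integer vector of residue counts (as from
#'   [column_counts()]); names outside the 20-letter alphabet are rejected.
#' @param correct_small_sample Apply the `e_n` correction (default `FALSE`).
#' @return Information content in bits, in `[0, log2(20)]`.
#' @examples
#' relative_entropy(c(Y = 50L)) # fully conserved: log2(20) = 4.3219 bits
#' @export
relative_entropy <- function(counts, correct_small_sample = FALSE) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    stop("all-gap column: relative entropy undefined", call. = FALSE)
  }
  if (!all(names(counts) %in% AA20)) {
    stop("counts must be named by canonical amino-acid letters", call. = FALSE)
  }
  n <- sum(counts)
  f <- counts / n
  h <- -sum(f * log2(f))
  e_n <- if (correct_small_sample) (length(AA20) - 1) / (2 * log(2) * n) else 0
  max(log2(length(AA20)) - (h + e_n), 0)
}

#' Frequency of one residue in an alignment column
#'
#' @param counts Named integer residue counts for the column.
#' @param aa Single amino-acid letter.
#' @return Percentage of non-gap rows carrying `aa` (gaps excluded from the
#'   denominator).
#' @examples
#' residue_frequency(c(Y = 7L, F = 2L), "Y") # 77.78
#' @export
residue_frequency <- function(counts, aa) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    stop("all-gap column: frequency undefined", call. = FALSE)
  }
  100 * sum(counts[names(counts) == toupper(aa)]) / sum(counts)
}

#' Map reference residue positions to alignment columns
#'
#' @param alignment Named character vector of equal-length aligned sequences.
#' @param reference_id Name of the reference sequence.
#' @return A tibble with `position` (1-based, ungapped reference coordinate),
#'   `column` (alignment column index) and `ref_letter`.
#' @export
map_columns_to_reference <- function(alignment, reference_id) {
  aln <- check_alignment(alignment)
  if (!reference_id %in% names(aln)) {
    stop("reference sequence '", reference_id, "' not in alignment",
         call. = FALSE)
  }
  ref <- stringr::str_split_1(aln[[reference_id]], "")
  non_gap <- !(ref %in% c("-", "."))
  tibble::tibble(position = seq_len(sum(non_gap)),
                 column = which(non_gap),
                 ref_letter = ref[non_gap])
}

check_alignment <- function(alignment) {
  if (is.null(names(alignment)) || any(names(alignment) == "")) {
    stop("alignment sequences must be named", call. = FALSE)
  }
  w <- unique(nchar(alignment))
  if (length(w) != 1) {
    stop("aligned sequences must share one width", call. = FALSE)
  }
  alignment
}

alignment_matrix <- function(alignment) {
  aln <- check_alignment(alignment)
  do.call(rbind, strsplit(toupper(unname(aln)), ""))
}

#' Per-position conservation table in reference coordinates
#'
#' For every non-gap position of the reference sequence, computes the column's
#' relative entropy and the tyrosine frequency (gaps excluded), and flags
#' highlighted positions (typically the phosphosites).
#'
#' @param alignment Named character vector of aligned sequences.
#' @param reference_id Name of the reference row.
#' @param highlight Integer positions (reference coordinates) to flag.
#' @param correct_small_sample Passed to [relative_entropy()].
#' @return A `conservation_profile` tibble: `position`, `column`, `ref_letter`,
#'   `n_seqs`, `R_bits`, `Y_percent`, `highlighted`.
#' @export
conservation_table <- function(alignment, reference_id, highlight = integer(),
                               correct_small_sample = FALSE) {
  m <- alignment_matrix(alignment)
  map <- map_columns_to_reference(alignment, reference_id)
  rows <- purrr::pmap(map, function(position, column, ref_letter) {
    cc <- suppressWarnings(column_counts(m[, column]))
    tibble::tibble(
      position = position, column = column, ref_letter = ref_letter,
      n_seqs = sum(cc$counts),
      R_bits = relative_entropy(cc$counts, correct_small_sample),
      Y_percent = residue_frequency(cc$counts, "Y")
    )
  }) |> dplyr::bind_rows() |>
    dplyr::mutate(highlighted = .data$position %in% highlight)
  class(rows) <- c("conservation_profile", class(rows))
  rows
}

#' Stacked letter-height table for a conservation logo
#'
#' Letter heights follow the relative-entropy logo convention: each residue's
#' height in a column is its frequency times the column's information content,
#' so the heights stack to the column's `R`.
#'
#' @inheritParams conservation_table
#' @return A tibble with one row per (position, letter) with positive height:
#'   `position`, `column`, `letter`, `height`, `R_bits`, `highlighted`.
#' @export
logo_table <- function(alignment, reference_id, highlight = integer(),
                       correct_small_sample = FALSE) {
  m <- alignment_matrix(alignment)
  map <- map_columns_to_reference(alignment, reference_id)
  purrr::pmap(map, function(position, column, ref_letter) {
    cc <- suppressWarnings(column_counts(m[, column]))
    counts <- cc$counts[cc$counts > 0]
    r <- relative_entropy(cc$counts, correct_small_sample)
    tibble::tibble(
      position = position, column = column,
      letter = names(counts),
      height = r * as.numeric(counts) / sum(counts),
      R_bits = r
    )
  }) |> dplyr::bind_rows() |>
    dplyr::mutate(highlighted = .data$position %in% highlight)
}
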