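# Readers and writers for the plain-text formats the pipeline consumes:
# two-column centroid peak lists, quant/rule CSVs and aligned sequences.

#' Read a centroided peak list
#'
#' Accepts two-column text (m/z, intensity) with either comma or whitespace
#' delimiters; `#` lines are comments and an optional `mz,intensity` header is
#' skipped. Rows are sorted by m/z and duplicate m/z rows are summed.
#'
#' @param path File path.
#' @return A tibble with columns `mz` and `intensity`.
#' @export
read_peaklist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("empty peak list: ", path, call. = FALSE)
  if (grepl("^\\s*m/?z\\b", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]; lineno <- lineno[-1]
  }
  fields <- stringr::str_split(trimws(lines), "[,\\s]+")
  vals <- purrr::map2(fields, lineno, function(f, ln) {
    v <- suppressWarnings(as.numeric(f))
    if (length(v) < 2 || anyNA(v[1:2])) {
      stop("unparseable peak-list row at line ", ln, call. = FALSE)
    }
    v[1:2]
  })
  tibble::tibble(
    mz = purrr::map_dbl(vals, 1),
    intensity = purrr::map_dbl(vals, 2)
  ) |>
    dplyr::group_by(.data$mz) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    dplyr::arrange(.data$mz)
}

#' Write a peak list
#'
#' @param spectrum A tibble with `mz` and `intensity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(spectrum, path) {
  readr::write_csv(spectrum[c("mz", "intensity")], path)
  invisible(path)
}

quant_cols <- c("peptide", "charge", "mods", "auc", "replicate", "sample",
                "time_point")

#' Read a bottom-up quant table
#'
#' Schema: `peptide,charge,mods,auc,replicate,sample,time_point` with `mods`
#' as semicolon-joined `pos:name` tokens (empty for unmodified). Every mods
#' token is validated up front; a malformed one reports its row number.
#'
#' @param path CSV path.
#' @return A quant-record tibble.
#' @export
read_quant_csv <- function(path) {
  spec <- list(peptide = "c", charge = "i", mods = "c", auc = "d",
               replicate = "i", sample = "c", time_point = "d")
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = do.call(readr::cols,
                                           spec[intersect(names(spec), hdr)]))
  miss <- setdiff(quant_cols, names(x))
  if (length(miss)) {
    stop("quant table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x$mods[is.na(x$mods)] <- ""
  for (i in seq_len(nrow(x))) {
    ok <- tryCatch({ parse_mods(x$mods[i]); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("malformed mods token in row ", i, ": '", x$mods[i], "'",
                  call. = FALSE)
  }
  x[quant_cols]
}

#' @rdname read_quant_csv
#' @param records A quant-record tibble.
#' @export
write_quant_csv <- function(records, path) {
  readr::write_csv(records[quant_cols], path)
  invisible(path)
}

#' Read / write a representative-peptide rule table
#'
#' Schema: `residue,peptide,charge,pool_met_oxidation`.
#'
#' @param path CSV path.
#' @return A rule tibble.
#' @export
read_rules_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         residue = "c", peptide = "c", charge = "i",
                         pool_met_oxidation = "l"
                       ))
  miss <- setdiff(c("residue", "peptide", "charge"), names(x))
  if (length(miss)) {
    stop("rule table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' @rdname read_rules_csv
#' @param rules A rule tibble.
#' @export
write_rules_csv <- function(rules, path) {
  readr::write_csv(rules, path)
  invisible(path)
}

#' Read an alignment from aligned FASTA or Stockholm
#'
#' FASTA reading goes through Biostrings; the minimal single-block Stockholm
#' reader accepts the `# STOCKHOLM 1.0` ... `//` layout with one sequence per
#' line (annotation lines starting with `#=` are ignored).
#'
#' @param path File path.
#' @param format `"fasta"` (default) or `"stockholm"`.
#' @return A named character vector of equal-width aligned sequences.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  aln <- if (format == "fasta") {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA requires the Biostrings package", call. = FALSE)
    }
    s <- Biostrings::readAAStringSet(path)
    stats::setNames(as.character(s), names(s))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^(#|//|\\s*$)", lines)]
    if (length(lines) == 0) stop("no sequences in ", path, call. = FALSE)
    parts <- stringr::str_split(trimws(lines), "\\s+")
    bad <- purrr::map_int(parts, length) != 2
    if (any(bad)) stop("unparseable Stockholm line: ", lines[bad][1],
                       call. = FALSE)
    nm <- purrr::map_chr(parts, 1)
    sq <- purrr::map_chr(parts, 2)
    # interleaved blocks concatenate per name
    tapply(sq, factor(nm, levels = unique(nm)), paste, collapse = "") |>
      c()
  }
  check_alignment(aln)
}

#' Write an alignment as aligned FASTA
#'
#' @param alignment Named character vector of aligned sequences.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(alignment, path) {
  check_alignment(alignment)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(alignment)) {
    writeLines(c(paste0(">", names(alignment)[i]), alignment[[i]]), con)
  }
  invisible(path)
}
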