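# Bottom-up phosphosite relative quantification: representative-peptide
# filtering, reference-peptide normalisation, percent-of-maximum profiles,
# autodephosphorylation-resistance classification and phosphopattern tables.

parse_mods <- function(mods) {
  # "3:phospho;1:oxidation" -> tibble(position, name); "" -> zero rows
  purrr::map(mods, function(m) {
    if (is.na(m) || m == "") {
      return(tibble::tibble(position = integer(), name = character()))
    }
    tok <- stringr::str_split_1(m, ";")
    bad <- !stringr::str_detect(tok, "^\\d+:[A-Za-z_]+$")
    if (any(bad)) {
      stop("malformed mods token: '", tok[bad][1], "'", call. = FALSE)
    }
    tibble::tibble(
      position = as.integer(stringr::str_extract(tok, "^\\d+")),
      name = stringr::str_remove(tok, "^\\d+:")
    )
  })
}

#' Filter quant records down to each site's representative peptide
#'
#' Chymotryptic digestion of a multiply phosphorylated protein yields
#' heterogeneous phosphopeptides (missed cleavages after phospho-Tyr, multiple
#' charges, multi-phospho forms), so each residue is quantified through one
#' representative peptide at one charge, carrying a phosphate on that residue
#' only. Records failing the rule are excluded; when `pool_met_oxidation` is
#' set on a rule, oxidised and unoxidised forms of the same peptide and charge
#' are summed.
#'
#' @param records A quant table: columns `peptide`, `charge`, `mods`
#'   (semicolon-joined `pos:name` tokens), `auc`, `replicate`, `sample`,
#'   `time_point`.
#' @param rules Rule table: columns `residue`, `peptide`, `charge`,
#'   `pool_met_oxidation`. Each rule peptide must contain exactly one tyrosine.
#' @return A tibble of per-site records: `residue`, `sample`, `time_point`,
#'   `replicate`, `auc`.
#' @export
select_representative <- function(records, rules) {
  stopifnot(all(c("peptide", "charge", "mods", "auc", "replicate", "sample",
                  "time_point") %in% names(records)),
            all(c("residue", "peptide", "charge") %in% names(rules)))
  if (!"pool_met_oxidation" %in% names(rules)) rules$pool_met_oxidation <- FALSE
  y_pos <- stringr::str_locate_all(rules$peptide, "Y")
  n_y <- purrr::map_int(y_pos, nrow)
  if (any(n_y != 1)) {
    stop("each rule peptide must contain exactly one tyrosine; offending: ",
         paste(rules$peptide[n_y != 1], collapse = ", "), call. = FALSE)
  }
  rules$y_position <- purrr::map_int(y_pos, function(m) as.integer(m[1, 1]))

  mods <- parse_mods(records$mods)
  records$n_phospho <- purrr::map_int(mods, function(m) sum(m$name == "phospho"))
  records$phospho_pos <- purrr::map_int(mods, function(m) {
    p <- m$position[m$name == "phospho"]
    if (length(p) == 1) p else NA_integer_
  })
  records$n_other_mods <- purrr::map_int(mods, function(m) {
    sum(m$name != "phospho")
  })

  records |>
    dplyr::inner_join(
      rules[c("residue", "peptide", "charge", "y_position",
              "pool_met_oxidation")],
      by = c("peptide", "charge")
    ) |>
    dplyr::filter(.data$n_phospho == 1,
                  .data$phospho_pos == .data$y_position,
                  # without pooling only the unoxidised form represents the site
                  .data$pool_met_oxidation | .data$n_other_mods == 0) |>
    dplyr::group_by(.data$residue, .data$sample, .data$time_point,
                    .data$replicate) |>
    dplyr::summarise(auc = sum(.data$auc), .groups = "drop")
}

#' Normalise site AUCs to a non-phosphorylatable reference peptide
#'
#' Within each replicate the phosphopeptide AUC is divided by the AUC of a
#' reference peptide that cannot be phosphorylated in the reaction (and carries
#' no Cys/Met); replicate ratios are then averaged per residue and time point.
#' Division by a same-replicate reference cancels loading and injection
#' differences, so the ratio is invariant to a global per-replicate scaling of
#' all AUCs.
#'
#' @param site_records Output of [select_representative()].
#' @param records The full quant table (the reference records are looked up
#'   here, unmodified forms only).
#' @param reference_peptide,reference_charge Identity of the reference peptide.
#' @return A tibble: `residue`, `sample`, `time_point`, `mean_ratio`,
#'   `sd_ratio`, `n_replicates`.
#' @export
normalize_to_reference <- function(site_records, records, reference_peptide,
                                   reference_charge) {
  mods <- parse_mods(records$mods)
  is_ref <- records$peptide == reference_peptide &
    records$charge == reference_charge &
    purrr::map_int(mods, nrow) == 0
  ref <- records[is_ref, c("sample", "time_point", "replicate", "auc")] |>
    dplyr::rename(ref_auc = "auc")
  joined <- dplyr::left_join(site_records, ref,
                             by = c("sample", "time_point", "replicate"))
  bad <- is.na(joined$ref_auc) | joined$ref_auc <= 0
  if (any(bad)) {
    b <- joined[bad, ][1, ]
    stop(sprintf(
      "missing or zero reference AUC for sample '%s', time %s, replicate %s",
      b$sample, format(b$time_point), format(b$replicate)), call. = FALSE)
  }
  joined |>
    dplyr::mutate(ratio = .data$auc / .data$ref_auc) |>
    dplyr::group_by(.data$residue, .data$sample, .data$time_point) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio),
                     sd_ratio = if (dplyr::n() > 1) stats::sd(.data$ratio) else 0,
                     n_replicates = dplyr::n(), .groups = "drop")
}

#' Percent-of-maximum kinetic profiles per residue
#'
#' Each residue's mean ratios across the time course are divided by that
#' residue's largest mean ratio and scaled to 0-100; replicate SDs are rescaled
#' by the same factor, so profile shapes are comparable across residues while
#' absolute levels are not.
#'
#' @param ratios Output of [normalize_to_reference()].
#' @return A `site_profiles` tibble: `residue`, `sample`, `time_point`,
#'   `mean_ratio`, `percent`, `sd_percent`, `all_zero` (flag for residues whose
#'   every mean is zero; their percents are reported as 0 with a warning).
#' @export
percent_of_max <- function(ratios) {
  stopifnot(all(c("residue", "time_point", "mean_ratio") %in% names(ratios)))
  out <- ratios |>
    dplyr::group_by(.data$residue) |>
    dplyr::mutate(
      .max = max(.data$mean_ratio),
      all_zero = .data$.max <= 0,
      percent = dplyr::if_else(.data$.max > 0,
                               100 * .data$mean_ratio / .data$.max, 0),
      sd_percent = dplyr::if_else(.data$.max > 0,
                                  100 * .data$sd_ratio / .data$.max, 0)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".max")
  if (any(out$all_zero)) {
    warning("all-zero ratio series for residue(s): ",
            paste(unique(out$residue[out$all_zero]), collapse = ", "),
            call. = FALSE)
  }
  class(out) <- c("site_profiles", class(out))
  out
}

#' Classify residues as resistant or labile to autodephosphorylation
#'
#' In an experiment whose later span exposes phosphosites to an active
#' phosphatase, a residue still detected at the final sampling time resists
#' autodephosphorylation; one no longer detected is labile. The call is made
#' on the reference-normalised mean ratio at the final time point (a
#' percent-of-max series always ends at 100 for a monotonically rising site,
#' so percent values cannot carry the final-time call).
#'
#' @param ratios Output of [normalize_to_reference()] (per-residue mean ratios
#'   over the time course).
#' @param final_time Time point at which the call is made; defaults to the
#'   latest time in the table, which must be sampled for every residue.
#' @param threshold Detection bound on the mean ratio (default 0.01; with
#'   matched phospho and reference signal scales this corresponds to ~1% site
#'   occupancy).
#' @return A tibble: `residue`, `final_ratio`, `resistant` (logical),
#'   `resistance_class` (`"resistant"` / `"labile"`).
#' @export
classify_resistance <- function(ratios, final_time = NULL, threshold = 0.01) {
  stopifnot(all(c("residue", "time_point", "mean_ratio") %in% names(ratios)))
  if (is.null(final_time)) final_time <- max(ratios$time_point)
  at_end <- dplyr::filter(ratios, .data$time_point == final_time)
  if (nrow(at_end) == 0) {
    stop("no sample at the requested final time point", call. = FALSE)
  }
  missing <- setdiff(unique(ratios$residue), at_end$residue)
  if (length(missing)) {
    stop("no final-time sample for residue(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  at_end |>
    dplyr::transmute(
      residue = .data$residue,
      final_ratio = .data$mean_ratio,
      resistant = .data$mean_ratio >= threshold,
      resistance_class = dplyr::if_else(.data$resistant, "resistant", "labile")
    ) |>
    dplyr::arrange(residue_position(.data$residue))
}

#' Residues detected in a set of normalised ratios
#'
#' @param ratios Output of [normalize_to_reference()].
#' @param threshold Detection bound on the per-time mean ratio; the default 0
#'   calls any strictly positive signal detected (presence/absence semantics).
#' @return Character vector of residues detected at any time point.
#' @export
detected_sites <- function(ratios, threshold = 0) {
  det <- ratios |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(hit = any(.data$mean_ratio > threshold), .groups = "drop") |>
    dplyr::filter(.data$hit)
  res <- det$residue
  res[order(residue_position(res))]
}

residue_position <- function(residue) {
  as.integer(stringr::str_extract(residue, "\\d+"))
}

#' Build a condition-by-residue phosphopattern table
#'
#' @param detections A tibble with columns `condition` and `residue`, one row
#'   per detected phosphoresidue per condition. Serine residues (e.g. "S138")
#'   are first-class labels alongside tyrosines. Residues detected in no
#'   condition never appear; condition labels must be unique in the sense that
#'   duplicated (condition, residue) rows collapse to one detection.
#' @param conditions Optional character vector fixing row order (and including
#'   conditions with no detections); defaults to order of first appearance.
#' @return A `phospho_pattern` tibble: one row per condition, one logical
#'   column per residue, residues ordered by sequence position.
#' @export
build_pattern_table <- function(detections, conditions = NULL) {
  stopifnot(all(c("condition", "residue") %in% names(detections)))
  if (is.null(conditions)) conditions <- unique(detections$condition)
  if (anyDuplicated(conditions)) {
    stop("duplicate condition labels", call. = FALSE)
  }
  residues <- unique(detections$residue)
  residues <- residues[order(residue_position(residues),
                             stringr::str_sub(residues, 1, 1))]
  out <- tidyr::expand_grid(condition = conditions, residue = residues) |>
    dplyr::left_join(
      dplyr::distinct(detections) |> dplyr::mutate(detected = TRUE),
      by = c("condition", "residue")
    ) |>
    dplyr::mutate(detected = !is.na(.data$detected)) |>
    tidyr::pivot_wider(names_from = "residue", values_from = "detected")
  class(out) <- c("phospho_pattern", class(out))
  out
}

#' Render a phosphopattern table as plain text
#'
#' Detected cells are marked `X`, the customary presentation of such tables.
#'
#' @param pattern A [build_pattern_table()] result.
#' @return A character vector of lines (invisibly printed with `cat()` when
#'   at the console via the print method).
#' @export
render_pattern_table <- function(pattern) {
  stopifnot(inherits(pattern, "phospho_pattern") || is.data.frame(pattern))
  res_cols <- setdiff(names(pattern), "condition")
  widths <- pmax(nchar(res_cols), 1)
  cond_w <- max(nchar(c("Condition", pattern$condition)))
  header <- paste0(formatC("Condition", width = cond_w, flag = "-"), "  ",
                   paste(purrr::map2_chr(res_cols, widths,
                                         function(s, w) formatC(s, width = w)),
                         collapse = " "))
  rows <- purrr::map_chr(seq_len(nrow(pattern)), function(i) {
    marks <- purrr::map_chr(seq_along(res_cols), function(j) {
      formatC(if (isTRUE(pattern[[res_cols[j]]][i])) "X" else "",
              width = widths[j])
    })
    paste0(formatC(pattern$condition[i], width = cond_w, flag = "-"), "  ",
           paste(marks, collapse = " "))
  })
  c(header, rows)
}
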