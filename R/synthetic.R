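# Seeded generators for every input the pipeline consumes: centroided native
# spectra, bottom-up quant tables and multiple sequence alignments. Each
# generator is a pure function of its configuration; a fixed seed gives
# byte-identical output.

#' Configuration for the synthetic-data generators
#'
#' Bundles an experiment design (see [eya3_design()]) with the instrument- and
#' noise-model parameters of the generators. Defaults encode the study
#' conditions the packaged designs emulate: a ~65.6 kDa protein observed at
#' charges 14+ to 18+, a partially acetylated N terminus, three technical
#' replicates with ~10% multiplicative AUC noise, and a 721-sequence homologue
#' alignment.
#'
#' @param design An [eya3_design()] list (or the name of one).
#' @param seed Integer seed; every generator derives its stream from it.
#' @param base_mass Neutral average mass of the unmodified, start-Met-cleaved
#'   base proteoform in Da.
#' @param acetyl_fraction Fraction of molecules carrying the N-terminal
#'   acetyl group.
#' @param charges Charge states of the envelope.
#' @param charge_profile Relative envelope intensity per charge (same length
#'   as `charges`); the default is triangular, peaking at 16+.
#' @param total_intensity Summed intensity laid down for the base envelope.
#' @param noise_floor Noise-peak intensity ceiling, relative to the tallest
#'   signal peak.
#' @param n_noise_peaks Number of uniform noise peaks added per spectrum.
#' @param include_complex Also lay down the envelope of the 1:1 chaperone
#'   complex at `base_mass + complex_partner_mass`.
#' @param complex_partner_mass Mass of the co-purified chaperone trimer in Da.
#' @param complex_charges Charge states used for the complex envelope.
#' @param n_replicates Technical replicates per quant time point.
#' @param auc_cv Coefficient of variation of the multiplicative log-normal
#'   AUC noise.
#' @param auc_scale Expected AUC of a fully occupied site (and of the
#'   reference peptide).
#' @param met_ox_fraction Fraction of a Met-containing peptide's signal found
#'   in the oxidised form.
#' @param alignment_n Number of homologue rows in the generated alignment.
#' @param ref_length Length of the synthetic reference sequence.
#' @param gap_rate Per-cell gap probability in homologue rows.
#' @param conservation_default Probability a homologue keeps the reference
#'   letter at an unlisted position.
#' @param conservation_by_position Named numeric vector (names are reference
#'   positions) overriding `conservation_default`; the default conserves the
#'   resistant phosphosites at 0.95 and the remaining phosphosites at 0.7.
#' @return A `phospho_sim_config` list.
#' @export
generator_config <- function(design = "d311n_timecourse",
                             seed = 20191213L,
                             base_mass = 65608.09,
                             acetyl_fraction = 0.3,
                             charges = 14:18,
                             charge_profile = c(1, 2, 3, 2, 1),
                             total_intensity = 1e5,
                             noise_floor = 0.01,
                             n_noise_peaks = 20L,
                             include_complex = FALSE,
                             complex_partner_mass = 47075.05,
                             complex_charges = 19:23,
                             n_replicates = 3L,
                             auc_cv = 0.1,
                             auc_scale = 1e6,
                             met_ox_fraction = 0.3,
                             alignment_n = 721L,
                             ref_length = 573L,
                             gap_rate = 0.05,
                             conservation_default = 0.3,
                             conservation_by_position = NULL) {
  if (is.character(design)) design <- eya3_design(design)
  stopifnot(length(charges) == length(charge_profile),
            acetyl_fraction >= 0, acetyl_fraction <= 1,
            auc_cv >= 0, gap_rate >= 0, gap_rate < 1)
  if (is.null(conservation_by_position)) {
    resistant <- c(77, 96, 105, 237, 508)
    other <- setdiff(eya3_sites()$position, resistant)
    conservation_by_position <- stats::setNames(
      c(rep(0.95, length(resistant)), rep(0.7, length(other))),
      c(resistant, other)
    )
  }
  if (any(conservation_by_position < 0 | conservation_by_position > 1)) {
    stop("conservation values must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(design = design, seed = as.integer(seed), base_mass = base_mass,
         acetyl_fraction = acetyl_fraction, charges = as.integer(charges),
         charge_profile = charge_profile / sum(charge_profile),
         total_intensity = total_intensity, noise_floor = noise_floor,
         n_noise_peaks = as.integer(n_noise_peaks),
         include_complex = include_complex,
         complex_partner_mass = complex_partner_mass,
         complex_charges = as.integer(complex_charges),
         n_replicates = as.integer(n_replicates), auc_cv = auc_cv,
         auc_scale = auc_scale, met_ox_fraction = met_ox_fraction,
         alignment_n = as.integer(alignment_n),
         ref_length = as.integer(ref_length), gap_rate = gap_rate,
         conservation_default = conservation_default,
         conservation_by_position = conservation_by_position),
    class = "phospho_sim_config"
  )
}

# log-normal multiplier with unit mean and the configured CV
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a centroided native spectrum for one time point
#'
#' Simulates the site occupancies of the configured design at `time_point`,
#' bridges them to a phosphate-count distribution (Poisson-binomial), and lays
#' down centroid peaks for every (acetyl, nP) proteoform state at its
#' theoretical m/z across the configured charges, heights proportional to
#' state fraction times the fixed per-charge envelope profile. Uniform noise
#' peaks are added below `noise_floor`; optionally the chaperone-complex
#' envelope is included.
#'
#' @param config A [generator_config()].
#' @param time_point Time in hours (within the design's phase span).
#' @return A peak-list tibble (`mz`, `intensity`, sorted, duplicates merged)
#'   with attributes `time_point`, `label` and `truth` (the generating state
#'   fractions: tibble `acetylated`, `n_phospho`, `fraction`).
#' @export
gen_native_spectrum <- function(config, time_point) {
  stopifnot(inherits(config, "phospho_sim_config"))
  withr::local_seed(config$seed %% 1000000L + round(1000 * time_point))
  d <- config$design
  occ <- purrr::map2_dbl(d$site_rates$k_p, d$site_rates$k_d,
                         function(kp, kd) {
                           site_occupancy(time_point, kp, kd, d$phases)
                         })
  stoich <- stoichiometry_from_occupancies(occ)
  d_ace <- mod_delta("acetyl", "avg")
  d_pho <- mod_delta("phospho", "avg")

  truth <- tidyr::expand_grid(
    acetylated = c(FALSE, TRUE),
    n_phospho = stoich$n_phospho
  ) |>
    dplyr::left_join(stoich[c("n_phospho", "fraction")], by = "n_phospho") |>
    dplyr::mutate(
      fraction = .data$fraction *
        dplyr::if_else(.data$acetylated, config$acetyl_fraction,
                       1 - config$acetyl_fraction)
    ) |>
    dplyr::filter(.data$fraction > 1e-9)

  peaks <- truth |>
    dplyr::mutate(mass = config$base_mass +
                    as.integer(.data$acetylated) * d_ace +
                    .data$n_phospho * d_pho) |>
    tidyr::expand_grid(k = seq_along(config$charges)) |>
    dplyr::mutate(
      charge = config$charges[.data$k],
      mz = mass_to_mz(.data$mass, .data$charge),
      intensity = config$total_intensity * .data$fraction *
        config$charge_profile[.data$k]
    ) |>
    dplyr::select("mz", "intensity")

  if (config$include_complex) {
    cplx_mass <- config$base_mass + config$complex_partner_mass
    peaks <- dplyr::bind_rows(
      peaks,
      tibble::tibble(
        mz = mass_to_mz(cplx_mass, config$complex_charges),
        intensity = 0.2 * config$total_intensity *
          rep_len(config$charge_profile, length(config$complex_charges))
      )
    )
  }

  if (config$n_noise_peaks > 0) {
    rng <- range(peaks$mz)
    span <- diff(rng) + 200
    peaks <- dplyr::bind_rows(
      peaks,
      tibble::tibble(
        mz = stats::runif(config$n_noise_peaks, rng[1] - 100, rng[2] + 100),
        intensity = stats::runif(config$n_noise_peaks, 0,
                                 config$noise_floor * max(peaks$intensity))
      )
    )
    stopifnot(span > 0)
  }

  out <- peaks |>
    dplyr::group_by(mz = round(.data$mz, 6)) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    dplyr::arrange(.data$mz)
  attr(out, "time_point") <- time_point
  attr(out, "label") <- paste0(d$name, "_t", format(time_point))
  attr(out, "truth") <- truth
  out
}

#' Generate a bottom-up quant table for the configured design
#'
#' For every representative peptide, time point and replicate, the AUC is the
#' site occupancy times `auc_scale` times a unit-mean log-normal factor
#' (`auc_cv`); the reference peptide's AUC is `auc_scale` times its own noise
#' factor. Met-containing peptides configured for oxidation pooling are split
#' into oxidised and unoxidised records (`met_ox_fraction` of the signal in
#' the oxidised form). A site with zero occupancy yields a zero-AUC record.
#'
#' @param config A [generator_config()].
#' @return A quant-record tibble with the [select_representative()] schema
#'   (`peptide`, `charge`, `mods`, `auc`, `replicate`, `sample`,
#'   `time_point`), time points in hours.
#' @export
gen_quant_table <- function(config) {
  stopifnot(inherits(config, "phospho_sim_config"))
  withr::local_seed(config$seed %% 1000000L + 1L)
  d <- config$design
  occ <- d$site_rates |>
    tidyr::expand_grid(time_point = d$sample_times) |>
    dplyr::mutate(p = purrr::pmap_dbl(
      list(.data$k_p, .data$k_d, .data$time_point),
      function(kp, kd, tt) site_occupancy(tt, kp, kd, d$phases)
    ))

  site_recs <- occ |>
    dplyr::inner_join(d$rules, by = "residue") |>
    tidyr::expand_grid(replicate = seq_len(config$n_replicates)) |>
    dplyr::mutate(
      auc = config$auc_scale * .data$p * lnoise(dplyr::n(), config$auc_cv),
      y_pos = stringr::str_locate(.data$peptide, "Y")[, 1],
      mods = paste0(.data$y_pos, ":phospho"),
      sample = d$name
    )

  split_ox <- site_recs |>
    dplyr::mutate(m_pos = stringr::str_locate(.data$peptide, "M")[, 1],
                  split = .data$pool_met_oxidation & !is.na(.data$m_pos))
  plain <- split_ox |>
    dplyr::filter(!.data$split) |>
    dplyr::select("peptide", "charge", "mods", "auc", "replicate",
                  "sample", "time_point")
  oxpairs <- split_ox |>
    dplyr::filter(.data$split)
  ox <- dplyr::bind_rows(
    dplyr::mutate(oxpairs, auc = .data$auc * (1 - config$met_ox_fraction)),
    dplyr::mutate(oxpairs, auc = .data$auc * config$met_ox_fraction,
                  mods = paste0(.data$mods, ";", .data$m_pos, ":oxidation"))
  ) |>
    dplyr::select("peptide", "charge", "mods", "auc", "replicate",
                  "sample", "time_point")

  ref <- tidyr::expand_grid(time_point = d$sample_times,
                            replicate = seq_len(config$n_replicates)) |>
    dplyr::mutate(
      peptide = d$reference_peptide, charge = d$reference_charge,
      mods = "", sample = d$name,
      auc = config$auc_scale * lnoise(dplyr::n(), config$auc_cv)
    ) |>
    dplyr::select("peptide", "charge", "mods", "auc", "replicate",
                  "sample", "time_point")

  dplyr::bind_rows(plain, ox, ref) |>
    dplyr::arrange(.data$time_point, .data$replicate, .data$peptide)
}

#' Generate a synthetic homologue alignment
#'
#' Builds a synthetic reference scaffold (tyrosines planted at the phosphosite
#' positions) and samples `alignment_n` homologue rows column-wise: with the
#' configured per-position conservation probability a row keeps the reference
#' letter, otherwise it draws uniformly from the other 19 residues; gaps are
#' inserted at `gap_rate`. The reference row itself is included ungapped.
#'
#' @param config A [generator_config()].
#' @param reference_id Name given to the reference row.
#' @return A named character vector of aligned sequences (reference first).
#' @export
gen_alignment <- function(config, reference_id = "EYA3_synthetic") {
  stopifnot(inherits(config, "phospho_sim_config"))
  withr::local_seed(config$seed %% 1000000L + 2L)
  len <- config$ref_length
  ref <- sample(setdiff(AA20, "Y"), len, replace = TRUE)
  planted <- as.integer(names(config$conservation_by_position))
  planted <- planted[planted >= 1 & planted <= len]
  ref[eya3_sites()$position[eya3_sites()$position <= len]] <- "Y"
  cons <- rep(config$conservation_default, len)
  cons[planted] <- config$conservation_by_position[as.character(planted)]

  n <- config$alignment_n
  rows <- matrix("", nrow = n, ncol = len)
  for (j in seq_len(len)) {
    keep <- stats::runif(n) < cons[j]
    alt <- sample(setdiff(AA20, ref[j]), n, replace = TRUE)
    col <- ifelse(keep, ref[j], alt)
    col[stats::runif(n) < config$gap_rate] <- "-"
    rows[, j] <- col
  }
  seqs <- c(paste(ref, collapse = ""),
            apply(rows, 1, paste, collapse = ""))
  stats::setNames(seqs, c(reference_id,
                          sprintf("hom%04d", seq_len(n))))
}
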