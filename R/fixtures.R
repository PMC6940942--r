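# Packaged study designs for the EYA3/Src system.
#
# EYA3 is a tyrosine phosphatase that Src phosphorylates on 13 tyrosines and
# that removes those phosphates itself (autodephosphorylation). The three
# designs below encode the in-vitro experiments the pipeline is exercised on:
# a kinase time course on the phosphatase-dead D311N mutant, a kinase time
# course on wild-type protein (kinase and phosphatase simultaneously active),
# and a two-phase workflow in which phospho-D311N is handed to an active
# phosphatase after kinase inhibition.

#' The 13 in-vitro Src phosphosites of EYA3
#'
#' @return A tibble with `residue` and `position` (mature-protein numbering),
#'   ordered by position.
#' @export
eya3_sites <- function() {
  pos <- c(67L, 72L, 77L, 90L, 96L, 105L, 108L, 115L, 208L, 237L, 426L,
           508L, 532L)
  tibble::tibble(residue = paste0("Y", pos), position = pos)
}

# synthetic chymotryptic-style representative peptides, one tyrosine each;
# the two Met-containing peptides exercise oxidised/unoxidised pooling
eya3_rules <- function() {
  tibble::tibble(
    residue = eya3_sites()$residue,
    peptide = c("AGTSYEL", "SNQYGTF", "DKPYSML", "TEGYRAF", "QSIYNDL",
                "HRAYTEF", "GNDYKSL", "PTEYAGF", "SMKYDRL", "NGEYTSF",
                "RDSYPKL", "ETAYGNF", "KSDYELF"),
    charge = 2L,
    pool_met_oxidation = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                           FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Packaged experiment designs
#'
#' Returns the phase schedule, per-site rate set, sampling times,
#' representative-peptide rules and reference peptide of one of the three
#' packaged designs:
#'
#' * `"d311n_timecourse"`: phosphatase-dead substrate, kinase on for 6 h,
#'   sampled at 5 min, 30 min, 2 h and 6 h. Eleven sites participate; fast
#'   sites carry `k_p = 1.5`/h, slow sites 0.1/h, and two sites (Y115, Y508)
#'   are not phosphorylated in this design.
#' * `"wt_src_timecourse"`: kinase and phosphatase simultaneously active for
#'   6 h. Resistant sites (Y77, Y96, Y105, Y237, `k_d = 0.05`/h) settle near
#'   full occupancy; Y72 settles below the detection bound
#'   (`k_p = 0.01`, `k_d = 2`/h); seven labile sites never accumulate
#'   detectable occupancy (`k_p = 0`).
#' * `"d311n_dephospho"`: two-phase workflow - kinase on 0-1.5 h, kinase
#'   inhibited 1.5-2.5 h, active phosphatase added for 2.5-6.5 h, sampled at
#'   5 min, 90 min and at 0 h, 2 h, 4 h of dephosphorylation. Eleven sites
#'   participate (Y67 and Y532 absent); resistant sites (Y77, Y96, Y237,
#'   Y508) carry `k_d = 0.05`/h, labile sites 2/h.
#'
#' The rate constants are the package's calibration of the observed
#' phenomenology (which sites appear when, and which survive the phosphatase),
#' not measured quantities.
#'
#' @param name One of `"d311n_timecourse"`, `"wt_src_timecourse"`,
#'   `"d311n_dephospho"`.
#' @return A list with elements `name`, `site_rates`, `phases`,
#'   `sample_times`, `rules`, `reference_peptide`, `reference_charge`.
#' @export
eya3_design <- function(name = c("d311n_timecourse", "wt_src_timecourse",
                                 "d311n_dephospho")) {
  name <- match.arg(name)
  sites <- eya3_sites()$residue
  rates <- switch(
    name,
    d311n_timecourse = {
      fast <- c("Y72", "Y77", "Y96", "Y105", "Y237")
      absent <- c("Y115", "Y508")
      tibble::tibble(
        residue = sites,
        k_p = dplyr::case_when(sites %in% fast ~ 1.5,
                               sites %in% absent ~ 0,
                               TRUE ~ 0.1),
        k_d = 0
      )
    },
    wt_src_timecourse = {
      resistant <- c("Y77", "Y96", "Y105", "Y237")
      tibble::tibble(
        residue = sites,
        k_p = dplyr::case_when(sites %in% resistant ~ 1.5,
                               sites == "Y72" ~ 0.01,
                               TRUE ~ 0),
        k_d = dplyr::if_else(sites %in% resistant, 0.05, 2)
      )
    },
    d311n_dephospho = {
      resistant <- c("Y77", "Y96", "Y237", "Y508")
      absent <- c("Y67", "Y532")
      tibble::tibble(
        residue = sites,
        k_p = dplyr::if_else(sites %in% absent, 0, 1.5),
        k_d = dplyr::if_else(sites %in% resistant, 0.05, 2)
      )
    }
  )
  phases <- switch(
    name,
    d311n_timecourse = phase_schedule(0, 6, TRUE, FALSE),
    wt_src_timecourse = phase_schedule(0, 6, TRUE, TRUE),
    d311n_dephospho = phase_schedule(
      start = c(0, 1.5, 2.5), end = c(1.5, 2.5, 6.5),
      kinase_active = c(TRUE, FALSE, FALSE),
      phosphatase_active = c(FALSE, FALSE, TRUE)
    )
  )
  sample_times <- switch(
    name,
    d311n_timecourse = c(5 / 60, 0.5, 2, 6),
    wt_src_timecourse = c(5 / 60, 0.5, 2, 6),
    d311n_dephospho = c(5 / 60, 1.5, 2.5, 4.5, 6.5)
  )
  ref <- if (name == "wt_src_timecourse") {
    # DnaK peptide, a co-purified chaperone not phosphorylated by Src
    list(peptide = "ENAEGDRTTPSIIAY", charge = 2L)
  } else {
    list(peptide = "GVTGQTNSDAESTTL", charge = 2L)
  }
  list(name = name, site_rates = rates, phases = phases,
       sample_times = sample_times, rules = eya3_rules(),
       reference_peptide = ref$peptide, reference_charge = ref$charge)
}

#' Condition-by-residue phosphopatterns observed in HEK293T cells
#'
#' The cell-culture phosphopattern table used as a worked input for
#' [build_pattern_table()]: six overexpression conditions against seven
#' tyrosine and four serine residues.
#'
#' @return A tibble with columns `condition` and `residue`, one row per
#'   detected phosphoresidue.
#' @export
eya3_hek_detections <- function() {
  base_ser <- c("S138", "S225", "S438")
  rows <- list(
    "EYA3 WT" = base_ser,
    "EYA3 D309N" = base_ser,
    "EYA3 D309N Y77F" = base_ser,
    "EYA3 WT + c-Src Y527F" = c("Y77", "Y108", "Y208",
                                "S138", "S157", "S225", "S438"),
    "EYA3 D309N + c-Src Y527F" = c("Y72", "Y77", "Y90", "Y105", "Y108",
                                   "Y208", "Y325",
                                   "S138", "S157", "S225", "S438"),
    "EYA3 D309N Y77F + c-Src Y527F" = c("Y72", "Y90", "Y105", "Y108",
                                        "Y208", "Y325",
                                        "S138", "S157", "S225", "S438")
  )
  purrr::imap(rows, function(res, cond) {
    tibble::tibble(condition = cond, residue = res)
  }) |> dplyr::bind_rows()
}
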