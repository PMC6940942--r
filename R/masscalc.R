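# Closed-form mass/charge calculus for intact proteoforms.
#
# All charge carriers are protons (positive-mode ESI); masses are neutral.

#' Mass of the proton charge carrier, in Da
#'
#' Positive-mode electrospray adds protons, so every observed peak sits at
#' `(M + z * m_H) / z`. The constant is exposed so downstream code and user
#' scripts agree on the value to the last digit.
#'
#' @format A length-one numeric, 1.007276 Da.
#' @export
proton_mass <- 1.007276

#' Modification mass deltas used for proteoform ladder annotation
#'
#' Monoisotopic deltas are appropriate at peptide scale; for a ~65 kDa intact
#' protein the centroided isotope cluster tracks the average mass, so intact
#' ladder matching uses the `avg` column.
#'
#' @return A tibble with columns `name`, `mono` and `avg` (Da, signed) covering
#'   phosphorylation, acetylation and start-methionine loss.
#' @examples
#' modification_deltas()
#' @export
modification_deltas <- function() {
  tibble::tibble(
    name = c("phospho", "acetyl", "met_loss"),
    mono = c(79.966, 42.011, -131.040),
    avg  = c(79.980, 42.037, -131.197)
  )
}

mod_delta <- function(name, type = c("avg", "mono")) {
  type <- match.arg(type)
  d <- modification_deltas()
  i <- match(name, d$name)
  if (anyNA(i)) {
    stop("unknown modification: ", paste(name[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  d[[type]][i]
}

#' Convert an m/z value to a neutral mass
#'
#' `M = z * (m/z - m_H)` with `m_H` the proton mass. Vectorised over both
#' arguments.
#'
#' @param mz Observed m/z in thomson (Da per charge). Must exceed the proton
#'   mass.
#' @param charge Positive integer charge state.
#' @return Neutral mass in Da.
#' @examples
#' mz_to_mass(4101.72, 16) # ~65611.4 Da
#' @export
mz_to_mass <- function(mz, charge) {
  check_charge(charge)
  if (any(!is.finite(mz)) || any(mz <= proton_mass)) {
    stop("`mz` must be finite and exceed the proton mass (1.007276 Da)",
         call. = FALSE)
  }
  charge * (mz - proton_mass)
}

#' Convert a neutral mass to an m/z value
#'
#' Inverse of [mz_to_mass()].
#'
#' @param mass Neutral mass in Da, positive.
#' @param charge Positive integer charge state.
#' @return m/z in thomson.
#' @export
mass_to_mz <- function(mass, charge) {
  check_charge(charge)
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("`mass` must be finite and positive", call. = FALSE)
  }
  mass / charge + proton_mass
}

check_charge <- function(charge) {
  if (any(!is.finite(charge)) || any(charge < 1) ||
      any(charge != round(charge))) {
    stop("`charge` must be a positive integer", call. = FALSE)
  }
  invisible(charge)
}

#' Combine per-charge mass readings into one estimate
#'
#' Each charge state of one species gives an independent mass reading; the
#' intact mass is the unweighted mean of the per-charge `mz_to_mass()` values
#' and the quoted uncertainty is their sample standard deviation (0 when only
#' one charge is available).
#'
#' @param peaks A data frame with columns `mz` and `charge` (one row per
#'   charge state; `intensity` is allowed and ignored here). Charges must be
#'   distinct.
#' @return A one-row tibble with columns `mass`, `sd` and `n_charges`.
#' @examples
#' peaks <- tibble::tibble(charge = 14:18, mz = mass_to_mz(65611.22, 14:18))
#' combine_charge_estimates(peaks)
#' @export
combine_charge_estimates <- function(peaks) {
  stopifnot(is.data.frame(peaks), all(c("mz", "charge") %in% names(peaks)))
  if (nrow(peaks) < 1) stop("need at least one peak", call. = FALSE)
  if (anyDuplicated(peaks$charge)) {
    stop("duplicate charge states; each charge contributes one reading",
         call. = FALSE)
  }
  masses <- mz_to_mass(peaks$mz, peaks$charge)
  tibble::tibble(
    mass = mean(masses),
    sd = if (length(masses) > 1) stats::sd(masses) else 0,
    n_charges = length(masses)
  )
}

#' Modification mass from an m/z gap at one charge state
#'
#' Two peaks of the same charge separated by `dmz` thomson differ in neutral
#' mass by `z * dmz`; the sign of the gap is preserved.
#'
#' @param mz_a,mz_b m/z of the lighter and heavier species.
#' @param charge Shared charge state.
#' @return Signed mass difference in Da.
#' @examples
#' delta_from_mz_gap(4101.72, 4104.27, 16) # ~40.8 Da, an acetyl group
#' @export
delta_from_mz_gap <- function(mz_a, mz_b, charge) {
  check_charge(charge)
  charge * (mz_b - mz_a)
}

#' Infer a charge state from two adjacent envelope peaks
#'
#' For one species observed at consecutive charges z (at `mz_a`) and z + 1
#' (at `mz_b`, the lower m/z), `z = (mz_b - m_H) / (mz_a - mz_b)`. The value is
#' rounded to the nearest integer; a rounding residue above `slack` means the
#' two peaks are not a clean consecutive pair and an error is raised rather
#' than returning a wrong charge.
#'
#' @param mz_a m/z of the peak whose charge is returned (the higher m/z of the
#'   pair).
#' @param mz_b m/z of the adjacent lower-m/z (charge z + 1) peak.
#' @param slack Maximum tolerated distance between the exact ratio and the
#'   nearest integer (default 0.25).
#' @return The integer charge of the `mz_a` peak.
#' @examples
#' infer_charge_from_adjacent(4101.72, 3860.50) # 16
#' @export
infer_charge_from_adjacent <- function(mz_a, mz_b, slack = 0.25) {
  if (!is.finite(mz_a) || !is.finite(mz_b)) {
    stop("m/z values must be finite", call. = FALSE)
  }
  if (mz_a - mz_b <= 0) {
    stop("`mz_b` must be strictly below `mz_a` (higher charge, lower m/z)",
         call. = FALSE)
  }
  exact <- (mz_b - proton_mass) / (mz_a - mz_b)
  z <- round(exact)
  if (abs(exact - z) > slack) {
    stop(sprintf("ambiguous charge: exact value %.3f is %.3f from an integer",
                 exact, abs(exact - z)), call. = FALSE)
  }
  if (z < 1) stop("inferred charge below 1", call. = FALSE)
  as.integer(z)
}
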