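# Deconvolution of centroided native spectra into charge envelopes,
# proteoform-ladder annotation and phospho-stoichiometry quantification.

#' Group spectrum peaks into charge-state envelopes
#'
#' Greedy, deterministic envelope search. Seeding is on the most intense peak
#' not yet assigned; every charge hypothesis in `charge_range` is scored by how
#' many unassigned peaks lie within `mz_tol` of the theoretical m/z series for
#' the implied mass, ties broken by the smaller root-mean-square m/z residual.
#' An envelope is emitted when at least `min_charges` charges match; each peak
#' belongs to at most one envelope. Peaks that seed no envelope are retained in
#' the `unassigned` attribute of the result, never silently dropped.
#'
#' @param spectrum A data frame with columns `mz` and `intensity` (a centroided
#'   peak list, e.g. from [read_peaklist()] or [gen_native_spectrum()]).
#' @param min_charges Minimum number of matched charge states for an envelope
#'   (default 3; must be at least 2).
#' @param mz_tol m/z matching tolerance in thomson (default 0.1).
#' @param charge_range Inclusive integer range of charges to hypothesise
#'   (default 5 to 30).
#' @return A tibble with one row per envelope, ordered by total intensity:
#'   columns `envelope`, `mass`, `mass_sd`, `n_charges`, `total_intensity` and
#'   a list-column `peaks` (tibbles of `mz`, `charge`, `intensity`).
#' @export
pick_envelopes <- function(spectrum, min_charges = 3, mz_tol = 0.1,
                           charge_range = c(5L, 30L)) {
  stopifnot(is.data.frame(spectrum),
            all(c("mz", "intensity") %in% names(spectrum)))
  if (nrow(spectrum) == 0) stop("empty spectrum", call. = FALSE)
  if (min_charges < 2) stop("`min_charges` must be at least 2", call. = FALSE)
  spectrum <- dplyr::arrange(spectrum, .data$mz)
  zs <- seq.int(charge_range[1], charge_range[2])

  mz <- spectrum$mz
  int <- spectrum$intensity
  available <- rep(TRUE, length(mz))   # not yet assigned to an envelope
  seedable <- rep(TRUE, length(mz))    # not yet tried as a seed
  envelopes <- list()

  match_series <- function(mass, avail) {
    # nearest available peak within tolerance at each hypothesised charge
    pred <- mass / zs + proton_mass
    idx <- rep(NA_integer_, length(zs))
    for (k in seq_along(zs)) {
      j <- which(avail & abs(mz - pred[k]) <= mz_tol)
      if (length(j)) idx[k] <- j[which.min(abs(mz[j] - pred[k]))]
    }
    # one peak may satisfy two adjacent charges at very low mass; keep first
    dup <- duplicated(idx, incomparables = NA)
    idx[dup] <- NA_integer_
    idx
  }

  while (any(available & seedable)) {
    seed <- which(available & seedable)[
      which.max(int[available & seedable])]
    best <- NULL
    for (z in zs) {
      mass <- z * (mz[seed] - proton_mass)
      idx <- match_series(mass, available)
      n <- sum(!is.na(idx))
      if (n < min_charges) next
      res <- sqrt(mean((mz[idx[!is.na(idx)]] -
                          (mass / zs[!is.na(idx)] + proton_mass))^2))
      if (is.null(best) || n > best$n || (n == best$n && res < best$res)) {
        best <- list(z = z, idx = idx, n = n, res = res)
      }
    }
    if (is.null(best)) {
      seedable[seed] <- FALSE
      next
    }
    keep <- !is.na(best$idx)
    members <- tibble::tibble(
      mz = mz[best$idx[keep]],
      charge = zs[keep],
      intensity = int[best$idx[keep]]
    )
    est <- combine_charge_estimates(members)
    envelopes[[length(envelopes) + 1L]] <- tibble::tibble(
      mass = est$mass, mass_sd = est$sd, n_charges = est$n_charges,
      total_intensity = sum(members$intensity), peaks = list(members)
    )
    available[best$idx[keep]] <- FALSE
    seedable[best$idx[keep]] <- FALSE
  }

  out <- if (length(envelopes)) {
    dplyr::bind_rows(envelopes) |>
      dplyr::arrange(dplyr::desc(.data$total_intensity)) |>
      dplyr::mutate(envelope = dplyr::row_number(), .before = 1)
  } else {
    tibble::tibble(envelope = integer(), mass = numeric(),
                   mass_sd = numeric(), n_charges = integer(),
                   total_intensity = numeric(), peaks = list())
  }
  attr(out, "unassigned") <- spectrum[available, , drop = FALSE]
  out
}

#' Annotate envelope masses with a proteoform ladder
#'
#' Each envelope mass is matched against `base_mass + a * acetyl + n * phospho`
#' for `a` in \{0, 1\} and `n` in `0:n_max`, taking the hypothesis with the
#' smallest absolute mass error within `mass_tol`. Average-mass deltas are used
#' (the centroided cluster of a ~65 kDa protein tracks average mass).
#' Hypotheses closer than 0.01 Da to each other set the `ambiguous` flag
#' instead of raising an error; envelopes with no hypothesis within tolerance
#' come back with `n_phospho = NA` (unassigned).
#'
#' @param envelopes Output of [pick_envelopes()] (or any tibble with a `mass`
#'   column).
#' @param base_mass Neutral mass of the unmodified (start-Met-cleaved) base
#'   species in Da.
#' @param mass_tol Mass-domain matching tolerance in Da (default 1.5, wide
#'   enough to absorb mono/average differences at intact scale).
#' @param n_max Largest phosphate count entertained (default 15).
#' @return The input tibble with columns `acetylated`, `n_phospho`,
#'   `mass_error` and `ambiguous` appended.
#' @export
annotate_ladder <- function(envelopes, base_mass, mass_tol = 1.5,
                            n_max = 15L) {
  stopifnot(is.data.frame(envelopes), "mass" %in% names(envelopes))
  if (base_mass <= 0 || mass_tol <= 0) {
    stop("`base_mass` and `mass_tol` must be positive", call. = FALSE)
  }
  d_ace <- mod_delta("acetyl", "avg")
  d_pho <- mod_delta("phospho", "avg")
  grid <- tidyr::expand_grid(a = 0:1, n = 0:n_max) |>
    dplyr::mutate(hyp_mass = base_mass + .data$a * d_ace + .data$n * d_pho)

  ann <- purrr::map(envelopes$mass, function(m) {
    err <- abs(m - grid$hyp_mass)
    i <- which.min(err)
    if (err[i] > mass_tol) {
      return(tibble::tibble(acetylated = NA, n_phospho = NA_integer_,
                            mass_error = NA_real_, ambiguous = FALSE))
    }
    nearby <- sort(err)
    tibble::tibble(
      acetylated = grid$a[i] == 1,
      n_phospho = as.integer(grid$n[i]),
      mass_error = m - grid$hyp_mass[i],
      ambiguous = length(nearby) > 1 && (nearby[2] - nearby[1]) < 0.01
    )
  }) |> dplyr::bind_rows()
  dplyr::bind_cols(envelopes, ann)
}

#' Phospho-stoichiometry distribution at one charge state
#'
#' Quantifies the fraction of molecules carrying 0, 1, 2, ... phosphates from
#' the centroid peak intensities of the annotated proteoform states at a single
#' charge state. The acetylated and unmodified families are quantified
#' separately by default; `channel = "pooled"` sums the two families per
#' phosphate count.
#'
#' @param states Output of [annotate_ladder()] (needs `acetylated`,
#'   `n_phospho` and the `peaks` list-column).
#' @param charge Charge state used for quantification (default 16).
#' @param channel One of `"unmodified"`, `"acetylated"`, `"pooled"`.
#' @param time_point Optional time annotation carried into the result.
#' @return A `stoich_distribution` tibble with columns `n_phospho`,
#'   `intensity`, `fraction` (summing to 1), plus `channel` and `time_point`.
#' @export
stoichiometry_at_charge <- function(states, charge = 16L,
                                    channel = c("unmodified", "acetylated",
                                                "pooled"),
                                    time_point = NA_real_) {
  channel <- match.arg(channel)
  stopifnot(is.data.frame(states),
            all(c("acetylated", "n_phospho", "peaks") %in% names(states)))
  assigned <- states |>
    dplyr::filter(!is.na(.data$n_phospho)) |>
    dplyr::mutate(
      at_charge = purrr::map_dbl(.data$peaks, function(p) {
        sum(p$intensity[p$charge == charge])
      })
    )
  if (channel != "pooled") {
    assigned <- dplyr::filter(assigned, .data$acetylated == (channel == "acetylated"))
  }
  out <- assigned |>
    dplyr::group_by(n_phospho = .data$n_phospho) |>
    dplyr::summarise(intensity = sum(.data$at_charge), .groups = "drop") |>
    dplyr::filter(.data$intensity > 0) |>
    dplyr::arrange(.data$n_phospho)
  if (nrow(out) == 0 || sum(out$intensity) <= 0) {
    stop(sprintf("no intensity at charge %d for channel '%s'", charge, channel),
         call. = FALSE)
  }
  out <- out |>
    dplyr::mutate(fraction = .data$intensity / sum(.data$intensity),
                  channel = channel, time_point = time_point)
  class(out) <- c("stoich_distribution", class(out))
  out
}

#' Assign a complex mass to a combination of components
#'
#' Enumerates all non-empty subsets of the candidate component masses (each
#' component used at most once, 1:1 stoichiometry) and reports the subset whose
#' summed mass is closest to the observed envelope mass, provided the residual
#' is within `mass_tol`.
#'
#' @param mass Observed complex neutral mass in Da.
#' @param components Numeric vector of candidate component masses, optionally
#'   named.
#' @param mass_tol Acceptance tolerance in Da (default 2).
#' @return A one-row tibble: `assigned` (logical), `composition` (list-column
#'   of component masses used), `total_mass`, `residual` (observed - summed;
#'   NA when unassigned).
#' @examples
#' assign_complex(112683.3, c(eya3 = 65608.09, skp3 = 47075.05))
#' @export
assign_complex <- function(mass, components, mass_tol = 2) {
  if (length(components) < 1) stop("need at least one component", call. = FALSE)
  if (mass_tol <= 0) stop("`mass_tol` must be positive", call. = FALSE)
  n <- length(components)
  if (n > 20) stop("too many candidate components for exhaustive search",
                   call. = FALSE)
  best <- NULL
  for (code in seq_len(2^n - 1)) {
    pick <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1)))
    total <- sum(components[pick])
    res <- mass - total
    if (is.null(best) || abs(res) < abs(best$res)) {
      best <- list(pick = pick, total = total, res = res)
    }
  }
  if (abs(best$res) <= mass_tol) {
    tibble::tibble(assigned = TRUE, composition = list(components[best$pick]),
                   total_mass = best$total, residual = best$res)
  } else {
    tibble::tibble(assigned = FALSE, composition = list(numeric()),
                   total_mass = NA_real_, residual = NA_real_)
  }
}

#' Rescale state intensities by a per-sample spike-in signal
#'
#' Dividing every state intensity by the spike-in signal of its sample makes
#' absolute phospho-state signal comparable across samples that were loaded or
#' ionised differently.
#'
#' @param x A data frame with a `sample` column and an `intensity` column.
#' @param spike A named numeric vector of spike-in intensities, one per sample
#'   present in `x`; all values must be positive.
#' @return `x` with `intensity` replaced by `intensity / spike[sample]` (the
#'   raw value preserved as `intensity_raw`).
#' @export
spikein_normalize <- function(x, spike) {
  stopifnot(is.data.frame(x), all(c("sample", "intensity") %in% names(x)))
  miss <- setdiff(unique(x$sample), names(spike))
  if (length(miss)) {
    stop("no spike-in intensity for sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(spike)) || any(spike <= 0)) {
    stop("spike-in intensities must be positive", call. = FALSE)
  }
  dplyr::mutate(x, intensity_raw = .data$intensity,
                intensity = .data$intensity / unname(spike[.data$sample]))
}
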