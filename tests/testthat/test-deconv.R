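test_that("envelope search recovers one and two species from clean spectra", {
  env1 <- theoretical_envelope(65611.22, 14:18)
  sp <- tibble::tibble(mz = env1$mz, intensity = env1$intensity)
  got <- pick_envelopes(sp, min_charges = 3)
  expect_equal(nrow(got), 1)
  expect_equal(got$mass, 65611.22, tolerance = 1e-8)
  expect_equal(got$n_charges, 5L)

  env2 <- theoretical_envelope(47075.05, 10:13, intensity = 60)
  sp2 <- dplyr::arrange(
    tibble::tibble(mz = c(env1$mz, env2$mz),
                   intensity = c(env1$intensity, env2$intensity)), mz)
  got2 <- pick_envelopes(sp2, min_charges = 3)
  expect_equal(nrow(got2), 2)
  expect_equal(sort(got2$mass), c(47075.05, 65611.22), tolerance = 1e-6)
  # no peak shared between envelopes
  used <- dplyr::bind_rows(got2$peaks)
  expect_false(anyDuplicated(used$mz) > 0)

  expect_equal(nrow(pick_envelopes(tibble::tibble(mz = 1000, intensity = 5))), 0)
  expect_error(pick_envelopes(tibble::tibble(mz = numeric(),
                                             intensity = numeric())), "empty")
})

test_that("ladder annotation picks the nearest (acetyl, nP) hypothesis", {
  base <- 65608.1
  dpho <- modification_deltas()$avg[modification_deltas()$name == "phospho"]
  dace <- modification_deltas()$avg[modification_deltas()$name == "acetyl"]
  env <- tibble::tibble(mass = c(base, base + dpho, base + 2 * dpho))
  ann <- annotate_ladder(env, base_mass = base)
  expect_equal(ann$n_phospho, 0:2)
  expect_true(all(!ann$acetylated))

  # unmodified vs acetylated pair (printed-mass style)
  ann2 <- annotate_ladder(tibble::tibble(mass = c(65608.1, 65650.8)),
                          base_mass = 65608.1)
  expect_equal(ann2$acetylated, c(FALSE, TRUE))
  expect_equal(ann2$n_phospho, c(0L, 0L))

  # out-of-ladder mass stays unassigned
  ann3 <- annotate_ladder(tibble::tibble(mass = base + 200), base_mass = base)
  expect_true(is.na(ann3$n_phospho))

  # translation invariance of the assignments
  shift <- 1234.5
  ann4 <- annotate_ladder(dplyr::mutate(env, mass = mass + shift),
                          base_mass = base + shift)
  expect_equal(ann4$n_phospho, ann$n_phospho)
  expect_equal(ann4$acetylated, ann$acetylated)
  expect_equal(ann4$mass_error, ann$mass_error, tolerance = 1e-9)
})

test_that("stoichiometry at a charge normalises family intensities", {
  mk_state <- function(n, acetyl, i16) {
    tibble::tibble(mass = 65608.1 + n * 79.98 + 42.037 * acetyl,
                   acetylated = acetyl, n_phospho = as.integer(n),
                   peaks = list(tibble::tibble(mz = 1, charge = 16L,
                                               intensity = i16)))
  }
  states <- dplyr::bind_rows(mk_state(0, FALSE, 3000), mk_state(1, FALSE, 1000),
                             mk_state(0, TRUE, 500))
  d <- stoichiometry_at_charge(states, 16, "unmodified")
  expect_equal(d$fraction, c(0.75, 0.25))
  expect_equal(sum(d$fraction), 1)

  single <- stoichiometry_at_charge(mk_state(2, FALSE, 10), 16, "unmodified")
  expect_equal(single$fraction, 1)

  pooled <- stoichiometry_at_charge(states, 16, "pooled")
  expect_equal(pooled$fraction, c(3500, 1000) / 4500)
  expect_error(stoichiometry_at_charge(states, 12, "unmodified"),
               "no intensity")
})

test_that("complex assignment finds the 1:1 component combination", {
  comp <- assign_complex(112683.3, c(eya3 = 65608.09, skp3 = 47075.05))
  expect_true(comp$assigned)
  expect_equal(abs(comp$residual), 0.16, tolerance = 1e-9)
  expect_setequal(names(comp$composition[[1]]), c("eya3", "skp3"))

  solo <- assign_complex(65608.09, c(65608.09))
  expect_true(solo$assigned)
  expect_equal(solo$residual, 0)
  expect_equal(length(solo$composition[[1]]), 1)

  none <- assign_complex(100000, c(65608.09, 47075.05), mass_tol = 2)
  expect_false(none$assigned)
  expect_error(assign_complex(1000, numeric()), "component")
})

test_that("spike-in rescaling equalises proportionally loaded samples", {
  x <- tibble::tibble(sample = c("a", "a"), n = 0:1, intensity = c(100, 50))
  got <- spikein_normalize(x, c(a = 50))
  expect_equal(got$intensity, c(2, 1))
  # samples with a true 2x loading difference and proportional spikes agree
  y <- tibble::tibble(sample = rep(c("s1", "s2"), each = 2), n = rep(0:1, 2),
                      intensity = c(100, 40, 200, 80))
  got2 <- spikein_normalize(y, c(s1 = 10, s2 = 20))
  expect_equal(got2$intensity[got2$sample == "s1"],
               got2$intensity[got2$sample == "s2"])
  expect_error(spikein_normalize(x, c(a = 0)), "positive")
  expect_error(spikein_normalize(x, c(b = 5)), "no spike-in")
})

test_that("generated spectra round-trip through the full deconvolution", {
  cfg <- generator_config("d311n_timecourse", acetyl_fraction = 0.3)
  for (tt in c(5 / 60, 2)) {
    sp <- gen_native_spectrum(cfg, tt)
    truth <- attr(sp, "truth")
    env <- pick_envelopes(sp, min_charges = 3, mz_tol = 0.1)
    states <- annotate_ladder(env, base_mass = cfg$base_mass)
    for (ch in c("unmodified", "acetylated")) {
      est <- stoichiometry_at_charge(states, 16, ch)
      tr <- truth[truth$acetylated == (ch == "acetylated"), ]
      tr$fraction <- tr$fraction / sum(tr$fraction)
      cmp <- dplyr::full_join(est[c("n_phospho", "fraction")],
                              tr[c("n_phospho", "fraction")],
                              by = "n_phospho", suffix = c("_est", "_true"))
      err <- abs(dplyr::coalesce(cmp$fraction_est, 0) -
                   dplyr::coalesce(cmp$fraction_true, 0))
      expect_lt(max(err), 0.02)
    }
  }
  # the 5-min kinase spectrum is dominated by unphosphorylated molecules
  sp5 <- gen_native_spectrum(cfg, 5 / 60)
  env5 <- annotate_ladder(pick_envelopes(sp5), base_mass = cfg$base_mass)
  d5 <- stoichiometry_at_charge(env5, 16, "unmodified")
  expect_equal(d5$n_phospho[which.max(d5$fraction)], 0L)
})

test_that("generated complex envelope is assignable within 0.25 Da", {
  cfg <- generator_config("d311n_timecourse", include_complex = TRUE,
                          acetyl_fraction = 0)
  sp <- gen_native_spectrum(cfg, 0.05)
  env <- pick_envelopes(sp, min_charges = 3,
                        charge_range = c(5L, 30L))
  cplx_mass <- cfg$base_mass + cfg$complex_partner_mass
  hit <- env[which.min(abs(env$mass - cplx_mass)), ]
  comp <- assign_complex(hit$mass,
                         c(cfg$base_mass, cfg$complex_partner_mass))
  expect_true(comp$assigned)
  expect_lt(abs(comp$residual), 0.25)
})
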