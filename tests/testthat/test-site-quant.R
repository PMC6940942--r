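mk_record <- function(peptide, charge, mods, auc, replicate = 1L,
                      sample = "s", time_point = 0.5) {
  tibble::tibble(peptide = peptide, charge = as.integer(charge), mods = mods,
                 auc = auc, replicate = as.integer(replicate),
                 sample = sample, time_point = time_point)
}

rule_y77 <- tibble::tibble(residue = "Y77", peptide = "DKPYSML", charge = 2L,
                           pool_met_oxidation = TRUE)

test_that("representative filtering enforces peptide, charge and single phospho", {
  recs <- dplyr::bind_rows(
    mk_record("DKPYSML", 2, "4:phospho", 700),              # keep
    mk_record("DKPYSML", 2, "4:phospho;7:oxidation", 300),  # pooled in
    mk_record("DKPYSML", 3, "4:phospho", 999),              # wrong charge
    mk_record("DKPYSML", 2, "4:phospho;1:phospho", 50),     # two phosphos
    mk_record("DKPYSML", 2, "6:phospho", 40),               # wrong site
    mk_record("OTHERPEP", 2, "2:phospho", 10)               # wrong peptide
  )
  got <- select_representative(recs, rule_y77)
  expect_equal(nrow(got), 1)
  expect_equal(got$auc, 1000) # oxidised + unoxidised summed
  expect_equal(got$residue, "Y77")

  # without pooling, the oxidised form is excluded
  rule_nopool <- dplyr::mutate(rule_y77, pool_met_oxidation = FALSE)
  got2 <- select_representative(recs, rule_nopool)
  expect_equal(got2$auc, 700)

  bad_rule <- tibble::tibble(residue = "YY", peptide = "AYBYC", charge = 2L,
                             pool_met_oxidation = FALSE)
  expect_error(select_representative(recs, bad_rule), "exactly one tyrosine")
})

test_that("reference normalisation averages replicate ratios and is scale invariant", {
  recs <- dplyr::bind_rows(
    mk_record("DKPYSML", 2, "4:phospho", 1000, replicate = 1),
    mk_record("DKPYSML", 2, "4:phospho", 4000, replicate = 2),
    mk_record("DKPYSML", 2, "4:phospho", 9000, replicate = 3),
    mk_record("GVTGQTNSDAESTTL", 2, "", 1000, replicate = 1),
    mk_record("GVTGQTNSDAESTTL", 2, "", 2000, replicate = 2),
    mk_record("GVTGQTNSDAESTTL", 2, "", 3000, replicate = 3)
  )
  sel <- select_representative(recs, rule_y77)
  rat <- normalize_to_reference(sel, recs, "GVTGQTNSDAESTTL", 2L)
  expect_equal(rat$mean_ratio, mean(c(1, 2, 3)))
  expect_equal(rat$sd_ratio, stats::sd(c(1, 2, 3)))
  expect_equal(rat$n_replicates, 3L)

  # doubling every AUC in one replicate leaves its ratio unchanged
  scaled <- dplyr::mutate(recs,
                          auc = ifelse(replicate == 2, auc * 2, auc))
  rat2 <- normalize_to_reference(select_representative(scaled, rule_y77),
                                 scaled, "GVTGQTNSDAESTTL", 2L)
  expect_equal(rat2$mean_ratio, rat$mean_ratio)
  expect_equal(rat2$sd_ratio, rat$sd_ratio)

  # a missing reference replicate is a hard, named error
  broken <- dplyr::filter(recs, !(peptide == "GVTGQTNSDAESTTL" &
                                    replicate == 2))
  expect_error(
    normalize_to_reference(select_representative(broken, rule_y77),
                           broken, "GVTGQTNSDAESTTL", 2L),
    "replicate 2")
})

test_that("percent-of-max rescales each residue to its own peak", {
  ratios <- tibble::tibble(
    residue = rep(c("Y77", "Y96"), each = 3),
    sample = "s",
    time_point = rep(c(0.5, 2, 6), 2),
    mean_ratio = c(2, 4, 1, 0.3, 0.1, 0.05),
    sd_ratio = c(0.2, 0.4, 0.1, 0.03, 0.01, 0.005),
    n_replicates = 3L
  )
  prof <- percent_of_max(ratios)
  expect_equal(prof$percent[prof$residue == "Y77"], c(50, 100, 25))
  expect_equal(prof$sd_percent[prof$residue == "Y77"], c(5, 10, 2.5))
  expect_equal(max(prof$percent[prof$residue == "Y96"]), 100)

  single <- percent_of_max(ratios[1, ])
  expect_equal(single$percent, 100)

  zero <- dplyr::mutate(ratios[1:3, ], mean_ratio = 0)
  expect_warning(pz <- percent_of_max(zero), "all-zero")
  expect_true(all(pz$percent == 0) && all(pz$all_zero))
})

test_that("resistance calls are made on the final-time normalised ratio", {
  ratios <- tibble::tibble(
    residue = rep(c("Y77", "Y72"), each = 2),
    sample = "s", time_point = rep(c(0.5, 6), 2),
    mean_ratio = c(0.9, 0.4, 0.5, 0), sd_ratio = 0, n_replicates = 3L
  )
  cls <- classify_resistance(ratios)
  expect_equal(cls$resistance_class[cls$residue == "Y77"], "resistant")
  expect_equal(cls$resistance_class[cls$residue == "Y72"], "labile")
  expect_error(classify_resistance(ratios[c(1, 4), ]), "final-time")
})

test_that("pattern tables are rectangular, ordered and text-renderable", {
  det <- tibble::tibble(condition = c("A", "A"), residue = c("Y77", "S138"))
  pat <- build_pattern_table(det, conditions = c("A", "B"))
  expect_equal(nrow(pat), 2)
  expect_equal(setdiff(names(pat), "condition"), c("Y77", "S138"))
  expect_true(pat$Y77[pat$condition == "A"])
  expect_false(any(unlist(pat[pat$condition == "B", -1])))
  expect_error(build_pattern_table(det, conditions = c("A", "A")), "duplicate")

  txt <- render_pattern_table(pat)
  expect_length(txt, 3)
  expect_match(txt[2], "X")
  expect_false(grepl("X", txt[3]))
})

test_that("the cell-culture pattern fixture reproduces its printed structure", {
  det <- eya3_hek_detections()
  pat <- build_pattern_table(det)
  wt <- dplyr::filter(pat, condition == "EYA3 WT")
  on_cols <- names(wt[-1])[unlist(wt[-1])]
  # without kinase co-expression no tyrosine is phosphorylated
  expect_setequal(on_cols, c("S138", "S225", "S438"))
  expect_false(any(startsWith(on_cols, "Y")))
  # kinase co-expression brings in the tyrosines, led by the resistant Y77
  co <- dplyr::filter(pat, condition == "EYA3 WT + c-Src Y527F")
  expect_true(co$Y77)
  full <- dplyr::filter(pat, condition == "EYA3 D309N + c-Src Y527F")
  expect_equal(sum(unlist(full[-1])), 11)
})

test_that("synthetic quant tables recover occupancy ranks and resistance sets", {
  # WT + kinase: the four resistant residues survive the full time course
  wt <- quantify_design("wt_src_timecourse")
  cls <- classify_resistance(wt$ratios)
  expect_setequal(cls$residue[cls$resistant],
                  c("Y77", "Y96", "Y105", "Y237"))

  # noiseless ratios are exactly proportional to occupancies
  nn <- quantify_design("d311n_timecourse", auc_cv = 0)
  d <- nn$design
  occ <- d$site_rates |>
    tidyr::expand_grid(time_point = d$sample_times) |>
    dplyr::mutate(p = purrr::pmap_dbl(
      list(k_p, k_d, time_point),
      function(kp, kd, tt) site_occupancy(tt, kp, kd, d$phases)))
  cmp <- dplyr::inner_join(nn$ratios, occ, by = c("residue", "time_point"))
  expect_equal(cmp$mean_ratio, cmp$p, tolerance = 1e-9)

  # with 10% CV noise, percent-of-max series track true occupancy (Spearman)
  noisy <- quantify_design("d311n_timecourse")
  prof <- suppressWarnings(percent_of_max(noisy$ratios))
  by_res <- dplyr::inner_join(prof, occ, by = c("residue", "time_point")) |>
    dplyr::filter(p > 0) |>
    dplyr::group_by(residue) |>
    dplyr::summarise(rho = stats::cor(percent, p, method = "spearman"))
  expect_true(all(by_res$rho >= 0.9))

  # determinism: same seed, identical table
  q1 <- gen_quant_table(generator_config("d311n_timecourse"))
  q2 <- gen_quant_table(generator_config("d311n_timecourse"))
  expect_identical(q1, q2)
})

test_that("in-vitro designs yield 13 distinct phosphotyrosines in union", {
  a <- quantify_design("d311n_timecourse")
  c2 <- quantify_design("d311n_dephospho")
  det_a <- detected_sites(a$ratios)
  det_c <- detected_sites(c2$ratios)
  expect_length(det_a, 11)
  expect_length(det_c, 11)
  expect_length(union(det_a, det_c), 13)
  expect_setequal(union(det_a, det_c), eya3_sites()$residue)
})
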