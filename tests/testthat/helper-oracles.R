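# Independent oracles and small builders shared across the suite.

# noiseless theoretical charge-envelope peak list for one neutral mass
theoretical_envelope <- function(mass, charges, intensity = 100) {
  tibble::tibble(
    mz = mass / charges + 1.007276,
    charge = charges,
    intensity = rep_len(intensity, length(charges))
  )
}

# exhaustive 2^n Poisson-binomial oracle
pb_enumerate <- function(p) {
  n <- length(p)
  out <- numeric(n + 1)
  for (mask in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    out[sum(bits) + 1] <- out[sum(bits) + 1] + prod(ifelse(bits, p, 1 - p))
  }
  out
}

# brute-force charge assignment: which integer z best explains a consecutive
# m/z pair, scanning z = 1..60
bruteforce_charge <- function(mz_a, mz_b) {
  zs <- 1:60
  err <- abs((mz_b - 1.007276) / (mz_a - mz_b) - zs)
  zs[which.min(err)]
}

# closed-form single-phase occupancy for cross-checking site_occupancy
closed_form_occupancy <- function(t, k_p, k_d, p0 = 0) {
  k <- k_p + k_d
  if (k == 0) return(rep(p0, length(t)))
  pss <- k_p / k
  pss + (p0 - pss) * exp(-k * t)
}

quantify_design <- function(design_name, seed = 20191213L, ...) {
  d <- eya3_design(design_name)
  cfg <- generator_config(d, seed = seed, ...)
  q <- gen_quant_table(cfg)
  sel <- select_representative(q, d$rules)
  list(design = d, records = q,
       ratios = normalize_to_reference(sel, q, d$reference_peptide,
                                       d$reference_charge))
}
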