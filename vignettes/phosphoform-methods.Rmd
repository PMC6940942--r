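---
title: "Methods: models, parameters and design choices in phosphoform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in phosphoform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoform)
library(dplyr)
```

phosphoform studies a protein that is simultaneously a kinase substrate and
its own tyrosine phosphatase: Src phosphorylates human EYA3 on many tyrosines
while EYA3's phosphatase activity removes those phosphates again
(autodephosphorylation). The package provides the computational side of three
complementary measurements of this tug of war — intact-protein native mass
spectrometry, bottom-up per-site quantification, and evolutionary
conservation of the sites — plus seeded generators that produce every input
so the whole pipeline runs without instrument data.

## Intact mass calculus

Positive-mode electrospray of a folded protein yields a charge-state
envelope: peaks at `(M + z m_H)/z` for consecutive proton counts `z`. The
package fixes the charge carrier as the proton (`m_H` = 1.007276 Da), so

* `mz_to_mass(mz, z) = z (mz - m_H)`,
* multi-charge mass estimates are the unweighted mean of the per-charge
  readings with their sample SD as the quoted uncertainty (no weighting
  scheme is imposed because peak intensity does not usefully predict the m/z
  error of a centroid at this scale),
* a modification mass is read off an m/z gap at fixed charge as `z Δmz`,
* the charge of a peak is inferred from an adjacent envelope peak as
  `(mz_b - m_H)/(mz_a - mz_b)` rounded to the nearest integer; a rounding
  residue above 0.25 raises an ambiguity error instead of returning a
  plausible-looking wrong charge. The sensitivity of that ratio to centroid
  error grows roughly as `z (z+1)^2 / M`, so at 65 kDa the guard only trips
  above charge ~30 for half-thomson errors — at the charges this protein
  actually shows (14+–18+), centroid noise perturbs the ratio by a few
  hundredths at most.

Modification deltas are kept in both monoisotopic and average form
(`modification_deltas()`). Intact-level ladder matching uses **average**
masses: a 65 kDa centroid integrates the isotope cluster, and the 1.5 Da
ladder tolerance makes the mono/average distinction immaterial anyway.
Peptide-level bookkeeping (mods strings in quant tables) is monoisotopic by
convention of the upstream search engines.

## Envelope deconvolution and proteoform ladders

`pick_envelopes()` is a deterministic greedy search: seed on the most intense
unassigned peak, score every charge hypothesis in a configurable range (5–30
by default) by how many unassigned peaks fall within the m/z tolerance
(default 0.1 Th) of the implied theoretical series, and keep the hypothesis
with the most matches (ties to the smaller RMS residual). Envelopes need at
least `min_charges` members (default 3); each peak joins at most one
envelope, and leftovers are reported in an attribute rather than dropped.
Greediness by intensity makes the algorithm reproducible and easy to reason
about; it is not a globally optimal assignment, which matters only for
heavily overlapped envelopes beyond its intended use.

`annotate_ladder()` matches each envelope mass to
`base + a·42.037 + n·79.980` Da over `a ∈ {0,1}` acetyl and `n = 0..15`
phosphates, choosing the smallest absolute error within 1.5 Da. Fifteen is a
deliberate margin over the twelve phosphates actually observed on the
phosphatase-dead protein. Two hypotheses within 0.01 Da of one another set an
`ambiguous` flag rather than failing, since downstream quantification may not
care which label wins.

`stoichiometry_at_charge()` quantifies the phosphate-count distribution from
centroid peak heights at a single charge state (default 16+). Acetylated and
unmodified families are quantified separately by default — they are distinct
molecular populations whose ionisation need not match — with a pooled channel
on request. Quantifying at one charge avoids having to model how the charge
profile itself shifts with modification state; the generator's round-trip
tests confirm fractions are recovered within 0.02 at the noise levels
simulated.

`assign_complex()` explains an observed mass as a 1:1 sum over a subset of
candidate components by exhaustive enumeration (tolerance 2 Da), reporting
the signed residual. `spikein_normalize()` divides per-state intensities by a
per-sample spike-in signal so absolute signal can be compared across samples.

## Site kinetics

Each site follows first-order mass-action kinetics,

$$\frac{dp}{dt} = k_p (1 - p) - k_d\, p,$$

with `k_p` gated by kinase-active phases and `k_d` by phosphatase-active
phases (`phase_schedule()`). Within a phase the closed form
`p(t) = p_ss + (p_0 - p_ss) e^{-(k_p + k_d) t}`, `p_ss = k_p/(k_p+k_d)`, is
evaluated exactly; trajectories are continuous across boundaries and the
occupancy is frozen when both rates are gated off. Rates are per hour. This
minimal model reproduces the phenomenology the measurements show —
saturation on a phosphatase-dead substrate, kinase/phosphatase compensation
at steady state, and fast-versus-slow dephosphorylation classes — without
positing site coupling. Occupancy coupling between sites is plausible but has
no stated functional form, so it is deliberately not modelled.

A moderate activation of the phosphatase by its own phosphorylation is
available as an option on `simulate_timecourse()` (`ptp_boost`): all `k_d`
are multiplied by the factor from the first time mean occupancy crosses a
level (found by bisection, the schedule split there). It is off by default.

Sites are treated as independent, so the number of phosphates on one
molecule is Poisson-binomial in the site occupancies.
`stoichiometry_from_occupancies()` computes it by exact dynamic programming
(one convolution per site, O(n²) total); tests verify equality with
exhaustive 2^n enumeration up to n = 12 and with 10^6-draw Monte-Carlo at
n = 13, and that the distribution mean equals the occupancy sum to 1e-12.
This is the bridge between the bottom-up view (per-site occupancy) and the
native-MS view (per-molecule phosphate count).

Presence/absence calls use an occupancy threshold of 0.01: the bottom-up
experiments report binary detected/not-detected with no stated limit of
detection, and 1% occupancy is a conservative stand-in for what a targeted
chromatogram reliably shows. `fit_site_rates()` (least squares over a small
start grid, box-constrained quasi-Newton) is plumbing for identifiability
checks; it recovers generating rates from noiseless trajectories within 1%.

## Bottom-up quantification

The quantification rules mirror standard practice for chymotryptic
phosphopeptide data:

1. **Representative peptides** (`select_representative()`): chymotrypsin does
   not cut after phosphotyrosine, so each residue is quantified through one
   peptide at one charge carrying exactly one phosphate on that residue.
   Met-containing peptides can pool their oxidised and unoxidised forms
   (summed AUC); without pooling only the unoxidised form represents the
   site.
2. **Reference normalisation** (`normalize_to_reference()`): each AUC is
   divided by the same-replicate AUC of a peptide that cannot be
   phosphorylated in the reaction and carries no Cys/Met; replicate ratios
   are averaged per residue and time. A missing or zero reference in any
   replicate is a hard error naming the replicate — silently dropping it
   would bias means. The reference is fully configurable because different
   experimental arms legitimately use different reference peptides (one from
   the substrate itself, one from a co-purified chaperone).
3. **Percent-of-maximum** (`percent_of_max()`): each residue's means are
   scaled to its own maximum (= 100), SDs rescaled by the same factor. This
   makes kinetic shapes comparable across residues and is also why
   percent-of-max cannot carry absolute claims.

**Resistance classification** (`classify_resistance()`) calls a residue
resistant to autodephosphorylation when it is still detected at the final
time point of a design whose late span exposes sites to active phosphatase.
The call is made on the final-time *mean ratio* (default threshold 0.01),
not on percent-of-max: any monotonically rising site ends at 100% of its own
maximum, so percent values are uninformative exactly where the call is made.
With phospho and reference signal on the same scale the ratio threshold
coincides with the 1% occupancy convention of the kinetics module.

Pattern tables (`build_pattern_table()` / `render_pattern_table()`) collect
per-condition detections into a condition × residue boolean matrix, residues
ordered by sequence position, serines first-class alongside tyrosines.
`eya3_hek_detections()` ships the cell-culture pattern used as a worked
example.

## Conservation scoring

`relative_entropy()` implements the information-content convention for
sequence logos: `R = log2(20) − (H + e_n)` bits with `H` the Shannon entropy
of the non-gap residue frequencies, clamped at zero. Gaps (and ambiguity
letters B/Z/X/U, with a warning) are excluded from the denominator — a
column's conservation should reflect the residues actually present, not
alignment coverage. The small-sample correction `e_n = 19/(2 ln 2 · n)` is
off by default: at the hundreds-of-sequences scale these alignments have it
is ~0.02 bits, well under biological interest, but the flag exists for small
alignments. `residue_frequency()` reports per-column tyrosine percentages on
the same gap-excluded denominator. Positions are reported in reference
coordinates via `map_columns_to_reference()`; letter heights in
`logo_table()` are frequency × R, so they stack exactly to R.

## What the generators emulate — and what they do not

`generator_config()` + `gen_native_spectrum()` / `gen_quant_table()` /
`gen_alignment()` are pure functions of their seeded configuration
(byte-identical under a fixed seed; default seed 20191213).

* **Spectra**: centroid peaks at theoretical m/z for every (acetyl, nP)
  state across charges 14+–18+, heights = state fraction × a fixed
  triangular charge profile peaking at 16+, plus uniform noise peaks below
  1% of the base peak, optionally the 112.7 kDa substrate–chaperone complex
  envelope. Not emulated: isotope structure, adducts, profile-mode peak
  shapes, baseline. Passing round-trip tests therefore shows the inference
  logic is correct, not that vendor-grade peak picking is reproduced.
* **Quant tables**: AUC = scale × occupancy × unit-mean log-normal noise
  (CV 10%, three technical replicates), a reference peptide with its own
  noise, Met peptides split 70/30 into unoxidised/oxidised forms. Not
  emulated: missed cleavages, co-elution, search-engine misassignment.
* **Alignments**: a synthetic reference scaffold (573 residues, tyrosines
  planted at the phosphosite positions) with 721 homologue rows sampled
  column-wise — reference letter with the configured conservation
  probability (0.95 at resistant sites, 0.7 at other sites, 0.3 elsewhere),
  uniform otherwise, 5% gaps. The scaffold is synthetic; no real homologue
  set is shipped.

The three packaged designs (`eya3_design()`) encode the study conditions:
a 6 h kinase time course on the phosphatase-dead mutant sampled at 5 min,
30 min, 2 h, 6 h (eleven participating sites; `k_p` 1.5/h for the five
early-appearing sites, 0.1/h for the six late ones); a wild-type time course
with kinase and phosphatase simultaneously active (resistant sites Y77, Y96,
Y105, Y237 at `k_d` = 0.05/h settle near full occupancy; Y72 at
`k_p` = 0.01, `k_d` = 2/h settles below the detection bound; seven sites do
not accumulate detectable occupancy); and a two-phase workflow — kinase on
for 90 min, inhibited for 1 h, then 4 h of active phosphatase — in which
eleven sites participate and exactly Y77, Y96, Y237 and Y508
(`k_d` = 0.05/h versus 2/h for labile sites) survive to the final sample.
The rate constants are calibrations of the observed phenomenology (which
sites appear when, and which survive), chosen once; they are not measured
rate constants. One consequence is documented openly: a constant-rate model
cannot reproduce a rise-then-fall profile within a single phase, so the
wild-type design encodes Y72's eventual disappearance through its
steady-state level rather than through a non-monotone trajectory.

Problem sizes throughout (5-charge envelopes, 13 sites, 3 replicates,
721-row alignments, 10^6 Monte-Carlo draws in tests) are the package's
choices for a thorough-but-quick default suite; all are configurable.

## Numerical conventions

* Tolerances: 0.1 Th for m/z matching, 1.5 Da for ladder annotation, 2 Da
  for complex assignment, 0.25 for charge-rounding ambiguity, 0.01 for
  detection — each configurable at its call site.
* Ladder ties within 0.01 Da flag ambiguity; envelope-score ties break to
  the smaller RMS residual; equal-intensity seed ties break to the
  lower-m/z peak (stable order).
* Degenerate inputs: all-gap columns, empty spectra, missing reference
  replicates and all-zero ratio series raise or flag as documented rather
  than propagating NaN.
* `percent_of_max()` of an all-zero series returns zeros with a warning and
  an `all_zero` flag instead of dividing by zero.

## Limitations

* Site independence is assumed everywhere the Poisson-binomial bridge is
  used; cooperative phosphorylation would break the bridge quantitatively.
* The two-rate model has no substrate-level saturation (no Michaelis–Menten
  regime) and no site-specific phosphatase activation.
* Deconvolution assumes centroided input and resolved envelope peaks;
  overlapping proteoforms within the m/z tolerance merge.
* Conservation scoring does not weight sequences phylogenetically; heavily
  sampled clades inflate apparent conservation.
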