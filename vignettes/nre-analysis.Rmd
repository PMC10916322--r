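---
title: "Models and methods behind the NRE pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the NRE pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions in `nrekit`, in the spirit of a methods section: what each
stage assumes, why the defaults are what they are, and where the
boundaries of the approach lie.

## The biological object

Plant receptor-like kinases (RLKs) pair an intracellular kinase domain
with, in receptor kinases (RKs), an extracellular ligand-binding domain
and a single transmembrane (TM) helix. Receptor-like cytoplasmic kinases
(RLCKs) lack the ectodomain and may or may not retain a TM helix. The
sequence between the membrane (or the protein start) and the kinase
domain — the N-terminal regulatory element, NRE — is conformationally
flexible, serine-rich, heavily phosphorylated, and ends in a conserved
14-residue consensus (`FSYEELEKAT[D/N]NF[S/D]`) whose T-x-x-F "ST motif"
caps the first helix of the kinase domain. The pipeline extracts these
segments, profiles them, finds class-specific motifs and maps
experimentally determined phosphosites into them.

All coordinates in the package are 1-based and inclusive on both ends, in
protein residues; the convention is enforced at the I/O boundary.
Degenerate letters B = {D,N}, Z = {E,Q}, J = {I,L} and X = any are
admitted in sequences and motif consensi and are scored as
background-weighted averages over their expansion sets.

## Topology classification

A protein is an **RK** when it has both an annotated ectodomain and a TM
helix; an **RLCK with TM** when it has a TM but no ectodomain and fewer
than `extracellular_max_len` residues N-terminal of the TM (default 60
residues, the protein-level reading of "shorter than 180 nt"; signal
peptides are subtracted); an **RLCK without TM** when it has no TM; and
`unclassified` otherwise. Ectodomain presence is taken strictly from
annotations — the package does not attempt domain recognition.

TM intervals come from a *consensus* over annotation sources: intervals
corroborated by a second source (pairwise overlap ≥ 5 residues) are
reported as the intersection of the corroborating intervals, the most
conservative reading of "consensus"; uncorroborated intervals pass
through flagged `single_source`. When no TM annotation exists at all, a
single-pass Kyte–Doolittle detector stands in: positions whose
`tm_window = 19`-residue window mean hydropathy reaches
`tm_gravy_threshold = 1.6` form maximal runs, and runs of ≥ 15 positions
are reported. Windows truncate at the sequence termini so helices close
to the N-terminus (common in RLCKs with a short extracellular stretch)
remain detectable. These thresholds follow common single-pass TM
practice; the detector is a fallback only and never overrides provided
annotations.

**Known limitation.** The NRE typically opens with a basic R/K run (the
positive-inside rule) directly after the TM helix. Those strongly
hydrophilic residues depress the window means near the helix C-terminus
and can shorten the qualifying run below 15 positions, so the fallback
misses a minority of genuine helices. The test suite asserts ≥ 80%
fallback recovery on simulated data rather than pretending to 100%.

## Kinase boundary and NRE extraction

Kinase-domain HMM profiles carry a conserved `(L/I/V)GXG` 4-mer at
positions 5–8 of the domain. `locate_kinase_start()` therefore searches
`anchor_search_radius = 30` residues around the annotated start for a
candidate start `d` whose positions 5–8 (the 4-mer at `d + 4`) match
`[LIV]G.G`; among candidates the one closest to the annotation wins, ties
going to the more N-terminal start (deterministic, annotation-preserving).
If no candidate matches, the annotation is kept and flagged unrefined,
preserving both behaviours for audit.

The NRE is then `[tm_end + 1, domain_start − 1]` (JM) for TM-bearing
topologies and `[1, domain_start − 1]` minus any annotated signal peptide
(NKE) otherwise. A TM end at or beyond the kinase start is a boundary
conflict; empty segments are counted, not fabricated. Before motif work
the final `cterm_strip = 14` residues — the C-terminal consensus, which
would otherwise dominate discovery — are removed.

## Profiling

**Scaled composition.** Segments of different lengths are aligned onto
`scale_bins = 200` positions. Residue `i` of a length-`L` segment
occupies the real interval `[(i−1)·200/L, i·200/L)` and spreads its unit
weight over the bins it overlaps, proportionally to the overlap. This
mass-conserving mapping (total weight = Σ segment lengths, asserted at
1e-6) is preferred over nearest-bin rounding because it is unbiased by
segment length; boundary bins receive split weight, which is the exact
consequence of the mapping. Residue weighting is the default; sequence
weighting (each segment contributes weight 1) is exposed as an option
because the choice is genuinely open.

**Logos.** Terminal logos use the first/last `terminal_window = 20`
residues; columns report letter frequencies and information content
`IC = log2(20) − H` in bits, without small-sample correction — the
intended corpora are large, and `n` is reported so users can judge.

**Signature.** The 14-residue consensus matcher scans the last 40
residues for the best ungapped agreement with
`FSYEELEKAT[D/N]NF[S/D]`; a hit needs ≥ `signature_min_agree = 10` of 14
agreements (the consensus itself fixes no matcher, so the threshold is
configurable and reported with every hit), ties resolving toward the
C-terminus where the element lives. Independently, the ST-motif flag
checks T at −5 and F at −2 of the segment (−1 = last residue), the
negative-position convention used throughout, including the LRR-VI-2
type-1 rule (serine at −28 *and* a class-motif match at the scan
threshold).

## Motif model

**Background and PWMs.** The background is the letter frequency over all
trimmed segments with +1 pseudocounts. PWM cells get a pseudocount of
`pwm_pseudocount = 0.1` times the background letter probability, so each
column sums to `n_sites + 0.1`; log-odds are base-2 against the
background. Consensus strings report the per-column argmax, or the
degenerate code when the runner-up is within 0.8× of the maximum and the
pair is one of {D,N}, {E,Q}, {I,L}.

**Exact p-values.** Per-position log-odds are discretised to integer
multiples of `pvalue_resolution = 1/1000` bit and the exact distribution
of a random word's total score under the background is built by dynamic
programming (convolution across positions). Scanning scores words on the
*same* integer grid, so scan p-values are exact for the discretised score
and within `w·resolution/2` bits of the undiscretised one; the test suite
checks the DP against full enumeration. Matches are reported at
`scan_p = 0.001`; transitively overlapping matches of one motif resolve
to the best p, ties leftmost. A word at the distribution's maximum keeps
a positive p (its own probability); realised scores can never exceed the
table.

**ZOOPS EM.** Discovery assumes zero-or-one motif occurrence per
sequence: with prior γ a sequence carries one site at a uniformly chosen
offset. The E-step computes per-offset posterior occurrence
probabilities against the background; the M-step re-estimates the PWM
(with the Dirichlet pseudocount) and γ. Because the M-step is a MAP
update, the quantity that is provably non-decreasing — and asserted at
every iteration — is the penalised log-likelihood (log-posterior), not
the raw likelihood. Degenerate letters enter the E-step through their
background mixture and are split in the M-step by posterior
responsibility, which keeps the objective monotone even on masked data.

Starts are data-driven: a wide pool of sampled k-mer windows is screened
by a cheap one-pass score (the sum of positive per-sequence best
log-likelihood ratios, excluding the seed's own sequence, so that
recurring k-mers outrank one-off self-matches) and the best `n_starts = 5`
run EM to convergence (`tol = 1e-6` relative, `max_iter = 200`). A
column-shift refinement then re-runs EM from models shifted by ±1–3
columns while the objective improves, escaping the phase-shifted local
optima that plague fixed-width EM. Models are ranked across widths by a
chi-square approximation to the log-likelihood-ratio statistic
(df = 19·w + 1) and accepted at `discovery_p = 0.005`. This preserves the
threshold semantics of the original tool-based analysis but is *not* the
same calibration as that tool's E-values — a documented deviation.
Between successive motifs, accepted sites (posterior > 0.5) are
hard-masked with X, a deterministic stand-in for probabilistic erasure.
Everything is reproducible from the seed.

## Enrichment and phosphosites

The class-enrichment statistic is the normalized frequency
`F = Nm²·Ntotal / (P·Nc²)`, computed and verified against its factored
form `(Nm/(P·Ac))·(Nm/Nc)` at 1e-9. `Ntotal` is the *domain-free* NRE
corpus: segments overlapping an annotated extra domain are excluded
before counting, the same exclusion the published tables imply. `Nm`
counts occurrences (matches), not distinct sequences. Motifs with `F`
strictly above `nf_threshold = 1` in a class are overrepresented there.

Two algebraic facts worth knowing when constructing nulls: summing `Nm`
over classes always returns `P`; and under a uniform per-class occurrence
rate `Nm/Nc = r` the statistic equals `F = r·Ntotal/P · r = r`, i.e. it
calibrates to exactly 1 only when the motif occurs once per segment
(`P = Ntotal`). The calibration test constructs that null; planted
single-class motifs give `F > 1` in their class and `F < 1` elsewhere.

Phosphosite containment is inclusive on both match boundaries (the edge
semantics are unstated in the source analysis; inclusive is the wider
reading and is tested explicitly). Sequence identity is the fraction of
consensus-agreeing positions, degenerate letters agreeing with their
expansion sets; conservation tiers cut at mean SI > 80% (high) and 50–80%
(moderate), exactly 80% falling in moderate because "more than 80%"
defines high. Mean SI averages over matches; averaging over sequences or
species would be a different, also defensible choice, which is why the
identity list is returned alongside the mean. A motif whose consensus
lacks S, T or Y at any observed phosphosite offset is excluded from the
phospho-motif report and surfaced in the exclusions table.

## The synthetic generator

`simulate_rlk_dataset()` emulates the survey's study conditions: a
topology mix proportional to the reported corpus composition
(0.614 / 0.091 / 0.295 for RK / RLCK-TM / RLCK-noTM), NRE lengths from a
two-mode normal mixture (modes 40 and 50 residues, the reported peaks),
an 8-residue basic R/K run, a serine-rich middle (serine fraction 0.25,
the reported mid-NRE plateau), one published motif consensus per class
planted at rate 0.8 with 10% per-position substitution, the 14-residue
consensus tail with its D/N and S/D variants (0.7/0.3), and a kinase stub
whose positions 5–8 carry the anchor. The anchor is rejection-sampled to
be unique within the search window, so boundary recovery is well-posed.
Phosphosites are emitted at the planted motif offsets; those positions
are protected from substitution noise so the site residue always matches
the sequence, mirroring the validity guarantee of a curated phosphosite
export. Optional knobs add motif-free classes, internal domains (to
exercise the corpus exclusion) and random background sites (to exercise
the S/T/Y exclusion and non-containment paths).

What the generator does **not** emulate: real amino-acid k-mer statistics
beyond letter frequencies, gapped or variable-width motifs, annotation
noise beyond uniform jitter/dropout, homology between proteins, and the
actual class-size imbalance of a 500-genome corpus. Passing recovery
tests therefore demonstrates the correctness of the machinery under
known-truth conditions, not field performance on real proteomes.

## Problem sizes and determinism

The test and acceptance workloads use 80–1,000 synthetic proteins,
discovery on 200 trimmed segments at the planted width, and full
enumeration oracles up to width 3 over 20 letters and width 8 over 4
letters — sizes at which every oracle is exact and a full run completes
in minutes on one CPU. All stochastic stages (generator, EM seeding)
derive from a single integer seed; re-running any stage with the same
inputs and seed reproduces identical bytes, which the suite asserts.

## Known limitations

- ECD presence is never inferred; proteins lacking ectodomain annotations
  can only be RKs if annotated as such.
- The discovery significance is a chi-square LLR approximation, useful
  for ranking and thresholding, not a calibrated E-value.
- The fallback TM detector inherits the blind spots of single-pass
  hydropathy scans (see above).
- `F` compares occurrence concentrations, not statistical significance;
  very small `Nc` can produce large `F` from few matches. The counts are
  always reported alongside.
- RLCKs "without NKE" (no kinase N-flank at all) have no defining rule in
  the source analysis and end up `unclassified` here rather than guessed.
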