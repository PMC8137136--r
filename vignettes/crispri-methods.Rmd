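---
title: "Methods: guide scoring and the percent-repression statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guide scoring and the percent-repression statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pombeCRISPRi)
```

## The problem

CRISPRi represses a gene by parking nuclease-dead Cas9 (dCas9) on it: an
sgRNA base-pairs its 20-nt targeting sequence with genomic DNA next to an
NGG PAM, and the bound ribonucleoprotein obstructs RNA polymerase. In
fission yeast the efficacy of a guide depends strongly on two design
variables:

* **offset** — the signed distance from the transcription start site
  (TSS) to the center of the protospacer, positive downstream in the
  direction of transcription;
* **orientation** — `forward` when the targeting sequence is identical
  to the non-template strand (the protospacer sits on the gene's
  strand), `reverse` when it matches the template strand.

This package turns those observations into a deterministic design
procedure, and implements the statistic used to quantify the resulting
knockdown from RT-qPCR data.

## Coordinate and orientation conventions

All external coordinates are 1-based and inclusive, strand `+`/`-`, with
the TSS defined as the single first transcribed base; TSS intervals are
not supported, and duplicate TSS records per gene are rejected. Reported
`start`/`end` of a protospacer are always plus-strand coordinates of the
20-bp footprint (PAM excluded); `protospacer` and `pam` are written
5'→3' on the carrying strand. For a 20-nt (even-length) spacer the
center, and therefore the offset, is an exact half-integer; it is never
rounded, so ties in |offset − peak| between mirrored candidates are
exact and are resolved by the documented tie-break (below).

`N` bases are retained in the genome but poison any candidate window
that touches them (protospacer or PAM): such windows are simply not
candidates, which keeps match semantics unambiguous.

## The scoring model

Efficacy has two peaks: forward guides work best ~60–120 bp downstream
of the TSS, and reverse guides in a narrow band centered near −5 bp,
overlapping the TSS; a broad −30 to +100 bp band is still preferable to
distant sites. Both statements are encoded rather than reconciled:

* **tier A** — forward with offset in [60, 120], or reverse with offset
  in [−30, 15];
* **tier B** — offset in [−30, 100], either orientation, not tier A;
* **tier C** — everything else.

The evidence for directionality immediately around the TSS is mixed;
tier A for reverse-only there follows the stated design guideline rather
than every data point, and the broad band survives as tier B precisely
so that near-TSS forward guides are still ranked well.

No quantitative efficacy function is established for this system, so the
numeric score is deliberately minimal: `base(tier) − 10⁻⁴·|offset −
peak(orientation)|`, clamped at 0.01, with bases 1.0 / 0.5 / 0.1 and
peaks at +90 (forward) and −5 (reverse). The penalty is small enough
that tier bands can never overlap (tier A scores stay above 0.99 inside
a window at most 60 bp wide; tier B tops out at 0.5), so the tier
ordering is guaranteed, and the score only orders guides *within* a
tier by distance to the empirical optimum. Remaining ties break by
start coordinate ascending, then `+` strand before `-` — full
determinism for fixed inputs. All window constants are exposed through
`scoring_rules()` / `crispri_config()` rather than hard-coded.

The default scan window is 200 bp upstream to 300 bp downstream of the
TSS (in transcription direction): wide enough to contain both efficacy
peaks, the broad band, and clearly-inferior distal sites, so ranking is
informative at the edges. Candidates overlapping the window edge are
kept when their center lies inside. Spacer length is fixed at 20 nt —
longer spacers do not improve CRISPRi — but lengths 18–25 are accepted
with a warning.

## Off-target screening

Specificity is operationalized as exact matching, which is the
appropriate desk-scale notion for choosing a unique guide: `n20` counts
genomic sites (both strands, any NGG PAM; the PAM's N is never compared)
whose protospacer equals the query, and `unique` means `n20 == 1` — the
candidate's own site and nothing else. A second, stricter count `n12`
uses only the PAM-proximal 12-nt seed, the region that dominates Cas9
binding specificity; `n12 ≥ n20` always. Mismatch-tolerant off-target
prediction is intentionally out of scope.

## Cloning oligos

For spacer `S`, the duplex is `CACC + S` over `AAAC + revcomp(S)`
(both written 5'→3'), presenting the 4-nt 5' overhangs that direct
ligation into the BbsI-cut sgRNA vector; the overhangs are configuration
values since a different vector digestion would change them. The spacer
melting temperature defaults to the Wallace rule, `2(#A+#T) + 4(#G+#C)`
°C — deterministic, dependency-free, and standard for 20-mers — with a
unified nearest-neighbor alternative (`method = "nn"`, 50 mM Na⁺, 20 µM
oligo) behind a switch. The annealing program is 95 °C for 2 min,
cooling at −2 °C/min to Tm, 5 min at Tm, then cooling to 25 °C; the
final ramp rate is not independently specified anywhere, so −2 °C/min is
reused for symmetry. Ramp durations follow from the rate (e.g. Tm 60 °C
gives 17.5 min per ramp), and a zero-span ramp is kept as a no-op step
so the program shape is invariant.

## The percent-repression statistic

Per sample, the target transcript is quantified against a reference
transcript by the ΔCq model, `rel = E^(Cq_ref − Cq_target)`, with
efficiency `E` configurable in (1, 2.2] and defaulting to 2 (perfect
doubling); standard-curve quantification is out of scope. Each
replicate's relative level is then divided by the *mean* level of the
nonsense-control group — per-replicate division, as the procedure is
stated, rather than a ratio of group means — and inverted to a
repression index `R`. Percent repression per replicate is

$$\%R_i = \frac{R_i - \overline{R_{ns}}}{\overline{R_{max}} - \overline{R_{ns}}} \times 100$$

with `R_ns` the nonsense-control indices and `R_max` those of the
designated most-effective guide. Two identities follow algebraically for
*any* positive data and anchor the scale: the nonsense group averages
exactly 0% and the R_max group exactly 100%. The statistic is invariant
under a common positive rescaling of all indices, and strictly monotone
in decreasing relative mRNA. Equal `mean(R_max)` and `mean(R_ns)` makes
the denominator vanish and is reported as a degenerate-normalization
error.

R_max can be designated explicitly (reproducing a fixed published
choice) or as `"auto"`, which picks the guide with the highest mean
repression index; both exist because the published designation is not
always the empirically strongest guide. Replicate summaries are mean ±
sample SD (n − 1 denominator, the convention behind "mean ± standard
deviation"); groups with fewer than three biological replicates are
summarized but flagged rather than rejected.

## What the simulators emulate — and what they do not

`generate_genome_fixture()` draws i.i.d. bases at a configurable GC
fraction (default 0.36, fission-yeast-like) and plants protospacer+NGG
sites at requested orientations and half-integer offsets; uniqueness is
enforced by rejection sampling of the planted 20-mer against both
strands of the whole genome (capped at 1000 attempts; failure is an
error, never silent). An optional mode resamples 150 bp upstream of each
TSS at GC 0.25, mimicking the AT-rich promoters that make PAM-bearing
candidates sparse upstream of real TSSs. The generator is
bit-reproducible under a fixed seed.

`generate_qpcr_fixture()` inverts the ΔCq model: reference Cq near a
baseline of 15 cycles, target Cq shifted by −log_E(level), each plus
Gaussian noise of configurable SD. Zero noise makes the quantification
chain recover planted levels exactly (a round-trip identity used
throughout the tests); SD 0.1 cycles with 100 replicates is used for the
seeded statistical-recovery checks.

Passing tests on these fixtures demonstrates the *algorithmic* contract:
sites are found exactly, offsets and orientations are classified
correctly, ranking follows the rules, and the statistic chain is
self-consistent. They do not demonstrate biological efficacy: i.i.d.
backgrounds lack repeats, homopolymers and compositional structure of a
real genome (off-target counts on real genomes will be larger), and
simulated Cq noise is Gaussian and independent, with none of the
pipetting, efficiency-drift or batch structure of real RT-qPCR.

## Problem sizes and numerical choices

The test suite works at desk scale by choice: oracle-equivalence checks
run 20 random sequences of 0.2–5 kb against a brute-force enumeration;
off-target agreement uses multi-chromosome genomes up to ~7 kb;
statistical recovery uses 100 replicates at 0.1-cycle noise and asserts
agreement within three standard errors under fixed seeds. Floating-point
equality (e.g. the 0%/100% anchors) is asserted at testthat's default
tolerance, since the identities are algebraic; the zero-noise
round-trips are asserted to 1e-12.

## Known limitations

* Efficacy tiers and the distance penalty codify qualitative positional
  preferences; the score is a ranking device, not a calibrated efficacy
  prediction, and ignores sequence features (GC content, homopolymers,
  secondary structure, chromatin).
* Off-target screening is exact-match only.
* One TSS per gene; genes with alternative or dispersed starts need
  separate records under distinct ids.
* The ΔCq model assumes a single stable reference transcript and equal
  amplification efficiency across targets.
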