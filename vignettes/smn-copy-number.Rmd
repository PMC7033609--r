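---
title: "Methods: MLPA copy-number analysis of the SMN region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MLPA copy-number analysis of the SMN region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SMNcnv)
```

# Scope and model

SMNcnv analyzes multiplex ligation-dependent probe amplification (MLPA)
dosage data over the *SMN1*/*SMN2* segmental duplication at 5q13. The
region's defining difficulties shape every design choice here: probe
targets are duplicated and hypervariable (diploid totals from 0 to 6 and
beyond), several probes cannot distinguish the two gene copies and report
only a combined dose, there is no reliable physical map of the region, and
dosage totals say nothing about phase — a total of 2 can be one copy per
homolog (1:1) or two copies in cis against a deletion (2:0, a silent SMA
carrier).

The package treats region identifiers as abstract labels rather than
coordinates. Twelve SMN-region labels are used: gene-specific
`SMN1_e7, SMN1_e8, SMN2_e7, SMN2_e8, NAIP_e5, SERF1B, RAD17` and combined
`SMN12_e1, SMN12_e4, SMN12_e6, NAIPc_e13, GTF2H2_e5`. A combined probe
hybridizes identically to both genes; its expected diploid dose is 4
(two genes × two homologs) where a gene-specific probe's is 2. The
bundled P021 panel carries 46 probes (7 dosage-quality control fragments,
2 sex probes, 22 autosomal reference probes, 15 SMN-region targets); the
published kit description fixes only these totals, so the distribution of
the 15 target probes over the 12 regions (three combined regions carry two
probes each) is a package convention, and the assumed region order is a
configurable panel attribute with no genomic claim.

# Dosage quotients and copy-number calling

Normalization is two-stage. Within a sample, each probe signal is divided
by the median reference-probe signal, cancelling sample-scale effects
(DNA input, injection efficiency); this ratio is then divided by the
median of the same ratio across the external control samples (at least
three required), cancelling probe-specific amplification efficiency. The
result is a dosage quotient (DQ) with 1.0 ≡ the reference diploid dose.
Medians are used at both stages for robustness to single-probe outliers.
The commercial analysis software performs a proprietary regression-based
normalization; the median-ratio scheme here is a documented, transparent
contract, and real exports may differ in the second decimal of DQ.

Integer calling offers two modes:

* **`table1`** reproduces the published lookup exactly: DQ bins
  `[0, 0.35) [0.35, 0.65) [0.65, 1.35) [1.35, 1.65) [1.65, 2.35)` map to
  0/1/2/3/4 copies (gene-specific) or 0/2/4/6/8 (combined). Bins are
  left-closed: a DQ of exactly 0.65 calls two copies. The published table
  stops at 2.35 although observed cohorts reach six copies; above 2.35 the
  call is `round(DQ × expected diploid dose)`, the only continuation
  consistent with the bin centres.
* **`rounding`** (pipeline default) uses `round(DQ × expected dose)`
  throughout. It is the only mode that can call *odd* combined totals
  (the published combined column lists even counts only); e.g. DQ 0.75 on
  a combined probe calls 3 in rounding mode but 4 in table mode — a
  documented divergence. Rounding is half-away-from-zero, so calls are
  deterministic at exact half-copy doses.

Calls whose DQ lies within `tol` (default 0.05) of an interior bin
boundary {0.35, 0.65, 1.35, 1.65, 2.35} are flagged borderline, never
suppressed. The zero edge is not a decision boundary and does not flag.
Where a region carries two probes their DQs are averaged before calling.

QC follows the control-fragment design: the four Q fragments amplify when
too little DNA is ligated, so a Q-fragment median at or above half the
reference median fails the DNA-quantity (and ligation) flag; the two D
fragments fail denaturation when below 0.3× the reference median. Both
thresholds are configurable. Sex probes are used only for a
reported-versus-inferred consistency flag.

# Genotype groups and cohort summaries

Exon-7 totals classify individuals into the diagnostic groups: `M1M1`
(SMN1_e7 = 0), `M2M2` (SMN2_e7 = 0 with SMN1 present), `HET_DEL`
(SMN1_e7 = 1, the 1:0 carrier state), `NORMAL_2`, `MULTI` (> 2), and
`NULL_BOTH` for the joint null. The joint null takes priority over
M1M1/M2M2: the diagnostic assay distinguishes the two deletions and never
reports a joint null, so such a profile is labelled distinctly and flagged
for review rather than silently absorbed. The clinically-referred "U/U"
category is cohort metadata, not a copy-number state, and is never
inferred from a profile. Summaries tabulate 0/1/2/>2 bins per region;
percentages round half-up to one decimal to match the published
formatting byte-for-byte.

# Pedigree phasing and de novo events

For each region, each parent's total T decomposes into unordered allele
splits (a, b), a + b = T, a ≤ b ≤ k_max. A split assignment for both
parents is feasible when every child's total equals one allele from each
parent simultaneously. A family is *informative* when every analyzed
region admits exactly one feasible assignment (phase is certain),
*uninformative* when some region admits several, and *discrepant* when
some region admits none under strictly Mendelian transmission. When some
regions are uninformative and none are infeasible the family is
uninformative; any infeasible region makes it discrepant — the
interpretation this package fixes, with per-region detail always recorded.

Regions are phased independently by default: the region order on a
haplotype is unknown and reported exon copy numbers do not correlate
fully, so joint phasing cannot assume contiguity. An optional joint mode
intersects per-region assignments under a shared transmission choice per
child (each child receives one whole haplotype per parent), which can only
shrink the feasible sets.

Discrepant families trigger a minimal-event search. An event is a
one-copy gain or loss on one transmitted allele at one region, or an
*SMN1*→*SMN2* exon-7 conversion on one transmitted haplotype (one copy
leaves SMN1_e7, one joins SMN2_e7). Every event class costs 1 — the data
cannot adjudicate event type, so a conversion is one event, not a loss
plus a gain, and all tied minimal explanations are reported. Donor
constraints are enforced (a lost or converted copy must exist on the
transmitted allele). With one child per family, an event is detectable
only when it pushes the child outside the transmissible range (e.g. a
gain against two zero-copy parents); events inside the range are
absorbed by split ambiguity — an intrinsic identifiability limit of
dosage data, not of the search. k_max defaults to 6, covering the
observed 1–6 diploid range, and is raised automatically when a parental
total requires it.

# Hardy-Weinberg allele frequencies and carrier risk

Per-allele copy-count frequencies f₀..f₆ are estimated from diploid totals
by maximum likelihood under random mating (each total is the sum of two
independent draws from f), via EM with an L1 stopping tolerance of 1e-8
and a 10,000-iteration cap. The EM is initialized from a smoothed
histogram of halved totals rather than an exactly uniform vector: the
likelihood has symmetric stationary points (e.g. every total equal and
even) on which a perfectly symmetric start would sit forever, while the
halved-totals start is equally deterministic and breaks the symmetry
toward the data. No random restarts are used; estimation is a pure
function of its inputs.

The silent-carrier risk of a total t is the Hardy-Weinberg posterior mass
of splits containing a zero allele: 2·f₀·f_t / Σ_{(a,b): a+b=t} w·f_a·f_b
with w = 2 off the diagonal. Totals 0 and 1 give risk 1; a population
with no zero-copy allele gives risk 0; a total unreachable under f is an
error, not a silent zero.

# Population presets and the forward simulator

The simulator exists so every downstream stage is testable without
patient material. Its presets *are* the study conditions: per-region
allele frequencies for the `black_SA` and `white_SA` pools are fitted at
run time from the bundled published cohort bin counts
(`inst/extdata/cohort_bins.tsv`: the negative-control rows for the four
SMN exon regions, plus NAIP_e5 and RAD17 from the reported
multi-copy percentages). The fit uses an interval-censored extension of
the same EM — 0/1/2 bins enter as exact totals, the ">2" bin as the
censored event total ≥ 3. The censored likelihood is preferred over
expanding ">2" into concrete totals because any expansion is arbitrary
and measurably biases the fit (with the expansion used in fixtures, the
fitted multi-copy mass drops to 0.48 versus the published 0.508; the
censored fit reproduces the published bin fractions exactly wherever the
Hardy-Weinberg family permits). Regions with no published distribution
default to the diploid state. Haplotypes are composed per region
independently, matching the reported lack of full correlation between
exons; an explicit haplotype table is accepted where linkage is needed.

Pedigree simulation transmits one uniformly chosen haplotype per parent.
With probability `de_novo_rate` per transmitted haplotype (default
0.0165, the per-haplotype rate implied by a 3.3% per-family event rate in
one-child families: 1 − (1 − r)² ≈ 0.0327) an event is applied, chosen
uniformly between a ±1 copy change at a uniform region and an exon-7
conversion, rejecting infeasible draws (loss at zero, gain above k_max).

Signal simulation inverts the normalization model:
`signal = base(probe) × true/expected × exp(ε)`, ε ~ N(0, σ²), with
probe-specific base intensities drawn once per run and σ defaulting to
0.08. Q fragments are scaled low so simulated samples pass QC. What this
does and does not show about real data: the noiseless round trip is exact
for every copy state by construction, and at σ = 0.08 calls for copy
states ≤ 2 err below ~2% (the nearest decision boundary is ≥ 0.25 DQ away
while the effective DQ noise SD — probe noise plus the three-control
median term — is ~0.10). Copy states ≥ 3, however, occupy DQ bins only
0.15 wide, so one-copy miscalls there are intrinsic to the bin design at
realistic noise, for any caller; real-world multi-copy calls carry the
same caveat. The simulator also omits capillary trace artifacts,
primer-site SNP dropout and mosaicism.

Fixtures (`makeFixtures()`) are fully deterministic: cohort files whose
bin counts equal the published rows exactly, the ">2" bin expanded as
threes except one four per ten samples (any expansion matching the bin
count is faithful; this one is fixed and auditable), and a 61-trio
pedigree fixture with exactly two planted Mendelian-inconsistent
transmissions — gains at SMN2_e7 against two zero-copy parents, the
configuration a single-child family can actually expose — yielding a
3.3% (2/61) family-level event rate. The event-rate denominator follows
the 61-family count (the alternative 2/60 reading appears in the source
material's haplotype-analysis section and is not silently reconciled).

# Cohort statistics

Kruskal-Wallis is computed on mid-ranks with the standard tie-correction
divisor 1 − Σ(t³−t)/(N³−N) and a χ² p-value on k − 1 degrees of freedom;
copy numbers are ordinal integers, and pre-binned input (a ">2" category)
is rejected rather than approximated, since bins destroy rank
information. Pearson's chi-square is the classical Σ(O−E)²/E with
margin-based expectations, optional Yates correction for 2×2. Both are
cross-checked in the test suite against the independent base-R
implementations to 1e-9. No multiple-testing correction is applied by
default, matching the source analyses; Bonferroni/BH are available.

One documented discrepancy: the published referral-audit comparison
(123/991 versus 9/192 homozygous *SMN2* exon-7 deletions) prints
χ² = 11.64, p = 0.000645, but the Pearson statistic from those printed
counts is ≈ 9.68 (Yates, lower still). The printed value is internally
consistent as a 1-df statistic yet not reproducible from the printed
table; the package computes and reports 9.68 and this divergence is
asserted, not "fixed". The published Kruskal-Wallis H values (e.g. 32.7
for the black/white *SMN1* exon-7 contrast) require the per-individual
data, which is not printed; equivalence with reference implementations
stands in for value reproduction.

# Numerical and testing choices

Problem sizes were chosen to make the full suite complete in about a
minute: preset calibration checks use 10⁴ diplotype draws against a ±0.03
band, EM recovery uses 200 replicates at n = 2000 (L1 < 0.06 in ≥ 95%),
the type-I error of the cohort comparison uses 1000 null replicates at
n = 50 per group against the [0.03, 0.07] band (the test is mildly
conservative under heavy ties, empirically ~0.04), and statistical
cross-checks use 1000 randomized inputs at 1e-9. The phasing engine is
verified exhaustively against a brute-force enumerator over all trio
total combinations 0–6. All stochastic tests run under fixed seeds;
fixture generation is byte-reproducible.

# Known limitations

* Phase inference assumes nuclear families with a single couple;
  multi-generation pedigrees must be split.
* Per-region independent phasing can over-accept conversion explanations
  relative to a fully haplotype-resolved model, since allele choices at
  the two exon-7 regions are not forced onto the same homolog outside
  joint mode.
* The DQ normalization is a stand-in contract for proprietary software
  output; absolute DQs may differ in the second decimal.
* Presets model per-region independence; real haplotypes may carry
  linkage the independent pool cannot express (an explicit haplotype
  table is the escape hatch).
* Copy states above ~4 are intrinsically noisy at realistic signal CVs,
  as quantified above.
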