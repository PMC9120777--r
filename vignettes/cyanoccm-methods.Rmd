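---
title: "Methods: comparative genomics of the cyanobacterial CO2-concentrating mechanism"
author: "cyanoccm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of the cyanobacterial CCM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanoccm)
```

## Scope and scientific background

Thermophilic cyanobacteria inhabit hot springs where dissolved inorganic
carbon (Ci) is scarce: CO2 solubility falls steeply with temperature, and
the speciation of the carbonate system (CO2\*(aq), HCO3^-^, CO3^2-^) shifts
with pH, temperature and salinity. To photosynthesize under these
conditions they operate a CO2-concentrating mechanism (CCM): active Ci
uptake systems at the membranes (the NDH-1~3~ and NDH-1~4~ CO2-uptake
complexes; the BicA, SbtA/SbtB and BCT1 bicarbonate transporters) feed
HCO3^-^ into carboxysomes, protein microcompartments whose shell
(ccmK1-K4, ccmL, ccmM, ccmN, ccmO, ccmP) encloses Rubisco (rbcL/rbcS,
chaperone rbcX) together with a carbonic anhydrase (CA).

`cyanoccm` re-implements, as a tested pipeline, the comparative-genomics
workflow used to characterize these components across 17 well-described
thermophilic strains: ortholog detection by bidirectional best hit (BBH),
presence/absence genotyping, locus-organization analysis, genome
relatedness (ANI/AAI/POCP) with taxon delimitation rules, a γ-CA domain
assessment of ccmM, and the carbonate speciation model that frames the
ecology. Genome sequencing/assembly, annotation transfer and phylogenetic
tree inference are outside the package's scope.

## The carbonate model

Speciation fractions come from the closed forms

$$\alpha_{CO_2} = \frac{1}{1 + K_1/h + K_1K_2/h^2},\quad
  \alpha_{HCO_3} = \frac{1}{h/K_1 + 1 + K_2/h},\quad
  \alpha_{CO_3} = \frac{1}{h^2/(K_1K_2) + h/K_2 + 1},$$

with $h = 10^{-\mathrm{pH}}$ on the free hydrogen-ion scale; activity
coefficients are ignored, so the Bjerrum curves are concentration-based.
The constants are classical empirical fits, stored in a versioned YAML
file so an alternative parameterization can be swapped in:

* $K_0$ (Henry solubility, mol kg^-1^ atm^-1^): Weiss-form polynomial
  $\ln K_0 = a_1 + a_2(100/T) + a_3\ln(T/100) + S[b_1 + b_2(T/100) +
  b_3(T/100)^2]$.
* freshwater $pK_1$, $pK_2$: Harned-Davis / Harned-Scholes polynomials
  $a/T + b + cT$.
* salinity: Millero-style increments $\Delta pK(S,T) = (A_1\sqrt S + A_2 S
  + A_3 S^2) + (B_1\sqrt S + B_2 S)/T + C_1\sqrt S\ln T$, which vanish at
  $S = 0$.

These fits are stated for roughly 0-50 °C. Hot-spring temperatures above
that are accepted up to 100 °C but flagged `extrapolated = TRUE` in every
result, mirroring how the underlying curves are commonly extrapolated to
~72 °C. Temperature enters in °C at the interface and is converted to
Kelvin internally.

```{r carbonate}
equilibrium_constants(45, 0)
solubility_change(30, 60, 0)   # percent CO2 solubility lost on warming
```

Two structural checks anchor the model: the fractions sum to one to
within 1e-12 everywhere, and the pH at which adjacent species are equally
abundant — found independently by bisection on the speciation curves
(`speciation_crossover()`) — equals $pK_1$ (resp. $pK_2$) to 1e-6 pH
units. Warming acid-shifts both crossovers, which is the mechanistic core
of the "less Ci available at higher temperature" argument.

## Alignment engine and statistics

All identity/coverage/E-value thresholds downstream act on explicit exact
local alignments rather than a heuristic search: a Smith-Waterman /
Gotoh affine-gap dynamic program (C++ via Rcpp), with BLOSUM62 and gap
open -11 / extend -1 as the protein default and +1/-1 with gaps -2/-1
for DNA. A length-$L$ gap costs $11 + L$ — the BLAST convention. The
ambiguity residue X scores 0 against everything, so masked residues are
neutral. Traceback is deterministic (diagonal > up > left at ties; the
first maximal cell in row-major order), so equal-scoring alignments
always resolve identically.

Identity is counted over all aligned columns including gap columns (the
BLAST convention); coverage is the aligned span of a sequence divided by
its full length, per sequence separately. Both definitions are
config-independent of each other, because published threshold statements
rarely pin them down. E-values use the Karlin-Altschul form
$E = K m n e^{-\lambda S}$ with the standard gapped BLOSUM62 constants
($\lambda = 0.267$, $K = 0.041$) and full sequence lengths — not
effective lengths — as the search space, a deliberate simplification.

The engine is checked two independent ways: a plain cubic
dynamic program (scanning every gap length explicitly, no Gotoh states)
on thousands of small random pairs, and Biostrings' independent C
implementation on longer pairs. The engine is exact-only; for genome-scale
work an external aligner can be substituted upstream as long as it yields
the same hit-record fields.

## Ortholog detection

A reference set of 29 proteins (28 CCM proteins of *Synechocystis* sp.
PCC 6803 plus the α-CA ecaA of *Anabaena* sp. PCC 7120; the symbol ↔
locus-tag manifest ships with the package, the sequences are
user-supplied) is searched against each strain proteome. A hit survives
when E ≤ 1e-6, identity ≥ 30 % and coverage ≥ 70 %; a symbol is called
present only when forward and reverse best hits agree (BBH). Design
choices the published thresholds leave open, and how they were fixed
here:

* **Coverage of which sequence?** The query, in each direction (so the
  reference must be 70 %-covered in the forward search). This blocks
  short-fragment calls — e.g. a partial transporter CDS — from passing on
  the strength of a locally perfect match; a stricter both-sequences
  mode is available (`bbh_thresholds(coverage_mode = "both")`).
* **Reverse-search target.** The 29-entry reference set itself, keeping
  the pipeline self-contained; a full reference-organism proteome can be
  passed via `reverse_target` when available.
* **Tie-breaks.** Higher score, then lower E-value, then lexicographically
  smallest subject id — fully deterministic.

## Genome relatedness and taxon rules

* **AAI**: mean identity over reciprocal best-hit protein pairs passing
  the 30/70 filters.
* **POCP**: a protein is conserved when it hits the other proteome at
  E < 1e-5, identity > 40 % and an aligned region > 50 % of its own
  length; POCP $= 100(C_1+C_2)/(T_1+T_2)$.
* **ANI**: BLAST-style fragment ANI ("ANIb-style"): genome A is chopped
  into consecutive 1020-bp fragments (trailing fragments shorter than
  100 bp are dropped), each is locally aligned to genome B, fragments
  aligning at ≥ 70 % identity over ≥ 70 % of their length are retained,
  and the retained identities are averaged; the two-way value averages
  both directions. The original analysis used an unnamed web calculator,
  so exact agreement is not promised; reports label the method
  ANIb-style.

Decision rules: redundant duplicates at ANI > 99.9 %; same species at
ANI > 96 or AAI ≥ 95; same genus at ANI ≥ 83, AAI > 70 or POCP ≥ 50.
ANI in (83, 96] without a species-level trigger is reported as
species-rank inconclusive while the genus bound still applies; the
rationale string always names the inequality that fired, and the rules
are monotone (raising a metric can never demote a pair).

## Genotyping and the CA complement

System completeness rules reflect the biology of each transporter: the
NDH-1 complexes need all three subunit genes; BicA counts with either
paralog (bicA1/bicA2); Sbt counts with either sbtA or sbtB, because
strains carrying only the regulator sbtB group with the sbt-bearing
genotype (a strict both-genes mode exists); BCT1, a four-subunit ABC
transporter, needs all of cmpA-cmpD — partial complements are reported
as "partial" and treated as absent. Genotypes: **I** = all five Ci-uptake
systems; **II** = Sbt without BCT1; **III** = BCT1 without Sbt; anything
else is "unclassified" rather than an error, since non-study inputs may
lack NDH systems entirely. The classifier consumes only
`system_present()` outputs, never raw symbols.

The γ-CA-like domain check of ccmM aligns the N-terminal domain window of
a query to an active reference and requires (i) the configured
conserved-region positions to match the active reference by coarse
physicochemical residue class and (ii) the two disulfide cysteines to be
present. The verdict falls back to "inactive-like" when the match count
does not exceed what known-inactive references themselves achieve, and
"indeterminate" otherwise. **The position coordinates are
curator-supplied configuration** (`gamma_ca_config()`), not values from
any printed table, and should be revised against structural knowledge
when applying the check to real ccmM sequences. A strain lacking ccaA
whose ccmM looks active-like is flagged a "ccmM-compensation candidate".

## Locus organization

Two CCM genes join a locus when they are on the same contig, at most
5 kb apart and separated by at most 2 non-CCM genes. The thresholds are
declared, not inferred — the notion of "clustered together" is never
quantified in comparative-genomics prose — and both are exposed
(`max_gap_bp`, `max_intervening`); shrinking the gap can only split
clusters, never merge them. Strand is recorded but not required to
match, since operon figures show transcription direction without
asserting co-orientation. Labels: MCL (≥1 of ccmK1/ccmK2 plus ccmL,
ccmM, ccmN), rubisco (rbcL+rbcS+rbcX), satellite ccmP / ccmK3-K4 /
solitary ccmO, and Ci-uptake operons. `mcl_report()` additionally states
whether ccmO sits at an MCL boundary ("terminal") or lives as a
satellite — the feature that separates the *Thermosynechococcus* pattern
from the rest.

## Synthetic data: what it emulates, and what it does not

The generators produce every input class the pipeline consumes, each
deterministic given `(spec, seed)` and isolated from the caller's RNG:

* `mutate_protein()` substitutes exactly $\lceil(1 - t/100)\,n\rceil$
  positions, uniformly chosen, replacements uniform over the 19 other
  residues. The model is deliberately not score-matrix-biased; where a
  test depends on the achieved identity, it is measured by alignment
  rather than assumed.
* `generate_proteome()` plants mutated (optionally centrally sliced)
  reference copies among decoys whose lengths are uniform over
  [0.5, 1.5]× the mean reference length — wide enough to exercise the
  coverage filter.
* `generate_genome_pair()` applies i.i.d. substitutions (rate ≤ 0.5) for
  ANI recovery tests; `generate_annotated_genome()` lays out planted loci
  with configurable intra-locus gaps, 15-20 kb inter-locus spacers and
  random filler sequence, and survives a GFF3/FASTA round trip exactly.

None of this emulates indels, rearrangements, codon structure, rate
heterogeneity, paralogous families or contamination. Passing the
recovery suites therefore shows that the *decision machinery* (filters,
reciprocity, clustering, labels) is correct under its stated model — not
that the thresholds are optimal for real, messier proteomes.

The published presence/identity matrices themselves ship as transcribed
TSV fixtures (`load_fixture()`), so the characterization stage runs with
no download. Where the source text and its tables disagree (the cmp
identity range is quoted as 59.5-75.8 in prose while the table contains
78.2; the ccmP range as 67.6-76.1 while the table contains 67.3), the
fixtures follow the tables, and summaries report the table-derived
ranges.

## Numerical and testing choices

Problem sizes used by the test batteries, chosen to exercise each
property while keeping the default suite fast: engine-vs-oracle on 10^4
random pairs of ≤ 8 residues over a 4-letter alphabet (plus 100 longer
pairs against Biostrings); planted-ortholog recovery over 5 reference
proteins × identities {40, 60, 80} % × seeds 1-20 with 20 decoys each
(observed: 100 % sensitivity, 0 decoy calls); ANI recovery at
substitution rates {0.02, 0.10} × seeds 1-10 on 10.2-kb genomes
(observed error ≈ 0.03 points, asserted < 1.5); locus-label recovery on
20 random 4-locus layouts; speciation normalization over the full
(pH × T × S) grid at 1e-12.

Known limitations: exact DP only (quadratic time — genome-scale ANI/AAI
on real assemblies wants the pluggable-aligner route); E-values use raw
lengths, so they are conservative for short sequences; the γ-CA position
set is a configurable placeholder pending curation; fragment ANI here is
one member of the ANI-method family and can differ by a few tenths of a
point from other calculators on the same pair.
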