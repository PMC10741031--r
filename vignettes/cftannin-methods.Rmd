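---
title: "Methods: tannin annotation and spectrum-effect chemometrics in cftannin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tannin annotation and spectrum-effect chemometrics in cftannin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cftannin)
```

# Scope

`cftannin` re-implements, as a tested pipeline, an integrative strategy for
profiling the phenolcarboxylic and hydrolyzable-tannin constituents of
Chebulae Fructus (CF, the dried ripe fruit of *Terminalia chebula*) from
negative-mode LC-MS/MS data, together with the fingerprint chemometrics and
spectrum-antioxidant correlation used to nominate its antioxidant markers.
The package operates on three kinds of input: the packaged in-house compound
library (122 records with retention times, ion formulas, observed m/z, CCS
values and MS/MS fragment lists), tandem mass spectra in MGF, and per-batch
common-peak area plus antioxidant activity tables. Because no raw
instrument or plate-reader data are publicly deposited for this system, a
seeded synthetic-data module generates study-shaped datasets with known
ground truth; every claim the package makes about recovery rates is a claim
about that synthetic design, computed by the test suite and the acceptance
script.

# Mass arithmetic

Monoisotopic masses are summed from most-abundant-isotope atomic masses
(IUPAC values, hard-coded to >= 8 decimals for C, H, N, O, S). Two
conventions matter:

* **Ion formulas are stored as ions.** The library's formula column is the
  formula of the deprotonated/adducted species itself (e.g. `C7H5O5` for the
  gallate anion), so the theoretical m/z is simply its monoisotopic mass
  divided by the charge.
* **No electron-mass correction.** The theoretical m/z of an anion is the
  plain monoisotopic mass of the ion formula. This is the convention that
  reproduces the library's tabulated mass errors (gallic acid at +4.7 ppm);
  adding an electron mass (~0.00055 Da, ~3 ppm at m/z 169) would not.

Four ion species cover everything in the library: `[M-H]-`, `[2M-H]-`,
`[M-2H]2-` and the formate adduct `[M+HCOOH-H]-`. `expected_species_mz()`
converts an observed m/z between species by recovering the neutral mass and
reapplying the target species; homolog mass differences are annotated
against a small catalogue of biosynthetic deltas (methylation +14.0157,
dehydration -18.0106, decarboxylation -43.9898, ketene -42.0106, galloyl
residue +152.0110, gallic acid +170.0215, hexose residue +162.0528, each up
to multiplicity 5, matched at 0.01 Da).

Four library rows cannot be reproduced from their own printed values: two
print an ion formula one oxygen away from their observed mass, and two
print a ppm error inconsistent with their own observed m/z at any formula.
The library is deliberately left as printed -- it is a transcription, not a
curation -- and the affected record ids are asserted as known
inconsistencies in the test suite.

# Diagnostic classification

Hydrolyzable tannins hydrolyze along their ester bonds, so their MS/MS
spectra are dominated by a small set of acyl-unit ions. The classifier is a
priority-ordered rule set over those ions (all tolerances 0.01 Da, matching
the networking fragment tolerance):

1. **Chebuloyl chemistry implies a chebulic ellagitannin.** The chebuloyl
   ion at m/z 337.0201, its dehydrated 319.0090, and -- because the
   methylated derivative series is prominent in this matrix -- the methyl
   and dimethyl chebulate ions at 351.0357/365.0514; or the
   dehydration/decarboxylation cascade ions 293.0303/275.0200 together with
   the 205.0506 companion; or, for chebulic-acid polyol esters, two or more
   of the ester-family ions {205.0506, 193.0141, 163.0398, 133.0656,
   249.0401} at precursors >= 450.
2. **HHDP chemistry implies an ellagitannin.** The ellagic anion 300.9990,
   flavogallonic 450.9940 or HHDP-glucose 481.0663.
3. **Galloyl + glucose chemistry implies a gallotannin.** Galloyl ions
   (169.0137 and/or 125.0243) with galloylglucose core ions
   {313.0565, 271.0459, 211.0243} or a neutral loss of a galloyl residue,
   gallic acid, ketene or a hexosyl residue from the precursor.
4. **Otherwise, free phenolcarboxylic acids.** Galloyl ions with the
   shikimate ion 93.0344 (galloylshikimic series); the ellagic-core ion
   145.0294 (urolithin/brevifolin-type); the pyrogallol radical pair
   124.0166/78.0113; galloyl ions alone below m/z 550; or chebulic-family
   ions below m/z 450 (free chebulic acid and its methyl esters).

The priorities encode class nesting: a chebulic ellagitannin such as
chebulagic acid shows chebuloyl, HHDP *and* galloyl ions and must resolve
to the most specific class. The 550/450 precursor boundaries separating
free acids from tannins are heuristics chosen to reproduce the library's
own partition; they are documented, configurable and exported in the JSON
rule schema. By construction the chebulic class can only arise from a
chebuloyl-family rule (soundness), which the suite verifies by fuzzing.

Classification accuracy on the library's printed fragment lists is reported,
not forced: some printed lists simply omit their class's canonical marker
(chebulanin's list, for instance, contains 275.0196 but no chebuloyl ion),
and a handful of free acids (digallic acid, ellagic acid, flavogallonic
acid, terminalin) genuinely carry tannin-type marker ions. The acceptance
threshold is >= 80 % exact-class recovery over the 106 phenolcarboxylic/
tannic records; the acceptance script prints the measured rate.

# Molecular networking

`modified_cosine()` implements the classic networking similarity: peaks
pair directly or after shifting by the precursor mass difference,
intensities are square-root transformed and L2-normalised, and a one-to-one
pairing maximising the summed intensity products is chosen. Production
pairing is greedy in descending product order; for small candidate sets
(<= 8 pairs) an exact branch-and-bound optimum is used, and the same
exhaustive computation serves as the independent oracle in the tests.

`build_network()` follows the classic conventions: fragment and precursor
tolerances 0.01 Da, minimum cosine 0.7, minimum 6 matched peaks, a mutual
top-10 edge rule, and components capped at 100 nodes by pruning weakest
edges. Degree-zero nodes are flagged orphans and excluded from component
numbering. Components inherit a class when at least half of their annotated
nodes agree (`enhance_component_classes()`), and unannotated members
receive it as an explicitly *propagated*, never asserted, label. The
original 430-node network of the source study is not reproducible (its raw
data are not deposited); networking is validated on constructed spectrum
families with known separation and on spectra synthesised from library
fragment lists.

# Evidence integration and CCS

Per feature, the pipeline merges: library hits (precursor search at 10 ppm,
ranked by shared fragments, then precursor deviation, then record id),
diagnostic class, network-propagated class, homolog links against library
precursors, and collision cross-section agreement. Precedence is fixed:
standard-confirmed hit > hit consistent with the diagnostic class >
diagnostic class (optionally homolog-supported) > bare library hit >
network class > homolog lineage; disagreement between retained streams sets
a conflict flag rather than discarding evidence.

CCS prediction for these compounds is only trustworthy for small
glycosides, so measured-vs-predicted comparison (default tolerance 3 %)
*demotes* a flagged candidate instead of deleting it, and the demotion is
subordinate to fragment and precursor evidence -- it acts as the final
tie-break among otherwise indistinguishable isomer candidates. Ranking
positional isomers whose printed records are literally identical (same
observed mass, same fragment list) is ill-posed; such twins resolve to the
lower record id and account for the few percent of synthetic spectra that
map to an isomeric record rather than their source.

# Fingerprint chemometrics

Common peaks are aligned by single-linkage clustering of retention times
cut at 0.1 min; a cluster present in every batch is a common peak.
Similarity against the mean (default), median or a named batch fingerprint
is the congruence (cosine) coefficient, as used by the standard
pharmacopoeia fingerprint software. All multivariate steps run on
unit-variance autoscaled areas -- the usual default when the source of
variation spans compounds of very different absolute abundance.

* **HCA**: Ward linkage (`ward.D2`) on Euclidean distances by default;
  average/complete linkage and correlation distance are available.
* **PCA**: `prcomp` with a deterministic sign convention (the largest
  loading of each component is positive); explained fractions are relative
  to total variance so they sum to 1 at full rank.
* **OPLS-DA**: hand-written NIPALS with orthogonal signal correction
  (no installed package provides O-PLS with VIP): `n_orthogonal` components
  (default 1) are removed before a single predictive component is fitted.
  `R2X`/`R2Y` are fitted variance fractions; `Q2` uses 7-fold
  cross-validation over contiguous batch blocks, refitting the whole model
  per fold. With zero orthogonal components the model is exactly
  one-component PLS-DA, which the suite checks against an independent PLS
  oracle. VIP uses the standard weighted-loadings formula over all
  components, so the squared scores average to one and `VIP > 1` marks
  above-average discriminants.

# Spectrum-effect correlation

Antioxidant activity enters as a DPPH IC50 (lower = stronger) and
ABTS/FRAP total antioxidant capacities (higher = stronger). Pearson
correlation flags antioxidant-consistent peaks at the published thresholds:
r < -0.5 against IC50 and r > +0.5 against both capacities ("dual"
flags). Grey relational analysis uses Deng's coefficient with resolution
rho = 0.5 and min-max normalisation by default (mean normalisation is
available; the choice changes the degrees, and nothing in the published
account pins it down, so both are exposed). The reference sequence is
1/IC50, making "better antioxidant" monotone increasing to match the
capacity assays. IC50 itself is computed from dose-response series by
log-linear interpolation at the first 50 % crossing -- assumption-light and
exactly testable; a four-parameter logistic is left as an extension point.
UPLC-DPPH scoring is the mean percent peak-area decrease across replicate
injections, negative means flagged as within-noise increases. The consensus
ranks peaks by how many methods select them (dual Pearson flags, GRA degree
>= 0.7, DPPH decrease above the 70th percentile), ties broken by DPPH
decrease.

# The synthetic design

`synthetic_design()` encodes the emulated study: 18 batches in three origin
groups (5 + 7 + 6; groups I-II whole fruits, group III fruit flesh) over
the 23 common peaks, log-normal multiplicative noise with a 15 % CV (a
realistic between-batch figure for integrated UPLC areas of a processed
botanical), activities rescaled into the published ranges (IC50
2.993-10.110 ug/mL with group III weakest, ABTS up to 14.47 mmol/g, FRAP
up to 1.566 mmol/g), and DPPH susceptibilities seeded from the published
decreases (punicalagin B 43.16 % down to chebulic acid 4.19 %).

The planted structure separates two roles. Eight marker peaks discriminate
the groups: six hydrolyzable-tannin peaks (terflavin A, tri- and
penta-galloylglucoses, chebulagic, chebulinic acid) high in groups I-II and
depressed in the flesh-derived group III, with chebulagic acid additionally
dominant in group I and chebulinic acid in group II, plus two
degradation-prone constituents enriched in group III. The six
group-III-depressed tannins are also the planted antioxidants driving the
activity assays. Free ellagic and gallic acid are held at a flat absolute
level, so they become *relatively* dominant in group III exactly as
degradation arguments predict, without leaking into the discriminant set.
Four further peaks are depressed in group I so that each group has a
multi-peak identity, as real origin groups do -- with only two
distinguishing peaks against 21 noise dimensions, no clustering method
could separate groups I and II at this noise level, which is a property of
the geometry, not of the implementation.

Two deliberate simplifications follow from identifiability. First, the
planted antioxidant set is a subset of the planted marker set: with a
reciprocal IC50 link and these group sizes, a peak that correlates strongly
with activity but stays quiet in the II-vs-III discriminant is not
constructible, so the generator mirrors the published set *sizes* (8
markers, 6 dual-flagged antioxidants) rather than the exact published
memberships. Second, VIP recovery is asserted as "the planted eight are the
top eight, all above 1": with 13 samples in the contrast, a null peak's
sample correlation exceeds the VIP-1 boundary a few percent of the time, so
the exact-set reading is unattainable by any design at realistic noise.

What the generator does not emulate: chromatographic drift and co-elution,
heteroscedastic and correlated peak noise, assay plate effects, matrix
suppression, and any real relationship between a compound's structure and
its activity weight. Passing recovery tests therefore demonstrate that the
statistical machinery recovers planted structure under honest noise -- not
that the published compound rankings are themselves correct.

# Numerical choices and degenerate inputs

Tolerances default to the acquisition-level values (0.01 Da fragments,
10 ppm precursors) and are arguments everywhere. Ties are broken
deterministically (record id, spectrum id, lowest index) so all outputs are
order-invariant. Degenerate cases are explicit: empty fragment queries,
all-zero fingerprints, constant peaks (dropped with a warning before
scaling), zero-variance GRA sequences under mean normalisation, never-
crossing dose-response curves (undefined IC50 with status), and spectra
with no pairable peaks (cosine 0). Grey relational coefficients handle the
all-identical case (max deviation 0) as degree 1. Synthetic generators are
pure functions of (design, seed); identical inputs give bit-identical
output files.

# Problem sizes

The suite and the acceptance script run everything at the study's own
scale: 122 library records, 18 x 23 peak tables, networks of up to ~130
synthesised spectra, and 50-100 seeded repetitions of the recovery
analyses. These sizes keep every analysis exact (no subsampling) while the
whole suite completes in well under a minute.

# Known limitations

* The classifier's free-acid/tannin precursor boundaries are heuristics;
  compounds such as digallic acid (a galloyl ester of gallic acid) are
  structurally on the boundary and classify as gallotannins.
* CCS-based isomer discrimination inherits the quality of the predicted
  values, which for larger tannins is poor; the package demotes rather than
  filters for exactly this reason.
* The similarity, PCA, OPLS-DA and GRA figures published for the real
  18-batch study depend on per-batch areas that were never deposited; the
  package can emulate their ranges but cannot reproduce their values, and
  nothing in the test suite pretends otherwise.
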