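---
title: "Methods: how citmap models citrullination-altered antigen processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how citmap models citrullination-altered antigen processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citmap)
```

## The scientific question

Peptidylarginine deiminases (PADs) convert arginine residues of
self-proteins into citrulline, removing a positive charge.  In rheumatoid
arthritis this modification marks the dominant autoantigens.  Beyond
creating modified epitopes directly, citrullination can change *which*
peptides lysosomal proteases produce from an antigen at all — by altering
cleavage-site susceptibility next to the modified residue (proximal
effects) and by destabilising protein structure far from it (distal
effects).  `citmap` implements the computational side of an in vitro
proteolytic-mapping experiment that measures this: paired native and
citrullinated digests of the same antigen are quantified by label-free
mass spectrometry (LFQ), and the package turns the two peptide repertoires
into maps of created and destroyed regions, candidate cleavage sites,
bootstrap tests of citrulline association, distance-to-citrulline
analyses, an overall antigen processing change score, and a classification
of the MHC class II binding-core repertoire.

## Pipeline model, stage by stage

**Citrullination sites.**  For every arginine, the evidence is the LFQ
abundance of all peptides spanning it (`total_abundance`) and the share of
that abundance carried by citrulline-annotated peptides
(`cit_abundance`); their ratio is the citrullination fraction.  A residue
is called citrullinated when fraction >= 10% *and* citrullinated abundance
>= 1e6 — the dual threshold removes trace deamidation signal seen even in
native samples.  `sweep_thresholds()` reports kept/excluded counts over a
threshold grid so the operating point can be inspected;
`merge_site_evidence()` takes the union of residues passing in either of
two mapping experiments (e.g. a tryptic site-mapping digest and the
processing digest itself).  Exclusion and preservation percentages can be
computed per antigen or pooled; the pipeline reports pooled values because
the thresholds are global, but nothing depends on that choice.

**Enrichment profile.**  Per residue, the sums of abundances of all
covering peptides (replicates pooled) in the two conditions form
`log2(cit/native)`.  Where only one condition covers a residue the ratio
is undefined; we store a capped sentinel (`+10`/`-10`, configurable) so
fully created or destroyed stretches remain visible in the profile and in
region calling.  Residues covered in neither condition are masked (`NA`).
Pooling replicates before the ratio (rather than averaging) is scale-free:
the ratio cancels the replicate count.

**Regions.**  Created regions are maximal runs of contiguous residues
with `log2(enrichment) >= 1`, destroyed regions runs `<= -1` — a twofold
change.  Masked residues break runs.  The boundary is inclusive.

**Differential peptides.**  Each peptide species (identified by its span
and modification state, with the native-arginine and citrulline forms of
one span paired as a single measurement) is tested with a paired
two-sided Student's t-test across replicates; p-values are adjusted by
the Benjamini–Krieger–Yekutieli two-stage step-up procedure, implemented
from the published definition and verified in the test suite against an
independent reference implementation to 1e-10.  Significance requires
q <= 0.05 *and* a twofold gate on the mean fold change.  A significant
peptide absent in exactly one condition is classed created or destroyed;
otherwise enriched or reduced.  Tests run on raw intensities by default
(a `log_transform` flag enables log2(x+1)); a peptide with zero
within-pair variance and equal means carries no information and is pinned
at q = 1.

**Change score.**  The percentage of all identified peptides
significantly changed in either direction.  The companion quantity
`fraction_sequence_changed()` is the span union of significant peptides
over the covered residues; the full-length denominator is available via
an argument since either convention is defensible.

**Cleavage sites.**  Exopeptidase trimming blurs peptide termini, so cut
sites are not read off peptide ends.  Instead the discrete derivative of
the enrichment profile marks bonds where differential abundance steps:
`d[i] = log2E[i+1] - log2E[i]`.  Bonds are reported when `|d|` exceeds
log2(1.3) and is a strict local maximum of `|d|` among unmasked
neighbours; a plateau of equal values is reported once, at its leftmost
bond (the minimum-separation parameter defaults to 1, i.e. off).  A site
is *novel* when the flank with the larger `|log2E|` is enriched, *masked*
when it is depleted; ties at zero are uninformative and excluded with a
warning.  This dominant-flank rule is the package's operationalisation of
"relative abundance on either side" and is deliberately isolated in
`classify_cut_site()` so alternatives can be swapped.

**Citrulline association at cut sites.**  Windows follow the
Schechter–Berger convention: for the bond between residues i and i+1,
P1 = i, P1' = i+1; the "P2..P2' 4-mer" is residues i-1..i+2, truncated at
the protein termini.  A citrulline shared by two overlapping windows
counts once per window.  The null shuffles the observed number of
citrullines uniformly, without replacement, onto residues with adequate
MS coverage (abundance >= 1e6 in either condition), 1000 iterations; the
expected count is the null mean and the empirical p-value the fraction
of iterations reaching the observed count, reported as 0 (i.e.
< 1/iterations) when none does — no +1 smoothing.  The position-wise test
repeats this per offset P4..P4'.  Cut sites can be pooled across antigens
(each antigen shuffling within its own eligible set) or analysed per
antigen; the pipeline reports both.

**Distance to citrulline.**  Linear distance is measured from the region
*endpoints* to the nearest citrulline (0 if the region contains one); the
3D distance is the minimum Calpha–Calpha Euclidean distance over *all*
region residues.  The asymmetry is intentional and matches the two
measurement conventions.  The three bootstrap nulls use three different
eligible sets — all residues (linear), structure-covered residues (3D),
high-coverage residues (cut sites) — because each null answers a
different question about where a citrulline could have been observed.
Expectations are per region (2000 iterations).  Negative
actual-minus-expected values are citrulline-proximal, positive distal;
`summarize_actual_minus_expected()` adds a Shapiro–Wilk normality check
via `stats::shapiro.test`.

**Binding cores.**  Citrulline is modelled as glutamine in sequence
space (same terminal amide, same neutral charge).  Predictions for the
five RA-associated shared-epitope alleles (DRB1\*01:01, \*04:01, \*04:04,
\*04:05, \*10:01) are grouped by 9-mer core; a core is retained when its
minimum affinity over those alleles is strictly below 500 nM.  Core
identity is the 9-mer sequence in Q-substituted space, pooled across
peptides and registers; per-allele analysis is available.  Abundance is
the sum over peptides containing the core as a substring, matched in the
condition-appropriate space so a citrulline-containing core matches only
citrulline-carrying peptides and vice versa.  Classification uses a 50%
margin (created / enriched / unchanged / reduced / destroyed, with
created/destroyed reserved for one-sided presence), and citrullines at
core offsets 1, 4, 6, 9 are anchor contacts, elsewhere TCR contacts.
Created-versus-destroyed affinity distributions are compared with a
two-sided Mann–Whitney U test (`stats::wilcox.test`, exact for small
tie-free samples).

## The synthetic digest generator

The generator is first-class, tested code: it emulates the paired
experiment with known ground truth so every stage has a no-download test
bed.

*Cleavage.*  Each peptide bond is cleavage-susceptible with probability
`baseline_cleavage` times the product of positional multipliers for
citrullines at P4..P4' offsets (citrullinated condition only; defaults
P1 = 5, P2' = 3).  One uniform draw per bond, shared between conditions,
is compared against the per-condition rate: susceptibility is a property
of the sequence, the citrullinated cut set nests the native one, and
equal rates give identical cut patterns.  Susceptible bonds are cleaved
in every replicate — protease specificity, not replicate chance, decides
where cuts fall; replicate-to-replicate variation enters through
abundance noise, as in real LFQ data.

*Products.*  Partial digestion yields a ladder: every span between cut
bonds with up to `max_missed_cleavages = 2` internal cuts becomes a
product, attenuated by `missed_cleavage_penalty = 0.3` per missed
cleavage.  Products outside the observable length window `[5, 35]` are
discarded.  Without the ladder, short (<5) and long (>35) unobservable
fragments punch coverage holes that no real repertoire shows.

*Abundance.*  `abundance_scale (1e7) x boundary-rate ratio x
accessibility multiplier x LogNormal(0, sigma = 0.3)`.  The boundary-rate
ratio — the cleavage rate of the product's N-terminal boundary bond over
baseline — encodes first-order digestion kinetics: product downstream of
a faster cut accumulates proportionally.  This is what places a step
change in per-residue abundance at every novel cut site, the signal the
derivative stage detects.  Accessibility regions multiply every
*overlapping* product's abundance in the named condition, emulating
structural opening or occlusion acting at a distance from any
citrulline.  Noise is drawn per (seed, replicate, condition):
measurement noise is independent across the paired samples, while the
systematic difference between conditions comes only from the multipliers.

*Pairing.*  `simulate_protmap()` merges the two condition tables by
span: the citrulline-carrying species and its unmodified counterpart are
one measurement, so the paired test measures the processing change, not
the modification's mass shift.

*Defaults as study conditions.*  Protein length 500 and arginine
frequency 9% mirror the autoantigens this assay targets (roughly 350–870
residues, 7–11% arginine — above the vertebrate average);
citrullination rate 0.5 per arginine matches the observed conversion
range; baseline cleavage 0.10 gives mean products of ~10 residues,
typical of MS-observed lysosomal digest peptides, and ~94% residue
coverage.  At sparser cleavage (e.g. 0.07) the digest leaves several
unobservable >35-residue stretches per protein, an artefact real
profiles do not show, which intermittently hides planted effects from
the region caller; the default was set to avoid that artefact, not to
weaken any test.

*What the generator does not emulate.*  No m/z or spectra, no
identification error, no ionisation bias, no shared-peptide ambiguity
across proteins, no partial site occupancy (citrullination is
all-or-nothing per site), and replicate cut patterns are fully
reproducible rather than stochastic.  Passing the recovery tests
therefore shows the statistics recover planted effects under honest
noise and coverage conditions — not that the pipeline is robust to
search-engine artefacts upstream.

## Numerical choices

- log2 sentinels are capped at ±10 and participate in region calling and
  derivatives; masked bonds (adjacent to uncovered residues) cannot
  become extrema, preventing spurious cut sites at coverage boundaries.
- Empirical bootstrap p-values use the plain fraction, reported as 0 with
  the printed annotation `< 1/iterations` when no iteration reaches the
  observed value.
- Ambiguous peptide placements take the first match and set a flag.
- Windows truncated at protein termini are kept (truncated), not dropped.
- All randomness flows from one master seed through `mix_seed()`, a
  deterministic integer mixer kept below 2^31; any stage can be re-run in
  isolation and identical configs reproduce byte-identical reports.
- Problem sizes in the test suite — 500-residue proteins, 4 replicates,
  20 seeds for recovery rates, 1000/2000 bootstrap iterations — are the
  scales at which the assay's own analyses run, and keep the whole suite
  in seconds.

## Known limitations

- The dominant-flank classification of cut sites is a reconstruction of
  an informally described rule; alternative strategies (e.g. both-flank
  mean) can be substituted in `classify_cut_site()` but are not
  implemented.
- The binding-core stage consumes prediction tables; it does not run a
  binding predictor, and the bundled toy affinity generator is a seeded
  hash with no biological content, for tests only.
- Structural comparison scalars (RMSD, TM-score) are inputs; the package
  does not align structures.
- The t-test on raw LFQ intensities is the reproduction default; for
  strongly skewed data the `log_transform` flag is more appropriate.
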