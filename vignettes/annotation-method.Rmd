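---
title: "Propagating metabolite annotations across multilayer networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating metabolite annotations across multilayer networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Untargeted LC-MS/MS metabolomics detects thousands of features — (m/z,
retention time) peaks with per-sample intensities — but spectral libraries
cover only a small fraction of real metabolites, and a large share of peaks
are not independent metabolites at all but alternative ion forms (isotopes,
adducts, neutral losses, in-source fragments) of something already annotated.
`metanno` addresses both gaps at once:

1. **Reach beyond the library.** Metabolites that differ by one enzymatic or
   chemical transformation tend to have similar structures, similar
   fragmentation, and similar retention. A reaction network expanded from
   known metabolites into *predicted unknowns* therefore lets a confident
   library match ("seed") vouch for its reaction-paired neighbors.
2. **Deconvolve ion redundancy.** Grouping co-eluting features around each
   annotated base peak and classifying them as isotopes/adducts/neutral
   losses/ISF both removes false metabolite annotations (a peak that is
   really an in-source fragment) and explains a multiple of the annotated
   peaks.

The pipeline runs in three layers: (1) the metabolic reaction network,
(2) the knowledge-guided MS/MS similarity network built by recursive
annotation propagation, and (3) the global peak correlation network.

## Layer 1: reaction-network expansion

Known metabolites (the standard library, or any curated node table) are
expanded by a declarative biotransformation rule table: each rule carries a
signed elemental-formula delta (e.g. `-HPO3` for dephosphorylation, `+SO3`
for sulfation, `+C6H8O6` for glucuronidation) whose monoisotopic mass delta
is recomputed from atomic masses and checked to 1e-4 Da. Products are
generated for one or two steps; a product is dropped when any element count
would go negative, when it contains an element outside CHONPS, or when it
equals the substrate (e.g. `+H2` then `-H2`).

When both structures of a substrate/product pair are available, the pair is
retained only if its Tanimoto fingerprint similarity is **strictly greater
than 0.7** (atom-pair 1024-bit fingerprints via ChemmineR). Formula-only
rules produce no product structure; such pairs pass only in an explicit
*structureless* mode, recorded in the edge provenance — the synthetic
fixtures use this mode. Stereoisomers are merged on the first 14 characters
of the InChIKey (the 2D-skeleton block): the lexicographically smallest node
id survives, `known` origin beats `predicted`, and edges are rewired.
Predicted metabolites left without any surviving edge are discarded.
Two-step products are connected both to the substrate (a 2-step edge) and to
the intermediate when it survives.

## Layer 2: seed annotation and propagation

**Seeds.** A feature becomes a seed when it matches a library record on
(i) MS1 m/z of the protonated/deprotonated ion within **15 ppm**, and
(ii) MS/MS similarity **>= 0.8**; with a library RT within **20 s** it is
level 1, without a library RT level 2. All tolerances are inclusive; when a
record has several spectra (collision energies) the best score counts. A
feature without MS2 can never seed.

**MS/MS similarity** is the square-root-weighted dot product: intensities
are square-root transformed and the score is the cosine of the transformed
intensity vectors aligned by a greedy, closest-ppm-first, one-to-one
fragment pairing (25 ppm with a 0.004 Th floor). Spectra are first cleaned:
fragments above precursor + 0.5 Th removed, a 0.1% relative-intensity floor
applied, base peak renormalized to 100. The score is symmetric and invariant
to rescaling either spectrum.

**Retention-time model.** A random forest (ranger) maps molecular
descriptors to seed RTs, with 10-fold cross-validated selection of `mtry`
and `min.node.size`. Descriptor sets default to 8 named descriptors for
HILIC and 5 for reversed phase; the identities are package defaults and any
provider that fills those columns (an RDKit/rcdk calculator or a precomputed
TSV cache keyed by InChIKey block) can substitute. Below 20 usable seeds no
model is trained; the RT constraint is then disabled with an explicit
message rather than silently fit.

**Propagation.** Each seed's reaction-network neighbors (constraint 1) are
searched in the feature table over the polarity's adduct list — 11 positive
/ 8 negative adducts by default — at <= 15 ppm (constraint 2), RT-filtered by
`|observed - predicted| / predicted <= 30%` (constraint 3; the predicted RT
is the denominator), and accepted when the candidate's spectrum scores
**> 0.5** against the seed's experimental spectrum used as a surrogate
reference, **or** shares **>= 5** matched fragments with it (constraint 4;
"more than 4" is implemented as >= 5). Newly annotated features join the
seed pool and the process repeats to a fixed point; a
(feature, candidate, adduct) triple is annotated at most once (lowest round
wins), which guarantees termination even on cyclic networks. Seeds are
processed in sorted order so reruns are bit-identical. Candidates that are
known network metabolites get level 3.1, predicted unknowns level 3.2.

## Layer 3: peak-correlation deconvolution

For every annotation hypothesis (base feature + adduct), co-eluting features
within **±3 s** (inclusive) form a peak group, screened as:

* **Isotopes** at `mz + 1.003355 × N` (N = 1..3) within **25 ppm**, retained
  when the relative-intensity deviation `|Int_E − Int_T| / Int_T × 100`
  is at most **500%**. `Int_T` uses a binomial ¹³C model on the candidate
  formula's carbon count, or an m/z-scaled carbon estimate (m/z / 17) when
  no formula is known — the wide tolerance makes the result insensitive to
  this choice.
* **Adducts and neutral losses** at the theoretical m/z implied by the
  base's neutral-mass hypothesis, within 25 ppm, retained when the
  across-sample Pearson correlation with the base is **> 0.3** (with fewer
  than 4 samples the correlation cannot be estimated; the filter is skipped
  with a notice).
* **In-source fragments**: the five most intense MS2 fragments of the base
  matched against group members' MS1 m/z at 25 ppm.
* Isotopes of each retained ion, recognized the same way.

**Optimization** proceeds in three steps. Step 1 applies an editable
empirical-rule table: a multimer base (`[2M+...]`) without in-group monomer
evidence loses its subnetwork; a subnetwork must contain its base; an N = 1
isotope more intense than its parent, or a neutral-loss ion more than 10×
the base intensity, loses that member (with cascade to its dependents).
Step 2 resolves a base peak carrying two adduct hypotheses by keeping the
larger subnetwork. Step 3 consolidates globally so that **every feature
ends with at most one role**: subnetworks repeatedly claim their unassigned
members in decreasing order of *current* size (ties: higher base intensity,
then id), and a subnetwork whose base has been claimed as an ion form of a
larger one is removed together with its metabolite annotations — this is
what demotes a fragment-like "metabolite" to an ISF of its true precursor.

Step 3 is exact, not heuristic: the intended objective is the
lexicographically maximal sequence of retained-subnetwork
(size, base intensity, id) tuples — preferring to keep the largest
subnetwork fully intact, then the next, and so on. (A maximize-total-peaks
objective would instead keep a doomed base alive by stripping one member
from the larger subnetwork, which is not the deconvolution behavior wanted
here.) Because the first tuple of any consistent outcome can never exceed
the current-largest subnetwork kept intact, the optimum always retains that
subnetwork with all its remaining members; recursing on what is left shows
the iterative greedy realizes the optimum. The test suite checks this
against an independent brute-force enumeration over random conflict fixtures.

Removed annotations are reported with their step and reason; the removal
then filters the candidate list before scoring.

## Scoring and reporting

Each surviving candidate gets an identification score
`S_iden = 0.25·s_mz + 0.25·s_rt + 0.5·s_msms` with linear
tolerance-normalized sub-scores (`s_mz = max(0, 1 − |ppm|/15)`; `s_rt`
normalized by 20 s for seeds and by the 30% relative window for propagated
candidates; `s_msms` the square-root dot product; a missing component scores
0 and is flagged), a confidence score of 3 / 2 / 1 for levels 1 / 2 / 3.x,
and `S_total = S_iden + S_confidence`. Per feature, only candidates at the
best available confidence tier are reported — dominance is enforced by this
filter, not by the score — ranked by `S_total` (ties: higher `s_msms`, then
candidate id) and truncated at 10. Evaluation counts a feature correct when
any top-3 candidate shares the truth's InChIKey first block; ion-form roles
are correct on role class, plus the isotope index for isotopes and the label
for adducts.

## The synthetic study

The generator plants a complete, truth-labeled study so every stage is
testable offline. Defaults (the package's standard simulated conditions):
100 known seeds, each spawning one predicted unknown through a feasible
default rule (200 metabolites); per metabolite a protonated base feature
with its planted 10-fragment spectrum, extra adducts at rates 0.4/0.3/0.3
(Na/NH4/water loss), isotope peaks at rates 0.9/0.4/0.1 for N = 1..3 with
per-sample intensities at exactly the theoretical ratio, and an ISF feature
mirroring the most intense fragment at rate 0.3; 10 samples; reaction pairs
share 60% of their fragments (encoding the premise that reaction-paired
metabolites fragment similarly); 30% decoy features with random m/z/RT and
(half of them) random spectra. Noise: 5 ppm Gaussian m/z jitter, 2 s
metabolite-level RT jitter, 20% multiplicative intensity noise.

Two structural choices deserve emphasis:

* **RT jitter is shared within a metabolite.** Co-eluting ion forms come
  from one chromatographic peak, so the 2 s retention deviation applies at
  the metabolite level, with only a 0.3 s within-group term per feature. An
  i.i.d. 2 s per-feature jitter would make true ion forms routinely violate
  the ±3 s co-elution premise, which real data do not.
* **Correlation structure.** Per-sample intensities share a metabolite-level
  lognormal factor (sdlog 0.5) times feature-level noise (sdlog = CV), so
  same-metabolite ions correlate well above the 0.3 Pearson threshold while
  decoy pairs hover near zero.

Retention times follow `rt = 120 + 30·d1 + 8·d2 + 4·d3` on descriptors
uniform on [0, 10]; predicted unknowns inherit a perturbed copy of the
parent's descriptors (structural similarity implies similar RT). Library
InChIKey blocks are synthetic (deterministic letter codes) and predicted
nodes receive their own, so identity evaluation is exact.

What the generator does **not** emulate: isotope fine structure,
chromatographic peak shapes, ion suppression, charge states above 1,
instrument-specific adduct preferences, and real fragmentation chemistry
(spectra are fragment sets over a continuous m/z alphabet). Passing tests
therefore demonstrate the correctness of the network logic, matching rules
and conflict resolution under the stated statistical structure — not
annotation accuracy on any real instrument run.

## Numerical choices and degenerate inputs

* Feature ids round m/z and RT with round-half-even (R's `round`);
  collisions get `_1`, `_2`, ... suffixes in input order.
* All stated tolerances are inclusive (`<=` / `>=`); the Tanimoto retention
  threshold and the propagation score threshold are strict (>), following
  their "larger than" phrasing.
* Fragment matching uses `max(25 ppm, 0.004 Th)` so low-m/z fragments keep a
  sane absolute window; one tolerance is used for all spectral comparisons
  and is configurable.
* Empty spectra after cleaning signal the caller (`NULL`), score 0, and can
  never seed or be annotated.
* Duplicate seed rows are deduplicated before RT training, making the model
  invariant to input repetition; fold assignment and forest growth are
  seeded from the pipeline seed.
* With fewer than 4 samples the Pearson filter is skipped (logged), since a
  correlation over 3 points is meaningless.
* Test problem sizes: unit fixtures use 3-30 metabolites; the end-to-end
  simulated study uses 200 metabolites (~750 planted features plus decoys),
  which exercises every code path in well under a minute per run.

## Known limitations

* Predicted unknowns from formula rules carry no structure, so the Tanimoto
  filter only bites when an external structure-aware rule engine supplies
  product SMILES through the same interface.
* The default descriptor lists are named placeholders for whatever
  descriptor provider is plugged in; the shipped fixtures supply descriptors
  via TSV cache.
* One fragment-match tolerance serves all spectral comparisons; instruments
  with very different MS1/MS2 accuracy may want them split.
* Annotation levels 3.1/3.2 share one confidence score, so the reporting
  filter (not `S_total`) is what separates them from level 1/2 candidates.
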