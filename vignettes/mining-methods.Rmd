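---
title: "Methods: mining coniine-pathway candidates from a de novo transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining coniine-pathway candidates from a de novo transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conmine)
```

`conmine` nominates transcript candidates for the uncharacterized enzymes of
the coniine biosynthesis pathway of poison hemlock — polyketide reductase
(PKR), l-alanine:5-keto-octanal aminotransferase (AAT), γ-coniceine
reductase (CR) and the SAM-dependent coniine *N*-methyltransferase (CSAM) —
starting from a de novo transcriptome assembly, its standard annotation
outputs, and an organ-by-replicate fragment-count matrix. This vignette
explains the models and conventions behind each stage, the parameters that
matter, and the choices made where the design was genuinely open.

## Coding regions and molecular weight

ORFs are maximal start-to-stop stretches on all six frames: within each
frame, the first ATG after the preceding stop opens the ORF and the next
in-frame stop closes it. ORFs running off the end of the transcript are
reported as incomplete. Coordinates are 0-based half-open on the forward
sequence, for both strands, so that strand symmetry is a pure coordinate
mirror. The size conventions used in candidate reporting are: the CDS length
in nucleotides *excludes* the stop codon, and the residue length is exactly
nt/3 — the convention under which every printed candidate row's bp and aa
columns are consistent.

Peptide molecular weight is the sum of standard *average* (not
monoisotopic) residue masses plus one water (18.01524 Da), reported in kDa —
the convention of protein-size reporting in the field. It is sequence-only:
no post-translational assumption enters, which matters when comparing
against an experimentally determined enzyme weight (the aminotransferase
cascade therefore uses a generous ±10 kDa window rather than a point
match).

Defaults: annotation-time ORF scans use `min_len_aa = 100`; the mining
stages rescan at `min_len_aa = 50` because genuine candidates can be as
short as ~130 aa and incomplete. When a transcript has several ORFs the
longest is its representative peptide (ties broken by start coordinate,
then strand); the others are retained and flagged.

## Annotation filtering, integration, decontamination

Three evidence streams feed one integrated record per transcript:

| stream | filter | bound |
|---|---|---|
| protein alignment hits | identity ≥ 80 %, query coverage ≥ 50 % | inclusive |
| PFAM domain hits | domain E-value < 10⁻²⁰ | strict |
| classifier predictions | PPV ≥ 0.5, then PPV ≥ 0.9 × max(PPV) per ORF | inclusive |

The asymmetry (inclusive vs strict) follows the wording of each rule as
stated for the original analysis. Coverage is alignment length over the
*query* protein length; the denominator is configurable because homology
searches are run in both orientations in practice. The per-ORF relative PPV
cutoff is computed over the predictions that survive the floor — the
alternative (pre-floor maximum) would make the two screens order-dependent;
post-floor keeps `screen_pannzer` idempotent.

GO terms, EC numbers and PFAM accessions are unioned per transcript; EC
numbers with all four fields determined are additionally flagged, since
only those can be linked to metabolic-network positions. A transcript is
"annotated" iff at least one stream contributed.

Decontamination removes a transcript iff it has at least one taxon-bearing
hit *and every* taxon-bearing hit resolves to Bacteria or Opisthokonta;
transcripts with no taxonomic evidence are kept (absence of evidence is not
treated as contamination). Kingdom resolution maps the first recognized
lineage token through {Bacteria; Opisthokonta ← Fungi, Metazoa, Animalia;
Viridiplantae}; unrecognized lineages count as no evidence. The operation
is a fixed point: applying it to its own output removes nothing.

## Expression: FPKM, TMM, presence, organ sets

FPKM = count / (length/10³ × library/10⁶), with the effective length taken
as the transcript length (no fragment-length correction — a documented
simplification; at desk scale the presence/absence structure, not the
point estimates, drives the analysis).

Between-sample scaling uses the trimmed mean of M-values exactly as
published: the reference sample is the one whose upper quartile of
library-scaled counts is closest to the mean upper quartile; per sample,
transcripts zero in either member of the pair are excluded; 30 % of
M-values and 5 % of A-values are trimmed two-sided (rank-based, ties
averaged); the pair factor is 2 to the precision-weighted trimmed mean of
M, with inverse asymptotic-variance weights. `tmm_factors()` returns
*effective size factors* — library size × TMM normalization factor,
rescaled to geometric mean 1 — so that two samples with identical
composition but different depth get factors proportional to their depths,
and dividing counts by the factor makes samples directly comparable. The
edgeR-convention normalization factors are kept as an attribute, and the
implementation reproduces `edgeR::calcNormFactors` to < 10⁻⁹ (a test
cross-checks this). The precision weighting is the published default; an
unweighted option exists, under which the factor of a sample scales
*exactly* with a rescaling of its counts (with weights this holds only
approximately, because the weights depend on absolute counts). The
TMM-adjusted expression layer is FPKM computed with effective library
sizes (geometric-mean library × size factor), keeping FPKM-like units.

Presence: a transcript is expressed in an organ iff its replicate-averaged
TMM-adjusted value exceeds 0 (strictly). No cutoff above zero is imposed by
default because the analysis this mirrors stated none; the threshold is a
parameter, and both the FPKM and TMM layers are exposed, since it is not
stated which layer the original organ counts used. Organ set summaries are
reported in both "exactly this combination" (exclusive) and "at least these
organs" (shared) forms; exclusive sizes partition the transcripts present
anywhere.

## Preranked enrichment

Each organ's ranked list is its expressed transcripts ordered by
replicate-averaged TMM-adjusted value, descending, with ties broken by
transcript id for determinism; unexpressed transcripts are excluded. The
enrichment score is the classic weighted running sum: hits advance by
|s|ʷ/Σ_hits|s|ʷ (default w = 1), misses retreat by 1/(N−N_H), and ES is the
signed maximum deviation. Sets smaller than 15 *after* intersection with
the ranked list are dropped — intersection-first is the only reading under
which the tested set size equals the size entering the statistic.

The null is a gene-label permutation (the only null available to preranked
input): set labels are redrawn uniformly at random, and

p = (1 + #{ |ES\*| ≥ |ES| }) / (n_perm + 1).

This is a two-sided test on the magnitude of the score. The package
deliberately does **not** condition the count on the sign of the observed
ES: by exchangeability of the observed and permuted sets the two-sided p is
exactly uniform under the null, so random sets are rejected at the nominal
level itself (~1 % at α = 0.01, floor 1/(n_perm+1)), whereas a
sign-conditioned count is uniform only within each sign class and rejects
random sets at about twice the nominal level. A calibration test (500
Monte-Carlo repetitions at n_perm = 500) checks the rejection rate stays
within one percentage point of 1 %. Only nominal p is reported; FDR
q-values are out of scope at the set counts involved.

## Enzyme cascades

Each enzyme is specified declaratively (`enzyme_seed_spec()`): a
protein-family seed set and/or bait sequences, required expression organs
(default flower + developing fruit, the organs where the pathway entry
enzyme is expressed), an optional inclusive molecular-weight window, a
cofactor requirement, and an EC filter. The shipped presets are:

* **cpks5** — bait homology; candidates are the Pareto-optimal hits in
  (percent identity, alignment length), i.e. the top-right corner of the
  identity–length scatter. Dominance is weak on both axes with strict
  improvement in at least one; removing any dominated hit provably leaves
  the selection unchanged.
* **pkr** — KR-domain seed (PF08659, from the bacterial koreenceine
  ketoreductase), flower+fruit expression.
* **aat** — aminotransferase families PF00155/PF00202/PF00266 (united with
  any homology-search hits via `search_union()`, which keeps per-search
  provenance), flower+fruit expression, inclusive 45–65 kDa window on the
  representative peptide, then a relevance filter with two admission
  routes: an alanine-aminotransferase EC whitelist (2.6.1.2, 2.6.1.4,
  2.6.1.12, 2.6.1.44) *or* class-III family membership (PF00202) — the
  encoded form of an otherwise manual curation step.
* **cr** — NAD(P)H-oxidoreductase families PF00106/PF08659/PF13561 (the
  koreenceine kecG/kecH domains), flower+fruit expression, cofactor label
  NADPH or NADPH/NADH (NADH-only excluded; cofactor labels are pipeline
  *inputs* from an external predictor or the synthetic truth — the module
  never predicts cofactors), EC prefix 1.3.1. One shared EC prefix is used
  for both cofactor groups, the natural reading when nothing distinguishes
  them.
* **csam** — SAM-dependent carboxyl methyltransferase family PF03492, then
  EC 2.1.1.49 (amine-*N*-methyltransferases).

Stages are evaluated as independent predicates and intersected, so the
final membership cannot depend on stage order (a property test permutes
the order); the audit trail and survivor counts use the canonical order
seed → expression → MW → cofactor → EC. Survivor counts are monotone
non-increasing by construction. Candidate rows whose representative
peptides are identical are merged into one row with slash-joined ids, the
convention used in candidate tables for indistinguishable isoforms.

An optional co-expression criterion (Pearson correlation with the entry
enzyme's organ profile above a cutoff) exists but is off by default:
correlation alone is a misleading selector — a transcript can correlate
highly with the entry enzyme yet have the wrong predicted function, and
the best-supported candidate may correlate poorly — so functional evidence
is preferred and correlation is opt-in.

## qPCR relative quantification

Per organ, ΔCt = mean Ct(GOI) − mean Ct(HKG); ΔΔCt subtracts the
calibrator organ's ΔCt (default leaf); fold = 2^−ΔΔCt, so the calibrator's
fold is exactly 1. The standard deviation of ΔΔCt is the quadrature sum of
the four per-(gene, organ) Ct standard deviations, and error bars are the
asymmetric band 2^−(ΔΔCt±σ). By default σ components pool technical ×
biological replicates per cell; a per-biological-replicate-mean scheme is
available (`pooling = "by_bio"`) since the pooling level is a reporting
choice, not a property of the formula. Amplification efficiency is fixed
at 2 (the 2^−ΔΔCt model); efficiency correction is out of scope. One
housekeeping gene is used per call; averaging over a housekeeping panel is
left to the caller.

## The synthetic study: what it does and does not emulate

`generate_study()` produces a self-contained study with known truth:

* five organs × two replicates (the study design), counts
  negative-binomial per (transcript, organ) with dispersion 0.3 and
  lognormal baselines, zero-inflated through random organ-presence
  patterns — the simplest model reproducing organ-exclusive expression
  sets;
* a contaminant fraction (default 50/1000) whose alignment hits carry
  exclusively bacterial or opisthokont lineages, root-biased in
  expression;
* per enzyme family, three planted candidates satisfying *every* criterion
  of their cascade — designed CDSs with in-window molecular weights for
  AAT, family PFAM domains at passing E-values, correct EC labels,
  cofactor labels for CR, guaranteed nonzero flower/fruit counts — and
  three near-miss decoys each violating exactly one criterion (a failing
  domain E-value, a missing fruit expression, an out-of-window weight at
  360 aa ≈ 40 kDa, an NADH-only label, or a wrong EC). Decoys are minimal:
  relaxing exactly the violated criterion admits them (a test relaxes the
  domain E-value bound and checks this);
* entry-enzyme homology hits with a constructed Pareto structure: planted
  candidates form the front, decoys and background hits are dominated.

Everything is drawn from a single seeded RNG, so outputs are byte-identical
across runs. Background transcripts never carry the reserved seed PFAMs,
making planted recovery well-defined with precision = recall = 1 as the
target property.

What it does *not* emulate: read-level sequencing (no reads, no assembler
artifacts, no isoform graphs), realistic codon usage or GC structure,
homology between background transcripts, correlated contaminant
communities, or organ counts at the scale of a real assembly
(10³ transcripts, not 10⁵). Passing tests therefore demonstrate the
*logic* of the filters and statistics — thresholds applied at the right
boundaries, set operations exact, recovery of a planted signal — not
performance on real assemblies, where annotation noise and isoform
redundancy dominate.

## Numerical choices and degenerate inputs

* Trim bounds use `rank()` with averaged ties; the A-statistic is computed
  as (log₂x + log₂y)/2 — algebraically equal alternatives differ in the
  last float bit and can flip near-tied ranks across the 5 % trim
  boundary.
* A pair of samples sharing no doubly-nonzero transcript is an error
  (there is no information to scale on); identical samples short-circuit
  to factor 1.
* Empty hit lists warn and return empty selections; empty gene-set
  collections after the size filter warn and return an empty result.
* `organ_presence` with threshold ∞ yields all-false, with a negative
  threshold all-true for transcripts with data.
* ORF scans reject characters outside {A, C, G, T, N}; codons containing N
  translate to X, and peptides containing X get `NA` molecular weight
  (they can never pass a weight window).
* The permutation p-value is bounded below by 1/(n_perm+1); a fixed seed
  reproduces results exactly.

## Problem sizes used by the test-suite

The default synthetic study is 1,000 transcripts (50 contaminants, 3
planted + 3 decoys per family) — the size at which planted recovery is
asserted. Oracle-equivalence tests use 250×5 count matrices, 1.5–2 kb
random sequences, 150–200-gene ranked lists, and 200×5 presence matrices;
the calibration test runs 500 Monte-Carlo repetitions at n_perm = 500 on a
~200-gene ranked list. These sizes were chosen so each property is checked
well inside a minute while remaining large enough that boundary effects
(trim fractions, set-size filters) are exercised.

## Known limitations

* Coverage uses a single denominator (query length); subject-coverage
  filtering would need subject lengths, which the hit tables do not carry.
* The TMM effective length equals transcript length; fragment-length
  corrected effective lengths would shift FPKM but not presence calls.
* EC matching is prefix/whitelist-based; no EC hierarchy expansion.
* The miner trusts its inputs: cofactor labels and annotations are taken
  as given, and candidates are nominations for in vitro testing, not
  functional assignments.
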