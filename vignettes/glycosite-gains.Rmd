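---
title: "Screening for N-glycosylation sequon gains in the human lineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for N-glycosylation sequon gains in the human lineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glygain)
```

## The question and the procedure

N-linked glycosylation decorates an asparagine only when it sits in the
sequon Asn-X-Ser/Thr, where X is any residue except proline.  A single
substitution that completes this motif can therefore add a whole glycan to a
protein — a small genetic change with a potentially large phenotypic effect.
`glygain` implements a comparative screen for such events along the human
lineage: given experimentally verified human N-glycosylation sites and
per-gene orthologous protein alignments across mammals, it asks, for each
site, whether the sequon is a recent acquisition and on which ancestral
branch it appeared.

The screen proceeds per annotated site:

1. **Evidence filter.**  Only sites whose feature description carries the
   N-linked (GlcNAc...) term and no non-experimental qualifier
   (*potential*, *by similarity*, *partial*, *probable*) are considered.
2. **State computation.**  The human Asn position is mapped to its
   alignment columns and every species is classified as `sequon`,
   `no_sequon` or `missing` at the homologous position.
3. **Ancestral-conservation filter.**  If more than 30% of the informative
   non-Euarchonta species carry the motif, the site is likely ancestral and
   is discarded rather than a lineage-specific gain.
4. **Curation filters.**  Paralogy suspicion (UniProt vs genome-derived
   human sequence differing at three or more residues), non-consensus
   annotations, absence of a chimpanzee row, and low species coverage each
   fail the record with a machine-readable reason code.
5. **Timing assignment.**  A passing gain is dated to the most inclusive
   clade of the nested human-lineage ladder
   (hum ⊂ hac ⊂ aga ⊂ gra ⊂ ape ⊂ cat ⊂ sim ⊂ pri ⊂ eua)
   whose sampled members all carry the sequon.

Every input site appears exactly once in the output with its full decision
trail; nothing is dropped silently.

## The species model

The roster is 62 mammals: humans plus 12 other Euarchonta species
(chimpanzees through treeshrews), 13 Glires, 25 Laurasiatheria,
6 Afrotheria, 1 Xenarthra, 3 Marsupialia and 1 Monotremata species.  It
ships as a plain-text config (`inst/extdata/mammals62.tsv`) mapping each
species to its innermost ladder clade or outgroup group, with UCSC
genome-assembly codes as aliases, so other taxonomies can be substituted.
Ladder nesting is machine-checked at load.  Only clade membership enters the
screen; no tree inference is performed and outgroup topology is irrelevant.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `ancestral_threshold` | 0.30 | discard when *more than* this fraction of informative outgroups carry the motif; exactly 0.30 is kept (the rule is strict) |
| `min_informative_species` | 20 | minimum species with determined state; operationalises the "only a small number of sequences aligned" discard, which has no published numeric value |
| `max_uniprot_mismatch` | 2 | mismatches tolerated between UniProt and genome-derived human sequences (Hamming over the shorter overlap plus the length difference); 3+ suggests paralogy |
| `require_chimpanzee` | TRUE | a dataset without a usable chimpanzee row cannot resolve the human branch |
| `max_row_gap_fraction` | 0.5 | rows gappier than this are removed as low-quality before state computation (not a record failure) |
| `mode` | `columns` | read states off the human motif columns; `species_local` instead takes the species residue at the Asn column plus its next two residues, which matters only when a species has an insertion inside the motif span |
| `timing_loss_tolerance` | 0 | fraction of a clade's informative members allowed to lack the motif when dating (secondary losses) |
| `timing_unsampled` | `skip` | see below |

The denominator of the 30% rule counts only informative (non-missing)
outgroup species: an undetermined row is no evidence for or against
ancestral presence, and coverage is policed separately.

## Decisions where the design was open

**Columns vs species-local motif reading.**  Both are defensible; they
coincide whenever no species has an insertion inside the motif span, which
is the overwhelmingly common case.  The default (`columns`) corresponds to
reading a printed alignment down its columns; the flag records the choice.

**Ambiguity in the motif.**  A gap or `X` at the Asn or Ser/Thr slot can
never certify a sequon and fails.  At the middle slot the default is also
conservative — `X` fails because "any residue except proline" cannot be
certified — with a permissive option.  Selenocysteine U and pyrrolysine O
map to `X` on input.  No constraint is placed on the residue after the
Ser/Thr: the motif definition used throughout is exactly N-X≠P-[ST].

**Dating with unsampled taxa** (`timing_unsampled`).  When every species
distinguishing a candidate clade from the next-inner clade is missing, the
data cannot place the gain on that clade's branch.  The literal
most-inclusive-consistent-clade rule (`"extend"`) would assign such a clade
vacuously; the default (`"skip"`) refuses and falls back to the innermost
clade with an actual supporting observation, which is how a curator reading
the alignment would date the gain.  The two differ only when a ladder step's
distinguishing taxa are entirely unsampled, where the truth is genuinely
unidentifiable; the skip rule is also the more accurate one in expectation
under realistic gain-frequency profiles, because inner clades harbour more
gains than their immediate parents in this dataset family.

**Branch-site null distribution.**  The branch-site comparison (model A vs
null model A) is tested against plain chi-square with df = 1, which is the
convention the published P values follow; the 50:50 mixture null
(point mass at 0 and chi-square(1)) is available via `mixture = TRUE` and
halves positive-statistic P values.

**Free-ratio degrees of freedom.**  An unrooted bifurcating tree of *n*
taxa has 2*n* − 3 branches, so free-ratio vs one-ratio has (2*n* − 3) − 1
degrees of freedom — 8 for the six-primate trees used in the worked
analyses.

**LRT clamping.**  A statistic negative within 1e-6 is an optimizer
artifact and is clamped to zero silently; a larger negative value clamps
with a warning.  P values come from `chi2_upper_tail()`, the regularized
upper incomplete gamma Q(df/2, x/2).

**Coordinates.**  All files and reports are 1-based (UniProt convention).
Alignment columns are also 1-based, matching R string semantics; the
mapping functions `ungapped_to_column()`/`column_to_ungapped()` are exact
inverses on residue positions.

## What the simulator emulates — and what it does not

`simulate_dataset()` evolves a uniformly random root protein down the clade
ladder: Poisson(rate × length) substitutions per branch with replacements
uniform over the 19 alternatives, a motif written at a chosen clade's
ancestor for each planted gain, optional independent outgroup gains (the
pattern real data show in, e.g., whales and ruminants), secondary losses at
chosen tips, uniformly missing taxa, and gap runs.  Planted motif triplets
are protected from substitution noise so the ground truth stays exact, and
gap runs avoid them for the same reason.  Defaults: sequence length 300
(60 for the single-site corpora, where only the window around the site
matters), branch rate 0.02 substitutions/site/branch — roughly 20%
human-to-outgroup divergence, typical of mammalian proteins.

The generator deliberately does **not** emulate: empirical amino-acid
exchangeabilities (uniform replacement keeps the oracle simple; the screen
tests motif presence, not evolutionary realism), insertions (alignment
columns equal sequence positions, so the two state-reading modes coincide),
rate variation across sites or lineages, codon-level evolution, or
alignment error.  Passing the recovery tests therefore shows the pipeline's
logic is correct under its stated model, not that real multiz alignments
are this clean — on real data, alignment error and paralogy are handled
only insofar as the curation filters catch them.

Corpus studies use one 62-species alignment per planted site, with the
planted-timing mix following the empirically observed per-branch gain
profile of the human lineage (3/2/10/4/12/16/45/15/5 for hum..eua), scaled
to the corpus size (200 sites for the recovery studies).  Noise-free
recovery is exact by construction.  With 10% of taxa missing, recovery is
bounded by identifiability: five ladder steps are distinguished by a single
species (gorilla, orangutan, gibbon, bushbaby, treeshrew), and when that
species is unsampled no rule can date the adjacent gains correctly, so
expected recovery sits near 95% and its exact value fluctuates with the
seed.  All randomness is explicitly seeded; the same seed reproduces
byte-identical datasets.

## Known limitations

- The rare-variant exclusion applied in manual curation cannot be computed
  from these inputs; passing records carry a `RARE_VARIANT_UNCHECKED` flag
  for human review instead.
- codeml is never executed: log-likelihoods, ω estimates and BEB posteriors
  are parsed inputs, and BEB posteriors are reported verbatim, never
  recomputed.
- Mature-protein renumbering (e.g. a signal-peptide offset) is not applied;
  positions refer to the canonical precursor sequence.
- Realignment (the published procedure re-ran MUSCLE per gene) is out of
  scope; input alignments are taken as given.
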