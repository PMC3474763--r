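---
title: "Methods: genome-wide MAPK/MAPKK family surveys with mapksurvey"
author: "mapksurvey authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide MAPK/MAPKK family surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapksurvey)
```

## The problem this package addresses

Mitogen-activated protein kinase (MAPK) cascades are three-tier
phosphorylation relays (MAPKKK → MAPKK → MAPK) that transduce stress and
developmental signals in plants. A genome-wide survey of the last two
tiers in a newly sequenced genome follows a well-worn recipe: screen the
predicted proteome for candidate gene models and accept them by motif
rules; analyse their chromosomal architecture (tandem arrays, segmental
duplicates, clusters); build a distance-based phylogeny; scan promoters
for stress-responsive cis-elements; and relate family members across
species through synteny and expression correlation. `mapksurvey`
implements that recipe as a reusable, fully testable pipeline, with
seeded synthetic-data generators that provide exact ground truth for
every stage, and packaged fixtures for the *Brachypodium distachyon*
MAPK/MAPKK census (16 MAPKs, 12 MAPKKs) and its 17 ortholog/paralog
expression pairs.

## Motif acceptance rules

A candidate **MAPK** model is accepted when the serine/threonine-kinase
anchor motifs occur in order — the `HRD` catalytic motif, the `DFG`
motif, and the `APE` motif — and a `TxY` activation loop (TEY or TDY;
the rare MEY substitution is also accepted, since genuine family members
carry it) lies between DFG and APE. "Appropriately positioned" is not a
precisely defined notion in the survey literature; we operationalize it
as *strictly between the DFG and APE anchors*, and the anchors are
configurable (`default_kinase_anchors()`). Within a signature type, an
in-context match is preferred, then the leftmost.

A candidate **MAPKK** model must carry the dual-specificity active-site
motif `D(I/L/V)K` and the plant phosphorylation target site
`S/T-X5-S/T`. Divergent members carry this loop shifted 3–5 residues
downstream of its canonical position, or lack it altogether. The
canonical position is defined relative to the active site: the first
`[ST]x{5}[ST]` match starting 120–170 residues downstream of the
`D[ILV]K` aspartate is canonical (the window is configurable; the
literature locates the shift only relative to "the canonical position",
so the package makes the reference point explicit rather than implicit).
Strict mode rejects absent-loop models; lenient mode retains them
flagged for review, which mirrors how divergent-but-expressed members
are handled in practice.

Two further motif operations: the C-terminal **CD docking domain**
(`DxxDE(P)xC`, searched only in the trailing 150 residues; the
parenthesised proline is treated as an optional residue, consistent with
the alternatives notation used for the other motifs), and **EST
support** (local alignment of ESTs against a CDS at match +1, mismatch
−1, gap open 2, extend 1, with a 95% identity threshold over the
aligned region; only the single top-scoring EST is reported, because
highly similar paralogs make lower-ranked hits unreliable).

All residue positions in the package are 1-based, the R convention.

## Duplication, clusters, synteny

Two family genes are **duplicated** when a global alignment (BLOSUM62,
gap open 10, extend 0.5 — conventional protein settings, configurable)
covers ≥ 70% of the longer gene with ≥ 70% identity over the aligned
columns. Duplicates on one chromosome within 200 kb are **tandem**;
other duplicates **segmental**. The criterion is applied to identity;
where a survey reports "similarity", identity is the default reading
unless a similarity matrix is configured. Only one duplication event is
counted for tightly linked genes: tandem-linked duplicates are collapsed
by connected component, and each segmental link between the collapsed
groups adds one event. "Tightly linked" reuses the 200-kb cluster
distance, as no separate threshold is established in the field.

A **cluster** is a maximal run of consecutive same-family genes whose
span (max end − min start) is at most 200 kb, with at least 4 genes
(Holub rule) or at least 2 (relaxed rule). Span is measured end-to-end
because "within 200 kb" is not otherwise defined.

**Synteny blocks** are consumed as input (the package does not chain
blocks de novo). A gene maps to a block when its interval overlaps the
block interval by at least one base (1-based inclusive intervals; genes
merely abutting a block are not assigned), and partner pairs are
other-species family genes overlapping the mate interval of the same
block.

Without the drawn segment maps of a published figure, tandem/segmental
classification is distance-based; an optional table of intra-genome
block pairs can refine segmental calls.

## Phylogeny

Distances come from aligned sequences by pairwise-deletion p-distance
and a correction: Kimura's protein correction
\(d = -\ln(1 - p - 0.2p^2)\) by default, the nucleotide Kimura
two-parameter model \(d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)\),
or raw p. Surveys in this literature describe protein trees built under
a "Kimura two-parameter model", which is strictly a nucleotide model;
both interpretations are provided and the protein correction is the
default for protein input. Saturation (a non-positive logarithm
argument) is an explicit error, not a silent `NaN`.

Neighbor joining is the classic Q-criterion/Saitou–Nei algorithm. Ties
are broken by the lowest (row, column) index pair, making output
deterministic; negative branch lengths are clamped to zero with the
deficit moved to the sibling branch (preserving the pairwise sum), and
the number of clamped branches is recorded. On additive matrices the
tree reproduces the input distances exactly; the test suite verifies
this and cross-checks topologies against an independent reference
implementation. Bootstrap support resamples alignment columns with
replacement, deterministic given the seed. `terminal_pairs()` extracts
the cherries used for ortholog/paralog pairing; a 3-taxon star is
reported as having no informative cherries (with a warning), since
every pair is trivially terminal.

Input alignments are consumed pre-aligned; multiple-sequence alignment
construction is out of scope, and synthetic tests use gap-free
equal-length sequences.

## Promoter scanning

The four elements tracked are the W-box (`TGACY`), CBF (`GTCGAC`), DRE
(`RCCGAC`) and GCC box. The GCC consensus is not universally printed in
surveys; the canonical ERF-binding `GCCGCC` is the default, and every
pattern is configurable IUPAC. Both strands are scanned by default
(cis-elements are conventionally treated as orientation-independent),
with a forward-only mode since published strand conventions are often
unstated; overlapping occurrences are counted. For palindromic patterns
(CBF), a reverse-strand hit at the same interval as a forward hit is
counted once. Pattern ambiguity codes are interpreted in the pattern
only, so `N` runs in a promoter match nothing. Promoters are the 1 kb
upstream of the gene start, strand-aware, truncated with a warning at
chromosome edges.

## Expression

Raw intensity matrices are log2-transformed (with a state flag guarding
against double transformation and an optional floor, off by default)
and quantile-normalized: every column is mapped onto the cross-column
mean quantile vector, ties receiving the mean of their tied reference
quantiles (delegated to `limma::normalizeQuantiles(ties = TRUE)`).

A gene is **up-regulated** in a contrast when its mean paired log2
ratio (treated − mock over stated mock partners) exceeds 0.5 *and* its
multiplicity-adjusted two-sided paired t-test p-value is ≤ 0.05;
down-regulation is symmetric. The adjustment is Benjamini–Hochberg by
default with a Bonferroni option — survey methods sections sometimes
describe their correction ambiguously ("FDR, adjusted Bonferroni"), so
both are exposed and the choice is recorded in the output. Genes with
fewer than two complete pairs are skipped with a warning; genes with
missing values are rejected at import (no imputation).

Ortholog/paralog pair correlation is plain Pearson r over the ordered
vector of shared conditions, computed on the log2 scale (matching how
such profiles are published). Hierarchical clustering for heatmap
ordering uses 1 − Pearson dissimilarity with average linkage by
default; constant profiles are excluded with a warning.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline consumes, with exact
ground truth:

- **Family sequences** (`generate_family_sequences`): uniform random
  residues with planted anchors, loops and active sites. After
  planting, the background is cleaned by mutating any unplanned match
  of any scanned pattern to one of the residues N/Q/W, which occur in
  no constrained position of any pattern — an edit that provably cannot
  create a new match, so the cleanup terminates and the ledger is exact.
- **Gene coordinates** (`generate_gene_coordinates`): planted clusters,
  dispersed genes and duplicate pairs, with ≥ 250 kb between independent
  blocks so the 200-kb rules have unambiguous answers.
- **Duplicate pairs** (`generate_duplicate_pair`): identity is
  controlled by substituting an exact count of positions (always to a
  different residue). The realized identity is an exact positional
  count, which makes the ±2-point realization guarantee deterministic
  rather than probabilistic — a deliberate strengthening of a
  per-site-Bernoulli scheme.
- **Promoters** (`generate_promoters`): planted element instances with
  ≥ 6 bp between planted spans; background cleaned of spurious matches
  on both strands by targeted mutation.
- **Expression** (`generate_expression`): pair correlations planted by
  the shared-factor construction `x = s`, `y = ρs + √(1−ρ²)e`
  (exact at |ρ| = 1, converging at rate 1/√n otherwise), and log2
  shifts planted on treated-condition means. Default replicate noise is
  0.1 on the log2 scale — typical of well-replicated array data — and
  the default profile layout has 39 treatment-point columns, matching
  the panel size over which published pair correlations are computed.

What the generators do **not** emulate: probe-level microarray
artifacts, sequencing reads, codon usage, realistic residue composition
or indel structure, gapped alignments, or correlated noise between
samples. Passing the round-trip tests therefore demonstrates that the
analysis rules recover exactly what they are defined to recover; it
does not validate the biological sensitivity of those rules on real
proteomes, where motif context is messier than planted anchors.

## Numerical choices and degenerate inputs

- NJ joins break ties by lowest index pair; hclust agglomeration is
  deterministic; bootstrap and all generators are seeded.
- Saturated distances, zero-variance correlations, all-gap overlaps,
  empty EST sets, off-chromosome loci, over-full promoters and
  impossible layouts raise explicit errors.
- The 3-taxon NJ star uses the closed-form branch lengths
  \(v_i = (d_{ij} + d_{ik} - d_{jk})/2\).
- Problem sizes used by the packaged checks: 16-record motif cohorts,
  two-chromosome layouts with one 4-gene/150-kb cluster and three
  duplicate pairs, 6 promoters × 1 kb, 10-taxon additive matrices,
  1200-gene DE simulations at 10 replicate pairs, and 2000-sample
  correlation recovery. These sizes give stable verdicts (binomial and
  Monte-Carlo error well inside the asserted tolerances) while keeping
  a full run fast.

## A worked example

```{r example}
cfg <- survey_config(seed = 1)
dir <- file.path(tempdir(), "bundle")
simulate_survey(cfg, dir)
report <- run_survey(dir, cfg)
report
report$architecture$clusters_strict
head(report$identify, 4)
```

## Known limitations

- Tandem/segmental classification is distance-based unless intra-genome
  block pairs are supplied; it cannot reproduce classifications drawn
  from figure-level segment maps.
- The published per-family promoter averages and duplication shares of
  any specific genome require that genome's sequences and annotation;
  the packaged fixtures cover the census and pair-correlation tables,
  and everything else is validated property-style on synthetic data.
- Whether published "similarity" percentages are identities or
  positive-substitution similarities is not always decidable; the
  package defaults to identity.
- Profile-HMM screening, de novo motif discovery and MSA construction
  are out of scope; the motif rules operate on candidate sequences.
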