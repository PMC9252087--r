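---
title: "Decoy-aware gene-family annotation: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoy-aware gene-family annotation: model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefamdb)
```

## The problem

Profiling a defined catalogue of gene families — phosphorus-cycling genes
are the motivating case — from metagenome ORFs by homology search is
dominated by one failure mode: a query that belongs to *no* catalogued
family still finds a moderately similar catalogued sequence and is called a
false positive. General-purpose orthology databases mitigate this with very
strict identity cutoffs, at the price of false negatives. The alternative
implemented here is a *decoy-aware* database: alongside family-labelled
representative sequences, the database deliberately contains related but
non-target **homologues**. Because annotation is by single best hit, a query
that is really a neighbour of the family lands on the homologue first and is
rejected, while genuine family members still out-score the decoys.

## The annotation model

For query $q$ the engine retains the best local-alignment hit (highest bit
score; ties broken by higher identity, then lexicographically smallest
subject id) with e-value at most $10^{-5}$. The call is then:

* no retained hit → unassigned (`no_hit`);
* hit fails identity or hit-length filters → unassigned (`failed_filter`);
* hit subject is a homologue → unassigned (`homologue_hit`), *terminally* —
  the second-best hit is never consulted, because consulting it would undo
  exactly the decoy mechanism;
* otherwise the query inherits the subject's family.

A single-label best-hit rule was chosen over multi-hit weighting: the
workflow this package reproduces annotates each ORF with one family, and
every validation design below assumes that.

### Filter parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_identity` | 30.0 | % of alignment columns | main false-positive control for read/ORF profiling |
| `min_aln_len` | 25 | aligned amino acids | guards against short spurious HSPs; suited to ORFs from ~150 bp reads |
| `max_evalue` | 1e-5 | — | search-time significance gate |

All thresholds are inclusive (`>=` / `<=`). For whole-genome proteomes the
CLI exposes a `genome` preset that raises `min_identity` to 70 %: complete
genes align over their full length, so a much stricter identity is
affordable and removes most residual false positives.

"Hit length" is the aligned-column count of the HSP (including gap
columns), not the query length.

## Alignment and scoring

Pairwise alignment is delegated to Biostrings (`pairwiseAlignment`),
BLOSUM62 with affine gap costs 11/1 (a gap of length $k$ costs $11 + k$).
**Global identity** — used by all clustering and database-construction
steps — is identical columns divided by *all* alignment columns of the
end-to-end alignment, terminal gaps included. This is the strictest of the
common identity conventions and makes identities symmetric and
length-aware; an alternative convention excluding terminal gaps would
report higher values for length-mismatched pairs.

The internal search backend converts raw Smith–Waterman-style scores $S$ to
e-values with the standard gapped Karlin–Altschul constants for BLOSUM62
($\lambda = 0.267$, $K = 0.041$), database length $n$ = summed record
lengths: $E = K m n e^{-\lambda S}$. These constants only need to be
realistic enough for the $10^{-5}$ gate to separate genuine homology from
background — downstream logic never consumes absolute e-values. The
external backend consumes 12-column tabular hit files from any standard
search tool (DIAMOND, BLASTP, MMseqs2) and applies byte-identical best-hit
selection, so large-scale runs and the in-package engine agree by
construction on everything after the search itself.

Alignment tie-breaking follows Biostrings' deterministic dynamic
programme. Where several optimal alignments exist, reported `matches`
values are those of Biostrings' canonical traceback.

## Database construction

`build_core` clusters all candidates greedily (longest first, ties by id;
each sequence joins the first centroid at ≥ 30 % global identity). Label
handling in a cluster:

* one labelled family → all members become representatives of it
  (unlabelled members inherit the label);
* several families → the whole cluster is demoted to homologues. This is
  deliberately conservative: a cluster that mixes curated labels is
  evidence that the threshold cannot separate those families, and a wrong
  representative is costlier than a lost one;
* no labels at all → homologues. Letting unlabelled sequences found new
  representative clusters would manufacture families out of noise, so they
  are retained only as decoys; every such decision is logged in the review
  table (`db$metadata$review`) for manual inspection, replacing the
  interactive curation checkpoint of the original workflow with a
  machine-readable one.

`expand_orthology` (30 %) and `merge_bulk` (80 %) add records whose best
representative identity clears the threshold; a record whose claimed family
conflicts with its best hit becomes a homologue. The stricter bulk
threshold reflects that very large unlabelled sources contribute volume,
not curation, and only near-certain members are worth admitting.
`compact_family` (95 %) replaces a family's representatives by centroids,
for families whose sources are known to be redundant. Dereplication at
100 % keeps the earlier record on exact sequence ties, so re-merging a
source is a no-op.

## Abundance

Per family and sample, coverage is
$\sum_{\text{ORFs}} (N \times l / L) / S$ with $N$ mapped reads, $l$ read
length, $L$ ORF length, $S$ sequencing size in Gb. $S$ is interpreted as
total sequenced bases / $10^9$ (not bytes): the quantity is then a
read-depth sum normalised per sequenced gigabase and is exactly linear in
$N$ and $l$ and inversely proportional to $L$ and $S$ — properties the test
suite asserts numerically. Read length is a per-sample constant
(Illumina-style); variable-length data must be pre-averaged by the caller.

## Validation designs

**Simulated gene sets.** Queries carry truth labels (target family or
non-target). Confusion counts default to the *binary* level — a target
assigned to any family is a true positive — because the design's negatives
are whole non-target gene families, making set-level truth the natural
reading. The *family* level is available as an option; there, a target
assigned to the wrong family counts as a false positive (not a false
negative) so that PPV penalises cross-family confusion. Metrics with a zero
denominator are reported as `NA`, never 0, and never raise.

**Threshold sweeps.** The default grid is identity 0.2–99.9 % in steps of
0.1 (998 points) by hit length 2–99 aa in steps of 1 (98 points). The grid
is computed from one pass over the best hits (a 2-D suffix sum of the
per-query threshold histogram); the test suite proves this equal to naive
per-cell re-filtering and re-scoring. Along the identity axis, sensitivity
is non-increasing and specificity non-decreasing, and the binary class
margins TP+FN and TN+FP are invariant — violations would indicate a
bookkeeping bug, so they are asserted on every synthetic run.

**Mock genomes.** A genome's predicted family set (from annotation) is
divided by its annotation-derived family count, extracted from its GFF3
`gene=`/`product=` attributes through the same keyword rules the builder
uses. The detection-ratio classes use exact comparison of the integer
counts — ratios of small integers need no tolerance. Keyword matching is
token-wise and case-insensitive; multiword keywords must appear as a
contiguous token phrase.

## The synthetic-data generator

Generators are pure functions of a seed. Each family draws a uniform-random
ancestor (default length 300 aa) and derives members by i.i.d.
substitutions at `within_divergence` (default 0.1); the unmutated ancestor
itself is the family's first representative, so member-to-nearest-
representative identity tracks $100(1-d)$ analytically. Decoys derive from
a decoy ancestor at `decoy_divergence` (default 0.45) from the family
ancestor, with database homologue records and decoy queries drawn around
it — this reproduces the geometry the decoy mechanism needs: a decoy query
is ~80 % identical to its homologue record but only ~50 % to the
representatives. Negatives are independent random proteins (background
global identity well under 30 %).

Defaults are chosen to mirror the validated operating regime: members
clear the 30 % (and 70 %) identity gates with margin, decoys sit between
members and background, negatives sit below every gate. The generator
does **not** emulate real protein evolution: no substitution-rate
heterogeneity, no profile/domain structure, no shared domains between
families, and indels default to 0 (a rate knob exists) so that identities
stay analytically controllable. Passing tests therefore demonstrate the
*logic* of the pipeline — filtering, decoy rejection, sweep algebra,
ratio bookkeeping — not its discrimination power on real protein families,
where within/between-family identity distributions overlap.

Problem sizes used by the test suite and the acceptance script — e.g. 10
families × 6 members at length 150–300, 100 search-oracle instances, a
100 × 20 naive-sweep cross-check, 10 mock genomes — were chosen as the
smallest sets that exercise every code path with clear planted margins.

## Degenerate inputs and numerical choices

* Empty sequences, empty pools and empty truth tables are errors, not
  silent empties; empty hit *files* are valid (zero hits).
* Terminal stop codons (`*`) are stripped on FASTA input; internal stops
  and non-amino-acid letters are rejected with the record id.
* Clustering order is decreasing length with id tie-break, making every
  clustering deterministic; dereplication at 100 % keeps the
  lexicographically smallest id.
* Coverage inversion (`make_read_mappings`) requires integer read counts
  and reports the nearest achievable coverage otherwise.
* All TSV/FASTA outputs order rows and columns lexicographically, so
  repeat runs are byte-identical.

## Known limitations

* The internal search engine is exhaustive (every query against every
  record): correct and convenient at validation scale, not a substitute
  for DIAMOND-class tools on millions of ORFs — that is what the external
  backend is for.
* Only protein input is supported (no nucleotide queries, no six-frame
  translation).
* GFF-derived "annotated family" sets are only as good as the keyword
  rules; synonyms absent from the rules deflate the detection-ratio
  denominator.
* The binary/family scoring choice materially affects PPV when families
  are similar; both levels are exposed, and reports state which was used.
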