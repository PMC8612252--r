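---
title: "Methods: genomic-context inference for heliorhodopsins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic-context inference for heliorhodopsins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heliocontext)
```

`heliocontext` turns the screening and context-analysis rules used in
comparative surveys of heliorhodopsins (HeRs) into explicit, tested
functions. This vignette documents the models and procedures, every tunable
parameter with its default and rationale, the synthetic-data generator the
tests rely on, and the design decisions taken where the underlying rules
left room. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Coordinates and containers

All coordinates are 1-based and inclusive (the GFF3 convention); contigs are
linear, with no wrap-around adjacency. A `genome_annotation` holds ordered,
stranded genes with set-valued domain annotations: a gene carrying two
copies of a Pfam domain carries it once, because every downstream rule —
marker counting, enrichment, neighborhood multisets — is about *presence*.
Contig lengths come from `##sequence-region` pragmas and are otherwise
inferred as the maximum gene end, which under-estimates true length by the
trailing intergenic region; only the 5 kb taxonomy floor consumes contig
length, so the bias is conservative (borderline contigs are excluded, never
falsely included).

Domain-hit tables are filtered at E-value $< 10^{-3}$, a *strict*
inequality: a hit at exactly `1e-3` is dropped. Two dialects are read — a
minimal 5-column table and the per-domain tabular output of profile-HMM
searches, from which the *independent* (per-domain) E-value is used, since
the threshold is applied per domain occurrence rather than per full
sequence.

## The rhodopsin screen

A candidate is retained as a bona fide rhodopsin iff it has exactly 7
transmembrane helices and a helix-7 anchor motif: `SxxxK` calls a
heliorhodopsin, `DxxxK` a type-1 (proteo-)rhodopsin. Verdicts partition
exhaustively — every protein is `heliorhodopsin`, `type1`, or `rejected`
with machine-readable reasons (`tm_count`, `no_motif`).

**Motif window.** Predicted helix boundaries are imprecise, so the motif is
sought within TM7 extended by `motif_pad = 3` residues on each side, the
whole 5-mer inside the window. Three residues is half a helix turn: enough
to absorb predictor jitter without reaching into the preceding loop.

**Orientation.** HeRs have an inverted topology, N terminus cytoplasmic.
Sources disagree internally on the wording of this orientation; we treat
N-in as canonical. Because the retention criteria are TM count and motif
only, a heliorhodopsin whose predicted N terminus faces out keeps its
verdict and gains an `orientation_conflict` reason rather than being
rejected — the conflict is surfaced, not silently resolved either way.

**Motif collisions.** `SxxxK` and `DxxxK` differ at their first fixed
position, so they cannot match at the same offset, but both can occur at
different offsets within the window. The HeR call then takes precedence
(this is a heliorhodopsin screen) and `ambiguous_motif` is recorded.

**Fallback topology.** When no predictor table is supplied,
`predict_topology_fallback()` segments the sequence by sliding-window
Kyte–Doolittle hydropathy: window 19 (the classic TM window), candidate
centers at mean ≥ 1.6 (a conventional KD cutoff for membrane helices), runs
merged across gaps ≤ 3, edges refined outward while per-residue hydropathy
stays positive, minimum refined length 15. Edge refinement matters: raw
window thresholding shrinks detected helices by roughly half a window at
each end; refinement restores the hydrophobic run's true extent.
N-terminus side uses the positive-inside rule, counting K+R in alternate
loops. The fallback is deterministic and adequate for idealized (e.g.
synthetic) architectures; it does not replace a dedicated predictor on real
proteins, whose helices are less cleanly hydrophobic — supply a topology
table for production screens.

## Envelope classification

Diderm (outer-membrane-bearing) genomes are recognized by counting
*distinct* outer-envelope marker domains: ≥ 10 → `diderm`. The package adds
a lower band: ≤ 2 → `monoderm_consistent`, 3–9 → `ambiguous`. The band
edges follow the two instructive edge cases in the HeR literature: an
incomplete genome with 2 markers was deemed uninterpretable-as-diderm, and
a complete genome with 5 markers was judged to lack a classical diderm
envelope — so 2 sits below the monoderm ceiling and 5 inside the ambiguous
band. Completeness below 0.8 (or unknown) attaches a `low_completeness`
caveat, because missing markers in an incomplete genome are weak evidence
of absence. The 27 curated marker identities belong to the survey's
supplementary material and are not embedded; `her_config()` ships 27
synthetic placeholder slots (`OMM001`–`OMM027`) and `read_marker_set()`
loads a real list. Whether the published criterion counted distinct domains
per genome or per protein is not stated; per-genome distinct domains is the
natural reading of "presence of at least 10 marker domains" and is what we
implement.

## Contig taxonomy

A contig of ≥ 5,000 bp is assigned a phylum iff ≥ 60% (inclusive) of its
genes give best hits to that phylum. The denominator is *all* predicted
genes on the contig, so hitless genes dilute support — the literal reading
of the rule and the stricter one; `taxonomy_hits_only = TRUE` switches to a
genes-with-hits denominator. At most one phylum can reach 60% of all genes,
so assignment is structurally unique. Upstream sequence dereplication is
consumed, not performed; `drop_duplicate_contigs()` removes exact
duplicates only.

## Gene context and operon candidates

Intergenic distance is `start(next) − end(prev) − 1`: abutting genes give
0, overlaps are negative. A neighbor is a cotranscription candidate iff its
distance to the chain is < 10 bp (strict; overlaps qualify) *and* it shares
the anchor's strand. The published rule is stated pairwise against the HeR,
but multi-gene transcription units imply transitive extension, so the
default extends the chain while consecutive pairs qualify and emits one
maximal chain per anchor; `operon_transitive = FALSE` gives the literal
direct-neighbor reading. Neighborhoods come in two modes matching how
contexts are examined: `by_genes` (up to 10 genes per side — the enrichment
draw) and `by_window` (all genes overlapping anchor ± 10 kb — the
inspection window).

## Neighborhood enrichment

For each genome whose HeR anchor has ≥ 10 genes on both flanks (so the draw
is exactly $n = 20$), every domain present in the neighborhood is tested
with the upper-tail hypergeometric probability $P(X \ge k)$ of drawing $k$
carrier genes in $n$ from a genome of $N$ genes with $K$ carriers. The
population is *genes*, not domain copies: $N$ counts protein-coding genes,
$K$ genes carrying the domain. $k = 0$ returns exactly 1. The computation
delegates to `stats::phyper`; the test suite checks it against exhaustive
combinatorial enumeration for every valid instance with $N \le 40$ at
$10^{-12}$.

All (genome × anchor × domain) p-values of a run are Benjamini–Hochberg
adjusted **together** — the adjustment family is not specified by the
published rule, and the run-level family is the conservative choice for
cross-genome selection; `bh_scope = "genome"` adjusts within genomes
instead. A genome is significant for a domain when *any* of its eligible
loci reaches q < 0.05 (genomes usually have one HeR locus; OR-ing
generalizes that). A domain is **selected** when significant in ≥ 10% of
eligible genomes. The phrase "located in the proximity of HeR in at least
10% of genomes with low probability" admits a weaker reading —
present-in-10% plus significant somewhere — available as
`selection_mode = "present"`. The whole procedure reruns per phylum with
≥ 5 eligible genomes (`per_phylum_runs()`), re-adjusting within the phylum.

## Fusion motifs and extensions

Consensus patterns use uppercase fixed residues and lowercase `x`
wildcards, compiled to fixed-span matchers with an optional mismatch budget
on fixed positions. MORN repeats (`YEGEWxNGKxHGYG`, span 14) are matched
greedily left-to-right without overlap, because tandem repeats abut; zinc
ribbons (`CxxC` + exactly 17 arbitrary residues + `CxxC`, span 25) report
*all* matches including overlapping ones, because cysteine spacings can
nest. Whether the 17-residue spacer was exact in the original matches is
not stated; exact spacing is the default and `zn_spacer = c(lo, hi)` scans
a range. Terminal regions (`ntv`, `ctv`) are always reported when
non-empty; inter-helix loops only when strictly longer than 50 aa. Loop
sidedness alternates from the N terminus (N-in ⇒ loop after TM1 is ECL1,
after TM4 ICL2, after TM6 ICL3), and flipping the terminus swaps every
ECL↔ICL label and nothing else. Clustering extensions into variant families
is out of scope — regions are exported as FASTA for external profile
tools.

## The synthetic-data generator

`generate_cohort()` emulates the statistical structure the pipeline
assumes, with ground truth serialized alongside:

- one linear contig per genome, 100–400 genes of 300–3,000 bp;
- genes grouped into cotranscription units (sizes 1–4, weighted toward
  singletons); within-unit gaps are uniform on −20..9 bp (overlaps
  included), unit boundaries are either wide gaps (30..300 bp) or, with
  probability 0.15, a small-gap *decoy* with a strand flip — so a planted
  chain is exactly the maximal qualifying chain and decoys exercise both
  failure modes of the operon rule;
- per-gene background domains: 50 accessions, each present per gene with
  probability 0.02;
- one HeR anchor per genome with full 10-gene flanks; planted enrichment
  raises a chosen accession to 40% presence among the 20 neighborhood genes
  against the 2% background, in 30% of genomes by default — the power
  conditions the enrichment properties are stated at;
- envelope labels plant 10–27 distinct markers (diderm) or 0–2 (monoderm);
- anchor proteins are built by `generate_protein()`: Leu/Ile/Val/Phe-rich
  helices, hydrophilic loops, K/R confined to cytoplasmic-side loops so the
  positive-inside rule recovers the planted orientation, and the motif
  embedded ≥ 5 residues from helix edges so hydropathy segmentation is not
  perturbed at boundaries;
- best-hit tables (`generate_besthits()`) hit the target phylum in exactly
  `ceiling(concordance × n)` genes, the remainder split between decoy
  phyla and no-hits.

Gap and length distributions are uniform within their ranges — no
generative model is claimed by the source material — and the ranges
straddle every decision threshold (10 bp, 5 kb, 50 aa, 60%, 10 markers).
Everything is drawn from a single stream keyed by `seed`; equal seeds give
byte-identical datasets and reports.

**What passing tests do and do not show.** The generator's proteins have
idealized hydropathy, its domains are independent Bernoulli draws, and its
operon structure is exactly the rule being tested. Recovery at 100% on
synthetic cohorts therefore validates the *decision logic* — thresholds,
windows, tie-breaks, bookkeeping — not performance on real annotations,
where topology predictors err, domain co-occurrence is correlated, and
assembly artifacts blur gene adjacency.

## Numerical choices and degenerate inputs

- E-value and operon-gap comparisons are strict (`<`); marker, concordance
  and flank thresholds are inclusive (`≥`), each matching its source
  wording.
- `bh_adjust()` rejects values outside $(0, 1]$; hypergeometric bounds
  violations are hard errors, not NA.
- Empty hit files, markerless genomes, hitless contigs and neighborhoods
  without domains all return typed empty results rather than errors;
  ineligible enrichment loci and anchors missing from a contig are hard
  errors.
- Report writing sorts rows by every column and comma-collapses list
  columns, making outputs byte-deterministic.
- Results are invariant to genome input order; p-value ties need no
  breaking (closed form), and tied q-values are preserved as equal.

## Problem sizes used by the test suite

The statistical properties are checked at the scale the procedures are
specified at: hypergeometric enumeration over all valid instances with
$N \le 40$; null calibration on 50 replicate 100-genome cohorts with no
planted signal (expecting an empty selection in ≥ 95%); power on 50
replicate 20-genome cohorts with the default planting (selection of the
planted domain in ≥ 95%); exact recovery of planted operons, rhodopsin
classes and envelope labels on 20-genome cohorts. These sizes are the
package's stated validation conditions and are fixed in the tests.

## Known limitations

- The fallback topology predictor is a hydropathy heuristic; real screens
  should supply predictor output via `read_topology()`.
- The placeholder marker set must be replaced by a curated list for real
  envelope calls.
- Enrichment treats genomes as independent; no phylogenetic correction is
  applied, so clades of near-identical genomes can dominate selection.
- Domain co-occurrence within a gene is ignored (set-valued presence), and
  hit coordinates are carried but not used for overlap resolution.
- No circular-contig handling: adjacency across the origin is invisible.
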