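---
title: "Typing Paramecium bursaria syngens from molecular signatures"
author: "SyngenMarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing Paramecium bursaria syngens from molecular signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SyngenMarkers)
```

## The problem

*Paramecium bursaria*, the green ciliate, is a complex of five mating
groups ("syngens", R1–R5) that behave as reproductively isolated
biological species but are essentially indistinguishable by morphology.
They can, however, be told apart molecularly: each syngen carries *fixed,
private character states* — synapomorphies in the diagnostic-character
sense — at a modest number of positions in the nuclear SSU and ITS rDNA
and in the translated mitochondrial COI gene.  SyngenMarkers implements
the complete typing workflow around those characters:

1. **discover** the variable alignment columns of each marker and classify
   them (synapomorphy / within-syngen variable / other variable);
2. **type** new, possibly partial and unaligned, sequences against the
   combined signature;
3. build **statistical-parsimony haplotype networks** annotated with the
   geographic origin of every record;
4. **verify** that the labelled syngens are monophyletic in a
   neighbor-joining tree, with column-bootstrap support;
5. **simulate** truth-tracked datasets with the same structure, so that
   every stage is testable without fetching sequence data.

## The signature model

Let an alignment of $n$ records over $L$ columns be partitioned into
labelled clades $c_1, \dots, c_k$ (plus possibly unlabelled records).
Gaps, IUPAC ambiguity codes, and `X` in peptides are treated as *missing*:
they are excluded from state sets and never match anything.  This is
deliberately conservative — public COI and rDNA fragments have ragged ends,
and an `R` that "could be" an `A` should not found a confident call.

For a column $j$:

* a clade $c$ is **fixed** at $j$ if all its non-missing members share one
  state and at least one member is non-missing;
* column $j$ is a **synapomorphy** for $c$ if $c$ is fixed for a state
  that occurs in *no* record outside $c$ (several clades can be diagnostic
  at the same column, each for its own private state);
* a column where no clade is diagnostic but some clade shows two or more
  states is **within-clade variable**;
* remaining variable columns — typically a fixed difference shared by two
  or more clades — are **other variable**.  The textbook case is the SSU,
  where R1 and R2 share all their derived states and are therefore
  inseparable by that marker alone.

A clade is **separable** by a marker if it owns at least one synapomorphy
there; by construction such a state distinguishes it from every other
clade.  `combineMarkers()` reports separability per marker and for the
marker combination — the formal version of "R1 and R2 cannot be
distinguished by the SSU alone, but the ITS resolves them".

All column indices in reports are 1-based alignment coordinates.  COI is
analysed at the amino-acid level: the alignment is translated codon by
codon under a selectable NCBI genetic code — the default is table 4
(mold/protozoan mitochondrial, TGA = Trp), since COI is mitochondrial;
tables 1 and 6 are available for sensitivity checks, and conclusions that
depend on TGA handling should be re-run under both 1 and 4.  Codons
containing any gap or ambiguity character translate to `X` (missing), and
a codon-column map ties every amino-acid column back to its three
nucleotide columns.

## Typing queries

Queries are unaligned and often partial, so they are first mapped onto
reference alignment columns: a global pairwise alignment with free end
gaps (match $+1$, mismatch $-1$, gap $-2$) against the majority-rule
consensus of the reference alignment (gap-majority columns excluded)
yields a strictly monotone column mapping.  This replaces
similarity-search-based assignment with an explicit, reproducible
coordinate mapping.

At each diagnostic (marker, column, state) triple whose column the query
covers with a non-missing state, the query either supports or contradicts
the owning clade.  A clade *matches* if it has at least one evaluable
triple and no contradiction; a clade with an evaluable contradiction is
*excluded*; a clade with no evaluable triple is neither.  The final call
is:

* `ASSIGNED(c)` — exactly one clade matches;
* `AMBIGUOUS({...})` — several matched clades tie, or no clade matches
  positively and two or more remain unexcluded (an SSU-only query from R1
  or R2 ends here as `AMBIGUOUS(R1,R2)`);
* `INSUFFICIENT` — fewer than `minEvaluable` (default 3) distinct
  diagnostic columns covered; the default guards against confident calls
  from tiny fragments;
* `CONFLICT` — everything else, including the corner case where no clade
  matches positively and only one clade is unexcluded without evidence:
  we deliberately refuse to assign on zero positive evidence.

## Statistical-parsimony networks

Records are collapsed to haplotypes (`strict`: identical strings; `infer`:
identical over mutually non-missing columns — that relation is not
transitive, so groups are kept as cliques, filled deterministically in
record order).  The representative is the member with fewest missing
characters (ties: smallest id).  Steps between haplotypes are Hamming
distances over shared non-missing columns.

The connection limit follows the statistical-parsimony (TCS) idea: link
haplotypes only while the mutational path between them is credibly free of
homoplasy.  Our estimator evaluates that probability directly from the
underlying model: under the coalescent the number of mutations a site
experiences between two sequences is geometric with parameter $q$, and
states change per Jukes–Cantor, so the expected per-site divergence is
$p(q) = q/(1+q/3)$.  For haplotypes differing at $j$ of $L$ compared
characters we set $\hat q$ by method of moments from $j/L$ and compute

$$P_j = \left[\frac{(1-\hat q)\,\hat q}{p(\hat q)}\right]^{\,j}
        \left[\frac{1-\hat q}{1-p(\hat q)}\right]^{\,L-j},$$

the probability that every observed difference reflects exactly one
mutation and every identity none.  The limit $J$ is the largest $j$ with
$P_j > \alpha$ (default $\alpha = 0.95$).  Two numerical notes: the
computation is done in log space, and divergence at or beyond Jukes–Cantor
saturation ($j/L \ge 3/4$) has no single-hit explanation and receives
$P_j = 0$, so even $\alpha \to 0$ admits only steps below the saturation
bound.  $L$ defaults to the number of columns non-missing in at least 90 %
of records (`comparedCharacters()`), not the raw alignment length.

This is a deliberately conservative reading of the published method:
widely used TCS implementations are reported to return larger limits
(around 2 % of $L$ at the 95 % level, versus roughly 1 % here), and they
insert inferred intermediate haplotypes (median vectors), which we do not —
networks here contain sampled haplotypes only.  Both choices can make our
networks fall apart into more components than a TCS/PopART rendering of
the same data; $\alpha$ is configurable if a looser limit is wanted.

Edges are added in non-decreasing step order.  Within one step value,
every candidate edge joining two components that were distinct before
that step value started is kept — equal-step alternatives therefore show
up as reticulations, as in classic TCS graphics — while equal-step edges
internal to an already-connected component are dropped.  The result is
deterministic, independent of input order up to haplotype ids, and within
each component the kept edges always contain a minimum spanning tree of
the admissible-pair graph (verified against exhaustive oracles in the test
suite).

`summarizeBiogeography()` aggregates, per clade, the regions of its
records (six-continent vocabulary plus UNKNOWN) and flags Europe-only
clades; per network component it reports the clade composition.

## Tree check

The workflow's phylogenetic component is intentionally light: p-distances
(mismatch fraction over shared non-missing columns) on the column-wise
concatenated SSU+ITS alignment, neighbor joining (negative branch lengths
clamped to zero), and a bipartition test of monophyly for every labelled
clade, with unlabelled leaves ignored on both sides of each split.
`bootstrapSupport()` resamples columns with replacement and reports the
fraction of replicates in which each clade is monophyletic.  Model
selection, maximum likelihood and parsimony searches are out of scope:
clade recovery, not branch-length fidelity, is the contract.

## The synthetic generator

`simulationConfig()` describes a dataset the way the workflow assumes it:
clades with planted fixed substitutions, optional states shared between a
clade pair in a named marker, within-clade polymorphic columns carried by
a random proper subset of a clade's members, a COI open reading frame
(no internal stops under the configured code) whose planted changes are
nonsynonymous, and a per-clade distribution over geographic regions.
`simulateSyngens()` draws a uniform random root per marker and applies the
plan; all randomness flows from one seed through fixed per-marker
substreams, so equal seeds give byte-identical output.

The defaults are the package's study conditions and mirror the real
five-syngen data structure:

* 48 records sized like the reference strain set (R1: 11, R2: 12, R3: 20,
  R4: 4, R5: 1 — the fifth syngen is known from a single strain, which is
  why `minCladeSize` defaults to 1);
* SSU 1700 nt with 30 variable columns: 8 synapomorphies each for R3, R4,
  R5 plus 6 columns at which R1 and R2 share one derived state — making
  them inseparable by SSU alone;
* ITS 500 nt with 23 variable columns: 4 synapomorphies per clade plus 3
  within-clade variable sites;
* COI 600 nt whose translation has 18 variable amino-acid columns, 13 of
  them diagnostic (3/3/3/2/2), the other 5 shared between clade pairs;
* regions: R1 and R5 are Europe-only *by construction* — Europe-only
  clades draw only Europe, and every other clade is guaranteed at least
  one non-European member (if sampling yields none, the last member gets
  the model's most probable non-European region), so the planted
  biogeography holds for every seed.

What the generator does *not* emulate: within-clade descent is a star
(no branching process or rate heterogeneity), substitutions are placed
i.i.d. uniformly, and there are no alignment gaps outside query fragment
windows.  Passing tests on synthetic data therefore demonstrate the
correctness of the discovery/typing/network logic under the assumed data
model, not robustness to alignment error or deep within-syngen structure
in real data.  One visible consequence of the realistic signal thinness:
R1 and R2 differ in only 8 of 2200 concatenated columns, so column
bootstrap support for those clades is high but not always exactly 1.

## A worked run

```{r run}
sim <- simulateSyngens(referencePreset(seed = 42))
disc <- discoverSignatures(sim$alignments, sim$meta)
vapply(disc$tables, function(t) nrow(signatureEntries(t)), integer(1))
separability(disc$signature)
```

```{r type}
q <- makeQueries(sim, "ITS", seed = 7)
calls <- batchType(q$queries, disc$signature, disc$refAlns, "ITS")
table(calls$call_type)
```

```{r net}
aln <- sim$alignments$ITS
net <- buildNetwork(collapseHaplotypes(aln, sim$meta),
                    connectionLimit(comparedCharacters(aln)))
net
bio <- summarizeBiogeography(net, joinAlignmentMetadata(aln, sim$meta))
bio$clades[, c("clade", "regions", "europe_only")]
```

## Numerical and design choices

* **Missing data**: excluded from state sets by default
  (`missingPolicy = "ignore"`); `"as_state"` is available because it is
  not documented whether published variable-position counts treated gaps
  as states.  Ambiguity codes never match anything.
* **Reading frame**: the in-frame COI default is frame 1;
  `pickFrame()` suggests the frame minimising internal stops (ties to the
  lower frame) but is never applied silently.
* **Gap-only columns**: a `dropGapOnlyColumns()` utility exists and is
  never applied implicitly.
* **Alignment scoring** for query mapping is fixed (+1/−1/−2, free end
  gaps) and exposed; end gaps are free because public records are often
  partial.
* **Problem sizes** in the shipped tests: randomized oracle corpora of
  1000 diagnostics cases, 500 network cases and 100 additive-matrix NJ
  cases, and bootstrap checks at 20 replicates on the 48-record preset —
  sizes at which every oracle is exhaustive while the whole suite stays
  comfortably interactive.
* **Known limitations**: no median vectors in networks; no
  likelihood-based assignment; typing treats markers one at a time (a
  query is a single-marker sequence); NEXUS support is limited to simple
  (optionally interleaved) matrices.
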