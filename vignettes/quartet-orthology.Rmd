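---
title: "Quartet-based orthology inference: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quartet-based orthology inference: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoquartet)
```

## The problem and the model

Two homologous genes in different species are *orthologs* when their most
recent common ancestor was a speciation event, and *paralogs* when it was a
gene duplication. The distinction matters because function transfers most
safely across orthologs. The classical similarity-based proxy --
bidirectional best hits (BBH) between two proteomes -- is fast but blind to
*hidden paralogy*: when complementary gene copies were lost in the two
lineages, two paralogs become each other's best hits.

The remedy implemented here interrogates third species. For a candidate
pair $(x, y)$ and a third species carrying $z_1$ (the BBH partner of $x$
there) and $z_2$ (the BBH partner of $y$), the topology of the implied
four-gene tree reveals whether a duplication separates $x$ from $y$: if it
does, same-side similarities ($x$--$z_1$, $y$--$z_2$) are systematically
larger than all cross similarities. Rather than reconstructing the quartet
tree by alignment and maximum likelihood, the package evaluates the analytic
score

$$
\alpha \;=\; \tfrac{1}{2}\,\min(S_{x,z_1},\, S_{y,z_2})
\;-\; \tfrac{1}{4}\,\bigl(S_{x,z_2} + S_{y,z_1} + S_{x,y} + S_{z_1,z_2}\bigr),
$$

where $S_{i,j}$ is the symmetric pairwise similarity (bit-score semantics).
Large $\alpha$ means strong duplication evidence. The score is computed
against every available third species and the **maximum** is stored per
pair, so any downstream cutoff can be applied without rescoring. A pair is
called an ortholog when its maximum $\alpha \le \Omega$ (inclusive), or when
no third species yields a witness at all -- a corpus-wide search that finds
no duplication evidence is positive evidence of orthology, not missing data.

Useful structural facts about $\alpha$, all asserted as tests:

* if all six similarities equal $s$, then $\alpha = -s/2$ exactly;
* $\alpha$ is invariant under the simultaneous swap
  $(x \leftrightarrow y,\, z_1 \leftrightarrow z_2)$;
* $\alpha(c\,S) = c\,\alpha(S)$ for $c > 0$, so the cutoff lives on the same
  scale as the similarities;
* the called-ortholog set is nested and non-decreasing in $\Omega$, which is
  exactly the accuracy/coverage dial exposed to the user.

## Pipeline stages and their contracts

1. **Ingest.** Protein identifiers, species assignments and sequence
   lengths come from FASTA plus a species table (or a precomputed length
   table); all-vs-all search results are read from the standard 12-column
   tabular format. Coverage of each sequence is the inclusive aligned span
   $|{\rm end} - {\rm start}| + 1$ over the full length, which makes
   reversed subject coordinates harmless.
2. **Quality filter.** A hit survives when it covers at least half of
   *both* sequences and its bit-score strictly exceeds 50; self-hits are
   dropped. The filter is applied corpus-wide *before* any best-hit
   ranking, because within-species hits that pass it are needed later for
   inparalog detection.
3. **Similarity store.** Per direction only the best-scoring segment pair
   is kept (no HSP tiling); when both directions survive, $S$ is their
   arithmetic mean -- symmetric and order-independent. Absent pairs stay
   absent: a missing similarity is "no evidence recorded", never zero.
4. **BBH and quartet scoring.** Best hits are directional maxima of $S$
   with ties broken toward the lexicographically smallest identifier, so
   runs are reproducible across platforms. Witnesses require *mutual*
   best-hit partnership of $z_1$ with $x$ and $z_2$ with $y$; a third
   species whose partners coincide ($z_1 = z_2$) cannot witness a
   duplication and is skipped.
5. **Groups.** Called pairs form a graph weighted by $S$; a self-contained
   Markov-clustering engine partitions it, and clusters spanning at least
   three distinct species become orthologous groups `QTS_1`, `QTS_2`, ...
   (numbered by decreasing size, ties by smallest member). Consensus
   annotation adopts a facet only when more than 80% of *all* group
   members share it -- 4 of 5 (exactly 0.8) is not a consensus, 5 of 6 is.
6. **Inparalogs.** Within a species, candidate groups are connected
   components of the graph whose edges are quality-filtered within-species
   pairs more similar than either endpoint's best cross-species similarity
   ("external ceiling"). Each component must then pass the set-level
   condition -- minimum internal similarity strictly above every member's
   external ceiling -- or it is split at its weakest internal edge and
   re-tested. Every emitted group therefore satisfies the defining
   condition literally, whatever path construction took.

## Tunable parameters

| parameter | default | units / range | why this default |
|---|---|---|---|
| `omega` | 20 | bit-score scale | standard operating point balancing accuracy and coverage |
| `bit_threshold` | 50 (strict `>`) | bits | noise floor of all-vs-all searches; ~1e-5 e-value at corpus scale |
| `coverage_threshold` | 0.5 (inclusive `>=`) | fraction of each sequence | rejects domain-only matches |
| `inflation` | 2.0 | MCL exponent, > 1 | the customary MCL default; larger values fragment clusters |
| `missing_policy` | `"skip"` | `skip` / `impute_zero` | see "Numerical choices" |
| `min_species` | 3 | species | a "group" is a multi-species statement |
| `consensus_threshold` | 0.8 (strict `>`) | fraction of members | super-majority annotation transfer |

## Numerical choices and degenerate inputs

* **"Exceeds 50"** is read strictly: a bit-score of exactly 50 is removed,
  while coverage of exactly 0.5 survives the inclusive "at least half".
  Both boundaries are pinned by tests and configurable.
* **Missing similarities inside the quartet.** If any of the six $S$
  values is not stored, the default policy skips that witness rather than
  imputing 0: an imputed zero inflates $\alpha$ by up to a quarter of the
  missing mass and manufactures duplication evidence out of filter
  drop-outs. The alternative (`impute_zero`) is implemented behind a flag
  for users who prefer recall of duplication evidence over robustness.
* **No-evidence sentinel.** "No witness anywhere" is `NA` in memory and
  `"NA"` in output files, never $-\infty$; such pairs are called orthologs
  at every cutoff.
* **MCL details.** Self-loops with weight equal to the node's maximum
  incident edge weight regularise the flow matrix before column
  normalisation; expansion (matrix squaring) alternates with inflation
  (entrywise power, renormalisation) and pruning of entries below `1e-5`;
  iteration stops when the matrix changes by less than `1e-6` or after 100
  rounds. Columns re-sum to 1 within `1e-9` after every renormalisation
  (asserted per iteration in tests). Clusters are the attractor-row
  supports; a node claimed by overlapping attractor systems goes to the
  cluster whose smallest member sorts first, and an emptied column (an
  extreme pruning artifact) is revived as its own singleton.
* **Inparalog splitting.** A failing component is split by removing its
  weakest internal edge, ties broken lexicographically by the edge's
  endpoint identifiers -- deterministic, and re-verified post hoc.
* **Degenerate inputs** -- empty FASTA, empty hit tables, empty stores,
  single-member clusters -- flow through every stage as empty results, not
  errors; genuinely malformed input (wrong column counts, unknown
  identifiers, duplicate identifiers) fails hard with the offending line
  or identifier named.

## The simulator: what it emulates, and what it does not

Because the method's claims are about recovering *known* evolutionary
history, the package ships a generator that produces corpora with ground
truth rather than fixtures. A species tree is drawn from the coalescent
(`ape::rcoal`: exponential inter-coalescence times, hence ultrametric); a
single ancestral gene enters a stem branch of length 1 above the root and
evolves by a linear birth--death process -- duplication rate `dup_rate` and
loss rate `loss_rate` per unit branch length per lineage -- splitting at
every speciation. Extinct subtrees are pruned and unary nodes suppressed,
so every internal node of the emitted gene tree is a labelled speciation or
duplication. Truth labels are read off that tree: a pair is orthologous
iff its most recent common ancestor is a speciation; true inparalog sets
are same-species genes whose pairwise ancestors are duplications with no
surviving speciation below them.

The ultrametric species tree is a deliberate choice, not a convenience.
The inparalog definition compares similarities ("closer to each other than
to anything abroad"), and similarity ranks mirror divergence-time ranks
only under a molecular clock; on a non-clock tree the set condition and the
"duplication after the last speciation" reading provably part ways, and no
detector based on similarities alone could satisfy both. For the same
reason a speciation whose entire other side went extinct is treated as
unobservable when truth labels are derived: it leaves no trace in either
the gene tree or the similarity store.

Similarity is simulated directly as
$S_{ij} = \max\{0,\; s_0\, e^{-\lambda d_{ij}} + \varepsilon\}$, with
$d_{ij}$ the gene-tree path length, $\varepsilon \sim N(0, \sigma^2)$ drawn
once per unordered pair, and pairs not exceeding the bit threshold omitted
-- mimicking hits that fall below the filter. Defaults $s_0 = 500$ (the
bit-score scale of a strong full-length hit between ~300-residue
proteins), $\lambda = 0.2$ per unit branch length (keeping within-family
scores in the realistic 50--500 range at coalescent tree depths), and
$\sigma = 10$ (a few percent of signal; noise-free checks set it to 0).
All randomness flows from one seeded generator, and the corpus writer
emits the exact file formats the pipeline consumes, so end-to-end runs are
exercised through the same interface as real data.

What the simulator does **not** emulate -- and hence what passing tests do
not show about real data: sequence evolution and alignment artifacts
(similarity is a clean monotone map of distance, real bit-scores are not),
rate heterogeneity across lineages and sites, horizontal transfer, gene
conversion, fragmented gene models, and domain-level chimerism. One
practical consequence of the clean exponential map at coalescent depths is
that deep hidden paralogy mostly manifests as *missing* witnesses (scores
below the storage threshold) rather than as large positive $\alpha$; real
corpora, with their greater dynamic range of divergence, populate the
$\alpha$ axis more broadly. The cutoff's monotone accuracy/coverage
trade-off -- the property that matters -- holds either way and is asserted
on simulated corpora.

## Problem sizes used by the test-suite

The suite runs entirely on generated data: quartet-score oracles on 1000
random six-tuples; exhaustive witness enumeration on 50 corpora of up to 6
species x 4 genes; clustering cross-checks against an independently coded
reference engine on 20 random graphs of up to 50 nodes; cutoff sweeps on an
8-species, 30-family corpus; parameter-recovery runs on five 6-species,
50-family noise-free corpora; and 100 small random stores for post-hoc
inparalog verification. These sizes keep the full suite under a couple of
minutes while leaving every code path multiply covered; all expected
values are either hand-computed, closed-form, or produced by the
independent oracles that live next to the tests.

## Known limitations

* Witnesses are exactly the pair (BBH of $x$, BBH of $y$) per third
  species; sub-optimal homologs in the third species are not enumerated.
  This is the intended trade of sensitivity for speed, and the extension
  point is deliberately left closed.
* Many-to-many BBH relaxations (score windows) are out of scope; co-
  orthology is expressed through inparalog expansion instead.
* Group construction is flat: no taxon-level hierarchy of groups.
* The consensus denominator counts unannotated members; an
  annotated-members-only variant is available behind
  `consensus_denominator = "annotated"`.
* Gene trees for groups (alignment + likelihood reconstruction) are not
  produced; the simulator's trees serve testing, not reporting.
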