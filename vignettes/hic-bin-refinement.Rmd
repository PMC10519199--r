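---
title: "Refining metagenome bins with Hi-C: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining metagenome bins with Hi-C: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicrefine)
```

## The problem

Metagenome binning groups assembled scaffolds by genome of origin. With only
one or a few samples there is no co-abundance signal across samples, and
composition plus single-sample coverage leaves many bins badly incomplete:
a genome ends up split across several bins, or much of it stays unbinned.
Hi-C proximity ligation offers orthogonal, physical evidence: a read pair
whose two mates map to *different* scaffolds (an informative pair) ties those
scaffolds to the same cell, hence the same genome.

`hicrefine` uses that evidence in two steps on top of an existing binning:

1. **merge** bins that the Hi-C link structure, coverage and composition all
   say belong to one genome, and
2. **recruit** unbinned scaffolds into bins via community detection on the
   scaffold link graph.

Both steps are driven by a *self-supervised* classifier: no reference
genomes are used; the training labels come from the initial binning itself.

## The pair classifier

For every scaffold pair $(s_1, s_2)$ connected by at least one Hi-C link we
compute six features from the link count $R$, the scaffold lengths
$l_1, l_2$, mean coverages $d_1, d_2$, coverage variances $v_1, v_2$ and
connection degrees $c_1, c_2$ (number of distinct link partners):

| feature | formula | reads as |
|---|---|---|
| f1 | $10^6 R/(l_1 l_2)$ | length-normalized link density |
| f2 | $10^6 R/(d_1 l_1 + d_2 l_2 + \epsilon)$ | coverage-normalized link density |
| f3 | $R/\max(c_1+c_2, 1)$ | link count vs. partner promiscuity |
| f4 | $\min(d_1,d_2)/\max(d_1,d_2,\epsilon)$ | depth compatibility |
| f5 | $\min(v_1,v_2)/\max(v_1,v_2)$ (with $\epsilon$) | variance compatibility |
| f6 | $\min(l_1, l_2)$ | shorter scaffold length |

with $\epsilon = 10^{-9}$ guarding divisions. The $10^6$ factor keeps f1/f2
away from floating-point underflow. All six are symmetric in the two
scaffolds. Pairs with no Hi-C link are never scored — scoring all
$O(n^2)$ pairs is both intractable and pointless, since without a link there
is no proximity evidence; downstream code treats them as probability 0.

**Self-supervised labels.** Large bins in a single-sample binning are the
trustworthy ones (the dominant failure mode is incompleteness, not
contamination), so the training set is drawn from the `train_bins = 10`
largest bins by total bp. Linked pairs inside one training bin are positives
(label 1, weight 1); linked pairs spanning two training bins are negatives
(label 0). A "negative" can actually be a same-genome pair that the binner
split across bins, so negatives carry a reduced weight,
`neg_weight = 0.5`. Negatives are subsampled to balance the classes (or
positives, when negatives are scarcer). A probability random forest
(`ranger`, 100 trees, per-row weights) is fitted on a stratified 70/15/15
train/validation/test split; accuracy, precision and recall are reported on
the untouched 15% test partition. The validation partition is reserved for
optional tuning and otherwise deliberately unused.

## Bin merging

The trained model yields $\mathrm{prob}(s, s')$ for every linked pair. With
cutoff `minscore = 0.5`, define $\mathrm{pair}(s, s') = 1$ iff
$\mathrm{prob} \ge \mathrm{minscore}$. For bins $b_i, b_j$:

* **link-rate score**
  $\mathrm{LR}(b_i,b_j) = \sum_{m}\sum_{n} \mathrm{pair}(s_{im}, s_{jn}) /
  (\mathrm{num}(b_i)\,\mathrm{num}(b_j))$ — the fraction of cross-bin
  scaffold pairs the classifier connects;
* **depth score** — the two-sided Welch t-test p-value comparing the two
  bins' per-scaffold mean-depth vectors (high p = compatible abundance);
* **TNF score** — cosine similarity of the bins' tetranucleotide-frequency
  vectors (136 reverse-complement-canonicalized 4-mer classes; a bin's TNF
  is the length-weighted mean of member TNFs).

Bins become nodes of a graph with an edge wherever all three scores clear
their thresholds (`lr_min = 0.1`, `depth_min = 0.05`, `tnf_min = 0.90`);
connected components are merged. The thresholds read naturally: at least
10% of cross pairs connected; fail to reject equal depth at the 5% level;
composition at least as similar as typical same-species scaffolds. They are
all user-exposed because no universal values exist.

Note the deliberate asymmetry of the gate: `depth_min` keeps *high*
p-values. Its p-value is uniform when two bins truly share one genome's
depth distribution, so roughly 5% of genuinely mergeable bin pairs will be
(conservatively) vetoed by the depth test. That type-I veto is inherent to
using a p-value as a similarity gate; with connected components a single
genome spread over more than two bins usually still coalesces through the
remaining edges.

## Scaffold recruitment

After merging, a weighted graph is built over *all* scaffolds — binned and
unbinned — with an edge for every pair with $\mathrm{prob} \ge
\mathrm{minscore}$, weighted by the raw probability (the thresholded
predicate discards confidence; the weights keep it). Label propagation
(default) or Louvain partitions the graph. An unbinned scaffold is recruited
iff its partition contains **exactly one** known bin; zero known bins means
there is nothing to join, two or more means the evidence is ambiguous and
the scaffold stays unbinned. Binned scaffolds are never reassigned —
recruitment only ever grows bins. Merging runs strictly before recruitment
so that recruitment sees the consolidated bins.

Label propagation is randomized; the implementation fixes a canonical
(sorted-id) vertex order and drives all randomness — negative subsampling,
the data split, the forest, the partitioning — from one master seed through
named sub-seeds, so a run is a pure function of inputs and seed
(byte-identical output files, as the test suite asserts).

## Inputs and conventions

* **Scaffold floor:** scaffolds shorter than `min_len = 1500` bp are removed
  from every computation, matching standard binner practice; composition and
  coverage are too noisy below that.
* **Alignment filter:** records with any bit of SAM flag 2316 set (unmapped,
  mate unmapped, secondary, supplementary) are dropped, as are records with
  the duplicate bit 1024 (so BAMs with pre-marked PCR duplicates behave the
  same as upstream-deduplicated ones). The MAPQ filter defaults to off
  (`mapq_min = 0`). Mates are joined by read name; only pairs spanning two
  different scaffolds count.
* **Depth tables:** metaBAT-style TSV; `totalAvgDepth` is the mean and the
  first sample's variance column is the variance — the single-sample regime
  is the method's target.
* **Degenerate depth tests:** two constant profiles score 1 if their means
  agree and 0 otherwise; a single-scaffold bin falls back to a pooled
  (equal-variance) test borrowing the other bin's variance, or to 1 when
  that is degenerate too. Real bins are frequently tiny, so these cases are
  conventions, not corner cases.
* **Ties:** training-bin selection breaks total-bp ties lexicographically;
  merged bins get fresh ids `merged_<k>` recording their parents in the run
  report.

## The synthetic community generator

`simulate_community()` builds a mock community in the style of a staggered
mock standard, with full ground truth, so the entire pipeline is testable
without any sequencing data:

* **Composition.** Each genome draws its own order-3 Markov chain
  (Dirichlet(1) transition rows), giving genome-specific TNF signatures
  without real sequences.
* **Abundance.** Genome mean depths are log-spaced across 5–80×: staggered
  designs are the norm for mock communities precisely because they make
  abundance informative. Per-scaffold depth is Gaussian around the genome
  mean (sd = 10% of the mean, truncated at 0) and the variance column is set
  consistently with that noise.
* **Fragmentation.** Genomes (~300 kb nominal, ±15%) are cut into scaffolds
  of 2–12 kb, all above the 1500 bp floor, with genomic positions retained.
* **Hi-C links.** Intra-genome pairs at genomic distance $d$ draw
  $\mathrm{Poisson}\!\left(r_\mathrm{intra}(1 + d/d_0)^{-\alpha}\right)$
  links with $r_\mathrm{intra} = 10$, $d_0 = 20$ kb, $\alpha = 2$ — the
  power-law contact decay characteristic of proximity ligation. Inter-genome
  pairs draw $\mathrm{Poisson}(0.25)$ background links. The decay matters:
  it is what makes cross-bin same-genome pairs a *minority* of the
  self-supervised negatives (the label noise the reduced negative weight
  exists for) while still leaving enough boundary-spanning links for split
  halves to be re-merged. A uniform intra-genome rate would make the noisy
  negatives feature-identical to positives and the self-labels unlearnable.
  Setting equal intra/inter rates with $\alpha = 0$ gives the null
  community used as a negative control.
* **Scenarios.** `split` halves every genome's bin (completeness ~0.5,
  the merge test case); `holdout` unbins a fraction (default 30%) of each
  genome's scaffolds (the recruitment test case); `mixed` does both.

What the generator does **not** emulate: strain-level variation, shared or
horizontally transferred sequence between genomes, restriction-site and
GC biases of real Hi-C libraries, chimeric scaffolds, plasmids, and
eukaryote-sized genomes. Passing tests on this generator therefore
demonstrate the machinery is correct and self-consistent — not that the
default thresholds are optimal for any particular real community.

## Problem sizes used by the tests

The packaged checks run the full pipeline on the default community
(8 genomes × ~300 kb ≈ 2.4 Mb, ~360 scaffolds, ~12k linked pairs) for the
split, holdout and null scenarios, and smaller 4-genome communities for
module-level properties; these sizes exercise every code path in seconds
while keeping the statistics stable (hundreds of test pairs, hundreds of
held-out scaffolds).

## Known limitations

* The method needs informative Hi-C pairs; with sparse inter-scaffold
  connectivity the training-set constructor fails loudly rather than
  producing a weak model.
* Negatives drawn from split genomes remain mislabeled at training time; the
  weighting mitigates but does not remove them, so held-out "accuracy" is
  measured against noisy self-labels and slightly understates accuracy
  against truth.
* Contamination removal (splitting impure bins) is out of scope: merging and
  recruitment only ever grow bins.
* Louvain optimizes modularity and can absorb weakly-linked satellite
  scaffolds more aggressively than label propagation; LPA is the default for
  that reason.
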