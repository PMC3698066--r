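---
title: "Single-gene phage typing: methods and design notes"
author: "tmpclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-gene phage typing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmpclust)
```

## The problem

Mycobacteriophages (and siphoviruses generally) are organised into clusters
and subclusters by whole-genome comparison, but genome mosaicism — segments
with distinct evolutionary histories exchanged horizontally — makes
whole-genome alignment unreliable and whole-genome phylogenetics awkward. A
single, ubiquitous, evolutionarily stable marker gene offers a shortcut: the
tape measure protein (TMP) gene, typically the longest gene in a siphovirus
genome (~3 kb), tracks whole-genome cluster assignments closely. `tmpclust`
implements that idea end to end: classify a phage from its TMP sequence
alone, design subcluster-specific degenerate PCR primers inside TMP so the
assignment can be made at the bench without sequencing, and quantify how
well marker-gene trees reproduce genome trees.

## Dotplot classification

The classifier operationalises what a trained eye does with a dotplot
gallery. A dotplot between sequences $a$ and $b$ at word length $w$ marks a
hit at $(i, j)$ whenever the $w$-mer starting at $i$ in $a$ equals the
$w$-mer starting at $j$ in $b$; homology shows up as diagonal runs. The
scalar evidence used for classification is the word coverage

$$\mathrm{cov}(a \mid b) = \frac{|\{\, i : \text{word } i \text{ of } a
\text{ occurs anywhere in } b \,\}|}{|a| - w + 1},$$

and a query is assigned the cluster/subcluster of the panel sequence with
the highest coverage, or left unassigned when the best coverage falls below
a threshold. Defaults:

* `word_length` 10 for nucleotide, 3 for amino acid — the classic dotplot
  defaults; the underlying figures do not state the exact word size, so it
  is a parameter.
* `threshold = 0.25`. This is calibrated against the published singleton
  behaviour: a phage sharing only ~10% TMP word similarity with its
  nominal cluster is called a singleton, while a phage showing "almost 50%"
  similarity to a neighbouring cluster is not. A quarter of words covered
  sits between those anchors. The threshold is exposed everywhere.
* Coverage ties are broken by global-alignment percent identity, then
  lexicographically by reference id, so calls are deterministic.

At ~10% within-subcluster nucleotide divergence the expected fraction of
intact 10-mers is roughly $0.9^{10} \approx 0.35$, comfortably above the
threshold; between unrelated clusters coverage is essentially the word
collision rate, $\sim 10^{-3}$. That separation is why a single gene
suffices.

## Alignment machinery

`global_align()` is a Gotoh affine-gap aligner (written in C++ via Rcpp)
with the marker-gene protocol's parameters as defaults: match $+5$,
mismatch $-4$, gap open 12, gap extension 3, free end gaps. A gap of length
$k$ costs $12 + 3k$. Ties in the traceback resolve diagonal > up > left,
making alignments deterministic. Percent identity counts identical residue
columns over columns where at least one sequence has a residue; under free
end gaps the terminal overhangs are excluded from the denominator (the
published identity tables do not state their denominator; this choice is
switchable via `exclude_overhangs`).

`msa()` is a small progressive aligner: pairwise identity distances, a
neighbor-joining guide tree, then profile–profile merges under the same
scoring. It approximates the classic ClustalW procedure rather than cloning
it, which is why identity statistics on real alignments should be treated
as tolerance-level reproductions except in the degenerate case of fully
identical inputs (where 100% is forced). The aligner stores only traceback
pointers plus rolling score rows, so marker-gene-scale inputs (up to ~7 kb)
align in modest memory; megabase genome alignment is out of scope.

## Primer design and in-silico PCR

Subcluster-specific primers come from conserved windows of a subcluster's
TMP alignment: every gap-free window of 16–22 columns whose column-wise
consensus (the minimal IUPAC code covering the observed bases per column)
has at most 3 degenerate columns. Gapped columns disqualify a window
because a primer has a fixed length. Pairs are formed from an upstream
window (forward primer = consensus) and a downstream window (reverse primer
= reverse complement of consensus) whose predicted product — inclusive of
both primer footprints, in 1-based inclusive coordinates — lies within
`product_range` (default 150–900 bp, bracketing the published products of
205–873 bp) on every row. Pairs are ranked by total degeneracy, then product
length, and capped at a combined degeneracy of 64 (product of per-base set
sizes across both primers; the most degenerate published pair reaches 48).

`insilico_pcr()` matches the forward primer IUPAC-wise on the plus strand
and the reverse primer as its reverse complement downstream, plus the
mirror-image orientation, so results are strand-symmetric. A degenerate
template base (including N) matches no primer base — the conservative
default for screening, relaxable with `match_template_n`. Zero mismatches
outside IUPAC degeneracy is the default; `max_mismatch` exists for
robustness studies. Melting temperature, hairpin and dimer screens are
deliberately absent — the protocol being modelled did not use them.

## Alignment-free phylogenetics

`ffp_profile()` counts sliding 20-mers (feature frequency profile);
`ffp_distance()` is the Jensen–Shannon divergence between normalised
profiles. The divergence measure is fixed to JSD — the standard choice in
the FFP literature — because the source protocol does not name its measure;
JSD is symmetric, bounded by $\ln 2$, and zero iff the normalised profiles
coincide. Trees are neighbor-joining (`ape::nj`) with negative branch
lengths clamped to zero. `bootstrap_consensus()` resamples features (for
profiles) or columns (for alignments) with replacement, rebuilds a tree per
replicate and keeps splits above 50% occurrence; the resampling unit is a
package decision since the protocol does not state one, and both units are
available.

Tree comparison uses the Matching Splits distance: a minimum-cost perfect
matching (Hungarian algorithm) between the two trees' non-trivial splits,
where matching two splits costs the smaller symmetric-difference size over
the two side pairings. When split sets differ in size, the smaller set is
padded with dummy splits costing the unmatched split's smaller side size —
the padding convention had to be fixed and this one makes the distance to a
star tree equal the sum of each split's smaller side, which is the
normaliser used for the "percent different" figure (582/722 = 81% in the
worked comparison). The genealogical sorting index of a group is
$(n-1)/\sum_{u}(d_u - 1)$ over the internal nodes uniting the group up to
its most recent common ancestor, rescaled between its tree-wide minimum and
1; it is exactly 1 iff the group is monophyletic. gsi needs a rooted tree;
`clade_recovery()` midpoint-roots unrooted input, and an outgroup leaf can
simply be included like any other.

## The synthetic panel generator

`generate_panel()` emulates a labelled phage collection. Defaults: 5
clusters × 2 subclusters × 2 members (4 members per cluster), 20 kb genomes
with a 3 kb marker embedded at position 2001, per-subcluster divergence
0.20 from the cluster ancestor and per-member divergence 0.05 from the
subcluster ancestor. Substitutions are uniform over the three alternative
bases, so two members at rate $r$ agree per site with probability
$(1-r)^2 + r^2/3$ (≈0.903 at $r = 0.05$) — the quantity the generator tests
verify. Cluster ancestors are independent random sequences by default
because real clusters share little nucleotide similarity; `shared_root`
exists for experiments needing a connected phylogeny. Indel and
mosaic-swap rates default to zero — substitution-only panels keep the
identity expectations exact and the marker trivially extractable;
`mosaic_swap()` adds cross-cluster segment transfers (marker-protected by
default) for experiments on mosaicism, and can be applied repeatedly to
accumulate heavy mosaicism.

What the generator does *not* model: codon structure, gene content
evolution, recombination hotspots, GC skew. Tests passing on these panels
show the machinery behaves as designed under clean cluster structure, not
that real phage collections will classify at the same rates.

## Problem sizes and numerical choices

The packaged experiments run on deliberately modest sizes chosen so the
full suite re-runs in about a minute: default panels of 20 genomes for
classification and primer screening, and a 24-genome, 4-cluster panel for
the tree contrast. The genome-versus-marker FFP contrast uses a
divergence-stressed configuration (per-member rate 0.18, 3 members per
subcluster) rather than the defaults: the published degradation of
marker-only trees is driven by sequence length — a 3 kb gene carries too
few shared 20-mers once divergence is appreciable, while a 20 kb genome
still carries enough. At per-member rate $r$ the expected shared-20-mer
count between two members is $((1-r)^2 + r^2/3)^{20} \cdot (\ell - 19)$:
at $r = 0.18$ that is ~10 for 20 kb genomes but ~1.5 for a 3 kb gene, which
is exactly the regime where the genome tree resolves subclusters and the
marker tree cannot. At the default $r = 0.05$ both lengths carry hundreds
of shared features and both trees succeed, so the defaults are kept for
classification while the contrast experiment states its own configuration.

Other numerical conventions: all reported coordinates are 1-based inclusive
(the wet-lab convention for primer positions; this package uses it
internally too rather than a 0-based scheme); the Wald interval is computed
on the unrounded proportion — note that 244/247 gives a half-width of 1.37
at two decimals, while the published 1.36 arises if the proportion is first
rounded to 0.988; coverage ties and DP traceback ties have fixed
deterministic orders; empty sequences align to an all-gap result with score
0 under free end gaps.

## A worked example

```{r example}
cfg <- synth_config(seed = 42)
p <- generate_panel(cfg)
labs <- label_table(p$truth$id, p$truth$cluster, p$truth$subcluster)
panel <- reference_panel(p$tmp_genes, labs)

calls <- classify_panel(p$tmp_genes, panel, loo = TRUE)
evaluate_recovery(calls, p$truth)
```

```{r primers}
rows <- msa(p$tmp_genes[p$truth$subcluster == "A1"])
pairs <- design_primer_pairs(find_conserved_windows(rows), rows, group = "A1")
pairs[1, c("group", "forward", "reverse", "product_length")]
insilico_pcr(p$tmp_genes[["phage_A1_1"]], pairs[1, ])
```

## Known limitations

* The classifier is only as good as its reference panel; a query from a
  genuinely novel cluster is reported `unassigned`, never as a new cluster.
* The progressive MSA is a pragmatic stand-in for a production aligner;
  for large or highly gapped alignments use a dedicated MSA tool and feed
  the rows back into `find_conserved_windows()`/`identity_stats()`.
* Maximum-likelihood and Bayesian tree inference are out of scope; trees
  built elsewhere can be read as newick and evaluated with
  `matching_splits()`, `gsi()` and `clade_recovery()`.
* In-silico PCR models annealing as exact IUPAC matching, not
  thermodynamics.
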