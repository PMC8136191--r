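---
title: "Detecting lineage-specific selection signatures in a mitochondrial gene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lineage-specific selection signatures in a mitochondrial gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selsig)
```

## The scientific problem

Several rodent lineages have independently colonised the subterranean
niche, a hypoxic, energetically demanding environment. Because
mitochondrially encoded proteins sit at the core of oxidative
phosphorylation, a recurring question is whether such ecological shifts
leave detectable signatures in genes like cytochrome *b*: an elevated
ratio of nonsynonymous to synonymous substitution rates (ω = dN/dS) on
the foreground branches, an uneven distribution of replacements across
protein domains, physicochemically radical replacements, and — most
strikingly — the same derived amino acid arising in unrelated foreground
lineages.

`selsig` packages that comparative workflow. The phylogeny is an input
(tree inference is out of scope): every branch is classified
`foreground`, `background`, or `excluded` (outgroup), and all analyses
contrast the first two classes. The package also owns a codon
simulator, so each analysis stage can be validated against data whose
true history is known.

## Branch labeling

`label_branches()` supports two modes. `terminal` labels only the
pendant branches of foreground taxa — appropriate when each foreground
species represents an independent colonisation. `clade` additionally
labels the stem and internal branches of every maximal all-foreground
clade, treating a monophyletic group of foreground species as one event
(the default, matching how a subterranean genus would be handled).
Outgroup branches are `excluded`: they are omitted from the counting
contrasts, and evolve under the background ω in the likelihood model.
Whether outgroup branches should instead count as background in the
contrasts is genuinely open; exclusion is the conservative default
because outgroup sampling is usually sparse and divergent.

*Independent lineages* are connected components of foreground branches:
two foreground branches belong to the same lineage exactly when they are
linked through foreground ancestors.

## Substitution mapping

Ancestral states are reconstructed per codon site by Fitch parsimony
over the sense-codon state space — codon-level states keep the
synonymous/nonsynonymous decomposition well defined per event. Missing
codons (anything containing a non-ACGT symbol) contribute the full
sense-codon set and impose no constraint. Ties are resolved
deterministically: the top-down pass prefers the parent's state whenever
it lies in the child's candidate set (pushing changes tipward), and
otherwise takes the lexicographically smallest candidate.

A multi-nucleotide codon change is decomposed by enumerating all
orderings of its single-nucleotide steps, discarding pathways through
stop codons, scoring each step by the genetic code, and averaging over
surviving pathways. If every pathway is blocked (rare), the
decomposition falls back to endpoint comparison and the event is
flagged.

Parsimony mapping, not stochastic mapping, is used deliberately: the
downstream statistics are counts of discrete events, the method is
deterministic and assumption-light, and the simulator's true event logs
show that at realistic divergences ≥90% of single-hit events are
recovered exactly (see the test suite).

## Counting contrasts

For a domain *D* (or a single site), the foreground event count *a* is
compared against its *opportunity* — the number of codon sites in *D*
times the number of foreground branches — and likewise for the
background, giving a 2×2 table tested with the two-sided Fisher exact
test (sum of hypergeometric probabilities ≤ the observed table's, with a
1e-12 relative tolerance on the comparison so exact ties are included).

Multiplicity is handled with the Holm step-down. Two points matter:

- The family for the domain scan is **all domains × both substitution
  classes jointly** (34 tests for the 17-region cytochrome-*b* map) —
  the only family size consistent with published raw/adjusted pairs for
  this kind of scan. `holm_adjust()` therefore takes an explicit
  `family_size`, so a printed subset of the smallest p-values can be
  adjusted against the family it came from.
- The reported frequency is events per codon site per branch of the
  class. Published tables of this kind print frequencies without
  defining the denominator; this convention is declared here and in the
  output metadata, and it will not numerically reproduce frequencies
  computed under an unknown alternative normalisation.

Amino-acid usage patterns (`aa_site_patterns()`) test, per site and per
amino acid, whether the fraction of sequences carrying that amino acid
differs between groups. Sequences, not species, are the sampling unit —
the design explicitly accommodates heavily unbalanced groups (hundreds
versus thousands of sequences) and intraspecific variation. Per-amino-
acid 2×2 tables are used rather than a full 2×K exact test: they remain
computationally exact, are interpretable per residue, and one surviving
amino-acid test suffices to call the site significant.

## Radicality

The property table ships 31 physicochemical scales drawn from the
published AAindex collection (hydrophobicity, volume, polarity, charge,
secondary-structure propensities, energy terms; accessions in
`inst/extdata/aa_properties_31.tsv`) and is fully configurable via
`read_property_table()`. For each property, the absolute property
change of every replacement reachable by a single nucleotide change is
binned into 8 equal-width categories over [0, max]; boundary values go
to the higher category, so the maximal change is always category 8, and
the binning is invariant to rescaling the property. Categories 6–8 are
"radical".

The scan statistic is a sliding-window z-score (window 20 codons, step
1): within a window holding *N* nonsynonymous events, the count in
category *c* is compared to the binomial expectation *N·p~c~*, where
*p~c~* is the category's share among **all** single-nucleotide
nonsynonymous sense-codon changes, weighted uniformly. A uniform
neutral distribution is the simplest defensible null; codon-usage
weighting is a documented alternative, not the default. An event is
flagged radical when, for at least one property, it is in category ≥ 6
and lies in a window where that (property, category) shows a positive
z with one-tailed p < 0.001. The binomial variance form is one of
several plausible z-test variants in this family of methods; it is
declared here and used consistently.

## Convergence

`find_convergent()` reports (site, derived amino acid) pairs carried by
at least `min_lineages` (default 3) independent foreground lineages and
absent from every background sequence at that site. A lineage is
witnessed either by a mapped foreground event ending in that amino acid
or by a foreground leaf carrying it. The leaf-state witness is needed
for robustness: when a single foreground tip holds a unique codon,
parsimony may with equal cost place the change on the adjacent
background branch (the classic ACCTRAN/DELTRAN ambiguity), and an
event-only rule would then miss a genuine foreground replacement.
Because the amino acid must be absent from the entire background, a
foreground leaf carrying it is itself evidence of a derived replacement
on that terminal lineage.

## The codon model and branch tests

The rate matrix is GY94-style on the 60 sense codons of the vertebrate
mitochondrial code: `q_ij = π_j · κ^[transition] · ω^[nonsynonymous]`
for single-nucleotide neighbours, zero otherwise. Codon frequencies are
fixed at F3x4 estimates (positional nucleotide frequencies, floored at
1e-8 and renormalised so π stays strictly positive). The matrix set is
scaled so one unit of branch length equals one expected substitution
per codon **under the background ω**; foreground branches reinterpret
their lengths under the foreground ω. Per-class scaling is available
but not default. κ is shared across classes.

Likelihoods use Felsenstein pruning over compressed site patterns, with
per-branch transition matrices from the eigendecomposition of the
symmetrised reversible generator (`S = D Q D⁻¹`, `D = diag(√π)`), and
per-pattern log-scaling against underflow; the recursion runs in
compiled (RcppArmadillo) code. Missing codons are summed over all sense
states.

Three models mirror the classic branch analysis: `M0` (one ω),
`b_free` (ω_fg, ω_bg free), `b_neut` (ω_fg ≡ 1). In all of them κ and
a global branch-length scale are re-estimated — including the
background ω in `b_neut`, since the nested comparison is against
`b_free`, not `M0`. Optimisation runs on log-parameters with bounded
PORT iterations (relative tolerance 1e-10, which holds the optimum to
well below 1e-6 log-likelihood units) from two deterministic starts
(ω = 0.2 and 1.5), keeping the better; fits report `boundary` or
`no_convergence` status instead of failing, because degenerate inputs
(e.g. invariant alignments) leave ω unidentifiable. LRTs use
`max(0, 2Δln L)` against χ² with df = 1 for both standard comparisons.

## The simulator and what the tests do (and do not) show

`simulate_codon_alignment()` draws root codons from π and evolves each
site along each branch by exact Gillespie simulation under the branch
class's scaled generator, recording every realised event. Replaying
the log reproduces the leaf sequences exactly, which pins down the
mapping stages against ground truth. All randomness flows from a single
mandatory seed.

`study_like_scenario()` fixes the simulation conditions used throughout
the tests: a 31-leaf tree with five phylogenetically independent
foreground lineages (an early-diverging singleton, a four-leaf
foreground clade, three scattered singletons — the layout of
subterranean lineages within a vole radiation), 381 codons (a
cytochrome-*b*-length protein), κ = 4, background ω = 0.03, foreground
ω = 0.08, uniform codon frequencies, branch lengths in expected
substitutions per codon totalling ≈ 3.7 across the tree. Within this
design, parameter-recovery runs use the stronger published-style
contrast ω_fg = 0.1325 / ω_bg = 0.0269; the null-calibration runs (200
replicates under single-ratio truth) use 150 codons, a deliberate
reduction — the χ² calibration of the LRT does not depend on alignment
length, while recovery and power replicates stay at full length with
20 replicates.

What passing tests show: the arithmetic of every statistic is right
(enumeration and closed-form oracles), the ML machinery recovers known
parameters without bias at realistic information content, the LRT holds
its nominal level, and the convergence pipeline flags exactly the
planted signal. What they do not show: behaviour under real-data
features the simulator omits — among-site rate variation, selection
heterogeneity along the gene, codon-usage skew (the default π is
uniform), indels and alignment error, saturation on deep branches, or
intraspecific polymorphism. Results on real alignments inherit those
caveats, as they do for any codon-model analysis.

## Numerical and design notes

- Coordinates are 1-based inclusive everywhere; codon site *i* occupies
  nucleotides 3i−2..3i.
- Any codon containing a non-ACGT symbol is missing data — in mapping
  it contributes no constraint, in the likelihood it is summed over.
  Internal stop codons are an error in strict mode (masked under
  `strict = FALSE`); a terminal stop column is always masked.
- The Fisher tie tolerance (1e-12 relative), the Holm family sizes, the
  z-score window (20), the radical category threshold (6) and its alpha
  (0.001), and the lineage threshold (3) are all exposed as arguments
  with these defaults.
- Exact tests on sparse 2×2 tables are conservative; the site-level
  scan's attained level is below nominal at realistic event densities.
- `run_pipeline()` is the file-level entry point (YAML config in, TSV
  bundle out, stage-tagged errors, byte-identical reruns for a fixed
  config and seed).

## Known limitations

Parsimony undercounts on long branches (multiple hits); the branch
model assumes a single ω per class along the whole gene; the radicality
null ignores codon usage; convergence detection conditions on strict
absence in the background, so a single background carrier (including
sequencing error) suppresses a site; and the simulator's homogeneity
means power estimates are optimistic relative to heterogeneous real
data.
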