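---
title: "Dissecting phylogenomic conflict: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting phylogenomic conflict: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`polyconflict` re-implements, as a tested pipeline over synthetic data with
known ground truth, the discordance-dissection and paleopolyploidy-inference
machinery used in phylotranscriptomic studies of plant radiations: gene-tree
curation, a coalescent simulation test for cytonuclear conflict, quartet
concordance-factor hypothesis tests, ABBA-BABA D statistics, shared-gene-
duplication mapping, multilabeled-tree reconciliation, and Ks mixture
modeling.  This vignette explains each model, its assumptions, the tunable
parameters, and the places where design decisions were genuinely open.

## The multispecies coalescent engine

All discordance tests rest on the multispecies coalescent (MSC): gene
lineages evolve within the branches of a species tree whose internal branch
lengths are in coalescent units (CU; time divided by population size, so two
lineages in one population coalesce at rate 1).  `simulate_msc_gene_trees()`
samples one lineage per species (matching a one-transcriptome-per-species
design), runs the standard coalescent within each branch of length `scale ×
CU`, and lets remaining lineages coalesce freely above the root.

For a quadruple of species with an internal branch of length *t* separating
the two pairs, the concordant unrooted quartet appears in a gene tree with
probability 1 − (2/3)e^(−t).  The simulator is calibrated against this
closed form at t ∈ {0, 0.5, 1, 2, 5} (10,000 trees per point, three binomial
standard errors).

Two policies deserve mention:

* **Terminal branches.**  Coalescent-summary species trees (e.g. ASTRAL
  output) carry no terminal branch lengths.  The simulators assign a default
  of 2 CU to missing terminal branches (`default_tip_len`), applied before
  the `scale` multiplier; the value is exposed because no published
  convention exists.  Setting `default_tip_len = NULL` makes missing lengths
  an error.
* **Non-ultrametric trees.**  Branch lengths are taken as given; each
  lineage enters a branch at the branch's own start, so MSC simulation is
  branch-local.  Introgression simulation additionally needs a global time
  axis and therefore requires a time-consistent (ultrametric) species tree.

`simulate_network_gene_trees()` adds introgression edges: at the event time,
every lineage on the recipient branch independently moves to the donor
branch with probability γ.  γ = 0 reduces exactly to the MSC; γ = 1 is the
MSC on the rewired tree.  The per-gene truth (how many lineages moved, and
for which species) is returned so that power analyses can condition on the
realized history.

## The plastome ILS test

If incomplete lineage sorting alone explains a conflict between the nuclear
species tree and the plastid tree, the plastid tree's clades should be
common among genealogies simulated under the MSC on the nuclear tree.
`plastome_ils_test()` simulates `n_sim = 10000` genealogies with every
branch multiplied by `scale = 4.0` — the conventional factor for a haploid,
uniparentally inherited organellar genome (effective population size one
quarter of the nuclear autosomal value) — and reports each plastid clade's
frequency.  Clades absent from the nuclear topology ("unique" clades) with
frequency at or below `threshold = 0.15` are classified ILS-implausible,
pointing at hybridization (e.g. chloroplast capture) instead.

The 15% default mirrors the reading of observed results rather than a
published cutoff, and is exposed.  Note the classification is one-sided by
construction: a *low* simulated frequency is evidence *against* ILS as the
sole cause.

## Quartet concordance factors and the T1/T3 tests

For every quadruple of taxa, the counts (n1, n2, n3) of the three possible
resolutions across gene trees (the quartet count concordance factor) should,
under the MSC, follow a multinomial with probabilities (1 − 2μ, μ, μ),
μ ≤ 1/3.  Two likelihood-ratio tests are provided:

* **T3** — no species tree assumed: the concordant class is the modal count;
  μ̂ = min((n − n_max)/(2n), 1/3).
* **T1** — the species tree fixes the concordant class, so a modal count
  that contradicts it inflates the statistic and is rejected.

The null hypothesis sits on the boundary of the parameter space and the
published tests use bespoke asymptotics.  Here the default calibration is a
parametric bootstrap (B = 2000) from the fitted null, which is
assumption-light and empirically calibrated: under a (0.6, 0.2, 0.2)
multinomial with 365 gene trees, the empirical type-I error at α = 0.01 sits
inside the exact binomial 99% interval over 2000 replicates.  A χ²(1)
approximation (`pvalue_method = "chisq1"`) is offered for speed; it is
conservative near the boundary.  α defaults to 0.01.

Rejected quadruples are mapped back onto the species tree by
`map_rejected_quartets()`: every internal edge on the path forming the
induced quartet's internal edge is incremented.  Gene flow concentrates
rejections around particular branches; gene-tree estimation error spreads
them uniformly.  The attribution rule (all edges on the path) is this
package's construction — the mapping used in the literature is not
specified — and is validated on caterpillar examples where the path is
known.

`eqp_ic()` scores each internal edge by an internode-certainty-style measure
over the quadripartition around it: quartets with one taxon per part are
aggregated into (q1, q2, q3) with q1 the species-tree resolution, and the
score is 1 + Σ p_i log₃ p_i, negated when the modal resolution conflicts.
It is 1 for complete concordance, 0 at maximum entropy, negative when a
conflicting resolution dominates, and monotone in the reference frequency.
Published per-edge certainty scores differ in aggregation details; this is a
documented, testable analogue, not a byte-level reimplementation.

## D statistics

`count_site_patterns()` applies the strict biallelic rule: only gap-free,
unambiguous sites with exactly two states among the four rows count, with
the outgroup state ancestral.  D = (nABBA − nBABA)/(nABBA + nBABA);
significance comes from resampling alignment columns with replacement
(`n_boot = 200`), Z = D/SD and a two-tailed normal p-value, with
Holm-Bonferroni correction across all combinations of a four-group design
and the two-condition significance rule Z > 3 *and* adjusted p < 0.05.
Designs are summarized by the fraction of significant combinations: above
50% "significant gene flow", below 10% "insignificant", and the unnamed
middle band is reported as "ambiguous".

**Resampling unit.**  The default bootstrap unit is the single site
(`block = 1`).  On a concatenation of coalescent gene blocks this is
anticonservative: sites within a gene share a genealogy, the between-gene
variance dominates, and single-site resampling understates the SD of D (in
our experiments up to ~18% of no-gene-flow concatenations reached |Z| > 3).
The `block` argument restores calibration by resampling contiguous blocks
(set it to the gene length); the null-calibration checks in the test suite
use iid sites on a fixed symmetric tree, where the single-site bootstrap is
the correct unit.  Which unit the original analyses used is not stated in
the literature this mirrors; both are exposed.

## Gene-tree curation

`select_orthogroups()` retains an orthogroup iff every species is present
(configurable via `min_presence`), the mean copy number is ≤ 5 and the
median ≤ 2.  The mean/median are taken over species with at least one copy;
`include_absent = TRUE` includes zeros, since the convention is unstated.

`prune_long_branches()` iterates to a fixed point: branches longer than 0.5
substitutions/site are cut (keeping the larger component; ties keep the
rootward side), then terminal branches longer than 0.2 *and* more than 10
times the longest terminal branch of their sister clade are pruned.  The
sister-clade statistic is the *maximum* by default ("10× longer than that
(or those) representing its sister clade" is ambiguous between max and
mean); max is the conservative reading — it prunes less — and `sister_stat =
"mean"` is available.  Absolute cuts run before the ratio rule on each
sweep.  Trees reduced below `min_tips = 4` come back flagged as discarded,
not as errors, so batch curation can log and continue.

`extract_rt_orthologs()` implements rooted-tree orthology: root on the
outgroup copies, then walk rootward-to-tipward; a node whose child subtrees
share a species is a putative duplication and only the child with more
distinct species survives (ties: more tips, then the lexicographically
smallest species set — fully deterministic).  Maximal single-copy subtrees
with at least `min_taxa` species are emitted.  On duplication-free homolog
trees the input comes back unchanged, and every output is strictly
single-copy per species by construction (asserted over simulated inputs).

## Duplication mapping (ladder profiling)

`simulate_dl_gene_trees()` runs a birth-death process of gene lineages down
the species tree (rates per CU per lineage), with an optional whole-genome
duplication at a chosen node: every lineage arriving there duplicates and
the extra copy survives with probability `retention`.  Gene copies are named
`species@k` and a taxon map is emitted; per-tree truth records every
surviving duplication's species branch.  Families reduced to fewer than two
copies are redrawn (the redraw count is reported), i.e. simulation is
conditioned on family survival.

`maps_analysis()` walks a ladder of nested clades from a seed taxon to the
root.  At each ladder node it examines the maximal gene subtrees that
LCA-map to that node, contain both ingroup and sister copies, and branch
concordantly with the ladder (strictly nested MRCAs of one representative
per group); a subtree supports a shared duplication iff it contains a node
mapping to the ladder node with ingroup taxa in both children.  The
percentage of supporting subtrees per node is the profile.  With a clean WGD
(full retention, no background rates) the true node scores 100% and all
others 0%; at retention r the expected percentage tracks r closely (a
simulated WGD with r = 0.5 yields ≈48%, comparable to the ~40% bursts
reported in empirical work).

`maps_significance()` compares observed per-node counts against pooled
simulated null (no WGD) and positive (WGD) replicates by one-sided Fisher
exact tests; a node is WGD-like iff significantly above the null and not
significantly below the positive expectation.  Two choices are deliberate:

* Counts are pooled across replicates rather than rank-tested per replicate
  — simpler and transparent; the replicate structure is still available to
  callers.
* The null-comparison p-values are Holm-adjusted across ladder nodes by
  default (`adjust = "holm"`): per-node tests at α = 0.05 over several nodes
  would false-flag a large fraction of WGD-free data sets, while the real
  WGD signal sits many orders of magnitude below α and is unaffected.

## MUL-tree reconciliation

`build_mul_tree()` grafts a second copy of the hypothesized polyploid clade
H1 onto an edge H2 (halfway along); `h2 = h1` is the autopolyploidy
hypothesis (the copy attaches to H1's own stem).  `mul_reconcile()`
minimizes the LCA duplication+loss score over assignments of each ambiguous
gene copy to either MUL copy — exhaustively up to `cap = 12` ambiguous tips,
beyond that by a greedy descent over 1- and 2-flip neighbourhoods from
deterministic starts (validated to agree with the exhaustive mode on
simulated instances).  The reconciliation core is compiled (Rcpp), since a
hypothesis search evaluates hundreds of gene trees × hypotheses ×
assignments.

`grampa_search()` ranks all (H1, H2) hypotheses and the singly-labeled tree
by total score.  One subtlety: a MUL tree whose grafted copy lies outside
every gene root's LCA map incurs *no* penalty under standard LCA loss
counting (losses above the gene root are not charged), so such hypotheses
tie the baseline exactly while explaining nothing.  Ties are therefore
resolved in favour of the singly-labeled tree, then fewer duplications, then
lexicographic hypothesis id; a polyploidy hypothesis must strictly beat the
baseline to rank first.  With allopolyploid simulations (both subgenomes
retained, moderate loss) the true (H1, H2) ranks first and beats the
baseline; WGD-free simulations leave the baseline on top.

## Ks estimation and mixture modeling

`ng86_ks()` implements Nei-Gojobori (1986) counting: per-codon synonymous
site fractions averaged between the two sequences, multi-hit codons resolved
by averaging over all minimal substitution pathways, and the Jukes-Cantor
correction Ks = −(3/4)ln(1 − (4/3)pS) (undefined at pS ≥ 3/4, reported via a
flag rather than an error).  Pathways passing through a stop codon get zero
weight (unless all do), and mutations that would create stops count as
nonsynonymous in the site tallies.  The implementation is checked codon by
codon against an independent pathway-enumeration oracle that takes its
genetic code from a different source.

`simulate_codon_pairs()` provides generator truth for the estimator: a
Gillespie process fires each synonymous single-nucleotide change at rate
`ks_true/3` and each nonsynonymous change at `ka_true/3` over one time unit,
so the expected number of synonymous events per synonymous site is `ks_true`
before correction; stop-creating changes have rate zero.  The NG86 mean over
100 replicates at ks_true = 0.2 and 5,000 codons lands within 10% of truth.

`fit_gmm()` fits unequal-variance Gaussian mixtures to log-Ks — the
WGD-literature convention, since Ks bursts are roughly log-normal — with
BIC(k) = −2LL + (3k − 1)ln n and the minimizing k selected.  Component peaks
are reported as back-transformed medians exp(mean).  The EM behind it is
mclust's (deterministic hierarchical initialization), so `seed`/`n_restarts`
exist only for interface stability.  On a simulated two-component mixture
with medians 0.18 and 0.75 (n = 3000), BIC selects k = 2 and the medians are
recovered within ±0.03 and ±0.10.

`within_orthogroup_compare()` restricts paralog and ortholog Ks tables to
shared orthogroups (controlling gene-specific rate variation), isolates the
focal component of each class by posterior membership ≥ 0.95 — our reading
of "isolated with 95% probability", which could also mean a 95% component
interval — and compares the classes by a Welch unpaired t-test (no pooled-
variance claim is warranted).  The direction ("paralogs older/younger") is
reported alongside the test.

## Problem sizes used by the tests and the acceptance script

The calibration checks run at the sizes stated above (10,000 MSC trees per
calibration point; 2000 type-I replicates of 365 gene trees; 200 D-statistic
data sets; 20 ladder/MUL data sets of 300-1000 trees; 500 reconciliation
oracle instances).  The ladder-profiling null and positive pools use 10
replicates × 1000 trees (pooled 10,000 subtree observations per node), a
size at which the Fisher comparisons are already far from their decision
boundaries; `analysis/06_dup_mapping.R` exposes the replicate count for
larger designs.  `scripts/acceptance.R` recomputes every headline quantity
at reduced replicate counts (60 D-statistic sets, 6 recovery data sets, 150
oracle instances) chosen so the whole script reruns in a few minutes.

## What the synthetic data do and do not emulate

The generators reproduce the *model structure* the analyses assume: MSC
genealogies (with reticulation), birth-death gene families with episodic
WGD, iid JC69 sites, and log-normal Ks mixtures.  They do not emulate
gene-tree estimation error, alignment error, rate heterogeneity across sites
or lineages, codon-usage bias, indels, or missing data beyond lineage loss.
Passing tests therefore demonstrate correctness of the machinery under its
own assumptions — not robustness of the underlying methods to the
violations real transcriptome data bring, which is a property of the
methods, not of this implementation.

## Known limitations

* Introgression simulation requires ultrametric species trees.
* `clade_frequencies()` treats trees with fewer than three shared tips as
  uninformative for every clade.
* The MUL search considers one polyploidy event (one grafted copy); nested
  or serial WGDs are out of scope.
* NG86 with pathway averaging is the classical counting estimator; it is
  biased at high divergence (hence the defined-flag at pS ≥ 3/4) and does
  not model transition/transversion or codon-frequency effects.
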