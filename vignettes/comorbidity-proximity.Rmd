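---
title: "Measuring disease comorbidity proximity from transcriptomic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring disease comorbidity proximity from transcriptomic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbsim)
```

## The question the package answers

Diseases that co-occur in patients — Alzheimer's disease and its
neurodegenerative comorbidities being the motivating case — often leave
related footprints in tissue transcriptomes. `comorbsim` quantifies that
relatedness at three levels: the differentially expressed genes (DEGs)
each disease's case/control comparison produces, the Gene Ontology (GO)
biological-process terms those genes enrich, and the diseases' own
positions in the Disease Ontology (DO). Each level yields a symmetric
proximity matrix with values in $[0,1]$, which is then clustered to show
which diseases travel together.

## Ontology semantic similarity

All three levels rest on one similarity measure over ontology DAGs, in
the style of Wang's graph-based measure. For a focal term $T$, every
term $t$ in its reflexive ancestor closure receives a *semantic
contribution*

$$S_T(T) = 1, \qquad
  S_T(t) = \max_{t' \in \mathrm{children}(t)} \; w_e \cdot S_T(t'),$$

where the maximum runs over children of $t$ lying on a path from $T$ and
$w_e$ is the contribution factor of the connecting edge's relation. The
aggregate semantic value is $SV(T) = \sum_{t} S_T(t)$, and two terms
compare as

$$\mathrm{sim}(X, Y) =
  \frac{\sum_{t \in A_X \cap A_Y} S_X(t) + S_Y(t)}{SV(X) + SV(Y)}.$$

Term sets (a gene's annotations, a disease's enriched terms) compare by
the best-match average: each term's best match in the opposite set,
averaged over both directions. Implementation is a dynamic program in
topological order, checked in the test suite against exhaustive
max-over-all-paths enumeration on hundreds of random DAGs.

Three choices here were genuinely open and are worth recording:

* **The closure is reflexive** ($T \in A_T$, $S_T(T) = 1$ included in
  $SV$). Without it, $\mathrm{sim}(X,X) \ne 1$ and the measure would not
  be a similarity; reflexivity is also what makes the set-level identity
  `BMA(S, S) = 1` hold.
* **Contribution factors** default to $w_{is\_a} = 0.8$ and
  $w_{part\_of} = 0.6$, the convention of the Wang measure as
  implemented by the standard GO similarity tooling; they are fully
  configurable through `semsim_policy()`, and any weight must lie
  strictly in $(0,1)$ so contributions decay and $SV$ stays finite.
  Relations other than `is_a`/`part_of` (e.g. `regulates`) carry no
  weight and are dropped at parse time.
* **Gene-level similarity uses direct annotations only.** Propagating
  annotations to ancestors before a best-match average would let the
  ontology root dominate every match and compress all similarities
  toward a constant. Enrichment analysis (below) *does* propagate —
  the true-path rule is correct for counting, wrong for matching — and
  the two choices are deliberately independent.

Empty annotation sets raise an error rather than scoring 0: a silent 0
would feed nonsense into the downstream clustering.

```{r toy}
toy <- parse_obo(paste(c(
  "[Term]", "id: R", "name: root", "",
  "[Term]", "id: A", "name: a", "is_a: R", "",
  "[Term]", "id: B", "name: b", "is_a: R", "",
  "[Term]", "id: C", "name: c", "is_a: A"), collapse = "\n"))
term_similarity(toy, "A", "B")        # siblings: (0.8+0.8)/(1.8+1.8) = 4/9
set_similarity_bma(toy, "A", c("A", "B"))
```

## Differential expression screen

Each dataset is a log2 expression matrix with a two-group (case vs
control) design. The per-gene fit is ordinary least squares — log2 fold
change as case mean minus control mean, pooled residual variance $s^2_g$
on $n_1 + n_2 - 2$ degrees of freedom — followed by empirical-Bayes
variance moderation: $s^2_g$ is squeezed toward a prior $s_0^2$ with
weight $d_0$,

$$\tilde s^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d},$$

and the moderated $t = \widehat{\mathrm{logFC}} / \sqrt{\tilde s^2_g
(1/n_1 + 1/n_2)}$ is referred to a t-distribution on $d_0 + d$ degrees
of freedom. The hyperparameters are estimated by the method of moments
on $\log s^2$ (mean and excess spread matched to the log-F model, the
excess inverted through the trigamma function). Setting $d_0 = 0$
recovers the classical two-sample t exactly; $d_0 \to \infty$ pools all
genes to one variance; zero-variance genes stay finite whenever
$d_0 > 0$. The test suite cross-checks both hyperparameters and the full
t/p vectors against `limma`'s empirical Bayes on shared input.

DEGs are genes with $p \le 0.05$ and $|\mathrm{logFC}| \ge 1$, both
bounds inclusive. **Raw p-values are the operative default**: on many
small microarray series nothing survives FDR adjustment yet the
screening stage must still produce gene lists for the downstream
similarity comparison; BH-adjusted values are always reported and a flag
switches the filter to them. Probe-level matrices collapse to one row
per gene by keeping the probe with the largest provisional $|t|$
(deterministic and sensitive; per-gene averaging and
highest-expression alternatives are available). Rows with missing
values are dropped by default (mean imputation optional), and a
heuristic warning fires when the matrix maximum exceeds 50, which almost
always means un-logged intensities.

## Enrichment

GO over-representation uses the one-sided hypergeometric tail
$P(X \ge k)$ for a term annotating $K$ of $N$ universe genes with $k$
hits among $n$ DEGs — numerically identical to the one-sided Fisher's
exact test, an identity the tests assert. Annotations follow the
true-path rule (propagated to ancestors along admitted relations), the
universe is *all genes measured on the platform* after probe collapsing
(standard over-representation practice), and terms annotating fewer
than 3 universe genes are skipped to suppress singleton noise. The top
5 terms per dataset (raw-p order, ties broken lexicographically by term
id) feed the GO-level similarity matrix. Pathway gene sets from GMT
files go through the identical machinery without propagation, flagged
significant at BH-adjusted $p \le 0.05$.

## The pipeline and its outputs

`run_pipeline()` screens each dataset, then builds:

1. **DEG level** — per dataset, the union of the direct GO annotation
   sets of its DEGs, compared pairwise by best-match average. A flag
   (`restrict_top_terms`) restricts each dataset's DEGs to those
   annotated under its top enriched terms first; the unrestricted union
   is the default because it is well-defined for every dataset.
2. **GO-term level** — each dataset's top-5 enriched terms as a set.
3. **DO level** — plain term similarity between the diseases' DO
   identifiers (the eight neurodegenerative defaults ship in
   `default_disease_terms()`).

Datasets with no DEGs at the thresholds are excluded from levels 1–2
with a warning rather than assigned similarity 0. Each matrix with at
least two entities is clustered agglomeratively on $d = 1 -
\mathrm{sim}$ (average linkage by default, complete/single selectable)
and written as a Newick tree whose cophenetic distances equal the merge
heights. The DEG overlap table lists genes shared between the reference
disease's datasets and any comorbidity dataset, ordered by breadth.
All outputs are plain text (TSV, Newick, JSON manifest) and contain no
timestamps, so identical configurations produce byte-identical files —
a property the acceptance tests check literally.

## What the synthetic data emulates — and what it does not

The generators exist so the whole pipeline can be exercised without any
external download. `simulate_expression()` draws per-gene baselines from
Normal(7, 1) on the log2 scale with i.i.d. Normal(0, $\sigma^2$) noise
and adds a constant $\pm$`lfc` shift to the case group of planted genes
— the data class of a normalized two-colour/oligo microarray comparison,
deliberately *not* an RNA-seq count model. Default study conditions are
5 cases vs 5 controls (the screening floor below which the design
validator warns), 1000 genes with 100 planted at $|\mathrm{logFC}| = 2$
and $\sigma = 0.5$ — effect and noise scales typical of the stronger
microarray contrasts this kind of screen targets. Constant shifts keep
power analytically checkable; a Normal effect-size mode exists behind
`effect_sd`. `simulate_ontology()` builds a rooted $b$-ary tree of a
given depth (depth counts edge levels: depth 0 is the root alone, depth
2 with branching 2 gives the 7-term binary tree) plus random shortcut
edges that create diamond motifs while preserving acyclicity.
`simulate_annotations()` draws Poisson(mean)+1 terms per gene with
leaves weighted 3:1 over internal terms, mimicking curation's
preference for specific terms.

What passing tests on such data shows is that the machinery is
numerically correct and recovers planted structure; it does not show
robustness to probe-level artifacts, batch effects, correlated genes,
or annotation bias, none of which the generators model.

On the null simulation, note one calibration subtlety: the quantity with
expectation 0.05 is the rejection rate of the *p-value filter alone*.
The fold-change floor is an effect-size filter, not an error-rate
control — under a null with $\sigma = 0.5$ virtually no gene reaches
$|\mathrm{logFC}| \ge 1$, so the joint filter's false-positive rate is
near zero, far below nominal. The calibration check therefore measures
$\Pr(p \le 0.05)$.

## The synthetic Disease Ontology slice

Published disease–disease similarity values (e.g. spinal muscular
atrophy vs amyotrophic lateral sclerosis, Parkinson's disease vs Lewy
body dementia) depend on the DO release used. The package bundles
`synthetic_do_slice.obo`, a hand-built, clearly-labelled stand-in that
mirrors the `is_a` topology of the neurodegenerative neighbourhood
(motor neuron diseases, synucleinopathies, tauopathies, demyelinating
diseases, dementias) around the eight default disease terms. On it the
qualitative structure holds — SMA–ALS is ALS's closest association and
PD–LBD exceeds PD's similarity to Alzheimer's disease — but the decimals
are not those of any real release; pass a downloaded DO OBO to
`do_similarity_matrix()` whenever exact published values matter.

## Numerical and scale choices

* Ties in best-match maxima are benign (max of equal values); no
  tie-breaking is needed anywhere in the similarity layer.
* Symmetry of written matrices is enforced to $10^{-9}$; similarity
  computations themselves are symmetric to machine precision.
* The trigamma inversion uses Newton iteration to relative $10^{-10}$
  with closed-form guards at both tails.
* Test problem sizes — DAGs of up to 50 terms, 100–500 random DAGs per
  property, 1000-gene simulations, a 150-gene three-dataset pipeline
  study — were chosen so each property is exercised well past its edge
  cases while the whole suite stays interactive (about a minute).

## Known limitations

Two-group designs only — no covariates, batches, or multi-level models;
microarray-style continuous log2 data only; GO "classic" Fisher scoring
without elim/weight decorrelation; no information-content similarity
variants; no network inference. Ingestion is strictly local files — the
package never downloads expression series or ontology releases.
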