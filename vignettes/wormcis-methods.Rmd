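---
title: "Methods: mapping and annotating accessible chromatin elements"
author: "wormcis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping and annotating accessible chromatin elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In *C. elegans*, many protein-coding genes are trans-spliced: transcription
starts at a promoter that can lie hundreds of base pairs upstream of the
first exon, and the intervening transcribed region (the *outron*) is removed
from the mature mRNA. Annotated gene models therefore do not reveal where
transcription actually initiates, and a promoter cannot be linked to its
gene by proximity alone. `wormcis` implements a pipeline that (i) maps focal
accessible-chromatin sites from ATAC-seq coverage, (ii) decides from nuclear
capped-RNA signal whether each site is a promoter, an enhancer-like
initiation site, or something else, linking promoters to genes across
outrons, (iii) clusters the temporal accessibility of regulated promoters
over a developmental and an ageing time course, and (iv) tests promoter
clusters for tissue-biased gene expression and transcription-factor (TF)
binding enrichment.

Because the original measurements are large sequencing datasets, the package
ships a first-class synthetic-data module that generates a toy genome and
signal tracks with planted ground truth. Every stage of the pipeline is
exercised and validated against that ground truth.

# Peak calling

**Model.** Accessible sites appear as smooth unimodal bumps in per-bp ATAC
coverage. The caller convolves the cross-stage mean coverage with the second
derivative of a Gaussian kernel (default bandwidth 50 bp, roughly the
half-width of a nucleosome-free region) and takes maximal runs of strictly
negative smoothed second derivative ("concave regions") as candidates;
runs shorter than 20 bp are discarded. The kernel is mean-centred so a
constant track maps exactly to zero. The candidate summit ("peak
accessibility") is the position of maximal mean coverage within the run,
leftmost on ties. This detector is deliberately very sensitive; specificity
comes from reproducibility filtering.

**Scoring and IDR.** Each candidate is scored per sample by the magnitude of
that sample's smoothed second derivative at the summit, floored at zero.
For every stage, the two replicate score vectors enter an
irreproducible-discovery-rate model: ranks are converted to pseudo-values
through the empirical CDF, mapped to a latent Gaussian scale through the
current mixture marginal, and fit by EM as a two-component Gaussian copula —
a reproducible component with common mean $\mu > 0$, variance $\sigma^2$ and
correlation $\rho > 0$, and an independent standard-normal component. The
local idr of a candidate is its posterior probability of irreproducibility;
the global IDR is the running mean of local idr along the ranking, which is
nondecreasing by construction. EM stops when the log-likelihood improves by
less than $10^{-6}$ or after 500 iterations. A candidate is retained when
IDR $\le 0.001$ in at least one stage. Boundaries are the summit extended by
75 bp on each side, rendered half-open as $[s-75, s+76)$, width 151 bp.

Peak sets called from different read configurations are merged with
earlier-set precedence: a later-set peak is kept only if it shares no base
pair with an already-kept peak.

# Transcription evidence

Per site, strand and stage, elongation is tested on long-cap 5'-end counts
in the windows $-250{:}-75$ (upstream) and $+75{:}+250$ (downstream) of the
summit, rendered half-open (175 bp each) and mirrored on the minus strand:

* **jump test** — a one-sided negative-binomial Wald test of downstream
  versus upstream counts; pass at $\log_2\mathrm{FC} > 1.5$ and BH-adjusted
  $p < 0.1$ (adjustment across sites within each stage/strand).
* **incr test** — a deterministic rule for weak signal: zero reads
  upstream, at least one read downstream in each replicate, at least three
  downstream reads in total.

The NB machinery is shared across the package: median-of-ratios size
factors; per-site method-of-moments dispersion shrunk half-and-half toward
an $a_0 + a_1/\mu$ trend fitted across sites; fold change with a 0.5
pseudo-count. The same pseudo-count enters the variance
($v = (\mu + 0.5 + \alpha (\mu + 0.5)^2)/n$), so zero-count groups carry
sampling uncertainty — without this, an upstream window of (0,0) against a
downstream (2,3) would receive an absurdly small Wald p and flood the
annotation with false "jumps". Calibration is checked by simulation: on an
NB null (mean 20, dispersion 0.05, two replicates) the one-sided test
rejects at 4–5% at $\alpha = 0.05$, and the full jump rule passes
$\le 0.1\%$.

Initiation uses short-cap 5'-end tracks pooled across replicates, masked to
base pairs where at least two replicates are nonzero. A site has initiation
when any masked bp lies within 125 bp of the summit (inclusive); the
representative mode is the masked bp with maximal pooled signal (ties:
closest to the summit, then strand-relative downstream). Sites without
reproducible signal get a best-guess mode 60 bp strand-relative downstream.

# Element classification

Per strand, a site is a coding/pseudogene promoter when:

1. in some stage it has initiation and passes an elongation test, or passes
   both elongation tests;
2. the initiation mode is strand-relative upstream of the closest eligible
   first exon (eligible: 5' end at most 250 bp upstream of the summit,
   anywhere downstream), or lies inside the annotated 5' UTR no more than
   250 bp past the first-exon 5' end;
3. no same-strand non-first-exon 5' end lies between summit and first exon;
4. distal sites (summit > 250 bp from the first exon) additionally need
   (a) continuous long-cap coverage (replicate-mean $\ge 1\times$ in at
   least one criterion-1 stage) from 250 bp downstream of the summit to the
   first exon — the outron-continuity requirement that links distal
   promoters to genes — and (b) > 250 bp distance from every same-strand
   non-first exon.

Genes still lacking a promoter are revisited: among sites passing criteria
2–4 for the gene that are intergenic or within 250 bp of the first exon,
the site with the largest jump-test fold change is assigned as a
low-confidence promoter if that fold change exceeds 1 (log2). Rescue never
demotes an existing assignment.

Remaining per-stage labels follow a fixed precedence: non-coding RNA
(summit within 250 bp of a same-strand tRNA/snRNA/snoRNA/miRNA/rRNA 5'
end), unassigned promoter (intergenic, > 250 bp from all exons, initiation
plus jump), then transcription initiation / no transcription. Stage labels
aggregate by the ranking coding_promoter > pseudogene_promoter >
non-coding_RNA > unassigned_promoter > transcription_initiation >
no_transcription, and strands combine to the final type, with
transcription initiation on either strand defining a putative enhancer.
An element is a divergent promoter when both strands carry coding
promoters of two distinct, oppositely oriented genes.

Design choices the source procedure left open (documented here as this
package's readings): "intergenic" means the summit overlaps no gene body;
distances are summit-based and inclusive at 250 bp; criterion 4b measures
the distance to the non-first-exon *interval*; the ncRNA proximity rule is
applied per strand; the best-guess mode is strand-relative downstream; the
continuity threshold is $1\times$ replicate-mean coverage (configurable).

# Accessibility dynamics

All sites are tested for differential ATAC counts between every pair of
time points within a course (two-sided NB Wald, BH across sites per pair);
a site is *regulated* when some pair reaches $\ge 2$-fold absolute change
with adjusted $p < 0.01$. Regulated promoters are clustered on relative
accessibility, $\log_2(c_t + 1) - \log_2(\overline{c} + 1)$ with the mean
taken within the course, using PAM k-medoids (default $k = 16$ development,
$k = 10$ ageing) — BUILD greedy seeding plus steepest-descent SWAP,
deterministic with lowest-index tie-breaking. An explicit merge map (empty
by default) reproduces the kind of manual cluster merge the original
analysis performed on the ageing course. PAM is a local search: on
unstructured random instances it (like the reference `cluster::pam`)
occasionally converges to a non-global local optimum; the test suite
records this honestly rather than asserting global optimality.

Promoter accessibility is compared with gene expression by applying the
same relative transform to replicate-averaged FPM values and correlating
per promoter over time points (Pearson), averaging within clusters.

# Tissue bias and TF enrichment

A gene is tissue-biased when its top tissue exceeds the second by
$\ge 3$-fold (TPM + 0.1 pseudo-value on both) with adjusted $p < 0.01$ from
the shared NB test on replicate counts (the original analysis did not state
its test; this stand-in is declared). Cluster composition is the percentage
of member genes biased toward each tissue.

TF peaks are assigned to elements when their summit falls in the 400-bp
half-open window centred at the element midpoint. Elements bound by
$\ge 19$ factors are HOT and removed from enrichment; factors need more
than 200 peaks on non-HOT elements (at synthetic desk scale this filter is
configured down — see below). Per factor and cluster a 2×2 table against
all other non-HOT clustered promoters gives an odds ratio (Haldane 0.5
correction only when a zero cell occurs) and a two-sided Fisher exact p;
factors are kept at $p < 0.01$ somewhere and maximum OR $> 2$. Relative TF
expression per tissue is $\log_2((\mathrm{TPM}+0.1)/\mathrm{mean}_t
(\mathrm{TPM}+0.1))$, with expression deciles calibrated per tissue on
TPM $\ge 1$ entries only.

# The synthetic world

The generator's defaults are fixed once and define the conditions the
validation tests assume:

* one 2 Mb chromosome, 200 genes on ~10 kb slots; 70% of protein-coding
  genes trans-spliced with outrons of 300–1200 bp; 60% with 5' UTRs; at
  least one gene of each non-coding biotype;
* 150 planted coding promoters (at outron starts, or 50 bp upstream of the
  first exon for non-trans-spliced genes), 100 enhancers (> 250 bp from
  every exon 5' end), 50 inactive elements; four temporal archetypes
  (early, late, mid-development, ageing-rising) define true clusters;
* eleven stages (six wild-type developmental, five ageing), two replicates;
  ATAC bumps are Gaussian (sd 75 bp, emulating 150-bp-extended, 75-bp
  shifted single-end reads) with amplitude depth × stage multiplier
  (depth 50) over Poisson background 1.0/bp; replicate counts are negative
  binomial (dispersion 0.05), matching the downstream test's assumptions;
* long-cap 5' ends at 0.08/bp × multiplier over 400 bp downstream of
  promoters versus 0.01/bp background; a deterministic coverage plateau of
  ceiling(2 × multiplier) spans promoter → outron → first exon, so
  continuity holds in active stages and fails across random background
  (P(replicate-mean ≥ 1) ≈ 0.59 per bp);
* short-cap initiation of ~6 expected reads per replicate concentrated
  within ±15 bp of the mode, on both strands at enhancers and with a weak
  divergent antisense mode at promoters;
* TF peak sets with planted per-cluster binding odds ratios, a designated
  HOT subset, and a TPM table giving each cluster's genes a dominant
  tissue at ≥ 3-fold.

What the generator does **not** emulate: sequence content (no motifs unless
requested), mappability artifacts, fragment-length structure, chromatin
domains, replicate batch effects, or the biological correlation structure
between neighbouring elements. A green end-to-end test therefore
establishes that the implementation performs the stated inference correctly
under its own model assumptions — not that it would reproduce the original
study's numbers on real data, which the validation deliberately does not
claim.

Scale-dependent settings chosen for the desk-scale fixture (decided with
the fixture, not tuned afterwards): the TF min-peak filter is lowered
(200 → 10) because a 150-promoter universe cannot carry 200 peaks per
factor; the enrichment universe is the developmental promoter clustering.

# Numerical choices and limitations

* EM and PAM iteration orders are fixed and documented; identical seeds
  give byte-identical outputs end to end (the determinism test compares
  written files).
* The IDR latent-scale inversion uses a 4000-point grid interpolation of
  the mixture CDF; parameters are clamped to $\mu \ge 0$,
  $\sigma^2 \ge 10^{-4}$, $\rho \in [10^{-3}, 0.999]$,
  $\pi_1 \in [10^{-4}, 1-10^{-4}]$. All-tied score vectors are rejected.
* The one-sided jump test is a test against zero fold change with the 1.5
  threshold applied to the estimate afterwards (the alternative — a
  composite null at 1.5 — would be strictly more conservative).
* The decile rule collapses duplicated quantile breaks and rescales to a
  1–10 span when ties reduce the number of distinct bins.
* CpG density (CG-start count over a centred window) is a declared
  stand-in; the upstream definition lives in work this package does not
  restate.
* Fisher p-values come from `stats::fisher.test`; the test suite checks
  them against an independent hypergeometric enumeration oracle to 1e-10
  on tables with total ≤ 200.
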