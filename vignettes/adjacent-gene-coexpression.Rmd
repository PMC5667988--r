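---
title: "Dissecting copy-number-driven co-expression of adjacent genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting copy-number-driven co-expression of adjacent genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adjacoex)
```

## The scientific problem

Recurrently amplified chromosome arms — the long arm of chromosome 20 in
colorectal cancer being the canonical example — carry genes that are both
over-expressed and strikingly co-expressed with their physical neighbours.
Three regulatory mechanisms are commonly invoked to explain why adjacent
genes rise and fall together: a strong *cis* effect of shared copy-number
gain, shared transcriptional control (common transcription factors, and in
the extreme case a single bidirectional promoter driving a head-to-head
gene pair), and competition for a limited pool of microRNAs (the ceRNA
hypothesis). `adjacoex` implements each detection step of that argument as
a testable, reusable component and wires them into one pipeline.

## The statistical model

Every association in the pipeline is a Pearson correlation

$$r = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
           {\sqrt{\sum_i (x_i-\bar x)^2 \sum_i (y_i-\bar y)^2}},$$

with a two-sided p-value from the exact transform
$t = r\sqrt{(n-2)/(1-r^2)}$ against a t distribution with $n - 2$ degrees
of freedom. Missing cells are deleted pairwise and the number of complete
pairs actually used is carried in every result (`n_used`); values are
never imputed, mirroring the practice of restricting each comparison to
samples with quantifiable measurements. Constant vectors raise an error
rather than silently contributing $r = 0$, because silent zeros corrupt
screens. Benjamini–Hochberg q-values are attached across every batch; the
classical screening rules threshold the raw p-value (`p_mode = "raw"`),
and the q column is additional.

Positional enrichment of a significant gene set within a cytoband uses
the one-sided hypergeometric upper tail: with $N$ annotated genes, $K$ on
the band and a significant set of size $n$ overlapping the band in $k$
genes, $p = P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$. Raw
per-band fractions are reported alongside because they are the quantity
usually quoted, but they are incomparable across bands of different size,
which is why the enrichment p-value exists. The same tail probability
drives shared-regulator enrichment.

## Stage conventions that matter

* **Coordinates** are 0-based half-open everywhere; GFF3 is converted at
  the boundary. A single arithmetic convention makes spacer lengths
  unambiguous: intergenic distance is exactly `right.start - left.end`,
  so the classic 89-bp promoter interval (32207791 to 32207880) has
  length 89 with no off-by-one caveats.
* **Cytoband assignment** uses the gene's start coordinate, which is
  deterministic for genes straddling a band boundary, and is idempotent.
* **Co-expression threshold** `r >= 0.6` is inclusive; the cis screen
  (`r > 0.65`, `p < 1e-4`) is strict on both sides. The seed gene is
  excluded from its own significant set, so reported counts never include
  the trivial self-correlation.
* **Adjacency clustering** scans genes in coordinate order and tolerates
  at most `max_gap` consecutive non-significant genes per interruption
  (default 0, i.e. strict physical adjacency; 1 is the documented
  alternative for interrupted runs). Interrupting genes are skipped, not
  made members. Clusters below `min_size = 2` are dropped: a cluster of
  one is just a gene.
* **Orientation** is defined on the pair ordered by start: left `-` /
  right `+` is divergent (head-to-head) because under half-open
  coordinates a `+` gene's TSS is its interval start and a `-` gene's TSS
  its interval end — the 5' ends then face each other across the spacer.
  The bidirectional flag requires divergent orientation and strict
  `distance < 1000` bp; only coordinate-adjacent pairs are candidates,
  and overlapping pairs are reported but never flagged.
* **CpG islands** default to the classical criteria (length ≥ 200 bp,
  GC ≥ 0.5, observed/expected CpG ≥ 0.6, with obs/exp computed as
  $N_{CpG} L / (N_C N_G)$ and `N` bases excluded from all counts).
  Bidirectional promoter spacers are frequently CpG-rich but shorter than
  200 bp — an 87-bp island overlapping a compact promoter is typical — so
  `len_min` (and the window, which bounds detectable sequence length
  from below) are configurable; the pipeline clamps the window to the
  spacer length when annotating spacers.
* **PWM scanning** scores
  $\sum_i \log_2\left((f_{b_i,i} + \varepsilon)/(0.25 + \varepsilon)\right)$
  bits against a uniform background with pseudocount
  $\varepsilon = 0.01$; no background model is assumed beyond uniformity.
  Reverse-strand hits are scored on the reverse complement and reported
  at their forward-strand offset.
* **TF sign classes** partition strictly at zero: `r >= 0` is
  activator-like, `r < 0` repressor-like. (Published summaries sometimes
  quote `>= 0` and `<= 0` splits that double-count the boundary; a strict
  partition keeps fractions additive.)
* **ceRNA verdicts** require all three lines of evidence at once: a
  shared-miRNA union of at least `min_shared = 5` across evidence
  sources, pair co-expression `r >= 0.6`, and at least `min_support = 3`
  shared miRNAs individually anti-correlated (`r < 0`, `p < 0.05`) with
  *both* genes. The verdict is monotone in every threshold. Source tags
  (e.g. TarBase-, miRTarBase-, starBase-style collections) are free-form
  strings; per-source intersections are kept separate before pooling
  because evidence classes differ in kind.

## What the synthetic-data generator emulates

The generator plants, on one deterministic chromosome arm of 60 genes in
8 named bands, every structure the pipeline is meant to find:

* **Focal amplifications**: two band-sized segments; per sample each
  segment gains +2 copies (from the diploid baseline 2) with probability
  0.5, and all genes inside a gained segment share the gain.
* **cis effects**: genes inside amplified segments get slope
  $\beta = 1$ in the linear-Gaussian model
  $\mathrm{expr} = \mu + \beta(\mathrm{cna} - 2) + \sum_b \tau_b f_b -
  \sum_m \gamma_m m + \varepsilon$, all latent factors standard normal
  and $\varepsilon \sim N(0, 1)$. With gain 2 at probability 0.5,
  $\mathrm{sd(cna)} = 1$ and the model-implied cis correlation is
  $\beta/\sqrt{\beta^2 + \sigma^2} = 1/\sqrt2 \approx 0.71$ — the regime
  of a screen at $r > 0.65$. A per-segment `beta` override plants
  "passenger" amplifications (copies gained, no dosage effect), the
  condition under which screen specificity is a meaningful measurement.
* **Co-expression blocks**: two blocks of consecutive genes (sizes 5 and
  3) sharing a latent factor with $\tau = 1.5$; within-block correlation
  is $\tau^2/(\tau^2+\sigma^2) \approx 0.69$ for the plain block and
  $\approx 0.77$ for the block nested inside the second amplified
  segment (the amplified-neighbourhood configuration). Block 2 sits
  wholly inside its amplified band by design — a block straddling the
  amplification boundary would leave members with unequal variances and
  a mutual correlation sitting exactly on the 0.6 threshold, which is a
  different (and untestable) condition from the one being planted.
* **A divergent pair** at gene indices 21/22 with an 89-bp CpG-rich
  spacer, placed head-to-head with exactly that intergenic length. The
  CpG-rich spacer is redrawn until GC ≥ 0.5 and obs/exp ≥ 0.6 hold, so
  the constraint is guaranteed; non-flagged spacers have every CpG
  dinucleotide broken.
* **ceRNA coupling**: six miRNAs, each repressing the same gene pair
  with $\gamma = 1$, split 3/4/3 across three evidence-source tags
  (union six). Marginally the pair's correlation is
  $6\gamma^2/(6\gamma^2 + \sigma^2) = 6/7 \approx 0.86$ and each
  miRNA–target correlation $-\gamma/\sqrt{6\gamma^2+\sigma^2} \approx
  -0.38$ — comfortably detected at $n = 200$. Repression enters
  linearly; positive co-target covariance is the emergent signature, no
  titration kinetics are simulated.
* **Decoys**: ten TFs and six miRNAs with random target sets and no
  expression effect, so enrichment rankings have something to beat.

The generator is a linear-Gaussian model, not a count model: every
statistic downstream is a Pearson correlation on continuous normalized
values, so Gaussian latents exercise exactly the quantities under test.
What passing tests therefore show is that the detection rules recover
planted linear structure at realistic effect sizes and cohort size
($n = 200$, echoing a few-hundred-sample tumour cohort); they do not
show robustness to count noise, outliers, normalization artefacts,
subclonal copy number, or annotation error in real data.

Determinism: gene layout is seed-independent given the configuration;
copy-number, expression and decoy draws use fixed offsets from the
config seed, so a config reproduces its bundle byte for byte.

## Problem sizes and numerical choices

The validation suite measures, at the fixture's own conditions: Pearson
agreement with the definitional formula to 1e-12 on 1000 random vectors
and null calibration (rejection rate at $p<0.05$ over $10^4$ null pairs);
specificity of the cis screen on passenger-amplified genes, cluster
recovery (Jaccard against planted blocks), divergent-pair recovery and
ceRNA recovery over 20 simulation seeds; and exact agreement of the
hypergeometric tail with exhaustive enumeration on every universe up to
size 12. These sizes keep the full suite in the minutes range on one CPU
while leaving the Monte-Carlo margins far from their thresholds.

Tie-breaks and degenerate inputs: abutting genes have distance 0 with an
empty intergenic interval; overlapping genes have distance 0 with an
overlap flag; sequences shorter than the scan window yield empty CpG
results by contract; `p.adjust(..., "BH")` handles multiplicity; the
hypergeometric tail is `phyper(k - 1, K, N - K, n, lower.tail = FALSE)`.

## Known limitations

* Identifier matching is exact and case-sensitive; alias resolution is
  out of scope, as are liftover and probe-to-gene mapping.
* Only Pearson correlation is offered — no rank or partial correlation,
  and no permutation p-values.
* The bidirectional-promoter stage classifies and annotates; it does not
  model transcription initiation or use conservation/chromatin tracks.
* Enrichment universes default to the expression matrix's genes; results
  depend on that choice, and no attempt is made to reconstruct the
  library-specific universes of external enrichment services.
* The ceRNA call is a screening heuristic over shared-target sets and
  anti-correlation; it does not estimate binding-site occupancy or
  dose-response.
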