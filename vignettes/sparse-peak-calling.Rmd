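---
title: "Empirical signal-block peak calling for sparse CUT&RUN coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical signal-block peak calling for sparse CUT&RUN coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsepeaks)
```

## The problem

CUT&RUN and related antibody-tethered nuclease methods release DNA fragments
almost exclusively at sites of protein binding, so their genome-wide coverage
is dominated by zeros: a handful of sharply covered loci over a background of
scattered single fragments. Peak callers built for ChIP-seq model a dense
background (Poisson or negative-binomial read counts, local lambda) and are
tuned for recall; on sparse data they happily promote every stray background
fragment to a peak. What sparse data needs is the opposite: a precision-first,
model-free rule calibrated on the global background distribution itself.

`sparsepeaks` implements such a rule. It is empirical and data driven
throughout - no distributional model of coverage is fitted, no p-values are
computed - and an IgG control experiment plays the role the background model
would otherwise play.

## The method

**Signal blocks.** Nonzero bedgraph intervals that are exactly adjacent
(`end[i] == start[i+1]`, 0-based half-open) are concatenated into maximal
*signal blocks*, the unit of calling. Each block is summarized by its total
signal

$$t \;=\; \sum_{i} (\mathrm{end}_i - \mathrm{start}_i)\,\times\,\mathrm{signal}_i ,$$

the sum running left-to-right over its component intervals (so totals are
bit-reproducible), together with the maximum component signal and the span
attaining it (leftmost on ties). For paired-end data the total equals the
number of sequenced bases in the block, which is why it discriminates between
a fragment pile-up and an isolated background fragment irrespective of block
width - the same statistic works for a 300 bp transcription-factor peak and a
50 kb repressive chromatin domain.

**Threshold selection.** Let $r_1,\dots,r_m$ be target block totals and
$s_1,\dots,s_n$ (scaled) control totals. For every candidate threshold $t$
(0 and every distinct observed total - the curve is a step function, so this
grid is exact) define the remaining fractions
$p_T(t) = \#\{r_i > t\}/m$ and $p_C(t) = \#\{s_j > t\}/n$ and

$$F(t) \;=\; \frac{p_T(t)}{p_T(t) + p_C(t)} ,$$

the fraction of target blocks among all blocks remaining above $t$.
Candidates where nothing remains are excluded. *Stringent* mode thresholds at
the smallest candidate attaining $\max F$ (the smallest maximizer retains the
most blocks at equal discrimination, i.e. maximizes recall). *Relaxed* mode
finds the negatively inflected knee of the curve - the candidate with
negative discrete second difference and $F$ nearest below the maximum - and
thresholds where $F$ first reaches $F_{\max} - (F_{\max} - k)/2$, halfway
between knee and maximum in $F$-space, locating $t$ by linear interpolation
between the flanking candidates. Retention is strictly greater-than
everywhere (curve construction, filtering, FDR), so ties at a threshold are
excluded consistently.

An alternative difference form of the selection functional (counting blocks
*removed* at $t$, with a pooled denominator) is available behind
`f_variant = "printed"`. It is not the default: the removed-count ratio is
maximized deep in the upper tail more or less unconditionally, which makes
its maximizer degenerate, whereas the remaining-fraction form is
self-consistent with the remaining-percentage curves the method is built on.

**Normalization.** With `norm = TRUE` (the default when a control file is
given) the control is brought onto the target scale before thresholding.
Background block totals concentrate around a typical single-fragment value;
the mode of each total-signal distribution is located by a Gaussian KDE
(Silverman bandwidth) and every control total is multiplied by
$\mathrm{mode}(\text{target})/\mathrm{mode}(\text{control})$. The KDE argmax
is first found on a 512-point grid over $[0, \max]$ and then refined by
evaluating the exact KDE at observed totals within one grid step: with
heavy-tailed totals the grid spacing ($\max/512$) can exceed the data spacing
near the background mode, and the unrefined grid argmax would carry up to
half a grid step of error - enough to flip the scaling factor across 1 on
depth-matched pairs. The refined estimate is resolution independent and
exactly linear (`mode(c*x) = c*mode(x)`). Use `norm = FALSE` for
depth-matched or spike-in-calibrated pairs.

**IgG-overlap exclusion.** Repeated regions and recurrent artifact loci
accumulate coverage in both target and control. After thresholding, a target
peak is discarded if it shares at least 1 bp with a control block whose
scaled total also exceeds the threshold. The gate always uses the *stringent*
threshold, in both modes: the relaxed threshold is deliberately permissive
about target blocks, and letting it also enlarge the exclusion set would make
the more permissive mode more aggressively filtered - and would break the
guarantee that the relaxed peak set contains the stringent one. (At the
stringent threshold itself the gate is frequently inert, because when
$F_{\max} = 1$ the threshold equals the largest scaled control total and no
control block lies strictly above it.)

**Empirical FDR.** At threshold $t$ the reported empirical false discovery
rate is $\#\{s_j > t\} / (\#\{r_i > t\} + \#\{s_j > t\})$ - the fraction of
surviving blocks that come from the control - and 0 when nothing survives.

**Control-free mode.** With a numeric fraction $q \in (0,1)$ instead of a
control, the threshold is the empirical $(1-q)$ order statistic of the target
totals: the top $\lceil qm \rceil$ blocks are retained and the threshold is
the next total below them. A quantile rather than a raw signal value is used
because raw totals scale with sequencing depth. No overlap filtering or FDR
is possible in this mode.

## The degenerate-input safeguard

$F(0) = 1/2$ always, and when target and control are statistically
exchangeable (no true enrichment - e.g. profiling an unexpressed factor) the
whole curve fluctuates around $1/2$. The maximizer of such a curve is a noise
artifact, and it is *scale-invariantly* unstable: the best random excursion
above $1/2$ is equally likely to occur among the top 5 blocks as among the
top 500, so the bare rule occasionally places the threshold in the bulk of
the distribution and retains a large fraction of background. (In simulation
under an exact null, roughly one replicate in five retained more than 5% of
target blocks, with a tail reaching 85%.)

`call_peaks()` therefore trusts the curve only if some candidate rises
credibly above the baseline: $F(t) - 1/2$ must exceed `enrichment_z`
(default 4) binomial standard errors, $z\cdot\tfrac{1}{2}/\sqrt{k(t)}$, where
$k(t)$ is the pooled number of blocks still above $t$. Genuine enrichment
passes easily ($F \to 1$ while tens of blocks remain); exchangeable noise
essentially never does. When the test fails, the pipeline falls back to the
most conservative empirical threshold - the largest scaled control total, so
only target blocks exceeding the *entire* control distribution survive - and
records `threshold_source = "control_max"` in the result. When
$F_{\max} = 1$, as in any clearly enriched dataset, the fallback threshold
coincides with the bare rule's choice anyway, so the safeguard only changes
behavior where the bare rule is unreliable. Note that `compute_f_curve()`
itself always reports the bare rule's `t_stringent`; the safeguard is a
pipeline decision.

## The synthetic-data generator

Every property of the pipeline is exercised on seeded fixtures from
`simulate_pair()`, so the package is testable without any external download.
The generator emulates the sparse regime directly at the fragment level
(the premise of block calling is fragment-spanning paired-end coverage):

* **Background**: Poisson-many fragments per megabase (default 100/Mb over a
  5 Mb two-chromosome toy genome - about one fragment per 10 kb, the
  "background dominated by zeros" regime), placed uniformly and
  independently, with the *identical* law for target and IgG, so the pair is
  depth-matched by construction.
* **Planted peaks** (`tf` preset): 20 non-overlapping intervals of 200-700 bp
  receiving Poisson(100) fragments each; `histone`: 10 regions of 2-10 kb,
  Poisson(400) fragments.
* **Broad domain** (`broad` preset): one contiguous 50 kb domain at 1000x
  the background fragment density (about 5000 fragments, mean per-base depth
  ~17), dense enough that a zero-coverage gap inside the domain is
  vanishingly rare - the domain-coherence property is about the *caller* not
  fragmenting the domain, so the generator must not fragment its coverage.
* **Null mode**: background only, target exchangeable with IgG - the
  synthetic analog of profiling an unexpressed factor, where every call is a
  false positive.
* **Fragment lengths**: each preset uses a single characteristic
  protected-fragment length (120 bp for TF-like, 170 bp nucleosomal). Fixed
  lengths make background block totals exact multiples of the fragment
  length, so the strict `>` retention rule cleanly separates $k$-fragment
  from $(k{+}1)$-fragment background pile-ups. This discreteness is a
  deliberate caricature: under a continuous totals law, the number of target
  background blocks exceeding the maximum of $n$ exchangeable control blocks
  has expectation $m/(n+1) \approx 1$ *whatever the law's parameters*, so
  matched-background fixtures would carry an irreducible ~1 false positive
  per replicate at the stringent threshold - a property of top-order-statistic
  exchangeability, not of the caller. A truncated-normal length law between
  configurable (min, max) bounds is available for experiments that want
  continuous totals.

What the fixtures do **not** model: mappability and GC bias, chromatin
accessibility structure in the background, continuous fragment-size spread
(by default), inter-replicate variability, and spike-in calibration. Passing
tests on these fixtures therefore demonstrate the correctness and the
designed statistical behavior of the algorithm, not end-to-end performance on
real libraries.

Because generated target and IgG are depth-matched exactly, the fixture
pipelines run with `norm = FALSE` (the mode intended for calibrated input);
normalization is exercised separately on deliberately depth-shifted controls,
where the scaling factor must recover the known shift.

## Evaluation utilities

`precision_recall_f1()` scores a called set against a reference with
`bedtools intersect -u` semantics: precision is the fraction of called peaks
sharing at least 1 bp with a reference peak, recall the symmetric fraction,
and $F_1 = 2PR/(P+R)$ (0 when $P+R=0$). `pr_curve()` sweeps a ranking metric
(block total signal for this caller) over its distinct values, grouping ties
at one cutoff, and integrates precision over recall by the trapezoid rule
*without* extrapolating to recall 0 or 1 - no interpolation convention is
imposed on data that were never observed, which makes the area conservative
and comparable across methods evaluated the same way. A constant metric
collapses the curve to one point, reported as precision x recall with a
warning. Reference-set score filters (e.g. keeping reference peaks with
$-\log_{10}\mathrm{FDR} > 10$) are the caller's responsibility via
`read_bed()`'s configurable score column.

## Numerical and interface choices

* Coordinates are 0-based half-open everywhere; bookended intervals do not
  overlap; chromosomes sort lexicographically (no genome file needed).
* Explicit zero-signal bedgraph rows are legal input but are dropped at parse
  time and thus split blocks exactly as a gap would - the two representations
  of "no signal" must be indistinguishable downstream.
* Block totals are summed left-to-right in genomic order; output numbers are
  written as the shortest decimal that round-trips to the same double.
* Max-signal subregion ties keep the leftmost component; F-maximum ties keep
  the smallest threshold; knee ties keep the largest qualifying F.
* The merge gap for block aggregation defaults to 0 (strict adjacency) and is
  configurable but not recommended: gap-tolerant merging changes the unit of
  calling.
* Peak output is the 6-column BED dialect (chrom, start, end, total signal,
  max signal, max-signal span) used by the community around this method, so
  downstream tooling is compatible; the sorted file is written with no
  header and a trailing newline.
* Test problem sizes: fixtures use 2-5 Mb toy genomes with a few hundred
  background blocks per dataset, 10-20 replicates per property, and
  brute-force oracles (per-base coverage, exhaustive threshold enumeration,
  all-pairs overlap) on instances small enough to enumerate. These sizes give
  each property enough replication to be meaningful while keeping the whole
  suite fast.

## Known limitations

* The empirical threshold needs enough blocks to estimate the curve; datasets
  with a handful of blocks fall back conservatively (and `select_relaxed()`
  falls back to the stringent threshold below 3 candidates).
* With no true enrichment the stringent call is deliberately near-empty; the
  method cannot (and should not) rank marginal candidates below the control
  maximum in that regime.
* The empirical FDR is a descriptive contamination fraction, not a
  frequentist error rate; it is reported, not controlled.
* Normalization by density-peak ratio assumes unimodal background totals; for
  spike-in-calibrated data prefer `norm = FALSE`.
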