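---
title: "Calling significant 4C-Seq interactions with fourCcall"
author: "fourCcall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling significant 4C-Seq interactions with fourCcall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourCcall)
```

## The model

A 4C-Seq experiment fixes one genomic locus — the viewpoint — and
sequences the loci ligated to it, reporting for every restriction fragment
of the 3C enzyme a non-negative read count. `fourCcall` treats the
fragment map as the coordinate system: fragments tile each chromosome
exactly (0-based half-open in every file the package writes; the GRanges
convention in memory), and all statistics are computed over the *analysis
set* — fragments that are mappable under the library design and not
removed by a mask.

### Fragment mappability

A fragment end can be observed only if the piece between the primary-site
boundary and the nearest secondary-enzyme cut inside the fragment (length
*d*) is long enough to align (*d* ≥ `minMapLength`, default 20 bp) and
yields an amplicon inside the size selection
(`sizeMin` ≤ *d* + `primerLength` ≤ `sizeMax`). Fragments with no internal
secondary site ("blind" fragments) and fragments shorter than
`minMapLength` are unmappable. This amplicon-length rule is the package's
concrete parameterization of the library-design factors that determine
observability; adapter lengths are folded into `primerLength`, and a
linearization enzyme, when given, only annotates fragments carrying its
site because its effect is viewpoint-specific. Recognition sites are
IUPAC-degenerate; matching is single-strand for palindromic sites (where
it equals double-strand matching) and two-strand, with cut positions
mapped back to reference coordinates, otherwise. `N` bases never match, so
unplaced sequence cannot create phantom sites.

### The significance threshold

For one chromosome with analysis-set counts $x_1,\dots,x_n$ and window
size $W$, the observed statistics are the sliding-window sums
$s_i = \sum_{j=i}^{i+W-1} x_j$. A shuffle redistributes the counts among
the same fragments, and after **each** shuffle the cutoff

$$X = \min\{\,c \ge 1 : \widehat{\mathrm{FDR}}(c) < \alpha\,\},\qquad
\widehat{\mathrm{FDR}}(c) = \frac{\#\{\text{shuffled windows} \ge c\}}
{\#\{\text{observed windows} \ge c\}}$$

is recorded (the ratio is defined as 0 when no observed window reaches
$c$, so $X$ always exists). Over $P$ permutations this gives a
distribution of cutoffs; the final threshold is the order statistic of
rank $P - \lfloor Pk/100\rfloor + 1$ — the smallest $X$ within the top
$k$ percent, always an attained value, with no interpolation. A window is
significant iff its sum is $\ge T$ (the cutoff is defined as a minimum
required count, hence inclusive).

The published description of this procedure prints no FDR formula; the
estimator above is the package's declared reading, and the percentile is
taken over all $P$ values rather than unique ones. The comparator
`pooled_mean` mode instead averages the shuffled tail over permutations
before thresholding, $T = \min\{c : \frac{1}{P}\sum_p
\#\{\text{shuffled}_p \ge c\}/\#\{\text{observed} \ge c\} < \alpha\}$,
which reproduces the behavior of earlier averaged-FDR callers: a single
extreme shuffle can move the average, whereas it barely moves a deep
order statistic.

### Defaults and tunables

| parameter | default | meaning |
|---|---|---|
| `window` (W) | 5 fragments | resolution/sensitivity trade-off; small W resolves fine structure, large W favors reproducible broad contacts |
| `fdr` (α) | 0.01 | target empirical FDR per chromosome |
| `nPermutations` (P) | 1000 | shuffles per chromosome; at least 1000 recommended |
| `topPercentile` (k) | 5 | confidence level on the cutoff distribution |
| `shuffleUnit` | `"vector"` | `"vector"` permutes the count multiset; `"read"` scatters each read independently |
| `minMapq` | 1 | uniquely aligned reads only |
| `boundaryTolerance` | 4 bp | boundary assignment slack, mirroring a 4-base random barcode |

Per-permutation RNG streams are derived deterministically from
`(seed, chromosome, permutation index)` (`permutationSeed()`), so results
are identical regardless of chromosome execution order and can be
reproduced piecewise; this derivation is part of the package's
reproducibility contract and is what the test-suite's independent
transcription of the algorithm seeds itself with.

### The two shuffle units

Count-vector permutation preserves the multiset of per-fragment counts
exactly and is the conservative default for overdispersed data: a lone
extreme fragment re-appears in every shuffle, so it can never make itself
significant. The flip side is structural: an isolated single-fragment
spike is indistinguishable from its own shuffles, so vector-mode calls
require read mass spread over more than one fragment. Per-read scattering
(`"read"`) places each read independently and uniformly, giving a lighter
(multinomial) null under which single-fragment enrichments — including any
call at window size one — are detectable, at the price of weaker control
when the true background is overdispersed. The package exposes both; the
recovery analyses below use the vector default for spread peaks and the
read unit where single-fragment detection is itself the property under
study.

### Masking and localized backgrounds

Masking removes whole fragments (any overlap counts) from both the
observed windows and the shuffle pool, and is recorded as an
inclusion flag so the fragment map keeps its tiling invariant. Mask-out
of a region equals restriction to its (fragment-aligned) complement.
Typical uses: excluding the viewpoint-proximal zone, whose counts can be
orders of magnitude above the distal background, or restricting to a few
megabases around a locus to compute a local threshold for a weak contact.

### Prioritization

For each significant window with sum $S$, most abundant fragment count
$m$ (leftmost on ties): Broad iff $S - m \ge T$; else Intermediate iff
$S - m + \bar{m} \ge T$ where $\bar{m}$ is the real-valued mean of the 1–2
in-window neighbors of the maximum (0 when $W = 1$); else Narrow. The
neighbor set is restricted to the window — a chromosome-wide neighbor rule
would contradict the fact that every $W=1$ call must be Narrow. The
conditions are nested (Broad ⊂ Intermediate ⊂ significant), interactions
inherit the broadest member-window category, and replicate intersections
retain the broadest category across replicates. Interaction spans are
trimmed of read-free end fragments only; interior zeros and sub-threshold
flanking fragments with reads are kept, and the reported read total is the
sum over the retained fragments so span and mass agree.

## The synthetic-data generator

`simulate4C()` emulates the features of 4C count data that matter to the
statistics:

* **Fragment map** — geometric fragment lengths (default mean 2500 bp, the
  order of a 6-cutter digest), a 10% unmappable fraction by default.
* **Background** — i.i.d. negative-binomial counts on mappable fragments,
  mean `mu = 2`, `dispersion = 0.3` in the sense standard in count-based
  genomics (variance $\mu + 0.3\mu^2$; `rnbinom(size = 1/dispersion)`).
  Exchangeability across mappable fragments makes this exactly the null
  the shuffle tests, so it is the calibration benchmark. A Poisson
  background would understate window-sum variance and make thresholds
  unrealistically tight.
* **Distance decay** — independent Poisson draws with mean
  $s(1+d)^{-\gamma}$ at ordinal distance $d$ from the viewpoint (defaults
  $s = 50$, $\gamma = 1.2$, giving a near-viewpoint background tens of
  reads high that falls below one read within a few hundred fragments).
  Adding draws rather than scaling keeps the table a counting process, so
  shuffle calibration stays meaningful.
* **Planted peaks** — exactly `nReads` reads multinomially distributed
  over a discretized Gaussian kernel of width `spread` fragments
  (`spread = 0` is a single-fragment spike).

What the generator does **not** emulate: fragment-length-dependent capture
efficiency, PCR jackpotting, undigested/self-ligated viewpoint artifacts,
trans-chromosomal background, or correlated noise between neighboring
fragments. Passing the recovery tests therefore shows the statistical
machinery behaves as designed on its own model, not that any particular
biological dataset will yield the same sensitivity.

## Numerical choices and degenerate inputs

* Candidate cutoffs are integers; tail counts are computed by tabulation,
  bounded by the sum of the $W$ largest counts (vector unit), which keeps
  each permutation $O(n)$.
* Empty window vectors ($W$ larger than the analysis set) give a cutoff
  of 1 with a warning; a chromosome whose analysis set is emptied by
  masking is an error naming the chromosome.
* Ties for the most abundant fragment go to the leftmost position; the
  Broad test is tie-invariant, only the Intermediate neighbor set can
  differ.
* Thresholds are attained X values in percentile mode (`T ∈ X
  distribution` is a class invariant checked by validity).
* Zero-length fragments from coincident cuts are suppressed at map
  construction; a cut at position 0 or at the chromosome end produces no
  empty leading/trailing fragment.

## Study sizes used by the test suite

The packaged checks run at sizes chosen to exercise the asymptotics while
staying comfortable on a laptop: 200 permutations and 2000-fragment
chromosomes for calibration and recovery (200 and 100 simulations), 100
permutations for the 20-trial variance comparison and window-size trends,
and a 20-fragment fixture against a literal straight-line transcription
of the threshold procedure. The recommended operational settings remain
P ≥ 1000.

## Known limitations

* The mappability model does not check alignment uniqueness (k-mer
  self-similarity of the genome); `minMapLength` is a proxy.
* Allele tags on count tables are opaque labels: allele-specific
  significance calling is out of scope, only pass-through and set
  analysis are provided.
* Thresholds are per chromosome; there is no cross-chromosome pooling and
  no analytic null.
* Replicate intersection requires exact fragment identity on a shared
  map, not positional overlap between different maps.

## A complete run

```{r example, eval = FALSE}
sim <- simulate4C(nFragments = 2000, viewpoint = 1000,
                  peaks = list(list(center = 500, nReads = 150, spread = 3)),
                  seed = 42)
fr <- fragments(sim$fmap)
mask <- data.frame(chrom = "chrS",
                   start = GenomicRanges::start(fr)[950] - 1,
                   end   = GenomicRanges::end(fr)[1050])
cfg <- thresholdConfig(window = 5, fdr = 0.01, nPermutations = 1000,
                       topPercentile = 5, seed = 7)
ints <- callInteractions(sim$table, cfg, masks = mask)
ints
writeInteractionsBed(ints, "interactions.bed",
                     config = list(seed = 7, window = 5, fdr = 0.01))
```
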