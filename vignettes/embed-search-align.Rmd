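---
title: "Embed-Search-Align: aligning short reads by vector retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embed-Search-Align: aligning short reads by vector retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Classical short-read aligners index the reference with suffix arrays or
FM-indices and seed-and-extend each read. `esalign` implements the
alternative studied by recent transformer-DNA work: treat alignment as
*vector search*. An encoder $h_\Theta$ maps any DNA sequence to a
unit-length embedding such that cosine distance
$d(x, y) = 1 - \cos(h(x), h(y))$ tracks edit similarity. The reference $R$
(length $N$) is sharded into fragments $F_1, F_2, \dots$ of length 1250
overlapping by at least the maximum read length $Q_{\max} = 250$, so every
read is wholly contained in at least one fragment and the union of
fragments covers $R$. Fragment embeddings populate a vector store. A read
$r$ is embedded, the nearest $K$ fragments *per chromosome* are retrieved
(a diversity prior over the candidate slate), and the winner is decided by
Smith–Waterman (SW) fine-alignment over the slate:

$$v^* \approx \min_{F_j \in \{F_1,\dots,F_K\}} \mathrm{SA}(r, F_j),$$

with the global position reconstructed as
$q^* = q_{|F^*} + q_{F^*|R}$ — the within-fragment offset plus the
fragment's global start. Scoring uses the minimization convention
(match $m = -2$, mismatch $n = +1$, gap open $+0.5$, gap extend $+0.1$),
and the success of a (read, fragment) pair can be judged by the
normalized distance from the optimum,

$$d_{SW} = \frac{v^* - mQ}{(n - m)\,Q},$$

which is 0 for a perfect full-length match; the default acceptance bound
is $d_{SW} \le 2\%$. Direct evaluation of this formula at $Q = 250$ puts
the 2% bound at five mismatch-equivalents ($15 / 3$).

## Contrastive training

The encoder is trained by self-supervision only: sample a fragment
$F_j$ uniformly from the genome with $|F_j| \sim U([800, 2000])$, sample a
read $r_j$ *inside* it with $|r_j| \sim U([150, 500])$, and minimize the
in-batch-negative softmax loss at temperature $\tau = 0.05$:

$$\ell_r = -\log
\frac{e^{-d(h(r), h(F_j))/\tau}}
     {e^{-d(h(r), h(F_j))/\tau} + \sum_{i \ne j} e^{-d(h(r), h(F_i))/\tau}},$$

where the other $B - 1 = 15$ fragments of the batch serve as negatives.
To emulate sequencing noise, 40% of reads (in expectation) receive
substitution noise at a per-read rate drawn from $[0.01, 0.05]$. Reads and
fragments pass through the same weights with independently drawn dropout
masks (rate 0.1); gradients accumulate over 16 micro-batches per optimizer
update; the learning rate follows a one-cycle cosine schedule.

### Architecture choices left open by the recipe

The reference recipe fixes 6 layers, 12 heads, a 10,000-token vocabulary,
projection to $\mathbb{R}^{1020}$, dropout, temperature and the sampling
ranges, but not the token aggregation, model width, feed-forward width, or
positional encoding. The package's choices:

* **Aggregation**: masked mean over final-layer token states, then a linear
  projection to $\mathbb{R}^{1020}$, then L2 normalization — the
  sentence-embedding convention; unit norm makes cosine distance equal to
  half the squared Euclidean distance.
* **Width**: 768 for the full profile (64 per head); the reduced test
  profile (`encoder_config_small()`) uses 2 layers, 4 heads, width 256.
* **Feed-forward width**: equal to the model width. The usual 4x expansion
  is a throughput luxury the retrieval task did not need at desk scale.
* **Positions**: learned absolute embeddings up to `max_tokens` (512).
* **Tokenizer**: byte-pair encoding (the convention of the DNA-LM lineage
  the vocabulary size comes from), trained on non-overlapping 2 kb genome
  windows, greedy longest-match segmentation at encode time. The four
  single bases are always retained, so segmentation is lossless and
  total. On uniform synthetic DNA a 10,000-token vocabulary yields
  ~5.4 bases/token.
* **Initialization**: residual-branch output projections (attention output
  and feed-forward output) start at zero. A fresh encoder therefore
  reduces to a pooled bag-of-token-embeddings model, which already ranks
  containing fragments well; training then grows the contextual terms.
  This "zero-init residual" pattern also motivates the gentle default
  one-cycle peak ($3 \times 10^{-4}$, 20% warmup): early aggressive
  Adam steps can collapse the embedding geometry the init provides.
* **Distance in the loss**: $d = 1 - \text{cosine}$ (range $[0, 2]$); the
  recipe names cosine similarity but not the distance transform.

## Sharding and retrieval

`shard()` places fragment starts at $0, s, 2s, \dots$ with stride
$s = 1250 - 250 = 1000$ and right-anchors a final fragment at the
chromosome end, so coverage is total and every substring of length
$\le 250$ is contained in some fragment; a 3 Gb reference yields
$\approx 3 \times 10^6$ fragments. The vector store is local:

* `exact` backend — brute-force cosine scan (a matrix-vector product);
  appropriate through at least $10^5$ vectors.
* `approx` backend — an inverted-file (IVF) index: a k-means coarse
  quantizer with $\sim 2\sqrt{n}$ cells of which 20% are probed per query.
  IVF was chosen over graph-based indexes because a dependable, tunable
  implementation falls out of `stats::kmeans` directly; at the package's
  scales the exact scan is the default and the approximate backend is an
  accuracy-versus-speed option (top-1 agreement $\ge 99\%$ on random
  unit vectors in the test suite).

Ties in retrieval and alignment break deterministically on
(chromosome order, start position), and equal-score alignment ties are
additionally flagged, which matters for reads from repeats.

## Coordinates, SW bookkeeping, degenerate inputs

All coordinates are 0-based half-open internally; SAM output converts to
1-based at the boundary. The SW minimization is realized by negating the
scheme and running a maximizing affine-gap Gotoh recurrence; `open_gap` is
charged on the first gap base and `continue_gap` on each subsequent base.
Local alignment may soft-clip read ends (mutations at the first or last
positions), which is why the exact-location criterion allows
$|q^* - \hat q^*| \le 2$. IUPAC ambiguity codes in input FASTA are
replaced at load time by a seeded-random concrete base compatible with the
code, with a warning carrying the count — the model's alphabet is strictly
$\{A, C, G, T\}$. An empty genome, an empty FASTA record, duplicate record
names, a chromosome shorter than the read length, and a non-positive
temperature are all rejected with descriptive errors.

## The read simulator

`simulate_reads()` emulates the external simulator configurations used in
the benchmark rather than any specific tool's internals: per-base Phred
scores uniform over a configured band ($[10,30]$, $[30,60]$ or $[60,90]$),
substitution probability $10^{-\text{phred}/10}$ per base, and
position-wise Bernoulli insertions/deletions at rates
$I, D \in \{0, 10^{-2}\}$, after which the read is restored to exactly
$Q$ bases by continuing along the reference. The truth table records the
pre-noise origin (chromosome, 0-based start, strand). `strand_mode="both"`
reverse-complements a fair coin's worth of reads; the default is
forward-only, matching the training regime, and reverse-complement search
in `best_alignment()` covers the other orientation when enabled.
What the simulator does *not* model: empirical machine quality profiles,
sequence-context-dependent error rates, coverage bias, and paired ends —
so passing tests say the pipeline recovers planted origins under
idealized i.i.d. noise, not that it matches any particular instrument.

## Synthetic genomes

`generate_synthetic_genome()` draws i.i.d. uniform bases and can plant
exact repeat copies at recorded non-overlapping positions. Uniform DNA is
the *hardest* case for this retrieval design in one sense (no long-range
structure for the encoder to exploit) and the easiest in another (no
genuine repeat families beyond those planted, and chance 250-mer
collisions are vanishingly rare), which is exactly what makes planted
repeats a controlled probe of multi-mapping behaviour: a read from one
copy aligns with $d_{SW} = 0$ at every copy, fails the exact-location
criterion when the tie-break picks another copy, and passes the
distance-bound criterion.

## Problem sizes in the validation suite

The published configuration (6x12 encoder on a 3 Gb reference with
3M fragment vectors) is a GPU-scale training run. The package's own
validation uses sizes a single CPU handles: the acceptance run trains the
reduced profile on a 2 Mb two-chromosome synthetic genome (30 optimizer
updates of effective batch 256, ~7,700 pairs), indexes 2,000 fragments,
and evaluates 1,000 noisy reads ($Q = 250$, $I = D = 10^{-2}$, Phred
$[30, 60]$) at $K = 50$ and $K = 25$ per chromosome with the 2% distance
bound. Headline recall at full scale is reported in the high 90s; the
desk-scale run is checked against a recall floor of 0.95 and the
$K$-monotonicity trend, which is the directional claim this scale can
support. The exact-location plumbing (shard arithmetic, position
reconstruction, judging, intervals) is validated separately with a
deterministic k-mer-profile hash encoder, independent of any learning.

A note on training at this scale: with only 15 in-batch negatives and a
sharp temperature, the contrastive objective saturates once positives
beat the batch negatives by a few temperature units. From the
bag-of-tokens initialization that point is reached quickly, and
aggressive schedules then *degrade* whole-genome retrieval while still
lowering the loss — the small negative sample no longer constrains the
geometry the 2,000-fragment ranking depends on. The calibrated gentle
schedule both lowers the loss and improves retrieval containment; the
test suite asserts the improvement explicitly (held-out top-1 accuracy
after versus before training).

## Known limitations

* Desk-scale contrastive training sees ~2% of even a 2 Mb genome's
  possible pairs; recall numbers here are directional, not the published
  full-scale figures.
* The IVF approximate backend trades recall for speed and is not an HNSW
  replacement at the tens-of-millions-of-vectors scale.
* SW here is a correctness-first scalar implementation (no banding or
  SIMD striping); fine-alignment cost, not retrieval, dominates the
  evaluation loop.
* The encoder is not trained to map a read near its reverse complement's
  source fragment, so for `strand_mode="both"` data the pipeline embeds
  and queries both orientations, merges the two candidate slates, and
  lets fine-alignment decide the strand. This doubles retrieval and
  alignment cost when enabled.
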