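---
title: "Self-training splice junction filtering: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-training splice junction filtering: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Spliced aligners place RNA-seq reads across introns via reference-skip
CIGAR operations. Each distinct skip interval is a candidate splice
junction (SJ), but a substantial fraction of candidates are artifacts:
reads stacked by PCR or mapping bias, sequencing errors forcing a spurious
split, genomic repeats that let an anchor match on the wrong side of a gap,
and isolated single-read alignments. Because artifacts accumulate with
depth, deep datasets can contain more false junction *loci* than true
ones. `junctionfilter` scores and filters the candidate set using only the
alignments and the genome, training a fresh classifier for every dataset so
that it adapts to read length, error rate, species and mapper without any
pre-trained model.

# The junction model

A junction is keyed by its intron interval — contig, 0-based half-open
`[start, end)` — with strand resolved later from the boundary
dinucleotides. All internal coordinates use this convention; conversions to
1-based formats happen only in the readers and writers. Each supporting
split read contributes its anchors, uniqueness/pairing flags, edit
distance, and its mismatch-truncated match lengths on both sides of the
junction.

## Alignment-derived metrics

* **Support classes.** `nb_raw` counts all supporting split reads;
  `nb_unique_split` those spanning a single intron; `nb_unique_mapped`
  those mapped to one locus; `nb_reliable` those both uniquely mapped and
  properly paired. `reliable_ratio = nb_reliable / nb_raw` summarizes
  support quality independently of depth.
* **Offset entropy.** The anchor start offset of a read is the length of
  its upstream anchor. Under random sampling offsets are uniform, so the
  Shannon entropy (bits) of the offset distribution is near `log2(A)` for
  genuine junctions with enough reads and 0 for stacked support. Base 2 is
  a convention; any monotone rescaling would carry the same information
  into the classifier.
* **Anchor deviations.** With `n` reads over `A` possible offsets (capped
  at 20 positions), the expected per-position count is `E = n / A` and the
  reported deviation at position `i` is `|O_i - E| / sqrt(E)` — a
  standardized residual, chosen so that the feature scale is stable across
  coverage levels. Sharp localized departures from uniform coverage are the
  failure signal this captures. Deviations are computed on the upstream
  anchor only; the downstream anchor is mirrored information for reads of
  one length, and keeping one side halves the feature count.
* **Overhang and MaxMMES.** Both are `max` over reads of `min(left,
  right)`; for MaxMMES each side's run of matches is truncated at the first
  mismatch walking away from the junction, localized by comparing the read
  sequence against the genome base by base (correctness over speed at this
  scale; aligner mismatch strings are not required). `maxmmes <=
  max_overhang` always, and both are bounded by half the longest read.

## Genome-derived metrics

* **Splice sites.** The first/last two intronic bases are tested as-is and
  reverse-complemented; the strand resolving to GT–AG wins, then GC–AG /
  AT–AC; ambiguous bases give `novel`/unknown. Classification of a
  junction and of its reverse complement are consistent by construction.
* **Repeat hamming scores.** The last `W` bases of the left anchor are
  compared with the last `W` bases of the intron, and the first `W` of the
  intron with the first `W` of the right anchor (`W = 10` by default,
  anchored directly at the junction boundaries). A repeat spanning the
  boundary makes one of these distances collapse toward 0, which is
  exactly how repeat-triggered skips look; `min_hamming` is the feature.
* **Intron-size score.** Fitted from the positive training set:
  `L95` is the nearest-rank 95th percentile of positive intron lengths;
  lengths up to `L95` score 0 and longer introns score `log2(len / L95)`.
  The log keeps the feature bounded in practice while still growing with
  excess length, and the percentile adapts the score to the species at
  hand.
* **PWM and splicing-signal scores.** Position weight matrices are trained
  over windows around the donor (`[-3, +8)`) and acceptor (`[-20, +3)`)
  sites in transcript orientation, where negative offsets are upstream of
  the site — exonic for the donor, intronic (pyrimidine tract plus AG) for
  the acceptor, the geometry classical splice-site models use. Both
  windows are configurable. Probabilities are `(count + c) / (n + 4c)`
  with pseudocount `c = 0.5`; the PWM score is the log-odds against the
  genome-wide mononucleotide background, and the splicing signal is the
  log-likelihood contrast between the positive-set and negative-set
  models. These are deliberately two distinct, non-redundant features:
  one measures motif strength against the genome, the other against the
  rejected junctions. Unknown-strand loci are scored on both strands and
  take the maximum; windows that would leave the contig contribute 0.

# Self-training and classification

Rule thresholds (all configurable via `junction_rules()`) label only
extreme cases, because the training sets need precision rather than
completeness:

* positive: canonical or semi-canonical sites, `nb_reliable >= 5`,
  `entropy >= 1`, `maxmmes >= 12`, `mean_mismatches <= 1`,
  `min_hamming >= 5`;
* negative (any of): novel sites with `nb_raw <= 2`; `entropy == 0` with
  `nb_raw <= 5`; `min_hamming <= 2`; `maxmmes <= 6` with no reliable
  reads.

The two families are mutually exclusive by construction; everything else
stays unlabelled and is only scored. If either set is smaller than 20 the
run aborts with advice to relax the rules rather than silently training a
degenerate model. The intron-size model and both PWMs are fitted **after**
labelling, on the labelled sets, then added to every junction's feature
vector — a two-stage flow in which the cheap rule-eligible metrics
bootstrap the model-derived ones.

The sets are balanced by SMOTE: synthetic minority points are placed
uniformly on segments between a minority point and one of its `k = 5`
nearest minority neighbours (Euclidean, raw feature scale; `k` is clamped
for tiny minorities and a singleton minority falls back to duplication).
No synthetic majority points are ever created. A 100-tree random forest is
trained on the balanced 28-feature matrix; the reported probability is the
fraction of trees voting genuine, and the verdict is `probability >=
threshold` with `threshold = 0.5` by default (inclusive, so an exactly
split vote passes). One pipeline seed drives SMOTE sampling and forest
training, making whole runs byte-reproducible; junction metric computation
itself is deterministic and partitionable by contig, so results are
independent of the thread setting.

Unlabelled junctions never enter training: semi-supervised extensions are
possible but unvalidated, and the labelled sets are already large on
realistic inputs.

# The synthetic fixture

The generator builds the complete study environment in code: a random
genome (2 contigs x 100 kb by default), planted introns with log-normal
lengths (median ~100 bases, clamped to [61, 1500] so every intron
accommodates the signature windows), and spliced 76-base reads written
directly as SAM. Genuine junctions get GT–AG boundaries (half on each
strand), 30 reads each with uniformly drawn anchor offsets, reliable
flags, and 0.5% per-base substitution noise with consistent edit-distance
tags. The four spurious archetypes each violate exactly one designated
signature:

* *low-entropy*: four reads stacked on a single offset (entropy exactly 0);
* *non-canonical*: AA…TT boundaries (novel on both strands), one or two
  reads;
* *repeat-induced*: the 12 bases left of the junction are copied over the
  intron's last 12, so the hamming window distance is 0;
* *single-read*: one non-unique read with a substitution three bases from
  the junction (mismatch-truncated match of 2).

Writing alignments directly — rather than simulating a mapper — plants
the precise failure modes the classifier must learn while keeping the
fixture fully self-contained and byte-deterministic under its seed. What
the fixture does **not** emulate: realistic expression-level dispersion,
indels and clipped alignments, overlapping genes and shared splice sites,
intron retention, GC/repeat genome structure beyond the planted signatures,
and mapper-specific ambiguity. Passing tests therefore demonstrate the
mechanics of the method — extraction exactness, metric correctness,
self-training, and separation of the planted artifact classes — not
performance on real tissue data, where class boundaries are genuinely
fuzzier.

# Numerical and design choices

* Intron length bounds default to `[4, 500000]`: long enough to exclude
  tiny-deletion artifacts, loose enough for large mammalian introns; both
  configurable.
* A read counts as uniquely mapped when its hit-count tag (`NH`) is 1,
  falling back to `mapq >= 30` when the tag is absent, since mappers
  disagree on multi-mapping conventions. Secondary and supplementary
  records are excluded from support by default so a read is counted once.
* Reads clipped adjacent to a junction are counted normally but their clip
  lengths are recorded on each support row for downstream rule use.
* A skip flanked by zero aligned reference bases cannot define anchors; the
  record is dropped and tallied in the diagnostics rather than erroring.
* Text writers print integers plainly and other numbers with 17
  significant digits, so write → read → write is byte-identical and staged
  runs compose exactly to full runs (the full pipeline literally feeds the
  analysis stage's tab file to the filter stage).
* Reference comparison matches junction boundaries against annotated
  intron boundary positions (starts against starts, ends against ends),
  strand-aware only when both sides record a strand — mappers emit
  unknown strands, and strict strand matching would inflate the novel
  class.
* Nestedness of threshold sweeps is the subset relation: raising the
  threshold can only shrink (or preserve) the genuine set. On cleanly
  separable data the sets at several thresholds can coincide.

# Problem sizes

The test suite exercises the default study conditions — 300 genuine + 300
spurious junctions at 30x coverage (~9,700 reads) — for two seeds, a
three-sample shared-truth fixture (150 genuine junctions, 70% shared) for
the merged-versus-union comparison, and ~1,000 randomized instances per
metric for oracle equivalence, sizes chosen to keep a full run of the
suite in the low minutes on one CPU while still covering every code path
at realistic support levels.

# Limitations

* The rule thresholds, while configurable, were chosen for typical
  short-read data; exotic protocols (very short anchors, extreme depth)
  may need relaxed positive rules for the training floor.
* PWM windows assume at least ~20 bases of exonic/intronic context;
  junctions hard against contig edges fall back to a zero contribution.
* Only reference-skip evidence is used: junctions supported solely by
  clipped or unspliced reads are invisible.
* The classifier is per-dataset by design; there is deliberately no
  cross-dataset pre-trained model to ship.
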