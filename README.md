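# junctionfilter

Splice junctions (SJs) reported by spliced RNA-seq aligners are a mixture of
genuine introns and artifacts: short reads, sequencing errors and genomic
repeats routinely trigger misaligned split reads, and the number of distinct
false junctions grows with sequencing depth. `junctionfilter` separates the
two classes **after** mapping, for any aligner that emits reference-skip
(`N`) CIGAR operations, so junction cleanup is fully decoupled from the
choice of mapper. It is aimed at transcriptome annotators and anyone feeding
junction sets into transcript assembly, alternative-splicing analysis or
two-pass alignment.

## Method

Every distinct junction is the collapsed set of split reads sharing one
intron interval (0-based, half-open). For each junction the package computes:

- **Support classes** — raw split reads `nb_raw`, single-intron reads,
  uniquely mapped reads, and *reliable* reads (uniquely mapped **and**
  properly paired), plus the reliable-to-raw ratio.
- **Shannon entropy** of the anchor start offsets,
  `H = -Σ p_i log2 p_i`. Random sampling makes read starts uniform across
  the upstream anchor; stacked starts (low `H`) are suspicious.
- **Anchor deviations** — for anchor positions `i = 1..20`, the standardized
  residual `|O_i − E| / sqrt(E)` of observed versus uniform-expected counts.
- **Maximal overhang** and **MaxMMES** — `max_r min(left_r, right_r)` over
  supporting reads, where for MaxMMES each side's match run is truncated at
  the first mismatch walking away from the junction; the best attainable
  value is half the read length.
- **Genome-derived features** — donor/acceptor dinucleotides with strand
  resolution (GT–AG canonical; GC–AG, AT–AC semi-canonical), hamming
  distances between anchor-edge and intron-edge windows (low values flag
  repeat-induced misalignment), an intron-size score
  `log2(length / L95)` above the positive set's 95th-percentile length, and
  donor/acceptor position-weight-matrix and splicing-signal scores.

Filtering is **self-trained per dataset**: aggressive rules label a precise
positive set (canonical sites, strong clean support) and a precise negative
set (characteristic failure signatures); the intron-size and PWM models are
fitted on those sets; the sets are balanced with SMOTE; and a 100-tree
random forest over 28 canonical features scores every junction. Junctions
with probability ≥ 0.5 (tree-vote fraction) are kept — the threshold is
adjustable to trade recall against precision.

A companion toolkit handles tab/BED6/BED12/GFF3-hint/mapper-hint formats,
set algebra with per-sample markup, four-class comparison against a
reference annotation, and recall/precision/F1 evaluation. A synthetic
fixture generator plants genuine junctions and four spurious archetypes
(low-entropy, non-canonical, repeat-induced, single-read) so the whole
pipeline is testable without external data.

## Worked example

```r
library(junctionfilter)

spec <- fixture_spec(seed = 4, n_genuine = 80,
                     n_spurious = c(low_entropy = 20, non_canonical = 20,
                                    repeat_induced = 20, single_read = 20),
                     coverage = 20)
fx <- generate_fixture(spec, "demo_fixture")
res <- run_full(fx$paths$sam, fx$paths$genome,
                pipeline_config(seed = 4), output_dir = "demo_out")
ev <- evaluate_junctions(res$filtered, fx$truth)
```

This prints/produces:

```
synthetic junction fixture: 80 genuine + 80 spurious junctions, 1790 reads
analyzed: 160
kept:     80
recall 1.000 precision 1.000 F1 1.000
```

160 junctions are extracted from the alignments (half planted artifacts);
the self-trained forest keeps exactly the 80 genuine ones. The filtered tab
file carries every metric per junction:

```
id           contig start  end  strand nb_raw entropy  maxmmes min_hamming probability
JUNC00000001 ctg1   136    197  +      20     3.92     34      7           1
JUNC00000005 ctg1   1055   1195 -      20     4.32     33      5           1
JUNC00000006 ctg1   1301   1367 +      20     3.78     37      4           1
```

`res$model$importance` shows which features the forest leaned on (here the
anchor-deviation and reliable-support features dominate). Outputs are
written in tab and exon-BED12 formats for both the full scored set and the
filtered subset, along with a JSON report (counts, training-set sizes,
feature importances, seed).

Command-line wrappers live in `inst/cli/`: `junction-filter
<full|prep|junc|filter>` runs the pipeline, `junctools
<convert|set|compare|markup>` the set toolkit.

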