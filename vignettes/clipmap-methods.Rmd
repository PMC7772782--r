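---
title: "clipmap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clipmap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

clipmap implements the post-alignment analysis chain used to characterise a
splicing-regulatory RNA-binding protein from iCLIP data: read-level
preprocessing, definition of reproducible single-protein binding sites from
peak-caller output, transcript-region annotation, k-mer motif analytics, and
position-dependent RNA splicing maps that contrast regulated cassette exons
against inclusion-matched backgrounds. This vignette explains the models and
rules each stage implements, the parameters that matter, what the bundled
synthetic-data generator does and does not emulate, and the design decisions
taken where the procedure left room.

## 1. Read preprocessing

iCLIP reads begin with a 9-nt barcode region: positions 1–3 and 8–9 are
random nucleotides (the unique molecular identifier, UMI) and positions 4–7
are the sample barcode. The implemented rules are:

* **Quality filter** (`filter_barcode_quality()`): a read is discarded when
  more than one sample-barcode position has Phred quality < 20, or when any
  random-barcode position has quality < 17. Both comparisons are strict;
  Phred+33 encoding is assumed (configurable offset).
* **Demultiplexing** (`demultiplex()`): the 4-mer at positions 4–7 must match
  a sample barcode exactly (no mismatches); everything else goes to an
  `undetermined` bin. The full 9-nt barcode is trimmed and appended to the
  read name so the UMI survives for deduplication after alignment.
* **Adapter trimming** (`trim_adapter()`): the longest read suffix matching
  a prefix of `AGATCGGAAGAGCGGTTCAG` with at most `floor(overlap/10)`
  mismatches and at least 1 nt of overlap is removed. The published
  parameters do not fix a tie-break; we prefer the longest admissible trim,
  the conservative choice for iCLIP where untrimmed adapter bases would
  shift crosslink positions. A consequence worth knowing: a read whose
  insert genuinely ends in `A` loses that base.
* **Length filter** (`length_filter()`): reads shorter than 15 nt after all
  trimming are discarded.
* **UMI deduplication** (`dedup_random_barcode()`): among aligned read stubs
  sharing (chromosome, strand, 5'-end position), one representative per
  distinct UMI string is kept. The 5'-end position is the key because the
  reverse-transcriptase truncation site *is* the signal in iCLIP. Alignment
  itself is out of scope; the contract is defined on aligned stubs.

## 2. Binding-site definition

The input is a set of single-nucleotide significant crosslink sites, each
with a peak-caller score (a "PureCLIP score"), plus strand-specific
per-nucleotide crosslink-event tracks for four replicates and their merge.
The procedure (`call_binding_sites()`):

1. Drop the 5% lowest-scoring sites. The threshold is the type-7 empirical
   quantile; sites scoring exactly at the cutoff are kept, so a degenerate
   all-equal score distribution loses nothing. On integer-valued score
   distributions with heavy ties the realised drop fraction can therefore be
   well below 5% — this is the intended strict reading of "the 5% lowest".
2. Cluster remaining sites closer than 8 nt (strictly) into regions; discard
   regions narrower than 3 nt.
3. Resolve regions into 9-nt windows centered on the crosslink summit (the
   position with the highest merged event count). Regions shorter than 9 nt
   are extended symmetrically, 4 nt on each side of the summit; regions of
   exactly 9 nt are emitted unchanged even when their summit is off-center;
   longer regions are split iteratively — place a window at the current
   global summit, mask it, repeat while some unmasked position has a nonzero
   merged count and a would-be window with at least 2 significant positions
   that does not overlap an already placed site. Summit ties break towards
   the 5' end in transcript orientation (leftmost on `+`, rightmost on `-`).
   Windows that would leave the chromosome are dropped with a warning rather
   than clipped, keeping all sites exactly 9 nt wide.
4. Reproducibility: for each replicate the support threshold is the 20%
   type-7 quantile of that replicate's event sums over all binding sites; a
   site needs `>=` threshold support (the published wording is ambiguous
   between `>=` and `>`; `strict = TRUE` switches) in at least 3 of 4
   replicates.

Two structural invariants hold on every output and are asserted in the test
suite: all sites are 9 nt wide and strand-wise non-overlapping, and each
site's center is the admissible-summit argmax of merged events. The entire
pipeline is additionally verified against an independently coded brute-force
transcription of the rules on 1,000 random small instances.

Site *strength* is the log2-transformed score (the maximum significant-site
score inside the window).

## 3. Transcript-region annotation

Gene models come from a GENCODE-dialect GTF. Genes with annotation `level`
> 2 and transcripts with `transcript_support_level` > 3 (or non-numeric) are
removed. Per transcript, intervals for intron, CDS, 5'UTR and 3'UTR are
derived from the exon and CDS records; they tile the transcript span.

Assignment is strand-matched (iCLIP is strand-specific). By default genes
whose spans overlap another retained gene on the same strand are removed
first ("overlapping annotations were removed" is read at gene level;
`remove_overlapping_genes = FALSE` restores the alternative where such
sites become ambiguous). A site is then kept only when it overlaps exactly
one protein-coding gene; region labels are decided per site by letting each
retained transcript of that gene vote with the region it sees the site in
(multi-region overlaps within one transcript resolved by the hierarchy
intron > CDS > 3'UTR > 5'UTR), majority across transcripts, ties again by
the hierarchy. Transcripts without CDS records can only contribute intron
votes for coding genes. Densities are reported per 1,000 nt of the summed
region lengths over bound genes; the gene-biotype distribution uses the
unique-gene rule without the protein-coding restriction.

## 4. Motif analytics

All counting operates on DNA internally (Biostrings); motif labels are
converted to the RNA alphabet (`to_rna()`) for presentation only.

* `sample_sites()` draws up to 5,000 sites per region class, uniformly
  without replacement, so region classes of very different sizes are
  comparable.
* `pentamer_window_counts()` counts overlapping pentamers in the 9-nt site
  and in the 20-nt flanks up- and downstream (transcript orientation,
  minus-strand sites reverse-complemented) and averages over sites.
* `positional_profiles()` tallies, for each offset −100..+100 relative to
  the site center, the fraction of sites whose pentamer starting at that
  offset equals each of the 1,024 pentamers. At every offset that can hold a
  full pentamer the 1,024 frequencies partition the sites and sum to 1; the
  last four offsets of the window cannot and are reported as 0.
* `cluster_profiles()` ranks pentamers by in-site frequency (the CDS class
  in the analysis scripts), takes the top 300 and k-means clusters their
  profiles with 3 centroids. k-means is seeded and restarted (`nstart = 10`)
  so the assignment is reproducible; with fewer than 300 pentamers observed
  the rank list is truncated.
* `triplet_strength_analysis()` counts GAA and UUC (scanned as TTC on the
  sense strand — the control triplet is counted in the site's own sequence,
  not on the opposite strand) in a 49-nt window centered on the site. The
  published description gives both "49-nt windows" and "within 30 nt of the
  center" for this analysis; the Methods number (49) is the default and the
  width is a parameter. Counts are maximal non-overlapping left-to-right
  placements, which for period-3 triplets equals the overlapping count.
  Strength distributions are summarised per count category, capped at "7+".
* `consecutive_run_analysis()` classifies sites by the maximal chain of
  triplet occurrences separated by exactly 0, 1 or 2 nt: `0-1`,
  `ge2_direct`, `ge2_gap1`, `ge2_gap2`, with `ge2_scattered` added for
  sites carrying two or more triplets that form no chain at any allowed
  gap (the published classes leave these sites undefined).

## 5. Cassette-exon filtering and the AS region

Cassette-exon tables are read and written in the rMATS SE dialect (0-based
starts, comma-joined per-replicate values, `SAMPLE_1` = control by
default). dPSI is defined as mean knockdown PSI minus mean control PSI, so
"more skipping after knockdown" is negative. An event is significant when
FDR < 0.05, |dPSI| > 0.05 and the log2 of the mean junction-read support
exceeds 5, all strict. Junction support is the per-replicate sum of
inclusion plus skipping junction reads, averaged over all replicate
measurements before the log — the published phrase "log2-transformed sum …
(mean between replicates)" admits the other order, which is available via
`log_before_mean = TRUE`. FDR is consumed from the table, not recomputed.

The alternatively spliced region of an event runs, in transcript
orientation, from 100 nt before the 5' splice site of the upstream
constitutive exon to 100 nt after the 3' splice site of the downstream
constitutive exon; `as_region_overlap()` attaches all strand-matched
binding sites inside it and the strongest site strength.

## 6. RNA splicing maps

For each regulated set, occupancy is the fraction of events with at least
one crosslink event at each offset −100..+100 around six anchors: the 3'
and 5' splice sites of the upstream, alternative and downstream exon
(anchor = the terminal exonic nucleotide; minus-strand events are counted
in mirrored orientation). Windows of neighbouring anchors may overlap on
short exons/introns and are counted independently per anchor, as in the
published metaprofiles.

Because crosslink coverage on an exon scales with its inclusion level, a
raw comparison against all unchanged exons would confound binding with
abundance. The background is therefore PSI-matched: the regulated set's
control-PSI distribution is split into 5% quantile bins and an equal number
of unchanged events is drawn from each bin, without replacement within an
iteration. Bins with too few pool events fall back to sampling with
replacement, and empty bins to the nearest-PSI pool events, each with a
warning — at the intended scale (hundreds of regulated events over a much
larger pool) these fallbacks do not trigger. Subsampling is repeated
`n_iter = 50` times (the published methods say 50, one figure legend says
100; the parameter is exposed), and per position the background mean and SD
give `z = (f_obs − mean)/sd`. p-values are one-sided upper-tail normal —
only enrichment over background is displayed in this analysis — with an
empirical-rank alternative (`pvalue = "empirical"`); Benjamini–Hochberg
adjustment runs across all offsets and anchors of one set's map
(consistent with the BH use elsewhere in the analysis chain; the published
text says only "adjusted p-value"). Positions with zero background SD get
`z = 0`, `p = 1` and a flag. A position is significant when `z > 0` and the
adjusted p-value is below 0.05.

`exon_crosslink_density()` (log2 of length-normalised events with a
pseudocount of 1) documents the inclusion-coverage bias that motivates the
matching.

## 7. The synthetic study

`synth_config()` + `simulate_study()` generate a complete desk-scale study
so the whole chain can run and be tested without external data. Defaults —
chosen once as the study conditions for all tests and analysis scripts:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 300 | genes; one cassette-exon event each |
| `exons_per_gene` | 3–8 | a middle exon is the cassette exon |
| `exon_len`, `intron_len` | 80–250, 150–500 nt | compact gene geometry |
| `n_replicates` | 4 | iCLIP replicates |
| `background_rate` | 0.15 events/nt | sparse baseline crosslinking |
| `dispersion` | 0.5 | NB size; strongly overdispersed counts |
| `enrichment_factor` | 12 | motif-run rate multiplier, ramped 3'-wards |
| `region_enrichment` | 5 | regulated-region (exon body / flanks) multiplier |
| `motif_repeat_range` | 2–6 | consecutive GAA triplets per planted run |
| `ce_fraction_down`, `ce_fraction_up` | 0.08, 0.04 | regulated fractions (down-skew as observed for an inclusion-promoting factor) |
| `dpsi_effect` | 0.2 | mean planted \|dPSI\| |
| `n_psi_replicates` | 5 | paired control/KD PSI replicates |
| `psi_concentration` | 300 | beta concentration; replicate PSI SD ≈ 0.02–0.03, typical of rMATS estimates at moderate depth and required for the planted effects to be recoverable through the stage filters |
| `read_depth` | 60 | junction reads/replicate; most events clear the log2 > 5 filter, a 5% low-depth fraction exercises it |

The generator emulates the statistical structure downstream stages assume:
NB-overdispersed per-nucleotide counts (the published data do not
characterise the count distribution; NB is the simplest overdispersed
choice and is a modelling decision, not a claim about the source data);
clustered pile-ups over planted GAA runs with the rate ramped towards the
run's 3' end, so sites position near the end of motif-enriched stretches;
rate scaling with the number of planted triplets, so caller scores grow
with motif count; exon-body binding on down-regulated events and
flanking-exon binding on up-regulated ones; alternative-exon coverage
scaling with control PSI (the abundance bias); and paired beta-distributed
PSI replicates with a shared per-pair offset, a paired-t p-value and BH FDR
across events. Significant sites come from a clearly-labelled *surrogate
caller* — position significant when its merged count exceeds the per-gene
99% count quantile, score = merged count. It is a stand-in for an HMM peak
caller on synthetic runs only and is not claimed to be equivalent.
Per-gene RNG sub-streams derived from one master seed keep each gene's data
stable under unrelated config edits.

What it does not emulate — and hence what green tests do not show about
real data: sequence-dependent crosslinking biases (e.g. the uridine
preference of UV crosslinking), alignment and mappability artefacts,
multi-isoform genes (one transcript per gene; the multi-transcript voting
rules are exercised by constructed fixtures instead), antisense or
intergenic signal, correlated replicate noise, and non-cassette splicing
event types. Generated genomes are uniform-random, so pentamer backgrounds
are flat; real intronic U-richness is absent.

## 8. Numerical choices and problem sizes

All quantiles are type-7 (linear interpolation). Coordinates are 1-based
closed inside R (the GRanges/Biostrings convention); BED, bedGraph and
rMATS files are converted at the boundary. Determinism: every stochastic
step takes a seed and restores the caller's RNG state; repeated runs are
byte-identical, which the test suite asserts on all written artefacts.

The test and acceptance runs use desk-scale sizes chosen to exercise every
code path with comfortable statistical margins: the default 300-gene study
(~550 kb of genome, ≈180 reproducible binding sites, ≈32 regulated
events), 2,000-gene runs for PSI-table calibration, 1,000 random ≤1-kb
instances for the binding-site oracle, and 5,000 sites for the
motif–strength recovery.

## 9. Known limitations

* The unique-gene and overlapping-gene filters implement one reading of an
  ambiguous published sentence; the alternative is available behind a flag
  but the default was chosen to match the stated intent of uniqueness.
* Splicing-map p-values assume approximate normality of the background
  occupancy fractions; at very small regulated-set sizes the empirical-rank
  option is the safer choice, at the cost of a resolution floor of
  1/(n_iter + 1).
* The AS-region window and splicing-map anchors assume intact three-exon
  geometry; events with overlapping exon annotations are not special-cased.
* `percent_inclusion()` implements the RT-PCR molarity formula exactly and
  is provided for completeness of the event-level toolkit; no gel
  quantification is modelled.
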