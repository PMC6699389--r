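---
title: "SNP-aware pre-miRNA processing and isomiR discovery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-aware pre-miRNA processing and isomiR discovery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpIsomiR)
```

## The problem

A microRNA is excised from its hairpin precursor (pre-miRNA) by two RNase
III cuts: Drosha defines one end of the mature sequence, Dicer the other,
leaving a ~22-bp miRNA:miRNA\* duplex with a 2-nt 3' overhang on each
strand. Because the cut positions are read off the hairpin's sequence and
secondary structure, a single nucleotide polymorphism (SNP) inside the
precursor can move them, producing mature isoforms (isomiRs) with shifted
ends or substituted bases. Such isomiRs retarget messenger RNAs and are
candidate disease markers that can be predicted from an individual's
genotype alone.

`snpIsomiR` implements that prediction end to end for one individual:

1. extract the biallelic SNVs a sample carries from its VCF;
2. place each SNP at a strand-resolved, 0-based index inside every
   overlapping pre-miRNA hairpin;
3. enumerate all $2^n - 1$ SNP-substituted precursor sequences per hairpin;
4. predict the four processing sites (P5_5, P5_3 on the 5' arm; P3_5, P3_3
   on the 3' arm) of canonical and variant precursors with per-site
   classifiers;
5. call as isomiRs the variant-induced mature sequences absent from the
   canonical candidate set, and attribute them to their SNP subset
   ("functional SNPs");
6. validate calls by exact substring search in small-RNA sequencing reads.

## Coordinate conventions and the spacer rule

Genomic coordinates are 1-based inclusive (VCF/GFF convention); all
within-hairpin indices are 0-based. A SNP at genomic position $POS$ inside
a hairpin spanning $[start, end]$ has spacer $d = POS - start$ on both
strands. On the plus strand the hairpin index equals $d$; on the minus
strand the hairpin runs antiparallel to the reference, so the index is
found counting $d$ from the back, $L - 1 - d$, and the VCF alleles are
complemented onto the hairpin strand. This is the only rule consistent with
front-to-back placement of plus-strand SNPs and back-to-front placement of
minus-strand SNPs at their annotated distances. A `complement_minus = FALSE`
switch preserves the literal (uncomplemented) allele reading for users who
want it; complementing is the default because substitution happens in the
hairpin-strand sequence. Reference-base verification against the hairpin
sequence is on by default, since annotation sequences may predate the
variant build.

Variant enumeration takes all non-empty SNP subsets regardless of phase:
the package deliberately does not restrict combinations to
haplotype-consistent subsets, trading specificity for completeness. A cap
(default 12 SNPs, i.e. 4095 variants per hairpin) bounds the combinatorial
growth.

## Folding

Two folding backends sit behind one contract (sequence in, dot-bracket and
energy out). The `vienna` backend shells out to an RNAfold binary when one
is on the PATH. The `internal` backend — the package default — is a
weighted base-pair-maximization dynamic program compiled via Rcpp: minimum
hairpin loop 3 nt, pair weights GC/AU/GU $= -3/-2/-1$ (reported on a
kcal/mol-like scale). The internal backend is the default because it is
bit-reproducible across machines and fast enough to fold every training
window; it ignores stacking context and loop entropies, so its energies are
ordinal rather than physical. The terminal loop is taken as the unpaired
run directly enclosed by the deepest-stacking helix, with ties going to the
5'-most candidate; sequences that fold with no base pairs are rejected as
non-hairpins.

The four flank-window MFE features (below) are always scored with the
internal energy model, whichever backend folded the hairpin: tens of
thousands of short windows are scored per training run, which rules out one
process launch per window, and a single consistent energy scale across
examples is what the classifier needs.

## The duplex alignment and the 115 features

For a candidate 5'-arm mature start $p$ (window length 22), the
miRNA:miRNA\* duplex is laid out over exactly 25 columns: the mature row
5'→3' on top, its 3'-arm partners (read 3'→5') below, `-` inserted opposite
bulges on either strand so paired bases share a column, the star strand's
2-nt 3' overhang in leading columns when those nucleotides exist, and
right-padding with `-` up to column 25. The 25-column width is the smallest
window holding a 22-nt mature plus overhang/bulge columns, and it is what
makes the feature counts below come out exact.

The feature vector has 115 entries, in fixed order:

| block | count | content |
|---|---|---|
| MFE | 5 | duplex MFE; refolds of windows starting 9/5/3 nt left and 3 nt right of the Drosha site, through the 5'-arm Dicer site |
| duplex structure | 50 | per column × strand, a code from {AM, CM, GM, UM, AN, CN, GN, UN, -N} (M paired, N unpaired, `-` gap) |
| Drosha left flank | 18 | 9 positions × (own base, partner base), same coding |
| Dicer right flank | 6 | 3 positions × 2, same coding |
| pairing | 25 | per column, a code from the 16 base pairs + 8 half-gaps + `--` padding |
| gap counts | 3 | `-` frequency in duplex windows +3..+8 and +9..+12 right of the Drosha column and −2..+2 around it |
| mature row | 7 | first-nucleotide type; first-nucleotide-paired; A/C/G/U/`-` frequencies over the 25 columns |
| distance | 1 | Drosha site to terminal-loop start |

Categorical codes are fixed integers scaled into $[0,1]$ (code/9 for the
structure alphabet, code/25 for the pair alphabet); the distance is divided
by 100. Windows that run off the hairpin are coded as gaps/padding rather
than raised as errors, so sites near the hairpin ends remain scoreable.
Three counting choices deserve a note, since the block totals constrain
them but do not determine them uniquely: the 50 duplex-structure features
are 25 columns × 2 strands (symmetric with the 18 = 9 × 2 flank count);
the 25-symbol pair alphabet is the 24 base/half-gap symbols plus `--` for
padding columns; and the mature gap frequency is counted within the mature
alignment extent only, so neither the star overhang columns nor right
padding register as mature-row gaps (a perfect stem scores exactly 0).
The distance feature runs from the 5'-arm Drosha site (the mature start) to
the terminal-loop start, following the biological definition of the
feature.

## Training-set geometry and the classifiers

Each of the four sites gets its own binary classifier. For a hairpin with
an annotated 5p mature $[s, e]$ (and a 3p span either annotated or derived
through the pair table with the 2-nt overhang correspondence,
$P3\_3 = \text{partner}(P5\_5) + 2$, $P3\_5 = \text{partner}(P5\_3) + 2$),
the positive example of a site is its annotated position and the negatives
are every offset in $\pm 15$ whose 22-nt window stays inside the arm.
3'-arm candidate positions are carried into the 5'-arm frame through the
pair table (nearest paired neighbour within 3 nt, with antiparallel
adjustment) before feature extraction, mirroring how the 3'-arm training
windows are constructed from the 5'-arm ones. The $\pm 15$ range is a
design choice: taking only the two 1-nt-shifted windows as negatives
generates far too few to learn from, and $\pm 15$ covers the 5-nt
evaluation tolerance with margin while staying inside typical arms.

The classifier is a soft-margin RBF SVM (e1071/libsvm), $C = 10$,
$\gamma = 1/115$, on features standardized by training-set statistics, with
class weights balancing the ≈1:30 positive:negative ratio. Only a
real-valued decision score is required of the classifier, so swapping in
another margin scorer means implementing one function. At prediction time
every admissible position on the relevant arm is scored and the top five
kept (ties to the 5'-most position); the canonical candidate set used for
isomiR calling is exactly those five per site, which absorbs rank
instability near the true site and suppresses false isomiR calls.

Position-deviation accuracy — the fraction of held-out hairpins whose
rank-1 candidate falls within 5 nt of the annotation — is the evaluation
the package exposes. Accuracies on real miRBase-annotated hairpins depend
on the annotation release and on a feature-selection step not reproducible
here, so the package's tests instead assert parameter recovery on the
synthetic generator below; users with miRBase data can run
`evaluate_matpred()` on it directly.

## What the synthetic generator emulates — and what it does not

`fixture_spec()` hairpins are two complementary 45-nt arms around an 8-nt
loop (98 nt total, inside the 60–110 nt range of real precursors), with a
22-nt mature planted at a uniformly random offset 4–19 from the hairpin 5'
end. The planted, learnable determinants are: a paired U at the mature 5'
start preceded by G; strand mismatches at fixed offsets (start−3, end+2);
a 4% background mismatch rate outside protected neighbourhoods; and a 3p
span carrying the canonical 2-nt overhang. The loop is inert (all A) and
the three loop-adjacent stem positions are G/C-clamped so the planted
terminal loop is also the folded one — this determinism is what lets truth
tables drive exact assertions. Companion generators emit a per-sample VCF
(with indel/multi-allelic/hom-ref decoys) and a read set with canonical
matures, spiked SNP-substituted matures at known counts, and random noise.

With ~24 admissible positions per site, a random ranker's within-5-nt
accuracy is ≈0.46, so the ≥0.80 held-out recovery asserted in the tests
(140 training / 60 held-out hairpins; end-to-end recovery on a separate
100-hairpin bundle) is informative, not vacuous. What passing these tests
does *not* show: performance on real hairpins, whose processing
determinants (CNNC, UG, mismatched GHG and friends) are richer than the
planted ones; robustness to multi-loop precursors; or behaviour under
sequencing error, which the read generator models only as uniform noise
reads. Generator defaults are fixed study conditions, not tuning knobs.

## Numerical and degenerate-input choices

- Score ties at prediction break toward the 5'-most position; training is
  deterministic given the seed, and models serialize/reload bit-exactly.
- A variant precursor that no longer folds (no base pairs) is recorded as
  fold-disrupted and excluded from calling rather than erroring the run.
- Two SNPs at one hairpin index are a hard error (the VCF reader already
  splits multi-allelic records into per-allele records upstream).
- Multi-allelic VCF rows contribute one record per carried single-
  nucleotide alternate allele; rows whose carried alleles are all
  indels are skipped and counted, so records plus skips always equal the
  data-line count.
- Read validation is exact substring matching after U/T normalization;
  a mismatch-tolerant mode is deliberately out of scope.
- isomiR-vs-canonical comparison is at sequence level by default (a
  `compare = "position"` switch gives the positional reading): a
  SNP-containing mature at an unshifted position still differs in sequence
  and is biologically an isomiR.

## Problem sizes used in the shipped tests

The test suite trains on 140 synthetic hairpins, holds out 60 for
recovery, runs the full pipeline on a 100-hairpin bundle, and checks the
mapping, round-trip and read-count oracles on 100×20, 1000 and 1000-read
instances respectively — sizes at which the whole suite completes in a few
minutes on one core while keeping the binomial uncertainty on the 0.8
recovery thresholds small relative to the observed margins.
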