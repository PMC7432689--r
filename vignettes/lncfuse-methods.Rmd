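---
title: "lncfuse: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncfuse: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem and the model

Long non-coding RNAs are transcripts of at least 200 nt with no
protein-coding capacity. Distinguishing them from mRNAs without any
reference alignment rests on sequence-intrinsic signals: mRNAs carry one
long open reading frame with biased codon usage; lncRNAs do not. lncfuse
classifies a transcript by fusing three views of the sequence:

* the **OFH vector** `[l_ORF, l_ORF/L, S_F, S_H]` of classic
  coding-potential statistics,
* the **k-mer frequency vector** over all `4^k` words (k = 6 by default),
* the raw sequence as a **one-hot matrix** (4 × maxlen, maxlen = 3000 by
  default).

Each view feeds a small submodel (dense stacks for the two vector views;
a convolutional module conv → batch-norm → ReLU → max-pool for the
one-hot view). The activations of each submodel's last hidden layer — its
*descriptor* — are concatenated and passed to a dense fusion network with
a sigmoid output giving `P(lncRNA)`. lncRNA is the positive class
(label 1) throughout, so sensitivity measures lncRNA recovery.

Training is deliberately two-step:

1. each submodel is pretrained independently against the labels with
   binary cross-entropy;
2. the fusion network is trained on frozen submodels, then all parameters
   are fine-tuned together at a ~10× reduced learning rate.

During the frozen phase the submodels run in inference mode, so their
batch-normalization running statistics are also untouched; "frozen"
means bitwise-unchanged parameters, which the test suite asserts.
Any non-empty subset of the three modalities can be fused through the
same code path, giving the single-modality and pairwise ablation
architectures, and a majority-vote decision-fusion baseline is provided
for comparison.

# Feature conventions

**ORF.** Forward strand only, three frames; start codon ATG; stops TAA,
TAG, TGA; no internal in-frame stop; the reported length *includes* the
stop codon (the dominant convention in coding-potential tools; it shifts
`l_ORF` by a constant 3). Ties are broken by length, then 5'-most start,
then lowest frame index, so results are deterministic.

**Fickett score.** For each base, the codon-position asymmetry
`B_pos = MAX(B1,B2,B3)/(MIN(B1,B2,B3)+1)` is computed over the whole
transcript anchored at the 5' end (not at the ORF start), together with
the composition fraction over non-N bases; the eight statistics map
through the classic TESTCODE lookup bins (shipped as a versioned TSV
under `extdata`) and combine as a weighted sum. Note that `B_pos` is only
asymptotically invariant under sequence repetition — the `+1`
regularizer shifts the raw values slightly, which can move a statistic
across a lookup-bin boundary; the tests therefore check exact
repetition-invariance on composition and bin-stable cases only.

**Hexamer score.** `F_c` is estimated from in-frame (step-3) hexamers
inside each coding training transcript's longest ORF; `F_nc` from step-1
windows over noncoding training transcripts; a pseudocount of 1 in every
one of the 4096 cells prevents `log(0)`. Scoring slides step-1 windows
over the *whole* transcript (`m = L − 6 + 1`), the printed formula of the
method this package re-implements, even though the frequencies are
"in-frame" quantities; the step is exposed as an argument
(`hexamer_score(..., step = 3)`) so the alternative is testable. The
logarithm is natural; the base only rescales the feature. Windows
containing N are skipped and the mean taken over the remainder; an
all-skipped transcript scores 0.

**k-mer and one-hot.** k-mer frequencies are counts over valid (N-free)
windows, so the vector sums to 1 whenever any valid window exists.
One-hot rows are ordered A, T, C, G with codes (1,0,0,0) ... (0,0,0,1);
transcripts longer than maxlen keep their 5' prefix, shorter ones are
right-padded with zero columns, and N positions give all-zero columns.
N never fabricates a base identity anywhere in the feature layer.

**OFH standardization.** `l_ORF` is on the scale of thousands while the
other entries are order-1, so the OFH matrix is standardized to
training-set mean/sd before entering its submodel; the scaling
parameters are bound to the trained model together with the hexamer
table and Fickett lookup, because predictions are undefined without the
training-time feature state.

# Optimization choices

The original method's searched hyper-parameters are not available, so the
defaults here are fixed and documented: dense stacks 64–32 (OFH) and
128–64 (k-mer); convolutional module 32 filters, kernel 10, pool 5, two
blocks, then a 64-unit dense layer; fusion 64; dropout 0.2; Adam at 1e-3
(fine-tuning 1e-4); batch 128; 20/10/10 pretrain/fusion/fine-tune epochs.
`fast_model_config()` shrinks this (16 filters, one block, maxlen 500,
8/6/3 epochs) so a full train/evaluate cycle on a few thousand synthetic
transcripts takes minutes on one CPU; the reduced maxlen is a deliberate
desk-scale truncation, stated wherever it is used. Early stopping is off
(fixed epochs) for reproducibility. Initialization is He-scaled normal;
all stochasticity (init, shuffling, dropout) draws from R's RNG, so a
seed makes runs bit-reproducible single-threaded. The engine's backward
passes are verified against numerical differentiation in the test suite.

# Evaluation

ACC, Sn, Sp and MCC follow the standard confusion-count definitions; MCC
of a degenerate denominator is defined as 0 (the formula is undefined
there). Cross-validation is stratified (matching the balanced two-class
design), and the hexamer table and OFH scaling are re-estimated inside
each training fold — the per-fold table fingerprints are exposed so the
leakage guard is assertable. Hyper-parameters are fixed across folds.
McNemar's test uses the exact two-sided binomial form when the
discordance count `b + c < 25` and the continuity-corrected chi-square
form `(|b−c|−1)²/(b+c)` otherwise, a standard switchover; a fully
concordant pair returns p = 1 with a degeneracy flag.

# The synthetic world

The generator emulates exactly the signals the classifier exploits, and
nothing else. Coding-like transcripts are a random 5' UTR + ATG +
codon-biased sense codons + stop + random 3' UTR, with ORF coverage drawn
from [0.5, 0.9] and at least 153 nt. Noncoding-like transcripts are
i.i.d. base draws at the target GC (0.5), rejection-sampled until the
longest ORF is ≤ 120 nt. Lengths are uniform on [200, 1000] for both
classes: a desk-scale compromise — lncRNA lengths center below 1 kb, and
the rejection step (no ORF > 120 nt) becomes exponentially expensive for
multi-kilobase random sequence. Default 1000 transcripts per class.

The default codon bias is a stylized distribution, not an organism table:
75% of the mass sits on the 27 purine-only (A/G) codons with geometric
decay, the rest spread uniformly. The purine restriction is deliberate:
no stop codon is purine-only, so the purine codon set is closed under
frame shift, and out-of-frame windows over a biased ORF still land inside
the in-frame hexamer support. A generic lexicographic skew fails this —
its out-of-frame windows fall to the pseudocount floor of `F_c` and drag
the coding-class mean hexamer score below zero under whole-transcript
step-1 scoring — whereas real codon usage, like the purine-closed bias,
produces a frame-robust signal. With the default, the coding-class mean
`S_H` is strongly positive and the noncoding-class mean strongly negative
under a self-built table, which the tests assert.

What the generator does **not** emulate: splicing structure, polyA
signals, realistic UTR composition, GENCODE length distributions,
pseudogenes, or lncRNAs that retain degenerate ORF remnants. The classes
are far more separable than real annotation data — a single ORF-length
threshold already classifies most of the benchmark. A green end-to-end
test therefore establishes that the pipeline wiring, feature
definitions, optimization and fusion logic work and that fusion does not
lose accuracy relative to its parts; it does not establish real-data
accuracy at the level the original study reports, which would require
the full GENCODE/RefSeq corpora and full-scale training.

# Degenerate inputs and errors

Transcripts shorter than 6 nt cannot be featurized; prediction flags
them (`status = "too_short"`, NA probability) rather than guessing.
Sequences of all N yield zero k-mer vectors, zero hexamer windows
(score 0) and all-zero one-hot columns. FASTA reading normalizes U→T and
maps other unexpected characters to N with a counted warning; empty
records are skipped with a warning; duplicate ids across classes are a
hard error. The generator refuses configurations whose minimum length
cannot fit a 153 nt ORF, and names the violated constraint when
rejection sampling cannot satisfy the spurious-ORF cap.

# Known limitations

* No reverse-strand ORFs, alternative start codons, or translation-level
  features; no secondary-structure modality.
* The hand-rolled neural engine is single-threaded and CPU-oriented; it
  is exact but not fast at the original study's data scale.
* The Fickett lookup content is the classic TESTCODE table as
  redistributed by standard coding-potential tools; the package's tests
  verify internal consistency (dual-implementation oracle), not the 1982
  print original.
* No train/test near-duplicate removal beyond id uniqueness is
  performed.
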