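---
title: "Two-stage denoising of 454 amplicon reads: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage denoising of 454 amplicon reads: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

454 pyrosequencing infers homopolymer lengths from analog flow signal
intensities: at each nucleotide flow, the light signal is roughly
proportional to the number of bases incorporated, and the base caller
rounds it to an integer. The dominant error modes follow directly from
this readout:

* **homopolymer over/under-calls** — the signal's standard deviation grows
  with run length, so a true run of 3 is occasionally read as 2 or 4
  (deletions and insertions);
* **positional degradation** — signal noise accumulates along the
  flowgram, so error rates rise toward the 3' end of the read;
* **CAFIE phase artifacts** — *carry-forward* (leftover nucleotide
  incorporates templates one flow early, leaking signal into an earlier
  flow of the same base) and *incomplete extension* (templates lag one
  flow behind, deferring signal), both concentrated around homopolymers.

In 16S rRNA amplicon studies these errors inflate the number of apparent
sequence variants and, downstream, the number of OTUs. Denoising trades
read length and yield against the residual error rate.

`denoise454` implements a two-stage corrector:

1. **Error classifier.** A support vector machine with a Pearson VII
   universal kernel (PUK), trained by sequential minimal optimization on
   thirteen per-position attributes extracted from the flowgram, flags
   nucleotide positions that are likely sequencing errors.
2. **Masking-aware preclustering.** Reads are projected into a template
   alignment's column space, the flagged positions are masked, and an
   abundance-sorted single-linkage-style preclustering merges each
   low-abundance read into the first sufficiently abundant read within a
   2% mismatch budget — masked columns do not count as differences. Reads
   that never merge have their masked positions restored from the original
   call, so masking alone never alters a sequence.

The intuition: an erroneous read is a low-abundance satellite of an
abundant correct sequence. Masking the classifier's suspicions lets such
satellites merge with their center even when the raw mismatch count would
just exceed the budget, while restoration guarantees that unconfirmed
suspicions are harmless.

## The thirteen attributes

For each called base, five attributes describe the position itself:

1. position in the (trimmed) read, 1-based;
2. Phred quality score;
3. homopolymer code — `N` outside runs; within a run `A` marks the first
   position, `Z` the last, and `B`, `C`, ... the second, third, ...
   interior positions (a run of 2 is `AZ`, the maximal run of 8 is
   `ABCDEFGZ`);
4. carry-forward sensitivity — whether a flow of this base's nucleotide
   occurs, uncalled, among the flows skipped immediately upstream of the
   base's calling flow (the canonical carry-forward signature; the first
   base uses the flowgram start as its boundary);
5. flow signal intensity at the base's calling flow, in flow units.

Four more are copied from each of the two neighbouring bases: their Phred
score, homopolymer code, flow intensity, and the *highest uncalled flow
value* between the base's calling flow and the neighbour's (0 when the
flows are adjacent) — a strong uncalled signal next to a position is
exactly what an off-by-one rounding leaves behind. Missing neighbours at
the read ends take sentinels (Phred −1, code `N`, intensities 0), keeping
the schema rectangular. For the kernel, the three categorical code fields
are one-hot encoded over their nine levels and all columns are min–max
normalized to [0, 1] with statistics frozen from the training subset.

## Classifier training protocol

Labelled instances are dereplicated on exact (feature vector, label)
equality, split 1:9 stratified by class into a training subset A and a
held-out subset B, and subset A is rebalanced by uniform sampling without
replacement to 132 instances per error type plus 700 clean instances.
When a class falls short of its target all targets are scaled down
proportionally (with a warning) rather than silently changing the class
mix. Four classes are kept throughout — clean, insertion, deletion,
substitution — so that each error type is trained and assessed equally;
the binary collapse to error/clean happens only at masking and evaluation
time.

The kernel is `K(x,y) = 1 / (1 + (2·sqrt(2^(1/ω)−1)·||x−y|| / σ)²)^ω`
with ω = σ = 1 and soft-margin cost C = 1 (the classical defaults of the
toolkit that popularized the kernel; all three are exposed as arguments).
One binary machine is trained per class pair (six machines) with SMO via
`kernlab`; each machine's support vectors, dual coefficients and offset
are extracted into a plain, JSON-serializable model, and *all*
predictions are computed in-package from that support set by pairwise
voting (ties broken in the fixed order clean < insertion < deletion <
substitution). This makes serialization exact by construction — a
reloaded model is the same decision function — and lets tests verify the
decision values against a brute-force kernel sum.

A deletion has no base of its own to carry features, so it is anchored to
the called base immediately 3' of the missing reference base (the read's
last base for a terminal deletion). The anchor choice is invisible to the
merging stage — it only determines which position's features represent
the deletion — but it must be used consistently by the labeler and the
simulator's ground truth, and it is.

## Trimming

Two filters precede everything else. *Basic trimming* removes reads with
any ambiguous base, reads shorter than 200 bp (strict inequality: a
200 bp read survives), and reads containing a homopolymer longer than
8 bp, counted on the called bases; filters apply in that order and each
read is counted once under its first failing rule. *Strict trimming*
optionally follows: a 100 nt window slides one base at a time and the
read is truncated immediately before the first window whose mean Phred
falls below 30, then the 200 bp minimum is re-applied. Cutting *before*
the failing window (rather than inside it) matches the documented
behaviour of the established sliding-window trimmers this reproduces.

## Reference-based labelling

Training labels come from aligning each read to its best-matching
reference: candidates are shortlisted by shared 8-mer count (top 5), each
is aligned read-global / reference-local with affine gaps (match +1,
mismatch −1, gap open −2, gap extend −1), and ties break by fewest indel
columns, then lexicographic reference id. Before labelling, indel gaps
inside homopolymer runs are shifted to the 3' end of the run — a
score-preserving canonicalization that makes labels invariant to the
aligner's arbitrary gap placement. Mismatched columns are substitutions,
read-over-gap columns insertions, gap-over-reference columns deletions
(anchored as above).

## The simulator

Real mock-community SFF data is large and external; the package instead
ships a flowgram simulator whose ground truth is bookkept during
generation, so the labelling code can be validated against an oracle it
never sees. For each read a reference is drawn by abundance weight and
walked along the cyclic flow order `TACG`; the true incorporation count
`n` at each flow is perturbed and then called as `floor(signal + 0.5)`:

* Gaussian intensity noise with sd `(0.08 + 0.03·n)·(1 + 0.001·flow)` —
  the linear growth with run length and the slow positional inflation
  reproduce the two dominant observed error gradients;
* carry-forward with probability 0.005 per positive flow adds a leak of
  U(0.2, 0.7) flow units to the most recent preceding flow of the same
  nucleotide. The leak is additive rather than conserved: the out-of-phase
  template fraction it represents is far below call resolution on the
  donor flow, and an additive model keeps the artifact's signature
  (an upstream insertion next to a homopolymer) clean;
* incomplete extension with probability 0.005 per positive flow moves a
  U(0.2, 0.7) residual from the flow to the next flow of the same
  nucleotide (conserved, since the donor loss *is* this artifact's
  signature);
* signals are quantized to hundredths — the SFF on-disk resolution — so
  that a written and re-read SFF file reproduces the simulation exactly;
* Phred scores follow `Q = clamp(round(40 − 60·|signal − called| −
  0.01·flow), 2, 40)`: crude, but monotone in the two drivers that
  matter — distance to the rounding boundary and position.

Defaults (10 references of 400 bp at 10% divergence, log-uniform
abundances spanning 0.5–50%, 2,000 reads, 800 flows) yield a raw
per-base error rate around 0.6–0.9%, the order observed in basic-trimmed
454 amplicon data, with the realistic type mix (insertions most common,
then deletions, then substitutions) and a rising positional profile.

Ground truth is recorded in the coordinate system the labeler uses:
insertions at the 3' end of a flow's call block, deletions anchored to
the next called base, terminal deletions dropped (a read-global /
reference-local alignment cannot see them), and a deletion+insertion
pair with no intervening called base rewritten as the substitution
columns an affine aligner prefers whenever that shift explains the pair
with at most two mismatched columns (beyond two, the aligner's scoring
favours keeping the indel pair: two gaps cost 4, three substitutions
cost 5 against 1). On default simulations the alignment-based labels
reproduce ≥ 98% of truth events; residual disagreements sit at
homopolymer-boundary columns where several alignments are exactly
equivalent.

What the simulator does *not* emulate: PCR point errors and chimera
formation kinetics (chimeric fixtures are constructed explicitly by
`make_chimeras`), plate-position effects, template-specific signal
droop, and key/adapter sequence. Passing tests therefore demonstrate the
machinery is correct under the stated error model, not that real-data
error rates will match any particular value.

## Template alignment and preclustering

Reads are projected NAST-style into the column space of a template
alignment (in the bundled scenario the references themselves, which are
generated substitution-only and hence gapless and trivially aligned —
the projection machinery still handles gapped templates). Insertions
relative to the template open shared pad columns, only as wide as the
longest insertion observed at that point across the read set; degapping
any projected read returns its exact input sequence.

Identical called sequences are dereplicated first (abundance = copy
count; mask columns = the union over copies, since a position flagged in
any copy is suspect for the unique sequence). Preclustering then sorts
by abundance (ties: longer read first, then id — a total order, so
results are reproducible), fixes reads as seeds in order, and merges
each read into the first seed with at most `floor(0.02 × unaligned
length)` counted differences. A column is skipped when masked in
*either* read (the symmetric reading of "masked positions do not add
differences"); an internal gap against a base counts as one difference;
leading/trailing gap columns are ignored; `floor` keeps the budget
conservative — never merging above 2%. Merged reads adopt their seed's
sequence and donate their abundance; seeds are emitted byte-identical to
their pre-masking originals (restoration), so total abundance is
conserved exactly. Seeds that accreted members keep their own called
sequence — only evidence from merging, never the mask itself, changes a
base.

## Assessment

`compute_error_report` reproduces the standard mock-community audit:
reads and references are placed in a common alignment space; a read is
chimeric when some two-parent breakpoint combination of references
explains at least 3 more of its mismatches than the best single
reference (computed exactly via per-reference prefix mismatch arrays,
O(refs·columns) per read after an O(refs) scan per breakpoint);
chimeras are excluded, every other read is labelled against its best
reference, and the global error rate is erroneous nucleotides over total
nucleotides, abundance-weighted. `positional_profile` tabulates
per-position insertion/deletion/substitution rates over coverage for
plotting.

## Numerical and design choices

* Rounding of flow signals is *half-up* (`floor(s + 0.5)`), not banker's
  rounding, so behaviour at the .5 boundary is deterministic and
  direction-consistent.
* Affine gap scores are realized with `gapOpening = 1, gapExtension = 1`
  in `Biostrings::pairwiseAlignment`, whose convention charges
  `opening + L·extension` for a length-L gap — i.e. −2 for the first gap
  base and −1 for each further one, the stated scheme.
* The k-mer prescreen (k = 8, top 5 candidates) stands in for a
  heuristic database search; it is deterministic and, on the bundled
  scenario, recovers the true source reference for >99% of reads.
* `sample()` and friends drive all randomness through explicit integer
  seeds carried in `sim_params`/`pipeline_config`; every pipeline output
  is bit-reproducible from its config.
* The bundled scenario (10 references × 400 bp, 2,000 reads) keeps the
  full end-to-end run, including training and two assessment passes, in
  a few minutes of one core; the same machinery scales to larger read
  sets linearly in reads × references.
* Where a feature vector is shared by instances with different labels,
  dereplication keeps one instance per (vector, label) pair rather than
  resolving the conflict; the SVM sees the ambiguity instead of a
  silent majority vote.

## Known limitations

* The classifier is only as good as its training labels; on real data
  the labelling step requires trusted reference sequences for a mock
  community sequenced in the same run.
* The NAST projection counts one extra difference for a small fraction
  of distant read pairs compared with free pairwise alignment (gap
  placement against different templates); within-species pairs — the
  ones the merge budget actually compares — agree ≥95% exactly.
* Only two-parent chimeras are scored, per the standard mock-community
  procedure; real multi-parent chimeras are flagged only if a two-parent
  explanation already beats the margin.
* The CLI wrapper under `inst/scripts/` is a convenience; the package
  functions are the supported interface.
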