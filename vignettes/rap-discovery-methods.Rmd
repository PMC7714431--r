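---
title: "Methods: scoring Pol II-binding aptamer discovery"
author: "rapscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring Pol II-binding aptamer discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rapscan)
```

# The experiment this package models

Genomic SELEX transcribes a fragmented genome into a pool of short
(30–400 nt) RNAs and iterates binding to purified RNA polymerase II:
bound molecules are recovered, amplified, and re-selected over several
cycles, so sequences with affinity for the polymerase are over-represented
in the final pool. Deep sequencing of that pool yields reads whose genomic
origin, strand, and codon content carry the signal. `rapscan` implements
the downstream quantitative analysis — enrichment scoring, translated-
repeat alignment against the Pol II carboxy-terminal domain (CTD), and a
codon-normalised composition statistic — together with a generator that
emulates the experiment so that every stage can be validated against known
ground truth.

# Enrichment over repeat families

Reads (as placements on a reference) are assigned to a repeat family when
the read **midpoint** falls inside one of the family's annotated
intervals. The midpoint rule is a deliberate choice: it assigns each read
to exactly one window or interval and avoids double counting at
boundaries. The read strand relative to the repeat's annotated strand
splits counts into sense and antisense; the **dominant strand** is the one
with more reads (ties resolve to sense, a documented arbitrary
convention).

Fold enrichment normalises the dominant strand's read share by the
family's *strand-specific* genomic abundance:

$$\mathrm{fold} \;=\; \frac{d/N}{\,b/(2G)\,}$$

with $d$ dominant-strand reads, $N$ total reads, $b$ annotated family
bases and $G$ genome length. The factor 2 appears because reads are drawn
from both strands of a double-stranded genome while the family annotation
occupies one strand: with it, uniformly random sampling gives
$\mathrm{fold} = 1$ for every family, which is the calibration identity
the test-suite checks. A per-base denominator is used rather than a
per-locus one because locus counts are not well defined when the selected
pool and the reference genome differ in repeat copy number. Each placement
is counted once; fractional weighting of multi-mapping reads is a
reasonable alternative that this implementation does not apply.

Contig stacks tile the genome with non-overlapping 400-nt windows from
position 0 and count reads by midpoint; windows with zero reads are
omitted.

CA-richness — a hallmark of polymerase-binding RNAs — is the pooled C+A
base fraction of the selected set, tested upper-tailed against i.i.d.
background sequences of the same lengths; the CA-dinucleotide frequency is
reported alongside as a secondary descriptor.

# Translated repeats versus the CTD

Repeat DNA is translated with the universal genetic code in reading
frames 0, 1 and 2 of the given strand only (the selected molecule is an
RNA read 5'→3'; its reverse complement is a different molecule). Stop
codons translate to `*`, codons containing `N` to `X`; both are excluded,
with renormalisation, from every composition vector — the 20-amino-acid
comparison to the CTD cannot include them, and exclusion avoids biasing
the composition. Trailing partial codons are dropped.

Global alignment is Needleman–Wunsch with BLOSUM62 (shipped as a
plain-text data file and checksum-tested against an independent copy) and
affine gaps. "Opening penalty 12, extension penalty 2" is read in the
lalign/FASTA convention — a gap of length $L$ costs $12 + 2L$ — because
that is the convention of the tool family those parameter names come
from; the textbook dialect $12 + 2(L-1)$ is available behind a flag.
End gaps are penalised (strict global alignment); a semiglobal flag
exists for exploration. The traceback is made deterministic by a fixed
tie order (substitution, then gap in the second sequence, then gap in the
first); the identity count is reported from that single traceback.

Because the CTD fragment used in the original figure is not specified
beyond "equivalent length", `bestCtdFragment()` scans every contiguous
CTD window of the query's length and returns the best-scoring one
(smallest start on ties). Reproducing a published translated-unit
comparison therefore means: translate the unit in three frames, scan each
frame's peptide, keep the best window — the package's reproduction
strategy, not a claim about the original fragment choice.

# The codon-normalised composition statistic

The pooled amino-acid composition of the selected pool is computed over
**all sequences and all three frames**; pooling is per unique sequence,
unweighted by read count (the alternative of abundance weighting is easy
to apply upstream by repeating sequences). Because amino acids differ in
how many codons encode them, raw compositions of translated random RNA
are far from uniform; dividing each frequency by the amino acid's codon
multiplicity (L, S, R = 6 … M, W = 1; multiplicities sum to 61) and
renormalising removes exactly that combinatorial factor, so a uniform
random codon stream converges to the uniform composition 1/20. The CTD
reference — by default the consensus heptad YSPTSPS, whose normalised
composition is Y 2/7, S 2/7, P 2/7, T 1/7 — is normalised by the same
rule.

Divergence is Jensen–Shannon with base-2 logarithms, bounding the
statistic by 1. The base is a free choice: changing it rescales observed
value, null mean and null sd identically, leaving z and p-values
invariant.

The null distribution regenerates, per replicate, a full pool of i.i.d.
random sequences from the background base model with lengths matched
sequence-by-sequence to the observed set, and scores it through the
identical pipeline. Matching lengths per sequence (not just total
length) reproduces the partial-codon and frame-boundary structure of the
observed pool. The test is **lower-tailed**: CTD-like codon content
manifests as unusually *small* divergence, so the empirical p-value is
$(m+1)/(n+1)$ with $m$ the number of null values at or below the observed
one. This estimator never returns 0; when the signal saturates the floor
$1/(n+1)$, the z-score $(\mathrm{JSD}_{obs} - \mu_{null})/\sigma_{null}$
is extrapolated through the lower normal tail — at $z = -10$ that tail is
$7.6\times10^{-24}$, i.e. below $10^{-23}$. The Gaussian extrapolation is
an approximation for communicating depth-of-signal, not a claim that the
null is exactly normal.

The default replicate count is $10^4$ at the desk ($10^3$ in the
examples and checks below); the original-scale analysis would use $10^6$,
which changes only the floor of the empirical p-value. A fresh random
pool is generated for every replicate (no resampling). Seeds are
mandatory arguments; the null sampler is a pure function of
(lengths, background, reference, nSets, seed).

Implementation note: the pooled three-frame codon count of a sequence
equals the count over *all* consecutive trinucleotide windows, since each
window is a codon of exactly one frame. The Monte-Carlo sampler exploits
this with integer-coded bases; a test holds this fast path equal to the
literal translate-each-frame route.

# The synthetic experiment

The generator emulates the statistical structure of the screen, not its
biochemistry:

* **Genome.** i.i.d. bases from a background model; the default is a
  human-like composition (A = T = 0.295, C = G = 0.205). Planted repeat
  copies are placed at non-overlapping uniform positions, on the
  configured strand (antisense copies insert the reverse complement).
* **Families.** Unit builders: `random` (background bases), `simple`
  (a tiled motif such as CA), and `ctd` — tandem reverse-translated
  YSPTSPS heptads with codons drawn uniformly per amino acid, so a
  147-bp unit is 7 heptads and its frame-0 translation at noise 0 is
  exact heptads. Uniform codon choice is the default; a organism-specific
  codon-usage table could replace it but would only sharpen the planted
  signal.
* **Selection.** A single weighted draw stands in for the multi-cycle
  selection: read start positions are sampled with probability
  proportional to the local affinity weight (family weight inside planted
  intervals, 1 elsewhere), lengths uniform in 30–400 nt, strands uniform,
  then substitution noise. One round with weight $w$ emulates the
  cumulative over-recovery of the real experiment's cycles; compounding
  ($w^{\mathrm{rounds}}$) is a trivial re-parameterisation the user can
  apply, and the recovered-fraction dynamics of the real cycles are not
  modelled quantitatively.
* **Noise.** Substitutions only, no indels — this keeps reading frames
  interpretable, and is a documented limitation (real selected pools
  contain indels and chimeras).

`expectedFamilyFold()` computes the exact expectation of the per-strand
fold under this sampling rule — for every start position (weighted) and
read length (uniform), the midpoint is computed exactly as the assignment
step computes it, including truncation at the genome end — and serves as
the analytic oracle for recovery checks. This matters: with 30–400 nt
reads, midpoints of reads starting inside a short planted interval often
fall outside it, so the naive expectation $wf/(wf + 1 - f)$ can be off by
tens of percent; the exact oracle is the fair target.

What passing synthetic checks does **not** show: performance on real
pools with mapping ambiguity, chimeric reads, copy-number divergence
between source and reference genomes, or sequencing-platform error
profiles. The generator shares none of those features.

# Numerical and design details

* Coordinates are GRanges-style 1-based closed in memory; all on-disk
  formats (BED6, placement TSVs) are 0-based half-open.
* `AAFreqDist` vectors must sum to 1 within 1e-9; JSD clamps sub-1e-15
  negative entropy differences to 0.
* TSV outputs render doubles at 6 significant digits so identical runs
  are byte-identical; the pipeline manifest records config, seeds,
  package version and md5 digests of every output.
* Degenerate inputs: empty compositions (no scorable codon) are errors,
  not silent zeros; a null sd of exactly 0 flags z as undefined while the
  empirical p-value is still returned; families absent from the
  annotation are errors in fold computation.
* Reference checks in the suite use small problem sizes chosen to make
  Monte-Carlo error negligible relative to the tolerance being asserted:
  alignment oracle equivalence on 500 random pairs of length ≤ 6
  (scores must match exactly), JSD axioms on 1000 random distribution
  pairs at 1e-12, null calibration over 200 runs of 20 × 100 nt pools
  with 500 null sets each, planted-signal recovery at 100 × 150 nt with
  70% CTD codons and 1000 null sets, and enrichment recovery at
  $10^5$ reads over a 100-kb genome with a 1%-abundance family at weight
  50 (±10% of the analytic expectation; uniform control within 3 SE
  of 1).

# Known limitations

* The CTD fragment and reading frame behind any particular published
  identity count are reconstructed by exhaustive scan, not known.
* Alignment significance (E-values) is out of scope; the score and
  identity count are descriptive.
* Real-genome read mapping is out of scope: the enrichment module
  consumes placements produced by the simulator's ground truth or by any
  external aligner.
* The composition test treats sequences as unweighted unique molecules;
  strongly skewed read-count distributions should be weighted upstream if
  abundance-weighted composition is wanted.
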