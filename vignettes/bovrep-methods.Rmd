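---
title: "Methods: simulating and characterizing bovine IgG heavy-chain repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and characterizing bovine IgG heavy-chain repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

bovrep analyzes expressed IgG heavy-chain (VH) amplicon repertoires read at
high per-base accuracy, as produced by circular consensus sequencing (CCS)
of ~300-450 nt amplicons spanning the leader primer to the C1 primer.  The
pipeline is: per-read Phred quality filtering, FR1-anchored reading-frame
and strand determination, in silico translation with stop-codon screening,
a conserved-C1 anchor requirement, rule-based extraction of the three
complementarity determining regions (CDR1-3), repertoire descriptive
statistics, and paratope (CDR1+CDR2+CDR3) similarity networks.

Because raw bovine CCS repertoire data are not generally redistributable,
the package pairs the pipeline with a bovine-constrained V(D)J + somatic
hypermutation (SHM) + CCS simulator that carries complete ground truth.
Every claim the test suite makes is a property of the pipeline measured
against that truth, not a reproduction of any particular animal's numbers.

## The germline model

The bovine heavy-chain locus expresses a single closely related family of V
segments (13-20 conserved segments are hypothesized), with roughly 10 D and
6 J segments.  `build_germline()` generates such a set (defaults 15 V, 10
D, 6 J) with a fixed architecture, positions 1-based from the FR1 start:

* FR1 1-25, identical across V segments (it is the frame-calling anchor);
* CDR1 26-35, always 10 aa, with G26, F27, L29, V34 fixed and S28/S30
  strongly preferred; positions 31-33 and 35 vary per segment;
* FR2 36-47; CDR2 48-60 (13 aa) with conserved residues at 48, 49, 55, 57
  and 59; eight CDR2 positions vary per segment;
* FR3 61-92, ending in the conserved cysteine that opens CDR3;
* a 2-aa V tail (e.g. A-K) donated to the CDR3 head, D segments of 3-18 aa,
  and J segments consisting of a 2-aa head (mostly D-A, the source of the
  conserved IMGT 116-117 pair) plus an 11-aa FR4 bearing exactly one
  W-G-x-G motif; a conserved 12-aa IgG C1 prefix closes the amplicon.

Segments are *generated*, not downloaded: no reference database is
consulted, and fidelity is claimed only for the statistical architecture,
not for real bovine alleles.  Users with real germline FASTA can load it
through `read_germline()`.  The packaged default set was built once with
`build_germline(seed = 20120914)` and committed as plain text, keeping the
test suite hermetic.  Pairwise V identity under this design is >= 85%,
comfortably above the 70% single-family floor that `validate_germline()`
enforces.

## Junction simulation and its design choices

CDR3 length is drawn from a two-regime mixture (the observed bovine length
distribution is bimodal; the generating mechanism is a modeling choice):

* a **short regime** (default weight 0.4) over 4-8 aa peaking equally at 5
  and 6, realized by heavy trimming — including into the J head — and few
  N-additions;
* a **long regime** (weight 0.6) over 18-28 aa peaking at 22-23, realized
  by long D usage plus many N-additions;
* a rare **very-long tail** (probability 4e-4, 36-62 aa) emulating the
  handful of extremely long CDR3s seen in expressed IgG repertoires.

Letting the short regime trim the J head has a second, deliberate effect:
the J-donated D-A pair (IMGT 116-117) is conserved in the long length
classes but not in very short ones, matching the observation that those
positions are conserved "in longer size classes", and it keeps the tiny
short-junction sequence space diverse enough that exact deduplication does
not distort junction statistics.

All trims and N-blocks are whole codons.  This is an idealization (real
junctions are not codon-aligned); it guarantees in-frame, stop-free joins
by construction and makes the truth bookkeeping exact.  Trim fields are
still recorded in nucleotides, and `reconstruct_rearrangement()` must
reproduce every emitted sequence exactly from segments + trims +
N-additions + logged SHM events — a property the suite asserts.

**Cysteine-length coupling.**  The mean cysteine count of a CDR3 of length
L targets `cys_intercept + cys_slope * L` (defaults 0 and 0.08/aa).  The
N-addition composition itself contains no cysteine; cysteines are placed
only by this mechanism, as `floor(target)` plus a Bernoulli draw on the
fractional part.  The low-variance rounding keeps per-length-class means
tight, so the configured slope is recoverable from ~10,000 unique CDR3s
within 10%.  Slope-recovery checks regress over the main length range
(<= 35 aa, the same threshold the length distribution uses for its long
tail): the very-long classes are single observations by construction
(their rate mirrors the observed ~0.04% of reads), so their integer-count
jitter would dominate an unweighted per-class OLS — and empirically the
linear cysteine trend in real repertoires is reported as holding only up
to roughly 32 residues before fluctuating.  Within the N blocks,
cysteines are placed with a Gaussian bias toward the loop midpoint, so
the mean cysteine position tracks ~0.5 x length with a strong fit, the
centrally located pattern seen in expressed bovine CDR3s.

**SHM.**  Substitutions are uniform over the V(D)J coding region (leader
and C1 excluded) at 0.002/nt by default — deliberately modest, appropriate
to young, relatively naive animals — with stop-creating draws redrawn.
CDR2 indels occur with probability 0.09 per read (the observed fraction of
variant-length unique CDR2s is about 9%), are multiples of 3 nt confined
to the CDR2 interval, and keep CDR2 within 10-18 aa.  Frame-breaking SHM
is not modeled: such molecules would be removed by the stop-codon screen
anyway, so simulating them would only rescale read counts.

**CCS errors and qualities.**  Residual consensus error is stochastic and
position-independent (default 0.001/base substitutions, no systematic
term).  Per read, qualities come from a high profile (normal around Q35,
truncated above Q20) or a low profile (around Q12, truncated at/below
Q20); a planned fraction of reads (default 0.3) receives strictly more
than 3% at-or-below-Q20 bases and the rest strictly fewer, so the planned
label is an exact oracle for the 97%/Q>20 filter.  Early CCS instruments
passed a much smaller fraction of raw reads; that rate is a property of a
particular chemistry generation, not of the pipeline, so the default is
the package's worked-example value rather than an instrument constant.

## Filtering, frame calling, extraction

* **Quality rule**: a read passes when at least 97% of bases have quality
  *strictly* greater than Q20.  Q20 itself fails the per-base test; the
  fraction comparison runs in integer arithmetic (the fraction is taken to
  4 decimal places), so 97/100 passes and 96/100 fails exactly.
* **Frame calling** scores all six conceptual translations against the FR1
  consensus with the same local-alignment scorer the network uses
  (BLOSUM62, gap open 11, extend 1).  The default acceptance floor is 60%
  of the consensus self-score; ties break toward higher score, then
  forward strand, then smaller offset.  Any scorer that recovers the
  correct frame on clean data satisfies the contract; this one does, and
  the suite asserts 100% recovery with SHM and errors off.
* **Stop screen**: internal stops reject a read; a stop in the final codon
  is trimmed (simulated amplicons never end in one).  Ambiguous codons
  translate to X, never to a stop.
* **CDR extraction** is anchor-based: CDR1 is the fixed 10-aa block at
  26-35 from the located FR1 (no length variation is modeled there, since
  none is observed); CDR2 runs from position 48 to the located FR3 anchor
  (elastic 10-18 aa under indels); CDR3 sits strictly between the
  FR3-terminal cysteine and the FR4 W-G-x-G motif.  Motif matching allows
  one substitution per anchor; the FR4 search takes the *last* W-G-x-G at
  or after the CDR3 start, because the true FR4 always lies downstream of
  any chance junction motif while the C1 prefix is motif-free by
  construction.  Boundary offsets are configuration (`germline_anchors()`),
  since published boundary conventions differ.

## Statistics

"Unique" means exact string deduplication throughout.  Entropy is Shannon
entropy in bits per alignment column; frequency profiles are
column-normalized with a hydrophobicity display ordering (charged at the
bottom).  Mode detection takes strict local maxima on the integer
histogram, merging exact ties into plateaus, with an optional centered
3-bin smoothing; lengths above 35 aa are tallied separately as the long
tail and excluded from mode detection, so a handful of scattered very-long
observations cannot masquerade as modes.  Cysteine regressions are
ordinary least squares on per-length-class means (matching how such data
are conventionally summarized), not per-sequence points; a zero-variance
response reports slope 0 and R-squared 0 rather than an undefined fit.
The hydrophobic-usage statistic counts membership in a configurable
10-residue set, defaulting to the Kyte-Doolittle top ten
(I, V, L, F, C, M, A, G, T, S), computed on unique CDR3s.

## Networks

Edges come from all-vs-all Smith-Waterman local alignment (BLOSUM62,
11/1 — `Biostrings::pairwiseAlignment` supplies the alignment engine; the
suite checks it against an exhaustive alignment enumeration on short
peptides).  Significance uses Karlin-Altschul statistics
`E = K m n exp(-lambda S)` with the standard gapped-BLOSUM62 constants
lambda = 0.267, K = 0.041 as documented defaults; `n` defaults to the
summed length of all paratopes (database semantics, as an all-vs-all
search tool would report), with per-pair semantics available.  An edge
requires E <= 1e-8 in either direction; its weight is the summed bit score
of the qualifying hits, which with one optimal hit per direction and
symmetric scoring deduplicates to the single best-hit bit score.  Bit
scores (not raw scores) are summed.  The clustering coefficient is
`C_i = 2 n_i / (k_i (k_i - 1))`, defined for degree >= 2 only, and the
network value averages over exactly those nodes; components are the
default cluster notion.  Low-complexity masking is off: paratopes are
short concatenates that masking would erase.

## Problem sizes and what passing shows

The suite runs at the sizes stated in the test files: 1,000-read filter
and translation checks, a shared 10,000-record SHM-on simulation for
extraction accuracy (>= 99% exact CDR recovery) and shape recovery
(bimodal modes within the configured 5-6 and 22-23 targets; cysteine
slope within 10%), 200 exhaustively enumerated alignment pairs, 100
random graphs for the clustering oracle, and two simulated clone families
that must separate into components with >= 95% label purity.  The
pipeline's end-to-end reports are validated for cascade monotonicity and
determinism under a fixed seed.

What passing does *not* show: the simulator draws lengths from a clean
two-regime mixture, so intermediate lengths (9-17 aa) are essentially
absent, whereas real repertoires fill them; PCR chimerism, amplification
bias, light chains, isotype subclasses and instrument-specific error
signatures are not modeled; and germline sequences are synthetic, so
V/D/J assignment of real reads is out of scope.  Results on real data
inherit none of the generator's guarantees beyond what the rule-based
stages themselves enforce.

## Numerical and degenerate-input conventions

Empty reads, empty sequence lists and single length classes raise errors
rather than returning silent defaults.  Alignment scores floor at 0 (the
empty local alignment).  `E`-value monotonicity and graph invariants (no
self-loops, positive symmetric weights) are asserted on every build in the
suite.  All randomness flows through explicit seeds via scoped RNG, so no
call disturbs the caller's RNG stream.
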