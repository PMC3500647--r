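# bovrep

Simulation and analysis of expressed bovine IgG heavy-chain (VH)
repertoires from high-accuracy circular consensus (CCS) amplicon reads.

Cattle build antibody diversity differently from humans and mice: a single
closely related family of germline V segments (hypothesized at 13-20
members) recombines with roughly 10 D and 6 J segments, and the shortfall
in combinatorial diversity is offset by extreme CDR3 length variation —
the unique-CDR3 length distribution is bimodal, with a short mode near 5-6
residues and a long mode near 22-23 — by cysteine-rich long loops whose
mean cysteine count rises with length, and by somatic insertions/deletions
inside CDR2.  bovrep implements the full desk side of a repertoire
characterization for this system:

1. **Quality filter** — retain reads in which at least 97% of bases have
   Phred quality strictly greater than Q20;
2. **Frame calling** — score all six conceptual translations against a
   conserved FR1 consensus (Smith-Waterman, BLOSUM62, gap 11/1), translate,
   drop reads with internal stop codons, require the conserved IgG C1
   anchor;
3. **CDR extraction** — anchor-based CDR1 (fixed 10 aa at positions 26-35
   from the FR1 start), elastic CDR2 (position 48 to the FR3 anchor,
   10-18 aa), CDR3 strictly between the FR3-terminal cysteine and the FR4
   W-G-x-G motif;
4. **Statistics** — per-position Shannon entropy `H_j = -sum_a p_aj log2
   p_aj`, amino-acid composition, length histograms with plateau-merging
   mode detection, OLS regressions of per-length-class cysteine count and
   mean position, hydrophobic-10 usage, IMGT CDR3 numbering;
5. **Networks** — all-vs-all local alignment with Karlin-Altschul
   E-values (`E = K m n e^{-lambda S}`, lambda = 0.267, K = 0.041), edges at
   E <= 1e-8 weighted by bit score, clustering coefficient
   `C_i = 2 n_i / (k_i (k_i - 1))` averaged over nodes of degree >= 2,
   GraphML/TSV export.

A bovine-constrained V(D)J + SHM + CCS simulator with complete ground
truth (segment choices, trims, N-additions, SHM events, true CDR
coordinates) replaces raw sequencing data, so every pipeline stage is
testable against known rearrangements.

## Worked example

```r
library(bovrep)

report <- run_pipeline(pipeline_config(n_reads = 500, seed = 3,
                                       network_max_nodes = 150))
report
```

```
repertoire_report (seed 3)
  cascade:  input=500 -> quality_passed=347 -> fr1_located=347 -> stop_free=341 -> c1_anchored=341 -> cdr_extracted=341
  extraction accuracy vs truth: 0.9355
  network: 150 nodes, 714 edges, mean C = 0.977
```

Reading this: 500 reads were simulated with the default error model, which
plans ~30% of reads to fail the 97%/Q>20 rule (347 passed here); every
surviving read was frame-located on the FR1 consensus; six reads acquired
stop codons through simulated CCS error and were dropped; all 341
survivors carried the C1 anchor and yielded a full CDR set.  Extraction
accuracy compares extracted CDR strings against the simulator's ground
truth *on the error-bearing reads* — residual CCS errors inside a CDR
count as misses here, which is why it sits near 0.94 rather than the
>= 0.99 achieved on error-free proteins.  The network summarizes a
150-paratope subsample of the unique paratopes at E <= 1e-8.

Individual stages are exported (`quality_pass()`, `locate_fr1()`,
`extract_cdrs()`, `length_distribution()`, `build_network()`, ...), and a
thin CLI wraps the common ones:

```sh
Rscript inst/cli/bovrep.R simulate --n-reads 2000 --seed 1 --out-prefix sim
Rscript inst/cli/bovrep.R filter sim.fastq -o passed.fastq --report report.json
Rscript inst/cli/bovrep.R run --n-reads 2000 --seed 1 --out-dir results/
```

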