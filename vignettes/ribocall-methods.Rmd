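---
title: "ribocall: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribocall: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `ribocall`, the
tunable parameters and their defaults, the numerical conventions, what the
synthetic benchmark does and does not emulate, and the design decisions
taken where the method left room for choice. It states no empirical result
beyond what the package's test suite and `scripts/acceptance.R` themselves
compute.

## 1. The signal model

Ribosome-protected fragments (RPFs) of 24–31 nt place their 5' ends at a
length-dependent distance upstream of the ribosomal A-site. After shifting
each read by its per-length offset, two properties distinguish elongating
ribosomes from other footprint sources:

* **3-nt periodicity.** A-sites of translated ORFs fall predominantly on
  the first codon nucleotide (≈65%, versus ≈24% and ≈11% on the second and
  third). Per candidate ORF we compute the codon-position fractions
  `f1`, `f2`, `f3` over the ORF span excluding the stop codon.
* **Coverage uniformity (PME).** With `N` A-site reads over `L` codons,
  the ORF is partitioned into regions — one codon per region if `N > L`,
  otherwise regions of `floor(L/N)` codons with the remainder appended to
  the last region — and

  `PME = H / log2(n_regions)` with `H = -sum(p_i log2 p_i)`,
  `p_i = N_i / N`.

  Uniform coverage gives 1; a single pileup (characteristic of footprints
  protected by non-ribosomal complexes, e.g. snoRNPs) gives 0.

Two conventions deserve note. The entropy is the standard Shannon form
with the negative sign, and `0 * log 0 := 0`; `max(H)` is the idealised
continuous maximum `log2(n_regions)` even when `N` is not divisible by the
region count, so finite-`N` PME can fall slightly below 1 but never above.
Where the remainder codons go when `L mod region_length != 0` is not fixed
by the definition; appending them to the last region is the convention
here, and the tests pin it.

## 2. Offset calibration

For each read length, candidate offsets over `0:24` nt are scored on
canonical coding regions by two complementary signals:

1. the **in-frame fraction** of shifted positions across CDS interiors
   (the first and last 15 nt of each ORF are excluded, because initiation
   and termination pausing distort the local distribution) — this selects
   the offset's residue modulo 3 but cannot distinguish `d` from `d ± 3`;
2. the **start-codon anchor**: among offsets with the winning residue, the
   one maximising the count of 5' ends landing exactly `offset` nt
   upstream of annotated start codons wins. Ties go to the smaller offset.

Lengths with fewer than `support_min = 100` usable reads, or whose
in-frame fraction falls below `frame_min = 0.5`, are left out of the
offset table (reads of those lengths are then simply not used). A dataset
with no usable canonical reads raises an error instructing the user to
provide an offset table explicitly.

## 3. The classifier

Feature vector: `(f1, f2, pme)` — `f3` is redundant since the fractions
sum to one. Positives: expressed canonical ORFs. Negatives: off-frame
AUG-start ORFs inside coding regions plus candidate ORFs in short
non-coding RNAs. Both pools pass the expression filter (RPKM > 1 and more
than 10 A-site reads). Training and test sets (defaults 600 positives /
300 negatives each, configurable) are drawn disjointly without
replacement under a fixed seed.

The SVM uses the radial-basis kernel with `(cost, gamma)` selected over
the grid `{0.1, 1, 10, 100} x {0.01, 0.1, 1, 10}` by five-fold
cross-validation. Selection ranks by mean held-out AUC; the mean Brier
score of the Platt-scaled probabilities breaks ties. The tie-break
matters: on well-separated data many grid points rank perfectly, but
low-`cost`/low-`gamma` fits can leave the Platt sigmoid nearly flat, with
all probabilities near 0.5 — a perfect ranker that never crosses the call
cutoff. Ranking plus calibration, not ranking alone, is what the 0.7
cutoff consumes. Probability calibration is Platt scaling as implemented
by `e1071::svm(probability = TRUE)`; the method's description of a
"predicted translating probability" does not name a calibration, and
Platt scaling is the standard choice for SVMs.

Calls use a stringent probability cutoff of 0.7. Among called ORFs
sharing a stop codon, the representative start is chosen by: restrict to
AUG starts if any; take the 5'-most; while no A-site read lies strictly
between the current start and the next downstream candidate, advance.

## 4. Quantification

* **Expression:** RNA-seq counts are tested against a Poisson null with
  `lambda_t = library_size * length_t / sum(length)` over the tested
  transcripts (an effective-transcriptome-length null; the original
  method does not define its null rate, and this choice is configurable
  in spirit by passing a different `library_size`/length set). P-values
  are upper tails `P(X >= observed)`, BH-corrected; expressed means
  `q < 1e-3` and more than 10 reads, or encoding a called peptide.
* **Translation efficiency:** `log2(ribo RPKM / RNA RPKM)` over the same
  ORF span; eligible only with more than 10 reads in both libraries and
  when less than half of the span is overlapped by called ORFs of another
  type (per-nucleotide mask). Zero RNA denominators are flagged infinite
  and excluded from summaries; no pseudocount by default.
* **Relative TE classes:** a non-canonical ORF is `high`/`low` versus the
  canonical ORF of its gene when the TE ratio exceeds three-fold either
  way, `neither` otherwise.
* **C:N ratio:** `log2(cytosolic RPKM / nuclear RPKM)`, requiring more
  than 50 combined RNA-seq reads; `epsilon = 0` by default with explicit
  exclusion of zero denominators (a pseudocount mode exists).

## 5. Ka/Ks (NG86)

Site counts: each codon position contributes the fraction of its three
possible point mutations that are synonymous; mutations creating stop
codons count as nonsynonymous. Differences: per codon pair, synonymous /
nonsynonymous changes are averaged over all minimal mutational pathways
(1, 2 or 6 orderings); pathways through stop-codon intermediates are
excluded from the average, and if every pathway is blocked all are used —
standard NG86 practice, stated here because the cited implementation
leaves it open. Sites are averaged across the two sequences; `pS`, `pN`
receive the Jukes–Cantor correction `d = -(3/4) ln(1 - (4/3) p)`;
proportions at or above 3/4 are saturated and raise an error rather than
returning an undefined number. `Ks = 0` flags the ratio undefined.
Input pairs are assumed pre-aligned and gapless (homology search and
alignment are upstream concerns).

## 6. The synthetic benchmark

`sim_config()` fixes the generative conditions: codon-phase probabilities
0.65/0.24/0.11; read lengths 24–31 nt with weights
0.04/0.07/0.12/0.18/0.22/0.18/0.12/0.07 (a unimodal distribution peaking
at 28 nt, as RPF length distributions do) and true offsets 12–18 nt
(monotone per-length table 12,13,14,15,15,16,17,18); negative-binomial
depth per translated ORF (mean 300, size 8); a mild 3x initiation peak at
the start codon; sparse phase-random reads (mean 25) on untranslated
ORFs; narrow pileups (mean depth 150, 90% on a single nucleotide) on
short-ncRNA contaminants. The default transcriptome carries 200 truly
translated ORFs (170 canonical mRNA ORFs + 30 lncRNA ORFs, with planted
uORFs/dORFs on a quarter/tenth of mRNAs) and 200 truly untranslated ones
(30 lncRNA ORFs, 150 contaminants, 20 pseudogene ORFs). Reads are emitted
pre-aligned (the simulator knows the coordinates); adapter trimming,
alignment, rRNA filtering and multimapper resolution are upstream of this
tool's contract.

What the simulator does **not** emulate: sequencing errors, rRNA
contamination, UMI structure, codon-level dwell-time variation,
overlapping gene loci, alternative isoforms sharing exons, and biased
nucleotide composition. Passing tests therefore demonstrate correctness
of the algorithms under the stated signal model, not performance on any
particular real library, where periodicity strength and contamination
rates vary with protocol.

Problem sizes used in the tests and acceptance script — a ~400-transcript
transcriptome per seed, three seeds for classifier recovery, 80/80
training and held-out examples (the 200-ORF positive pool cannot supply
the method's 600/300 default draw, which remains the default for real
data), 10,000 random instances for the PME oracle, 1,000 sequences for
the enumeration oracle, 10,000 codons for the neutral Ka/Ks limit — were
chosen so the full suite runs in a few minutes on a laptop while keeping
Monte-Carlo error well inside the asserted bands.

## 7. Design decisions and open choices

* Internal coordinates are 0-based half-open; genePred is native, GTF is
  converted on read. Transcript positions always run 5'→3' of the RNA, so
  ORF logic is strand-free. `T` and `U` are equivalent on input;
  sequences are stored as DNA, start codons reported as RNA.
* "Overlap" in the biotype rules means at least one shared exonic base on
  the same strand — the conservative reading of an otherwise undefined
  term.
* Reads are counted once per transcript at the single A-site nucleotide,
  not spread over the footprint; periodicity and PME are defined on
  A-sites. A read overlapping several transcripts counts in each; the
  classifier operates per ORF, so no double-count correction is applied.
* Near-cognate starts are allowed in all ORF classes (whether the
  original catalog restricted them for canonical-gene variants is not
  stated); the start-codon set is a parameter.
* An off-frame ORF starting inside the CDS and ending beyond it is typed
  `internal`; in-frame ORFs nested in the CDS with a different stop are
  impossible by the first-stop rule. The stop codon belongs to the ORF's
  coordinates but is excluded from all feature windows; initiation-peak
  trimming of feature windows is off by default.
* Discovery reports ORFs of at least 6 aa (PME needs a handful of codons
  to be meaningful); summaries at 10 aa / 100 aa are reporting choices.
* Annotation sources often duplicate transcripts across catalogs; the
  package treats transcript ids as the unit and leaves cross-source
  deduplication (e.g. by identical intron chains) to the user.

## 8. Known limitations

* Offset calibration assumes some initiation-peak signal to anchor the
  exact offset within the frame family; on initiation-depleted data the
  frame is still recovered but the anchor weakens, and a user-supplied
  offset table may be preferable.
* PME is undefined in any informative sense for single-region ORFs
  (`N = 0`, or one region after division); these return 0 and are flagged
  rather than guessed.
* The Poisson expression null ignores positional biases and
  overdispersion of RNA-seq counts; it matches the published filter
  rather than a modern DE model.
* The classifier's false-call behaviour at very low read counts (~20
  reads) is intrinsically limited: a phase-random ORF can fluctuate into
  periodic-looking fractions, and a stringent probability cutoff cannot
  fully compensate at that depth.
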