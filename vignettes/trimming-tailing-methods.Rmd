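---
title: "Quantifying miRNA 3' trimming and tailing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying miRNA 3' trimming and tailing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimtail)
library(dplyr)
```

## The problem

Plant mature miRNAs are 2'-O-methylated at their 3' end by HEN1, which
protects them against two degradation-associated modifications: 3'-to-5'
exonucleolytic shortening (*trimming*) and the addition of nontemplated
nucleotides, frequently uridines added by the nucleotidyl transferases
HESO1 and URT1 (*tailing*). The fraction of a miRNA's reads that carry
either mark is a sensitive readout of miRNA turnover, and differences in
that fraction between genotypes, immunoprecipitates or subcellular
fractions localize where turnover acts. trimtail quantifies both marks
from adapter-trimmed small RNA-seq libraries and tests for differences
between lines.

## The pipeline

1. **Reference preparation.** Mature guide and star coordinates (GFF3
   records with feature type `miRNA`, as in Araport11 — never the whole
   primary MIR transcript) are extracted strand-aware from the genome.
   Loci with byte-identical mature sequences — typically members of one
   family — are collapsed into a single reference whose id joins the
   member names (`miR165a/miR165b`), since their reads cannot be told
   apart. All sequences are canonicalized to uppercase DNA (U to T), so
   miRBase-style RNA input and FASTQ reads share one alphabet.

2. **Masking and the intake filter.** Every mature locus footprint is
   replaced by `N` in the genome. A read that still matches this masked
   genome exactly (either strand) is an ordinary genomic small RNA and is
   removed; what remains — reads that fail to map only because their
   source locus is masked, or because a nontemplated tail breaks the
   match — is the candidate set of unaltered, trimmed and tailed miRNA
   reads. Reads are first collapsed to unique-sequence counts, which makes
   every later stage linear in the number of distinct sequences.

3. **Cross-mapping exclusion.** A miRNA whose exact mature sequence also
   occurs somewhere *outside* its own (masked) loci would lose its
   unaltered reads to the genome filter and its indexes would be biased.
   Such references are excluded up front and reported with one match
   coordinate. The criterion is a perfect match on either strand;
   near-matches do not exclude.

4. **Classification.** Each retained unique sequence is tested against
   each reference `m` for a 5'-anchored decomposition: trim `t` bases off
   the reference 3' end, append a tail of `u` bases, with `t <= 7` and
   `u <= 7` bounded independently. The decomposition is canonical — `t`
   and `u` derive from the maximal matching prefix, so a tail never starts
   with the base that would extend the match and `t + u` is minimal for
   that reference. Among compatible references, minimal `t + u` wins;
   a tie between distinct references makes the read `ambiguous`, which is
   excluded from indexes rather than double-counted. Only the 3' end is
   modelled: 5' isomiRs, substitutions and internal indels are out of
   scope, matching the operational definition of tailing as any 3'
   nucleotide not matching the miRNA.

5. **Indexes and statistics.** The trimming (tailing) index of a miRNA in
   a replicate is the fraction of its classified reads with `t >= 1`
   (`u >= 1`), *each read counting once* regardless of the degree of
   modification; a trimmed-and-tailed read contributes to both indexes.
   Index differences (IDs) subtract the reference line's per-miRNA mean
   index (over replicates) from the line's. Significance per (line,
   modification) comes from a two-sided paired t-test pairing per-miRNA
   mean indexes, and p-values are Benjamini–Hochberg corrected within each
   modification across *all* comparisons of the run, irrespective of any
   study grouping.

## Worked example on synthetic data

```{r example, message = FALSE, warning = FALSE}
cfg <- sim_config(seed = 42, n_mirnas = 6, genome_len = 3000,
                  n_background_reads = 200, reads_per_mirna = 400)
dir <- file.path(tempdir(), "tt_vignette")
lines <- tibble::tibble(line_id = c("wt", "hen1_like"),
                        pi_trim = c(NA, 0.45),
                        reference_line_id = c(NA, "wt"))
experiment <- simulate_experiment(cfg, lines, dir)
res <- run_pipeline(experiment$sample_sheet,
                    file.path(dir, "genome.fa"),
                    file.path(dir, "annotation.gff3"),
                    file.path(dir, "out"), min_len = 13)
tidy(res$comparison)
```

```{r boxplot, fig.width = 6, fig.height = 3.5}
autoplot(res$comparison)
```

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `max_trim`, `max_tail` | 7, 7 | Positions of trimming / tailing considered; bounded independently, so a read may be 7-trimmed *and* 7-tailed. |
| `min_len`, `max_len` | 18, 32 nt | Intake length gate. Products of trimming a 20-nt mature by 6–7 nt are 13–14 nt, below the default gate; analyses that must observe deep trimming should set `min_len = 13` (shortest mature − `max_trim`), as `run_pipeline()` calls in this vignette do. The default matches common small-RNA library practice. |
| `min_pairs` | 3 | Minimum per-miRNA pairs for a paired t-test p-value. Below it the comparison is reported without p. |
| `min_total` | 1 | Minimum classified reads for a per-replicate index row; no threshold by default. |

## The missing-data policy

A miRNA with zero classified reads in a replicate has an *undefined*
index there, not a zero: 0/0 is absence of evidence, not evidence of
absence of modification. Means are taken over the replicates where the
index is defined (`n_used` records how many), and a paired t-test pair
requires a defined mean in both lines. How the original downstream
analysis treated partially-detected miRNAs is not documented; this policy
is the package's own choice and errs against fabricating zeros.

## Degenerate statistics

Paired differences with (numerically) zero variance cannot be t-tested:
with zero mean difference the comparison is uninformative and no p-value
is emitted; with nonzero mean difference the shift is certain at the
resolution of the data, and the machine floor p-value is reported with an
explicit flag rather than an error or a silent `NaN`. Benjamini–Hochberg
correction skips missing p-values entirely so they do not inflate the
denominator.

## What the simulator emulates — and what it does not

`simulate_reference()` builds a random genome with non-overlapping MIR
loci (a guide and a star mature per locus, alternating strands), writes
miRBase-style mature FASTA in the RNA alphabet, and guarantees by
rejection sampling that no mature occurs elsewhere in the genome and that
no two matures are within prefix Hamming distance 2 — so cross-mapping
exclusion and classification ambiguity are impossible *by construction*,
which is exactly what makes recovery tests interpretable.
`simulate_reads()` then draws, per mature, Poisson read totals around an
abundance-weighted expected depth (log-normal abundance, mean-normalized;
`abund_sdlog = 0` gives equal depth for calibration runs), applies
trimming with probability `pi_trim` and truncated-geometric length, and
tailing with probability `pi_tail`, truncated-geometric length and a
U-rich composition (P(T) = 0.8) reflecting HESO1/URT1 uridylation.
Background reads are exact genomic substrings (20–24 nt) from unmasked
regions, so the genome filter must remove every one of them.

With `collision_free = TRUE` (default) the first tail base of a
trimmed-and-tailed read is forced to differ from the reference base it
replaces, so the realized (trim, tail) pair survives classification
unchanged and index recovery is unbiased. With `collision_free = FALSE`
a tail can coincidentally re-extend the reference match; the canonical
(maximal-prefix) classification then absorbs those bases into the match,
and measured indexes *underestimate* the generating rates — a real
phenomenon of tail sequencing, not a classifier defect.

The simulator has no sequencing-error model, no adapter remnants, no
ligation bias and no 5' heterogeneity, because the analysis under test
contains no components addressing them. Passing recovery tests therefore
demonstrates correctness of the classification and statistics on clean 3'
isomiR structure, not robustness to those artifacts in real libraries.

## Validation scale and results

The package's own validation (the test suite and
`scripts/acceptance.R`) runs at desk scale, chosen to finish in minutes
while keeping binomial noise well below the effects of interest: 20 MIR
loci, 3 replicates, ~2,000 reads per mature, 200 null line-pairs for the
type-I study and 50 simulations of a +0.15 trimming shift for power.
At these sizes the classifier agrees with a brute-force enumerator on
100% of random reads, per-miRNA indexes recover the generating rates
with mean absolute error well under 0.01, the paired-t type-I rate is
compatible with the nominal 0.05, and the +0.15 shift is detected with
p < 0.01 and a median ID above +0.10 in every simulation.

## Numerical and coordinate conventions

* Coordinates are 1-based inclusive end to end (GFF3 convention, the
  native convention of the IRanges/GenomicRanges stack used internally);
  BED-style half-open windows are accepted for coverage with
  `coords = "bed"`.
* Exact-match searching uses fixed-alphabet matching, so masked `N`
  positions never match a read base — which is what makes masking
  equivalent to removing the loci from the mappable space.
* The masked-genome filter implements "mapping" as an exact, 0-mismatch,
  both-strand match — the strictest reading. A short-read aligner with
  default mismatch tolerance would additionally remove near-matching
  reads; for reads that are perfect genomic copies (the case the filter
  exists for) the two behave identically.
* Coverage normalization is reads-per-million of the total deduplicated
  library, with multi-offset placements inside the window counted at
  every offset.

## Known limitations

* Family collapsing uses byte-identical mature sequences only; near
  identical paralogs remain separate references and can in principle
  make reads ambiguous (such reads are reported, not assigned).
* Identical matures annotated as guide in one locus and star in another
  collapse to a single guide-labelled reference with a warning.
* Trimming depths greater than `max_trim` are unclassifiable by design;
  raising the bound also lengthens the shortest classifiable product and
  interacts with `min_len` (see the parameter table).
* The paired t-test treats per-miRNA mean indexes as exchangeable pairs;
  it inherits the usual sensitivity to heavy tails at small miRNA counts,
  which is why `min_pairs` exists.
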