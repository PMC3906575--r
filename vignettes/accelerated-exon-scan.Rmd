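---
title: "Detecting accelerated coding-exon evolution from aggregate read differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting accelerated coding-exon evolution from aggregate read differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelexon)
library(dplyr)
```

## The problem

Scans for positive selection on coding sequence almost always start from
well-defined orthologous (and, for gene families, paralogous) alignments and a
gene tree. Genes inside segmental duplications (SDs) break both requirements:
draft primate assemblies collapse or drop duplicated loci, and gene trees for
young duplicates are unreliable. `accelexon` implements an assembly-free
alternative: align raw whole-genome shotgun (WGS) reads from two species
(here: human and rhesus macaque) to the *reference* genome of one of them,
pool the reads of all gene copies, and ask — exon by exon — whether coding
sequence accumulates nucleotide differences faster than the flanking introns,
which serve as a local neutral reference.

The unit of evidence is the **composite sequence**: for each transcript
region, every position is flagged as a *difference* when at least two
accepted reads carry a high-quality (Phred ≥ 27) mismatch against the
reference at that position. SNPs within a copy, paralogous sequence variants
between copies, and interspecies divergence are deliberately conflated; the
point is the aggregate amount of change across all copies, which grows with
copy number and therefore *gains* power exactly where tree-based methods fail.

## The statistic

For one exon, let $x_e$ be the number of difference-flagged positions among
the $n_e$ unmasked exonic positions, and $x_i$, $n_i$ the same for the
exon's intronic reference windows. Modelling
$x_k \sim \mathrm{Binom}(n_k, p_k)$, $k \in \{e, i\}$, independently, the
hypotheses are

$$H_0: p_e \le p_i \qquad H_1: p_e > p_i,$$

and the test is the likelihood-ratio statistic $-2\ln\lambda$ with

$$\lambda = \frac{\sup_{p_e \le p_i} L(p_e, p_i)}{\sup_{[0,1]^2} L(p_e, p_i)}.$$

The unconstrained maximum is at $\hat p_k = x_k / n_k$. When
$\hat p_e \le \hat p_i$ the null region contains the unconstrained maximum,
$\lambda = 1$ and the statistic is 0; otherwise the null supremum sits on the
boundary $p_e = p_i$ at the pooled rate $(x_e + x_i)/(n_e + n_i)$. The
statistic is referred to $\chi^2_1$, one-sided by construction because of the
$D_e > D_i$ requirement on calls ($D_k = x_k/n_k$ are the observed rates).
All likelihood arithmetic is in log space with $0\ln 0 := 0$.

Two calibration notes. First, because the null hypothesis is composite with
the true parameter typically *inside* the null region (purifying selection
makes $p_e < p_i$ the norm), the plain $\chi^2_1$ reference is conservative:
the package's type-I simulations at $p_e = p_i$ reject at roughly half the
nominal rate, and strictly less often when $p_e < p_i$. A
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ boundary mixture would halve the
p-values; we keep plain $\chi^2_1$ as the method's published calibration (the
mixture is a one-line change in `chi2_pvalue()` callers, since it only
rescales non-zero statistics). Second, multiple testing is controlled with
Storey q-values (`storey_qvalues()`): $\hat\pi_0$ from the smoother method on
the grid $\lambda = 0.05, \dots, 0.95$ (cubic smoothing spline, df = 3,
evaluated at $\lambda = 0.95$), with a fallback to
$\hat\pi_0 = \min(1, 2\bar p)$ below 100 tests, where the smoother is
unstable. With $\pi_0 = 1$ the q-values reduce exactly to
Benjamini–Hochberg.

## From reads to counts

**Alignment filters** (`filter_alignments()`), applied in a fixed order so
the first failing criterion is reported: score ≥ 220; percent identity ≥ 94
(human reads) / ≥ 88 (macaque reads); aligned length > 300 bp; aligned
fraction of the read > 40%; > 200 aligned bases with Phred ≥ 27; > 200
aligned bases outside repeat/tandem/CpG/gap masks. The asymmetric identity
thresholds admit macaque reads at typical interspecies divergence while
keeping human reads near-identical; the length criteria reflect Sanger-scale
reads (~500–1000 bp), long enough to span exon/intron boundaries.

**Composite construction** (`build_composite()`): a difference needs at least
two supporting reads, pooled across species. The paper's wording ("at least
two of the aligned reads") does not qualify the species nor require the same
alternative base; both stricter readings are available as flags
(`pool_species = FALSE`, `same_allele = TRUE`). Multiple alternative alleles
at a site collapse to one binary change; the majority allele is retained for
downstream dN/dS work (ties break alphabetically, deterministically).
Reference bases are trusted as finished-assembly quality; only read Phred is
thresholded. Indel columns never produce differences — the model is strictly
substitutional.

**Intron reference** (`select_intron_reference()`): walking outward from each
exon edge, the first 50 bp are discarded (splice-site constraint), as is any
position within 50 bp of *any* exon, inside another exon, or masked
(interspersed repeats, tandem repeats of period < 12, CpG islands, assembly
gaps — all four tracks; soft-masked lower-case runs in the region FASTA fold
into the repeat track). Qualifying positions accumulate until 400 bp per
side, fragmenting around exclusions, for up to 800 bp of reference per exon.
Masked-position exclusion applies identically to the exon side, so $n_e$ and
$n_i$ count comparable sequence. First/last exons draw their outer reference
from the transcript's 800 bp flank.

## The filter cascade

Significant exons (q ≤ 0.05 and $D_e > D_i$) pass through independent
artifact filters (`filter_cascade()`); every failing rule is recorded, so
verdicts do not depend on evaluation order:

* **Coverage comparability**: reject if mean macaque exon coverage > 2 while
  the intron's is < 2 — the intron is blind where the exon is not.
* **Intronic floor**: reject if $D_i < 0.01$; such introns are conserved or
  under-represented and make a meaningless reference.
* **Processed pseudogenes**: a read whose alignment runs contiguously out of
  the last 10 bp of one coding exon into the first 10 bp of the next, with
  the intron skipped, betrays a reverse-transcribed intronless template.
  Flagged reads are removed, the composite rebuilt, and the exon rejected if
  the recomputed $D_e$ falls below the recomputed $D_i$. The junction-window
  size is a parameter (`pg_window`). Note a structural limit of this
  published rule: it cannot reject a contaminated exon whose *clean* exonic
  noise happens to exceed the intron rate; it is reliable exactly in the
  realistic regime where pseudogene parents are conserved genes
  ($D_e^{clean} \ll D_i$).
* **Tandem-domain families**: rejected via a caller-supplied gene list; no
  automatic domain inference is attempted.
* **Tiling path**: every unmasked position of the exon and its windows must
  have coverage ≥ 1 (a stricter mode demands adjacent reads overlap).
* **Stop-codon sensitivity** (report, not a rejection): reads carrying a
  difference that creates a stop codon are removed and the LRT re-run; exons
  losing significance are flagged `fragile` with the counts of stop reads and
  lost differences. A strict mode (`strict_stop`) turns the report into a
  filter.

`aggregate_transcript()` lifts the analysis to transcript level by summing
exon counts and deduplicating intron windows shared by adjacent exons before
re-applying the same LRT.

## Post-hoc statistics

`annotate_duplication()` marks an exon duplicated on ≥ 1 bp overlap with any
SD interval. `fisher_enrichment()` tests the significant-by-duplicated 2×2
table exactly (log-space hypergeometric; both one- and two-sided p reported
— at the extremity of the published tables they agree to three significant
figures). `delta_compare()` contrasts $\Delta = D_e - D_i$ between exon
classes with Welch's t-test (the pooled-variance test is a flag; the source
only says "t-test").

`ng86_dnds()` is a Nei–Gojobori (1986) counting estimator: expected
synonymous sites per codon averaged over the two sequences (mutations to stop
codons count as nonsynonymous), observed differences averaged over all
mutation pathways with stop-codon intermediates excluded (all pathways used
if every one is blocked), Jukes–Cantor correction, ratio undefined at
$d_S = 0$. It replaces a pairwise maximum-likelihood estimator in the
permutation design below; since the permutation comparison is rank-based
across identically-constructed sets, any consistent estimator serves, and the
estimator is pluggable. `permutation_dnds()` compares the concatenated
composite-vs-reference dN/dS of a target exon set against sets of equal size
drawn from the eligible pool (coding length ≥ 20 bp, no annotation-induced
stop). Exon coding sequences are extracted *in frame*, trimming partial
codons at exon edges, because exon boundaries are not codon-aligned and
concatenating out-of-frame fragments would scramble every downstream codon.

## The simulator

`simulate_reference()` / `simulate_reads()` generate the study conditions
end-to-end with no external data: per gene, a region
`flank | exon | intron | exon | ... | flank` (defaults: 200 bp exons, 600 bp
introns, 800 bp flanks) on a random genome. Each (species, copy) pair owns a
haplotype: the primary human copy is the reference; further human copies
diverge at `paralog_divergence` (default 0.02/bp); macaque copies diverge at
`intron_rate` (default 0.03/bp, the generative counterpart of $D_i$). Inside
accelerated exons the per-haplotype divergence is multiplied by
`exon_rate_factor`. Reads (default 700 bp, Sanger-like, so single reads span
exon/intron boundaries) sample uniformly per haplotype with Phred-40 bases, a
10% fraction at Phred 15, and per-base miscalls at $10^{-q/10}$; all paralog
reads are emitted in primary-locus coordinates, reproducing the cross-copy
pooling the composite performs on real data. Retro-pseudogene contamination
draws reads from the spliced exon sequence diverged at
`pseudogene_rate_factor` × the neutral rate; they align with reference-skip
junctions and are emitted as macaque reads, since at several percent
divergence real pseudogene reads survive the alignment filters only under
the more permissive identity threshold. Everything is a deterministic
function of the seed.

What the simulator does **not** emulate: indels and rearrangements, shared
phylogenetic structure among copies (each haplotype diverges independently),
chromatogram-level error structure, polymorphism within species beyond the
generic difference rate, and alignment ambiguity (it is a perfect aligner;
the filter thresholds are exercised through planted score/identity values).
Passing tests on simulated data therefore validate the statistics, counting
rules and filter logic — not the behaviour of any external aligner on real
repeats.

```{r example, fig.width = 5.5, fig.height = 4}
scan <- run_pipeline(run_config(
  sim = sim_config(seed = 3, n_genes = 12, n_accelerated = 3,
                   exon_rate_factor = 3, copy_number = 2)))
glance(scan)
tidy(scan) |>
  select(exon_id, x_e, n_e, x_i, n_i, D_e, D_i, p_value, q_value) |>
  arrange(q_value) |>
  head(5)
ggplot2::autoplot(scan)
```

## Numerical and design choices

* Coordinates are 0-based half-open throughout (BED convention); GenePred is
  consumed natively in the same convention.
* The statistic is defined as exactly 0 whenever $\hat p_e \le \hat p_i$;
  after the $D_e > D_i$ call filter this is observationally identical to
  applying the pooled estimates unconditionally, and it is the correct
  one-sided LRT.
* Serialization is deterministic: doubles at six significant digits, fixed
  column order, so re-running a configuration reproduces artifacts byte for
  byte; the run manifest records every threshold and input checksum.
* Problem sizes used in the packaged studies: the LRT oracle comparison uses
  500 random count quadruples at $n \le 1000$; type-I calibration uses
  10,000 null pairs at $n_e = 200$, $n_i = 800$, $p = 0.03$; the power study
  runs 100 single-gene replicates per copy-number cell at 3 reads per copy
  per species (shallow coverage chosen so the copy-number effect is visible
  rather than saturated); recovery runs 200 genes (100 accelerated at
  3× with 2 copies, 10 reads per copy); the pseudogene study runs 30
  two-exon conserved genes (exon rate 0.2× neutral, neutral rate 0.06/bp,
  40% contamination at 1.5× divergence).
* Ties in the q-value computation need no special rank handling: the
  cumulative-minimum over the sorted p-values makes the result invariant to
  tie order.
* Degenerate inputs are explicit: pairs with $n_e = 0$ or $n_i = 0$ are
  flagged untestable and excluded from q-value computation; a fully masked
  interval reports zero coverage with a flag; degenerate 2×2 margins return
  p = 1 with a warning.

## Limitations

The method detects *acceleration of differences*, not selection per se:
relaxed constraint, gene conversion between diverged copies, or systematic
alignment artifacts in regions our masks miss would produce the same signal —
hence the cascade and the dN/dS permutation as orthogonal checks. The
composite collapses allele identity, so it cannot distinguish one recurrent
substitution from many distinct ones. Because reads of all copies are pooled,
the branch on which change happened is unidentifiable by design. Finally, the
intronic reference assumes flanking introns are neutral; where they are not
(the $D_i < 0.01$ floor catches the extreme case), the test is conservative
rather than wrong.
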