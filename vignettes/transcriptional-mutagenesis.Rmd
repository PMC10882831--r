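---
title: "Detecting transcriptional mutagenesis from UMI-tagged single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transcriptional mutagenesis from UMI-tagged single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmseq)
library(dplyr)
```

## The measurement problem

RNA polymerase II misincorporates bases at a low background rate, and far
more often when it transcribes across an unrepaired DNA lesion.
O⁶-methylguanine (O⁶-mG), the classic alkylation lesion induced by agents
such as methylazoxymethanol (MAM), directs incorporation of U opposite the
damaged G on the template strand, so the transcript carries a C→U change
relative to the mRNA-sense reference while the DNA sequence itself is
unchanged. This *transcriptional mutagenesis* is invisible to DNA
sequencing and, in bulk RNA-seq, indistinguishable from sequencing noise:
reads in bulk data may come from different cells whose lesions sit at
different positions.

Two experimental designs make it measurable, and this package implements
the analysis for both:

1. **UMI-tagged single-cell RNA-seq.** Every captured mRNA molecule gets a
   unique molecular identifier (UMI) and a cell barcode. Reads sharing one
   (barcode, UMI, transcript) key derive from one original molecule, so a
   consensus over the family removes sequencing errors and late PCR
   errors. Within one cell, a lesion produces *recurrent*, identical
   mutant molecules at one site — a signature no stochastic error process
   mimics.
2. **Rolling-circle consensus sequencing (CirSeq).** An RNA fragment is
   circularised and copied in tandem within a single read. Errors made
   before circularisation (that is, during transcription) recur in every
   repeat; sequencing errors hit single copies and vanish when the repeats
   are folded into a consensus.

Quiescent (non-dividing) cells matter for the single-cell design: without
replication, lesions are not fixed into DNA mutations, so RNA-level
recurrence can be attributed to damage rather than to genotype.

## The estimator

For each consensus molecule we compare every unmasked base to the
reference transcript. For substitution type X→Y the error rate is

$$\hat r_{X \to Y} \;=\;
  \frac{\text{mutant molecule bases of type } X \to Y}
       {\text{surveyed consensus-molecule bases with reference base } X},$$

in units of errors per transcribed base (bp⁻¹). The numerator counts
*molecules* (UMI families), never raw reads, so the estimate is a
per-transcription-event error rate; a `unit = "site"` flag switches the
numerator to distinct error records instead. The overall N→N rate divides
all erroneous bases by all surveyed bases.

Three exclusions keep the denominator honest:

* **Masked positions.** A consensus column whose reads disagree (under the
  default unanimity rule) becomes `N` and leaves both numerator and
  denominator.
* **Candidate DNA mutations.** A site whose *pooled* mutant fraction
  across cells reaches 0.95 with pooled coverage ≥ 10 molecules behaves
  like a real mutation in the cell population and is removed entirely —
  numerator and denominator. In quiescent cells a true mutation yields
  ~100 % mutant transcripts in every carrier cell, whereas a fully
  miscoding lesion on one allele saturates near 50 %.
* **Blacklist hook.** An optional BED blacklist (0-based, half-open) can
  mask known recurrent artifact sites such as RNA-editing positions; it
  ships empty.

Substitution types live in transcript space and are never folded by
reverse complement: transcripts are single-stranded, so C→U and G→A are
different measurements. That asymmetry is the DNA-mutation control — a
genomic G:C→A:T mutation elevates both complementary types in RNA from the
two strands' genes, while an O⁶-mG lesion elevates only the cognate C→U.

## Why unanimity-of-two suffices

With per-read sequencing error $e$ and alternate bases chosen uniformly
among the three non-reference bases, two independent reads display the
*same* wrong base at the *same* position with probability $e^2/3$ per
base. At $e = 10^{-3}$ that is $3.3\times10^{-7}$ — well below the
weakest biological signal of interest here (the vehicle-condition C→U
rate of $6.7\times10^{-6}$). The default family threshold is therefore
`min_reads = 2` with `min_agreement = 1`; both are exposed because the
original analysis's thresholds are not published. Ties under relaxed
agreement are always masked `N`, never broken randomly.

PCR errors are only partially suppressed: an error during the first
duplication is inherited by every read of the family and survives any
consensus rule. The simulator models this as a binary duplication tree of
depth `pcr_cycles`; an error on an edge at depth $d$ is shared by the
sampled reads below that edge. The surviving floor is roughly
`pcr_error_rate` per base divided by 3 per specific substitution (only
all-read-ancestral edges matter, and their expected count per molecule is
below one). At the high-fidelity default of $10^{-7}$ per base per
duplication this floor sits two orders of magnitude under the vehicle
signal. It is quantified empirically in the test suite via the
simulator's truth table.

## Pseudo-alleles

Within one cell, a site that yields both wild-type and identical mutant
molecules mimics a heterozygous allele; we call it a pseudo-allele. A
fully miscoding lesion on one of two alleles produces mutant fractions
around 50 %. Following the reporting convention of the single-cell
analysis, a (cell, site, alternate base) is reported when its mutant
fraction strictly exceeds 10 % ("more than 10 % mutant mRNAs"), with two
supporting requirements that the published filter leaves unstated and we
therefore chose and exposed as parameters: at least 2 mutant molecules
(one molecule cannot establish recurrence) and at least 10 total
molecules (a 10 % filter is meaningless below 10× coverage). The ratio
histogram uses fixed width-0.05 bins over (0.10, 1.00].

## CirSeq processing

Period detection minimises the mismatch fraction between the read and
itself shifted by a candidate period $p$, over `[min_period,
max_period]`, subject to a mismatch fraction ≤ 0.1 and at least
`min_repeats = 3` full repeats; ties prefer the smallest $p$. Self-offset
minimisation was chosen over FFT or suffix-automaton methods because it is
transparent and directly checkable against a brute-force scan at the
scales this package targets. Folding takes a quality-weighted plurality
per column (partial trailing repeats contribute where they cover); a
column is masked when the winner's summed quality is under twice the
runner-up's, and a read is rejected when more than 20 % of its columns
mask. With three repeats and per-copy error $e$, a folded column is wrong
only when two copies err identically — probability $\approx e^2$ — which
the tests verify against an exact enumeration of all $4^3$ copy outcomes.

Bulk RNA has no cell structure, so the DNA-mutation exclusion for CirSeq
uses the pooled ≥ 0.95-fraction rule per site.

## The forward simulator

The generator is first-class, tested code; every pipeline claim is
verified against its ground truth. Per cell, each transcript yields a
Poisson number of molecules (whole transcripts by default, or fragments
of `fragment_length` with uniform starts). Molecules then accumulate, in
precedence order at coinciding sites:

1. **DNA mutations** (`dna_mutation_sites`): fully penetrant in the
   carrier cell — quiescent cells, no subclonal fractions. Listing a site
   for every cell models the clonal mutations the exclusion rule is
   designed to remove.
2. **Lesions**: sampled per cell at rate `lesion_site_rate` per transcript
   base whose reference base is `lesion_ref_base` (a C→U lesion is
   undefined elsewhere); a molecule drawn from the lesioned allele
   (probability `lesioned_allele_fraction`, default 0.5 for a diploid
   one-allele hit) miscodes with `lesion_miscoding_prob`. The expected
   mutant fraction, recorded in the truth table, is the product of the
   two.
3. **Directed molecule-level errors** (`molecule_error_rates`): per
   reference-base, per-molecule substitution-specific rates. This is the
   natural way to express a condition's aggregate molecule-level C→U rate
   (for example the published 6.9×10⁻⁵) without imposing per-cell site
   clustering; biologically it corresponds to many weak lesions rather
   than few strong ones.
4. **Background transcription errors** (`background_tx_error_rate`):
   uniform positions, alternate base uniform among the three
   non-template bases.

Reads per molecule follow a shifted Poisson (`reads_min +
Poisson(mean - reads_min)`, default mean 2.2, minimum 2); all reads of a
molecule share the UMI and extent. PCR errors are drawn on the
duplication tree as described above — events are sampled on (read, cycle)
path slots and thinned by the number of reads sharing the edge, which
reproduces the per-edge binomial process exactly on the covered edges —
and sequencing errors are independent per read base. Event positions are
sampled by drawing a binomial count over the total base space and placing
events uniformly, which is equivalent to per-base Bernoulli draws but
costs time proportional to the number of events, not the number of bases.

A fixed seed makes the output byte-identical, including the FASTQ files
(`@<readid>|CB:<barcode>|UMI:<umi>|TX:<transcript>|POS:<start0>`).

**What the generator does not emulate:** expression-level biology (no
per-gene rates), splicing, cell-type heterogeneity, UMI sequencing errors
that split families (exact-match grouping only; a directional-adjacency
collapse is out of scope and logged as a limitation), chemistry and dose
kinetics, quality-score variation (constant Phred), and indels. Passing
tests therefore demonstrate correctness of the estimator and its error
suppression under this generative model, not robustness to alignment
artifacts or library-preparation quirks in real data.

## Scenario calibration and study conditions

The two condition scenarios (`mam_scenario()`) inject a total
molecule-level C→U rate equal to the published condition averages —
treated 6.9×10⁻⁵ bp⁻¹, vehicle 6.7×10⁻⁶ bp⁻¹ — on top of a small uniform
background (3×10⁻⁶ per base) whose C→U share is subtracted from the
directed injection so the realised C→U rate equals the target exactly.
Sequencing error defaults to 10⁻³ per base (modern short-read
instruments), PCR to 10⁻⁷ per base per duplication with 12 cycles
(high-fidelity polymerase).

Replicate counts and molecule depths for the original experiments are not
published; the demonstration scenario uses 3 vs 3 replicates. Recovery
analyses are sized from first principles instead: a rate $r$ estimated
from $N_C$ surveyed C bases has relative standard error
$1/\sqrt{rN_C}$, so runs target at least 100–200 expected events — about
3×10⁶ C bases at the treated rate and 1.5–3×10⁷ at the vehicle rate. The
group-comparison analysis uses 3 treated and 3 vehicle replicates sized
to ≥ 100 expected events each, repeated over 20 seeds. Uniform base
composition (25 % C, near the mammalian transcriptome average) is the
reference default.

## Numerical and design choices

* Coordinates are 0-based, half-open everywhere internally and in TSVs;
  only the VCF-like export is 1-based, flagged in its header.
* RNA U is stored as T; only substitution labels render T as U.
* Rates with a zero denominator are `NA` (undefined), never 0, and carry
  a warning.
* Consensus trims to the intersection of read extents (synthetic reads
  share extents anyway); families below `min_reads`, chimeric families
  and non-overlapping families are rejected and tallied, never silently
  dropped.
* The group test is Student's pooled-variance unpaired two-tailed t by
  default — the published comparison specifies only "unpaired two-tailed
  t-test" — with Welch behind `var_equal = FALSE` and an off-by-default
  Bonferroni (×12) flag; a single pre-specified substitution type is the
  primary comparison, so no multiplicity correction is applied by
  default.
* Every stage logs input/output record counts so conservation (reads =
  Σ family sizes; surveyed + masked + excluded = total consensus bases)
  can be audited from logs alone.
* The consensus vote and mismatch scan run in two small C++ kernels; all
  statistics and bookkeeping stay in R. The kernels are cross-checked
  against independent brute-force oracles on randomized fixtures in the
  test suite.

## Known limitations

* Exact-match UMI grouping slightly inflates molecule counts when UMIs
  carry sequencing errors (such reads usually form rejected singletons,
  deflating coverage, not rates).
* First-duplication PCR errors are an irreducible floor below ~3×10⁻⁸
  per type at defaults.
* Site classification needs pooled coverage ≥ 10; a clonal mutation seen
  in fewer molecules passes as a transcription error (conservative for
  mutation exclusion, anticonservative for rate estimates at trivial
  depth).
* CirSeq consensi are compared through the simulator's coordinate tags;
  aligning externally sequenced CirSeq reads to a genome is out of scope.
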