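---
title: "Deciding homokaryosis from single-nucleus sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding homokaryosis from single-nucleus sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Arbuscular mycorrhizal (AM) fungi grow as a coenocyte: a continuous mycelium
holding thousands of nuclei in shared cytoplasm, with no single-nucleus
bottleneck in the life cycle. Two readings of the genetic variation observed
in such organisms compete. Under *heterokaryosis* the variation is
distributed over genetically divergent nuclei coexisting in one individual;
under *homokaryosis* the nuclei are near-identical and the observed
variation lives *within* each nucleus — most prominently among the tandem
copies of the 45S rDNA locus, whose ITS region is famously polymorphic.

The two hypotheses make different predictions for sequencing data from
amplified single nuclei versus bulk mycelium:

* heterokaryosis: single-nucleus samples differ from one another at many
  sites, and bulk samples show mixed alleles that partition over nuclei;
* homokaryosis: single-nucleus samples are near-identical to one another,
  while a multi-copy repeat can still be highly polymorphic *inside* every
  single nucleus.

`coenokaryo` implements the complete computational path from reads to that
verdict, plus a synthetic-data generator so the whole pipeline is testable
against known ground truth without any sequencing download.

## Pipeline overview

1. **Simulation** (`make_study_design`): one haploid founder genome with a
   central tandem repeat array; haploid nuclei derived at low divergence;
   multiple-displacement-amplification (MDA) coverage bias with window
   dropout for single-nucleus samples; mycelium samples pooling all nuclei
   without dropout; 90 bp paired-end reads from ~350 bp fragments.
2. **Colored de Bruijn graph** (`count_kmers`, `merge_colors`,
   `clean_graph`): canonical k-mer counts per sample (color), cleaned by the
   k-mer frequency spectrum.
3. **Assembly** (`unitigs`, `scaffold_contigs`, `assembly_stats`): maximal
   non-branching paths, read-pair scaffolding with the "more than 3 linking
   pairs" rule, strict >100 bp scaffold filter, N20/N50/N80 statistics.
4. **Reference-free bubble calling** (`find_bubbles`, `classify_bubble`,
   `genotype_bubbles`, `joint_call`): bubbles in the merged multi-color
   graph at k = 31 and k = 61, classified as SNP / INS / DEL or decomposed
   composites, genotyped per sample from branch coverage, deduplicated
   across the two k passes.
5. **Reference comparison** (`map_reads`, `pileup_reads`, `count_variants`,
   `identity_statistic`): seed-and-extend mapping with banded edit-distance
   extension, per-sample SNP/indel counts, per-window density tracks, the
   aligned-identity statistic, and the self-alignment redundancy check
   (>70% alignable at >=95% identity).
6. **Repeat-locus analysis** (`pileup_on_unit`, `repeat_site_table`,
   `heterogeneity_summary`): all copies of the repeat collapse onto the unit
   reference; per-site reference-genotype (G1) versus polymorphic-genotype
   (G2) read support per sample, against the sample's average unit depth.
7. **Verdict** (`classify_karyotype`, `run_karyotype_analysis`,
   `write_report`).

```{r}
library(coenokaryo)
design <- make_study_design(seed = 1)
res <- run_karyotype_analysis(design)
res$report
```

## The verdict model

Let `aligned_bp` be the reference positions callable (depth >= 5) in every
single-nucleus sample, outside the region matching the repeat unit. For a
pair of samples the aligned identity is

```
identity = 1 - (differing SNP sites + differing indel bp) / aligned_bp
```

computed over sites callable in both samples; a joint variant (same site and
allele in both) is not a difference. The verdict is:

* **homokaryotic** if the minimum pairwise identity among nucleus samples is
  at least `identity_threshold` (default 0.999) *and* no nucleus carries
  private variants — sites where exactly one nucleus sample shows the
  alternate allele with all nucleus samples callable — at a rate above
  `private_rate_threshold` (default 1e-3 per aligned bp);
* **heterokaryotic** if either condition fails;
* **inconclusive** if less than `min_callable_fraction` (default 0.1) of the
  reference is callable in all nucleus samples.

Repeat-locus polymorphism never enters these conditions: heterogeneity
among copies of a multi-copy repeat is within-nucleus variation, and the
package reports it separately precisely so it cannot masquerade as
inter-nucleus divergence. This separation is the pipeline's central claim
and is tested by construction (identical nuclei with a highly polymorphic
array must stay homokaryotic).

The thresholds are operational choices, not empirical constants: observed
identities in the homokaryotic regime sit around 0.9995-1.0 while even 1%
mutual divergence drops them to ~0.99, so 0.999 separates the regimes by an
order of magnitude on either side. Mycelium samples contribute a
concordance check only (pooled genotypes should contain the union of
nucleus alleles); they never decide the verdict.

## What "divergence" means here

Simulation divergence parameters are expected *pairwise* densities between
two nuclei: each nucleus is derived from the founder at `divergence/2` per
bp, so two nuclei differ at `divergence` per bp in expectation. The default
(`divergence_snp = 3e-4`, `divergence_indel = 3e-5`) puts pairwise
identities just below 99.97%, the regime where homokaryosis with slight
nucleus-to-nucleus drift is the correct call.

## Key modelling and numerical choices

* **Canonical k-mers, odd k.** A k-mer and its reverse complement are one
  object (lexicographic minimum); odd k excludes self-reverse-complement
  palindromes. k = 31 (sensitive at low coverage) and k = 61 (specific in
  repeats) are run as separate passes and their call sets united,
  deduplicated by lifted position and alleles.
* **Cleaning threshold.** `max(2, coverage/10)`, with coverage estimated as
  the count-weighted median of the k-mer frequency spectrum. The weighting
  matters: at realistic error rates the plain median over distinct k-mers
  collapses to 1 because singleton error k-mers outnumber genomic ones.
* **Bubble branches.** A bubble is a fork k-mer whose two simple-path
  branches reconverge at one join k-mer; a branch is the bases contributed
  by its interior nodes, so an isolated SNP gives two branches of length
  exactly k and a d-bp indel gives a length difference of d. Branches longer
  than `2k + 50` are dropped. Classification uses unit-cost global
  alignment with a gap-affinity traceback (equal-cost split gaps are merged
  into one contiguous event) to decompose composite bubbles into
  SNP/INDEL-from-composite components.
* **Genotyping.** A sample supports a branch if its mean branch k-mer
  coverage is at least `min_support = 2`; supporting both branches
  ("both") is the expected state for mycelium pools and for within-nucleus
  repeat variants; supporting neither is recorded as missing (dropout).
* **Coordinates.** 0-based half-open internally; 1-based only in VCF-style
  outputs. Without a reference, calls live on per-bubble pseudo-reference
  contigs (5' flank + branch a + the join k-mer's last base); with one,
  bubbles are lifted by exact flank+branch matching, in either orientation,
  and calls whose context is not unique in the reference stay on the
  pseudo-reference.
* **Read mapping.** Exact k-mer seeds propose placements; a banded
  semi-global edit-distance alignment scores them; equally good distinct
  placements leave the read unmapped. Determinism is preferred over
  sensitivity in repeats — which also makes the collapsed repeat locus
  invisible to reference-based counting, consistent with analysing it
  separately. The locus is additionally masked explicitly
  (`unit_region_mask`) so boundary effects cannot leak repeat variation
  into the genome-wide counts.
* **Repeat-unit pileup.** The tandem array is treated as circular: reads
  are placed on a doubled unit with placements folded modulo the unit
  length, and read ends may be soft-clipped (one edit per 4 clipped bases)
  so locus-boundary reads contribute their array-derived half without
  contaminating columns with flank bases. The average-depth line is total
  aligned bases / unit length. A site is intra-sample polymorphic when both
  genotypes have >= 3 supporting reads and the minor genotype holds >= 5%
  of the G1+G2 support (the histogram thresholds are not externally fixed;
  these defaults suppress 0.1%-level sequencing error).
* **Scaffolding rules.** "Connected by more than 3 read pairs" is read
  strictly: joins need >= 4 linking pairs. Links with inconsistent implied
  orientation are discarded before counting; a contig end implicated in two
  or more qualifying junctions is conflicted and left unscaffolded on that
  side. Gap estimates are `insert_mean` minus observed overhangs, floored
  at 1 N so joins stay visible. The scaffold length filter is strictly
  >100 bp; the joint-assembly contig filter keeps >=200 bp.
* **Identity numerator.** Whether the identity statistic should count indel
  events or affected bases is not canonical; both are reported
  (`identity` uses bases, `identity_events` uses events).

## What the simulator does and does not emulate

It emulates: haploid nuclei descending from one founder at low divergence;
a multi-copy repeat array with per-copy variant realisation at specified
copy fractions; MDA amplification bias (per-window log-normal multipliers,
mean 1) with window dropout producing contiguous uncovered loci; pooled
mycelium samples without dropout; FR paired-end reads (90 bp, ~350 bp
fragments, truncated-normal insert) with i.i.d. substitution errors;
constant Phred-40 qualities; optional exact-duplicate-pair removal.

It does not emulate: chimeric MDA artifacts, GC-dependent coverage,
position-dependent Illumina error profiles, quality-score structure, or
structural variation beyond 1-10 bp indels. Passing tests therefore
demonstrate the *logic* of the inference — recovery of planted truth,
correct separation of within- from between-nucleus variation — not
robustness to every artifact of real single-cell libraries. Fragments are
rejected rather than truncated at dropout windows, so dropout regions are
exactly read-free; indel lengths are uniform on 1-10 bp; variants are kept
~400 bp clear of sequence ends (the coverage taper of finite molecules) and
~70 bp clear of the repeat-locus boundary.

## Problem sizes

The package's tests and the acceptance script run at desk scale by choice:
founders of 20-100 kb, 4 single-nucleus plus up to 2 mycelium samples at
20-30x coverage, a 10-copy 200 bp repeat unit, and 20 seeds per cell for
the verdict grid over planted divergences {0, 1e-5, 1e-4, 1e-2, 5e-2}.
These sizes keep every property checkable in minutes while preserving the
regime structure (coverage per allele, repeat copy number, error-to-signal
ratios) of the full-scale study design.

## Known limitations

* Bubble calling assumes near-clean branch paths; variants closer together
  than k are reported as composite decompositions, and variants inside
  repeats longer than both k values are invisible by construction.
* Reference-based indel events in ambiguous (shift-prone) context may be
  reported with a shifted anchor or eroded length; positions agree within
  the indel footprint.
* The genotype model is a coverage threshold, not a likelihood; it is
  adequate at >=20x per sample but has no calibrated error rate.
* The verdict thresholds are documented operational choices; data near the
  threshold boundary deserve the full report, not just the verdict string.
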