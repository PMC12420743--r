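---
title: "Methods: genotyping transposon-excision bolters at StCDF1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotyping transposon-excision bolters at StCDF1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bolterseq)
```

## The biological problem and the model

Cultivated potato is autotetraploid and clonally propagated. The maturity
gene *StCDF1* carries an allelic series at a single position in its second
exon: the wild-type allele *StCDF1.1*, an 865-nt Class II TIR transposon
insertion (*StCDF1.3*) conferring strong early maturity, and several small
"footprint" indels (7-nt insertions *StCDF1.2a/2b/4*, a 6-nt in-frame
insertion *StCDF1.7*, a 1-nt deletion *StCDF1.8*) left behind when the
element excises. A "bolter" is a somatic sport in which one *StCDF1.3* dose
has excised, so the plant carries a new footprint allele absent from its
variety and a reduced (duplex variety) or zero (simplex variety) *StCDF1.3*
read frequency, together with a later-maturity phenotype.

bolterseq models exactly this call chain. Its units are:

* a **locus model**: the 150-nt variable region, with a canonical insertion
  site immediately 3' of the TSD-like motif `ACACTAG`;
* a **transposon model**: the two junction-proximal fragments (27 and 30 nt;
  the 3' fragment ends with the duplicated TSD copy), a synthetic interior,
  and a total length of 865 nt;
* an **allele catalog**: each allele is an edit at the insertion site, and
  its diagnostic pattern is derived as left flank (27 nt) + edit + right
  flank (22 nt), or two junction patterns for the transposon allele. With
  these defaults the derived patterns reproduce the published diagnostic
  strings byte for byte, which the test suite asserts.

Only the 49-nt wild-type core, the junction fragments, the 865-nt length and
the footprint insertions are biological. The padding that extends the core
to the 150-nt probe region, the transposon interior, the *StCDF1.4*
insertion (`GCACTAG`, the remaining single-substitution TSD variant) and the
*StCDF1.8* deletion placement are fixed synthetic choices, marked as such in
the catalog. The synthetic padding and interior are drawn from a T-free
alphabet: they cannot contain stop codons in any frame, spurious `ACACTAG`
copies, or fragments of any diagnostic pattern, which keeps pattern
uniqueness and the coding fixture analysable. The two possible placements of
the 1-nt deletion (last base of the motif vs first base of the right flank)
give the same sequence, so the choice is immaterial.

## Allele typing

Reads are classified by exact substring search of every catalog pattern
against the read and its reverse complement. Exact matching (no mismatches)
mirrors pattern-based read counting; a read matching one or both transposon
junction patterns is counted once for that allele; a read matching two
distinct alleles would be left unclassified ("uniquely matching" semantics),
though the packaged catalog's mutual non-containment makes this impossible.
Frequencies are computed over classified reads only — unclassified reads
(sequencing errors inside the pattern window, or windows of the transposon
interior) are reported separately — and an allele is retained when its
frequency is **at least 5%** (the rule excludes groups *below* 5%, so the
boundary is kept).

Tetraploid dosage is inferred by exhaustive multinomial maximum likelihood:
for retained alleles with counts $c_a$, every integer dosage vector $d$
summing to the ploidy (4) is scored with expected frequencies
$p_a \propto d_a \, b_a$, where $b_a$ is an optional PCR amplification-bias
weight. The enumeration is at most $\binom{7}{3} = 35$ vectors at ploidy 4,
so no optimization is needed. Ties break toward the most balanced vector,
then lexicographic allele order. The bias preset `pcr_bias_preset()` encodes
the reported ~8-fold depth disadvantage of the long transposon amplicon: an
observed 8:1 read ratio under bias 8:1 is correctly read as a balanced 2:2
genotype.

Sample comparison (`compare_samples()`) is deliberately per-pair rather than
a group test: a single candidate against a single variety control must be
decidable without replicates. The transposon allele is called `absent` at
frequency zero, `reduced` at a relative drop of at least 0.3 (default), and
the verdict is `bolter` when a new retained allele appears or the transposon
signal drops. A group-level Welch test is available separately
(`welch_t()`, `compare_phenotypes()`).

## Footprint discovery

Reads are globally aligned to the wild-type region (Needleman–Wunsch,
affine gaps). The scoring constants — match +2, mismatch −3, gap open −5,
gap extend −2, a length-$k$ gap costing $5 + 2k$ — are an artifact choice,
set so that a 7-nt insertion (−19) is cheaper than 7 scattered mismatches
(−21) and alignment of footprint alleles is unambiguous. The engine is
`Biostrings::pairwiseAlignment`; the test suite checks it against an
independent quadratic dynamic-programming oracle with the same scoring on
1,000 random cases, and checks that the extracted edit lists reconstruct
each read exactly.

Indel placement in repeat context is ambiguous, so edits are normalized by
shifting indels as far 3' as possible; at this locus true footprints then
abut the insertion site. `footprint_compatible` is nevertheless decided by
sequence equivalence around the site (prefix and suffix comparison of the
reconstructed haplotype), because an insertion starting with `G` normalizes
one base past the site while still being placement-equivalent to a footprint.
Haplotypes are groups of reads with identical canonical edit profiles;
sequencing errors scatter into rare profiles that are absorbed by the
support threshold `max(min_reads = 3, 0.05 × aligned reads)` — the 3-read
floor supplements the 5% rule to suppress single-error haplotypes at low
depth. Discovery expects reads covering the full variable region
(long-amplicon reads or assembled sequences); probe-window short reads carry
truncation artifacts at their ends and are better served by the exact-match
classifier. Transposon-like variants (junction with 1–3 substitutions, no
exact match) are reported as partial profiles with an explicit `incomplete`
flag rather than guessed full alleles, since a junction window cannot
characterize the element interior. Novel alleles continue the literature's
numeric series (next unused integer suffix).

## Consequence prediction

The true coding frame of the variable region is not part of the packaged
model, so `predict_consequence()` requires a `coding_context` (upstream CDS,
phase, downstream CDS through and past the wild-type stop). The packaged
fixture `stcdf1_coding_context()` is synthetic, engineered so that the three
reported outcomes are realized: the 7-nt insertions shift the frame onto a
stop within the downstream variable region (premature stop, truncated
protein), the 6-nt `CACTAG` insertion is in frame and adds exactly two
residues, and the 1-nt deletion shifts onto a stop beyond the wild-type stop
(longer, altered C-terminus). Consequence calls against this fixture
characterize each allele's indel arithmetic, not the real gene; whether the
real phase gives +2 residues with zero substitutions for *StCDF1.7* cannot
be verified without the gene sequence. Translation uses the standard code
and stops at the first stop codon; an insertion that splits a codon may
introduce one junction substitution and is still `in_frame_insertion` when
the rest of the protein is unchanged.

## Clonal identity and mosaicism

Whether a candidate bolter is truly a somatic derivative of its variety (as
opposed to a volunteer plant or seed admixture) is decided from a
genome-wide panel of multilocus allele calls (up to four identifiers per
locus per sample). The pairwise distance is the per-locus **multiset
symmetric difference** — the number of allele copies that differ — summed
over loci present in both samples; this is a metric (symmetry, zero
diagonal, triangle inequality are asserted on every output and checked
against an exhaustive oracle). A set-based variant is available behind
`mode = "set"`. Missing loci are skipped pairwise, never imputed; pairs
sharing under half the loci are marked low-confidence.

Because "failing to cluster with its variety" is not automatable from a
dendrogram, admixture is flagged by an explicit rule: a sample is admixture
when its distance to every control of its labeled variety exceeds
`max(within-variety control–control distance, floor)`, with a documented
default floor of 5 mismatches. A true excision bolter differs from its
control by exactly 2 at the target locus (one allele out, one in), far below
the floor, while an unrelated clone differs at hundreds of loci, far above
it — the rule is insensitive to the floor over a wide range. The
complete-linkage dendrogram is still computed (via `stats::hclust`, checked
against a naive agglomeration oracle) and exported as Newick for visual
inspection.

A plant sampled as several stems is **mosaic** when stems retain different
allele sets at the target locus, and carries a **chimera flag** when a
single stem retains both the ancestral transposon allele and a footprint —
the signature of two cell lineages (periclinal layers) in one tissue. Layer
geometry is not modeled; a mixed stem is reduced to cell fractions.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with known truth:

* **Reads** (`simulate_reads()`): component chosen by cell fraction, then a
  template allele with probability ∝ dosage × amplification bias; the
  long-amplicon design emits full assembled sequences, the targeted design
  uniform 150-nt windows; substitution errors at a per-base rate (indel
  errors are off by default because the classifier is exact-match); strand
  flipped with probability 0.5; constant Q30 qualities in FASTQ output.
  Defaults are the assay's conditions: 5,000 reads per sample, and a
  documented 8:1 bias preset for the long-amplicon emulation.
* **Multilocus fingerprints** (`simulate_multilocus_calls()`): 790 loci by
  default; controls carry their variety profile, bolters differ by one
  allele swap at the target locus, contaminants share a configurable 70% of
  loci with their labeled variety, and contaminants in one group share a
  single profile (genetically identical clones from different fields).
* **Phenotypes** (`simulate_phenotypes()`): normal draws at the measured
  group means (total inflorescences 9.5 vs 1.0, flowering 3.5 vs 0.0, stem
  93.9 vs 74.8 cm; 8 bolters vs 4 controls). Variances are not reported, so
  SDs are free parameters (defaults 2.0/0.5, 1.5/—, 8/6); the control total
  SD of 0.5 keeps the zero-truncation bias of the rounded, truncated counts
  below 2%. A count trait with mean 0 is emitted as exactly zero ("all
  senesced").

Every operation takes one integer seed and spawns a single seeded stream, so
identical configurations are byte-identical; output headers record the seed.

What the generator does **not** emulate — and therefore what green tests do
not establish about real data — includes ONT/SPET error profiles (indels,
homopolymer errors, quality-dependent errors), PCR chimeras, alignment-level
reference bias, locus-specific dropout in the genotyping panel, and the
spatial L1/L2/L3 geometry of chimeras. The classifier's exact-match design
is robust to the substitution model used here but would lose more reads
under an indel-heavy error model.

## Numerical choices and problem sizes

Frequencies compare against thresholds with plain `>=` on doubles (counts
are integers, so ratios are exact at the boundary cases tested). Dosage
likelihoods are evaluated with `dmultinom` in log space; ties (exactly equal
log-likelihoods) are resolved deterministically as described above.
Alignment strand ties keep the forward orientation. Degenerate inputs error
early with explicit messages: empty or non-ACGT sequences, genotypes not
summing to the ploidy, zero classified reads (a classed condition), more
retained alleles than ploidy, samples with no calls at any locus, a single
stem for mosaic detection (warning + `unevaluable`).

The shipped verification sizes are: 200 seeded replicate pairs at 5,000
reads for the excision-signature check (mean relative drop within 45–55%);
200 replicates at 5,000 reads, genotypes drawn across all 168 two- and
three-allele dosage shapes of the catalog, for ≥99% dosage recovery; 10,000
random reads against the classifier oracle; 1,000 random cases against the
alignment oracle; 100 random matrices (n ≤ 6) against the linkage oracle;
and 50 seeded cohorts (3 varieties × 5 clones × 790 loci) for contaminant
flagging. These sizes make the checks statistically meaningful while keeping
the default suite in the minutes range on one CPU.

## Known limitations

* The catalog cannot encode *StCDF1.5*, which differs from *StCDF1.7* by a
  single amino-acid-changing SNP whose position is not published.
* *StCDF1.4* and *StCDF1.8* sequences are synthetic stand-ins; calls against
  them are exercises of the machinery, not biological claims.
* The coding context is a fixture; real-gene consequence calls require the
  user to supply the true CDS and phase.
* Admixture cutoffs and the 0.3 reduction threshold are artifact defaults,
  not estimated from data; both are exposed as parameters.
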