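---
title: "Genotyping acetylcholinesterase resistance alleles from Sanger consensus sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping acetylcholinesterase resistance alleles from Sanger consensus sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdace)
```

## The biological problem

Organophosphate (OP) and carbamate (CB) insecticides kill insects by
inhibiting acetylcholinesterase (AChE). In the housefly *Musca domestica*
a single gene (ACE2) encodes the enzyme, and a small set of point
mutations — producing the amino-acid substitutions V260L, A316S, G342A,
G342V, F407Y (and, outside the fragment handled here, G445A) — render the
enzyme insensitive to inhibition. Surveys of field populations therefore
sequence a fragment of the gene spanning these diagnostic codons, score
each fly as homozygous susceptible (SS), heterozygous (RS) or homozygous
resistant (RR) at each codon, and summarise the population as a set of
named resistance alleles.

`mdace` implements that entire analysis as a reusable, tested pipeline:

1. **Reference model** — an annotated genomic fragment (534-nt exon I,
   85–88-nt intron, 205-nt exon II; about 824–827 nt in total) carrying
   the diagnostic-site definitions and the allele catalog.
2. **Alignment and splicing** — global Needleman–Wunsch alignment of each
   specimen consensus to the reference, followed by intron excision to a
   739-nt spliced coding sequence.
3. **Genotyping** — RR/RS/SS calls at the diagnostic codons from IUPAC
   ambiguity codes, plus a cohort-wide SNP catalog.
4. **Allele nomenclature** — haplotype reconstruction and matching against
   the allele catalog (alleles I–VI, laboratory synonyms V1–V15), with
   novel-allele detection.
5. **Population statistics** — allele frequencies, substitution carrier
   prevalences, genotype-class counts.
6. **Phylogenetics** — Tamura–Nei (TN93) distances and neighbor-joining
   trees with column bootstrap; amino-acid trees from p-distances.
7. **Synthetic cohorts** — a generator that produces reference and
   specimen FASTA with known truth, so the whole pipeline is testable
   end-to-end without any external download.

## Heterozygotes as IUPAC codes

Field genotyping of this gene reads heterozygosity off the Sanger
chromatogram: a diploid fly heterozygous at a position produces two
overlapping fluorescence peaks. Raw trace files are out of scope here;
the information the analysis actually uses is retained by encoding each
double peak as the corresponding two-base IUPAC ambiguity code in the
consensus (e.g. an A/T double peak becomes `W`). `call_genotype()`
expands the code at a site's variable position and classifies:

* reference base only → **SS**;
* reference plus one resistant base → **RS**;
* a single resistant base → **RR**;
* two distinct resistant bases → **RR_mixed** (possible in principle at
  G342, where both G→T and G→C alternates segregate; never observed in
  the packaged cohort);
* anything else (N in the codon, ambiguity away from the variable
  position, a base outside the annotated allele set) → **no_call**, and
  no-called specimens leave that site's denominator.

## Coordinates

Three coordinate systems coexist. *Fragment-local* positions index the
genomic fragment including the intron; *spliced-local* positions index
the 739-nt coding sequence; *reporting labels* are spliced-local
positions plus a fixed offset of 1040, anchoring the fragment at label
1041 (so spliced 433 ↔ label 1473). The conventional labels quoted for
the three polymorphic diagnostic positions (1174, 1473, 1668) are not
mutually consistent with any single reading frame, so they are stored as
per-site annotation metadata (`variable_position_label`) and attached to
SNP records at those positions; all other positions get the arithmetic
label. We chose the reading frame with codons starting at spliced
position 1; under that frame the packaged background SNP at spliced 447
is a genuine third-codon-position synonymous site, and the diagnostic
codons are placed self-consistently (V260L codon at 133 with its
variable base at codon position 1; G342 at 433, variable base second in
codon, G→T giving valine and G→C alanine; F407Y at 628, variable base
second in codon, T→A giving tyrosine).

## Alignment and trimming

Alignment is global Needleman–Wunsch with affine gaps (Gotoh three-state
recursion, implemented in C++). Defaults: match +1, mismatch −1, gap
opening −5 plus −1 per gapped base. Any two IUPAC codes whose base sets
intersect score as a match, so heterozygote codes align cleanly.
Traceback ties are broken deterministically (diagonal, then
gap-in-reference, then gap-in-specimen), making every output
byte-reproducible.

Specimen reads carry non-homologous sequence at both ends; the
synchronisation convention of this analysis deletes 148 nt from the
start and 74 nt from the end. The pipeline deletes them from the raw
sequence *before* aligning. This is a deliberate design choice: an
optimal global alignment of a sequence with random flanks will sometimes
pay a gap-opening cost to "borrow" a few flank bases that coincidentally
match the reference ends, which manifests as spurious coding insertions;
trimming first removes the possibility at its source. An alignment-level
`trim_flanks()` is also provided for inputs whose flanks align as clean
overhangs. Pipeline results are invariant to whether specimens carry
flanks (and the matching trim lengths are used) — one of the tested
properties.

Within exons, specimen deletions become `N` placeholders (the affected
codons are then no-called) because truncated or partially degraded
Sanger reads are common; insertions are rejected as errors because a
coding indel would break the reading frame and none are expected in
this fragment. Intron-length variation (85–88 nt) is absorbed entirely
by the alignment; splicing discards intron columns, and results are
identical across intron lengths (also a tested property).

## Allele assignment

Phase cannot be resolved from a single diploid consensus, so each
specimen is summarised by its **maximal-resistance haplotype**: at every
site with at least one resistant allele (RS or RR) the resistant residue
is reported, otherwise the wild type. This rule reproduces the published
per-specimen allele table exactly from the published genotype table,
which is why it was adopted; any assignment that used a heterozygous
call is flagged `phase_unresolved` so the ambiguity stays visible. An
exact catalog match returns the catalog name and sensitivity class; an
unmatched combination is reported as `novel-<residues>` and classed
putative-insensitive when it carries at least one resistant residue.
Assignment is pure and monotone: growing the catalog never changes the
assignment of an already-matched haplotype.

Allele frequencies are per specimen (each fly counts once), matching how
field surveys of this gene tabulate alleles; a per-chromosome mode
(RR = 2 copies, RS = 1, out of 2n) is available as an option. Carrier
prevalence counts RS, RR and RR_mixed together.

## SNP catalog accounting

Every spliced position where any specimen's base set differs from the
reference yields one record, with transition/transversion class, coding
effect (by substituting into the reference codon under the standard
genetic code), exon of origin, carrier count and zygosity summary. A
multi-allelic site is counted once when all its alternates share a
class (e.g. G342's G→T and G→C are both transversions), which is the
accounting under which the packaged cohort totals 11 sites: 7
transitions and 4 transversions, 7 in exon I and 4 in exon II.

## Distances and trees

The nucleotide distance is the closed-form Tamura–Nei (TN93) estimator,
with separate purine (A↔G) and pyrimidine (C↔T) transition terms, a
transversion term, and base frequencies estimated empirically from each
pooled pair. Sites with N, gaps or ambiguity codes in either sequence
are excluded pairwise. Saturated pairs (any logarithm argument ≤ 0) are
capped at 5 substitutions/site with a warning rather than returning
infinity. Two limit identities pin the implementation down in tests: a
transversion-only pair with equal base frequencies equals Kimura's
two-parameter distance, and a pair with exactly balanced substitution
types and equal frequencies equals the Jukes–Cantor closed form; random
pairs are additionally checked against an independent TN93
implementation to 1e−10.

Trees are built by neighbor joining (via `ape::nj`), which recovers any
additive distance matrix exactly — the property the test suite asserts
on random 8-leaf trees. Negative branch-length estimates are clamped to
zero with a warning. Bootstrap supports resample alignment columns with
replacement (via `ape::boot.phylo`), rebuild the tree per replicate, and
label each internal node of the full-data tree with the percentage of
replicates containing its bipartition; runs are deterministic under a
seed. The original study fitted a maximum-likelihood tree under the TrN
model; this package deliberately substitutes distance-based NJ under the
same substitution model, because NJ's correctness is property-testable
(additivity, model limits) whereas reproducing a specific published
topology is not possible without the underlying sequence data. No rate
heterogeneity or model selection is attempted. The amino-acid tree uses
the p-distance (fraction of differing determined positions), since no
protein substitution model was specified; codons whose IUPAC expansions
disagree translate to `X` and drop out of the comparison. Trees are
emitted unrooted, as no outgroup is defined for this fragment.

## The synthetic cohort generator

`generate_reference()` draws a random stop-free coding sequence and pins
fixed codons at twelve positions: the four diagnostic codons (wild type)
and the eight background-SNP codons used by the packaged fixture. The
intron is random with canonical GT..AG ends. Pinning makes the fixture's
SNP plan valid under any seed, so the whole analysis is reproducible
from a single integer.

The packaged `iran20` fixture encodes the 20-specimen field cohort this
package models: the exact per-specimen genotypes at V260L, G342A/V
(with the alternate base chosen per specimen, so both G342A and G342V
segregate) and F407Y; three all-wild-type specimens; per-specimen intron
lengths spanning 85–88 nt; and eight synonymous background SNPs. Only
one background position is individually documented in the source data
(the A/G change at spliced 447, carried homozygously by specimen
MK257686 — homozygously, because that is what lets a nucleotide tree
separate this specimen from the other sensitive flies despite 100%
amino-acid identity); the remaining seven are fixed constants placed at
third codon positions and chosen once so the cohort-wide catalog
reproduces the documented aggregate counts (7 transitions + 4
transversions; 7 exon-I + 4 exon-II sites). Specimen identifiers reuse
the survey's accession strings purely as labels.

What the generator emulates: consensus-level heterozygosity, intron
length variation, non-homologous flanks, background synonymous
variation. What it does not: sequencing error, base-quality variation,
chromatogram artefacts, indels in coding sequence, or any linkage
structure beyond the configured genotypes. Passing the round-trip tests
therefore demonstrates that the pipeline's logic is exact on clean
consensus data; it does not certify robustness to noisy traces, which
would need real chromatograms.

## Numerical and testing choices

* Alignment scoring is configurable; the defaults above are conventional
  DNA values. The brute-force alignment oracle in the tests enumerates
  all alignments of short pairs (≤ 8 nt), so the dynamic program is
  checked against an exhaustive ground truth on 500 random pairs.
* Round-trip property tests run 200 random cohorts (3–6 specimens each,
  random genotypes, random intron lengths, optional background SNPs)
  through generator → pipeline and require exact recovery of every
  genotype, haplotype and allele name; 20 further cohorts exercise the
  flank- and intron-invariance properties. These sizes keep the full
  suite around three minutes on one core while covering the genotype
  space densely.
* Bootstrap tests use 25–100 replicates on small synthetic clades
  (documented signal ≫ noise, so all supports are 100); the cohort-scale
  default remains 1000 replicates.
* Percentages are reported to 2 decimals; all counts are exact integers.

## Known limitations

* Phase is not inferred; the maximal-resistance haplotype can in
  principle attribute two heterozygous substitutions to one chromosome
  when they lie on different ones. The `phase_unresolved` flag marks
  every assignment where this matters.
* The G445A diagnostic codon lies outside the fragment and is not in the
  default annotation (the schema accepts it if a user annotates a longer
  fragment).
* TN93 distances require both purines and both pyrimidines present in a
  pair; degenerate compositions raise an error rather than a silent
  fallback.
* The SNP catalog classifies coding effect per single alternate against
  the reference codon; compound effects of two substitutions in the same
  codon are not modelled (none occur at the packaged sites).
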