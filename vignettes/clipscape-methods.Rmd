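---
title: "Methods: CLIP tag processing, motif enrichment and intron geometry with clipscape"
author: "clipscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CLIP tag processing with clipscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipscape)
```

# Overview

Cross-linking immunoprecipitation (CLIP) recovers short RNA fragments
("tags") protected by an RNA binding protein. In the Sanger-cloning variant
of the protocol, each sequenced clone is expected to read
`adapter5 + insert + adapter3`, possibly from the other end of the vector
(i.e. reverse-complemented). Downstream of cloning, a CLIP study asks a
stereotyped series of questions: which distinct inserts were recovered; how
many are contaminants (bacterial rRNA is the classic one) or cannot be
placed uniquely on the genome; where the uniquely placed tags fall relative
to gene models (intron, 5'UTR, CDS, 3'UTR); whether short motifs — for a
CELF-family protein, UG dinucleotides and UG-rich hexamers — are enriched
relative to chance; and how tags sit inside the introns that contain them
(intron length, distance to the donor and acceptor splice sites).

`clipscape` implements that series as composable stages with a
machine-checkable contract at each step, together with a seeded
synthetic-data generator so that every stage can be validated against known
ground truth without any external download. Two companion analyses round
out the toolkit: premature-termination-codon (PTC) logic for cassette
exons, and fold-change categorisation of a two-condition
differential-expression (DE) table.

# Tag extraction

`extractTag()` accepts a clone when the 5' adapter ends before the 3'
adapter begins — the correct cloning orientation. The forward read is tried
first; the reverse complement is searched only when the forward orientation
yields no valid insert, reflecting that a Sanger clone may be read from
either end but has only one true orientation. When an adapter occurs more
than once, the leftmost 5' adapter and the rightmost subsequent 3' adapter
delimit the insert; a further adapter copy strictly inside that insert
leaves the true insert undefined and the clone is rejected as
`ambiguous_multiple_placements`. Rejections are always categorical
(`no_adapter5`, `no_adapter3`, `wrong_orientation`, `too_short`,
`too_long`, ambiguous), and `tabulateTags()` reports totals per category so
that accepted plus rejected always equals the library size.

Adapter matching is exact by default. Sanger reads are accurate enough that
exact matching is the reproducible choice; a Hamming tolerance
(`max_mismatches`) is available for lower-quality reads. The minimum
accepted insert is 15 nt — the shortest fragment that can plausibly be
placed uniquely on a vertebrate-sized genome — and no upper bound is
applied by default.

"Distinct tags" means distinct insert sequences; per-tag occurrence counts
and source clone ids are retained but all downstream motif statistics are
computed over distinct sequences, unweighted, so that a clone duplicated by
PCR does not masquerade as independent evidence.

# Mapping and triage

The internal mapper (`mapTagsExact()`) is an exact-substring search of both
genome strands: zero hits is `unmapped`, one is `unique`, two or more is
`multi`. It exists to exercise the pipeline at desk scale, not to compete
with a real aligner; alignments from external tools enter through
`importAlignments()` (BED6, 0-based half-open on disk, 1-based closed in
memory). A tag matching the contaminant reference (either strand, exact
substring) is `contaminant` and is never searched against the genome —
screening precedes mapping, so a sequence matching both is reported as
contamination. `summarizeMapping()` produces the standard triage:
contaminant / unmapped-or-multi / uniquely mapped, with fractions of the
total.

No confidence score is attached to the internal mapper (exact matches are
binary); the import path tolerates a score column but deliberately applies
no default cutoff, since any such threshold belongs to the external
aligner's scoring model.

# Annotation against gene models

`GeneModels` stores one transcript per gene: sorted, disjoint exon blocks,
a genomic CDS span, and a known/unknown flag. "Unknown" marks loci with
transcript evidence but no annotation — a property of the input annotation,
never an inference this package makes. Introns are derived as the gaps
between consecutive exon blocks.

`assignGeneContext()` assigns each uniquely mapped tag to a gene by
overlap, preferring known genes over unknown ones, then the larger overlap,
then the lexicographically smaller gene id (a deterministic, documented
order for the rare overlapping-gene case). Within a known gene, the
category is decided by majority vote over per-base feature labels, with
ties broken toward `cds`, then `intron`: a tag straddling an exon/intron
boundary goes to whichever feature holds more of its bases. UTR naming is
strand-aware — the 5'UTR is 5' in transcription direction. The
majority-overlap rule (rather than full containment or any-overlap) is the
choice that degrades most gracefully for boundary-straddling tags; the
package's tests verify it base-by-base against an independent brute-force
oracle.

# Intron geometry

For each intronic tag, `locateContainingIntron()` reports the containing
intron's length and the tag's distance to both splice sites. Conventions,
fixed once and asserted as an invariant on all data:

* Distances use the *exclusive gap*: the number of intronic nucleotides
  strictly between the splice junction and the tag's proximal end, so a tag
  abutting the junction has distance 0 and
  `dist_upstream + tag_length + dist_downstream == intron_length` holds
  exactly for every context.
* *Upstream* and *downstream* are transcription-direction terms: the
  upstream splice site of an intron is its donor. Flipping a gene's strand
  swaps the two distances exactly.
* Distances are measured from the tag's proximal end, not its midpoint;
  for the 500-nt proximity question the two differ by at most half a tag
  length, which is immaterial at intron scale.

`summarizeGeometry()` reports mean, SEM (sample standard deviation over
the square root of n), median (mean of the central pair for even n), min
and max per metric. SEM rather than SD is reported after a mean because
that is how tag-geometry tables in the CLIP literature are typically
annotated; a single-context summary reports SEM 0 with an explicit
`sem_defined = FALSE` flag rather than NA, so downstream tabulation never
breaks. `proximityFractions()` uses inclusive thresholds (distance
&le; threshold), and "either side" uses the minimum of the two distances.
`lengthBins()` uses half-open bins `[b1, b2)` so every length falls in
exactly one bin.

# k-mer incidence and motif statistics

`countKmers()` counts every overlapping window (step 1) of width k = 1..6
over the distinct tags in the RNA alphabet; windows containing ambiguous
bases are excluded from counts and from the window total. The expectation
line is *uniform*: `total_windows / 4^k`, i.e. the incidence each word
would have if all words were equally represented. A composition-adjusted
expectation (product of observed mononucleotide frequencies) is available
but is not the default, because the uniform line is the conventional
reference for "expected by chance" in dinucleotide plots and makes
enrichment directly readable. Ranking is by descending count with
lexicographic tie-breaks, so the top-k list is reproducible.

Per-tag motif distributions (`motifCountDistribution()`) count overlapping
occurrences — "UGUG" contains two UGs — which is what makes the
occurrences-per-tag histogram well defined and is the standard convention.
Group comparisons (`compareGroupMotifCounts()`, e.g. UG counts in UTR tags
versus coding-exon tags) use a t-test assuming unequal variances (Welch),
one-tailed in a direction the caller must declare (default: first group
greater). Identical degenerate groups return t = 0 and one-tailed p = 0.5
rather than erroring, since "no evidence either way" is the correct answer
for equal constant groups.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline's claims are checked.

* **Genome**: i.i.d. bases from a configurable composition (default
  uniform), default one chromosome of 2 Mb.
* **Gene models**: default 60 non-overlapping genes, each with a
  5'UTR-bearing first exon (150 nt UTR), 2–4 internal coding exons of
  120 nt, and a 3'UTR-bearing last exon (300 nt UTR); 10% of genes are
  flagged unknown. Intron lengths follow a log-normal law parameterised by
  its median (default 3,000 nt) and the fraction of mass above a large
  cutoff (default 15% above 10 kb), reproducing the heavy-tailed intron
  length distributions of vertebrate genomes in which binding-site-bearing
  introns are often tens of kilobases long; draws are capped at one
  twentieth of the chromosome so genes remain placeable (the cap is ~3
  standard deviations into the tail at the defaults).
* **Binding sites**: copies of a UG-repeat motif (default `UGUGUG`,
  written `TGTGTG` on the DNA strand) overwrite intronic positions drawn
  uniformly over eligible offsets, without overlap, preserving genome
  length. Site placement is uniform because the planted truth makes no
  positional claim. The DNA/RNA duality is presentation-only: storage is
  DNA, motif reporting is RNA.
* **Clones**: each clone is a site-derived, background, contaminant, or
  malformed draw (defaults 0.5 / 0.2 / 0.25 / 0.05). Site-derived inserts
  are genomic windows overlapping a planted site; backgrounds are random
  genomic windows; contaminants are substrings of a deterministic GC-rich
  5 kb "rRNA-like" reference; malformed clones lack one adapter or carry
  both in the wrong orientation. Insert lengths are uniform on 30–80 nt,
  typical of Sanger-cloned CLIP inserts. Well-formed clones are emitted
  reverse-complemented with probability 0.5 by default. The truth manifest
  records every clone exactly once with its origin and genomic interval.
* **DE tables**: per-gene FPKM-like expression in two conditions with known
  categories. Regulated genes draw their fold change as
  `1.5 * exp(Exp(rate))` with separate rates for the two directions
  (defaults put roughly one third of down-regulated and two thirds of
  up-regulated genes beyond 2-fold, the asymmetry typical of knockdown
  transcriptomes); condition-exclusive genes have expression exactly 0 on
  one side; unchanged genes stay below the 1.5-fold gate and are not
  flagged significant.

All generator randomness funnels through the configuration seed, and
identical configurations produce byte-identical outputs.

**What the generator does not emulate.** There are no sequencing errors,
quality scores, spliced tags, paired reads, isoform diversity (one
transcript per gene), or positional structure of binding relative to
regulated exons. Background tag placement is uniform over the genome, so
the within-gene category mix of synthetic tags follows feature lengths
(mostly intronic) rather than any biological binding preference. Passing
recovery tests therefore demonstrates correctness of the bookkeeping —
extraction, screening, placement, interval arithmetic, statistics — not
that the pipeline would draw the same biological conclusions on real data.

One statistical subtlety is worth recording. Planting a k-nt motif
mechanically removes the overwritten windows from the pool available to
every other word, so a control dinucleotide (CA, the composition-matched
control for UG) is depressed slightly below its uniform expectation in
site-derived tags; and when many site-derived clones sample the *same*
planted site, their windows are correlated and a binomial band understates
the sampling variance. The chance-level behaviour of the control motif —
which the enrichment analysis relies on — therefore holds in the
sparse-binding regime, and the motif-recovery checks plant roughly one
site per expected binding-event clone. The test suite asserts, for three
fixed seeds at that setting, that the CA deviation stays inside ±3
binomial standard deviations while UG exceeds its expectation and the
planted hexamer ranks in the top 20.

# PTC detection and virtual RT-PCR

`detectPrematureStop()` builds the inclusion isoform by inserting the
cassette exon into the skip transcript, translates both in the frame given
by the CDS start offset, and reports the first in-frame stop codon present
in the inclusion isoform where the skip isoform reads through, along with
whether the exon length preserves frame (length divisible by 3). No
50-nt-junction NMD rule is applied: the codon index of the stop is
reported so callers can apply whichever NMD model they favour — the
package takes no position beyond the presence of the PTC.

`rtpcrProductSizes()` computes, per isoform, the number of exonic
nucleotides between the 5' ends of a primer pair, inclusive — a virtual
amplicon. By construction the inclusion product exceeds the skip product by
exactly the cassette exon length, and this identity is asserted as an
invariant.

# DE categorisation

`categorizeDe()` consumes a table of per-gene expression in a control and
a knockdown condition with a significance flag (the upstream differential
test — read mapping, assembly, CuffDiff-style inference — is out of scope
and never re-implemented). Fold change is a linear ratio,
`max(a/b, b/a)`, direction given by which condition is higher. The 1.5-fold
gate is inclusive ("at least 1.5-fold"); the strong 2-fold subset is strict
("more than 2-fold"). Genes at or below the expression floor in exactly one
condition are condition-exclusive (`only_control` / `only_kd`) and count
toward down-/up-regulation respectively. The floor defaults to exactly 0 —
"expressed only in" is read literally — with a configurable epsilon for
noisy FPKM estimates.

# Pipeline and problem sizes

`runClipPipeline()` chains all stages from one `SimConfig`, halts on the
first failing stage with the stage named, and returns a result bundle whose
machine-readable summary contains only numbers recomputable by calling the
stage functions directly — there is no pipeline-only arithmetic.
`runComparison()` stacks geometry summary blocks for several context
tables (e.g. tag sets from different tissues or proteins) into one
side-by-side table.

The package's tests and the acceptance script run entirely on synthetic
data at desk scale: the reference study is 1 chromosome × 2 Mb, 60 genes
and 500 clones (about half a minute end to end); oracle-equivalence checks
use a 100 kb genome with 20 genes and 300 tags; geometry invariants are
asserted on 1,000 simulated contexts; motif recovery uses three seeds of a
400 kb / 150-clone configuration. These sizes were chosen so the complete
validation cycle runs in a few minutes on a laptop while keeping every
count large enough for the statistical checks to bite.

# Known limitations

* The exact-match mapper does not handle mismatches, indels or spliced
  alignment; real genomes require an external aligner via the BED import.
* One transcript per gene: overlapping isoforms, alternative promoters and
  nested genes are out of scope (overlapping *genes* are resolved by the
  documented preference order).
* The uniform k-mer expectation ignores composition bias; the
  composition-adjusted option mitigates but does not model dinucleotide
  autocorrelation.
* The Welch comparison treats per-tag motif counts as independent
  observations; tags from the same binding site violate this mildly.
* The known/unknown flag must be supplied by the annotation; the package
  performs no homology or synteny inference.
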