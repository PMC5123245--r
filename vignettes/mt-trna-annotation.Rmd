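---
title: "Methods: structure-aware annotation of mitochondrial tRNA variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-aware annotation of mitochondrial tRNA variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MitoVarAnnot)
```

## The annotation model

Human mtDNA encodes 22 tRNAs, 2 rRNAs and 13 protein subunits on a 16,569-bp
circular genome (rCRS coordinates, 1-based inclusive throughout). A variant
in a tRNA gene is hard to interpret from the sequence alone: its consequence
depends on where the position sits in the cloverleaf secondary structure and
the L-shaped tertiary fold, and on whether the mature tRNA carries a
post-transcriptional modification there. The package therefore attaches to
every tRNA position a five-field structural annotation,

```
sprinzl ; trna_type ; domain ; mature_nt ; folding
```

with the fields defined as follows.

* **Sprinzl position** — the standard structural numbering 1–73 (CCA end
  excluded) that makes positions comparable across tRNAs; the anticodon is
  always 34–36. mt-tRNAs are shorter than the canonical 73 positions, so a
  curated alignment maps each gene offset (counted along the tRNA's own
  5'→3' direction, i.e. reversed for light-strand genes) to a Sprinzl
  number; offsets with no structural counterpart are unmapped and render as
  `-`. Unmapped positions remain annotatable: type and `folding=N` are still
  reported. Keeping the five-field contract fixed in field count is why `-`
  is used rather than dropping the field.
* **tRNA type** — the four structural classes of human mt-tRNAs: type 0
  (quasi-canonical, D-loop/T-loop interaction preserved), type II (the most
  common; D/T interaction lost), and two singletons: type I (atypical
  anticodon stem) and type III (no D-stem).
* **Cloverleaf domain** — `AS`/`DS`/`CS`/`TS` stems, `DL`/`CL`/`VL`/`TL`
  loops, `E` for the 3' end (discriminator), `-` for junction nucleotides.
  The canonical layout used for curation and validation is: acceptor stem
  1–7/66–72, junctions 8–9 and 26, D-arm 10–13/14–21/22–25, anticodon arm
  27–31/32–38/39–43, variable loop 44–48, T-arm 49–53/54–60/61–65,
  discriminator 73.
* **Mature nucleotide** — the nucleotide present in the functional tRNA
  after post-transcriptional processing, written in RNA alphabet (U not T)
  because it describes the transcript; one-character Modomics symbols
  (`"`, `K`, `L`, `D`, `R`, `P`, `'`, `Ê`, `Q`, `Ǝ`, `>`, `6`, `+`, `*`,
  `?`, `T`) replace the plain base wherever the bundled modification table
  lists that (tRNA species, Sprinzl position) pair. Note that the symbol `T`
  (5-methyluridine) cannot collide with a plain base precisely because
  unmodified uridines are written `U`.
* **Folding** — `Y` iff the Sprinzl number participates in the gene's
  tertiary-interaction set: the canonical triplets 10-25-45, 9-23-12 and
  13-22-46 plus, for type-0 tRNAs, the D/T-loop pairs 18-55 and 19-56. Base
  stacking is deliberately *not* encoded: it involves nearly every
  nucleotide, so folding it into the flag would make the flag uninformative.

### Invariants enforced at load time

The bundle loader cross-validates every table: Sprinzl numbers strictly
increase with gene offset; Sprinzl 34–36 always carry domain `CL` and `CL`
appears nowhere outside 32–38; `folding=Y` exactly at tertiary-set members;
mature nucleotides are plain bases unless the modification table says
otherwise; every tRNA locus has a map covering each gene position exactly
once; the human map has 22/2/13 genes with exactly one type-I and one
type-III tRNA; stored normalized scores equal `raw/max` to 3 decimals.

## Pathogenicity scoring

Literature scores for RNA-gene variants come from two different rubrics:
an integer 0–20 scale for tRNA variants and a six-level 0–5 scale for rRNA
variants. Raw scores are the citable source of truth and are stored as
integers; normalization to `[0, 1]` (`raw / max`, rounded half-even to three
decimals) happens at load. The damaging/neutral call is
`normalized >= threshold`, with thresholds **0.350** (tRNA, i.e. raw 7/20)
and **0.600** (rRNA, raw 3/5); the boundary is inclusive by definition of
the original rubrics. Score lookup is allele-aware — (position, ref, alt)
exactly — because distinct substitutions at one site have distinct published
scores; there is no position-only fallback. Database annotations that the
package does not compute (MITOMAP disease associations, ClinVar, dbSNP,
OMIM, conservation and variability scores) are pass-through columns filled
from bundled tables when present and left as empty strings otherwise.

## Coding-space enumeration

Every position of every protein-coding gene model is substituted with the
three alternate bases and classified codon-wise under the vertebrate
mitochondrial genetic code (TGA = Trp, ATA = Met, AGA/AGG = stop, obtained
from `Biostrings::getGeneticCode("SGC1")`). No other code reproduces
mitochondrial stop-codon behaviour. Choices where conventions genuinely
differ:

* **Incomplete terminal codons.** Several mitochondrial mRNAs end in a
  codon completed to UAA by polyadenylation. By default those positions are
  excluded from enumeration (and counted in
  `summary$skipped_incomplete_positions`, never silently dropped);
  `include_incomplete_stops = TRUE` pads the terminal codon with A's and
  enumerates the real positions, which makes stop-loss events at those sites
  visible.
* **Overlapping genes.** A position inside two gene models is classified
  independently in each reading frame (the tracks are per-gene); the
  summary also reports counts de-duplicated over unique
  (pos, ref, alt, effect) tuples, since published totals may count
  overlapping-frame duplicates either once or twice.
* **Strand.** Complementary-strand genes are handled via the strand flag of
  the gene model (alleles reported on the forward strand, codons in coding
  orientation) — no gene is special-cased by name. A metamorphic test checks
  that reverse-complementing a toy genome and re-annotating yields identical
  effect partitions.

The reference genome is user-supplied FASTA; the package never downloads
sequence at runtime and does not bundle the rCRS.

## The reference bundle

Tables are tab-delimited UTF-8 with a one-line header plus a JSON manifest
(row counts, genome length, schema version, counting conventions);
serializing a loaded bundle and re-loading it yields identical records. Two
curation points deserve explicit statement:

* **Strand bookkeeping.** The gene map records strand per gene from the
  RefSeq-style annotation (8 tRNAs on the light strand) rather than
  inferring it from sequence, because published statements about mt-tRNA
  strand distribution are not mutually consistent.
* **Structure-map provenance.** Only the MT-TM (tRNA-Met) map is curated
  from the real gene sequence; it reproduces the known annotation of
  position 4450 (Sprinzl 53, type II, TΨC stem, mature G, folding N) and
  places the Met modifications at Sprinzl 27 (pseudouridine), 34
  (5-formylcytidine) and 50 (pseudouridine) on chemically consistent bases.
  The other 21 maps are *synthetic stand-ins* generated by
  `generate_trna_map()` with the real gene lengths, literature type
  assignments (type III = Ser(AGY), type I = Ser(UCN), five type-0 genes,
  the rest type II), real anticodons and the bundled modification
  placements; their `provenance` column says `synthetic`. Structural
  conclusions drawn from those 21 maps are therefore illustrative, not
  biological claims; swapping in a fully curated `trna_structure.tsv`
  requires no code change.
* **Modification counting.** The modification table keeps one record per
  (position, modification, tRNA species) — 116 records across the
  human/bovine/model-organism evidence classes — while *modified residues*
  are counted as unique (position, species) pairs, of which there are 110:
  six residues carry two alternative modifications. Both conventions are
  recorded in the manifest. The per-record evidence label is best-effort
  where the source tabulation was ambiguous.
* **Gene-position tallies.** Summing the 22 tRNA gene lengths of the
  RefSeq-style map gives 1508 positions (1504 unique, after the 3-bp
  MT-TI/MT-TQ and 1-bp MT-TC/MT-TY overlaps); the rRNA genes sum to 2513.
  Published tallies that de-duplicate only some overlaps can differ from
  either number by a few positions; the `MT-RNA` track emits one record per
  (gene, position), i.e. 1508 + 2513 records, and the manifest records both
  tallies.

## GFF3 tracks

Four tracks are built: all possible non-synonymous coding substitutions
(`MT-patho.CDS`), all possible stop-gain/stop-loss substitutions
(`MT-patho.STOP`), the scored RNA variants with the normalized score in the
GFF3 score column (`MT-patho.RNA`), and one record per tRNA/rRNA gene
position with its five-field annotation (`MT-RNA`). Records carry HGVS names
(`m.<pos><ref>><alt>`, `m.<pos>del`, `m.<pos>_<pos+1>ins<seq>`) in the
`Name` attribute, attribute values are percent-encoded, files start with
`##gff-version 3`, and sorting by start is a checked postcondition. The
seqid defaults to `chrM` with `MT`/`NC_012920.1` options, since browsers
disagree on the dialect. The writer is part of the package (the attribute
vocabulary is a documented repo convention); re-parsing in tests goes
through `rtracklayer::import()` as an independent strict parser.

## Synthetic fixtures and what passing tests show

`generate_trna_map()`, `generate_toy_genome()` and `generate_variants()`
drive all offline testing from a single integer seed each (no global RNG
state is touched; regeneration is bit-identical). Toy genomes place
ATG/ATA-initiated, mito-stop-terminated genes of configurable codon count on
alternating strands of a small circular sequence, with optional synthetic
tRNA genes; ground-truth effect classes are computed by an embedded
brute-force oracle (mutate the raw sequence string, re-translate with
Biostrings, diff the amino-acid strings) that shares no code with the
codon-wise classifier under test, and expected tRNA annotations come from
raw alignment lookup, not from the annotation module. An optional AT-rich
composition mode mimics the strong A/U/C bias of mt-tRNAs; by default
composition is uniform.

What the fixtures do *not* emulate: realistic mutation-rate spectra,
heteroplasmy, sequencing error, or the true structural alignments of the 21
non-curated tRNAs. Passing tests therefore demonstrate correctness of the
annotation/enumeration machinery and internal consistency of the bundle, not
the biological accuracy of the synthetic maps.

Problem sizes used by the shipped test-suite: toy genomes of ≤ 3 genes × ≤
10 codons over 20 seeds for oracle-equivalence of enumeration; all 1508
bundled tRNA positions for annotation exhaustiveness; the full 0–20 and 0–5
scoring grids; end-to-end determinism checked byte-exactly on command
outputs.

## Numerical and edge-case choices

* Rounding of normalized scores: R's `round()` (half-even), 3 decimals.
* Threshold comparison: `>=` (inclusive), per the original rubrics.
* Positions shared by two overlapping tRNA genes are annotated in the
  context of the gene starting first; `locate_position()` returns both loci.
* A position annotated in two alternative modifications resolves by evidence
  preference human → bovine → model organism, then table order.
* The generator requires at least 59 mapped positions per map — the length
  of the shortest human mt-tRNA gene (the D-armless Ser(AGY)).
* The circular genome allows exactly one origin-wrapping locus (the control
  region); interval logic and coding-index arithmetic are wrap-aware.
* Variant normalization trims VCF anchor bases before HGVS naming;
  equal-length multi-base replacements are typed `other` and excluded from
  the transition/transversion/insertion/deletion partition.

## Known limitations

* The 21 synthetic structure maps (above) — the package's architecture is
  table-driven precisely so that a fully curated map can replace them.
* The bundled scored-variant table contains the curated worked-example
  record plus a handful of rows flagged `synthetic-example`; the full
  literature sets are not redistributed here.
* No secondary-structure prediction, folding energetics, read-level
  processing, heteroplasmy quantification or haplogroup inference: upstream
  or out of scope by design.
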