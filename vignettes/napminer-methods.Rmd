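---
title: "Methods: from gene clusters to detected natural products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gene clusters to detected natural products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napminer)
```

## The problem

Nonribosomal peptides (NRPs) and type I polyketides (PKs) are assembled by
modular enzyme assembly lines whose gene order largely determines the
product's monomer order (co-linearity). Sequenced bacterial genomes carry
far more of these biosynthetic gene clusters (BGCs) than known compounds,
so a productive discovery route is: predict the product's structure from
the cluster, enumerate a library of hypothetical variants around that
prediction, fragment each variant *in silico*, and look for matching MS/MS
scans in an LC-MS/MS run of a crude extract. napminer implements that
pipeline end to end: annotation ingestion, cluster and module grammar,
scaffold chemistry, deoxysugar prediction, combinatorial enumeration,
fragmentation, and decoy-normalized spectral scoring.

## Representation: residue graphs, not atom graphs

Every structure the pipeline builds is represented as a **residue graph**:
monomer instances (amino acids, ketide extender units, fatty-acyl starters,
sugars) joined by typed bonds (`amide`, ketide Claisen `cc`, `ester`,
`glycosidic`). Each monomer carries an elemental formula, so masses are
exact sums: every bond costs one water (ketide units are stored as their
acid equivalents precisely so that this rule is uniform), and reductive-loop
or N-methyl modifications are fixed deltas (KR +2.015650, DH -18.010565,
ER +2.015650, N-methyl +14.015650 Da). SMILES is composed from curated
per-monomer templates and checked against OpenBabel (ChemmineOB): in the
test suite, bookkeeping masses and OpenBabel's exact masses agree to
better than 1e-3 Da across peptides, hybrid PK/NRP chains, macrocycles and
glycosides.

The residue level is the right granularity for this chemistry: all
cleavable bonds of the fragmentation model (amide, ester, glycosidic) are
inter-residue bonds, mass conservation is exact by construction, and the
monomer provenance of every fragment is retained. The cost is that
structures loaded from plain SMILES lists (without the package's serialized
residue graph column) cannot be cleaved at bonds - they participate in
matching via their precursor mass and neutral losses only. Libraries
written by `write_structure_library()` round-trip with full fragmentation.

## Cluster and module grammar

Domain hits are ingested from HMMER3 `--domtblout` tables with four
adjustable bitscore cutoffs (adenylation 25, acyltransferase 25,
thiolation/thioesterase 15, other 20 bits - the classes are adjustable by
design; the defaults are this package's choices). Same-family hits
overlapping by more than 30% of the shorter hit are merged keeping the
higher score, to avoid double-counted modules. Annotated genes are grouped
by a greedy scan that starts a new cluster when the gap from the end of one
gene to the start of the next exceeds 10 kb (the gap anchors are a package
decision; the window is the conventional default). Clusters survive only
with at least one adenylation-or-acyltransferase and one
condensation-or-ketosynthase domain.

Modules are condensation-to-thiolation spans containing an adenylation
domain (NRPS) or ketosynthase-to-thiolation spans containing an
acyltransferase (PKS); a leading adenylation-thiolation span before any
anchor is the initiation module. Two deliberate decisions:

* a condensation domain *opening* module 1 flags **starter acylation**
  (lipopeptide-type initiation); the scaffold then carries an open `R_acyl`
  site rather than a guessed fatty acid;
* standalone adenylation-thiolation didomain genes are surfaced as
  **trans-acting** modules and never inserted into the chain automatically,
  because their position genuinely is ambiguous - combinatorialization
  recipes are the place to resolve them (the shipped lipopeptide recipe
  does exactly that with four scaffold variants).

A consequence of the second rule is that an initiation module occupying a
gene by itself is indistinguishable from a trans didomain and is reported
as trans; on real assembly lines initiation modules almost always share a
gene with downstream modules, which disambiguates them.

Genes on either strand contribute; assembly-line order follows genomic
coordinates, with domains inside each gene in translation order.
Multi-contig clusters and trans-AT PKSs are out of scope and flagged, not
guessed. Stereochemistry is never predicted (MS cannot confirm it);
all stereocenters are emitted unspecified.

## ORF detection

For cluster-sized DNA inputs, all six frames are scanned for
start-codon-to-stop spans (ATG/GTG/TTG accepted, bacterial convention;
minimum 50 aa by default - the thresholds are package decisions).
Coordinates are 0-based half-open on the forward strand, which keeps the
clustering-window arithmetic unambiguous. Whole-genome gene calling is
delegated: supply protein FASTA (one cluster per file, as location
information is absent) or an external gene caller's coordinates.

## Deoxysugar prediction

Glycosylated products are predicted with a **glycogenomic code**: a table
mapping each sugar to the set of sugar-pathway gene families its
biosynthesis requires. The shipped `sugar_code_synthetic.tsv` is a
*synthetic reconstruction* - 14 deoxysugar/pentose entries over 20 gene
families (including the UDP-glucose dehydrogenase/decarboxylase pentose
route), plus 4 hexoses - built from the public glycogenomics literature; it
is deliberately user-replaceable, and mycaminose/ravidosamine carry
identical family sets because diastereomers are genomically
indistinguishable.

The number of deoxysugar slots is the glycosyltransferase count minus those
whose top homology hit indicates a hexose substrate (glucose, mannose,
gulose, N-acetylglucosamine; an empty homology result conservatively keeps
the enzyme in the deoxysugar count). Every **multiset** of that size over
the code is evaluated: `missing` = pathway families absent from the
cluster, `extra` = cluster sugar-gene families unexplained by the
combination, in set semantics over family names (pathways share enzymes, so
copy number is not compared). The two objectives are folded into their sum
with a smaller-`missing`-first tie-break and a lexicographic final
tie-break; all co-optimal multisets are retained, since the data genuinely
cannot distinguish them. Multisets (repetition allowed) are used because a
product can carry the same sugar twice. Exhaustive search is bounded at 4
slots by default (about 9e5 combinations for a 67-sugar code; the
evaluation is bitmask-vectorized when there are at most 31 families).
Hexoses from the glycosyltransferase calls are appended after optimization.
Glycosylation sites are drawn from the scaffold's free hydroxyls with a
seeded generator, or enumerated exhaustively on request.

## Combinatorial libraries

A library recipe is a plain-text file of scaffold token lists plus axes
(residue substitutions, glycosylation choices) and cyclization options;
`enumerate_library()` emits the full cartesian product in deterministic
provenance order with **no deduplication**, so the library size is exactly
the product law over blocks. The six shipped recipes reproduce the
published library sizes for the worked examples: 768 (lipopeptide with
four trans-didomain placements x 3 acyl chains x 6 binary interchanges),
576 twice (2 cyclization x 2x2 Ser/Thr x 6x6 ornithine side-chain states x
2 malonate/methylmalonate), 32, 42 and 120. Two factorizations deserve a
note, as the sources print the axis types and the totals but not the full
factorizations: the 42-member glycosylated-polyketide recipe encodes
"methylmalonates interchangeable with malonate" as a six-option
single-position swap axis (none, or one of the five extender units), the
only reading consistent with 42 = (4+3) x 6; and the 576-member recipes use
a lactone for the "macrocycle" option because the scaffold's acylated
N-terminus rules out a head-to-tail lactam. The 120-member recipe's axes
(3 x 2 x 2 x 10) are fully determined.

## In-silico fragmentation

Cleavable bonds are typed from the residue graph: backbone and starter
amides, lactone esters, and glycosidic bonds gated on the sugar ring
matching an **oxan-2-ol** SMARTS pattern (six-membered oxygen ring with an
exocyclic oxygen at the anomeric carbon). Budgets are per-channel
`c(min, max)` cleavage counts (plus water/ammonia neutral losses), with the
summed maxima globally bounded (default 6).

Hydrogen transfer follows one convention, applied uniformly: the
amine/alkoxy-side fragment is emitted as the free (hydrolysis-equivalent)
neutral species, the acyl side as the ketene equivalent (parent minus the
free side). For glycosidic bonds the aglycone keeps its hydroxyl and the
sugar leaves as the anhydro/oxocarbenium-equivalent species; the
inverse-ester channel flips the ester assignment (free acid + dehydrated
alkoxy side). This makes single-cleavage mass conservation *exact*
(tested to 1e-6 Da), and for linear peptides the amide series coincides
with the classical b/y neutral series, verified in the tests against an
independent computation from residue masses. Both hydrolytic and
ketene-type species are observed in CID data; one consistent convention
that conserves mass is preferable to emitting both and double-counting.

The first cleavage of a macrocycle yields a ring-opened species of
unchanged mass, which is what "1-2 amide cleavages" means for a
cyclic peptide: one cut to open, one to fragment. Internal fragments
(two or more cut ends on an acyclic chain) are only emitted when the summed
cleavage budget is at least 3, to control combinatorial blow-up. Fragment
substructure SMILES are emitted where a clean neutral valence form exists
(free ends; ketene acyl ends); sugar-side anhydro species and loss-modified
variants carry `NA` - their masses are still exact. Masses are
monoisotopic throughout; protonated ions are computed at 1+ (and 2+ above a
400 Da floor, configurable).

## Spectral matching and scoring

Scans are read from mzXML (via mzR) or MGF, MS2 only. Precursor filtering
deconvolutes the neutral mass at the scan's charge (or every allowed
charge when unknown) and keeps scans within +/- W of the candidate mass; W
is directionless by design, matching how precursor windows are quoted.
Fragment matching is greedy nearest-m/z within a tolerance (default 0.5 Da,
suitable for ion-trap CID; set ~0.01 for Orbitrap data), each peak and each
theoretical fragment used at most once.

The original platform's P1/P2 formulas were published only by reference, so
this package defines its scores explicitly and treats them as its contract:

* **P1** = -10 log10 of the binomial upper-tail probability of at least
  `k` of `n` theoretical fragments matching by chance, with per-fragment
  chance probability `q = min(1, n_peaks * 2 * tol / mz_range)`;
* **P2** = the same tail statistic restricted to the intensity-rank top
  half of the peaks, so matches carried by noise-level peaks score zero.

Both are clamped to [0, 200]; an empty spectrum scores (0, 0). The scale
is decibel-like and lives where the conventional cutoffs (5/10/15/20) are
useful: with 10 theoretical fragments, q = 0.01 and 3 matches, P1 is about
39.4. Exact numerical equivalence to the predecessor tool is a non-goal.

For the **prediction-guided discovery chart**, each scan whose top-ranked
hit (P1, ties by P2, then compound id) is a prediction-library compound
passing both cutoffs contributes its top P1 divided by the mean P1 of the
decoy ("dummy") library on that scan; the denominator is floored at 1 so
scans where decoys score ~0 do not explode. Normalized values are summed in
half-open 0.25-minute retention-time buckets. Eluting compounds span
several scans, so true signals accumulate across a bucket while isolated
chance matches do not.

## The synthetic-data generators

`make_cluster_fixture()` writes real on-disk formats (protein FASTA, a
HMMER3-format domtblout, a homology TSV, gene coordinates) from a domain
string recipe, so every test exercises the same readers as real data.
`make_spectrum_fixture()` writes mzXML/MGF whose peaks are a structure's
theoretical fragment m/z values at fixed high intensity plus a seeded
fraction of uniform-random noise peaks at lower random intensities;
`make_decoy_library()` draws random 4-10-residue linear peptides. These
emulate annotated clusters, spectra of known compounds, and a background
structure library - they do **not** emulate chromatographic peak shapes,
isotope envelopes, co-eluting chimeras, calibration drift, or the real
false-annotation rate of homology search. A passing self-identification
test therefore shows the pipeline's internal consistency and its noise
robustness under the stated model, not field performance on real extracts,
which additionally depends on expression, ionization and prediction
accuracy.

## Problem sizes and numerical choices

The test suite enumerates all six shipped recipes (2114 structures),
compares sugar prediction against exhaustive search on 100 random toy codes
(up to 10 sugars, 3 slots), checks fragmentation conservation and the b/y
oracle on dozens of random peptides, and runs 120 self-identification
trials against 50 decoys (20 noiseless with per-trial random planted
hexapeptides, 100 at 20% noise with a fixed planted compound, where
rank-1 recovery of at least 95% is required). These sizes were chosen to
give stable pass/fail behaviour at interactive runtimes. Seeds are fixed
throughout; seeded draws save and restore the caller's RNG state.

Degenerate inputs are handled explicitly: empty FASTA records, malformed
domtblout lines (reported with line numbers), empty substrate calls
(wildcard monomer rendered as an attachment site), clusters with no
recoverable modules, zero-slot sugar predictions, spectra with no peaks,
and empty decoy libraries (chart disabled with a warning) all have defined
behaviour and tests.

## Known limitations

* Epimerase-driven D/L assignment, thioesterase regiochemistry, tailoring
  enzymes outside the module string (halogenases, beta-hydroxylases,
  N-acyltransferases) are not auto-applied; they are combinatorial axes.
* Trans-AT PKS systems, iterative modules, and docking-domain reordering
  are out of scope.
* Graph-less SMILES libraries match on precursor mass and losses only.
* The thioether cleavage channel is accepted in settings but the builder's
  monomer chemistry never produces thioether bonds, so it is inert unless a
  residue graph with such bonds is constructed by hand.
* The shipped sugar code is a labelled synthetic reconstruction intended
  for method development and testing; serious glycogenomics should swap in
  a curated table via `load_sugar_code(path)`.
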