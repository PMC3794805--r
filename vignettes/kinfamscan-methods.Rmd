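---
title: "Methods: a genome-wide kinase gene-family survey pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a genome-wide kinase gene-family survey pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kinfamscan` re-implements, as a tested and reusable pipeline, the standard
machinery of a genome-wide MAP kinase kinase kinase (MAPKKK) family survey
in a plant genome: homology screening against a query family set, redundancy
removal, PROSITE-style kinase hallmark validation, ZIK/MEKK/Raf subfamily
classification by conserved signature motifs, theoretical pI and molecular
weight, a neighbor-joining phylogeny with bootstrap support, cDNA-to-genome
exon/intron inference, tandem/dispersed duplication calling, and RPKM
expression quantification from uniquely mapped reads. Because the real
survey inputs are a full diploid cotton genome and archived sequencing runs,
the package ships a synthetic-data generator whose truth table plants a
cotton-like family composition, so that every stage can be scored for exact
parameter recovery.

This vignette records the models, the tunable parameters and their defaults,
the numerical choices, and the design decisions taken where the methodology
left the design open.

## The identification funnel

The funnel mirrors how plant kinase families are identified in practice:

1. **Identity screen** (`screenByIdentity`). Each candidate protein is
   aligned locally (Smith–Waterman, BLOSUM62, gap open 10 / extend 1; a gap
   of length $k$ costs $\mathrm{open} + k\,\mathrm{ext}$) against every
   query. Identity is computed over the local alignment's columns
   (BLAST-hit semantics), where *aligned length* counts residue-vs-residue
   columns and the identity denominator includes gap columns. Candidates
   with best identity $\ge$ 0.50 pass.

   Two columns of fine print, both deliberate. First, the 50% identity
   could alternatively be read as identity over the query length; we use
   identity over the hit, and the report carries coverage so users can
   re-derive the other reading. Second, an unfiltered optimal local
   alignment between two *unrelated* proteins is occasionally just a
   handful of columns long with deceptively high identity (we measured
   hits of 6 columns at 83% identity between random sequences); a
   heuristic search never reports such hits, so the screen requires at
   least `min_aligned = 50` aligned columns. Without this filter a few
   percent of random decoys "pass" the screen on 6-residue hits — and are
   then discarded by hallmark validation anyway.

2. **Redundancy removal** (`removeRedundancy`). Sequences passing the
   screen are aligned globally against each other; pairs with identity
   $\ge$ 0.98 and mutual coverage $\ge$ 0.98 are linked, clusters are formed
   by single linkage, and the longest member per cluster is kept (ties go
   to the lexicographically smallest id, making the operation
   order-independent). The thresholds collapse only near-identical database
   duplicates; no threshold is stated in the survey literature for this
   step, so they are configurable. Global identity can never exceed the
   short/long length ratio, which the implementation uses as an exact
   pre-filter to skip hopeless pairs.

3. **Hallmark validation** (`validateHallmarks`). A candidate is accepted
   only if all three configured kinase hallmark patterns match: a
   glycine-rich ATP-binding loop, a serine/threonine (HRD) active-site
   loop, and a DFG kinase-domain motif. The patterns live in
   `inst/extdata/hallmarks.yaml` in PROSITE grammar. One of the canonical
   hallmarks is, in the original databases, a *profile* rather than a
   pattern; here it is operationalized as a packaged pattern so that the
   shipped matcher can evaluate it, and the file is configuration — users
   with a profile scanner can substitute its output.

The funnel is monotone: raising the identity threshold never enlarges the
accepted set.

## Subfamily classification

The three diagnostic signatures sit in kinase subdomain VIII:

* ZIK — the literal `GTPEFMAPELY`;
* MEKK — `G-[TS]-P-x-[WF]-M-A-P-E-V`;
* Raf — `G-T-x-x-[WY]-M-A-P-E-[LV]`.

`x` is read as "any of the 20 standard residues", not "unknown residue",
and matches are strict (no mismatch tolerance — the survey methodology does
not state any). The ZIK literal structurally cannot satisfy the MEKK
pattern (terminal V required) or the Raf pattern (W/Y at position 5), but
the MEKK and Raf patterns intersect (e.g. `GTPAWMAPEV` matches both).
Classification therefore applies the precedence **ZIK > MEKK > Raf** —
most-specific first — and preserves the information in an `ambiguous` flag
when more than one class matches. The kinase-domain span is taken from the
hallmark hits (leftmost ATP-loop hit to rightmost active-site hit), and its
midpoint position is labelled N-terminal / central / C-terminal by thirds
of the sequence length.

## Protein parameters

Net charge at a given pH follows the Henderson–Hasselbalch form: the
N-terminus and the side chains of H, K, R contribute
$+1/(1+10^{pH-pK})$; the C-terminus and the side chains of C, D, E, Y
contribute $-1/(1+10^{pK-pH})$. The packaged pK set
(`inst/extdata/pk_bjellqvist.tsv`) is the immobilized-pH-gradient
calibration used by the ExPASy Compute pI/Mw tool, including the
residue-specific N-terminal variants and the C-terminal side-chain variants
for D and E; the code treats the table as opaque configuration. Because the
net charge is strictly decreasing in pH, the isoelectric point is the
unique root; it is found by bisection on [0, 14] to a tolerance of
$10^{-4}$ (matching the display precision of the reference tool), which is
robust where Newton iterations can stall on flat charge profiles.
Molecular weight is the sum of average isotopic residue masses plus one
water, reported in kDa rounded to two decimals in the per-gene table.

## Phylogeny

The tree stage is a ClustalW-style progressive alignment followed by
neighbor joining:

* **Guide tree and merges.** Pairwise global alignments give p-distances
  (1 − identity); the NJ merge order is the guide; profiles are merged by
  profile–profile dynamic programming with average sum-of-pairs BLOSUM62
  column scores and a linear gap penalty equal to the gap-opening cost.
  Ties in the traceback break diagonal > up > left, for determinism.
* **Distances.** p-distance with pairwise deletion: mismatches over
  columns where both rows carry a residue. A distance correction (Poisson,
  JTT) would be defensible; p-distance is the simplest reading of
  "default parameters" in the reference methodology and is swappable.
* **Neighbor joining.** Saitou–Nei $Q$ criterion, ties resolved toward the
  lexicographically smallest pair of cluster labels, rate-corrected branch
  lengths, negative estimates clamped to zero (the behaviour of the usual
  desktop implementations). On additive matrices the generating topology
  is recovered exactly — this is tested against random trees.
* **Bootstrap.** Columns are resampled with replacement; each replicate is
  rebuilt end-to-end (p-distance + NJ); an internal edge's support is the
  percentage of replicates containing the same bipartition. The survey
  convention is 1000 replicates and that is the pipeline default; the test
  suite and the bundled acceptance run use 100, a scale chosen so the
  whole analysis re-runs comfortably on a laptop while leaving the
  supported/unsupported distinction intact.

## Gene structure

Each family cDNA is located on the genome by exact 20-nt seeds (both
orientations; the 20-nt length reuses the survey's minimum read-signature
convention). The chromosome/strand with the most matching seeds wins; ties
are flagged `ambiguous` rather than silently resolved, and no hit anywhere
is `unplaced`. Exon/intron structure then comes from chaining maximal exact
matches between the cDNA and the locus: genomic gaps of at least
`min_intron = 20` nt become introns, gaps on the cDNA side are not allowed,
and the chain must cover 100% of the cDNA or the gene is reported
`unresolvable`. Where a splice junction is locally ambiguous (the cDNA can
coincidentally match the first bases of the intron), the boundary is chosen
to give a canonical GT..AG intron, falling back to the least-overshoot
boundary; non-canonical introns are counted and logged, not rejected.
Exact-match chaining (rather than a mismatch-tolerant spliced aligner) is a
deliberate scope decision: the procedure being modelled aligns a cDNA to
its *own* genomic locus.

## Duplication calling

All unordered gene pairs are evaluated by global nucleotide alignment
(match 2 / mismatch −3 / gap open 5 / extend 2; N never matches anything).
A pair is a duplication when the aligned region covers **more than 80%** of
the longer gene and its identity **exceeds 80%** — both strictly, so a pair
at exactly 0.8 is excluded. "Aligned length" is the number of
residue-vs-residue columns, consistent with the alignment module. Pairs on
one chromosome whose spans lie within `linkage_window` (default 250 kb — a
declared choice; "tightly linked" has no published definition here) are
tandem; tightly linked pairs merge into a single duplication event by
single linkage, so a tandem cluster of three mutually similar genes counts
once. The operation is brute force by design at family scale (~3000
pairs), and the tests verify it against an independent per-pair
recomputation. Alignment on cDNA rather than protein is the package's
reading of "gene" in the duplication criteria.

## Expression

Reads are assigned to transcripts by exact substring matching in either
orientation (library strandedness is not assumed); reads shorter than 20 nt
are rejected. A read counts only if it matches exactly one transcript —
multi-mappers are dropped entirely, the strict reading of "uniquely
aligned". Per transcript and tissue,
$\mathrm{RPKM} = 10^6 C / (N L / 10^3)$ with $C$ the transcript's unique
read count, $N$ the sample total of unique counts and $L$ the transcript
length in bases. A gene is *expressed* when any tissue has at least
`min_reads = 1` unique read — chosen because the generator's silent genes
receive exactly zero reads, and configurable for real data where a noise
floor exists. The 0-DPA/3-DPA preference label compares ovule RPKMs with
strict inequality. No "strongly expressed" cutoff is implemented: the
survey literature never defines one.

## The synthetic dataset and what it does (not) show

`generateProteome`/`generateGenome`/`simulateReads` build a cotton-like
dataset with a complete truth table. The packaged paper profile
(`inst/extdata/paper_profile.yaml`) plants 78 family genes (12 ZIK, 22
MEKK, 44 Raf) plus 200 decoys; 13 chromosomes with 11 genes on chromosome
6 and 3 on chromosome 10, ZIK and MEKK genes confined to ten chromosomes;
exon counts from 1 to 23 with the ZIK layouts (two 2-exon and two 8-exon
pair genes, the rest 7 exons); 12 duplication pairs of which 2 are tandem;
60 genes expressed and 18 silent, with 11 Raf genes higher in 0-DPA ovules
and 8 higher in 3-DPA ovules. All of this is configuration, not code.

Construction details that matter for interpreting results:

* Every family protein is a per-subfamily ancestor mutated at
  `mutation_rate = 0.25` per residue outside a motif mask; a 130-residue
  scaffold block carries realizations of the three hallmarks and exactly
  one subfamily signature (ZIK members the literal; MEKK/Raf members a
  per-gene realization sampled by rejection so it never satisfies a
  higher-precedence pattern). The block sits N-terminally in ZIK,
  C-terminally in Raf, uniformly in MEKK proteins. The query set contains
  three ancestor variants per subfamily with the block at the ends and
  middle of the allowed window, the way a real Arabidopsis/rice query
  collection spans domain arrangements. The divergence level is chosen
  once, for separation of the planted decision boundaries: members sit at
  ~0.60–0.77 identity to their nearest query (screen at 0.50), non-partner
  same-subfamily cDNAs at ~0.70 identity (duplication criterion at 0.80),
  and duplication partners, mutated copies at `partner_divergence = 0.04`,
  at ~0.95.
* Reverse translation uses a packaged one-codon-per-residue table —
  determinism beats codon realism here. CDSs are split into the planted
  exon layout with random GT..AG introns of 60–300 nt; the generator
  verifies each gene's structure is unambiguously recoverable and resamples
  introns in the rare ambiguous case. Reads are error-free, single-end,
  50 nt, 50,000 per tissue, drawn uniformly with multiplicity proportional
  to truth RPKM × length; log-normal RPKM truth (meanlog 3, sdlog 1) keeps
  every expressed gene's expected coverage far above the 1-read call
  threshold.

Passing the recovery tests therefore shows that the pipeline's decision
rules are implemented correctly and recover a planted truth **under the
generator's assumptions**: no sequencing error, no splice variation, no
length variation within subfamilies, exact exon-concatenation cDNAs, and
cleanly separated identity regimes. It does not show robustness to the
messiness of real proteomes (fragmented gene models, chimeric domains,
borderline homologs), which is where the configurable thresholds exist.

## Numerical and scale choices

* Alignment is executed by `Biostrings::pairwiseAlignment`; identity,
  aligned length and coverage are derived in this package and verified in
  the tests against an independent plain-R affine-gap dynamic programme
  and, at tiny lengths, against exhaustive enumeration of all alignments.
* The bundled analysis scales: 278 candidate proteins, ~3000 all-vs-all
  cDNA pairs, 50,000 reads per tissue, 100 bootstrap replicates; a full
  run takes a few minutes on one core.
* Bisection tolerance $10^{-4}$ pH; Mw additivity holds to $10^{-9}$ Da;
  NJ branch-length arithmetic is exact to floating point (3-taxon closed
  form tested at $10^{-9}$).
* Determinism: every stochastic stage derives its RNG stream from the run
  seed; two runs with one seed produce identical summaries, trees and
  FASTQ files.

## Command-line interface

The exported functions are the primary interface, and `runPipeline()`
writes every stage's output as a checkpoint file (TSV/GFF3/newick/JSON) so
an analysis can be re-entered at any stage. A thin `Rscript` front end at
`inst/scripts/kinfamscan` covers the common entry points (`simulate`,
`run-all`, `identify`, `express`, `score`); the remaining stage verbs are
deliberately not duplicated as shell commands — they are one function call
each on the checkpoint files.

## Known limitations

* No E-value model in the screen; the aligned-length filter is a proxy for
  hit significance.
* True PROSITE *profiles* (position-specific scores) are not evaluated;
  the hallmark set is pattern-based configuration.
* The progressive aligner targets correctness and determinism, not
  ClustalW feature parity (no sequence weighting, no position-specific gap
  penalties).
* Duplication linkage ("tandem") depends on a declared window, not on a
  synteny model; whole-genome duplication blocks are out of scope.
* Expression has no mismatch tolerance and no fractional multi-mapping
  mode; both would change C and N on real, error-containing reads.
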