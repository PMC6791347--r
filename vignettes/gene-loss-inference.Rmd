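---
title: "Inferring gene loss from genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene loss from genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneloss)
```

# The problem

A protein-coding gene is lost when ORF-abolishing lesions — frameshifting
indels, in-frame premature stop codons, locus truncations — become fixed in a
lineage. Comparative genomics can detect such losses by screening orthologous
loci across species, but each step has failure modes that this package treats
explicitly: orthology must be established (synteny, not just sequence
similarity), apparent lesions can be sequencing or assembly artefacts (hence
validation against raw reads), assembly gaps make loci unscorable rather than
intact, shared lesions must be distinguished from independent ones on the
species tree, and the mutational evidence should be corroborated by the
signature that selection leaves in substitution rates: a pseudogene drifts at
dN/dS (omega) near 1, while a functional gene is held near omega << 1 by
purifying selection.

`geneloss` implements that chain end to end, with a synthetic-data generator
that produces ground-truth loci, reads and trees so that every stage is
testable without downloads. The motivating use case is a single-exon
G-protein-coupled-receptor gene independently eroded in toothed and baleen
whales, and the bundled `cetacea` fixture mirrors that situation: a shared
2-nt deletion in all sampled odontocetes except the sperm whale, a
sperm-whale-private premature stop plus 1-nt insertion, a 1-nt deletion shared
by three of four mysticetes, and one taxon whose locus is 5'-fragmented by
assembly gaps (unscorable, not intact).

# Models and procedures

## Synthetic loci (`simulate_cds_evolution`, `inject_lesions`, `build_locus`, `simulate_reads`)

Coding sequences evolve on a rooted tree under the Goldman–Yang (GY94) codon
model: 61 sense-codon states, instantaneous rate proportional to the target
codon frequency, multiplied by kappa for transitions and omega for
nonsynonymous changes, zero for multi-nucleotide changes, scaled to one
expected substitution per codon per unit branch length. Each branch may carry
its own omega. Evolution is sampled exactly per site from the branch
transition matrix `expm(Q t)` (spectral decomposition via the reversibility
symmetrization), not by event-level simulation — simpler, and sufficient for
testing estimators. Stop codons cannot arise because they are not in the
state space.

Lesions are then injected at deterministic coordinates: indels of 1–2 nt at a
fractional CDS position, and nonsense changes that overwrite the codon at
`floor(frac * n_codons)` with the stop codon reachable by the fewest
substitutions (ties resolved TAA, then TAG, then TGA). Indel truth
coordinates are left-aligned against the reference context (the VCF
convention) so that injected truth and alignment-derived calls share one
coordinate system in repetitive sequence.

A locus embeds the (UTR-flanked) gene between conserved flank genes with
random intergenic spacers, optionally masks intervals with N runs (assembly
gaps), and can be emitted as the reverse complement. Reads have uniform start
positions, substitution-only errors, random orientation, and can be drawn
from a mixture of alleles with *exact* mixture proportions — the mix models a
population allele fraction, not a sampling probability. All randomness flows
from one mandatory seed per call, and the caller's RNG state is restored.

What the generator does **not** emulate: assembly artefacts other than N
runs, quality-score structure, paired-end geometry, context-dependent
mutation, CpG effects, and indel sequencing errors (optional errors are
substitution-only). A green test therefore establishes correctness of the
inference machinery under the stated model, not robustness to every real
assembly pathology.

## Synteny (`best_hit`, `build_synteny_map`, `locate_target_region`)

Neighbor genes are located by affine-gap Smith–Waterman on both strands
(match 2 / mismatch −3 / gap open 5 / gap extend 2 — megablast-like), hits
ranked lexicographically by (query coverage, percent identity), with ties
broken by alignment length, contig name, then coordinate, so the choice is a
total order independent of input order. The candidate region is the interval
between the innermost anchor hits, padded and clipped to the contig; anchors
on different contigs raise a typed error (`synteny_unresolved`) signalling
the fallback to a direct CDS search. Acceptance thresholds (identity >= 70,
coverage >= 50) are permissive defaults for cross-species anchors; the source
procedure states none.

## Annotation (`map_reference_cds`, `call_inactivating_mutations`, `detect_truncation`, `classify_coding_status`)

The UTR-flanked single-exon reference gene is mapped onto the region by
semi-global alignment — reference global, region local, better-scoring
strand — with match 1 / mismatch −2 / gap open 12 / gap extend 3, tolerant of
roughly 20% divergence; N in the region is a zero-score wildcard, so assembly
gaps are uninformative rather than mismatches. A region is "no ortholog" if
aligned CDS coverage < 0.2 *or* identity over aligned CDS columns < 0.55: the
identity floor is needed because a globally-aligned reference reaches full
"coverage" even against unrelated sequence, which still shows ~40–45% column
identity under affine realignment.

Mutation calling emits every CDS indel with length not divisible by 3 as a
frameshift (reference-projected, left-aligned), tracks the running frame
offset, and reports premature stops from two scans whose union is
deduplicated per reference codon: the running (shifted) frame — the actual
reading frame downstream of frameshifts — and reference-frame codon positions
aligned 1:1, which is what alignment screening shows and which recovers a
stop that an upstream frameshift has moved out of the reading frame. Codons
containing N or spanning gaps are never stops; a stop at the reference's
terminal codon is never premature. Frameshift groups whose net offset
returns to 0 mod 3 are flagged `compensated` but still reported.

Truncations are called from sliding-window identity (window 60 nt, step 15):
after any window at or above 70%, the first pair of consecutive windows below
the low threshold marks the breakpoint. The low threshold defaults to 50%,
not lower: affine realignment keeps unrelated sequence near 40–45% identity,
so a 30% floor would never fire. Windows dominated by N are uninformative; a
drop that lies entirely in N windows yields an *inconclusive* flag, not a
truncation. All four knobs are arguments.

Coding status is `inconclusive` when unambiguous (non-N, aligned) CDS
coverage is below 0.9, else `eroded` with at least one mutation (truncations
count), else `intact`. The order matters: fragmentation masks, it does not
exonerate.

## Read validation (`validate_mutation`, `validate_all`)

Instead of mapping plus pileup, each read is aligned to two haplotype
windows — the region as observed (mutant) and the same window with the
reference allele restored (wild type). A read is informative if it spans the
variant with at least half the flank anchored on each side and scores
strictly better on one haplotype. With fewer than `min_reads` (3) informative
reads the verdict is `no_data`; support fraction >= 0.8 confirms, <= 0.2
refutes, and the band between is `polymorphic` — the signature of a loss
allele still segregating in the population. Across independent read sets the
consensus is confirmed only if no set refutes and at least one confirms;
disagreement is flagged. A k-mer prescreen (18-mers tiled every 6 nt from
both windows, both orientations) discards reads that cannot overlap the site;
a read overlapping a window by two-thirds of a k-mer length passes unless
errors hit every tile.

## Loss events (`build_mutation_matrix`, `count_independent_losses`)

Lesions are homologous only on exact (kind, reference coordinate, length)
match — the coordinate-exactness that left-alignment guarantees; a +/-1
tolerance flag exists but is off by default. Taxa with inconclusive status
are *unknown* at lesions falling in their uncovered intervals and are set
aside before monophyly testing — this is what lets a fragmented genome sit
inside a stem event rather than break it. Under Dollo parsimony (a lesion
arises once, never reverts) each lesion is placed on the stem of the maximal
clades whose known leaves are all carriers; a lesion valid at the root is
pushed to the root's child branches, since no branch above the root exists.
Each eroded leaf's inactivation branch is the most basal lesion-bearing
branch on its root path; the event set is the distinct inactivation
branches. On trees of up to six leaves this equals the minimum over an
exhaustive enumeration of Dollo-consistent origin assignments (tested).

## Branch-category selection analysis (`f3x4_frequencies`, `gy94_rate_matrix`, `codon_log_likelihood`, `fit_branch_model`, `lrt_neutral`)

Codon equilibrium frequencies are F3x4: position-specific nucleotide
frequencies over unambiguous characters, codon frequency the product of its
three positional frequencies, stop mass removed, renormalized (zero products
floored at 1e-10 to keep the generator diagonalizable). The log-likelihood is
Felsenstein pruning over the 61 states with per-branch-category transition
matrices; any codon containing a gap, N or `?` — including stop codons
recorded as missing by the translation aligner — is fully ambiguous (all 61
states), so ambiguous sites are included, not dropped. Site patterns are
compressed; per-node scaling prevents underflow; the C++ kernel also returns
analytic derivatives with respect to every branch length.

Fitting is a bounded coordinate cycle: branch lengths jointly by L-BFGS-B
with the analytic gradient (category spectra fixed within the block), then
(kappa, free omegas) by bounded L-BFGS-B on the log scale; cycles repeat
until the log-likelihood improves by less than 1e-6. Bounds: omega in
[1e-4, 10], kappa in [0.1, 20], branch lengths in [1e-6, 50]. Three
deterministic omega starts (0.1, 1, 2) are probed briefly and the best is
polished — multi-start guards against local optima while staying
reproducible. Branch lengths are re-estimated within every fit.

Each category is tested by its own two-ratio design
(`test_branch_category`): all other branches collapse into one background
category; the alternative frees both omegas, the null fixes the focal omega
at 1 with the background omega still free; 2(l_alt − l_null), clamped at 0
against boundary noise, is referred to the chi-squared upper tail with 1
degree of freedom. This per-category two-ratio reading is the conventional
one when seven separate p-values are reported; the null warm-starts from the
alternative's optimum, which both speeds it up and guarantees nesting.

The seven-category cetacean scheme partitions branches into: functional
background (outgroups and backbone), common cetacean stem, crown Mysticeti,
stem Mysticeti, crown Odontoceti, stem Odontoceti excluding the sperm whale,
and the sperm-whale ancestor (terminal) branch. Two placements are not
dictated by the source description and were decided here: the Odontoceti
crown stem belongs to the crown-Odontoceti category, and the sperm-whale
terminal branch belongs to its own category rather than to "Odontoceti
branches" (a partition must assign each branch exactly once).

## Translation alignment (`translation_align`)

Inputs are frame-consistent triplet strings (frameshift indels already
removed by `frame_corrected_cds`, which emits one symbol per reference CDS
position: the aligned base, N under assembly gaps, `?` where deleted).
Sequences are translated (stops become unknown residues), aligned
progressively under BLOSUM62 with affine gaps (open 10, extend 0.5) using a
profile–profile Gotoh DP, guide order from average-linkage clustering of
protein p-distances, and the protein alignment is back-threaded to codons.
Premature and terminal stops enter the codon alignment as `???` (fully
ambiguous), matching the "stop codons recorded as missing" convention. The
guide tree deviates from the original neighbor-joining plan: NJ is undefined
below four taxa and unrooted, while progressive merging needs a rooted order;
average linkage is the standard progressive-aligner choice.

# Numerical and design notes

- Reversible generators are diagonalized via the symmetric similarity
  transform; transition matrices are clamped at 0 against round-off.
- The likelihood kernel's gradient is exact per branch (path recomputation
  with stored per-edge contributions and shared scalers), verified against
  central differences to ~1e-6.
- Coordinates are 0-based half-open inside the synteny module and 1-based
  inclusive in every report; reference-CDS coordinates in mutation tables are
  1-based.
- Verdict thresholds (0.8 confirm, min 3 informative reads) and the
  polymorphic band [0.2, 0.8] are defaults with arguments; the source
  procedure reports only an approximately 50% split for its polymorphic case.
- The pipeline excludes from the selection alignment taxa that are
  inconclusive or truncated: downstream of a truncation the "CDS" is
  unrelated sequence and would inflate nonsynonymous rates.
- Fixture worlds are stated once: 479 sense codons plus terminal stop
  (a 1,440-nt CDS, the size of the motivating receptor gene), kappa 2.5,
  moderately GC-biased F3x4 frequencies, mammal-scale branch lengths
  (0.006–0.11 expected substitutions per codon), strong purifying selection
  (omega 0.08–0.1) while functional, neutral (omega 1) after loss,
  intermediate omegas on stems where loss happened partway.

# Known limitations

- Single-exon gene models only; no splice sites (the motivating gene family
  is single-exon).
- Site- and branch-site models (positive-selection tests) are out of scope;
  only branch models with per-category omega are fitted.
- The read model is quality-blind; genotype likelihoods are not computed.
- Exact reproduction of published omega decimals additionally depends on the
  original optimizer's internals; agreement is expected to about two
  decimals, not bit-exact, and requires the original accession data, which
  this package does not download.
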