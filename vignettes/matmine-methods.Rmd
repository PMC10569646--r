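---
title: "Mining fungal mating genes: models, rules and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining fungal mating genes: models, rules and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matmine)
```

# The problem

Ascomycete sexual strategy (thallism) is written into the genome at the
mating-type (MAT) locus. Heterothallic species carry one of two
dissimilar alternatives (idiomorphs) — MAT1-1, organized around the
alpha-box gene *MAT1-1-1*, or MAT1-2, organized around the HMG-box gene
*MAT1-2-1* — while self-fertile (homothallic) species carry genes of
both, either fused at one locus or interconverted by programmed
mating-type switching. Downstream of the locus, mating is coordinated by
two short peptide pheromones (the alpha-factor and the a-factor) and
their seven-transmembrane receptors (STE2, STE3). None of these
components is reliably annotated by standard genome pipelines: MAT genes
are fast-evolving and intron-rich, pheromone genes are tiny and often
missing from annotation sets altogether.

`matmine` implements the rule-based mining procedures for all of these
components as tested, reusable code, together with a synthetic-genome
generator that plants each structure with known ground truth, so that
every detector can be validated end to end.

# Models and rules

## The a-factor screen

The a-factor precursor is a short (<= 100 aa) protein whose only strictly
conserved feature is a C-terminal prenylation box, CAAX or CPAX (C =
cysteine, A = aliphatic, P = polar, X = any residue). `filter_proteome()`
keeps exactly the annotated proteins with length <= 100 (inclusive) and a
terminal box; `rank_candidates()` then orders candidates by the number of
relative genomes in which a translated six-frame search recovers them
(conservation), breaking ties by supporting evidence — an S/T-rich
N-terminal window and a glycine-tyrosine (GY) motif near the box — then
by length and id, so the ordering is fully deterministic.

The residue classes are configurable. The defaults (aliphatic
\{A,V,L,I,M\}; polar \{S,T,C,N,Q,Y,H,K,R,D,E\}) cover every terminal box
observed among real candidates (CTVM, CVVM, CIVM, CTIL, CSIM, CSVM)
while leaving G, P, W and F in neither class; proline is deliberately not
polar, since no observed box requires it. The S/T window is 20 residues
with a richness verdict at >= 0.30, and the GY window is 15 residues
upstream of the box cysteine; neither number is prescribed by the
screen's description, so both are exposed in the configuration.

## The alpha-factor repeat grammar

The alpha-factor pro-protein is a signal peptide followed by 2–18 copies
of a 9–14 residue mature pheromone, each copy preceded by an STE13
dipeptidyl-aminopeptidase run (XA/XP units) and followed by a KEX1/2
dibasic site (KR, RR or KK). `annotate_repeats()` formalizes the manual
annotation rules:

1. KEX dipeptide hits are merged into cleavage blocks; a repeat ends
   where the next block starts.
2. Each repeat starts immediately after the STE13 run anchored at the end
   of the previous cleavage block. Anchoring matters: XA/XP dipeptides
   occur freely inside mature repeats, but STE13 is an aminopeptidase and
   only trims from a free N-terminus, so runs are only recognized where a
   new N-terminus is created.
3. The first repeat has no upstream cleavage block, so its start is
   back-filled using the modal candidate length (ties resolved toward the
   shorter length) — the length-consistency rule. Candidates longer than
   the mode are trimmed to it; the surplus before the KEX site is linker.
4. Over-long candidates containing an internal STE13 run of at least two
   units are split at those runs; together with a backward walk through
   exact-length STE13-separated repeats upstream of the first block, this
   recovers architectures that rely on STE13 processing in place of
   missing KEX sites.
5. Repeats outside 9–14 aa are flagged, never dropped: real pro-pheromones
   reach both extremes.

The architecture class follows from the parse: `typical` (>= 2 repeats,
all KEX-released), `ste13_dominant` (some repeats released by STE13
runs), `atypical_single_repeat` (exactly one repeat and no KEX site
anywhere), else `unparseable`. A protein with a single KEX-flanked repeat
matches no described architecture and is reported unparseable. An
optional GQ-anchored fallback (off by default) windows putative repeats
on the beta-turn dipeptide when the grammar finds nothing; it annotates
but never classifies.

`scan_intergenic_for_alpha()` applies the grammar to every ORF of a
microsynteny window. Short random ORFs can satisfy the grammar by chance
(a 40-aa random protein avoids KEX dipeptides with probability ~0.74 and
almost surely contains an XA/XP singleton), so scanned candidates must
additionally look like pheromones: at least two in-range repeats, or —
for the single-repeat atypical architecture — a detected signal peptide
and a GQ beta-turn, mirroring the described atypical anatomy.

## Homology search

`search_genome()` is a translated search: each contig is translated in
all six frames, every stop-free segment is aligned to the query by
Smith–Waterman with affine gaps (BLOSUM62, gap open 11 / extend 1), and
hits are mapped back to forward-strand DNA coordinates, so hits never
cross frame stops. Significance uses a Karlin–Altschul approximation
with precomputed BLOSUM62 gapped constants (lambda = 0.267, K = 0.041)
and the conventional acceptance threshold E <= 0.05. There is no seeding
heuristic: the full dynamic program runs per segment, which is exact and
entirely adequate for desk-scale genomes (hundreds of kb). Reproducing
any specific BLAST implementation's bit scores is a non-goal; the
threshold semantics are what is preserved.

## MAT locus assembly and the thallism cascade

`locate_mat_locus()` searches a genome with reference MAT proteins plus
the APN2/SLA2 anchors that conventionally flank the Pezizomycotina MAT
locus, groups hits into loci (gaps > 2 kb separate loci), and assigns
each reference a status from its covered fraction: a single hit covering
>= 0.9 is `intact`; >= 0.9 only in interrupted pieces is `pseudogenised`;
0.5–0.9 with an end-biased hit is a 5' or 3' truncation; < 0.5 is a
`fragment`. These thresholds are package choices — the verbal
distinctions they implement carry no published numbers. Hits also need
>= 50% alignment identity to count as locus evidence: the E <= 0.05
cutoff is a per-search expectation and admits occasional chance
alignments at desk-scale search spaces, and the identity floor plays the
role of the curation step that dismisses such hits (true MAT homologs
from related references align far above it).

`classify_thallism()` then applies a decision cascade: (1) an intact
*MAT1-1-3* as the only MAT1-1 gene with no trace of *MAT1-1-1* and no
MAT1-2 genes is the HMG-only strategy seen in *Lachnellula*; (2) intact
genes from exactly one idiomorph mean heterothallism — crucially,
fragments of the opposite idiomorph do not count, since heterothallic
idiomorphs commonly embed fragments of the other (otherwise every
*Botrytis*-like idiomorph would misclassify as homothallic); (3) both
idiomorphs at one locus with *MAT1-1-1* fragments flanking the MAT1-2
genes and an identical inverted repeat pair is switching by inversion; a
direct pair is switching by deletion; otherwise intact principal genes
mean primary homothallism; (4) both idiomorphs intact on separate loci is
a possible mixed culture; (5) anything else — truncated principal genes,
fragmented multi-contig loci — is left undetermined, deliberately: no
call is guessed.

`detect_repeat_pairs()` finds the switching signature itself: all maximal
pairs of identical substrings >= 100 bp in direct or inverted
orientation, by exact k-mer matching with diagonal merging (the described
switching repeats are identical 250-bp copies; approximate matching is
reserved, not implemented).

## Receptor QC

`qc_receptor()` translates a ste2/ste3 gene model and applies, in order:
absent gene -> deleted; untranslatable model -> unannotatable; internal
stop -> premature stop; CDS under half the reference length -> truncated;
otherwise transmembrane helices are counted by Kyte–Doolittle sliding
windows (window 19, threshold 1.6, minimum run 15 centres, gaps <= 3
bridged) and exactly seven means intact. Hydropathy counting replaces
profile-HMM domain search on purpose: it is dependency-free and exact on
the synthetic constructs the package validates against, but its counts
on real receptors need not match any external predictor's.

## Ancestral thallism (Mk2)

Thallism is encoded 0 = homothallic, 1 = heterothallic, ? = unknown, and
evolves on a fixed rooted tree under a two-state continuous-time Markov
chain with rates `q01`, `q10`. The transition matrix has the closed form
`P(t) = Pi + (I - Pi) exp(-(q01+q10) t)`; `mk2_loglik()` runs Felsenstein
pruning with per-node rescaling, unknown tips contributing a flat
partial; `marginal_posteriors()` is the standard inside-outside pass; and
`mcmc_rates()` integrates over rate uncertainty by Metropolis–Hastings
with independent exponential(mean 1) priors and log-normal proposals
(sd 0.5), averaging node posteriors over retained samples. The default
root prior is the stationary distribution of the sampled rates
(configurable to any proper prior). The default chain — 1000 retained
samples at thinning 100, i.e. a 100,000-generation run — matches common
practice for this analysis; the test suite uses shorter chains
(400 x 25 for 64-taxon recovery, 200 x 10 for the 124-taxon cohort),
sizes at which the checks below are already stable.

Note one exact property used in testing: with all tips unknown, node
marginals equal the root prior only when that prior is stationary; under
any other prior the root posterior equals the prior but interior
marginals relax toward stationarity along the branches.

## Expression

`rpkm()` is the classical reads-per-kilobase-per-million normalization,
`count * 1e9 / (library_size * length)`. `mating_dependence()` calls a
gene exclusive to a mating type only when it is on (RPKM >= 1, the
conventional "very low expression" boundary) in at least one pure sample
of that type and off in all observed pure samples of the other type;
mixed-type libraries are excluded, and without samples of the opposite
type exclusivity is never claimed. Verdicts carry the per-type sample
counts so users can judge the support.

# The synthetic cohort: what it emulates, and what it does not

The generator module is first-class code and defines the study
conditions:

* `gen_alpha_gene()` builds grammar-valid pro-pheromones — fixed
  hydrophobic signal, 1–3-unit STE13 spacers, sampled 9–14 aa repeats
  with a GQ or PG beta-turn, KEX sites — reverse-translated with random
  synonymous codons and optionally split by one 50–80 bp GT..AG intron
  (probability 0.5). Planted repeats satisfy the constraints any real
  mature pheromone must: no internal KEX dipeptide (maturation would
  destroy it), termini outside K/R, and no A/P at position 2 (the
  preceding STE13 run would trim into the peptide).
* `gen_afactor_gene()` plants 45–64 aa proteins with a chosen terminal
  box, an S/T-rich prefix and a tail GY motif on demand;
  `gen_afactor_cohort()` shares one such protein across genomes
  (independently reverse-translated, so DNA diverges while the protein is
  conserved) among up to 10 private random CAAX/CPAX decoys per genome.
* `gen_mat_architecture()` lays out ten described locus architectures —
  both heterothallic idiomorphs, the fused homothallic locus, inversion
  and deletion switching with identical 250-bp repeat pairs, the two
  HMG-only idiomorphs, a split two-contig locus, a truncated locus and a
  three-contig fragmented locus — from divergent stand-ins made by
  mutating bundled reference proteins at 20% of sites (homology stays
  detectable but non-identical). The bundled references themselves are
  deterministic random proteins of realistic lengths, clearly labelled
  synthetic; they stand in for a curated reference set without shipping
  third-party sequence data.
* `gen_cohort()` draws a birth-death tree (`ape::rphylo`, birth 1, death
  0.5, depth rescaled to 1.5), evolves thallism under the Mk2 model or
  fixes a requested composition (homothallic taxa marked clade-wise, as
  clustered transitions, plus a set of unknowns), and can emit a
  state-consistent architecture per genome. Background DNA is order-0
  random at 45% GC.

What passing tests on these data do **not** show: recovery from real
assemblies with repetitive DNA, fragmented loci beyond the modelled
cases, non-canonical introns, annotation errors, or receptors whose true
helix count disagrees with hydropathy. The generator plants exactly the
structures the rules describe; the tests certify the rules are
implemented faithfully and are mutually consistent, not that the rules
themselves are complete for every genome.

# Numerical choices and degenerate inputs

Coordinates are 0-based half-open on the forward strand everywhere
inside the package; GFF3 (1-based inclusive) converts only at the I/O
boundary. Translation uses the standard code only; ambiguous codons give
X; a CDS length not divisible by three warns and flags rather than
errors. Alignment tie-breaks are delegated to the single optimal score
(scores, not tracebacks, are the contract; the independent oracle checks
scores). The repeat-length tie-break is mode-then-shorter. MCMC seeds
make chains bit-reproducible; every generator accepts a seed and
restores the global RNG state.

# Validation design

Each detector is tested against an independent oracle: local alignment
against a plain-R Gotoh dynamic program; repeat pairs against a
shift-scan over all offsets; Mk2 marginals against exhaustive state
enumeration over every rooted topology of up to six tips; the two-tip
likelihood against its closed form; and every generator against its own
detector (plant-and-recover round trips: 500 seeded pro-pheromones, 200
seeded screening cohorts, all ten locus architectures, 20 rate-recovery
replicates). `scripts/acceptance.R` re-runs this battery from scratch on
a supplied seed and writes the measured rates as JSON.
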