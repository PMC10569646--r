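# matmine

Rule-based mining of fungal mating genes from genome assemblies:
mating-type (MAT) locus assembly and thallism classification, pheromone
gene discovery, receptor quality control, and ancestral-state
reconstruction of sexual strategy — with a synthetic-genome simulator
that plants every structure the detectors look for.

## Who this is for

Mycologists and comparative genomicists working with ascomycete
assemblies in which the sexual machinery is poorly annotated: MAT genes
are fast-evolving and intron-rich, and the pheromone genes are so short
that annotation pipelines routinely miss them. `matmine` turns the manual
curation rules used to mine these genes into deterministic, tested code.

## What it computes

**Thallism classification.** MAT genes (`MAT1-1-1`, `MAT1-1-3`,
`MAT1-1-5`, `MAT1-1-13`, `MAT1-2-1`, `MAT1-2-10`) are located by
translated six-frame Smith–Waterman search (BLOSUM62, gap 11/1,
E ≤ 0.05), anchored by the APN2/SLA2 genes flanking the locus. A
decision cascade over idiomorph content, gene truncation, identical
repeat pairs and contig layout distinguishes heterothallism (either
idiomorph), primary homothallism, mating-type switching by inversion or
by deletion (both signalled by identical ≥100-bp direct/inverted repeat
pairs, canonically 250 bp), the HMG-only strategy (an intact *MAT1-1-3*
as the sole MAT gene), possible mixed cultures, and undetermined cases.

**α-factor annotation.** The pro-pheromone grammar — signal peptide,
then 2–18 copies of a 9–14 aa mature repeat, each between an STE13 run
(XA/XP units) and a KEX1/2 site (KR/RR/KK) — is parsed by
`annotate_repeats()`, which excises the mature repeats, marks GQ/PG
β-turn dipeptides, and classifies the architecture as typical,
STE13-dominant, atypical single-repeat, or unparseable.

**a-factor screen.** `filter_proteome()` keeps proteins ≤ 100 aa ending
in a CAAX/CPAX prenylation box; `rank_candidates()` orders them by
cross-genome conservation, then by S/T-rich N-terminus and C-terminal GY
motif evidence.

**Receptor QC.** `qc_receptor()` verifies that ste2/ste3 models
translate cleanly and span the membrane exactly seven times
(Kyte–Doolittle hydropathy).

**Ancestral thallism.** A two-state Markov model
(0 = homothallic, 1 = heterothallic, `?` = unknown) on a fixed rooted
tree: exact pruning likelihoods `P(t) = Π + (I − Π)e^{−(q01+q10)t}`,
marginal node posteriors, and a Metropolis–Hastings sampler over the
rates with exponential priors.

**Expression.** `rpkm()` (= count · 10⁹ / (library · length)) and a
mating-type exclusivity test at the RPKM ≥ 1 threshold.

## Worked example

Generate a cohort of genomes with planted MAT architectures, classify
each, and reconstruct the ancestral strategy:

```r
library(matmine)

# one genome with a described switching architecture
arch <- gen_mat_architecture("inversion_switch", seed = 1)
refs <- synthetic_reference_set()
loc  <- locate_mat_locus(arch$genome,
                         refs[!names(refs) %in% c("ste2","ste3","PPG1")])
reps <- detect_repeat_pairs(arch$genome[[1]], min_len = 100)
classify_thallism(loc$genes, reps, loc$split_anchors)
#> <thallism_call> switching_inversion
#>   evidence: MAT1-1-1:fragment(cov=0.44); MAT1-1-1:fragment(cov=0.43);
#>   MAT1-1-5:intact(cov=1.00); MAT1-2-1:intact(cov=1.00);
#>   MAT1-2-10:intact(cov=1.00); APN2:intact(cov=1.00);
#>   SLA2:intact(cov=1.00); repeat_pair:inverted:250bp

# annotate a pro-pheromone
p <- paste0("MKFLSLLALAAVVSA", "DAEA", "WCGRPGQPC", "KR",
            "EAEA", "WCGRPGQPC", "KR")
annotate_repeats(p)
#> <alpha_annotation> protein: typical, 2 repeat(s)
#>   WCGRPGQPC [19,28) beta-turn=GQ
#>   WCGRPGQPC [34,43) beta-turn=GQ

# ancestral state on a 124-taxon cohort (96 heterothallic, 15
# homothallic, 13 unknown)
coh <- gen_cohort(124, seed = 42, n_hom = 15, n_unknown = 13)
m <- mcmc_rates(coh$tree, coh$states, n_samples = 200, thin = 10,
                seed = 7)
m$posterior[paste0("node", 125), ]
#>        P0        P1
#> 0.0255558 0.9744442
```

The root posterior of ~0.97 for state 1 says the cohort's common
ancestor was almost certainly heterothallic — self-sterility is the
ancestral condition and homothallism arose repeatedly within clades.

`run_all()` drives every stage over a manifest of FASTA/GFF3 files and
writes per-genome JSON reports plus cohort TSV summaries; see
`?run_all` and the methods vignette (`vignettes/matmine-methods.Rmd`)
for the full model descriptions.

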