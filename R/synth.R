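# Synthetic genomes, gene models, trees and count tables with planted
# ground truth for every structure the detectors look for. Background
# sequence is order-0 random DNA at 45% GC; planted genes are built by
# reverse-translating proteins with uniformly sampled synonymous codons,
# and MAT-gene stand-ins diverge from the bundled synthetic references by
# point mutations at 20% of sites so that homology remains detectable
# but non-identical.

GENETIC_CODE_BY_AA <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- split(names(Biostrings::GENETIC_CODE),
                                        unname(Biostrings::GENETIC_CODE))
    cache
  }
})

#' Reverse-translate a protein with random synonymous codons
#'
#' @param protein protein string (standard residues; `*` allowed).
#' @return DNA string (no stop appended unless `*` is present).
#' @export
reverse_translate <- function(protein) {
  tab <- GENETIC_CODE_BY_AA()
  cc <- chars(protein)
  bad <- setdiff(cc, names(tab))
  if (length(bad)) stop("cannot reverse-translate residue(s): ",
                        paste(unique(bad), collapse = ", "))
  paste(vapply(cc, function(a) {
    cod <- tab[[a]]
    if (length(cod) == 1L) cod else sample(cod, 1L)
  }, character(1L)), collapse = "")
}

## substitute a fraction of residues with random different residues
mutate_protein <- function(protein, rate = 0.2) {
  cc <- chars(protein)
  idx <- which(runif(length(cc)) < rate)
  for (i in idx) cc[i] <- sample(setdiff(AA_STANDARD, cc[i]), 1L)
  paste(cc, collapse = "")
}

## hydrophobic signal peptide used by generated pro-pheromones; contains
## no dibasic (KEX) site
ALPHA_SIGNAL <- "MKFLSLLALAAVVSA"

## sample one mature-repeat sequence compatible with unambiguous
## processing-site annotation: no internal KEX dipeptide, termini outside
## {K, R} (which would extend a cleavage block into the repeat), and no
## A/P at position 2 (which would let the preceding STE13 run eat the
## first two residues of the repeat)
sample_mature_repeat <- function(len = NULL, beta = NULL) {
  len <- len %||% sample(9:14, 1L)
  stopifnot(len >= 4L)
  beta <- beta %||% sample(c("GQ", "PG"), 1L)
  repeat {
    cc <- sample(AA_STANDARD, len, replace = TRUE)
    pos <- sample(3:(len - 3L), 1L)
    cc[pos:(pos + 1L)] <- chars(beta)
    rep_seq <- paste(cc, collapse = "")
    if (repeat_is_annotatable(rep_seq)) return(rep_seq)
  }
}

## the constraints a planted mature repeat must satisfy (mature
## pheromones cannot contain processing sites, or maturation would
## destroy them)
repeat_is_annotatable <- function(rep_seq) {
  cc <- chars(rep_seq)
  n <- length(cc)
  di <- paste0(cc[-n], cc[-1L])
  if (any(di %in% c("KR", "RR", "KK"))) return(FALSE)
  if (cc[1L] %in% c("K", "R") || cc[n] %in% c("K", "R")) return(FALSE)
  if (cc[2L] %in% c("A", "P")) return(FALSE)
  TRUE
}

## an STE13 spacer run of n_units X[AP] dipeptides, X outside {K, R}
sample_ste13_run <- function(n_units = NULL) {
  n_units <- n_units %||% sample(1:3, 1L)
  paste(vapply(seq_len(n_units), function(i)
    paste0(sample(setdiff(AA_STANDARD, c("K", "R")), 1L),
           sample(c("A", "P"), 1L)), character(1L)), collapse = "")
}

## insert a spliceosomal intron (GT..AG, 50-80 bp) at a random interior
## position of a CDS; returns list(dna, exons) with exons relative to
## the gene start, 0-based half-open
insert_intron <- function(cds, len = NULL) {
  len <- len %||% sample(50:80, 1L)
  core <- rand_dna(len - 4L)
  intron <- paste0("GT", core, "AG")
  at <- sample(seq(3L, nchar(cds) - 3L), 1L)
  list(dna = paste0(substr(cds, 1L, at), intron,
                    substr(cds, at + 1L, nchar(cds))),
       exons = rbind(c(0L, at), c(at + len, nchar(cds) + len)))
}

#' Generate an alpha-factor pro-pheromone gene with planted truth
#'
#' Builds a grammar-valid pro-protein — hydrophobic signal peptide, then
#' `n_repeats` copies of the mature repeat, each preceded by an STE13
#' spacer run and followed by a KEX1/2 site — reverse-translates it, and
#' optionally splits the CDS with one spliceosomal intron.
#'
#' @param repeat_seq mature repeat (9-14 aa); sampled when `NULL`. A
#'   supplied repeat must satisfy the annotatability constraints (no
#'   internal KEX site, termini outside K/R, no A/P at position 2).
#' @param n_repeats number of mature repeat copies (>= 1).
#' @param intron `TRUE`, `FALSE`, or `NULL` (insert with probability 0.5).
#' @param flank random flanking DNA on each side of the gene (bp).
#' @param seed optional integer seed (global RNG state is restored).
#' @return list with `contig` (DNA), `gene` (a [gene_model]), `protein`,
#'   and `truth` (`repeat_seq`, `n_repeats`, `klass`).
#' @export
gen_alpha_gene <- function(repeat_seq = NULL, n_repeats = 3L,
                           intron = NULL, flank = 200L, seed = NULL) {
  if (n_repeats < 1L) stop("n_repeats must be at least 1")
  run <- function() {
    rep_seq <- repeat_seq %||% sample_mature_repeat()
    if (!repeat_is_annotatable(rep_seq))
      stop("supplied repeat violates the annotatability constraints")
    parts <- ALPHA_SIGNAL
    for (i in seq_len(n_repeats))
      parts <- c(parts, sample_ste13_run(), rep_seq,
                 sample(c("KR", "RR", "KK"), 1L))
    protein <- paste(parts, collapse = "")
    cds <- paste0(reverse_translate(protein),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    use_intron <- intron %||% (runif(1L) < 0.5)
    if (use_intron) {
      sp <- insert_intron(cds)
      gene_dna <- sp$dna
      exons <- sp$exons
    } else {
      gene_dna <- cds
      exons <- rbind(c(0L, nchar(cds)))
    }
    left <- rand_dna(flank)
    contig <- paste0(left, gene_dna, rand_dna(flank))
    gene <- gene_model("alpha1", "ctg_alpha", "+", exons + flank,
                       tag = "alpha_pheromone")
    list(contig = contig, gene = gene, protein = protein,
         truth = list(repeat_seq = rep_seq, n_repeats = n_repeats,
                      klass = if (n_repeats >= 2L) "typical" else
                        "unparseable"))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

AFACTOR_BOXES <- c("CTVM", "CVVM", "CIVM", "CTIL", "CSIM", "CSVM")

#' Generate an a-factor pheromone gene with planted truth
#'
#' A short protein (45-64 aa by default) ending in a CAAX/CPAX box, with
#' an S/T-rich N-terminal window and a GY motif near the C-terminus when
#' requested.
#'
#' @param length_aa protein length (>= 15).
#' @param box terminal 4-mer; one of CTVM, CVVM, CIVM, CTIL, CSIM, CSVM
#'   (or any 4-mer passing [terminal_caax_class()]).
#' @param st_rich plant an S/T-rich N-terminal window (fraction >= 0.3)?
#' @param gy plant a GY motif within 15 residues of the box cysteine?
#' @param seed optional integer seed.
#' @return list with `protein`, `dna` (CDS + stop), and `truth`.
#' @export
gen_afactor_gene <- function(length_aa = NULL, box = "CTVM",
                             st_rich = TRUE, gy = TRUE, seed = NULL) {
  run <- function() {
    len <- length_aa %||% sample(45:64, 1L)
    if (len < 15L) stop("length_aa must be at least 15")
    if (terminal_caax_class(paste0("XXXX", box)) == "none")
      stop("'", box, "' is not a valid CAAX/CPAX box")
    repeat {
      pre_n <- min(19L, len - 10L)
      prefix <- if (st_rich)
        sample(c("S", "T", AA_STANDARD), pre_n, replace = TRUE,
               prob = c(6, 6, rep(1, 20)) / 32) else
        sample(AA_STANDARD, pre_n, replace = TRUE)
      mid_n <- len - 1L - pre_n - 9L
      mid <- sample(AA_STANDARD, max(0L, mid_n), replace = TRUE)
      tail9 <- if (gy)
        c("G", "Y", sample(AA_STANDARD, 3L, replace = TRUE), chars(box))
      else c(sample(AA_STANDARD, 5L, replace = TRUE), chars(box))
      protein <- paste(c("M", prefix, mid, tail9), collapse = "")
      stf <- st_fraction(protein, 20L)
      gy_hit <- find_gy_motif(protein, 15L)
      ok <- nchar(protein) == len &&
        (if (st_rich) stf >= 0.30 else stf < 0.30) &&
        (if (gy) !is.null(gy_hit) else is.null(gy_hit))
      if (ok) break
    }
    list(protein = protein,
         dna = paste0(reverse_translate(protein),
                      sample(c("TAA", "TAG", "TGA"), 1L)),
         truth = list(length_aa = len, box = box, st_rich = st_rich,
                      gy = gy))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

## a decoy: short random protein ending in a valid box (private to one
## genome; carries no designed S/T or GY evidence)
gen_decoy_caax <- function(length_aa = NULL) {
  len <- length_aa %||% sample(20:100, 1L)
  paste(c(sample(AA_STANDARD, len - 4L, replace = TRUE),
          chars(sample(AFACTOR_BOXES, 1L))), collapse = "")
}

HYDROPHILIC <- c("D", "E", "K", "R", "S", "T", "N", "Q", "G")
## helix pool weighted toward the strongest hydropathy residues so that
## every sampled 25-mer stays above the detection threshold
HYDROPHOBIC <- c("L", "I", "V", "F")
HYDROPHOBIC_W <- c(0.35, 0.30, 0.30, 0.05)

#' Generate a synthetic seven-transmembrane receptor construct
#'
#' Alternating strongly hydrophobic 25-residue helices and charged
#' 15-residue loops, flanked by hydrophilic termini, so that the default
#' hydropathy settings recover exactly `n_tm` transmembrane segments.
#'
#' @param n_tm number of transmembrane helices.
#' @param premature_stop insert an in-frame stop mid-protein?
#' @param seed optional integer seed.
#' @return list with `protein`, `dna` (CDS + stop), and `truth`.
#' @export
gen_receptor_construct <- function(n_tm = 7L, premature_stop = FALSE,
                                   seed = NULL) {
  run <- function() {
    seg <- function(n, pool, w = NULL)
      paste(sample(pool, n, replace = TRUE, prob = w), collapse = "")
    parts <- c("M", seg(24L, HYDROPHILIC))
    for (i in seq_len(n_tm)) {
      parts <- c(parts, seg(25L, HYDROPHOBIC, HYDROPHOBIC_W))
      if (i < n_tm) parts <- c(parts, seg(15L, HYDROPHILIC))
    }
    parts <- c(parts, seg(25L, HYDROPHILIC))
    protein <- paste(parts, collapse = "")
    if (premature_stop) {
      at <- nchar(protein) %/% 2L
      protein <- paste0(substr(protein, 1L, at), "*",
                        substr(protein, at + 2L, nchar(protein)))
    }
    list(protein = protein,
         dna = paste0(reverse_translate(protein), "TAA"),
         truth = list(n_tm = n_tm, premature_stop = premature_stop))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Bundled synthetic reference proteins
#'
#' A deterministic, clearly synthetic stand-in for a curated reference
#' protein set: random proteins of realistic lengths for the MAT genes
#' and the APN2/SLA2 anchors, hydropathy-valid constructs for the STE2
#' and STE3 receptors, and a grammar-valid alpha-factor pro-pheromone
#' (PPG1). Planted genes in the synthetic genomes are divergent copies
#' of these references, so the same set drives the homology searches.
#'
#' @return named character vector of proteins.
#' @export
synthetic_reference_set <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cache <<- with_seed(190823L, {
      lens <- c(`MAT1-1-1` = 370L, `MAT1-1-3` = 240L, `MAT1-1-5` = 200L,
                `MAT1-1-13` = 90L, `MAT1-2-1` = 300L,
                `MAT1-2-10` = 160L, APN2 = 400L, SLA2 = 450L)
      refs <- vapply(lens, rand_protein, character(1L))
      refs[["ste2"]] <- gen_receptor_construct(7L)$protein
      refs[["ste3"]] <- gen_receptor_construct(7L)$protein
      refs[["PPG1"]] <- gen_alpha_gene("WCGRPGQPC", 3L,
                                       intron = FALSE)$protein
      refs
    })
    cache
  }
})

MAT_ARCHITECTURES <- c("het_MAT1_1", "het_MAT1_2", "fused_homothallic",
                       "inversion_switch", "deletion_switch",
                       "lachnellula_MAT1_1", "lachnellula_MAT1_2",
                       "split_mixed", "truncated_undetermined",
                       "sborealis_fragmented")

ARCHITECTURE_STRATEGY <- c(
  het_MAT1_1 = "heterothallic_MAT1_1",
  het_MAT1_2 = "heterothallic_MAT1_2",
  fused_homothallic = "primary_homothallic",
  inversion_switch = "switching_inversion",
  deletion_switch = "switching_deletion",
  lachnellula_MAT1_1 = "lachnellula_HMG_only",
  lachnellula_MAT1_2 = "heterothallic_MAT1_2",
  split_mixed = "possible_mixed_culture",
  truncated_undetermined = "undetermined",
  sborealis_fragmented = "undetermined")

## divergent coding DNA for a reference protein (or a fragment of it)
standin_dna <- function(ref, from = 0, to = 1, rate = 0.2) {
  n <- nchar(ref)
  part <- substr(ref, floor(from * n) + 1L, floor(to * n))
  paste0(reverse_translate(mutate_protein(part, rate)), "TAA")
}

#' Generate a MAT-locus architecture with planted truth
#'
#' Builds the contig(s) of one named MAT-locus architecture: APN2/SLA2
#' anchors plus divergent stand-ins of the reference MAT proteins
#' arranged as in the corresponding described locus; switching
#' architectures embed identical 250-bp direct or inverted repeats, and
#' fragmented architectures plant partial genes.
#'
#' @param name one of `het_MAT1_1`, `het_MAT1_2`, `fused_homothallic`,
#'   `inversion_switch`, `deletion_switch`, `lachnellula_MAT1_1`,
#'   `lachnellula_MAT1_2`, `split_mixed`, `truncated_undetermined`,
#'   `sborealis_fragmented`.
#' @param seed optional integer seed.
#' @param refs reference proteins (default [synthetic_reference_set()]).
#' @param repeat_len switching repeat length (default 250 bp).
#' @return list with `genome` (named character vector of contigs),
#'   `truth` (architecture name, expected strategy, planted parts).
#' @export
gen_mat_architecture <- function(name, seed = NULL,
                                 refs = synthetic_reference_set(),
                                 repeat_len = 250L) {
  if (!name %in% MAT_ARCHITECTURES)
    stop("unknown architecture '", name, "'; valid names: ",
         paste(MAT_ARCHITECTURES, collapse = ", "))
  run <- function() {
    spacer <- function() rand_dna(sample(550:800, 1L))
    R <- rand_dna(repeat_len)
    piece <- function(nm, from = 0, to = 1)
      list(name = nm, dna = standin_dna(refs[[nm]], from, to))
    raw <- function(dna) list(name = NA_character_, dna = dna)
    assemble <- function(parts) {
      dna <- rand_dna(500L)
      placed <- list()
      for (p in parts) {
        if (!is.na(p$name))
          placed[[length(placed) + 1L]] <-
            list(name = p$name, start = nchar(dna),
                 end = nchar(dna) + nchar(p$dna))
        dna <- paste0(dna, p$dna, spacer())
      }
      list(dna = paste0(dna, rand_dna(500L)), placed = placed)
    }
    layouts <- switch(
      name,
      het_MAT1_1 = list(ctg1 = list(
        piece("APN2"), piece("MAT1-1-1"), piece("MAT1-1-5"),
        piece("MAT1-2-1", 0.7, 1), piece("SLA2"))),
      het_MAT1_2 = list(ctg1 = list(
        piece("APN2"), piece("MAT1-2-1"), piece("MAT1-2-10"),
        piece("SLA2"))),
      fused_homothallic = list(ctg1 = list(
        piece("APN2"), piece("MAT1-1-1"), piece("MAT1-1-3"),
        piece("MAT1-2-1"), piece("SLA2"))),
      inversion_switch = list(ctg1 = list(
        piece("APN2"), piece("MAT1-1-5"),
        raw(paste0(standin_dna(refs[["MAT1-1-1"]], 0, 0.45), R)),
        piece("MAT1-2-1"), piece("MAT1-2-10"),
        raw(paste0(revcomp(R),
                   standin_dna(refs[["MAT1-1-1"]], 0.55, 1))),
        piece("SLA2"))),
      deletion_switch = list(ctg1 = list(
        piece("APN2"), piece("MAT1-1-1"), raw(R), piece("MAT1-2-1"),
        piece("MAT1-2-10"), raw(R), piece("SLA2"))),
      lachnellula_MAT1_1 = list(ctg1 = list(
        piece("APN2"), piece("MAT1-1-3"), piece("SLA2"))),
      lachnellula_MAT1_2 = list(ctg1 = list(
        piece("APN2"), piece("MAT1-2-1"), piece("SLA2"))),
      split_mixed = list(
        ctg1 = list(piece("APN2"), piece("MAT1-1-1"),
                    piece("MAT1-1-3"), piece("SLA2")),
        ctg2 = list(piece("MAT1-2-1"))),
      truncated_undetermined = list(ctg1 = list(
        piece("APN2"), piece("MAT1-1-1", 0, 0.6),
        piece("MAT1-2-1", 0.4, 1), piece("SLA2"))),
      sborealis_fragmented = list(
        ctg1 = list(piece("APN2"), piece("MAT1-1-1", 0, 0.4)),
        ctg2 = list(piece("MAT1-2-1", 0.6, 1),
                    piece("MAT1-2-10", 0, 0.4)),
        ctg3 = list(piece("MAT1-1-3", 0, 0.45), piece("SLA2"))))
    genome <- character(0)
    placed <- list()
    for (ctg in names(layouts)) {
      asm <- assemble(layouts[[ctg]])
      genome[[ctg]] <- asm$dna
      for (p in asm$placed) placed[[length(placed) + 1L]] <-
          c(list(contig = ctg), p)
    }
    ## the inversion-switch MAT-1-1-1 fragments must fall in separate
    ## locus groups; the intervening MAT1-2 genes ensure > 2 kb spacing
    list(genome = genome,
         truth = list(architecture = name,
                      expected_strategy =
                        unname(ARCHITECTURE_STRATEGY[[name]]),
                      placed = placed,
                      repeat_len = if (name %in% c("inversion_switch",
                                                   "deletion_switch"))
                        repeat_len else NA_integer_))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate an a-factor screening cohort
#'
#' One focal genome plus relatives. A single planted a-factor protein is
#' shared by every genome (reverse-translated independently, so the DNA
#' differs but the protein is conserved); each genome additionally
#' carries its own private CAAX/CPAX decoy ORFs. The focal genome's
#' annotated proteome (planted gene + decoys) is returned for screening.
#'
#' @param n_genomes total genomes including the focal one (>= 2).
#' @param n_decoys private decoy ORFs per genome.
#' @param seed optional integer seed.
#' @return list with `proteome` (named proteins of the focal genome),
#'   `relatives` (list of genomes: named contig vectors), and `truth`
#'   (`planted_id`, `protein`).
#' @export
gen_afactor_cohort <- function(n_genomes = 5L, n_decoys = 10L,
                               seed = NULL) {
  stopifnot(n_genomes >= 2L)
  run <- function() {
    af <- gen_afactor_gene()
    make_genome <- function(gid) {
      decoys <- if (n_decoys > 0L)
        vapply(seq_len(n_decoys), function(i) gen_decoy_caax(),
               character(1L)) else character(0)
      parts <- c(paste0(reverse_translate(af$protein), "TAA"),
                 vapply(decoys, function(p)
                   paste0(reverse_translate(p), "TAA"), character(1L)))
      dna <- rand_dna(150L)
      for (p in parts) dna <- paste0(dna, p, rand_dna(150L))
      list(genome = setNames(paste0("", dna), paste0(gid, "_ctg1")),
           decoys = decoys)
    }
    focal <- make_genome("g1")
    relatives <- lapply(seq_len(n_genomes - 1L) + 1L, function(i)
      make_genome(paste0("g", i))$genome)
    names(relatives) <- paste0("g", seq_len(n_genomes - 1L) + 1L)
    proteome <- c(setNames(af$protein, "afactor_planted"),
                  setNames(focal$decoys,
                           sprintf("decoy_%02d", seq_along(focal$decoys))))
    list(proteome = proteome, relatives = relatives,
         truth = list(planted_id = "afactor_planted",
                      protein = af$protein))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a full study cohort: tree, thallism states, genomes
#'
#' A birth-death tree over `n_genomes` taxa with per-taxon thallism
#' states either simulated under the two-state Markov model or fixed to
#' a requested composition (`n_hom` homothallic taxa clustered in a few
#' clades and `n_unknown` unknowns, the remainder heterothallic —
#' mirroring the clade-clustered homothallism seen in real cohorts).
#' Optionally, a MAT-locus architecture consistent with each taxon's
#' state is generated per genome.
#'
#' @param n_genomes number of taxa (>= 2).
#' @param seed optional integer seed.
#' @param n_hom,n_unknown fixed-state composition; both `NULL` simulates
#'   states under the Mk2 model instead.
#' @param q01,q10 simulation rates when states are simulated.
#' @param with_genomes also generate per-genome MAT architectures
#'   (slower)?
#' @return list with `tree` (phylo), `states` (named vector of
#'   0/1/?), `genomes` (when requested: named list with `genome` and
#'   `truth` per taxon), and `truth` (state counts, architectures).
#' @export
gen_cohort <- function(n_genomes, seed = NULL, n_hom = NULL,
                       n_unknown = NULL, q01 = 0.3, q10 = 0.3,
                       with_genomes = FALSE) {
  stopifnot(n_genomes >= 2L)
  run <- function() {
    tree <- ape::rphylo(n_genomes, birth = 1, death = 0.5)
    tree$edge.length <- tree$edge.length * 1.5 /
      max(ape::node.depth.edgelength(tree))
    tree$tip.label <- sprintf("t%03d", seq_len(n_genomes))
    if (is.null(n_hom) && is.null(n_unknown)) {
      sim <- simulate_mk2(tree, q01, q10)
      states <- as.character(sim$tips)
      names(states) <- names(sim$tips)
    } else {
      n_hom <- n_hom %||% 0L
      n_unknown <- n_unknown %||% 0L
      stopifnot(n_hom + n_unknown <= n_genomes)
      states <- setNames(rep("1", n_genomes), tree$tip.label)
      ## mark whole small clades homothallic until the quota is met
      ntip <- ape::Ntip(tree)
      remaining <- n_hom
      internal <- sample((ntip + 1L):(ntip + tree$Nnode))
      for (nd in internal) {
        if (remaining <= 0L) break
        tips_in <- ape::extract.clade(tree, nd)$tip.label
        if (length(tips_in) <= min(remaining, 8L) &&
            all(states[tips_in] == "1")) {
          states[tips_in] <- "0"
          remaining <- remaining - length(tips_in)
        }
      }
      if (remaining > 0L) {
        pool <- names(states)[states == "1"]
        states[sample(pool, remaining)] <- "0"
      }
      pool <- names(states)[states == "1"]
      if (n_unknown > 0L) states[sample(pool, n_unknown)] <- "?"
    }
    genomes <- NULL
    archs <- setNames(rep(NA_character_, n_genomes), tree$tip.label)
    if (with_genomes) {
      genomes <- list()
      for (tx in tree$tip.label) {
        arch <- switch(states[[tx]],
          "1" = sample(c("het_MAT1_1", "het_MAT1_2"), 1L),
          "0" = sample(c("fused_homothallic", "inversion_switch",
                         "deletion_switch"), 1L),
          "?" = sample(c("truncated_undetermined",
                         "sborealis_fragmented"), 1L))
        archs[[tx]] <- arch
        g <- gen_mat_architecture(arch)
        names(g$genome) <- paste0(tx, "_", names(g$genome))
        genomes[[tx]] <- g
      }
    }
    list(tree = tree, states = states, genomes = genomes,
         truth = list(
           n_heterothallic = sum(states == "1"),
           n_homothallic = sum(states == "0"),
           n_unknown = sum(states == "?"),
           architectures = archs))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
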