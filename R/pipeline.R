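# Pipeline orchestration: a single configuration object and a run_all()
# driver that executes every stage over a cohort manifest and writes the
# per-genome and cross-genome reports. Each stage is an exported
# function, so any step can be re-run on its own files.

#' Pipeline configuration
#'
#' Collects every tunable threshold with its default. Unknown settings
#' are rejected.
#'
#' @param ... overrides of the defaults.
#' @return list of settings.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    max_len = 100L,            # a-factor screen length bound (aa)
    st_min = 0.30,             # S/T-richness verdict threshold
    alpha = alpha_config(),    # repeat grammar bounds (9-14 aa)
    mat = mat_params(),        # locus coverage / repeat thresholds
    search = search_params(),  # BLOSUM62 11/1, E <= 0.05
    rpkm_threshold = 1.0,      # expression on/off (RPKM)
    rank_afactor = TRUE,       # cross-genome conservation ranking
    references = NULL,         # named protein vector; NULL = bundled
    asr_samples = 200L,        # retained MCMC samples in run_all
    asr_thin = 10L,            # generations between samples
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the full pipeline over a cohort manifest
#'
#' For each genome: MAT-locus location, repeat-pair detection and
#' thallism classification; translation of annotated genes; the a-factor
#' screen (ranked against the other genomes of the manifest); alpha
#' pheromone annotation of tagged genes; receptor QC of tagged ste2/ste3
#' models; RPKM summaries when counts are supplied. When a tree and
#' states file are supplied, ancestral thallism is reconstructed over
#' the cohort. Reports are written under `out_dir`: one JSON per genome
#' plus cohort TSVs.
#'
#' @param manifest data.frame with columns `genome_id`, `fasta`, and
#'   optionally `gff`, `counts`, `samples` (NA when absent).
#' @param out_dir output directory (created if needed).
#' @param config see [pipeline_config()].
#' @param tree_path,states_path optional Newick tree and states TSV for
#'   the ancestral-state stage.
#' @return invisibly, a list with the cohort summary tables.
#' @export
run_all <- function(manifest, out_dir, config = pipeline_config(),
                    tree_path = NULL, states_path = NULL) {
  if (!is.data.frame(manifest) || !nrow(manifest))
    stop("manifest must be a non-empty data.frame")
  if (!all(c("genome_id", "fasta") %in% names(manifest)))
    stop("manifest needs genome_id and fasta columns")
  for (i in seq_len(nrow(manifest)))
    if (!file.exists(manifest$fasta[i]))
      stop("manifest line ", i, ": missing fasta ", manifest$fasta[i])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  refs <- config$references %||% synthetic_reference_set()
  mat_refs <- refs[names(refs) %in% c(MAT_TAGS, "APN2", "SLA2")]

  genomes <- list()
  annots <- list()
  for (i in seq_len(nrow(manifest))) {
    gid <- manifest$genome_id[i]
    genomes[[gid]] <- read_fasta(manifest$fasta[i], "dna")
    gff <- if ("gff" %in% names(manifest)) manifest$gff[i] else NA
    annots[[gid]] <- if (!is.na(gff)) {
      if (!file.exists(gff))
        stop("manifest line ", i, ": missing gff ", gff)
      read_gff3(gff, contigs = names(genomes[[gid]]))
    } else list()
  }

  thallism <- list()
  afactor_tabs <- list()
  alpha_anns <- list()
  receptor_calls <- list()
  for (gid in names(genomes)) {
    genome <- genomes[[gid]]
    ## MAT locus and thallism
    locus <- locate_mat_locus(genome, mat_refs, config$mat)
    hit_ctgs <- unique(stats::na.omit(locus$genes$contig))
    reps <- do.call(rbind, lapply(hit_ctgs, function(ctg)
      detect_repeat_pairs(genome[[ctg]], config$mat$repeat_len_min)))
    if (is.null(reps)) reps <- detect_repeat_pairs("", 100L)
    call <- classify_thallism(locus$genes, reps, locus$split_anchors)
    thallism[[gid]] <- call
    write_locus_json(gid, locus, reps, call,
                     file.path(out_dir, paste0(gid, "_mat.json")))
    ## translated proteome of annotated genes
    genes <- annots[[gid]]
    proteome <- vapply(genes, function(g) {
      p <- suppressWarnings(extract_cds_and_translate(genome, g))
      gsub("*", "", as.character(p), fixed = TRUE)
    }, character(1L))
    ## a-factor screen
    cand <- filter_proteome(proteome, max_len = config$max_len)
    if (nrow(cand) && config$rank_afactor && length(genomes) > 1L)
      cand <- rank_candidates(cand, genomes[names(genomes) != gid],
                              params = config$search,
                              st_min = config$st_min)
    afactor_tabs[[gid]] <- cand
    ## alpha pheromone annotation of tagged genes
    tags <- vapply(genes, `[[`, "", "tag")
    for (g in genes[tags == "alpha_pheromone"])
      alpha_anns[[paste0(gid, ":", g$gene_id)]] <-
        annotate_repeats(proteome[[g$gene_id]], config$alpha,
                         protein_id = paste0(gid, ":", g$gene_id))
    ## receptor QC
    for (g in genes[tags %in% c("ste2", "ste3")]) {
      rec <- toupper(g$tag)
      receptor_calls[[paste0(gid, ":", g$gene_id)]] <-
        qc_receptor(g, genome, rec,
                    ref_len = nchar(refs[[tolower(rec)]]))
    }
    ## expression
    cts <- if ("counts" %in% names(manifest))
      manifest$counts[match(gid, manifest$genome_id)] else NA
    if (!is.na(cts)) {
      smp <- manifest$samples[match(gid, manifest$genome_id)]
      ct <- read_count_table(cts, smp)
      write_rpkm_tsv(ct, file.path(out_dir, paste0(gid, "_rpkm.tsv")))
    }
  }

  thallism_tab <- data.frame(
    genome = names(thallism),
    strategy = vapply(thallism, `[[`, "", "strategy"),
    stringsAsFactors = FALSE, row.names = NULL)
  write.table(thallism_tab, file.path(out_dir, "thallism_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  if (length(alpha_anns)) {
    write_alpha_tsv(alpha_anns, file.path(out_dir, "alpha_summary.tsv"))
    sharing <- repeat_sharing_matrix(alpha_anns)
  } else sharing <- NULL

  afac <- do.call(rbind, lapply(names(afactor_tabs), function(gid) {
    t <- afactor_tabs[[gid]]
    if (!nrow(t)) return(NULL)
    cbind(genome = gid, t[, setdiff(names(t), "sequence"),
                          drop = FALSE])
  }))
  if (!is.null(afac))
    write.table(afac, file.path(out_dir, "afactor_candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  if (length(receptor_calls)) {
    rt <- receptor_table(receptor_calls)
    write.table(rt, file.path(out_dir, "receptor_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else rt <- NULL

  asr <- NULL
  if (!is.null(tree_path)) {
    if (is.null(states_path))
      stop("states_path is required with tree_path")
    tree <- ape::read.tree(tree_path)
    states <- read_states_tsv(states_path)
    asr <- mcmc_rates(tree, states, n_samples = config$asr_samples,
                      thin = config$asr_thin, seed = config$seed)
    write_posteriors_tsv(asr$posterior,
                         file.path(out_dir, "asr_posteriors.tsv"))
  }

  invisible(list(thallism = thallism_tab, afactor = afac,
                 alpha = alpha_anns, alpha_sharing = sharing,
                 receptors = rt, asr = asr))
}
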