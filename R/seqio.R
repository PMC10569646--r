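# FASTA/GFF3 input-output and coding-sequence translation.
#
# Internal coordinate convention: 0-based half-open intervals on the
# forward strand of each contig. GFF3 (1-based inclusive) is converted at
# the I/O boundary and nowhere else.

#' Read a FASTA file
#'
#' @param path file path.
#' @param alphabet `"dna"`, `"protein"`, or `"auto"` (guess from content).
#' @return named character vector of sequences, in file order, with an
#'   `"alphabet"` attribute. An empty file yields an empty vector with a
#'   warning.
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e)))
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  if (length(out) == 0L) {
    warning("empty FASTA file: ", path)
    attr(out, "alphabet") <- if (alphabet == "auto") "dna" else alphabet
    return(out)
  }
  if (any(!nzchar(out)))
    stop("empty sequence for record '",
         names(out)[which(!nzchar(out))[1L]], "' in ", path)
  if (alphabet == "auto") {
    pool <- paste(substr(out, 1L, 500L), collapse = "")
    frac_acgt <- mean(chars(pool) %in% c("A", "C", "G", "T", "N"))
    alphabet <- if (frac_acgt > 0.95) "dna" else "protein"
  }
  attr(out, "alphabet") <- alphabet
  out
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  set <- Biostrings::BStringSet(as.character(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

MAT_TAGS <- c("MAT1-1-1", "MAT1-1-3", "MAT1-1-5", "MAT1-1-13",
              "MAT1-2-1", "MAT1-2-10")
GENE_TAGS <- c(MAT_TAGS, "APN2", "SLA2", "alpha_pheromone", "a_pheromone",
               "ste2", "ste3", "other")

#' Construct a gene model
#'
#' A gene model is an exon-structured gene on a contig: coding exons as
#' 0-based half-open intervals on the forward strand, plus a functional
#' tag (MAT gene, pheromone, receptor, anchor, or `"other"`).
#'
#' @param gene_id,contig_id identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column integer matrix of `[start, end)` intervals.
#' @param tag functional tag: a MAT gene name (`MAT1-1-1`, `MAT1-1-3`,
#'   `MAT1-1-5`, `MAT1-1-13`, `MAT1-2-1`, `MAT1-2-10`), `APN2`, `SLA2`,
#'   `alpha_pheromone`, `a_pheromone`, `ste2`, `ste3`, or `other`.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig_id, strand, exons, tag = "other") {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("gene model needs at least one exon")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("exon end must exceed start (0-based half-open)")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("exons overlap in gene ", gene_id)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!tag %in% GENE_TAGS) stop("unknown gene tag: ", tag)
  structure(list(gene_id = gene_id, contig_id = contig_id,
                 strand = strand, exons = exons, tag = tag),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s [%s] %s:%s %d exon(s), CDS %d nt\n",
              x$gene_id, x$tag, x$contig_id, x$strand, nrow(x$exons),
              sum(x$exons[, 2L] - x$exons[, 1L])))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' CDS features are grouped per gene (directly, or via their mRNA parent)
#' and converted from 1-based inclusive to 0-based half-open coordinates.
#' Both `ID=` and `locus_tag=` are accepted as gene identifiers. A `Name`
#' attribute matching a known functional tag (e.g. `MAT1-1-1`) is carried
#' into the model's `tag`.
#'
#' @param path GFF3 file.
#' @param contigs optional character vector of valid contig names; features
#'   on other contigs raise an error.
#' @return list of [gene_model] objects.
#' @export
read_gff3 <- function(path, contigs = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("malformed GFF3 in ", path, ": ",
                        conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (!is.null(contigs)) {
    bad <- setdiff(unique(as.character(df$seqnames)), contigs)
    if (length(bad))
      stop("GFF3 features on unknown contig(s): ",
           paste(bad, collapse = ", "))
  }
  get_id <- function(row) {
    id <- row[["ID"]]
    if (is.null(id) || is.na(id) || !nzchar(id)) id <- row[["locus_tag"]]
    id
  }
  ## map every feature ID to its gene ancestor
  feat_id <- if ("ID" %in% names(df)) as.character(df$ID) else
    rep(NA_character_, nrow(df))
  if ("locus_tag" %in% names(df))
    feat_id <- ifelse(is.na(feat_id) | !nzchar(feat_id),
                      as.character(df$locus_tag), feat_id)
  parent_of <- function(i) {
    p <- df$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }
  is_gene <- df$type == "gene"
  gene_rows <- which(is_gene)
  gene_ids <- feat_id[gene_rows]
  mrna_rows <- which(df$type %in% c("mRNA", "transcript"))
  mrna_gene <- setNames(vapply(mrna_rows, parent_of, ""), feat_id[mrna_rows])

  cds_rows <- which(df$type == "CDS")
  if (length(cds_rows) == 0L) return(list())
  cds_gene <- character(length(cds_rows))
  for (k in seq_along(cds_rows)) {
    p <- parent_of(cds_rows[k])
    if (is.na(p))
      stop("CDS without a parent feature at ", path, " line for ",
           df$seqnames[cds_rows[k]], ":", df$start[cds_rows[k]])
    if (p %in% names(mrna_gene) && !is.na(mrna_gene[[p]]))
      p <- mrna_gene[[p]]
    cds_gene[k] <- p
  }
  models <- list()
  for (g in unique(cds_gene)) {
    rows <- cds_rows[cds_gene == g]
    contig <- unique(as.character(df$seqnames[rows]))
    if (length(contig) > 1L)
      stop("CDS of gene ", g, " spans multiple contigs")
    strand <- unique(as.character(df$strand[rows]))
    if (length(strand) > 1L || !strand %in% c("+", "-"))
      stop("inconsistent or missing strand for gene ", g)
    exons <- cbind(df$start[rows] - 1L, df$end[rows])  # to 0-based half-open
    tag <- "other"
    gi <- which(gene_ids == g)
    if (length(gi) == 1L && "Name" %in% names(df)) {
      nm <- as.character(df$Name[gene_rows[gi]])
      if (!is.na(nm) && nm %in% GENE_TAGS) tag <- nm
    }
    models[[g]] <- gene_model(g, contig, strand, exons, tag)
  }
  models[order(names(models))]
}

#' Write gene models to GFF3
#'
#' Emits gene + mRNA + CDS rows per model with a `##gff-version 3` pragma,
#' converting internal 0-based half-open coordinates back to 1-based
#' inclusive.
#'
#' @param genes list of [gene_model].
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    span <- c(min(g$exons[, 1L]) + 1L, max(g$exons[, 2L]))
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = g$contig_id, source = "matmine", type = "gene",
      start = span[1L], end = span[2L], score = ".", strand = g$strand,
      phase = ".",
      attributes = sprintf("ID=%s;Name=%s", g$gene_id, g$tag))
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = g$contig_id, source = "matmine", type = "mRNA",
      start = span[1L], end = span[2L], score = ".", strand = g$strand,
      phase = ".",
      attributes = sprintf("ID=%s.t1;Parent=%s", g$gene_id, g$gene_id))
    for (i in seq_len(nrow(g$exons)))
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = g$contig_id, source = "matmine", type = "CDS",
        start = g$exons[i, 1L] + 1L, end = g$exons[i, 2L], score = ".",
        strand = g$strand, phase = ".",
        attributes = sprintf("ID=%s.cds;Parent=%s.t1", g$gene_id,
                             g$gene_id))
  }
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(tab))
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Extract and translate the coding sequence of a gene model
#'
#' Exon sequences are concatenated in transcription order (the forward
#' concatenation is reverse-complemented for minus-strand genes) and
#' translated with the standard genetic code. A trailing stop codon is
#' removed; internal stop codons are retained as `*` and flagged via the
#' `internal_stop` attribute. A CDS length not divisible by 3 triggers a
#' warning and sets the `phase_error` attribute.
#'
#' @param genome named character vector of contig sequences.
#' @param gene a [gene_model].
#' @return protein string with attributes `internal_stop` and
#'   `phase_error`.
#' @export
extract_cds_and_translate <- function(genome, gene) {
  if (!gene$contig_id %in% names(genome))
    stop("contig '", gene$contig_id, "' not in genome")
  contig <- genome[[gene$contig_id]]
  if (max(gene$exons[, 2L]) > nchar(contig))
    stop("exons of ", gene$gene_id, " exceed contig bounds")
  cds <- paste(substr0(contig, gene$exons[, 1L], gene$exons[, 2L]),
               collapse = "")
  if (gene$strand == "-") cds <- revcomp(cds)
  phase_error <- nchar(cds) %% 3L != 0L
  if (phase_error)
    warning("CDS length of ", gene$gene_id, " not divisible by 3")
  prot <- translate_dna(cds)
  if (endsWith(prot, "*")) prot <- substr(prot, 1L, nchar(prot) - 1L)
  attr(prot, "internal_stop") <- grepl("*", prot, fixed = TRUE)
  attr(prot, "phase_error") <- phase_error
  prot
}

#' Six-frame translation of a contig
#'
#' @param contig single DNA string (or named length-1 vector).
#' @return data.frame with one row per frame: `frame` (+1,+2,+3,-1,-2,-3),
#'   `strand`, `offset` (0-based offset of the frame's first base on the
#'   strand read), and `aa` (protein string, stops as `*`). For a frame
#'   with offset `o`, protein position `p` (0-based) maps to forward-strand
#'   contig coordinates `[o + 3p, o + 3p + 3)` on `+`, and
#'   `[L - o - 3p - 3, L - o - 3p)` on `-`.
#' @export
six_frame_translate <- function(contig) {
  dna <- toupper(as.character(contig)[1L])
  rc <- revcomp(dna)
  frames <- data.frame(
    frame = c(1L, 2L, 3L, -1L, -2L, -3L),
    strand = rep(c("+", "-"), each = 3L),
    offset = rep(0:2, 2L),
    stringsAsFactors = FALSE)
  frames$aa <- vapply(seq_len(nrow(frames)), function(i) {
    src <- if (frames$strand[i] == "+") dna else rc
    translate_dna(substr(src, frames$offset[i] + 1L, nchar(src)))
  }, character(1L))
  frames
}
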