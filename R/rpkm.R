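# RPKM expression summaries and the mating-type dependence test for
# pheromone genes. Read mapping is upstream of this module: counts,
# gene lengths and library sizes (total mapped reads) are inputs.

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count * 1e9 / (library_size * gene_length_bp)`. Vectorized.
#'
#' @param count non-negative read count(s).
#' @param gene_length_bp gene length(s) in bp (> 0).
#' @param library_size total mapped reads in the library (> 0).
#' @return numeric RPKM value(s).
#' @export
rpkm <- function(count, gene_length_bp, library_size) {
  if (any(gene_length_bp <= 0)) stop("gene length must be positive")
  if (any(library_size <= 0)) stop("library size must be positive")
  count * 1e9 / (library_size * gene_length_bp)
}

#' Assemble a count table
#'
#' @param counts integer matrix, genes x samples (dimnames required).
#' @param gene_length_bp named vector of gene lengths.
#' @param samples data.frame with `sample_id`, `mating_type` (one of
#'   `"MAT1-1"`, `"MAT1-2"`, `"mixed"`) and `library_size`. Library size
#'   is the total mapped reads and may exceed the column sums.
#' @return object of class `count_table`.
#' @export
count_table <- function(counts, gene_length_bp, samples) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            all(rownames(counts) %in% names(gene_length_bp)),
            all(c("sample_id", "mating_type", "library_size") %in%
                  names(samples)),
            all(colnames(counts) %in% samples$sample_id))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(samples$mating_type %in% c("MAT1-1", "MAT1-2", "mixed")))
    stop("mating_type must be MAT1-1, MAT1-2 or mixed")
  structure(list(counts = counts,
                 gene_length_bp = gene_length_bp[rownames(counts)],
                 samples = samples[match(colnames(counts),
                                         samples$sample_id), ]),
            class = "count_table")
}

#' RPKM matrix for a count table
#'
#' @param ct a [count_table].
#' @return numeric matrix, genes x samples.
#' @export
rpkm_table <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  sweep(ct$counts * 1e9 / ct$gene_length_bp, 2L,
        ct$samples$library_size, "/")
}

#' Mating-type dependence of a gene's expression
#'
#' A gene is called exclusive to one mating type when its RPKM reaches
#' `threshold_on` in at least one pure sample of that type while staying
#' below the threshold in all observed pure samples of the other type;
#' mixed-type samples are excluded. Without samples of the opposite type
#' exclusivity cannot be established and expression above threshold is
#' reported as `both`.
#'
#' @param ct a [count_table].
#' @param gene_id gene to test.
#' @param threshold_on RPKM on/off threshold (default 1.0; "very low"
#'   expression is conventionally RPKM < 1).
#' @return one of `"MAT1_1_exclusive"`, `"MAT1_2_exclusive"`, `"both"`,
#'   `"neither"`, with attribute `n_samples` giving the pure sample count
#'   per mating type.
#' @export
mating_dependence <- function(ct, gene_id, threshold_on = 1.0) {
  stopifnot(inherits(ct, "count_table"))
  if (!gene_id %in% rownames(ct$counts))
    stop("gene '", gene_id, "' not in count table")
  r <- rpkm_table(ct)[gene_id, ]
  mt <- ct$samples$mating_type
  if (!any(mt != "mixed")) stop("no sample of known mating type")
  v11 <- r[mt == "MAT1-1"]
  v12 <- r[mt == "MAT1-2"]
  on11 <- any(v11 >= threshold_on)
  on12 <- any(v12 >= threshold_on)
  verdict <- if (on11 && length(v12) && !on12) "MAT1_1_exclusive"
  else if (on12 && length(v11) && !on11) "MAT1_2_exclusive"
  else if (on11 || on12) "both"
  else "neither"
  structure(verdict,
            n_samples = c(`MAT1-1` = length(v11), `MAT1-2` = length(v12)))
}

#' Read a counts TSV and a samples TSV into a count table
#'
#' The counts file holds `gene_id`, `gene_length_bp`, then one column per
#' sample; the samples file holds `sample_id`, `mating_type`,
#' `library_size`.
#'
#' @param counts_path,samples_path file paths.
#' @return a [count_table].
#' @export
read_count_table <- function(counts_path, samples_path) {
  cts <- read.table(counts_path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  smp <- read.table(samples_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  m <- as.matrix(cts[, !(names(cts) %in% c("gene_id", "gene_length_bp")),
                     drop = FALSE])
  rownames(m) <- cts$gene_id
  count_table(m, setNames(cts$gene_length_bp, cts$gene_id), smp)
}

#' Write an RPKM table as TSV
#'
#' @param ct a [count_table].
#' @param path output path.
#' @export
write_rpkm_tsv <- function(ct, path) {
  r <- rpkm_table(ct)
  out <- data.frame(gene_id = rownames(r), round(r, 2),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
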