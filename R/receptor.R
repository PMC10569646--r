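# Pheromone receptor quality control. STE2 (alpha-factor receptor) and
# STE3 (a-factor receptor) are G-protein coupled receptors expected to
# span the membrane exactly seven times; gene models whose translation
# carries premature stops or whose hydropathy profile yields a different
# helix count are flagged as defective.

#' Quality-control a pheromone receptor gene model
#'
#' Translates the gene model and applies, in order: missing gene ->
#' `deleted`; untranslatable model (CDS phase error) -> `unannotatable`;
#' internal stop codon -> `premature_stop`; CDS shorter than half the
#' reference length -> `truncated`; then transmembrane helices are
#' counted by sliding-window hydropathy and exactly 7 gives `intact`,
#' anything else `wrong_tm_count`.
#'
#' @param gene a [gene_model] tagged `ste2`/`ste3`, or `NULL` when the
#'   gene is absent from the genome.
#' @param genome named character vector of contig DNA.
#' @param receptor `"STE2"` or `"STE3"`.
#' @param ref_len optional reference protein length for the truncation
#'   check.
#' @param tm_window,tm_threshold,tm_min_run,tm_merge_gap hydropathy
#'   settings (see [hydropathy_segments()]).
#' @return object of class `receptor_call`: list with `gene_id`,
#'   `receptor`, `tm_count`, `internal_stop`, `verdict`.
#' @export
qc_receptor <- function(gene, genome, receptor = c("STE2", "STE3"),
                        ref_len = NULL, tm_window = 19L,
                        tm_threshold = 1.6, tm_min_run = 15L,
                        tm_merge_gap = 3L) {
  receptor <- match.arg(receptor)
  res <- function(gene_id, tm, stop, verdict)
    structure(list(gene_id = gene_id, receptor = receptor,
                   tm_count = tm, internal_stop = stop,
                   verdict = verdict), class = "receptor_call")
  if (is.null(gene) || (!is.null(gene$contig_id) &&
                        !gene$contig_id %in% names(genome)))
    return(res(NA_character_, NA_integer_, NA, "deleted"))
  prot <- tryCatch(
    withCallingHandlers(
      extract_cds_and_translate(genome, gene),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (is.null(prot) || !nzchar(prot) || isTRUE(attr(prot, "phase_error")))
    return(res(gene$gene_id, NA_integer_, NA, "unannotatable"))
  if (isTRUE(attr(prot, "internal_stop")))
    return(res(gene$gene_id, NA_integer_, TRUE, "premature_stop"))
  if (!is.null(ref_len) && nchar(prot) < 0.5 * ref_len)
    return(res(gene$gene_id, NA_integer_, FALSE, "truncated"))
  seg <- hydropathy_segments(prot, window = tm_window,
                             threshold = tm_threshold,
                             min_run = tm_min_run,
                             merge_gap = tm_merge_gap)
  tm <- nrow(seg)
  res(gene$gene_id, tm, FALSE,
      if (tm == 7L) "intact" else "wrong_tm_count")
}

#' @export
print.receptor_call <- function(x, ...) {
  cat(sprintf("<receptor_call> %s (%s): %s (TM=%s)\n",
              x$gene_id %||% "absent", x$receptor, x$verdict,
              ifelse(is.na(x$tm_count), "?", x$tm_count)))
  invisible(x)
}

#' Tabulate receptor calls across genomes
#'
#' @param calls named list of `receptor_call` objects (names are
#'   genome ids).
#' @return data.frame with columns genome, receptor, tm_count, verdict.
#' @export
receptor_table <- function(calls) {
  do.call(rbind, lapply(names(calls), function(g)
    data.frame(genome = g, receptor = calls[[g]]$receptor,
               tm_count = calls[[g]]$tm_count,
               verdict = calls[[g]]$verdict, stringsAsFactors = FALSE)))
}
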