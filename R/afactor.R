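# BLAST-independent a-factor pheromone screen: keep annotated proteins of
# at most 100 residues ending in a CAAX/CPAX prenylation box, then rank
# candidates by cross-genome conservation with supporting evidence from
# the S/T-rich N-terminus and the C-terminal GY motif.

#' Filter a proteome to a-factor pheromone candidates
#'
#' Retains exactly those proteins with length at most `max_len`
#' (boundary inclusive) and a terminal CAAX or CPAX box. Candidates are
#' returned sorted by protein id, with the S/T fraction of the N-terminal
#' window and the GY-motif position populated.
#'
#' @param proteins named character vector of protein sequences
#'   (translated CDS products, stop codons stripped).
#' @param classes a [residue_classes] object.
#' @param max_len maximum length in residues (default 100).
#' @param st_window N-terminal window for [st_fraction()].
#' @param gy_window tail window for [find_gy_motif()].
#' @return data.frame of candidates: `protein_id`, `length_aa`,
#'   `terminal_class`, `terminal_box`, `st_frac`, `gy_start` (0-based, NA
#'   when absent), `sequence`.
#' @export
filter_proteome <- function(proteins, classes = residue_classes(),
                            max_len = 100L, st_window = 20L,
                            gy_window = 15L) {
  empty <- data.frame(protein_id = character(0), length_aa = integer(0),
                      terminal_class = character(0),
                      terminal_box = character(0), st_frac = numeric(0),
                      gy_start = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE)
  if (!length(proteins)) return(empty)
  if (is.null(names(proteins))) stop("proteins must be named")
  rows <- list()
  for (id in sort(names(proteins))) {
    p <- proteins[[id]]
    n <- nchar(p)
    if (n > max_len || n < 4L) next
    cls <- terminal_caax_class(p, classes)
    if (cls == "none") next
    gy <- find_gy_motif(p, gy_window)
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = id, length_aa = n, terminal_class = cls,
      terminal_box = substr(p, n - 3L, n),
      st_frac = st_fraction(p, st_window),
      gy_start = if (is.null(gy)) NA_integer_ else gy$start,
      sequence = p, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Rank a-factor candidates by cross-genome conservation
#'
#' Conservation is the number of relative genomes with a passing
#' homology hit ([conservation_count()]). Candidates are ordered by
#' conservation (descending), then an evidence score
#' `w_st * [st_frac >= st_min] + w_gy * [GY present]` (descending), then
#' length (ascending), then protein id — a fully deterministic order.
#'
#' @param candidates data.frame from [filter_proteome()].
#' @param relatives list of genomes (named character vectors of contigs).
#' @param params see [search_params()].
#' @param st_min S/T-richness verdict threshold (default 0.30).
#' @param w_st,w_gy evidence weights (default 1 each).
#' @return the candidates data.frame with `conservation`, `evidence` and
#'   `rank` columns, ordered by rank.
#' @export
rank_candidates <- function(candidates, relatives,
                            params = search_params(), st_min = 0.30,
                            w_st = 1, w_gy = 1) {
  if (length(relatives) < 1L)
    stop("supply at least one relative genome to rank candidates")
  if (!nrow(candidates)) {
    candidates$conservation <- integer(0)
    candidates$evidence <- numeric(0)
    candidates$rank <- integer(0)
    return(candidates)
  }
  presence <- conservation_matrix(candidates$sequence, relatives, params)
  candidates$conservation <- as.integer(rowSums(presence))
  candidates$evidence <- w_st * (candidates$st_frac >= st_min) +
    w_gy * !is.na(candidates$gy_start)
  ord <- order(-candidates$conservation, -candidates$evidence,
               candidates$length_aa, candidates$protein_id)
  candidates <- candidates[ord, , drop = FALSE]
  candidates$rank <- seq_len(nrow(candidates))
  rownames(candidates) <- NULL
  candidates
}

#' Structured evidence report for one a-factor candidate
#'
#' @param candidate one-row data.frame from [rank_candidates()] (or
#'   [filter_proteome()]; missing conservation is reported as NA).
#' @return list with `tsv` (one-row data.frame with the fixed six columns
#'   protein_id, length_aa, terminal_box, st_frac, gy, conservation) and
#'   `text` (a human-readable line).
#' @export
evidence_report <- function(candidate) {
  stopifnot(nrow(candidate) == 1L)
  gy <- if (is.na(candidate$gy_start)) "no" else
    sprintf("yes@%d", candidate$gy_start - candidate$length_aa)
  cons <- if ("conservation" %in% names(candidate))
    candidate$conservation else NA_integer_
  tsv <- data.frame(protein_id = candidate$protein_id,
                    length_aa = candidate$length_aa,
                    terminal_box = candidate$terminal_box,
                    st_frac = round(candidate$st_frac, 3),
                    gy = gy, conservation = cons,
                    stringsAsFactors = FALSE)
  text <- sprintf(
    "%s: %d aa, box %s (%s), N-terminal S/T %.2f, GY motif %s, conserved in %s genome(s)",
    candidate$protein_id, candidate$length_aa, candidate$terminal_box,
    candidate$terminal_class, candidate$st_frac, gy,
    ifelse(is.na(cons), "?", cons))
  list(tsv = tsv, text = text)
}
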