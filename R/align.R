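# Protein-protein and protein-vs-genome (six-frame) local alignment
# search with approximate E-values, plus microsynteny utilities. This is
# the internal stand-in for translated BLAST searches: full
# Smith-Waterman dynamic programming per stop-free frame segment, suited
# to desk-scale synthetic genomes.

## Karlin-Altschul parameters for BLOSUM62 with gap open 11 / extend 1
KA_LAMBDA <- 0.267
KA_K <- 0.041

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Default homology-search parameters
#'
#' BLOSUM62 with affine gap penalties 11 (open) / 1 (extend) and an
#' approximate E-value acceptance threshold of 0.05 — the conventional
#' translated-BLAST defaults and cutoff.
#'
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param evalue_max hits with larger approximate E-value are dropped.
#' @param score_min optional raw-score floor applied in addition.
#' @param min_segment shortest stop-free frame segment searched.
#' @return list of parameters.
#' @export
search_params <- function(gap_open = 11L, gap_extend = 1L,
                          evalue_max = 0.05, score_min = NULL,
                          min_segment = 9L) {
  list(matrix = blosum62(), gap_open = gap_open, gap_extend = gap_extend,
       evalue_max = evalue_max, score_min = score_min,
       min_segment = min_segment)
}

karlin_altschul_evalue <- function(score, m, n) {
  KA_K * m * n * exp(-KA_LAMBDA * score)
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman with affine gaps (a gap of length L costs
#' `gap_open + L * gap_extend`). Residues outside the standard alphabet
#' are treated as X.
#'
#' @param query,target protein strings (non-empty).
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend positive gap penalties.
#' @param query_id,target_id identifiers carried into the hit.
#' @return a one-row data.frame (an alignment hit): `query_id`,
#'   `target_id`, `score`, `query_start`, `query_end`, `target_start`,
#'   `target_end` (0-based half-open), `identity`, `evalue`.
#' @export
local_align <- function(query, target, matrix = blosum62(),
                        gap_open = 11L, gap_extend = 1L,
                        query_id = "query", target_id = "target") {
  stopifnot(nzchar(query), nzchar(target))
  q <- sanitize_protein(gsub("*", "X", query, fixed = TRUE))
  t <- sanitize_protein(gsub("*", "X", target, fixed = TRUE))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(t),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(data.frame(query_id = query_id, target_id = target_id,
                      score = 0, query_start = 0L, query_end = 0L,
                      target_start = 0L, target_end = 0L, identity = 0,
                      evalue = karlin_altschul_evalue(0, nchar(q),
                                                     nchar(t)),
                      stringsAsFactors = FALSE))
  }
  pr <- list(start = Biostrings::start(Biostrings::pattern(pa)),
             end = Biostrings::end(Biostrings::pattern(pa)))
  sr <- list(start = Biostrings::start(Biostrings::subject(pa)),
             end = Biostrings::end(Biostrings::subject(pa)))
  data.frame(query_id = query_id, target_id = target_id, score = sc,
             query_start = pr$start - 1L, query_end = pr$end,
             target_start = sr$start - 1L, target_end = sr$end,
             identity = Biostrings::pid(pa) / 100,
             evalue = karlin_altschul_evalue(sc, nchar(q), nchar(t)),
             stringsAsFactors = FALSE)
}

## stop-free segments of a frame translation: data.frame(aa_start, seq)
## aa_start is the 0-based protein position of the segment within the frame
frame_segments <- function(aa, min_segment) {
  pieces <- strsplit(aa, "*", fixed = TRUE)[[1L]]
  if (!length(pieces)) return(NULL)
  starts <- cumsum(c(0L, nchar(pieces) + 1L))[seq_along(pieces)]
  keep <- nchar(pieces) >= min_segment
  if (!any(keep)) return(NULL)
  data.frame(aa_start = starts[keep], seq = pieces[keep],
             stringsAsFactors = FALSE)
}

#' Precompute the six-frame segment index of a genome
#'
#' [search_genome()] accepts this in place of the raw genome, saving
#' repeated translation when many queries are searched against the same
#' genome.
#'
#' @param genome named character vector of contig DNA.
#' @param params see [search_params()].
#' @return object of class `genome_index`.
#' @export
genome_index <- function(genome, params = search_params()) {
  segs <- list()
  for (contig in names(genome)) {
    fr <- six_frame_translate(genome[[contig]])
    for (i in seq_len(nrow(fr))) {
      s <- frame_segments(fr$aa[i], params$min_segment)
      if (is.null(s)) next
      s$contig <- contig
      s$strand <- fr$strand[i]
      s$frame <- fr$frame[i]
      s$offset <- fr$offset[i]
      s$contig_len <- nchar(genome[[contig]])
      segs[[length(segs) + 1L]] <- s
    }
  }
  segs <- if (length(segs)) do.call(rbind, segs) else NULL
  structure(list(segs = segs,
                 subjects = if (is.null(segs)) NULL else
                   Biostrings::AAStringSet(segs$seq),
                 search_space = if (is.null(segs)) 0L else
                   sum(nchar(segs$seq))),
            class = "genome_index")
}

#' Search a genome with a protein query (six-frame translation)
#'
#' Each contig is translated in all six frames; every stop-free segment is
#' aligned to the query by Smith-Waterman, so hits never cross frame
#' stops. Passing hits are mapped back to forward-strand contig
#' coordinates and sorted by descending score.
#'
#' @param query protein string.
#' @param genome named character vector of contig DNA, or a prebuilt
#'   [genome_index()].
#' @param params see [search_params()].
#' @param query_id identifier carried into hits.
#' @return data.frame of hits: `query_id`, `target_id`, `score`, `strand`,
#'   `frame`, `query_start`, `query_end`, `target_start`, `target_end`
#'   (DNA, 0-based half-open, forward strand), `identity`, `evalue`.
#' @export
search_genome <- function(query, genome, params = search_params(),
                          query_id = "query") {
  q <- sanitize_protein(gsub("*", "X", query, fixed = TRUE))
  idx <- if (inherits(genome, "genome_index")) genome else
    genome_index(genome, params)
  empty <- data.frame(query_id = character(0), target_id = character(0),
                      score = numeric(0), strand = character(0),
                      frame = integer(0), query_start = integer(0),
                      query_end = integer(0), target_start = integer(0),
                      target_end = integer(0), identity = numeric(0),
                      evalue = numeric(0), stringsAsFactors = FALSE)
  if (is.null(idx$segs)) return(empty)
  segs <- idx$segs
  search_space <- idx$search_space
  pa <- Biostrings::pairwiseAlignment(
    idx$subjects, Biostrings::AAString(q),
    substitutionMatrix = params$matrix, gapOpening = params$gap_open,
    gapExtension = params$gap_extend, type = "local")
  sc <- Biostrings::score(pa)
  ev <- karlin_altschul_evalue(sc, nchar(q), search_space)
  pass <- sc > 0 & ev <= params$evalue_max
  if (!is.null(params$score_min)) pass <- pass & sc >= params$score_min
  if (!any(pass)) return(empty)
  pr <- list(start = Biostrings::start(Biostrings::pattern(pa))[pass],
             end = Biostrings::end(Biostrings::pattern(pa))[pass])
  sr <- list(start = Biostrings::start(Biostrings::subject(pa))[pass],
             end = Biostrings::end(Biostrings::subject(pa))[pass])
  segs <- segs[pass, , drop = FALSE]
  ## protein coords within the frame -> DNA coords on the read strand
  p0 <- segs$aa_start + pr$start - 1L
  p1 <- segs$aa_start + pr$end
  d0 <- segs$offset + 3L * p0
  d1 <- segs$offset + 3L * p1
  fwd0 <- ifelse(segs$strand == "+", d0, segs$contig_len - d1)
  fwd1 <- ifelse(segs$strand == "+", d1, segs$contig_len - d0)
  out <- data.frame(query_id = query_id, target_id = segs$contig,
                    score = sc[pass], strand = segs$strand,
                    frame = segs$frame,
                    query_start = sr$start - 1L, query_end = sr$end,
                    target_start = as.integer(fwd0),
                    target_end = as.integer(fwd1),
                    identity = Biostrings::pid(pa)[pass] / 100,
                    evalue = ev[pass], stringsAsFactors = FALSE)
  out[order(-out$score), , drop = FALSE]
}

#' Inter-anchor microsynteny window
#'
#' Given hits for two anchor genes (e.g. APN2 and SLA2, or the genes
#' flanking a pheromone in a close relative), returns the interval between
#' them (anchors excluded), orientation-normalized so that the leftmost
#' anchor comes first. Anchors on different contigs yield a split-locus
#' flag instead of a window.
#'
#' @param hit_a,hit_b one-row hit data.frames from [search_genome()].
#' @return list with `contig`, `start`, `end` (0-based half-open), and
#'   `split` (logical). Overlapping anchors give an empty window and a
#'   warning.
#' @export
microsynteny_window <- function(hit_a, hit_b) {
  if (hit_a$target_id != hit_b$target_id)
    return(list(contig = NA_character_, start = NA_integer_,
                end = NA_integer_, split = TRUE))
  if (hit_a$target_start > hit_b$target_start) { tmp <- hit_a; hit_a <- hit_b; hit_b <- tmp }
  s <- hit_a$target_end
  e <- hit_b$target_start
  if (e <= s) {
    warning("anchor hits overlap; empty microsynteny window")
    e <- s
  }
  list(contig = hit_a$target_id, start = s, end = e, split = FALSE)
}

#' Count genomes conserving a candidate protein
#'
#' Number of genomes with at least one passing [search_genome()] hit for
#' the candidate; the cross-genome conservation criterion used to rank
#' a-factor candidates.
#'
#' @param candidate protein string.
#' @param genomes list of named character vectors (one per genome) or of
#'   prebuilt [genome_index()] objects.
#' @param params see [search_params()].
#' @return integer count.
#' @export
conservation_count <- function(candidate, genomes,
                               params = search_params()) {
  if (length(genomes) < 1L) stop("at least one genome is required")
  sum(vapply(genomes, function(g)
    nrow(search_genome(candidate, g, params)) > 0L, logical(1L)))
}

## presence/absence of each candidate in each genome, computed with one
## vectorized alignment call per genome (cross-product of candidates and
## frame segments)
conservation_matrix <- function(candidates, genomes,
                                params = search_params()) {
  if (length(genomes) < 1L) stop("at least one genome is required")
  cands <- vapply(candidates, function(x)
    sanitize_protein(gsub("*", "X", x, fixed = TRUE)), character(1L),
    USE.NAMES = FALSE)
  out <- matrix(FALSE, length(cands), length(genomes))
  for (j in seq_along(genomes)) {
    idx <- genomes[[j]]
    if (!inherits(idx, "genome_index")) idx <- genome_index(idx, params)
    if (is.null(idx$segs)) next
    nseg <- length(idx$subjects)
    pa <- Biostrings::pairwiseAlignment(
      rep(idx$subjects, length(cands)),
      Biostrings::AAStringSet(rep(cands, each = nseg)),
      substitutionMatrix = params$matrix, gapOpening = params$gap_open,
      gapExtension = params$gap_extend, type = "local")
    sc <- matrix(Biostrings::score(pa), nrow = nseg)
    for (i in seq_along(cands)) {
      ev <- karlin_altschul_evalue(sc[, i], nchar(cands[i]),
                                   idx$search_space)
      pass <- sc[, i] > 0 & ev <= params$evalue_max
      if (!is.null(params$score_min))
        pass <- pass & sc[, i] >= params$score_min
      out[i, j] <- any(pass)
    }
  }
  out
}

#' Write alignment hits as a tab-separated report
#'
#' Fixed column order: query_id, target_id, score, evalue, target_start,
#' target_end, strand, frame, identity.
#'
#' @param hits data.frame from [search_genome()].
#' @param path output path.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("query_id", "target_id", "score", "evalue", "target_start",
            "target_end", "strand", "frame", "identity")
  write.table(hits[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
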