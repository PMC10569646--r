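# MAT-locus assembly and thallism classification.
#
# MAT genes are sought genome-wide by six-frame homology to reference
# proteins; APN2/SLA2 anchor hits delimit the locus when no MAT gene is
# found directly. Each reference receives a status per locus from the
# fraction of its length covered by (chained) hits, and the per-genome
# sexual strategy is called by a decision cascade over idiomorph content,
# identical repeat pairs and contig layout.

MAT1_1_GENES <- c("MAT1-1-1", "MAT1-1-3", "MAT1-1-5", "MAT1-1-13")
MAT1_2_GENES <- c("MAT1-2-1", "MAT1-2-10")

#' MAT-locus analysis parameters
#'
#' @param coverage_intact minimum reference coverage for an intact call
#'   (default 0.9; an intact gene must also be uninterrupted by stops,
#'   i.e. covered by a single frame segment).
#' @param coverage_fragment coverage below this is a fragment (default
#'   0.5); coverage between the two bounds with an end-biased hit is a 5'
#'   or 3' truncation.
#' @param locus_gap_bp hits on one contig separated by more than this are
#'   treated as distinct loci (default 2000).
#' @param repeat_len_min minimum identical-repeat length for switching
#'   signatures (default 100 bp; the described switching repeats are
#'   250 bp).
#' @param identity_min minimum alignment identity for a hit to count as
#'   locus evidence (default 0.5). The E-value cutoff alone admits
#'   occasional chance alignments at desk-scale search spaces; real MAT
#'   homologs from related references align far above this floor, so the
#'   floor plays the role of the curation step that dismisses nonsense
#'   hits.
#' @param search see [search_params()].
#' @return list of settings.
#' @export
mat_params <- function(coverage_intact = 0.9, coverage_fragment = 0.5,
                       locus_gap_bp = 2000L, repeat_len_min = 100L,
                       identity_min = 0.5, search = search_params()) {
  list(coverage_intact = coverage_intact,
       coverage_fragment = coverage_fragment,
       locus_gap_bp = locus_gap_bp, repeat_len_min = repeat_len_min,
       identity_min = identity_min, search = search)
}

## assign a status to one locus-group of hits for a reference of length L
locus_status <- function(hits, ref_len, par) {
  iv <- cbind(hits$query_start, hits$query_end)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  merged <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    if (iv[i, 1L] <= merged[nrow(merged), 2L])
      merged[nrow(merged), 2L] <- max(merged[nrow(merged), 2L], iv[i, 2L])
    else merged <- rbind(merged, iv[i, , drop = FALSE])
  }
  cov <- sum(merged[, 2L] - merged[, 1L]) / ref_len
  cov_start <- merged[1L, 1L] / ref_len
  cov_end <- merged[nrow(merged), 2L] / ref_len
  best_single <- max(hits$query_end - hits$query_start) / ref_len
  if (cov >= par$coverage_intact) {
    ## a single full-length hit is intact even when weak secondary hits
    ## overlap it; full coverage only in interrupted pieces means the
    ## reading frame is broken
    if (best_single >= par$coverage_intact) "intact" else "pseudogenised"
  } else if (cov < par$coverage_fragment) {
    "fragment"
  } else if (cov_start > 0.25) {
    "truncated_5prime"
  } else if (cov_end < 0.75) {
    "truncated_3prime"
  } else "fragment"
}

#' Locate the MAT locus and status its genes
#'
#' Searches a genome with reference MAT proteins (and the APN2/SLA2
#' anchors), groups hits into loci, and assigns each reference gene a
#' status (`intact`, `truncated_5prime`, `truncated_3prime`, `fragment`,
#' `pseudogenised`, `absent`). When no MAT gene is found, the inter-anchor
#' APN2-SLA2 window is reported for downstream scanning.
#'
#' @param genome named character vector of contig DNA.
#' @param references named character vector of reference proteins; names
#'   must use the MAT gene tags plus optionally `APN2` and `SLA2`.
#' @param par see [mat_params()].
#' @return list with `genes` (data.frame: name, status, contig, start,
#'   end, strand, coverage; one row per reference-locus, absent references
#'   included with NA coordinates), `window` (APN2/SLA2 microsynteny
#'   window or NULL), and `split_anchors` (logical).
#' @export
locate_mat_locus <- function(genome, references, par = mat_params()) {
  rows <- list()
  anchor_hits <- list()
  for (nm in names(references)) {
    ref <- references[[nm]]
    hits <- search_genome(ref, genome, par$search, query_id = nm)
    hits <- hits[hits$identity >= par$identity_min, , drop = FALSE]
    if (!nrow(hits)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, status = "absent", contig = NA_character_,
        start = NA_integer_, end = NA_integer_, strand = NA_character_,
        coverage = 0, stringsAsFactors = FALSE)
      next
    }
    ## group hits into loci per contig by genomic proximity
    hits <- hits[order(hits$target_id, hits$target_start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      hits$target_id[-1L] != hits$target_id[-nrow(hits)] |
        hits$target_start[-1L] - hits$target_end[-nrow(hits)] >
          par$locus_gap_bp)))
    for (g in unique(grp)) {
      h <- hits[grp == g, , drop = FALSE]
      cov <- sum(h$query_end - h$query_start) / nchar(ref)
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, status = locus_status(h, nchar(ref), par),
        contig = h$target_id[1L], start = min(h$target_start),
        end = max(h$target_end), strand = h$strand[1L],
        coverage = min(1, cov), stringsAsFactors = FALSE)
    }
    if (nm %in% c("APN2", "SLA2"))
      anchor_hits[[nm]] <- hits[1L, , drop = FALSE]
  }
  genes <- do.call(rbind, rows)
  window <- NULL
  split_anchors <- FALSE
  if (all(c("APN2", "SLA2") %in% names(anchor_hits))) {
    w <- suppressWarnings(
      microsynteny_window(anchor_hits$APN2, anchor_hits$SLA2))
    if (w$split) split_anchors <- TRUE else window <- w
  }
  list(genes = genes, window = window, split_anchors = split_anchors)
}

#' Detect identical direct/inverted repeat pairs
#'
#' Finds all maximal pairs of identical substrings of at least `min_len`
#' bases in direct or inverted (reverse-complement) orientation within a
#' locus window. Matching is exact; the switching repeats this targets
#' are described as identical.
#'
#' @param dna DNA string (a locus window).
#' @param min_len minimum repeat length (default 100 bp).
#' @param identity_min reserved; only exact matching (1.0) is supported.
#' @return data.frame: `a_start`, `a_end`, `b_start`, `b_end` (0-based
#'   half-open, a before b), `length_bp`, `orientation`
#'   (`direct`/`inverted`), `identity`.
#' @export
detect_repeat_pairs <- function(dna, min_len = 100L, identity_min = 1.0) {
  if (identity_min < 1.0)
    warning("only exact repeat matching is implemented; using identity 1")
  empty <- data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      length_bp = integer(0), orientation = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE)
  n <- nchar(dna)
  k <- as.integer(min_len)
  if (n < 2L * k) return(empty)
  starts <- 1:(n - k + 1L)
  kmers <- substring(dna, starts, starts + k - 1L)
  out <- list()

  pair_runs <- function(ia, ib, orientation) {
    ## ia, ib: 1-based start positions of matching k-mers (a in dna,
    ## b in dna), same length; merge anti/diagonal runs into maximal pairs
    if (!length(ia)) return(NULL)
    key <- if (orientation == "direct") ib - ia else ib + ia
    ord <- order(key, ia)
    ia <- ia[ord]; ib <- ib[ord]; key <- key[ord]
    brk <- c(TRUE, diff(ia) != 1L | diff(key) != 0L)
    grp <- cumsum(brk)
    res <- list()
    for (g in unique(grp)) {
      i0 <- ia[grp == g]
      j0 <- ib[grp == g]
      len <- length(i0) + k - 1L
      a0 <- i0[1L] - 1L; a1 <- a0 + len
      if (orientation == "direct") {
        b0 <- j0[1L] - 1L; b1 <- b0 + len
      } else {
        b0 <- j0[length(j0)] - 1L; b1 <- j0[1L] - 1L + k
      }
      if (b0 < a0) { tmp <- c(a0, a1); a0 <- b0; a1 <- b1; b0 <- tmp[1L]; b1 <- tmp[2L] }
      if (b0 < a1) next                      # overlapping / self match
      res[[length(res) + 1L]] <- data.frame(
        a_start = a0, a_end = a1, b_start = b0, b_end = b1,
        length_bp = len, orientation = orientation, identity = 1.0,
        stringsAsFactors = FALSE)
    }
    if (length(res)) do.call(rbind, res) else NULL
  }

  ## direct: duplicated k-mers
  dup <- which(kmers %in% kmers[duplicated(kmers)])
  if (length(dup)) {
    idx <- split(dup, kmers[dup])
    ia <- integer(0); ib <- integer(0)
    for (pos in idx) {
      pr <- t(utils::combn(pos, 2L))
      ia <- c(ia, pr[, 1L]); ib <- c(ib, pr[, 2L])
    }
    out[[length(out) + 1L]] <- pair_runs(ia, ib, "direct")
  }
  ## inverted: k-mers matching reverse-complemented k-mers
  rc <- revcomp(dna)
  kmers_rc <- substring(rc, starts, starts + k - 1L)
  rc_kmers <- kmers_rc[n - starts - k + 2L]   # revcomp of each fwd k-mer
  hitm <- match(rc_kmers, kmers)
  ok <- which(!is.na(hitm))
  if (length(ok)) {
    ia <- ok; ib <- hitm[ok]
    keep <- ia < ib                          # canonical order, no self
    out[[length(out) + 1L]] <- pair_runs(ia[keep], ib[keep], "inverted")
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  ## drop pairs contained in a longer reported pair
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res)))
    for (j in seq_len(nrow(res)))
      if (i != j && keep[i] && keep[j] &&
          res$length_bp[i] <= res$length_bp[j] &&
          res$a_start[i] >= res$a_start[j] &&
          res$a_end[i] <= res$a_end[j] &&
          res$b_start[i] >= res$b_start[j] &&
          res$b_end[i] <= res$b_end[j] &&
          !(res$length_bp[i] == res$length_bp[j] && i < j))
        keep[i] <- FALSE
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res[res$length_bp >= min_len, , drop = FALSE]
}

#' Classify the sexual strategy of a genome
#'
#' Decision cascade over MAT gene statuses, identical repeat pairs and
#' contig layout:
#' 1. an intact MAT1-1-3 as the only MAT1-1 gene, with no trace of
#'    MAT1-1-1 and no MAT1-2 genes, is the HMG-only strategy
#'    (`lachnellula_HMG_only`);
#' 2. intact genes from exactly one idiomorph give `heterothallic_MAT1_1`
#'    or `heterothallic_MAT1_2` (fragments of the opposite idiomorph,
#'    common inside heterothallic idiomorphs, do not count);
#' 3. both idiomorphs at a single locus: MAT1-1-1 fragments flanking the
#'    MAT1-2 genes with an inverted repeat pair give
#'    `switching_inversion`; a direct repeat pair gives
#'    `switching_deletion`; otherwise intact principal genes (MAT1-1-1
#'    and MAT1-2-1) give `primary_homothallic`;
#' 4. both idiomorphs intact but on separate loci/contigs give
#'    `possible_mixed_culture`;
#' 5. anything else (e.g. truncated principal genes without a switching
#'    signature, or contradictory evidence) is `undetermined`.
#'
#' @param genes data.frame from [locate_mat_locus()]`$genes`.
#' @param repeats data.frame from [detect_repeat_pairs()] (may be empty).
#' @param split_anchors logical layout flag from [locate_mat_locus()].
#' @return object of class `thallism_call`: list with `strategy` and
#'   `evidence` (character vector of facts).
#' @export
classify_thallism <- function(genes, repeats = NULL,
                              split_anchors = FALSE) {
  if (is.null(repeats)) repeats <- detect_repeat_pairs("", 100L)
  ev <- character(0)
  present <- genes[genes$status != "absent", , drop = FALSE]
  intact <- present[present$status == "intact", , drop = FALSE]
  intact11 <- intact$name[intact$name %in% MAT1_1_GENES]
  intact12 <- intact$name[intact$name %in% MAT1_2_GENES]
  frags111 <- present[present$name == "MAT1-1-1" &
                        present$status != "intact", , drop = FALSE]
  has_inv <- any(repeats$orientation == "inverted")
  has_dir <- any(repeats$orientation == "direct")
  for (i in seq_len(nrow(present)))
    ev <- c(ev, sprintf("%s:%s(cov=%.2f)", present$name[i],
                        present$status[i], present$coverage[i]))
  if (nrow(repeats))
    ev <- c(ev, sprintf("repeat_pair:%s:%dbp", repeats$orientation,
                        repeats$length_bp))
  if (split_anchors) ev <- c(ev, "anchors_on_separate_contigs")
  if (!length(ev)) ev <- "no_mat_evidence"

  call <- function(strategy)
    structure(list(strategy = strategy, evidence = ev),
              class = "thallism_call")

  no_mat12 <- !any(present$name %in% MAT1_2_GENES)
  no_mat111 <- !any(present$name == "MAT1-1-1")

  ## 1. HMG-only strategy (MAT1-1 side)
  if (identical(intact11, "MAT1-1-3") && no_mat111 && no_mat12 &&
      !length(intact12))
    return(call("lachnellula_HMG_only"))

  ## contradictory: switching signature without both idiomorphs
  if ((has_inv || has_dir) && nrow(frags111) >= 2L &&
      (length(intact11) == 0L || length(intact12) == 0L) &&
      !(length(intact11) || length(intact12)))
    return(call("undetermined"))

  ## 2. a single idiomorph
  if (length(intact11) && !length(intact12)) {
    if ((has_inv || has_dir) && nrow(frags111) >= 2L)
      return(call("undetermined"))
    return(call("heterothallic_MAT1_1"))
  }
  if (length(intact12) && !length(intact11)) {
    if ((has_inv || has_dir) && nrow(frags111) >= 2L)
      return(call("undetermined"))
    return(call("heterothallic_MAT1_2"))
  }

  ## 3./4. both idiomorphs
  if (length(intact11) && length(intact12)) {
    c11 <- unique(intact$contig[intact$name %in% MAT1_1_GENES])
    c12 <- unique(intact$contig[intact$name %in% MAT1_2_GENES])
    single_locus <- length(intersect(c11, c12)) > 0L ||
      (length(c11) == 1L && length(c12) == 1L && c11 == c12)
    if (single_locus) {
      if (has_inv && nrow(frags111) >= 2L)
        return(call("switching_inversion"))
      if (has_dir)
        return(call("switching_deletion"))
      if ("MAT1-1-1" %in% intact11 && "MAT1-2-1" %in% intact12)
        return(call("primary_homothallic"))
      return(call("undetermined"))
    }
    return(call("possible_mixed_culture"))
  }

  ## 5. nothing intact (fragments/truncations only), or nothing at all
  call("undetermined")
}

#' @export
print.thallism_call <- function(x, ...) {
  cat(sprintf("<thallism_call> %s\n  evidence: %s\n", x$strategy,
              paste(x$evidence, collapse = "; ")))
  invisible(x)
}

#' Per-genome MAT locus report as JSON
#'
#' @param genome_id identifier.
#' @param locus result of [locate_mat_locus()].
#' @param repeats result of [detect_repeat_pairs()].
#' @param call result of [classify_thallism()].
#' @param path output path.
#' @export
write_locus_json <- function(genome_id, locus, repeats, call, path) {
  jsonlite::write_json(
    list(genome = genome_id, strategy = call$strategy,
         evidence = call$evidence, genes = locus$genes,
         repeat_pairs = repeats,
         split_anchors = locus$split_anchors),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
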