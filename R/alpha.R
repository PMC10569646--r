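# Alpha-factor pro-pheromone annotation.
#
# The pro-protein begins with a hydrophobic signal region and carries
# repeats of a conserved 9-14 aa mature pheromone. Repeats sit between
# STE13 recognition runs (XA/XP dipeptide units trimmed from a free
# N-terminus) and KEX1/2 dibasic cleavage sites (KR/RR/KK). The annotator
# formalizes the manual curation rules:
#   * KEX hits merged into cleavage blocks; a repeat ends where the next
#     block starts;
#   * each repeat starts immediately after the STE13 run (if any)
#     anchored at the end of the previous cleavage block;
#   * the first repeat, whose upstream anchor is ambiguous, is back-filled
#     using the modal repeat length (ties resolved toward the shorter
#     length), mirroring the length-consistency rule used for manual
#     annotation;
#   * candidates longer than the modal length are trimmed to it (the
#     intervening residues are linker, not mature peptide);
#   * candidates still longer than max_len containing an internal STE13
#     run of >= 2 units are split at those runs (STE13-dominant
#     processing).

#' Configuration for alpha-factor annotation
#'
#' @param min_total shortest protein considered (default 40 aa).
#' @param min_len,max_len soft bounds on mature repeat length (9-14 aa);
#'   out-of-range repeats are flagged, not dropped.
#' @param gq_anchor optional fallback: when the grammar yields nothing,
#'   anchor putative repeats on GQ dipeptides (off by default; exploratory
#'   only, the class is still assigned from the grammar).
#' @param gq_len window length used by the GQ fallback.
#' @return list of settings.
#' @export
alpha_config <- function(min_total = 40L, min_len = 9L, max_len = 14L,
                         gq_anchor = FALSE, gq_len = 10L) {
  list(min_total = min_total, min_len = min_len, max_len = max_len,
       gq_anchor = gq_anchor, gq_len = gq_len)
}

## merge overlapping/adjacent KEX dipeptide hits into cleavage blocks
kex_blocks <- function(protein) {
  hits <- find_kex_sites(protein)
  if (!nrow(hits)) return(hits)
  out <- hits[1L, , drop = FALSE]
  for (i in seq_len(nrow(hits))[-1L]) {
    if (hits$start[i] <= out$end[nrow(out)]) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], hits$end[i])
    } else out <- rbind(out, hits[i, , drop = FALSE])
  }
  out
}

mature_repeat <- function(protein, start, end, preceded_by, followed_by,
                          cfg) {
  seq <- substr0(protein, start, end)
  beta <- if (grepl("GQ", seq, fixed = TRUE)) "GQ" else
    if (grepl("PG", seq, fixed = TRUE)) "PG" else "none"
  data.frame(sequence = seq, start = start, end = end, beta_turn = beta,
             preceded_by = preceded_by, followed_by = followed_by,
             length_flag = (end - start) < cfg$min_len |
               (end - start) > cfg$max_len,
             stringsAsFactors = FALSE)
}

## modal value of an integer vector; ties resolved toward the smaller
mode_shorter <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which(tab == max(tab))[1L]])
}

#' Annotate mature repeats in an alpha-factor pro-pheromone
#'
#' Applies the processing-site grammar (see the package vignette for the
#' full rule set) and assigns an architecture class:
#' `typical` (>= 2 repeats, each released by a KEX1/2 site),
#' `ste13_dominant` (repeats separated by STE13 runs with fewer KEX sites
#' than repeats), `atypical_single_repeat` (one repeat, no KEX site at
#' all), or `unparseable`.
#'
#' @param protein protein string (stop codons stripped).
#' @param cfg see [alpha_config()].
#' @param protein_id identifier carried into the annotation.
#' @return object of class `alpha_annotation`: list with `protein_id`,
#'   `signal` (hit or NULL), `sites` (KEX blocks and STE13 runs),
#'   `repeats` (data.frame of mature repeats), `klass`.
#' @export
annotate_repeats <- function(protein, cfg = alpha_config(),
                             protein_id = "protein") {
  protein <- sanitize_protein(protein)
  if (nchar(protein) < cfg$min_total)
    stop("protein shorter than min_total (", cfg$min_total, " aa)")
  signal <- find_signal(protein)
  blocks <- kex_blocks(protein)
  ste13 <- find_ste13_sites(protein)
  reps <- list()

  if (nrow(blocks) >= 1L) {
    k <- nrow(blocks)
    ## candidates anchored after each cleavage block (repeats 2..k)
    cand <- list()
    for (i in seq_len(k - 1L)) {
      anchor <- blocks$end[i]
      run_end <- ste13_run_end(protein, anchor)
      if (run_end < blocks$start[i + 1L])
        cand[[length(cand) + 1L]] <- list(
          start = run_end, end = blocks$start[i + 1L],
          preceded = if (run_end > anchor) "STE13" else "KEX")
    }
    lens <- vapply(cand, function(cc) cc$end - cc$start, integer(1L))
    ## composite candidates (to be split at internal STE13 runs later)
    ## must not pollute the modal length
    m <- if (any(lens <= cfg$max_len))
      mode_shorter(lens[lens <= cfg$max_len]) else NA_integer_
    ## trim candidates longer than the modal length (but not composites):
    ## the surplus between repeat end and the KEX site is linker
    if (!is.na(m))
      cand <- lapply(cand, function(cc) {
        len <- cc$end - cc$start
        if (len > m && len <= cfg$max_len) cc$end <- cc$start + m
        cc
      })
    ## repeats upstream of the first cleavage block: back-fill by modal
    ## length, else by the closest upstream STE13 run; then walk further
    ## upstream through exact-length STE13-separated repeats (the
    ## STE13-dominant architecture) until the signal region is reached
    sig_end <- if (is.null(signal)) 0L else signal$end
    lead <- list()
    if (!is.na(m) && blocks$start[1L] - m >= 0L) {
      s <- blocks$start[1L] - m
      pre <- if (any(ste13$end == s)) "STE13" else "none"
      lead <- list(list(start = s, end = blocks$start[1L],
                        preceded = pre))
      while (pre == "STE13") {
        a <- max(ste13$start[ste13$end == s])
        s_up <- a - m
        if (s_up < sig_end || !any(ste13$end == s_up)) break
        lead <- c(list(list(start = s_up, end = a, preceded = "STE13",
                            followed = "STE13")), lead)
        s <- s_up
      }
    } else if (is.na(m)) {
      ok <- ste13[ste13$end <= blocks$start[1L] - cfg$min_len, ,
                  drop = FALSE]
      if (nrow(ok)) {
        lead <- list(list(start = max(ok$end), end = blocks$start[1L],
                          preceded = "STE13"))
      } else if (sig_end > 0L && sig_end < blocks$start[1L]) {
        lead <- list(list(start = sig_end, end = blocks$start[1L],
                          preceded = "none"))
      }
    }
    cand <- c(lead, cand)
    ## STE13-dominant split: over-long candidates broken at internal
    ## STE13 runs of at least two dipeptide units
    split_cand <- list()
    for (cc in cand) {
      if (cc$end - cc$start > cfg$max_len) {
        inner <- find_ste13_sites(substr0(protein, cc$start, cc$end))
        inner <- inner[inner$end - inner$start >= 4L &
                         inner$start > 0L, , drop = FALSE]
        if (nrow(inner)) {
          bounds <- cc$start
          for (j in seq_len(nrow(inner))) {
            split_cand[[length(split_cand) + 1L]] <- list(
              start = bounds, end = cc$start + inner$start[j],
              preceded = if (identical(bounds, cc$start)) cc$preceded
                         else "STE13",
              followed = "STE13")
            bounds <- cc$start + inner$end[j]
          }
          split_cand[[length(split_cand) + 1L]] <- list(
            start = bounds, end = cc$end, preceded = "STE13",
            followed = "KEX")
          next
        }
      }
      cc$followed <- cc$followed %||% "KEX"
      split_cand[[length(split_cand) + 1L]] <- cc
    }
    for (cc in split_cand)
      if (cc$end > cc$start)
        reps[[length(reps) + 1L]] <- mature_repeat(
          protein, cc$start, cc$end, cc$preceded, cc$followed, cfg)
  } else if (nrow(ste13) >= 1L) {
    ## no KEX sites at all: single putative mature peptide after the
    ## first STE13 site downstream of the signal region (atypical
    ## architecture)
    sig_end <- if (is.null(signal)) 0L else signal$end
    after <- ste13[ste13$start >= sig_end, , drop = FALSE]
    if (nrow(after)) {
      s <- after$end[1L]
      nxt <- after$start[after$start >= s + cfg$min_len]
      e <- if (length(nxt)) min(nxt) else nchar(protein)
      if (e > s)
        reps[[1L]] <- mature_repeat(protein, s, e, "STE13", "none", cfg)
    }
  }

  repeats <- if (length(reps)) do.call(rbind, reps) else
    data.frame(sequence = character(0), start = integer(0),
               end = integer(0), beta_turn = character(0),
               preceded_by = character(0), followed_by = character(0),
               length_flag = logical(0), stringsAsFactors = FALSE)
  if (nrow(repeats))
    repeats <- repeats[order(repeats$start), , drop = FALSE]

  n <- nrow(repeats)
  klass <- if (n == 0L) "unparseable"
  else if (n == 1L && nrow(blocks) == 0L) "atypical_single_repeat"
  else if (n >= 2L && all(repeats$followed_by == "KEX")) "typical"
  else if (n >= 2L && any(repeats$followed_by == "STE13")) "ste13_dominant"
  else "unparseable"

  if (klass == "unparseable" && cfg$gq_anchor && n == 0L) {
    cc <- chars(protein)
    gq <- which(cc[-length(cc)] == "G" & cc[-1L] == "Q") - 1L
    reps <- lapply(gq, function(g) {
      s <- max(0L, g - (cfg$gq_len %/% 2L) + 1L)
      mature_repeat(protein, s, min(nchar(protein), s + cfg$gq_len),
                    "none", "none", cfg)
    })
    if (length(reps)) repeats <- do.call(rbind, reps)
  }

  sites <- rbind(blocks, ste13)
  if (nrow(sites)) sites <- sites[order(sites$start), , drop = FALSE]
  structure(list(protein_id = protein_id, protein = protein,
                 signal = signal, sites = sites, repeats = repeats,
                 klass = klass),
            class = "alpha_annotation")
}

#' @export
print.alpha_annotation <- function(x, ...) {
  cat(sprintf("<alpha_annotation> %s: %s, %d repeat(s)\n", x$protein_id,
              x$klass, nrow(x$repeats)))
  if (nrow(x$repeats))
    cat(paste0("  ", x$repeats$sequence, " [", x$repeats$start, ",",
               x$repeats$end, ") beta-turn=", x$repeats$beta_turn,
               collapse = "\n"), "\n")
  invisible(x)
}

## all ORFs (M..stop) of at least min_aa residues in all six frames of a
## DNA window; returns a data.frame with frame metadata and protein
find_orfs <- function(dna, min_aa) {
  fr <- six_frame_translate(dna)
  L <- nchar(dna)
  out <- list()
  for (i in seq_len(nrow(fr))) {
    aa <- fr$aa[i]
    segs <- frame_segments(aa, 1L)
    if (is.null(segs)) next
    for (j in seq_len(nrow(segs))) {
      mpos <- regexpr("M", segs$seq[j], fixed = TRUE)
      if (mpos < 0L) next
      orf <- substr(segs$seq[j], mpos, nchar(segs$seq[j]))
      if (nchar(orf) < min_aa) next
      p0 <- segs$aa_start[j] + mpos - 1L         # 0-based in frame
      p1 <- p0 + nchar(orf)
      d0 <- fr$offset[i] + 3L * p0
      d1 <- fr$offset[i] + 3L * p1
      if (fr$strand[i] == "-") { tmp <- d0; d0 <- L - d1; d1 <- L - tmp }
      out[[length(out) + 1L]] <- data.frame(
        protein = orf, strand = fr$strand[i], frame = fr$frame[i],
        start = d0, end = d1, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(protein = character(0), strand = character(0),
                      frame = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Scan an intergenic window for alpha-factor-like genes
#'
#' Translates all ORFs of at least `min_orf_aa` residues on both strands
#' of a microsynteny window and runs [annotate_repeats()] on each;
#' parseable ORFs are returned ranked by repeat count, then length.
#'
#' Because short random ORFs can satisfy the grammar by chance, a
#' candidate must additionally look like a pheromone: either at least
#' two repeats within the expected length range, or — for the
#' single-repeat atypical architecture — a detected signal peptide and a
#' GQ beta-turn dipeptide in the mature peptide.
#'
#' @param window_dna DNA string (e.g. from [microsynteny_window()]).
#' @param cfg see [alpha_config()].
#' @param min_orf_aa minimum ORF length in residues.
#' @return list of candidates, each with `annotation`, `strand`, `frame`,
#'   `start`, `end` (window coordinates).
#' @export
scan_intergenic_for_alpha <- function(window_dna, cfg = alpha_config(),
                                      min_orf_aa = NULL) {
  min_orf_aa <- min_orf_aa %||% cfg$min_total
  orfs <- find_orfs(window_dna, min_orf_aa)
  out <- list()
  for (i in seq_len(nrow(orfs))) {
    ann <- annotate_repeats(orfs$protein[i], cfg,
                            protein_id = sprintf("orf_%d", i))
    if (ann$klass == "unparseable") next
    plausible <- if (ann$klass == "atypical_single_repeat")
      !is.null(ann$signal) && any(ann$repeats$beta_turn == "GQ") else
      sum(!ann$repeats$length_flag) >= 2L
    if (!plausible) next
    out[[length(out) + 1L]] <- list(annotation = ann,
                                    strand = orfs$strand[i],
                                    frame = orfs$frame[i],
                                    start = orfs$start[i],
                                    end = orfs$end[i])
  }
  if (!length(out)) return(list())
  ord <- order(-vapply(out, function(x) nrow(x$annotation$repeats),
                       integer(1L)),
               -vapply(out, function(x) nchar(x$annotation$protein),
                       integer(1L)))
  out[ord]
}

#' Incidence of mature repeats across species
#'
#' Exact-string (uppercase) incidence of each distinct mature repeat
#' across a set of per-species annotations.
#'
#' @param annotations named list of `alpha_annotation` objects (names are
#'   species).
#' @return logical species-by-repeat incidence matrix with per-repeat
#'   species counts in attribute `"counts"`.
#' @export
repeat_sharing_matrix <- function(annotations) {
  if (!length(annotations)) stop("at least one annotation is required")
  if (is.null(names(annotations)))
    names(annotations) <- vapply(annotations, `[[`, "", "protein_id")
  reps <- lapply(annotations, function(a) unique(toupper(a$repeats$sequence)))
  all_reps <- sort(unique(unlist(reps)))
  mat <- matrix(FALSE, nrow = length(annotations), ncol = length(all_reps),
                dimnames = list(names(annotations), all_reps))
  for (i in seq_along(reps)) mat[i, reps[[i]]] <- TRUE
  structure(mat, counts = colSums(mat))
}

#' Write per-species alpha-factor annotations as TSV
#'
#' Columns: protein_id, n_repeats, repeats (';'-joined), class.
#'
#' @param annotations list of `alpha_annotation` objects.
#' @param path output path.
#' @export
write_alpha_tsv <- function(annotations, path) {
  tab <- do.call(rbind, lapply(annotations, function(a)
    data.frame(protein_id = a$protein_id, n_repeats = nrow(a$repeats),
               repeats = paste(a$repeats$sequence, collapse = ";"),
               class = a$klass, stringsAsFactors = FALSE)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
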