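# Residue-class motif primitives: CAAX/CPAX terminal boxes, KEX1/2 and
# STE13 processing sites, S/T richness, the GY motif, and Kyte-Doolittle
# hydropathy segmentation for signal peptides and transmembrane helices.
#
# All hit coordinates are 0-based half-open in protein space.

#' Residue classes for CAAX/CPAX box matching
#'
#' The prenylation box grammar uses C = cysteine, A = any aliphatic
#' residue, P = any polar residue, X = any residue. The default classes
#' cover every terminal box observed in Leotiomycete a-factor candidates
#' (CTVM, CVVM, CIVM, CTIL, CSIM, CSVM) while leaving G, P, W and F in
#' neither class; both sets are configurable because the class membership
#' of borderline residues is a modelling choice, not a fixed standard.
#'
#' @param aliphatic,polar character vectors of one-letter residue codes.
#' @return object of class `residue_classes`.
#' @export
residue_classes <- function(aliphatic = c("A", "V", "L", "I", "M"),
                            polar = c("S", "T", "C", "N", "Q", "Y", "H",
                                      "K", "R", "D", "E")) {
  stopifnot(all(aliphatic %in% AA_STANDARD), all(polar %in% AA_STANDARD))
  structure(list(aliphatic = aliphatic, polar = polar),
            class = "residue_classes")
}

motif_hit <- function(kind, start, end) {
  data.frame(kind = kind, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

no_hits <- function() motif_hit(character(0), integer(0), integer(0))

#' Classify the C-terminal prenylation box of a protein
#'
#' Inspects exactly the last four residues. Position 1 must be cysteine;
#' the box is CAAX when positions 2 and 3 are both aliphatic, CPAX when
#' position 2 is polar and position 3 aliphatic; position 4 is
#' unconstrained. CAAX takes precedence when both patterns match.
#'
#' @param protein protein string.
#' @param classes a [residue_classes] object.
#' @return `"CAAX"`, `"CPAX"`, or `"none"`.
#' @export
terminal_caax_class <- function(protein, classes = residue_classes()) {
  n <- nchar(protein)
  if (n < 4L) {
    warning("protein shorter than 4 residues; no terminal box")
    return("none")
  }
  box <- chars(substr(protein, n - 3L, n))
  if (box[1L] != "C") return("none")
  if (!box[3L] %in% classes$aliphatic) return("none")
  if (box[2L] %in% classes$aliphatic) return("CAAX")
  if (box[2L] %in% classes$polar) return("CPAX")
  "none"
}

#' Find KEX1/2 recognition sites (KR, RR, KK dipeptides)
#'
#' Every occurrence is reported, overlapping occurrences included, sorted
#' by start.
#'
#' @param protein protein string.
#' @return data.frame of hits (`kind`, `start`, `end`), 0-based half-open.
#' @export
find_kex_sites <- function(protein) {
  n <- nchar(protein)
  if (n < 2L) return(no_hits())
  cc <- chars(protein)
  di <- paste0(cc[-n], cc[-1L])
  pos <- which(di %in% c("KR", "RR", "KK"))
  if (!length(pos)) return(no_hits())
  motif_hit("KEX", pos - 1L, pos + 1L)
}

## chain of X[AP] dipeptides stepping by 2 from a fixed 0-based anchor;
## returns the 0-based end of the run (== anchor if no unit matches)
ste13_run_end <- function(protein, anchor) {
  n <- nchar(protein)
  pos <- anchor
  while (pos + 2L <= n &&
         substr(protein, pos + 2L, pos + 2L) %in% c("A", "P"))
    pos <- pos + 2L
  pos
}

#' Find STE13 recognition runs (XA/XP dipeptide units)
#'
#' STE13 is a dipeptidyl aminopeptidase that trims X-A/X-P units; a
#' recognition region is therefore a maximal run of dipeptides of the form
#' (any residue)(A|P), anchored on even steps from the run start.
#' Singleton XA/XP sites are reported too. Runs of both phases are
#' reported when present.
#'
#' @param protein protein string.
#' @return data.frame of hits (`kind`, `start`, `end`), 0-based half-open.
#' @export
find_ste13_sites <- function(protein) {
  n <- nchar(protein)
  if (n < 2L) return(no_hits())
  cc <- chars(protein)
  ## is_ok[i]: the dipeptide starting at 1-based position i ends in A/P
  is_ok <- c(cc[-1L] %in% c("A", "P"), FALSE)
  if (!any(is_ok)) return(no_hits())
  runlen <- integer(n + 2L)                  # units in the run from i
  for (i in n:1L)
    if (is_ok[i]) runlen[i] <- 1L + runlen[i + 2L]
  starts <- which(is_ok & !c(FALSE, FALSE, is_ok[seq_len(n - 2L)]))
  motif_hit("STE13", starts - 1L, starts - 1L + 2L * runlen[starts])
}

#' Serine/threonine fraction of the N-terminal window
#'
#' @param protein protein string (non-empty).
#' @param window number of N-terminal residues to inspect (default 20).
#' @return fraction of S + T residues in the first
#'   `min(window, nchar(protein))` residues.
#' @export
st_fraction <- function(protein, window = 20L) {
  if (!nzchar(protein)) stop("empty protein")
  stopifnot(window >= 1L)
  w <- min(window, nchar(protein))
  cc <- chars(substr(protein, 1L, w))
  mean(cc %in% c("S", "T"))
}

#' Find the C-terminal glycine-tyrosine (GY) motif
#'
#' Reports the last `GY` occurrence whose start lies within `tail_window`
#' residues upstream of the cysteine of the terminal CAAX/CPAX box (the
#' caller is responsible for having classified the tail).
#'
#' @param protein protein string.
#' @param tail_window search window upstream of the terminal cysteine.
#' @return one-row hit data.frame, or `NULL` when absent.
#' @export
find_gy_motif <- function(protein, tail_window = 15L) {
  n <- nchar(protein)
  if (n < 6L) return(NULL)
  c_pos <- n - 4L                      # 0-based index of the box cysteine
  cc <- chars(protein)
  gy <- which(cc[-n] == "G" & cc[-1L] == "Y") - 1L   # 0-based starts
  gy <- gy[gy >= c_pos - tail_window & gy < c_pos]
  if (!length(gy)) return(NULL)
  motif_hit("GY", max(gy), max(gy) + 2L)
}

#' Kyte-Doolittle hydropathy scale
#' @return named numeric vector over the 20 standard residues.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Hydrophobic segments by sliding-window hydropathy
#'
#' Computes the mean hydropathy in a centred sliding window and reports
#' maximal runs of window centres above `threshold`, merging runs
#' separated by gaps of at most `merge_gap` centres and keeping runs of at
#' least `min_run` centres. Reported intervals extend each run by half a
#' window on both sides (clipped to the protein). A segment starting
#' within the first `signal_zone` residues carries `signal_like = TRUE`.
#'
#' Defaults (window 19, threshold 1.6, min_run 15) follow standard
#' hydropathy practice for transmembrane helix detection; use
#' `window = 9, min_run = 5` for signal-peptide style detection.
#'
#' @param protein protein string.
#' @param scale per-residue hydropathy table (default Kyte-Doolittle);
#'   residues absent from the table score 0.
#' @param window odd window size, at least 5.
#' @param threshold mean-hydropathy cutoff.
#' @param min_run minimum run length in window centres.
#' @param merge_gap sub-threshold gaps up to this length are bridged.
#' @param signal_zone prefix length within which a segment is flagged
#'   signal-like.
#' @return data.frame of hits (`kind`, `start`, `end`, `signal_like`);
#'   empty when the protein is shorter than the window.
#' @export
hydropathy_segments <- function(protein, scale = kyte_doolittle(),
                                window = 19L, threshold = 1.6,
                                min_run = 15L, merge_gap = 3L,
                                signal_zone = 30L) {
  stopifnot(window >= 5L, window %% 2L == 1L)
  n <- nchar(protein)
  if (n < window) return(cbind(no_hits(), signal_like = logical(0)))
  h <- scale[chars(protein)]
  h[is.na(h)] <- 0
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  half <- window %/% 2L
  centres <- (half + 1L):(n - half)            # 1-based centre positions
  above <- means[centres] > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ## bridge short FALSE gaps between TRUE runs
  for (i in seq_along(r$values))
    if (!r$values[i] && r$lengths[i] <= merge_gap &&
        i > 1L && i < length(r$values))
      above[starts[i]:ends[i]] <- TRUE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  if (!length(keep)) return(cbind(no_hits(), signal_like = logical(0)))
  seg_start <- pmax(0L, centres[starts[keep]] - 1L - half)
  seg_end <- pmin(n, centres[ends[keep]] + half)
  out <- motif_hit("TM", seg_start, seg_end)
  out$signal_like <- out$start < signal_zone
  out
}

#' Locate a signal-peptide-like hydrophobic prefix
#'
#' Convenience wrapper around [hydropathy_segments()] with short-window
#' settings; returns the first segment that starts inside the signal zone,
#' reported with kind `"signal"`, or `NULL`.
#'
#' @param protein protein string.
#' @param window,threshold,min_run,signal_zone tuning; see
#'   [hydropathy_segments()].
#' @export
find_signal <- function(protein, window = 9L, threshold = 1.6,
                        min_run = 5L, signal_zone = 30L) {
  seg <- hydropathy_segments(protein, window = window,
                             threshold = threshold, min_run = min_run,
                             merge_gap = 2L, signal_zone = signal_zone)
  seg <- seg[seg$signal_like, , drop = FALSE]
  if (!nrow(seg)) return(NULL)
  motif_hit("signal", seg$start[1L], seg$end[1L])
}
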