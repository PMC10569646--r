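# Independent reference implementations used as oracles. These share no
# code with the package internals they check.

## plain-R affine-gap Smith-Waterman (Gotoh recurrences); a gap of
## length L costs go + ge * L
sw_oracle <- function(a, b, M, go = 11, ge = 1) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1L] - go - ge, E[i, j - 1L] - ge)
      F[i, j] <- max(H[i - 1L, j] - go - ge, F[i - 1L, j] - ge)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + M[A[i - 1L], B[j - 1L]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

## exhaustive-state-enumeration marginal posteriors for the two-state
## Markov model on a small rooted tree (stationary root prior)
enum_posteriors <- function(tree, tips, q01, q10) {
  tr <- ape::reorder.phylo(tree, "postorder")
  E <- tr$edge
  ntip <- ape::Ntip(tr)
  nn <- ntip + tr$Nnode
  r <- q01 + q10
  pi0 <- if (r == 0) 0.5 else q10 / r
  prior <- c(pi0, 1 - pi0)
  P <- function(t) {
    e <- exp(-r * t)
    rbind(c(pi0 + (1 - pi0) * e, (1 - pi0) * (1 - e)),
          c(pi0 * (1 - e), (1 - pi0) + pi0 * e))
  }
  tipst <- tips[tr$tip.label]
  tipsets <- lapply(seq_len(ntip), function(i)
    if (tipst[i] == "?") 0:1 else as.integer(tipst[i]))
  internals <- (ntip + 1L):nn
  combos <- expand.grid(rep(list(0:1), length(internals)))
  tipgrid <- expand.grid(tipsets)
  post <- matrix(0, nn, 2L)
  tot <- 0
  root <- E[nrow(E), 1L]
  for (ci in seq_len(nrow(combos))) {
    states <- integer(nn)
    states[internals] <- as.integer(combos[ci, ])
    for (ti in seq_len(nrow(tipgrid))) {
      states[seq_len(ntip)] <- as.integer(tipgrid[ti, ])
      L <- prior[states[root] + 1L]
      for (k in seq_len(nrow(E)))
        L <- L * P(tr$edge.length[k])[states[E[k, 1L]] + 1L,
                                      states[E[k, 2L]] + 1L]
      tot <- tot + L
      for (v in seq_len(nn))
        post[v, states[v] + 1L] <- post[v, states[v] + 1L] + L
    }
  }
  post / tot
}

## shift-scan maximal identical repeat pairs (direct and inverted) of at
## least min_len, by comparing the sequence against itself at every
## offset (and against its reverse complement along every anti-diagonal)
repeat_pairs_oracle <- function(dna, min_len) {
  n <- nchar(dna)
  cc <- strsplit(dna, "")[[1L]]
  rc <- rev(chartr("ACGT", "TGCA", cc))
  out <- NULL
  for (d in seq_len(n - min_len)) {          # direct, offset d
    eq <- cc[seq_len(n - d)] == cc[seq_len(n - d) + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths >= min_len)) {
      s <- ends[k] - r$lengths[k] + 1L
      if (r$lengths[k] > d) next             # tandem self-overlap
      out <- rbind(out, data.frame(
        a_start = s - 1L, a_end = s - 1L + r$lengths[k],
        b_start = s - 1L + d, b_end = s - 1L + r$lengths[k] + d,
        length_bp = r$lengths[k], orientation = "direct"))
    }
  }
  ## inverted: forward position i matches rc position j with the
  ## forward-coordinate pair (i, n - j - len + 1 ...); scan every
  ## alignment offset of dna vs its reverse complement
  for (d in -(n - min_len):(n - min_len)) {
    i1 <- max(1L, 1L - d); i2 <- min(n, n - d)
    if (i2 - i1 + 1L < min_len) next
    idx <- i1:i2
    eq <- cc[idx] == rc[idx + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths >= min_len)) {
      s <- idx[ends[k] - r$lengths[k] + 1L]  # fwd start (1-based)
      len <- r$lengths[k]
      ## rc index j maps to forward position n - j + 1
      jr <- (s + d)                          # rc start
      b_end_fwd <- n - jr + 1L               # fwd coord of first rc base
      b_start_fwd <- b_end_fwd - len + 1L
      a <- c(s - 1L, s - 1L + len)
      b <- c(b_start_fwd - 1L, b_start_fwd - 1L + len)
      if (b[1L] < a[1L]) { tmp <- a; a <- b; b <- tmp }
      if (b[1L] < a[2L]) next                # overlapping halves
      out <- rbind(out, data.frame(
        a_start = a[1L], a_end = a[2L], b_start = b[1L], b_end = b[2L],
        length_bp = len, orientation = "inverted"))
    }
  }
  if (is.null(out)) return(out)
  unique(out)
}

## named tip-state vector from a simulate_mk2 result
states_of <- function(sim) setNames(as.character(sim$tips),
                                    names(sim$tips))

mat_reference_subset <- function() {
  refs <- synthetic_reference_set()
  refs[names(refs) %in% c("MAT1-1-1", "MAT1-1-3", "MAT1-1-5",
                          "MAT1-1-13", "MAT1-2-1", "MAT1-2-10",
                          "APN2", "SLA2")]
}

## classify one generated architecture end to end
classify_architecture <- function(arch, seed) {
  g <- gen_mat_architecture(arch, seed = seed)
  loc <- locate_mat_locus(g$genome, mat_reference_subset())
  ctgs <- unique(stats::na.omit(loc$genes$contig))
  reps <- do.call(rbind, lapply(ctgs, function(ctg)
    detect_repeat_pairs(g$genome[[ctg]], 100L)))
  if (is.null(reps)) reps <- detect_repeat_pairs("", 100L)
  list(call = classify_thallism(loc$genes, reps, loc$split_anchors),
       truth = g$truth, locus = loc, repeats = reps)
}
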