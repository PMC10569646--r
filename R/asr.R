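# Two-state Markov (Mk2) ancestral-state reconstruction of thallism on a
# fixed rooted tree. States: 0 = homothallic, 1 = heterothallic,
# "?" = unknown (contributes a flat partial likelihood). The model is a
# two-state continuous-time Markov chain with gain/loss rates q01 and
# q10; likelihoods use Felsenstein pruning with per-node rescaling, node
# posteriors use the standard inside-outside (up-down) pass, and rate
# uncertainty is integrated by a Metropolis-Hastings sampler.

## encode a tip-state vector (named by tip label) as a 2-column partial
## likelihood matrix in the order of tree$tip.label
tip_partials <- function(tree, tips) {
  lbl <- tree$tip.label
  if (!all(lbl %in% names(tips)))
    stop("missing states for tips: ",
         paste(setdiff(lbl, names(tips)), collapse = ", "))
  s <- as.character(tips[lbl])
  if (!all(s %in% c("0", "1", "?", NA)))
    stop("tip states must be 0, 1 or ?")
  m <- matrix(1, length(lbl), 2L)
  m[s %in% "0", 2L] <- 0
  m[s %in% "1", 1L] <- 0
  m
}

check_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || !length(tree$tip.label))
    stop("tree has no tip labels")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  tree
}

resolve_prior <- function(root_prior, q01, q10) {
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == 2L,
              abs(sum(root_prior) - 1) < 1e-9)
    return(root_prior)
  }
  r <- q01 + q10
  if (r == 0) c(0.5, 0.5) else c(q10, q01) / r
}

## downpass over postorder edges; returns partials, per-edge transition
## entries, per-edge messages, and the log-scaling accumulator
mk2_downpass <- function(tree, tips, q01, q10) {
  tr <- ape::reorder.phylo(tree, "postorder")
  E <- tr$edge
  ne <- nrow(E)
  nn <- ape::Ntip(tr) + tr$Nnode
  r <- q01 + q10
  pi0 <- if (r == 0) 0.5 else q10 / r
  pi1 <- 1 - pi0
  ex <- exp(-r * tr$edge.length)
  P00 <- pi0 + pi1 * ex; P01 <- pi1 * (1 - ex)
  P10 <- pi0 * (1 - ex); P11 <- pi1 + pi0 * ex
  D <- matrix(1, nn, 2L)
  D[seq_len(ape::Ntip(tr)), ] <- tip_partials(tr, tips)
  msg <- matrix(NA_real_, ne, 2L)
  logscale <- 0
  for (i in seq_len(ne)) {
    p <- E[i, 1L]; ch <- E[i, 2L]
    m0 <- P00[i] * D[ch, 1L] + P01[i] * D[ch, 2L]
    m1 <- P10[i] * D[ch, 1L] + P11[i] * D[ch, 2L]
    msg[i, ] <- c(m0, m1)
    v0 <- D[p, 1L] * m0; v1 <- D[p, 2L] * m1
    s <- v0 + v1
    if (s <= 0) return(list(impossible = TRUE))
    D[p, ] <- c(v0, v1) / s
    logscale <- logscale + log(s)
  }
  list(tree = tr, edge = E, D = D, msg = msg,
       P = cbind(P00, P01, P10, P11), logscale = logscale,
       root = E[ne, 1L], prior0 = pi0, impossible = FALSE)
}

#' Log-likelihood of tip states under the two-state Markov model
#'
#' Felsenstein pruning with the exact two-state transition probabilities
#' `P(t) = Pi + (I - Pi) exp(-(q01+q10) t)`. Unknown (`?`) tips
#' contribute a flat partial likelihood.
#'
#' @param tree rooted `phylo` tree with branch lengths.
#' @param tips named vector of tip states (`0`, `1`, `?`).
#' @param q01 rate of the 0 to 1 (homothallic to heterothallic)
#'   transition.
#' @param q10 rate of the reverse transition.
#' @param root_prior `"stationary"` (default) or a numeric probability
#'   pair for states (0, 1).
#' @return log-likelihood.
#' @export
mk2_loglik <- function(tree, tips, q01, q10,
                       root_prior = "stationary") {
  check_tree(tree)
  stopifnot(q01 >= 0, q10 >= 0)
  dp <- mk2_downpass(tree, tips, q01, q10)
  if (dp$impossible) return(-Inf)
  prior <- resolve_prior(root_prior, q01, q10)
  lik <- sum(prior * dp$D[dp$root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + dp$logscale
}

#' Marginal ancestral-state posteriors at every node
#'
#' Standard inside-outside (up-down) marginalization: the posterior at a
#' node combines the downpass partial of its subtree with the outside
#' contribution of the rest of the tree, normalized per node.
#'
#' @inheritParams mk2_loglik
#' @return matrix with one row per node (tips first, in `tip.label`
#'   order, then internal nodes in ape numbering) and columns
#'   `P0` (homothallic), `P1` (heterothallic). Row names are tip labels
#'   and `node<k>`. Attribute `"loglik"` carries the log-likelihood.
#' @export
marginal_posteriors <- function(tree, tips, q01, q10,
                                root_prior = "stationary") {
  check_tree(tree)
  dp <- mk2_downpass(tree, tips, q01, q10)
  if (dp$impossible) stop("tip states have zero likelihood on this tree")
  prior <- resolve_prior(root_prior, q01, q10)
  E <- dp$edge
  ne <- nrow(E)
  nn <- nrow(dp$D)
  U <- matrix(NA_real_, nn, 2L)
  U[dp$root, ] <- prior
  ## reverse postorder = parents before children
  for (i in rev(seq_len(ne))) {
    p <- E[i, 1L]; ch <- E[i, 2L]
    sib <- which(E[, 1L] == p)
    sib <- sib[sib != i]
    out <- U[p, ]
    for (j in sib) out <- out * dp$msg[j, ]
    u0 <- dp$P[i, "P00"] * out[1L] + dp$P[i, "P10"] * out[2L]
    u1 <- dp$P[i, "P01"] * out[1L] + dp$P[i, "P11"] * out[2L]
    s <- u0 + u1
    U[ch, ] <- if (s > 0) c(u0, u1) / s else c(0.5, 0.5)
  }
  post <- U * dp$D
  post <- post / rowSums(post)
  ntip <- ape::Ntip(dp$tree)
  rownames(post) <- c(dp$tree$tip.label,
                      paste0("node", (ntip + 1L):nn))
  colnames(post) <- c("P0", "P1")
  lik <- sum(prior * dp$D[dp$root, ])
  attr(post, "loglik") <- log(lik) + dp$logscale
  post
}

#' Simulate tip states under the two-state Markov model
#'
#' The root state is drawn from the root prior and states evolve down
#' each branch with the exact two-state transition probabilities.
#'
#' @inheritParams mk2_loglik
#' @param seed optional integer seed (global RNG state is restored).
#' @return list with `tips` (named 0/1 vector) and `node_states`
#'   (0/1 vector over internal nodes, ape numbering).
#' @export
simulate_mk2 <- function(tree, q01, q10, root_prior = "stationary",
                         seed = NULL) {
  check_tree(tree)
  stopifnot(q01 >= 0, q10 >= 0)
  run <- function() {
    tr <- ape::reorder.phylo(tree, "postorder")
    E <- tr$edge
    ntip <- ape::Ntip(tr)
    nn <- ntip + tr$Nnode
    prior <- resolve_prior(root_prior, q01, q10)
    r <- q01 + q10
    pi0 <- if (r == 0) 0.5 else q10 / r
    ex <- exp(-r * tr$edge.length)
    state <- integer(nn)
    root <- E[nrow(E), 1L]
    state[root] <- rbinom(1L, 1L, prior[2L])
    for (i in rev(seq_len(nrow(E)))) {
      p1 <- if (state[E[i, 1L]] == 0L)
        (1 - pi0) * (1 - ex[i]) else 1 - pi0 * (1 - ex[i])
      state[E[i, 2L]] <- rbinom(1L, 1L, p1)
    }
    list(tips = setNames(state[seq_len(ntip)], tr$tip.label),
         node_states = state[(ntip + 1L):nn])
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Posterior sampling of Mk2 rates with model-averaged node posteriors
#'
#' Metropolis-Hastings on `(q01, q10)` (or a single shared rate when
#' `equal_rates = TRUE`) with independent exponential priors and
#' log-normal proposals. Node posteriors are averaged over the retained
#' samples. With the defaults, 1000 retained samples at a thinning
#' interval of 100 correspond to a 100,000-generation chain.
#'
#' @inheritParams mk2_loglik
#' @param n_samples retained samples (> 0).
#' @param thin generations between retained samples.
#' @param burnin_frac burn-in generations as a fraction of the chain.
#' @param prior_mean means of the exponential rate priors.
#' @param proposal_sd standard deviation of the log-scale proposal.
#' @param equal_rates constrain q01 = q10.
#' @param seed optional integer seed (global RNG state is restored).
#' @return list with `samples` (data.frame of q01, q10, loglik),
#'   `posterior` (averaged node-posterior matrix as in
#'   [marginal_posteriors()]), `acceptance` (rate), and `rate_summary`
#'   (posterior mean and sd per rate).
#' @export
mcmc_rates <- function(tree, tips, n_samples = 1000L, thin = 100L,
                       burnin_frac = 0.1, prior_mean = c(1, 1),
                       proposal_sd = 0.5, equal_rates = FALSE,
                       root_prior = "stationary", seed = NULL) {
  check_tree(tree)
  if (n_samples < 1L) stop("n_samples must be positive")
  run <- function() {
    ll <- function(q) mk2_loglik(tree, tips, q[1L], q[2L], root_prior)
    lprior <- function(q) sum(dexp(q, rate = 1 / prior_mean, log = TRUE))
    q <- c(0.5, 0.5)
    cur_ll <- ll(q)
    cur_lp <- lprior(q)
    ngen <- n_samples * thin
    nburn <- ceiling(burnin_frac * ngen)
    keep <- matrix(NA_real_, n_samples, 3L)
    acc <- 0L
    kept <- 0L
    post_sum <- NULL
    for (g in seq_len(ngen + nburn)) {
      u <- log(q)
      if (equal_rates) {
        u2 <- u + rnorm(1L, 0, proposal_sd)
      } else {
        u2 <- u + rnorm(2L, 0, proposal_sd)
      }
      q2 <- exp(u2)
      new_ll <- ll(q2)
      new_lp <- lprior(q2)
      ## symmetric proposal on log scale: include the log-Jacobian
      logr <- (new_ll + new_lp + sum(u2)) - (cur_ll + cur_lp + sum(u))
      if (is.finite(logr) && log(runif(1L)) < logr) {
        q <- q2; cur_ll <- new_ll; cur_lp <- new_lp
        acc <- acc + 1L
      }
      if (g > nburn && (g - nburn) %% thin == 0L) {
        kept <- kept + 1L
        keep[kept, ] <- c(q, cur_ll)
        mp <- marginal_posteriors(tree, tips, q[1L], q[2L], root_prior)
        post_sum <- if (is.null(post_sum)) mp else post_sum + mp
      }
    }
    if (acc == 0L)
      warning("no proposal accepted; consider retuning proposal_sd")
    samples <- data.frame(q01 = keep[, 1L], q10 = keep[, 2L],
                          loglik = keep[, 3L])
    post <- post_sum / n_samples
    attr(post, "loglik") <- NULL
    list(samples = samples, posterior = post,
         acceptance = acc / (ngen + nburn),
         rate_summary = data.frame(
           rate = c("q01", "q10"),
           mean = c(mean(samples$q01), mean(samples$q10)),
           sd = c(stats::sd(samples$q01), stats::sd(samples$q10))))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Read tip states from a TSV file
#'
#' Two columns: taxon and state (0/1/?).
#'
#' @param path file path.
#' @return named character vector of states.
#' @export
read_states_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character")
  setNames(df[[2L]], df[[1L]])
}

#' Write node posteriors as TSV
#'
#' @param post matrix from [marginal_posteriors()].
#' @param path output path.
#' @export
write_posteriors_tsv <- function(post, path) {
  out <- data.frame(node = rownames(post),
                    p_homothallic = post[, "P0"],
                    p_heterothallic = post[, "P1"])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
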