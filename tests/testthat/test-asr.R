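test_that("two-tip likelihoods match the analytic two-state forms", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  for (mu in c(0.1, 1, 10)) {
    e <- exp(-2 * mu)
    closed <- 0.5 * ((0.5 * (1 + e))^2 + (0.5 * (1 - e))^2)
    expect_equal(mk2_loglik(tr, c(a = "1", b = "1"), mu, mu,
                            root_prior = c(0.5, 0.5)),
                 log(closed), tolerance = 1e-12)
  }
  ## zero-branch limit: both tips mirror the root draw
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  expect_equal(mk2_loglik(tr0, c(a = "1", b = "1"), 1, 1, c(0.5, 0.5)),
               log(0.5))
  ## stationary limit: tips independent
  tr_inf <- ape::read.tree(text = "(a:500,b:500);")
  expect_equal(mk2_loglik(tr_inf, c(a = "1", b = "1"), 1, 1,
                          c(0.5, 0.5)), log(0.25), tolerance = 1e-9)
  expect_error(mk2_loglik(ape::read.tree(text = "(a:-1,b:1);"),
                          c(a = "1", b = "1"), 1, 1), "branch")
})

test_that("likelihood is invariant to child order at any node", {
  set.seed(111)
  tr <- ape::rtree(8)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
  st <- setNames(sample(c("0", "1"), 8, TRUE), tr$tip.label)
  l1 <- mk2_loglik(tr, st, 0.7, 0.4)
  tr2 <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(mk2_loglik(tr2, st, 0.7, 0.4), l1, tolerance = 1e-10)
})

test_that("marginal posteriors sum to one and match enumeration on
          small trees", {
  set.seed(112)
  for (i in 1:15) {
    n <- sample(3:6, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 2)
    st <- setNames(sample(c("0", "1", "?"), n, TRUE,
                          prob = c(.4, .4, .2)), tr$tip.label)
    if (all(st == "?")) st[1] <- "1"
    q01 <- runif(1, .1, 2); q10 <- runif(1, .1, 2)
    mp <- marginal_posteriors(tr, st, q01, q10)
    expect_true(all(abs(rowSums(mp) - 1) < 1e-9))
    ep <- enum_posteriors(tr, st, q01, q10)
    expect_lt(max(abs(mp - ep)), 1e-9)
  }
})

test_that("consensus and no-data limits behave as expected", {
  tr <- ape::stree(10, type = "star")
  tr$edge.length <- rep(0.01, 10)
  st <- setNames(rep("1", 10), tr$tip.label)
  mp <- marginal_posteriors(tr, st, 0.5, 0.5)
  expect_gt(mp["node11", "P1"], 0.999)
  ## all-unknown tips with the (default) stationary root prior: every
  ## node posterior equals that prior
  st_q <- setNames(rep("?", 10), tr$tip.label)
  mp_q <- marginal_posteriors(tr, st_q, 0.8, 0.2)
  expect_true(all(abs(mp_q[, "P0"] - 0.2) < 1e-9))
  ## with any root prior, the root posterior itself equals the prior
  mp_q2 <- marginal_posteriors(tr, st_q, 0.8, 0.2,
                               root_prior = c(0.3, 0.7))
  expect_equal(unname(mp_q2["node11", ]), c(0.3, 0.7), tolerance = 1e-9)
})

test_that("simulation respects rate limits and is seed-reproducible", {
  set.seed(113)
  tr <- ape::rtree(30)
  ## zero rates: all tips inherit the root state
  s0 <- simulate_mk2(tr, 0, 0, seed = 5)
  expect_equal(length(unique(s0$tips)), 1L)
  ## seed determinism
  expect_identical(simulate_mk2(tr, 0.5, 0.5, seed = 9),
                   simulate_mk2(tr, 0.5, 0.5, seed = 9))
  ## stationarity: large rates on long branches approach pi1 = q01/r
  tr2 <- ape::stree(400, type = "star")
  tr2$edge.length <- rep(50, 400)
  s <- simulate_mk2(tr2, 3, 1, seed = 11)
  p1 <- mean(s$tips == 1L)
  expect_lt(abs(p1 - 0.75), 3 * sqrt(0.75 * 0.25 / 400))
})

test_that("the rate sampler is seed-reproducible and recovers
          simulated rates", {
  coh <- gen_cohort(64, seed = 114)
  sim <- simulate_mk2(coh$tree, 0.6, 0.4, seed = 1)
  st <- states_of(sim)
  m1 <- mcmc_rates(coh$tree, st, n_samples = 50, thin = 5, seed = 3)
  m2 <- mcmc_rates(coh$tree, st, n_samples = 50, thin = 5, seed = 3)
  expect_identical(m1$samples, m2$samples)
  expect_error(mcmc_rates(coh$tree, st, n_samples = 0), "positive")

  m <- mcmc_rates(coh$tree, st, n_samples = 300, thin = 20, seed = 4)
  expect_gt(m$acceptance, 0.05)
  expect_lt(abs(m$rate_summary$mean[1] - 0.6),
            2 * m$rate_summary$sd[1] + 1e-9)
  ## averaged posteriors remain normalized
  expect_true(all(abs(rowSums(m$posterior) - 1) < 1e-6))
})

test_that("states and posteriors round-trip through TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tstate", "t1\t1", "t2\t0", "t3\t?"), f)
  st <- read_states_tsv(f)
  expect_equal(unname(st), c("1", "0", "?"))
  tr <- ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")
  mp <- marginal_posteriors(tr, st, 0.5, 0.5)
  fo <- withr::local_tempfile(fileext = ".tsv")
  write_posteriors_tsv(mp, fo)
  out <- read.table(fo, header = TRUE, sep = "\t")
  expect_equal(nrow(out), 5L)
  expect_equal(out$p_heterothallic + out$p_homothallic, rep(1, 5),
               tolerance = 1e-9)
})
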