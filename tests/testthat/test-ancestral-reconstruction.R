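test_that("pruning log-likelihood equals exhaustive enumeration", {
  m <- aa_model()
  tr <- parse_newick("((A:0.12,B:0.3):0.1,(C:0.2,D:0.05):0.07);")
  sim <- simulate_protein_alignment(tr, m, 2, seed = 3)
  ll <- compute_log_likelihood(sim$alignment, tr, m)
  expect_lt(abs(as.numeric(ll) - enum_loglik_protein(sim$alignment, tr, m)),
            1e-8)

  # with a gap: missing tips marginalize out
  seqs <- apply(unclass(sim$alignment), 1, paste, collapse = "")
  seqs["B"] <- paste0("-", substring(seqs["B"], 2))
  gapped <- protein_alignment(seqs)
  llg <- compute_log_likelihood(gapped, tr, m)
  expect_lt(abs(as.numeric(llg) - enum_loglik_protein(gapped, tr, m)), 1e-8)
})

test_that("likelihood limits and invariances hold", {
  m <- aa_model()
  # identical sequences joined by zero length: sum of log frequencies
  tz <- parse_newick("(A:0,B:0);")
  aln <- protein_alignment(c(A = "ACDE", B = "ACDE"))
  expect_equal(as.numeric(compute_log_likelihood(aln, tz, m)),
               4 * log(1 / 20), tolerance = 1e-10)

  # invariance under re-rooting (reversible model, pulley principle)
  tr <- make_study_fixture(2)
  sim <- simulate_protein_alignment(tr, m, 30, seed = 5)
  ll1 <- as.numeric(compute_log_likelihood(sim$alignment, tr, m))
  rr <- ape::root(ape::unroot(tr), outgroup = "Homo_sapiens",
                  resolve.root = TRUE)
  expect_lt(abs(ll1 - as.numeric(compute_log_likelihood(sim$alignment, rr,
                                                        m))), 1e-8)

  # invariance under taxon reordering of the alignment
  perm <- sample(rownames(sim$alignment))
  shuffled <- protein_alignment(unclass(sim$alignment)[perm, ])
  expect_equal(ll1, as.numeric(compute_log_likelihood(shuffled, tr, m)),
               tolerance = 1e-10)

  expect_error(compute_log_likelihood(
    protein_alignment(unclass(sim$alignment)[-1, ]), tr, m),
    "lacks taxa")
})

test_that("marginal posteriors equal brute-force Bayes on a 3-leaf tree", {
  m <- aa_model()
  tr <- parse_newick("((A:0.2,B:0.35):0.1,C:0.15);")
  sim <- simulate_protein_alignment(tr, m, 6, seed = 11)
  rec <- reconstruct_marginal(sim$alignment, tr, m)
  ti <- echoconv:::tree_index(tr)
  st <- echoconv:::tip_state_matrix(sim$alignment, tr, echoconv:::AA_STATES)
  plist <- lapply(ti$length, function(t) expm_pmat(m$Q * 1, t))
  for (s in 1:6) {
    for (node in 4:5) {
      expect_lt(max(abs(rec$posterior[as.character(node), s, ] -
                          enum_node_posterior(ti, st[, s], plist, m$freqs,
                                              node))), 1e-8)
    }
  }
})

test_that("posteriors normalize and constant columns reconstruct cleanly", {
  m <- aa_model()
  tr <- make_study_fixture(4, scale = 0.5)
  sim <- simulate_protein_alignment(tr, m, 40, seed = 7)
  rec <- reconstruct_marginal(sim$alignment, tr, m)
  expect_lt(max(abs(apply(rec$posterior, 1:2, sum) - 1)), 1e-9)
  expect_true(all(rec$prob > 0 & rec$prob <= 1 + 1e-12))

  const <- protein_alignment(matrix("W", nrow = 19, ncol = 3,
                                    dimnames = list(tr$tip.label, NULL)))
  rc <- reconstruct_marginal(const, tr, m)
  expect_true(all(rc$state == "W"))
  expect_true(all(rc$prob >= 0.99))

  td <- tidy(rec)
  expect_equal(nrow(td), 18 * 40)
  expect_true(all(c("gene", "node", "site", "state", "posterior",
                    "tie") %in% names(td)))
})

test_that("gamma rate heterogeneity mixes categories correctly", {
  mg <- aa_model(gamma_shape = 0.5, ncat = 4)
  expect_equal(mean(mg$rates), 1, tolerance = 1e-8)
  expect_equal(length(mg$rates), 4)
  tr <- parse_newick("((A:0.2,B:0.35):0.1,C:0.15);")
  sim <- simulate_protein_alignment(tr, aa_model(), 10, seed = 2)
  # mixture likelihood equals the average of per-rate likelihoods
  per_rate <- vapply(mg$rates, function(r) {
    trr <- tr
    trr$edge.length <- tr$edge.length * r
    as.numeric(compute_log_likelihood(sim$alignment, trr, aa_model()))
  }, numeric(1))
  mix <- as.numeric(compute_log_likelihood(sim$alignment, tr, mg))
  expect_equal(mix, sum(log(rowMeans(exp(
    vapply(mg$rates, function(r) {
      trr <- tr
      trr$edge.length <- tr$edge.length * r
      attr(compute_log_likelihood(sim$alignment, trr, aa_model()),
           "site_loglik")
    }, numeric(10)))))), tolerance = 1e-8)
  rec <- reconstruct_marginal(sim$alignment, tr, mg)
  expect_lt(max(abs(apply(rec$posterior, 1:2, sum) - 1)), 1e-9)
})

test_that("branch-length fitting is monotone and recovers truth", {
  m <- aa_model()
  # identical sequences drive lengths to zero
  t2 <- parse_newick("(A:0.3,B:0.2);")
  same <- protein_alignment(c(A = "ACDEFGHIKL", B = "ACDEFGHIKL"))
  f <- fit_branch_lengths(same, t2, m)
  expect_true(all(f$tree$edge.length < 1e-6))

  # fitted likelihood never drops below the starting likelihood
  tr <- selection_subtree(3)
  sim <- simulate_protein_alignment(tr, m, 300, seed = 31)
  start <- tr
  start$edge.length <- rep(0.08, nrow(tr$edge))
  ll0 <- as.numeric(compute_log_likelihood(sim$alignment, start, m))
  fit <- fit_branch_lengths(sim$alignment, start, m)
  expect_gte(fit$loglik, ll0)
  expect_true(fit$converged)

  # recovery study (reduced size): mean relative error <= 10% on long
  # alignments. Branch lengths are kept in an informative range
  # (>= 0.05 expected replacements/site, i.e. >= 100 expected changes in
  # 2,000 sites); below that the per-branch information bound alone
  # exceeds the target error.
  # comparison on the unrooted tree: under a reversible model only the
  # sum of the two root-adjacent lengths is identifiable
  errs <- unlist(lapply(1:4, function(r) {
    tt <- selection_subtree(40 + r)
    set.seed(140 + r)
    tt$edge.length <- stats::runif(nrow(tt$edge), 0.05, 0.3)
    sim <- simulate_protein_alignment(tt, m, 2000, seed = 50 + r)
    init <- tt
    init$edge.length <- rep(0.1, nrow(tt$edge))
    est <- fit_branch_lengths(sim$alignment, init, m)$tree
    tu <- ape::unroot(tt)
    eu <- ape::unroot(est)
    k <- match(edge_keys(tu), edge_keys(eu))
    abs(eu$edge.length[k] - tu$edge.length) / tu$edge.length
  }))
  expect_lte(mean(errs), 0.10)
})

test_that("branch-length estimates agree with an independent implementation", {
  skip_if_not_installed("phangorn")
  # WAG exchangeabilities, reordered to this package's alphabetical
  # residue convention
  wag <- get(".WAG", envir = asNamespace("phangorn"))
  ord_ph <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  M <- matrix(0, 20, 20, dimnames = list(ord_ph, ord_ph))
  M[lower.tri(M)] <- wag$Q
  M <- M + t(M)
  perm <- match(echoconv:::AA_STATES, ord_ph)
  m <- aa_model(M[perm, perm], freqs = as.numeric(wag$bf)[perm])
  tt <- selection_subtree(7)
  sim <- simulate_protein_alignment(tt, m, 500, seed = 77)
  init <- tt
  init$edge.length <- rep(0.1, nrow(tt$edge))
  ours <- fit_branch_lengths(sim$alignment, init, m)
  dat <- phangorn::phyDat(unclass(sim$alignment), type = "AA")
  fit <- phangorn::pml(ape::unroot(init), dat, model = "WAG",
                       bf = as.numeric(wag$bf))
  fit <- phangorn::optim.pml(fit, optEdge = TRUE, optBf = FALSE,
                             optQ = FALSE,
                             control = phangorn::pml.control(trace = 0))
  expect_equal(ours$loglik, as.numeric(stats::logLik(fit)), tolerance = 1e-4)
  # per-branch comparison: match unrooted edges by the tip bipartition
  our_unrooted <- ape::unroot(ours$tree)
  k1 <- edge_keys(our_unrooted)
  k2 <- edge_keys(fit$tree)
  shared <- intersect(k1, k2)
  expect_gt(length(shared), 10)
  expect_equal(our_unrooted$edge.length[match(shared, k1)],
               fit$tree$edge.length[match(shared, k2)], tolerance = 0.02)
})

test_that("reconstruction accuracy is high at low divergence and degrades with height", {
  m <- aa_model()
  acc_at <- function(scale, seeds, n_sites = 300) {
    mean(vapply(seeds, function(s) {
      tr <- make_study_fixture(s, scale = scale)
      sim <- simulate_protein_alignment(tr, m, n_sites, seed = 100 + s)
      rec <- reconstruct_marginal(sim$alignment, tr, m)
      ntip <- length(tr$tip.label)
      truth <- matrix(echoconv:::AA_STATES[
        sim$node_state[(ntip + 1):nrow(sim$node_state), ]], nrow = tr$Nnode)
      mean(rec$state == truth)
    }, numeric(1)))
  }
  low <- acc_at(0.6, 1:6)     # tree height ~0.25
  expect_gte(low, 0.95)
  mid <- acc_at(1.2, 1:3)
  high <- acc_at(3.5, 1:3)
  expect_gte(low, mid - 0.005)
  expect_gte(mid, high - 0.005)
})
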