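test_that("GY94 generator has the prescribed rate structure", {
  Q <- build_gy94(kappa = 2, omega = 0.5)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  sc <- sense_codons()
  # synonymous transition (TTT->TTC) vs nonsynonymous transversion
  # (TTT->TTA): ratio kappa/omega = 4 under uniform frequencies
  expect_equal(Q[sc == "TTT", sc == "TTC"] / Q[sc == "TTT", sc == "TTA"],
               4, tolerance = 1e-12)
  # multi-step changes are forbidden
  expect_equal(Q[sc == "TTT", sc == "AAT"], 0)
  expect_equal(Q[sc == "TTT", sc == "CCC"], 0)
  # mean rate at equilibrium is 1
  expect_equal(-sum(diag(Q)) / 61, 1, tolerance = 1e-12)

  # reversibility for non-uniform frequencies on random codon pairs
  set.seed(8)
  pi <- rgamma(61, 2)
  pi <- pi / sum(pi)
  Q2 <- build_gy94(3.1, 0.27, pi)
  idx <- cbind(sample(61, 1000, TRUE), sample(61, 1000, TRUE))
  expect_lt(max(abs(pi[idx[, 1]] * Q2[idx] -
                      pi[idx[, 2]] * Q2[idx[, 2:1]])), 1e-14)
  expect_error(build_gy94(2, 0.5, rep(0.5, 61)), "sum to 1")
})

test_that("F3x4 frequencies are a positive distribution over sense codons", {
  aln <- codon_alignment(c(a = "ATGAAACCCGGG", b = "ATGAAGCCAGGA"))
  pi <- codon_freqs_f3x4(aln)
  expect_equal(sum(pi), 1, tolerance = 1e-12)
  expect_true(all(pi > 0))
  expect_equal(length(pi), 61)
})

test_that("branch-site mixture likelihood equals exhaustive enumeration", {
  tr <- parse_newick("((A:0.2,B#1:0.3):0.1,(C:0.15,D:0.25):0.05);")
  par <- site_class_params(p0 = 0.5, p1 = 0.3, omega0 = 0.2, omega2 = 3,
                           kappa = 2)
  sim <- simulate_codon_alignment(tr, par, 3, seed = 4)
  ti <- echoconv:::tree_index(tr)
  fg <- echoconv:::foreground_mask(tr)[ti$orig_edge]
  pat <- echoconv:::compress_patterns(
    echoconv:::tip_state_matrix(sim$alignment, tr, sense_codons()))
  parts <- echoconv:::bs_class_loglik(ti, pat, fg, rep(1 / 61, 61),
                                      par$p0, par$p1, par$omega0,
                                      par$omega2, par$kappa)
  mine <- echoconv:::bs_mix_loglik(parts, pat$weights)
  oracle <- enum_loglik_branch_site(sim$alignment, tr, par)
  expect_lt(abs(mine - oracle), 1e-8)

  # single-class (omega2 = 1 collapses 2a/2b onto 0/1 rates) also agrees
  par1 <- site_class_params(p0 = 0.6, p1 = 0.4 - 1e-9, omega0 = 0.1,
                            omega2 = 1, kappa = 1.5)
  parts1 <- echoconv:::bs_class_loglik(ti, pat, fg, rep(1 / 61, 61),
                                       par1$p0, par1$p1, par1$omega0, 1,
                                       par1$kappa)
  expect_lt(abs(echoconv:::bs_mix_loglik(parts1, pat$weights) -
                  enum_loglik_branch_site(sim$alignment, tr, par1)), 1e-8)
})

test_that("alternative fit never falls below the null fit", {
  tr <- selection_subtree(1)
  for (s in 1:3) {
    sim <- simulate_codon_alignment(tr, site_class_params(), 120,
                                    seed = 600 + s)
    f0 <- fit_branch_site(sim$alignment, tr, null = TRUE,
                          branch_lengths = "fixed")
    f1 <- fit_branch_site(sim$alignment, tr, null = FALSE,
                          branch_lengths = "fixed", init = f0)
    expect_gte(f1$loglik, f0$loglik - 1e-6)
    expect_equal(f0$estimate[["omega2"]], 1)
    expect_gte(f1$estimate[["omega2"]], 1)
    est <- f1$estimate
    expect_true(est[["p0"]] >= 0 && est[["p1"]] >= 0 &&
                  est[["p0"]] + est[["p1"]] <= 1)
    expect_true(est[["omega0"]] > 0 && est[["omega0"]] < 1)
    # class posteriors are a distribution per site
    expect_lt(max(abs(rowSums(f1$class_posterior) - 1)), 1e-9)
  }
  expect_error(fit_branch_site(sim$alignment,
                               make_study_fixture(1), null = TRUE),
               "FOREGROUND")
})

test_that("likelihood is invariant to alignment row order", {
  tr <- selection_subtree(2)
  sim <- simulate_codon_alignment(tr, site_class_params(), 80, seed = 9)
  f1 <- fit_branch_site(sim$alignment, tr, null = TRUE,
                        branch_lengths = "fixed")
  perm <- sample(rownames(sim$alignment))
  shuf <- codon_alignment(
    stats::setNames(apply(unclass(sim$alignment)[perm, ], 1, paste,
                          collapse = ""), perm))
  f2 <- fit_branch_site(shuf, tr, null = TRUE, branch_lengths = "fixed")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("M0 branch-length estimation recovers simulated lengths", {
  tr <- selection_subtree(5)
  sim <- simulate_codon_alignment(tr, site_class_params(p0 = 0.999,
                                                        p1 = 0.001,
                                                        omega0 = 0.3),
                                  400, seed = 12)
  pi <- codon_freqs_f3x4(sim$alignment)
  ts <- echoconv:::tip_state_matrix(sim$alignment, tr, sense_codons())
  start <- tr
  start$edge.length <- rep(0.05, nrow(tr$edge))
  m0 <- echoconv:::fit_m0(ts, start, pi)
  # compare unrooted: the root-edge split is unidentifiable under a
  # reversible model
  tu <- ape::unroot(tr)
  eu <- ape::unroot(m0$tree)
  k <- match(edge_keys(tu), edge_keys(eu))
  expect_gt(stats::cor(eu$edge.length[k], tu$edge.length), 0.9)
  expect_lt(abs(m0$omega - 0.3), 0.12)
  expect_lt(abs(m0$kappa - 2), 0.8)
})

test_that("the LRT maps statistics to chi-square tail probabilities", {
  f_like <- function(gene, null, ll) {
    structure(list(gene = gene, null = null, loglik = ll),
              class = "branch_site_fit")
  }
  same <- lrt(f_like("g", FALSE, -100), f_like("g", TRUE, -100))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  crit <- lrt(f_like("g", FALSE, -100), f_like("g", TRUE, -100 - 3.841 / 2))
  expect_equal(crit$p_value, 0.05, tolerance = 1e-3)
  # numerical jitter below the null clamps to zero
  jit <- lrt(f_like("g", FALSE, -100.0000001), f_like("g", TRUE, -100))
  expect_equal(jit$statistic, 0)
  expect_error(lrt(f_like("g1", FALSE, -1), f_like("g2", TRUE, -1)),
               "different genes")
  expect_error(lrt(f_like("g", TRUE, -1), f_like("g", TRUE, -1)),
               "alternative, null")
})

test_that("Benjamini-Hochberg adjustment is the step-up procedure", {
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand-computed step-up on an unsorted vector
  p <- c(0.03, 0.002, 0.2, 0.04)
  expect_equal(fdr_adjust(p), c(0.16 / 3, 0.008, 0.2, 0.16 / 3),
               tolerance = 1e-12)
  # order-preserving with the input: q follows the rank order of p
  set.seed(3)
  p2 <- runif(50)
  q2 <- fdr_adjust(p2)
  expect_true(all(diff(q2[order(p2)]) >= -1e-15))
  expect_true(all(q2 >= p2))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BEB refuses unconverged fits and flags no null sites", {
  tr <- selection_subtree(3)
  sim <- simulate_codon_alignment(tr, site_class_params(), 100, seed = 31)
  f1 <- fit_branch_site(sim$alignment, tr, null = FALSE,
                        branch_lengths = "fixed")
  bad <- f1
  bad$converged <- FALSE
  expect_error(beb_sites(bad), "did not converge")
  expect_error(beb_sites(fit_branch_site(sim$alignment, tr, null = TRUE,
                                         branch_lengths = "fixed")),
               "alternative")
  beb <- beb_sites(f1)
  expect_equal(nrow(beb), 100)
  expect_true(all(beb$posterior >= 0 & beb$posterior <= 1))
})

test_that("power to detect selection increases with omega2", {
  tr <- selection_subtree(4, config = "CF")
  stat_at <- function(om2, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_codon_alignment(
        tr, site_class_params(omega2 = om2), 150,
        seed = substream_seed(800 + om2 * 10, s))
      f0 <- fit_branch_site(sim$alignment, tr, null = TRUE,
                            branch_lengths = "fixed")
      f1 <- fit_branch_site(sim$alignment, tr, null = FALSE,
                            branch_lengths = "fixed", init = f0)
      lrt(f1, f0)$statistic
    }, numeric(1)))
  }
  seeds <- 1:4
  s2 <- stat_at(2, seeds)
  s8 <- stat_at(8, seeds)
  expect_gte(s8, s2)
})
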