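test_that("classification criteria reproduce enumerated truth over all state triples", {
  # two tested terminal branches with hand-set ancestral states; every
  # (parent A, parent B, shared derived) combination enumerated
  tr <- parse_newick("((A:0.1,C:0.1):0.1,(B:0.1,D:0.1):0.1);")
  AA <- echoconv:::AA_STATES
  combos <- expand.grid(a = AA, b = AA, d = AA, stringsAsFactors = FALSE)
  S <- nrow(combos)
  pa_states <- combos$a
  pb_states <- combos$b
  tips <- c(A = paste(combos$d, collapse = ""),
            B = paste(combos$d, collapse = ""),
            C = paste(rep("A", S), collapse = ""),
            D = paste(rep("A", S), collapse = ""))
  ntip <- 4
  rec <- stub_recon(tr, tips, list(
    "5" = rep("A", S),                 # root, irrelevant to the criteria
    "6" = pa_states,                   # parent of A (and C)
    "7" = pb_states))                  # parent of B (and D)
  calls <- classify_pair(rec, "A", "B")
  truth_call <- combos$d != combos$a & combos$d != combos$b
  expect_identical(sort(calls$site), which(truth_call))
  truth_type <- ifelse(combos$a == combos$b, "parallel", "convergent")
  expect_identical(calls$type[order(calls$site)],
                   truth_type[truth_call])
  # forced examples from the definition
  pick <- function(a, b, d) which(combos$a == a & combos$b == b &
                                    combos$d == d)
  expect_true(pick("A", "A", "S") %in% calls$site[calls$type == "parallel"])
  expect_true(pick("A", "T", "S") %in% calls$site[calls$type == "convergent"])
  expect_false(pick("A", "A", "A") %in% calls$site)

  # differing extant residues are never called: with B fixed at "W",
  # only combos whose derived residue is "W" can satisfy criterion 1
  tips2 <- tips
  tips2["B"] <- paste(rep("W", S), collapse = "")
  rec2 <- stub_recon(tr, tips2, list("5" = rep("A", S), "6" = pa_states,
                                     "7" = pb_states))
  some <- classify_pair(rec2, "A", "B")
  expect_true(all(combos$d[some$site] == "W"))
})

test_that("pair classification is symmetric and rejects nested branches", {
  m <- aa_model()
  tr <- make_study_fixture(6, scale = 0.6)
  sim <- simulate_protein_alignment(tr, m, 150, seed = 3)
  rec <- reconstruct_marginal(sim$alignment, tr, m)
  ab <- classify_pair(rec, "Aselliscus_stoliczkanus", "Orcinus_orca")
  ba <- classify_pair(rec, "Orcinus_orca", "Aselliscus_stoliczkanus")
  expect_equal(ab$site, ba$site)
  expect_equal(ab$type, ba$type)
  expect_equal(ab$parent_a, ba$parent_b)
  # every call is exactly one of parallel/convergent
  expect_true(all(ab$type %in% c("parallel", "convergent")))
  root_child <- tr$edge[tr$edge[, 1] == 20, 2][1]
  expect_error(classify_pair(rec, root_child,
                             match("Homo_sapiens", tr$tip.label)),
               "paraphyletic")
})

test_that("substitution calls match the definition and the true history", {
  m <- aa_model()
  tr <- parse_newick("((A:0.1,C:0.1):0.1,(B:0.1,D:0.1):0.1);")
  # identical parent and child everywhere: no substitutions
  rec <- stub_recon(tr, c(A = "AAAA", B = "AAAA", C = "AAAA", D = "AAAA"),
                    list("5" = rep("A", 4), "6" = rep("A", 4),
                         "7" = rep("A", 4)))
  expect_equal(nrow(call_substitutions(rec, "A")), 0)
  # constructed column parent = A, child = S
  rec2 <- stub_recon(tr, c(A = "SAAA", B = "AAAA", C = "AAAA", D = "AAAA"),
                     list("5" = rep("A", 4), "6" = rep("A", 4),
                          "7" = rep("A", 4)))
  cs <- call_substitutions(rec2, "A")
  expect_equal(cs$site, 1L)
  expect_equal(cs$parent_state, "A")
  expect_equal(cs$child_state, "S")
  expect_error(call_substitutions(rec2, "Z"), "not in tree")

  # precision against the true history at low divergence
  prec <- vapply(1:5, function(r) {
    tt <- make_study_fixture(60 + r, scale = 0.6)
    sim <- simulate_protein_alignment(tt, m, 400, seed = 70 + r)
    rc <- reconstruct_marginal(sim$alignment, tt, m)
    leaf <- "Tursiops_truncatus"
    got <- call_substitutions(rc, leaf)
    ch <- match(leaf, tt$tip.label)
    true_sites <- unique(sim$history$site[sim$history$branch == ch])
    if (nrow(got) == 0) return(NA_real_)
    mean(got$site %in% true_sites)
  }, numeric(1))
  expect_gte(mean(prec, na.rm = TRUE), 0.95)
})

test_that("excess-test expectations match a 100,000-draw Monte-Carlo oracle", {
  m <- aa_model()
  tr <- make_study_fixture(7, scale = 3)   # deep tree: many substitutions
  sim <- simulate_protein_alignment(tr, m, 200, seed = 17)
  rec <- reconstruct_marginal(sim$alignment, tr, m)
  pair <- c("Aselliscus_stoliczkanus", "Taphozous_melanopogon")
  ex <- convergence_excess_test(rec, pair[1], pair[2], m)
  sub_a <- call_substitutions(rec, pair[1])
  sub_b <- call_substitutions(rec, pair[2])
  shared <- intersect(sub_a$site, sub_b$site)
  expect_gt(length(shared), 2)   # the fixture must exercise the sum

  rp <- echoconv:::replacement_probs(m)
  set.seed(99)
  R <- 100000
  mc_par <- numeric(R); mc_con <- numeric(R)
  for (s in shared) {
    a <- match(sub_a$parent_state[sub_a$site == s], echoconv:::AA_STATES)
    b <- match(sub_b$parent_state[sub_b$site == s], echoconv:::AA_STATES)
    xa <- sample.int(20, R, replace = TRUE, prob = rp[a, ])
    xb <- sample.int(20, R, replace = TRUE, prob = rp[b, ])
    same <- xa == xb
    if (a == b) mc_par <- mc_par + same
    else mc_con <- mc_con + (same & xa != a & xa != b)
  }
  expect_lt(abs(ex$exp_parallel - mean(mc_par)),
            3 * stats::sd(mc_par) / sqrt(R) + 1e-12)
  expect_lt(abs(ex$exp_convergent - mean(mc_con)),
            3 * stats::sd(mc_con) / sqrt(R) + 1e-12)
  expect_true(ex$p_parallel >= 0 && ex$p_parallel <= 1)
  expect_true(ex$p_convergent >= 0 && ex$p_convergent <= 1)
})

test_that("excess test degenerates gracefully with no substitutions", {
  tr <- parse_newick("((A:0.1,C:0.1):0.1,(B:0.1,D:0.1):0.1);")
  rec <- stub_recon(tr, c(A = "AAAA", B = "CCCC", C = "AAAA", D = "CCCC"),
                    list("5" = rep("A", 4), "6" = rep("A", 4),
                         "7" = rep("C", 4)))
  ex <- convergence_excess_test(rec, "A", "B", aa_model())
  expect_equal(ex$exp_parallel, 0)
  expect_equal(ex$exp_convergent, 0)
  expect_equal(ex$p_parallel, 1)
  expect_equal(ex$p_convergent, 1)
})

test_that("null simulations keep the excess-test rejection rate near nominal", {
  m <- aa_model()
  tr <- make_study_fixture(8, scale = 1.5)
  pair <- c("Aselliscus_stoliczkanus", "Tursiops_truncatus")
  ps <- vapply(1:120, function(r) {
    sim <- simulate_protein_alignment(tr, m, 120,
                                      seed = substream_seed(300, r))
    rec <- reconstruct_marginal(sim$alignment, tr, m)
    ex <- convergence_excess_test(rec, pair[1], pair[2], m)
    c(ex$p_parallel, ex$p_convergent)
  }, numeric(2))
  expect_lte(mean(ps[1, ] < 0.05), 0.08)
  expect_lte(mean(ps[2, ] < 0.05), 0.08)
})

test_that("pair summaries count genes once and find core parallel genes", {
  design <- study_design()[study_design()$side == "echo", ]
  empty <- summarize_pairs(
    tibble::tibble(gene = character(0), site = integer(0),
                   type = character(0), pair = character(0)), design)
  expect_true(all(empty$summary$parallel_genes == 0))
  expect_equal(empty$core_genes, character(0))

  pairs <- unique(design$pair)
  calls <- dplyr::bind_rows(lapply(pairs, function(p)
    tibble::tibble(gene = "g1", site = c(10L, 11L), type = "parallel",
                   pair = p)))
  one <- summarize_pairs(calls, design)
  expect_true(all(one$summary$parallel_genes == 1))
  expect_true(all(one$summary$parallel_sites == 2))
  expect_equal(one$core_genes, "g1")

  # a gene missing from one comparison is not core
  two <- summarize_pairs(calls[calls$pair != pairs[1], ], design)
  expect_equal(two$core_genes, character(0))
  expect_error(summarize_pairs(calls, design[-1, ]), "lacks")
})

test_that("echo vs matched-control counts are exchangeable under the null", {
  # negative-control harness: on selection-free simulations the paired
  # echo-minus-control difference is centred at zero
  m <- aa_model()
  design <- study_design()
  ok <- vapply(1:5, function(run) {
    tr <- make_study_fixture(400 + run, scale = 1)
    calls <- list()
    for (g in 1:8) {
      sim <- simulate_protein_alignment(
        tr, m, 150, seed = substream_seed(500 + run, g))
      rec <- reconstruct_marginal(sim$alignment, tr, m)
      for (r in seq_len(nrow(design))) {
        d <- design[r, ]
        cl <- classify_pair(rec, d$branch_a, d$branch_b)
        if (nrow(cl)) {
          cl$pair <- d$pair; cl$side <- d$side; cl$row <- d$row
          cl$gene <- paste0("g", g)
          calls[[length(calls) + 1]] <- cl
        }
      }
    }
    calls <- dplyr::bind_rows(calls)
    tab <- echoconv:::pipeline_paired_table(calls, design)
    p <- tryCatch(
      paired_t_test(tab, "parallel_sites")$p_value,
      error = function(e) 1)   # zero-variance differences: no signal
    p > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})
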