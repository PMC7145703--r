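# Independent oracles used across the suite. These never call the
# package's pruning/posterior code paths: transition matrices come from
# Matrix::expm and likelihoods from literal enumeration over all internal
# state assignments.

expm_pmat <- function(Q, t) as.matrix(Matrix::expm(Q * t))

# Exhaustive single-site likelihood: sum over every assignment of states
# to internal nodes. `tipstates_col` is an integer vector over tips (NA =
# missing), `plist` transition matrices per postorder edge row.
enum_site_lik <- function(ti, tipstates_col, plist, pi) {
  n <- length(pi)
  internals <- (ti$ntip + 1L):(ti$ntip + ti$nnode)
  grid <- do.call(expand.grid, rep(list(seq_len(n)), length(internals)))
  st <- matrix(NA_integer_, nrow(grid), ti$ntip + ti$nnode)
  for (i in seq_len(ti$ntip)) st[, i] <- tipstates_col[i]
  for (j in seq_along(internals)) st[, internals[j]] <- grid[[j]]
  p <- pi[st[, ti$root]]
  for (k in seq_len(nrow(ti$edge))) {
    ch <- ti$edge[k, 2]
    if (ch <= ti$ntip && is.na(tipstates_col[ch])) next
    p <- p * plist[[k]][cbind(st[, ti$edge[k, 1]], st[, ch])]
  }
  sum(p)
}

# Exhaustive marginal posterior of one internal node at one site.
enum_node_posterior <- function(ti, tipstates_col, plist, pi, node) {
  n <- length(pi)
  post <- vapply(seq_len(n), function(x) {
    internals <- (ti$ntip + 1L):(ti$ntip + ti$nnode)
    grid <- do.call(expand.grid, rep(list(seq_len(n)), length(internals)))
    grid <- grid[grid[[match(node, internals)]] == x, , drop = FALSE]
    st <- matrix(NA_integer_, nrow(grid), ti$ntip + ti$nnode)
    for (i in seq_len(ti$ntip)) st[, i] <- tipstates_col[i]
    for (j in seq_along(internals)) st[, internals[j]] <- grid[[j]]
    p <- pi[st[, ti$root]]
    for (k in seq_len(nrow(ti$edge))) {
      ch <- ti$edge[k, 2]
      if (ch <= ti$ntip && is.na(tipstates_col[ch])) next
      p <- p * plist[[k]][cbind(st[, ti$edge[k, 1]], st[, ch])]
    }
    sum(p)
  }, numeric(1))
  post / sum(post)
}

# Full-alignment exhaustive log-likelihood under an aa_model.
enum_loglik_protein <- function(aln, tree, model) {
  ti <- echoconv:::tree_index(tree)
  st <- echoconv:::tip_state_matrix(aln, tree, echoconv:::AA_STATES)
  plist <- lapply(ti$length, function(t) expm_pmat(model$Q, t))
  sum(vapply(seq_len(ncol(st)), function(s)
    log(enum_site_lik(ti, st[, s], plist, model$freqs)), numeric(1)))
}

# Exhaustive model-A mixture log-likelihood for a codon alignment.
enum_loglik_branch_site <- function(aln, tree, params, pi = rep(1 / 61, 61)) {
  gen <- echoconv:::model_a_generators(params)
  ti <- echoconv:::tree_index(tree)
  fg <- echoconv:::foreground_mask(tree)[ti$orig_edge]
  st <- echoconv:::tip_state_matrix(aln, tree, sense_codons())
  Qbg <- list(gen$Q$omega0, gen$Q$omega1, gen$Q$omega0, gen$Q$omega1)
  Qfg <- list(gen$Q$omega0, gen$Q$omega1, gen$Q$omega2, gen$Q$omega2)
  total <- 0
  for (s in seq_len(ncol(st))) {
    site <- 0
    for (cl in 1:4) {
      plist <- lapply(seq_len(nrow(ti$edge)), function(k)
        expm_pmat(if (fg[k]) Qfg[[cl]] else Qbg[[cl]], ti$length[k]))
      site <- site + gen$prop[cl] * enum_site_lik(ti, st[, s], plist, pi)
    }
    total <- total + log(site)
  }
  total
}

# Hand-built reconstruction object with chosen ancestral states, for
# exercising the classification criteria against enumerated truth.
stub_recon <- function(tree, tip_seqs, internal_states) {
  aln <- protein_alignment(tip_seqs, gene_id = "stub")
  tipstates <- echoconv:::tip_state_matrix(aln, tree, echoconv:::AA_STATES)
  S <- ncol(tipstates)
  ntip <- length(tree$tip.label)
  state <- do.call(rbind, internal_states)
  rownames(state) <- names(internal_states)
  prob <- matrix(1, nrow(state), S, dimnames = list(rownames(state), NULL))
  structure(
    list(posterior = NULL, state = state, prob = prob,
         tie = prob > 2, loglik = NA_real_, tree = tree,
         tipstates = tipstates, tip_label = tree$tip.label,
         gene_id = "stub"),
    class = "ancestral_reconstruction"
  )
}

# 8-taxon subtree (CF + FM bats + human outgroup) used by the codon
# simulation studies.
selection_subtree <- function(seed = 1, config = "CF") {
  tr <- make_study_fixture(seed)
  keep <- c(study_lineages()$CF, study_lineages()$FM, "Homo_sapiens")
  mark_foreground(ape::keep.tip(tr, keep), config)
}

# alignment body as a plain character matrix (class/gene attributes
# stripped), for exact comparisons
aln_matrix <- function(a) {
  m <- unclass(a)
  attr(m, "gene_id") <- NULL
  m
}

# bipartition key per edge (child-side tip set) for matching branches
# between trees, typically after ape::unroot()
edge_keys <- function(tr) {
  vapply(seq_len(nrow(tr$edge)), function(e) {
    ch <- tr$edge[e, 2]
    tips <- if (ch <= length(tr$tip.label)) tr$tip.label[ch] else
      ape::extract.clade(tr, ch)$tip.label
    paste(sort(tips), collapse = "|")
  }, character(1))
}
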