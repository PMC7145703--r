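#' Marginal empirical-Bayes ancestral amino-acid reconstruction
#'
#' For every internal node and alignment site, the marginal posterior
#' distribution over the 20 residues given the tip data, with model
#' parameters and branch lengths fixed at their (empirical-Bayes)
#' estimates. Computed by a down-pass (pruning) and an up-pass; the
#' posterior at node v is proportional to the inside partial times the
#' outside partial. The argmax state is recorded per node/site; exact
#' posterior ties are broken toward the alphabetically first residue and
#' flagged.
#'
#' Node identifiers follow ape's numbering of the input tree: tips are
#' `1..ntip` in `tree$tip.label` order and internal nodes
#' `(ntip+1)..(ntip+Nnode)` with the root at `ntip+1`.
#'
#' @param aln A `protein_alignment`.
#' @param tree Rooted `phylo` with branch lengths (typically from
#'   [fit_branch_lengths()]).
#' @param model An [aa_model()].
#' @return An object of class `ancestral_reconstruction`: list with
#'   `posterior` (3-d array internal node x site x state), `state`
#'   (character matrix of argmax states), `prob` (their posteriors),
#'   `tie` (logical matrix), `loglik`, `tree`, `aln`, `gene_id`.
#' @export
reconstruct_marginal <- function(aln, tree, model) {
  stopifnot(inherits(aln, "protein_alignment"), inherits(model, "aa_model"))
  ti <- tree_index(tree)
  tipstates <- tip_state_matrix(aln, tree, AA_STATES)
  S <- ncol(tipstates)
  nstates <- length(AA_STATES)
  nint <- ti$nnode
  rates <- model$rates
  wts <- model$rate_weights

  # per rate category: joint posterior accumulation P(state, rate | data)
  post <- array(0, dim = c(nint, S, nstates))
  site_ll_by_rate <- matrix(0, length(rates), S)
  store <- vector("list", length(rates))
  for (r in seq_along(rates)) {
    plist <- lapply(ti$length * rates[r], pmat, eig = model$eig)
    pr <- prune_pass(ti, tipstates, plist, model$freqs, keep = TRUE)
    U <- up_pass(ti, pr, plist, model$freqs)
    site_ll_by_rate[r, ] <- pr$site_loglik
    store[[r]] <- list(pr = pr, U = U)
  }
  lw <- log(wts)
  site_ll <- log_colsums_exp(site_ll_by_rate + lw)
  # P(rate | data per site)
  rate_post <- exp(site_ll_by_rate + lw - rep(site_ll, each = length(rates)))
  for (r in seq_along(rates)) {
    pr <- store[[r]]$pr
    U <- store[[r]]$U
    for (v in seq_len(nint)) {
      node <- ti$ntip + v
      m <- pr$partial[[node]] * U[[node]]   # nstates x S, unnormalized
      cs <- .colSums(m, nstates, S)
      m <- m * rep(rate_post[r, ] / cs, each = nstates)
      post[v, , ] <- post[v, , ] + t(m)
    }
  }

  state_idx <- matrix(0L, nint, S)
  prob <- matrix(0, nint, S)
  tie <- matrix(FALSE, nint, S)
  for (v in seq_len(nint)) {
    pv <- post[v, , , drop = TRUE]
    if (S == 1L) pv <- matrix(pv, nrow = 1)
    idx <- max.col(pv, ties.method = "first")
    mx <- pv[cbind(seq_len(S), idx)]
    state_idx[v, ] <- idx
    prob[v, ] <- mx
    tie[v, ] <- rowSums(abs(pv - mx) < 1e-12) > 1L
  }
  state <- matrix(AA_STATES[state_idx], nint, S)
  rownames(state) <- rownames(prob) <- rownames(tie) <-
    as.character(ti$ntip + seq_len(nint))
  dimnames(post) <- list(as.character(ti$ntip + seq_len(nint)), NULL, AA_STATES)

  structure(
    list(posterior = post, state = state, prob = prob, tie = tie,
         loglik = sum(site_ll), site_loglik = site_ll, tree = tree,
         tipstates = tipstates, tip_label = ti$tip_label,
         gene_id = gene_id(aln)),
    class = "ancestral_reconstruction"
  )
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat("Marginal ancestral reconstruction: gene", x$gene_id, "\n")
  cat("  ", nrow(x$state), "internal nodes x", ncol(x$state), "sites;",
      "log-likelihood", format(x$loglik, digits = 8), "\n")
  invisible(x)
}

#' Tidy an ancestral reconstruction
#'
#' @param x An `ancestral_reconstruction`.
#' @param ... Unused.
#' @return Tibble with one row per internal node x site: `gene`, `node`,
#'   `site`, `state`, `posterior`, `tie`.
#' @method tidy ancestral_reconstruction
#' @export
tidy.ancestral_reconstruction <- function(x, ...) {
  nint <- nrow(x$state)
  S <- ncol(x$state)
  tibble::tibble(
    gene = x$gene_id,
    node = rep(as.integer(rownames(x$state)), times = S),
    site = rep(seq_len(S), each = nint),
    state = as.vector(x$state),
    posterior = as.vector(x$prob),
    tie = as.vector(x$tie)
  )
}

# state (residue) at a node for each site: tips come from the alignment
# (NA for gap/ambiguity), internal nodes from the reconstruction argmax.
node_states <- function(recon, node) {
  ntip <- length(recon$tip_label)
  if (node <= ntip) {
    st <- recon$tipstates[node, ]
    ifelse(is.na(st), NA_character_, AA_STATES[st])
  } else {
    recon$state[as.character(node), ]
  }
}

node_posteriors <- function(recon, node) {
  ntip <- length(recon$tip_label)
  if (node <= ntip) {
    st <- recon$tipstates[node, ]
    ifelse(is.na(st), NA_real_, 1)
  } else {
    recon$prob[as.character(node), ]
  }
}
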