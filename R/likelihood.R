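# Felsenstein pruning on an arbitrary finite state space, with per-column
# rescaling so alignments up to at least 10,000 sites x 50 taxa do not
# underflow. The same engine drives amino-acid likelihoods/ancestral
# reconstruction and (via per-class transition matrices) the codon
# branch-site mixture.

# Precomputed traversal of a rooted phylo: postorder edge list keyed so
# every child appears before its parent.
tree_index <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  # map postorder edge rows back to original edge rows (by child node,
  # which is unique)
  orig <- match(po$edge[, 2], tree$edge[, 2])
  edge <- po$edge
  storage.mode(edge) <- "integer"
  list(
    edge = edge,
    length = tree$edge.length[orig],
    orig_edge = orig,
    ntip = ntip,
    nnode = tree$Nnode,
    root = ntip + 1L,
    tip_label = tree$tip.label
  )
}

# Integer tip states (rows ordered by tip number, NA = gap/ambiguity).
tip_state_matrix <- function(aln, tree, states) {
  missing <- setdiff(tree$tip.label, rownames(aln))
  if (length(missing)) {
    stop("alignment lacks taxa present in tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- unclass(aln)[tree$tip.label, , drop = FALSE]
  out <- matrix(match(m, states), nrow = nrow(m))
  rownames(out) <- tree$tip.label
  out
}

# Core pruning pass. `plist` is a list over postorder edge rows of
# transition matrices P for that edge. Returns per-site log-likelihood
# and, if keep = TRUE, per-node partials/scales and per-edge messages for
# the up-pass.
prune_pass <- function(ti, tipstates, plist, pi, keep = FALSE) {
  nstates <- length(pi)
  S <- ncol(tipstates)
  nn <- ti$ntip + ti$nnode
  if (!keep) {
    ts <- tipstates
    ts[is.na(ts)] <- 0L
    storage.mode(ts) <- "integer"
    ll <- cpp_prune_loglik(ti$edge, plist, ts, pi, nn, ti$root)
    return(list(site_loglik = as.numeric(ll)))
  }
  partial <- vector("list", nn)
  lscale <- vector("list", nn)
  msg <- if (keep) vector("list", nrow(ti$edge)) else NULL

  for (k in seq_len(nrow(ti$edge))) {
    pa <- ti$edge[k, 1]
    ch <- ti$edge[k, 2]
    P <- plist[[k]]
    if (ch <= ti$ntip) {
      st <- tipstates[ch, ]
      M <- matrix(1, nstates, S)
      obs <- which(!is.na(st))
      if (length(obs)) M[, obs] <- P[, st[obs]]
      sc <- numeric(S)
    } else {
      M <- P %*% partial[[ch]]
      sc <- lscale[[ch]]
    }
    if (keep) msg[[k]] <- list(M = M, sc = sc)
    if (is.null(partial[[pa]])) {
      partial[[pa]] <- M
      lscale[[pa]] <- sc
    } else {
      M2 <- partial[[pa]] * M
      cs <- .colSums(M2, nstates, S)
      cs[cs == 0] <- 1e-300
      partial[[pa]] <- M2 * rep(1 / cs, each = nstates)
      lscale[[pa]] <- lscale[[pa]] + sc + log(cs)
    }
  }
  rootp <- partial[[ti$root]]
  site_l <- .colSums(rootp * pi, nstates, S)
  ll <- log(site_l) + lscale[[ti$root]]
  if (!keep) {
    return(list(site_loglik = ll))
  }
  list(site_loglik = ll, partial = partial, lscale = lscale, msg = msg,
       site_l = site_l)
}

# Up-pass: for every node v, the "outside" partial U_v(x) proportional to
# P(data outside subtree(v), state x at v), including the root prior.
# Needs the msg list from prune_pass(keep = TRUE). Rescaled per column;
# only ratios are used downstream.
up_pass <- function(ti, pr, plist, pi) {
  nstates <- length(pi)
  S <- length(pr$site_loglik)
  nn <- ti$ntip + ti$nnode
  U <- vector("list", nn)
  U[[ti$root]] <- matrix(pi, nstates, S)
  ne <- nrow(ti$edge)
  # preorder = reverse postorder
  children_of <- split(seq_len(ne), ti$edge[, 1])
  for (k in rev(seq_len(ne))) {
    pa <- ti$edge[k, 1]
    ch <- ti$edge[k, 2]
    sibs <- setdiff(children_of[[as.character(pa)]], k)
    W <- U[[pa]]
    for (j in sibs) W <- W * pr$msg[[j]]$M
    M <- crossprod(plist[[k]], W)  # t(P) %*% W : transition toward child
    cs <- .colSums(M, nstates, S)
    cs[cs == 0] <- 1e-300
    U[[ch]] <- M * rep(1 / cs, each = nstates)
  }
  U
}

#' Protein alignment log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood (nats) of a protein alignment on a rooted
#' tree with branch lengths under an [aa_model()]. Gaps and ambiguities
#' contribute partial likelihood 1 in every state. With gamma rate
#' heterogeneity the site likelihood is the equal-weight mixture over
#' discrete categories.
#'
#' @param aln A `protein_alignment` containing every tree taxon.
#' @param tree A rooted `phylo` with branch lengths.
#' @param model An [aa_model()].
#' @return Scalar log-likelihood; attribute `site_loglik` carries the
#'   per-site vector.
#' @export
compute_log_likelihood <- function(aln, tree, model) {
  stopifnot(inherits(aln, "protein_alignment"), inherits(model, "aa_model"))
  ti <- tree_index(tree)
  tipstates <- tip_state_matrix(aln, tree, AA_STATES)
  ll <- aa_site_loglik(ti, tipstates, model)
  structure(sum(ll), site_loglik = ll)
}

# per-site log-likelihood under an aa_model (gamma mixture handled here)
aa_site_loglik <- function(ti, tipstates, model) {
  mix <- lapply(seq_along(model$rates), function(r) {
    plist <- pmats(model$eig, ti$length * model$rates[r])
    prune_pass(ti, tipstates, plist, model$freqs)$site_loglik
  })
  if (length(mix) == 1L) {
    return(mix[[1]])
  }
  m <- do.call(rbind, mix)
  log_colsums_exp(m + log(model$rate_weights))
}

# numerically stable log(colSums(exp(m))) for a matrix of log values
log_colsums_exp <- function(m) {
  mx <- do.call(pmax, c(asplit(m, 1), list(na.rm = TRUE)))
  mx + log(colSums(exp(m - rep(mx, each = nrow(m)))))
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Optimizes every branch length of `tree` for a protein alignment under
#' an [aa_model()], by repeated one-dimensional (Brent) optimization of
#' each edge with all others held fixed, sweeping until the log-likelihood
#' gain falls below `tol`. Each edge update can only increase the
#' likelihood, so the final likelihood is at least the starting one.
#'
#' @param aln A `protein_alignment`.
#' @param tree Rooted `phylo`; current lengths are the starting point
#'   (missing lengths start at 0.1).
#' @param model An [aa_model()] (single-rate models only).
#' @param max_sweeps Sweep budget before the fit is flagged unconverged.
#' @param tol Log-likelihood convergence tolerance between sweeps.
#' @param max_length Upper bound per branch (expected replacements/site).
#' @return A list: `tree` (with fitted lengths), `loglik`, `converged`,
#'   `sweeps`.
#' @export
fit_branch_lengths <- function(aln, tree, model, max_sweeps = 10L,
                               tol = 1e-6, max_length = 10) {
  stopifnot(inherits(aln, "protein_alignment"), inherits(model, "aa_model"))
  if (length(model$rates) > 1L) {
    stop("branch-length fitting supports single-rate models", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  }
  tipstates <- tip_state_matrix(aln, tree, AA_STATES)
  pi <- model$freqs
  eig <- model$eig
  nstates <- length(pi)
  S <- ncol(tipstates)

  ll_of <- function(tr) {
    ti <- tree_index(tr)
    plist <- lapply(ti$length, pmat, eig = eig)
    sum(prune_pass(ti, tipstates, plist, pi)$site_loglik)
  }

  cur <- ll_of(tree)
  start_ll <- cur
  converged <- FALSE
  sweeps <- 0L
  for (sweep in seq_len(max_sweeps)) {
    sweeps <- sweep
    for (e in seq_len(nrow(tree$edge))) {
      ti <- tree_index(tree)
      plist <- lapply(ti$length, pmat, eig = eig)
      pr <- prune_pass(ti, tipstates, plist, pi, keep = TRUE)
      U <- up_pass(ti, pr, plist, pi)
      k <- match(e, ti$orig_edge)  # postorder row of this edge
      pa <- ti$edge[k, 1]
      ch <- ti$edge[k, 2]
      # outside partial at the parent w.r.t. this edge
      W <- U[[pa]]
      ne <- nrow(ti$edge)
      for (j in setdiff(which(ti$edge[, 1] == pa), k)) {
        W <- W * pr$msg[[j]]$M
      }
      if (ch <= ti$ntip) {
        st <- tipstates[ch, ]
        obs <- which(!is.na(st))
        edge_ll <- function(t) {
          P <- pmat(eig, t)
          M <- matrix(1, nstates, S)
          if (length(obs)) M[, obs] <- P[, st[obs]]
          sum(log(.colSums(W * M, nstates, S)))
        }
      } else {
        D <- pr$partial[[ch]]
        edge_ll <- function(t) {
          P <- pmat(eig, t)
          sum(log(.colSums(W * (P %*% D), nstates, S)))
        }
      }
      opt <- stats::optimize(edge_ll, c(0, max_length), maximum = TRUE,
                             tol = 1e-8)
      if (opt$objective >= edge_ll(tree$edge.length[e])) {
        tree$edge.length[e] <- opt$maximum
      }
    }
    new <- ll_of(tree)
    if (new - cur < tol) {
      cur <- max(new, cur)
      converged <- TRUE
      break
    }
    cur <- new
  }
  # zero-length cleanup: Brent can sit at ~1e-9 for identical sequences
  tree$edge.length[tree$edge.length < 1e-8] <- 0
  final <- ll_of(tree)
  if (final < start_ll - 1e-9) {
    # contract: never return a worse tree than the input
    converged <- FALSE
  }
  list(tree = tree, loglik = final, converged = converged, sweeps = sweeps)
}
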