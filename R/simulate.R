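# Stochastic sequence simulation with full event histories. Exact
# (Gillespie) simulation per branch per site, so the emitted alignment
# comes with the complete record of substitution events and true internal
# node states -- the ground truth every downstream stage is tested
# against.

#' Derive a reproducible substream seed
#'
#' Substream k of root seed s is `(s + 1664525 * k) mod (2^31 - 1)`, so
#' per-gene simulations are reproducible independently of batch order.
#'
#' @param seed Root seed (integer).
#' @param k Substream index (integer >= 0).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1664525 * as.numeric(k)) %% 2147483647)
}

#' The 19-taxon study tree
#'
#' A rooted binary tree over the study's 19 mammals, topologically
#' consistent with the accepted species phylogeny used for the scan
#' (CF bats sister to the pteropodid clade within Yinpterochiroptera,
#' FM bats in Yangochiroptera, toothed whales sister to the baleen whale
#' within Cetartiodactyla, and five outgroup mammals). Branch lengths are
#' drawn reproducibly from `seed` (gamma, mean `mean_length`) and scaled
#' by `scale`.
#'
#' @param seed Integer seed for branch lengths.
#' @param mean_length Mean branch length (expected substitutions/site).
#' @param scale Multiplier applied to all lengths (e.g. to set a lower
#'   overall divergence for reconstruction studies).
#' @return A rooted `phylo` with 19 tips and empty `edge.tags`.
#' @export
make_study_fixture <- function(seed = 1L, mean_length = 0.05, scale = 1) {
  topo <- paste0(
    "((Homo_sapiens,Mus_musculus),(((((Rousettus_aegyptiacus,",
    "Rousettus_leschenaultii),(Pteropus_vampyrus,Pteropus_alecto)),",
    "(Rhinolophus_sinicus,(Hipposideros_armiger,Aselliscus_stoliczkanus))),",
    "((Myotis_davidii,(Myotis_brandtii,Myotis_lucifugus)),",
    "Taphozous_melanopogon)),((Bos_taurus,((Orcinus_orca,Tursiops_truncatus),",
    "Balaenoptera_acutorostrata)),(Equus_caballus,Canis_lupus_familiaris))));"
  )
  tree <- parse_newick(topo)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tree$edge.length <- scale *
    stats::rgamma(nrow(tree$edge), shape = 4, rate = 4 / mean_length)
  tree
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Site-class parameters of the branch-site simulation model
#'
#' Model A site classes: class 0 (proportion `p0`, omega0 everywhere),
#' class 1 (`p1`, omega 1 everywhere), classes 2a/2b (sharing
#' `1 - p0 - p1` in ratio `p0 : p1`) with omega0/1 on background branches
#' and `omega2` on foreground branches.
#'
#' @param p0,p1 Class proportions, `p0 + p1 <= 1`.
#' @param omega0 Purifying-class dN/dS, in (0, 1).
#' @param omega2 Foreground dN/dS of classes 2a/2b, `>= 1`.
#' @param kappa Transition/transversion rate ratio, `> 0`.
#' @param pi Codon equilibrium frequencies (61-vector, sums to 1);
#'   `NULL` for uniform.
#' @return A validated list of class `site_class_params`.
#' @export
site_class_params <- function(p0 = 0.45, p1 = 0.45, omega0 = 0.1,
                              omega2 = 1, kappa = 2, pi = NULL) {
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  stopifnot(length(pi) == 61)
  if (abs(sum(pi) - 1) > 1e-6) stop("pi must sum to 1", call. = FALSE)
  if (!(p0 >= 0 && p1 >= 0 && p0 + p1 <= 1 && p0 + p1 > 0)) {
    stop("need p0, p1 >= 0 with 0 < p0 + p1 <= 1", call. = FALSE)
  }
  if (!(omega0 > 0 && omega0 < 1)) stop("omega0 must be in (0,1)", call. = FALSE)
  if (omega2 < 1) stop("omega2 must be >= 1", call. = FALSE)
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  structure(list(p0 = p0, p1 = p1, omega0 = omega0, omega2 = omega2,
                 kappa = kappa, pi = pi / sum(pi)),
            class = "site_class_params")
}

# class proportions (0, 1, 2a, 2b) of model A
class_proportions <- function(params) {
  p2 <- max(0, 1 - params$p0 - params$p1)
  c(params$p0, params$p1,
    p2 * params$p0 / (params$p0 + params$p1),
    p2 * params$p1 / (params$p0 + params$p1))
}

# Shared rate normalization of the model-A mixture: unscaled GY94
# generators for each omega, divided by the proportion-weighted mean
# background equilibrium rate. Simulator and fitter use this identically.
model_a_generators <- function(params) {
  prop <- class_proportions(params)
  Q0 <- gy94_unscaled(params$kappa, params$omega0, params$pi)
  Q1 <- gy94_unscaled(params$kappa, 1, params$pi)
  Q2 <- gy94_unscaled(params$kappa, params$omega2, params$pi)
  r <- function(Q) -sum(params$pi * diag(Q))
  scale <- (prop[1] + prop[3]) * r(Q0) + (prop[2] + prop[4]) * r(Q1)
  list(Q = list(omega0 = Q0 / scale, omega1 = Q1 / scale,
                omega2 = Q2 / scale),
       prop = prop, scale = scale)
}

# Exact simulation of one branch for a set of sites. `Qs` is a list of
# generators, `widx[s]` the generator index for site s, `state0` the
# parent states. Returns final states and an event data.frame.
gillespie_branch <- function(state0, Qs, widx, len, rate_mult = NULL) {
  n <- nrow(Qs[[1]])
  S <- length(state0)
  state <- state0
  ev_site <- integer(0); ev_time <- numeric(0)
  ev_from <- integer(0); ev_to <- integer(0)
  if (len <= 0) {
    return(list(state = state,
                events = data.frame(site = integer(0), time = numeric(0),
                                    from = integer(0), to = integer(0))))
  }
  for (s in seq_len(S)) {
    st <- state[s]
    Q <- Qs[[widx[s]]]
    mult <- if (is.null(rate_mult)) 1 else rate_mult[s]
    if (mult <= 0) next
    t <- 0
    repeat {
      exit <- -Q[st, st] * mult
      if (exit <= 0) break
      t <- t + stats::rexp(1, exit)
      if (t > len) break
      p <- Q[st, ]
      p[st] <- 0
      nxt <- sample.int(n, 1L, prob = p)
      ev_site <- c(ev_site, s); ev_time <- c(ev_time, t)
      ev_from <- c(ev_from, st); ev_to <- c(ev_to, nxt)
      st <- nxt
    }
    state[s] <- st
  }
  list(state = state,
       events = data.frame(site = ev_site, time = ev_time,
                           from = ev_from, to = ev_to))
}

# Generic tree simulation given root states and per-branch generator
# assignment. Returns node state matrix + event tibble.
simulate_on_tree <- function(tree, root_state, Qs, widx_for_edge,
                             rate_mult = NULL) {
  ti <- tree_index(tree)
  nn <- ti$ntip + ti$nnode
  S <- length(root_state)
  node_state <- matrix(NA_integer_, nn, S)
  node_state[ti$root, ] <- root_state
  ne <- nrow(ti$edge)
  ev <- vector("list", ne)
  for (k in rev(seq_len(ne))) {   # preorder: parents before children
    pa <- ti$edge[k, 1]; ch <- ti$edge[k, 2]
    res <- gillespie_branch(node_state[pa, ], Qs, widx_for_edge(ti$orig_edge[k]),
                            ti$length[k], rate_mult)
    node_state[ch, ] <- res$state
    if (nrow(res$events)) {
      res$events$branch <- ch
      res$events$edge <- ti$orig_edge[k]
      ev[[k]] <- res$events
    }
  }
  events <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  if (is.null(events)) {
    events <- data.frame(site = integer(0), time = numeric(0),
                         from = integer(0), to = integer(0),
                         branch = integer(0), edge = integer(0))
  }
  list(node_state = node_state, events = events)
}

#' Simulate a codon alignment under the branch-site (model A) process
#'
#' Each site draws one of the four model-A classes; substitution follows
#' the GY94 continuous-time Markov chain with the class's omega --
#' `omega2` on `FOREGROUND`-tagged branches for classes 2a/2b. Exact
#' stochastic simulation records every substitution event and all true
#' internal states.
#'
#' @param tree Rooted `phylo`, `FOREGROUND` tags where omega2 applies.
#' @param params A [site_class_params()].
#' @param n_sites Number of codon sites (>= 1).
#' @param seed Integer seed.
#' @param gene_id Gene identifier.
#' @return A list of class `sim_alignment`: `alignment`
#'   (`codon_alignment`), `history` (tibble: `branch` child node, `edge`,
#'   `site`, `time`, `from`, `to` as codon strings), `node_state`
#'   (integer matrix node x site), `site_class` (factor levels
#'   `0,1,2a,2b`), `tree`, `params`, `seed`.
#' @export
simulate_codon_alignment <- function(tree, params, n_sites, seed,
                                     gene_id = "gene") {
  stopifnot(inherits(params, "site_class_params"), n_sites >= 1)
  gen <- model_a_generators(params)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cls <- sample.int(4L, n_sites, replace = TRUE, prob = gen$prop)
  root <- sample.int(61L, n_sites, replace = TRUE, prob = params$pi)
  fg <- foreground_mask(tree)
  # generator index per class: background (omega0, 1, omega0, 1),
  # foreground (omega0, 1, omega2, omega2)
  bg_idx <- c(1L, 2L, 1L, 2L)[cls]
  fg_idx <- c(1L, 2L, 3L, 3L)[cls]
  Qs <- unname(gen$Q)
  sim <- simulate_on_tree(tree, root, Qs,
                          function(e) if (fg[e]) fg_idx else bg_idx)
  codons <- sense_codons()
  ntip <- length(tree$tip.label)
  seqs <- apply(sim$node_state[seq_len(ntip), , drop = FALSE], 1,
                function(x) paste(codons[x], collapse = ""))
  names(seqs) <- tree$tip.label
  aln <- codon_alignment(seqs, gene_id = gene_id)
  history <- tibble::tibble(
    branch = sim$events$branch,
    edge = sim$events$edge,
    site = sim$events$site,
    time = sim$events$time,
    from = codons[sim$events$from],
    to = codons[sim$events$to]
  )
  structure(
    list(alignment = aln, history = history, node_state = sim$node_state,
         site_class = factor(c("0", "1", "2a", "2b")[cls],
                             levels = c("0", "1", "2a", "2b")),
         tree = tree, params = params, seed = seed, alphabet = codons),
    class = "sim_alignment"
  )
}

#' Simulate a protein alignment with event history
#'
#' 20-state analogue of [simulate_codon_alignment()] under an
#' [aa_model()]; with gamma rate heterogeneity each site draws a discrete
#' rate category.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param model An [aa_model()].
#' @param n_sites Number of amino-acid sites.
#' @param seed Integer seed.
#' @param gene_id Gene identifier.
#' @return A `sim_alignment` whose `alignment` is a `protein_alignment`
#'   and whose history states are residues; `site_rate` records each
#'   site's rate multiplier.
#' @export
simulate_protein_alignment <- function(tree, model, n_sites, seed,
                                       gene_id = "gene") {
  stopifnot(inherits(model, "aa_model"), n_sites >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rate_cat <- sample.int(length(model$rates), n_sites, replace = TRUE,
                         prob = model$rate_weights)
  rate <- model$rates[rate_cat]
  root <- sample.int(20L, n_sites, replace = TRUE, prob = model$freqs)
  sim <- simulate_on_tree(tree, root, list(model$Q), function(e) rep(1L, n_sites),
                          rate_mult = rate)
  ntip <- length(tree$tip.label)
  seqs <- apply(sim$node_state[seq_len(ntip), , drop = FALSE], 1,
                function(x) paste(AA_STATES[x], collapse = ""))
  names(seqs) <- tree$tip.label
  aln <- protein_alignment(seqs, gene_id = gene_id)
  history <- tibble::tibble(
    branch = sim$events$branch,
    edge = sim$events$edge,
    site = sim$events$site,
    time = sim$events$time,
    from = AA_STATES[sim$events$from],
    to = AA_STATES[sim$events$to]
  )
  structure(
    list(alignment = aln, history = history, node_state = sim$node_state,
         site_rate = rate, tree = tree, model = model, seed = seed,
         alphabet = AA_STATES),
    class = "sim_alignment"
  )
}

#' @export
print.sim_alignment <- function(x, ...) {
  cat("Simulated", if (identical(x$alphabet, AA_STATES)) "protein" else
    "codon", "alignment:", nrow(x$alignment), "taxa x",
    ncol(x$alignment), "sites;", nrow(x$history), "recorded events",
    paste0("(seed ", x$seed, ")"), "\n")
  if (!is.null(x$truth) && nrow(x$truth)) {
    cat("  injected:", sum(x$truth$type == "parallel"), "parallel,",
        sum(x$truth$type == "convergent"), "convergent sites\n")
  }
  invisible(x)
}

#' Inject parallel/convergent substitutions into a simulated protein gene
#'
#' Edits a protein `sim_alignment` so that the two named (paraphyletic)
#' branches each carry a substitution to a common derived residue at
#' `n_parallel` sites whose two parent (most recent ancestor) states are
#' equal and `n_convergent` sites where they differ. The event history
#' and all descendant node states are rewritten consistently (each edited
#' branch carries exactly one event at that site; descendants carry the
#' derived state).
#'
#' @param sim A protein `sim_alignment`.
#' @param branch_pair Character vector of two leaf labels (terminal
#'   branches) or integer child node ids; must be paraphyletic.
#' @param n_parallel,n_convergent Numbers of sites to edit.
#' @param seed Integer seed for site/residue choices.
#' @param candidate_sites Optional site subset to draw the edited sites
#'   from (default: all sites).
#' @return The edited `sim_alignment`, with a `truth` tibble
#'   (`site`, `type`, `derived`, `parent_a`, `parent_b`).
#' @export
inject_convergence <- function(sim, branch_pair, n_parallel, n_convergent,
                               seed, candidate_sites = NULL) {
  stopifnot(inherits(sim, "sim_alignment"),
            identical(sim$alphabet, AA_STATES))
  tree <- sim$tree
  ids <- resolve_branch_children(tree, branch_pair)
  if (is_ancestor(tree, ids[1], ids[2]) || is_ancestor(tree, ids[2], ids[1])) {
    stop("branch pair is not paraphyletic", call. = FALSE)
  }
  pa <- vapply(ids, function(v) tree$edge[tree$edge[, 2] == v, 1], numeric(1))
  a <- sim$node_state[pa[1], ]
  b <- sim$node_state[pa[2], ]
  elig_par <- which(a == b)
  elig_con <- which(a != b)
  used <- if (!is.null(sim$truth)) sim$truth$site else integer(0)
  elig_par <- setdiff(elig_par, used)
  elig_con <- setdiff(elig_con, used)
  if (!is.null(candidate_sites)) {
    elig_par <- intersect(elig_par, candidate_sites)
    elig_con <- intersect(elig_con, candidate_sites)
  }
  if (length(elig_par) < n_parallel) {
    stop("insufficient eligible parallel sites: need ", n_parallel,
         ", have ", length(elig_par), call. = FALSE)
  }
  if (length(elig_con) < n_convergent) {
    stop("insufficient eligible convergent sites: need ", n_convergent,
         ", have ", length(elig_con), call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sites_par <- if (n_parallel) sort(sample(elig_par, n_parallel)) else integer(0)
  sites_con <- if (n_convergent) sort(sample(elig_con, n_convergent)) else integer(0)

  desc <- lapply(ids, function(v) subtree_nodes(tree, v))
  edit_one <- function(sim, s, derived) {
    for (i in 1:2) {
      par_state <- sim$node_state[pa[i], s]
      nodes <- desc[[i]]
      sim$node_state[nodes, s] <- derived
      # rewrite history: the tested branch gets exactly one event, all
      # branches inside the subtree lose their events at this site
      inside <- sim$history$branch %in% nodes & sim$history$site == s
      sim$history <- sim$history[!inside, , drop = FALSE]
      len <- tree$edge.length[tree$edge[, 2] == ids[i]]
      sim$history <- dplyr::bind_rows(
        sim$history,
        tibble::tibble(branch = as.integer(ids[i]),
                       edge = as.integer(which(tree$edge[, 2] == ids[i])),
                       site = as.integer(s), time = len / 2,
                       from = AA_STATES[par_state],
                       to = AA_STATES[derived])
      )
    }
    sim
  }

  truth <- list()
  for (s in sites_par) {
    derived <- sample(setdiff(seq_len(20L), a[s]), 1L)
    sim <- edit_one(sim, s, derived)
    truth[[length(truth) + 1]] <- tibble::tibble(
      site = s, type = "parallel", derived = AA_STATES[derived],
      parent_a = AA_STATES[a[s]], parent_b = AA_STATES[b[s]])
  }
  for (s in sites_con) {
    derived <- sample(setdiff(seq_len(20L), c(a[s], b[s])), 1L)
    sim <- edit_one(sim, s, derived)
    truth[[length(truth) + 1]] <- tibble::tibble(
      site = s, type = "convergent", derived = AA_STATES[derived],
      parent_a = AA_STATES[a[s]], parent_b = AA_STATES[b[s]])
  }
  # refresh leaf alignment from node states
  ntip <- length(tree$tip.label)
  seqs <- apply(sim$node_state[seq_len(ntip), , drop = FALSE], 1,
                function(x) paste(AA_STATES[x], collapse = ""))
  names(seqs) <- tree$tip.label
  sim$alignment <- protein_alignment(seqs, gene_id = gene_id(sim$alignment))
  sim$truth <- dplyr::bind_rows(sim$truth,
                                if (length(truth)) dplyr::bind_rows(truth))
  if (is.null(sim$truth)) {
    sim$truth <- tibble::tibble(site = integer(0), type = character(0),
                                derived = character(0),
                                parent_a = character(0),
                                parent_b = character(0))
  }
  sim
}

# leaf label(s) or node id(s) -> child node ids
resolve_branch_children <- function(tree, x) {
  if (is.character(x)) {
    idx <- match(x, tree$tip.label)
    if (anyNA(idx)) {
      stop("taxon not in tree: ", paste(x[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    idx
  } else {
    as.integer(x)
  }
}

# all nodes in the subtree rooted at (and including) node v
subtree_nodes <- function(tree, v) {
  out <- v
  frontier <- v
  while (length(frontier)) {
    kids <- tree$edge[tree$edge[, 1] %in% frontier, 2]
    out <- c(out, kids)
    frontier <- kids
  }
  unique(out)
}

#' Inject all-gap codon columns (filter test utility)
#'
#' Replaces the chosen codon columns with gap codons in a random subset
#' of taxa (at least one per column). Purely a fixture utility for the
#' alignment-hygiene filter; the simulator itself is gap-free.
#'
#' @param aln A `codon_alignment`.
#' @param columns Codon columns to hit.
#' @param seed Integer seed.
#' @return The gapped `codon_alignment`.
#' @export
inject_gaps <- function(aln, columns, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- unclass(aln)
  for (j in columns) {
    rows <- sample(nrow(m), sample(nrow(m), 1))
    m[rows, j] <- CODON_GAP
  }
  structure(m, class = class(aln), gene_id = gene_id(aln))
}

#' Replay an event history from the root states
#'
#' Test oracle: applies every recorded event chain from the root state
#' downward and returns the implied leaf alignment matrix, which must
#' reproduce the emitted alignment exactly.
#'
#' @param sim A `sim_alignment`.
#' @return Character matrix taxa x sites.
#' @export
replay_history <- function(sim) {
  tree <- sim$tree
  ti <- tree_index(tree)
  nn <- ti$ntip + ti$nnode
  S <- ncol(sim$alignment)
  alpha <- sim$alphabet
  node_state <- matrix(NA_integer_, nn, S)
  node_state[ti$root, ] <- sim$node_state[ti$root, ]
  h <- sim$history
  for (k in rev(seq_len(nrow(ti$edge)))) {
    pa <- ti$edge[k, 1]; ch <- ti$edge[k, 2]
    st <- node_state[pa, ]
    rows <- which(h$branch == ch)
    if (length(rows)) {
      rows <- rows[order(h$site[rows], h$time[rows])]
      for (r in rows) {
        s <- h$site[r]
        stopifnot(alpha[st[s]] == h$from[r])  # chain consistency
        st[s] <- match(h$to[r], alpha)
      }
    }
    node_state[ch, ] <- st
  }
  out <- matrix(alpha[node_state[seq_len(ti$ntip), , drop = FALSE]],
                nrow = ti$ntip)
  rownames(out) <- tree$tip.label
  out
}
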