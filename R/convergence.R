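# Parallel/convergent substitution detection between paraphyletic lineage
# pairs, on reconstructed (or true) ancestral states. A site is called
# when (1) the two tested extant nodes carry the identical residue,
# (2) each differs from the residue at its own most recent ancestral
# node; the call is "parallel" when the two ancestral residues are equal
# and "convergent" when they differ.

#' Substitutions along one branch
#'
#' All sites where the argmax ancestral state at the branch's parent node
#' differs from the state at its child (a leaf state from the alignment,
#' or the reconstructed argmax for an internal child). Sites with missing
#' data at either end, or with an ancestral posterior below
#' `min_posterior`, are skipped.
#'
#' @param recon An `ancestral_reconstruction`.
#' @param branch A leaf label (terminal branch) or child node id.
#' @param min_posterior Minimum ancestral argmax posterior for a site to
#'   be usable (default 0: no cut-off).
#' @return Tibble: `gene`, `site`, `parent_state`, `child_state`.
#' @export
call_substitutions <- function(recon, branch, min_posterior = 0) {
  stopifnot(inherits(recon, "ancestral_reconstruction"))
  tree <- recon$tree
  ch <- resolve_branch_children(tree, branch)
  edge <- which(tree$edge[, 2] == ch)
  if (length(edge) != 1L) {
    stop("branch with child ", branch, " not in tree", call. = FALSE)
  }
  pa <- tree$edge[edge, 1]
  pst <- node_states(recon, pa)
  cst <- node_states(recon, ch)
  ok <- !is.na(pst) & !is.na(cst) &
    node_posteriors(recon, pa) >= min_posterior &
    node_posteriors(recon, ch) >= min_posterior
  hit <- ok & pst != cst
  tibble::tibble(gene = recon$gene_id, site = which(hit),
                 parent_state = pst[hit], child_state = cst[hit])
}

#' Classify parallel/convergent sites between two branches
#'
#' Applies the three call criteria per site for a paraphyletic branch
#' pair and types each call by equality of the two ancestral residues.
#'
#' @param recon An `ancestral_reconstruction`.
#' @param branch_a,branch_b Leaf labels or child node ids of the two
#'   tested branches; must be paraphyletic (neither ancestral to the
#'   other).
#' @param min_posterior Minimum ancestral posterior (see
#'   [call_substitutions()]).
#' @return Tibble of class calls: `gene`, `site`, `branch_a`, `branch_b`,
#'   `derived`, `parent_a`, `parent_b`, `type` (`"parallel"` or
#'   `"convergent"`).
#' @export
classify_pair <- function(recon, branch_a, branch_b, min_posterior = 0) {
  stopifnot(inherits(recon, "ancestral_reconstruction"))
  tree <- recon$tree
  ids <- c(resolve_branch_children(tree, branch_a),
           resolve_branch_children(tree, branch_b))
  if (is_ancestor(tree, ids[1], ids[2]) || is_ancestor(tree, ids[2], ids[1])) {
    stop("not paraphyletic: one tested branch is ancestral to the other",
         call. = FALSE)
  }
  pa <- vapply(ids, function(v) tree$edge[tree$edge[, 2] == v, 1], numeric(1))
  ca <- node_states(recon, ids[1]); cb <- node_states(recon, ids[2])
  aa <- node_states(recon, pa[1]);  ab <- node_states(recon, pa[2])
  ok <- !is.na(ca) & !is.na(cb) & !is.na(aa) & !is.na(ab) &
    node_posteriors(recon, pa[1]) >= min_posterior &
    node_posteriors(recon, pa[2]) >= min_posterior
  hit <- ok & ca == cb & ca != aa & cb != ab
  lab <- function(v) if (v <= length(tree$tip.label)) tree$tip.label[v] else
    as.character(v)
  tibble::tibble(
    gene = recon$gene_id,
    site = which(hit),
    branch_a = lab(ids[1]), branch_b = lab(ids[2]),
    derived = ca[hit], parent_a = aa[hit], parent_b = ab[hit],
    type = ifelse(aa[hit] == ab[hit], "parallel", "convergent")
  )
}

# replacement distribution of a derived residue given a parent residue
# under an aa_model: P(x | a) proportional to q_ax, x != a
replacement_probs <- function(model) {
  Q <- model$Q
  P <- Q
  diag(P) <- 0
  P / rowSums(P)
}

#' Excess test for parallel/convergent substitutions
#'
#' Tests whether the observed parallel and convergent counts between two
#' branches exceed the neutral expectation. Null: conditional on the
#' observed substitutions on each branch (sites and parent states fixed),
#' each derived residue is drawn independently in proportion to the
#' model's replacement rate from its parent, excluding the parent. The
#' per-site probabilities of an identical derived residue are summed into
#' expected parallel/convergent counts, and one-sided P values come from
#' the Poisson upper tail of the expected count at the observed count.
#'
#' @param recon An `ancestral_reconstruction`.
#' @param branch_a,branch_b Tested branches, as in [classify_pair()].
#' @param model An [aa_model()] giving the replacement distribution.
#' @param min_posterior Minimum ancestral posterior for usable sites.
#' @return A `convergence_test` tibble row: observed and expected
#'   parallel/convergent counts and one-sided P values.
#' @export
convergence_excess_test <- function(recon, branch_a, branch_b, model,
                                    min_posterior = 0) {
  calls <- classify_pair(recon, branch_a, branch_b, min_posterior)
  sub_a <- call_substitutions(recon, branch_a, min_posterior)
  sub_b <- call_substitutions(recon, branch_b, min_posterior)
  shared <- intersect(sub_a$site, sub_b$site)
  rp <- replacement_probs(model)
  exp_par <- 0; exp_con <- 0
  for (s in shared) {
    a <- sub_a$parent_state[sub_a$site == s]
    b <- sub_b$parent_state[sub_b$site == s]
    ia <- match(a, AA_STATES); ib <- match(b, AA_STATES)
    if (a == b) {
      exp_par <- exp_par + sum(rp[ia, -ia] * rp[ib, -ib])
    } else {
      keep <- setdiff(seq_len(20L), c(ia, ib))
      exp_con <- exp_con + sum(rp[ia, keep] * rp[ib, keep])
    }
  }
  obs_par <- sum(calls$type == "parallel")
  obs_con <- sum(calls$type == "convergent")
  pois_p <- function(obs, lambda) {
    if (obs == 0) return(1)
    if (lambda == 0) return(0)
    stats::ppois(obs - 1, lambda, lower.tail = FALSE)
  }
  p_par <- if (nrow(sub_a) == 0 || nrow(sub_b) == 0) 1 else
    pois_p(obs_par, exp_par)
  p_con <- if (nrow(sub_a) == 0 || nrow(sub_b) == 0) 1 else
    pois_p(obs_con, exp_con)
  tree <- recon$tree
  lab <- function(v) {
    id <- resolve_branch_children(tree, v)
    if (id <= length(tree$tip.label)) tree$tip.label[id] else as.character(id)
  }
  structure(
    tibble::tibble(
      gene = recon$gene_id,
      branch_a = lab(branch_a),
      branch_b = lab(branch_b),
      n_sub_a = nrow(sub_a), n_sub_b = nrow(sub_b),
      obs_parallel = obs_par, obs_convergent = obs_con,
      exp_parallel = exp_par, exp_convergent = exp_con,
      p_parallel = p_par, p_convergent = p_con
    ),
    class = c("convergence_test", "tbl_df", "tbl", "data.frame")
  )
}

#' Summarize convergence calls over a comparison design
#'
#' Counts, per focal pair, the genes with at least one parallel call, the
#' parallel sites, and the same for convergent calls (a gene counts once
#' per pair however many sites are called). The core parallel gene set
#' contains the genes with a parallel call in every one of the six
#' echolocator comparisons spanning all four lineages.
#'
#' @param calls Tibble of [classify_pair()] rows across genes, with a
#'   `pair` column naming the comparison.
#' @param design Tibble with columns `pair`, `branch_a`, `branch_b`
#'   (see [study_design()]); all six echolocator comparisons must be
#'   present.
#' @return List: `summary` (tibble per pair) and `core_genes` (character
#'   vector).
#' @export
summarize_pairs <- function(calls, design) {
  echo_pairs <- c("CF vs FM", "CF vs CLICK", "FM vs CLICK", "CF vs TW",
                  "FM vs TW", "CLICK vs TW")
  missing <- setdiff(echo_pairs, design$pair)
  if (length(missing)) {
    stop("comparison design lacks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  base <- tibble::tibble(pair = unique(design$pair))
  if (nrow(calls) == 0) {
    summary <- dplyr::mutate(base, parallel_genes = 0L, parallel_sites = 0L,
                             convergent_genes = 0L, convergent_sites = 0L)
    return(list(summary = summary, core_genes = character(0)))
  }
  counts <- calls |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(
      parallel_genes = dplyr::n_distinct(.data$gene[.data$type == "parallel"]),
      parallel_sites = sum(.data$type == "parallel"),
      convergent_genes =
        dplyr::n_distinct(.data$gene[.data$type == "convergent"]),
      convergent_sites = sum(.data$type == "convergent"),
      .groups = "drop"
    )
  summary <- base |>
    dplyr::left_join(counts, by = "pair") |>
    dplyr::mutate(dplyr::across(-"pair", ~ tidyr::replace_na(.x, 0L)))
  core <- calls |>
    dplyr::filter(.data$type == "parallel", .data$pair %in% echo_pairs) |>
    dplyr::distinct(.data$gene, .data$pair) |>
    dplyr::count(.data$gene) |>
    dplyr::filter(.data$n == length(echo_pairs)) |>
    dplyr::pull(.data$gene)
  list(summary = summary, core_genes = core)
}

#' The study's pairwise comparison design
#'
#' The six echolocator pairwise comparisons and, for each Table-1 row,
#' the matched control comparison at equal phylogenetic distance, using
#' one representative taxon per lineage (the RNA-Seq species for the
#' three sequenced bat lineages).
#'
#' @return Tibble: `row`, `side` (`"echo"`/`"control"`), `pair`,
#'   `branch_a`, `branch_b`.
#' @export
study_design <- function() {
  cf <- "Aselliscus_stoliczkanus"; fm <- "Taphozous_melanopogon"
  cl <- "Rousettus_leschenaultii"; tw <- "Tursiops_truncatus"
  nb <- "Pteropus_vampyrus"; nw <- "Balaenoptera_acutorostrata"
  echo <- tibble::tibble(
    row = 1:7, side = "echo",
    pair = c("CF vs FM", "CF vs CLICK", "FM vs CLICK", "CF vs TW",
             "FM vs TW", "CLICK vs TW", "CLICK vs TW"),
    branch_a = c(cf, cf, fm, cf, fm, cl, cl),
    branch_b = c(fm, cl, cl, tw, tw, tw, tw)
  )
  ctrl <- tibble::tibble(
    row = 1:7, side = "control",
    pair = c("CF vs NONECHO_BAT", "CF vs NONECHO_BAT", "FM vs NONECHO_BAT",
             "CF vs NONECHO_WHALE", "FM vs NONECHO_WHALE",
             "CLICK vs NONECHO_WHALE", "NONECHO_BAT vs TW"),
    branch_a = c(cf, cf, fm, cf, fm, cl, nb),
    branch_b = c(nb, nb, nb, nw, nw, nw, tw)
  )
  dplyr::bind_rows(echo, ctrl)
}
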