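#' Parse a Newick tree, keeping PAML-style foreground tags
#'
#' Reads a rooted Newick string into an [ape::phylo] object. PAML-style
#' branch marks (`#1`, `#2`, ...) attached to a taxon label or to a clade's
#' closing parenthesis are stripped from the labels and recorded as edge
#' tags; `#1` maps to the tag `"FOREGROUND"`, `#k` (k > 1) to
#' `"FOREGROUND<k>"`. Tags live in `tree$edge.tags`, a list of character
#' vectors parallel to the rows of `tree$edge`.
#'
#' @param text A Newick string (single tree, terminating `;` optional).
#' @return A `phylo` object with an `edge.tags` element.
#' @export
#' @examples
#' tr <- parse_newick("((A:0.1,B#1:0.1):0.05,C:0.15);")
#' edge_tags(tr)
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("malformed Newick: ", n_open, " '(' vs ", n_close, " ')'",
         call. = FALSE)
  }
  # Encode '#k' marks into labels ape can carry, then recover them.
  enc <- gsub("[ \t]*#([0-9]+)", "__MARK\\1", text)
  tr <- tryCatch(ape::read.tree(text = enc),
                 error = function(e) stop("malformed Newick: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("malformed Newick: unparseable string", call. = FALSE)

  ntip <- length(tr$tip.label)
  labels <- c(tr$tip.label, if (!is.null(tr$node.label)) tr$node.label else
                rep("", tr$Nnode))
  marks <- rep(NA_integer_, length(labels))
  hit <- grepl("__MARK([0-9]+)$", labels)
  marks[hit] <- as.integer(sub(".*__MARK([0-9]+)$", "\\1", labels[hit]))
  labels <- sub("__MARK[0-9]+$", "", labels)
  tr$tip.label <- labels[seq_len(ntip)]
  if (!is.null(tr$node.label)) {
    tr$node.label <- labels[ntip + seq_len(tr$Nnode)]
  }

  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(tr$edge.length)) {
    bad <- which(!is.finite(tr$edge.length) | tr$edge.length < 0)
    if (length(bad)) {
      stop("negative or non-finite branch length on edge to node ",
           tr$edge[bad[1], 2], " (length ", tr$edge.length[bad[1]], ")",
           call. = FALSE)
    }
  }

  tags <- vector("list", nrow(tr$edge))
  for (node in which(!is.na(marks))) {
    k <- marks[node]
    e <- which(tr$edge[, 2] == node)
    tag <- if (k == 1L) "FOREGROUND" else paste0("FOREGROUND", k)
    if (length(e) == 1L) tags[[e]] <- union(tags[[e]], tag)
    # a mark on the root itself has no parent edge; silently ignored
  }
  tr$edge.tags <- tags
  tr
}

#' Serialize a tree back to Newick, re-emitting foreground tags
#'
#' Inverse of [parse_newick()]: edges tagged `"FOREGROUND"` are written as
#' PAML `#1` marks on the corresponding label or clade.
#'
#' @param tree A `phylo` object, optionally with `edge.tags`.
#' @return A Newick string.
#' @export
write_newick <- function(tree) {
  tr <- tree
  tagged <- tagged_edges(tree, "FOREGROUND")
  if (length(tagged)) {
    nodes <- tr$edge[tagged, 2]
    ntip <- length(tr$tip.label)
    tips <- nodes[nodes <= ntip]
    internals <- nodes[nodes > ntip]
    tr$tip.label[tips] <- paste0(tr$tip.label[tips], "__MARK1")
    if (length(internals)) {
      if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
      idx <- internals - ntip
      tr$node.label[idx] <- paste0(tr$node.label[idx], "__MARK1")
    }
  }
  out <- ape::write.tree(tr)
  gsub("__MARK1", " #1", out, fixed = TRUE)
}

#' Edge indices carrying a given tag
#'
#' @param tree A `phylo` with `edge.tags`.
#' @param tag Tag string, default `"FOREGROUND"`.
#' @return Integer vector of row indices into `tree$edge`.
#' @export
tagged_edges <- function(tree, tag = "FOREGROUND") {
  if (is.null(tree$edge.tags)) return(integer(0))
  which(vapply(tree$edge.tags, function(x) tag %in% x, logical(1)))
}

#' Edge tags as a tibble
#'
#' @param tree A `phylo` with `edge.tags`.
#' @return A tibble with columns `edge`, `parent`, `child`, `child_label`
#'   (leaf label or empty), `tags` (comma-separated).
#' @export
edge_tags <- function(tree) {
  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  lab <- ifelse(child <= ntip, tree$tip.label[child], "")
  tags <- if (is.null(tree$edge.tags)) {
    rep("", nrow(tree$edge))
  } else {
    vapply(tree$edge.tags, function(x) paste(x, collapse = ","), character(1))
  }
  tibble::tibble(edge = seq_len(nrow(tree$edge)), parent = tree$edge[, 1],
                 child = child, child_label = lab, tags = tags)
}

# --- study lineages -------------------------------------------------------

#' Lineage membership of the 19-taxon study design
#'
#' Groups: constant-frequency (CF) bats, frequency-modulated (FM) bats,
#' tongue-click bats, nonecholocating bats, echolocating toothed whales,
#' the nonecholocating baleen whale, and five outgroup mammals.
#'
#' @return Named list of character vectors of taxon labels.
#' @export
study_lineages <- function() {
  list(
    CF = c("Rhinolophus_sinicus", "Hipposideros_armiger",
           "Aselliscus_stoliczkanus"),
    FM = c("Myotis_davidii", "Myotis_brandtii", "Myotis_lucifugus",
           "Taphozous_melanopogon"),
    CLICK = c("Rousettus_aegyptiacus", "Rousettus_leschenaultii"),
    NONECHO_BAT = c("Pteropus_vampyrus", "Pteropus_alecto"),
    TW = c("Orcinus_orca", "Tursiops_truncatus"),
    NONECHO_WHALE = "Balaenoptera_acutorostrata",
    OUTGROUP = c("Homo_sapiens", "Mus_musculus", "Bos_taurus",
                 "Equus_caballus", "Canis_lupus_familiaris")
  )
}

#' The seven foreground configurations of the branch-site scan
#'
#' @return Named list mapping configuration name to the echolocator
#'   lineages whose terminal branches form the foreground.
#' @export
foreground_configs <- function() {
  list(
    "CF" = "CF",
    "FM" = "FM",
    "CLICK" = "CLICK",
    "TW" = "TW",
    "CF+FM" = c("CF", "FM"),
    "CF+FM+CLICK" = c("CF", "FM", "CLICK"),
    "CF+FM+CLICK+TW" = c("CF", "FM", "CLICK", "TW")
  )
}

#' Tag the foreground branches of a configuration
#'
#' Clears any existing `"FOREGROUND"` tags, then tags the terminal branches
#' of every member lineage of `config_name` (one of the seven study
#' configurations, e.g. `"CF"` or `"CF+FM+CLICK+TW"`).
#'
#' @param tree A `phylo` whose tips include the member taxa.
#' @param config_name One of `names(foreground_configs())`.
#' @param lineages Lineage membership, defaults to [study_lineages()].
#' @return The tree with updated `edge.tags`.
#' @export
mark_foreground <- function(tree, config_name, lineages = study_lineages()) {
  cfgs <- foreground_configs()
  if (!config_name %in% names(cfgs)) {
    stop("unknown foreground configuration '", config_name, "'; expected one of ",
         paste(names(cfgs), collapse = ", "), call. = FALSE)
  }
  taxa <- unlist(lineages[cfgs[[config_name]]], use.names = FALSE)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    stop("tree lacks foreground taxa for '", config_name, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tags <- tree$edge.tags
  if (is.null(tags)) tags <- vector("list", nrow(tree$edge))
  tags <- lapply(tags, function(x) setdiff(x, "FOREGROUND"))
  tip_idx <- match(taxa, tree$tip.label)
  for (i in tip_idx) {
    e <- which(tree$edge[, 2] == i)
    tags[[e]] <- union(tags[[e]], "FOREGROUND")
  }
  tree$edge.tags <- tags
  tree
}

# Logical vector over edges: is edge foreground?
foreground_mask <- function(tree) {
  m <- rep(FALSE, nrow(tree$edge))
  m[tagged_edges(tree, "FOREGROUND")] <- TRUE
  m
}

# terminal edge index for a leaf label
terminal_edge <- function(tree, label) {
  tip <- match(label, tree$tip.label)
  if (is.na(tip)) stop("taxon '", label, "' not in tree", call. = FALSE)
  which(tree$edge[, 2] == tip)
}

# is node `a` an ancestor of node `b`?
is_ancestor <- function(tree, a, b) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  node <- b
  while (node != root) {
    parent <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(parent) == 0L) break
    if (parent == a) return(TRUE)
    node <- parent
  }
  FALSE
}
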