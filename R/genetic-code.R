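#' @importFrom Biostrings GENETIC_CODE
NULL

# Amino-acid alphabet, fixed alphabetical order. All state indexing and
# tie-breaking in the package uses this order.
AA_STATES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_GAP <- "-"
AA_AMBIG <- "X"
CODON_GAP <- "---"
CODON_AMBIG <- "NNN"

# The 61 sense codons of the standard genetic code, alphabetical order,
# with their encoded amino acids. Built once at load from Biostrings'
# genetic-code table.
.codon_env <- new.env(parent = emptyenv())

#' Sense codons of the standard genetic code
#'
#' Returns the 61 sense codons (stop codons excluded) in the fixed
#' alphabetical order used for all codon state indexing in the package.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  if (is.null(.codon_env$codons)) {
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)[gc != "*"]
    codons <- sort(codons)
    .codon_env$codons <- codons
    .codon_env$aa <- unname(gc[codons])
  }
  .codon_env$codons
}

#' Amino acid encoded by each sense codon
#'
#' @return Character vector of length 61, parallel to [sense_codons()].
#' @export
codon_aa <- function() {
  sense_codons()
  .codon_env$aa
}

# Lookup: codon string -> index in 1..61, NA for stops/unknown.
codon_index <- function(codons) {
  match(codons, sense_codons())
}

stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc == "*"])
}

# Pairwise codon relations used by the GY94 generator: for each ordered
# codon pair differing at exactly one position, whether the change is a
# transition and whether it is synonymous. Cached.
codon_pair_info <- function() {
  if (!is.null(.codon_env$pairs)) {
    return(.codon_env$pairs)
  }
  codons <- sense_codons()
  aa <- codon_aa()
  n <- length(codons)
  mat <- do.call(rbind, strsplit(codons, ""))
  is_transition <- function(x, y) {
    (x %in% c("A", "G") & y %in% c("A", "G")) |
      (x %in% c("C", "T") & y %in% c("C", "T"))
  }
  diff_count <- matrix(0L, n, n)
  pos_diff <- matrix(0L, n, n)
  for (p in 1:3) {
    d <- outer(mat[, p], mat[, p], "!=")
    diff_count <- diff_count + d
    pos_diff[d & pos_diff == 0L] <- p
  }
  single <- diff_count == 1L
  ts <- matrix(FALSE, n, n)
  for (p in 1:3) {
    sel <- single & pos_diff == p
    if (any(sel)) {
      idx <- which(sel, arr.ind = TRUE)
      ts[sel] <- is_transition(mat[idx[, 1], p], mat[idx[, 2], p])
    }
  }
  syn <- outer(aa, aa, "==")
  .codon_env$pairs <- list(single = single, transition = ts, synonymous = syn)
  .codon_env$pairs
}
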