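#' Construct a codon alignment
#'
#' A codon alignment is a character matrix of codon triplets (columns are
#' 1-based codon sites, rows are taxa) of class `codon_alignment`.
#' Sequences are supplied as in-frame nucleotide strings; gaps must be
#' whole-codon `"---"` and ambiguity `"NNN"`. Any other symbol, and any
#' internal stop codon, is an error.
#'
#' @param seqs Named character vector of equal-length nucleotide strings.
#' @param gene_id Gene identifier carried through all result tables.
#' @param allow_stops Keep terminal/internal stop codons? Only the
#'   simulator uses this; user data should leave it `FALSE`.
#' @return A `codon_alignment`: character matrix taxa x codon sites.
#' @export
codon_alignment <- function(seqs, gene_id = "gene", allow_stops = FALSE) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  nc <- unique(nchar(seqs))
  if (length(nc) != 1L) {
    stop("alignment rows differ in length: ", paste(nc, collapse = ", "),
         call. = FALSE)
  }
  if (nc %% 3 != 0) {
    stop("row length ", nc, " not divisible by 3", call. = FALSE)
  }
  n_codon <- nc %/% 3
  mat <- matrix("", nrow = length(seqs), ncol = n_codon,
                dimnames = list(names(seqs), NULL))
  starts <- seq(1L, nc, by = 3L)
  for (i in seq_along(seqs)) {
    s <- toupper(seqs[[i]])
    mat[i, ] <- substring(s, starts, starts + 2L)
  }
  ok <- mat %in% sense_codons() | mat == CODON_GAP | mat == CODON_AMBIG
  if (!allow_stops) {
    stop_hit <- matrix(mat %in% stop_codons(), nrow = nrow(mat))
    if (any(stop_hit)) {
      idx <- which(stop_hit, arr.ind = TRUE)[1, , drop = TRUE]
      stop("stop codon in taxon '", rownames(mat)[idx[1]],
           "' at codon position ", idx[2], call. = FALSE)
    }
  } else {
    ok <- ok | mat %in% stop_codons()
  }
  if (!all(ok)) {
    idx <- which(matrix(!ok, nrow = nrow(mat)), arr.ind = TRUE)[1, , drop = TRUE]
    stop("invalid codon '", mat[idx[1], idx[2]], "' in taxon '",
         rownames(mat)[idx[1]], "' at codon position ", idx[2], call. = FALSE)
  }
  structure(mat, class = c("codon_alignment", "matrix", "array"),
            gene_id = gene_id)
}

#' Construct a protein alignment
#'
#' Character matrix of single amino-acid residues (20 states, `"-"` gap,
#' `"X"` ambiguity), class `protein_alignment`.
#'
#' @param seqs Named character vector of equal-length amino-acid strings,
#'   or a character matrix taxa x sites.
#' @param gene_id Gene identifier.
#' @return A `protein_alignment`.
#' @export
protein_alignment <- function(seqs, gene_id = "gene") {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    stopifnot(!is.null(names(seqs)))
    nc <- unique(nchar(seqs))
    if (length(nc) != 1L) {
      stop("alignment rows differ in length: ", paste(nc, collapse = ", "),
           call. = FALSE)
    }
    mat <- matrix(unlist(strsplit(toupper(seqs), "")), nrow = length(seqs),
                  byrow = TRUE, dimnames = list(names(seqs), NULL))
  }
  ok <- mat %in% c(AA_STATES, AA_GAP, AA_AMBIG)
  if (!all(ok)) {
    idx <- which(matrix(!ok, nrow = nrow(mat)), arr.ind = TRUE)[1, , drop = TRUE]
    stop("invalid residue '", mat[idx[1], idx[2]], "' in taxon '",
         rownames(mat)[idx[1]], "' at site ", idx[2], call. = FALSE)
  }
  structure(mat, class = c("protein_alignment", "matrix", "array"),
            gene_id = gene_id)
}

gene_id <- function(aln) attr(aln, "gene_id") %||% "gene"

#' Translate a codon alignment
#'
#' Standard genetic code; `"---"` maps to `"-"` and `"NNN"` to `"X"`.
#' Coordinates are preserved: protein site i is codon site i.
#'
#' @param aln A `codon_alignment`.
#' @return A `protein_alignment` of identical dimensions.
#' @export
translate_alignment <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  codons <- sense_codons()
  aa <- codon_aa()
  out <- matrix(AA_AMBIG, nrow = nrow(aln), ncol = ncol(aln),
                dimnames = dimnames(aln))
  idx <- match(unclass(aln), codons)
  out[] <- ifelse(is.na(idx), ifelse(unclass(aln) == CODON_GAP, AA_GAP, AA_AMBIG),
                  aa[idx])
  stops <- unclass(aln) %in% stop_codons()
  if (any(stops)) {
    w <- which(matrix(stops, nrow = nrow(aln)), arr.ind = TRUE)[1, , drop = TRUE]
    stop("stop codon in taxon '", rownames(aln)[w[1]], "' at codon position ",
         w[2], call. = FALSE)
  }
  protein_alignment(out, gene_id = gene_id(aln))
}

#' Filter a codon alignment by column hygiene and minimum length
#'
#' Drops every codon column containing any of the symbols in
#' `drop_columns_with` in any taxon (default: gap and ambiguity, so
#' downstream site classification only ever sees fully resolved columns),
#' then flags the gene as discarded if fewer than `min_cds_nt` nucleotides
#' remain. The returned coordinate map reports filtered positions in
#' original 1-based codon coordinates.
#'
#' @param aln A `codon_alignment`.
#' @param min_cds_nt Minimum post-filter CDS length in nucleotides
#'   (default 150).
#' @param drop_columns_with Codon symbols that disqualify a column.
#' @return A list with elements `alignment` (filtered `codon_alignment`),
#'   `site_map` (integer vector: original codon coordinate of each kept
#'   column), `discarded` (logical), and `report` (one-row tibble).
#' @export
filter_alignment <- function(aln, min_cds_nt = 150,
                             drop_columns_with = c(CODON_GAP, CODON_AMBIG)) {
  stopifnot(inherits(aln, "codon_alignment"))
  bad <- apply(unclass(aln), 2, function(col) any(col %in% drop_columns_with))
  keep <- which(!bad)
  out <- unclass(aln)[, keep, drop = FALSE]
  out <- structure(out, class = class(aln), gene_id = gene_id(aln))
  discarded <- (3L * length(keep)) < min_cds_nt
  report <- tibble::tibble(
    gene = gene_id(aln),
    original_length_nt = 3L * ncol(aln),
    filtered_length_nt = 3L * length(keep),
    discarded = discarded
  )
  list(alignment = out, site_map = keep, discarded = discarded,
       report = report)
}

# --- FASTA IO -------------------------------------------------------------

#' Read a codon alignment from FASTA
#'
#' @param path FASTA file; gene id defaults to the file name without
#'   extension.
#' @param gene_id Optional explicit gene id.
#' @return A `codon_alignment`.
#' @export
read_codon_fasta <- function(path, gene_id = NULL) {
  x <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(x), names(x))
  codon_alignment(seqs, gene_id = gene_id %||%
                    tools::file_path_sans_ext(basename(path)))
}

#' Write an alignment to FASTA
#'
#' @param aln A `codon_alignment` or `protein_alignment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
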