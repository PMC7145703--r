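#' Branch-site positive-selection scan across genes and configurations
#'
#' Runs the null/alternative branch-site fits, the likelihood-ratio test
#' and BEB site identification for every gene under each requested
#' foreground configuration, and applies Benjamini-Hochberg correction
#' across genes within each configuration.
#'
#' @param alignments Named list of filtered `codon_alignment`s.
#' @param tree Rooted `phylo` over the study taxa (tags are reset per
#'   configuration).
#' @param configurations Character vector of foreground configuration
#'   names (subset of `names(foreground_configs())`).
#' @param beb_threshold BEB posterior cut-off for selected sites.
#' @param fdr_threshold Significance cut-off on the adjusted q value.
#' @param site_maps Optional named list of coordinate maps (from
#'   [filter_alignment()]) used to report BEB sites in original
#'   coordinates.
#' @param ... Passed to [fit_branch_site()] (e.g. `branch_lengths`,
#'   `n_starts`).
#' @return A `selection_scan` tibble: one row per gene x configuration
#'   with `lnL_alt`, `lnL_null`, `statistic`, `p_value`, `q_value`,
#'   `significant`, `beb` (list column of per-site tibbles) and
#'   `beb_sites` (compact `site:posterior` string of flagged sites).
#' @export
scan_positive_selection <- function(alignments, tree, configurations = "CF",
                                    beb_threshold = 0.90,
                                    fdr_threshold = 0.05,
                                    site_maps = NULL, ...) {
  stopifnot(length(alignments) > 0)
  if (is.null(names(alignments))) {
    names(alignments) <- vapply(alignments, gene_id, character(1))
  }
  rows <- list()
  for (cfg in configurations) {
    tr <- mark_foreground(tree, cfg)
    for (g in names(alignments)) {
      fit0 <- fit_branch_site(alignments[[g]], tr, null = TRUE, ...)
      fit1 <- fit_branch_site(alignments[[g]], tr, null = FALSE, init = fit0,
                              ...)
      res <- lrt(fit1, fit0)
      beb <- if (fit1$converged) {
        beb_sites(fit1, threshold = beb_threshold)
      } else {
        tibble::tibble(gene = g, site = integer(0), posterior = numeric(0),
                       selected = logical(0))
      }
      if (!is.null(site_maps[[g]])) {
        beb$site <- site_maps[[g]][beb$site]
      }
      rows[[length(rows) + 1]] <- dplyr::mutate(
        res, configuration = cfg,
        omega2 = fit1$estimate[["omega2"]],
        converged = fit1$converged,
        beb = list(beb), .after = "gene")
    }
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$configuration) |>
    dplyr::mutate(q_value = fdr_adjust(.data$p_value),
                  significant = .data$q_value < fdr_threshold) |>
    dplyr::ungroup()
  out$beb_sites <- vapply(out$beb, function(b) {
    b <- b[b$selected, , drop = FALSE]
    paste(sprintf("%d:%.3f", b$site, b$posterior), collapse = ";")
  }, character(1))
  class(out) <- c("selection_scan", class(out))
  out
}

#' BEB results of a scan as one tidy table
#'
#' @param scan A `selection_scan`.
#' @param selected_only Keep only flagged sites (default `TRUE`).
#' @return Tibble: `gene`, `configuration`, `site`, `posterior`,
#'   `selected`.
#' @export
scan_beb_table <- function(scan, selected_only = TRUE) {
  out <- scan |>
    dplyr::select("gene", "configuration", "beb") |>
    tidyr::unnest("beb", names_repair = "minimal")
  out <- out[, c("gene", "configuration", "site", "posterior", "selected")]
  if (selected_only) out <- dplyr::filter(out, .data$selected)
  out
}

#' @method autoplot selection_scan
#' @export
autoplot.selection_scan <- function(object, ...) {
  df <- dplyr::mutate(object,
                      neglog_q = -log10(pmax(.data$q_value, 1e-16)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$neglog_q,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$configuration)) +
    ggplot2::labs(y = "-log10 q (BH)", x = NULL, colour = "q < 0.05") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
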