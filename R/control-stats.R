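# Matched phylogenetic-control comparison of convergence counts: each
# echolocator pairwise comparison is paired with a comparison between the
# same echolocating lineage and a nonecholocating lineage at equal
# phylogenetic distance, and the paired counts are compared by a
# paired-sample t test.

#' Load the packaged paired-count table
#'
#' The seven published rows of parallel/convergent gene and site counts
#' for the echolocator pairwise comparisons and their matched
#' equally-distant controls.
#'
#' @return A `paired_count_table` tibble (7 rows).
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_paired_counts.tsv",
                      package = "echoconv", mustWork = TRUE)
  tab <- utils::read.delim(path, check.names = FALSE)
  paired_count_table(tibble::as_tibble(tab))
}

#' Construct a paired count table
#'
#' @param x Tibble/data frame with columns `echo_comparison`,
#'   `control_comparison` and, for each side, `*_parallel_genes`,
#'   `*_parallel_sites`, `*_convergent_genes`, `*_convergent_sites`.
#' @return A `paired_count_table`.
#' @export
paired_count_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c(paste0("echo_", c("parallel_genes", "parallel_sites",
                              "convergent_genes", "convergent_sites")),
            paste0("control_", c("parallel_genes", "parallel_sites",
                                 "convergent_genes", "convergent_sites")))
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("paired count table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- as.matrix(x[need])
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  class(x) <- c("paired_count_table", class(x))
  x
}

#' Paired-sample t test of echolocator vs control counts
#'
#' Classical two-sided paired t test on the (echolocating - control)
#' differences of the chosen metric, df = rows - 1.
#'
#' @param table A `paired_count_table`.
#' @param metric One of `"parallel_genes"`, `"parallel_sites"`,
#'   `"convergent_genes"`, `"convergent_sites"`.
#' @return Tibble: `metric`, `estimate` (mean difference), `statistic`,
#'   `df`, `p_value`.
#' @export
paired_t_test <- function(table, metric = c("parallel_genes",
                                            "parallel_sites",
                                            "convergent_genes",
                                            "convergent_sites")) {
  stopifnot(inherits(table, "paired_count_table"))
  metric <- match.arg(metric)
  echo <- table[[paste0("echo_", metric)]]
  ctrl <- table[[paste0("control_", metric)]]
  if (length(echo) < 2) stop("need at least 2 paired rows", call. = FALSE)
  d <- echo - ctrl
  if (stats::var(d) == 0) {
    stop("degenerate pairs: all differences identical (variance 0)",
         call. = FALSE)
  }
  tt <- stats::t.test(echo, ctrl, paired = TRUE)
  tibble::tibble(metric = metric,
                 estimate = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value)
}

#' All four paired metric tests of a count table
#'
#' @param table A `paired_count_table`.
#' @return Tibble with one row per metric (see [paired_t_test()]).
#' @export
paired_t_tests <- function(table) {
  metrics <- c("parallel_genes", "parallel_sites", "convergent_genes",
               "convergent_sites")
  dplyr::bind_rows(lapply(metrics, function(m) paired_t_test(table, m)))
}

#' Sites both positively selected and parallel
#'
#' Site-level intersection of the positively selected sites (BEB flagged)
#' with the parallel convergence calls, per gene, listing the foreground
#' configuration(s) and comparison pair(s) supporting each site.
#'
#' @param beb Tibble of BEB results across genes with columns `gene`,
#'   `site`, `selected`, and optionally `configuration`.
#' @param parallel_calls Tibble of [classify_pair()] calls with columns
#'   `gene`, `site`, `type`, and optionally `pair`.
#' @return Tibble: `gene`, `site`, `configurations`, `pairs`.
#' @export
adaptive_overlap <- function(beb, parallel_calls) {
  if (!"configuration" %in% names(beb)) beb$configuration <- ""
  if (!"pair" %in% names(parallel_calls)) parallel_calls$pair <- ""
  sel <- beb |>
    dplyr::filter(.data$selected) |>
    dplyr::group_by(.data$gene, .data$site) |>
    dplyr::summarise(
      configurations = paste(sort(unique(.data$configuration)),
                             collapse = ";"),
      .groups = "drop")
  par <- parallel_calls |>
    dplyr::filter(.data$type == "parallel") |>
    dplyr::group_by(.data$gene, .data$site) |>
    dplyr::summarise(pairs = paste(sort(unique(.data$pair)), collapse = ";"),
                     .groups = "drop")
  dplyr::inner_join(sel, par, by = c("gene", "site")) |>
    dplyr::arrange(.data$gene, .data$site)
}

#' Plot a paired count table
#'
#' Dot-and-segment comparison of echolocator vs matched-control counts
#' for one metric across the seven paired rows.
#'
#' @param table A `paired_count_table`.
#' @param metric Metric to plot (see [paired_t_test()]).
#' @return A ggplot object.
#' @export
plot_paired_counts <- function(table, metric = "parallel_genes") {
  echo <- table[[paste0("echo_", metric)]]
  ctrl <- table[[paste0("control_", metric)]]
  lab <- paste0(table$echo_comparison, " | ", table$control_comparison)
  df <- tibble::tibble(
    row = factor(rep(lab, 2), levels = rev(unique(lab))),
    side = rep(c("echolocating", "control"), each = nrow(table)),
    count = c(echo, ctrl)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$row)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$row), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$side), size = 2.5) +
    ggplot2::labs(x = metric, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
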