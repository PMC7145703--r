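# End-to-end orchestration: simulate (or load) -> filter -> translate ->
# reconstruct -> converge -> select -> control stats, with one root seed,
# per-stage TSV outputs and a manifest of counts and checksums.

#' Build a pipeline run configuration
#'
#' All thresholds default to the study values: BEB posterior 0.90, FDR
#' 0.05, minimum CDS length 150 nt. When `alignment_files` is `NULL` the
#' pipeline simulates `n_genes` codon alignments on the 19-taxon study
#' tree; `n_selected` of them evolve under foreground selection
#' (`params_selected`) on `selection_config`'s branches and additionally
#' receive `n_inject_parallel` injected parallel amino-acid sites (at
#' positively-selected site classes) on the first echolocator comparison
#' of the design, so the adaptive-overlap stage has known truth.
#'
#' @param seed Root seed; every stage derives substreams from it.
#' @param out_dir Output directory.
#' @param n_genes,n_sites Simulated gene count and codon length.
#' @param n_selected Genes carrying foreground selection + injection.
#' @param n_inject_parallel Injected parallel sites per selected gene.
#' @param params,params_selected [site_class_params()] for background
#'   and selected genes.
#' @param selection_config Foreground configuration used for simulation
#'   and scanning.
#' @param configurations Configurations to scan (default: the
#'   simulation's).
#' @param alignment_files,tree_file Optional FASTA paths and Newick path
#'   to analyse instead of simulating.
#' @param design Comparison design, default [study_design()].
#' @param min_cds_nt,beb_threshold,fdr_threshold Study thresholds.
#' @param branch_lengths Codon-fit branch-length policy (`"fixed"` or
#'   `"m0"`).
#' @param asr_branch_lengths `"fit"` (ML per gene) or `"input"`.
#' @param n_starts Optimizer starts for the branch-site fits.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("echoconv_run_"),
                            n_genes = 12L, n_sites = 120L, n_selected = 2L,
                            n_inject_parallel = 4L,
                            params = site_class_params(),
                            params_selected = site_class_params(omega2 = 8),
                            selection_config = "CF+FM",
                            configurations = selection_config,
                            alignment_files = NULL, tree_file = NULL,
                            design = study_design(),
                            min_cds_nt = 150L, beb_threshold = 0.90,
                            fdr_threshold = 0.05,
                            branch_lengths = "fixed",
                            asr_branch_lengths = "fit",
                            n_starts = 1L) {
  stopifnot(beb_threshold > 0, beb_threshold < 1,
            fdr_threshold > 0, fdr_threshold < 1)
  stopifnot(all(configurations %in% names(foreground_configs())))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage of the configuration, writes per-stage TSVs
#' under `config$out_dir` and returns a manifest (also written as JSON)
#' recording the seed, per-stage gene counts and the MD5 checksum of
#' every output file. Re-running the same configuration and seed
#' reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly a list; elements include `seed`,
#'   `counts`, `checksums`, `outputs`, and the in-memory stage results
#'   in `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  outputs <- character(0)

  ## stage 1: obtain gene set -------------------------------------------
  if (is.null(config$alignment_files)) {
    tree <- make_study_fixture(substream_seed(config$seed, 0))
    sim_tree <- mark_foreground(tree, config$selection_config)
    genes <- list(); truth <- list(); prot_sims <- list()
    for (i in seq_len(config$n_genes)) {
      gid <- sprintf("g%03d", i)
      selected <- i <= config$n_selected
      pars <- if (selected) config$params_selected else config$params
      sim <- simulate_codon_alignment(sim_tree, pars, config$n_sites,
                                      substream_seed(config$seed, i),
                                      gene_id = gid)
      psim <- protein_sim_from_codon(sim)
      if (selected && config$n_inject_parallel > 0) {
        echo1 <- config$design[config$design$side == "echo", ][1, ]
        cand <- which(sim$site_class %in% c("2a", "2b"))
        psim <- inject_convergence(
          psim, c(echo1$branch_a, echo1$branch_b),
          n_parallel = config$n_inject_parallel, n_convergent = 0,
          seed = substream_seed(config$seed, 10000 + i),
          candidate_sites = cand)
        tr <- psim$truth
        if (nrow(tr)) tr$gene <- gid
        truth[[gid]] <- tr
      }
      genes[[gid]] <- sim$alignment
      prot_sims[[gid]] <- psim
    }
    truth <- dplyr::bind_rows(truth)
  } else {
    tree <- parse_newick(paste(readLines(config$tree_file), collapse = ""))
    genes <- lapply(config$alignment_files, read_codon_fasta)
    names(genes) <- vapply(genes, gene_id, character(1))
    prot_sims <- NULL
    truth <- tibble::tibble()
  }

  ## stage 2: filter ----------------------------------------------------
  filt <- lapply(genes, filter_alignment, min_cds_nt = config$min_cds_nt)
  report <- dplyr::bind_rows(lapply(filt, `[[`, "report"))
  outputs <- c(outputs, tsv(report, "filter_report.tsv"))
  kept <- names(filt)[!vapply(filt, `[[`, logical(1), "discarded")]
  aln <- lapply(filt[kept], `[[`, "alignment")
  maps <- lapply(filt[kept], `[[`, "site_map")

  ## stage 3: translate + ASR -------------------------------------------
  model <- aa_model("poisson")
  recons <- list()
  for (g in kept) {
    paln <- if (!is.null(prot_sims)) {
      # analysis runs on the (possibly injected) protein alignment,
      # restricted to the filter-surviving columns
      pa <- prot_sims[[g]]$alignment
      protein_alignment(unclass(pa)[, maps[[g]], drop = FALSE], gene_id = g)
    } else {
      translate_alignment(aln[[g]])
    }
    tr_g <- tree
    if (config$asr_branch_lengths == "fit") {
      tr_g <- fit_branch_lengths(paln, tree, model)$tree
    }
    recons[[g]] <- reconstruct_marginal(paln, tr_g, model)
  }
  asr_tab <- dplyr::bind_rows(lapply(recons, tidy))
  outputs <- c(outputs, tsv(asr_tab, "ancestral_states.tsv"))

  ## stage 4: convergence -----------------------------------------------
  calls <- list(); excess <- list()
  for (g in kept) {
    for (r in seq_len(nrow(config$design))) {
      d <- config$design[r, ]
      cl <- classify_pair(recons[[g]], d$branch_a, d$branch_b)
      if (nrow(cl)) {
        cl$site <- maps[[g]][cl$site]       # original coordinates
        cl$pair <- d$pair
        cl$side <- d$side
        cl$row <- d$row
        calls[[length(calls) + 1]] <- cl
      }
      ex <- convergence_excess_test(recons[[g]], d$branch_a, d$branch_b,
                                    model)
      ex$pair <- d$pair; ex$side <- d$side; ex$row <- d$row
      excess[[length(excess) + 1]] <- ex
    }
  }
  calls <- dplyr::bind_rows(calls)
  if (nrow(calls) == 0) {
    calls <- tibble::tibble(gene = character(0), site = integer(0),
                            branch_a = character(0), branch_b = character(0),
                            derived = character(0), parent_a = character(0),
                            parent_b = character(0), type = character(0),
                            pair = character(0), side = character(0),
                            row = integer(0))
  }
  excess <- dplyr::bind_rows(excess)
  outputs <- c(outputs, tsv(calls, "convergence_calls.tsv"),
               tsv(excess, "convergence_excess.tsv"))
  summ <- summarize_pairs(calls[calls$side == "echo", , drop = FALSE],
                          config$design[config$design$side == "echo", ])
  outputs <- c(outputs, tsv(summ$summary, "pair_summary.tsv"))

  ## stage 5: selection scan --------------------------------------------
  if (length(aln)) {
    scan <- scan_positive_selection(
      aln, tree, configurations = config$configurations,
      beb_threshold = config$beb_threshold,
      fdr_threshold = config$fdr_threshold, site_maps = maps,
      branch_lengths = config$branch_lengths, n_starts = config$n_starts)
  } else {
    scan <- structure(
      tibble::tibble(gene = character(0), configuration = character(0),
                     omega2 = numeric(0), converged = logical(0),
                     beb = list(), lnL_alt = numeric(0),
                     lnL_null = numeric(0), statistic = numeric(0),
                     df = numeric(0), p_value = numeric(0),
                     q_value = numeric(0), significant = logical(0),
                     beb_sites = character(0)),
      class = c("selection_scan", "tbl_df", "tbl", "data.frame"))
  }
  outputs <- c(outputs,
               tsv(dplyr::select(scan, -"beb"), "selection_scan.tsv"))

  ## stage 6: control stats + overlap -----------------------------------
  paired <- pipeline_paired_table(calls, config$design)
  ttests <- tryCatch(paired_t_tests(paired), error = function(e) {
    tibble::tibble(metric = character(0), estimate = numeric(0),
                   statistic = numeric(0), df = numeric(0),
                   p_value = numeric(0))
  })
  outputs <- c(outputs, tsv(paired, "paired_counts.tsv"),
               tsv(ttests, "paired_t_tests.tsv"))
  overlap <- if (nrow(scan)) {
    adaptive_overlap(scan_beb_table(scan, selected_only = FALSE),
                     calls[calls$side == "echo", , drop = FALSE])
  } else {
    tibble::tibble(gene = character(0), site = integer(0),
                   configurations = character(0), pairs = character(0))
  }
  outputs <- c(outputs, tsv(overlap, "adaptive_overlap.tsv"))

  manifest <- list(
    seed = config$seed,
    counts = list(genes_in = length(genes),
                  genes_discarded = length(genes) - length(kept),
                  genes_analyzed = length(kept)),
    outputs = basename(outputs),
    checksums = as.list(tools::md5sum(outputs))
  )
  names(manifest$checksums) <- basename(outputs)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$results <- list(filter = report, calls = calls, excess = excess,
                           pair_summary = summ, scan = scan,
                           paired = paired, t_tests = ttests,
                           overlap = overlap, truth = truth)
  invisible(manifest)
}

# per-row echo vs control paired counts from pipeline calls
pipeline_paired_table <- function(calls, design) {
  count_side <- function(r, side) {
    d <- design[design$row == r & design$side == side, ]
    cl <- calls[calls$row == r & calls$side == side, , drop = FALSE]
    c(parallel_genes = length(unique(cl$gene[cl$type == "parallel"])),
      parallel_sites = sum(cl$type == "parallel"),
      convergent_genes = length(unique(cl$gene[cl$type == "convergent"])),
      convergent_sites = sum(cl$type == "convergent"))
  }
  rows <- sort(unique(design$row))
  tab <- tibble::tibble(
    row = rows,
    echo_comparison = vapply(rows, function(r)
      design$pair[design$row == r & design$side == "echo"], character(1)),
    control_comparison = vapply(rows, function(r)
      design$pair[design$row == r & design$side == "control"], character(1))
  )
  em <- t(vapply(rows, count_side, numeric(4), side = "echo"))
  cm <- t(vapply(rows, count_side, numeric(4), side = "control"))
  colnames(em) <- paste0("echo_", colnames(em))
  colnames(cm) <- paste0("control_", colnames(cm))
  paired_count_table(dplyr::bind_cols(tab, tibble::as_tibble(em),
                                      tibble::as_tibble(cm)))
}

# protein-level view of a codon simulation: node states, alignment and
# history mapped through the genetic code (synonymous events drop out)
protein_sim_from_codon <- function(sim) {
  stopifnot(inherits(sim, "sim_alignment"),
            identical(sim$alphabet, sense_codons()))
  aa_idx <- match(codon_aa(), AA_STATES)
  node_state <- matrix(aa_idx[sim$node_state], nrow = nrow(sim$node_state))
  h <- sim$history
  from_aa <- codon_aa()[match(h$from, sense_codons())]
  to_aa <- codon_aa()[match(h$to, sense_codons())]
  keep <- from_aa != to_aa
  history <- tibble::tibble(branch = h$branch[keep], edge = h$edge[keep],
                            site = h$site[keep], time = h$time[keep],
                            from = from_aa[keep], to = to_aa[keep])
  structure(
    list(alignment = translate_alignment(sim$alignment), history = history,
         node_state = node_state, site_class = sim$site_class,
         tree = sim$tree, seed = sim$seed, alphabet = AA_STATES),
    class = "sim_alignment"
  )
}
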