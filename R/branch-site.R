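# Branch-site (model A) positive-selection machinery. Four site classes:
#   0:  omega0 on every branch          (proportion p0)
#   1:  omega = 1 on every branch       (proportion p1)
#   2a: omega0 background / omega2 foreground
#   2b: omega 1 background / omega2 foreground
# with (2a, 2b) sharing 1 - p0 - p1 in ratio p0:p1. The null fixes
# omega2 = 1; the alternative estimates omega2 >= 1.

# site-pattern compression: unique tip-state columns with weights
compress_patterns <- function(tipstates) {
  key <- apply(tipstates, 2, paste, collapse = ",")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(states = tipstates[, u, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = sum(u))),
       index = idx)
}

# per-class per-pattern log-likelihood of the model-A mixture;
# omegas = c(omega0, 1, omega2), shared scale over classes.
bs_class_loglik <- function(ti, pat, fg_po, pi, p0, p1, omega0, omega2,
                            kappa, scale_override = NULL) {
  Q0 <- gy94_unscaled(kappa, omega0, pi)
  Q1 <- gy94_unscaled(kappa, 1, pi)
  prop <- c(p0, p1,
            (1 - p0 - p1) * p0 / (p0 + p1),
            (1 - p0 - p1) * p1 / (p0 + p1))
  r <- function(Q) -sum(pi * diag(Q))
  scale <- scale_override %||%
    ((prop[1] + prop[3]) * r(Q0) + (prop[2] + prop[4]) * r(Q1))
  eig0 <- rev_eigen(Q0 / scale, pi)
  eig1 <- rev_eigen(Q1 / scale, pi)
  same2 <- abs(omega2 - 1) < 1e-12
  eig2 <- if (same2) eig1 else
    rev_eigen(gy94_unscaled(kappa, omega2, pi) / scale, pi)
  ne <- nrow(ti$edge)
  P0 <- pmats(eig0, ti$length)
  P1 <- pmats(eig1, ti$length)
  P2 <- if (same2) P1 else {
    out <- vector("list", ne)
    out[fg_po] <- pmats(eig2, ti$length[fg_po])
    out
  }
  pick <- function(bg, fg) {
    out <- bg
    out[fg_po] <- fg[fg_po]
    out
  }
  plists <- list(P0, P1, pick(P0, P2), pick(P1, P2))
  ll <- matrix(0, 4, ncol(pat$states))
  for (cl in 1:4) {
    ll[cl, ] <- prune_pass(ti, pat$states, plists[[cl]], pi)$site_loglik
  }
  list(class_loglik = ll, prop = prop, scale = scale)
}

bs_mix_loglik <- function(parts, weights) {
  lp <- log(parts$prop)
  persite <- log_colsums_exp(parts$class_loglik + lp)
  sum(weights * persite)
}

#' Fit the branch-site model A (alternative or null) to one gene
#'
#' Maximizes the model-A mixture likelihood for a codon alignment on a
#' tree whose `FOREGROUND`-tagged branches form the foreground. Codon
#' frequencies are F3x4 from the alignment (or uniform); branch lengths
#' are re-estimated once under the single-omega (M0) model and then held
#' fixed (`branch_lengths = "m0"`, the default) or taken from the tree
#' as given (`"fixed"`). Optimization is bounded quasi-Newton on
#' transformed parameters from `n_starts` deterministic starts; the
#' alternative is additionally started from the null optimum so its
#' log-likelihood can never fall below the null's.
#'
#' @param aln A filtered `codon_alignment`.
#' @param tree Rooted `phylo` with `FOREGROUND` tags (see
#'   [mark_foreground()]).
#' @param null Fit the null (omega2 fixed at 1)?
#' @param branch_lengths `"m0"` or `"fixed"`.
#' @param freqs `"f3x4"` or `"uniform"`.
#' @param n_starts Deterministic optimizer starts (>= 1).
#' @param init Optional `branch_site_fit` whose parameter estimates seed
#'   an extra start (used to chain alternative after null).
#' @param tol Relative log-likelihood convergence tolerance.
#' @return A `branch_site_fit`: log-likelihood, estimates (`p0`, `p1`,
#'   `omega0`, `omega2`, `kappa`), per-site class posteriors, convergence
#'   diagnostics, plus internal state reused by [beb_sites()].
#' @export
fit_branch_site <- function(aln, tree, null = FALSE,
                            branch_lengths = c("m0", "fixed"),
                            freqs = c("f3x4", "uniform"),
                            n_starts = 2L, init = NULL, tol = 1e-8) {
  stopifnot(inherits(aln, "codon_alignment"))
  branch_lengths <- match.arg(branch_lengths)
  freqs <- match.arg(freqs)
  if (!length(tagged_edges(tree, "FOREGROUND"))) {
    stop("tree has no FOREGROUND-tagged branch", call. = FALSE)
  }
  pi <- if (freqs == "f3x4") codon_freqs_f3x4(aln) else rep(1 / 61, 61)
  tipstates <- tip_state_matrix(aln, tree, sense_codons())
  degenerate <- all(apply(tipstates, 2, function(x) {
    x <- x[!is.na(x)]
    length(unique(x)) <= 1L
  }))
  m0 <- NULL
  if (branch_lengths == "m0") {
    m0 <- fit_m0(tipstates, tree, pi)
    tree <- m0$tree
  }
  ti <- tree_index(tree)
  fg_po <- foreground_mask(tree)[ti$orig_edge]
  pat <- compress_patterns(tipstates)

  # unconstrained parameterization: softmax for (p0, p1, p2), logit for
  # omega0 in (0,1), log(omega2 - 1), log kappa
  unpack <- function(x, null) {
    e <- exp(c(x[1], x[2], 0))
    p <- e / sum(e)
    list(p0 = p[1], p1 = p[2],
         omega0 = stats::plogis(x[3]),
         omega2 = if (null) 1 else 1 + exp(x[4]),
         kappa = exp(x[if (null) 4 else 5]))
  }
  pack <- function(p0, p1, omega0, omega2, kappa, null) {
    p2 <- max(1 - p0 - p1, 1e-6)
    base <- c(log(max(p0, 1e-6) / p2), log(max(p1, 1e-6) / p2),
              stats::qlogis(min(max(omega0, 1e-6), 1 - 1e-6)))
    if (null) c(base, log(kappa))
    else c(base, log(max(omega2 - 1, 1e-6)), log(kappa))
  }
  nll <- function(x) {
    th <- unpack(x, null)
    parts <- bs_class_loglik(ti, pat, fg_po, pi, th$p0, th$p1, th$omega0,
                             th$omega2, th$kappa)
    v <- bs_mix_loglik(parts, pat$weights)
    if (!is.finite(v)) 1e10 else -v
  }

  if (is.null(init)) {
    starts <- list(
      pack(0.70, 0.20, 0.20, 2.0, 2.0, null),
      pack(0.45, 0.45, 0.05, 1.5, 1.5, null)
    )[seq_len(min(2L, max(1L, n_starts)))]
  } else {
    # chain from the supplied fit (typically null -> alternative): one
    # start at its optimum, one exploring a clearly selective omega2
    est <- init$estimate
    starts <- list(pack(est[["p0"]], est[["p1"]], est[["omega0"]],
                        max(if (null) 1 else est[["omega2"]], 1.001),
                        est[["kappa"]], null))
    if (!null) {
      starts <- c(starts, list(pack(est[["p0"]], est[["p1"]], est[["omega0"]],
                                    3, est[["kappa"]], null)))
    }
  }
  best <- NULL
  codes <- integer(0)
  for (x0 in starts) {
    opt <- stats::nlminb(x0, nll,
                         control = list(iter.max = 300, eval.max = 600,
                                        rel.tol = tol))
    codes <- c(codes, opt$convergence)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  th <- unpack(best$par, null)
  parts <- bs_class_loglik(ti, pat, fg_po, pi, th$p0, th$p1, th$omega0,
                           th$omega2, th$kappa)
  lp <- log(parts$prop)
  persite_pat <- log_colsums_exp(parts$class_loglik + lp)
  loglik <- sum(pat$weights * persite_pat)
  # naive empirical Bayes class posteriors per original site
  post_pat <- exp(parts$class_loglik + lp -
                    rep(persite_pat, each = 4))
  class_posterior <- t(post_pat)[pat$index, , drop = FALSE]
  colnames(class_posterior) <- c("0", "1", "2a", "2b")

  structure(
    list(
      gene = gene_id(aln),
      null = null,
      loglik = loglik,
      estimate = c(p0 = th$p0, p1 = th$p1, omega0 = th$omega0,
                   omega2 = th$omega2, kappa = th$kappa),
      scale = parts$scale,
      class_posterior = class_posterior,
      converged = any(codes == 0L) && !degenerate,
      degenerate = degenerate,
      n_starts = length(starts),
      convergence_codes = codes,
      tree = tree,
      m0 = if (!is.null(m0)) m0[c("kappa", "omega", "loglik")],
      pi = pi,
      ti = ti, fg_po = fg_po, pat = pat
    ),
    class = "branch_site_fit"
  )
}

#' @export
print.branch_site_fit <- function(x, ...) {
  cat(sprintf("Branch-site %s fit: gene %s  lnL = %.6f\n",
              if (x$null) "null (omega2 = 1)" else "alternative",
              x$gene, x$loglik))
  print(round(x$estimate, 4))
  invisible(x)
}

#' @method tidy branch_site_fit
#' @export
tidy.branch_site_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate))
}

#' @method glance branch_site_fit
#' @export
glance.branch_site_fit <- function(x, ...) {
  tibble::tibble(gene = x$gene, null = x$null, logLik = x$loglik,
                 converged = x$converged, degenerate = x$degenerate,
                 n_starts = x$n_starts)
}

# M0 (single omega) fit: kappa, omega and branch lengths, by alternating
# (kappa, omega) quasi-Newton with edgewise branch-length sweeps.
fit_m0 <- function(tipstates, tree, pi, rounds = 2L) {
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  pat <- compress_patterns(tipstates)
  kappa <- 2; omega <- 0.5
  ll <- -Inf
  for (r in seq_len(rounds)) {
    # branch lengths given (kappa, omega)
    eig <- rev_eigen(build_gy94(kappa, omega, pi), pi)
    tree <- m0_length_sweep(tree, pat, pi, eig)
    # (kappa, omega) given lengths
    ti <- tree_index(tree)
    nl <- function(x) {
      eig <- rev_eigen(build_gy94(exp(x[1]), exp(x[2]), pi), pi)
      plist <- lapply(ti$length, pmat, eig = eig)
      v <- sum(pat$weights *
                 prune_pass(ti, pat$states, plist, pi)$site_loglik)
      if (!is.finite(v)) 1e10 else -v
    }
    opt <- stats::optim(log(c(kappa, omega)), nl, method = "BFGS",
                        control = list(maxit = 100, reltol = 1e-8))
    kappa <- exp(opt$par[1]); omega <- exp(opt$par[2])
    if (-opt$value - ll < 1e-6 && r > 1) { ll <- max(-opt$value, ll); break }
    ll <- -opt$value
  }
  list(tree = tree, kappa = kappa, omega = omega, loglik = ll)
}

# one-dimensional Brent updates of every branch under a fixed codon model
m0_length_sweep <- function(tree, pat, pi, eig, sweeps = 2L) {
  n <- 61L
  S <- ncol(pat$states)
  w <- pat$weights
  for (sw in seq_len(sweeps)) {
    for (e in seq_len(nrow(tree$edge))) {
      ti <- tree_index(tree)
      plist <- lapply(ti$length, pmat, eig = eig)
      pr <- prune_pass(ti, pat$states, plist, pi, keep = TRUE)
      U <- up_pass(ti, pr, plist, pi)
      k <- match(e, ti$orig_edge)
      pa <- ti$edge[k, 1]; ch <- ti$edge[k, 2]
      W <- U[[pa]]
      for (j in setdiff(which(ti$edge[, 1] == pa), k)) W <- W * pr$msg[[j]]$M
      if (ch <= ti$ntip) {
        st <- pat$states[ch, ]
        obs <- which(!is.na(st))
        f <- function(t) {
          P <- pmat(eig, t)
          M <- matrix(1, n, S)
          if (length(obs)) M[, obs] <- P[, st[obs]]
          sum(w * log(.colSums(W * M, n, S)))
        }
      } else {
        D <- pr$partial[[ch]]
        f <- function(t) {
          P <- pmat(eig, t)
          sum(w * log(.colSums(W * (P %*% D), n, S)))
        }
      }
      opt <- stats::optimize(f, c(0, 10), maximum = TRUE, tol = 1e-7)
      if (opt$objective >= f(tree$edge.length[e])) {
        tree$edge.length[e] <- opt$maximum
      }
    }
  }
  tree
}

#' Likelihood-ratio test of the branch-site alternative vs null
#'
#' Statistic `max(0, 2 * (lnL_alt - lnL_null))`, compared to chi-square
#' with 1 degree of freedom (the conservative reference recommended for
#' this test).
#'
#' @param fit_alt,fit_null `branch_site_fit`s of the same gene
#'   (alternative / null).
#' @param mixture_ref Use the 50:50 mixture of 0 and chi-square(1)
#'   reference instead? Default `FALSE`.
#' @return Tibble: `gene`, `lnL_alt`, `lnL_null`, `statistic`, `df`,
#'   `p_value`.
#' @export
lrt <- function(fit_alt, fit_null, mixture_ref = FALSE) {
  stopifnot(inherits(fit_alt, "branch_site_fit"),
            inherits(fit_null, "branch_site_fit"))
  if (!identical(fit_alt$gene, fit_null$gene)) {
    stop("fits are for different genes: '", fit_alt$gene, "' vs '",
         fit_null$gene, "'", call. = FALSE)
  }
  if (fit_alt$null || !fit_null$null) {
    stop("lrt() expects (alternative, null) in that order", call. = FALSE)
  }
  stat <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (mixture_ref) p <- if (stat == 0) 1 else p / 2
  tibble::tibble(gene = fit_alt$gene, lnL_alt = fit_alt$loglik,
                 lnL_null = fit_null$loglik, statistic = stat, df = 1,
                 p_value = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values, order-preserving with the input.
#'
#' @param p Numeric vector of P values in `[0, 1]`.
#' @return Numeric vector of q values.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("P values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Bayes empirical Bayes positively selected sites
#'
#' Per-site posterior probability that a site belongs to the foreground
#' positive-selection classes (2a or 2b), averaging over a uniform
#' discrete prior grid on the mixture parameters: 10 points each for the
#' class-proportion coordinates (`p0 + p1` and `p0/(p0+p1)`), omega0 in
#' (0, 1) and omega2 in (1, 11); kappa, branch lengths and the mixture
#' rate normalization stay at their MLEs. Sites with posterior > 0.90
#' are flagged as positively selected.
#'
#' @param fit_alt A converged alternative `branch_site_fit`.
#' @param grid_points Grid resolution per parameter dimension.
#' @param threshold Posterior cut-off for flagging (default 0.90).
#' @return Tibble: `gene`, `site` (alignment coordinates), `posterior`,
#'   `selected`.
#' @export
beb_sites <- function(fit_alt, grid_points = 10L, threshold = 0.90) {
  stopifnot(inherits(fit_alt, "branch_site_fit"))
  if (fit_alt$null) stop("beb_sites() needs the alternative fit", call. = FALSE)
  if (!fit_alt$converged) {
    stop("alternative fit for gene '", fit_alt$gene,
         "' did not converge (", paste(fit_alt$convergence_codes,
                                       collapse = ","),
         "); refusing BEB", call. = FALSE)
  }
  ti <- fit_alt$ti
  pat <- fit_alt$pat
  fg_po <- fit_alt$fg_po
  pi <- fit_alt$pi
  kappa <- fit_alt$estimate[["kappa"]]
  scale <- fit_alt$scale
  g <- grid_points
  mid <- (seq_len(g) - 0.5) / g
  w0_grid <- mid                 # omega0 in (0,1)
  w2_grid <- 1 + 10 * mid        # omega2 in (1,11)

  # per-(bg omega, fg omega) pattern log-likelihood; omega values indexed
  # 1..g for omega0 grid, g+1 for 1, g+2..2g+1 for omega2 grid
  omegas <- c(w0_grid, 1, w2_grid)
  eigs <- lapply(omegas, function(w)
    rev_eigen(gy94_unscaled(kappa, w, pi) / scale, pi))
  Pm <- lapply(seq_along(omegas), function(i) pmats(eigs[[i]], ti$length))
  npat <- ncol(pat$states)
  pass <- function(bg, fg) {
    plist <- Pm[[bg]]
    if (fg != bg) {
      plist[fg_po] <- Pm[[fg]][fg_po]
    }
    prune_pass(ti, pat$states, plist, pi)$site_loglik
  }
  i1 <- g + 1L
  L00 <- t(vapply(seq_len(g), function(a) pass(a, a), numeric(npat)))
  L11 <- pass(i1, i1)
  L02 <- array(0, dim = c(g, g, npat))   # bg omega0_a, fg omega2_b
  for (a in seq_len(g)) {
    for (b in seq_len(g)) L02[a, b, ] <- pass(a, g + 1L + b)
  }
  L12 <- t(vapply(seq_len(g), function(b) pass(i1, g + 1L + b),
                  numeric(npat)))

  # proportion grid
  t1 <- mid   # p0 + p1
  t2 <- mid   # p0 / (p0 + p1)
  combos <- expand.grid(a = seq_len(g), b = seq_len(g),
                        i = seq_len(g), j = seq_len(g))
  p0 <- t1[combos$i] * t2[combos$j]
  p1 <- t1[combos$i] * (1 - t2[combos$j])
  p2a <- (1 - t1[combos$i]) * t2[combos$j]
  p2b <- (1 - t1[combos$i]) * (1 - t2[combos$j])

  nG <- nrow(combos)
  logf <- matrix(0, nG, npat)        # log site likelihood per grid point
  post_sel_num <- matrix(0, nG, npat)
  lp <- cbind(log(p0), log(p1), log(p2a), log(p2b))
  for (rix in seq_len(nG)) {
    a <- combos$a[rix]; b <- combos$b[rix]
    m <- rbind(L00[a, ] + lp[rix, 1],
               L11 + lp[rix, 2],
               L02[a, b, ] + lp[rix, 3],
               L12[b, ] + lp[rix, 4])
    fx <- log_colsums_exp(m)
    logf[rix, ] <- fx
    post_sel_num[rix, ] <- exp(log_colsums_exp(m[3:4, , drop = FALSE]) - fx)
  }
  logL_grid <- logf %*% pat$weights            # total data log-lik per grid pt
  wgrid <- exp(logL_grid - max(logL_grid))
  wgrid <- wgrid / sum(wgrid)                  # uniform prior
  post_pat <- as.numeric(crossprod(post_sel_num, wgrid))
  posterior <- post_pat[pat$index]
  tibble::tibble(gene = fit_alt$gene, site = seq_along(posterior),
                 posterior = posterior, selected = posterior > threshold)
}
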