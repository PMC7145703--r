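#' Amino-acid replacement model
#'
#' A reversible 20-state replacement model assembled from a symmetric
#' exchangeability matrix and equilibrium frequencies, scaled to one
#' expected replacement per unit branch length at equilibrium. The default
#' is the Poisson (equal-exchangeability) model; any symmetric 20x20
#' matrix with the package's alphabetical residue order may be supplied
#' (e.g. an empirical matrix). Optional discrete-gamma rate heterogeneity.
#'
#' @param exchangeability `"poisson"` or a symmetric 20x20 numeric matrix
#'   (diagonal ignored) in [AA_STATES] order.
#' @param freqs Equilibrium frequencies: `NULL` for uniform, or a
#'   20-vector summing to 1 in [AA_STATES] order.
#' @param gamma_shape Shape of discrete-gamma rate variation across
#'   sites, or `NULL` (default) for a single rate.
#' @param ncat Number of discrete gamma categories (default 4).
#' @return An object of class `aa_model` with elements `Q` (scaled
#'   generator), `freqs`, `rates`, `rate_weights`, `eig`.
#' @export
aa_model <- function(exchangeability = "poisson", freqs = NULL,
                     gamma_shape = NULL, ncat = 4L) {
  n <- length(AA_STATES)
  if (identical(exchangeability, "poisson")) {
    R <- matrix(1, n, n)
  } else {
    R <- as.matrix(exchangeability)
    stopifnot(identical(dim(R), c(n, n)))
    if (max(abs(R - t(R))) > 1e-8) {
      stop("exchangeability matrix must be symmetric", call. = FALSE)
    }
  }
  diag(R) <- 0
  if (is.null(freqs)) freqs <- rep(1 / n, n)
  stopifnot(length(freqs) == n, all(freqs > 0))
  if (abs(sum(freqs) - 1) > 1e-6) {
    stop("frequencies must sum to 1", call. = FALSE)
  }
  freqs <- freqs / sum(freqs)
  Q <- R * rep(freqs, each = n)     # q_ij = r_ij * pi_j
  diag(Q) <- -rowSums(Q)
  rate <- -sum(freqs * diag(Q))
  Q <- Q / rate
  if (is.null(gamma_shape)) {
    rates <- 1
    wts <- 1
  } else {
    stopifnot(gamma_shape > 0, ncat >= 2)
    rates <- discrete_gamma_rates(gamma_shape, ncat)
    wts <- rep(1 / ncat, ncat)
  }
  structure(
    list(Q = Q, freqs = freqs, rates = rates, rate_weights = wts,
         gamma_shape = gamma_shape, eig = rev_eigen(Q, freqs)),
    class = "aa_model"
  )
}

# Mean rates of k equal-probability discrete gamma categories (mean 1),
# category means of the gamma distribution between quantile cut points.
discrete_gamma_rates <- function(shape, ncat) {
  cuts <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape = shape,
                        rate = shape)
  # category mean via the incomplete-gamma identity
  p <- stats::pgamma(cuts, shape = shape + 1, rate = shape)
  means <- diff(p) * ncat
  means / mean(means)
}

# Eigen system of a reversible generator, via symmetrization with
# diag(sqrt(pi)). Returns the pieces needed for fast P(t).
rev_eigen <- function(Q, pi) {
  s <- sqrt(pi)
  B <- Q * (s %o% (1 / s))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(vec = e$vectors / s, inv = t(e$vectors * s), values = e$values)
}

# Transition probability matrix P(t) = exp(Qt) from a rev_eigen system.
pmat <- function(eig, t) {
  P <- (eig$vec * rep(exp(eig$values * t), each = nrow(eig$vec))) %*% eig$inv
  P[P < 0] <- 0
  P
}

# batched P(t) for a vector of branch lengths (compiled)
pmats <- function(eig, lengths) {
  cpp_pmats(eig$vec, eig$inv, eig$values, lengths)
}
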