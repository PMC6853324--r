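#' Brooks-Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor per parameter:
#' `sqrt(((n-1)/n * W + (1 + 1/m) * B/n) / W)` over `m` chains of length
#' `n`, with `W` the mean within-chain variance and `B/n` the variance of
#' the chain means. Values near 1 indicate the chains have mixed; the
#' conventional flag threshold used here is 1.1. Degenerate cases are
#' defined rather than errors: all chains constant and identical gives 1,
#' constant but separated chains give `Inf`.
#'
#' @param draws a [coda::mcmc.list], or a list of per-chain draw matrices
#'   (equal dimensions, columns = parameters).
#' @param threshold convergence flag threshold.
#' @return named vector of statistics with attribute `converged` (logical
#'   vector at `threshold`).
#' @export
bgr <- function(draws, threshold = 1.1) {
  mats <- chain_matrices(draws)
  if (length(mats) < 2L) stop("BGR requires at least 2 chains")
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1L) stop("chains must have equal length")
  params <- colnames(mats[[1]]) %||% paste0("par", seq_len(ncol(mats[[1]])))
  m <- length(mats)
  stat <- vapply(seq_along(params), function(j) {
    x <- vapply(mats, function(ch) ch[, j], numeric(n))  # n x m
    W <- mean(apply(x, 2, stats::var))
    B_over_n <- stats::var(colMeans(x))
    if (W < .Machine$double.eps) {
      return(if (B_over_n < .Machine$double.eps) 1 else Inf)
    }
    sqrt(((n - 1) / n * W + (1 + 1 / m) * B_over_n) / W)
  }, numeric(1))
  names(stat) <- params
  attr(stat, "converged") <- stat < threshold
  attr(stat, "threshold") <- threshold
  stat
}

#' Monte Carlo error rule
#'
#' Checks, per parameter, that the Monte Carlo standard error of the
#' posterior mean (estimated by batch means within each chain, which is
#' robust to autocorrelation) is below a fraction of the posterior standard
#' deviation -- the run-length rule "MC error < 5% of the posterior sd".
#'
#' @param draws a [coda::mcmc.list] or list of per-chain draw matrices.
#' @param frac threshold fraction (default 0.05).
#' @param min_draws minimum post-burn-in draws per chain required for
#'   batching.
#' @return data.frame with `parameter`, `mc_se`, `post_sd`, `ratio`, `ok`.
#' @export
mc_error_check <- function(draws, frac = 0.05, min_draws = 100) {
  mats <- chain_matrices(draws)
  n <- nrow(mats[[1]])
  if (n < min_draws)
    stop("too few draws per chain for batch means (need >= ", min_draws, ")")
  params <- colnames(mats[[1]]) %||% paste0("par", seq_len(ncol(mats[[1]])))
  nb <- floor(sqrt(n))
  bs <- n %/% nb
  res <- t(vapply(seq_along(params), function(j) {
    bm <- unlist(lapply(mats, function(ch) {
      x <- ch[seq_len(nb * bs), j]
      colMeans(matrix(x, nrow = bs))
    }))
    # se of the pooled mean from independent-ish batch means
    mc_se <- stats::sd(bm) / sqrt(length(bm))
    post_sd <- stats::sd(unlist(lapply(mats, function(ch) ch[, j])))
    c(mc_se = mc_se, post_sd = post_sd)
  }, numeric(2)))
  ratio <- ifelse(res[, "post_sd"] > 0, res[, "mc_se"] / res[, "post_sd"], 0)
  data.frame(parameter = params, mc_se = res[, "mc_se"],
             post_sd = res[, "post_sd"], ratio = ratio,
             ok = ratio < frac, row.names = NULL,
             stringsAsFactors = FALSE)
}

# normalize mcmc.list / matrix list / single matrix into a list of matrices
chain_matrices <- function(draws) {
  if (inherits(draws, "mcmc.list")) return(lapply(draws, as.matrix))
  if (is.matrix(draws)) return(list(draws))
  if (is.list(draws)) {
    return(lapply(draws, function(ch) {
      m <- as.matrix(ch)
      if (is.null(dim(m))) m <- matrix(m, ncol = 1)
      m
    }))
  }
  stop("draws must be an mcmc.list, a matrix, or a list of matrices")
}
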