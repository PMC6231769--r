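# Irreproducible discovery rate: two-component Gaussian copula mixture over
# replicate score ranks, fit by EM with pseudo-value reassignment each
# iteration.  The reproducible component is bivariate normal with common
# mean mu > 0, variance sigma^2 and correlation rho > 0; the irreproducible
# component is standard bivariate normal with zero correlation.

#' @noRd
dbinorm_log <- function(z1, z2, mu, sigma2, rho) {
  # log density of bivariate normal with equal means/variances
  q <- ((z1 - mu)^2 - 2 * rho * (z1 - mu) * (z2 - mu) + (z2 - mu)^2) /
    (sigma2 * (1 - rho^2))
  -log(2 * pi) - log(sigma2) - 0.5 * log(1 - rho^2) - q / 2
}

# inverse of the mixture marginal CDF G(z) = pi1 Phi((z-mu)/sigma) + pi0 Phi(z)
#' @noRd
mixture_quantile <- function(u, pi1, mu, sigma, grid_n = 4000L) {
  lo <- min(stats::qnorm(min(u)) , mu + sigma * stats::qnorm(min(u))) - 1
  hi <- max(stats::qnorm(max(u)), mu + sigma * stats::qnorm(max(u))) + 1
  zg <- seq(lo, hi, length.out = grid_n)
  Gg <- pi1 * stats::pnorm((zg - mu) / sigma) + (1 - pi1) * stats::pnorm(zg)
  stats::approx(Gg, zg, xout = u, rule = 2, ties = "ordered")$y
}

#' Fit the IDR copula mixture to two replicate score vectors
#'
#' Scores are converted to pseudo-values via the empirical CDF
#' (`rank / (n + 1)`, average ranks on ties), mapped to the latent Gaussian
#' scale through the current mixture marginal, and the two-component model is
#' fit by EM.  The local idr of a candidate is its posterior probability of
#' belonging to the irreproducible component; the (global) IDR is the
#' running mean of local idr along the ranking by increasing local idr,
#' which is nondecreasing by construction.
#'
#' @param scores_rep1,scores_rep2 equal-length numeric score vectors over
#'   the same candidates (>= 50 candidates).
#' @param max_iter EM iteration cap (default 500).
#' @param tol stop when the log-likelihood improves by less than this
#'   (default 1e-6).
#' @return List of class `wormcis_idr`: `pi1`, `mu`, `sigma2`, `rho`,
#'   `idr_local`, `IDR` (aligned with the input order), `loglik`,
#'   `n_iter`, `converged`.
#' @export
fit_idr <- function(scores_rep1, scores_rep2, max_iter = 500L, tol = 1e-6) {
  n <- length(scores_rep1)
  stopifnot(length(scores_rep2) == n)
  if (n < 50L) stop("need at least 50 candidates for the IDR fit", call. = FALSE)
  if (length(unique(scores_rep1)) == 1L || length(unique(scores_rep2)) == 1L)
    stop("degenerate all-tied scores", call. = FALSE)
  u1 <- rank(scores_rep1, ties.method = "average") / (n + 1)
  u2 <- rank(scores_rep2, ties.method = "average") / (n + 1)

  pi1 <- 0.3; mu <- 2.5; sigma2 <- 1; rho <- 0.8
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  gamma <- rep(pi1, n)
  while (it < max_iter) {
    it <- it + 1L
    sigma <- sqrt(sigma2)
    z1 <- mixture_quantile(u1, pi1, mu, sigma)
    z2 <- mixture_quantile(u2, pi1, mu, sigma)
    l1 <- dbinorm_log(z1, z2, mu, sigma2, rho)
    l0 <- dbinorm_log(z1, z2, 0, 1, 0)
    m <- pmax(l1, l0)
    denom <- pi1 * exp(l1 - m) + (1 - pi1) * exp(l0 - m)
    gamma <- pi1 * exp(l1 - m) / denom
    ll <- sum(m + log(denom))
    # M step
    sg <- sum(gamma)
    pi1 <- min(max(sg / n, 1e-4), 1 - 1e-4)
    if (sg > 0) {
      mu <- max(sum(gamma * (z1 + z2)) / (2 * sg), 0)
      sigma2 <- max(sum(gamma * ((z1 - mu)^2 + (z2 - mu)^2)) / (2 * sg), 1e-4)
      rho <- sum(gamma * (z1 - mu) * (z2 - mu)) / (sg * sigma2)
      rho <- min(max(rho, 1e-3), 0.999)
    }
    if (is.finite(ll) && ll - ll_old < tol && it > 1L) { converged <- TRUE; break }
    ll_old <- ll
  }
  idr_local <- 1 - gamma
  ord <- order(idr_local)
  IDR_sorted <- cumsum(idr_local[ord]) / seq_len(n)
  IDR <- numeric(n)
  IDR[ord] <- IDR_sorted
  structure(list(pi1 = pi1, mu = mu, sigma2 = sigma2, rho = rho,
                 idr_local = idr_local, IDR = IDR, loglik = ll_old,
                 n_iter = it, converged = converged),
            class = "wormcis_idr")
}

#' Simulate scores from the IDR copula mixture
#'
#' Draws latent bivariate-normal pairs from the two components and returns
#' them on the observed-score scale (the latent scale itself serves, since
#' the model only uses ranks).  Used for model-recovery validation.
#'
#' @param n candidates; `pi1` reproducible proportion; `mu` shift; `sigma2`
#'   variance; `rho` correlation; `seed` integer seed.
#' @return List: `s1`, `s2`, `labels` (TRUE = reproducible component).
#' @export
simulate_idr_scores <- function(n = 2000L, pi1 = 0.5, mu = 3, sigma2 = 1,
                                rho = 0.95, seed = 1L) {
  with_seed(seed, {
    lab <- stats::runif(n) < pi1
    z1 <- stats::rnorm(n)
    z2 <- numeric(n)
    z2[!lab] <- stats::rnorm(sum(!lab))
    if (any(lab)) {
      k <- sum(lab)
      z1[lab] <- mu + sqrt(sigma2) * z1[lab]
      z2[lab] <- mu + sqrt(sigma2) *
        (rho * (z1[lab] - mu) / sqrt(sigma2) + sqrt(1 - rho^2) * stats::rnorm(k))
    }
    list(s1 = z1, s2 = z2, labels = lab)
  })
}
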