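#' Negative-binomial log-likelihood
#'
#' Parameterized by mean `mu` and dispersion `phi` so that
#' Var(Y) = mu + phi * mu^2; `phi = 0` is the Poisson limit.
#'
#' @param y counts. @param mu fitted means. @param phi dispersion (scalar).
#' @return scalar log-likelihood.
#' @export
nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (phi < 1e-8) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

#' Fit a negative-binomial GLM with log link for one gene
#'
#' Iteratively reweighted least squares with step halving, run to a score
#' (gradient) norm below `tol` or `max_iter` iterations. Deterministic given
#' its inputs. Offsets are log effective library sizes. A gene whose fit
#' fails to converge, or with all-zero counts under a non-trivial design, is
#' returned with `degenerate = TRUE`; callers report such genes with p = 1
#' (fit failure) or p = NA (all-zero).
#'
#' @param y integer counts, one per sample.
#' @param X design matrix (full column rank after dropping unused levels).
#' @param offset log effective library sizes (one per sample).
#' @param phi dispersion; Var = mu + phi mu^2.
#' @param beta0 optional starting coefficients.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter iteration cap.
#' @return list with `coefficients`, `loglik`, `fitted` (means),
#'   `converged`, `iterations`, `degenerate`.
#' @export
fit_nb_glm <- function(y, X, offset = rep(0, length(y)), phi = 0,
                       beta0 = NULL, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient")
  .nb_fit(y, X, offset, phi, beta0, tol, max_iter)
}

# hot path shared by the dispersion grid and the LRT loops; assumes X is
# a full-rank matrix (validated once by the callers)
.nb_fit <- function(y, X, offset = rep(0, length(y)), phi = 0,
                    beta0 = NULL, tol = 1e-8, max_iter = 100L) {
  n <- length(y)
  p <- ncol(X)
  if (all(y == 0)) {
    # boundary: likelihood maximized as mu -> 0; report the limit
    return(list(coefficients = stats::setNames(rep(-Inf, p), colnames(X)),
                loglik = 0, fitted = rep(0, n), converged = TRUE,
                iterations = 0L, degenerate = TRUE))
  }
  beta <- beta0
  if (is.null(beta)) {
    eta0 <- log(pmax(y, max(mean(y) / 6, 1e-3))) - offset
    beta <- qr.coef(qr(X), eta0)
    beta[!is.finite(beta)] <- 0
  }
  ll_of <- function(beta) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    nb_loglik(y, exp(eta), phi)
  }
  ll <- ll_of(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    score <- drop(crossprod(X, (y - mu) / (1 + phi * mu)))
    if (sqrt(sum(score^2)) < tol) { converged <- TRUE; break }
    XtWX <- crossprod(X, X * w)
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving keeps the likelihood monotone
    fac <- 1
    repeat {
      cand <- beta + fac * step
      ll_new <- ll_of(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-8) { cand <- beta; ll_new <- ll; break }
    }
    if (abs(ll_new - ll) < 1e-13 && sqrt(sum(score^2)) < 1e-4) {
      beta <- cand; ll <- ll_new; converged <- TRUE; break
    }
    beta <- cand
    ll <- ll_new
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  list(coefficients = stats::setNames(drop(beta), colnames(X)),
       loglik = ll, fitted = exp(eta), converged = converged,
       iterations = iter, degenerate = FALSE)
}

# parabolic refinement of a grid maximum in log-phi coordinates
.refine_grid_max <- function(logphi, val) {
  k <- which.max(val)
  if (k == 1 || k == length(val)) return(exp(logphi[k]))
  x <- logphi[(k - 1):(k + 1)]
  y <- val[(k - 1):(k + 1)]
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) /
    denom
  if (!is.finite(a) || a >= 0) return(exp(logphi[k]))
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
          x[1]^2 * (y[2] - y[3])) / denom
  opt <- -b / (2 * a)
  exp(min(max(opt, x[1]), x[3]))
}

#' Estimate common and tagwise NB dispersions
#'
#' Dispersion (phi, with Var = mu + phi mu^2) measures variance among
#' replicates and governs DE sensitivity: samples collected across a
#' population (nonsiblings) typically show higher dispersion than sibling
#' collections, and correspondingly lower power. The common dispersion
#' maximizes the summed Cox-Reid adjusted profile likelihood (APL) over all
#' genes; tagwise values maximize each gene's APL plus `prior_weight` times
#' the per-gene mean APL, shrinking gene-wise estimates toward the common
#' value as per-gene information decreases. Both maximizations are on a
#' log-spaced grid with parabolic refinement, so results are deterministic.
#'
#' @param x CountMatrix (or plain count matrix).
#' @param design design matrix for the full model (see [de_design()]).
#' @param offsets log effective library sizes; default log total counts.
#' @param prior_weight weight (in gene-equivalents) of the common
#'   likelihood in tagwise shrinkage; default 10.
#' @param grid dispersion grid; default 18 log-spaced points in
#'   [1e-4, 4].
#' @return `DispersionEstimates`: list with `common`, `tagwise` (named per
#'   gene), `prior_weight`, and the `grid` used.
#' @export
estimate_dispersions <- function(x, design, offsets = NULL,
                                 prior_weight = 10,
                                 grid = exp(seq(log(1e-4), log(4),
                                                length.out = 18))) {
  counts <- if (inherits(x, "CountMatrix")) x$counts else as.matrix(x)
  if (all(counts == 0)) stop("all-zero count matrix")
  if (is.null(offsets)) offsets <- log(pmax(colSums(counts), 1))
  X <- as.matrix(design)
  G <- nrow(counts)
  logphi <- log(grid)
  apl <- matrix(0, G, length(grid))
  for (g in seq_len(G)) {
    y <- counts[g, ]
    if (all(y == 0)) next
    beta0 <- NULL
    for (k in seq_along(grid)) {
      fit <- .nb_fit(y, X, offsets, grid[k], beta0 = beta0, tol = 1e-6,
                        max_iter = 50L)
      beta0 <- fit$coefficients  # warm start along the grid
      mu <- pmax(fit$fitted, 1e-10)
      w <- mu / (1 + grid[k] * mu)
      apl[g, k] <- fit$loglik -
        0.5 * as.numeric(determinant(crossprod(X, X * w), TRUE)$modulus)
    }
  }
  informative <- rowSums(counts) > 0
  col_mean <- colMeans(apl[informative, , drop = FALSE])
  common <- .refine_grid_max(logphi, colSums(apl[informative, , drop = FALSE]))
  tagwise <- numeric(G)
  for (g in seq_len(G)) {
    if (!informative[g]) { tagwise[g] <- common; next }
    tagwise[g] <- .refine_grid_max(logphi, apl[g, ] + prior_weight * col_mean)
  }
  names(tagwise) <- rownames(counts)
  structure(list(common = common, tagwise = tagwise,
                 prior_weight = prior_weight, grid = grid),
            class = "DispersionEstimates")
}

#' @export
print.DispersionEstimates <- function(x, ...) {
  cat(sprintf("DispersionEstimates: common %.4g; tagwise mean %.4g (%d genes)\n",
              x$common, mean(x$tagwise), length(x$tagwise)))
  invisible(x)
}

#' Trimmed-mean-of-ratios effective library size factors
#'
#' Optional alternative to plain total-count offsets: scales each sample's
#' library size by a doubly trimmed mean of per-gene log ratios against a
#' reference sample, down-weighting composition effects of a few dominant
#' genes.
#'
#' @param counts gene x sample count matrix.
#' @param trim_m,trim_a trim fractions on log-ratios and log-abundance.
#' @return named vector of effective library sizes.
#' @export
effective_library_sizes <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  counts <- if (inherits(counts, "CountMatrix")) counts$counts else counts
  lib <- colSums(counts)
  ref <- which.min(abs(lib - stats::median(lib)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    ok <- counts[, j] > 0 & counts[, ref] > 0
    if (sum(ok) < 10) return(1)
    m <- log2((counts[ok, j] / lib[j]) / (counts[ok, ref] / lib[ref]))
    a <- 0.5 * log2((counts[ok, j] / lib[j]) * (counts[ok, ref] / lib[ref]))
    keep <- m >= stats::quantile(m, trim_m) & m <= stats::quantile(m, 1 - trim_m) &
      a >= stats::quantile(a, trim_a) & a <= stats::quantile(a, 1 - trim_a)
    if (!any(keep)) return(1)
    2^mean(m[keep])
  }, numeric(1))
  f <- f / exp(mean(log(f)))  # factors multiply to 1
  stats::setNames(lib * f, colnames(counts))
}
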