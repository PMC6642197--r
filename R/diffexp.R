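#' Design matrices for digit differential-expression models
#'
#' Builds the full and reduced model matrices for likelihood-ratio testing.
#' The full model contains the digit factor, an additive stage factor when
#' more than one stage is present (limbs sampled at two stages enter one
#' model), and any continuous covariates (e.g., a first-principal-component
#' score used to absorb a known technical artifact). The reduced model drops
#' the digit factor only.
#'
#' @param samples per-sample metadata data frame (`digit`, `stage` columns).
#' @param covariates optional named list / data frame of per-sample numeric
#'   covariates, aligned with `samples` rows.
#' @return list with `full`, `reduced` model matrices and `df` (their
#'   column-count difference = residual df of the test).
#' @export
de_design <- function(samples, covariates = NULL) {
  digit <- factor(samples$digit)
  if (nlevels(digit) < 2) stop("need >= 2 digit levels in the design")
  if (any(table(digit) < 2)) stop("each tested digit level needs >= 2 samples")
  terms <- list(digit = digit)
  if (length(unique(samples$stage)) > 1)
    terms$stage <- factor(samples$stage)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(samples))
      stop("covariates must have one row per sample")
    if (any(!vapply(covariates, is.numeric, logical(1))) ||
        any(!is.finite(as.matrix(covariates))))
      stop("covariates must be finite numerics")
    for (nm in names(covariates)) terms[[nm]] <- covariates[[nm]]
  }
  full <- stats::model.matrix(~., data = as.data.frame(terms))
  reduced <- if (length(terms) > 1)
    stats::model.matrix(~., data = as.data.frame(terms[-1]))
  else matrix(1, nrow(samples), 1, dimnames = list(NULL, "(Intercept)"))
  list(full = full, reduced = reduced, df = ncol(full) - ncol(reduced))
}

# Shared LRT engine over a prepared sample subset.
.run_lrt <- function(counts, samples, design, offsets, tagwise, lengths,
                     contrast_label) {
  G <- nrow(counts)
  lr <- p <- rep(NA_real_, G)
  l2fc <- rep(NA_real_, G)
  flagged <- logical(G)
  df <- design$df
  for (g in seq_len(G)) {
    y <- counts[g, ]
    if (all(y == 0)) next  # excluded from m, p = NA
    f1 <- .nb_fit(y, design$full, offsets, tagwise[g])
    f0 <- .nb_fit(y, design$reduced, offsets, tagwise[g],
                     beta0 = rep(0, ncol(design$reduced)))
    if (!f1$converged || !f0$converged) {
      flagged[g] <- TRUE
      lr[g] <- 0; p[g] <- 1
      next
    }
    lr[g] <- max(0, 2 * (f1$loglik - f0$loglik))
    p[g] <- stats::pchisq(lr[g], df = df, lower.tail = FALSE)
    dcols <- grep("^digit", colnames(design$full))
    if (length(dcols) == 1) {
      l2fc[g] <- f1$coefficients[dcols] / log(2)
    } else if (length(dcols) > 1) {
      # any-digit contrast: spread of fitted digit effects, in log2 units
      eff <- c(0, f1$coefficients[dcols])
      l2fc[g] <- (max(eff) - min(eff)) / log(2)
    }
  }
  out <- data.frame(gene_id = rownames(counts), log2_fc = l2fc, lr = lr,
                    df = df, p_value = p, stringsAsFactors = FALSE)
  out$p_bh <- adjust_bh(out$p_value)
  sq <- storey_q(out$p_value)
  out$q_storey <- sq$q
  # per-level TPM (or CPM) means
  lev <- sort(unique(samples$digit))
  for (d in lev) {
    cols <- which(samples$digit == d)
    vals <- if (!is.null(lengths)) {
      rate <- counts[, cols, drop = FALSE] / lengths[rownames(counts)]
      sweep(rate, 2, pmax(colSums(rate), 1e-12), "/") * 1e6
    } else {
      sweep(counts[, cols, drop = FALSE], 2,
            pmax(exp(offsets[cols]), 1), "/") * 1e6
    }
    out[[paste0("mean_d", d)]] <- rowMeans(vals)
  }
  out$flagged <- flagged
  attr(out, "contrast") <- contrast_label
  attr(out, "pi0") <- sq$pi0
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Likelihood-ratio test for an adjacent-digit (pairwise) contrast
#'
#' Tests each gene for differential expression between two digit positions
#' of one limb by comparing a full NB GLM (digit + stage + covariates) with
#' the reduced model lacking the digit term, on the samples of the two
#' digits. The LR statistic is referred to chi-square with 1 df. Genes with
#' zero counts in all tested samples are reported with p = NA and excluded
#' from the multiple-testing m; non-converged fits are flagged with p = 1.
#' `log2_fc` is the fitted log2 fold change of the posterior digit over the
#' anterior one.
#'
#' @param x CountMatrix for one species/limb.
#' @param digits length-2 integer vector, anterior first (e.g., `c(1, 2)`).
#' @param dispersions optional [estimate_dispersions()] result; estimated
#'   from the full digit design of `x` when absent.
#' @param lengths optional named transcript-length vector; when supplied the
#'   per-level means are TPM, otherwise counts-per-million.
#' @param covariates optional per-sample covariate data frame over all of
#'   `x`'s samples (e.g., `pc1_covariate(...)`).
#' @param offsets optional named log effective library sizes; default
#'   log total counts of `x`.
#' @return `DEResult` data frame: per gene `log2_fc`, `lr`, `df`,
#'   `p_value`, `p_bh`, `q_storey`, per-level means, `flagged`.
#' @export
lrt_pairwise <- function(x, digits, dispersions = NULL, lengths = NULL,
                         covariates = NULL, offsets = NULL) {
  stopifnot(inherits(x, "CountMatrix"), length(digits) == 2)
  absent <- setdiff(digits, x$samples$digit)
  if (length(absent) > 0)
    stop("digit level(s) absent from the data: ", paste(absent, collapse = ", "))
  if (is.null(offsets))
    offsets <- stats::setNames(log(pmax(colSums(x$counts), 1)),
                               colnames(x$counts))
  if (is.null(dispersions)) {
    d_all <- de_design(x$samples, covariates)
    dispersions <- estimate_dispersions(x, d_all$full,
                                        offsets[colnames(x$counts)])
  }
  keep <- which(x$samples$digit %in% digits)
  samples <- x$samples[keep, , drop = FALSE]
  # relevel so the anterior digit of the requested pair is baseline
  samples$digit <- factor(samples$digit, levels = digits)
  cov_sub <- if (!is.null(covariates))
    as.data.frame(covariates)[keep, , drop = FALSE] else NULL
  design <- de_design(samples, cov_sub)
  .run_lrt(x$counts[, keep, drop = FALSE], samples, design,
           offsets[colnames(x$counts)[keep]], dispersions$tagwise, lengths,
           paste0("D", digits[1], "_vs_D", digits[2]))
}

#' Likelihood-ratio test across all digits of a limb ("any-digit")
#'
#' ANOVA-like multi-coefficient LRT: the full model carries the complete
#' digit factor, the reduced model drops it, and the LR statistic has
#' (number of digits - 1) df. A small p indicates the gene differs between
#' some pair of digits, without indicating which; `log2_fc` reports the
#' log2 spread between the most and least expressed fitted digit effects.
#'
#' @inheritParams lrt_pairwise
#' @return `DEResult` data frame as in [lrt_pairwise()].
#' @export
lrt_any_digit <- function(x, dispersions = NULL, lengths = NULL,
                          covariates = NULL, offsets = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  digits <- sort(unique(x$samples$digit))
  if (length(digits) < 3) {
    message("fewer than 3 digit levels; deferring to the pairwise test")
    return(lrt_pairwise(x, digits, dispersions, lengths, covariates, offsets))
  }
  if (is.null(offsets))
    offsets <- stats::setNames(log(pmax(colSums(x$counts), 1)),
                               colnames(x$counts))
  design <- de_design(x$samples, covariates)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(x, design$full,
                                        offsets[colnames(x$counts)])
  .run_lrt(x$counts, x$samples, design, offsets[colnames(x$counts)],
           dispersions$tagwise, lengths, "any_digit")
}

#' First-principal-component technical covariate
#'
#' Computes PC1 scores of the full-transcriptome sqrt-TPM matrix of a
#' dataset, for use as a continuous regressor when the leading principal
#' component tracks a non-biological artifact rather than digit identity.
#'
#' @param x CountMatrix.
#' @param lengths named transcript-length vector.
#' @return data frame with a single `pc1` column, one row per sample of `x`.
#' @export
pc1_covariate <- function(x, lengths) {
  expr <- sqrt_transform(tpm_normalize(x, lengths))
  model <- fit_pca(expr)
  data.frame(pc1 = model$scores[colnames(x$counts), 1])
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' NA p-values propagate as NA and are excluded from the number of tests m.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs allowed).
#' @return adjusted p-values, capped at 1, monotone in p-rank.
#' @export
adjust_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Storey q-values with smoother pi0 estimation
#'
#' Estimates the null proportion pi0 on the lambda grid by
#' `#\{p > lambda\} / (m (1 - lambda))`, smooths with a cubic spline, and
#' evaluates at the largest lambda; q-values are pi0 times the BH step-up
#' values (so q <= BH-adjusted p whenever pi0 <= 1). With fewer than 100
#' non-missing p-values the pi0 estimate is unreliable and falls back to 1
#' with a warning, making q identical to BH.
#'
#' @param p p-values in [0, 1]; NAs excluded from m and returned as NA.
#' @param lambda grid for pi0 estimation.
#' @return list with `q` (vector aligned with `p`) and `pi0`.
#' @export
storey_q <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(list(q = out, pi0 = NA_real_))
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  if (m < 100) {
    warning("fewer than 100 p-values; pi0 set to 1")
    pi0 <- 1
  } else {
    pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, max(lambda))$y
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  out[ok] <- pmin(pi0 * stats::p.adjust(pv, method = "BH"), 1)
  list(q = out, pi0 = pi0)
}

#' Genes passing an FDR threshold
#'
#' @param de `DEResult`.
#' @param fdr threshold on the adjusted value (default 0.05).
#' @param method "bh" or "storey".
#' @return character vector of gene identifiers.
#' @export
de_genes <- function(de, fdr = 0.05, method = c("bh", "storey")) {
  method <- match.arg(method)
  col <- if (method == "bh") de$p_bh else de$q_storey
  de$gene_id[!is.na(col) & col < fdr]
}
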