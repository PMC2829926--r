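# Signature discovery: two routes to genes covarying with a quantitative
# clinical covariate.
#
# Route 1 (sam_quantitative): the SAM quantitative-response statistic
#   d_i = r_i / (s_i + s0), with r_i the least-squares slope of gene i's
#   expression on the centered covariate, s_i its residual standard error and
#   s0 a fudge constant stabilising low-variance genes. The null is built by
#   permuting the covariate; the FDR at a |d| cutoff is
#   pi0 * median permuted count / observed count, monotonized per gene.
# Route 2 (moderated_covariate_test): per-gene simple regression with the
#   residual variances shrunk toward a common prior by empirical Bayes
#   (method-of-moments fit of a scaled inverse chi-square prior on the log
#   residual variances), two-sided p from the moderated t with augmented df,
#   Benjamini-Hochberg FDR.
# The signature is the FDR-bounded, sign-consistent intersection.

# per-gene least squares of rows of X on covariate y (with intercept)
gene_regression <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  if (syy == 0) stop("covariate is constant across samples")
  slope <- drop(X %*% yc) / syy
  Xc <- X - rowMeans(X)
  sxx <- rowSums(Xc^2)
  sse <- pmax(sxx - slope^2 * syy, 0)
  se <- sqrt(sse / ((n - 2) * syy))
  list(slope = slope, se = se, syy = syy, sxx = sxx, sse = sse, n = n)
}

get_covariate <- function(study, covariate_name) {
  y <- study$clinical[[covariate_name]]
  if (is.null(y)) stop("no clinical covariate named '", covariate_name, "'")
  if (!is.numeric(y)) stop("covariate '", covariate_name, "' is not numeric")
  if (anyNA(y)) stop("covariate '", covariate_name, "' has missing values")
  if (stats::sd(y) == 0) stop("covariate '", covariate_name, "' is constant")
  y
}

# SAM's fudge-factor selection: choose the percentile of s minimizing the
# coefficient of variation of window-wise MAD(d) across s quantile windows.
choose_s0 <- function(slope, se) {
  alphas <- seq(0, 1, by = 0.05)
  cand <- stats::quantile(se, alphas, names = FALSE)
  nwin <- max(2L, min(100L, floor(length(se) / 20)))
  win <- cut(rank(se, ties.method = "first"), nwin, labels = FALSE)
  cvs <- vapply(cand, function(s0) {
    d <- slope / (se + s0)
    mads <- tapply(d, win, stats::mad)
    m <- mean(mads)
    if (!is.finite(m) || m == 0) return(Inf)
    stats::sd(mads) / m
  }, numeric(1))
  cand[which.min(cvs)]
}

permutation_matrix <- function(n, n_permutations, seed) {
  if (n <= 7) {
    perms <- all_permutations(n)
  } else {
    set.seed(seed)
    perms <- t(vapply(seq_len(n_permutations), function(i) sample.int(n),
                      integer(n)))
  }
  perms
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  storage.mode(out) <- "integer"
  out
}

#' Quantitative SAM with permutation FDR
#'
#' Scores every gene with the SAM quantitative-response statistic
#' `d = slope / (se + s0)` against a continuous covariate and estimates a
#' per-gene FDR from a seeded covariate-permutation null (exhaustive
#' enumeration when the sample count is <= 7). The per-gene FDR is the
#' smallest Delta-level FDR at which the gene is called,
#' `pi0 * median permuted count(|d| >= cutoff) / observed count`,
#' monotonized to be non-increasing in |d|; pi0 is the SAM quartile
#' estimator, capped at 1.
#'
#' @param study an [expression_study()] with >= 4 samples.
#' @param covariate_name clinical column to regress on (default
#'   "weight_loss_pct").
#' @param n_permutations permutations of the covariate (default 200; a
#'   warning is logged below 25).
#' @param s0_mode "auto" (SAM coefficient-of-variation criterion),
#'   "percentile" (5th percentile of the gene standard errors) or "fixed".
#' @param s0_value the fudge constant when `s0_mode = "fixed"`.
#' @param seed integer seed for the permutation draw.
#' @return A `GeneStatTable` data.frame with columns
#'   `gene_id, slope, slope_se, s0, d_stat, sam_fdr`.
#' @export
sam_quantitative <- function(study, covariate_name = "weight_loss_pct",
                             n_permutations = 200,
                             s0_mode = c("auto", "percentile", "fixed"),
                             s0_value = NULL, seed = 1L) {
  stopifnot(inherits(study, "ExpressionStudy"))
  s0_mode <- match.arg(s0_mode)
  if (ncol(study$values) < 4) stop("need >= 4 samples")
  y <- get_covariate(study, covariate_name)
  if (n_permutations < 25)
    warning("n_permutations < 25: permutation FDR will be unstable")

  X <- study$values
  fit <- gene_regression(X, y)
  s0 <- switch(s0_mode,
               auto = choose_s0(fit$slope, fit$se),
               percentile = stats::quantile(fit$se, 0.05, names = FALSE),
               fixed = {
                 if (is.null(s0_value) || s0_value < 0)
                   stop("s0_mode='fixed' needs a non-negative s0_value")
                 s0_value
               })
  d <- fit$slope / (fit$se + s0)

  perms <- permutation_matrix(fit$n, n_permutations, seed)
  B <- nrow(perms)
  m <- nrow(X)
  # permuted d for all genes x permutations via matrix algebra
  yc_perm <- apply(perms, 1, function(p) y[p] - mean(y))
  slopes_p <- (X %*% yc_perm) / fit$syy
  sse_p <- pmax(fit$sxx - slopes_p^2 * fit$syy, 0)
  se_p <- sqrt(sse_p / ((fit$n - 2) * fit$syy))
  d_perm <- slopes_p / (se_p + s0)

  # pi0: fraction of observed d inside the permuted interquartile band / 0.5
  q <- stats::quantile(d_perm, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, sum(d > q[1] & d < q[2]) / (0.5 * m))

  ord <- order(abs(d), decreasing = TRUE)
  cutoffs <- abs(d)[ord]
  counts <- matrix(0, m, B)
  for (b in seq_len(B)) {
    sorted_b <- sort(abs(d_perm[, b]))
    counts[, b] <- m - findInterval(cutoffs, sorted_b,
                                    left.open = TRUE)
  }
  med_count <- apply(counts, 1, stats::median)
  raw_fdr <- pmin(1, pi0 * med_count / seq_len(m))
  q_sorted <- rev(cummin(rev(raw_fdr)))
  fdr <- numeric(m)
  fdr[ord] <- q_sorted

  structure(data.frame(gene_id = rownames(X), slope = fit$slope,
                       slope_se = fit$se, s0 = s0, d_stat = d,
                       sam_fdr = fdr, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("GeneStatTable", "data.frame"), pi0 = pi0,
            n_permutations = B)
}

# Newton solve of trigamma(y) = x, vectorized scalar use
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical Bayes moderated covariate test
#'
#' Per-gene simple linear regression on a continuous covariate with the
#' residual variances shrunk toward a common prior: a scaled inverse
#' chi-square prior (d0, s0^2) is fitted by method of moments on the log
#' residual variances, the posterior variance is
#' `(d0 * s0^2 + d_res * s^2) / (d0 + d_res)`, and the moderated t uses
#' `d0 + d_res` degrees of freedom. Two-sided p-values are adjusted by
#' Benjamini-Hochberg.
#'
#' @inheritParams sam_quantitative
#' @return A `GeneStatTable` data.frame with columns
#'   `gene_id, slope, slope_se, mod_t, mod_p, mod_fdr`; attributes `d0` and
#'   `s02` carry the fitted prior.
#' @export
moderated_covariate_test <- function(study,
                                     covariate_name = "weight_loss_pct") {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (ncol(study$values) < 4) stop("need >= 4 samples")
  y <- get_covariate(study, covariate_name)
  n <- length(y)
  if (n - 2 < 1) stop("fewer than 1 residual degree of freedom")
  fit <- gene_regression(study$values, y)
  df_res <- n - 2
  s2 <- fit$sse / df_res

  ok <- s2 > 0
  if (!any(ok)) stop("all genes have zero residual variance")
  z <- log(s2[ok])
  e <- z - digamma(df_res / 2) + log(df_res / 2)
  evar <- stats::var(e) - trigamma(df_res / 2)
  if (length(z) < 2 || is.na(evar)) evar <- -1
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }

  s2_post <- if (is.finite(d0)) {
    (d0 * s02 + df_res * s2) / (d0 + df_res)
  } else rep(s02, length(s2))
  mod_se <- sqrt(s2_post / fit$syy)
  mod_t <- ifelse(mod_se > 0, fit$slope / mod_se, 0)
  df_total <- d0 + df_res
  p <- 2 * stats::pt(-abs(mod_t), df = df_total)
  fdr <- stats::p.adjust(p, method = "BH")

  structure(data.frame(gene_id = rownames(study$values), slope = fit$slope,
                       slope_se = fit$se, mod_t = mod_t, mod_p = p,
                       mod_fdr = fdr, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("GeneStatTable", "data.frame"),
            d0 = d0, s02 = s02, df_total = df_total)
}

#' Per-gene Pearson correlation with a covariate
#'
#' Product-moment correlation of each gene's expression with the covariate,
#' with a two-sided p-value from the t transform on n-2 degrees of freedom.
#' Zero-variance genes get `NA` with a logged message.
#'
#' @inheritParams sam_quantitative
#' @return data.frame `gene_id, pearson_r, p_value`.
#' @export
pearson_per_gene <- function(study, covariate_name = "weight_loss_pct") {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (ncol(study$values) < 3) stop("need >= 3 samples")
  y <- get_covariate(study, covariate_name)
  n <- length(y)
  fit <- gene_regression(study$values, y)
  r <- ifelse(fit$sxx > 0,
              fit$slope * sqrt(fit$syy) / sqrt(pmax(fit$sxx, .Machine$double.eps)),
              NA_real_)
  r <- pmin(1, pmax(-1, r))
  if (anyNA(r))
    message(sum(is.na(r)), " zero-variance gene(s): correlation undefined")
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[!is.na(r) & abs(r) == 1] <- 0
  data.frame(gene_id = rownames(study$values), pearson_r = r, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect the two discovery procedures into a signature
#'
#' A gene enters the signature when both the permutation-FDR SAM arm and the
#' moderated arm call it below `fdr_bound` and the two statistics agree in
#' sign; the shared sign annotates the direction.
#'
#' @param sam output of [sam_quantitative()].
#' @param moderated output of [moderated_covariate_test()] over the same gene
#'   universe.
#' @param fdr_bound FDR bound, default 0.10 (strict `<`).
#' @return A `SignatureSet` data.frame `gene_id, direction` with attribute
#'   `fdr_bound`.
#' @export
intersect_signature <- function(sam, moderated, fdr_bound = 0.10) {
  if (!identical(sam$gene_id, moderated$gene_id))
    stop("gene universes of the two procedures do not match")
  keep <- sam$sam_fdr < fdr_bound & moderated$mod_fdr < fdr_bound &
    sign(sam$d_stat) == sign(moderated$mod_t) & sign(sam$d_stat) != 0
  keep[is.na(keep)] <- FALSE
  structure(data.frame(
    gene_id = sam$gene_id[keep],
    direction = ifelse(sam$d_stat[keep] > 0, "positive", "negative"),
    row.names = NULL, stringsAsFactors = FALSE),
    class = c("SignatureSet", "data.frame"), fdr_bound = fdr_bound)
}
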