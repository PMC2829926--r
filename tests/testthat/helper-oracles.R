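# Independent oracles used to freeze expected values. These deliberately
# share no code with the implementation paths they check.

# brute-force both-strand scanner: enumerate every window explicitly,
# score the reverse strand by reverse-complementing the window itself
oracle_scan <- function(sequence, wm) {
  score1 <- function(win) {
    ch <- strsplit(win, "")[[1]]
    if (any(!ch %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(vapply(seq_along(ch), function(j) wm$logratio[ch[j], j], 0))
  }
  revcomp <- function(x)
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  L <- ncol(wm$logratio)
  n <- nchar(sequence)
  hits <- data.frame(position = integer(0), strand = character(0),
                     score = numeric(0))
  for (i in seq_len(max(0, n - L + 1))) {
    win <- substr(sequence, i, i + L - 1)
    sf <- score1(win)
    if (!is.na(sf) && sf >= wm$threshold)
      hits <- rbind(hits, data.frame(position = i - 1L, strand = "+",
                                     score = sf))
    sr <- score1(revcomp(win))
    if (!is.na(sr) && sr >= wm$threshold)
      hits <- rbind(hits, data.frame(position = i - 1L, strand = "-",
                                     score = sr))
  }
  hits[order(hits$position, hits$strand), , drop = FALSE]
}

# two-sided Fisher p by explicit hypergeometric enumeration: sum the
# probabilities of all tables (fixed margins) no more probable than observed
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive-permutation SAM d distribution for tiny samples
oracle_perm_d <- function(X, y, s0) {
  perms <- t(as.matrix(expand.grid(rep(list(seq_along(y)), length(y)))))
  perms <- perms[, apply(perms, 2, function(p) !any(duplicated(p))),
                 drop = FALSE]
  apply(perms, 2, function(p) {
    yp <- y[p]
    yc <- yp - mean(yp)
    syy <- sum(yc^2)
    vapply(seq_len(nrow(X)), function(g) {
      x <- X[g, ]
      slope <- sum(x * yc) / syy
      res <- x - mean(x) - slope * yc
      se <- sqrt(sum(res^2) / ((length(y) - 2) * syy))
      slope / (se + s0)
    }, 0)
  })
}

# direct product-moment formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

random_dna <- function(n, allow_n = FALSE) {
  alpha <- if (allow_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  pr <- if (allow_n) c(0.24, 0.24, 0.24, 0.24, 0.04) else rep(0.25, 4)
  paste(sample(alpha, n, replace = TRUE, prob = pr), collapse = "")
}

random_pfm <- function(L, id = "RND") {
  counts <- matrix(sample(0:20, 4 * L, replace = TRUE), 4, L)
  counts[1, colSums(counts) == 0] <- 1
  weight_matrix(counts, id)
}

# small study built by hand (no generator) for filter/regression unit tests
toy_study <- function(values, wl = NULL, detected = NULL) {
  n <- ncol(values)
  if (is.null(wl)) wl <- seq(0, 20, length.out = n)
  clin <- data.frame(sample_id = colnames(values) %||% sprintf("S%02d", 1:n),
                     weight_loss_pct = wl)
  colnames(values) <- clin$sample_id
  expression_study(values, detected, clin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

panel_motifs <- function() {
  load_pfm_dir(system.file("extdata", "pfm", package = "cachexsig"))
}
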