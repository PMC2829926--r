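# Promoter motif over/under-representation analysis.
#
# A position frequency matrix (PFM) of base counts is turned into a log-ratio
# scoring matrix against a zero-order uniform background with pseudo-count 1:
#   score[b, j] = log2(((counts[b, j] + 1) / (colsum_j + 4)) / 0.25)
# The hit threshold sits at a fixed fraction (default 0.8) of the matrix's
# scoring range: threshold = min_score + fraction * (max_score - min_score),
# where min/max_score sum the column minima/maxima. Both strands of every
# promoter are scanned; a window is a hit when its score >= threshold
# (ties count as hits). Windows containing N are excluded from both hits and
# the scanned-bp denominator. Per motif, sequence-level over-representation
# in a foreground set against a background set uses Fisher's exact test on
# sequences-with-hit, and per-bp over/under-representation uses a binomial
# Z-score on hits per scanned window start.

BASES <- c("A", "C", "G", "T")

#' Build a motif weight matrix from base counts
#'
#' @param counts 4 x L non-negative numeric matrix, rows A, C, G, T.
#' @param motif_id identifier for the motif.
#' @param threshold_fraction fraction of the scoring range at which the hit
#'   threshold sits (default 0.8).
#' @param pseudocount added to every count before the log-ratio transform
#'   (default 1).
#' @return An object of class `WeightMatrix`: list with `motif_id`, `counts`,
#'   `logratio`, `min_score`, `max_score`, `threshold_fraction`, `threshold`.
#' @export
weight_matrix <- function(counts, motif_id, threshold_fraction = 0.8,
                          pseudocount = 1) {
  if (!is.matrix(counts) || nrow(counts) != 4)
    stop("'counts' must be a 4-row matrix (A, C, G, T)")
  if (ncol(counts) < 1) stop("motif must have >= 1 column")
  if (any(counts < 0)) stop("negative counts in motif '", motif_id, "'")
  if (threshold_fraction < 0 || threshold_fraction > 1)
    stop("'threshold_fraction' must be in [0, 1]")
  rownames(counts) <- BASES
  col_tot <- colSums(counts)
  freq <- sweep(counts + pseudocount, 2, col_tot + 4 * pseudocount, "/")
  logratio <- log2(freq / 0.25)
  min_score <- sum(apply(logratio, 2, min))
  max_score <- sum(apply(logratio, 2, max))
  threshold <- min_score + threshold_fraction * (max_score - min_score)
  structure(list(motif_id = motif_id, counts = counts, logratio = logratio,
                 min_score = min_score, max_score = max_score,
                 threshold_fraction = threshold_fraction,
                 threshold = threshold, pseudocount = pseudocount),
            class = "WeightMatrix")
}

#' @export
print.WeightMatrix <- function(x, ...) {
  cat("WeightMatrix '", x$motif_id, "': ", ncol(x$counts), " bp, score range [",
      round(x$min_score, 3), ", ", round(x$max_score, 3), "], threshold ",
      round(x$threshold, 3), " (", x$threshold_fraction,
      " of range)\n", sep = "")
  invisible(x)
}

#' Parse a JASPAR-format PFM file
#'
#' Accepts the JASPAR text format: an optional `>` header line followed by
#' four count rows, either bare whitespace-separated numbers or the
#' `A [ 4 19 0 ]` bracketed dialect.
#'
#' @param path PFM file path.
#' @param threshold_fraction,pseudocount passed to [weight_matrix()].
#' @return A [weight_matrix()].
#' @export
load_pfm <- function(path, threshold_fraction = 0.8, pseudocount = 1) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("'", path, "': empty PFM file")
  motif_id <- tools::file_path_sans_ext(basename(path))
  if (startsWith(lines[1], ">")) {
    motif_id <- strsplit(sub("^>\\s*", "", lines[1]), "\\s+")[[1]][1]
    lines <- lines[-1]
  }
  if (length(lines) != 4)
    stop("'", path, "': expected 4 count rows, found ", length(lines))
  rows <- lapply(seq_along(lines), function(i) {
    ln <- lines[i]
    ln <- sub("^[ACGTacgt]\\s*", "", ln)
    ln <- gsub("\\[|\\]", " ", ln)
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    if (anyNA(v)) stop("'", path, "' row ", i, ": non-numeric count")
    v
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1)
    stop("'", path, "': ragged rows (lengths ",
         paste(lens, collapse = ", "), ")")
  counts <- do.call(rbind, rows)
  weight_matrix(counts, motif_id, threshold_fraction, pseudocount)
}

#' Load every PFM file in a directory
#' @param dir directory containing `.pfm`/`.txt` JASPAR matrices.
#' @param ... passed to [load_pfm()].
#' @return named list of [weight_matrix()] objects.
#' @export
load_pfm_dir <- function(dir, ...) {
  paths <- list.files(dir, pattern = "\\.(pfm|txt)$", full.names = TRUE)
  if (!length(paths)) stop("no .pfm/.txt files in ", dir)
  wms <- lapply(paths, load_pfm, ...)
  names(wms) <- vapply(wms, function(w) w$motif_id, character(1))
  wms
}

encode_dna <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  code <- match(chars, c(BASES, "N"))
  if (anyNA(code))
    stop("sequence contains characters outside {A,C,G,T,N}")
  code[code == 5L] <- NA_integer_
  code
}

# reverse-complement scoring matrix: scoring forward windows with it equals
# scoring the reverse complement of the window with the original matrix
revcomp_matrix <- function(logratio) {
  logratio[4:1, rev(seq_len(ncol(logratio))), drop = FALSE]
}

# score all windows of an integer-coded sequence against a 4 x L matrix;
# windows containing NA (i.e. N) score NA
score_windows <- function(code, M) {
  L <- ncol(M)
  nw <- length(code) - L + 1L
  if (nw < 1) return(numeric(0))
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    sc <- sc + M[, j][code[j:(j + nw - 1L)]]
  }
  sc
}

#' Scan one sequence with a weight matrix on both strands
#'
#' Scores every length-L window on the forward strand and on the reverse
#' complement; a window is a hit when its score is at or above the matrix
#' threshold. Positions are 0-based half-open on forward-strand coordinates.
#' Windows containing N are skipped.
#'
#' @param sequence a single DNA string over A, C, G, T, N.
#' @param wm a [weight_matrix()].
#' @return data.frame `position, strand, score`, one row per hit.
#' @export
scan_motif <- function(sequence, wm) {
  stopifnot(inherits(wm, "WeightMatrix"))
  code <- encode_dna(sequence)
  fwd <- score_windows(code, wm$logratio)
  rev <- score_windows(code, revcomp_matrix(wm$logratio))
  hit_f <- which(!is.na(fwd) & fwd >= wm$threshold)
  hit_r <- which(!is.na(rev) & rev >= wm$threshold)
  out <- data.frame(
    position = c(hit_f, hit_r) - 1L,
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    score = c(fwd[hit_f], rev[hit_r]),
    stringsAsFactors = FALSE)
  out[order(out$position, out$strand), , drop = FALSE]
}

# Pre-encode a promoter set for repeated scanning: all sequences are
# concatenated into one integer vector with a block of Ns between them, so
# that cross-boundary windows score NA and vector-shift scoring works on the
# whole set at once. `pad` must be >= longest motif - 1.
encode_promoter_set <- function(promoters, pad = 39L) {
  seqs <- as.character(promoters)
  if (!length(seqs)) stop("empty promoter set")
  joined <- paste(toupper(seqs), collapse = strrep("N", pad))
  code <- match(strsplit(joined, "")[[1]], c(BASES, "N"))
  if (anyNA(code))
    stop("sequence contains characters outside {A,C,G,T,N}")
  code[code == 5L] <- NA_integer_
  lens <- nchar(seqs)
  starts <- cumsum(c(1L, utils::head(lens + pad, -1L)))
  structure(list(code = code, starts = starts, lens = lens,
                 n_sequences = length(seqs), pad = pad),
            class = "EncodedPromoterSet")
}

# hit tally for one matrix over an encoded set
profile_encoded <- function(enc, wm) {
  L <- ncol(wm$logratio)
  if (L - 1L > enc$pad) stop("motif longer than the encoding pad")
  n_with_hit <- 0L; total_hits <- 0L; scanned <- 0
  hit_seqs <- integer(0)
  total <- length(enc$code)
  nw <- total - L + 1L
  if (nw >= 1) {
    for (M in list(wm$logratio, revcomp_matrix(wm$logratio))) {
      sc <- numeric(nw)
      for (j in seq_len(L))
        sc <- sc + M[, j][enc$code[j:(j + nw - 1L)]]
      valid <- !is.na(sc)
      hits <- which(valid & sc >= wm$threshold)
      scanned <- scanned + sum(valid)
      total_hits <- total_hits + length(hits)
      if (length(hits))
        hit_seqs <- c(hit_seqs, findInterval(hits, enc$starts))
    }
    n_with_hit <- length(unique(hit_seqs))
  }
  structure(list(motif_id = wm$motif_id, n_sequences = enc$n_sequences,
                 n_sequences_with_hit = as.integer(n_with_hit),
                 total_hits = as.integer(total_hits),
                 total_scanned_bp = scanned),
            class = "HitProfile")
}

#' Tally motif hits over a promoter set
#'
#' Aggregates both-strand scanning over all sequences of a set: the number of
#' sequences, the number with at least one hit, the total hit count, and the
#' total scanned base pairs (valid window starts on both strands, N windows
#' excluded).
#'
#' @param promoters named character vector (or `PromoterSet`) of sequences,
#'   or a pre-encoded set from the internal encoder (used by
#'   [motif_enrichment()] to avoid re-encoding per motif).
#' @param wm a [weight_matrix()].
#' @return An object of class `HitProfile`.
#' @export
profile_set <- function(promoters, wm) {
  stopifnot(inherits(wm, "WeightMatrix"))
  if (!inherits(promoters, "EncodedPromoterSet"))
    promoters <- encode_promoter_set(promoters,
                                     pad = max(39L, ncol(wm$logratio)))
  profile_encoded(promoters, wm)
}

#' Sequence-level Fisher test of motif over-representation
#'
#' Exact two-sided test on the 2x2 table of sequences with / without a hit in
#' the foreground versus background set. The odds ratio is the sample
#' cross-product ratio, with the Haldane 0.5 correction applied when any cell
#' is zero.
#'
#' @param fg,bg `HitProfile`s from [profile_set()] under the same matrix.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return list `p_value`, `odds_ratio`.
#' @export
fisher_sequence_test <- function(fg, bg, alternative = "two.sided") {
  if (fg$n_sequences < 1 || bg$n_sequences < 1)
    stop("both sets need >= 1 sequence")
  tab <- matrix(c(fg$n_sequences_with_hit,
                  fg$n_sequences - fg$n_sequences_with_hit,
                  bg$n_sequences_with_hit,
                  bg$n_sequences - bg$n_sequences_with_hit),
                nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  if (any(tab == 0)) tab <- tab + 0.5
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p_value = min(p, 1), odds_ratio = or)
}

#' Per-bp Z-score of motif over/under-representation
#'
#' Treats every scanned window start as a Bernoulli trial at the background
#' hit rate: with `rate = bg$total_hits / bg$total_scanned_bp`,
#' `z = (fg$total_hits - expected) / sqrt(fg_bp * rate * (1 - rate))`.
#' Positive z means over-representation in the foreground, negative z
#' under-representation.
#'
#' @param fg,bg `HitProfile`s from [profile_set()] under the same matrix.
#' @return signed z (NA with a warning when the background rate is 0 or 1).
#' @export
zscore_bp_test <- function(fg, bg) {
  if (fg$total_scanned_bp <= 0 || bg$total_scanned_bp <= 0)
    stop("total_scanned_bp must be positive in both sets")
  rate <- bg$total_hits / bg$total_scanned_bp
  if (rate <= 0 || rate >= 1) {
    warning("background hit rate is ", rate, ": Z undefined")
    return(NA_real_)
  }
  expected <- fg$total_scanned_bp * rate
  (fg$total_hits - expected) /
    sqrt(fg$total_scanned_bp * rate * (1 - rate))
}

#' Motif enrichment of a foreground promoter set against a background
#'
#' Runs [profile_set()], [fisher_sequence_test()] and [zscore_bp_test()] for
#' every motif.
#'
#' @param fg,bg promoter sets (named character vectors).
#' @param motifs list of [weight_matrix()] objects.
#' @param alternative passed to [fisher_sequence_test()].
#' @return An `EnrichmentTable` data.frame: per motif, foreground and
#'   background tallies, `fisher_p`, `odds_ratio`, `z_score` and `direction`
#'   ("over" iff z > 0).
#' @export
motif_enrichment <- function(fg, bg, motifs, alternative = "two.sided") {
  pad <- max(39L, max(vapply(motifs, function(w) ncol(w$logratio),
                             integer(1))))
  fg <- encode_promoter_set(fg, pad)
  bg <- encode_promoter_set(bg, pad)
  rows <- lapply(motifs, function(wm) {
    pf <- profile_set(fg, wm)
    pb <- profile_set(bg, wm)
    fish <- fisher_sequence_test(pf, pb, alternative)
    z <- suppressWarnings(zscore_bp_test(pf, pb))
    data.frame(motif_id = wm$motif_id,
               fg_sequences = pf$n_sequences,
               fg_with_hit = pf$n_sequences_with_hit,
               fg_hits = pf$total_hits, fg_scanned_bp = pf$total_scanned_bp,
               bg_sequences = pb$n_sequences,
               bg_with_hit = pb$n_sequences_with_hit,
               bg_hits = pb$total_hits, bg_scanned_bp = pb$total_scanned_bp,
               fisher_p = fish$p_value, odds_ratio = fish$odds_ratio,
               z_score = z,
               direction = if (is.na(z)) NA_character_ else
                 if (z > 0) "over" else "under",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("EnrichmentTable", "data.frame"))
}

#' Assemble a motifs x gene-sets Z-score heatmap matrix
#'
#' Collects the per-bp Z-scores of several [motif_enrichment()] runs (one per
#' gene set) into a single matrix with stable lexicographic row and column
#' order, and optionally writes it as TSV.
#'
#' @param results named list of `EnrichmentTable`s, one per gene set.
#' @param path optional TSV output path.
#' @return the motifs x sets numeric matrix, invisibly if written.
#' @export
enrichment_heatmap <- function(results, path = NULL) {
  if (!length(results)) stop("need >= 1 gene set")
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("'results' must be a named list (one name per gene set)")
  sets <- sort(names(results))
  motifs <- sort(unique(unlist(lapply(results, `[[`, "motif_id"))))
  mat <- matrix(NA_real_, length(motifs), length(sets),
                dimnames = list(motifs, sets))
  for (s in sets) {
    tab <- results[[s]]
    mat[tab$motif_id, s] <- tab$z_score
  }
  if (!is.null(path)) {
    out <- data.frame(motif_id = rownames(mat), mat, check.names = FALSE)
    write_tsv_strict(out, path)
    return(invisible(mat))
  }
  mat
}

#' Read promoters from a FASTA file
#'
#' Sequences longer than `window` are right-truncated, keeping the 3' end
#' nearest the gene start (the proximal promoter convention).
#'
#' @param path FASTA path.
#' @param window promoter window in bp (default 1500).
#' @return named character vector of class `PromoterSet`.
#' @export
read_promoters <- function(path, window = 1500) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  long <- nchar(seqs) > window
  if (any(long))
    seqs[long] <- substr(seqs[long], nchar(seqs[long]) - window + 1,
                         nchar(seqs[long]))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1)
  if (anyDuplicated(names(seqs))) stop("duplicate promoter names in ", path)
  structure(seqs, class = "PromoterSet")
}

#' Write promoters to FASTA
#' @param promoters named character vector.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_promoters <- function(promoters, path) {
  ss <- Biostrings::DNAStringSet(as.character(unclass(promoters)))
  names(ss) <- names(promoters)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
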