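# Validation of a discovered signature: subject clustering, qRT-PCR delta-Ct
# quantification, cross-platform concordance, and comparative marker panels.

#' Cluster subjects on a gene signature
#'
#' Partitions the samples into `k` groups using only the signature genes'
#' expression and scores agreement with the WL/WS weight-loss labelling as
#' best-matching-assignment accuracy (each cluster mapped to the label that
#' maximises total agreement).
#'
#' Hierarchical clustering uses distance 1 - Pearson correlation between
#' subjects over the (gene-centered) signature expression, average linkage,
#' tree cut at `k`. k-means runs 25 seeded restarts on the centered
#' signature profiles and keeps the best inertia.
#'
#' @param study an [expression_study()].
#' @param signature a [intersect_signature()] `SignatureSet` (or any
#'   data.frame with a `gene_id` column).
#' @param method "hierarchical" or "kmeans".
#' @param k number of clusters (default 2).
#' @param seed seed for the k-means restarts.
#' @return list with `assignment` (named integer vector), `accuracy`,
#'   `method`, `k`.
#' @export
cluster_subjects <- function(study, signature,
                             method = c("hierarchical", "kmeans"),
                             k = 2, seed = 1L) {
  stopifnot(inherits(study, "ExpressionStudy"))
  method <- match.arg(method)
  genes <- intersect(signature$gene_id, rownames(study$values))
  if (length(genes) == 0)
    stop("empty signature: nothing to cluster on; ",
         "check the FDR bound and upstream filters")
  n <- ncol(study$values)
  if (k < 2 || k > n) stop("k must satisfy 2 <= k <= n_samples")

  M <- study$values[genes, , drop = FALSE]
  # center genes (baseline abundance is not signal); genes are deliberately
  # not scaled to unit SD: subject-subject correlation is already
  # per-subject scale-free, and unit-scaling would give weakly-responding
  # genes the same weight as strongly-responding ones
  M <- M - rowMeans(M)

  if (method == "hierarchical") {
    if (length(genes) >= 2) {
      d <- stats::as.dist(1 - stats::cor(M))
    } else {
      d <- stats::dist(t(M))
    }
    hc <- stats::hclust(d, method = "average")
    assignment <- stats::cutree(hc, k = k)
  } else {
    set.seed(seed)
    km <- stats::kmeans(t(M), centers = k, nstart = 25)
    assignment <- km$cluster
  }
  names(assignment) <- colnames(study$values)

  labels <- study$clinical$wl_label
  acc <- mapping_accuracy(assignment, labels)
  list(assignment = assignment, accuracy = acc, method = method, k = k)
}

# best cluster-to-label mapping accuracy: each cluster takes its majority
# label (the maximum over all cluster -> label maps)
mapping_accuracy <- function(assignment, labels) {
  tab <- table(assignment, labels)
  sum(apply(tab, 1, max)) / length(labels)
}

#' Read a Ct table from TSV
#'
#' Expected columns: `sample_id, gene_id, replicate, ct`.
#'
#' @param path TSV path.
#' @param reference_gene designated reference gene id (default "RNA18S").
#' @return a `CtTable` data.frame.
#' @export
read_ct_table <- function(path, reference_gene = "RNA18S") {
  ct <- read_tsv_strict(path)
  need <- c("sample_id", "gene_id", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table must have columns ", paste(need, collapse = ", "))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  structure(ct, class = c("CtTable", "data.frame"),
            reference_gene = reference_gene)
}

#' Quantify a Ct table by the delta-Ct method
#'
#' Averages the replicate wells per (sample, gene), subtracts the sample's
#' mean reference-gene Ct, and reports
#' `deltaCt = mean Ct(target) - mean Ct(reference)` and relative expression
#' `2^(-deltaCt)`. Samples missing the reference gene get `NA` with a logged
#' warning.
#'
#' @param ct a `CtTable` ([generate_ct_table()] or [read_ct_table()]).
#' @param reference_gene overrides the table's designated reference.
#' @return data.frame `sample_id, gene_id, delta_ct, rel_expr`.
#' @export
delta_ct <- function(ct, reference_gene = NULL) {
  if (is.null(reference_gene))
    reference_gene <- attr(ct, "reference_gene")
  if (is.null(reference_gene)) reference_gene <- "RNA18S"
  mean_ct <- stats::aggregate(ct ~ sample_id + gene_id, data = ct, FUN = mean)
  ref <- mean_ct[mean_ct$gene_id == reference_gene, c("sample_id", "ct")]
  names(ref)[2] <- "ref_ct"
  tgt <- mean_ct[mean_ct$gene_id != reference_gene, ]
  out <- merge(tgt, ref, by = "sample_id", all.x = TRUE, sort = FALSE)
  if (anyNA(out$ref_ct))
    warning("reference gene '", reference_gene, "' missing for sample(s): ",
            paste(unique(out$sample_id[is.na(out$ref_ct)]), collapse = ", "))
  out$delta_ct <- out$ct - out$ref_ct
  out$rel_expr <- 2^(-out$delta_ct)
  out <- out[order(out$sample_id, out$gene_id),
             c("sample_id", "gene_id", "delta_ct", "rel_expr")]
  rownames(out) <- NULL
  out
}

#' Cross-platform concordance of trait correlations
#'
#' Scores, gene by gene, whether the qPCR trait correlation reproduces the
#' array trait correlation: `sign_concordant` when both coefficients are
#' non-zero with matching sign, `validated` when additionally the qPCR
#' regression p-value is below `alpha`. Genes missing a qPCR coefficient
#' count as tested but not validated.
#'
#' @param coeffs data.frame with columns `gene_id`, `array_r`, `qpcr_r`,
#'   `qpcr_p`; `NA` marks a missing measurement.
#' @param alpha significance level for the qPCR regression (default 0.05).
#' @return A `ConcordanceReport` data.frame with per-gene columns plus
#'   attributes `n_tested` and `n_validated`.
#' @export
concordance <- function(coeffs, alpha = 0.05) {
  need <- c("gene_id", "array_r", "qpcr_r", "qpcr_p")
  if (!all(need %in% names(coeffs)))
    stop("'coeffs' must have columns ", paste(need, collapse = ", "))
  both <- !is.na(coeffs$array_r) & !is.na(coeffs$qpcr_r)
  if (!any(both))
    stop("no gene has coefficients on both platforms")
  sc <- both & sign(coeffs$array_r) == sign(coeffs$qpcr_r) &
    coeffs$array_r != 0 & coeffs$qpcr_r != 0
  val <- sc & !is.na(coeffs$qpcr_p) & coeffs$qpcr_p < alpha
  out <- data.frame(gene_id = coeffs$gene_id, array_r = coeffs$array_r,
                    qpcr_r = coeffs$qpcr_r, qpcr_p = coeffs$qpcr_p,
                    sign_concordant = sc, validated = val,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("ConcordanceReport", "data.frame"),
            n_tested = nrow(out), n_validated = sum(val))
}

#' Read a marker panel (one gene id per line)
#'
#' @param path plain-text file, one id per line; the panel name is the file
#'   name without extension.
#' @return list with `name` and `genes` (class `MarkerPanel`).
#' @export
read_marker_panel <- function(path) {
  genes <- trimws(readLines(path))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("marker panel '", path, "' is empty")
  structure(list(name = tools::file_path_sans_ext(basename(path)),
                 genes = genes), class = "MarkerPanel")
}

#' Comparative marker-panel analysis
#'
#' For published top-regulated marker panels from other muscle physiological
#' states, compares each panel gene's expression between the below-cut and
#' at-or-above-cut weight-loss groups: group means with SEM and a two-sided
#' Welch t-test. Panel ids absent from the study are excluded with a logged
#' message.
#'
#' @param study an [expression_study()].
#' @param panels list of `MarkerPanel` objects ([read_marker_panel()]).
#' @param group_cut weight-loss percentage splitting the two groups
#'   (default 5).
#' @return named list, one data.frame per panel
#'   (`gene_id, mean_low, sem_low, mean_high, sem_high, p_value`), each with
#'   attribute `n_significant` (count of p < 0.05).
#' @export
comparative_panels <- function(study, panels, group_cut = 5) {
  stopifnot(inherits(study, "ExpressionStudy"))
  grp_high <- study$clinical$weight_loss_pct >= group_cut
  if (!any(grp_high) || all(grp_high))
    stop("group_cut = ", group_cut, " leaves an empty group")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  res <- lapply(panels, function(panel) {
    genes <- panel$genes[panel$genes %in% rownames(study$values)]
    dropped <- setdiff(panel$genes, genes)
    if (length(dropped))
      message("panel '", panel$name, "': ", length(dropped),
              " id(s) not in study, excluded")
    rows <- lapply(genes, function(g) {
      lo <- study$values[g, !grp_high]
      hi <- study$values[g, grp_high]
      p <- tryCatch(stats::t.test(hi, lo)$p.value, error = function(e) NA_real_)
      data.frame(gene_id = g, mean_low = mean(lo), sem_low = sem(lo),
                 mean_high = mean(hi), sem_high = sem(hi), p_value = p,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab))
      tab <- data.frame(gene_id = character(0), mean_low = numeric(0),
                        sem_low = numeric(0), mean_high = numeric(0),
                        sem_high = numeric(0), p_value = numeric(0))
    attr(tab, "n_significant") <- sum(tab$p_value < 0.05, na.rm = TRUE)
    tab
  })
  names(res) <- vapply(panels, function(p) p$name, character(1))
  res
}
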