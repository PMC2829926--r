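#' Construct an ExpressionStudy
#'
#' Bundles a log-scale expression matrix (genes x samples), the matching
#' detection-call matrix, and a per-sample clinical table into a validated
#' container used by every downstream stage.
#'
#' The clinical table must carry `sample_id` and `weight_loss_pct`; `bmi` and
#' `crp` are optional. The weight-losing label (`wl_label`, "WL"/"WS") is
#' derived at the `wl_cut` threshold (>= 5 percent weight loss by default) and
#' the systemic-inflammation flag (`si_flag`) at `si_cut` (serum CRP >= 5 mg/l
#' by default); if those columns are already present they are checked against
#' the thresholds instead.
#'
#' @param values numeric matrix, genes x samples, log-scale expression.
#'   Row names are gene ids, column names sample ids.
#' @param detected logical matrix of the same dimension: TRUE where the gene
#'   was called detected (present or marginal) on that array. Defaults to all
#'   TRUE.
#' @param clinical data.frame with one row per sample, aligned to
#'   `colnames(values)` via its `sample_id` column.
#' @param wl_cut weight-loss percentage defining the WL group (default 5).
#' @param si_cut CRP concentration in mg/l defining systemic inflammation
#'   (default 5).
#' @return An object of class `ExpressionStudy`: a list with elements
#'   `values`, `detected`, `clinical`.
#' @export
expression_study <- function(values, detected = NULL, clinical,
                             wl_cut = 5, si_cut = 5) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%05d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  if (is.null(detected)) {
    detected <- matrix(TRUE, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  }
  if (!identical(dim(detected), dim(values)))
    stop("'detected' must have the same dimensions as 'values'")
  if (!is.logical(detected))
    stop("'detected' must be a logical matrix")
  dimnames(detected) <- dimnames(values)

  if (!is.data.frame(clinical) || is.null(clinical$sample_id))
    stop("'clinical' must be a data.frame with a 'sample_id' column")
  if (!setequal(clinical$sample_id, colnames(values)) ||
      anyDuplicated(clinical$sample_id))
    stop("clinical 'sample_id' must match the sample columns 1:1")
  clinical <- clinical[match(colnames(values), clinical$sample_id), ,
                       drop = FALSE]
  rownames(clinical) <- NULL
  if (is.null(clinical$weight_loss_pct))
    stop("'clinical' must contain 'weight_loss_pct'")

  wl <- ifelse(clinical$weight_loss_pct >= wl_cut, "WL", "WS")
  if (is.null(clinical$wl_label)) {
    clinical$wl_label <- wl
  } else if (!identical(as.character(clinical$wl_label), wl)) {
    stop("'wl_label' inconsistent with weight_loss_pct at the ", wl_cut,
         "% cut")
  }
  if (!is.null(clinical$crp)) {
    si <- clinical$crp >= si_cut
    if (is.null(clinical$si_flag)) {
      clinical$si_flag <- si
    } else if (!identical(clinical$si_flag, si)) {
      stop("'si_flag' inconsistent with crp at ", si_cut, " mg/l")
    }
    if (anyNA(clinical$crp))
      message("CRP missing for ", sum(is.na(clinical$crp)),
              " sample(s); SI flag undefined there")
  }

  structure(list(values = values, detected = detected, clinical = clinical),
            class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat("ExpressionStudy: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  detected on >=1 array: ", sum(rowSums(x$detected) > 0), " genes\n",
      sep = "")
  cat("  WL (>=5% weight loss): ", sum(x$clinical$wl_label == "WL"),
      " of ", nrow(x$clinical), " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.ExpressionStudy <- function(x) dim(x$values)

# restrict a study to a subset of gene indices, preserving order
subset_genes <- function(study, keep) {
  study$values <- study$values[keep, , drop = FALSE]
  study$detected <- study$detected[keep, , drop = FALSE]
  study
}

#' Remove genes absent on every array
#'
#' Drops genes whose detection call is absent on all arrays, the standard
#' pre-analysis filter for present/absent-called expression matrices. Genes
#' detected on at least one array survive; order is preserved.
#'
#' @param study an [expression_study()].
#' @return The filtered `ExpressionStudy`.
#' @export
filter_all_absent <- function(study) {
  stopifnot(inherits(study, "ExpressionStudy"))
  subset_genes(study, rowSums(study$detected) > 0)
}

#' Remove genes with low across-sample standard deviation
#'
#' Drops genes whose standard deviation across samples falls strictly below
#' the `sd_quantile` quantile of all gene SDs. With `sd_quantile = 0` this is
#' the identity.
#'
#' @param study an [expression_study()] with at least 2 samples.
#' @param sd_quantile fraction in `[0, 1)`; default 0.25.
#' @return The filtered `ExpressionStudy`.
#' @export
filter_low_sd <- function(study, sd_quantile = 0.25) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (ncol(study$values) < 2) stop("need >= 2 samples to compute SDs")
  if (!is.numeric(sd_quantile) || length(sd_quantile) != 1 ||
      sd_quantile < 0 || sd_quantile >= 1)
    stop("'sd_quantile' must be a single number in [0, 1)")
  sds <- apply(study$values, 1, stats::sd)
  cut <- stats::quantile(sds, sd_quantile, names = FALSE)
  subset_genes(study, sds >= cut)
}
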