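# Plain-text I/O for expression studies.
#
# Expression TSV: first column the gene id, remaining columns one per sample.
# Detection TSV: same shape, cells P/M/A (present / marginal / absent);
# P and M both count as detected. Clinical TSV: header
# sample_id, weight_loss_pct, bmi, crp (bmi/crp may be empty). All numeric
# parsing is locale-independent with '.' as the decimal separator.

read_tsv_strict <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

write_tsv_strict <- function(x, path, row.names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row.names, col.names = TRUE)
}

#' Read an ExpressionStudy from TSV files
#'
#' @param expression_path path to the expression TSV (first column gene id).
#' @param clinical_path path to the clinical TSV.
#' @param detection_path optional path to the companion detection TSV with
#'   P/M/A calls; when absent every gene is treated as detected.
#' @return An [expression_study()].
#' @export
read_expression_study <- function(expression_path, clinical_path,
                                  detection_path = NULL) {
  expr <- read_tsv_strict(expression_path)
  values <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(expr[[1]])

  detected <- NULL
  if (!is.null(detection_path)) {
    det <- read_tsv_strict(detection_path, colClasses = "character")
    calls <- as.matrix(det[, -1, drop = FALSE])
    if (!all(calls %in% c("P", "M", "A")))
      stop("detection calls must be P, M or A")
    if (!identical(dim(calls), dim(values)) ||
        !identical(as.character(det[[1]]), rownames(values)))
      stop("detection TSV does not match the expression TSV shape")
    detected <- calls != "A"
  }

  clinical <- read_tsv_strict(clinical_path)
  clinical$sample_id <- as.character(clinical$sample_id)
  if (!is.null(clinical$si_flag))
    clinical$si_flag <- as.logical(clinical$si_flag)
  expression_study(values, detected, clinical)
}

#' Write an ExpressionStudy to TSV files
#'
#' Writes the expression matrix, P/A detection calls and clinical table as
#' three TSV files.
#'
#' @param study an [expression_study()].
#' @param expression_path,detection_path,clinical_path output paths.
#' @return Invisibly, the study.
#' @export
write_expression_study <- function(study, expression_path, detection_path,
                                   clinical_path) {
  stopifnot(inherits(study, "ExpressionStudy"))
  expr <- data.frame(gene_id = rownames(study$values), study$values,
                     check.names = FALSE)
  write_tsv_strict(expr, expression_path)
  calls <- ifelse(study$detected, "P", "A")
  det <- data.frame(gene_id = rownames(study$values), calls,
                    check.names = FALSE)
  write_tsv_strict(det, detection_path)
  clin <- study$clinical
  clin$si_flag <- if (!is.null(clin$si_flag)) as.integer(clin$si_flag)
  write_tsv_strict(clin, clinical_path)
  invisible(study)
}
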