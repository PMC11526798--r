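#' Stage-annotated expression container
#'
#' A light S3 container for a log2-scale gene x sample expression matrix with
#' per-sample class (control/tumor) and AJCC stage annotation. It is the
#' central object of the pipeline: the ingest functions build it, the filters
#' subset it, and the modelling functions consume its matrix together with a
#' design built from its stage vector.
#'
#' @param values numeric gene x sample matrix (log2 scale) with unique
#'   rownames (gene symbols) and colnames (sample barcodes/ids).
#' @param sample_class character/factor, one of `"control"`/`"tumor"` per
#'   sample (column).
#' @param stage per-sample stage: `"control"` for controls, `"I"`..`"IV"` for
#'   tumors, `NA` when the stage annotation is missing.
#' @param gene_meta optional data.frame of per-gene metadata (e.g. the
#'   composite `SYMBOL|ENTREZ` identifier), one row per gene.
#' @param sample_data optional data.frame of per-sample clinical fields
#'   (e.g. `os_time`, `os_event`), one row per sample.
#'
#' @return An object of class `annotated_expression`: a list with elements
#'   `values`, `sample_class` (factor), `stage` (factor with levels control,
#'   I..IV), `gene_meta`, `sample_data`.
#' @export
annotated_expression <- function(values, sample_class, stage,
                                 gene_meta = NULL, sample_data = NULL) {
  values <- as.matrix(values)
  # R normalizes empty dimnames to NULL, so only require names when nonempty
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids in expression matrix")
  n <- ncol(values)
  sample_class <- factor(as.character(sample_class),
                         levels = c("control", "tumor"))
  stage <- factor(as.character(stage), levels = stage_levels())
  if (length(sample_class) != n || length(stage) != n)
    stop("sample annotations must match the number of columns")
  if (anyNA(sample_class))
    stop("sample_class must be 'control' or 'tumor'")
  ctrl <- sample_class == "control"
  if (any(ctrl != (!is.na(stage) & stage == "control")))
    stop("stage must be 'control' exactly for control samples")
  if (!is.null(gene_meta) && nrow(gene_meta) != nrow(values))
    stop("gene_meta must have one row per gene")
  if (!is.null(sample_data) && nrow(sample_data) != n)
    stop("sample_data must have one row per sample")
  structure(
    list(values = values, sample_class = sample_class, stage = stage,
         gene_meta = gene_meta, sample_data = sample_data),
    class = "annotated_expression"
  )
}

stage_levels <- function() c("control", "I", "II", "III", "IV")
tumor_stages <- function() c("I", "II", "III", "IV")

#' @export
print.annotated_expression <- function(x, ...) {
  cat(sprintf("annotated_expression: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  print(table(stage = addNA(x$stage, ifany = TRUE)))
  invisible(x)
}

#' @export
dim.annotated_expression <- function(x) dim(x$values)

#' Subset an annotated expression object
#'
#' @param x an `annotated_expression`.
#' @param i gene index (row) selector.
#' @param j sample index (column) selector.
#' @param ... ignored.
#' @return the subset `annotated_expression`.
#' @export
`[.annotated_expression` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  annotated_expression(
    x$values[i, j, drop = FALSE],
    x$sample_class[j],
    x$stage[j],
    gene_meta = if (!is.null(x$gene_meta)) x$gene_meta[i, , drop = FALSE],
    sample_data = if (!is.null(x$sample_data)) x$sample_data[j, , drop = FALSE]
  )
}
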