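#' Read a firebrowse-style expression matrix
#'
#' Parses the firebrowse RSEM-normalized dialect: row 1 is
#' `Hybridization REF` followed by full TCGA sample barcodes, row 2 is a
#' per-column annotation row (skipped), and each gene row starts with a
#' composite `SYMBOL|ENTREZ` identifier. Sample class is derived from the
#' barcode sample-type field (4th barcode field, first two digits): codes
#' 01-09 are tumors, 10-19 controls. Samples with malformed barcodes or other
#' type codes are excluded with a warning. Duplicate gene symbols keep the
#' highest-variance row.
#'
#' @param path path to the TSV.
#' @return an [annotated_expression()]; tumor stages are `NA` until
#'   [merge_and_annotate()] is applied. The composite identifiers are kept in
#'   `gene_meta$composite`.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  barcodes <- header[-1]
  dat <- tryCatch(
    utils::read.delim(path, skip = 2, header = FALSE,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        data.frame()
      else stop(e)
    })
  if (nrow(dat) == 0) {
    message("expression file contains no gene rows: ", path)
    values <- matrix(numeric(0), 0, length(barcodes),
                     dimnames = list(character(0), barcodes))
  } else {
    composite <- as.character(dat[[1]])
    values <- as.matrix(dat[, -1, drop = FALSE])
    if (ncol(values) != length(barcodes))
      stop("header/body column mismatch in ", path)
    dimnames(values) <- list(composite, barcodes)
  }

  type <- barcode_sample_type(barcodes)
  bad <- is.na(type)
  if (any(bad)) {
    for (b in barcodes[bad])
      warning("excluding sample with unparseable barcode: ", b,
              call. = FALSE)
    values <- values[, !bad, drop = FALSE]
    type <- type[!bad]
  }
  cls <- ifelse(type <= 9, "tumor", "control")

  symbol <- sub("\\|.*$", "", rownames(values))
  if (anyDuplicated(symbol)) {
    v <- apply(values, 1, stats::var)
    keep <- unlist(lapply(split(seq_along(symbol), symbol),
                          function(i) i[which.max(v[i])]), use.names = FALSE)
    dropped <- setdiff(seq_along(symbol), keep)
    message(length(dropped), " duplicate gene symbol row(s) dropped ",
            "(kept highest-variance row)")
    keep <- sort(keep)
    values <- values[keep, , drop = FALSE]
    symbol <- symbol[keep]
  }
  meta <- data.frame(symbol = symbol, composite = rownames(values),
                     stringsAsFactors = FALSE)
  rownames(values) <- symbol
  annotated_expression(values,
                       sample_class = cls,
                       stage = ifelse(cls == "control", "control", NA),
                       gene_meta = meta)
}

# sample-type code from a TCGA barcode; NA when malformed
barcode_sample_type <- function(barcodes) {
  fields <- strsplit(barcodes, "-", fixed = TRUE)
  vapply(fields, function(f) {
    if (length(f) < 4 || !grepl("^[0-9]{2}", f[4])) return(NA_integer_)
    code <- as.integer(substr(f[4], 1, 2))
    if (code < 1 || code > 19) NA_integer_ else code
  }, integer(1))
}

barcode_patient <- function(barcodes) {
  vapply(strsplit(barcodes, "-", fixed = TRUE), function(f)
    paste(f[seq_len(min(3, length(f)))], collapse = "-"), character(1))
}

#' Read a TCGA-style clinical table
#'
#' One header row with lowercase attribute names; `pathologic_stage` is
#' required (hard error when absent). The raw stage token is preserved —
#' sub-stage collapse happens in [merge_and_annotate()]. Retains the
#' demographic/survival fields when present (age, gender, height, weight,
#' vital_status, os_time, os_event).
#'
#' @param path path to the clinical TSV.
#' @return data.frame with a `barcode` column (patient-level) plus the
#'   retained attributes.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  dat <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(dat) <- tolower(names(dat))
  if (!"pathologic_stage" %in% names(dat))
    stop("clinical table lacks required column 'pathologic_stage'")
  bc_col <- intersect(c("bcr_patient_barcode", "hybridization_ref"),
                      names(dat))
  bc_col <- if (length(bc_col)) bc_col[1] else names(dat)[1]
  keep <- intersect(c("pathologic_stage", "age", "gender", "sex", "height",
                      "weight", "vital_status", "os_time", "os_event"),
                    names(dat))
  out <- cbind(data.frame(barcode = as.character(dat[[bc_col]]),
                          stringsAsFactors = FALSE),
               dat[, keep, drop = FALSE])
  out
}

#' Collapse a pathologic-stage token to its parent stage
#'
#' Lowercases, strips a leading "stage", strips one trailing sub-stage letter
#' (A/B/C), and maps roman or arabic numerals to `"I"`..`"IV"`. Anything else
#' (including literal "NA") maps to `NA`.
#'
#' @param token character vector of raw stage strings.
#' @return character vector in `c("I","II","III","IV", NA)`.
#' @export
collapse_stage <- function(token) {
  t <- tolower(trimws(as.character(token)))
  t <- sub("^stage\\s*", "", t)
  t <- sub("[abc]$", "", t)
  t <- trimws(t)
  map <- c(i = "I", ii = "II", iii = "III", iv = "IV",
           "1" = "I", "2" = "II", "3" = "III", "4" = "IV")
  unname(map[t])
}

#' Merge clinical annotation into an expression object
#'
#' Joins at the patient level (first three barcode fields). Tumor samples get
#' the collapsed parent stage; controls keep stage `"control"` regardless of
#' any clinical record; tumor samples with no clinical match or an
#' unparseable stage token get stage `NA` (flagged here, dropped later by
#' [apply_filters()]). Survival fields, when present, are carried into
#' `sample_data`.
#'
#' @param expr an [annotated_expression()] from [read_expression_matrix()].
#' @param clinical a data.frame from [read_clinical_table()].
#' @return the annotated [annotated_expression()] (same samples, no drops).
#' @export
merge_and_annotate <- function(expr, clinical) {
  ids <- colnames(expr$values)
  patient <- barcode_patient(ids)
  m <- match(patient, clinical$barcode)
  stage <- as.character(expr$stage)
  tum <- expr$sample_class == "tumor"
  unmatched <- tum & is.na(m)
  if (any(unmatched))
    warning(sum(unmatched), " tumor sample(s) without clinical match; ",
            "stage set to NA", call. = FALSE)
  stage[tum] <- ifelse(is.na(m[tum]), NA,
                       collapse_stage(clinical$pathologic_stage[m[tum]]))
  sd <- data.frame(sample_id = ids, patient = patient,
                   stringsAsFactors = FALSE)
  for (col in intersect(c("os_time", "os_event", "age", "gender",
                          "vital_status"), names(clinical)))
    sd[[col]] <- clinical[[col]][m]
  annotated_expression(expr$values, expr$sample_class, stage,
                       gene_meta = expr$gene_meta, sample_data = sd)
}

#' Apply the variance and missing-stage filters
#'
#' Removes tumor samples whose stage is missing, then removes genes whose
#' standard deviation over all retained samples (controls included, log2
#' scale) falls strictly below `sd_threshold`. A gene with sd exactly at the
#' threshold is retained. Emits a filter report via `message()`. Idempotent.
#'
#' @param ds an annotated, merged [annotated_expression()].
#' @param sd_threshold strict lower sd cutoff (default 1, log2 units).
#' @return the filtered [annotated_expression()].
#' @export
apply_filters <- function(ds, sd_threshold = 1.0) {
  keep_s <- !(ds$sample_class == "tumor" & is.na(ds$stage))
  ds2 <- ds[, keep_s]
  sds <- apply(ds2$values, 1, stats::sd)
  keep_g <- sds >= sd_threshold
  if (!any(keep_g)) stop("no variable genes: all fall below sd threshold ",
                         sd_threshold)
  message(sprintf(
    "filters: %d -> %d samples (NA-stage removed), %d -> %d genes (sd < %g)",
    ncol(ds$values), ncol(ds2$values), nrow(ds2$values), sum(keep_g),
    sd_threshold))
  ds2[keep_g, ]
}

#' Back-transform log2 values to pseudo-counts
#'
#' The RSEM firebrowse matrix is log2-transformed; voom wants count-like
#' input, so the pipeline takes the antilog, `2^v - 1`, clipped at zero.
#'
#' @param values log2-scale matrix (or an [annotated_expression()]).
#' @return nonnegative pseudo-count matrix.
#' @export
to_pseudocounts <- function(values) {
  if (inherits(values, "annotated_expression")) values <- values$values
  pmax(2^values - 1, 0)
}

#' Voom transform: log-CPM with precision weights
#'
#' Computes log2 counts-per-million with the 0.5/+1 offsets and
#' per-observation inverse-variance weights from a lowess mean-variance trend
#' fitted to sqrt residual standard deviations, via `limma::voom`. With fewer
#' than 10 genes the trend is not estimable and constant unit weights are
#' returned with a warning.
#'
#' @param counts nonnegative gene x sample count-like matrix.
#' @param design full-rank design matrix (see [build_design()]).
#' @param span lowess span of the trend fit.
#' @return a `limma::EList` with elements `E` (logcpm) and `weights`.
#' @export
voom_transform <- function(counts, design = NULL, span = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(design))
    design <- matrix(1, ncol(counts), 1, dimnames = list(NULL, "intercept"))
  if (nrow(design) != ncol(counts))
    stop("design rows must match the number of samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  E <- log2(t((t(counts) + 0.5) / (lib + 1)) * 1e6)
  if (nrow(counts) < 10) {
    warning("fewer than 10 genes: mean-variance trend not estimable, ",
            "using constant weights", call. = FALSE)
    return(new("EList", list(E = E, weights = array(1, dim(counts),
                                                    dimnames(counts)),
                             design = design)))
  }
  # a degenerate (flat) mean-variance relation gives every observation the
  # same precision; lowess interpolation is undefined there
  sigma <- limma::lmFit(E, design)$sigma
  if (diff(range(sigma)) < 1e-10)
    return(new("EList", list(E = E, weights = array(1, dim(counts),
                                                    dimnames(counts)),
                             design = design)))
  limma::voom(counts, design, span = span)
}
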