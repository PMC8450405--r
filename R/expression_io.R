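#' Construct a gene-by-sample expression matrix
#'
#' The central expression container: a non-negative numeric matrix of TPM
#' (transcripts per million) with gene symbols as row names, sample ids as
#' column names, and a group label (tissue name, or `"tumor"`/`"normal"`)
#' per sample.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   dimnames set. All values must be finite and non-negative.
#' @param sample_groups Named character vector mapping every sample id to a
#'   group label. When omitted, each sample is its own group (tissue-style
#'   tables where columns *are* the groups).
#' @return An object of class `gag_expr` (the matrix with a
#'   `sample_groups` attribute).
#' @export
expression_matrix <- function(values, sample_groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names")
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite values")
  if (any(values < 0))
    stop("negative TPM values are not allowed (",
         sum(values < 0), " cells < 0)")
  if (is.null(sample_groups)) {
    sample_groups <- setNames(colnames(values), colnames(values))
  }
  missing <- setdiff(colnames(values), names(sample_groups))
  if (length(missing) > 0L)
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  structure(values,
            sample_groups = sample_groups[colnames(values)],
            class = c("gag_expr", "matrix", "array"))
}

#' @export
print.gag_expr <- function(x, ...) {
  groups <- attr(x, "sample_groups")
  cat("TPM expression matrix: ", nrow(x), " genes x ", ncol(x),
      " samples (", length(unique(groups)), " groups)\n", sep = "")
  invisible(x)
}

#' Sample group labels of an expression matrix
#'
#' @param m A `gag_expr` object.
#' @return Named character vector, one group label per sample.
#' @export
sample_groups <- function(m) {
  stopifnot(inherits(m, "gag_expr"))
  attr(m, "sample_groups")
}

#' Read a TPM table from a tab-separated file
#'
#' Reads gene-by-sample (or sample-by-gene) TPM tables in the two dialects
#' used with tissue atlases and tumor cohorts: a consensus-tissue table whose
#' columns are tissues, or a cohort table whose columns are samples paired
#' with a two-column manifest (`sample_id<TAB>group`). Orientation is never
#' guessed: the caller states where the genes are.
#'
#' @param path TSV file with a header row; first column holds row labels.
#' @param orientation `"genes_in_rows"` or `"genes_in_cols"`; tables in the
#'   latter orientation are transposed on read.
#' @param manifest Optional path to a manifest TSV (`sample_id`, `group`,
#'   no header required; a header line `sample_id<TAB>group` is tolerated).
#'   When omitted, each sample is its own group.
#' @param xena_log Set `TRUE` when the file stores `log2(TPM + 0.001)`
#'   values (UCSC Xena convention); they are converted to TPM via
#'   [xena_log_to_tpm()]. Plain TPM otherwise.
#' @return A [expression_matrix()] (`gag_expr`).
#' @export
read_tpm_table <- function(path,
                           orientation = c("genes_in_rows", "genes_in_cols"),
                           manifest = NULL, xena_log = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- unique(count.fields(path, sep = "\t", quote = ""))
  if (length(nf) > 1L)
    stop("ragged TSV '", path, "': rows have differing field counts (",
         paste(sort(nf), collapse = ", "), ")")
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    row.names = 1L, stringsAsFactors = FALSE, quote = "")
  for (j in seq_along(tab)) {
    if (!is.numeric(tab[[j]])) {
      bad <- tab[[j]][is.na(suppressWarnings(as.numeric(tab[[j]])))][1L]
      stop("non-numeric cell in column '", colnames(tab)[j], "' of '",
           path, "': '", bad, "'")
    }
  }
  m <- as.matrix(tab)
  if (orientation == "genes_in_cols") m <- t(m)
  if (xena_log) {
    m <- xena_log_to_tpm(m)
  } else if (any(m < 0)) {
    stop("negative TPM in '", path, "' (", sum(m < 0),
         " cells); for log2(TPM + 0.001) input use xena_log = TRUE")
  }
  groups <- NULL
  if (!is.null(manifest)) {
    groups <- read_manifest(manifest)
    missing <- setdiff(colnames(m), names(groups))
    if (length(missing) > 0L)
      stop("manifest '", manifest, "' is missing samples: ",
           paste(missing, collapse = ", "))
    groups <- groups[colnames(m)]
  }
  expression_matrix(m, sample_groups = groups)
}

read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
  if (ncol(tab) < 2L) stop("manifest '", path, "' needs two columns ",
                           "(sample_id, group)")
  if (identical(tolower(tab[1L, 1L]), "sample_id")) tab <- tab[-1L, ]
  setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Write a TPM matrix to a tab-separated file
#'
#' @param m A `gag_expr` or plain matrix.
#' @param path Output TSV path; row labels go in a leading `gene` column.
#' @return `path`, invisibly.
#' @export
write_tpm_table <- function(m, path) {
  df <- data.frame(gene = rownames(m), as.data.frame(unclass(m)[, , drop = FALSE],
                   check.names = FALSE), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert Xena-style log2(TPM + 0.001) values back to TPM
#'
#' Harmonized TCGA/GTEx expression is distributed as `log2(TPM + 0.001)`;
#' the inverse transform is `2^x - 0.001`. Values that fall below zero by
#' floating-point error alone (the encoding of TPM = 0 is
#' `log2(0.001)` = -9.9658) are clamped to 0.
#'
#' @param x Numeric value, vector or matrix on the log scale.
#' @return TPM on the linear scale, same shape as `x`.
#' @examples
#' xena_log_to_tpm(0)    # 0.999
#' xena_log_to_tpm(10)   # 1023.999
#' @export
xena_log_to_tpm <- function(x) {
  out <- 2^x - 0.001
  out[out < 0] <- 0
  out
}

#' log2(TPM + 1) transform for plotting
#'
#' The transform applied to expression values before drawing boxplots:
#' monotone, maps 0 to 0 and compresses the heavy right tail of TPM.
#'
#' @param tpm Non-negative numeric value, vector or matrix.
#' @return `log2(tpm + 1)`, same shape as input.
#' @examples
#' log2_tpm_plus1(c(0, 1, 7))  # 0 1 3
#' @export
log2_tpm_plus1 <- function(tpm) {
  if (any(tpm < 0, na.rm = TRUE)) stop("negative TPM input")
  log2(tpm + 1)
}

#' Harmonize expression row symbols against a knowledge base
#'
#' Upper-cases row symbols, maps KB aliases to canonical symbols (e.g.
#' `Bpnt2` -> `IMPAD1`), collapses duplicate rows for one canonical symbol
#' by taking the per-sample maximum, and reports which KB genes remain
#' unmatched. Harmonization is idempotent.
#'
#' @param m A `gag_expr` object.
#' @param kb A `gag_kb` object.
#' @return List with `matrix` (harmonized `gag_expr`) and `report`, a list
#'   with `n_genes_matched`, `unmatched_kb_genes` and `alias_resolutions`
#'   (data frame of input/canonical symbol pairs).
#' @export
harmonize_symbols <- function(m, kb) {
  stopifnot(inherits(m, "gag_expr"), inherits(kb, "gag_kb"))
  groups <- sample_groups(m)
  input <- rownames(m)
  canon <- resolve_alias(kb, input)
  changed <- canon != toupper(input) | toupper(input) != input
  alias_res <- data.frame(input_symbol = input[canon != toupper(input)],
                          canonical_symbol = canon[canon != toupper(input)],
                          stringsAsFactors = FALSE)
  vals <- unclass(m)
  if (anyDuplicated(canon)) {
    vals <- do.call(rbind, lapply(split(seq_along(canon), canon), function(i) {
      apply(vals[i, , drop = FALSE], 2, max)
    }))
    # split() orders by symbol; restore first-occurrence order
    first <- unique(canon)
    vals <- vals[first, , drop = FALSE]
  } else {
    rownames(vals) <- canon
  }
  kb_syms <- kb_genes(kb)
  matched <- intersect(kb_syms, rownames(vals))
  report <- list(
    n_genes_matched = length(matched),
    unmatched_kb_genes = setdiff(kb_syms, rownames(vals)),
    alias_resolutions = alias_res
  )
  list(matrix = expression_matrix(vals, sample_groups = groups),
       report = report)
}
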