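#' Aggregate one gene group into a reaction activity
#'
#' Applies the gene-to-reaction aggregation rule: alternative isozymes are
#' summarized by the **maximum** TPM among members (any one isozyme
#' suffices), obligate complex subunits by the **minimum** (the scarcest
#' subunit limits complex formation). Ties are broken by the first-listed
#' member in KB order, making aggregation deterministic.
#'
#' @param values Named numeric vector of member TPM, in KB listing order.
#' @param semantics `"ALTERNATIVES"` (max) or `"COMPLEX"` (min).
#' @return List with `activity` (TPM) and `contributor` (the gene symbol
#'   achieving the extremum).
#' @examples
#' aggregate_group(c(XYLT1 = 5, XYLT2 = 10), "ALTERNATIVES")  # 10, XYLT2
#' aggregate_group(c(EXT1 = 8, EXT2 = 3), "COMPLEX")          # 3, EXT2
#' @export
aggregate_group <- function(values, semantics = c("ALTERNATIVES", "COMPLEX")) {
  semantics <- match.arg(semantics)
  if (length(values) == 0L) stop("empty gene group")
  if (is.null(names(values))) stop("'values' must be named by gene symbol")
  idx <- if (semantics == "ALTERNATIVES") which.max(values) else
    which.min(values)  # which.* return the first extremum: KB-order tie-break
  list(activity = unname(values[idx]), contributor = names(values)[idx])
}

#' Map gene-level TPM to reaction-level activity
#'
#' Computes one activity value per (reaction, sample): the aggregate of the
#' reaction's gene group under its semantics (see [aggregate_group()]).
#' The result is the reaction-by-sample matrix underlying pathway heatmaps
#' and tumor/normal comparisons.
#'
#' @param kb A `gag_kb` object.
#' @param m A harmonized `gag_expr` matrix (see [harmonize_symbols()]).
#' @param missing_policy `"STRICT"` errors when any KB reaction gene is
#'   absent from `m`. `"PERMISSIVE"` drops absent members of an
#'   ALTERNATIVES group and treats an absent COMPLEX subunit as TPM 0 (an
#'   absent obligate subunit implies no complex); imputations are recorded.
#' @return An object of class `gag_activity`: the reaction-by-sample
#'   activity matrix with attributes `sample_groups`, `provenance` (matrix
#'   of contributing gene symbols, same shape) and `imputed` (character
#'   vector of genes treated as missing under PERMISSIVE).
#' @examples
#' kb <- load_kb()
#' tpm <- matrix(1, nrow = 66, ncol = 2,
#'               dimnames = list(kb_genes(kb), c("s1", "s2")))
#' act <- reaction_activity(kb, expression_matrix(tpm))
#' dim(act)  # 29 2
#' @export
reaction_activity <- function(kb, m,
                              missing_policy = c("STRICT", "PERMISSIVE")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(kb, "gag_kb"), inherits(m, "gag_expr"))
  needed <- kb_genes(kb, include_auxiliary = FALSE)
  absent <- setdiff(needed, rownames(m))
  if (length(absent) > 0L && missing_policy == "STRICT") {
    stop("KB reaction genes absent from expression matrix: ",
         paste(absent, collapse = ", "),
         " (use missing_policy = \"PERMISSIVE\" to impute)")
  }
  vals <- unclass(m)
  ids <- kb_reaction_ids(kb)
  act <- matrix(NA_real_, nrow = length(ids), ncol = ncol(vals),
                dimnames = list(ids, colnames(vals)))
  prov <- matrix(NA_character_, nrow = length(ids), ncol = ncol(vals),
                 dimnames = list(ids, colnames(vals)))
  for (id in ids) {
    r <- kb$reactions[[id]]
    members <- r$genes
    present <- members[members %in% rownames(vals)]
    gm <- if (length(present) > 0L)
      vals[present, , drop = FALSE] else
      matrix(numeric(0), nrow = 0, ncol = ncol(vals))
    if (r$semantics == "COMPLEX") {
      # absent subunit contributes 0 under PERMISSIVE
      miss <- setdiff(members, present)
      if (length(miss) > 0L) {
        zero <- matrix(0, nrow = length(miss), ncol = ncol(vals),
                       dimnames = list(miss, colnames(vals)))
        gm <- rbind(gm, zero)
      }
      gm <- gm[members, , drop = FALSE]  # KB order for tie-breaking
    } else {
      if (length(present) == 0L)
        stop("reaction '", id, "' has no member present in the matrix")
      gm <- gm[members[members %in% present], , drop = FALSE]
    }
    for (j in seq_len(ncol(gm))) {
      ag <- aggregate_group(setNames(gm[, j], rownames(gm)), r$semantics)
      act[id, j] <- ag$activity
      prov[id, j] <- ag$contributor
    }
  }
  structure(act,
            sample_groups = attr(m, "sample_groups"),
            provenance = prov,
            imputed = absent,
            class = c("gag_activity", "matrix", "array"))
}

#' @export
print.gag_activity <- function(x, ...) {
  cat("Reaction activity matrix: ", nrow(x), " reactions x ", ncol(x),
      " samples\n", sep = "")
  imp <- attr(x, "imputed")
  if (length(imp) > 0L)
    cat("  imputed-as-missing genes: ", paste(imp, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
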