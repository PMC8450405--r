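#' Median-based fold change between two cohorts
#'
#' The tumor/normal effect measure: the ratio of pseudocounted medians,
#' `fc = (median(tumor) + pseudocount) / (median(normal) + pseudocount)`.
#' The pseudocount (default 1) keeps the ratio finite for unexpressed genes
#' but attenuates fold changes of low-abundance genes, so the raw median
#' ratio is reported alongside (`fc_raw`, `Inf` or `NaN` when the normal
#' median is 0).
#'
#' @param tumor_values,normal_values Non-empty numeric TPM vectors.
#' @param pseudocount Added to both medians before taking the ratio.
#' @return List with `median_tumor`, `median_normal`, `fc`, `fc_raw`,
#'   `n_tumor`, `n_normal`.
#' @examples
#' median_fold_change(c(5, 5, 5), c(1, 1, 1))$fc  # 3
#' @export
median_fold_change <- function(tumor_values, normal_values, pseudocount = 1) {
  if (length(tumor_values) == 0L || length(normal_values) == 0L)
    stop("empty value vector")
  mt <- median(tumor_values)
  mn <- median(normal_values)
  list(median_tumor = mt, median_normal = mn,
       fc = (mt + pseudocount) / (mn + pseudocount),
       fc_raw = mt / mn,
       n_tumor = length(tumor_values), n_normal = length(normal_values))
}

#' Classify a fold change as up, down, or unchanged
#'
#' Strict thresholds: `UP` iff `fc > up`, `DOWN` iff `fc < down`, else
#' `UNCHANGED`. The defaults (up 1.5, down 1/1.5 = 0.667 at display
#' precision) are exact reciprocals, so classification is antisymmetric
#' under swapping the cohorts (`fc -> 1/fc` maps UP to DOWN).
#'
#' @param fc Positive fold change(s).
#' @param up Upper threshold (strict).
#' @param down Lower threshold (strict); default `1/up`.
#' @return Character vector in `{"UP", "DOWN", "UNCHANGED"}`.
#' @examples
#' classify_direction(c(3, 1.5, 0.5))  # "UP" "UNCHANGED" "DOWN"
#' @export
classify_direction <- function(fc, up = 1.5, down = 1 / up) {
  if (any(fc <= 0, na.rm = TRUE)) stop("fold changes must be positive")
  ifelse(fc > up, "UP", ifelse(fc < down, "DOWN", "UNCHANGED"))
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test of location shift between two independent samples.
#' The p-value is exact -- from the null distribution of the
#' Mann-Whitney U via [stats::pwilcox()] when the pooled sample is tie-free
#' and both arms have at most 25 observations, or by full enumeration of
#' group-label assignments for small tied layouts -- and otherwise uses the
#' normal approximation with tie correction and continuity correction.
#'
#' Although tumor/normal comparisons are often described with a
#' matched-pairs test, unequal cohort sizes make pairing impossible; this
#' unpaired test is the default throughout, with [rank_test_paired()]
#' available for genuinely paired designs.
#'
#' @param a,b Numeric vectors, at least 3 observations each.
#' @return List with `statistic` (U for sample `a`), `p_value`, and
#'   `method` (`"exact"`, `"enumeration"`, or `"normal_approx"`).
#' @examples
#' rank_test(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
rank_test <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L)
    stop("rank_test needs at least 3 observations per arm")
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(pooled) > 0L

  if (!ties && m <= 25L && n <= 25L) {
    p_le <- stats::pwilcox(u, m, n)
    p_ge <- 1 - stats::pwilcox(u - 1, m, n)
    return(list(statistic = u, p_value = min(1, 2 * min(p_le, p_ge)),
                method = "exact"))
  }
  if (choose(m + n, m) <= 20000) {
    us <- u_null_distribution(r, m)
    eps <- 1e-9
    p_le <- mean(us <= u + eps)
    p_ge <- mean(us >= u - eps)
    return(list(statistic = u, p_value = min(1, 2 * min(p_le, p_ge)),
                method = "enumeration"))
  }
  mu <- m * n / 2
  nt <- table(pooled)
  N <- m + n
  sigma <- sqrt(m * n / 12 * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1))))
  z <- u - mu
  z <- z - sign(z) * 0.5  # continuity correction
  p <- if (sigma == 0) 1 else min(1, 2 * stats::pnorm(-abs(z) / sigma))
  list(statistic = u, p_value = p, method = "normal_approx")
}

# Null distribution of U over all assignments of m pooled ranks to group a.
u_null_distribution <- function(pooled_ranks, m) {
  idx <- utils::combn(length(pooled_ranks), m)
  colSums(matrix(pooled_ranks[idx], nrow = m)) - m * (m + 1) / 2
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for equal-length paired samples. Zero
#' differences are dropped (standard practice); the p-value is exact via
#' [stats::psignrank()] for tie-free absolute differences with at most 25
#' informative pairs, by enumeration of sign assignments for small tied
#' layouts, and a tie-corrected normal approximation otherwise.
#'
#' @param a,b Numeric vectors of equal length (pairs).
#' @return List with `statistic` (V, sum of positive-difference ranks),
#'   `p_value`, `n_used` (pairs after dropping zero differences), `method`.
#' @export
rank_test_paired <- function(a, b) {
  if (length(a) != length(b)) stop("paired test needs equal-length vectors")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) return(list(statistic = 0, p_value = 1, n_used = 0L,
                          method = "degenerate"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= 25L) {
    p_le <- stats::psignrank(v, n)
    p_ge <- 1 - stats::psignrank(v - 1, n)
    return(list(statistic = v, p_value = min(1, 2 * min(p_le, p_ge)),
                n_used = n, method = "exact"))
  }
  if (n <= 14L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% r)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(vs <= v + eps), mean(vs >= v - eps)))
    return(list(statistic = v, p_value = p, n_used = n,
                method = "enumeration"))
  }
  mu <- n * (n + 1) / 4
  tt <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48)
  z <- v - mu
  z <- z - sign(z) * 0.5
  p <- if (sigma == 0) 1 else min(1, 2 * stats::pnorm(-abs(z) / sigma))
  list(statistic = v, p_value = p, n_used = n, method = "normal_approx")
}

#' Compare tumor and normal cohorts at gene and reaction level
#'
#' The tumor-vs-normal engine: harmonizes both cohorts against the
#' knowledge base, computes per-gene median fold changes
#' (`(median TPM + 1) / (median TPM + 1)`), classifies each as
#' UP (> 1.5), DOWN (< 0.667) or UNCHANGED, attaches a two-sided rank-sum
#' p-value, and produces one record per KB reaction by first mapping each
#' sample to reaction activities and then taking cohort medians
#' (aggregate-then-median; per-sample mapping mirrors feeding each sample's
#' TPM through the pathway map). The alternative median-then-aggregate
#' ordering is available for sensitivity analysis; it has no per-sample
#' activity values, so its reaction records carry `p_value = NA`.
#'
#' @param kb A `gag_kb` object.
#' @param tumor,normal `gag_expr` matrices (need not be pre-harmonized).
#' @param pseudocount Median pseudocount, default 1.
#' @param up,down Classification thresholds (strict); defaults 1.5 and
#'   1/1.5.
#' @param missing_policy Passed to [reaction_activity()].
#' @param reaction_order `"aggregate_then_median"` (default) or
#'   `"median_then_aggregate"`.
#' @param extra_genes Pass-through gene-level records for genes outside the
#'   KB (e.g. proteoglycan core proteins): a character vector of symbols,
#'   or `"shared"` for every non-KB gene present in both cohorts. Default
#'   none.
#' @param bh Add a Benjamini-Hochberg adjusted p-value column (`p_adj`,
#'   adjusted within gene and reaction levels separately). Off by default:
#'   the classification contract is on raw fold changes and raw p-values.
#' @return A data frame of class `gag_comparison` with columns `target_id`,
#'   `level`, `category`, `median_tumor`, `median_normal`, `fc`, `fc_raw`,
#'   `direction`, `p_value`, `n_tumor`, `n_normal` and attributes
#'   `thresholds` and `alpha_display` (0.0001, the significance level used
#'   when annotating figures).
#' @export
compare_cohorts <- function(kb, tumor, normal, pseudocount = 1,
                            up = 1.5, down = 1 / up,
                            missing_policy = c("STRICT", "PERMISSIVE"),
                            reaction_order = c("aggregate_then_median",
                                               "median_then_aggregate"),
                            extra_genes = NULL, bh = FALSE) {
  missing_policy <- match.arg(missing_policy)
  reaction_order <- match.arg(reaction_order)
  stopifnot(inherits(kb, "gag_kb"))
  ht <- harmonize_symbols(tumor, kb)
  hn <- harmonize_symbols(normal, kb)
  tm <- ht$matrix; nm <- hn$matrix
  kb_syms <- kb_genes(kb)
  shared_kb <- intersect(intersect(kb_syms, rownames(tm)), rownames(nm))
  if (length(shared_kb) == 0L)
    stop("no KB gene is present in both cohorts; check gene symbols")
  if (missing_policy == "STRICT") {
    absent <- setdiff(kb_syms, shared_kb)
    if (length(absent) > 0L)
      stop("KB genes absent from a cohort: ", paste(absent, collapse = ", "))
  }

  gene_targets <- shared_kb
  if (!is.null(extra_genes)) {
    extras <- if (identical(extra_genes, "shared"))
      setdiff(intersect(rownames(tm), rownames(nm)), kb_syms)
    else setdiff(extra_genes, kb_syms)
    missing_extras <- setdiff(extras, intersect(rownames(tm), rownames(nm)))
    if (length(missing_extras) > 0L)
      stop("requested extra genes absent from a cohort: ",
           paste(missing_extras, collapse = ", "))
    gene_targets <- c(gene_targets, extras)
  }

  one_record <- function(id, level, category, tv, nv, with_p = TRUE) {
    f <- median_fold_change(tv, nv, pseudocount = pseudocount)
    p <- if (with_p) rank_test(tv, nv)$p_value else NA_real_
    data.frame(target_id = id, level = level, category = category,
               median_tumor = f$median_tumor, median_normal = f$median_normal,
               fc = f$fc, fc_raw = f$fc_raw,
               direction = classify_direction(f$fc, up = up, down = down),
               p_value = p, n_tumor = f$n_tumor, n_normal = f$n_normal,
               stringsAsFactors = FALSE)
  }

  gene_cat <- gene_category_map(kb)
  gene_rec <- lapply(gene_targets, function(g) {
    one_record(g, "gene",
               if (g %in% names(gene_cat)) gene_cat[[g]] else NA_character_,
               unclass(tm)[g, ], unclass(nm)[g, ])
  })

  if (reaction_order == "aggregate_then_median") {
    at <- reaction_activity(kb, tm, missing_policy = missing_policy)
    an <- reaction_activity(kb, nm, missing_policy = missing_policy)
    rx_rec <- lapply(kb_reaction_ids(kb), function(id) {
      one_record(id, "reaction", kb$reactions[[id]]$category,
                 unclass(at)[id, ], unclass(an)[id, ])
    })
  } else {
    med_t <- apply(unclass(tm)[shared_kb, , drop = FALSE], 1, median)
    med_n <- apply(unclass(nm)[shared_kb, , drop = FALSE], 1, median)
    mk <- function(v, label) expression_matrix(
      matrix(v, ncol = 1, dimnames = list(names(v), label)))
    at <- reaction_activity(kb, mk(med_t, "tumor_median"),
                            missing_policy = missing_policy)
    an <- reaction_activity(kb, mk(med_n, "normal_median"),
                            missing_policy = missing_policy)
    rx_rec <- lapply(kb_reaction_ids(kb), function(id) {
      rec <- one_record(id, "reaction", kb$reactions[[id]]$category,
                        unclass(at)[id, 1], unclass(an)[id, 1],
                        with_p = FALSE)
      rec$n_tumor <- ncol(tm); rec$n_normal <- ncol(nm)
      rec
    })
  }

  records <- do.call(rbind, c(gene_rec, rx_rec))
  if (isTRUE(bh)) {
    records$p_adj <- NA_real_
    for (lev in unique(records$level)) {
      i <- records$level == lev & !is.na(records$p_value)
      records$p_adj[i] <- stats::p.adjust(records$p_value[i], method = "BH")
    }
  }
  structure(records,
            thresholds = c(up = up, down = down),
            pseudocount = pseudocount,
            alpha_display = 1e-4,
            reaction_order = reaction_order,
            class = c("gag_comparison", "data.frame"))
}

# Gene -> category lookup (reaction genes get their reaction's category,
# auxiliary genes their role).
gene_category_map <- function(kb) {
  out <- list()
  for (r in kb$reactions) for (g in r$genes) {
    if (is.null(out[[g]])) out[[g]] <- r$category
  }
  for (a in kb$auxiliary) for (g in a$members) {
    if (is.null(out[[g]])) out[[g]] <- a$role
  }
  out
}

#' Write a comparison result to TSV
#'
#' @param comparison A `gag_comparison` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  write.table(as.data.frame(comparison), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
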