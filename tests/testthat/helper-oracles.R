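# Independent oracles, deliberately written along different routes than the
# package implementation.

# Brute-force reaction activity: explicit loops over every gene of every
# group, scanning for the extremum with first-listed tie-break.
brute_force_activity <- function(kb, tpm) {
  ids <- kb_reaction_ids(kb)
  act <- matrix(NA_real_, length(ids), ncol(tpm),
                dimnames = list(ids, colnames(tpm)))
  prov <- matrix(NA_character_, length(ids), ncol(tpm),
                 dimnames = list(ids, colnames(tpm)))
  for (id in ids) {
    info <- genes_for_reaction(kb, id)
    for (j in seq_len(ncol(tpm))) {
      best_val <- NA_real_
      best_gene <- NA_character_
      for (g in info$members) {
        v <- tpm[g, j]
        take <- if (is.na(best_val)) TRUE
        else if (info$semantics == "ALTERNATIVES") v > best_val
        else v < best_val
        if (take) {
          best_val <- v
          best_gene <- g
        }
      }
      act[id, j] <- best_val
      prov[id, j] <- best_gene
    }
  }
  list(activity = act, provenance = prov)
}

# Exact two-sided Mann-Whitney p by enumerating group assignments and
# counting (a > b) pairs directly (no ranks).
enumerate_ranksum_p <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  u_of <- function(av, bv) {
    u <- 0
    for (x in av) for (y in bv) {
      if (x > y) u <- u + 1 else if (x == y) u <- u + 0.5
    }
    u
  }
  u_obs <- u_of(a, b)
  picks <- combn(length(pooled), m)
  us <- apply(picks, 2, function(i) u_of(pooled[i], pooled[-i]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Pearson r via the raw-moment covariance formula.
closed_form_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# A small random TPM matrix over the KB gene set.
random_kb_tpm <- function(kb, n_samples = 10, with_ties = FALSE) {
  genes <- kb_genes(kb)
  vals <- if (with_ties)
    matrix(sample(0:20, length(genes) * n_samples, replace = TRUE),
           nrow = length(genes))
  else
    matrix(round(2^runif(length(genes) * n_samples, 0, 10), 3),
           nrow = length(genes))
  dimnames(vals) <- list(genes, paste0("s", seq_len(n_samples)))
  expression_matrix(vals)
}

# Write a tiny gene-by-sample TSV and return its path.
write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
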