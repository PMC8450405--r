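KB_CATEGORIES <- c("BACKBONE", "HS_SULFATION", "CSDS_SULFATION", "KS", "HA")
KB_SEMANTICS <- c("ALTERNATIVES", "COMPLEX")
KB_AUX_ROLES <- c("TRANSPORTER", "PAPS_SYNTHESIS", "NUCLEOTIDE_CATABOLISM",
                  "REGULATOR")

# Inventory the packaged knowledge base must satisfy: 66 distinct genes over
# 29 reactions in 5 categories; backbone has 12 numbered steps and CS/DS
# sulfation 5.
KB_EXPECTED <- list(n_genes = 66L, n_reactions = 29L, n_categories = 5L,
                    n_backbone = 12L, n_csds = 5L)

#' Load a GAG reaction-gene knowledge base
#'
#' Reads a knowledge base (KB) file describing the enzymatic reactions of
#' glycosaminoglycan (GAG) biosynthesis and catabolism: which genes catalyze
#' each reaction, whether alternative isozymes (aggregate by maximum) or an
#' obligate enzyme complex (aggregate by minimum) carry the activity, the
#' pathway graph between reactions, and auxiliary gene sets (nucleotide-sugar
#' and PAPS transporters, PAPS synthesis, nucleotide catabolism, regulators).
#'
#' The packaged default KB (`"gag-kb-v1"`) covers 29 reactions in five
#' categories -- GAG backbone assembly, heparan sulfate sulfation,
#' chondroitin/dermatan sulfate sulfation, keratan sulfate, and hyaluronan
#' synthesis/catabolism -- spanning 66 distinct human genes.
#'
#' @param path Path to a KB JSON file. When `NULL` (default) the packaged
#'   KB is loaded.
#' @return An object of class `gag_kb`: a list with elements `version`,
#'   `reactions` (list of reaction records), `auxiliary` (list of role sets)
#'   and `aliases` (named character vector mapping alternative symbols to
#'   canonical ones).
#' @examples
#' kb <- load_kb()
#' length(kb$reactions)        # 29
#' length(kb_genes(kb))        # 66
#' @export
load_kb <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gag_kb_v1.json", package = "gagmap",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("knowledge base file not found: ", path)
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("failed to parse knowledge base file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  kb <- new_kb(raw, source = path)
  viol <- validate_kb(kb, expect_inventory = FALSE)
  structural <- viol[viol$rule %in% c("reaction_id_unique", "field_missing",
                                      "bad_enum", "empty_group"), , drop = FALSE]
  if (nrow(structural) > 0L) {
    stop("invalid knowledge base '", path, "':\n  ",
         paste(structural$message, collapse = "\n  "), call. = FALSE)
  }
  ref <- viol[viol$rule == "unknown_successor", , drop = FALSE]
  if (nrow(ref) > 0L) {
    stop("invalid knowledge base '", path, "':\n  ",
         paste(ref$message, collapse = "\n  "), call. = FALSE)
  }
  kb
}

# Build a gag_kb from parsed JSON, checking field presence only.
new_kb <- function(raw, source = NA_character_) {
  for (field in c("version", "reactions", "auxiliary")) {
    if (is.null(raw[[field]])) {
      stop("knowledge base is missing required field '", field, "'",
           call. = FALSE)
    }
  }
  reactions <- lapply(raw$reactions, function(r) {
    for (field in c("reaction_id", "display_number", "category", "semantics",
                    "genes")) {
      if (is.null(r[[field]])) {
        stop("reaction record ",
             if (!is.null(r$reaction_id)) paste0("'", r$reaction_id, "' "),
             "is missing field '", field, "'", call. = FALSE)
      }
    }
    list(
      reaction_id = as.character(r$reaction_id),
      display_number = as.integer(r$display_number),
      category = as.character(r$category),
      semantics = as.character(r$semantics),
      genes = vapply(r$genes, as.character, character(1)),
      substrate = if (is.null(r$substrate)) "" else as.character(r$substrate),
      product = if (is.null(r$product)) "" else as.character(r$product),
      successors = vapply(r$successors, as.character, character(1))
    )
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "reaction_id")
  auxiliary <- lapply(raw$auxiliary, function(a) {
    list(role = as.character(a$role),
         members = vapply(a$members, as.character, character(1)))
  })
  aliases <- if (is.null(raw$aliases)) character(0) else
    vapply(raw$aliases, as.character, character(1))
  structure(
    list(version = as.character(raw$version), reactions = reactions,
         auxiliary = auxiliary, aliases = aliases, source = source),
    class = "gag_kb"
  )
}

#' Validate a knowledge base against its structural invariants
#'
#' Checks referential integrity (unique reaction ids, successors that exist,
#' an acyclic pathway graph per category), gene-group sanity (non-empty
#' groups, no duplicate members, valid semantics), alias consistency, and --
#' by default -- the packaged inventory: 66 distinct genes, 29 reactions,
#' 5 categories, 12 backbone steps and 5 CS/DS sulfation steps.
#'
#' A gene must belong to exactly one reaction, with one deliberate exception:
#' an obligate complex may catalyze several consecutive activities (the
#' EXT1/EXT2 heparan sulfate polymerase catalyzes both polymerization steps),
#' so duplicated membership is allowed only when the duplicated reactions
#' carry an identical gene group in the same category.
#'
#' @param kb A `gag_kb` object.
#' @param expect_inventory Check the packaged gene/reaction/category counts
#'   (default `TRUE`). Set `FALSE` for user-modified KBs of different scope.
#' @return A data frame of violations with columns `rule`, `id`, `message`;
#'   zero rows means the KB is valid. Violations are data, not errors.
#' @examples
#' report <- validate_kb(load_kb())
#' nrow(report)  # 0
#' @export
validate_kb <- function(kb, expect_inventory = TRUE) {
  stopifnot(inherits(kb, "gag_kb"))
  v <- list()
  add <- function(rule, id, message) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, id = id,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  rx <- kb$reactions
  ids <- vapply(rx, `[[`, character(1), "reaction_id")
  dup_ids <- unique(ids[duplicated(ids)])
  for (d in dup_ids) add("reaction_id_unique", d,
                         paste0("duplicate reaction_id '", d, "'"))

  for (r in rx) {
    if (!r$category %in% KB_CATEGORIES)
      add("bad_enum", r$reaction_id,
          paste0("reaction '", r$reaction_id, "' has unknown category '",
                 r$category, "'"))
    if (!r$semantics %in% KB_SEMANTICS)
      add("bad_enum", r$reaction_id,
          paste0("reaction '", r$reaction_id, "' has unknown semantics '",
                 r$semantics, "'"))
    if (length(r$genes) == 0L)
      add("empty_group", r$reaction_id,
          paste0("reaction '", r$reaction_id, "' has an empty gene group"))
    if (anyDuplicated(r$genes))
      add("duplicate_member", r$reaction_id,
          paste0("reaction '", r$reaction_id,
                 "' lists a gene more than once"))
    for (s in r$successors) {
      if (!s %in% ids)
        add("unknown_successor", r$reaction_id,
            paste0("reaction '", r$reaction_id,
                   "' references unknown successor '", s, "'"))
    }
  }

  # acyclicity per category (successor edges)
  for (cat in unique(vapply(rx, `[[`, character(1), "category"))) {
    sub <- rx[vapply(rx, function(r) r$category == cat, logical(1))]
    if (has_cycle(sub)) {
      add("cyclic_graph", cat,
          paste0("pathway graph for category '", cat, "' contains a cycle"))
    }
  }

  # gene-to-reaction assignment: exactly one reaction per gene, except
  # identical gene groups within one category (multi-activity complex)
  occ <- list()
  for (r in rx) for (g in r$genes) occ[[g]] <- c(occ[[g]], r$reaction_id)
  for (g in names(occ)) {
    if (length(occ[[g]]) > 1L) {
      groups <- lapply(occ[[g]], function(id)
        list(genes = rx[[id]]$genes, category = rx[[id]]$category))
      identical_groups <- all(vapply(groups, function(grp)
        identical(grp, groups[[1L]]), logical(1)))
      if (!identical_groups) {
        add("gene_multiple_reactions", g,
            paste0("gene '", g, "' appears in reactions with differing ",
                   "groups: ", paste(occ[[g]], collapse = ", ")))
      }
    }
  }

  # auxiliary sets: known roles, members disjoint from reaction genes
  reaction_genes <- unique(unlist(lapply(rx, `[[`, "genes")))
  aux_genes <- character(0)
  for (a in kb$auxiliary) {
    if (!a$role %in% KB_AUX_ROLES)
      add("bad_enum", a$role, paste0("unknown auxiliary role '", a$role, "'"))
    if (anyDuplicated(a$members))
      add("duplicate_member", a$role,
          paste0("auxiliary set '", a$role, "' lists a gene more than once"))
    overlap <- intersect(a$members, reaction_genes)
    for (g in overlap)
      add("aux_overlaps_reaction", g,
          paste0("auxiliary gene '", g, "' also appears in a reaction step"))
    dup_aux <- intersect(a$members, aux_genes)
    for (g in dup_aux)
      add("duplicate_symbol", g,
          paste0("gene '", g, "' appears in two auxiliary sets"))
    aux_genes <- c(aux_genes, a$members)
  }

  # aliases resolve to exactly one shipped canonical symbol
  all_genes <- unique(c(reaction_genes, aux_genes))
  for (al in names(kb$aliases)) {
    if (!kb$aliases[[al]] %in% all_genes)
      add("alias_unknown_target", al,
          paste0("alias '", al, "' maps to unknown symbol '",
                 kb$aliases[[al]], "'"))
    if (al %in% all_genes)
      add("alias_shadows_symbol", al,
          paste0("alias '", al, "' is itself a canonical symbol"))
  }

  if (isTRUE(expect_inventory)) {
    cats <- unique(vapply(rx, `[[`, character(1), "category"))
    if (length(rx) != KB_EXPECTED$n_reactions)
      add("inventory", "reactions",
          paste0("reaction count ", length(rx), " != ",
                 KB_EXPECTED$n_reactions))
    if (length(all_genes) != KB_EXPECTED$n_genes)
      add("inventory", "genes",
          paste0("distinct gene count ", length(all_genes), " != ",
                 KB_EXPECTED$n_genes))
    if (length(cats) != KB_EXPECTED$n_categories)
      add("inventory", "categories",
          paste0("category count ", length(cats), " != ",
                 KB_EXPECTED$n_categories))
    n_bb <- sum(vapply(rx, function(r) r$category == "BACKBONE", logical(1)))
    if (n_bb != KB_EXPECTED$n_backbone)
      add("inventory", "BACKBONE",
          paste0("backbone step count ", n_bb, " != ",
                 KB_EXPECTED$n_backbone))
    n_csds <- sum(vapply(rx, function(r) r$category == "CSDS_SULFATION",
                         logical(1)))
    if (n_csds != KB_EXPECTED$n_csds)
      add("inventory", "CSDS_SULFATION",
          paste0("CS/DS sulfation step count ", n_csds, " != ",
                 KB_EXPECTED$n_csds))
  }

  if (length(v) == 0L) {
    return(data.frame(rule = character(0), id = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

# DFS cycle detection over successor edges restricted to the given reactions.
has_cycle <- function(reactions) {
  ids <- vapply(reactions, `[[`, character(1), "reaction_id")
  adj <- lapply(reactions, function(r) intersect(r$successors, ids))
  names(adj) <- ids
  state <- setNames(rep(0L, length(ids)), ids)  # 0 new, 1 active, 2 done
  visit <- function(id) {
    if (state[[id]] == 1L) return(TRUE)
    if (state[[id]] == 2L) return(FALSE)
    state[[id]] <<- 1L
    for (s in adj[[id]]) if (visit(s)) return(TRUE)
    state[[id]] <<- 2L
    FALSE
  }
  for (id in ids) if (visit(id)) return(TRUE)
  FALSE
}

#' Look up the gene group catalyzing a reaction
#'
#' @param kb A `gag_kb` object.
#' @param reaction_id Reaction identifier, e.g. `"backbone.01.xyl_transfer"`.
#' @return A list with `members` (gene symbols in KB order) and `semantics`
#'   (`"ALTERNATIVES"` for interchangeable isozymes, `"COMPLEX"` for obligate
#'   complex subunits).
#' @examples
#' genes_for_reaction(load_kb(), "backbone.08.hs_glca_polymerization")
#' @export
genes_for_reaction <- function(kb, reaction_id) {
  stopifnot(inherits(kb, "gag_kb"))
  r <- kb$reactions[[reaction_id]]
  if (is.null(r)) stop("unknown reaction_id: '", reaction_id, "'")
  list(members = r$genes, semantics = r$semantics)
}

#' Gene symbols in a knowledge base
#'
#' @param kb A `gag_kb` object.
#' @param include_auxiliary Include transporter/PAPS/regulator auxiliary
#'   genes in addition to reaction genes (default `TRUE`).
#' @return Character vector of distinct canonical gene symbols, reaction
#'   genes first in pathway order.
#' @export
kb_genes <- function(kb, include_auxiliary = TRUE) {
  stopifnot(inherits(kb, "gag_kb"))
  g <- unlist(lapply(kb$reactions, `[[`, "genes"), use.names = FALSE)
  if (include_auxiliary) {
    g <- c(g, unlist(lapply(kb$auxiliary, `[[`, "members"), use.names = FALSE))
  }
  unique(g)
}

#' Reaction identifiers, optionally restricted to one category
#'
#' @param kb A `gag_kb` object.
#' @param category Optional category name (one of `"BACKBONE"`,
#'   `"HS_SULFATION"`, `"CSDS_SULFATION"`, `"KS"`, `"HA"`).
#' @return Character vector of reaction ids in KB order.
#' @export
kb_reaction_ids <- function(kb, category = NULL) {
  stopifnot(inherits(kb, "gag_kb"))
  ids <- names(kb$reactions)
  if (!is.null(category)) {
    category <- match.arg(category, KB_CATEGORIES)
    keep <- vapply(kb$reactions, function(r) r$category == category,
                   logical(1))
    ids <- ids[keep]
  }
  ids
}

#' Resolve gene symbols through the KB alias table
#'
#' Symbols are upper-cased and alternative symbols (e.g. `BPNT2`, `CEMIP2`,
#' `HYAL5`) mapped to their canonical KB symbol.
#'
#' @param kb A `gag_kb` object.
#' @param symbols Character vector of input symbols.
#' @return Character vector of canonical symbols, same length as input.
#' @export
resolve_alias <- function(kb, symbols) {
  stopifnot(inherits(kb, "gag_kb"))
  up <- toupper(symbols)
  hit <- up %in% names(kb$aliases)
  up[hit] <- unname(kb$aliases[up[hit]])
  up
}

#' Serialize a knowledge base to JSON
#'
#' `write_kb()` followed by [load_kb()] round-trips to an identical KB.
#'
#' @param kb A `gag_kb` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  stopifnot(inherits(kb, "gag_kb"))
  out <- list(
    version = jsonlite::unbox(kb$version),
    reactions = lapply(unname(kb$reactions), function(r) list(
      reaction_id = jsonlite::unbox(r$reaction_id),
      display_number = jsonlite::unbox(r$display_number),
      category = jsonlite::unbox(r$category),
      semantics = jsonlite::unbox(r$semantics),
      genes = as.list(r$genes),
      substrate = jsonlite::unbox(r$substrate),
      product = jsonlite::unbox(r$product),
      successors = as.list(r$successors)
    )),
    auxiliary = lapply(kb$auxiliary, function(a) list(
      role = jsonlite::unbox(a$role),
      members = as.list(a$members)
    )),
    aliases = as.list(kb$aliases)
  )
  jsonlite::write_json(out, path, pretty = TRUE, auto_unbox = FALSE)
  invisible(path)
}

#' Flatten a knowledge base to a long-format table
#'
#' One row per (reaction, gene) pair, convenient for diffing KB versions.
#'
#' @param kb A `gag_kb` object.
#' @return Data frame with columns `reaction_id`, `display_number`,
#'   `category`, `semantics`, `gene_symbol`.
#' @export
kb_to_table <- function(kb) {
  stopifnot(inherits(kb, "gag_kb"))
  rows <- lapply(unname(kb$reactions), function(r) {
    data.frame(reaction_id = r$reaction_id,
               display_number = r$display_number,
               category = r$category,
               semantics = r$semantics,
               gene_symbol = r$genes,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.gag_kb <- function(x, ...) {
  cats <- table(vapply(x$reactions, `[[`, character(1), "category"))
  cat("GAG knowledge base '", x$version, "'\n", sep = "")
  cat("  reactions: ", length(x$reactions), " in ", length(cats),
      " categories (", paste(names(cats), cats, sep = ": ", collapse = ", "),
      ")\n", sep = "")
  cat("  genes: ", length(kb_genes(x)), " distinct (",
      length(kb_genes(x, include_auxiliary = FALSE)), " in reactions)\n",
      sep = "")
  cat("  aliases: ", length(x$aliases), "\n", sep = "")
  invisible(x)
}
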