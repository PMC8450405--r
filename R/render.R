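GAG_COLOR_UP <- "#E8A0BF"      # pink: reaction increased in tumor
GAG_COLOR_DOWN <- "#7FBF7F"    # green: reaction decreased in tumor
GAG_COLOR_NEUTRAL <- "#888888"

#' Render a pathway category diagram as SVG
#'
#' Draws the reaction graph of one GAG category as a layered left-to-right
#' diagram: nodes are glycan intermediates (the KB substrate/product
#' labels), edges are reactions annotated with their display step number
#' and gene symbols, and each edge is colored by the comparison outcome of
#' its reaction -- pink for UP, green for DOWN, gray for UNCHANGED. The
#' layout is purely a function of the KB graph (longest-path layering,
#' label-sorted within layers), so output is byte-identical across runs.
#'
#' @param kb A `gag_kb` object.
#' @param comparison A `gag_comparison` containing a reaction-level record
#'   for every reaction in the category (see [compare_cohorts()]).
#' @param category One of `"BACKBONE"`, `"HS_SULFATION"`,
#'   `"CSDS_SULFATION"`, `"KS"`, `"HA"`.
#' @param file Optional path; when given the SVG is written there.
#' @param colors Named vector overriding the `up`/`down`/`neutral` hexes.
#' @return The SVG document as a single character string (invisibly when
#'   `file` is given).
#' @export
render_pathway <- function(kb, comparison, category, file = NULL,
                           colors = c(up = GAG_COLOR_UP,
                                      down = GAG_COLOR_DOWN,
                                      neutral = GAG_COLOR_NEUTRAL)) {
  stopifnot(inherits(kb, "gag_kb"), inherits(comparison, "gag_comparison"))
  category <- match.arg(category, KB_CATEGORIES)
  ids <- kb_reaction_ids(kb, category = category)
  rx <- kb$reactions[ids]
  cmp <- as.data.frame(comparison)
  cmp <- cmp[cmp$level == "reaction", , drop = FALSE]
  missing <- setdiff(ids, cmp$target_id)
  if (length(missing) > 0L)
    stop("comparison lacks reaction records: ",
         paste(missing, collapse = ", "))
  dir <- setNames(cmp$direction, cmp$target_id)[ids]

  nodes <- unique(unlist(lapply(rx, function(r) c(r$substrate, r$product))))
  edges <- lapply(rx, function(r) c(from = r$substrate, to = r$product))

  # longest-path layering over the intermediate graph
  depth <- setNames(rep(0L, length(nodes)), nodes)
  for (i in seq_len(length(nodes) + 1L)) {
    changed <- FALSE
    for (e in edges) {
      want <- depth[[e[["from"]]]] + 1L
      if (depth[[e[["to"]]]] < want) {
        depth[[e[["to"]]]] <- want
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  dx <- 230; dy <- 95; x0 <- 120; y0 <- 70
  pos <- list()
  for (d in sort(unique(depth))) {
    layer <- sort(names(depth)[depth == d])
    for (i in seq_along(layer)) {
      pos[[layer[i]]] <- c(x = x0 + d * dx, y = y0 + (i - 1L) * dy)
    }
  }
  width <- x0 + (max(depth) + 1L) * dx
  height <- y0 + max(vapply(split(depth, depth), length, integer(1))) * dy

  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  svg <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    '<defs>',
    paste0('<marker id="arrow-', names(colors),
           '" viewBox="0 0 10 10" refX="9" refY="5" markerWidth="7" ',
           'markerHeight="7" orient="auto-start-reverse">',
           '<path d="M 0 0 L 10 5 L 0 10 z" fill="', unname(colors),
           '"/></marker>'),
    '</defs>',
    sprintf('<text x="%d" y="28" font-size="18" font-family="sans-serif" font-weight="bold">%s</text>',
            20, esc(category))
  )
  for (i in seq_along(rx)) {
    r <- rx[[i]]
    cls <- switch(dir[[r$reaction_id]], UP = "up", DOWN = "down", "neutral")
    col <- unname(colors[[cls]])
    p1 <- pos[[r$substrate]]; p2 <- pos[[r$product]]
    mx <- (p1[["x"]] + p2[["x"]]) / 2
    my <- (p1[["y"]] + p2[["y"]]) / 2
    svg <- c(svg,
      sprintf('<line class="reaction %s" data-reaction="%s" x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="%s" stroke-width="2.5" marker-end="url(#arrow-%s)"/>',
              cls, esc(r$reaction_id), p1[["x"]], p1[["y"]], p2[["x"]],
              p2[["y"]], col, cls),
      sprintf('<text x="%.1f" y="%.1f" font-size="11" font-family="sans-serif" fill="%s" text-anchor="middle">%d: %s</text>',
              mx, my - 6, col, r$display_number,
              esc(paste(r$genes, collapse = "/"))))
  }
  for (nd in names(pos)) {
    p <- pos[[nd]]
    svg <- c(svg,
      sprintf('<circle cx="%.1f" cy="%.1f" r="4" fill="#333333"/>',
              p[["x"]], p[["y"]]),
      sprintf('<text x="%.1f" y="%.1f" font-size="10" font-family="sans-serif" fill="#333333" text-anchor="middle">%s</text>',
              p[["x"]], p[["y"]] + 18, esc(nd)))
  }
  svg <- c(svg, '</svg>')
  doc <- paste(svg, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

#' Long-format log2(TPM + 1) table for boxplots
#'
#' One row per (gene, sample) with the transformed expression value and the
#' sample's group label -- the shape expected by ggplot-style boxplot code.
#'
#' @param m A `gag_expr` matrix.
#' @param genes Character vector of genes to include.
#' @return Data frame with columns `gene`, `sample`, `group`,
#'   `log2_tpm_plus1`.
#' @export
boxplot_table <- function(m, genes) {
  stopifnot(inherits(m, "gag_expr"))
  unknown <- setdiff(genes, rownames(m))
  if (length(unknown) > 0L)
    stop("unknown genes: ", paste(unknown, collapse = ", "))
  groups <- sample_groups(m)
  vals <- unclass(m)[genes, , drop = FALSE]
  data.frame(
    gene = rep(genes, times = ncol(vals)),
    sample = rep(colnames(vals), each = length(genes)),
    group = rep(unname(groups), each = length(genes)),
    log2_tpm_plus1 = as.vector(log2_tpm_plus1(vals)),
    stringsAsFactors = FALSE
  )
}
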