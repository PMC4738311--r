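#' Build the condition-annotated bait-prey network
#'
#' Turns a replicate-averaged count table into directed bait-to-prey
#' edges, one per (bait, condition, prey) whose mean spectral count
#' reaches the policy threshold ("three or better" by default). Edge
#' colors encode the stimulation condition (black/green/orange for 0, 10
#' and 30 minutes of insulin under the default map); an unknown condition
#' label yields color `"unmapped"` and a message.
#'
#' @param avg Averaged-count table from [average_counts()].
#' @param policy A [quant_policy()] supplying the threshold and the
#'   condition-to-color map.
#' @return An edge tibble (`bait`, `prey`, `condition`, `mean_counts`,
#'   `color`), deterministically ordered.
#' @export
build_network <- function(avg, policy = quant_policy()) {
  keep <- avg$mean_counts >= policy$min_average_counts &
    avg$bait != avg$prey # self-loops (the bait pulling itself) carry no PPI
  edges <- avg[keep, , drop = FALSE]
  cmap <- policy$condition_colors
  color <- unname(cmap[edges$condition])
  unmapped <- is.na(color)
  if (any(unmapped)) {
    inform(sprintf(
      "condition label(s) without a color mapping: %s",
      paste(unique(edges$condition[unmapped]), collapse = ", ")
    ))
    color[unmapped] <- "unmapped"
  }
  out <- tibble(
    bait = edges$bait,
    prey = edges$prey,
    condition = edges$condition,
    mean_counts = edges$mean_counts,
    color = color
  )
  out[order(out$bait, out$condition, out$prey), ]
}

#' Export a bait-prey network
#'
#' Writes the edge list in one of three formats for network-analysis
#' software:
#' * `"sif"` — simple interaction format, one `bait interacts prey`
#'   triple per line (attributes are not representable; duplicate triples
#'   from multiple conditions are collapsed);
#' * `"tsv"` — the full edge-attribute table;
#' * `"graphml"` — GraphML with `mean_counts`, `condition` and `color` as
#'   edge attributes (directed).
#'
#' @param edges Edge tibble from [build_network()].
#' @param path Output path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, path, format = c("sif", "graphml", "tsv")) {
  format <- tryCatch(
    match.arg(format),
    error = function(e) {
      validation_error(sprintf(
        "unknown format '%s'; supported formats: sif, graphml, tsv",
        format[1]
      ))
    }
  )
  edges <- edges[order(edges$bait, edges$condition, edges$prey), ,
                 drop = FALSE]
  if (format == "tsv") {
    write_tsv_plain(edges, path)
  } else if (format == "sif") {
    triples <- if (nrow(edges) == 0) character() else
      unique(paste(edges$bait, "interacts", edges$prey, sep = "\t"))
    writeLines(sort(triples), path)
  } else {
    nodes <- sort(unique(c(edges$bait, edges$prey)))
    g <- igraph::make_empty_graph(directed = TRUE) +
      igraph::vertices(nodes)
    if (nrow(edges) > 0) {
      g <- igraph::add_edges(
        g, rbind(match(edges$bait, nodes), match(edges$prey, nodes)),
        mean_counts = edges$mean_counts,
        condition = edges$condition,
        color = edges$color
      )
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import an exported network
#'
#' Reads back a network written by [export_network()] in `"tsv"` or
#' `"graphml"` format, reproducing the edge-attribute table (SIF carries
#' no attributes and is not re-importable into edge attributes).
#'
#' @param path File path.
#' @param format `"tsv"` or `"graphml"`.
#' @return An edge tibble with the same columns as [build_network()].
#' @export
read_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- read_tsv_strict(path, c("bait", "prey", "condition",
                                   "mean_counts", "color"))
    return(as_tibble(tab))
  }
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g, names = TRUE)
  out <- tibble(
    bait = as.character(el[, 1]),
    prey = as.character(el[, 2]),
    condition = as.character(igraph::edge_attr(g, "condition") %||%
                               character(nrow(el))),
    mean_counts = as.numeric(igraph::edge_attr(g, "mean_counts") %||%
                               numeric(nrow(el))),
    color = as.character(igraph::edge_attr(g, "color") %||%
                           character(nrow(el)))
  )
  out[order(out$bait, out$condition, out$prey), ]
}
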