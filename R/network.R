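#' Assemble a bipartite miRNA-to-mRNA regulatory network
#'
#' One node per distinct miRNA and gene, one directed edge (miRNA -> gene,
#' encoding repression) per distinct confirmed pair. Nodes and edges are kept
#' in C-locale lexicographic order so every export is deterministic.
#'
#' @param confirmed A tibble with columns `mirna_id`, `gene_id` (for example
#'   `tidy()` of a [confirm_pairs()] result); duplicates are collapsed.
#' @param cancer_label Free-text label for the cohort (e.g. `"lSCC"`).
#' @return An object of class `regulatory_network` with elements
#'   `cancer_label`, `nodes` (tibble `id`, `kind`) and `edges` (tibble
#'   `mirna_id`, `gene_id`). `tidy()` returns the edges, `glance()` the
#'   summary counts.
#' @export
build_network <- function(confirmed, cancer_label = "unlabelled") {
  check_columns(confirmed, c("mirna_id", "gene_id"), "`confirmed`")
  edges <- confirmed |>
    select("mirna_id", "gene_id") |>
    distinct() |>
    arrange_c("mirna_id", "gene_id")
  nodes <- bind_rows(
    tibble(id = sort_c(unique(edges$mirna_id)), kind = "mirna"),
    tibble(id = sort_c(unique(edges$gene_id)), kind = "gene")
  )
  structure(
    list(cancer_label = cancer_label, nodes = nodes, edges = edges),
    class = "regulatory_network"
  )
}

# arrange by columns using C-locale ordering
arrange_c <- function(df, ...) {
  cols <- c(...)
  ord <- do.call(order, c(unname(as.list(df[cols])), list(method = "radix")))
  df[ord, , drop = FALSE]
}

#' Summary counts of a regulatory network
#'
#' @param net A `regulatory_network`.
#' @return A one-row tibble: `cancer_label`, `n_mirna`, `n_gene`, `n_edges`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  tibble(
    cancer_label = net$cancer_label,
    n_mirna = sum(net$nodes$kind == "mirna"),
    n_gene = sum(net$nodes$kind == "gene"),
    n_edges = nrow(net$edges)
  )
}

#' Combined summary over several per-cancer networks
#'
#' By default returns the component-wise sum of the per-network counts (the
#' convention behind published per-cohort totals, where a feature shared by
#' two cancers is counted in each). With `dedupe = TRUE` the counts are
#' computed on the union of nodes and edges instead.
#'
#' @param nets A list of `regulatory_network` objects.
#' @param dedupe Count each distinct miRNA/gene/edge once across networks?
#' @return A one-row tibble `cancer_label`, `n_mirna`, `n_gene`, `n_edges`.
#' @export
combined_summary <- function(nets, dedupe = FALSE) {
  if (length(nets) == 0) abort("`nets` must contain at least one network")
  stopifnot(all(vapply(nets, inherits, logical(1), "regulatory_network")))
  label <- paste(vapply(nets, function(x) x$cancer_label, character(1)),
                 collapse = "+")
  if (dedupe) {
    nodes <- distinct(bind_rows(lapply(nets, function(x) x$nodes)))
    edges <- distinct(bind_rows(lapply(nets, function(x) x$edges)))
    return(tibble(
      cancer_label = label,
      n_mirna = sum(nodes$kind == "mirna"),
      n_gene = sum(nodes$kind == "gene"),
      n_edges = nrow(edges)
    ))
  }
  per <- bind_rows(lapply(nets, network_summary))
  tibble(
    cancer_label = label,
    n_mirna = sum(per$n_mirna),
    n_gene = sum(per$n_gene),
    n_edges = sum(per$n_edges)
  )
}

as_igraph <- function(net) {
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, nrow(net$nodes),
                            name = net$nodes$id, kind = net$nodes$kind)
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(g, rbind(net$edges$mirna_id, net$edges$gene_id))
  }
  g
}

#' Export a regulatory network
#'
#' Writes either a GraphML document (node attribute `kind`, stable node and
#' edge order) or a two-column edge TSV. [import_network()] reconstructs an
#' identical network from either format.
#'
#' @param net A `regulatory_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  stopifnot(inherits(net, "regulatory_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    readr::write_tsv(net$edges, path)
  }
  invisible(path)
}

#' @rdname export_network
#' @param cancer_label Label for the reconstructed network.
#' @export
import_network <- function(path, format = c("graphml", "edge_tsv"),
                           cancer_label = "unlabelled") {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::ecount(g) == 0) {
      edges <- tibble(mirna_id = character(), gene_id = character())
    } else {
      el <- igraph::as_edgelist(g, names = TRUE)
      edges <- tibble(mirna_id = el[, 1], gene_id = el[, 2])
    }
  } else {
    edges <- readr::read_tsv(path, col_types = "cc")
    check_columns(edges, c("mirna_id", "gene_id"), basename(path))
  }
  build_network(edges, cancer_label = cancer_label)
}

#' @export
print.regulatory_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(
    "# regulatory_network '%s': %d miRNA(s) -> %d gene(s), %d edge(s)\n",
    s$cancer_label, s$n_mirna, s$n_gene, s$n_edges
  ))
  invisible(x)
}

#' @rdname build_network
#' @param x A `regulatory_network`.
#' @param ... Unused.
#' @method tidy regulatory_network
#' @export
tidy.regulatory_network <- function(x, ...) as_tibble(x$edges)

#' @rdname build_network
#' @method glance regulatory_network
#' @export
glance.regulatory_network <- function(x, ...) network_summary(x)

#' @export
`==.regulatory_network` <- function(e1, e2) {
  identical(e1$nodes, e2$nodes) && identical(e1$edges, e2$edges)
}

#' Plot a bipartite regulatory network
#'
#' miRNA nodes on the left, target genes on the right, one segment per
#' repressive edge.
#'
#' @param object A `regulatory_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot regulatory_network
#' @export
autoplot.regulatory_network <- function(object, ...) {
  nodes <- object$nodes |>
    group_by(.data$kind) |>
    mutate(
      x = if_else(.data$kind == "mirna", 0, 1),
      y = (row_number() - 1) / max(1, n() - 1)
    ) |>
    ungroup()
  edges <- object$edges |>
    left_join(select(filter(nodes, .data$kind == "mirna"), "id", xm = "x", ym = "y"),
              by = c(mirna_id = "id")) |>
    left_join(select(filter(nodes, .data$kind == "gene"), "id", xg = "x", yg = "y"),
              by = c(gene_id = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xm, y = .data$ym, xend = .data$xg, yend = .data$yg),
      colour = "grey60", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$kind), size = 2
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x + if_else(.data$kind == "mirna", -0.03, 0.03),
                   y = .data$y, label = .data$id,
                   hjust = if_else(.data$kind == "mirna", 1, 0)),
      size = 2.6
    ) +
    ggplot2::scale_x_continuous(limits = c(-0.6, 1.6), breaks = NULL) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(
      title = sprintf("Regulatory network: %s", object$cancer_label),
      x = NULL, y = NULL, colour = NULL
    ) +
    ggplot2::theme_minimal()
}
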