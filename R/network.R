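#' Build the weighted bipartite chemical-target network
#'
#' One directed edge per chemical x gene pair whose gene score G is present
#' and at least `z_threshold`; the edge weight is G itself (edge thickness
#' is proportional to the gene score). Chemicals form the source side,
#' genes the target side; the graph is strictly bipartite. Nodes with no
#' surviving edge are dropped unless `keep_isolated` lists them.
#'
#' @param scores Long gene-score tibble (`chemical_id`, `gene_symbol`, `G`)
#'   as produced by [gene_scores()]`$scores`.
#' @param z_threshold Minimum gene score for an edge (default 0: activity
#'   at or below cytotoxic potency).
#' @param keep_isolated Optional list with character vectors `chemicals`
#'   and/or `genes` to retain as isolated nodes.
#' @return An igraph object; vertex attribute `type` is FALSE for chemicals
#'   and TRUE for genes, `side` is `"chemical"`/`"gene"`, edge attribute
#'   `weight` carries G.
#' @export
build_network <- function(scores, z_threshold = 0, keep_isolated = NULL) {
  stopifnot(all(c("chemical_id", "gene_symbol", "G") %in% names(scores)))
  edges <- scores[!is.na(scores$G) & scores$G >= z_threshold, ]
  if (nrow(edges) == 0L) {
    warning("z_threshold excludes all edges; returning an empty network",
            call. = FALSE)
  }
  chems <- sort(unique(c(edges$chemical_id, keep_isolated$chemicals)))
  genes <- sort(unique(c(edges$gene_symbol, keep_isolated$genes)))
  clash <- intersect(chems, genes)
  if (length(clash)) {
    stop("identifier(s) used on both sides of the bipartite graph: ",
         paste(head(clash, 5), collapse = ", "), call. = FALSE)
  }
  vertices <- tibble::tibble(
    name = c(chems, genes),
    type = c(rep(FALSE, length(chems)), rep(TRUE, length(genes))),
    side = c(rep("chemical", length(chems)), rep("gene", length(genes)))
  )
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$chemical_id, to = edges$gene_symbol,
               weight = edges$G),
    directed = TRUE, vertices = as.data.frame(vertices))
  g
}

#' Annotate network nodes with mode-of-action classes and MRDT provenance
#'
#' Gene nodes receive a class label (e.g. the functional-annotation domains
#' of a mode-of-action map); genes absent from the map are labeled
#' `"unmapped"` and reported via the `unmapped_genes` graph attribute.
#' Chemical nodes optionally receive their MRDT flag source.
#'
#' @param net Bipartite igraph from [build_network()].
#' @param annotation Tibble `gene_symbol`, `class_label` (may be empty).
#' @param mrdt_flags Optional tibble `chemical_id`, `source`.
#' @return The annotated igraph.
#' @export
annotate_nodes <- function(net, annotation = NULL, mrdt_flags = NULL) {
  nm <- igraph::V(net)$name
  is_gene <- igraph::V(net)$type
  class_label <- rep(NA_character_, length(nm))
  if (is.null(annotation) || nrow(annotation) == 0L) {
    class_label[is_gene] <- "unmapped"
  } else {
    idx <- match(nm, annotation$gene_symbol)
    class_label[is_gene] <- ifelse(is.na(idx[is_gene]), "unmapped",
                                   annotation$class_label[idx][is_gene])
  }
  igraph::V(net)$class_label <- class_label
  unmapped <- nm[is_gene & class_label == "unmapped"]
  net <- igraph::set_graph_attr(net, "unmapped_genes", unmapped)

  if (!is.null(mrdt_flags)) {
    src <- rep(NA_character_, length(nm))
    idx <- match(nm, mrdt_flags$chemical_id)
    src[!is_gene] <- mrdt_flags$source[idx][!is_gene]
    igraph::V(net)$mrdt_source <- src
  }
  net
}

#' Degree and strength statistics of the bipartite network
#'
#' @param net Bipartite igraph.
#' @return A tibble `node`, `side`, `degree`, `strength` (sum of incident
#'   edge weights), with attribute `summary`: median degree per side and
#'   whether chemical-side promiscuity (median degree) exceeds the gene
#'   side.
#' @export
degree_stats <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) {
    out <- tibble::tibble(node = character(), side = character(),
                          degree = integer(), strength = numeric())
    attr(out, "summary") <- list(median_degree_chemical = NA_real_,
                                 median_degree_gene = NA_real_,
                                 chemical_promiscuity_exceeds_gene = NA)
    return(out)
  }
  out <- tibble::tibble(
    node = igraph::V(net)$name,
    side = igraph::V(net)$side,
    degree = unname(igraph::degree(net, mode = "all")),
    strength = unname(igraph::strength(net, mode = "all"))
  )
  med_c <- stats::median(out$degree[out$side == "chemical"])
  med_g <- stats::median(out$degree[out$side == "gene"])
  attr(out, "summary") <- list(
    median_degree_chemical = med_c,
    median_degree_gene = med_g,
    chemical_promiscuity_exceeds_gene = isTRUE(med_c > med_g))
  out
}

#' Deterministic force-directed layout
#'
#' Seeded Fruchterman-Reingold layout: for a fixed seed, graph and
#' iteration count the coordinates are identical across runs. Connected
#' nodes end up closer together than random non-adjacent pairs, which is
#' the only geometric property asserted (no equivalence to any published
#' figure's geometry).
#'
#' @param net Nonempty igraph.
#' @param seed Integer seed.
#' @param iterations Iteration count (default 500).
#' @return A list of class `layout_result`: `coords` (matrix with node
#'   rownames and columns x, y), `seed`, `iterations`.
#' @export
force_layout <- function(net, seed = 1L, iterations = 500L) {
  if (igraph::vcount(net) == 0L) stop("cannot lay out an empty network", call. = FALSE)
  coords <- with_preserved_seed(seed, {
    igraph::layout_with_fr(net, niter = iterations, grid = "nogrid")
  })
  rownames(coords) <- igraph::V(net)$name
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, seed = seed, iterations = iterations),
            class = "layout_result")
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Export / import the network as GraphML or GEXF
#'
#' `export_graph()` writes a standards-conformant file carrying edge
#' weights, node class labels and (optionally) layout coordinates as
#' attributes; `import_graph()` reads it back into an igraph whose node
#' set, edge set and weights match the source. GraphML goes through
#' igraph's writer; GEXF is emitted and parsed with xml2.
#'
#' @param net Bipartite igraph.
#' @param path Output file path.
#' @param layout Optional `layout_result` whose coordinates are embedded.
#' @param format `"graphml"` or `"gexf"`.
#' @return `export_graph()` returns `path` invisibly; `import_graph()`
#'   returns an igraph.
#' @export
export_graph <- function(net, path, layout = NULL,
                         format = c("graphml", "gexf")) {
  format <- match.arg(format)
  if (!is.null(layout)) {
    idx <- match(igraph::V(net)$name, rownames(layout$coords))
    igraph::V(net)$x <- layout$coords[idx, "x"]
    igraph::V(net)$y <- layout$coords[idx, "y"]
  }
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    write_gexf(net, path)
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("graphml", "gexf")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (!is.null(igraph::V(g)$side)) igraph::V(g)$type <- igraph::V(g)$side == "gene"
    g
  } else {
    read_gexf(path)
  }
}

node_attr_or_na <- function(net, attr) {
  v <- igraph::vertex_attr(net, attr)
  if (is.null(v)) rep(NA, igraph::vcount(net)) else v
}

write_gexf <- function(net, path) {
  doc <- xml2::xml_new_root("gexf",
    xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "directed")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "side", type = "string")
  xml2::xml_add_child(attrs, "attribute", id = "1", title = "class_label", type = "string")
  xml2::xml_add_child(attrs, "attribute", id = "2", title = "x", type = "double")
  xml2::xml_add_child(attrs, "attribute", id = "3", title = "y", type = "double")

  nm <- igraph::V(net)$name
  side <- node_attr_or_na(net, "side")
  cls <- node_attr_or_na(net, "class_label")
  xs <- node_attr_or_na(net, "x")
  ys <- node_attr_or_na(net, "y")

  nodes <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_along(nm)) {
    nd <- xml2::xml_add_child(nodes, "node", id = nm[i], label = nm[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0", value = as.character(side[i]))
    if (!is.na(cls[i])) {
      xml2::xml_add_child(av, "attvalue", `for` = "1", value = cls[i])
    }
    if (!is.na(xs[i])) {
      xml2::xml_add_child(av, "attvalue", `for` = "2",
                          value = format(xs[i], digits = 17))
      xml2::xml_add_child(av, "attvalue", `for` = "3",
                          value = format(ys[i], digits = 17))
    }
  }
  el <- igraph::as_edgelist(net)
  w <- igraph::E(net)$weight
  edges <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(el))) {
    xml2::xml_add_child(edges, "edge", id = as.character(i - 1L),
                        source = el[i, 1], target = el[i, 2],
                        weight = format(w[i], digits = 17))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  node_xml <- xml2::xml_find_all(doc, ".//nodes/node")
  get_att <- function(nd, id) {
    v <- xml2::xml_attr(
      xml2::xml_find_first(nd, sprintf(".//attvalue[@for='%s']", id)), "value")
    v
  }
  nm <- xml2::xml_attr(node_xml, "id")
  side <- vapply(node_xml, get_att, character(1), id = "0")
  cls <- vapply(node_xml, get_att, character(1), id = "1")
  xs <- suppressWarnings(as.numeric(vapply(node_xml, get_att, character(1), id = "2")))
  ys <- suppressWarnings(as.numeric(vapply(node_xml, get_att, character(1), id = "3")))

  edge_xml <- xml2::xml_find_all(doc, ".//edges/edge")
  vertices <- data.frame(name = nm, type = side == "gene", side = side,
                         class_label = cls, stringsAsFactors = FALSE)
  if (any(!is.na(xs))) { vertices$x <- xs; vertices$y <- ys }
  edges <- data.frame(
    from = xml2::xml_attr(edge_xml, "source"),
    to = xml2::xml_attr(edge_xml, "target"),
    weight = as.numeric(xml2::xml_attr(edge_xml, "weight")),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}
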