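## Consensus network serialization: GraphML (via igraph) and XGMML (via
## xml2; no installed package writes XGMML).  Both formats round-trip the
## edge attributes f, r, modulator and class and the network cutoff.

#' @noRd
consensus_to_igraph <- function(net) {
  ed <- net$edges
  ed$r[is.na(ed$r)] <- NaN
  ed$modulator[is.na(ed$modulator)] <- ""
  g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                     vertices = net$nodes)
  igraph::graph_attr(g, "cutoff") <- net$cutoff
  igraph::graph_attr(g, "M") <- as.numeric(net$M)
  g
}

#' Write / read a consensus network
#'
#' @param net a `consensus_network`.
#' @param path output path.
#' @param format `"xgmml"`, `"graphml"`, or `"tsv"` (edge list).
#' @return `write_network` returns `path` invisibly; `read_network` the
#'   reconstructed `consensus_network`.
#' @export
write_network <- function(net, path, format = c("xgmml", "graphml", "tsv")) {
  stopifnot(inherits(net, "consensus_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(consensus_to_igraph(net), path, format = "graphml")
  } else if (format == "tsv") {
    write.table(net$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    write_xgmml(net, path)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("xgmml", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    names(ed)[1:2] <- c("parent", "child")
    ed$modulator[!nzchar(ed$modulator)] <- NA_character_
    ed$r[is.nan(ed$r)] <- NA_real_
    net <- consensus_network_new(ed, igraph::graph_attr(g, "cutoff"),
                                 as.integer(igraph::graph_attr(g, "M")))
    net$nodes <- sort(igraph::V(g)$name)
    net$n_nodes <- length(net$nodes)
    net$edges_per_node <- if (net$n_nodes) net$n_edges / net$n_nodes
                          else NA_real_
    return(net)
  }
  read_xgmml(path)
}

#' @noRd
num_attr <- function(x) sprintf("%.10g", x)

#' @noRd
write_xgmml <- function(net, path) {
  doc <- xml2::xml_new_root("graph",
                            label = "consensus", directed = "1",
                            xmlns = "http://www.cs.rpi.edu/XGMML")
  add_att <- function(parent, name, type, value) {
    xml2::xml_add_child(parent, "att", name = name, type = type,
                        value = value)
  }
  add_att(doc, "cutoff", "real", num_attr(net$cutoff))
  add_att(doc, "M", "integer", as.character(net$M))
  ids <- setNames(seq_along(net$nodes), net$nodes)
  for (v in net$nodes)
    xml2::xml_add_child(doc, "node", id = as.character(ids[[v]]), label = v)
  ed <- net$edges
  for (i in seq_len(nrow(ed))) {
    e <- xml2::xml_add_child(doc, "edge",
                             source = as.character(ids[[ed$parent[i]]]),
                             target = as.character(ids[[ed$child[i]]]),
                             label = paste0(ed$parent[i], "->", ed$child[i]))
    add_att(e, "f", "real", num_attr(ed$f[i]))
    if (!is.na(ed$r[i])) add_att(e, "r", "real", num_attr(ed$r[i]))
    if (!is.na(ed$modulator[i]))
      add_att(e, "modulator", "string", ed$modulator[i])
    add_att(e, "class", "string", ed$class[i] %||% "plain")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @noRd
read_xgmml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(x = xml2::xml_ns(doc)[[1]])
  att_of <- function(node, name) {
    a <- xml2::xml_find_first(node,
                              sprintf("./x:att[@name='%s']", name), ns)
    if (inherits(a, "xml_missing")) NA_character_
    else xml2::xml_attr(a, "value")
  }
  nodes <- xml2::xml_find_all(doc, "./x:node", ns)
  id2label <- setNames(xml2::xml_attr(nodes, "label"),
                       xml2::xml_attr(nodes, "id"))
  edges <- xml2::xml_find_all(doc, "./x:edge", ns)
  ed <- data.frame(
    parent = unname(id2label[xml2::xml_attr(edges, "source")]),
    child = unname(id2label[xml2::xml_attr(edges, "target")]),
    f = as.numeric(vapply(edges, att_of, "", name = "f")),
    r = as.numeric(vapply(edges, att_of, "", name = "r")),
    modulator = vapply(edges, att_of, "", name = "modulator"),
    class = vapply(edges, att_of, "", name = "class"),
    stringsAsFactors = FALSE)
  cutoff <- as.numeric(att_of(doc, "cutoff"))
  m_net <- suppressWarnings(as.integer(att_of(doc, "M")))
  net <- consensus_network_new(ed, cutoff, m_net)
  net$nodes <- sort(unname(id2label))
  net$n_nodes <- length(net$nodes)
  net$edges_per_node <- if (net$n_nodes) net$n_edges / net$n_nodes
                        else NA_real_
  net
}
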