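# GraphML serialization, written directly with xml2 so node and edge
# attribute layout is deterministic and round-trip parseable anywhere.

graphml_key <- function(root, id, domain, name, type) {
  k <- xml2::xml_add_child(root, "key", id = id, `for` = domain,
                           attr.name = name, attr.type = type)
  invisible(k)
}

#' Write a weighted network (optionally with a solution) as GraphML
#'
#' Node attributes: `state` (booleanized, profile orientation), `roles`
#' (comma-joined), `is_root`, `is_terminal`, `in_tree`. Edge attributes:
#' `sign`, `weight`, `cost`, `in_tree`. The file parses with any GraphML
#' reader; [read_graphml_edges()] recovers the edge table.
#'
#' @param wnet A `weighted_network`.
#' @param path Output path.
#' @param solution Optional `steiner_solution`; its edges and nodes are
#'   flagged `in_tree`.
#' @param profile Optional booleanized profile for node states.
#' @param roles Optional role tibble from [classify_roles()].
#' @return `path`, invisibly.
#' @export
write_graphml <- function(wnet, path, solution = NULL, profile = NULL,
                          roles = NULL) {
  stopifnot(inherits(wnet, "weighted_network"))
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  graphml_key(doc, "d0", "node", "state", "int")
  graphml_key(doc, "d1", "node", "roles", "string")
  graphml_key(doc, "d2", "node", "is_root", "boolean")
  graphml_key(doc, "d3", "node", "is_terminal", "boolean")
  graphml_key(doc, "d4", "node", "in_tree", "boolean")
  graphml_key(doc, "d5", "edge", "sign", "int")
  graphml_key(doc, "d6", "edge", "weight", "double")
  graphml_key(doc, "d7", "edge", "cost", "double")
  graphml_key(doc, "d8", "edge", "in_tree", "boolean")
  graph <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")

  nodes <- network_nodes(wnet)
  tree_key <- character(0)
  tree_nodes <- character(0)
  if (!is.null(solution)) {
    te <- solution$tree_edges
    tree_key <- paste(te$source, te$target, te$sign)
    tree_nodes <- unique(c(wnet$root, te$source, te$target))
  }
  role_str <- function(gene) {
    if (is.null(roles)) return("")
    paste(sort(roles$role[roles$gene == gene]), collapse = ",")
  }

  for (nd in nodes) {
    node <- xml2::xml_add_child(graph, "node", id = nd)
    st <- if (is.null(profile) || nd == wnet$root) 0L else profile_state(profile, nd)
    xml2::xml_add_child(node, "data", key = "d0", as.character(st))
    xml2::xml_add_child(node, "data", key = "d1", role_str(nd))
    xml2::xml_add_child(node, "data", key = "d2",
                        tolower(as.character(nd == wnet$root)))
    xml2::xml_add_child(node, "data", key = "d3",
                        tolower(as.character(nd %in% wnet$terminals)))
    xml2::xml_add_child(node, "data", key = "d4",
                        tolower(as.character(nd %in% tree_nodes)))
  }
  e <- wnet$edges
  for (i in seq_len(nrow(e))) {
    edge <- xml2::xml_add_child(graph, "edge",
                                id = paste0("e", i),
                                source = e$source[i], target = e$target[i])
    xml2::xml_add_child(edge, "data", key = "d5", as.character(e$sign[i]))
    xml2::xml_add_child(edge, "data", key = "d6",
                        format(e$weight[i], digits = 17))
    xml2::xml_add_child(edge, "data", key = "d7",
                        format(e$cost[i], digits = 17))
    xml2::xml_add_child(edge, "data", key = "d8", tolower(as.character(
      paste(e$source[i], e$target[i], e$sign[i]) %in% tree_key)))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read the edge table back from a GraphML file written by [write_graphml()]
#'
#' @param path Path to the GraphML file.
#' @return A tibble (`source`, `target`, `sign`, `weight`, `cost`,
#'   `in_tree`).
#' @export
read_graphml_edges <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  get_data <- function(edge, key) {
    xml2::xml_text(xml2::xml_find_first(
      edge, paste0("./g:data[@key='", key, "']"), ns))
  }
  tibble(
    source = xml2::xml_attr(edges, "source"),
    target = xml2::xml_attr(edges, "target"),
    sign = as.integer(vapply(edges, get_data, "", key = "d5")),
    weight = as.numeric(vapply(edges, get_data, "", key = "d6")),
    cost = as.numeric(vapply(edges, get_data, "", key = "d7")),
    in_tree = vapply(edges, get_data, "", key = "d8") == "true"
  )
}
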