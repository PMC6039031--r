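#' Write a vessel graph to GraphML, JSON or edge-list CSV
#'
#' Output is bit-stable for a fixed graph: nodes and edges are written in
#' sorted id order with full-precision (17 significant digit) numbers.
#' GraphML carries node attributes `ix, iy, iz, x, y, z, role` and edge
#' attributes `length_cm, radius_cm`; the JSON dialect mirrors the node and
#' edge tables; the CSV holds edges only (`u, v, length_cm, radius_cm`) plus
#' a companion understanding that roles travel with GraphML/JSON.
#'
#' @param graph A `vessel_graph`.
#' @param path Output file path.
#' @param format `"graphml"`, `"json"` or `"csv"`; inferred from the file
#'   extension when missing.
#' @return `path`, invisibly.
#' @export
write_vessel_graph <- function(graph, path,
                               format = c("auto", "graphml", "json", "csv")) {
  stopifnot(inherits(graph, "vessel_graph"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  nodes <- dplyr::arrange(graph$nodes, .data$id)
  edges <- dplyr::arrange(graph$edges, .data$edge)
  num <- function(x) formatC(x, digits = 17, format = "g")
  switch(format,
    graphml = write_graphml(nodes, edges, graph, path, num),
    json = {
      obj <- list(
        side = graph$side, n = graph$n,
        nodes = nodes[, intersect(c("id", "ix", "iy", "iz", "x", "y", "z", "role"),
                                  names(nodes))],
        edges = edges[, c("edge", "u", "v", "length_cm", "radius_cm")]
      )
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    },
    csv = {
      out <- edges[, c("u", "v", "length_cm", "radius_cm")]
      utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    }
  )
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, graphml = "graphml", xml = "graphml", json = "json",
         csv = "csv",
         stop("cannot infer graph format from extension '", ext, "'"))
}

write_graphml <- function(nodes, edges, graph, path, num) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(
    c("d_ix", "node", "ix", "int"), c("d_iy", "node", "iy", "int"),
    c("d_iz", "node", "iz", "int"), c("d_x", "node", "x", "double"),
    c("d_y", "node", "y", "double"), c("d_z", "node", "z", "double"),
    c("d_role", "node", "role", "string"),
    c("d_len", "edge", "length_cm", "double"),
    c("d_rad", "edge", "radius_cm", "double")
  )
  for (k in keys) {
    xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                        attr.name = k[3], attr.type = k[4])
  }
  g <- xml2::xml_add_child(doc, "graph", id = "vessel_graph",
                           edgedefault = "undirected",
                           side = num(graph$side),
                           n = as.character(graph$n))
  has_idx <- all(c("ix", "iy", "iz") %in% names(nodes))
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = paste0("n", nodes$id[i]))
    add <- function(key, val) {
      d <- xml2::xml_add_child(nd, "data", key = key)
      xml2::xml_text(d) <- val
    }
    if (has_idx) {
      add("d_ix", as.character(nodes$ix[i]))
      add("d_iy", as.character(nodes$iy[i]))
      add("d_iz", as.character(nodes$iz[i]))
    }
    add("d_x", num(nodes$x[i])); add("d_y", num(nodes$y[i]))
    add("d_z", num(nodes$z[i])); add("d_role", nodes$role[i])
  }
  for (i in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(g, "edge", id = paste0("e", edges$edge[i]),
                              source = paste0("n", edges$u[i]),
                              target = paste0("n", edges$v[i]))
    d <- xml2::xml_add_child(ed, "data", key = "d_len")
    xml2::xml_text(d) <- num(edges$length_cm[i])
    d <- xml2::xml_add_child(ed, "data", key = "d_rad")
    xml2::xml_text(d) <- num(edges$radius_cm[i])
  }
  xml2::write_xml(doc, path)
}

#' Read a vessel graph written by [write_vessel_graph()]
#'
#' GraphML and JSON restore the full graph; the CSV edge list needs node
#' roles supplied separately via `nodes`.
#'
#' @param path Input file path.
#' @param format `"graphml"`, `"json"` or `"csv"`; inferred from extension.
#' @param nodes For CSV input: a node tibble (`id, x, y, z, role`).
#' @param side,n For CSV input: geometry metadata.
#' @return A `vessel_graph`.
#' @export
read_vessel_graph <- function(path, format = c("auto", "graphml", "json", "csv"),
                              nodes = NULL, side = 1, n = NA_integer_) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
    json = {
      obj <- jsonlite::read_json(path, simplifyVector = TRUE)
      vessel_graph(tibble::as_tibble(obj$nodes), tibble::as_tibble(obj$edges),
                   side = obj$side,
                   n = if (is.null(obj$n) || is.na(obj$n)) NA_integer_ else obj$n)
    },
    csv = {
      edges <- tibble::as_tibble(utils::read.csv(path))
      need <- c("u", "v", "length_cm", "radius_cm")
      miss <- setdiff(need, names(edges))
      if (length(miss))
        stop("CSV edge list missing column(s): ", paste(miss, collapse = ", "))
      if (is.null(nodes))
        stop("CSV input carries no node roles; supply a `nodes` table")
      vessel_graph(nodes, edges, side = side, n = n)
    },
    graphml = read_graphml(path)
  )
}

read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  key_name <- stats::setNames(xml2::xml_attr(keys, "attr.name"),
                              xml2::xml_attr(keys, "id"))
  gnode <- xml2::xml_find_first(doc, ".//graph")
  side <- as.numeric(xml2::xml_attr(gnode, "side"))
  n <- suppressWarnings(as.integer(xml2::xml_attr(gnode, "n")))
  parse_elems <- function(xpath, id_attr) {
    elems <- xml2::xml_find_all(doc, xpath)
    purrr::map_dfr(elems, function(el) {
      dat <- xml2::xml_find_all(el, "./data")
      vals <- stats::setNames(xml2::xml_text(dat),
                              key_name[xml2::xml_attr(dat, "key")])
      c(as.list(xml2::xml_attrs(el)), as.list(vals))
    })
  }
  nd <- parse_elems(".//node", "id")
  ed <- parse_elems(".//edge", "id")
  if (!"role" %in% names(nd)) stop("GraphML is missing the node attribute 'role'")
  if (!"radius_cm" %in% names(ed)) stop("GraphML is missing the edge attribute 'radius_cm'")
  if (!"length_cm" %in% names(ed)) stop("GraphML is missing the edge attribute 'length_cm'")
  nodes <- tibble::tibble(
    id = as.integer(sub("^n", "", nd$id)),
    x = as.numeric(nd$x), y = as.numeric(nd$y), z = as.numeric(nd$z),
    role = nd$role
  )
  if (all(c("ix", "iy", "iz") %in% names(nd))) {
    nodes$ix <- as.integer(nd$ix); nodes$iy <- as.integer(nd$iy)
    nodes$iz <- as.integer(nd$iz)
  }
  edges <- tibble::tibble(
    edge = as.integer(sub("^e", "", ed$id)),
    u = as.integer(sub("^n", "", ed$source)),
    v = as.integer(sub("^n", "", ed$target)),
    length_cm = as.numeric(ed$length_cm),
    radius_cm = as.numeric(ed$radius_cm)
  )
  vessel_graph(dplyr::arrange(nodes, id), dplyr::arrange(edges, edge),
               side = ifelse(is.na(side), 1, side), n = n)
}
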