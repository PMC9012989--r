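#' Coverage ranking of attributes
#'
#' Total order used to lay the APOS hierarchy: attributes sorted by
#' coverage (number of objects possessing them) descending, ties broken
#' lexicographically by name. Attributes covering no object are dropped.
#'
#' @param context a [build_formal_context()] result (any binary 0/1 matrix
#'   with attribute column names works).
#' @return Character vector of attribute names, most universal first.
#' @export
attribute_ranking <- function(context) {
  if (!nrow(context) || !ncol(context))
    ta_error("context must be nonempty", "validation_error")
  cov <- colSums(context)
  keep <- cov > 0
  nm <- colnames(context)[keep]
  nm[order(-cov[keep], nm)]
}

#' Build the attribute partial order structure (APOS)
#'
#' Realizes the four generation principles — more-covered attributes higher,
#' similar objects adjacent, higher nodes more universal, one branch per
#' object's attribute set — as a prefix trie over each object's intent
#' ordered by [attribute_ranking()]. Node level is the depth in the trie;
#' objects with identical intents share a branch (leaf). The
#' extent-containment partial order (`a <= b` iff every object with `a`
#' also has `b`) is computed as an auxiliary relation.
#'
#' @param context a binary object x attribute [build_formal_context()].
#' @return An object of class `apos_graph`: `nodes` (data.frame id, parent,
#'   attribute, level, coverage), `leaves` (leaf node id -> object ids),
#'   `root_objects` (objects with empty intent), `ranking`, `order`
#'   (logical attribute x attribute containment matrix) and `context`.
#' @examples
#' ctx <- matrix(c(1, 1, 0, 1, 1, 1), 2, 3,
#'               dimnames = list(c("o1", "o2"), c("a", "b", "c")))
#' g <- build_apos(ctx)
#' level_report(g)
#' @export
build_apos <- function(context) {
  ranking <- attribute_ranking(context)
  cov <- colSums(context)
  rank_pos <- stats::setNames(seq_along(ranking), ranking)
  ids <- rownames(context)
  if (is.null(ids)) ids <- paste0("obj", seq_len(nrow(context)))

  node_parent <- integer(0); node_attr <- character(0); node_level <- integer(0)
  child_map <- new.env(parent = emptyenv())
  leaves <- list()
  root_objects <- character(0)

  for (i in seq_len(nrow(context))) {
    intent <- colnames(context)[context[i, ] == 1]
    if (!length(intent)) {
      ta_warn(sprintf("object %s has an empty intent: placed on the root", ids[i]))
      root_objects <- c(root_objects, ids[i])
      next
    }
    path <- intent[order(rank_pos[intent])]
    cur <- 0L
    for (a in path) {
      key <- paste0(cur, "|", a)
      if (!is.null(child_map[[key]])) {
        cur <- child_map[[key]]
      } else {
        node_parent <- c(node_parent, cur)
        node_attr <- c(node_attr, a)
        node_level <- c(node_level, if (cur == 0L) 1L else node_level[cur] + 1L)
        cur <- length(node_attr)
        child_map[[key]] <- cur
      }
    }
    k <- as.character(cur)
    leaves[[k]] <- c(leaves[[k]], ids[i])
  }

  attrs <- intersect(colnames(context), ranking)
  x <- context[, attrs, drop = FALSE]
  inter <- crossprod(x)                      # |extent(a) n extent(b)|
  ord <- inter == matrix(diag(inter), length(attrs), length(attrs))
  dimnames(ord) <- list(attrs, attrs)        # ord[a, b]: extent(a) subset of extent(b)

  structure(list(nodes = data.frame(id = seq_along(node_attr),
                                    parent = node_parent,
                                    attribute = node_attr,
                                    level = node_level,
                                    coverage = as.integer(cov[node_attr])),
                 leaves = leaves, root_objects = root_objects,
                 ranking = ranking, order = ord, context = context,
                 object_ids = ids),
            class = "apos_graph")
}

#' @export
print.apos_graph <- function(x, ...) {
  cat(sprintf("<apos_graph> %d attribute nodes, %d branches, %d objects, depth %d\n",
              nrow(x$nodes), length(x$leaves), nrow(x$context),
              if (nrow(x$nodes)) max(x$nodes$level) else 0L))
  invisible(x)
}

# root->leaf attribute path ending at node id
node_path <- function(graph, id) {
  path <- character(0)
  while (id != 0L) {
    path <- c(graph$nodes$attribute[id], path)
    id <- graph$nodes$parent[id]
  }
  path
}

#' Branch of one object
#'
#' The ordered attribute path from the root to the object's leaf; the path
#' set equals the object's intent, and objects with identical intents share
#' the branch.
#'
#' @param graph a [build_apos()] result.
#' @param object object identifier (context row name).
#' @return An object of class `object_branch`: `objects` (all ids sharing
#'   the branch) and `attributes` (root-to-leaf order).
#' @export
query_branch <- function(graph, object) {
  stopifnot(inherits(graph, "apos_graph"))
  if (!object %in% graph$object_ids)
    ta_error(sprintf("unknown object: %s", object), "lookup_error")
  if (object %in% graph$root_objects)
    return(structure(list(objects = graph$root_objects, attributes = character(0)),
                     class = "object_branch"))
  for (k in names(graph$leaves)) {
    if (object %in% graph$leaves[[k]])
      return(structure(list(objects = graph$leaves[[k]],
                            attributes = node_path(graph, as.integer(k))),
                       class = "object_branch"))
  }
  ta_error(sprintf("object %s not found on any branch", object), "lookup_error")
}

#' Attributes present at each level of the graph
#'
#' Reading the diagram top-down: for each depth, the set of attribute nodes
#' occurring there. This is the view used to read off rules such as which
#' regions' high-temperature attributes dominate the top of the hierarchy.
#'
#' @inheritParams query_branch
#' @return Named list, one character vector of attributes per level.
#' @export
level_report <- function(graph) {
  stopifnot(inherits(graph, "apos_graph"))
  if (!nrow(graph$nodes)) return(stats::setNames(list(), character(0)))
  lapply(split(graph$nodes$attribute, graph$nodes$level),
         function(a) sort(unique(a)))
}

# mean trie depth of a set of attributes (NA if absent from the graph)
mean_attribute_depth <- function(graph, attributes) {
  d <- graph$nodes$level[graph$nodes$attribute %in% attributes]
  if (!length(d)) NA_real_ else mean(d)
}

#' Export an APOS graph
#'
#' Lossless node/edge export (ids, attributes, levels, coverage, leaf
#' object lists) as JSON, Graphviz DOT, or GraphML.
#'
#' @inheritParams query_branch
#' @param path output file path.
#' @param format `"json"`, `"dot"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("json", "dot", "graphml")) {
  stopifnot(inherits(graph, "apos_graph"))
  format <- match.arg(format)
  nd <- graph$nodes
  switch(format,
    json = jsonlite::write_json(
      list(nodes = nd,
           edges = data.frame(from = nd$parent, to = nd$id),
           leaves = graph$leaves, root_objects = graph$root_objects,
           ranking = graph$ranking),
      path, auto_unbox = FALSE, digits = NA),
    dot = {
      esc <- function(s) gsub('"', '\\\\"', s)
      lines <- c("digraph apos {", "  rankdir=TB;",
                 '  node [shape=box, fontsize=10];',
                 '  n0 [label="root"];',
                 sprintf('  n%d [label="%s\\n(%d)"];', nd$id,
                         esc(nd$attribute), nd$coverage),
                 sprintf("  n%d -> n%d;", nd$parent, nd$id),
                 "}")
      writeLines(lines, path)
    },
    graphml = {
      esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s))
      hdr <- c('<?xml version="1.0" encoding="UTF-8"?>',
               '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
               '<key id="attr" for="node" attr.name="attribute" attr.type="string"/>',
               '<key id="lvl" for="node" attr.name="level" attr.type="int"/>',
               '<key id="cov" for="node" attr.name="coverage" attr.type="int"/>',
               '<graph edgedefault="directed">',
               '<node id="n0"/>')
      nodes <- sprintf(paste0('<node id="n%d"><data key="attr">%s</data>',
                              '<data key="lvl">%d</data>',
                              '<data key="cov">%d</data></node>'),
                       nd$id, esc(nd$attribute), nd$level, nd$coverage)
      edges <- sprintf('<edge source="n%d" target="n%d"/>', nd$parent, nd$id)
      writeLines(c(hdr, nodes, edges, "</graph>", "</graphml>"), path)
    })
  invisible(path)
}

#' @rdname export_graph
#' @export
read_apos_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
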