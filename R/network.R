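#' Construct a bipartite interaction network
#'
#' Both the MEI (biomarker-enzyme) and MTI (biomarker-target) networks are
#' bipartite: biomarkers form the left partition, enzymes or targets the
#' right. Duplicate edges collapse, self- and cross-partition violations are
#' impossible by construction, and isolated nodes are excluded: every node in
#' a network participates in at least one edge.
#'
#' @param edges data.frame with columns `left`, `right` and optionally
#'   `weight` (pKd).
#' @param right_role label for the right partition: `"enzyme"` or `"target"`.
#' @param node_attrs optional named list of data.frames (`left`, `right`)
#'   carrying annotations (trend, functions, systems) keyed by an `id`
#'   column; retained for SIF/GraphML export.
#' @return object of class `bipartite_network` with elements `left_nodes`,
#'   `right_nodes`, `edges` (sorted data.frame), `right_role`, `node_attrs`.
#' @export
bipartite_network <- function(edges, right_role = c("enzyme", "target"),
                              node_attrs = NULL) {
  right_role <- match.arg(right_role)
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(left = character(), right = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("left", "right") %in% names(edges)))
    if (!"weight" %in% names(edges)) edges$weight <- NA_real_
    edges <- edges[c("left", "right", "weight")]
    edges$left <- as.character(edges$left)
    edges$right <- as.character(edges$right)
    overlap <- intersect(unique(edges$left), unique(edges$right))
    if (length(overlap)) {
      stop(sprintf("id(s) appear in both partitions: %s",
                   paste(utils::head(overlap, 5), collapse = ", ")),
           call. = FALSE)
    }
    edges <- edges[!duplicated(edges[c("left", "right")]), , drop = FALSE]
    edges <- edges[order(edges$left, edges$right), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(
    list(left_nodes = sort(unique(edges$left)),
         right_nodes = sort(unique(edges$right)),
         edges = edges, right_role = right_role,
         node_attrs = node_attrs),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network (biomarker x %s): %d x %d nodes, %d edges\n",
              x$right_role, length(x$left_nodes), length(x$right_nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Summarize a bipartite network
#'
#' Reports node and edge counts plus the two mean-degree ratios: the average
#' number of right-partition partners per left node (`mean_right_per_left` =
#' edges / left nodes) and the converse. Exact values satisfy
#' `mean_right_per_left * n_left == n_edges`; `*_rounded` fields apply
#' half-up rounding to two decimals for reporting (e.g. a 13-biomarker,
#' 78-target, 232-edge network reports 17.85 and 2.97). An empty network
#' yields zero counts and zero means, flagged `empty`.
#'
#' @param network a `bipartite_network`
#' @return object of class `network_summary`.
#' @export
summarize_network <- function(network) {
  stopifnot(inherits(network, "bipartite_network"))
  n_left <- length(network$left_nodes)
  n_right <- length(network$right_nodes)
  n_edges <- nrow(network$edges)
  empty <- n_edges == 0L
  mrl <- if (empty) 0 else n_edges / n_left
  mlr <- if (empty) 0 else n_edges / n_right
  structure(
    list(n_left = n_left, n_right = n_right, n_edges = n_edges,
         mean_right_per_left = mrl, mean_left_per_right = mlr,
         mean_right_per_left_rounded = round_half_up(mrl, 2),
         mean_left_per_right_rounded = round_half_up(mlr, 2),
         right_role = network$right_role, empty = empty),
    class = "network_summary"
  )
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    "network_summary: %d biomarkers, %d %ss, %d edges%s\n",
    x$n_left, x$n_right, x$right_role, x$n_edges,
    if (x$empty) " (empty)" else ""))
  if (!x$empty) {
    cat(sprintf("  mean %ss per biomarker: %.2f\n", x$right_role,
                x$mean_right_per_left_rounded))
    cat(sprintf("  mean biomarkers per %s: %.2f\n", x$right_role,
                x$mean_left_per_right_rounded))
  }
  invisible(x)
}

#' Degree table of one network partition
#'
#' Degree centrality here is the raw degree: the number of edges incident to
#' a node, the sole topology statistic used to rank biomarkers, enzymes and
#' targets. Rows are ordered degree descending, id ascending on ties, so
#' tables are reproducible. Optionally a normalized variant (degree divided
#' by the size of the opposite partition) is appended; raw degree remains
#' the ranking key.
#'
#' @param network a `bipartite_network`
#' @param role which partition: `"biomarker"` (left) or the network's right
#'   role (`"enzyme"`/`"target"`).
#' @param normalized also report degree / opposite-partition size.
#' @return data.frame with columns `id`, `role`, `degree`
#'   (and `degree_normalized` if requested).
#' @export
node_degrees <- function(network, role, normalized = FALSE) {
  stopifnot(inherits(network, "bipartite_network"))
  if (!role %in% c("biomarker", network$right_role)) {
    stop(sprintf("unknown role '%s'; expected 'biomarker' or '%s'",
                 role, network$right_role), call. = FALSE)
  }
  side <- if (role == "biomarker") "left" else "right"
  ids <- network[[paste0(side, "_nodes")]]
  deg <- table(factor(network$edges[[side]], levels = ids))
  out <- data.frame(id = ids, role = rep(role, length(ids)),
                    degree = as.integer(deg[ids]),
                    stringsAsFactors = FALSE)
  if (normalized) {
    opp <- length(network[[if (side == "left") "right_nodes" else "left_nodes"]])
    out$degree_normalized <- if (opp > 0) out$degree / opp else 0
  }
  out <- out[order(-out$degree, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select hub nodes by exclusive degree cutoff
#'
#' Returns the nodes whose degree strictly exceeds `min_degree` ("associated
#' with more than ten enzymes" selects biomarkers of degree > 10). Ordering
#' is inherited from the degree table, so hubs come out degree-descending.
#'
#' @param degree_table data.frame with `id` and `degree` columns (as from
#'   [node_degrees()]).
#' @param min_degree exclusive threshold (default 10).
#' @return data.frame subset of `degree_table` (the hubs).
#' @export
select_hubs <- function(degree_table, min_degree = 10L) {
  stopifnot(all(c("id", "degree") %in% names(degree_table)),
            min_degree >= 0)
  out <- degree_table[degree_table$degree > min_degree, , drop = FALSE]
  rownames(out) <- NULL
  out
}

assert_handshake <- function(network) {
  dl <- sum(node_degrees(network, "biomarker")$degree)
  dr <- sum(node_degrees(network, network$right_role)$degree)
  ne <- nrow(network$edges)
  if (dl != ne || dr != ne) {
    stop(sprintf("handshake lemma violated: left %d, right %d, edges %d",
                 dl, dr, ne), call. = FALSE)
  }
  invisible(TRUE)
}

#' Export a network as a SIF edge list
#'
#' Simple interaction format for Cytoscape: one
#' `biomarker<TAB>interacts<TAB>partner` line per edge.
#'
#' @param network a `bipartite_network`
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path) {
  e <- network$edges
  lines <- sprintf("%s\tinteracts\t%s", e$left, e$right)
  writeLines(lines, path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Builds an igraph bipartite graph carrying node role, any annotations
#' supplied at construction (trend, functions, systems, membership class)
#' and pKd edge weights, and writes GraphML for Cytoscape/Gephi.
#'
#' @param network a `bipartite_network`
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert to an igraph object
#'
#' @param network a `bipartite_network`
#' @return an igraph graph with a logical `type` vertex attribute
#'   (TRUE = right partition) and `role` labels.
#' @export
as_igraph <- function(network) {
  verts <- data.frame(
    name = c(network$left_nodes, network$right_nodes),
    type = c(rep(FALSE, length(network$left_nodes)),
             rep(TRUE, length(network$right_nodes))),
    role = c(rep("biomarker", length(network$left_nodes)),
             rep(network$right_role, length(network$right_nodes))),
    stringsAsFactors = FALSE
  )
  attach_attr <- function(side, ids) {
    at <- network$node_attrs[[side]]
    if (is.null(at)) return(NULL)
    at[match(ids, at$id), setdiff(names(at), "id"), drop = FALSE]
  }
  la <- attach_attr("left", network$left_nodes)
  ra <- attach_attr("right", network$right_nodes)
  # display names must not clobber the vertex id column
  if (!is.null(la) && "name" %in% names(la)) names(la)[names(la) == "name"] <- "label"
  if (!is.null(ra) && "name" %in% names(ra)) names(ra)[names(ra) == "name"] <- "label"
  for (col in setdiff(union(names(la), names(ra)), c("name", "type", "role"))) {
    lv <- if (!is.null(la) && col %in% names(la)) la[[col]] else
      rep(NA, length(network$left_nodes))
    rv <- if (!is.null(ra) && col %in% names(ra)) ra[[col]] else
      rep(NA, length(network$right_nodes))
    if (is.list(lv)) lv <- join_multi(lv)
    if (is.list(rv)) rv <- join_multi(rv)
    verts[[col]] <- c(as.vector(lv), as.vector(rv))
  }
  e <- network$edges
  edf <- data.frame(from = e$left, to = e$right, stringsAsFactors = FALSE)
  if (any(!is.na(e$weight))) edf$weight <- e$weight
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = verts)
}
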