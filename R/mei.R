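#' Build the metabolic-biomarker-enzyme interaction (MEI) network
#'
#' One edge per distinct (biomarker, enzyme) relation; duplicate relation
#' rows collapse. Every relation endpoint must resolve in its catalog.
#' Biomarker trend and enzyme function annotations are carried on the nodes
#' for export.
#'
#' @param relations data.frame with `biomarker_id`, `enzyme_id` columns.
#' @param biomarkers biomarker catalog (`id`, `name`, `platform`, `trend`).
#' @param enzymes enzyme catalog (`id`, `name`, `functions` list column).
#' @return a `bipartite_network` with right role `"enzyme"`.
#' @export
build_mei_network <- function(relations, biomarkers, enzymes) {
  bad_b <- setdiff(relations$biomarker_id, biomarkers$id)
  bad_e <- setdiff(relations$enzyme_id, enzymes$id)
  if (length(bad_b) || length(bad_e)) {
    stop(sprintf(
      "dangling relation endpoint(s): %s",
      paste(c(sprintf("biomarker '%s'", bad_b),
              sprintf("enzyme '%s'", bad_e)), collapse = ", ")),
      call. = FALSE)
  }
  edges <- data.frame(left = relations$biomarker_id,
                      right = relations$enzyme_id,
                      stringsAsFactors = FALSE)
  net <- bipartite_network(
    edges, right_role = "enzyme",
    node_attrs = list(
      left = biomarkers[c("id", "name", "trend")],
      right = data.frame(id = enzymes$id, name = enzymes$name,
                         functions = join_multi(enzymes$functions),
                         stringsAsFactors = FALSE)
    )
  )
  assert_handshake(net)
  net
}

#' Tally enzyme function categories in a network
#'
#' Each enzyme contributes one count to every function category it carries
#' (an enzyme annotated Acyltransferase and Transferase increments both).
#' Categories are returned count-descending, name ascending on ties. In
#' published MEI analyses the dominant categories are hydrolases,
#' transferases and acyltransferases.
#'
#' @param network an MEI `bipartite_network`
#' @param enzymes enzyme catalog with `id` and `functions` (list column)
#' @return data.frame with `category` and `n_enzymes` columns.
#' @export
enzyme_function_tally <- function(network, enzymes) {
  stopifnot(inherits(network, "bipartite_network"),
            network$right_role == "enzyme")
  in_net <- enzymes$id %in% network$right_nodes
  cats <- unlist(enzymes$functions[in_net], use.names = FALSE)
  if (!length(cats)) {
    return(data.frame(category = character(), n_enzymes = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(cats)
  out <- data.frame(category = names(tab), n_enzymes = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_enzymes, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
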