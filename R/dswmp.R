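#' Docking score-weighted multiple pharmacology index (DSWMP) of one pathway
#'
#' Sums the pKd of every retained biomarker-target edge whose target belongs
#' to the pathway member set, then normalizes by a biomarker count whose
#' reading is configurable (`count_mode`):
#' \describe{
#'   \item{contributing_biomarkers (default)}{divide the sum by the number
#'     of distinct biomarkers with at least one retained edge into the
#'     pathway; keeps scores comparable across pathways of different reach.}
#'   \item{n_biomarkers}{divide by the total number of biomarkers in the
#'     edge universe (all rows of the docking matrix); additive over
#'     disjoint pathway member sets.}
#'   \item{per_biomarker_edge_count}{divide each biomarker's pathway score
#'     sum by its own pathway edge count, then sum the per-biomarker means.}
#' }
#' A pathway untouched by any edge scores 0; a pathway with an empty member
#' set is a scoring error (distinct from a legal zero).
#'
#' @param edges thresholded weighted edge list
#'   (`biomarker_id`, `target_id`, `pkd`), e.g. from [threshold_edges()].
#' @param members character vector of pathway member target ids (non-empty).
#' @param count_mode denominator reading, see Details.
#' @param n_biomarkers total biomarker count for `"n_biomarkers"` mode;
#'   defaults to the number of distinct biomarkers in `edges`.
#' @return scalar score with attribute `contributing_edges` (the
#'   data.frame of (biomarker, target, pkd) triples that produced it).
#' @export
dswmp_score <- function(edges,
                        members,
                        count_mode = c("contributing_biomarkers",
                                       "n_biomarkers",
                                       "per_biomarker_edge_count"),
                        n_biomarkers = NULL) {
  count_mode <- match.arg(count_mode)
  if (length(members) == 0) {
    stop("pathway has an empty member set; cannot score", call. = FALSE)
  }
  stopifnot(all(c("biomarker_id", "target_id", "pkd") %in% names(edges)))
  contrib <- edges[edges$target_id %in% members, , drop = FALSE]
  contrib <- contrib[order(contrib$biomarker_id, contrib$target_id), ,
                     drop = FALSE]
  rownames(contrib) <- NULL
  if (nrow(contrib) == 0) {
    return(structure(0, contributing_edges = contrib))
  }
  score <- switch(
    count_mode,
    contributing_biomarkers = sum(contrib$pkd) /
      length(unique(contrib$biomarker_id)),
    n_biomarkers = {
      nb <- if (is.null(n_biomarkers)) {
        length(unique(edges$biomarker_id))
      } else {
        as.integer(n_biomarkers)
      }
      if (nb < 1) stop("`n_biomarkers` must be >= 1", call. = FALSE)
      sum(contrib$pkd) / nb
    },
    per_biomarker_edge_count = {
      per <- tapply(contrib$pkd, contrib$biomarker_id, mean)
      sum(per)
    }
  )
  structure(as.numeric(score), contributing_edges = contrib)
}

#' Score every pathway in every system
#'
#' Applies [dswmp_score()] to each pathway against each system's retained
#' edge set. Rows are ordered within system by score descending, pathway id
#' ascending on ties; `score` is the exact value, `score_rounded` the 2-dp
#' half-up value for reporting.
#'
#' @param edges_by_system named list (system -> thresholded edge list).
#'   Each system is scored against its own system-restricted edge set.
#' @param pathways pathway membership table
#'   (`pathway_id`, `pathway_name`, `target_id`).
#' @param count_mode passed to [dswmp_score()].
#' @param n_biomarkers optional fixed biomarker count for `n_biomarkers`
#'   mode (e.g. the docking matrix row count).
#' @return data.frame: `system`, `pathway_id`, `pathway_name`, `score`,
#'   `score_rounded`, `n_contributing_biomarkers`, `n_contributing_edges`.
#' @export
score_all_pathways <- function(edges_by_system, pathways,
                               count_mode = "contributing_biomarkers",
                               n_biomarkers = NULL) {
  if (nrow(pathways) == 0) stop("pathway catalog is empty", call. = FALSE)
  members_by_pw <- split(pathways$target_id, pathways$pathway_id)
  pw_names <- pathways$pathway_name[match(names(members_by_pw),
                                          pathways$pathway_id)]
  res <- lapply(names(edges_by_system), function(sys) {
    edges <- edges_by_system[[sys]]
    rows <- lapply(seq_along(members_by_pw), function(i) {
      s <- dswmp_score(edges, members_by_pw[[i]], count_mode = count_mode,
                       n_biomarkers = n_biomarkers)
      ce <- attr(s, "contributing_edges")
      data.frame(
        system = sys,
        pathway_id = names(members_by_pw)[i],
        pathway_name = pw_names[i],
        score = as.numeric(s),
        n_contributing_biomarkers = length(unique(ce$biomarker_id)),
        n_contributing_edges = nrow(ce),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out[order(-out$score, out$pathway_id), , drop = FALSE]
  })
  out <- do.call(rbind, res)
  out$score_rounded <- round_half_up(out$score, 2)
  rownames(out) <- NULL
  out[c("system", "pathway_id", "pathway_name", "score", "score_rounded",
        "n_contributing_biomarkers", "n_contributing_edges")]
}

#' Top-k pathways per system
#'
#' Truncates each system's ranked pathway table to its first `k` rows
#' (fewer if fewer pathways exist). Ranking order is score descending,
#' pathway id ascending on ties, as produced by [score_all_pathways()].
#'
#' @param scores output of [score_all_pathways()]
#' @param k ranking depth (default 10)
#' @return data.frame subset, with a `rank` column per system.
#' @export
top_k_pathways <- function(scores, k = 10L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be >= 1", call. = FALSE)
  parts <- lapply(split(scores, scores$system), function(df) {
    df <- df[order(-df$score, df$pathway_id), , drop = FALSE]
    df <- utils::head(df, k)
    df$rank <- seq_len(nrow(df))
    df
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Cross-system overlap of top-ranked pathways
#'
#' Classifies each pathway appearing in any system's top-k list by the
#' number of systems (1, 2 or 3) whose list contains it, and emits the
#' alluvial edge table (one row per system-pathway presence) that underlies
#' system-to-pathway flow plots.
#'
#' @param top_table output of [top_k_pathways()] (all systems).
#' @return list with `alluvial` (data.frame `system`, `pathway_id`,
#'   `pathway_name`, `score`, `rank`) and `classes` (data.frame
#'   `pathway_id`, `pathway_name`, `n_systems`, `systems`).
#' @export
cross_system_overlap <- function(top_table) {
  stopifnot(all(c("system", "pathway_id", "score") %in% names(top_table)))
  alluvial <- top_table[order(top_table$system, -top_table$score,
                              top_table$pathway_id),
                        intersect(c("system", "pathway_id", "pathway_name",
                                    "score", "rank"), names(top_table)),
                        drop = FALSE]
  rownames(alluvial) <- NULL
  by_pw <- split(alluvial$system, alluvial$pathway_id)
  classes <- data.frame(
    pathway_id = names(by_pw),
    n_systems = vapply(by_pw, function(s) length(unique(s)), integer(1)),
    systems = vapply(by_pw, function(s) paste(sort(unique(s)),
                                              collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE
  )
  if ("pathway_name" %in% names(alluvial)) {
    classes$pathway_name <- alluvial$pathway_name[
      match(classes$pathway_id, alluvial$pathway_id)]
    classes <- classes[c("pathway_id", "pathway_name", "n_systems",
                         "systems")]
  }
  classes <- classes[order(-classes$n_systems, classes$pathway_id), ,
                     drop = FALSE]
  rownames(classes) <- NULL
  list(alluvial = alluvial, classes = classes)
}
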