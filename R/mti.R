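# pKd range over which the 5.52 cutoff was calibrated (80-83% accuracy for
# classifying good binders); thresholds outside it draw a warning.
CALIBRATED_PKD_RANGE <- c(4.82, 6.11)

#' Edge-retention rule for docking scores
#'
#' An interaction is retained when its docking score passes the threshold
#' under the comparator. The default is the strict rule: pKd strictly
#' greater than 5.52 (the pKd of a 3 uM Kd). Thresholds outside the
#' calibrated range [4.82, 6.11] pKd are legal but trigger a warning,
#' because the accuracy of the good-binder classification was only
#' established inside it.
#'
#' @param threshold pKd cutoff (default 5.52)
#' @param comparator `"greater"` (default) or `"greater_equal"`
#' @return object of class `threshold_rule`.
#' @export
threshold_rule <- function(threshold = 5.52,
                           comparator = c("greater", "greater_equal")) {
  comparator <- match.arg(comparator)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  if (threshold < CALIBRATED_PKD_RANGE[1] ||
      threshold > CALIBRATED_PKD_RANGE[2]) {
    warning(sprintf(
      "threshold %.2f pKd lies outside the calibrated range [%.2f, %.2f]",
      threshold, CALIBRATED_PKD_RANGE[1], CALIBRATED_PKD_RANGE[2]),
      call. = FALSE)
  }
  structure(list(threshold = threshold, comparator = comparator),
            class = "threshold_rule")
}

#' Threshold a docking-score matrix into a weighted edge list
#'
#' Emits one edge per (biomarker, target) cell whose pKd passes the rule;
#' missing entries (NA, "no measured interaction") never pass. Output is
#' sorted by (biomarker, target) for determinism.
#'
#' @param scores numeric matrix, rownames = biomarker ids, colnames =
#'   target ids, entries pKd or NA.
#' @param rule a [threshold_rule()] (default: strict > 5.52).
#' @return data.frame with columns `biomarker_id`, `target_id`, `pkd`.
#' @export
threshold_edges <- function(scores, rule = threshold_rule()) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            !is.null(colnames(scores)))
  pass <- if (rule$comparator == "greater") {
    !is.na(scores) & scores > rule$threshold
  } else {
    !is.na(scores) & scores >= rule$threshold
  }
  idx <- which(pass, arr.ind = TRUE)
  out <- data.frame(
    biomarker_id = rownames(scores)[idx[, 1]],
    target_id = colnames(scores)[idx[, 2]],
    pkd = scores[idx],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$biomarker_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a per-system biomarker-target interaction (MTI) network
#'
#' Restricts a thresholded edge list to the targets belonging to one
#' physiological system and assembles the bipartite network. Biomarkers
#' with no surviving edge into the system are dropped (which is why only a
#' subset of a study's biomarkers appears in each MTI network). pKd edge
#' weights are preserved; targets carry their system-membership class
#' (1, 2 or 3 systems) as a node attribute.
#'
#' @param edges thresholded edge list from [threshold_edges()]
#' @param system one of `"nervous"`, `"immune"`, `"endocrine"`
#' @param targets target catalog (`id`, `name`, `systems` list column)
#' @return a `bipartite_network` with right role `"target"`.
#' @export
build_mti_network <- function(edges, system, targets) {
  if (!is.character(system) || length(system) != 1L ||
      !system %in% SYSTEMS) {
    stop(sprintf("unknown system '%s'; expected one of %s",
                 paste(system, collapse = ","),
                 paste(SYSTEMS, collapse = ", ")), call. = FALSE)
  }
  in_sys <- targets$id[vapply(targets$systems, function(s) system %in% s,
                              logical(1))]
  keep <- edges$target_id %in% in_sys
  e <- edges[keep, , drop = FALSE]
  cls <- system_membership_classes(targets)
  net <- bipartite_network(
    data.frame(left = e$biomarker_id, right = e$target_id,
               weight = e$pkd, stringsAsFactors = FALSE),
    right_role = "target",
    node_attrs = list(
      right = data.frame(
        id = targets$id, name = targets$name,
        systems = join_multi(targets$systems),
        n_systems = cls$n_systems[match(targets$id, cls$target_id)],
        stringsAsFactors = FALSE
      )
    )
  )
  assert_handshake(net)
  net
}

#' Classify targets by system-membership multiplicity
#'
#' Partitions targets by how many of the three systems contain them: class 1
#' (one system, rendered blue in the source figures), class 2 (yellow) or
#' class 3 (red). A target with an empty systems set is a validation error.
#'
#' @param targets target catalog (`id`, `systems` list column)
#' @return object of class `membership_classes`: data.frame
#'   (`target_id`, `n_systems`, `class_color`) plus a `counts` attribute
#'   (named vector over classes 1..3).
#' @export
system_membership_classes <- function(targets) {
  n_sys <- vapply(targets$systems,
                  function(s) length(intersect(unique(s), SYSTEMS)),
                  integer(1))
  if (any(n_sys == 0)) {
    stop(sprintf("target(s) with empty systems set: %s",
                 paste(targets$id[n_sys == 0], collapse = ", ")),
         call. = FALSE)
  }
  colors <- c("blue", "yellow", "red")
  out <- data.frame(target_id = targets$id, n_systems = n_sys,
                    class_color = colors[n_sys],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_systems, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  counts <- vapply(1:3, function(k) sum(n_sys == k), integer(1))
  names(counts) <- c("1", "2", "3")
  attr(out, "counts") <- counts
  class(out) <- c("membership_classes", class(out))
  out
}

#' Targets shared by all per-system MTI networks
#'
#' Exact intersection of the target (right-partition) node sets of the
#' per-system networks, sorted for determinism. In the depression study this
#' intersection held nine targets active in all three systems.
#'
#' @param networks named list of three `bipartite_network`s, one per system.
#' @return sorted character vector of shared target ids.
#' @export
shared_targets <- function(networks) {
  if (!is.list(networks) || length(networks) < 3L) {
    stop("`networks` must list one network per system (three networks)",
         call. = FALSE)
  }
  sets <- lapply(networks, function(n) {
    stopifnot(inherits(n, "bipartite_network"))
    n$right_nodes
  })
  sort(Reduce(intersect, sets))
}
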