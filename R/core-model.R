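# Domain containers are plain data.frames bundled in a `study_bundle` list:
#   biomarkers: id, name, platform, trend
#   enzymes:    id, name, functions (list column of character vectors)
#   relations:  biomarker_id, enzyme_id
#   targets:    id, name, systems (list column; subset of SYSTEMS)
#   scores:     numeric matrix, rownames = biomarker ids, colnames = target ids,
#               NA = no measured interaction
#   pathways:   pathway_id, pathway_name, target_id (one membership per row)

#' The three-physiological-system universe
#'
#' Targets are annotated with membership in one or more of the nervous,
#' immune and endocrine systems.
#' @export
SYSTEMS <- c("nervous", "immune", "endocrine")

PLATFORMS <- c("GC-MS", "LC-MS", "1H-NMR", "multiple")
TRENDS <- c("up", "down", "unknown")

#' Analysis configuration
#'
#' Bundles the tunable constants of the pipeline: the pKd retention
#' threshold (default 5.52, the pKd of a 3 uM dissociation constant), the
#' comparator (strict "greater" by default), the DSWMP denominator reading
#' (`count_mode`), the pathway ranking depth `top_k`, and the exclusive hub
#' degree cutoff.
#'
#' @param threshold_pkd edge-retention threshold in pKd units, in [0, 15].
#' @param comparator `"greater"` (strict, default) or `"greater_equal"`.
#' @param count_mode DSWMP denominator: `"contributing_biomarkers"` (default;
#'   divide the pathway's docking-score sum by the number of biomarkers with
#'   at least one retained edge into the pathway), `"n_biomarkers"` (divide
#'   by the total biomarker count of the edge universe), or
#'   `"per_biomarker_edge_count"` (each biomarker's sum divided by its own
#'   pathway edge count, then summed).
#' @param top_k pathways reported per system (default 10).
#' @param hub_min_degree exclusive degree cutoff for hub selection
#'   (default 10: hubs have degree strictly greater than 10).
#' @param seed integer seed for any stochastic stage.
#' @return an object of class `study_config`.
#' @export
study_config <- function(threshold_pkd = 5.52,
                         comparator = c("greater", "greater_equal"),
                         count_mode = c("contributing_biomarkers",
                                        "n_biomarkers",
                                        "per_biomarker_edge_count"),
                         top_k = 10L,
                         hub_min_degree = 10L,
                         seed = 1L) {
  comparator <- match.arg(comparator)
  count_mode <- match.arg(count_mode)
  stopifnot(is.numeric(threshold_pkd), length(threshold_pkd) == 1L,
            is.finite(threshold_pkd))
  if (threshold_pkd < 0 || threshold_pkd > 15) {
    stop("`threshold_pkd` must lie in [0, 15] pKd", call. = FALSE)
  }
  top_k <- as.integer(top_k)
  if (is.na(top_k) || top_k < 1L) stop("`top_k` must be >= 1", call. = FALSE)
  hub_min_degree <- as.integer(hub_min_degree)
  if (is.na(hub_min_degree) || hub_min_degree < 0L) {
    stop("`hub_min_degree` must be >= 0", call. = FALSE)
  }
  structure(
    list(threshold_pkd = threshold_pkd, comparator = comparator,
         count_mode = count_mode, top_k = top_k,
         hub_min_degree = hub_min_degree, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("study_config:\n")
  cat(sprintf("  threshold: %.2f pKd (%s)\n", x$threshold_pkd,
              if (x$comparator == "greater") ">" else ">="))
  cat(sprintf("  count_mode: %s\n", x$count_mode))
  cat(sprintf("  top_k: %d   hub_min_degree: > %d   seed: %d\n",
              x$top_k, x$hub_min_degree, x$seed))
  invisible(x)
}

new_study_bundle <- function(biomarkers, enzymes, relations, targets,
                             scores, pathways) {
  structure(
    list(biomarkers = biomarkers, enzymes = enzymes, relations = relations,
         targets = targets, scores = scores, pathways = pathways),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("study_bundle:\n")
  cat(sprintf("  %d biomarkers, %d enzymes, %d biomarker-enzyme relations\n",
              nrow(x$biomarkers), nrow(x$enzymes), nrow(x$relations)))
  cat(sprintf("  %d targets; score matrix %d x %d (%d measured)\n",
              nrow(x$targets), nrow(x$scores), ncol(x$scores),
              sum(!is.na(x$scores))))
  cat(sprintf("  %d pathways (%d membership rows)\n",
              length(unique(x$pathways$pathway_id)), nrow(x$pathways)))
  invisible(x)
}

split_multi <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(v) trimws(v[nzchar(trimws(v))]))
}

join_multi <- function(x) {
  vapply(x, paste, character(1), collapse = ";")
}

detect_sep <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

read_table_file <- function(path, required, delimiter = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path, delimiter),
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Read and validate a complete study bundle
#'
#' Loads the plain-text tables of a study (biomarker catalog, enzyme catalog,
#' biomarker-enzyme relations, target catalog with system memberships,
#' docking-score matrix, pathway memberships), resolves all cross references
#' and returns a validated `study_bundle`. The score matrix may be supplied
#' either long form (`biomarker_id,target_id,pkd`) or wide form (first column
#' `biomarker_id`, one column per target accession); both yield identical
#' matrices. Delimiters are inferred from the extension (`.tsv`/`.tab`/`.txt`
#' = tab, otherwise comma) and can be overridden.
#'
#' @param dir directory holding the default file names
#'   (`biomarkers.csv`, `enzymes.csv`, `relations.csv`, `targets.csv`,
#'   `scores_long.csv` or `scores_wide.csv`, `pathways.csv`); individual
#'   paths override the directory lookup.
#' @param biomarkers,enzymes,relations,targets,scores_long,scores_wide,pathways
#'   explicit file paths (optional when `dir` is given).
#' @param delimiter field delimiter override (`","` or `"\t"`), default
#'   inferred per file.
#' @return a `study_bundle`.
#' @export
read_study_inputs <- function(dir = NULL,
                              biomarkers = NULL, enzymes = NULL,
                              relations = NULL, targets = NULL,
                              scores_long = NULL, scores_wide = NULL,
                              pathways = NULL, delimiter = NULL) {
  pick <- function(explicit, fname) {
    if (!is.null(explicit)) return(explicit)
    if (is.null(dir)) return(NULL)
    p <- file.path(dir, fname)
    if (file.exists(p)) p else NULL
  }
  p_bio <- pick(biomarkers, "biomarkers.csv")
  p_enz <- pick(enzymes, "enzymes.csv")
  p_rel <- pick(relations, "relations.csv")
  p_tar <- pick(targets, "targets.csv")
  p_sl  <- pick(scores_long, "scores_long.csv")
  p_sw  <- pick(scores_wide, "scores_wide.csv")
  p_pw  <- pick(pathways, "pathways.csv")
  for (nm in c("p_bio", "p_enz", "p_rel", "p_tar", "p_pw")) {
    if (is.null(get(nm))) {
      stop(sprintf("required input table missing: %s",
                   sub("^p_", "", nm)), call. = FALSE)
    }
  }
  if (is.null(p_sl) && is.null(p_sw)) {
    stop("a score table is required (scores_long or scores_wide)",
         call. = FALSE)
  }

  bio <- read_table_file(p_bio, c("id", "name", "platform", "trend"), delimiter)
  enz <- read_table_file(p_enz, c("id", "name", "functions"), delimiter)
  rel <- read_table_file(p_rel, c("biomarker_id", "enzyme_id"), delimiter)
  tar <- read_table_file(p_tar, c("id", "name", "systems"), delimiter)
  pw  <- read_table_file(p_pw, c("pathway_id", "pathway_name", "target_id"),
                         delimiter)

  enz$functions <- split_multi(enz$functions)
  tar$systems <- split_multi(tar$systems)

  if (!is.null(p_sl)) {
    sl <- read_table_file(p_sl, c("biomarker_id", "target_id", "pkd"),
                          delimiter)
    scores <- scores_from_long(sl, bio$id, tar$id, basename(p_sl))
  } else {
    sw <- read_table_file(p_sw, "biomarker_id", delimiter)
    scores <- scores_from_wide(sw)
  }

  bundle <- new_study_bundle(bio, enz, rel, tar, scores, pw)
  issues <- validate_study(bundle)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs)) {
    stop(paste0("study validation failed:\n",
                paste0("  - ", errs$message, collapse = "\n")),
         call. = FALSE)
  }
  bundle
}

scores_from_long <- function(sl, biomarker_ids, target_ids, src = "scores") {
  pkd <- suppressWarnings(as.numeric(sl$pkd))
  bad <- which(is.na(pkd) & nzchar(sl$pkd) & !toupper(sl$pkd) %in% c("NA", ""))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric pkd at row %d: '%s'",
                 src, bad[1], sl$pkd[bad[1]]), call. = FALSE)
  }
  dup <- duplicated(sl[c("biomarker_id", "target_id")])
  if (any(dup)) {
    stop(sprintf("%s: duplicate (biomarker, target) pair at row %d: (%s, %s)",
                 src, which(dup)[1], sl$biomarker_id[which(dup)[1]],
                 sl$target_id[which(dup)[1]]), call. = FALSE)
  }
  bids <- if (length(biomarker_ids)) biomarker_ids else unique(sl$biomarker_id)
  tids <- if (length(target_ids)) target_ids else unique(sl$target_id)
  m <- matrix(NA_real_, length(bids), length(tids),
              dimnames = list(bids, tids))
  keep <- sl$biomarker_id %in% bids & sl$target_id %in% tids
  m[cbind(sl$biomarker_id[keep], sl$target_id[keep])] <- pkd[keep]
  # dangling ids are reported by validate_study; keep them out of the matrix
  attr(m, "dangling") <- sl[!keep, c("biomarker_id", "target_id"), drop = FALSE]
  m
}

scores_from_wide <- function(sw) {
  bids <- sw$biomarker_id
  tids <- setdiff(names(sw), "biomarker_id")
  m <- matrix(NA_real_, length(bids), length(tids),
              dimnames = list(bids, tids))
  for (t in tids) {
    v <- sw[[t]]
    m[, t] <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
  }
  m
}

#' Write a study bundle to plain-text tables
#'
#' Inverse of [read_study_inputs()]: writes `biomarkers.csv`, `enzymes.csv`,
#' `relations.csv`, `targets.csv`, `scores_long.csv` and `pathways.csv` into
#' `dir`. Missing matrix entries are omitted from the long score table.
#'
#' @param bundle a `study_bundle`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, fname) {
    utils::write.csv(df, file.path(dir, fname), row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  }
  wr(bundle$biomarkers, "biomarkers.csv")
  enz <- bundle$enzymes
  enz$functions <- join_multi(enz$functions)
  wr(enz, "enzymes.csv")
  wr(bundle$relations, "relations.csv")
  tar <- bundle$targets
  tar$systems <- join_multi(tar$systems)
  wr(tar, "targets.csv")
  idx <- which(!is.na(bundle$scores), arr.ind = TRUE)
  sl <- data.frame(
    biomarker_id = rownames(bundle$scores)[idx[, 1]],
    target_id = colnames(bundle$scores)[idx[, 2]],
    pkd = bundle$scores[idx],
    stringsAsFactors = FALSE
  )
  sl <- sl[order(sl$biomarker_id, sl$target_id), , drop = FALSE]
  wr(sl, "scores_long.csv")
  wr(bundle$pathways, "pathways.csv")
  invisible(dir)
}

issue <- function(severity, message) {
  data.frame(severity = severity, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a study bundle
#'
#' Checks identifiers, cross references, score-matrix invariants and
#' accession shapes. Never throws: returns a deterministic, ordered
#' data.frame of issues with columns `severity` (`"error"`/`"warning"`) and
#' `message`; an empty frame means the bundle is clean. Accession-shape
#' deviations (HMDB/UniProt/hsa patterns) are warnings only, so non-KEGG
#' catalogs remain usable; dangling references, duplicate ids, negative or
#' non-finite scores, and system labels outside the nervous/immune/endocrine
#' universe are errors.
#'
#' @param bundle a `study_bundle`
#' @return data.frame of issues (zero rows when clean), errors first.
#' @export
validate_study <- function(bundle) {
  iss <- list()
  add <- function(sev, msg) iss[[length(iss) + 1L]] <<- issue(sev, msg)

  chk_dup <- function(ids, what) {
    d <- unique(ids[duplicated(ids)])
    for (x in d) add("error", sprintf("duplicate %s id: %s", what, x))
    empty <- which(!nzchar(ids) | is.na(ids))
    for (i in empty) add("error", sprintf("empty %s id at row %d", what, i))
  }
  chk_dup(bundle$biomarkers$id, "biomarker")
  chk_dup(bundle$enzymes$id, "enzyme")
  chk_dup(bundle$targets$id, "target")

  bad_trend <- which(!bundle$biomarkers$trend %in% TRENDS)
  for (i in bad_trend) {
    add("error", sprintf("biomarker %s: trend '%s' not in {%s}",
                         bundle$biomarkers$id[i], bundle$biomarkers$trend[i],
                         paste(TRENDS, collapse = ", ")))
  }
  bad_plat <- which(!bundle$biomarkers$platform %in% PLATFORMS)
  for (i in bad_plat) {
    add("warning", sprintf("biomarker %s: unrecognized platform '%s'",
                           bundle$biomarkers$id[i],
                           bundle$biomarkers$platform[i]))
  }

  # cross references
  for (i in which(!bundle$relations$biomarker_id %in% bundle$biomarkers$id)) {
    add("error", sprintf("relations row %d: unknown biomarker id '%s'",
                         i, bundle$relations$biomarker_id[i]))
  }
  for (i in which(!bundle$relations$enzyme_id %in% bundle$enzymes$id)) {
    add("error", sprintf("relations row %d: unknown enzyme id '%s'",
                         i, bundle$relations$enzyme_id[i]))
  }
  for (i in which(!bundle$pathways$target_id %in% bundle$targets$id)) {
    add("error", sprintf("pathways row %d: unknown target id '%s'",
                         i, bundle$pathways$target_id[i]))
  }

  # system membership
  for (i in seq_len(nrow(bundle$targets))) {
    sys <- bundle$targets$systems[[i]]
    if (length(sys) == 0) {
      add("error", sprintf("target %s: empty systems set",
                           bundle$targets$id[i]))
    } else {
      extra <- setdiff(sys, SYSTEMS)
      for (x in extra) {
        add("error", sprintf("target %s: unknown system label '%s'",
                             bundle$targets$id[i], x))
      }
    }
  }

  # score matrix
  sc <- bundle$scores
  dang <- attr(sc, "dangling")
  if (!is.null(dang) && nrow(dang)) {
    for (i in seq_len(nrow(dang))) {
      add("error", sprintf("score table: unresolved pair (%s, %s)",
                           dang$biomarker_id[i], dang$target_id[i]))
    }
  }
  chk_dup(rownames(sc), "score-matrix biomarker")
  chk_dup(colnames(sc), "score-matrix target")
  bad_cells <- which((!is.na(sc)) & (sc < 0 | !is.finite(sc)), arr.ind = TRUE)
  if (length(bad_cells)) {
    for (r in seq_len(nrow(bad_cells))) {
      i <- bad_cells[r, 1]; j <- bad_cells[r, 2]
      add("error", sprintf("score matrix cell (%s, %s): invalid pKd %s",
                           rownames(sc)[i], colnames(sc)[j],
                           format(sc[i, j])))
    }
  }
  for (x in setdiff(rownames(sc), bundle$biomarkers$id)) {
    add("error", sprintf("score matrix row '%s' not in biomarker catalog", x))
  }
  for (x in setdiff(colnames(sc), bundle$targets$id)) {
    add("error", sprintf("score matrix column '%s' not in target catalog", x))
  }

  # accession shapes: warnings only
  shape_warn <- function(ids, pattern, what, shape) {
    for (x in ids[!grepl(pattern, ids)]) {
      add("warning", sprintf("%s id '%s' does not match the %s shape",
                             what, x, shape))
    }
  }
  shape_warn(bundle$biomarkers$id, "^HMDB[0-9]{7}$", "biomarker", "HMDBnnnnnnn")
  shape_warn(unique(bundle$pathways$pathway_id), "^hsa[0-9]{5}$",
             "pathway", "hsannnnn")

  # coverage warnings
  orphan_bio <- setdiff(bundle$biomarkers$id, bundle$relations$biomarker_id)
  for (x in orphan_bio) {
    add("warning", sprintf("biomarker %s has no enzyme relations", x))
  }
  unpathed <- setdiff(bundle$targets$id, bundle$pathways$target_id)
  for (x in unpathed) {
    add("warning", sprintf("target %s belongs to no pathway", x))
  }

  if (!length(iss)) {
    return(data.frame(severity = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, iss)
  out <- out[order(match(out$severity, c("error", "warning")), out$message), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
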