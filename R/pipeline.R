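#' Run the full network-pharmacology pipeline
#'
#' Executes the stages in order on a study bundle: validation, MEI network
#' construction with degree tables, hub selection and enzyme-function
#' tally; docking-score thresholding and per-system MTI networks with
#' summaries, membership classes and the shared-target intersection; DSWMP
#' pathway scoring with top-k ranking and cross-system overlap. Returns a
#' self-describing report (config echoed, every number recomputable from
#' the inputs) and, when `out_dir` is given, writes TSV/SIF/GraphML/JSON
#' artifacts. Deterministic for fixed inputs and config.
#'
#' @param bundle a `study_bundle` (from [read_study_inputs()] or
#'   [gen_study()]); alternatively supply `config_path` pointing to a JSON
#'   config that names the input directory or requests simulation.
#' @param config a [study_config()].
#' @param out_dir optional artifact directory.
#' @param config_path optional JSON config file; fields `input_dir` or
#'   `simulate` (logical), plus any `study_config()` argument. Explicit
#'   `bundle`/`config` arguments override the file.
#' @return object of class `pipeline_report` (a nested list).
#' @export
run_pipeline <- function(bundle = NULL, config = study_config(),
                         out_dir = NULL, config_path = NULL) {
  if (!is.null(config_path)) {
    cfg_file <- jsonlite::read_json(config_path, simplifyVector = TRUE)
    cfg_args <- cfg_file[intersect(names(cfg_file),
                                   names(formals(study_config)))]
    if (length(cfg_args)) config <- do.call(study_config, cfg_args)
    if (is.null(bundle)) {
      if (!is.null(cfg_file$input_dir)) {
        bundle <- read_study_inputs(dir = cfg_file$input_dir)
      } else if (isTRUE(cfg_file$simulate)) {
        bundle <- gen_study(simulation_spec(seed = config$seed))
      } else {
        stop("config must provide `input_dir` or `simulate: true`",
             call. = FALSE)
      }
    }
  }
  stopifnot(inherits(bundle, "study_bundle"),
            inherits(config, "study_config"))
  message(sprintf(
    "pipeline: threshold=%.2f pKd (%s), count_mode=%s, top_k=%d, seed=%d",
    config$threshold_pkd, config$comparator, config$count_mode,
    config$top_k, config$seed))

  # stage 1: validate
  issues <- validate_study(bundle)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs)) {
    stop(paste0("stage validate: bundle has errors:\n",
                paste0("  - ", errs$message, collapse = "\n")),
         call. = FALSE)
  }

  # stage 2: MEI
  mei <- build_mei_network(bundle$relations, bundle$biomarkers,
                           bundle$enzymes)
  mei_bio_deg <- node_degrees(mei, "biomarker")
  mei_enz_deg <- node_degrees(mei, "enzyme")
  mei_hubs <- select_hubs(mei_bio_deg, config$hub_min_degree)
  fun_tally <- enzyme_function_tally(mei, bundle$enzymes)

  # stage 3: threshold + MTI
  rule <- threshold_rule(config$threshold_pkd, config$comparator)
  edges <- threshold_edges(bundle$scores, rule)
  nets <- lapply(stats::setNames(SYSTEMS, SYSTEMS), function(sys) {
    build_mti_network(edges, sys, bundle$targets)
  })
  summaries <- lapply(nets, summarize_network)
  classes <- system_membership_classes(bundle$targets)
  shared <- shared_targets(nets)
  edges_by_system <- lapply(nets, function(n) {
    e <- n$edges
    data.frame(biomarker_id = e$left, target_id = e$right, pkd = e$weight,
               stringsAsFactors = FALSE)
  })

  # stage 4: DSWMP
  scores <- score_all_pathways(edges_by_system, bundle$pathways,
                               count_mode = config$count_mode,
                               n_biomarkers = nrow(bundle$scores))
  top <- top_k_pathways(scores, config$top_k)
  overlap <- cross_system_overlap(top)

  report <- structure(
    list(config = unclass(config),
         validation = issues,
         mei = list(network = mei,
                    biomarker_degrees = mei_bio_deg,
                    enzyme_degrees = mei_enz_deg,
                    hubs = mei_hubs,
                    function_tally = fun_tally),
         mti = list(networks = nets, summaries = summaries,
                    membership_classes = classes,
                    membership_counts = attr(classes, "counts"),
                    shared_targets = shared,
                    n_edges_total = nrow(edges)),
         dswmp = list(scores = scores, top = top,
                      alluvial = overlap$alluvial,
                      overlap_classes = overlap$classes),
         tool = list(package = "dswmpnet",
                     version = as.character(utils::packageVersion("dswmpnet")),
                     timestamp = format(Sys.time(), tz = "UTC",
                                        "%Y-%m-%dT%H:%M:%SZ"))),
    class = "pipeline_report"
  )
  if (!is.null(out_dir)) write_report_artifacts(report, bundle, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  config: threshold %.2f pKd (%s), count_mode %s, top_k %d\n",
              x$config$threshold_pkd, x$config$comparator,
              x$config$count_mode, x$config$top_k))
  s <- summarize_network(x$mei$network)
  cat(sprintf("  MEI: %d biomarkers x %d enzymes, %d edges; %d hub biomarkers\n",
              s$n_left, s$n_right, s$n_edges, nrow(x$mei$hubs)))
  for (sys in names(x$mti$summaries)) {
    sm <- x$mti$summaries[[sys]]
    cat(sprintf(
      "  MTI %-9s: %d biomarkers, %d targets, %d edges (means %.2f / %.2f)%s\n",
      sys, sm$n_left, sm$n_right, sm$n_edges,
      sm$mean_right_per_left_rounded, sm$mean_left_per_right_rounded,
      if (sm$empty) " [empty]" else ""))
  }
  cat(sprintf("  shared targets across systems: %d\n",
              length(x$mti$shared_targets)))
  cat(sprintf("  DSWMP: %d scored (system, pathway) pairs; top-%d per system\n",
              nrow(x$dswmp$scores), x$config$top_k))
  invisible(x)
}

write_report_artifacts <- function(report, bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, fname) {
    utils::write.table(df, file.path(out_dir, fname), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  tsv(report$mei$biomarker_degrees, "mei_biomarker_degrees.tsv")
  tsv(report$mei$enzyme_degrees, "mei_enzyme_degrees.tsv")
  tsv(report$mei$hubs, "mei_hub_biomarkers.tsv")
  tsv(report$mei$function_tally, "mei_function_tally.tsv")
  write_sif(report$mei$network, file.path(out_dir, "mei_network.sif"))
  write_graphml(report$mei$network, file.path(out_dir, "mei_network.graphml"))
  summ <- do.call(rbind, lapply(names(report$mti$summaries), function(sys) {
    s <- report$mti$summaries[[sys]]
    data.frame(system = sys, n_biomarkers = s$n_left, n_targets = s$n_right,
               n_edges = s$n_edges,
               mean_targets_per_biomarker = s$mean_right_per_left_rounded,
               mean_biomarkers_per_target = s$mean_left_per_right_rounded,
               empty = s$empty, stringsAsFactors = FALSE)
  }))
  tsv(summ, "mti_summaries.tsv")
  tsv(as.data.frame(report$mti$membership_classes),
      "target_membership_classes.tsv")
  tsv(data.frame(target_id = report$mti$shared_targets),
      "shared_targets.tsv")
  for (sys in names(report$mti$networks)) {
    net <- report$mti$networks[[sys]]
    if (nrow(net$edges)) {
      write_sif(net, file.path(out_dir, sprintf("mti_%s.sif", sys)))
      write_graphml(net, file.path(out_dir, sprintf("mti_%s.graphml", sys)))
    }
  }
  tsv(report$dswmp$scores, "dswmp_scores.tsv")
  tsv(report$dswmp$top, "dswmp_top.tsv")
  tsv(report$dswmp$alluvial, "dswmp_alluvial.tsv")
  tsv(report$dswmp$overlap_classes, "dswmp_overlap_classes.tsv")
  json_report <- list(
    config = report$config,
    mti_summaries = summ,
    membership_counts = as.list(report$mti$membership_counts),
    shared_targets = report$mti$shared_targets,
    top_pathways = report$dswmp$top,
    overlap_classes = report$dswmp$overlap_classes,
    tool = report$tool
  )
  jsonlite::write_json(json_report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
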