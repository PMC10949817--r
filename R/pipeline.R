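.pipeline_stages <- c("sc", "hbonds", "disulfides", "rmsd", "pore", "graph")

#' Read and validate a pipeline configuration
#'
#' YAML configuration with the input path(s), the stages to run, a
#' \code{params:} block mirroring \code{\link{analysis_parameters}}
#' field names, the output directory and a seed. Validation happens
#' before any computation: unknown stage names, missing inputs and a
#' graph stage without the sc stage it consumes are all rejected here.
#'
#' @param path YAML file, or a pre-parsed list.
#' @return A validated configuration list of class
#'   \code{"gj_pipeline_config"}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(cfg$stages)) cfg$stages <- .pipeline_stages
  bad <- setdiff(cfg$stages, .pipeline_stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; valid stages: ", paste(.pipeline_stages, collapse = ", "),
         call. = FALSE)
  if ("graph" %in% cfg$stages && !"sc" %in% cfg$stages)
    stop("the graph stage consumes the sc stage output; add \"sc\" to stages",
         call. = FALSE)
  if (is.null(cfg$trajectory) && is.null(cfg$structure))
    stop("config needs a 'trajectory' or 'structure' input path", call. = FALSE)
  input <- if (!is.null(cfg$trajectory)) cfg$trajectory else cfg$structure
  if (!file.exists(input))
    stop("input file does not exist: ", input, call. = FALSE)
  if (is.null(cfg$output_dir)) stop("config needs an 'output_dir'", call. = FALSE)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$frame_interval_ps)) cfg$frame_interval_ps <- 10
  if (is.null(cfg$scope)) cfg$scope <- "extracellular"
  if (is.null(cfg$chains_counted)) cfg$chains_counted <- "all"
  if (is.null(cfg$stride)) cfg$stride <- 1L
  cfg$params <- if (is.null(cfg$params)) analysis_parameters() else
    do.call(analysis_parameters, cfg$params)
  class(cfg) <- "gj_pipeline_config"
  cfg
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages of a docking-analysis run over one
#' trajectory: stabilization-center dynamics (sc), the three
#' hydrogen-bond detectors (hbonds), geometric disulfide read-out on the
#' first frame (disulfides), the extracellular RMSD series (rmsd), the
#' minimum-channel-diameter series (pore) and the residue connectivity
#' graph (graph). Each stage writes a TSV next to a machine-readable
#' \code{report.json}; parameters, seed and input checksums go to
#' \code{run.log}. A stage failure aborts the run naming the stage. With
#' a fixed seed the report is byte-reproducible (timings live only in
#' the log).
#'
#' @param config path to a YAML configuration, or a list (see
#'   \code{\link{read_pipeline_config}}).
#' @return The report, invisibly (also written to
#'   \code{output_dir/report.json}).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "gj_pipeline_config")) config else
    read_pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- connexin_annotation()
  params <- cfg$params
  input <- if (!is.null(cfg$trajectory)) cfg$trajectory else cfg$structure
  traj <- if (!is.null(cfg$trajectory))
    read_trajectory(cfg$trajectory, cfg$frame_interval_ps)
  else {
    s <- read_structure(cfg$structure)
    gj_trajectory(s, matrix(as.numeric(t(coords(s))), nrow = 1L),
                  cfg$frame_interval_ps)
  }

  log_lines <- c(
    paste0("gjdock pipeline run"),
    paste0("input: ", input, " (md5 ", unname(tools::md5sum(input)), ")"),
    paste0("frames: ", n_frames(traj), ", dt = ", traj$frame_interval_ps,
           " ps, stride = ", cfg$stride),
    paste0("seed: ", cfg$seed),
    paste0("stages: ", paste(cfg$stages, collapse = ", ")),
    "parameters:",
    paste0("  ", utils::capture.output(utils::str(unclass(params),
                                                  give.attr = FALSE))))
  report <- list(input = input, n_frames = n_frames(traj),
                 frame_interval_ps = traj$frame_interval_ps,
                 seed = cfg$seed, stages = list())
  sc_result <- NULL

  run_stage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage %-10s %.2f s", stage,
                                       proc.time()[["elapsed"]] - t0))
    out
  }

  for (stage in cfg$stages) {
    report$stages[[stage]] <- switch(
      stage,
      disulfides = run_stage("disulfides", function() {
        ss <- detect_disulfides(frame_structure(traj, 1L), params = params)
        .write_tsv(ss, file.path(cfg$output_dir, "disulfides.tsv"))
        list(n_disulfides = nrow(ss), n_canonical = sum(ss$canonical))
      }),
      sc = run_stage("sc", function() {
        ts <- sc_timeseries(traj, scope = cfg$scope, params = params,
                            annotation = ann, stride = cfg$stride)
        kept <- filter_extracellular(ts$stability, ann,
                                     params$sc_min_stability_fraction)
        .write_tsv(ts$stability, file.path(cfg$output_dir, "sc.tsv"))
        .write_tsv(ts$per_frame, file.path(cfg$output_dir, "sc_frames.tsv"))
        sc_result <<- kept
        list(n_pairs = nrow(ts$stability), n_reportable = nrow(kept),
             n_trans_gj = sum(kept$class == "trans-GJ"))
      }),
      hbonds = run_stage("hbonds", function() {
        out <- list()
        for (cat in c("trans_gj", "cys_cys", "cys_interface")) {
          hb <- tryCatch(
            hbond_timeseries(traj, cat, chains_counted = cfg$chains_counted,
                             params = params, annotation = ann,
                             stride = cfg$stride),
            error = function(e) NULL)  # e.g. no hydrogens for this category
          if (is.null(hb)) { out[[cat]] <- NA; next }
          .write_tsv(hb$counts,
                     file.path(cfg$output_dir, paste0("hb_", cat, ".tsv")))
          out[[cat]] <- list(mean_bonds = mean(hb$counts$n_bonds),
                             max_bonds = max(hb$counts$n_bonds))
        }
        out
      }),
      rmsd = run_stage("rmsd", function() {
        r <- extracellular_rmsd_series(traj, ann)
        .write_tsv(r, file.path(cfg$output_dir, "rmsd.tsv"))
        list(mean_rmsd = mean(r$rmsd), max_rmsd = max(r$rmsd))
      }),
      pore = run_stage("pore", function() {
        pz <- if (!is.null(cfg$pore)) cfg$pore else list()
        md <- min_diameter_series(
          traj, step = if (is.null(pz$step)) 0.5 else pz$step,
          r_max = if (is.null(pz$r_max)) 15 else pz$r_max,
          window = if (is.null(pz$window)) "extracellular" else
            unlist(pz$window),
          seed = cfg$seed, annotation = ann, params = params,
          stride = cfg$stride)
        .write_tsv(md, file.path(cfg$output_dir, "pore.tsv"))
        list(min_diameter = suppressWarnings(min(md$min_diameter,
                                                 na.rm = TRUE)))
      }),
      graph = run_stage("graph", function() {
        g <- build_sc_graph(sc_result)
        export_graph(g, file.path(cfg$output_dir, "graph.graphml"),
                     "graphml")
        export_graph(g, file.path(cfg$output_dir, "sc_edges.tsv"), "tsv")
        list(n_nodes = nrow(g$nodes), n_edges = nrow(g$edges))
      }))
  }

  json <- file.path(cfg$output_dir, "report.json")
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(log_lines, file.path(cfg$output_dir, "run.log"))
  invisible(report)
}
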