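STAGE_DIRS <- c(image_embedding = "1.image_embedding",
                ppi_embedding = "2.ppi_embedding",
                coembedding = "3.coembedding",
                hierarchy = "4.hierarchy",
                hierarchyeval = "5.hierarchyeval")

# Global seed fans out to per-stage seeds: resuming a later stage must not
# shift the randomness of untouched earlier ones.
stage_seed <- function(seed, idx) (abs(seed) * 131L + idx) %% (.Machine$integer.max - 1L) + 1L

#' Assemble a pipeline configuration
#'
#' @param outdir output root; the five stage directories are created
#'   beneath it.
#' @param edge_list PPI edge list TSV path.
#' @param image_features per-image feature TSV path.
#' @param reference optional reference-sets TSV for the evaluation stage.
#' @param min_score confidence filter applied to the edge list.
#' @param seed global seed (fans out per stage).
#' @param resume skip stages whose directories already validate.
#' @param ppi,image,coembedding,hierarchy,eval per-stage parameter
#'   blocks (lists; see the respective stage functions).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(outdir, edge_list, image_features,
                            reference = NULL, min_score = 0.7, seed = 1,
                            resume = FALSE, ppi = list(), image = list(),
                            coembedding = list(), hierarchy = list(),
                            eval = list()) {
  structure(list(outdir = outdir, edge_list = edge_list,
                 image_features = image_features, reference = reference,
                 min_score = min_score, seed = as.integer(seed),
                 resume = resume, ppi = ppi, image = image,
                 coembedding = coembedding, hierarchy = hierarchy,
                 eval = eval),
            class = "PipelineConfig")
}

#' Run the full cell-mapping pipeline
#'
#' Executes the five stages in fixed order -- image embedding, PPI
#' embedding, co-embedding, hierarchy generation, hierarchy evaluation --
#' each writing its outputs, log and provenance record into a numbered
#' directory under `config$outdir`. With `resume = TRUE`, stages whose
#' directories already pass [validate_stage()] are left untouched.
#'
#' @param config a [pipeline_config()] (or a path to a JSON file of the
#'   same fields).
#' @return Invisibly, a list with the per-stage directories, the final
#'   `HierarchyDAG`, and the evaluation result (or `NULL`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(pipeline_config, cfg)
  }
  dirs <- file.path(config$outdir, STAGE_DIRS)
  names(dirs) <- names(STAGE_DIRS)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  done <- function(d) isTRUE(config$resume) && dir.exists(d) &&
    isTRUE(validate_stage(d)$valid)
  run_stage <- function(name, fn) {
    d <- dirs[[name]]
    if (done(d)) {
      message(sprintf("[%s] valid stage directory found; skipping", name))
      return(invisible(NULL))
    }
    unlink(d, recursive = TRUE)
    tryCatch(fn(d), error = function(e) {
      cm_stop(sprintf("pipeline aborted in stage '%s': %s", name,
                      conditionMessage(e)), "cm_stage_error")
    })
  }

  run_stage("image_embedding", function(d) {
    do.call(image_embed, c(list(table = config$image_features, outdir = d),
                           config$image))
  })
  run_stage("ppi_embedding", function(d) {
    net <- read_edge_list(config$edge_list, min_score = config$min_score)
    s <- stage_seed(config$seed, 2L)
    args <- utils::modifyList(list(network = net, outdir = d, seed = s,
                                   inputs = config$edge_list), config$ppi)
    if (is.null(args$sg_config))
      args$sg_config <- do.call(skipgram_config,
                                c(list(seed = s), config$ppi$sg %||% list()))
    args$sg <- NULL
    do.call(ppi_embed, args)
  })
  run_stage("coembedding", function(d) {
    cc <- do.call(coembed_config,
                  utils::modifyList(list(seed = stage_seed(config$seed, 3L)),
                                    config$coembedding))
    coembed(dirs[["ppi_embedding"]], dirs[["image_embedding"]], d, config = cc)
  })
  run_stage("hierarchy", function(d) {
    hp <- do.call(hierarchy_params, config$hierarchy)
    generate_hierarchy(dirs[["coembedding"]], d, params = hp,
                       seed = stage_seed(config$seed, 4L))
  })
  evalres <- NULL
  run_stage("hierarchyeval", function(d) {
    dag <- read_hierarchy(dirs[["hierarchy"]])
    if (is.null(config$reference)) {
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
      export_naming_requests(dag, file.path(d, "naming_requests.json"))
      stage_log(d, "hierarchyeval", "no reference provided; naming requests only")
      register_stage(d, inputs = dirs[["hierarchy"]], params = list(),
                     stage_name = "hierarchyeval")
    } else {
      evalres <<- do.call(hierarchy_eval,
                          c(list(hierarchy = dirs[["hierarchy"]],
                                 reference = config$reference, outdir = d),
                            config$eval))
    }
  })

  dag <- read_hierarchy(dirs[["hierarchy"]])
  invisible(list(dirs = as.list(dirs), dag = dag, evaluation = evalres,
                 config = config))
}

#' Validate an externally produced stage directory
#'
#' Checks that `external_dir` contains files matching the named stage's
#' output schema, so downstream stages can consume it in place of the
#' built-in implementation. A missing provenance record is reported as a
#' warning, not an error (external inputs are declared, not registered).
#'
#' @param stage_name one of `"image_embedding"`, `"ppi_embedding"`,
#'   `"coembedding"`, `"hierarchy"`.
#' @param external_dir candidate directory.
#' @return List with `ok` (logical), `issues`, `warnings`.
#' @export
substitute_stage <- function(stage_name, external_dir) {
  cm_assert(stage_name %in% names(STAGE_DIRS)[1:4],
            sprintf("unknown stage '%s'", stage_name))
  issues <- character(); warnings <- character()
  check_embedding <- function() {
    f <- tryCatch(find_embedding_file(external_dir),
                  error = function(e) {issues <<- c(issues, conditionMessage(e)); NULL})
    if (!is.null(f))
      tryCatch(invisible(read_embedding_tsv(f)),
               error = function(e) issues <<- c(issues, conditionMessage(e)))
  }
  if (stage_name %in% c("image_embedding", "ppi_embedding", "coembedding")) {
    check_embedding()
  } else {
    for (f in c("hierarchy_edges.tsv", "hierarchy_nodes.tsv"))
      if (!file.exists(file.path(external_dir, f)))
        issues <- c(issues, sprintf("missing %s", f))
    if (length(issues) == 0L)
      tryCatch(invisible(read_hierarchy(external_dir)),
               error = function(e) issues <<- c(issues, conditionMessage(e)))
  }
  if (!file.exists(file.path(external_dir, PROVENANCE_FILE)))
    warnings <- c(warnings, "no provenance record (external input, declared not registered)")
  list(stage = stage_name, ok = length(issues) == 0L,
       issues = issues, warnings = warnings)
}

#' Emit a template provenance description for external inputs
#'
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
example_provenance <- function(path) {
  tpl <- list(name = "My cell map", organization = "My lab",
              project = "Subcellular mapping",
              cell_line = "U2OS", treatment = "untreated",
              gene_set = "600 proteins across 3 compartments",
              inputs = list(
                list(file = "ppi_edgelist.tsv",
                     description = "high-confidence PPI subnetwork"),
                list(file = "image_features.tsv",
                     description = "per-image classifier features")))
  jsonlite::write_json(tpl, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
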