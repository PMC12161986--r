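PROVENANCE_FILE <- "ro-crate-metadata.json"

stage_record_id <- function(stage_name, digests) {
  combined <- paste(sort(paste(names(digests), digests, sep = ":")), collapse = ";")
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(combined, tf)
  paste0(stage_name, "@", substr(unname(tools::md5sum(tf)), 1, 12))
}

resolve_input <- function(x) {
  if (is.list(x)) return(x)  # already a resolved descriptor
  x <- as.character(x)
  meta <- file.path(x, PROVENANCE_FILE)
  if (dir.exists(x) && file.exists(meta)) {
    rec <- jsonlite::read_json(meta)
    list(id = rec$record_id, type = "stage", path = x)
  } else if (dir.exists(x)) {
    # unregistered directory: declared external input, no digest
    list(id = paste0("external-dir:", basename(x)), type = "external", path = x)
  } else if (file.exists(x)) {
    list(id = paste0("external@", substr(unname(tools::md5sum(x)), 1, 12)),
         type = "external", path = x)
  } else {
    list(id = x, type = "declared", path = NA_character_)
  }
}

#' Register a pipeline stage directory with a provenance record
#'
#' Writes a simplified RO-Crate-style JSON document
#' (`ro-crate-metadata.json`) into `stage_dir` recording the stage name,
#' resolved input artifact ids, the flat parameter map, software version,
#' timestamps, and an output manifest with an MD5 digest per file.
#'
#' @param stage_dir directory containing the stage outputs.
#' @param inputs character vector of input paths (prior stage directories
#'   or external files) or pre-resolved descriptors.
#' @param params flat named list of stage parameters.
#' @param stage_name stage label; defaults to `basename(stage_dir)`.
#' @return The StageRecord, invisibly (a named list mirroring the JSON).
#' @export
register_stage <- function(stage_dir, inputs = character(), params = list(),
                           stage_name = basename(stage_dir)) {
  cm_assert(dir.exists(stage_dir), sprintf("stage_dir %s does not exist", stage_dir))
  files <- setdiff(list.files(stage_dir, recursive = TRUE), PROVENANCE_FILE)
  paths <- file.path(stage_dir, files)
  digests <- unname(tools::md5sum(paths))
  names(digests) <- files
  resolved <- lapply(inputs, resolve_input)
  rec <- list(
    record_id = stage_record_id(stage_name, digests),
    stage_name = stage_name,
    input_artifact_ids = lapply(resolved, function(r) r[c("id", "type")]),
    parameter_map = params,
    software = list(package = "cellmapr",
                    version = as.character(utils::packageVersion("cellmapr"))),
    timestamps = list(registered = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    output_file_manifest = lapply(seq_along(files), function(i) {
      list(file = files[i], md5 = unname(digests[i]),
           size = file.size(paths[i]))
    })
  )
  jsonlite::write_json(rec, file.path(stage_dir, PROVENANCE_FILE),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rec)
}

#' Validate a registered stage directory
#'
#' Re-reads the stage's provenance document and verifies that every
#' manifest entry still exists and that its digest matches the file on
#' disk.
#'
#' @param stage_dir directory previously passed to [register_stage()].
#' @return A list with `valid` (logical), `missing` and `mismatched`
#'   (character vectors of offending manifest files), and `record`.
#' @export
validate_stage <- function(stage_dir) {
  meta <- file.path(stage_dir, PROVENANCE_FILE)
  if (!file.exists(meta))
    return(list(valid = FALSE, missing = PROVENANCE_FILE,
                mismatched = character(), record = NULL))
  rec <- jsonlite::read_json(meta)
  missing <- character(); mismatched <- character()
  for (entry in rec$output_file_manifest) {
    p <- file.path(stage_dir, entry$file)
    if (!file.exists(p)) {
      missing <- c(missing, entry$file)
    } else if (!identical(unname(tools::md5sum(p)), entry$md5)) {
      mismatched <- c(mismatched, entry$file)
    }
  }
  list(valid = length(missing) + length(mismatched) == 0L,
       missing = missing, mismatched = mismatched, record = rec)
}

stage_log <- function(stage_dir, stage_name, lines) {
  logf <- file.path(stage_dir, paste0(stage_name, ".log"))
  stamped <- paste(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), lines)
  cat(stamped, file = logf, sep = "\n", append = TRUE)
  invisible(logf)
}
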