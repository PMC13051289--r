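#' Read a pipeline configuration file (YAML or JSON)
#'
#' The file may contain sections `loss`, `lora`, `train`, and `data`; any
#' missing section or field falls back to the study defaults baked into
#' [loss_config()], [lora_spec()] and [train_config()]. Unknown field names
#' are an error, so typos do not silently revert to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `loss` ([loss_config()]), `lora`
#'   ([lora_spec()]), `train` ([train_config()]), `data` (list, as given).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  build <- function(section, fn) {
    args <- raw[[section]] %||% list()
    known <- names(formals(fn))
    bad <- setdiff(names(args), known)
    if (length(bad) > 0) {
      stop("unknown field(s) in '", section, "' section: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    do.call(fn, args)
  }
  list(
    loss = build("loss", loss_config),
    lora = build("lora", lora_spec),
    train = build("train", train_config),
    data = raw$data %||% list()
  )
}

#' Write a pipeline configuration to YAML
#'
#' @param config A list as returned by [read_pipeline_config()] (or any
#'   subset of its sections).
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::write_yaml(lapply(config, strip), path)
  invisible(path)
}
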