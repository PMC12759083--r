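#' @title Readers, writers and configuration
#' @name io_cli
#' @description Plain-text I/O for the pipeline's tables and images: guide
#'   count TSVs, flow-event CSVs, multi-page TIFF image stacks with a JSON
#'   sidecar, and a YAML run configuration with validated keys and defaults
#'   equal to the published thresholds.
NULL

#' Read / write a guide count table (TSV)
#'
#' Canonical format: tab-separated with header
#' `guide_id  gene  <rep columns...>`. `write_guide_counts()` followed by
#' `read_guide_counts()` is byte-preserving for canonical tables.
#'
#' @param path file path.
#' @param table a guide count data frame.
#' @return `read_guide_counts()`: the data frame; `write_guide_counts()`:
#'   `path`, invisibly.
#' @export
read_guide_counts <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  tb <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("guide_id", "gene") %in% names(tb)))
    stop_input("%s lacks guide_id/gene columns", path)
  tb
}

#' @rdname read_guide_counts
#' @export
write_guide_counts <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a flow-cytometry event table (CSV)
#'
#' One row per event; one column per channel plus any metadata columns
#' (a logical `positive` column survives the round trip).
#'
#' @param path file path.
#' @param events event data frame.
#' @return `read_flow_events()`: the data frame; `write_flow_events()`:
#'   `path`, invisibly.
#' @export
read_flow_events <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_flow_events
#' @export
write_flow_events <- function(events, path) {
  utils::write.csv(events, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an image stack as multi-page TIFF plus JSON sidecar
#'
#' One 32-bit float page per channel, values divided by the stack maximum;
#' the sidecar (`<path>.json`) records channel names and the scale so the
#' raw intensities round-trip (to float32 precision).
#'
#' @param stack an [image_stack()].
#' @param path TIFF path (sidecar written next to it).
#' @return `write_image_stack()`: `path`, invisibly; `read_image_stack()`:
#'   the [image_stack()].
#' @export
write_image_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack")) stop_input("'stack' must be an image_stack")
  scale <- max(1, max(vapply(stack$channels, max, numeric(1))))
  pages <- lapply(stack$channels, function(ch) ch / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(channels = names(stack$channels), scale = scale)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) stop_input("missing sidecar: %s", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$channels))
    stop_input("page count does not match sidecar channel list")
  chans <- lapply(pages, function(p) p * meta$scale)
  names(chans) <- meta$channels
  image_stack(chans)
}

# Defaults equal to the published thresholds wherever one exists.
default_run_config <- function() {
  list(
    bonferroni_mode = "standard",
    aggregation = "best_guide_pair",
    screen = list(
      pseudocount = 0.5,
      alpha = 0.05,
      lfc_activator = -1,
      lfc_activator_diff = -1.25,
      lfc_facilitator = 1
    ),
    flow = list(
      keima_spillover = 0.10,
      bfp_quantile = 0.95
    ),
    image = list(
      threshold = c(80, 255),
      n_rand = 20,
      block = 5,
      shuffle = "block"
    ),
    proteomics = list(
      lfc_cut = 1.0,
      fdr_alpha = 0.05
    )
  )
}

merge_config <- function(defaults, user, prefix = "") {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(defaults))
      stop_config("unknown configuration key: '%s'", full)
    if (is.list(defaults[[key]]) && !is.list(user[[key]]))
      stop_config("configuration key '%s' must be a mapping", full)
    defaults[[key]] <- if (is.list(defaults[[key]]))
      merge_config(defaults[[key]], user[[key]], paste0(full, "."))
    else user[[key]]
  }
  defaults
}

#' Load a YAML run configuration
#'
#' Missing keys are filled with defaults (which equal the published
#' thresholds: activator log2fc cuts -1 / -1.25, facilitator cut +1,
#' 8-bit mask window 80-255, 20 randomizations, keima spillover 0.10,
#' proteomics lfc cut 1.0); unknown keys are rejected by name. An empty file
#' yields all defaults.
#'
#' @param path YAML file path.
#' @return a `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("no such configuration file: %s", path)
  user <- tryCatch(yaml::read_yaml(path),
                   error = function(e) stop_config("cannot parse %s: %s",
                                                   path, conditionMessage(e)))
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop_config("configuration root must be a mapping")
  cfg <- merge_config(default_run_config(), user)
  if (!cfg$bonferroni_mode %in% c("standard", "as_printed"))
    stop_config("bonferroni_mode must be 'standard' or 'as_printed'")
  if (!cfg$aggregation %in% c("best_guide_pair", "mean"))
    stop_config("aggregation must be 'best_guide_pair' or 'mean'")
  structure(cfg, class = "run_config")
}
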