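#' Write a sweep table to CSV with a manifest sidecar
#'
#' Writes the sweep as a wide CSV (one row per scenario, full floating-point
#' precision so a read-back reproduces the values exactly) and a
#' JSON manifest recording the package version, timestamp, preset, grids,
#' coefficient provenance and constants. Byte-identical CSV output for
#' repeated identical sweeps (the manifest carries the timestamp, not the
#' CSV).
#'
#' @param x A `"sweep_table"` from [run_sweep()] (any tibble is accepted).
#' @param path Output CSV path.
#' @param manifest Manifest path (default `paste0(path, ".manifest.json")`);
#'   `NULL` suppresses the manifest.
#' @param command Free-text description of the producing command, stored in
#'   the manifest.
#' @param constants Constant set recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(x, path, manifest = paste0(path, ".manifest.json"),
                            command = "run_sweep", constants = ox_constants()) {
  readr::write_csv(x, path)
  if (!is.null(manifest)) {
    write_manifest(manifest,
                   command = command,
                   outputs = path,
                   preset = attr(x, "preset"),
                   grids = attr(x, "grids"),
                   b0 = attr(x, "b0"),
                   hct_mode = attr(x, "hct_mode"),
                   profile_mode = attr(x, "profile_mode"),
                   coefficient_provenance =
                     as.list(attr(x, "coefficient_provenance")),
                   constants = unclass(constants))
  }
  invisible(path)
}

#' Read back a sweep CSV
#'
#' Uses the correctly rounded base-R float parser so that the shortest
#' round-trip representations written by [write_sweep_csv()] reproduce the
#' original doubles bit for bit.
#'
#' @param path CSV path written by [write_sweep_csv()].
#' @return A tibble with the same values to full precision.
#' @export
read_sweep_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write a run manifest
#'
#' Every command-line invocation emits exactly one manifest describing what
#' produced which files: command, inputs, seed (if any), outputs, package
#' version and timestamp.
#'
#' @param path Manifest path (JSON).
#' @param command Command description.
#' @param ... Further named fields stored verbatim.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, ...) {
  manifest <- c(
    list(
      command = command,
      package = "hyperoxr1",
      version = as.character(utils::packageVersion("hyperoxr1")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    list(...)
  )
  manifest <- manifest[!vapply(manifest, is.null, logical(1))]
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
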