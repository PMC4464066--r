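#' Build a run manifest
#'
#' A manifest records everything needed to reproduce a run: the tool
#' version, every user-set option, input file names with MD5 content
#' hashes, output file names and the random seed. It is written as a single
#' JSON document so downstream tooling in any language can parse it.
#'
#' @param options named list of user options (values must be JSON
#'   serializable: atomic vectors and lists thereof).
#' @param inputs character vector of input file paths (hashed when they
#'   exist).
#' @param outputs character vector of output file paths.
#' @param seed integer random seed of the run, or `NULL` (recorded as
#'   null).
#' @return object of class `run_manifest`.
#' @export
run_manifest <- function(options = list(), inputs = character(),
                         outputs = character(), seed = NULL) {
  check_serializable(options)
  hash <- function(p) if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
  structure(list(
    tool = "tmwas",
    tool_version = as.character(utils::packageVersion("tmwas")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (is.null(seed)) NA else as.integer(seed),
    options = options,
    inputs = lapply(stats::setNames(inputs, basename(inputs)),
                    function(p) list(path = p, md5 = hash(p))),
    outputs = as.list(outputs)
  ), class = "run_manifest")
}

check_serializable <- function(x, where = "options") {
  ok <- function(v) is.null(v) || is.atomic(v) || (is.list(v) && all(vapply(v, ok, logical(1))))
  if (!ok(x))
    stop("unserializable value in ", where,
         ": only atomic vectors and lists thereof are allowed", call. = FALSE)
  invisible(x)
}

#' Write / read a run manifest as JSON
#'
#' @param manifest a [run_manifest()].
#' @param path file path of the JSON document.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   returns the parsed `run_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       null = "null", na = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  m$outputs <- as.list(unlist(m$outputs))
  class(m) <- "run_manifest"
  m
}

#' Compare two manifests ignoring timestamps
#'
#' Two runs with identical options, inputs and outputs produce manifests
#' equal under this comparison even though their creation timestamps
#' differ.
#'
#' @param a,b `run_manifest` objects.
#' @return `TRUE`/`FALSE`.
#' @export
manifest_equal <- function(a, b) {
  strip <- function(m) { m <- unclass(m); m$created <- NULL; m }
  identical(jsonlite::toJSON(strip(a), auto_unbox = TRUE, null = "null",
                             na = "null", digits = NA),
            jsonlite::toJSON(strip(b), auto_unbox = TRUE, null = "null",
                             na = "null", digits = NA))
}
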