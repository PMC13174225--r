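# JSON serialization of effect-size blocks and access to the bundled
# synthetic fixtures.

#' Write / read effect-size blocks as JSON
#'
#' A file holds a named list of blocks, each mirroring the fields of
#' [effect_sizes()]. Requires the `jsonlite` package.
#'
#' @param blocks Named list of `effect_sizes` objects (or a single one).
#' @param path Output file.
#' @export
write_effect_sizes <- function(blocks, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_config("effect-size JSON i/o requires the 'jsonlite' package")
  }
  if (inherits(blocks, "effect_sizes")) blocks <- list(effects = blocks)
  payload <- lapply(blocks, function(b) unclass(b))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_effect_sizes
#' @return `read_effect_sizes()`: named list of `effect_sizes` objects.
#' @export
read_effect_sizes <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_config("effect-size JSON i/o requires the 'jsonlite' package")
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(b) {
    effect_sizes(intercept = b$intercept, beta_g = b$beta_g, beta_e = b$beta_e,
                 beta_d = b$beta_d, beta_gxe = b$beta_gxe,
                 beta_dxe = b$beta_dxe, partners = b$partners %||% list(),
                 sigma2 = b$sigma2)
  })
}

#' Bundled synthetic effect-size blocks
#'
#' Effect sizes estimated (via [estimate_effect_sizes()] on whitened
#' synthetic F2 data; see `tools/make_fixtures.R` in the package sources) for
#' three archetypal loci: a temperature-sensitive locus with dominance and
#' epistatic partners, a purely additive locus, and an overdominant locus.
#' These are synthetic stand-ins on the log-bpm scale: the effect sizes of
#' the original fish dataset are not public, so the simulator's worked
#' examples run on these blocks instead.
#'
#' @param name Block name (`NULL` lists all blocks).
#' @return A single `effect_sizes` object, or a named list of all blocks.
#' @export
bundled_effect_sizes <- function(name = NULL) {
  path <- system.file("extdata", "synthetic_effect_sizes.json",
                      package = "interax", mustWork = TRUE)
  blocks <- read_effect_sizes(path)
  if (is.null(name)) return(blocks)
  if (!name %in% names(blocks)) {
    stop_config("unknown block '", name, "'; available: ",
                paste(names(blocks), collapse = ", "))
  }
  blocks[[name]]
}
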