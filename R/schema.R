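#' Read attribute schemas from a YAML file
#'
#' The YAML maps each attribute name to a `labels` list (which must include
#' `"NULL"`) and a `lexicon` mapping labels to alias lists.
#'
#' @param path YAML path; by default the schemas bundled with the package
#'   (12 tumor sites, 8 histologies, coarse TNM: T in 0-4/is, N in 0/1+,
#'   M in 0/1 — structurally like ICD-O-3 topography/morphology plus TNM,
#'   but far smaller).
#' @return named list of [AttributeSchema-class] objects.
#' @export
readSchemas <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "schemas.yaml", package = "OncoAbstract",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(a) {
    entry <- raw[[a]]
    lex <- lapply(entry$lexicon, as.character)
    new("AttributeSchema", attribute = a,
        labels = as.character(entry$labels), lexicon = lex)
  })
  stats::setNames(out, names(raw))
}

.schema_cache <- new.env(parent = emptyenv())

#' Default attribute schemas bundled with the package
#' @return named list of [AttributeSchema-class], one per attribute.
#' @export
defaultSchemas <- function() {
  if (is.null(.schema_cache$schemas))
    .schema_cache$schemas <- readSchemas()
  .schema_cache$schemas
}
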