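#' Packaged example data: a Zanthoxylum nitidum rhizosphere survey
#'
#' Small plain-text tables from a published survey of the rhizosphere soil
#' bacterial communities of *Zanthoxylum nitidum* sampled across six
#' origins in southern China, shipped so the worked examples and the grey
#' relational golden path run without any download:
#'
#' * `znitidum_pooled_genus_percent.tsv` — genus-level relative abundances
#'   (percent) of 15 focal genera, with the six samples pooled by origin
#'   pair into three points (`A1/A3`, `A2/B1`, `B2/B3`; each pooled value is
#'   the arithmetic mean of the member samples' percentages).
#' * `znitidum_nitidine_chloride.tsv` — nitidine chloride content (percent
#'   of root dry weight) per pooled origin, the parent series of the grey
#'   relational analysis.
#' * `znitidum_soil_properties.tsv` — per-sample soil environmental
#'   factors: pH, organic matter ORM (g/kg), altitude HT (m), clay CP,
#'   sand SP and silt SSG (g/kg).
#' * `znitidum_genus_percent_per_sample.tsv` — per-sample relative
#'   abundances of the genera whose values are reported for both members of
#'   the `A1/A3` origin pair; pooling them reproduces the corresponding
#'   pooled cells exactly.
#'
#' @param file Name of one of the files above, or `NULL` to list them.
#' @return A filesystem path (or a character vector of available names).
#' @examples
#' rhizolink_example()
#' tab <- read_count_table(rhizolink_example("znitidum_pooled_genus_percent.tsv"),
#'                         unit = "percent")
#' @export
rhizolink_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "rhizolink")))
  path <- system.file("extdata", file, package = "rhizolink")
  if (!nzchar(path)) stop("no packaged file named '", file, "'")
  path
}
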