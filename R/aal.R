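#' AAL-116 region names with a conventional lobe grouping
#'
#' The 116 regions of the automated anatomical labelling (AAL) atlas, in
#' standard order, each assigned to a coarse lobe used for compilation tables
#' (frontal, limbic, occipital, parietal, subcortical, temporal, insula,
#' cerebellum, vermis). The lobe grouping is the conventional coarse one;
#' border regions (paracentral lobule, fusiform, temporal poles) follow common
#' usage.
#'
#' @return A data.frame with columns `region` and `lobe` (116 rows).
#' @export
aal_regions <- function() {
  path <- system.file("extdata", "aal116_lobes.csv", package = "scnet",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
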