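#' Accessors for SMR containers
#'
#' `tissue()` returns the tissue label of a per-tissue experiment;
#' `alphaLevel()` the family-wise error level; `threshold()` the per-test
#' Bonferroni cutoff; `nTested()` the number of instruments tested;
#' `loadSummary()` the per-file accept/reject/duplicate log stored at load
#' time.
#'
#' @param x an object.
#' @return `tissue`, `alphaLevel`, `threshold`: length-one vectors;
#'   `nTested`: integer; `loadSummary`: a list.
#' @name smr-accessors
#' @aliases tissue alphaLevel threshold nTested loadSummary
#' @examples
#' sim <- simulateStudy(simulationSpec(nGenes = 5, nTissues = 1, seed = 1))
#' inst <- selectInstruments(sim$eqtl[[1]], sim$gwas)
#' ex <- runTissueExperiment(inst)
#' tissue(ex); threshold(ex); nTested(ex)
NULL

#' @rdname smr-accessors
#' @export
setGeneric("tissue", function(x) standardGeneric("tissue"))

#' @rdname smr-accessors
#' @export
setGeneric("alphaLevel", function(x) standardGeneric("alphaLevel"))

#' @rdname smr-accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname smr-accessors
#' @export
setGeneric("nTested", function(x) standardGeneric("nTested"))

#' @rdname smr-accessors
#' @export
setGeneric("loadSummary", function(x) standardGeneric("loadSummary"))

#' @rdname smr-accessors
setMethod("tissue", "SmrExperiment", function(x) x@tissue)

#' @rdname smr-accessors
setMethod("alphaLevel", "SmrExperiment", function(x) x@alpha)

#' @rdname smr-accessors
setMethod("threshold", "SmrExperiment", function(x) x@threshold)

#' @rdname smr-accessors
setMethod("nTested", "SmrExperiment", function(x) nrow(x))

#' @rdname smr-accessors
setMethod("loadSummary", "DFrame", function(x) metadata(x)$load_summary)
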