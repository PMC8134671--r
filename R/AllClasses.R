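#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- setValidity2
NULL

.VALID_BASES <- c("A", "C", "G", "T")

.checkCols <- function(object, required) {
    missing <- setdiff(required, colnames(object))
    if (length(missing))
        return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    NULL
}

#' GWAS summary statistics
#'
#' A [S4Vectors::DataFrame] of per-SNP associations with the phenotype
#' (outcome side of the SMR model). One row per SNP: the per-allele effect
#' `beta` is \eqn{b_{ZY}}, its standard error `se` is \eqn{se_{ZY}}. For
#' binary traits `beta` is on the log-odds scale. The load summary
#' (accepted/rejected/duplicate counts) is kept in `metadata()`.
#'
#' @slot .Data inherited; columns `snp_id`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `p`, `n`, and optionally `chrom`, `pos`.
#' @seealso [readGwas()]
#' @export
setClass("GwasSumstats", contains = "DFrame")

S4Vectors::setValidity2("GwasSumstats", function(object) {
    msg <- .checkCols(object, c("snp_id", "effect_allele", "other_allele",
                                "eaf", "beta", "se", "p"))
    if (!is.null(msg)) return(msg)
    if (nrow(object) == 0L) return(TRUE)
    if (any(object$se <= 0, na.rm = TRUE)) return("se must be > 0")
    if (any(object$p <= 0 | object$p > 1, na.rm = TRUE))
        return("p must lie in (0, 1]")
    if (any(object$effect_allele == object$other_allele, na.rm = TRUE))
        return("effect_allele must differ from other_allele")
    eaf <- object$eaf
    if (any(eaf < 0 | eaf > 1, na.rm = TRUE)) return("eaf must lie in [0, 1]")
    TRUE
})

#' cis-eQTL summary statistics for one tissue
#'
#' A [S4Vectors::DataFrame] of per-(SNP, gene) associations with expression
#' (exposure side of the SMR model): `beta` is \eqn{b_{ZX}}, `se` is
#' \eqn{se_{ZX}}. Every row carries the tissue label supplied at load time.
#'
#' @slot .Data inherited; columns `gene_id`, `probe_id`, `snp_id`, `tissue`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `p`, `n`, and optionally
#'   `chrom`, `pos`.
#' @seealso [readEqtl()]
#' @export
setClass("EqtlSumstats", contains = "DFrame")

S4Vectors::setValidity2("EqtlSumstats", function(object) {
    msg <- .checkCols(object, c("gene_id", "probe_id", "snp_id", "tissue",
                                "effect_allele", "other_allele", "beta",
                                "se", "p"))
    if (!is.null(msg)) return(msg)
    if (nrow(object) == 0L) return(TRUE)
    if (any(object$se <= 0, na.rm = TRUE)) return("se must be > 0")
    if (any(object$p <= 0 | object$p > 1, na.rm = TRUE))
        return("p must lie in (0, 1]")
    if (any(!nzchar(object$tissue))) return("tissue labels must be non-empty")
    if (any(object$effect_allele == object$other_allele, na.rm = TRUE))
        return("effect_allele must differ from other_allele")
    TRUE
})

#' Harmonized instruments
#'
#' One row per (gene, probe, tissue): the instrument SNP with both effect
#' sizes referred to the same allele (`aligned_allele`). The
#' `harmonization_action` column records what alignment did: `"none"`,
#' `"sign_flip"` (eQTL effect negated because the allele pair was swapped),
#' `"dropped_ambiguous"` (strand-ambiguous A/T or C/G SNP that the allele
#' frequency could not resolve) or `"dropped_mismatch"` (irreconcilable
#' allele sets). Dropped rows are retained for audit but excluded from
#' analysis by [runTissueExperiment()].
#'
#' @seealso [selectInstruments()], [harmonizePair()]
#' @export
setClass("InstrumentSet", contains = "DFrame")

.HARMONIZE_ACTIONS <- c("none", "sign_flip", "dropped_ambiguous",
                        "dropped_mismatch")

S4Vectors::setValidity2("InstrumentSet", function(object) {
    msg <- .checkCols(object, c("snp_id", "gene_id", "probe_id", "tissue",
                                "b_zy", "se_zy", "b_zx", "se_zx",
                                "aligned_allele", "harmonization_action"))
    if (!is.null(msg)) return(msg)
    if (nrow(object) == 0L) return(TRUE)
    if (!all(object$harmonization_action %in% .HARMONIZE_ACTIONS))
        return("unknown harmonization_action")
    kept <- !startsWith(object$harmonization_action, "dropped")
    if (any(object$se_zy[kept] <= 0) || any(object$se_zx[kept] <= 0))
        return("standard errors of kept instruments must be > 0")
    TRUE
})

#' Per-tissue SMR experiment result
#'
#' One SMR test per instrument in one tissue. Columns: `snp_id`, `gene_id`,
#' `probe_id`, `tissue`, `b_xy` (Wald-ratio estimate \eqn{b_{ZY}/b_{ZX}}),
#' `se_xy` (delta-method standard error), `t_smr` (chi-square(1) statistic),
#' `p_smr`, `log_p` (natural-log p, exact for tiny tails) and `significant`
#' (Bonferroni at the experiment's `threshold()`). Rows are sorted by
#' `p_smr`.
#'
#' @slot tissue single tissue label.
#' @slot alpha family-wise error level the threshold was derived from.
#' @slot threshold per-test significance cutoff (`alpha / nTested`).
#' @seealso [runTissueExperiment()], [smrTest()]
#' @export
setClass("SmrExperiment", contains = "DFrame",
         representation(tissue = "character", alpha = "numeric",
                        threshold = "numeric"))

S4Vectors::setValidity2("SmrExperiment", function(object) {
    msg <- .checkCols(object, c("snp_id", "gene_id", "probe_id", "tissue",
                                "b_xy", "se_xy", "t_smr", "p_smr",
                                "significant"))
    if (!is.null(msg)) return(msg)
    if (length(object@tissue) != 1L) return("tissue must be a single label")
    if (nrow(object) == 0L) return(TRUE)
    if (any(object$t_smr < 0, na.rm = TRUE)) return("t_smr must be >= 0")
    if (any(object$p_smr <= 0 | object$p_smr > 1, na.rm = TRUE))
        return("p_smr must lie in (0, 1]")
    if (!identical(object$significant,
                   as.logical(object$p_smr < object@threshold)))
        return("significant flags must equal p_smr < threshold")
    TRUE
})

#' Cross-tissue table of significant SNP-gene pairs
#'
#' Rows of (`snp_id`, `gene_id`, `p_smr`, `tissue`), unique on the
#' (snp, gene, tissue) triple; the tissue-tagged pair is the unit in which
#' cross-tissue results are counted. Produced by [aggregatePairs()], which
#' collapses probe-level duplicates to the minimum p.
#'
#' @seealso [crossTissueSummary()], [snpRepetitionCounts()]
#' @export
setClass("PairTable", contains = "DFrame")

S4Vectors::setValidity2("PairTable", function(object) {
    msg <- .checkCols(object, c("snp_id", "gene_id", "p_smr", "tissue"))
    if (!is.null(msg)) return(msg)
    if (nrow(object) == 0L) return(TRUE)
    key <- paste(object$snp_id, object$gene_id, object$tissue, sep = "\r")
    if (anyDuplicated(key))
        return("rows must be unique on (snp_id, gene_id, tissue)")
    if (any(object$p_smr <= 0 | object$p_smr > 1, na.rm = TRUE))
        return("p_smr must lie in (0, 1]")
    TRUE
})

#' Annotation term sets for over-representation analysis
#'
#' @slot terms named list mapping term id to a character vector of gene ids.
#' @slot universe character vector of all annotatable gene ids; every term
#'   must be a subset of it.
#' @seealso [hypergeomEnrich()], [readAnnotation()]
#' @export
setClass("AnnotationSets",
         representation(terms = "list", universe = "character"))

S4Vectors::setValidity2("AnnotationSets", function(object) {
    if (length(object@universe) == 0L) return("universe must be non-empty")
    if (anyDuplicated(object@universe)) return("universe ids must be unique")
    if (length(object@terms)) {
        if (is.null(names(object@terms)) || any(!nzchar(names(object@terms))))
            return("terms must be named by term id")
        outside <- vapply(object@terms,
                          function(g) any(!(g %in% object@universe)),
                          logical(1))
        if (any(outside))
            return(sprintf("term(s) not contained in the universe: %s",
                           paste(names(object@terms)[outside], collapse = ", ")))
    }
    TRUE
})

#' @describeIn AnnotationSets constructor; gene ids absent from `universe`
#'   but present in a term are added to the universe when
#'   `extendUniverse = TRUE` (default), mirroring how annotation files are
#'   usually taken to define their own background.
#' @param terms named list of character vectors (term id -> gene ids).
#' @param universe character vector of background gene ids.
#' @param extendUniverse logical; grow the universe to cover all term genes.
#' @export
AnnotationSets <- function(terms, universe = NULL, extendUniverse = TRUE) {
    terms <- lapply(terms, function(g) unique(as.character(g)))
    allGenes <- unique(unlist(terms, use.names = FALSE))
    if (is.null(universe)) universe <- allGenes
    universe <- unique(as.character(universe))
    if (extendUniverse) universe <- union(universe, allGenes)
    new("AnnotationSets", terms = terms, universe = universe)
}

setMethod("show", "AnnotationSets", function(object) {
    cat(sprintf("AnnotationSets with %d term(s) over a universe of %d gene(s)\n",
                length(object@terms), length(object@universe)))
})

setMethod("show", "SmrExperiment", function(object) {
    cat(sprintf("SmrExperiment: tissue %s, %d instrument(s) tested, %d significant\n",
                object@tissue, nrow(object), sum(object$significant)))
    cat(sprintf("  alpha = %g, Bonferroni threshold = %g\n",
                object@alpha, object@threshold))
    callNextMethod()
})
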