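.TISSUE_MAP <- c(Artery = "Artery_Tibial",
                 Blood = "Blood",
                 Fibroblast = "Cells_Cultured_fibroblasts",
                 Neuro = "Nerve_Tibial",
                 Skin = "Skin_Sun_Exposed_Lower_leg")

#' Published gingivitis SNP-gene pair table
#'
#' The 26 significant SNP-gene pairs reported by a published cross-tissue
#' SMR study of gingivitis, which combined one GWAS with cis-eQTL summary
#' data from five GTEx tissues. Shipped verbatim (SNP, gene, p-value,
#' tissue) as a reference result for the aggregation and overlap
#' machinery. The short tissue labels of the publication are normalized to
#' the GTEx tissue names (`Artery` -> `Artery_Tibial`, `Skin` ->
#' `Skin_Sun_Exposed_Lower_leg`, `Neuro` -> `Nerve_Tibial`, `Fibroblast`
#' -> `Cells_Cultured_fibroblasts`, `Blood` -> `Blood`) unless
#' `normalize = FALSE`.
#'
#' @param normalize logical; map the printed short tissue labels onto the
#'   GTEx tissue names.
#' @return a [PairTable] with 26 rows.
#' @examples
#' pairs <- gingivitisPairs()
#' nrow(pairs)                    # 26
#' max(pairs$p_smr)               # 3.03e-06
#' length(unique(pairs$tissue))   # 5
#' @export
gingivitisPairs <- function(normalize = TRUE) {
    path <- system.file("extdata", "gingivitis_pairs.tsv", package = "smrmt",
                        mustWork = TRUE)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    tis <- as.character(df$tissue)
    if (normalize) tis <- unname(.TISSUE_MAP[tis])
    out <- new("PairTable", DataFrame(snp_id = as.character(df$snp),
                                      gene_id = as.character(df$gene),
                                      p_smr = as.numeric(df$p),
                                      tissue = tis))
    validObject(out)
    out
}

#' Published pairs as per-tissue experiments
#'
#' Re-expresses [gingivitisPairs()] as one [SmrExperiment] per tissue so
#' the aggregation path ([aggregatePairs()]) can be exercised against the
#' published table. Only the columns the publication prints are available:
#' effect sizes are `NA`, every printed row is significant, and the
#' per-tissue threshold is set just above the largest printed p-value
#' (3.03e-06), the scale a Bonferroni cutoff evidently took in that study.
#'
#' @inheritParams gingivitisPairs
#' @return a list of five [SmrExperiment] objects.
#' @export
gingivitisExperiments <- function(normalize = TRUE) {
    pairs <- gingivitisPairs(normalize = normalize)
    thr <- 3.05e-06
    lapply(split(as.data.frame(pairs), pairs$tissue), function(df) {
        t_smr <- stats::qchisq(df$p_smr, df = 1, lower.tail = FALSE)
        res <- DataFrame(snp_id = df$snp_id, gene_id = df$gene_id,
                         probe_id = df$gene_id, tissue = df$tissue,
                         b_xy = NA_real_, se_xy = NA_real_,
                         t_smr = t_smr, p_smr = df$p_smr,
                         log_p = log(df$p_smr),
                         significant = df$p_smr < thr)
        res <- res[order(res$p_smr), , drop = FALSE]
        rownames(res) <- NULL
        new("SmrExperiment", res, tissue = df$tissue[1], alpha = NA_real_,
            threshold = thr)
    })
}
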