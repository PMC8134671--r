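# Small builders for summary-statistic objects and files used across tests.

makeGwas <- function(snp_id, effect_allele = "A", other_allele = "G",
                     eaf = 0.3, beta = 0.1, se = 0.02, p = NULL, n = 5e4) {
    k <- length(snp_id)
    recycle <- function(x) rep_len(x, k)
    beta <- recycle(beta); se <- recycle(se)
    if (is.null(p)) p <- pmax(2 * pnorm(-abs(beta / se)),
                              .Machine$double.xmin)
    new("GwasSumstats", S4Vectors::DataFrame(
        snp_id = snp_id, chrom = NA_character_, pos = NA_integer_,
        effect_allele = recycle(effect_allele),
        other_allele = recycle(other_allele),
        eaf = recycle(eaf), beta = beta, se = se, p = recycle(p),
        n = recycle(n)))
}

makeEqtl <- function(snp_id, gene_id = "GENE1", probe_id = gene_id,
                     tissue = "Blood", effect_allele = "A",
                     other_allele = "G", beta = 0.5, se = 0.05, p = NULL,
                     n = 1000) {
    k <- length(snp_id)
    recycle <- function(x) rep_len(x, k)
    beta <- recycle(beta); se <- recycle(se)
    if (is.null(p)) p <- pmax(2 * pnorm(-abs(beta / se)),
                              .Machine$double.xmin)
    new("EqtlSumstats", S4Vectors::DataFrame(
        gene_id = recycle(gene_id), probe_id = recycle(probe_id),
        snp_id = snp_id, tissue = recycle(tissue),
        chrom = NA_character_, pos = NA_integer_,
        effect_allele = recycle(effect_allele),
        other_allele = recycle(other_allele),
        beta = beta, se = se, p = recycle(p), n = recycle(n)))
}

writeTsv <- function(lines, ext = ".tsv") {
    f <- tempfile(fileext = ext)
    writeLines(lines, f)
    f
}

# Minimal SmrExperiment from a (snp, gene, p) table, for aggregation tests.
makeExperiment <- function(snp_id, gene_id, p_smr, tissue,
                           probe_id = gene_id, threshold = 1e-3) {
    res <- S4Vectors::DataFrame(
        snp_id = snp_id, gene_id = gene_id, probe_id = probe_id,
        tissue = tissue, b_xy = rep(NA_real_, length(snp_id)),
        se_xy = rep(NA_real_, length(snp_id)),
        t_smr = qchisq(p_smr, 1, lower.tail = FALSE), p_smr = p_smr,
        log_p = log(p_smr), significant = p_smr < threshold)
    res <- res[order(res$p_smr), , drop = FALSE]
    rownames(res) <- NULL
    new("SmrExperiment", res, tissue = tissue[1], alpha = NA_real_,
        threshold = threshold)
}
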