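.DEFAULT_TISSUES <- c("Artery_Tibial", "Blood", "Cells_Cultured_fibroblasts",
                      "Nerve_Tibial", "Skin_Sun_Exposed_Lower_leg")

#' Specification of a synthetic multi-tissue summary-statistics study
#'
#' Describes a study in which each gene has one (or a few) causal cis
#' SNP(s), the SNP affects expression in every tissue with true effect
#' \eqn{b_{ZX}}, and the trait effect follows the causal chain
#' \eqn{b_{ZY} = b_{XY} \cdot b_{ZX} + \theta}, where \eqn{b_{XY}} is the
#' gene's true causal effect on the phenotype (0 for null genes) and
#' \eqn{\theta} a direct (pleiotropic) SNP-on-trait effect bypassing
#' expression. Observed effect sizes are drawn at the summary level,
#' \eqn{\hat b \sim N(b, se^2)} with the standardized-trait approximation
#' \eqn{se = 1/\sqrt{2\,maf(1-maf)\,n}}, so the generator is fast, exact,
#' and fully determined by `seed`.
#'
#' @param nGenes number of genes.
#' @param nTissues number of tissues (labels default to five GTEx tissue
#'   names, recycled with suffixes beyond five).
#' @param tissues optional character vector of tissue labels.
#' @param snpsPerGene candidate cis SNPs simulated per gene.
#' @param mafRange range in (0, 0.5] from which each SNP's minor-allele
#'   frequency is drawn uniformly.
#' @param eqtlN,gwasN sample sizes (>= 50) of the eQTL and GWAS studies.
#' @param bXY true causal effect(s) of expression on the phenotype: a
#'   scalar applied to every gene, or a vector of length `nGenes`.
#' @param pleiotropy direct SNP-on-trait effect(s) bypassing expression;
#'   scalar or length `nGenes`.
#' @param bZXRange range of true instrument-effect magnitudes; the sign of
#'   each \eqn{b_{ZX}} is random.
#' @param flipFraction fraction of eQTL rows written in the opposite
#'   allele orientation (alleles swapped, effect negated) to exercise
#'   harmonization.
#' @param seed integer seed fully determining the study.
#' @return a `smr_simspec` list.
#' @export
simulationSpec <- function(nGenes = 100, nTissues = 5, tissues = NULL,
                           snpsPerGene = 1, mafRange = c(0.1, 0.5),
                           eqtlN = 1000, gwasN = 100000,
                           bXY = 0, pleiotropy = 0,
                           bZXRange = c(0.5, 1.0), flipFraction = 0.3,
                           seed = 1) {
    if (is.null(tissues)) {
        tissues <- rep_len(.DEFAULT_TISSUES, nTissues)
        if (nTissues > length(.DEFAULT_TISSUES))
            tissues <- make.unique(tissues, sep = "_")
    }
    if (length(tissues) != nTissues)
        stop("'tissues' must have length nTissues")
    if (eqtlN < 50 || gwasN < 50)
        stop("sample sizes must be >= 50")
    if (any(mafRange <= 0) || any(mafRange > 0.5))
        stop("'mafRange' must lie within (0, 0.5]")
    if (flipFraction < 0 || flipFraction > 1)
        stop("'flipFraction' must lie in [0, 1]")
    expand <- function(x, what) {
        if (length(x) == 1L) x <- rep(x, nGenes)
        if (length(x) != nGenes)
            stop(sprintf("'%s' must be a scalar or of length nGenes", what))
        x
    }
    structure(list(nGenes = as.integer(nGenes),
                   nTissues = as.integer(nTissues), tissues = tissues,
                   snpsPerGene = as.integer(snpsPerGene),
                   mafRange = mafRange, eqtlN = eqtlN, gwasN = gwasN,
                   bXY = expand(bXY, "bXY"),
                   pleiotropy = expand(pleiotropy, "pleiotropy"),
                   bZXRange = bZXRange, flipFraction = flipFraction,
                   seed = as.integer(seed)),
              class = "smr_simspec")
}

# Ordered non-palindromic allele pairs; sampling from these keeps the
# harmonization exercise free of strand-ambiguity drops.
.ALLELE_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                          "G","A", "G","T", "T","C", "T","G"),
                        ncol = 2, byrow = TRUE)

#' Simulate a GWAS plus multi-tissue eQTL summary-statistics study
#'
#' Draws a complete synthetic study from a [simulationSpec()]: one GWAS
#' table, one cis-eQTL table per tissue, and a truth table recording every
#' generative parameter per gene and SNP. The true instrument effect of a
#' SNP is shared across tissues (each tissue observes it with its own
#' sampling noise), which keeps the single SNP-on-trait truth
#' \eqn{b_{ZY} = b_{XY} b_{ZX} + \theta} coherent across the study. A
#' `flipFraction` of eQTL rows is emitted in the opposite allele
#' orientation so that the harmonization step has real work to do.
#'
#' The same spec (same seed) always yields the same study; [writeStudy()]
#' serializes it byte-identically.
#'
#' @param spec a [simulationSpec()].
#' @return a list: `gwas` ([GwasSumstats]), `eqtl` (named list of
#'   [EqtlSumstats], one per tissue), `truth` (data.frame with `gene_id`,
#'   `snp_id`, `maf`, `b_zx_true`, `b_xy_true`, `pleiotropy`, `b_zy_true`).
#' @examples
#' sim <- simulateStudy(simulationSpec(nGenes = 3, nTissues = 2, seed = 7))
#' sapply(sim$eqtl, nrow)
#' @export
simulateStudy <- function(spec) {
    stopifnot(inherits(spec, "smr_simspec"))
    if (exists(".Random.seed", envir = globalenv())) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(spec$seed)

    nSnp <- spec$nGenes * spec$snpsPerGene
    geneIdx <- rep(seq_len(spec$nGenes), each = spec$snpsPerGene)
    gene_id <- sprintf("GENE%05d", geneIdx)
    snp_id <- sprintf("rs%07d", seq_len(nSnp))
    maf <- stats::runif(nSnp, spec$mafRange[1], spec$mafRange[2])
    pair <- .ALLELE_PAIRS[sample.int(nrow(.ALLELE_PAIRS), nSnp,
                                     replace = TRUE), , drop = FALSE]
    ea <- pair[, 1]; oa <- pair[, 2]

    b_zx_true <- stats::runif(nSnp, spec$bZXRange[1], spec$bZXRange[2]) *
        sample(c(-1, 1), nSnp, replace = TRUE)
    b_xy_true <- spec$bXY[geneIdx]
    theta <- spec$pleiotropy[geneIdx]
    b_zy_true <- b_xy_true * b_zx_true + theta

    se_zy <- 1 / sqrt(2 * maf * (1 - maf) * spec$gwasN)
    b_zy <- stats::rnorm(nSnp, b_zy_true, se_zy)
    p_zy <- pmax(2 * stats::pnorm(-abs(b_zy / se_zy)), .Machine$double.xmin)
    gwas <- new("GwasSumstats", DataFrame(
        snp_id = snp_id, chrom = NA_character_, pos = NA_integer_,
        effect_allele = ea, other_allele = oa, eaf = maf,
        beta = b_zy, se = se_zy, p = p_zy, n = spec$gwasN))

    eqtl <- lapply(seq_len(spec$nTissues), function(ti) {
        se_zx <- 1 / sqrt(2 * maf * (1 - maf) * spec$eqtlN)
        b_zx <- stats::rnorm(nSnp, b_zx_true, se_zx)
        p_zx <- pmax(2 * stats::pnorm(-abs(b_zx / se_zx)),
                     .Machine$double.xmin)
        flip <- stats::runif(nSnp) < spec$flipFraction
        new("EqtlSumstats", DataFrame(
            gene_id = gene_id, probe_id = gene_id, snp_id = snp_id,
            tissue = spec$tissues[ti], chrom = NA_character_,
            pos = NA_integer_,
            effect_allele = ifelse(flip, oa, ea),
            other_allele = ifelse(flip, ea, oa),
            beta = ifelse(flip, -b_zx, b_zx), se = se_zx, p = p_zx,
            n = spec$eqtlN))
    })
    names(eqtl) <- spec$tissues

    truth <- data.frame(gene_id = gene_id, snp_id = snp_id, maf = maf,
                        b_zx_true = b_zx_true, b_xy_true = b_xy_true,
                        pleiotropy = theta, b_zy_true = b_zy_true,
                        stringsAsFactors = FALSE)
    list(gwas = gwas, eqtl = eqtl, truth = truth, spec = spec)
}

#' Write a simulated study to disk
#'
#' Serializes the output of [simulateStudy()]: `gwas.ma` (COJO layout),
#' one `<tissue>.eqtl.tsv` per tissue (flat tissue-tagged layout) and
#' `truth.tsv`. Output is a pure function of the spec, so the same spec
#' written twice produces byte-identical files.
#'
#' @param sim the list returned by [simulateStudy()].
#' @param dir output directory, created if needed.
#' @return named character vector of files written, invisibly.
#' @export
writeStudy <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(gwas = file.path(dir, "gwas.ma"))
    writeGwas(sim$gwas, files["gwas"])
    for (tis in names(sim$eqtl)) {
        f <- file.path(dir, paste0(tis, ".eqtl.tsv"))
        writeEqtl(sim$eqtl[[tis]], f)
        files[tis] <- f
    }
    files["truth"] <- file.path(dir, "truth.tsv")
    utils::write.table(sim$truth, files["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(files)
}
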