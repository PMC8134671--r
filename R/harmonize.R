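.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.isPalindromic <- function(a1, a2) {
    ok <- a1 %in% names(.COMPLEMENT) & a2 %in% names(.COMPLEMENT)
    out <- rep(FALSE, length(a1))
    out[ok] <- .COMPLEMENT[a1[ok]] == a2[ok]
    out
}

# Vectorized allele alignment of the eQTL side onto the GWAS orientation.
# For palindromic SNPs the face-value and strand-complement readings are
# indistinguishable from labels, so the complement branches apply only to
# non-palindromic SNPs; palindromic SNPs are taken at face value when the
# effect-allele frequency is informative and dropped otherwise.
.alignAlleles <- function(gEA, gOA, eEA, eOA, eaf,
                          ambiguityBand = c(0.42, 0.58)) {
    n <- length(gEA)
    pal <- .isPalindromic(gEA, gOA)
    same <- eEA == gEA & eOA == gOA
    swap <- eEA == gOA & eOA == gEA
    cEA <- unname(.COMPLEMENT[eEA]); cOA <- unname(.COMPLEMENT[eOA])
    cEA[is.na(cEA)] <- "?"; cOA[is.na(cOA)] <- "?"
    sameC <- !pal & cEA == gEA & cOA == gOA  # other strand, same orientation
    swapC <- !pal & cEA == gOA & cOA == gEA  # other strand, swapped

    action <- rep("dropped_mismatch", n)
    flip <- rep(FALSE, n)
    action[same | sameC] <- "none"
    action[swap | swapC] <- "sign_flip"
    flip[swap | swapC] <- TRUE

    # Strand-ambiguous SNPs: frequency must decide; near 0.5 (or missing)
    # it cannot, so the instrument is dropped.
    undecidable <- is.na(eaf) |
        (eaf >= ambiguityBand[1] & eaf <= ambiguityBand[2])
    amb <- pal & (same | swap) & undecidable
    action[amb] <- "dropped_ambiguous"
    flip[amb] <- FALSE
    list(action = action, flip = flip)
}

#' Harmonize a GWAS record and an eQTL record onto one effect allele
#'
#' Alleles in summary files are arbitrary in orientation: the eQTL study
#' may report the effect of the opposite allele, or of the opposite strand.
#' Before the Wald ratio \eqn{b_{ZY}/b_{ZX}} is taken, both effects must
#' refer to the same allele. The rules, applied with the GWAS orientation
#' as the reference: matching allele pairs need no change (`none`); swapped
#' pairs (possibly on the other strand) negate the eQTL effect
#' (`sign_flip`); strand-ambiguous A/T or C/G SNPs are dropped when the
#' effect-allele frequency is missing or inside `ambiguityBand`
#' (`dropped_ambiguous`); irreconcilable allele sets are dropped
#' (`dropped_mismatch`). The operation is idempotent: aligning an already
#' aligned pair changes nothing.
#'
#' @param gwas a single-row [GwasSumstats] (or a one-SNP subset).
#' @param eqtl a single-row [EqtlSumstats] for the same SNP.
#' @param ambiguityBand numeric length-2; the effect-allele-frequency
#'   interval within which a palindromic SNP is considered unresolvable.
#' @return a one-row [InstrumentSet].
#' @examples
#' g <- new("GwasSumstats", S4Vectors::DataFrame(
#'   snp_id = "rs1", effect_allele = "A", other_allele = "G",
#'   eaf = 0.3, beta = 0.1, se = 0.02, p = 1e-6, n = 5e4))
#' e <- new("EqtlSumstats", S4Vectors::DataFrame(
#'   gene_id = "GENE1", probe_id = "GENE1", snp_id = "rs1", tissue = "Blood",
#'   effect_allele = "G", other_allele = "A", beta = 0.2, se = 0.05,
#'   p = 1e-8, n = 600))
#' harmonizePair(g, e)$b_zx   # -0.2: swapped alleles flip the sign
#' @export
harmonizePair <- function(gwas, eqtl, ambiguityBand = c(0.42, 0.58)) {
    stopifnot(is(gwas, "GwasSumstats"), is(eqtl, "EqtlSumstats"),
              nrow(gwas) == 1L, nrow(eqtl) == 1L)
    if (gwas$snp_id != eqtl$snp_id)
        stop(sprintf("snp_id mismatch: '%s' vs '%s'",
                     gwas$snp_id, eqtl$snp_id))
    al <- .alignAlleles(gwas$effect_allele, gwas$other_allele,
                        eqtl$effect_allele, eqtl$other_allele,
                        gwas$eaf, ambiguityBand)
    out <- DataFrame(snp_id = gwas$snp_id, gene_id = eqtl$gene_id,
                     probe_id = eqtl$probe_id, tissue = eqtl$tissue,
                     b_zy = gwas$beta, se_zy = gwas$se,
                     b_zx = ifelse(al$flip, -eqtl$beta, eqtl$beta),
                     se_zx = eqtl$se,
                     p_zx = eqtl$p,
                     aligned_allele = gwas$effect_allele,
                     harmonization_action = al$action)
    new("InstrumentSet", out)
}

#' Select one instrument SNP per gene per tissue
#'
#' For each (gene, probe, tissue) in the eQTL table, among the SNPs present
#' in both tables whose eQTL p-value is below `pInstrument`, the top cis
#' SNP is chosen as the instrument: smallest eQTL p, ties broken by larger
#' \eqn{|b/se|}, then by lexicographically smaller SNP id. The chosen pair
#' is allele-harmonized (see [harmonizePair()]); rows dropped by
#' harmonization are retained in the result with their `dropped_*` action
#' and skipped by [runTissueExperiment()]. When both the gene and SNP
#' positions are available a cis-window restriction of `cisWindow` bp
#' around the gene is applied first; with positions absent all shared SNPs
#' are eligible.
#'
#' @param eqtl an [EqtlSumstats] (one tissue).
#' @param gwas a [GwasSumstats].
#' @param pInstrument eQTL p-value threshold an instrument must pass;
#'   default `5e-8`, conventional genome-wide significance for the top
#'   cis-eQTL.
#' @param ambiguityBand see [harmonizePair()].
#' @param cisWindow half-width in bp of the cis window, used only when a
#'   `gene_pos` column is present in `eqtl` and SNP positions are known.
#' @param harmonize logical; when `FALSE` allele alignment is skipped and
#'   both tables are taken at face value (action `"none"` everywhere).
#'   Only useful to demonstrate what mis-oriented alleles do to the
#'   estimates; leave `TRUE` for analysis.
#' @return an [InstrumentSet]; `metadata()` records how many genes had no
#'   qualifying SNP and how many instruments harmonization dropped.
#' @export
selectInstruments <- function(eqtl, gwas, pInstrument = 5e-8,
                              ambiguityBand = c(0.42, 0.58),
                              cisWindow = 1e6, harmonize = TRUE) {
    stopifnot(is(eqtl, "EqtlSumstats"), is(gwas, "GwasSumstats"))
    if (!(pInstrument > 0 && pInstrument < 1))
        stop("'pInstrument' must lie in (0, 1)")
    e <- as.data.frame(eqtl)
    nGenesAll <- length(unique(paste(e$gene_id, e$probe_id)))
    gidx <- match(e$snp_id, gwas$snp_id)
    keep <- !is.na(gidx) & e$p < pInstrument
    if ("gene_pos" %in% colnames(e)) {
        havePos <- keep & !is.na(e$gene_pos) & !is.na(e$pos)
        keep[havePos] <- abs(e$pos[havePos] - e$gene_pos[havePos]) <= cisWindow
    }
    e <- e[keep, , drop = FALSE]
    gidx <- gidx[keep]
    if (nrow(e) == 0L) {
        warning("no SNP shared between the eQTL and GWAS tables passes the instrument threshold")
        out <- new("InstrumentSet", DataFrame(
            snp_id = character(), gene_id = character(),
            probe_id = character(), tissue = character(),
            b_zy = numeric(), se_zy = numeric(),
            b_zx = numeric(), se_zx = numeric(), p_zx = numeric(),
            aligned_allele = character(), harmonization_action = character()))
        metadata(out)$selection <- list(n_genes_seen = nGenesAll,
                                        n_genes_instrumented = 0L,
                                        n_genes_no_instrument = nGenesAll,
                                        n_dropped_harmonization = 0L)
        return(out)
    }
    # top SNP per (gene, probe): min p, then max |z|, then smallest snp_id
    z <- abs(e$beta / e$se)
    ord <- order(e$gene_id, e$probe_id, e$p, -z, e$snp_id)
    e <- e[ord, , drop = FALSE]
    gidx <- gidx[ord]
    first <- !duplicated(paste(e$gene_id, e$probe_id, sep = "\r"))
    e <- e[first, , drop = FALSE]
    gidx <- gidx[first]

    al <- if (harmonize) {
        .alignAlleles(gwas$effect_allele[gidx], gwas$other_allele[gidx],
                      e$effect_allele, e$other_allele,
                      gwas$eaf[gidx], ambiguityBand)
    } else {
        list(action = rep("none", nrow(e)), flip = rep(FALSE, nrow(e)))
    }
    out <- DataFrame(snp_id = e$snp_id, gene_id = e$gene_id,
                     probe_id = e$probe_id, tissue = e$tissue,
                     b_zy = gwas$beta[gidx], se_zy = gwas$se[gidx],
                     b_zx = ifelse(al$flip, -e$beta, e$beta),
                     se_zx = e$se, p_zx = e$p,
                     aligned_allele = gwas$effect_allele[gidx],
                     harmonization_action = al$action)
    out <- out[order(out$gene_id, out$probe_id), , drop = FALSE]
    rownames(out) <- NULL
    out <- new("InstrumentSet", out)
    nInstr <- length(unique(paste(out$gene_id, out$probe_id)))
    metadata(out)$selection <- list(
        n_genes_seen = nGenesAll,
        n_genes_instrumented = nInstr,
        n_genes_no_instrument = nGenesAll - nInstr,
        n_dropped_harmonization =
            sum(startsWith(out$harmonization_action, "dropped")))
    out
}
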