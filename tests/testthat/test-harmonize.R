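test_that("swapped allele pairs flip the eQTL effect sign", {
    g <- makeGwas("rs1", effect_allele = "A", other_allele = "G", beta = 0.10)
    e <- makeEqtl("rs1", effect_allele = "G", other_allele = "A", beta = 0.20)
    inst <- harmonizePair(g, e)
    expect_equal(inst$harmonization_action, "sign_flip")
    expect_equal(inst$b_zx, -0.20)
    expect_equal(inst$aligned_allele, "A")
})

test_that("identical orientation leaves effects unchanged", {
    g <- makeGwas("rs1", effect_allele = "A", other_allele = "G", beta = 0.10)
    e <- makeEqtl("rs1", effect_allele = "A", other_allele = "G", beta = 0.20)
    inst <- harmonizePair(g, e)
    expect_equal(inst$harmonization_action, "none")
    expect_equal(inst$b_zx, 0.20)
})

test_that("strand-complement pairs of non-ambiguous SNPs are resolved", {
    g <- makeGwas("rs1", effect_allele = "A", other_allele = "G")
    sameStrand <- harmonizePair(g, makeEqtl("rs1", effect_allele = "T",
                                            other_allele = "C", beta = 0.2))
    expect_equal(sameStrand$harmonization_action, "none")
    expect_equal(sameStrand$b_zx, 0.2)
    swapped <- harmonizePair(g, makeEqtl("rs1", effect_allele = "C",
                                         other_allele = "T", beta = 0.2))
    expect_equal(swapped$harmonization_action, "sign_flip")
    expect_equal(swapped$b_zx, -0.2)
})

test_that("palindromic SNPs are dropped when frequency cannot resolve the strand", {
    e <- makeEqtl("rs1", effect_allele = "A", other_allele = "T")
    atBand <- makeGwas("rs1", effect_allele = "A", other_allele = "T",
                       eaf = 0.50)
    expect_equal(harmonizePair(atBand, e)$harmonization_action,
                 "dropped_ambiguous")
    noFreq <- makeGwas("rs1", effect_allele = "A", other_allele = "T",
                       eaf = NA_real_)
    expect_equal(harmonizePair(noFreq, e)$harmonization_action,
                 "dropped_ambiguous")
    informative <- makeGwas("rs1", effect_allele = "A", other_allele = "T",
                            eaf = 0.15)
    expect_equal(harmonizePair(informative, e)$harmonization_action, "none")
    edge <- makeGwas("rs1", effect_allele = "C", other_allele = "G",
                     eaf = 0.42)
    expect_equal(harmonizePair(edge, makeEqtl("rs1", effect_allele = "C",
                                              other_allele = "G"))$harmonization_action,
                 "dropped_ambiguous")
})

test_that("irreconcilable allele sets are dropped and snp mismatch is a usage error", {
    g <- makeGwas("rs1", effect_allele = "A", other_allele = "G")
    e <- makeEqtl("rs1", effect_allele = "A", other_allele = "C")
    expect_equal(harmonizePair(g, e)$harmonization_action,
                 "dropped_mismatch")
    expect_error(harmonizePair(g, makeEqtl("rs2")), "mismatch")
})

test_that("harmonization is idempotent: aligning an aligned pair changes nothing", {
    g <- makeGwas("rs1", effect_allele = "A", other_allele = "G", beta = 0.1)
    for (eEA in list(c("G", "A"), c("A", "G"), c("C", "T"))) {
        e <- makeEqtl("rs1", effect_allele = eEA[1], other_allele = eEA[2],
                      beta = 0.2)
        once <- harmonizePair(g, e)
        e2 <- makeEqtl("rs1", effect_allele = once$aligned_allele,
                       other_allele = g$other_allele, beta = once$b_zx)
        twice <- harmonizePair(g, e2)
        expect_equal(twice$harmonization_action, "none")
        expect_equal(twice$b_zx, once$b_zx)
    }
})

test_that("swapping alleles and negating beta in both records leaves the SMR estimate unchanged", {
    set.seed(42)
    for (i in 1:20) {
        b_zy <- rnorm(1, 0, 0.1); b_zx <- rnorm(1, 0.5, 0.2)
        if (b_zx == 0) next
        g1 <- makeGwas("rs1", effect_allele = "A", other_allele = "G",
                       beta = b_zy, eaf = 0.3)
        e1 <- makeEqtl("rs1", effect_allele = "A", other_allele = "G",
                       beta = b_zx)
        g2 <- makeGwas("rs1", effect_allele = "G", other_allele = "A",
                       beta = -b_zy, eaf = 0.7)
        e2 <- makeEqtl("rs1", effect_allele = "G", other_allele = "A",
                       beta = -b_zx)
        i1 <- harmonizePair(g1, e1); i2 <- harmonizePair(g2, e2)
        s1 <- smrStat(i1$b_zy, i1$se_zy, i1$b_zx, i1$se_zx)
        s2 <- smrStat(i2$b_zy, i2$se_zy, i2$b_zx, i2$se_zx)
        expect_equal(s1$b_xy, s2$b_xy)
        expect_equal(s1$t_smr, s2$t_smr)
        expect_equal(s1$p_smr, s2$p_smr)
    }
})

test_that("instrument selection picks the top eQTL SNP under the stated tie-breaks", {
    g <- makeGwas(c("rs1", "rs2", "rs3", "rs4"))
    # argmin p
    e <- makeEqtl(c("rs1", "rs2"), gene_id = "G1",
                  beta = c(0.5, 0.5), se = c(0.05, 0.05),
                  p = c(1e-12, 1e-9))
    inst <- selectInstruments(e, g)
    expect_equal(inst$snp_id, "rs1")
    # below-threshold genes are omitted and counted
    e2 <- makeEqtl("rs3", gene_id = "G2", p = 1e-6)
    expect_warning(i2 <- selectInstruments(e2, g, pInstrument = 5e-8),
                   "no SNP")
    expect_equal(nrow(i2), 0L)
    expect_equal(S4Vectors::metadata(i2)$selection$n_genes_no_instrument, 1L)
    # equal p: larger |beta/se| wins
    e3 <- makeEqtl(c("rs1", "rs2"), gene_id = "G1",
                   beta = c(0.4, 0.6), se = c(0.05, 0.05),
                   p = c(1e-12, 1e-12))
    expect_equal(selectInstruments(e3, g)$snp_id, "rs2")
    # equal p and |z|: lexicographically smaller snp id
    e4 <- makeEqtl(c("rs4", "rs2"), gene_id = "G1",
                   beta = c(0.5, 0.5), se = c(0.05, 0.05),
                   p = c(1e-12, 1e-12))
    expect_equal(selectInstruments(e4, g)$snp_id, "rs2")
})

test_that("SNPs absent from the GWAS table are not eligible instruments", {
    g <- makeGwas("rs1")
    e <- makeEqtl(c("rs1", "rs9"), gene_id = c("G1", "G1"),
                  p = c(1e-9, 1e-30))
    inst <- selectInstruments(e, g)
    expect_equal(inst$snp_id, "rs1")
})

test_that("the cis-window restriction applies only when positions are known", {
    g <- makeGwas(c("rs1", "rs2"))
    base <- as.data.frame(makeEqtl(c("rs1", "rs2"), gene_id = "G1",
                                   p = c(1e-12, 1e-20)))
    base$pos <- c(1000L, 5000000L)
    withPos <- base
    withPos$gene_pos <- c(2000L, 2000L)
    e <- new("EqtlSumstats", S4Vectors::DataFrame(withPos))
    inst <- selectInstruments(e, g, cisWindow = 1e6)
    expect_equal(inst$snp_id, "rs1")   # rs2 is 5 Mb away despite smaller p
    e2 <- new("EqtlSumstats", S4Vectors::DataFrame(base))
    inst2 <- selectInstruments(e2, g, cisWindow = 1e6)
    expect_equal(inst2$snp_id, "rs2")  # without gene positions all SNPs are eligible
})
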