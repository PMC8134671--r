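test_that("the hand-derived example reproduces: b_xy, t_smr and the chi-square tail", {
    st <- smrStat(b_zy = 0.10, se_zy = 0.02, b_zx = 0.50, se_zx = 0.05)
    expect_equal(st$b_xy, 0.20)
    # z_zy = 5, z_zx = 10 -> t = (25 * 100) / 125 = 20
    expect_equal(st$t_smr, 20)
    # independent route to the chi-square(1) upper tail: 2 * Phi(-sqrt(t))
    expect_equal(st$p_smr, 2 * pnorm(-sqrt(20)), tolerance = 1e-12)
    # delta-method se against the explicit |b_xy| * sqrt(...) form
    expect_equal(st$se_xy,
                 abs(0.2) * sqrt(0.02^2 / 0.10^2 + 0.05^2 / 0.50^2),
                 tolerance = 1e-12)
})

test_that("a null numerator gives a null estimate and p = 1", {
    st <- smrStat(b_zy = 0, se_zy = 0.02, b_zx = 0.5, se_zx = 0.05)
    expect_equal(st$b_xy, 0)
    expect_equal(st$t_smr, 0)
    expect_equal(st$p_smr, 1)
    expect_equal(st$se_xy, 0.02 / 0.5)  # guarded form se_zy / |b_zx|
})

test_that("equal z-scores give t = z^2 / 2 and the statistic never beats either z^2", {
    z <- c(0.5, 1, 3, 7)
    st <- smrStat(b_zy = z * 0.1, se_zy = 0.1, b_zx = z * 0.2, se_zx = 0.2)
    expect_equal(st$t_smr, z^2 / 2)

    set.seed(101)
    for (i in 1:200) {
        b_zy <- rnorm(1); se_zy <- runif(1, 0.01, 1)
        b_zx <- rnorm(1); if (b_zx == 0) next
        se_zx <- runif(1, 0.01, 1)
        st <- smrStat(b_zy, se_zy, b_zx, se_zx)
        expect_lte(st$t_smr,
                   min((b_zy / se_zy)^2, (b_zx / se_zx)^2) + 1e-12)
        expect_gte(st$t_smr, 0)
    }
})

test_that("p is invariant to double sign flips; b_xy flips with exactly one beta", {
    set.seed(7)
    b_zy <- rnorm(50, 0, 0.1); b_zx <- runif(50, 0.2, 1)
    s0 <- smrStat(b_zy, 0.02, b_zx, 0.05)
    sBoth <- smrStat(-b_zy, 0.02, -b_zx, 0.05)
    sOne <- smrStat(b_zy, 0.02, -b_zx, 0.05)
    expect_equal(sBoth$p_smr, s0$p_smr)
    expect_equal(sBoth$b_xy, s0$b_xy)
    expect_equal(sOne$b_xy, -s0$b_xy)
    expect_equal(sOne$p_smr, s0$p_smr)
})

test_that("tiny p-values stay in log space and never underflow to zero", {
    st <- smrStat(b_zy = 1, se_zy = 0.01, b_zx = 1, se_zx = 0.01)
    expect_equal(st$t_smr, 100^2 / 2)
    expect_gt(st$p_smr, 0)
    expect_lt(st$log_p, -1000)
    expect_equal(st$log_p,
                 pchisq(5000, 1, lower.tail = FALSE, log.p = TRUE))
})

test_that("degenerate instruments are refused", {
    expect_error(smrStat(0.1, 0.02, 0, 0.05), "degenerate")
    expect_error(smrStat(0.1, -0.02, 0.5, 0.05), "must be > 0")
})

test_that("|z| recovered from a p-value inverts the two-sided normal tail", {
    z <- c(0.1, 1, 5, 10, 35)
    p <- 2 * pnorm(-z)
    expect_equal(zFromP(p), z, tolerance = 1e-9)
    expect_error(zFromP(0), "must lie in")
})

test_that("a tissue experiment applies Bonferroni, sorts by p, and records attrition", {
    g <- makeGwas(c("rs1", "rs2", "rs3"), beta = c(0.10, 0.002, 0.08),
                  se = 0.02)
    e <- makeEqtl(c("rs1", "rs2", "rs3"),
                  gene_id = c("G1", "G2", "G3"),
                  beta = c(0.5, 0.5, 0.05), se = 0.05,
                  p = c(1e-20, 1e-20, 1e-20))
    inst <- selectInstruments(e, g)
    ex <- runTissueExperiment(inst, alpha = 0.05)
    # G3's instrument has |z_zx| = 1 < 1.96 and is refused
    expect_equal(nTested(ex), 2L)
    expect_equal(S4Vectors::metadata(ex)$counts$n_refused_weak, 1L)
    expect_equal(threshold(ex), 0.05 / 2)
    expect_equal(ex$p_smr, sort(ex$p_smr))
    expect_identical(ex$significant, as.logical(ex$p_smr < threshold(ex)))
    expect_equal(tissue(ex), "Blood")
    expect_equal(alphaLevel(ex), 0.05)
})

test_that("an empty instrument set yields an empty experiment, not an error", {
    g <- makeGwas("rs1")
    e <- makeEqtl("rs1", p = 0.5)
    suppressWarnings(inst <- selectInstruments(e, g))
    ex <- runTissueExperiment(inst)
    expect_equal(nTested(ex), 0L)
    expect_equal(nrow(ex), 0L)
})

test_that("instruments spanning several tissues are refused", {
    g <- makeGwas(c("rs1", "rs2"))
    e1 <- makeEqtl("rs1", gene_id = "G1", tissue = "Blood", p = 1e-20)
    e2 <- makeEqtl("rs2", gene_id = "G2", tissue = "Skin", p = 1e-20)
    inst <- rbind(selectInstruments(e1, g), selectInstruments(e2, g))
    expect_error(runTissueExperiment(inst), "one experiment per tissue")
})

test_that("dropped instruments are excluded from testing", {
    g <- makeGwas(c("rs1", "rs2"), effect_allele = c("A", "A"),
                  other_allele = c("G", "T"), eaf = c(0.3, 0.5))
    e <- makeEqtl(c("rs1", "rs2"), gene_id = c("G1", "G2"),
                  effect_allele = c("A", "A"), other_allele = c("G", "T"),
                  p = c(1e-20, 1e-20))
    inst <- selectInstruments(e, g)
    expect_setequal(inst$harmonization_action,
                    c("none", "dropped_ambiguous"))
    ex <- runTissueExperiment(inst)
    expect_equal(nTested(ex), 1L)
    expect_equal(ex$gene_id, "G1")
    expect_equal(S4Vectors::metadata(ex)$counts$n_dropped_harmonization, 1L)
})

test_that("the delta-method se tracks the Monte-Carlo SD of the ratio for a strong instrument", {
    b_zy <- 0.10; se_zy <- 0.02; b_zx <- 0.50; se_zx <- 0.05  # z_zx = 10
    st <- smrStat(b_zy, se_zy, b_zx, se_zx)
    set.seed(2024)
    num <- rnorm(2e5, b_zy, se_zy)
    den <- rnorm(2e5, b_zx, se_zx)
    expect_equal(st$se_xy, sd(num / den), tolerance = 0.05)
})
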