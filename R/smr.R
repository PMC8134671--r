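#' The SMR statistic for one or more instruments
#'
#' `smrStat()` is the numerical core of the package, vectorized over
#' instruments. For an instrument SNP Z, exposure X (expression) and
#' outcome Y (phenotype), the causal effect of expression on the phenotype
#' is estimated by the Wald ratio
#' \deqn{\hat b_{XY} = b_{ZY} / b_{ZX},}
#' with first-order delta-method standard error
#' \deqn{se_{XY} = |\hat b_{XY}|\sqrt{se_{ZY}^2/b_{ZY}^2 + se_{ZX}^2/b_{ZX}^2}}
#' (computed in the algebraically equivalent form
#' \eqn{\sqrt{se_{ZY}^2/b_{ZX}^2 + b_{ZY}^2 se_{ZX}^2 / b_{ZX}^4}}, which
#' is also exact at \eqn{b_{ZY}=0}, where it reduces to
#' \eqn{se_{ZY}/|b_{ZX}|}). The test statistic is the product form on the
#' z-scores \eqn{z = b/se}:
#' \deqn{T_{SMR} = \frac{z_{ZY}^2\, z_{ZX}^2}{z_{ZY}^2 + z_{ZX}^2},}
#' referred to the upper tail of a chi-square distribution with 1 degree of
#' freedom. `T_SMR` never exceeds \eqn{\min(z_{ZY}^2, z_{ZX}^2)} and equals
#' \eqn{z^2/2} when the two z-scores coincide. Tiny p-values are computed
#' in log space (`log_p`) and never underflow to an exact 0.
#'
#' @param b_zy,se_zy SNP effect on the phenotype and its standard error.
#' @param b_zx,se_zx SNP effect on expression and its standard error.
#' @return a [S4Vectors::DataFrame] with columns `b_xy`, `se_xy`, `t_smr`,
#'   `p_smr`, `log_p`.
#' @examples
#' smrStat(b_zy = 0.10, se_zy = 0.02, b_zx = 0.50, se_zx = 0.05)
#' # b_xy = 0.2, t_smr = (25 * 100) / 125 = 20
#' @export
smrStat <- function(b_zy, se_zy, b_zx, se_zx) {
    if (any(se_zy <= 0) || any(se_zx <= 0))
        stop("standard errors must be > 0")
    if (any(b_zx == 0))
        stop("degenerate instrument: b_zx must be non-zero")
    b_xy <- b_zy / b_zx
    se_xy <- sqrt(se_zy^2 / b_zx^2 + (b_zy^2 * se_zx^2) / b_zx^4)
    z2_zy <- (b_zy / se_zy)^2
    z2_zx <- (b_zx / se_zx)^2
    t_smr <- ifelse(z2_zy == 0, 0, (z2_zy * z2_zx) / (z2_zy + z2_zx))
    log_p <- stats::pchisq(t_smr, df = 1, lower.tail = FALSE, log.p = TRUE)
    p_smr <- pmax(exp(log_p), .Machine$double.xmin)
    DataFrame(b_xy = b_xy, se_xy = se_xy, t_smr = t_smr,
              p_smr = p_smr, log_p = log_p)
}

#' Recover |z| from a p-value
#'
#' For summary files that lack a standard-error column, the absolute
#' z-score can be recovered from the two-sided p-value by inverting the
#' normal tail in log space, avoiding underflow for genome-wide-scale
#' p-values.
#'
#' @param p two-sided p-values in (0, 1].
#' @return non-negative |z| of the same length.
#' @examples
#' zFromP(2 * pnorm(-5))   # 5
#' @export
zFromP <- function(p) {
    if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
    -stats::qnorm(log(p) - log(2), log.p = TRUE)
}

#' Run the SMR test across one tissue
#'
#' Applies [smrStat()] to every usable instrument of one tissue and
#' controls the family-wise error by Bonferroni: the per-test threshold is
#' `alpha / nTested`. Instruments dropped by harmonization are skipped;
#' instruments whose expression z-score is weaker than `zxFloor` are
#' refused to guard the ratio against near-zero denominators (a weak
#' instrument makes the Wald ratio explode), with counts of both recorded
#' in the result's `metadata()`.
#'
#' @param instruments an [InstrumentSet], all rows from one tissue.
#' @param alpha family-wise error level in (0, 1); default 0.05.
#' @param zxFloor minimum \eqn{|z_{ZX}|} an instrument must reach; default
#'   1.96.
#' @return an [SmrExperiment], rows sorted by `p_smr`.
#' @export
runTissueExperiment <- function(instruments, alpha = 0.05, zxFloor = 1.96) {
    stopifnot(is(instruments, "InstrumentSet"))
    if (!(alpha > 0 && alpha < 1)) stop("'alpha' must lie in (0, 1)")
    tissues <- unique(instruments$tissue)
    if (length(tissues) > 1L)
        stop("instruments span several tissues; run one experiment per tissue")
    tis <- if (length(tissues)) tissues else NA_character_

    kept <- !startsWith(instruments$harmonization_action, "dropped")
    inst <- instruments[kept, , drop = FALSE]
    weak <- abs(inst$b_zx / inst$se_zx) < zxFloor | inst$b_zx == 0
    inst <- inst[!weak, , drop = FALSE]

    if (nrow(inst) == 0L) {
        res <- DataFrame(snp_id = character(), gene_id = character(),
                         probe_id = character(), tissue = character(),
                         b_xy = numeric(), se_xy = numeric(),
                         t_smr = numeric(), p_smr = numeric(),
                         log_p = numeric(), significant = logical())
        out <- new("SmrExperiment", res, tissue = tis, alpha = alpha,
                   threshold = NA_real_)
    } else {
        st <- smrStat(inst$b_zy, inst$se_zy, inst$b_zx, inst$se_zx)
        thr <- alpha / nrow(inst)
        res <- DataFrame(snp_id = inst$snp_id, gene_id = inst$gene_id,
                         probe_id = inst$probe_id, tissue = inst$tissue,
                         b_xy = st$b_xy, se_xy = st$se_xy,
                         t_smr = st$t_smr, p_smr = st$p_smr,
                         log_p = st$log_p,
                         significant = as.logical(st$p_smr < thr))
        res <- res[order(res$p_smr, res$gene_id, res$snp_id), , drop = FALSE]
        rownames(res) <- NULL
        out <- new("SmrExperiment", res, tissue = tis, alpha = alpha,
                   threshold = thr)
    }
    metadata(out)$counts <- list(
        n_input = nrow(instruments),
        n_dropped_harmonization = sum(!kept),
        n_refused_weak = sum(weak),
        n_tested = nrow(out))
    validObject(out)
    out
}

#' Write a per-tissue SMR result table
#'
#' @param x an [SmrExperiment].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeSmrResults <- function(x, path) {
    stopifnot(is(x, "SmrExperiment"))
    df <- as.data.frame(x)[, c("snp_id", "gene_id", "probe_id", "tissue",
                               "b_xy", "se_xy", "t_smr", "p_smr",
                               "significant")]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
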