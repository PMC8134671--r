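#' Column-mapping dialects for summary-statistic tables
#'
#' A dialect maps the header names of a tab-separated summary-statistics
#' file onto the fields the package needs, so that differently formatted
#' exports are readable without editing code. `cojoDialect()` matches the
#' widely used COJO-style `.ma` layout (`SNP A1 A2 freq b se p n`, with
#' `A1` the effect allele); `eqtlDialect()` matches the flat tissue-tagged
#' eQTL layout this package writes
#' (`gene probe SNP A1 A2 b se p n`); `gtexDialect()` matches GTEx
#' significant-pair exports, whose compound variant id
#' (`chr_pos_ref_alt_build`, e.g. `chr3_45958159_T_C_b38`) is split into
#' chromosome, position and alleles, with the alt allele as effect allele.
#'
#' @param snp,effect_allele,other_allele,eaf,beta,or,se,p,n,gene,probe,chrom,pos
#'   header names for each field, or `NULL` when the file lacks it. Supply
#'   `or` (odds ratio) instead of `beta` for binary-trait GWAS exported on
#'   the odds-ratio scale; it is converted to log-odds at load.
#' @param compound_snp header name of a compound `chr_pos_ref_alt_build`
#'   variant-id column to be split, or `NULL`.
#' @return a `smr_dialect` list.
#' @examples
#' d <- makeDialect(snp = "rsid", beta = "effect", se = "stderr", p = "pval",
#'                  effect_allele = "ea", other_allele = "nea")
#' @export
makeDialect <- function(snp = NULL, effect_allele = NULL, other_allele = NULL,
                        eaf = NULL, beta = NULL, or = NULL, se = NULL,
                        p = NULL, n = NULL, gene = NULL, probe = NULL,
                        chrom = NULL, pos = NULL, compound_snp = NULL) {
    if (!is.null(beta) && !is.null(or))
        stop("map either a beta column or an odds-ratio column, not both")
    structure(list(snp = snp, effect_allele = effect_allele,
                   other_allele = other_allele, eaf = eaf, beta = beta,
                   or = or, se = se, p = p, n = n, gene = gene,
                   probe = probe, chrom = chrom, pos = pos,
                   compound_snp = compound_snp),
              class = "smr_dialect")
}

#' @rdname makeDialect
#' @export
cojoDialect <- function() {
    makeDialect(snp = "SNP", effect_allele = "A1", other_allele = "A2",
                eaf = "freq", beta = "b", se = "se", p = "p", n = "n")
}

#' @rdname makeDialect
#' @export
eqtlDialect <- function() {
    makeDialect(gene = "gene", probe = "probe", snp = "SNP",
                effect_allele = "A1", other_allele = "A2",
                beta = "b", se = "se", p = "p", n = "n")
}

#' @rdname makeDialect
#' @export
gtexDialect <- function() {
    makeDialect(gene = "gene_id", compound_snp = "variant_id",
                beta = "slope", se = "slope_se", p = "pval_nominal",
                n = "ma_samples")
}

.resolveCols <- function(dialect, header, required, path) {
    mapped <- dialect[!vapply(dialect, is.null, logical(1))]
    missingReq <- setdiff(required, names(mapped))
    if (length(missingReq))
        stop(sprintf("dialect does not map required field(s): %s",
                     paste(missingReq, collapse = ", ")))
    absent <- setdiff(unlist(mapped), header)
    if (length(absent))
        stop(sprintf("column(s) %s not found in header of '%s'",
                     paste(sQuote(absent), collapse = ", "), path))
    mapped
}

# Split GTEx-style compound variant ids into chrom/pos/ref/alt.
.splitCompoundId <- function(id) {
    parts <- strsplit(id, "_", fixed = TRUE)
    ok <- lengths(parts) >= 4L
    get <- function(i) vapply(parts, function(x)
        if (length(x) >= 4L) x[[i]] else NA_character_, character(1))
    chrom <- sub("^chr", "", get(1L))
    list(ok = ok, chrom = chrom,
         pos = suppressWarnings(as.integer(get(2L))),
         ref = toupper(get(3L)), alt = toupper(get(4L)))
}

.readTsv <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
}

.num <- function(x) suppressWarnings(as.numeric(x))

# Shared invariant screen; returns keep mask plus per-row reasons.
.screenRows <- function(df) {
    reason <- rep(NA_character_, nrow(df))
    flag <- function(bad, why) {
        bad[is.na(bad)] <- FALSE
        reason[bad & is.na(reason)] <<- why
    }
    flag(is.na(df$beta), "beta missing or non-numeric")
    flag(is.na(df$se), "se missing or non-numeric")
    flag(df$se <= 0, "se must be > 0")
    flag(is.na(df$p), "p missing or non-numeric")
    flag(df$p <= 0 | df$p > 1, "p out of (0,1]")
    flag(is.na(df$snp_id) | !nzchar(df$snp_id), "missing snp id")
    flag(is.na(df$effect_allele) | is.na(df$other_allele),
         "missing allele(s)")
    flag(df$effect_allele == df$other_allele, "alleles identical")
    if (!is.null(df$eaf)) flag(df$eaf < 0 | df$eaf > 1, "eaf out of [0,1]")
    reason
}

.loadSummaryLog <- function(path, reason, dupKey) {
    rejected <- table(reason[!is.na(reason)])
    list(path = path,
         n_rows = length(reason),
         n_accepted = sum(is.na(reason)),
         n_rejected = sum(!is.na(reason)),
         rejected_by_reason = as.list(rejected),
         n_duplicate_keys = sum(duplicated(dupKey[is.na(reason)])))
}

#' Read GWAS summary statistics
#'
#' Reads a tab-separated GWAS summary-statistics file, applies the column
#' mapping of `dialect`, screens every row against the field invariants
#' (`se > 0`, `p` in (0,1], distinct alleles, `eaf` in \[0,1\]) and returns
#' the accepted rows as a [GwasSumstats] object. Rejected rows are dropped
#' with a per-reason tally in `loadSummary()`; an odds-ratio column, when
#' mapped, is converted to log-odds so all effects are additive.
#'
#' @param path path to a tab-separated file with a single header row.
#' @param dialect column mapping, see [makeDialect()]. Default: COJO `.ma`.
#' @return a [GwasSumstats]; `loadSummary(x)` holds the attrition log.
#' @examples
#' f <- tempfile(fileext = ".ma")
#' writeLines(c("SNP\tA1\tA2\tfreq\tb\tse\tp\tn",
#'              "rs1\tA\tG\t0.3\t0.12\t0.03\t6.3e-5\t50000"), f)
#' g <- readGwas(f)
#' loadSummary(g)$n_accepted
#' @export
readGwas <- function(path, dialect = cojoDialect()) {
    raw <- .readTsv(path)
    cols <- .resolveCols(dialect, colnames(raw),
                         required = c("snp", "effect_allele", "other_allele",
                                      if (is.null(dialect$or)) "beta" else "or",
                                      "se", "p"),
                         path)
    grab <- function(field) if (field %in% names(cols)) raw[[cols[[field]]]] else NULL
    beta <- if (!is.null(dialect$or)) log(.num(grab("or"))) else .num(grab("beta"))
    df <- data.frame(
        snp_id = as.character(grab("snp")),
        chrom = if (!is.null(grab("chrom"))) as.character(grab("chrom")) else NA_character_,
        pos = if (!is.null(grab("pos"))) as.integer(grab("pos")) else NA_integer_,
        effect_allele = toupper(as.character(grab("effect_allele"))),
        other_allele = toupper(as.character(grab("other_allele"))),
        eaf = if (!is.null(grab("eaf"))) .num(grab("eaf")) else NA_real_,
        beta = beta,
        se = .num(grab("se")),
        p = .num(grab("p")),
        n = if (!is.null(grab("n"))) .num(grab("n")) else NA_real_,
        stringsAsFactors = FALSE)
    reason <- .screenRows(df)
    out <- new("GwasSumstats", DataFrame(df[is.na(reason), , drop = FALSE]))
    rownames(out) <- NULL
    metadata(out)$load_summary <- .loadSummaryLog(path, reason, out$snp_id)
    if (nrow(out) == 0L)
        stop(sprintf("no valid GWAS rows in '%s'", path))
    validObject(out)
    out
}

#' Read cis-eQTL summary statistics for one tissue
#'
#' As [readGwas()], for the expression side: reads a per-tissue eQTL
#' summary table, tags every accepted row with `tissue`, and screens rows
#' against the field invariants. When the dialect declares a compound
#' variant-id column (GTEx style, `chr_pos_ref_alt_build`), the id is split
#' into chromosome, position and alleles, with the alt allele taken as the
#' effect allele and the id string kept as `snp_id`. Duplicate
#' (gene, snp) keys are retained — significant-pair exports legitimately
#' carry several probes per gene — and counted in `loadSummary()`.
#'
#' @inheritParams readGwas
#' @param tissue non-empty tissue label stamped on every record.
#' @return an [EqtlSumstats]; `loadSummary(x)` holds the attrition log.
#' @export
readEqtl <- function(path, tissue, dialect = eqtlDialect()) {
    if (missing(tissue) || !nzchar(tissue))
        stop("'tissue' must be a non-empty label")
    raw <- .readTsv(path)
    compound <- !is.null(dialect$compound_snp)
    cols <- .resolveCols(dialect, colnames(raw),
                         required = c("gene",
                                      if (compound) "compound_snp"
                                      else c("snp", "effect_allele", "other_allele"),
                                      "beta", "se", "p"),
                         path)
    grab <- function(field) if (field %in% names(cols)) raw[[cols[[field]]]] else NULL
    if (compound) {
        id <- as.character(grab("compound_snp"))
        sp <- .splitCompoundId(id)
        snp_id <- id
        effect_allele <- sp$alt
        other_allele <- sp$ref
        chrom <- sp$chrom
        pos <- sp$pos
    } else {
        snp_id <- as.character(grab("snp"))
        effect_allele <- toupper(as.character(grab("effect_allele")))
        other_allele <- toupper(as.character(grab("other_allele")))
        chrom <- if (!is.null(grab("chrom"))) as.character(grab("chrom")) else NA_character_
        pos <- if (!is.null(grab("pos"))) as.integer(grab("pos")) else NA_integer_
    }
    gene <- as.character(grab("gene"))
    probe <- if (!is.null(grab("probe"))) as.character(grab("probe")) else gene
    df <- data.frame(
        gene_id = gene, probe_id = probe, snp_id = snp_id,
        tissue = tissue, chrom = chrom, pos = pos,
        effect_allele = effect_allele, other_allele = other_allele,
        beta = .num(grab("beta")), se = .num(grab("se")), p = .num(grab("p")),
        n = if (!is.null(grab("n"))) .num(grab("n")) else NA_real_,
        stringsAsFactors = FALSE)
    reason <- .screenRows(df)
    bad <- is.na(df$gene_id) | !nzchar(df$gene_id)
    reason[bad & is.na(reason)] <- "missing gene id"
    out <- new("EqtlSumstats", DataFrame(df[is.na(reason), , drop = FALSE]))
    rownames(out) <- NULL
    key <- paste(out$gene_id, out$snp_id, out$tissue)
    metadata(out)$load_summary <- .loadSummaryLog(path, reason, key)
    if (nrow(out) == 0L)
        stop(sprintf("no valid eQTL rows in '%s'", path))
    validObject(out)
    out
}

#' Write summary-statistic tables
#'
#' Writes a [GwasSumstats] back in the COJO `.ma` layout, or an
#' [EqtlSumstats] in the flat tissue-tagged layout, such that re-reading
#' reproduces identical records.
#'
#' @param x the object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGwas <- function(x, path) {
    stopifnot(is(x, "GwasSumstats"))
    df <- data.frame(SNP = x$snp_id, A1 = x$effect_allele,
                     A2 = x$other_allele, freq = x$eaf, b = x$beta,
                     se = x$se, p = x$p, n = x$n)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeGwas
#' @export
writeEqtl <- function(x, path) {
    stopifnot(is(x, "EqtlSumstats"))
    df <- data.frame(gene = x$gene_id, probe = x$probe_id, SNP = x$snp_id,
                     A1 = x$effect_allele, A2 = x$other_allele,
                     b = x$beta, se = x$se, p = x$p, n = x$n)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
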