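#' Aggregate per-tissue experiments into a cross-tissue pair table
#'
#' Collects the significant results of several per-tissue SMR experiments
#' into one table of tissue-tagged SNP-gene pairs. Because several
#' expression probes can tag the same gene, probe-level hits for one
#' (snp, gene, tissue) triple are collapsed to a single row keeping the
#' smallest p-value. Rows are sorted by tissue, then p.
#'
#' @param experiments a list of [SmrExperiment] objects with distinct
#'   tissue labels.
#' @return a [PairTable].
#' @examples
#' pairs <- gingivitisPairs()   # bundled published pair table
#' nrow(pairs)                  # 26
#' @export
aggregatePairs <- function(experiments) {
    if (is(experiments, "SmrExperiment")) experiments <- list(experiments)
    stopifnot(all(vapply(experiments, is, logical(1), "SmrExperiment")))
    labs <- vapply(experiments, tissue, character(1))
    if (anyDuplicated(labs[!is.na(labs)]))
        stop("experiments must carry distinct tissue labels")
    rows <- lapply(experiments, function(ex) {
        df <- as.data.frame(ex)
        df[df$significant, c("snp_id", "gene_id", "p_smr", "tissue"),
           drop = FALSE]
    })
    df <- do.call(rbind, rows)
    if (is.null(df) || nrow(df) == 0L)
        return(new("PairTable", DataFrame(snp_id = character(),
                                          gene_id = character(),
                                          p_smr = numeric(),
                                          tissue = character())))
    # collapse probe-level duplicates: keep min p per (snp, gene, tissue)
    df <- df[order(df$snp_id, df$gene_id, df$tissue, df$p_smr), , drop = FALSE]
    key <- paste(df$snp_id, df$gene_id, df$tissue, sep = "\r")
    df <- df[!duplicated(key), , drop = FALSE]
    df <- df[order(df$tissue, df$p_smr, df$snp_id, df$gene_id), , drop = FALSE]
    rownames(df) <- NULL
    out <- new("PairTable", DataFrame(df))
    validObject(out)
    out
}

#' Cross-tissue counts and gene-by-tissue overlap
#'
#' From a [PairTable], computes (i) per-tissue counts of distinct SNPs,
#' distinct genes and pairs, and (ii) the gene-by-tissue overlap: which
#' tissues each gene reaches, how many genes occur in exactly k tissues,
#' and which genes are tissue-specific (exactly one tissue).
#'
#' @param pairs a [PairTable].
#' @return a list with elements `tissueCounts` (data.frame: `tissue`,
#'   `n_snps`, `n_genes`, `n_pairs`) and `overlap` (list: `incidence`,
#'   a named list gene -> sorted tissue vector; `k_counts`, named integer
#'   vector over k = 1..T; `tissue_specific`, named list tissue -> genes).
#' @examples
#' s <- crossTissueSummary(gingivitisPairs())
#' s$tissueCounts
#' names(which(vapply(s$overlap$incidence, length, 1L) == 4))
#' @export
crossTissueSummary <- function(pairs) {
    stopifnot(is(pairs, "PairTable"))
    df <- as.data.frame(pairs)
    if (nrow(df) == 0L)
        return(list(tissueCounts = data.frame(tissue = character(),
                                              n_snps = integer(),
                                              n_genes = integer(),
                                              n_pairs = integer()),
                    overlap = list(incidence = list(),
                                   k_counts = integer(),
                                   tissue_specific = list())))
    byTissue <- split(df, df$tissue)
    tissueCounts <- data.frame(
        tissue = names(byTissue),
        n_snps = vapply(byTissue, function(x) length(unique(x$snp_id)), 1L),
        n_genes = vapply(byTissue, function(x) length(unique(x$gene_id)), 1L),
        n_pairs = vapply(byTissue, nrow, 1L),
        row.names = NULL)

    incidence <- lapply(split(df$tissue, df$gene_id),
                        function(t) sort(unique(t)))
    nTis <- length(byTissue)
    k <- vapply(incidence, length, 1L)
    k_counts <- vapply(seq_len(nTis), function(i) sum(k == i), 1L)
    names(k_counts) <- as.character(seq_len(nTis))
    specific <- lapply(names(byTissue), function(tis)
        sort(names(incidence)[k == 1L &
                              vapply(incidence, function(x) x[1] == tis,
                                     logical(1))]))
    names(specific) <- names(byTissue)
    list(tissueCounts = tissueCounts,
         overlap = list(incidence = incidence, k_counts = k_counts,
                        tissue_specific = specific))
}

#' How often each SNP recurs across the pair table
#'
#' Counts the rows of a [PairTable] per SNP across all tissues. In
#' cross-tissue SMR the same SNP is frequently selected as the instrument
#' for several genes and tissues; recurrent selection is a useful signal
#' of a locus-level association.
#'
#' @param pairs a [PairTable].
#' @return a named integer vector (snp id -> count), decreasing.
#' @examples
#' snpRepetitionCounts(gingivitisPairs())[["rs72121193"]]   # 9
#' @export
snpRepetitionCounts <- function(pairs) {
    stopifnot(is(pairs, "PairTable"))
    if (nrow(pairs) == 0L) return(integer())
    tab <- table(pairs$snp_id)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    sort(counts, decreasing = TRUE)
}

#' Write cross-tissue summary outputs
#'
#' Writes the pair table (`pairs.tsv`), per-tissue counts
#' (`tissue_counts.tsv`), SNP repetition counts (`repetitions.tsv`) and the
#' overlap summary (`overlap.json`) into a directory.
#'
#' @param pairs a [PairTable].
#' @param dir output directory, created if needed.
#' @return named character vector of the files written, invisibly.
#' @export
writeCrossTissueOutputs <- function(pairs, dir) {
    stopifnot(is(pairs, "PairTable"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    s <- crossTissueSummary(pairs)
    files <- c(pairs = file.path(dir, "pairs.tsv"),
               tissue_counts = file.path(dir, "tissue_counts.tsv"),
               repetitions = file.path(dir, "repetitions.tsv"),
               overlap = file.path(dir, "overlap.json"))
    utils::write.table(as.data.frame(pairs), files["pairs"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(s$tissueCounts, files["tissue_counts"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    reps <- snpRepetitionCounts(pairs)
    utils::write.table(data.frame(snp_id = names(reps), count = reps),
                       files["repetitions"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
        list(incidence = s$overlap$incidence,
             k_counts = as.list(s$overlap$k_counts),
             tissue_specific = s$overlap$tissue_specific),
        files["overlap"], auto_unbox = TRUE, pretty = TRUE)
    invisible(files)
}
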