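#' Hypergeometric over-representation test
#'
#' Tests whether a query gene list is enriched for each annotation term
#' set. With a universe of `N` annotatable genes, `K` of which carry the
#' term, and an effective query of `n` genes, `k` of them hitting the
#' term, the raw p-value is the upper tail of the hypergeometric
#' distribution, \eqn{P(X \ge k)} for \eqn{X \sim Hypergeom(N, K, n)};
#' p-values are adjusted across terms by Benjamini-Hochberg. Query genes
#' outside the universe are dropped (their count is messaged and recorded
#' in the result metadata). The `ease = TRUE` option applies the
#' conservative EASE variant, scoring the tail at `k - 1` hits, for
#' comparability with DAVID-style tools; the plain tail is the default.
#'
#' @param query character vector of gene ids.
#' @param annot an [AnnotationSets].
#' @param alpha significance level applied to the adjusted p-values;
#'   default 0.05.
#' @param ease logical; use the EASE-score variant.
#' @return a [S4Vectors::DataFrame] with one row per term (`term_id`,
#'   `n_hits`, `n_term`, `n_query`, `n_universe`, `p_raw`, `p_adj`,
#'   `significant`), sorted by `p_raw`.
#' @examples
#' annot <- AnnotationSets(list(T1 = letters[1:5]), universe = letters[1:20])
#' hypergeomEnrich(letters[1:5], annot)$p_raw   # 1 / choose(20, 5)
#' @export
hypergeomEnrich <- function(query, annot, alpha = 0.05, ease = FALSE) {
    stopifnot(is(annot, "AnnotationSets"))
    validObject(annot)
    query <- unique(as.character(query))
    eff <- intersect(query, annot@universe)
    nDropped <- length(query) - length(eff)
    if (length(eff) == 0L)
        stop("no query gene is contained in the annotation universe")
    if (nDropped > 0L)
        message(sprintf("%d query gene(s) outside the universe dropped",
                        nDropped))
    N <- length(annot@universe)
    n <- length(eff)
    K <- unname(vapply(annot@terms, length, 1L))
    k <- unname(vapply(annot@terms, function(g) length(intersect(g, eff)), 1L))
    scoreAt <- if (ease) pmax(k - 1L, 0L) else k
    # P(X >= scoreAt); phyper gives P(X <= q), so q = scoreAt - 1
    p_raw <- stats::phyper(scoreAt - 1L, K, N - K, n, lower.tail = FALSE)
    p_raw <- pmin(pmax(p_raw, .Machine$double.xmin), 1)
    p_adj <- stats::p.adjust(p_raw, method = "BH")
    out <- DataFrame(term_id = names(annot@terms), n_hits = k, n_term = K,
                     n_query = n, n_universe = N, p_raw = p_raw,
                     p_adj = p_adj, significant = p_adj < alpha)
    out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
    rownames(out) <- NULL
    metadata(out)$n_query_dropped <- nDropped
    out
}

#' Read annotation term sets
#'
#' Reads either a two-column TSV (`term_id`, `gene_id`; header optional,
#' detected from the first line) or a GMT file (term, description, then
#' gene ids, tab-separated) into an [AnnotationSets]. The universe
#' defaults to the union of all annotated genes.
#'
#' @param path annotation file.
#' @param universe optional character vector overriding the background.
#' @return an [AnnotationSets].
#' @export
readAnnotation <- function(path, universe = NULL) {
    if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop(sprintf("empty annotation file: '%s'", path))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    isGmt <- all(lengths(fields) >= 3L)
    if (isGmt) {
        terms <- lapply(fields, function(x) unique(x[-(1:2)]))
        names(terms) <- vapply(fields, `[`, "", 1L)
    } else {
        if (any(lengths(fields) < 2L))
            stop("two-column annotation rows must have term_id and gene_id")
        term <- vapply(fields, `[`, "", 1L)
        gene <- vapply(fields, `[`, "", 2L)
        if (tolower(term[1]) %in% c("term", "term_id") ||
            tolower(gene[1]) %in% c("gene", "gene_id")) {
            term <- term[-1]; gene <- gene[-1]
        }
        terms <- lapply(split(gene, term), unique)
    }
    AnnotationSets(terms, universe = universe)
}

#' Write an enrichment result table
#'
#' @param x the [S4Vectors::DataFrame] returned by [hypergeomEnrich()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeEnrichment <- function(x, path) {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
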