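.dialectByName <- function(x) {
    if (inherits(x, "smr_dialect")) return(x)
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L) {
        return(switch(x,
                      cojo = cojoDialect(),
                      eqtl = eqtlDialect(),
                      gtex = gtexDialect(),
                      stop(sprintf("unknown dialect name '%s' (use cojo, eqtl or gtex)", x))))
    }
    if (is.list(x)) return(do.call(makeDialect, x))
    stop("cannot interpret dialect specification")
}

.validateConfig <- function(config) {
    need <- function(cond, msg) if (!cond) stop("invalid config: ", msg)
    need(!is.null(config$gwas$path), "gwas$path is required")
    need(length(config$tissues) >= 1L, "at least one tissue is required")
    for (t in config$tissues) {
        need(!is.null(t$label) && nzchar(t$label),
             "every tissue needs a non-empty label")
        need(!is.null(t$path), sprintf("tissue '%s' needs a path", t$label))
    }
    paths <- c(config$gwas$path,
               vapply(config$tissues, function(t) t$path, ""))
    need(!anyDuplicated(paths), "input paths must be distinct")
    labs <- vapply(config$tissues, function(t) t$label, "")
    need(!anyDuplicated(labs), "tissue labels must be distinct")
    alpha <- config$alpha %||% 0.05
    pInstr <- config$p_instrument %||% 5e-8
    need(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
    need(pInstr > 0 && pInstr < 1, "p_instrument must lie in (0, 1)")
    invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full multi-tissue SMR pipeline
#'
#' Orchestrates load -> instrument selection -> per-tissue SMR ->
#' cross-tissue aggregation -> summaries (-> optional enrichment) from a
#' single configuration, and writes every output plus a reproducibility
#' manifest into one directory.
#'
#' The configuration is a list (or path to a YAML file) with fields:
#' `gwas` (`path`, optional `dialect`: `"cojo"`, `"gtex"`, `"eqtl"` or a
#' mapping passed to [makeDialect()]); `tissues`, a list of entries with
#' `label`, `path`, optional `dialect`; `alpha` (default 0.05);
#' `p_instrument` (default 5e-8); `zx_floor` (default 1.96);
#' `harmonization` (default `TRUE`); `out_dir`; `seed` (recorded in the
#' manifest; the analysis itself is deterministic); optional `enrichment`
#' with `annot` (file) and optionally `query` (file of gene ids, default:
#' the significant genes) and `ease`.
#'
#' Outputs written to `out_dir`: `<label>.smr.tsv` per tissue, `pairs.tsv`,
#' `tissue_counts.tsv`, `overlap.json`, `repetitions.tsv`, optional
#' `enrichment.tsv`, and `manifest.json` recording the config, thresholds,
#' input MD5 digests and per-stage record counts.
#'
#' @param config list or path to a YAML config file.
#' @return invisibly, a list with the `pairs` [PairTable], the list of
#'   [SmrExperiment]s, the summary, and the manifest.
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config))
            stop(sprintf("config file not found: '%s'", config))
        config <- yaml::read_yaml(config)
    }
    .validateConfig(config)
    outDir <- config$out_dir %||% "."
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    alpha <- config$alpha %||% 0.05
    pInstr <- config$p_instrument %||% 5e-8
    zxFloor <- config$zx_floor %||% 1.96
    harmonize <- config$harmonization %||% TRUE
    band <- unlist(config$ambiguity_band %||% c(0.42, 0.58))

    gwas <- readGwas(config$gwas$path,
                     .dialectByName(config$gwas$dialect) %||% cojoDialect())
    stageCounts <- list(gwas = loadSummary(gwas))

    experiments <- list()
    for (t in config$tissues) {
        eq <- readEqtl(t$path, tissue = t$label,
                       .dialectByName(t$dialect) %||% eqtlDialect())
        inst <- selectInstruments(eq, gwas, pInstrument = pInstr,
                                  ambiguityBand = band,
                                  harmonize = harmonize)
        ex <- runTissueExperiment(inst, alpha = alpha, zxFloor = zxFloor)
        writeSmrResults(ex, file.path(outDir, paste0(t$label, ".smr.tsv")))
        stageCounts[[t$label]] <- c(loadSummary(eq),
                                    metadata(inst)$selection,
                                    metadata(ex)$counts)
        experiments[[t$label]] <- ex
    }

    pairs <- aggregatePairs(experiments)
    files <- writeCrossTissueOutputs(pairs, outDir)
    summary <- crossTissueSummary(pairs)

    enrichment <- NULL
    if (!is.null(config$enrichment)) {
        annot <- readAnnotation(config$enrichment$annot)
        query <- if (!is.null(config$enrichment$query))
            readLines(config$enrichment$query) else unique(pairs$gene_id)
        enrichment <- hypergeomEnrich(query, annot, alpha = alpha,
                                      ease = isTRUE(config$enrichment$ease))
        writeEnrichment(enrichment, file.path(outDir, "enrichment.tsv"))
    }

    inputs <- c(config$gwas$path,
                vapply(config$tissues, function(t) t$path, ""))
    manifest <- list(
        config = config,
        alpha = alpha, p_instrument = pInstr, zx_floor = zxFloor,
        harmonization = harmonize,
        seed = config$seed %||% NA,
        thresholds = lapply(experiments, threshold),
        input_md5 = as.list(tools::md5sum(inputs)),
        stage_counts = stageCounts,
        n_pairs = nrow(pairs))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    invisible(list(pairs = pairs, experiments = experiments,
                   summary = summary, enrichment = enrichment,
                   manifest = manifest, files = files))
}
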