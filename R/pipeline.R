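#' Run the full prioritization pipeline from a configuration
#'
#' Orchestrates every stage over files on disk: reads the paired expression
#' matrices, interaction table and optional annotation / validated-target /
#' gene-set / clinical inputs, computes the feature table, integrates it
#' with the requested method, and writes the outputs (`features.tsv`,
#' `ranking.tsv`, plus `cumulative_curve.tsv` and `overlap_tests.tsv` when
#' an annotation is given, `enrichment.tsv` when gene sets are given, and
#' `survival.tsv` when a clinical table is given) into the output
#' directory. Identical inputs and configuration produce identical outputs.
#'
#' @param config named list or path to a YAML file with fields:
#'   `mirna`, `genes`, `interactions` (character paths; `interactions` may
#'   list several files), optional `annotation`, `validated`, `gene_sets`,
#'   `clinical`; `transform` (`"none"`/`"log2p1"`, default `"none"`);
#'   `method` (`"orderstat"` default, `"average_ratio"`,
#'   `"inverse_normal"`, `"weighted"`); `weights` (for `"weighted"`);
#'   `top_k` (integer vector for overlap tests, default `c(20, 100)`);
#'   `pathway_top` (default 20); `survival_top` (default 100); `outdir`.
#' @return invisibly, a named list of the in-memory stage results.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  need <- c("mirna", "genes", "interactions", "outdir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config missing fields: ", paste(miss, collapse = ", "))
  transform <- if (is.null(config$transform)) "none" else config$transform
  method <- if (is.null(config$method)) "orderstat" else config$method
  topK <- if (is.null(config$top_k)) c(20L, 100L) else
    as.integer(config$top_k)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- "data_io"
  out <- tryCatch({
    mirna <- readExpressionMatrix(config$mirna, transform)
    genes <- readExpressionMatrix(config$genes, transform)
    clinical <- if (!is.null(config$clinical))
      readClinical(config$clinical) else NULL
    dataset <- alignPaired(mirna, genes, clinical)
    interactions <- readInteractions(unlist(config$interactions))

    stage <- "features"
    ft <- buildFeatureTable(dataset, interactions)
    writeFeatureTable(ft, file.path(outdir, "features.tsv"))

    stage <- "integration"
    if (method == "orderstat") {
      res <- integrateRanks(ft)
      writeIntegrationResult(res, ft, file.path(outdir, "ranking.tsv"))
      ranked <- rankedIds(res)
    } else {
      df <- switch(method,
        average_ratio = integrateAverageRatio(ft),
        inverse_normal = integrateInverseNormal(ft),
        weighted = integrateAverageRatio(
          ft, as.numeric(config$weights)),
        stop("unknown integration method: ", method))
      res <- df
      utils::write.table(df, file.path(outdir, "ranking.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ranked <- df$mirna
    }

    evalOut <- NULL
    if (!is.null(config$annotation)) {
      stage <- "evaluation"
      ann <- readAnnotation(config$annotation)
      curve <- cumulativeRatio(ranked, ann)
      utils::write.table(curve,
                         file.path(outdir, "cumulative_curve.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      Muniv <- length(ranked)
      K <- sum(ranked %in% ann$mirnaIds)
      tests <- do.call(rbind, lapply(topK[topK <= Muniv], function(n)
        hypergeomOverlap(Muniv, K, n, curve$count[n])))
      utils::write.table(tests, file.path(outdir, "overlap_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      evalOut <- list(curve = curve, tests = tests)
    }

    enr <- NULL
    if (!is.null(config$gene_sets)) {
      stage <- "pathway_enrichment"
      gsc <- readGMT(config$gene_sets)
      validated <- if (!is.null(config$validated))
        readInteractions(unlist(config$validated)) else NULL
      top <- if (is.null(config$pathway_top)) 20L else
        as.integer(config$pathway_top)
      enr <- enrichTopMirnas(ranked, dataset, gsc, validated,
                             top = top)
      utils::write.table(enr, file.path(outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    surv <- NULL
    if (!is.null(config$clinical) && nrow(clinicalData(dataset))) {
      stage <- "survival"
      top <- if (is.null(config$survival_top)) 100L else
        as.integer(config$survival_top)
      surv <- survivalScreen(ranked, dataset,
                             top = min(top, length(ranked)))
      utils::write.table(surv, file.path(outdir, "survival.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    list(dataset = dataset, features = ft, result = res,
         ranked = ranked, evaluation = evalOut, enrichment = enr,
         survival = surv)
  }, error = function(e)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE))
  invisible(out)
}
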