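#' Genes related to a miRNA: top-|PCC| genes plus validated targets
#'
#' Builds the per-miRNA query gene set used for pathway enrichment: the
#' union of (a) the `ceiling(fraction * G)` genes whose expression is most
#' strongly correlated (largest |PCC|) with the miRNA's expression, where G
#' is the number of genes in the matrix, and (b) genes experimentally
#' validated to interact with the miRNA (a miRTarbase-style table). Genes
#' tied with the cutoff |PCC| are all included. Zero-variance genes carry no
#' defined correlation and cannot enter via (a).
#'
#' @param mirnaId miRNA id present in the dataset.
#' @param dataset a [PairedDataset-class].
#' @param validated optional data.frame of validated interactions with
#'   columns `mirna`, `gene`.
#' @param fraction top fraction of genes by |PCC|, default 0.01.
#' @return character vector of gene ids.
#' @export
relatedGenes <- function(mirnaId, dataset, validated = NULL,
                         fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  mi <- mirnaExprs(dataset)
  if (!mirnaId %in% rownames(mi))
    stop("miRNA not in expression matrix: ", mirnaId)
  ge <- geneExprs(dataset)
  G <- nrow(ge)
  x <- mi[mirnaId, ]
  if (stats::var(x) == 0)
    stop("miRNA has zero variance; correlations undefined: ", mirnaId)
  gvar <- apply(ge, 1L, stats::var)
  r <- rep(NA_real_, G)
  names(r) <- rownames(ge)
  r[gvar > 0] <- abs(as.numeric(
    stats::cor(x, t(ge[gvar > 0, , drop = FALSE]))))
  nTop <- min(ceiling(fraction * G), sum(!is.na(r)))
  thr <- sort(r, decreasing = TRUE, na.last = NA)[nTop]
  top <- names(r)[!is.na(r) & r >= thr]
  val <- if (is.null(validated)) character() else
    unique(validated$gene[validated$mirna == mirnaId])
  union(top, val)
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' Tests a query gene set against every set in a collection with the
#' upper-tail hypergeometric test (universe = the collection's declared
#' background), then adjusts the p-values across the sets of this one query
#' with the Benjamini-Hochberg step-up procedure. Sets with q < `alpha` are
#' flagged significant. Query genes outside the background are dropped with
#' a warning. Output order (by p, then set name) does not depend on the
#' collection's iteration order.
#'
#' @param query character vector of gene ids.
#' @param collection a [GeneSetCollection-class].
#' @param alpha significance threshold on q, default 0.05.
#' @param mirnaId optional label recorded in the output.
#' @return data.frame with columns `mirna`, `set_name`, `overlap`,
#'   `set_size`, `query_size`, `background_size`, `p`, `q`, `significant`.
#' @export
enrichGeneSets <- function(query, collection, alpha = 0.05,
                           mirnaId = NA_character_) {
  bg <- geneBackground(collection)
  if (!length(bg)) stop("empty background universe")
  query <- unique(query)
  inBg <- query %in% bg
  if (any(!inBg))
    warning(sum(!inBg), " query gene(s) outside background dropped")
  query <- query[inBg]
  sets <- geneSets(collection)
  Mbg <- length(bg)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    x <- length(intersect(query, s))
    p <- hypergeomOverlap(Mbg, length(s), n, x)$p
    data.frame(mirna = mirnaId, set_name = nm, overlap = x,
               set_size = length(s), query_size = n,
               background_size = Mbg, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  out <- out[order(out$p, out$set_name), ]
  rownames(out) <- NULL
  out
}

#' Pathway enrichment for the top-ranked miRNAs
#'
#' Convenience wrapper: for each of the `top` highest-priority miRNAs,
#' builds its related-gene set with [relatedGenes()] and runs
#' [enrichGeneSets()]; BH correction is applied per miRNA.
#'
#' @param result an [IntegrationResult-class], or a character vector of
#'   miRNA ids already in ranked order.
#' @param dataset the [PairedDataset-class] the ranking came from.
#' @param collection a [GeneSetCollection-class].
#' @param validated optional validated-interaction data.frame.
#' @param top number of top miRNAs to analyze, default 20.
#' @param fraction top-|PCC| gene fraction, default 0.01.
#' @return data.frame of stacked [enrichGeneSets()] rows.
#' @export
enrichTopMirnas <- function(result, dataset, collection, validated = NULL,
                            top = 20L, fraction = 0.01) {
  ids <- if (is.character(result)) result else rankedIds(result)
  ids <- utils::head(ids, top)
  ids <- ids[ids %in% rownames(mirnaExprs(dataset))]
  do.call(rbind, lapply(ids, function(id) {
    q <- relatedGenes(id, dataset, validated, fraction)
    suppressWarnings(enrichGeneSets(q, collection, mirnaId = id))
  }))
}
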