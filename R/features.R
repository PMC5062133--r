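#' Mean tumor expression per miRNA (feature F1)
#'
#' Arithmetic mean of each miRNA's expression across all tumor samples.
#' Normal samples play no role anywhere in the method.
#'
#' @param dataset a [PairedDataset-class].
#' @return named numeric vector `a`, one entry per miRNA.
#' @export
meanExpression <- function(dataset) {
  m <- mirnaExprs(dataset)
  if (ncol(m) < 1L) stop("no samples")
  rowMeans(m)
}

#' Mean absolute miRNA-gene correlation (feature F2)
#'
#' For each miRNA, the mean over all retained genes of the absolute Pearson
#' correlation between that miRNA's expression and the gene's expression
#' across samples. All genes in the matrix are used, not only predicted
#' targets: the feature is meant to capture network-wide association.
#' Genes with zero variance across samples have no defined correlation and
#' are excluded globally, so every miRNA is averaged over the same gene
#' universe. A zero-variance miRNA gets `c = 0` with a warning.
#'
#' @param dataset a [PairedDataset-class] with at least 3 samples.
#' @return named numeric vector `c` in [0,1], one entry per miRNA.
#' @export
meanAbsCorrelation <- function(dataset) {
  mi <- mirnaExprs(dataset)
  ge <- geneExprs(dataset)
  if (ncol(mi) < 3L) stop("need at least 3 samples for correlations")
  gvar <- apply(ge, 1L, stats::var)
  keep <- gvar > 0
  if (!any(keep)) stop("all genes have zero variance")
  ge <- ge[keep, , drop = FALSE]
  mvar <- apply(mi, 1L, stats::var)
  cc <- rep(0, nrow(mi))
  names(cc) <- rownames(mi)
  if (any(mvar == 0))
    warning("zero-variance miRNA(s) assigned c = 0: ",
            paste(rownames(mi)[mvar == 0], collapse = ", "))
  ok <- mvar > 0
  if (any(ok)) {
    r <- stats::cor(t(mi[ok, , drop = FALSE]), t(ge))
    cc[ok] <- rowMeans(abs(r))
  }
  cc
}

#' Predicted target count per miRNA (feature F3)
#'
#' Number of distinct genes paired with each miRNA in the deduplicated
#' predicted-interaction table. Sequence-based target predictions do not
#' depend on the expression data, so this feature is identical across
#' cancer datasets. miRNAs absent from the table get 0.
#'
#' @param mirnaIds character vector of miRNA ids to count for.
#' @param interactions data.frame with columns `mirna`, `gene`
#'   (see [readInteractions()]).
#' @return named integer vector `t`.
#' @export
targetCount <- function(mirnaIds, interactions) {
  pairs <- unique(interactions[, c("mirna", "gene")])
  tab <- table(factor(pairs$mirna, levels = mirnaIds))
  stats::setNames(as.integer(tab), mirnaIds)
}

#' Build the per-miRNA feature table
#'
#' Composes [meanExpression()], [meanAbsCorrelation()] and [targetCount()]
#' over the dataset's miRNA id order.
#'
#' @param dataset a [PairedDataset-class].
#' @param interactions predicted-interaction data.frame.
#' @return a [FeatureTable-class].
#' @export
buildFeatureTable <- function(dataset, interactions) {
  ids <- mirnaIds(dataset)
  methods::new("FeatureTable",
               mirna = ids,
               a = unname(meanExpression(dataset)),
               c = unname(pmin(1, meanAbsCorrelation(dataset))),
               t = as.numeric(targetCount(ids, interactions)))
}

#' Serialize / deserialize a feature table as 4-column TSV
#'
#' @param ft a [FeatureTable-class].
#' @param path file path.
#' @export
writeFeatureTable <- function(ft, path) {
  df <- as.data.frame(ft)
  df$a <- sprintf("%.17g", df$a)
  df$c <- sprintf("%.17g", df$c)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  methods::new("FeatureTable", mirna = as.character(df$mirna),
               a = as.numeric(df$a), c = as.numeric(df$c),
               t = as.numeric(df$t))
}

#' Construct a feature table directly from vectors
#'
#' Mainly useful for simulation studies and tests.
#'
#' @param mirna character ids; `a`, `c`, `t` numeric feature vectors.
#' @param a,c,t feature vectors (mean expression, mean |PCC|, target count).
#' @return a [FeatureTable-class].
#' @export
featureTable <- function(mirna, a, c, t) {
  methods::new("FeatureTable", mirna = as.character(mirna),
               a = as.numeric(a), c = as.numeric(c), t = as.numeric(t))
}
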