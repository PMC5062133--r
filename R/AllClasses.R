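#' @import methods
NULL

#' Paired miRNA/mRNA tumor expression dataset
#'
#' Container holding a miRNA expression matrix and a gene expression matrix
#' measured on the same tumor samples (columns), optionally with a clinical
#' table (overall survival in days plus a death/censoring indicator) for a
#' subset of those samples. Both matrices are entities x samples with unique
#' row and column names and no missing values; the sample columns are aligned
#' to identical order.
#'
#' @slot mirna numeric matrix, miRNAs x samples.
#' @slot genes numeric matrix, genes x samples; `colnames(genes)` must equal
#'   `colnames(mirna)` in the same order.
#' @slot clinical data.frame with columns `sample_id`, `time` (days, >= 0)
#'   and `event` (1 = deceased, 0 = censored); may have zero rows. Sample ids
#'   must be a subset of the expression sample ids.
#'
#' @seealso [alignPaired()] to construct one from possibly unaligned
#'   matrices, [buildFeatureTable()] for the downstream feature computation.
#' @export
setClass("PairedDataset",
  representation(mirna = "matrix", genes = "matrix", clinical = "data.frame"),
  prototype(clinical = data.frame(sample_id = character(),
                                  time = numeric(), event = integer()))
)

setValidity("PairedDataset", function(object) {
  msg <- character()
  for (nm in c("mirna", "genes")) {
    m <- slot(object, nm)
    if (!is.numeric(m)) msg <- c(msg, sprintf("'%s' must be numeric", nm))
    if (is.null(rownames(m)) || is.null(colnames(m)))
      msg <- c(msg, sprintf("'%s' must have row and column names", nm))
    else {
      if (anyDuplicated(rownames(m)))
        msg <- c(msg, sprintf("duplicate entity ids in '%s'", nm))
      if (anyDuplicated(colnames(m)))
        msg <- c(msg, sprintf("duplicate sample ids in '%s'", nm))
    }
    if (anyNA(m)) msg <- c(msg, sprintf("missing values in '%s'", nm))
  }
  if (!identical(colnames(object@mirna), colnames(object@genes)))
    msg <- c(msg, "mirna and genes sample ids differ (order included)")
  cl <- object@clinical
  if (nrow(cl)) {
    if (!all(c("sample_id", "time", "event") %in% names(cl)))
      msg <- c(msg, "clinical needs columns sample_id, time, event")
    else {
      if (anyDuplicated(cl$sample_id))
        msg <- c(msg, "duplicate clinical sample ids")
      if (!all(cl$sample_id %in% colnames(object@mirna)))
        msg <- c(msg, "clinical sample ids not all present in expression data")
      if (any(cl$time < 0)) msg <- c(msg, "negative survival times")
      if (!all(cl$event %in% c(0L, 1L))) msg <- c(msg, "event must be 0/1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-miRNA feature table
#'
#' Holds the three prioritization features for M miRNAs: `a` (mean tumor
#' expression), `c` (mean absolute Pearson correlation against all retained
#' genes, in [0,1]) and `t` (number of distinct predicted target genes).
#'
#' @slot mirna character vector of M unique miRNA ids.
#' @slot a numeric, mean expression per miRNA.
#' @slot c numeric in [0,1], mean |PCC| per miRNA.
#' @slot t non-negative numeric (integer-valued), predicted target counts.
#'
#' @seealso [buildFeatureTable()], [integrateRanks()]
#' @export
setClass("FeatureTable",
  representation(mirna = "character", a = "numeric", c = "numeric",
                 t = "numeric"))

setValidity("FeatureTable", function(object) {
  M <- length(object@mirna)
  msg <- character()
  if (anyDuplicated(object@mirna)) msg <- c(msg, "duplicate miRNA ids")
  if (length(object@a) != M || length(object@c) != M || length(object@t) != M)
    msg <- c(msg, "feature vectors must all have length M")
  if (anyNA(object@c) || any(object@c < 0 | object@c > 1))
    msg <- c(msg, "c entries must lie in [0,1]")
  if (anyNA(object@t) || any(object@t < 0) ||
      any(object@t != round(object@t)))
    msg <- c(msg, "t entries must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' Order-statistics integration result
#'
#' Per-miRNA Q statistics in both ranking directions and the derived
#' rankings. `q1` integrates the descending (relevance) ranking ratios and is
#' small when a miRNA ranks uniformly high on all features; `q2` integrates
#' the ascending (irrelevance) ratios and is small when it ranks uniformly
#' low. `rq1` ranks `q1` ascending, `rq2` ranks `q2` descending (average
#' ranks on ties), `rq = rq1 + rq2`, and `finalRank` is the permutation of
#' 1..M ordering `rq` ascending with ties broken by smaller `rq1`, then
#' lexicographic miRNA id.
#'
#' @slot mirna character, miRNA ids.
#' @slot q1,q2 numeric in [0,1].
#' @slot rq1,rq2,rq numeric rank vectors.
#' @slot finalRank integer permutation of 1..M (1 = top candidate).
#'
#' @seealso [integrateRanks()], [rankedIds()]
#' @export
setClass("IntegrationResult",
  representation(mirna = "character", q1 = "numeric", q2 = "numeric",
                 rq1 = "numeric", rq2 = "numeric", rq = "numeric",
                 finalRank = "integer"))

setValidity("IntegrationResult", function(object) {
  M <- length(object@mirna)
  msg <- character()
  lens <- vapply(c("q1", "q2", "rq1", "rq2", "rq", "finalRank"),
                 function(s) length(slot(object, s)), integer(1))
  if (!all(lens == M)) msg <- c(msg, "all slots must have length M")
  if (any(object@q1 < -1e-12 | object@q1 > 1 + 1e-12) ||
      any(object@q2 < -1e-12 | object@q2 > 1 + 1e-12))
    msg <- c(msg, "Q statistics must lie in [0,1]")
  if (!identical(sort(object@finalRank), seq_len(M)))
    msg <- c(msg, "finalRank must be a permutation of 1..M")
  if (max(abs(object@rq - (object@rq1 + object@rq2))) > 1e-9)
    msg <- c(msg, "rq must equal rq1 + rq2")
  if (length(msg)) msg else TRUE
})

#' Named gene sets over a declared background universe
#'
#' @slot sets named list of character vectors; every member gene belongs to
#'   `background`, set names are unique.
#' @slot background character vector, the enrichment universe.
#'
#' @seealso [readGMT()], [enrichGeneSets()]
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", background = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "sets must be uniquely named")
  if (anyDuplicated(object@background))
    msg <- c(msg, "duplicate genes in background")
  ok <- vapply(object@sets,
               function(s) all(s %in% object@background), logical(1))
  if (!all(ok))
    msg <- c(msg, "every gene-set member must be in the background universe")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "PairedDataset", function(object) {
  cat("PairedDataset\n",
      " miRNAs : ", nrow(object@mirna), "\n",
      " genes  : ", nrow(object@genes), "\n",
      " samples: ", ncol(object@mirna), "\n",
      " clinical records: ", nrow(object@clinical), "\n", sep = "")
})

#' @export
setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable with", length(object@mirna), "miRNAs\n")
  print(utils::head(as.data.frame(object), 5L))
  if (length(object@mirna) > 5L) cat("...\n")
})

#' @export
setMethod("show", "IntegrationResult", function(object) {
  cat("IntegrationResult with", length(object@mirna), "miRNAs\n")
  df <- as.data.frame(object)
  print(utils::head(df[order(df$final_rank), ], 5L))
  if (length(object@mirna) > 5L) cat("...\n")
})

#' @export
setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets over",
      length(object@background), "background genes\n")
})

#' @describeIn PairedDataset miRNA expression matrix accessor.
#' @param object,x an object of the documented class.
#' @export
setGeneric("mirnaExprs", function(object) standardGeneric("mirnaExprs"))
setMethod("mirnaExprs", "PairedDataset", function(object) object@mirna)

#' @describeIn PairedDataset gene expression matrix accessor.
#' @export
setGeneric("geneExprs", function(object) standardGeneric("geneExprs"))
setMethod("geneExprs", "PairedDataset", function(object) object@genes)

#' @describeIn PairedDataset clinical table accessor (possibly zero rows).
#' @export
setGeneric("clinicalData", function(object) standardGeneric("clinicalData"))
setMethod("clinicalData", "PairedDataset", function(object) object@clinical)

#' @describeIn PairedDataset sample ids (shared by both matrices).
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
setMethod("sampleIds", "PairedDataset",
          function(object) colnames(object@mirna))

#' miRNA ids held by an object
#' @param object a `PairedDataset`, `FeatureTable` or `IntegrationResult`.
#' @export
setGeneric("mirnaIds", function(object) standardGeneric("mirnaIds"))
setMethod("mirnaIds", "PairedDataset", function(object) rownames(object@mirna))
setMethod("mirnaIds", "FeatureTable", function(object) object@mirna)
setMethod("mirnaIds", "IntegrationResult", function(object) object@mirna)

#' @describeIn GeneSetCollection named list of gene sets.
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))
setMethod("geneSets", "GeneSetCollection", function(object) object@sets)

#' @describeIn GeneSetCollection background gene universe.
#' @export
setGeneric("geneBackground", function(object) standardGeneric("geneBackground"))
setMethod("geneBackground", "GeneSetCollection",
          function(object) object@background)

#' Final prioritized miRNA ordering
#'
#' @param object an `IntegrationResult`.
#' @return character vector of miRNA ids, best candidate first.
#' @export
setGeneric("rankedIds", function(object) standardGeneric("rankedIds"))
setMethod("rankedIds", "IntegrationResult", function(object)
  object@mirna[order(object@finalRank)])

#' @export
as.data.frame.FeatureTable <- function(x, ...) {
  data.frame(mirna = x@mirna, a = x@a, c = x@c, t = x@t,
             stringsAsFactors = FALSE)
}
#' @export
setMethod("as.data.frame", "FeatureTable", as.data.frame.FeatureTable)

#' @export
as.data.frame.IntegrationResult <- function(x, ...) {
  data.frame(mirna = x@mirna, q1 = x@q1, q2 = x@q2, rq1 = x@rq1,
             rq2 = x@rq2, rq = x@rq, final_rank = x@finalRank,
             stringsAsFactors = FALSE)
}
#' @export
setMethod("as.data.frame", "IntegrationResult",
          as.data.frame.IntegrationResult)
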