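#' Normalize miRNA/gene identifiers
#'
#' Deterministic rule applied by every reader so that expression matrices,
#' interaction tables and annotation lists can be matched by exact string
#' equality: trim surrounding whitespace, lowercase, and strip a leading
#' `"hsa-"` species prefix. Mature vs precursor miRNA naming is *not*
#' reconciled; ids that differ beyond this rule are treated as distinct.
#'
#' @param ids character vector.
#' @return normalized character vector of the same length.
#' @examples
#' normalizeIds(c("hsa-miR-21 ", "MIR-21", "TP53"))
#' @export
normalizeIds <- function(ids) {
  ids <- tolower(trimws(as.character(ids)))
  sub("^hsa-", "", ids)
}

#' Read an expression matrix from a tab-separated file
#'
#' Expects a header row of sample ids and a first column of entity ids
#' (miRNAs or genes), i.e. entities x samples. Entity ids are passed through
#' [normalizeIds()]. Rows containing any missing value are dropped with a
#' message stating how many.
#'
#' @param path file path.
#' @param transform `"none"` or `"log2p1"` (applies `log2(x + 1)`, the usual
#'   RNA-Seq count stabilization).
#' @return numeric matrix with entity rownames and sample colnames.
#' @export
readExpressionMatrix <- function(path, transform = c("none", "log2p1")) {
  transform <- match.arg(transform)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty or headerless expression file: ", path)
  ids <- normalizeIds(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate entity ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample ids in ", path)
  raw <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- array(as.numeric(raw), dim = dim(raw)))
  bad <- is.na(num) & !(is.na(raw) | raw %in% c("NA", ""))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                 raw[bad][1L], ids[w[1L]], samples[w[2L]], path))
  }
  dimnames(num) <- list(ids, samples)
  miss <- apply(is.na(num), 1L, any)
  if (any(miss)) {
    message(sum(miss), " row(s) with missing values dropped from ", path)
    num <- num[!miss, , drop = FALSE]
  }
  if (nrow(num) == 0L) stop("no complete rows left in ", path)
  if (transform == "log2p1") {
    if (any(num < 0)) stop("log2p1 transform requires non-negative values")
    num <- log2(num + 1)
  }
  num
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [readExpressionMatrix()] (with `transform = "none"`); values
#' are written at full double precision so read/write round-trips are
#' lossless.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param idColumn header for the entity-id column.
#' @export
writeExpressionMatrix <- function(mat, path, idColumn = "id") {
  out <- cbind(rownames(mat),
               matrix(sprintf("%.17g", mat), nrow = nrow(mat)))
  colnames(out) <- c(idColumn, colnames(mat))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read predicted miRNA-target interactions
#'
#' Each file is two-column tab-separated (miRNA id, gene id). Pairs are
#' unioned across files and deduplicated; both columns are normalized with
#' [normalizeIds()].
#'
#' @param paths character vector of file paths.
#' @return data.frame with columns `mirna`, `gene`, one row per distinct
#'   pair.
#' @export
readInteractions <- function(paths) {
  pieces <- lapply(paths, function(p) {
    lines <- readLines(p)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
      return(data.frame(mirna = character(), gene = character()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 2L))
      stop(sprintf("malformed interaction line %d in %s",
                   which(nf < 2L)[1L], p))
    data.frame(mirna = normalizeIds(vapply(parts, `[[`, "", 1L)),
               gene = normalizeIds(vapply(parts, `[[`, "", 2L)),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, pieces)
  if (any(!nzchar(all$mirna)) || any(!nzchar(all$gene)))
    stop("empty identifier in interaction table")
  unique(all)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. The background
#' universe defaults to the union of all member genes.
#'
#' @param path GMT file path.
#' @param background optional explicit universe (character); member genes
#'   outside it raise an error via the class validity check.
#' @return a [GeneSetCollection-class] object.
#' @export
readGMT <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop(sprintf("GMT line %d has fewer than 3 fields in %s",
                 which(nf < 3L)[1L], path))
  sets <- lapply(parts, function(f) unique(normalizeIds(f[-c(1L, 2L)])))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in ", path)
  if (is.null(background)) background <- unique(unlist(sets))
  else background <- unique(normalizeIds(background))
  methods::new("GeneSetCollection", sets = sets, background = background)
}

#' Construct a gene-set collection in memory
#'
#' @param sets named list of character vectors.
#' @param background universe; defaults to the union of all members.
#' @return a [GeneSetCollection-class].
#' @export
geneSetCollection <- function(sets, background = NULL) {
  sets <- lapply(sets, unique)
  if (is.null(background)) background <- unique(unlist(sets))
  methods::new("GeneSetCollection", sets = sets,
               background = unique(background))
}

#' Read a disease-miRNA annotation list
#'
#' One miRNA id per line (a curated disease-association list such as an
#' HMDD export). Ids are normalized with [normalizeIds()].
#'
#' @param path file path.
#' @param diseaseLabel label attached to the set.
#' @return list with elements `disease` (character scalar) and `mirnaIds`
#'   (unique character vector).
#' @export
readAnnotation <- function(path, diseaseLabel = "disease") {
  stopifnot(nzchar(diseaseLabel))
  ids <- readLines(path)
  ids <- normalizeIds(ids[nzchar(trimws(ids))])
  list(disease = diseaseLabel, mirnaIds = unique(ids))
}

#' Read a clinical survival table
#'
#' Tab-separated with header `sample_id`, `time`, `event`: survival time in
#' days (>= 0) and a 0/1 event flag (1 = deceased, 0 = censored).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readClinical <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("clinical table needs columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate clinical sample ids")
  if (!is.numeric(df$time) || any(df$time < 0))
    stop("clinical time must be non-negative days")
  if (!all(df$event %in% c(0, 1))) stop("clinical event must be 0/1")
  df$event <- as.integer(df$event)
  df
}

#' Align miRNA and gene matrices into a PairedDataset
#'
#' Restricts both matrices to the intersection of their sample ids, in a
#' canonical (sorted) order, and attaches clinical records for samples
#' present in the expression data. Idempotent and invariant to input column
#' permutations.
#'
#' @param mirna,genes numeric matrices, entities x samples.
#' @param clinical optional clinical data.frame (see [readClinical()]);
#'   records for samples absent from the expression data are dropped with a
#'   message.
#' @return a [PairedDataset-class].
#' @export
alignPaired <- function(mirna, genes, clinical = NULL) {
  common <- intersect(colnames(mirna), colnames(genes))
  if (!length(common))
    stop("no samples shared between miRNA and gene matrices")
  common <- sort(common)
  mirna <- mirna[, common, drop = FALSE]
  genes <- genes[, common, drop = FALSE]
  if (is.null(clinical)) {
    clinical <- data.frame(sample_id = character(), time = numeric(),
                           event = integer())
  } else {
    keep <- clinical$sample_id %in% common
    if (any(!keep))
      message(sum(!keep),
              " clinical record(s) without expression data dropped")
    clinical <- clinical[keep, , drop = FALSE]
    rownames(clinical) <- NULL
  }
  methods::new("PairedDataset", mirna = mirna, genes = genes,
               clinical = clinical)
}
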