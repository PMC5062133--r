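#' Configuration for the synthetic paired-data generator
#'
#' Defines the simulated study: a tumor cohort with paired miRNA and gene
#' expression in which `nDrivers` "driver" miRNAs carry signal in all three
#' prioritization features, plus matching interaction, annotation, gene-set
#' and clinical fixtures. Defaults describe the strong planted-signal
#' condition used for validation: 100 samples, 1000 genes, 200 miRNAs with
#' 10 drivers; drivers are elevated by 3 noise-SD in mean expression, have
#' 50 predicted targets (vs 5 for background miRNAs) and share a latent
#' factor with their targets at loading 0.8. Survival follows an
#' exponential proportional-hazards model (baseline mean 500 days, a
#' GBM-like scale) with hazard multiplied by `survivalEffect` per SD of a
#' sample's mean standardized driver expression, and ~30% independent
#' exponential censoring.
#'
#' @param nSamples,nGenes,nMirnas,nDrivers cohort dimensions.
#' @param driverExprShift driver mean-expression elevation in noise-SD
#'   units.
#' @param driverTargetCount,backgroundTargetCount predicted targets per
#'   driver / non-driver miRNA.
#' @param driverCorr latent-factor loading in [0, 1); 0 gives a null
#'   construction with no miRNA-target correlation.
#' @param noiseSd residual SD of expression noise.
#' @param survivalEffect hazard multiplier per SD of driver-expression
#'   score; 1 = no survival signal.
#' @param censorRate target censoring fraction in [0, 1).
#' @param seed integer seed; all randomness flows from it.
#' @return validated config list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(nSamples = 100L, nGenes = 1000L,
                            nMirnas = 200L, nDrivers = 10L,
                            driverExprShift = 3, driverTargetCount = 50L,
                            backgroundTargetCount = 5L, driverCorr = 0.8,
                            noiseSd = 1, survivalEffect = 3,
                            censorRate = 0.3, seed = 1L) {
  cfg <- list(nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
              nMirnas = as.integer(nMirnas), nDrivers = as.integer(nDrivers),
              driverExprShift = driverExprShift,
              driverTargetCount = as.integer(driverTargetCount),
              backgroundTargetCount = as.integer(backgroundTargetCount),
              driverCorr = driverCorr, noiseSd = noiseSd,
              survivalEffect = survivalEffect, censorRate = censorRate,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(nSamples > 0, nGenes > 0, nMirnas > 0, nDrivers > 0,
              nDrivers <= nMirnas, driverTargetCount >= 0,
              backgroundTargetCount >= 0, driverTargetCount <= nGenes,
              backgroundTargetCount <= nGenes, driverCorr >= 0,
              driverCorr < 1, noiseSd > 0, driverExprShift >= 0,
              survivalEffect > 0, censorRate >= 0, censorRate < 1)
  })
  structure(cfg, class = "SyntheticConfig")
}

#' A null configuration with no planted signal
#'
#' Drivers keep their labels but are exchangeable with background miRNAs:
#' no expression shift, no latent-factor correlation, equal target counts,
#' no survival effect.
#'
#' @param ... overrides passed to [syntheticConfig()].
#' @return a `"SyntheticConfig"`.
#' @export
nullSyntheticConfig <- function(...) {
  args <- list(driverExprShift = 0, driverCorr = 0,
               driverTargetCount = 5L, backgroundTargetCount = 5L,
               survivalEffect = 1)
  override <- list(...)
  args[names(override)] <- override
  do.call(syntheticConfig, args)
}

#' Generate a synthetic bundle of pipeline inputs
#'
#' Produces, deterministically from `config$seed`, every input the pipeline
#' consumes: a [PairedDataset-class] (with clinical table), a predicted
#' interaction table, a disease annotation naming the planted drivers, a
#' [GeneSetCollection-class] whose "driver pathway" sets are built around
#' each driver's targets, and the ground-truth driver ids.
#'
#' Signal construction per driver: (F1) mean expression elevated by
#' `driverExprShift * noiseSd`; (F3) `driverTargetCount` predicted targets
#' vs `backgroundTargetCount` for background miRNAs; (F2) a driver-specific
#' Gaussian latent factor entering the driver's expression and each of its
#' targets' expression with loading `driverCorr`, the target-side sign
#' randomized per gene so only |PCC| carries signal. Survival times are
#' exponential with per-sample hazard `(1/500) * survivalEffect^z`, where z
#' is the sample's mean standardized driver expression; censoring is an
#' independent exponential calibrated so about `censorRate` of subjects are
#' censored.
#'
#' @param config a `"SyntheticConfig"` from [syntheticConfig()].
#' @return list with elements `dataset`, `interactions`, `annotation`,
#'   `geneSets`, `truth`.
#' @export
generateBundle <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(config$seed)
  ns <- config$nSamples; ng <- config$nGenes; nm <- config$nMirnas
  nd <- config$nDrivers; sdN <- config$noiseSd
  lam <- config$driverCorr
  mirnaIds <- sprintf("mir-%04d", seq_len(nm))
  geneIds <- sprintf("gene-%05d", seq_len(ng))
  sampleIds <- sprintf("s%04d", seq_len(ns))
  drivers <- sort(sample(mirnaIds, nd))
  isDriver <- mirnaIds %in% drivers

  # latent factors, one per driver
  fac <- matrix(stats::rnorm(nd * ns), nrow = nd,
                dimnames = list(drivers, sampleIds))

  mu <- stats::rnorm(nm, mean = 5, sd = 1)
  mu[isDriver] <- mu[isDriver] + config$driverExprShift * sdN
  mirna <- mu + sdN * matrix(stats::rnorm(nm * ns), nrow = nm)
  dimnames(mirna) <- list(mirnaIds, sampleIds)
  resid <- sqrt(1 - lam^2)
  mirna[drivers, ] <- mu[isDriver] +
    sdN * (lam * fac + resid * matrix(stats::rnorm(nd * ns), nrow = nd))

  # interactions: drivers get driverTargetCount targets, others background
  nTarget <- ifelse(isDriver, config$driverTargetCount,
                    config$backgroundTargetCount)
  targets <- lapply(seq_len(nm), function(i)
    sample(geneIds, nTarget[i]))
  names(targets) <- mirnaIds
  interactions <- data.frame(
    mirna = rep(mirnaIds, nTarget),
    gene = unlist(targets, use.names = FALSE),
    stringsAsFactors = FALSE)

  gmu <- stats::rnorm(ng, mean = 5, sd = 1)
  genes <- gmu + sdN * matrix(stats::rnorm(ng * ns), nrow = ng)
  dimnames(genes) <- list(geneIds, sampleIds)
  claimed <- character()
  for (d in drivers) {
    tg <- setdiff(targets[[d]], claimed)
    claimed <- c(claimed, tg)
    if (!length(tg)) next
    sgn <- sample(c(-1, 1), length(tg), replace = TRUE)
    genes[tg, ] <- gmu[match(tg, geneIds)] +
      sdN * (sgn * lam * matrix(rep(fac[d, ], each = length(tg)),
                                nrow = length(tg)) +
             resid * matrix(stats::rnorm(length(tg) * ns),
                            nrow = length(tg)))
  }

  annotation <- list(disease = "synthetic_cancer", mirnaIds = drivers)

  # gene sets: one "pathway" built around each driver's targets + decoys
  sets <- list()
  for (i in seq_along(drivers)) {
    tg <- targets[[drivers[i]]]
    fill <- sample(setdiff(geneIds, tg),
                   min(10L, ng - length(tg)))
    sets[[sprintf("driver_pathway_%02d", i)]] <- c(tg, fill)
  }
  for (i in seq_len(15L))
    sets[[sprintf("random_set_%02d", i)]] <-
      sample(geneIds, min(50L, ng))
  geneSetsObj <- geneSetCollection(sets, background = geneIds)

  # clinical: exponential PH model on the mean standardized driver score
  z <- rowMeans(scale(t(mirna[drivers, , drop = FALSE])))
  z <- (z - mean(z)) / stats::sd(z)
  base <- 1 / 500  # baseline hazard, 1/days
  hazard <- base * config$survivalEffect^z
  tEvent <- stats::rexp(ns, rate = hazard)
  if (config$censorRate > 0) {
    cRate <- base * config$censorRate / (1 - config$censorRate)
    tCens <- stats::rexp(ns, rate = cRate)
  } else tCens <- rep(Inf, ns)
  clinical <- data.frame(sample_id = sampleIds,
                         time = pmin(tEvent, tCens),
                         event = as.integer(tEvent <= tCens),
                         stringsAsFactors = FALSE)

  dataset <- alignPaired(mirna, genes, clinical)
  list(dataset = dataset, interactions = interactions,
       annotation = annotation, geneSets = geneSetsObj, truth = drivers)
}

#' Write a synthetic bundle to disk in the standard exchange formats
#'
#' Emits `mirna.tsv`, `genes.tsv` (expression matrices), `interactions.tsv`
#' (two-column pairs), `annotation.txt` (one id per line), `gene_sets.gmt`
#' and `clinical.tsv` into `dir`, all readable by the package's readers.
#'
#' @param bundle output of [generateBundle()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written file paths.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mirna = file.path(dir, "mirna.tsv"),
             genes = file.path(dir, "genes.tsv"),
             interactions = file.path(dir, "interactions.tsv"),
             annotation = file.path(dir, "annotation.txt"),
             geneSets = file.path(dir, "gene_sets.gmt"),
             clinical = file.path(dir, "clinical.tsv"))
  writeExpressionMatrix(mirnaExprs(bundle$dataset), paths["mirna"],
                        idColumn = "mirna")
  writeExpressionMatrix(geneExprs(bundle$dataset), paths["genes"],
                        idColumn = "gene")
  utils::write.table(bundle$interactions, paths["interactions"],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  writeLines(bundle$annotation$mirnaIds, paths["annotation"])
  sets <- geneSets(bundle$geneSets)
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), ""),
    paths["geneSets"])
  cl <- clinicalData(bundle$dataset)
  cl$time <- sprintf("%.17g", cl$time)
  utils::write.table(cl, paths["clinical"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
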