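## Orchestration: a validated run configuration with every study default
## recorded, an input manifest with digests, and the two analysis arms
## (stratified regression per trait; specificity + bootstrap enrichment
## per gene set). Outputs are deterministic given the config seeds.

#' Write / read an LD panel (variants + genotype dosages)
#'
#' Two TSVs: `<prefix>.variants.tsv` (variant dialect plus a `BLOCK`
#' column) and `<prefix>.genotypes.tsv` (individuals x variants dosages,
#' header = SNP ids).
#'
#' @param panel an [LdPanel-class].
#' @param prefix file path prefix.
#' @param provenance named list for the sidecar record.
#' @return The prefix (write, invisibly) or an [LdPanel-class] (read).
#' @export
writeLdPanel <- function(panel, prefix, provenance = list()) {
  v <- variants(panel)
  d <- data.frame(CHR = v$chromosome, BP = v$position, SNP = v$snp_id,
                  A1 = v$a1, A2 = v$a2, MAF = v$maf,
                  BLOCK = blockIndex(panel))
  .writeTsv(d, paste0(prefix, ".variants.tsv"))
  .writeTsv(as.data.frame(genotypes(panel)),
            paste0(prefix, ".genotypes.tsv"))
  .writeProvenance(paste0(prefix, ".variants.tsv"), provenance)
  invisible(prefix)
}

#' @rdname writeLdPanel
#' @export
readLdPanel <- function(prefix) {
  d <- utils::read.delim(paste0(prefix, ".variants.tsv"),
                         colClasses = c(CHR = "character"))
  g <- as.matrix(utils::read.delim(paste0(prefix, ".genotypes.tsv"),
                                   check.names = FALSE))
  vt <- variantTable(data.frame(
    snp_id = d$SNP, chromosome = d$CHR, position = d$BP, a1 = d$A1,
    a2 = d$A2, maf = d$MAF, stringsAsFactors = FALSE))
  new("LdPanel", genotypes = g, variants = vt,
      blockIndex = as.integer(d$BLOCK), nIndividuals = nrow(g))
}

#' Assemble a run configuration with the study defaults
#'
#' Every analysis constant has its conventional default recorded here:
#' common-variant MAF floor 0.05, MHC exclusion chr6:25.5-33.5 Mb
#' (GRCh37), 100 kb annotation windows, top fraction 0.1, 35 kb/10 kb
#' gene-association windows, 100,000 bootstraps, 200 jackknife blocks.
#' Overrides are logged. The config round-trips losslessly through YAML
#' ([writeRunConfig()] / [readRunConfig()]).
#'
#' @param panelPrefix LD panel path prefix (see [writeLdPanel()]).
#' @param annotFiles character vector of annot TSV paths.
#' @param sumstatsFiles named character vector: trait -> sumstats path.
#' @param exprFile gene x cell-type mean-expression TSV.
#' @param covariatesFile TSV with `gene_id`, `length_bp`, `gc`.
#' @param genesetsFile GMT of target gene sets.
#' @param outputDir output directory.
#' @param mafMin,annotationWindow,fraction,geneUp,geneDown,ldWindow
#'   study constants (defaults above).
#' @param nBoot,nBins,nBlocks,weighting,alpha analysis settings.
#' @param seed integer seed governing all randomness of a run.
#' @param matching EWCE bootstrap matching mode.
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(panelPrefix = NULL, annotFiles = character(),
                      sumstatsFiles = character(), exprFile = NULL,
                      covariatesFile = NULL, genesetsFile = NULL,
                      outputDir = tempfile("cellherit_run"),
                      mafMin = 0.05, annotationWindow = 100000,
                      fraction = 0.1, geneUp = 35000, geneDown = 10000,
                      ldWindow = 1e6, nBoot = 100000, nBins = 10,
                      nBlocks = 200, weighting = "ldsc_weights",
                      matching = "length_gc_bins", alpha = 0.05,
                      seed = 1L) {
  defaults <- list(mafMin = 0.05, annotationWindow = 100000,
                   fraction = 0.1, geneUp = 35000, geneDown = 10000,
                   ldWindow = 1e6, nBoot = 100000, nBins = 10,
                   nBlocks = 200, weighting = "ldsc_weights",
                   matching = "length_gc_bins", alpha = 0.05)
  cfg <- list(panelPrefix = panelPrefix, annotFiles = annotFiles,
              sumstatsFiles = sumstatsFiles, exprFile = exprFile,
              covariatesFile = covariatesFile,
              genesetsFile = genesetsFile, outputDir = outputDir,
              mafMin = mafMin, annotationWindow = annotationWindow,
              fraction = fraction, geneUp = geneUp, geneDown = geneDown,
              ldWindow = ldWindow, nBoot = nBoot, nBins = nBins,
              nBlocks = nBlocks, weighting = weighting,
              matching = matching, alpha = alpha,
              seed = as.integer(seed))
  over <- names(defaults)[vapply(names(defaults), function(k)
    !identical(cfg[[k]], defaults[[k]]), logical(1))]
  if (length(over))
    .msg("config overrides defaults: %s", paste(over, collapse = ", "))
  structure(cfg, class = "RunConfig")
}

#' Write / read a run configuration as YAML
#'
#' @param config a [runConfig()].
#' @param path YAML path.
#' @return The path (write, invisibly) or the config (read).
#' @export
writeRunConfig <- function(config, path) {
  cfg <- unclass(config)
  # named vectors serialise as YAML maps, keeping the trait names
  cfg$sumstatsFiles <- as.list(cfg$sumstatsFiles)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$sumstatsFiles <- unlist(cfg$sumstatsFiles)
  cfg$annotFiles <- as.character(unlist(cfg$annotFiles))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "RunConfig")
}

#' Validate inputs and write a run manifest
#'
#' Checks every referenced input file (all missing files are reported
#' together, not first-failure), records md5 digests of the inputs, the
#' fully resolved parameter set and the seed registry, and writes
#' `manifest.json` in the output directory. A pre-existing manifest with
#' different content blocks the run (old results are never silently
#' overwritten); set `overwrite = TRUE` to replace it.
#'
#' @param config a [runConfig()].
#' @param overwrite replace a differing prior manifest; default FALSE.
#' @return The manifest list, invisibly.
#' @export
validateAndManifest <- function(config, overwrite = FALSE) {
  paths <- c(
    if (!is.null(config$panelPrefix))
      paste0(config$panelPrefix, c(".variants.tsv", ".genotypes.tsv")),
    config$annotFiles, unname(config$sumstatsFiles), config$exprFile,
    config$covariatesFile, config$genesetsFile)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("unreadable input file(s):\n  ",
         paste(missing, collapse = "\n  "), call. = FALSE)
  digests <- if (length(paths))
    as.list(tools::md5sum(paths)) else list()
  manifest <- list(package = "cellHerit",
                   version = as.character(utils::packageVersion("cellHerit")),
                   parameters = unclass(config)[setdiff(names(config),
                     c("outputDir"))],
                   seeds = list(run = config$seed),
                   inputs = digests)
  if (!dir.exists(config$outputDir))
    dir.create(config$outputDir, recursive = TRUE)
  mpath <- file.path(config$outputDir, "manifest.json")
  body <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (file.exists(mpath) && !overwrite) {
    old <- paste(readLines(mpath), collapse = "\n")
    if (!identical(as.character(body), old))
      stop("output directory holds a differing prior manifest; ",
           "refusing to overwrite its results", call. = FALSE)
  }
  writeLines(body, mpath)
  invisible(manifest)
}

#' Run the stratified-regression arm from a configuration
#'
#' Reads the panel, the annotation files (duplicated category labels
#' across files are a manifest error raised before any computation) and
#' each trait's summary statistics; computes LD scores once; fits the
#' stratified regression and partitions heritability per trait; writes
#' one results TSV per trait and flags rows at the Bonferroni threshold
#' `alpha / (n_traits * n_categories)`.
#'
#' @param config a [runConfig()] with `panelPrefix`, `annotFiles` and
#'   `sumstatsFiles` set.
#' @return List (the regression part of a results bundle): `results`
#'   (rows per trait x category, with `significant` flags), `threshold`,
#'   `manifest`.
#' @export
runLdscArm <- function(config) {
  manifest <- validateAndManifest(config)
  panel <- readLdPanel(config$panelPrefix)
  annots <- lapply(config$annotFiles, readAnnotMatrix,
                   variants = variants(panel))
  labels <- unlist(lapply(annots, categories))
  if (anyDuplicated(labels))
    stop("duplicated category labels across annotation files: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  memb <- do.call(cbind, lapply(annots, membership))
  annot <- annotationMatrix(variants(panel), memb)
  lt <- computeLdScores(panel, annot, window = config$ldWindow)
  nTraits <- length(config$sumstatsFiles)
  thr <- bonferroniThreshold(config$alpha, nTraits, length(labels))
  rows <- lapply(names(config$sumstatsFiles), function(trait) {
    ss <- readSumStats(config$sumstatsFiles[[trait]], trait = trait)
    ord <- match(lt@snp, ss@snp)
    if (any(is.na(ord)))
      stop("sumstats for trait '", trait,
           "' do not cover the panel SNPs", call. = FALSE)
    ss <- sumStats(ss@snp[ord], z = ss@z[ord],
                   n = if (length(ss@n) == 1L) ss@n else ss@n[ord],
                   trait = trait)
    fit <- fitStratified(ss, lt, nBlocks = config$nBlocks,
                         weighting = config$weighting)
    part <- partitionHeritability(fit, annot)
    writeResultsTable(fit, part,
                      file.path(config$outputDir,
                                sprintf("ldsc_results.%s.tsv", trait)))
    cbind(trait = trait, coefTable(fit),
          part[, c("prop_snps", "prop_h2", "enrichment")])
  })
  results <- do.call(rbind, rows)
  results$significant <- results$coefficient_p < thr
  rownames(results) <- NULL
  list(results = results, threshold = thr, manifest = manifest)
}

#' Run the expression-enrichment arm from a configuration
#'
#' Builds the specificity matrix from the configured mean-expression and
#' covariate files, runs the bootstrap enrichment test for every gene
#' set of the GMT against every cell type, and adjusts p-values with
#' Benjamini-Hochberg over the full gene-set x cell-type grid of the
#' run. Per-gene-set seeds are derived deterministically from the run
#' seed.
#'
#' @param config a [runConfig()] with `exprFile`, `covariatesFile` and
#'   `genesetsFile` set.
#' @return List (the enrichment part of a results bundle): `results`
#'   (tidy rows: `gene_set`, `cell_type`, `observed`, `boot_mean`,
#'   `boot_sd`, `sd_from_mean`, `p`, `q`), `manifest`.
#' @export
runEwceArm <- function(config) {
  manifest <- validateAndManifest(config)
  expr <- readExpressionMatrix(config$exprFile)
  cov <- utils::read.delim(config$covariatesFile)
  rownames(cov) <- cov$gene_id
  spec <- specificityMatrix(expr, cov[, c("length_bp", "gc")])
  sets <- readGmt(config$genesetsFile)
  rows <- lapply(seq_along(sets), function(i) {
    res <- ewceTest(sets[[i]], spec, nBoot = config$nBoot,
                    matching = config$matching, nBins = config$nBins,
                    seed = config$seed + i)
    cbind(gene_set = names(sets)[i],
          ewceTable(res)[, c("cell_type", "observed", "boot_mean",
                             "boot_sd", "sd_from_mean_raw",
                             "sd_from_mean", "p")])
  })
  results <- do.call(rbind, rows)
  # BH family: every (gene set, cell type) pair of this run
  results$q <- stats::p.adjust(results$p, method = "BH")
  rownames(results) <- NULL
  .writeTsv(results, file.path(config$outputDir, "ewce_results.tsv"))
  list(results = results, manifest = manifest)
}
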