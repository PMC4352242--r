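#' Pipeline configuration
#'
#' Bundles the per-module configurations, the run directory, the master
#' seed and the stage toggles for [runPipeline()]. Defaults are sized for a
#' desk-scale demonstration run.
#'
#' @param runDir Run directory (created if missing); all outputs land here
#'   and the manifest records paths relative to it.
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it.
#' @param sim A [simConfig()]; its own seed is overridden by `seed`.
#' @param trim A [trimConfig()].
#' @param mapper Within-species [mapperConfig()].
#' @param crossMapper Cross-species [mapperConfig()]; shorter seeds and a
#'   laxer mismatch cap so diverged orthologs still map.
#' @param cluster A [clusterConfig()].
#' @param orf An [orfConfig()]; the demo default lowers the minimum ORF
#'   length, since uniformly random transcripts rarely harbor 100-codon
#'   ORFs.
#' @param orthology An [orthologyConfig()].
#' @param enrich An [enrichmentConfig()]; the tissue grouping is completed
#'   from the simulated tissue names.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "trim", "map", "filter", "cluster", "orf", "rbh",
#'   "enrich")` (dependency order is enforced).
#' @param inputFasta Optional path to a user-supplied assembly FASTA; when
#'   given, it replaces the simulator-truth assembly.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(runDir = tempfile("txforge_run_"),
                           seed = 1,
                           sim = simConfig(nGenes = 30,
                                           lengthRange = c(300, 900),
                                           coverageTarget = 15),
                           trim = trimConfig(),
                           mapper = mapperConfig(),
                           crossMapper = mapperConfig(
                             k = 15, maxMismatchRate = 0.12),
                           cluster = clusterConfig(),
                           orf = orfConfig(trainingSetSize = 200,
                                           minOrfLength = 30),
                           orthology = orthologyConfig(),
                           enrich = enrichmentConfig(),
                           stages = c("simulate", "trim", "map", "filter",
                                      "cluster", "orf", "rbh", "enrich"),
                           inputFasta = NULL) {
  sim@seed <- as.integer(seed)
  grouping <- setNames(sim@tissueNames, sim@tissueNames)
  grouping[grouping %in% c("ovary", "testis")] <- "gonad"
  enrich$tissueGrouping <- grouping
  structure(list(runDir = runDir, seed = as.integer(seed), sim = sim,
                 trim = trim, mapper = mapper, crossMapper = crossMapper,
                 cluster = cluster, orf = orf, orthology = orthology,
                 enrich = enrich, stages = stages, inputFasta = inputFasta),
            class = "PipelineConfig")
}

relChecksums <- function(runDir, files) {
  sums <- tools::md5sum(file.path(runDir, files))
  setNames(unname(sums), files)
}

#' Run the end-to-end workflow
#'
#' Executes the enabled stages in dependency order -- simulate reads, trim
#' and synchronize, map back, coverage-filter, cluster, annotate coding
#' regions, reciprocal-best-hit orthology with identity statistics, and
#' enrichment discovery -- writing every stage's outputs under the run
#' directory and recording parameters, counts and md5 checksums in a
#' manifest (`manifest.yaml`). Reruns with an identical configuration and
#' seed reproduce identical manifests. A stage failure halts the run with
#' the stage name; outputs of completed stages are preserved.
#'
#' @param config A [pipelineConfig()].
#' @return The manifest, invisibly a list; elements `stages` (per-stage
#'   records) and `checksum` (md5 over the serialized stage records).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!is.null(config$inputFasta) && !file.exists(config$inputFasta)) {
    stop(sprintf("input FASTA '%s' does not exist", config$inputFasta))
  }
  dir.create(config$runDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())

  runStage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    rec <- tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- rec
    invisible(NULL)
  }

  runStage("simulate", function() {
    sim <- generateTranscriptome(config$sim)
    state$txA <- sim$transcripts
    state$truth <- sim$truth
    state$txB <- evolveOrthologs(sim$transcripts, config$sim@jcDistance,
                                 seed = config$seed + 1000L,
                                 exclude = aOnlySet(sim$truth),
                                 idMap = orthologMap(sim$truth))
    Biostrings::writeXStringSet(state$txA,
                                file.path(config$runDir, "speciesA.fasta"))
    Biostrings::writeXStringSet(state$txB,
                                file.path(config$runDir, "speciesB.fasta"))
    writeTruthTables(state$truth, file.path(config$runDir, "truth"))
    state$reads <- list()
    files <- c("speciesA.fasta", "speciesB.fasta")
    for (t in config$sim@tissueNames) {
      r <- simulateReads(state$txA, state$truth, t, config$sim)
      state$reads[[t]] <- r
      f1 <- sprintf("reads_%s_1.fastq", t)
      f2 <- sprintf("reads_%s_2.fastq", t)
      writePairedFastq(r, file.path(config$runDir, f1),
                       file.path(config$runDir, f2))
      files <- c(files, f1, f2)
    }
    # two independent species-B whole-organism datasets, used by the
    # species-enrichment filter
    exprB <- rowSums(expressionLevel(state$truth))
    names(exprB) <- rownames(expressionLevel(state$truth))
    shared <- names(orthologMap(state$truth))
    exprB <- setNames(exprB[shared], unname(orthologMap(state$truth)[shared]))
    state$readsB <- lapply(1:2, function(i) {
      simulateReads(state$txB, state$truth, tissue = "whole",
                    config = config$sim, seed = config$seed + 2000L + i,
                    expression = exprB)
    })
    list(params = list(nGenes = config$sim@nGenes,
                       jcDistance = config$sim@jcDistance,
                       seed = config$seed),
         counts = list(genesA = length(state$txA),
                       genesB = length(state$txB),
                       pairsPerTissue = vapply(state$reads, function(r)
                         length(r$mate1), integer(1))),
         checksums = as.list(relChecksums(config$runDir, files)))
  })

  runStage("trim", function() {
    state$trimmed <- lapply(state$reads, function(r) {
      synchronizePairs(r$mate1, r$mate2, config$trim)
    })
    state$trimmedB <- lapply(state$readsB, function(r) {
      synchronizePairs(r$mate1, r$mate2, config$trim)
    })
    rep <- do.call(rbind, lapply(state$trimmed, `[[`, "report"))
    rep$tissue <- names(state$trimmed)
    utils::write.table(rep, file.path(config$runDir, "trim_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(params = unclass(config$trim),
         counts = list(retainedPairs = sum(rep$retained_pairs),
                       inputPairs = sum(rep$input_pairs)),
         checksums = as.list(relChecksums(config$runDir,
                                          "trim_report.tsv")))
  })

  runStage("map", function() {
    state$assembly <- if (!is.null(config$inputFasta)) {
      Biostrings::readDNAStringSet(config$inputFasta)
    } else {
      state$txA
    }
    state$index <- buildIndex(state$assembly, config$mapper$k)
    state$countsPerTissue <- lapply(names(state$trimmed), function(t) {
      tr <- state$trimmed[[t]]
      countAndCoverage(tr$mate1, tr$mate2, state$index, config$mapper,
                       sample = t)
    })
    names(state$countsPerTissue) <- names(state$trimmed)
    state$countsAll <- combineTxCounts(state$countsPerTissue)
    cm <- counts(state$countsAll)
    utils::write.table(
      data.frame(transcript = rownames(cm), cm,
                 avg_coverage = avgCoverage(state$countsAll),
                 check.names = FALSE),
      file.path(config$runDir, "counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(params = unclass(config$mapper),
         counts = list(mappedPairs = sum(cm)),
         checksums = as.list(relChecksums(config$runDir, "counts.tsv")))
  })

  runStage("filter", function() {
    flt <- coverageFilter(state$assembly, state$countsAll)
    state$assembly <- flt$retained
    metrics <- computeMetrics(
      state$assembly, state$countsAll,
      totalInputReads = sum(vapply(state$reads, function(r)
        length(r$mate1), integer(1))))
    utils::write.table(metrics,
                       file.path(config$runDir, "assembly_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(params = list(minAvgCoverage = 1.0),
         counts = list(retained = length(state$assembly),
                       removed = length(flt$removed)),
         checksums = as.list(relChecksums(config$runDir,
                                          "assembly_metrics.tsv")))
  })

  runStage("cluster", function() {
    cl <- clusterTranscripts(state$assembly, config$cluster)
    state$assembly <- clusterRepresentatives(state$assembly, cl)
    utils::write.table(cl, file.path(config$runDir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(params = unclass(config$cluster),
         counts = list(clusters = max(cl$cluster),
                       sequences = nrow(cl)),
         checksums = as.list(relChecksums(config$runDir, "clusters.tsv")))
  })

  runStage("orf", function() {
    ann <- annotateCoding(state$assembly, config$orf,
                          seed = config$seed + 3000L)
    state$orfCalls <- ann$calls
    state$peptides <- ann$peptides
    utils::write.table(
      ann$calls[, c("transcript", "start", "end", "strand", "frame",
                    "llr")],
      file.path(config$runDir, "orf_calls.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(params = unclass(config$orf),
         counts = list(reportedOrfs = nrow(ann$calls)),
         checksums = as.list(relChecksums(config$runDir, "orf_calls.tsv")))
  })

  runStage("rbh", function() {
    rbh <- reciprocalBestHits(state$assembly, state$txB, config$orthology)
    state$rbh <- rbh
    stats <- identityStats(rbh, minLengthFraction = 0.75)
    utils::write.table(rbh, file.path(config$runDir, "rbh_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(params = list(evalueCutoff = config$orthology$evalueCutoff),
         counts = list(pairs = nrow(rbh),
                       meanIdentityPct = round(100 * stats$meanIdentity,
                                               3)),
         checksums = as.list(relChecksums(config$runDir,
                                          "rbh_pairs.tsv")))
  })

  runStage("enrich", function() {
    annotated <- state$rbh$qid
    sampleSets <- lapply(names(state$countsPerTissue), function(t) {
      cm <- counts(state$countsPerTissue[[t]])
      intersect(rownames(cm)[cm[, 1L] >= 1L], annotated)
    })
    tissues <- names(state$countsPerTissue)
    groups <- tissueUnion(sampleSets, tissues, config$enrich)
    te <- tissueEnriched(groups)
    # species-B read counts on the species-A assembly
    crossIndex <- buildIndex(state$assembly, config$crossMapper$k)
    countsB <- lapply(state$trimmedB, function(tr) {
      countAndCoverage(tr$mate1, tr$mate2, crossIndex, config$crossMapper,
                       sample = "speciesB")
    })
    aVec <- rowSums(counts(state$countsAll))[names(state$assembly)]
    se <- speciesEnriched(aVec, countsB[[1L]], countsB[[2L]],
                          config$enrich)
    state$speciesEnriched <- se
    # synthetic flat term map over the assembly universe
    universe <- names(state$assembly)
    termMap <- withSeed(config$seed + 4000L, {
      data.frame(gene = sample(universe, 10 * length(universe),
                               replace = TRUE),
                 term = sample(sprintf("T%02d", 1:10),
                               10 * length(universe), replace = TRUE))
    })
    go <- if (length(se)) goOverrepresentation(se, universe, termMap)
          else data.frame()
    utils::write.table(
      data.frame(group = rep(names(te$enriched),
                             lengths(te$enriched)),
                 gene = unlist(te$enriched, use.names = FALSE)),
      file.path(config$runDir, "tissue_enriched.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(transcript = se),
                       file.path(config$runDir, "species_enriched.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(go)) {
      utils::write.table(go, file.path(config$runDir, "go_terms.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(params = list(minReadsSpeciesA = config$enrich$minReadsSpeciesA,
                       maxReadsSpeciesB = config$enrich$maxReadsSpeciesB),
         counts = list(tissueEnriched = vapply(te$enriched, length,
                                               integer(1)),
                       shared = length(te$shared),
                       speciesEnriched = length(se)),
         checksums = as.list(relChecksums(
           config$runDir, c("tissue_enriched.tsv",
                            "species_enriched.tsv"))))
  })

  tmp <- tempfile()
  yaml::write_yaml(manifest$stages, tmp)
  manifest$checksum <- unname(tools::md5sum(tmp))
  unlink(tmp)
  yaml::write_yaml(manifest, file.path(config$runDir, "manifest.yaml"))
  invisible(manifest)
}

# Combine per-sample TxCounts over a shared transcript universe: counts are
# column-bound, coverage vectors are summed.
combineTxCounts <- function(countsList) {
  cm <- do.call(cbind, lapply(countsList, counts))
  cov <- countsList[[1L]]@coverage
  for (x in countsList[-1L]) {
    for (id in names(cov)) cov[[id]] <- cov[[id]] + x@coverage[[id]]
  }
  mapped <- sum(vapply(countsList, function(x)
    attr(x@counts, "mappedPairs"), integer(1)))
  total <- sum(vapply(countsList, function(x)
    attr(x@counts, "totalPairs"), integer(1)))
  obj <- new("TxCounts", counts = cm, coverage = cov,
             txLengths = countsList[[1L]]@txLengths)
  attr(obj@counts, "mappedPairs") <- mapped
  attr(obj@counts, "totalPairs") <- total
  obj
}

#' Compare two assemblies side by side
#'
#' Computes per-assembly contig metrics plus, when supplied, core-gene
#' recovery (via coding annotation of each assembly) and the
#' reciprocal-best-hit count against a reference transcript set.
#'
#' @param assemblyA,assemblyB Named `DNAStringSet`s (both non-empty).
#' @param core Optional named `AAStringSet` of core proteins.
#' @param reference Optional named `DNAStringSet` of reference transcripts
#'   for RBH counting; an empty set yields zero RBH counts.
#' @param orf,orthology Module configurations used for the optional
#'   columns.
#' @return Data.frame with one row per assembly: `assembly`,
#'   `contig_count`, `total_bp`, `mean_contig_length`, `n50`, and when
#'   requested `core_recovery` and `rbh_count`.
#' @export
compareAssemblies <- function(assemblyA, assemblyB, core = NULL,
                              reference = NULL,
                              orf = orfConfig(trainingSetSize = 200,
                                              minOrfLength = 30),
                              orthology = orthologyConfig()) {
  if (length(assemblyA) == 0L || length(assemblyB) == 0L) {
    stop("both assemblies must be non-empty")
  }
  row <- function(name, tx) {
    m <- computeMetrics(tx)
    r <- data.frame(assembly = name, contig_count = m$contig_count,
                    total_bp = m$total_bp,
                    mean_contig_length = m$mean_contig_length,
                    n50 = m$n50)
    if (!is.null(core)) {
      ann <- annotateCoding(tx, orf)
      r$core_recovery <- coreGeneRecovery(ann$peptides, core)$fraction
    }
    if (!is.null(reference)) {
      r$rbh_count <- if (length(reference) == 0L) 0L else {
        ref <- reference
        names(ref) <- paste0("ref_", names(ref))
        nrow(reciprocalBestHits(tx, ref, orthology))
      }
    }
    r
  }
  out <- rbind(row("A", assemblyA), row("B", assemblyB))
  rownames(out) <- NULL
  out
}
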