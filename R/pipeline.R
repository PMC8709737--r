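#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow with the defaults of
#' the reference protocol: differential-weight exponent \code{gamma = 4},
#' 1000-fold permutation test at edge cut-off \code{pCutoff = 0.05},
#' disparity threshold \code{alpha = 0.3}, 70/30 stratified split, 20-times
#' repeated 10-fold cross-validation with at most 10 candidate components,
#' and key-node product threshold 0.5.
#'
#' @param input path to a delimited abundance table (see
#'   [readAbundanceTable()]), or an [AbundanceTable-class] when driving the
#'   pipeline programmatically.
#' @param groupColumn name of the phenotype column (files only).
#' @param caseLevel,controlLevel the phenotype pair to analyse; required
#'   when the file holds more than two levels, otherwise inferred (first
#'   level = case).
#' @param gamma,nPermutations,pCutoff differential-network settings.
#' @param alpha disparity-filter threshold.
#' @param trainFraction stratified training fraction.
#' @param cvRepeats,cvFolds,maxComponents component-selection settings.
#' @param keyNodeThreshold key-node product threshold.
#' @param seed single pipeline seed; per-stage seeds (split, permutations,
#'   CV) are derived from it so stages can be re-run in isolation.
#' @param outputDir directory for all artifacts (created if needed).
#' @param delimiter input field separator.
#' @param logScale set to \code{TRUE} when the input is already
#'   log-transformed.
#' @param impute enable within-group median imputation of missing values.
#' @return a validated \code{PipelineConfig} list.
#' @seealso [runPipeline()]
#' @export
pipelineConfig <- function(input, groupColumn = "group", caseLevel = NULL,
                           controlLevel = NULL, gamma = 4,
                           nPermutations = 1000L, pCutoff = 0.05,
                           alpha = 0.3, trainFraction = 0.7,
                           cvRepeats = 20L, cvFolds = 10L,
                           maxComponents = 10L, keyNodeThreshold = 0.5,
                           seed = 1L, outputDir = "diffnet_run",
                           delimiter = ",", logScale = FALSE,
                           impute = FALSE) {
    stopifnot(gamma > 1, nPermutations >= 100, pCutoff > 0, pCutoff <= 1,
              alpha > 0, alpha < 1, trainFraction > 0, trainFraction < 1,
              cvRepeats >= 1, cvFolds >= 2, maxComponents >= 1,
              keyNodeThreshold >= 0)
    structure(list(input = input, groupColumn = groupColumn,
                   caseLevel = caseLevel, controlLevel = controlLevel,
                   gamma = gamma, nPermutations = as.integer(nPermutations),
                   pCutoff = pCutoff, alpha = alpha,
                   trainFraction = trainFraction,
                   cvRepeats = as.integer(cvRepeats),
                   cvFolds = as.integer(cvFolds),
                   maxComponents = as.integer(maxComponents),
                   keyNodeThreshold = keyNodeThreshold,
                   seed = as.integer(seed), outputDir = outputDir,
                   delimiter = delimiter, logScale = logScale,
                   impute = impute),
              class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of [pipelineConfig()].
#'
#' @param path configuration file (\code{.yaml}/\code{.yml} or
#'   \code{.json}).
#' @return a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    do.call(pipelineConfig, cfg)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    path
}

.reportAsList <- function(report) {
    c(as.list(report@metrics),
      list(TP = report@tp, FP = report@fp, TN = report@tn, FN = report@fn,
           cohort = report@cohort))
}

#' Run the full differential-network classification pipeline
#'
#' Executes, in order: read/validate, log transform, stratified split,
#' shared-shuffle permutation differential network on the training set,
#' disparity-filter backbone, centralities and key nodes, backbone feature
#' construction (training scaling frozen for the test set), component
#' selection by repeated CV, final PLS-DA fit, evaluation on the CV grid
#' and the held-out test set, and the VIP table. Every stage writes its
#' artifact into \code{config$outputDir}; a log file records all
#' parameters and derived stage seeds. Identical configuration and seed
#' reproduce byte-identical numeric outputs. On failure a \code{FAILED}
#' marker naming the stage is left next to the partial outputs.
#'
#' @param config a [pipelineConfig()] object.
#' @return invisibly, a list with the fitted objects (\code{split},
#'   \code{network}, \code{backbone}, \code{centrality}, \code{keyNodes},
#'   \code{cv}, \code{model}, \code{reports}, \code{vip}) and the output
#'   directory.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outputDir, f)
    logFile <- out("run_log.txt")
    logLine <- function(...) cat(sprintf(...), "\n", sep = "",
                                 file = logFile, append = TRUE)
    cat("", file = logFile)
    seeds <- deriveSeeds(config$seed, c("split", "permutation", "cv"))
    cfgOut <- config
    cfgOut$input <- if (is.character(config$input)) config$input else
        "<in-memory AbundanceTable>"
    jsonlite::write_json(unclass(cfgOut), out("config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    logLine("pipeline seed %d; stage seeds: split=%d permutation=%d cv=%d",
            config$seed, seeds["split"], seeds["permutation"], seeds["cv"])
    stage <- "input"
    result <- tryCatch({
        table <- if (is.character(config$input))
            readAbundanceTable(config$input, config$groupColumn,
                               delimiter = config$delimiter,
                               keepLevels = if (!is.null(config$caseLevel))
                                   c(config$caseLevel, config$controlLevel),
                               impute = config$impute,
                               scaleState = if (config$logScale) "log"
                                            else "raw")
        else config$input
        caseLevel <- config$caseLevel %||% levels(groupLabels(table))[1L]
        logLine("input: %d samples x %d metabolites, case level '%s'",
                ncol(table), nrow(table), caseLevel)

        stage <- "log transform"
        if (scaleState(table) == "raw") table <- logTransform(table)

        stage <- "stratified split"
        split <- stratifiedSplit(table, config$trainFraction,
                                 seed = seeds["split"])
        .writeTsv(data.frame(
            sample_id = c(colnames(split@train), colnames(split@test)),
            group = c(as.character(groupLabels(split@train)),
                      as.character(groupLabels(split@test))),
            partition = rep(c("train", "test"),
                            c(ncol(split@train), ncol(split@test)))),
            out("split_manifest.tsv"))

        stage <- "differential network"
        network <- buildDifferentialNetwork(
            split@train, gamma = config$gamma, pCutoff = config$pCutoff,
            nPermutations = config$nPermutations,
            seed = seeds["permutation"], caseLevel = caseLevel)
        writeEdgeList(network, out("differential_edges.tsv"))
        exportGraphML(network, out("differential_network.graphml"))
        logLine("differential network: %d nodes, %d edges",
                length(nodes(network)), nrow(edges(network)))

        stage <- "backbone"
        backbone <- extractBackbone(network, alphaCutoff = config$alpha)
        writeEdgeList(backbone, out("backbone_edges.tsv"))
        exportGraphML(backbone, out("backbone.graphml"))
        rec <- disparityRecords(network)
        expFit <- tryCatch(disparityExponentFit(rec),
                           error = function(e) NA_real_)
        jsonlite::write_json(list(
            connected_nodes = length(nodes(backbone)),
            isolated_nodes = length(backbone@isolatedNodes),
            edges = nrow(edges(backbone)),
            edge_fraction = backbone@edgeFraction,
            weight_fraction = backbone@weightFraction,
            disparity_exponent = expFit),
            out("backbone_summary.json"), auto_unbox = TRUE, digits = NA)
        logLine("backbone: %d nodes, %d edges (%.1f%% edges, %.1f%% weight)",
                length(nodes(backbone)), nrow(edges(backbone)),
                100 * backbone@edgeFraction, 100 * backbone@weightFraction)

        stage <- "topology"
        centrality <- centralities(backbone,
                                   keyThreshold = config$keyNodeThreshold)
        keyNodes <- identifyKeyNodes(centrality, config$keyNodeThreshold)
        writeCentralityTable(centrality, out("centrality.tsv"))
        logLine("key nodes (%d): %s", length(keyNodes),
                paste(keyNodes, collapse = ", "))

        stage <- "features"
        trainFeatures <- buildFeatureMatrix(split@train, backbone)
        testFeatures <- applyFeatureMatrix(split@test, trainFeatures)
        writeFeatureMatrix(trainFeatures, out("features_train.tsv"))
        writeFeatureMatrix(testFeatures, out("features_test.tsv"))

        stage <- "cross-validation"
        cv <- selectComponents(trainFeatures, repeats = config$cvRepeats,
                               folds = config$cvFolds,
                               maxComponents = config$maxComponents,
                               seed = seeds["cv"])
        .writeTsv(cv@grid, out("cv_results.tsv"))
        logLine("chosen components: %d", cv@chosen)

        stage <- "classification"
        model <- fitPlsda(trainFeatures, cv@chosen)
        chosenRow <- cv@grid[cv@grid$ncomp == cv@chosen, ]
        trainReport <- evaluateClassifier(model, trainFeatures, "train")
        testReport <- evaluateClassifier(model, testFeatures, "test")
        metrics <- list(
            cv = list(ncomp = cv@chosen, accuracy = chosenRow$accuracy,
                      accuracy_sd = chosenRow$accuracy_sd,
                      auroc = chosenRow$auroc,
                      auroc_sd = chosenRow$auroc_sd),
            train = .reportAsList(trainReport),
            test = .reportAsList(testReport))
        jsonlite::write_json(metrics, out("metrics.json"),
                             auto_unbox = TRUE, digits = NA)
        vip <- vipTable(model, trainFeatures)
        .writeTsv(vip, out("vip.tsv"))
        .writeTsv(data.frame(sample_id = rownames(model@scores),
                             label = as.character(
                                 featureLabels(trainFeatures)),
                             comp1 = model@scores[, 1L],
                             comp2 = if (ncol(model@scores) >= 2L)
                                 model@scores[, 2L] else NA_real_),
                  out("scores.tsv"))
        logLine("test accuracy %.3f, AUROC %.3f",
                testReport@metrics["accuracy"], testReport@metrics["auroc"])

        list(split = split, network = network, backbone = backbone,
             centrality = centrality, keyNodes = keyNodes,
             trainFeatures = trainFeatures, testFeatures = testFeatures,
             cv = cv, model = model,
             reports = list(train = trainReport, test = testReport),
             vip = vip, outputDir = config$outputDir)
    }, error = function(e) {
        writeLines(sprintf("stage '%s' failed: %s", stage,
                           conditionMessage(e)), out("FAILED"))
        stop(sprintf(
            "pipeline stage '%s' failed: %s (partial outputs kept in %s)",
            stage, conditionMessage(e), config$outputDir), call. = FALSE)
    })
    invisible(result)
}
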