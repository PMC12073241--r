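#' Run the full marker-validation pipeline
#'
#' Orchestrates every stage on a phenotype table plus a marker panel —
#' germination index, per-environment and across-environment BLUPs,
#' variance components and heritability, environment-mean comparison,
#' marker QC (strand harmonization, filter cascade, heterozygote
#' removal, complete-LD detection), single-marker association and
#' stability, all-subsets AIC model selection, haplotype analysis of
#' the top multi-marker models and selection-efficiency comparison
#' against the best single marker. When no inputs are given a synthetic
#' study is generated from \code{config} (see [simulationConfig()]).
#'
#' Report tables are written as CSV when \code{outDir} is given:
#' \code{variance_components.csv}, \code{environment_means.csv},
#' \code{association.csv}, \code{models.csv}, \code{haplotypes.csv},
#' \code{selection.csv} and a YAML \code{manifest.yaml} (run
#' parameters, seed, package version). Values are rounded only in the
#' written reports (GI to 2 decimals, percentages to integers, PVE to
#' 1 decimal); returned objects carry full precision.
#'
#' @param config a [simulationConfig()], a YAML file path holding its
#'   fields, or \code{NULL} for defaults (used only when simulating).
#' @param plots plot germination table (see [buildPhenotypeTable()]);
#'   simulated when \code{NULL}.
#' @param panel a \linkS4class{MarkerPanel}; must accompany
#'   \code{plots} when those are given.
#' @param outDir optional output directory for report CSVs.
#' @param seed RNG seed for the simulated study.
#' @param kTop number of top models to report (default 10).
#' @param alpha significance level used throughout.
#' @return list with elements \code{gi}, \code{blupsByEnv},
#'   \code{across}, \code{vc}, \code{h2}, \code{shares},
#'   \code{envMeans}, \code{panel} (post-QC), \code{ldGroups},
#'   \code{assoc}, \code{stability}, \code{pool}, \code{selection}
#'   (model search), \code{haplotypes}, \code{efficiency},
#'   \code{truth} (when simulated).
#' @export
runPipeline <- function(config = NULL, plots = NULL, panel = NULL,
                        outDir = NULL, seed = 1L, kTop = 10,
                        alpha = 0.05) {
  if (is.character(config)) config <- readPipelineConfig(config)
  truth <- NULL
  if (is.null(plots)) {
    if (!is.null(panel))
      stop("a marker panel was given without phenotype plots; ",
           "supply 'plots' or neither")
    cfg <- if (is.null(config)) simulationConfig(rngSeed = seed)
           else config
    sim <- simulateStudy(cfg, seed = seed)
    plots <- sim$plots; panel <- sim$panel; truth <- sim$truth
  } else if (is.null(panel)) {
    stop("pipeline input incomplete: phenotype plots were given but ",
         "the genotype section (marker panel) is missing")
  }

  gi <- buildPhenotypeTable(plots)

  envs <- sort(unique(gi$environment_id))
  blupsByEnv <- lapply(envs, function(e)
    fitWithinEnv(gi[gi$environment_id == e, , drop = FALSE])$blup)
  names(blupsByEnv) <- envs
  acrossFit <- if (length(envs) > 1) fitAcrossEnv(gi)
               else fitWithinEnv(gi)
  vc <- acrossFit$vc
  h2 <- heritability(vc)
  shares <- if (length(envs) > 1) varianceShares(vc) else NULL
  stacked <- do.call(rbind, lapply(envs, function(e)
    cbind(blupsByEnv[[e]], environment_id = e)))
  envMeans <- if (length(envs) > 1) compareEnvMeans(stacked, alpha)
              else NULL

  panel <- harmonizeStrand(panel)
  panel <- applyFilters(qcStats(panel))
  analysisPanel <- dropHeterozygotes(panel)
  ldGroups <- detectCompleteLD(analysisPanel)

  scanBlups <- c(blupsByEnv, list(across = acrossFit$blup))
  assoc <- associationScan(scanBlups, analysisPanel)
  stability <- classifyStability(assoc, alpha = alpha)

  pool <- tryCatch(candidatePool(stability, ldGroups),
                   error = function(e) character())
  selection <- NULL; haplotypeTables <- list(); efficiency <- NULL
  if (length(pool)) {
    selection <- allSubsetsRegression(acrossFit$blup, analysisPanel,
                                      pool, kTop = kTop)
    # best single marker = highest across-environment PVE in the pool
    acrossRows <- assoc[assoc$environment_id == "across" &
                          assoc$marker_id %in% pool, , drop = FALSE]
    best <- acrossRows$marker_id[which.max(acrossRows$pve)]
    bestTol <- acrossRows$tolerant_allele[acrossRows$marker_id == best]
    calls <- markerCalls(analysisPanel)[best, ]
    markerMembers <- names(calls)[!is.na(calls) &
                                    .allele1(calls) == bestTol]
    effRows <- list()
    for (i in seq_len(nrow(selection$models))) {
      mk <- strsplit(selection$models$markers[i], ",", fixed = TRUE)[[1]]
      if (length(mk) < 2) next
      haps <- buildHaplotypes(analysisPanel, mk)
      tab <- tryCatch(
        haplotypeMixedModel(stacked, haps, alpha = alpha),
        error = function(e) NULL)
      if (is.null(tab)) next
      modelId <- paste0("model", selection$models$rank[i])
      haplotypeTables[[modelId]] <- tab
      bestHap <- tab$haplotype[!is.na(tab$letter)][1]
      hapMembers <-
        haps$membership$genotype_id[haps$membership$haplotype == bestHap]
      eff <- selectionEfficiency(acrossFit$blup, hapMembers,
                                 markerMembers)
      effRows[[modelId]] <- cbind(model = modelId,
                                  best_haplotype = bestHap, eff,
                                  stringsAsFactors = FALSE)
    }
    if (length(effRows)) efficiency <- do.call(rbind, effRows)
    if (!is.null(efficiency)) rownames(efficiency) <- NULL
  }

  result <- list(gi = gi, blupsByEnv = blupsByEnv, across = acrossFit,
                 vc = vc, h2 = h2, shares = shares, envMeans = envMeans,
                 panel = panel, ldGroups = ldGroups, assoc = assoc,
                 stability = stability, pool = pool,
                 selection = selection, haplotypes = haplotypeTables,
                 efficiency = efficiency, truth = truth, seed = seed)
  if (!is.null(outDir)) writeReports(result, outDir)
  invisible(result)
}

#' Read a pipeline/simulation configuration from YAML
#'
#' Top-level keys mirror the arguments of [simulationConfig()]; a
#' \code{markers} key, when present, is a list of per-marker records
#' (fields as in [defaultMarkerSpec()]).
#'
#' @param path YAML file path.
#' @return a [simulationConfig()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$markers))
    y$markers <- do.call(rbind, lapply(y$markers, function(m) {
      m$ld_partner <- if (is.null(m$ld_partner)) NA_character_
                      else m$ld_partner
      m$strand_flag <- isTRUE(m$strand_flag)
      for (f in c("effect1", "missing_rate", "het_rate"))
        if (is.null(m[[f]])) m[[f]] <- 0
      if (is.null(m$role)) m$role <- "clean"
      as.data.frame(m, stringsAsFactors = FALSE)
    }))
  known <- names(formals(simulationConfig))
  do.call(simulationConfig, y[intersect(names(y), known)])
}

#' Write the pipeline report tables
#'
#' @param result a [runPipeline()] result.
#' @param outDir directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeReports <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(outDir, name)
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  s <- varComp(result$vc)
  vcTab <- data.frame(
    source = c("genotype", "environment", "gxe", "replicate",
               "residual"),
    variance = signif(unname(s), 3),
    pct_total = c(if (!is.null(result$shares))
      unname(result$shares[c("g", "e", "gxe")]) else rep(NA, 3), NA,
      if (!is.null(result$shares)) unname(result$shares["eps"]) else NA),
    heritability = c(roundHalfUp(result$h2, 2), rep(NA, 4)))
  wr(vcTab, "variance_components.csv")
  if (!is.null(result$envMeans)) {
    em <- result$envMeans
    em$mean <- roundHalfUp(em$mean, 2); em$sd <- roundHalfUp(em$sd, 2)
    em$min <- roundHalfUp(em$min, 2); em$max <- roundHalfUp(em$max, 2)
    wr(em, "environment_means.csv")
  }
  assoc <- result$assoc
  for (col in c("effect")) assoc[[col]] <- roundHalfUp(assoc[[col]], 3)
  assoc$relative_change <- roundHalfUp(assoc$relative_change, 0)
  assoc$pve <- roundHalfUp(assoc$pve, 1)
  assoc$freq_tolerant <- roundHalfUp(100 * assoc$freq_tolerant, 0)
  wr(assoc, "association.csv")
  if (!is.null(result$selection)) {
    mods <- result$selection$models
    num <- vapply(mods, is.numeric, logical(1))
    mods$pve <- roundHalfUp(mods$pve, 1)
    mods$aic <- round(mods$aic, 2)
    for (col in setdiff(names(mods)[num], c("rank", "size", "pve", "aic")))
      mods[[col]] <- roundHalfUp(mods[[col]], 2)
    wr(mods, "models.csv")
  }
  if (length(result$haplotypes)) {
    ht <- do.call(rbind, lapply(names(result$haplotypes), function(id)
      cbind(model = id, result$haplotypes[[id]],
            stringsAsFactors = FALSE)))
    ht$lsmean <- roundHalfUp(ht$lsmean, 2)
    wr(ht, "haplotypes.csv")
  }
  if (!is.null(result$efficiency)) {
    ef <- result$efficiency
    ef$hap_mean_gi <- roundHalfUp(ef$hap_mean_gi, 2)
    ef$marker_mean_gi <- roundHalfUp(ef$marker_mean_gi, 2)
    ef$t_test_p <- signif(ef$t_test_p, 3)
    wr(ef, "selection.csv")
  }
  manifest <- list(
    package = "sproutval",
    version = as.character(utils::packageVersion("sproutval")),
    seed = result$seed,
    n_genotypes = length(unique(result$gi$genotype_id)),
    environments = sort(unique(result$gi$environment_id)),
    markers_input = nrow(result$panel),
    markers_retained = length(retainedMarkers(result$panel)),
    outputs = basename(paths))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(c(paths, file.path(outDir, "manifest.yaml")))
}
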