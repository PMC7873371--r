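## End-to-end orchestration: simulate/load -> prune -> MSEA -> selection ->
## merge -> confirm -> KDA -> disease enrichment, with a JSON run manifest.

.stage <- function(name, fingerprint, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed (inputs: %s): %s",
                 name, fingerprint, conditionMessage(e)), call. = FALSE))
}

.cfgGet <- function(config, key, default) {
  v <- config[[key]]
  if (is.null(v)) default else v
}

#' Run the full enrichment-to-key-driver pipeline
#'
#' Executes, in order: input loading (or synthetic generation), LD pruning
#' (skipped with a warning when no LD table is available), MSEA with BH FDR
#' selection, optional intersection with a second independent dataset,
#' redundancy merging of the significant sets into supersets, second-round
#' confirmation with Bonferroni correction, key driver analysis of each
#' confirmed superset on the network, and disease-gene enrichment of the
#' supersets.  All tables are written to `outDir` together with a
#' `manifest.json` recording the package version, seed, parameters, row
#' counts at every stage and md5 checksums of every written file, so a rerun
#' with the same config is verifiably identical.
#'
#' @param config a named list (or path to a YAML file with the same
#'   structure).  Recognized entries: `seed`; `simulate` (list of
#'   [SimConfig()] arguments; presence switches on synthetic input
#'   generation); `inputs` (list of paths: gwas, map, sets, and optionally
#'   ld, network, disease, annotation); `msea` (list of [MseaParams()]
#'   arguments plus `fdrMax`); `secondDataset` (list of paths: gwas,
#'   optionally ld); `merge` (list: rho); `confirm` (list: alpha); `kda`
#'   (list of [KdaParams()] arguments); `disease` (list: alpha); `r2Max`.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results (markers, map,
#'   kept, msea, significant, supersets, confirmation, kda, subnetworks,
#'   disease, manifest).
#' @export
runPipeline <- function(config = list(), outDir = tempfile("netmsea_run_")) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(.cfgGet(config, "seed", 1L))
  manifest <- list(package = "netMSEA",
                   version = as.character(utils::packageVersion("netMSEA")),
                   seed = seed, config = config, counts = list())

  ## ---- inputs ----
  truth <- NULL; net <- NULL; ld <- NULL
  diseaseSets <- NULL; annotationSets <- NULL
  if (!is.null(config$simulate) || is.null(config$inputs)) {
    simArgs <- if (is.list(config$simulate)) config$simulate else list()
    if (is.null(simArgs$seed)) simArgs$seed <- seed
    cfg <- .stage("simulate", "config", do.call(SimConfig, simArgs))
    study <- .stage("simulate", "config", simulateStudy(cfg))
    writeSimulatedStudy(study, file.path(outDir, "inputs"))
    markers <- study$markers; map <- study$map; sets <- study$sets
    ld <- study$ld; net <- study$network; truth <- study$truth
  } else {
    ins <- config$inputs
    fp <- paste(unlist(ins), collapse = ",")
    markers <- .stage("read_gwas", fp, readGwas(ins$gwas))
    map <- .stage("read_map", fp, readMarkerGeneMap(ins$map))
    sets <- .stage("read_sets", fp, readGeneSetsGmt(ins$sets))
    if (!is.null(ins$ld)) ld <- .stage("read_ld", fp, readLdTable(ins$ld))
    if (!is.null(ins$network))
      net <- .stage("read_network", fp, readNetwork(ins$network))
    if (!is.null(ins$disease))
      diseaseSets <- .stage("read_disease", fp,
                            readGeneSetsGmt(ins$disease, source = "disease"))
    if (!is.null(ins$annotation))
      annotationSets <- .stage("read_annotation", fp,
                               readGeneSetsGmt(ins$annotation))
  }
  manifest$counts$markers <- nrow(markers)
  manifest$counts$map_entries <- nrow(mapEntries(map))
  manifest$counts$gene_sets <- nSets(sets)

  ## ---- LD pruning ----
  r2Max <- .cfgGet(config, "r2Max", 0.5)
  if (is.null(ld)) {
    warning("no LD table supplied: pruning stage skipped")
    kept <- markers$marker_id
    prunedMap <- map
  } else {
    kept <- .stage("prune_ld", sprintf("%d markers", nrow(markers)),
                   pruneLd(markers, ld, r2Max = r2Max))
    prunedMap <- .stage("prune_map", sprintf("%d kept", length(kept)),
                        pruneMap(map, kept))
  }
  writeLines(kept, file.path(outDir, "kept_markers.txt"))
  manifest$counts$markers_kept <- length(kept)
  manifest$counts$map_entries_pruned <- nrow(mapEntries(prunedMap))

  ## ---- MSEA ----
  mseaCfg <- .cfgGet(config, "msea", list())
  fdrMax <- .cfgGet(mseaCfg, "fdrMax", 0.10)
  mseaCfg$fdrMax <- NULL
  if (is.null(mseaCfg$seed)) mseaCfg$seed <- seed
  params <- do.call(MseaParams, mseaCfg)
  index <- .stage("index", sprintf("%d entries", nrow(mapEntries(prunedMap))),
                  buildGeneMarkerIndex(prunedMap, markers))
  msea <- .stage("msea", sprintf("%d sets", nSets(sets)),
                 runMsea(sets, index, params))
  .writeTsv(msea, file.path(outDir, "msea.tsv"))
  sig <- msea$set_id[msea$status == "ok" & !is.na(msea$fdr) &
                     msea$fdr < fdrMax]
  manifest$counts$significant_sets <- length(sig)

  ## ---- optional second independent dataset ----
  if (!is.null(config$secondDataset)) {
    sd <- config$secondDataset
    markersB <- .stage("read_gwas_b", sd$gwas, readGwas(sd$gwas))
    mapB <- map
    if (!is.null(sd$ld)) {
      ldB <- .stage("read_ld_b", sd$ld, readLdTable(sd$ld))
      keptB <- pruneLd(markersB, ldB, r2Max = r2Max)
      mapB <- pruneMap(map, keptB)
    }
    indexB <- buildGeneMarkerIndex(mapB, markersB)
    mseaB <- .stage("msea_b", sprintf("%d sets", nSets(sets)),
                    runMsea(sets, indexB, params))
    .writeTsv(mseaB, file.path(outDir, "msea_second_dataset.tsv"))
    comb <- combineTwoDatasets(msea, mseaB, fdrMaxA = fdrMax)
    sig <- comb$setIds
    manifest$counts$significant_sets_combined <- length(sig)
    manifest$combined_fdr_bound <- comb$combinedFdrBound
  }
  writeLines(sig, file.path(outDir, "significant_sets.txt"))

  ## ---- merge into supersets + confirm ----
  supersets <- NULL; confirmation <- NULL
  kdaRes <- list(); subnets <- list(); diseaseRes <- NULL
  if (length(sig) > 0) {
    keep <- match(sig, sets@setId)
    sigSets <- GeneSetList(setNames(sets@genes[keep], sets@setId[keep]),
                           description = sets@description[keep],
                           source = sets@source[keep])
    rho <- .cfgGet(.cfgGet(config, "merge", list()), "rho", 0.33)
    supersets <- .stage("merge", sprintf("%d sets", length(sig)),
                        mergeGeneSets(sigSets, rho = rho))
    writeGeneSetsGmt(supersets, file.path(outDir, "supersets.gmt"))
    prov <- data.frame(
      superset_id = rep(supersets@setId, lengths(supersets@memberSets)),
      member_set_id = unlist(supersets@memberSets, use.names = FALSE))
    .writeTsv(prov, file.path(outDir, "superset_members.tsv"))
    manifest$counts$supersets <- nSets(supersets)

    if (!is.null(annotationSets)) {
      universe <- unique(mapEntries(map)$gene_id)
      ann <- do.call(rbind, lapply(seq_len(nSets(supersets)), function(i) {
        a <- annotateSuperset(supersets@genes[[i]], annotationSets, universe)
        if (nrow(a) > 0) cbind(superset_id = supersets@setId[i], a) else NULL
      }))
      if (!is.null(ann))
        .writeTsv(ann, file.path(outDir, "superset_annotation.tsv"))
    }

    alphaConfirm <- .cfgGet(.cfgGet(config, "confirm", list()), "alpha", 0.05)
    confirmation <- .stage("confirm", sprintf("%d supersets",
                                              nSets(supersets)),
                           confirmSupersets(supersets, index, params,
                                            alpha = alphaConfirm))
    .writeTsv(confirmation, file.path(outDir, "confirmation.tsv"))
    manifest$counts$supersets_confirmed <-
      sum(confirmation$pass, na.rm = TRUE)

    ## ---- KDA per confirmed superset ----
    if (!is.null(net)) {
      kdaCfg <- .cfgGet(config, "kda", list())
      kparams <- do.call(KdaParams, kdaCfg)
      passing <- confirmation$superset_id[!is.na(confirmation$pass) &
                                          confirmation$pass]
      for (sid in passing) {
        gset <- supersets@genes[[match(sid, supersets@setId)]]
        kd <- .stage(paste0("kda_", sid), sprintf("%d genes", length(gset)),
                     suppressMessages(kdaTest(net, gset, kparams)))
        kdaRes[[sid]] <- kd
        .writeTsv(kd, file.path(outDir, sprintf("kda_%s.tsv", sid)))
        drivers <- kd$gene[kd$is_kd]
        if (length(drivers) > 0) {
          sub <- exportSubnetwork(net, drivers, gset,
                                  KdaParams(edgeMinStudies = 2L),
                                  map = prunedMap, markers = markers)
          subnets[[sid]] <- sub
          .writeTsv(sub, file.path(outDir, sprintf("subnetwork_%s.tsv", sid)))
        }
      }
      manifest$counts$key_drivers <-
        sum(vapply(kdaRes, function(k) sum(k$is_kd), 0L))
    }

    ## ---- disease enrichment ----
    if (!is.null(diseaseSets)) {
      universe <- unique(mapEntries(map)$gene_id)
      diseaseRes <- .stage("disease", sprintf("%d diseases",
                                              nSets(diseaseSets)),
                           enrichmentMatrix(supersets, diseaseSets, universe,
                                            alpha = .cfgGet(
                                              .cfgGet(config, "disease",
                                                      list()),
                                              "alpha", 0.05)))
      .writeTsv(diseaseRes, file.path(outDir, "disease_enrichment.tsv"))
    }
  } else {
    message("runPipeline: no significant gene sets; downstream stages idle")
  }

  ## ---- manifest ----
  files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                        "manifest.json"))
  manifest$checksums <- as.list(tools::md5sum(file.path(outDir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(outDir = outDir, markers = markers, map = prunedMap,
                 kept = kept, msea = msea, significant = sig,
                 supersets = supersets, confirmation = confirmation,
                 kda = kdaRes, subnetworks = subnets, disease = diseaseRes,
                 truth = truth, manifest = manifest))
}
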