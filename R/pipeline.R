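## End-to-end orchestration: read inputs, annotate, filter harmful,
## landscape + domain + prioritisation + enrichment + network stages,
## format-stable outputs and a run manifest.

#' Pipeline configuration
#'
#' Collects input paths, analysis parameters and the output directory.
#' All thresholds of the analysis are surfaced here with their standard
#' defaults (2-sample filter, 95th percentile, 2 % recurrence with the
#' 100-sample gate, 20-protein query cutoff, FDR tiers 0.01/0.001/0.05).
#'
#' @param variants,gff3,reference,predictions,domains,go_gmt,pathway_gmt,network,cancer_genes
#'   input file paths (see the respective readers).
#' @param out_dir output directory.
#' @param seed seed for the (deterministic) clustering stage.
#' @param selection a [selectionParams()] list.
#' @param policy a [queryPolicy()] list.
#' @param unique_substitutions count unique substitutions instead of
#'   occurrences in domain and AAS-matrix statistics.
#' @return list of class `pipeline_config`.
#' @export
pipelineConfig <- function(variants, gff3, reference, predictions,
                           domains, go_gmt, pathway_gmt, network,
                           cancer_genes, out_dir, seed = 1L,
                           selection = selectionParams(),
                           policy = queryPolicy(),
                           unique_substitutions = FALSE) {
  structure(list(paths = list(variants = variants, gff3 = gff3,
                              reference = reference,
                              predictions = predictions, domains = domains,
                              go_gmt = go_gmt, pathway_gmt = pathway_gmt,
                              network = network,
                              cancer_genes = cancer_genes),
                 out_dir = out_dir, seed = as.integer(seed),
                 selection = selection, policy = policy,
                 unique_substitutions = unique_substitutions),
            class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Schema checks for every input file: existence, required columns,
#' allele alphabet, probability ranges, and cross-file gene-id
#' references.  Problems are reported, not thrown.
#'
#' @param config a [pipelineConfig()].
#' @return data.frame with columns `file`, `problem`, `line` (NA when
#'   not line-specific); zero rows when everything is valid.
#' @export
validateInputs <- function(config) {
  probs <- list()
  note <- function(file, problem, line = NA_integer_)
    probs[[length(probs) + 1L]] <<- data.frame(
      file = file, problem = problem, line = line,
      stringsAsFactors = FALSE)
  p <- config$paths
  for (nm in names(p))
    if (!file.exists(p[[nm]])) note(p[[nm]], "file does not exist")
  if (length(probs)) {
    out <- do.call(rbind, probs)
    rownames(out) <- NULL
    return(out)
  }
  v <- try(readVariants(p$variants), silent = TRUE)
  if (inherits(v, "try-error")) {
    note(p$variants, attr(v, "condition")$message)
  } else {
    bad <- which(!v$ref %in% .BASES | !v$alt %in% .BASES | v$ref == v$alt)
    if (length(bad))
      note(p$variants, paste0(length(bad), " row(s) with invalid alleles"),
           bad[1] + 1L)
  }
  models <- try(readGeneModels(p$gff3, p$reference), silent = TRUE)
  if (inherits(models, "try-error"))
    note(p$gff3, attr(models, "condition")$message)
  pred <- try(loadPredictions(p$predictions), silent = TRUE)
  if (inherits(pred, "try-error"))
    note(p$predictions, attr(pred, "condition")$message)
  dom <- try(readDomains(p$domains), silent = TRUE)
  if (inherits(dom, "try-error"))
    note(p$domains, attr(dom, "condition")$message)
  if (!inherits(models, "try-error")) {
    genes <- unique(transcriptTable(models)$gene_id)
    for (gmt in c(p$go_gmt, p$pathway_gmt)) {
      sets <- try(readGMT(gmt), silent = TRUE)
      if (inherits(sets, "try-error")) {
        note(gmt, attr(sets, "condition")$message)
      } else {
        unknown <- setdiff(unique(unlist(sets)), genes)
        if (length(unknown))
          note(gmt, paste0(length(unknown),
                           " gene id(s) not present in the gene models"))
      }
    }
  }
  g <- try(readSIF(p$network), silent = TRUE)
  if (inherits(g, "try-error")) note(p$network, attr(g, "condition")$message)
  out <- do.call(rbind, c(probs, list(data.frame(
    file = character(), problem = character(), line = integer(),
    stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: annotation (cached on input
#' checksums under `out_dir/cache`), harmful-AAS filtering, per-cancer
#' spectra and AAS matrices, domain statistics, protein prioritisation,
#' GO/pathway enrichment with the two-tier query policy, network
#' reduction/degree/modules, and the cross-cancer overlap networks.
#' Tabular outputs and a manifest (input checksums, seed, stage row
#' counts) are written under `out_dir`.
#'
#' Missing inputs raise an error of class `somaticAAS_missing_input`
#' naming the path; a failure inside a stage raises
#' `somaticAAS_stage_error` naming the stage.
#'
#' @param config a [pipelineConfig()].
#' @return a list of class `ResultBundle` with elements `summary`,
#'   `aas`, `harmful`, `spectra`, `aas_matrices`, `domain_frequencies`,
#'   `selections`, `enrichment`, `degrees`, `modules`, `overlap`,
#'   `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (pth in unlist(config$paths))
    if (!file.exists(pth))
      stop(structure(class = c("somaticAAS_missing_input", "error",
                               "condition"),
                     list(message = paste0("missing input: ", pth),
                          call = sys.call())))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(structure(class = c("somaticAAS_stage_error", "error",
                               "condition"),
                     list(message = paste0("stage '", name, "' failed: ",
                                           conditionMessage(e)),
                          call = sys.call()))))
  }
  log <- list()
  checksums <- vapply(unlist(config$paths), function(f)
    unname(tools::md5sum(f)), character(1))

  inputs <- stage("read_inputs", {
    list(variants = readVariants(config$paths$variants),
         models = readGeneModels(config$paths$gff3,
                                 config$paths$reference),
         predictions = loadPredictions(config$paths$predictions),
         domains = readDomains(config$paths$domains),
         go = readGMT(config$paths$go_gmt),
         pathways = readGMT(config$paths$pathway_gmt),
         network = readSIF(config$paths$network),
         cgc = readGeneList(config$paths$cancer_genes))
  })
  log$n_variants <- nrow(inputs$variants)

  ## annotation, cached on the checksums of its inputs
  ann <- stage("annotation", {
    cache_dir <- file.path(out_dir, "cache")
    if (!dir.exists(cache_dir)) dir.create(cache_dir)
    key <- paste(checksums[c("variants", "gff3", "reference")],
                 collapse = "")
    cache_file <- file.path(cache_dir,
                            paste0("annotation-", substr(key, 1, 32),
                                   substr(key, 65, 96), ".rds"))
    if (file.exists(cache_file)) {
      readRDS(cache_file)
    } else {
      a <- annotateCatalog(inputs$variants, inputs$models)
      saveRDS(a, cache_file)
      a
    }
  })
  log$n_aas <- nrow(ann$aas)

  harmful <- stage("harmfulness", joinHarmful(ann$aas, inputs$predictions))
  log$n_harmful <- nrow(harmful)

  tx <- as.data.frame(transcriptTable(inputs$models))
  prot_len <- stats::setNames(tx$protein_length, tx$transcript_id)
  prot2gene <- stats::setNames(tx$gene_id, tx$transcript_id)
  cancers <- sort(unique(inputs$variants$cancer_type))
  n_samples <- vapply(cancers, function(cc) length(unique(
    inputs$variants$sample_id[inputs$variants$cancer_type == cc])),
    integer(1))

  spectra <- stage("spectra", {
    out <- list()
    for (cc in cancers) {
      mis <- ann$aas[ann$aas$consequence == "missense", , drop = FALSE]
      out[[cc]] <- list(all = buildSpectrum(mis, cancer = cc),
                        harmful = buildSpectrum(harmful, cancer = cc))
      writeSpectrum(out[[cc]]$all,
                    file.path(out_dir, paste0("spectrum_all_", cc, ".tsv")))
      writeSpectrum(out[[cc]]$harmful,
                    file.path(out_dir, paste0("spectrum_harmful_", cc,
                                              ".tsv")))
    }
    out
  })

  aas_matrices <- stage("aas_matrix", {
    lapply(stats::setNames(cancers, cancers), function(cc) list(
      all = buildAASMatrix(ann$aas, cancer = cc,
                           uniqueSubstitutions = config$unique_substitutions),
      harmful = buildAASMatrix(harmful, cancer = cc,
                               uniqueSubstitutions =
                                 config$unique_substitutions)))
  })

  domain_freq <- stage("domains", {
    out <- lapply(stats::setNames(cancers, cancers), function(cc) list(
      all = domainNormalizedFrequency(ann$aas, inputs$domains, cancer = cc,
        uniqueSubstitutions = config$unique_substitutions),
      harmful = domainNormalizedFrequency(harmful, inputs$domains,
        cancer = cc,
        uniqueSubstitutions = config$unique_substitutions)))
    prev <- domainCancerPrevalence(harmful, inputs$domains)
    utils::write.table(prev, file.path(out_dir,
                                       "domain_cancer_prevalence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    c(out, list(prevalence = prev))
  })

  selections <- stage("prioritization", {
    out <- list()
    for (cc in cancers) {
      sel <- selectProteins(harmful, cc, n_samples[[cc]],
                            params = config$selection,
                            proteinLengths = prot_len)
      tb <- as.data.frame(selectionTable(sel))
      tb$gene_id <- unname(prot2gene[tb$protein_id])
      tb$in_known_list <- tb$gene_id %in% inputs$cgc
      utils::write.table(tb, file.path(out_dir,
                                       paste0("selection_", cc, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out[[cc]] <- sel
    }
    out
  })

  enrichment <- stage("enrichment", {
    out <- list()
    for (cc in cancers) {
      sel_genes <- unique(unname(
        prot2gene[selectedProteins(selections[[cc]])]))
      harm_genes <- unique(harmful$gene_id[harmful$cancer_type == cc])
      q <- buildQuery(sel_genes, harm_genes, config$policy)
      go <- enrichTerms(q$query, inputs$go, fdr = q$go_fdr)
      pw <- enrichTerms(q$query, inputs$pathways, fdr = q$pathway_fdr)
      utils::write.table(go, file.path(out_dir, paste0("go_", cc, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(pw, file.path(out_dir,
                                       paste0("pathways_", cc, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out[[cc]] <- list(query = q, go = go, pathways = pw)
    }
    out
  })

  degrees <- stage("network", {
    overall <- averageDegree(NULL, inputs$network)
    out <- list(overall = overall)
    for (cc in cancers) {
      sel_genes <- unique(unname(
        prot2gene[selectedProteins(selections[[cc]])]))
      harm_genes <- unique(harmful$gene_id[harmful$cancer_type == cc])
      present <- igraph::V(inputs$network)$name
      sub <- reduceNetwork(inputs$network, intersect(sel_genes, present),
                           intersect(harm_genes, present))
      out[[cc]] <- list(
        selected = if (length(intersect(sel_genes, present)))
          averageDegree(intersect(sel_genes, present), inputs$network)
        else NULL,
        harmful_other = if (length(setdiff(intersect(harm_genes, present),
                                           sel_genes)))
          averageDegree(setdiff(intersect(harm_genes, present), sel_genes),
                        inputs$network) else NULL,
        reduced = sub,
        modules = if (igraph::vcount(sub))
          clusterModules(sub, seed = config$seed) else integer(0))
    }
    rows <- do.call(rbind, lapply(cancers, function(cc) data.frame(
      cancer_type = cc,
      selected_degree = if (is.null(out[[cc]]$selected)) NA else
        out[[cc]]$selected$average_degree,
      harmful_other_degree = if (is.null(out[[cc]]$harmful_other)) NA else
        out[[cc]]$harmful_other$average_degree,
      overall_degree = overall$average_degree)))
    utils::write.table(rows, file.path(out_dir, "degrees.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out
  })

  overlap <- stage("overlap", {
    pw_by_cancer <- lapply(enrichment, function(e)
      e$pathways$term[e$pathways$significant])
    prot_by_cancer <- lapply(selections, selectedProteins)
    ov <- if (length(cancers) >= 2)
      cancerOverlap(pw_by_cancer, prot_by_cancer,
                    splitCutoff = config$policy$selected_cutoff) else NULL
    if (!is.null(ov)) {
      for (side in names(ov))
        if (igraph::vcount(ov[[side]]))
          igraph::write_graph(ov[[side]],
                              file.path(out_dir, paste0("overlap_", side,
                                                        ".graphml")),
                              format = "graphml")
    }
    ov
  })

  manifest <- list(package = "somaticAAS",
                   version = as.character(utils::packageVersion("somaticAAS")),
                   seed = config$seed, input_checksums = as.list(checksums),
                   counts = log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(summary = ann$summary, aas = ann$aas, harmful = harmful,
                 spectra = spectra, aas_matrices = aas_matrices,
                 domain_frequencies = domain_freq, selections = selections,
                 enrichment = enrichment, degrees = degrees,
                 overlap = overlap, manifest = manifest),
            class = "ResultBundle")
}

#' @export
print.ResultBundle <- function(x, ...) {
  cat("somaticAAS ResultBundle\n")
  cat("  variants:", x$manifest$counts$n_variants,
      "| coding AAS records:", x$manifest$counts$n_aas,
      "| harmful:", x$manifest$counts$n_harmful, "\n")
  for (cc in names(x$selections))
    cat("  ", cc, ": ", sum(selectionTable(x$selections[[cc]])$selected),
        " selected proteins, ",
        sum(x$enrichment[[cc]]$pathways$significant),
        " significant pathways\n", sep = "")
  invisible(x)
}
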