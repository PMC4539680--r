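## Synthetic cohort generator: every pipeline input with planted truth
## (driver proteins, spectrum biases, enriched pathways, harmfulness
## probabilities correlated with driver status) so that each downstream
## stage has a recovery-based test without external data.

#' Configuration of the synthetic cohort generator
#'
#' The defaults define the reference simulation used throughout the test
#' suite: 3 cancer types of 100 samples on a 560-gene chromosome, a
#' 40-gene driver pool organised in 5 blocks of 8 (each cancer draws 3
#' blocks, 24 drivers), ~145 background SNVs per sample with
#' cancer-specific trinucleotide spectra, a 20x missense boost in drivers
#' (with per-driver variability), and harmfulness probabilities
#' Beta(50, 1) for driver missense AASs versus Beta(0.25, 0.30) for the
#' background (placing roughly 20 % of passenger AASs above the 0.95
#' harmful cutoff, comparable to reported false-positive behaviour of
#' harmfulness predictors on benign variants).
#'
#' @param seed master seed; every stage derives its own substream from it
#'   so stages can be regenerated independently.
#' @param n_cancers,samples_per_cancer cohort dimensions.
#' @param n_genes number of genes on the synthetic chromosome.
#' @param transcripts_per_gene integer range; genes with more than one
#'   transcript produce shorter isoforms by skipping codon-aligned
#'   internal exons.
#' @param cds_length_range CDS length range in codons (incl. stop).
#' @param drivers_per_cancer planted drivers per cancer; must equal
#'   `blocks_per_cancer * driver_blocks` block size, i.e. be divisible by
#'   `blocks_per_cancer`.
#' @param driver_blocks,blocks_per_cancer the driver pool is split into
#'   `driver_blocks` blocks; each cancer plants the drivers of
#'   `blocks_per_cancer` randomly chosen blocks (shared blocks create
#'   cross-cancer overlap).
#' @param background_rate expected SNVs per sample (over gene loci).
#' @param driver_boost fold enrichment of missense SNVs in driver
#'   proteins.
#' @param driver_jitter range of a per-driver uniform multiplier on
#'   `driver_boost`, giving drivers heterogeneous mutation frequencies.
#' @param spectrum_weights optional 96 x `n_cancers` matrix of channel
#'   probabilities (class-major channel order); default presets bias
#'   cancer 1 towards C>T, cancer 2 towards C>A, cancer 3 towards T>C.
#' @param harm_high,harm_low Beta(shape1, shape2) parameters for
#'   harmfulness probabilities of driver vs background missense AASs.
#' @param harm_thresholds `c(low, high)` probability thresholds for the
#'   neutral/unknown/harmful classes.
#' @param pathway_size genes per pathway gene set.
#' @param n_pathways optional cap on the number of background pathways;
#'   by default as many as needed to cover all genes.
#' @param n_go_terms,go_size_range GO collection dimensions.
#' @param network_density cross-pathway edge probability; within-pathway
#'   pairs are connected with `within_pathway_density`.
#' @param within_pathway_density within-pathway edge probability.
#' @param domains_per_protein integer range of domain instances per
#'   protein.
#' @param cgc_decoys non-driver genes added to the synthetic cancer-gene
#'   list.
#' @return validated list of class `synthetic_config`.
#' @export
syntheticConfig <- function(seed = 1L,
                            n_cancers = 3L,
                            samples_per_cancer = 100L,
                            n_genes = 560L,
                            transcripts_per_gene = c(1L, 3L),
                            cds_length_range = c(200L, 500L),
                            drivers_per_cancer = 24L,
                            driver_blocks = 5L,
                            blocks_per_cancer = 3L,
                            background_rate = 145,
                            driver_boost = 20,
                            driver_jitter = c(0.4, 1),
                            spectrum_weights = NULL,
                            harm_high = c(50, 1),
                            harm_low = c(0.25, 0.30),
                            harm_thresholds = c(0.05, 0.95),
                            pathway_size = 12L,
                            n_pathways = NULL,
                            n_go_terms = 60L,
                            go_size_range = c(5L, 40L),
                            network_density = 0.004,
                            within_pathway_density = 0.6,
                            domains_per_protein = c(1L, 3L),
                            cgc_decoys = 15L) {
  bad <- function(field, why) stop("invalid configuration field '", field,
                                   "': ", why, call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    bad("seed", "must be a single integer")
  if (n_cancers < 1) bad("n_cancers", "must be >= 1")
  if (samples_per_cancer < 0) bad("samples_per_cancer", "must be >= 0")
  if (n_genes < 2) bad("n_genes", "must be >= 2")
  if (length(transcripts_per_gene) != 2 ||
      transcripts_per_gene[1] > transcripts_per_gene[2] ||
      transcripts_per_gene[1] < 1)
    bad("transcripts_per_gene", "must be an increasing range >= 1")
  if (length(cds_length_range) != 2 || cds_length_range[1] < 10 ||
      cds_length_range[1] > cds_length_range[2])
    bad("cds_length_range", "must be an increasing range >= 10 codons")
  if (drivers_per_cancer >= n_genes)
    bad("drivers_per_cancer", "must be smaller than n_genes")
  if (drivers_per_cancer %% blocks_per_cancer != 0)
    bad("drivers_per_cancer", "must be divisible by blocks_per_cancer")
  if (blocks_per_cancer > driver_blocks)
    bad("blocks_per_cancer", "cannot exceed driver_blocks")
  block_size <- drivers_per_cancer %/% blocks_per_cancer
  if (driver_blocks * block_size >= n_genes)
    bad("driver_blocks", "driver pool must be smaller than n_genes")
  if (background_rate < 0) bad("background_rate", "must be >= 0")
  if (driver_boost < 0) bad("driver_boost", "must be >= 0")
  if (length(driver_jitter) != 2 || driver_jitter[1] <= 0 ||
      driver_jitter[1] > driver_jitter[2])
    bad("driver_jitter", "must be a positive increasing range")
  if (is.null(spectrum_weights))
    spectrum_weights <- .defaultSpectrumWeights(n_cancers)
  spectrum_weights <- as.matrix(spectrum_weights)
  if (nrow(spectrum_weights) != 96 || ncol(spectrum_weights) != n_cancers)
    bad("spectrum_weights", "must be a 96 x n_cancers matrix")
  if (any(spectrum_weights < 0))
    bad("spectrum_weights", "must be non-negative")
  spectrum_weights <- sweep(spectrum_weights, 2, colSums(spectrum_weights),
                            "/")
  stopifnot(all(abs(colSums(spectrum_weights) - 1) < 1e-9))
  for (f in c("harm_high", "harm_low"))
    if (any(get(f) <= 0) || length(get(f)) != 2)
      bad(f, "must be two positive Beta shape parameters")
  if (length(harm_thresholds) != 2 || harm_thresholds[1] < 0 ||
      harm_thresholds[1] >= harm_thresholds[2] || harm_thresholds[2] > 1)
    bad("harm_thresholds", "must satisfy 0 <= low < high <= 1")
  if (pathway_size > n_genes)
    bad("pathway_size", "cannot exceed n_genes")
  if (pathway_size <= block_size)
    bad("pathway_size", "must exceed the driver block size")
  if (n_go_terms < 1) bad("n_go_terms", "must be >= 1")
  if (network_density < 0 || network_density > 1)
    bad("network_density", "must be a probability")
  if (within_pathway_density < 0 || within_pathway_density > 1)
    bad("within_pathway_density", "must be a probability")
  structure(list(seed = as.integer(seed), n_cancers = as.integer(n_cancers),
                 samples_per_cancer = as.integer(samples_per_cancer),
                 n_genes = as.integer(n_genes),
                 transcripts_per_gene = as.integer(transcripts_per_gene),
                 cds_length_range = as.integer(cds_length_range),
                 drivers_per_cancer = as.integer(drivers_per_cancer),
                 driver_blocks = as.integer(driver_blocks),
                 blocks_per_cancer = as.integer(blocks_per_cancer),
                 block_size = as.integer(block_size),
                 background_rate = background_rate,
                 driver_boost = driver_boost,
                 driver_jitter = driver_jitter,
                 spectrum_weights = spectrum_weights,
                 harm_high = harm_high, harm_low = harm_low,
                 harm_thresholds = harm_thresholds,
                 pathway_size = as.integer(pathway_size),
                 n_pathways = n_pathways,
                 n_go_terms = as.integer(n_go_terms),
                 go_size_range = as.integer(go_size_range),
                 network_density = network_density,
                 within_pathway_density = within_pathway_density,
                 domains_per_protein = as.integer(domains_per_protein),
                 cgc_decoys = as.integer(cgc_decoys)),
            class = "synthetic_config")
}

## cancer-specific 96-channel presets: C>T/CpG-heavy, C>A-heavy (smoking
## like), T>C-heavy (liver like); additional cancers cycle through these.
.defaultSpectrumWeights <- function(n_cancers) {
  base <- matrix(1, 6, 16)
  presets <- list(
    { m <- base; m[3, ] <- 6; m[3, 9:12] <- 24; m },  # C>T, CpG-heavy
    { m <- base; m[1, ] <- 8; m },                               # C>A
    { m <- base; m[5, ] <- 8; m })                               # T>C
  w <- vapply(seq_len(n_cancers), function(i) {
    m <- presets[[(i - 1L) %% length(presets) + 1L]]
    as.vector(t(m)) / sum(m)
  }, numeric(96))
  matrix(w, nrow = 96, ncol = n_cancers)
}

## stage substreams derived from the master seed
.stageSeed <- function(config, offset)
  as.integer((as.numeric(config$seed) * 7919 + offset * 104729) %% 2147483629)

.withStageSeed <- function(config, offset, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(.stageSeed(config, offset))
  expr
}

.cancerNames <- function(config) sprintf("cancer%02d", seq_len(config$n_cancers))

## uniform draws from an integer range (safe when the range is a point)
.sampleRange <- function(range, n = 1L) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate synthetic gene models and reference sequence
#'
#' Builds one linear chromosome of non-overlapping multi-exon genes on
#' both strands.  Every transcript CDS starts with ATG, ends with a stop
#' codon, has length divisible by three and contains no internal stop.
#' Genes with several transcripts produce shorter isoforms by skipping
#' codon-aligned internal exons, so longest-transcript selection is
#' exercised.
#'
#' @param config a [syntheticConfig()].
#' @return a [GeneModelSet-class].
#' @export
generateGenes <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .withStageSeed(config, 1L, {
    ng <- config$n_genes
    sense <- setdiff(names(Biostrings::GENETIC_CODE),
                     names(Biostrings::GENETIC_CODE)[
                       Biostrings::GENETIC_CODE == "*"])
    stops <- c("TAA", "TAG", "TGA")
    n_tx <- .sampleRange(config$transcripts_per_gene, ng)
    if (all(n_tx == 1) && config$transcripts_per_gene[2] > 1)
      n_tx[1] <- 2L
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    if (length(unique(strand)) == 1L)
      strand[1] <- setdiff(c("+", "-"), strand[1])

    chrom_parts <- list(); cursor <- 0L
    exon_rows <- vector("list", ng)
    gene_ids <- sprintf("G%04d", seq_len(ng))
    for (gi in seq_len(ng)) {
      L <- .sampleRange(config$cds_length_range)
      n_exons <- if (n_tx[gi] > 1) n_tx[gi] + 1L else sample(1:3, 1L)
      n_exons <- min(n_exons, L %/% 2L)
      ## split L codons into n_exons parts of >= 2 codons
      cuts <- sort(sample(seq(2L, L - 2L), n_exons - 1L))
      sizes <- diff(c(0L, cuts, L))
      while (any(sizes < 2L)) {  # rare; resample
        cuts <- sort(sample(seq(2L, L - 2L), n_exons - 1L))
        sizes <- diff(c(0L, cuts, L))
      }
      codons <- c("ATG", sample(sense, L - 2L, replace = TRUE),
                  sample(stops, 1L))
      cds <- paste(codons, collapse = "")
      gap <- sample(100:300, 1L)
      introns <- if (n_exons > 1) sample(30:80, n_exons - 1L,
                                         replace = TRUE) else integer(0)
      gene_start <- cursor + gap + 1L
      chrom_parts[[length(chrom_parts) + 1L]] <-
        sample(.BASES, gap, replace = TRUE)
      ## genomic exon layout
      ex_start <- integer(n_exons); ex_end <- integer(n_exons)
      p <- gene_start
      gseq <- if (strand[gi] == "+") cds else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
      ## genomic exon sizes: coding order equals genomic order on '+',
      ## reversed on '-'; sizes are symmetric either way
      gsizes <- if (strand[gi] == "+") sizes * 3L else rev(sizes) * 3L
      off <- 0L
      for (e in seq_len(n_exons)) {
        ex_start[e] <- p; ex_end[e] <- p + gsizes[e] - 1L
        chrom_parts[[length(chrom_parts) + 1L]] <-
          strsplit(substring(gseq, off + 1L, off + gsizes[e]), "")[[1]]
        off <- off + gsizes[e]
        p <- ex_end[e] + 1L
        if (e < n_exons) {
          chrom_parts[[length(chrom_parts) + 1L]] <-
            sample(.BASES, introns[e], replace = TRUE)
          p <- p + introns[e]
        }
      }
      cursor <- ex_end[n_exons]
      ## transcripts: T1 = all exons; T(k+1) skips internal exon k
      ## (internal exons in coding order)
      tx_rows <- list()
      coding_order <- if (strand[gi] == "+") seq_len(n_exons) else
        rev(seq_len(n_exons))
      for (t in seq_len(n_tx[gi])) {
        keep <- if (t == 1L) seq_len(n_exons) else {
          skip_coding <- t  # internal exon index in coding order (2..n-1)
          setdiff(seq_len(n_exons), coding_order[skip_coding])
        }
        tid <- sprintf("%s.T%d", gene_ids[gi], t)
        tx_rows[[t]] <- data.frame(
          start = ex_start[keep], end = ex_end[keep],
          strand = strand[gi], gene_id = gene_ids[gi],
          transcript_id = tid, stringsAsFactors = FALSE)
      }
      exon_rows[[gi]] <- do.call(rbind, tx_rows)
    }
    chrom_parts[[length(chrom_parts) + 1L]] <-
      sample(.BASES, 150L, replace = TRUE)
    chrom <- paste(unlist(chrom_parts), collapse = "")
    ex <- do.call(rbind, exon_rows)
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(ex$start, ex$end),
                                 strand = ex$strand)
    S4Vectors::mcols(gr)$gene_id <- ex$gene_id
    S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
    ref <- Biostrings::DNAStringSet(c(chr1 = chrom))
    GeneModelSet(gr, ref)
  })
}

## ---- position maps over the synthetic genome (longest transcripts) ----

## Per-chromosome arrays: CDS position, transcript index, splice flag and
## gene-span flag per base, plus per-transcript CDS strings.  This is the
## generator's own position-indexed bookkeeping, independent of the
## interval-projection engine used by the annotation module.
.genomeMaps <- function(genes) {
  keep <- selectLongestTranscript(genes)
  idx <- .transcriptIndex(genes, keep)
  chrlens <- vapply(idx$refchars, length, integer(1))
  maps <- lapply(chrlens, function(n)
    list(cds = integer(n), tx = integer(n),
         splice = logical(n), span = logical(n)))
  tx_ids <- unique(idx$tx_of_exon)
  for (j in seq_along(idx$exons)) {
    ch <- idx$chrom[j]
    rng <- idx$start[j]:idx$end[j]
    maps[[ch]]$cds[rng] <- if (idx$strand[j] == "+")
      idx$cum_before[j] + seq_along(rng)
    else idx$cum_before[j] + rev(seq_along(rng))
    maps[[ch]]$tx[rng] <- match(idx$tx_of_exon[j], tx_ids)
  }
  ## gene spans and splice flags
  mc <- S4Vectors::mcols(idx$exons)
  for (tid in tx_ids) {
    i <- which(idx$tx_of_exon == tid)
    ch <- idx$chrom[i[1]]
    span <- min(idx$start[i]):max(idx$end[i])
    maps[[ch]]$span[span] <- TRUE
    sts <- sort(idx$start[i]); ens <- sort(idx$end[i])
    if (length(i) > 1) for (e in seq_len(length(i) - 1L)) {
      maps[[ch]]$splice[(ens[e] + 1L):min(ens[e] + 2L, length(maps[[ch]]$splice))] <- TRUE
      maps[[ch]]$splice[max(sts[e + 1L] - 2L, 1L):(sts[e + 1L] - 1L)] <- TRUE
    }
  }
  ## splice flags only outside CDS of the transcript itself
  for (ch in names(maps))
    maps[[ch]]$splice <- maps[[ch]]$splice & maps[[ch]]$cds == 0L
  strand_of_tx <- vapply(tx_ids, function(t)
    idx$strand[match(t, idx$tx_of_exon)], character(1))
  gene_of_tx <- vapply(tx_ids, function(t)
    idx$gene_of_exon[match(t, idx$tx_of_exon)], character(1))
  list(maps = maps, tx_ids = tx_ids, strand = strand_of_tx,
       gene = gene_of_tx, cds_seq = idx$cds_seq[tx_ids],
       refchars = idx$refchars)
}

## Label variants with their coding consequence using the position maps.
.labelVariants <- function(gm, chrom, pos, ref, alt) {
  n <- length(pos)
  lab <- character(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    m <- gm$maps[[ch]]
    cdsp <- m$cds[pos[i]]
    coding <- cdsp > 0L
    noncod <- i[!coding]
    spl <- m$splice[pos[noncod]]
    lab[noncod[spl]] <- "splice_site"
    lab[noncod[!spl]] <- "noncoding"
    if (any(coding)) {
      ii <- i[coding]
      txi <- m$tx[pos[ii]]
      minus <- gm$strand[txi] == "-"
      cref <- ifelse(minus, .compBase(ref[ii]), ref[ii])
      calt <- ifelse(minus, .compBase(alt[ii]), alt[ii])
      cp <- cdsp[coding]
      cidx <- (cp - 1L) %/% 3L + 1L
      offs <- (cp - 1L) %% 3L + 1L
      rc <- substring(gm$cds_seq[txi], 3L * cidx - 2L, 3L * cidx)
      ac <- rc
      substring(ac, offs, offs) <- calt
      lab[ii] <- .consequenceFromAA(translateCodon(rc), translateCodon(ac))
    }
  }
  lab
}

## ---- driver planting (shared deterministic substream) ----

.plantDrivers <- function(config, genes) {
  .withStageSeed(config, 10L, {
    gene_ids <- unique(transcriptTable(genes)$gene_id)
    pool <- sort(sample(gene_ids, config$driver_blocks * config$block_size))
    blocks <- split(sample(pool), rep(seq_len(config$driver_blocks),
                                      each = config$block_size))
    names(blocks) <- sprintf("block%d", seq_len(config$driver_blocks))
    cancers <- .cancerNames(config)
    chosen <- lapply(cancers, function(cc)
      sort(sample(config$driver_blocks, config$blocks_per_cancer)))
    names(chosen) <- cancers
    drivers <- lapply(chosen, function(b) sort(unlist(blocks[b],
                                                      use.names = FALSE)))
    list(pool = pool, blocks = blocks, chosen_blocks = chosen,
         drivers = drivers,
         driver_pathways = lapply(chosen, function(b)
           sprintf("PW_PLANTED_%d", b)))
  })
}

## canonical 32-key (pyrimidine x 16 contexts) index of genomic positions
.contextKeys <- function(chars, positions) {
  ref <- chars[positions]
  five <- chars[positions - 1L]
  three <- chars[positions + 1L]
  flip <- ref %in% c("A", "G")
  pyr <- ifelse(flip, .COMPLEMENT[ref], ref)
  c5 <- ifelse(flip, .COMPLEMENT[three], five)
  c3 <- ifelse(flip, .COMPLEMENT[five], three)
  ## context index identical to the .CONTEXTS (column-major outer) order
  (match(pyr, c("C", "T")) - 1L) * 16L +
    (match(c3, .BASES) - 1L) * 4L + match(c5, .BASES)
}

## channel (1..96) -> canonical key (1..32) and alternate pyrimidine base
.channelTable <- function() {
  cls <- rep(seq_len(6L), each = 16L)
  ctx <- rep(seq_len(16L), times = 6L)
  pyr <- ifelse(cls <= 3L, "C", "T")
  alt <- c("A", "G", "T", "A", "C", "G")[cls]
  key <- (match(pyr, c("C", "T")) - 1L) * 16L + ctx
  list(key = key, alt = alt, pyr = pyr)
}

#' Generate a synthetic somatic SNV cohort with planted truth
#'
#' Background SNVs are placed over gene loci with per-cancer trinucleotide
#' channel frequencies following `spectrum_weights` exactly (channels are
#' drawn first, then positions matching the channel's canonical context).
#' Driver proteins additionally receive missense-only SNVs at
#' `driver_boost` times their background missense rate (scaled by a
#' per-driver jitter).  The planted truth (drivers, pathway names, channel
#' weights, per-record consequence labels) is returned alongside and must
#' never be fed to the analysis pipeline.
#'
#' @param config a [syntheticConfig()].
#' @param genes the [GeneModelSet-class] from [generateGenes()].
#' @return list with `variants` (data.frame: `sample_id`, `cancer_type`,
#'   `chrom`, `pos`, `ref`, `alt`) and `truth` (list: `drivers`,
#'   `driver_pathways`, `chosen_blocks`, `pool`, `channel_weights`,
#'   `consequence` labels parallel to the variant rows).
#' @export
generateCohort <- function(config, genes) {
  stopifnot(inherits(config, "synthetic_config"))
  if (missing(genes) || !methods::is(genes, "GeneModelSet") ||
      !nrow(transcriptTable(genes)))
    stop("empty or missing gene set")
  planted <- .plantDrivers(config, genes)
  gm <- .genomeMaps(genes)
  cancers <- .cancerNames(config)
  .withStageSeed(config, 2L, {
    if (config$samples_per_cancer == 0L) {
      variants <- data.frame(sample_id = character(),
                             cancer_type = character(),
                             chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             stringsAsFactors = FALSE)
      truth <- c(planted, list(channel_weights = config$spectrum_weights,
                               consequence = character()))
      return(list(variants = variants, truth = truth))
    }
    ch <- "chr1"
    chars <- gm$refchars[[ch]]
    cand <- which(gm$maps[[ch]]$span)
    cand <- cand[cand > 1L & cand < length(chars)]
    keys <- .contextKeys(chars, cand)
    by_key <- split(cand, factor(keys, levels = 1:32))
    chan <- .channelTable()

    ## driver missense catalogue: genomic (pos, alt, channel) triples
    driver_tx <- names(gm$gene)[gm$gene %in% planted$pool]
    drv_tab <- .missenseCatalogue(gm, driver_tx)
    total_cand <- length(cand)

    rows <- vector("list", length(cancers) * 2L)
    ri <- 0L
    for (ci in seq_along(cancers)) {
      cc <- cancers[ci]
      w <- config$spectrum_weights[, ci]
      ns <- config$samples_per_cancer
      sample_ids <- sprintf("%s_S%03d", cc, seq_len(ns))
      ## background SNVs
      n_per <- stats::rpois(ns, config$background_rate)
      tot <- sum(n_per)
      if (tot) {
        cdraw <- sample.int(96L, tot, replace = TRUE, prob = w)
        pos <- integer(tot)
        for (k in unique(chan$key[cdraw])) {
          sel <- chan$key[cdraw] == k
          grp <- by_key[[k]]
          if (!length(grp)) stop("no genomic context for channel key ", k)
          pos[sel] <- grp[sample.int(length(grp), sum(sel), replace = TRUE)]
        }
        ref <- chars[pos]
        flip <- ref %in% c("A", "G")
        alt <- ifelse(flip, .COMPLEMENT[chan$alt[cdraw]], chan$alt[cdraw])
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          sample_id = rep(sample_ids, n_per), cancer_type = cc,
          chrom = ch, pos = pos, ref = unname(ref), alt = unname(alt),
          stringsAsFactors = FALSE)
      }
      ## driver extra missense SNVs
      drivers <- planted$drivers[[cc]]
      if (length(drivers) && config$driver_boost > 1 && nrow(drv_tab)) {
        jit <- stats::runif(length(drivers), config$driver_jitter[1],
                            config$driver_jitter[2])
        for (di in seq_along(drivers)) {
          dsel <- drv_tab$gene == drivers[di]
          if (!any(dsel)) next
          dsub <- drv_tab[dsel, , drop = FALSE]
          ## background missense rate of this gene, in expected SNVs per
          ## sample: one third of its missense-capable changes over all
          ## candidate positions
          base_rate <- config$background_rate * (nrow(dsub) / 3) / total_cand
          lam <- max(0, config$driver_boost * jit[di] - 1) * base_rate
          k_per <- stats::rpois(ns, lam)
          totd <- sum(k_per)
          if (!totd) next
          cdraw <- sample.int(96L, totd, replace = TRUE, prob = w)
          avail <- tabulate(dsub$channel, 96L) > 0L
          redo <- !avail[cdraw]
          while (any(redo)) {  # resample channels unavailable in this gene
            cdraw[redo] <- sample.int(96L, sum(redo), replace = TRUE,
                                      prob = w)
            redo <- !avail[cdraw]
          }
          pick <- integer(totd)
          for (cch in unique(cdraw)) {
            sel <- cdraw == cch
            opts <- which(dsub$channel == cch)
            pick[sel] <- opts[sample.int(length(opts), sum(sel),
                                         replace = TRUE)]
          }
          ri <- ri + 1L
          rows[[ri]] <- data.frame(
            sample_id = rep(sample_ids, k_per), cancer_type = cc,
            chrom = ch, pos = dsub$pos[pick], ref = dsub$ref[pick],
            alt = dsub$alt[pick], stringsAsFactors = FALSE)
        }
      }
    }
    variants <- do.call(rbind, rows[seq_len(ri)])
    ## one substitution per (sample, position)
    variants <- variants[!duplicated(paste(variants$sample_id,
                                           variants$pos)), , drop = FALSE]
    variants <- variants[order(variants$cancer_type, variants$sample_id,
                               variants$pos), , drop = FALSE]
    rownames(variants) <- NULL
    truth <- c(planted,
               list(channel_weights = config$spectrum_weights,
                    consequence = .labelVariants(gm, variants$chrom,
                                                 variants$pos, variants$ref,
                                                 variants$alt)))
    list(variants = variants, truth = truth)
  })
}

## all single-base missense changes within the CDS of given transcripts:
## genomic position, genomic alt, 96-channel
.missenseCatalogue <- function(gm, tx_ids) {
  out <- list()
  for (tid in tx_ids) {
    txi <- match(tid, gm$tx_ids)
    ch <- "chr1"
    m <- gm$maps[[ch]]
    pos <- which(m$tx == txi & m$cds > 0L)
    if (!length(pos)) next
    chars <- gm$refchars[[ch]]
    minus <- gm$strand[txi] == "-"
    cp <- m$cds[pos]
    cidx <- (cp - 1L) %/% 3L + 1L
    offs <- (cp - 1L) %% 3L + 1L
    rc <- substring(gm$cds_seq[txi], 3L * cidx - 2L, 3L * cidx)
    ref <- chars[pos]
    res <- list()
    for (b in .BASES) {
      keep <- ref != b
      calt <- unname(if (minus) .COMPLEMENT[[b]] else b)
      ac <- rc[keep]
      substring(ac, offs[keep], offs[keep]) <- calt
      cons <- .consequenceFromAA(translateCodon(rc[keep]),
                                 translateCodon(ac))
      mis <- cons == "missense"
      if (!any(mis)) next
      p <- pos[keep][mis]
      chanidx <- pyrimidineCanonical(chars[p], b, chars[p - 1L],
                                     chars[p + 1L])$channel
      res[[b]] <- data.frame(gene = unname(gm$gene[txi]), pos = p,
                             ref = chars[p],
                             alt = b, channel = chanidx,
                             stringsAsFactors = FALSE)
    }
    out[[tid]] <- do.call(rbind, res)
  }
  if (!length(out))
    return(data.frame(gene = character(), pos = integer(),
                      ref = character(), alt = character(),
                      channel = integer(), stringsAsFactors = FALSE))
  r <- do.call(rbind, out)
  rownames(r) <- NULL
  r
}

#' Generate harmfulness predictions for a synthetic AAS table
#'
#' Every unique missense substitution receives a probability drawn from
#' Beta(`harm_high`) when its protein belongs to the planted driver pool
#' and from Beta(`harm_low`) otherwise; classes follow the
#' [classifyByProbability()] threshold rule with `config$harm_thresholds`.
#'
#' @param aas AAS table from annotating the synthetic cohort.
#' @param truth the planted truth from [generateCohort()].
#' @param config the [syntheticConfig()].
#' @return prediction data.frame (`protein_id`, `position`, `ref_aa`,
#'   `alt_aa`, `probability`, `class`); attribute `n_skipped` counts
#'   non-missense rows ignored.
#' @export
generatePredictions <- function(aas, truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  mis <- aas[aas$consequence == "missense", , drop = FALSE]
  n_skipped <- nrow(aas) - nrow(mis)
  u <- unique(mis[, c("gene_id", "protein_id", "residue_pos", "ref_aa",
                      "alt_aa")])
  u <- u[order(u$protein_id, u$residue_pos, u$ref_aa, u$alt_aa), ,
         drop = FALSE]
  .withStageSeed(config, 3L, {
    isdrv <- u$gene_id %in% truth$pool
    p <- numeric(nrow(u))
    p[isdrv] <- stats::rbeta(sum(isdrv), config$harm_high[1],
                             config$harm_high[2])
    p[!isdrv] <- stats::rbeta(sum(!isdrv), config$harm_low[1],
                              config$harm_low[2])
    out <- data.frame(protein_id = u$protein_id, position = u$residue_pos,
                      ref_aa = u$ref_aa, alt_aa = u$alt_aa,
                      probability = p,
                      class = classifyByProbability(
                        p, config$harm_thresholds[1],
                        config$harm_thresholds[2]),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "n_skipped") <- as.integer(n_skipped)
    out
  })
}

#' Generate gene-set collections and an interaction network
#'
#' Planted pathways contain the driver blocks plus filler genes; the
#' remaining genes are partitioned into background pathways of
#' `pathway_size`.  The interaction network connects genes within the
#' same pathway with probability `within_pathway_density` and across
#' pathways with probability `network_density`, so pathway communities
#' are denser than the background.  The GO collection covers all genes
#' with randomly drawn term sizes.
#'
#' @param genes the [GeneModelSet-class].
#' @param truth planted truth from [generateCohort()].
#' @param config the [syntheticConfig()].
#' @return list with `pathways`, `go` (named lists of gene ids),
#'   `network` (undirected simple [igraph::graph]) and `cgc`
#'   (character vector: synthetic cancer-gene list).
#' @export
generateGenesetsAndNetwork <- function(genes, truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  gene_ids <- sort(unique(transcriptTable(genes)$gene_id))
  .withStageSeed(config, 4L, {
    ## planted pathways: block drivers + exclusive fillers
    nonpool <- setdiff(gene_ids, truth$pool)
    n_fill <- config$pathway_size - config$block_size
    fillers <- sample(nonpool, n_fill * length(truth$blocks))
    pathways <- list()
    for (b in seq_along(truth$blocks)) {
      pathways[[sprintf("PW_PLANTED_%d", b)]] <-
        sort(c(truth$blocks[[b]],
               fillers[((b - 1L) * n_fill + 1L):(b * n_fill)]))
    }
    rest <- setdiff(gene_ids, unlist(pathways))
    rest <- sample(rest)
    n_bg <- ceiling(length(rest) / config$pathway_size)
    if (!is.null(config$n_pathways))
      n_bg <- min(n_bg, max(0L, config$n_pathways - length(pathways)))
    if (n_bg > 0) {
      grp <- rep(seq_len(n_bg), each = config$pathway_size,
                 length.out = length(rest))
      bg <- split(rest, grp)
      names(bg) <- sprintf("PW_%04d", seq_len(n_bg))
      pathways <- c(pathways, lapply(bg, sort))
    }
    ## GO terms: a covering partition plus random sets
    go <- list()
    shuffled <- sample(gene_ids)
    gsz <- 20L
    n_cov <- ceiling(length(shuffled) / gsz)
    cov <- split(shuffled, rep(seq_len(n_cov), each = gsz,
                               length.out = length(shuffled)))
    for (i in seq_along(cov)) go[[sprintf("GO:%07d", i)]] <- sort(cov[[i]])
    while (length(go) < config$n_go_terms) {
      sz <- .sampleRange(config$go_size_range)
      go[[sprintf("GO:%07d", length(go) + 1L)]] <-
        sort(sample(gene_ids, min(sz, length(gene_ids))))
    }
    ## network: stochastic block model over the pathway partition
    membership <- stats::setNames(rep(NA_integer_, length(gene_ids)),
                                  gene_ids)
    for (i in seq_along(pathways))
      membership[pathways[[i]]] <- i
    edges <- .sbmEdges(gene_ids, membership,
                       config$within_pathway_density,
                       config$network_density)
    g <- igraph::make_empty_graph(n = length(gene_ids), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = gene_ids)
    if (nrow(edges))
      g <- igraph::add_edges(g, t(as.matrix(edges)))
    g <- igraph::simplify(g)
    cgc <- sort(c(truth$pool,
                  sample(setdiff(nonpool, fillers), config$cgc_decoys)))
    list(pathways = pathways, go = go, network = g, cgc = cgc,
         pathway_membership = membership)
  })
}

## stochastic-block-model edge sampling over all unordered pairs
.sbmEdges <- function(ids, membership, p_in, p_out) {
  n <- length(ids)
  pr <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  m1 <- membership[pr[, 1]]; m2 <- membership[pr[, 2]]
  same <- !is.na(m1) & !is.na(m2) & m1 == m2
  p <- ifelse(same, p_in, p_out)
  keep <- stats::runif(nrow(pr)) < p
  if (!any(keep))
    return(data.frame(from = character(), to = character()))
  data.frame(from = ids[pr[keep, 1]], to = ids[pr[keep, 2]],
             stringsAsFactors = FALSE)
}

#' Generate synthetic protein domain annotations
#'
#' Each longest-transcript protein receives 1-3 non-hotspot domain
#' instances at random positions; every driver-pool protein additionally
#' carries an instance of the hotspot accession `DOM_HOTSPOT` covering
#' its central 40 %, which therefore accumulates boosted driver AASs
#' across cancers.
#'
#' @param genes the [GeneModelSet-class].
#' @param truth planted truth from [generateCohort()].
#' @param config the [syntheticConfig()].
#' @return data.frame `protein_id`, `accession`, `name`, `start`, `end`.
#' @export
generateDomains <- function(genes, truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  tx <- as.data.frame(transcriptTable(genes))
  keep <- selectLongestTranscript(genes)
  tx <- tx[tx$transcript_id %in% keep, , drop = FALSE]
  .withStageSeed(config, 5L, {
    accs <- sprintf("DOM_%04d", seq_len(40L))
    rows <- list()
    for (i in seq_len(nrow(tx))) {
      L <- tx$protein_length[i]
      nd <- .sampleRange(config$domains_per_protein)
      for (d in seq_len(nd)) {
        len <- max(5L, round(L * stats::runif(1, 0.08, 0.25)))
        st <- sample(seq_len(max(1L, L - len + 1L)), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = tx$transcript_id[i], accession = sample(accs, 1L),
          start = st, end = min(L, st + len - 1L),
          stringsAsFactors = FALSE)
      }
      if (tx$gene_id[i] %in% truth$pool) {
        st <- max(1L, round(0.3 * L))
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = tx$transcript_id[i], accession = "DOM_HOTSPOT",
          start = st, end = min(L, st + round(0.4 * L)),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out$name <- out$accession
    out[, c("protein_id", "accession", "name", "start", "end")]
  })
}

#' Simulate a full cohort and write every pipeline input to disk
#'
#' Runs [generateGenes()], [generateCohort()], annotation,
#' [generatePredictions()], [generateGenesetsAndNetwork()] and
#' [generateDomains()], then writes: `variants.tsv`, `genes.gff3`,
#' `reference.fa`, `predictions.tsv`, `domains.tsv`, `go.gmt`,
#' `pathways.gmt`, `network.sif`, `cancer_genes.txt` and the truth
#' sidecar `truth.json` (never an input to the pipeline).
#'
#' @param config a [syntheticConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the generated objects and file `paths`.
#' @export
simulateCohort <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genes <- generateGenes(config)
  cohort <- generateCohort(config, genes)
  ann <- annotateCatalog(cohort$variants, genes)
  preds <- generatePredictions(ann$aas, cohort$truth, config)
  sets <- generateGenesetsAndNetwork(genes, cohort$truth, config)
  domains <- generateDomains(genes, cohort$truth, config)
  paths <- list(
    variants = file.path(dir, "variants.tsv"),
    gff3 = file.path(dir, "genes.gff3"),
    reference = file.path(dir, "reference.fa"),
    predictions = file.path(dir, "predictions.tsv"),
    domains = file.path(dir, "domains.tsv"),
    go = file.path(dir, "go.gmt"),
    pathways = file.path(dir, "pathways.gmt"),
    network = file.path(dir, "network.sif"),
    cgc = file.path(dir, "cancer_genes.txt"),
    truth = file.path(dir, "truth.json"))
  utils::write.table(cohort$variants, paths$variants, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeGeneModels(genes, paths$gff3, paths$reference)
  utils::write.table(preds, paths$predictions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(domains, paths$domains, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeGMT(sets$go, paths$go)
  writeGMT(sets$pathways, paths$pathways)
  writeSIF(sets$network, paths$network)
  writeLines(sets$cgc, paths$cgc)
  truth <- cohort$truth
  truth$channel_weights <- unname(as.list(as.data.frame(
    truth$channel_weights)))
  jsonlite::write_json(truth, paths$truth, auto_unbox = FALSE, digits = NA)
  invisible(list(config = config, genes = genes,
                 variants = cohort$variants, truth = cohort$truth,
                 aas = ann$aas, summary = ann$summary,
                 predictions = preds, genesets = sets, domains = domains,
                 paths = paths))
}
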