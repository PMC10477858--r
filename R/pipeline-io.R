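#' Read a FASTA file
#'
#' Sequences are normalised to upper case; duplicate ids are an error.
#'
#' @param path File path.
#' @param type `"DNA"` or `"AA"`.
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet].
#' @export
readFasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  raw <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(raw))) {
    stop("duplicate sequence id(s) in ", path)
  }
  seqs <- toupper(as.character(raw))
  if (type == "DNA") {
    Biostrings::DNAStringSet(seqs)
  } else {
    Biostrings::AAStringSet(seqs)
  }
}

#' Write sequences as 60-column-wrapped FASTA
#'
#' @param x A named [Biostrings::XStringSet].
#' @param path Output path.
#' @export
writeFasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write methylation sites as base-modification GFF3
#'
#' One row per modified base in the dialect of single-molecule
#' base-modification output: source `kinModCall`, type `m6A`/`m4C`,
#' `start == end` (1-based), and `coverage=`/`IPDRatio=` attributes.
#'
#' @param sites [GenomicRanges::GRanges] with `mod_type`, `coverage`,
#'   `ipd_ratio` metadata columns.
#' @param path Output path.
#' @export
writeMethylationGff <- function(sites, path) {
  lines <- sprintf(
    "%s\tkinModCall\t%s\t%d\t%d\t.\t%s\t.\tcoverage=%d;IPDRatio=%.2f",
    as.character(GenomicRanges::seqnames(sites)),
    sites$mod_type,
    BiocGenerics::start(sites),
    BiocGenerics::start(sites),
    as.character(BiocGenerics::strand(sites)),
    as.integer(sites$coverage),
    sites$ipd_ratio
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read base-modification GFF3 into methylation sites
#'
#' Accepts the dialect written by [writeMethylationGff()]: `start` must
#' equal `end`, types must be `m6A` or `m4C`, and each row must carry
#' `coverage=` and `IPDRatio=` attributes. Malformed rows raise an error
#' with their line number.
#'
#' @param path File path.
#' @return A [GenomicRanges::GRanges] with `mod_type`, `coverage`,
#'   `ipd_ratio`.
#' @export
readMethylationGff <- function(path) {
  lines <- readLines(path)
  lineNo <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  lineNo <- lineNo[keep]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges(mod_type = character(),
                                  coverage = integer(),
                                  ipd_ratio = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0L) {
    stop("line ", lineNo[bad[1]], ": expected 9 tab-separated columns")
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | start != end)
  if (length(bad) > 0L) {
    stop("line ", lineNo[bad[1]],
         ": start must equal end for a single modified base")
  }
  bad <- which(!m[, 3] %in% c("m6A", "m4C"))
  if (length(bad) > 0L) {
    stop("line ", lineNo[bad[1]], ": unknown modification type ",
         m[bad[1], 3])
  }
  covM <- regmatches(m[, 9], regexec("coverage=([0-9]+)", m[, 9]))
  ipdM <- regmatches(m[, 9], regexec("IPDRatio=([0-9.]+)", m[, 9]))
  bad <- which(lengths(covM) != 2L | lengths(ipdM) != 2L)
  if (length(bad) > 0L) {
    stop("line ", lineNo[bad[1]],
         ": attributes must contain coverage= and IPDRatio=")
  }
  GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start, width = 1L),
    strand = m[, 7],
    mod_type = m[, 3],
    coverage = as.integer(vapply(covM, `[`, character(1), 2L)),
    ipd_ratio = as.numeric(vapply(ipdM, `[`, character(1), 2L))
  )
}

#' Write CDS annotations as GFF3
#'
#' @param cds [GenomicRanges::GRanges] with `cds_id` and `category`.
#' @param path Output path.
#' @export
writeCdsGff <- function(cds, path) {
  lines <- sprintf(
    "%s\t.\tCDS\t%d\t%d\t.\t%s\t.\tID=%s;category=%s",
    as.character(GenomicRanges::seqnames(cds)),
    BiocGenerics::start(cds),
    BiocGenerics::end(cds),
    as.character(BiocGenerics::strand(cds)),
    cds$cds_id, cds$category
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read CDS annotations from GFF3
#'
#' @param path File path.
#' @return A [GenomicRanges::GRanges] with `cds_id` and `category`.
#' @export
readCdsGff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges(cds_id = character(),
                                  category = character()))
  }
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  idM <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
  catM <- sub(".*category=([^;]+).*", "\\1", m[, 9])
  GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(as.integer(m[, 4]), as.integer(m[, 5])),
    strand = m[, 7],
    cds_id = idM,
    category = catM
  )
}

#' Write a synthetic community to disk
#'
#' Emits the community as plain-text files: `genomes.fasta`,
#' `methylation.gff3`, `cds.gff3`, `proteins_phage.faa`,
#' `proteins_bact.faa`, `abundance_counts.tsv`, `taxonomy.tsv`,
#' `gold_pairs.tsv`, `evidence.tsv` and `truth.json`.
#'
#' @param community A [PhageCommunity-class].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
writeCommunity <- function(community, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  writeFasta(genomes(community), fp("genomes.fasta"))
  writeMethylationGff(methylationSites(community), fp("methylation.gff3"))
  writeCdsGff(cdsAnnotations(community), fp("cds.gff3"))
  writeFasta(phageProteins(community), fp("proteins_phage.faa"))
  writeFasta(bacterialProteins(community), fp("proteins_bact.faa"))
  counts <- abundanceCounts(community)
  countsDf <- data.frame(genome_id = rownames(counts), counts,
                         check.names = FALSE)
  write.table(countsDf, fp("abundance_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(taxonomyTable(community), fp("taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(goldPairs(community), fp("gold_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(recognitionEvidence(community), fp("evidence.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- plantedTruth(community)
  jsonlite::write_json(
    list(true_host_pairs = truth$true_host_pairs,
         true_lifestyles = as.list(truth$true_lifestyles),
         planted_viral = as.list(truth$planted_viral)),
    fp("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' MTase similarity edges between phages and candidate hosts
#'
#' Aligns every phage MTase protein against every bacterial MTase protein
#' (seed-prefiltered, see [similarityEdges()]) and annotates each edge with
#' the source genomes, producing the input of [assignHosts()] and
#' [pairFeature()].
#'
#' @param community A [PhageCommunity-class].
#' @return data.frame with `phage_protein`, `host_protein`, `phage_id`,
#'   `host_id`, `identity`, `query_coverage`, `simscore`.
#' @export
hostPredictionEdges <- function(community) {
  edges <- similarityEdges(phageProteins(community),
                           bacterialProteins(community))
  org <- proteinOrigin(community)
  genomeOf <- setNames(org$genome_id, org$protein_id)
  data.frame(
    phage_protein = edges$query,
    host_protein = edges$subject,
    phage_id = unname(genomeOf[edges$query]),
    host_id = unname(genomeOf[edges$subject]),
    identity = edges$identity,
    query_coverage = edges$query_coverage,
    simscore = edges$simscore,
    stringsAsFactors = FALSE
  )
}

#' Per-genome methylation density profiles
#'
#' Computes, for every genome of the community, the genome-wide, coding and
#' non-coding densities of both modification types, the fraction of
#' methylated CDSs, and the accumulated-coverage sequencing-depth
#' covariate.
#'
#' @param community A [PhageCommunity-class].
#' @return data.frame with one row per genome.
#' @export
densityProfiles <- function(community) {
  g <- genomes(community)
  sites <- methylationSites(community)
  cds <- cdsAnnotations(community)
  depth <- plantedTruth(community)$depth
  rows <- lapply(names(g), function(id) {
    s <- sites[GenomicRanges::seqnames(sites) == id]
    k <- cds[GenomicRanges::seqnames(cds) == id]
    genome <- g[[id]]
    rs <- regionSplit(s, k, genome)
    cs <- cdsSummary(s, k)
    data.frame(
      genome_id = id,
      density_m6A = suppressWarnings(methylationDensity(s, genome, "m6A")),
      density_m4C = suppressWarnings(methylationDensity(s, genome, "m4C")),
      coding_m6A = rs$coding_density[rs$mod_type == "m6A"],
      noncoding_m6A = rs$noncoding_density[rs$mod_type == "m6A"],
      coding_m4C = rs$coding_density[rs$mod_type == "m4C"],
      noncoding_m4C = rs$noncoding_density[rs$mod_type == "m4C"],
      frac_methylated_cds_m6A = cs$fraction_methylated[["m6A"]],
      frac_methylated_cds_m4C = cs$fraction_methylated[["m4C"]],
      n_sites = length(s),
      sequencing_depth = unname(depth[id]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run the full community analysis pipeline
#'
#' Simulates a community (or uses one supplied), then runs every stage in
#' dependency order: viral-recognition voting and filtering, lifestyle
#' binning, methylation-density profiling, motif support/dereplication
#' accounting, prevalence and the depth-controlled partial correlation,
#' MTase annotation, similarity clustering with origin categorisation, and
#' MTase-homology host prediction with precision/recall and AUC against
#' random negative pairs. Re-running with the same config and seed
#' reproduces the identical report.
#'
#' @param config A [CommunityConfig-class].
#' @param seed Integer seed.
#' @param community Optional pre-simulated [PhageCommunity-class].
#' @param outDir Optional directory; when given, the report is written as
#'   `report.json` and side tables as TSV.
#' @param minMotifSupport Minimum genome support for motif retention,
#'   scaled to the community size by default.
#' @param stages Character vector of stages to run (subset of
#'   `c("recognition", "lifestyle", "methylome", "motifs", "prevalence",
#'   "mtase", "hosts")`).
#' @return A nested list (`AnalysisReport`) of per-stage summaries plus
#'   provenance.
#' @export
runPipeline <- function(config = CommunityConfig(), seed = config@seed,
                        community = NULL, outDir = NULL,
                        minMotifSupport = NULL,
                        stages = c("recognition", "lifestyle", "methylome",
                                   "motifs", "prevalence", "mtase",
                                   "hosts")) {
  if (is.null(community)) {
    community <- simulateCommunity(config, seed = seed)
  } else {
    config <- communityConfig(community)
  }
  report <- list(provenance = list(
    seed = seed,
    n_phages = config@nPhages,
    n_bacteria = config@nBacteria,
    n_samples = config@nSamples,
    thresholds = list(
      presence_rpkm = 0.5,
      min_simscore = 90,
      min_agreeing_matches = 2,
      mtase_evalue_max = 1e-5,
      min_query_coverage = 75,
      mcl_inflation = 2
    )
  ))

  if ("recognition" %in% stages) {
    ev <- recognitionEvidence(community)
    calls <- classifyViral(ev)
    filt <- filterContig(ev)
    truthViral <- plantedTruth(community)$planted_viral[calls$contig_id]
    report$recognition <- list(
      n_contigs = nrow(calls),
      calls_by_route = as.list(table(calls$route)),
      recall = mean(calls$is_virus[truthViral]),
      specificity = mean(!calls$is_virus[!truthViral]),
      n_dropped_by_filter = sum(!filt$keep)
    )
  }

  if ("lifestyle" %in% stages) {
    ls <- lifestyleTable(community)
    binned <- binLifestyle(ls$score)
    report$lifestyle <- list(
      counts = as.list(table(binned)),
      agreement_with_planted = mean(binned == ls$lifestyle)
    )
  }

  profiles <- NULL
  if (any(c("methylome", "prevalence") %in% stages)) {
    profiles <- densityProfiles(community)
  }
  if ("methylome" %in% stages) {
    ls <- lifestyleTable(community)
    byLs <- split(profiles, ls$lifestyle[match(profiles$genome_id,
                                               ls$genome_id)])
    report$methylome <- list(
      n_sites = length(methylationSites(community)),
      n_methylated_genomes = sum(profiles$n_sites > 0),
      mean_density_by_lifestyle = lapply(byLs, function(d) {
        list(m6A = mean(d$density_m6A), m4C = mean(d$density_m4C))
      })
    )
  }

  if ("motifs" %in% stages) {
    motifs <- config@motifSet
    patterns <- vapply(motifs, motifPattern, character(1))
    types <- vapply(motifs, modType, character(1))
    if (is.null(minMotifSupport)) {
      # the study-scale default of 100 genomes scaled to community size
      minMotifSupport <- max(2L, ceiling(0.012 * config@nPhages))
    }
    hits <- motifSupport(genomes(community), patterns)
    supported <- supportFilter(hits, minGenomes = minMotifSupport)
    derep <- dereplicateMotifs(patterns, types)
    acct <- typeUnionAccounting(patterns[types == "m4C"],
                                patterns[types == "m6A"])
    report$motifs <- list(
      n_planted = length(patterns),
      n_supported = length(supported),
      min_support = minMotifSupport,
      n_after_dereplication = length(derep),
      union_accounting = acct
    )
  }

  if ("prevalence" %in% stages) {
    prev <- prevalence(abundanceRPKM(community), threshold = 0.5)
    dens <- profiles$n_sites /
      Biostrings::width(genomes(community))[match(
        profiles$genome_id, names(genomes(community)))]
    pc <- partialPearson(prev[profiles$genome_id], dens,
                         profiles$sequencing_depth)
    report$prevalence <- list(
      mean_prevalence = mean(prev),
      partial_correlation = pc$estimate,
      partial_p = pc$p.value
    )
  }

  selfEdges <- NULL
  if (any(c("mtase", "hosts") %in% stages)) {
    allProteins <- c(phageProteins(community), bacterialProteins(community))
  }
  if ("mtase" %in% stages) {
    mtases <- annotateMtases(domainHits(community))
    selfEdges <- similarityEdges(allProteins, allProteins)
    graph <- buildSimilarityGraph(selfEdges, vertices = names(allProteins))
    mcl <- mclCluster(graph)
    org <- proteinOrigin(community)
    origin <- setNames(org$origin, org$protein_id)
    cat3 <- categorizeClusters(mcl$clusters, origin, edges = selfEdges)
    report$mtase <- list(
      n_mtases = length(mtases),
      n_clusters = cat3$n_clusters,
      category_counts = as.list(cat3$category_counts),
      fraction_phage_in_sharing = cat3$fraction_phage_in_sharing,
      mcl_iterations = mcl$iterations
    )
  }

  if ("hosts" %in% stages) {
    hp <- hostPredictionEdges(community)
    assignments <- assignHosts(hp)
    gold <- goldPairs(community)
    tx <- taxonomyTable(community)
    neg <- negativePairs(gold, unique(proteinOrigin(community)$genome_id[
      proteinOrigin(community)$origin == "phage"]),
      tx$genome_id, nPerPositive = 1L,
      seed = .subSeed(seed, 42L), taxonomy = tx)
    posF <- mapply(pairFeature, gold$phage_id, gold$host_id,
                   MoreArgs = list(edges = hp))
    negF <- mapply(pairFeature, neg$phage_id, neg$host_id,
                   MoreArgs = list(edges = hp))
    ranges <- if (nrow(assignments) > 0L) {
      vapply(split(assignments$host_id, assignments$phage_id),
             lcaHostRange, character(1), taxonomy = tx)
    } else {
      character()
    }
    report$hosts <- list(
      n_assignments = nrow(assignments),
      n_phages_assigned = length(unique(assignments$phage_id)),
      precision_species = evaluatePrecision(assignments, gold, tx,
                                            "species"),
      precision_genus = evaluatePrecision(assignments, gold, tx, "genus"),
      recall_species = evaluateRecall(assignments, gold, tx, "species"),
      auc = if (nrow(gold) > 0L) rocAuc(posF, negF) else NA_real_,
      host_range = as.list(table(ranges))
    )
  }

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    if (!is.null(profiles)) {
      write.table(profiles, file.path(outDir, "density_profiles.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report
}
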