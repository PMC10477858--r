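# Derive a stage-specific sub-seed from a master seed, kept within the
# 32-bit integer range.
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Functional categories of phage genes
#'
#' The vocabulary used for CDS annotation: eight known viral functions plus
#' tRNA genes and the two poorly characterised classes.
#'
#' @return Character vector of category names.
#' @export
phageGeneCategories <- function() {
  c("Assembly", "Immune evasion", "Lysis", "Integration", "Replication",
    "Regulation", "Packaging", "Infection", "tRNA", "hypothetical",
    "unsorted")
}

#' Generate a random genome sequence
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1-gc)/2`, so the expected G+C fraction equals `gc`.
#'
#' @param length Genome length in bp (>= 1).
#' @param gc Target G+C fraction in `[0,1]`.
#' @param seed Optional integer seed.
#' @return A [Biostrings::DNAString].
#' @export
generateGenome <- function(length, gc = 0.5, seed = NULL) {
  if (length < 1) stop("'length' must be positive")
  if (gc < 0 || gc > 1) stop("'gc' must be in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), size = length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  Biostrings::DNAString(paste(bases, collapse = ""))
}

#' Plant non-overlapping CDS intervals on a genome
#'
#' Places `nCds` disjoint 1-based inclusive intervals covering roughly
#' `targetCoverage` of the genome, each with a random strand and a functional
#' category drawn from `categories` (known viral functions and tRNA are
#' common; hypothetical/unsorted make up the remainder).
#'
#' @param genomeLength Genome length in bp.
#' @param nCds Number of CDS to place.
#' @param categories Category vocabulary (see [phageGeneCategories()]).
#' @param targetCoverage Target fraction of the genome covered by CDS.
#' @param minLen Minimum CDS length in bp.
#' @param seed Optional integer seed.
#' @return data.frame with `cds_id`, `start`, `end`, `strand`, `category`.
#' @export
plantCds <- function(genomeLength, nCds,
                     categories = phageGeneCategories(),
                     targetCoverage = 0.7, minLen = 150L, seed = NULL) {
  if (nCds == 0L) {
    return(data.frame(cds_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      category = character(), stringsAsFactors = FALSE))
  }
  if (!is.null(seed)) set.seed(seed)
  totalBases <- round(targetCoverage * genomeLength)
  totalBases <- max(totalBases, nCds * minLen)
  if (totalBases > genomeLength) {
    stop("infeasible packing: ", nCds, " CDS of >= ", minLen,
         " bp do not fit in ", genomeLength, " bp")
  }
  extra <- totalBases - nCds * minLen
  lens <- rep(as.integer(minLen), nCds)
  if (extra > 0L) {
    lens <- lens + as.integer(rmultinom(1L, extra, rep(1, nCds)))
  }
  free <- genomeLength - totalBases
  gaps <- as.integer(rmultinom(1L, free, rep(1, nCds + 1L)))
  starts <- integer(nCds)
  pos <- 1L
  for (i in seq_len(nCds)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + lens[i]
  }
  catProb <- ifelse(categories == "hypothetical", 0.20,
                    ifelse(categories == "unsorted", 0.10,
                           ifelse(categories == "tRNA", 0.06, 0.08)))
  data.frame(
    cds_id = sprintf("cds_%03d", seq_len(nCds)),
    start = starts,
    end = starts + lens - 1L,
    strand = sample(c("+", "-"), nCds, replace = TRUE),
    category = sample(categories, nCds, replace = TRUE, prob = catProb),
    stringsAsFactors = FALSE
  )
}

#' Plant methylation sites inside motif occurrences
#'
#' For each modification type, all occurrences of the motifs of that type are
#' enumerated on both strands and a subset is sampled so that the realised
#' methylation density (methylated bases over target bases on both strands)
#' hits the requested target. Every emitted site therefore sits at the
#' methylated-position index of a motif occurrence. If the target density
#' exceeds what the motif occurrences allow, a warning is raised and the
#' maximum achievable set is emitted.
#'
#' @param genome A [Biostrings::DNAString] or character string.
#' @param motifs List of [IupacMotif-class] objects.
#' @param densityTarget Named numeric, e.g. `c(m6A = 0.01, m4C = 0.005)`.
#' @param seed Optional integer seed.
#' @return data.frame with `position` (1-based forward coordinate of the
#'   methylated base), `strand`, `mod_type`, `motif`, `coverage`,
#'   `ipd_ratio`.
#' @export
plantMethylation <- function(genome, motifs, densityTarget, seed = NULL) {
  if (is.character(genome)) genome <- Biostrings::DNAString(genome)
  if (!is.null(seed)) set.seed(seed)
  types <- names(densityTarget)
  if (is.null(types)) stop("'densityTarget' must be named by mod type")
  freq <- Biostrings::letterFrequency(genome, c("A", "C", "G", "T"))
  denom <- c(m6A = unname(freq["A"] + freq["T"]),
             m4C = unname(freq["C"] + freq["G"]))
  out <- list()
  for (tp in types) {
    target <- densityTarget[[tp]]
    if (target == 0) next
    mts <- Filter(function(m) m@modType == tp, motifs)
    if (length(mts) == 0L) {
      stop("no motifs supplied for requested type ", tp)
    }
    cand <- do.call(rbind, lapply(mts, function(m) {
      occ <- scanMotif(genome, m@pattern, bothStrands = TRUE,
                       methylatedIndex = m@methylatedIndex)
      if (nrow(occ) == 0L) return(NULL)
      data.frame(position = occ$meth_pos, strand = occ$strand,
                 motif = m@pattern, stringsAsFactors = FALSE)
    }))
    if (is.null(cand) || nrow(cand) == 0L) {
      warning("no occurrence of any ", tp,
              " motif in genome; emitting zero sites")
      next
    }
    cand <- cand[!duplicated(cand[c("position", "strand")]), , drop = FALSE]
    nTarget <- round(target * denom[[tp]])
    if (nTarget > nrow(cand)) {
      warning(sprintf(
        "%s density %.4f unreachable (%d motif positions available); %s",
        tp, target, nrow(cand), "emitting maximum achievable"))
      take <- seq_len(nrow(cand))
    } else {
      take <- sample(nrow(cand), nTarget)
    }
    if (length(take) == 0L) next
    sel <- cand[take, , drop = FALSE]
    sel$mod_type <- tp
    out[[tp]] <- sel
  }
  if (length(out) == 0L) {
    return(data.frame(position = integer(), strand = character(),
                      mod_type = character(), motif = character(),
                      coverage = integer(), ipd_ratio = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  n <- nrow(res)
  res$coverage <- rnbinom(n, mu = 30, size = 5) + 5L
  res$ipd_ratio <- round(runif(n, 2, 7), 2)
  res[c("position", "strand", "mod_type", "motif", "coverage", "ipd_ratio")]
}

#' Generate a random protein sequence
#'
#' @param length Protein length in residues.
#' @param seed Optional integer seed.
#' @return Character string over the 20 amino acids.
#' @export
randomProtein <- function(length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(.AA20, length, replace = TRUE), collapse = "")
}

#' Evolve a protein to a target fractional identity
#'
#' Applies exactly `round((1 - targetIdentity) * L)` point substitutions at
#' distinct positions (no indels); each substituted residue differs from the
#' original, so the realised identity equals the target up to rounding.
#'
#' @param parent Parent protein sequence (character).
#' @param targetIdentity Fractional identity in `(0, 1]`.
#' @param seed Optional integer seed.
#' @return Mutated protein sequence (character).
#' @export
evolveProtein <- function(parent, targetIdentity, seed = NULL) {
  if (targetIdentity <= 0 || targetIdentity > 1) {
    stop("'targetIdentity' must be in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  res <- strsplit(parent, "")[[1]]
  L <- length(res)
  k <- round((1 - targetIdentity) * L)
  if (k == 0L) return(parent)
  if (k >= L) stop("target identity below achievable floor for length ", L)
  pos <- sample(L, k)
  for (p in pos) {
    res[p] <- sample(setdiff(.AA20, res[p]), 1L)
  }
  paste(res, collapse = "")
}

#' Generate a rank-labelled taxonomy
#'
#' Builds a rooted tree root -> family -> genus -> species in which every
#' species has exactly one parent genus and every genus one parent family,
#' so all leaves sit at the same depth.
#'
#' @param nSpecies,nGenera,nFamilies Level sizes with
#'   `nSpecies >= nGenera >= nFamilies >= 1`.
#' @param seed Optional integer seed.
#' @return data.frame of nodes with columns `node`, `rank`, `parent`.
#' @export
generateTaxonomy <- function(nSpecies, nGenera, nFamilies, seed = NULL) {
  if (!(nSpecies >= nGenera && nGenera >= nFamilies && nFamilies >= 1)) {
    stop("need nSpecies >= nGenera >= nFamilies >= 1")
  }
  if (!is.null(seed)) set.seed(seed)
  fam <- sprintf("f_%02d", seq_len(nFamilies))
  gen <- sprintf("g_%02d", seq_len(nGenera))
  spc <- sprintf("s_%03d", seq_len(nSpecies))
  # every family gets at least one genus, every genus at least one species
  genParent <- c(fam, if (nGenera > nFamilies)
    sample(fam, nGenera - nFamilies, replace = TRUE))
  spcParent <- c(gen, if (nSpecies > nGenera)
    sample(gen, nSpecies - nGenera, replace = TRUE))
  rbind(
    data.frame(node = "root", rank = "root", parent = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(node = fam, rank = "family", parent = "root",
               stringsAsFactors = FALSE),
    data.frame(node = gen, rank = "genus", parent = genParent,
               stringsAsFactors = FALSE),
    data.frame(node = spc, rank = "species", parent = spcParent,
               stringsAsFactors = FALSE)
  )
}

#' Generate MTase repertoires with planted phage-host links
#'
#' Every bacterium receives 2-3 random MTase proteins. A configured fraction
#' of phages is linked to a host: each linked phage carries two MTases
#' evolved from its host's at `mtaseShareIdentity`, and one or two non-host
#' decoy bacteria receive additional copies of the same parents at the lower
#' `decoyIdentity`. Some unlinked phages carry an unrelated MTase. The
#' planted truth (host pairs and homology clusters) is recorded.
#'
#' @param config A [CommunityConfig-class].
#' @param phageIds,bacteriaIds Genome identifiers.
#' @param seed Optional integer seed.
#' @return List with `phageProteins`/`bacterialProteins`
#'   ([Biostrings::AAStringSet]), `proteinOrigin` (protein_id, genome_id,
#'   origin), `goldPairs` (phage_id, host_id) and `clusterTruth` (named
#'   integer mapping protein_id to its planted homology cluster).
#' @export
generateHostLinks <- function(config, phageIds, bacteriaIds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bactSeqs <- character()
  phageSeqs <- character()
  origin <- list()
  clusterTruth <- integer()
  clusterId <- 0L

  newCluster <- function() {
    clusterId <<- clusterId + 1L
    clusterId
  }
  addProtein <- function(id, seq, genome, orig, cl) {
    if (orig == "phage") phageSeqs[id] <<- seq else bactSeqs[id] <<- seq
    origin[[id]] <<- data.frame(protein_id = id, genome_id = genome,
                                origin = orig, stringsAsFactors = FALSE)
    clusterTruth[id] <<- cl
  }

  bactClusters <- list()  # per bacterium: data.frame(seq, cluster)
  for (b in bacteriaIds) {
    nMt <- sample(2:3, 1L)
    info <- data.frame(protein_id = character(nMt), seq = character(nMt),
                       cluster = integer(nMt), stringsAsFactors = FALSE)
    for (k in seq_len(nMt)) {
      id <- sprintf("%s_mt%d", b, k)
      sq <- randomProtein(sample(130:180, 1L))
      cl <- newCluster()
      addProtein(id, sq, b, "bacteria", cl)
      info[k, ] <- list(id, sq, cl)
    }
    bactClusters[[b]] <- info
  }

  nLinked <- round(config@linkedFraction * length(phageIds))
  linked <- sort(sample(seq_along(phageIds), nLinked))
  gold <- list()
  for (i in linked) {
    ph <- phageIds[i]
    host <- sample(bacteriaIds, 1L)
    parents <- bactClusters[[host]][seq_len(2L), ]
    for (k in 1:2) {
      id <- sprintf("%s_mt%d", ph, k)
      sq <- evolveProtein(parents$seq[k], config@mtaseShareIdentity)
      addProtein(id, sq, ph, "phage", parents$cluster[k])
    }
    decoyPool <- setdiff(bacteriaIds, host)
    decoys <- if (length(decoyPool) > 0L) {
      sample(decoyPool, min(length(decoyPool), sample(1:2, 1L)))
    } else {
      character()
    }
    for (d in decoys) {
      k <- sample(1:2, 1L)
      nExisting <- nrow(bactClusters[[d]])
      id <- sprintf("%s_mt%d", d, nExisting + 1L)
      sq <- evolveProtein(parents$seq[k], config@decoyIdentity)
      addProtein(id, sq, d, "bacteria", parents$cluster[k])
      bactClusters[[d]] <- rbind(bactClusters[[d]], data.frame(
        protein_id = id, seq = sq, cluster = parents$cluster[k],
        stringsAsFactors = FALSE))
    }
    gold[[ph]] <- data.frame(phage_id = ph, host_id = host,
                             stringsAsFactors = FALSE)
  }
  for (i in setdiff(seq_along(phageIds), linked)) {
    if (runif(1) < 0.5) {
      ph <- phageIds[i]
      id <- sprintf("%s_mt1", ph)
      addProtein(id, randomProtein(sample(130:180, 1L)), ph, "phage",
                 newCluster())
    }
  }
  goldPairs <- if (length(gold) > 0L) {
    do.call(rbind, unname(gold))
  } else {
    data.frame(phage_id = character(), host_id = character(),
               stringsAsFactors = FALSE)
  }
  list(
    phageProteins = Biostrings::AAStringSet(phageSeqs),
    bacterialProteins = Biostrings::AAStringSet(bactSeqs),
    proteinOrigin = do.call(rbind, unname(origin)),
    goldPairs = goldPairs,
    clusterTruth = clusterTruth
  )
}

#' Generate the abundance model of the community
#'
#' Presence of each genome in each sample is Bernoulli with a per-genome
#' probability whose logit rises with the z-scored planted methylation
#' density at strength `coupling` (a monotone logit link). Present genomes
#' receive a log-normal RPKM level, converted to read counts given the
#' sample library size; the emitted RPKM matrix is then recomputed exactly
#' from the counts via [computeRpkm()]. The sequencing-depth covariate is
#' the accumulated per-genome coverage implied by the counts.
#'
#' @param genomeLengths Named numeric of genome lengths (bp).
#' @param densities Named numeric of planted overall methylation densities.
#' @param nSamples Number of samples.
#' @param depthRange Mapped reads per sample (interval).
#' @param coupling Coupling coefficient in `[0,1]`.
#' @param seed Optional integer seed.
#' @param basePrevalence Baseline presence probability at average density.
#' @param readLength Read length used for the coverage covariate.
#' @return List with `counts`, `rpkm`, `librarySizes`, `depth` (named
#'   per-genome accumulated coverage) and `presenceProb`.
#' @export
generateAbundance <- function(genomeLengths, densities, nSamples,
                              depthRange = c(5e5, 5e6), coupling = 0.8,
                              seed = NULL, basePrevalence = 0.3,
                              readLength = 150) {
  if (nSamples < 1L) stop("'nSamples' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  g <- names(genomeLengths)
  n <- length(g)
  lib <- round(runif(nSamples, depthRange[1], depthRange[2]))
  z <- if (sd(densities) > 0) {
    as.numeric(scale(densities[g]))
  } else {
    rep(0, n)
  }
  p <- plogis(qlogis(basePrevalence) + coupling * 4 * z)
  magnitude <- rlnorm(n, meanlog = log(5), sdlog = 0.8)
  counts <- matrix(0, nrow = n, ncol = nSamples,
                   dimnames = list(g, sprintf("sample_%03d", seq_len(nSamples))))
  for (j in seq_len(nSamples)) {
    present <- rbinom(n, 1L, p) == 1L
    level <- ifelse(present,
                    magnitude * rlnorm(n, 0, 0.4),
                    runif(n, 0, 0.2))
    counts[, j] <- round(level * (genomeLengths[g] / 1000) * (lib[j] / 1e6))
  }
  rpkm <- computeRpkm(counts,
                      matrix(genomeLengths[g], nrow = n, ncol = nSamples),
                      matrix(lib, nrow = n, ncol = nSamples, byrow = TRUE))
  depth <- rowSums(counts) * readLength / genomeLengths[g]
  list(counts = counts, rpkm = rpkm, librarySizes = lib,
       depth = depth, presenceProb = p)
}

#' Generate per-contig viral-recognition evidence with planted labels
#'
#' Planted-viral contigs receive at least two passing recognition criteria
#' with probability `sensitivity` (otherwise a single passing criterion and a
#' sub-threshold CheckV completeness, so the voting rule misses them);
#' non-viral contigs receive sub-threshold scores with an occasional single
#' spurious pass. A fraction of viral contigs is circular.
#'
#' @param contigIds Contig identifiers.
#' @param lengths Contig lengths (bp).
#' @param viralLabels Logical vector of planted viral labels.
#' @param sensitivity Probability that a planted viral contig receives >= 2
#'   passing criteria.
#' @param circularFraction Fraction of viral contigs flagged circular.
#' @param seed Optional integer seed.
#' @return data.frame of recognition evidence columns plus `planted_viral`.
#' @export
generateRecognitionEvidence <- function(contigIds, lengths, viralLabels,
                                        sensitivity = 0.95,
                                        circularFraction = 0.1,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(contigIds)
  stopifnot(length(lengths) == n, length(viralLabels) == n)
  ev <- data.frame(
    contig_id = contigIds,
    length = as.numeric(lengths),
    circular = FALSE,
    virsorter_score = NA_real_,
    virfinder_score = NA_real_,
    pprmeta_score = NA_real_,
    refseq_identity = NA_real_,
    refseq_coverage = NA_real_,
    pog_orf_hits = 0L,
    checkv_completeness = NA_real_,
    bact_identity = NA_real_,
    bact_fraction = NA_real_,
    planted_viral = viralLabels,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    if (viralLabels[i]) {
      ev$circular[i] <- runif(1) < circularFraction
      if (runif(1) < sensitivity) {
        pass <- sample(1:5, sample(2:4, 1L))
      } else {
        pass <- sample(1:5, 1L)
      }
      if (1 %in% pass) ev$virsorter_score[i] <- runif(1, 0.7, 1)
      if (2 %in% pass) ev$virfinder_score[i] <- runif(1, 0.61, 1)
      if (3 %in% pass) ev$pprmeta_score[i] <- runif(1, 0.71, 1)
      if (4 %in% pass) {
        ev$refseq_identity[i] <- runif(1, 51, 100)
        ev$refseq_coverage[i] <- runif(1, 91, 100)
      }
      if (5 %in% pass) {
        ev$pog_orf_hits[i] <- max(3L, ceiling(2 * ev$length[i] / 10000))
      }
      ev$checkv_completeness[i] <- if (length(pass) >= 2) {
        runif(1, 90, 100)
      } else {
        runif(1, 40, 89)
      }
    } else {
      if (runif(1) < 0.1) {
        crit <- sample(1:3, 1L)
        if (crit == 1) ev$virsorter_score[i] <- runif(1, 0.7, 0.85)
        if (crit == 2) ev$virfinder_score[i] <- runif(1, 0.61, 0.75)
        if (crit == 3) ev$pprmeta_score[i] <- runif(1, 0.71, 0.8)
      } else {
        ev$virsorter_score[i] <- runif(1, 0, 0.5)
        ev$virfinder_score[i] <- runif(1, 0, 0.6)
      }
      ev$checkv_completeness[i] <- runif(1, 0, 60)
    }
  }
  ev
}

#' Simulate a complete synthetic phage-bacterium community
#'
#' Runs every generator stage under stage-specific sub-seeds derived from
#' `seed`: lifestyles, genomes, CDS, planted methylation, taxonomy, MTase
#' repertoires with host links, the abundance model, recognition evidence
#' and domain hits. The same config and seed reproduce the identical
#' community.
#'
#' @param config A [CommunityConfig-class].
#' @param seed Integer seed (defaults to the config's).
#' @return A [PhageCommunity-class].
#' @export
simulateCommunity <- function(config = CommunityConfig(),
                              seed = config@seed) {
  validObject(config)
  nP <- config@nPhages
  phageIds <- sprintf("phage_%03d", seq_len(nP))
  bactIds <- sprintf("bact_%03d", seq_len(config@nBacteria))

  # lifestyles and virulence scores within the label's bin
  set.seed(.subSeed(seed, 1L))
  lsNames <- names(config@lifestyleProportions)
  lifestyles <- sample(lsNames, nP, replace = TRUE,
                       prob = config@lifestyleProportions)
  binEdges <- list(temperate = c(0, 0.3), uncertain_temperate = c(0.3, 0.5),
                   uncertain_virulent = c(0.5, 0.7), virulent = c(0.7, 1))
  scores <- vapply(lifestyles, function(l) {
    e <- binEdges[[l]]
    runif(1, e[1] + 1e-6, e[2])
  }, numeric(1))

  # genomes
  lens <- round(runif(nP, config@phageLengthRange[1],
                      config@phageLengthRange[2]))
  seqs <- lapply(seq_len(nP), function(i) {
    generateGenome(lens[i], config@gcContent, seed = .subSeed(seed, 100L + i))
  })
  genomes <- Biostrings::DNAStringSet(
    setNames(vapply(seqs, as.character, character(1)), phageIds))

  # CDS
  cdsList <- lapply(seq_len(nP), function(i) {
    df <- plantCds(lens[i], nCds = max(3L, round(lens[i] / 1200)),
                   targetCoverage = config@cdsCoverage,
                   seed = .subSeed(seed, 200L + i))
    df$genome_id <- phageIds[i]
    df
  })
  cdsDf <- do.call(rbind, cdsList)
  cds <- GenomicRanges::GRanges(
    seqnames = cdsDf$genome_id,
    ranges = IRanges::IRanges(cdsDf$start, cdsDf$end),
    strand = cdsDf$strand,
    cds_id = paste(cdsDf$genome_id, cdsDf$cds_id, sep = ":"),
    category = cdsDf$category
  )

  # methylation
  siteList <- lapply(seq_len(nP), function(i) {
    dens <- config@densityByLifestyle[[lifestyles[i]]]
    df <- plantMethylation(seqs[[i]], config@motifSet, dens,
                           seed = .subSeed(seed, 300L + i))
    if (nrow(df) == 0L) return(NULL)
    df$genome_id <- phageIds[i]
    df
  })
  siteDf <- do.call(rbind, siteList)
  set.seed(.subSeed(seed, 4L))
  sites <- GenomicRanges::GRanges(
    seqnames = siteDf$genome_id,
    ranges = IRanges::IRanges(siteDf$position, width = 1L),
    strand = siteDf$strand,
    mod_type = siteDf$mod_type,
    motif = siteDf$motif,
    coverage = siteDf$coverage,
    ipd_ratio = siteDf$ipd_ratio,
    sample = sprintf("sample_%03d",
                     sample.int(config@nSamples, nrow(siteDf),
                                replace = TRUE))
  )
  GenomeInfoDb::seqlengths(sites) <- setNames(lens, phageIds)[
    GenomeInfoDb::seqlevels(sites)]

  # taxonomy: one species per bacterium
  nGen <- max(1L, round(config@nBacteria / 3))
  nFam <- max(1L, round(config@nBacteria / 9))
  taxNodes <- generateTaxonomy(config@nBacteria, nGen, nFam,
                               seed = .subSeed(seed, 5L))
  spc <- taxNodes$node[taxNodes$rank == "species"]
  genOf <- setNames(taxNodes$parent[taxNodes$rank == "species"], spc)
  famOf <- setNames(taxNodes$parent[taxNodes$rank == "genus"],
                    taxNodes$node[taxNodes$rank == "genus"])
  assignment <- data.frame(
    genome_id = bactIds,
    species = spc[seq_along(bactIds)],
    genus = unname(genOf[spc[seq_along(bactIds)]]),
    family = unname(famOf[genOf[spc[seq_along(bactIds)]]]),
    stringsAsFactors = FALSE
  )

  # host links and MTase repertoires
  links <- generateHostLinks(config, phageIds, bactIds,
                             seed = .subSeed(seed, 6L))

  # overall planted density per genome (sites per bp)
  nSites <- table(factor(siteDf$genome_id, levels = phageIds))
  densOverall <- as.numeric(nSites) / lens
  names(densOverall) <- phageIds

  ab <- generateAbundance(setNames(lens, phageIds), densOverall,
                          config@nSamples, config@depthRange,
                          config@prevalenceDensityCoupling,
                          seed = .subSeed(seed, 7L))

  # recognition evidence: phage contigs are viral; bacterial contigs are not
  evIds <- c(phageIds, sub("bact", "contig", bactIds))
  evLens <- c(lens, round(runif(config@nBacteria, 6000, 80000)))
  set.seed(.subSeed(seed, 8L))
  evidence <- generateRecognitionEvidence(
    evIds, evLens, c(rep(TRUE, nP), rep(FALSE, config@nBacteria)),
    seed = .subSeed(seed, 9L))

  # domain hits: every MTase protein hits the MTase domain whitelist;
  # one extra non-MTase protein per genome hits an unrelated domain
  set.seed(.subSeed(seed, 10L))
  mtIds <- links$proteinOrigin$protein_id
  hits <- data.frame(
    protein_id = mtIds,
    accession = sample(mtaseDomainWhitelist(), length(mtIds), replace = TRUE),
    evalue = 10^-runif(length(mtIds), 6, 50),
    stringsAsFactors = FALSE
  )
  otherIds <- sprintf("%s_hyp1", c(phageIds, bactIds))
  hits <- rbind(hits, data.frame(
    protein_id = otherIds,
    accession = sample(c("pfam00001", "COG1234", "cd00001"),
                       length(otherIds), replace = TRUE),
    evalue = 10^-runif(length(otherIds), 6, 50),
    stringsAsFactors = FALSE
  ))

  truth <- list(
    true_host_pairs = links$goldPairs,
    true_lifestyles = setNames(lifestyles, phageIds),
    lifestyle_scores = setNames(unname(scores), phageIds),
    planted_densities = lapply(
      setNames(lifestyles, phageIds),
      function(l) config@densityByLifestyle[[l]]),
    overall_density = densOverall,
    planted_cluster_ids = links$clusterTruth,
    planted_viral = setNames(c(rep(TRUE, nP), rep(FALSE, config@nBacteria)),
                             evIds),
    presence_prob = ab$presenceProb,
    depth = ab$depth
  )

  new("PhageCommunity",
      genomes = genomes,
      sites = sites,
      cds = cds,
      phageProteins = links$phageProteins,
      bacterialProteins = links$bacterialProteins,
      proteinOrigin = links$proteinOrigin,
      domainHits = hits,
      counts = ab$counts,
      rpkm = ab$rpkm,
      librarySizes = ab$librarySizes,
      taxonomy = list(nodes = taxNodes, assignment = assignment),
      evidence = evidence,
      lifestyles = data.frame(genome_id = phageIds, lifestyle = lifestyles,
                              score = unname(scores),
                              stringsAsFactors = FALSE),
      goldPairs = links$goldPairs,
      truth = truth,
      config = config)
}
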