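#' IupacMotif: a degenerate methylation motif
#'
#' A degenerate nucleotide pattern together with the 1-based index of the
#' methylated base within the pattern and the modification type it carries.
#' The IUPAC set at the methylated index must contain `A` for m6A motifs and
#' `C` for m4C motifs.
#'
#' @slot pattern Degenerate pattern over the IUPAC nucleotide alphabet.
#' @slot methylatedIndex 1-based position of the methylated base.
#' @slot modType `"m6A"` or `"m4C"`.
#' @export
setClass("IupacMotif", representation(
  pattern = "character",
  methylatedIndex = "integer",
  modType = "character"
))

setValidity("IupacMotif", function(object) {
  msg <- character()
  if (length(object@pattern) != 1L || !nzchar(object@pattern)) {
    msg <- c(msg, "'pattern' must be a single non-empty string")
  }
  if (!object@modType %in% c("m6A", "m4C")) {
    msg <- c(msg, "'modType' must be 'm6A' or 'm4C'")
  }
  if (length(msg) == 0L) {
    k <- nchar(object@pattern)
    i <- object@methylatedIndex
    if (i < 1L || i > k) {
      msg <- c(msg, "'methylatedIndex' outside pattern")
    } else {
      need <- if (object@modType == "m6A") "A" else "C"
      if (!need %in% iupacSet(substr(object@pattern, i, i))) {
        msg <- c(msg, sprintf(
          "IUPAC set at methylated index must contain %s for %s",
          need, object@modType))
      }
    }
  }
  if (length(msg) > 0L) msg else TRUE
})

#' Construct an IupacMotif
#'
#' @param pattern Degenerate nucleotide pattern.
#' @param methylatedIndex 1-based index of the methylated base.
#' @param modType `"m6A"` or `"m4C"`.
#' @return An [IupacMotif-class] object.
#' @examples
#' IupacMotif("GATC", 2, "m6A")
#' @export
IupacMotif <- function(pattern, methylatedIndex, modType) {
  new("IupacMotif",
      pattern = toupper(as.character(pattern)),
      methylatedIndex = as.integer(methylatedIndex),
      modType = as.character(modType))
}

#' @describeIn IupacMotif-class Pattern accessor.
#' @param object,x An `IupacMotif`.
#' @export
setGeneric("motifPattern", function(x) standardGeneric("motifPattern"))

#' @rdname IupacMotif-class
#' @export
setMethod("motifPattern", "IupacMotif", function(x) x@pattern)

#' @rdname IupacMotif-class
#' @export
setGeneric("methylatedIndex", function(x) standardGeneric("methylatedIndex"))

#' @rdname IupacMotif-class
#' @export
setMethod("methylatedIndex", "IupacMotif", function(x) x@methylatedIndex)

#' @rdname IupacMotif-class
#' @export
setGeneric("modType", function(x) standardGeneric("modType"))

#' @rdname IupacMotif-class
#' @export
setMethod("modType", "IupacMotif", function(x) x@modType)

setMethod("show", "IupacMotif", function(object) {
  cat(sprintf("IupacMotif %s (%s at position %d)\n",
              object@pattern, object@modType, object@methylatedIndex))
})

#' CommunityConfig: parameters of the synthetic community generator
#'
#' Holds every tunable of the synthetic phage-bacterium community: community
#' sizes, genome composition, the planted motif set, per-lifestyle
#' methylation-density targets, MTase-sharing identities, and the
#' abundance/prevalence model. The same config plus the same seed always
#' reproduces the identical community.
#'
#' @slot nPhages,nBacteria Community sizes.
#' @slot phageLengthRange Genome length interval in bp.
#' @slot gcContent Target G+C fraction of phage genomes.
#' @slot motifSet List of [IupacMotif-class] motifs available for planting.
#' @slot densityByLifestyle Named list mapping lifestyle to a named numeric
#'   `c(m6A=, m4C=)` of target methylation densities in `[0,1]`.
#' @slot lifestyleProportions Named numeric summing to 1.
#' @slot mtaseShareIdentity Fractional identity of phage MTase copies to
#'   their true host's MTases.
#' @slot decoyIdentity Fractional identity of decoy (non-host) MTase copies;
#'   must be below `mtaseShareIdentity`.
#' @slot linkedFraction Fraction of phages with a planted host link.
#' @slot nSamples Number of sequencing samples.
#' @slot depthRange Mapped reads per sample (interval).
#' @slot prevalenceDensityCoupling Strength in `[0,1]` of the monotone
#'   (logit-link) coupling between planted methylation density and presence
#'   probability.
#' @slot cdsCoverage Target fraction of each genome covered by CDS.
#' @slot seed Default integer seed.
#' @export
setClass("CommunityConfig", representation(
  nPhages = "integer",
  nBacteria = "integer",
  phageLengthRange = "numeric",
  gcContent = "numeric",
  motifSet = "list",
  densityByLifestyle = "list",
  lifestyleProportions = "numeric",
  mtaseShareIdentity = "numeric",
  decoyIdentity = "numeric",
  linkedFraction = "numeric",
  nSamples = "integer",
  depthRange = "numeric",
  prevalenceDensityCoupling = "numeric",
  cdsCoverage = "numeric",
  seed = "integer"
))

setValidity("CommunityConfig", function(object) {
  msg <- character()
  if (object@nPhages < 1L || object@nBacteria < 1L) {
    msg <- c(msg, "community sizes must be positive")
  }
  if (length(object@phageLengthRange) != 2L ||
      any(object@phageLengthRange < 1) ||
      diff(object@phageLengthRange) < 0) {
    msg <- c(msg, "'phageLengthRange' must be an increasing bp interval")
  }
  if (object@gcContent < 0 || object@gcContent > 1) {
    msg <- c(msg, "'gcContent' must be in [0,1]")
  }
  if (!all(vapply(object@motifSet, is, logical(1), "IupacMotif"))) {
    msg <- c(msg, "'motifSet' must be a list of IupacMotif objects")
  }
  dens <- unlist(object@densityByLifestyle)
  if (length(dens) > 0 && (any(dens < 0) || any(dens > 1))) {
    msg <- c(msg, "all density targets must be in [0,1]")
  }
  if (abs(sum(object@lifestyleProportions) - 1) > 1e-8) {
    msg <- c(msg, "'lifestyleProportions' must sum to 1")
  }
  if (!all(names(object@densityByLifestyle) %in%
           names(object@lifestyleProportions))) {
    msg <- c(msg, "density lifestyles must match lifestyle proportions")
  }
  if (object@mtaseShareIdentity <= object@decoyIdentity) {
    msg <- c(msg, "'mtaseShareIdentity' must exceed 'decoyIdentity'")
  }
  if (object@mtaseShareIdentity > 1 || object@decoyIdentity < 0) {
    msg <- c(msg, "identities must be fractions in [0,1]")
  }
  if (object@prevalenceDensityCoupling < 0 ||
      object@prevalenceDensityCoupling > 1) {
    msg <- c(msg, "'prevalenceDensityCoupling' must be in [0,1]")
  }
  if (object@nSamples < 1L) msg <- c(msg, "'nSamples' must be >= 1")
  if (length(msg) > 0L) msg else TRUE
})

#' Default planted motif set
#'
#' Six short recognition motifs of the kind written by restriction-
#' modification systems: three adenine-methylation motifs (Dam-like `GATC`,
#' `GANTC`, `CATG`) and three cytosine-methylation motifs (Dcm-like `CCWGG`,
#' `GCGC`, `CCGG`).
#'
#' @return List of [IupacMotif-class] objects.
#' @export
defaultMotifSet <- function() {
  list(
    IupacMotif("GATC", 2, "m6A"),
    IupacMotif("GANTC", 2, "m6A"),
    IupacMotif("CATG", 2, "m6A"),
    IupacMotif("CCWGG", 2, "m4C"),
    IupacMotif("GCGC", 2, "m4C"),
    IupacMotif("CCGG", 1, "m4C")
  )
}

#' Construct a CommunityConfig
#'
#' Defaults describe a 50-phage / 50-bacterium community with 104 samples,
#' phage genomes of 10-30 kb at 50% GC, per-lifestyle methylation-density
#' targets that rise with virulence for m4C and fall for m6A, host-shared
#' MTase copies at 95% identity versus decoys at 70%, and a prevalence-
#' density coupling of 0.8.
#'
#' @param nPhages,nBacteria Community sizes.
#' @param phageLengthRange Genome length interval in bp.
#' @param gcContent Target G+C fraction.
#' @param motifSet List of [IupacMotif-class] motifs.
#' @param densityByLifestyle Named list of `c(m6A=, m4C=)` targets.
#' @param lifestyleProportions Named numeric summing to 1.
#' @param mtaseShareIdentity,decoyIdentity Planted protein identities.
#' @param linkedFraction Fraction of phages with a planted host.
#' @param nSamples Number of samples.
#' @param depthRange Mapped reads per sample.
#' @param prevalenceDensityCoupling Coupling coefficient in `[0,1]`.
#' @param cdsCoverage Target CDS coverage fraction per genome.
#' @param seed Default seed.
#' @return A [CommunityConfig-class] object.
#' @export
CommunityConfig <- function(nPhages = 50L,
                            nBacteria = 50L,
                            phageLengthRange = c(10000, 30000),
                            gcContent = 0.5,
                            motifSet = defaultMotifSet(),
                            densityByLifestyle = list(
                              temperate          = c(m6A = 0.010, m4C = 0.004),
                              uncertain_temperate = c(m6A = 0.008, m4C = 0.006),
                              uncertain_virulent = c(m6A = 0.006, m4C = 0.008),
                              virulent           = c(m6A = 0.004, m4C = 0.010)
                            ),
                            lifestyleProportions = c(
                              temperate = 0.1368,
                              uncertain_temperate = 0.5958,
                              uncertain_virulent = 0.1861,
                              virulent = 0.0811
                            ),
                            mtaseShareIdentity = 0.95,
                            decoyIdentity = 0.70,
                            linkedFraction = 0.6,
                            nSamples = 104L,
                            depthRange = c(5e5, 5e6),
                            prevalenceDensityCoupling = 0.8,
                            cdsCoverage = 0.7,
                            seed = 1L) {
  lifestyleProportions <- lifestyleProportions / sum(lifestyleProportions)
  new("CommunityConfig",
      nPhages = as.integer(nPhages),
      nBacteria = as.integer(nBacteria),
      phageLengthRange = as.numeric(phageLengthRange),
      gcContent = as.numeric(gcContent),
      motifSet = motifSet,
      densityByLifestyle = densityByLifestyle,
      lifestyleProportions = lifestyleProportions,
      mtaseShareIdentity = as.numeric(mtaseShareIdentity),
      decoyIdentity = as.numeric(decoyIdentity),
      linkedFraction = as.numeric(linkedFraction),
      nSamples = as.integer(nSamples),
      depthRange = as.numeric(depthRange),
      prevalenceDensityCoupling = as.numeric(prevalenceDensityCoupling),
      cdsCoverage = as.numeric(cdsCoverage),
      seed = as.integer(seed))
}

setMethod("show", "CommunityConfig", function(object) {
  cat("CommunityConfig\n")
  cat(sprintf("  %d phages (%.0f-%.0f bp, GC %.2f), %d bacteria, %d samples\n",
              object@nPhages, object@phageLengthRange[1],
              object@phageLengthRange[2], object@gcContent,
              object@nBacteria, object@nSamples))
  cat(sprintf("  %d planted motifs; MTase share identity %.2f vs decoy %.2f\n",
              length(object@motifSet), object@mtaseShareIdentity,
              object@decoyIdentity))
  cat(sprintf("  prevalence-density coupling %.2f; seed %d\n",
              object@prevalenceDensityCoupling, object@seed))
})

#' PhageCommunity: a simulated phage-bacterium community
#'
#' Container for one realisation of the synthetic community: phage genome
#' sequences, planted methylation sites (as a [GenomicRanges::GRanges] with
#' `mod_type`, `coverage`, `ipd_ratio`, `sample` and `motif` metadata), CDS
#' annotations with functional categories, phage and bacterial MTase
#' proteins, domain-hit evidence, the abundance model (counts, RPKM,
#' library sizes), a rank-labelled taxonomy, viral-recognition evidence, and
#' the planted ground truth used to validate every downstream stage.
#'
#' @slot genomes [Biostrings::DNAStringSet] of phage genomes.
#' @slot sites [GenomicRanges::GRanges] of planted methylation sites.
#' @slot cds [GenomicRanges::GRanges] of CDS with `cds_id` and `category`.
#' @slot phageProteins,bacterialProteins [Biostrings::AAStringSet].
#' @slot proteinOrigin data.frame (`protein_id`, `genome_id`, `origin`).
#' @slot domainHits data.frame (`protein_id`, `accession`, `evalue`).
#' @slot counts,rpkm Genome-by-sample matrices.
#' @slot librarySizes Mapped reads per sample.
#' @slot taxonomy List with `nodes` (node, rank, parent) and `assignment`
#'   (genome_id, species, genus, family).
#' @slot evidence data.frame of per-contig viral-recognition evidence.
#' @slot lifestyles data.frame (`genome_id`, `lifestyle`, `score`).
#' @slot goldPairs data.frame (`phage_id`, `host_id`) of planted host links.
#' @slot truth List of planted ground truth.
#' @slot config The generating [CommunityConfig-class].
#' @export
setClass("PhageCommunity", representation(
  genomes = "ANY",
  sites = "ANY",
  cds = "ANY",
  phageProteins = "ANY",
  bacterialProteins = "ANY",
  proteinOrigin = "data.frame",
  domainHits = "data.frame",
  counts = "matrix",
  rpkm = "matrix",
  librarySizes = "numeric",
  taxonomy = "list",
  evidence = "data.frame",
  lifestyles = "data.frame",
  goldPairs = "data.frame",
  truth = "list",
  config = "CommunityConfig"
))

setValidity("PhageCommunity", function(object) {
  msg <- character()
  if (!is(object@genomes, "DNAStringSet")) {
    msg <- c(msg, "'genomes' must be a DNAStringSet")
  }
  if (!is(object@sites, "GRanges")) {
    msg <- c(msg, "'sites' must be a GRanges")
  }
  if (!identical(dim(object@counts), dim(object@rpkm))) {
    msg <- c(msg, "'counts' and 'rpkm' must have identical dimensions")
  }
  if (ncol(object@counts) != length(object@librarySizes)) {
    msg <- c(msg, "'librarySizes' must have one entry per sample")
  }
  if (length(msg) > 0L) msg else TRUE
})

setMethod("show", "PhageCommunity", function(object) {
  cat("PhageCommunity\n")
  cat(sprintf("  %d phage genomes (%.1f kb median), %d bacteria\n",
              length(object@genomes),
              median(Biostrings::width(object@genomes)) / 1000,
              object@config@nBacteria))
  cat(sprintf("  %d methylation sites (%d m6A, %d m4C), %d CDS\n",
              length(object@sites),
              sum(object@sites$mod_type == "m6A"),
              sum(object@sites$mod_type == "m4C"),
              length(object@cds)))
  cat(sprintf("  %d phage and %d bacterial MTase proteins; %d planted host links\n",
              length(object@phageProteins), length(object@bacterialProteins),
              nrow(object@goldPairs)))
  cat(sprintf("  abundance: %d x %d counts/RPKM\n",
              nrow(object@counts), ncol(object@counts)))
})

# ---- accessors ----

#' Accessors for PhageCommunity slots
#'
#' @param x A [PhageCommunity-class].
#' @return The corresponding component.
#' @name community-accessors
NULL

#' @rdname community-accessors
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))
#' @rdname community-accessors
#' @export
setMethod("genomes", "PhageCommunity", function(x) x@genomes)

#' @rdname community-accessors
#' @export
setGeneric("methylationSites", function(x) standardGeneric("methylationSites"))
#' @rdname community-accessors
#' @export
setMethod("methylationSites", "PhageCommunity", function(x) x@sites)

#' @rdname community-accessors
#' @export
setGeneric("cdsAnnotations", function(x) standardGeneric("cdsAnnotations"))
#' @rdname community-accessors
#' @export
setMethod("cdsAnnotations", "PhageCommunity", function(x) x@cds)

#' @rdname community-accessors
#' @export
setGeneric("phageProteins", function(x) standardGeneric("phageProteins"))
#' @rdname community-accessors
#' @export
setMethod("phageProteins", "PhageCommunity", function(x) x@phageProteins)

#' @rdname community-accessors
#' @export
setGeneric("bacterialProteins",
           function(x) standardGeneric("bacterialProteins"))
#' @rdname community-accessors
#' @export
setMethod("bacterialProteins", "PhageCommunity",
          function(x) x@bacterialProteins)

#' @rdname community-accessors
#' @export
setGeneric("proteinOrigin", function(x) standardGeneric("proteinOrigin"))
#' @rdname community-accessors
#' @export
setMethod("proteinOrigin", "PhageCommunity", function(x) x@proteinOrigin)

#' @rdname community-accessors
#' @export
setGeneric("domainHits", function(x) standardGeneric("domainHits"))
#' @rdname community-accessors
#' @export
setMethod("domainHits", "PhageCommunity", function(x) x@domainHits)

#' @rdname community-accessors
#' @export
setGeneric("abundanceCounts", function(x) standardGeneric("abundanceCounts"))
#' @rdname community-accessors
#' @export
setMethod("abundanceCounts", "PhageCommunity", function(x) x@counts)

#' @rdname community-accessors
#' @export
setGeneric("abundanceRPKM", function(x) standardGeneric("abundanceRPKM"))
#' @rdname community-accessors
#' @export
setMethod("abundanceRPKM", "PhageCommunity", function(x) x@rpkm)

#' @rdname community-accessors
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))
#' @rdname community-accessors
#' @export
setMethod("librarySizes", "PhageCommunity", function(x) x@librarySizes)

#' @rdname community-accessors
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))
#' @rdname community-accessors
#' @export
setMethod("taxonomyTable", "PhageCommunity",
          function(x) x@taxonomy$assignment)

#' @rdname community-accessors
#' @export
setGeneric("taxonomyNodes", function(x) standardGeneric("taxonomyNodes"))
#' @rdname community-accessors
#' @export
setMethod("taxonomyNodes", "PhageCommunity", function(x) x@taxonomy$nodes)

#' @rdname community-accessors
#' @export
setGeneric("recognitionEvidence",
           function(x) standardGeneric("recognitionEvidence"))
#' @rdname community-accessors
#' @export
setMethod("recognitionEvidence", "PhageCommunity", function(x) x@evidence)

#' @rdname community-accessors
#' @export
setGeneric("lifestyleTable", function(x) standardGeneric("lifestyleTable"))
#' @rdname community-accessors
#' @export
setMethod("lifestyleTable", "PhageCommunity", function(x) x@lifestyles)

#' @rdname community-accessors
#' @export
setGeneric("goldPairs", function(x) standardGeneric("goldPairs"))
#' @rdname community-accessors
#' @export
setMethod("goldPairs", "PhageCommunity", function(x) x@goldPairs)

#' @rdname community-accessors
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))
#' @rdname community-accessors
#' @export
setMethod("plantedTruth", "PhageCommunity", function(x) x@truth)

#' @rdname community-accessors
#' @export
setGeneric("communityConfig", function(x) standardGeneric("communityConfig"))
#' @rdname community-accessors
#' @export
setMethod("communityConfig", "PhageCommunity", function(x) x@config)
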