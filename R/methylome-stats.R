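# check that the base under each site matches its modification type:
# forward-strand m6A sits on A (minus-strand on T in forward coordinates),
# m4C on C (minus-strand on G)
.validateSites <- function(sites, genome) {
  if (length(sites) == 0L) return(invisible(TRUE))
  pos <- BiocGenerics::start(sites)
  if (any(pos < 1L) || any(pos > length(genome))) {
    stop("site position outside genome")
  }
  base <- strsplit(as.character(Biostrings::extractAt(
    genome, IRanges::IRanges(pos, width = 1L))), "")
  base <- vapply(base, `[`, character(1), 1L)
  str <- as.character(BiocGenerics::strand(sites))
  tp <- sites$mod_type
  expected <- ifelse(tp == "m6A",
                     ifelse(str == "-", "T", "A"),
                     ifelse(str == "-", "G", "C"))
  bad <- base != expected
  if (any(bad)) {
    stop(sum(bad), " site(s) whose base mismatches the modification type, ",
         "first at position ", pos[which(bad)[1]])
  }
  invisible(TRUE)
}

.targetBaseCount <- function(genome, modType, regions = NULL) {
  letters <- if (modType == "m6A") c("A", "T") else c("C", "G")
  if (is.null(regions)) {
    sum(Biostrings::letterFrequency(genome, letters))
  } else {
    regions <- IRanges::reduce(regions)
    if (length(regions) == 0L) return(0)
    v <- Biostrings::extractAt(genome, regions)
    sum(Biostrings::letterFrequency(v, letters))
  }
}

#' Methylation density of a genome
#'
#' The number of distinct methylated bases of one modification type divided
#' by the total number of target bases on both strands (for m6A: forward A
#' plus forward T, i.e. all adenines of the double strand; for m4C the
#' cytosines). An optional region mask restricts both numerator and
#' denominator.
#'
#' @param sites [GenomicRanges::GRanges] of methylation sites for one genome
#'   with a `mod_type` metadata column.
#' @param genome The genome sequence ([Biostrings::DNAString] or character).
#' @param modType `"m6A"` or `"m4C"`.
#' @param regions Optional [IRanges::IRanges] mask (forward coordinates).
#' @return Density fraction in `[0,1]`; 0 with a warning when the mask
#'   contains no target base.
#' @export
methylationDensity <- function(sites, genome, modType = c("m6A", "m4C"),
                               regions = NULL) {
  modType <- match.arg(modType)
  if (is.character(genome)) genome <- Biostrings::DNAString(genome)
  .validateSites(sites, genome)
  denom <- .targetBaseCount(genome, modType, regions)
  if (denom == 0) {
    warning("no target base in region; density reported as 0")
    return(0)
  }
  sel <- sites[sites$mod_type == modType]
  if (!is.null(regions)) {
    regions <- IRanges::reduce(regions)
    hit <- IRanges::overlapsAny(IRanges::IRanges(
      BiocGenerics::start(sel), width = 1L), regions)
    sel <- sel[hit]
  }
  key <- paste(BiocGenerics::start(sel),
               as.character(BiocGenerics::strand(sel)))
  length(unique(key)) / denom
}

#' Split methylation density into coding and non-coding regions
#'
#' A position is coding when it falls inside the union of the CDS intervals.
#' The genome-wide density of each type is the base-count-weighted mean of
#' the coding and non-coding densities.
#'
#' @param sites [GenomicRanges::GRanges] of sites for one genome.
#' @param cds CDS intervals for the genome ([IRanges::IRanges] or a
#'   [GenomicRanges::GRanges] whose ranges are used).
#' @param genome Genome sequence.
#' @return data.frame with one row per modification type and columns
#'   `mod_type`, `coding_density`, `noncoding_density`, `coding_sites`,
#'   `noncoding_sites`, `coding_bases`, `noncoding_bases`.
#' @export
regionSplit <- function(sites, cds, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAString(genome)
  if (is(cds, "GRanges")) cds <- IRanges::ranges(cds)
  if (length(cds) > 0 &&
      (min(BiocGenerics::start(cds)) < 1L ||
       max(BiocGenerics::end(cds)) > length(genome))) {
    stop("CDS interval outside genome")
  }
  coding <- IRanges::reduce(cds)
  noncoding <- IRanges::gaps(coding, start = 1L, end = length(genome))
  out <- lapply(c("m6A", "m4C"), function(tp) {
    sel <- sites[sites$mod_type == tp]
    inCds <- IRanges::overlapsAny(
      IRanges::IRanges(BiocGenerics::start(sel), width = 1L), coding)
    data.frame(
      mod_type = tp,
      coding_density = suppressWarnings(
        methylationDensity(sites, genome, tp, regions = coding)),
      noncoding_density = suppressWarnings(
        methylationDensity(sites, genome, tp, regions = noncoding)),
      coding_sites = sum(inCds),
      noncoding_sites = sum(!inCds),
      coding_bases = .targetBaseCount(genome, tp, coding),
      noncoding_bases = .targetBaseCount(genome, tp, noncoding),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Per-CDS methylation summaries
#'
#' For each modification type, the fraction of CDSs carrying at least one
#' site, and the per-CDS ratio of modified bases to CDS length (or, with
#' `perGenomeLength = TRUE`, to the whole genome length).
#'
#' @param sites [GenomicRanges::GRanges] of sites for one genome.
#' @param cds CDS intervals ([IRanges::IRanges] or [GenomicRanges::GRanges]).
#' @param perGenomeLength Use the genome length as the ratio denominator
#'   instead of each CDS length.
#' @param genomeLength Required when `perGenomeLength = TRUE`.
#' @return List with `fraction_methylated` (named by type) and `ratios`
#'   (matrix CDS x type).
#' @export
cdsSummary <- function(sites, cds, perGenomeLength = FALSE,
                       genomeLength = NULL) {
  if (is(cds, "GRanges")) cds <- IRanges::ranges(cds)
  if (length(cds) == 0L) stop("at least one CDS required")
  if (perGenomeLength && is.null(genomeLength)) {
    stop("'genomeLength' required when perGenomeLength = TRUE")
  }
  types <- c("m6A", "m4C")
  counts <- sapply(types, function(tp) {
    sel <- sites[sites$mod_type == tp]
    IRanges::countOverlaps(
      cds, IRanges::IRanges(BiocGenerics::start(sel), width = 1L))
  })
  counts <- matrix(counts, nrow = length(cds),
                   dimnames = list(NULL, types))
  denom <- if (perGenomeLength) genomeLength else IRanges::width(cds)
  list(
    fraction_methylated = colMeans(counts > 0L),
    ratios = counts / denom
  )
}

#' Methylation rates by gene functional category
#'
#' Across a set of genomes, the fraction of genomes in which at least one
#' gene of a functional category carries at least one methylation site of a
#' given type. Fractions are computed only over genomes that possess the
#' category; categories absent from every genome are excluded.
#'
#' @param cds [GenomicRanges::GRanges] of CDS across genomes, with seqnames
#'   identifying the genome and a `category` metadata column.
#' @param sites [GenomicRanges::GRanges] of methylation sites across the
#'   same genomes.
#' @return data.frame with `category`, `mod_type`, `n_genomes`,
#'   `n_methylated`, `fraction`.
#' @export
functionalRates <- function(cds, sites) {
  out <- list()
  for (tp in c("m6A", "m4C")) {
    sel <- sites[sites$mod_type == tp]
    hits <- GenomicRanges::countOverlaps(cds, sel, ignore.strand = TRUE)
    df <- data.frame(
      genome = as.character(GenomicRanges::seqnames(cds)),
      category = cds$category,
      methylated = hits > 0L,
      stringsAsFactors = FALSE
    )
    agg <- aggregate(methylated ~ genome + category, df, any)
    byCat <- aggregate(methylated ~ category, agg,
                       function(x) c(n = length(x), k = sum(x)))
    out[[tp]] <- data.frame(
      category = byCat$category,
      mod_type = tp,
      n_genomes = byCat$methylated[, "n"],
      n_methylated = byCat$methylated[, "k"],
      fraction = byCat$methylated[, "k"] / byCat$methylated[, "n"],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / ((length/1000) * (library/1e6))`.
#'
#' @param count Mapped read count(s); vector or matrix.
#' @param genomeLength Genome length(s) in bp.
#' @param libraryReads Total mapped reads of the library/libraries.
#' @return RPKM values with the shape of `count`.
#' @examples
#' computeRpkm(1000, 10000, 1e6)  # 100
#' @export
computeRpkm <- function(count, genomeLength, libraryReads) {
  if (any(genomeLength <= 0)) stop("'genomeLength' must be positive")
  if (any(libraryReads <= 0)) stop("'libraryReads' must be positive")
  if (any(count < 0)) stop("'count' must be non-negative")
  count / ((genomeLength / 1000) * (libraryReads / 1e6))
}

#' Prevalence from an abundance matrix
#'
#' The number of samples in which each genome is present, where presence is
#' RPKM at or above the threshold (a value exactly at the threshold counts
#' as present).
#'
#' @param rpkm Genome-by-sample RPKM matrix.
#' @param threshold Presence threshold (default 0.5 RPKM).
#' @return Named integer vector of per-genome sample counts.
#' @export
prevalence <- function(rpkm, threshold = 0.5) {
  if (threshold < 0) stop("'threshold' must be >= 0")
  rowSums(rpkm >= threshold)
}

#' Residuals of an ordinary least-squares fit with intercept
#'
#' @param v Response vector.
#' @param z Covariate vector.
#' @return Residuals of `lm(v ~ z)`; when `z` is constant, the mean-centred
#'   `v`.
#' @export
residualize <- function(v, z) {
  if (length(v) != length(z)) stop("lengths differ")
  if (length(v) < 3L) stop("need n >= 3")
  if (sd(z) == 0) return(v - mean(v))
  unname(resid(lm(v ~ z)))
}

#' First-order partial Pearson correlation
#'
#' The correlation between `x` and `y` after removing the linear effect of
#' the control variable `z`:
#' `r = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, with the
#' two-sided p-value from `t = r sqrt((n-3)/(1-r^2))` on `n - 3` degrees of
#' freedom. Identical to the Pearson correlation of the OLS residuals of `x`
#' and `y` on `z`.
#'
#' @param x,y Variables of interest.
#' @param z Control variable; a constant `z` reduces to the plain Pearson
#'   correlation.
#' @return List with `estimate`, `statistic`, `p.value`, `n`.
#' @export
partialPearson <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("lengths differ")
  if (n < 4L) stop("need n >= 4")
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate variance in x or y")
  if (sd(z) == 0) {
    r <- cor(x, y)
  } else {
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    den <- (1 - rxz^2) * (1 - ryz^2)
    if (den < 1e-12) {
      stop("control variable removes all variance from x or y")
    }
    r <- (rxy - rxz * ryz) / sqrt(den)
  }
  tstat <- r * sqrt((n - 3) / (1 - r^2))
  list(estimate = r,
       statistic = tstat,
       p.value = 2 * pt(-abs(tstat), df = n - 3),
       n = n)
}

#' Rarefaction curve of unique methylation sites
#'
#' Subsamples the per-sample site records at each depth fraction and counts
#' the distinct methylation sites recovered, averaged over replicates. At
#' fraction 1 the exact total unique count is returned.
#'
#' @param records data.frame of site records (one row per observed call,
#'   possibly redundant across samples).
#' @param fractions Depth fractions in `(0, 1]`.
#' @param reps Number of subsampling replicates per fraction.
#' @param seed Optional integer seed.
#' @param keyCols Columns identifying a unique site (default: all columns
#'   except `sample`).
#' @return data.frame with `fraction`, `mean_unique`.
#' @export
rarefactionCurve <- function(records, fractions, reps = 50L, seed = NULL,
                             keyCols = setdiff(names(records), "sample")) {
  if (any(fractions <= 0) || any(fractions > 1)) {
    stop("'fractions' must be in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  key <- do.call(paste, c(records[keyCols], sep = "\r"))
  n <- length(key)
  total <- length(unique(key))
  means <- vapply(sort(fractions), function(f) {
    if (f == 1) return(as.numeric(total))
    k <- max(1L, round(f * n))
    mean(vapply(seq_len(reps), function(r) {
      length(unique(key[sample.int(n, k)]))
    }, numeric(1)))
  }, numeric(1))
  data.frame(fraction = sort(fractions), mean_unique = means)
}
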