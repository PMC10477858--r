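#' Viral-contig recognition by evidence voting
#'
#' A contig is called viral if it is circular, or meets at least two of five
#' recognition criteria, or meets one criterion while being high-quality
#' (CheckV completeness >= 90%). The criteria, with their exact comparators:
#' \enumerate{
#'   \item VirSorter score >= 0.7
#'   \item VirFinder score > 0.6
#'   \item PPR-Meta phage score > 0.7
#'   \item Viral RefSeq hit with > 50% identity and > 90% coverage
#'   \item At least three ORFs with phage-orthologous-group hits
#'     (e <= 1e-5), at a density of at least two per 10 kb of contig length
#' }
#' Missing tool scores count as criterion-failed.
#'
#' @param evidence data.frame with columns `contig_id`, `length`, `circular`,
#'   `virsorter_score`, `virfinder_score`, `pprmeta_score`,
#'   `refseq_identity`, `refseq_coverage`, `pog_orf_hits`,
#'   `checkv_completeness` (`NA` = absent).
#' @return data.frame with `contig_id`, `is_virus`, `n_criteria`, `criteria`
#'   (comma-separated indices of satisfied criteria) and `route` in
#'   `c("circular", "voting", "checkv_plus_one", "rejected")`.
#' @export
classifyViral <- function(evidence) {
  if (any(is.na(evidence$length)) || any(evidence$length <= 0)) {
    stop("every contig needs a positive length")
  }
  nz <- function(x) !is.na(x)
  c1 <- nz(evidence$virsorter_score) & evidence$virsorter_score >= 0.7
  c2 <- nz(evidence$virfinder_score) & evidence$virfinder_score > 0.6
  c3 <- nz(evidence$pprmeta_score) & evidence$pprmeta_score > 0.7
  c4 <- nz(evidence$refseq_identity) & nz(evidence$refseq_coverage) &
    evidence$refseq_identity > 50 & evidence$refseq_coverage > 90
  pog <- ifelse(is.na(evidence$pog_orf_hits), 0L, evidence$pog_orf_hits)
  c5 <- pog >= 3 & pog / (evidence$length / 10000) >= 2
  crit <- cbind(c1, c2, c3, c4, c5)
  n <- rowSums(crit)
  checkvHq <- nz(evidence$checkv_completeness) &
    evidence$checkv_completeness >= 90
  circular <- !is.na(evidence$circular) & evidence$circular
  route <- ifelse(circular, "circular",
                  ifelse(n >= 2, "voting",
                         ifelse(n >= 1 & checkvHq, "checkv_plus_one",
                                "rejected")))
  data.frame(
    contig_id = evidence$contig_id,
    is_virus = route != "rejected",
    n_criteria = as.integer(n),
    criteria = apply(crit, 1L, function(r) {
      paste(which(r), collapse = ",")
    }),
    route = route,
    stringsAsFactors = FALSE
  )
}

#' Contamination and length filtering of contigs
#'
#' Drops a contig when it has a bacterial hit with >= 90% identity covering
#' >= 50% of its length (contamination), or when it is too short: linear
#' contigs must be longer than 5 kb, circular contigs longer than 1.5 kb.
#'
#' @param evidence data.frame with `contig_id`, `length`, `circular`,
#'   `bact_identity` (percent), `bact_fraction` (fraction of contig length).
#' @return data.frame with `contig_id`, `keep` and `reason` (`""`,
#'   `"contamination"` or `"length"`).
#' @export
filterContig <- function(evidence) {
  contaminated <- !is.na(evidence$bact_identity) &
    !is.na(evidence$bact_fraction) &
    evidence$bact_identity >= 90 & evidence$bact_fraction >= 0.5
  circular <- !is.na(evidence$circular) & evidence$circular
  tooShort <- ifelse(circular, evidence$length <= 1500,
                     evidence$length <= 5000)
  reason <- ifelse(contaminated, "contamination",
                   ifelse(tooShort, "length", ""))
  data.frame(
    contig_id = evidence$contig_id,
    keep = reason == "",
    reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Bin a virulence score into a lifestyle label
#'
#' Scores partition `[0, 1]` into `[0, 0.3]` temperate, `(0.3, 0.5]`
#' uncertain temperate, `(0.5, 0.7]` uncertain virulent and `(0.7, 1]`
#' virulent (half-open bins anchored by the explicit "<= 0.3" and "> 0.7"
#' endpoints; a score of exactly 0.5 is uncertain temperate).
#'
#' @param score Numeric vector of virulence scores in `[0, 1]`.
#' @return Character vector of lifestyle labels.
#' @examples
#' binLifestyle(c(0.3, 0.5, 0.85))
#' @export
binLifestyle <- function(score) {
  if (any(is.na(score)) || any(score < 0) || any(score > 1)) {
    stop("scores must be in [0, 1]")
  }
  as.character(cut(score, breaks = c(0, 0.3, 0.5, 0.7, 1),
                   labels = c("temperate", "uncertain_temperate",
                              "uncertain_virulent", "virulent"),
                   include.lowest = TRUE, right = TRUE))
}

#' crAssphage classification
#'
#' A contig is a crAssphage when it is longer than 70 kb and either has a
#' BLASTx hit to the prototypical crAssphage polymerase or terminase at
#' e < 1e-10, or shows >= 95% nucleotide identity over >= 80% of its length
#' to the prototypical genome.
#'
#' @param length Contig length(s) in bp.
#' @param blastxEvalue Best BLASTx e-value (`NA` = absent).
#' @param ntIdentity Nucleotide identity percent (`NA` = absent).
#' @param ntCoverage Fraction of contig length covered (`NA` = absent).
#' @return Logical vector.
#' @export
classifyCrassphage <- function(length, blastxEvalue = NA_real_,
                               ntIdentity = NA_real_,
                               ntCoverage = NA_real_) {
  critProtein <- !is.na(blastxEvalue) & blastxEvalue < 1e-10
  critNt <- !is.na(ntIdentity) & !is.na(ntCoverage) &
    ntIdentity >= 95 & ntCoverage >= 0.80
  length > 70000 & (critProtein | critNt)
}

#' Gubaphage genus assignment
#'
#' Assigns one of the four Gubaphage genera by the best (lowest e-value)
#' large-terminase hit with e < 1e-5; e-value ties are broken by the
#' lexicographically smaller genus.
#'
#' @param terminaseHits data.frame with columns `genus` (one of `G1.1`,
#'   `G1.2`, `G1.3`, `G2`) and `evalue`.
#' @return The assigned genus, or `"none"` when no hit qualifies.
#' @export
classifyGubaphage <- function(terminaseHits) {
  if (is.null(terminaseHits) || nrow(terminaseHits) == 0L) return("none")
  if (any(terminaseHits$evalue <= 0)) stop("e-values must be positive")
  ok <- terminaseHits[terminaseHits$evalue < 1e-5, , drop = FALSE]
  if (nrow(ok) == 0L) return("none")
  ok <- ok[order(ok$evalue, ok$genus), , drop = FALSE]
  ok$genus[1L]
}
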