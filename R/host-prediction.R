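#' SimScore: protein similarity score
#'
#' The product of percent identity and percent query coverage, scaled back
#' to a percentage: `identity * coverage / 100`.
#'
#' @param identity Percent identity in `[0, 100]`.
#' @param queryCoverage Percent query coverage in `[0, 100]`.
#' @return SimScore in `[0, 100]`.
#' @examples
#' simScore(95, 80)  # 76
#' @export
simScore <- function(identity, queryCoverage) {
  if (any(identity < 0 | identity > 100, na.rm = TRUE) ||
      any(queryCoverage < 0 | queryCoverage > 100, na.rm = TRUE)) {
    stop("identity and coverage must be in [0, 100]")
  }
  identity * queryCoverage / 100
}

#' Per-pair SimScore feature
#'
#' The maximum SimScore over all MTase-protein edges between one phage and
#' one candidate host genome, 0 when no edge exists.
#'
#' @param phageId,hostId Genome identifiers.
#' @param edges data.frame with `phage_id`, `host_id`, `simscore`.
#' @return Numeric scalar.
#' @export
pairFeature <- function(phageId, hostId, edges) {
  sel <- edges$phage_id == phageId & edges$host_id == hostId
  if (!any(sel)) return(0)
  max(edges$simscore[sel])
}

#' Sample random non-interacting phage-host pairs
#'
#' Negative pairs are drawn uniformly without replacement from the
#' phage-by-host cross product, excluding the gold-standard pairs and
#' (optionally, when a taxonomy is supplied) hosts of the same species as a
#' phage's known host, to avoid label noise.
#'
#' @param gold data.frame of positive pairs (`phage_id`, `host_id`).
#' @param phages,hosts Identifier vectors.
#' @param nPerPositive Number of negatives per positive pair.
#' @param seed Optional integer seed.
#' @param taxonomy Optional data.frame (`genome_id`, `species`, ...).
#' @param excludeSameSpecies Apply the same-species exclusion?
#' @return data.frame (`phage_id`, `host_id`) of sampled negatives.
#' @export
negativePairs <- function(gold, phages, hosts, nPerPositive = 1L,
                          seed = NULL, taxonomy = NULL,
                          excludeSameSpecies = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  all <- expand.grid(phage_id = phages, host_id = hosts,
                     stringsAsFactors = FALSE)
  goldKey <- paste(gold$phage_id, gold$host_id)
  pool <- all[!(paste(all$phage_id, all$host_id) %in% goldKey), ,
              drop = FALSE]
  if (!is.null(taxonomy) && excludeSameSpecies && nrow(gold) > 0L) {
    sp <- setNames(taxonomy$species, taxonomy$genome_id)
    goldSpecies <- paste(gold$phage_id, sp[gold$host_id])
    pool <- pool[!(paste(pool$phage_id, sp[pool$host_id]) %in%
                     goldSpecies), , drop = FALSE]
  }
  nNeg <- nPerPositive * nrow(gold)
  if (nNeg == 0L) {
    return(pool[0L, , drop = FALSE])
  }
  if (nNeg > nrow(pool)) {
    stop("requested ", nNeg, " negatives but only ", nrow(pool),
         " non-positive pairs exist")
  }
  out <- pool[sample(nrow(pool), nNeg), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties contributing 1/2.
#'
#' @param positiveScores,negativeScores Numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @examples
#' rocAuc(c(3, 1), c(2, 0))  # 0.75
#' @export
rocAuc <- function(positiveScores, negativeScores) {
  n1 <- length(positiveScores)
  n2 <- length(negativeScores)
  if (n1 == 0L || n2 == 0L) stop("both score lists must be non-empty")
  r <- rank(c(positiveScores, negativeScores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Rule-based host assignment from MTase similarity
#'
#' Each phage MTase protein is first reduced to its highest-SimScore edge
#' (ties kept). A host genome is assigned to a phage when at least
#' `minAgreeingMatches` distinct phage MTase proteins hit that host with
#' SimScore strictly above `minSimscore`. All qualifying hosts are
#' returned.
#'
#' @param edges data.frame with `phage_protein`, `phage_id`, `host_id`,
#'   `simscore` (one row per phage-protein/host-protein match).
#' @param minSimscore SimScore threshold (strict `>`, default 90).
#' @param minAgreeingMatches Minimum distinct supporting phage proteins.
#' @return data.frame with `phage_id`, `host_id`, `n_support`,
#'   `min_simscore`, `max_simscore`.
#' @export
assignHosts <- function(edges, minSimscore = 90, minAgreeingMatches = 2L) {
  empty <- data.frame(phage_id = character(), host_id = character(),
                      n_support = integer(), min_simscore = numeric(),
                      max_simscore = numeric(), stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) return(empty)
  best <- do.call(rbind, lapply(split(edges, edges$phage_protein),
                                function(e) {
    e[e$simscore == max(e$simscore), , drop = FALSE]
  }))
  best <- best[best$simscore > minSimscore, , drop = FALSE]
  if (nrow(best) == 0L) return(empty)
  grp <- split(best, paste(best$phage_id, best$host_id, sep = "\r"))
  rows <- lapply(grp, function(g) {
    nSupport <- length(unique(g$phage_protein))
    if (nSupport < minAgreeingMatches) return(NULL)
    data.frame(phage_id = g$phage_id[1], host_id = g$host_id[1],
               n_support = nSupport,
               min_simscore = min(g$simscore),
               max_simscore = max(g$simscore),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$phage_id, out$host_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.RANKS <- c("species", "genus", "family", "order", "class", "phylum",
            "domain", "root")

#' Host range as the rank of the last common ancestor
#'
#' A phage with a single predicted host has host range at the species
#' level; with multiple hosts, the range is the rank of the deepest
#' taxonomic level on which all hosts agree.
#'
#' @param hostIds Predicted host genome ids for one phage.
#' @param taxonomy data.frame with `genome_id`, `species`, `genus`,
#'   `family`.
#' @return One of `"species"`, `"genus"`, `"family"`, `"root"`.
#' @export
lcaHostRange <- function(hostIds, taxonomy) {
  miss <- setdiff(hostIds, taxonomy$genome_id)
  if (length(miss) > 0L) {
    stop("host(s) absent from taxonomy: ", paste(miss, collapse = ", "))
  }
  if (length(hostIds) == 0L) stop("no hosts supplied")
  if (length(hostIds) == 1L) return("species")
  tx <- taxonomy[match(hostIds, taxonomy$genome_id), , drop = FALSE]
  for (rk in c("species", "genus", "family")) {
    if (length(unique(tx[[rk]])) == 1L) return(rk)
  }
  "root"
}

#' Precision of host assignments against a gold standard
#'
#' An assignment is correct when its host matches any gold-standard host of
#' that phage at the requested taxonomic rank; precision is the fraction of
#' correct assignments. Each assignment counts once.
#'
#' @param assignments data.frame with `phage_id`, `host_id`.
#' @param gold data.frame of gold pairs (`phage_id`, `host_id`).
#' @param taxonomy data.frame with `genome_id`, `species`, `genus`.
#' @param rank `"species"` or `"genus"`.
#' @return Precision in `[0, 1]`, or `NA` when there are no assignments.
#' @export
evaluatePrecision <- function(assignments, gold, taxonomy,
                              rank = c("species", "genus")) {
  rank <- match.arg(rank)
  if (nrow(assignments) == 0L) return(NA_real_)
  lv <- setNames(taxonomy[[rank]], taxonomy$genome_id)
  goldLv <- paste(gold$phage_id, lv[gold$host_id])
  correct <- paste(assignments$phage_id, lv[assignments$host_id]) %in% goldLv
  mean(correct)
}

#' Recall of planted host pairs
#'
#' The fraction of gold-standard pairs recovered among the assignments at
#' the given rank.
#'
#' @inheritParams evaluatePrecision
#' @return Recall in `[0, 1]` (`NA` for an empty gold set).
#' @export
evaluateRecall <- function(assignments, gold, taxonomy,
                           rank = c("species", "genus")) {
  rank <- match.arg(rank)
  if (nrow(gold) == 0L) return(NA_real_)
  lv <- setNames(taxonomy[[rank]], taxonomy$genome_id)
  asgLv <- paste(assignments$phage_id, lv[assignments$host_id])
  mean(paste(gold$phage_id, lv[gold$host_id]) %in% asgLv)
}
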