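#' Domain-accession whitelist for MTase annotation
#'
#' The eleven conserved-domain accessions whose hits identify a protein as a
#' DNA methyltransferase.
#'
#' @return Character vector of accessions (without the `.smp` file suffix).
#' @export
mtaseDomainWhitelist <- function() {
  c("cd21179", "COG0350", "KOG3191", "pfam05869", "pfam12047",
    "PRK10904", "PRK11524", "TIGR00589", "TIGR00675", "TIGR01712",
    "TIGR02987")
}

#' Annotate MTases from conserved-domain hits
#'
#' A protein is an MTase when it has at least one hit to the domain
#' whitelist with e-value at or below the cutoff. Malformed rows (missing
#' fields or non-positive e-values) are skipped with a warning.
#'
#' @param hits data.frame with `protein_id`, `accession`, `evalue`.
#' @param evalueMax E-value cutoff (default 1e-5).
#' @param whitelist Domain accessions (default [mtaseDomainWhitelist()]);
#'   a trailing `.smp` suffix on hit accessions is ignored.
#' @return Sorted character vector of MTase protein ids.
#' @export
annotateMtases <- function(hits, evalueMax = 1e-5,
                           whitelist = mtaseDomainWhitelist()) {
  bad <- is.na(hits$protein_id) | is.na(hits$accession) |
    is.na(hits$evalue) | hits$evalue <= 0
  if (any(bad)) {
    warning(sum(bad), " malformed domain-hit row(s) skipped")
    hits <- hits[!bad, , drop = FALSE]
  }
  acc <- sub("\\.smp$", "", hits$accession)
  sel <- acc %in% whitelist & hits$evalue <= evalueMax
  sort(unique(hits$protein_id[sel]))
}

#' Orphan/non-orphan classification by reference best hits
#'
#' Each query MTase is represented by its best reference hit (lowest
#' e-value; ties broken by highest SimScore, then lexicographic subject id).
#' For each identity bin the proportion of queries whose best hit is a
#' non-orphan reference MTase is reported.
#'
#' @param referenceHits data.frame with `query`, `subject`, `identity`
#'   (percent), `evalue`, `subject_nonorphan` (logical) and optionally
#'   `simscore`.
#' @param identityBins Lower identity bounds of the bins (each bin is
#'   "identity >= bound").
#' @return data.frame with `min_identity`, `n_with_hit`, `n_nonorphan`,
#'   `proportion_pct` (`NA` for empty bins).
#' @export
classifyOrphan <- function(referenceHits, identityBins = c(0, 50, 90)) {
  if (nrow(referenceHits) == 0L) {
    return(data.frame(min_identity = identityBins,
                      n_with_hit = 0L, n_nonorphan = 0L,
                      proportion_pct = NA_real_))
  }
  if (is.null(referenceHits$simscore)) referenceHits$simscore <- 0
  ord <- order(referenceHits$query, referenceHits$evalue,
               -referenceHits$simscore, referenceHits$subject)
  best <- referenceHits[ord, , drop = FALSE]
  best <- best[!duplicated(best$query), , drop = FALSE]
  out <- lapply(identityBins, function(b) {
    sel <- best$identity >= b
    n <- sum(sel)
    k <- sum(sel & best$subject_nonorphan)
    data.frame(min_identity = b, n_with_hit = n, n_nonorphan = k,
               proportion_pct = if (n > 0) 100 * k / n else NA_real_)
  })
  do.call(rbind, out)
}

#' Enrichment of non-orphan MTases
#'
#' Tests whether a sample of `n` MTases containing `k` non-orphans is
#' enriched relative to a population of `N` with `K` non-orphans:
#' one-sided hypergeometric upper tail `P(X >= k)` for drawing `n` from the
#' population, and the chi-square test on the 2x2 table of sample versus
#' population (no continuity correction).
#'
#' @param k Non-orphans in the sample.
#' @param n Sample size.
#' @param K Non-orphans in the population.
#' @param N Population size.
#' @return List with `proportion_sample`, `proportion_population`,
#'   `p_hypergeometric`, `chisq_statistic`, `p_chisq`.
#' @examples
#' orphanEnrichment(3, 3, 3, 6)$p_hypergeometric  # 1/20
#' @export
orphanEnrichment <- function(k, n, K, N) {
  if (k < 0 || k > n || K < 0 || K > N || n > N) {
    stop("invalid counts: need 0 <= k <= n <= N and 0 <= K <= N")
  }
  pHyper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  # Pearson chi-square on the 2x2 table, no continuity correction
  tab <- rbind(c(k, n - k), c(K, N - K))
  if (k * N == K * n || any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    stat <- 0
    pChi <- 1
  } else {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - expected)^2 / expected)
    pChi <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(proportion_sample = if (n > 0) k / n else NA_real_,
       proportion_population = K / N,
       p_hypergeometric = pHyper,
       chisq_statistic = stat,
       p_chisq = pChi)
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.alignStats <- function(aln, queryLengths) {
  identity <- Biostrings::pid(aln, type = "PID1")
  qs <- BiocGenerics::start(Biostrings::pattern(aln))
  qe <- BiocGenerics::end(Biostrings::pattern(aln))
  qcov <- 100 * (qe - qs + 1) / queryLengths
  data.frame(identity = identity,
             query_coverage = qcov,
             simscore = identity * qcov / 100,
             score = BiocGenerics::score(aln))
}

#' Pairwise local protein alignment
#'
#' Smith-Waterman local alignment with BLOSUM62 and affine gaps
#' (open 11, extend 1). Identity is matches over alignment columns; query
#' coverage is the aligned query span over the query length; SimScore is
#' their product over 100.
#'
#' @param a Query protein sequence (character or [Biostrings::AAString]).
#' @param b Subject protein sequence.
#' @return One-row data.frame with `identity`, `query_coverage`, `simscore`,
#'   `score`, `evalue` (`NA`: no e-value is computed for in-package
#'   alignments).
#' @export
alignProteins <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1)
  out <- .alignStats(aln, nchar(a))
  out$evalue <- NA_real_
  out
}

.kmerIndex <- function(seqs, k) {
  lapply(as.character(seqs), function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1), k:n))
  })
}

#' All-against-all protein similarity edges
#'
#' Aligns query proteins against subject proteins with [alignProteins()]
#' semantics. Pairs are pre-screened by shared k-mer seeds (as homology
#' search tools do), so unrelated sequence pairs produce no edge; pairs
#' sharing at least `minSharedKmers` distinct k-mers are aligned.
#'
#' @param query,subject Named [Biostrings::AAStringSet]s (or named character
#'   vectors).
#' @param seedLength Seed k-mer length.
#' @param minSharedKmers Minimum distinct shared k-mers to trigger an
#'   alignment (set to 0 to align every pair).
#' @param dropSelf Drop pairs with identical query and subject names.
#' @return data.frame with `query`, `subject`, `identity`,
#'   `query_coverage`, `simscore`, `score`, `evalue` (`NA`).
#' @export
similarityEdges <- function(query, subject, seedLength = 4L,
                            minSharedKmers = 3L, dropSelf = TRUE) {
  qn <- names(query); sn <- names(subject)
  if (is.null(qn) || is.null(sn)) stop("sequence sets must be named")
  qChar <- as.character(query); sChar <- as.character(subject)
  if (minSharedKmers > 0L) {
    qK <- .kmerIndex(qChar, seedLength)
    inv <- new.env(hash = TRUE, parent = emptyenv())
    sK <- .kmerIndex(sChar, seedLength)
    for (j in seq_along(sK)) {
      for (km in sK[[j]]) {
        inv[[km]] <- c(get0(km, envir = inv, ifnotfound = NULL), j)
      }
    }
    candidates <- lapply(seq_along(qChar), function(i) {
      hits <- unlist(lapply(qK[[i]], function(km) {
        get0(km, envir = inv, ifnotfound = NULL)
      }), use.names = FALSE)
      if (length(hits) == 0L) return(integer())
      tab <- tabulate(hits, nbins = length(sChar))
      which(tab >= minSharedKmers)
    })
  } else {
    candidates <- rep(list(seq_along(sChar)), length(qChar))
  }
  # group by subject so each pairwiseAlignment call vectorises over queries
  bySubject <- vector("list", length(sChar))
  for (i in seq_along(candidates)) {
    for (j in candidates[[i]]) {
      bySubject[[j]] <- c(bySubject[[j]], i)
    }
  }
  rows <- list()
  for (j in seq_along(bySubject)) {
    qs <- bySubject[[j]]
    if (is.null(qs)) next
    if (dropSelf) qs <- qs[qn[qs] != sn[j]]
    if (length(qs) == 0L) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(qChar[qs]), Biostrings::AAString(sChar[j]),
      type = "local", substitutionMatrix = .blosum62(),
      gapOpening = 11, gapExtension = 1)
    st <- .alignStats(aln, nchar(qChar[qs]))
    st$query <- qn[qs]
    st$subject <- sn[j]
    rows[[length(rows) + 1L]] <- st
  }
  if (length(rows) == 0L) {
    return(data.frame(query = character(), subject = character(),
                      identity = numeric(), query_coverage = numeric(),
                      simscore = numeric(), score = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$evalue <- NA_real_
  rownames(out) <- NULL
  out[c("query", "subject", "identity", "query_coverage", "simscore",
        "score", "evalue")]
}

#' Build the similarity graph for clustering
#'
#' Keeps edges with query coverage strictly above the threshold and e-value
#' at or below `evalueMax` (edges without an e-value, i.e. produced by the
#' in-package aligner, pass the e-value filter), drops self edges, and
#' symmetrises by keeping the maximum SimScore of the two directions.
#'
#' @param edges data.frame as returned by [similarityEdges()].
#' @param minQueryCoverage Coverage threshold (strict `>`).
#' @param evalueMax E-value cutoff.
#' @param vertices Optional character vector of vertex names to include even
#'   when isolated.
#' @return An undirected [igraph::igraph] with edge attribute `weight`
#'   (SimScore).
#' @export
buildSimilarityGraph <- function(edges, minQueryCoverage = 75,
                                 evalueMax = 1e-5, vertices = NULL) {
  keep <- edges$query_coverage > minQueryCoverage &
    (is.na(edges$evalue) | edges$evalue <= evalueMax) &
    edges$query != edges$subject
  e <- edges[keep, , drop = FALSE]
  if (nrow(e) > 0L) {
    a <- pmin(e$query, e$subject)
    b <- pmax(e$query, e$subject)
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -e$simscore)
    e <- data.frame(from = a, to = b, weight = e$simscore,
                    key = key, stringsAsFactors = FALSE)[ord, ]
    e <- e[!duplicated(e$key), c("from", "to", "weight")]
  } else {
    e <- data.frame(from = character(), to = character(),
                    weight = numeric(), stringsAsFactors = FALSE)
  }
  if (is.null(vertices)) {
    vertices <- unique(c(e$from, e$to))
  } else {
    vertices <- unique(c(vertices, e$from, e$to))
  }
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = vertices))
}

#' Markov clustering of a similarity graph
#'
#' Runs the Markov Cluster (MCL) iteration on the column-stochastic matrix
#' of the weighted graph with self-loops (each node's loop weight is its
#' maximum incident edge weight): expansion (matrix squaring), inflation
#' (entry-wise power followed by column renormalisation) and pruning of
#' entries below `prune`, until the largest entry change drops below `tol`.
#' Clusters are the connected components of the support of the limit
#' matrix; every node is assigned (isolated nodes become singletons).
#'
#' @param graph An [igraph::igraph] with `weight` edge attribute, or a
#'   non-negative adjacency matrix with dimnames.
#' @param inflation Inflation exponent (default 2, the algorithm's
#'   conventional default).
#' @param prune Entries below this value are zeroed each iteration.
#' @param maxIter Maximum number of iterations.
#' @param tol Convergence tolerance on the maximum entry change.
#' @return List with `membership` (named integer), `clusters` (list of
#'   member-id vectors), `iterations`, `converged`, and
#'   `colSumDeviation` (largest deviation of any column sum from 1 observed
#'   after renormalisation across all iterations).
#' @export
mclCluster <- function(graph, inflation = 2, prune = 1e-5,
                       maxIter = 100L, tol = 1e-8) {
  if (igraph::is_igraph(graph)) {
    A <- igraph::as_adjacency_matrix(graph, attr =
      if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL,
      sparse = FALSE)
  } else {
    A <- as.matrix(graph)
  }
  if (is.null(rownames(A))) {
    rownames(A) <- colnames(A) <- paste0("v", seq_len(nrow(A)))
  }
  if (any(A < 0)) stop("edge weights must be non-negative")
  n <- nrow(A)
  if (n == 0L) {
    return(list(membership = setNames(integer(), character()),
                clusters = list(), iterations = 0L, converged = TRUE,
                colSumDeviation = 0))
  }
  diag(A) <- 0
  loop <- apply(A, 2L, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  normalize <- function(M) sweep(M, 2L, colSums(M), "/")
  M <- normalize(A)
  colDev <- max(abs(colSums(M) - 1))
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- normalize(M2)
    M2[M2 < prune] <- 0
    zero <- colSums(M2) == 0
    if (any(zero)) M2[cbind(which(zero), which(zero))] <- 1
    M2 <- normalize(M2)
    colDev <- max(colDev, max(abs(colSums(M2) - 1)))
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", maxIter,
            " iterations; returning current interpretation")
  }
  supp <- (M > 0) | t(M > 0)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    supp, mode = "undirected", diag = FALSE))
  membership <- setNames(as.integer(comp$membership), rownames(A))
  clusters <- split(names(membership), membership)
  names(clusters) <- NULL
  list(membership = membership, clusters = clusters,
       iterations = iter, converged = converged,
       colSumDeviation = colDev)
}

#' Categorise protein clusters by member origin
#'
#' Labels each cluster `phage_only`, `bacteria_only` or `gene_sharing`
#' (containing both phage- and bacteria-encoded members), and reports the
#' fraction of phage proteins that sit inside gene-sharing clusters. When
#' similarity edges are supplied, the identity of each phage protein to its
#' best bacterial homolog is also returned.
#'
#' @param clusters List of member-id vectors (or the `clusters` element of
#'   [mclCluster()]).
#' @param origin Named character vector mapping protein id to `"phage"` or
#'   `"bacteria"`; every member must be labelled.
#' @param edges Optional data.frame of similarity edges for the identity
#'   distribution.
#' @return List with `category_counts`, `n_clusters`, `cluster_table`,
#'   `fraction_phage_in_sharing` and (with edges)
#'   `phage_best_bacterial_identity`.
#' @export
categorizeClusters <- function(clusters, origin, edges = NULL) {
  members <- unlist(clusters, use.names = FALSE)
  unlabeled <- setdiff(members, names(origin))
  if (length(unlabeled) > 0L) {
    stop("unlabeled member(s): ", paste(head(unlabeled, 3L), collapse = ", "))
  }
  category <- vapply(clusters, function(m) {
    o <- unique(origin[m])
    if (all(o == "phage")) "phage_only"
    else if (all(o == "bacteria")) "bacteria_only"
    else "gene_sharing"
  }, character(1))
  counts <- c(phage_only = sum(category == "phage_only"),
              bacteria_only = sum(category == "bacteria_only"),
              gene_sharing = sum(category == "gene_sharing"))
  phage <- names(origin)[origin == "phage"]
  phage <- intersect(phage, members)
  inSharing <- unlist(clusters[category == "gene_sharing"],
                      use.names = FALSE)
  frac <- if (length(phage) > 0L) {
    length(intersect(phage, inSharing)) / length(phage)
  } else {
    NA_real_
  }
  out <- list(
    category_counts = counts,
    n_clusters = length(clusters),
    cluster_table = data.frame(
      cluster_id = seq_along(clusters),
      size = lengths(clusters),
      category = category,
      stringsAsFactors = FALSE
    ),
    fraction_phage_in_sharing = frac
  )
  if (!is.null(edges)) {
    toBact <- edges[origin[edges$query] == "phage" &
                      origin[edges$subject] == "bacteria", , drop = FALSE]
    best <- vapply(split(toBact$identity, toBact$query), max, numeric(1))
    out$phage_best_bacterial_identity <- best
  }
  out
}
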