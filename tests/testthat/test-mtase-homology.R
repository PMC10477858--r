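test_that("MTase annotation applies the domain whitelist and e-value cutoff", {
  hits <- data.frame(
    protein_id = c("p1", "p2", "p3", "p4"),
    accession = c("COG0350", "pfam00001", "TIGR00589", "cd21179.smp"),
    evalue = c(1e-6, 1e-50, 1e-4, 1e-8))
  expect_identical(annotateMtases(hits), c("p1", "p4"))
  # monotone in the e-value cutoff
  loose <- annotateMtases(hits, evalueMax = 1e-3)
  expect_true(all(annotateMtases(hits) %in% loose))
  expect_identical(loose, c("p1", "p3", "p4"))
  # malformed rows are skipped with a warning
  bad <- rbind(hits, data.frame(protein_id = "p5", accession = "COG0350",
                                evalue = -1))
  expect_warning(res <- annotateMtases(bad), "malformed")
  expect_identical(res, c("p1", "p4"))
})

test_that("orphan classification picks best hits and bins by identity", {
  # the headline proportion: 3758 non-orphans among 4030 with hits
  ref <- data.frame(
    query = sprintf("q%04d", 1:4030),
    subject = "r1",
    identity = 95,
    evalue = 1e-20,
    subject_nonorphan = c(rep(TRUE, 3758), rep(FALSE, 272)))
  out <- classifyOrphan(ref, identityBins = 0)
  expect_identical(out$n_with_hit, 4030L)
  expect_equal(out$proportion_pct, 93.25, tolerance = 0.005)

  # best-hit selection: lowest e-value wins, ties by simscore then subject
  multi <- data.frame(
    query = "q1",
    subject = c("rOrphan", "rNon", "rAlt"),
    identity = c(99, 80, 80),
    simscore = c(50, 80, 70),
    evalue = c(1e-5, 1e-30, 1e-30),
    subject_nonorphan = c(FALSE, TRUE, TRUE))
  out2 <- classifyOrphan(multi, identityBins = c(0, 90))
  expect_identical(out2$n_nonorphan[out2$min_identity == 0], 1L)
  expect_identical(out2$n_with_hit[out2$min_identity == 90], 0L)
  # empty input yields empty bins without division by zero
  empty <- classifyOrphan(ref[0, ], identityBins = c(0, 50))
  expect_true(all(is.na(empty$proportion_pct)))
})

test_that("orphan classification matches enumeration on a planted fixture", {
  set.seed(33)
  n <- 200
  ref <- data.frame(
    query = sprintf("q%03d", 1:n),
    subject = sprintf("r%03d", 1:n),
    identity = runif(n, 40, 100),
    evalue = 10^-runif(n, 6, 40),
    subject_nonorphan = runif(n) < 0.8)
  out <- classifyOrphan(ref, identityBins = c(0, 50, 90))
  for (b in c(0, 50, 90)) {
    sel <- ref$identity >= b
    expect_identical(out$n_with_hit[out$min_identity == b],
                     as.integer(sum(sel)))
    expect_identical(out$n_nonorphan[out$min_identity == b],
                     as.integer(sum(sel & ref$subject_nonorphan)))
  }
})

test_that("hypergeometric enrichment is exact", {
  e <- orphanEnrichment(3, 3, 3, 6)
  expect_equal(e$p_hypergeometric, 1 / 20, tolerance = 1e-12)
  # equal proportions: chi-square statistic 0, p = 1
  eq <- orphanEnrichment(10, 20, 100, 200)
  expect_equal(eq$chisq_statistic, 0)
  expect_equal(eq$p_chisq, 1)
  expect_error(orphanEnrichment(5, 3, 10, 20), "invalid")
  # the 2x2 statistic matches the standard implementation without correction
  ref <- suppressWarnings(chisq.test(rbind(c(30, 20), c(40, 60)),
                                     correct = FALSE))
  got <- orphanEnrichment(30, 50, 40, 100)
  expect_equal(got$chisq_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_chisq, ref$p.value, tolerance = 1e-12)
  # random sample against the combinatorial-sum oracle
  set.seed(44)
  for (i in 1:50) {
    N <- sample(5:30, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(orphanEnrichment(k, n, K, N)$p_hypergeometric,
                 oracleHyperUpper(k, n, K, N), tolerance = 1e-12)
  }
})

test_that("local alignment recovers identity and coverage of planted pairs", {
  a <- randomProtein(100, seed = 51)
  self <- alignProteins(a, a)
  expect_equal(self$identity, 100)
  expect_equal(self$query_coverage, 100)
  expect_equal(self$simscore, 100)
  # ten interior substitutions: identity 90 +/- 1, full coverage
  res <- strsplit(a, "")[[1]]
  set.seed(52)
  pos <- sample(10:90, 10)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  for (p in pos) res[p] <- sample(setdiff(aa, res[p]), 1)
  b <- paste(res, collapse = "")
  mut <- alignProteins(a, b)
  expect_lt(abs(mut$identity - 90), 1)
  expect_equal(mut$query_coverage, 100)
  expect_error(alignProteins("", a), "empty")
})

test_that("unrelated random proteins do not score above the shuffled null", {
  a <- randomProtein(120, seed = 61)
  b <- randomProtein(120, seed = 62)
  observed <- alignProteins(a, b)$score
  set.seed(63)
  null <- replicate(50, {
    shuf <- paste(sample(strsplit(b, "")[[1]]), collapse = "")
    alignProteins(a, shuf)$score
  })
  expect_lte(observed, max(null) + 5)
  # and the seeded edge search yields no edge for them
  qs <- Biostrings::AAStringSet(c(qa = a))
  ss <- Biostrings::AAStringSet(c(sb = b))
  expect_identical(nrow(similarityEdges(qs, ss)), 0L)
})

test_that("seeded edge search finds planted homologs at their identity", {
  parent <- randomProtein(150, seed = 71)
  child <- evolveProtein(parent, 0.9, seed = 72)
  qs <- Biostrings::AAStringSet(c(p1 = parent))
  ss <- Biostrings::AAStringSet(c(c1 = child, r1 = randomProtein(150,
                                                                 seed = 73)))
  edges <- similarityEdges(qs, ss)
  expect_identical(edges$subject, "c1")
  expect_lt(abs(edges$identity - 90), 2)
})

test_that("similarity graph filtering and symmetrisation follow the rules", {
  edges <- data.frame(
    query = c("a", "b", "a", "c"),
    subject = c("b", "a", "c", "c"),
    identity = c(95, 95, 80, 100),
    query_coverage = c(90, 80, 75, 99),  # a->c at exactly 75 must drop
    simscore = c(85.5, 76, 60, 99),
    score = 1, evalue = NA_real_)
  g <- buildSimilarityGraph(edges)
  expect_identical(sort(igraph::V(g)$name), c("a", "b"))
  expect_equal(igraph::ecount(g), 1)
  # symmetrised weight is the maximum of the two directions
  expect_equal(igraph::E(g)$weight, 85.5)
  # the coverage comparator is strict; self edges are dropped
  empty <- buildSimilarityGraph(edges[3:4, ])
  expect_equal(igraph::ecount(empty), 0)
  e0 <- buildSimilarityGraph(edges[0, ], vertices = c("x", "y"))
  expect_equal(igraph::vcount(e0), 2)
  # a real e-value above the cutoff is filtered
  evEdge <- data.frame(query = "a", subject = "b", identity = 90,
                       query_coverage = 99, simscore = 89, score = 1,
                       evalue = 1e-3)
  expect_equal(igraph::ecount(buildSimilarityGraph(evEdge)), 0)
})

test_that("MCL splits structure and respects graph components", {
  # two disjoint triangles
  tri <- igraph::graph_from_edgelist(rbind(
    c("a1", "a2"), c("a2", "a3"), c("a1", "a3"),
    c("b1", "b2"), c("b2", "b3"), c("b1", "b3")), directed = FALSE)
  igraph::E(tri)$weight <- 1
  res <- mclCluster(tri)
  expect_identical(length(res$clusters), 2L)
  expect_setequal(lengths(res$clusters), c(3L, 3L))
  # isolated node becomes a singleton and output partitions all nodes
  iso <- igraph::add_vertices(tri, 1, name = "solo")
  resIso <- mclCluster(iso)
  expect_identical(sort(unlist(resIso$clusters)),
                   sort(igraph::V(iso)$name))
  expect_true("solo" %in% unlist(resIso$clusters[lengths(resIso$clusters) == 1]))
  # clusters never span connected components
  comp <- igraph::components(iso)$membership
  for (cl in resIso$clusters) {
    expect_identical(length(unique(comp[cl])), 1L)
  }
  expect_lte(res$colSumDeviation, 1e-9)
})

test_that("MCL agrees with a hand-coded dense-matrix oracle on the bridge fixture", {
  # two 4-cliques joined by a single weak bridge
  A <- matrix(0, 8, 8, dimnames = list(paste0("n", 1:8), paste0("n", 1:8)))
  for (i in 1:4) for (j in 1:4) if (i != j) A[i, j] <- 1
  for (i in 5:8) for (j in 5:8) if (i != j) A[i, j] <- 1
  A[4, 5] <- A[5, 4] <- 0.1
  res <- mclCluster(A, inflation = 2)
  expect_identical(length(res$clusters), 2L)
  expect_setequal(vapply(res$clusters, length, integer(1)), c(4L, 4L))
  oracle <- oracleMcl(A)
  expect_equal(randIndex(res$membership[paste0("n", 1:8)],
                         oracle[paste0("n", 1:8)]), 1)
})

test_that("cluster categorisation counts origins and gene sharing", {
  clusters <- list(c("p1", "p2"), c("b1", "b2"), c("p3", "b3"), "b4")
  origin <- c(p1 = "phage", p2 = "phage", p3 = "phage",
              b1 = "bacteria", b2 = "bacteria", b3 = "bacteria",
              b4 = "bacteria")
  res <- categorizeClusters(clusters, origin)
  expect_identical(unname(res$category_counts),
                   c(1L, 2L, 1L))
  expect_identical(sum(res$category_counts), res$n_clusters)
  expect_equal(res$fraction_phage_in_sharing, 1 / 3)
  # all-phage input has no gene-sharing clusters
  allPhage <- categorizeClusters(list(c("p1", "p2")), origin)
  expect_identical(unname(allPhage$category_counts["gene_sharing"]), 0L)
  expect_error(categorizeClusters(list("zz"), origin), "unlabeled")
})

test_that("planted homology clusters are recovered from the community", {
  cm <- smallCommunity(seed = 3)
  prot <- c(phageProteins(cm), bacterialProteins(cm))
  edges <- similarityEdges(prot, prot)
  g <- buildSimilarityGraph(edges, vertices = names(prot))
  res <- mclCluster(g)
  truth <- plantedTruth(cm)$planted_cluster_ids
  ids <- intersect(names(res$membership), names(truth))
  expect_gte(randIndex(res$membership[ids], truth[ids]), 0.95)
  org <- proteinOrigin(cm)
  cat3 <- categorizeClusters(res$clusters,
                             setNames(org$origin, org$protein_id),
                             edges = edges)
  expect_identical(sum(cat3$category_counts), cat3$n_clusters)
  # linked phages share >90%-identity homology with bacterial proteins
  expect_gte(median(cat3$phage_best_bacterial_identity), 90)
})
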