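test_that("genome generation respects composition and determinism", {
  g0 <- generateGenome(40, gc = 0, seed = 1)
  expect_true(all(strsplit(as.character(g0), "")[[1]] %in% c("A", "T")))
  g1 <- generateGenome(10000, gc = 0.5, seed = 3)
  gcObs <- sum(Biostrings::letterFrequency(g1, c("G", "C"))) / 10000
  expect_gte(gcObs, 0.45)
  expect_lte(gcObs, 0.55)
  expect_identical(as.character(generateGenome(500, 0.4, seed = 9)),
                   as.character(generateGenome(500, 0.4, seed = 9)))
  expect_error(generateGenome(0, 0.5), "positive")
  expect_error(generateGenome(10, 1.5), "\\[0,1\\]")
})

test_that("CDS planting yields disjoint in-bounds intervals at target coverage", {
  expect_identical(nrow(plantCds(1000, 0)), 0L)
  cds <- plantCds(1000, 3, seed = 2)
  expect_identical(nrow(cds), 3L)
  expect_true(all(cds$start >= 1 & cds$end <= 1000))
  ir <- IRanges::IRanges(cds$start, cds$end)
  expect_identical(length(IRanges::reduce(ir)), 3L)  # no merging => disjoint
  # coverage close to target
  cds2 <- plantCds(20000, 15, targetCoverage = 0.7, seed = 4)
  cov <- sum(cds2$end - cds2$start + 1) / 20000
  expect_lt(abs(cov - 0.7), 0.05)
  expect_error(plantCds(1000, 10, minLen = 200), "infeasible")
})

test_that("planted methylation sites sit inside motif occurrences at target density", {
  set.seed(31)
  g <- generateGenome(20000, 0.5, seed = 31)
  motifs <- defaultMotifSet()
  target <- c(m6A = 0.008, m4C = 0.006)
  sites <- plantMethylation(g, motifs, target, seed = 5)
  expect_true(all(sites$mod_type %in% c("m6A", "m4C")))
  # consistency: every site is at the methylated index of an occurrence of
  # its recorded motif (re-scan oracle)
  for (tp in c("m6A", "m4C")) {
    sel <- sites[sites$mod_type == tp, ]
    for (m in motifs) {
      if (m@modType != tp) next
      occ <- scanMotif(g, m@pattern, bothStrands = TRUE,
                       methylatedIndex = m@methylatedIndex)
      sub <- sel[sel$motif == m@pattern, ]
      if (nrow(sub) == 0) next
      expect_true(all(paste(sub$position, sub$strand) %in%
                        paste(occ$meth_pos, occ$strand)))
    }
  }
  # realized density within 10% relative of target
  freq <- Biostrings::letterFrequency(g, c("A", "C", "G", "T"))
  dens6 <- sum(sites$mod_type == "m6A") / (freq[["A"]] + freq[["T"]])
  dens4 <- sum(sites$mod_type == "m4C") / (freq[["C"]] + freq[["G"]])
  expect_lt(abs(dens6 - target[["m6A"]]) / target[["m6A"]], 0.1)
  expect_lt(abs(dens4 - target[["m4C"]]) / target[["m4C"]], 0.1)
})

test_that("methylation planting handles zero targets and missing motifs", {
  g <- generateGenome(5000, 0.5, seed = 8)
  none <- plantMethylation(g, defaultMotifSet(), c(m6A = 0, m4C = 0))
  expect_identical(nrow(none), 0L)
  # a genome with no occurrence of the only requested motif
  gAT <- Biostrings::DNAString(strrep("AT", 200))
  rareMotif <- list(IupacMotif("GGAGG", 3, "m6A"))
  expect_warning(
    out <- plantMethylation(gAT, rareMotif, c(m6A = 0.5)),
    "no occurrence")
  expect_identical(nrow(out), 0L)
  # unreachable density warns and emits the maximum achievable
  expect_warning(
    capped <- plantMethylation(g, defaultMotifSet(), c(m6A = 0.9)),
    "unreachable")
  expect_gt(nrow(capped), 0)
})

test_that("protein evolution applies exactly the requested substitutions", {
  parent <- randomProtein(100, seed = 12)
  expect_identical(evolveProtein(parent, 1.0), parent)
  child <- evolveProtein(parent, 0.90, seed = 13)
  a <- strsplit(parent, "")[[1]]
  b <- strsplit(child, "")[[1]]
  expect_identical(sum(a != b), 10L)
  # substituted residues never equal the original
  expect_true(all(b[a != b] != a[a != b]))
  expect_error(evolveProtein(parent, 0), "\\(0, 1\\]")
  expect_error(evolveProtein("AC", 0.1), "floor")
})

test_that("taxonomy generation builds a uniform-depth rooted tree", {
  t1 <- generateTaxonomy(1, 1, 1)
  expect_identical(t1$rank, c("root", "family", "genus", "species"))
  tx <- generateTaxonomy(20, 6, 2, seed = 3)
  parent <- setNames(tx$parent, tx$node)
  depth <- function(node) {
    d <- 0
    while (!is.na(parent[[node]])) { node <- parent[[node]]; d <- d + 1 }
    d
  }
  depths <- vapply(tx$node[tx$rank == "species"], depth, numeric(1))
  expect_true(all(depths == 3))
  # every species has exactly one genus and family above it
  expect_true(all(tx$parent[tx$rank == "species"] %in%
                    tx$node[tx$rank == "genus"]))
  expect_error(generateTaxonomy(2, 3, 1), ">=")
})

test_that("abundance model couples prevalence to density and is self-consistent", {
  lens <- setNames(rep(20000, 200), sprintf("g%03d", 1:200))
  set.seed(21)
  dens <- runif(200, 0.001, 0.02)
  names(dens) <- names(lens)
  ab <- generateAbundance(lens, dens, nSamples = 60, coupling = 0.8,
                          seed = 22)
  expect_true(all(ab$counts >= 0))
  expect_true(all(ab$counts == round(ab$counts)))
  # emitted RPKM is exactly recomputable from counts
  recomputed <- computeRpkm(
    ab$counts,
    matrix(lens, nrow = 200, ncol = 60),
    matrix(ab$librarySizes, nrow = 200, ncol = 60, byrow = TRUE))
  expect_equal(unname(ab$rpkm), unname(recomputed), tolerance = 1e-12)
  # positive partial correlation at coupling 0.8
  prev <- prevalence(ab$rpkm)
  pc <- partialPearson(prev, dens, ab$depth)
  expect_gt(pc$estimate, 0)
  expect_lt(pc$p.value, 0.05)
  # coupling 0 leaves prevalence independent of density
  ab0 <- generateAbundance(lens, dens, nSamples = 60, coupling = 0,
                           seed = 23)
  pc0 <- partialPearson(prevalence(ab0$rpkm), dens, ab0$depth)
  expect_lt(abs(pc0$estimate), 0.2)
})

test_that("host-link generation plants MTase homology at the target identity", {
  cfg <- CommunityConfig(nPhages = 1, nBacteria = 1, linkedFraction = 1)
  links <- generateHostLinks(cfg, "phage_001", "bact_001", seed = 3)
  expect_identical(links$goldPairs$phage_id, "phage_001")
  ph <- as.character(links$phageProteins)
  expect_length(ph, 2L)
  for (id in names(ph)) {
    k <- sub(".*_mt", "", id)
    parent <- as.character(links$bacterialProteins[[paste0("bact_001_mt", k)]])
    a <- strsplit(parent, "")[[1]]
    b <- strsplit(ph[[id]], "")[[1]]
    ident <- mean(a == b)
    expect_lt(abs(ident - 0.95), 0.011)  # within one percentage point
  }
  # no links => empty gold standard
  cfg0 <- CommunityConfig(nPhages = 2, nBacteria = 2, linkedFraction = 0)
  links0 <- generateHostLinks(cfg0, c("p1", "p2"), c("b1", "b2"), seed = 4)
  expect_identical(nrow(links0$goldPairs), 0L)
})

test_that("recognition evidence drives the voting rule at the planted labels", {
  ids <- sprintf("c%03d", 1:200)
  lens <- rep(30000, 200)
  labels <- rep(c(TRUE, FALSE), each = 100)
  ev <- generateRecognitionEvidence(ids, lens, labels, sensitivity = 0.95,
                                    seed = 6)
  calls <- classifyViral(ev)
  expect_gte(mean(calls$is_virus[labels]), 0.90)
  expect_gte(mean(!calls$is_virus[!labels]), 0.95)
  # all-negative labels yield no planted virals
  ev0 <- generateRecognitionEvidence(ids[1:10], lens[1:10], rep(FALSE, 10),
                                     seed = 7)
  expect_true(all(!ev0$planted_viral))
  # reproducibility
  ev2 <- generateRecognitionEvidence(ids, lens, labels, sensitivity = 0.95,
                                     seed = 6)
  expect_identical(ev, ev2)
})

test_that("community simulation is deterministic for a fixed config and seed", {
  cm1 <- smallCommunity(seed = 19)
  cm2 <- smallCommunity(seed = 19)
  d1 <- file.path(tempdir(), "comm1")
  d2 <- file.path(tempdir(), "comm2")
  writeCommunity(cm1, d1)
  writeCommunity(cm2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
  # a different seed changes the community
  cm3 <- smallCommunity(seed = 20)
  expect_false(identical(as.character(genomes(cm1)),
                         as.character(genomes(cm3))))
})
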