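mkSites <- function(pos, strand, type, seqname = "g") {
  GenomicRanges::GRanges(
    seqnames = rep(seqname, length(pos)),
    ranges = IRanges::IRanges(pos, width = 1L),
    strand = strand,
    mod_type = type)
}

test_that("methylation density counts distinct sites over both-strand bases", {
  # "AACC": two adenines on the forward strand, none on the reverse
  s <- mkSites(1, "+", "m6A")
  expect_equal(methylationDensity(s, "AACC", "m6A"), 0.5)
  expect_equal(methylationDensity(mkSites(integer(), character(),
                                          character()), "AACC", "m6A"), 0)
  # every adenine of both strands methylated ("AT": one A forward at 1,
  # one A reverse at 2)
  full <- mkSites(c(1, 2), c("+", "-"), c("m6A", "m6A"))
  expect_equal(methylationDensity(full, "AT", "m6A"), 1.0)
  # duplicate (position, strand) records count once
  dup <- mkSites(c(1, 1), c("+", "+"), c("m6A", "m6A"))
  expect_equal(methylationDensity(dup, "AACC", "m6A"), 0.5)
})

test_that("density validates site bases and handles empty denominators", {
  # an m6A call on a C is inconsistent
  bad <- mkSites(3, "+", "m6A")
  expect_error(methylationDensity(bad, "AACC", "m6A"), "mismatch")
  # m4C on the minus strand sits on a forward G
  okMinus <- mkSites(1, "-", "m4C")
  expect_silent(d <- methylationDensity(okMinus, "GGGG", "m4C"))
  expect_equal(d, 0.25)
  expect_warning(d0 <- methylationDensity(
    mkSites(integer(), character(), character()), "GGCC", "m6A"),
    "no target base")
  expect_equal(d0, 0)
})

test_that("region split is exact against per-position brute force", {
  set.seed(77)
  for (rep in 1:5) {
    g <- generateGenome(300, 0.5, seed = 700 + rep)
    # on a 300 bp genome the 5% targets exceed the motif occurrences, so the
    # planter warns and emits every occurrence; that maximal set is what the
    # brute-force comparison wants
    sites <- suppressWarnings(
      plantMethylation(g, defaultMotifSet(), c(m6A = 0.05, m4C = 0.05),
                       seed = 800 + rep))
    gr <- mkSites(sites$position, sites$strand, sites$mod_type)
    cds <- IRanges::IRanges(c(20, 150), c(90, 230))
    rs <- regionSplit(gr, cds, g)
    chars <- strsplit(as.character(g), "")[[1]]
    coding <- rep(FALSE, 300)
    coding[c(20:90, 150:230)] <- TRUE
    for (tp in c("m6A", "m4C")) {
      letters <- if (tp == "m6A") c("A", "T") else c("C", "G")
      sel <- sites[sites$mod_type == tp, ]
      inCds <- coding[sel$position]
      row <- rs[rs$mod_type == tp, ]
      expect_equal(row$coding_density,
                   sum(inCds) / sum(chars[coding] %in% letters))
      expect_equal(row$noncoding_density,
                   sum(!inCds) / sum(chars[!coding] %in% letters))
      # conservation of sites and the weighted-density identity
      expect_identical(row$coding_sites + row$noncoding_sites,
                       as.integer(nrow(sel)))
      whole <- methylationDensity(gr, g, tp)
      weighted <- (row$coding_density * row$coding_bases +
                     row$noncoding_density * row$noncoding_bases) /
        (row$coding_bases + row$noncoding_bases)
      expect_equal(whole, weighted, tolerance = 1e-12)
    }
  }
})

test_that("region split degenerate cases behave as documented", {
  g <- "AAAATTTT"
  s <- mkSites(c(2, 3), c("+", "+"), c("m6A", "m6A"))
  # all sites inside the single CDS
  rs <- regionSplit(s, IRanges::IRanges(1, 4), g)
  expect_equal(rs$noncoding_density[rs$mod_type == "m6A"], 0)
  # CDS covering the whole genome reproduces the genome-wide density
  rsFull <- regionSplit(s, IRanges::IRanges(1, 8), g)
  expect_equal(rsFull$coding_density[rsFull$mod_type == "m6A"],
               methylationDensity(s, g, "m6A"))
  expect_error(regionSplit(s, IRanges::IRanges(1, 99), g), "outside")
})

test_that("per-CDS summaries match hand counts", {
  cds <- IRanges::IRanges(c(1, 11, 21), c(10, 20, 30))
  s <- mkSites(c(2, 5, 12), c("+", "+", "+"), rep("m6A", 3))
  cs <- cdsSummary(s, cds)
  expect_equal(cs$fraction_methylated[["m6A"]], 2 / 3)
  expect_equal(cs$fraction_methylated[["m4C"]], 0)
  expect_equal(cs$ratios[, "m6A"], c(2 / 10, 1 / 10, 0))
  # genome-length denominator variant
  csG <- cdsSummary(s, cds, perGenomeLength = TRUE, genomeLength = 100)
  expect_equal(csG$ratios[, "m6A"], c(2, 1, 0) / 100)
  # two CDSs, sites only in the first
  half <- cdsSummary(mkSites(2, "+", "m6A"),
                     IRanges::IRanges(c(1, 11), c(10, 20)))
  expect_equal(half$fraction_methylated[["m6A"]], 0.5)
  none <- cdsSummary(mkSites(integer(), character(), character()), cds)
  expect_equal(none$fraction_methylated[["m6A"]], 0)
  expect_true(all(none$ratios == 0))
})

test_that("functional methylation rates aggregate per category and genome", {
  cds <- GenomicRanges::GRanges(
    seqnames = c("g1", "g1", "g2", "g2", "g3", "g4"),
    ranges = IRanges::IRanges(c(1, 100, 1, 100, 1, 1),
                              c(50, 150, 50, 150, 50, 50)),
    strand = "+",
    category = c("tRNA", "Lysis", "tRNA", "hypothetical", "Lysis", "tRNA"))
  sites <- GenomicRanges::GRanges(
    seqnames = c("g1", "g2", "g3"),
    ranges = IRanges::IRanges(c(10, 120, 20), width = 1),
    strand = "+",
    mod_type = "m6A")
  fr <- functionalRates(cds, sites)
  m6 <- fr[fr$mod_type == "m6A", ]
  get <- function(cat, col) m6[[col]][m6$category == cat]
  # tRNA present in g1, g2, g4; methylated in g1 only
  expect_identical(get("tRNA", "n_genomes"), 3L)
  expect_equal(get("tRNA", "fraction"), 1 / 3)
  # Lysis present in g1, g3; methylated in g3 only
  expect_equal(get("Lysis", "fraction"), 1 / 2)
  # hypothetical present only in g2; its site at 120 is inside the interval
  expect_equal(get("hypothetical", "fraction"), 1)
  # absent categories are excluded
  expect_false("Assembly" %in% fr$category)
  # single genome, tRNA with one site
  one <- functionalRates(cds[1], sites[1])
  expect_equal(one$fraction[one$category == "tRNA" &
                              one$mod_type == "m6A"], 1)
})

test_that("RPKM is the standard per-kilobase per-million normalisation", {
  expect_equal(computeRpkm(1000, 10000, 1e6), 100)
  expect_equal(computeRpkm(0, 5000, 1e6), 0)
  expect_equal(computeRpkm(2000, 10000, 1e6),
               2 * computeRpkm(1000, 10000, 1e6))
  expect_error(computeRpkm(10, 0, 1e6), "positive")
  expect_error(computeRpkm(10, 1000, 0), "positive")
})

test_that("prevalence counts samples at or above the threshold", {
  m <- rbind(a = c(0.4, 0.4, 0.4), b = c(0.5, 0.2, 7), c = c(6, 6, 6))
  p <- prevalence(m)
  expect_identical(unname(p), c(0, 2, 3))
  # value exactly at the threshold counts as present
  expect_identical(unname(prevalence(rbind(x = 0.5))), 1)
  # monotone non-increasing in the threshold (sensitivity mode up to 5)
  for (th in c(0.5, 1, 2, 5)) {
    expect_true(all(prevalence(m, th) >= prevalence(m, th + 0.5)))
  }
})

test_that("partial correlation equals the residual-correlation oracle", {
  set.seed(12)
  for (i in 1:100) {
    x <- rnorm(30); z <- rnorm(30)
    y <- 0.5 * x + 0.3 * z + rnorm(30)
    pc <- partialPearson(x, y, z)
    expect_equal(pc$estimate, oraclePartial(x, y, z), tolerance = 1e-10)
  }
  # constant control reduces to the plain Pearson correlation
  x <- rnorm(20); y <- rnorm(20)
  pc <- partialPearson(x, y, rep(3, 20))
  expect_equal(pc$estimate, cor(x, y), tolerance = 1e-12)
  # x identical to the control is degenerate
  expect_error(partialPearson(x, y, x), "variance")
})

test_that("partial correlation is symmetric and affine-invariant", {
  set.seed(13)
  x <- rnorm(40); y <- rnorm(40); z <- rnorm(40)
  a <- partialPearson(x, y, z)
  b <- partialPearson(y, x, z)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  shifted <- partialPearson(3 * x + 1, -2 * y + 5, 0.5 * z - 7)
  expect_equal(abs(shifted$estimate), abs(a$estimate), tolerance = 1e-12)
  expect_equal(shifted$p.value, a$p.value, tolerance = 1e-10)
})

test_that("residualization matches the normal equations", {
  z <- c(1, 2, 3, 4, 5)
  v <- 2 * z + 1
  expect_equal(residualize(v, z), rep(0, 5), tolerance = 1e-12)
  set.seed(14)
  v2 <- rnorm(50); z2 <- rnorm(50)
  r <- residualize(v2, z2)
  expect_equal(mean(r), 0, tolerance = 1e-10)
  expect_equal(sum(r * z2), 0, tolerance = 1e-8)
  X <- cbind(1, z2)
  beta <- solve(t(X) %*% X, t(X) %*% v2)
  expect_equal(r, as.numeric(v2 - X %*% beta), tolerance = 1e-10)
  # constant covariate: mean-centred response
  expect_equal(residualize(v2, rep(1, 50)), v2 - mean(v2))
})

test_that("rarefaction is exact at full depth and matches tiny enumeration", {
  records <- data.frame(
    sample = c("s1", "s1", "s2", "s2"),
    genome = "g",
    position = c(1, 2, 1, 3))
  rc <- rarefactionCurve(records, c(0.5, 1), reps = 4000, seed = 1)
  expect_equal(rc$mean_unique[rc$fraction == 1], 3)
  # enumeration over all C(4,2) = 6 subsamples of size 2
  combos <- combn(4, 2)
  key <- paste(records$genome, records$position)
  exact <- mean(apply(combos, 2, function(ix) length(unique(key[ix]))))
  expect_lt(abs(rc$mean_unique[rc$fraction == 0.5] - exact), 0.05)
  # monotone non-decreasing means on a larger record set
  set.seed(15)
  big <- data.frame(sample = sample(letters[1:5], 400, TRUE),
                    genome = sample(c("g1", "g2"), 400, TRUE),
                    position = sample(1:120, 400, TRUE))
  curve <- rarefactionCurve(big, c(0.2, 0.4, 0.6, 0.8, 1), reps = 50,
                            seed = 2)
  expect_true(all(diff(curve$mean_unique) >= 0))
  expect_error(rarefactionCurve(big, c(0, 0.5)), "\\(0, 1\\]")
})
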