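# bitmask encoding of the IUPAC nucleotide alphabet: A=1, C=2, G=4, T=8
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

.patternBits <- function(pattern) {
  sym <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(sym, names(.IUPAC_BITS))
  if (length(bad) > 0) {
    stop("unknown IUPAC symbol(s): ", paste(unique(bad), collapse = ", "))
  }
  .IUPAC_BITS[sym]
}

#' Base set of an IUPAC nucleotide symbol
#'
#' Expands a single degenerate nucleotide code into the set of concrete
#' bases it stands for (e.g. `K` -> G,T; `N` -> A,C,G,T).
#'
#' @param symbol A single character from the IUPAC nucleotide alphabet.
#' @return Character vector of bases from `c("A","C","G","T")`.
#' @examples
#' iupacSet("K")
#' iupacSet("N")
#' @export
iupacSet <- function(symbol) {
  if (!is.character(symbol) || length(symbol) != 1L || nchar(symbol) != 1L) {
    stop("'symbol' must be a single character")
  }
  bits <- .patternBits(symbol)
  c("A", "C", "G", "T")[bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0L]
}

#' Reverse complement of an IUPAC pattern
#'
#' @param pattern Degenerate nucleotide pattern.
#' @return The reverse-complement pattern, degenerate codes included.
#' @export
reverseComplementPattern <- function(pattern) {
  sym <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(sym, names(.IUPAC_COMPLEMENT))
  if (length(bad) > 0) {
    stop("unknown IUPAC symbol(s): ", paste(unique(bad), collapse = ", "))
  }
  paste(rev(.IUPAC_COMPLEMENT[sym]), collapse = "")
}

# TRUE iff some window of `long` is position-wise subsumed by `short`,
# i.e. every base compatible with the window symbol is also compatible with
# the corresponding symbol of `short` (the window is "one of the
# possibilities" of `short`). Requires nchar(long) >= nchar(short).
.windowSubsumed <- function(longBits, shortBits) {
  nl <- length(longBits)
  ns <- length(shortBits)
  if (nl < ns) return(FALSE)
  for (o in 0:(nl - ns)) {
    w <- longBits[(o + 1L):(o + ns)]
    if (all(bitwAnd(w, shortBits) == w)) return(TRUE)
  }
  FALSE
}

#' Test whether two degenerate motifs overlap
#'
#' Two motifs overlap when the more specific one (the longer pattern, or for
#' equal lengths the pattern with the narrower base sets) is one of the
#' sequence possibilities of the more general one: some window of the longer
#' pattern is position-wise subsumed by the shorter pattern. For example
#' `AKCTCG` is overlapped by `BCNC` because its window `KCTC` is one of the
#' possibilities of `BCNC`. Equal-length patterns are tested in both subset
#' directions.
#'
#' @param candidate,reference Degenerate nucleotide patterns.
#' @param checkRevcomp If `TRUE`, the reverse complement of `candidate` is
#'   also tested against `reference`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' motifOverlapped("AKCTCG", "BCNC")  # TRUE
#' motifOverlapped("AKCTCG", "CCCC")  # FALSE
#' @export
motifOverlapped <- function(candidate, reference, checkRevcomp = FALSE) {
  if (!nzchar(candidate) || !nzchar(reference)) {
    stop("patterns must be non-empty")
  }
  test1 <- function(a, b) {
    ab <- .patternBits(a)
    bb <- .patternBits(b)
    if (length(ab) == length(bb)) {
      .windowSubsumed(ab, bb) || .windowSubsumed(bb, ab)
    } else if (length(ab) > length(bb)) {
      .windowSubsumed(ab, bb)
    } else {
      .windowSubsumed(bb, ab)
    }
  }
  out <- test1(candidate, reference)
  if (!out && isTRUE(checkRevcomp)) {
    out <- test1(reverseComplementPattern(candidate), reference)
  }
  out
}

# TRUE iff pattern x is redundant with respect to pattern y: x is one of the
# possibilities of y (x at least as long, some window of x subsumed by y).
.motifRedundantTo <- function(x, y) {
  xb <- .patternBits(x)
  yb <- .patternBits(y)
  if (length(xb) < length(yb)) return(FALSE)
  .windowSubsumed(xb, yb)
}

#' Dereplicate a set of degenerate motifs
#'
#' Removes motifs that are sequence possibilities of a more general motif of
#' the same modification type, iterating to a fixed point. When two patterns
#' mutually subsume each other (equivalent patterns) the lexicographically
#' smaller one is kept. The result is a subset of the input in which no two
#' retained motifs of the same type overlap, and the operation is idempotent.
#'
#' @param patterns Character vector of degenerate patterns.
#' @param modType Optional parallel vector of modification types
#'   (`"m6A"`/`"m4C"`); only motifs of the same type compete. `NULL` treats
#'   all motifs as one group.
#' @return Character vector of retained patterns (a subset of `patterns`).
#' @examples
#' dereplicateMotifs(c("AKCTCG", "BCNC"))  # "BCNC"
#' @export
dereplicateMotifs <- function(patterns, modType = NULL) {
  patterns <- as.character(patterns)
  if (length(patterns) == 0L) return(character())
  if (is.null(modType)) modType <- rep("all", length(patterns))
  if (length(modType) != length(patterns)) {
    stop("'modType' must parallel 'patterns'")
  }
  keep <- !duplicated(paste(modType, toupper(patterns)))
  repeat {
    changed <- FALSE
    idx <- which(keep)
    for (i in idx) {
      if (!keep[i]) next
      for (j in which(keep)) {
        if (i == j || modType[i] != modType[j]) next
        iRj <- .motifRedundantTo(patterns[i], patterns[j])
        jRi <- .motifRedundantTo(patterns[j], patterns[i])
        if (iRj && jRi) {
          # equivalent patterns: keep the lexicographically smaller
          drop <- if (toupper(patterns[i]) > toupper(patterns[j])) i else j
          keep[drop] <- FALSE
          changed <- changed || TRUE
        } else if (iRj) {
          keep[i] <- FALSE
          changed <- TRUE
          break
        } else if (jRi) {
          keep[j] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  patterns[keep]
}

#' Scan a sequence for occurrences of a degenerate motif
#'
#' Matches are found with [Biostrings::matchPattern()] treating degenerate
#' codes in the pattern as base sets and the subject as literal. Minus-strand
#' occurrences are matches of the reverse-complement pattern, reported in
#' forward coordinates.
#'
#' @param sequence A [Biostrings::DNAString] or single character string.
#' @param pattern Degenerate nucleotide pattern.
#' @param bothStrands Scan the reverse complement too?
#' @param methylatedIndex Optional 1-based index of the methylated base
#'   within the pattern; when given, the forward-coordinate position of that
#'   base is reported for each occurrence.
#' @return A `data.frame` with columns `start` (1-based start of the match in
#'   forward coordinates), `strand`, and `meth_pos` when `methylatedIndex`
#'   is given.
#' @examples
#' scanMotif("ACGTACGT", "ACGT")
#' @export
scanMotif <- function(sequence, pattern, bothStrands = FALSE,
                      methylatedIndex = NULL) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  pattern <- toupper(pattern)
  k <- nchar(pattern)
  if (length(sequence) < k) {
    stop("sequence shorter than pattern")
  }
  fwd <- Biostrings::matchPattern(pattern, sequence, fixed = "subject")
  out <- data.frame(
    start = BiocGenerics::start(fwd),
    strand = rep("+", length(fwd)),
    stringsAsFactors = FALSE
  )
  if (isTRUE(bothStrands)) {
    rcpat <- reverseComplementPattern(pattern)
    rev <- Biostrings::matchPattern(rcpat, sequence, fixed = "subject")
    out <- rbind(out, data.frame(
      start = BiocGenerics::start(rev),
      strand = rep("-", length(rev)),
      stringsAsFactors = FALSE
    ))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(methylatedIndex)) {
    mi <- as.integer(methylatedIndex)
    if (mi < 1L || mi > k) stop("'methylatedIndex' outside pattern")
    out$meth_pos <- ifelse(out$strand == "+",
                           out$start + mi - 1L,
                           out$start + k - mi)
  }
  out
}

#' Expand a degenerate motif into its literal sequences
#'
#' @param pattern Degenerate nucleotide pattern.
#' @param max Maximum number of expansions allowed (guards against `N`-rich
#'   patterns).
#' @return Character vector of all concrete sequences matching the pattern.
#' @export
expandMotif <- function(pattern, max = 65536L) {
  sets <- lapply(strsplit(toupper(pattern), "")[[1]], iupacSet)
  n <- prod(lengths(sets))
  if (n > max) stop("pattern expands to more than ", max, " sequences")
  apply(expand.grid(rev(sets), stringsAsFactors = FALSE), 1L,
        function(r) paste(rev(r), collapse = ""))
}

#' Filter motifs by genome support
#'
#' Retains motifs found in at least `minGenomes` distinct genomes, the
#' false-positive guard used for community-scale motif catalogues.
#'
#' @param motifHits Named list mapping motif pattern to a character vector of
#'   genomes with at least one occurrence.
#' @param minGenomes Minimum number of distinct supporting genomes.
#' @return Character vector of retained motif patterns.
#' @export
supportFilter <- function(motifHits, minGenomes = 100L) {
  if (length(motifHits) == 0L) return(character())
  support <- vapply(motifHits, function(g) length(unique(g)), integer(1))
  names(support)[support >= minGenomes]
}

#' Count genome support for motifs
#'
#' @param genomes A [Biostrings::DNAStringSet].
#' @param patterns Character vector of motif patterns.
#' @param bothStrands Scan both strands?
#' @return Named list mapping each pattern to the genome names with at least
#'   one occurrence (the input expected by [supportFilter()]).
#' @export
motifSupport <- function(genomes, patterns, bothStrands = TRUE) {
  if (is.null(names(genomes))) stop("'genomes' must be named")
  hits <- lapply(patterns, function(p) {
    has <- vapply(seq_along(genomes), function(i) {
      nrow(scanMotif(genomes[[i]], p, bothStrands = bothStrands)) > 0L
    }, logical(1))
    names(genomes)[has]
  })
  names(hits) <- patterns
  hits
}

#' Count overlaps of a motif set with a reference catalogue
#'
#' A motif is counted as overlapping when [motifOverlapped()] holds against
#' any reference motif (the relaxed, possibility-based criterion).
#'
#' @param motifs Character vector of query patterns.
#' @param referenceMotifs Character vector of reference patterns.
#' @param checkRevcomp Also test reverse complements of queries?
#' @return List with `n_overlapping` and `matches`, a named list giving the
#'   reference motifs matching each query.
#' @export
referenceOverlap <- function(motifs, referenceMotifs, checkRevcomp = FALSE) {
  matches <- lapply(motifs, function(m) {
    if (length(referenceMotifs) == 0L) return(character())
    hit <- vapply(referenceMotifs, function(r) {
      motifOverlapped(m, r, checkRevcomp = checkRevcomp)
    }, logical(1))
    referenceMotifs[hit]
  })
  names(matches) <- motifs
  list(
    n_overlapping = sum(lengths(matches) > 0L),
    matches = matches
  )
}

#' Union accounting of m4C and m6A motif sets
#'
#' Motifs of the two modification types are counted on pattern identity: a
#' pattern present in both sets (the same motif sequence with different
#' methylated bases) is shared, and the non-redundant total is
#' `n_m4C + n_m6A - n_shared`.
#'
#' @param m4cPatterns,m6aPatterns Character vectors of motif patterns.
#' @return List with `n_m4C`, `n_m6A`, `n_shared`, `n_total`.
#' @export
typeUnionAccounting <- function(m4cPatterns, m6aPatterns) {
  m4 <- unique(toupper(m4cPatterns))
  m6 <- unique(toupper(m6aPatterns))
  shared <- intersect(m4, m6)
  list(
    n_m4C = length(m4),
    n_m6A = length(m6),
    n_shared = length(shared),
    n_total = length(m4) + length(m6) - length(shared)
  )
}
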