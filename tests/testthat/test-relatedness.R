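.vsFix <- function(label, df, L = 1e6) {
  df$qual <- 50; df$depth <- 50
  variantSet(label, df, L)
}

test_that("dosages encode zygosity and absence; coding subset filters by CDS", {
  a <- .vsFix("a", data.frame(chrom = "chr1", pos = c(120, 90), ref = "A",
                              alt = "T", zygosity = c("hom", "het")))
  b <- .vsFix("b", data.frame(chrom = "chr1", pos = 120, ref = "A",
                              alt = "T", zygosity = "hom"))
  gm <- buildGenotypeMatrix(list(a, b))
  d <- dosageMatrix(gm)
  i120 <- which(siteInfo(gm)$pos == 120)
  i90 <- which(siteInfo(gm)$pos == 90)
  expect_equal(unname(d[i120, ]), c(2, 2))   # shared hom site
  expect_equal(unname(d[i90, ]), c(1, 0))    # het in a, absent in b

  models <- utrFixture()  # CDS 131-190 and 331-390
  a2 <- .vsFix("a", data.frame(chrom = "chr1", pos = c(150, 90), ref = "A",
                               alt = "T", zygosity = "hom"))
  b2 <- .vsFix("b", data.frame(chrom = "chr1", pos = 150, ref = "A",
                               alt = "T", zygosity = "het"))
  coding <- buildGenotypeMatrix(list(a2, b2), models, "coding")
  expect_equal(nrow(coding)[1], 1L)
  expect_equal(siteInfo(coding)$pos, 150)
})

test_that("coding subset equals a brute-force interval-overlap count", {
  st <- sharedStudy()
  sets <- lapply(st$vars$variantSets, filterVariants)
  gmAll <- buildGenotypeMatrix(sets, st$ref$models, "whole")
  gmCds <- buildGenotypeMatrix(sets, st$ref$models, "coding")
  cds <- as.data.frame(unlist(cdsIntervals(st$ref$models)))
  s <- siteInfo(gmAll)
  inCds <- vapply(seq_len(nrow(s)), function(i)
    any(cds$seqnames == s$chrom[i] & s$pos[i] >= cds$start &
          s$pos[i] <= cds$end), logical(1))
  expect_equal(nrow(gmCds)[1], sum(inCds))
})

test_that("conflicting REF alleles across genotypes are rejected", {
  a <- .vsFix("a", data.frame(chrom = "chr1", pos = 100, ref = "A",
                              alt = "T", zygosity = "hom"))
  b <- .vsFix("b", data.frame(chrom = "chr1", pos = 100, ref = "G",
                              alt = "T", zygosity = "hom"))
  expect_error(buildGenotypeMatrix(list(a, b)), "conflicting REF")
  # SNP vs spanning deletion at one position is legitimate
  d <- .vsFix("b", data.frame(chrom = "chr1", pos = 100, ref = "ATT",
                              alt = "A", zygosity = "hom"))
  expect_silent(gm <- buildGenotypeMatrix(list(a, d)))
  expect_equal(nrow(gm)[1], 2L)
})

test_that("allele-sharing distance has the IBS properties", {
  mkGm <- function(dos) new("GenotypeMatrix",
    sites = S4Vectors::DataFrame(chrom = "c", pos = seq_len(nrow(dos)),
                                 ref = "A", alt = "T"),
    dosage = dos)
  expect_equal(ibsDistance(mkGm(cbind(a = c(2, 1, 0), b = c(0, 1, 2))))["a", "b"],
               2 / 3, tolerance = 1e-12)
  expect_equal(ibsDistance(mkGm(cbind(a = c(1, 2), b = c(1, 2))))["a", "b"], 0)
  expect_equal(ibsDistance(mkGm(cbind(a = rep(2, 7), b = rep(0, 7))))["a", "b"], 1)

  set.seed(14)
  for (i in 1:5) {
    dos <- matrix(sample(0:2, 60, TRUE), 20, 3,
                  dimnames = list(NULL, c("x", "y", "z")))
    D <- ibsDistance(mkGm(dos))
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0 & D <= 1))
  }
  emptyGm <- new("GenotypeMatrix",
                 sites = S4Vectors::DataFrame(chrom = character(),
                                              pos = integer(),
                                              ref = character(),
                                              alt = character()),
                 dosage = matrix(numeric(), 0, 2,
                                 dimnames = list(NULL, c("a", "b"))))
  expect_error(ibsDistance(emptyGm), "zero sites")
})

test_that("UPGMA merges by average linkage with deterministic tie-breaks", {
  cherry <- upgma(matrix(c(0, .4, .4, 0), 2,
                         dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(cherry$height, 0.2)

  d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  expect_equal(tr$height, 0.3)
  expect_setequal(dendroLeaves(tr$left), c("A", "B"))
  expect_equal(dendroLeaves(tr$right), "C")

  # all-tied distances: lexicographically smallest pair merges first
  tied <- matrix(0.5, 3, 3, dimnames = list(c("C", "A", "B"),
                                            c("C", "A", "B")))
  diag(tied) <- 0
  trTied <- upgma(tied)
  expect_setequal(dendroLeaves(trTied$left), c("A", "B"))

  expect_error(upgma(matrix(c(0, NaN, NaN, 0), 2,
                            dimnames = list(c("a", "b"), c("a", "b")))),
               "NaN")
})

test_that("UPGMA is ultrametric and agrees with an independent implementation", {
  set.seed(31)
  for (i in 1:6) {
    n <- 5
    m <- matrix(stats::runif(n * n, 0.1, 1), n)
    D <- (m + t(m)) / 2; diag(D) <- 0
    dimnames(D) <- list(letters[1:n], letters[1:n])
    tr <- upgma(D)
    expect_lt(max(abs(dendroDepths(tr) - tr$height)), 1e-9)
    mine <- ape::cophenetic.phylo(dendroToPhylo(tr))
    orac <- ape::cophenetic.phylo(phangorn::upgma(stats::as.dist(D)))
    expect_equal(mine[rownames(orac), colnames(orac)], orac,
                 tolerance = 1e-9)
  }
})

test_that("a divergent genotype attaches last in the panel dendrogram", {
  set.seed(8)
  nSites <- 400
  base <- sample(0:2, nSites, TRUE)
  flip <- function(x, k) { i <- sample(nSites, k); x[i] <- (x[i] + 1) %% 3; x }
  dos <- cbind(g1 = flip(base, 15), g2 = flip(base, 15), g3 = flip(base, 20),
               g4 = flip(base, 25), g5 = flip(base, 20),
               out = sample(0:2, nSites, TRUE))
  gm <- new("GenotypeMatrix",
            sites = S4Vectors::DataFrame(chrom = "c", pos = seq_len(nSites),
                                         ref = "A", alt = "T"),
            dosage = dos)
  tr <- upgma(ibsDistance(gm))
  sides <- list(dendroLeaves(tr$left), dendroLeaves(tr$right))
  expect_true(any(vapply(sides, function(s) identical(s, "out"), logical(1))))
})
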