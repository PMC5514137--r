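# The published 25-row decision table, restated literally so the lookup is
# checked against an independent transcription.
.publishedAcronyms <- list(
  list(c("LRR", "NB-ARC"), "NL"),
  list(c("LRR", "NB-ARC", "CC"), "CNL"),
  list(c("LRR", "NB-ARC", "TIR"), "TNL"),
  list(c("LRR", "NB-ARC", "TM"), "other-TMNL"),
  list(c("LRR", "NB-ARC", "TM", "CC"), "other-LNTMC"),
  list(c("NB-ARC"), "N"),
  list(c("NB-ARC", "CC"), "CN"),
  list(c("NB-ARC", "TIR"), "TN"),
  list(c("NB-ARC", "TM"), "other-NT"),
  list(c("NB-ARC", "TM", "CC"), "other-NTMC"),
  list(c("LRR", "Pkinase", "TM"), "RLK"),
  list(c("LRR", "TM"), "RLP"),
  list(c("Pkinase"), "other-K"),
  list(c("Pkinase", "CC"), "other-KC"),
  list(c("Pkinase", "TM"), "other-KTM"),
  list(c("Pkinase", "TM", "CC"), "other-KTMC"),
  list(c("LRR", "Pkinase"), "KL"),
  list(c("LRR", "Pkinase", "TM", "CC"), "other-LRTMC"),
  list(c("LRR", "TM", "CC"), "other-CLTM"),
  list(c("TIR"), "T"),
  list(c("LRR"), "L"),
  list(c("ABC_tran"), "other-A"),
  list(c("ABC_tran", "Pkinase", "TM"), "other-AKTM"),
  list(c("ABC_tran", "TM"), "other-ATM"),
  list(c("ABC_tran", "TM", "CC"), "other-ACTM"))

test_that("all 25 published architecture combinations return their acronym", {
  for (row in .publishedAcronyms)
    expect_equal(classifyArchitecture(row[[1]]), row[[2]],
                 label = paste(row[[1]], collapse = ":"))
  # order independence
  for (row in .publishedAcronyms)
    expect_equal(classifyArchitecture(rev(row[[1]])), row[[2]])
})

test_that("unlisted combinations use the canonical letter-generation rule", {
  expect_equal(classifyArchitecture(c("TIR", "Pkinase")), "other-TK")
  expect_equal(classifyArchitecture(c("TIR", "CC")), "other-TC")
  expect_equal(classifyArchitecture(c("LRR", "NB-ARC", "TIR", "CC")),
               "other-LNTC")
  expect_equal(classifyArchitecture("WD40"), "other-W")
  expect_equal(classifyArchitecture(c("WD40", "LRR")), "other-LW")
})

test_that("classification is total over all non-empty domain subsets", {
  cats <- c("LRR", "NB-ARC", "TIR", "Pkinase", "ABC_tran", "WD40", "TM", "CC")
  tab <- rgaArchitectureTable()
  for (mask in seq_len(2^8 - 1)) {
    doms <- cats[bitwAnd(mask, 2^(0:7)) > 0]
    acr <- classifyArchitecture(doms)
    expect_true(nzchar(acr))
    key <- paste(sort(doms), collapse = ":")
    if (key %in% tab$domains)
      expect_equal(acr, tab$acronym[tab$domains == key])
    else
      expect_match(acr, "^other-")
  }
  expect_error(classifyArchitecture(character()), "empty")
})

test_that("domain collapse honours the E-value cutoff and the LRR merge", {
  hits <- data.frame(accession = c("PF00931", "PF13855"),
                     evalue = c(1e-30, 1e-12))
  expect_equal(collapseDomains(hits, hasCc = TRUE, hasTm = FALSE),
               c("CC", "LRR", "NB-ARC"))
  # 1e-9 fails the 1e-10 cutoff; 1e-10 itself passes
  pk <- data.frame(accession = "PF00069", evalue = 1e-9)
  expect_equal(collapseDomains(pk, FALSE, TRUE), "TM")
  pk$evalue <- 1e-10
  expect_equal(collapseDomains(pk, FALSE, TRUE), c("Pkinase", "TM"))
  # two distinct LRR accessions collapse to one category
  lrr2 <- data.frame(accession = c("PF00560", "PF13516"),
                     evalue = c(1e-20, 1e-15))
  expect_equal(collapseDomains(lrr2, FALSE, FALSE), "LRR")
  expect_warning(collapseDomains(data.frame(accession = "PF99999",
                                            evalue = 1e-30), FALSE, FALSE),
                 "unknown")
  expect_equal(collapseDomains(hits[0, ], FALSE, TRUE), "TM")
})

test_that("family groups follow the NB-first precedence", {
  expect_equal(rgaFamilyGroup(c("LRR", "NB-ARC", "CC")), "NB")
  expect_equal(rgaFamilyGroup(c("LRR", "NB-ARC", "TM")), "NB")
  expect_equal(rgaFamilyGroup(c("LRR", "Pkinase", "TM")), "RLK")
  expect_equal(rgaFamilyGroup(c("LRR", "TM")), "RLP")
  expect_equal(rgaFamilyGroup("LRR"), "LRR_only")
  expect_equal(rgaFamilyGroup(c("ABC_tran", "TM")), "ABC")
  expect_equal(rgaFamilyGroup(c("Pkinase", "TM")), "other_KTM")
  expect_equal(rgaFamilyGroup("TIR"), "other")
})

test_that("hmmscan domtblout rows parse into protein/accession/E-value", {
  fmt <- paste("%-20s %-12s 300 %-10s - 450 %.1e 120.5 0.1 1 1",
               "%.1e %.1e 110.0 0.1 5 290 10 300 8 300 0.95 desc text")
  p <- tempfile()
  writeLines(c(
    "# hmmscan :: search sequence(s) against a profile database",
    sprintf(fmt, "NB-ARC", "PF00931.25", "protA", 1e-30, 1e-28, 1e-29),
    sprintf(fmt, "Pkinase", "PF00069.28", "protB", 1e-15, 1e-14, 1e-14),
    "#"), p)
  hits <- readDomtblout(p)
  expect_equal(hits$protein_id, c("protA", "protB"))
  expect_equal(hits$accession, c("PF00931", "PF00069"))
  expect_equal(hits$evalue, c(1e-30, 1e-15))

  bad <- tempfile()
  writeLines("NB-ARC PF00931 protA", bad)
  expect_error(readDomtblout(bad), "malformed")
  none <- tempfile(); writeLines("# only comments", none)
  expect_equal(nrow(readDomtblout(none)), 0L)
})

test_that("the evidence-to-acronym pipeline recovers simulated truth exactly", {
  spec <- simulationSpec(rngSeed = 17)
  dom <- simulateDomainTables(spec, 400)
  cls <- classifyRgaTable(dom$hits, dom$flags)
  merged <- merge(cls, dom$truth, by = "protein_id")
  expect_equal(mean(merged$acronym.x == merged$acronym.y), 1.0)
  # counts equal the truth-label histogram
  sm <- summarizeClasses(cls)
  expect_equal(as.vector(sm$counts[sort(names(sm$counts))]),
               as.vector(table(dom$truth$acronym)[sort(names(sm$counts))]))
  expect_equal(sm$total, 400L)
  # proteins failing the homology screen are skipped
  dom$flags$passed_homology[1:10] <- FALSE
  expect_message(cls2 <- classifyRgaTable(dom$hits, dom$flags), "skipped")
  expect_equal(nrow(cls2), 390L)
})

test_that("summary over published per-class counts totals 611", {
  refCounts <- c(NL = 9, CNL = 4, TNL = 0, `other-TMNL` = 1,
                 `other-LNTMC` = 0, N = 9, CN = 7, TN = 1, `other-NT` = 4,
                 `other-NTMC` = 3, RLK = 173, RLP = 86, `other-K` = 59,
                 `other-KC` = 9, `other-KTM` = 157, `other-KTMC` = 4,
                 KL = 1, `other-LRTMC` = 5, `other-CLTM` = 1, T = 2,
                 L = 22, `other-A` = 1, `other-AKTM` = 0,
                 `other-ATM` = 49, `other-ACTM` = 4)
  expect_equal(summarizeClasses(refCounts)$total, 611)
  empty <- summarizeClasses(data.frame(acronym = character(),
                                       n_hmm_domains = integer()))
  expect_equal(empty$total, 0L)
})

test_that("RGA clusters are windows holding enough genes of one group", {
  chromLengths <- c(chr1 = 5e6, chr2 = 5e6)
  pos <- c(1.2e6, 1.3e6, 1.5e6, 1.8e6, 1.95e6,  # 5 NB genes in window 2
           3.5e6, 2e5)
  gr <- GenomicRanges::GRanges(c(rep("chr1", 6), "chr2"),
                               IRanges::IRanges(pos, pos + 1000))
  groups <- c(rep("NB", 5), "NB", "RLK")
  out <- clusterRgas(gr, groups, "NB", chromLengths)
  expect_equal(nrow(out$clusters), 1L)
  expect_equal(out$clusters$n_genes, 5)
  expect_equal(out$clusters$start, 1e6 + 1)
  expect_equal(sum(trackValues(out$track)), 6)  # conservation for group NB

  spread <- clusterRgas(GenomicRanges::GRanges(c("chr1", "chr2"),
                                               IRanges::IRanges(c(1e6, 2e6),
                                                                c(1e6, 2e6))),
                        c("RLP", "RLP"), "RLP", chromLengths)
  expect_equal(nrow(spread$clusters), 0L)
  expect_error(clusterRgas(gr, groups, "NOPE", chromLengths), "unknown")
})
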