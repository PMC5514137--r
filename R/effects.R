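.regionLevels <- c("CDS", "UTR", "splice_site", "intron", "intergenic")
.classLevels <- c("synonymous", "missense", "nonsense", "stop_lost",
                  "start_lost", "frameshift", "inframe_indel", "none")
.impactLevels <- c("high", "moderate", "low", "modifier")

## per-transcript annotation geometry, computed once
.effectIndex <- function(gms, spliceBp = 2L) {
  cds <- cdsIntervals(gms)
  ex <- exonIntervals(gms)
  txspan <- unlist(range(ex))
  exAll <- unlist(ex)
  cdsAll <- unlist(cds)
  utr <- GenomicRanges::setdiff(exAll, cdsAll)
  introns <- GenomicRanges::setdiff(txspan, exAll)
  spl <- c(GenomicRanges::resize(introns, spliceBp, fix = "start"),
           GenomicRanges::resize(introns, spliceBp, fix = "end"))
  spl <- spl[width(introns)[c(seq_along(introns), seq_along(introns))] >=
               spliceBp]
  list(cds = cdsAll, utr = utr, splice = spl, intron = introns,
       tx = txspan, cdsByTx = cds)
}

#' Assign the genomic region of each variant
#'
#' Classifies variant positions into `CDS`, `UTR`, `splice_site`,
#' `intron` or `intergenic` with precedence CDS > UTR > splice_site >
#' intron > intergenic (a position matching several regions across
#' overlapping transcripts gets the most severe one). Splice sites are
#' the first and last 2 bp of each intron — the canonical donor and
#' acceptor dinucleotides. Positions on chromosomes absent from the
#' models are intergenic, with a warning.
#'
#' @param vs a [VariantSet-class].
#' @param gms a [GeneModelSet-class].
#' @return Character vector of regions, one per record.
#' @export
assignRegion <- function(vs, gms) {
  r <- variantRecords(vs)
  if (!nrow(r)) return(character())
  idx <- .effectIndex(gms)
  chrAnn <- unique(as.character(seqnames(idx$tx)))
  missing <- setdiff(unique(r$chrom), chrAnn)
  if (length(missing))
    warning("no gene models on chromosome(s): ",
            paste(missing, collapse = ", "), "; variants there are intergenic")
  pos <- GRanges(r$chrom, IRanges(r$pos, r$pos))
  hit <- function(gr) GenomicRanges::countOverlaps(pos, gr) > 0
  region <- rep("intergenic", nrow(r))
  region[hit(idx$intron)] <- "intron"
  region[hit(idx$splice)] <- "splice_site"
  region[hit(idx$utr)] <- "UTR"
  region[hit(idx$cds)] <- "CDS"
  region
}

.translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Functional class of a CDS variant
#'
#' For a SNP inside a transcript's CDS: rebuilds the affected codon on
#' the coding strand, translates reference and mutant codons with the
#' standard genetic code and returns `synonymous` (same amino acid),
#' `missense` (different, non-stop), `nonsense` (new stop),
#' `stop_lost` (reference stop destroyed) or `start_lost` (first-codon
#' ATG destroyed). For an indel, `frameshift` when the length change is
#' not a multiple of 3, else `inframe_indel` — the codon is never
#' consulted.
#'
#' @param chrom,pos,ref,alt the variant (1-based position of the first
#'   reference base).
#' @param txId transcript id in `gms` whose CDS contains the position.
#' @param gms a [GeneModelSet-class].
#' @param genome a named `DNAStringSet` of reference chromosomes.
#' @return One of the functional class strings.
#' @export
classifyCdsVariant <- function(chrom, pos, ref, alt, txId, gms, genome) {
  if (nchar(ref) != nchar(alt)) {
    shift <- abs(nchar(ref) - nchar(alt))
    return(if (shift %% 3 != 0) "frameshift" else "inframe_indel")
  }
  if (nchar(ref) != 1L) {
    # multi-base substitution: classify by full-codon comparison is out of
    # scope of the four-class scheme; treat as missense-like via first base
    stop("multi-base substitutions are not supported; split into SNPs")
  }
  cds <- cdsIntervals(gms)[[txId]]
  if (is.null(cds)) stop("unknown transcript: ", txId)
  tx <- transcriptInfo(gms)
  strand <- tx$strand[tx$tx_id == txId]
  cdsLen <- sum(width(cds))
  if (cdsLen %% 3 != 0)
    stop("CDS of ", txId, " has length ", cdsLen, ", not divisible by 3")
  chrSeq <- genome[[chrom]]
  if (is.null(chrSeq)) stop("chromosome ", chrom, " absent from genome")
  cdsSeq <- paste(vapply(seq_along(cds), function(i)
    as.character(Biostrings::subseq(chrSeq, start(cds)[i], end(cds)[i])),
    character(1)), collapse = "")
  # forward-strand offset of pos within the concatenated CDS
  cum <- cumsum(width(cds))
  iv <- which(pos >= start(cds) & pos <= end(cds))
  if (!length(iv)) stop("position ", pos, " not in CDS of ", txId)
  fwd <- (if (iv > 1) cum[iv - 1] else 0L) + (pos - start(cds)[iv] + 1L)
  if (strand == "-") {
    cdsSeq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cdsSeq)))
    cpos <- cdsLen - fwd + 1L
    refC <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ref)))
    altC <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(alt)))
  } else {
    cpos <- fwd
    refC <- ref; altC <- alt
  }
  codonIdx <- ceiling(cpos / 3)
  within <- cpos - (codonIdx - 1L) * 3L
  refCodon <- substr(cdsSeq, (codonIdx - 1L) * 3L + 1L, codonIdx * 3L)
  if (substr(refCodon, within, within) != refC)
    stop("reference allele mismatch at ", chrom, ":", pos,
         " (genome has ", substr(refCodon, within, within), ", record says ",
         refC, ")")
  altCodon <- refCodon
  substr(altCodon, within, within) <- altC
  refAA <- .translateCodon(refCodon)
  altAA <- .translateCodon(altCodon)
  if (is.na(refAA) || is.na(altAA)) return("none")
  if (refAA == altAA) return("synonymous")
  if (refAA == "*") return("stop_lost")
  if (altAA == "*") return("nonsense")
  if (codonIdx == 1L && refAA == "M") return("start_lost")
  "missense"
}

#' Impact tier of an annotated variant
#'
#' The four-tier scheme: `high` for variants that modify splice sites,
#' stop or start codons (gain or loss) or shift the reading frame;
#' `moderate` for amino-acid-changing variants (missense, in-frame
#' indels); `low` for coding variants that leave the protein unchanged
#' (synonymous); `modifier` for everything outside coding sequence —
#' intergenic, intronic and UTR positions. Total over every
#' region x class combination.
#'
#' @param region region from [assignRegion()].
#' @param class functional class from [classifyCdsVariant()] (`"none"`
#'   for non-CDS variants).
#' @return One of `"high"`, `"moderate"`, `"low"`, `"modifier"`
#'   (vectorized).
#' @export
assignImpact <- function(region, class) {
  stopifnot(length(region) == length(class))
  out <- rep("modifier", length(region))
  out[region == "splice_site"] <- "high"
  out[class %in% c("nonsense", "stop_lost", "start_lost", "frameshift")] <-
    "high"
  out[class %in% c("missense", "inframe_indel")] <- "moderate"
  out[class == "synonymous"] <- "low"
  out
}

#' Annotate a variant set with region, class and impact
#'
#' Runs the full effect-annotation chain: region assignment, CDS
#' functional classification against the reference sequence, and impact
#' tiering. A variant overlapping the CDS of several transcripts gets
#' one annotation — the most severe across transcripts (severity
#' high > moderate > low > modifier). Zygosity is carried through.
#'
#' @param vs a [VariantSet-class].
#' @param gms a [GeneModelSet-class].
#' @param genome named `DNAStringSet` of reference chromosomes.
#' @return `data.frame` with one row per record: `chrom`, `pos`, `ref`,
#'   `alt`, `zygosity`, `region`, `class`, `impact`.
#' @export
annotateVariants <- function(vs, gms, genome) {
  r <- as.data.frame(variantRecords(vs))
  region <- assignRegion(vs, gms)
  class <- rep("none", nrow(r))
  if (nrow(r)) {
    cdsByTx <- cdsIntervals(gms)
    cdsAll <- unlist(cdsByTx)
    txOf <- rep(names(cdsByTx), lengths(cdsByTx))
    pos <- GRanges(r$chrom, IRanges(r$pos, r$pos))
    ov <- GenomicRanges::findOverlaps(pos, cdsAll)
    sev <- function(cl) match(assignImpact("CDS", cl), .impactLevels)
    for (i in which(region == "CDS")) {
      txs <- unique(txOf[S4Vectors::subjectHits(ov)[
        S4Vectors::queryHits(ov) == i]])
      cls <- vapply(txs, function(tx)
        classifyCdsVariant(r$chrom[i], r$pos[i], r$ref[i], r$alt[i],
                           tx, gms, genome), character(1))
      class[i] <- cls[which.min(vapply(cls, sev, numeric(1)))]
    }
    # indels assigned to CDS still classify by length even if the matched
    # transcript set was empty (should not happen when region == CDS)
  }
  data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
             zygosity = r$zygosity, region = region, class = class,
             impact = assignImpact(region, class),
             stringsAsFactors = FALSE)
}

#' Effect fractions by impact and region, split by zygosity
#'
#' For the homozygous and heterozygous subsets separately, the fraction
#' of variants in each impact tier and each region. Fractions within a
#' subset sum to 1.
#'
#' @param ann annotation `data.frame` from [annotateVariants()].
#' @return A list with elements `hom` and `het`, each a list of two
#'   named numeric vectors `byImpact` and `byRegion` (empty subsets
#'   give empty vectors).
#' @export
summarizeEffects <- function(ann) {
  one <- function(sub) {
    if (!nrow(sub)) return(list(byImpact = numeric(), byRegion = numeric()))
    list(
      byImpact = prop.table(table(factor(sub$impact, .impactLevels))),
      byRegion = prop.table(table(factor(sub$region, .regionLevels))))
  }
  list(hom = one(ann[ann$zygosity == "hom", , drop = FALSE]),
       het = one(ann[ann$zygosity == "het", , drop = FALSE]))
}

#' Aggregate deleterious calls over pathway gene sets
#'
#' For each pathway, counts its non-synonymous variants with an
#' external deleteriousness score and flags as deleterious those with
#' score at or below the cutoff (-2.5 by default; more negative = more
#' damaging, and a score of exactly -2.5 counts as deleterious).
#' Variants with a missing score are excluded with a warning and
#' reported.
#'
#' @param scores `data.frame` with columns `pathway`, `variant_id`,
#'   `score` — one row per non-synonymous variant in a pathway gene.
#' @param cfg a [RunConfig-class] supplying `proveanCutoff`.
#' @return `data.frame` with one row per pathway: `pathway`, `n`
#'   (scored non-synonymous variants), `n_deleterious`, `pct`
#'   (1 decimal), `n_missing_score`.
#' @examples
#' sc <- data.frame(pathway = "CQA", variant_id = paste0("v", 1:33),
#'                  score = c(rep(-3, 10), rep(0, 23)))
#' flagDeleterious(sc)$pct  # 30.3
#' @export
flagDeleterious <- function(scores, cfg = runConfig()) {
  stopifnot(all(c("pathway", "variant_id", "score") %in% colnames(scores)))
  miss <- is.na(scores$score)
  if (any(miss))
    warning(sum(miss), " variant(s) without a score excluded")
  out <- lapply(split(scores, scores$pathway), function(s) {
    nm <- sum(is.na(s$score))
    s <- s[!is.na(s$score), , drop = FALSE]
    d <- sum(s$score <= cfg@proveanCutoff)
    data.frame(pathway = s$pathway[1], n = nrow(s), n_deleterious = d,
               pct = if (nrow(s)) round(100 * d / nrow(s), 1) else NA_real_,
               n_missing_score = nm, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
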