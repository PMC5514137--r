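#' Filter variants on call quality and depth
#'
#' Retains a record iff `qual >= qualMin` and
#' `depthMin <= depth <= depthMax` (all boundaries inclusive: a call of
#' quality exactly 20 is kept, as are depths of exactly 8 and 450 under
#' the defaults). Record order is preserved and the operation is
#' idempotent.
#'
#' @param vs a [VariantSet-class] with `qual` and `depth` populated.
#' @param cfg a [RunConfig-class]; defaults qual >= 20, depth in [8, 450].
#' @return The filtered [VariantSet-class].
#' @examples
#' vs <- variantSet("g1", data.frame(
#'   chrom = "chr1", pos = c(10, 20), ref = "A", alt = "T",
#'   zygosity = "het", qual = c(19, 20), depth = c(100, 8)), 1e6)
#' length(filterVariants(vs))  # 1: the qual-19 record is removed
#' @export
filterVariants <- function(vs, cfg = runConfig()) {
  r <- variantRecords(vs)
  if (anyNA(r$depth)) {
    bad <- which(is.na(r$depth))[1]
    stop("record ", bad, " (", r$chrom[bad], ":", r$pos[bad],
         ") has missing depth")
  }
  keep <- r$qual >= cfg@qualMin &
    r$depth >= cfg@depthMin & r$depth <= cfg@depthMax
  variantSet(genotypeLabel(vs), r[keep, , drop = FALSE], refLength(vs))
}

#' Per-genotype SNP/indel count and rate summary
#'
#' Computes, from SNP count S, indel count I and reference length L, the
#' row set of a resequencing statistics table: total T = S + I, percent
#' rates 100*S/L etc., variants per kb, and the mean spacing "1 SNP
#' every L/S bp". When a count is zero the corresponding spacing is
#' `NA` (an undefined sentinel), never an infinity.
#'
#' Values are exact; presentation rounding (rates to 2 decimals, spacing
#' to 1 decimal below 1000 bp and to the nearest integer at or above) is
#' applied only by [formatRateSummary()].
#'
#' @param vs a [VariantSet-class], or `NULL` when `S`, `I`, `L` are given
#'   directly (e.g. from a published count table).
#' @param S,I,L SNP count, indel count and reference length in bp;
#'   derived from `vs` when it is supplied.
#' @return A one-row `data.frame` with columns `genotype`, `S`, `I`, `T`,
#'   `snp_rate_pct`, `indel_rate_pct`, `rate_pct`, `snp_per_kb`,
#'   `indel_per_kb`, `per_kb`, `one_snp_every`, `one_indel_every`,
#'   `one_any_every`.
#' @examples
#' summarizeRates(S = 5900934, I = 443603, L = 724700000)$snp_rate_pct
#' @export
summarizeRates <- function(vs = NULL, S = NULL, I = NULL, L = NULL,
                           genotype = NA_character_) {
  if (!is.null(vs)) {
    stopifnot(is(vs, "VariantSet"))
    snp <- isSnp(vs)
    S <- sum(snp); I <- sum(!snp); L <- refLength(vs)
    genotype <- genotypeLabel(vs)
  }
  stopifnot(is.numeric(S), is.numeric(I), is.numeric(L), L > 0, S >= 0, I >= 0)
  T <- S + I
  every <- function(n) if (n > 0) L / n else NA_real_
  data.frame(
    genotype = genotype, S = S, I = I, T = T,
    snp_rate_pct = 100 * S / L,
    indel_rate_pct = 100 * I / L,
    rate_pct = 100 * T / L,
    snp_per_kb = 1000 * S / L,
    indel_per_kb = 1000 * I / L,
    per_kb = 1000 * T / L,
    one_snp_every = every(S),
    one_indel_every = every(I),
    one_any_every = every(T),
    stringsAsFactors = FALSE)
}

#' Presentation rounding for a rate summary
#'
#' Rates are printed to 2 decimal places, per-kb densities to 2, and
#' "1 every (bp)" spacings to 1 decimal when below 1000 bp and to the
#' nearest integer otherwise.
#'
#' @param rs a one- or multi-row summary from [summarizeRates()].
#' @return The summary with presentation rounding applied.
#' @export
formatRateSummary <- function(rs) {
  roundEvery <- function(x)
    ifelse(is.na(x), NA_real_, ifelse(x < 1000, round(x, 1), round(x)))
  for (col in c("snp_rate_pct", "indel_rate_pct", "rate_pct"))
    rs[[col]] <- round(rs[[col]], 2)
  for (col in c("snp_per_kb", "indel_per_kb", "per_kb"))
    rs[[col]] <- round(rs[[col]], 2)
  for (col in c("one_snp_every", "one_indel_every", "one_any_every"))
    rs[[col]] <- roundEvery(rs[[col]])
  rs
}

#' Fixed-window variant density track
#'
#' Tiles each chromosome into `windowBp`-wide windows (1-based inclusive;
#' window k covers `[(k-1)*windowBp + 1, k*windowBp]`, the last window
#' truncated at the chromosome end) and counts the variants whose
#' position falls in each window. A variant at position `windowBp`
#' exactly belongs to window 1. Each variant lands in exactly one
#' window, so window counts sum to the (optionally zygosity-filtered)
#' variant count.
#'
#' @param vs a [VariantSet-class].
#' @param chromLengths named numeric vector of chromosome lengths in bp;
#'   every chromosome carrying a variant must be present, and no variant
#'   may lie beyond its chromosome end.
#' @param windowBp window width in bp (default 1e6).
#' @param zygosity `NULL` for all records, or `"het"`/`"hom"` to count
#'   only that subset.
#' @return A [WindowTrack-class] covering all chromosomes in
#'   `chromLengths`.
#' @export
windowDensity <- function(vs, chromLengths, windowBp = 1e6,
                          zygosity = NULL) {
  stopifnot(windowBp >= 1, length(chromLengths) > 0,
            !is.null(names(chromLengths)))
  r <- variantRecords(vs)
  if (!is.null(zygosity)) {
    stopifnot(zygosity %in% c("het", "hom"))
    r <- r[r$zygosity == zygosity, , drop = FALSE]
  }
  if (nrow(r)) {
    unknown <- setdiff(unique(r$chrom), names(chromLengths))
    if (length(unknown))
      stop("variants on chromosome(s) absent from chromLengths: ",
           paste(unknown, collapse = ", "))
    over <- r$pos > chromLengths[r$chrom] | r$pos < 1
    if (any(over))
      stop("variant beyond chromosome length at ",
           r$chrom[over][1], ":", r$pos[over][1])
  }
  tiles <- lapply(names(chromLengths), function(chr) {
    len <- chromLengths[[chr]]
    starts <- seq(1, len, by = windowBp)
    ends <- pmin(starts + windowBp - 1, len)
    GRanges(chr, IRanges(starts, ends))
  })
  gr <- suppressWarnings(do.call(c, tiles))
  idx <- numeric(length(gr))
  if (nrow(r)) {
    vgr <- GRanges(r$chrom, IRanges(r$pos, r$pos))
    hits <- GenomicRanges::countOverlaps(gr, vgr)
    idx <- as.numeric(hits)
  }
  S4Vectors::mcols(gr)$score <- idx
  new("WindowTrack", windows = gr, windowBp = windowBp)
}

#' Count features per fixed window
#'
#' Generic windowed counter for point or interval features (genes, RGA
#' loci): each feature is counted in every window its `start` position
#' falls in (exactly one), so counts are conserved.
#'
#' @param gr a `GRanges` of features.
#' @param chromLengths named numeric chromosome lengths.
#' @param windowBp window width in bp.
#' @return A [WindowTrack-class].
#' @export
windowCount <- function(gr, chromLengths, windowBp = 1e6) {
  pts <- data.frame(chrom = as.character(seqnames(gr)),
                    pos = start(gr), ref = "A", alt = "T",
                    zygosity = "hom", qual = 99, depth = 50)
  vs <- variantSet("features", pts, max(chromLengths))
  windowDensity(vs, chromLengths, windowBp)
}

#' Scan for homozygous-fixed regions
#'
#' Finds maximal runs of consecutive windows in which heterozygous-SNP
#' density is at most `hetMaxPerMb` and homozygous-SNP density is at
#' least `homMinPerMb` (densities per Mb, computed from the actual
#' window width so truncated terminal windows are handled). Adjacent
#' qualifying windows on a chromosome merge into one region; runs
#' separated by a non-qualifying window do not. Each region is annotated
#' with its gene count from `geneTrack`.
#'
#' These regions are the signature of loci driven to homozygosity — in a
#' domesticated crop panel, candidate selection/breeding footprints.
#'
#' @param hetTrack,homTrack,geneTrack [WindowTrack-class] objects sharing
#'   identical windowing (same chromosomes, boundaries and width).
#' @param cfg a [RunConfig-class] providing `hetMaxPerMb` (default 10)
#'   and `homMinPerMb` (default 100).
#' @return A `data.frame` with columns `chrom`, `start`, `end`,
#'   `n_windows`, `het_per_mb`, `hom_per_mb`, `gene_count`; zero rows
#'   when nothing qualifies.
#' @export
scanFixedRegions <- function(hetTrack, homTrack, geneTrack,
                             cfg = runConfig()) {
  gw <- trackWindows(hetTrack)
  same <- function(t) {
    w <- trackWindows(t)
    length(w) == length(gw) &&
      all(as.character(seqnames(w)) == as.character(seqnames(gw))) &&
      all(start(w) == start(gw)) && all(end(w) == end(gw))
  }
  if (!same(homTrack) || !same(geneTrack))
    stop("tracks must share identical windowing")
  wMb <- width(gw) / 1e6
  hetD <- trackValues(hetTrack) / wMb
  homD <- trackValues(homTrack) / wMb
  ok <- hetD <= cfg@hetMaxPerMb & homD >= cfg@homMinPerMb
  chrom <- as.character(seqnames(gw))
  # runs must not cross chromosome boundaries
  runKey <- paste(chrom, cumsum(!ok | c(TRUE, chrom[-1] != chrom[-length(chrom)])))
  out <- list()
  for (key in unique(runKey[ok])) {
    i <- which(runKey == key & ok)
    out[[length(out) + 1L]] <- data.frame(
      chrom = chrom[i[1]],
      start = min(start(gw)[i]), end = max(end(gw)[i]),
      n_windows = length(i),
      het_per_mb = sum(trackValues(hetTrack)[i]) / sum(wMb[i]),
      hom_per_mb = sum(trackValues(homTrack)[i]) / sum(wMb[i]),
      gene_count = sum(trackValues(geneTrack)[i]),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      het_per_mb = numeric(), hom_per_mb = numeric(),
                      gene_count = numeric()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Mean of a per-genotype metric
#'
#' Arithmetic mean across genotypes of a published or computed metric
#' (sequencing depth, reconstruction percentage, ...), with 1-decimal
#' presentation rounding.
#'
#' @param values numeric vector, one value per genotype; must be
#'   non-empty.
#' @param digits presentation rounding (default 1).
#' @return The rounded mean.
#' @examples
#' aggregateMetrics(c(24.6, 38.5, 33.7, 34.3, 45.3))  # 35.3
#' @export
aggregateMetrics <- function(values, digits = 1) {
  if (!length(values)) stop("no values to aggregate")
  round(mean(values), digits)
}
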