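#' Normalize gene counts by library size
#'
#' Rescales each genotype's per-gene mapped-read counts by the ratio of
#' the mean library total to that genotype's library total:
#' `norm(g, i) = raw(g, i) * mean(totals) / totals[i]`. Scaling to the
#' mean library keeps normalized values on a read-count scale, so the
#' absolute presence/absence thresholds (6 and 29 reads) remain
#' meaningful after normalization. Within a genotype the rescaling is a
#' positive constant, so rank order is preserved.
#'
#' @param t a [GeneCountTable-class] with positive library totals.
#' @return Numeric matrix of normalized counts, same dimnames as the raw
#'   matrix.
#' @export
normalizeCounts <- function(t) {
  stopifnot(is(t, "GeneCountTable"))
  lt <- libraryTotals(t)
  if (any(lt <= 0)) stop("library totals must be positive")
  sweep(geneCounts(t), 2, mean(lt) / lt, `*`)
}

#' Call presence/absence-variable genes
#'
#' A gene is a putative PAV gene iff some genotype shows fewer than
#' `pavAbsentThreshold` normalized reads (absent) while some other
#' genotype shows more than `pavPresentThreshold` (confidently present).
#' Per-genotype state is `absent` iff the normalized count is below the
#' absent threshold; intermediate counts (in `[6, 29]` by default) count
#' as present for state purposes but cannot by themselves qualify a
#' gene.
#'
#' When the table carries a column for the reference genotype itself
#' (whose genes are present by construction), name it in
#' `referenceGenotype` so that categorization can exclude it; the column
#' still participates in the selection rule.
#'
#' @param norm normalized count matrix from [normalizeCounts()] (or a
#'   raw matrix if libraries are equal).
#' @param cfg a [RunConfig-class]; thresholds default to 6 and 29.
#' @param referenceGenotype optional column name of the reference
#'   genotype.
#' @return A list of class `pavCalls`: `calls` (logical genes x
#'   genotypes absence matrix restricted to PAV genes), `isPav` (named
#'   logical over all genes), `referenceGenotype`.
#' @examples
#' m <- rbind(gA = c(3, 45, 30, 31), gB = c(10, 20, 25, 28))
#' colnames(m) <- paste0("G", 1:4)
#' callPav(m)$isPav  # gA TRUE (absent in G1), gB FALSE
#' @export
callPav <- function(norm, cfg = runConfig(), referenceGenotype = NULL) {
  stopifnot(is.matrix(norm), ncol(norm) >= 2)
  absent <- norm < cfg@pavAbsentThreshold
  present <- norm > cfg@pavPresentThreshold
  isPav <- apply(absent, 1, any) & apply(present, 1, any)
  structure(list(
    calls = absent[isPav, , drop = FALSE],
    isPav = isPav,
    referenceGenotype = referenceGenotype), class = "pavCalls")
}

#' @export
print.pavCalls <- function(x, ...) {
  cat("pavCalls:", nrow(x$calls), "PAV gene(s) over", ncol(x$calls),
      "genotype(s)\n")
  invisible(x)
}

#' Categorize PAV absence patterns
#'
#' Buckets every PAV gene by the number of resequenced genotypes it is
#' absent from (the reference genotype's own column, if any, is
#' excluded: its genes are present by construction). Also reports the
#' genes exclusively present in a single genotype, and a per-genotype
#' set summary usable for a Venn diagram.
#'
#' Percentages are `100 * bucket / total PAV genes`, rounded to 1
#' decimal.
#'
#' @param calls a `pavCalls` object from [callPav()], or a logical
#'   genes x genotypes absence matrix.
#' @return A list: `total`, `buckets` (data.frame `n_absent`, `count`,
#'   `pct` for k = 1..n genotypes), `absentInAll` count and `pctAbsentInAll`,
#'   `absentInOne` count and `pctAbsentInOne`, `exclusiveToOne` (named
#'   count of genes present only in that genotype), `absentPerGenotype`
#'   (named counts), `sets` (list of absent gene ids per genotype).
#' @export
categorizePav <- function(calls) {
  if (inherits(calls, "pavCalls")) {
    m <- calls$calls
    if (!is.null(calls$referenceGenotype))
      m <- m[, setdiff(colnames(m), calls$referenceGenotype), drop = FALSE]
  } else m <- calls
  stopifnot(is.logical(m))
  if (!nrow(m)) stop("no PAV calls to categorize")
  n <- ncol(m)
  k <- rowSums(m)
  total <- nrow(m)
  buckets <- data.frame(
    n_absent = seq_len(n),
    count = vapply(seq_len(n), function(i) sum(k == i), numeric(1)))
  buckets$pct <- round(100 * buckets$count / total, 1)
  excl <- k == n - 1  # present in exactly one genotype
  exclWho <- colnames(m)[apply(!m[excl, , drop = FALSE], 1, which)]
  list(
    total = total,
    buckets = buckets,
    absentInAll = sum(k == n),
    pctAbsentInAll = round(100 * sum(k == n) / total, 1),
    absentInOne = sum(k == 1),
    pctAbsentInOne = round(100 * sum(k == 1) / total, 1),
    exclusiveToOne = table(factor(exclWho, levels = colnames(m))),
    absentPerGenotype = colSums(m),
    sets = apply(m, 2, function(col) rownames(m)[col], simplify = FALSE))
}

#' Read / write a gene count table as TSV
#'
#' Format: a `#library_total` comment row carrying the per-genotype
#' genome-wide mapped-read totals, a header row `gene_id` plus one
#' column per genotype, then one row per gene. Tab-separated, UTF-8,
#' `#` comments.
#'
#' @param path file path.
#' @return `readGeneCountTable()` returns a [GeneCountTable-class].
#' @export
readGeneCountTable <- function(path) {
  lines <- readLines(path)
  ltLine <- grep("^#library_total\t", lines, value = TRUE)
  if (length(ltLine) != 1)
    stop("expected exactly one #library_total row")
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  lt <- as.numeric(strsplit(ltLine, "\t")[[1]][-1])
  names(lt) <- colnames(m)
  geneCountTable(m, lt)
}

#' @rdname readGeneCountTable
#' @param t a [GeneCountTable-class].
#' @export
writeGeneCountTable <- function(t, path) {
  m <- geneCounts(t)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#library_total", libraryTotals(t)), collapse = "\t"),
             con)
  writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
  utils::write.table(data.frame(gene_id = rownames(m), m,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
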