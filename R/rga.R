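## Pfam accession -> domain category map used for RGA screening.
## The nine LRR accessions collapse to a single LRR category.
.pfamMap <- c(
  PF00931 = "NB-ARC",
  PF01582 = "TIR",
  PF00560 = "LRR", PF07723 = "LRR", PF07725 = "LRR", PF007725 = "LRR",
  PF08263 = "LRR", PF12799 = "LRR", PF13306 = "LRR", PF13516 = "LRR",
  PF13855 = "LRR", PF14580 = "LRR",
  PF00069 = "Pkinase",
  PF00005 = "ABC_tran",
  PF00400 = "WD40"
)

## The published decision table: domain-set -> acronym, 25 combinations.
## Keys are the sorted domain sets joined by ":". The printed acronyms are
## kept verbatim (their generated-letter order is historical and not
## consistent); only unlisted combinations go through the canonical
## generation rule in classifyArchitecture().
.rgaTable <- local({
  combos <- list(
    c("LRR", "NB-ARC")                    , "NL",
    c("LRR", "NB-ARC", "CC")              , "CNL",
    c("LRR", "NB-ARC", "TIR")             , "TNL",
    c("LRR", "NB-ARC", "TM")              , "other-TMNL",
    c("LRR", "NB-ARC", "TM", "CC")        , "other-LNTMC",
    c("NB-ARC")                           , "N",
    c("NB-ARC", "CC")                     , "CN",
    c("NB-ARC", "TIR")                    , "TN",
    c("NB-ARC", "TM")                     , "other-NT",
    c("NB-ARC", "TM", "CC")               , "other-NTMC",
    c("LRR", "Pkinase", "TM")             , "RLK",
    c("LRR", "TM")                        , "RLP",
    c("Pkinase")                          , "other-K",
    c("Pkinase", "CC")                    , "other-KC",
    c("Pkinase", "TM")                    , "other-KTM",
    c("Pkinase", "TM", "CC")              , "other-KTMC",
    c("LRR", "Pkinase")                   , "KL",
    c("LRR", "Pkinase", "TM", "CC")       , "other-LRTMC",
    c("LRR", "TM", "CC")                  , "other-CLTM",
    c("TIR")                              , "T",
    c("LRR")                              , "L",
    c("ABC_tran")                         , "other-A",
    c("ABC_tran", "Pkinase", "TM")        , "other-AKTM",
    c("ABC_tran", "TM")                   , "other-ATM",
    c("ABC_tran", "TM", "CC")             , "other-ACTM")
  keys <- vapply(combos[seq(1, length(combos), 2)],
                 function(s) paste(sort(s), collapse = ":"), character(1))
  stats::setNames(unlist(combos[seq(2, length(combos), 2)]), keys)
})

#' The published RGA architecture decision table
#'
#' @return A `data.frame` with the 25 recognized domain combinations
#'   (sorted, colon-joined) and their acronyms.
#' @export
rgaArchitectureTable <- function() {
  data.frame(domains = names(.rgaTable), acronym = unname(.rgaTable),
             stringsAsFactors = FALSE)
}

#' Parse an hmmscan --domtblout file
#'
#' Reads HMMER's per-domain tabular output (whitespace-separated fixed
#' leading columns, free-text description last, `#` comment lines) and
#' returns, per protein, the Pfam profile hits with their full-sequence
#' E-values. For `hmmscan` the target is the profile and the query the
#' protein.
#'
#' @param path path to a domtblout file.
#' @return `data.frame` with columns `protein_id`, `accession`
#'   (version suffix stripped), `evalue`.
#' @export
readDomtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(protein_id = character(), accession = character(),
                      evalue = numeric()))
  fields <- strsplit(trimws(lines), "[ \t]+")
  short <- lengths(fields) < 13
  if (any(short))
    stop("malformed domtblout row (fewer than 13 columns) at data line ",
         which(short)[1])
  data.frame(
    protein_id = vapply(fields, `[`, character(1), 4),
    accession = sub("\\..*$", "", vapply(fields, `[`, character(1), 2)),
    evalue = as.numeric(vapply(fields, `[`, character(1), 7)),
    stringsAsFactors = FALSE)
}

#' Collapse domain evidence to a domain set
#'
#' Keeps Pfam hits with E-value at most `hmmEvalueMax` (1e-10 by
#' default, inclusive), maps accessions to domain categories (all nine
#' LRR accessions collapse to `LRR`), drops unknown accessions with a
#' warning, and appends the coiled-coil / transmembrane flags as `CC` /
#' `TM`. Copy numbers are ignored: the result is a set.
#'
#' @param hits `data.frame` with columns `accession`, `evalue` for one
#'   protein (zero rows allowed).
#' @param hasCc,hasTm logical coiled-coil / transmembrane flags,
#'   predicted upstream.
#' @param cfg a [RunConfig-class].
#' @return Sorted character vector of domain categories (possibly
#'   empty).
#' @export
collapseDomains <- function(hits, hasCc = FALSE, hasTm = FALSE,
                            cfg = runConfig()) {
  dom <- character()
  if (nrow(hits)) {
    keep <- hits$evalue <= cfg@hmmEvalueMax
    acc <- hits$accession[keep]
    unknown <- setdiff(acc, names(.pfamMap))
    if (length(unknown))
      warning("ignoring unknown Pfam accession(s): ",
              paste(unique(unknown), collapse = ", "))
    dom <- unique(unname(.pfamMap[intersect(acc, names(.pfamMap))]))
  }
  if (isTRUE(hasCc)) dom <- c(dom, "CC")
  if (isTRUE(hasTm)) dom <- c(dom, "TM")
  sort(unique(dom))
}

## canonical letter order for generated acronyms
.acronymLetters <- c(LRR = "L", `NB-ARC` = "N", TIR = "T", Pkinase = "K",
                     ABC_tran = "A", TM = "TM", CC = "C", WD40 = "W")

#' Classify an RGA domain architecture
#'
#' Exact lookup of the domain set against the 25 published
#' combinations; any other non-empty set gets a generated acronym
#' `"other-"` followed by one letter per domain (L = LRR, N = NB-ARC,
#' T = TIR, K = Pkinase, A = ABC transporter, TM, C = CC) in the fixed
#' canonical order L, N, T, K, A, TM, C; a WD40 domain appends `W`
#' last. The lookup is a deterministic function of the set — hit order
#' and domain copy number never matter.
#'
#' @param domains character vector of domain categories from
#'   [collapseDomains()]; must be non-empty.
#' @return The acronym string.
#' @examples
#' classifyArchitecture(c("LRR", "NB-ARC", "CC"))   # "CNL"
#' classifyArchitecture(c("TIR", "Pkinase"))        # "other-TK"
#' @export
classifyArchitecture <- function(domains) {
  domains <- sort(unique(domains))
  if (!length(domains)) stop("empty domain set cannot be classified")
  bad <- setdiff(domains, names(.acronymLetters))
  if (length(bad))
    stop("unknown domain category: ", paste(bad, collapse = ", "))
  key <- paste(domains, collapse = ":")
  if (key %in% names(.rgaTable)) return(unname(.rgaTable[key]))
  ord <- names(.acronymLetters)
  paste0("other-",
         paste(.acronymLetters[ord[ord %in% domains]], collapse = ""))
}

#' Family group of a classified RGA
#'
#' The phylogenetic grouping used downstream: `NB` for any protein
#' containing an NB-ARC domain, `RLK` (LRR + Pkinase + TM), `RLP`
#' (LRR + TM, no kinase), `LRR_only`, `ABC` (contains ABC transporter,
#' no NB-ARC), `other_KTM` (Pkinase + TM, not RLK/RLP), else `other`.
#'
#' @param domains domain set of the protein.
#' @return One of `"NB"`, `"RLK"`, `"RLP"`, `"LRR_only"`, `"ABC"`,
#'   `"other_KTM"`, `"other"`.
#' @export
rgaFamilyGroup <- function(domains) {
  domains <- sort(unique(domains))
  acr <- classifyArchitecture(domains)
  if ("NB-ARC" %in% domains) return("NB")
  if (acr == "RLK") return("RLK")
  if (acr == "RLP") return("RLP")
  if (identical(domains, "LRR")) return("LRR_only")
  if ("ABC_tran" %in% domains) return("ABC")
  if (all(c("Pkinase", "TM") %in% domains)) return("other_KTM")
  "other"
}

#' Classify a table of candidate RGA proteins
#'
#' Runs the full evidence-to-acronym pipeline over a protein table:
#' proteins failing the upstream homology screen are skipped (with a
#' message giving the count), Pfam hits are collapsed per protein, and
#' each non-empty domain set is classified. Proteins that pass homology
#' but show no surviving domain evidence are reported with an `NA`
#' acronym.
#'
#' @param hits `data.frame` from [readDomtblout()].
#' @param flags `data.frame` with columns `protein_id`,
#'   `passed_homology`, `has_cc`, `has_tm` (one row per candidate).
#' @param cfg a [RunConfig-class].
#' @return `data.frame` with columns `protein_id`, `domains`
#'   (colon-joined), `acronym`, `group`, `n_hmm_domains`.
#' @export
classifyRgaTable <- function(hits, flags, cfg = runConfig()) {
  stopifnot(all(c("protein_id", "passed_homology", "has_cc", "has_tm")
                %in% colnames(flags)))
  skip <- !flags$passed_homology
  if (any(skip))
    message(sum(skip), " protein(s) skipped: failed homology screen")
  flags <- flags[!skip, , drop = FALSE]
  res <- lapply(seq_len(nrow(flags)), function(i) {
    pid <- flags$protein_id[i]
    h <- hits[hits$protein_id == pid, , drop = FALSE]
    dom <- collapseDomains(h, flags$has_cc[i], flags$has_tm[i], cfg)
    nHmm <- length(setdiff(dom, c("CC", "TM")))
    if (!length(dom))
      return(data.frame(protein_id = pid, domains = "", acronym = NA,
                        group = NA, n_hmm_domains = 0L))
    data.frame(protein_id = pid,
               domains = paste(dom, collapse = ":"),
               acronym = classifyArchitecture(dom),
               group = rgaFamilyGroup(dom),
               n_hmm_domains = nHmm, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Summarize RGA classes
#'
#' Per-acronym counts plus the total number of classified proteins and
#' the fraction carrying at least one HMM (non-CC/TM) domain.
#'
#' @param classification `data.frame` from [classifyRgaTable()], or a
#'   named numeric vector of per-acronym counts (e.g. a published
#'   column).
#' @return A list: `counts` (named), `total`, `fracWithHmmDomain`
#'   (`NA` when counts were supplied directly).
#' @export
summarizeClasses <- function(classification) {
  if (is.numeric(classification)) {
    counts <- classification
    return(list(counts = counts, total = sum(counts),
                fracWithHmmDomain = NA_real_))
  }
  cl <- classification[!is.na(classification$acronym), , drop = FALSE]
  counts <- table(cl$acronym)
  list(counts = counts, total = nrow(cl),
       fracWithHmmDomain = if (nrow(cl)) mean(cl$n_hmm_domains >= 1)
                           else NA_real_)
}

#' Detect chromosomal RGA clusters
#'
#' Counts the genes of a selected family group falling into fixed
#' genome windows (by gene start position) and reports the windows
#' holding at least `minClusterSize` of them, merging adjacent
#' qualifying windows into one cluster.
#'
#' @param geneRanges `GRanges` of classified RGA gene coordinates.
#' @param groups character vector parallel to `geneRanges` with the
#'   family group of each gene.
#' @param group the group to scan (one of the values of
#'   [rgaFamilyGroup()]).
#' @param chromLengths named chromosome lengths in bp.
#' @param cfg a [RunConfig-class] supplying `windowBp` and
#'   `minClusterSize`.
#' @return A list: `track` (a [WindowTrack-class] of per-window counts)
#'   and `clusters` (`data.frame` with `chrom`, `start`, `end`,
#'   `n_genes`).
#' @export
clusterRgas <- function(geneRanges, groups, group, chromLengths,
                        cfg = runConfig()) {
  valid <- c("NB", "RLK", "RLP", "LRR_only", "ABC", "other_KTM", "other")
  if (!group %in% valid)
    stop("unknown family group '", group, "'")
  sel <- geneRanges[!is.na(groups) & groups == group]
  track <- windowCount(sel, chromLengths, cfg@windowBp)
  gw <- trackWindows(track)
  v <- trackValues(track)
  ok <- v >= cfg@minClusterSize
  chrom <- as.character(seqnames(gw))
  runKey <- paste(chrom,
                  cumsum(!ok | c(TRUE, chrom[-1] != chrom[-length(chrom)])))
  out <- list()
  for (key in unique(runKey[ok])) {
    i <- which(runKey == key & ok)
    out[[length(out) + 1L]] <- data.frame(
      chrom = chrom[i[1]], start = min(start(gw)[i]),
      end = max(end(gw)[i]), n_genes = sum(v[i]),
      stringsAsFactors = FALSE)
  }
  clusters <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_genes = numeric())
  list(track = track, clusters = clusters)
}
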