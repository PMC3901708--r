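# Array-design construction, CpG counting and file readers/writers.

#' Count CpG dinucleotides and C/G mononucleotides
#'
#' Counts are case-insensitive; `N` positions are excluded from all counts
#' (an `N` also interrupts any CG dinucleotide spanning it). CG occurrences
#' cannot overlap each other, so the count is simply the number of "CG"
#' matches.
#'
#' @param sequence a character vector of nucleotide strings over
#'   `A,C,G,T,N` (any case), or a [Biostrings::DNAStringSet].
#' @return An integer matrix with one row per input sequence and columns
#'   `cpg_count`, `c_count`, `g_count`.
#' @examples
#' countCpg("CGCG")   # 2 CpGs, 2 C, 2 G
#' countCpg("cGtN")   # case-folded; N excluded
#' @export
countCpg <- function(sequence) {
  if (is.character(sequence)) {
    bad <- grepl("[^ACGTNacgtn]", sequence)
    if (any(bad))
      stop(sprintf("non-IUPAC (non A/C/G/T/N) character in sequence(s): %s",
                   paste(which(bad), collapse = ", ")))
    sequence <- Biostrings::DNAStringSet(toupper(sequence))
  } else if (!methods::is(sequence, "DNAStringSet")) {
    stop("'sequence' must be character or a DNAStringSet")
  }
  mono <- Biostrings::letterFrequency(sequence, letters = c("C", "G"))
  cpg <- Biostrings::vcountPattern("CG", sequence, fixed = TRUE)
  out <- cbind(cpg_count = as.integer(cpg),
               c_count = as.integer(mono[, "C"]),
               g_count = as.integer(mono[, "G"]))
  rownames(out) <- names(sequence)
  out
}

## Extract sequences for a GRanges from a genome (DNAStringSet keyed by
## chromosome, or FASTA path). Errors when a range leaves its chromosome.
regionSequences <- function(gr, genome) {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stop("'genome' must be a DNAStringSet or a FASTA path")
  names(genome) <- sub("\\s.*$", "", names(genome))
  chr <- as.character(GenomicRanges::seqnames(gr))
  miss <- setdiff(unique(chr), names(genome))
  if (length(miss))
    stop("chromosome(s) absent from genome: ", paste(miss, collapse = ", "))
  lens <- Biostrings::width(genome)[match(chr, names(genome))]
  if (any(GenomicRanges::start(gr) < 1L | GenomicRanges::end(gr) > lens))
    stop("range(s) outside chromosome bounds: ",
         paste(utils::head(which(GenomicRanges::start(gr) < 1L |
                                   GenomicRanges::end(gr) > lens), 5),
               collapse = ", "))
  seqs <- Biostrings::DNAStringSet(genome[chr],
                                   start = GenomicRanges::start(gr),
                                   end = GenomicRanges::end(gr))
  names(seqs) <- NULL
  seqs
}

## Fill cpg/c/g metadata columns of the probe GRanges from a genome.
addProbeCounts <- function(probes, genome) {
  cnt <- countCpg(regionSequences(probes, genome))
  probes$cpg_count <- cnt[, "cpg_count"]
  probes$c_count <- cnt[, "c_count"]
  probes$g_count <- cnt[, "g_count"]
  probes
}

#' Build a promoter tiling-array design from a TSS table
#'
#' Lays probes across a strand-aware window around every transcription
#' start site, at fixed spacing, and assigns each probe to every promoter
#' window it overlaps by at least 1 bp (so closely spaced alternative TSSs
#' of one gene share probes). Probes are centred on offsets
#' `-upstream, -upstream + spacing, ..., +downstream` along the direction
#' of transcription; probes identical in genomic coordinates are collapsed
#' and get coordinate-derived ids.
#'
#' @param tss a `data.frame` with columns `promoter_id`, `gene_id`,
#'   `chrom`, `tss` (1-based position of the TSS) and `strand`
#'   (`"+"`/`"-"`).
#' @param spacing probe spacing in bp (default 100).
#' @param upstream,downstream window extent around the TSS in bp
#'   (defaults 1000 and 200, i.e. a 1200 bp window).
#' @param probeLength probe length in bp (default 50).
#' @param genome optional genome (`DNAStringSet` named by chromosome, or a
#'   FASTA path); when supplied, per-probe CpG/C/G counts are filled.
#' @param genomeBuild label stored in the design.
#' @return An [ArrayDesign].
#' @export
buildArrayDesign <- function(tss, spacing = 100, upstream = 1000,
                             downstream = 200, probeLength = 50,
                             genome = NULL, genomeBuild = "synthetic") {
  need <- c("promoter_id", "gene_id", "chrom", "tss", "strand")
  if (!all(need %in% colnames(tss)))
    stop("'tss' needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tss$promoter_id)) stop("promoter_id values must be unique")
  if (!all(tss$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")

  plus <- tss$strand == "+"
  win_start <- ifelse(plus, tss$tss - upstream, tss$tss - downstream + 1L)
  promoters <- GenomicRanges::GRanges(
    tss$chrom,
    IRanges::IRanges(start = win_start, width = upstream + downstream),
    strand = tss$strand,
    promoter_id = tss$promoter_id, gene_id = tss$gene_id, tss = tss$tss)

  offs <- seq(-upstream, downstream, by = spacing)
  half <- floor(probeLength / 2)
  n <- nrow(tss)
  ctr <- rep(tss$tss, each = length(offs)) +
    rep(ifelse(plus, 1L, -1L), each = length(offs)) * rep(offs, n)
  pstart <- ctr - half
  probe_chrom <- rep(tss$chrom, each = length(offs))
  probe_id <- sprintf("%s:%d-%d", probe_chrom, pstart - 1L,
                      pstart + probeLength - 1L)  # BED-style id
  keep <- !duplicated(probe_id)
  probesGR <- GenomicRanges::GRanges(
    probe_chrom[keep],
    IRanges::IRanges(start = pstart[keep], width = probeLength),
    probe_id = probe_id[keep])

  ov <- GenomicRanges::findOverlaps(probesGR, promoters, minoverlap = 1L,
                                    ignore.strand = TRUE)
  probeMap <- data.frame(
    probe_id = probesGR$probe_id[S4Vectors::queryHits(ov)],
    promoter_id = promoters$promoter_id[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE)

  if (!is.null(genome)) probesGR <- addProbeCounts(probesGR, genome)
  else {
    probesGR$cpg_count <- NA_integer_
    probesGR$c_count <- NA_integer_
    probesGR$g_count <- NA_integer_
  }
  methods::new("ArrayDesign", probes = probesGR, promoters = promoters,
               probeMap = probeMap, upstream = upstream,
               downstream = downstream, genomeBuild = genomeBuild)
}

#' Read an array design from a tab-separated file
#'
#' The design file is long-format (one row per probe-promoter assignment)
#' with columns `chrom`, `start` (0-based), `end` (exclusive), `probe_id`,
#' `promoter_id`, `gene_id`, `tss` (1-based), `strand`. Coordinates are
#' converted to the internal 1-based closed convention here, exactly once.
#'
#' @param path design TSV path.
#' @param genome optional genome (`DNAStringSet` or FASTA path) for CpG
#'   counting; also enables chromosome-bound validation.
#' @param upstream,downstream promoter-window extent used to rebuild the
#'   windows from the TSS column.
#' @param genomeBuild label stored in the design.
#' @return An [ArrayDesign].
#' @export
loadArrayDesign <- function(path, genome = NULL, upstream = 1000,
                            downstream = 200, genomeBuild = "unspecified") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assertColumns(df, c("chrom", "start", "end", "probe_id", "promoter_id",
                      "gene_id", "tss", "strand"), path)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 |
                 df$end <= df$start | is.na(df$tss) | df$chrom == "" |
                 !df$strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("malformed design row(s) at line(s): %s of '%s'",
                 paste(utils::head(bad + 1L, 5), collapse = ", "), path))

  ## promoter table: one row per promoter_id, must be internally consistent
  prm <- unique(df[, c("promoter_id", "gene_id", "chrom", "tss", "strand")])
  if (anyDuplicated(prm$promoter_id))
    stop("inconsistent gene/tss/strand annotation for some promoter_id")

  prb <- unique(df[, c("probe_id", "chrom", "start", "end")])
  if (anyDuplicated(prb$probe_id))
    stop("inconsistent coordinates for some probe_id")

  probesGR <- GenomicRanges::GRanges(
    prb$chrom, IRanges::IRanges(start = prb$start + 1L, end = prb$end),
    probe_id = prb$probe_id)
  plus <- prm$strand == "+"
  win_start <- ifelse(plus, prm$tss - upstream, prm$tss - downstream + 1L)
  promoters <- GenomicRanges::GRanges(
    prm$chrom, IRanges::IRanges(start = win_start,
                                width = upstream + downstream),
    strand = prm$strand,
    promoter_id = prm$promoter_id, gene_id = prm$gene_id, tss = prm$tss)

  probeMap <- unique(df[, c("probe_id", "promoter_id")])
  if (!all(probeMap$promoter_id %in% prm$promoter_id))
    stop("design references unknown promoter_id")  # referential integrity

  if (!is.null(genome)) {
    probesGR <- addProbeCounts(probesGR, genome)
  } else if (all(c("cpg_count", "c_count", "g_count") %in% colnames(df))) {
    ## counts persisted in the file by writeArrayDesign()
    prb2 <- df[match(prb$probe_id, df$probe_id), ]
    probesGR$cpg_count <- as.integer(prb2$cpg_count)
    probesGR$c_count <- as.integer(prb2$c_count)
    probesGR$g_count <- as.integer(prb2$g_count)
    if ("coupling_cpg" %in% colnames(df))
      probesGR$coupling_cpg <- as.integer(prb2$coupling_cpg)
  } else {
    probesGR$cpg_count <- NA_integer_
    probesGR$c_count <- NA_integer_
    probesGR$g_count <- NA_integer_
  }
  methods::new("ArrayDesign", probes = probesGR, promoters = promoters,
               probeMap = probeMap, upstream = upstream,
               downstream = downstream, genomeBuild = genomeBuild)
}

#' Write an array design to the long-format TSV read by [loadArrayDesign()]
#'
#' @param design an [ArrayDesign].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeArrayDesign <- function(design, path) {
  pr <- probes(design)
  pm <- probeMap(design)
  prm <- promoterWindows(design)
  i <- match(pm$probe_id, pr$probe_id)
  j <- match(pm$promoter_id, prm$promoter_id)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(pr))[i],
    start = GenomicRanges::start(pr)[i] - 1L,  # back to 0-based half-open
    end = GenomicRanges::end(pr)[i],
    probe_id = pm$probe_id,
    promoter_id = pm$promoter_id,
    gene_id = prm$gene_id[j],
    tss = prm$tss[j],
    strand = as.character(GenomicRanges::strand(prm))[j])
  ## persist CpG counts so designs round-trip without the genome
  for (col in c("cpg_count", "c_count", "g_count", "coupling_cpg")) {
    v <- GenomicRanges::mcols(pr)[[col]]
    if (!is.null(v) && !all(is.na(v))) df[[col]] <- v[i]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-channel raw intensity table
#'
#' Expects a TSV with a `probe_id` column plus, per array, columns
#' `<array>.bound` and `<array>.input` (and optionally `<array>.bound_bg`,
#' `<array>.input_bg` background estimates). Probes present in the file but
#' absent from the design are dropped with a warning; duplicated probe rows
#' are an error. Missing values stay `NA` (never coerced to zero), and
#' negative intensities are retained -- they are handled by the offset
#' policy at normalization time and merely flagged during QC.
#'
#' @param path intensity TSV path.
#' @param design an [ArrayDesign] defining the expected probes.
#' @return A list with matrices `bound`, `input` (probes x arrays, rownames
#'   = probe ids, colnames = array ids), optional `bound_bg`/`input_bg`,
#'   and `dropped` (character vector of unknown probe ids).
#' @export
loadIntensityTable <- function(path, design) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  assertColumns(df, "probe_id", path)
  if (anyDuplicated(df$probe_id))
    stop(sprintf("duplicated probe row(s) in '%s': %s", path,
                 paste(utils::head(unique(df$probe_id[duplicated(df$probe_id)]), 3),
                       collapse = ", ")))
  known <- df$probe_id %in% probes(design)$probe_id
  dropped <- df$probe_id[!known]
  if (length(dropped)) {
    warning(sprintf("%d probe(s) not in design dropped from '%s'",
                    length(dropped), path))
    df <- df[known, , drop = FALSE]
  }
  chan_cols <- grep("\\.(bound|input|bound_bg|input_bg)$", colnames(df),
                    value = TRUE)
  if (!length(chan_cols))
    stop(sprintf("no '<array>.bound' / '<array>.input' columns in '%s'", path))
  chan <- sub("^.*\\.", "", chan_cols)
  arr <- sub("\\.(bound|input|bound_bg|input_bg)$", "", chan_cols)
  arrays <- unique(arr)
  pick <- function(which_chan) {
    cols <- chan_cols[chan == which_chan]
    if (!length(cols)) return(NULL)
    m <- as.matrix(df[, cols, drop = FALSE])
    colnames(m) <- arr[chan == which_chan]
    m <- m[, arrays[arrays %in% colnames(m)], drop = FALSE]
    rownames(m) <- df$probe_id
    storage.mode(m) <- "double"
    m
  }
  bound <- pick("bound"); input <- pick("input")
  if (is.null(bound) || is.null(input) ||
      !identical(colnames(bound), colnames(input)))
    stop(sprintf("every array in '%s' needs both a bound and an input column",
                 path))
  list(bound = bound, input = input,
       bound_bg = pick("bound_bg"), input_bg = pick("input_bg"),
       dropped = dropped)
}

#' Write intensity matrices to the TSV read by [loadIntensityTable()]
#' @param raw list as returned by [loadIntensityTable()] or
#'   [simulateMedipArrays()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIntensityTable <- function(raw, path) {
  arrays <- colnames(raw$bound)
  out <- data.frame(probe_id = rownames(raw$bound))
  for (a in arrays) {
    out[[paste0(a, ".bound")]] <- raw$bound[, a]
    out[[paste0(a, ".input")]] <- raw$input[, a]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export scored intervals as BED6
#'
#' Writes a 6-column BED (0-based half-open) with
#' `score = -10 * log10(q)` capped at 1000, the convention used for the
#' promoter-level false-discovery rate of differential-methylation calls.
#'
#' @param intervals a `GRanges` (1-based internally; converted on write)
#'   with a `name` metadata column, or names taken from `names(intervals)`.
#' @param q numeric vector of q-values in (0, 1] used for the score.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
writeDmrBed <- function(intervals, q, path) {
  stopifnot(length(intervals) == length(q))
  if (length(intervals)) {
    score <- pmin(1000, -10 * log10(pmax(q, 1e-100)))
    gr <- GenomicRanges::granges(intervals)
    nm <- intervals$name %||% names(intervals) %||%
      sprintf("region_%d", seq_along(intervals))
    gr$name <- nm
    gr$score <- score
    rtracklayer::export(gr, path, format = "BED")
  } else {
    writeLines(character(0), path)  # empty call set -> empty file
  }
  invisible(path)
}

#' Read a sample sheet CSV
#'
#' Columns: `subject_id`, `group` (`CPA`/`NPA`), `sex` (`F`/`M`),
#' `array_id` (one row per array; replicates share a subject), optional
#' `pool_id`.
#'
#' @param path CSV path.
#' @return A validated `data.frame`.
#' @export
loadSampleSheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assertColumns(df, c("subject_id", "group", "array_id"), path)
  validateSampleSheet(df)
}

validateSampleSheet <- function(df) {
  if (!all(df$group %in% c("CPA", "NPA")))
    stop("group must be 'CPA' or 'NPA'")
  if (length(unique(df$group)) < 2L)
    stop("both groups must be present in the sample sheet")
  if (anyDuplicated(df$array_id)) stop("array_id values must be unique")
  df
}
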