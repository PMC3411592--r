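# Alignment, insert-size and exome-coverage statistics: the key figures
# of the summary report (fold coverage, capture specificity, expected
# duplicates by chance).

# mapped primary records, optionally excluding flagged duplicates
mapped_primary <- function(records, exclude_duplicates = TRUE) {
  keep <- !has_flag(records$flag, FLAG_UNMAPPED) &
    !has_flag(records$flag, FLAG_SECONDARY) &
    !has_flag(records$flag, FLAG_SUPPLEMENTARY)
  if (exclude_duplicates) keep <- keep & !has_flag(records$flag, FLAG_DUPLICATE)
  records[keep, , drop = FALSE]
}

#' Basic alignment totals
#'
#' Total, mapped and unmapped read counts, plus genome fold coverage:
#' reference bases covered by mapped primary records (their CIGAR
#' footprints) divided by the genome length.
#'
#' @param sam a `sam_set`.
#' @param genome_length total reference length in bases.
#' @return A list with `total_reads`, `mapped`, `unmapped`,
#'   `genome_fold_coverage`.
#' @export
bam_stats <- function(sam, genome_length = NA_real_) {
  r <- sam$records
  primary <- !has_flag(r$flag, FLAG_SECONDARY) &
    !has_flag(r$flag, FLAG_SUPPLEMENTARY)
  r <- r[primary, , drop = FALSE]
  unmapped <- has_flag(r$flag, FLAG_UNMAPPED)
  mapped_bases <- if (any(!unmapped))
    sum(as.numeric(cigar_ref_width(r$cigar[!unmapped]))) else 0
  list(total_reads = nrow(r), mapped = sum(!unmapped),
       unmapped = sum(unmapped),
       genome_fold_coverage = if (is.na(genome_length) || genome_length <= 0)
         NA_real_ else mapped_bases / genome_length)
}

#' High-level alignment summary metrics
#'
#' Over mapped primary records: median read (query) length; the
#' fraction of records containing at least one insertion (`I`) or
#' deletion (`D`) CIGAR operation; and the number of aligned
#' (`M`/`=`/`X`-consumed) query bases in records at or above the
#' mapping-quality threshold.
#'
#' @param sam a `sam_set`.
#' @param mapq_threshold minimum MAPQ for the high-quality base count
#'   (default 20).
#' @return A list with `median_read_length`, `insertion_rate`,
#'   `deletion_rate`, `high_quality_aligned_bases`.
#' @export
alignment_summary_metrics <- function(sam, mapq_threshold = 20L) {
  r <- mapped_primary(sam$records, exclude_duplicates = FALSE)
  if (nrow(r) == 0L)
    return(list(median_read_length = NA_real_, insertion_rate = NA_real_,
                deletion_rate = NA_real_, high_quality_aligned_bases = 0))
  qlen <- ifelse(r$seq == "*",
                 GenomicAlignments::cigarWidthAlongQuerySpace(r$cigar),
                 nchar(r$seq))
  hq <- r$mapq >= mapq_threshold
  aligned <- if (any(hq)) {
    ops <- GenomicAlignments::explodeCigarOps(r$cigar[hq])
    lens <- GenomicAlignments::explodeCigarOpLengths(r$cigar[hq])
    sum(as.numeric(unlist(mapply(function(o, l) l[o %in% c("M", "=", "X")],
                                 ops, lens, SIMPLIFY = FALSE))))
  } else 0
  list(median_read_length = stats::median(qlen),
       insertion_rate = mean(grepl("I", r$cigar, fixed = TRUE)),
       deletion_rate = mean(grepl("D", r$cigar, fixed = TRUE)),
       high_quality_aligned_bases = aligned)
}

#' Insert-size metrics for paired-end data
#'
#' One observation per fragment: only proper-pair records with positive
#' TLEN are counted.  Fragments with `|TLEN|` above `outlier_factor`
#' times the median are excluded from the mean and standard deviation
#' (chimeric pairs otherwise dominate); the histogram keeps every
#' observation.
#'
#' @param sam a `sam_set`.
#' @param outlier_factor multiple of the median beyond which a fragment
#'   is excluded from mean/sd (default 10; `Inf` disables).
#' @return A list with `n`, `mean`, `median`, `sd` and `histogram`
#'   (data.frame `insert_size`, `count`); empty with a notice for
#'   single-end input.
#' @export
insert_size_metrics <- function(sam, outlier_factor = 10) {
  r <- sam$records
  obs <- r$tlen[has_flag(r$flag, FLAG_PROPER_PAIR) & r$tlen > 0L]
  if (length(obs) == 0L) {
    message("insert_size_metrics: no proper pairs (single-end data?)")
    return(list(n = 0L, mean = NA_real_, median = NA_real_, sd = NA_real_,
                histogram = data.frame(insert_size = integer(),
                                       count = integer())))
  }
  med <- stats::median(obs)
  core <- obs[obs <= outlier_factor * med]
  hist_df <- as.data.frame(table(insert_size = obs), stringsAsFactors = FALSE)
  hist_df$insert_size <- as.integer(hist_df$insert_size)
  names(hist_df)[2] <- "count"
  list(n = length(obs), mean = mean(core), median = med,
       sd = stats::sd(core), histogram = hist_df)
}

#' Per-exon read counts and fold coverage
#'
#' For every target interval: the number of overlapping reads (same
#' overlap rule as [filter_on_target()]), the number of interval bases
#' covered by at least one read, and fold coverage = aligned bases
#' attributed to the interval / interval length, where attribution
#' intersects each record's reference footprint with the interval.
#' Aggregate exome fold coverage is total on-target aligned bases over
#' total target length (not the mean of per-interval folds).  Flagged
#' duplicates are ignored.
#'
#' @param sam a `sam_set`.
#' @param targets capture-region `GRanges` (normalized internally;
#'   interval names are preserved when unambiguous).
#' @param min_overlap minimum overlap for the per-interval read count.
#' @param genome_length optional genome length for the aggregate genome
#'   fold coverage.
#' @param low_threshold,high_threshold fold-coverage bin edges for the
#'   "not covered" and "highly covered" interval fractions (defaults 1
#'   and 20).
#' @return A list of class `coverage_profile` with `per_interval` (a
#'   data.frame) and `aggregate` (named list).
#' @export
exon_coverage <- function(sam, targets, min_overlap = 1L,
                          genome_length = NA_real_,
                          low_threshold = 1, high_threshold = 20) {
  norm <- normalize_targets(targets)
  if (length(norm) == length(targets) && !is.null(targets$name)) {
    ord <- GenomicRanges::match(norm, GenomicRanges::sort(targets))
    norm$name <- GenomicRanges::sort(targets)$name[ord]
  } else if (length(norm) > 0L) {
    norm$name <- paste0("target_", seq_along(norm))
  }
  r <- mapped_primary(sam$records)
  nt <- length(norm)
  read_count <- integer(nt); bases <- numeric(nt); covered <- numeric(nt)
  total_aligned <- 0
  if (nrow(r) > 0L) {
    fp <- footprint_granges(r)
    total_aligned <- sum(as.numeric(GenomicRanges::width(fp)))
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(fp, norm, minoverlap = min_overlap))
    rc <- table(factor(S4Vectors::subjectHits(hits), levels = seq_len(nt)))
    read_count <- as.integer(rc)
    # aligned-base attribution: any overlap counts its intersection width
    hits1 <- suppressWarnings(GenomicRanges::findOverlaps(fp, norm))
    ov_w <- GenomicRanges::width(IRanges::pintersect(
      fp[S4Vectors::queryHits(hits1)], norm[S4Vectors::subjectHits(hits1)]))
    bases <- as.numeric(tapply(ov_w,
      factor(S4Vectors::subjectHits(hits1), levels = seq_len(nt)), sum))
    bases[is.na(bases)] <- 0
    # covered bases need per-position depth; Rle coverage per chromosome
    cov <- GenomicRanges::coverage(fp)
    for (chrom in unique(as.character(GenomicRanges::seqnames(norm)))) {
      idx <- which(as.character(GenomicRanges::seqnames(norm)) == chrom)
      if (!chrom %in% names(cov)) next
      v <- cov[[chrom]]
      for (i in idx) {
        s <- GenomicRanges::start(norm)[i]; e <- GenomicRanges::end(norm)[i]
        if (s > length(v)) next
        seg <- S4Vectors::window(v, s, min(e, length(v)))
        covered[i] <- sum(S4Vectors::runLength(seg)[S4Vectors::runValue(seg) > 0])
      }
    }
  }
  w <- GenomicRanges::width(norm)
  per <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(norm)),
    start = GenomicRanges::start(norm) - 1L,    # report BED-style 0-based
    end = GenomicRanges::end(norm),
    name = if (nt > 0L) norm$name else character(),
    length = w,
    read_count = read_count,
    covered_bases = covered,
    aligned_bases = bases,
    fold_coverage = ifelse(w > 0L, bases / w, NA_real_),
    stringsAsFactors = FALSE)
  agg <- list(
    exome_size = sum(as.numeric(w)),
    n_intervals = nt,
    exome_fold_coverage = if (nt > 0L) sum(bases) / sum(as.numeric(w)) else NA_real_,
    genome_fold_coverage = if (is.na(genome_length) || genome_length <= 0)
      NA_real_ else total_aligned / genome_length,
    fraction_intervals_below = if (nt > 0L)
      mean(per$fold_coverage < low_threshold) else NA_real_,
    fraction_intervals_at_or_above = if (nt > 0L)
      mean(per$fold_coverage >= high_threshold) else NA_real_)
  structure(list(per_interval = per, aggregate = agg),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile:", x$aggregate$n_intervals, "intervals,",
      sprintf("exome fold %.2f\n", x$aggregate$exome_fold_coverage))
  invisible(x)
}

#' Exome capture specificity
#'
#' The fraction of mapped, non-duplicate reads overlapping the capture
#' targets; computed after duplicate removal.  With `unit = "bases"`
#' the fraction of aligned footprint bases falling inside targets is
#' reported instead.
#'
#' @param sam a `sam_set`.
#' @param targets capture-region `GRanges`.
#' @param min_overlap minimum overlap in bases for a read to count as
#'   on-target.
#' @param unit `"reads"` (default) or `"bases"`.
#' @return Fraction in `[0, 1]`, or `NA` when no read is mapped.
#' @export
capture_specificity <- function(sam, targets, min_overlap = 1L,
                                unit = c("reads", "bases")) {
  unit <- match.arg(unit)
  targets <- normalize_targets(targets)
  r <- mapped_primary(sam$records)
  if (nrow(r) == 0L) return(NA_real_)
  fp <- footprint_granges(r)
  if (unit == "reads") {
    on <- suppressWarnings(
      IRanges::overlapsAny(fp, targets, minoverlap = min_overlap))
    sum(on) / nrow(r)
  } else {
    hits <- suppressWarnings(GenomicRanges::findOverlaps(fp, targets))
    ov <- sum(as.numeric(GenomicRanges::width(IRanges::pintersect(
      fp[S4Vectors::queryHits(hits)], targets[S4Vectors::subjectHits(hits)]))))
    ov / sum(as.numeric(GenomicRanges::width(fp)))
  }
}

#' Expected PCR duplicates arising by chance
#'
#' Under uniform placement of `n_reads` fragments over `n_start_sites`
#' distinguishable start sites (by default both strands of the target
#' space), the expected number of occupied sites is
#' `P (1 - (1 - 1/P)^n)`; every read beyond the first at a site is
#' flagged, so the expected flagged count is
#' `n - P (1 - (1 - 1/P)^n)`.
#'
#' @param n_reads number of mapped reads.
#' @param n_start_sites number of distinguishable start sites `P`
#'   (default convention: 2 x target length).
#' @return Expected number of reads flagged as duplicates.
#' @export
expected_duplicates_by_chance <- function(n_reads, n_start_sites) {
  if (n_start_sites <= 0) stop("n_start_sites must be positive")
  if (n_reads <= 0) return(0)
  n <- as.numeric(n_reads); P <- as.numeric(n_start_sites)
  # expm1/log1p keep precision when 1/P is tiny
  n + P * expm1(n * log1p(-1 / P))
}
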