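# Read QC statistics, trimmers and filters with per-stage accounting.
#
# Stage order follows the pipeline convention: trimmers first (so length
# is checked post-trim), then the length / N-fraction / quality-fraction
# filters applied sequentially.  For paired-end data a pair is dropped
# whenever either mate fails a filter, keeping the surviving files
# aligner-ready.

#' Per-stage filter accounting row
#'
#' Bookkeeping emitted by every trimming and filtering stage:
#' `input = passed + removed` always holds, and `passed_percent` is
#' `100 * passed / input` (an empty stage reports 100% with zero
#' counts).
#'
#' @param stage stage name.
#' @param input number of reads entering the stage.
#' @param passed number of reads surviving the stage.
#' @return A one-row data.frame with columns `stage`, `input`,
#'   `passed`, `removed`, `passed_percent`.
#' @export
filter_accounting <- function(stage, input, passed) {
  input <- as.integer(input); passed <- as.integer(passed)
  stopifnot(passed <= input, passed >= 0L)
  data.frame(stage = stage, input = input, passed = passed,
             removed = input - passed,
             passed_percent = if (input == 0L) 100 else 100 * passed / input,
             stringsAsFactors = FALSE)
}

#' Summary statistics for a set of reads
#'
#' Computes the raw-read overview the quality report is built from:
#' read count, read-length distribution, per-position base composition,
#' per-position mean quality, and unidentified-call (`N`) statistics.
#'
#' @param reads a [read_set()].
#' @return A list of class `read_qc_stats` with elements `read_count`,
#'   `length_histogram` (data.frame `length`, `count`),
#'   `per_position_base_counts` (matrix, rows `A,C,G,T,N,other`),
#'   `per_position_mean_quality` (numeric vector) and `n_stats`
#'   (`reads_with_n`, `n_fraction_histogram`).
#' @export
read_qc_stats <- function(reads) {
  n <- nrow(reads)
  len <- read_lengths(reads)
  lh <- as.data.frame(table(length = len), stringsAsFactors = FALSE)
  lh$length <- as.integer(lh$length)
  names(lh)[2] <- "count"
  maxlen <- if (n > 0L) max(nchar(reads$bases)) else 0L
  base_levels <- c("A", "C", "G", "T", "N", "other")
  bc <- matrix(0L, nrow = length(base_levels), ncol = maxlen,
               dimnames = list(base_levels, NULL))
  mq <- numeric(0)
  if (n > 0L && maxlen > 0L) {
    chars <- strsplit(reads$bases, "", fixed = TRUE)
    pos <- unlist(lapply(nchar(reads$bases), seq_len), use.names = FALSE)
    ch <- unlist(chars, use.names = FALSE)
    ch[!ch %in% base_levels[1:5]] <- "other"
    tab <- table(factor(ch, levels = base_levels), factor(pos, levels = seq_len(maxlen)))
    bc[] <- as.integer(tab)
    qlen <- lengths(reads$quals)
    qmax <- max(qlen, 0L)
    if (qmax > 0L) {
      qpos <- unlist(lapply(qlen, seq_len), use.names = FALSE)
      qv <- unlist(reads$quals, use.names = FALSE)
      mq <- as.numeric(tapply(qv, factor(qpos, levels = seq_len(qmax)), mean))
      mq[is.na(mq)] <- NaN
    }
  }
  n_count <- if (n > 0L) {
    vapply(gregexpr("N", reads$bases, fixed = TRUE), function(m)
      sum(m > 0L), integer(1))
  } else integer(0)
  nfrac <- as.numeric(ifelse(len > 0L, n_count / len, 0))
  nfrac_hist <- if (length(nfrac) == 0L) integer(20L) else
    graphics::hist(nfrac, breaks = seq(0, 1, 0.05), plot = FALSE,
                   right = TRUE)$counts
  structure(list(
    read_count = n,
    length_histogram = lh,
    per_position_base_counts = bc,
    per_position_mean_quality = mq,
    n_stats = list(
      reads_with_n = sum(n_count > 0L),
      n_fraction_histogram = nfrac_hist)
  ), class = "read_qc_stats")
}

#' @export
print.read_qc_stats <- function(x, ...) {
  cat("read_qc_stats:", x$read_count, "reads;",
      x$n_stats$reads_with_n, "with >=1 N\n")
  invisible(x)
}

#' Trim leading and trailing runs of one nucleotide
#'
#' Removes the maximal run of `base` from both ends of every read,
#' trimming qualities in lockstep; interior occurrences are untouched.
#' A read consisting only of `base` trims to an empty read (removed
#' later by the length filter).  Colour-space reads have no per-position
#' nucleotide identity, so the trimmer is inapplicable and returns them
#' unchanged with a notice.
#'
#' @param reads a [read_set()].
#' @param base single character to trim (default `"N"`).
#' @return The trimmed `read_set`.
#' @export
trim_nucleotide <- function(reads, base = "N") {
  stopifnot(nchar(base) == 1L)
  if (identical(attr(reads, "encoding"), "solid")) {
    message("trim_nucleotide: colour-space reads have no base identity; skipped")
    return(reads)
  }
  if (nrow(reads) == 0L) return(reads)
  b <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", base)
  lead <- attr(regexpr(paste0("^", b, "+"), reads$bases), "match.length")
  lead[lead < 0L] <- 0L
  trail <- attr(regexpr(paste0(b, "+$"), reads$bases), "match.length")
  trail[trail < 0L] <- 0L
  n <- nchar(reads$bases)
  trail <- pmin(trail, n - lead)   # all-`base` read: count the run once
  from <- lead + 1L
  to <- n - trail
  bases <- substr(reads$bases, from, to)
  quals <- mapply(function(q, f, t) if (t < f) integer() else q[f:t],
                  reads$quals, from, to, SIMPLIFY = FALSE)
  replace_seq(reads, bases, quals)
}

#' Trim the Read Segment Quality Control Indicator tail
#'
#' Illumina 1.3+/1.5+ mark unreliable read tails by assigning Phred
#' quality 2 (the `B` character in Phred+64).  This trimmer removes the
#' maximal trailing run of quality-2 positions; leading or interior
#' quality-2 calls are untouched.
#'
#' @param reads a [read_set()].
#' @return The trimmed `read_set`.
#' @export
trim_rsqci <- function(reads) {
  trim_trailing(reads, function(q) q == 2L)
}

#' Truncate reads to a maximum length
#'
#' 3' truncation: positions beyond `max_len` are dropped.
#'
#' @param reads a [read_set()].
#' @param max_len maximum retained length.
#' @return The truncated `read_set`.
#' @export
trim_to_length <- function(reads, max_len) {
  stopifnot(max_len >= 0L)
  if (nrow(reads) == 0L) return(reads)
  solid <- identical(attr(reads, "encoding"), "solid")
  keep_bases <- if (solid) max_len + 1L else max_len
  bases <- substr(reads$bases, 1L, keep_bases)
  quals <- lapply(reads$quals, function(q) utils::head(q, max_len))
  replace_seq(reads, bases, quals)
}

#' Trim low-quality read tails
#'
#' Removes the maximal trailing run of positions with quality below
#' `q_threshold`.
#'
#' @param reads a [read_set()].
#' @param q_threshold Phred threshold; trailing positions with
#'   `q < q_threshold` are removed.
#' @return The trimmed `read_set`.
#' @export
trim_quality <- function(reads, q_threshold) {
  trim_trailing(reads, function(q) q < q_threshold)
}

# drop the maximal trailing run of positions where pred(qual) is TRUE
trim_trailing <- function(reads, pred) {
  if (nrow(reads) == 0L) return(reads)
  solid <- identical(attr(reads, "encoding"), "solid")
  keep <- vapply(reads$quals, function(q) {
    bad <- pred(q)
    k <- length(q)
    while (k > 0L && bad[k]) k <- k - 1L
    k
  }, numeric(1))
  bases <- substr(reads$bases, 1L, if (solid) keep + 1L else keep)
  quals <- mapply(function(q, k) utils::head(q, k), reads$quals, keep,
                  SIMPLIFY = FALSE)
  replace_seq(reads, bases, quals)
}

#' Minimum-length read filter
#'
#' Fails reads shorter than `min_len`; a read of exactly `min_len`
#' passes.
#'
#' @param reads a [read_set()].
#' @param min_len minimum length (default 25).
#' @return Logical vector, `TRUE` for passing reads.
#' @export
filter_length <- function(reads, min_len = 25L) {
  read_lengths(reads) >= min_len
}

#' Unidentified-base-call filter
#'
#' Fails reads in which more than `max_frac` of positions are
#' unidentified calls (`N` in nucleotide space, `.` in colour space);
#' a read at exactly the threshold fraction passes.
#'
#' @param reads a [read_set()].
#' @param max_frac maximum tolerated fraction (default 0.05).
#' @return Logical vector, `TRUE` for passing reads.
#' @export
filter_nmax <- function(reads, max_frac = 0.05) {
  solid <- identical(attr(reads, "encoding"), "solid")
  pat <- if (solid) "." else "N"
  n_count <- vapply(gregexpr(pat, reads$bases, fixed = TRUE), function(m)
    sum(m > 0L), integer(1))
  len <- read_lengths(reads)
  ifelse(len > 0L, n_count / len <= max_frac, n_count == 0L)
}

#' Unreliable-base-call filter
#'
#' Fails reads in which more than `max_frac` of positions have quality
#' below `q_unreliable`; the boundary fraction passes.
#'
#' @param reads a [read_set()].
#' @param q_unreliable Phred value below which a call counts as
#'   unreliable (default 20).
#' @param max_frac maximum tolerated fraction (default 0.05).
#' @return Logical vector, `TRUE` for passing reads.
#' @export
filter_quality <- function(reads, q_unreliable = 20L, max_frac = 0.05) {
  low <- vapply(reads$quals, function(q) sum(q < q_unreliable), integer(1))
  len <- lengths(reads$quals)
  ifelse(len > 0L, low / len <= max_frac, low == 0L)
}

#' Preprocessing configuration
#'
#' @param trim_n trim leading/trailing `N` runs.
#' @param trim_rsqci trim quality-2 tails.
#' @param trim_quality_threshold Phred threshold for tail quality
#'   trimming, or `NULL` to disable.
#' @param trim_length maximum read length, or `NULL` to disable.
#' @param min_length minimum post-trim length (default 25).
#' @param max_n_frac maximum unidentified-call fraction (default 0.05).
#' @param lowq_threshold Phred value below which a call is unreliable
#'   (default 20).
#' @param max_lowq_frac maximum unreliable-call fraction (default 0.05).
#' @return A named list of class `preprocess_config`.
#' @export
preprocess_config <- function(trim_n = TRUE, trim_rsqci = TRUE,
                              trim_quality_threshold = NULL,
                              trim_length = NULL,
                              min_length = 25L, max_n_frac = 0.05,
                              lowq_threshold = 20L, max_lowq_frac = 0.05) {
  structure(list(trim_n = trim_n, trim_rsqci = trim_rsqci,
                 trim_quality_threshold = trim_quality_threshold,
                 trim_length = trim_length, min_length = min_length,
                 max_n_frac = max_n_frac, lowq_threshold = lowq_threshold,
                 max_lowq_frac = max_lowq_frac),
            class = "preprocess_config")
}

# strip mate decorations so R1/R2 identifiers can be compared
strip_mate_tag <- function(id) {
  sub("(/[12]|[_.][Rr][12])$", "", id)
}

#' Run the full preprocessing chain
#'
#' Applies the configured trimmers then the three filters sequentially,
#' emitting a [filter_accounting()] row per stage and QC statistics on
#' the raw and the surviving reads.  For paired-end input the two
#' streams must match in length and identifier order (mate decorations
#' `/1`, `/2`, `_R1`, `_R2` are ignored); a pair is removed whenever
#' either mate fails a filter and both mates are counted removed at that
#' stage.
#'
#' @param r1 a [read_set()] (single-end reads, or first mates).
#' @param r2 second-mate `read_set`, or `NULL` for single-end data.
#' @param config a [preprocess_config()].
#' @return A list with elements `r1`, `r2` (surviving reads),
#'   `accounting` (data.frame of per-stage rows), `qc_before`,
#'   `qc_after`.
#' @export
run_preprocess <- function(r1, r2 = NULL, config = preprocess_config()) {
  paired <- !is.null(r2)
  if (paired) {
    if (nrow(r1) != nrow(r2))
      stop("paired-end streams differ in length (", nrow(r1), " vs ",
           nrow(r2), ")")
    mism <- which(strip_mate_tag(r1$id) != strip_mate_tag(r2$id))
    if (length(mism) > 0L)
      stop("paired-end identifier mismatch at record ", mism[1L], ": '",
           r1$id[mism[1L]], "' vs '", r2$id[mism[1L]], "'")
  }
  qc_before <- if (paired) read_qc_stats(rbind_reads(r1, r2)) else read_qc_stats(r1)

  acct <- list()
  count_in <- nrow(r1) * (1L + paired)

  apply_trimmer <- function(stage, fn) {
    r1 <<- fn(r1)
    if (paired) r2 <<- fn(r2)
    acct[[length(acct) + 1L]] <<- filter_accounting(stage, count_in, count_in)
  }
  if (isTRUE(config$trim_n)) apply_trimmer("trim-n", trim_nucleotide)
  if (isTRUE(config$trim_rsqci)) apply_trimmer("trim-rsqci", trim_rsqci)
  if (!is.null(config$trim_quality_threshold))
    apply_trimmer("trim-quality", function(r)
      trim_quality(r, config$trim_quality_threshold))
  if (!is.null(config$trim_length))
    apply_trimmer("trim-length", function(r)
      trim_to_length(r, config$trim_length))

  apply_filter <- function(stage, fn) {
    pass <- fn(r1)
    if (paired) pass <- pass & fn(r2)
    n_in <- nrow(r1) * (1L + paired)
    r1 <<- subset_reads(r1, pass)
    if (paired) r2 <<- subset_reads(r2, pass)
    n_out <- nrow(r1) * (1L + paired)
    acct[[length(acct) + 1L]] <<- filter_accounting(stage, n_in, n_out)
  }
  apply_filter("min-length-filter", function(r)
    filter_length(r, config$min_length))
  apply_filter("n-max-filter", function(r)
    filter_nmax(r, config$max_n_frac))
  apply_filter("quality-filter", function(r)
    filter_quality(r, config$lowq_threshold, config$max_lowq_frac))

  qc_after <- if (paired) read_qc_stats(rbind_reads(r1, r2)) else read_qc_stats(r1)
  list(r1 = r1, r2 = if (paired) r2 else NULL,
       accounting = do.call(rbind, acct),
       qc_before = qc_before, qc_after = qc_after)
}

rbind_reads <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  structure(out, encoding = attr(a, "encoding"), mate = "none",
            class = c("read_set", "data.frame"))
}

#' Write per-stage accounting as TSV
#'
#' @param accounting data.frame of [filter_accounting()] rows.
#' @param path output path.
#' @export
write_accounting <- function(accounting, path) {
  out <- accounting
  out$passed_percent <- sprintf("%.1f", out$passed_percent)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
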