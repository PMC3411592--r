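# Alignment filtering chain: unmapped/secondary removal, proper-pair
# filter, coordinate-based PCR-duplicate marking, and on-target
# (exome-region) selection, each with per-stage accounting.

# reference width consumed by a CIGAR (M/D/N/=/X)
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

# leading/trailing clip lengths (soft + hard)
cigar_clips <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  lead <- mapply(function(o, l) {
    k <- 0L
    for (i in seq_along(o)) {
      if (o[i] %in% c("S", "H")) k <- k + l[i] else break
    }
    k
  }, ops, lens)
  trail <- mapply(function(o, l) {
    k <- 0L
    for (i in rev(seq_along(o))) {
      if (o[i] %in% c("S", "H")) k <- k + l[i] else break
    }
    k
  }, ops, lens)
  list(lead = as.integer(lead), trail = as.integer(trail))
}

#' Unclipped 5' start of mapped records
#'
#' The coordinate identifying the sequenced fragment end that
#' duplicate marking keys on: for forward-strand records the leftmost
#' mapped position minus any leading clip (soft or hard); for
#' reverse-strand records the rightmost mapped position plus any
#' trailing clip.  Independent of base qualities and read names.
#'
#' @param records SAM record data.frame (from a `sam_set`).
#' @return Integer vector of unclipped 5' positions.
#' @export
unclipped_start <- function(records) {
  clips <- cigar_clips(records$cigar)
  rev_strand <- has_flag(records$flag, FLAG_REVERSE)
  fwd <- records$pos - clips$lead
  rev5 <- records$pos + cigar_ref_width(records$cigar) - 1L + clips$trail
  as.integer(ifelse(rev_strand, rev5, fwd))
}

# sum of base qualities of a Phred+33 quality string ('*' scores 0)
qual_sum <- function(qual) {
  vapply(qual, function(s) {
    if (identical(s, "*") || !nzchar(s)) 0L else sum(utf8ToInt(s) - 33L)
  }, integer(1), USE.NAMES = FALSE)
}

# reference footprint of mapped records as GRanges (contiguous span of
# reference-consuming CIGAR ops)
footprint_granges <- function(records) {
  w <- cigar_ref_width(records$cigar)
  GenomicRanges::GRanges(records$rname,
                         IRanges::IRanges(start = records$pos, width = w))
}

#' Remove unmapped and secondary alignments
#'
#' Records with the unmapped flag set are removed, as are secondary and
#' supplementary alignments (downstream coverage statistics must not
#' double-count a read).
#'
#' @param sam a `sam_set`.
#' @return `list(sam = kept sam_set, accounting = one-row data.frame)`.
#' @export
filter_unmapped <- function(sam) {
  r <- sam$records
  keep <- !has_flag(r$flag, FLAG_UNMAPPED) &
    !has_flag(r$flag, FLAG_SECONDARY) &
    !has_flag(r$flag, FLAG_SUPPLEMENTARY)
  list(sam = sam_set(sam$header, r[keep, , drop = FALSE]),
       accounting = filter_accounting("unmapped-filter", nrow(r), sum(keep)))
}

#' Remove improperly paired records
#'
#' Paired records lacking the proper-pair flag are removed.  Single-end
#' input (no record with the paired flag) passes through unchanged with
#' a notice.
#'
#' @param sam a `sam_set`.
#' @return `list(sam, accounting)` as in [filter_unmapped()].
#' @export
filter_proper_pair <- function(sam) {
  r <- sam$records
  if (!any(has_flag(r$flag, FLAG_PAIRED))) {
    message("filter_proper_pair: single-end data; no-op")
    return(list(sam = sam,
                accounting = filter_accounting("proper-pair-filter",
                                               nrow(r), nrow(r))))
  }
  keep <- has_flag(r$flag, FLAG_PROPER_PAIR)
  list(sam = sam_set(sam$header, r[keep, , drop = FALSE]),
       accounting = filter_accounting("proper-pair-filter", nrow(r), sum(keep)))
}

#' Mark (or remove) PCR duplicates
#'
#' Coordinate-based duplicate detection: records are grouped by the
#' duplicate key (reference, strand, unclipped 5' start; for pairs the
#' canonically ordered pair of both mates' triples, so a fragment is
#' flagged as a unit).  Within each group the record or pair with the
#' highest sum of base qualities is kept unflagged, ties broken by
#' lexicographically smallest query name; all others get the duplicate
#' flag.  The result is independent of input record order.
#'
#' Records are expected mapped and primary (run [filter_unmapped()]
#' first).  A paired record whose mate is missing from the input or
#' unmapped is keyed on its own coordinates like a single-end record
#' (but never pooled with true single-end records).
#'
#' @param sam a `sam_set`.
#' @param drop if `TRUE`, duplicates are removed; otherwise they stay
#'   with flag bit 0x400 set.
#' @return `list(sam, accounting)`; accounting counts flagged records
#'   as removed.
#' @export
mark_duplicates <- function(sam, drop = FALSE) {
  r <- sam$records
  n <- nrow(r)
  if (n == 0L)
    return(list(sam = sam,
                accounting = filter_accounting("duplicate-filter", 0L, 0L)))
  r$flag <- bitwAnd(r$flag, bitwNot(FLAG_DUPLICATE))  # reset stale flags

  end_key <- paste(r$rname,
                   ifelse(has_flag(r$flag, FLAG_REVERSE), "-", "+"),
                   unclipped_start(r))
  paired <- has_flag(r$flag, FLAG_PAIRED) & !has_flag(r$flag, FLAG_MATE_UNMAPPED)

  # units: a full pair (both mates present) is one unit; everything else
  # is a singleton unit
  unit_id <- seq_len(n)
  qn <- r$qname
  pair_rows <- which(paired)
  if (length(pair_rows) > 0L) {
    by_name <- split(pair_rows, qn[pair_rows])
    for (rows in by_name) {
      if (length(rows) == 2L) unit_id[rows] <- rows[1L]
    }
  }
  units <- split(seq_len(n), unit_id)
  unit_key <- vapply(units, function(rows) {
    k <- sort(end_key[rows])
    paste0(if (length(rows) == 2L) "P:" else
             if (paired[rows[1L]]) "p1:" else "S:",
           paste(k, collapse = "|"))
  }, character(1))
  unit_score <- vapply(units, function(rows) sum(qual_sum(r$qual[rows])),
                       numeric(1))
  unit_qname <- vapply(units, function(rows) qn[rows[1L]], character(1))

  dup_unit <- logical(length(units))
  for (grp in split(seq_along(units), unit_key)) {
    if (length(grp) < 2L) next
    best <- grp[order(-unit_score[grp], unit_qname[grp])][1L]
    dup_unit[setdiff(grp, best)] <- TRUE
  }
  dup <- logical(n)
  dup[unlist(units[dup_unit], use.names = FALSE)] <- TRUE

  r$flag[dup] <- bitwOr(r$flag[dup], FLAG_DUPLICATE)
  out <- if (drop) r[!dup, , drop = FALSE] else r
  list(sam = sam_set(sam$header, out),
       accounting = filter_accounting("duplicate-filter", n, n - sum(dup)))
}

#' Keep only records overlapping the capture targets
#'
#' A record is kept iff its reference footprint (the contiguous span of
#' reference-consuming CIGAR operations, so deletions count) overlaps
#' any target interval by at least `min_overlap` bases.  Records on
#' reference sequences absent from the target set are counted
#' off-target (with a notice).
#'
#' @param sam a `sam_set` of mapped records.
#' @param targets a `GRanges` of capture regions; normalized internally
#'   ([normalize_targets()]).
#' @param min_overlap minimum overlap in bases (default 1).
#' @return `list(sam, accounting)`.
#' @export
filter_on_target <- function(sam, targets, min_overlap = 1L) {
  r <- sam$records
  targets <- normalize_targets(targets)
  if (nrow(r) == 0L)
    return(list(sam = sam,
                accounting = filter_accounting("exome-filter", 0L, 0L)))
  fp <- footprint_granges(r)
  unknown <- !(r$rname %in% as.character(unique(GenomicRanges::seqnames(targets))))
  if (any(unknown))
    message("filter_on_target: ", sum(unknown),
            " record(s) on reference sequences absent from the target set")
  keep <- rep(FALSE, nrow(r))
  # differing seqlevel universes are expected here, not a data problem
  keep[!unknown] <- suppressWarnings(
    IRanges::overlapsAny(fp[!unknown], targets, minoverlap = min_overlap))
  list(sam = sam_set(sam$header, r[keep, , drop = FALSE]),
       accounting = filter_accounting("exome-filter", nrow(r), sum(keep)))
}

#' Run the full alignment-filter chain
#'
#' Applies, in order: unmapped/secondary removal, the proper-pair
#' filter (paired-end data only), duplicate marking, and the on-target
#' filter, collecting one accounting row per stage.
#'
#' @param sam a `sam_set`.
#' @param targets capture-region `GRanges`.
#' @param drop_duplicates remove duplicates rather than only flagging
#'   them (default `TRUE`).  With `FALSE` flagged records stay in the
#'   output and the end-to-end survivor count exceeds input minus
#'   per-stage removals by the flagged count; coverage and specificity
#'   functions skip flagged records either way.
#' @param min_overlap minimum target overlap in bases.
#' @return `list(sam, accounting)` where `accounting` stacks all stage
#'   rows in order.
#' @export
run_alnfilter <- function(sam, targets, drop_duplicates = TRUE,
                          min_overlap = 1L) {
  acct <- list()
  s1 <- filter_unmapped(sam)
  acct[[1]] <- s1$accounting
  s2 <- filter_proper_pair(s1$sam)
  acct[[2]] <- s2$accounting
  s3 <- mark_duplicates(s2$sam, drop = drop_duplicates)
  acct[[3]] <- s3$accounting
  s4 <- filter_on_target(s3$sam, targets, min_overlap = min_overlap)
  acct[[4]] <- s4$accounting
  list(sam = s4$sam, accounting = do.call(rbind, acct))
}
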