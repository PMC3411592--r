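# Independent brute-force oracles and small fixture builders.  Every
# oracle re-derives its quantity from first principles (own CIGAR
# parsing, per-base arrays, O(N^2) comparisons) so it shares no code
# path with the implementation it checks.

# --- quality conversion oracle -----------------------------------------

# Solexa -> Phred through explicit probability space: Solexa quality is
# -10*log10(p/(1-p)); recover the error probability, then re-express it
# on the Phred scale, rounding half-up.
oracle_solexa_to_phred <- function(q_solexa) {
  p_err <- 1 / (1 + 10^(q_solexa / 10))
  phred <- -10 * log10(p_err)
  floor(phred + 0.5)
}

# --- own CIGAR parsing (regex based, no GenomicAlignments) -------------

parse_cigar_ops <- function(cigar) {
  m <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar)[[1]]
  parts <- regmatches(cigar, gregexpr("([0-9]+)([MIDNSHP=X])", cigar))[[1]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", parts)),
       op = sub("^[0-9]+", "", parts))
}

oracle_ref_span <- function(cigar) {
  ops <- parse_cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

oracle_lead_clip <- function(cigar) {
  ops <- parse_cigar_ops(cigar)
  k <- 0L
  for (i in seq_along(ops$op)) {
    if (ops$op[i] %in% c("S", "H")) k <- k + ops$len[i] else break
  }
  k
}

oracle_trail_clip <- function(cigar) {
  ops <- parse_cigar_ops(cigar)
  k <- 0L
  for (i in rev(seq_along(ops$op))) {
    if (ops$op[i] %in% c("S", "H")) k <- k + ops$len[i] else break
  }
  k
}

# --- per-base exome coverage oracle ------------------------------------

# depth accumulation into a plain integer array; targets given 1-based
# closed; returns per-target read_count / covered / aligned bases and
# the aggregate fold.
oracle_exon_coverage <- function(records, target_start, target_end,
                                 genome_length, min_overlap = 1L) {
  depth <- integer(genome_length)
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(nrow(records))) {
    fl <- records$flag[i]
    if (bitwAnd(fl, 0x4L) != 0L || bitwAnd(fl, 0x100L) != 0L ||
        bitwAnd(fl, 0x400L) != 0L || bitwAnd(fl, 0x800L) != 0L) next
    s <- records$pos[i]
    e <- s + oracle_ref_span(records$cigar[i]) - 1L
    depth[s:e] <- depth[s:e] + 1L
    starts <- c(starts, s); ends <- c(ends, e)
  }
  nt <- length(target_start)
  rc <- integer(nt); covered <- integer(nt); bases <- numeric(nt)
  for (j in seq_len(nt)) {
    ts <- target_start[j]; te <- target_end[j]
    bases[j] <- sum(depth[ts:te])
    covered[j] <- sum(depth[ts:te] > 0L)
    if (length(starts) > 0L) {
      ov <- pmin(ends, te) - pmax(starts, ts) + 1L
      rc[j] <- sum(ov >= min_overlap)
    }
  }
  list(read_count = rc, covered_bases = covered, aligned_bases = bases,
       fold = bases / (target_end - target_start + 1L),
       exome_fold = sum(bases) / sum(target_end - target_start + 1L))
}

# --- O(N^2) duplicate-marking oracle -----------------------------------

# Pairwise comparator over "units" (full qname pairs, or singletons).
# Key per record: (rname, strand, unclipped 5' start); a unit's key is
# the multiset of its records' keys plus its pairing class.  Groups are
# formed by pairwise equality; the kept unit has the highest summed
# base quality, ties broken by smallest qname.
oracle_mark_duplicates <- function(records) {
  n <- nrow(records)
  rev_strand <- bitwAnd(records$flag, 0x10L) != 0L
  paired <- bitwAnd(records$flag, 0x1L) != 0L &
    bitwAnd(records$flag, 0x8L) == 0L
  key <- character(n)
  for (i in seq_len(n)) {
    p5 <- if (rev_strand[i]) {
      records$pos[i] + oracle_ref_span(records$cigar[i]) - 1L +
        oracle_trail_clip(records$cigar[i])
    } else {
      records$pos[i] - oracle_lead_clip(records$cigar[i])
    }
    key[i] <- paste(records$rname[i], if (rev_strand[i]) "-" else "+", p5)
  }
  qsum <- vapply(records$qual, function(s)
    if (identical(s, "*")) 0L else sum(utf8ToInt(s) - 33L), integer(1),
    USE.NAMES = FALSE)

  units <- list()
  used <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (used[i]) next
    if (paired[i]) {
      j <- setdiff(which(records$qname == records$qname[i] & paired), i)
      if (length(j) == 1L) {
        units[[length(units) + 1L]] <- c(i, j)
        used[c(i, j)] <- TRUE
        next
      }
    }
    units[[length(units) + 1L]] <- i
    used[i] <- TRUE
  }
  ukey <- vapply(units, function(u) paste(
    if (length(u) == 2L) "P" else if (paired[u]) "p1" else "S",
    paste(sort(key[u]), collapse = "|")), character(1))
  uscore <- vapply(units, function(u) sum(qsum[u]), numeric(1))
  uqname <- vapply(units, function(u) records$qname[u[1L]], character(1))

  nu <- length(units)
  dup_unit <- rep(FALSE, nu)
  for (a in seq_len(nu)) {
    grp <- which(vapply(seq_len(nu), function(b) ukey[b] == ukey[a], logical(1)))
    if (length(grp) < 2L) next
    best <- grp[1L]
    for (b in grp[-1L]) {
      if (uscore[b] > uscore[best] ||
          (uscore[b] == uscore[best] && uqname[b] < uqname[best])) best <- b
    }
    dup_unit[setdiff(grp, best)] <- TRUE
  }
  dup <- rep(FALSE, n)
  for (k in seq_len(nu)) if (dup_unit[k]) dup[units[[k]]] <- TRUE
  dup
}

# --- random SAM generators ---------------------------------------------

rand_cigar_seq <- function(qlen, genome) {
  lead <- if (stats::runif(1) < 0.3) sample.int(5L, 1L) else 0L
  trail <- if (stats::runif(1) < 0.2) sample.int(5L, 1L) else 0L
  ins <- if (stats::runif(1) < 0.3) sample.int(3L, 1L) else 0L
  core <- qlen - lead - trail - ins
  m1 <- sample.int(core - 1L, 1L)
  m2 <- core - m1
  del <- if (stats::runif(1) < 0.3) sample.int(5L, 1L) else 0L
  parts <- c(if (lead > 0L) paste0(lead, "S"),
             paste0(m1, "M"),
             if (ins > 0L) paste0(ins, "I"),
             if (del > 0L) paste0(del, "D"),
             paste0(m2, "M"),
             if (trail > 0L) paste0(trail, "S"))
  paste(parts, collapse = "")
}

# random single-end SAM with optional proper pairs and planted key
# collisions (positions drawn from a small pool)
gen_random_sam <- function(n_records, genome_length = 10000L,
                           qlen = 50L, pos_pool = 40L,
                           pair_fraction = 0) {
  pool <- sort(sample.int(genome_length - 3L * qlen, pos_pool))
  rec <- list()
  i <- 1L
  while (length(rec) < n_records) {
    pos <- sample(pool, 1L)
    qual <- intToUtf8(sample(35:73, qlen, replace = TRUE))
    seqs <- paste(sample(c("A", "C", "G", "T"), qlen, TRUE), collapse = "")
    if (pair_fraction > 0 && stats::runif(1) < pair_fraction &&
        length(rec) < n_records - 1L) {
      mpos <- pos + qlen + sample.int(100L, 1L)
      qual2 <- intToUtf8(sample(35:73, qlen, replace = TRUE))
      qn <- sprintf("pair_%04d", i)
      rec[[length(rec) + 1L]] <- data.frame(
        qname = qn, flag = 1L + 2L + 32L + 64L, rname = "chr1", pos = pos,
        mapq = 60L, cigar = rand_cigar_seq(qlen), rnext = "=", pnext = mpos,
        tlen = mpos + qlen - pos, seq = seqs, qual = qual, tags = "",
        stringsAsFactors = FALSE)
      rec[[length(rec) + 1L]] <- data.frame(
        qname = qn, flag = 1L + 2L + 16L + 128L, rname = "chr1", pos = mpos,
        mapq = 60L, cigar = rand_cigar_seq(qlen), rnext = "=", pnext = pos,
        tlen = -(mpos + qlen - pos), seq = seqs, qual = qual2, tags = "",
        stringsAsFactors = FALSE)
    } else {
      rec[[length(rec) + 1L]] <- data.frame(
        qname = sprintf("read_%04d", i),
        flag = sample(c(0L, 16L), 1L), rname = "chr1", pos = pos,
        mapq = 60L, cigar = rand_cigar_seq(qlen), rnext = "*", pnext = 0L,
        tlen = 0L, seq = seqs, qual = qual, tags = "",
        stringsAsFactors = FALSE)
    }
    i <- i + 1L
  }
  sam_set(header = c("@HD\tVN:1.6",
                     paste0("@SQ\tSN:chr1\tLN:", genome_length)),
          records = do.call(rbind, rec))
}

# --- tiny read builders ------------------------------------------------

make_reads <- function(bases, quals = NULL, encoding = "sanger",
                       ids = NULL, mate = "none") {
  if (is.null(quals)) quals <- lapply(nchar(bases), function(l) rep(30L, l))
  if (!is.list(quals)) quals <- list(quals)
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(bases))
  read_set(id = ids, bases = bases, quals = quals, encoding = encoding,
           mate = mate)
}
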