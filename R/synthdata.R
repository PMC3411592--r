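# Seeded fixture generator: reads, alignments and variants with
# planted, recoverable ground truth, so every pipeline stage is
# testable without external downloads.  Counts a downstream test can
# assert exactly are planted exactly by construction; quantities
# checked against a confidence interval are sampled.

# run code under a pinned, restorable RNG state (Mersenne-Twister, so
# fixtures are stable across platforms and R versions)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Fixture plan: the declarative ground truth of a synthetic data set
#'
#' A plan plus its seed fully determines every generated file
#' byte-for-byte.  Defaults describe a single-end Illumina-like exome
#' run at desk scale: 75 bp reads, a 100 kb genome with 50 capture
#' targets of 200 bp, 63% of reads mappable, a 12% duplicate rate, 40%
#' of unique fragments on target, and roughly 2% of raw reads failing
#' preprocessing.  Variant defaults plant Ti/Tv 2.0 exactly by count
#' and a 0.3 homozygous fraction for both SNPs (by genotype) and DIPs
#' (by allele fraction, off the dsP = 80 boundary).
#'
#' @param seed integer RNG seed.
#' @param genome_length reference length in bases (single chromosome).
#' @param n_targets,target_length capture-target layout (evenly spaced,
#'   non-overlapping).
#' @param paired generate paired-end data.
#' @param read_length read length in bases.
#' @param n_fastq_reads raw reads (or pairs) for the preprocessing
#'   fixture.
#' @param fail_length,fail_nmax,fail_quality planted counts of reads
#'   (or, for PE, pairs with one failing mate) removed by the
#'   min-length, N-fraction and quality-fraction filters; `NULL`
#'   defaults to 0.7% / 0.65% / 0.65% of `n_fastq_reads` (about 2%
#'   failing overall).
#' @param trimmed_n,trimmed_rsqci planted counts of surviving reads
#'   that exercise the N and RSQCI trimmers; `NULL` defaults to 2.5%
#'   of `n_fastq_reads` each.
#' @param n_reads alignment records in the SAM fixture.
#' @param unmapped_fraction fraction of records that are unmapped.
#' @param improper_fraction for PE, fraction of mapped pairs lacking
#'   the proper-pair flag.
#' @param duplicate_rate fraction of mapped records that are planted
#'   duplicate copies (`duplicate_mode = "planted"`), or ignored under
#'   `"uniform"`, where fragments are placed uniformly over start sites
#'   and duplicates arise only by chance.
#' @param duplicate_mode `"planted"` or `"uniform"`.
#' @param clip_fraction fraction of planted duplicate copies carrying a
#'   5 bp leading soft-clip (same unclipped start, shifted POS).
#' @param on_target_fraction probability that a unique fragment is
#'   placed on target.
#' @param insert_size_mean,insert_size_sd PE fragment-length
#'   distribution (truncated to fit one target).
#' @param base_quality Phred quality of generated base calls.
#' @param n_ti,n_tv planted transition and transversion SNP counts.
#' @param snp_hom_fraction fraction of SNPs with homozygous genotype.
#' @param n_dips planted DIP count.
#' @param dip_hom_fraction fraction of DIPs with alt-allele fraction
#'   above dsP.
#' @param dsP DIP zygosity threshold percentage.
#' @param dbsnp_fraction,refseq_fraction,coding_fraction planted
#'   annotation rates.
#' @return A list of class `fixture_plan`.
#' @export
fixture_plan <- function(seed = 1L,
                         genome_length = 100000L,
                         n_targets = 50L, target_length = 200L,
                         paired = FALSE,
                         read_length = 75L,
                         n_fastq_reads = 2000L,
                         fail_length = NULL, fail_nmax = NULL,
                         fail_quality = NULL,
                         trimmed_n = NULL, trimmed_rsqci = NULL,
                         n_reads = 10000L,
                         unmapped_fraction = 0.37,
                         improper_fraction = 0.21,
                         duplicate_rate = 0.12,
                         duplicate_mode = c("planted", "uniform"),
                         clip_fraction = 0.1,
                         on_target_fraction = 0.4,
                         insert_size_mean = 150L, insert_size_sd = 15,
                         base_quality = 35L,
                         n_ti = 2000L, n_tv = 1000L,
                         snp_hom_fraction = 0.3,
                         n_dips = 400L, dip_hom_fraction = 0.3,
                         dsP = 80,
                         dbsnp_fraction = 0.83, refseq_fraction = 0.99,
                         coding_fraction = 0.5) {
  duplicate_mode <- match.arg(duplicate_mode)
  # planted preprocessing counts default to ~2% total failures (0.7% too
  # short, 0.65% N-heavy, 0.65% low quality) and 2.5% per trimmer kind,
  # scaled with the read count
  if (is.null(fail_length)) fail_length <- round(0.007 * n_fastq_reads)
  if (is.null(fail_nmax)) fail_nmax <- round(0.0065 * n_fastq_reads)
  if (is.null(fail_quality)) fail_quality <- round(0.0065 * n_fastq_reads)
  if (is.null(trimmed_n)) trimmed_n <- round(0.025 * n_fastq_reads)
  if (is.null(trimmed_rsqci)) trimmed_rsqci <- round(0.025 * n_fastq_reads)
  fail_length <- as.integer(fail_length)
  fail_nmax <- as.integer(fail_nmax)
  fail_quality <- as.integer(fail_quality)
  trimmed_n <- as.integer(trimmed_n)
  trimmed_rsqci <- as.integer(trimmed_rsqci)
  plan <- as.list(environment())
  fracs <- c(unmapped_fraction, improper_fraction, duplicate_rate,
             clip_fraction, on_target_fraction, snp_hom_fraction,
             dip_hom_fraction, dbsnp_fraction, refseq_fraction,
             coding_fraction)
  stopifnot(all(fracs >= 0 & fracs <= 1), dsP >= 0, dsP <= 100)
  structure(plan, class = "fixture_plan")
}

random_bases <- function(n_strings, len) {
  if (length(len) == 1L) len <- rep(len, n_strings)
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate the synthetic reference genome and capture targets
#'
#' A random single-chromosome genome of the planned length with
#' `n_targets` evenly spaced, non-overlapping target intervals.
#'
#' @param plan a [fixture_plan()].
#' @return `list(genome = character(1), targets = GRanges)`; targets
#'   are 1-based closed (BED conversion happens on export).
#' @export
gen_reference <- function(plan) {
  with_seed(plan$seed * 7L + 101L, {
    occupied <- plan$n_targets * plan$target_length
    if (occupied >= plan$genome_length)
      stop("targets (", occupied, " bases) do not fit in the genome (",
           plan$genome_length, " bases)")
    genome <- random_bases(1L, plan$genome_length)
    gap <- (plan$genome_length - occupied) / (plan$n_targets + 1L)
    starts <- round(gap * seq_len(plan$n_targets) +
                      plan$target_length * (seq_len(plan$n_targets) - 1L)) + 1L
    targets <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(start = starts, width = plan$target_length),
      name = sprintf("target_%03d", seq_len(plan$n_targets)))
    list(genome = genome, targets = targets)
  })
}

#' Generate raw reads with planted preprocessing outcomes
#'
#' Constructs reads so that, at the default thresholds and stage order
#' of [run_preprocess()], each filter removes exactly the planted
#' count: length-failing reads are 20 bp, N-failing reads carry just
#' over 5% interior Ns, quality-failing reads just over 5% interior
#' sub-threshold calls.  Additional surviving reads exercise the N and
#' RSQCI trimmers without failing any filter.  For paired-end plans
#' each planted failure sits on one random mate of a distinct pair, so
#' the pair-synchronised accounting removes two records per plant.
#'
#' @param plan a [fixture_plan()].
#' @return `list(r1, r2, manifest)`: `read_set`s (Sanger encoding;
#'   `r2` is `NULL` for single-end plans) and a manifest data.frame of
#'   expected per-stage removals.
#' @export
gen_reads <- function(plan) {
  with_seed(plan$seed * 7L + 202L, {
    n <- plan$n_fastq_reads
    L <- plan$read_length
    q <- plan$base_quality
    n_fail <- plan$fail_length + plan$fail_nmax + plan$fail_quality
    n_trim <- plan$trimmed_n + plan$trimmed_rsqci
    if (n_fail + n_trim > n)
      stop("planted read counts exceed n_fastq_reads")

    kinds <- c(rep("fail_length", plan$fail_length),
               rep("fail_nmax", plan$fail_nmax),
               rep("fail_quality", plan$fail_quality),
               rep("trim_n", plan$trimmed_n),
               rep("trim_rsqci", plan$trimmed_rsqci),
               rep("plain", n - n_fail - n_trim))
    kinds <- sample(kinds)

    n_over <- floor(0.05 * L) + 1L  # just over the 5% fraction
    make_read <- function(kind) {
      switch(kind,
        fail_length = list(bases = random_bases(1L, 20L), quals = rep(q, 20L)),
        fail_nmax = {
          b <- strsplit(random_bases(1L, L), "")[[1]]
          b[10:(9L + n_over)] <- "N"
          list(bases = paste(b, collapse = ""), quals = rep(q, L))
        },
        fail_quality = {
          qq <- rep(q, L)
          qq[10:(9L + n_over)] <- 10L
          list(bases = random_bases(1L, L), quals = qq)
        },
        trim_n = {
          core <- random_bases(1L, L - 6L)
          list(bases = paste0("NNN", core, "NNN"), quals = rep(q, L))
        },
        trim_rsqci = {
          qq <- c(rep(q, L - 5L), rep(2L, 5L))
          list(bases = random_bases(1L, L), quals = qq)
        },
        plain = list(bases = random_bases(1L, L), quals = rep(q, L)))
    }

    built <- lapply(kinds, make_read)
    ids <- sprintf("read_%06d", seq_len(n))
    mk_set <- function(b, qs, mate) read_set(
      id = ids, bases = b, quals = qs, encoding = "sanger", mate = mate)

    if (!plan$paired) {
      r1 <- mk_set(vapply(built, `[[`, character(1), "bases"),
                   lapply(built, `[[`, "quals"), "none")
      r2 <- NULL
    } else {
      plain <- lapply(seq_len(n), function(i) make_read("plain"))
      on_r1 <- sample(c(TRUE, FALSE), n, replace = TRUE)
      pick <- function(i, first) if (xor(first, !on_r1[i])) built[[i]] else plain[[i]]
      b1 <- lapply(seq_len(n), pick, first = TRUE)
      b2 <- lapply(seq_len(n), pick, first = FALSE)
      r1 <- mk_set(vapply(b1, `[[`, character(1), "bases"),
                   lapply(b1, `[[`, "quals"), "R1")
      r2 <- mk_set(vapply(b2, `[[`, character(1), "bases"),
                   lapply(b2, `[[`, "quals"), "R2")
    }
    per_plant <- if (plan$paired) 2L else 1L
    manifest <- data.frame(
      stage = c("min-length-filter", "n-max-filter", "quality-filter"),
      expected_removed = per_plant * c(plan$fail_length, plan$fail_nmax,
                                       plan$fail_quality),
      stringsAsFactors = FALSE)
    list(r1 = r1, r2 = r2, manifest = manifest)
  })
}

# start positions whose whole footprint of width w stays off target:
# IRanges of allowed starts given a normalized target set
offtarget_start_ranges <- function(targets, genome_length, w) {
  t <- IRanges::ranges(normalize_targets(targets))
  blocked <- IRanges::IRanges(pmax(IRanges::start(t) - w + 1L, 1L),
                              IRanges::end(t))
  allowed <- IRanges::setdiff(IRanges::IRanges(1L, genome_length - w + 1L),
                              IRanges::reduce(blocked))
  allowed
}

# sample k integers uniformly from a set of IRanges (with replacement)
sample_from_ranges <- function(ranges, k, replace = TRUE) {
  offs <- cumsum(c(0L, IRanges::width(ranges)))
  total <- offs[length(offs)]
  if (!replace && k > total) stop("not enough candidate positions")
  u <- sample.int(total, k, replace = replace)
  bin <- findInterval(u - 1L, offs, rightmost.closed = FALSE)
  IRanges::start(ranges)[bin] + (u - offs[bin] - 1L)
}

#' Generate a SAM alignment fixture with planted structure
#'
#' Mapped reads are placed on the reference with an on-target
#' probability from the plan; off-target reads lie wholly outside the
#' capture targets.  Under `duplicate_mode = "planted"` unique
#' fragments get distinct duplicate keys (sampled without replacement)
#' and the planted duplicate count is added as extra copies sharing a
#' key, some with a leading soft-clip; under `"uniform"` fragments are
#' placed uniformly over the on-target start-site space and duplicates
#' arise only by chance, for comparison with
#' [expected_duplicates_by_chance()].
#'
#' @param plan a [fixture_plan()].
#' @param reference output of [gen_reference()] (regenerated from the
#'   plan when `NULL`).
#' @return `list(sam, manifest)`: a `sam_set` and a manifest list of
#'   realized counts (`n_records`, `n_unmapped`, `n_mapped`,
#'   `n_improper`, `n_planted_duplicates`, `n_unique_fragments`,
#'   `n_on_target`, `n_start_sites`, on-target status per record
#'   excluded).
#' @export
gen_alignments <- function(plan, reference = NULL) {
  if (is.null(reference)) reference <- gen_reference(plan)
  with_seed(plan$seed * 7L + 303L, {
    genome <- reference$genome
    targets <- normalize_targets(reference$targets)
    L <- plan$read_length
    n <- plan$n_reads
    qstr <- strrep(intToUtf8(plan$base_quality + 33L), L)
    tstarts <- GenomicRanges::start(targets)
    twidth <- GenomicRanges::width(targets)
    if (any(twidth < L)) stop("targets shorter than the read length")

    n_unmapped <- round(n * plan$unmapped_fraction)
    n_mapped <- n - n_unmapped

    # on-target start-site space: fully-inside starts, both strands
    per_target <- twidth - L + 1L
    on_ranges <- IRanges::IRanges(tstarts, width = per_target)
    n_sites_on <- 2L * sum(per_target)

    uniform <- plan$duplicate_mode == "uniform"
    n_dup <- if (uniform) 0L else round(n_mapped * plan$duplicate_rate)
    n_unique <- n_mapped - n_dup

    on_target <- stats::runif(n_unique) < plan$on_target_fraction
    n_on <- sum(on_target)
    # PE fragments span up to one target width; pad off-target placement
    # so no mate can creep into a target
    off_pad <- if (plan$paired) min(twidth) else L
    off_ranges <- offtarget_start_ranges(targets, plan$genome_length, off_pad)

    pos <- integer(n_unique)
    strand_rev <- logical(n_unique)
    if (uniform) {
      # uniform placement with replacement over (strand, start) sites
      site <- sample.int(n_sites_on, n_on, replace = TRUE)
      strand_rev[on_target] <- site > sum(per_target)
      idx <- ifelse(site > sum(per_target), site - sum(per_target), site)
      offs <- cumsum(c(0L, per_target))
      bin <- findInterval(idx - 1L, offs)
      pos[on_target] <- tstarts[bin] + (idx - offs[bin] - 1L)
    } else {
      # distinct (strand, start) keys for unique on-target fragments
      site <- sample.int(n_sites_on, n_on, replace = FALSE)
      strand_rev[on_target] <- site > sum(per_target)
      idx <- ifelse(site > sum(per_target), site - sum(per_target), site)
      offs <- cumsum(c(0L, per_target))
      bin <- findInterval(idx - 1L, offs)
      pos[on_target] <- tstarts[bin] + (idx - offs[bin] - 1L)
    }
    if (any(!on_target)) {
      n_off <- sum(!on_target)
      n_sites_off <- sum(IRanges::width(off_ranges))
      if (uniform) {
        pos[!on_target] <- sample_from_ranges(off_ranges, n_off)
        strand_rev[!on_target] <- sample(c(TRUE, FALSE), n_off, replace = TRUE)
      } else {
        site <- sample.int(2L * n_sites_off, n_off, replace = FALSE)
        strand_rev[!on_target] <- site > n_sites_off
        idx <- ifelse(site > n_sites_off, site - n_sites_off, site)
        offso <- cumsum(c(0L, IRanges::width(off_ranges)))
        bino <- findInterval(idx - 1L, offso)
        pos[!on_target] <- IRanges::start(off_ranges)[bino] + (idx - offso[bino] - 1L)
      }
    }

    # planted duplicate copies of randomly chosen unique fragments
    src <- if (n_dup > 0L) sample.int(n_unique, n_dup, replace = TRUE) else integer()
    clip <- stats::runif(n_dup) < plan$clip_fraction

    all_pos <- c(pos, pos[src])
    all_rev <- c(strand_rev, strand_rev[src])
    all_on <- c(on_target, on_target[src])
    is_dup_copy <- c(rep(FALSE, n_unique), rep(TRUE, n_dup))
    cigar <- rep(sprintf("%dM", L), n_unique + n_dup)

    # a clipped copy keeps the unclipped 5' start: forward reads shift
    # POS right behind a leading soft-clip, reverse reads extend a
    # trailing soft-clip instead (single-end plans only; paired copies
    # must reproduce both mates' coordinates exactly)
    if (n_dup > 0L && any(clip) && !plan$paired) {
      ci <- n_unique + which(clip)
      fwd <- !all_rev[ci]
      cigar[ci[fwd]] <- sprintf("5S%dM", L - 5L)
      all_pos[ci[fwd]] <- all_pos[ci[fwd]] + 5L
      cigar[ci[!fwd]] <- sprintf("%dM5S", L - 5L)
    }

    seq_of <- function(p, cg) {
      w <- GenomicAlignments::cigarWidthAlongReferenceSpace(cg)
      aligned <- substr(genome, p, p + w - 1L)
      pad <- L - nchar(aligned)
      if (pad > 0L) paste0(aligned, random_bases(1L, pad)) else aligned
    }

    nm <- n_unique + n_dup
    flags <- ifelse(all_rev, 16L, 0L)
    rec <- data.frame(
      qname = sprintf("frag_%06d", seq_len(nm)),
      flag = flags, rname = "chr1", pos = all_pos, mapq = 60L,
      cigar = cigar, rnext = "*", pnext = 0L, tlen = 0L,
      seq = mapply(seq_of, all_pos, cigar), qual = qstr,
      tags = "", stringsAsFactors = FALSE)

    n_improper <- 0L
    if (plan$paired) {
      # mate geometry: forward mate at pos, reverse mate insert-L later;
      # duplicate copies inherit their source fragment's insert size and
      # properness so both mates' coordinates match
      insert_u <- pmin(pmax(round(stats::rnorm(n_unique, plan$insert_size_mean,
                                               plan$insert_size_sd)), L),
                       min(twidth))
      improper_u <- stats::runif(n_unique) < plan$improper_fraction
      insert <- c(insert_u, insert_u[src])
      improper <- c(improper_u, improper_u[src])
      n_improper <- 2L * sum(improper)
      base_flag <- 1L + ifelse(improper, 0L, 2L)
      r1 <- rec
      r1$flag <- base_flag + 64L + 32L   # paired, first, mate reverse
      r1$rnext <- "="; r1$pnext <- rec$pos + insert - L
      r1$tlen <- insert
      r2 <- rec
      r2$flag <- base_flag + 128L + 16L  # paired, second, reverse
      r2$pos <- rec$pos + insert - L
      r2$cigar <- sprintf("%dM", L)
      r2$seq <- vapply(r2$pos, function(p) substr(genome, p, p + L - 1L),
                       character(1))
      r2$rnext <- "="; r2$pnext <- rec$pos
      r2$tlen <- -insert
      rec <- rbind(r1, r2)
      all_on <- c(all_on, all_on)
      is_dup_copy <- c(is_dup_copy, is_dup_copy)
    }

    if (n_unmapped > 0L) {
      un <- data.frame(
        qname = sprintf("unm_%06d", seq_len(n_unmapped)),
        flag = 4L, rname = "*", pos = 0L, mapq = 0L, cigar = "*",
        rnext = "*", pnext = 0L, tlen = 0L,
        seq = random_bases(n_unmapped, L), qual = qstr, tags = "",
        stringsAsFactors = FALSE)
      rec <- rbind(rec, un)
      all_on <- c(all_on, rep(NA, n_unmapped))
      is_dup_copy <- c(is_dup_copy, rep(FALSE, n_unmapped))
    }

    shuffle <- sample.int(nrow(rec))
    rec <- rec[shuffle, , drop = FALSE]
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                paste0("@SQ\tSN:chr1\tLN:", plan$genome_length))
    manifest <- list(
      n_records = nrow(rec),
      n_unmapped = n_unmapped,
      n_mapped = nrow(rec) - n_unmapped,
      n_improper = n_improper,
      n_planted_duplicates = n_dup * (1L + plan$paired),
      n_unique_fragments = n_unique,
      n_on_target_unique = n_on,
      on_target_fraction_planted = plan$on_target_fraction,
      n_start_sites = n_sites_on)
    list(sam = sam_set(header, rec), manifest = manifest)
  })
}

#' Generate SNP and DIP call sets with planted properties
#'
#' SNP substitution types are assigned by count, so the planted Ti/Tv
#' ratio is exact; genotypes plant the homozygous fraction exactly.
#' DIP allele fractions are placed well off the dsP boundary (95% for
#' homozygous, 50% for heterozygous plants), so the zygosity split at
#' the planned dsP recovers the planted fraction exactly.  dbSNP
#' membership, RefSeq association and coding annotations are planted
#' at exact counts.
#'
#' @param plan a [fixture_plan()].
#' @param reference output of [gen_reference()] (regenerated when
#'   `NULL`).
#' @return `list(snps, dips, manifest)`: two variant tables (as from
#'   [read_vcf()]) and a manifest list of planted counts.
#' @export
gen_vcf <- function(plan, reference = NULL) {
  if (is.null(reference)) reference <- gen_reference(plan)
  with_seed(plan$seed * 7L + 404L, {
    genome <- reference$genome
    targets <- normalize_targets(reference$targets)
    n_snps <- plan$n_ti + plan$n_tv
    n_all <- n_snps + plan$n_dips
    # distinct positions inside targets, DIPs padded away from ends
    tr <- IRanges::ranges(targets)
    inner <- IRanges::IRanges(IRanges::start(tr), IRanges::end(tr) - 5L)
    avail <- sum(IRanges::width(inner))
    if (n_all > avail)
      stop("not enough target positions for ", n_all, " variants")
    pos <- sort(sample_from_ranges(inner, n_all, replace = FALSE))
    base_at <- function(p) substr(genome, p, p)

    TI_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
    TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))

    snp_rows <- sort(sample.int(n_all, n_snps))
    snp_pos <- pos[snp_rows]
    dip_pos <- pos[-snp_rows]

    is_ti <- sample(rep(c(TRUE, FALSE), c(plan$n_ti, plan$n_tv)))
    ref_s <- vapply(snp_pos, base_at, character(1))
    alt_s <- ifelse(is_ti, TI_PARTNER[ref_s],
                    vapply(ref_s, function(b) sample(TV_PARTNERS[[b]], 1L),
                           character(1)))
    n_hom_snp <- round(n_snps * plan$snp_hom_fraction)
    gt_s <- sample(rep(c("1/1", "0/1"), c(n_hom_snp, n_snps - n_hom_snp)))
    n_db <- round(n_snps * plan$dbsnp_fraction)
    vid_s <- rep(".", n_snps)
    vid_s[sample.int(n_snps, n_db)] <- paste0("rs", snp_pos[seq_len(n_db)])
    dp_s <- ifelse(gt_s == "1/1", 30L, 30L)
    ad_alt_s <- ifelse(gt_s == "1/1", 29L, 15L)

    ann_for <- function(n, refseq_fraction, coding_fraction) {
      has_rs <- seq_len(n) %in% sample.int(n, round(n * refseq_fraction))
      has_cd <- seq_len(n) %in% sample.int(n, round(n * coding_fraction))
      lapply(seq_len(n), function(i) {
        a <- character()
        if (has_rs[i]) a <- c(a, RefSeq = sprintf("NM_%06d", i))
        if (has_cd[i]) a <- c(a, ExonicFunc = "nonsynonymous")
        a
      })
    }

    snps <- empty_variant_table()
    if (n_snps > 0L) {
      snps <- data.frame(
        chrom = "chr1", pos = snp_pos, vid = vid_s, ref = ref_s,
        alt = unname(alt_s), qual = 100, gt = gt_s, depth = dp_s,
        ref_depth = dp_s - ad_alt_s, alt_depth = ad_alt_s,
        stringsAsFactors = FALSE)
      snps$ann <- ann_for(n_snps, plan$refseq_fraction, plan$coding_fraction)
    }

    dips <- empty_variant_table()
    if (plan$n_dips > 0L) {
      nd <- plan$n_dips
      is_del <- sample(rep(c(TRUE, FALSE), c(floor(nd / 2), ceiling(nd / 2))))
      ref_d <- ifelse(is_del,
                      vapply(dip_pos, function(p) substr(genome, p, p + 3L),
                             character(1)),
                      vapply(dip_pos, base_at, character(1)))
      alt_d <- ifelse(is_del, vapply(dip_pos, base_at, character(1)),
                      paste0(vapply(dip_pos, base_at, character(1)),
                             random_bases(nd, 3L)))
      n_hom_dip <- round(nd * plan$dip_hom_fraction)
      hom_d <- sample(rep(c(TRUE, FALSE), c(n_hom_dip, nd - n_hom_dip)))
      depth_d <- rep(20L, nd)
      alt_dp <- ifelse(hom_d, 19L, 10L)   # 95% vs 50%, both off dsP = 80
      dips <- data.frame(
        chrom = "chr1", pos = dip_pos, vid = ".", ref = ref_d,
        alt = alt_d, qual = 100, gt = ifelse(hom_d, "1/1", "0/1"),
        depth = depth_d, ref_depth = depth_d - alt_dp, alt_depth = alt_dp,
        stringsAsFactors = FALSE)
      dips$ann <- ann_for(nd, plan$refseq_fraction, plan$coding_fraction)
    }
    manifest <- list(
      n_snps = n_snps, n_ti = plan$n_ti, n_tv = plan$n_tv,
      titv = if (plan$n_tv > 0L) plan$n_ti / plan$n_tv else NA_real_,
      n_snp_hom = n_hom_snp,
      n_dips = plan$n_dips,
      n_dip_hom = if (plan$n_dips > 0L) round(plan$n_dips * plan$dip_hom_fraction) else 0L,
      dsP = plan$dsP,
      n_dbsnp = n_db)
    list(snps = snps, dips = dips, manifest = manifest)
  })
}

#' Write a complete fixture set to a directory
#'
#' Materialises the plan as files: `genome.fasta`, `targets.bed`,
#' `reads_R1.fastq` (and `_R2` for PE plans), `alignments.sam`,
#' `snps.vcf`, `dips.vcf`, and `manifest.tsv` echoing the planted
#' ground truth.
#'
#' @param plan a [fixture_plan()].
#' @param out_dir output directory (created if needed).
#' @return The manifest as a data.frame of `key`/`value` rows,
#'   invisibly.
#' @export
gen_fixture_set <- function(plan, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- gen_reference(plan)
  write_fasta_genome(ref$genome, "chr1", file.path(out_dir, "genome.fasta"))
  write_bed(ref$targets, file.path(out_dir, "targets.bed"))
  reads <- gen_reads(plan)
  if (plan$paired) {
    write_fastq(reads$r1, file.path(out_dir, "reads_R1.fastq"))
    write_fastq(reads$r2, file.path(out_dir, "reads_R2.fastq"))
  } else {
    write_fastq(reads$r1, file.path(out_dir, "reads_R1.fastq"))
  }
  aln <- gen_alignments(plan, ref)
  write_sam(aln$sam, file.path(out_dir, "alignments.sam"))
  vcfs <- gen_vcf(plan, ref)
  write_vcf(vcfs$snps, file.path(out_dir, "snps.vcf"))
  write_vcf(vcfs$dips, file.path(out_dir, "dips.vcf"))
  manifest <- rbind(
    data.frame(key = paste0("reads.", reads$manifest$stage),
               value = as.character(reads$manifest$expected_removed),
               stringsAsFactors = FALSE),
    data.frame(key = paste0("aln.", names(aln$manifest)),
               value = vapply(aln$manifest, as.character, character(1)),
               stringsAsFactors = FALSE),
    data.frame(key = paste0("vcf.", names(vcfs$manifest)),
               value = vapply(vcfs$manifest, as.character, character(1)),
               stringsAsFactors = FALSE))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

write_fasta_genome <- function(genome, name, path) {
  n <- nchar(genome)
  starts <- seq(1L, n, by = 60L)
  writeLines(c(paste0(">", name),
               substring(genome, starts, pmin(starts + 59L, n))), path)
  invisible(path)
}
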