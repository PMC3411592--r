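# Alignment totals, summary metrics, insert sizes, exome coverage and
# the duplicates-by-chance model.

test_that("bam_stats counts reads and computes genome fold coverage", {
  sam <- sam_set(records = data.frame(
    qname = paste0("r", 1:5),
    flag = c(0L, 0L, 16L, 4L, 4L), rname = c(rep("chr1", 3), "*", "*"),
    pos = c(1L, 101L, 201L, 0L, 0L), mapq = 60L,
    cigar = c("1000M", "500M", "500M", "*", "*"), rnext = "*", pnext = 0L,
    tlen = 0L, seq = "*", qual = "*", tags = "", stringsAsFactors = FALSE))
  st <- bam_stats(sam, genome_length = 1000)
  expect_equal(st$total_reads, 5L)
  expect_equal(st$mapped, 3L)
  expect_equal(st$unmapped, 2L)
  expect_equal(st$genome_fold_coverage, 2.0)
  empty <- bam_stats(sam_set(), genome_length = 1000)
  expect_equal(empty$total_reads, 0L)
  expect_equal(empty$genome_fold_coverage, 0)
})

test_that("summary metrics: median length, indel rates, HQ bases", {
  mk <- function(cigar, mapq, len) data.frame(
    qname = "r", flag = 0L, rname = "chr1", pos = 1L, mapq = mapq,
    cigar = cigar, rnext = "*", pnext = 0L, tlen = 0L,
    seq = strrep("A", len), qual = strrep("I", len), tags = "",
    stringsAsFactors = FALSE)
  sam <- sam_set(records = rbind(mk("50M", 60L, 50L), mk("60M", 60L, 60L),
                                 mk("70M", 60L, 70L)))
  m <- alignment_summary_metrics(sam)
  expect_equal(m$median_read_length, 60)

  sam <- sam_set(records = rbind(mk("25M2I23M", 60L, 50L), mk("50M", 60L, 50L),
                                 mk("50M", 60L, 50L), mk("25M2D25M", 60L, 50L)))
  m <- alignment_summary_metrics(sam)
  expect_equal(m$insertion_rate, 0.25)
  expect_equal(m$deletion_rate, 0.25)

  sam <- sam_set(records = mk("100M", 30L, 100L))
  expect_equal(alignment_summary_metrics(sam)$high_quality_aligned_bases, 100)
  # below the MAPQ threshold nothing counts
  sam <- sam_set(records = mk("100M", 10L, 100L))
  expect_equal(alignment_summary_metrics(sam)$high_quality_aligned_bases, 0)
  # soft-clipped bases are not aligned bases
  sam <- sam_set(records = mk("10S80M10S", 60L, 100L))
  expect_equal(alignment_summary_metrics(sam)$high_quality_aligned_bases, 80)
})

test_that("insert sizes count one observation per fragment", {
  mk <- function(tlen, flag = 3L) data.frame(
    qname = "r", flag = flag, rname = "chr1", pos = 1L, mapq = 60L,
    cigar = "50M", rnext = "=", pnext = 100L, tlen = tlen,
    seq = strrep("A", 50L), qual = strrep("I", 50L), tags = "",
    stringsAsFactors = FALSE)
  sam <- sam_set(records = rbind(mk(200L), mk(-200L)))
  m <- insert_size_metrics(sam)
  expect_equal(m$n, 1L)
  expect_equal(m$mean, 200)

  sam <- sam_set(records = rbind(mk(100L), mk(-100L), mk(300L), mk(-300L)))
  m <- insert_size_metrics(sam)
  expect_equal(m$mean, 200)
  expect_equal(m$median, 200)

  se <- sam_set(records = mk(0L, flag = 0L))
  expect_message(m <- insert_size_metrics(se), "no proper pairs")
  expect_equal(m$n, 0L)
  expect_true(is.na(m$mean))

  # outliers leave mean/sd but stay in the histogram
  sam <- sam_set(records = rbind(mk(200L), mk(201L), mk(199L), mk(10000L)))
  m <- insert_size_metrics(sam)
  expect_equal(m$mean, 200)
  expect_equal(sum(m$histogram$count), 4L)
})

test_that("exon coverage handles fully contained and straddling reads", {
  t <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101L, 200L))
  mk <- function(pos, n = 1L, cigar = "10M", len = 10L) do.call(rbind, lapply(
    seq_len(n), function(i) data.frame(
      qname = paste0("r", pos, "_", i), flag = 0L, rname = "chr1", pos = pos,
      mapq = 60L, cigar = cigar, rnext = "*", pnext = 0L, tlen = 0L,
      seq = strrep("A", len), qual = strrep("I", len), tags = "",
      stringsAsFactors = FALSE)))
  sam <- sam_set(records = mk(111L, n = 10L))
  cov <- exon_coverage(sam, t)
  expect_equal(cov$per_interval$read_count, 10L)
  expect_equal(cov$per_interval$fold_coverage, 1.0)
  expect_equal(cov$per_interval$covered_bases, 10)

  # read straddling the target start: 4 bases inside
  sam <- sam_set(records = mk(95L))
  cov <- exon_coverage(sam, t)
  expect_equal(cov$per_interval$read_count, 1L)
  expect_equal(cov$per_interval$aligned_bases, 4)

  empty <- exon_coverage(sam_set(), t)
  expect_equal(empty$per_interval$read_count, 0L)
  expect_equal(empty$aggregate$exome_fold_coverage, 0)
})

test_that("fold times length sums to total on-target aligned bases", {
  set.seed(31)
  for (i in 1:5) {
    sam <- gen_random_sam(200L, genome_length = 5000L, pos_pool = 150L)
    t <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(201L, 1001L, 2501L), c(600L, 1500L, 3200L)))
    cov <- exon_coverage(sam, t)
    lhs <- sum(cov$per_interval$fold_coverage * cov$per_interval$length)
    expect_equal(lhs, sum(cov$per_interval$aligned_bases))
    expect_equal(cov$aggregate$exome_fold_coverage,
                 sum(cov$per_interval$aligned_bases) /
                   sum(cov$per_interval$length))
  }
})

test_that("capture specificity is the on-target fraction of mapped reads", {
  t <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001L, 2000L))
  mk <- function(pos, n, flag = 0L) do.call(rbind, lapply(seq_len(n),
    function(i) data.frame(
      qname = sprintf("r%d_%d", pos, i), flag = flag, rname = "chr1",
      pos = pos, mapq = 60L, cigar = "50M", rnext = "*", pnext = 0L,
      tlen = 0L, seq = strrep("A", 50L), qual = strrep("I", 50L), tags = "",
      stringsAsFactors = FALSE)))
  sam <- sam_set(records = rbind(mk(1100L, 40L), mk(100L, 60L)))
  expect_equal(capture_specificity(sam, t), 0.40)
  expect_equal(capture_specificity(sam_set(records = mk(1100L, 5L)), t), 1.0)
  expect_true(is.na(capture_specificity(sam_set(), t)))
  # flagged duplicates are excluded
  sam <- sam_set(records = rbind(mk(1100L, 4L), mk(100L, 6L),
                                 mk(100L, 10L, flag = 1024L)))
  expect_equal(capture_specificity(sam, t), 0.4)
})

test_that("expected duplicates by chance follows the collision model", {
  expect_equal(expected_duplicates_by_chance(2, 1), 1.0)
  expect_equal(expected_duplicates_by_chance(1, 5000), 0.0)
  expect_equal(expected_duplicates_by_chance(0, 10), 0.0)
  expect_error(expected_duplicates_by_chance(10, 0), "positive")
  # closed form at small n: n=2, P sites -> expected collisions 1/P
  for (P in c(2, 10, 100)) {
    expect_equal(expected_duplicates_by_chance(2, P), 1 / P)
  }
  # vanishes as the site space grows
  expect_lt(expected_duplicates_by_chance(1000, 1e12), 1e-5)
})
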