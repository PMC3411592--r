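# Variant classification, zygosity splitting, Ti/Tv, association rates,
# annotation merging and summaries.

vt <- function(ref, alt, gt = "0/1", depth = 20L, alt_depth = 10L,
               vid = ".", ann = NULL) {
  n <- length(ref)
  out <- data.frame(chrom = "chr1", pos = seq_len(n) * 100L,
                    vid = rep_len(vid, n), ref = ref, alt = alt, qual = 50,
                    gt = rep_len(gt, n), depth = rep_len(depth, n),
                    ref_depth = rep_len(depth - alt_depth, n),
                    alt_depth = rep_len(alt_depth, n),
                    stringsAsFactors = FALSE)
  out$ann <- if (is.null(ann)) rep(list(character()), n) else ann
  out
}

test_that("variant class is determined by allele lengths alone", {
  expect_identical(classify_variant(c("A", "A", "ACT"), c("G", "ACT", "A")),
                   c("SNP", "insertion", "deletion"))
  expect_error(classify_variant("A", "A"), "must differ")
})

test_that("SNP zygosity comes from the genotype field", {
  v <- vt(rep("A", 4), rep("G", 4), gt = c("1/1", "0/1", "1|1", "0|1"))
  expect_identical(split_zygosity_snp(v), c("hom", "het", "hom", "het"))
  v <- vt("A", "G", gt = "1/2")
  expect_message(z <- split_zygosity_snp(v), "multi-allelic")
  expect_identical(z, "het")
  v <- vt(c("A", "A"), c("G", "G"), gt = c("./.", "0/0"))
  expect_identical(split_zygosity_snp(v), c(NA_character_, NA_character_))
})

test_that("DIP zygosity applies the inclusive dsP boundary", {
  v <- vt(c("A", "A", "A"), c("AC", "AC", "AC"), depth = 10L,
          alt_depth = c(8L, 7L, 0L))
  expect_identical(split_zygosity_dip(v, dsP = 80),
                   c("hom", "het", "het"))
  expect_identical(split_zygosity_dip(v, dsP = 0),
                   c("hom", "hom", "hom"))
  # zero depth is unclassifiable, not an error
  v0 <- vt("A", "AC", depth = 0L, alt_depth = 0L)
  expect_identical(split_zygosity_dip(v0, dsP = 80), "unclassifiable")
  # dsP = 100 still classifies pure-alt sites homozygous
  v1 <- vt("A", "AC", depth = 10L, alt_depth = 10L)
  expect_identical(split_zygosity_dip(v1, dsP = 100), "hom")
})

test_that("increasing dsP never grows the homozygous set", {
  plan <- fixture_plan(seed = 17, n_dips = 120L)
  dips <- gen_vcf(plan)$dips
  sizes <- vapply(seq(0, 100, by = 5), function(d)
    sum(split_zygosity_dip(dips, dsP = d) == "hom"), integer(1))
  expect_true(all(diff(sizes) <= 0L))
  z <- split_zygosity_dip(dips, dsP = 80)
  expect_equal(sum(z == "hom") + sum(z == "het") +
                 sum(z == "unclassifiable"), nrow(dips))
})

test_that("Ti/Tv counts transitions over transversions", {
  expect_equal(titv_ratio(ref = c("A", "C", "A"), alt = c("G", "T", "C")), 2.0)
  expect_true(is.na(titv_ratio(ref = "A", alt = "G")))   # zero transversions
  expect_true(is.na(titv_ratio(ref = character(), alt = character())))
  # invariant under strand complement
  ref <- c("A", "C", "G", "T", "A", "C")
  alt <- c("G", "T", "T", "G", "C", "A")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(titv_ratio(ref = unname(comp[ref]), alt = unname(comp[alt])),
               titv_ratio(ref = ref, alt = alt))
  # non-SNP rows are ignored
  expect_equal(titv_ratio(ref = c("A", "AC", "C"), alt = c("G", "A", "A")),
               titv_ratio(ref = c("A", "C"), alt = c("G", "A")))
})

test_that("association rates read the ID field and RefSeq annotation", {
  v <- vt(rep("A", 4), rep("G", 4), vid = c("rs1", "rs2", "rs3", "."),
          ann = list(c(RefSeq = "NM_1"), character(), c(RefSeq = "NM_2"),
                     character()))
  a <- association_rates(v)
  expect_equal(a$dbsnp_fraction, 0.75)
  expect_equal(a$refseq_fraction, 0.5)
  none <- association_rates(vt("A", "G"))
  expect_equal(none$dbsnp_fraction, 0)
  expect_equal(none$refseq_fraction, 0)
  expect_equal(association_rates(empty_variant_table())$dbsnp_fraction, 0)
})

test_that("annotation merging is a full outer join with source prefixes", {
  p <- data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "A", alt = "G",
                  Gene = c("TP53", "BRCA1"), score = c(1, 2),
                  stringsAsFactors = FALSE)
  s <- data.frame(chrom = "chr1", pos = c(200L, 300L), ref = "A", alt = "G",
                  Gene = c("BRCA1", "EGFR"), freq = c(0.1, 0.2),
                  stringsAsFactors = FALSE)
  m <- merge_annotation_tables(p, s)
  expect_equal(nrow(m), 3L)
  expect_true(all(c("gatk.Gene", "annovar.Gene", "score", "freq") %in%
                    names(m)))
  expect_equal(m$pos, c(100L, 200L, 300L))
  expect_true(is.na(m$freq[1]))            # primary-only key
  expect_true(is.na(m$gatk.Gene[3]))       # secondary-only key retained
  # key-symmetry: swapping roles only permutes the prefixes
  m2 <- merge_annotation_tables(s, p, prefixes = c("annovar", "gatk"))
  expect_identical(sort(names(m)), sort(names(m2)))
  expect_identical(m$gatk.Gene, m2$gatk.Gene)

  dupkey <- rbind(p, p[1, ])
  expect_error(merge_annotation_tables(dupkey, s), "duplicate key")
  expect_error(merge_annotation_tables(p[, -2], s), "lacks key column")
})

test_that("annotation tables round-trip through TSV files", {
  p <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                  Gene = "TP53", stringsAsFactors = FALSE)
  s <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                  Func = "exonic", stringsAsFactors = FALSE)
  fp <- withr::local_tempfile(fileext = ".tsv")
  fs <- withr::local_tempfile(fileext = ".tsv")
  write.table(p, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(s, fs, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- merge_annotation_tables(fp, fs)
  expect_equal(nrow(m), 1L)
  expect_identical(m$Gene, "TP53")
  expect_identical(m$Func, "exonic")
})

test_that("variant summaries are internally consistent", {
  plan <- fixture_plan(seed = 23, n_ti = 100L, n_tv = 50L, n_dips = 60L)
  v <- gen_vcf(plan)
  vs <- variant_summaries(v$snps, v$dips, dsP = plan$dsP)
  expect_equal(vs$dip$n_deletions + vs$dip$n_insertions, vs$dip$n_dips)
  expect_equal(vs$snp$n_snps, 150L)
  expect_equal(vs$snp$titv_ratio, 2.0)
  expect_equal(vs$snp$n_hom + vs$snp$n_het, vs$snp$n_snps)
  expect_equal(vs$dip$n_hom, v$manifest$n_dip_hom)
  # sections can be absent
  vs2 <- variant_summaries(snps = v$snps)
  expect_null(vs2$dip)
})

test_that("zygosity splitting partitions the table exhaustively", {
  plan <- fixture_plan(seed = 29, n_ti = 40L, n_tv = 20L, n_dips = 30L)
  v <- gen_vcf(plan)
  for (args in list(list(v$snps, "snp"), list(v$dips, "dip"))) {
    sp <- split_zygosity(args[[1]], args[[2]], dsP = 80)
    expect_equal(nrow(sp$hom) + nrow(sp$het) + nrow(sp$other),
                 nrow(args[[1]]))
    expect_length(intersect(sp$hom$pos, sp$het$pos), 0L)
  }
})
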