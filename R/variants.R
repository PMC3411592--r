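# Variant post-processing: classification, zygosity splitting (genotype
# based for SNPs, allele-fraction based for DIPs), Ti/Tv, database
# association rates, annotation-table merging and summaries.
#
# "DIP" (deletion/insertion polymorphism) is the pipeline's term for
# small indels; "dsP" the percentage threshold on the alt-allele
# fraction separating homozygous from heterozygous DIP calls.

#' Classify variants by allele length
#'
#' Determined solely by `length(ref)` vs `length(alt)`: equal lengths
#' are SNPs (including MNPs), longer alt an insertion, shorter alt a
#' deletion.
#'
#' @param ref,alt character vectors of reference and alternate alleles.
#' @return Character vector over `{"SNP", "insertion", "deletion"}`.
#' @export
classify_variant <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  d <- nchar(alt) - nchar(ref)
  ifelse(d > 0L, "insertion", ifelse(d < 0L, "deletion", "SNP"))
}

# parse "0/1", "1|1", "./." into a 2-column allele-index matrix
parse_gt <- function(gt) {
  parts <- strsplit(ifelse(is.na(gt), "./.", gt), "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1L)))
  a2 <- suppressWarnings(as.integer(vapply(parts, function(x)
    if (length(x) > 1L) x[2L] else x[1L], character(1))))
  cbind(a1, a2)
}

#' Zygosity of SNP calls from the genotype field
#'
#' Two identical non-reference allele indices are homozygous; any mixed
#' genotype (including two different alternate alleles, which is logged
#' as multi-allelic) is heterozygous.  Missing or reference-only
#' genotypes return `NA`.
#'
#' @param variants a variant table ([read_vcf()]).
#' @return Character vector over `{"hom", "het", NA}`.
#' @export
split_zygosity_snp <- function(variants) {
  g <- parse_gt(variants$gt)
  out <- unname(ifelse(is.na(g[, 1]) | is.na(g[, 2]), NA_character_,
                ifelse(g[, 1] == g[, 2] & g[, 1] > 0L, "hom",
                       ifelse(g[, 1] == 0L & g[, 2] == 0L, NA_character_,
                              "het"))))
  multi <- !is.na(g[, 1]) & !is.na(g[, 2]) & g[, 1] != g[, 2] &
    g[, 1] > 0L & g[, 2] > 0L
  if (any(multi))
    message("split_zygosity_snp: ", sum(multi),
            " multi-allelic genotype(s) classified heterozygous")
  out
}

#' Zygosity of DIP calls from the alt-allele fraction
#'
#' A DIP is homozygous iff `100 * alt_depth / depth >= dsP` (boundary
#' inclusive, so `dsP = 100` still classifies pure-alt sites as
#' homozygous and `dsP = 0` classifies everything homozygous).
#' Zero or missing depth cannot be classified and is routed to an
#' `"unclassifiable"` bucket.
#'
#' @param variants a variant table.
#' @param dsP percentage threshold in `[0, 100]`.
#' @param denominator `"depth"` (default: total depth `DP`) or
#'   `"ref_alt"` (ref-supporting + alt-supporting reads).
#' @return Character vector over `{"hom", "het", "unclassifiable"}`.
#' @export
split_zygosity_dip <- function(variants, dsP = 80, denominator = c("depth", "ref_alt")) {
  denominator <- match.arg(denominator)
  stopifnot(dsP >= 0, dsP <= 100)
  den <- if (denominator == "ref_alt" && !is.null(variants$ref_depth))
    variants$ref_depth + variants$alt_depth else variants$depth
  bad <- is.na(den) | den <= 0L | is.na(variants$alt_depth)
  frac <- ifelse(bad, NA_real_, 100 * variants$alt_depth / den)
  ifelse(bad, "unclassifiable", ifelse(frac >= dsP, "hom", "het"))
}

#' Transition/transversion ratio
#'
#' Transitions are `A<->G` and `C<->T`; the other eight substitutions
#' are transversions.  Non-SNP rows are ignored.  With zero
#' transversions the ratio is undefined and reported as `NA` (never
#' infinity).
#'
#' @param variants a variant table, or `ref`/`alt` given directly.
#' @param ref,alt optional allele vectors overriding `variants`.
#' @return `n_ti / n_tv` as a double, or `NA`.
#' @export
titv_ratio <- function(variants = NULL, ref = variants$ref, alt = variants$alt) {
  stopifnot(length(ref) == length(alt))
  snp <- nchar(ref) == 1L & nchar(alt) == 1L & ref != alt &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  ref <- ref[snp]; alt <- alt[snp]
  ti <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  n_ti <- sum(ti); n_tv <- sum(!ti)
  if (n_tv == 0L) NA_real_ else n_ti / n_tv
}

#' Database association rates
#'
#' dbSNP membership is a non-`.` VCF ID; RefSeq association is a
#' non-empty value under the `refseq_key` annotation.
#'
#' @param variants a variant table.
#' @param refseq_key annotation key carrying the RefSeq name (default
#'   `"RefSeq"`).
#' @return A list with `dbsnp_fraction` and `refseq_fraction` (0 for an
#'   empty table).
#' @export
association_rates <- function(variants, refseq_key = "RefSeq") {
  n <- nrow(variants)
  if (n == 0L) return(list(dbsnp_fraction = 0, refseq_fraction = 0))
  in_dbsnp <- !is.na(variants$vid) & variants$vid != "." & nzchar(variants$vid)
  has_refseq <- vapply(variants$ann, function(a)
    refseq_key %in% names(a) && nzchar(a[[refseq_key]]), logical(1))
  list(dbsnp_fraction = sum(in_dbsnp) / n,
       refseq_fraction = sum(has_refseq) / n)
}

#' Merge two variant annotation tables
#'
#' Full outer join of two tab-delimited annotation tables on the
#' variant key (`chrom`, `pos`, `ref`, `alt` by default).  Non-key
#' column names colliding between the tables are prefixed with their
#' source name (`gatk.Gene` / `annovar.Gene`).  Output rows are sorted
#' by `(chrom, pos)`.  Duplicate keys within one table are an error.
#'
#' @param primary,secondary data.frames or paths to TSV files with
#'   header rows containing the key columns.
#' @param key character vector of join columns.
#' @param prefixes length-2 source names used to disambiguate
#'   colliding columns.
#' @return The merged data.frame.
#' @export
merge_annotation_tables <- function(primary, secondary,
                                    key = c("chrom", "pos", "ref", "alt"),
                                    prefixes = c("gatk", "annovar")) {
  load_tab <- function(x, label) {
    if (is.character(x) && length(x) == 1L)
      x <- utils::read.delim(x, stringsAsFactors = FALSE, check.names = FALSE)
    miss <- setdiff(key, names(x))
    if (length(miss) > 0L)
      stop(label, " table lacks key column(s): ", paste(miss, collapse = ", "))
    kk <- do.call(paste, c(x[key], sep = ":"))
    dup <- unique(kk[duplicated(kk)])
    if (length(dup) > 0L)
      stop("duplicate key(s) in ", label, " table: ",
           paste(utils::head(dup, 5L), collapse = "; "))
    x
  }
  p <- load_tab(primary, prefixes[1L])
  s <- load_tab(secondary, prefixes[2L])
  clash <- intersect(setdiff(names(p), key), setdiff(names(s), key))
  if (length(clash) > 0L) {
    names(p)[match(clash, names(p))] <- paste0(prefixes[1L], ".", clash)
    names(s)[match(clash, names(s))] <- paste0(prefixes[2L], ".", clash)
  }
  m <- merge(p, s, by = key, all = TRUE, sort = FALSE)
  m <- m[order(m$chrom, m$pos), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Summaries of SNP and DIP call sets
#'
#' The figures of the report's variant sections: deletion/insertion
#' counts, RefSeq association and coding count for DIPs; SNP count,
#' dbSNP count and fraction, Ti/Tv ratio and zygosity counts for SNPs.
#' A DIP counts as coding when it carries a non-empty annotation under
#' `coding_key` (annotation engines are external; their tabular output
#' is consumed, not recomputed).
#'
#' @param snps,dips variant tables ([read_vcf()]); either may be `NULL`.
#' @param dsP DIP zygosity threshold percentage.
#' @param refseq_key,coding_key annotation keys consulted.
#' @return A list of class `variant_summary` with elements `dip` and
#'   `snp` (either `NULL` when not supplied).
#' @export
variant_summaries <- function(snps = NULL, dips = NULL, dsP = 80,
                              refseq_key = "RefSeq",
                              coding_key = "ExonicFunc") {
  dip_sec <- NULL
  if (!is.null(dips)) {
    cls <- if (nrow(dips) > 0L) classify_variant(dips$ref, dips$alt)
           else character()
    zyg <- split_zygosity_dip(dips, dsP = dsP)
    assoc <- association_rates(dips, refseq_key = refseq_key)
    coding <- vapply(dips$ann, function(a)
      coding_key %in% names(a) && nzchar(a[[coding_key]]), logical(1))
    dip_sec <- list(
      n_dips = nrow(dips),
      n_deletions = sum(cls == "deletion"),
      n_insertions = sum(cls == "insertion"),
      n_refseq_associated = round(assoc$refseq_fraction * nrow(dips)),
      refseq_fraction = assoc$refseq_fraction,
      n_coding = sum(coding),
      n_hom = sum(zyg == "hom"),
      n_het = sum(zyg == "het"),
      n_unclassifiable = sum(zyg == "unclassifiable"),
      dsP = dsP)
  }
  snp_sec <- NULL
  if (!is.null(snps)) {
    zyg <- split_zygosity_snp(snps)
    assoc <- association_rates(snps, refseq_key = refseq_key)
    snp_sec <- list(
      n_snps = nrow(snps),
      n_dbsnp = round(assoc$dbsnp_fraction * nrow(snps)),
      dbsnp_fraction = assoc$dbsnp_fraction,
      titv_ratio = titv_ratio(snps),
      n_hom = sum(zyg == "hom", na.rm = TRUE),
      n_het = sum(zyg == "het", na.rm = TRUE))
  }
  structure(list(dip = dip_sec, snp = snp_sec), class = "variant_summary")
}

#' Split a variant table by zygosity
#'
#' Convenience wrapper returning the homozygous and heterozygous
#' subsets (SNP tables split on genotype, DIP tables on the
#' alt-allele fraction at `dsP`).
#'
#' @param variants a variant table.
#' @param type `"snp"` or `"dip"`.
#' @param dsP DIP threshold percentage (ignored for SNPs).
#' @return `list(hom =, het =, other =)` of variant tables.
#' @export
split_zygosity <- function(variants, type = c("snp", "dip"), dsP = 80) {
  type <- match.arg(type)
  z <- if (type == "snp") split_zygosity_snp(variants)
       else split_zygosity_dip(variants, dsP = dsP)
  list(hom = variants[!is.na(z) & z == "hom", , drop = FALSE],
       het = variants[!is.na(z) & z == "het", , drop = FALSE],
       other = variants[is.na(z) | !(z %in% c("hom", "het")), , drop = FALSE])
}
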