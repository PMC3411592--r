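# Multi-section summary report: alignment key figures, the full filter
# accounting table, and the DIP and SNP summaries, written as sectioned
# TSV (one block per section, blank-line separated; spreadsheet
# rendering is out of scope, content over container).

#' Assemble the multi-section summary report
#'
#' Section 1 carries the alignment key figures (exome size, genome and
#' exome fold coverage, capture specificity, estimated PCR duplicates
#' by chance); section 2 the per-stage filter table (preprocessing and
#' alignment rows in stage order); sections 3 and 4 the DIP and SNP
#' summaries.  A missing upstream stage is rendered as an explicit
#' `not_run` row, never silently dropped.  Percentages are shown with
#' one decimal place, always alongside the raw counts; a full-precision
#' machine column keeps every numeric field exactly recoverable.
#'
#' @param accountings data.frame stacking every [filter_accounting()]
#'   row in stage order, or `NULL`.
#' @param coverage a `coverage_profile` from [exon_coverage()], or
#'   `NULL`.
#' @param capture_specificity fraction from [capture_specificity()], or
#'   `NA`.
#' @param expected_duplicates value from
#'   [expected_duplicates_by_chance()], or `NA`.
#' @param variant_summary a `variant_summary` from
#'   [variant_summaries()], or `NULL`.
#' @return A list of class `summary_report` with one element per
#'   section.
#' @export
build_report <- function(accountings = NULL, coverage = NULL,
                         capture_specificity = NA_real_,
                         expected_duplicates = NA_real_,
                         variant_summary = NULL) {
  num_row <- function(metric, value) data.frame(
    metric = metric,
    value = ifelse(is.na(value), "NA", format(value, digits = 17)),
    display = ifelse(is.na(value), "NA",
                     ifelse(grepl("percent|fold|ratio|fraction", metric),
                            sprintf("%.1f", value), format(value))),
    stringsAsFactors = FALSE)

  key <- if (is.null(coverage)) {
    data.frame(metric = "not_run", value = "TRUE", display = "TRUE",
               stringsAsFactors = FALSE)
  } else {
    agg <- coverage$aggregate
    rbind(num_row("exome_size_bases", agg$exome_size),
          num_row("exome_intervals", agg$n_intervals),
          num_row("genome_fold_coverage", agg$genome_fold_coverage),
          num_row("exome_fold_coverage", agg$exome_fold_coverage),
          num_row("capture_specificity_percent", 100 * capture_specificity),
          num_row("expected_pcr_duplicates_by_chance", expected_duplicates),
          num_row("fraction_intervals_not_covered_percent",
                  100 * agg$fraction_intervals_below),
          num_row("fraction_intervals_highly_covered_percent",
                  100 * agg$fraction_intervals_at_or_above))
  }

  filt <- if (is.null(accountings)) {
    data.frame(stage = "not_run", input = NA_integer_, passed = NA_integer_,
               removed = NA_integer_, passed_percent = NA_character_,
               passed_percent_value = NA_character_, stringsAsFactors = FALSE)
  } else {
    # recomputed from the counts in the same row, so the table is
    # self-consistent whatever precision the stage file carried
    pct <- ifelse(accountings$input == 0L, 100,
                  100 * accountings$passed / accountings$input)
    data.frame(stage = accountings$stage, input = accountings$input,
               passed = accountings$passed, removed = accountings$removed,
               passed_percent = sprintf("%.1f", pct),
               passed_percent_value = format(pct, digits = 17),
               stringsAsFactors = FALSE)
  }

  dip <- if (is.null(variant_summary) || is.null(variant_summary$dip)) {
    data.frame(metric = "not_run", value = "TRUE", display = "TRUE",
               stringsAsFactors = FALSE)
  } else {
    d <- variant_summary$dip
    rbind(num_row("n_dips", d$n_dips),
          num_row("n_deletions", d$n_deletions),
          num_row("n_insertions", d$n_insertions),
          num_row("refseq_associated_percent", 100 * d$refseq_fraction),
          num_row("n_coding", d$n_coding),
          num_row("n_homozygous", d$n_hom),
          num_row("n_heterozygous", d$n_het),
          num_row("n_unclassifiable", d$n_unclassifiable),
          num_row("dsP_percent_threshold", d$dsP))
  }

  snp <- if (is.null(variant_summary) || is.null(variant_summary$snp)) {
    data.frame(metric = "not_run", value = "TRUE", display = "TRUE",
               stringsAsFactors = FALSE)
  } else {
    s <- variant_summary$snp
    rbind(num_row("n_snps", s$n_snps),
          num_row("n_dbsnp", s$n_dbsnp),
          num_row("dbsnp_percent", 100 * s$dbsnp_fraction),
          num_row("titv_ratio", s$titv_ratio),
          num_row("n_homozygous", s$n_hom),
          num_row("n_heterozygous", s$n_het))
  }

  structure(list(alignment_key_figures = key, filter_table = filt,
                 dip_summary = dip, snp_summary = snp),
            class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  for (sec in names(x)) {
    cat("##", sec, "\n")
    print(x[[sec]], row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' Write a summary report as sectioned TSV (or CSV)
#'
#' One block per section, introduced by a `#section <name>` line and
#' separated by blank lines.  [read_report()] reconstructs every
#' numeric field exactly from the full-precision value columns.
#'
#' @param report a `summary_report`.
#' @param path output path.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  for (sec in names(report)) {
    writeLines(paste0("#section ", sec), con)
    utils::write.table(report[[sec]], con, sep = sep, quote = FALSE,
                       row.names = FALSE, na = "NA")
    writeLines("", con)
  }
  invisible(path)
}

#' Read back a sectioned summary report
#'
#' @param path file written by [write_report()].
#' @param format `"tsv"` or `"csv"`.
#' @return A `summary_report` list of data.frames.
#' @export
read_report <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  lines <- readLines(path)
  idx <- grep("^#section ", lines)
  stopifnot(length(idx) > 0L)
  bounds <- c(idx, length(lines) + 1L)
  out <- list()
  for (i in seq_along(idx)) {
    name <- sub("^#section ", "", lines[idx[i]])
    block <- lines[(idx[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[nzchar(block)]
    out[[name]] <- utils::read.table(text = block, sep = sep, header = TRUE,
                                     colClasses = "character",
                                     stringsAsFactors = FALSE)
  }
  structure(out, class = "summary_report")
}

# newest mtime of a set of files; -Inf when any is missing
stage_current <- function(outputs, inputs) {
  if (!all(file.exists(outputs))) return(FALSE)
  if (length(inputs) == 0L) return(TRUE)
  min(file.mtime(outputs)) >= max(file.mtime(inputs))
}

#' Run the full post-alignment pipeline and write all outputs
#'
#' The end-to-end driver over the package's stages: preprocessing of
#' the raw reads, alignment filtering of the (externally produced) SAM,
#' coverage and capture statistics, variant post-processing, and the
#' multi-section summary report.  Alignment itself and variant calling
#' are external concerns; their outputs are this driver's inputs.
#'
#' The run is resumable: a stage is skipped when all of its output
#' files already exist and are at least as new as its inputs, so
#' re-running a completed directory performs no recomputation and
#' leaves every output byte-identical.
#'
#' @param fastq_r1 path to raw reads (FASTQ); `NULL` skips
#'   preprocessing.
#' @param fastq_r2 second-mate FASTQ for PE data, or `NULL`.
#' @param sam path to the alignment SAM; `NULL` skips alignment
#'   stages.
#' @param targets_bed path to the capture-target BED file (required
#'   when `sam` is given).
#' @param snp_vcf,dip_vcf variant call files; `NULL` skips the variant
#'   sections.
#' @param gatk_table,annovar_table optional annotation TSVs to merge.
#' @param out_dir output directory.
#' @param dsP DIP zygosity threshold percentage.
#' @param genome_length reference length for fold coverage (taken from
#'   the SAM `@SQ` header when `NA`).
#' @param encoding FASTQ quality dialect, or `NULL` to auto-detect.
#' @param config a [preprocess_config()].
#' @return The `summary_report`, invisibly.
#' @export
run_all <- function(fastq_r1 = NULL, fastq_r2 = NULL, sam = NULL,
                    targets_bed = NULL, snp_vcf = NULL, dip_vcf = NULL,
                    gatk_table = NULL, annovar_table = NULL,
                    out_dir = ".", dsP = 80, genome_length = NA_real_,
                    encoding = NULL, config = preprocess_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  acct_all <- NULL

  if (!is.null(fastq_r1)) {
    outs <- c(p("preprocess_accounting.tsv"), p("reads_pass_R1.fastq"),
              if (!is.null(fastq_r2)) p("reads_pass_R2.fastq"))
    if (!stage_current(outs, c(fastq_r1, fastq_r2))) {
      r1 <- read_fastq(fastq_r1, encoding = encoding, mate =
                         if (is.null(fastq_r2)) "none" else "R1")
      r2 <- if (is.null(fastq_r2)) NULL
            else read_fastq(fastq_r2, encoding = encoding, mate = "R2")
      pp <- run_preprocess(r1, r2, config = config)
      write_accounting(pp$accounting, p("preprocess_accounting.tsv"))
      write_fastq(pp$r1, p("reads_pass_R1.fastq"))
      if (!is.null(pp$r2)) write_fastq(pp$r2, p("reads_pass_R2.fastq"))
    }
    acct_all <- read_accounting(p("preprocess_accounting.tsv"))
  }

  coverage <- NULL; spec <- NA_real_; exp_dup <- NA_real_
  if (!is.null(sam)) {
    stopifnot(!is.null(targets_bed))
    outs <- c(p("alignments_filtered.sam"), p("alnfilter_accounting.tsv"),
              p("exon_coverage.tsv"))
    if (!stage_current(outs, c(sam, targets_bed))) {
      aln <- read_sam(sam)
      targets <- read_bed(targets_bed)
      if (is.na(genome_length)) genome_length <- genome_length_from_header(aln)
      flt <- run_alnfilter(aln, targets)
      write_sam(flt$sam, p("alignments_filtered.sam"))
      write_accounting(flt$accounting, p("alnfilter_accounting.tsv"))
      cov <- exon_coverage(flt$sam, targets, genome_length = genome_length)
      utils::write.table(cov$per_interval, p("exon_coverage.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    targets <- read_bed(targets_bed)
    filtered <- read_sam(p("alignments_filtered.sam"))
    if (is.na(genome_length)) genome_length <- genome_length_from_header(filtered)
    acct_aln <- read_accounting(p("alnfilter_accounting.tsv"))
    acct_all <- rbind(acct_all, acct_aln)
    coverage <- exon_coverage(filtered, targets, genome_length = genome_length)
    # specificity = on-target / mapped-after-dedup, i.e. the exome-filter
    # stage's pass fraction (the filtered SAM itself is all on-target)
    ex <- acct_aln[acct_aln$stage == "exome-filter", ]
    spec <- if (nrow(ex) == 1L && ex$input > 0L) ex$passed / ex$input
            else NA_real_
    n_after_dup <- acct_aln$passed[acct_aln$stage == "duplicate-filter"]
    exp_dup <- expected_duplicates_by_chance(
      n_after_dup, 2 * coverage$aggregate$exome_size)
  }

  vs <- NULL
  if (!is.null(snp_vcf) || !is.null(dip_vcf)) {
    snps <- if (is.null(snp_vcf)) NULL else read_vcf(snp_vcf)
    dips <- if (is.null(dip_vcf)) NULL else read_vcf(dip_vcf)
    vs <- variant_summaries(snps, dips, dsP = dsP)
    if (!is.null(snps)) {
      sp <- split_zygosity(snps, "snp")
      if (!stage_current(c(p("snps_hom.vcf"), p("snps_het.vcf")), snp_vcf)) {
        write_vcf(sp$hom, p("snps_hom.vcf"))
        write_vcf(sp$het, p("snps_het.vcf"))
      }
    }
    if (!is.null(dips)) {
      sp <- split_zygosity(dips, "dip", dsP = dsP)
      if (!stage_current(c(p("dips_hom.vcf"), p("dips_het.vcf")), dip_vcf)) {
        write_vcf(sp$hom, p("dips_hom.vcf"))
        write_vcf(sp$het, p("dips_het.vcf"))
      }
    }
    if (!is.null(gatk_table) && !is.null(annovar_table) &&
        !stage_current(p("annotation_merged.tsv"), c(gatk_table, annovar_table))) {
      merged <- merge_annotation_tables(gatk_table, annovar_table)
      utils::write.table(merged, p("annotation_merged.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  report <- build_report(accountings = acct_all, coverage = coverage,
                         capture_specificity = spec,
                         expected_duplicates = exp_dup,
                         variant_summary = vs)
  if (!file.exists(p("summary_report.tsv")) ||
      !identical(readLines(p("summary_report.tsv")),
                 report_lines(report))) {
    write_report(report, p("summary_report.tsv"))
  }
  invisible(report)
}

report_lines <- function(report) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_report(report, tmp)
  readLines(tmp)
}

read_accounting <- function(path) {
  acct <- utils::read.delim(path, stringsAsFactors = FALSE)
  acct$passed_percent <- as.numeric(acct$passed_percent)
  acct
}

genome_length_from_header <- function(sam) {
  sq <- grep("^@SQ", sam$header, value = TRUE)
  if (length(sq) == 0L) return(NA_real_)
  ln <- sub(".*\tLN:([0-9]+).*", "\\1", sq)
  sum(as.numeric(ln))
}
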