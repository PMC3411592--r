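# Readers, writers and quality-encoding conversion for the standard
# sequencing formats the pipeline touches: FASTQ (Sanger / Solexa /
# Illumina 1.3+ dialects), ABI SOLiD csfasta + qual pairs, SAM, BED, VCF.

# ASCII offsets and legal Phred/Solexa ranges per FASTQ dialect.
.FQ_OFFSET <- c(sanger = 33L, solexa = 64L, illumina13 = 64L)
.FQ_QMIN   <- c(sanger = 0L,  solexa = -5L, illumina13 = 0L)
.FQ_QMAX   <- c(sanger = 93L, solexa = 62L, illumina13 = 62L)

#' Construct a read set
#'
#' A read set is the in-memory carrier for sequencing reads: a
#' `data.frame` with one row per read, columns `id` (identifier without
#' the leading `@`), `bases` (nucleotides over `A,C,G,T,N`, or for
#' SOLiD colour space a leading adapter base followed by colours over
#' `0,1,2,3,.`), and `quals` (a list column of integer Phred values, one
#' per base; for colour space one per colour, the adapter base carries
#' no quality).  The quality encoding (`sanger`, `solexa`, `illumina13`
#' or `solid`) and the mate tag (`none`, `R1`, `R2`) are stored as
#' attributes of the data frame.
#'
#' @param id character vector of read identifiers.
#' @param bases character vector of base (or colour) strings.
#' @param quals list of integer vectors of per-position qualities.
#' @param encoding quality encoding of `quals`.
#' @param mate mate tag for the whole set.
#' @return A `read_set` data.frame.
#' @export
read_set <- function(id = character(), bases = character(), quals = list(),
                     encoding = c("sanger", "solexa", "illumina13", "solid"),
                     mate = c("none", "R1", "R2")) {
  encoding <- match.arg(encoding)
  mate <- match.arg(mate)
  stopifnot(length(id) == length(bases), length(id) == length(quals))
  expected <- if (encoding == "solid") pmax(nchar(bases) - 1L, 0L) else nchar(bases)
  actual <- lengths(quals)
  if (any(actual != expected)) {
    bad <- which(actual != expected)[1L]
    stop("quality length does not match sequence length for read '",
         id[bad], "' (", actual[bad], " vs ", expected[bad], ")")
  }
  rs <- data.frame(id = as.character(id), bases = as.character(bases),
                   stringsAsFactors = FALSE)
  rs$quals <- quals
  structure(rs, encoding = encoding, mate = mate,
            class = c("read_set", "data.frame"))
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", nrow(x), "reads, encoding", attr(x, "encoding"),
      if (attr(x, "mate") != "none") paste0("(", attr(x, "mate"), ")"), "\n")
  if (nrow(x) > 0L) {
    show <- utils::head(x, 3L)
    for (i in seq_len(nrow(show)))
      cat(" ", show$id[i], substr(show$bases[i], 1L, 40L), "\n")
    if (nrow(x) > 3L) cat("  ...\n")
  }
  invisible(x)
}

#' Number of scored positions per read
#'
#' Sequence length as seen by filters and trimmers: number of
#' nucleotides, or number of colours for SOLiD reads (the adapter base
#' is not a scored position).
#'
#' @param reads a `read_set`.
#' @return Integer vector.
#' @export
read_lengths <- function(reads) {
  n <- nchar(reads$bases)
  if (identical(attr(reads, "encoding"), "solid")) n <- pmax(n - 1L, 0L)
  n
}

# keep a read_set's attributes through a row subset
subset_reads <- function(reads, idx) {
  out <- reads[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, encoding = attr(reads, "encoding"), mate = attr(reads, "mate"),
            class = c("read_set", "data.frame"))
}

# replace bases/quals wholesale, preserving attributes
replace_seq <- function(reads, bases, quals) {
  reads$bases <- bases
  reads$quals <- quals
  reads
}

#' Detect the FASTQ quality dialect from quality lines
#'
#' Inspects the ASCII code points of a sample of quality lines.  Codes
#' below 59 can only be Phred+33 (Sanger); codes in 59--63 rule out
#' Sanger's companions and indicate Solexa; lines confined to the
#' overlapping high range (>= 64) are ambiguous between Solexa and
#' Illumina 1.3+ (and legal Sanger), and resolve to `default`.
#'
#' @param qual_lines character vector of raw FASTQ quality lines.
#' @param default dialect returned when the observed range is ambiguous.
#' @return One of `"sanger"`, `"solexa"`, `"illumina13"`.
#' @export
detect_fastq_dialect <- function(qual_lines,
                                 default = c("sanger", "solexa", "illumina13")) {
  default <- match.arg(default)
  qual_lines <- qual_lines[nzchar(qual_lines)]
  if (length(qual_lines) == 0L)
    stop("need at least one non-empty quality line")
  codes <- unlist(lapply(qual_lines, utf8ToInt), use.names = FALSE)
  bad <- codes[codes < 33L | codes > 126L]
  if (length(bad) > 0L)
    stop("quality character code ", bad[1L],
         " is outside every FASTQ dialect range [33,126]")
  m <- min(codes)
  if (m < 59L) "sanger" else if (m < 64L) "solexa" else default
}

#' Convert quality values between FASTQ encodings
#'
#' Sanger and Illumina 1.3+ both store Phred-scaled qualities (only the
#' ASCII offset differs), so conversion between them is the identity on
#' the quality value.  Solexa qualities are odds-scaled,
#' `q_solexa = -10 log10(p / (1 - p))`; conversion to Phred goes through
#' probability space, `q_phred = 10 log10(10^(q_solexa/10) + 1)`,
#' rounded half-up to the nearest integer (matching the published
#' conversion tables).  Results are clamped to the target encoding's
#' legal range.
#'
#' @param q integer vector of quality values in the source encoding.
#' @param from,to source and target encodings (`sanger`, `solexa`,
#'   `illumina13`).
#' @return Integer vector of converted quality values.
#' @export
convert_quality <- function(q, from = c("sanger", "solexa", "illumina13"),
                            to = c("sanger", "solexa", "illumina13")) {
  from <- match.arg(from)
  to <- match.arg(to)
  q <- as.integer(q)
  if (any(q < .FQ_QMIN[[from]] | q > .FQ_QMAX[[from]]))
    stop("quality value out of range [", .FQ_QMIN[[from]], ",",
         .FQ_QMAX[[from]], "] for encoding '", from, "'")
  if (length(q) == 0L || from == to) return(q)
  phred_scaled <- c(sanger = TRUE, solexa = FALSE, illumina13 = TRUE)
  x <- if (phred_scaled[[from]]) as.numeric(q)
       else 10 * log10(10^(q / 10) + 1)       # solexa -> phred
  if (!phred_scaled[[to]]) {
    # phred -> solexa: inverse odds mapping; phred 0 maps below the floor
    x <- ifelse(x <= 0, -Inf, 10 * log10(pmax(10^(x / 10) - 1, .Machine$double.xmin)))
  }
  x <- floor(x + 0.5)                          # round half up
  as.integer(pmin(pmax(x, .FQ_QMIN[[to]]), .FQ_QMAX[[to]]))
}

# quality string <-> integer vector for a given dialect
quals_from_string <- function(s, encoding) {
  off <- .FQ_OFFSET[[encoding]]
  lapply(s, function(x) utf8ToInt(x) - off)
}

quals_to_string <- function(quals, encoding) {
  off <- .FQ_OFFSET[[encoding]]
  vapply(quals, function(q) {
    if (length(q) == 0L) "" else intToUtf8(as.integer(q) + off)
  }, character(1))
}

#' Read a FASTQ file
#'
#' Reads 4-line FASTQ records.  When `encoding` is `NULL` the dialect is
#' detected heuristically from up to 1000 quality lines
#' ([detect_fastq_dialect()]); pass an explicit encoding to bypass
#' detection, as overlapping code ranges make it fallible.
#'
#' @param path FASTQ file path.
#' @param encoding quality dialect, or `NULL` to auto-detect.
#' @param default dialect used when detection is ambiguous.
#' @param mate mate tag to attach (`none`, `R1`, `R2`).
#' @return A [read_set()].
#' @export
read_fastq <- function(path, encoding = NULL, default = "sanger",
                       mate = c("none", "R1", "R2")) {
  mate <- match.arg(mate)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ file '", path, "' does not contain 4-line records (",
         length(lines), " lines)")
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(read_set(encoding = if (is.null(encoding)) default else encoding,
                    mate = mate))
  idl <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  quall <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(substr(idl, 1L, 1L) != "@"))
    stop("malformed FASTQ record header in '", path, "'")
  if (is.null(encoding))
    encoding <- detect_fastq_dialect(utils::head(quall, 1000L), default = default)
  read_set(id = substring(idl, 2L), bases = seqs,
           quals = quals_from_string(quall, encoding),
           encoding = encoding, mate = mate)
}

#' Write a FASTQ file (always in the Sanger dialect)
#'
#' Qualities are converted to Phred+33 on the way out regardless of the
#' set's encoding; Sanger input round-trips byte-identically.  Colour
#' space reads cannot be written as FASTQ (use [write_csfasta_qual()]).
#'
#' @param reads a `read_set`.
#' @param path output path.
#' @return Number of records written, invisibly.
#' @export
write_fastq <- function(reads, path) {
  enc <- attr(reads, "encoding")
  if (identical(enc, "solid"))
    stop("colour-space reads cannot be written as FASTQ; use write_csfasta_qual()")
  quals <- if (enc == "sanger") reads$quals
           else lapply(reads$quals, convert_quality, from = enc, to = "sanger")
  out <- character(4L * nrow(reads))
  if (nrow(reads) > 0L) {
    out[seq(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$id)
    out[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$bases
    out[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
    out[seq(4L, by = 4L, length.out = nrow(reads))] <-
      quals_to_string(quals, "sanger")
  }
  writeLines(out, path)
  invisible(nrow(reads))
}

# minimal FASTA reader: returns list(id=, seq=); '#' comment lines allowed
# (csfasta convention).  Sequence may span multiple lines.
read_fasta_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  hdr <- startsWith(lines, ">")
  if (length(lines) > 0L && !hdr[1L])
    stop("'", path, "' is not in FASTA layout (no leading '>')")
  grp <- cumsum(hdr)
  ids <- substring(lines[hdr], 2L)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = " ")
  # records with empty sequence keep an empty string
  full <- setNames(character(length(ids)), seq_along(ids))
  full[names(seqs)] <- seqs
  list(id = ids, seq = unname(full))
}

#' Read an ABI SOLiD csfasta + qual file pair
#'
#' Both files are FASTA-layout; records are paired positionally and
#' must agree on identifiers.  The colour string keeps its leading
#' adapter base; qualities attach one per colour.
#'
#' @param csfasta_path colour-space FASTA path.
#' @param qual_path matching quality FASTA path (space-separated
#'   integers).
#' @return A [read_set()] with encoding `"solid"`.
#' @export
read_csfasta_qual <- function(csfasta_path, qual_path) {
  cs <- read_fasta_records(csfasta_path)
  qu <- read_fasta_records(qual_path)
  n <- length(cs$id)
  if (n != length(qu$id)) {
    k <- min(n, length(qu$id)) + 1L
    first <- if (k <= n) cs$id[k] else qu$id[k]
    stop("csfasta/qual record count mismatch (", n, " vs ", length(qu$id),
         "); first unpaired record: '", first, "'")
  }
  diverge <- which(cs$id != qu$id)
  if (length(diverge) > 0L)
    stop("csfasta/qual identifier mismatch at record ", diverge[1L], ": '",
         cs$id[diverge[1L]], "' vs '", qu$id[diverge[1L]], "'")
  bases <- gsub(" ", "", cs$seq)
  quals <- lapply(qu$seq, function(s) {
    if (!nzchar(trimws(s))) integer() else as.integer(strsplit(trimws(s), "\\s+")[[1]])
  })
  read_set(id = cs$id, bases = bases, quals = quals, encoding = "solid")
}

#' Write an ABI SOLiD csfasta + qual file pair
#'
#' @param reads a colour-space `read_set`.
#' @param csfasta_path,qual_path output paths.
#' @return Number of records written, invisibly.
#' @export
write_csfasta_qual <- function(reads, csfasta_path, qual_path) {
  stopifnot(identical(attr(reads, "encoding"), "solid"))
  writeLines(as.vector(rbind(paste0(">", reads$id), reads$bases)), csfasta_path)
  qlines <- vapply(reads$quals, paste, character(1), collapse = " ")
  writeLines(as.vector(rbind(paste0(">", reads$id), qlines)), qual_path)
  invisible(nrow(reads))
}

#' Read a BED file of capture target regions
#'
#' BED is 0-based half-open on disk; the returned `GRanges` follows the
#' Bioconductor 1-based closed convention (the conversion is done by
#' rtracklayer at the boundary, as for every cross-format position in
#' this package).
#'
#' @param path BED3+/BED6 file path.
#' @return A [GenomicRanges::GRanges] with a `name` column when present.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Write target regions as BED
#'
#' @param targets a `GRanges`.
#' @param path output path.
#' @export
write_bed <- function(targets, path) {
  rtracklayer::export(targets, path, format = "bed")
  invisible(path)
}

#' Normalize a target set
#'
#' Sorts intervals and merges overlapping or bookended ones, the form
#' the on-target filter and coverage metrics expect.
#'
#' @param targets a `GRanges`.
#' @return Sorted, reduced `GRanges`.
#' @export
normalize_targets <- function(targets) {
  GenomicRanges::reduce(GenomicRanges::sort(targets))
}

#' Read a VCF into a variant table
#'
#' Parses a VCF v4.x file (via vcfR) into a flat per-alt-allele variant
#' table: multi-allelic records are split into one row per alternate
#' allele so every downstream count is well-defined.  Genotype (`GT`),
#' total depth (`DP`) and allele depth (`AD`) are extracted from the
#' first sample when present; INFO key=value pairs become a named list
#' column `ann`.
#'
#' @param path VCF file path.
#' @return A data.frame with columns `chrom`, `pos`, `vid`, `ref`,
#'   `alt`, `qual`, `gt`, `depth`, `ref_depth`, `alt_depth` and list
#'   column `ann`.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_variant_table())
  gt <- dp <- ad <- rep(NA_character_, nrow(fix))
  if (ncol(vcf@gt) >= 2L) {
    gt <- as.vector(vcfR::extract.gt(vcf, element = "GT"))
    dp <- as.vector(vcfR::extract.gt(vcf, element = "DP"))
    ad <- as.vector(vcfR::extract.gt(vcf, element = "AD"))
  }
  ann <- lapply(fix$INFO, parse_info_field)
  alts <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  nalt <- pmax(lengths(alts), 1L)
  idx <- rep(seq_len(nrow(fix)), nalt)
  which_alt <- unlist(lapply(nalt, seq_len), use.names = FALSE)
  ad_split <- strsplit(ifelse(is.na(ad), "", ad), ",", fixed = TRUE)
  alt_depth <- mapply(function(a, k) {
    # AD lists ref first, then one depth per alt allele
    if (length(a) >= k + 1L) suppressWarnings(as.integer(a[k + 1L])) else NA_integer_
  }, ad_split[idx], which_alt)
  ref_depth <- vapply(ad_split[idx], function(a) {
    if (length(a) >= 1L && nzchar(a[1L]))
      suppressWarnings(as.integer(a[1L])) else NA_integer_
  }, integer(1))
  out <- data.frame(
    chrom = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    vid = ifelse(is.na(fix$ID[idx]), ".", fix$ID[idx]),
    ref = fix$REF[idx],
    alt = unlist(lapply(alts, function(a) if (length(a)) a else NA_character_),
                 use.names = FALSE),
    qual = suppressWarnings(as.numeric(fix$QUAL[idx])),
    gt = gt[idx],
    depth = suppressWarnings(as.integer(dp[idx])),
    ref_depth = as.integer(ref_depth),
    alt_depth = as.integer(alt_depth),
    stringsAsFactors = FALSE)
  out$ann <- ann[idx]
  rownames(out) <- NULL
  out
}

empty_variant_table <- function() {
  out <- data.frame(chrom = character(), pos = integer(), vid = character(),
                    ref = character(), alt = character(), qual = numeric(),
                    gt = character(), depth = integer(), ref_depth = integer(),
                    alt_depth = integer(), stringsAsFactors = FALSE)
  out$ann <- list()
  out
}

parse_info_field <- function(info) {
  if (is.na(info) || info == "." || !nzchar(info)) return(character())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[2L] else "", character(1))
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  vals
}

#' Write a variant table as a minimal VCF
#'
#' Emits plain-text VCF v4.2 with a single sample carrying
#' `GT:DP:AD`.  Annotation list columns are serialised back into INFO.
#'
#' @param variants a variant table as returned by [read_vcf()].
#' @param path output path.
#' @param sample_name sample column header.
#' @export
write_vcf <- function(variants, path, sample_name = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", sample_name, sep = "\t"))
  body <- character(0)
  if (nrow(variants) > 0L) {
    info <- vapply(seq_len(nrow(variants)), function(i) {
      a <- variants$ann[[i]]
      if (length(a) == 0L) return(".")
      paste(ifelse(nzchar(a), paste0(names(a), "=", a), names(a)), collapse = ";")
    }, character(1))
    dp <- ifelse(is.na(variants$depth), ".", as.character(variants$depth))
    rd <- if (!is.null(variants$ref_depth) && !all(is.na(variants$ref_depth)))
      variants$ref_depth else variants$depth - variants$alt_depth
    ad <- ifelse(is.na(variants$alt_depth) | is.na(rd), ".",
                 paste0(rd, ",", variants$alt_depth))
    body <- paste(variants$chrom, variants$pos, variants$vid, variants$ref,
                  variants$alt,
                  ifelse(is.na(variants$qual), ".", format(variants$qual)),
                  "PASS", info, "GT:DP:AD",
                  paste(ifelse(is.na(variants$gt), "./.", variants$gt), dp, ad,
                        sep = ":"),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(nrow(variants))
}

# SAM flag bits
FLAG_PAIRED <- 0x1L; FLAG_PROPER_PAIR <- 0x2L; FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L; FLAG_REVERSE <- 0x10L; FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST_IN_PAIR <- 0x40L; FLAG_SECOND_IN_PAIR <- 0x80L
FLAG_SECONDARY <- 0x100L; FLAG_DUPLICATE <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

#' Test SAM flag bits
#'
#' @param flag integer vector of SAM FLAG values.
#' @param bit one flag bit constant (e.g. `FLAG_UNMAPPED`).
#' @return Logical vector.
#' @export
has_flag <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

#' Read a SAM file
#'
#' Parses a tab-delimited SAM text file into an alignment set: a list
#' with `header` (the `@`-lines verbatim) and `records`, a data.frame
#' with the eleven mandatory columns plus `tags` (remaining fields,
#' tab-joined).  For mapped records with both SEQ and CIGAR present the
#' CIGAR query width must equal the sequence length.
#'
#' @param path SAM file path.
#' @return An alignment set (class `sam_set`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  body <- lines[!is_hdr & nzchar(lines)]
  if (length(body) == 0L) return(sam_set(header = header))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("SAM record with fewer than 11 fields at line ",
         which(!is_hdr & nzchar(lines))[which(nf < 11L)[1L]])
  pick <- function(k) vapply(fields, `[[`, character(1), k)
  rec <- data.frame(
    qname = pick(1L), flag = as.integer(pick(2L)), rname = pick(3L),
    pos = as.integer(pick(4L)), mapq = as.integer(pick(5L)),
    cigar = pick(6L), rnext = pick(7L), pnext = as.integer(pick(8L)),
    tlen = as.integer(pick(9L)), seq = pick(10L), qual = pick(11L),
    tags = vapply(fields, function(x)
      if (length(x) > 11L) paste(x[-(1:11)], collapse = "\t") else "",
      character(1)),
    stringsAsFactors = FALSE)
  mapped <- !has_flag(rec$flag, FLAG_UNMAPPED) & rec$cigar != "*" & rec$seq != "*"
  if (any(mapped)) {
    qw <- GenomicAlignments::cigarWidthAlongQuerySpace(rec$cigar[mapped])
    bad <- which(qw != nchar(rec$seq[mapped]))
    if (length(bad) > 0L)
      stop("CIGAR/sequence length mismatch for record '",
           rec$qname[mapped][bad[1L]], "'")
  }
  if (any(rec$pos < 0L)) stop("negative POS in SAM record")
  sam_set(header = header, records = rec)
}

#' Construct an alignment set
#'
#' @param header character vector of SAM header lines.
#' @param records data.frame of SAM records (11 mandatory columns plus
#'   `tags`).
#' @return A `sam_set` list.
#' @export
sam_set <- function(header = character(), records = NULL) {
  if (is.null(records))
    records <- data.frame(qname = character(), flag = integer(),
                          rname = character(), pos = integer(),
                          mapq = integer(), cigar = character(),
                          rnext = character(), pnext = integer(),
                          tlen = integer(), seq = character(),
                          qual = character(), tags = character(),
                          stringsAsFactors = FALSE)
  rownames(records) <- NULL
  structure(list(header = header, records = records), class = "sam_set")
}

#' @export
print.sam_set <- function(x, ...) {
  cat("sam_set:", nrow(x$records), "records,", length(x$header),
      "header lines\n")
  invisible(x)
}

#' Write an alignment set as SAM
#'
#' @param sam a `sam_set`.
#' @param path output path.
#' @return Number of records written, invisibly.
#' @export
write_sam <- function(sam, path) {
  r <- sam$records
  body <- character(0)
  if (nrow(r) > 0L) {
    body <- paste(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, r$rnext,
                  r$pnext, r$tlen, r$seq, r$qual, sep = "\t")
    extra <- nzchar(r$tags)
    body[extra] <- paste(body[extra], r$tags[extra], sep = "\t")
  }
  writeLines(c(sam$header, body), path)
  invisible(nrow(r))
}
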