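# Format boundaries. Coordinates: VCF is 1-based inclusive, BED 0-based
# half-open; internal interval arithmetic is 0-based half-open with
# conversion only here and in utils.R.

#' Read a single-nucleus VCF
#'
#' Reads a VCF v4.2 with one sample per nucleus and per-sample GT/DP/AD,
#' as written by [export_fixture()] or by a haploid joint-genotyping run.
#' INFO must carry the QD/FS/MQ/SOR annotations (rank sums optional; when
#' absent they are recorded as missing and never fail hard filters); the
#' QUAL column must be populated.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @return List with `obs` (an [observation_matrix()]), `annotations`
#'   (a [site_annotations()]) and `nucleus_ids`.
#' @section Errors: multi-allelic records are rejected (the caller
#'   emulation is biallelic, `max_alternate_alleles = 1`); malformed
#'   records propagate a parse error naming the offending record.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_invalid("read_vcf: no such file: %s", path)
  validate_vcf_lines(path)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) {
      stop_invalid("read_vcf: parse error in %s: %s", path,
                   conditionMessage(e))
    })
  rr <- SummarizedExperiment::rowRanges(vcf)
  n_alt <- S4Vectors::elementNROWS(rr$ALT)
  if (any(n_alt > 1L)) {
    stop_invalid(
      "read_vcf: multi-allelic record at %s:%d (max_alternate_alleles = 1)",
      as.character(GenomicRanges::seqnames(rr))[which(n_alt > 1L)[1L]],
      GenomicRanges::start(rr)[which(n_alt > 1L)[1L]])
  }
  sites <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = vapply(seq_along(rr$ALT), function(i) {
      a <- rr$ALT[[i]]
      if (length(a) == 0L) "N" else as.character(a)[1L]
    }, character(1)),
    stringsAsFactors = FALSE)
  geno <- VariantAnnotation::geno(vcf)
  for (f in c("DP", "AD")) {
    if (!f %in% names(geno)) stop_invalid("read_vcf: FORMAT lacks %s", f)
  }
  dp <- geno$DP
  dp[is.na(dp)] <- 0L
  rownames(dp) <- NULL
  ad <- geno$AD
  S <- nrow(sites); N <- ncol(dp)
  ref_count <- matrix(0L, S, N, dimnames = dimnames(dp))
  alt_count <- ref_count
  if (is.list(ad) || is.array(ad)) {
    for (j in seq_len(N)) {
      for (i in seq_len(S)) {
        v <- if (length(dim(ad)) == 3L) ad[i, j, ] else ad[[(j - 1L) * S + i]]
        v[is.na(v)] <- 0L
        if (length(v) >= 1L) ref_count[i, j] <- v[1L]
        if (length(v) >= 2L) alt_count[i, j] <- v[2L]
      }
    }
  }
  info <- VariantAnnotation::info(vcf)
  qual <- rr$QUAL
  if (anyNA(qual)) stop_invalid("read_vcf: QUAL column not populated")
  need <- c("QD", "FS", "MQ", "SOR")
  if (!all(need %in% names(info))) {
    stop_invalid("read_vcf: INFO lacks %s",
                 paste(setdiff(need, names(info)), collapse = ", "))
  }
  get_num <- function(field, default = NA_real_) {
    if (field %in% names(info)) as.numeric(info[[field]]) else
      rep(default, S)
  }
  ann <- site_annotations(
    QD = get_num("QD"), FS = get_num("FS"), MQ = get_num("MQ"),
    MQRankSum = get_num("MQRankSum"),
    ReadPosRankSum = get_num("ReadPosRankSum"),
    QUAL = as.numeric(qual), SOR = get_num("SOR"))
  obs <- observation_matrix(sites, storage_int(dp), storage_int(ref_count),
                            storage_int(alt_count))
  list(obs = obs, annotations = ann, nucleus_ids = colnames(dp))
}

# Structural pre-scan so malformed records fail with their line number
# (the full parser is more forgiving than the contract allows).
validate_vcf_lines <- function(path) {
  lines <- readLines(path)
  data_idx <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in data_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 10L) {
      stop_invalid("read_vcf: parse error at line %d: fewer than 10 columns",
                   i)
    }
    if (is.na(suppressWarnings(as.integer(f[2L])))) {
      stop_invalid("read_vcf: parse error at line %d: POS '%s' not an integer",
                   i, f[2L])
    }
  }
  invisible()
}

storage_int <- function(m) {
  storage.mode(m) <- "integer"
  m
}

#' Read a BED file as a normalized interval set
#'
#' @param path path to a 3+ column BED file (0-based half-open); track and
#'   browser lines are skipped.
#' @return Interval set `data.frame` (contig, start, end), sorted and
#'   merged, with the exact merged total length as attribute `total_bp`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_invalid("read_bed: no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    iv <- interval_set()
    attr(iv, "total_bp") <- 0
    return(iv)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad) > 0L) {
    stop_invalid("read_bed: line %d has fewer than 3 columns", bad[1L])
  }
  contig <- vapply(parts, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop_invalid("read_bed: non-numeric coordinate at line %d",
                 which(is.na(start) | is.na(end))[1L])
  }
  if (any(end <= start)) {
    stop_invalid("read_bed: end <= start at line %d", which(end <= start)[1L])
  }
  iv <- interval_set(contig, start, end)
  attr(iv, "total_bp") <- sum(iv$end - iv$start)
  iv
}

#' Write an interval set as BED
#'
#' @param intervals interval set `data.frame` (0-based half-open).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  df <- intervals[, c("contig", "start", "end"), drop = FALSE]
  write.table(format(df, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- fixture export ------------------------------------------------------

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = digits, format = "g"))
}

#' Export a simulated spore as an on-disk fixture
#'
#' Writes a minimal VCF v4.2 (one sample per nucleus, FORMAT GT:DP:AD,
#' INFO QD/FS/MQ/MQRankSum/ReadPosRankSum/SOR, populated QUAL), repeat and
#' coding BED masks, a contig size table, and the truth TSV. Reading the
#' VCF back with [read_vcf()] reproduces the observation matrices exactly.
#'
#' @param truth a `spore_truth`.
#' @param obs an [observation_matrix()].
#' @param annotations matching [site_annotations()].
#' @param ref the [reference_model()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the files written (vcf, repeat_bed,
#'   coding_bed, contigs, truth).
#' @export
export_fixture <- function(truth, obs, annotations, ref, out_dir) {
  stopifnot(inherits(obs, "observation_matrix"),
            nrow(annotations) == nrow(obs$sites))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("export_fixture: cannot create %s", out_dir))
  }
  paths <- c(vcf = file.path(out_dir, "observations.vcf"),
             repeat_bed = file.path(out_dir, "repeats.bed"),
             coding_bed = file.path(out_dir, "coding.bed"),
             contigs = file.path(out_dir, "contigs.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_obs_vcf(obs, annotations, ref, paths[["vcf"]])
  write_bed(ref$repeat_intervals, paths[["repeat_bed"]])
  write_bed(ref$coding_intervals, paths[["coding_bed"]])
  write.table(ref$contigs, paths[["contigs"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth$variant_sites, paths[["truth"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

write_obs_vcf <- function(obs, ann, ref, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=karyosnp-simulator",
    sprintf("##contig=<ID=%s,length=%.0f>", ref$contigs$contig,
            ref$contigs$length),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias (phred)\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank-sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank-sum\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt read counts after quality gates\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", obs$nucleus_ids), collapse = "\t"))
  S <- nrow(obs$sites)
  body <- character(0)
  if (S > 0L) {
    gt <- call_haploid_genotype(obs$depth, obs$ref_count, obs$alt_count)
    gt_str <- matrix(ifelse(is.na(gt), ".", as.character(gt)),
                     nrow(gt), ncol(gt))
    sample_fields <- matrix(
      paste0(gt_str, ":", obs$depth, ":", obs$ref_count, ",",
             obs$alt_count),
      nrow(gt), ncol(gt))
    info <- sprintf("QD=%s;FS=%s;MQ=%s%s%s;SOR=%s",
                    fmt_num(ann$QD), fmt_num(ann$FS), fmt_num(ann$MQ),
                    ifelse(is.na(ann$MQRankSum), "",
                           paste0(";MQRankSum=", fmt_num(ann$MQRankSum))),
                    ifelse(is.na(ann$ReadPosRankSum), "",
                           paste0(";ReadPosRankSum=",
                                  fmt_num(ann$ReadPosRankSum))),
                    fmt_num(ann$SOR))
    fixed <- cbind(obs$sites$contig, obs$sites$pos, ".", obs$sites$ref,
                   obs$sites$alt, fmt_num(ann$QUAL), ".", info, "GT:DP:AD")
    body <- apply(cbind(fixed, sample_fields), 1L, paste, collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a truth TSV written by [export_fixture()]
#'
#' @param path path to `truth.tsv`.
#' @return `data.frame` with columns contig, pos, ref, alt, carrier.
#' @export
read_truth <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c("character", "integer", "character",
                            "character", "character"))
}

#' Serialize a filter report as TSV
#'
#' @param report a `filter_report` from [run_filter_chain()].
#' @param path output file path.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(field = names(report),
                   value = unlist(report, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
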