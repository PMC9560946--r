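# Core containers. Genotype calls are coded as an integer matrix:
# 0 = REF, 1 = ALT, NA = MISSING (mirrors haploid VCF GT 0 / 1 / .).

#' Construct an observation matrix
#'
#' Per-(site, nucleus) read evidence: total depth and post-gate ref/alt
#' read counts. `ref_count + alt_count <= depth`; the gap is reads
#' discarded by quality gates.
#'
#' @param sites `data.frame` with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, one row per site, in genomic order.
#' @param depth,ref_count,alt_count integer matrices, sites x nuclei, with
#'   nucleus ids as column names.
#' @return An object of class `observation_matrix`.
#' @export
observation_matrix <- function(sites, depth, ref_count, alt_count) {
  stopifnot(is.data.frame(sites),
            all(c("contig", "pos", "ref", "alt") %in% names(sites)))
  S <- nrow(sites)
  for (m in list(depth, ref_count, alt_count)) {
    if (!is.matrix(m) || nrow(m) != S) {
      stop_invalid("observation_matrix: matrix dimensions inconsistent")
    }
  }
  if (!identical(dim(depth), dim(ref_count)) ||
      !identical(dim(depth), dim(alt_count))) {
    stop_invalid("observation_matrix: matrix dimensions inconsistent")
  }
  if (any(depth < 0) || any(ref_count < 0) || any(alt_count < 0)) {
    stop_invalid("observation_matrix: negative counts")
  }
  if (any(ref_count + alt_count > depth)) {
    stop_invalid("observation_matrix: ref_count + alt_count > depth")
  }
  structure(list(sites = sites, depth = depth, ref_count = ref_count,
                 alt_count = alt_count,
                 nucleus_ids = colnames(depth) %||%
                   sprintf("nucleus_%02d", seq_len(ncol(depth)))),
            class = "observation_matrix")
}

#' @export
print.observation_matrix <- function(x, ...) {
  cat(sprintf("observation_matrix: %d sites x %d nuclei\n",
              nrow(x$sites), length(x$nucleus_ids)))
  invisible(x)
}

#' Construct per-site quality annotations
#'
#' The seven per-site quality statistics used for hard filtering. The two
#' rank-sum statistics may be `NA` (annotation absent at sites without
#' mixed evidence); a missing rank-sum never fails its hard-filter test.
#'
#' @param QD,FS,MQ,MQRankSum,ReadPosRankSum,QUAL,SOR numeric vectors of a
#'   common length (one value per site).
#' @return A `data.frame` of class `site_annotations`.
#' @export
site_annotations <- function(QD, FS, MQ, MQRankSum, ReadPosRankSum,
                             QUAL, SOR) {
  df <- data.frame(QD = QD, FS = FS, MQ = MQ, MQRankSum = MQRankSum,
                   ReadPosRankSum = ReadPosRankSum, QUAL = QUAL, SOR = SOR)
  for (f in c("QD", "FS", "MQ", "QUAL", "SOR")) {
    if (anyNA(df[[f]])) {
      stop_invalid("site_annotations: mandatory annotation %s has NA", f)
    }
  }
  if (any(df$FS < 0) || any(df$QUAL < 0) || any(df$SOR < 0)) {
    stop_invalid("site_annotations: FS/QUAL/SOR must be >= 0")
  }
  class(df) <- c("site_annotations", "data.frame")
  df
}

GT_REF <- 0L
GT_ALT <- 1L

gt_labels <- function(g) {
  ifelse(is.na(g), "MISSING", ifelse(g == GT_ALT, "ALT", "REF"))
}
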