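# SNP post-processing chain, in fixed order: site hard filters on quality
# annotations -> per-nucleus haploid genotype calls -> depth/allele-fraction
# cell masking -> cross-nucleus missingness filter -> SNP extraction.

#' Hard-filter thresholds
#'
#' The standard recommended hard-filter thresholds for SNPs. A site fails
#' when any statistic crosses its threshold strictly: QD < `qd_min`,
#' FS > `fs_max`, MQ < `mq_min`, MQRankSum < `mqranksum_min`,
#' ReadPosRankSum < `readposranksum_min`, QUAL < `qual_min`, or
#' SOR > `sor_max`. Boundary values pass.
#'
#' @param qd_min default 2.
#' @param fs_max default 60.
#' @param mq_min default 40.
#' @param mqranksum_min default -12.5.
#' @param readposranksum_min default -8.
#' @param qual_min default 30.
#' @param sor_max default 3.0.
#' @return A list of class `hard_filter_thresholds`.
#' @export
hard_filter_thresholds <- function(qd_min = 2, fs_max = 60, mq_min = 40,
                                   mqranksum_min = -12.5,
                                   readposranksum_min = -8,
                                   qual_min = 30, sor_max = 3.0) {
  structure(list(qd_min = qd_min, fs_max = fs_max, mq_min = mq_min,
                 mqranksum_min = mqranksum_min,
                 readposranksum_min = readposranksum_min,
                 qual_min = qual_min, sor_max = sor_max),
            class = "hard_filter_thresholds")
}

#' Apply site-level hard filters
#'
#' @param ann a [site_annotations()] `data.frame`.
#' @param thr a [hard_filter_thresholds()].
#' @return Logical vector, `TRUE` where the site passes all seven tests.
#'   Missing (`NA`) rank-sum annotations never fail their test, matching
#'   the behavior of threshold filtering on absent annotations.
#' @examples
#' ann <- site_annotations(QD = c(1.9, 2), FS = 10, MQ = 50,
#'                         MQRankSum = 0, ReadPosRankSum = 0,
#'                         QUAL = 100, SOR = 1)
#' apply_site_hard_filters(ann)  # FALSE TRUE
#' @export
apply_site_hard_filters <- function(ann, thr = hard_filter_thresholds()) {
  stopifnot(inherits(ann, "site_annotations"))
  fail <- ann$QD < thr$qd_min |
    ann$FS > thr$fs_max |
    ann$MQ < thr$mq_min |
    (!is.na(ann$MQRankSum) & ann$MQRankSum < thr$mqranksum_min) |
    (!is.na(ann$ReadPosRankSum) &
       ann$ReadPosRankSum < thr$readposranksum_min) |
    ann$QUAL < thr$qual_min |
    ann$SOR > thr$sor_max
  !fail
}

#' Call haploid genotypes from read counts
#'
#' Majority-vote haploid call per (site, nucleus): zero depth is MISSING, a
#' ref-count majority is REF, an alt-count majority is ALT, and a tie with
#' positive depth is MISSING (a haploid call is indefensible at an even
#' split).
#'
#' @param depth,ref_count,alt_count integer vectors or matrices of common
#'   shape (`ref_count + alt_count <= depth`).
#' @return Integer vector/matrix of calls: `0` REF, `1` ALT, `NA` MISSING.
#' @export
call_haploid_genotype <- function(depth, ref_count, alt_count) {
  if (any(depth < 0) || any(ref_count < 0) || any(alt_count < 0)) {
    stop_invalid("call_haploid_genotype: negative counts")
  }
  if (any(ref_count + alt_count > depth)) {
    stop_invalid("call_haploid_genotype: counts exceed depth")
  }
  g <- ifelse(depth == 0L, NA_integer_,
              ifelse(ref_count > alt_count, GT_REF,
                     ifelse(alt_count > ref_count, GT_ALT, NA_integer_)))
  if (is.matrix(depth)) {
    g <- matrix(as.integer(g), nrow(depth), ncol(depth),
                dimnames = dimnames(depth))
  } else {
    g <- as.integer(g)
  }
  g
}

#' Cell-masking rule
#'
#' The bespoke reliability mask for single-nucleus calls: a (site, nucleus)
#' cell is set to MISSING when the depth condition (`depth < min_depth`)
#' and/or the ambiguity condition (`af_low < AF < af_high`, strict) holds,
#' combined with `combine`. AF is `alt/(ref+alt)` over gate-surviving
#' reads; with zero informative reads AF is undefined and the ambiguity
#' condition is false, so depth alone governs.
#'
#' @param min_depth default 5 (cells with fewer than 5 reads).
#' @param af_low,af_high default 0.1 and 0.9 (open interval).
#' @param combine `"AND"` (default; the literal reading of the rule) or
#'   `"OR"`.
#' @return A list of class `nucleus_mask_rule`.
#' @export
nucleus_mask_rule <- function(min_depth = 5L, af_low = 0.1, af_high = 0.9,
                              combine = c("AND", "OR")) {
  combine <- match.arg(combine)
  if (!(af_low >= 0 && af_low < af_high && af_high <= 1)) {
    stop_invalid("nucleus_mask_rule: need 0 <= af_low < af_high <= 1")
  }
  structure(list(min_depth = as.integer(min_depth), af_low = af_low,
                 af_high = af_high, combine = combine),
            class = "nucleus_mask_rule")
}

#' Mask unreliable cells in a genotype matrix
#'
#' @param gt integer genotype matrix (0/1/NA) from
#'   [call_haploid_genotype()].
#' @param obs the [observation_matrix()] the calls came from.
#' @param rule a [nucleus_mask_rule()].
#' @return The genotype matrix with masked cells set to `NA`; attribute
#'   `n_masked` counts cells newly masked.
#' @export
mask_unreliable_cells <- function(gt, obs, rule = nucleus_mask_rule()) {
  stopifnot(inherits(obs, "observation_matrix"))
  if (!identical(dim(gt), dim(obs$depth))) {
    stop_invalid("mask_unreliable_cells: gt and obs dimensions differ")
  }
  informative <- obs$ref_count + obs$alt_count
  af <- ifelse(informative > 0, obs$alt_count / informative, NA_real_)
  low_depth <- obs$depth < rule$min_depth
  ambiguous <- !is.na(af) & af > rule$af_low & af < rule$af_high
  mask <- if (rule$combine == "AND") low_depth & ambiguous else
    low_depth | ambiguous
  n_masked <- sum(mask & !is.na(gt))
  gt[mask] <- NA_integer_
  attr(gt, "n_masked") <- n_masked
  gt
}

#' Filter sites by cross-nucleus missingness
#'
#' Removes sites where the fraction of MISSING calls over all sequenced
#' nuclei exceeds `max_missing_fraction` strictly. The denominator is the
#' total nucleus count, not the non-missing count; at exactly the threshold
#' (e.g. 3 of 9 at 1/3) the site is retained.
#'
#' @param gt genotype matrix (0/1/NA).
#' @param max_missing_fraction default `1/3`.
#' @param n_nuclei number of sequenced nuclei; must equal `ncol(gt)`.
#' @return List with `retained` (integer site indices) and `n_removed`.
#' @export
filter_by_missingness <- function(gt, max_missing_fraction = 1 / 3,
                                  n_nuclei = ncol(gt)) {
  if (max_missing_fraction < 0 || max_missing_fraction > 1) {
    stop_invalid("filter_by_missingness: fraction outside [0,1]")
  }
  if (n_nuclei != ncol(gt)) {
    stop_invalid("filter_by_missingness: n_nuclei (%d) != matrix width (%d)",
                 n_nuclei, ncol(gt))
  }
  miss_frac <- rowSums(is.na(gt)) / n_nuclei
  retained <- which(miss_frac <= max_missing_fraction)
  list(retained = retained, n_removed = nrow(gt) - length(retained))
}

#' Extract SNP sites from a filtered genotype matrix
#'
#' A retained site is a SNP iff at least one non-missing call is ALT.
#' Sites where every non-missing call is ALT are counted as SNPs too (they
#' may be assembly-consensus artifacts) but flagged separately.
#'
#' @param gt genotype matrix (0/1/NA).
#' @param retained integer indices of sites surviving earlier filters.
#' @return List with `snp_index` (indices into the site list, genomic order
#'   preserved) and `all_alt_index` (the subset where no non-missing call
#'   is REF).
#' @export
extract_snp_sites <- function(gt, retained = seq_len(nrow(gt))) {
  if (length(retained) == 0L) {
    return(list(snp_index = integer(0), all_alt_index = integer(0)))
  }
  sub <- gt[retained, , drop = FALSE]
  n_alt <- rowSums(sub == GT_ALT, na.rm = TRUE)
  n_ref <- rowSums(sub == GT_REF, na.rm = TRUE)
  is_snp <- n_alt >= 1L
  list(snp_index = retained[is_snp],
       all_alt_index = retained[is_snp & n_ref == 0L])
}

#' Run the full SNP filter chain
#'
#' Composition, in fixed order: hard filters on site annotations, haploid
#' genotype calling, cell masking, missingness filtering, SNP extraction.
#'
#' @param obs an [observation_matrix()].
#' @param ann matching [site_annotations()] (one row per site).
#' @param thresholds a [hard_filter_thresholds()].
#' @param rule a [nucleus_mask_rule()].
#' @param max_missing_fraction default `1/3`.
#' @return A list of class `filter_result`:
#'   \describe{
#'     \item{snp_sites}{`data.frame` of SNP site rows (contig, pos, ref,
#'       alt) in genomic order}
#'     \item{genotypes}{masked genotype matrix over retained sites}
#'     \item{retained_sites}{site table for rows of `genotypes`}
#'     \item{report}{`filter_report` stage counts}
#'   }
#' @export
run_filter_chain <- function(obs, ann,
                             thresholds = hard_filter_thresholds(),
                             rule = nucleus_mask_rule(),
                             max_missing_fraction = 1 / 3) {
  stopifnot(inherits(obs, "observation_matrix"))
  if (nrow(ann) != nrow(obs$sites)) {
    stop_invalid("run_filter_chain: annotation rows != site rows")
  }
  n_input <- nrow(obs$sites)
  pass <- apply_site_hard_filters(ann, thresholds)
  keep <- which(pass)
  sub <- subset_obs(obs, keep)
  gt <- call_haploid_genotype(sub$depth, sub$ref_count, sub$alt_count)
  gt <- mask_unreliable_cells(gt, sub, rule)
  n_masked <- attr(gt, "n_masked")
  miss <- filter_by_missingness(gt, max_missing_fraction)
  snp <- extract_snp_sites(gt, miss$retained)
  report <- structure(list(
    n_sites_input = n_input,
    n_failed_hard_filters = n_input - length(keep),
    n_cells_masked = n_masked,
    n_sites_removed_missingness = miss$n_removed,
    n_snp_sites = length(snp$snp_index),
    n_snp_sites_all_alt = length(snp$all_alt_index)),
    class = "filter_report")
  gt_ret <- gt[miss$retained, , drop = FALSE]
  attr(gt_ret, "n_masked") <- NULL
  snp_sites <- sub$sites[snp$snp_index, , drop = FALSE]
  retained_sites <- sub$sites[miss$retained, , drop = FALSE]
  rownames(snp_sites) <- rownames(retained_sites) <- NULL
  structure(list(
    snp_sites = snp_sites,
    genotypes = gt_ret,
    retained_sites = retained_sites,
    snp_in_retained = match(snp$snp_index, miss$retained),
    report = report),
    class = "filter_result")
}

subset_obs <- function(obs, idx) {
  observation_matrix(obs$sites[idx, , drop = FALSE],
                     obs$depth[idx, , drop = FALSE],
                     obs$ref_count[idx, , drop = FALSE],
                     obs$alt_count[idx, , drop = FALSE])
}

#' @export
print.filter_report <- function(x, ...) {
  cat("SNP filter report\n")
  for (f in names(x)) cat(sprintf("  %-28s %d\n", f, x[[f]]))
  invisible(x)
}
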