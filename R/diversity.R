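# Intra-spore diversity summary: SNP counts partitioned by the repeat mask
# and coding annotation, and SNPs/kb over the non-repeat genome.

#' Count SNP sites outside an interval set
#'
#' @param snp_sites `data.frame` with `contig` and `pos` (1-based).
#' @param intervals interval set (0-based half-open); normalized internally
#'   if unsorted or overlapping.
#' @return Integer count of sites whose position falls in no interval.
#' @export
count_outside_intervals <- function(snp_sites, intervals) {
  nrow(snp_sites) - count_inside_intervals(snp_sites, intervals)
}

#' Count SNP sites inside an interval set
#'
#' Complement of [count_outside_intervals()]; the two always sum to the
#' total site count.
#'
#' @inheritParams count_outside_intervals
#' @return Integer count of sites covered by at least one interval.
#' @export
count_inside_intervals <- function(snp_sites, intervals) {
  if (nrow(snp_sites) == 0L) return(0L)
  iv <- interval_set(intervals$contig, intervals$start, intervals$end)
  sum(positions_in_intervals(snp_sites$contig, snp_sites$pos, iv))
}

#' SNP density per kilobase
#'
#' The density statistic: SNP count in the non-repeat genome divided by the
#' non-repeat size, expressed per kb. Reporting rounds half-up to 2
#' decimals; full precision is retained internally.
#'
#' @param n_snps_nonrepeat SNP count outside the repeat mask.
#' @param nonrepeat_size_bp non-repeat assembly size in bp (> 0).
#' @return Density in SNPs/kb (full precision).
#' @examples
#' compute_density(17404, 134.3e6 - 68.22e6)  # ~0.263, prints as 0.26
#' @export
compute_density <- function(n_snps_nonrepeat, nonrepeat_size_bp) {
  if (nonrepeat_size_bp <= 0) {
    stop_invalid("compute_density: nonrepeat_size_bp must be > 0")
  }
  1000 * n_snps_nonrepeat / nonrepeat_size_bp
}

#' Build the diversity report for one spore
#'
#' @param snp_sites SNP site `data.frame` (`contig`, `pos`), e.g.
#'   `run_filter_chain(...)$snp_sites`.
#' @param ref a [reference_model()] supplying the repeat mask, coding
#'   annotation and exact non-repeat size.
#' @return A list of class `diversity_report` with fields `n_snps_total`,
#'   `n_snps_nonrepeat`, `n_snps_coding`, `nonrepeat_size_bp`,
#'   `density_snp_per_kb` and `density_rounded`.
#' @export
build_report <- function(snp_sites, ref) {
  stopifnot(inherits(ref, "spore_reference"))
  n_total <- nrow(snp_sites)
  n_nonrep <- count_outside_intervals(snp_sites, ref$repeat_intervals)
  n_coding <- count_inside_intervals(snp_sites, ref$coding_intervals)
  dens <- compute_density(n_nonrep, ref$nonrepeat_size_bp)
  structure(list(n_snps_total = n_total,
                 n_snps_nonrepeat = n_nonrep,
                 n_snps_coding = n_coding,
                 nonrepeat_size_bp = ref$nonrepeat_size_bp,
                 density_snp_per_kb = dens,
                 density_rounded = round_half_up(dens, 2)),
            class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Total number of SNPs         %d\n",
    "Number of SNPs non-rep       %d\n",
    "Number of SNPs coding region %d\n",
    "Density SNP/kb               %.2f\n"),
    x$n_snps_total, x$n_snps_nonrepeat, x$n_snps_coding,
    x$density_rounded))
  invisible(x)
}

#' Serialize a diversity report as TSV
#'
#' Writes the four-row summary with its conventional row labels.
#'
#' @param report a `diversity_report`.
#' @param path output file path.
#' @export
write_diversity_report <- function(report, path) {
  df <- data.frame(
    statistic = c("Total number of SNPs", "Number of SNPs non-rep",
                  "Number of SNPs coding region", "Density SNP/kb"),
    value = c(report$n_snps_total, report$n_snps_nonrepeat,
              report$n_snps_coding,
              sprintf("%.2f", report$density_rounded)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
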