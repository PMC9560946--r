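# Reference assembly model: contig sizes plus repeat / coding masks.
# The repeat mask is the denominator of the SNP density statistic, so the
# realized sizes are exact interval arithmetic, never rounded Mb values.

#' Construct a reference model
#'
#' A reference model bundles contig lengths with a repeat-interval mask and
#' an optional coding-interval annotation. The non-repeat size in base pairs
#' is the denominator of the SNP density statistic.
#'
#' @param contigs `data.frame` with columns `contig` (character) and
#'   `length` (integer bp).
#' @param repeat_intervals,coding_intervals interval sets as produced by
#'   [interval_set()] (0-based half-open); normalized on construction.
#' @return An object of class `spore_reference` with fields `contigs`,
#'   `repeat_intervals`, `coding_intervals`, `total_size_bp`,
#'   `repeat_size_bp`, `nonrepeat_size_bp`.
#' @export
reference_model <- function(contigs,
                            repeat_intervals = interval_set(),
                            coding_intervals = interval_set()) {
  stopifnot(is.data.frame(contigs),
            all(c("contig", "length") %in% names(contigs)))
  if (nrow(contigs) == 0L) stop_invalid("reference_model: no contigs")
  if (any(contigs$length <= 0)) {
    stop_invalid("reference_model: non-positive contig length")
  }
  if (anyDuplicated(contigs$contig)) {
    stop_invalid("reference_model: duplicated contig ids")
  }
  repeat_intervals <- interval_set(repeat_intervals$contig,
                                   repeat_intervals$start,
                                   repeat_intervals$end)
  coding_intervals <- interval_set(coding_intervals$contig,
                                   coding_intervals$start,
                                   coding_intervals$end)
  check_within_contigs(repeat_intervals, contigs, "repeat")
  check_within_contigs(coding_intervals, contigs, "coding")
  total <- sum(as.numeric(contigs$length))
  rep_bp <- interval_total_length(repeat_intervals)
  obj <- list(contigs = contigs[, c("contig", "length")],
              repeat_intervals = repeat_intervals,
              coding_intervals = coding_intervals,
              total_size_bp = total,
              repeat_size_bp = rep_bp,
              nonrepeat_size_bp = total - rep_bp)
  stopifnot(obj$nonrepeat_size_bp >= 0)
  structure(obj, class = "spore_reference")
}

check_within_contigs <- function(iv, contigs, what) {
  if (nrow(iv) == 0L) return(invisible())
  len <- setNames(contigs$length, contigs$contig)
  if (!all(iv$contig %in% contigs$contig)) {
    stop_invalid("%s intervals reference unknown contig", what)
  }
  if (any(iv$end > len[iv$contig])) {
    stop_invalid("%s intervals extend past contig end", what)
  }
  invisible()
}

#' @export
print.spore_reference <- function(x, ...) {
  cat(sprintf(
    "spore_reference: %d contig(s), %.0f bp total\n  repeat mask: %.0f bp (%.1f%%), non-repeat: %.0f bp\n  coding annotation: %.0f bp in %d interval(s)\n",
    nrow(x$contigs), x$total_size_bp, x$repeat_size_bp,
    100 * x$repeat_size_bp / x$total_size_bp, x$nonrepeat_size_bp,
    interval_total_length(x$coding_intervals), nrow(x$coding_intervals)))
  invisible(x)
}

#' Simulate a reference assembly with repeat and coding masks
#'
#' Draws contig lengths and places repeat and coding intervals so that the
#' realized masked fractions closely match the requested ones (within 1% of
#' `repeat_fraction * total_len_bp` for genomes of at least 100 kb; in
#' practice within a few bp because the final interval is trimmed to the
#' target). Coding intervals are placed outside the repeat mask.
#'
#' @param total_len_bp total assembly size in bp (positive integer).
#' @param n_contigs number of contigs (positive integer, at most
#'   `total_len_bp`).
#' @param repeat_fraction,coding_fraction fractions of the genome to mask,
#'   each in `[0, 1)` and summing to less than 1.
#' @param seed integer seed; identical seeds give identical references.
#' @return A [reference_model()] object.
#' @examples
#' ref <- simulate_reference(1e6, 5, repeat_fraction = 0.5, seed = 7)
#' ref$repeat_size_bp / ref$total_size_bp
#' @export
simulate_reference <- function(total_len_bp, n_contigs = 1,
                               repeat_fraction = 0, coding_fraction = 0,
                               seed = NULL) {
  if (total_len_bp <= 0 || n_contigs <= 0) {
    stop_invalid("simulate_reference: length and contig count must be positive")
  }
  if (total_len_bp < n_contigs) {
    stop_invalid("simulate_reference: total_len_bp < n_contigs")
  }
  if (repeat_fraction < 0 || repeat_fraction >= 1 ||
      coding_fraction < 0 || coding_fraction >= 1 ||
      repeat_fraction + coding_fraction >= 1) {
    stop_invalid("simulate_reference: fractions must lie in [0,1) and sum < 1")
  }
  with_rng(seed, {
    lengths <- random_partition(total_len_bp, n_contigs)
    contigs <- data.frame(contig = sprintf("contig_%03d", seq_len(n_contigs)),
                          length = lengths, stringsAsFactors = FALSE)
    rep_iv <- place_intervals(contigs, round(repeat_fraction * total_len_bp),
                              avoid = NULL)
    cod_iv <- place_intervals(contigs, round(coding_fraction * total_len_bp),
                              avoid = rep_iv)
    reference_model(contigs, rep_iv, cod_iv)
  })
}

# Split total into n positive parts with uniform random break points.
random_partition <- function(total, n) {
  if (n == 1L) return(total)
  cuts <- sort(sample.int(total - 1L, n - 1L))
  diff(c(0L, cuts, total))
}

# Greedily drop lognormal-length intervals (mean ~3 kb, the scale of fungal
# TE fragments) at uniform positions until the merged length reaches
# target_bp, then trim the overshoot off the final interval.
place_intervals <- function(contigs, target_bp, avoid = NULL) {
  if (target_bp <= 0) return(interval_set())
  cur <- interval_set()
  guard <- 0L
  while (interval_total_length(cur) < target_bp && guard < 1e5) {
    guard <- guard + 1L
    k <- max(64L, nrow(contigs) * 8L)
    ci <- sample.int(nrow(contigs), k, replace = TRUE,
                     prob = contigs$length)
    len <- pmax(50, round(rlnorm(k, meanlog = log(3000), sdlog = 0.6)))
    st <- floor(runif(k) * pmax(1, contigs$length[ci] - len))
    en <- pmin(st + len, contigs$length[ci])
    cand <- data.frame(contig = contigs$contig[ci], start = st, end = en)
    cand <- cand[cand$end > cand$start, , drop = FALSE]
    if (!is.null(avoid) && nrow(avoid) > 0L) {
      gr <- suppressWarnings(
        GenomicRanges::setdiff(intervals_to_gr(cand),
                               intervals_to_gr(avoid)))
      cand <- gr_to_intervals(gr)
    }
    cur <- interval_set(c(cur$contig, cand$contig),
                        c(cur$start, cand$start),
                        c(cur$end, cand$end))
    excess <- interval_total_length(cur) - target_bp
    if (excess > 0) cur <- trim_excess(cur, excess)
  }
  cur
}

# Remove `excess` bp from the tail of the interval set (whole intervals,
# then shorten the last survivor), keeping the realized total exact.
trim_excess <- function(iv, excess) {
  widths <- iv$end - iv$start
  i <- nrow(iv)
  while (excess > 0 && i >= 1L) {
    if (widths[i] <= excess) {
      excess <- excess - widths[i]
      widths[i] <- 0
    } else {
      widths[i] <- widths[i] - excess
      excess <- 0
    }
    i <- i - 1L
  }
  keep <- widths > 0
  iv$end <- iv$start + widths
  iv[keep, , drop = FALSE]
}
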