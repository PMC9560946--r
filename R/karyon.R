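# Karyon inference: is the nucleus population of a spore consistent with a
# homokaryon (one genotype class) or a heterokaryon (two classes)?
# Evidence combined: non-repeat SNP density against published density
# bands, a two-group clustering of nuclei, and a permutation null for the
# clustering score. Verdicts are deliberately "-consistent": without a
# mating-type marker this is evidence, not proof.

#' Karyon classification thresholds
#'
#' Density bands are borrowed priors from cultured *Rhizophagus
#' irregularis* strains: around 0.2 SNPs/kb for MAT-locus homokaryons,
#' 0.45-0.8 SNPs/kb for heterokaryons. Their transferability to other
#' genera is unknown; they are defaults, not constants.
#'
#' @param homokaryon_density_max SNPs/kb, default 0.2.
#' @param heterokaryon_density_min SNPs/kb, default 0.45.
#' @param partition_score_min minimum clustering score for a two-class
#'   signal, default 0.8.
#' @param permutation_alpha significance level for the permutation test,
#'   default 0.05.
#' @param n_permutations default 999.
#' @return A list of class `karyon_thresholds`.
#' @export
karyon_thresholds <- function(homokaryon_density_max = 0.2,
                              heterokaryon_density_min = 0.45,
                              partition_score_min = 0.8,
                              permutation_alpha = 0.05,
                              n_permutations = 999L) {
  if (homokaryon_density_max >= heterokaryon_density_min) {
    stop_invalid("karyon_thresholds: homokaryon band must lie below heterokaryon band")
  }
  structure(list(homokaryon_density_max = homokaryon_density_max,
                 heterokaryon_density_min = heterokaryon_density_min,
                 partition_score_min = partition_score_min,
                 permutation_alpha = permutation_alpha,
                 n_permutations = as.integer(n_permutations)),
            class = "karyon_thresholds")
}

#' Per-site alternate-allele fraction spectrum
#'
#' For each site, the fraction of non-missing calls that are ALT, plus a
#' fixed-bin histogram (bin width 0.05). Sites with all calls missing are
#' excluded with a warning. In a 50/50 heterokaryon the spectrum piles up
#' near 0.5; with only private mutations it piles up near 1/n_nuclei.
#'
#' @param gt genotype matrix (0/1/NA).
#' @param retained site indices to include (default all).
#' @return List with `fractions` (in site order, excluded sites dropped),
#'   `included` (their indices) and `histogram` (named counts over 20 bins
#'   of width 0.05; the top bin is closed so the counts sum to the number
#'   of included sites).
#' @export
site_alt_fraction_spectrum <- function(gt, retained = seq_len(nrow(gt))) {
  sub <- gt[retained, , drop = FALSE]
  n_obs <- rowSums(!is.na(sub))
  if (any(n_obs == 0L)) {
    warning(sprintf("%d site(s) with all calls missing excluded from spectrum",
                    sum(n_obs == 0L)))
  }
  keep <- n_obs > 0L
  frac <- rowSums(sub == GT_ALT, na.rm = TRUE)[keep] / n_obs[keep]
  breaks <- seq(0, 1, by = 0.05)
  # left-closed bins of width 0.05; the top bin is closed at 1 so the
  # counts always sum to the number of included sites
  counts <- tabulate(findInterval(frac, breaks, rightmost.closed = TRUE),
                     nbins = 20L)
  names(counts) <- sprintf("[%.2f,%.2f%s", breaks[-length(breaks)],
                           breaks[-1],
                           c(rep(")", 19), "]"))
  list(fractions = unname(frac), included = retained[keep],
       histogram = counts)
}

# Pairwise normalized Hamming distance over shared non-missing sites.
# Pairs sharing fewer than min_shared sites get the mean distance of the
# well-covered pairs (0.5 when no pair is well covered).
hamming_distance_matrix <- function(gt, min_shared = 10L) {
  Mobs <- !is.na(gt)
  A <- (!is.na(gt) & gt == GT_ALT) * 1
  R <- (!is.na(gt) & gt == GT_REF) * 1
  mism <- crossprod(A, R)
  mism <- mism + t(mism)
  shared <- crossprod(Mobs * 1)
  d <- ifelse(shared > 0, mism / shared, 0.5)
  ok <- shared >= min_shared
  diag(ok) <- TRUE
  off <- upper.tri(d)
  if (any(ok[off])) {
    fill <- mean(d[off & ok])
  } else {
    fill <- 0.5
  }
  d[!ok] <- fill
  diag(d) <- 0
  dimnames(d) <- list(colnames(gt), colnames(gt))
  d
}

partition_score_from_dist <- function(d, labels) {
  n <- nrow(d)
  same <- outer(labels, labels, "==")
  off <- upper.tri(d)
  within <- d[off & same]
  between <- d[off & !same]
  if (length(between) == 0L) return(0)
  mb <- mean(between)
  mw <- if (length(within) == 0L) 0 else mean(within)
  if (mb <= 0) return(0)
  min(1, max(0, 1 - mw / mb))
}

#' Partition nuclei into two putative genotype classes
#'
#' Average-linkage agglomerative clustering (two groups) on pairwise
#' normalized Hamming distance over shared non-missing sites, chosen for
#' determinism and auditability. The partition score is
#' `1 - mean(within-group distance) / mean(between-group distance)`,
#' clamped to `[0, 1]`: 1 for two internally identical, mutually distinct
#' classes; 0 when groups are no tighter than the whole.
#'
#' @param gt genotype matrix (0/1/NA), nuclei in columns.
#' @param retained site indices to use (default all).
#' @param min_shared minimum shared non-missing sites for a pair's
#'   distance to be trusted (default 10); sparser pairs are imputed with
#'   the mean trusted distance.
#' @return List with `labels` (per-nucleus `"A"`/`"B"`; the group of the
#'   first nucleus is `"A"`) and `score`.
#' @export
partition_nuclei <- function(gt, retained = seq_len(nrow(gt)),
                             min_shared = 10L) {
  if (ncol(gt) < 2L) stop_invalid("partition_nuclei: fewer than 2 nuclei")
  if (length(retained) < 1L) stop_invalid("partition_nuclei: no sites")
  sub <- gt[retained, , drop = FALSE]
  d <- hamming_distance_matrix(sub, min_shared)
  grp <- stats::cutree(stats::hclust(stats::as.dist(d), method = "average"),
                       k = 2)
  labels <- ifelse(grp == grp[1L], "A", "B")
  list(labels = setNames(labels, colnames(gt)),
       score = partition_score_from_dist(d, labels))
}

#' Permutation null for the partition score
#'
#' Each permutation shuffles the calls within every site independently,
#' preserving the per-site ALT count and the missingness pattern, then
#' re-runs the clustering and score. The p-value is
#' `(1 + #(permuted score >= observed)) / (n_permutations + 1)`.
#'
#' @inheritParams partition_nuclei
#' @param n_permutations at least 99; default 999.
#' @param seed integer seed for the shuffles.
#' @return List with `p_value`, `observed` score and `null_scores`.
#' @export
permutation_null <- function(gt, retained = seq_len(nrow(gt)),
                             n_permutations = 999L, seed = NULL,
                             min_shared = 10L) {
  if (n_permutations < 99L) {
    stop_invalid("permutation_null: n_permutations must be >= 99")
  }
  sub <- gt[retained, , drop = FALSE]
  obs_part <- partition_nuclei(sub, min_shared = min_shared)
  observed <- obs_part$score
  S <- nrow(sub)
  N <- ncol(sub)
  obs_mask <- !is.na(sub)
  vals <- sub[obs_mask]                 # non-missing calls, column-major
  site_of <- row(sub)[obs_mask]
  idx_by_site <- order(site_of)         # stable: entries grouped by site
  null_scores <- with_rng(seed, {
    vapply(seq_len(n_permutations), function(b) {
      # random within-site permutation, vectorized: both orderings walk the
      # sites in the same group order, so this maps each site's calls onto
      # a random arrangement of that same site's slots
      ord <- order(site_of, runif(length(vals)))
      vals_new <- vals
      vals_new[idx_by_site] <- vals[ord]
      perm <- sub
      perm[obs_mask] <- vals_new
      partition_nuclei(perm, min_shared = min_shared)$score
    }, numeric(1))
  })
  list(p_value = (1 + sum(null_scores >= observed)) / (n_permutations + 1),
       observed = observed, null_scores = null_scores)
}

#' Classify a spore as homokaryon- or heterokaryon-consistent
#'
#' Combines the non-repeat SNP density with the nucleus-partition evidence:
#' heterokaryon-consistent requires density at or above the heterokaryon
#' band AND a strong, significant bipartition; homokaryon-consistent
#' requires density at or below the homokaryon band AND no significant
#' strong bipartition; anything else is undetermined (as for field spores
#' with densities between the bands).
#'
#' @param report a `diversity_report` for the spore.
#' @param partition_score score from [partition_nuclei()].
#' @param permutation_p p-value from [permutation_null()].
#' @param thr a [karyon_thresholds()].
#' @param partition per-nucleus labels to attach to the call (optional).
#' @return A list of class `karyon_call` with fields `verdict`,
#'   `density_used`, `partition_score`, `permutation_p`, `partition`.
#' @export
classify_karyon <- function(report, partition_score, permutation_p,
                            thr = karyon_thresholds(), partition = NULL) {
  density <- report$density_snp_per_kb
  strong <- partition_score >= thr$partition_score_min &&
    permutation_p <= thr$permutation_alpha
  verdict <- if (density >= thr$heterokaryon_density_min && strong) {
    "heterokaryon-consistent"
  } else if (density <= thr$homokaryon_density_max && !strong) {
    "homokaryon-consistent"
  } else {
    "undetermined"
  }
  if (verdict == "heterokaryon-consistent" && !is.null(partition) &&
      length(unique(partition)) < 2L) {
    verdict <- "undetermined"   # two non-empty groups are required
  }
  structure(list(verdict = verdict, density_used = density,
                 partition_score = partition_score,
                 permutation_p = permutation_p,
                 partition = partition),
            class = "karyon_call")
}

#' @export
print.karyon_call <- function(x, ...) {
  cat(sprintf(paste0(
    "karyon call: %s\n  density: %.3f SNPs/kb  partition score: %.3f",
    "  permutation p: %.4g\n"),
    x$verdict, x$density_used, x$partition_score, x$permutation_p))
  invisible(x)
}

#' Serialize a karyon call as TSV
#'
#' @param call a `karyon_call`.
#' @param path output file path.
#' @export
write_karyon_call <- function(call, path) {
  df <- data.frame(
    field = c("verdict", "density_snp_per_kb", "partition_score",
              "permutation_p"),
    value = c(call$verdict, sprintf("%.6g", call$density_used),
              sprintf("%.6g", call$partition_score),
              sprintf("%.6g", call$permutation_p)))
  if (!is.null(call$partition)) {
    df <- rbind(df, data.frame(
      field = paste0("partition.", names(call$partition)),
      value = unname(call$partition)))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
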