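# Synthetic multinucleate spore: nucleus populations with known truth, and
# per-nucleus read-count observations with MDA-style coverage bias.

#' Observation-model parameters
#'
#' Parameters of the per-site, per-nucleus read evidence model. Coverage is
#' lognormal (MDA amplification is highly uneven) with an independent
#' per-site dropout, quality gates discard a fraction of reads before
#' counting, and each surviving read reports the wrong allele with
#' probability `error_rate`.
#'
#' @param mean_depth mean per-site read depth (> 0). Default 30.
#' @param depth_dispersion lognormal sigma of depth (> 0). Default 1.
#' @param dropout_rate probability a site has zero coverage in a nucleus
#'   (MDA locus dropout), in `[0, 1]`. Default 0.1.
#' @param error_rate per-read miscall probability, in `[0, 1)`.
#'   Default 0.005.
#' @param mq_below_gate_rate,bq_below_gate_rate probabilities that a read
#'   fails the mapping-quality (>= 30) or base-quality (>= 20) gate and is
#'   discarded before counting, each in `[0, 1)`. Defaults 0.05 and 0.02.
#' @return A list of class `obs_params`.
#' @export
obs_params <- function(mean_depth = 30, depth_dispersion = 1,
                       dropout_rate = 0.1, error_rate = 0.005,
                       mq_below_gate_rate = 0.05,
                       bq_below_gate_rate = 0.02) {
  if (mean_depth <= 0) stop_invalid("obs_params: mean_depth must be > 0")
  if (depth_dispersion <= 0) {
    stop_invalid("obs_params: depth_dispersion must be > 0")
  }
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop_invalid("obs_params: dropout_rate outside [0,1]")
  }
  for (r in c(error_rate, mq_below_gate_rate, bq_below_gate_rate)) {
    if (r < 0 || r >= 1) stop_invalid("obs_params: rate outside [0,1)")
  }
  structure(list(mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 dropout_rate = dropout_rate,
                 error_rate = error_rate,
                 mq_below_gate_rate = mq_below_gate_rate,
                 bq_below_gate_rate = bq_below_gate_rate),
            class = "obs_params")
}

#' Variant-caller parameter set
#'
#' The haploid single-nucleus calling parameters emulated by the simulator
#' and filter chain. Defaults are the standard single-nucleus settings:
#' ploidy 1, minimum mapping quality 30, minimum base quality 20, at most
#' one alternate allele (biallelic records only).
#'
#' @param ploidy integer, default 1.
#' @param min_mapping_quality integer, default 30.
#' @param min_base_quality integer, default 20.
#' @param max_alternate_alleles integer, default 1.
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(ploidy = 1L, min_mapping_quality = 30L,
                          min_base_quality = 20L,
                          max_alternate_alleles = 1L) {
  structure(list(ploidy = as.integer(ploidy),
                 min_mapping_quality = as.integer(min_mapping_quality),
                 min_base_quality = as.integer(min_base_quality),
                 max_alternate_alleles = as.integer(max_alternate_alleles)),
            class = "caller_params")
}

BASES <- c("A", "C", "G", "T")

#' Simulate the nucleus population of one spore
#'
#' Generates the truth set for a spore that is either a homokaryon (a
#' single haplotype class; any variation comes from per-nucleus private
#' mutations) or a heterokaryon (two haplotype classes, A and B, separated
#' by fixed differences at a stated density).
#'
#' Fixed differences are Poisson in number (`divergence_per_kb` per kb of
#' assembly) at uniform unique positions; at each such site the alternate
#' allele is carried by exactly one class (chosen at random per site, since
#' the reference assembly is a consensus of both). Class sizes are
#' binomial(`n_nuclei`, `class_ratio`), resampled until both classes are
#' non-empty. Private mutations are placed at `private_mut_per_kb` per kb
#' of assembly over the whole spore — the rate of the aggregated SNP set,
#' the scale on which published density bands are expressed — and each
#' site is carried by a single uniformly chosen nucleus.
#'
#' @param ref a [reference_model()].
#' @param n_nuclei number of sequenced nuclei (>= 2); field spores carry
#'   on the order of 19-24 sequenced nuclei.
#' @param mode `"homokaryon"` or `"heterokaryon"`.
#' @param divergence_per_kb fixed-difference density between classes
#'   (heterokaryon mode only; forced to 0 for homokaryons).
#' @param class_ratio expected fraction of nuclei in class A, in (0, 1).
#' @param private_mut_per_kb per-nucleus private mutation density.
#' @param seed integer seed.
#' @return A list of class `spore_truth` with fields `mode`, `n_nuclei`,
#'   `nucleus_ids`, `class_assignment` (per-nucleus `"A"`/`"B"`),
#'   `divergence_per_kb`, `private_mut_per_kb`, and `variant_sites`, a
#'   `data.frame` (contig, pos 1-based, ref, alt, carrier) where carrier is
#'   `"A"`/`"B"` for fixed differences or a nucleus id for private
#'   mutations.
#' @export
simulate_nucleus_population <- function(ref, n_nuclei,
                                        mode = c("heterokaryon",
                                                 "homokaryon"),
                                        divergence_per_kb = 0.5,
                                        class_ratio = 0.5,
                                        private_mut_per_kb = 0,
                                        seed = NULL) {
  mode <- match.arg(mode)
  if (n_nuclei < 2) stop_invalid("simulate_nucleus_population: n_nuclei < 2")
  if (class_ratio <= 0 || class_ratio >= 1) {
    stop_invalid("simulate_nucleus_population: class_ratio outside (0,1)")
  }
  if (mode == "homokaryon") divergence_per_kb <- 0
  with_rng(seed, {
    ids <- sprintf("nucleus_%02d", seq_len(n_nuclei))
    cls <- rep("A", n_nuclei)
    if (mode == "heterokaryon") {
      repeat {
        nA <- rbinom(1L, n_nuclei, class_ratio)
        if (nA > 0 && nA < n_nuclei) break
      }
      cls[sample.int(n_nuclei, n_nuclei - nA)] <- "B"
    }
    total_kb <- ref$total_size_bp / 1000
    n_div <- rpois(1L, divergence_per_kb * total_kb)
    div <- draw_sites(ref, n_div, exclude = NULL)
    if (nrow(div) > 0L) {
      div$carrier <- sample(c("A", "B"), nrow(div), replace = TRUE)
    } else {
      div$carrier <- character(0)
    }
    # spore-level private-site density: the SNP set a spore presents
    # aggregates every nucleus's private mutations, so the rate applies to
    # the whole spore and each site is assigned to one nucleus at random
    n_priv <- rpois(1L, private_mut_per_kb * total_kb)
    priv <- draw_sites(ref, n_priv, exclude = div)
    if (nrow(priv) > 0L) {
      priv$carrier <- ids[sample.int(n_nuclei, nrow(priv), replace = TRUE)]
    } else {
      priv$carrier <- character(0)
    }
    variant_sites <- rbind(div, priv)
    variant_sites <- dedup_sites(variant_sites)
    variant_sites <- variant_sites[order(variant_sites$contig,
                                         variant_sites$pos), , drop = FALSE]
    rownames(variant_sites) <- NULL
    structure(list(mode = mode, n_nuclei = as.integer(n_nuclei),
                   nucleus_ids = ids, class_assignment = cls,
                   divergence_per_kb = divergence_per_kb,
                   class_ratio = class_ratio,
                   private_mut_per_kb = private_mut_per_kb,
                   variant_sites = variant_sites),
              class = "spore_truth")
  })
}

# Uniform unique genomic positions with random ref/alt base labels.
draw_sites <- function(ref, n, exclude = NULL) {
  empty <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
  if (n <= 0) return(empty)
  out <- empty
  guard <- 0L
  while (nrow(out) < n && guard < 50L) {
    guard <- guard + 1L
    need <- n - nrow(out)
    ci <- sample.int(nrow(ref$contigs), need, replace = TRUE,
                     prob = ref$contigs$length)
    pos <- 1L + floor(runif(need) * ref$contigs$length[ci])
    rb <- sample(BASES, need, replace = TRUE)
    ab <- vapply(rb, function(b) sample(setdiff(BASES, b), 1L), character(1))
    cand <- data.frame(contig = ref$contigs$contig[ci], pos = as.integer(pos),
                       ref = rb, alt = unname(ab), stringsAsFactors = FALSE)
    out <- rbind(out, cand)
    key <- paste(out$contig, out$pos)
    drop <- duplicated(key)
    if (!is.null(exclude) && nrow(exclude) > 0L) {
      drop <- drop | key %in% paste(exclude$contig, exclude$pos)
    }
    out <- out[!drop, , drop = FALSE]
  }
  out[seq_len(min(n, nrow(out))), , drop = FALSE]
}

dedup_sites <- function(sites) {
  if (nrow(sites) == 0L) return(sites)
  sites[!duplicated(paste(sites$contig, sites$pos)), , drop = FALSE]
}

#' Simulate per-nucleus read-count observations and site annotations
#'
#' Produces the read evidence the filter chain consumes: for every emitted
#' site (the truth set's variant sites plus `n_decoy_sites` invariant decoy
#' sites) and every nucleus, a total depth, and post-gate ref/alt read
#' counts.
#'
#' Per (site, nucleus): depth is 0 with probability `dropout_rate`,
#' otherwise `round(rlnorm(...))` with mean `mean_depth` and sigma
#' `depth_dispersion`. Reads failing the mapping- or base-quality gate are
#' discarded before counting (they contribute to depth but not to the
#' ref/alt counts). Each surviving read reports the nucleus's true allele
#' with probability `1 - error_rate`, otherwise the other allele.
#'
#' Site quality annotations (QD, FS, MQ, MQRankSum, ReadPosRankSum, QUAL,
#' SOR) are drawn from fixed nominal distributions; a fraction
#' `ann_violation_rate` of sites is given exactly one annotation beyond its
#' hard-filter threshold. A fraction `ranksum_missing_rate` of sites lacks
#' the rank-sum annotations (recorded as `NA`), as happens at sites without
#' mixed ref/alt evidence.
#'
#' @param truth a `spore_truth` from [simulate_nucleus_population()].
#' @param ref the [reference_model()] used to build `truth`.
#' @param obs an [obs_params()].
#' @param caller a [caller_params()] (biallelic emulation; gates are
#'   expressed through `obs`'s gate rates).
#' @param n_decoy_sites number of invariant decoy sites; default 10x the
#'   variant count.
#' @param ann_violation_rate fraction of sites violating at least one
#'   hard-filter threshold. Default 0.05.
#' @param ranksum_missing_rate fraction of sites with missing rank-sum
#'   annotations. Default 0.1.
#' @param seed integer seed.
#' @return A list with `obs` (an observation matrix, see
#'   [observation_matrix()]) and `annotations` (a [site_annotations()]
#'   `data.frame`).
#' @export
simulate_observations <- function(truth, ref, obs = obs_params(),
                                  caller = caller_params(),
                                  n_decoy_sites = NULL,
                                  ann_violation_rate = 0.05,
                                  ranksum_missing_rate = 0.1,
                                  seed = NULL) {
  stopifnot(inherits(truth, "spore_truth"), inherits(ref, "spore_reference"),
            inherits(obs, "obs_params"))
  if (ann_violation_rate < 0 || ann_violation_rate > 1) {
    stop_invalid("simulate_observations: ann_violation_rate outside [0,1]")
  }
  n_var <- nrow(truth$variant_sites)
  if (is.null(n_decoy_sites)) n_decoy_sites <- 10L * n_var
  with_rng(seed, {
    decoys <- draw_sites(ref, n_decoy_sites, exclude = truth$variant_sites)
    if (nrow(decoys) > 0L) decoys$carrier <- "none" else {
      decoys$carrier <- character(0)
    }
    sites <- rbind(truth$variant_sites, decoys)
    sites <- sites[order(sites$contig, sites$pos), , drop = FALSE]
    rownames(sites) <- NULL
    S <- nrow(sites)
    N <- truth$n_nuclei

    # truth allele per (site, nucleus): TRUE where the nucleus carries alt
    alt_truth <- matrix(FALSE, S, N)
    for (j in seq_len(N)) {
      carrier <- sites$carrier
      alt_truth[, j] <- carrier == truth$class_assignment[j] |
        carrier == truth$nucleus_ids[j]
    }

    depth <- matrix(0L, S, N)
    covered <- matrix(runif(S * N) >= obs$dropout_rate, S, N)
    n_cov <- sum(covered)
    if (n_cov > 0L) {
      meanlog <- log(obs$mean_depth) - obs$depth_dispersion^2 / 2
      depth[covered] <- as.integer(round(
        rlnorm(n_cov, meanlog, obs$depth_dispersion)))
    }
    p_keep <- (1 - obs$mq_below_gate_rate) * (1 - obs$bq_below_gate_rate)
    kept <- matrix(rbinom(S * N, as.vector(depth), p_keep), S, N)
    # alt reads among kept: true-alt nuclei emit alt w.p. 1-e, others w.p. e
    p_alt <- ifelse(alt_truth, 1 - obs$error_rate, obs$error_rate)
    alt_count <- matrix(rbinom(S * N, as.vector(kept), as.vector(p_alt)),
                        S, N)
    ref_count <- kept - alt_count

    dimnames(depth) <- dimnames(ref_count) <- dimnames(alt_count) <-
      list(NULL, truth$nucleus_ids)
    om <- observation_matrix(sites[, c("contig", "pos", "ref", "alt")],
                             depth, ref_count, alt_count)
    ann <- draw_annotations(S, ann_violation_rate, ranksum_missing_rate)
    list(obs = om, annotations = ann,
         site_carrier = sites$carrier)
  })
}

# Nominal annotation draws sit comfortably inside the hard-filter
# thresholds; a violating site gets exactly one annotation pushed past its
# threshold (uniform choice among the seven tests).
draw_annotations <- function(n_sites, violation_rate, ranksum_missing_rate) {
  ann <- site_annotations(
    QD = runif(n_sites, 10, 35),
    FS = runif(n_sites, 0, 20),
    MQ = runif(n_sites, 50, 60),
    MQRankSum = runif(n_sites, -2, 2),
    ReadPosRankSum = runif(n_sites, -2, 2),
    QUAL = runif(n_sites, 100, 1000),
    SOR = runif(n_sites, 0.3, 2))
  miss <- runif(n_sites) < ranksum_missing_rate
  ann$MQRankSum[miss] <- NA_real_
  ann$ReadPosRankSum[miss] <- NA_real_
  viol <- which(runif(n_sites) < violation_rate)
  if (length(viol) > 0L) {
    which_test <- sample.int(7L, length(viol), replace = TRUE)
    for (k in seq_along(viol)) {
      i <- viol[k]
      switch(which_test[k],
             ann$QD[i] <- runif(1, 0, 1.9),
             ann$FS[i] <- runif(1, 61, 200),
             ann$MQ[i] <- runif(1, 20, 39.5),
             ann$MQRankSum[i] <- runif(1, -20, -12.6),
             ann$ReadPosRankSum[i] <- runif(1, -15, -8.1),
             ann$QUAL[i] <- runif(1, 0, 29.5),
             ann$SOR[i] <- runif(1, 3.1, 6))
    }
  }
  ann
}
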