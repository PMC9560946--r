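# Builders for small in-code fixtures shared across test files.

# Observation matrix for a single contig from per-site-per-nucleus vectors.
make_obs <- function(depth, ref_count, alt_count, contig = "c1",
                     pos = NULL) {
  depth <- as.matrix(depth)
  ref_count <- as.matrix(ref_count)
  alt_count <- as.matrix(alt_count)
  storage.mode(depth) <- storage.mode(ref_count) <-
    storage.mode(alt_count) <- "integer"
  S <- nrow(depth)
  colnames(depth) <- colnames(ref_count) <- colnames(alt_count) <-
    sprintf("nucleus_%02d", seq_len(ncol(depth)))
  sites <- data.frame(contig = rep(contig, length.out = S),
                      pos = if (is.null(pos)) seq_len(S) * 10L else pos,
                      ref = rep("A", S), alt = rep("T", S),
                      stringsAsFactors = FALSE)
  observation_matrix(sites, depth, ref_count, alt_count)
}

# Annotations that pass every hard filter, one row per site.
nominal_annotations <- function(n) {
  site_annotations(QD = rep(25, n), FS = rep(5, n), MQ = rep(55, n),
                   MQRankSum = rep(0, n), ReadPosRankSum = rep(0, n),
                   QUAL = rep(500, n), SOR = rep(1, n))
}

# Genotype matrix from a character matrix of "R"/"A"/"." codes.
gt_from_codes <- function(codes) {
  m <- matrix(NA_integer_, nrow(codes), ncol(codes))
  m[codes == "R"] <- 0L
  m[codes == "A"] <- 1L
  colnames(m) <- sprintf("nucleus_%02d", seq_len(ncol(codes)))
  m
}

# A small simulated spore world used by several files.
toy_world <- function(seed = 11, mode = "heterokaryon", n_nuclei = 8,
                      divergence_per_kb = 1, private_mut_per_kb = 0.05,
                      total_len = 2e5, obs = obs_params(), ...) {
  ref <- simulate_reference(total_len, 3, 0.2, 0.2, seed = seed)
  truth <- simulate_nucleus_population(
    ref, n_nuclei, mode = mode, divergence_per_kb = divergence_per_kb,
    private_mut_per_kb = private_mut_per_kb, seed = seed + 1)
  so <- simulate_observations(truth, ref, obs = obs, seed = seed + 2, ...)
  list(ref = ref, truth = truth, obs = so$obs, ann = so$annotations)
}

# Noiseless observation parameters: full depth everywhere, no errors,
# no gate losses.
noiseless_obs <- function(mean_depth = 30) {
  obs_params(mean_depth = mean_depth, depth_dispersion = 0.2,
             dropout_rate = 0, error_rate = 0,
             mq_below_gate_rate = 0, bq_below_gate_rate = 0)
}

# Independent step-by-step oracle for the filter chain, written as a flat
# per-site scan (deliberately naive; never calls the chain's internals).
chain_oracle <- function(obs, ann, thr = hard_filter_thresholds(),
                         rule = nucleus_mask_rule(), max_miss = 1 / 3) {
  snp <- character(0)
  for (i in seq_len(nrow(obs$sites))) {
    a <- ann[i, ]
    if (a$QD < thr$qd_min || a$FS > thr$fs_max || a$MQ < thr$mq_min ||
        (!is.na(a$MQRankSum) && a$MQRankSum < thr$mqranksum_min) ||
        (!is.na(a$ReadPosRankSum) &&
         a$ReadPosRankSum < thr$readposranksum_min) ||
        a$QUAL < thr$qual_min || a$SOR > thr$sor_max) next
    calls <- character(ncol(obs$depth))
    for (j in seq_len(ncol(obs$depth))) {
      d <- obs$depth[i, j]; r <- obs$ref_count[i, j]; al <- obs$alt_count[i, j]
      call <- if (d == 0) "." else if (r > al) "R" else if (al > r) "A"
        else "."
      inf <- r + al
      amb <- inf > 0 && (al / inf) > rule$af_low && (al / inf) < rule$af_high
      low <- d < rule$min_depth
      masked <- if (rule$combine == "AND") low && amb else low || amb
      if (masked) call <- "."
      calls[j] <- call
    }
    if (sum(calls == ".") / length(calls) > max_miss) next
    if (any(calls == "A")) snp <- c(snp, paste(obs$sites$contig[i],
                                               obs$sites$pos[i]))
  }
  snp
}

expect_sites_equal <- function(a, b) {
  a <- a[order(a$contig, a$pos), c("contig", "pos"), drop = FALSE]
  b <- b[order(b$contig, b$pos), c("contig", "pos"), drop = FALSE]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
}
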