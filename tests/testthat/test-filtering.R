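# Filter chain: hard-filter boundaries, haploid calls, cell masking,
# missingness, SNP extraction, composition against a scripted oracle, and
# the monotonicity / stage-order properties.

hard_filter_cases <- list(
  # field, failing value, boundary (passing) value
  list("QD", 1.9, 2), list("FS", 60.5, 60), list("MQ", 39.9, 40),
  list("MQRankSum", -12.6, -12.5), list("ReadPosRankSum", -8.1, -8),
  list("QUAL", 29.9, 30), list("SOR", 3.1, 3.0))

test_that("hard filters are strict: boundaries pass, violations fail", {
  for (case in hard_filter_cases) {
    ann <- nominal_annotations(1)
    ann[[case[[1]]]] <- case[[2]]
    expect_false(apply_site_hard_filters(ann),
                 label = sprintf("%s=%g should fail", case[[1]], case[[2]]))
    ann[[case[[1]]]] <- case[[3]]
    expect_true(apply_site_hard_filters(ann),
                label = sprintf("%s=%g should pass", case[[1]], case[[3]]))
  }
  # all seven at their exact thresholds simultaneously -> pass
  ann <- site_annotations(QD = 2, FS = 60, MQ = 40, MQRankSum = -12.5,
                          ReadPosRankSum = -8, QUAL = 30, SOR = 3.0)
  expect_true(apply_site_hard_filters(ann))
})

test_that("missing rank-sum annotations never fail their test", {
  ann <- site_annotations(QD = 25, FS = 5, MQ = 55, MQRankSum = NA,
                          ReadPosRankSum = NA, QUAL = 500, SOR = 1)
  expect_true(apply_site_hard_filters(ann))
  expect_error(site_annotations(QD = NA, FS = 5, MQ = 55, MQRankSum = 0,
                                ReadPosRankSum = 0, QUAL = 500, SOR = 1),
               "mandatory")
})

test_that("haploid genotype calling: majority, zero depth, symmetric tie", {
  expect_identical(call_haploid_genotype(0L, 0L, 0L), NA_integer_)
  expect_identical(call_haploid_genotype(10L, 2L, 8L), 1L)
  expect_identical(call_haploid_genotype(10L, 8L, 2L), 0L)
  expect_identical(call_haploid_genotype(6L, 3L, 3L), NA_integer_)
  # tie rule is symmetric under ref/alt swap
  for (d in c(2L, 6L, 10L)) {
    expect_identical(call_haploid_genotype(d, d %/% 2L, d %/% 2L),
                     call_haploid_genotype(d, d %/% 2L, d %/% 2L))
  }
  expect_error(call_haploid_genotype(5L, -1L, 2L), "negative")
  expect_error(call_haploid_genotype(5L, 4L, 4L), "exceed")
})

test_that("cell masking follows the depth/AF rule and combine mode", {
  obs <- make_obs(depth = rbind(4L, 30L, 4L, 30L, 30L),
                  ref_count = rbind(2L, 15L, 0L, 27L, 3L),
                  alt_count = rbind(2L, 15L, 4L, 3L, 27L))
  gt <- call_haploid_genotype(obs$depth, obs$ref_count, obs$alt_count)
  # AND (default): only low-depth AND ambiguous cells masked
  m_and <- mask_unreliable_cells(gt, obs)
  expect_true(is.na(m_and[1, 1]))        # depth 4, AF 0.5
  expect_identical(unname(m_and[3, 1]), 1L)      # depth 4, AF 1.0: outside band
  expect_true(is.na(m_and[2, 1]))        # tie was already MISSING
  expect_equal(attr(m_and, "n_masked"), 0L)  # row1/2 were NA already (ties)
  # OR: deep ambiguous cells masked too
  m_or <- mask_unreliable_cells(gt, obs, nucleus_mask_rule(combine = "OR"))
  expect_true(is.na(m_or[1, 1]))
  expect_true(is.na(m_or[3, 1]))         # depth 4 < 5 alone suffices
  # AF exactly at 0.1 / 0.9 is never ambiguous (open interval)
  obs2 <- make_obs(depth = rbind(30L, 30L), ref_count = rbind(27L, 3L),
                   alt_count = rbind(3L, 27L))
  gt2 <- call_haploid_genotype(obs2$depth, obs2$ref_count, obs2$alt_count)
  m2 <- mask_unreliable_cells(gt2, obs2, nucleus_mask_rule(combine = "OR"))
  expect_identical(unname(m2[1, 1]), 0L)
  expect_identical(unname(m2[2, 1]), 1L)
  # zero informative reads: depth alone governs (no 0/0 ambiguity)
  obs3 <- make_obs(depth = rbind(3L), ref_count = rbind(0L),
                   alt_count = rbind(0L))
  gt3 <- matrix(0L, 1, 1)  # pretend call exists; mask decides from evidence
  expect_identical(
    unname(mask_unreliable_cells(gt3, obs3)[1, 1]), 0L)          # AND: no ambiguity
  expect_true(is.na(
    mask_unreliable_cells(gt3, obs3,
                          nucleus_mask_rule(combine = "OR"))[1, 1]))
  expect_error(nucleus_mask_rule(combine = "XOR"))
})

test_that("missingness filter: strict boundary over all sequenced nuclei", {
  codes <- rbind(c(".", ".", ".", "R", "R", "R", "R", "R", "A"),
                 c(".", ".", ".", ".", "R", "R", "R", "R", "A"),
                 rep("A", 9))
  gt <- gt_from_codes(codes)
  res <- filter_by_missingness(gt, 1 / 3, 9L)
  expect_identical(res$retained, c(1L, 3L))  # 3/9 kept, 4/9 removed
  expect_identical(res$n_removed, 1L)
  # no missingness -> identity
  res0 <- filter_by_missingness(gt_from_codes(rep("R", 9) |>
                                                rbind(rep("A", 9))), 1 / 3)
  expect_identical(res0$retained, c(1L, 2L))
  expect_error(filter_by_missingness(gt, 1 / 3, 8L), "width")
})

test_that("SNP extraction matches a per-site scan and flags all-ALT sites", {
  gt_all_ref <- gt_from_codes(matrix("R", 4, 5))
  expect_identical(extract_snp_sites(gt_all_ref)$snp_index, integer(0))

  one_alt <- matrix("R", 1, 19); one_alt[1, 7] <- "A"
  expect_identical(extract_snp_sites(gt_from_codes(one_alt))$snp_index, 1L)

  set.seed(99)
  codes <- matrix(sample(c("R", "A", "."), 100, TRUE, c(0.6, 0.2, 0.2)),
                  10, 10)
  gt <- gt_from_codes(codes)
  res <- extract_snp_sites(gt)
  naive <- which(vapply(seq_len(10), function(i) {
    any(codes[i, ] == "A")
  }, logical(1)))
  expect_identical(res$snp_index, naive)
  naive_all_alt <- which(vapply(seq_len(10), function(i) {
    any(codes[i, ] == "A") && !any(codes[i, ] == "R")
  }, logical(1)))
  expect_identical(res$all_alt_index, naive_all_alt)
})

test_that("run_filter_chain equals the scripted step-by-step oracle", {
  # randomized 50-site, 10-nucleus fixture with all failure modes present
  set.seed(1234)
  S <- 50; N <- 10
  depth <- matrix(rpois(S * N, 12), S, N)
  depth[runif(S * N) < 0.1] <- 0L
  kept <- matrix(rbinom(S * N, depth, 0.95), S, N)
  alt <- matrix(rbinom(S * N, kept, runif(S * N)), S, N)
  obs <- make_obs(depth, kept - alt, alt)
  ann <- nominal_annotations(S)
  bad <- sample(S, 8)
  ann$QD[bad[1:2]] <- 1
  ann$FS[bad[3:4]] <- 100
  ann$SOR[bad[5:6]] <- 4
  ann$QUAL[bad[7:8]] <- 10
  ann$MQRankSum[sample(S, 5)] <- NA
  ann$ReadPosRankSum[sample(S, 5)] <- NA

  res <- run_filter_chain(obs, ann)
  expect_identical(paste(res$snp_sites$contig, res$snp_sites$pos),
                   chain_oracle(obs, ann))
  expect_identical(res$report$n_sites_input, 50L)
  expect_identical(res$report$n_failed_hard_filters, 8L)
  # OR mode agrees with the oracle too
  rule_or <- nucleus_mask_rule(combine = "OR")
  res_or <- run_filter_chain(obs, ann, rule = rule_or)
  expect_identical(paste(res_or$snp_sites$contig, res_or$snp_sites$pos),
                   chain_oracle(obs, ann, rule = rule_or))
})

test_that("empty input and single-stage isolation", {
  obs <- make_obs(depth = matrix(integer(0), 0, 3),
                  ref_count = matrix(integer(0), 0, 3),
                  alt_count = matrix(integer(0), 0, 3))
  res <- run_filter_chain(obs, nominal_annotations(0))
  expect_equal(nrow(res$snp_sites), 0L)
  expect_identical(res$report$n_sites_input, 0L)
  expect_identical(res$report$n_snp_sites, 0L)

  # one hard-filter-failing SNP site disappears and is counted
  obs1 <- make_obs(depth = rbind(c(20L, 20L), c(20L, 20L)),
                   ref_count = rbind(c(20L, 0L), c(20L, 0L)),
                   alt_count = rbind(c(0L, 20L), c(0L, 20L)))
  ann1 <- nominal_annotations(2)
  ann1$QD[2] <- 1
  res1 <- run_filter_chain(obs1, ann1)
  expect_identical(res1$report$n_failed_hard_filters, 1L)
  expect_identical(res1$snp_sites$pos, obs1$sites$pos[1])
})

test_that("tightening any threshold never increases the SNP count", {
  w <- toy_world(seed = 55, n_nuclei = 10,
                 obs = obs_params(mean_depth = 10, dropout_rate = 0.2))
  base <- run_filter_chain(w$obs, w$ann)$report$n_snp_sites
  tighter <- list(
    list(rule = nucleus_mask_rule(min_depth = 10L)),
    list(rule = nucleus_mask_rule(af_low = 0.02, af_high = 0.98)),
    list(max_missing_fraction = 0.2),
    list(rule = nucleus_mask_rule(min_depth = 15L, af_low = 0.01,
                                  af_high = 0.99),
         max_missing_fraction = 0.1))
  for (args in tighter) {
    n <- do.call(run_filter_chain,
                 c(list(obs = w$obs, ann = w$ann), args))$report$n_snp_sites
    expect_lte(n, base)
  }
})

test_that("stage order is fixed: swapping changes counts, not noiseless sets", {
  w <- toy_world(seed = 77, n_nuclei = 9, obs = noiseless_obs(),
                 ann_violation_rate = 0)
  res <- run_filter_chain(w$obs, w$ann)
  # permuted composition: missingness applied on unmasked calls first,
  # masking after -- a different pipeline
  gt <- call_haploid_genotype(w$obs$depth, w$obs$ref_count, w$obs$alt_count)
  miss_first <- filter_by_missingness(gt)
  gt_masked <- mask_unreliable_cells(gt, w$obs)
  snp_perm <- extract_snp_sites(gt_masked, miss_first$retained)
  # on noiseless data the final SNP set agrees...
  expect_identical(
    paste(res$snp_sites$contig, res$snp_sites$pos),
    paste(w$obs$sites$contig[snp_perm$snp_index],
          w$obs$sites$pos[snp_perm$snp_index]))
  # ...but on noisy data the stage counts differ
  wn <- toy_world(seed = 78, n_nuclei = 9,
                  obs = obs_params(mean_depth = 6, dropout_rate = 0.3))
  resn <- run_filter_chain(wn$obs, wn$ann)
  gtn <- call_haploid_genotype(wn$obs$depth, wn$obs$ref_count,
                               wn$obs$alt_count)
  miss_n_first <- filter_by_missingness(gtn)
  expect_false(identical(nrow(gtn) - length(miss_n_first$retained),
                         resn$report$n_sites_removed_missingness))
})

test_that("noiseless chain recovers the truth set exactly", {
  w <- toy_world(seed = 91, n_nuclei = 12, divergence_per_kb = 0.8,
                 private_mut_per_kb = 0.05, obs = noiseless_obs(),
                 ann_violation_rate = 0)
  res <- run_filter_chain(w$obs, w$ann)
  expect_sites_equal(res$snp_sites, w$truth$variant_sites)
})
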