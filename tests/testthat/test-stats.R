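test_that("site calling requires conjugate evidence for confirmation", {
  obs <- data.frame(
    accession = c("P1", "P1", "P1", "P2", "P2"),
    protein_pos = c(10L, 10L, 44L, 7L, 7L),
    residue = c("S", "S", "T", "C", "C"),
    evidence_form = c("direct", "GSH", "direct", "XL", "direct"),
    specimen_id = c("a", "b", "a", "a", "c"))
  sites <- call_sites(obs)
  expect_equal(nrow(sites), 3)
  s10 <- sites[sites$protein_pos == 10, ]
  expect_true(s10$confirmed)          # conjugate present
  expect_equal(s10$n_specimens, 2)
  expect_false(sites[sites$protein_pos == 44, ]$confirmed)  # direct only
  expect_true(sites[sites$protein_pos == 7, ]$confirmed)    # XL counts
  expect_equal(nrow(call_sites(obs[0, ])), 0)
})

test_that("prevalence thresholds are inclusive and counts monotone", {
  sites <- data.frame(accession = c("A", "A", "B"),
                      protein_pos = 1:3, residue = "S",
                      evidence_forms = "GSH",
                      n_specimens = c(2L, 4L, 3L),
                      specimens = "", confirmed = TRUE)
  tab <- prevalence_summary(sites, 4)
  # 2/4 counts at 50% but not 80%; 3/4 at 50% only; 4/4 everywhere
  expect_equal(tab$n_sites, c(3, 3, 1, 1))     # any, 50%, 80%, 100%
  expect_equal(tab$n_proteins, c(2, 2, 1, 1))
  expect_true(all(diff(tab$n_sites) <= 0))
  expect_error(prevalence_summary(sites, 0), "positive")
  # brute-force recount agreement on random patterns
  set.seed(21)
  for (i in 1:200) {
    n_spec <- sample(3:12, 1)
    n_sites <- sample(1:30, 1)
    st <- data.frame(accession = sample(LETTERS[1:6], n_sites, TRUE),
                     protein_pos = seq_len(n_sites), residue = "S",
                     evidence_forms = "GSH",
                     n_specimens = sample(0:n_spec, n_sites, TRUE),
                     specimens = "", confirmed = TRUE)
    th <- runif(1)
    got <- prevalence_summary(st, n_spec, thresholds = th)
    sel <- st$n_specimens / n_spec >= th
    expect_equal(got$n_sites, sum(sel))
    expect_equal(got$n_proteins, length(unique(st$accession[sel])))
  }
})

test_that("LFQ aggregation sums fractions and median-normalizes", {
  psms <- data.frame(spectrum_id = c("1", "2", "3", "4"),
                     run_id = c("f1", "f2", "f1", "f1"),
                     specimen_id = c("s1", "s1", "s2", "s2"),
                     group = c("AD", "AD", "CTR", "CTR"),
                     accession = "P", start = 1L,
                     peptide = c("PEPA", "PEPA", "PEPA", "PEPB"),
                     mods = "", c_term_heavy_O = 0L, score = 1,
                     q_value = 0, mass_error_ppm = 0,
                     intensity = c(10, 20, 60, 30))
  agg <- lfq_aggregate(psms, normalize = FALSE)
  expect_equal(agg$matrix["PEPA", "s1"], 30)   # fractions sum
  expect_equal(agg$matrix["PEPA", "s2"], 60)
  expect_true(is.na(agg$matrix["PEPB", "s1"]))
  expect_equal(unname(agg$groups[c("s1", "s2")]), c("AD", "CTR"))
  # doubling a specimen is undone by median normalization
  psms2 <- psms[c(1, 3, 4), ]
  psms2$intensity <- c(10, 20, 40)
  psms2$peptide <- c("PEPA", "PEPA", "PEPB")
  psms2 <- rbind(psms2,
                 transform(psms2[2:3, ], specimen_id = "s3",
                           intensity = intensity * 2))
  norm <- lfq_aggregate(psms2)$matrix
  expect_equal(norm["PEPA", "s2"], norm["PEPA", "s3"])
  expect_equal(nrow(lfq_aggregate(psms[0, ])$matrix), 0)
})

test_that("differential abundance matches an independent t-test", {
  mat <- rbind(sig = c(9.9, 10, 10.1, 0.9, 1, 1.1),
               null = c(5, 6, 7, 5, 6, 7))
  groups <- setNames(rep(c("AD", "CTR"), each = 3),
                     c("a1", "a2", "a3", "c1", "c2", "c3"))
  colnames(mat) <- names(groups)
  res <- differential_abundance(mat, groups)
  expect_equal(res$log2_fold_change[1], log2(10), tolerance = 0.01)
  oracle <- t.test(log2(mat[1, 1:3]), log2(mat[1, 4:6]))
  expect_equal(res$t_statistic[1], unname(oracle$statistic),
               tolerance = 1e-9)
  expect_equal(res$p_value[1], oracle$p.value, tolerance = 1e-9)
  expect_lt(res$p_value[1], 0.05)
  expect_equal(res$log2_fold_change[2], 0)
  expect_equal(res$t_statistic[2], 0)
  expect_equal(res$p_value[2], 1)
})

test_that("degenerate and missing-data features are flagged, not fatal", {
  mat <- rbind(zerovar = c(2, 2, 2, 1, 1, 1),
               sparse = c(3, NA, NA, 1, 2, 3))
  colnames(mat) <- c("a1", "a2", "a3", "c1", "c2", "c3")
  groups <- setNames(rep(c("AD", "CTR"), each = 3), colnames(mat))
  expect_message(res <- differential_abundance(mat, groups), "skipped")
  expect_equal(res$flag, c("degenerate_zero_variance",
                           "skipped_missingness"))
  expect_equal(res$p_value[1], 0)  # distinct constant groups: limit p
  expect_true(is.na(res$p_value[2]))
  # paired mode equals the base paired t-test
  mat2 <- rbind(f = c(4, 6, 8, 1, 2, 3))
  colnames(mat2) <- colnames(mat)
  resp <- differential_abundance(mat2, groups, paired = TRUE)
  oracle <- t.test(log2(mat2[1, 1:3]), log2(mat2[1, 4:6]), paired = TRUE)
  expect_equal(resp$t_statistic, unname(oracle$statistic), tolerance = 1e-9)
  expect_equal(resp$p_value, oracle$p.value, tolerance = 1e-9)
})

test_that("permutation FDR agrees with exhaustive enumeration at 3 vs 3", {
  set.seed(8)
  mat <- matrix(rlnorm(20 * 6, log(1e5), 0.4), 20, 6,
                dimnames = list(paste0("f", 1:20),
                                c("a1", "a2", "a3", "c1", "c2", "c3")))
  mat[1, 1:3] <- mat[1, 1:3] * 8
  groups <- setNames(rep(c("AD", "CTR"), each = 3), colnames(mat))
  got <- permutation_fdr(mat, groups, exhaustive = TRUE)
  # independent oracle: every choose(6,3) relabelling via t.test
  lx <- log2(mat)
  tstat <- function(i1, i2) apply(lx, 1, function(r)
    tryCatch(abs(t.test(r[i1], r[i2])$statistic), error = function(e) NA))
  obs <- tstat(1:3, 4:6)
  combos <- combn(6, 3)
  perm <- lapply(seq_len(ncol(combos)), function(j)
    tstat(combos[, j], setdiff(1:6, combos[, j])))
  fdr <- vapply(sort(obs), function(t0) {
    e <- mean(vapply(perm, function(p) sum(p >= t0 - 1e-12), numeric(1)))
    min(1, e / sum(obs >= t0 - 1e-12))
  }, numeric(1))
  expect_equal(got$q_permutation[order(got$t_abs)], unname(cummin(fdr)),
               tolerance = 1e-9)
  # determinism and feature-order invariance for the sampled version
  q1 <- permutation_fdr(mat, groups, n_perm = 50, seed = 3)
  q2 <- permutation_fdr(mat, groups, n_perm = 50, seed = 3)
  expect_equal(q1, q2)
  shuf <- sample(nrow(mat))
  q3 <- permutation_fdr(mat[shuf, ], groups, n_perm = 50, seed = 3)
  expect_equal(q3$q_permutation[match(q1$feature, q3$feature)],
               q1$q_permutation)
})

test_that("a dominant feature gets permutation q of zero", {
  set.seed(14)
  mat <- matrix(rlnorm(50 * 12, log(1e5), 0.3), 50, 12)
  colnames(mat) <- paste0("s", 1:12)
  mat[1, 1:6] <- mat[1, 1:6] * 50
  groups <- setNames(rep(c("AD", "CTR"), each = 6), colnames(mat))
  q <- permutation_fdr(mat, groups, n_perm = 200, seed = 5)
  expect_equal(q$q_permutation[1], 0)
})

test_that("occupancy summarizes ratios with a bootstrap-consistent SEM", {
  expect_equal(occupancy_summary(25, 75)$mean, 0.25)
  zero <- occupancy_summary(rep(0, 5), c(1, 2, 3, 4, 5))
  expect_equal(zero$mean, 0)
  expect_equal(zero$sem, 0)
  expect_error(occupancy_summary(c(0, 0), c(0, 0)), "zero total")
  set.seed(31)
  modv <- rlnorm(20, log(200), 0.4)
  unmodv <- rlnorm(20, log(600), 0.4)
  occ <- occupancy_summary(modv, unmodv)
  boots <- replicate(2000, {
    idx <- sample(20, replace = TRUE)
    mean(modv[idx] / (modv[idx] + unmodv[idx]))
  })
  expect_lt(abs(occ$sem - sd(boots)) / sd(boots), 0.1)
})

test_that("association fractions are exact set arithmetic", {
  groups <- list(DHAA = c("P1", "P2", "P3", "P4"),
                 Phospho = c("P5", "P6"))
  nft <- c("P1", "P2", "P3", "P4")
  sp <- c("P9")
  res <- association_fraction(groups, nft, sp)
  expect_equal(res$fraction_nft, c(1, 0))
  expect_equal(res$fraction_sp, c(0, 0))
  expect_error(association_fraction(list(x = character()), nft, sp),
               "empty")
  set.seed(6)
  for (i in 1:100) {
    g <- list(a = sample(LETTERS, sample(1:10, 1)))
    l1 <- sample(LETTERS, sample(0:15, 1))
    l2 <- sample(LETTERS, sample(0:15, 1))
    r <- association_fraction(g, l1, l2)
    expect_equal(r$fraction_nft, length(intersect(g$a, l1)) / length(unique(g$a)))
    expect_equal(r$fraction_sp, length(intersect(g$a, l2)) / length(unique(g$a)))
  }
})
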