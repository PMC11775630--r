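#' Aggregate PSM precursor intensities into a feature-by-specimen matrix
#'
#' Label-free quantification by aggregation: the intensity of a
#' peptidoform feature in a specimen is the sum of its precursor
#' intensities over all PSMs (fractions/runs of the same specimen sum
#' together).  Specimens are then median-normalized to a common scale.
#' Missing values stay `NA` (absent), never zero-imputed.
#'
#' @param psms data.frame in the `PSM_COLUMNS` layout with `intensity`,
#'   `specimen_id` and optionally `group`.
#' @param normalize Median-normalize specimens (default `TRUE`).
#' @return List with `matrix` (features x specimens, `NA` = absent) and
#'   `groups` (named character vector specimen -> group label).
#' @export
lfq_aggregate <- function(psms, normalize = TRUE) {
  if (nrow(psms) == 0)
    return(list(matrix = matrix(numeric(0), 0, 0), groups = character(0)))
  feature <- paste0(psms$peptide,
                    ifelse(nzchar(psms$mods), paste0("[", psms$mods, "]"), ""),
                    ifelse(psms$c_term_heavy_O > 0, "{heavy}", ""))
  agg <- stats::aggregate(list(intensity = psms$intensity),
                          list(feature = feature,
                               specimen = psms$specimen_id), sum)
  feats <- sort(unique(agg$feature))
  specs <- sort(unique(agg$specimen))
  m <- matrix(NA_real_, length(feats), length(specs),
              dimnames = list(feats, specs))
  m[cbind(match(agg$feature, feats), match(agg$specimen, specs))] <-
    agg$intensity
  if (normalize && ncol(m) > 1) {
    med <- apply(m, 2, stats::median, na.rm = TRUE)
    target <- stats::median(med, na.rm = TRUE)
    m <- sweep(m, 2, target / med, "*")
  }
  groups <- character(0)
  if ("group" %in% names(psms)) {
    g <- psms$group[match(specs, psms$specimen_id)]
    groups <- stats::setNames(as.character(g), specs)
  }
  list(matrix = m, groups = groups)
}

# Vectorized Welch two-sample t on the rows of a (log-scale) matrix.
# Returns t, df, p; rows with < 2 non-missing values in either group get NA.
row_welch_t <- function(x, idx1, idx2) {
  n1 <- rowSums(!is.na(x[, idx1, drop = FALSE]))
  n2 <- rowSums(!is.na(x[, idx2, drop = FALSE]))
  m1 <- rowMeans(x[, idx1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(x[, idx2, drop = FALSE], na.rm = TRUE)
  v1 <- apply(x[, idx1, drop = FALSE], 1, stats::var, na.rm = TRUE)
  v2 <- apply(x[, idx2, drop = FALSE], 1, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  zerovar <- !is.na(se2) & se2 == 0
  t[zerovar] <- ifelse(m1[zerovar] == m2[zerovar], 0, Inf * sign(m1 - m2)[zerovar])
  df[zerovar] <- n1[zerovar] + n2[zerovar] - 2
  p <- 2 * stats::pt(-abs(t), df)
  p[zerovar & t == 0] <- 1
  p[zerovar & is.infinite(t)] <- 0
  bad <- n1 < 2 | n2 < 2
  t[bad] <- NA; p[bad] <- NA; df[bad] <- NA
  list(t = unname(t), df = unname(df), p = unname(p),
       n1 = unname(n1), n2 = unname(n2), zerovar = unname(bad | zerovar))
}

#' Differential abundance between disease and control specimens
#'
#' Fold changes are ratios of group means on the raw intensity scale;
#' confidence comes from a two-tailed t-test on log2 intensities (Welch by
#' default; a paired test is available for balanced, matched designs).
#' Features with fewer than two non-missing values in either group are
#' skipped with a reason.  Zero-variance features report the limiting
#' p-value (1 for equal means, 0 otherwise) and are flagged degenerate
#' rather than erroring.
#'
#' @param mat Feature-by-specimen intensity matrix (raw scale, `NA` =
#'   absent), e.g. `lfq_aggregate(...)$matrix`.
#' @param groups Named character vector (specimen -> `"AD"`/`"CTR"`), or a
#'   vector aligned with `colnames(mat)`.
#' @param paired Use a paired t-test (requires equal group sizes and
#'   column-order matching); default `FALSE` (Welch).
#' @return data.frame with `feature`, `mean_AD`, `mean_CTR`,
#'   `log2_fold_change`, `t_statistic`, `p_value`, `df`, `flag`.
#' @export
differential_abundance <- function(mat, groups, paired = FALSE) {
  groups <- align_groups(mat, groups)
  idx1 <- which(groups == "AD")
  idx2 <- which(groups == "CTR")
  if (length(idx1) < 2 || length(idx2) < 2)
    stop("each group needs at least two specimens")
  lx <- log2(mat)
  if (paired) {
    if (length(idx1) != length(idx2))
      stop("paired testing requires equal group sizes")
    d <- lx[, idx1, drop = FALSE] - lx[, idx2, drop = FALSE]
    n <- rowSums(!is.na(d))
    md <- rowMeans(d, na.rm = TRUE)
    sd_d <- apply(d, 1, stats::sd, na.rm = TRUE)
    t <- md / (sd_d / sqrt(n))
    df <- n - 1
    p <- 2 * stats::pt(-abs(t), df)
    zerovar <- !is.na(sd_d) & sd_d == 0
    t[zerovar] <- ifelse(md[zerovar] == 0, 0, Inf)
    p[zerovar] <- ifelse(md[zerovar] == 0, 1, 0)
    bad <- n < 2
    t[bad] <- NA; p[bad] <- NA
    res <- list(t = t, df = df, p = p,
                n1 = rowSums(!is.na(lx[, idx1, drop = FALSE])),
                n2 = rowSums(!is.na(lx[, idx2, drop = FALSE])))
    zv <- zerovar
  } else {
    res <- row_welch_t(lx, idx1, idx2)
    zv <- res$zerovar & res$n1 >= 2 & res$n2 >= 2
  }
  mean_AD <- rowMeans(mat[, idx1, drop = FALSE], na.rm = TRUE)
  mean_CTR <- rowMeans(mat[, idx2, drop = FALSE], na.rm = TRUE)
  skipped <- res$n1 < 2 | res$n2 < 2
  out <- data.frame(
    feature = if (is.null(rownames(mat))) paste0("f", seq_len(nrow(mat)))
              else rownames(mat),
    mean_AD = mean_AD, mean_CTR = mean_CTR,
    log2_fold_change = log2(mean_AD / mean_CTR),
    t_statistic = res$t, p_value = res$p, df = res$df,
    flag = ifelse(skipped, "skipped_missingness",
                  ifelse(zv, "degenerate_zero_variance", "")))
  if (any(skipped))
    message(sum(skipped), " feature(s) skipped: fewer than 2 values per group")
  rownames(out) <- NULL
  out
}

align_groups <- function(mat, groups) {
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(mat), names(groups))
    if (length(missing))
      stop("no group label for specimen(s): ", paste(missing, collapse = ", "))
    groups <- groups[colnames(mat)]
  } else if (length(groups) != ncol(mat)) {
    stop("groups must be named or aligned with the matrix columns")
  }
  as.character(groups)
}

#' Permutation-based FDR for differential abundance
#'
#' Group labels are permuted (unrestricted label permutation); for each
#' observed |t| threshold the expected number of null features exceeding
#' it (mean over permutations) is divided by the observed count, giving an
#' FDR estimate that is then converted to monotone q-values.
#' Deterministic for a fixed seed and invariant to feature order.
#'
#' @param mat Feature-by-specimen intensity matrix (raw scale).
#' @param groups Group labels as in [differential_abundance()].
#' @param n_perm Number of label permutations (default 1000).
#' @param seed RNG seed.
#' @param exhaustive Enumerate every distinct label assignment instead of
#'   sampling (feasible only for small designs).
#' @return data.frame with `feature`, `t_abs`, `q_permutation`.
#' @export
permutation_fdr <- function(mat, groups, n_perm = 1000, seed = 1,
                            exhaustive = FALSE) {
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1")
  groups <- align_groups(mat, groups)
  idx1 <- which(groups == "AD")
  idx2 <- which(groups == "CTR")
  lx <- log2(mat)
  obs <- abs(row_welch_t(lx, idx1, idx2)$t)
  ncols <- length(idx1) + length(idx2)
  cols <- c(idx1, idx2)
  n1 <- length(idx1)
  if (exhaustive) {
    combos <- utils::combn(ncols, n1)
    perms <- lapply(seq_len(ncol(combos)), function(j) combos[, j])
  } else {
    perms <- withr_seed(seed, lapply(seq_len(n_perm), function(b)
      sample(ncols, n1)))
  }
  perm_t <- lapply(perms, function(sel) {
    a <- cols[sel]; b <- cols[-sel]
    abs(row_welch_t(lx, a, b)$t)
  })
  ok <- !is.na(obs)
  t_ok <- obs[ok]
  ord <- order(t_ok)                      # ascending |t|
  sorted <- t_ok[ord]
  n_obs_ge <- length(sorted) - seq_along(sorted) + 1
  exp_ge <- rowMeans(matrix(vapply(perm_t, function(pt) {
    pt <- pt[!is.na(pt)]
    length(pt) - findInterval(sorted - 1e-12, sort(pt))
  }, numeric(length(sorted))), nrow = length(sorted)))
  fdr <- pmin(1, exp_ge / n_obs_ge)
  # q-value: minimum FDR over any call set containing the feature
  q_sorted <- cummin(fdr)
  q <- rep(NA_real_, length(obs))
  q[ok][ord] <- q_sorted
  data.frame(feature = if (is.null(rownames(mat)))
               paste0("f", seq_len(nrow(mat))) else rownames(mat),
             t_abs = obs, q_permutation = q)
}

# evaluate `expr` under a locally-seeded RNG without disturbing the
# caller's random state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Site occupancy with standard-error propagation
#'
#' Occupancy is the fraction of a site's signal carried by the modified
#' form, `modified / (modified + unmodified)`, computed per specimen;
#' the summary is the mean across specimens with its standard error.
#'
#' @param modified,unmodified Non-negative intensity vectors, one entry
#'   per specimen.
#' @return List with `occupancy` (per specimen), `mean`, `sem`,
#'   `n_specimens`.
#' @export
occupancy_summary <- function(modified, unmodified) {
  stopifnot(length(modified) == length(unmodified))
  if (any(modified < 0 | unmodified < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  denom <- modified + unmodified
  if (all(is.na(denom) | denom == 0))
    stop("all specimens have zero total intensity")
  keep <- !is.na(denom) & denom > 0
  occ <- modified[keep] / denom[keep]
  n <- length(occ)
  sem <- if (n > 1) stats::sd(occ) / sqrt(n) else 0
  list(occupancy = occ, mean = mean(occ), sem = sem, n_specimens = n)
}
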