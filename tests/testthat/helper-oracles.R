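# Independent oracles used across the suite.  These are deliberately
# naive (enumeration / direct counting) and share no code with the
# implementation paths they check.

# exhaustive isotopologue enumeration for small compositions (<= ~12
# atoms): every way of assigning isotopes to atoms, aggregated into
# nucleon-offset bins with intensity-weighted centroid masses
enumerate_isotopologues <- function(counts) {
  tabs <- dhaaxl:::ISOTOPE_TABLE
  per_element <- lapply(names(counts), function(el) {
    n <- counts[[el]]
    tab <- tabs[[el]]
    k <- nrow(tab)
    # all ways to distribute n atoms over k isotopes
    distribute <- function(n, k) {
      if (k == 1) return(matrix(n, 1, 1))
      out <- list()
      for (i in 0:n) {
        rest <- distribute(n - i, k - 1)
        out[[length(out) + 1]] <- cbind(i, rest)
      }
      do.call(rbind, out)
    }
    combos <- distribute(n, k)
    prob <- apply(combos, 1, function(cc)
      factorial(n) / prod(factorial(cc)) * prod(tab[, "abundance"]^cc))
    mass <- combos %*% tab[, "mass"]
    offs <- combos %*% round(tab[, "mass"] - tab[1, "mass"])
    data.frame(prob = prob, mass = as.numeric(mass),
               offset = as.integer(offs))
  })
  # cartesian product over elements
  acc <- data.frame(prob = 1, mass = 0, offset = 0L)
  for (d in per_element) {
    acc <- do.call(rbind, lapply(seq_len(nrow(acc)), function(i)
      data.frame(prob = acc$prob[i] * d$prob,
                 mass = acc$mass[i] + d$mass,
                 offset = acc$offset[i] + d$offset)))
  }
  agg_p <- tapply(acc$prob, acc$offset, sum)
  agg_m <- tapply(acc$prob * acc$mass, acc$offset, sum) / agg_p
  data.frame(offset = as.integer(names(agg_p)),
             mass = as.numeric(agg_m),
             intensity = as.numeric(agg_p))[order(as.integer(names(agg_p))), ]
}

# brute-force tryptic digest: every substring whose boundaries are valid
# cleavage points and whose interior has <= max_missed cleavage sites
brute_digest <- function(seq, max_missed, min_len, max_len) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  is_cut <- function(i) {  # cleavage allowed after position i
    if (i == 0 || i == n) return(TRUE)
    res[i] %in% c("K", "R") && res[i + 1] != "P"
  }
  out <- list()
  for (s in 1:n) for (e in s:n) {
    if (!is_cut(s - 1) || !is_cut(e)) next
    interior <- if (e > s) sum(vapply(s:(e - 1), is_cut, logical(1))) else 0
    if (interior > max_missed) next
    len <- e - s + 1
    if (len < min_len || len > max_len) next
    out[[length(out) + 1]] <- data.frame(
      peptide = paste(res[s:e], collapse = ""), start = s,
      missed = interior)
  }
  do.call(rbind, out)
}

# direct-counting target-decoy q oracle
brute_q <- function(score, is_decoy) {
  raw <- vapply(score, function(s) {
    d <- sum(is_decoy & score >= s)
    t <- sum(!is_decoy & score >= s)
    if (t == 0) 1 else min(1, d / t)
  }, numeric(1))
  vapply(seq_along(score), function(i)
    min(raw[score <= score[i]]), numeric(1))
}

# small ready-made simulation shared by search/validation tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- simulation_params(seed = 11, n_proteins = 10,
                             segments_per_protein = 10,
                             n_direct_sites = 3,
                             n_conjugate_sites = c(GSH = 2, HC = 1,
                                                   DTT = 1, TCEP = 1),
                             n_crosslinks_intra = 3, n_crosslinks_inter = 3,
                             n_crosslinks_light_only = 2, n_runs = 1)
      cache <<- simulate_study(p)
    }
    cache
  }
})

# orientation-free crosslink key: a link connects two protein sites; for
# C-C links the donor/acceptor assignment is mass- and fragment-identical
# either way, so truth comparisons use the unordered site pair
xl_key <- function(acc1, pos1, acc2, pos2) {
  k1 <- paste(acc1, pos1)
  k2 <- paste(acc2, pos2)
  ifelse(k1 < k2, paste(k1, k2, sep = "::"), paste(k2, k1, sep = "::"))
}
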