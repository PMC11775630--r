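#' Tryptic digestion parameters
#' @param max_missed_cleavages Maximum missed cleavages (default 2).
#' @param min_length,max_length Peptide length bounds (default 6-40).
#' @param cleave_before_proline Allow cleavage when the following residue
#'   is proline (default `FALSE`, the classical no-P rule).
#' @return An object of class `"digest_params"`.
#' @export
digest_params <- function(max_missed_cleavages = 2L, min_length = 6L,
                          max_length = 40L, cleave_before_proline = FALSE) {
  stopifnot(max_missed_cleavages >= 0, min_length <= max_length)
  structure(list(max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 cleave_before_proline = isTRUE(cleave_before_proline)),
            class = "digest_params")
}

#' In-silico tryptic digestion
#'
#' Cleaves after K/R (suppressed before proline unless
#' `cleave_before_proline`), enumerates every missed-cleavage combination
#' up to the maximum, and applies the length filter.  Zero-missed peptides
#' tile the protein exactly; every missed-cleavage peptide is a
#' concatenation of adjacent zero-missed peptides.
#'
#' @param sequence Protein sequence (or a one-row protein data.frame).
#' @param params A [digest_params()].
#' @return data.frame with columns `peptide`, `start` (1-based), `missed`.
#' @examples
#' tryptic_digest("AKRPK", digest_params(1, min_length = 1))
#' @export
tryptic_digest <- function(sequence, params = digest_params()) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  if (!params$cleave_before_proline)
    cut_after <- cut_after[cut_after == n | res[cut_after + 1] != "P"]
  bounds <- c(0L, cut_after[cut_after < n], n)  # segment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  nseg <- length(starts)
  out <- list()
  for (i in seq_len(nseg)) {
    for (m in 0:min(params$max_missed_cleavages, nseg - i)) {
      s <- starts[i]; e <- ends[i + m]
      len <- e - s + 1L
      if (len < params$min_length || len > params$max_length) next
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(sequence, s, e), start = s, missed = m)
    }
  }
  if (length(out) == 0)
    return(data.frame(peptide = character(), start = integer(),
                      missed = integer()))
  do.call(rbind, out)
}

#' Digest every protein in a database
#' @param proteins data.frame as from [read_fasta()].
#' @param params A [digest_params()].
#' @return data.frame with `accession`, `peptide`, `start`, `missed`.
#' @export
digest_proteome <- function(proteins, params = digest_params()) {
  pieces <- lapply(seq_len(nrow(proteins)), function(i) {
    d <- tryptic_digest(proteins$sequence[i], params)
    if (nrow(d)) d$accession <- proteins$accession[i]
    d
  })
  out <- do.call(rbind, pieces[vapply(pieces, nrow, integer(1)) > 0])
  if (is.null(out))
    return(data.frame(accession = character(), peptide = character(),
                      start = integer(), missed = integer()))
  out[, c("accession", "peptide", "start", "missed")]
}

#' Build a targeted protein database for crosslink searching
#'
#' Crosslink search space grows quadratically with database size, so
#' searches run against small targeted databases: a curated panel of
#' aggregation-prone proteins, the set of proteins already found to carry
#' DHAAs or their conjugates, or the most abundant proteins of a specimen.
#'
#' @param mode `"aggregation_panel"`, `"dhaa_containing"` or
#'   `"top_abundant"`.
#' @param proteins Full protein database (data.frame as from
#'   [read_fasta()]).
#' @param panel Character vector of accessions (for `aggregation_panel`).
#' @param sites data.frame with an `accession` column (for
#'   `dhaa_containing`), e.g. called eliminylation sites.
#' @param abundance data.frame with `accession` and `intensity` columns
#'   (for `top_abundant`).
#' @param n Number of proteins to keep in `top_abundant` mode (default
#'   500); ties broken by accession.
#' @return Deduplicated data.frame of protein records.
#' @export
build_targeted_database <- function(mode = c("aggregation_panel",
                                             "dhaa_containing",
                                             "top_abundant"),
                                    proteins, panel = NULL, sites = NULL,
                                    abundance = NULL, n = 500L) {
  mode <- match.arg(mode)
  accs <- switch(mode,
    aggregation_panel = {
      if (is.null(panel) || length(panel) == 0)
        stop("aggregation_panel mode requires a non-empty panel")
      unique(panel)
    },
    dhaa_containing = {
      if (is.null(sites) || nrow(sites) == 0)
        stop("dhaa_containing mode requires non-empty site results")
      unique(sites$accession)
    },
    top_abundant = {
      if (is.null(abundance) || nrow(abundance) == 0)
        stop("top_abundant mode requires a non-empty abundance ranking")
      ab <- stats::aggregate(intensity ~ accession, abundance, sum)
      ab <- ab[order(-ab$intensity, ab$accession), ]
      utils::head(ab$accession, n)
    })
  db <- proteins[proteins$accession %in% accs, , drop = FALSE]
  db <- db[!duplicated(db$accession), , drop = FALSE]
  rownames(db) <- NULL
  db
}

#' The shipped aggregation-panel accession list
#'
#' A curated, editable list of proteins reported to aggregate in
#' neurodegenerative disease (Tau/MAPT, APP, the CRMP family,
#' alpha-synuclein, GFAP, GAPDH, VDAC2, myelin proteins, ...).  This is
#' configuration, not ground truth; edit the file to change the panel.
#' @return Character vector of identifiers.
#' @export
aggregation_panel <- function() {
  path <- system.file("extdata", "aggregation_panel.txt", package = "dhaaxl")
  x <- readLines(path)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Plan the crosslink search grid
#'
#' One search job per (donor chemistry, acceptor residue, dataset,
#' database): three potential DHAA donors (S, T, C) times three
#' nucleophilic acceptors (C, K, H) gives nine chemistry combinations per
#' dataset per database.
#'
#' @param datasets Character vector of dataset identifiers (unique).
#' @param databases Character vector of database identifiers (unique).
#' @param donors Donor precursor residues (default S, T, C).
#' @param acceptors Acceptor residues (default C, K, H).
#' @return data.frame of jobs: `donor`, `acceptor`, `dataset`, `database`,
#'   with `nrow = donors x acceptors x datasets x databases`, in
#'   deterministic order.
#' @examples
#' nrow(plan_crosslink_searches(paste0("d", 1:16), paste0("db", 1:3)))  # 432
#' @export
plan_crosslink_searches <- function(datasets, databases,
                                    donors = c("S", "T", "C"),
                                    acceptors = c("C", "K", "H")) {
  if (length(datasets) < 1 || length(databases) < 1 ||
      length(donors) < 1 || length(acceptors) < 1)
    stop("all job dimensions must be non-empty")
  if (anyDuplicated(datasets)) stop("duplicate dataset ids")
  if (anyDuplicated(databases)) stop("duplicate database ids")
  jobs <- expand.grid(acceptor = acceptors, donor = donors,
                      dataset = datasets, database = databases,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  jobs <- jobs[, c("donor", "acceptor", "dataset", "database")]
  rownames(jobs) <- NULL
  jobs
}

#' Append accepted crosslinks to a modification database
#'
#' Each accepted crosslink becomes a site-specific custom modification at
#' its donor site whose delta is the full mass of the partner peptide plus
#' the crosslinker delta, so that a standard linear search can re-find the
#' crosslinked species against the full proteome.  In heavy mode the
#' partner's C-terminus carries the double 18-O label, adding +4.00849 Da.
#'
#' @param mod_db Named list of [modification()] objects to augment.
#' @param crosslinks data.frame in the CSM layout (see `CSM_COLUMNS`);
#'   `alpha_protein_site` must be resolved.
#' @param label_state `"light"` or `"heavy"`.
#' @param registry Modification registry used to decode partner
#'   peptidoforms.
#' @return The augmented named list of modifications.
#' @export
append_crosslinks_to_database <- function(mod_db, crosslinks,
                                          label_state = c("light", "heavy"),
                                          registry = built_in_modifications()) {
  label_state <- match.arg(label_state)
  if (is.null(crosslinks) || nrow(crosslinks) == 0) return(mod_db)
  if (any(is.na(crosslinks$alpha_protein_site)))
    stop("crosslink without a resolved donor protein site")
  for (i in seq_len(nrow(crosslinks))) {
    row <- crosslinks[i, ]
    partner <- decode_peptidoform(row$beta_peptide, row$beta_mods,
                                  registry = registry)
    donor_res <- substr(row$alpha_peptide, row$donor_site, row$donor_site)
    delta <- monoisotopic_mass(partner) + eliminylation_delta(donor_res) +
      if (label_state == "heavy") label_18O_shift(1) else 0
    name <- sprintf("XLmod:%s@%s%d:%s%s", row$beta_peptide,
                    row$alpha_accession, row$alpha_protein_site,
                    donor_res,
                    if (label_state == "heavy") "[heavy]" else "")
    mod <- modification(name, "conjugate", donor_res, delta_mass = delta)
    mod$site_specific <- list(accession = row$alpha_accession,
                              protein_pos = row$alpha_protein_site)
    mod_db[[name]] <- mod
  }
  mod_db
}
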