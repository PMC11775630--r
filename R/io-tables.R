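# Tab-separated identification tables with fixed, documented column
# orders.  Peptidoform modifications are serialized as
# "pos:name,pos:name" against the modification registry, and the heavy
# C-terminus as an integer 18-O atom count, so records survive a round
# trip exactly.

PSM_COLUMNS <- c("spectrum_id", "run_id", "specimen_id", "group",
                 "accession", "start", "peptide", "mods", "c_term_heavy_O",
                 "score", "q_value", "mass_error_ppm", "intensity")

CSM_COLUMNS <- c("spectrum_id", "run_id", "label_state",
                 "alpha_peptide", "alpha_mods", "alpha_accession",
                 "alpha_protein_site",
                 "beta_peptide", "beta_mods", "beta_accession",
                 "beta_protein_site",
                 "donor_site", "acceptor_site", "chemistry",
                 "precursor_mass", "rt", "score", "q_value",
                 "mass_error_ppm", "link_class")

#' Serialize / parse site-modification strings
#'
#' `encode_mods()` turns a peptidoform's site-modification list into a
#' `"pos:name,pos:name"` string; `decode_mods()` reverses it against a
#' modification registry.
#' @param p A [peptidoform()].
#' @return A character scalar (empty when unmodified).
#' @export
encode_mods <- function(p) {
  if (length(p$site_mods) == 0) return("")
  paste(sprintf("%s:%s", names(p$site_mods),
                vapply(p$site_mods, `[[`, character(1), "name")),
        collapse = ",")
}

#' @rdname encode_mods
#' @param sequence Peptide sequence.
#' @param mods_string Serialized modification string.
#' @param c_term_heavy_O 18-O atom count at the C-terminus.
#' @param registry Named list of modifications, e.g.
#'   [built_in_modifications()].
#' @export
decode_peptidoform <- function(sequence, mods_string = "",
                               c_term_heavy_O = 0L,
                               registry = built_in_modifications()) {
  site_mods <- list()
  if (!is.na(mods_string) && nzchar(mods_string)) {
    for (tok in strsplit(mods_string, ",", fixed = TRUE)[[1]]) {
      pos <- sub(":.*$", "", tok)
      name <- sub("^[0-9]+:", "", tok)  # mod names may contain colons
      m <- registry[[name]]
      if (is.null(m)) stop("modification not in registry: ", name)
      site_mods[[pos]] <- m
    }
  }
  peptidoform(sequence, site_mods, c_term_heavy_O)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " table lacks column(s): ", paste(missing, collapse = ", "))
  df[, cols, drop = FALSE]
}

#' Read and write PSM / CSM / site tables
#'
#' Peptide-spectrum matches, crosslink-spectrum matches and eliminylation
#' sites are exchanged as TSV with fixed column orders (`PSM_COLUMNS`,
#' `CSM_COLUMNS`); re-reading reproduces the records exactly.
#' @param psms,csms,sites data.frame in the documented column layout.
#' @param path File path.
#' @return The data.frame (readers) or `path` invisibly (writers).
#' @export
write_psms <- function(psms, path) {
  utils::write.table(check_columns(psms, PSM_COLUMNS, "PSM"), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psms
#' @export
read_psms <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(mods = "character",
                                         spectrum_id = "character",
                                         specimen_id = "character"))
  df$mods[is.na(df$mods)] <- ""
  check_columns(df, PSM_COLUMNS, "PSM")
}

#' @rdname write_psms
#' @export
write_csms <- function(csms, path) {
  utils::write.table(check_columns(csms, CSM_COLUMNS, "CSM"), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psms
#' @export
read_csms <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(alpha_mods = "character",
                                         beta_mods = "character",
                                         spectrum_id = "character"))
  df$alpha_mods[is.na(df$alpha_mods)] <- ""
  df$beta_mods[is.na(df$beta_mods)] <- ""
  check_columns(df, CSM_COLUMNS, "CSM")
}

#' @rdname write_psms
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_psms
#' @export
read_sites <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
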