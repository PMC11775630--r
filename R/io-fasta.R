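#' Read a protein FASTA file
#'
#' Parsing is delegated to Biostrings; the first whitespace-delimited token
#' of each header is the accession, the remainder the description.
#' Accessions must be unique.
#' @param path Path to a FASTA file.
#' @return data.frame with columns `accession`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(accession = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  seqs <- Biostrings::readAAStringSet(path)
  if (any(Biostrings::width(seqs) == 0))
    stop("malformed FASTA: header without sequence in ", path)
  headers <- names(seqs)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(accession))
    stop("duplicate accession(s): ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  data.frame(accession = accession, description = description,
             sequence = toupper(as.character(seqs)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write protein records to FASTA
#' @param records data.frame with `accession`, `description`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("accession", "sequence") %in% names(records)))
  if (anyDuplicated(records$accession))
    stop("duplicate accession(s) in records")
  seqs <- Biostrings::AAStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description else ""
  names(seqs) <- ifelse(nzchar(desc),
                        paste(records$accession, desc), records$accession)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
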