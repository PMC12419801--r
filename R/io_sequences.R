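#' Read family-tagged protein sequences
#'
#' Combines a FASTA file with a family-assignment TSV (columns
#' `sequence_id`, `family_id`) into the sequence-record table used by the
#' propensity functions.
#'
#' @param fasta_path Protein FASTA file.
#' @param family_path Family assignment TSV. Sequences absent from the
#'   table are dropped with a message; table entries without a sequence
#'   raise an error.
#' @return Data frame with columns `sequence_id`, `family_id`, `residues`.
#' @export
read_family_fasta <- function(fasta_path, family_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  fam <- read_fc_tsv(family_path, required = c("sequence_id", "family_id"))
  missing <- setdiff(fam$sequence_id, ids)
  fc_assert(length(missing) == 0L,
            sprintf("family table references absent sequence(s): %s",
                    paste(utils::head(missing, 5), collapse = ", ")),
            class = "famcontext_format_error")
  unassigned <- setdiff(ids, fam$sequence_id)
  if (length(unassigned) > 0L) {
    message(sprintf("dropping %d sequence(s) without family assignment",
                    length(unassigned)))
  }
  idx <- match(fam$sequence_id, ids)
  out <- data.frame(sequence_id = fam$sequence_id,
                    family_id = fam$family_id,
                    residues = unname(as.character(seqs[idx])),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write family-tagged sequences as FASTA plus family TSV
#'
#' @param records Data frame with `sequence_id`, `family_id`, `residues`.
#' @param fasta_path Output FASTA path.
#' @param family_path Output family TSV path.
#' @return Invisibly, a list with both paths.
#' @export
write_family_fasta <- function(records, fasta_path, family_path) {
  fc_assert(all(c("sequence_id", "family_id", "residues") %in% names(records)),
            "records needs columns sequence_id, family_id, residues")
  fc_assert(!anyDuplicated(records$sequence_id), "duplicate sequence_id")
  seqs <- Biostrings::AAStringSet(records$residues)
  names(seqs) <- records$sequence_id
  Biostrings::writeXStringSet(seqs, fasta_path, width = 60L)
  write_fc_tsv(records[, c("sequence_id", "family_id")], family_path)
  invisible(list(fasta = fasta_path, families = family_path))
}
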