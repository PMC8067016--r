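#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readBStringSet()] keeping sequences as
#' plain uppercase character strings, which is the representation the
#' aligner and simulators use.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences; names are the full FASTA
#'   headers (id plus any `key=value` tags).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- names(ss)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width (columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a labelled 16S reference FASTA
#'
#' Headers carry the group label as `>ref_id group=<label>`.
#'
#' @param path path to the reference FASTA.
#' @return data.frame with columns `ref_id`, `group`, `sequence`.
#' @export
read_refdb <- function(path) {
  seqs <- read_fasta(path)
  headers <- names(seqs)
  ref_id <- sub("\\s.*$", "", headers)
  group <- ifelse(grepl("group=", headers),
                  sub(".*group=(\\S+).*", "\\1", headers),
                  NA_character_)
  if (anyNA(group)) {
    stop("reference headers without a group= tag: ",
         paste(ref_id[is.na(group)], collapse = ", "))
  }
  data.frame(ref_id = ref_id, group = group, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a labelled 16S reference FASTA
#'
#' @param refdb data.frame with columns `ref_id`, `group`, `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_refdb <- function(refdb, path) {
  seqs <- refdb$sequence
  names(seqs) <- paste0(refdb$ref_id, " group=", refdb$group)
  write_fasta(seqs, path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
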