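## Wildcard protein-motif scanning.
##
## The default pattern is the conserved catalytic motif of
## glycoside-hydrolase chitinases, DXXDXDXE, where X matches any of the
## 20 standard amino acids. Matching is implemented as a direct
## positional comparison (not via regular expressions, which serve as
## the independent oracle in the test suite).

#' Scan proteins for a wildcard motif
#'
#' Reports every match, including overlapping ones, sorted by
#' (protein id, start). `X` in the pattern matches any standard
#' residue; non-standard residues (B, Z, U, `*`, ...) match neither a
#' literal nor `X`.
#'
#' @param proteins named character vector of uppercase protein
#'   sequences (or a FASTA path, read via [read_fasta()]).
#' @param pattern wildcard pattern over the 20 amino-acid letters and
#'   `X`.
#' @return data.frame `protein_id`, `start` (0-based), `end` (0-based
#'   half-open), `match` (the matched substring).
#' @export
scan_motif <- function(proteins, pattern = "DXXDXDXE") {
  if (!nzchar(pattern)) stop("empty motif pattern")
  if (length(proteins) == 1 && is.null(names(proteins)) &&
      nchar(proteins) < 1000 && file.exists(proteins)) {
    proteins <- read_fasta(proteins)
  }
  pat <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  m <- length(pat)
  standard <- AA_LETTERS
  hits <- lapply(seq_along(proteins), function(i) {
    seq <- proteins[[i]]
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    L <- length(chars)
    if (L < m) return(NULL)
    ok <- rep(TRUE, L - m + 1L)
    for (j in seq_len(m)) {
      cj <- chars[j:(L - m + j)]
      ok <- ok & if (pat[j] == "X") cj %in% standard else cj == pat[j]
    }
    starts <- which(ok)
    if (length(starts) == 0) return(NULL)
    data.frame(
      protein_id = names(proteins)[i] %||% as.character(i),
      start = starts - 1L,
      end = starts - 1L + m,
      match = substring(seq, starts, starts + m - 1L),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), match = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$protein_id, out$start), , drop = FALSE]
}
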