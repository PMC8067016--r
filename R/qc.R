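## Genome quality gate and k-mer ANI dereplication.
##
## QC thresholds follow the study's selection standard for medium- and
## high-quality genomes: completeness strictly above 70%, contamination
## strictly below 10%, and at least 22 conserved proteins. Redundant
## genomes at >= 98.5% average nucleotide identity are collapsed to one
## representative.

#' QC and dereplication thresholds
#'
#' @param min_completeness completeness must be strictly greater than
#'   this (percent).
#' @param max_contamination contamination must be strictly less than
#'   this (percent).
#' @param min_conserved minimum number of conserved proteins
#'   (inclusive).
#' @param ani_dedup ANI at or above which two genomes are treated as
#'   redundant (fraction).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_completeness = 70, max_contamination = 10,
                          min_conserved = 22, ani_dedup = 0.985) {
  stopifnot(min_completeness > 0, max_contamination > 0,
            min_conserved > 0, ani_dedup > 0)
  structure(list(min_completeness = min_completeness,
                 max_contamination = max_contamination,
                 min_conserved = min_conserved,
                 ani_dedup = ani_dedup),
            class = "qc_thresholds")
}

#' Filter genomes on completeness, contamination and conserved proteins
#'
#' A genome passes when completeness > 70 (strict), contamination < 10
#' (strict) and the conserved-protein count is at least 22, under the
#' default thresholds. Input order is preserved.
#'
#' @param genomes data.frame of genome metadata with columns
#'   `genome_id`, `completeness`, `contamination`, `n_conserved`.
#' @param t a [qc_thresholds()].
#' @return character vector of passing genome ids, in input order.
#' @export
qc_filter <- function(genomes, t = qc_thresholds()) {
  for (field in c("completeness", "contamination", "n_conserved")) {
    if (!field %in% names(genomes)) {
      stop("metadata is missing QC field: ", field)
    }
    bad <- is.na(genomes[[field]])
    if (any(bad)) {
      stop("missing ", field, " for genome ",
           genomes$genome_id[which(bad)[1]])
    }
  }
  keep <- genomes$completeness > t$min_completeness &
    genomes$contamination < t$max_contamination &
    genomes$n_conserved >= t$min_conserved
  genomes$genome_id[keep]
}

# canonical k-mer set: lexicographic min of each k-mer and its reverse
# complement; windows containing N are skipped
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) stop("sequence shorter than k-mer size ", k)
  starts <- seq_len(n - k + 1L)
  fwd <- substring(seq, starts, starts + k - 1L)
  rcseq <- revcomp(seq)
  # k-mer starting at i on the forward strand is the reverse complement
  # of the k-mer starting at n - k - i + 2 on the reverse strand
  rc <- substring(rcseq, starts, starts + k - 1L)[rev(seq_along(starts))]
  keep <- !grepl("N", fwd, fixed = TRUE)
  unique(pmin(fwd[keep], rc[keep]))
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

#' Estimate ANI from canonical k-mer Jaccard similarity
#'
#' Computes the Jaccard index J of the canonical k-mer sets of the two
#' sequences and transforms it to an ANI estimate with the Mash
#' distance formula: `ani = 1 + (1/k) * log(2J / (1 + J))`, clamped to
#' \[0, 1\]. When the k-mer sets are disjoint (J = 0) the ANI is
#' undefined and returned as `NA`.
#'
#' @param seqA,seqB DNA sequences over A/C/G/T/N, each of length >= k.
#' @param k k-mer size (default 16).
#' @return an `ani_result` list: `jaccard`, `ani` (`NA` when
#'   undefined), `k`.
#' @export
estimate_ani <- function(seqA, seqB, k = 16L) {
  ka <- canonical_kmers(toupper(seqA), k)
  kb <- canonical_kmers(toupper(seqB), k)
  inter <- length(intersect(ka, kb))
  uni <- length(ka) + length(kb) - inter
  j <- if (uni == 0) 0 else inter / uni
  ani <- if (j == 0) NA_real_ else
    min(1, max(0, 1 + log(2 * j / (1 + j)) / k))
  structure(list(jaccard = j, ani = ani, k = as.integer(k)),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("k-mer ANI estimate (k = %d): J = %.4f, ANI = %s\n",
              x$k, x$jaccard,
              if (is.na(x$ani)) "undefined" else sprintf("%.4f", x$ani)))
  invisible(x)
}

# union-find over n elements
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Dereplicate genomes by single-linkage ANI clustering
#'
#' Pairs at ANI >= `t$ani_dedup` (default 0.985) are linked;
#' single-linkage connected components form clusters. Each cluster is
#' represented by its highest-completeness genome, ties broken by lower
#' contamination, then by lexicographically smaller genome id. The
#' result is invariant to input ordering.
#'
#' @param genomes metadata data.frame (must include `genome_id`,
#'   `completeness`, `contamination` for the representative rule).
#' @param sequences named character vector of genome sequences, one per
#'   genome id.
#' @param t a [qc_thresholds()].
#' @param k k-mer size passed to [estimate_ani()].
#' @return list with `representatives` (character vector) and
#'   `clusters` (data.frame `genome_id`, `representative`) and `ani`
#'   (data.frame of all pairwise comparisons).
#' @export
dedup <- function(genomes, sequences, t = qc_thresholds(), k = 16L) {
  ids <- sort(genomes$genome_id)
  missing <- setdiff(ids, names(sequences))
  if (length(missing)) {
    stop("missing sequence for genome: ", paste(missing, collapse = ", "))
  }
  n <- length(ids)
  parent <- uf_new(n)
  pairs <- list()
  if (n >= 2) {
    kmers <- lapply(ids, function(id) canonical_kmers(sequences[[id]], k))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        inter <- length(intersect(kmers[[i]], kmers[[j]]))
        uni <- length(kmers[[i]]) + length(kmers[[j]]) - inter
        jac <- if (uni == 0) 0 else inter / uni
        ani <- if (jac == 0) NA_real_ else
          min(1, max(0, 1 + log(2 * jac / (1 + jac)) / k))
        pairs[[length(pairs) + 1L]] <-
          data.frame(genome_a = ids[i], genome_b = ids[j],
                     jaccard = jac, ani = ani, stringsAsFactors = FALSE)
        if (!is.na(ani) && ani >= t$ani_dedup) {
          ri <- uf_find(parent, i); rj <- uf_find(parent, j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  meta <- genomes[match(ids, genomes$genome_id), , drop = FALSE]
  rep_of <- character(n)
  for (r in unique(roots)) {
    members <- which(roots == r)
    o <- order(-meta$completeness[members],
               meta$contamination[members],
               meta$genome_id[members])
    rep_of[members] <- ids[members[o[1]]]
  }
  list(
    representatives = sort(unique(rep_of)),
    clusters = data.frame(genome_id = ids, representative = rep_of,
                          stringsAsFactors = FALSE),
    ani = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(genome_a = character(), genome_b = character(),
                 jaccard = numeric(), ani = numeric(),
                 stringsAsFactors = FALSE)
  )
}
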