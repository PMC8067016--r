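## 16S miTag classification and depth-stratified abundance profiling.
##
## Reads are assigned to the four Bdellovibrionota groups by a seeded
## banded semi-global aligner (read end-to-end, reference overhangs
## free), keeping only miTags longer than 100 bp with > 97% identity to
## their best reference. Relative abundance is the percentage of
## assigned miTags among all 16S miTags of the sample; layers are
## compared with Welch's t-test.

#' Alignment and filtering configuration for miTag classification
#'
#' Defaults follow the study's filters: reads must be longer than
#' 100 bp (strict) and match a reference at more than 97% identity
#' (strict). The raw-score floor replaces a BLAST E-value cutoff: at
#' the identity and length this pipeline accepts, any reportable hit is
#' far above it.
#'
#' @param min_read_len reads of this length or shorter are unassigned
#'   (bp, strict >).
#' @param min_identity identity must be strictly greater than this
#'   (fraction; identity = matches / aligned columns, gap columns
#'   included).
#' @param k_seed seed k-mer length triggering alignment.
#' @param match,mismatch match/mismatch scores.
#' @param gap_open,gap_ext gap penalties (positive); a gap of length L
#'   costs `gap_open + gap_ext * (L - 1)`.
#' @param min_score minimum alignment score for a reportable hit.
#' @param band half-width of the alignment band around seed diagonals.
#' @return a `match_config` list.
#' @export
match_config <- function(min_read_len = 100L, min_identity = 0.97,
                         k_seed = 12L, match = 2L, mismatch = -3L,
                         gap_open = 5L, gap_ext = 2L, min_score = 60L,
                         band = 12L) {
  stopifnot(min_read_len > 0, min_identity > 0, k_seed > 0,
            k_seed <= 15, gap_open > 0, gap_ext > 0, min_score > 0)
  structure(list(min_read_len = as.integer(min_read_len),
                 min_identity = min_identity, k_seed = as.integer(k_seed),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_ext = as.integer(gap_ext),
                 min_score = as.integer(min_score),
                 band = as.integer(band)),
            class = "match_config")
}

#' Align one read against one reference
#'
#' Seed-and-extend banded semi-global alignment: a shared `k_seed`-mer
#' triggers affine-gap dynamic programming in a band around the seed
#' diagonals; the read is aligned end-to-end while reference overhangs
#' are free. Returns the maximal-score alignment, or `NULL` when no
#' seed is shared or the best score is below `cfg$min_score`. The
#' forward read only is aligned here; strand handling lives in
#' [classify_read()].
#'
#' @param read,ref DNA sequences over A/C/G/T/N.
#' @param cfg a [match_config()].
#' @return a list (`score`, `identity`, `aln_len`, `matches`,
#'   `ref_start`, `ref_end`) or `NULL`.
#' @export
align_read <- function(read, ref, cfg = match_config()) {
  if (!nzchar(read)) stop("empty read")
  a <- .align_one_cpp(toupper(read), toupper(ref), cfg$k_seed,
                      cfg$match, cfg$mismatch, cfg$gap_open,
                      cfg$gap_ext, cfg$band)
  if (!a$found || a$score < cfg$min_score) return(NULL)
  list(score = a$score, identity = a$matches / a$aln_len,
       aln_len = a$aln_len, matches = a$matches,
       ref_start = a$ref_start, ref_end = a$ref_end)
}

# batch classification core shared by classify_read / profile_sample;
# refs sorted by ref_id so C++ tie-breaks are lexicographic
classify_core <- function(reads, refdb, cfg) {
  refdb <- refdb[order(refdb$ref_id), , drop = FALSE]
  group <- rep("unassigned", length(reads))
  eligible <- nchar(reads) > cfg$min_read_len
  if (any(eligible)) {
    hits <- .classify_batch_cpp(unname(toupper(reads[eligible])),
                                refdb$sequence, cfg$k_seed, cfg$match,
                                cfg$mismatch, cfg$gap_open, cfg$gap_ext,
                                cfg$band, cfg$min_score)
    identity <- hits$matches / hits$aln_len
    ok <- hits$ref_index > 0 & !is.na(identity) &
      identity > cfg$min_identity
    assigned <- rep("unassigned", nrow(hits))
    assigned[ok] <- refdb$group[hits$ref_index[ok]]
    group[eligible] <- assigned
    hits_df <- data.frame(
      read_id = names(reads)[eligible] %||% which(eligible),
      ref_id = ifelse(hits$ref_index > 0, refdb$ref_id[hits$ref_index],
                      NA_character_),
      identity = identity, aln_len = hits$aln_len, score = hits$score,
      group = assigned, stringsAsFactors = FALSE)
  } else {
    hits_df <- data.frame(read_id = character(), ref_id = character(),
                          identity = numeric(), aln_len = integer(),
                          score = integer(), group = character(),
                          stringsAsFactors = FALSE)
  }
  list(group = group, hits = hits_df)
}

#' Classify one read against a labelled reference set
#'
#' Reads of length <= 100 bp are unassigned. Otherwise the best hit
#' over all references and both strands is taken (ties: higher
#' identity, then longer alignment, then lexicographically smaller
#' reference id); the read is assigned to the best reference's group
#' only when identity exceeds 0.97 (strict).
#'
#' @param read DNA sequence.
#' @param refdb data.frame with `ref_id`, `group`, `sequence`.
#' @param cfg a [match_config()].
#' @return group label, or `"unassigned"`.
#' @export
classify_read <- function(read, refdb, cfg = match_config()) {
  stopifnot(nrow(refdb) > 0)
  classify_core(stats::setNames(read, "read"), refdb, cfg)$group
}

#' Assign an ocean depth to a vertical layer
#'
#' Half-open layers: epipelagic \[0, 200) m, mesopelagic \[200, 1000) m,
#' deep \[1000, Inf) m. 1000 m falls in the deep layer, matching a
#' trench data set defined as >= 1000 m.
#'
#' @param depth_m depth in meters, >= 0 (vectorized).
#' @return character vector of layer labels.
#' @export
assign_layer <- function(depth_m) {
  if (any(depth_m < 0)) stop("depth must be non-negative")
  ifelse(depth_m < 200, "epipelagic",
         ifelse(depth_m < 1000, "mesopelagic", "deep"))
}

#' Profile one miTag sample
#'
#' Classifies every read and reports, per group, 100 x (assigned read
#' count) / total 16S miTags in the sample.
#'
#' @param sample list with `sample_id`, `depth_m`, `total_mitags` and
#'   `reads` (named character vector), as produced by
#'   [simulate_mitags()] or read from a sample sheet.
#' @param refdb labelled reference data.frame.
#' @param cfg a [match_config()].
#' @return an `abundance_profile`: list with `sample_id`, `depth_m`,
#'   `layer`, `abundance` (named percent vector over the four groups)
#'   and `hits` (per-read hit table).
#' @export
profile_sample <- function(sample, refdb, cfg = match_config()) {
  if (is.null(sample$total_mitags) || sample$total_mitags <= 0) {
    stop("total_mitags must be positive")
  }
  cls <- classify_core(sample$reads, refdb, cfg)
  groups <- sort(unique(refdb$group))
  counts <- vapply(groups, function(g) sum(cls$group == g), numeric(1))
  structure(list(sample_id = sample$sample_id,
                 depth_m = sample$depth_m,
                 layer = assign_layer(sample$depth_m),
                 abundance = 100 * counts / sample$total_mitags,
                 hits = cls$hits),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("miTag profile %s (%.0f m, %s)\n", x$sample_id,
              x$depth_m, x$layer))
  for (g in names(x$abundance)) {
    cat(sprintf("  %-16s %6.3f %%\n", g, x$abundance[[g]]))
  }
  invisible(x)
}

#' Collect abundance profiles into one table
#'
#' @param profiles list of `abundance_profile` objects.
#' @return data.frame with `sample_id`, `depth_m`, `layer` and one
#'   abundance column (percent) per group.
#' @export
profile_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    cbind(data.frame(sample_id = p$sample_id, depth_m = p$depth_m,
                     layer = p$layer, stringsAsFactors = FALSE),
          as.data.frame(as.list(p$abundance), check.names = FALSE))
  }))
}

#' Compare one group's abundance between two depth layers
#'
#' Welch's unequal-variance two-sided t-test on per-sample relative
#' abundances, annotated `****` below p = 1e-4 and `*` below p = 0.05.
#'
#' @param profiles data.frame from [profile_table()] (or a list of
#'   profiles, converted internally).
#' @param group group column to compare.
#' @param layerA,layerB layer labels.
#' @return list with `statistic`, `p_value`, `significance`.
#' @export
compare_layers <- function(profiles, group, layerA, layerB) {
  if (!is.data.frame(profiles)) profiles <- profile_table(profiles)
  a <- profiles[profiles$layer == layerA, group]
  b <- profiles[profiles$layer == layerB, group]
  if (length(a) < 2 || length(b) < 2) {
    stop("each layer needs at least 2 samples")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: constant within both layers
    if (mean(a) == mean(b)) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- list(statistic = sign(mean(a) - mean(b)) * Inf, p.value = 0)
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  sig <- if (tt$p.value < 1e-4) "****" else
    if (tt$p.value < 0.05) "*" else "ns"
  list(statistic = tt$statistic, p_value = tt$p.value,
       significance = sig)
}
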