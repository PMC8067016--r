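## Presence/absence and copy-number analytics over KEGG/COG/MEROPS/CAZy
## annotations: group-level presence ("at least 50% of a group's
## genomes"), group-specific calling ("more than 50% in exactly one
## group"), marine-enrichment percentages, peptidase Venn partitions,
## CAZy class profiles, environment-source tallies and Wilcoxon
## copy-number tests. The two 50% rules are deliberately different:
## group-level presence is inclusive (>= 0.5), specificity is strict
## (> 0.5).

#' Build a presence/copy-number matrix from a long annotation table
#'
#' @param annotations data.frame with columns `genome_id`, `namespace`
#'   (KEGG, COG, MEROPS or CAZy), `gene_id`, `copies`; duplicate
#'   (genome, gene) rows are summed.
#' @param genome_ids optional character vector of genome ids to include
#'   as columns even when they have no annotation (e.g. all genomes of
#'   the metadata table); defaults to the genomes observed.
#' @return a `presence_matrix`: list with `copies` (genes x genomes
#'   integer matrix), `presence` (logical, `copies > 0`) and
#'   `namespace` (named character per gene).
#' @export
build_presence_matrix <- function(annotations, genome_ids = NULL) {
  stopifnot(all(c("genome_id", "namespace", "gene_id", "copies") %in%
                  names(annotations)))
  if (nrow(annotations) > 0 && any(annotations$copies < 0)) {
    stop("negative copy number in annotation table")
  }
  genomes <- genome_ids %||% sort(unique(annotations$genome_id))
  genes <- sort(unique(annotations$gene_id))
  copies <- matrix(0L, nrow = length(genes), ncol = length(genomes),
                   dimnames = list(genes, genomes))
  if (nrow(annotations) > 0) {
    unknown <- setdiff(annotations$genome_id, genomes)
    if (length(unknown)) {
      stop("annotation rows reference unknown genomes: ",
           paste(unknown, collapse = ", "))
    }
    agg <- stats::aggregate(copies ~ gene_id + genome_id,
                            data = annotations, FUN = sum)
    copies[cbind(match(agg$gene_id, genes),
                 match(agg$genome_id, genomes))] <- as.integer(agg$copies)
  }
  ns <- character(length(genes))
  names(ns) <- genes
  if (nrow(annotations) > 0) {
    ns[annotations$gene_id] <- annotations$namespace
  }
  structure(list(copies = copies, presence = copies > 0L,
                 namespace = ns),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence matrix: %d genes x %d genomes (%s)\n",
              nrow(x$copies), ncol(x$copies),
              paste(names(table(x$namespace)), collapse = ", ")))
  invisible(x)
}

#' Serialize / rebuild a presence matrix as a long-form TSV
#'
#' `presence_to_long()` emits one row per present (gene, genome) pair;
#' [build_presence_matrix()] on that table (with the same genome set)
#' reproduces the matrix exactly.
#'
#' @param m a `presence_matrix`.
#' @return data.frame `genome_id`, `namespace`, `gene_id`, `copies`.
#' @export
presence_to_long <- function(m) {
  idx <- which(m$copies > 0L, arr.ind = TRUE)
  out <- data.frame(
    genome_id = colnames(m$copies)[idx[, 2]],
    namespace = unname(m$namespace[rownames(m$copies)[idx[, 1]]]),
    gene_id = rownames(m$copies)[idx[, 1]],
    copies = m$copies[idx],
    stringsAsFactors = FALSE)
  out[order(out$genome_id, out$gene_id), , drop = FALSE]
}

group_sizes_from_meta <- function(meta) {
  stopifnot(!anyNA(meta$group))
  table(meta$group)
}

#' Per-group presence fractions
#'
#' For every gene and group, the exact fraction of the group's genomes
#' carrying the gene, with the group-level presence flag at
#' fraction >= 0.5 (inclusive: "at least 50%").
#'
#' @param m a `presence_matrix`.
#' @param meta metadata data.frame with `genome_id` and `group`.
#' @return data.frame `gene_id`, `namespace`, `group`, `n_present`,
#'   `n_group`, `fraction`, `present` (group-level flag).
#' @export
group_presence <- function(m, meta) {
  meta <- meta[meta$genome_id %in% colnames(m$copies), , drop = FALSE]
  if (anyNA(meta$group)) stop("genomes with NA group label")
  groups <- unique(meta$group)
  empty <- vapply(groups, function(g) {
    sum(meta$group == g) == 0
  }, logical(1))
  if (any(empty)) stop("empty group: ", paste(groups[empty], collapse = ", "))
  out <- lapply(groups, function(g) {
    ids <- meta$genome_id[meta$group == g]
    n_present <- rowSums(m$presence[, ids, drop = FALSE])
    ng <- nrow(m$copies)
    data.frame(gene_id = rownames(m$copies) %||% character(0),
               namespace = unname(m$namespace),
               group = rep(g, ng),
               n_present = unname(n_present),
               n_group = rep(length(ids), ng),
               fraction = unname(n_present) / length(ids),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$present <- out$fraction >= 0.5
  out[order(out$gene_id, out$group), , drop = FALSE]
}

#' Call a gene group-specific
#'
#' A gene is specific to a group when that group's presence fraction is
#' strictly above 0.5 ("more than 50%") and every other group's
#' fraction is at or below 0.5. Returns `NA` when no group, or more
#' than one, exceeds the threshold.
#'
#' @param gp data.frame from [group_presence()].
#' @param gene gene id to call.
#' @return the group label, or `NA_character_`.
#' @export
call_group_specific <- function(gp, gene) {
  rows <- gp[gp$gene_id == gene, , drop = FALSE]
  over <- rows$group[rows$fraction > 0.5]
  if (length(over) == 1) over else NA_character_
}

#' Count group-specific genes per group within a namespace
#'
#' @param m a `presence_matrix`.
#' @param meta metadata with `genome_id` and `group`.
#' @param namespace `"KEGG"` or `"COG"`.
#' @return named integer vector, one count per group in `meta`.
#' @export
count_group_specific <- function(m, meta, namespace = "KEGG") {
  stopifnot(namespace %in% c("KEGG", "COG"))
  gp <- group_presence(m, meta)
  gp <- gp[gp$namespace == namespace, , drop = FALSE]
  groups <- unique(meta$group)
  counts <- stats::setNames(integer(length(groups)), groups)
  for (gene in unique(gp$gene_id)) {
    lab <- call_group_specific(gp, gene)
    if (!is.na(lab)) counts[lab] <- counts[lab] + 1L
  }
  counts
}

#' Marine-enrichment table for one group
#'
#' Splits the group's genomes into marine and non-marine by their
#' environment source and reports, per gene, the presence percentage on
#' each side (2-decimal, half-away-from-zero), with the underlying
#' counts. When one side has no genomes its percentage is `NA` and the
#' row is flagged. Rows are sorted by marine percentage, descending.
#'
#' @param m a `presence_matrix`.
#' @param meta metadata with `genome_id`, `group`, `environment`.
#' @param group group to tabulate.
#' @param namespace optional namespace filter (e.g. `"KEGG"`).
#' @return data.frame `gene_id`, `group`, `marine_n`, `nonmarine_n`,
#'   `marine_present`, `nonmarine_present`, `marine_pct`,
#'   `nonmarine_pct`, `undefined_side`.
#' @export
enrichment_table <- function(m, meta, group, namespace = NULL) {
  gm <- meta[meta$group == group, , drop = FALSE]
  if (nrow(gm) == 0) stop("unknown group: ", group)
  mar <- gm$genome_id[is_marine(gm$environment)]
  non <- gm$genome_id[!is_marine(gm$environment)]
  keep <- rep(TRUE, nrow(m$copies))
  if (!is.null(namespace)) keep <- m$namespace == namespace
  genes <- (rownames(m$copies) %||% character(0))[keep]
  pres <- m$presence[keep, , drop = FALSE]
  mp <- rowSums(pres[, mar, drop = FALSE])
  np <- rowSums(pres[, non, drop = FALSE])
  pct <- function(cnt, n) {
    if (n == 0) rep(NA_real_, length(cnt)) else
      round_half_away(100 * cnt / n, 2)
  }
  ng <- length(genes)
  out <- data.frame(
    gene_id = genes, group = rep(group, ng),
    marine_n = rep(length(mar), ng), nonmarine_n = rep(length(non), ng),
    marine_present = unname(mp), nonmarine_present = unname(np),
    marine_pct = unname(pct(mp, length(mar))),
    nonmarine_pct = unname(pct(np, length(non))),
    undefined_side = rep(length(mar) == 0 || length(non) == 0, ng),
    stringsAsFactors = FALSE)
  out[order(-xtfrm(out$marine_pct), out$gene_id), , drop = FALSE]
}

#' Two-sample Wilcoxon rank-sum test on copy-number vectors
#'
#' Midrank tie handling; the exact null distribution is used when
#' `min(nA, nB) <= 8` and there are no ties, otherwise the normal
#' approximation with continuity and tie correction. Raw p-values can
#' be adjusted downstream with Benjamini-Hochberg via
#' [copy_tests_by_gene()].
#'
#' @param copiesA,copiesB non-empty numeric vectors of per-genome copy
#'   numbers.
#' @return list with `W` (rank-sum statistic of the first sample) and
#'   `p_value` (two-sided).
#' @export
wilcoxon_copy_test <- function(copiesA, copiesB) {
  if (length(copiesA) == 0 || length(copiesB) == 0) {
    stop("copy-number vectors must be non-empty")
  }
  ties <- any(duplicated(c(copiesA, copiesB)))
  exact <- min(length(copiesA), length(copiesB)) <= 8 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(copiesA, copiesB, exact = exact, correct = TRUE))
  list(W = unname(ht$statistic), p_value = ht$p.value)
}

#' Per-gene Wilcoxon copy-number comparison between two groups
#'
#' @param m a `presence_matrix`.
#' @param meta metadata with `genome_id` and `group`.
#' @param groupA,groupB groups to compare.
#' @return data.frame `gene_id`, `W`, `p_value`, `p_adjusted`
#'   (Benjamini-Hochberg).
#' @export
copy_tests_by_gene <- function(m, meta, groupA, groupB) {
  ia <- meta$genome_id[meta$group == groupA]
  ib <- meta$genome_id[meta$group == groupB]
  if (length(ia) == 0 || length(ib) == 0) stop("empty group")
  res <- lapply(rownames(m$copies), function(g) {
    wt <- wilcoxon_copy_test(m$copies[g, ia], m$copies[g, ib])
    data.frame(gene_id = g, W = wt$W, p_value = wt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Venn partition of MEROPS peptidase families across the four groups
#'
#' A group "has" a family under the inclusive >= 50% group-level rule;
#' each family with a non-empty group signature falls into exactly one
#' of the 15 region combinations.
#'
#' @param m a `presence_matrix` containing MEROPS-namespace genes.
#' @param meta metadata with `genome_id` and `group`.
#' @return a `venn_partition`: list with `regions` (named list of
#'   family-id vectors, names like `"Oligoflexia+Bdello-group2"`) and
#'   `counts` (named integer vector over the 15 regions).
#' @export
peptidase_venn <- function(m, meta) {
  gp <- group_presence(m, meta)
  gp <- gp[gp$namespace == "MEROPS" & gp$present, , drop = FALSE]
  groups <- intersect(BDELLO_GROUPS, unique(meta$group))
  sets <- lapply(groups, function(g) gp$gene_id[gp$group == g])
  names(sets) <- groups
  fams <- sort(unique(unlist(sets)))
  signature <- vapply(fams, function(f) {
    paste(groups[vapply(sets, function(s) f %in% s, logical(1))],
          collapse = "+")
  }, character(1))
  # all 15 non-empty combinations, smallest first
  combos <- unlist(lapply(seq_along(groups), function(k) {
    apply(utils::combn(groups, k), 2, paste, collapse = "+")
  }))
  regions <- lapply(combos, function(cb) unname(fams[signature == cb]))
  names(regions) <- combos
  structure(list(regions = regions,
                 counts = vapply(regions, length, integer(1))),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("peptidase Venn partition (", sum(x$counts), " families)\n",
      sep = "")
  nz <- x$counts[x$counts > 0]
  for (r in names(nz)) cat(sprintf("  %-60s %d\n", r, nz[[r]]))
  invisible(x)
}

#' Per-group mean CAZy class counts
#'
#' The class of a CAZy gene is its leading alphabetic prefix (GH, PL,
#' GT, CE, CBM or AA). For every genome, copy numbers are summed per
#' class; the result is the per-group mean of those sums.
#' Unrecognized prefixes raise a warning and are excluded.
#'
#' @param m a `presence_matrix` containing CAZy-namespace genes.
#' @param meta metadata with `genome_id` and `group`.
#' @return matrix groups x classes of mean summed copy numbers.
#' @export
cazy_class_counts <- function(m, meta) {
  classes <- c("GH", "PL", "GT", "CE", "CBM", "AA")
  caz <- rownames(m$copies)[m$namespace == "CAZy"]
  pre <- sub("^([A-Za-z]+).*$", "\\1", caz)
  bad <- !(pre %in% classes)
  if (any(bad)) {
    warning("excluding CAZy genes with unrecognized class prefix: ",
            paste(caz[bad], collapse = ", "))
    caz <- caz[!bad]
    pre <- pre[!bad]
  }
  groups <- unique(meta$group)
  out <- matrix(0, nrow = length(groups), ncol = length(classes),
                dimnames = list(groups, classes))
  for (g in groups) {
    ids <- meta$genome_id[meta$group == g]
    for (cl in classes) {
      genes <- caz[pre == cl]
      per_genome <- colSums(m$copies[genes, ids, drop = FALSE])
      out[g, cl] <- mean(per_genome)
    }
  }
  out
}

#' Environment-source composition per group
#'
#' Percentage of each environment source within every group, 2-decimal
#' half-away-from-zero rounding; unrounded percentages sum to 100 per
#' group.
#'
#' @param meta metadata with `genome_id`, `group`, `environment`.
#' @return data.frame `group`, `environment`, `n`, `pct`.
#' @export
source_tally <- function(meta) {
  if (anyNA(meta$environment)) stop("every genome needs a source label")
  out <- lapply(unique(meta$group), function(g) {
    env <- meta$environment[meta$group == g]
    tab <- table(env)
    data.frame(group = g, environment = names(tab),
               n = as.integer(tab),
               pct = round_half_away(100 * as.integer(tab) / length(env), 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
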