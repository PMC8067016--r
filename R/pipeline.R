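## Pipeline orchestration: QC -> dedup -> compare -> profile -> scan on
## a YAML config, with a checksum manifest so identical configs yield
## byte-identical output trees.

#' Read and validate a pipeline run configuration
#'
#' The config is a flat YAML file. Recognized keys: `metadata`,
#' `annotations` (TSV paths), `fasta_dir` (genome FASTAs, enables the
#' dedup stage), `refdb` (labelled 16S FASTA) and `samples` (sample
#' sheet TSV: `sample_id`, `depth_m`, `total_mitags`, `fasta`) for the
#' profile stage, `proteins` (FASTA) and `motif` for the scan stage,
#' `out_dir`, `seed`, `stages` (named logical), plus any
#' [qc_thresholds()] or [match_config()] field under `thresholds:` /
#' `match:`.
#'
#' @param path YAML file path.
#' @return validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$out_dir <- cfg$out_dir %||% "bdellocomp_out"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  stages <- list(qc = TRUE, dedup = FALSE, compare = TRUE,
                 profile = FALSE, scan = FALSE)
  stages[names(cfg$stages %||% list())] <- cfg$stages
  cfg$stages <- stages
  cfg$thresholds <- do.call(qc_thresholds, cfg$thresholds %||% list())
  cfg$match <- do.call(match_config, cfg$match %||% list())
  cfg$motif <- cfg$motif %||% "DXXDXDXE"
  required <- c("metadata", if (stages$compare) "annotations",
                if (stages$profile) c("refdb", "samples"),
                if (stages$scan) "proteins",
                if (stages$dedup) "fasta_dir")
  for (key in required) {
    if (is.null(cfg[[key]])) stop("config is missing required key: ", key)
    if (!file.exists(cfg[[key]])) {
      stop("config path does not exist: ", key, " = ", cfg[[key]])
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the comparative-genomics pipeline
#'
#' Executes the enabled stages in dependency order (QC, dedup, compare,
#' profile, scan), writes every stage table as TSV under
#' `cfg$out_dir`, and finishes with `MANIFEST.tsv` recording the md5 of
#' every output, the input checksums, the thresholds used, the seed and
#' the package version. A failed stage leaves partial outputs plus a
#' `FAILED` marker file and raises an error.
#'
#' @param cfg a `run_config` from [read_run_config()], or a path to a
#'   YAML config.
#' @return a `run_report` list with per-stage results and the manifest
#'   path, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed, stages = list())
  inputs <- c(cfg$metadata, cfg$annotations, cfg$refdb, cfg$samples,
              cfg$proteins)
  on_fail <- function(e) {
    writeLines(conditionMessage(e), file.path(out, "FAILED"))
    stop(e)
  }
  tryCatch({
    meta <- read_tsv(cfg$metadata)

    if (isTRUE(cfg$stages$qc)) {
      message("[qc] filtering ", nrow(meta), " genomes")
      pass <- qc_filter(meta, cfg$thresholds)
      verdicts <- data.frame(
        genome_id = meta$genome_id,
        completeness = meta$completeness,
        contamination = meta$contamination,
        n_conserved = meta$n_conserved,
        pass = meta$genome_id %in% pass, stringsAsFactors = FALSE)
      write_tsv(verdicts, file.path(out, "qc_verdicts.tsv"))
      meta <- meta[meta$genome_id %in% pass, , drop = FALSE]
      report$stages$qc <- list(n_pass = length(pass), verdicts = verdicts)
    }

    if (isTRUE(cfg$stages$dedup)) {
      files <- list.files(cfg$fasta_dir, pattern = "\\.(fa|fasta|fna)$",
                          full.names = TRUE)
      seqs <- unlist(lapply(files, read_fasta))
      names(seqs) <- sub("\\s.*$", "", names(seqs))
      message("[dedup] ", length(seqs), " genome sequences")
      dd <- dedup(meta, seqs, cfg$thresholds)
      write_tsv(dd$ani, file.path(out, "ani_pairs.tsv"))
      write_tsv(dd$clusters, file.path(out, "ani_clusters.tsv"))
      meta <- meta[meta$genome_id %in% dd$representatives, , drop = FALSE]
      report$stages$dedup <- dd
    }

    if (isTRUE(cfg$stages$compare)) {
      ann <- read_tsv(cfg$annotations)
      message("[compare] ", nrow(ann), " annotation rows, ",
              length(unique(ann$gene_id)), " genes")
      m <- build_presence_matrix(ann, genome_ids = meta$genome_id)
      gp <- group_presence(m, meta)
      write_tsv(gp, file.path(out, "group_presence.tsv"))
      pm <- data.frame(gene_id = rownames(m$copies), 1L * m$presence,
                       check.names = FALSE, stringsAsFactors = FALSE)
      write_tsv(pm, file.path(out, "presence_matrix.tsv"))
      enr <- do.call(rbind, lapply(unique(meta$group), function(g) {
        enrichment_table(m, meta, g)
      }))
      write_tsv(enr, file.path(out, "enrichment.tsv"))
      st <- source_tally(meta)
      write_tsv(st, file.path(out, "source_tally.tsv"))
      venn <- NULL
      if (any(m$namespace == "MEROPS")) {
        venn <- peptidase_venn(m, meta)
        vt <- data.frame(region = names(venn$counts),
                         n_families = unname(venn$counts),
                         families = vapply(venn$regions, paste,
                                           character(1), collapse = ","),
                         stringsAsFactors = FALSE)
        write_tsv(vt, file.path(out, "peptidase_venn.tsv"))
      }
      cazy <- NULL
      if (any(m$namespace == "CAZy")) {
        cazy <- cazy_class_counts(m, meta)
        write_tsv(data.frame(group = rownames(cazy), cazy,
                             check.names = FALSE),
                  file.path(out, "cazy_classes.tsv"))
      }
      report$stages$compare <- list(n_genes = nrow(m$copies),
                                    presence = m, group_presence = gp,
                                    enrichment = enr, sources = st,
                                    venn = venn, cazy = cazy)
    }

    if (isTRUE(cfg$stages$profile)) {
      sheet <- read_tsv(cfg$samples)
      refdb <- read_refdb(cfg$refdb)
      message("[profile] ", nrow(sheet), " samples against ",
              nrow(refdb), " references")
      profiles <- lapply(seq_len(nrow(sheet)), function(i) {
        reads <- read_fasta(sheet$fasta[i])
        profile_sample(list(sample_id = sheet$sample_id[i],
                            depth_m = sheet$depth_m[i],
                            total_mitags = sheet$total_mitags[i],
                            reads = reads), refdb, cfg$match)
      })
      pt <- profile_table(profiles)
      write_tsv(pt, file.path(out, "abundance.tsv"))
      hits <- do.call(rbind, lapply(profiles, function(p) {
        cbind(sample_id = p$sample_id, p$hits)
      }))
      write_tsv(hits, file.path(out, "hits.tsv"))
      tests <- layer_tests(pt)
      if (nrow(tests)) write_tsv(tests, file.path(out, "layer_tests.tsv"))
      report$stages$profile <- list(profiles = pt, tests = tests)
    }

    if (isTRUE(cfg$stages$scan)) {
      prot <- read_fasta(cfg$proteins)
      message("[scan] ", length(prot), " proteins, motif ", cfg$motif)
      hits <- scan_motif(prot, cfg$motif)
      write_tsv(hits, file.path(out, "motif_hits.tsv"))
      report$stages$scan <- list(hits = hits)
    }
  }, error = on_fail)

  manifest <- write_manifest(out, inputs, cfg)
  report$manifest <- manifest
  class(report) <- "run_report"
  invisible(report)
}

# all pairwise layer comparisons for every group column
layer_tests <- function(pt) {
  groups <- setdiff(names(pt), c("sample_id", "depth_m", "layer"))
  layers <- unique(pt$layer)
  rows <- list()
  if (length(layers) >= 2) {
    for (g in groups) {
      for (i in seq_len(length(layers) - 1)) {
        for (j in (i + 1):length(layers)) {
          ok <- sum(pt$layer == layers[i]) >= 2 &&
            sum(pt$layer == layers[j]) >= 2
          if (!ok) next
          ct <- compare_layers(pt, g, layers[i], layers[j])
          rows[[length(rows) + 1L]] <- data.frame(
            group = g, layer_a = layers[i], layer_b = layers[j],
            statistic = ct$statistic, p_value = ct$p_value,
            significance = ct$significance, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), layer_a = character(),
               layer_b = character(), statistic = numeric(),
               p_value = numeric(), significance = character(),
               stringsAsFactors = FALSE)
}

write_manifest <- function(out, inputs, cfg) {
  outputs <- setdiff(list.files(out, full.names = TRUE),
                     file.path(out, "MANIFEST.tsv"))
  rows <- rbind(
    data.frame(kind = "input", file = inputs,
               md5 = unname(tools::md5sum(inputs)),
               stringsAsFactors = FALSE),
    data.frame(kind = "output", file = basename(outputs),
               md5 = unname(tools::md5sum(outputs)),
               stringsAsFactors = FALSE),
    data.frame(kind = "param",
               file = c("seed", "min_completeness", "max_contamination",
                        "min_conserved", "ani_dedup", "min_read_len",
                        "min_identity", "min_score", "version"),
               md5 = c(cfg$seed, cfg$thresholds$min_completeness,
                       cfg$thresholds$max_contamination,
                       cfg$thresholds$min_conserved,
                       cfg$thresholds$ani_dedup, cfg$match$min_read_len,
                       cfg$match$min_identity, cfg$match$min_score,
                       as.character(utils::packageVersion("bdellocomp"))),
               stringsAsFactors = FALSE))
  path <- file.path(out, "MANIFEST.tsv")
  write_tsv(rows, path)
  path
}

#' Render enrichment tables as human-readable text
#'
#' Formats each group's marine-enrichment rows in the published table
#' layout (group, gene, whole-percent non-marine and marine display
#' columns alongside the 2-decimal values).
#'
#' @param report a `run_report` from [run_pipeline()], or an
#'   enrichment data.frame from [enrichment_table()].
#' @param min_marine_pct only rows at or above this marine percentage
#'   are shown (default 50, the published table's focus).
#' @return character vector of formatted lines, invisibly; also printed.
#' @export
render_tables <- function(report, min_marine_pct = 50) {
  enr <- if (is.data.frame(report)) report else
    report$stages$compare$enrichment
  lines <- character()
  if (is.null(enr) || nrow(enr) == 0) {
    lines <- "no rows"
  } else {
    for (g in unique(enr$group)) {
      rows <- enr[enr$group == g & !is.na(enr$marine_pct) &
                    enr$marine_pct >= min_marine_pct, , drop = FALSE]
      if (nrow(rows) == 0) next
      lines <- c(lines, sprintf("%s (marine n=%d, non-marine n=%d)",
                                g, rows$marine_n[1], rows$nonmarine_n[1]))
      lines <- c(lines, sprintf(
        "  %-10s non-marine %3.0f%% (%6.2f)  marine %3.0f%% (%6.2f)",
        rows$gene_id, round_half_away(rows$nonmarine_pct, 0),
        rows$nonmarine_pct, round_half_away(rows$marine_pct, 0),
        rows$marine_pct))
    }
    if (length(lines) == 0) lines <- "no rows"
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.run_report <- function(x, ...) {
  cat("bdellocomp run (seed ", x$seed, ")\n", sep = "")
  cat("  stages:", paste(names(x$stages), collapse = ", "), "\n")
  cat("  manifest:", x$manifest, "\n")
  invisible(x)
}
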