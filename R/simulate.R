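## Seeded simulators: annotation tables with known generating
## probabilities, layered 16S miTag read sets with known group
## abundances, mutated genome pairs for the ANI estimator, and proteins
## with planted motifs. Identical seeds give identical outputs.

DNA_BASES <- c("A", "C", "G", "T")
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# i.i.d. substitutions at rate p; a mutated site always changes base
mutate_dna <- function(seq, p) {
  if (p == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit)) {
    shift <- sample(1:3, length(hit), replace = TRUE)
    cur <- match(chars[hit], DNA_BASES)
    chars[hit] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  paste(chars, collapse = "")
}

# substitution pass over many reads at once (one RNG stream draw)
mutate_many <- function(reads, p) {
  if (p == 0 || length(reads) == 0) return(reads)
  lens <- nchar(reads)
  chars <- unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE)
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit)) {
    shift <- sample(1:3, length(hit), replace = TRUE)
    cur <- match(chars[hit], DNA_BASES)
    ok <- !is.na(cur)    # leave N untouched
    chars[hit[ok]] <- DNA_BASES[((cur[ok] - 1L + shift[ok]) %% 4L) + 1L]
  }
  grp <- rep.int(seq_along(reads), lens)
  out <- vapply(split(chars, grp), paste, character(1), collapse = "")
  names(out) <- names(reads)
  out
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data module. Defaults emulate the
#' study conditions: four groups with mixed marine/non-marine
#' composition, per-gene Bernoulli presence probabilities, mean copy
#' number near one, and layered miTag samples of 10^4 150 bp-scale reads
#' at 0.5% per-base error.
#'
#' @param seed integer RNG seed; the same seed reproduces every output
#'   byte for byte.
#' @param group_sizes named list, group -> `c(n_marine, n_nonmarine)`.
#' @param gene_probs data.frame with columns `gene`, `group`,
#'   `environment` (`"marine"` or `"non-marine"`) and `prob` in \[0,1\]:
#'   the Bernoulli presence probability of that gene in that stratum.
#' @param copy_dist mean copy number for present genes (>= 1); copies
#'   are drawn as 1 + Poisson(copy_dist - 1).
#' @param background_rate presence probability of non-focal background
#'   genes (ids carry the reserved `BG` prefix so truth tables stay
#'   unambiguous).
#' @param n_background number of background genes.
#' @param mitag list of miTag settings: `n_reads` per sample,
#'   `n_samples` per depth layer, `read_len = c(min, max)` (uniform),
#'   `error_rate` per base, `divergence` (named per group, distance of
#'   each group's 16S reference from the common ancestor), and
#'   `layer_abundance`, a groups x layers matrix of relative abundances
#'   with column sums <= 1 (the remainder is non-Bdellovibrionota
#'   background).
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       group_sizes = NULL,
                       gene_probs = NULL,
                       copy_dist = 1.2,
                       background_rate = 0.3,
                       n_background = 20L,
                       mitag = NULL) {
  mt <- list(
    n_reads = 10000L,
    n_samples = 10L,
    read_len = c(120L, 180L),
    error_rate = 0.005,
    divergence = c("Oligoflexia" = 0.05, "Bdello-group1" = 0.06,
                   "Bdello-group2" = 0.04, "Bacteriovoracia" = 0.05),
    # Fig-2-like vertical structure: Bdello-group2 richest at the
    # surface, Bacteriovoracia richest at depth, the other two rare
    layer_abundance = matrix(
      c(0.001, 0.001, 0.030, 0.005,
        0.001, 0.001, 0.015, 0.015,
        0.001, 0.001, 0.005, 0.030),
      nrow = 4, dimnames = list(BDELLO_GROUPS,
                                c("epipelagic", "mesopelagic", "deep")))
  )
  if (!is.null(mitag)) mt[names(mitag)] <- mitag
  cfg <- list(seed = as.integer(seed), group_sizes = group_sizes,
              gene_probs = gene_probs, copy_dist = copy_dist,
              background_rate = background_rate,
              n_background = as.integer(n_background), mitag = mt)
  if (!is.null(gene_probs)) {
    stopifnot(all(c("gene", "group", "environment", "prob") %in%
                    names(gene_probs)))
    if (any(gene_probs$prob < 0 | gene_probs$prob > 1)) {
      stop("gene presence probabilities must lie in [0, 1]")
    }
  }
  if (any(mt$layer_abundance < 0)) {
    stop("abundance vectors must be non-negative")
  }
  if (any(colSums(mt$layer_abundance) > 1)) {
    stop("per-layer abundances must sum to at most 1")
  }
  if (mt$error_rate < 0 || mt$error_rate >= 0.5) {
    stop("per-base error rate must lie in [0, 0.5)")
  }
  if (copy_dist < 1) stop("mean copy number must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Simulate an annotation table with known presence probabilities
#'
#' Draws, for every (gene, group, environment) stratum in
#' `cfg$gene_probs`, Bernoulli presence per genome and 1 + Poisson copy
#' numbers for present genes, plus background genes at
#' `cfg$background_rate`. The generating probabilities are returned as a
#' truth table alongside the fixture bundle.
#'
#' @param cfg a [sim_config()] with non-empty `group_sizes`.
#' @return list with `bundle` (a `fixture_bundle`) and `truth` (the
#'   gene_probs data.frame used to generate it).
#' @export
simulate_annotations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$group_sizes) || length(cfg$group_sizes) == 0) {
    stop("group_sizes must be a non-empty named list")
  }
  set.seed(cfg$seed)
  meta <- do.call(rbind, lapply(names(cfg$group_sizes), function(g) {
    ns <- cfg$group_sizes[[g]]
    fixture_group_meta(g, ns[[1]], ns[[2]])
  }))
  rows <- list()
  draw_rows <- function(ids, gene, namespace, p) {
    if (length(ids) == 0 || p == 0) return(NULL)
    present <- ids[stats::runif(length(ids)) < p]
    if (length(present) == 0) return(NULL)
    copies <- 1L + stats::rpois(length(present), cfg$copy_dist - 1)
    data.frame(genome_id = present, namespace = namespace,
               gene_id = gene, copies = copies, stringsAsFactors = FALSE)
  }
  gp <- cfg$gene_probs
  if (!is.null(gp)) {
    for (i in seq_len(nrow(gp))) {
      gmeta <- meta[meta$group == gp$group[i], , drop = FALSE]
      ids <- if (gp$environment[i] == "marine") {
        gmeta$genome_id[is_marine(gmeta$environment)]
      } else {
        gmeta$genome_id[!is_marine(gmeta$environment)]
      }
      ns <- if ("namespace" %in% names(gp)) gp$namespace[i] else "KEGG"
      rows[[length(rows) + 1L]] <- draw_rows(ids, gp$gene[i], ns,
                                             gp$prob[i])
    }
  }
  if (cfg$n_background > 0 && cfg$background_rate > 0) {
    for (b in seq_len(cfg$n_background)) {
      rows[[length(rows) + 1L]] <-
        draw_rows(meta$genome_id, sprintf("BG%04d", b), "KEGG",
                  cfg$background_rate)
    }
  }
  ann <- if (length(rows)) do.call(rbind, rows) else empty_annotations()
  bundle <- new_fixture_bundle("simulated", meta, ann,
                               "Seeded Bernoulli presence simulation.")
  list(bundle = bundle, truth = gp)
}

#' Simulate a labelled 16S reference database
#'
#' One reference per group, derived from a shared random ancestor by
#' i.i.d. substitutions at the per-group divergence in `cfg$mitag`.
#'
#' @param cfg a [sim_config()].
#' @param ref_len reference length in bp (16S-scale default).
#' @return data.frame with `ref_id`, `group`, `sequence`.
#' @export
simulate_refdb <- function(cfg, ref_len = 1500L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ancestor <- random_dna(ref_len)
  div <- cfg$mitag$divergence
  seqs <- vapply(names(div), function(g) mutate_dna(ancestor, div[[g]]),
                 character(1))
  data.frame(ref_id = paste0("ref_", GROUP_PREFIX[names(div)]),
             group = names(div), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Simulate layered miTag read sets with known group abundances
#'
#' For each depth layer, draws `n_samples` samples of `n_reads` reads.
#' Each read's taxon is drawn from the layer's abundance vector; the
#' remaining probability mass yields background reads from decoy
#' references generated independently of the group references (hence
#' far beyond the 97% identity filter). A Bdellovibrionota read is a
#' uniform-random substring of its group's reference with i.i.d.
#' per-base substitutions at the error rate.
#'
#' @param cfg a [sim_config()].
#' @param refdb labelled reference set as from [simulate_refdb()] (or
#'   [read_refdb()]); sequences must be at least as long as the maximum
#'   read length.
#' @return list with `samples` (list of per-sample lists: `sample_id`,
#'   `depth_m`, `layer`, `total_mitags`, `reads` named character) and
#'   `truth` (data.frame `sample_id`, `read_id`, `group`, with
#'   `"background"` for decoy reads).
#' @export
simulate_mitags <- function(cfg, refdb) {
  stopifnot(inherits(cfg, "sim_config"))
  mt <- cfg$mitag
  if (mt$error_rate < 0 || mt$error_rate >= 0.5) {
    stop("per-base error rate must lie in [0, 0.5)")
  }
  if (min(nchar(refdb$sequence)) < max(mt$read_len)) {
    stop("reference sequences must be at least as long as the reads")
  }
  set.seed(cfg$seed + 1L)
  ab <- mt$layer_abundance
  layers <- colnames(ab)
  groups <- rownames(ab)
  # decoys: independent random sequences (>> 15% divergent from all refs)
  decoys <- vapply(1:3, function(i) random_dna(max(nchar(refdb$sequence))),
                   character(1))
  depth_range <- list(epipelagic = c(5, 150), mesopelagic = c(250, 900),
                      deep = c(1000, 6000))
  samples <- list()
  truth <- list()
  si <- 0L
  for (layer in layers) {
    for (s in seq_len(mt$n_samples)) {
      si <- si + 1L
      sid <- sprintf("S%03d", si)
      depth <- round(stats::runif(1, depth_range[[layer]][1],
                                  depth_range[[layer]][2]))
      n <- mt$n_reads
      p <- c(ab[, layer], background = 1 - sum(ab[, layer]))
      taxon <- sample(names(p), n, replace = TRUE, prob = p)
      lens <- sample(seq(mt$read_len[1], mt$read_len[2]), n,
                     replace = TRUE)
      src <- character(n)
      for (g in groups) {
        idx <- which(taxon == g)
        if (length(idx)) {
          cand <- refdb$sequence[refdb$group == g]
          src[idx] <- cand[sample.int(length(cand), length(idx),
                                      replace = TRUE)]
        }
      }
      idx <- which(taxon == "background")
      if (length(idx)) {
        src[idx] <- decoys[sample.int(length(decoys), length(idx),
                                      replace = TRUE)]
      }
      start <- floor(stats::runif(n) * (nchar(src) - lens + 1)) + 1
      reads <- substring(src, start, start + lens - 1)
      reads <- mutate_many(reads, mt$error_rate)
      names(reads) <- sprintf("%s_r%05d", sid, seq_len(n))
      samples[[sid]] <- list(sample_id = sid, depth_m = depth,
                             layer = layer, total_mitags = n,
                             reads = reads)
      truth[[sid]] <- data.frame(sample_id = sid, read_id = names(reads),
                                 group = taxon, stringsAsFactors = FALSE)
    }
  }
  list(samples = samples, truth = do.call(rbind, truth))
}

#' Simulate a genome pair at a known mutation rate
#'
#' `seqB` is `seqA` with i.i.d. substitutions at rate `p`; the expected
#' ANI of the pair is 1 - p.
#'
#' @param length sequence length in bp (must be at least the default
#'   k-mer size, 16).
#' @param p per-base substitution rate in \[0, 0.3).
#' @param seed integer RNG seed.
#' @return list with `seqA` and `seqB` character strings.
#' @export
simulate_genome_pair <- function(length, p, seed = 1L) {
  if (p < 0 || p >= 0.3) stop("mutation rate must lie in [0, 0.3)")
  if (length < 16) stop("length must be at least the k-mer size (16)")
  set.seed(seed)
  a <- random_dna(length)
  list(seqA = a, seqB = mutate_dna(a, p))
}

#' Simulate proteins with planted motif instances
#'
#' Background residues are uniform over the 20 standard amino acids;
#' with probability `motif_rate` a protein receives one planted
#' instance of the wildcard motif (X positions instantiated at random)
#' at a uniform-random offset. Spurious background matches remain
#' possible and are not recorded in the truth table.
#'
#' @param n number of proteins.
#' @param motif_rate probability in \[0,1\] that a protein carries a
#'   planted motif instance.
#' @param seed integer RNG seed.
#' @param len protein length in residues.
#' @param motif wildcard pattern (default the chitinase catalytic motif
#'   `DXXDXDXE`; X matches any residue).
#' @return list with `proteins` (named character vector) and `truth`
#'   (data.frame `protein_id`, `start`, 0-based planted offsets).
#' @export
simulate_proteins <- function(n, motif_rate, seed = 1L, len = 300L,
                              motif = "DXXDXDXE") {
  if (motif_rate < 0 || motif_rate > 1) {
    stop("motif_rate must lie in [0, 1]")
  }
  set.seed(seed)
  pat <- strsplit(motif, "", fixed = TRUE)[[1]]
  m <- length(pat)
  proteins <- character(n)
  truth <- list()
  for (i in seq_len(n)) {
    chars <- sample(AA_LETTERS, len, replace = TRUE)
    if (stats::runif(1) < motif_rate) {
      at <- sample.int(len - m + 1L, 1L)
      inst <- ifelse(pat == "X", sample(AA_LETTERS, m, replace = TRUE),
                     pat)
      chars[at:(at + m - 1L)] <- inst
      truth[[length(truth) + 1L]] <-
        data.frame(protein_id = sprintf("prot%04d", i), start = at - 1L,
                   stringsAsFactors = FALSE)
    }
    proteins[i] <- paste(chars, collapse = "")
  }
  names(proteins) <- sprintf("prot%04d", seq_len(n))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(protein_id = character(), start = integer(),
               stringsAsFactors = FALSE)
  list(proteins = proteins, truth = truth)
}
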