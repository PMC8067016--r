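toy_meta <- function() {
  data.frame(
    genome_id = c("o1", "o2", "b1", "b2", "b3"),
    group = c("Oligoflexia", "Oligoflexia", "Bacteriovoracia",
              "Bacteriovoracia", "Bacteriovoracia"),
    environment = c("marine", "ground water", "marine", "marine",
                    "waste water"),
    stringsAsFactors = FALSE)
}

test_that("build_presence_matrix sums duplicates and round-trips", {
  ann <- data.frame(
    genome_id = c("o1", "o1", "b1"),
    namespace = "KEGG",
    gene_id = c("K00001", "K00001", "K00002"),
    copies = c(2L, 1L, 4L), stringsAsFactors = FALSE)
  m <- build_presence_matrix(ann, genome_ids = toy_meta()$genome_id)
  expect_equal(m$copies["K00001", "o1"], 3L)
  expect_equal(m$copies["K00002", "b1"], 4L)
  expect_true(all(m$presence == (m$copies > 0)))

  long <- presence_to_long(m)
  m2 <- build_presence_matrix(long, genome_ids = colnames(m$copies))
  expect_identical(m2$copies, m$copies)

  empty <- build_presence_matrix(ann[0, ], genome_ids = "g1")
  expect_equal(nrow(empty$copies), 0)
  bad <- ann; bad$copies[1] <- -1L
  expect_error(build_presence_matrix(bad, toy_meta()$genome_id),
               "negative copy number")
  expect_error(build_presence_matrix(ann, genome_ids = "g1"),
               "unknown genomes")
})

test_that("group presence is inclusive at 50% while specificity is strict", {
  ann <- data.frame(
    genome_id = c("o1", "b1", "b2", "b3",   # geneA: 1/2 and 3/3
                  "o1", "b1",               # geneB: 1/2 and 1/3
                  "o1", "o2"),              # geneC: 2/2 and 0/3
    namespace = "KEGG",
    gene_id = c(rep("geneA", 4), rep("geneB", 2), rep("geneC", 2)),
    copies = 1L, stringsAsFactors = FALSE)
  m <- build_presence_matrix(ann, genome_ids = toy_meta()$genome_id)
  gp <- group_presence(m, toy_meta())

  a_olig <- gp[gp$gene_id == "geneA" & gp$group == "Oligoflexia", ]
  expect_equal(a_olig$fraction, 0.5)
  expect_true(a_olig$present)          # "at least 50%" is inclusive
  expect_equal(call_group_specific(gp, "geneA"), "Bacteriovoracia")
  # fraction exactly 0.5 never wins specificity ("more than 50%")
  expect_true(is.na(call_group_specific(gp, "geneB")))
  expect_equal(call_group_specific(gp, "geneC"), "Oligoflexia")

  b_bact <- gp[gp$gene_id == "geneB" & gp$group == "Bacteriovoracia", ]
  expect_false(b_bact$present)         # 1/3 < 0.5

  counts <- count_group_specific(m, toy_meta(), "KEGG")
  expect_equal(unname(counts[c("Oligoflexia", "Bacteriovoracia")]),
               c(1L, 1L))
  expect_error(group_presence(m, transform(toy_meta(), group = NA)),
               "NA")
})

test_that("group-specific calls on simulated matrices recover planted truth", {
  gp_tab <- expand.grid(
    gene = c("S_Olig", "S_Bvor", "shared", "nowhere"),
    group = c("Oligoflexia", "Bacteriovoracia"),
    environment = c("marine", "non-marine"),
    stringsAsFactors = FALSE)
  gp_tab$prob <- 0
  gp_tab$prob[gp_tab$gene == "S_Olig" & gp_tab$group == "Oligoflexia"] <- 1
  gp_tab$prob[gp_tab$gene == "S_Bvor" & gp_tab$group == "Bacteriovoracia"] <- 1
  gp_tab$prob[gp_tab$gene == "shared"] <- 1
  cfg <- sim_config(seed = 31,
                    group_sizes = list("Oligoflexia" = c(5, 5),
                                       "Bacteriovoracia" = c(5, 5)),
                    gene_probs = gp_tab, background_rate = 0)
  sim <- simulate_annotations(cfg)
  m <- build_presence_matrix(sim$bundle$annotations,
                             genome_ids = sim$bundle$metadata$genome_id)
  counts <- count_group_specific(m, sim$bundle$metadata, "KEGG")
  expect_equal(unname(counts[c("Oligoflexia", "Bacteriovoracia")]),
               c(1L, 1L))
})

test_that("enrichment percentages recompute exactly from stored counts", {
  h <- fixture_matrix("W1_enrichment")
  for (g in unique(h$fx$metadata$group)) {
    et <- enrichment_table(h$m, h$fx$metadata, g)
    expect_equal(et$marine_pct,
                 round_half_away(100 * et$marine_present / et$marine_n, 2))
    expect_equal(et$nonmarine_pct,
                 round_half_away(100 * et$nonmarine_present /
                                   et$nonmarine_n, 2))
  }
  expect_error(enrichment_table(h$m, h$fx$metadata, "NoSuchGroup"),
               "unknown group")

  # all-marine group: the non-marine side is undefined and flagged
  meta1 <- data.frame(genome_id = "x1", group = "G",
                      environment = "marine", stringsAsFactors = FALSE)
  m1 <- build_presence_matrix(
    data.frame(genome_id = "x1", namespace = "KEGG", gene_id = "K1",
               copies = 1L, stringsAsFactors = FALSE), "x1")
  et1 <- enrichment_table(m1, meta1, "G")
  expect_true(all(et1$undefined_side))
  expect_true(is.na(et1$nonmarine_pct))
  expect_equal(et1$marine_pct, 100)
})

test_that("wilcoxon_copy_test matches enumeration exactly and handles edge cases", {
  same <- wilcoxon_copy_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  sep <- wilcoxon_copy_test(1:4, 10:13)
  expect_equal(sep$W, 0)
  expect_equal(sep$p_value, 2 / choose(8, 4))

  # exact p equals full-enumeration permutation p, all balanced n <= 6
  set.seed(41)
  for (n in 2:6) {
    for (rep in 1:3) {
      a <- round(stats::rnorm(n, 10, 3), 6)
      b <- round(stats::rnorm(n, 12, 3), 6)
      if (any(duplicated(c(a, b)))) next
      expect_equal(wilcoxon_copy_test(a, b)$p_value, perm_wilcox_p(a, b),
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }
  expect_error(wilcoxon_copy_test(numeric(0), 1:3), "non-empty")
})

test_that("large-sample Wilcoxon approximation tracks a Monte-Carlo oracle", {
  set.seed(42)
  a <- c(1, 1, 2, 2, 2, 3, 3, 4, 4, 5, 5, 6)   # ties: normal approximation
  b <- c(2, 3, 3, 4, 4, 4, 5, 5, 6, 6, 7, 8)
  got <- wilcoxon_copy_test(a, b)$p_value
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[1:12]) - 12 * 13 / 2
  mc <- replicate(40000, {
    idx <- sample(24, 12)
    sum(r[idx]) - 12 * 13 / 2
  })
  p_mc <- min(1, 2 * min(mean(mc <= u_obs), mean(mc >= u_obs)))
  expect_equal(got, p_mc, tolerance = 0.01)
})

test_that("peptidase_venn partitions families with conserved counts", {
  h <- fixture_matrix("W4_peptidases")
  v <- peptidase_venn(h$m, h$fx$metadata)
  all4 <- paste(c("Oligoflexia", "Bdello-group1", "Bdello-group2",
                  "Bacteriovoracia"), collapse = "+")
  expect_equal(unname(v$counts[all4]), 6L)
  expect_equal(unname(v$counts["Oligoflexia"]), 1L)
  expect_equal(v$regions[["Oligoflexia"]], "S33")
  # conservation: region counts sum to families present in >= 1 group
  gp <- group_presence(h$m, h$fx$metadata)
  fams <- unique(gp$gene_id[gp$namespace == "MEROPS" & gp$present])
  expect_equal(sum(v$counts), length(fams))
  # permutation invariance to genome ordering
  meta2 <- h$fx$metadata[rev(seq_len(nrow(h$fx$metadata))), ]
  v2 <- peptidase_venn(h$m, meta2)
  expect_equal(v2$counts, v$counts)
})

test_that("cazy_class_counts sums copies per genome and averages per group", {
  ann <- data.frame(
    genome_id = c("o1", "o1", "o2", "b1"),
    namespace = "CAZy",
    gene_id = c("GT2", "GT4", "GT2", "GH13"),
    copies = c(3L, 1L, 2L, 5L), stringsAsFactors = FALSE)
  m <- build_presence_matrix(ann, genome_ids = toy_meta()$genome_id)
  cc <- cazy_class_counts(m, toy_meta())
  expect_equal(cc["Oligoflexia", "GT"], 3)      # genomes: 4 and 2
  expect_equal(cc["Bacteriovoracia", "GH"], 5 / 3)
  expect_equal(cc["Bacteriovoracia", "GT"], 0)

  bad <- rbind(ann, data.frame(genome_id = "o1", namespace = "CAZy",
                               gene_id = "ZZ9", copies = 1L))
  mbad <- build_presence_matrix(bad, genome_ids = toy_meta()$genome_id)
  expect_warning(ccb <- cazy_class_counts(mbad, toy_meta()),
                 "unrecognized class prefix.*ZZ9")
  expect_equal(ccb, cc)
})

test_that("planted GT surplus in one group is recovered in the ordering", {
  gp_tab <- expand.grid(gene = sprintf("GT%d", 1:5),
                        group = c("Oligoflexia", "Bacteriovoracia"),
                        environment = c("marine", "non-marine"),
                        stringsAsFactors = FALSE)
  gp_tab$namespace <- "CAZy"
  gp_tab$prob <- ifelse(gp_tab$group == "Oligoflexia", 0.9, 0.2)
  cfg <- sim_config(seed = 77,
                    group_sizes = list("Oligoflexia" = c(10, 10),
                                       "Bacteriovoracia" = c(10, 10)),
                    gene_probs = gp_tab, background_rate = 0)
  sim <- simulate_annotations(cfg)
  m <- build_presence_matrix(sim$bundle$annotations,
                             genome_ids = sim$bundle$metadata$genome_id)
  cc <- cazy_class_counts(m, sim$bundle$metadata)
  expect_gt(cc["Oligoflexia", "GT"], cc["Bacteriovoracia", "GT"])
})

test_that("source_tally reproduces per-group source percentages", {
  st <- source_tally(toy_meta())
  olig_marine <- st$pct[st$group == "Oligoflexia" &
                          st$environment == "marine"]
  expect_equal(olig_marine, 50)
  single <- data.frame(genome_id = "g", group = "G",
                       environment = "ground water",
                       stringsAsFactors = FALSE)
  st1 <- source_tally(single)
  expect_equal(st1$pct, 100)
  # unrounded percentages sum to 100 within each group
  for (g in unique(st$group)) {
    expect_equal(sum(st$n[st$group == g]) /
                   sum(st$n[st$group == g]) * 100, 100)
  }
})

test_that("marine-enrichment effects planted at 0.9 vs 0.1 rank on top", {
  hits <- 0
  for (seed in 1:20) {
    gp_tab <- data.frame(
      gene = c("target", "target", sprintf("flat%d", 1:8),
               sprintf("flat%d", 1:8)),
      group = "Bacteriovoracia",
      environment = c("marine", "non-marine", rep("marine", 8),
                      rep("non-marine", 8)),
      prob = c(0.9, 0.1, rep(0.4, 16)), stringsAsFactors = FALSE)
    cfg <- sim_config(seed = seed,
                      group_sizes = list("Bacteriovoracia" = c(50, 50)),
                      gene_probs = gp_tab, background_rate = 0)
    sim <- simulate_annotations(cfg)
    m <- build_presence_matrix(sim$bundle$annotations,
                               genome_ids = sim$bundle$metadata$genome_id)
    et <- enrichment_table(m, sim$bundle$metadata, "Bacteriovoracia")
    diff <- et$marine_pct - et$nonmarine_pct
    if (et$gene_id[which.max(diff)] == "target") hits <- hits + 1
  }
  expect_gte(hits, 19)
})
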