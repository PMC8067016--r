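test_that("align_read reproduces identity and substitution cases", {
  set.seed(101)
  ref <- rand_dna(1200)
  read <- substr(ref, 301, 450)
  a <- align_read(read, ref)
  expect_equal(a$identity, 1.0)
  expect_equal(a$aln_len, 150)
  expect_equal(a$score, 300)
  expect_equal(a$ref_start, 301)

  r5 <- mutate_read(read, 5)
  a5 <- align_read(r5, ref)
  expect_equal(a5$identity, 145 / 150)
  expect_equal(a5$score, full_dp_score(r5, ref))

  # no shared 12-mer: a C-homopolymer against an ACGT-periodic reference
  periodic <- strrep("ACGT", 100)
  expect_null(align_read(strrep("C", 150), periodic))
  expect_error(align_read("", ref), "empty read")
})

test_that("classify_read enforces the length and identity filters strictly", {
  set.seed(102)
  refdb <- data.frame(
    ref_id = c("bv1", "og1"),
    group = c("Bacteriovoracia", "Oligoflexia"),
    sequence = c(rand_dna(1500), rand_dna(1500)),
    stringsAsFactors = FALSE)

  exact100 <- substr(refdb$sequence[1], 101, 200)   # 100 bp, perfect
  expect_equal(classify_read(exact100, refdb), "unassigned")

  exact150 <- substr(refdb$sequence[1], 101, 250)
  expect_equal(classify_read(exact150, refdb), "Bacteriovoracia")

  # 150 bp with 5 substitutions: identity 145/150 < 0.97 -> unassigned
  low <- mutate_read(exact150, 5)
  expect_equal(classify_read(low, refdb), "unassigned")

  # identity exactly 0.97 (194/200) is rejected: strict inequality
  exact200 <- substr(refdb$sequence[1], 101, 300)
  edge <- mutate_read(exact200, 6)
  hit <- align_read(edge, refdb$sequence[1])
  expect_equal(hit$identity, 0.97)
  expect_equal(classify_read(edge, refdb), "unassigned")

  # reverse-complement reads classify to the same reference
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(exact150, "")[[1]]), collapse = ""))
  expect_equal(classify_read(rc, refdb), "Bacteriovoracia")
})

test_that("assign_layer uses half-open depth bins with 1000 m in the deep layer", {
  expect_equal(assign_layer(5), "epipelagic")
  expect_equal(assign_layer(c(0, 199.9)), c("epipelagic", "epipelagic"))
  expect_equal(assign_layer(200), "mesopelagic")
  expect_equal(assign_layer(999), "mesopelagic")
  expect_equal(assign_layer(1000), "deep")
  expect_equal(assign_layer(5992), "deep")
  expect_error(assign_layer(-1), "non-negative")
})

test_that("profile_sample divides assigned counts by total miTags", {
  set.seed(103)
  refdb <- data.frame(ref_id = "bv1", group = "Bacteriovoracia",
                      sequence = rand_dna(1500), stringsAsFactors = FALSE)
  reads <- vapply(1:15, function(i) {
    st <- sample(1:1300, 1)
    substr(refdb$sequence, st, st + 149)
  }, character(1))
  reads <- c(reads, vapply(1:25, function(i) rand_dna(150), character(1)))
  names(reads) <- sprintf("r%02d", seq_along(reads))
  p <- profile_sample(list(sample_id = "s1", depth_m = 40,
                           total_mitags = 1000, reads = reads), refdb)
  expect_equal(unname(p$abundance[["Bacteriovoracia"]]), 1.5)
  expect_equal(p$layer, "epipelagic")

  none <- profile_sample(list(sample_id = "s2", depth_m = 40,
                              total_mitags = 1000,
                              reads = c(r1 = rand_dna(150))), refdb)
  expect_equal(unname(none$abundance[["Bacteriovoracia"]]), 0)
  expect_error(profile_sample(list(sample_id = "s3", depth_m = 1,
                                   total_mitags = 0, reads = reads),
                              refdb), "total_mitags")
})

test_that("lowering the identity threshold never lowers abundance", {
  set.seed(104)
  cfg1 <- sim_config(seed = 104, mitag = list(
    n_reads = 400L, n_samples = 1L,
    layer_abundance = matrix(c(0.02, 0.02, 0.05, 0.05), nrow = 4,
                             dimnames = list(c("Oligoflexia",
                                               "Bdello-group1",
                                               "Bdello-group2",
                                               "Bacteriovoracia"),
                                             "epipelagic")),
    error_rate = 0.02))   # high error so the filter actually bites
  refdb <- simulate_refdb(cfg1)
  sim <- simulate_mitags(cfg1, refdb)
  s <- sim$samples[[1]]
  strict <- profile_sample(s, refdb, match_config(min_identity = 0.97))
  loose <- profile_sample(s, refdb, match_config(min_identity = 0.90))
  expect_true(all(loose$abundance >= strict$abundance))
  expect_gt(sum(loose$abundance), sum(strict$abundance))
})

test_that("compare_layers matches the closed-form Welch statistic", {
  pt <- data.frame(
    sample_id = sprintf("s%d", 1:6),
    depth_m = c(5, 10, 20, 2000, 3000, 4000),
    layer = rep(c("epipelagic", "deep"), each = 3),
    grp = c(1, 2, 3, 4, 5, 6), stringsAsFactors = FALSE)
  ct <- compare_layers(pt, "grp", "epipelagic", "deep")
  # closed form: means 2 and 5, each variance 1 over n = 3,
  # t = -3 / sqrt(2/3), Welch df = 4
  t_expected <- -3 / sqrt(2 / 3)
  expect_equal(ct$statistic, t_expected)
  expect_equal(ct$p_value, 2 * stats::pt(t_expected, df = 4))
  expect_equal(ct$significance, "*")

  same <- pt
  same$grp <- rep(c(1, 2, 3), 2)
  ct0 <- compare_layers(same, "grp", "epipelagic", "deep")
  expect_equal(ct0$statistic, 0)
  expect_equal(ct0$p_value, 1)
  expect_equal(ct0$significance, "ns")

  expect_error(compare_layers(pt[-(1:2), ], "grp", "epipelagic", "deep"),
               "at least 2 samples")
})
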