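# The toy genome / annotation builders live in helper-toygenome.R.
motif_seq <- toy_motif

test_that("promoter extraction is strand-aware with clipping and linkers", {
  toy <- toy_promoters()
  pr <- toy$promoters
  genome <- toy$genome
  rownames_id <- function(id) pr[pr$transcript_id == id, ]

  plus <- rownames_id("txPlus")
  expect_equal(plus$upstream_start, 1001L)
  expect_equal(plus$upstream_end, 7000L)
  expect_equal(plus$intron_start, 7201L)
  expect_equal(plus$intron_end, 7500L)
  expected <- paste0(substr(genome, 1001, 7000), strrep("N", 20),
                     substr(genome, 7201, 7500))
  expect_equal(plus$sequence, expected)

  clip <- rownames_id("txClip")
  expect_equal(clip$upstream_start, 1L)
  expect_equal(clip$upstream_end, 99L)
  expect_equal(nchar(clip$sequence), 99 + 20 + (299 - 201 + 1))

  single <- rownames_id("txSingle")
  expect_false(grepl("N", single$sequence, fixed = TRUE))  # no linker
  # TSS at 5000: the 6000-nt window clips at the chromosome start
  expect_equal(single$upstream_start, 1L)
  expect_equal(nchar(single$sequence), 4999L)

  minus <- rownames_id("txMinus")
  expect_equal(minus$upstream_start, 2601L)
  expect_equal(minus$upstream_end, 8600L)
  expect_equal(minus$intron_start, 2101L)
  expect_equal(minus$intron_end, 2399L)
  expected_minus <- paste0(
    revcomp_chr(substr(genome, 2601, 8600)), strrep("N", 20),
    revcomp_chr(substr(genome, 2101, 2399))
  )
  expect_equal(minus$sequence, expected_minus)
})

test_that("planted motif presence is recovered exactly from promoters", {
  toy <- toy_promoters()
  pr <- toy$promoters
  present <- pr$transcript_id[grepl(motif_seq, pr$sequence, fixed = TRUE)]
  # planted in txPlus upstream and txMinus intron (sense strand) only
  expect_setequal(present, c("txPlus", "txMinus"))
})

test_that("transcripts on unknown contigs are skipped with a warning", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", strrep("ACGT", 500)), fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tmRNA\t1000\t1500\t.\t+\t.\tID=ok",
    "chr1\ttoy\texon\t1000\t1500\t.\t+\t.\tParent=ok",
    "chrZ\ttoy\tmRNA\t10\t80\t.\t+\t.\tID=lost",
    "chrZ\ttoy\texon\t10\t80\t.\t+\t.\tParent=lost"
  ), gff)
  expect_warning(pr <- extract_promoters(gff, fa), "chrZ")
  expect_equal(pr$transcript_id, "ok")
})

test_that("motif scans collapse to presence/absence at the p threshold", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("motif_id", "sequence_name", "start", "stop", "strand",
            "score", "p-value"), collapse = "\t"),
    "m1\ttx1\t10\t21\t+\t12.3\t1e-6",
    "m1\ttx1\t400\t411\t-\t10.1\t2e-5",   # second occurrence, same promoter
    "m1\ttx2\t5\t16\t+\t8.0\t6e-5",       # fails the 5e-5 threshold
    "m2\ttx2\t7\t18\t+\t9.9\t4.9e-5"
  ), tsv)
  tab <- load_fimo(tsv, universe = c("tx1", "tx2", "tx3"))
  expect_equal(nrow(tab$hits), 2)
  expect_equal(tab$hits$transcript_id[tab$hits$motif_id == "m1"], "tx1")
  expect_equal(tab$hits$transcript_id[tab$hits$motif_id == "m2"], "tx2")
  expect_equal(tab$universe, c("tx1", "tx2", "tx3"))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("motif_id\tfoo", "m1\t1"), bad)
  expect_error(load_fimo(bad), "sequence_name")
})

test_that("hypergeometric enrichment matches the combinatorial oracle", {
  universe <- sprintf("t%02d", 1:20)
  hits <- tibble::tibble(
    motif_id = "m",
    transcript_id = universe[1:5]
  )
  tab <- motif_table(universe, hits)
  cluster <- universe[c(1:4, 10:13)]  # n = 8, k = 4, K = 5, M = 20
  res <- motif_enrichment(cluster, tab, min_cluster = 5)
  expect_equal(res$k, 4)
  expect_equal(res$p_value, hyper_tail_oracle(4, 5, 20, 8), tolerance = 1e-12)

  # motif everywhere: k = n, K = M -> p = 1
  all_tab <- motif_table(universe,
                         tibble::tibble(motif_id = "m", transcript_id = universe))
  expect_equal(motif_enrichment(cluster, all_tab, min_cluster = 5)$p_value, 1)

  # absent motif in the cluster: k = 0 -> p = 1
  out_tab <- motif_table(universe,
                         tibble::tibble(motif_id = "m", transcript_id = universe[14:16]))
  expect_equal(motif_enrichment(universe[1:10], out_tab, min_cluster = 5)$p_value, 1)

  expect_error(motif_enrichment(c(cluster, "zz"), tab), "outside")
  expect_error(motif_enrichment(universe[1:3], tab), "fewer than")
})

test_that("enrichment is invariant under consistent relabelling", {
  set.seed(82)
  universe <- sprintf("t%02d", 1:25)
  hits <- tibble::tibble(motif_id = "m", transcript_id = sample(universe, 9))
  cluster <- sample(universe, 12)
  p1 <- motif_enrichment(cluster, motif_table(universe, hits))$p_value
  # permute all ids consistently
  perm <- setNames(sample(universe), universe)
  p2 <- motif_enrichment(
    unname(perm[cluster]),
    motif_table(unname(perm[universe]),
                tibble::tibble(motif_id = "m",
                               transcript_id = unname(perm[hits$transcript_id])))
  )$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("Welch comparisons match the textbook formula", {
  universe <- sprintf("t%02d", 1:9)
  tab <- motif_table(universe,
                     tibble::tibble(motif_id = "m", transcript_id = universe[1:4]))
  stats_tbl <- tibble::tibble(
    transcript_id = universe,
    rp24 = c(1, 2, 3, 4, 2, 4, 6, 8, 10),
    median_expr = c(5, 5, 5, 5, 5, 5, 5, 5, 5)
  )
  res <- motif_effect_tests(universe, tab, stats_tbl)
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8, 10)
  t_hand <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(res$t_rp24, t_hand, tolerance = 1e-12)
  expect_true(res$testable)

  # identical subgroups: t = 0, p = 1
  tab2 <- motif_table(universe[1:6],
                      tibble::tibble(motif_id = "m", transcript_id = universe[1:3]))
  stats2 <- tibble::tibble(transcript_id = universe[1:6],
                           rp24 = c(1, 2, 3, 1, 2, 3),
                           median_expr = c(4, 5, 6, 4, 5, 6))
  res2 <- motif_effect_tests(universe[1:6], tab2, stats2)
  expect_equal(res2$t_rp24, 0, tolerance = 1e-12)
  expect_equal(res2$p_rp24, 1, tolerance = 1e-12)

  # subgroup of one is untestable
  tab3 <- motif_table(universe[1:6],
                      tibble::tibble(motif_id = "m", transcript_id = universe[1]))
  res3 <- motif_effect_tests(universe[1:6], tab3, stats2)
  expect_false(res3$testable)
  expect_true(is.na(res3$t_rp24))
})

test_that("motif effects are detected in a planted simulation", {
  set.seed(83)
  ids <- sprintf("t%02d", 1:40)
  tab <- motif_table(ids, tibble::tibble(motif_id = "m", transcript_id = ids[1:20]))
  stats_tbl <- tibble::tibble(
    transcript_id = ids,
    rp24 = c(rnorm(20, 3, 0.5), rnorm(20, 1, 0.5)),
    median_expr = rnorm(40, 10, 1)
  )
  res <- motif_effect_tests(ids, tab, stats_tbl)
  expect_lt(res$p_rp24, 1e-4)
  expect_gt(res$p_expr, 0.001)  # no planted expression effect
})
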