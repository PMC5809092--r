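test_that("allelic-state classifier follows the four-way rule", {
  # recombinant matches a donor allele that differs from the ancestor
  expect_equal(classify_allelic_state("A", "G", "T", "G"), "K12_ONLY")
  # recombinant back to an ancestor that differs from the donor
  expect_equal(classify_allelic_state("A", "G", "T", "A"), "ANC_ONLY")
  # donor identical to ancestor, recombinant matches both
  expect_equal(classify_allelic_state("A", "A", "T", "A"), "K12_EQ_ANC")
  # degenerate: all four identical
  expect_equal(classify_allelic_state("ACGT", "ACGT", "ACGT", "ACGT"),
               "K12_EQ_ANC")
  # patchwork allele matching nothing
  expect_equal(classify_allelic_state("AAA", "GAA", "ATA", "GTC"),
               "NEW_ALLELE")
  # gaps act as a fifth symbol
  expect_equal(classify_allelic_state("A-G", "ACG", "ATG", "A-G"), "ANC_ONLY")
  expect_error(classify_allelic_state("AC", "ACG", "AC", "AC"), "equal length")
})

test_that("the packaged replaced-loci fixture aggregates to the published counts", {
  loci <- replaced_loci_fixture()
  expect_equal(nrow(loci), 30L)
  agg <- aggregate_states(classify_loci(loci))
  expect_equal(unname(agg$counts),
               c(5L, 18L, 4L, 3L))
  expect_equal(agg$reverted_to_ancestor, 22L)
  expect_equal(agg$reverted_in_selected_genes, 11L)
  expect_equal(sum(agg$counts), nrow(loci))
})

test_that("aggregation of an empty table is all zeros", {
  empty <- data.frame(state = character(), strong_selection = logical())
  agg <- aggregate_states(empty)
  expect_equal(sum(agg$counts), 0L)
  expect_equal(agg$reverted_to_ancestor, 0L)
})

test_that("gene conversion threshold is strictly within-genome", {
  one_clone <- data.frame(gene = "nohB", genome = "c1", pos = c(10, 20, 30))
  expect_equal(detect_gene_conversion(one_clone)$gene, "nohB")
  split_clones <- data.frame(gene = "waaQ", genome = c("c1", "c1", "c2", "c2"),
                             pos = c(10, 20, 10, 20))
  expect_equal(nrow(detect_gene_conversion(split_clones)), 0L)
  expect_equal(nrow(detect_gene_conversion(one_clone[0, ])), 0L)
})

test_that("gene-conversion calls match a brute-force groupby oracle", {
  set.seed(13)
  for (rep in 1:10) {
    n <- 120
    df <- data.frame(gene = sample(paste0("g", 1:12), n, replace = TRUE),
                     genome = sample(paste0("c", 1:5), n, replace = TRUE),
                     pos = sample.int(5000, n, replace = TRUE))
    calls <- detect_gene_conversion(df)
    # brute-force: nested loops over gene x genome
    flagged <- character()
    for (g in unique(df$gene)) for (cl in unique(df$genome)) {
      if (sum(df$gene == g & df$genome == cl) >= 3) flagged <- c(flagged, g)
    }
    expect_setequal(calls$gene, unique(flagged))
    for (g in calls$gene) {
      expect_equal(calls$mutation_count[calls$gene == g], sum(df$gene == g))
      expect_equal(calls$lineages_mutated[calls$gene == g],
                   length(unique(df$genome[df$gene == g])))
      expect_equal(calls$positions_mutated[calls$gene == g],
                   length(unique(df$pos[df$gene == g])))
    }
    # invariance to input order
    shuffled <- detect_gene_conversion(df[sample.int(n), ])
    expect_equal(shuffled, calls)
  }
})

test_that("Welch test matches the closed-form computation", {
  x <- c(0, 0, 0, 0, 0)
  y <- c(12.3, 45.6, 7.8, 90.1, 33.3, 20.2)
  res <- gscore_welch_test(x, y)
  # independent closed form: t, Welch-Satterthwaite df, two-sided p
  se2 <- stats::var(x) / length(x) + stats::var(y) / length(y)
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((stats::var(x) / length(x))^2 / (length(x) - 1) +
                        (stats::var(y) / length(y))^2 / (length(y) - 1))
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p_two_sided, p_hand, tolerance = 1e-12)
  expect_equal(res$mean1, 0)
})

test_that("Welch test degenerate and identical-group behaviour", {
  same <- c(1, 2, 3, 4)
  expect_equal(gscore_welch_test(same, same)$p_two_sided, 1)
  degen <- gscore_welch_test(c(5, 5, 5), c(5, 5, 5))
  expect_true(is.na(degen$p_two_sided))
  expect_error(gscore_welch_test(1, c(1, 2)), "at least two")
})

test_that("recombination:mutation ratio bounds reproduce printed rows", {
  r1 <- rec_mut_ratio(8788, 2, 2)
  expect_equal(r1$lower, 2197)
  expect_equal(r1$upper, 4394)
  expect_false(r1$single)
  r2 <- rec_mut_ratio(0, 1, 0)
  expect_equal(r2$lower, 0)
  expect_true(r2$single)
  r3 <- rec_mut_ratio(5228, 0, 1)
  expect_equal(r3$lower, 5228)
  expect_true(is.na(r3$upper))
  r4 <- rec_mut_ratio(3730, 1, 0)
  expect_equal(r4$lower, 3730)
  expect_true(r4$single)
  # fully undefined when nothing mutated
  r5 <- rec_mut_ratio(100, 0, 0)
  expect_true(is.na(r5$lower) && is.na(r5$upper))
})

test_that("ratio bounds are ordered and scale-invariant", {
  set.seed(77)
  for (i in 1:30) {
    a <- sample.int(10000, 1); b <- sample.int(10, 1); d <- sample.int(10, 1)
    r <- rec_mut_ratio(a, b, d)
    if (!is.na(r$lower) && !is.na(r$upper)) expect_lte(r$lower, r$upper)
    k <- sample.int(5, 1)
    rk <- rec_mut_ratio(k * a, k * b, k * d)
    expect_equal(rk$lower, r$lower)
    expect_equal(rk$upper, r$upper)
  }
})

test_that("mutations are assigned to the realized painted segment", {
  m <- data.frame(pos = c(100, 200, 300, 400), type = c("B", "K12", "K12", "B"))
  seg <- infer_segments(m, 1000, circular = FALSE)
  expect_equal(assign_to_segments(c(50, 250, 400, 900), seg),
               c("RECIPIENT", "DONOR", "DONOR", "RECIPIENT"))
  expect_error(assign_to_segments(2000, seg), "not covered")
})
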