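test_that("donor_union and donor_specific match brute-force set algebra", {
  set.seed(21)
  for (rep in 1:5) {
    inst <- random_label_instance(40)
    u <- donor_union(inst$donors)
    brute <- unique(unlist(lapply(inst$donors,
                                  function(d) site_key(d$variants))))
    expect_setequal(site_key(u), brute)
    expect_false(anyDuplicated(site_key(u)) > 0)

    spec <- donor_specific(inst$donors)
    all_keys <- unlist(lapply(inst$donors, function(d) site_key(d$variants)))
    for (i in seq_along(inst$donors)) {
      mine <- site_key(inst$donors[[i]]$variants)
      brute_spec <- mine[vapply(mine, function(k)
        sum(all_keys == k) == 1L, logical(1))]
      expect_setequal(site_key(spec[[i]]), brute_spec)
    }
  }
})

test_that("single-donor union is the donor itself; specificity needs two", {
  set.seed(3)
  d <- call_set("d1", "donor", random_variants(10))
  expect_setequal(site_key(donor_union(list(d))), site_key(d$variants))
  expect_error(donor_specific(list(d)), "at least two")
})

test_that("disjoint donors union to the sum of their sizes", {
  a <- call_set("d1", "donor", variant_table(pos = 1:3, kind = "SNP", alt = "A"))
  b <- call_set("d2", "donor", variant_table(pos = 4:7, kind = "SNP", alt = "C"))
  expect_equal(nrow(donor_union(list(a, b))), 7L)
})

test_that("labels match the per-site truth-table oracle on random instances", {
  set.seed(99)
  for (rep in 1:20) {
    inst <- random_label_instance(50)
    lab <- suppressMessages(
      label_mutations(inst$recombinant, inst$recipient, inst$donors))
    oracle <- oracle_labels(inst)
    truth <- oracle[!(oracle$label %in% c("ignored", "absent")), ]
    # REL606 markers inside recombinant deletions are dropped by design
    dropped <- truth$label == "REL606" &
      in_deletion("sim", truth$pos, inst$recombinant)
    truth <- truth[!dropped, ]
    expect_setequal(site_key(lab), truth$key)
    m <- match(site_key(lab), truth$key)
    expect_equal(lab$label, truth$label[m])
  }
})

test_that("a recombinant identical to its recipient is all LTEE mutations", {
  set.seed(8)
  v <- random_variants(20, L = 5000L)
  recip <- call_set("recipient", "recipient", v)
  recomb <- call_set("recombinant", "recombinant", v)
  donors <- list(call_set("d1", "donor", variant_table(
    pos = 6000L + 0:5, kind = "SNP", alt = "T", chrom = "sim")))
  lab <- label_mutations(recomb, recip, donors, ref_length = 10000L)
  expect_equal(sum(lab$label == "LTEE"), nrow(v))
  expect_equal(sum(lab$label %in% c("K12", "NEW", "DELETED")), 0L)
})

test_that("a lost recipient site is DELETED, flagged only inside deletions", {
  base <- variant_table(chrom = "sim", pos = c(100L, 200L, 300L),
                        kind = "SNP", alt = c("A", "C", "G"))
  recip <- call_set("recipient", "recipient", base)
  # recombinant lost pos 200 (no deletion) and pos 300 (inside a deletion)
  keep <- base[base$pos == 100L, , drop = FALSE]
  del <- variant_table(chrom = "sim", pos = 250L, kind = "large_deletion",
                       alt = "100")
  recomb <- call_set("recombinant", "recombinant", rbind(keep, del))
  donors <- list(call_set("d1", "donor",
                          variant_table(chrom = "sim", pos = 900L,
                                        kind = "SNP", alt = "T")))
  lab <- label_mutations(recomb, recip, donors)
  d200 <- lab[lab$pos == 200L & lab$kind == "SNP", ]
  d300 <- lab[lab$pos == 300L & lab$kind == "SNP", ]
  expect_equal(d200$label, "DELETED")
  expect_false(d200$in_deleted_region)
  expect_equal(d300$label, "DELETED")
  expect_true(d300$in_deleted_region)
})

test_that("label partition covers the non-identical universe exactly once", {
  set.seed(31)
  inst <- random_label_instance(80)
  lab <- suppressMessages(
    label_mutations(inst$recombinant, inst$recipient, inst$donors))
  expect_false(anyDuplicated(site_key(lab)) > 0)
  oracle <- oracle_labels(inst)
  informative <- oracle[!(oracle$label %in% c("ignored", "absent")), ]
  dropped <- informative$label == "REL606" &
    in_deletion("sim", informative$pos, inst$recombinant)
  expect_equal(nrow(lab), nrow(informative) - sum(dropped))
})

test_that("donor-specific attribution flows into per-clone marker counts", {
  shared <- variant_table(chrom = "sim", pos = 1:10 * 100L, kind = "SNP",
                          alt = "A")
  own1 <- variant_table(chrom = "sim", pos = 1501L, kind = "SNP", alt = "C")
  own2 <- variant_table(chrom = "sim", pos = 2501L, kind = "SNP", alt = "G")
  d1 <- call_set("d1", "donor", rbind(shared, own1))
  d2 <- call_set("d2", "donor", rbind(shared, own2))
  recip <- call_set("r", "recipient", variant_table(chrom = "sim", pos = 99L,
                                                    kind = "SNP", alt = "T"))
  # clone A took d1 material; clone B took nothing
  cloneA <- call_set("A", "recombinant", rbind(shared[1:3, ], own1))
  cloneB <- call_set("B", "recombinant", variant_table())
  labA <- label_mutations(cloneA, recip, list(d1, d2))
  labB <- label_mutations(cloneB, recip, list(d1, d2))
  expect_equal(labA$donor_origin[labA$pos == 1501L], "d1")
  counts <- donor_marker_counts(list(A = labA, B = labB),
                                donor_ids = c("d1", "d2"))
  expect_equal(counts$d1[counts$clone_id == "A"], 1L)
  expect_equal(counts$d2[counts$clone_id == "A"], 0L)
  expect_equal(unlist(counts[counts$clone_id == "B", c("d1", "d2")]),
               c(d1 = 0L, d2 = 0L))
  # donor-specific counts can never exceed the clone's K12 total
  expect_lte(sum(counts[counts$clone_id == "A", c("d1", "d2")]),
             sum(labA$label == "K12"))
})

test_that("sites beyond the reference length raise an error", {
  v <- variant_table(chrom = "sim", pos = 5000L, kind = "SNP", alt = "A")
  recomb <- call_set("x", "recombinant", v)
  recip <- call_set("r", "recipient", variant_table())
  d <- list(call_set("d", "donor", variant_table(chrom = "sim", pos = 10L,
                                                 kind = "SNP", alt = "C")))
  expect_error(label_mutations(recomb, recip, d, ref_length = 1000L),
               "reference length")
})
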