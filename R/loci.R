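#' Four-way allelic-state classification of a replaced locus
#'
#' Compares aligned variable-site sequences of one locus across the four
#' relevant genomes — the pre-experiment ancestor (REL606), the K-12 donor,
#' the evolved recipient, and the recombinant — and assigns one of four
#' states:
#'
#' * `"K12_ONLY"` — recombinant matches the donor, and the donor differs
#'   from the ancestor (printed "K-12").
#' * `"K12_EQ_ANC"` — recombinant matches the donor, and donor and ancestor
#'   are identical (printed "K-12 (REL606)"): the replacement reverted the
#'   gene to its pre-experiment state via a donor sequence equal to it.
#' * `"ANC_ONLY"` — recombinant matches the ancestor, which differs from the
#'   donor (printed "REL606").
#' * `"NEW_ALLELE"` — none of the above: a patchwork of donor, recipient,
#'   and new mutations.
#'
#' Sequences are compared on variable sites only; gaps (`-`) act as a fifth
#' symbol. Comparison is exact and case-insensitive.
#'
#' @param ancestor,donor,recipient,recombinant equal-length character
#'   strings (or character vectors of single symbols) over the variable
#'   sites of the locus.
#' @return one of `"K12_ONLY"`, `"K12_EQ_ANC"`, `"ANC_ONLY"`,
#'   `"NEW_ALLELE"`.
#' @examples
#' classify_allelic_state("A", "G", "T", "G")  # K12_ONLY
#' classify_allelic_state("A", "G", "T", "A")  # ANC_ONLY
#' @export
classify_allelic_state <- function(ancestor, donor, recipient, recombinant) {
  seqs <- lapply(list(ancestor = ancestor, donor = donor,
                      recipient = recipient, recombinant = recombinant),
                 function(s) toupper(paste(s, collapse = "")))
  len <- vapply(seqs, nchar, integer(1))
  if (length(unique(len)) != 1L)
    stop("locus sequences must be aligned to equal length; got ",
         paste(len, collapse = "/"))
  eq <- function(a, b) identical(seqs[[a]], seqs[[b]])
  if (eq("recombinant", "donor")) {
    if (eq("donor", "ancestor")) "K12_EQ_ANC" else "K12_ONLY"
  } else if (eq("recombinant", "ancestor")) {
    "ANC_ONLY"
  } else {
    "NEW_ALLELE"
  }
}

#' Classify a table of replaced loci
#'
#' @param loci data.frame with columns `ancestor, donor, recipient,
#'   recombinant` (variable-site sequences) and optionally
#'   `strong_selection` (logical or "Yes"/"No"); other columns are carried
#'   through.
#' @return `loci` with an added `state` column.
#' @export
classify_loci <- function(loci) {
  required <- c("ancestor", "donor", "recipient", "recombinant")
  if (!all(required %in% names(loci)))
    stop("loci table needs columns ", paste(required, collapse = ", "))
  loci$state <- vapply(seq_len(nrow(loci)), function(i)
    classify_allelic_state(loci$ancestor[i], loci$donor[i],
                           loci$recipient[i], loci$recombinant[i]),
    character(1))
  loci
}

#' Aggregate allelic states over classified loci
#'
#' Counts loci per state and summarizes reversion to the pre-experiment
#' ancestral sequence: a locus "reverted to ancestor" when its state is
#' `K12_EQ_ANC` (donor identical to ancestor) or `ANC_ONLY` (recombinant
#' back to the ancestor despite a different donor).
#'
#' @param classified output of [classify_loci()]; uses `state` and, when
#'   present, `strong_selection`.
#' @return list with `counts` (named integer vector over the four states),
#'   `reverted_to_ancestor`, and `reverted_in_selected_genes` (`NA` when no
#'   `strong_selection` column is supplied).
#' @export
aggregate_states <- function(classified) {
  states <- c("K12_ONLY", "K12_EQ_ANC", "ANC_ONLY", "NEW_ALLELE")
  counts <- vapply(states, function(s) sum(classified$state == s), integer(1))
  reverted <- classified$state %in% c("K12_EQ_ANC", "ANC_ONLY")
  sel <- NA_integer_
  if ("strong_selection" %in% names(classified)) {
    flag <- classified$strong_selection
    if (is.character(flag)) flag <- tolower(flag) %in% c("yes", "true", "1")
    sel <- sum(reverted & flag)
  }
  list(counts = counts,
       reverted_to_ancestor = sum(reverted),
       reverted_in_selected_genes = sel)
}

#' Read the packaged replaced-loci fixture
#'
#' A synthetic variable-site encoding of the 30 replaced loci observed in
#' the odd-numbered non-mutator recombinant clones: for each locus the four
#' aligned sequences (ancestor, donor, recipient, recombinant) realize the
#' published allelic relations, together with the strong-positive-selection
#' annotation. The sequences themselves are constructed, not real; only the
#' relations among them are data.
#'
#' @return data.frame ready for [classify_loci()].
#' @export
replaced_loci_fixture <- function() {
  path <- system.file("extdata", "replaced_loci_synthetic.tsv",
                      package = "introscan", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Detect putative gene-conversion events from clustered new mutations
#'
#' A gene is flagged as a putative gene conversion when any single
#' recombinant genome carries three or more new mutations in it — a cluster
#' far denser than point mutation produces, and the signature of
#' non-reciprocal replacement by a diverged paralog or non-orthologous donor
#' sequence. The threshold is strictly within-genome: two mutations in each
#' of two genomes do not qualify.
#'
#' @param new_mutations data.frame with columns `gene`, `genome`, `pos`
#'   (one row per new mutation).
#' @param min_mutations within-genome threshold (default 3).
#' @return data.frame per flagged gene: `gene, lineages_mutated,
#'   mutation_count, positions_mutated` (distinct positions), sorted by
#'   gene. Zero-row when nothing is flagged.
#' @export
detect_gene_conversion <- function(new_mutations, min_mutations = 3L) {
  empty <- data.frame(gene = character(), lineages_mutated = integer(),
                      mutation_count = integer(),
                      positions_mutated = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(new_mutations) == 0L) return(empty)
  required <- c("gene", "genome", "pos")
  if (!all(required %in% names(new_mutations)))
    stop("new_mutations needs columns ", paste(required, collapse = ", "))
  per <- stats::aggregate(pos ~ gene + genome, data = new_mutations, FUN = length)
  flagged <- unique(per$gene[per$pos >= min_mutations])
  if (length(flagged) == 0L) return(empty)
  rows <- lapply(sort(flagged), function(g) {
    m <- new_mutations[new_mutations$gene == g, , drop = FALSE]
    data.frame(gene = g,
               lineages_mutated = length(unique(m$genome)),
               mutation_count = nrow(m),
               positions_mutated = length(unique(m$pos)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Welch's t-test on G scores of two gene groups
#'
#' Compares the positive-selection G scores of genes hit by putative
#' gene-conversion events against genes carrying the remaining new
#' nonsynonymous mutations, with Welch's unequal-variance t statistic and
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param conversion_gscores,other_gscores numeric G-score vectors (each
#'   n >= 2).
#' @return list `mean1, mean2, statistic, df, p_two_sided`; the p-value is
#'   `NA` when both groups are degenerate (zero variance).
#' @export
gscore_welch_test <- function(conversion_gscores, other_gscores) {
  if (length(conversion_gscores) < 2L || length(other_gscores) < 2L)
    stop("both groups need at least two observations")
  m1 <- mean(conversion_gscores); m2 <- mean(other_gscores)
  if (stats::sd(conversion_gscores) == 0 && stats::sd(other_gscores) == 0) {
    return(list(mean1 = m1, mean2 = m2, statistic = NA_real_, df = NA_real_,
                p_two_sided = NA_real_))
  }
  tt <- stats::t.test(conversion_gscores, other_gscores, var.equal = FALSE)
  list(mean1 = m1, mean2 = m2, statistic = unname(tt$statistic),
       df = unname(tt$parameter), p_two_sided = unname(tt$p.value))
}

#' Recombination-to-mutation ratio of synonymous changes
#'
#' Bounds on the ratio of synonymous changes introduced by recombination to
#' those introduced by mutation, per recombinant clone. Synonymous new
#' mutations in donor-derived segments may themselves be recombination
#' artifacts, so the lower bound counts them in the denominator and the
#' upper bound excludes them:
#' `lower = replacements / (recipient_muts + donor_muts)`,
#' `upper = replacements / recipient_muts`. A bound is undefined (`NA`,
#' printed ND) when its denominator is zero; when there are no
#' donor-segment mutations the two bounds coincide and a single value is
#' reported.
#'
#' @param recombined_replacements synonymous changes introduced by
#'   recombination.
#' @param syn_muts_recipient_segments,syn_muts_donor_segments new synonymous
#'   mutations in recipient- and donor-derived segments.
#' @return list `lower, upper, single` (`single` is `TRUE` when one value
#'   suffices).
#' @examples
#' rec_mut_ratio(8788, 2, 2)   # 2197 - 4394
#' rec_mut_ratio(5228, 0, 1)   # 5228 - ND
#' @export
rec_mut_ratio <- function(recombined_replacements, syn_muts_recipient_segments,
                          syn_muts_donor_segments) {
  stopifnot(recombined_replacements >= 0, syn_muts_recipient_segments >= 0,
            syn_muts_donor_segments >= 0)
  denom_lower <- syn_muts_recipient_segments + syn_muts_donor_segments
  lower <- if (denom_lower > 0) recombined_replacements / denom_lower else NA_real_
  upper <- if (syn_muts_recipient_segments > 0)
    recombined_replacements / syn_muts_recipient_segments else NA_real_
  list(lower = lower, upper = upper,
       single = syn_muts_donor_segments == 0)
}

#' Assign mutations to painted segments
#'
#' Positions are matched to the realized (painted) segment containing them;
#' positions inside boundary uncertainty intervals therefore go to the
#' flanking segment the painting assigned them to.
#'
#' @param pos positions to assign.
#' @param segments segment table from [infer_segments()] (single clone).
#' @return character vector of states (`"DONOR"`/`"RECIPIENT"`) per
#'   position.
#' @export
assign_to_segments <- function(pos, segments) {
  vapply(pos, function(p) {
    hit <- (segments$wraps & (p >= segments$start | p <= segments$end)) |
      (!segments$wraps & p >= segments$start & p <= segments$end)
    if (!any(hit)) stop("position ", p, " not covered by the painting")
    segments$state[which(hit)[1]]
  }, character(1))
}
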