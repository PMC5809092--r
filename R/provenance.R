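#' Provenance labels
#'
#' The five primary label values assigned by [label_mutations()]:
#'
#' * `LTEE` — present in recombinant and its parent recipient, absent from
#'   the donor pool: a mutation that arose in the recipient lineage before
#'   the recombination experiment and persisted.
#' * `K12` — present in the recombinant and in the donor union but not the
#'   recipient: a horizontally transferred donor allele. When the site is
#'   specific to exactly one donor strain, `donor_origin` records which,
#'   giving the four donor-specific sub-categories.
#' * `NEW` — present only in the recombinant: a mutation that arose during
#'   the recombination experiment.
#' * `REL606` — present in the donor union but in neither recipient nor
#'   recombinant: a marker differentiating the donor (K-12) from the
#'   recipient (B/REL606) background, retained in its recipient state. These
#'   sites supply the recipient-side evidence for ancestry painting.
#' * `DELETED` — present in the recipient but missing from the recombinant:
#'   a recipient mutation erased by recombination or lost; the
#'   `in_deleted_region` flag marks those lying inside a large deletion
#'   called in the recombinant.
#' @format character vector of the five primary labels.
#' @export
PROVENANCE_LABELS <- c("LTEE", "K12", "NEW", "REL606", "DELETED")

#' Union of donor call sets
#'
#' @param donors list of donor [call_set()]s (at least one).
#' @return variant table holding the set union of all donor sites (by site
#'   identity), sorted.
#' @export
donor_union <- function(donors) {
  stopifnot(length(donors) >= 1L)
  tabs <- lapply(donors, as_variants)
  all <- do.call(rbind, tabs)
  out <- all[!duplicated(site_key(all)), , drop = FALSE]
  rownames(out) <- NULL
  order_sites(out)
}

#' Donor-specific marker sets
#'
#' A site is specific to donor *d* when it is called in *d* and in no other
#' donor. With a single donor the notion is vacuous and an error is raised.
#'
#' @param donors list of at least two donor [call_set()]s.
#' @return named list (by donor `sample_id`) of variant tables.
#' @export
donor_specific <- function(donors) {
  if (length(donors) < 2L)
    stop("donor specificity requires at least two donors")
  keys <- lapply(donors, function(d) site_key(as_variants(d)))
  counts <- table(unlist(keys))
  out <- lapply(seq_along(donors), function(i) {
    v <- as_variants(donors[[i]])
    v <- v[counts[site_key(v)] == 1L, , drop = FALSE]
    rownames(v) <- NULL
    order_sites(v)
  })
  stats::setNames(out, vapply(donors, function(d) d$sample_id, character(1)))
}

#' Label every variant in a recombinant genome by provenance
#'
#' Classifies each site appearing in the recombinant, its parent recipient,
#' or the donor union, by set algebra over the three call-set memberships
#' (R = recombinant, P = parent recipient, D = donor union):
#'
#' | R | P | D | label |
#' |---|---|---|-------|
#' | x | x | x | ignored (identical in all genomes, uninformative) |
#' | x | x |   | `LTEE` |
#' | x |   | x | `K12` (+ `donor_origin` when donor-specific) |
#' | x |   |   | `NEW` |
#' |   | x | x | `DELETED` |
#' |   | x |   | `DELETED` (`in_deleted_region` when inside a recombinant deletion) |
#' |   |   | x | `REL606` (dropped with a logged count when inside a recombinant deletion) |
#'
#' `K12` additionally requires absence from the recipient so that the
#' recipient-shared category (`LTEE`) and the transferred category are
#' disjoint; a marker present in both parents carries no ancestry signal.
#'
#' @param recombinant,recipient [call_set()]s sharing the reference.
#' @param donors list of donor [call_set()]s.
#' @param ref_length reference chromosome length (bp); positions beyond it
#'   are an error.
#' @return data.frame with columns `chrom, pos, kind, alt, gene, syn, label,
#'   in_deleted_region, donor_origin, recombinant_id`, sorted by site
#'   identity.
#' @export
label_mutations <- function(recombinant, recipient, donors, ref_length = NULL) {
  rec <- as_variants(recombinant)
  par <- as_variants(recipient)
  dun <- donor_union(donors)
  if (!is.null(ref_length) && any(rec$pos > ref_length))
    stop("recombinant has site(s) beyond the reference length (",
         format_span(ref_length), " bp)")

  universe <- rbind(rec, par, dun)
  universe <- universe[!duplicated(site_key(universe)), , drop = FALSE]
  k <- site_key(universe)
  in_rec <- k %in% site_key(rec)
  in_par <- k %in% site_key(par)
  in_don <- k %in% site_key(dun)

  label <- rep(NA_character_, nrow(universe))
  label[in_rec & in_par & !in_don] <- "LTEE"
  label[in_rec & !in_par & in_don] <- "K12"
  label[in_rec & !in_par & !in_don] <- "NEW"
  label[!in_rec & in_par] <- "DELETED"
  label[!in_rec & !in_par & in_don] <- "REL606"
  # R & P & D stays NA: identical across all genomes, explicitly ignored.

  out <- universe
  out$label <- label
  out <- out[!is.na(out$label), , drop = FALSE]

  out$in_deleted_region <- FALSE
  deld <- out$label == "DELETED"
  if (any(deld))
    out$in_deleted_region[deld] <-
      in_deletion(out$chrom[deld], out$pos[deld], rec)

  # Donor-side markers erased by a recombinant deletion are unusable for
  # painting: drop them with a logged count.
  relm <- out$label == "REL606"
  if (any(relm)) {
    gone <- relm & in_deletion(out$chrom, out$pos, rec)
    if (any(gone)) {
      message(sum(gone), " donor marker(s) inside recombinant deletions dropped")
      out <- out[!gone, , drop = FALSE]
    }
  }

  out$donor_origin <- NA_character_
  if (length(donors) >= 2L) {
    spec <- donor_specific(donors)
    k12 <- which(out$label == "K12")
    if (length(k12) > 0L) {
      kk <- site_key(out[k12, , drop = FALSE])
      for (d in names(spec)) {
        hit <- kk %in% site_key(spec[[d]])
        out$donor_origin[k12[hit]] <- d
      }
    }
  }
  out$recombinant_id <- if (inherits(recombinant, "call_set"))
    recombinant$sample_id else NA_character_
  out <- order_sites(out)
  rownames(out) <- NULL
  out
}

#' Count donor-specific markers per recombinant clone
#'
#' Tabulates, for each clone and each donor, how many transferred sites are
#' attributable to that specific donor (`label == "K12"` with a
#' `donor_origin`). Clones with no donor DNA get a row of zeros.
#'
#' @param labeled_list named list of labeled tables (one per clone, from
#'   [label_mutations()]); names are clone ids (fall back to the tables'
#'   `recombinant_id`).
#' @param donor_ids donor sample ids defining the columns; defaults to all
#'   donors observed across clones.
#' @return data.frame: one row per clone, one count column per donor.
#' @export
donor_marker_counts <- function(labeled_list, donor_ids = NULL) {
  if (is.null(names(labeled_list)))
    names(labeled_list) <- vapply(labeled_list, function(x)
      x$recombinant_id[1] %||% NA_character_, character(1))
  if (is.null(donor_ids)) {
    donor_ids <- sort(unique(unlist(lapply(labeled_list, function(x)
      stats::na.omit(x$donor_origin)))))
  }
  rows <- lapply(names(labeled_list), function(cl) {
    x <- labeled_list[[cl]]
    hits <- x$donor_origin[x$label == "K12" & !is.na(x$donor_origin)]
    counts <- vapply(donor_ids, function(d) sum(hits == d), integer(1))
    cbind(data.frame(clone_id = cl, stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)))
  })
  out <- do.call(rbind, rows)
  names(out) <- c("clone_id", donor_ids)
  rownames(out) <- NULL
  out
}
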