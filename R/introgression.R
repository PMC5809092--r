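#' Partition a genome into fixed-width bins
#'
#' Bins are half-open `[start, start + bin_size)` internally and reported
#' 1-based inclusive; the last bin is truncated when `genome_length` is not
#' divisible by `bin_size`. `n_bins = ceiling(genome_length / bin_size)`.
#'
#' @param genome_length,bin_size both in bp, both >= 1.
#' @return an object of class `genome_binning` with fields `genome_length`,
#'   `bin_size`, `n_bins`, a data.frame `bins` (`bin, start, end`), and a
#'   `bin_index(pos)` function mapping positions to bin numbers.
#' @examples
#' make_binning(4629812, 8327)$n_bins  # 556
#' @export
make_binning <- function(genome_length, bin_size) {
  if (genome_length < 1 || bin_size < 1)
    stop("genome_length and bin_size must be >= 1")
  n_bins <- as.integer(ceiling(genome_length / bin_size))
  starts <- 1 + (seq_len(n_bins) - 1) * bin_size
  ends <- pmin(starts + bin_size - 1, genome_length)
  bin_index <- function(pos) {
    if (any(pos < 1 | pos > genome_length))
      stop("position(s) outside [1, genome_length]")
    as.integer((pos - 1) %/% bin_size + 1)
  }
  structure(list(genome_length = genome_length, bin_size = bin_size,
                 n_bins = n_bins,
                 bins = data.frame(bin = seq_len(n_bins), start = starts,
                                   end = ends),
                 bin_index = bin_index),
            class = "genome_binning")
}

#' @export
print.genome_binning <- function(x, ...) {
  cat(sprintf("<genome_binning> %d bins of %s bp over %s bp\n",
              x$n_bins, format(x$bin_size, big.mark = ","),
              format(x$genome_length, big.mark = ",")))
  invisible(x)
}

#' Count sites per bin
#'
#' @param pos positions of sites (e.g. differentiating-marker positions for
#'   a divergence profile).
#' @param binning a [make_binning()] object.
#' @return integer vector of length `n_bins`; sums to `length(pos)`.
#' @export
bin_counts <- function(pos, binning) {
  tabulate(binning$bin_index(pos), nbins = binning$n_bins)
}

#' Parallel-introgression profile across clones
#'
#' For every site that differentiates the donor (K-12) and recipient (B)
#' backgrounds, counts in how many of the included clones the donor allele
#' is present (provenance label `K12`). Differentiating sites are the union,
#' over included clones, of sites labeled `K12` or `REL606`. Pass one clone
#' per population to count parallel introgression across populations, and
#' use `exclude` to omit aberrant lineages.
#'
#' @param labeled_list named list of labeled tables from [label_mutations()].
#' @param exclude clone names to omit (a warning is issued for names not
#'   found).
#' @return data.frame `chrom, pos, kind, alt, count` sorted by site, with
#'   attribute `n_clones` = number of included clones. Counts lie in
#'   `[0, n_clones]`.
#' @export
parallel_introgression <- function(labeled_list, exclude = character()) {
  if (is.null(names(labeled_list)))
    names(labeled_list) <- vapply(labeled_list, function(x)
      x$recombinant_id[1], character(1))
  missing <- setdiff(exclude, names(labeled_list))
  if (length(missing) > 0L)
    warning("excluded clone(s) not found: ", paste(missing, collapse = ", "))
  keep <- setdiff(names(labeled_list), exclude)
  labeled_list <- labeled_list[keep]
  marker_rows <- lapply(labeled_list, function(x)
    x[x$label %in% c("K12", "REL606"),
      c("chrom", "pos", "kind", "alt"), drop = FALSE])
  markers <- do.call(rbind, marker_rows)
  if (is.null(markers) || nrow(markers) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(), kind = character(),
                      alt = character(), count = integer())
    attr(out, "n_clones") <- length(labeled_list)
    return(out)
  }
  markers <- markers[!duplicated(site_key(markers)), , drop = FALSE]
  mk <- site_key(markers)
  count <- integer(nrow(markers))
  for (x in labeled_list) {
    kk <- site_key(x[x$label == "K12", , drop = FALSE])
    count <- count + (mk %in% kk)
  }
  markers$count <- count
  out <- order_sites(markers)
  rownames(out) <- NULL
  attr(out, "n_clones") <- length(labeled_list)
  out
}

#' Parallel-fixation profile from inferred LCA haplotypes
#'
#' Same counting as [parallel_introgression()], but over the donor markers
#' inferred fixed in each population's last common ancestor (see
#' [infer_lca()]): for each site, the number of included populations whose
#' LCA set contains it. Because every LCA set is a subset of the clones'
#' transferred sites, this profile is pointwise bounded by the
#' clone-presence profile.
#'
#' @param lca_list named list of variant tables (one fixed-haplotype set per
#'   population).
#' @param exclude population names to omit.
#' @return data.frame `chrom, pos, kind, alt, count` with attribute
#'   `n_populations`.
#' @export
fixed_marker_profile <- function(lca_list, exclude = character()) {
  missing <- setdiff(exclude, names(lca_list))
  if (length(missing) > 0L)
    warning("excluded population(s) not found: ", paste(missing, collapse = ", "))
  lca_list <- lca_list[setdiff(names(lca_list), exclude)]
  tabs <- lapply(lca_list, function(x)
    as_variants(x)[, c("chrom", "pos", "kind", "alt"), drop = FALSE])
  all <- do.call(rbind, tabs)
  if (is.null(all) || nrow(all) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(), kind = character(),
                      alt = character(), count = integer())
    attr(out, "n_populations") <- length(lca_list)
    return(out)
  }
  sites <- all[!duplicated(site_key(all)), , drop = FALSE]
  sk <- site_key(sites)
  count <- integer(nrow(sites))
  for (x in tabs) count <- count + (sk %in% site_key(x))
  sites$count <- count
  out <- order_sites(sites)
  rownames(out) <- NULL
  attr(out, "n_populations") <- length(lca_list)
  out
}

#' Natural-cubic-spline smoothing of a genome profile
#'
#' Least-squares regression of the profile counts on a natural cubic spline
#' basis with the requested degrees of freedom (default 100), knots placed
#' at quantiles of the marker positions (scale-invariant). The fit is an
#' ordinary linear model, hence deterministic.
#'
#' @param profile data.frame with columns `pos` and `count`.
#' @param df effective degrees of freedom of the spline basis.
#' @return `profile` with an added `smoothed` column.
#' @export
smooth_profile <- function(profile, df = 100L) {
  stopifnot(all(c("pos", "count") %in% names(profile)))
  if (nrow(profile) < df + 1L)
    stop("need at least df + 1 = ", df + 1L, " points, got ", nrow(profile))
  basis <- splines::ns(profile$pos, df = df)
  fit <- stats::lm.fit(cbind(1, basis), profile$count)
  profile$smoothed <- as.numeric(cbind(1, basis) %*% fit$coefficients)
  profile
}

#' Divergence-versus-events tests on binned profiles
#'
#' Given a per-bin divergence profile (counts of K-12-vs-B differentiating
#' markers) and a per-bin event count (parallel introgressions or
#' recombination breakpoints), computes (i) the Spearman rank correlation
#' between divergence and event counts (tie-handled) and (ii) a
#' Kruskal-Wallis test comparing the divergence of bins with versus without
#' events.
#'
#' @param divergence,events equal-length per-bin count vectors.
#' @return list `spearman_r, spearman_p, kw_p`; correlation entries are `NA`
#'   (undefined) when either vector is constant, and `kw_p` is `NA` when all
#'   bins fall in one event class.
#' @export
divergence_tests <- function(divergence, events) {
  if (length(divergence) != length(events))
    stop("divergence and events must have the same length (one per bin)")
  r <- p <- NA_real_
  if (stats::sd(divergence) > 0 && stats::sd(events) > 0) {
    ct <- suppressWarnings(
      stats::cor.test(divergence, events, method = "spearman"))
    r <- unname(ct$estimate)
    p <- unname(ct$p.value)
  }
  has <- events > 0
  kw_p <- NA_real_
  if (length(unique(has)) == 2L)
    kw_p <- unname(stats::kruskal.test(divergence, factor(has))$p.value)
  list(spearman_r = r, spearman_p = p, kw_p = kw_p)
}

#' Assign recombination breakpoints to bins
#'
#' Segment boundaries are intervals, not points: the true breakpoint lies
#' between the last same-state marker of the left segment and the first
#' same-state marker of the right segment. Each boundary is assigned to the
#' bin containing the midpoint of that inter-marker uncertainty interval
#' (falling back to the realized boundary when markers are not supplied).
#'
#' @param segments a segment table from [infer_segments()] (single clone).
#' @param binning a [make_binning()] object.
#' @param markers optional `pos`/`type` marker table used to delimit the
#'   uncertainty intervals.
#' @return integer vector of per-bin breakpoint counts.
#' @export
breakpoints_per_bin <- function(segments, binning, markers = NULL) {
  if (nrow(segments) < 2L) return(integer(binning$n_bins))
  mids <- numeric(nrow(segments) - 1L)
  for (i in seq_len(nrow(segments) - 1L)) {
    lo <- segments$end[i]
    hi <- segments$start[i + 1L]
    if (!is.null(markers)) {
      lt <- if (segments$state[i] == "DONOR") "K12" else "B"
      rt <- if (segments$state[i + 1L] == "DONOR") "K12" else "B"
      lm <- markers$pos[markers$type == lt & markers$pos <= segments$end[i]]
      rm <- markers$pos[markers$type == rt & markers$pos >= segments$start[i + 1L]]
      if (length(lm) > 0L) lo <- max(lm)
      if (length(rm) > 0L) hi <- min(rm)
    }
    mids[i] <- (lo + hi) / 2
  }
  mids <- pmin(pmax(round(mids), 1), binning$genome_length)
  tabulate(binning$bin_index(mids), nbins = binning$n_bins)
}
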