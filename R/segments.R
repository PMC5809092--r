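#' Paint a chromosome into donor/recipient ancestry segments
#'
#' Implements the alternating state machine used to delimit donor- and
#' recipient-derived tracts from an ordered sequence of differentiating
#' markers. A `K12` marker is a donor allele observed in the recombinant; a
#' `B` marker is a differentiating site at which the recombinant retains the
#' recipient allele. True recombination breakpoints lie somewhere between a
#' donor-specific and a recipient-specific marker, so any painting is an
#' estimate: this one takes the minimal estimate on the left edge of a donor
#' segment (the segment starts at its first `K12` marker) and the maximal
#' estimate on the right edge (it ends at the next `B` marker), which makes
#' average segment lengths tend to the midpoint of the min/max estimates.
#'
#' Scanning left to right, the state switches exactly at each first marker
#' of the alternate type. The segment containing the first marker extends
#' left to position 1 (a convention; in circular mode the closure step
#' re-joins the origin anyway). If the first and last segments of a circular
#' chromosome share a state they are merged into one wrapping segment
#' (`wraps = TRUE`, with `start > end`).
#'
#' @param markers data.frame with columns `pos` (sorted ascending) and
#'   `type` (`"K12"` or `"B"`).
#' @param genome_length chromosome length in bp.
#' @param circular merge first/last segments across the origin when they
#'   share a state.
#' @param clone_id optional clone label carried into the output.
#' @return data.frame of segments: `clone_id, start, end, wraps, state,
#'   n_markers, length`. With no markers, a single `RECIPIENT` segment
#'   spanning the genome. Segments tile `[1, genome_length]` with no gaps or
#'   overlaps and alternate states.
#' @examples
#' m <- data.frame(pos = c(100, 200, 300, 400), type = c("B", "K12", "K12", "B"))
#' infer_segments(m, 1000, circular = FALSE)
#' @export
infer_segments <- function(markers, genome_length, circular = TRUE,
                           clone_id = NA_character_) {
  stopifnot(genome_length >= 1)
  if (is.null(markers) || nrow(markers) == 0L) {
    return(data.frame(clone_id = clone_id, start = 1L,
                      end = as.integer(genome_length), wraps = FALSE,
                      state = "RECIPIENT", n_markers = 0L,
                      length = as.integer(genome_length),
                      stringsAsFactors = FALSE))
  }
  if (is.unsorted(markers$pos))
    stop("markers must be sorted by position")
  if (any(markers$pos < 1 | markers$pos > genome_length))
    stop("marker positions must lie in [1, genome_length]")
  bad <- setdiff(unique(markers$type), c("K12", "B"))
  if (length(bad) > 0L) stop("unknown marker type(s): ", paste(bad, collapse = ", "))

  state_of <- function(type) if (type == "K12") "DONOR" else "RECIPIENT"
  pos <- markers$pos
  type <- markers$type

  starts <- 1L
  states <- state_of(type[1])
  ends <- integer(0)
  cur <- type[1]
  for (i in seq_along(pos)) {
    if (type[i] != cur) {
      if (cur == "K12") {
        # donor segment extends to the alternate (B) marker: maximal right
        ends <- c(ends, as.integer(pos[i]))
        starts <- c(starts, as.integer(pos[i]) + 1L)
      } else {
        # donor segment starts exactly at its first K12 marker: minimal left
        ends <- c(ends, as.integer(pos[i]) - 1L)
        starts <- c(starts, as.integer(pos[i]))
      }
      states <- c(states, state_of(type[i]))
      cur <- type[i]
    }
  }
  ends <- c(ends, as.integer(genome_length))

  seg <- data.frame(clone_id = clone_id, start = starts, end = ends,
                    wraps = FALSE, state = states, stringsAsFactors = FALSE)

  # A B marker immediately followed by a K12 marker leaves a degenerate
  # (empty) recipient segment between two donor segments; drop it and merge
  # its donor neighbours so that states keep alternating.
  while (any(deg <- seg$end < seg$start)) {
    i <- which(deg)[1]
    if (i > 1L && i < nrow(seg)) {
      seg$end[i - 1L] <- seg$end[i + 1L]
      seg <- seg[-c(i, i + 1L), , drop = FALSE]
    } else {
      seg <- seg[-i, , drop = FALSE]
    }
  }

  if (circular && nrow(seg) > 1L) {
    n <- nrow(seg)
    if (seg$state[1] == seg$state[n]) {
      seg$start[1] <- seg$start[n]
      seg$wraps[1] <- TRUE
      seg <- seg[-n, , drop = FALSE]
    } else {
      # apply the same switch rules across the origin: the junction between
      # the last marker and the first marker is an ordinary state switch
      p1 <- as.integer(pos[1])
      if (seg$state[1] == "DONOR") {
        # donor min-left: the leading donor segment starts at its first K12
        # marker; the recipient tail wraps up to just before it
        if (p1 > 1L) {
          seg$start[1] <- p1
          seg$end[n] <- p1 - 1L
          seg$wraps[n] <- seg$start[n] > seg$end[n]
        }
      } else {
        # donor max-right: the trailing donor segment extends through the
        # origin to the first B marker
        seg$end[n] <- p1
        seg$wraps[n] <- seg$start[n] > seg$end[n]
        seg$start[1] <- p1 + 1L
        if (seg$start[1] > seg$end[1]) {
          # the leading recipient segment was squeezed out entirely: its
          # donor neighbours meet across it
          seg <- seg[-1, , drop = FALSE]
          n <- nrow(seg)
          if (n > 1L && seg$state[1] == seg$state[n]) {
            seg$start[1] <- seg$start[n]
            seg$wraps[1] <- TRUE
            seg <- seg[-n, , drop = FALSE]
          }
        }
      }
    }
  }

  seg$n_markers <- vapply(seq_len(nrow(seg)), function(i) {
    want <- if (seg$state[i] == "DONOR") "K12" else "B"
    inside <- if (seg$wraps[i])
      pos >= seg$start[i] | pos <= seg$end[i]
    else
      pos >= seg$start[i] & pos <= seg$end[i]
    sum(inside & type == want)
  }, integer(1))
  seg$length <- ifelse(seg$wraps,
                       as.integer(genome_length) - seg$start + 1L + seg$end,
                       seg$end - seg$start + 1L)
  rownames(seg) <- NULL
  seg
}

#' Painting markers from a labeled table
#'
#' Converts provenance labels into the two painting marker types:
#' transferred donor alleles (`label == "K12"`) become `K12` markers, and
#' differentiating sites at which the recombinant retains the recipient
#' allele (`label == "REL606"`) become `B` markers — the absence of the
#' donor allele at a differentiating site is positive evidence of recipient
#' ancestry.
#'
#' @param labeled a labeled table from [label_mutations()].
#' @return data.frame `pos, type` sorted by position, ready for
#'   [infer_segments()].
#' @export
painting_markers <- function(labeled) {
  keep <- labeled$label %in% c("K12", "REL606")
  out <- data.frame(pos = labeled$pos[keep],
                    type = ifelse(labeled$label[keep] == "K12", "K12", "B"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment-length summary
#'
#' Splits painted segments into per-clone, per-state sorted length lists and
#' log10-scale histogram bins, the representation used to compare length
#' distributions across recombinant lineages.
#'
#' @param segments a segment data.frame (possibly several clones row-bound).
#' @param n_bins number of log10-spaced histogram bins.
#' @return list with `lengths` (nested list: clone -> state -> sorted bp
#'   lengths) and `histogram` (data.frame of log10 bin edges and counts per
#'   clone/state).
#' @export
length_distribution <- function(segments, n_bins = 20L) {
  clones <- unique(segments$clone_id)
  lengths <- lapply(stats::setNames(clones, clones), function(cl) {
    s <- segments[segments$clone_id %in% cl, , drop = FALSE]
    list(DONOR = sort(s$length[s$state == "DONOR"]),
         RECIPIENT = sort(s$length[s$state == "RECIPIENT"]))
  })
  all_len <- unlist(lengths, use.names = FALSE)
  hist <- NULL
  if (length(all_len) > 0L) {
    edges <- seq(0, max(log10(max(all_len)), 1), length.out = n_bins + 1L)
    rows <- list()
    for (cl in clones) for (st in c("DONOR", "RECIPIENT")) {
      x <- lengths[[as.character(cl)]][[st]]
      if (length(x) == 0L) next
      bin <- pmin(pmax(findInterval(log10(x), edges, rightmost.closed = TRUE),
                       1L), n_bins)
      cnt <- tabulate(bin, nbins = n_bins)
      rows[[length(rows) + 1L]] <- data.frame(
        clone_id = cl, state = st, log10_lo = edges[-length(edges)],
        log10_hi = edges[-1], count = cnt, stringsAsFactors = FALSE)
    }
    hist <- do.call(rbind, rows)
  }
  structure(list(lengths = lengths, histogram = hist),
            class = "segment_length_summary")
}

#' Kruskal-Wallis heterogeneity test on segment lengths
#'
#' Tests whether donor-derived segment lengths differ in distribution across
#' recombinant lineages, using the Kruskal-Wallis rank-sum test with tie
#' correction (df = number of groups - 1). For very small samples an exact
#' permutation p-value can be computed by enumerating all assignments of the
#' observations to groups.
#'
#' @param groups list of numeric vectors of segment lengths, one per clone;
#'   each must be nonempty.
#' @param exact compute the permutation p-value (feasible only for small
#'   total n); default uses the chi-squared approximation.
#' @return list with `statistic` (H, tie-corrected), `df`, and `p_value`.
#' @export
length_heterogeneity_test <- function(groups, exact = FALSE) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 1L))
    stop("every group needs at least one observation")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(x, g)
  p <- unname(kt$p.value)
  if (exact) {
    p <- kw_exact_p(x, g, unname(kt$statistic))
  }
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = p)
}

# Exact permutation p-value: enumerate every distinct assignment of the
# pooled observations to groups of the observed sizes and compare H.
kw_exact_p <- function(x, g, h_obs) {
  n <- length(x)
  if (n > 10L) stop("exact enumeration is limited to n <= 10")
  sizes <- table(g)
  perms <- group_assignments(seq_len(n), as.integer(sizes))
  hs <- vapply(perms, function(idx) {
    gg <- factor(rep(seq_along(sizes), as.integer(sizes)))
    unname(stats::kruskal.test(x[idx], gg)$statistic)
  }, numeric(1))
  mean(hs >= h_obs - 1e-12)
}

# All ways to split `items` into ordered groups of the given sizes.
group_assignments <- function(items, sizes) {
  if (length(sizes) == 1L) return(list(items))
  first <- utils::combn(seq_along(items), sizes[1], simplify = FALSE)
  out <- list()
  for (f in first) {
    rest <- group_assignments(items[-f], sizes[-1])
    out <- c(out, lapply(rest, function(r) c(items[f], r)))
  }
  out
}

#' Maximum length bound of an introgressed tract from flanking markers
#'
#' Given the last position known to retain the recipient state and the first
#' donor-side differentiating marker NOT introduced by the event, the
#' replaced tract can be at most their difference long. Amino-acid
#' coordinates convert to bp at 3 bp per residue.
#'
#' @param last_untouched_pos last recipient-state position (aa or bp).
#' @param first_absent_donor_marker_pos first donor marker position beyond
#'   the tract (same units); must exceed `last_untouched_pos`.
#' @param units `"aa"` or `"bp"`.
#' @return list with `bound` (in the input units) and `bound_bp`.
#' @examples
#' max_introgression_bound(144, 364, "aa")  # 220 aa = 660 bp
#' @export
max_introgression_bound <- function(last_untouched_pos,
                                    first_absent_donor_marker_pos,
                                    units = c("bp", "aa")) {
  units <- match.arg(units)
  d <- first_absent_donor_marker_pos - last_untouched_pos
  if (d <= 0) stop("first absent donor marker must lie beyond the last untouched position")
  list(bound = d, units = units, bound_bp = if (units == "aa") 3 * d else d)
}
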