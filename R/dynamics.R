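#' Allele-frequency change between two population samples
#'
#' Matches sites by identity across the two timepoints of a continuation
#' experiment (conjugation stopped) and computes per-site trajectories.
#' Sites absent from one sample have frequency 0 there: the caller reports
#' only variant sites, so absence means the reference (recipient) allele.
#'
#' @param pop_t0,pop_t1 population-role [call_set()]s from the same
#'   population at the initial and final timepoints.
#' @param position_bin_size optional bp width used to add a `position_bin`
#'   grouping column (sites close on the chromosome likely share a
#'   haplotype); `NULL` omits it.
#' @return data.frame `chrom, pos, kind, alt, f0, f1, delta, direction`
#'   (`"up"`, `"down"`, `"flat"`), sorted by site.
#' @export
frequency_change <- function(pop_t0, pop_t1, position_bin_size = NULL) {
  stopifnot(pop_t0$role == "population", pop_t1$role == "population")
  v0 <- as_variants(pop_t0); v1 <- as_variants(pop_t1)
  if (any(!is.na(c(v0$freq, v1$freq)) & (c(v0$freq, v1$freq) < 0 |
                                         c(v0$freq, v1$freq) > 1)))
    stop("frequencies must lie in [0, 1]")
  u <- rbind(v0[, c("chrom", "pos", "kind", "alt")],
             v1[, c("chrom", "pos", "kind", "alt")])
  u <- u[!duplicated(site_key(u)), , drop = FALSE]
  k <- site_key(u)
  f0 <- v0$freq[match(k, site_key(v0))]
  f1 <- v1$freq[match(k, site_key(v1))]
  u$f0 <- ifelse(is.na(f0), 0, f0)
  u$f1 <- ifelse(is.na(f1), 0, f1)
  u$delta <- u$f1 - u$f0
  u$direction <- ifelse(u$delta > 0, "up", ifelse(u$delta < 0, "down", "flat"))
  if (!is.null(position_bin_size))
    u$position_bin <- as.integer((u$pos - 1) %/% position_bin_size + 1)
  u <- order_sites(u)
  rownames(u) <- NULL
  u
}

#' Infer the fixed haplotype of a population's last common ancestor
#'
#' A mutation is inferred present in the last common ancestor of a
#' population when it is at 100% frequency in both the initial and final
#' population samples of the continuation experiment AND present in both
#' recombinant clones isolated from that population: the four-set
#' intersection. "Frequency equal to 1" is taken literally, with a 1e-9
#' float tolerance.
#'
#' @param pop_t0,pop_t1 population-role [call_set()]s.
#' @param clone_a,clone_b the two sequenced recombinant clones.
#' @param population_id label carried into the result.
#' @return list of class `fixed_haplotype` with `population_id` and `sites`
#'   (a variant table).
#' @export
infer_lca <- function(pop_t0, pop_t1, clone_a, clone_b,
                      population_id = NA_character_) {
  eps <- 1e-9
  v0 <- as_variants(pop_t0); v1 <- as_variants(pop_t1)
  fixed0 <- v0[!is.na(v0$freq) & v0$freq >= 1 - eps, , drop = FALSE]
  k <- site_key(fixed0)
  keep <- k %in% site_key(v1[!is.na(v1$freq) & v1$freq >= 1 - eps, , drop = FALSE]) &
    k %in% site_key(as_variants(clone_a)) &
    k %in% site_key(as_variants(clone_b))
  sites <- order_sites(fixed0[keep, , drop = FALSE])
  sites$freq <- NA_real_
  rownames(sites) <- NULL
  structure(list(population_id = population_id, sites = sites),
            class = "fixed_haplotype")
}

#' @export
print.fixed_haplotype <- function(x, ...) {
  cat(sprintf("<fixed_haplotype> %s: %d sites fixed in the LCA\n",
              x$population_id, nrow(x$sites)))
  invisible(x)
}

#' Plasmid frequency from relative read coverage
#'
#' Estimates the fraction of cells carrying a plasmid as the ratio of mean
#' plasmid coverage to mean chromosome coverage, assuming one chromosome
#' per cell and one plasmid per plasmid-bearing cell. Values above 1
#' indicate multi-copy plasmids and are flagged, not clipped.
#'
#' @param chrom_cov,plasmid_cov mean reads per site on the chromosome and
#'   plasmid; `chrom_cov` must be positive. Alternatively pass a one-row
#'   data.frame with `chrom_cov`/`plasmid_cov` columns as the first
#'   argument.
#' @return list `frequency` (unrounded), `multicopy` (logical). Round with
#'   `signif(frequency, 2)` to report at two significant figures.
#' @examples
#' signif(plasmid_frequency(686.9, 250.3)$frequency, 2)  # 0.36
#' @export
plasmid_frequency <- function(chrom_cov, plasmid_cov = NULL) {
  if (is.data.frame(chrom_cov)) {
    plasmid_cov <- chrom_cov$plasmid_cov
    chrom_cov <- chrom_cov$chrom_cov
  }
  if (any(chrom_cov <= 0)) stop("chromosome coverage must be positive")
  if (any(plasmid_cov < 0)) stop("plasmid coverage must be nonnegative")
  f <- plasmid_cov / chrom_cov
  list(frequency = f, multicopy = f > 1)
}

#' Fixation probability of a neutral allele under the sweep ratchet
#'
#' Under the hitchhiking-ratchet model, a neutral donor-derived allele
#' currently at frequency `p` is driven to fixation by the next clonal
#' sweep with probability `p` (the sweep founder is a uniform draw from the
#' population) and to extinction with probability `1 - p`.
#'
#' @param p allele frequency in `[0, 1]`.
#' @return `p`, after validation.
#' @export
ratchet_fixation_probability <- function(p) {
  if (any(p < 0 | p > 1)) stop("frequency must lie in [0, 1]")
  p
}
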