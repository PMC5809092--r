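#' Conjugation parameters
#'
#' Parameters of the Hfr transfer-decay law and of the pulsed-conjugation
#' regime. The decay law is anchored at two distances from the transfer
#' origin: per-exposure transfer probability `p_near` at `d_near` bp
#' (default 10^-2.5 at 100 kb) declining log-linearly to `p_far` at `d_far`
#' bp (default 10^-6 at 2.3 Mb), flat below `d_near`, and zero beyond
#' `max_fraction_transferred` of the chromosome (the most DNA a mating can
#' move in one exposure, default 60%).
#'
#' @param p_near transfer probability at `d_near` from oriT.
#' @param p_far transfer probability at `d_far` from oriT; must be below
#'   `p_near`.
#' @param d_near,d_far anchor distances in bp.
#' @param donor_recipient_ratio donor:recipient cell ratio during a pulse.
#' @param max_fraction_transferred fraction of the chromosome transferable
#'   in one mating, in (0, 1].
#' @param cycle_interval_generations generations between conjugation pulses.
#' @param n_cycles number of conjugation pulses.
#' @param matings_per_cell_per_pulse donor contacts per recipient cell per
#'   pulse (donors are in excess, and a one-hour exposure allows repeated
#'   contacts).
#' @param fragmentation_rate per-kb probability that a transferred tract is
#'   broken into mosaic pieces with untouched gaps (default 0: contiguous
#'   integration).
#' @param selection_on discard recombinants that acquire a donor auxotrophy
#'   allele (purifying selection in minimal medium).
#' @return a list of class `conjugation_params`.
#' @export
conjugation_params <- function(p_near = 10^-2.5, p_far = 1e-6,
                               d_near = 1e5, d_far = 2.3e6,
                               donor_recipient_ratio = 4,
                               max_fraction_transferred = 0.6,
                               cycle_interval_generations = 33L,
                               n_cycles = 30L,
                               matings_per_cell_per_pulse = 20L,
                               fragmentation_rate = 0,
                               selection_on = TRUE) {
  stopifnot(p_far < p_near, p_near <= 1, d_near < d_far,
            max_fraction_transferred > 0, max_fraction_transferred <= 1)
  structure(list(p_near = p_near, p_far = p_far, d_near = d_near,
                 d_far = d_far, donor_recipient_ratio = donor_recipient_ratio,
                 max_fraction_transferred = max_fraction_transferred,
                 cycle_interval_generations = as.integer(cycle_interval_generations),
                 n_cycles = as.integer(n_cycles),
                 matings_per_cell_per_pulse = as.integer(matings_per_cell_per_pulse),
                 fragmentation_rate = fragmentation_rate,
                 selection_on = selection_on),
            class = "conjugation_params")
}

#' Rescale decay-law anchor distances to a smaller chromosome
#'
#' The anchor distances of the transfer-decay law refer to a ~4.6-Mb
#' chromosome. Simulations on a scaled-down chromosome keep the decay
#' geometry (the shape of the law relative to chromosome length) by scaling
#' the anchor distances by `genome_length / reference_length`; the anchor
#' probabilities are untouched.
#'
#' @param params a [conjugation_params()].
#' @param genome_length simulated chromosome length (bp).
#' @param reference_length chromosome length the anchors refer to.
#' @return rescaled `conjugation_params`.
#' @export
scale_decay_distances <- function(params, genome_length,
                                  reference_length = 4629812) {
  f <- genome_length / reference_length
  params$d_near <- params$d_near * f
  params$d_far <- params$d_far * f
  params
}

#' Transfer probability at a distance from oriT
#'
#' @param distance distance(s) from the transfer origin, in bp along the
#'   direction of transfer; must be nonnegative.
#' @param params a [conjugation_params()].
#' @param genome_length chromosome length (bp), needed for the
#'   `max_fraction_transferred` cutoff.
#' @return per-exposure probability that a locus at that distance is
#'   transferred: flat at `p_near` below `d_near`, log-linear decay through
#'   the two anchors, zero beyond the cutoff.
#' @export
transfer_probability <- function(distance, params, genome_length) {
  if (any(distance < 0)) stop("distance must be nonnegative")
  slope <- (log10(params$p_far) - log10(params$p_near)) /
    (params$d_far - params$d_near)
  lp <- log10(params$p_near) + pmax(distance - params$d_near, 0) * slope
  p <- 10^lp
  cutoff <- params$max_fraction_transferred * genome_length
  p[distance > cutoff] <- 0
  p
}

# Inverse of the decay law as a survival function of tract length: draws n
# transfer lengths (0 = no transfer) from u ~ U(0,1) with
# P(length >= d) = transfer_probability(d).
draw_transfer_lengths <- function(n, params, genome_length) {
  u <- stats::runif(n)
  slope <- (log10(params$p_far) - log10(params$p_near)) /
    (params$d_far - params$d_near)
  len <- numeric(n)
  ok <- u <= params$p_near
  len[ok] <- params$d_near + (log10(u[ok]) - log10(params$p_near)) / slope
  cutoff <- params$max_fraction_transferred * genome_length
  pmin(len, cutoff)
}

#' Generate a divergent-marker landscape
#'
#' Draws the sites that differentiate the donor (K-12-like) and recipient
#' (B-like) backgrounds: marker positions are uniform on the chromosome at
#' the requested density, each with a donor-side allele. A configurable
#' fraction of markers is specific to a single (uniformly chosen) donor
#' strain; the rest are shared by all donors.
#'
#' @param genome_length chromosome length in bp.
#' @param markers_per_kb expected marker density (the two source strains
#'   differ by ~8 mutations per kb).
#' @param n_donors number of donor strains.
#' @param donor_specific_fraction fraction of markers specific to one donor.
#' @param seed integer RNG seed.
#' @param chrom contig name used in emitted files.
#' @return data.frame `chrom, pos, alt, donor_specific` (donor id or `NA`),
#'   sorted by position, with attribute `genome_length`.
#' @export
make_marker_landscape <- function(genome_length = 200000L, markers_per_kb = 8,
                                  n_donors = 4L, donor_specific_fraction = 0.2,
                                  seed = 1L, chrom = "sim") {
  set.seed(seed)
  n <- stats::rpois(1, markers_per_kb * genome_length / 1000)
  n <- min(n, genome_length)
  pos <- sort(sample.int(genome_length, n))
  if (n == 0L) {
    out <- data.frame(chrom = character(), pos = integer(), alt = character(),
                      donor_specific = character(), stringsAsFactors = FALSE)
    attr(out, "genome_length") <- genome_length
    return(out)
  }
  alt <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  specific <- rep(NA_character_, n)
  is_spec <- stats::runif(n) < donor_specific_fraction
  specific[is_spec] <- paste0("donor", sample.int(n_donors, sum(is_spec),
                                                  replace = TRUE))
  out <- data.frame(chrom = chrom, pos = pos, alt = alt,
                    donor_specific = specific, stringsAsFactors = FALSE)
  attr(out, "genome_length") <- genome_length
  out
}

#' Donor strain models
#'
#' Places an oriT (position + orientation) for each donor, spaced around the
#' circular chromosome, and assigns each donor one auxotrophy site chosen
#' among its donor-specific marker sites (auxotrophy alleles are themselves
#' donor-specific differences, lethal to a recombinant in minimal medium).
#'
#' @param landscape a [make_marker_landscape()] table.
#' @param n_donors number of donors (ids `donor1..donorN`).
#' @param seed integer RNG seed.
#' @return list of `donor_model` lists: `donor_id, oriT_pos, orientation,
#'   auxotrophy_positions`.
#' @export
make_donor_models <- function(landscape, n_donors = 4L, seed = 1L) {
  set.seed(seed + 101L)
  genome_length <- attr(landscape, "genome_length")
  base <- round(seq(0, genome_length, length.out = n_donors + 1L))[seq_len(n_donors)]
  jitter <- stats::runif(n_donors, 0, genome_length / (4 * n_donors))
  oriT <- as.integer((base + jitter) %% genome_length) + 1L
  orientation <- rep(c("+", "-"), length.out = n_donors)
  lapply(seq_len(n_donors), function(i) {
    id <- paste0("donor", i)
    own <- landscape$pos[!is.na(landscape$donor_specific) &
                           landscape$donor_specific == id]
    aux <- if (length(own) > 0L) sample(own, 1L) else integer(0)
    structure(list(donor_id = id, oriT_pos = oriT[i],
                   orientation = orientation[i],
                   auxotrophy_positions = aux),
              class = "donor_model")
  })
}

#' Distance from a donor's oriT along its direction of transfer
#'
#' Hfr transfer is unidirectional: the transfer coordinate of a position is
#' its distance from the oriT measured along the donor's orientation on the
#' circular chromosome.
#'
#' @param pos position(s) on the chromosome.
#' @param donor a `donor_model`.
#' @param genome_length chromosome length (bp).
#' @return nonnegative distances in bp.
#' @export
transfer_distance <- function(pos, donor, genome_length) {
  if (donor$orientation == "+") (pos - donor$oriT_pos) %% genome_length
  else (donor$oriT_pos - pos) %% genome_length
}

# Positions covered by the tract [oriT, oriT + len) in transfer direction.
tract_interval <- function(donor, len, genome_length) {
  if (len <= 0) return(NULL)
  if (donor$orientation == "+") {
    start <- donor$oriT_pos
    end <- donor$oriT_pos + ceiling(len) - 1
  } else {
    start <- donor$oriT_pos - ceiling(len) + 1
    end <- donor$oriT_pos
  }
  # normalize to [1, genome_length], possibly wrapping
  start <- ((start - 1) %% genome_length) + 1
  end <- ((end - 1) %% genome_length) + 1
  list(start = start, end = end, wraps = start > end)
}

in_circular_interval <- function(pos, iv) {
  if (is.null(iv)) return(rep(FALSE, length(pos)))
  if (iv$wraps) pos >= iv$start | pos <= iv$end
  else pos >= iv$start & pos <= iv$end
}

empty_haplotype <- function() {
  list(k12_idx = integer(), k12_origin = character(),
       lost_ltee = integer(), new_mut = integer(),
       tracts = data.frame(start = integer(), end = integer(),
                           wraps = logical(), donor = character(),
                           stringsAsFactors = FALSE))
}

#' Simulate one conjugative mating
#'
#' A single Hfr exposure: a tract length is drawn from the transfer-decay
#' law (usually zero — no transfer), the tract starts at the donor's oriT
#' and extends unidirectionally, and — optionally fragmented into mosaic
#' pieces — replaces the recipient's alleles over the integrated pieces:
#' shared and own-donor-specific markers flip to the donor state,
#' other-donor markers and recipient mutations inside the tract revert to
#' the donor (reference-like) state. When selection is on, a recombinant
#' that acquires any donor auxotrophy allele is discarded.
#'
#' @param hap a haplotype (see Details) or `NULL` for an unmodified
#'   recipient.
#' @param donor a `donor_model`.
#' @param params a [conjugation_params()].
#' @param landscape the marker landscape.
#' @param ltee_pos positions of the recipient's own (pre-experiment)
#'   mutations.
#' @return list `haplotype` (possibly updated), `transferred`, `rejected`,
#'   `interval` (the drawn tract or `NULL`), `pieces` (integrated
#'   intervals).
#' @details A haplotype is a list with `k12_idx` (landscape row indices
#'   carrying the donor allele), `k12_origin` (delivering donor per index),
#'   `lost_ltee` (indices into `ltee_pos` erased by donor DNA), `new_mut`
#'   (indices into a new-mutation table, managed by the population
#'   simulation), and `tracts` (history of integrated pieces).
#' @export
conjugate <- function(hap, donor, params, landscape, ltee_pos = integer(),
                      new_pos = integer()) {
  if (is.null(hap)) hap <- empty_haplotype()
  genome_length <- attr(landscape, "genome_length")
  len <- draw_transfer_lengths(1L, params, genome_length)
  if (len <= 0)
    return(list(haplotype = hap, transferred = FALSE, rejected = FALSE,
                interval = NULL, pieces = list()))
  out <- integrate_tract(hap, donor, len, params, landscape, ltee_pos, new_pos)
  list(haplotype = out$haplotype, transferred = !out$rejected,
       rejected = out$rejected,
       interval = tract_interval(donor, len, genome_length),
       pieces = out$pieces)
}

# Split a tract into mosaic pieces: breaks arrive at fragmentation_rate per
# kb; each resulting piece is integrated independently with probability 1/2
# (always at least the oriT-proximal piece). With rate 0 the whole tract is
# one piece.
fragment_tract <- function(iv, donor, len, params, genome_length) {
  if (params$fragmentation_rate <= 0) return(list(iv))
  n_breaks <- stats::rpois(1, params$fragmentation_rate * len / 1000)
  if (n_breaks == 0L) return(list(iv))
  cuts <- sort(stats::runif(n_breaks, 0, len))
  bounds <- c(0, cuts, len)
  pieces <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    if (i > 1L && stats::runif(1) < 0.5) next
    d0 <- bounds[i]; d1 <- bounds[i + 1L]
    if (donor$orientation == "+") {
      s <- donor$oriT_pos + floor(d0); e <- donor$oriT_pos + ceiling(d1) - 1
    } else {
      s <- donor$oriT_pos - ceiling(d1) + 1; e <- donor$oriT_pos - floor(d0)
    }
    s <- ((s - 1) %% genome_length) + 1
    e <- ((e - 1) %% genome_length) + 1
    pieces[[length(pieces) + 1L]] <- list(start = s, end = e, wraps = s > e)
  }
  pieces
}

#' One generation of Wright-Fisher resampling
#'
#' Each of the N offspring draws its parent uniformly at random with
#' replacement: pure neutral drift, under which expected heterozygosity
#' decays by a factor (1 - 1/N) per generation.
#'
#' @param pop integer vector of haplotype ids (one per individual).
#' @return resampled population of the same size.
#' @export
wright_fisher_step <- function(pop) {
  pop[sample.int(length(pop), length(pop), replace = TRUE)]
}

#' Clonal sweep operator
#'
#' The hitchhiking-ratchet model of beneficial sweeps: a sweep founder is
#' drawn uniformly from the population and instantly replaces it, so any
#' neutral allele at frequency p fixes with probability p and otherwise
#' goes extinct.
#'
#' @param pop integer vector of haplotype ids (one per individual).
#' @return the population after the sweep (all individuals the founder's
#'   haplotype).
#' @export
apply_sweep <- function(pop) {
  rep(pop[sample.int(length(pop), 1L)], length(pop))
}

#' Forward simulation of a pulsed-conjugation population
#'
#' Wright-Fisher resampling of `N` haploid individuals with periodic
#' conjugation pulses (every `cycle_interval_generations`, for `n_cycles`
#' pulses), new mutation, instantaneous clonal sweeps at `sweep_rate` per
#' generation, and optional purifying selection against donor auxotrophy
#' alleles — followed by a continuation phase with conjugation switched
#' off. Population allele frequencies are recorded at the end of the main
#' phase (t0) and the end of the continuation (t1), and two clones are
#' sampled at t0.
#'
#' @param landscape a [make_marker_landscape()] table.
#' @param donors list of `donor_model`s.
#' @param params a [conjugation_params()].
#' @param N population size.
#' @param n_ltee number of recipient (pre-experiment) mutations.
#' @param mutation_rate expected new mutations per genome per generation.
#' @param sweep_rate probability of a clonal sweep per generation.
#' @param continuation_generations length of the conjugation-free phase.
#' @param seed integer RNG seed.
#' @return object of class `sim_population`: landscape, donors, recipient
#'   mutation table, sampled `clones` (two haplotypes), frequency tables
#'   `freq_t0`/`freq_t1`, the haplotype table, and a `truth` list per
#'   sampled clone (tract intervals and per-site labels).
#' @export
evolve_population <- function(landscape, donors, params, N = 1000L,
                              n_ltee = 80L, mutation_rate = 0.0005,
                              sweep_rate = 0.02,
                              continuation_generations = 200L, seed = 1L) {
  set.seed(seed)
  genome_length <- attr(landscape, "genome_length")
  free <- setdiff(seq_len(genome_length), landscape$pos)
  ltee_pos <- sort(sample(free, min(n_ltee, length(free))))
  # new mutations are drawn from positions not already segregating, so every
  # simulated site has a single unambiguous identity in the truth files
  free_pool <- setdiff(free, ltee_pos)
  ltee <- data.frame(chrom = landscape$chrom[1] %||% "sim", pos = ltee_pos,
                     alt = sample(c("A", "C", "G", "T"), length(ltee_pos),
                                  replace = TRUE),
                     stringsAsFactors = FALSE)

  haps <- list(empty_haplotype())
  new_muts <- data.frame(pos = integer(), alt = character(),
                         stringsAsFactors = FALSE)
  pop <- rep(1L, N)

  main_gens <- params$n_cycles * params$cycle_interval_generations
  total <- main_gens + continuation_generations
  pulse_gens <- (seq_len(params$n_cycles) - 1L) * params$cycle_interval_generations + 1L

  freq_t0 <- NULL
  for (g in seq_len(total)) {
    if (g <= main_gens && g %in% pulse_gens) {
      res <- conjugation_pulse(pop, haps, donors, params, landscape, ltee_pos,
                               new_muts$pos)
      pop <- res$pop; haps <- res$haps
    }
    pop <- wright_fisher_step(pop)
    if (mutation_rate > 0) {
      n_new <- stats::rpois(1, mutation_rate * N)
      for (j in seq_len(n_new)) {
        if (length(free_pool) == 0L) break
        i <- sample.int(N, 1L)
        pick <- sample.int(length(free_pool), 1L)
        mpos <- free_pool[pick]
        free_pool <- free_pool[-pick]
        new_muts <- rbind(new_muts, data.frame(
          pos = mpos, alt = sample(c("A", "C", "G", "T"), 1L),
          stringsAsFactors = FALSE))
        h <- haps[[pop[i]]]
        h$new_mut <- c(h$new_mut, nrow(new_muts))
        haps[[length(haps) + 1L]] <- h
        pop[i] <- length(haps)
      }
    }
    if (stats::runif(1) < sweep_rate) pop <- apply_sweep(pop)
    if (g == main_gens) freq_t0 <- population_frequencies(pop, haps, landscape,
                                                          ltee, new_muts)
  }
  freq_t1 <- population_frequencies(pop, haps, landscape, ltee, new_muts)
  if (is.null(freq_t0)) freq_t0 <- freq_t1

  clone_idx <- sample.int(N, 2L)
  clones <- lapply(clone_idx, function(i) haps[[pop[i]]])
  truth <- lapply(clones, function(h)
    haplotype_truth(h, landscape, ltee, new_muts))

  structure(list(landscape = landscape, donors = donors, params = params,
                 N = N, ltee = ltee, new_muts = new_muts,
                 clones = clones, truth = truth,
                 freq_t0 = freq_t0, freq_t1 = freq_t1),
            class = "sim_population")
}

conjugation_pulse <- function(pop, haps, donors, params, landscape, ltee_pos,
                              new_pos = integer()) {
  N <- length(pop)
  n_exposures <- N * params$matings_per_cell_per_pulse
  # each exposure independently transfers with probability p_near at most;
  # draw the number of non-trivial exposures then handle them one by one
  n_events <- stats::rbinom(1, n_exposures, params$p_near)
  for (e in seq_len(n_events)) {
    i <- sample.int(N, 1L)
    donor <- donors[[sample.int(length(donors), 1L)]]
    # conditional on transfer: invert the survival law on u ~ U(0, p_near)
    u <- stats::runif(1, 0, params$p_near)
    len <- invert_decay(u, params, attr(landscape, "genome_length"))
    if (len <= 0) next
    out <- integrate_tract(haps[[pop[i]]], donor, len, params, landscape,
                           ltee_pos, new_pos)
    if (out$rejected) next
    haps[[length(haps) + 1L]] <- out$haplotype
    pop[i] <- length(haps)
  }
  list(pop = pop, haps = haps)
}

invert_decay <- function(u, params, genome_length) {
  slope <- (log10(params$p_far) - log10(params$p_near)) /
    (params$d_far - params$d_near)
  len <- params$d_near + (log10(u) - log10(params$p_near)) / slope
  min(len, params$max_fraction_transferred * genome_length)
}

# Core of a successful mating: draw the mosaic pieces for a tract of the
# given length, reject on auxotrophy acquisition, otherwise replace
# recipient alleles over the integrated pieces (donor alleles flip on,
# other-donor-specific sites and recipient/new mutations inside revert to
# the donor state).
integrate_tract <- function(hap, donor, len, params, landscape, ltee_pos,
                            new_pos = integer()) {
  genome_length <- attr(landscape, "genome_length")
  iv <- tract_interval(donor, len, genome_length)
  pieces <- fragment_tract(iv, donor, len, params, genome_length)
  covered <- rep(FALSE, nrow(landscape))
  for (p in pieces) covered <- covered | in_circular_interval(landscape$pos, p)
  if (params$selection_on && length(donor$auxotrophy_positions) > 0L) {
    aux_idx <- match(donor$auxotrophy_positions, landscape$pos)
    if (any(covered[aux_idx]))
      return(list(haplotype = hap, rejected = TRUE, pieces = pieces))
  }
  transfer <- covered & (is.na(landscape$donor_specific) |
                           landscape$donor_specific == donor$donor_id)
  keep <- !(hap$k12_idx %in% which(covered))
  k12_idx <- c(hap$k12_idx[keep], which(transfer))
  k12_origin <- c(hap$k12_origin[keep], rep(donor$donor_id, sum(transfer)))
  o <- order(k12_idx)
  lost <- hap$lost_ltee
  if (length(ltee_pos) > 0L) {
    hit <- rep(FALSE, length(ltee_pos))
    for (p in pieces) hit <- hit | in_circular_interval(ltee_pos, p)
    lost <- sort(union(lost, which(hit)))
  }
  new_mut <- hap$new_mut
  if (length(new_mut) > 0L && length(new_pos) > 0L) {
    hit <- rep(FALSE, length(new_mut))
    for (p in pieces) hit <- hit | in_circular_interval(new_pos[new_mut], p)
    new_mut <- new_mut[!hit]
  }
  tracts <- rbind(hap$tracts,
                  do.call(rbind, lapply(pieces, function(p)
                    data.frame(start = p$start, end = p$end, wraps = p$wraps,
                               donor = donor$donor_id, stringsAsFactors = FALSE))))
  list(haplotype = list(k12_idx = k12_idx[o], k12_origin = k12_origin[o],
                        lost_ltee = lost, new_mut = new_mut,
                        tracts = tracts),
       rejected = FALSE, pieces = pieces)
}

population_frequencies <- function(pop, haps, landscape, ltee, new_muts) {
  N <- length(pop)
  counts <- table(pop)
  ids <- as.integer(names(counts))
  k12 <- numeric(nrow(landscape))
  lost <- numeric(nrow(ltee))
  newf <- numeric(nrow(new_muts))
  for (j in seq_along(ids)) {
    h <- haps[[ids[j]]]
    w <- as.numeric(counts[j])
    if (length(h$k12_idx) > 0L) k12[h$k12_idx] <- k12[h$k12_idx] + w
    if (length(h$lost_ltee) > 0L) lost[h$lost_ltee] <- lost[h$lost_ltee] + w
    if (length(h$new_mut) > 0L) newf[h$new_mut] <- newf[h$new_mut] + w
  }
  list(k12 = k12 / N, ltee = 1 - lost / N, new_mut = newf / N)
}

haplotype_truth <- function(h, landscape, ltee, new_muts) {
  n <- nrow(landscape)
  label <- rep("REL606", n)
  label[h$k12_idx] <- "K12"
  donor_origin <- rep(NA_character_, n)
  donor_origin[h$k12_idx] <- ifelse(
    is.na(landscape$donor_specific[h$k12_idx]), NA_character_,
    h$k12_origin)
  marker_truth <- data.frame(chrom = landscape$chrom, pos = landscape$pos,
                             kind = "SNP", alt = landscape$alt, label = label,
                             donor_origin = donor_origin,
                             stringsAsFactors = FALSE)
  ltee_truth <- data.frame(chrom = ltee$chrom, pos = ltee$pos, kind = "SNP",
                           alt = ltee$alt,
                           label = ifelse(seq_len(nrow(ltee)) %in% h$lost_ltee,
                                          "DELETED", "LTEE"),
                           donor_origin = NA_character_,
                           stringsAsFactors = FALSE)
  new_truth <- if (length(h$new_mut) > 0L)
    data.frame(chrom = landscape$chrom[1], pos = new_muts$pos[h$new_mut],
               kind = "SNP", alt = new_muts$alt[h$new_mut], label = "NEW",
               donor_origin = NA_character_, stringsAsFactors = FALSE)
  else NULL
  labels <- rbind(marker_truth, ltee_truth, new_truth)
  labels <- labels[order(labels$pos), , drop = FALSE]
  rownames(labels) <- NULL
  list(labels = labels, tracts = h$tracts)
}

#' Call sets of the simulated genomes
#'
#' Expresses a simulated experiment in the pipeline's own currency: one
#' donor call set per donor (shared markers plus its specific markers,
#' which include the auxotrophy sites), the recipient call set (its
#' pre-experiment mutations), one recombinant call set per sampled clone,
#' and the two population frequency tables.
#'
#' @param sim a `sim_population` from [evolve_population()].
#' @return list `donors` (list of call sets), `recipient`, `recombinants`
#'   (list), `pop_t0`, `pop_t1` (population call sets).
#' @export
sim_call_sets <- function(sim) {
  lsc <- sim$landscape
  donor_sets <- lapply(sim$donors, function(d) {
    keep <- is.na(lsc$donor_specific) | lsc$donor_specific == d$donor_id
    call_set(d$donor_id, "donor",
             variant_table(chrom = lsc$chrom[keep], pos = lsc$pos[keep],
                           kind = "SNP", alt = lsc$alt[keep]))
  })
  recipient <- call_set("recipient", "recipient",
                        variant_table(chrom = sim$ltee$chrom, pos = sim$ltee$pos,
                                      kind = "SNP", alt = sim$ltee$alt))
  recombinants <- lapply(seq_along(sim$clones), function(i) {
    h <- sim$clones[[i]]
    kept_ltee <- setdiff(seq_len(nrow(sim$ltee)), h$lost_ltee)
    v <- rbind(
      if (length(h$k12_idx) > 0L)
        variant_table(chrom = lsc$chrom[h$k12_idx], pos = lsc$pos[h$k12_idx],
                      kind = "SNP", alt = lsc$alt[h$k12_idx]),
      if (length(kept_ltee) > 0L)
        variant_table(chrom = sim$ltee$chrom[kept_ltee],
                      pos = sim$ltee$pos[kept_ltee], kind = "SNP",
                      alt = sim$ltee$alt[kept_ltee]),
      if (length(h$new_mut) > 0L)
        variant_table(chrom = lsc$chrom[1], pos = sim$new_muts$pos[h$new_mut],
                      kind = "SNP", alt = sim$new_muts$alt[h$new_mut]))
    if (is.null(v)) v <- variant_table()
    v <- v[!duplicated(site_key(v)), , drop = FALSE]
    call_set(paste0("recombinant", i), "recombinant", order_sites(v))
  })
  pops <- lapply(c("freq_t0", "freq_t1"), function(fn) {
    f <- sim[[fn]]
    keep_m <- f$k12 > 0
    keep_l <- f$ltee > 0
    keep_n <- f$new_mut > 0
    v <- rbind(
      if (any(keep_m))
        variant_table(chrom = lsc$chrom[keep_m], pos = lsc$pos[keep_m],
                      kind = "SNP", alt = lsc$alt[keep_m],
                      freq = f$k12[keep_m]),
      if (any(keep_l))
        variant_table(chrom = sim$ltee$chrom[keep_l],
                      pos = sim$ltee$pos[keep_l], kind = "SNP",
                      alt = sim$ltee$alt[keep_l], freq = f$ltee[keep_l]),
      if (any(keep_n))
        variant_table(chrom = lsc$chrom[1], pos = sim$new_muts$pos[keep_n],
                      kind = "SNP", alt = sim$new_muts$alt[keep_n],
                      freq = f$new_mut[keep_n]))
    if (is.null(v)) v <- variant_table()
    v <- v[!duplicated(site_key(v)), , drop = FALSE]
    call_set(fn, "population", order_sites(v))
  })
  list(donors = donor_sets, recipient = recipient, recombinants = recombinants,
       pop_t0 = pops[[1]], pop_t1 = pops[[2]])
}

#' Write a simulated experiment to disk
#'
#' Emits the full file bundle a real experiment would provide — donor,
#' recipient, and recombinant variant tables (GenomeDiff subset), two
#' population frequency tables (VCF with AF), a donor annotation table
#' (oriT position/orientation, auxotrophy positions), and per-clone truth
#' files (true labels and true transferred tracts). Output is deterministic
#' given the simulation object.
#'
#' @param sim a `sim_population`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
emit <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cs <- sim_call_sets(sim)
  paths <- character()
  for (d in cs$donors) {
    p <- file.path(out_dir, paste0(d$sample_id, ".gd"))
    write_variant_table(d, p); paths[d$sample_id] <- p
  }
  p <- file.path(out_dir, "recipient.gd")
  write_variant_table(cs$recipient, p); paths["recipient"] <- p
  for (r in cs$recombinants) {
    p <- file.path(out_dir, paste0(r$sample_id, ".gd"))
    write_variant_table(r, p); paths[r$sample_id] <- p
  }
  p <- file.path(out_dir, "population_t0.vcf")
  write_variant_table(cs$pop_t0, p); paths["population_t0"] <- p
  p <- file.path(out_dir, "population_t1.vcf")
  write_variant_table(cs$pop_t1, p); paths["population_t1"] <- p

  ann <- do.call(rbind, lapply(sim$donors, function(d)
    data.frame(donor_id = d$donor_id, oriT_pos = d$oriT_pos,
               orientation = d$orientation,
               auxotrophy_positions = paste(d$auxotrophy_positions,
                                            collapse = ","),
               stringsAsFactors = FALSE)))
  p <- file.path(out_dir, "donor_annotations.tsv")
  utils::write.table(ann, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["donor_annotations"] <- p

  for (i in seq_along(sim$truth)) {
    p <- file.path(out_dir, paste0("truth_labels_recombinant", i, ".tsv"))
    utils::write.table(sim$truth[[i]]$labels, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    paths[paste0("truth_labels_recombinant", i)] <- p
    p <- file.path(out_dir, paste0("truth_tracts_recombinant", i, ".tsv"))
    utils::write.table(sim$truth[[i]]$tracts, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    paths[paste0("truth_tracts_recombinant", i)] <- p
  }
  invisible(paths)
}

#' Run a full multi-population simulated experiment
#'
#' Convenience wrapper: builds one marker landscape and donor panel, scales
#' the decay-law anchors to the simulated chromosome, and evolves
#' `n_populations` independent populations with derived seeds.
#'
#' @param n_populations number of replicate populations.
#' @param genome_length simulated chromosome length (default 200 kb).
#' @param params a [conjugation_params()]; anchors are rescaled via
#'   [scale_decay_distances()] unless `scale_anchors = FALSE`.
#' @param N,sweep_rate,continuation_generations passed to
#'   [evolve_population()].
#' @param markers_per_kb,donor_specific_fraction,n_donors passed to
#'   [make_marker_landscape()].
#' @param scale_anchors rescale decay anchor distances to `genome_length`.
#' @param seed master seed; population i uses `seed + i`.
#' @return list with the shared `landscape`, `donors`, `params`, and
#'   `populations` (list of `sim_population`s).
#' @export
simulate_experiment <- function(n_populations = 10L, genome_length = 200000L,
                                params = conjugation_params(),
                                N = 1000L, sweep_rate = 0.02,
                                continuation_generations = 200L,
                                markers_per_kb = 8,
                                donor_specific_fraction = 0.2,
                                n_donors = 4L, scale_anchors = TRUE,
                                seed = 1L) {
  if (scale_anchors) params <- scale_decay_distances(params, genome_length)
  landscape <- make_marker_landscape(genome_length, markers_per_kb, n_donors,
                                     donor_specific_fraction, seed = seed)
  donors <- make_donor_models(landscape, n_donors, seed = seed)
  populations <- lapply(seq_len(n_populations), function(i)
    evolve_population(landscape, donors, params, N = N,
                      sweep_rate = sweep_rate,
                      continuation_generations = continuation_generations,
                      seed = seed + i))
  list(landscape = landscape, donors = donors, params = params,
       populations = populations)
}
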