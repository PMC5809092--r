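# Shared fixture builders for the test suite. All randomness is seeded by
# the caller.

# A random variant table over `n` sites on a genome of length L.
random_variants <- function(n, L = 10000L, chrom = "sim") {
  if (n == 0L) return(variant_table())
  pos <- sort(sample.int(L, n))
  kind <- sample(c("SNP", "small_indel", "IS_insertion", "large_deletion"),
                 n, replace = TRUE, prob = c(0.7, 0.15, 0.1, 0.05))
  alt <- character(n)
  alt[kind == "SNP"] <- sample(c("A", "C", "G", "T"), sum(kind == "SNP"),
                               replace = TRUE)
  alt[kind == "small_indel"] <- paste0("+",
    sample(c("A", "AC", "GAT"), sum(kind == "small_indel"), replace = TRUE))
  alt[kind == "IS_insertion"] <- sample(paste0("IS", 1:5),
                                        sum(kind == "IS_insertion"),
                                        replace = TRUE)
  alt[kind == "large_deletion"] <- as.character(
    sample(50:500, sum(kind == "large_deletion"), replace = TRUE))
  variant_table(chrom = chrom, pos = pos, kind = kind, alt = alt,
                syn = sample(c(NA, "synonymous", "nonsynonymous"), n,
                             replace = TRUE))
}

# Random donor/recipient/recombinant instance: a universe of sites with
# independent membership in each genome, for truth-table checks.
random_label_instance <- function(n_sites = 50L, n_donors = 4L, L = 100000L) {
  pos <- sort(sample.int(L, n_sites))
  alt <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  universe <- variant_table(chrom = "sim", pos = pos, kind = "SNP", alt = alt)
  member <- function() runif(n_sites) < 0.4
  donors <- lapply(seq_len(n_donors), function(i)
    call_set(paste0("donor", i), "donor", universe[member(), , drop = FALSE]))
  recipient <- call_set("recipient", "recipient",
                        universe[member(), , drop = FALSE])
  recombinant <- call_set("recombinant", "recombinant",
                          universe[member(), , drop = FALSE])
  list(universe = universe, donors = donors, recipient = recipient,
       recombinant = recombinant)
}

# Independent per-site truth table for the provenance labels: literal
# enumeration of the membership cases, written without set operations.
oracle_labels <- function(instance) {
  u <- instance$universe
  rk <- site_key(instance$recombinant$variants)
  pk <- site_key(instance$recipient$variants)
  dk <- unique(unlist(lapply(instance$donors,
                             function(d) site_key(d$variants))))
  out <- character(nrow(u))
  keys <- site_key(u)
  for (i in seq_len(nrow(u))) {
    r <- keys[i] %in% rk
    p <- keys[i] %in% pk
    d <- keys[i] %in% dk
    out[i] <-
      if (r && p && d) "ignored"
      else if (r && p && !d) "LTEE"
      else if (r && !p && d) "K12"
      else if (r && !p && !d) "NEW"
      else if (!r && p) "DELETED"
      else if (!r && !p && d) "REL606"
      else "absent"
  }
  data.frame(pos = u$pos, key = keys, label = out, stringsAsFactors = FALSE)
}

# A tiny deterministic simulated experiment sized for unit tests.
small_sim <- function(seed = 7L, n_populations = 1L) {
  simulate_experiment(
    n_populations = n_populations, genome_length = 50000L,
    params = conjugation_params(n_cycles = 6L,
                                matings_per_cell_per_pulse = 20L),
    N = 100L, sweep_rate = 0.02, continuation_generations = 60L,
    seed = seed)
}

# All permutations of 1..n (tiny n only), for enumeration oracles.
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- combinat_perms(n - 1L)
  out <- list()
  for (p in sub) for (k in 0:(n - 1L)) {
    out[[length(out) + 1L]] <- append(p, n, after = k)
  }
  out
}
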