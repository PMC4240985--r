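# Small fixtures and independent brute-force oracles used across tests.

make_aln <- function(strings, labels = NULL, locus = "test",
                     genome = "nuclear") {
  multiple_alignment(strings, labels = labels, locus = locus, genome = genome)
}

# random gapped alignment as raw strings
random_aln <- function(n_rows, n_cols, gap_prob = 0.1) {
  states <- c("A", "C", "G", "T", "N", "-")
  probs <- c(rep((1 - gap_prob) / 4, 4), gap_prob / 2, gap_prob / 2)
  m <- matrix(sample(states, n_rows * n_cols, replace = TRUE, prob = probs),
              nrow = n_rows)
  rownames(m) <- paste0("t", seq_len(n_rows))
  multiple_alignment(m)
}

is_base <- function(x) x %in% c("A", "C", "G", "T")

# brute-force double loops, written independently of the package internals
oracle_variable <- function(aln) {
  m <- unclass(aln)
  cnt <- 0L
  for (j in seq_len(ncol(m))) {
    seen <- character(0)
    for (i in seq_len(nrow(m))) if (is_base(m[i, j]))
      seen <- union(seen, m[i, j])
    if (length(seen) >= 2L) cnt <- cnt + 1L
  }
  cnt
}

oracle_pi_sites <- function(aln) {
  m <- unclass(aln)
  cnt <- 0L
  for (j in seq_len(ncol(m))) {
    counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    for (i in seq_len(nrow(m))) if (is_base(m[i, j]))
      counts[m[i, j]] <- counts[m[i, j]] + 1L
    if (sum(counts >= 2L) >= 2L) cnt <- cnt + 1L
  }
  cnt
}

oracle_pi <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  vals <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    diffs <- 0L; comp <- 0L
    for (s in seq_len(ncol(m))) {
      if (is_base(m[i, s]) && is_base(m[j, s])) {
        comp <- comp + 1L
        if (m[i, s] != m[j, s]) diffs <- diffs + 1L
      }
    }
    if (comp > 0L) vals <- c(vals, diffs / comp)
  }
  mean(vals)
}

# exact minimum set-cover size by bitmask enumeration over all subsets
oracle_min_cover_size <- function(cells, candidates, required = character(0)) {
  k <- length(candidates)
  best <- Inf
  for (mask in seq_len(2^k) - 1L) {
    set <- candidates[bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0]
    if (!all(required %in% set)) next
    if (all(vapply(cells, function(cl) any(cl %in% set), logical(1))))
      best <- min(best, length(set))
  }
  best
}

# alignment -> phangorn phyDat for independent parsimony scoring
as_phydat <- function(aln) {
  m <- tolower(unclass(aln))
  m[m == "n"] <- "?"
  phangorn::phyDat(m, type = "DNA")
}

# cached mid-size zero-noise dataset shared by several tests
zero_noise_cache <- new.env(parent = emptyenv())
zero_noise_dataset <- function() {
  if (is.null(zero_noise_cache$ds)) {
    cfg <- sim_config(n_species = 6, n_nuclear_loci = 6,
                      locus_length_range = c(300, 600),
                      n_cultivars = 8, parental_pool_size = 3,
                      parental_set_sizes = c(1, 2),
                      post_origin_mutation_rate = 0, clone_error_rate = 0,
                      clone_range = c(4, 8))
    zero_noise_cache$cfg <- cfg
    zero_noise_cache$ds <- simulate_dataset(cfg, seed = 42)
  }
  list(cfg = zero_noise_cache$cfg, ds = zero_noise_cache$ds)
}
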