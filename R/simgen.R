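# Synthetic homoploid-hybridization data generator: a wild-species panel
# (species tree -> per-locus alignments + one linked chloroplast haplotype),
# optional chloroplast capture, and hybrid cultivars with recorded truth.

#' Simulation configuration
#'
#' Defaults emulate a wild panel of nine shrubby species split into two
#' subsections, 25 nuclear intron loci (322-3656 bp, per-locus rates
#' spanning roughly the 3.6-18.8% variable-site band), a single linked
#' chloroplast haplotype at lower diversity, and 47 cultivars drawn from a
#' 5-species parental pool with one dominant maternal donor.
#'
#' @param n_species number of wild species.
#' @param birth_rate pure-birth speciation rate (per unit time) for the
#'   species tree.
#' @param n_nuclear_loci number of nuclear loci.
#' @param locus_length_range bp range loci are drawn from.
#' @param rate_range per-locus substitution scale (substitutions/site over
#'   unit branch length) drawn uniformly.
#' @param cp_length chloroplast haplotype length (bp).
#' @param cp_rate chloroplast substitution scale (lower than nuclear).
#' @param alleles_per_species accessions (allele rows) per species per locus.
#' @param within_species_rate per-site mutation rate applied to accession
#'   copies within a species (shallow within-species variation).
#' @param n_cultivars number of hybrid cultivars.
#' @param parental_pool_size number of species forming the cultivar
#'   parental pool (taken from the larger subsection when possible).
#' @param parental_set_sizes possible per-cultivar parental-set sizes.
#' @param maternal_bias probability that the pool's first (dominant)
#'   species is the maternal donor of a cultivar.
#' @param post_origin_mutation_rate per-site mutation applied to cultivar
#'   allele and chloroplast copies after the hybridization event.
#' @param clone_range range of clones sequenced per cultivar per locus.
#' @param clone_error_rate per-site error rate on clones (PCR/sequencing).
#' @param capture_probability probability, per non-donor species, of one
#'   chloroplast-capture event when building the panel.
#' @param model substitution model, `"JC69"` or `"K2P"`.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_species = 9,
                       birth_rate = 1,
                       n_nuclear_loci = 25,
                       locus_length_range = c(322, 3656),
                       rate_range = c(0.008, 0.025),
                       cp_length = 3700,
                       cp_rate = 0.006,
                       alleles_per_species = 2,
                       within_species_rate = 0.002,
                       n_cultivars = 47,
                       parental_pool_size = 5,
                       parental_set_sizes = c(2, 3),
                       maternal_bias = 0.7,
                       post_origin_mutation_rate = 0.001,
                       clone_range = c(8, 16),
                       clone_error_rate = 5e-4,
                       capture_probability = 0,
                       model = "JC69") {
  cfg <- list(n_species = n_species, birth_rate = birth_rate,
              n_nuclear_loci = n_nuclear_loci,
              locus_length_range = locus_length_range,
              rate_range = rate_range, cp_length = cp_length,
              cp_rate = cp_rate, alleles_per_species = alleles_per_species,
              within_species_rate = within_species_rate,
              n_cultivars = n_cultivars,
              parental_pool_size = parental_pool_size,
              parental_set_sizes = parental_set_sizes,
              maternal_bias = maternal_bias,
              post_origin_mutation_rate = post_origin_mutation_rate,
              clone_range = clone_range, clone_error_rate = clone_error_rate,
              capture_probability = capture_probability, model = model)
  rates <- c(cfg$birth_rate, cfg$rate_range, cfg$cp_rate,
             cfg$within_species_rate, cfg$post_origin_mutation_rate,
             cfg$clone_error_rate, cfg$capture_probability)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (any(cfg$locus_length_range < 1)) stop("locus lengths must be >= 1")
  if (cfg$parental_pool_size > cfg$n_species)
    stop("parental pool cannot exceed the number of species")
  if (any(cfg$parental_set_sizes > cfg$parental_pool_size))
    stop("parental-set sizes cannot exceed the pool size")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an ultrametric species tree
#'
#' Pure-birth (Yule) tree conditioned on the number of tips; tips are
#' labelled `sp01`, `sp02`, ...
#'
#' @param n_species number of species (>= 2).
#' @param birth_rate speciation rate per unit time (> 0).
#' @param seed integer seed; identical inputs give identical trees.
#' @return a rooted ultrametric `phylo` tree.
#' @export
simulate_species_tree <- function(n_species, birth_rate = 1, seed = 1) {
  if (n_species < 2) stop("n_species must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  tr <- withr::with_seed(seed, ape::rphylo(n_species, birth = birth_rate,
                                           death = 0))
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tr
}

#' Evolve one locus along a tree
#'
#' Simulates a gap-free alignment (one row per tip) under JC69 or K2P with
#' the given per-site substitution scale applied to branch lengths.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param length locus length in bp (>= 1).
#' @param rate substitutions per site per unit branch length (>= 0).
#' @param model `"JC69"` or `"K2P"` (transition/transversion ratio 2).
#' @param seed integer seed.
#' @param locus,genome passed to the alignment container.
#' @return a `multiple_alignment` with one row per tree tip.
#' @export
evolve_locus <- function(tree, length, rate, model = c("JC69", "K2P"),
                         seed = 1, locus = "locus", genome = "nuclear") {
  model <- match.arg(model)
  if (length < 1) stop("length must be >= 1")
  if (rate < 0) stop("rate must be >= 0")
  if (rate == 0) {
    base <- withr::with_seed(seed, sample(BASES, length, replace = TRUE))
    m <- matrix(rep(base, each = length(tree$tip.label)),
                nrow = length(tree$tip.label),
                dimnames = list(tree$tip.label, NULL))
    return(multiple_alignment(m, locus = locus, genome = genome))
  }
  Q <- if (model == "K2P") c(1, 2, 1, 1, 2, 1) else rep(1, 6)
  sim <- withr::with_seed(seed,
    phangorn::simSeq(tree, l = length, Q = Q, type = "DNA", rate = rate))
  m <- toupper(as.character(sim))
  rownames(m) <- names(sim)
  multiple_alignment(m, locus = locus, genome = genome)
}

# per-site random substitution: each site mutates with probability `rate`
# to one of the three other bases, uniformly
mutate_sequence <- function(seq_chars, rate) {
  if (rate <= 0) return(seq_chars)
  hit <- which(stats::runif(length(seq_chars)) < rate)
  for (i in hit) {
    seq_chars[i] <- sample(setdiff(BASES, seq_chars[i]), 1L)
  }
  seq_chars
}

#' Simulate a wild-species reference panel
#'
#' Builds the species tree, evolves every nuclear locus and the linked
#' chloroplast haplotype along it, expands each species into
#' `alleles_per_species` accession rows by shallow within-species mutation,
#' and (optionally) applies random chloroplast-capture events.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return a list of class `species_panel` with elements `species_ids`,
#'   `subsection_of`, `tree`, `loci` (list of `multiple_alignment`),
#'   `cp_haplotypes` (species -> string), `capture_events` (data.frame).
#' @export
simulate_panel <- function(cfg = sim_config(), seed = 1) {
  tree <- simulate_species_tree(cfg$n_species, cfg$birth_rate, seed = seed)
  species <- tree$tip.label
  # subsections from the two root clades
  root <- length(species) + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  left <- if (kids[1L] <= length(species)) species[kids[1L]] else
    ape::extract.clade(tree, kids[1L])$tip.label
  subsection <- stats::setNames(
    ifelse(species %in% left, "subsectA", "subsectB"), species)
  withr::with_seed(seed + 1L, {
    lens <- sample(seq(cfg$locus_length_range[1], cfg$locus_length_range[2]),
                   cfg$n_nuclear_loci, replace = TRUE)
    rates <- stats::runif(cfg$n_nuclear_loci, cfg$rate_range[1],
                          cfg$rate_range[2])
    locus_seeds <- sample.int(.Machine$integer.max, cfg$n_nuclear_loci + 1L)
  })
  loci <- vector("list", cfg$n_nuclear_loci)
  names(loci) <- sprintf("nuc%02d", seq_len(cfg$n_nuclear_loci))
  for (k in seq_len(cfg$n_nuclear_loci)) {
    base <- evolve_locus(tree, lens[k], rates[k], model = cfg$model,
                         seed = locus_seeds[k], locus = names(loci)[k])
    loci[[k]] <- expand_accessions(base, cfg$alleles_per_species,
                                   cfg$within_species_rate,
                                   seed = locus_seeds[k] %% 1000003L)
  }
  cp_base <- evolve_locus(tree, cfg$cp_length, cfg$cp_rate, model = cfg$model,
                          seed = locus_seeds[cfg$n_nuclear_loci + 1L],
                          locus = "cp", genome = "chloroplast")
  cp <- alignment_strings(cp_base)
  # wild species carry distinguishable chloroplast genotypes before any
  # capture event; species left identical by the simulation are separated
  # by two deterministic private substitutions each
  if (anyDuplicated(cp)) {
    withr::with_seed(locus_seeds[cfg$n_nuclear_loci + 1L] %% 1000003L, {
      while (anyDuplicated(cp)) {
        for (i in which(duplicated(cp))) {
          chars <- strsplit(cp[[i]], "")[[1]]
          pos <- sample(length(chars), 2L)
          chars[pos] <- vapply(chars[pos], function(b)
            sample(setdiff(BASES, b), 1L), character(1))
          cp[[i]] <- paste(chars, collapse = "")
        }
      }
    })
  }
  panel <- structure(list(species_ids = species,
                          subsection_of = subsection,
                          tree = tree, loci = loci, cp_haplotypes = cp,
                          capture_events = data.frame(donor = character(),
                                                      recipient = character())),
                     class = "species_panel")
  if (cfg$capture_probability > 0) {
    withr::with_seed(seed + 2L, {
      for (sp in species) {
        if (stats::runif(1) < cfg$capture_probability) {
          donor <- sample(setdiff(species, sp), 1L)
          panel <- apply_chloroplast_capture(panel, donor, sp)
        }
      }
    })
  }
  panel
}

# one base row per species -> alleles_per_species accession rows with
# shallow within-species mutation; labels "species|aNN"
expand_accessions <- function(base, n_alleles, rate, seed) {
  m <- unclass(base)
  out <- list()
  withr::with_seed(seed, {
    for (sp in rownames(m)) {
      for (a in seq_len(n_alleles)) {
        out[[paste0(sp, "|a", a)]] <- mutate_sequence(m[sp, ], rate)
      }
    }
  })
  mat <- do.call(rbind, out)
  multiple_alignment(mat, locus = attr(base, "locus"),
                     genome = attr(base, "genome"))
}

#' @export
print.species_panel <- function(x, ...) {
  cat(sprintf("<species_panel> %d species, %d nuclear loci, cp %d bp, %d capture event(s)\n",
              length(x$species_ids), length(x$loci),
              nchar(x$cp_haplotypes[[1]]), nrow(x$capture_events)))
  invisible(x)
}

#' Apply a chloroplast-capture event to a panel
#'
#' Replaces the recipient's chloroplast haplotype with a copy of the
#' donor's; nuclear loci are untouched and the event is recorded.
#'
#' @param panel a `species_panel`.
#' @param donor,recipient species ids (distinct, both in the panel).
#' @return the modified panel.
#' @export
apply_chloroplast_capture <- function(panel, donor, recipient) {
  if (donor == recipient) stop("donor and recipient must differ")
  for (sp in c(donor, recipient)) {
    if (!sp %in% panel$species_ids) stop("unknown species: ", sp)
  }
  panel$cp_haplotypes[[recipient]] <- panel$cp_haplotypes[[donor]]
  panel$capture_events <- rbind(panel$capture_events,
                                data.frame(donor = donor,
                                           recipient = recipient))
  panel
}

#' Generate hybrid cultivars with recorded truth
#'
#' Each cultivar draws a parental set from the pool (the pool's first
#' species is the maternal donor with probability `maternal_bias`), copies
#' its chloroplast from the maternal species, and at each nuclear locus
#' copies two alleles from accession rows of (recorded) parental species;
#' all copies are then mutated at `post_origin_mutation_rate`.
#'
#' @param panel a `species_panel`.
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @param pool optional explicit parental pool (species ids); by default
#'   the first `parental_pool_size` species of the larger subsection,
#'   topped up from the other subsection if needed.
#' @return list with `cultivars` (per-cultivar records: id, cp_haplotype,
#'   alleles[[locus]] = two strings) and `truth` (class `sim_truth`).
#' @export
generate_cultivars <- function(panel, cfg = sim_config(), seed = 1,
                               pool = NULL) {
  if (length(panel$loci) == 0L) stop("empty panel: no loci")
  if (is.null(pool)) {
    tab <- table(panel$subsection_of)
    big <- names(tab)[which.max(tab)]
    cand <- panel$species_ids[panel$subsection_of == big]
    pool <- utils::head(cand, cfg$parental_pool_size)
    if (length(pool) < cfg$parental_pool_size)
      pool <- c(pool, utils::head(setdiff(panel$species_ids, pool),
                                  cfg$parental_pool_size - length(pool)))
  }
  stopifnot(all(pool %in% panel$species_ids))
  loci <- names(panel$loci)
  # accession rows available per species per locus
  rows_of <- lapply(panel$loci, function(a) {
    sp <- sub("\\|.*$", "", rownames(a))
    split(rownames(a), sp)
  })
  cultivars <- vector("list", cfg$n_cultivars)
  truth_list <- vector("list", cfg$n_cultivars)
  ids <- sprintf("cv%02d", seq_len(cfg$n_cultivars))
  withr::with_seed(seed, {
    for (i in seq_len(cfg$n_cultivars)) {
      wts <- c(cfg$maternal_bias,
               rep((1 - cfg$maternal_bias) / (length(pool) - 1L),
                   length(pool) - 1L))
      maternal <- sample(pool, 1L, prob = wts)
      k <- if (length(cfg$parental_set_sizes) == 1L) cfg$parental_set_sizes
           else sample(cfg$parental_set_sizes, 1L)
      others <- setdiff(pool, maternal)
      pset <- sort(c(maternal, if (k > 1L) sample(others, k - 1L)))
      cp <- paste(mutate_sequence(strsplit(panel$cp_haplotypes[[maternal]],
                                           "")[[1]],
                                  cfg$post_origin_mutation_rate),
                  collapse = "")
      alleles <- list()
      origins <- list()
      for (lc in loci) {
        aln <- panel$loci[[lc]]
        osp <- sample(pset, 2L, replace = TRUE)
        pair <- character(2L)
        for (h in 1:2) {
          row <- if (length(rows_of[[lc]][[osp[h]]]) == 1L)
            rows_of[[lc]][[osp[h]]] else sample(rows_of[[lc]][[osp[h]]], 1L)
          pair[h] <- paste(mutate_sequence(unclass(aln)[row, ],
                                           cfg$post_origin_mutation_rate),
                           collapse = "")
        }
        alleles[[lc]] <- pair
        origins[[lc]] <- osp
      }
      cultivars[[i]] <- list(id = ids[i], cp_haplotype = cp,
                             alleles = alleles)
      truth_list[[i]] <- list(maternal_species = maternal,
                              parental_set = pset,
                              allele_origins = origins)
    }
  })
  names(cultivars) <- ids
  names(truth_list) <- ids
  truth <- structure(list(cultivars = truth_list,
                          capture_events = panel$capture_events,
                          pool = pool),
                     class = "sim_truth")
  list(cultivars = cultivars, truth = truth)
}

#' Sample sequencing clones from an allele pair
#'
#' Each clone copies one of the two alleles uniformly at random and then
#' receives independent per-site errors at `error_rate`.
#'
#' @param allele_pair character vector of two aligned allele strings.
#' @param n_clones number of clones (>= 1).
#' @param error_rate per-site error rate in [0, 1).
#' @param seed integer seed.
#' @return character vector of clone strings.
#' @export
sample_clones <- function(allele_pair, n_clones, error_rate = 0, seed = 1) {
  stopifnot(length(allele_pair) == 2L)
  if (n_clones < 1) stop("n_clones must be >= 1")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  withr::with_seed(seed, {
    vapply(seq_len(n_clones), function(i) {
      src <- strsplit(allele_pair[sample(2L, 1L)], "")[[1]]
      paste(mutate_sequence(src, error_rate), collapse = "")
    }, character(1))
  })
}

#' Simulate a complete dataset (panel + cultivars + clones + truth)
#'
#' Orchestrates [simulate_panel()], optional capture events,
#' [generate_cultivars()] and per-locus clone sampling
#' ([sample_clones()]).
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed fixing every random draw.
#' @param capture optional data.frame with columns `donor`, `recipient` of
#'   capture events to apply deterministically.
#' @return list of class `sim_dataset`: `panel`, `cultivars` (with a
#'   `clones[[locus]]` element per cultivar), `truth`, `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 1, capture = NULL) {
  panel <- simulate_panel(cfg, seed = seed)
  if (!is.null(capture)) {
    for (r in seq_len(nrow(capture))) {
      panel <- apply_chloroplast_capture(panel, capture$donor[r],
                                         capture$recipient[r])
    }
  }
  gen <- generate_cultivars(panel, cfg, seed = seed + 10L)
  cultivars <- gen$cultivars
  withr::with_seed(seed + 20L, {
    clone_seeds <- sample.int(.Machine$integer.max,
                              length(cultivars) * length(panel$loci))
    n_clones_draw <- sample(seq(cfg$clone_range[1], cfg$clone_range[2]),
                            length(cultivars) * length(panel$loci),
                            replace = TRUE)
  })
  idx <- 0L
  for (i in seq_along(cultivars)) {
    clones <- list()
    for (lc in names(panel$loci)) {
      idx <- idx + 1L
      clones[[lc]] <- sample_clones(cultivars[[i]]$alleles[[lc]],
                                    n_clones = n_clones_draw[idx],
                                    error_rate = cfg$clone_error_rate,
                                    seed = clone_seeds[idx])
    }
    cultivars[[i]]$clones <- clones
  }
  structure(list(panel = panel, cultivars = cultivars, truth = gen$truth,
                 cfg = cfg, seed = seed),
            class = "sim_dataset")
}

#' Write a simulated dataset to disk
#'
#' Emits one aligned FASTA per nuclear locus (panel accessions plus
#' cultivar clones, labels `SPECIES|accession` and `CULTIVAR|cloneN`), a
#' chloroplast FASTA, a truth TSV (one row per cultivar) and a plain-text
#' key-value config echo.
#'
#' @param dataset a `sim_dataset` from [simulate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return data.frame manifest of the files written.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  panel <- dataset$panel
  files <- character(0)
  for (lc in names(panel$loci)) {
    seqs <- alignment_strings(panel$loci[[lc]])
    for (cv in dataset$cultivars) {
      cl <- cv$clones[[lc]]
      names(cl) <- sprintf("%s|clone%02d", cv$id, seq_along(cl))
      seqs <- c(seqs, cl)
    }
    f <- file.path(out_dir, paste0(lc, ".fasta"))
    write_fasta(seqs, f)
    files <- c(files, f)
  }
  cp <- panel$cp_haplotypes
  cp_cv <- vapply(dataset$cultivars, `[[`, character(1), "cp_haplotype")
  f <- file.path(out_dir, "cp.fasta")
  write_fasta(c(cp, cp_cv), f)
  files <- c(files, f)
  tr <- dataset$truth$cultivars
  truth_df <- data.frame(
    cultivar = names(tr),
    maternal_species = vapply(tr, `[[`, character(1), "maternal_species"),
    parental_set = vapply(tr, function(x) paste(x$parental_set,
                                                collapse = ","), character(1)),
    allele_origins = vapply(tr, function(x) {
      paste(vapply(names(x$allele_origins), function(lc) {
        paste0(lc, ":", paste(x$allele_origins[[lc]], collapse = ","))
      }, character(1)), collapse = ";")
    }, character(1)),
    row.names = NULL)
  f <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth_df, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "config.txt")
  write_config(dataset$cfg, f, seed = dataset$seed)
  files <- c(files, f)
  data.frame(file = files,
             type = c(rep("fasta", length(panel$loci) + 1L), "truth",
                      "config"),
             row.names = NULL)
}
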