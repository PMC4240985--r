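# Synthetic-data generator: seed determinism, substitution-model closure,
# chloroplast capture, zero-noise identities, clone statistics, round trips.

test_that("species-tree simulation is seeded, ultrametric and binary", {
  t2 <- simulate_species_tree(2, 1, seed = 5)
  depth <- ape::node.depth.edgelength(t2)
  expect_equal(depth[1], depth[2], tolerance = 1e-10)
  a <- simulate_species_tree(8, 1, seed = 9)
  b <- simulate_species_tree(8, 1, seed = 9)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_equal(a$Nnode, 7)  # any rooted binary 8-leaf tree
  expect_true(ape::is.ultrametric(a))
  expect_error(simulate_species_tree(1), ">= 2")
})

test_that("locus evolution respects rate zero, determinism and the JC expectation", {
  tr <- simulate_species_tree(5, 1, seed = 3)
  a0 <- evolve_locus(tr, 300, 0, seed = 1)
  expect_equal(variable_site_count(a0), 0)
  a1 <- evolve_locus(tr, 300, 0.05, seed = 2)
  a2 <- evolve_locus(tr, 300, 0.05, seed = 2)
  expect_identical(unclass(a1), unclass(a2))
  expect_error(evolve_locus(tr, 300, 0.05, model = "HKY"), "arg")
  # two-leaf tree, path 2t: expected p-distance (3/4)(1 - exp(-4 d / 3))
  two <- ape::read.tree(text = "(A:1,B:1);")
  rate <- 0.05
  sim <- evolve_locus(two, 10000, rate, seed = 11)
  p_obs <- unname(pairwise_distance(sim, "p")["A", "B"])
  p_exp <- 0.75 * (1 - exp(-4 * 2 * rate / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("chloroplast capture copies the donor haplotype and leaves nuclei alone", {
  cfg <- sim_config(n_species = 6, n_nuclear_loci = 3,
                    locus_length_range = c(200, 400), n_cultivars = 0)
  panel <- simulate_panel(cfg, seed = 31)
  before <- lapply(panel$loci, unclass)
  cap <- apply_chloroplast_capture(panel, "sp01", "sp04")
  expect_identical(cap$cp_haplotypes[["sp04"]], cap$cp_haplotypes[["sp01"]])
  expect_identical(lapply(cap$loci, unclass), before)
  expect_equal(nrow(cap$capture_events), 1)
  cap2 <- apply_chloroplast_capture(cap, "sp02", "sp05")
  expect_equal(nrow(cap2$capture_events), 2)
  expect_error(apply_chloroplast_capture(panel, "sp01", "sp01"), "differ")
  expect_error(apply_chloroplast_capture(panel, "sp01", "spXX"), "unknown")
})

test_that("capture makes chloroplast and nuclear NJ trees discordant", {
  cfg <- sim_config(n_species = 6, n_nuclear_loci = 4,
                    locus_length_range = c(400, 800),
                    alleles_per_species = 1, within_species_rate = 0,
                    n_cultivars = 0)
  panel <- simulate_panel(cfg, seed = 57)
  nuc <- concatenate(panel$loci)
  rownames(nuc) <- sub("\\|.*$", "", rownames(nuc))
  nuc_tree <- neighbor_joining(pairwise_distance(nuc, "p"))
  make_cp_tree <- function(p) {
    cp_aln <- multiple_alignment(unlist(p$cp_haplotypes), locus = "cp",
                                 genome = "chloroplast")
    neighbor_joining(pairwise_distance(cp_aln, "p"))
  }
  # donor and recipient from opposite sides of the nuclear root split
  sides <- split(names(panel$subsection_of), panel$subsection_of)
  donor <- sides[[1]][1]; recipient <- sides[[2]][1]
  cap <- apply_chloroplast_capture(panel, donor, recipient)
  cp_tree <- make_cp_tree(cap)
  expect_gt(robinson_foulds(cp_tree, nuc_tree), 0)
})

test_that("zero post-origin noise makes cultivar alleles exact panel copies", {
  zn <- zero_noise_dataset()
  ds <- zn$ds
  refs <- species_reference(panel = ds$panel)
  for (cv in ds$cultivars[1:4]) {
    truth <- ds$truth$cultivars[[cv$id]]
    expect_identical(cv$cp_haplotype,
                     ds$panel$cp_haplotypes[[truth$maternal_species]])
    for (lc in names(cv$alleles)) {
      for (h in 1:2) {
        origin <- truth$allele_origins[[lc]][h]
        expect_true(cv$alleles[[lc]][h] %in%
                      refs$nuclear[[lc]][[origin]])
        expect_true(origin %in% truth$parental_set)
      }
    }
    expect_true(truth$maternal_species %in% truth$parental_set)
  }
})

test_that("singleton parental sets force every allele origin", {
  cfg <- sim_config(n_species = 4, n_nuclear_loci = 2,
                    locus_length_range = c(100, 150), n_cultivars = 3,
                    parental_pool_size = 2, parental_set_sizes = 1,
                    post_origin_mutation_rate = 0, clone_error_rate = 0)
  ds <- simulate_dataset(cfg, seed = 77)
  for (cv_id in names(ds$truth$cultivars)) {
    truth <- ds$truth$cultivars[[cv_id]]
    expect_length(truth$parental_set, 1)
    expect_true(all(unlist(truth$allele_origins) == truth$parental_set))
  }
})

test_that("clone sampling reproduces alleles and the binomial error expectation", {
  a <- paste(rep("A", 200), collapse = "")
  b <- paste(rep("C", 200), collapse = "")
  cl <- sample_clones(c(a, b), 16, error_rate = 0, seed = 3)
  expect_true(all(cl %in% c(a, b)))
  cl2 <- sample_clones(c(a, a), 8, error_rate = 0, seed = 4)
  expect_true(all(cl2 == a))
  # error_rate 0.01 on 1000 sites: about 10 erroneous sites per clone
  long <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                collapse = "")
  errs <- c()
  for (r in 1:200) {
    cl <- sample_clones(c(long, long), 16, error_rate = 0.01, seed = 100 + r)
    errs <- c(errs, vapply(cl, function(x)
      sum(strsplit(x, "")[[1]] != strsplit(long, "")[[1]]), numeric(1)))
  }
  se <- sqrt(1000 * 0.01 * 0.99 / length(errs))
  expect_lt(abs(mean(errs) - 10), 3 * se)
  expect_error(sample_clones(c(a, b), 0), "n_clones")
  expect_error(sample_clones(c(a, b), 4, error_rate = 1), "error_rate")
})

test_that("datasets are seed-deterministic and round-trip through disk", {
  zn <- zero_noise_dataset()
  ds <- zn$ds
  ds2 <- simulate_dataset(zn$cfg, seed = 42)
  expect_identical(ds[c("panel", "cultivars", "truth")],
                   ds2[c("panel", "cultivars", "truth")])
  dir <- file.path(tempdir(), "simds")
  unlink(dir, recursive = TRUE)
  manifest <- write_dataset(ds, dir)
  expect_equal(sum(manifest$type == "fasta"), length(ds$panel$loci) + 1)
  truth_df <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth_df), length(ds$cultivars))
  back <- read_dataset(dir)
  for (lc in names(ds$panel$loci)) {
    expect_identical(alignment_strings(back$panel_loci[[lc]]),
                     alignment_strings(ds$panel$loci[[lc]]))
  }
  expect_identical(sort(names(back$cultivar_clones)),
                   sort(names(ds$cultivars)))
  expect_identical(back$truth$cultivars$cv01$parental_set,
                   ds$truth$cultivars$cv01$parental_set)
})
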