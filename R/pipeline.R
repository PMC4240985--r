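# Config-driven end-to-end orchestration: simulate (or load) -> marker
# statistics and selection -> nuclear and chloroplast trees with
# discordance measures -> parentage matrix, calls and cohort summary ->
# recovery evaluation against simulation truth.

#' Pipeline configuration
#'
#' Analysis knobs layered on top of a [sim_config()]. `NULL` entries in
#' `...` fall back to the defaults shown.
#'
#' @param sim a [sim_config()] describing the simulated input (or `NULL`
#'   when reading data from `input_dir`).
#' @param input_dir directory holding a written dataset (see
#'   [write_dataset()]); used when `sim` is `NULL`.
#' @param select_k number of nuclear loci retained by marker screening.
#' @param builder tree builder for bootstrap, `"nj"` or `"mp"`.
#' @param bootstrap_reps bootstrap replicates.
#' @param max_mismatch nuclear allele-matching tolerance (0 = strict).
#' @param min_count clone dereplication threshold.
#' @param cp_ceiling maternal-assignment p-distance ceiling.
#' @param seed integer seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            select_k = 7, builder = "nj",
                            bootstrap_reps = 100, max_mismatch = 0,
                            min_count = 2, cp_ceiling = 0.01, seed = 1) {
  if (is.null(sim) && is.null(input_dir))
    stop("either a simulation config or an input directory is required")
  structure(list(sim = sim, input_dir = input_dir, select_k = select_k,
                 builder = builder, bootstrap_reps = bootstrap_reps,
                 max_mismatch = max_mismatch, min_count = min_count,
                 cp_ceiling = cp_ceiling, seed = seed),
            class = "pipeline_config")
}

#' Write a config echo as plain-text key = value lines
#' @param cfg a `sim_config` or `pipeline_config` (nested `sim` flattened
#'   with a `sim.` prefix).
#' @param path output path.
#' @param seed optional seed recorded alongside.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path, seed = NULL) {
  flat <- list()
  for (k in names(cfg)) {
    v <- cfg[[k]]
    if (is.null(v)) next
    if (inherits(v, "sim_config")) {
      for (k2 in names(v)) flat[[paste0("sim.", k2)]] <- v[[k2]]
    } else flat[[k]] <- v
  }
  if (!is.null(seed)) flat[["seed"]] <- seed
  lines <- vapply(names(flat), function(k) {
    paste0(k, " = ", paste(flat[[k]], collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text key = value config file
#'
#' Values are split on commas; numeric-looking fields are converted.
#' Keys with a `sim.` prefix populate the nested simulation config.
#'
#' @param path config file path.
#' @return named list (with a `sim` sublist when `sim.` keys are present).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",")[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    v <- if (!anyNA(nums)) nums else parts
    if (startsWith(key, "sim.")) {
      out$sim[[sub("^sim\\.", "", key)]] <- v
    } else out[[key]] <- v
  }
  out
}

#' Read a written dataset back from disk
#'
#' Reverses [write_dataset()]: per-locus FASTAs are split into panel
#' accessions (labels `SPECIES|accession`) and cultivar clones (labels
#' `CULTIVAR|cloneNN`), the cp FASTA into species haplotypes and cultivar
#' haplotypes, and the truth TSV is parsed when present.
#'
#' @param dir dataset directory.
#' @return list: `panel_loci`, `cp_refs`, `cultivar_clones`
#'   (cultivar -> locus -> clone strings), `cultivar_cp`, `truth` (or
#'   `NULL`).
#' @export
read_dataset <- function(dir) {
  fastas <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (length(fastas) == 0L) stop("no FASTA files in ", dir)
  is_clone <- function(labs) grepl("\\|clone[0-9]+$", labs)
  panel_loci <- list()
  cultivar_clones <- list()
  for (f in setdiff(fastas, file.path(dir, "cp.fasta"))) {
    locus <- sub("\\.fasta$", "", basename(f))
    seqs <- read_fasta(f, aligned = FALSE)
    cl <- is_clone(names(seqs))
    panel_loci[[locus]] <- multiple_alignment(seqs[!cl], locus = locus)
    for (lab in names(seqs)[cl]) {
      cv <- sub("\\|clone[0-9]+$", "", lab)
      cultivar_clones[[cv]][[locus]] <-
        c(cultivar_clones[[cv]][[locus]], unname(seqs[lab]))
    }
  }
  cp_refs <- NULL
  cultivar_cp <- NULL
  cp_file <- file.path(dir, "cp.fasta")
  if (file.exists(cp_file)) {
    seqs <- read_fasta(cp_file, aligned = FALSE)
    cvs <- names(seqs) %in% names(cultivar_clones)
    cp_refs <- as.list(seqs[!cvs])
    cultivar_cp <- seqs[cvs]
  }
  truth <- NULL
  truth_file <- file.path(dir, "truth.tsv")
  if (file.exists(truth_file)) {
    df <- utils::read.delim(truth_file, stringsAsFactors = FALSE)
    truth_list <- lapply(seq_len(nrow(df)), function(i) {
      origins <- NULL
      if (nzchar(df$allele_origins[i])) {
        parts <- strsplit(df$allele_origins[i], ";")[[1]]
        origins <- lapply(parts, function(p)
          strsplit(sub("^[^:]*:", "", p), ",")[[1]])
        names(origins) <- sub(":.*$", "", parts)
      }
      list(maternal_species = df$maternal_species[i],
           parental_set = strsplit(df$parental_set[i], ",")[[1]],
           allele_origins = origins)
    })
    names(truth_list) <- df$cultivar
    truth <- structure(list(cultivars = truth_list,
                            capture_events = NULL, pool = NULL),
                       class = "sim_truth")
  }
  list(panel_loci = panel_loci, cp_refs = cp_refs,
       cultivar_clones = cultivar_clones, cultivar_cp = cultivar_cp,
       truth = truth)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate the dataset; per-locus marker
#' statistics and top-k selection; nuclear concatenated tree with
#' bootstrap, chloroplast tree, and discordance summary; clone
#' dereplication, parentage matrix, per-cultivar calls and cohort summary;
#' recovery evaluation when simulation truth is available. All artifacts
#' are written to `out_dir` (TSV / Newick / FASTA plus a config echo), and
#' a rerun with the same config and seed reproduces them byte-identically.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (`NULL` = no files written).
#' @param quiet suppress per-stage messages.
#' @return list of class `pipeline_result`: `marker_stats`,
#'   `selected_loci`, `nuclear_tree`, `cp_tree`, `discordance`, `pmat`,
#'   `calls`, `summary`, `recovery` (or `NULL`), `dataset`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[hybparent] ", ...)
  stage <- "load"
  res <- tryCatch({
    # ---- stage: load or simulate ----
    if (!is.null(cfg$sim)) {
      say("simulating dataset (seed ", cfg$seed, ")")
      ds <- simulate_dataset(cfg$sim, seed = cfg$seed)
      panel_loci <- ds$panel$loci
      cp_refs <- as.list(ds$panel$cp_haplotypes)
      cultivar_clones <- lapply(ds$cultivars, `[[`, "clones")
      cultivar_cp <- vapply(ds$cultivars, `[[`, character(1), "cp_haplotype")
      truth <- ds$truth
    } else {
      say("reading dataset from ", cfg$input_dir)
      ds <- read_dataset(cfg$input_dir)
      panel_loci <- ds$panel_loci
      cp_refs <- ds$cp_refs
      cultivar_clones <- ds$cultivar_clones
      cultivar_cp <- ds$cultivar_cp
      truth <- ds$truth
    }
    say(length(panel_loci), " loci, ", length(cultivar_clones),
        " cultivars")

    # ---- stage: marker statistics and selection ----
    stage <- "markerstats"
    stats_df <- do.call(rbind, lapply(panel_loci, marker_stats))
    k <- min(cfg$select_k, nrow(stats_df))
    selected <- rank_and_select_markers(stats_df, k = k, genome = "nuclear")
    say("selected ", k, " most informative nuclear loci: ",
        paste(selected, collapse = ", "))

    # ---- stage: trees and discordance ----
    stage <- "trees"
    concat <- concatenate(panel_loci)
    nuclear_tree <- bootstrap_support(concat, builder = cfg$builder,
                                      reps = cfg$bootstrap_reps,
                                      seed = cfg$seed)
    species <- sort(unique(sub("\\|.*$", "", rownames(concat))))
    # species-level nuclear tree (first accession per species)
    reps_rows <- vapply(species, function(s)
      grep(paste0("^", s, "\\|"), rownames(concat), value = TRUE)[1],
      character(1))
    sp_concat_m <- unclass(concat)[reps_rows, , drop = FALSE]
    rownames(sp_concat_m) <- species
    sp_concat <- multiple_alignment(sp_concat_m, locus = "concat")
    nuclear_sp_tree <- ape::unroot(
      neighbor_joining(pairwise_distance(sp_concat, "p")))
    cp_aln <- multiple_alignment(unlist(lapply(cp_refs, `[`, 1L)),
                                 labels = names(cp_refs), locus = "cp",
                                 genome = "chloroplast")
    cp_tree <- ape::unroot(neighbor_joining(pairwise_distance(cp_aln, "p")))
    rf <- robinson_foulds(cp_tree, nuclear_sp_tree)
    mono_fail <- character(0)
    for (s in species) {
      accs <- grep(paste0("^", s, "\\|"), rownames(concat), value = TRUE)
      if (length(accs) >= 2L && !is_monophyletic(nuclear_tree, accs))
        mono_fail <- c(mono_fail, s)
    }
    discordance <- list(rf_cp_vs_nuclear = rf,
                        nuclear_monophyly_failures = mono_fail)
    say("RF(cp, nuclear) = ", rf)

    # ---- stage: parentage ----
    stage <- "parentage"
    pmat <- NULL; calls <- NULL; summary <- NULL
    if (length(cultivar_clones) == 0L) {
      say("no cultivars: parentage stage skipped")
    } else {
      refs <- species_reference(
        nuclear = lapply(panel_loci[selected], function(a) {
          sp <- sub("\\|.*$", "", rownames(a))
          lapply(split(alignment_strings(a), sp), unique)
        }),
        cp = cp_refs)
      observations <- list()
      for (cv in names(cultivar_clones)) {
        for (lc in intersect(selected, names(cultivar_clones[[cv]]))) {
          observations[[length(observations) + 1L]] <-
            dereplicate_clones(cultivar_clones[[cv]][[lc]],
                               min_count = cfg$min_count, refs = refs,
                               locus = lc, cultivar = cv)
        }
      }
      pmat <- build_parentage_matrix(observations, refs,
                                     cp_haplotypes = cultivar_cp,
                                     max_mismatch = cfg$max_mismatch,
                                     cp_ceiling = cfg$cp_ceiling)
      calls <- call_parentage(pmat)
      summary <- cohort_summary(calls)
      say("cohort parental union: ",
          paste(summary$parental_union, collapse = ", "))
    }

    # ---- stage: evaluation ----
    stage <- "evaluate"
    recovery <- NULL
    if (!is.null(calls) && !is.null(truth)) {
      recovery <- evaluate_recovery(calls, truth)
      say(sprintf("recovery: precision %.3f, recall %.3f, maternal %.3f",
                  recovery$precision, recovery$recall,
                  recovery$maternal_accuracy))
    }
    list(marker_stats = stats_df, selected_loci = selected,
         nuclear_tree = nuclear_tree, nuclear_species_tree = nuclear_sp_tree,
         cp_tree = cp_tree, discordance = discordance, pmat = pmat,
         calls = calls, summary = summary, recovery = recovery,
         dataset = ds)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(res, cfg, out_dir)
  res
}

write_pipeline_outputs <- function(res, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name, comment) {
    f <- file.path(out_dir, name)
    con <- file(f, "w")
    writeLines(paste0("# ", comment), con)
    close(con)
    suppressWarnings(utils::write.table(df, f, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    f
  }
  tsv(format_marker_stats(res$marker_stats), "marker_stats.tsv",
      "per-locus statistics: aligned length, variable %, parsimony-informative %, pi, base-composition chi2")
  writeLines(res$selected_loci, file.path(out_dir, "selected_loci.txt"))
  write_newick(res$nuclear_tree, file.path(out_dir, "nuclear_tree.nwk"))
  write_newick(res$cp_tree, file.path(out_dir, "cp_tree.nwk"))
  writeLines(c(paste0("rf_cp_vs_nuclear\t", res$discordance$rf_cp_vs_nuclear),
               paste0("nuclear_monophyly_failures\t",
                      paste(res$discordance$nuclear_monophyly_failures,
                            collapse = ","))),
             file.path(out_dir, "discordance.tsv"))
  if (!is.null(res$pmat)) {
    tsv(parentage_matrix_table(res$pmat), "parentage_matrix.tsv",
        "cultivar x marker matched species (semicolon-joined; empty = no 100% match)")
    calls_df <- data.frame(
      cultivar = names(res$calls),
      maternal = vapply(res$calls, function(x)
        if (is.null(x$maternal) || is.na(x$maternal$species)) ""
        else x$maternal$species, character(1)),
      maternal_distance = vapply(res$calls, function(x)
        if (is.null(x$maternal)) NA_real_ else x$maternal$distance,
        numeric(1)),
      parental_set = vapply(res$calls, function(x)
        paste(x$parental_set, collapse = ","), character(1)),
      unexplained = vapply(res$calls, `[[`, numeric(1), "unexplained"),
      row.names = NULL)
    tsv(calls_df, "parentage_calls.tsv",
        "per-cultivar maternal assignment and minimal parental set")
    cs <- res$summary
    tsv(data.frame(species = names(cs$per_species_counts),
                   cultivars_supported = as.integer(cs$per_species_counts)),
        "cohort_summary.tsv",
        paste0("parental union: ", paste(cs$parental_union, collapse = ",")))
  }
  if (!is.null(res$recovery)) {
    rec <- res$recovery
    tsv(data.frame(metric = c("precision", "recall", "f1",
                              "maternal_accuracy", "exact_set_rate"),
                   value = c(rec$precision, rec$recall, rec$f1,
                             rec$maternal_accuracy, rec$exact_set_rate)),
        "recovery.tsv", "recovery vs simulation truth")
  }
  write_config(cfg, file.path(out_dir, "config_echo.txt"))
  invisible(out_dir)
}

#' Evaluate parentage calls against simulation truth
#'
#' Cohort precision and recall compare the inferred and true parental
#' unions; maternal accuracy is the fraction of cultivars whose primary
#' maternal assignment equals the true maternal species; the exact-set
#' rate is the fraction whose minimal cover equals the true parental set.
#'
#' @param calls list of `parentage_call` objects.
#' @param truth a `sim_truth`.
#' @return list of class `recovery_report`: `precision` (`NA` when the
#'   inferred union is empty), `recall`, `f1`, `maternal_accuracy`,
#'   `exact_set_rate`, `inferred_union`, `true_union`.
#' @export
evaluate_recovery <- function(calls, truth) {
  ids_c <- names(calls)
  ids_t <- names(truth$cultivars)
  orphans <- c(setdiff(ids_c, ids_t), setdiff(ids_t, ids_c))
  if (length(orphans) > 0)
    stop("cultivar ids do not align between calls and truth: ",
         paste(orphans, collapse = ", "))
  inferred <- sort(unique(unlist(lapply(calls, `[[`, "parental_set"))))
  true_union <- sort(unique(unlist(lapply(truth$cultivars, `[[`,
                                          "parental_set"))))
  inter <- length(intersect(inferred, true_union))
  precision <- if (length(inferred) == 0L) NA_real_ else
    inter / length(inferred)
  recall <- inter / length(true_union)
  f1 <- if (is.na(precision) || precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  mat_ok <- vapply(ids_c, function(cv) {
    m <- calls[[cv]]$maternal
    !is.null(m) && !is.na(m$species) &&
      m$species == truth$cultivars[[cv]]$maternal_species
  }, logical(1))
  exact_ok <- vapply(ids_c, function(cv) {
    setequal(calls[[cv]]$parental_set, truth$cultivars[[cv]]$parental_set)
  }, logical(1))
  structure(list(precision = precision, recall = recall, f1 = f1,
                 maternal_accuracy = mean(mat_ok),
                 exact_set_rate = mean(exact_ok),
                 inferred_union = inferred, true_union = true_union),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> precision %.3f, recall %.3f, F1 %.3f; maternal accuracy %.3f; exact-set rate %.3f\n",
              x$precision, x$recall, x$f1, x$maternal_accuracy,
              x$exact_set_rate))
  invisible(x)
}
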