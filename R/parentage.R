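# Identity-based parentage inference: dereplicate cultivar clones into
# allele haplotypes, match them against a wild-species reference panel at
# 100% identity (with an optional mismatch tolerance), assign the maternal
# donor from the chloroplast haplotype, and infer the minimal parental
# species set by exact set cover.

#' Build a species reference from a simulated panel or explicit lists
#'
#' @param panel optional `species_panel`; its accession rows are grouped by
#'   species (label prefix before `|`) and deduplicated per locus.
#' @param nuclear optional list: locus -> species -> character vector of
#'   allele strings (used when `panel` is `NULL`).
#' @param cp optional list: species -> character vector of chloroplast
#'   haplotypes.
#' @param exclude species ids to drop (e.g. outgroups).
#' @return list of class `species_reference` with elements `nuclear`, `cp`,
#'   `locus_length` (locus -> bp).
#' @export
species_reference <- function(panel = NULL, nuclear = NULL, cp = NULL,
                              exclude = character(0)) {
  if (!is.null(panel)) {
    nuclear <- lapply(panel$loci, function(a) {
      sp <- sub("\\|.*$", "", rownames(a))
      lapply(split(alignment_strings(a), sp), unique)
    })
    cp <- lapply(panel$cp_haplotypes, identity)
  }
  if (is.null(nuclear) || length(nuclear) == 0L)
    stop("a species reference needs at least one nuclear locus")
  if (length(exclude) > 0) {
    nuclear <- lapply(nuclear, function(x) x[setdiff(names(x), exclude)])
    if (!is.null(cp)) cp <- cp[setdiff(names(cp), exclude)]
  }
  for (lc in names(nuclear)) {
    if (any(vapply(nuclear[[lc]], length, integer(1)) == 0L))
      stop("every species must carry >= 1 allele at locus ", lc)
  }
  locus_length <- vapply(nuclear, function(x) nchar(x[[1]][1]), integer(1))
  structure(list(nuclear = nuclear, cp = cp, locus_length = locus_length),
            class = "species_reference")
}

# mismatches between two equal-length strings, sites missing (N/-) in
# either excluded; returns c(mismatches, compared)
string_mismatch <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  comp <- x %in% BASES & y %in% BASES
  c(mismatch = sum(x[comp] != y[comp]), compared = sum(comp))
}

#' Dereplicate sequencing clones into allele haplotypes
#'
#' Identical clones are collapsed with counts. Haplotypes seen fewer than
#' `min_count` times are discarded as likely PCR/sequencing artifacts,
#' unless they exactly match a reference allele (rescue rule). The most
#' frequent haplotype is always retained.
#'
#' @param clones character vector of clone strings (>= 1).
#' @param min_count minimum clone count for retention.
#' @param refs optional `species_reference` used for the rescue rule.
#' @param locus locus id (needed for rescue).
#' @param cultivar cultivar id recorded in the observation.
#' @return list of class `allele_observation`: `cultivar`, `locus`,
#'   `alleles` (data.frame haplotype/count, most frequent first).
#' @export
dereplicate_clones <- function(clones, min_count = 2, refs = NULL,
                               locus = NULL, cultivar = NA_character_) {
  if (length(clones) == 0L) stop("empty clone list")
  tab <- sort(table(clones), decreasing = TRUE)
  haps <- names(tab)
  counts <- as.integer(tab)
  keep <- counts >= min_count
  if (!is.null(refs) && !is.null(locus) && locus %in% names(refs$nuclear)) {
    ref_alleles <- unique(unlist(refs$nuclear[[locus]], use.names = FALSE))
    keep <- keep | haps %in% ref_alleles
  }
  keep[which.max(counts)] <- TRUE
  structure(list(cultivar = cultivar, locus = locus,
                 alleles = data.frame(haplotype = haps[keep],
                                      count = counts[keep],
                                      row.names = NULL)),
            class = "allele_observation")
}

#' Match one allele haplotype against the reference panel
#'
#' With `max_mismatch = 0` (default) returns every species owning an
#' allele 100% identical to the haplotype (missing sites excluded
#' pairwise). With `max_mismatch > 0`, returns the species achieving the
#' minimum mismatch count, provided it is within the tolerance; the
#' distance is attached as an attribute.
#'
#' @param haplotype allele string, same aligned length as the locus.
#' @param refs a `species_reference`.
#' @param locus locus id.
#' @param max_mismatch mismatch tolerance (0 = strict identity).
#' @return character vector of matched species (possibly empty) with
#'   attribute `distance` (mismatch count of the match, `NA` if none).
#' @export
match_allele <- function(haplotype, refs, locus, max_mismatch = 0) {
  if (!locus %in% names(refs$nuclear)) stop("unknown locus: ", locus)
  if (nchar(haplotype) != refs$locus_length[[locus]])
    stop("haplotype length ", nchar(haplotype),
         " does not match the aligned length ",
         refs$locus_length[[locus]], " of locus ", locus)
  per_species <- vapply(refs$nuclear[[locus]], function(alleles) {
    min(vapply(alleles, function(a) string_mismatch(haplotype, a)[1L],
               numeric(1)))
  }, numeric(1))
  if (max_mismatch == 0) {
    hit <- names(per_species)[per_species == 0]
    dist <- if (length(hit) > 0) 0 else NA_real_
  } else {
    best <- min(per_species)
    if (best <= max_mismatch) {
      hit <- names(per_species)[per_species == best]
      dist <- best
    } else {
      hit <- character(0)
      dist <- NA_real_
    }
  }
  structure(sort(hit), distance = dist)
}

#' Build the cultivar x marker parentage matrix
#'
#' Each nuclear cell is the union of [match_allele()] results over the
#' cultivar's haplotypes at that locus; unmatched haplotypes are tallied
#' separately. When cultivar chloroplast haplotypes and cp references are
#' supplied, a final `cp` column holds the maternal assignment.
#'
#' @param observations list of `allele_observation` objects.
#' @param refs a `species_reference`.
#' @param cp_haplotypes optional named character vector (cultivar -> cp
#'   haplotype string).
#' @param max_mismatch nuclear matching tolerance (default strict).
#' @param cp_ceiling p-distance ceiling for maternal assignment.
#' @return list of class `parentage_matrix`: `cells` (cultivar x marker
#'   list-matrix of species sets), `maternal` (per-cultivar assignment
#'   list), `unmatched` (data.frame cultivar/locus/n_unmatched).
#' @export
build_parentage_matrix <- function(observations, refs, cp_haplotypes = NULL,
                                   max_mismatch = 0, cp_ceiling = 0.01) {
  loci <- unique(vapply(observations, `[[`, character(1), "locus"))
  bad <- setdiff(loci, names(refs$nuclear))
  if (length(bad) > 0) stop("loci absent from reference: ",
                            paste(bad, collapse = ", "))
  cultivars <- unique(vapply(observations, `[[`, character(1), "cultivar"))
  markers <- c(loci, if (!is.null(cp_haplotypes)) "cp")
  cells <- matrix(vector("list", length(cultivars) * length(markers)),
                  nrow = length(cultivars),
                  dimnames = list(cultivars, markers))
  for (cv in cultivars) for (lc in loci) cells[[cv, lc]] <- character(0)
  unmatched <- data.frame(cultivar = character(), locus = character(),
                          n_unmatched = integer())
  for (obs in observations) {
    hit <- character(0)
    n_un <- 0L
    for (h in obs$alleles$haplotype) {
      sp <- match_allele(h, refs, obs$locus, max_mismatch = max_mismatch)
      if (length(sp) == 0L) n_un <- n_un + 1L
      hit <- union(hit, sp)
    }
    cells[[obs$cultivar, obs$locus]] <-
      sort(union(cells[[obs$cultivar, obs$locus]], hit))
    if (n_un > 0L)
      unmatched <- rbind(unmatched,
                         data.frame(cultivar = obs$cultivar,
                                    locus = obs$locus, n_unmatched = n_un))
  }
  maternal <- NULL
  if (!is.null(cp_haplotypes)) {
    maternal <- vector("list", length(cultivars))
    names(maternal) <- cultivars
    for (cv in cultivars) {
      if (!cv %in% names(cp_haplotypes)) {
        cells[[cv, "cp"]] <- character(0)
        next
      }
      nm <- nuclear_match_counts(cells[cv, loci, drop = TRUE])
      asg <- assign_maternal(cp_haplotypes[[cv]], refs, ceiling = cp_ceiling,
                             nuclear_matches = nm)
      maternal[[cv]] <- asg
      cells[[cv, "cp"]] <- if (is.na(asg$species)) character(0) else
        asg$species
    }
  }
  structure(list(cells = cells, maternal = maternal, unmatched = unmatched,
                 species = sort(unique(unlist(lapply(refs$nuclear, names))))),
            class = "parentage_matrix")
}

nuclear_match_counts <- function(cell_list) {
  sp <- unlist(cell_list, use.names = FALSE)
  if (length(sp) == 0L) return(integer(0))
  table(sp)
}

#' @export
print.parentage_matrix <- function(x, ...) {
  cat(sprintf("<parentage_matrix> %d cultivars x %d markers; %d unmatched haplotype record(s)\n",
              nrow(x$cells), ncol(x$cells), nrow(x$unmatched)))
  invisible(x)
}

#' Export a parentage matrix as a character data.frame
#'
#' Cells become semicolon-joined species ids (empty string = no match) —
#' a machine-readable version of the allele-sharing figure.
#'
#' @param pmat a `parentage_matrix`.
#' @return data.frame with a `cultivar` column plus one column per marker.
#' @export
parentage_matrix_table <- function(pmat) {
  df <- data.frame(cultivar = rownames(pmat$cells), row.names = NULL)
  for (mk in colnames(pmat$cells)) {
    df[[mk]] <- vapply(pmat$cells[, mk],
                       function(s) paste(s, collapse = ";"), character(1))
  }
  df
}

#' Assign the maternal donor from a chloroplast haplotype
#'
#' The species minimising the p-distance to the cultivar's chloroplast
#' haplotype is assigned (distance 0 reported as exact). Ties are broken by
#' the species matching at the most nuclear markers for that cultivar,
#' then lexically; all tied species are reported. Distances above
#' `ceiling` leave the cultivar unassigned.
#'
#' @param cp_haplotype cultivar chloroplast haplotype string.
#' @param refs a `species_reference` with nonempty `cp`.
#' @param ceiling maximum p-distance for an assignment.
#' @param nuclear_matches optional named counts of nuclear-marker matches
#'   per species for this cultivar (tie-breaking evidence).
#' @return list: `species` (primary, `NA` if unassigned), `distance`
#'   (p-distance), `exact` (logical), `ties` (all minimising species).
#' @export
assign_maternal <- function(cp_haplotype, refs, ceiling = 0.01,
                            nuclear_matches = NULL) {
  if (is.null(refs$cp) || length(refs$cp) == 0L)
    stop("reference has no chloroplast haplotypes")
  d <- vapply(refs$cp, function(haps) {
    min(vapply(haps, function(h) {
      mm <- string_mismatch(cp_haplotype, h)
      if (mm[2L] == 0L) return(Inf)
      mm[1L] / mm[2L]
    }, numeric(1)))
  }, numeric(1))
  best <- min(d)
  if (!is.finite(best) || best > ceiling)
    return(list(species = NA_character_, distance = best, exact = FALSE,
                ties = character(0)))
  ties <- sort(names(d)[d == best])
  primary <- ties
  if (length(ties) > 1L && !is.null(nuclear_matches) &&
      length(nuclear_matches) > 0L) {
    nm <- vapply(ties, function(s) {
      v <- nuclear_matches[s]
      if (is.na(v)) 0L else as.integer(v)
    }, integer(1))
    primary <- ties[nm == max(nm)]
  }
  list(species = sort(primary)[1L], distance = unname(best),
       exact = best == 0, ties = if (length(ties) > 1L) ties else character(0))
}

# exact minimum set cover by subset-size enumeration; cells is a list of
# nonempty character sets, candidates the universe of species
set_cover_exact <- function(cells, candidates, required = character(0)) {
  covers_all <- function(set) all(vapply(cells, function(cl)
    any(cl %in% set), logical(1)))
  free <- setdiff(candidates, required)
  base_k <- length(required)
  for (extra in 0:length(free)) {
    combos <- if (extra == 0L) list(character(0)) else
      utils::combn(free, extra, simplify = FALSE)
    sols <- Filter(function(s) covers_all(c(required, s)), combos)
    if (length(sols) > 0)
      return(lapply(sols, function(s) sort(c(required, s))))
  }
  list()
}

set_cover_greedy <- function(cells, candidates, required = character(0)) {
  chosen <- required
  remaining <- Filter(function(cl) !any(cl %in% chosen), cells)
  while (length(remaining) > 0L) {
    gain <- vapply(setdiff(candidates, chosen), function(s)
      sum(vapply(remaining, function(cl) s %in% cl, logical(1))),
      integer(1))
    if (length(gain) == 0L || max(gain) == 0L) break
    pick <- names(gain)[gain == max(gain)]
    chosen <- c(chosen, sort(pick)[1L])
    remaining <- Filter(function(cl) !any(cl %in% chosen), remaining)
  }
  list(sort(chosen))
}

#' Infer the minimal parental species set for one cultivar
#'
#' Finds the minimum-cardinality species set that contains the maternal
#' species (when assigned) and hits every nonempty marker cell — set cover
#' with cells as subsets. Exact enumeration for up to `exact_max` candidate
#' species, greedy beyond. Among minimal covers, ties are broken by total
#' marker coverage then lexical order; all co-optimal covers are reported.
#'
#' @param cells list (or one `parentage_matrix` row) of species sets per
#'   marker; empty cells are ignored.
#' @param maternal maternal species id or `NA`/`NULL`.
#' @param exact_max largest candidate count for exact search.
#' @param known_species reference species ids; when the maternal species is
#'   absent from every cell *and* from this list, an inconsistency warning
#'   is raised and the cover is computed without the maternal constraint
#'   (`NULL` = treat the maternal species as known).
#' @return list: `parental_set` (primary cover), `all_covers` (list of all
#'   minimal covers), `exact` (logical).
#' @export
infer_parent_set <- function(cells, maternal = NULL, exact_max = 15,
                             known_species = NULL) {
  cells <- Filter(length, cells)
  if (is.null(maternal) || length(maternal) == 0L || is.na(maternal))
    maternal <- NULL
  if (!is.null(maternal) && !is.null(known_species) &&
      !maternal %in% known_species &&
      !maternal %in% unlist(cells, use.names = FALSE)) {
    warning("maternal species ", maternal, " absent from every cell and ",
            "from the references; cover computed without constraint")
    maternal <- NULL
  }
  candidates <- sort(unique(c(unlist(cells, use.names = FALSE), maternal)))
  if (length(cells) == 0L) {
    if (is.null(maternal)) stop("no nonempty cell and no maternal species")
    return(list(parental_set = maternal, all_covers = list(maternal),
                exact = TRUE))
  }
  required <- if (is.null(maternal)) character(0) else maternal
  exact <- length(candidates) <= exact_max
  covers <- if (exact) set_cover_exact(cells, candidates, required)
            else set_cover_greedy(cells, candidates, required)
  if (length(covers) == 0L) covers <- set_cover_greedy(cells, candidates,
                                                       required)
  coverage <- vapply(covers, function(s)
    sum(vapply(cells, function(cl) sum(cl %in% s), integer(1))), integer(1))
  keys <- vapply(covers, paste, character(1), collapse = ",")
  ord <- order(-coverage, keys)
  covers <- covers[ord]
  list(parental_set = covers[[1L]], all_covers = covers, exact = exact)
}

#' Call parentage for every cultivar in a parentage matrix
#'
#' @param pmat a `parentage_matrix` (with maternal assignments when a cp
#'   column is present).
#' @param exact_max passed to [infer_parent_set()].
#' @return list of `parentage_call` objects: `cultivar`, `maternal`
#'   (assignment list or `NULL`), `parental_set`, `all_covers`,
#'   `evidence` (the matrix row), `unexplained` (unmatched haplotype
#'   count).
#' @export
call_parentage <- function(pmat, exact_max = 15) {
  loci <- setdiff(colnames(pmat$cells), "cp")
  out <- vector("list", nrow(pmat$cells))
  names(out) <- rownames(pmat$cells)
  for (cv in rownames(pmat$cells)) {
    maternal <- if (!is.null(pmat$maternal)) pmat$maternal[[cv]] else NULL
    msp <- if (!is.null(maternal)) maternal$species else NULL
    cover <- infer_parent_set(pmat$cells[cv, loci, drop = TRUE],
                              maternal = msp, exact_max = exact_max,
                              known_species = pmat$species)
    un <- pmat$unmatched[pmat$unmatched$cultivar == cv, , drop = FALSE]
    out[[cv]] <- structure(list(cultivar = cv, maternal = maternal,
                                parental_set = cover$parental_set,
                                all_covers = cover$all_covers,
                                evidence = pmat$cells[cv, , drop = TRUE],
                                unexplained = sum(un$n_unmatched)),
                           class = "parentage_call")
  }
  out
}

#' @export
print.parentage_call <- function(x, ...) {
  mat <- if (is.null(x$maternal) || is.na(x$maternal$species)) "unassigned"
         else sprintf("%s (d=%.4g%s)", x$maternal$species,
                      x$maternal$distance,
                      if (x$maternal$exact) ", exact" else "")
  cat(sprintf("<parentage_call> %s: maternal %s; parents {%s}; %d unexplained haplotype(s)\n",
              x$cultivar, mat, paste(x$parental_set, collapse = ", "),
              x$unexplained))
  invisible(x)
}

#' Summarise parentage calls over a cultivar cohort
#'
#' @param calls list of `parentage_call` objects.
#' @return list of class `cohort_summary`: `parental_union`,
#'   `per_species_counts` (cultivars supported per species),
#'   `maternal_tally` (cultivar counts per maternal donor),
#'   `n_unassigned_maternal`, `per_marker_frequencies`.
#' @export
cohort_summary <- function(calls) {
  if (length(calls) == 0L) stop("no parentage calls")
  psets <- lapply(calls, `[[`, "parental_set")
  parental_union <- sort(unique(unlist(psets)))
  per_species <- vapply(parental_union, function(s)
    sum(vapply(psets, function(p) s %in% p, logical(1))), integer(1))
  mats <- vapply(calls, function(x) {
    if (is.null(x$maternal) || is.na(x$maternal$species)) NA_character_
    else x$maternal$species
  }, character(1))
  maternal_tally <- table(mats[!is.na(mats)])
  markers <- unique(unlist(lapply(calls, function(x) names(x$evidence))))
  per_marker <- lapply(stats::setNames(markers, markers), function(mk) {
    sp <- unlist(lapply(calls, function(x) x$evidence[[mk]]))
    if (length(sp) == 0L) table(character(0)) else table(sp)
  })
  structure(list(parental_union = parental_union,
                 per_species_counts = per_species,
                 maternal_tally = maternal_tally,
                 n_unassigned_maternal = sum(is.na(mats)),
                 per_marker_frequencies = per_marker,
                 n_cultivars = length(calls)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d cultivars\n", x$n_cultivars))
  cat("  parental union:", paste(x$parental_union, collapse = ", "), "\n")
  cat("  cultivars supported per species:\n")
  for (s in names(x$per_species_counts))
    cat(sprintf("    %s: %d\n", s, x$per_species_counts[[s]]))
  cat("  maternal donors:\n")
  for (s in names(x$maternal_tally))
    cat(sprintf("    %s: %d\n", s, x$maternal_tally[[s]]))
  if (x$n_unassigned_maternal > 0)
    cat("  maternally unassigned:", x$n_unassigned_maternal, "\n")
  invisible(x)
}
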