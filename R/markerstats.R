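# Per-locus informativeness statistics. Gaps ("-") and "N" are missing data
# throughout: excluded per column for site counts and pairwise for diversity.

BASES <- c("A", "C", "G", "T")

site_states <- function(col) col[col %in% BASES]

#' Count variable sites
#'
#' A column is variable when it shows at least two distinct non-missing
#' states across the rows.
#'
#' @param aln a `multiple_alignment`.
#' @return integer count of variable columns.
#' @export
variable_site_count <- function(aln) {
  check_alignment(aln)
  sum(apply(unclass(aln), 2L, function(col) {
    length(unique(site_states(col))) >= 2L
  }))
}

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative when at least two states are each
#' carried by at least two rows (missing states excluded).
#'
#' @param aln a `multiple_alignment`.
#' @return integer count of informative columns.
#' @export
parsimony_informative_count <- function(aln) {
  check_alignment(aln)
  sum(apply(unclass(aln), 2L, function(col) {
    tab <- table(site_states(col))
    sum(tab >= 2L) >= 2L
  }))
}

#' Nucleotide diversity per site (pi)
#'
#' Average over all unordered row pairs of (pairwise differences / pairwise
#' compared sites); sites missing in either member of a pair are excluded
#' for that pair, and pairs with no comparable site are dropped.
#'
#' @param aln a `multiple_alignment`.
#' @return numeric, average pairwise difference per site.
#' @export
nucleotide_diversity <- function(aln) {
  check_alignment(aln)
  m <- unclass(aln)
  ok <- matrix(m %in% BASES, nrow = nrow(m))
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    if (!any(comp)) next
    vals <- c(vals, sum(m[i, comp] != m[j, comp]) / sum(comp))
  }
  if (length(vals) == 0L)
    stop("no pair of rows shares a comparable site; pi undefined")
  mean(vals)
}

#' Chi-squared test of base-composition heterogeneity among rows
#'
#' Builds the taxa x base count table (missing states excluded), drops rows
#' with no countable base (with a warning) and bases absent from every row,
#' and computes the classical Pearson chi-squared statistic with
#' df = (rows - 1) x (bases - 1) after dropping.
#'
#' @param aln a `multiple_alignment`.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
base_composition_chi2 <- function(aln) {
  check_alignment(aln)
  m <- unclass(aln)
  counts <- t(apply(m, 1L, function(r) {
    tabulate(match(r, BASES), nbins = 4L)
  }))
  colnames(counts) <- BASES
  empty <- rowSums(counts) == 0L
  if (any(empty)) {
    warning("rows with zero countable bases excluded: ",
            paste(rownames(m)[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  if (nrow(counts) < 2L) stop("fewer than 2 rows with countable bases")
  counts <- counts[, colSums(counts) > 0L, drop = FALSE]
  r <- nrow(counts); cc <- ncol(counts)
  df <- (r - 1L) * (cc - 1L)
  if (df == 0L)
    return(list(statistic = 0, df = 0L, p.value = 1))
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' MaxChi-style recombination scan
#'
#' For every unordered sequence pair, slides a breakpoint along the
#' alignment and contrasts mismatch counts in the half-windows left and
#' right of the breakpoint with a 2x2 chi-squared statistic. Candidate
#' breakpoints are the observed mismatch positions of the pair; p-values
#' are Bonferroni-corrected over all pairs x candidate breakpoints within
#' the locus, and candidates significant at `alpha` are returned sorted by
#' corrected p.
#'
#' @param aln a `multiple_alignment` with >= 3 rows.
#' @param window total window width in bp (half on each side of the
#'   breakpoint); must be >= 4 and smaller than the aligned length.
#' @param alpha significance level applied after correction.
#' @return data.frame with columns `seq1`, `seq2`, `breakpoint`,
#'   `chi2`, `p`, `p_adj` (possibly zero rows).
#' @export
maxchi_scan <- function(aln, window = 200, alpha = 0.05) {
  check_alignment(aln)
  if (nrow(aln) < 3L) stop("maxchi_scan needs at least 3 rows")
  L <- ncol(aln)
  if (window < 4 || window >= L)
    stop("window must be >= 4 and < aligned length (", L, ")")
  half <- floor(window / 2)
  m <- unclass(aln)
  ok <- matrix(m %in% BASES, nrow = nrow(m))
  labs <- rownames(m)
  n <- nrow(m)
  hits <- list()
  n_tests <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    mis <- comp & (m[i, ] != m[j, ])
    bp_cand <- which(mis)
    bp_cand <- bp_cand[bp_cand > half & bp_cand <= L - half]
    n_tests <- n_tests + length(bp_cand)
    if (length(bp_cand) == 0L) next
    cmis <- cumsum(mis)
    ccomp <- cumsum(comp)
    best <- c(chi2 = -1, bp = NA_real_)
    for (k in bp_cand) {
      a <- cmis[k] - cmis[k - half]            # left mismatches
      n1 <- ccomp[k] - ccomp[k - half]         # left comparable
      b <- cmis[k + half] - cmis[k]            # right mismatches
      n2 <- ccomp[k + half] - ccomp[k]         # right comparable
      if (n1 == 0L || n2 == 0L) next
      tot <- n1 + n2; mm <- a + b; mt <- tot - mm
      if (mm == 0L || mt == 0L) next
      num <- (a * (n2 - b) - b * (n1 - a))^2 * tot
      stat <- num / (as.numeric(n1) * n2 * mm * mt)
      if (stat > best["chi2"]) best <- c(chi2 = stat, bp = k)
    }
    if (best["chi2"] < 0) next
    p <- stats::pchisq(best["chi2"], df = 1L, lower.tail = FALSE)
    hits[[length(hits) + 1L]] <- data.frame(
      seq1 = labs[i], seq2 = labs[j], breakpoint = best[["bp"]],
      chi2 = best[["chi2"]], p = p)
  }
  if (length(hits) == 0L)
    return(data.frame(seq1 = character(), seq2 = character(),
                      breakpoint = numeric(), chi2 = numeric(),
                      p = numeric(), p_adj = numeric()))
  res <- do.call(rbind, hits)
  res$p_adj <- pmin(1, res$p * n_tests)
  res <- res[res$p_adj < alpha, , drop = FALSE]
  res[order(res$p_adj, res$p), , drop = FALSE]
}

#' Compute the marker statistics row for one locus
#'
#' @param aln a `multiple_alignment`.
#' @param run_maxchi also run [maxchi_scan()] and set `recombination_flag`.
#' @param window,alpha passed to [maxchi_scan()] when `run_maxchi = TRUE`.
#' @return one-row data.frame with the per-locus statistics (percentages to
#'   full precision; format with [format_marker_stats()] for reporting).
#' @export
marker_stats <- function(aln, run_maxchi = FALSE, window = 200, alpha = 0.05) {
  check_alignment(aln)
  L <- ncol(aln)
  vs <- variable_site_count(aln)
  pis <- parsimony_informative_count(aln)
  chi <- base_composition_chi2(aln)
  flag <- NA
  if (run_maxchi && nrow(aln) >= 3L && window < L)
    flag <- nrow(maxchi_scan(aln, window = window, alpha = alpha)) > 0L
  data.frame(
    locus = attr(aln, "locus"),
    genome = attr(aln, "genome"),
    aligned_length = L,
    variable_pct = 100 * vs / L,
    pi_informative_pct = 100 * pis / L,
    pi_diversity = nucleotide_diversity(aln),
    chi2_stat = chi$statistic,
    chi2_df = chi$df,
    chi2_p = chi$p.value,
    recombination_flag = flag,
    stringsAsFactors = FALSE)
}

#' Format a marker statistics table for reporting
#'
#' Percentages are rounded to one decimal place, mirroring the usual
#' presentation of per-locus summary tables.
#'
#' @param stats data.frame as returned by [marker_stats()] (rows bound).
#' @return the data.frame with rounded percentage columns.
#' @export
format_marker_stats <- function(stats) {
  stats$variable_pct <- round(stats$variable_pct, 1)
  stats$pi_informative_pct <- round(stats$pi_informative_pct, 1)
  stats
}

#' Rank loci by informativeness and select the top k
#'
#' Loci are sorted by parsimony-informative percentage, with ties broken by
#' variable percentage, then aligned length (longer first), then locus id.
#'
#' @param stats data.frame of per-locus statistics ([marker_stats()] rows).
#' @param k number of loci to select.
#' @param genome restrict to loci with this genome tag (`NULL` = all).
#' @return character vector of selected locus ids, best first.
#' @export
rank_and_select_markers <- function(stats, k, genome = NULL) {
  if (k <= 0) stop("k must be positive")
  if (!is.null(genome)) stats <- stats[stats$genome == genome, , drop = FALSE]
  if (k > nrow(stats))
    stop("k (", k, ") exceeds the number of loci with this tag (",
         nrow(stats), ")")
  ord <- order(-stats$pi_informative_pct, -stats$variable_pct,
               -stats$aligned_length, stats$locus)
  stats$locus[ord][seq_len(k)]
}
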