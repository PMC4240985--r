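# Desk-scale tree inference: distances, neighbour joining, Fitch parsimony
# (exact for small n, NNI hill-climbing beyond), bootstrap support, and
# bipartition-based discordance measures.

#' Pairwise distance matrix from an alignment
#'
#' p-distances use pairwise deletion (sites missing in either row are
#' skipped for that pair). The JC69 transform is
#' d = -(3/4) log(1 - 4p/3); pairs with p >= 0.75 are saturated, capped at
#' `cap` and flagged in the `saturated` attribute.
#'
#' @param aln a `multiple_alignment`.
#' @param model `"p"` (default) or `"JC69"`.
#' @param cap distance assigned to saturated pairs under JC69.
#' @return symmetric numeric matrix with taxon dimnames; attribute
#'   `saturated` lists capped pairs (JC69 only).
#' @export
pairwise_distance <- function(aln, model = c("p", "JC69"), cap = 5) {
  model <- match.arg(model)
  check_alignment(aln)
  D <- pdist_from_int(encode_bases(aln))
  sat <- NULL
  if (model == "JC69") {
    idx <- which(D >= 0.75 & upper.tri(D), arr.ind = TRUE)
    if (nrow(idx) > 0)
      sat <- data.frame(taxon1 = rownames(D)[idx[, 1]],
                        taxon2 = rownames(D)[idx[, 2]])
    Dj <- D
    low <- D < 0.75
    Dj[low] <- -0.75 * log(1 - 4 * D[low] / 3)
    Dj[!low] <- cap
    diag(Dj) <- 0
    D <- Dj
  }
  attr(D, "saturated") <- sat
  D
}

#' Neighbour-joining tree
#'
#' Wraps the standard NJ algorithm; negative intermediate branch lengths
#' are clamped to zero with the deficit transferred to a sibling edge, and
#' a warning is issued.
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @return unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix is not symmetric")
  if (nrow(D) < 3L) stop("neighbour joining needs at least 3 taxa")
  tr <- ape::nj(D)
  neg <- which(tr$edge.length < 0)
  if (length(neg) > 0) {
    for (e in neg) {
      parent <- tr$edge[e, 1L]
      sib <- setdiff(which(tr$edge[, 1L] == parent), e)
      if (length(sib) > 0)
        tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + tr$edge.length[e]
      tr$edge.length[e] <- 0
    }
    warning(length(neg), " negative branch length(s) clamped to zero")
  }
  tr
}

state_code <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 15L, `-` = 15L)

# integer-coded alignment (A..T -> 1..4, missing -> NA); fast path for
# repeated distance computations (bootstrap)
encode_bases <- function(aln) {
  m <- unclass(aln)
  matrix(match(m, BASES), nrow = nrow(m), dimnames = dimnames(m))
}

pdist_from_int <- function(mi) {
  n <- nrow(mi)
  D <- matrix(0, n, n, dimnames = list(rownames(mi), rownames(mi)))
  for (i in seq_len(n - 1L)) {
    xi <- mi[i, ]
    for (j in (i + 1L):n) {
      xj <- mi[j, ]
      comp <- !is.na(xi) & !is.na(xj)
      nc <- sum(comp)
      if (nc == 0L)
        stop("no comparable sites between ", rownames(mi)[i], " and ",
             rownames(mi)[j])
      D[i, j] <- D[j, i] <- sum(xi[comp] != xj[comp]) / nc
    }
  }
  D
}

#' Fitch small-parsimony score of a tree on an alignment
#'
#' Missing states (`N`, `-`) are treated as fully ambiguous {A,C,G,T} and
#' contribute no change.
#'
#' @param tree a `phylo` tree whose tips match the alignment taxa.
#' @param aln a `multiple_alignment`.
#' @return integer parsimony score (sum over columns).
#' @export
fitch_score <- function(tree, aln) {
  check_alignment(aln)
  miss1 <- setdiff(tree$tip.label, rownames(aln))
  miss2 <- setdiff(rownames(aln), tree$tip.label)
  if (length(miss1) + length(miss2) > 0)
    stop("tree/alignment label mismatch; tree-only: [",
         paste(miss1, collapse = ", "), "], alignment-only: [",
         paste(miss2, collapse = ", "), "]")
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  S <- ncol(aln)
  states <- matrix(0L, ntip + tr$Nnode, S)
  states[seq_len(ntip), ] <- matrix(
    state_code[unclass(aln)[tr$tip.label, , drop = FALSE]], nrow = ntip)
  score <- integer(S)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    cm <- states[ch, ]
    pm <- states[par, ]
    if (pm[1L] == 0L && all(pm == 0L)) {
      states[par, ] <- cm
    } else {
      inter <- bitwAnd(pm, cm)
      zero <- inter == 0L
      score <- score + zero
      inter[zero] <- bitwOr(pm, cm)[zero]
      states[par, ] <- inter
    }
  }
  sum(score)
}

#' Parsimony tree search
#'
#' For up to `exhaustive_max` taxa every unrooted topology is scored (exact
#' search); beyond that, NNI hill-climbing is run from the NJ tree plus
#' random restarts. All co-optimal trees found are returned.
#'
#' @param aln a `multiple_alignment` with >= 4 rows.
#' @param exhaustive_max largest taxon count for exact enumeration (hard
#'   cap 9; the number of topologies grows as (2n-5)!!).
#' @param restarts random restarts for the heuristic search.
#' @param seed seed for the heuristic restarts.
#' @return list with `trees` (a `multiPhylo` of co-optimal trees), `score`,
#'   and `exact` (logical).
#' @export
parsimony_search <- function(aln, exhaustive_max = 9, restarts = 2, seed = 1) {
  check_alignment(aln)
  if (exhaustive_max > 9)
    stop("exhaustive enumeration above 9 taxa is refused: there are ",
         "(2n-5)!! topologies; use the heuristic (exhaustive_max <= 9)")
  n <- nrow(aln)
  if (n < 4L) stop("parsimony search needs at least 4 taxa")
  if (n <= exhaustive_max) {
    all_tr <- phangorn::allTrees(n, rooted = FALSE, tip.label = rownames(aln))
    scores <- vapply(all_tr, fitch_score, integer(1), aln = aln)
    best <- min(scores)
    trees <- all_tr[scores == best]
    class(trees) <- "multiPhylo"
    return(list(trees = trees, score = best, exact = TRUE))
  }
  climb <- function(tree) {
    cur <- fitch_score(tree, aln)
    repeat {
      nbrs <- phangorn::nni(tree)
      sc <- vapply(nbrs, fitch_score, integer(1), aln = aln)
      if (min(sc) >= cur) return(list(tree = tree, score = cur))
      tree <- nbrs[[which.min(sc)]]
      cur <- min(sc)
    }
  }
  start <- ape::unroot(neighbor_joining(pairwise_distance(aln, "p")))
  results <- list(climb(start))
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      rt <- ape::rtree(n, tip.label = sample(rownames(aln)))
      results[[length(results) + 1L]] <- climb(ape::unroot(rt))
    }
  })
  scores <- vapply(results, `[[`, numeric(1), "score")
  best <- min(scores)
  cand <- lapply(results[scores == best], `[[`, "tree")
  keep <- cand[1]
  if (length(cand) > 1) {
    for (tcand in cand[-1]) {
      if (all(vapply(keep, function(t0) robinson_foulds(t0, tcand) > 0,
                     logical(1))))
        keep[[length(keep) + 1L]] <- tcand
    }
  }
  class(keep) <- "multiPhylo"
  list(trees = keep, score = best, exact = FALSE)
}

# Canonical keys for the nontrivial bipartitions of an unrooted tree.
# Each split is represented by the side not containing the alphabetically
# first leaf, sorted and collapsed; names give the internal node below the
# defining edge.
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  if (tree$Nnode < 2L) return(character(0))
  pp <- ape::prop.part(tree)
  ref <- min(tree$tip.label)
  keys <- character(0)
  for (i in 2:length(pp)) {
    clade <- tree$tip.label[pp[[i]]]
    if (length(clade) < 2L || length(clade) > n - 2L) next
    side <- if (ref %in% clade) setdiff(tree$tip.label, clade) else clade
    k <- paste(sort(side), collapse = "\001")
    keys[length(keys) + 1L] <- k
    names(keys)[length(keys)] <- as.character(n + i)
  }
  keys
}

split_key <- function(leafset, all_leaves) {
  ref <- min(all_leaves)
  side <- if (ref %in% leafset) setdiff(all_leaves, leafset) else leafset
  paste(sort(side), collapse = "\001")
}

#' Test monophyly of a leaf set on an (unrooted) tree
#'
#' True iff some edge separates exactly `leafset` from the remaining
#' leaves. Singletons, complements of singletons and the full leaf set are
#' trivially monophyletic.
#'
#' @param tree a `phylo` tree.
#' @param leafset character vector of tip labels.
#' @return logical flag.
#' @export
is_monophyletic <- function(tree, leafset) {
  unknown <- setdiff(leafset, tree$tip.label)
  if (length(unknown) > 0)
    stop("unknown labels: ", paste(unknown, collapse = ", "))
  k <- length(unique(leafset))
  n <- length(tree$tip.label)
  if (k <= 1L || k >= n - 1L) return(TRUE)
  split_key(unique(leafset), tree$tip.label) %in% tree_bipartitions(tree)
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the nontrivial bipartition sets of
#' the two unrooted trees.
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @return integer RF distance.
#' @export
robinson_foulds <- function(t1, t2) {
  d1 <- setdiff(t1$tip.label, t2$tip.label)
  d2 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(d1) + length(d2) > 0)
    stop("leaf sets differ; only in t1: [", paste(d1, collapse = ", "),
         "], only in t2: [", paste(d2, collapse = ", "), "]")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Bootstrap support for a tree built from an alignment
#'
#' Columns are resampled with replacement `reps` times; each focal
#' bipartition of the reference tree gets the percentage of successful
#' replicate trees that contain it. Replicates whose builder fails are
#' skipped, counted, and reported in a warning.
#'
#' @param aln a `multiple_alignment`.
#' @param builder `"nj"` (p-distance neighbour joining) or `"mp"`
#'   (parsimony hill-climb, first co-optimal tree).
#' @param reps number of bootstrap replicates.
#' @param seed seed controlling the resampling.
#' @return the reference `phylo` tree with `node.label` holding percentage
#'   supports (empty for the basal node).
#' @export
bootstrap_support <- function(aln, builder = c("nj", "mp"), reps = 100,
                              seed = 1) {
  builder <- match.arg(builder)
  check_alignment(aln)
  if (reps < 1) stop("reps must be >= 1")
  mi <- encode_bases(aln)
  build_cols <- function(cols) {
    if (builder == "nj") {
      ape::unroot(neighbor_joining(pdist_from_int(mi[, cols, drop = FALSE])))
    } else {
      a <- multiple_alignment(unclass(aln)[, cols, drop = FALSE],
                              locus = attr(aln, "locus"),
                              genome = attr(aln, "genome"))
      parsimony_search(a, exhaustive_max = min(9, nrow(a)),
                       restarts = 0)$trees[[1]]
    }
  }
  ref <- build_cols(seq_len(ncol(aln)))
  ref_splits <- tree_bipartitions(ref)
  counts <- integer(length(ref_splits))
  failed <- 0L
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      cols <- sample.int(ncol(aln), replace = TRUE)
      rep_tree <- tryCatch(build_cols(cols), error = function(e) NULL)
      if (is.null(rep_tree)) { failed <- failed + 1L; next }
      counts <- counts + (ref_splits %in% tree_bipartitions(rep_tree))
    }
  })
  if (failed > 0L)
    warning(failed, " bootstrap replicate(s) failed and were skipped")
  good <- reps - failed
  support <- round(100 * counts / max(good, 1L))
  labs <- rep("", ref$Nnode)
  node_ids <- as.integer(names(ref_splits))
  labs[node_ids - length(ref$tip.label)] <- as.character(support)
  ref$node.label <- labs
  attr(ref, "support") <- stats::setNames(support, ref_splits)
  attr(ref, "failed_replicates") <- failed
  ref
}

#' Bootstrap support of a specific clade
#'
#' Convenience accessor: the percentage support recorded for the edge
#' separating `leafset` from the rest, or `NA` if the reference tree does
#' not contain that bipartition.
#'
#' @param tree result of [bootstrap_support()].
#' @param leafset character vector of tip labels.
#' @return numeric support percentage or `NA`.
#' @export
clade_support <- function(tree, leafset) {
  sup <- attr(tree, "support")
  if (is.null(sup)) stop("tree carries no bootstrap support attribute")
  key <- split_key(leafset, tree$tip.label)
  if (!key %in% names(sup)) return(NA_real_)
  unname(sup[key])
}
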