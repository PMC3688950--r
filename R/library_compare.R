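.check_libraries <- function(table, libraries) {
  stopifnot(inherits(table, "otu_table"))
  if (is.null(libraries)) libraries <- colnames(table$counts)
  unknown <- setdiff(libraries, colnames(table$counts))
  if (length(unknown) > 0L)
    stop("unknown library label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  libraries
}

# Chao-type estimate of richness shared between two libraries: the observed
# shared count plus a joint-rarity correction term in direct analogy to the
# bias-corrected Chao1 (f11 = shared OTUs that are singletons in both
# libraries, f22 = doubletons in both).
.chao_shared <- function(counts_a, counts_b) {
  shared <- counts_a > 0 & counts_b > 0
  d12 <- sum(shared)
  f11 <- sum(shared & counts_a == 1 & counts_b == 1)
  f22 <- sum(shared & counts_a == 2 & counts_b == 2)
  d12 + f11 * (f11 - 1) / (2 * (f22 + 1))
}

#' Venn partition of OTU richness across 2-3 libraries
#'
#' Region-wise richness of OTU incidence. In "observed" mode (default, the
#' tested surface) each region counts the OTUs present in exactly that label
#' subset. In "chao_shared" mode the per-library totals are replaced by
#' Chao1 point estimates and the pairwise shared richness by a Chao-type
#' shared estimator (joint-rarity corrected; see Details); regions are then
#' reconciled by inclusion-exclusion, flooring every region at its observed
#' count. The triple-overlap region always stays observed.
#'
#' @param table An [build_otu_table()] result.
#' @param libraries 2 or 3 library labels (default: all, must be 2-3).
#' @param mode "observed" or "chao_shared".
#' @return An object of class `venn_partition`: list with `labels`, `mode`
#'   and `regions` (named numeric vector; region names are label subsets
#'   joined by "&").
#' @export
venn_partition <- function(table, libraries = NULL,
                           mode = c("observed", "chao_shared")) {
  mode <- match.arg(mode)
  libraries <- .check_libraries(table, libraries)
  k <- length(libraries)
  if (k < 2L || k > 3L)
    stop("venn_partition supports 2 or 3 libraries", call. = FALSE)
  inc <- otu_incidence(table)[, libraries, drop = FALSE]

  subset_names <- function(members) paste(members, collapse = "&")
  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(libraries, m, simplify = FALSE)), recursive = FALSE)

  observed <- vapply(subsets, function(s) {
    in_s <- rowSums(inc[, s, drop = FALSE]) == length(s)
    out_s <- rowSums(inc[, setdiff(libraries, s), drop = FALSE]) == 0L
    sum(in_s & out_s)
  }, numeric(1))
  names(observed) <- vapply(subsets, subset_names, character(1))

  if (mode == "observed") {
    regions <- observed
  } else {
    counts <- table$counts[, libraries, drop = FALSE]
    totals <- vapply(libraries, function(l) {
      v <- counts[, l]
      chao1(v[v > 0])$value
    }, numeric(1))
    pair_idx <- utils::combn(libraries, 2L, simplify = FALSE)
    shared <- vapply(pair_idx, function(p) {
      max(.chao_shared(counts[, p[1L]], counts[, p[2L]]),
          sum(inc[, p[1L]] & inc[, p[2L]]))
    }, numeric(1))
    names(shared) <- vapply(pair_idx, subset_names, character(1))
    regions <- observed
    if (k == 2L) {
      ab <- names(shared)[1L]
      regions[ab] <- max(shared[[ab]] - 0, observed[[ab]])
      for (l in libraries)
        regions[[l]] <- max(totals[[l]] - regions[[ab]], observed[[l]])
    } else {
      triple <- observed[[subset_names(libraries)]]
      for (p in pair_idx) {
        nm <- subset_names(p)
        regions[[nm]] <- max(shared[[nm]] - triple, observed[[nm]])
      }
      for (l in libraries) {
        pair_sum <- sum(vapply(pair_idx, function(p)
          if (l %in% p) regions[[subset_names(p)]] else 0, numeric(1)))
        regions[[l]] <- max(totals[[l]] - pair_sum - triple, observed[[l]])
      }
    }
  }
  structure(list(labels = libraries, mode = mode, regions = regions,
                 observed = observed),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("Venn partition (%s) of libraries %s:\n", x$mode,
              paste(x$labels, collapse = ", ")))
  for (nm in names(x$regions))
    cat(sprintf("  %-12s %g\n", nm, x$regions[[nm]]))
  invisible(x)
}

#' Richness gain from combining libraries
#'
#' Quantifies how much OTU richness the non-richest libraries add on top of
#' the richest one: `gain = 100 * novel / hR`, where `hR` is the observed
#' richness of the richest library. Because the other libraries may share
#' novel phylotypes with each other, two conventions are reported: the union
#' convention counts each novel phylotype once (`|union(others) \ richest|`,
#' the headline value), while the literal-sum convention adds the per-library
#' novel counts (and so may double-count).
#'
#' @param table An [build_otu_table()] result.
#' @param libraries At least 2 library labels (default: all).
#' @return An object of class `gain_result`: list with `richest`, `hR`,
#'   `novel_union`, `novel_sum`, `novel_per_library`, `gain_pct_union`,
#'   `gain_pct_sum`, `tied_richest`.
#' @export
richness_gain <- function(table, libraries = NULL) {
  libraries <- .check_libraries(table, libraries)
  if (length(libraries) < 2L)
    stop("need at least 2 libraries", call. = FALSE)
  inc <- otu_incidence(table)[, libraries, drop = FALSE]
  richness <- colSums(inc)
  max_rich <- max(richness)
  tied <- sort(names(richness)[richness == max_rich])
  richest <- tied[1L]
  others <- setdiff(libraries, richest)
  novel_per_library <- vapply(others, function(l)
    sum(inc[, l] & !inc[, richest]), numeric(1))
  novel_union <- sum(rowSums(inc[, others, drop = FALSE]) > 0L &
                       !inc[, richest])
  novel_sum <- sum(novel_per_library)
  structure(list(richest = richest, hR = max_rich,
                 novel_union = novel_union, novel_sum = novel_sum,
                 novel_per_library = novel_per_library,
                 gain_pct_union = 100 * novel_union / max_rich,
                 gain_pct_sum = 100 * novel_sum / max_rich,
                 tied_richest = tied),
            class = "gain_result")
}

#' @export
print.gain_result <- function(x, ...) {
  cat(sprintf("Richest library: %s (hR = %d OTUs)\n", x$richest, x$hR))
  cat(sprintf("Richness gain: %.1f%% (union of %d novel phylotypes); %.1f%% (literal sum, %d)\n",
              x$gain_pct_union, x$novel_union, x$gain_pct_sum, x$novel_sum))
  if (length(x$tied_richest) > 1L)
    cat("Richest library tied among:", paste(x$tied_richest, collapse = ", "), "\n")
  invisible(x)
}

#' Jaccard dissimilarity between libraries
#'
#' `d(A, B) = 1 - |A intersect B| / |A union B|` on OTU incidence. A library
#' with zero OTUs is at distance 1 from every other library (with a
#' warning).
#'
#' @param table An [build_otu_table()] result.
#' @return Symmetric numeric matrix over library labels.
#' @export
jaccard_dissimilarity <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  inc <- otu_incidence(table)
  libs <- colnames(inc)
  if (length(libs) < 2L) stop("need at least 2 libraries", call. = FALSE)
  if (any(colSums(inc) == 0L))
    warning("library with zero OTUs: distance 1 to all others")
  d <- matrix(0, length(libs), length(libs), dimnames = list(libs, libs))
  for (i in seq_along(libs)) for (j in seq_along(libs)) {
    if (i >= j) next
    un <- sum(inc[, i] | inc[, j])
    d[i, j] <- d[j, i] <- if (un == 0L) 1 else 1 - sum(inc[, i] & inc[, j]) / un
  }
  d
}

.check_distance_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric", call. = FALSE)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("item", seq_len(nrow(d)))
  d
}

#' UPGMA dendrogram
#'
#' Agglomerative clustering with arithmetic-mean linkage; the merge height
#' of each cluster equals the average inter-cluster distance at merging, so
#' `stats::cophenetic()` on the result returns UPGMA linkage distances.
#'
#' @param d Symmetric distance matrix (or `dist`) over at least 2 items.
#' @return An `hclust` object (subclass `upgma`); convert with
#'   `ape::as.phylo()` for Newick export.
#' @export
upgma <- function(d) {
  d <- .check_distance_matrix(d)
  if (nrow(d) < 2L) stop("need at least 2 items", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  class(hc) <- c("upgma", "hclust")
  hc
}

# Clamp negative NJ branch lengths to zero, transferring each deficit to the
# first sister edge (same parent) so root-to-tip path lengths are preserved
# where possible.
.clamp_negative_branches <- function(tree) {
  for (iter in seq_len(10L * nrow(tree$edge))) {
    neg <- which(tree$edge.length < -1e-12)
    if (length(neg) == 0L) break
    e <- neg[1L]
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    sisters <- setdiff(which(tree$edge[, 1L] == tree$edge[e, 1L]), e)
    if (length(sisters) > 0L)
      tree$edge.length[sisters[1L]] <- tree$edge.length[sisters[1L]] + deficit
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix (unrooted output).
#' Negative branch lengths, which NJ can produce on non-additive input, are
#' clamped to zero with the deficit transferred to the sister edge.
#'
#' @param d Symmetric distance matrix (or `dist`) over at least 3 items.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- .check_distance_matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 items", call. = FALSE)
  .clamp_negative_branches(ape::nj(stats::as.dist(d)))
}

# Edge-by-tip incidence: inc[e, t] is TRUE when tip t descends from edge e.
.edge_tip_incidence <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  below <- matrix(FALSE, n_node, n_tip)
  below[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    c_ <- tree$edge[e, 2L]
    below[p, ] <- below[p, ] | below[c_, ]
  }
  list(tree = tree, inc = below[tree$edge[, 2L], , drop = FALSE])
}

.unifrac_distance <- function(inc, edge_length, tips_a, tips_b) {
  leads_a <- inc %*% tips_a > 0
  leads_b <- inc %*% tips_b > 0
  either <- leads_a | leads_b
  unique_ <- xor(leads_a, leads_b)
  tot <- sum(edge_length[either])
  if (tot == 0) return(0)
  sum(edge_length[unique_]) / tot
}

#' Unweighted UniFrac distance with permutation significance
#'
#' For each pair of communities, the unweighted UniFrac distance is the
#' branch length leading exclusively to leaves of one community divided by
#' the branch length leading to leaves of either community. Significance is
#' assessed by permuting the community labels among the leaves of the pair
#' (pairwise-restricted shuffling); the p-value uses the add-one convention
#' `p = (# permuted >= observed + 1) / (permutations + 1)` so it never
#' reaches 0. The Bonferroni column multiplies p by the number of pairs
#' tested in the call (capped at 1).
#'
#' @param tree An `ape::phylo` with branch lengths; every leaf must appear
#'   in `communities`.
#' @param communities Named character vector mapping leaf labels to
#'   community labels.
#' @param pair Optional length-2 character vector restricting the test to
#'   one community pair; default: all pairs.
#' @param permutations Number of label permutations (default 100).
#' @param seed Optional integer seed for the permutations.
#' @return A data frame of class `unifrac_result` with columns `community_a`,
#'   `community_b`, `distance`, `p_value`, `p_bonferroni`, `permutations`.
#' @export
unifrac_unweighted <- function(tree, communities, pair = NULL,
                               permutations = 100L, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths", call. = FALSE)
  missing_tips <- setdiff(tree$tip.label, names(communities))
  if (length(missing_tips) > 0L)
    stop("unlabeled leaf(s): ", paste(utils::head(missing_tips, 5L),
                                      collapse = ", "), call. = FALSE)
  labels <- communities[tree$tip.label]
  all_pairs <- if (is.null(pair)) {
    utils::combn(sort(unique(labels)), 2L, simplify = FALSE)
  } else {
    stopifnot(length(pair) == 2L)
    list(sort(pair))
  }
  et <- .edge_tip_incidence(tree)
  labels <- communities[et$tree$tip.label]
  inc <- et$inc
  len <- et$tree$edge.length

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
  }
  n_pairs <- length(all_pairs)
  rows <- lapply(all_pairs, function(p) {
    in_a <- labels == p[1L]
    in_b <- labels == p[2L]
    if (sum(in_a) == 0L || sum(in_b) == 0L)
      stop("community with zero leaves: ",
           p[c(sum(in_a) == 0L, sum(in_b) == 0L)][1L], call. = FALSE)
    obs <- .unifrac_distance(inc, len, as.numeric(in_a), as.numeric(in_b))
    members <- which(in_a | in_b)
    n_a <- sum(in_a)
    ge <- 0L
    for (r in seq_len(permutations)) {
      perm_a <- numeric(length(labels))
      perm_b <- numeric(length(labels))
      shuffled <- sample(members)
      perm_a[shuffled[seq_len(n_a)]] <- 1
      perm_b[shuffled[-seq_len(n_a)]] <- 1
      if (.unifrac_distance(inc, len, perm_a, perm_b) >= obs - 1e-12)
        ge <- ge + 1L
    }
    p_val <- (ge + 1L) / (permutations + 1L)
    data.frame(community_a = p[1L], community_b = p[2L], distance = obs,
               p_value = p_val, p_bonferroni = min(1, p_val * n_pairs),
               permutations = permutations, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("unifrac_result", "data.frame")
  out
}
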