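# Independent brute-force oracles. Each re-derives its quantity from first
# principles, sharing no code with the package implementation.

# IUPAC sets written out again, literally, for the oracle's own use.
oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  I = c("A", "C", "G", "T"))

oracle_base_match <- function(p, t) {
  if (t == "N") return(TRUE)
  t %in% oracle_iupac[[p]]
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N", I = "I")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# window-by-window scan over both strands; returns the same column layout as
# find_primer_sites for direct comparison
oracle_primer_sites <- function(primer, template, max_mismatch,
                                anchor_3prime) {
  scan_one <- function(pr, strand) {
    pc <- strsplit(pr, "")[[1]]
    tc <- strsplit(template, "")[[1]]
    L <- length(pc)
    rows <- list()
    if (L > length(tc)) return(rows)
    anchor <- if (strand == "+") seq(L - min(anchor_3prime, L) + 1, L)
              else seq_len(min(anchor_3prime, L))
    if (anchor_3prime == 0) anchor <- integer(0)
    for (s in 0:(length(tc) - L)) {
      ok <- vapply(seq_len(L),
                   function(j) oracle_base_match(pc[j], tc[s + j]),
                   logical(1))
      if (sum(!ok) <= max_mismatch && all(ok[anchor]))
        rows[[length(rows) + 1]] <- data.frame(
          strand = strand, start = s, end = s + L, mismatches = sum(!ok))
    }
    rows
  }
  rows <- c(scan_one(primer, "+"), scan_one(oracle_revcomp(primer), "-"))
  if (length(rows) == 0)
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand != "+"), , drop = FALSE]
}

# column-walking pairwise distance under pairwise deletion
oracle_pair_distance <- function(seq_i, seq_j) {
  a <- strsplit(seq_i, "")[[1]]
  b <- strsplit(seq_j, "")[[1]]
  comp <- 0; mism <- 0
  for (k in seq_along(a)) {
    if (a[k] %in% c("A", "C", "G", "T") && b[k] %in% c("A", "C", "G", "T")) {
      comp <- comp + 1
      if (a[k] != b[k]) mism <- mism + 1
    }
  }
  if (comp == 0) 1 else mism / comp
}

# naive O(n^3) agglomerative clustering: repeatedly merge the closest pair
# of clusters while the linkage distance is at or below the cutoff
oracle_agglomerative <- function(d, cutoff, linkage) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  link <- function(ci, cj) {
    vals <- d[ci, cj, drop = FALSE]
    switch(linkage, single = min(vals), complete = max(vals),
           average = mean(vals))
  }
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dij <- link(clusters[[i]], clusters[[j]])
      if (dij < best_d) { best_d <- dij; best <- c(i, j) }
    }
    if (best_d > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  assignment <- integer(n)
  for (k in seq_along(clusters)) assignment[clusters[[k]]] <- k
  assignment
}

# naive UPGMA returning the cophenetic matrix (merge height of the first
# cluster joining each pair)
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d) { best_d <- dij; best <- c(i, j) }
    }
    for (a in clusters[[best[1]]]) for (b in clusters[[best[2]]])
      coph[a, b] <- coph[b, a] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  dimnames(coph) <- dimnames(d)
  coph
}

# recursive edge-walking unweighted UniFrac
oracle_unifrac <- function(tree, labels, a, b) {
  tips_below <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  uniq <- 0; tot <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tips_below(tree$edge[e, 2])
    has_a <- any(labels[tips] == a)
    has_b <- any(labels[tips] == b)
    if (has_a || has_b) tot <- tot + tree$edge.length[e]
    if (xor(has_a, has_b)) uniq <- uniq + tree$edge.length[e]
  }
  if (tot == 0) 0 else uniq / tot
}

# random gapped alignment rows for distance/clustering property tests
random_gapped_alignment <- function(n, len, gap_p = 0.1, n_p = 0.05) {
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T", "-", "N"), len, replace = TRUE,
                 prob = c(rep((1 - gap_p - n_p) / 4, 4), gap_p, n_p)),
          collapse = "")
  }, character(1))
  multiple_alignment(sprintf("seq%02d", seq_len(n)), seqs,
                     rep("lib1", n))
}

# small otu_table built directly from an incidence/count matrix
make_otu_table <- function(counts) {
  counts <- as.matrix(counts)
  rownames(counts) <- paste0("OTU_", seq_len(nrow(counts)))
  structure(list(counts = matrix(as.integer(counts), nrow = nrow(counts),
                                 dimnames = dimnames(counts)),
                 representatives = stats::setNames(rownames(counts),
                                                   rownames(counts)),
                 cutoff = 0.03, linkage = "average"),
            class = "otu_table")
}
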