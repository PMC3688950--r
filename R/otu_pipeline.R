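#' Construct a multiple alignment of clone sequences
#'
#' Aligned (gapped) clone-library sequences with a library label per record.
#' Alignment construction itself is upstream of this package; the object just
#' validates columnar structure.
#'
#' @param ids Character vector of unique sequence ids.
#' @param seqs Character vector of gapped sequences over A/C/G/T/N/-; all the
#'   same length.
#' @param libraries Character vector of library labels, one per sequence.
#' @return An object of class `multiple_alignment`.
#' @export
multiple_alignment <- function(ids, seqs, libraries) {
  stopifnot(length(ids) == length(seqs), length(ids) == length(libraries))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L)
    stop("alignment rows have unequal lengths", call. = FALSE)
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("invalid alignment character(s) in: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  structure(list(ids = as.character(ids), seqs = unname(seqs),
                 libraries = as.character(libraries),
                 length = widths[1L]),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("Multiple alignment: %d sequences x %d columns, %d libraries\n",
              length(x$ids), x$length, length(unique(x$libraries))))
  invisible(x)
}

#' Pairwise distances under pairwise deletion
#'
#' For each sequence pair, compared columns are those holding an unambiguous
#' base (A/C/G/T) in both rows; gap and N columns are dropped pair by pair.
#' The distance is mismatches / compared columns. A pair with zero comparable
#' columns gets distance 1 with a warning.
#'
#' @param aln A [multiple_alignment()] with at least 2 records.
#' @return A symmetric numeric matrix in [0, 1] with sequence ids as
#'   dimnames.
#' @export
pairwise_distances <- function(aln) {
  stopifnot(inherits(aln, "multiple_alignment"))
  n <- length(aln$ids)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  chars <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  valid <- chars == "A" | chars == "C" | chars == "G" | chars == "T"
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  warned <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- valid[i, ] & valid[j, ]
    nc <- sum(comp)
    if (nc == 0L) {
      d[i, j] <- d[j, i] <- 1
      warned <- TRUE
    } else {
      d[i, j] <- d[j, i] <- sum(chars[i, comp] != chars[j, comp]) / nc
    }
  }
  if (warned)
    warning("sequence pair(s) with no comparable columns assigned distance 1")
  d
}

#' Cluster sequences into OTUs at a distance cutoff
#'
#' Agglomerative clustering of a pairwise distance matrix; merging proceeds
#' while the minimal inter-cluster linkage distance is at or below the
#' cutoff, so sequences within `cutoff` of each other may co-cluster. The
#' conventional "97% similarity" OTU definition corresponds to
#' `cutoff = 0.03`. Default linkage is average neighbor (UPGMA-style);
#' complete and single linkage are selectable.
#'
#' @param d Symmetric distance matrix with ids as dimnames (or a `dist`).
#' @param cutoff Distance cutoff in [0, 1] (default 0.03).
#' @param linkage "average" (default), "complete" or "single".
#' @return An object of class `otu_assignment`: list with `otu` (named
#'   integer vector, dense ids in order of first appearance), `cutoff`,
#'   `linkage`.
#' @export
cluster_otus <- function(d, cutoff = 0.03, linkage = c("average", "complete",
                                                       "single")) {
  linkage <- match.arg(linkage)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (length(d) == 0L) stop("empty distance matrix", call. = FALSE)
  if (!(cutoff >= 0 && cutoff <= 1)) stop("cutoff must lie in [0, 1]",
                                          call. = FALSE)
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix needs row names", call. = FALSE)
  if (nrow(d) == 1L) {
    otu <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = linkage)
    otu <- stats::cutree(hc, h = cutoff)
    # renumber densely in order of first appearance
    otu <- stats::setNames(match(otu, unique(otu)), ids)
  }
  structure(list(otu = otu, cutoff = cutoff, linkage = linkage),
            class = "otu_assignment")
}

#' @export
print.otu_assignment <- function(x, ...) {
  cat(sprintf("OTU assignment: %d sequences -> %d OTUs (cutoff %.3g, %s linkage)\n",
              length(x$otu), max(x$otu), x$cutoff, x$linkage))
  invisible(x)
}

#' Build an OTU-by-library abundance table
#'
#' Tabulates OTU membership per library. Each OTU's representative id is its
#' lexicographically first member (members of a clone-library OTU are
#' equally weighted single reads, so lexicographic order is the
#' deterministic tie-break).
#'
#' @param assignment An [cluster_otus()] result.
#' @param libraries Named character vector mapping every sequence id to a
#'   library label.
#' @return An object of class `otu_table`: list with `counts` (OTU x library
#'   integer matrix) and `representatives` (named by OTU row).
#' @export
build_otu_table <- function(assignment, libraries) {
  stopifnot(inherits(assignment, "otu_assignment"))
  ids <- names(assignment$otu)
  missing_ids <- setdiff(ids, names(libraries))
  if (length(missing_ids) > 0L)
    stop("no library label for sequence(s): ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  lib <- libraries[ids]
  otu_names <- paste0("OTU_", seq_len(max(assignment$otu)))
  counts <- table(factor(otu_names[assignment$otu], levels = otu_names),
                  factor(lib, levels = sort(unique(lib))))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  reps <- vapply(split(ids, assignment$otu),
                 function(members) sort(members)[1L], character(1))
  names(reps) <- otu_names
  structure(list(counts = counts, representatives = reps,
                 cutoff = assignment$cutoff, linkage = assignment$linkage),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d libraries, %d sequences total\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Per-library OTU abundance vectors
#'
#' @param table An [build_otu_table()] result.
#' @return Named list of positive integer count vectors, one per library
#'   (zero-count OTUs dropped).
#' @export
library_abundances <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  lapply(stats::setNames(colnames(table$counts), colnames(table$counts)),
         function(l) {
           v <- table$counts[, l]
           v[v > 0L]
         })
}

#' Presence/absence incidence of OTUs across libraries
#'
#' @param table An [build_otu_table()] result.
#' @return Logical OTU x library matrix.
#' @export
otu_incidence <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  table$counts > 0L
}

#' Write an OTU table to TSV
#'
#' @param table An [build_otu_table()] result.
#' @param path Output path.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  out <- data.frame(otu = rownames(table$counts),
                    representative = unname(table$representatives),
                    table$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
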