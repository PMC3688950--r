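#' Construct a strain-by-primer detection matrix
#'
#' The substrate of all panel-coverage computation: a logical matrix whose
#' rows are strains and whose columns are primer pairs, `TRUE` meaning PCR
#' with that primer yielded a product for that strain. Strains that no primer
#' detects are legitimate and stay in every denominator.
#'
#' @param detected Logical matrix with unique row names (strain ids) and
#'   unique column names (primer codes).
#' @param metadata Optional data frame of per-strain annotation (taxon label,
#'   phylogenetic group, growth flags ...), one row per strain in matrix
#'   order.
#' @return An object of class `detection_matrix`.
#' @export
detection_matrix <- function(detected, metadata = NULL) {
  if (!is.matrix(detected) || !is.logical(detected))
    stop("`detected` must be a logical matrix", call. = FALSE)
  if (is.null(rownames(detected)) || is.null(colnames(detected)))
    stop("`detected` needs strain row names and primer column names",
         call. = FALSE)
  if (anyDuplicated(rownames(detected)))
    stop("duplicate strain id(s): ",
         paste(unique(rownames(detected)[duplicated(rownames(detected))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(detected)))
    stop("duplicate primer code(s): ",
         paste(unique(colnames(detected)[duplicated(colnames(detected))]),
               collapse = ", "), call. = FALSE)
  if (anyNA(detected))
    stop("detection matrix may not contain NA", call. = FALSE)
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
    if (nrow(metadata) != nrow(detected))
      stop("metadata rows must match strains", call. = FALSE)
    rownames(metadata) <- rownames(detected)
  }
  structure(list(strains = rownames(detected), primers = colnames(detected),
                 detected = detected, metadata = metadata),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat(sprintf("Detection matrix: %d strains x %d primers (%s)\n",
              length(x$strains), length(x$primers),
              paste(x$primers, collapse = ", ")))
  pos <- colSums(x$detected)
  cat("Positives per primer:",
      paste(sprintf("%s=%d", x$primers, pos), collapse = " "), "\n")
  cat(sprintf("Strains never detected: %d\n", sum(rowSums(x$detected) == 0L)))
  invisible(x)
}

#' Read a detection matrix from TSV
#'
#' First column: strain id. Columns listed in `meta_cols` (when present) are
#' kept as strain metadata; every remaining column is interpreted as a primer
#' with cells drawn from `symbols`. Both ASCII `-` and the typographic minus
#' sign are accepted as negatives by default.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param meta_cols Column names to treat as metadata rather than primers.
#' @param symbols Named logical vector mapping cell symbols to
#'   detected/undetected.
#' @return A [detection_matrix()].
#' @export
read_detection_matrix <- function(path,
                                  meta_cols = c("group", "taxon", "hep",
                                                "accession"),
                                  symbols = c("+" = TRUE, "1" = TRUE,
                                              "-" = FALSE, "0" = FALSE,
                                              "−" = FALSE)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L)
    stop("detection matrix needs a strain column plus primer columns",
         call. = FALSE)
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate strain id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  meta_present <- intersect(meta_cols, names(tab)[-1L])
  primer_cols <- setdiff(names(tab)[-1L], meta_present)
  if (length(primer_cols) == 0L)
    stop("no primer columns found", call. = FALSE)
  det <- matrix(NA, nrow = nrow(tab), ncol = length(primer_cols),
                dimnames = list(ids, primer_cols))
  for (p in primer_cols) {
    cell <- tab[[p]]
    bad <- which(!cell %in% names(symbols))
    if (length(bad) > 0L)
      stop(sprintf("unknown symbol '%s' in row '%s', column '%s'",
                   cell[bad[1L]], ids[bad[1L]], p), call. = FALSE)
    det[, p] <- unname(symbols[cell])
  }
  meta <- if (length(meta_present) > 0L) tab[meta_present] else NULL
  detection_matrix(det, metadata = meta)
}

#' The packaged alkB strain-by-primer detection matrix
#'
#' PCR amplification outcomes of the \emph{alkB} gene for 43 alkane-degrading
#' bacterial strains (all able to grow on heptadecane as sole carbon source)
#' screened with the eight \emph{alkB}-targeting primer pairs of
#' [alkb_primers()]. Strain metadata records the phylogenetic group and the
#' BLAST-N taxon assignment.
#'
#' @return A [detection_matrix()] with 43 strains and primers "a".."h".
#' @export
alkb_detection_matrix <- function() {
  read_detection_matrix(system.file("extdata", "alkb_detection_matrix.tsv",
                                    package = "alkbpanel", mustWork = TRUE))
}

.check_codes <- function(dm, codes) {
  unknown <- setdiff(codes, dm$primers)
  if (length(unknown) > 0L)
    stop("unknown primer code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  invisible(codes)
}

.evaluate_panel <- function(dm, panel) {
  covered <- rowSums(dm$detected[, panel, drop = FALSE]) > 0L
  structure(list(panel = sort(panel),
                 covered_count = sum(covered),
                 coverage_pct = 100 * sum(covered) / length(dm$strains),
                 covered_ids = dm$strains[covered],
                 uncovered_ids = dm$strains[!covered],
                 n_strains = length(dm$strains)),
            class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat(sprintf("Panel {%s}: %d/%d strains covered (%.1f%%)\n",
              paste(x$panel, collapse = ","), x$covered_count, x$n_strains,
              x$coverage_pct))
  if (!is.null(x$trace)) {
    cat("Greedy selection trace:\n")
    print(x$trace, row.names = FALSE)
  }
  if (!is.null(x$ties) && length(x$ties) > 1L)
    cat(sprintf("Tied optima: %s\n",
                paste(vapply(x$ties, function(p) paste(p, collapse = ","),
                             character(1)), collapse = " | ")))
  invisible(x)
}

#' Coverage of a single primer pair
#'
#' @param dm A [detection_matrix()].
#' @param primer A primer code present in `dm`.
#' @return A `panel_evaluation` (panel, covered_count, coverage_pct,
#'   covered/uncovered strain ids).
#' @examples
#' primer_coverage(alkb_detection_matrix(), "e")  # 21/43 strains, 48.8%
#' @export
primer_coverage <- function(dm, primer) {
  stopifnot(inherits(dm, "detection_matrix"), length(primer) == 1L)
  .check_codes(dm, primer)
  .evaluate_panel(dm, primer)
}

#' Union coverage of a primer panel
#'
#' A strain is covered if it is positive for at least one panel member.
#'
#' @param dm A [detection_matrix()].
#' @param panel Non-empty character vector of primer codes.
#' @return A `panel_evaluation`.
#' @examples
#' panel_union_coverage(alkb_detection_matrix(), c("d", "e", "f"))  # 34/43, 79.1%
#' @export
panel_union_coverage <- function(dm, panel) {
  stopifnot(inherits(dm, "detection_matrix"))
  if (length(panel) == 0L) stop("panel must be non-empty", call. = FALSE)
  .check_codes(dm, panel)
  .evaluate_panel(dm, unique(panel))
}

#' Enumerate and rank all k-primer panels
#'
#' Evaluates every size-`k` subset of the primers and ranks them by covered
#' strain count (descending), ties broken lexicographically by the sorted
#' panel codes. Comparisons are made on exact counts, never on rounded
#' percentages.
#'
#' @param dm A [detection_matrix()].
#' @param k Panel size, between 1 and the number of primers.
#' @return A data frame with columns `panel` (codes joined by "+"),
#'   `covered_count` and `coverage_pct`, one row per subset; the code vectors
#'   themselves are in `attr(, "panels")`.
#' @export
enumerate_panels <- function(dm, k) {
  stopifnot(inherits(dm, "detection_matrix"))
  n <- length(dm$primers)
  if (!(k >= 1L && k <= n))
    stop("k must be between 1 and ", n, call. = FALSE)
  combos <- utils::combn(sort(dm$primers), k, simplify = FALSE)
  evals <- lapply(combos, function(p) .evaluate_panel(dm, p))
  counts <- vapply(evals, `[[`, integer(1), "covered_count")
  labels <- vapply(combos, paste, character(1), collapse = "+")
  ord <- order(-counts, labels)
  out <- data.frame(panel = labels[ord], covered_count = counts[ord],
                    coverage_pct = vapply(evals, `[[`, numeric(1),
                                          "coverage_pct")[ord],
                    stringsAsFactors = FALSE)
  attr(out, "panels") <- combos[ord]
  out
}

#' Best k-primer panel by exhaustive or greedy maximum coverage
#'
#' Exhaustive search returns the true maximum-coverage subset (all tied
#' optima are reported; the canonical winner is the lexicographically first).
#' Greedy search picks the primer with maximal marginal gain at each step
#' (ties lexicographic) and reports the per-step trace; greedy coverage can
#' be strictly below the exhaustive optimum. When `choose(n, k)` exceeds
#' 1e6, exhaustive requests fall back to greedy with a warning.
#'
#' @param dm A [detection_matrix()].
#' @param k Panel size.
#' @param method "exhaustive" (default) or "greedy".
#' @return A `panel_evaluation`; exhaustive results carry `$ties` (all
#'   optimal panels), greedy results carry `$trace` (step, primer, gain,
#'   cumulative coverage).
#' @examples
#' best_panel(alkb_detection_matrix(), 3)  # {d,e,f}, 34/43 strains
#' @export
best_panel <- function(dm, k, method = c("exhaustive", "greedy")) {
  stopifnot(inherits(dm, "detection_matrix"))
  method <- match.arg(method)
  n <- length(dm$primers)
  if (!(k >= 1L && k <= n))
    stop("k must be between 1 and ", n, call. = FALSE)
  if (method == "exhaustive" && choose(n, k) > 1e6) {
    warning("choose(n, k) > 1e6; falling back to greedy selection")
    method <- "greedy"
  }
  if (method == "exhaustive") {
    ranked <- enumerate_panels(dm, k)
    best_count <- ranked$covered_count[1L]
    ties <- attr(ranked, "panels")[ranked$covered_count == best_count]
    res <- .evaluate_panel(dm, ties[[1L]])
    res$method <- "exhaustive"
    res$ties <- ties
    return(res)
  }
  panel <- character(0)
  trace <- data.frame(step = integer(0), primer = character(0),
                      gain = integer(0), cumulative = integer(0),
                      stringsAsFactors = FALSE)
  for (step in seq_len(k)) {
    candidates <- sort(setdiff(dm$primers, panel))
    gains <- vapply(candidates, function(cand)
      marginal_gain(dm, panel, cand)$gain, integer(1))
    pick <- candidates[which.max(gains)]  # ties: lexicographically first
    panel <- c(panel, pick)
    trace <- rbind(trace, data.frame(
      step = step, primer = pick, gain = gains[[pick]],
      cumulative = .evaluate_panel(dm, panel)$covered_count,
      stringsAsFactors = FALSE))
  }
  res <- .evaluate_panel(dm, panel)
  res$method <- "greedy"
  res$trace <- trace
  res
}

#' Strains added by one more primer
#'
#' @param dm A [detection_matrix()].
#' @param panel Character vector of primer codes already in the panel (may be
#'   empty).
#' @param candidate A primer code not in `panel`.
#' @return A list with `gain` (number of newly covered strains, always >= 0)
#'   and `added_ids` (their strain ids).
#' @examples
#' marginal_gain(alkb_detection_matrix(), c("d", "e", "f"), "c")  # +2 strains
#' @export
marginal_gain <- function(dm, panel, candidate) {
  stopifnot(inherits(dm, "detection_matrix"), length(candidate) == 1L)
  .check_codes(dm, c(panel, candidate))
  if (candidate %in% panel)
    stop("candidate '", candidate, "' is already in the panel", call. = FALSE)
  before <- if (length(panel) == 0L) rep(FALSE, length(dm$strains)) else
    rowSums(dm$detected[, panel, drop = FALSE]) > 0L
  added <- !before & dm$detected[, candidate]
  list(gain = sum(added), added_ids = dm$strains[added])
}

#' Strains a panel never detects
#'
#' @param dm A [detection_matrix()].
#' @param panel Non-empty character vector of primer codes.
#' @return A data frame of the undetected strains with their metadata.
#' @examples
#' undetected_strains(alkb_detection_matrix(), letters[1:8])  # the 7 never-detected strains
#' @export
undetected_strains <- function(dm, panel) {
  eval <- panel_union_coverage(dm, panel)
  out <- data.frame(strain = eval$uncovered_ids, stringsAsFactors = FALSE)
  if (!is.null(dm$metadata))
    out <- cbind(out, dm$metadata[eval$uncovered_ids, , drop = FALSE])
  rownames(out) <- NULL
  out
}
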