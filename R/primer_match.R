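# IUPAC degeneracy sets, plus inosine (I) as a universal-pairing analog.
# Primer-side symbols only; templates are restricted to A/C/G/T/N.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T")
)

.PRIMER_ALPHABET <- names(.IUPAC_SETS)
.TEMPLATE_ALPHABET <- c("A", "C", "G", "T", "N")

# 16 x 5 lookup: does primer symbol (row) accept template base (column)?
# Template N is unknown and accepts any primer symbol (screening policy:
# under-calling a site is worse than over-calling one).
.MATCH_TABLE <- local({
  m <- matrix(FALSE, nrow = length(.PRIMER_ALPHABET), ncol = length(.TEMPLATE_ALPHABET),
              dimnames = list(.PRIMER_ALPHABET, .TEMPLATE_ALPHABET))
  for (p in .PRIMER_ALPHABET) m[p, .IUPAC_SETS[[p]]] <- TRUE
  m[, "N"] <- TRUE
  m
})

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", D = "H", H = "D", V = "B", N = "N", I = "I")

.check_alphabet <- function(x, alphabet, what) {
  bad <- setdiff(unique(x), alphabet)
  if (length(bad) > 0L)
    stop(sprintf("invalid %s symbol(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible(x)
}

.split_upper <- function(seq) strsplit(toupper(seq), "", fixed = TRUE)[[1L]]

#' Does a degenerate primer base match a template base?
#'
#' Implements IUPAC degeneracy matching with two policies: inosine (`I`)
#' matches all four bases, and a template `N` (unknown) matches any primer
#' symbol. Degeneracy is honored on the primer side only; template symbols
#' other than A/C/G/T/N are rejected.
#'
#' @param primer_base Character vector of primer symbols (A/C/G/T, IUPAC
#'   degeneracies R,Y,S,W,K,M,B,D,H,V,N, or inosine I).
#' @param template_base Character vector of template bases (A/C/G/T/N).
#' @return Logical vector; `TRUE` where the template base lies in the
#'   degeneracy set of the primer symbol.
#' @examples
#' iupac_match("R", "A")  # TRUE: R = A/G
#' iupac_match("R", "C")  # FALSE
#' iupac_match("I", "T")  # TRUE: inosine pairs universally
#' @export
iupac_match <- function(primer_base, template_base) {
  primer_base <- toupper(primer_base)
  template_base <- toupper(template_base)
  .check_alphabet(primer_base, .PRIMER_ALPHABET, "primer")
  .check_alphabet(template_base, .TEMPLATE_ALPHABET, "template")
  .MATCH_TABLE[cbind(primer_base, template_base)]
}

#' Reverse complement of a (possibly degenerate) oligo
#'
#' Complements IUPAC degeneracy symbols onto their partner sets
#' (R<->Y, K<->M, B<->V, D<->H; S, W, N, I are self-complementary).
#'
#' @param seq Single oligo string.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(seq) {
  chars <- .split_upper(seq)
  .check_alphabet(chars, names(.COMPLEMENT), "sequence")
  paste(rev(.COMPLEMENT[chars]), collapse = "")
}

#' Construct a primer pair
#'
#' A forward/reverse pair of degenerate oligos with (optional) expected
#' amplicon coordinates on a reference gene, given 1-based inclusive.
#'
#' @param code Single-character panel code (e.g. "a".."h").
#' @param seq_fwd,seq_rev Oligo strings over the extended alphabet
#'   (IUPAC degeneracies and inosine allowed). Minimum length 10.
#' @param name_fwd,name_rev Free-text oligo names.
#' @param ref_start,ref_end 1-based inclusive coordinates of the expected
#'   fragment on the reference gene, or `NA`.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(code, seq_fwd, seq_rev, name_fwd = NA_character_,
                        name_rev = NA_character_, ref_start = NA_integer_,
                        ref_end = NA_integer_) {
  stopifnot(is.character(code), length(code) == 1L)
  seq_fwd <- toupper(gsub("[[:space:]]", "", seq_fwd))
  seq_rev <- toupper(gsub("[[:space:]]", "", seq_rev))
  .check_alphabet(.split_upper(seq_fwd), .PRIMER_ALPHABET, "primer")
  .check_alphabet(.split_upper(seq_rev), .PRIMER_ALPHABET, "primer")
  if (nchar(seq_fwd) < 10L || nchar(seq_rev) < 10L)
    stop("primer sequences must be at least 10 nt", call. = FALSE)
  if (!is.na(ref_start) && !is.na(ref_end) && ref_start >= ref_end)
    stop("ref_start must be < ref_end", call. = FALSE)
  structure(list(code = code, name_fwd = name_fwd, name_rev = name_rev,
                 seq_fwd = seq_fwd, seq_rev = seq_rev,
                 ref_start = as.integer(ref_start),
                 ref_end = as.integer(ref_end)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("Primer pair (%s): %s / %s\n", x$code,
              ifelse(is.na(x$name_fwd), "fwd", x$name_fwd),
              ifelse(is.na(x$name_rev), "rev", x$name_rev)))
  cat(sprintf("  fwd 5'-%s-3'\n  rev 5'-%s-3'\n", x$seq_fwd, x$seq_rev))
  if (!is.na(x$ref_start))
    cat(sprintf("  expected fragment: %d..%d nt (%d nt)\n",
                x$ref_start, x$ref_end, expected_fragment_length(x)))
  invisible(x)
}

#' Read a primer panel from TSV
#'
#' Expects columns `code`, `seq_fwd`, `seq_rev` and optionally `name_fwd`,
#' `name_rev`, `ref_start`, `ref_end`. Codes must be unique.
#'
#' @param path Path to a tab-separated file.
#' @return A named list of [primer_pair()] objects, class `primer_panel`.
#' @export
read_primer_panel <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("code", "seq_fwd", "seq_rev")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    stop("primer panel file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$code))
    stop("duplicate primer code(s): ",
         paste(unique(tab$code[duplicated(tab$code)]), collapse = ", "),
         call. = FALSE)
  get_col <- function(col, default) if (col %in% names(tab)) tab[[col]] else rep(default, nrow(tab))
  pairs <- lapply(seq_len(nrow(tab)), function(i) {
    primer_pair(code = tab$code[i], seq_fwd = tab$seq_fwd[i],
                seq_rev = tab$seq_rev[i],
                name_fwd = get_col("name_fwd", NA_character_)[i],
                name_rev = get_col("name_rev", NA_character_)[i],
                ref_start = get_col("ref_start", NA_integer_)[i],
                ref_end = get_col("ref_end", NA_integer_)[i])
  })
  names(pairs) <- tab$code
  structure(pairs, class = "primer_panel")
}

#' The packaged alkB-targeting primer panel
#'
#' Eight published degenerate primer pairs targeting the bacterial alkane
#' monooxygenase gene \emph{alkB}, with expected fragment coordinates on the
#' complete \emph{Pseudomonas putida} Gp01 \emph{alkB} reference gene.
#'
#' @return A `primer_panel` (named list of [primer_pair()] objects, codes
#'   "a" through "h").
#' @export
alkb_primers <- function() {
  read_primer_panel(system.file("extdata", "alkb_primers.tsv",
                                package = "alkbpanel", mustWork = TRUE))
}

#' Expected amplicon length from reference coordinates
#'
#' @param pair A [primer_pair()] with reference coordinates set.
#' @return Fragment length in nt (`ref_end - ref_start + 1`).
#' @examples
#' p <- primer_pair("a", "ACGGSCAYTTCTACRTCG", "CCGTAARTGYTCGAGRTAG",
#'                  ref_start = 481, ref_end = 823)
#' expected_fragment_length(p)  # 343
#' @export
expected_fragment_length <- function(pair) {
  stopifnot(inherits(pair, "primer_pair"))
  if (is.na(pair$ref_start) || is.na(pair$ref_end))
    stop("reference coordinates not available for primer pair ", pair$code,
         call. = FALSE)
  pair$ref_end - pair$ref_start + 1L
}

.empty_hits <- function() {
  data.frame(template_id = character(0), strand = character(0),
              start = integer(0), end = integer(0), mismatches = integer(0),
              stringsAsFactors = FALSE)
}

# Scan one oriented primer along the plus strand of a template.
# Returns 0-based half-open windows with mismatch counts; the positions in
# `anchor_idx` (1-based within the window) must match exactly.
.scan_oriented <- function(primer_chars, tmpl_chars, max_mismatch, anchor_idx) {
  L <- length(primer_chars)
  n <- length(tmpl_chars)
  if (L > n) return(list(start = integer(0), mism = integer(0)))
  n_win <- n - L + 1L
  # mismatch count per window, accumulated position by position
  mism <- integer(n_win)
  anchor_ok <- rep(TRUE, n_win)
  for (j in seq_len(L)) {
    ok <- .MATCH_TABLE[cbind(rep(primer_chars[j], n_win),
                             tmpl_chars[j:(j + n_win - 1L)])]
    mism <- mism + !ok
    if (j %in% anchor_idx) anchor_ok <- anchor_ok & ok
  }
  keep <- mism <= max_mismatch & anchor_ok
  list(start = which(keep) - 1L, mism = mism[keep])
}

#' Find degenerate-primer binding sites on a template
#'
#' Slides the primer along both strands of the template, counting per-position
#' IUPAC mismatches ([iupac_match()]). The reverse strand is searched as the
#' reverse complement of the primer against the plus strand; hits are always
#' reported in plus-strand coordinates (0-based, half-open), ordered by start
#' with plus-strand hits before minus-strand hits at equal start.
#'
#' @param primer Oligo string (degeneracies and inosine allowed).
#' @param template Template string over A/C/G/T/N.
#' @param max_mismatch Maximum tolerated mismatches per site (default 3).
#' @param anchor_3prime Number of 3'-terminal primer positions required to
#'   match exactly (default 3); 3' fidelity dominates PCR extension.
#' @param template_id Identifier recorded in the hit table.
#' @return A data frame with columns `template_id`, `strand` ("+"/"-"),
#'   `start`, `end` (0-based half-open), `mismatches`.
#' @export
find_primer_sites <- function(primer, template, max_mismatch = 3L,
                              anchor_3prime = 3L, template_id = "template") {
  stopifnot(max_mismatch >= 0L, anchor_3prime >= 0L)
  primer <- toupper(gsub("[[:space:]]", "", primer))
  pr <- .split_upper(primer)
  tm <- .split_upper(template)
  .check_alphabet(pr, .PRIMER_ALPHABET, "primer")
  .check_alphabet(tm, .TEMPLATE_ALPHABET, "template")
  L <- length(pr)
  anchor_3prime <- min(anchor_3prime, L)

  # plus strand: primer 3' end is the window's right end
  plus <- .scan_oriented(pr, tm, max_mismatch,
                         anchor_idx = if (anchor_3prime > 0L) (L - anchor_3prime + 1L):L else integer(0))
  # minus strand: reverse-complemented primer against the plus strand;
  # the primer 3' end maps to the window's left end
  prc <- .split_upper(revcomp(primer))
  minus <- .scan_oriented(prc, tm, max_mismatch,
                          anchor_idx = if (anchor_3prime > 0L) 1L:anchor_3prime else integer(0))

  hits <- rbind(
    if (length(plus$start) > 0L)
      data.frame(template_id = template_id, strand = "+", start = plus$start,
                 end = plus$start + L, mismatches = plus$mism,
                 stringsAsFactors = FALSE),
    if (length(minus$start) > 0L)
      data.frame(template_id = template_id, strand = "-", start = minus$start,
                 end = minus$start + L, mismatches = minus$mism,
                 stringsAsFactors = FALSE)
  )
  if (is.null(hits)) return(.empty_hits())
  hits[order(hits$start, hits$strand != "+"), , drop = FALSE]
}

#' Predict PCR amplicons for a primer pair on a template
#'
#' Pairs every plus-strand forward-primer hit with every downstream
#' minus-strand reverse-primer hit and keeps products whose length (forward
#' start to reverse end, both primers included) lies within bounds. The two
#' primer footprints may not overlap.
#'
#' @param pair A [primer_pair()].
#' @param template Template string over A/C/G/T/N.
#' @param min_len,max_len Product length bounds in nt (`0 < min_len <= max_len`).
#' @param max_mismatch,anchor_3prime Passed to [find_primer_sites()].
#' @param template_id Identifier recorded in the output.
#' @return A data frame with columns `template_id`, `start`, `end`, `length`
#'   (0-based half-open product coordinates) plus forward/reverse hit
#'   coordinates and mismatch counts.
#' @export
predict_amplicons <- function(pair, template, min_len = 50L, max_len = 5000L,
                              max_mismatch = 3L, anchor_3prime = 3L,
                              template_id = "template") {
  stopifnot(inherits(pair, "primer_pair"))
  if (!(min_len > 0L && min_len <= max_len))
    stop("need 0 < min_len <= max_len", call. = FALSE)
  fwd <- find_primer_sites(pair$seq_fwd, template, max_mismatch,
                           anchor_3prime, template_id)
  rev <- find_primer_sites(pair$seq_rev, template, max_mismatch,
                           anchor_3prime, template_id)
  fwd <- fwd[fwd$strand == "+", , drop = FALSE]
  rev <- rev[rev$strand == "-", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(fwd))) for (j in seq_len(nrow(rev))) {
    if (rev$start[j] < fwd$end[i]) next  # reverse site must lie downstream
    len <- rev$end[j] - fwd$start[i]
    if (len < min_len || len > max_len) next
    out[[length(out) + 1L]] <- data.frame(
      template_id = template_id, start = fwd$start[i], end = rev$end[j],
      length = len,
      fwd_start = fwd$start[i], fwd_end = fwd$end[i],
      fwd_mismatches = fwd$mismatches[i],
      rev_start = rev$start[j], rev_end = rev$end[j],
      rev_mismatches = rev$mismatches[j],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      fwd_start = integer(0), fwd_end = integer(0),
                      fwd_mismatches = integer(0), rev_start = integer(0),
                      rev_end = integer(0), rev_mismatches = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}
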