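# Run expr under a fixed RNG seed, restoring the caller's RNG state.
.with_rng <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(expr)
}

#' Specification for synthetic panel/clone-library data
#'
#' Bundles every parameter of the synthetic generators with a mandatory
#' seed, so each generated object is a pure function of its spec. Defaults
#' mirror a desk-scale primer-panel screen and clone-library study: 43
#' strains screened with 8 primer pairs of which a planted triplet covers
#' 80%, 3 primer-biased libraries of 60 clones over 15 phylotype templates
#' of 400 nt at 8% mutual divergence, and a log-series abundance law (the
#' classic singleton-heavy clone-library shape).
#'
#' @param seed Integer seed (mandatory).
#' @param n_strains,n_primers Detection-matrix dimensions.
#' @param planted_panel Primer codes of the planted optimal panel.
#' @param target_coverage Fraction of strains covered by the planted panel.
#' @param offpanel_rate Detection probability of off-panel primers.
#' @param n_phylotypes,template_length,divergence Phylotype templates:
#'   count, alignment length (nt) and guaranteed pairwise divergence
#'   (substitution fraction; must exceed twice the OTU cutoff for planted
#'   recovery).
#' @param abundance "logseries" or "lognormal".
#' @param logseries_x Log-series parameter in (0, 1); larger values thicken
#'   the rare tail.
#' @param lognormal_meanlog,lognormal_sdlog Lognormal abundance parameters.
#' @param clones_per_library Clones sampled per library.
#' @param libraries Library labels (one simulated primer each).
#' @param primer_bias Optional list of per-library phylotype inclusion
#'   weight vectors (length `n_phylotypes`); default: each library sees a
#'   random 60% subset of phylotypes, emulating primer-specific sampling
#'   bias.
#' @param n_leaves,tree_regime,tree_rate Labeled-tree generator: leaf count,
#'   "clustered" (communities on disjoint clades) or "interleaved" (labels
#'   independent of topology), and exponential branch-length rate.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed,
                           n_strains = 43L, n_primers = 8L,
                           planted_panel = c("p1", "p2", "p3"),
                           target_coverage = 0.8, offpanel_rate = 0.15,
                           n_phylotypes = 15L, template_length = 400L,
                           divergence = 0.08,
                           abundance = c("logseries", "lognormal"),
                           logseries_x = 0.95,
                           lognormal_meanlog = 0, lognormal_sdlog = 1.2,
                           clones_per_library = 60L,
                           libraries = c("d", "e", "f"),
                           primer_bias = NULL,
                           n_leaves = 16L,
                           tree_regime = c("clustered", "interleaved"),
                           tree_rate = 1) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  abundance <- match.arg(abundance)
  tree_regime <- match.arg(tree_regime)
  stopifnot(target_coverage >= 0, target_coverage <= 1,
            offpanel_rate >= 0, offpanel_rate <= 1,
            divergence > 0, divergence < 1,
            logseries_x > 0, logseries_x < 1)
  if (!is.null(primer_bias)) {
    stopifnot(is.list(primer_bias),
              length(primer_bias) == length(libraries),
              all(vapply(primer_bias, length, integer(1)) == n_phylotypes))
  }
  structure(list(seed = as.integer(seed), n_strains = as.integer(n_strains),
                 n_primers = as.integer(n_primers),
                 planted_panel = planted_panel,
                 target_coverage = target_coverage,
                 offpanel_rate = offpanel_rate,
                 n_phylotypes = as.integer(n_phylotypes),
                 template_length = as.integer(template_length),
                 divergence = divergence, abundance = abundance,
                 logseries_x = logseries_x,
                 lognormal_meanlog = lognormal_meanlog,
                 lognormal_sdlog = lognormal_sdlog,
                 clones_per_library = as.integer(clones_per_library),
                 libraries = libraries, primer_bias = primer_bias,
                 n_leaves = as.integer(n_leaves), tree_regime = tree_regime,
                 tree_rate = tree_rate),
            class = "synthetic_spec")
}

#' Generate a detection matrix with a planted optimal panel
#'
#' The covered strains (a `target_coverage` fraction) are partitioned into
#' one block per planted-panel primer; planted primer i detects exactly its
#' block, so the planted panel is the unique maximum-coverage subset of its
#' size. Off-panel primers detect random subsets of the covered strains, at
#' rate `offpanel_rate` and capped below the smallest block, so they never
#' displace a planted primer. Reproducible from the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A [detection_matrix()] with primers `p1..pn` (planted codes must
#'   be among them).
#' @export
gen_detection_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  primers <- paste0("p", seq_len(spec$n_primers))
  if (!all(spec$planted_panel %in% primers))
    stop("planted panel must be a subset of the primer set", call. = FALSE)
  k <- length(spec$planted_panel)
  n_cov <- round(spec$target_coverage * spec$n_strains)
  if (k > 0 && n_cov > 0 && n_cov < k)
    stop("too few covered strains to fill the planted blocks", call. = FALSE)
  .with_rng(spec$seed, {
    strains <- sprintf("s%02d", seq_len(spec$n_strains))
    det <- matrix(FALSE, spec$n_strains, spec$n_primers,
                  dimnames = list(strains, primers))
    if (n_cov > 0 && k > 0) {
      covered <- sample(spec$n_strains, n_cov)
      block_of <- rep(seq_len(k), length.out = n_cov)
      for (i in seq_len(k))
        det[covered[block_of == i], spec$planted_panel[i]] <- TRUE
      min_block <- min(tabulate(block_of, k))
      off <- setdiff(primers, spec$planted_panel)
      for (p in off) {
        size <- min(max(0L, min_block - 1L),
                    stats::rbinom(1L, n_cov, spec$offpanel_rate))
        if (size > 0L) det[sample(covered, size), p] <- TRUE
      }
    }
    detection_matrix(det)
  })
}

# phylotype templates: each template mutates the root at ceil(divergence*L)
# random positions, so expected pairwise divergence is about twice the
# requested value; the minimum pairwise divergence is verified and the draw
# repeated until the requested floor holds (deterministic under the spec
# seed), erroring when the template length cannot support it.
.gen_templates <- function(spec) {
  L <- spec$template_length
  k <- ceiling(spec$divergence * L)
  if (k > L)
    stop("requested divergence unattainable at this template length",
         call. = FALSE)
  bases <- c("A", "C", "G", "T")
  for (attempt in 1:20) {
    root <- sample(bases, L, replace = TRUE)
    tmpl_chars <- lapply(seq_len(spec$n_phylotypes), function(i) {
      pos <- sample.int(L, k)
      s <- root
      s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1L),
                       character(1))
      s
    })
    min_div <- 1
    for (i in seq_len(spec$n_phylotypes - 1L))
      for (j in (i + 1L):spec$n_phylotypes)
        min_div <- min(min_div,
                       sum(tmpl_chars[[i]] != tmpl_chars[[j]]) / L)
    if (spec$n_phylotypes < 2L || min_div >= spec$divergence) {
      templates <- vapply(tmpl_chars, paste, character(1), collapse = "")
      names(templates) <- sprintf("phylo%02d", seq_len(spec$n_phylotypes))
      return(templates)
    }
  }
  stop("requested divergence unattainable at this template length",
       call. = FALSE)
}

.abundance_probs <- function(spec, n) {
  ranks <- sample(n)  # each library emphasises different phylotypes
  p <- switch(spec$abundance,
    logseries = spec$logseries_x^ranks / ranks,
    lognormal = stats::rlnorm(n, spec$lognormal_meanlog,
                              spec$lognormal_sdlog))
  p / sum(p)
}

#' Generate primer-biased clone libraries over planted phylotypes
#'
#' Builds phylotype templates by mutating a random root sequence in disjoint
#' position blocks (pairwise divergence exactly twice the spec divergence,
#' guaranteed), then samples clones per library from the abundance law,
#' filtered by per-library phylotype inclusion weights that emulate
#' primer-specific amplification bias. Clones are exact template copies, so
#' the emitted gap-free alignment carries the planted OTU structure.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `alignment` (a [multiple_alignment()]), `libraries`
#'   (named id -> label vector), `phylotype_of` (named id -> template
#'   vector) and `templates`.
#' @export
gen_clone_libraries <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_rng(spec$seed, {
    templates <- .gen_templates(spec)
    n_phylo <- spec$n_phylotypes
    bias <- spec$primer_bias
    if (is.null(bias)) {
      bias <- lapply(seq_along(spec$libraries), function(i) {
        w <- numeric(n_phylo)
        w[sample(n_phylo, max(1L, round(0.6 * n_phylo)))] <- 1
        w
      })
    }
    ids <- character(0); seqs <- character(0); libs <- character(0)
    phylo_of <- character(0)
    for (i in seq_along(spec$libraries)) {
      lab <- spec$libraries[i]
      p <- .abundance_probs(spec, n_phylo) * bias[[i]]
      if (sum(p) == 0)
        stop("library '", lab, "' has all-zero inclusion weights",
             call. = FALSE)
      p <- p / sum(p)
      draws <- sample.int(n_phylo, spec$clones_per_library, replace = TRUE,
                          prob = p)
      id_i <- sprintf("%s_%03d", lab, seq_len(spec$clones_per_library))
      ids <- c(ids, id_i)
      seqs <- c(seqs, unname(templates[draws]))
      libs <- c(libs, rep(lab, spec$clones_per_library))
      phylo_of <- c(phylo_of, stats::setNames(names(templates)[draws], id_i))
    }
    list(alignment = multiple_alignment(ids, seqs, libs),
         libraries = stats::setNames(libs, ids),
         phylotype_of = phylo_of,
         templates = templates)
  })
}

#' Generate a community-labeled random tree
#'
#' Coalescent-topology tree (via `ape::rcoal`) with independent exponential
#' branch lengths. In the "clustered" regime the two communities occupy the
#' two clades descending from the root (maximally separated communities); in
#' the "interleaved" regime labels are assigned to leaves independently of
#' topology (the UniFrac null).
#'
#' @param spec A [synthetic_spec()].
#' @param communities Two community labels (default "A", "B").
#' @return A list with `tree` (`ape::phylo`, leaf labels `t1..tn`) and
#'   `communities` (named leaf -> label vector).
#' @export
gen_labeled_tree <- function(spec, communities = c("A", "B")) {
  stopifnot(inherits(spec, "synthetic_spec"), length(communities) == 2L)
  if (spec$n_leaves < 4L) stop("need at least 4 leaves", call. = FALSE)
  .with_rng(spec$seed, {
    tree <- ape::rcoal(spec$n_leaves)
    tree$edge.length <- stats::rexp(nrow(tree$edge), rate = spec$tree_rate)
    labels <- character(spec$n_leaves)
    names(labels) <- tree$tip.label
    if (spec$tree_regime == "clustered") {
      root <- spec$n_leaves + 1L
      first_child <- tree$edge[tree$edge[, 1L] == root, 2L][1L]
      # leaves under the first root child form community 1
      clade1 <- if (first_child <= spec$n_leaves) first_child else {
        et <- .edge_tip_incidence(tree)
        which(et$inc[which(et$tree$edge[, 2L] == first_child), ])
      }
      labels[] <- communities[2L]
      labels[tree$tip.label[clade1]] <- communities[1L]
    } else {
      labels[] <- sample(communities, spec$n_leaves, replace = TRUE)
      # guarantee both communities occur
      if (length(unique(labels)) == 1L)
        labels[sample(spec$n_leaves, 1L)] <-
          setdiff(communities, labels[1L])
    }
    list(tree = tree, communities = labels)
  })
}
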