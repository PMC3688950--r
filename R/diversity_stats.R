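.check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L) stop("empty abundance vector", call. = FALSE)
  if (any(counts < 1 | counts != floor(counts)))
    stop("abundances must be positive integers", call. = FALSE)
  counts
}

# frequency-of-frequencies: f[j] = number of OTUs with count exactly j
.freq_counts <- function(counts, j) sum(counts == j)

.estimate <- function(name, value, lower = NA_real_, upper = NA_real_,
                      parameters = list()) {
  structure(list(estimator = name, value = value, lower = lower,
                 upper = upper, parameters = parameters),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  ci <- if (!is.na(x$lower)) sprintf(" (95%% CI %.2f-%.2f)", x$lower, x$upper) else ""
  cat(sprintf("%s: %.4g%s\n", x$estimator, x$value, ci))
  invisible(x)
}

#' Chao1 richness estimate with log-normal confidence bounds
#'
#' Nonparametric richness extrapolation from singleton (f1) and doubleton
#' (f2) frequencies. The bias-corrected form (default) is
#' `S_obs + f1(f1-1)/(2(f2+1))`; the classic form is `S_obs + f1^2/(2 f2)`,
#' falling back to bias-corrected when f2 = 0. The 95% interval is the
#' log-normal interval of Chao (1987): with `T = S_hat - S_obs` and the
#' variant's variance, `K = exp(1.96 sqrt(log(1 + var/T^2)))`,
#' `lower = S_obs + T/K`, `upper = S_obs + T*K`; when T = 0 the interval
#' degenerates to `[S_obs, S_obs]`.
#'
#' @param counts Positive integer abundance vector (one entry per OTU).
#' @param variant "bias_corrected" (default) or "classic".
#' @return A `diversity_estimate` with point value and 95% bounds.
#' @examples
#' chao1(c(1, 1, 2, 3))$value              # 4.5
#' chao1(c(1, 1, 2, 3), "classic")$value   # 6
#' @export
chao1 <- function(counts, variant = c("bias_corrected", "classic")) {
  counts <- .check_counts(counts)
  variant <- match.arg(variant)
  s_obs <- length(counts)
  f1 <- .freq_counts(counts, 1)
  f2 <- .freq_counts(counts, 2)
  used <- variant
  if (variant == "classic" && f2 == 0) used <- "bias_corrected"
  if (used == "classic") {
    s_hat <- s_obs + f1^2 / (2 * f2)
    r <- f1 / f2
    v <- f2 * (r^2 / 2 + r^3 + r^4 / 4)
  } else {
    s_hat <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    v <- f1 * (f1 - 1) / (2 * (f2 + 1)) +
      f1 * (2 * f1 - 1)^2 / (4 * (f2 + 1)^2) +
      f1^2 * f2 * (f1 - 1)^2 / (4 * (f2 + 1)^4)
  }
  t_extra <- s_hat - s_obs
  if (t_extra > 0 && v > 0) {
    k <- exp(1.96 * sqrt(log(1 + v / t_extra^2)))
    lower <- s_obs + t_extra / k
    upper <- s_obs + t_extra * k
  } else {
    lower <- upper <- s_obs
  }
  .estimate("chao1", s_hat, lower, upper,
            list(variant = variant, variant_used = used, f1 = f1, f2 = f2,
                 s_obs = s_obs))
}

#' ACE richness estimate
#'
#' Abundance-based coverage estimator. OTUs with counts at or below
#' `rare_cutoff` form the rare group; with `N_rare` their total count,
#' `C_ace = 1 - f1/N_rare` the rare-group sample coverage and `gamma^2` the
#' (non-negative) squared coefficient of variation,
#' `ACE = S_abund + S_rare/C_ace + (f1/C_ace) * gamma^2`. When the rare
#' group is all singletons (`C_ace = 0`) the estimate falls back to
#' [chao1()] with a warning.
#'
#' @param counts Positive integer abundance vector.
#' @param rare_cutoff Count threshold separating rare from abundant OTUs
#'   (default 10).
#' @return A `diversity_estimate`.
#' @export
ace <- function(counts, rare_cutoff = 10) {
  counts <- .check_counts(counts)
  rare <- counts[counts <= rare_cutoff]
  s_abund <- sum(counts > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0L)
    return(.estimate("ace", length(counts),
                     parameters = list(rare_cutoff = rare_cutoff)))
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("all rare OTUs are singletons (C_ace = 0); falling back to chao1")
    est <- chao1(counts)
    est$parameters$fallback <- "chao1"
    est$parameters$rare_cutoff <- rare_cutoff
    return(est)
  }
  jj <- seq_len(rare_cutoff)
  fj <- vapply(jj, function(j) .freq_counts(rare, j), numeric(1))
  gamma2 <- max(0, (s_rare / c_ace) * sum(jj * (jj - 1) * fj) /
                  (n_rare * (n_rare - 1)) - 1)
  value <- s_abund + s_rare / c_ace + (f1 / c_ace) * gamma2
  .estimate("ace", value,
            parameters = list(rare_cutoff = rare_cutoff, c_ace = c_ace,
                              gamma2 = gamma2, s_rare = s_rare,
                              s_abund = s_abund))
}

#' Shannon diversity index
#'
#' `H' = -sum p_i log(p_i)` with `p_i = n_i / N`; natural log by default
#' (base-2 and base-10 selectable).
#'
#' @param counts Positive integer abundance vector.
#' @param base Logarithm base (default `exp(1)`).
#' @return A `diversity_estimate`.
#' @examples
#' shannon(rep(5, 4))$value  # log(4)
#' @export
shannon <- function(counts, base = exp(1)) {
  counts <- .check_counts(counts)
  p <- counts / sum(counts)
  .estimate("shannon", -sum(p * log(p, base = base)),
            parameters = list(base = base))
}

#' Good's coverage
#'
#' `C = 1 - f1/N`: the estimated probability that one more sampled clone
#' belongs to an already-observed OTU (f1 = OTUs seen exactly once, N =
#' clones sampled).
#'
#' @param counts Positive integer abundance vector.
#' @return A `diversity_estimate` with value in [0, 1].
#' @examples
#' goods_coverage(c(1, 2, 3))$value  # 1 - 1/6
#' @export
goods_coverage <- function(counts) {
  counts <- .check_counts(counts)
  .estimate("goods_coverage", 1 - .freq_counts(counts, 1) / sum(counts))
}

#' Boneh-style prediction of new OTUs under further sampling
#'
#' Predicts how many additional OTUs would be observed if `m` further clones
#' were sampled from the same community. The unseen-species pool is sized by
#' the bias-corrected Chao term `S0 = f1(f1-1)/(2(f2+1))`, the Good-Turing
#' missing probability mass `f1/N` is split equally across the unseen pool
#' (per-clone rate `mu0 = f1/(N*S0)`), and the prediction is
#' `B(m) = S0 * (1 - (1 - mu0)^m)`. The prediction is 0 at m = 0,
#' non-decreasing in m, 0 when the library has no singleton tail, and
#' saturates at S0. Default `m = N` (a doubling of the library).
#'
#' @param counts Positive integer abundance vector.
#' @param m Number of additional clones (non-negative; default `sum(counts)`).
#' @return A `diversity_estimate`.
#' @export
boneh <- function(counts, m = NULL) {
  counts <- .check_counts(counts)
  n <- sum(counts)
  if (is.null(m)) m <- n
  if (m < 0) stop("m must be non-negative", call. = FALSE)
  f1 <- .freq_counts(counts, 1)
  f2 <- .freq_counts(counts, 2)
  s0 <- f1 * (f1 - 1) / (2 * (f2 + 1))
  value <- if (s0 <= 0 || f1 == 0) 0 else {
    mu0 <- min(1, f1 / (n * s0))
    s0 * (1 - (1 - mu0)^m)
  }
  .estimate("boneh", value, parameters = list(m = m, s0 = s0, f1 = f1))
}

#' Rarefaction curve (expected richness in subsamples)
#'
#' The hypergeometric closed form
#' `E[S(n)] = S_obs - sum_i C(N - n_i, n) / C(N, n)`, evaluated with
#' log-gamma arithmetic (`lchoose`) so no factorial overflows. The curve is
#' non-decreasing in depth, equals 1 at depth 1 and `S_obs` at depth N.
#'
#' @param counts Positive integer abundance vector.
#' @param depths Integer subsample sizes in [1, N]; default `1:N`.
#' @param label Optional library label stored on the result.
#' @return A data frame of class `rarefaction_curve` with columns `depth`
#'   and `richness`.
#' @export
rarefaction <- function(counts, depths = NULL, label = NA_character_) {
  counts <- .check_counts(counts)
  n_total <- sum(counts)
  if (is.null(depths)) depths <- seq_len(n_total)
  if (any(depths < 1 | depths > n_total))
    stop("depths must lie in [1, N]", call. = FALSE)
  s_obs <- length(counts)
  richness <- vapply(depths, function(n) {
    s_obs - sum(exp(lchoose(n_total - counts, n) - lchoose(n_total, n)))
  }, numeric(1))
  structure(data.frame(depth = depths, richness = richness),
            class = c("rarefaction_curve", "data.frame"), label = label)
}

#' Tidy table of diversity estimates per library
#'
#' Applies the requested estimators to each library of an OTU table and
#' returns one row per (library, estimator).
#'
#' @param table An [build_otu_table()] result.
#' @param estimators Character vector among "sobs", "chao1", "ace",
#'   "shannon", "coverage", "boneh".
#' @param boneh_m Additional-clone count for [boneh()] (default: the library
#'   size).
#' @return A data frame with columns `library`, `estimator`, `value`,
#'   `lower`, `upper`.
#' @export
diversity_table <- function(table, estimators = c("sobs", "chao1", "ace",
                                                  "shannon", "coverage",
                                                  "boneh"),
                            boneh_m = NULL) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  abund <- library_abundances(table)
  rows <- list()
  for (lib in names(abund)) {
    v <- abund[[lib]]
    for (e in estimators) {
      est <- switch(e,
        sobs = .estimate("sobs", length(v)),
        chao1 = chao1(v),
        ace = ace(v),
        shannon = shannon(v),
        coverage = goods_coverage(v),
        boneh = boneh(v, m = boneh_m))
      rows[[length(rows) + 1L]] <- data.frame(
        library = lib, estimator = est$estimator, value = est$value,
        lower = est$lower, upper = est$upper, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
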