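# Per-locus diversity statistics and the association tests used in
# collection surveys: PIC = 1 - sum(p_i^2), observed/expected heterozygosity,
# F_S = (H_exp - H_obs)/H_exp and F_ST = (H_T - H_S)/H_T with size-weighted
# H_S and pooled-frequency H_T (the standard G_ST orientation, positive under
# differentiation).

#' Per-locus allele frequencies
#'
#' @param x a [genotype_matrix()].
#' @param samples optional vector of sample ids or indices to restrict to.
#' @return Data frame with one row per locus: `locus`, `p_ref` (frequency of
#'   the reference allele among called copies), `maf`, `n_called` (number of
#'   non-missing diploid genotypes). Loci with no called genotype in the
#'   subset get `NA` frequencies.
#' @export
locus_frequencies <- function(x, samples = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (nrow(d) == 0) stop("empty sample subset", call. = FALSE)
  n_called <- colSums(!is.na(d))
  p_ref <- colSums(d, na.rm = TRUE) / (2 * n_called)
  p_ref[n_called == 0] <- NA_real_
  data.frame(locus = x$locus_ids,
             p_ref = unname(p_ref),
             maf = unname(pmin(p_ref, 1 - p_ref)),
             n_called = unname(n_called),
             row.names = NULL)
}

#' Polymorphism information content
#'
#' `PIC = 1 - sum(p_i^2)` over the allele frequencies of one locus; for a
#' biallelic locus this equals the expected heterozygosity `2p(1-p)`.
#'
#' @param p numeric vector of allele frequencies for one locus (must sum
#'   to 1).
#' @return The PIC value.
#' @export
pic <- function(p) {
  if (any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-9)
    stop("allele frequencies must lie in [0,1] and sum to 1", call. = FALSE)
  1 - sum(p^2)
}

#' Observed and expected heterozygosity at one locus
#'
#' @param x a [genotype_matrix()].
#' @param locus locus id or index.
#' @param samples optional sample subset.
#' @param unbiased apply the small-sample factor `2n/(2n-1)` to `H_exp`.
#' @return Named vector `c(h_obs, h_exp)`: `h_obs` is the fraction of called
#'   genotypes that are heterozygous, `h_exp = 1 - sum(p_i^2)` from the same
#'   subset.
#' @export
heterozygosities <- function(x, locus, samples = NULL, unbiased = FALSE) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.character(locus)) locus <- match(locus, x$locus_ids)
  d <- x$dosage[, locus]
  if (!is.null(samples)) d <- d[samples]
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("no called genotype at locus", call. = FALSE)
  n <- length(d)
  p <- sum(d) / (2 * n)
  h_exp <- 2 * p * (1 - p)
  if (unbiased) h_exp <- h_exp * 2 * n / (2 * n - 1)
  c(h_obs = mean(d == 1L), h_exp = h_exp)
}

#' Within-population fixation index F_S
#'
#' `F_S = (H_exp - H_obs) / H_exp`; negative values indicate heterozygote
#' excess (outbreeding), positive values a heterozygote deficit.
#'
#' @param h_exp,h_obs expected and observed heterozygosity (vectorized).
#' @return `F_S`, `NA` where `h_exp` is 0 (monomorphic; such loci are
#'   excluded from summaries).
#' @export
fixation_fs <- function(h_exp, h_obs) {
  out <- (h_exp - h_obs) / h_exp
  out[h_exp == 0] <- NA_real_
  out
}

#' Among-population differentiation F_ST per locus
#'
#' For each locus, `H_S` is the average within-subpopulation expected
#' heterozygosity weighted by the subpopulation's called-genotype count, and
#' `H_T` the expected heterozygosity of the pooled allele frequencies;
#' `F_ST = (H_T - H_S) / H_T` (non-negative by the Wahlund inequality).
#'
#' @param x a [genotype_matrix()].
#' @param partition named vector (or factor) mapping each sample id to a
#'   subpopulation label; must cover at least two subpopulations.
#' @param unbiased apply the `2n/(2n-1)` factor to each heterozygosity.
#' @return Data frame per locus: `locus`, `h_s`, `h_t`, `f_st`. Loci with
#'   fewer than two subpopulations called, or with `h_t = 0`, get `NA`.
#' @export
fixation_fst <- function(x, partition, unbiased = FALSE) {
  stopifnot(inherits(x, "genotype_matrix"))
  partition <- .check_partition(x, partition)
  groups <- split(seq_along(partition), partition)
  if (length(groups) < 2) stop("need at least 2 subpopulations", call. = FALSE)
  d <- x$dosage
  L <- ncol(d)

  n_s <- sapply(groups, function(ii) colSums(!is.na(d[ii, , drop = FALSE])))
  p_s <- sapply(groups, function(ii) {
    ds <- d[ii, , drop = FALSE]
    colSums(ds, na.rm = TRUE) / (2 * colSums(!is.na(ds)))
  })
  n_s <- matrix(n_s, nrow = L); p_s <- matrix(p_s, nrow = L)
  h_s_mat <- 2 * p_s * (1 - p_s)
  if (unbiased) h_s_mat <- h_s_mat * (2 * n_s) / (2 * n_s - 1)
  h_s_mat[n_s == 0] <- NA_real_

  w <- n_s / rowSums(n_s)
  h_s <- rowSums(w * h_s_mat)

  n_tot <- colSums(!is.na(d))
  p_t <- colSums(d, na.rm = TRUE) / (2 * n_tot)
  h_t <- 2 * p_t * (1 - p_t)
  if (unbiased) h_t <- h_t * (2 * n_tot) / (2 * n_tot - 1)

  ok <- rowSums(n_s > 0) >= 2
  f_st <- ifelse(ok & h_t > 0, (h_t - h_s) / h_t, NA_real_)
  h_s[!ok] <- NA_real_
  data.frame(locus = x$locus_ids, h_s = unname(h_s), h_t = unname(h_t),
             f_st = unname(f_st), row.names = NULL)
}

.check_partition <- function(x, partition) {
  p <- as.character(partition)
  if (!is.null(names(partition))) {
    if (!all(x$sample_ids %in% names(partition)))
      stop("partition must name every sample", call. = FALSE)
    p <- as.character(partition[x$sample_ids])
  } else if (length(p) != length(x$sample_ids)) {
    stop("partition length must equal the number of samples", call. = FALSE)
  }
  p
}

#' Per-locus diversity table
#'
#' One row per locus with allele frequencies, MAF, PIC, observed and expected
#' heterozygosity, `F_S`, and — when a partition is supplied — `H_S`, `H_T`
#' and `F_ST`.
#'
#' @inheritParams fixation_fst
#' @param partition optional subpopulation mapping (see [fixation_fst()]).
#' @return Data frame of per-locus statistics; monomorphic loci carry
#'   `PIC = 0` and `NA` fixation indices.
#' @export
locus_diversity <- function(x, partition = NULL, unbiased = FALSE) {
  fr <- locus_frequencies(x)
  d <- x$dosage
  n_called <- fr$n_called
  h_obs <- colSums(d == 1L, na.rm = TRUE) / n_called
  h_exp <- 2 * fr$p_ref * (1 - fr$p_ref)
  if (unbiased) h_exp <- h_exp * (2 * n_called) / (2 * n_called - 1)
  fr$pic <- 2 * fr$p_ref * (1 - fr$p_ref)
  fr$h_obs <- unname(h_obs)
  fr$h_exp <- h_exp
  fr$f_s <- fixation_fs(h_exp, h_obs)
  if (!is.null(partition)) {
    fst <- fixation_fst(x, partition, unbiased = unbiased)
    fr$h_s <- fst$h_s; fr$h_t <- fst$h_t; fr$f_st <- fst$f_st
  }
  fr
}

# Signed-rank test with the package conventions: zeros dropped, exact
# distribution up to 25 informative values, normal approximation with
# continuity correction above.
.signed_rank <- function(x) {
  x <- x[!is.na(x)]
  x <- x[x != 0]
  n <- length(x)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = 1, n = 0L, degenerate = TRUE))
  ht <- suppressWarnings(wilcox.test(x, mu = 0, exact = n <= 25, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n = n,
       degenerate = FALSE)
}

.rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  exact <- length(x) <= 25 && length(y) <= 25
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Diversity summary for a two-subpopulation partition
#'
#' Computes per-subpopulation medians of expected heterozygosity and `F_S`,
#' the median per-locus `F_ST`, and the three tests usually reported for a
#' two-group collection: one-sample signed-rank of `F_S` against 0 in each
#' subpopulation, rank-sum comparison of `H_exp` between the subpopulations,
#' and one-sample signed-rank of `F_ST` against 0. Monomorphic or uncalled
#' loci are excluded from `F_S`/`F_ST` medians; all tests drop `NA` values
#' and signed-rank tests drop zeros (a fully degenerate test is reported
#' with `p_value = 1` and `degenerate = TRUE`).
#'
#' @inheritParams fixation_fst
#' @return A list of class `partition_summary`: `per_subpop` (data frame of
#'   medians and `F_S` tests), `h_exp_test`, `f_st_median`, `f_st_test`,
#'   and the per-locus table in `loci`.
#' @export
summarize_partition <- function(x, partition, unbiased = FALSE) {
  p <- .check_partition(x, partition)
  labs <- sort(unique(p))
  if (length(labs) != 2)
    stop("summarize_partition expects exactly 2 subpopulations", call. = FALSE)

  per <- lapply(labs, function(lab) {
    idx <- which(p == lab)
    ld <- locus_diversity(x[idx, ], unbiased = unbiased)
    ld
  })
  names(per) <- labs

  n_inf <- min(sapply(per, function(ld) sum(!is.na(ld$f_s))))
  if (n_inf < 6)
    warning("fewer than 6 informative loci; tests unreliable")

  per_subpop <- do.call(rbind, lapply(labs, function(lab) {
    ld <- per[[lab]]
    ts <- .signed_rank(ld$f_s)
    data.frame(subpop = lab,
               n_samples = sum(p == lab),
               median_h_exp = median(ld$h_exp, na.rm = TRUE),
               median_f_s = median(ld$f_s, na.rm = TRUE),
               f_s_statistic = ts$statistic, f_s_p_value = ts$p_value,
               f_s_degenerate = ts$degenerate, row.names = NULL)
  }))

  h_test <- .rank_sum(per[[1]]$h_exp, per[[2]]$h_exp)
  fst <- fixation_fst(x, p, unbiased = unbiased)
  fst_test <- .signed_rank(fst$f_st)

  structure(list(
    per_subpop = per_subpop,
    h_exp_test = h_test,
    f_st_median = median(fst$f_st, na.rm = TRUE),
    f_st_test = fst_test,
    loci = locus_diversity(x, partition = p, unbiased = unbiased)),
    class = "partition_summary")
}

#' @method print partition_summary
#' @export
print.partition_summary <- function(x, ...) {
  cat("Two-subpopulation diversity summary\n")
  print(x$per_subpop, digits = 3)
  cat(sprintf("H_exp rank-sum p = %.3g\n", x$h_exp_test$p_value))
  cat(sprintf("median F_ST = %.3f (signed-rank p = %.3g)\n",
              x$f_st_median, x$f_st_test$p_value))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by full enumeration of the hypergeometric support
#' at the observed margins: the sum of the probabilities of all tables no
#' more probable than the observed one.
#'
#' @param tab 2x2 matrix (or something coercible) of non-negative integer
#'   counts.
#' @return List with `p_value`, the observed table probability `p_obs`, and
#'   `degenerate` (`TRUE` when a margin is zero, in which case `p_value = 1`
#'   by convention).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0)
    return(list(p_value = 1, p_obs = 1, degenerate = TRUE))
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(1, p), p_obs = p_obs, degenerate = FALSE)
}

#' Pearson chi-square homogeneity / goodness-of-fit test
#'
#' With `expected_props`, tests an observed count vector against stated
#' proportions (`df = cells - 1`); with `observed2`, tests homogeneity of two
#' count vectors via the usual two-row contingency table
#' (`df = cells - 1`). Statistic is `sum((O - E)^2 / E)` with the upper-tail
#' chi-square p-value.
#'
#' @param observed vector of non-negative counts.
#' @param expected_props proportions summing to 1 (one of `expected_props`
#'   and `observed2` must be given).
#' @param observed2 second count vector for a homogeneity test.
#' @param df optional expected degrees of freedom; an error is raised when it
#'   does not match the table shape.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_homogeneity <- function(observed, expected_props = NULL,
                                   observed2 = NULL, df = NULL) {
  if (is.null(expected_props) == is.null(observed2))
    stop("supply exactly one of expected_props or observed2", call. = FALSE)
  if (!is.null(expected_props)) {
    if (length(expected_props) != length(observed))
      stop("expected_props length mismatch", call. = FALSE)
    expected <- sum(observed) * expected_props
    if (any(expected <= 0)) stop("expected cell counts must be > 0", call. = FALSE)
    stat <- sum((observed - expected)^2 / expected)
    df_used <- length(observed) - 1L
  } else {
    if (length(observed2) != length(observed))
      stop("count vectors must have equal length", call. = FALSE)
    tab <- rbind(observed, observed2)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected <= 0)) stop("expected cell counts must be > 0", call. = FALSE)
    stat <- sum((tab - expected)^2 / expected)
    df_used <- ncol(tab) - 1L
  }
  if (!is.null(df) && df != df_used)
    stop("stated df (", df, ") does not match table shape (df = ",
         df_used, ")", call. = FALSE)
  list(statistic = stat, df = df_used,
       p_value = stats::pchisq(stat, df_used, lower.tail = FALSE))
}

#' Write a per-locus statistics table as TSV
#'
#' @param loci data frame from [locus_diversity()].
#' @param file output path.
#' @export
write_locus_stats <- function(loci, file) {
  utils::write.table(loci, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
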