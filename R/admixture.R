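# Maximum-likelihood admixture model: each individual's genome is a mixture
# Q[i, ] over K ancestral populations with reference-allele frequencies
# P[k, l]; the diploid dosage likelihood is fitted by EM with multiple random
# restarts, and the number of populations is selected by the Evanno
# second-difference statistic on the restart log-likelihoods.

#' Admixture model log-likelihood
#'
#' `sum over called (i,l) of g*log(sum_k q_ik p_kl) +
#' (2-g)*log(sum_k q_ik (1-p_kl))`. Missing dosages contribute 0.
#'
#' @param G integer matrix of reference-allele dosages (samples x loci,
#'   0/1/2, `NA` missing) or a [genotype_matrix()].
#' @param Q samples x K ancestry proportions (rows on the simplex).
#' @param P K x loci reference-allele frequencies in `(0, 1)`.
#' @return The log-likelihood; `-Inf` (with attribute `zero_prob = TRUE`)
#'   when a mixture probability is 0 where the data demand a positive one.
#' @export
admixture_loglik <- function(G, Q, P) {
  G <- .dosage_of(G)
  Q <- as.matrix(Q); P <- as.matrix(P)
  if (nrow(Q) != nrow(G) || ncol(P) != ncol(G) || ncol(Q) != nrow(P))
    stop("dimension mismatch between G, Q and P", call. = FALSE)
  if (any(Q < 0) || any(abs(rowSums(Q) - 1) > 1e-6))
    stop("Q rows must be ancestry proportions on the simplex", call. = FALSE)
  f <- Q %*% P
  called <- !is.na(G)
  g <- G[called]; fv <- f[called]
  bad <- (fv <= 0 & g > 0) | (fv >= 1 & g < 2)
  if (any(bad)) {
    out <- -Inf
    attr(out, "zero_prob") <- TRUE
    return(out)
  }
  sum(ifelse(g > 0, g * log(fv), 0) + ifelse(g < 2, (2 - g) * log1p(-fv), 0))
}

.dosage_of <- function(G) {
  if (inherits(G, "genotype_matrix")) G <- G$dosage
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  G
}

#' Fit the admixture model by EM with random restarts
#'
#' E-step responsibilities split each called allele copy over the K ancestral
#' populations; the M-step renormalizes ancestry rows and allele frequencies.
#' Restarts draw `Q` rows from a symmetric Dirichlet(1) and `P` from
#' Uniform(0.05, 0.95), with per-restart seeds derived from `seed`.
#' `K = 1` is solved in closed form (observed allele frequencies).
#'
#' @inheritParams admixture_loglik
#' @param K number of ancestral populations.
#' @param restarts number of random restarts.
#' @param seed master integer seed.
#' @param tol stop when the per-iteration log-likelihood gain drops below
#'   this.
#' @param max_iter iteration cap per restart.
#' @return Object of class `admixture_fit`: `Q`, `P`, `loglik`, `trace`
#'   (per-iteration log-likelihoods of the best restart), `n_iter`,
#'   `converged`, `K`, `restart_logliks`, `restart_seed` (seed of the best
#'   restart), `degenerate` (`TRUE` when some ancestry column of the best
#'   fit is empty).
#' @export
fit_admixture <- function(G, K, restarts = 20, seed = NULL,
                          tol = 1e-6, max_iter = 2000) {
  G <- .dosage_of(G)
  n <- nrow(G); L <- ncol(G)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (K > n) stop("K cannot exceed the number of samples", call. = FALSE)
  if (any(rowSums(!is.na(G)) == 0))
    stop("every sample needs at least one called locus", call. = FALSE)

  if (K == 1) {
    p <- colSums(G, na.rm = TRUE) / (2 * colSums(!is.na(G)))
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    Q <- matrix(1, n, 1, dimnames = list(rownames(G), NULL))
    P <- matrix(p, 1, L, dimnames = list(NULL, colnames(G)))
    ll <- admixture_loglik(G, Q, P)
    return(structure(list(Q = Q, P = P, loglik = ll, trace = ll,
                          n_iter = 0L, converged = TRUE, K = 1L,
                          restart_logliks = rep(ll, restarts),
                          restart_seed = NA_integer_, degenerate = FALSE),
                     class = "admixture_fit"))
  }

  if (!is.null(seed)) set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max - 1L, restarts)
  best <- NULL
  lls <- numeric(restarts)
  for (r in seq_len(restarts)) {
    set.seed(restart_seeds[r])
    Q0 <- matrix(rgamma(n * K, 1), n, K)
    Q0 <- Q0 / rowSums(Q0)
    P0 <- matrix(runif(K * L, 0.05, 0.95), K, L)
    fit <- em_admixture_cpp(G, Q0, P0, tol, as.integer(max_iter), 1e-6)
    lls[r] <- fit$loglik
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit
      best$restart_seed <- restart_seeds[r]
    }
  }
  dimnames(best$Q) <- list(rownames(G), NULL)
  dimnames(best$P) <- list(NULL, colnames(G))
  structure(list(Q = best$Q, P = best$P, loglik = best$loglik,
                 trace = best$trace, n_iter = best$n_iter,
                 converged = best$converged, K = as.integer(K),
                 restart_logliks = lls, restart_seed = best$restart_seed,
                 degenerate = any(colSums(best$Q) / n < 1e-6)),
            class = "admixture_fit")
}

#' @method print admixture_fit
#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K = %d, loglik = %.2f (%d iterations%s)\n",
              x$K, x$loglik, x$n_iter,
              if (x$converged) ", converged" else ", NOT converged"))
  if (x$degenerate) cat("  warning: empty ancestry component\n")
  invisible(x)
}

#' Evanno delta-K table
#'
#' `delta_K(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))` with
#' the sample standard deviation across restarts; defined only for interior
#' K with `sd > 0`. The selected K maximizes delta-K; ties break to the
#' smallest K (parsimony) and are flagged.
#'
#' @param logliks named list (names = K values, consecutive, length >= 3) of
#'   numeric restart log-likelihood vectors (>= 2 restarts each), or a
#'   restarts x K matrix with K values as column names.
#' @return Data frame of class `evanno_k`: `K`, `mean_loglik`, `sd_loglik`,
#'   `delta_k`; attributes `selected_k`, `tie` and `undefined` (K values
#'   where `sd = 0`).
#' @export
evanno_delta_k <- function(logliks) {
  if (is.matrix(logliks))
    logliks <- setNames(lapply(seq_len(ncol(logliks)), function(j) logliks[, j]),
                        colnames(logliks))
  Ks <- as.integer(names(logliks))
  if (any(is.na(Ks)) || !all(diff(Ks) == 1))
    stop("logliks must be named by consecutive K values", call. = FALSE)
  if (length(Ks) < 3) stop("need at least 3 consecutive K values", call. = FALSE)
  if (any(lengths(logliks) < 2)) stop("need >= 2 restarts per K", call. = FALSE)

  mu <- vapply(logliks, mean, 0)
  sdv <- vapply(logliks, sd, 0)
  dk <- rep(NA_real_, length(Ks))
  interior <- seq(2, length(Ks) - 1)
  dk[interior] <- abs(mu[interior + 1] - 2 * mu[interior] + mu[interior - 1]) /
    sdv[interior]
  undefined <- Ks[interior][sdv[interior] == 0]
  dk[!is.finite(dk)] <- NA_real_
  if (all(is.na(dk)))
    stop("delta-K undefined at every interior K (zero restart spread)",
         call. = FALSE)
  best <- max(dk, na.rm = TRUE)
  cand <- Ks[which(!is.na(dk) & dk == best)]
  out <- data.frame(K = Ks, mean_loglik = unname(mu), sd_loglik = unname(sdv),
                    delta_k = dk, row.names = NULL)
  attr(out, "selected_k") <- min(cand)
  attr(out, "tie") <- length(cand) > 1
  attr(out, "undefined") <- undefined
  class(out) <- c("evanno_k", "data.frame")
  out
}

#' @method print evanno_k
#' @export
print.evanno_k <- function(x, ...) {
  print.data.frame(x, digits = 4)
  cat(sprintf("selected K = %d%s\n", attr(x, "selected_k"),
              if (isTRUE(attr(x, "tie"))) " (tie, smallest taken)" else ""))
  invisible(x)
}

#' Scan K and select the number of subpopulations
#'
#' Fits the admixture model for each K in `k_values` with `restarts` random
#' restarts and applies [evanno_delta_k()] to the restart log-likelihoods.
#'
#' @inheritParams fit_admixture
#' @param k_values consecutive K values to scan (default 1:6).
#' @return List of class `admixture_scan`: `fits` (best fit per K),
#'   `logliks` (restarts x K matrix), `evanno` (the [evanno_delta_k()]
#'   table), `selected_k`.
#' @export
admixture_scan <- function(G, k_values = 1:6, restarts = 20, seed = NULL,
                           tol = 1e-6, max_iter = 2000) {
  G <- .dosage_of(G)
  if (!is.null(seed)) set.seed(seed)
  k_seeds <- sample.int(.Machine$integer.max - 1L, length(k_values))
  fits <- vector("list", length(k_values))
  lls <- matrix(NA_real_, restarts, length(k_values),
                dimnames = list(NULL, k_values))
  for (i in seq_along(k_values)) {
    fits[[i]] <- fit_admixture(G, k_values[i], restarts = restarts,
                               seed = k_seeds[i], tol = tol,
                               max_iter = max_iter)
    lls[, i] <- fits[[i]]$restart_logliks
  }
  names(fits) <- k_values
  ev <- evanno_delta_k(lls)
  structure(list(fits = fits, logliks = lls, evanno = ev,
                 selected_k = attr(ev, "selected_k")),
            class = "admixture_scan")
}

#' @method print admixture_scan
#' @export
print.admixture_scan <- function(x, ...) {
  print(x$evanno)
  invisible(x)
}

#' Match ancestry columns to a reference up to label switching
#'
#' Permutes the columns of `Q` to minimize the mean absolute error against
#' `Q_ref` (exhaustive over permutations; K is small).
#'
#' @param Q,Q_ref samples x K ancestry matrices.
#' @return List with the permuted `Q`, the permutation used and the
#'   resulting `mae`.
#' @export
match_ancestry <- function(Q, Q_ref) {
  K <- ncol(Q)
  stopifnot(ncol(Q_ref) == K, K <= 7)
  perms <- .permutations(K)
  maes <- apply(perms, 1, function(pp) mean(abs(Q[, pp] - Q_ref)))
  best <- which.min(maes)
  list(Q = Q[, perms[best, ], drop = FALSE], perm = perms[best, ],
       mae = maes[best])
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1)
  out <- do.call(rbind, lapply(seq_len(k), function(pos) {
    cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
          sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
  }))
  storage.mode(out) <- "integer"
  out
}

#' Write an ancestry matrix
#'
#' Whitespace-delimited table (id, assigned cluster = argmax Q, q_1..q_K)
#' plus an optional CSV copy.
#'
#' @param fit an `admixture_fit`.
#' @param file output path.
#' @param csv optional path for a CSV copy.
#' @export
write_q_matrix <- function(fit, file, csv = NULL) {
  stopifnot(inherits(fit, "admixture_fit"))
  df <- data.frame(id = rownames(fit$Q),
                   cluster = max.col(fit$Q, ties.method = "first"),
                   round(fit$Q, 6))
  names(df)[-(1:2)] <- paste0("q_", seq_len(ncol(fit$Q)))
  utils::write.table(df, file, quote = FALSE, row.names = FALSE)
  if (!is.null(csv)) write.csv(df, csv, row.names = FALSE, quote = FALSE)
  invisible(file)
}
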