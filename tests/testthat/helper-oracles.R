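# Independent oracles used across the suite. These deliberately use
# different algorithms (regex engines, exhaustive enumeration, naive loops)
# than the package implementations they check.

# --- Fisher 2x2: exhaustive enumeration with choose() arithmetic ----------
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  denom <- choose(N, c1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / denom
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / denom
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- SSR brute force: regex per unit length -------------------------------
oracle_scan_ssrs <- function(s, min_repeats = c(`1` = 10, `2` = 6, `3` = 5,
                                                `4` = 5, `5` = 5, `6` = 5)) {
  s <- toupper(s)
  is_periodic <- function(motif) {
    k <- nchar(motif)
    any(vapply(seq_len(k - 1), function(d) {
      k %% d == 0 && motif == strrep(substr(motif, 1, d), k / d)
    }, TRUE))
  }
  out <- list()
  for (k in 1:6) {
    mr <- min_repeats[[as.character(k)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, mr - 1)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (idx in seq_along(m)) {
      start <- m[idx]
      len <- attr(m, "match.length")[idx]
      count <- len %/% k
      motif <- substr(s, start, start + k - 1)
      if (is_periodic(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        start = start, end = start + k * count - 1L,
        motif = motif, repeat_count = count)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), repeat_count = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, nchar(res$motif)), , drop = FALSE]
}

# --- longest ORF: per-start codon walk (vs the stop-partition scan) -------
oracle_longest_orf <- function(s, min_aa = 67, both_strands = TRUE) {
  s <- toupper(s)
  scan1 <- function(seq) {
    nc <- nchar(seq)
    best <- NULL
    for (start in seq_len(max(0, nc - 5))) {
      if (substr(seq, start, start + 2) != "ATG") next
      pos <- start + 3
      while (pos + 2 <= nc) {
        cod <- substr(seq, pos, pos + 2)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          aa <- (pos - start - 3) / 3
          if (aa >= min_aa && (is.null(best) || aa > best$aa))
            best <- list(start = start, end = pos + 2, aa = aa)
          break
        }
        pos <- pos + 3
      }
    }
    best
  }
  revcomp <- function(x)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  fwd <- scan1(s)
  hit <- if (!is.null(fwd))
    list(start = fwd$start, end = fwd$end, strand = "+", length_aa = fwd$aa)
  else NULL
  if (both_strands) {
    rv <- scan1(revcomp(s))
    if (!is.null(rv) && (is.null(hit) || rv$aa > hit$length_aa)) {
      nc <- nchar(s)
      hit <- list(start = nc - rv$end + 1, end = nc - rv$start + 1,
                  strand = "-", length_aa = rv$aa)
    }
  }
  hit
}

# --- PSA distance: naive per-pair double loop -----------------------------
oracle_distance_matrix <- function(gm) {
  d <- gm$dosage
  n <- nrow(d)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(d[i, ]) & !is.na(d[j, ])
      ps <- 0
      for (l in which(ok)) {
        gi <- d[i, l]; gj <- d[j, l]
        # multiset intersection of {ref x gi, alt x (2-gi)} with sample j
        ps <- ps + min(gi, gj) + min(2 - gi, 2 - gj)
      }
      D[i, j] <- D[j, i] <- 1 - ps / (2 * sum(ok))
    }
  }
  D
}

# --- Ward: greedy minimum-variance merges from the set-based formula ------
# Merge cost 2 * |A||B|/(|A|+|B|) * ||cA - cB||^2 computed directly from the
# squared-distance sums (algebraically what the Lance-Williams ward.D2
# recursion tracks); returns the merge sequence as leaf-set lists.
oracle_ward_merges <- function(D) {
  D2 <- as.matrix(D)^2
  clusters <- as.list(seq_len(nrow(D2)))
  merges <- list()
  cost <- function(A, B) {
    TAB <- sum(D2[A, B, drop = FALSE])
    TAA <- sum(D2[A, A, drop = FALSE])
    TBB <- sum(D2[B, B, drop = FALSE])
    nA <- length(A); nB <- length(B)
    cc <- TAB / (nA * nB) - TAA / (2 * nA^2) - TBB / (2 * nB^2)
    2 * nA * nB / (nA + nB) * cc
  }
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        cc <- cost(clusters[[i]], clusters[[j]])
        if (cc < best - 1e-12) { best <- cc; bi <- i; bj <- j }
      }
    }
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    merges[[length(merges) + 1L]] <-
      list(set = merged, height = sqrt(best))
    clusters[[bi]] <- merged
    clusters[[bj]] <- NULL
  }
  merges
}

# leaf sets of every merge of an hclust object
hclust_merge_sets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  for (m in seq_len(nrow(tree$merge))) {
    get <- function(v) if (v < 0) -v else sets[[v]]
    sets[[m]] <- sort(c(get(tree$merge[m, 1]), get(tree$merge[m, 2])))
  }
  sets
}

# --- admixture loglik: three nested loops ---------------------------------
oracle_admixture_loglik <- function(G, Q, P) {
  ll <- 0
  for (i in seq_len(nrow(G))) {
    for (l in seq_len(ncol(G))) {
      g <- G[i, l]
      if (is.na(g)) next
      f <- 0
      for (k in seq_len(ncol(Q))) f <- f + Q[i, k] * P[k, l]
      ll <- ll + g * log(f) + (2 - g) * log(1 - f)
    }
  }
  ll
}

# --- misc helpers ---------------------------------------------------------
random_genotypes <- function(n, L, miss = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  d[matrix(runif(n * L) < miss, n, L)] <- NA
  genotype_matrix(d, rep("A", L), rep("G", L))
}

# partition agreement up to label swapping (two groups)
same_partition <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  all(a == b) || all(a == 3L - b)
}
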