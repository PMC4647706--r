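# Proportion-of-shared-alleles distances, Ward dendrograms with a fixed
# tie-break, locus-bootstrap branch support and tree cutting.
#
# For two diploid genotypes at the same biallelic locus with reference-allele
# dosages g_i, g_j, the number of shared alleles (multiset intersection) is
# PS = 2 - |g_i - g_j|; PSA = sum(PS) / (2 * L) over jointly called loci and
# D = 1 - PSA.

#' Proportion of shared alleles between two samples
#'
#' @param d_i,d_j per-locus reference-allele dosage vectors (0/1/2, `NA`
#'   missing) for the two samples, aligned on the same loci.
#' @return List with `psa` and `l_used` (count of jointly called loci).
#'   Loci missing in either sample are excluded (pairwise deletion).
#' @export
psa_pair <- function(d_i, d_j) {
  if (length(d_i) != length(d_j)) stop("dosage vectors differ in length", call. = FALSE)
  ok <- !is.na(d_i) & !is.na(d_j)
  L <- sum(ok)
  if (L == 0) stop("no jointly called locus for this pair", call. = FALSE)
  ps <- 2L - abs(d_i[ok] - d_j[ok])
  list(psa = sum(ps) / (2 * L), l_used = L)
}

#' Shared-allele distance matrix
#'
#' Computes `D = 1 - PSA` for all sample pairs with pairwise deletion of
#' missing loci.
#'
#' @param x a [genotype_matrix()] (typically after [apply_qc()]).
#' @return Object of class `shared_allele_dist`: list with the symmetric
#'   distance matrix `D` (zero diagonal, entries in `[0, 1]`), `L_used`
#'   (per-pair jointly called locus counts) and `sample_ids`.
#' @export
shared_allele_dist <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosage
  called <- !is.na(d)
  # sum over jointly called loci of |g_i - g_j| via indicator cross-products
  I <- lapply(0:2, function(g) {
    m <- (d == g) & called
    storage.mode(m) <- "double"
    m
  })
  abs_sum <- tcrossprod(I[[1]], I[[2]]) + tcrossprod(I[[2]], I[[1]]) +
    tcrossprod(I[[2]], I[[3]]) + tcrossprod(I[[3]], I[[2]]) +
    2 * (tcrossprod(I[[1]], I[[3]]) + tcrossprod(I[[3]], I[[1]]))
  storage.mode(called) <- "double"
  L_used <- tcrossprod(called)
  if (any(L_used[upper.tri(L_used)] == 0))
    stop("sample pair(s) with no jointly called locus", call. = FALSE)
  D <- abs_sum / (2 * L_used)
  diag(D) <- 0
  dimnames(D) <- dimnames(L_used) <- list(x$sample_ids, x$sample_ids)
  structure(list(D = D, L_used = L_used, sample_ids = x$sample_ids),
            class = "shared_allele_dist")
}

#' @export
as.dist.shared_allele_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$D, diag = diag, upper = upper)
}

#' @method print shared_allele_dist
#' @export
print.shared_allele_dist <- function(x, ...) {
  cat(sprintf("<shared_allele_dist> %d samples, D in [%.3f, %.3f]\n",
              length(x$sample_ids), min(x$D[upper.tri(x$D)]),
              max(x$D[upper.tri(x$D)])))
  invisible(x)
}

#' Write a distance matrix as TSV or PHYLIP square format
#'
#' @param dm a [shared_allele_dist()] object or square matrix.
#' @param file output path.
#' @param format `"tsv"` (header + row names) or `"phylip"` (square).
#' @export
write_distance_matrix <- function(dm, file, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  D <- if (inherits(dm, "shared_allele_dist")) dm$D else as.matrix(dm)
  if (format == "tsv") {
    utils::write.table(data.frame(sample = rownames(D), D, check.names = FALSE),
                       file, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(file, "w"); on.exit(close(con))
    writeLines(sprintf("%d", nrow(D)), con)
    for (i in seq_len(nrow(D)))
      writeLines(paste(c(rownames(D)[i], sprintf("%.6f", D[i, ])),
                       collapse = "  "), con)
  }
  invisible(file)
}

#' Ward minimum-variance dendrogram
#'
#' Agglomerative clustering under Ward's criterion applied to the raw
#' dissimilarities (the `ward.D2` convention): the Lance--Williams recursion
#' runs on squared dissimilarities and merge heights are reported on the
#' original scale. Ties in merge cost are broken deterministically by the
#' smallest pair of cluster slot indices (singletons occupy slots in input
#' order; a merged cluster inherits the lower slot), so the tree is
#' reproducible across platforms.
#'
#' @param d a [shared_allele_dist()] object, a `dist`, or a symmetric
#'   non-negative matrix.
#' @return An object of class `hclust` (usable with [stats::cutree()],
#'   [ape::as.phylo()], `plot()`, ...).
#' @export
ward_tree <- function(d) {
  D <- if (inherits(d, "shared_allele_dist")) d$D else as.matrix(d)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(D < 0)) stop("distances must be non-negative", call. = FALSE)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))

  S <- D^2                       # Lance-Williams state on squared scale
  diag(S) <- Inf
  size <- rep(1L, n)
  code <- -seq_len(n)            # hclust coding: negative leaf, positive merge
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (m in seq_len(n - 1)) {
    Sm <- S
    Sm[!active, ] <- Inf; Sm[, !active] <- Inf
    Sm[lower.tri(Sm, diag = TRUE)] <- Inf
    best <- min(Sm)
    cand <- which(Sm == best, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]

    height[m] <- sqrt(best)
    pair <- sort(c(code[i], code[j]))
    if (pair[1] < 0 && pair[2] < 0) pair <- sort(abs(pair)) * -1L  # (-a,-b), a<b
    merge[m, ] <- pair

    # Lance-Williams Ward update into slot i
    k <- which(active & seq_len(n) != i & seq_len(n) != j)
    if (length(k)) {
      S[i, k] <- ((size[i] + size[k]) * S[i, k] + (size[j] + size[k]) * S[j, k] -
                    size[k] * best) / (size[i] + size[j] + size[k])
      S[k, i] <- S[i, k]
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    code[i] <- m
  }

  order <- .hclust_order(merge, n)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "ward.D2",
                 call = match.call(), dist.method = "shared_allele"),
            class = "hclust")
}

# leaf ordering by iterative traversal of the merge tree
.hclust_order <- function(merge, n) {
  stack <- list(nrow(merge))
  out <- integer(0)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (node < 0) {
      out <- c(out, -node)
    } else {
      stack[[length(stack) + 1L]] <- merge[node, 2]
      stack[[length(stack) + 1L]] <- merge[node, 1]
    }
  }
  out
}

# Canonical bipartition keys for each merge of an hclust tree: the leaf set
# of the cluster, flipped to the side NOT containing leaf 1 so the key is
# root-invariant. Trivial bipartitions (|S| < 2 or |S| > n-2) get NA.
.bipartition_keys <- function(merge, n) {
  sets <- vector("list", nrow(merge))
  keys <- rep(NA_character_, nrow(merge))
  for (m in seq_len(nrow(merge))) {
    get <- function(v) if (v < 0) -v else sets[[v]]
    s <- sort(c(get(merge[m, 1]), get(merge[m, 2])))
    sets[[m]] <- s
    size <- length(s)
    if (size >= 2 && size <= n - 2) {
      side <- if (1L %in% s) setdiff(seq_len(n), s) else s
      keys[m] <- paste(side, collapse = ",")
    }
  }
  keys
}

#' Locus-bootstrap support for a Ward dendrogram
#'
#' Builds the reference Ward tree from all loci, then for each bootstrap
#' replicate resamples loci with replacement, recomputes the shared-allele
#' distances and the Ward tree, and scores every internal bipartition of the
#' reference tree by the percentage of replicate trees containing the same
#' unordered leaf-set split (heights ignored). Replicates in which some
#' sample pair has no jointly called locus are redrawn and counted.
#'
#' @param x a [genotype_matrix()].
#' @param n_boot number of bootstrap replicates (0 returns the reference
#'   tree with no supports).
#' @param seed integer seed; one master seed drives a pre-drawn per-replicate
#'   seed stream, so results are reproducible.
#' @return Object of class `boot_dendrogram`: list with `tree` (`hclust`),
#'   `supports` (data frame `merge`, `size`, `support`; `NA` support on
#'   trivial bipartitions), `n_boot`, `n_redrawn`.
#' @export
bootstrap_supports <- function(x, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  ref <- ward_tree(shared_allele_dist(x))
  n <- length(ref$labels)
  sets <- vector("list", n - 1)
  for (m in seq_len(n - 1)) {
    get <- function(v) if (v < 0) -v else sets[[v]]
    sets[[m]] <- sort(c(get(ref$merge[m, 1]), get(ref$merge[m, 2])))
  }
  sizes <- lengths(sets)
  keys <- .bipartition_keys(ref$merge, n)
  out <- list(tree = ref,
              supports = data.frame(merge = seq_len(n - 1), size = sizes,
                                    support = NA_real_),
              n_boot = n_boot, n_redrawn = 0L)
  class(out) <- "boot_dendrogram"
  if (n_boot == 0) return(out)

  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_boot)
  L <- ncol(x$dosage)
  hits <- setNames(numeric(sum(!is.na(keys))), keys[!is.na(keys)])
  redrawn <- 0L
  done <- 0L
  stream <- 0L
  while (done < n_boot) {
    stream <- stream + 1L
    if (stream > length(rep_seeds))
      stop("too many degenerate bootstrap replicates", call. = FALSE)
    set.seed(rep_seeds[stream])
    idx <- sample.int(L, L, replace = TRUE)
    db <- x$dosage[, idx, drop = FALSE]
    colnames(db) <- sprintf("b%d", seq_along(idx))  # resampled loci repeat
    xb <- genotype_matrix(db, x$ref[idx], x$alt[idx])
    db <- tryCatch(shared_allele_dist(xb), error = function(e) NULL)
    if (is.null(db)) { redrawn <- redrawn + 1L; next }
    tb <- ward_tree(db)
    kb <- .bipartition_keys(tb$merge, n)
    found <- intersect(names(hits), kb)
    hits[found] <- hits[found] + 1
    done <- done + 1L
  }
  sup <- rep(NA_real_, n - 1)
  sup[!is.na(keys)] <- 100 * hits[keys[!is.na(keys)]] / n_boot
  out$supports$support <- sup
  out$n_redrawn <- redrawn
  out
}

#' @method print boot_dendrogram
#' @export
print.boot_dendrogram <- function(x, ...) {
  cat(sprintf("<boot_dendrogram> %d leaves, %d replicates (%d redrawn)\n",
              length(x$tree$labels), x$n_boot, x$n_redrawn))
  s <- x$supports$support
  if (any(!is.na(s)))
    cat(sprintf("  internal bipartition support: min %.0f / median %.0f / max %.0f\n",
                min(s, na.rm = TRUE), median(s, na.rm = TRUE), max(s, na.rm = TRUE)))
  invisible(x)
}

#' Cut a dendrogram into k subpopulations
#'
#' Cuts at the height giving exactly `k` clusters and relabels clusters
#' stably: label 1 is the largest cluster (ties broken by the smallest
#' member index). Labels are arbitrary but reproducible; no orientation with
#' respect to any published grouping is implied.
#'
#' @param tree an `hclust` tree (e.g. from [ward_tree()]) or a
#'   `boot_dendrogram`.
#' @param k number of clusters, `1 <= k <= n`.
#' @return Named integer vector mapping each sample to a cluster label.
#' @export
cut_partitions <- function(tree, k) {
  if (inherits(tree, "boot_dendrogram")) tree <- tree$tree
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must be between 1 and n", call. = FALSE)
  cl <- cutree(tree, k = k)
  tab <- table(cl)
  first_member <- sapply(names(tab), function(g) min(which(cl == g)))
  ord <- order(-as.integer(tab), first_member)
  relabel <- setNames(seq_along(ord), names(tab)[ord])
  out <- relabel[as.character(cl)]
  names(out) <- tree$labels
  out
}

#' Write a dendrogram as newick
#'
#' Bootstrap supports (rounded percentages) become internal-node labels.
#'
#' @param tree a `boot_dendrogram` or `hclust`.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, file) {
  supports <- NULL
  if (inherits(tree, "boot_dendrogram")) {
    supports <- tree$supports
    tree <- tree$tree
  }
  phy <- ape::as.phylo(tree)
  if (!is.null(supports)) {
    n <- length(phy$tip.label)
    keys <- .bipartition_keys(tree$merge, n)
    lookup <- setNames(supports$support, keys)
    parts <- ape::prop.part(phy)
    lab_order <- match(tree$labels, phy$tip.label)
    node_lab <- character(phy$Nnode)
    for (i in seq_along(parts)) {
      tips <- sort(match(phy$tip.label[parts[[i]]], tree$labels))
      key <- if (1L %in% tips)
        paste(setdiff(seq_len(n), tips), collapse = ",") else
          paste(tips, collapse = ",")
      s <- lookup[key]
      node_lab[i] <- if (!is.na(s)) sprintf("%.0f", s) else ""
    }
    phy$node.label <- node_lab
  }
  ape::write.tree(phy, file = file)
  invisible(file)
}
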