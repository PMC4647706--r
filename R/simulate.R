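# Synthetic-data generators with exact ground truth.
#
# Genotype collections follow the Balding-Nichols construction: ancestral
# allele frequencies are Uniform(0.05, 0.95); each subpopulation draws its
# frequency from Beta(p(1-F)/F, (1-p)(1-F)/F), whose expected differentiation
# equals F; individuals are pure or Dirichlet-admixed mixtures of the
# subpopulations, and dosages are Binomial(2, q %*% p).

#' Define a genotype-collection scenario
#'
#' @param n_samples number of accessions.
#' @param n_loci number of biallelic SNP loci.
#' @param K number of ancestral subpopulations.
#' @param fst Balding-Nichols differentiation parameter `F`, in `(0, 1)`;
#'   `F = 0` is rejected as degenerate (simulate identical frequencies
#'   explicitly if that is wanted).
#' @param admixed_fraction fraction of samples whose ancestry is drawn from
#'   a Dirichlet rather than being pure.
#' @param admix_alpha Dirichlet concentration vector (recycled to length K)
#'   for admixed samples.
#' @param missing_rate baseline per-call no-call probability, in `[0, 1)`.
#' @param n_high_missing_samples,n_high_missing_loci number of samples/loci
#'   deliberately planted with elevated missingness (for QC testing).
#' @param high_missing_rate the elevated no-call probability.
#' @param name scenario label.
#' @return A list of class `collection_scenario`.
#' @export
collection_scenario <- function(n_samples = 74, n_loci = 239, K = 2,
                                fst = 0.03, admixed_fraction = 0.2,
                                admix_alpha = 0.5, missing_rate = 0.05,
                                n_high_missing_samples = 0,
                                n_high_missing_loci = 0,
                                high_missing_rate = 0.5,
                                name = "custom") {
  if (fst <= 0 || fst >= 1)
    stop("fst must lie strictly in (0, 1); F = 0 is a degenerate scenario",
         call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (admixed_fraction < 0 || admixed_fraction > 1)
    stop("admixed_fraction must lie in [0, 1]", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_loci = as.integer(n_loci), K = as.integer(K), fst = fst,
                 admixed_fraction = admixed_fraction,
                 admix_alpha = rep_len(admix_alpha, K),
                 missing_rate = missing_rate,
                 n_high_missing_samples = as.integer(n_high_missing_samples),
                 n_high_missing_loci = as.integer(n_high_missing_loci),
                 high_missing_rate = high_missing_rate,
                 name = name),
            class = "collection_scenario")
}

#' Read a collection scenario from JSON
#'
#' @param file JSON path with fields named as in [collection_scenario()].
#' @return A `collection_scenario`.
#' @export
read_collection_scenario <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(collection_scenario, x)
}

#' The shipped two-subpopulation reference scenario
#'
#' 74 accessions x 239 loci, two subpopulations at Balding-Nichols `F =
#' 0.03`, 20\% of samples admixed with Dirichlet(0.5, 0.5) ancestries, 5\%
#' scattered no-calls — the collection-survey conditions the package's
#' recovery checks run under.
#'
#' @return A `collection_scenario`.
#' @export
paper_like_scenario <- function() {
  read_collection_scenario(system.file("extdata", "paper_like.json",
                                       package = "germdiv", mustWork = TRUE))
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a genotype collection with known ground truth
#'
#' @param scenario a [collection_scenario()].
#' @param seed integer seed; all randomness derives from it, so equal seeds
#'   give byte-identical output.
#' @return List of class `sim_collection`:
#'   \describe{
#'     \item{genotypes}{a [genotype_matrix()];}
#'     \item{Q_true}{true ancestry proportions (samples x K);}
#'     \item{P_true}{true subpopulation reference-allele frequencies
#'       (K x loci);}
#'     \item{partition}{named majority-ancestry subpopulation labels;}
#'     \item{high_missing_samples, high_missing_loci}{ids planted with
#'       elevated missingness;}
#'     \item{scenario}{the scenario used.}
#'   }
#' @export
simulate_collection <- function(scenario = paper_like_scenario(), seed = NULL) {
  stopifnot(inherits(scenario, "collection_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_samples; L <- scenario$n_loci; K <- scenario$K
  F <- scenario$fst

  p_anc <- runif(L, 0.05, 0.95)
  P <- t(vapply(seq_len(K), function(k) {
    rbeta(L, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  }, numeric(L)))

  n_adm <- round(scenario$admixed_fraction * n)
  n_pure <- n - n_adm
  Q <- matrix(0, n, K)
  pure_pop <- rep_len(seq_len(K), n_pure)
  for (i in seq_len(n_pure)) Q[i, pure_pop[i]] <- 1
  if (n_adm > 0)
    Q[(n_pure + 1):n, ] <- .rdirichlet(n_adm, scenario$admix_alpha)

  f <- Q %*% P
  dosage <- matrix(rbinom(n * L, 2L, f), n, L)

  miss <- matrix(runif(n * L) < scenario$missing_rate, n, L)
  hs <- integer(0); hl <- integer(0)
  if (scenario$n_high_missing_samples > 0) {
    hs <- sort(sample.int(n, scenario$n_high_missing_samples))
    miss[hs, ] <- miss[hs, ] |
      matrix(runif(length(hs) * L) < scenario$high_missing_rate,
             length(hs), L)
  }
  if (scenario$n_high_missing_loci > 0) {
    hl <- sort(sample.int(L, scenario$n_high_missing_loci))
    miss[, hl] <- miss[, hl] |
      matrix(runif(n * length(hl)) < scenario$high_missing_rate,
             n, length(hl))
  }
  dosage[miss] <- NA_integer_

  pairs <- c("A,G", "C,T", "A,C", "G,T", "A,T", "C,G")
  al <- strsplit(pairs[sample.int(6, L, replace = TRUE)], ",")
  ref <- vapply(al, `[`, "", 1)
  alt <- vapply(al, `[`, "", 2)

  sample_ids <- sprintf("acc%02d", seq_len(n))
  locus_ids <- sprintf("snp%03d", seq_len(L))
  dimnames(dosage) <- list(sample_ids, locus_ids)
  rownames(Q) <- sample_ids
  colnames(P) <- locus_ids

  partition <- setNames(max.col(Q, ties.method = "first"), sample_ids)
  structure(list(genotypes = genotype_matrix(dosage, ref, alt),
                 Q_true = Q, P_true = P, partition = partition,
                 high_missing_samples = sample_ids[hs],
                 high_missing_loci = locus_ids[hl],
                 scenario = scenario),
            class = "sim_collection")
}

#' @method print sim_collection
#' @export
print.sim_collection <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("<sim_collection> '%s': %d x %d, K = %d, F = %.3f\n",
              s$name, s$n_samples, s$n_loci, s$K, s$fst))
  invisible(x)
}

#' Define a transcript-set scenario
#'
#' Each simulated contig carries an optional planted longest ORF, an
#' optional planted SSR in the 3' flank, and optional planted SNP sites
#' drawn from the four joint genotype categories.
#'
#' @param n_contigs number of contigs.
#' @param contig_length contig length in bases.
#' @param orf_aa amino acids strictly between the planted start and stop
#'   codons (0 plants no ORF).
#' @param orf_strand `"+"`, `"-"`, or `"both"` to alternate.
#' @param ssr_motif planted repeat unit (`NULL` plants no SSR).
#' @param ssr_repeats planted repeat count.
#' @param n_snps planted SNP sites per contig.
#' @param snp_category_weights expected proportions of the `HoHo`, `HeHo`,
#'   `HoHe`, `HeHe` categories used when sampling planted SNP categories.
#' @param min_aa,min_repeats thresholds used when screening the background
#'   for accidental features (match the scanner settings).
#' @return A list of class `transcript_scenario`.
#' @export
transcript_scenario <- function(n_contigs = 20, contig_length = 1200,
                                orf_aa = 80, orf_strand = "both",
                                ssr_motif = "GAA", ssr_repeats = 6,
                                n_snps = 4,
                                snp_category_weights =
                                  c(HoHo = 24, HeHo = 34, HoHe = 164, HeHe = 110),
                                min_aa = 67,
                                min_repeats = MISA_DEFAULT_MIN_REPEATS) {
  need <- 0
  if (orf_aa > 0) need <- need + 3 * (orf_aa + 2)
  if (!is.null(ssr_motif)) need <- need + nchar(ssr_motif) * ssr_repeats
  if (need + 20 > contig_length)
    stop("planted features exceed the contig length", call. = FALSE)
  structure(list(n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 orf_aa = as.integer(orf_aa), orf_strand = orf_strand,
                 ssr_motif = ssr_motif, ssr_repeats = as.integer(ssr_repeats),
                 n_snps = as.integer(n_snps),
                 snp_category_weights = snp_category_weights,
                 min_aa = as.integer(min_aa), min_repeats = min_repeats),
            class = "transcript_scenario")
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# codons free of stop codons and of ATG (keeps the planted start unique
# enough for exact ground truth; screening rejects the rest)
.random_codons <- function(n_aa) {
  bad <- c("TAA", "TAG", "TGA", "ATG")
  all3 <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                paste0), c("A", "C", "G", "T"), paste0))
  pool <- setdiff(all3, bad)
  paste(sample(pool, n_aa, replace = TRUE), collapse = "")
}

#' Simulate transcript contigs with planted ORFs, SSRs and SNPs
#'
#' Background sequence is i.i.d. uniform over ACGT, rejection-sampled so
#' that the planted SSR is the only qualifying repeat and the planted ORF is
#' the unique longest qualifying ORF; rejection counts are returned.
#'
#' @param scenario a [transcript_scenario()].
#' @param seed integer seed.
#' @return List of class `sim_transcripts`: `sequences` (named character),
#'   `orfs`, `ssrs`, `snps` (ground-truth data frames; `snps` has the two
#'   accessions' calls and the true `category`), `n_rejected`.
#' @export
simulate_transcripts <- function(scenario = transcript_scenario(), seed = NULL) {
  stopifnot(inherits(scenario, "transcript_scenario"))
  if (!is.null(seed)) set.seed(seed)
  sc <- scenario
  seqs <- character(sc$n_contigs)
  orfs <- list(); ssrs <- list(); snps <- list()
  n_rejected <- 0L
  cats <- c("HoHo", "HeHo", "HoHe", "HeHe")

  for (ci in seq_len(sc$n_contigs)) {
    id <- sprintf("contig%03d", ci)
    strand <- switch(sc$orf_strand, `+` = "+", `-` = "-",
                     both = if (ci %% 2) "+" else "-")
    repeat {
      len <- sc$contig_length
      orf_len <- if (sc$orf_aa > 0) 3 * (sc$orf_aa + 2) else 0
      ssr_len <- if (!is.null(sc$ssr_motif))
        nchar(sc$ssr_motif) * sc$ssr_repeats else 0
      # layout: [flank1][ORF][flank2][SSR][flank3], flank lengths random
      free <- len - orf_len - ssr_len
      cuts <- sort(sample.int(free - 2, 2))
      f1 <- cuts[1]; f2 <- cuts[2] - cuts[1]; f3 <- free - cuts[2]
      orf_seq <- if (orf_len > 0)
        paste0("ATG", .random_codons(sc$orf_aa), "TAA") else ""
      if (orf_len > 0 && strand == "-") orf_seq <- .revcomp(orf_seq)
      ssr_seq <- if (ssr_len > 0)
        strrep(sc$ssr_motif, sc$ssr_repeats) else ""
      s <- paste0(.random_seq(f1), orf_seq, .random_seq(f2), ssr_seq,
                  .random_seq(f3))
      orf_start <- f1 + 1L; orf_end <- f1 + orf_len
      ssr_start <- f1 + orf_len + f2 + 1L
      ssr_end <- ssr_start + ssr_len - 1L

      # screen: planted features must be exactly what the scanners see
      found_ssr <- scan_ssrs(setNames(s, id), min_repeats = sc$min_repeats)
      ssr_ok <- if (ssr_len > 0) {
        nrow(found_ssr) == 1 && found_ssr$start == ssr_start &&
          found_ssr$end == ssr_end && found_ssr$motif == sc$ssr_motif
      } else nrow(found_ssr) == 0
      orf_found <- find_longest_orf(s, min_aa = sc$min_aa)
      orf_ok <- if (orf_len > 0) {
        !is.null(orf_found) && orf_found$start == orf_start &&
          orf_found$end == orf_end && orf_found$strand == strand
      } else is.null(orf_found)
      if (ssr_ok && orf_ok) break
      n_rejected <- n_rejected + 1L
      if (n_rejected > 200 * sc$n_contigs)
        stop("rejection sampling failed; scenario too constrained",
             call. = FALSE)
    }
    seqs[ci] <- s
    names(seqs)[ci] <- id
    if (orf_len > 0)
      orfs[[length(orfs) + 1L]] <-
        data.frame(contig = id, start = orf_start, end = orf_end,
                   strand = strand, length_aa = sc$orf_aa)
    if (ssr_len > 0)
      ssrs[[length(ssrs) + 1L]] <-
        data.frame(contig = id, start = ssr_start, end = ssr_end,
                   motif = sc$ssr_motif, repeat_count = sc$ssr_repeats,
                   canonical_pair = canonical_pair(sc$ssr_motif))
    if (sc$n_snps > 0) {
      pos <- sort(sample.int(len, sc$n_snps))
      chars <- strsplit(s, "")[[1]]
      for (p in pos) {
        ref <- chars[p]
        if (!ref %in% c("A", "C", "G", "T")) next
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        cat_i <- sample(cats, 1, prob = sc$snp_category_weights)
        het <- paste(sort(c(ref, alt)), collapse = "/")
        hom_r <- paste0(ref, "/", ref); hom_a <- paste0(alt, "/", alt)
        calls <- switch(cat_i,
                        HoHo = c(hom_r, hom_a),
                        HeHo = c(het, sample(c(hom_r, hom_a), 1)),
                        HoHe = c(sample(c(hom_r, hom_a), 1), het),
                        HeHe = c(het, het))
        snps[[length(snps) + 1L]] <-
          data.frame(contig = id, position = p, ref = ref, alt = alt,
                     call_1 = calls[1], call_2 = calls[2],
                     category_true = cat_i)
      }
    }
  }
  bindf <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  structure(list(
    sequences = seqs,
    orfs = bindf(orfs, data.frame(contig = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  length_aa = integer())),
    ssrs = bindf(ssrs, data.frame(contig = character(), start = integer(),
                                  end = integer(), motif = character(),
                                  repeat_count = integer(),
                                  canonical_pair = character())),
    snps = bindf(snps, data.frame(contig = character(), position = integer(),
                                  ref = character(), alt = character(),
                                  call_1 = character(), call_2 = character(),
                                  category_true = character())),
    n_rejected = n_rejected, scenario = sc),
    class = "sim_transcripts")
}

#' @method print sim_transcripts
#' @export
print.sim_transcripts <- function(x, ...) {
  cat(sprintf("<sim_transcripts> %d contigs, %d ORFs, %d SSRs, %d SNPs (%d rejected draws)\n",
              length(x$sequences), nrow(x$orfs), nrow(x$ssrs), nrow(x$snps),
              x$n_rejected))
  invisible(x)
}
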