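# Transcript-level variation: joint genotype categories of a SNP in two
# accessions (HoHo/HeHo/HoHe/HeHe), longest-ORF annotation and in/out-ORF
# assignment, and perfect microsatellite (SSR) scanning with canonical
# reverse-complement motif pairing.

MISA_DEFAULT_MIN_REPEATS <- c(`1` = 10, `2` = 6, `3` = 5, `4` = 5, `5` = 5, `6` = 5)

.revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Classify the joint genotype category of a SNP in two accessions
#'
#' Each call is heterozygous (He) or homozygous (Ho); the pair falls into
#' HoHo, HeHo, HoHe or HeHe (first letter pair = first accession). Two
#' identical homozygous calls describe a monomorphic site, not a SNP, and
#' raise an error.
#'
#' @param call_1,call_2 genotype calls of the two accessions, as `"A/G"`,
#'   `"AG"` or `"A:G"` strings (vectorized).
#' @return Character vector of categories.
#' @export
classify_genotype_pair <- function(call_1, call_2) {
  c1 <- .parse_calls(call_1, no_call = character(0))
  c2 <- .parse_calls(call_2, no_call = character(0))
  if (anyNA(c1) || anyNA(c2))
    stop("missing call is unclassifiable", call. = FALSE)
  he1 <- substr(c1, 1, 1) != substr(c1, 2, 2)
  he2 <- substr(c2, 1, 1) != substr(c2, 2, 2)
  mono <- !he1 & !he2 & c1 == c2
  if (any(mono))
    stop("identical homozygous calls describe a monomorphic site, not a SNP",
         call. = FALSE)
  paste0(ifelse(he1, "He", "Ho"), ifelse(he2, "He", "Ho"))
}

# ATG..stop ORFs in one strand of one sequence; returns spans on that strand.
.orf_scan_strand <- function(s, min_aa) {
  nc <- nchar(s)
  best <- NULL
  for (f in 0:2) {
    starts <- seq.int(f + 1, by = 3, length.out = (nc - f) %/% 3)
    if (length(starts) == 0) next
    codons <- substring(s, starts, starts + 2)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_atg <- codons == "ATG"
    stop_idx <- which(is_stop)
    prev_stop <- 0L
    for (st in stop_idx) {
      atg <- which(is_atg[seq.int(prev_stop + 1L, st)])
      if (length(atg)) {
        a <- prev_stop + atg[1]
        aa <- st - a - 1L          # codons strictly between start and stop
        if (aa >= min_aa) {
          cand <- c(start = starts[a], end = starts[st] + 2L, aa = aa)
          if (is.null(best) || aa > best["aa"] ||
              (aa == best["aa"] && cand["start"] < best["start"])) best <- cand
        }
      }
      prev_stop <- st
    }
  }
  best
}

#' Longest open reading frame of a transcript contig
#'
#' Scans all six reading frames (both strands unless `both_strands = FALSE`)
#' for `ATG ... stop` spans and returns the longest with at least `min_aa`
#' amino acids, where the amino-acid length counts the codons strictly
#' between the start and stop codons. Coordinates are 1-based inclusive on
#' the forward strand and include the stop codon. Codons containing `N`
#' count as ordinary non-start, non-stop codons.
#'
#' @param sequence nucleotide string over `A/C/G/T/N`.
#' @param min_aa minimum amino-acid length (default 67).
#' @param both_strands scan the reverse complement too (default `TRUE`).
#' @return `NULL` when no qualifying ORF exists, otherwise a list with
#'   `start`, `end`, `strand` (`"+"`/`"-"`), `length_aa`. Ties in length go
#'   to the forward strand, then to the smallest forward start.
#' @export
find_longest_orf <- function(sequence, min_aa = 67, both_strands = TRUE) {
  s <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", s))
    stop("sequence must be over A/C/G/T/N", call. = FALSE)
  nc <- nchar(s)
  fwd <- .orf_scan_strand(s, min_aa)
  hit <- if (!is.null(fwd))
    list(start = unname(fwd["start"]), end = unname(fwd["end"]),
         strand = "+", length_aa = unname(fwd["aa"])) else NULL
  if (both_strands) {
    rev <- .orf_scan_strand(.revcomp(s), min_aa)
    if (!is.null(rev) && (is.null(hit) || rev["aa"] > hit$length_aa)) {
      hit <- list(start = nc - unname(rev["end"]) + 1L,
                  end = nc - unname(rev["start"]) + 1L,
                  strand = "-", length_aa = unname(rev["aa"]))
    }
  }
  hit
}

#' Longest-ORF annotations for a set of contigs
#'
#' @param sequences named character vector of contig sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @inheritParams find_longest_orf
#' @return Data frame (`contig`, `start`, `end`, `strand`, `length_aa`) with
#'   one row per contig that has a qualifying ORF.
#' @export
find_orfs <- function(sequences, min_aa = 67, both_strands = TRUE) {
  sequences <- .as_seq_vector(sequences)
  rows <- lapply(names(sequences), function(id) {
    hit <- find_longest_orf(sequences[[id]], min_aa, both_strands)
    if (is.null(hit)) return(NULL)
    data.frame(contig = id, start = hit$start, end = hit$end,
               strand = hit$strand, length_aa = hit$length_aa)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      length_aa = integer())
  out
}

.as_seq_vector <- function(x) {
  if (methods::is(x, "DNAStringSet")) x <- as.character(x)
  if (is.null(names(x))) names(x) <- paste0("contig", seq_along(x))
  x
}

#' Assign SNP positions relative to an ORF
#'
#' `inORF` iff `start <= position <= end` (1-based inclusive,
#' strand-agnostic); `no_orf` when the contig has no qualifying ORF.
#'
#' @param position SNP position(s), 1-based.
#' @param orf an ORF annotation (list or one-row data frame with `start`,
#'   `end`) or `NULL`.
#' @return `"inORF"`, `"outORF"` or `"no_orf"` per position.
#' @export
locate_snp <- function(position, orf) {
  if (is.null(orf) || (is.data.frame(orf) && nrow(orf) == 0))
    return(rep("no_orf", length(position)))
  ifelse(position >= orf$start & position <= orf$end, "inORF", "outORF")
}

#' Classify a SNP table against ORF annotations
#'
#' Adds the joint genotype `category` and the `orf_class`
#' (`inORF`/`outORF`/`no_orf`) to a variant table.
#'
#' @param snps data frame with columns `contig`, `position`, `call_1`,
#'   `call_2`.
#' @param orfs data frame from [find_orfs()] (one ORF per contig).
#' @return The input with `category` and `orf_class` columns added.
#' @export
classify_snp_table <- function(snps, orfs) {
  stopifnot(all(c("contig", "position", "call_1", "call_2") %in% names(snps)))
  snps$category <- classify_genotype_pair(snps$call_1, snps$call_2)
  idx <- match(snps$contig, orfs$contig)
  has <- !is.na(idx)
  cls <- rep("no_orf", nrow(snps))
  cls[has] <- ifelse(snps$position[has] >= orfs$start[idx[has]] &
                       snps$position[has] <= orfs$end[idx[has]],
                     "inORF", "outORF")
  snps$orf_class <- cls
  snps
}

#' Read a two-accession SNP table (TSV)
#'
#' Reads a VarScan-style variant table with one genotype call column per
#' accession, as distributed in transcriptome-variation supplements.
#'
#' @param file TSV path with columns `contig`, `position`, `ref`, `alt`,
#'   `call_1`, `call_2` (extra columns kept).
#' @return Data frame.
#' @export
read_snp_table <- function(file) {
  df <- read.csv(file, sep = "\t", check.names = FALSE,
                 colClasses = "character")
  need <- c("contig", "position", "call_1", "call_2")
  if (!all(need %in% names(df)))
    stop("SNP table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$position <- as.integer(df$position)
  df
}

#' Scan perfect microsatellites (SSRs)
#'
#' Finds all maximal perfect tandem repeats with unit length 1--6 that meet
#' the per-unit-length minimum repeat counts (defaults are the published
#' MISA defaults: 10 for mono-, 6 for di-, 5 for tri- to hexanucleotides).
#' A run is reported once at its smallest repeat unit; `N` never occurs
#' inside a reported repeat; a reported repeat cannot be extended by a full
#' unit in either direction.
#'
#' @param sequences named character vector (or `DNAStringSet`) of sequences
#'   over `A/C/G/T/N`; a single unnamed string is accepted.
#' @param min_repeats named numeric vector of minimum repeat counts per unit
#'   length (names `"1"`..`"6"`).
#' @return Data frame `contig`, `start`, `end` (1-based inclusive, spanning
#'   `repeat_count` whole units), `motif`, `repeat_count`, `canonical_pair`.
#' @export
scan_ssrs <- function(sequences, min_repeats = MISA_DEFAULT_MIN_REPEATS) {
  if (is.character(sequences) && length(sequences) == 1 && is.null(names(sequences)))
    names(sequences) <- "seq1"
  sequences <- .as_seq_vector(sequences)
  rows <- lapply(names(sequences), function(id) {
    r <- .scan_ssrs_one(toupper(sequences[[id]]), min_repeats)
    if (nrow(r)) r$contig <- id
    r
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), motif = character(),
                      repeat_count = integer(), canonical_pair = character()))
  out$canonical_pair <- vapply(out$motif, canonical_pair, "", USE.NAMES = FALSE)
  out <- out[order(match(out$contig, names(sequences)), out$start),
             c("contig", "start", "end", "motif", "repeat_count",
               "canonical_pair")]
  rownames(out) <- NULL
  out
}

.scan_ssrs_one <- function(s, min_repeats) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  acgt <- chars %in% c("A", "C", "G", "T")
  out <- list()
  for (k in 1:6) {
    min_rep <- min_repeats[[as.character(k)]]
    if (is.null(min_rep) || n < k * min_rep) next
    eq <- chars[seq_len(n - k)] == chars[seq.int(k + 1, n)] &
      acgt[seq_len(n - k)] & acgt[seq.int(k + 1, n)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (ri in runs) {
      j <- starts[ri]
      m <- r$lengths[ri]
      count <- (m + k) %/% k
      if (count < min_rep) next
      motif <- substr(s, j, j + k - 1)
      if (.is_periodic(motif)) next
      out[[length(out) + 1L]] <-
        data.frame(start = j, end = j + k * count - 1L,
                   motif = motif, repeat_count = count)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), motif = character(),
               repeat_count = integer())
}

.is_periodic <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0 &&
        motif == strrep(substr(motif, 1, d), k / d)) return(TRUE)
  }
  FALSE
}

#' Canonical reverse-complement pair label of an SSR motif
#'
#' Pairs a motif with its reverse complement, lexicographically smaller
#' member first (e.g. `"GA"` -> `"GA/TC"`, `"AT"` -> `"AT/AT"`). Rotational
#' variants are kept distinct (`AG/CT` is not merged with `GA/TC`).
#'
#' @param motif repeat unit of length 1--6 over `A/C/G/T`.
#' @return The `"PLUS/MINUS"` label.
#' @export
canonical_pair <- function(motif) {
  motif <- toupper(motif)
  if (!grepl("^[ACGT]{1,6}$", motif))
    stop("motif must be 1-6 bases over A/C/G/T", call. = FALSE)
  rc <- .revcomp(motif)
  pair <- sort(c(motif, rc))
  paste0(pair[1], "/", pair[2])
}

#' Summarize an SSR census
#'
#' Tabulates repeat counts by unit length (percentages over all SSRs) and by
#' canonical reverse-complement motif pair within the di- and trinucleotide
#' classes (percentages within each class).
#'
#' @param records data frame from [scan_ssrs()].
#' @return List of class `ssr_summary` with data frames `by_length`,
#'   `dinucleotide`, `trinucleotide` and the total count `n`.
#' @export
summarize_ssrs <- function(records) {
  n <- nrow(records)
  if (n == 0) {
    empty <- data.frame(canonical_pair = character(), n = integer(),
                        percent = numeric())
    return(structure(list(by_length = data.frame(unit_length = integer(),
                                                 n = integer(),
                                                 percent = numeric()),
                          dinucleotide = empty, trinucleotide = empty, n = 0L),
                     class = "ssr_summary"))
  }
  ulen <- nchar(records$motif)
  bl <- as.data.frame(table(unit_length = factor(ulen, levels = 1:6)),
                      responseName = "n")
  bl$unit_length <- as.integer(as.character(bl$unit_length))
  bl$percent <- 100 * bl$n / n
  class_tab <- function(k) {
    sub <- records[ulen == k, ]
    if (nrow(sub) == 0)
      return(data.frame(canonical_pair = character(), n = integer(),
                        percent = numeric()))
    t <- as.data.frame(table(canonical_pair = sub$canonical_pair),
                       responseName = "n")
    t$canonical_pair <- as.character(t$canonical_pair)
    t$percent <- 100 * t$n / nrow(sub)
    t[order(-t$n, t$canonical_pair), ]
  }
  structure(list(by_length = bl, dinucleotide = class_tab(2),
                 trinucleotide = class_tab(3), n = n),
            class = "ssr_summary")
}

#' @method print ssr_summary
#' @export
print.ssr_summary <- function(x, ...) {
  cat(sprintf("SSR summary: %d repeats\n", x$n))
  print(x$by_length, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Read / write FASTA
#'
#' Thin wrappers over `Biostrings`.
#'
#' @param file path.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(file) {
  as.character(Biostrings::readDNAStringSet(file))
}

#' @rdname read_fasta
#' @param sequences named character vector of sequences.
#' @export
write_fasta <- function(sequences, file) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), file)
  invisible(file)
}

#' Write ORF or SSR annotations as GFF3
#'
#' @param annotations data frame from [find_orfs()] (`type = "ORF"`) or
#'   [scan_ssrs()] (`type = "microsatellite"`).
#' @param file output path.
#' @param type feature type written to the GFF3 type column.
#' @export
write_gff3 <- function(annotations, file,
                       type = c("ORF", "microsatellite")) {
  type <- match.arg(type)
  strand <- if ("strand" %in% names(annotations)) annotations$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$contig,
    ranges = IRanges::IRanges(annotations$start, annotations$end),
    strand = strand)
  gr$type <- type
  gr$source <- "germdiv"
  gr$ID <- paste0(tolower(type), "_", seq_along(gr))
  if (type == "ORF") {
    gr$length_aa <- annotations$length_aa
  } else {
    gr$motif <- annotations$motif
    gr$repeat_count <- annotations$repeat_count
    gr$canonical_pair <- annotations$canonical_pair
  }
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}
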