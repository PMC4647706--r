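# SNP genotype categories, ORF finding, SSR scanning.

test_that("joint genotype categories follow the He/Ho status of each call", {
  expect_identical(classify_genotype_pair("A/A", "G/G"), "HoHo")
  expect_identical(classify_genotype_pair("A/G", "A/A"), "HeHo")
  expect_identical(classify_genotype_pair("A/A", "A/G"), "HoHe")
  expect_identical(classify_genotype_pair("A/G", "A/G"), "HeHe")
  # orientation-insensitive
  expect_identical(classify_genotype_pair("G/A", "AG"), "HeHe")
  expect_error(classify_genotype_pair("A/A", "A/A"), "monomorphic")
  expect_error(classify_genotype_pair("A/A", "NC"), "unparseable|unclassifiable")
})

test_that("the minimum ORF length counts codons between start and stop", {
  s <- paste0("ATG", strrep("GCT", 66), "TAA")
  expect_null(find_longest_orf(s, min_aa = 67))
  hit <- find_longest_orf(s, min_aa = 66)
  expect_equal(hit$length_aa, 66)
  expect_equal(hit$start, 1)
  expect_equal(hit$end, nchar(s))  # stop codon inside the span
  expect_identical(hit$strand, "+")
})

test_that("no start codon on either strand means no ORF", {
  # CAT on the minus strand is ATG; avoid A entirely
  s <- strrep("GGCCTC", 60)
  expect_null(find_longest_orf(s, min_aa = 5))
})

test_that("the longer reverse-strand ORF wins and is reported forward", {
  set.seed(3)
  fwd_orf <- paste0("ATG", germdiv:::.random_codons(80), "TAA")
  rev_orf <- germdiv:::.revcomp(paste0("ATG", germdiv:::.random_codons(100), "TGA"))
  flank <- function(n) paste(sample(c("C", "G"), n, replace = TRUE), collapse = "")
  s <- paste0(flank(30), fwd_orf, flank(31), rev_orf, flank(30))
  hit <- find_longest_orf(s, min_aa = 67)
  expect_identical(hit$strand, "-")
  expect_equal(hit$length_aa, 100)
  orc <- oracle_longest_orf(s, min_aa = 67)
  expect_equal(hit[c("start", "end", "strand", "length_aa")],
               orc[c("start", "end", "strand", "length_aa")])
})

test_that("ORF length is invariant under reverse complementation", {
  set.seed(14)
  for (rep in 1:5) {
    sim <- simulate_transcripts(transcript_scenario(n_contigs = 1,
                                                    contig_length = 700,
                                                    orf_aa = 70, n_snps = 0,
                                                    ssr_motif = NULL),
                                seed = rep)
    s <- sim$sequences[[1]]
    h1 <- find_longest_orf(s)
    h2 <- find_longest_orf(germdiv:::.revcomp(s))
    expect_equal(h1$length_aa, h2$length_aa)
    expect_true(h1$strand != h2$strand)
  }
})

test_that("longest-ORF search agrees with the per-start walk oracle", {
  set.seed(27)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 450, replace = TRUE),
               collapse = "")
    hit <- find_longest_orf(s, min_aa = 10)
    orc <- oracle_longest_orf(s, min_aa = 10)
    if (is.null(orc)) {
      expect_null(hit)
    } else {
      expect_equal(hit$length_aa, orc$length_aa)
      expect_equal(hit$start, orc$start)
      expect_equal(hit$end, orc$end)
    }
  }
})

test_that("SNPs are located against the ORF with inclusive boundaries", {
  orf <- list(start = 10, end = 90)
  expect_identical(locate_snp(10, orf), "inORF")
  expect_identical(locate_snp(90, orf), "inORF")
  expect_identical(locate_snp(9, orf), "outORF")
  expect_identical(locate_snp(91, orf), "outORF")
  expect_identical(locate_snp(5, NULL), "no_orf")
})

test_that("SSR scanning honours per-unit-length thresholds and maximality", {
  # fixed repeat-free flank that cannot extend any of the planted units
  flank <- function(n = 20) "CCGGTCTAGTTGACGAGCTC"
  s <- paste0(flank(), strrep("AT", 7), flank())
  r <- scan_ssrs(s)
  expect_identical(nrow(r), 1L)
  expect_identical(r$motif, "AT")
  expect_identical(r$repeat_count, 7L)
  expect_identical(r$start, 21L)
  expect_identical(r$end, 34L)

  expect_identical(nrow(scan_ssrs(paste0(flank(), strrep("GAA", 5), flank()))), 1L)
  expect_identical(nrow(scan_ssrs(paste0(flank(), strrep("GAA", 4), flank()))), 0L)
  expect_identical(nrow(scan_ssrs(paste0(flank(), strrep("A", 9), flank()))), 0L)
  expect_identical(nrow(scan_ssrs(paste0(flank(), strrep("A", 10), flank()))), 1L)
})

test_that("a run is reported once, at its smallest unit, and never across N", {
  s <- paste0("CCGCCG", strrep("A", 12), "CCG")   # poly-A, not (AA)n/(AAA)n
  r <- scan_ssrs(s)
  expect_identical(r$motif, "A")
  expect_identical(r$repeat_count, 12L)

  sN <- paste0(strrep("A", 6), "N", strrep("A", 6))
  expect_identical(nrow(scan_ssrs(sN)), 0L)
})

test_that("SSR scan equals the regex brute-force oracle on random sequence", {
  set.seed(61)
  n_checked <- 0
  for (rep in 1:40) {
    base <- sample(c("A", "C", "G", "T"), 900, replace = TRUE)
    # splice in a few genuine repeats so non-empty cases are exercised
    s <- paste0(paste(base, collapse = ""), strrep("TTG", 6), strrep("CA", 8))
    mine <- scan_ssrs(s)
    orc <- oracle_scan_ssrs(s)
    expect_equal(nrow(mine), nrow(orc))
    if (nrow(mine)) {
      expect_equal(mine$start, orc$start)
      expect_equal(mine$end, orc$end)
      expect_equal(mine$motif, orc$motif)
      expect_equal(mine$repeat_count, orc$repeat_count)
      n_checked <- n_checked + nrow(mine)
    }
  }
  expect_gt(n_checked, 50)
})

test_that("canonical pairs join motifs with their reverse complements", {
  expect_identical(canonical_pair("AT"), "AT/AT")
  expect_identical(canonical_pair("GA"), "GA/TC")
  expect_identical(canonical_pair("GAA"), "GAA/TTC")
  # involution: a motif and its reverse complement share one label
  set.seed(9)
  for (rep in 1:25) {
    m <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), replace = TRUE),
               collapse = "")
    expect_identical(canonical_pair(m), canonical_pair(germdiv:::.revcomp(m)))
  }
  expect_error(canonical_pair("ANT"), "A/C/G/T")
})

test_that("SSR summaries report class percentages and within-class motifs", {
  rec <- data.frame(contig = "c", start = 1, end = 2,
                    motif = c(rep("GAA", 7), rep("AT", 3)),
                    repeat_count = 5,
                    canonical_pair = c(rep("GAA/TTC", 7), rep("AT/AT", 3)))
  s <- summarize_ssrs(rec)
  expect_equal(s$by_length$percent[s$by_length$unit_length == 3], 70)
  expect_equal(s$by_length$percent[s$by_length$unit_length == 2], 30)
  expect_equal(s$trinucleotide$percent, 100)
  expect_equal(s$dinucleotide$percent, 100)
  one <- summarize_ssrs(rec[1, ])
  expect_equal(one$trinucleotide$percent, 100)
  expect_identical(summarize_ssrs(rec[0, ])$n, 0L)
})

test_that("category counts partition any classified SNP table", {
  sim <- simulate_transcripts(transcript_scenario(n_contigs = 6,
                                                  contig_length = 900,
                                                  orf_aa = 70, n_snps = 8),
                              seed = 10)
  orfs <- find_orfs(sim$sequences)
  cls <- classify_snp_table(sim$snps, orfs)
  expect_identical(cls$category, cls$category_true)
  expect_identical(sum(table(cls$category)), nrow(cls))
  expect_true(all(cls$orf_class %in% c("inORF", "outORF")))
  # truth of orf_class from planted coordinates
  truth_in <- mapply(function(ct, p) {
    o <- sim$orfs[sim$orfs$contig == ct, ]
    p >= o$start & p <= o$end
  }, cls$contig, cls$position)
  expect_identical(cls$orf_class == "inORF", unname(truth_in))
})

test_that("SNP tables round-trip through TSV", {
  sim <- simulate_transcripts(transcript_scenario(n_contigs = 3,
                                                  contig_length = 800,
                                                  orf_aa = 0, ssr_motif = NULL,
                                                  n_snps = 5),
                              seed = 77)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(sim$snps, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_snp_table(f)
  expect_identical(back$contig, sim$snps$contig)
  expect_identical(back$position, sim$snps$position)
  expect_identical(classify_genotype_pair(back$call_1, back$call_2),
                   sim$snps$category_true)
})

test_that("GFF3 export round-trips ORF and SSR annotations", {
  sim <- simulate_transcripts(transcript_scenario(n_contigs = 4,
                                                  contig_length = 900,
                                                  orf_aa = 70, n_snps = 0),
                              seed = 21)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$orfs, f, type = "ORF")
  gr <- rtracklayer::import(f)
  expect_equal(length(gr), nrow(sim$orfs))
  expect_equal(GenomicRanges::start(gr), sim$orfs$start)
  expect_equal(GenomicRanges::end(gr), sim$orfs$end)
  expect_identical(as.character(GenomicRanges::strand(gr)), sim$orfs$strand)

  f2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$ssrs, f2, type = "microsatellite")
  gr2 <- rtracklayer::import(f2)
  expect_identical(gr2$motif, sim$ssrs$motif)
})

test_that("FASTA I/O round-trips sequences", {
  sim <- simulate_transcripts(transcript_scenario(n_contigs = 3,
                                                  contig_length = 600,
                                                  orf_aa = 0, ssr_motif = NULL,
                                                  n_snps = 0),
                              seed = 31)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(sim$sequences, f)
  back <- read_fasta(f)
  expect_identical(back, sim$sequences)
})
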