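# Genotype matrix container and delimited-text / VCF readers.
#
# Internal representation: an integer dosage matrix (samples x loci) counting
# copies of the locus reference allele (0/1/2, NA = no call), plus per-locus
# ref/alt allele symbols. Calls are unordered allele pairs, so "A/G" and
# "G/A" are the same genotype.

DEFAULT_NO_CALL <- c("NC", "NN", "NO CALL", "NOCALL", "", "NA", "./.", ".")

#' Construct a genotype matrix
#'
#' Builds the package's genotype container from a dosage matrix and per-locus
#' allele symbols. Most users will obtain one from [read_genotype_table()],
#' [read_genotype_vcf()] or [simulate_collection()] instead.
#'
#' @param dosage integer matrix, samples x loci; entries count copies of the
#'   locus reference allele (0, 1 or 2), `NA` for a missing call. Row names
#'   are sample ids, column names locus ids.
#' @param ref,alt character vectors of per-locus allele symbols (A/C/G/T).
#'   `alt` may be `NA` for a locus observed monomorphic.
#' @return An object of class `genotype_matrix` with fields `dosage`, `ref`,
#'   `alt`, `sample_ids`, `locus_ids`.
#' @export
genotype_matrix <- function(dosage, ref, alt) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("L", seq_len(ncol(dosage)))
  if (anyDuplicated(rownames(dosage)))
    stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(dosage)))
    stop("duplicate locus ids", call. = FALSE)
  if (length(ref) != ncol(dosage) || length(alt) != ncol(dosage))
    stop("ref/alt length must equal the number of loci", call. = FALSE)
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  structure(
    list(dosage = dosage,
         ref = as.character(ref), alt = as.character(alt),
         sample_ids = rownames(dosage), locus_ids = colnames(dosage)),
    class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  d <- dim(x)
  miss <- mean(is.na(x$dosage))
  cat(sprintf("<genotype_matrix> %d samples x %d loci (%.1f%% missing, %d monomorphic)\n",
              d[1], d[2], 100 * miss, sum(is.na(x$alt))))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i,j sample / locus indices (integer, logical or names).
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$sample_ids)
  if (missing(j)) j <- seq_along(x$locus_ids)
  if (is.character(j)) j <- match(j, x$locus_ids)
  if (is.logical(j)) j <- which(j)
  genotype_matrix(x$dosage[i, j, drop = FALSE], x$ref[j], x$alt[j])
}

#' Fraction of missing calls per sample or locus
#'
#' @param x a [genotype_matrix()].
#' @param margin `"sample"` or `"locus"`.
#' @return Named numeric vector of missing-call fractions.
#' @export
missing_fraction <- function(x, margin = c("sample", "locus")) {
  margin <- match.arg(margin)
  if (margin == "sample") rowMeans(is.na(x$dosage)) else colMeans(is.na(x$dosage))
}

#' Loci observed with a single allele
#'
#' @param x a [genotype_matrix()].
#' @return Logical vector, `TRUE` where the locus has no alternate allele.
#' @export
is_monomorphic <- function(x) is.na(x$alt)

# Parse heterogeneous call spellings ("AG", "A/G", "a:g", "No Call", ...)
# into a canonical sorted two-letter code or NA.
.parse_calls <- function(x, no_call = DEFAULT_NO_CALL) {
  x <- toupper(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  miss <- x %in% toupper(no_call) | is.na(x)
  x2 <- gsub("[/|:]", "", x[!miss])
  ok <- grepl("^[ACGT]{2}$", x2)
  if (!all(ok))
    stop("unparseable genotype call(s): ",
         paste(unique(x[!miss][!ok]), collapse = ", "), call. = FALSE)
  a <- substr(x2, 1, 1); b <- substr(x2, 2, 2)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out[!miss] <- paste0(a, b)
  out
}

# Canonical "AB" call strings (samples x loci) -> genotype_matrix.
.calls_to_genotype <- function(calls) {
  n_loc <- ncol(calls)
  ref <- alt <- rep(NA_character_, n_loc)
  dosage <- matrix(NA_integer_, nrow(calls), n_loc,
                   dimnames = dimnames(calls))
  for (j in seq_len(n_loc)) {
    cj <- calls[, j]
    alleles <- sort(unique(c(substr(cj, 1, 1), substr(cj, 2, 2))))
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) > 2)
      stop("locus '", colnames(calls)[j], "' has ", length(alleles),
           " distinct alleles (", paste(alleles, collapse = ","),
           "); only biallelic loci are supported", call. = FALSE)
    ref[j] <- if (length(alleles)) alleles[1] else NA_character_
    alt[j] <- if (length(alleles) == 2) alleles[2] else NA_character_
    if (length(alleles)) {
      dosage[, j] <- (substr(cj, 1, 1) == ref[j]) + (substr(cj, 2, 2) == ref[j])
    }
  }
  genotype_matrix(dosage, ref, alt)
}

#' Read a genotype call table
#'
#' Reads a delimited samples-x-loci table of biallelic SNP calls, as exported
#' by Fluidigm EP1 final-call software or written by [write_genotype_table()].
#' Cell spellings `"AG"`, `"A/G"`, `"A:G"`, `"G/A"` are all normalized to the
#' same unordered allele pair; no-call tokens become missing values.
#'
#' @param file path to a CSV/TSV file (first column sample ids, header row
#'   locus ids).
#' @param dialect `"simple_csv"` (plain CSV) or `"fluidigm_csv"` (skips
#'   leading comment lines starting with `#`, accepts colon-separated calls
#'   and the `"No Call"` token).
#' @param no_call character vector of tokens treated as missing calls.
#' @param sep field separator, default `","`.
#' @return A [genotype_matrix()]. Loci observed with one allele are kept and
#'   flagged by [is_monomorphic()]; three or more alleles at a locus is an
#'   error naming the locus.
#' @export
read_genotype_table <- function(file, dialect = c("simple_csv", "fluidigm_csv"),
                                no_call = DEFAULT_NO_CALL, sep = ",") {
  dialect <- match.arg(dialect)
  df <- read.csv(file, sep = sep, check.names = FALSE,
                 colClasses = "character",
                 comment.char = if (dialect == "fluidigm_csv") "#" else "")
  if (ncol(df) < 2) stop("genotype table needs an id column plus loci", call. = FALSE)
  ids <- trimws(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  calls <- vapply(df[-1], .parse_calls, character(nrow(df)), no_call = no_call)
  calls <- matrix(calls, nrow = nrow(df),
                  dimnames = list(ids, names(df)[-1]))
  .calls_to_genotype(calls)
}

#' Write a genotype matrix as canonical CSV
#'
#' Calls are written as `"A/G"` (alleles sorted), missing as `"NN"`.
#'
#' @param x a [genotype_matrix()].
#' @param file output path.
#' @export
write_genotype_table <- function(x, file) {
  cm <- calls_matrix(x)
  df <- data.frame(sample = x$sample_ids, cm, check.names = FALSE)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Genotype calls as allele-pair strings
#'
#' @param x a [genotype_matrix()].
#' @param sep separator between the two alleles.
#' @param missing token used for missing calls.
#' @return Character matrix of `"A/G"`-style calls.
#' @export
calls_matrix <- function(x, sep = "/", missing = "NN") {
  out <- matrix(missing, nrow(x$dosage), ncol(x$dosage),
                dimnames = dimnames(x$dosage))
  for (j in seq_len(ncol(out))) {
    d <- x$dosage[, j]
    a <- x$ref[j]; b <- x$alt[j]
    if (is.na(a)) next
    if (is.na(b)) b <- a
    g <- c(paste(b, b, sep = sep), paste(sort(c(a, b))[1], sort(c(a, b))[2], sep = sep),
           paste(a, a, sep = sep))
    called <- !is.na(d)
    out[called, j] <- g[d[called] + 1L]
  }
  out
}

#' Read genotypes from a minimal VCF
#'
#' Reads biallelic SNP sites from a VCF with GT fields, mapping `0/0`, `0/1`,
#' `1/1` and `./.` genotypes onto reference-allele dosages. Sites that are
#' not biallelic SNPs are dropped with a warning.
#'
#' @param file path to an (uncompressed or gzipped) VCF.
#' @return A [genotype_matrix()] with samples as rows and sites
#'   (`CHROM_POS` or the ID column when present) as loci.
#' @export
read_genotype_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # drop vcfR class quirks
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(keep))
    warning(sum(!keep), " non-biallelic-SNP site(s) dropped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  ref <- ref[keep]; alt <- alt[keep]
  ids <- fix[keep, "ID"]
  noid <- is.na(ids) | ids == "." | ids == ""
  ids[noid] <- paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"])[noid]
  gt_clean <- gsub("\\|", "/", gt)
  dos_alt <- matrix(NA_integer_, nrow(gt_clean), ncol(gt_clean))
  dos_alt[gt_clean == "0/0"] <- 0L
  dos_alt[gt_clean %in% c("0/1", "1/0")] <- 1L
  dos_alt[gt_clean == "1/1"] <- 2L
  # internal dosage counts the REF allele
  dosage <- t(2L - dos_alt)
  dimnames(dosage) <- list(colnames(gt), ids)
  genotype_matrix(dosage, ref, alt)
}
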