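# Missingness-based genotype QC: samples first, then loci, single pass,
# strict thresholds ("more than", not "at least").

#' Apply missing-call quality control
#'
#' Removes samples whose fraction of missing calls strictly exceeds
#' `sample_max_missing`, then loci whose missing fraction — recomputed on the
#' surviving samples — strictly exceeds `locus_max_missing`. Defaults mirror
#' the usual panel-genotyping practice of dropping samples with more than
#' 10\% no-calls and assays with more than 30\%.
#'
#' @param x a [genotype_matrix()].
#' @param sample_max_missing maximum tolerated missing fraction per sample.
#' @param locus_max_missing maximum tolerated missing fraction per locus.
#' @return A list of class `germdiv_qc` with elements
#'   \describe{
#'     \item{genotypes}{the filtered [genotype_matrix()], a sub-grid of the
#'       input with no call altered;}
#'     \item{report}{a list with `removed_samples` and `removed_loci` data
#'       frames (`id`, `missing_fraction`) and the thresholds used.}
#'   }
#' @export
apply_qc <- function(x, sample_max_missing = 0.10, locus_max_missing = 0.30) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (nrow(x$dosage) == 0 || ncol(x$dosage) == 0)
    stop("empty genotype matrix", call. = FALSE)

  smiss <- missing_fraction(x, "sample")
  drop_s <- smiss > sample_max_missing
  if (all(drop_s)) stop("QC removed every sample", call. = FALSE)
  kept <- x[!drop_s, ]

  lmiss <- missing_fraction(kept, "locus")
  drop_l <- lmiss > locus_max_missing
  if (all(drop_l)) stop("QC removed every locus", call. = FALSE)
  out <- kept[, !drop_l]

  report <- list(
    removed_samples = data.frame(id = x$sample_ids[drop_s],
                                 missing_fraction = unname(smiss[drop_s])),
    removed_loci = data.frame(id = kept$locus_ids[drop_l],
                              missing_fraction = unname(lmiss[drop_l])),
    sample_max_missing = sample_max_missing,
    locus_max_missing = locus_max_missing)
  structure(list(genotypes = out, report = report), class = "germdiv_qc")
}

#' @method print germdiv_qc
#' @export
print.germdiv_qc <- function(x, ...) {
  r <- x$report
  cat(sprintf("QC (sample > %.0f%%, locus > %.0f%% no-call removed):\n",
              100 * r$sample_max_missing, 100 * r$locus_max_missing))
  cat(sprintf("  removed %d sample(s), %d locus/loci; kept %d x %d\n",
              nrow(r$removed_samples), nrow(r$removed_loci),
              nrow(x$genotypes$dosage), ncol(x$genotypes$dosage)))
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param qc a `germdiv_qc` object from [apply_qc()].
#' @param file output path.
#' @export
write_qc_report <- function(qc, file) {
  stopifnot(inherits(qc, "germdiv_qc"))
  jsonlite::write_json(qc$report, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(file)
}
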