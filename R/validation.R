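#' Match a 25-mer probe against a read pool
#'
#' Scans every read and its reverse complement for full-length 25-mer
#' windows at Hamming distance 0 or 1 from the probe (the operative
#' criterion behind a blastn e-value cutoff that admits at most one
#' mismatch per 25 bp alignment; indels are not considered).  Ambiguity
#' characters in reads count as mismatches.
#'
#' @param probe_25mer character or \code{DNAString}, length 25, ACGT.
#' @param reads a \code{DNAStringSet} (or character vector) of reads.
#' @return List with \code{status} (\code{perfect}, \code{one_mismatch} or
#'   \code{none}), \code{n_perfect} and \code{n_one_mismatch} window
#'   counts across both strands.
#' @export
match_probe_to_reads <- function(probe_25mer, reads) {
  probe <- Biostrings::DNAString(as.character(probe_25mer))
  if (length(probe) != 25L) stop("match_probe_length: probe must be 25 nt")
  if (!inherits(reads, "DNAStringSet")) reads <- Biostrings::DNAStringSet(reads)
  count <- function(p, mm) {
    sum(Biostrings::vcountPattern(p, reads, max.mismatch = mm, fixed = TRUE))
  }
  rc <- Biostrings::reverseComplement(probe)
  n0 <- count(probe, 0L) + count(rc, 0L)
  n1 <- count(probe, 1L) + count(rc, 1L) - n0
  status <- if (n0 > 0L) "perfect" else if (n1 > 0L) "one_mismatch" else "none"
  list(status = status, n_perfect = n0, n_one_mismatch = n1)
}

#' Sequence-expected parent-specificity class for one probe
#'
#' A probe is expected TC-specific when it mismatches the diploid-parent
#' (AT) cDNA by one base while each polyploid read pool contains both a
#' perfect-match and a one-mismatch read (the polyploid carries both
#' homoeologous alleles); expected AT-specific when it matches the AT cDNA
#' perfectly under the same polyploid-pool condition; otherwise
#' unclassified.
#'
#' @param at,poly1,poly2 match results from
#'   \code{\link{match_probe_to_reads}} for the diploid-parent pool and
#'   the two polyploid pools.
#' @return \code{"expected_TC_specific"}, \code{"expected_AT_specific"} or
#'   \code{"unclassified"}.
#' @export
sequence_expected_class <- function(at, poly1, poly2) {
  both <- function(x) x$n_perfect >= 1L && x$n_one_mismatch >= 1L
  if (both(poly1) && both(poly2)) {
    if (at$status == "one_mismatch") return("expected_TC_specific")
    if (at$status == "perfect") return("expected_AT_specific")
  }
  "unclassified"
}

#' Sequence-concordance records for a set of called PSFs
#'
#' @param psf a \code{PsfRecord} data.frame restricted to called PSFs
#'   (class != non_PSF).
#' @param probe_seqs data.frame with \code{probeset_id},
#'   \code{probe_index}, \code{sequence}.
#' @param at_reads,poly1_reads,poly2_reads read pools
#'   (\code{DNAStringSet} or character).
#' @return A data.frame of class \code{ConcordanceRecord} with the
#'   expected class, observed d sign and concordance flag per probe.
#' @export
sequence_concordance <- function(psf, probe_seqs, at_reads, poly1_reads,
                                 poly2_reads) {
  called <- psf[psf$class != "non_PSF", , drop = FALSE]
  key <- paste(probe_seqs$probeset_id, probe_seqs$probe_index, sep = "\r")
  i <- match(paste(called$probeset_id, called$probe_index, sep = "\r"), key)
  if (anyNA(i)) stop("sequence_concordance_missing: probe sequence absent for called PSF")
  expected <- character(nrow(called))
  for (r in seq_len(nrow(called))) {
    seqr <- probe_seqs$sequence[i[r]]
    expected[r] <- sequence_expected_class(
      match_probe_to_reads(seqr, at_reads),
      match_probe_to_reads(seqr, poly1_reads),
      match_probe_to_reads(seqr, poly2_reads))
  }
  concordant <- (expected == "expected_TC_specific" & called$d > 0) |
    (expected == "expected_AT_specific" & called$d < 0)
  out <- data.frame(called[, c("probeset_id", "probe_index", "d", "class")],
                    expected_class = expected, concordant = concordant,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ConcordanceRecord", "data.frame")
  out
}

#' Empirical false-discovery percentage per observed PSF class
#'
#' @param concordance a \code{ConcordanceRecord} data.frame; rows with
#'   expected class \code{unclassified} are ignored.
#' @return Named numeric vector of percentages (discordant / classified x
#'   100, one decimal) for classes \code{AT_specific} and
#'   \code{TC_specific}; \code{NA} for an empty class.
#' @export
empirical_fdr <- function(concordance) {
  use <- concordance[concordance$expected_class != "unclassified", , drop = FALSE]
  vapply(c(AT_specific = "AT_specific", TC_specific = "TC_specific"),
         function(cl) {
           sub <- use[use$class == cl, , drop = FALSE]
           if (nrow(sub) == 0L) return(NA_real_)
           round(100 * sum(!sub$concordant) / nrow(sub), 1)
         }, numeric(1))
}

#' Experimentally determined false-positive rate from a parental RNA mix
#'
#' Computes E_p/E_t ratios for the AT, TC and MIX samples, fits the
#' one-way genotype model, and tests MIX against the in-silico mid-parent
#' value (AT + TC)/2 under BH control.  Since the mix truly contains each
#' parental transcript at half its parental level, significant probes are
#' false positives of the mid-parent test.
#'
#' @param m a \code{ProbeMatrix} containing AT, TC and MIX samples.
#' @param psf a \code{PsfRecord} data.frame of called PSFs.
#' @param samples a \code{SampleSheet}.
#' @param alpha FDR level (default 0.05).
#' @return List with \code{fraction_significant}, \code{n_significant},
#'   \code{n_tested} and the per-PSF test table.
#' @export
mix_false_positive_rate <- function(m, psf, samples, alpha = 0.05) {
  if (!any(samples$genotype == "MIX")) {
    stop("mix_fp_no_mix: no MIX samples in the sample sheet")
  }
  rt <- compute_ep_et(m, psf)
  fit <- fit_ratio_model(rt, samples, genotypes = c("AT", "TC", "MIX"))
  ctr <- list(MIX_vs_mid11 = c(AT = -1 / 2, TC = -1 / 2, MIX = 1))
  tests <- test_contrasts(fit, contrasts = ctr)
  adj <- bh_adjust(tests$p[, 1L], alpha)
  list(fraction_significant = mean(adj$significant),
       n_significant = sum(adj$significant),
       n_tested = length(adj$significant),
       table = data.frame(fit$info[, c("probeset_id", "probe_index")],
                          estimate = tests$estimate[, 1L],
                          p = tests$p[, 1L], q = adj$q,
                          significant = adj$significant,
                          stringsAsFactors = FALSE, row.names = NULL))
}

#' Efficiency-corrected qPCR starting quantity
#'
#' R0 = R_Ct (1 + E)^(-Ct): the threshold-cycle fluorescence
#' back-extrapolated to cycle zero given amplification efficiency E.
#'
#' @param r_ct fluorescence at the threshold cycle (> 0).
#' @param ct threshold cycle (>= 0).
#' @param efficiency amplification efficiency E, 0 < E <= 1.
#' @return R0, on the fluorescence scale.
#' @export
qpcr_r0 <- function(r_ct, ct, efficiency) {
  if (any(efficiency <= 0)) stop("qpcr_r0_efficiency: E must be > 0")
  if (any(r_ct <= 0)) stop("qpcr_r0_fluorescence: R_Ct must be > 0")
  r_ct * (1 + efficiency)^(-ct)
}

#' Compare reference-normalized qPCR quantities between two groups
#'
#' Each R0 is divided by its group's reference-gene (actin) R0 and
#' log-transformed; groups are compared with a pooled-variance one-tailed
#' t-test in the caller-specified direction.
#'
#' @param group1_r0,group2_r0 R0 replicate vectors (length >= 2).
#' @param ref1_r0,ref2_r0 reference-gene R0 values for each group
#'   (scalar or per-replicate).
#' @param direction alternative hypothesis for group1 relative to group2:
#'   \code{"greater"} or \code{"less"}.
#' @return List with \code{p}, \code{t}, \code{df}, \code{estimate}
#'   (difference of log means) and a \code{degenerate} flag set when the
#'   pooled variance is zero (p is then 0, 1 or 0.5 by the sign of the
#'   difference).
#' @export
qpcr_compare <- function(group1_r0, group2_r0, ref1_r0, ref2_r0,
                         direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (any(c(ref1_r0, ref2_r0) <= 0)) stop("qpcr_compare_reference: reference R0 must be > 0")
  x <- log(group1_r0 / ref1_r0)
  y <- log(group2_r0 / ref2_r0)
  if (length(x) < 2L || length(y) < 2L) stop("qpcr_compare_replicates: need >= 2 replicates per group")
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  est <- mean(x) - mean(y)
  if (sp2 == 0) {
    signed <- if (direction == "greater") est else -est
    p <- if (signed > 0) 0 else if (signed < 0) 1 else 0.5
    return(list(p = p, t = NA_real_, df = df, estimate = est, degenerate = TRUE))
  }
  tval <- est / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- if (direction == "greater") stats::pt(tval, df, lower.tail = FALSE)
       else stats::pt(tval, df)
  list(p = p, t = tval, df = df, estimate = est, degenerate = FALSE)
}
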