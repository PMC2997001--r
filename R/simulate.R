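#' Simulation configuration for a probe-level allopolyploid experiment
#'
#' The generator emulates a two-parent design: a diploid parent (AT), a
#' tetraploid parent (TC), their synthetic allopolyploid (SN) and a 1:1
#' RNA mix (MIX), hybridized to probesets of short-oligo probes.  A
#' parent-specific feature (PSF) hybridizes with the mismatched parental
#' transcript pool at reduced efficiency 2^-delta.
#'
#' @param n_probesets number of simulated genes/probesets.
#' @param probes_per_probeset probes per probeset (default 11).
#' @param replicates biological replicates per genotype (default 4).
#' @param psf_count_probs probabilities of 0..4 PSFs per probeset.
#' @param class_balance probability a PSF is TC-specific (default 0.5).
#' @param mismatch_penalty_range range of the cross-hybridization penalty
#'   delta in log2 units (default uniform on [0.5, 2]).
#' @param baseline_mean,baseline_sd log2 baseline expression distribution
#'   (default Normal(8, 1.5^2)).
#' @param parental_divergence_fraction fraction of genes with divergent
#'   parental expression (default 0.5).
#' @param divergence_sd sd of the log2 parental expression difference
#'   (default 1).
#' @param nonadditive_fraction fraction of genes with a non-additive
#'   genome contribution in SN (default 0.2).
#' @param shift_size magnitude of the non-additive log2 shift applied to
#'   one genome's SN contribution, sign drawn at random (default 1).
#' @param sn_dosage_model \code{"1to1"} (AT and TC contribute equally) or
#'   \code{"1to2"} (TC contributes two parts).
#' @param noise_sigma log2-scale Gaussian measurement noise sd (default 0.15).
#' @param affinity_sd sd of per-probe log2 affinity offsets (default 0.7).
#' @param mix_model \code{"linear"}: MIX intensities arise from the
#'   physical mix of transcript pools, (AT + TC)/2 on the linear scale
#'   (the study condition); \code{"log_mid"}: MIX probe values are placed
#'   at the midpoint of the parental log2 values, the idealized data for
#'   which the ratio-scale mid-parent null is exactly true (used for null
#'   calibration of the mix false-positive rate).
#' @param seed mandatory integer seed.
#' @return A list of class \code{SimConfig}.
#' @export
sim_config <- function(n_probesets = 2000L, probes_per_probeset = 11L,
                       replicates = 4L,
                       psf_count_probs = c(0.35, 0.25, 0.20, 0.12, 0.08),
                       class_balance = 0.5,
                       mismatch_penalty_range = c(0.5, 2),
                       baseline_mean = 8, baseline_sd = 1.5,
                       parental_divergence_fraction = 0.5,
                       divergence_sd = 1,
                       nonadditive_fraction = 0.2,
                       shift_size = 1,
                       sn_dosage_model = c("1to1", "1to2"),
                       noise_sigma = 0.15,
                       affinity_sd = 0.7,
                       mix_model = c("linear", "log_mid"),
                       seed) {
  sn_dosage_model <- match.arg(sn_dosage_model)
  mix_model <- match.arg(mix_model)
  if (missing(seed)) stop("sim_config_seed: a seed is mandatory")
  stopifnot(length(psf_count_probs) == 5L,
            abs(sum(psf_count_probs) - 1) < 1e-8,
            all(mismatch_penalty_range > 0),
            parental_divergence_fraction >= 0, parental_divergence_fraction <= 1,
            nonadditive_fraction >= 0, nonadditive_fraction <= 1,
            noise_sigma >= 0)
  structure(as.list(environment()), class = "SimConfig")
}

#' Generate a probe-level experiment with known ground truth
#'
#' Parental transcript levels are drawn per gene; SN genome contributions
#' follow the dosage model, multiplied by 2^shift for non-additive genes;
#' MIX is the exact linear mid-parent.  A PSF probe's linear signal is
#' 2^affinity x (matched-pool abundance + 2^-delta x mismatched-pool
#' abundance); non-PSF probes see the total pool.  Observed log2 intensity
#' adds Gaussian noise.  Fully reproducible given the seed.
#'
#' @param config a \code{SimConfig}.
#' @return List with \code{probes} (log2-scale \code{ProbeMatrix}),
#'   \code{samples} (\code{SampleSheet}) and \code{truth} (list with
#'   per-probe and per-gene tables and the noiseless per-genotype log2
#'   values).
#' @export
generate_experiment <- function(config) {
  set.seed(config$seed)
  n <- config$n_probesets
  k <- config$probes_per_probeset
  reps <- config$replicates

  ps_id <- sprintf("ps%05d", seq_len(n))
  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  at_level <- 2^baseline
  divergent <- stats::runif(n) < config$parental_divergence_fraction
  div_effect <- ifelse(divergent, stats::rnorm(n, 0, config$divergence_sd), 0)
  tc_level <- 2^(baseline + div_effect)

  nonadd <- stats::runif(n) < config$nonadditive_fraction
  shifted_genome <- ifelse(nonadd, sample(c("AT", "TC"), n, replace = TRUE), NA)
  shift <- ifelse(nonadd, sample(c(-1, 1), n, replace = TRUE) * config$shift_size, 0)

  w <- if (config$sn_dosage_model == "1to1") c(1 / 2, 1 / 2) else c(1 / 3, 2 / 3)
  shift_at <- ifelse(nonadd & !is.na(shifted_genome) & shifted_genome == "AT", shift, 0)
  shift_tc <- ifelse(nonadd & !is.na(shifted_genome) & shifted_genome == "TC", shift, 0)
  sn_at <- w[1] * at_level * 2^shift_at
  sn_tc <- w[2] * tc_level * 2^shift_tc

  n_psf <- sample(0:4, n, replace = TRUE, prob = config$psf_count_probs)
  gene_of <- rep(seq_len(n), each = k)
  probe_index <- rep(seq_len(k), n)
  is_psf <- logical(n * k)
  for (g in seq_len(n)) {
    if (n_psf[g] > 0L) {
      is_psf[(g - 1L) * k + sample.int(k, n_psf[g])] <- TRUE
    }
  }
  class <- rep("non_PSF", n * k)
  class[is_psf] <- ifelse(stats::runif(sum(is_psf)) < config$class_balance,
                          "TC_specific", "AT_specific")
  delta <- rep(NA_real_, n * k)
  delta[is_psf] <- stats::runif(sum(is_psf), config$mismatch_penalty_range[1],
                                config$mismatch_penalty_range[2])
  affinity <- stats::rnorm(n * k, 0, config$affinity_sd)

  # Per-genotype transcript pools (linear scale) indexed by gene.
  pools <- list(AT = cbind(at_level, 0),
                TC = cbind(0, tc_level),
                SN = cbind(sn_at, sn_tc),
                MIX = cbind(at_level / 2, tc_level / 2))

  probe_signal <- function(p_at, p_tc) {
    sig <- p_at + p_tc
    atp <- class == "AT_specific"
    tcp <- class == "TC_specific"
    sig[atp] <- p_at[atp] + 2^(-delta[atp]) * p_tc[atp]
    sig[tcp] <- p_tc[tcp] + 2^(-delta[tcp]) * p_at[tcp]
    2^affinity * sig
  }
  noiseless <- vapply(pools, function(pl) {
    log2(probe_signal(pl[gene_of, 1L], pl[gene_of, 2L]))
  }, numeric(n * k))
  if (config$mix_model == "log_mid") {
    noiseless[, "MIX"] <- (noiseless[, "AT"] + noiseless[, "TC"]) / 2
  }

  genotypes <- c("AT", "TC", "SN", "MIX")
  samples <- SampleSheet(
    sample_id = paste(rep(genotypes, each = reps), seq_len(reps), sep = "_"),
    genotype = rep(genotypes, each = reps),
    replicate = rep(seq_len(reps), 4L))
  x <- noiseless[, samples$genotype, drop = FALSE]
  if (config$noise_sigma > 0) {
    x <- x + stats::rnorm(length(x), 0, config$noise_sigma)
  }
  colnames(x) <- samples$sample_id
  pm <- ProbeMatrix(x, ps_id[gene_of], probe_index, scale = "log2")

  truth <- list(
    probes = data.frame(probeset_id = ps_id[gene_of], probe_index = probe_index,
                        is_psf = is_psf, class = class, delta = delta,
                        affinity = affinity, stringsAsFactors = FALSE),
    genes = data.frame(probeset_id = ps_id, at_level = at_level,
                       tc_level = tc_level, sn_at = sn_at, sn_tc = sn_tc,
                       divergent = divergent, div_effect = div_effect,
                       nonadditive = nonadd, shifted_genome = shifted_genome,
                       shift = shift,
                       category = ifelse(nonadd, "non_additive", "mid_parent"),
                       direction = ifelse(nonadd, ifelse(shift > 0, "up", "down"),
                                          "none"),
                       stringsAsFactors = FALSE),
    noiseless = noiseless)
  list(probes = pm, samples = samples, truth = truth)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substitute_base <- function(seq, pos) {
  base <- substr(seq, pos, pos)
  repl <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
  paste0(substr(seq, 1L, pos - 1L), repl, substr(seq, pos + 1L, nchar(seq)))
}

embed_read <- function(allele, read_length) {
  flank <- read_length - nchar(allele)
  lead <- sample.int(flank + 1L, 1L) - 1L
  read <- paste0(if (lead > 0L) random_dna(lead) else "",
                 allele,
                 if (flank - lead > 0L) random_dna(flank - lead) else "")
  if (stats::runif(1) < 0.5) {
    read <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  }
  read
}

#' Generate probe sequences and matched cDNA read pools
#'
#' Emulates the sequence-validation inputs: each probe gets a random
#' 25-mer; a PSF probe's two parental alleles differ by one substitution
#' at a uniform position.  The diploid-parent pool carries the AT allele;
#' each polyploid pool carries both alleles (so it contains a
#' perfect-match and a one-mismatch read for every PSF).  Reads embed the
#' allele at a random offset on a random strand.
#'
#' @param truth the \code{truth} element of
#'   \code{\link{generate_experiment}} output (or any data.frame-bearing
#'   list with a \code{probes} table).
#' @param reads_per_pool reads emitted per allele per pool (default 1).
#' @param read_length read length (>= 25; default 60).
#' @param seed integer seed.
#' @param psf_only generate reads only for PSF probes (default TRUE).
#' @return List with \code{probe_seqs} (probeset_id, probe_index,
#'   sequence) and \code{DNAStringSet} pools \code{at}, \code{poly1},
#'   \code{poly2}.
#' @export
generate_reads <- function(truth, reads_per_pool = 1L, read_length = 60L,
                           seed = 1L, psf_only = TRUE) {
  stopifnot(read_length >= 25L)
  set.seed(seed)
  pr <- truth$probes
  if (psf_only) pr <- pr[pr$is_psf, , drop = FALSE]
  n <- nrow(pr)
  seqs <- character(n)
  at_reads <- list(); poly1 <- list(); poly2 <- list()
  for (i in seq_len(n)) {
    probe <- random_dna(25L)
    seqs[i] <- probe
    if (pr$is_psf[i]) {
      other <- substitute_base(probe, sample.int(25L, 1L))
      if (pr$class[i] == "AT_specific") {
        at_allele <- probe          # probe matches the diploid parent
      } else {
        at_allele <- other          # probe matches the tetraploid parent
      }
      alleles_poly <- c(probe, other)
    } else {
      at_allele <- probe
      alleles_poly <- probe
    }
    key <- paste0(pr$probeset_id[i], "_p", pr$probe_index[i])
    for (r in seq_len(reads_per_pool)) {
      at_reads[[paste0(key, "_at", r)]] <- embed_read(at_allele, read_length)
      for (a in seq_along(alleles_poly)) {
        poly1[[paste0(key, "_c", a, "_", r)]] <- embed_read(alleles_poly[a], read_length)
        poly2[[paste0(key, "_j", a, "_", r)]] <- embed_read(alleles_poly[a], read_length)
      }
    }
  }
  list(probe_seqs = data.frame(probeset_id = pr$probeset_id,
                               probe_index = pr$probe_index,
                               sequence = seqs, stringsAsFactors = FALSE),
       at = Biostrings::DNAStringSet(unlist(at_reads)),
       poly1 = Biostrings::DNAStringSet(unlist(poly1)),
       poly2 = Biostrings::DNAStringSet(unlist(poly2)))
}

#' Score pipeline calls against simulation truth
#'
#' @param psf_calls a \code{PsfRecord} data.frame covering every simulated
#'   probe.
#' @param expression_calls an \code{ExpressionCall} data.frame (may cover
#'   a subset of PSFs), or NULL.
#' @param truth the \code{truth} element of
#'   \code{\link{generate_experiment}} output.
#' @return List of metrics: PSF \code{sensitivity}, \code{realized_fdr} and
#'   \code{class_accuracy}; and, when expression calls are given,
#'   \code{additive_midparent_rate} (fraction of PSFs in additive genes
#'   called strictly mid_parent), \code{nonadditive_detection_rate} and
#'   \code{direction_accuracy} for PSFs tracking the shifted genome, and
#'   the category \code{confusion} table.  PSFs of non-additive genes that
#'   track the unshifted genome have no deterministic truth category and
#'   are excluded from category scoring.
#' @export
truth_evaluation <- function(psf_calls, expression_calls, truth) {
  key_t <- paste(truth$probes$probeset_id, truth$probes$probe_index, sep = "\r")
  key_c <- paste(psf_calls$probeset_id, psf_calls$probe_index, sep = "\r")
  i <- match(key_c, key_t)
  if (anyNA(i)) stop("truth_evaluation_keys: calls contain probes absent from truth")
  tp <- truth$probes[i, , drop = FALSE]
  called <- psf_calls$class != "non_PSF"
  out <- list(
    sensitivity = if (any(tp$is_psf)) mean(called[tp$is_psf]) else NA_real_,
    realized_fdr = if (any(called)) mean(!tp$is_psf[called]) else 0,
    class_accuracy = if (any(called & tp$is_psf)) {
      mean(psf_calls$class[called & tp$is_psf] == tp$class[called & tp$is_psf])
    } else NA_real_)

  if (!is.null(expression_calls)) {
    key_e <- paste(expression_calls$probeset_id, expression_calls$probe_index,
                   sep = "\r")
    it <- match(key_e, key_t)
    if (anyNA(it)) stop("truth_evaluation_keys: expression calls absent from truth")
    tpe <- truth$probes[it, , drop = FALSE]
    ig <- match(tpe$probeset_id, truth$genes$probeset_id)
    gene <- truth$genes[ig, , drop = FALSE]
    genome <- ifelse(tpe$class == "AT_specific", "AT", "TC")
    truth_cat <- ifelse(!gene$nonadditive, "mid_parent",
                        ifelse(genome == gene$shifted_genome, "non_additive", NA))
    add <- !is.na(truth_cat) & truth_cat == "mid_parent" & tpe$is_psf
    shifted <- !is.na(truth_cat) & truth_cat == "non_additive" & tpe$is_psf
    out$additive_midparent_rate <-
      if (any(add)) mean(expression_calls$category[add] == "mid_parent") else NA_real_
    out$nonadditive_detection_rate <-
      if (any(shifted)) mean(expression_calls$category[shifted] == "non_additive") else NA_real_
    hit <- shifted & expression_calls$category == "non_additive"
    out$direction_accuracy <-
      if (any(hit)) mean(expression_calls$direction[hit] == gene$direction[hit]) else NA_real_
    scored <- !is.na(truth_cat) & tpe$is_psf
    out$confusion <- table(truth = truth_cat[scored],
                           called = expression_calls$category[scored])
  }
  out
}
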