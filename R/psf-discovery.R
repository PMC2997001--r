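#' Configuration for SAM-style feature calling
#'
#' @param delta threshold applied to the departure of observed from
#'   permutation-expected d-statistics (>= 0).
#' @param s0_method fudge-factor rule: \code{"percentile"} (a fixed
#'   percentile of the per-probe standard errors, deterministic and cheap)
#'   or \code{"cv_minimization"} (search over s-percentiles minimizing the
#'   coefficient of variation of the median absolute d across s-quantile
#'   windows).
#' @param s0_percentile percentile used by the percentile rule (default 5).
#' @param permutations \code{"all"} to enumerate every balanced label
#'   assignment, or an integer count of sampled permutations (>= 10).
#' @param seed integer seed used when permutations are sampled.
#' @param target_fdr optional target false discovery rate; when set,
#'   \code{sam_call} scans a delta grid (step 0.01) for the smallest delta
#'   whose estimated FDR is at or below the target.
#' @param pi0 \code{"estimate"} for the interquartile-range estimate of the
#'   null proportion, or \code{"one"} to leave the permutation FDR unscaled.
#' @return A list of class \code{SamConfig}.
#' @export
sam_config <- function(delta = 0.2, s0_method = c("percentile", "cv_minimization"),
                       s0_percentile = 5, permutations = "all", seed = 1L,
                       target_fdr = NULL, pi0 = c("estimate", "one")) {
  s0_method <- match.arg(s0_method)
  pi0 <- match.arg(pi0)
  if (delta < 0) stop("sam_config_delta: delta must be >= 0")
  if (!identical(permutations, "all")) {
    permutations <- as.integer(permutations)
    if (permutations < 10L) stop("sam_config_permutations: sampled permutations must be >= 10")
  }
  structure(list(delta = delta, s0_method = s0_method,
                 s0_percentile = s0_percentile, permutations = permutations,
                 seed = as.integer(seed), target_fdr = target_fdr, pi0 = pi0),
            class = "SamConfig")
}

#' Mutation-budget configuration for probeset filtering
#'
#' Defaults correspond to neutral divergence between the diploid ancestors
#' of the wheat genomes: rate 5.5e-9 per site per year over 2.7 million
#' years across the 275 bp covered by 11 x 25-mer probes.
#'
#' @param mutation_rate substitutions per site per year.
#' @param divergence_time years since divergence of the parental lineages.
#' @param probeset_length interrogated bases per probeset (bp).
#' @param max_psf maximum PSFs retained per probeset.
#' @return A list of class \code{MutationBudgetConfig}.
#' @export
mutation_budget_config <- function(mutation_rate = 5.5e-9,
                                   divergence_time = 2.7e6,
                                   probeset_length = 275,
                                   max_psf = 4L) {
  stopifnot(mutation_rate >= 0, divergence_time > 0, probeset_length > 0,
            max_psf >= 1L)
  structure(list(mutation_rate = mutation_rate,
                 divergence_time = divergence_time,
                 probeset_length = probeset_length,
                 max_psf = as.integer(max_psf)),
            class = "MutationBudgetConfig")
}

#' Expected divergent mutations per probeset
#'
#' @param budget a \code{MutationBudgetConfig}.
#' @return List with \code{expected} (rate x time x length) and
#'   \code{budget_integer} (its floor), the per-probeset PSF cap.
#' @export
expected_mutations <- function(budget = mutation_budget_config()) {
  expected <- budget$mutation_rate * budget$divergence_time * budget$probeset_length
  list(expected = expected, budget_integer = as.integer(floor(expected)))
}

#' Fit the additive probe + genotype model to parental probe data
#'
#' For each probeset, fits Y = mu + probe_i + genotype_j + error by least
#' squares to the log2 intensities of the two parental genotypes.  The
#' residuals carry the probe-by-genotype interaction that flags features
#' hybridizing differentially with the two parents.  For balanced designs
#' the closed form fitted(i,j) = probe_mean_i + genotype_mean_j -
#' grand_mean is used; unbalanced designs fall back to a generic
#' per-probeset least-squares fit with a warning.
#'
#' @param m a log2-scale \code{ProbeMatrix}.
#' @param samples a \code{SampleSheet}; only the genotypes in
#'   \code{genotypes} are used.
#' @param genotypes the two genotypes contrasted (default \code{AT}, \code{TC}).
#' @return A list of class \code{ProbeModelFit} with per-observation
#'   \code{residuals} and \code{fitted} matrices (probes x used samples),
#'   the column genotype assignment, and per-probeset effect estimates.
#' @export
fit_probe_model <- function(m, samples, genotypes = c("AT", "TC")) {
  if (m$scale != "log2") stop("fit_probe_model_scale: input must be log2 scale")
  use <- samples[samples$genotype %in% genotypes, , drop = FALSE]
  if (!all(genotypes %in% use$genotype)) {
    stop("fit_probe_model_genotypes: both genotypes must be present")
  }
  x <- m$intensity[, use$sample_id, drop = FALSE]
  geno <- use$genotype
  nrep <- table(geno)
  sets <- m$probeset_id
  set_f <- factor(sets, levels = unique(sets))
  k <- probes_per_set(m)

  if (length(unique(as.integer(nrep))) == 1L) {
    probe_mean <- rowMeans(x)
    gm <- lapply(genotypes, function(g) {
      rowsum(rowSums(x[, geno == g, drop = FALSE]), set_f) /
        (k * sum(geno == g))
    })
    names(gm) <- genotypes
    grand <- rowsum(rowSums(x), set_f) / (k * length(geno))
    fitted <- matrix(probe_mean, nrow(x), ncol(x))
    for (g in genotypes) {
      fitted[, geno == g] <- fitted[, geno == g] +
        (gm[[g]][as.integer(set_f)] - grand[as.integer(set_f)])
    }
  } else {
    warning("fit_probe_model: unbalanced design; using generic least squares")
    fitted <- x * NA_real_
    gf <- factor(geno, levels = genotypes)
    for (s in levels(set_f)) {
      rows <- which(set_f == s)
      sub <- x[rows, , drop = FALSE]
      long <- data.frame(y = as.vector(sub),
                         probe = factor(rep(seq_along(rows), ncol(sub))),
                         geno = rep(gf, each = length(rows)))
      fit <- stats::lm(y ~ probe + geno, data = long)
      fitted[rows, ] <- matrix(stats::fitted(fit), length(rows))
    }
  }
  dimnames(fitted) <- dimnames(x)
  structure(list(residuals = x - fitted, fitted = fitted,
                 genotype = geno, probeset_id = sets,
                 probe_index = m$probe_index, genotypes = genotypes),
            class = "ProbeModelFit")
}

#' SAM d-statistic for one probe
#'
#' d = (mean(TC) - mean(AT)) / (s + s0) with the pooled standard error
#' s = sqrt[(1/n1 + 1/n2) (SS_AT + SS_TC) / (n1 + n2 - 2)].  Features
#' hybridizing more strongly with the tetraploid parent have d > 0.
#'
#' @param residuals_AT,residuals_TC residual vectors (length >= 2 each).
#' @param s0 fudge factor added to the denominator.
#' @return The d-statistic.
#' @export
sam_d_statistic <- function(residuals_AT, residuals_TC, s0) {
  n1 <- length(residuals_AT); n2 <- length(residuals_TC)
  if (n1 < 1L || n2 < 1L) stop("sam_d_zero_group: empty group")
  ss <- sum((residuals_AT - mean(residuals_AT))^2) +
    sum((residuals_TC - mean(residuals_TC))^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  (mean(residuals_TC) - mean(residuals_AT)) / (s + s0)
}

# Vectorized numerator and pooled SE over all probes for one label assignment.
# tc_cols indexes the columns treated as the TC group.
d_components <- function(res, tc_cols) {
  at <- res[, -tc_cols, drop = FALSE]
  tc <- res[, tc_cols, drop = FALSE]
  n1 <- ncol(at); n2 <- ncol(tc)
  ma <- rowMeans(at); mt <- rowMeans(tc)
  ss <- rowSums((at - ma)^2) + rowSums((tc - mt)^2)
  list(num = mt - ma,
       s = sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2)))
}

#' Estimate the SAM fudge factor s0
#'
#' @param numerators per-probe d numerators (group mean differences); used
#'   only by the \code{cv_minimization} rule.
#' @param s per-probe pooled standard errors.
#' @param config a \code{SamConfig}.
#' @return The estimated s0.
#' @export
estimate_s0 <- function(numerators, s, config = sam_config()) {
  if (length(s) < 10L) stop("estimate_s0_few_probes: need >= 10 probes")
  if (config$s0_method == "percentile") {
    return(stats::quantile(s, config$s0_percentile / 100, names = FALSE, type = 7))
  }
  alphas <- seq(0, 1, by = 0.05)
  qs <- stats::quantile(s, alphas, names = FALSE, type = 7)
  nwin <- if (length(s) >= 1000L) 100L else 10L
  win <- cut(rank(s, ties.method = "first"), nwin, labels = FALSE)
  cv <- vapply(qs, function(s0) {
    d <- numerators / (s + s0)
    v <- vapply(split(abs(d), win), stats::median, numeric(1))
    stats::sd(v) / mean(v)
  }, numeric(1))
  qs[which.min(cv)]
}

balanced_assignments <- function(n1, n2, permutations, seed) {
  n <- n1 + n2
  if (identical(permutations, "all")) {
    utils::combn(n, n2, simplify = FALSE)
  } else {
    set.seed(seed)
    replicate(permutations, sort(sample.int(n, n2)), simplify = FALSE)
  }
}

#' SAM significance calling against permutation-expected d-statistics
#'
#' Probes are ordered by observed d and compared with the rank-wise mean of
#' the sorted permuted d-statistics.  On the upper side the smallest
#' observed d whose excess over its expected value exceeds delta defines
#' the cut point; it and all larger d are called significant (symmetric on
#' the lower side).  The estimated FDR is pi0 times the median, over
#' permutations, of the count of permuted d beyond the cut points divided
#' by the number called.  pi0 is estimated as min(1, #observed d inside the
#' interquartile range of the permuted d / (0.5 x #probes)).
#'
#' @param d observed d-statistics (one per probe).
#' @param perm_d matrix of permuted d-statistics, probes x permutations,
#'   each column one genotype-label permutation applied to every probe.
#' @param config a \code{SamConfig}; when \code{target_fdr} is set, delta
#'   is the smallest grid value (step 0.01) meeting the target.
#' @param info optional data.frame with \code{probeset_id} and
#'   \code{probe_index} aligned with \code{d}.
#' @return A data.frame of class \code{PsfRecord} with columns
#'   \code{probeset_id}, \code{probe_index}, \code{d}, \code{expected_d},
#'   \code{significant}, \code{class}, and attributes
#'   \code{estimated_fdr}, \code{delta}, \code{pi0}, \code{cut_points}.
#' @export
sam_call <- function(d, perm_d, config = sam_config(), info = NULL) {
  stopifnot(nrow(perm_d) == length(d))
  ord <- order(d)
  d_sorted <- d[ord]
  perm_sorted <- apply(perm_d, 2L, sort)
  expected <- rowMeans(perm_sorted)

  if (config$pi0 == "one") {
    pi0 <- 1
  } else {
    qs <- stats::quantile(perm_d, c(0.25, 0.75), names = FALSE)
    pi0 <- min(1, sum(d >= qs[1] & d <= qs[2]) / (0.5 * length(d)))
  }

  eval_delta <- function(delta) {
    up <- which(d_sorted > 0 & d_sorted - expected > delta)
    lo <- which(d_sorted < 0 & expected - d_sorted > delta)
    cutup <- if (length(up)) d_sorted[min(up)] else Inf
    cutlow <- if (length(lo)) d_sorted[max(lo)] else -Inf
    called <- d_sorted >= cutup | d_sorted <= cutlow
    n_called <- sum(called)
    fdr <- if (n_called == 0L) NaN else {
      false <- apply(perm_d, 2L, function(p) sum(p >= cutup | p <= cutlow))
      min(1, pi0 * stats::median(false) / n_called)
    }
    list(cutup = cutup, cutlow = cutlow, called = called,
         n_called = n_called, fdr = fdr)
  }

  delta <- config$delta
  if (!is.null(config$target_fdr)) {
    grid <- seq(0.01, max(abs(d_sorted - expected)) + 0.01, by = 0.01)
    delta <- grid[length(grid)]
    for (g in grid) {
      r <- eval_delta(g)
      if (!is.nan(r$fdr) && r$fdr <= config$target_fdr) { delta <- g; break }
      if (r$n_called == 0L) { delta <- g; break }
    }
  }
  res <- eval_delta(delta)

  significant <- logical(length(d))
  significant[ord] <- res$called
  expected_by_probe <- numeric(length(d))
  expected_by_probe[ord] <- expected

  if (is.null(info)) {
    info <- data.frame(probeset_id = NA_character_,
                       probe_index = seq_along(d))
  }
  records <- data.frame(probeset_id = info$probeset_id,
                        probe_index = info$probe_index,
                        d = d, expected_d = expected_by_probe,
                        significant = significant,
                        stringsAsFactors = FALSE)
  records <- classify_psf(records)
  attr(records, "estimated_fdr") <- res$fdr
  attr(records, "delta") <- delta
  attr(records, "pi0") <- pi0
  attr(records, "cut_points") <- c(lower = res$cutlow, upper = res$cutup)
  class(records) <- c("PsfRecord", "data.frame")
  records
}

#' Assign parent-specificity classes to called features
#'
#' Significant features with d < 0 hybridize more strongly with the
#' diploid parent (AT-specific); significant features with d > 0 with the
#' tetraploid parent (TC-specific).
#'
#' @param records data.frame with columns \code{d} and \code{significant}.
#' @return The records with a \code{class} column added, one of
#'   \code{AT_specific}, \code{TC_specific}, \code{non_PSF}.
#' @export
classify_psf <- function(records) {
  cls <- rep("non_PSF", nrow(records))
  cls[records$significant & records$d < 0] <- "AT_specific"
  cls[records$significant & records$d > 0] <- "TC_specific"
  if (any(records$significant & records$d == 0)) {
    warning("classify_psf: significant feature with d = 0 classified non_PSF")
  }
  records$class <- cls
  records
}

#' Filter probesets by PSF count
#'
#' Drops probesets carrying more PSFs than the mutation budget allows
#' (divergent members of multigene families) and probesets whose probes are
#' all PSFs (a gene silenced or weakly expressed in one parent makes every
#' probe look parent-specific).
#'
#' @param records a \code{PsfRecord} data.frame covering whole probesets.
#' @param budget a \code{MutationBudgetConfig}.
#' @return List with \code{retained} (probeset ids kept),
#'   \code{records} (records restricted to retained probesets),
#'   \code{n_dropped_budget} and \code{n_dropped_all_psf}.
#' @export
filter_probesets <- function(records, budget = mutation_budget_config()) {
  k <- table(records$probeset_id)
  npsf <- tapply(records$class != "non_PSF", records$probeset_id, sum)
  sets <- names(npsf)
  all_psf <- npsf == as.integer(k[sets])
  over <- npsf > budget$max_psf & !all_psf
  keep <- sets[!all_psf & !over]
  list(retained = keep,
       records = records[records$probeset_id %in% keep, , drop = FALSE],
       n_dropped_budget = sum(over),
       n_dropped_all_psf = sum(all_psf))
}

# Residuals with the genotype effect re-estimated from a reference subset
# of probes per probeset (typically the currently-non-PSF probes), so that
# strong parent-specific probes no longer leak interaction signal into
# their probeset neighbours through the additive fit.
reference_residuals <- function(x, geno, set_f, use_ref) {
  genotypes <- unique(geno)
  k_ref <- as.numeric(rowsum(as.numeric(use_ref), set_f))
  res <- x - rowMeans(x)
  for (g in genotypes) {
    cols <- geno == g
    gm <- rowsum(rowSums(res[, cols, drop = FALSE]) * as.numeric(use_ref), set_f) /
      (pmax(k_ref, 1L) * sum(cols))
    gm[k_ref == 0L] <- 0   # probeset entirely PSF: nothing to reference
    res[, cols] <- res[, cols] - gm[as.integer(set_f)]
  }
  res
}

run_sam <- function(res, geno, info, config) {
  tc_cols <- which(geno == "TC")
  obs <- d_components(res, tc_cols)
  s0 <- estimate_s0(obs$num, obs$s, config)
  d <- obs$num / (obs$s + s0)
  perms <- balanced_assignments(sum(geno == "AT"), length(tc_cols),
                                config$permutations, config$seed)
  perm_d <- vapply(perms, function(cols) {
    p <- d_components(res, cols)
    p$num / (p$s + s0)
  }, numeric(nrow(res)))
  rec <- sam_call(d, perm_d, config, info = info)
  attr(rec, "s0") <- s0
  rec
}

#' Discover parent-specific features from parental probe data
#'
#' End-to-end wrapper: fits the additive probe + genotype model, computes
#' per-probe d-statistics on the residuals, generates the permutation null
#' (all balanced label assignments when feasible), and applies the SAM cut
#' rule.
#'
#' With \code{refine = TRUE} (default) a second pass follows: the genotype
#' effect of each probeset is re-estimated using only the probes not
#' called in the first pass, and the d-statistics and the SAM call are
#' recomputed on those residuals.  Under the plain additive fit a strong
#' PSF leaks part of its probe-by-genotype interaction into every other
#' probe of its probeset (a shift of order the summed mismatch penalties
#' divided by the probe count), and the permutation null cannot see this
#' leakage, so neighbouring probes surface as spurious PSFs.  Referencing
#' the genotype effect on non-PSF probes only — the same move the
#' E_p/E_t ratio makes when it divides by the non-PSF mean — removes the
#' leakage while leaving genuine PSFs untouched.
#'
#' @param m a log2-scale \code{ProbeMatrix} containing the parental samples.
#' @param samples a \code{SampleSheet}.
#' @param config a \code{SamConfig}.
#' @param refine logical; run the leakage-correcting refinement passes.
#' @param max_refine maximum refinement passes (iteration stops earlier
#'   once the call set is stable).
#' @return A \code{PsfRecord} data.frame (see \code{\link{sam_call}}).
#' @export
discover_psf <- function(m, samples, config = sam_config(), refine = TRUE,
                         max_refine = 5L) {
  fit <- fit_probe_model(m, samples)
  info <- data.frame(probeset_id = fit$probeset_id,
                     probe_index = fit$probe_index,
                     stringsAsFactors = FALSE)
  rec <- run_sam(fit$residuals, fit$genotype, info, config)
  if (refine) {
    x <- m$intensity[, samples$sample_id[samples$genotype %in% fit$genotypes],
                     drop = FALSE]
    set_f <- factor(fit$probeset_id, levels = unique(fit$probeset_id))
    for (pass in seq_len(max_refine)) {
      if (!any(rec$significant)) break
      prev <- rec$significant
      res <- reference_residuals(x, fit$genotype, set_f, !prev)
      rec <- run_sam(res, fit$genotype, info, config)
      if (identical(rec$significant, prev)) break
    }
  }
  rec
}
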