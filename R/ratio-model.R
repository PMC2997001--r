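#' Compute E_p/E_t intensity ratios for parent-specific features
#'
#' For every PSF probe, the contribution of the matched parental genome to
#' total gene expression is estimated as the log2 ratio of the PSF's
#' intensity E_p to the averaged intensity E_t of the probeset's remaining
#' non-PSF probes: ratio = log2(E_p) - log2(E_t).  The average is taken on
#' the linear intensity scale by default (the log of a mean intensity), with
#' a log-scale mean available for sensitivity analysis.
#'
#' @param m a \code{ProbeMatrix} (linear or log2; converted internally).
#' @param psf a \code{PsfRecord} data.frame with columns
#'   \code{probeset_id}, \code{probe_index}, \code{class}.
#' @param e_bar_scale averaging scale for the non-PSF mean,
#'   \code{"linear"} (default) or \code{"log2"}.
#' @return A list of class \code{RatioTable}: \code{ratios} (PSF x sample
#'   matrix of log2 ratios), \code{info} (probeset_id, probe_index,
#'   psf_class, m_nonpsf), and \code{n_excluded} probesets that had no
#'   non-PSF probe left.
#' @export
compute_ep_et <- function(m, psf, e_bar_scale = c("linear", "log2")) {
  e_bar_scale <- match.arg(e_bar_scale)
  lin <- if (m$scale == "log2") 2^m$intensity else m$intensity

  key_m <- paste(m$probeset_id, m$probe_index, sep = "\r")
  psf_rows <- psf[psf$class != "non_PSF", , drop = FALSE]
  is_psf <- key_m %in% paste(psf_rows$probeset_id, psf_rows$probe_index, sep = "\r")

  set_f <- factor(m$probeset_id, levels = unique(m$probeset_id))
  n_nonpsf <- as.integer(rowsum(as.integer(!is_psf), set_f))
  names(n_nonpsf) <- levels(set_f)

  if (e_bar_scale == "linear") {
    sums <- rowsum(lin * as.numeric(!is_psf), set_f)
    ebar <- sums / n_nonpsf
  } else {
    sums <- rowsum(log2(lin) * as.numeric(!is_psf), set_f)
    ebar <- 2^(sums / n_nonpsf)
  }

  take <- which(is_psf & n_nonpsf[as.integer(set_f)] >= 1L)
  n_excluded <- length(unique(m$probeset_id[is_psf & n_nonpsf[as.integer(set_f)] == 0L]))
  ratios <- log2(lin[take, , drop = FALSE]) -
    log2(ebar[as.integer(set_f)[take], , drop = FALSE])
  dimnames(ratios) <- list(NULL, colnames(m$intensity))

  cls <- psf_rows$class[match(key_m[take],
                              paste(psf_rows$probeset_id, psf_rows$probe_index, sep = "\r"))]
  info <- data.frame(probeset_id = m$probeset_id[take],
                     probe_index = m$probe_index[take],
                     psf_class = cls,
                     m_nonpsf = n_nonpsf[as.integer(set_f)[take]],
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(ratios = ratios, info = info, n_excluded = n_excluded),
            class = "RatioTable")
}

#' Fit the one-way genotype model to E_p/E_t ratio data
#'
#' Fits Y = mu + genotype_j + error per PSF, pooling the error variance
#' within genotypes (df = N - number of genotypes; 9 for the 3-genotype,
#' 4-replicate design).
#'
#' @param rt a \code{RatioTable}.
#' @param samples a \code{SampleSheet}.
#' @param genotypes genotypes included in the fit (default AT, TC, SN).
#' @return A list of class \code{RatioModelFit}: genotype \code{means}
#'   (PSF x genotype), pooled \code{mse}, \code{df}, replicate counts
#'   \code{n}, \code{degenerate} flags (mse == 0) and the \code{info}
#'   data.frame carried over from the ratio table.
#' @export
fit_ratio_model <- function(rt, samples, genotypes = c("AT", "TC", "SN")) {
  use <- samples[samples$genotype %in% genotypes, , drop = FALSE]
  n <- table(factor(use$genotype, levels = genotypes))
  if (any(n < 2L)) stop("fit_ratio_model_replicates: need >= 2 replicates per genotype")
  x <- rt$ratios[, use$sample_id, drop = FALSE]
  means <- matrix(vapply(genotypes, function(g) {
    rowMeans(x[, use$genotype == g, drop = FALSE])
  }, numeric(nrow(x))), nrow(x), length(genotypes),
  dimnames = list(NULL, genotypes))
  ss <- rowSums(matrix(vapply(genotypes, function(g) {
    sub <- x[, use$genotype == g, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2)
  }, numeric(nrow(x))), nrow(x), length(genotypes)))
  df <- sum(n) - length(genotypes)
  mse <- ss / df
  structure(list(means = means, mse = mse, df = df, n = as.integer(n),
                 genotypes = genotypes, degenerate = mse == 0,
                 info = rt$info),
            class = "RatioModelFit")
}

default_contrasts <- function(genotypes) {
  stopifnot(all(c("AT", "TC", "SN") %in% genotypes))
  mk <- function(...) {
    v <- stats::setNames(numeric(length(genotypes)), genotypes)
    w <- c(...)
    v[names(w)] <- w
    v
  }
  list(AT_vs_SN = mk(AT = -1, SN = 1),
       TC_vs_SN = mk(TC = -1, SN = 1),
       SN_vs_mid11 = mk(AT = -1 / 2, TC = -1 / 2, SN = 1),
       SN_vs_mid12 = mk(AT = -1 / 3, TC = -2 / 3, SN = 1))
}

#' Test linear contrasts of genotype means on the ratio scale
#'
#' Each contrast L = sum c_j * mean_j is tested with SE = sqrt(MSE * sum
#' c_j^2 / n_j) against the t distribution on the pooled-fit degrees of
#' freedom (two-sided).  The defaults test AT vs SN, TC vs SN, and the SN
#' departure from the 1:1 mid-parent value (AT + TC)/2 and from the 1:2
#' dosage value (1/3 AT + 2/3 TC).  For degenerate fits (MSE = 0) a
#' nonzero estimate is reported with p = 0 and a zero estimate with p = 1.
#'
#' @param fit a \code{RatioModelFit}.
#' @param contrasts named list of coefficient vectors over
#'   \code{fit$genotypes}; defaults as above.
#' @return A list of class \code{ContrastTests} with matrices
#'   \code{estimate}, \code{se}, \code{t}, \code{p} (PSF x contrast),
#'   plus \code{df}, \code{degenerate} and \code{info}.
#' @export
test_contrasts <- function(fit, contrasts = NULL) {
  if (is.null(contrasts)) contrasts <- default_contrasts(fit$genotypes)
  cm <- do.call(cbind, contrasts)
  est <- fit$means %*% cm
  scale2 <- colSums(cm^2 / fit$n)
  se <- sqrt(outer(fit$mse, scale2))
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), df = fit$df)
  if (any(fit$degenerate)) {
    deg <- fit$degenerate
    p[deg, ] <- ifelse(est[deg, , drop = FALSE] != 0, 0, 1)
    tv <- sign(est[deg, , drop = FALSE]) * Inf
    tv[est[deg, , drop = FALSE] == 0] <- 0
    tval[deg, ] <- tv
  }
  dimnames(est) <- dimnames(se) <- dimnames(tval) <- dimnames(p) <-
    list(NULL, names(contrasts))
  structure(list(estimate = est, se = se, t = tval, p = p, df = fit$df,
                 degenerate = fit$degenerate, info = fit$info),
            class = "ContrastTests")
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up BH with monotone adjusted values, applied independently per
#' contrast family by the callers.
#'
#' @param p raw p values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return List with \code{q} (adjusted p) and \code{significant}
#'   (q <= alpha).
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("bh_adjust_range: p values must be in [0,1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = q <= alpha)
}

#' Classify expression category from the two mid-parent contrasts
#'
#' @param sig_1to1 logical; significant departure from the 1:1 model.
#' @param sig_1to2 logical; significant departure from the 1:2 model.
#' @return Character vector: \code{mid_parent} (neither), \code{non_additive}
#'   (both), \code{fits_1to1_only} (only the 1:2 model rejected),
#'   \code{fits_1to2_only} (only the 1:1 model rejected).
#' @export
classify_expression <- function(sig_1to1, sig_1to2) {
  out <- rep("mid_parent", length(sig_1to1))
  out[sig_1to1 & sig_1to2] <- "non_additive"
  out[!sig_1to1 & sig_1to2] <- "fits_1to1_only"
  out[sig_1to1 & !sig_1to2] <- "fits_1to2_only"
  out
}

#' Direction of non-additive expression change
#'
#' For non-additive calls the direction is the sign of the 1:1 mid-parent
#' contrast estimate: a SN ratio above the mid-parent value means the
#' tracked parental genome's share of total expression increased.
#' AT-specific PSFs report the D-genome (diploid parent) contribution;
#' TC-specific PSFs the combined AB-genome contribution.
#'
#' @param category character vector of expression categories.
#' @param estimate_mid11 1:1 contrast estimates.
#' @return Character vector \code{up}/\code{down}/\code{none}.
#' @export
call_direction <- function(category, estimate_mid11) {
  dir <- rep("none", length(category))
  na <- category == "non_additive"
  dir[na & estimate_mid11 > 0] <- "up"
  dir[na & estimate_mid11 < 0] <- "down"
  if (any(na & estimate_mid11 == 0)) {
    warning("call_direction: non-additive call with zero estimate; direction none")
  }
  dir
}

#' Build per-PSF expression calls from contrast tests
#'
#' Applies BH per mid-parent contrast family, classifies each PSF into an
#' expression category and assigns a direction to non-additive calls.
#'
#' @param tests a \code{ContrastTests} object containing the
#'   \code{SN_vs_mid11} and \code{SN_vs_mid12} contrasts.
#' @param alpha FDR level per contrast family.
#' @return A data.frame of class \code{ExpressionCall}: probeset_id,
#'   probe_index, psf_class, p11, p12, q11, q12, category, direction,
#'   est11.
#' @export
classify_homoeolog_calls <- function(tests, alpha = 0.05) {
  a11 <- bh_adjust(tests$p[, "SN_vs_mid11"], alpha)
  a12 <- bh_adjust(tests$p[, "SN_vs_mid12"], alpha)
  category <- classify_expression(a11$significant, a12$significant)
  direction <- call_direction(category, tests$estimate[, "SN_vs_mid11"])
  out <- data.frame(tests$info[, c("probeset_id", "probe_index", "psf_class")],
                    p11 = tests$p[, "SN_vs_mid11"],
                    p12 = tests$p[, "SN_vs_mid12"],
                    q11 = a11$q, q12 = a12$q,
                    category = category, direction = direction,
                    est11 = tests$estimate[, "SN_vs_mid11"],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ExpressionCall", "data.frame")
  out
}

#' Remove probesets with internally discordant direction calls
#'
#' A probeset whose PSFs of the same parent class make non-additive calls
#' in opposite directions (one up, one down) cannot be trusted and is
#' removed entirely.  An AT-specific "up" together with a TC-specific
#' "down" is biologically consistent and retained.
#'
#' @param calls an \code{ExpressionCall} data.frame.
#' @return List with \code{calls} (retained), \code{removed_probesets} and
#'   \code{n_removed}.
#' @export
concordance_filter <- function(calls) {
  na <- calls[calls$category == "non_additive", , drop = FALSE]
  grp <- paste(na$probeset_id, na$psf_class, sep = "\r")
  has_up <- tapply(na$direction == "up", grp, any)
  has_down <- tapply(na$direction == "down", grp, any)
  bad_grp <- names(has_up)[has_up & has_down]
  removed <- unique(sub("\r.*$", "", bad_grp))
  list(calls = calls[!calls$probeset_id %in% removed, , drop = FALSE],
       removed_probesets = removed,
       n_removed = length(removed))
}

#' Summary percentages over a parent-class x regulation count table
#'
#' @param counts numeric matrix with rows \code{AT_type}, \code{TC_type}
#'   and columns \code{down}, \code{up}, \code{mid_parent} (mid_parent may
#'   be absent for non-additive-only summaries).
#' @return List of percentage summaries: within-class up/down shares among
#'   non-additive calls, class shares within all up and all down calls, and
#'   up/down shares among all non-additive calls.
#' @export
call_summary_percentages <- function(counts) {
  pc <- function(x, tot) if (tot > 0) 100 * x / tot else NA_real_
  na_at <- counts["AT_type", "down"] + counts["AT_type", "up"]
  na_tc <- counts["TC_type", "down"] + counts["TC_type", "up"]
  up <- counts["AT_type", "up"] + counts["TC_type", "up"]
  down <- counts["AT_type", "down"] + counts["TC_type", "down"]
  list(
    within_class = rbind(
      AT_type = c(down = pc(counts["AT_type", "down"], na_at),
                  up = pc(counts["AT_type", "up"], na_at)),
      TC_type = c(down = pc(counts["TC_type", "down"], na_tc),
                  up = pc(counts["TC_type", "up"], na_tc))),
    class_within_direction = rbind(
      up = c(AT_type = pc(counts["AT_type", "up"], up),
             TC_type = pc(counts["TC_type", "up"], up)),
      down = c(AT_type = pc(counts["AT_type", "down"], down),
               TC_type = pc(counts["TC_type", "down"], down))),
    nonadditive_split = c(up = pc(up, up + down), down = pc(down, up + down)))
}

#' Summarize expression calls by parent class and regulation
#'
#' @param calls an \code{ExpressionCall} data.frame.
#' @return List with \code{counts} (AT_type/TC_type x down/up/mid_parent;
#'   mid_parent lumps every call that is not non-additive) and
#'   \code{percentages} (see \code{\link{call_summary_percentages}}).
#' @export
summarize_calls <- function(calls) {
  status <- ifelse(calls$category == "non_additive", calls$direction, "mid_parent")
  cls <- ifelse(calls$psf_class == "AT_specific", "AT_type", "TC_type")
  counts <- table(factor(cls, levels = c("AT_type", "TC_type")),
                  factor(status, levels = c("down", "up", "mid_parent")))
  counts <- unclass(as.matrix(counts))
  list(counts = counts, percentages = call_summary_percentages(counts))
}

#' Parental expression divergence and its overlap with non-additive calls
#'
#' Tests AT vs TC differential expression per probeset (pooled two-group
#' contrast, BH at \code{alpha}) on summarized probeset expression, and
#' cross-tabulates non-additive PSF calls against parental divergence.
#'
#' @param expr a \code{ProbesetExpression} data.frame.
#' @param samples a \code{SampleSheet}.
#' @param calls optional \code{ExpressionCall} data.frame; when given, the
#'   non-additive calls are intersected with the divergence calls.
#' @param alpha FDR level.
#' @return List with the per-probeset divergence table, the divergent
#'   fraction, and (when calls are given) the fraction of non-additive PSFs
#'   in divergent probesets plus the 8-cell breakdown parent-higher
#'   (AT/TC) x genome (D/AB) x direction (up/down).
#' @export
parental_divergence <- function(expr, samples, calls = NULL, alpha = 0.05) {
  at_cols <- sheet_samples(samples, "AT")
  tc_cols <- sheet_samples(samples, "TC")
  x_at <- as.matrix(expr[, at_cols, drop = FALSE])
  x_tc <- as.matrix(expr[, tc_cols, drop = FALSE])
  n1 <- ncol(x_at); n2 <- ncol(x_tc)
  m1 <- rowMeans(x_at); m2 <- rowMeans(x_tc)
  ss <- rowSums((x_at - m1)^2) + rowSums((x_tc - m2)^2)
  df <- n1 + n2 - 2
  se <- sqrt(ss / df * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  p <- 2 * stats::pt(-abs(diff / se), df = df)
  p[se == 0] <- ifelse(diff[se == 0] != 0, 0, 1)
  adj <- bh_adjust(p, alpha)
  tab <- data.frame(probeset_id = expr$probeset_id,
                    mean_AT = m1, mean_TC = m2, estimate = diff,
                    p = p, q = adj$q, divergent = adj$significant,
                    parent_higher = ifelse(diff > 0, "AT", "TC"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- list(table = tab, fraction_divergent = mean(adj$significant))

  if (!is.null(calls)) {
    na <- calls[calls$category == "non_additive", , drop = FALSE]
    i <- match(na$probeset_id, tab$probeset_id)
    div <- tab$divergent[i]
    out$fraction_nonadditive_in_divergent <- mean(div, na.rm = TRUE)
    keep <- !is.na(div) & div
    genome <- ifelse(na$psf_class == "AT_specific", "D", "AB")
    out$cross_tab <- table(
      parent_higher = factor(tab$parent_higher[i][keep], levels = c("AT", "TC")),
      genome = factor(genome[keep], levels = c("D", "AB")),
      direction = factor(na$direction[keep], levels = c("up", "down")))
    out$n_nonadditive <- nrow(na)
  }
  out
}
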