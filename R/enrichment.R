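#' Fisher exact over/under-representation of categories in a gene set
#'
#' For each category, builds the 2x2 table (in set / not in set x in
#' category / not) over the background and computes the exact two-sided
#' hypergeometric p (sum of table probabilities at most that of the
#' observed table), BH-adjusted across categories.
#'
#' @param categories data.frame with columns \code{gene_id} and
#'   \code{category} (a gene may carry several categories).
#' @param set character vector of tested gene ids (must all be in the
#'   background).
#' @param background character vector of background gene ids.
#' @param alpha FDR level.
#' @return data.frame per category: cell counts, odds ratio, \code{p},
#'   \code{q}, \code{significant}, \code{direction} (over/under, from the
#'   sample odds ratio vs 1, \code{none} at parity).
#' @export
fisher_enrichment <- function(categories, set, background, alpha = 0.05) {
  background <- unique(as.character(background))
  set <- unique(as.character(set))
  if (!all(set %in% background)) {
    stop("fisher_enrichment_background: tested genes missing from background")
  }
  categories <- categories[categories$gene_id %in% background, , drop = FALSE]
  cats <- unique(as.character(categories$category))
  if (length(cats) == 0L) {
    stop("fisher_enrichment_categories: no category overlaps the background")
  }
  n_bg <- length(background)
  n_set <- length(set)
  res <- lapply(cats, function(cl) {
    members <- unique(categories$gene_id[categories$category == cl])
    a <- sum(set %in% members)              # in set, in category
    b <- n_set - a                          # in set, not in category
    cc <- length(members) - a               # not in set, in category
    d <- n_bg - n_set - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2L))$p.value
    or <- (a * d) / (b * cc)
    direction <- if (is.nan(or) || or == 1) "none" else if (or > 1) "over" else "under"
    data.frame(category = cl, set_in = a, set_out = b, bg_in = cc, bg_out = d,
               odds_ratio = or, p = p, direction = direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  adj <- bh_adjust(out$p, alpha)
  out$q <- adj$q
  out$significant <- adj$significant
  out
}

# Exact two-sided rank-sum p by enumeration of all assignments of the
# pooled (average) ranks to the bin; correct under ties.
exact_ranksum_p <- function(bin_values, rest_values) {
  r <- rank(c(bin_values, rest_values))
  n1 <- length(bin_values)
  w <- sum(r[seq_len(n1)])
  ws <- utils::combn(length(r), n1, FUN = function(i) sum(r[i]))
  p_lo <- mean(ws <= w)
  p_hi <- mean(ws >= w)
  min(1, 2 * min(p_lo, p_hi))
}

#' Wilcoxon rank-sum test for coordinated regulation of functional bins
#'
#' Tests each bin's per-gene scores against all other genes.  The exact
#' null distribution (enumeration over rank assignments, valid under ties)
#' is used when the combined sample is at most 20 genes; larger samples use
#' the normal approximation with tie correction.  BH adjustment is applied
#' across bins.
#'
#' @param scores numeric per-gene scores (e.g. an expression-change
#'   statistic).
#' @param bins character/factor bin labels parallel to \code{scores}.
#' @param alpha FDR level.
#' @param min_bin smallest bin size tested (default 2).
#' @return data.frame per bin: \code{n}, \code{p}, \code{q},
#'   \code{significant}, \code{direction} (up/down/none from the median
#'   difference bin vs rest).
#' @export
wilcoxon_bin_test <- function(scores, bins, alpha = 0.05, min_bin = 2L) {
  bins <- as.character(bins)
  stopifnot(length(scores) == length(bins))
  labs <- unique(bins)
  res <- lapply(labs, function(b) {
    inb <- bins == b
    if (sum(inb) < min_bin) return(NULL)
    if (all(inb)) stop("wilcoxon_bin_complement: bin equals the full gene set")
    x <- scores[inb]; y <- scores[!inb]
    p <- if (length(scores) <= 20L) {
      exact_ranksum_p(x, y)
    } else {
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    }
    md <- stats::median(x) - stats::median(y)
    data.frame(bin = b, n = sum(inb), p = p,
               direction = if (md > 0) "up" else if (md < 0) "down" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("wilcoxon_bin_empty: no bin reaches the minimum size")
  adj <- bh_adjust(out$p, alpha)
  out$q <- adj$q
  out$significant <- adj$significant
  out
}
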