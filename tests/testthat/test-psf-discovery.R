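test_that("the mutation budget reproduces the substitution arithmetic", {
  em <- expected_mutations()
  expect_equal(em$expected, 5.5e-9 * 2.7e6 * 275, tolerance = 1e-12)
  expect_equal(round(em$expected, 2), 4.08)
  expect_identical(em$budget_integer, 4L)
  expect_identical(em$budget_integer, mutation_budget_config()$max_psf)
  expect_equal(mutation_budget_config()$probeset_length, 11 * 25)
})

test_that("balanced probe-model fit equals generic least squares", {
  set.seed(11)
  fx <- toy_probe_matrix(stats::rnorm(2 * 11 * 8, 8), sets = 2L, k = 11L,
                         genotype = rep(c("AT", "TC"), each = 4L))
  lg <- ProbeMatrix(fx$probes$intensity, fx$probes$probeset_id,
                    fx$probes$probe_index, scale = "log2")
  fit <- fit_probe_model(lg, fx$samples)
  for (s in unique(lg$probeset_id)) {
    rows <- which(lg$probeset_id == s)
    long <- data.frame(y = as.vector(lg$intensity[rows, ]),
                       probe = factor(rep(rows, 8L)),
                       geno = factor(rep(fx$samples$genotype, each = length(rows))))
    ref <- matrix(stats::resid(stats::lm(y ~ probe + geno, long)), length(rows))
    expect_equal(unname(fit$residuals[rows, ]), unname(ref), tolerance = 1e-10)
  }
})

test_that("SAM d-statistic matches the direct formula", {
  rat <- c(-0.2, 0.1, -0.1, 0.2)
  rtc <- c(0.9, 1.1, 1.0, 1.2)
  num <- mean(rtc) - mean(rat)
  s <- sqrt((1 / 4 + 1 / 4) *
              (sum((rat - mean(rat))^2) + sum((rtc - mean(rtc))^2)) / 6)
  expect_equal(sam_d_statistic(rat, rtc, s0 = 0.05), num / (s + 0.05),
               tolerance = 1e-12)
  expect_equal(sam_d_statistic(rat, rtc, s0 = 0.05), 6.489357,
               tolerance = 1e-6)
  # sign convention: stronger hybridization in TC gives d > 0
  expect_gt(sam_d_statistic(rat, rtc, 0.05), 0)
  expect_lt(sam_d_statistic(rtc, rat, 0.05), 0)
  # vectorized components agree with the scalar formula
  res <- rbind(c(rat, rtc), c(rtc, rat))
  cmp <- homoeoExpr:::d_components(res, tc_cols = 5:8)
  expect_equal(cmp$num / (cmp$s + 0.05),
               c(sam_d_statistic(rat, rtc, 0.05),
                 sam_d_statistic(rtc, rat, 0.05)), tolerance = 1e-12)
})

test_that("s0 percentile rule gives the type-7 quantile of s", {
  s <- as.numeric(1:100)
  cfg <- sam_config(s0_method = "percentile", s0_percentile = 5)
  expect_equal(estimate_s0(stats::rnorm(100), s, cfg), 5.95, tolerance = 1e-12)
  cfg50 <- sam_config(s0_method = "percentile", s0_percentile = 50)
  expect_equal(estimate_s0(stats::rnorm(100), s, cfg50), 50.5, tolerance = 1e-12)
})

test_that("balanced label assignments enumerate all C(8,4) = 70 splits", {
  perms <- homoeoExpr:::balanced_assignments(4L, 4L, "all", seed = 1L)
  expect_length(perms, choose(8, 4))
  expect_true(all(vapply(perms, length, integer(1)) == 4L))
  expect_identical(anyDuplicated(vapply(perms, paste, character(1),
                                        collapse = ",")), 0L)
  sub <- homoeoExpr:::balanced_assignments(4L, 4L, 20L, seed = 7L)
  expect_length(sub, 20L)
})

test_that("the SAM cut rule, pi0 and FDR behave on constructed data", {
  set.seed(5)
  d <- c(stats::rnorm(96, 0, 0.05), 4, 5, -4, -5)
  perm_d <- matrix(stats::rnorm(100 * 70, 0, 0.05), 100, 70)
  rec <- sam_call(d, perm_d, sam_config(delta = 0.5, pi0 = "one"))
  expect_s3_class(rec, "PsfRecord")
  expect_identical(which(rec$significant), 97:100)
  expect_identical(rec$class[97:98], c("TC_specific", "TC_specific"))
  expect_identical(rec$class[99:100], c("AT_specific", "AT_specific"))
  expect_true(all(rec$class[1:96] == "non_PSF"))
  expect_identical(attr(rec, "pi0"), 1)
  expect_lte(attr(rec, "estimated_fdr"), 0.1)
  cuts <- attr(rec, "cut_points")
  expect_true(cuts["upper"] > 0 && cuts["lower"] < 0)

  # delta search picks the smallest grid delta meeting the target FDR
  rec2 <- sam_call(d, perm_d, sam_config(target_fdr = 0.1, pi0 = "one"))
  expect_lte(attr(rec2, "estimated_fdr"), 0.1)
  rec3 <- sam_call(d, perm_d,
                   sam_config(delta = attr(rec2, "delta") - 0.01, pi0 = "one"))
  fdr3 <- attr(rec3, "estimated_fdr")
  expect_true(is.nan(fdr3) || fdr3 > 0.1 ||
                attr(rec2, "delta") == 0.01)
})

test_that("classify_psf maps signs of significant d to parent classes", {
  rec <- data.frame(d = c(-2, 2, -2, 2),
                    significant = c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(classify_psf(rec)$class,
                   c("AT_specific", "TC_specific", "non_PSF", "non_PSF"))
})

test_that("filter_probesets applies the budget and drops all-PSF sets", {
  mk <- function(id, npsf, k = 11L) {
    data.frame(probeset_id = id, probe_index = seq_len(k),
               d = 0, expected_d = 0,
               significant = seq_len(k) <= npsf,
               class = ifelse(seq_len(k) <= npsf, "TC_specific", "non_PSF"),
               stringsAsFactors = FALSE)
  }
  rec <- rbind(mk("keep0", 0L), mk("keep4", 4L), mk("over5", 5L),
               mk("allpsf", 11L))
  out <- filter_probesets(rec, mutation_budget_config())
  expect_setequal(out$retained, c("keep0", "keep4"))
  expect_identical(out$n_dropped_budget, 1L)
  expect_identical(out$n_dropped_all_psf, 1L)
  expect_true(all(out$records$probeset_id %in% c("keep0", "keep4")))
})

test_that("reference residuals with all probes as reference equal the model fit", {
  set.seed(21)
  fx <- toy_probe_matrix(stats::rnorm(2 * 5 * 8, 8), sets = 2L, k = 5L,
                         genotype = rep(c("AT", "TC"), each = 4L))
  lg <- ProbeMatrix(fx$probes$intensity, fx$probes$probeset_id,
                    fx$probes$probe_index, scale = "log2")
  fit <- fit_probe_model(lg, fx$samples)
  set_f <- factor(lg$probeset_id, levels = unique(lg$probeset_id))
  res <- homoeoExpr:::reference_residuals(lg$intensity, fx$samples$genotype,
                                          set_f, rep(TRUE, nrow(lg$intensity)))
  expect_equal(unname(res), unname(fit$residuals), tolerance = 1e-10)
})

test_that("refinement removes interaction leakage from sibling probes", {
  # One strong PSF per probeset; under the plain additive fit its
  # interaction leaks onto siblings, which the refined pass must not call.
  set.seed(31)
  n <- 60L; k <- 11L
  geno <- rep(c("AT", "TC"), each = 4L)
  base <- matrix(stats::rnorm(n * k * 8L, 8, 0.15), n * k, 8L)
  psf_rows <- seq(1L, n * k, by = k)            # probe 1 of every set
  base[psf_rows, geno == "TC"] <- base[psf_rows, geno == "TC"] - 2
  colnames(base) <- paste(geno, rep(1:4, 2L), sep = "_")
  m <- ProbeMatrix(base, rep(sprintf("g%03d", 1:n), each = k),
                   rep(1:k, n), scale = "log2")
  sheet <- SampleSheet(colnames(base), geno, rep(1:4, 2L))
  cfg <- sam_config(delta = 0.2, seed = 1L)
  raw <- discover_psf(m, sheet, cfg, refine = FALSE)
  ref <- discover_psf(m, sheet, cfg, refine = TRUE)
  truth_psf <- paste(m$probeset_id, m$probe_index)[psf_rows]
  called_ref <- paste(ref$probeset_id, ref$probe_index)[ref$significant]
  expect_true(all(truth_psf %in% called_ref))
  # refined false-positive count does not exceed the unrefined one
  expect_lte(sum(ref$significant & !seq_len(n * k) %in% psf_rows),
             sum(raw$significant & !seq_len(n * k) %in% psf_rows))
  expect_true(all(ref$class[psf_rows] == "AT_specific"))
})
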