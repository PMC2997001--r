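psf_one <- data.frame(probeset_id = "s01", probe_index = 1L,
                      class = "AT_specific", stringsAsFactors = FALSE)

test_that("E_p/E_t ratios divide the PSF by the non-PSF linear mean", {
  fx <- toy_probe_matrix(c(8, 2, 4), sets = 1L, k = 3L,
                         genotype = c("AT", "TC"))
  rt <- compute_ep_et(fx$probes, psf_one)
  expect_equal(unname(rt$ratios[1L, ]), rep(log2(8 / 3), 2L), tolerance = 1e-12)
  expect_identical(rt$info$psf_class, "AT_specific")
  expect_identical(rt$info$m_nonpsf, 2L)
  expect_identical(rt$n_excluded, 0L)

  # log2 input gives the same ratios
  rt_log <- compute_ep_et(log2_transform(fx$probes), psf_one)
  expect_equal(rt_log$ratios, rt$ratios, tolerance = 1e-12)

  # log-scale averaging uses the geometric mean
  rt_g <- compute_ep_et(fx$probes, psf_one, e_bar_scale = "log2")
  expect_equal(unname(rt_g$ratios[1L, ]), rep(log2(8 / sqrt(8)), 2L),
               tolerance = 1e-12)

  # probeset with every probe a PSF is excluded
  all_psf <- data.frame(probeset_id = "s01", probe_index = 1:3,
                        class = "AT_specific", stringsAsFactors = FALSE)
  expect_identical(compute_ep_et(fx$probes, all_psf)$n_excluded, 1L)
})

ratio_fixture <- function() {
  vals <- c(AT = list(c(0, 1, 0.5, 0.5)), TC = list(c(2, 3, 2.5, 2.5)),
            SN = list(c(1, 2, 1.5, 1.5)))
  geno <- rep(c("AT", "TC", "SN"), each = 4L)
  ids <- paste(geno, rep(1:4, 3L), sep = "_")
  ratios <- matrix(unlist(vals), 1L, 12L, dimnames = list(NULL, ids))
  rt <- structure(list(ratios = ratios,
                       info = data.frame(probeset_id = "s01", probe_index = 1L,
                                         psf_class = "AT_specific", m_nonpsf = 10L,
                                         stringsAsFactors = FALSE),
                       n_excluded = 0L), class = "RatioTable")
  list(rt = rt, samples = SampleSheet(ids, geno, rep(1:4, 3L)))
}

test_that("the one-way fit and contrasts reproduce hand-computed values", {
  fx <- ratio_fixture()
  fit <- fit_ratio_model(fx$rt, fx$samples)
  expect_equal(unname(fit$means[1L, ]), c(0.5, 2.5, 1.5), tolerance = 1e-12)
  expect_equal(fit$mse, 1 / 6, tolerance = 1e-12)
  expect_identical(fit$df, 9L)

  tst <- test_contrasts(fit)
  expect_equal(unname(tst$estimate[1L, c("SN_vs_mid11", "SN_vs_mid12")]),
               c(0, -1 / 3), tolerance = 1e-12)
  expect_equal(unname(tst$se[1L, "SN_vs_mid12"]), 0.2545875, tolerance = 1e-6)
  expect_equal(unname(tst$p[1L, "SN_vs_mid12"]), 0.2228684, tolerance = 1e-6)
  expect_equal(unname(tst$p[1L, "SN_vs_mid11"]), 1, tolerance = 1e-12)
})

test_that("contrast t and p agree with the lm/t-distribution oracle", {
  set.seed(9)
  fx <- ratio_fixture()
  fx$rt$ratios <- fx$rt$ratios + stats::rnorm(12L, 0, 0.2)
  fit <- fit_ratio_model(fx$rt, fx$samples)
  tst <- test_contrasts(fit)

  g <- factor(fx$samples$genotype, levels = c("AT", "TC", "SN"))
  lmfit <- stats::lm(as.vector(fx$rt$ratios) ~ 0 + g)
  cvec <- c(-1 / 2, -1 / 2, 1)
  est <- sum(cvec * stats::coef(lmfit))
  se <- sqrt(drop(t(cvec) %*% stats::vcov(lmfit) %*% cvec))
  expect_equal(unname(tst$estimate[1L, "SN_vs_mid11"]), est, tolerance = 1e-10)
  expect_equal(unname(tst$se[1L, "SN_vs_mid11"]), se, tolerance = 1e-10)
  expect_equal(unname(tst$p[1L, "SN_vs_mid11"]),
               2 * stats::pt(-abs(est / se), 9), tolerance = 1e-10)
})

test_that("degenerate zero-variance fits yield p of 0 or 1, not NaN", {
  fx <- ratio_fixture()
  fx$rt$ratios[] <- rep(c(0, 2, 1), each = 4L)   # no within-group spread
  fit <- fit_ratio_model(fx$rt, fx$samples)
  expect_true(fit$degenerate)
  tst <- test_contrasts(fit)
  expect_identical(unname(tst$p[1L, c("AT_vs_SN", "SN_vs_mid11", "SN_vs_mid12")]),
                   c(0, 1, 0))
  expect_identical(unname(tst$t[1L, "SN_vs_mid11"]), 0)
  expect_identical(unname(tst$t[1L, "AT_vs_SN"]), Inf)
  expect_identical(unname(tst$t[1L, "SN_vs_mid12"]), -Inf)
})

test_that("BH adjustment matches p.adjust and flags at the FDR level", {
  p <- c(0.001, 0.01, 0.02, 0.2, 0.9)
  adj <- bh_adjust(p, alpha = 0.05)
  expect_equal(adj$q, stats::p.adjust(p, "BH"), tolerance = 1e-15)
  expect_identical(adj$significant, adj$q <= 0.05)
  expect_error(bh_adjust(c(0.5, 1.2)), "bh_adjust_range")
})

test_that("category classification covers all four contrast outcomes", {
  expect_identical(
    classify_expression(c(FALSE, TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE, FALSE)),
    c("mid_parent", "non_additive", "fits_1to1_only", "fits_1to2_only"))
  expect_identical(call_direction(c("non_additive", "non_additive", "mid_parent"),
                                  c(2, -2, 3)),
                   c("up", "down", "none"))
  expect_warning(call_direction("non_additive", 0), "zero estimate")
})

test_that("the concordance filter removes only within-class conflicts", {
  mk <- function(id, cls, dir) {
    data.frame(probeset_id = id, probe_index = seq_along(cls), psf_class = cls,
               p11 = 0, p12 = 0, q11 = 0, q12 = 0,
               category = ifelse(dir == "none", "mid_parent", "non_additive"),
               direction = dir, est11 = 0, stringsAsFactors = FALSE)
  }
  calls <- rbind(
    mk("bad", c("AT_specific", "AT_specific"), c("up", "down")),
    mk("ok_cross", c("AT_specific", "TC_specific"), c("up", "down")),
    mk("ok_same", c("TC_specific", "TC_specific"), c("up", "up")),
    mk("ok_mid", "AT_specific", "none"))
  out <- concordance_filter(calls)
  expect_identical(out$removed_probesets, "bad")
  expect_identical(out$n_removed, 1L)
  expect_setequal(unique(out$calls$probeset_id),
                  c("ok_cross", "ok_same", "ok_mid"))
})

test_that("summary percentages sum to 100 within their denominators", {
  counts <- rbind(AT_type = c(down = 705, up = 1601, mid_parent = 13840),
                  TC_type = c(down = 406, up = 3718, mid_parent = 14399))
  pct <- call_summary_percentages(counts)
  expect_equal(rowSums(pct$within_class), c(AT_type = 100, TC_type = 100),
               tolerance = 0.1)
  expect_equal(rowSums(pct$class_within_direction), c(up = 100, down = 100),
               tolerance = 0.1)
  expect_equal(sum(pct$nonadditive_split), 100, tolerance = 0.1)
})

test_that("relabeling the parents flips attribution but not categories", {
  sim <- small_sim()
  psf <- truth_psf_records(sim$truth)
  rt <- compute_ep_et(sim$probes, psf)
  fit <- fit_ratio_model(rt, sim$samples)
  calls <- classify_homoeolog_calls(test_contrasts(fit))

  # rename AT<->TC everywhere: samples, PSF classes and contrast weights
  sw <- sim$samples
  sw$genotype <- c(AT = "TC", TC = "AT", SN = "SN", MIX = "MIX")[sw$genotype]
  psf_sw <- psf
  psf_sw$class <- c(AT_specific = "TC_specific", TC_specific = "AT_specific",
                    non_PSF = "non_PSF")[psf$class]
  psf_sw$d <- -psf$d
  rt_sw <- compute_ep_et(sim$probes, psf_sw)
  fit_sw <- fit_ratio_model(rt_sw, sw)
  ctr_sw <- list(AT_vs_SN = c(AT = 0, TC = -1, SN = 1),
                 TC_vs_SN = c(AT = -1, TC = 0, SN = 1),
                 SN_vs_mid11 = c(AT = -1 / 2, TC = -1 / 2, SN = 1),
                 SN_vs_mid12 = c(AT = -2 / 3, TC = -1 / 3, SN = 1))
  calls_sw <- classify_homoeolog_calls(test_contrasts(fit_sw, ctr_sw))

  expect_identical(calls_sw$category, calls$category)
  expect_identical(calls_sw$direction, calls$direction)
  expect_identical(calls_sw$psf_class,
                   unname(c(AT_specific = "TC_specific",
                            TC_specific = "AT_specific")[calls$psf_class]))
})

test_that("parental divergence matches the equal-variance t-test oracle", {
  sim <- small_sim()
  expr <- summarize_probesets(sim$probes, "mean")
  div <- parental_divergence(expr, sim$samples)
  i <- 7L
  at <- unlist(expr[i, sheet_samples(sim$samples, "AT")])
  tc <- unlist(expr[i, sheet_samples(sim$samples, "TC")])
  ref <- stats::t.test(at, tc, var.equal = TRUE)
  expect_equal(div$table$p[i], ref$p.value, tolerance = 1e-10)
  expect_equal(div$table$estimate[i], unname(diff(rev(ref$estimate))),
               tolerance = 1e-10)
  expect_equal(div$table$q, stats::p.adjust(div$table$p, "BH"),
               tolerance = 1e-12)
})
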