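mk_ct <- function(gene, condition, ct, n_tech = 1L) {
  do.call(rbind, lapply(seq_along(ct), function(b) {
    data.frame(gene = gene, condition = condition, bio_rep = b,
               tech_rep = seq_len(n_tech), ct = ct[b],
               stringsAsFactors = FALSE)
  }))
}

test_that("standard curve recovers slope, efficiency and fit quality", {
  curve <- fit_standard_curve(c(2, 1, 0), c(20.0, 23.3219, 26.6438), "g")
  expect_equal(curve$slope, -3.3219, tolerance = 1e-6)
  expect_equal(curve$efficiency, 2.0, tolerance = 1e-4)
  expect_equal(curve$r_squared, 1.0, tolerance = 1e-9)

  # planted E = 1.9, perfectly linear: recovered exactly, no QC warning
  m <- -1 / log10(1.9)
  lq <- 4:0
  expect_no_warning(curve <- fit_standard_curve(lq, 30 + m * lq, "g"))
  expect_equal(curve$efficiency, 1.9, tolerance = 1e-9)
  expect_equal(curve$r_squared, 1.0, tolerance = 1e-12)

  # an implausible efficiency triggers the QC warning but still fits
  m15 <- -1 / log10(1.5)
  expect_warning(low <- fit_standard_curve(lq, 30 + m15 * lq, "g"),
                 "outside")
  expect_equal(low$efficiency, 1.5, tolerance = 1e-9)

  expect_error(fit_standard_curve(c(1, 1, 1), c(20, 20.1, 19.9)),
               "distinct dilution points|zero variance")
  expect_error(fit_standard_curve(c(1, 2), c(20, 17)), "3 distinct")
})

test_that("technical replicates average with a divergence warning", {
  ct <- data.frame(gene = "g", condition = "c", bio_rep = 1L,
                   tech_rep = 1:2, ct = c(20.0, 20.2))
  expect_equal(collapse_technical(ct)$ct, 20.1)

  single <- ct[1, ]
  expect_equal(collapse_technical(single)$ct, 20.0)

  ct$ct <- c(20.0, 21.0)
  expect_warning(out <- collapse_technical(ct), "diverge")
  expect_equal(out$ct, 20.5)
})

test_that("reference normalization uses the geometric mean", {
  expect_equal(reference_normalization_factor(c(tbp = 4, ffs = 9)), 6)
  expect_equal(reference_normalization_factor(c(tbp = 5)), 5)
  expect_equal(reference_normalization_factor(c(a = 2, b = 8, c = 4)),
               reference_normalization_factor(c(c = 4, a = 2, b = 8)))
  expect_error(reference_normalization_factor(c(a = 0, b = 2)), "positive")
})

test_that("Pfaffl ratio matches its closed form", {
  # E_t = E_r = 2, dCt_t = 3, dCt_r = 1 -> R = 2^3 / 2^1 = 4
  ct <- rbind(mk_ct("tgt", "ctrl", c(20, 20)), mk_ct("tgt", "smp", c(17, 17)),
              mk_ct("ref", "ctrl", c(20, 20)), mk_ct("ref", "smp", c(19, 19)))
  r <- pfaffl_ratio(ct, "tgt", "ref", list(tgt = 2, ref = 2),
                    control = "ctrl", sample = "smp")
  expect_equal(r$ratio, 4.0)

  # null case: no Ct shift anywhere -> R = 1
  ct0 <- rbind(mk_ct("tgt", "ctrl", c(21, 21)), mk_ct("tgt", "smp", c(21, 21)),
               mk_ct("ref", "ctrl", c(25, 25)), mk_ct("ref", "smp", c(25, 25)))
  r0 <- pfaffl_ratio(ct0, "tgt", "ref", list(tgt = 2, ref = 2),
                     control = "ctrl", sample = "smp")
  expect_equal(r0$ratio, 1.0)

  expect_error(pfaffl_ratio(ct[ct$condition == "ctrl", ], "tgt", "ref",
                            list(tgt = 2, ref = 2), "ctrl", "smp"),
               "no Ct measurements")
})

test_that("Pfaffl reduces to 2^ddCt when all efficiencies are 2", {
  withr::local_seed(21)
  for (i in 1:25) {
    tc <- round(stats::runif(3, 18, 30), 2)
    ts <- round(stats::runif(3, 18, 30), 2)
    rc <- round(stats::runif(3, 18, 30), 2)
    rs <- round(stats::runif(3, 18, 30), 2)
    ct <- rbind(mk_ct("t", "a", tc), mk_ct("t", "b", ts),
                mk_ct("r", "a", rc), mk_ct("r", "b", rs))
    r <- suppressWarnings(
      pfaffl_ratio(ct, "t", "r", list(t = 2, r = 2), "a", "b"))
    ddct <- (mean(tc) - mean(ts)) - (mean(rc) - mean(rs))
    expect_equal(r$ratio, 2^ddct, tolerance = 1e-12)
  }
})

test_that("a uniform plate offset on one condition cancels out", {
  withr::local_seed(22)
  ct <- rbind(mk_ct("t", "a", c(20, 20.4, 19.8)),
              mk_ct("t", "b", c(18, 18.1, 18.3)),
              mk_ct("r", "a", c(24, 24.2, 23.9)),
              mk_ct("r", "b", c(24.1, 24.0, 24.3)))
  # with a shared assay efficiency the reference normalization absorbs
  # any per-condition plate offset
  base <- pfaffl_ratio(ct, "t", "r", list(t = 1.97, r = 1.97), "a", "b")
  shifted <- ct
  shifted$ct[shifted$condition == "b"] <-
    shifted$ct[shifted$condition == "b"] + 1.7
  moved <- pfaffl_ratio(shifted, "t", "r", list(t = 1.97, r = 1.97),
                        "a", "b")
  expect_equal(moved$ratio, base$ratio, tolerance = 1e-12)
  expect_equal(moved$per_replicate, base$per_replicate, tolerance = 1e-12)
})

test_that("absolute quantity inverts the standard curve", {
  curve <- fit_standard_curve(c(3, 2, 1, 0),
                              25 - 3.3219 * c(3, 2, 1, 0), "g")
  expect_equal(absolute_quantity(curve$intercept, curve), 1, tolerance = 1e-9)
  expect_equal(absolute_quantity(curve$intercept + curve$slope, curve), 10,
               tolerance = 1e-9)
  expect_true(all(diff(absolute_quantity(c(20, 22, 24), curve)) < 0))

  bad <- curve; bad$slope <- 1
  expect_error(absolute_quantity(20, bad), "negative")
})

test_that("planted 100-fold template difference is recovered absolutely", {
  spec <- qpcr_sim_spec(genes = c("hi", "lo"), reference_genes = "tbp",
                        conditions = c("cal", "smp"),
                        fold_changes = list(hi = c(smp = 100),
                                            lo = c(smp = 1)))
  d <- generate_qpcr_dataset(spec, seed = 5)
  curves <- lapply(split(d$dilutions, d$dilutions$gene), function(g)
    fit_standard_curve(g$log10_quantity, g$ct, g$gene[1]))
  tech <- collapse_technical(d$ct)
  q_of <- function(g) {
    cts <- tech$ct[tech$gene == g & tech$condition == "smp"]
    mean(absolute_quantity(cts, curves[[g]]))
  }
  expect_equal(q_of("hi") / q_of("lo"), 100, tolerance = 0.01)
})

test_that("group comparison matches t.test and gates on normality", {
  a <- c(19.8, 20.1, 20.3, 20.0)
  b <- c(21.2, 21.5, 21.1)
  cmp <- compare_conditions(a, b)
  expect_equal(cmp$p_value, stats::t.test(a, b, var.equal = TRUE)$p.value,
               tolerance = 1e-10)
  cmpw <- compare_conditions(a, b, welch = TRUE)
  expect_equal(cmpw$p_value, stats::t.test(a, b)$p.value, tolerance = 1e-10)
  expect_true(all(cmp$normality_ok))

  same <- compare_conditions(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$p_value, 1)
  expect_equal(same$t, 0)

  apart <- compare_conditions(c(1, 1, 1), c(5, 5, 5) + c(1, -1, 0) * 1e-9)
  expect_lt(apart$p_value, 0.001)

  skewed <- c(1, 1.01, 1.02, 1.03, 1.04, 50)
  expect_warning(gate <- compare_conditions(skewed, a), "Shapiro")
  expect_false(gate$normality_ok[["a"]])
  expect_true(is.finite(gate$p_value))

  expect_error(compare_conditions(1, c(2, 3)), ">= 2")
})

test_that("noisy Pfaffl recovery stays within 10% in the median", {
  planted <- c(phaC1 = 3.75, phaC3 = 5.86)
  spec <- qpcr_sim_spec(genes = names(planted),
                        reference_genes = c("tbp", "ffs"),
                        conditions = c("mid", "stat"),
                        fold_changes = lapply(planted,
                                              function(f) c(stat = f)),
                        ct_noise_sd = 0.1, n_bio = 3, n_tech = 2)
  rel_err <- sapply(1:200, function(s) {
    d <- generate_qpcr_dataset(spec, seed = s)
    vapply(names(planted), function(g) {
      r <- suppressWarnings(
        pfaffl_ratio(d$ct, g, c("tbp", "ffs"),
                     as.list(c(tbp = 2, ffs = 2, phaC1 = 2, phaC3 = 2)),
                     "mid", "stat"))
      abs(r$ratio - planted[[g]]) / planted[[g]]
    }, numeric(1))
  })
  expect_lt(stats::median(rel_err["phaC1", ]), 0.10)
  expect_lt(stats::median(rel_err["phaC3", ]), 0.10)
})
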