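test_that("trait generator is deterministic and schema-stable", {
  cfg <- trait_gen_config(n = 50, seed = 21)
  t1 <- gen_trait_table(cfg)
  t2 <- gen_trait_table(cfg)
  expect_identical(t1, t2)
  expect_named(t1, c("accession_id", "origin", "PH", "PeD", "IL1", "IL2",
                     "LS"))
  empty <- gen_trait_table(trait_gen_config(n = 0))
  expect_equal(nrow(empty), 0)
  expect_named(empty, names(t1))
  expect_false(identical(t1, gen_trait_table(trait_gen_config(n = 50,
                                                              seed = 22))))
})

test_that("generator recovers planted moments and correlations at scale", {
  tab <- gen_trait_table(trait_gen_config(n = 20000, seed = 31))
  mom <- default_trait_moments()
  for (i in seq_len(nrow(mom))) {
    tr <- mom$trait[i]
    expect_lt(abs(mean(tab[[tr]]) - mom$mean[i]) / abs(mom$mean[i]), 0.01)
    expect_lt(abs(sd(tab[[tr]]) - mom$sd[i]) / mom$sd[i], 0.02)
  }
  planted <- default_trait_correlations()
  cm <- correlation_matrix(tab[c(names(planted), "LS")])
  for (tr in names(planted)) {
    expect_lt(abs(cm[tr, "LS"] - planted[[tr]]), 0.02)
  }
  # induced predictor intercorrelation follows the single-factor structure
  b2 <- 0.9^2
  for (i in 1:3) for (j in (i + 1):4) {
    ti <- names(planted)[i]; tj <- names(planted)[j]
    expect_lt(abs(cm[ti, tj] - planted[[ti]] * planted[[tj]] / b2), 0.03)
  }
})

test_that("left-censoring yields the closed-form zero fraction", {
  tab <- gen_trait_table(trait_gen_config(n = 20000, seed = 41,
                                          zero_inflation = "censor"))
  expected <- pnorm(-0.288 / 0.263)
  expect_lt(abs(mean(tab$LS == 0) - expected), 0.01)
  expect_true(all(tab$LS >= 0 & tab$LS <= 1))
  # censored-mode correlations are attenuated but close (wider tolerance)
  cm <- correlation_matrix(tab[c("PH", "LS")])
  expect_lt(abs(cm["PH", "LS"] - 0.78), 0.05)
})

test_that("generator rejects configs that cannot be assembled", {
  expect_error(trait_gen_config(ls_loading = 0.5),
               "largest \\|correlation\\|")
  expect_error(trait_gen_config(n = -1), "non-negative")
  mom <- default_trait_moments(); mom$sd[1] <- 0
  expect_error(trait_gen_config(moments = mom), "positive")
})

test_that("plumb generator inverts the angle formula", {
  pm <- gen_plumb(c(0, 60, 90), hsl = 1, noise_sd = 0)
  expect_equal(pm$hv, c(1, 0.5, 0), tolerance = 1e-12)
  expect_equal(cai_from_plumb(pm$hv, pm$hsl), c(0, 60, 90),
               tolerance = 1e-9)
  noisy <- gen_plumb(rep(45, 100), hsl = 1, noise_sd = 0.05, seed = 3)
  expect_true(all(noisy$hv >= 0 & noisy$hv <= 1))
  expect_identical(noisy, gen_plumb(rep(45, 100), 1, 0.05, seed = 3))
  expect_error(gen_plumb(91), "\\[0, 90\\]")
})

test_that("canopy truth mask hits the target fraction by construction", {
  for (la in c(0, 15, 55, 100)) {
    gen <- gen_canopy_image(canopy_gen_config(la_true = la, seed = la + 1))
    expect_lte(abs(100 * mean(gen$truth_mask) - la), 0.5)
  }
  g0 <- gen_canopy_image(canopy_gen_config(la_true = 0, seed = 1))
  expect_true(all(g0$truth_mask == 0))
  g100 <- gen_canopy_image(canopy_gen_config(la_true = 100, seed = 1))
  expect_true(all(g100$truth_mask == 1))
  cfg <- canopy_gen_config(la_true = 30, seed = 5)
  expect_identical(gen_canopy_image(cfg), gen_canopy_image(cfg))
  expect_error(canopy_gen_config(la_true = 101), "\\[0, 100\\]")
  expect_error(canopy_gen_config(healthy_lab = rbind(L = c(35, 50),
                                                     a = c(5, 10),
                                                     b = c(20, 38))),
               "separable")
})

test_that("study fixture is internally consistent across artifacts", {
  study <- gen_study(n_accessions = 40, n_reps = 2, n_images = 2, seed = 17)
  expect_equal(nrow(study$traits), 80)
  scored <- score_plots(study$plots)
  expect_equal(scored$ls, study$traits$LS, tolerance = 1e-12)
  expect_equal(scored$la_pct, study$plots$la_true, tolerance = 1e-12)
  expect_true(all(study$plots$q1 <= 25 & study$plots$q2 <= 25 &
                  study$plots$q3 <= 25 & study$plots$q4 <= 25))
  # image truths follow the first plots' lodged areas
  expect_lte(abs(100 * mean(study$images[[1]]$truth_mask) -
                 study$plots$la_true[1]), 0.5)
})

test_that("the default study covers every severity class", {
  study <- gen_study(seed = 1, n_images = 0)
  sev <- classify_severity(study$traits$LS)
  expect_setequal(as.character(unique(sev)), severity_levels)
})

test_that("study CSV output is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  gen_study(n_accessions = 20, n_reps = 2, n_images = 1, seed = 9,
            out_dir = d1)
  gen_study(n_accessions = 20, n_reps = 2, n_images = 1, seed = 9,
            out_dir = d2)
  for (f in c("traits.csv", "plots.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  expect_identical(readBin(file.path(d1, "images", "img_001.png"), "raw", 1e6),
                   readBin(file.path(d2, "images", "img_001.png"), "raw", 1e6))
  # written plots round-trip through the reader to the same scores
  plots <- read_plot_csv(file.path(d1, "plots.csv"))
  expect_equal(score_plots(plots)$ls,
               read.csv(file.path(d1, "traits.csv"))$LS, tolerance = 1e-9)
})
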