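test_that("AICc follows the second-order formula and guards its domain", {
  # hand evaluation: -2*(-17.892) + 2*4 + 2*4*5/(21-4-1) = 46.284
  expect_equal(aicc(-17.892, 4, 21), 46.284, tolerance = 1e-12)
  expect_equal(aicc(0, 1, 1000), 2 + 4 / 998, tolerance = 1e-12)
  expect_error(aicc(-10, 9, 10), "undefined")
  expect_error(aicc(-10, 10, 10), "undefined")
})

test_that("Akaike weights normalize relative likelihoods", {
  w <- akaike_weights(c(0, 1.38, 2.40, 3.79, 6.51))
  expect_equal(round(w, 3), c(0.502, 0.252, 0.151, 0.075, 0.019))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(akaike_weights(0), 1)
  expect_equal(akaike_weights(c(0, 0)), c(0.5, 0.5))
  expect_equal(round(akaike_weights(c(0, 2.11, 4.20))[1], 3), 0.680)
  expect_error(akaike_weights(c(1, 2)), "minimum 0")
})

test_that("candidate ranking produces sorted deltas and weights", {
  fits <- list(fake_fit("L1", -0.5, 0.2, loglik = -17.892, n = 21),
               fake_fit("TIME", -0.4, 0.2, loglik = -16.833, n = 21),
               fake_fit("L1", -0.3, 0.2, loglik = -20.635, n = 21))
  fits[[1]]$k_params <- 4L
  fits[[2]]$k_params <- 5L
  fits[[3]]$k_params <- 3L
  tab <- rank_candidates(fits, n = 21)
  expect_equal(tab$delta_aicc[1], 0)
  expect_equal(tab$rank, 1:3)
  expect_true(all(diff(tab$aicc) >= 0))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_equal(which.max(tab$weight), 1L)

  single <- rank_candidates(fits[1], n = 21)
  expect_equal(single$delta_aicc, 0)
  expect_equal(single$weight, 1)

  # ties: equal AICc gives equal weight, fewer parameters ranked first
  f_tie <- list(fake_fit("L1", 1, 1, loglik = -10, n = 20),
                fake_fit("TIME", 1, 1, loglik = -10, n = 20))
  f_tie[[1]]$k_params <- 3L
  f_tie[[2]]$k_params <- 3L
  tt <- rank_candidates(f_tie, n = 20)
  expect_equal(tt$weight, c(0.5, 0.5))

  # unconverged fits are dropped with a warning
  fits[[2]]$converged <- FALSE
  expect_warning(tab2 <- rank_candidates(fits, n = 21), "unconverged")
  expect_equal(nrow(tab2), 2)
})

test_that("AICc translation invariance leaves deltas and weights unchanged", {
  set.seed(12)
  ds <- prepared(make_series(exp(rnorm(18, 1, 0.5))))
  fits <- lapply(enumerate_candidates(full_spec("overwinter")),
                 function(sp) fit_linear_ml(build_design(sp, ds)))
  tab <- rank_candidates(fits)
  # recompute with all logliks shifted by a constant (AICc shifts by 2c)
  shifted <- lapply(fits, function(f) { f$loglik <- f$loglik - 7.3; f })
  tab2 <- rank_candidates(shifted)
  expect_equal(tab2$delta_aicc, tab$delta_aicc, tolerance = 1e-10)
  expect_equal(tab2$weight, tab$weight, tolerance = 1e-10)
})

test_that("nested-model loglik monotonicity holds across a ranked table", {
  set.seed(21)
  ds <- prepared(make_series(exp(rnorm(20, 1, 0.5))))
  specs <- enumerate_candidates(full_spec("overwinter"))
  fits <- lapply(specs, function(sp) fit_linear_ml(build_design(sp, ds)))
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  labels <- vapply(specs, function(sp) paste(sp$terms, collapse = "+"),
                   character(1))
  for (i in seq_along(specs)) {
    for (j in seq_along(specs)) {
      if (all(specs[[i]]$terms %in% specs[[j]]$terms) && i != j) {
        expect_gte(ll[j] + 1e-10, ll[i])
      }
    }
  }
})

test_that("conditional model averaging renormalizes weights per term", {
  # equal-AICc pair, term estimated 0 and 2 with zero SE:
  # average 1.0, between-model SD 1, CI half-width 1.96
  fits <- list(fake_fit("L1", 0, 0, loglik = -10, n = 20),
               fake_fit(c("L1", "TIME"), c(2, 1), c(0, 0), loglik = -12,
                        n = 20))
  fits[[1]]$k_params <- 3L
  fits[[2]]$k_params <- 5L
  # equalize AICc: solve so both have same aicc at n=20
  fits[[2]]$loglik <- fits[[1]]$loglik -
    (aicc(0, 3, 20) - aicc(0, 5, 20)) / 2
  tab <- rank_candidates(fits, n = 20)
  expect_equal(tab$weight, c(0.5, 0.5), tolerance = 1e-12)
  avg <- model_average(tab)
  l1 <- avg[avg$term == "L1", ]
  expect_equal(l1$estimate, 1)
  expect_equal(l1$se, 1)
  expect_equal(c(l1$lower, l1$upper), c(1 - 1.96, 1 + 1.96),
               tolerance = 1e-3)
  expect_equal(l1$relative_importance, 1)
  # a term in exactly one model keeps that model's estimate
  tm <- avg[avg$term == "TIME", ]
  expect_equal(tm$estimate, 1)
  expect_equal(tm$relative_importance, 0.5, tolerance = 1e-12)
  expect_equal(tm$n_models, 1L)
})

test_that("zero-spread averaging returns the shared estimate with zero width", {
  fits <- list(fake_fit("L1", -1, 0, loglik = -10, n = 25),
               fake_fit(c("L1", "TIME"), c(-1, 0.2), c(0, 0), loglik = -9,
                        n = 25))
  fits[[1]]$k_params <- 3L
  fits[[2]]$k_params <- 4L
  tab <- rank_candidates(fits, n = 25)
  l1 <- model_average(tab)
  l1 <- l1[l1$term == "L1", ]
  expect_equal(l1$estimate, -1)
  expect_equal(l1$lower, -1)
  expect_equal(l1$upper, -1)
})

test_that("averaged estimates stay inside the per-model range", {
  set.seed(33)
  for (rep in 1:4) {
    ds <- prepared(make_series(exp(rnorm(16, 1, 0.4))))
    fits <- lapply(enumerate_candidates(full_spec("overwinter")),
                   function(sp) fit_linear_ml(build_design(sp, ds)))
    tab <- rank_candidates(fits)
    avg <- model_average(tab)
    for (i in seq_len(nrow(avg))) {
      term <- avg$term[i]
      ests <- unlist(lapply(attr(tab, "fits"), function(f) {
        f$coefficients$estimate[f$coefficients$term == term]
      }))
      expect_gte(avg$estimate[i], min(ests) - 1e-12)
      expect_lte(avg$estimate[i], max(ests) + 1e-12)
      expect_lte(avg$lower[i], avg$estimate[i])
      expect_gte(avg$upper[i], avg$estimate[i])
    }
  }
})

test_that("the report shows the cutoff set and flags plausible models", {
  fits <- lapply(c(-10, -10.69, -11.2, -12.5, -13.4), function(ll) {
    f <- fake_fit("L1", 1, 1, loglik = ll, n = 21)
    f$k_params <- 3L
    f
  })
  tab <- rank_candidates(fits, n = 21)
  lines <- report_table(tab, show_cut = 7, plausible_cut = 2)
  body <- lines[-c(1, length(lines))]
  expect_length(body, 5)
  expect_equal(sum(grepl("\\*$", trimws(body))), 2)  # deltas 0 and 1.38

  tab_far <- rank_candidates(list(fits[[1]], {
    f <- fake_fit("L1", 1, 1, loglik = -14, n = 21); f$k_params <- 3L; f
  }), n = 21)
  shown <- report_table(tab_far, show_cut = 7)
  expect_length(shown, 1 + 1 + 1)  # header + one row + footer

  empty <- tab[tab$delta_aicc > 99, ]
  expect_length(report_table(tab[0, ]), 0)
})
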