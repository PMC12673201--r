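test_that("AUC handles perfect separation and complete ties", {
  r <- roc_curve(scored(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)))
  expect_equal(r$auc, 1)
  r2 <- roc_curve(scored(rep(0.4, 10), rep(c(0, 1), 5)))
  expect_equal(r2$auc, 0.5)
  expect_error(roc_curve(scored(runif(5), rep(1, 5))), "positive and")
})

test_that("AUC equals brute-force pairwise enumeration on random score sets", {
  withr::with_seed(23, {
    for (i in 1:6) {
      n <- 30
      lab <- c(0, 1, rbinom(n - 2, 1, 0.4))
      sc <- round(runif(n), 2)  # rounding forces ties
      expect_equal(roc_curve(scored(sc, lab))$auc,
                   oracle_auc_pairwise(sc, lab), tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under monotone transforms and flips under relabeling", {
  withr::with_seed(29, {
    lab <- c(0, 1, rbinom(40, 1, 0.3))
    sc <- rnorm(42)
    a <- roc_curve(scored(sc, lab))$auc
    expect_equal(roc_curve(scored(exp(3 * sc), lab))$auc, a, tolerance = 1e-12)
    expect_equal(roc_curve(scored(sc, 1 - lab))$auc, 1 - a, tolerance = 1e-12)
  })
})

test_that("AUC agrees with an established ROC implementation", {
  withr::with_seed(31, {
    lab <- c(0, 1, rbinom(60, 1, 0.35))
    sc <- round(rnorm(62), 1)
    ours <- roc_curve(scored(sc, lab))$auc
    ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("Youden operating point equals the exhaustive threshold scan", {
  withr::with_seed(37, {
    for (i in 1:6) {
      lab <- c(0, 1, rbinom(38, 1, 0.5))
      sc <- round(runif(40), 2)
      op <- youden_operating_point(roc_curve(scored(sc, lab)))
      ref <- oracle_youden_scan(sc, lab)
      expect_equal(op$threshold, ref$threshold)
      expect_equal(op$sensitivity, ref$sens)
      expect_equal(op$specificity, ref$spec)
      expect_equal(op$accuracy,
                   mean((sc > ref$threshold) == (lab == 1)), tolerance = 1e-12)
    }
  })
  # perfect separation: J = 1 first reached at the highest negative score
  op <- youden_operating_point(roc_curve(scored(c(0.9, 0.8, 0.1, 0.2),
                                                c(1, 1, 0, 0))))
  expect_equal(op$youden_j, 1)
  expect_equal(op$threshold, 0.2)
})

test_that("DeLong on identical score sets gives z = 0, p = 1", {
  withr::with_seed(41, a <- scored(runif(30), c(0, 1, rbinom(28, 1, 0.5))))
  expect_warning(res <- delong_test(a, a), "zero variance")
  expect_equal(res$z, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$auc_a, res$auc_b)
})

test_that("DeLong is antisymmetric and matches an established implementation", {
  withr::with_seed(43, {
    lab <- c(0, 1, rbinom(58, 1, 0.4))
    sa <- rnorm(60) + lab
    sb <- rnorm(60) + 0.5 * lab
    a <- scored(sa, lab)
    b <- scored(sb, lab)
    ab <- delong_test(a, b)
    ba <- delong_test(b, a)
    expect_equal(ab$z, -ba$z, tolerance = 1e-12)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)

    ra <- pROC::roc(lab, sa, quiet = TRUE, direction = "<")
    rb <- pROC::roc(lab, sb, quiet = TRUE, direction = "<")
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(abs(ab$z), abs(as.numeric(ref$statistic)), tolerance = 1e-9)
    expect_equal(ab$p_value, as.numeric(ref$p.value), tolerance = 1e-9)
  })
  expect_error(delong_test(scored(runif(4), c(0, 1, 0, 1)),
                           scored(runif(3), c(0, 1, 0))), "same segments")
})

test_that("DeLong single-AUC variance has the right order on balanced data", {
  withr::with_seed(47, {
    sc <- scored(rnorm(80), rep(c(0, 1), 40))
    v <- delong_variance(sc)
    nominal <- 1 / (4 * 40)
    expect_gt(v, nominal / 10)
    expect_lt(v, nominal * 10)
  })
})

test_that("observer-case selection returns the requested class counts within tolerance", {
  withr::with_seed(53, {
    pool <- tibble::tibble(
      segment_id = sprintf("S%04d", 1:951),
      label = c(rep(1L, 84), rep(0L, 867)),
      score = c(rbeta(84, 4, 2), rbeta(867, 1.5, 5))
    )
  })
  sel <- select_observer_cases(pool, 40, 40, tolerance = 0.02, seed = 3)
  expect_equal(nrow(sel$selected), 80L)
  expect_equal(sum(sel$selected$label == 1), 40L)
  expect_equal(sum(sel$selected$label == 0), 40L)
  expect_lte(abs(sel$auc_subset - sel$auc_full), 0.02)
  expect_true(sel$converged)
  # deterministic given the seed
  sel2 <- select_observer_cases(pool, 40, 40, tolerance = 0.02, seed = 3)
  expect_identical(sel$segment_ids, sel2$segment_ids)
  # a vacuous tolerance accepts the first draw
  expect_equal(select_observer_cases(pool, 40, 40, tolerance = 1,
                                     seed = 5)$n_draws, 1L)
  expect_error(select_observer_cases(pool, 500, 40, seed = 1), "not enough")
})

test_that("group-averaged ROC averages AUCs and stays within member envelopes", {
  withr::with_seed(59, {
    lab <- c(0, 1, rbinom(38, 1, 0.5))
    base <- rnorm(40) + 1.5 * lab
    ratings <- dplyr::bind_rows(lapply(1:3, function(r) {
      tibble::tibble(reader_id = paste0("R", r),
                     segment_id = sprintf("S%02d", 1:40),
                     label = lab,
                     score = base + rnorm(40, sd = r / 2))
    }))
  })
  g <- group_average_roc(ratings)
  per_reader <- sapply(split(ratings, ratings$reader_id),
                       function(d) roc_curve(d)$auc)
  expect_equal(g$mean_auc, mean(per_reader), tolerance = 1e-12)
  expect_equal(sort(unname(g$reader_aucs)), sort(unname(per_reader)))
  expect_true(all(g$curve$mean_tpr >= g$curve$min_tpr - 1e-12))
  expect_true(all(g$curve$mean_tpr <= g$curve$max_tpr + 1e-12))

  one <- group_average_roc(ratings[ratings$reader_id == "R1", ])
  expect_equal(one$mean_auc, unname(per_reader["R1"]), tolerance = 1e-12)

  bad <- ratings
  bad$segment_id[1] <- "S99"
  expect_error(group_average_roc(bad), "same segments")
})
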