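test_that("replicate collapse averages determined values only", {
  tab <- data.frame(
    sample_id = rep("s1", 8),
    target = rep(c("A", "B", "C"), c(2, 3, 3)),
    replicate = c(1:2, 1:3, 1:3),
    ct = c(25.0, 25.2, 35, 36, NA, NA, NA, NA)
  )
  coll <- collapse_replicates(tab)
  expect_equal(coll$mean_ct[coll$target == "A"], 25.1)
  expect_equal(coll$mean_ct[coll$target == "B"], 35.5)
  expect_equal(coll$n_detected[coll$target == "B"], 2L)
  expect_true(is.na(coll$mean_ct[coll$target == "C"]))
  expect_equal(coll$n_detected[coll$target == "C"], 0L)
})

test_that("ct tables round-trip through CSV with UNDETERMINED literals", {
  tab <- simulate_plasma_panel(n_per_group = c(normal = 3, adenoma = 3,
                                               cancer = 3),
                               seed = 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(tab, path)
  expect_true(any(grepl("UNDETERMINED", readLines(path))))
  back <- read_ct_table(path)
  expect_equal(back$ct, tab$ct)
  expect_equal(back$sample_id, tab$sample_id)

  writeLines(c("sample_id,target,replicate,ct", "s1,A,1,oops"), path)
  expect_error(read_ct_table(path), "non-numeric")
})

test_that("delta-delta-Ct reproduces the Livak closed forms", {
  # calibrator identity
  cal <- delta_delta_ct(27.0, 20.0, calibrator_delta_ct = 7.0)
  expect_equal(cal$delta_delta_ct, 0)
  expect_equal(cal$rq, 1)

  # frozen worked case
  r <- delta_delta_ct(25.1, 20.1, calibrator_delta_ct = 7.0)
  expect_equal(r$delta_delta_ct, -2)
  expect_equal(r$rq, 4)

  # one extra cycle on the target halves the relative quantity exactly
  r2 <- delta_delta_ct(26.1, 20.1, calibrator_delta_ct = 7.0)
  expect_equal(r2$rq, r$rq / 2)

  expect_error(delta_delta_ct(c(25, NA), c(20, 20), 7), "undetermined|collapse")
})

test_that("tissue workflow flags discordant duplicates", {
  tab <- simulate_tissue_qpcr(c(1, 2), replicate_sd = 0, seed = 3L)
  tab$ct[tab$sample_id == "tissue_02" & tab$target == "KIAA1199"] <-
    c(25, 27)
  expect_warning(
    res <- tissue_relative_quantity(tab, calibrator = "tissue_01"),
    "discordant")
  expect_equal(res$rq[1], 1)
})

test_that("spike-in normalization matches its arithmetic and is yield-invariant", {
  # sample spike equal to the panel mean: normalized = raw
  expect_equal(normalize_plasma_ct(35, 27, 27), 35)
  # worked case
  expect_equal(normalize_plasma_ct(35, 28, 27), 34)

  # per-sample additive offsets cancel exactly
  set.seed(8)
  ct <- runif(10, 30, 38)
  arm <- runif(10, 26, 29)
  delta <- rnorm(10, 0, 3)
  base <- normalize_plasma_ct(ct, arm, mean(arm))
  shifted <- normalize_plasma_ct(ct + delta, arm + delta, mean(arm + delta))
  expect_equal(shifted - mean(delta), base - 0, tolerance = 1e-12)
  # a single sample's offset leaves other samples' normalized Ct untouched
  # up to the panel-mean term, and its own target/spike shift cancels fully
  one <- rep(0, 10); one[4] <- 5
  shifted1 <- normalize_plasma_ct(ct + one, arm + one, mean(arm + one))
  expect_equal(shifted1 - shifted1[4], base - base[4], tolerance = 1e-12)

  expect_warning(normalize_plasma_ct(c(35, 36), c(28, NA), 27),
                 "extraction failure")
})

test_that("fold change versus the control median follows the base-2 law", {
  ct <- c(30, 30, 30, 28, 32)
  grp <- c("normal", "normal", "normal", "cancer", "cancer")
  fc <- fold_change_vs_reference_group(ct, grp)
  expect_equal(fc[1:3], rep(1, 3))   # at the reference median
  expect_equal(fc[4], 4)             # two cycles below: 4-fold
  expect_equal(fc[5], 0.25)
  # reference-group median fold change is exactly 1 by construction
  expect_equal(median(fc[grp == "normal"]), 1)
  expect_error(fold_change_vs_reference_group(ct, grp, "plasmaX"),
               "no detected samples")
})

test_that("detection calls follow the replicate-majority rule", {
  expect_true(detection_call(3))
  expect_false(detection_call(1))
  expect_true(detection_call(1, min_detected_replicates = 1))
  expect_equal(detection_call(c(0, 1, 2, 3)), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("exact Mann-Whitney matches full enumeration", {
  r <- mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")

  # exchanging groups: U -> nx*ny - U, identical p
  r2 <- mann_whitney_exact(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$U, 9)
  expect_equal(r2$p, r$p)

  # exhaustive property: all tie-free inputs with n_x + n_y <= 8 reduce to
  # their rank pattern, so enumerate every (nx, ny) split of 1..8
  for (n in 4:8) {
    for (nx in 2:(n - 2)) {
      sets <- utils::combn(n, nx)
      take <- seq(1, ncol(sets), by = max(1L, ncol(sets) %/% 12))
      for (j in take) {
        x <- sets[, j]
        y <- setdiff(seq_len(n), x)
        mine <- mann_whitney_exact(x, y)
        oracle <- mw_enumeration_oracle(x, y)
        expect_equal(mine$U, oracle$U)
        expect_equal(mine$p, oracle$p, tolerance = 1e-12)
      }
    }
  }
})

test_that("exact Mann-Whitney agrees with wilcox.test on tie-free data", {
  set.seed(12)
  for (i in 1:15) {
    x <- rnorm(sample(3:6, 1))
    y <- rnorm(sample(3:6, 1))
    mine <- mann_whitney_exact(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the approximate path handles ties and identical groups", {
  x <- c(1, 2, 2, 3, 5, 6, 7, 8)
  r <- mann_whitney_exact(x, x)
  expect_equal(r$method, "approximate")
  expect_equal(r$p, 1)

  big_x <- rnorm(15); big_y <- rnorm(15, 2)
  r2 <- mann_whitney_exact(big_x, big_y)
  ref <- wilcox.test(big_x, big_y, exact = FALSE, correct = FALSE)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-10)
})

test_that("group separation of 3 cycles is detected reliably", {
  rejections <- vapply(1:200, function(r) {
    set.seed(5000 + r)
    ctrl <- rnorm(20, 38, 1)
    neo <- rnorm(20, 35, 1)
    mann_whitney_exact(neo, ctrl)$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})

test_that("plasma analysis integrates detection, normalization and fold change", {
  panel <- simulate_plasma_panel(seed = 4L)
  res <- analyze_plasma(panel)
  expect_equal(nrow(res), 60L)
  expect_true(all(is.na(res$fold_change[!res$detected])))
  det_norm <- res$detected & res$group == "normal"
  if (sum(det_norm) >= 1) {
    expect_equal(median(res$fold_change[det_norm]), 1)
  }
})

test_that("the penalized logistic classifier honors its contracts", {
  # perfectly separated toy: all six classified correctly
  ct <- c(38, 39, 40, 30, 31, 32)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic_classifier(ct, y)
  expect_true(fit$converged)
  expect_equal(unname(classify_neoplasia(fit, ct)), as.logical(y))

  # boundary: predicted probability exactly 0.5 classifies as neoplasia
  mid <- -fit$coefficients[1] / fit$coefficients[2]
  expect_equal(unname(predict(fit, mid)), 0.5, tolerance = 1e-9)
  expect_true(classify_neoplasia(fit, mid))

  # label flip negates coefficients and flips every classification
  flip <- fit_logistic_classifier(ct, 1 - y)
  expect_equal(flip$coefficients, -fit$coefficients, tolerance = 1e-7)
  expect_equal(unname(classify_neoplasia(flip, ct)), !as.logical(y))

  expect_error(fit_logistic_classifier(ct, c(0, 0, 0, 0, 0, 1)),
               "2 samples per class")
})

test_that("IRLS coefficients match a grid search of the penalized likelihood", {
  ct <- c(38, 39, 40, 30, 31, 32)
  y <- c(0, 0, 0, 1, 1, 1)
  lambda <- 1e-4
  fit <- fit_logistic_classifier(ct, y, lambda = lambda)

  pen_loglik <- function(b0, b1) {
    eta <- b0 + b1 * ct
    # numerically stable Bernoulli log-likelihood
    sum(-log1p(exp((1 - 2 * y) * eta))) - lambda / 2 * b1^2
  }
  # coarse-to-fine grid search, ranges chosen from the penalty scale
  b0s <- seq(0, 250, length.out = 251)
  b1s <- seq(-7, 0, length.out = 141)
  ll <- outer(b0s, b1s, Vectorize(pen_loglik))
  best <- arrayInd(which.max(ll), dim(ll))
  b0 <- b0s[best[1]]; b1 <- b1s[best[2]]
  for (i in 1:3) {
    b0s <- seq(b0 - 1, b0 + 1, length.out = 201)
    b1s <- seq(b1 - 0.05, b1 + 0.05, length.out = 201)
    ll <- outer(b0s, b1s, Vectorize(pen_loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    b0 <- b0s[best[1]]; b1 <- b1s[best[2]]
  }
  expect_equal(unname(fit$coefficients[1]), b0, tolerance = 5e-3)
  expect_equal(unname(fit$coefficients[2]), b1, tolerance = 5e-3)
})

test_that("well-conditioned fits agree with glm", {
  set.seed(31)
  ct <- c(rnorm(30, 37, 1.5), rnorm(30, 34, 1.5))
  y <- rep(c(0, 1), each = 30)
  fit <- fit_logistic_classifier(ct, y, lambda = 1e-8)
  ref <- glm(y ~ ct, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-4)
})
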