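test_that("roc_auc matches the pairwise-comparison oracle", {
  # forced cases
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c("A", "A", "B", "B"))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("A", "B"), 3))$auc, 0.5)

  # handcrafted 8 scores with one tie
  s <- c(0.9, 0.7, 0.7, 0.6, 0.5, 0.4, 0.3, 0.1)
  l <- c("A", "A", "B", "A", "B", "A", "B", "B")
  r <- roc_auc(s, l)
  expect_equal(r$auc, oracle_auc(s, l))

  # curve contracts
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(tail(r$points$fpr, 1), 1)
  expect_equal(tail(r$points$tpr, 1), 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))

  # randomised oracle agreement and monotone-transform invariance
  for (k in 1:10) {
    n <- 5 + (k %% 6)
    ss <- slideuq:::local_seed(300 + k, round(runif(n), 2))
    ll <- slideuq:::local_seed(400 + k,
                               c("A", "B", sample(c("A", "B"), n - 2, TRUE)))
    expect_equal(roc_auc(ss, ll)$auc, oracle_auc(ss, ll))
    expect_equal(roc_auc(plogis(5 * ss - 2), ll)$auc, roc_auc(ss, ll)$auc)
  }
  expect_error(roc_auc(c(0.1, 0.9), c("A", "A")), "both classes")
})

test_that("global rejection curves match exhaustive enumeration", {
  # all-correct case: accuracy constant at 1 across the whole grid
  d_ok <- fake_diagnoses(c(0.9, 0.8, 0.2, 0.1), c(4, 3, 2, 1) / 100,
                         truth = c("A", "A", "B", "B"))
  rc <- rejection_curve(d_ok, d_ok$truth, metric = "accuracy")
  expect_true(all(rc$points$metric_value == 1))
  expect_equal(rc$points$metric_value[rc$points$fraction_removed == 0], 1)

  # 10 slides, the 2 errors carry the 2 largest sigmas -> accuracy 1 at 20%
  mu <- c(0.9, 0.8, 0.7, 0.6, 0.6, 0.4, 0.4, 0.3, 0.45, 0.55)
  truth <- c("A", "A", "A", "A", "A", "B", "B", "B", "A", "B")
  sigma <- c(1, 2, 3, 4, 5, 6, 7, 8, 20, 19) / 100 # errors = slides 9, 10
  d10 <- fake_diagnoses(mu, sigma, truth)
  expect_equal(sum(d10$label != d10$truth), 2)
  rc10 <- rejection_curve(d10, truth, metric = "accuracy")
  acc20 <- rc10$points$metric_value[abs(rc10$points$fraction_removed - 0.2) < 1e-9]
  expect_equal(acc20, 1)

  # every grid point equals the enumeration oracle, both metrics
  for (metric in c("accuracy", "auc")) {
    rc <- rejection_curve(d10, truth, metric = metric)
    for (i in seq_len(nrow(rc$points))) {
      k <- floor(rc$points$fraction_removed[i] * nrow(d10) + 1e-9)
      expect_equal(rc$points$metric_value[i],
                   oracle_rejection_global(d10, k, metric))
    }
  }
})

test_that("class-specific rejection dominates global rejection", {
  # errors split across predicted classes at different sigma scales
  mu <- c(0.9, 0.8, 0.75, 0.3, 0.2, 0.25, 0.65, 0.35)
  truth <- c("A", "A", "A", "B", "B", "B", "B", "A")
  sigma <- c(0.01, 0.02, 0.03, 0.001, 0.002, 0.003, 0.05, 0.004)
  d8 <- fake_diagnoses(mu, sigma, truth) # errors: slides 7 (pred A), 8 (pred B)
  g <- rejection_curve(d8, truth, metric = "accuracy", mode = "global")
  cs <- rejection_curve(d8, truth, metric = "accuracy", mode = "class_specific")

  # every class-specific point matches the exhaustive 2-d search oracle
  for (i in seq_len(nrow(cs$points))) {
    k <- round(cs$points$fraction_removed[i] * nrow(d8))
    expect_equal(cs$points$metric_value[i], oracle_rejection_class(d8, k, "accuracy"))
  }

  # dominance at matching fractions, here and on random instances
  check_dominance <- function(d) {
    g <- rejection_curve(d, d$truth, metric = "accuracy", mode = "global")
    cs <- rejection_curve(d, d$truth, metric = "accuracy",
                          mode = "class_specific")
    for (i in seq_len(nrow(g$points))) {
      f <- g$points$fraction_removed[i]
      j <- which(abs(cs$points$fraction_removed - floor(f * nrow(d) + 1e-9) / nrow(d)) < 1e-9)
      if (length(j) == 1 && !is.na(cs$points$metric_value[j]) &&
          !is.na(g$points$metric_value[i])) {
        expect_gte(cs$points$metric_value[j], g$points$metric_value[i])
      }
    }
  }
  check_dominance(d8)
  for (k in 1:5) {
    n <- 6 + k
    d <- slideuq:::local_seed(500 + k, fake_diagnoses(
      runif(n), runif(n, 0, 0.05),
      truth = c("A", "B", sample(c("A", "B"), n - 2, TRUE))))
    check_dominance(d)
  }

  # class-specific reaches perfect accuracy no later than global
  first_perfect <- function(rc) {
    hit <- rc$points$fraction_removed[!is.na(rc$points$metric_value) &
                                        rc$points$metric_value == 1]
    if (length(hit)) min(hit) else Inf
  }
  expect_lte(first_perfect(cs), first_perfect(g))

  # undefined AUC points are flagged, never interpolated
  d3 <- fake_diagnoses(c(0.9, 0.8, 0.1), c(0.01, 0.02, 0.5),
                       truth = c("A", "A", "B"))
  rc3 <- rejection_curve(d3, d3$truth, metric = "auc",
                         fractions = c(0, 1 / 3))
  expect_true(is.na(rc3$points$metric_value[2]))
  expect_false(rc3$points$defined[2])
})

test_that("ood_threshold is the inclusive keep-quantile", {
  s <- c(rep(0.01, 90), rep(0.05, 10))
  t <- ood_threshold(s, 0.9)
  expect_gte(t, 0.01)
  expect_lte(t, 0.05)
  expect_equal(mean(s > t), 0.1)

  # keep 0.5 on {1..100}/1000: the type-1 quantile is the lower median
  t2 <- ood_threshold((1:100) / 1000, 0.5)
  expect_gte(t2, 0.050)
  expect_lte(t2, 0.051)

  # simulation: rejected fraction tracks 1 - keep_fraction
  big <- slideuq:::local_seed(77, abs(c(rnorm(800, 0.01, 0.003),
                                        rnorm(200, 0.03, 0.01))))
  t3 <- ood_threshold(big, 0.8)
  expect_lt(abs(mean(big > t3) - 0.2), 0.01)
  expect_error(ood_threshold(numeric(0)), "empty")
})

test_that("ood_report counts rejections on both sides", {
  internal <- slideuq:::local_seed(5, abs(rnorm(200, 0.01, 0.004)))
  same <- slideuq:::local_seed(6, abs(rnorm(200, 0.01, 0.004)))
  far <- rep(1, 50)

  null_rep <- ood_report(internal, same, keep_fraction = 0.9)
  expect_lt(abs(null_rep$ood_rejected_fraction - 0.1), 0.05)

  sep <- ood_report(internal, far, keep_fraction = 0.9)
  expect_equal(sep$ood_rejected_fraction, 1)

  # counting oracle
  ext <- slideuq:::local_seed(7, abs(rnorm(150, 0.05, 0.02)))
  rep3 <- ood_report(internal, ext, keep_fraction = 0.9)
  t <- sort(internal)[ceiling(0.9 * length(internal))]
  expect_equal(rep3$threshold, t)
  expect_equal(rep3$internal_rejected_fraction, sum(internal > t) / 200)
  expect_equal(rep3$ood_rejected_fraction, sum(ext > t) / 150)
})

test_that("uncertainty densities are proper and well-located", {
  # point mass: bandwidth floored (flagged), density integrates to ~1
  d1 <- uncertainty_density(list(g = rep(0.02, 30)))
  expect_true(d1$floored["g"])
  step <- diff(d1$grid[1:2])
  expect_equal(sum(d1$density$g) * step, 1, tolerance = 0.01)
  expect_lt(abs(d1$grid[which.max(d1$density$g)] - 0.02), 2 * step)

  # two disjoint groups: density modes ordered like the group means
  d2 <- uncertainty_density(list(lo = runif(40, 0.01, 0.02),
                                 hi = runif(40, 0.08, 0.09)))
  expect_lt(d2$grid[which.max(d2$density$lo)], d2$grid[which.max(d2$density$hi)])

  # seeded unimodal sample: integral ~1, mode near the histogram mode
  x <- slideuq:::local_seed(9, rnorm(200, 0.05, 0.008))
  d3 <- uncertainty_density(list(g = x))
  step3 <- diff(d3$grid[1:2])
  expect_equal(sum(d3$density$g) * step3, 1, tolerance = 0.01)
  h <- hist(x, breaks = 20, plot = FALSE)
  mode_hist <- h$mids[which.max(h$counts)]
  expect_lt(abs(d3$grid[which.max(d3$density$g)] - mode_hist),
            2 * d3$bandwidth["g"] + diff(h$mids[1:2]))
  expect_error(uncertainty_density(list(a = numeric(0))), "non-empty")
})

test_that("correctness_split partitions sigmas by diagnostic outcome", {
  d_ok <- fake_diagnoses(c(0.9, 0.1), c(0.01, 0.02), truth = c("A", "B"))
  cs_ok <- correctness_split(d_ok, d_ok$truth)
  expect_equal(length(cs_ok$erroneous), 0)

  mu <- c(0.9, 0.8, 0.3, 0.2, 0.6, 0.4)
  truth <- c("A", "A", "B", "B", "B", "A") # slides 5 and 6 are wrong
  sigma <- c(0.011, 0.012, 0.013, 0.014, 0.021, 0.022)
  d6 <- fake_diagnoses(mu, sigma, truth)
  cs <- correctness_split(d6, truth)
  expect_equal(sort(cs$correct), sort(sigma[1:4]))
  expect_equal(sort(cs$erroneous), sort(sigma[5:6]))

  # per-class splits partition the global split exactly
  expect_equal(sort(c(cs$by_class$A$correct, cs$by_class$B$correct)),
               sort(cs$correct))
  expect_equal(sort(c(cs$by_class$A$erroneous, cs$by_class$B$erroneous)),
               sort(cs$erroneous))
})
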