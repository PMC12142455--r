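test_that("treatment labels follow the 50%/5% overlap thresholds", {
  expect_equal(assign_treatment(c(0.6, 0.2, 0.01)),
               c("treated", "excluded", "control"))
  # boundaries excluded from treated/control
  expect_equal(assign_treatment(c(0.5, 0.05)), c("excluded", "excluded"))
  set.seed(41)
  fr <- runif(5000)
  lab <- assign_treatment(fr)
  expect_equal(sum(lab == "treated"), sum(fr > 0.5))
  expect_equal(sum(lab == "control"), sum(fr < 0.05))
  expect_equal(sum(lab == "excluded"), sum(fr >= 0.05 & fr <= 0.5))
  expect_error(assign_treatment(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("propensity scores behave under null, monotone and degenerate cases", {
  set.seed(51)
  n <- 800
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  # treatment independent of covariates
  tr <- runif(n) < 0.3
  sc <- propensity_scores(X, tr)
  expect_lt(abs(mean(sc) - mean(tr)), 0.02)
  auc <- c_statistic(sc, tr)
  expect_lt(auc, 0.5 + 3 * sqrt((n + 1) / (12 * sum(tr) * sum(!tr))))

  # single strongly predictive covariate: scores monotone in it
  x <- rnorm(n)
  tr2 <- runif(n) < plogis(2 * x)
  sc2 <- propensity_scores(data.frame(x = x), tr2)
  expect_equal(order(sc2), order(x))

  # constant covariates: every score equals the treated fraction
  sc3 <- propensity_scores(data.frame(k = rep(1, 20), j = rep(2, 20)),
                           rep(c(TRUE, FALSE), 10))
  expect_equal(unname(sc3), rep(0.5, 20))

  # perfect separation is an error
  xs <- c(rep(-2, 10), rep(2, 10))
  expect_error(propensity_scores(data.frame(x = xs),
                                 xs > 0), "separation")
  expect_error(propensity_scores(data.frame(x = 1:4), rep(TRUE, 4)),
               "at least one")
})

test_that("nearest-neighbour matching respects caliper and uniqueness", {
  # 1 treated, 1 control inside the caliper -> one pair
  m <- nn_match(c(0.52, 0.5), c(TRUE, FALSE), ids = 1:2, caliper_sd = 25)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$control_id, 2)

  # control outside the caliper -> discarded
  sc <- c(0.9, 0.1, 0.12, 0.11)
  m2 <- nn_match(sc, c(TRUE, FALSE, FALSE, FALSE), ids = 1:4,
                 caliper_sd = 0.25)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(unname(m2$discarded), 1)

  expect_warning(nn_match(c(0.5, 0.6), c(TRUE, TRUE), ids = 1:2),
                 "lacks control")
})

test_that("matching equals the greedy oracle on seeded problems", {
  for (seed in 1:5) {
    set.seed(seed)
    n_t <- 20; n_c <- 50
    sc_t <- runif(n_t, 0.3, 0.9)
    sc_c <- runif(n_c, 0.1, 0.8)
    scores <- c(sc_t, sc_c)
    trt <- rep(c(TRUE, FALSE), c(n_t, n_c))
    ids <- seq_len(n_t + n_c)
    m <- nn_match(scores, trt, ids = ids, caliper_sd = 0.25)
    cal <- 0.25 * sd(scores)
    ord <- order(-sc_t, ids[trt])
    oracle <- oracle_greedy_match(sc_t[ord], sc_c, ids[!trt], cal)
    got <- m$pairs$control_id[match(ids[trt][ord], m$pairs$treated_id)]
    expect_equal(got, oracle)
    # no control reused; all pair distances within the caliper
    expect_false(anyDuplicated(m$pairs$control_id) > 0)
    expect_true(all(m$pairs$distance <= cal))
  }
})

test_that("SMD measures balance with the pooled-SD normalization", {
  x <- c(rnorm(50), rnorm(50))
  tr <- rep(c(TRUE, FALSE), each = 50)
  x_id <- c(1:50, 1:50)  # identical groups
  smd0 <- balance_smd(c(1:50, 1:50), tr)
  expect_equal(as.numeric(smd0), 0)
  expect_true(attr(smd0, "balanced"))

  set.seed(61)
  a <- rnorm(200, 0, 1); b <- rnorm(200, 1, 1)
  smd1 <- balance_smd(c(a, b), rep(c(TRUE, FALSE), each = 200))
  expect_equal(as.numeric(smd1),
               abs(mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2))
  expect_false(attr(smd1, "balanced"))

  # zero pooled variance with unequal means: flagged unbalanced
  smd_inf <- balance_smd(rep(c(0, 1), each = 5), rep(c(TRUE, FALSE), each = 5))
  expect_equal(as.numeric(smd_inf), Inf)
  expect_false(attr(smd_inf, "balanced"))
})

test_that("C-statistic matches exhaustive concordance and its bounds", {
  # perfectly separating scores
  expect_equal(c_statistic(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # folding keeps it >= 0.5 even for anti-concordant scores
  expect_equal(c_statistic(c(0.1, 0.2, 0.9, 0.8), c(TRUE, TRUE, FALSE, FALSE)), 1)

  # 3 vs 3 hand-enumerable sample, including a tie
  sc <- c(0.3, 0.5, 0.7, 0.3, 0.4, 0.6)
  tr <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(c_statistic(sc, tr), oracle_c_statistic(sc, tr))

  set.seed(71)
  for (i in 1:5) {
    sc <- sample(round(runif(12), 1))  # ties likely
    tr <- sample(rep(c(TRUE, FALSE), 6))
    expect_equal(c_statistic(sc, tr), oracle_c_statistic(sc, tr))
  }

  # random scores: near 0.5
  set.seed(72)
  sc <- runif(2000); tr <- rep(c(TRUE, FALSE), 1000)
  se <- sqrt((2000 + 1) / (12 * 1000 * 1000))
  expect_lt(c_statistic(sc, tr), 0.5 + 3 * se)
})

test_that("paired Wilcoxon handles exact, approximate and degenerate cases", {
  # all positive, distinct magnitudes, n = 6: one-sided exact p = 1/2^6
  res <- paired_wilcoxon(c(2, 4, 6, 8, 10, 12), c(1, 2, 3, 4, 5, 6),
                         alternative = "greater")
  expect_equal(res$p_value, 1 / 64)

  # identical vectors: degenerate, p = 1 with flag
  res2 <- paired_wilcoxon(c(1, 2, 3), c(1, 2, 3))
  expect_true(res2$degenerate)
  expect_equal(res2$p_value, 1)
  expect_equal(res2$n_zero, 3)

  # zero differences dropped before ranking
  res3 <- paired_wilcoxon(c(1, 2, 3, 10), c(1, 2, 3, 4),
                          alternative = "greater")
  expect_equal(res3$n_pairs, 1)
  expect_equal(res3$p_value, 0.5)

  # large-sample path agrees with the base implementation
  set.seed(81)
  x <- rnorm(100); y <- rnorm(100)
  res4 <- paired_wilcoxon(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(res4$p_value, ref$p.value)
})

test_that("matching removes covariate imbalance the naive contrast retains", {
  g <- grid_spec(64, 64, 10)
  n_improved <- 0; n_cov <- 0
  naive_rej <- 0; matched_rej <- 0; n_seeds <- 10
  # outcome aligned with the protection drivers so the confounding bias of
  # the naive contrast does not cancel between covariates
  om <- c(bio_temp = 0.5, bio_prec = 0, land_cover = 0, human_footprint = 0,
          elevation = 0.5)
  for (seed in 1:n_seeds) {
    land <- make_protected_landscape(g, n_polygons = 0, outcome_model = om,
                                     seed = 1000 + seed)
    cells <- land$cells
    lab <- assign_treatment(cells$protection_fraction)
    keep <- lab != "excluded"
    sub <- cells[keep, ]; trt <- lab[keep] == "treated"
    covn <- c("bio_temp", "bio_prec", "land_cover", "human_footprint",
              "elevation")
    sc <- propensity_scores(sub[covn], trt)
    m <- nn_match(sc, trt, ids = sub$cell_id)
    it <- match(m$pairs$treated_id, sub$cell_id)
    ic <- match(m$pairs$control_id, sub$cell_id)
    ptr <- rep(c(TRUE, FALSE), each = nrow(m$pairs))
    smd_before <- vapply(covn, function(v)
      as.numeric(balance_smd(sub[[v]], trt)), numeric(1))
    smd_after <- vapply(covn, function(v)
      as.numeric(balance_smd(sub[[v]][c(it, ic)], ptr)), numeric(1))
    # matching never increases the number of imbalanced covariates
    n_cov <- n_cov + 1
    if (sum(smd_after > 0.1) <= sum(smd_before > 0.1))
      n_improved <- n_improved + 1
    # the generator's covariate-linked outcome: naive contrast is biased,
    # matched contrast is not (the outcome model is the confounder link)
    naive_p <- wilcox.test(sub$outcome[trt], sub$outcome[!trt],
                           exact = FALSE)$p.value
    matched_p <- paired_wilcoxon(sub$outcome[it], sub$outcome[ic])$p_value
    naive_rej <- naive_rej + (naive_p < 0.05)
    matched_rej <- matched_rej + (matched_p < 0.05)
  }
  expect_gte(n_improved / n_cov, 0.95)
  expect_gte(naive_rej / n_seeds, 0.9)   # confounding drives the naive test
  expect_lte(matched_rej / n_seeds, 0.3) # matching removes it
})

test_that("match_report assembles pairs, balance and tests per region", {
  g <- grid_spec(48, 48, 10)
  land <- make_protected_landscape(g, n_polygons = 0, n_regions = 2, seed = 3)
  cells <- land$cells
  covn <- c("bio_temp", "bio_prec", "land_cover", "human_footprint",
            "elevation")
  rep <- match_report(cells, covn, outcome_names = "outcome")
  expect_s3_class(rep, "match_report")
  expect_setequal(unique(rep$pairs$region), c("region_1", "region_2"))
  expect_true(all(rep$balance$smd_after <= rep$balance$smd_before + 0.05))
  expect_true(all(rep$c_statistic$c_after_refit < rep$c_statistic$c_before))
  expect_equal(nrow(rep$wilcoxon), 2)
  # controls never reused across the whole report
  expect_false(anyDuplicated(rep$pairs$control_id) > 0)
})
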