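test_that("Spearman rho matches the rank formula and the t reference", {
  expect_equal(spearman(1:6, (1:6)^2)$rho, 1)      # monotone invariance
  expect_equal(spearman(1:6, -(1:6))$rho, -1)
  s <- spearman(1:5, c(2, 1, 4, 3, 5))
  expect_equal(s$rho, 0.8)                          # 1 - 6*4/(5*24)
  # exact permutation p at n = 5 under the uniform null
  perms <- phagedyn:::all_permutations(5L)
  null <- apply(perms, 1, function(idx) cor(1:5, c(2, 1, 4, 3, 5)[idx]))
  expect_equal(s$p, mean(abs(null) >= 0.8 - 1e-12))
  # t-approximation branch agrees with cor.test for larger n
  set.seed(9)
  x <- rnorm(30); y <- x + rnorm(30)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  got <- spearman(x, y)
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-6)
  # invariance under strictly monotone transforms
  expect_equal(spearman(exp(x), y^3 - 2 * y^2 * 0)$rho, got$rho)
  expect_warning(out <- spearman(rep(1, 10), rnorm(10)),
                 class = "phagedyn_warning")
  expect_true(is.na(out$rho))
})

test_that("BH adjustment reproduces the textbook step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), class = "phagedyn_domain_error")
  # property vs brute-force step-up on random vectors
  set.seed(12)
  for (i in 1:10) {
    p <- runif(sample(3:12, 1))
    m <- length(p)
    o <- order(p)
    brute <- numeric(m)
    prev <- 1
    for (k in m:1) {
      prev <- min(prev, p[o[k]] * m / k)
      brute[o[k]] <- prev
    }
    got <- bh_adjust(p)
    expect_equal(got, brute)
    expect_true(all(got >= p))
  }
})

test_that("stratified pair correlation adjusts within the stratum family", {
  set.seed(21)
  samples <- tiny_samples(groups = c("CON", "HFD"), n_sub = 4, days = c(0, 10, 14))
  pm <- rand_abund(3, nrow(samples), seed = 1,
                   samples = samples$sample_id, taxa = c("P1", "P2", "P3"))
  bm <- rand_abund(3, nrow(samples), seed = 2,
                   samples = samples$sample_id, taxa = c("B1", "B2", "B3"))
  pairs <- data.frame(phage_id = c("P1", "P2", "P3"),
                      bacterium_id = c("B1", "B2", "B3"))
  res <- correlate_pairs(pm, bm, pairs, samples)
  expect_equal(nrow(res), 6L)  # 3 pairs x 2 strata
  for (s in c("CON", "HFD")) {
    sub <- res[res$stratum == s, ]
    expect_equal(sub$p_adj, bh_adjust(sub$p_raw))  # family size 3
    expect_equal(unique(sub$n), 12)
  }
  # small stratum skipped with a warning
  s2 <- samples; s2$group[s2$subject_id == "CON_m1"] <- "TINY"
  expect_warning(res2 <- correlate_pairs(pm, bm, pairs, s2),
                 class = "phagedyn_warning")
  expect_false("TINY" %in% res2$stratum)
})

test_that("interaction change classification follows the median + gate rule", {
  set.seed(31)
  base <- runif(20, 0.2, 0.6)
  expect_equal(classify_change(base, base)$direction, "non-significant")
  up <- classify_change(base, pmin(base + 0.4, 1))
  expect_equal(up$direction, "Increased")
  # antisymmetry
  down <- classify_change(pmin(base + 0.4, 1), base)
  expect_equal(down$direction, "Decreased")
  expect_equal(up$p, down$p)
  # shifted intervention detected in >= 95% of seeds
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    ctrl <- runif(20, 0.1, 0.5)
    classify_change(ctrl, pmin(ctrl + 0.4, 1))$direction == "Increased"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # equal medians cannot be called a direction even if p were small
  a <- c(0.1, 0.5, 0.5, 0.9); b <- c(0.3, 0.5, 0.5, 0.7)
  expect_equal(classify_change(a, b)$direction, "non-significant")
  expect_error(classify_change(numeric(0), base), class = "phagedyn_domain_error")
})

test_that("trend voting counts majorities exactly", {
  expect_equal(vote_trend(c(1, 1, -1))$trend, "increasing")
  expect_equal(vote_trend(c(1, -1))$trend, "indeterminate")
  expect_equal(vote_trend(numeric(0))$trend, "indeterminate")
  set.seed(14)
  for (i in 1:20) {
    d <- sample(c(-1, 1), sample(1:9, 1), replace = TRUE)
    v <- vote_trend(d)
    expect_equal(v$n_increase, sum(d == 1))
    expect_equal(v$n_decrease, sum(d == -1))
    expect_equal(v$trend, if (sum(d == 1) > sum(d == -1)) "increasing"
                 else if (sum(d == -1) > sum(d == 1)) "decreasing"
                 else "indeterminate")
  }
})

test_that("concordance scores shared projects only", {
  p <- c(a = 1, b = 1, c = -1, d = 1)
  h <- c(a = 1, b = -1, c = -1, d = 1, e = 1)
  cs <- concordance(p, h)
  expect_equal(cs$n_concordant, 3L)
  expect_equal(cs$n_discordant, 1L)
  expect_equal(cs$proportion_concordant, 0.75)
  expect_equal(concordance(c(x = 1), c(x = 1))$proportion_concordant, 1)
  expect_warning(out <- concordance(c(x = 1), c(y = 1)),
                 class = "phagedyn_warning")
  expect_true(is.na(out$proportion_concordant))
  # brute force over random tables
  set.seed(15)
  for (i in 1:10) {
    pr <- stats::setNames(sample(c(-1, 1), 6, TRUE), letters[1:6])
    hr <- stats::setNames(sample(c(-1, 1), 6, TRUE), letters[3:8])
    cs <- concordance(pr, hr)
    shared <- intersect(names(pr), names(hr))
    expect_equal(cs$n_concordant, sum(pr[shared] == hr[shared]))
    expect_equal(cs$n_discordant, sum(pr[shared] != hr[shared]))
  }
})

test_that("surrogate differential screen selects planted effects, not nulls", {
  set.seed(16)
  null_m <- make_abund(matrix(rpois(3 * 36, 50), 3, 36))
  grp <- rep(c("CON", "HFD", "FUC"), each = 12)
  res <- screen_differential(null_m, grp)
  expect_true(all(res$source == "surrogate_screen"))
  # identical distributions: nothing selected (alpha gate + effect gate)
  expect_lte(sum(res$selected), 1)
  # planted 10-fold difference, n = 12 per group
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    v <- c(rpois(12, 20), rpois(12, 200), rpois(12, 20))
    m <- make_abund(matrix(v, 1, 36))
    screen_differential(m, grp)$selected[1]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # supplied external calls bypass the screen verbatim
  sup <- screen_differential(null_m, grp, supplied = c("tA", "tB"))
  expect_identical(sup$taxon_id, c("tA", "tB"))
  expect_true(all(sup$source == "supplied"))
  expect_error(screen_differential(null_m, rep("one", 36)),
               class = "phagedyn_domain_error")
})
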