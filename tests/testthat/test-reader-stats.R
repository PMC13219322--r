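# Reader-study statistics: Turing-test bookkeeping, agreement
# coefficients (with brute-force oracles), and the group tests.

test_that("turing confusion matrix: perfect, worked, and chance cases", {
  truth <- rep(c("real", "generated"), each = 10)
  resp <- list(truth = truth,
               judgments = matrix(truth, 20, 1,
                                  dimnames = list(NULL, "rater_1")))
  perfect <- turing_confusion(resp, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(sum(perfect$matrix), 20)

  # worked 2x2: rater says real for 8 truly real + 4 truly generated
  j <- c(rep("real", 8), rep("generated", 2),      # 10 real items
         rep("real", 4), rep("generated", 6))      # 10 generated items
  resp$judgments <- matrix(j, 20, 1, dimnames = list(NULL, "rater_1"))
  wk <- turing_confusion(resp, "rater_1")
  expect_equal(wk$accuracy, 0.7)
  expect_equal(wk$sensitivity, 0.8)       # recall on truly real items
  expect_equal(wk$recall_generated, 0.6)  # recall on truly generated items

  # judgments independent of truth -> accuracy ~ 0.5
  set.seed(14)
  n <- 10000L
  truth <- sample(c("real", "generated"), n, replace = TRUE)
  resp <- list(truth = truth,
               judgments = matrix(sample(c("real", "generated"), n, TRUE),
                                  n, 1, dimnames = list(NULL, "rater_1")))
  expect_equal(turing_confusion(resp, 1)$accuracy, 0.5, tolerance = 0.02)
  expect_error(turing_confusion(resp, 7), "rater")
})

# independent, literal evaluation of the Fleiss formula
brute_fleiss <- function(m) {
  cats <- sort(unique(as.vector(m)))
  n <- nrow(m); r <- ncol(m)
  Pi <- numeric(n)
  for (i in 1:n) {
    s <- 0
    for (c1 in cats) s <- s + sum(m[i, ] == c1) * (sum(m[i, ] == c1) - 1)
    Pi[i] <- s / (r * (r - 1))
  }
  pj <- vapply(cats, function(c1) mean(m == c1), numeric(1))
  (mean(Pi) - sum(pj^2)) / (1 - sum(pj^2))
}

test_that("Fleiss' kappa: perfect agreement, null, sentinel, oracle", {
  m <- matrix(rep(c("a", "b", "a", "b"), each = 3), 4, 3, byrow = TRUE)
  expect_equal(fleiss_kappa(m)$kappa, 1)

  set.seed(15)
  m <- matrix(sample(c("x", "y"), 2000 * 5, TRUE), 2000, 5)
  expect_equal(fleiss_kappa(m)$kappa, 0, tolerance = 0.02)

  one <- matrix("a", 5, 3)
  fk <- fleiss_kappa(one)
  expect_true(is.na(fk$kappa))
  expect_match(fk$reason, "one category")

  set.seed(16)
  for (k in 1:10) {
    m <- matrix(sample(letters[1:3], 4 * 3, TRUE), 4, 3)
    if (length(unique(as.vector(m))) < 2) next
    expect_equal(fleiss_kappa(m)$kappa, brute_fleiss(m), tolerance = 1e-12)
  }
})

# literal weighted-kappa computation from the contingency table
brute_wkappa <- function(a, b, q) {
  cats <- sort(unique(c(a, b)))
  k <- length(cats)
  n <- length(a)
  po <- 0; pe <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    w <- 1 - (abs(i - j) / (k - 1))^q
    o <- sum(a == cats[i] & b == cats[j]) / n
    e <- (sum(a == cats[i]) / n) * (sum(b == cats[j]) / n)
    po <- po + w * o
    pe <- pe + w * e
  }
  (po - pe) / (1 - pe)
}

test_that("weighted Cohen's kappa: identity, null, and oracle", {
  s <- c(1, 3, 5, 2, 4, 4, 1)
  expect_equal(pairwise_kappa(s, s), 1)

  set.seed(17)
  a <- sample(1:5, 5000, TRUE)
  b <- sample(1:5, 5000, TRUE)
  expect_equal(pairwise_kappa(a, b), 0, tolerance = 0.03)

  set.seed(18)
  for (k in 1:10) {
    a <- sample(1:3, 30, TRUE)
    b <- pmin(pmax(a + sample(-1:1, 30, TRUE), 1), 3)
    expect_equal(pairwise_kappa(a, b, "quadratic"), brute_wkappa(a, b, 2),
                 tolerance = 1e-12)
    expect_equal(pairwise_kappa(a, b, "linear"), brute_wkappa(a, b, 1),
                 tolerance = 1e-12)
  }
})

# brute-force exact Wilcoxon: enumerate all sign patterns
brute_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  Ws <- vapply(0:(2^n - 1), function(mask) {
    sum(rk[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L])
  }, numeric(1))
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

test_that("Wilcoxon signed-rank: sentinel, worked case, oracle, symmetry", {
  r <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(is.na(r$statistic))

  x <- c(2.0, 3.5, 1.2, 4.4, 5.1)
  y <- x - c(0.5, 1.0, 0.2, 2.0, 1.4)  # all differences positive, distinct
  r <- wilcoxon_signed_rank(x, y)
  expect_equal(r$statistic, 15)
  expect_equal(r$p_value, 2 / 32)

  set.seed(19)
  for (n in 3:10) {
    x <- rnorm(n)
    y <- rnorm(n)
    r <- wilcoxon_signed_rank(x, y)
    expect_equal(r$p_value, brute_wilcoxon_p(x, y), tolerance = 1e-12)
    rf <- wilcoxon_signed_rank(y, x)  # sign-flip symmetry
    expect_equal(r$p_value, rf$p_value, tolerance = 1e-12)
  }
  # ties: mid-ranked, exact enumeration still matches the oracle
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(0, 1, 2, 5, 6, 4)  # |d| has ties
  expect_equal(wilcoxon_signed_rank(x, y)$p_value, brute_wilcoxon_p(x, y),
               tolerance = 1e-12)
})

test_that("group tests give textbook answers", {
  cg <- compare_groups(matrix(c(10, 20, 20, 40), 2, 2), method = "chi_square")
  expect_equal(cg$statistic, 0, tolerance = 1e-12)
  expect_equal(cg$p_value, 1, tolerance = 1e-12)

  kw <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4), method = "kruskal_wallis")
  expect_equal(kw$statistic, 0, tolerance = 1e-9)

  mw <- compare_groups(c(1, 2, 3), c(4, 5, 6), method = "mann_whitney")
  expect_equal(unname(mw$statistic), 0)

  pt <- compare_groups(c(1, 2, 3, 4, 5), c(1.2, 2.1, 3.3, 4.1, 5.2),
                       method = "paired_t")
  expect_lt(pt$p_value, 0.01)
})

test_that("rating summaries: closed forms and no-difference sentinel", {
  tab <- data.frame(item_id = rep(1:2, 2),
                    stratum = "2D-IA",
                    arm = rep(c("real", "generated"), each = 2),
                    rater_1 = c(5, 5, 5, 5), rater_2 = c(5, 4, 5, 4))
  sm <- summarize_ratings(tab)
  r5 <- sm$summary[sm$summary$arm == "real" & sm$summary$stratum == "2D-IA", ]
  expect_equal(r5$mean, mean(c(5, 5, 5, 4)))
  expect_true(is.na(sm$tests[["2D-IA"]]$statistic))  # arms identical

  expect_equal(mean(c(5, 5, 4, 5)), 4.75)
  expect_equal(sd(c(5, 5, 4, 5)), 0.5)
  tab2 <- data.frame(item_id = 1:4, stratum = "s", arm = "real",
                     rater_1 = c(5, 5, 4, 5))
  tab2 <- rbind(tab2, transform(tab2, arm = "generated", rater_1 = 5))
  sm2 <- summarize_ratings(tab2)
  g <- sm2$summary[sm2$summary$arm == "real" & sm2$summary$stratum == "s", ]
  expect_equal(g$mean, 4.75)
  expect_equal(g$sd, 0.5)
})

test_that("CSV schemas are validated and simulated responses attach", {
  design_file <- system.file("extdata", "turing_design.csv",
                             package = "angioflow")
  d <- read_turing_csv(design_file)
  expect_null(d$judgments)
  sim <- simulate_turing_responses(d, n_raters = 5, p_correct = 0.5, seed = 2)
  expect_equal(dim(sim$judgments), c(200L, 5L))
  expect_identical(simulate_turing_responses(d, 5, 0.5, seed = 2)$judgments,
                   sim$judgments)

  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_turing_csv(bad), "columns")
})
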