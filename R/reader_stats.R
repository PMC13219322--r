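# Reader-study statistics: visual Turing test confusion matrices,
# Fleiss' kappa, weighted Cohen's kappa, exact Wilcoxon signed-rank, and
# the standard group comparison tests.  Raw P-values are reported (no
# multiplicity correction); the significance convention is P < 0.05.

#' Read a visual Turing test response table
#'
#' Expected CSV schema: `item_id, stratum, truth, rater_1, ..., rater_k`
#' with `truth` and rater judgments in {"real", "generated"}.  Rater
#' columns may be absent (a design-only table).
#'
#' @param path CSV file
#' @return list with `item_id`, `strata`, `truth`, and `judgments`
#'   (items x raters character matrix, or NULL)
#' @export
read_turing_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("item_id", "stratum", "truth")
  if (!all(req %in% names(df)))
    stop("turing CSV must have columns: ", paste(req, collapse = ", "))
  rater_cols <- grep("^rater_", names(df), value = TRUE)
  bad <- setdiff(unique(df$truth), c("real", "generated"))
  if (length(bad)) stop("invalid truth labels: ", paste(bad, collapse = ", "))
  jm <- if (length(rater_cols)) as.matrix(df[rater_cols]) else NULL
  list(item_id = df$item_id, strata = df$stratum, truth = df$truth,
       judgments = jm)
}

#' Read an ordinal rating table
#'
#' Expected CSV schema: `item_id, stratum, arm, rater_1, ..., rater_k`
#' with `arm` in {"real", "generated"} and scores in 1..5; each
#' `item_id` appears once per arm (the pairing).
#'
#' @param path CSV file
#' @return data frame
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("item_id", "stratum", "arm")
  if (!all(req %in% names(df)))
    stop("ratings CSV must have columns: ", paste(req, collapse = ", "))
  rater_cols <- grep("^rater_", names(df), value = TRUE)
  if (!length(rater_cols)) stop("ratings CSV needs rater_* columns")
  sc <- as.matrix(df[rater_cols])
  if (any(!sc %in% 1:5)) stop("scores must be on the 5-level scale 1..5")
  df
}

#' Confusion matrix for one rater in the visual Turing test
#'
#' Counts rater judgments against truth.  Accuracy is overall proportion
#' correct; because "sensitivity" and "recall" are synonyms under the
#' usual definitions, both per-class recalls are emitted explicitly:
#' `sensitivity` (= recall on truly real items) and `recall_generated`
#' (recall on truly generated items).
#'
#' @param resp a response list from [read_turing_csv()] (with judgments)
#' @param rater rater column index or name
#' @return `list(matrix, accuracy, sensitivity, recall_real,
#'   recall_generated)`
#' @export
turing_confusion <- function(resp, rater) {
  if (is.null(resp$judgments)) stop("response table has no rater judgments")
  if (is.character(rater)) {
    if (!rater %in% colnames(resp$judgments)) stop("rater not present: ", rater)
    j <- resp$judgments[, rater]
  } else {
    if (rater < 1 || rater > ncol(resp$judgments)) stop("rater not present")
    j <- resp$judgments[, rater]
  }
  lv <- c("real", "generated")
  cm <- table(factor(j, lv), factor(resp$truth, lv), dnn = c("judged", "truth"))
  acc <- sum(diag(cm)) / sum(cm)
  rec_real <- if (sum(cm[, "real"]) > 0) cm["real", "real"] / sum(cm[, "real"]) else NA_real_
  rec_gen <- if (sum(cm[, "generated"]) > 0)
    cm["generated", "generated"] / sum(cm[, "generated"]) else NA_real_
  list(matrix = cm, accuracy = acc, sensitivity = rec_real,
       recall_real = rec_real, recall_generated = rec_gen)
}

#' Fleiss' kappa for multiple raters
#'
#' Standard formulation: per-item agreement `P_i`, mean agreement
#' `P_bar`, chance agreement `P_e` from the marginal category
#' proportions, and `kappa = (P_bar - P_e) / (1 - P_e)`.
#'
#' @param ratings items x raters matrix (character or factor categories)
#' @return `list(kappa, P_bar, P_e, n_items, n_raters)`; `kappa` is
#'   `NA` with an explanation when all ratings fall in one category
#'   (`P_e = 1`, agreement is undefined)
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); r <- ncol(ratings)
  if (n < 2 || r < 2) stop("need >= 2 items and >= 2 raters")
  cats <- sort(unique(as.vector(ratings)))
  counts <- t(apply(ratings, 1, function(row)
    vapply(cats, function(ct) sum(row == ct), numeric(1))))
  if (length(cats) < 2) {
    return(list(kappa = NA_real_, P_bar = 1, P_e = 1, n_items = n, n_raters = r,
                reason = "all ratings in one category: chance agreement is 1, kappa undefined"))
  }
  P_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  P_bar <- mean(P_i)
  p_j <- colSums(counts) / (n * r)
  P_e <- sum(p_j^2)
  list(kappa = (P_bar - P_e) / (1 - P_e), P_bar = P_bar, P_e = P_e,
       n_items = n, n_raters = r)
}

#' Weighted Cohen's kappa between two raters
#'
#' Agreement weights `w_ij = 1 - (|i - j| / (k - 1))^q` with `q = 1`
#' (linear), `q = 2` (quadratic, the default for ordinal scales) or
#' identity weights (`"none"`).
#'
#' @param scores_a,scores_b equal-length ordinal vectors
#' @param weighting `"quadratic"`, `"linear"` or `"none"`
#' @return kappa value
#' @export
pairwise_kappa <- function(scores_a, scores_b,
                           weighting = c("quadratic", "linear", "none")) {
  weighting <- match.arg(weighting)
  if (length(scores_a) != length(scores_b) || length(scores_a) < 2)
    stop("score vectors must have equal length >= 2")
  cats <- sort(unique(c(scores_a, scores_b)))
  k <- length(cats)
  O <- table(factor(scores_a, cats), factor(scores_b, cats)) / length(scores_a)
  pa <- rowSums(O); pb <- colSums(O)
  E <- outer(pa, pb)
  W <- if (k == 1) matrix(1, 1, 1) else switch(weighting,
    none = diag(k),
    linear = 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1),
    quadratic = 1 - (outer(seq_len(k), seq_len(k), "-") / (k - 1))^2)
  po <- sum(W * O)
  pe <- sum(W * E)
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Wilcoxon signed-rank test with exact small-sample p-values
#'
#' Zero differences are dropped (Wilcoxon's convention); ties in
#' `|difference|` receive mid-ranks.  For n <= 12 the two-sided p-value
#' is exact, from full enumeration of the 2^n sign patterns over the
#' observed (possibly tied) ranks; above that a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y paired numeric vectors
#' @return `list(statistic, p_value, n, method)`; a sentinel with
#'   `NA` statistic when all differences are zero
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, n = 0L,
                method = "undefined: all differences zero"))
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  if (n <= 12) {
    sums <- 0
    for (r in rk) sums <- c(sums, sums + r)  # all 2^n subset sums
    p_le <- mean(sums <= W + 1e-9)
    p_ge <- mean(sums >= W - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = W, p_value = p, n = n, method = method)
}

#' Group comparison tests
#'
#' Standard tests on the package's significance convention (alpha =
#' 0.05): paired t, Mann-Whitney U, chi-square on contingency counts
#' (without continuity correction), or Kruskal-Wallis across two or more
#' groups.
#'
#' @param a first sample; for `"chi_square"` a contingency matrix; for
#'   `"kruskal_wallis"` optionally a list of groups
#' @param b second sample (ignored for a chi-square table or a group
#'   list)
#' @param method one of `"paired_t"`, `"mann_whitney"`, `"chi_square"`,
#'   `"kruskal_wallis"`
#' @return `list(statistic, p_value, method)`
#' @export
compare_groups <- function(a, b = NULL,
                           method = c("paired_t", "mann_whitney",
                                      "chi_square", "kruskal_wallis")) {
  method <- match.arg(method)
  res <- switch(method,
    paired_t = {
      ht <- stats::t.test(a, b, paired = TRUE)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    mann_whitney = {
      ht <- suppressWarnings(stats::wilcox.test(a, b))
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    chi_square = {
      tab <- if (is.matrix(a) || is.table(a)) a else table(a, b)
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    kruskal_wallis = {
      groups <- if (is.list(a)) a else list(a, b)
      ht <- stats::kruskal.test(groups)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    })
  c(res, list(method = method))
}

#' Summarize ordinal ratings by stratum and arm
#'
#' Per-stratum and overall mean +/- sample standard deviation for the
#' real and generated arms, with a paired Wilcoxon signed-rank test per
#' stratum on per-item mean scores (items paired by `item_id` across
#' arms).
#'
#' @param table rating data frame from [read_ratings_csv()]
#' @param strata optional subset of strata to summarize
#' @return `list(summary, tests)`: a summary data frame (stratum, arm,
#'   mean, sd, n) and per-stratum Wilcoxon results
#' @export
summarize_ratings <- function(table, strata = NULL) {
  rater_cols <- grep("^rater_", names(table), value = TRUE)
  table$item_mean <- rowMeans(table[rater_cols])
  if (is.null(strata)) strata <- sort(unique(table$stratum))
  rows <- list()
  tests <- list()
  for (st in c(strata, "overall")) {
    sub <- if (st == "overall") table else table[table$stratum == st, ]
    for (arm in c("real", "generated")) {
      sc <- as.vector(as.matrix(sub[sub$arm == arm, rater_cols]))
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, arm = arm, mean = mean(sc), sd = stats::sd(sc),
        n = length(sc))
    }
    r <- sub[sub$arm == "real", c("item_id", "item_mean")]
    g <- sub[sub$arm == "generated", c("item_id", "item_mean")]
    mg <- merge(r, g, by = "item_id", suffixes = c("_real", "_gen"))
    tests[[st]] <- wilcoxon_signed_rank(mg$item_mean_real, mg$item_mean_gen)
  }
  list(summary = do.call(rbind, rows), tests = tests)
}

#' Simulate visual Turing test responses
#'
#' Given a design (items with truth labels), simulates rater judgments
#' with a fixed per-item probability of a correct call; 0.5 models
#' readers at chance (indistinguishable sequences).
#'
#' @param design list from [read_turing_csv()] or a data frame with
#'   `truth`
#' @param n_raters number of raters
#' @param p_correct probability a rater judges an item correctly
#' @param seed integer seed
#' @return the design list with a `judgments` matrix attached
#' @export
simulate_turing_responses <- function(design, n_raters = 5L, p_correct = 0.5,
                                      seed = 1L) {
  truth <- if (is.data.frame(design)) design$truth else design$truth
  n <- length(truth)
  other <- ifelse(truth == "real", "generated", "real")
  jm <- with_seed(seed, {
    vapply(seq_len(n_raters), function(r)
      ifelse(runif(n) < p_correct, truth, other), character(n))
  })
  colnames(jm) <- paste0("rater_", seq_len(n_raters))
  if (is.data.frame(design))
    design <- list(item_id = design$item_id, strata = design$stratum,
                   truth = design$truth)
  design$judgments <- jm
  design
}
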