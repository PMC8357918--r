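make_spec <- function(power, band = c(0.5, 30), df = 1) {
  structure(list(freqs = seq_along(power) * df, power = power,
                 band = band, df = df, n_epochs = 1L, n_rois = 1L),
            class = "power_spectrum")
}

rand_conn <- function(seed, band = "alpha") {
  set.seed(seed)
  v <- matrix(runif(90 * 90, 0.3, 0.7), 90)
  v <- (v + t(v)) / 2
  diag(v) <- NA
  structure(list(values = v, band = band,
                 band_limits = as.numeric(band_limits(band)), n_epochs = 1L),
            class = "connectivity_matrix")
}

test_that("KS spectral distance equals hand-computed CDF maxima", {
  p <- make_spec(c(0.4, 0.3, 0.2, 0.1))
  q <- make_spec(c(0.1, 0.2, 0.3, 0.4))
  # CDFs (0.4,0.7,0.9,1.0) vs (0.1,0.3,0.6,1.0): max gap 0.4
  expect_equal(as.numeric(ks_spectral_distance(p, q)), 0.4)
  expect_equal(as.numeric(ks_spectral_distance(p, p)), 0)
  a <- make_spec(c(1, 0, 0, 0)); b <- make_spec(c(0, 0, 0, 1))
  expect_equal(as.numeric(ks_spectral_distance(a, b)), 1)
  expect_equal(ks_spectral_distance(p, q), ks_spectral_distance(q, p))
  expect_error(ks_spectral_distance(p, make_spec(rep(1, 5))), "mismatch")
  withp <- ks_spectral_distance(p, q, return_p = TRUE)
  expect_true(attr(withp, "p_approx") >= 0 && attr(withp, "p_approx") <= 1)
})

test_that("Spearman matrix consistency is a rank statistic on the upper
           triangle", {
  a <- rand_conn(1)
  expect_equal(spearman_matrix_consistency(a, a), 1)
  sq <- a
  sq$values <- a$values^2            # monotone transform on [0,1]
  expect_equal(spearman_matrix_consistency(a, sq), 1)
  rev <- a
  rev$values <- 1 - a$values
  expect_equal(spearman_matrix_consistency(a, rev), -1)
  const <- a; const$values[] <- 0.5; diag(const$values) <- NA
  expect_error(spearman_matrix_consistency(a, const), "constant")
  expect_error(spearman_matrix_consistency(a, rand_conn(2, "beta")), "band")
})

test_that("the consistency table has the study's within/between layout", {
  tps <- c("BL", "FU1", "FU2")
  mk_subject <- function(s) {
    specs <- lapply(setNames(tps, tps), function(tp)
      make_spec(runif(40) + s / 10))
    conns <- lapply(setNames(tps, tps), function(tp)
      list(alpha = rand_conn(s * 10 + match(tp, tps)),
           beta = rand_conn(s * 100 + match(tp, tps), "beta")))
    list(specs = specs, conns = conns)
  }
  set.seed(30)
  subs <- lapply(1:8, mk_subject)
  tab <- build_consistency_table(lapply(subs, `[[`, "specs"),
                                 lapply(subs, `[[`, "conns"), tps)
  for (m in c("ks_d", "spearman_alpha", "spearman_beta")) {
    expect_equal(sum(tab$kind == "within" & tab$metric == m), 24L)
    expect_equal(sum(tab$kind == "between" & tab$metric == m), 24L)
  }
  expect_setequal(unique(tab$key[tab$kind == "within"]),
                  c("BL-FU1", "FU1-FU2", "BL-FU2"))
  expect_true(all(tab$value[tab$metric == "ks_d"] >= 0 &
                    tab$value[tab$metric == "ks_d"] <= 1))
  # two subjects: the between value is exactly the single cross metric
  subs2 <- subs[1:2]
  tab2 <- build_consistency_table(lapply(subs2, `[[`, "specs"),
                                  lapply(subs2, `[[`, "conns"), tps)
  b12 <- tab2$value[tab2$kind == "between" & tab2$metric == "ks_d" &
                      tab2$subject == 1 & tab2$key == "BL"]
  expect_equal(b12, as.numeric(ks_spectral_distance(
    subs[[1]]$specs$BL, subs[[2]]$specs$BL)))
  # identical data everywhere -> all KS-D zero
  one_spec <- subs[[1]]$specs$BL
  one_conn <- subs[[1]]$conns$BL
  same <- lapply(1:3, function(i) list(
    specs = lapply(setNames(tps, tps), function(tp) one_spec),
    conns = lapply(setNames(tps, tps), function(tp) one_conn)))
  tab3 <- build_consistency_table(lapply(same, `[[`, "specs"),
                                  lapply(same, `[[`, "conns"), tps)
  tab3 <- tab3[tab3$metric == "ks_d", ]
  expect_true(all(tab3$value == 0))
  expect_error(build_consistency_table(list(subs[[1]]$specs[1:2]),
                                       list(subs[[1]]$conns[1:2]), tps),
               "missing session|subject")
})

test_that("repeated-measures ANOVA matches the hand decomposition and aov", {
  # toy table with zero error sum of squares -> F = Inf, p = 0
  toy <- rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  r <- rm_anova(toy)
  expect_identical(r$statistic, Inf)
  expect_identical(r$p, 0)
  expect_equal(r$effect_size, 1)
  # all equal -> F = 0
  r0 <- rm_anova(matrix(1, 4, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$effect_size, 0)
  # dfs for 8 subjects x 3 conditions
  set.seed(40)
  v <- matrix(rnorm(24), 8, 3)
  r8 <- rm_anova(v)
  expect_equal(r8$df, c(2L, 14L))
  # oracle: stats::aov with an Error stratum
  d <- data.frame(y = as.vector(v),
                  subj = factor(rep(1:8, 3)),
                  cond = factor(rep(1:3, each = 8)))
  fit <- summary(stats::aov(y ~ cond + Error(subj / cond), data = d))
  tabl <- fit[["Error: subj:cond"]][[1]]
  expect_equal(r8$statistic, tabl["cond", "F value"], tolerance = 1e-10)
  expect_equal(r8$p, tabl["cond", "Pr(>F)"], tolerance = 1e-10)
  expect_error(rm_anova(matrix(1, 1, 3)), "at least 2")
})

test_that("within-vs-between unpaired t-test has the pooled df and obvious
           separations reach significance", {
  set.seed(41)
  tab <- data.frame(
    kind = rep(c("within", "between"), each = 24),
    metric = "ks_d",
    value = c(rnorm(24, 0.9, 0.01), rnorm(24, 0.1, 0.01)))
  r <- compare_within_between(tab, "ks_d")
  expect_equal(r$df, 46)
  expect_lt(r$p, 0.001)
  expect_gt(r$statistic, 0)
  tab_same <- tab
  tab_same$value <- rep(c(0.5, 0.6), 24)[order(rep(1:24, 2))]
  tab_same$value[tab_same$kind == "within"] <- rep(c(0.5, 0.6), 12)
  tab_same$value[tab_same$kind == "between"] <- rep(c(0.5, 0.6), 12)
  r2 <- compare_within_between(tab_same, "ks_d")
  expect_equal(r2$statistic, 0, tolerance = 1e-12)
  expect_equal(r2$p, 1, tolerance = 1e-12)
  # oracle: stats::t.test pooled
  tt <- t.test(tab$value[tab$kind == "within"],
               tab$value[tab$kind == "between"], var.equal = TRUE)
  expect_equal(r$statistic, unname(tt$statistic))
})

test_that("paired t-test dfs and degenerate cases", {
  set.seed(42)
  a <- rnorm(8); b <- rnorm(8)
  r <- paired_t(a, b)
  expect_equal(r$df, 7)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(r$statistic, unname(tt$statistic))
  expect_equal(r$p, tt$p.value)
  r0 <- paired_t(a, a)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  rinf <- paired_t(a + 1, a)
  expect_identical(rinf$statistic, Inf)
  expect_identical(rinf$p, 0)
  expect_match(rinf$note, "degenerate")
})

test_that("ROI-wise consistency maps localize a disrupted region", {
  a <- rand_conn(50)
  expect_equal(roiwise_consistency_map(a, a), rep(1, 90))
  b <- a
  set.seed(51)
  perm <- sample(setdiff(1:90, 7))
  b$values[7, -7] <- a$values[7, perm]
  b$values[-7, 7] <- b$values[7, -7]
  m <- roiwise_consistency_map(a, b)
  expect_length(m, 90)
  expect_lt(abs(m[7]), 0.3)
  expect_true(all(m[-7] > 0.9))
})
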