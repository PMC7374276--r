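test_that("baseline subtraction anchors series at zero", {
  expect_equal(baseline_subtract(c(5, 7, 9)), c(0, 2, 4))
  expect_equal(baseline_subtract(rep(3.3, 5)), rep(0, 5))
  set.seed(61)
  x <- rnorm(8)
  expect_equal(baseline_subtract(x)[1], 0)
  ## telescoping: endpoint difference survives baseline subtraction
  bs <- baseline_subtract(x)
  expect_equal(bs[8] - bs[1], x[8] - x[1])
  expect_error(baseline_subtract(numeric(0)), "empty")
})

test_that("mann_whitney_u matches enumeration for separated samples", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$u, 0)
  expect_equal(r$p, 2 / 6)
  expect_equal(r$method, "exact")
  r2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$u, 0)
  expect_equal(r2$p, p_by_enumeration(c(1, 2, 3), c(4, 5, 6)))
  ## identical samples: U = n^2/2 by symmetry
  x <- c(2.5, 7, 11, 13)
  expect_equal(mann_whitney_u(x, x)$u, length(x)^2 / 2)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("exact p equals exhaustive enumeration across sizes and ties", {
  set.seed(62)
  for (na in 2:5) {
    for (nb in 2:(10 - na)) {
      ## continuous data and tied data
      a <- rnorm(na); b <- rnorm(nb)
      r <- mann_whitney_u(a, b)
      expect_equal(r$u, u_by_pairs(a, b))
      expect_equal(r$p, p_by_enumeration(a, b))
      at <- sample(1:3, na, TRUE); bt <- sample(1:3, nb, TRUE)
      rt <- mann_whitney_u(at, bt)
      expect_equal(rt$u, u_by_pairs(at, bt))
      expect_equal(rt$p, p_by_enumeration(at, bt))
    }
  }
})

test_that("exact p agrees with the reference implementation without ties", {
  set.seed(63)
  for (rep in 1:5) {
    a <- rnorm(5); b <- rnorm(5)
    r <- mann_whitney_u(a, b)
    w <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(r$u, min(w$statistic, 25 - w$statistic),
                 ignore_attr = TRUE)
    expect_equal(r$p, w$p.value, tolerance = 1e-12)
  }
})

test_that("large samples switch to the tie- and continuity-corrected normal", {
  set.seed(64)
  a <- rnorm(12); b <- rnorm(12) + 0.8
  r <- mann_whitney_u(a, b)
  expect_equal(r$method, "normal")
  w <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(r$p, w$p.value, tolerance = 1e-10)
  expect_true(r$u >= 0 && r$u <= 144)
})

test_that("U and its complement sum to na*nb", {
  set.seed(65)
  for (rep in 1:20) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- sample(1:6, na, TRUE); b <- sample(1:6, nb, TRUE)
    r <- rank(c(a, b))
    ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    ub <- sum(r[-seq_len(na)]) - nb * (nb + 1) / 2
    expect_equal(ua + ub, na * nb)
    expect_equal(mann_whitney_u(a, b)$u, min(ua, ub))
  }
})

test_that("bonferroni multiplies by m and caps at one", {
  expect_equal(bonferroni(0.02, m = 6), 0.12)
  expect_equal(bonferroni(0.4, m = 6), 1)
  expect_equal(bonferroni(c(0.01, 0.03)), c(0.02, 0.06))
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
  expect_equal(ncol(utils::combn(4, 2)), 6L)  # 4 groups -> 6 pairs
})

## synthetic 4-group endpoint records: N fields, first/last time points
make_group_records <- function(groups, n_fields, shift, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(groups), function(gi) {
    d <- shift[gi]
    do.call(rbind, lapply(seq_len(n_fields), function(f) {
      start <- runif(1, 8, 12)
      data.frame(group = groups[gi], field_of_view = f,
                 time_index = c(0L, 96L),
                 red_pct = c(start, start + d + rnorm(1, 0, 2)))
    }))
  }))
}

test_that("endpoint_comparison emits one corrected test per group pair", {
  recs <- make_group_records(c("Tu", "TagRFP+", "DMSO", "Int"), 10,
                             shift = c(25, 40, 1, 0), seed = 70)
  out <- endpoint_comparison(recs)
  expect_equal(nrow(out), 6L)
  expect_equal(out$p_corrected, pmin(1, 6 * out$p_value))
  expect_true(all(out$u_statistic >= 0 & out$u_statistic <= 100))
  ## copied groups carry no signal after correction
  same <- make_group_records(c("A", "B"), 10, shift = c(0, 0), seed = 71)
  same$red_pct[same$group == "B"] <- same$red_pct[same$group == "A"]
  out2 <- endpoint_comparison(same)
  expect_equal(out2$p_corrected, 1)
})

test_that("a planted +20-point shift reaches corrected significance at N=10", {
  recs <- make_group_records(c("treated", "control"), 10,
                             shift = c(20, 0), seed = 72)
  extra <- make_group_records(c("posctl", "intact"), 10,
                              shift = c(35, 0.5), seed = 73)
  out <- endpoint_comparison(rbind(recs, extra))
  expect_equal(nrow(out), 6L)
  row <- out[(out$group_a == "control" & out$group_b == "treated") |
             (out$group_a == "treated" & out$group_b == "control"), ]
  expect_lt(row$p_corrected, 0.05)
})

test_that("endpoint_comparison validates completeness of fields", {
  recs <- make_group_records(c("A", "B"), 4, shift = c(0, 5), seed = 74)
  recs <- recs[-1, ]  # drop one starting point
  expect_error(endpoint_comparison(recs), "missing")
})

test_that("timepoint records join counts with the sample sheet", {
  counts <- data.frame(path = c("a.tif", "b.tif"),
                       cell_count = c(200, 400), red_count = c(50, 100),
                       threshold = 30L)
  sheet <- data.frame(path = c("a.tif", "b.tif"), group = "Tu", dose = 10,
                      field_of_view = 1:2, time_index = 0L)
  recs <- make_timepoint_records(counts, sheet)
  expect_equal(recs$red_pct, c(25, 25))
  expect_error(make_timepoint_records(counts, sheet[, -2]), "sample sheet")
})
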