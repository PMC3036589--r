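test_that("bioclim variables match closed forms on constant climate", {
  g <- constant_grid(tavg = 20, half_range = 5, prcp = 100)  # tmax - tmin = 10
  b <- derive_bioclim(g, cells = cbind(2, 2))
  expect_equal(b$bio1, 20)
  expect_equal(b$bio2, 10)
  expect_equal(b$bio3, 100)   # diurnal range equals annual range
  expect_equal(b$bio4, 0)
  expect_equal(b$bio5, 25)
  expect_equal(b$bio6, 15)
  expect_equal(b$bio7, 10)
  expect_equal(b$bio12, 1200)
  expect_equal(b$bio13, 100)
  expect_equal(b$bio14, 100)
  expect_equal(b$bio15, 0)
  expect_equal(b$bio8, 20); expect_equal(b$bio11, 20)
  expect_equal(b$bio16, 300); expect_equal(b$bio19, 300)
})

test_that("quarter selection equals the exhaustive 12-window oracle", {
  g <- test_world()
  all_cells <- which(g$land, arr.ind = TRUE)
  cells <- all_cells[seq(1, nrow(all_cells), by = 37), , drop = FALSE]
  b <- derive_bioclim(g, cells)
  for (i in seq_len(nrow(cells))) {
    r <- cells[i, 1]; c <- cells[i, 2]
    t <- g$tavg[r, c, ]; p <- g$prcp[r, c, ]
    wins <- lapply(1:12, function(s) ((s - 1 + 0:2) %% 12) + 1)
    qp <- vapply(wins, function(w) sum(p[w]), numeric(1))
    qt <- vapply(wins, function(w) mean(t[w]), numeric(1))
    expect_equal(b$bio10[i], qt[which.max(qt)])
    expect_equal(b$bio11[i], qt[which.min(qt)])
    expect_equal(b$bio16[i], qp[which.max(qp)])
    expect_equal(b$bio17[i], qp[which.min(qp)])
    expect_equal(b$bio8[i], qt[which.max(qp)])
    expect_equal(b$bio9[i], qt[which.min(qp)])
  }
  # single warm month dominates its three covering windows
  t1 <- rep(10, 12); t1[6] <- 30
  g1 <- grid_from_cells(list(t1), list(rep(100, 12)), 1, 1)
  b1 <- derive_bioclim(g1, cbind(1, 1))
  expect_equal(b1$bio10, mean(c(10, 10, 30)))  # earliest window containing June
})

test_that("bioclim identities hold on a generated world", {
  g <- test_world()
  b <- derive_bioclim(g)
  expect_true(all(b$bio5 >= b$bio6))
  expect_equal(b$bio7, b$bio5 - b$bio6)
  expect_true(all(b$bio13 >= b$bio14))
  expect_true(all(b$bio3 > 0 & b$bio3 <= 100))
  expect_equal(b$bio3, b$bio2 / b$bio7 * 100)
  # bio12 equals the monthly sum
  cells <- cbind(b$row, b$col)
  psum <- rowSums(vapply(1:12, function(m) g$prcp[, , m][cells],
                         numeric(nrow(cells))))
  expect_equal(b$bio12, psum)
})

test_that("degenerate annual range flags isothermality as undefined", {
  g <- constant_grid(tavg = 20, half_range = 0, prcp = 100)  # bio7 = 0
  b <- derive_bioclim(g, cbind(1, 1))
  expect_equal(b$bio7, 0)
  expect_true(is.na(b$bio3))
})

test_that("background sampling is seeded, uniform and bounded by the mask", {
  g <- test_world()
  s1 <- sample_background(g$land, n = 100, seed = 3)
  s2 <- sample_background(g$land, n = 100, seed = 3)
  expect_identical(s1, s2)
  expect_true(all(g$land[cbind(s1$row, s1$col)]))
  expect_equal(nrow(sample_background(g$land, n = 0, seed = 1)), 0)
  expect_error(sample_background(matrix(FALSE, 2, 2)), "empty")
  small <- matrix(FALSE, 4, 4); small[1, 1:3] <- TRUE
  expect_warning(all3 <- sample_background(small, n = 10, seed = 1), "only")
  expect_equal(nrow(all3), 3)

  # with-replacement frequencies over a tiny mask match the multinomial
  # expectation (chi-square GOF against uniform)
  tiny <- matrix(FALSE, 3, 3); tiny[1:2, 1:2] <- TRUE
  draws <- purrr::map_dfr(1:1500, function(i) {
    sample_background(tiny, n = 1, seed = 1000 + i)
  })
  counts <- table(paste(draws$row, draws$col))
  expect_equal(length(counts), 4)
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("the collinearity audit counts 171 pairs and honest histograms", {
  g <- test_world()
  b <- derive_bioclim(g, sample_background(g$land, 400, seed = 8))
  cs <- collinearity_summary(b)
  expect_equal(cs$pair_count, 171)
  expect_true(isSymmetric(unname(cs$r)))
  expect_true(all(diag(cs$r) == 1))
  expect_equal(sum(cs$histogram$count), cs$effective_pair_count)

  # two identical columns correlate at exactly 1
  b2 <- b
  b2$bio2 <- b2$bio1
  cs2 <- collinearity_summary(b2)
  expect_equal(cs2$r["bio1", "bio2"], 1)

  # independent Gaussian columns at n = 5000: no r above 0.5
  set.seed(99)
  fake <- tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(rnorm(5000 * 19), 5000, 19)), bioclim_cols <- paste0("bio", 1:19)))
  cs3 <- collinearity_summary(fake)
  expect_equal(cs3$counts$n_signed[cs3$counts$threshold == 0.5], 0)
  expect_equal(cs3$counts$n_absolute[cs3$counts$threshold == 0.5], 0)

  # zero-variance column: dropped, raw and effective pair counts reported
  b3 <- b
  b3$bio19 <- 5
  cs4 <- collinearity_summary(b3)
  expect_equal(cs4$pair_count, 171)
  expect_equal(cs4$effective_pair_count, 171 - 18)
  expect_equal(cs4$dropped, "bio19")
})
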