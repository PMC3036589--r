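test_that("locality monthly points apply the log10 floor rule", {
  g <- constant_grid(tavg = 25, prcp = 100)
  loc <- localities_at(g, 2, 2)
  pts <- locality_monthly_points(loc, g)
  expect_equal(nrow(pts), 12)
  expect_true(all(pts$t == 25))
  expect_true(all(pts$p_log == 2))

  # zero rainfall month floored at 0.1 mm -> p_log = -1
  tavg <- lapply(1, function(i) rep(25, 12))
  prcp <- lapply(1, function(i) c(0, rep(100, 11)))
  g0 <- grid_from_cells(tavg, prcp, 1, 1)
  pts0 <- locality_monthly_points(localities_at(g0, 1, 1), g0)
  expect_equal(pts0$p_log[1], -1)
  expect_equal(pts0$p_log[2], 2)

  # hand-computed spreadsheet check on an arbitrary cell of the test world
  g2 <- test_world()
  cell <- which(g2$land, arr.ind = TRUE)[10, ]
  loc2 <- localities_at(g2, cell[1], cell[2])
  pts2 <- locality_monthly_points(loc2, g2)
  expect_equal(pts2$t, g2$tavg[cell[1], cell[2], ])
  expect_equal(pts2$p_log, log10(pmax(g2$prcp[cell[1], cell[2], ], 0.1)))

  # sea cell errors with the locality id
  sea <- which(!g2$land, arr.ind = TRUE)[1, ]
  locsea <- localities_at(g2, sea[1], sea[2])
  expect_error(locality_monthly_points(locsea, g2), locsea$id[1])
})

test_that("active months drop the coldest h-block and hottest a-block with earliest-start ties", {
  # brute-force oracle over all circular windows
  oracle <- function(t, h, a) {
    wins <- function(k) lapply(1:12, function(s) ((s - 1 + 0:(k - 1)) %% 12) + 1)
    keep <- 1:12
    if (h > 0) {
      ws <- wins(h)
      means <- vapply(ws, function(w) mean(t[w]), numeric(1))
      keep <- setdiff(keep, ws[[which.min(round(means, 10))]])
    }
    if (a > 0) {
      ws <- Filter(function(w) all(w %in% keep), wins(a))
      means <- vapply(ws, function(w) mean(t[w]), numeric(1))
      keep <- setdiff(keep, ws[[which.max(round(means, 10))]])
    }
    sort(keep)
  }

  expect_equal(active_months(rnorm(12), 0, 0), 1:12)

  t_sin <- 15 + 10 * cos(2 * pi * ((1:12) - 7) / 12)  # peaks in July
  expect_equal(active_months(t_sin, 3, 0), sort(setdiff(1:12, c(12, 1, 2))))
  # h = 4 ties between Nov-Feb and Dec-Mar; earliest start (Nov) wins
  expect_equal(active_months(t_sin, 4, 0), sort(setdiff(1:12, c(11, 12, 1, 2))))

  set.seed(7)
  for (i in 1:50) {
    t <- rnorm(12, 15, 8)
    h <- sample(0:5, 1); a <- sample(0:(11 - h) %/% 2, 1)
    expect_equal(active_months(t, h, a), oracle(t, h, a))
  }
  # aestivation removed from the remaining arc, possibly abutting hibernation
  expect_equal(length(active_months(t_sin, 5, 5)), 2)
})

test_that("envelopes equal the brute-force hull and ignore interior localities", {
  g <- test_world()
  sp <- default_species(g, h_true = 3)
  loc <- sample_localities(sp, g, n = 50, error_rate = 0, seed = 3)
  env <- build_envelope(loc, g, h = 3)
  pts <- locality_monthly_points(loc, g)
  active <- do.call(rbind, lapply(split(pts, pts$id), function(d) {
    d <- d[order(d$month), ]
    act <- active_months(d$t, 3, 0)
    cbind(d$t[act], d$p_log[act])
  }))
  expect_equal(canon_poly(env$hull), canon_poly(giftwrap_hull(active)))

  # triangle from three constant-climate cells
  tavg <- list(rep(0, 12), rep(10, 12), rep(0, 12))
  prcp <- list(rep(0.1, 12), rep(0.1, 12), rep(1, 12))
  g3 <- grid_from_cells(tavg, prcp, 1, 3)
  env3 <- build_envelope(localities_at(g3, c(1, 1, 1), 1:3), g3)
  expect_equal(nrow(env3$hull), 3)

  # adding a locality whose points are strictly inside leaves the hull
  # bit-identical (divergent climates enlarge, redundant ones never shift it)
  # deterministic world: three climatically extreme cells span a triangle,
  # a fourth sits strictly inside it in climate space
  gi <- grid_from_cells(
    list(rep(5, 12), rep(30, 12), rep(30, 12), rep(22, 12)),
    list(rep(10, 12), rep(1000, 12), rep(10, 12), rep(50, 12)),
    1, 4
  )
  env3 <- build_envelope(localities_at(gi, rep(1, 3), 1:3), gi)
  env4 <- build_envelope(localities_at(gi, rep(1, 4), 1:4), gi)
  expect_identical(canon_poly(env3$hull), canon_poly(env4$hull))
  expect_equal(envelope_area(env3), envelope_area(env4))

  # duplicated localities cannot change the envelope (no weighting)
  loc_dup <- dplyr::bind_rows(loc, loc, loc)
  loc_dup$id <- sprintf("D%03d", seq_len(nrow(loc_dup)))
  env_dup <- build_envelope(loc_dup, g, h = 3)
  expect_identical(env$hull, env_dup$hull)

  # collinear climates -> degenerate envelope error
  gd <- grid_from_cells(list(rep(0, 12), rep(5, 12), rep(10, 12)),
                        list(rep(100, 12), rep(100, 12), rep(100, 12)), 1, 3)
  expect_error(build_envelope(localities_at(gd, c(1, 1, 1), 1:3), gd),
               "degenerate")
})

test_that("random hulls match the gift-wrapping oracle", {
  set.seed(21)
  for (i in 1:5) {
    pts <- cbind(rnorm(200, 0, 5), rnorm(200, 0, 1))
    expect_equal(canon_poly(convex_hull(pts)), canon_poly(giftwrap_hull(pts)))
  }
})

test_that("envelope area counts standard cells, matching closed forms and Monte Carlo", {
  # axis-aligned rectangle t in [0,10], p_log in [0,1]: 10 x 10 cells of
  # 1 degree x 0.1 log-units -> exactly 100 centres inside
  rect <- structure(list(hull = cbind(t = c(0, 10, 10, 0),
                                      p_log = c(0, 0, 1, 1)),
                         h = 0, a = 0), class = "climate_envelope")
  expect_equal(envelope_area(rect), 100)

  # tiny hull containing one cell centre -> 1
  tiny <- structure(list(hull = cbind(t = c(0.45, 0.55, 0.5),
                                      p_log = c(0.04, 0.04, 0.06)),
                         h = 0, a = 0), class = "climate_envelope")
  expect_equal(envelope_area(tiny), 1)

  # random hull vs dense Monte-Carlo area estimate (area in cell units)
  set.seed(33)
  pts <- cbind(rnorm(40, 10, 6), rnorm(40, 1.5, 0.6))
  hull <- convex_hull(pts)
  env <- structure(list(hull = hull, h = 0, a = 0), class = "climate_envelope")
  n_mc <- 1e6
  xr <- range(hull[, 1]); yr <- range(hull[, 2])
  mc <- cbind(runif(n_mc, xr[1], xr[2]), runif(n_mc, yr[1], yr[2]))
  frac <- mean(points_in_hull(mc, hull))
  mc_cells <- frac * diff(xr) * diff(yr) / (1 * 0.1)
  expect_lt(abs(envelope_area(env) - mc_cells) / mc_cells, 0.02)
})

test_that("containment implements the interaction rule with inclusive boundary", {
  # occupied: warm-wet and cool-dry sites; the cool-wet combination
  # (10 C, 1000 mm/mo) lies outside the polygon even though 10 C and
  # 1000 mm/mo each occur among occupied sites
  tavg <- list(rep(10, 12), rep(30, 12), rep(30, 12))
  prcp <- list(rep(10, 12), rep(1000, 12), rep(10, 12))
  g <- grid_from_cells(tavg, prcp, 1, 3)
  env <- build_envelope(localities_at(g, c(1, 1, 1), 1:3), g)
  expect_false(env_contains(env, 10, 3))      # 10 C x 1000 mm/mo
  expect_true(env_contains(env, 10, 1))       # occupied corner
  expect_true(env_contains(env, 30, 3))
  # hull vertices and centroid are inside
  expect_true(all(env_contains(env, env$hull[, 1], env$hull[, 2])))
  cen <- colMeans(env$hull)
  expect_true(env_contains(env, cen[1], cen[2]))
})

test_that("projection is monotone in localities and in tolerance months", {
  g <- test_world()
  sp <- default_species(g, h_true = 3)
  loc <- sample_localities(sp, g, n = 60, error_rate = 0, seed = 17)
  env <- build_envelope(loc, g, h = 3)

  # suitable set non-decreasing in h and a
  maps <- lapply(0:4, function(h) project_envelope(env, g, h = h, a = 0)$values)
  for (i in 1:4) {
    expect_true(all(maps[[i + 1]][maps[[i]] == 1] == 1, na.rm = TRUE))
  }
  m_a0 <- project_envelope(env, g, h = 3, a = 0)$values
  m_a2 <- project_envelope(env, g, h = 3, a = 2)$values
  expect_true(all(m_a2[m_a0 == 1] == 1, na.rm = TRUE))

  # adding localities never shrinks hull area
  area_sub <- envelope_area(build_envelope(loc[1:20, ], g, h = 3))
  expect_gte(envelope_area(env), area_sub)

  # training cells under the generating hypothesis are all suitable
  cells <- cell_from_lonlat(g, loc$lon, loc$lat)
  proj <- project_envelope(env, g)$values
  expect_true(all(proj[cbind(cells$row, cells$col)] == 1))
})
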