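# GR metrics, toxicity tiers, flux normalization and hit calling.

test_that("GR closed-form identities hold", {
  rec <- function(x, x0 = 100, x_ctrl = 400) {
    tibble::tibble(cell_line = "L", compound_id = "c",
                   x0 = x0, x = x, x_ctrl = x_ctrl)
  }
  expect_equal(compute_gr(rec(400))$gr, 1)   # x = x_ctrl
  expect_equal(compute_gr(rec(100))$gr, 0)   # x = x0
  expect_equal(compute_gr(rec(200))$gr, 2^(1 / 2) - 1)
  expect_lt(compute_gr(rec(50))$gr, 0)       # net cell loss
  # scale invariance and monotonicity in x
  set.seed(2)
  for (rep in 1:20) {
    x0 <- runif(1, 50, 500)
    xc <- x0 * runif(1, 1.5, 8)
    x1 <- runif(1, 10, xc)
    lam <- runif(1, 0.1, 10)
    g1 <- compute_gr(rec(x1, x0, xc))$gr
    expect_equal(compute_gr(rec(lam * x1, lam * x0, lam * xc))$gr, g1)
    x2 <- x1 * 1.1
    expect_gt(compute_gr(rec(x2, x0, xc))$gr, g1)
  }
  # a non-growing control line is a hard error naming the line
  expect_error(
    compute_gr(tibble::tibble(cell_line = "SW1783", compound_id = "c",
                              x0 = 100, x = 120, x_ctrl = 100)),
    "SW1783"
  )
})

test_that("growth response classes follow the three-category rule", {
  gr_tbl <- function(gr) {
    tibble::tibble(compound_id = "c", cell_line = paste0("L", seq_along(gr)),
                   gr = gr)
  }
  classify <- function(gr) classify_growth_response(gr_tbl(gr))$response
  expect_equal(classify(rep(1, 10)), "inactive")
  expect_equal(classify(rep(0.95, 10)), "inactive")
  expect_equal(classify(rep(0.5, 10)), "broad")
  expect_equal(classify(c(0.2, rep(1, 9))), "line_dependent")
  # between the bands: no line at -30% but not all vehicle-like -> inactive
  expect_equal(classify(rep(0.8, 10)), "inactive")
  # 75% of lines affected is broad, below that line-dependent
  expect_equal(classify(c(rep(0.5, 6), rep(1, 2))), "broad")
  expect_equal(classify(c(rep(0.5, 5), rep(1, 3))), "line_dependent")
  expect_error(classify_growth_response(gr_tbl(numeric())), "empty")
  expect_error(classify_growth_response(gr_tbl(1)), "two cell lines")
})

test_that("toxicity tiers partition the healthy-fraction axis", {
  tiers <- function(x) {
    as.character(classify_toxicity(tibble::tibble(healthy_fraction = x))$tier)
  }
  expect_equal(tiers(c(0.85, 0.8, 0.79, 0.5, 0.49, 1 / 3, 0.30, 0)),
               c("nontoxic", "nontoxic", "reduced", "reduced", "severe",
                 "severe", "extreme", "extreme"))
  # every value maps to exactly one tier
  set.seed(4)
  x <- c(runif(200, 0, 1.5), 0.8, 0.5, 1 / 3)
  expect_false(any(is.na(tiers(x))))
  expect_error(classify_toxicity(tibble::tibble(healthy_fraction = -0.1)),
               ">= 0")
})

test_that("per-kinase toxicity aggregation enforces the chemotype rule", {
  kinase_map <- tibble::tibble(
    compound_id = c("a", "b", "c"),
    kinase = c("K1", "K1", "K2"),
    bin = c("X", "Y", "X")        # K1: 2 chemotypes, K2: 1
  )
  tox <- tibble::tibble(compound_id = c("a", "b", "c"),
                        healthy_fraction = c(0.2, 0.4, 0.9))
  vehicle <- c(0.98, 1.01, 0.99, 1.02, 1.0)
  expect_warning(
    agg <- kinase_toxicity_aggregate(kinase_map, tox, vehicle),
    "K2"
  )
  expect_equal(agg$kinase, "K1")
  expect_equal(agg$mean_healthy, 0.3)
  expect_true(agg$flagged)
  expect_error(
    kinase_toxicity_aggregate(kinase_map, tox[1:2, ], vehicle),
    "no toxicity record"
  )
})

test_that("planted toxic kinases are flagged against vehicle noise", {
  set.seed(31)
  # toxic kinase: 3 inhibitors with low healthy fractions; null kinases
  # with vehicle-like inhibitors
  kinase_map <- tibble::tibble(
    compound_id = c("t1", "t2", "t3", "n1", "n2", "n3"),
    kinase = rep(c("TOXK", "NULLK"), each = 3),
    bin = c("X", "Y", "Z", "X", "Y", "Z")
  )
  tox <- tibble::tibble(
    compound_id = c("t1", "t2", "t3", "n1", "n2", "n3"),
    healthy_fraction = c(0.35 + rnorm(3, 0, 0.05), 1 + rnorm(3, 0, 0.05))
  )
  vehicle <- 1 + rnorm(6, 0, 0.05)
  agg <- kinase_toxicity_aggregate(kinase_map, tox, vehicle)
  expect_true(agg$flagged[agg$kinase == "TOXK"])
  expect_false(agg$flagged[agg$kinase == "NULLK"])
})

test_that("flux normalization maps vehicle to 0%, control to 100%", {
  times <- seq(0, 10, by = 2)
  veh <- 1 - 0.01 * times
  ctl <- 0.6 - 0.02 * times
  base <- dplyr::bind_rows(
    tibble::tibble(compound_id = "DMSO", time_h = times,
                   gfp_rfp_ratio = veh, role = "vehicle"),
    tibble::tibble(compound_id = "TORIN1", time_h = times,
                   gfp_rfp_ratio = ctl, role = "positive_control")
  )
  as_cmp <- function(id, ratio) {
    tibble::tibble(compound_id = id, time_h = times, gfp_rfp_ratio = ratio,
                   role = "compound")
  }
  pct <- autophagy_normalize(dplyr::bind_rows(
    base, as_cmp("likeveh", veh), as_cmp("likectl", ctl),
    as_cmp("mid", (veh + ctl) / 2)
  ))
  expect_equal(pct$pct_flux[pct$compound_id == "likeveh"], rep(0, 6))
  expect_equal(pct$pct_flux[pct$compound_id == "likectl"], rep(100, 6))
  expect_equal(pct$pct_flux[pct$compound_id == "mid"], rep(50, 6))
  # degenerate span is an error naming the time point
  degen <- dplyr::bind_rows(
    tibble::tibble(compound_id = "DMSO", time_h = times, gfp_rfp_ratio = 1,
                   role = "vehicle"),
    tibble::tibble(compound_id = "TORIN1", time_h = times,
                   gfp_rfp_ratio = c(1, ctl[-1]), role = "positive_control"),
    as_cmp("x", veh)
  )
  expect_error(autophagy_normalize(degen), "t = 0")
})

test_that("hit calling follows the strict 5-consecutive-point rule", {
  mk <- function(pct) {
    tibble::tibble(compound_id = "c", time_h = seq_along(pct), pct_flux = pct)
  }
  # 25% for 5 consecutive points is a hit
  h <- autophagy_hit_call(mk(c(0, 0, rep(25, 5), 0, 0, 0)))
  expect_true(h$is_hit)
  expect_equal(h$direction, "induced")
  expect_equal(h$run_start, 3L)
  expect_equal(h$run_length, 5L)
  # 4 points is not
  expect_false(autophagy_hit_call(mk(c(0, rep(25, 4), rep(0, 5))))$is_hit)
  # exactly 20% is not above threshold (strict)
  expect_false(autophagy_hit_call(mk(rep(20, 10)))$is_hit)
  # negative aberration counts, direction reduced
  h2 <- autophagy_hit_call(mk(rep(-30, 6)))
  expect_true(h2$is_hit)
  expect_equal(h2$direction, "reduced")
  expect_error(autophagy_hit_call(mk(rep(25, 4))), "fewer than")
})

test_that("hit calling equals the window-scan oracle on random series", {
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(8:30, 1)
    pct <- round(rnorm(n, 0, 18), 1)
    thr <- sample(c(10, 20, 30), 1)
    run <- sample(3:6, 1)
    got <- autophagy_hit_call(
      tibble::tibble(compound_id = "r", time_h = 1:n, pct_flux = pct),
      threshold = thr, min_run = run
    )
    want <- oracle_hit_scan(pct, thr, run)
    expect_equal(got$is_hit, want$is_hit)
    if (want$is_hit) {
      expect_equal(got$direction, want$direction)
      expect_equal(got$run_start, want$run_start)
      expect_equal(got$run_length, want$run_length)
    }
  }
})

test_that("hit calling is monotone in threshold and run length", {
  set.seed(19)
  for (rep in 1:30) {
    pct <- round(rnorm(15, 0, 25), 1)
    mk <- tibble::tibble(compound_id = "r", time_h = 1:15, pct_flux = pct)
    h_lo <- autophagy_hit_call(mk, threshold = 15, min_run = 4)$is_hit
    h_hi <- autophagy_hit_call(mk, threshold = 25, min_run = 4)$is_hit
    h_long <- autophagy_hit_call(mk, threshold = 15, min_run = 6)$is_hit
    if (h_hi) expect_true(h_lo)     # raising threshold never creates a hit
    if (h_long) expect_true(h_lo)   # nor does raising min_run
  }
})

test_that("autophagy categories cover the 6-cell grid exactly once", {
  grid <- expand.grid(
    direction = c("induced", "reduced"),
    proliferation = c("reduced", "unchanged"),
    appearance = c("normal", "abnormal"),
    stringsAsFactors = FALSE
  )
  hits <- tibble::tibble(
    compound_id = paste0("h", seq_len(nrow(grid))),
    is_hit = TRUE, direction = grid$direction
  )
  out <- autophagy_categorize(hits, grid$proliferation, grid$appearance)
  expect_true(all(out$category %in% 1:6))
  expect_setequal(unique(out$category), 1:6)
  # spec-style anchors
  one <- autophagy_categorize(
    tibble::tibble(compound_id = "a", is_hit = TRUE, direction = "induced"),
    "unchanged", "normal"
  )
  expect_equal(one$category, 1L)
  six <- autophagy_categorize(
    tibble::tibble(compound_id = "b", is_hit = TRUE, direction = "reduced"),
    "reduced", "normal"
  )
  expect_false(six$category == one$category)
  expect_error(
    autophagy_categorize(
      tibble::tibble(compound_id = "c", is_hit = FALSE,
                     direction = NA_character_),
      "unchanged", "normal"
    ),
    "non-hit"
  )
})
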