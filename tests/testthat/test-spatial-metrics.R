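test_that("nearest-neighbor distances handle the elementary cases", {
  expect_equal(as.numeric(nearest_neighbor_distances(cbind(0, 0), cbind(3, 4))),
               5)
  # no CD8 cells: assign-cap gives every tumor cell the cap
  d <- nearest_neighbor_distances(rbind(c(0, 0), c(10, 0)),
                                  matrix(numeric(0), 0, 2), cap = 1000)
  expect_equal(as.numeric(d), c(1000, 1000))
  expect_equal(attr(d, "n_capped"), 2L)
  # drop-core policy excludes the core instead
  expect_null(nearest_neighbor_distances(rbind(c(0, 0)),
                                         matrix(numeric(0), 0, 2),
                                         no_cd8_policy = "drop-core"))
  # empty tumor set is valid and empty
  expect_length(nearest_neighbor_distances(matrix(numeric(0), 0, 2),
                                           cbind(1, 1)), 0)
  expect_error(nearest_neighbor_distances(cbind(0, 0), cbind(1, 1), cap = -1),
               "cap")
})

test_that("the distance engine matches a brute-force oracle exactly", {
  set.seed(101)
  for (i in 1:30) {
    nt <- sample(20:300, 1); nc <- sample(1:40, 1)
    tumor <- cbind(runif(nt, -500, 500), runif(nt, -500, 500))
    cd8 <- cbind(runif(nc, -500, 500), runif(nc, -500, 500))
    expect_identical(as.numeric(nearest_neighbor_distances(tumor, cd8)),
                     brute_force_nnd(tumor, cd8))
  }
})

test_that("distances are invariant under rigid motions and monotone in CD8 additions", {
  set.seed(55)
  tumor <- cbind(runif(80, -400, 400), runif(80, -400, 400))
  cd8 <- cbind(runif(12, -400, 400), runif(12, -400, 400))
  d0 <- as.numeric(nearest_neighbor_distances(tumor, cd8))
  th <- 0.73
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(112.5, -34.25)
  d1 <- as.numeric(nearest_neighbor_distances(
    sweep(tumor %*% rot, 2, shift, "+"), sweep(cd8 %*% rot, 2, shift, "+")))
  expect_equal(d1, d0, tolerance = 1e-9)
  # adding a CD8 cell can only shrink each tumor cell's distance
  d2 <- as.numeric(nearest_neighbor_distances(tumor, rbind(cd8, c(0, 0))))
  expect_true(all(d2 <= d0 + 1e-12))
})

test_that("pooling concatenates log10 distances across cores", {
  s <- pool_participant(list(c(10, 100)), "P1")
  expect_equal(s$values, c(1, 2))
  split2 <- pool_participant(list(10, 100), "P1")
  expect_equal(sort(split2$values), sort(s$values))
  expect_equal(split2$n_distances, 2L)
  # degenerate: nothing pooled -> empty, flagged downstream
  empty <- pool_participant(list(), "P2")
  expect_equal(empty$n_distances, 0L)
  expect_equal(compute_metrics(empty, 0, 0)$flag, "no_distances")
  expect_error(pool_participant(list(c(10, 0)), "P3"), "coincident")
})

test_that("proximity and consistency equal their hand-computed values", {
  s <- pool_participant(list(c(10, 100)), "P1")   # log10 values {1, 2}
  m <- compute_metrics(s, lymphocyte_count = 7, n_cores_passed = 1)
  expect_equal(m$proximity, 1.5)
  expect_equal(m$consistency, 0.5)                # 1 - sample variance 0.5
  expect_equal(m$lymphocyte_count, 7L)

  all1 <- compute_metrics(pool_participant(list(rep(1, 5)), "P2"), 0, 1)
  expect_equal(all1$proximity, 3)                 # all NNDs at 1 micron
  expect_equal(all1$consistency, 1)

  single <- compute_metrics(pool_participant(list(10), "P3"), 1, 1)
  expect_true(is.na(single$consistency))
  expect_equal(single$flag, "single_distance")
})

test_that("moments match an independent two-pass recomputation on a large sample", {
  set.seed(77)
  d <- 10^runif(10000, 0, 3)
  m <- compute_metrics(pool_participant(list(d), "P1"), 0, 1)
  mom <- two_pass_moments(log10(d))
  expect_equal(m$proximity, 3 - mom$mean, tolerance = 1e-10)
  expect_equal(m$consistency, 1 - mom$var, tolerance = 1e-10)
})

test_that("scaling all distances tenfold shifts proximity by -1 and keeps consistency", {
  set.seed(78)
  d <- 10^runif(500, 0, 2)
  m1 <- compute_metrics(pool_participant(list(d), "P1"), 0, 1)
  m10 <- compute_metrics(pool_participant(list(10 * d), "P1"), 0, 1)
  expect_equal(m10$proximity, m1$proximity - 1, tolerance = 1e-12)
  expect_equal(m10$consistency, m1$consistency, tolerance = 1e-12)
})

test_that("counting double positives as targets never lowers proximity", {
  cfg <- simulation_config(n_participants = 6, cores_per_participant = 2,
                           tumor_intensity = 200, lymphocyte_intensity = 60,
                           stromal_intensity = 100, treg_fraction = 0.4,
                           seed = 91)
  coh <- simulate_cohort(cfg)
  cells <- classify_cells(coh$cells, suggested_thresholds())
  summ <- qc_filter_cores(summarize_cores(cells), 50, 150)
  off <- compute_cohort_metrics(cells, summ)
  on <- compute_cohort_metrics(cells, summ, include_double_positive = TRUE)
  expect_true(all(on$proximity >= off$proximity - 1e-12))
  expect_identical(on$lymphocyte_count, off$lymphocyte_count)
})

test_that("binarization uses the documented quantile conventions", {
  med <- binarize(c(1, 2, 3, 4), "median")
  expect_equal(as.character(med), c("low", "low", "high", "high"))
  expect_equal(attr(med, "cutpoint"), 2.5)
  q1 <- binarize(c(1, 2, 3, 4), "q1")
  expect_equal(as.character(q1), c("low", "high", "high", "high"))
  expl <- binarize(c(1, 2, 3), "explicit", explicit_value = 2)
  expect_equal(as.character(expl), c("low", "high", "high"))
  expect_error(binarize(rep(2, 5), "median"), "degenerate")
  expect_error(binarize(c(1, 2), "explicit"), "explicit_value")
  # median rule splits any tie-free cohort 50/50 within one participant
  set.seed(13)
  for (n in c(101, 102, 257, 400)) {
    cls <- binarize(runif(n), "median")
    expect_lte(abs(sum(cls == "high") - sum(cls == "low")), 1)
  }
})

test_that("cutpoint exploration collapses quartile groups by hazard", {
  # survival independent of the metric: everything merges, no cutpoint
  set.seed(9)
  vals <- runif(4000)
  sv <- simulate_step_survival(rep("high", 4000), hr_low = 1)
  ex <- explore_cutpoints(vals, sv)
  expect_equal(max(ex$blocks), 1)
  expect_true(is.na(ex$cutpoint))

  # a hazard step at the first quartile is recovered
  set.seed(10)
  vals <- runif(1500)
  cls <- as.character(binarize(vals, "q1"))
  sv <- simulate_step_survival(cls, hr_low = 2)
  ex <- explore_cutpoints(vals, sv)
  expect_equal(ex$quantile, 0.25)
  expect_equal(ex$cutpoint, unname(quantile(vals, 0.25)))

  # and a step at the median suggests the median
  set.seed(11)
  vals <- runif(1500)
  cls <- as.character(binarize(vals, "median"))
  sv <- simulate_step_survival(cls, hr_low = 2)
  ex <- explore_cutpoints(vals, sv)
  expect_equal(ex$quantile, 0.5)
})
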