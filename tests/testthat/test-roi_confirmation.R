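test_that("sphere masks enumerate the integer lattice correctly", {
  big <- c(31, 31, 31); ctr <- c(16, 16, 16)
  expect_equal(sphere_mask(ctr, 0, big),
               ambicon:::voxel_index(matrix(ctr, 1), big))
  expect_length(sphere_mask(ctr, 2, big), 33L)
  # lattice enumeration oracle for r <= 5
  for (r in 1:5) {
    oracle <- sum(outer(outer((-r:r)^2, (-r:r)^2, "+"), (-r:r)^2, "+") <= r^2)
    expect_length(sphere_mask(ctr, r, big), oracle)
  }
  # boundary clipping
  expect_length(sphere_mask(c(1, 1, 1), 2, big), 11L)  # octant of 33 + axes
  expect_error(sphere_mask(c(0, 5, 5), 2, big), "outside")
})

test_that("matched splitting balances the halves", {
  cohort <- sample_population(seed = 30)
  sp <- split_matched(cohort, seed = 1)
  expect_length(sp$group1, 16L)
  expect_length(sp$group2, 16L)
  expect_length(intersect(sp$group1, sp$group2), 0L)
  expect_equal(sum(cohort$sex[sp$group1] == "M"), 8L)
  expect_identical(sp, split_matched(cohort, seed = 1))

  # standardized group mean differences stay under 0.5 pooled SD
  for (s in 1:20) {
    co <- sample_population(seed = 200 + s)
    spl <- split_matched(co, seed = s)
    for (v in c("age", "ln_gamma_a", "gamma_c")) {
      z <- as.vector(scale(co[[v]]))
      expect_lt(abs(mean(z[spl$group1]) - mean(z[spl$group2])), 0.5)
    }
  }
})

test_that("splitting falls back to an unpaired split for single-sex strata", {
  cohort <- sample_population(population_spec(n_subjects = 5, prop_male = 0.2),
                              seed = 2)
  sp <- split_matched(cohort, seed = 3)
  expect_false(sp$paired)
  expect_lte(abs(length(sp$group1) - length(sp$group2)), 1L)
})

test_that("candidate peaks are local extrema pruned by separation", {
  grid_dim <- c(16, 16, 16)
  stat <- numeric(prod(grid_dim))
  blob <- function(ctr, amp, rad = 2) {
    idx <- sphere_mask(ctr, rad, grid_dim)
    co <- ambicon:::voxel_coords(idx, grid_dim)
    d <- sqrt(rowSums((co - matrix(ctr, length(idx), 3, byrow = TRUE))^2))
    stat[idx] <<- stat[idx] + amp * (1 - d / (rad + 1))
  }
  blob(c(5, 5, 5), 10)
  blob(c(12, 12, 12), 6)
  peaks <- find_candidate_rois(stat, grid_dim, threshold = 2)
  expect_equal(nrow(peaks), 2L)
  expect_equal(unlist(peaks[1, c("x", "y", "z")]), c(x = 5, y = 5, z = 5))
  # empty suprathreshold set
  expect_equal(nrow(find_candidate_rois(stat, grid_dim, threshold = 99)), 0L)
  # two blobs closer than min_sep: stronger survives
  stat <- numeric(prod(grid_dim))
  blob(c(8, 8, 8), 10)
  blob(c(10, 8, 8), 6)
  p2 <- find_candidate_rois(stat, grid_dim, threshold = 2, min_sep = 4)
  expect_equal(unlist(p2[1, c("x", "y", "z")]), c(x = 8, y = 8, z = 8))
  expect_true(all(sqrt((p2$x - 8)^2 + (p2$y - 8)^2 + (p2$z - 8)^2) == 0 |
                    sqrt((p2$x - 8)^2 + (p2$y - 8)^2 + (p2$z - 8)^2) >= 4))
})

test_that("planted effects present in both halves are confirmed out of sample", {
  ds <- small_planted_dataset(seed = 40)
  pe <- first_level_pe_maps(ds)
  tab <- run_confirmation_pipeline(ds, pe_maps = pe)
  sp <- attr(tab, "split")
  expect_length(intersect(sp$group1, sp$group2), 0L)
  pl <- ds$planted
  hit <- function(stream, ctr, sgn) {
    t2 <- tab[tab$stream == stream & tab$confirmed &
                sign(tab$confirm_stat) == sgn, , drop = FALSE]
    nrow(t2) > 0 &&
      any(sqrt((t2$x - ctr[1])^2 + (t2$y - ctr[2])^2 + (t2$z - ctr[3])^2) <= 3)
  }
  # the two strongly planted level regions replicate across the split
  expect_true(hit("A_level", unlist(pl[1, c("x", "y", "z")]), -1))
  expect_true(hit("C_level", unlist(pl[2, c("x", "y", "z")]), +1))
})

test_that("confirmation controls the error rate on pure-noise data", {
  ds <- small_planted_dataset(seed = 41, n_subjects = 10,
                              planted = default_planted_effects(c(12, 12, 12))[0, ])
  pe <- first_level_pe_maps(ds)
  n_cand <- 0L; n_conf <- 0L
  for (s in 1:40) {
    sp <- split_matched(ds$cohort, seed = s)
    tab <- run_confirmation_pipeline(ds, confirmation_config(max_peaks = 10, seed = s),
                                     pe_maps = pe, split = sp)
    n_cand <- n_cand + nrow(tab)
    n_conf <- n_conf + sum(tab$confirmed)
  }
  expect_gt(n_cand, 100L)
  # splits reuse one dataset, so candidate outcomes are positively
  # correlated; allow generous binomial slack around the nominal 0.05
  expect_lte(n_conf / n_cand, 0.12)
})

test_that("effects private to the exploratory half are rejected", {
  # plant an amplitude only in the subjects that exploration will see:
  # couple the amplitude to a variable that is zeroed in group 2
  grid_dim <- c(12, 12, 12)
  ds <- small_planted_dataset(seed = 42, n_subjects = 12,
                              planted = default_planted_effects(grid_dim)[0, ])
  sp <- split_matched(ds$cohort, seed = 7)
  # inject a strong group-1-only signal into a sphere, directly in the data
  mask <- sphere_mask(c(6, 6, 6), 2, grid_dim)
  for (s in sp$group1) {
    des <- ds$subjects[[s]]$design
    for (r in 1:2) {
      rows <- des$run == r
      sig <- 0.05 * des$X[rows, "ambiguity_level"]
      ds$subjects[[s]]$runs[[r]][mask, ] <-
        ds$subjects[[s]]$runs[[r]][mask, ] + rep(sig, each = length(mask))
    }
  }
  pe <- first_level_pe_maps(ds)
  tab <- run_confirmation_pipeline(ds, pe_maps = pe, split = sp)
  cand <- tab[tab$stream == "A_level" &
                sqrt((tab$x - 6)^2 + (tab$y - 6)^2 + (tab$z - 6)^2) <= 2, ]
  expect_gt(nrow(cand), 0L)          # exploration finds the overfit blob
  expect_false(any(cand$confirmed))  # held-out half rejects it
})
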