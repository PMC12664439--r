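params <- damage_parameters()

test_that("damage probability is the clamped linear ramp", {
  expect_equal(damage_probability(5), 0)
  expect_equal(damage_probability(37.5), 1)
  expect_equal(damage_probability(21.25), 0.5)
  expect_equal(damage_probability(100), 1)
  expect_equal(damage_probability(0), 0)
  e <- seq(0, 60, by = 0.5)
  expect_true(all(diff(damage_probability(e)) >= 0))
  # parameters are validated
  expect_error(damage_parameters(spoints_prob = 1.2), "0, 1")
  expect_error(damage_parameters(emin_damage_eV = 40), "emax")
  expect_error(damage_parameters(min_pts = 1), "min_pts")
  expect_equal(params$eps_nm, 10 * params$bp_length_nm)
})

test_that("break sampling follows the combined Bernoulli acceptance", {
  deps <- point_depositions(rep(37.5, 1e4))
  counts <- vapply(1:100, function(s) nrow(sample_breaks(deps, params, seed = s)), 0)
  se <- sqrt(1e4 * 0.07 * 0.93 / 100)
  expect_lt(abs(mean(counts) - 700), 3 * se)
  # zero-probability regimes
  expect_equal(nrow(sample_breaks(point_depositions(rep(5, 1000)), params, 1)), 0)
  p0 <- damage_parameters(spoints_prob = 0)
  expect_equal(nrow(sample_breaks(deps, p0, 1)), 0)
  # determinism and empty input
  expect_identical(sample_breaks(deps, params, 3), sample_breaks(deps, params, 3))
  expect_equal(nrow(sample_breaks(point_depositions(numeric(0)), params, 1)), 0)
})

test_that("raising the sensitive fraction never lowers expected break counts", {
  deps <- point_depositions(rep(30, 2000))
  mean_at <- function(sp) {
    p <- damage_parameters(spoints_prob = sp)
    mean(vapply(1:40, function(s) nrow(sample_breaks(deps, p, seed = s)), 0))
  }
  m <- vapply(c(0.02, 0.07, 0.2, 0.6), mean_at, 0)
  expect_true(all(diff(m) > 0))
})

test_that("clustering joins breaks strictly inside 3.4 nm", {
  two_close <- axis_breaks(c(0, 3.0), c(0, 1))
  cl <- cluster_breaks(two_close, params)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$size, 2)
  expect_equal(nrow(cl$isolated), 0)

  two_far <- axis_breaks(c(0, 3.5), c(0, 1))
  cl2 <- cluster_breaks(two_far, params)
  expect_equal(nrow(cl2$clusters), 0)
  expect_equal(nrow(cl2$isolated), 2)

  # exactly eps apart does not join (strict less-than)
  boundary <- axis_breaks(c(0, 3.4), c(0, 1))
  expect_equal(nrow(cluster_breaks(boundary, params)$clusters), 0)

  # chain A-B-C at 3.0 spacings joins transitively even though A-C is 6.0
  chain <- axis_breaks(c(0, 3.0, 6.0), c(0, 1, 0))
  cl3 <- cluster_breaks(chain, params)
  expect_equal(nrow(cl3$clusters), 1)
  expect_equal(cl3$clusters$size, 3)
  expect_equal(cl3$clusters$max_span_nm, 6.0)
})

test_that("clustering is independent of input order", {
  b <- random_breaks(300, side_nm = 40, seed = 12)
  perm <- withr::with_seed(99, sample(nrow(b)))
  cl_a <- cluster_breaks(b, params)
  cl_b <- cluster_breaks(b[perm, ], params)
  # compare partitions as sets of sorted original indices
  canon <- function(cl, idx) {
    sets <- lapply(cl$clusters$members, function(m) sort(idx[m]))
    sets[order(vapply(sets, min, 0))]
  }
  expect_identical(canon(cl_a, seq_len(nrow(b))), canon(cl_b, perm))
})

test_that("classification truth table: SSB, complex SSB, simple and complex DSB", {
  run <- function(strands) {
    b <- axis_breaks(seq(0, by = 2, length.out = length(strands)), strands)
    cl <- cluster_breaks(b, params)
    classify_clusters(cl$clusters, cl$isolated)
  }
  opp2 <- run(c(0, 1))   # one simple DSB
  expect_equal(opp2[, c("n_ssb", "n_complex_ssb", "n_simple_dsb", "n_complex_dsb")],
               tibble::tibble(n_ssb = 0L, n_complex_ssb = 0L,
                              n_simple_dsb = 1L, n_complex_dsb = 0L),
               ignore_attr = TRUE)
  same2 <- run(c(0, 0))  # complex SSB, no DSB
  expect_equal(same2$n_complex_ssb, 1L)
  expect_equal(same2$n_dsb, 0L)
  mixed3 <- run(c(0, 0, 1))  # complex DSB
  expect_equal(mixed3$n_complex_dsb, 1L)
  expect_equal(mixed3$n_simple_dsb, 0L)
  expect_equal(mixed3$n_dsb, 1L)
  same3 <- run(c(1, 1, 1))   # still a complex SSB
  expect_equal(same3$n_complex_ssb, 1L)
  expect_equal(same3$n_dsb, 0L)
  # n_dsb decomposes and the break count is conserved
  expect_equal(mixed3$n_dsb, mixed3$n_simple_dsb + mixed3$n_complex_dsb)
  expect_equal(mixed3$n_breaks, 3L)
})

test_that("cluster partition equals the brute-force oracle on random fixtures", {
  for (case in list(c(100, 30), c(400, 25), c(50, 300), c(0, 10), c(1, 10))) {
    b <- random_breaks(case[1], side_nm = case[2], seed = case[1] + case[2])
    expect_identical(cluster_breaks(b, params)$assignment,
                     brute_force_cluster(b, params$eps_nm)$assignment)
  }
  # degenerate: all points identical form one cluster of size n
  same <- axis_breaks(rep(0, 7), rep(c(0, 1), length.out = 7))
  expect_equal(brute_force_cluster(same)$clusters$size, 7L)
  expect_equal(cluster_breaks(same, params)$clusters$size, 7L)
  # empty input
  expect_equal(nrow(brute_force_cluster(axis_breaks(numeric(0), integer(0)))$clusters), 0)
})

test_that("damage counts are invariant under rigid motion", {
  b <- random_breaks(250, side_nm = 35, seed = 77)
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
  p <- as.matrix(b[, c("x_nm", "y_nm", "z_nm")]) %*% t(rot)
  b2 <- b
  b2$x_nm <- p[, 1] + 100; b2$y_nm <- p[, 2] - 40; b2$z_nm <- p[, 3] + 5
  cl1 <- cluster_breaks(b, params); cl2 <- cluster_breaks(b2, params)
  expect_equal(classify_clusters(cl1$clusters, cl1$isolated)[, 1:6],
               classify_clusters(cl2$clusters, cl2$isolated)[, 1:6])
})

test_that("conservation: cluster sizes plus isolated count equals accepted breaks", {
  m <- alpha_track_model()
  ex <- generate_nucleus_exposure(20, list(m), seed = 41)
  for (tid in unique(ex$depositions$track_id)[1:5]) {
    deps <- ex$depositions[ex$depositions$track_id == tid, ]
    brk <- sample_breaks(deps, params, seed = 100 + tid)
    cl <- cluster_breaks(brk, params)
    expect_equal(sum(cl$clusters$size) + nrow(cl$isolated), nrow(brk))
  }
})

test_that("single-strand exposures can never produce a DSB", {
  p1 <- damage_parameters(strand_prob = 1)
  m <- alpha_track_model()
  ex <- generate_nucleus_exposure(15, list(m), seed = 51)
  s <- score_exposure(ex, p1, seed = 2)
  expect_equal(sum(s$n_dsb), 0L)
  expect_gt(sum(s$n_complex_ssb), 0)  # clusters exist, all one strand
})

test_that("score_track composes the chain and guards its preconditions", {
  # empty deposition list gives the all-zero summary
  s0 <- score_track(point_depositions(numeric(0)), params, seed = 1,
                    particle = "e-")
  expect_equal(s0$n_breaks, 0L)
  expect_equal(s0$n_dsb, 0L)
  expect_equal(s0$deposited_energy_eV, 0)
  # a single deposit can never make a DSB
  s1 <- score_track(point_depositions(1e6), params, seed = 1)
  expect_lte(s1$n_breaks, 1L)
  expect_equal(s1$n_dsb, 0L)
  # deterministic across runs
  deps <- point_depositions(withr::with_seed(5, runif(50, 5, 100)))
  expect_identical(score_track(deps, params, seed = 9),
                   score_track(deps, params, seed = 9))
  # mixed track ids are rejected
  mixed <- rbind(point_depositions(10, track_id = 1L),
                 point_depositions(10, track_id = 2L))
  expect_error(score_track(mixed, params, seed = 1), "one track")
})

test_that("scoring never clusters across track boundaries", {
  deps <- rbind(point_depositions(rep(100, 30), track_id = 1L),
                point_depositions(rep(100, 30), track_id = 2L))
  ex <- lymphdsb:::new_nucleus_exposure(
    deps,
    tibble::tibble(track_id = 1:2, particle = "e-", ekin_MeV = 1,
                   chord_um = 1, alpha_track_length_um = NA_real_),
    nucleus_radius_um = 3.1, seed = 1)
  p_all <- damage_parameters(spoints_prob = 1)
  s <- score_exposure(ex, p_all, seed = 4)
  expect_equal(nrow(s), 2)
  # all 60 depositions sit at the origin 0 nm apart, but tracks stay separate:
  # each track forms one within-track cluster, never a merged one
  expect_true(all(vapply(s$cluster_sizes, max, 0L) <= 30L))
  # totals are additive over summaries
  expect_equal(sum(s$n_breaks), 60L)
})
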