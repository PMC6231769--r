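# Concavity detection, scoring, IDR filtering, boundaries, merging.

test_that("smoothed second derivative: constants, bumps, linearity", {
  expect_true(all(abs(smoothed_second_derivative(rep(5, 2000), 50)) < 1e-9))
  expect_error(smoothed_second_derivative(numeric(0), 50), "empty")

  x <- seq_len(4000)
  bump <- 40 * exp(-(x - 2000)^2 / (2 * 75^2))
  d2 <- smoothed_second_derivative(bump, 50)
  expect_lt(d2[2000], 0)
  run <- rle(d2 < 0)
  # the apex lies inside one contiguous negative run
  neg_at_apex <- cumsum(run$lengths)[run$values & cumsum(run$lengths) >= 2000][1]
  expect_false(is.na(neg_at_apex))

  y <- 10 * exp(-(x - 900)^2 / (2 * 50^2))
  expect_equal(smoothed_second_derivative(bump + y, 50),
               smoothed_second_derivative(bump, 50) +
                 smoothed_second_derivative(y, 50),
               tolerance = 1e-9)
})

test_that("find_concave_regions localizes summits and orders regions", {
  x <- seq_len(6000)
  flat <- rep(3, 6000)
  d2f <- smoothed_second_derivative(flat, 50)
  expect_equal(nrow(find_concave_regions(d2f, flat)), 0L)

  bump <- 40 * exp(-(x - 1500)^2 / (2 * 75^2))
  cand <- find_concave_regions(smoothed_second_derivative(bump, 50), bump)
  expect_equal(nrow(cand), 1L)
  expect_lte(abs(cand$summit - (1500 - 1L)), 5)  # 0-based vs apex index

  two <- bump + 40 * exp(-(x - 2500)^2 / (2 * 75^2))
  cand2 <- find_concave_regions(smoothed_second_derivative(two, 50), two)
  expect_equal(nrow(cand2), 2L)
  expect_true(cand2$summit[1] < cand2$summit[2])
})

test_that("score_candidates is pointwise, nonnegative and linear", {
  x <- seq_len(4000)
  mean_track <- 40 * exp(-(x - 2000)^2 / (2 * 75^2))
  d2 <- smoothed_second_derivative(mean_track, 50)
  cand <- find_concave_regions(d2, mean_track)
  s_same <- score_candidates(cand, mean_track, 50)
  expect_equal(s_same, abs(d2[cand$summit + 1L]), tolerance = 1e-7)
  expect_equal(score_candidates(cand, numeric(4000), 50),
               rep(0, nrow(cand)))
  expect_equal(score_candidates(cand, 2 * mean_track, 50), 2 * s_same,
               tolerance = 1e-9)
})

test_that("fit_idr: monotone IDR, null and mixture recovery, perfect reps", {
  sim0 <- simulate_idr_scores(n = 2000, pi1 = 0, seed = 3)
  f0 <- fit_idr(sim0$s1, sim0$s2)
  expect_lt(f0$pi1, 0.1)
  expect_gt(mean(f0$IDR > 0.5), 0.95)

  sim <- simulate_idr_scores(n = 2000, pi1 = 0.5, mu = 3, rho = 0.95, seed = 7)
  f <- fit_idr(sim$s1, sim$s2)
  expect_gte(mean((f$idr_local < 0.5) == sim$labels), 0.85)
  ord <- order(f$idr_local)
  expect_false(is.unsorted(f$IDR[ord]))

  set.seed(11); x <- rgamma(500, 2)
  fi <- fit_idr(x, x)
  expect_equal(min(fi$IDR), fi$IDR[which.max(x)], tolerance = 1e-6)
  expect_false(is.unsorted(fi$IDR[order(fi$idr_local)]))

  expect_error(fit_idr(rep(1, 100), rep(1, 100)), "tied")
  expect_error(fit_idr(rnorm(10), rnorm(10)), "50")
})

test_that("call_peaks applies the IDR cutoff and boundary rule", {
  set.seed(5)
  n <- 300
  cand <- data.table::data.table(chrom = "chr", start = seq_len(n) * 1000L,
                                 end = seq_len(n) * 1000L + 200L,
                                 summit = seq_len(n) * 1000L + 100L)
  # 30 reproducible candidates with high correlated scores
  base <- c(rexp(30, 1 / 20) + 15, rexp(n - 30, 1))
  s1 <- base + rnorm(n, 0, 0.5); s2 <- base + rnorm(n, 0, 0.5)
  s2[31:n] <- rexp(n - 30, 1)   # irreproducible tail
  sites <- call_peaks(cand, list(stageA = list(s1, s2)), idr_cutoff = 0.05)
  expect_true(all(sites$end - sites$start == 151L))
  expect_true(all(sites$summit - sites$start == 75L))
  expect_true(all(sites$idr <= 0.05))
  expect_gt(nrow(sites), 15)
  # boundary example: summit 1000 -> [925, 1076)
  i <- which(sites$summit == 1100L)[1]
  if (!is.na(i)) expect_equal(unlist(sites[i, .(start, end)]),
                              c(start = 1025L, end = 1176L))
})

test_that("merge_peak_sets keeps earlier-set precedence and tags sources", {
  p <- data.table::data.table(chrom = "chr", start = 100L, end = 251L)
  s <- data.table::data.table(chrom = "chr", start = 150L, end = 301L)
  m <- merge_peak_sets(p, s, NULL)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 100L)
  expect_equal(m$atac_source, "atac_wt_pe")

  m2 <- merge_peak_sets(data.table::data.table(chrom = character(0),
                                               start = integer(0),
                                               end = integer(0)), p, s)
  expect_equal(m2$atac_source, "atac_wt_se")   # secondary only (s overlaps p)

  d1 <- data.table::data.table(chrom = "chr", start = c(0L, 500L),
                               end = c(151L, 651L))
  d2 <- data.table::data.table(chrom = "chr", start = c(1000L, 1500L, 2000L),
                               end = c(1151L, 1651L, 2151L))
  d3 <- data.table::data.table(chrom = "chr",
                               start = 3000L + c(0L, 500L, 1000L, 1500L),
                               end = 3151L + c(0L, 500L, 1000L, 1500L))
  m3 <- merge_peak_sets(d1, d2, d3)
  expect_equal(nrow(m3), 9L)
  expect_equal(as.integer(table(m3$atac_source)[c("atac_wt_pe", "atac_wt_se",
                                                  "atac_glp1_se")]),
               c(2L, 3L, 4L))
  # idempotence: merging a set with itself returns the set
  m4 <- merge_peak_sets(d1, d1, d1)
  expect_equal(m4[, .(chrom, start, end)], d1)
})
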