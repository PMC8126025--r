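test_that("pooling 96 fractions with k = 2 gives 48 samples and conserves totals", {
  sim <- tiny_sim()
  pooled <- pool_fractions(sim$quant)
  expect_equal(sort(unique(pooled$sample)), 1:48)
  tot_in <- tapply(sim$quant$peak_area,
                   paste(sim$quant$protein_id, sim$quant$replicate), sum)
  tot_out <- tapply(pooled$peak_area,
                    paste(pooled$protein_id, pooled$replicate), sum)
  expect_equal(tot_out, tot_in[names(tot_out)], tolerance = 1e-12)
})

test_that("pooled values follow the pairwise-sum oracle", {
  # one protein with peak_area equal to its fraction index: pooled sample s
  # must equal (2s-1) + 2s = 4s - 1
  q <- tibble::tibble(protein_id = "p", sample = 1:96, replicate = 1L,
                      peak_area = as.numeric(1:96))
  attr(q, "sample_level") <- "fraction"
  pooled <- pool_fractions(q)
  expect_equal(pooled$peak_area, 4 * (1:48) - 1)
  # all-zero input stays all zero
  q0 <- dplyr::mutate(q, peak_area = 0)
  attr(q0, "sample_level") <- "fraction"
  expect_true(all(pool_fractions(q0)$peak_area == 0))
})

test_that("pooling rejects pooled-level input and bad widths", {
  pooled <- pool_fractions(tiny_sim()$quant)
  expect_error(pool_fractions(pooled), class = "ffeprof_usage_error")
  expect_error(pool_fractions(tiny_sim()$quant, k = 5),
               class = "ffeprof_usage_error")
})

test_that("OD pooling mirrors fraction pooling", {
  od <- tibble::tibble(fraction = 1:96, od280 = as.numeric(1:96))
  pod <- pool_od280(od)
  expect_equal(nrow(pod), 48)
  expect_equal(pod$od280, 4 * (1:48) - 1)
  expect_equal(sum(pod$od280), sum(od$od280))
  od0 <- dplyr::mutate(od, od280 = 0)
  expect_true(all(pool_od280(od0)$od280 == 0))
})

test_that("the analysis window reproduces the fraction 15-70 geometry", {
  od <- tibble::tibble(fraction = 1:96,
                       od280 = ifelse(dplyr::between(1:96, 15, 70), 0.5, 0))
  w <- select_analysis_window(pool_od280(od))
  expect_equal(w, 8:35)
  expect_length(w, 28)
})

test_that("window selection handles degenerate traces", {
  all_pos <- tibble::tibble(sample = 1:48, od280 = 1)
  expect_equal(select_analysis_window(all_pos), 1:48)
  none <- tibble::tibble(sample = 1:48, od280 = 0)
  expect_error(select_analysis_window(none),
               class = "ffeprof_empty_window_error")
  # largest of two disjoint runs wins; oracle: exhaustive scan of all
  # contiguous positive runs
  od <- rep(0, 48)
  od[5:9] <- 1    # length 5
  od[20:28] <- 1  # length 9
  runs <- rle(od > 0)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  best <- keep[which.max(runs$lengths[keep])]
  expect_equal(select_analysis_window(tibble::tibble(sample = 1:48, od280 = od)),
               starts[best]:ends[best])
  expect_equal(starts[best]:ends[best], 20:28)
})

test_that("window selection is idempotent", {
  sim <- tiny_sim()
  pod <- pool_od280(sim$od280)
  w <- select_analysis_window(pod)
  expect_equal(select_analysis_window(pod[pod$sample %in% w, ]), w)
})

test_that("OD normalization is per-sample division", {
  q <- tibble::tibble(protein_id = "p", sample = c(1L, 2L), replicate = 1L,
                      peak_area = c(10, 0))
  od <- tibble::tibble(sample = c(1L, 2L), od280 = c(0.5, 2))
  norm <- normalize_to_od280(q, od, window = 1:2)
  expect_equal(norm$peak_area, c(20, 0))
  # constant OD rescales uniformly, leaving profile shape unchanged
  sim <- clean_sim()
  pooled <- pool_fractions(sim$quant)
  flat <- tibble::tibble(sample = 1:48, od280 = 2)
  n1 <- normalize_to_od280(pooled, flat, 8:35)
  ref <- dplyr::filter(pooled, sample %in% 8:35)
  expect_equal(n1$peak_area, ref$peak_area / 2, tolerance = 1e-12)
  # zero OD inside the window is an invariant violation
  bad <- tibble::tibble(sample = 1:48, od280 = c(rep(1, 20), 0, rep(1, 27)))
  expect_error(normalize_to_od280(pooled, bad, 8:35),
               class = "ffeprof_integrity_error")
  expect_error(normalize_to_od280(pooled, flat, 40:50),
               class = "ffeprof_usage_error")
})

test_that("replicate averaging takes the arithmetic mean including zeros", {
  q <- tibble::tibble(protein_id = "p", sample = 1L, replicate = 1:3,
                      peak_area = c(1, 2, 3))
  avg <- average_replicates(q)
  expect_equal(avg$mean_area, 2)
  expect_equal(avg$sd_area, stats::sd(c(1, 2, 3)))
  # identical replicates: mean equals each, dispersion 0
  q2 <- tibble::tibble(protein_id = "p", sample = rep(1:2, each = 3),
                       replicate = rep(1:3, 2), peak_area = rep(c(5, 7), each = 3))
  avg2 <- average_replicates(q2)
  expect_equal(avg2$mean_area, c(5, 7))
  expect_equal(avg2$sd_area, c(0, 0))
  # an entirely missing replicate stays in the denominator, with a message
  q3 <- tibble::tibble(protein_id = "p", sample = rep(1L, 3), replicate = 1:3,
                       peak_area = c(3, 3, 0))
  expect_message(avg3 <- average_replicates(q3), "undetected")
  expect_equal(avg3$mean_area, 2)
})

test_that("unit normalization gives unit-sum profiles and flags empty ones", {
  prof <- tibble::tibble(protein_id = rep(c("a", "z"), each = 3),
                         sample = rep(1:3, 2),
                         mean_area = c(2, 2, 4, 0, 0, 0))
  u <- unit_normalize(prof)
  expect_equal(u$rel_abundance[u$protein_id == "a"], c(0.25, 0.25, 0.5))
  expect_true(all(u$zero_profile[u$protein_id == "z"]))
  expect_equal(u$rel_abundance[u$protein_id == "z"], c(0, 0, 0))
  # unit-sum input is unchanged
  u2 <- unit_normalize(dplyr::filter(u, protein_id == "a") |>
                         dplyr::mutate(mean_area = rel_abundance))
  expect_equal(u2$rel_abundance, c(0.25, 0.25, 0.5))
})

test_that("digital_westerns runs the full chain onto the analysis window", {
  sim <- clean_sim()
  dw <- digital_westerns(sim$quant, sim$od280)
  expect_s3_class(dw, "ffe_westerns")
  expect_equal(attr(dw, "window"), 8:35)
  expect_equal(sort(unique(dw$sample)), 8:35)
  sums <- tapply(dw$rel_abundance, dw$protein_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # averaging then unit-normalizing equals unit-normalizing the average
  pooled <- pool_fractions(sim$quant)
  pod <- pool_od280(sim$od280)
  norm <- normalize_to_od280(pooled, pod, 8:35)
  manual <- unit_normalize(average_replicates(norm))
  merged <- dplyr::inner_join(
    dw, manual, by = c("protein_id", "sample"), suffix = c("", ".m")
  )
  expect_equal(merged$rel_abundance, merged$rel_abundance.m, tolerance = 1e-12)
})
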