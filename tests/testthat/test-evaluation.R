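test_that("recall and precision follow their set definitions", {
  expect_equal(recall(1:10, 1:10), 1.0)
  expect_equal(recall(1:10, c(1:8, 99L, 98L, 97L)), 0.8)
  expect_equal(precision(1:10, 1:10), 1.0)
  expect_equal(precision(1:10, c(1:8, 91:98)), 0.5)
  expect_error(recall(integer(0), 1:3), "non-empty")
  expect_true(is.na(precision(1:10, integer(0)))) # undefined, not 0

  withr::with_seed(61, {
    for (i in 1:20) {
      e <- sample(1:200, sample(1:50, 1))
      c_ <- sample(1:200, sample(1:50, 1))
      hits <- sum(vapply(unique(e), function(t) t %in% c_, logical(1)))
      expect_equal(recall(e, c_), hits / length(unique(e)))
      expect_equal(precision(e, c_), hits / length(unique(c_)))
    }
  })
})

test_that("false positives lower precision and never touch recall", {
  expected <- 1:10
  classified <- 1:8
  r0 <- recall(expected, classified)
  p0 <- precision(expected, classified)
  for (extra in list(101L, 101:102, 101:110)) {
    cl <- c(classified, extra)
    expect_equal(recall(expected, cl), r0)
    expect_lt(precision(expected, cl), p0)
  }
  # doubling the false-positive species strictly decreases precision
  p1 <- precision(expected, c(classified, 101:104))
  p2 <- precision(expected, c(classified, 101:108))
  expect_lt(p2, p1)
})

test_that("species sets respect the count filter", {
  fix <- small_fixture()
  idx <- build_kmer_index(fix$genomes, k = 31)
  rs <- simulate_reads(fix$genomes, fix$profile, 1500, read_length = 100,
                       error_rate = 0, seed = 63)
  res <- classify_kmer(rs, idx, fix$tree)

  sets <- species_sets(res, rs$truth, min_count = 1, groups = fix$groups)
  for (i in seq_len(nrow(sets))) {
    expect_setequal(sets$classified[[i]], sets$expected[[i]]) # perfect classifier
  }

  # min_count above the largest count: nothing classified, precision undefined
  sat <- species_sets(res, rs$truth,
                      min_count = max(res$counts_at_species$count) + 1L,
                      groups = fix$groups)
  expect_true(all(lengths(sat$classified) == 0L))
  ev <- evaluate_run(res, rs$truth,
                     min_count = max(res$counts_at_species$count) + 1L,
                     groups = fix$groups)
  expect_true(all(is.na(ev$precision)))
  expect_true(all(ev$recall == 0))

  # min_count = 100 removes exactly the species with counts < 100
  counts <- res$counts_at_species
  direct <- sort(counts$taxid[counts$count >= 100L])
  sets100 <- species_sets(res, rs$truth, min_count = 100, groups = fix$groups)
  expect_setequal(unlist(sets100$classified), direct)
})

test_that("evaluation rows reconcile their counts", {
  fix <- small_fixture()
  idx <- build_kmer_index(fix$genomes, k = 31)
  rs <- simulate_reads(fix$genomes, fix$profile, 800, read_length = 100,
                       error_rate = 0, seed = 67)
  cls <- group_classifiers(fix$genomes, fix$tree)
  run <- run_ordered(rs, cls, "d")
  ev <- evaluate_run(run, rs$truth, replicate_id = 3L, depth = 800)
  expect_true(all(ev$n_correct <= pmin(ev$n_expected, ev$n_classified)))
  expect_true(all(ev$recall >= 0 & ev$recall <= 1))
  expect_true(all(ev$precision >= 0 & ev$precision <= 1, na.rm = TRUE))
  expect_equal(ev$replicate_id, rep(3L, nrow(ev)))

  # metrics invariant under read-id relabelling
  rs2 <- rs
  relabel <- stats::setNames(sprintf("x%05d", seq_len(nrow(rs$reads))), rs$reads$read_id)
  rs2$reads$read_id <- unname(relabel[rs$reads$read_id])
  rs2$truth$read_id <- unname(relabel[rs$truth$read_id])
  run2 <- run_ordered(rs2, cls, "d")
  ev2 <- evaluate_run(run2, rs2$truth, replicate_id = 3L, depth = 800)
  expect_equal(ev2, ev)
})

test_that("default abundance bins tile the axis contiguously", {
  bins <- abundance_bins()
  expect_equal(nrow(bins), 6L)
  expect_equal(bins$lower[-nrow(bins)], bins$upper[-1L]) # contiguous
  expect_true(all(diff(bins$lower) < 0)) # ordered, most abundant first
  # every abundance falls in exactly one bin
  for (a in c(0.5, 0.01, 0.005, 0.002, 1e-3, 4e-4, 2e-4, 1e-4, 7e-5, 5e-5, 1e-6)) {
    expect_equal(sum(a > bins$lower & a <= bins$upper), 1L)
  }
})

test_that("detection probability pools replicates and flags missing species", {
  fix <- small_fixture()
  prof <- fix$profile
  # perfect classifier: probability 1 in every occupied bin
  reps <- lapply(1:3, function(i) list(expected = prof$taxid, classified = prof$taxid))
  det <- detection_probability(reps, prof)
  occupied <- det$n_expected > 0L
  expect_true(all(det$probability[occupied] == 1))
  expect_equal(sum(det$n_expected), 3L * nrow(prof))

  # pooled detection over all bins equals overall recall (consistency identity)
  miss <- lapply(1:3, function(i) {
    list(expected = prof$taxid, classified = sample(prof$taxid, 7))
  })
  det2 <- detection_probability(miss, prof)
  pooled <- sum(det2$n_detected) / sum(det2$n_expected)
  overall <- mean(vapply(miss, function(r) recall(r$expected, r$classified), numeric(1)))
  expect_equal(pooled, overall)

  # per-replicate option
  det3 <- detection_probability(miss, prof, per_replicate = TRUE)
  expect_equal(sort(unique(det3$replicate)), 1:3)
  expect_equal(sum(det3$n_detected), sum(det2$n_detected))

  # species absent from the profile are a consistency error
  bad <- list(list(expected = c(prof$taxid, 99999L), classified = prof$taxid))
  expect_error(detection_probability(bad, prof), "absent from profile")
})

test_that("species under the sampling floor are rarely detected", {
  # a species expecting < 1 read at this depth: detection probability near 0
  prof <- tibble::tibble(
    taxid = c(1L, 2L), group = "bacteria", rank = c(1L, 2L),
    expected_abundance = c(1 - 5e-6, 5e-6)
  )
  reps <- lapply(1:4, function(i) list(expected = prof$taxid, classified = 1L))
  det <- detection_probability(reps, prof)
  tail_bin <- det[det$label == "< 5e-5", ]
  expect_equal(tail_bin$n_expected, 4L)
  expect_equal(tail_bin$probability, 0)
})

test_that("depth trends reproduce closed-form least squares", {
  # degenerate: constant precision
  const <- tibble::tibble(depth = rep(c(1e5, 1e6, 1e7), each = 2), precision = 0.7)
  expect_equal(depth_trend(const),
               tibble::tibble(slope = 0, r_squared = 0, p_value = 1, n = 6L))

  # exactly linear in log10(depth)
  lin <- tibble::tibble(depth = c(1e5, 1e6, 1e7), precision = c(0.9, 0.8, 0.7))
  fit <- suppressWarnings(depth_trend(lin)) # lm warns on an exact fit
  expect_equal(fit$slope, -0.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # random series against the closed-form OLS solution
  withr::with_seed(71, {
    d <- rep(c(1e5, 5e5, 1e6, 5e6, 1e7), each = 3)
    y <- stats::runif(length(d), 0.4, 0.9)
  })
  got <- depth_trend(tibble::tibble(depth = d, precision = y))
  x <- log10(d)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  ss_res <- sum((y - alpha - beta * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  expect_equal(got$slope, beta, tolerance = 1e-12)
  expect_equal(got$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-12)
  # t statistic for the slope
  se_beta <- sqrt(ss_res / (length(y) - 2) / sum((x - mean(x))^2))
  p <- 2 * stats::pt(abs(beta / se_beta), df = length(y) - 2, lower.tail = FALSE)
  expect_equal(got$p_value, p, tolerance = 1e-12)

  expect_error(depth_trend(tibble::tibble(depth = c(1e5, 1e6), precision = 1:2 / 10)),
               "3 distinct depths")
})

test_that("replicate summaries average metrics and skip undefined precision", {
  results <- dplyr::bind_rows(
    tibble::tibble(group = "virus", n_expected = 10L, n_classified = 10L,
                   n_correct = 8L, recall = 0.8, precision = 0.8,
                   replicate_id = 1L, depth = NA_real_),
    tibble::tibble(group = "virus", n_expected = 10L, n_classified = 5L,
                   n_correct = 4L, recall = 0.4, precision = 0.8,
                   replicate_id = 2L, depth = NA_real_),
    tibble::tibble(group = "virus", n_expected = 10L, n_classified = 0L,
                   n_correct = 0L, recall = 0, precision = NA_real_,
                   replicate_id = 3L, depth = NA_real_)
  )
  sm <- summarise_eval(results)
  expect_equal(sm$n_replicates, 3L)
  expect_equal(sm$recall_mean, mean(c(0.8, 0.4, 0)))
  expect_equal(sm$precision_mean, 0.8) # NA precision excluded, not zeroed
})
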