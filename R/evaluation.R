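#' Taxon-set recall and precision
#'
#' The two benchmark statistics for comparing a run's reported species set
#' against the truth. Recall is the number of correctly identified taxa
#' divided by the total expected number; precision is the number of correctly
#' identified taxa divided by the total number classified. Recall rewards
#' methods that classify broadly; precision penalises over-classification.
#' Precision is undefined when nothing was classified and is returned as `NA`
#' (reported as missing, not 0, so replicate means are not biased).
#'
#' @param expected_species Non-empty vector of truly present species taxids.
#' @param classified_species Vector of species taxids the run reported.
#' @return A fraction in `[0, 1]` (or `NA` for undefined precision).
#' @export
#' @examples
#' recall(1:10, c(1:8, 99L))      # 0.8
#' precision(1:10, c(1:8, 91:98)) # 0.5
recall <- function(expected_species, classified_species) {
  expected_species <- unique(expected_species)
  if (length(expected_species) == 0L) abort("`expected_species` must be non-empty.")
  length(intersect(expected_species, classified_species)) / length(expected_species)
}

#' @rdname recall
#' @export
precision <- function(expected_species, classified_species) {
  classified_species <- unique(classified_species)
  if (length(classified_species) == 0L) return(NA_real_)
  length(intersect(expected_species, classified_species)) / length(classified_species)
}

#' Expected and classified species sets per group
#'
#' Derives, per taxonomic group, the truth species set (species with at least
#' one simulated read in the group) and the reported species set (species
#' whose species-projected read count reaches `min_count`). `min_count` is the
#' abundance filter practitioners apply to tame over-classification — e.g. the
#' conventional arbitrary cut-off of 100 reads; the default 1 applies no
#' filter.
#'
#' For a `pipeline_run`, classified species are attributed to the group whose
#' classifier reported them. For a single [classification_result()] a
#' `groups` map (tibble `taxid`, `group`) must be supplied; species absent
#' from the map are kept under group `"unknown"`.
#'
#' @param run A `pipeline_run` or [classification_result()].
#' @param truth Truth tibble (`read_id`, `taxid`, `group`, ...).
#' @param min_count Minimum species-projected read count to call a species
#'   reported (default 1).
#' @param groups Optional species-to-group map, required for a bare
#'   `classification_result`.
#' @return Tibble with columns `group`, `expected` (list of taxid vectors),
#'   `classified` (list of taxid vectors).
#' @export
species_sets <- function(run, truth, min_count = 1, groups = NULL) {
  truth <- tibble::as_tibble(truth)
  expected_tbl <- truth |>
    dplyr::distinct(.data$group, .data$taxid) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(expected = list(sort(.data$taxid)), .groups = "drop")

  if (inherits(run, "pipeline_run")) {
    classified_tbl <- purrr::imap_dfr(run$results, function(res, g) {
      counts <- res$counts_at_species
      tibble::tibble(
        group = g,
        classified = list(sort(counts$taxid[counts$count >= min_count]))
      )
    })
  } else if (inherits(run, "classification_result")) {
    if (is.null(groups)) {
      abort("Supply a `groups` map (taxid, group) to attribute species of a bare classification_result.")
    }
    counts <- run$counts_at_species
    kept <- counts$taxid[counts$count >= min_count]
    g_of <- groups$group[match(kept, groups$taxid)]
    g_of[is.na(g_of)] <- "unknown"
    classified_tbl <- tibble::tibble(taxid = kept, group = g_of) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(classified = list(sort(.data$taxid)), .groups = "drop")
  } else {
    abort("`run` must be a pipeline_run or classification_result.")
  }

  bad <- setdiff(classified_tbl$group, c(unique(truth$group), "unknown"))
  dplyr::full_join(expected_tbl, classified_tbl, by = "group") |>
    dplyr::mutate(
      expected = purrr::map(.data$expected, ~ .x %||% integer(0)),
      classified = purrr::map(.data$classified, ~ .x %||% integer(0))
    ) |>
    dplyr::arrange(match(.data$group, c(GROUP_LEVELS, "unknown")))
}

#' Score a classification run against truth
#'
#' Convenience wrapper combining [species_sets()], [recall()] and
#' [precision()] into the per-group metric table used across replicates and
#' conditions.
#'
#' @inheritParams species_sets
#' @param replicate_id,depth Optional identifiers carried into the output
#'   (depth = total simulated reads of the replicate).
#' @return Tibble with one row per group: `group`, `n_expected`,
#'   `n_classified`, `n_correct`, `recall`, `precision`, `replicate_id`,
#'   `depth`.
#' @export
evaluate_run <- function(run, truth, min_count = 1, groups = NULL,
                         replicate_id = NA_integer_, depth = NA_real_) {
  sets <- species_sets(run, truth, min_count = min_count, groups = groups)
  sets |>
    dplyr::mutate(
      n_expected = lengths(.data$expected),
      n_classified = lengths(.data$classified),
      n_correct = purrr::map2_int(
        .data$expected, .data$classified,
        ~ length(intersect(.x, .y))
      ),
      recall = ifelse(
        .data$n_expected > 0L,
        .data$n_correct / .data$n_expected, NA_real_
      ),
      precision = ifelse(
        .data$n_classified > 0L,
        .data$n_correct / .data$n_classified, NA_real_
      ),
      replicate_id = replicate_id,
      depth = depth
    ) |>
    dplyr::select(
      "group", "n_expected", "n_classified", "n_correct",
      "recall", "precision", "replicate_id", "depth"
    )
}

#' Default expected-abundance bins
#'
#' Six bins over expected relative abundance used for detection-probability
#' curves. Boundaries 0.01, 0.002, 4e-4, 1e-4 and 5e-5 tile the abundance
#' axis contiguously; membership is `lower < abundance <= upper`, rows ordered
#' from most to least abundant.
#'
#' @return Tibble with columns `label`, `lower`, `upper`.
#' @export
abundance_bins <- function() {
  tibble::tibble(
    label = c("> 1e-2", "1e-2 - 2e-3", "2e-3 - 4e-4",
              "4e-4 - 1e-4", "1e-4 - 5e-5", "< 5e-5"),
    lower = c(1e-2, 2e-3, 4e-4, 1e-4, 5e-5, 0),
    upper = c(Inf, 1e-2, 2e-3, 4e-4, 1e-4, 5e-5)
  )
}

#' Per-abundance-bin species detection probability
#'
#' The probability that a truly present species is detected, as a function of
#' its expected relative abundance: every (replicate, expected species) pair
#' is an instance, binned by the species' profile abundance; the per-bin
#' probability is detected instances over instances. Replicates are pooled by
#' default; `per_replicate = TRUE` instead returns one probability per
#' replicate and bin.
#'
#' @param reps List of replicates, each either a [species_sets()] tibble (all
#'   groups pooled — detection is "any taxonomic group") or a list with
#'   elements `expected` and `classified` (taxid vectors).
#' @param profile Community profile supplying each species' expected
#'   abundance; every expected species must be present.
#' @param bins Bin table as from [abundance_bins()].
#' @param per_replicate Return per-replicate probabilities instead of pooling.
#' @return Tibble with columns `label`, `lower`, `upper`, `n_expected`,
#'   `n_detected`, `probability` (plus `replicate` when `per_replicate`),
#'   ordered from most to least abundant bin; unoccupied bins have
#'   `probability = NA`.
#' @export
detection_probability <- function(reps, profile, bins = abundance_bins(),
                                  per_replicate = FALSE) {
  if (!is.list(reps) || length(reps) == 0L) abort("`reps` must be a non-empty list.")
  inst <- purrr::imap_dfr(reps, function(rep, i) {
    if (is.data.frame(rep)) {
      expected <- unlist(rep$expected, use.names = FALSE)
      classified <- unlist(rep$classified, use.names = FALSE)
    } else {
      expected <- rep$expected
      classified <- rep$classified
    }
    tibble::tibble(
      replicate = i,
      taxid = as.integer(expected),
      detected = expected %in% classified
    )
  })
  ab <- profile$expected_abundance[match(inst$taxid, profile$taxid)]
  if (anyNA(ab)) {
    missing_sp <- unique(inst$taxid[is.na(ab)])
    abort(sprintf(
      "Consistency error: expected species absent from profile: %s.",
      paste(utils::head(missing_sp, 5L), collapse = ", ")
    ))
  }
  bin_of <- vapply(ab, function(a) {
    which(a > bins$lower & a <= bins$upper)[1L]
  }, integer(1L))
  inst$bin <- bin_of

  group_vars <- if (per_replicate) c("replicate", "bin") else "bin"
  counts <- inst |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_vars))) |>
    dplyr::summarise(
      n_expected = dplyr::n(),
      n_detected = sum(.data$detected),
      .groups = "drop"
    )
  scaffold <- if (per_replicate) {
    tidyr::expand_grid(replicate = unique(inst$replicate), bin = seq_len(nrow(bins)))
  } else {
    tibble::tibble(bin = seq_len(nrow(bins)))
  }
  scaffold |>
    dplyr::left_join(counts, by = group_vars) |>
    dplyr::mutate(
      label = bins$label[.data$bin],
      lower = bins$lower[.data$bin],
      upper = bins$upper[.data$bin],
      n_expected = dplyr::coalesce(.data$n_expected, 0L),
      n_detected = dplyr::coalesce(.data$n_detected, 0L),
      probability = ifelse(
        .data$n_expected > 0L,
        .data$n_detected / .data$n_expected, NA_real_
      )
    ) |>
    dplyr::select(-"bin") |>
    dplyr::relocate("label", "lower", "upper")
}

#' Trend of a metric across sequencing depths
#'
#' Ordinary least-squares regression of precision (or any metric column) on
#' `log10(depth)`, the scale on which depth series spanning orders of
#' magnitude are naturally compared. Returns the slope, the coefficient of
#' determination and the t-test p-value for the slope. A constant response is
#' reported as slope 0, `r_squared` 0, p 1.
#'
#' @param results Tibble with columns `depth` and the metric (default
#'   `precision`); rows with `NA` metric are dropped. At least 3 distinct
#'   depths are required.
#' @param metric Name of the metric column (default `"precision"`).
#' @return One-row tibble: `slope`, `r_squared`, `p_value`, `n`.
#' @export
depth_trend <- function(results, metric = "precision") {
  results <- tibble::as_tibble(results)
  if (!all(c("depth", metric) %in% names(results))) {
    abort(sprintf("`results` needs columns `depth` and `%s`.", metric))
  }
  y <- results[[metric]]
  keep <- !is.na(y) & !is.na(results$depth)
  y <- y[keep]
  x <- log10(results$depth[keep])
  if (dplyr::n_distinct(x) < 3L) abort("Need at least 3 distinct depths.")
  if (stats::var(y) == 0) {
    return(tibble::tibble(slope = 0, r_squared = 0, p_value = 1, n = length(y)))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2L]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2L, 4L],
    n = length(y)
  )
}

#' Summarise metrics over replicates
#'
#' Mean and standard deviation of recall and precision per group (and any
#' further grouping columns, e.g. classifier or recipe), the standard summary
#' layout for benchmark tables. `NA` metrics (undefined precision) are
#' excluded from the means rather than counted as zero.
#'
#' @param results Row-per-replicate metric tibble from [evaluate_run()]
#'   (possibly row-bound over conditions).
#' @param ... Additional grouping columns (tidy-select), besides `group`.
#' @return Tibble of means and standard deviations per group (and conditions).
#' @export
summarise_eval <- function(results, ...) {
  results |>
    dplyr::group_by(.data$group, ...) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      recall_mean = mean(.data$recall, na.rm = TRUE),
      recall_sd = stats::sd(.data$recall, na.rm = TRUE),
      precision_mean = mean(.data$precision, na.rm = TRUE),
      precision_sd = stats::sd(.data$precision, na.rm = TRUE),
      .groups = "drop"
    )
}
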