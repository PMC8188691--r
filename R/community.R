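#' Power-law rank-abundance model
#'
#' Expected (unnormalised) relative abundance of the species at a given rank
#' within its taxonomic group, under the exponential-decay model
#' `abundance = (scale * rank)^(-exponent)`. With the defaults
#' (`scale = 1.5`, `exponent = 2`) the most abundant species gets 4/9 and
#' abundance falls four-fold with every doubling of rank — the decay shape
#' observed in fecal metagenome profiles.
#'
#' @param rank Positive integer rank(s), 1 = most abundant.
#' @param scale Positive scale parameter (default 1.5).
#' @param exponent Positive decay exponent (default 2).
#' @return Numeric vector of unnormalised abundances, strictly decreasing in
#'   rank.
#' @export
#' @examples
#' model_abundance(1:5)
model_abundance <- function(rank, scale = 1.5, exponent = 2) {
  if (length(rank) == 0L || anyNA(rank) || any(rank < 1) || any(rank != trunc(rank))) {
    abort("`rank` must contain positive integers.")
  }
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0) {
    abort("`scale` must be a single positive number.")
  }
  if (!is.numeric(exponent) || length(exponent) != 1L || is.na(exponent) || exponent <= 0) {
    abort("`exponent` must be a single positive number.")
  }
  (scale * rank)^(-exponent)
}

#' Default community composition weights
#'
#' Fraction of reads attributed to each taxonomic group in the simulated
#' community: bacteria-dominant with small viral and eukaryotic fractions, as
#' in a typical fecal metagenome.
#'
#' @return Named numeric vector over bacteria / virus / eukaryote, summing to 1.
#' @export
default_group_weights <- function() {
  c(bacteria = 0.97, virus = 0.02, eukaryote = 0.01)
}

#' Build an expected rank-abundance community profile
#'
#' Assigns each species an expected relative abundance: within each group,
#' abundances follow [model_abundance()] over ranks 1..n (ranks restart at 1
#' per group, so each group carries the same decay shape), normalised so the
#' group sums to its weight; weights are renormalised over the groups actually
#' present, and the whole profile sums to 1.
#'
#' @param species_by_group Named list mapping group (`bacteria`, `virus`,
#'   `eukaryote`) to an ordered vector of species taxids; list order within a
#'   group defines rank.
#' @param group_weights Named positive weights for the groups present
#'   (default [default_group_weights()]).
#' @param scale,exponent Decay-model parameters, see [model_abundance()].
#' @return A tibble with columns `taxid`, `group`, `rank`,
#'   `expected_abundance`, one row per species, groups in canonical order
#'   (bacteria, virus, eukaryote).
#' @export
#' @examples
#' build_profile(list(bacteria = c(11L, 12L)), c(bacteria = 1))
build_profile <- function(species_by_group,
                          group_weights = default_group_weights(),
                          scale = 1.5, exponent = 2) {
  if (!is.list(species_by_group) || is.null(names(species_by_group))) {
    abort("`species_by_group` must be a named list of taxid vectors.")
  }
  species_by_group <- species_by_group[lengths(species_by_group) > 0L]
  if (length(species_by_group) == 0L) abort("No species supplied.")
  check_groups(names(species_by_group), "species_by_group name")
  all_tax <- unlist(species_by_group, use.names = FALSE)
  if (anyDuplicated(all_tax)) {
    dup <- unique(all_tax[duplicated(all_tax)])
    abort(sprintf(
      "Taxid(s) present in more than one group (or duplicated): %s.",
      paste(utils::head(dup, 5L), collapse = ", ")
    ))
  }

  present <- intersect(GROUP_LEVELS, names(species_by_group))
  w <- group_weights[present]
  if (anyNA(w) || any(w <= 0)) {
    abort("`group_weights` must supply a positive weight for every present group.")
  }
  w <- w / sum(w)

  purrr::map_dfr(present, function(g) {
    taxids <- as.integer(species_by_group[[g]])
    r <- seq_along(taxids)
    a <- model_abundance(r, scale = scale, exponent = exponent)
    tibble::tibble(
      taxid = taxids,
      group = g,
      rank = r,
      expected_abundance = w[[g]] * a / sum(a)
    )
  })
}

#' Write / read a community profile TSV
#'
#' Columns `taxid`, `group`, `rank`, `expected_abundance`.
#'
#' @param profile A profile tibble from [build_profile()].
#' @param path File path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()` returns
#'   the profile tibble.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(profile, path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    taxid = readr::col_integer(),
    group = readr::col_character(),
    rank = readr::col_integer(),
    expected_abundance = readr::col_double()
  ))
}

#' Read an observed rank-abundance table
#'
#' Two columns, rank then relative abundance, TSV or CSV (delimiter sniffed
#' from the first line). Header optional: a non-numeric first line is treated
#' as a header. Suitable as input to [fit_decay_model()].
#'
#' @param path File path.
#' @return Tibble with columns `rank`, `abundance`.
#' @export
read_observed_abundance <- function(path) {
  first <- readr::read_lines(path, n_max = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, delim)[[1L]][1L])))
  tab <- readr::read_delim(
    path, delim = delim,
    col_names = if (has_header) TRUE else c("rank", "abundance"),
    skip = 0L, col_types = readr::cols(.default = readr::col_double())
  )
  if (ncol(tab) < 2L) abort(sprintf("Expected two columns in %s.", path))
  tibble::tibble(rank = as.integer(tab[[1L]]), abundance = as.double(tab[[2L]]))
}

#' Fit the power-law decay model to observed rank abundances
#'
#' Least-squares fit of `log(abundance) = -exponent * log(scale * rank)` by
#' ordinary linear regression of log-abundance on log-rank: the slope estimates
#' `-exponent` and the intercept `-exponent * log(scale)`. `r_squared` is the
#' coefficient of determination of that regression in log--log space (the
#' package's declared convention for this fit).
#'
#' @param observed A data frame whose first two columns are rank and relative
#'   abundance (columns named `rank` and `abundance` are used when present).
#'   At least 3 points; abundances must be positive.
#' @return A `decay_fit` object with elements `scale`, `exponent`,
#'   `r_squared`, `n`, the underlying `lm` fit, and the data.
#' @seealso [model_abundance()], [tidy.decay_fit()], [autoplot.decay_fit()]
#' @export
#' @examples
#' obs <- data.frame(rank = 1:50, abundance = model_abundance(1:50))
#' fit_decay_model(obs)
fit_decay_model <- function(observed) {
  observed <- as.data.frame(observed)
  if (all(c("rank", "abundance") %in% names(observed))) {
    rank <- observed$rank
    abundance <- observed$abundance
  } else {
    rank <- observed[[1L]]
    abundance <- observed[[2L]]
  }
  keep <- !is.na(rank) & !is.na(abundance)
  rank <- rank[keep]
  abundance <- abundance[keep]
  if (length(rank) < 3L) abort("Need at least 3 observed (rank, abundance) points.")
  if (any(abundance <= 0)) abort("Abundances must be positive.")
  if (any(rank < 1)) abort("Ranks must be >= 1.")

  dat <- data.frame(log_rank = log(rank), log_ab = log(abundance))
  fit <- stats::lm(log_ab ~ log_rank, data = dat)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope >= 0) {
    warn("Fitted slope is non-negative; abundances do not decay with rank.")
  }
  exponent <- -slope
  scale <- exp(intercept / slope)
  structure(
    list(
      scale = scale,
      exponent = exponent,
      r_squared = summary(fit)$r.squared,
      n = length(rank),
      fit = fit,
      data = tibble::tibble(rank = rank, abundance = abundance)
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> abundance = (%.4g * rank)^-%.4g   R^2 = %.4f   (n = %d, log-log OLS)\n",
    x$scale, x$exponent, x$r_squared, x$n
  ))
  invisible(x)
}

#' Tidy a decay-model fit
#'
#' @param x A `decay_fit` from [fit_decay_model()].
#' @param ... Unused.
#' @return For `tidy()`, one row per parameter (`scale`, `exponent`); for
#'   `glance()`, a one-row model summary.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("scale", "exponent"),
    estimate = c(x$scale, x$exponent)
  )
}

#' @rdname tidy.decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    scale = x$scale,
    exponent = x$exponent,
    r.squared = x$r_squared,
    nobs = x$n
  )
}

#' Predicted abundances from a decay fit
#'
#' @param object A `decay_fit`.
#' @param newdata Optional data frame with a `rank` column; defaults to the
#'   fitted data.
#' @param ... Unused.
#' @return Numeric vector of predicted relative abundances.
#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  rank <- if (is.null(newdata)) object$data$rank else newdata$rank
  model_abundance(rank, scale = object$scale, exponent = object$exponent)
}
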