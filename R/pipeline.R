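#' Orders of sequential classification
#'
#' The seven canonical analysis orders for classifying reads against the three
#' taxonomic-group databases: labels `a`--`f` are the six permutations of
#' bacteria / viruses / eukaryotes applied sequentially (reads classified at
#' an earlier step are removed before the next), and `g` is the unordered mode
#' (every group classifies the full read set independently).
#'
#' @param label One of `"a"`--`"g"`, or an `order_recipe` to pass through.
#' @return An `order_recipe` with elements `label` and `sequence` (an ordered
#'   character vector over the groups; empty for `g`).
#' @export
#' @examples
#' order_recipe("d")  # bacteria > viruses > eukaryotes
order_recipe <- function(label) {
  if (inherits(label, "order_recipe")) return(label)
  recipes <- list(
    a = c("virus", "bacteria", "eukaryote"),
    b = c("virus", "eukaryote", "bacteria"),
    c = c("bacteria", "eukaryote", "virus"),
    d = c("bacteria", "virus", "eukaryote"),
    e = c("eukaryote", "bacteria", "virus"),
    f = c("eukaryote", "virus", "bacteria"),
    g = character(0)
  )
  if (!is.character(label) || length(label) != 1L || !label %in% names(recipes)) {
    abort("`label` must be one of \"a\"..\"g\".")
  }
  structure(
    list(label = label, sequence = recipes[[label]]),
    class = "order_recipe"
  )
}

#' @export
print.order_recipe <- function(x, ...) {
  seq_txt <- if (length(x$sequence) == 0L) "unordered" else paste(x$sequence, collapse = " > ")
  cat(sprintf("<order_recipe %s> %s\n", x$label, seq_txt))
  invisible(x)
}

#' Run ordered (or unordered) sequential classification
#'
#' Applies one classifier per taxonomic group to a read set. In an ordered run
#' (recipes `a`--`f`) the groups are classified sequentially and reads
#' classified at each step are excluded from the input to the next, so no read
#' can be claimed by two groups. In the unordered run (`g`) every group's
#' classifier sees the full read set, and a read may be claimed by several
#' groups — the mechanism by which cross-group contamination inflates
#' false-positive species.
#'
#' @param reads A [read_set()].
#' @param classifiers Named list mapping each group to a callable
#'   `function(read_set) -> classification_result`. Built-in k-mer classifiers
#'   (see [classify_kmer()]) and replayed external assignment tables both fit
#'   the contract.
#' @param recipe A recipe label `"a"`--`"g"` or an [order_recipe()].
#' @return A `pipeline_run` with elements `results` (named list of
#'   [classification_result()] per group), `steps` (the step log: `step`,
#'   `group`, `n_input`, `n_classified`, `n_carried_forward`), `recipe` and
#'   `n_initial`.
#' @export
run_ordered <- function(reads, classifiers, recipe) {
  stopifnot(inherits(reads, "read_set"))
  recipe <- order_recipe(recipe)
  needed <- if (length(recipe$sequence) > 0L) recipe$sequence else GROUP_LEVELS
  missing_cls <- setdiff(needed, names(classifiers))
  if (length(missing_cls) > 0L) {
    abort(sprintf(
      "Configuration error: no classifier for group(s): %s.",
      paste(missing_cls, collapse = ", ")
    ))
  }

  results <- list()
  steps <- list()
  if (length(recipe$sequence) > 0L) {
    current <- reads
    for (i in seq_along(recipe$sequence)) {
      g <- recipe$sequence[[i]]
      res <- classifiers[[g]](current)
      stopifnot(inherits(res, "classification_result"))
      results[[g]] <- res
      steps[[i]] <- tibble::tibble(
        step = i, group = g,
        n_input = nrow(current$reads),
        n_classified = res$n_classified,
        n_carried_forward = res$n_unclassified
      )
      current <- extract_unclassified(current, res)
    }
  } else {
    for (i in seq_along(needed)) {
      g <- needed[[i]]
      res <- classifiers[[g]](reads)
      stopifnot(inherits(res, "classification_result"))
      results[[g]] <- res
      steps[[i]] <- tibble::tibble(
        step = i, group = g,
        n_input = nrow(reads$reads),
        n_classified = res$n_classified,
        n_carried_forward = res$n_unclassified
      )
    }
  }
  structure(
    list(
      results = results,
      steps = dplyr::bind_rows(steps),
      recipe = recipe,
      n_initial = nrow(reads$reads)
    ),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf(
    "<pipeline_run> recipe %s over %d reads\n", x$recipe$label, x$n_initial
  ))
  print(x$steps)
  invisible(x)
}

#' Extract unclassified reads
#'
#' Builds the next step's input for an ordered run: the reads of `reads` not
#' classified by `result`, with the truth table filtered to match. The input
#' read set is untouched.
#'
#' @param reads A [read_set()].
#' @param result A [classification_result()] covering a subset of `reads`.
#' @return A [read_set()] containing exactly the unclassified read records.
#' @export
extract_unclassified <- function(reads, result) {
  stopifnot(inherits(reads, "read_set"), inherits(result, "classification_result"))
  stray <- setdiff(result$assignments$read_id, reads$reads$read_id)
  if (length(stray) > 0L) {
    abort(sprintf(
      "Consistency error: result references read id(s) absent from the read set: %s.",
      paste(utils::head(stray, 5L), collapse = ", ")
    ))
  }
  keep <- !(reads$reads$read_id %in% classified_ids(result))
  read_set(
    reads = reads$reads[keep, ],
    truth = reads$truth[reads$truth$read_id %in% reads$reads$read_id[keep], ],
    params = reads$params
  )
}
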