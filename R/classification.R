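#' Classification results
#'
#' A `classification_result` holds one classification step's per-read
#' assignments — a tibble (`read_id`, `taxid`) with `NA` for unclassified
#' reads — together with the species-level count table derived from them:
#' every assigned taxid is projected to species rank with
#' [project_to_rank()], and assignments above species (`NA` projection) count
#' as unclassified at species level.
#'
#' @param assignments Tibble with columns `read_id`, `taxid` (`NA` =
#'   unclassified).
#' @param tree A [taxonomy_tree()] used for the species projection.
#' @return A `classification_result` with elements `assignments`,
#'   `counts_at_species` (tibble `taxid`, `count`), `n_classified`,
#'   `n_unclassified`.
#' @export
classification_result <- function(assignments, tree) {
  assignments <- tibble::as_tibble(assignments)
  stopifnot(all(c("read_id", "taxid") %in% names(assignments)))
  if (anyDuplicated(assignments$read_id)) {
    abort("One assignment per read: duplicated read_id(s) found.")
  }
  assignments$taxid <- as.integer(assignments$taxid)

  assigned <- unique(assignments$taxid[!is.na(assignments$taxid)])
  species_of <- if (length(assigned) > 0L) {
    stats::setNames(project_to_rank(tree, assigned, "species"), assigned)
  } else {
    integer(0)
  }
  sp <- species_of[as.character(assignments$taxid)]
  counts <- tibble::tibble(taxid = as.integer(sp[!is.na(sp)])) |>
    dplyr::count(.data$taxid, name = "count") |>
    dplyr::arrange(.data$taxid)

  structure(
    list(
      assignments = assignments,
      counts_at_species = counts,
      n_classified = sum(!is.na(assignments$taxid)),
      n_unclassified = sum(is.na(assignments$taxid))
    ),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result> %d reads: %d classified, %d unclassified; %d species in count table\n",
    nrow(x$assignments), x$n_classified, x$n_unclassified, nrow(x$counts_at_species)
  ))
  invisible(x)
}

#' Read-id partitions of a classification result
#'
#' @param result A [classification_result()].
#' @return Character vector of read ids.
#' @export
classified_ids <- function(result) {
  stopifnot(inherits(result, "classification_result"))
  result$assignments$read_id[!is.na(result$assignments$taxid)]
}

#' @rdname classified_ids
#' @export
unclassified_ids <- function(result) {
  stopifnot(inherits(result, "classification_result"))
  result$assignments$read_id[is.na(result$assignments$taxid)]
}

#' Parse BLAST-tabular (b6) alignments
#'
#' Reads 12-column BLAST tabular output (query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' e-value, bit score), keeping the columns the LCA counter needs and
#' preserving file order within each read.
#'
#' @param path Path to a b6 file; an empty file yields an empty tibble.
#' @return Tibble with columns `read_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `bit_score`.
#' @export
parse_b6 <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      read_id = character(0), subject_id = character(0),
      percent_identity = double(0), alignment_length = integer(0),
      bit_score = double(0)
    ))
  }
  parts <- stringi::stri_split_fixed(lines, "\t")
  nf <- lengths(parts)
  bad <- which(nf != 12L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Parse error in %s at line %d: expected 12 tab-separated columns, found %d.",
      path, bad[1L], nf[bad[1L]]
    ))
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  tibble::tibble(
    read_id = m[, 1L],
    subject_id = m[, 2L],
    percent_identity = as.double(m[, 3L]),
    alignment_length = as.integer(m[, 4L]),
    bit_score = as.double(m[, 12L])
  )
}

#' Write hits as 12-column b6
#'
#' Inverse of [parse_b6()] for the columns it retains; the remaining BLAST
#' columns are filled with consistent placeholders.
#'
#' @param hits Tibble as returned by [parse_b6()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_b6 <- function(hits, path) {
  n <- nrow(hits)
  lines <- sprintf(
    "%s\t%s\t%.2f\t%d\t0\t0\t1\t%d\t1\t%d\t1e-10\t%.1f",
    hits$read_id, hits$subject_id, hits$percent_identity,
    hits$alignment_length, hits$alignment_length, hits$alignment_length,
    hits$bit_score
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read / write a subject-to-taxid map
#'
#' Two-column TSV (`subject_id`, `taxid`) linking alignment subject ids to
#' taxonomy nodes; an explicit map is used rather than parsing FASTA headers
#' because header conventions vary between databases.
#'
#' @param path File path.
#' @param map Named integer vector or two-column data frame (writer).
#' @return Named integer vector keyed by subject id (reader).
#' @export
read_subject_map <- function(path) {
  tab <- suppressWarnings(readr::read_tsv(path, col_names = c("subject_id", "taxid"),
                         col_types = readr::cols(
                           subject_id = readr::col_character(),
                           taxid = readr::col_integer()
                         )))
  probs <- readr::problems(tab)
  if (nrow(probs) > 0L || anyNA(tab$taxid)) {
    abort(sprintf("Parse error in %s: non-integer taxid.", path))
  }
  stats::setNames(tab$taxid, tab$subject_id)
}

#' @rdname read_subject_map
#' @export
write_subject_map <- function(map, path) {
  if (is.data.frame(map)) map <- stats::setNames(as.integer(map[[2L]]), map[[1L]])
  readr::write_tsv(
    tibble::tibble(subject_id = names(map), taxid = as.integer(map)),
    path, col_names = FALSE
  )
  invisible(path)
}

#' LCA counting over b6 alignment output
#'
#' The post-processing an all-hits aligner needs to become a classifier: for
#' each read, retain hits whose bit score is within `top_margin` of the read's
#' best bit score, map their subjects to taxids, and assign the read the
#' lowest common ancestor of the retained taxids. Reads in `read_ids` with no
#' hits are unclassified. Species-level counts come from projecting each
#' assignment to species rank; assignments resolved above species contribute
#' nothing to the species count table.
#'
#' @param hits Tibble from [parse_b6()].
#' @param tree A [taxonomy_tree()].
#' @param subject_map Named taxid vector keyed by subject id (see
#'   [read_subject_map()]).
#' @param top_margin Retain hits with `bit_score >= (1 - top_margin) * max`
#'   per read (default 0.01).
#' @param read_ids Optional character vector of all read ids in the step;
#'   defaults to the reads present in `hits`.
#' @return A [classification_result()].
#' @export
lca_count <- function(hits, tree, subject_map, top_margin = 0.01,
                      read_ids = NULL) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (!is.numeric(top_margin) || top_margin < 0 || top_margin >= 1) {
    abort("`top_margin` must be in [0, 1).")
  }
  unknown <- setdiff(unique(hits$subject_id), names(subject_map))
  if (length(unknown) > 0L) {
    abort(sprintf(
      "Subject id(s) not in subject map: %s.",
      paste(utils::head(unknown, 5L), collapse = ", ")
    ))
  }

  assigned <- if (nrow(hits) > 0L) {
    hits |>
      dplyr::mutate(taxid = unname(subject_map[.data$subject_id])) |>
      dplyr::group_by(.data$read_id) |>
      dplyr::filter(.data$bit_score >= (1 - top_margin) * max(.data$bit_score)) |>
      dplyr::summarise(
        taxid = lca(tree, unique(.data$taxid)),
        .groups = "drop"
      )
  } else {
    tibble::tibble(read_id = character(0), taxid = integer(0))
  }

  read_ids <- read_ids %||% unique(hits$read_id)
  no_hit <- setdiff(read_ids, assigned$read_id)
  assignments <- dplyr::bind_rows(
    assigned,
    tibble::tibble(read_id = no_hit, taxid = NA_integer_)
  )
  classification_result(assignments, tree)
}

#' Read / write a per-read assignment table
#'
#' Two-column TSV (`read_id`, `taxid`) with taxid 0 meaning unclassified —
#' the adapter format for replaying per-read output of external classifiers
#' through the pipeline.
#'
#' @param path File path.
#' @param tree A [taxonomy_tree()] (needed to derive species counts).
#' @param result A [classification_result()] (writer).
#' @return A [classification_result()] (reader); `path` invisibly (writer).
#' @export
read_assignment_table <- function(path, tree) {
  tab <- suppressWarnings(readr::read_tsv(path, col_names = c("read_id", "taxid"),
                         col_types = readr::cols(
                           read_id = readr::col_character(),
                           taxid = readr::col_integer()
                         )))
  probs <- readr::problems(tab)
  if (nrow(probs) > 0L || (nrow(tab) > 0L && anyNA(tab$taxid))) {
    bad_row <- if (nrow(probs) > 0L) probs$row[1L] else which(is.na(tab$taxid))[1L]
    abort(sprintf("Parse error in %s at line %d: non-integer taxid.", path, bad_row))
  }
  tab$taxid[tab$taxid == 0L] <- NA_integer_
  classification_result(tab, tree)
}

#' @rdname read_assignment_table
#' @export
write_assignment_table <- function(result, path) {
  stopifnot(inherits(result, "classification_result"))
  out <- result$assignments
  out$taxid[is.na(out$taxid)] <- 0L
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write a species-level count table
#'
#' Columns `taxid`, `name`, `count`.
#'
#' @param result A [classification_result()].
#' @param tree A [taxonomy_tree()] (source of scientific names).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_counts <- function(result, tree, path) {
  stopifnot(inherits(result, "classification_result"))
  counts <- result$counts_at_species
  counts$name <- tree$nodes$name[tax_index(tree, counts$taxid)]
  readr::write_tsv(counts[, c("taxid", "name", "count")], path)
  invisible(path)
}

#' Build an exact canonical k-mer index
#'
#' Maps every canonical k-mer (lexicographic minimum of a k-mer and its
#' reverse complement) of the genome set to the species containing it. This
#' backs the built-in test classifier; it is a deliberately simple exact-match
#' scheme, not a reimplementation of any production k-mer classifier.
#'
#' @param genomes A [genome_set()].
#' @param k Odd k-mer size, 11--31 (default 31; capped at 31 so a k-mer packs
#'   into one 64-bit word).
#' @return A `kmer_index` object.
#' @export
build_kmer_index <- function(genomes, k = 31) {
  stopifnot(inherits(genomes, "genome_set"))
  if (!is_count(k) || k %% 2L == 0L || k < 11L || k > 31L) {
    abort("`k` must be an odd integer between 11 and 31.")
  }
  k <- as.integer(k)
  kept <- genomes$length >= k
  if (!any(kept)) abort("No sequence of length >= k to index.")
  ptr <- .kmer_index_build(genomes$seq[kept], genomes$taxid[kept], k)
  structure(
    list(
      ptr = ptr,
      k = k,
      n_kmers = .kmer_index_size(ptr),
      taxids = sort(unique(genomes$taxid[kept]))
    ),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf(
    "<kmer_index> k = %d, %.0f canonical k-mers over %d species\n",
    x$k, x$n_kmers, length(x$taxids)
  ))
  invisible(x)
}

#' Look up k-mers in an index
#'
#' Queries are canonicalised before lookup, so a k-mer and its reverse
#' complement return the same posting set.
#'
#' @param index A `kmer_index`.
#' @param kmers Character vector of k-mers of length `k`.
#' @return List of sorted integer taxid vectors (empty when absent).
#' @export
kmer_index_lookup <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  .kmer_index_lookup(index$ptr, toupper(kmers))
}

#' Build one k-mer classifier callable per taxonomic group
#'
#' Splits the genome set by group, indexes each subset separately (one
#' "database" per group, as classifier benchmarks are set up), and returns a
#' named list of callables `function(read_set) -> classification_result`
#' satisfying the [run_ordered()] classifier contract.
#'
#' @param genomes A [genome_set()].
#' @param tree A [taxonomy_tree()].
#' @param k K-mer size passed to [build_kmer_index()].
#' @param min_hits Passed to [classify_kmer()].
#' @return Named list of classifier functions, one per group present.
#' @export
group_classifiers <- function(genomes, tree, k = 31, min_hits = 1) {
  groups <- unique(genomes$group)
  out <- lapply(groups, function(g) {
    idx <- build_kmer_index(
      genome_set(tibble::as_tibble(genomes)[genomes$group == g, ]), k = k
    )
    function(reads) classify_kmer(reads, idx, tree, min_hits = min_hits)
  })
  stats::setNames(out, groups)
}

#' Classify reads with the built-in exact k-mer classifier
#'
#' Kraken-style voting at fixture scale: each read's canonical k-mers are
#' looked up in the index, species accumulate one vote per matching k-mer they
#' appear in, and the read is assigned the top-voted species — or, when
#' several species tie for the top vote, the LCA of the tied species. Reads
#' with fewer than `min_hits` matching k-mers (including reads shorter than
#' `k`, which are flagged with a warning) are unclassified.
#'
#' @param reads A [read_set()].
#' @param index A `kmer_index` from [build_kmer_index()].
#' @param tree A [taxonomy_tree()].
#' @param min_hits Minimum number of matching k-mers to classify (default 1;
#'   `Inf` classifies nothing).
#' @return A [classification_result()].
#' @export
classify_kmer <- function(reads, index, tree, min_hits = 1) {
  stopifnot(inherits(reads, "read_set"), inherits(index, "kmer_index"))
  short <- nchar(reads$reads$seq) < index$k
  if (any(short)) {
    warn(sprintf("%d read(s) shorter than k = %d left unclassified.", sum(short), index$k))
  }
  mh <- if (is.infinite(min_hits)) .Machine$integer.max else as.integer(min_hits)
  res <- .kmer_classify(index$ptr, reads$reads$seq, mh)
  top <- res$top
  taxid <- vapply(top, function(t) {
    if (length(t) == 0L) NA_integer_ else if (length(t) == 1L) t else NA_integer_
  }, integer(1L))
  ties <- which(lengths(top) > 1L)
  if (length(ties) > 0L) {
    # LCA per distinct tied species set, not per read
    key <- vapply(top[ties], paste, character(1L), collapse = ",")
    uniq <- !duplicated(key)
    lca_of <- vapply(top[ties][uniq], function(t) lca(tree, t), integer(1L))
    names(lca_of) <- key[uniq]
    taxid[ties] <- lca_of[key]
  }
  classification_result(
    tibble::tibble(read_id = reads$reads$read_id, taxid = taxid),
    tree
  )
}
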