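#' Taxonomy trees
#'
#' A `taxonomy_tree` holds an NCBI-style taxonomy: a set of nodes, each with an
#' integer taxid, a parent taxid, a rank string (lower case; `"no rank"` where
#' the taxonomy does not assign one) and a scientific name. The root is its own
#' parent. The tree answers lineage, lowest-common-ancestor (LCA) and
#' rank-projection queries, which is all a read classifier needs to resolve
#' ambiguous multi-hit assignments and to count reads at a fixed rank.
#'
#' @param nodes A data frame with columns `taxid`, `parent_taxid`, `rank`,
#'   `name`.
#' @return An object of class `taxonomy_tree` with elements `nodes` (a tibble),
#'   `root_taxid`, and internal index vectors.
#' @export
taxonomy_tree <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  required <- c("taxid", "parent_taxid", "rank", "name")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`nodes` lacks column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(nodes) < 1L) abort("A taxonomy tree needs at least one node.")
  nodes$taxid <- as.integer(nodes$taxid)
  nodes$parent_taxid <- as.integer(nodes$parent_taxid)
  nodes$rank <- tolower(as.character(nodes$rank))
  nodes$name <- as.character(nodes$name)
  if (anyNA(nodes$taxid) || any(nodes$taxid < 1L)) {
    abort("Taxids must be positive integers.")
  }
  if (anyDuplicated(nodes$taxid)) {
    dup <- unique(nodes$taxid[duplicated(nodes$taxid)])
    abort(sprintf("Duplicated taxid(s): %s.", paste(utils::head(dup, 5L), collapse = ", ")))
  }

  root <- nodes$taxid[nodes$taxid == nodes$parent_taxid]
  if (length(root) != 1L) {
    abort(sprintf(
      "Structural error: expected exactly one root (node with parent == self), found %d.",
      length(root)
    ))
  }

  parent_idx <- match(nodes$parent_taxid, nodes$taxid)
  if (anyNA(parent_idx)) {
    orphan <- nodes$taxid[is.na(parent_idx)]
    abort(sprintf(
      "Structural error: parent taxid(s) absent from node set for node(s): %s.",
      paste(utils::head(orphan, 5L), collapse = ", ")
    ))
  }

  # Depth assignment by sweeping from the root; nodes never reached lie on a
  # cycle (or under one), which the NCBI dialect forbids.
  n <- nrow(nodes)
  depth <- rep(NA_integer_, n)
  depth[match(root, nodes$taxid)] <- 0L
  repeat {
    reachable <- is.na(depth) & !is.na(depth[parent_idx])
    if (!any(reachable)) break
    depth[reachable] <- depth[parent_idx[reachable]] + 1L
  }
  if (anyNA(depth)) {
    bad <- nodes$taxid[is.na(depth)]
    abort(sprintf(
      "Structural error: cycle detected (node(s) not reachable from root): %s.",
      paste(utils::head(bad, 5L), collapse = ", ")
    ))
  }

  structure(
    list(
      nodes = nodes,
      root_taxid = root,
      parent_idx = parent_idx,
      depth = depth
    ),
    class = "taxonomy_tree"
  )
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf(
    "<taxonomy_tree> %d nodes, root taxid %d, max depth %d\n",
    nrow(x$nodes), x$root_taxid, max(x$depth)
  ))
  ranks <- sort(table(x$nodes$rank), decreasing = TRUE)
  cat("  ranks:", paste(sprintf("%s (%d)", names(ranks), ranks), collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.taxonomy_tree <- function(x, ...) {
  sprintf("<taxonomy_tree: %d nodes>", nrow(x$nodes))
}

tax_index <- function(tree, taxids, arg = "taxid") {
  idx <- match(as.integer(taxids), tree$nodes$taxid)
  if (anyNA(idx)) {
    unknown <- unique(taxids[is.na(idx)])
    abort(sprintf(
      "Unknown %s(s): %s.", arg,
      paste(utils::head(unknown, 5L), collapse = ", ")
    ))
  }
  idx
}

#' Load a taxonomy from NCBI dump files or a fixture TSV
#'
#' Reads either the NCBI taxonomy dump dialect (`nodes.dmp` / `names.dmp`,
#' fields separated by `"\t|\t"` and lines terminated by `"\t|"`) or, when the
#' file contains no pipe delimiters, a headered four-column fixture TSV
#' (`taxid`, `parent_taxid`, `rank`, `name`) as written by [write_taxonomy()].
#' Only `"scientific name"` entries of the names file are used; when
#' `names_path` is `NULL` names default to `"taxid:<n>"`.
#'
#' @param nodes_path Path to `nodes.dmp` or a fixture TSV.
#' @param names_path Optional path to `names.dmp` (ignored for fixture TSVs,
#'   which carry names inline).
#' @return A [taxonomy_tree()].
#' @export
load_taxonomy <- function(nodes_path, names_path = NULL) {
  if (!file.exists(nodes_path)) abort(sprintf("File not found: %s", nodes_path))
  first <- readr::read_lines(nodes_path, n_max = 1L)
  if (length(first) == 0L) abort(sprintf("Parse error in %s: file is empty.", nodes_path))

  if (grepl("|", first, fixed = TRUE)) {
    nodes <- parse_ncbi_dmp(nodes_path, min_fields = 3L)
    tab <- tibble::tibble(
      taxid = suppressWarnings(as.integer(nodes$fields[[1L]])),
      parent_taxid = suppressWarnings(as.integer(nodes$fields[[2L]])),
      rank = nodes$fields[[3L]]
    )
    bad <- which(is.na(tab$taxid) | is.na(tab$parent_taxid))
    if (length(bad) > 0L) {
      abort(sprintf(
        "Parse error in %s at line %d: non-integer taxid.",
        nodes_path, nodes$line[bad[1L]]
      ))
    }
    tab$name <- sprintf("taxid:%d", tab$taxid)
    if (!is.null(names_path)) {
      nm <- parse_ncbi_dmp(names_path, min_fields = 4L)
      sci <- nm$fields[[4L]] == "scientific name"
      name_tax <- suppressWarnings(as.integer(nm$fields[[1L]][sci]))
      hit <- match(tab$taxid, name_tax)
      tab$name[!is.na(hit)] <- nm$fields[[2L]][sci][hit[!is.na(hit)]]
    }
    taxonomy_tree(tab)
  } else {
    tab <- suppressWarnings(readr::read_tsv(
      nodes_path,
      col_types = readr::cols(
        taxid = readr::col_integer(),
        parent_taxid = readr::col_integer(),
        rank = readr::col_character(),
        name = readr::col_character()
      )
    ))
    probs <- readr::problems(tab)
    if (nrow(probs) > 0L) {
      abort(sprintf(
        "Parse error in %s at line %d: %s.",
        nodes_path, probs$row[1L] + 1L, probs$expected[1L]
      ))
    }
    taxonomy_tree(tab)
  }
}

# Split an NCBI .dmp file into its "\t|\t"-delimited fields; returns a list of
# per-column character vectors plus original line numbers for error messages.
parse_ncbi_dmp <- function(path, min_fields) {
  lines <- readr::read_lines(path)
  keep <- nzchar(lines)
  lines <- sub("\t\\|$", "", lines[keep])
  line_no <- which(keep)
  parts <- stringi::stri_split_fixed(lines, "\t|\t")
  nf <- lengths(parts)
  bad <- which(nf < min_fields)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Parse error in %s at line %d: expected >= %d pipe-delimited fields, found %d.",
      path, line_no[bad[1L]], min_fields, nf[bad[1L]]
    ))
  }
  fields <- lapply(seq_len(min_fields), function(i) {
    vapply(parts, `[[`, character(1L), i)
  })
  list(fields = fields, line = line_no)
}

#' Write a taxonomy as a fixture TSV
#'
#' Four headered columns (`taxid`, `parent_taxid`, `rank`, `name`);
#' [load_taxonomy()] reads the format back, and the round trip preserves the
#' parent and rank maps exactly.
#'
#' @param tree A [taxonomy_tree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tree, path) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  readr::write_tsv(tree$nodes, path)
  invisible(path)
}

#' Lineage of a taxon
#'
#' @param tree A [taxonomy_tree()].
#' @param taxid A single taxid present in the tree.
#' @return Integer vector of taxids from `taxid` (first) up to the root (last).
#' @export
lineage <- function(tree, taxid) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (length(taxid) != 1L) abort("`taxid` must be a single taxid.")
  i <- tax_index(tree, taxid)
  out <- integer(tree$depth[i] + 1L)
  for (d in seq_along(out)) {
    out[d] <- tree$nodes$taxid[i]
    i <- tree$parent_idx[i]
  }
  out
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node lying on the root-path of every member. A single taxid is
#' its own LCA; the result does not depend on input order.
#'
#' @param tree A [taxonomy_tree()].
#' @param taxids Non-empty vector of taxids present in the tree.
#' @return A single taxid.
#' @export
lca <- function(tree, taxids) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0L) abort("`taxids` must be non-empty.")
  idx <- tax_index(tree, taxids)
  if (length(idx) == 1L) return(tree$nodes$taxid[idx])
  # climb all members to a common depth, then step up in lockstep
  d <- tree$depth[idx]
  dmin <- min(d)
  for (j in seq_along(idx)) {
    while (tree$depth[idx[j]] > dmin) idx[j] <- tree$parent_idx[idx[j]]
  }
  idx <- unique(idx)
  while (length(idx) > 1L) {
    idx <- unique(tree$parent_idx[idx])
  }
  tree$nodes$taxid[idx]
}

#' Project taxa onto a fixed rank
#'
#' Walks each taxon's lineage towards the root and returns the first node whose
#' rank matches `rank` (the taxon itself when it already has that rank). When
#' no ancestor carries the rank — e.g. a genus-level assignment projected to
#' species — the result is `NA`, the "unranked" sentinel: downstream counting
#' treats such assignments as unclassified at the requested rank, which is how
#' above-species calls are scored in species-level benchmarking.
#'
#' @param tree A [taxonomy_tree()].
#' @param taxids Vector of taxids present in the tree.
#' @param rank Target rank string (default `"species"`).
#' @return Integer vector, same length as `taxids`; `NA` where the assignment
#'   lies above the requested rank.
#' @export
project_to_rank <- function(tree, taxids, rank = "species") {
  stopifnot(inherits(tree, "taxonomy_tree"))
  rank <- tolower(rank)
  idx <- tax_index(tree, taxids)
  out <- rep(NA_integer_, length(idx))
  active <- seq_along(idx)
  while (length(active) > 0L) {
    at_rank <- tree$nodes$rank[idx[active]] == rank
    out[active[at_rank]] <- tree$nodes$taxid[idx[active[at_rank]]]
    active <- active[!at_rank]
    if (length(active) == 0L) break
    at_root <- tree$depth[idx[active]] == 0L
    active <- active[!at_root]
    idx[active] <- tree$parent_idx[idx[active]]
  }
  out
}

#' Generate a toy taxonomy
#'
#' Builds a deterministic miniature taxonomy shaped like the NCBI tree: one
#' root, one superkingdom node per taxonomic group (bacteria, viruses,
#' eukaryotes), a genus layer (roughly one genus per five species, assigned at
#' random under `seed`), and one species node per requested organism. Used as
#' the fixture taxonomy for simulation and classifier benchmarking, so no
#' taxonomy download is required.
#'
#' @param n_bacteria,n_viruses,n_eukaryotes Number of species per group
#'   (each >= 1).
#' @param seed Integer seed; the same seed yields an identical tree.
#' @return A list with elements `tree` (a [taxonomy_tree()]) and `groups`
#'   (a tibble `taxid`, `group` mapping every species taxid to its group).
#' @export
#' @examples
#' toy <- make_toy_taxonomy(3, 2, 1, seed = 1)
#' toy$tree
#' toy$groups
make_toy_taxonomy <- function(n_bacteria, n_viruses, n_eukaryotes, seed = 1) {
  counts <- c(bacteria = n_bacteria, virus = n_viruses, eukaryote = n_eukaryotes)
  for (g in names(counts)) {
    if (!is_count(counts[[g]])) abort(sprintf("`n_%s` must be a positive integer.", g))
  }
  counts <- as.integer(counts)
  names(counts) <- GROUP_LEVELS

  with_seed(seed, {
    rows <- list(
      tibble::tibble(
        taxid = 1L, parent_taxid = 1L, rank = "no rank", name = "root"
      )
    )
    sk_taxid <- c(bacteria = 2L, virus = 3L, eukaryote = 4L)
    sk_name <- c(bacteria = "Bacteria", virus = "Viruses", eukaryote = "Eukaryota")
    rows <- c(rows, list(tibble::tibble(
      taxid = unname(sk_taxid), parent_taxid = 1L,
      rank = "superkingdom", name = unname(sk_name)
    )))

    next_taxid <- 1000L
    group_rows <- vector("list", length(GROUP_LEVELS))
    names(group_rows) <- GROUP_LEVELS
    for (g in GROUP_LEVELS) {
      n_sp <- counts[[g]]
      n_gen <- max(1L, as.integer(ceiling(n_sp / 5)))
      genus_taxids <- next_taxid + seq_len(n_gen) - 1L
      next_taxid <- next_taxid + n_gen
      species_taxids <- next_taxid + seq_len(n_sp) - 1L
      next_taxid <- next_taxid + n_sp
      # every genus gets at least one species; the remainder land at random
      genus_of <- c(
        seq_len(n_gen),
        if (n_sp > n_gen) sample.int(n_gen, n_sp - n_gen, replace = TRUE)
      )
      rows <- c(rows, list(
        tibble::tibble(
          taxid = genus_taxids, parent_taxid = sk_taxid[[g]],
          rank = "genus", name = sprintf("%s_genus_%d", g, seq_len(n_gen))
        ),
        tibble::tibble(
          taxid = species_taxids, parent_taxid = genus_taxids[genus_of],
          rank = "species", name = sprintf("%s_species_%d", g, seq_len(n_sp))
        )
      ))
      group_rows[[g]] <- tibble::tibble(taxid = species_taxids, group = g)
    }
    list(
      tree = taxonomy_tree(dplyr::bind_rows(rows)),
      groups = dplyr::bind_rows(group_rows)
    )
  })
}
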