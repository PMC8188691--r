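# Independent oracles and shared fixtures. Everything here recomputes results
# from first principles (plain loops over the node table, substring search,
# closed forms) and never calls the package code paths it is used to check.

# --- independent taxonomy oracles (work on the raw nodes tibble) -------------

# parent map as a named vector, straight from the table
oracle_parent_map <- function(nodes) {
  stats::setNames(nodes$parent_taxid, nodes$taxid)
}

# root-to-self path by climbing the parent map directly
oracle_root_path <- function(nodes, taxid) {
  parent <- oracle_parent_map(nodes)
  path <- taxid
  while (parent[[as.character(taxid)]] != taxid) {
    taxid <- parent[[as.character(taxid)]]
    path <- c(path, taxid)
  }
  rev(path) # root first
}

# node depth by breadth-first traversal from the root
oracle_depth_bfs <- function(nodes, taxid) {
  parent <- oracle_parent_map(nodes)
  root <- nodes$taxid[nodes$taxid == nodes$parent_taxid]
  depth <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$taxid)
  depth[as.character(root)] <- 0L
  frontier <- root
  d <- 0L
  while (length(frontier) > 0L) {
    kids <- nodes$taxid[nodes$parent_taxid %in% frontier & !(nodes$taxid %in% frontier)]
    kids <- kids[is.na(depth[as.character(kids)])]
    d <- d + 1L
    depth[as.character(kids)] <- d
    frontier <- kids
  }
  unname(depth[as.character(taxid)])
}

# LCA as the last common element of the two root-down paths
oracle_lca_pair <- function(nodes, a, b) {
  pa <- oracle_root_path(nodes, a)
  pb <- oracle_root_path(nodes, b)
  common <- pa[seq_len(min(length(pa), length(pb)))] ==
    pb[seq_len(min(length(pa), length(pb)))]
  pa[max(which(common))]
}

oracle_lca_set <- function(nodes, taxids) {
  Reduce(function(a, b) oracle_lca_pair(nodes, a, b), taxids)
}

# random rooted tree on n nodes: node i attaches to a random earlier node
random_tree_nodes <- function(n, seed) {
  withr::with_seed(seed, {
    parent <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1L)))
    tibble::tibble(
      taxid = 1:n,
      parent_taxid = parent,
      rank = sample(c("species", "genus", "family", "no rank"), n, replace = TRUE),
      name = sprintf("node_%d", 1:n)
    )
  })
}

# --- brute-force LCA counting over b6-style hits ------------------------------

# recomputes the score filter, the LCA and the species-level counts per read
# with plain loops
brute_lca_count <- function(hits, nodes, subject_map, top_margin, read_ids) {
  assign_of <- list()
  for (rid in unique(hits$read_id)) {
    h <- hits[hits$read_id == rid, ]
    keep <- h$bit_score >= (1 - top_margin) * max(h$bit_score)
    taxa <- unique(unname(subject_map[h$subject_id[keep]]))
    assign_of[[rid]] <- oracle_lca_set(nodes, taxa)
  }
  taxid <- rep(NA_integer_, length(read_ids))
  names(taxid) <- read_ids
  for (rid in names(assign_of)) taxid[rid] <- assign_of[[rid]]

  # species projection by walking the root path
  rank_of <- stats::setNames(nodes$rank, nodes$taxid)
  species_of <- function(t) {
    path <- rev(oracle_root_path(nodes, t)) # self first
    at <- path[rank_of[as.character(path)] == "species"]
    if (length(at) == 0L) NA_integer_ else at[[1L]]
  }
  sp <- vapply(taxid, function(t) if (is.na(t)) NA_integer_ else species_of(t), integer(1L))
  counts <- table(sp[!is.na(sp)])
  list(
    taxid = unname(taxid),
    read_id = read_ids,
    counts = stats::setNames(as.integer(counts), names(counts))
  )
}

# --- shared fixtures ----------------------------------------------------------

# small three-group community used across module tests
small_fixture <- function(n_b = 6, n_v = 4, n_e = 2, seed = 11,
                          lengths = c(bacteria = 4000, virus = 1500, eukaryote = 8000),
                          read_length = 100) {
  toy <- make_toy_taxonomy(n_b, n_v, n_e, seed = seed)
  genomes <- make_toy_genomes(toy$groups, lengths, seed = seed + 1,
                              read_length = read_length)
  profile <- build_profile(split(toy$groups$taxid, toy$groups$group))
  list(tree = toy$tree, groups = toy$groups, genomes = genomes, profile = profile)
}

expect_setequal_int <- function(a, b) {
  expect_setequal(as.integer(a), as.integer(b))
}
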