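#' Concatenate per-gene representative sequences per sample
#'
#' Sequences are joined in the given gene order; every sample must have a
#' representative for every gene of the set.
#'
#' @param representatives tibble with `gene_id`, `sample_id`, `sequence`.
#' @param gene_order character vector of gene ids to concatenate (default:
#'   all genes present, in first-appearance order).
#' @return tibble with columns `sample_id` and `sequence` (length = sum of
#'   gene lengths).
#' @export
concatenate_representatives <- function(representatives,
                                        gene_order = unique(representatives$gene_id)) {
  wide <- tidyr::pivot_wider(
    representatives[c("sample_id", "gene_id", "sequence")],
    names_from = "gene_id", values_from = "sequence"
  )
  missing_genes <- setdiff(gene_order, names(wide))
  if (length(missing_genes) > 0) {
    stop("no representatives at all for gene(s): ",
         paste(missing_genes, collapse = ", "))
  }
  for (g in gene_order) {
    bad <- which(is.na(wide[[g]]))
    if (length(bad) > 0) {
      stop("sample ", wide$sample_id[bad[1]],
           " lacks a representative for gene ", g)
    }
  }
  tibble::tibble(
    sample_id = wide$sample_id,
    sequence = do.call(paste0, wide[gene_order])
  )
}

#' p-distance between two aligned sequences
#'
#' Mismatches over comparable sites, where a site is comparable iff both
#' sequences have a non-N base there. Returns 0 with a warning when no site
#' is comparable.
#'
#' @param a,b equal-length strings over `A/C/G/T/N`.
#' @return a single numeric in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences have unequal lengths")
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  comparable <- av %in% DNA_BASES & bv %in% DNA_BASES
  if (!any(comparable)) {
    warning("no comparable (both non-N) sites; returning distance 0")
    return(0)
  }
  sum(av[comparable] != bv[comparable]) / sum(comparable)
}

#' @keywords internal
concat_to_matrix <- function(concatenated) {
  seq_char_matrix(concatenated$sequence, concatenated$sample_id)
}

#' @keywords internal
dist_from_char_matrix <- function(m) {
  bin <- ape::as.DNAbin(m)
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
  dm <- as.matrix(d)
  if (any(is.nan(dm))) {
    warning("sample pair(s) share no comparable site; distance set to 0")
    dm[is.nan(dm)] <- 0
  }
  dm
}

#' Pairwise p-distance matrix of concatenated sequences
#'
#' @param concatenated tibble from [concatenate_representatives()].
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
distance_matrix <- function(concatenated) {
  dist_from_char_matrix(concat_to_matrix(concatenated))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via ape); negative branch lengths
#' are clamped to zero. This is the package's documented stand-in for
#' maximum-likelihood tree inference: the analysis targets recovery of
#' planted population structure, not reproduction of model-based trees.
#'
#' @param d symmetric distance matrix (or `dist`) over at least 3 samples.
#' @return an unrooted `phylo` object.
#' @export
nj_tree <- function(d) {
  dm <- as.matrix(d)
  if (any(!is.finite(dm))) stop("distance matrix contains non-finite values")
  if (nrow(dm) < 3) stop("neighbor-joining needs at least 3 samples")
  tr <- ape::nj(stats::as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Column-bootstrap supports for the NJ tree of a concatenated alignment
#'
#' Columns of the concatenated sample-by-site matrix are resampled with
#' replacement; a p-distance NJ tree is built per replicate, and the support
#' of each internal edge of the original tree is the percentage of replicates
#' whose tree contains the same bipartition.
#'
#' @param concatenated tibble from [concatenate_representatives()].
#' @param n_replicates number of bootstrap replicates (default 100).
#' @param seed optional integer seed for reproducible resampling.
#' @return list with `tree` (the original NJ `phylo`), `support` (integer
#'   vector, one entry per internal node in ape node order, percentage of
#'   `n_replicates`), and `n_replicates`.
#' @export
bootstrap_support <- function(concatenated, n_replicates = 100L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  m <- concat_to_matrix(concatenated)
  tree <- nj_tree(dist_from_char_matrix(m))
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    reps[[b]] <- nj_tree(dist_from_char_matrix(m[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- as.integer(round(100 * counts / n_replicates))
  list(tree = tree, support = support, n_replicates = n_replicates)
}

#' @keywords internal
clade_table <- function(tree, support) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tips_of <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) tips_of[[i]] <- tree$tip.label[i]
  # accumulate tip sets in reverse edge order (ape edges are cladewise)
  for (e in rev(seq_len(nrow(tree$edge)))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    tips_of[[parent]] <- c(tips_of[[parent]], tips_of[[child]])
  }
  nodes <- ntip + seq_len(nnode)
  tibble::tibble(
    node = nodes,
    tips = lapply(nodes, function(n) sort(unique(tips_of[[n]]))),
    support = if (is.null(support)) NA_integer_ else as.integer(support)
  )
}

#' Assess locality-group clustering in a bootstrapped tree
#'
#' For each locality group, reports the largest clade composed solely of that
#' group's samples whose bootstrap support reaches `min_support` (clades of
#' the unrooted tree are read as both sides of every internal edge). Groups
#' with no such multi-sample clade report size 1; groups absent from the tree
#' report size 0.
#'
#' @param boot list from [bootstrap_support()] (or a bare `phylo` in `tree`
#'   with `support = NULL` for a support-free assessment).
#' @param metadata tibble with `sample_id` and `locality_group`.
#' @param min_support minimum bootstrap percentage (default 70).
#' @return tibble with columns `locality_group`, `n_samples_in_tree`,
#'   `clade_size`, `clade_support`, `clade_samples` (list-column).
#' @export
assess_clusters <- function(boot, metadata, min_support = 70L) {
  tree <- boot$tree
  support <- boot$support
  tips <- tree$tip.label
  extra <- setdiff(tips, metadata$sample_id)
  if (length(extra) > 0) {
    stop("tree contains samples absent from metadata: ",
         paste(extra, collapse = ", "))
  }
  clades <- clade_table(tree, support)
  # both sides of each internal bipartition are candidate clusters
  all_tips <- sort(tips)
  flipped <- tibble::tibble(
    node = clades$node,
    tips = lapply(clades$tips, function(t) setdiff(all_tips, t)),
    support = clades$support
  )
  cand <- dplyr::bind_rows(clades, flipped)
  cand <- cand[lengths(cand$tips) > 0, ]
  groups <- unique(metadata$locality_group)
  rows <- lapply(groups, function(grp) {
    members <- metadata$sample_id[metadata$locality_group == grp]
    in_tree <- intersect(members, tips)
    if (length(in_tree) == 0) {
      return(tibble::tibble(locality_group = grp, n_samples_in_tree = 0L,
                            clade_size = 0L, clade_support = NA_integer_,
                            clade_samples = list(character(0))))
    }
    pure <- which(vapply(cand$tips, function(t)
      length(t) >= 2 && all(t %in% members), logical(1)))
    supported <- pure[is.na(cand$support[pure]) |
                        cand$support[pure] >= min_support]
    if (length(supported) == 0) {
      return(tibble::tibble(locality_group = grp,
                            n_samples_in_tree = length(in_tree),
                            clade_size = 1L, clade_support = NA_integer_,
                            clade_samples = list(character(0))))
    }
    best <- supported[which.max(lengths(cand$tips[supported]))]
    tibble::tibble(locality_group = grp,
                   n_samples_in_tree = length(in_tree),
                   clade_size = length(cand$tips[[best]]),
                   clade_support = cand$support[best],
                   clade_samples = cand$tips[best])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sv_clusters", class(out))
  out
}

#' Write a tree in newick format with bootstrap supports as node labels
#'
#' @param boot list from [bootstrap_support()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(boot, path) {
  tr <- boot$tree
  tr$node.label <- as.character(boot$support)
  ape::write.tree(tr, file = path)
  invisible(path)
}
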