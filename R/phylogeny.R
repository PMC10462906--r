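# Per-clone lineage trees.
#
# Unique sequences of a clone are collapsed (keeping duplicate-count
# weights), a root is constructed from the unmutated germline V and J with
# the clone's consensus junction in between, and a neighbor-joining tree
# is built on pairwise normalized Levenshtein distances over the unique
# sequences plus the root, then rooted at the root sequence.

#' Construct the unmutated root sequence of a clone
#'
#' Germline V + consensus junction + germline J. The consensus junction is
#' the position-wise majority over members (duplicate-count weighted, ties
#' broken by alphabetical base).
#'
#' @param clone one row of a `clone_set$clones` table (needs `v_gene`,
#'   `j_gene`, `consensus_junction`).
#' @param germlines germline set (defaults to the bundled one).
#' @return root DNA string.
#' @export
build_root <- function(clone, germlines = toy_germlines()) {
  if (!clone$v_gene %in% names(germlines$v)) {
    stop("unknown germline V call: ", clone$v_gene)
  }
  if (!clone$j_gene %in% names(germlines$j)) {
    stop("unknown germline J call: ", clone$j_gene)
  }
  v <- germlines$v[[clone$v_gene]]
  j <- germlines$j[[clone$j_gene]]
  paste0(v, clone$consensus_junction, j)
}

#' Build the lineage tree of a clone
#'
#' Collapses the clone's members to unique (sequence, GC) leaves weighted
#' by duplicate counts, keeps at most `max_leaves` leaves by weight,
#' computes pairwise normalized Levenshtein distances among the leaves and
#' the root, and joins them by neighbor joining, rooted at the root
#' sequence. With a single unique sequence the tree degenerates to a
#' leaf--root cherry.
#'
#' @param clone_id clone to build.
#' @param clone_set a `clone_set`.
#' @param records rearrangement data.frame.
#' @param germlines germline set.
#' @param max_leaves maximum leaves kept, by descending weight (default
#'   300).
#' @return a `clonal_tree`: list with `phylo` (ape tree rooted at tip
#'   "root"), `root_sequence`, `leaves` (data.frame `label`,
#'   `sequence_id`, `gc_id`, `weight`, `sequence`, `mutations` = Hamming
#'   distance to root where lengths match), `clone_id`.
#' @export
clone_tree <- function(clone_id, clone_set, records,
                       germlines = toy_germlines(), max_leaves = 300L) {
  cl <- clone_set$clones[clone_set$clones$clone_id == clone_id, ]
  if (nrow(cl) != 1) stop("unknown clone_id: ", clone_id)
  ids <- clone_set$membership$sequence_id[
    clone_set$membership$clone_id == clone_id]
  rec <- records[records$sequence_id %in% ids, ]
  key <- paste(rec$sequence, rec$gc_id, sep = "|")
  agg <- lapply(split(seq_len(nrow(rec)), key), function(ix) {
    r <- rec[ix, ]
    i <- ix[order(-r$duplicate_count, r$sequence_id)][1]
    data.frame(sequence_id = rec$sequence_id[i], gc_id = rec$gc_id[i],
               weight = sum(r$duplicate_count), sequence = rec$sequence[i],
               stringsAsFactors = FALSE)
  })
  leaves <- do.call(rbind, agg)
  leaves <- leaves[order(-leaves$weight, leaves$sequence_id), ]
  if (nrow(leaves) > max_leaves) leaves <- leaves[seq_len(max_leaves), ]
  rownames(leaves) <- NULL
  root_seq <- build_root(cl, germlines)
  leaves$label <- .escape_label(paste(leaves$sequence_id, leaves$gc_id,
                                      leaves$weight, sep = "|"))
  leaves$mutations <- ifelse(
    nchar(leaves$sequence) == nchar(root_seq),
    vapply(leaves$sequence, function(s) .hamming(s, root_seq), 0),
    NA_real_)

  seqs <- c(leaves$sequence, root_seq)
  labs <- c(leaves$label, "root")
  n <- length(seqs)
  lev <- utils::adist(seqs)
  d <- 2 * lev / (outer(nchar(seqs), nchar(seqs), `+`) + lev)
  d[is.nan(d)] <- 0
  dimnames(d) <- list(labs, labs)
  if (n == 2) {
    # single unique sequence: degenerate cherry leaf--root
    phy <- ape::read.tree(
      text = sprintf("(%s:%.10g,root:0);", labs[1], d[1, 2]))
  } else if (n == 3) {
    # three-point formula resolves the star exactly
    a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    r <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    phy <- ape::read.tree(
      text = sprintf("(%s:%.10g,%s:%.10g,root:%.10g);",
                     labs[1], max(a, 0), labs[2], max(b, 0), max(r, 0)))
  } else {
    phy <- ape::nj(stats::as.dist(d))
  }
  phy <- ape::root(phy, outgroup = "root", resolve.root = TRUE)
  structure(list(phylo = phy, root_sequence = root_seq, leaves = leaves,
                 clone_id = clone_id),
            class = "clonal_tree")
}

.escape_label <- function(x) {
  gsub("[][ ():;,']", "_", x)
}

#' Newick export of a clonal tree
#'
#' Leaf labels are `sequenceid|gc|count` with reserved Newick characters
#' escaped; parseable by standard readers.
#'
#' @param tree a `clonal_tree`.
#' @return Newick string.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "clonal_tree"))
  if (is.null(tree$phylo)) {
    return(sprintf("(%s);", tree$leaves$label[1]))
  }
  ape::write.tree(tree$phylo)
}

#' Per-GC distribution of leaf-to-root similarity
#'
#' For a clone spanning several GCs, computes `1 - Lev_norm(leaf, root)`
#' per leaf and summarizes per GC; GCs whose sequences are closer to the
#' root are candidates for having seeded the others.
#'
#' @param tree a `clonal_tree`.
#' @return list: `per_leaf` (data.frame `gc_id`, `label`, `similarity`,
#'   `weight`), `median_by_gc` (named vector, decreasing).
#' @export
root_distance_distribution <- function(tree) {
  stopifnot(inherits(tree, "clonal_tree"))
  lv <- tree$leaves
  sim <- vapply(lv$sequence, function(s) {
    1 - normalized_levenshtein(s, tree$root_sequence)
  }, numeric(1))
  per_leaf <- data.frame(gc_id = lv$gc_id, label = lv$label,
                         similarity = unname(sim), weight = lv$weight,
                         stringsAsFactors = FALSE)
  med <- sort(tapply(per_leaf$similarity, per_leaf$gc_id, stats::median),
              decreasing = TRUE)
  list(per_leaf = per_leaf, median_by_gc = med)
}

# tips under each internal node of a phylo (list indexed by node id)
.tips_under <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  below <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) below[[i]] <- i
  # process edges child-before-parent: reverse postorder
  ord <- ape::reorder.phylo(phy, "postorder")$edge
  for (e in seq_len(nrow(ord))) {
    p <- ord[e, 1]; ch <- ord[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

#' Mean number of mutations acquired before a crippling mutation
#'
#' For each maximal non-functional subtree of an F&NF clone's lineage
#' tree, takes the non-functional leaf closest to the root and counts its
#' mutations relative to the root, excluding differences within the
#' crippling stop codon itself; returns the mean over subtrees.
#'
#' @param tree a `clonal_tree`.
#' @param labels data.frame from [classify_sequences()] covering the
#'   tree's leaves (`sequence_id`, `functional_class`, `stop_codons`).
#' @return mean mutation count before crippling.
#' @export
mutations_before_crippling <- function(tree, labels) {
  stopifnot(inherits(tree, "clonal_tree"))
  lv <- tree$leaves
  lv$class <- labels$functional_class[match(lv$sequence_id,
                                            labels$sequence_id)]
  lv$stops <- labels$stop_codons[match(lv$sequence_id, labels$sequence_id)]
  nf <- lv$class != "functional"
  if (!any(nf, na.rm = TRUE)) stop("clone has no non-functional leaves")
  count_before <- function(i) {
    s <- lv$sequence[i]
    if (nchar(s) != nchar(tree$root_sequence)) return(NA_real_)
    a <- strsplit(s, "")[[1]]
    b <- strsplit(tree$root_sequence, "")[[1]]
    diffs <- which(a != b)
    stops <- as.integer(strsplit(lv$stops[i], ",")[[1]])
    stop_pos <- unlist(lapply(stops, function(c0) (3 * c0 + 1):(3 * c0 + 3)))
    length(setdiff(diffs, stop_pos))
  }
  if (is.null(tree$phylo)) {
    return(mean(vapply(which(nf), count_before, numeric(1)), na.rm = TRUE))
  }
  phy <- tree$phylo
  tip_nf <- setNames(nf[match(phy$tip.label, lv$label)], phy$tip.label)
  tip_nf["root" == phy$tip.label] <- FALSE
  tip_nf[is.na(tip_nf)] <- FALSE
  below <- .tips_under(phy)
  n_tip <- length(phy$tip.label)
  all_nf <- vapply(below, function(tips) all(tip_nf[tips]), logical(1))
  parent <- rep(NA_integer_, n_tip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  maximal <- which(all_nf &
                     (is.na(parent) | !all_nf[ifelse(is.na(parent), 1,
                                                     parent)]))
  vals <- vapply(maximal, function(nd) {
    tips <- below[[nd]]
    idx <- match(phy$tip.label[tips], lv$label)
    cnt <- vapply(idx, count_before, numeric(1))
    if (all(is.na(cnt))) NA_real_ else min(cnt, na.rm = TRUE)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}
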