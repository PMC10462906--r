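# Grouping rearrangements into clones.
#
# A clone is a set of rearrangements sharing the same V gene, J gene and
# CDR3 (junction) length, whose junction nucleotide sequences are linked at
# more than 84% identity under hierarchical agglomerative clustering
# (single linkage by default). Because junction length equality is a hard
# grouping key, identity between equal-length junctions is position-wise
# (Hamming-based).

#' Junction nucleotide identity
#'
#' Fraction of matching positions between two equal-length junction
#' sequences. Clonal grouping only ever compares junctions of equal length,
#' so unequal lengths are a caller error.
#'
#' @param j1,j2 DNA strings of equal length.
#' @return identity fraction in `[0, 1]`.
#' @export
#' @examples
#' junction_identity("ACGTACGTAC", "ACGTACGAAC")
junction_identity <- function(j1, j2) {
  if (nchar(j1) != nchar(j2)) {
    stop("junction_identity requires equal-length junctions; ",
         "partition by junction length first")
  }
  1 - .hamming(j1, j2) / nchar(j1)
}

#' Group rearrangements into clones
#'
#' Partitions records by (V gene, J gene, junction length) — gene calls are
#' collapsed to gene level, stripping the allele — then clusters the
#' junction sequences of each partition by hierarchical agglomerative
#' clustering on Hamming distance, cut so that clones are linked at
#' identity strictly greater than `threshold`. Records lacking a junction
#' are excluded and counted.
#'
#' @param records rearrangement data.frame.
#' @param threshold junction identity threshold (default 0.84).
#' @param linkage linkage criterion: `"single"` (default), `"complete"` or
#'   `"average"`.
#' @return a `clone_set`: list with `clones` (one row per clone:
#'   `clone_id` in `Vgene_JunctionLength_Jgene[_k]` form, `v_gene`,
#'   `v_subgroup`, `j_gene`, `junction_length`, `n_seqs`, `abundance`
#'   (duplicate-count weighted), `frequency`, `consensus_junction`,
#'   `representative_id`, `representative_junction`), `membership`
#'   (`sequence_id` to `clone_id` map), `threshold`, `linkage`,
#'   `n_excluded`.
#' @export
group_clones <- function(records, threshold = 0.84,
                         linkage = c("single", "complete", "average")) {
  linkage <- match.arg(linkage)
  miss <- is.na(records$junction) | records$junction == ""
  if (any(miss)) {
    message(sum(miss), " record(s) without junction excluded from grouping")
  }
  rec <- records[!miss, , drop = FALSE]
  v_gene <- gene_of(rec$v_call)
  j_gene <- gene_of(rec$j_call)
  key <- paste(v_gene, rec$junction_length, j_gene, sep = "_")
  cluster_id <- integer(nrow(rec))
  for (k in unique(key)) {
    sel <- which(key == k)
    ju <- sort(unique(rec$junction[sel]))
    if (length(ju) == 1L) {
      cl <- setNames(1L, ju)
    } else {
      d <- .hamming_frac_matrix(ju)
      hc <- stats::hclust(stats::as.dist(d), method = linkage)
      cl <- stats::cutree(hc, h = (1 - threshold) - 1e-9)
      names(cl) <- ju
    }
    cluster_id[sel] <- cl[rec$junction[sel]]
  }
  grp <- paste(key, cluster_id, sep = ".")

  # clone-level summaries
  clone_rows <- lapply(split(seq_len(nrow(rec)), grp), function(ix) {
    r <- rec[ix, , drop = FALSE]
    ab <- sum(r$duplicate_count)
    cons <- .consensus(r$junction, r$duplicate_count)
    rep_i <- ix[order(-r$duplicate_count, r$sequence_id)][1]
    data.frame(v_gene = gene_of(rec$v_call[rep_i]),
               v_subgroup = subgroup_of(rec$v_call[rep_i]),
               j_gene = gene_of(rec$j_call[rep_i]),
               junction_length = rec$junction_length[rep_i],
               n_seqs = nrow(r),
               abundance = ab,
               consensus_junction = cons,
               representative_id = rec$sequence_id[rep_i],
               representative_junction = rec$junction[rep_i],
               stringsAsFactors = FALSE)
  })
  clones <- do.call(rbind, clone_rows)
  clones$key <- paste(clones$v_gene, clones$junction_length, clones$j_gene,
                      sep = "_")
  # deterministic ids: _k suffix (by descending abundance, then consensus)
  # only where several clones share the Vgene_len_Jgene key
  clones <- clones[order(clones$key, -clones$abundance,
                         clones$consensus_junction), ]
  n_in_key <- ave(seq_len(nrow(clones)), clones$key, FUN = length)
  rank_in_key <- ave(seq_len(nrow(clones)), clones$key, FUN = seq_along)
  clones$clone_id <- ifelse(n_in_key > 1,
                            paste0(clones$key, "_", rank_in_key),
                            clones$key)
  id_by_grp <- setNames(clones$clone_id, rownames(clones))
  membership <- data.frame(sequence_id = rec$sequence_id,
                           clone_id = unname(id_by_grp[grp]),
                           stringsAsFactors = FALSE)
  clones$frequency <- clones$abundance / sum(clones$abundance)
  clones <- clones[order(-clones$abundance, clones$clone_id),
                   c("clone_id", "v_gene", "v_subgroup", "j_gene",
                     "junction_length", "n_seqs", "abundance", "frequency",
                     "consensus_junction", "representative_id",
                     "representative_junction")]
  rownames(clones) <- NULL
  structure(list(clones = clones, membership = membership,
                 threshold = threshold, linkage = linkage,
                 n_excluded = sum(miss)),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat("clone_set:", nrow(x$clones), "clones from",
      nrow(x$membership), "records (threshold", x$threshold,
      ", linkage", x$linkage, ")\n")
  invisible(x)
}

#' Merge clones from the same V subgroup with identical representative CDR3
#'
#' Sequencing that misses the start of FWR1 makes V-gene assignment within
#' a subgroup unreliable, so clones whose V genes belong to the same
#' subgroup, with equal J gene and junction length, are merged when the
#' junction of their most common sequence is identical. The clone id of the
#' larger partner is retained and abundances are summed.
#'
#' @param clone_set a `clone_set` from [group_clones()].
#' @return the merged `clone_set`.
#' @export
merge_same_subgroup <- function(clone_set) {
  cl <- clone_set$clones
  key <- paste(cl$v_subgroup, cl$j_gene, cl$junction_length,
               cl$representative_junction, sep = "|")
  keep <- clone_set
  remap <- character(0)
  merged_rows <- lapply(split(seq_len(nrow(cl)), key), function(ix) {
    if (length(ix) == 1L) return(cl[ix, , drop = FALSE])
    r <- cl[ix[order(-cl$abundance[ix], cl$clone_id[ix])], , drop = FALSE]
    out <- r[1, , drop = FALSE]
    out$n_seqs <- sum(r$n_seqs)
    out$abundance <- sum(r$abundance)
    remap[r$clone_id[-1]] <<- r$clone_id[1]
    out
  })
  clones <- do.call(rbind, merged_rows)
  clones$frequency <- clones$abundance / sum(clones$abundance)
  clones <- clones[order(-clones$abundance, clones$clone_id), ]
  rownames(clones) <- NULL
  membership <- keep$membership
  hit <- membership$clone_id %in% names(remap)
  membership$clone_id[hit] <- remap[membership$clone_id[hit]]
  structure(list(clones = clones, membership = membership,
                 threshold = keep$threshold, linkage = keep$linkage,
                 n_excluded = keep$n_excluded,
                 n_merged = length(remap)),
            class = "clone_set")
}

#' Group sequences by identical CDR3 amino-acid sequence
#'
#' Exact-match grouping on the translated CDR3 (junction minus the
#' conserved flanking Cys/Trp codons), irrespective of V and J genes.
#' Out-of-frame or untranslatable junctions are excluded and counted.
#'
#' @param records rearrangement data.frame.
#' @return list with `groups` (one row per CDR3 group: `cdr3_aa`, `n_seqs`,
#'   `abundance`), `membership` (`sequence_id` to `cdr3_aa`) and
#'   `n_excluded`.
#' @export
group_by_cdr3 <- function(records) {
  ok <- records$in_frame_junction & records$junction_length %% 3L == 0L &
    !is.na(records$junction) & records$junction != ""
  rec <- records[ok, , drop = FALSE]
  aa <- translate_dna(rec$junction)
  cdr3 <- substr(aa, 2L, nchar(aa) - 1L)
  bad <- grepl("\\*", cdr3) | cdr3 == ""
  rec <- rec[!bad, , drop = FALSE]
  cdr3 <- cdr3[!bad]
  ab <- tapply(rec$duplicate_count, cdr3, sum)
  ns <- tapply(rec$sequence_id, cdr3, length)
  groups <- data.frame(cdr3_aa = names(ab),
                       n_seqs = as.integer(ns[names(ab)]),
                       abundance = as.integer(ab),
                       stringsAsFactors = FALSE)
  groups <- groups[order(-groups$abundance, groups$cdr3_aa), ]
  rownames(groups) <- NULL
  list(groups = groups,
       membership = data.frame(sequence_id = rec$sequence_id,
                               cdr3_aa = cdr3, stringsAsFactors = FALSE),
       n_excluded = sum(!ok) + sum(bad))
}

#' Per-sample clone abundances
#'
#' Duplicate-count weighted abundance of each clone in each (GC, replicate)
#' sample, plus GC-level totals.
#'
#' @param clone_set a `clone_set`.
#' @param records the records the clones were built from (must carry
#'   `gc_id` and `replicate_id`).
#' @return data.frame with columns `clone_id`, `gc_id`, `replicate_id`,
#'   `abundance`.
#' @export
clone_sample_abundance <- function(clone_set, records) {
  m <- merge(clone_set$membership, records[, c("sequence_id", "gc_id",
                                               "replicate_id",
                                               "duplicate_count")],
             by = "sequence_id")
  out <- aggregate(duplicate_count ~ clone_id + gc_id + replicate_id,
                   data = m, FUN = sum)
  names(out)[names(out) == "duplicate_count"] <- "abundance"
  out[order(out$clone_id, out$gc_id, out$replicate_id), ]
}

#' Optimize the clonal identity threshold from distance-to-nearest
#' distributions
#'
#' For each record, computes the normalized Levenshtein distance to its
#' nearest same-(V gene, J gene, junction length) neighbour within the
#' sample, and the same quantity against a negation set (sequences known
#' to be clonally unrelated, e.g. from a different individual). The two
#' distributions are expected to be bimodal in combination: a low mode of
#' within-clone distances and a high mode of unrelated distances. The
#' chosen threshold is `1 - d*`, where `d*` is the minimum of the pooled
#' Gaussian kernel density (Silverman bandwidth) between the within-clone
#' mode and the negation mode.
#'
#' @param records rearrangement data.frame (>= 100 rows with junctions).
#' @param negation_records negation rearrangement data.frame (>= 100 rows).
#' @return a `threshold_diagnostics` list: `within_distances`,
#'   `negation_distances`, `within_mode`, `negation_mode`,
#'   `chosen_threshold` (NA with a warning when no valley exists).
#' @export
optimize_threshold <- function(records, negation_records) {
  if (is.null(negation_records) || nrow(negation_records) == 0) {
    stop("negation set is empty")
  }
  if (nrow(records) < 100 || nrow(negation_records) < 100) {
    stop("need at least 100 records in each set")
  }
  part_key <- function(r) {
    paste(gene_of(r$v_call), gene_of(r$j_call), r$junction_length, sep = "_")
  }
  norm_lev <- function(a, b) {
    lev <- utils::adist(a, b)
    den <- outer(nchar(a), nchar(b), `+`) + lev
    d <- 2 * lev / den
    d[den == 0] <- 0
    d
  }
  nearest_within <- function(rec) {
    key <- part_key(rec)
    out <- rep(NA_real_, nrow(rec))
    for (k in unique(key)) {
      sel <- which(key == k)
      if (length(sel) < 2) next
      d <- norm_lev(rec$junction[sel], rec$junction[sel])
      diag(d) <- NA
      out[sel] <- apply(d, 1, min, na.rm = TRUE)
    }
    out
  }
  nearest_cross <- function(rec, neg) {
    key <- part_key(rec)
    nkey <- part_key(neg)
    out <- rep(NA_real_, nrow(rec))
    for (k in unique(key)) {
      sel <- which(key == k)
      nsel <- which(nkey == k)
      if (!length(nsel)) next
      d <- norm_lev(rec$junction[sel], neg$junction[nsel])
      out[sel] <- apply(d, 1, min)
    }
    out
  }
  w <- nearest_within(records)
  w <- w[!is.na(w)]
  ng <- nearest_cross(records, negation_records)
  ng <- ng[!is.na(ng)]
  mode_of <- function(x) {
    d <- stats::density(x, bw = "nrd0")
    d$x[which.max(d$y)]
  }
  mw <- mode_of(w)
  mn <- mode_of(ng)
  diag <- list(within_distances = w, negation_distances = ng,
               within_mode = mw, negation_mode = mn,
               chosen_threshold = NA_real_)
  class(diag) <- "threshold_diagnostics"
  if (!(mw < mn)) {
    warning("within-sample and negation modes do not separate; ",
            "no threshold chosen")
    return(diag)
  }
  pooled <- stats::density(c(w, ng), bw = "nrd0")
  inside <- pooled$x > mw & pooled$x < mn
  if (!any(inside)) {
    warning("no density support between modes; no threshold chosen")
    return(diag)
  }
  ys <- pooled$y[inside]
  xs <- pooled$x[inside]
  i <- which.min(ys)
  if (i == 1L || i == length(ys)) {
    warning("pooled distance density has no interior valley; ",
            "no threshold chosen")
    return(diag)
  }
  diag$chosen_threshold <- 1 - xs[i]
  diag
}
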