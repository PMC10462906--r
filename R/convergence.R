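# Common-epitope (convergence) prediction between clones.
#
# Three similarity metrics are combined by a 2-of-3 vote: CDR similarity
# (average normalized Levenshtein over H1-H3, threshold 0.84), paratope
# identity ("Paratype": identical predicted-paratope residues over the
# smaller paratope, threshold 0.76), and a structure-based token score in
# the Ab-Ligity style (residue triples tokenized by chemical class and
# binned pairwise distances, Tanimoto over token multisets, threshold
# 0.26). A pair is predicted to bind a common epitope when at least two
# metrics pass and the CDR3 lengths are equal.

# seven chemical classes of amino-acid side chains
.AA_CLASS <- c(A = "ali", V = "ali", L = "ali", I = "ali", P = "ali",
               G = "ali", M = "ali",
               S = "hyd", T = "hyd",
               C = "sul",
               F = "aro", W = "aro", Y = "aro", H = "aro",
               D = "aci", E = "aci",
               N = "ami", Q = "ami",
               K = "bas", R = "bas")

.DEFAULT_THRESHOLDS <- c(cdr = 0.84, paratype = 0.76, abligity = 0.26)

#' Normalized Levenshtein distance
#'
#' `2 Lev / (|s1| + |s2| + Lev)`: a length-normalized edit distance in
#' `[0, 1]` that is symmetric, zero iff the strings are equal, and
#' satisfies the triangle inequality.
#'
#' @param s1,s2 strings (empty allowed).
#' @return distance in `[0, 1]`.
#' @export
#' @examples
#' normalized_levenshtein("ACGT", "ACGA")  # 2/9
normalized_levenshtein <- function(s1, s2) {
  lev <- as.numeric(utils::adist(s1, s2))
  denom <- nchar(s1) + nchar(s2) + lev
  if (denom == 0) return(0)
  2 * lev / denom
}

#' CDR similarity between two paratope profiles
#'
#' One minus the mean normalized Levenshtein distance over the three
#' heavy-chain CDRs.
#'
#' @param a,b `paratope_profile` objects (need `cdrs` with H1, H2, H3).
#' @return similarity in `[0, 1]`.
#' @export
cdr_similarity <- function(a, b) {
  for (p in list(a, b)) {
    if (is.null(p$cdrs) || length(p$cdrs) != 3 || anyNA(p$cdrs)) {
      stop("profile is missing one of the H1-H3 CDRs")
    }
  }
  d <- mean(vapply(1:3, function(i) {
    normalized_levenshtein(a$cdrs[[i]], b$cdrs[[i]])
  }, numeric(1)))
  1 - d
}

#' Paratope identity (Paratype)
#'
#' Number of positions that are predicted paratope in both profiles (same
#' numbering) with matching amino acid, divided by the smaller paratope
#' size. `NA` (with a warning) when either paratope is empty.
#'
#' @param a,b `paratope_profile` objects.
#' @return identity in `[0, 1]`, or `NA`.
#' @export
paratype_identity <- function(a, b) {
  pa <- a$numbering[a$mask]
  pb <- b$numbering[b$mask]
  if (length(pa) == 0 || length(pb) == 0) {
    warning("empty paratope; pair excluded from the paratype metric")
    return(NA_real_)
  }
  common <- intersect(pa, pb)
  if (length(common) == 0) return(0)
  aa_a <- substring(a$aa, match(common, a$numbering),
                    match(common, a$numbering))
  aa_b <- substring(b$aa, match(common, b$numbering),
                    match(common, b$numbering))
  sum(aa_a == aa_b) / min(length(pa), length(pb))
}

# token multiset of residue triples for one profile
.abligity_tokens <- function(p, distance_bin) {
  idx <- which(p$mask)
  if (is.null(p$coords) || length(idx) < 3) return(NULL)
  aa <- substring(p$aa, idx, idx)
  cls <- .AA_CLASS[aa]
  cls[is.na(cls)] <- "oth"
  xyz <- p$coords[idx, , drop = FALSE]
  trips <- utils::combn(seq_along(idx), 3)
  apply(trips, 2, function(t3) {
    dd <- c(sqrt(sum((xyz[t3[1], ] - xyz[t3[2], ])^2)),
            sqrt(sum((xyz[t3[1], ] - xyz[t3[3], ])^2)),
            sqrt(sum((xyz[t3[2], ] - xyz[t3[3], ])^2)))
    paste(paste(sort(cls[t3]), collapse = "."),
          paste(sort(floor(dd / distance_bin)), collapse = "."),
          sep = "|")
  })
}

#' Structural paratope token similarity (Ab-Ligity style)
#'
#' Every unordered triple of paratope residues is tokenized by its sorted
#' chemical-class triple and sorted binned pairwise distances; the score
#' is the Tanimoto coefficient of the two token multisets. Returns `NA`
#' (abstains) when either profile lacks coordinates or has fewer than 3
#' paratope residues.
#'
#' @param a,b `paratope_profile` objects with `coords`.
#' @param distance_bin distance bin width in \enc{Å}{Angstrom} (default
#'   1.0).
#' @return similarity in `[0, 1]`, or `NA`.
#' @export
abligity_score <- function(a, b, distance_bin = 1.0) {
  ta <- .abligity_tokens(a, distance_bin)
  tb <- .abligity_tokens(b, distance_bin)
  if (is.null(ta) || is.null(tb)) return(NA_real_)
  keys <- union(ta, tb)
  ca <- table(factor(ta, levels = keys))
  cb <- table(factor(tb, levels = keys))
  sum(pmin(ca, cb)) / sum(pmax(ca, cb))
}

#' Predict whether two clones bind a common epitope
#'
#' Computes the three metrics and applies the 2-of-3 vote: a metric votes
#' when it exceeds its threshold; an abstaining metric (paratype with an
#' empty paratope, Ab-Ligity without coordinates) casts no vote and cannot
#' be compensated — two positive votes are still required. The pair must
#' additionally have equal CDR3 length.
#'
#' @param a,b `paratope_profile` objects.
#' @param thresholds named vector `cdr`, `paratype`, `abligity`.
#' @param distance_bin Ab-Ligity bin width.
#' @return one-row data.frame: ids, the three metric values, `votes`,
#'   `same_cdr3_length`, `predicted`, `paratope_distance`.
#' @export
predict_common_epitope <- function(a, b,
                                   thresholds = .DEFAULT_THRESHOLDS,
                                   distance_bin = 1.0) {
  cdr <- cdr_similarity(a, b)
  pty <- suppressWarnings(paratype_identity(a, b))
  abl <- abligity_score(a, b, distance_bin)
  vals <- c(cdr = cdr, paratype = pty, abligity = abl)
  votes <- sum(vals > thresholds[names(vals)], na.rm = TRUE)
  same_len <- nchar(a$cdrs[["H3"]]) == nchar(b$cdrs[["H3"]])
  data.frame(id_a = a$id, id_b = b$id,
             clone_a = a$clone_id, clone_b = b$clone_id,
             gc_a = a$gc_id, gc_b = b$gc_id,
             cdr_similarity = cdr, paratype_identity = pty,
             abligity_score = abl, votes = votes,
             same_cdr3_length = same_len,
             predicted = votes >= 2 & same_len,
             paratope_distance = paratope_distance(pty, cdr),
             stringsAsFactors = FALSE)
}

#' Paratope distance of a clone pair
#'
#' `((1 - paratype identity) + (1 - CDR similarity)) / 2`.
#'
#' @param paratype_identity,cdr_similarity the two component similarities.
#' @return distance in `[0, 1]` (`NA` when a component is undefined).
#' @export
paratope_distance <- function(paratype_identity, cdr_similarity) {
  ((1 - paratype_identity) + (1 - cdr_similarity)) / 2
}

#' Categorize a predicted clone pair
#'
#' Precedence: same clone found in different GCs; same V and J gene with
#' divergent CDR3 (the pair was split at clone identification); different
#' V or J gene.
#'
#' @param pair one-row data.frame from [predict_common_epitope()].
#' @param clones `clone_set$clones` table.
#' @return one of `"same_clone_multi_gc"`, `"same_vj_divergent_cdr3"`,
#'   `"different_v_or_j"`.
#' @export
categorize_pair <- function(pair, clones) {
  if (pair$clone_a == pair$clone_b) return("same_clone_multi_gc")
  a <- clones[clones$clone_id == pair$clone_a, ]
  b <- clones[clones$clone_id == pair$clone_b, ]
  if (nrow(a) == 1 && nrow(b) == 1 &&
      a$v_gene == b$v_gene && a$j_gene == b$j_gene) {
    return("same_vj_divergent_cdr3")
  }
  "different_v_or_j"
}

# multiset Tanimoto of two token vectors
.tanimoto <- function(ta, tb) {
  keys <- unique(c(ta, tb))
  ca <- tabulate(match(ta, keys), length(keys))
  cb <- tabulate(match(tb, keys), length(keys))
  sum(pmin(ca, cb)) / sum(pmax(ca, cb))
}

# Vectorized all-pairs evaluation with the same semantics as
# predict_common_epitope(). CDR distances come from three adist() calls;
# the Ab-Ligity token score is evaluated lazily, only for same-CDR3-length
# pairs where the first two metrics leave the 2-of-3 vote undecided or
# already predicted (it can neither create nor remove a prediction
# elsewhere, where it is reported as NA).
.evaluate_all_pairs <- function(use, thresholds, distance_bin) {
  n <- length(use)
  h <- lapply(1:3, function(k) {
    vapply(use, function(p) p$cdrs[[k]], "")
  })
  nd <- lapply(h, function(s) {
    lev <- utils::adist(s)
    den <- outer(nchar(s), nchar(s), `+`) + lev
    d <- 2 * lev / den
    d[den == 0] <- 0
    d
  })
  cdr <- 1 - (nd[[1]] + nd[[2]] + nd[[3]]) / 3
  h3len <- nchar(h[[3]])
  para <- lapply(use, function(p) {
    list(num = p$numbering[p$mask],
         aa = substring(p$aa, which(p$mask), which(p$mask)))
  })
  tokens <- lapply(use, .abligity_tokens, distance_bin = distance_bin)
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- unlist(lapply(2:n, function(k) k:n))
  m <- length(ii)
  pty <- numeric(m)
  abl <- rep(NA_real_, m)
  for (q in seq_len(m)) {
    pa <- para[[ii[q]]]; pb <- para[[jj[q]]]
    if (!length(pa$num) || !length(pb$num)) {
      pty[q] <- NA_real_
      next
    }
    common <- intersect(pa$num, pb$num)
    pty[q] <- if (!length(common)) 0 else
      sum(pa$aa[match(common, pa$num)] == pb$aa[match(common, pb$num)]) /
        min(length(pa$num), length(pb$num))
  }
  cdr_p <- cdr[cbind(ii, jj)]
  same_len <- h3len[ii] == h3len[jj]
  v12 <- (cdr_p > thresholds[["cdr"]]) +
    ifelse(is.na(pty), 0, pty > thresholds[["paratype"]])
  need_abl <- same_len & v12 >= 1
  for (q in which(need_abl)) {
    ta <- tokens[[ii[q]]]; tb <- tokens[[jj[q]]]
    if (!is.null(ta) && !is.null(tb)) abl[q] <- .tanimoto(ta, tb)
  }
  votes <- v12 + ifelse(is.na(abl), 0, abl > thresholds[["abligity"]])
  ids <- vapply(use, `[[`, "", "id")
  data.frame(id_a = ids[ii], id_b = ids[jj],
             clone_a = vapply(use, `[[`, "", "clone_id")[ii],
             clone_b = vapply(use, `[[`, "", "clone_id")[jj],
             gc_a = vapply(use, `[[`, "", "gc_id")[ii],
             gc_b = vapply(use, `[[`, "", "gc_id")[jj],
             cdr_similarity = cdr_p, paratype_identity = pty,
             abligity_score = abl, votes = votes,
             same_cdr3_length = same_len,
             predicted = votes >= 2 & same_len,
             paratope_distance = paratope_distance(pty, cdr_p),
             stringsAsFactors = FALSE)
}

#' Structural (epitope binder) groups among dominant clones
#'
#' Selects the top `rank_threshold` clones per GC by abundance, evaluates
#' every pair of selected (clone, GC) profiles with
#' [predict_common_epitope()], links predicted pairs into a graph, and
#' returns its connected components as epitope groups, with per-group GC
#' occupancy and a per-GC group-size summary.
#'
#' @param profiles list of `paratope_profile` objects (one per clone per
#'   GC).
#' @param gc_abundance data.frame `clone_id`, `gc_id`, `abundance` (one
#'   row per clone per GC).
#' @param rank_threshold dominance ranking cut per GC (default 300).
#' @param thresholds,distance_bin passed to [predict_common_epitope()].
#' @param clones optional `clone_set$clones` table to categorize pairs.
#' @return list: `groups` (data.frame `id`, `clone_id`, `gc_id`, `group`),
#'   `pairs` (all evaluated pairs with predictions and categories),
#'   `group_gc_occupancy`, `group_sizes_by_gc`, `short_gcs`.
#' @export
epitope_groups <- function(profiles, gc_abundance, rank_threshold = 300L,
                           thresholds = .DEFAULT_THRESHOLDS,
                           distance_bin = 1.0, clones = NULL) {
  ab <- aggregate(abundance ~ clone_id + gc_id, data = gc_abundance, sum)
  sel <- do.call(rbind, lapply(split(ab, ab$gc_id), function(d) {
    d[order(-d$abundance, d$clone_id), ][seq_len(min(rank_threshold,
                                                     nrow(d))), ]
  }))
  short <- names(which(table(ab$gc_id) < rank_threshold))
  keys <- paste(sel$clone_id, sel$gc_id, sep = "@")
  prof_keys <- vapply(profiles, function(p) {
    paste(p$clone_id, p$gc_id, sep = "@")
  }, "")
  use <- profiles[prof_keys %in% keys]
  use <- use[order(vapply(use, `[[`, "", "id"))]
  n <- length(use)
  pairs <- if (n >= 2) {
    .evaluate_all_pairs(use, thresholds, distance_bin)
  }
  if (!is.null(pairs) && !is.null(clones)) {
    pairs$category <- vapply(seq_len(nrow(pairs)), function(i) {
      if (!pairs$predicted[i]) return(NA_character_)
      categorize_pair(pairs[i, ], clones)
    }, character(1))
  }
  ids <- vapply(use, `[[`, "", "id")
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (!is.null(pairs) && any(pairs$predicted)) {
    e <- pairs[pairs$predicted, c("id_a", "id_b")]
    g <- igraph::add_edges(g, rbind(match(e$id_a, ids), match(e$id_b, ids)))
  }
  comp <- igraph::components(g)$membership
  groups <- data.frame(id = ids,
                       clone_id = vapply(use, `[[`, "", "clone_id"),
                       gc_id = vapply(use, `[[`, "", "gc_id"),
                       group = unname(comp),
                       stringsAsFactors = FALSE)
  occ <- tapply(groups$gc_id, groups$group, function(x) length(unique(x)))
  sizes <- tapply(groups$id, list(groups$gc_id, groups$group), length)
  sizes[is.na(sizes)] <- 0
  list(groups = groups, pairs = pairs,
       group_gc_occupancy = occ,
       group_sizes_by_gc = sizes,
       short_gcs = short)
}

#' Estimate the number of targeted epitopes
#'
#' The raw estimate is the number of structural groups; because pair
#' recall may be low, a recall-corrected estimate scales the raw count by
#' the assumed pair recall (missed pairs would merge groups).
#'
#' @param groups output of [epitope_groups()] (or an integer group count).
#' @param pair_recall assumed recall of the pair prediction in `(0, 1]`.
#' @return list `raw_count`, `recall_corrected_count`, `pair_recall`.
#' @export
estimate_epitopes <- function(groups, pair_recall = 0.1) {
  if (pair_recall <= 0 || pair_recall > 1) {
    stop("pair_recall must be in (0, 1]")
  }
  raw <- if (is.list(groups)) length(unique(groups$groups$group)) else
    as.integer(groups)
  list(raw_count = raw,
       recall_corrected_count = raw * pair_recall,
       pair_recall = pair_recall)
}
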