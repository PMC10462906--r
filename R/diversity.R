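# Sample similarity and clonal diversity in Hill's framework.
#
# Counts are duplicate-count weighted (genomic DNA: one rearrangement is
# one cell). Diversity indices reported: dominance (1 / ^infD), observed
# and bias-corrected Chao1 richness (^0D), coverage-adjusted (Chao-Shen)
# Shannon entropy in nats (log ^1D), and evenness (^1D / ^0D).

#' Clonal abundance of one sample
#'
#' @param counts named integer vector of per-clone counts (cells).
#' @param sample_id optional sample label.
#' @return a `clonal_abundance`: list with `entries` (counts), `n` (total),
#'   `p` (normalized fractions summing to 1).
#' @export
clonal_abundance <- function(counts, sample_id = NA_character_) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("empty sample: no positive counts")
  if (is.null(names(counts))) names(counts) <- as.character(seq_along(counts))
  structure(list(sample_id = sample_id, entries = counts,
                 n = sum(counts), p = counts / sum(counts)),
            class = "clonal_abundance")
}

#' Sorensen-Dice similarity between two samples
#'
#' `1 - sum_i |x_i - y_i| / 2` over the union of clones, on normalized
#' abundances. One for identical samples, zero for samples sharing no
#' clone.
#'
#' @param x,y `clonal_abundance` objects.
#' @return similarity in `[0, 1]`.
#' @export
dice_similarity <- function(x, y) {
  stopifnot(inherits(x, "clonal_abundance"), inherits(y, "clonal_abundance"))
  ids <- union(names(x$p), names(y$p))
  px <- setNames(rep(0, length(ids)), ids); px[names(x$p)] <- x$p
  py <- setNames(rep(0, length(ids)), ids); py[names(y$p)] <- y$p
  1 - sum(abs(px - py)) / 2
}

#' Dominance of the most abundant clone
#'
#' @param x a `clonal_abundance`.
#' @return `max_i p_i`.
#' @export
dominance <- function(x) {
  stopifnot(inherits(x, "clonal_abundance"))
  max(x$p)
}

#' Bias-corrected Chao1 richness
#'
#' `N_obs + f1 (f1 - 1) / (2 (f2 + 1))`, where `f1` and `f2` are the
#' numbers of clones observed exactly once and twice.
#'
#' @param x a `clonal_abundance`.
#' @return estimated richness (>= observed richness).
#' @export
chao1_richness <- function(x) {
  stopifnot(inherits(x, "clonal_abundance"))
  f1 <- sum(x$entries == 1)
  f2 <- sum(x$entries == 2)
  length(x$entries) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Coverage-adjusted (Chao-Shen) Shannon entropy
#'
#' With sample coverage `C = 1 - f1/n` and adjusted abundances
#' `p~_i = C p_i`, the entropy estimate is
#' `H = -sum_i p~_i ln(p~_i) / (1 - (1 - p~_i)^n)`, in nats. When `C = 0`
#' (all clones are singletons) the estimator is undefined and the plug-in
#' entropy `-sum p_i ln p_i` is returned with a warning.
#'
#' @param x a `clonal_abundance` with `n >= 2`.
#' @return entropy in nats.
#' @export
shannon_chao <- function(x) {
  stopifnot(inherits(x, "clonal_abundance"))
  if (x$n < 2) stop("need a sample of at least 2 cells")
  f1 <- sum(x$entries == 1)
  C <- 1 - f1 / x$n
  if (C == 0) {
    warning("zero coverage (all singletons); returning plug-in entropy")
    return(-sum(x$p * log(x$p)))
  }
  pt <- C * x$p
  -sum(pt * log(pt) / (1 - (1 - pt)^x$n))
}

#' Evenness
#'
#' `exp(H_Chao) / N_Chao` (`^1D / ^0D`), clipped to `[0, 1]`; one for a
#' perfectly homogeneous sample.
#'
#' @param x a `clonal_abundance`.
#' @return evenness in `[0, 1]`.
#' @export
evenness <- function(x) {
  e <- exp(shannon_chao(x)) / chao1_richness(x)
  min(1, max(0, e))
}

#' Full diversity profile of one sample
#'
#' @param x a `clonal_abundance`.
#' @return one-row data.frame: `sample_id`, `n`, `dominance`,
#'   `richness_obs`, `richness_chao`, `shannon_chao`, `evenness`, `f1`,
#'   `f2`, `coverage`.
#' @export
diversity_profile <- function(x) {
  stopifnot(inherits(x, "clonal_abundance"))
  f1 <- sum(x$entries == 1)
  f2 <- sum(x$entries == 2)
  data.frame(sample_id = x$sample_id, n = x$n,
             dominance = dominance(x),
             richness_obs = length(x$entries),
             richness_chao = chao1_richness(x),
             shannon_chao = shannon_chao(x),
             evenness = evenness(x),
             f1 = f1, f2 = f2, coverage = 1 - f1 / x$n,
             stringsAsFactors = FALSE)
}

#' Dominant / expanded / non-expanded abundance classes
#'
#' Exactly one dominant clone (the most abundant; ties broken by clone
#' id); remaining clones with frequency strictly above
#' `expanded_threshold` are expanded; the rest are non-expanded.
#'
#' @param x a `clonal_abundance`.
#' @param expanded_threshold frequency cut for expansion (default 1%).
#' @return data.frame `clone_id`, `frequency`, `class`.
#' @export
abundance_classes <- function(x, expanded_threshold = 0.01) {
  stopifnot(inherits(x, "clonal_abundance"))
  ids <- names(x$p)
  dom <- ids[order(-x$p, ids)][1]
  cls <- ifelse(ids == dom, "dominant",
                ifelse(x$p > expanded_threshold, "expanded", "non_expanded"))
  data.frame(clone_id = ids, frequency = unname(x$p), class = cls,
             stringsAsFactors = FALSE)
}

#' Size-matched null sample from the pooled lymph node
#'
#' Draws `n` cells uniformly without replacement from the pooled abundance
#' (multivariate hypergeometric), emulating an artificial sample of
#' equivalent size used to show that per-GC diversity differences are not
#' a sub-sampling artifact.
#'
#' @param pooled a `clonal_abundance` of all GCs combined.
#' @param n cells to draw (`n <= pooled$n`).
#' @param seed integer seed.
#' @return a `clonal_abundance`.
#' @export
subsampled_null <- function(pooled, n, seed = 1L) {
  stopifnot(inherits(pooled, "clonal_abundance"))
  if (n > pooled$n) stop("n exceeds the pooled sample size")
  if (n == pooled$n) return(pooled)
  set.seed(seed)
  cells <- rep(names(pooled$entries), pooled$entries)
  drawn <- sample(cells, n)
  clonal_abundance(table(drawn) |> c(), sample_id = "null")
}

#' V-gene usage among each GC's top-k clones
#'
#' Counts how often each V gene appears among the `top_k` most abundant
#' clones of each GC, and the number of GCs whose top-k contains each V
#' gene. GCs with fewer than `top_k` clones use all their clones and are
#' flagged.
#'
#' @param clone_gc data.frame with `clone_id`, `gc_id`, `abundance`,
#'   `v_gene` (one row per clone per GC).
#' @param top_k clones per GC to consider (default 15).
#' @return list: `counts` (v_gene x gc_id matrix), `gcs_per_vgene`,
#'   `marginal` (overall frequency among selected clones),
#'   `short_gcs` (GCs with fewer than `top_k` clones).
#' @export
vgene_usage <- function(clone_gc, top_k = 15L) {
  sel <- do.call(rbind, lapply(split(clone_gc, clone_gc$gc_id), function(d) {
    d[order(-d$abundance, d$clone_id), ][seq_len(min(top_k, nrow(d))), ]
  }))
  short <- names(which(table(clone_gc$gc_id) < top_k))
  counts <- table(sel$v_gene, sel$gc_id)
  list(counts = counts,
       gcs_per_vgene = rowSums(counts > 0),
       marginal = rowSums(counts) / sum(counts),
       short_gcs = short)
}
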