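# Inter-GC clone sharing and the Poisson reactivation model.
#
# A clone belongs to a GC only if it is consistently identified in both
# NGS replicates of that GC (the replicate-consistency gate). The number
# of GCs a clone occupies beyond its founding one is modeled as Poisson
# with mean mu = lambda * t: the memoryless reactivation of a GC B cell
# seeding another GC.

#' Replicate-consistent clone presence per GC
#'
#' @param clone_set a `clone_set`.
#' @param records rearrangement data.frame with `gc_id`, `replicate_id`.
#' @return logical matrix clones x GCs: TRUE where the clone has at least
#'   one sequence in every replicate of that GC.
#' @export
consistent_presence <- function(clone_set, records) {
  m <- merge(clone_set$membership,
             records[, c("sequence_id", "gc_id", "replicate_id")],
             by = "sequence_id")
  reps_per_gc <- tapply(records$replicate_id, records$gc_id,
                        function(x) length(unique(x)))
  if (any(reps_per_gc < 2)) {
    stop("replicate-consistency gate undefined: GC(s) with a single ",
         "replicate: ",
         paste(names(reps_per_gc)[reps_per_gc < 2], collapse = ", "))
  }
  gcs <- sort(unique(records$gc_id))
  clones <- clone_set$clones$clone_id
  out <- matrix(FALSE, length(clones), length(gcs),
                dimnames = list(clones, gcs))
  tab <- tapply(m$replicate_id, list(m$clone_id, m$gc_id),
                function(x) length(unique(x)))
  tab[is.na(tab)] <- 0
  out[rownames(tab), colnames(tab)] <-
    tab >= rep(reps_per_gc[colnames(tab)], each = nrow(tab))
  out
}

#' Histogram of the number of GCs per clone
#'
#' Counts, for each k >= 1, the clones consistently present in exactly k
#' GCs (replicate gate applied). Clones failing the gate in every GC are
#' excluded and counted. The `expanded_counts` variant restricts to clones
#' whose within-GC frequency exceeds `dominance_threshold` in more than
#' one GC.
#'
#' @param clone_set a `clone_set`.
#' @param records rearrangement data.frame.
#' @param dominance_threshold within-GC frequency cut for the expanded
#'   summary (default 0.1%).
#' @return a `sharing_histogram`: list with `counts` (named by k),
#'   `total_clones`, `shared_fraction` (k >= 2), `n_gated_out`,
#'   `expanded_multi_gc` (clones above the dominance cut in > 1 GC), `k`
#'   (named per-clone k vector).
#' @export
sharing_histogram <- function(clone_set, records,
                              dominance_threshold = 0.001) {
  pres <- consistent_presence(clone_set, records)
  k <- rowSums(pres)
  gated_out <- sum(k == 0)
  k <- k[k >= 1]
  counts <- table(k)
  # within-GC frequencies (replicates pooled), gated by presence
  ab <- clone_sample_abundance(clone_set, records)
  gc_ab <- aggregate(abundance ~ clone_id + gc_id, data = ab, sum)
  tot <- tapply(gc_ab$abundance, gc_ab$gc_id, sum)
  gc_ab$freq <- gc_ab$abundance / tot[gc_ab$gc_id]
  gc_ab$gated <- pres[cbind(gc_ab$clone_id, gc_ab$gc_id)]
  exp_tab <- tapply(gc_ab$freq > dominance_threshold & gc_ab$gated,
                    gc_ab$clone_id, sum)
  structure(list(counts = counts,
                 total_clones = length(k),
                 shared_fraction = sum(k >= 2) / length(k),
                 n_gated_out = gated_out,
                 expanded_multi_gc = sum(exp_tab > 1, na.rm = TRUE),
                 k = k),
            class = "sharing_histogram")
}

#' Fit the Poisson reactivation model to a sharing histogram
#'
#' Under the default shifted parameterization every observed clone
#' occupies its home GC and seeds `N ~ Poisson(mu)` additional ones, so
#' the observed occupancy is `k = 1 + N` and the maximum-likelihood
#' estimate is `mu = mean(k) - 1` in closed form. The alternative
#' zero-truncated parameterization treats `k` as a Poisson count
#' conditioned on `k >= 1` and solves `mu / (1 - exp(-mu)) = mean(k)`.
#'
#' @param hist a `sharing_histogram` (or named count vector over k) with
#'   at least 10 clones.
#' @param method `"shifted"` (default) or `"zero_truncated"`.
#' @param lifetime_days optional GC lifetime to convert mu into a per-day
#'   seeding rate.
#' @return a `poisson_sharing_fit`: list with `mu`, `p_reactivation`,
#'   `lambda_per_day`, `lifetime_days`, `fit_method`, `log_likelihood`,
#'   `degenerate` (TRUE when all k = 1).
#' @export
fit_poisson <- function(hist, method = c("shifted", "zero_truncated"),
                        lifetime_days = NULL) {
  method <- match.arg(method)
  counts <- if (inherits(hist, "sharing_histogram")) hist$counts else hist
  ks <- as.integer(names(counts))
  n <- as.numeric(counts)
  if (sum(n) < 10) stop("need at least 10 clones to fit")
  if (any(ks < 1)) stop("occupancies must be >= 1")
  mean_k <- sum(ks * n) / sum(n)
  degenerate <- all(ks == 1)
  if (method == "shifted") {
    mu <- mean_k - 1
    ll <- sum(n * stats::dpois(ks - 1, max(mu, 1e-12), log = TRUE))
  } else {
    if (degenerate) {
      mu <- 0
      ll <- 0
    } else {
      f <- function(m) m / (1 - exp(-m)) - mean_k
      mu <- stats::uniroot(f, c(1e-8, 100))$root
      ll <- sum(n * (stats::dpois(ks, mu, log = TRUE) -
                       log(1 - exp(-mu))))
    }
  }
  structure(list(mu = mu,
                 p_reactivation = reactivation_probability(mu),
                 lifetime_days = lifetime_days,
                 lambda_per_day = if (!is.null(lifetime_days))
                   seeding_rate(mu, lifetime_days),
                 fit_method = method,
                 log_likelihood = ll,
                 mean_k = mean_k,
                 degenerate = degenerate),
            class = "poisson_sharing_fit")
}

#' @export
print.poisson_sharing_fit <- function(x, ...) {
  cat(sprintf("Poisson reactivation fit (%s): mu = %.4f, P(N>=1) = %.1f%%\n",
              x$fit_method, x$mu, 100 * x$p_reactivation))
  if (!is.null(x$lambda_per_day)) {
    cat(sprintf("  seeding rate: %.4g per clone per day (lifetime %g d)\n",
                x$lambda_per_day, x$lifetime_days))
  }
  invisible(x)
}

#' Probability that a clone seeds at least one other GC
#'
#' `P(N >= 1) = 1 - exp(-mu)` under the Poisson reactivation model.
#'
#' @param mu Poisson mean (>= 0).
#' @return probability in `[0, 1)`.
#' @export
reactivation_probability <- function(mu) {
  if (any(mu < 0)) stop("mu must be non-negative")
  1 - exp(-mu)
}

#' Per-day seeding rate
#'
#' `lambda = mu / t` for a GC lifetime of `t` days.
#'
#' @param mu Poisson mean.
#' @param lifetime_days GC lifetime in days (> 0).
#' @return seedings per clone per day.
#' @export
seeding_rate <- function(mu, lifetime_days) {
  if (any(lifetime_days <= 0)) stop("lifetime_days must be positive")
  mu / lifetime_days
}

#' Fraction of CDR3 groups shared among GCs
#'
#' Applies the replicate-consistency gate at the level of identical CDR3
#' amino-acid groups and counts groups present in at least two GCs.
#'
#' @param cdr3_groups output of [group_by_cdr3()].
#' @param records rearrangement data.frame.
#' @return list `shared`, `total`, `fraction`.
#' @export
shared_cdr3_fraction <- function(cdr3_groups, records) {
  m <- merge(cdr3_groups$membership,
             records[, c("sequence_id", "gc_id", "replicate_id")],
             by = "sequence_id")
  reps_per_gc <- tapply(records$replicate_id, records$gc_id,
                        function(x) length(unique(x)))
  tab <- tapply(m$replicate_id, list(m$cdr3_aa, m$gc_id),
                function(x) length(unique(x)))
  tab[is.na(tab)] <- 0
  gated <- tab >= rep(reps_per_gc[colnames(tab)], each = nrow(tab))
  k <- rowSums(gated)
  total <- sum(k >= 1)
  shared <- sum(k >= 2)
  list(shared = shared, total = total,
       fraction = if (total > 0) shared / total else 0)
}
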