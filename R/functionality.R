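# Functionality classification, allele pairing, and SHM summaries.
#
# Sequence classes: functional / out_of_frame / vdj_stop / shm_stop.
# Frame status is evaluated first (most non-functional rearrangements are
# frameshift-derived); among in-frame stop-bearing sequences, a stop codon
# overlapping an N-region interval by at least one nucleotide indicates a
# V(D)J recombination error (vdj_stop), otherwise the stop is attributed
# to somatic hypermutation (shm_stop).

.N_COLS <- c("n1_start", "n1_end", "n2_start", "n2_end")

#' Classify sequences by functionality
#'
#' @param records rearrangement data.frame.
#' @return data.frame `sequence_id`, `functional_class`, `stop_codons`
#'   (comma-separated 0-based codon indices, empty unless a stop class).
#' @export
classify_sequences <- function(records) {
  n <- nrow(records)
  cls <- character(n)
  stops_out <- character(n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    if (!r$in_frame_junction || r$junction_length %% 3L != 0L) {
      cls[i] <- "out_of_frame"
      stops_out[i] <- ""
      next
    }
    st <- .stop_codon_indices(r$sequence)
    if (length(st) == 0) {
      cls[i] <- "functional"
      stops_out[i] <- ""
      next
    }
    if (anyNA(unlist(r[.N_COLS]))) {
      stop("record ", r$sequence_id, " carries an in-frame stop codon but ",
           "no N-region bounds; cannot attribute the stop to V(D)J ",
           "recombination or SHM")
    }
    s0 <- 3L * st
    s1 <- s0 + 3L
    in_n <- (s0 < r$n1_end & s1 > r$n1_start) |
      (s0 < r$n2_end & s1 > r$n2_start)
    cls[i] <- if (any(in_n)) "vdj_stop" else "shm_stop"
    stops_out[i] <- paste(st, collapse = ",")
  }
  data.frame(sequence_id = records$sequence_id, functional_class = cls,
             stop_codons = stops_out, stringsAsFactors = FALSE)
}

#' Productivity index of a clone
#'
#' Fraction of productive (functional) sequences among a clone's members,
#' weighted by duplicate count when provided.
#'
#' @param classes character vector of member classes.
#' @param weights optional duplicate counts.
#' @return fraction in `[0, 1]`.
#' @export
productivity_index <- function(classes, weights = NULL) {
  if (length(classes) == 0) stop("empty clone")
  if (is.null(weights)) weights <- rep(1, length(classes))
  sum(weights[classes == "functional"]) / sum(weights)
}

#' Classify a clone as F, NF or F_and_NF
#'
#' Functional (`F`) when the productivity index exceeds 0.95,
#' non-functional (`NF`) below 0.05, otherwise `F_and_NF` (both
#' inequalities strict).
#'
#' @param index productivity index in `[0, 1]`.
#' @return `"F"`, `"NF"` or `"F_and_NF"`.
#' @export
classify_clone <- function(index) {
  ifelse(index > 0.95, "F", ifelse(index < 0.05, "NF", "F_and_NF"))
}

#' Clone-level functionality table
#'
#' Convenience wrapper: per-clone productivity index and F/NF/F_and_NF
#' class from sequence labels.
#'
#' @param clone_set a `clone_set`.
#' @param records rearrangement data.frame.
#' @param labels output of [classify_sequences()] (computed if NULL).
#' @return data.frame `clone_id`, `productivity_index`, `clone_class`.
#' @export
clone_functionality <- function(clone_set, records, labels = NULL) {
  if (is.null(labels)) labels <- classify_sequences(records)
  m <- merge(clone_set$membership, labels, by = "sequence_id")
  m <- merge(m, records[, c("sequence_id", "duplicate_count")],
             by = "sequence_id")
  idx <- vapply(split(m, m$clone_id), function(d) {
    productivity_index(d$functional_class, d$duplicate_count)
  }, numeric(1))
  data.frame(clone_id = names(idx), productivity_index = unname(idx),
             clone_class = classify_clone(unname(idx)),
             stringsAsFactors = FALSE)
}

#' Pair functional with non-functional alleles by abundance
#'
#' A B cell carrying a passenger non-functional IGH allele contributes the
#' same cells to both rearrangements, so a non-functional clone of similar
#' abundance to a functional clone in the same GC (consistently in both
#' replicates) is interpreted as its partner allele. Matching is greedy
#' and one-to-one within each GC: NF clones are processed by descending
#' abundance and matched to the unmatched F clone minimizing
#' `|log2(NF/F)|`, accepted iff that value is at most `max_log2_ratio` and
#' both clones are present in both replicates of the GC.
#'
#' @param clone_classes data.frame from [clone_functionality()].
#' @param gc_abundance data.frame from [clone_sample_abundance()].
#' @param max_log2_ratio acceptance tolerance on the log2 abundance ratio.
#' @return data.frame `gc_id`, `nonfunctional_clone_id`,
#'   `functional_clone_id`, `nf_abundance`, `f_abundance`, `ratio`,
#'   sorted by ratio closeness; unmatched NF clones in the
#'   `unmatched` attribute.
#' @export
pair_alleles <- function(clone_classes, gc_abundance, max_log2_ratio = 1.0) {
  reps <- unique(gc_abundance$replicate_id)
  ab <- aggregate(abundance ~ clone_id + gc_id, data = gc_abundance, sum)
  nrep <- aggregate(replicate_id ~ clone_id + gc_id, data = gc_abundance,
                    function(x) length(unique(x)))
  ab$consistent <- nrep$replicate_id[match(paste(ab$clone_id, ab$gc_id),
                                           paste(nrep$clone_id,
                                                 nrep$gc_id))] ==
    length(reps)
  cls <- setNames(clone_classes$clone_class, clone_classes$clone_id)
  pairs <- list()
  unmatched <- list()
  for (gc in sort(unique(ab$gc_id))) {
    d <- ab[ab$gc_id == gc & ab$consistent, ]
    f <- d[cls[d$clone_id] == "F", ]
    nf <- d[cls[d$clone_id] == "NF", ]
    nf <- nf[order(-nf$abundance, nf$clone_id), ]
    used <- character(0)
    for (i in seq_len(nrow(nf))) {
      avail <- f[!(f$clone_id %in% used), ]
      if (nrow(avail) == 0) {
        unmatched[[length(unmatched) + 1L]] <-
          data.frame(gc_id = gc, clone_id = nf$clone_id[i])
        next
      }
      lr <- abs(log2(nf$abundance[i] / avail$abundance))
      j <- order(lr, avail$clone_id)[1]
      if (lr[j] <= max_log2_ratio) {
        used <- c(used, avail$clone_id[j])
        pairs[[length(pairs) + 1L]] <- data.frame(
          gc_id = gc,
          nonfunctional_clone_id = nf$clone_id[i],
          functional_clone_id = avail$clone_id[j],
          nf_abundance = nf$abundance[i],
          f_abundance = avail$abundance[j],
          ratio = nf$abundance[i] / avail$abundance[j],
          stringsAsFactors = FALSE)
      } else {
        unmatched[[length(unmatched) + 1L]] <-
          data.frame(gc_id = gc, clone_id = nf$clone_id[i])
      }
    }
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gc_id = character(0), nonfunctional_clone_id = character(0),
               functional_clone_id = character(0), nf_abundance = numeric(0),
               f_abundance = numeric(0), ratio = numeric(0))
  out <- out[order(abs(log2(out$ratio))), ]
  rownames(out) <- NULL
  attr(out, "unmatched") <- if (length(unmatched)) do.call(rbind, unmatched)
  out
}

#' Clone-consensus mutational spectrum
#'
#' For each clone with at least two members of equal sequence length, the
#' reference is the position-wise most common base among members
#' (duplicate-count weighted); mismatches to it are counted per position
#' and aggregated over clones into a per-position mutation frequency.
#' Positions are comparable across clones over the fixed-length V segment;
#' junction positions are aggregated by offset from the junction start.
#' Also fills the 4x4 nucleotide substitution table (reference base ->
#' observed base).
#'
#' @param clone_set a `clone_set`.
#' @param records rearrangement data.frame.
#' @param region_layout region intervals on the V segment (defaults to the
#'   bundled layout).
#' @return list: `position_freq` (data.frame `position`, `region`,
#'   `n_mut`, `n_tot`, `freq` over V-segment positions), `substitution`
#'   (4x4 count matrix, zero diagonal), `n_singleton_clones`.
#' @export
mutational_spectrum <- function(clone_set, records,
                                region_layout = toy_germlines()$v_regions) {
  m <- merge(clone_set$membership,
             records[, c("sequence_id", "sequence", "duplicate_count")],
             by = "sequence_id")
  v_len <- max(vapply(region_layout, max, 0))
  n_mut <- numeric(v_len)
  n_tot <- numeric(v_len)
  sub <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  n_singleton <- 0L
  for (d in split(m, m$clone_id)) {
    if (nrow(d) < 2 || length(unique(nchar(d$sequence))) != 1) {
      n_singleton <- n_singleton + 1L
      next
    }
    mat <- .seq_matrix(d$sequence)
    w <- d$duplicate_count
    L <- min(ncol(mat), v_len)
    for (j in seq_len(L)) {
      tab <- tapply(w, mat[, j], sum)
      ref <- names(sort(tab, decreasing = TRUE))[1]
      mism <- mat[, j] != ref
      n_mut[j] <- n_mut[j] + sum(w[mism])
      n_tot[j] <- n_tot[j] + sum(w)
      if (any(mism)) {
        for (b in unique(mat[mism, j])) {
          if (b %in% rownames(sub) && ref %in% rownames(sub)) {
            sub[ref, b] <- sub[ref, b] + sum(w[mism & mat[, j] == b])
          }
        }
      }
    }
  }
  region <- rep("fwr", v_len)
  for (r in names(region_layout)) {
    iv <- region_layout[[r]]
    region[(iv[1] + 1):iv[2]] <- r
  }
  pf <- data.frame(position = seq_len(v_len), region = region,
                   n_mut = n_mut, n_tot = n_tot,
                   freq = ifelse(n_tot > 0, n_mut / n_tot, NA_real_))
  list(position_freq = pf, substitution = sub,
       n_singleton_clones = n_singleton)
}

#' Replacement and silent mutation counts against a reference
#'
#' Codon-by-codon comparison of an observed sequence to a codon-aligned
#' reference over the V segment: a differing codon whose translation
#' changes is a replacement (R), otherwise silent (S); codons are assigned
#' to the CDR class when their midpoint falls in CDR1 or CDR2, else FWR.
#'
#' @param seq,reference equal-length in-frame DNA strings.
#' @param region_layout V-segment region intervals.
#' @param v_only compare only the first 240 nt (V segment) when TRUE.
#' @return data.frame with `region_class` (`CDR`/`FWR`) and counts `R`,
#'   `S`.
#' @export
rs_counts <- function(seq, reference, region_layout = toy_germlines()$v_regions,
                      v_only = TRUE) {
  L <- min(nchar(seq), nchar(reference))
  if (v_only) L <- min(L, max(vapply(region_layout, max, 0)))
  L <- L - L %% 3L
  out <- c(CDR_R = 0L, CDR_S = 0L, FWR_R = 0L, FWR_S = 0L)
  cdr <- region_layout[c("cdr1", "cdr2")]
  for (c0 in seq(1L, L - 2L, by = 3L)) {
    ref_c <- substr(reference, c0, c0 + 2L)
    obs_c <- substr(seq, c0, c0 + 2L)
    if (ref_c == obs_c) next
    mid <- c0 + 1L  # 1-based midpoint; 0-based = mid - 1
    in_cdr <- any(vapply(cdr, function(iv) mid - 1 >= iv[1] && mid - 1 < iv[2],
                         logical(1)))
    type <- if (translate_dna(ref_c) == translate_dna(obs_c)) "S" else "R"
    key <- paste0(if (in_cdr) "CDR" else "FWR", "_", type)
    out[key] <- out[key] + 1L
  }
  data.frame(region_class = c("CDR", "FWR"),
             R = c(out[["CDR_R"]], out[["FWR_R"]]),
             S = c(out[["CDR_S"]], out[["FWR_S"]]))
}

#' Replacement/silent ratio
#'
#' @param R,S replacement and silent mutation counts.
#' @return `R/S`; `Inf` when `S = 0` and `R > 0`; `NaN` when both are zero.
#' @export
rs_ratio <- function(R, S) {
  if (R == 0 && S == 0) return(NaN)
  if (S == 0) return(Inf)
  R / S
}

#' Per-clone R/S summary against germline V
#'
#' Aggregates [rs_counts()] over a set of clones, using the germline V of
#' each clone's V call as reference for the V segment. Intended for
#' comparing selection pressure between expanded clones and singletons.
#'
#' @param clone_set a `clone_set`.
#' @param records rearrangement data.frame.
#' @param germlines germline set (defaults to the bundled one).
#' @return data.frame per clone: `clone_id`, `n_seqs`, `CDR_R`, `CDR_S`,
#'   `FWR_R`, `FWR_S`, `rs_cdr`, `rs_fwr`.
#' @export
rs_summary <- function(clone_set, records, germlines = toy_germlines()) {
  m <- merge(clone_set$membership,
             records[, c("sequence_id", "sequence", "v_call",
                         "in_frame_junction")],
             by = "sequence_id")
  m <- m[m$in_frame_junction, ]
  rows <- lapply(split(m, m$clone_id), function(d) {
    vg <- gene_of(d$v_call[1])
    if (!vg %in% names(germlines$v)) return(NULL)
    v <- germlines$v[[vg]]
    tot <- c(CDR_R = 0L, CDR_S = 0L, FWR_R = 0L, FWR_S = 0L)
    for (s in d$sequence) {
      rc <- rs_counts(s, v, germlines$v_regions)
      tot <- tot + c(rc$R[1], rc$S[1], rc$R[2], rc$S[2])
    }
    data.frame(clone_id = d$clone_id[1], n_seqs = nrow(d),
               CDR_R = tot[["CDR_R"]], CDR_S = tot[["CDR_S"]],
               FWR_R = tot[["FWR_R"]], FWR_S = tot[["FWR_S"]],
               rs_cdr = rs_ratio(tot[["CDR_R"]], tot[["CDR_S"]]),
               rs_fwr = rs_ratio(tot[["FWR_R"]], tot[["FWR_S"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
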