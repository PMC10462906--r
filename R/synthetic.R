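# Synthetic multi-GC lymph node generator with ground truth.
#
# The generator emulates the structure of a genomic-DNA Rep-seq experiment
# on laser-captured germinal centers: n_gcs GCs, two PCR/NGS replicates per
# GC, heavy-tailed clone sizes (stick-breaking), inter-GC clone sharing as
# "home GC + Poisson(mu) extra seedings", ~90% functional sequences with a
# fixed non-functional composition (frameshift / V(D)J stop / SHM stop),
# CDR-elevated somatic hypermutation, paired functional/non-functional
# alleles at similar abundance, skewed V-gene usage, and planted
# common-epitope clone groups.

#' Configuration for the synthetic lymph node generator
#'
#' Defaults reproduce the study conditions the package is validated
#' against: 10 GCs with 2 replicates each, sharing rate mu = 0.25,
#' functional fraction 0.90 with non-functional composition
#' 0.78/0.11/0.11 (out-of-frame / V(D)J stop / SHM stop), a mean of 3.6
#' mutations before an SHM crippling stop, clone-size skew targeting
#' per-GC dominance of roughly 5--30%, and V-gene usage skewed toward
#' three hot genes.
#'
#' @param n_gcs number of germinal centers.
#' @param n_replicates replicates per GC (the replicate-consistency gate
#'   requires 2).
#' @param seqs_per_sample sequences emitted per (GC, replicate) sample.
#' @param clones_per_gc founder clones seeded per GC.
#' @param sharing_rate_mu Poisson mean of extra GCs seeded per clone.
#' @param functional_fraction target fraction of functional sequences.
#' @param nf_composition simplex over out_of_frame / vdj_stop / shm_stop
#'   within the non-functional fraction.
#' @param dominance_concentration stick-breaking concentration; smaller
#'   values give more dominant clones.
#' @param shm_rate_cdr_multiplier relative SHM rate of CDR vs FWR positions.
#' @param mean_mutations mean SHM mutations per sequence.
#' @param mean_mutations_before_crippling mean mutations acquired before an
#'   SHM-derived crippling stop codon.
#' @param crippled_clone_fraction fraction of functional clones carrying a
#'   crippled (SHM-stop) sublineage.
#' @param crippled_within_clone nominal within-clone fraction of crippled
#'   cells (rescaled per GC to hit the class target exactly in expectation).
#' @param nf_pair_fraction fraction of functional clones carrying a matched
#'   non-functional partner allele.
#' @param shared_abundance_scale abundance down-scaling of a clone in GCs it
#'   seeded but was not founded in.
#' @param unique_variant_fraction unique SHM variants per cell sampled.
#' @param post_crippling_mutation_rate mean extra mutations after crippling.
#' @param n_epitopes number of planted common-epitope groups.
#' @param epitope_group_size clones per planted epitope group.
#' @param epitope_cdr3_divergence fraction of the epitope-group junction
#'   template forming the per-member hypervariable window (keeps group
#'   members below the clonal identity threshold).
#' @param paratope_noise sd of noise on paratope probabilities and
#'   coordinates (\enc{Å}{Angstrom}).
#' @param vgene_hot_weight sampling weight of the three hot V genes relative
#'   to the others.
#' @param seed integer seed; fully determines the output.
#' @return a `lymph_node_config` list.
#' @export
lymph_node_config <- function(n_gcs = 10L,
                              n_replicates = 2L,
                              seqs_per_sample = 5000L,
                              clones_per_gc = 350L,
                              sharing_rate_mu = 0.25,
                              functional_fraction = 0.90,
                              nf_composition = c(out_of_frame = 0.78,
                                                 vdj_stop = 0.11,
                                                 shm_stop = 0.11),
                              dominance_concentration = 12,
                              shm_rate_cdr_multiplier = 3,
                              mean_mutations = 5,
                              mean_mutations_before_crippling = 3.6,
                              crippled_clone_fraction = 0.08,
                              crippled_within_clone = 0.15,
                              nf_pair_fraction = 0.07,
                              shared_abundance_scale = 0.1,
                              unique_variant_fraction = 0.4,
                              post_crippling_mutation_rate = 0.5,
                              n_epitopes = 5L,
                              epitope_group_size = 3L,
                              epitope_cdr3_divergence = 0.33,
                              paratope_noise = 0.05,
                              vgene_hot_weight = 4,
                              seed = 42L) {
  cfg <- as.list(environment())
  if (cfg$n_gcs < 1 || cfg$seqs_per_sample < 1 || cfg$clones_per_gc < 1) {
    stop("degenerate config: n_gcs, seqs_per_sample and clones_per_gc ",
         "must all be >= 1")
  }
  if (cfg$n_replicates < 1) stop("degenerate config: n_replicates must be >= 1")
  if (abs(sum(nf_composition) - 1) > 1e-8) {
    stop("nf_composition must sum to 1")
  }
  if (functional_fraction < 0 || functional_fraction > 1) {
    stop("functional_fraction must be in [0, 1]")
  }
  if (sharing_rate_mu < 0) stop("sharing_rate_mu must be non-negative")
  class(cfg) <- "lymph_node_config"
  cfg
}

# stick-breaking (GEM) weights, normalized
.gem_weights <- function(n, alpha) {
  v <- stats::rbeta(n, 1, alpha)
  w <- v * cumprod(c(1, 1 - v[-n]))
  w / sum(w)
}

# random in-frame, stop-free junction: TGT + N1 + D + N2 + TGG.
# Returns junction string and N-interval offsets (0-based, relative to the
# junction start). For `frame_shift`, one nucleotide is added so the length
# is not a codon multiple; for `plant_stop`, a stop codon is placed
# frame-aligned inside N1.
.random_junction <- function(d_segments, frame_shift = FALSE,
                             plant_stop = FALSE) {
  bases <- c("A", "C", "G", "T")
  repeat {
    n1 <- if (plant_stop) sample(3:12, 1) else sample(0:12, 1)
    n2 <- sample(0:12, 1)
    d <- sample(d_segments, 1)
    len <- 6L + n1 + nchar(d) + n2
    pad <- (3L - len %% 3L) %% 3L
    n2 <- n2 + pad
    n1seq <- paste(sample(bases, n1, replace = TRUE), collapse = "")
    if (plant_stop) {
      # junction starts codon-aligned, so N1 (offset 3) is codon-aligned too
      substr(n1seq, 1, 3) <- sample(.STOP_CODONS, 1)
    }
    j <- paste0("TGT", n1seq, d,
                paste(sample(bases, n2, replace = TRUE), collapse = ""), "TGG")
    if (frame_shift) {
      j <- paste0(substr(j, 1, nchar(j) - 3), sample(bases, 1), "TGG")
    }
    stops <- .stop_codon_indices(j)
    keep <- if (plant_stop) identical(stops, 1L) else length(stops) == 0
    if (!frame_shift && !keep) next
    return(list(junction = j,
                n1 = c(3L, 3L + n1),
                n2 = c(3L + n1 + nchar(d), 3L + n1 + nchar(d) + n2)))
  }
}

# Mutate `k` positions of a character vector of bases. Positions are drawn
# with `weights`; substitutions creating a stop codon (frame 0) are retried
# unless allow_stop; positions in `protected` (1-based) are never touched.
.mutate_chars <- function(chars, k, weights, protected = integer(0),
                          allow_stop = FALSE) {
  if (k <= 0) return(chars)
  n <- length(chars)
  w <- weights
  if (length(protected)) w[protected] <- 0
  k <- min(k, sum(w > 0))
  if (k <= 0) return(chars)
  pos <- sample.int(n, k, prob = w)
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    old <- chars[p]
    for (try in 1:6) {
      nb <- sample(setdiff(bases, old), 1)
      chars[p] <- nb
      if (allow_stop) break
      cod <- (p - 1L) %/% 3L
      codon <- paste(chars[(3L * cod + 1L):min(3L * cod + 3L, n)],
                     collapse = "")
      if (!(codon %in% .STOP_CODONS)) break
      chars[p] <- old
    }
  }
  chars
}

# Epitope-group junction scaffold: a fixed-length (45 nt) template whose
# middle codons form a hypervariable window randomized per member clone,
# while the rest (including the paratope-contributing codons) is conserved
# across the group. Members of one group are therefore distinct clones
# (junction identity well below the clonal threshold) that still share
# near-identical CDR3 flanks -- the signature of convergent selection.
.EPITOPE_JLEN <- 45L

.epitope_template <- function(window_codons) {
  n_cod <- .EPITOPE_JLEN %/% 3L
  repeat {
    core <- paste(sample(c("A", "C", "G", "T"), .EPITOPE_JLEN - 6L,
                         replace = TRUE), collapse = "")
    j <- paste0("TGT", core, "TGG")
    if (length(.stop_codon_indices(j)) == 0) break
  }
  # window: `window_codons` codons centered in the CDR3
  w0 <- (n_cod - window_codons) %/% 2L
  window <- (w0 + 1L):(w0 + window_codons)          # 1-based codon index
  # paratope-contributing CDR3 codons: conserved, outside window and flanks
  avail <- setdiff(2:(n_cod - 1L), window)
  list(junction = j, n1 = c(3L, 9L), n2 = c(.EPITOPE_JLEN - 9L,
                                            .EPITOPE_JLEN - 3L),
       window_codons = window,
       cdr3_mask_codons = sort(sample(avail, 2)))
}

# member junction: template with the hypervariable window resampled
.epitope_member_junction <- function(template) {
  chars <- strsplit(template$junction, "")[[1]]
  ok <- setdiff(apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste0,
                      collapse = ""), .STOP_CODONS)
  for (cod in template$window_codons) {
    chars[(3L * (cod - 1L) + 1L):(3L * cod)] <-
      strsplit(sample(ok, 1), "")[[1]]
  }
  paste(chars, collapse = "")
}

.gc_label <- function(i) sprintf("GC%02d", i)

#' Generate a synthetic lymph node repertoire with ground truth
#'
#' Simulates the full multi-GC, replicated, annotated repertoire described
#' in [lymph_node_config()]. Per GC, founder clones receive stick-breaking
#' weights; each clone seeds `1 + Poisson(mu)` GCs (its home GC plus extra
#' ones where its abundance is down-scaled); sequence class masses are
#' balanced per GC so the expected functional fraction and non-functional
#' composition equal their configured targets; replicates are independent
#' multinomial resamples of the same GC pool. Somatic hypermutation places
#' substitutions with CDR-elevated rates and avoids creating stop codons in
#' functional lineages; crippled sublineages acquire a planted stop codon
#' outside the N-regions after a Poisson number of prior mutations.
#'
#' @param config a [lymph_node_config()].
#' @return list with `records` (rearrangement data.frame as produced by
#'   [read_rearrangements()]), and `truth` containing `sequences`
#'   (per-sequence clone and class labels), `clones` (per-clone home GC,
#'   latent Poisson seeding count, realized occupancy, type, allele partner
#'   and epitope label) and `epitopes` (planted templates used by
#'   [generate_paratopes()]).
#' @export
generate_lymph_node <- function(config = lymph_node_config()) {
  stopifnot(inherits(config, "lymph_node_config"))
  set.seed(config$seed)
  g <- toy_germlines()
  n_gcs <- config$n_gcs
  hot <- c("IGHV1-2", "IGHV2-5", "IGHV1-18")
  vw <- setNames(rep(1, length(g$v)), names(g$v))
  vw[hot] <- config$vgene_hot_weight

  nfc <- config$nf_composition
  p_oof_given_struct <- nfc[["out_of_frame"]] /
    (nfc[["out_of_frame"]] + nfc[["vdj_stop"]])

  ## ---- founder clones -------------------------------------------------
  clones <- list()
  uid <- 0L
  new_clone <- function(home, type, w, partner_of = NA_integer_,
                        v_call = NULL, j_call = NULL, junction = NULL) {
    uid <<- uid + 1L
    if (is.null(v_call)) v_call <- sample(names(g$v), 1, prob = vw)
    if (is.null(j_call)) j_call <- sample(names(g$j), 1)
    if (is.null(junction)) {
      junction <- .random_junction(g$d,
                                   frame_shift = type == "out_of_frame",
                                   plant_stop = type == "vdj_stop")
    }
    list(uid = uid, home_gc = home, type = type, weight = w,
         v_call = v_call, j_call = j_call,
         junction = junction$junction, n1 = junction$n1, n2 = junction$n2,
         partner_of = partner_of, epitope = NA_integer_,
         crippled = FALSE, k_prior = NA_integer_,
         n_extra = 0L, extra_gcs = integer(0))
  }

  for (gc in seq_len(n_gcs)) {
    # GCs are distinct competitive environments: per-GC concentration is
    # drawn around the configured base so dominance spans a wide range
    alpha_gc <- stats::runif(1, config$dominance_concentration / 2,
                             config$dominance_concentration * 2)
    wf <- .gem_weights(config$clones_per_gc, alpha_gc)
    for (i in seq_len(config$clones_per_gc)) {
      clones[[length(clones) + 1L]] <- new_clone(gc, "functional", wf[i])
    }
  }

  ## ---- planted epitope groups (among the largest functional clones) ----
  epitopes <- list()
  if (config$n_epitopes > 0 && config$epitope_group_size > 1) {
    fun_idx <- which(vapply(clones, function(x) x$type == "functional",
                            logical(1)))
    ord <- fun_idx[order(-vapply(clones[fun_idx], `[[`, 0, "weight"))]
    need <- config$n_epitopes * config$epitope_group_size
    picked <- ord[seq_len(min(need, length(ord)))]
    # interleave so each group spans several GCs
    grp <- rep(seq_len(config$n_epitopes),
               length.out = length(picked))
    n_cod <- .EPITOPE_JLEN %/% 3L
    window_codons <- max(3L, round(config$epitope_cdr3_divergence * n_cod))
    for (e in seq_len(config$n_epitopes)) {
      tmpl <- .epitope_template(window_codons)
      v_call <- sample(names(g$v), 1, prob = vw)
      j_call <- sample(names(g$j), 1)
      # planted paratope mask, in residue numbering (V 1..80, CDR3 100+i)
      mask_numbering <- sort(c(sample(26:33, 4), sample(51:58, 4),
                               100L + tmpl$cdr3_mask_codons))
      members <- picked[grp == e]
      taken <- character(0)
      for (ci in members) {
        # distinct clones: members must differ well beyond the clonal
        # identity threshold in their hypervariable window
        repeat {
          jx <- .epitope_member_junction(tmpl)
          if (!length(taken) ||
              min(vapply(taken, function(t) .hamming(jx, t), 0)) >= 12) {
            break
          }
        }
        taken <- c(taken, jx)
        clones[[ci]]$v_call <- v_call
        clones[[ci]]$j_call <- j_call
        clones[[ci]]$junction <- jx
        clones[[ci]]$n1 <- tmpl$n1
        clones[[ci]]$n2 <- tmpl$n2
        clones[[ci]]$epitope <- e
      }
      epitopes[[e]] <- list(epitope = e, v_call = v_call, j_call = j_call,
                            junction_template = tmpl$junction,
                            junction_length = .EPITOPE_JLEN,
                            window_codons = tmpl$window_codons,
                            mask_numbering = mask_numbering)
    }
  }

  ## ---- NF partner alleles and crippled sublineages ---------------------
  n_fun <- length(clones)
  for (ci in seq_len(n_fun)) {
    cl <- clones[[ci]]
    if (stats::runif(1) < config$nf_pair_fraction) {
      type <- if (stats::runif(1) < p_oof_given_struct) "out_of_frame"
              else "vdj_stop"
      w <- cl$weight * 2^stats::runif(1, -0.5, 0.5)
      clones[[length(clones) + 1L]] <- new_clone(cl$home_gc, type, w,
                                                 partner_of = cl$uid)
    }
    if (stats::runif(1) < config$crippled_clone_fraction) {
      clones[[ci]]$crippled <- TRUE
      clones[[ci]]$k_prior <-
        stats::rpois(1, config$mean_mutations_before_crippling)
    }
  }

  ## ---- sharing: home GC + Poisson(mu) extra GCs ------------------------
  for (ci in seq_along(clones)) {
    if (!is.na(clones[[ci]]$partner_of)) next
    n_extra <- stats::rpois(1, config$sharing_rate_mu)
    clones[[ci]]$n_extra <- n_extra
    k <- min(n_extra, n_gcs - 1L)
    if (k > 0) {
      others <- setdiff(seq_len(n_gcs), clones[[ci]]$home_gc)
      clones[[ci]]$extra_gcs <- sort(sample(others, k))
    }
  }
  # partner alleles travel with the cells that carry them
  for (ci in seq_along(clones)) {
    po <- clones[[ci]]$partner_of
    if (!is.na(po)) {
      clones[[ci]]$n_extra <- clones[[po]]$n_extra
      clones[[ci]]$extra_gcs <- clones[[po]]$extra_gcs
    }
  }

  ## ---- per-clone static data ------------------------------------------
  v_len <- .V_LEN
  for (ci in seq_along(clones)) {
    cl <- clones[[ci]]
    naive <- paste0(g$v[[cl$v_call]], cl$junction, g$j[[cl$j_call]])
    clones[[ci]]$naive <- naive
    jl <- nchar(cl$junction)
    # SHM position weights: CDRs elevated; conserved junction flanks and
    # planted V(D)J stop codons protected
    w <- rep(1, nchar(naive))
    for (r in c("cdr1", "cdr2")) {
      iv <- g$v_regions[[r]]
      w[(iv[1] + 1):iv[2]] <- config$shm_rate_cdr_multiplier
    }
    w[(v_len + 4):(v_len + jl - 3)] <- config$shm_rate_cdr_multiplier
    w[c(v_len + (1:3), v_len + jl - (0:2))] <- 0
    if (cl$type == "vdj_stop") {
      w[v_len + (cl$n1[1] + 1):(cl$n1[1] + 3)] <- 0
    }
    if (!is.na(cl$epitope)) {
      # convergent selection: CDR1/2 and the conserved CDR3 codons of
      # planted epitope binders mutate slowly; paratope residues are fixed
      tmpl <- epitopes[[cl$epitope]]
      for (r in c("cdr1", "cdr2")) {
        iv <- g$v_regions[[r]]
        w[(iv[1] + 1):iv[2]] <- 0.3
      }
      w[(v_len + 1):(v_len + jl)] <- 0.3
      w[c(v_len + (1:3), v_len + jl - (0:2))] <- 0
      for (v in tmpl$mask_numbering) {
        if (v <= 80) {
          w[(3L * (v - 1L) + 1L):(3L * v)] <- 0
        } else if (v > 100) {
          i <- v - 100L
          w[v_len + (3L * (i - 1L) + 1L):(3L * i)] <- 0
        }
      }
    }
    clones[[ci]]$shm_weights <- w
    if (isTRUE(cl$crippled)) {
      chars <- strsplit(naive, "")[[1]]
      chars <- .mutate_chars(chars, cl$k_prior, w)
      # plant a stop via single-base change in a V-segment codon (outside
      # the junction, hence outside the N-regions)
      repeat {
        cod <- sample.int(v_len %/% 3L, 1) - 1L
        span <- (3L * cod + 1L):(3L * cod + 3L)
        codon <- chars[span]
        hit <- FALSE
        for (p in sample(span)) {
          for (b in sample(c("A", "C", "G", "T"))) {
            trial <- codon; trial[p - span[1] + 1L] <- b
            if (paste(trial, collapse = "") %in% .STOP_CODONS && b != chars[p]) {
              chars[p] <- b; hit <- TRUE; break
            }
          }
          if (hit) break
        }
        if (hit) { clones[[ci]]$crippling_codon <- cod; break }
      }
      clones[[ci]]$crippled_ancestor <- chars
      wc <- w
      wc[(3L * clones[[ci]]$crippling_codon + 1L):
           (3L * clones[[ci]]$crippling_codon + 3L)] <- 0
      clones[[ci]]$crippled_weights <- wc
    }
  }

  ## ---- emission per (GC, replicate) ------------------------------------
  t_nf <- 1 - config$functional_fraction
  targets <- c(functional = config$functional_fraction +
                 t_nf * nfc[["shm_stop"]],
               out_of_frame = t_nf * nfc[["out_of_frame"]],
               vdj_stop = t_nf * nfc[["vdj_stop"]])

  clone_type <- vapply(clones, `[[`, "", "type")
  clone_home <- vapply(clones, `[[`, 0, "home_gc")
  clone_weight <- vapply(clones, `[[`, 0, "weight")
  clone_crippled <- vapply(clones, function(x) isTRUE(x$crippled), logical(1))

  rec_list <- list()
  truth_seq <- list()
  for (gc in seq_len(n_gcs)) {
    in_gc <- clone_home == gc |
      vapply(clones, function(x) gc %in% x$extra_gcs, logical(1))
    idx <- which(in_gc)
    wt <- clone_weight[idx] *
      ifelse(clone_home[idx] == gc, 1, config$shared_abundance_scale)
    type <- clone_type[idx]
    # rescale class blocks so expected class masses hit the targets
    p <- wt
    for (tp in names(targets)) {
      sel <- type == tp
      if (any(sel)) p[sel] <- wt[sel] / sum(wt[sel]) * targets[[tp]]
    }
    p <- p / sum(p)
    # within-GC crippled emission probability giving the exact shm_stop mass
    mass_crip <- sum(p[clone_crippled[idx]])
    q_crip <- if (mass_crip > 0) {
      min(0.9, t_nf * nfc[["shm_stop"]] / mass_crip)
    } else 0
    for (rep_i in seq_len(config$n_replicates)) {
      counts <- stats::rmultinom(1, config$seqs_per_sample, p)[, 1]
      sample_rows <- list()
      seq_no <- 0L
      for (k in which(counts > 0)) {
        ci <- idx[k]
        cl <- clones[[ci]]
        n_c <- counts[k]
        n_crip <- if (clone_crippled[ci]) stats::rbinom(1, n_c, q_crip) else 0L
        for (part in c("base", "crip")) {
          n_p <- if (part == "base") n_c - n_crip else n_crip
          if (n_p == 0L) next
          u <- max(1L, round(n_p * config$unique_variant_fraction))
          sizes <- stats::rmultinom(1, n_p, rep(1, u))[, 1]
          sizes <- sizes[sizes > 0]
          for (s in sizes) {
            if (part == "base") {
              chars <- strsplit(cl$naive, "")[[1]]
              kmut <- stats::rpois(1, config$mean_mutations)
              chars <- .mutate_chars(chars, kmut, cl$shm_weights)
              klass <- cl$type
            } else {
              chars <- cl$crippled_ancestor
              kmut <- stats::rpois(1, config$post_crippling_mutation_rate)
              chars <- .mutate_chars(chars, kmut, cl$crippled_weights)
              klass <- "shm_stop"
            }
            seq_no <- seq_no + 1L
            sample_rows[[length(sample_rows) + 1L]] <- list(
              seq = paste(chars, collapse = ""), clone = ci,
              count = s, class = klass)
          }
        }
      }
      # assemble records for this sample
      n_rows <- length(sample_rows)
      seqs <- vapply(sample_rows, `[[`, "", "seq")
      cls <- vapply(sample_rows, `[[`, 0L, "clone")
      cnt <- vapply(sample_rows, `[[`, 0L, "count")
      klass <- vapply(sample_rows, `[[`, "", "class")
      jl <- nchar(vapply(clones[cls], `[[`, "", "junction"))
      ids <- sprintf("%s_R%d_%05d", .gc_label(gc), rep_i, seq_len(n_rows))
      df <- data.frame(
        sequence_id = ids,
        sequence = seqs,
        v_call = vapply(clones[cls], `[[`, "", "v_call"),
        j_call = vapply(clones[cls], `[[`, "", "j_call"),
        junction = substr(seqs, v_len + 1L, v_len + jl),
        junction_length = jl,
        duplicate_count = cnt,
        fwr1_start = 0L, fwr1_end = 75L,
        cdr1_start = 75L, cdr1_end = 99L,
        fwr2_start = 99L, fwr2_end = 150L,
        cdr2_start = 150L, cdr2_end = 174L,
        fwr3_start = 174L, fwr3_end = v_len,
        cdr3_start = v_len + 3L, cdr3_end = v_len + jl - 3L,
        fwr4_start = v_len + jl, fwr4_end = v_len + jl + .J_LEN,
        n1_start = v_len + vapply(clones[cls], function(x) x$n1[1], 0L),
        n1_end = v_len + vapply(clones[cls], function(x) x$n1[2], 0L),
        n2_start = v_len + vapply(clones[cls], function(x) x$n2[1], 0L),
        n2_end = v_len + vapply(clones[cls], function(x) x$n2[2], 0L),
        gc_id = .gc_label(gc),
        replicate_id = paste0("R", rep_i),
        in_frame_junction = klass != "out_of_frame",
        stringsAsFactors = FALSE)
      rec_list[[length(rec_list) + 1L]] <- df
      truth_seq[[length(truth_seq) + 1L]] <- data.frame(
        sequence_id = ids, clone_uid = cls, gc_id = .gc_label(gc),
        replicate_id = paste0("R", rep_i), class = klass,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL

  truth_clones <- data.frame(
    clone_uid = vapply(clones, `[[`, 0L, "uid"),
    home_gc = .gc_label(clone_home),
    type = clone_type,
    weight = clone_weight,
    n_extra = vapply(clones, `[[`, 0L, "n_extra"),
    occupancy = 1L + vapply(clones, function(x) length(x$extra_gcs), 0L),
    gcs = vapply(clones, function(x)
      paste(.gc_label(sort(c(x$home_gc, x$extra_gcs))), collapse = ","), ""),
    v_call = vapply(clones, `[[`, "", "v_call"),
    j_call = vapply(clones, `[[`, "", "j_call"),
    junction_length = nchar(vapply(clones, `[[`, "", "junction")),
    partner_of = vapply(clones, `[[`, NA_integer_, "partner_of"),
    epitope = vapply(clones, `[[`, NA_integer_, "epitope"),
    crippled = clone_crippled,
    k_prior = vapply(clones, `[[`, NA_integer_, "k_prior"),
    stringsAsFactors = FALSE)

  list(records = records,
       truth = list(sequences = do.call(rbind, truth_seq),
                    clones = truth_clones,
                    epitopes = epitopes,
                    config = config))
}
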