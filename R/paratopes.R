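# Synthetic paratope profiles for convergence analysis.
#
# Emulates the inputs that a paratope predictor and an antibody homology
# model would provide: per-residue paratope probabilities (binarized at
# 0.67) and one 3-D point per residue. Clones sharing a planted epitope
# label receive similar masks and coordinates (a perturbed group
# template); all other clones receive independent ones.

.PARATOPE_BINARIZE <- 0.67

# residue numbering of an in-frame sequence with the fixed V/J layout:
# V segment 1..80, junction 101..(100 + len/3), FWR4 201..212
.residue_numbering <- function(junction_length) {
  c(1:80, 100L + seq_len(junction_length %/% 3L), 200L + 1:12)
}

# build one profile
.make_profile <- function(id, clone_id, gc_id, aa, cdrs, numbering,
                          mask_numbering, template_coords, noise) {
  n <- nchar(aa)
  probs <- stats::runif(n, 0, 0.3)
  mpos <- match(mask_numbering, numbering)
  mpos <- mpos[!is.na(mpos)]
  probs[mpos] <- pmin(1, pmax(0, 0.9 + stats::rnorm(length(mpos), 0, noise)))
  mask <- probs >= .PARATOPE_BINARIZE
  coords <- cbind(numbering * 1.5, 3 * sin(numbering), 3 * cos(numbering))
  if (!is.null(template_coords) && length(mpos)) {
    k <- min(length(mpos), nrow(template_coords))
    coords[mpos[seq_len(k)], ] <- template_coords[seq_len(k), , drop = FALSE] +
      matrix(stats::rnorm(3 * k, 0, noise), k, 3)
  }
  structure(list(id = id, clone_id = clone_id, gc_id = gc_id, aa = aa,
                 cdrs = cdrs, numbering = numbering, probs = probs,
                 mask = mask, coords = coords, empty = !any(mask)),
            class = "paratope_profile")
}

#' Generate synthetic paratope profiles for clones
#'
#' Builds one `paratope_profile` per (clone, GC) pair, using the most
#' abundant member sequence in that GC as representative. Clones mapped
#' (by member majority) to the same planted epitope group receive the
#' group's paratope mask and coordinate template perturbed by
#' `paratope_noise`; other clones receive independent random masks and
#' paratope geometries. Clones whose representative cannot be translated
#' in frame are skipped with a warning.
#'
#' @param clone_set a `clone_set`.
#' @param records rearrangement data.frame.
#' @param truth ground truth from [generate_lymph_node()] (or NULL for no
#'   planted groups).
#' @param config the `lymph_node_config` (supplies `paratope_noise` and
#'   `seed`).
#' @param clone_ids optional subset of clone ids.
#' @return named list of `paratope_profile` objects (names `clone@gc`),
#'   with the clone-to-epitope map in the `epitope_map` attribute.
#' @export
generate_paratopes <- function(clone_set, records, truth = NULL,
                               config = lymph_node_config(),
                               clone_ids = NULL) {
  set.seed(config$seed + 1L)
  noise <- config$paratope_noise
  cl <- clone_set$clones
  if (!is.null(clone_ids)) cl <- cl[cl$clone_id %in% clone_ids, ]
  # clone -> planted epitope, by member-majority truth clone
  if (!is.null(truth)) {
    mt <- merge(clone_set$membership,
                truth$sequences[, c("sequence_id", "clone_uid")],
                by = "sequence_id")
    top_uid <- vapply(split(mt$clone_uid, mt$clone_id), function(u) {
      as.integer(names(sort(table(u), decreasing = TRUE))[1])
    }, integer(1))
    epi <- truth$clones$epitope[match(top_uid[cl$clone_id],
                                      truth$clones$clone_uid)]
  } else {
    epi <- rep(NA_integer_, nrow(cl))
  }
  # per-epitope templates: planted masks from the ground truth, plus a
  # coordinate template drawn once per group
  templates <- list()
  for (e in sort(unique(epi[!is.na(epi)]))) {
    mask_num <- truth$epitopes[[e]]$mask_numbering
    coords <- matrix(stats::rnorm(3 * length(mask_num), 0, 4),
                     length(mask_num), 3)
    templates[[as.character(e)]] <- list(mask = mask_num, coords = coords)
  }
  m <- merge(clone_set$membership,
             records[, c("sequence_id", "gc_id", "sequence", "junction",
                         "junction_length", "in_frame_junction",
                         "duplicate_count")],
             by = "sequence_id")
  by_clone <- split(m, m$clone_id)
  profiles <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(cl))) {
    cid <- cl$clone_id[i]
    mm <- by_clone[[cid]]
    if (is.null(mm)) next
    for (gc in sort(unique(mm$gc_id))) {
      d <- mm[mm$gc_id == gc, ]
      r <- d[order(-d$duplicate_count, d$sequence_id)[1], ]
      if (!r$in_frame_junction || r$junction_length %% 3L != 0L) {
        skipped <- c(skipped, paste(cid, gc, sep = "@"))
        next
      }
      aa <- translate_dna(r$sequence)
      if (grepl("\\*", substr(aa, 1, 80))) {
        # crippled representative: paratope model not meaningful
        skipped <- c(skipped, paste(cid, gc, sep = "@"))
        next
      }
      jlaa <- r$junction_length %/% 3L
      numbering <- .residue_numbering(r$junction_length)
      jaa <- translate_dna(r$junction)
      cdrs <- list(H1 = substr(aa, 26, 33),
                   H2 = substr(aa, 51, 58),
                   H3 = substr(jaa, 2, jlaa - 1L))
      if (!is.na(epi[i])) {
        tpl <- templates[[as.character(epi[i])]]
        mask_num <- tpl$mask
        tcoords <- tpl$coords
      } else {
        mask_num <- c(sample(26:33, 4), sample(51:58, 4),
                      if (jlaa >= 4) sample(100L + 2:(jlaa - 1L), 2))
        tcoords <- matrix(stats::rnorm(3 * length(mask_num), 0, 4),
                          length(mask_num), 3)
      }
      id <- paste(cid, gc, sep = "@")
      profiles[[id]] <- .make_profile(id, cid, gc, aa, cdrs, numbering,
                                      mask_num, tcoords, noise)
    }
  }
  if (length(skipped)) {
    warning(length(skipped), " clone/GC representative(s) without usable ",
            "CDR annotation skipped")
  }
  attr(profiles, "epitope_map") <- setNames(epi, cl$clone_id)
  profiles
}
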