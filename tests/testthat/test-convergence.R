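# helper: build a minimal paratope profile by hand
make_profile <- function(id, aa, mask_idx, numbering = seq_len(nchar(aa)),
                         coords = NULL, cdrs = NULL) {
  mask <- rep(FALSE, nchar(aa))
  mask[mask_idx] <- TRUE
  if (is.null(cdrs)) {
    cdrs <- list(H1 = substr(aa, 1, 4), H2 = substr(aa, 5, 8),
                 H3 = substr(aa, 9, nchar(aa)))
  }
  structure(list(id = id, clone_id = id, gc_id = "GC01", aa = aa,
                 cdrs = cdrs, numbering = numbering,
                 probs = as.numeric(mask), mask = mask, coords = coords,
                 empty = !any(mask)),
            class = "paratope_profile")
}

test_that("normalized Levenshtein matches its formula and the DP oracle", {
  expect_equal(normalized_levenshtein("ACGT", "ACGT"), 0)
  expect_equal(normalized_levenshtein("ACGT", "ACGA"), 2 / 9)
  expect_equal(normalized_levenshtein("A", ""), 1)
  expect_equal(normalized_levenshtein("", ""), 0)
  set.seed(5)
  rnd <- function() paste(sample(c("A", "C", "G", "T"),
                                 sample(0:12, 1), replace = TRUE),
                          collapse = "")
  for (i in 1:200) {
    s1 <- rnd(); s2 <- rnd()
    lev <- lev_dp(s1, s2)
    expected <- if (nchar(s1) + nchar(s2) + lev == 0) 0 else
      2 * lev / (nchar(s1) + nchar(s2) + lev)
    expect_equal(normalized_levenshtein(s1, s2), expected)
    expect_equal(normalized_levenshtein(s1, s2),
                 normalized_levenshtein(s2, s1))
  }
  # triangle inequality on random triples
  for (i in 1:100) {
    s <- c(rnd(), rnd(), rnd())
    d12 <- normalized_levenshtein(s[1], s[2])
    d13 <- normalized_levenshtein(s[1], s[3])
    d23 <- normalized_levenshtein(s[2], s[3])
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("CDR similarity averages the three CDR distances", {
  a <- make_profile("a", "WGQGTLVTVSS", 1:3)
  b <- make_profile("b", "WGQGTLVTVSS", 1:3)
  expect_equal(cdr_similarity(a, b), 1)
  # identical H1, H2; H3 at a known normalized distance
  b2 <- b
  b2$cdrs$H3 <- "TVS"  # vs "VSS": lev 2 -> 2*2/(3+3+2) = 0.5
  expect_equal(cdr_similarity(a, b2), 1 - 0.5 / 3)
  # all three maximally distant
  c2 <- make_profile("c", "AAAAAAAAAAA", 1:3)
  c2$cdrs <- list(H1 = "", H2 = "", H3 = "")
  a2 <- a; a2$cdrs <- list(H1 = "W", H2 = "G", H3 = "Q")
  expect_equal(cdr_similarity(a2, c2), 0)
  bad <- a; bad$cdrs <- list(H1 = "W", H2 = NA_character_, H3 = "Q")
  expect_error(cdr_similarity(a, bad), "CDR")
})

test_that("paratype identity counts shared paratope residues", {
  a <- make_profile("a", "ACDEFGHIKL", c(1, 3, 5, 7))
  expect_equal(paratype_identity(a, a), 1)
  # a has 4 paratope residues, b has 6, 3 matching -> 3/4 (below 0.76)
  b <- make_profile("b", "ACDEFGHIKL", c(1, 3, 5, 8, 9, 10))
  expect_equal(paratype_identity(a, b), 3 / 4)
  # disjoint paratope positions
  d <- make_profile("d", "ACDEFGHIKL", c(2, 4, 6))
  expect_equal(paratype_identity(a, d), 0)
  e <- make_profile("e", "ACDEFGHIKL", integer(0))
  expect_warning(expect_true(is.na(paratype_identity(a, e))), "empty")
})

test_that("structural token score counts shared residue triples", {
  coords <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(0, 0, 5))
  a <- make_profile("a", "AASC", 1:4, coords = coords)
  expect_equal(abligity_score(a, a), 1)
  # different chemical classes, same geometry: no shared tokens
  b <- make_profile("b", "DDEK", 1:4, coords = coords)
  expect_equal(abligity_score(a, b), 0)
  # hand-constructed partial overlap: two 4-residue paratopes with
  # identical class triples; displace one point so that exactly the two
  # triples not containing it keep their binned distances...
  coords2 <- coords
  coords2[4, ] <- c(0, 0, 9)
  c2 <- make_profile("c", "AASC", 1:4, coords = coords2)
  # triples: {123} unchanged; {124},{134},{234} change distance bins
  expect_equal(abligity_score(a, c2), 1 / 7)
  # abstention: missing coordinates or < 3 paratope residues
  d <- make_profile("d", "AASC", 1:4)
  expect_true(is.na(abligity_score(a, d)))
  e <- make_profile("e", "AASC", 1:2, coords = coords)
  expect_true(is.na(abligity_score(a, e)))
})

test_that("the 2-of-3 vote with CDR3-length gate drives prediction", {
  coords <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(0, 0, 5))
  a <- make_profile("a", "ACDEFGHIKLMN", c(1, 3, 5, 7), coords = coords[
    c(1, 2, 3, 4), ])
  a$coords <- matrix(0, 12, 3); a$coords[c(1, 3, 5, 7), ] <- coords
  b <- a; b$id <- "b"; b$clone_id <- "b"
  # identical profiles: 3 votes, predicted
  p <- predict_common_epitope(a, b)
  expect_equal(p$votes, 3)
  expect_true(p$predicted)
  # two votes (cdr + paratype), abligity low: still predicted
  b2 <- b
  b2$coords <- matrix(stats::rnorm(36, 0, 8), 12, 3)
  p2 <- predict_common_epitope(a, b2)
  expect_true(p2$cdr_similarity > 0.84 && p2$paratype_identity > 0.76)
  expect_true(p2$predicted)
  # all metrics high but different CDR3 lengths: not predicted
  b3 <- b
  b3$cdrs$H3 <- substr(b3$cdrs$H3, 1, nchar(b3$cdrs$H3) - 1)
  p3 <- predict_common_epitope(a, b3)
  expect_false(p3$predicted)
  # abstention cannot substitute for a second vote
  b4 <- b
  b4$aa <- "ACWEYGMIKLMN"  # breaks paratype matches (positions 3,5,7)
  b4$cdrs <- a$cdrs        # keep cdr vote
  b4$coords <- NULL        # abligity abstains
  p4 <- predict_common_epitope(a, b4)
  expect_equal(p4$votes, 1)
  expect_false(p4$predicted)
  # symmetry
  p5 <- predict_common_epitope(b2, a)
  expect_equal(p5$votes, p2$votes)
  expect_equal(p5$cdr_similarity, p2$cdr_similarity)
})

test_that("pair categories follow the stated precedence", {
  clones <- data.frame(clone_id = c("X", "Y", "Z"),
                       v_gene = c("IGHV1-2", "IGHV1-2", "IGHV3-23"),
                       j_gene = c("IGHJ4", "IGHJ4", "IGHJ4"))
  pair <- function(a, b) data.frame(clone_a = a, clone_b = b)
  expect_equal(categorize_pair(pair("X", "X"), clones), "same_clone_multi_gc")
  expect_equal(categorize_pair(pair("X", "Y"), clones),
               "same_vj_divergent_cdr3")
  expect_equal(categorize_pair(pair("X", "Z"), clones), "different_v_or_j")
})

test_that("paratope distance averages the two component distances", {
  expect_equal(paratope_distance(1, 1), 0)
  expect_equal(paratope_distance(0.8, 0.9), 0.15)
  expect_equal(paratope_distance(0, 0), 1)
})

test_that("epitope groups are connected components of predicted pairs", {
  mk <- function(id, aa) {
    p <- make_profile(id, aa, c(1, 3, 5, 7))
    p$gc_id <- "GC01"
    p
  }
  a <- mk("A@GC01", "ACDEFGHIKLMN"); a$clone_id <- "A"
  b <- mk("B@GC01", "ACDEFGHIKLMN"); b$clone_id <- "B"
  c_ <- mk("C@GC01", "ACDEFGHIKKMN"); c_$clone_id <- "C"
  d <- mk("D@GC01", "WWWWYYYYPPPP"); d$clone_id <- "D"
  gc_ab <- data.frame(clone_id = c("A", "B", "C", "D"), gc_id = "GC01",
                      abundance = c(40, 30, 20, 10))
  eg <- epitope_groups(list(a, b, c_, d), gc_ab, rank_threshold = 10)
  grp <- setNames(eg$groups$group, eg$groups$clone_id)
  expect_equal(grp[["A"]], grp[["B"]])
  expect_equal(grp[["B"]], grp[["C"]])  # linked through B (A-C may differ)
  expect_false(grp[["D"]] == grp[["A"]])
  # no predicted pairs: every clone its own group
  eg2 <- epitope_groups(list(a, d), gc_ab[c(1, 4), ], rank_threshold = 10)
  expect_equal(length(unique(eg2$groups$group)), 2)
})

test_that("epitope count estimate applies the recall correction", {
  expect_equal(estimate_epitopes(5000)$recall_corrected_count, 500)
  expect_equal(estimate_epitopes(120, pair_recall = 1)$recall_corrected_count,
               120)
  expect_equal(estimate_epitopes(0)$raw_count, 0)
  expect_error(estimate_epitopes(10, pair_recall = 0), "pair_recall")
  expect_error(estimate_epitopes(10, pair_recall = 1.2), "pair_recall")
})

test_that("planted epitope groups are recovered from generator output", {
  cfg <- lymph_node_config(seqs_per_sample = 800, clones_per_gc = 120,
                           n_epitopes = 5, epitope_group_size = 4, seed = 3)
  ln <- generate_lymph_node(cfg)
  cs <- group_clones(ln$records)
  ab <- clone_sample_abundance(cs, ln$records)
  prof <- suppressWarnings(generate_paratopes(cs, ln$records, ln$truth, cfg))
  eg <- epitope_groups(prof, ab, rank_threshold = 25, clones = cs$clones)
  emap <- attr(prof, "epitope_map")
  pp <- eg$pairs
  epi_a <- emap[pp$clone_a]; epi_b <- emap[pp$clone_b]
  pos <- !is.na(epi_a) & !is.na(epi_b) & epi_a == epi_b &
    pp$clone_a != pp$clone_b
  expect_gte(sum(pos), 10)
  recall <- sum(pp$predicted[pos]) / sum(pos)
  expect_gte(recall, 0.9)
  # at least 4 of 5 planted groups recovered as distinct components
  sel <- eg$groups
  sel$epi <- emap[sel$clone_id]
  sel <- sel[!is.na(sel$epi), ]
  purity <- tapply(sel$group, sel$epi, function(g) max(table(g)) / length(g))
  expect_gte(sum(purity >= 0.75), 4)
  comp_of_epi <- tapply(sel$group, sel$epi, function(g) {
    names(sort(table(g), decreasing = TRUE))[1]
  })
  expect_gte(length(unique(comp_of_epi)), 4)
  # predicted pairs carry categories
  expect_true(all(!is.na(pp$category[pp$predicted])))
})

test_that("recall degrades as paratope noise rises", {
  recall_at <- function(noise) {
    cfg <- lymph_node_config(seqs_per_sample = 400, clones_per_gc = 60,
                             n_gcs = 4, n_epitopes = 3,
                             epitope_group_size = 4,
                             paratope_noise = noise, seed = 31)
    ln <- generate_lymph_node(cfg)
    cs <- group_clones(ln$records)
    ab <- clone_sample_abundance(cs, ln$records)
    prof <- suppressWarnings(generate_paratopes(cs, ln$records, ln$truth,
                                                cfg))
    eg <- epitope_groups(prof, ab, rank_threshold = 20)
    emap <- attr(prof, "epitope_map")
    pp <- eg$pairs
    epi_a <- emap[pp$clone_a]; epi_b <- emap[pp$clone_b]
    pos <- !is.na(epi_a) & !is.na(epi_b) & epi_a == epi_b &
      pp$clone_a != pp$clone_b
    if (!sum(pos)) return(NA_real_)
    sum(pp$predicted[pos]) / sum(pos)
  }
  expect_gte(recall_at(0.01), recall_at(1.5))
})
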