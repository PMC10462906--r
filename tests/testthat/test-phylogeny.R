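# tree tests use hand-built clones with disjoint mutation blocks so the
# expected topology is known, plus an exhaustive least-squares oracle.

flip_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

test_that("root construction is germline V + consensus junction + J", {
  j <- toy_junction(30)
  rec <- toy_records(toy_record("a", j), toy_record("b", j))
  cs <- group_clones(rec)
  root <- build_root(cs$clones[1, ])
  expect_equal(root, rec$sequence[1])
  # 2-vs-1 majority at a junction position
  j2 <- flip_at(j, 10)
  rec2 <- toy_records(toy_record("a", j), toy_record("b", j),
                      toy_record("c", j2))
  cs2 <- group_clones(rec2)
  expect_equal(build_root(cs2$clones[1, ]), rec$sequence[1])
  # 1-vs-1 tie: alphabetical base
  rec3 <- toy_records(toy_record("a", j), toy_record("c", j2))
  cs3 <- group_clones(rec3)
  cons <- cs3$clones$consensus_junction[1]
  b1 <- substr(j, 10, 10); b2 <- substr(j2, 10, 10)
  expect_equal(substr(cons, 10, 10), min(b1, b2))
  # unknown germline call errors with the call name
  bad <- cs$clones[1, ]; bad$v_gene <- "IGHV9-99"
  expect_error(build_root(bad), "IGHV9-99")
})

test_that("clone trees recover planted lineage topology", {
  # caterpillar: a -> b -> c -> d by disjoint 3-mutation steps in the V
  j <- toy_junction(30)
  a <- toy_record("a", j)
  b <- toy_record("b", j, mutate_v = c(10, 20, 30))
  c_ <- toy_record("c", j, mutate_v = c(10, 20, 30, 40, 50, 60))
  d <- toy_record("d", j, mutate_v = c(10, 20, 30, 40, 50, 60, 70, 80, 90))
  rec <- toy_records(a, b, c_, d)
  cs <- group_clones(rec)
  tr <- clone_tree(cs$clones$clone_id[1], cs, rec)
  phy <- tr$phylo
  expect_s3_class(phy, "phylo")
  expect_setequal(setdiff(phy$tip.label, "root"), tr$leaves$label)
  # leaf-to-root path lengths are ordered a < b < c < d
  rd <- root_distance_distribution(tr)
  sim <- setNames(rd$per_leaf$similarity,
                  substr(rd$per_leaf$label, 1, 1))
  expect_true(sim["a"] > sim["b"] && sim["b"] > sim["c"] &&
                sim["c"] > sim["d"])
  # path lengths from the root tip reproduce the chain order (leaf a is
  # the unmutated founder, identical to the root)
  lab <- function(id) tr$leaves$label[tr$leaves$sequence_id == id]
  coph <- ape::cophenetic.phylo(phy)
  expect_equal(coph["root", lab("a")], 0)
  expect_true(coph["root", lab("b")] < coph["root", lab("c")])
  expect_true(coph["root", lab("c")] < coph["root", lab("d")])
  expect_equal(unname(rownames(coph)[which.max(coph["root", ])]), lab("d"))
})

test_that("tree topology matches an exhaustive least-squares oracle", {
  skip_if_not_installed("phangorn")
  # random additive trees over <= 6 leaves realized as sequences with
  # disjoint mutation blocks per edge
  set.seed(21)
  j <- toy_junction(30)
  for (rep_i in 1:5) {
    # random rooted bifurcating topology; every edge carries two unique
    # V-segment mutations, so tip Hamming distances are exactly additive
    rooted <- ape::rtree(5)
    n_edge <- nrow(rooted$edge)
    # positions spaced 5 apart so edit distance equals Hamming distance
    pos_pool <- split(10 + 5 * seq_len(2 * n_edge),
                      rep(seq_len(n_edge), each = 2))
    recs <- list()
    for (tip in rooted$tip.label) {
      np <- ape::nodepath(rooted, from = length(rooted$tip.label) + 1,
                          to = match(tip, rooted$tip.label))
      eids <- vapply(seq_len(length(np) - 1), function(i) {
        which(rooted$edge[, 1] == np[i] & rooted$edge[, 2] == np[i + 1])
      }, numeric(1))
      recs[[tip]] <- toy_record(tip, j, mutate_v = unlist(pos_pool[eids]))
    }
    rec <- do.call(rbind, recs)
    cs <- group_clones(rec, threshold = 0.5)
    tr <- clone_tree(cs$clones$clone_id[1], cs, rec)
    phy <- ape::drop.tip(tr$phylo, "root")
    # oracle: enumerate all unrooted topologies on the 5 leaves, fit
    # branch lengths by least squares on the observed distances
    labs <- tr$leaves$label
    seqs <- tr$leaves$sequence
    lev <- utils::adist(seqs)
    dmat <- 2 * lev / (outer(nchar(seqs), nchar(seqs), `+`) + lev)
    dimnames(dmat) <- list(labs, labs)
    all_tops <- phangorn::allTrees(5, tip.label = labs)
    ss <- vapply(all_tops, function(tp) {
      tp$edge.length <- rep(1, nrow(tp$edge))
      inc <- sapply(seq_len(nrow(tp$edge)), function(e) {
        t2 <- tp
        t2$edge.length <- replace(rep(0, nrow(tp$edge)), e, 1)
        as.vector(as.dist(ape::cophenetic.phylo(t2)[labs, labs]))
      })
      y <- as.vector(as.dist(dmat))
      fit <- stats::lm.fit(inc, y)
      sum(fit$residuals^2)
    }, numeric(1))
    best <- all_tops[[which.min(ss)]]
    rf <- phangorn::RF.dist(ape::unroot(phy), best)
    expect_equal(rf, 0)
  }
})

test_that("identical sequences collapse to weighted leaves", {
  j <- toy_junction(30)
  rec <- toy_records(
    toy_record("a", j, duplicate_count = 3),
    toy_record("b", j, duplicate_count = 2),
    toy_record("c", flip_at(j, 12)))
  cs <- group_clones(rec)
  tr <- clone_tree(cs$clones$clone_id[1], cs, rec)
  expect_equal(nrow(tr$leaves), 2)
  expect_equal(sort(tr$leaves$weight), c(1, 5))
  # all-identical clone: single leaf plus root, zero distance
  rec2 <- toy_records(toy_record("a", j), toy_record("b", j))
  cs2 <- group_clones(rec2)
  tr2 <- clone_tree(cs2$clones$clone_id[1], cs2, rec2)
  expect_equal(nrow(tr2$leaves), 1)
  expect_equal(sum(tr2$phylo$edge.length), 0)
})

test_that("total tree length is invariant to leaf input order", {
  ln <- small_ln()
  cs <- group_clones(ln$records)
  big <- cs$clones$clone_id[which(cs$clones$n_seqs >= 6)[1]]
  ids <- cs$membership$sequence_id[cs$membership$clone_id == big]
  rec <- ln$records[ln$records$sequence_id %in% ids, ]
  t1 <- clone_tree(big, cs, ln$records)
  perm <- withr::with_seed(4, sample(nrow(rec)))
  cs2 <- group_clones(rec[perm, ])
  t2 <- clone_tree(cs2$clones$clone_id[1], cs2, rec[perm, ])
  expect_equal(sum(t1$phylo$edge.length), sum(t2$phylo$edge.length),
               tolerance = 1e-9)
})

test_that("newick export is parseable and escapes labels", {
  j <- toy_junction(30)
  rec <- toy_records(toy_record("a (x)", j),
                     toy_record("b;c", flip_at(j, 15)))
  cs <- group_clones(rec)
  tr <- clone_tree(cs$clones$clone_id[1], cs, rec)
  nwk <- to_newick(tr)
  parsed <- ape::read.tree(text = nwk)
  expect_s3_class(parsed, "phylo")
  expect_setequal(parsed$tip.label, c(tr$leaves$label, "root"))
  expect_false(any(grepl("[();,]", tr$leaves$label)))
})

test_that("mutation counts before crippling match constructed lineages", {
  j <- toy_junction(30)
  fun1 <- toy_record("f1", j, duplicate_count = 10)
  fun2 <- toy_record("f2", j, mutate_v = c(15))
  # NF leaf differing from the root only by the stop-creating mutation
  nf0 <- toy_record("n0", j)
  ch <- strsplit(nf0$sequence, "")[[1]]
  ch[121:123] <- c("T", "A", "A")  # codon 40 (0-based), FWR2
  nf0$sequence <- paste(ch, collapse = "")
  rec0 <- toy_records(fun1, fun2, nf0)
  cs0 <- group_clones(rec0)
  lab0 <- classify_sequences(rec0)
  tr0 <- clone_tree(cs0$clones$clone_id[1], cs0, rec0)
  expect_equal(mutations_before_crippling(tr0, lab0), 0)
  # three neutral mutations, then the stop
  nf3 <- toy_record("n3", j, mutate_v = c(30, 60, 90))
  ch <- strsplit(nf3$sequence, "")[[1]]
  ch[121:123] <- c("T", "A", "A")
  nf3$sequence <- paste(ch, collapse = "")
  rec3 <- toy_records(fun1, fun2, nf3)
  cs3 <- group_clones(rec3)
  lab3 <- classify_sequences(rec3)
  tr3 <- clone_tree(cs3$clones$clone_id[1], cs3, rec3)
  expect_equal(mutations_before_crippling(tr3, lab3), 3)
  # clone without NF leaves errors
  recf <- toy_records(fun1, fun2)
  csf <- group_clones(recf)
  trf <- clone_tree(csf$clones$clone_id[1], csf, recf)
  expect_error(mutations_before_crippling(trf, classify_sequences(recf)),
               "non-functional")
})

test_that("crippling timing is recovered from generator F&NF clones", {
  cfg <- lymph_node_config(seqs_per_sample = 2500, clones_per_gc = 60,
                           crippled_clone_fraction = 0.15, seed = 23)
  ln <- generate_lymph_node(cfg)
  cs <- group_clones(ln$records)
  labels <- classify_sequences(ln$records)
  cf <- clone_functionality(cs, ln$records, labels)
  sz <- setNames(cs$clones$n_seqs, cs$clones$clone_id)
  fnf <- cf$clone_id[cf$clone_class == "F_and_NF" & sz[cf$clone_id] >= 2]
  expect_gte(length(fnf), 50)
  est <- vapply(head(fnf, 80), function(cid) {
    mutations_before_crippling(clone_tree(cid, cs, ln$records), labels)
  }, numeric(1))
  expect_lt(abs(mean(est, na.rm = TRUE) - 3.6), 0.5)
})

test_that("GC seeding order shows in root similarity medians", {
  # clone seeded in GC-A, re-diversified in GC-B with extra mutations
  j <- toy_junction(30)
  recs <- list()
  for (i in 1:4) {
    recs[[length(recs) + 1L]] <-
      toy_record(paste0("a", i), j, gc_id = "GCA",
                 mutate_v = if (i > 1) 10 + i else integer(0))
  }
  for (i in 1:4) {
    recs[[length(recs) + 1L]] <-
      toy_record(paste0("b", i), j, gc_id = "GCB",
                 mutate_v = c(30, 40, 50, 60, 70 + i))
  }
  rec <- do.call(rbind, recs)
  cs <- group_clones(rec)
  tr <- clone_tree(cs$clones$clone_id[1], cs, rec)
  rd <- root_distance_distribution(tr)
  expect_gt(rd$median_by_gc[["GCA"]], rd$median_by_gc[["GCB"]])
  # identical leaves imply similarity one
  rec1 <- toy_records(toy_record("x", j), toy_record("y", j))
  cs1 <- group_clones(rec1)
  rd1 <- root_distance_distribution(clone_tree(cs1$clones$clone_id[1],
                                               cs1, rec1))
  expect_true(all(rd1$per_leaf$similarity == 1))
})
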