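# Shared fixtures: hand-built rearrangement records on the bundled
# germline layout (V = 240 nt, J = 36 nt, junction in between), plus
# small independent oracles.

GL <- toy_germlines()

# one valid record: sequence = germline V + junction + germline J
toy_record <- function(sequence_id, junction,
                       v_call = "IGHV1-2", j_call = "IGHJ4",
                       gc_id = "GC01", replicate_id = "R1",
                       duplicate_count = 1L,
                       in_frame = nchar(junction) %% 3L == 0L,
                       n1 = c(3L, 6L), n2 = NULL,
                       mutate_v = integer(0)) {
  v <- GL$v[[sub("\\*.*", "", v_call)]]
  if (length(mutate_v)) {
    ch <- strsplit(v, "")[[1]]
    for (p in mutate_v) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    v <- paste(ch, collapse = "")
  }
  jl <- nchar(junction)
  if (is.null(n2)) n2 <- c(jl - 6L, jl - 3L)
  seq <- paste0(v, junction, GL$j[[sub("\\*.*", "", j_call)]])
  data.frame(sequence_id = sequence_id, sequence = seq,
             v_call = v_call, j_call = j_call,
             junction = junction, junction_length = jl,
             duplicate_count = as.integer(duplicate_count),
             fwr1_start = 0L, fwr1_end = 75L, cdr1_start = 75L,
             cdr1_end = 99L, fwr2_start = 99L, fwr2_end = 150L,
             cdr2_start = 150L, cdr2_end = 174L, fwr3_start = 174L,
             fwr3_end = 240L, cdr3_start = 243L,
             cdr3_end = 240L + jl - 3L, fwr4_start = 240L + jl,
             fwr4_end = 240L + jl + 36L,
             n1_start = 240L + n1[1], n1_end = 240L + n1[2],
             n2_start = 240L + n2[1], n2_end = 240L + n2[2],
             gc_id = gc_id, replicate_id = replicate_id,
             in_frame_junction = in_frame,
             stringsAsFactors = FALSE)
}

toy_records <- function(...) do.call(rbind, list(...))

# a stop-free in-frame junction of given length
toy_junction <- function(len, seed = 1) {
  stopifnot(len %% 3 == 0)
  set.seed(seed)
  ok <- setdiff(apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste0,
                      collapse = ""), c("TAA", "TAG", "TGA"))
  repeat {
    j <- paste0("TGT", paste(sample(ok, len / 3 - 2, replace = TRUE),
                             collapse = ""), "TGG")
    if (nchar(j) == len) return(j)
  }
}

# independent dynamic-programming Levenshtein oracle
lev_dp <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- numeric(nb + 1)
    cur[1] <- i
    for (j in seq_len(nb)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (av[i] != bv[j]))
    }
    prev <- cur
  }
  prev[nb + 1]
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  sab <- sum(choose(tab, 2))
  n <- sum(tab)
  expected <- sa * sb / choose(n, 2)
  (sab - expected) / ((sa + sb) / 2 - expected)
}

# small deterministic lymph node shared across tests (built once)
small_ln <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- lymph_node_config(seqs_per_sample = 600, clones_per_gc = 80,
                               seed = 101)
      cache <<- c(generate_lymph_node(cfg), list(config = cfg))
    }
    cache
  }
})
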