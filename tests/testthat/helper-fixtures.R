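# Small fixtures built in code.

make_abund <- function(values, unit = "read_count",
                       taxa = sprintf("t%d", seq_len(nrow(values))),
                       samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(taxa, samples)
  abundance_matrix(values, unit)
}

rand_abund <- function(n_taxa, n_samples, unit = "read_count", seed = 1,
                       taxa = sprintf("t%d", seq_len(n_taxa)),
                       samples = sprintf("s%d", seq_len(n_samples))) {
  set.seed(seed)
  make_abund(matrix(rpois(n_taxa * n_samples, 30), n_taxa, n_samples), unit,
             taxa = taxa, samples = samples)
}

rand_hits <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    query_id = sprintf("q%02d", sample.int(max(2L, n %/% 2L), n, replace = TRUE)),
    subject_id = sprintf("ctg%02d", sample.int(20, n, replace = TRUE)),
    identity = round(runif(n, 50, 100), 2),
    alignment_length = sample(100:900, n, replace = TRUE),
    mismatches = sample(0:50, n, replace = TRUE),
    gap_opens = sample(0:4, n, replace = TRUE),
    q_start = 1L, q_end = sample(100:900, n, replace = TRUE),
    s_start = 1L, s_end = sample(100:900, n, replace = TRUE),
    e_value = signif(10^-runif(n, 0, 30), 3),
    bit_score = round(runif(n, 30, 500), 1),
    stringsAsFactors = FALSE)
}

tiny_samples <- function(groups = c("CON", "HFD"), n_sub = 3L,
                         days = c(0L, 10L)) {
  do.call(rbind, lapply(groups, function(g)
    do.call(rbind, lapply(seq_len(n_sub), function(m)
      data.frame(sample_id = sprintf("%s_m%d_d%d", g, m, days),
                 subject_id = sprintf("%s_m%d", g, m), group = g, day = days,
                 project_id = "p1", stringsAsFactors = FALSE)))))
}
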