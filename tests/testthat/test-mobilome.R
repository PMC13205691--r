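make_events <- function(n, groups = "HFD") {
  data.frame(event_id = sprintf("e%03d", seq_len(n)),
             donor_taxon = sprintf("B%d", seq_len(n)),
             recipient_taxon = sprintf("B%d", rev(seq_len(n))),
             donor_genus = "Bacteroides", recipient_genus = "Akkermansia",
             gene_id = sprintf("g%03d", seq_len(n)),
             amino_acid_identity = 90, gene_cluster_coverage = 80,
             alignment_length_bp = 400, group = rep_len(groups, n),
             phage_contig_id = NA_character_, phage_identity = NA_real_,
             phage_evalue = NA_real_, phage_mediated = FALSE,
             stringsAsFactors = FALSE)
}

hit_for <- function(gene, identity, e_value, bit = 200) {
  data.frame(query_id = gene, subject_id = "ctg1", identity = identity,
             alignment_length = 300, mismatches = 3, gap_opens = 0,
             q_start = 1, q_end = 300, s_start = 1, s_end = 300,
             e_value = e_value, bit_score = bit, stringsAsFactors = FALSE)
}

test_that("phage-mediated screen applies strict thresholds and keeps best hit", {
  ev <- make_events(3)
  hits <- rbind(hit_for("g001", 95, 1e-20, bit = 100),
                hit_for("g001", 97, 1e-30, bit = 300),  # best hit
                hit_for("g002", 90, 1e-20),             # boundary identity fails
                hit_for("g003", 95, 1e-5))              # boundary E-value fails
  out <- classify_phage_mediated(ev, hits)
  expect_equal(out$phage_mediated, c(TRUE, FALSE, FALSE))
  expect_equal(out$phage_identity[1], 97)

  # brute-force oracle on random tables
  set.seed(18)
  ev2 <- make_events(30)
  h2 <- rand_hits(80, seed = 4)
  h2$query_id <- sample(c(ev2$gene_id, "other"), 80, replace = TRUE)
  got <- classify_phage_mediated(ev2, h2)$phage_mediated
  want <- vapply(ev2$gene_id, function(g) {
    hh <- h2[h2$query_id == g, ]
    any(hh$identity > 90 & hh$e_value < 1e-5)
  }, logical(1))
  expect_equal(got, unname(want))

  # tightening thresholds never flags more events
  loose <- sum(classify_phage_mediated(ev2, h2, 80, 1e-3)$phage_mediated)
  tight <- sum(classify_phage_mediated(ev2, h2, 95, 1e-10)$phage_mediated)
  expect_lte(tight, loose)
})

test_that("HGT frequency change reports fold and percent against baseline", {
  f <- hgt_frequency_change(10, 2)
  expect_equal(f$fold, 0.2)
  expect_equal(f$percent_change, -80)
  expect_equal(hgt_frequency_change(5, 5)$percent_change, 0)
  expect_equal(hgt_frequency_change(4, 38)$fold, 9.5)
  expect_error(hgt_frequency_change(0, 5), class = "phagedyn_domain_error")
})

test_that("donor/recipient role bias is a strict-majority tally", {
  ev <- make_events(6)
  ev$donor_genus <- c("Amedibacterium", "Amedibacterium", "Acutalibacter",
                      "Bacteroides", "Amedibacterium", "Acutalibacter")
  ev$recipient_genus <- c("Bacteroides", "Bacteroides", "Acutalibacter",
                          "Akkermansia", "Akkermansia", "Acutalibacter")
  roles <- donor_recipient_roles(ev)
  get <- function(g) roles$role[roles$genus == g]
  expect_equal(get("Amedibacterium"), "donor-biased")
  expect_equal(get("Akkermansia"), "recipient-biased")
  expect_equal(get("Acutalibacter"), "balanced")
  # brute-force tally on random tables
  set.seed(19)
  ev2 <- make_events(40)
  pool <- c("Ga", "Gb", "Gc", "Gd")
  ev2$donor_genus <- sample(pool, 40, TRUE)
  ev2$recipient_genus <- sample(pool, 40, TRUE)
  r2 <- donor_recipient_roles(ev2)
  for (g in pool) {
    expect_equal(r2$n_donor[r2$genus == g], sum(ev2$donor_genus == g))
    expect_equal(r2$n_recipient[r2$genus == g], sum(ev2$recipient_genus == g))
  }
})

test_that("signed log10 change honors both conventions and antisymmetry", {
  expect_equal(signed_log10_change(1, 11), 1)
  expect_equal(signed_log10_change(11, 1), -1)
  expect_equal(signed_log10_change(5, 5), 0)
  expect_equal(signed_log10_change(0, 9, convention = "stabilized"), 1)
  set.seed(20)
  a <- rexp(20); b <- rexp(20)
  expect_equal(signed_log10_change(a, b), -signed_log10_change(b, a))
  expect_equal(signed_log10_change(a, b, "stabilized"),
               -signed_log10_change(b, a, "stabilized"))
  # stabilized convention shares its sign with the difference everywhere
  expect_equal(sign(signed_log10_change(a, b, "stabilized")), sign(b - a))
})

test_that("enzyme trajectories flag strictly increasing medians only", {
  samples <- tiny_samples(groups = c("CON", "FUC"), n_sub = 3,
                          days = c(0, 10, 14, 18))
  vals <- c(1, 2, 3, 4)  # FUC medians strictly increase; CON flat with tie
  rows <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    d <- match(samples$day[i], c(0, 10, 14, 18))
    v <- if (samples$group[i] == "FUC") vals[d] else c(1, 2, 2, 3)[d]
    data.frame(gene_key = "integrase", pathway = "HGT enzymes",
               sample_id = samples$sample_id[i], value = v,
               stringsAsFactors = FALSE)
  }))
  tr <- enzyme_trajectory(rows, samples)
  expect_true(tr$trend$continuously_increasing[tr$trend$group == "FUC"])
  expect_false(tr$trend$continuously_increasing[tr$trend$group == "CON"])
  # medians equal the brute-force per-cell medians
  set.seed(23)
  rows$value <- rexp(nrow(rows))
  tr2 <- enzyme_trajectory(rows, samples)
  for (k in seq_len(nrow(tr2$medians))) {
    cell <- tr2$medians[k, ]
    ids <- samples$sample_id[samples$group == cell$group & samples$day == cell$day]
    expect_equal(cell$median, stats::median(rows$value[rows$sample_id %in% ids]))
  }
})

test_that("AMG reversal filter retains then selects per its two criteria", {
  samples <- tiny_samples(groups = c("CON", "HFD", "FUC"), n_sub = 6,
                          days = c(0, 10, 14, 18))
  mk <- function(ko, pathway, mult_hfd, mult_fuc) {
    vapply(seq_len(nrow(samples)), function(i) {
      post <- samples$day[i] > 0
      base <- 10 + (i %% 5) * 0.1  # deterministic jitter, no RNG
      if (samples$group[i] == "HFD" && post) base * mult_hfd
      else if (samples$group[i] == "FUC" && post) base * mult_fuc
      else base
    }, numeric(1))
  }
  tab <- rbind(
    data.frame(gene_key = "K14157", pathway = "Lysine degradation",
               sample_id = samples$sample_id, value = mk("K14157", "", 8, 0.4)),
    data.frame(gene_key = "K00001", pathway = "Glycolysis",
               sample_id = samples$sample_id, value = mk("K00001", "", 1, 1)))
  res <- amg_reversal_filter(tab, samples)
  sel <- res[res$ko == "K14157", ]
  expect_true(all(sel$selected))
  expect_true(all(sel$hfd_percent_change > 0))
  expect_false(any(res$selected[res$ko == "K00001"]))  # flat KO never selected
  expect_false(any(res$retained[res$ko == "K00001"]))
  # ordering: pathway then descending day-10 HFD change
  expect_equal(res$pathway, sort(res$pathway))
})

test_that("AMG retention matches a hand-enumerated exact Wilcoxon oracle", {
  samples <- tiny_samples(groups = c("CON", "HFD", "FUC"), n_sub = 4,
                          days = c(0, 10))
  v <- numeric(nrow(samples))
  hfd0 <- samples$group == "HFD" & samples$day == 0
  hfd10 <- samples$group == "HFD" & samples$day == 10
  fuc0 <- samples$group == "FUC" & samples$day == 0
  fuc10 <- samples$group == "FUC" & samples$day == 10
  v[hfd0] <- c(1, 2, 3, 4);  v[hfd10] <- c(10, 11, 12, 13)  # complete separation
  v[fuc0] <- c(5, 6, 7, 8);  v[fuc10] <- c(1, 2, 3, 4) + 0.5
  v[samples$group == "CON"] <- 5
  tab <- data.frame(gene_key = "K1", pathway = "p", sample_id = samples$sample_id,
                    value = v, stringsAsFactors = FALSE)
  res <- amg_reversal_filter(tab, samples, eval_days = 10)
  # exact two-sided rank-sum p for complete separation at 4 vs 4: 2/choose(8,4)
  expect_equal(res$p_hfd, 2 / choose(8, 4))
  expect_equal(res$p_fuc, 2 / choose(8, 4))
  expect_true(res$retained)
  expect_true(res$selected)  # HFD up vs baseline and FUC below HFD at day 10
})

test_that("cross-kingdom homolog filter keeps first passing record per query", {
  hits <- rbind(hit_for("q1", 95, 1e-10, bit = 150),
                hit_for("q1", 96, 1e-12, bit = 400),
                hit_for("q2", 95, 1e-10, bit = 90),    # boundary bitscore fails
                hit_for("q3", 95, 1e-3, bit = 200))    # evalue fails
  out <- crosskingdom_homolog_filter(hits)
  expect_equal(nrow(out), 1L)
  expect_equal(out$bit_score, 150)  # first survivor, not best
  # brute-force oracle on random lists
  set.seed(25)
  h <- rand_hits(60, seed = 6)
  got <- crosskingdom_homolog_filter(h)
  keep <- h$e_value < 1e-5 & h$bit_score > 90
  want <- h[keep, ][!duplicated(h$query_id[keep]), ]
  expect_equal(got, want, ignore_attr = TRUE)
})
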