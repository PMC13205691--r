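test_that("abundance tables round-trip through TSV and reject malformed input", {
  m <- rand_abund(3, 2, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(m, path)
  back <- read_abundance(path, "read_count")
  expect_equal(dim(back), c(3L, 2L))
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)

  # random matrices round-trip exactly within 1e-12
  for (s in 1:5) {
    set.seed(s)
    mm <- make_abund(matrix(round(rexp(12, 0.1), 6), 4, 3))
    write_abundance(mm, path)
    expect_equal(unclass(read_abundance(path, "read_count")), unclass(mm),
                 tolerance = 1e-12)
  }

  # duplicated sample header
  writeLines(c("taxon_id\ts1\ts1", "t1\t1\t2"), path)
  expect_error(read_abundance(path, "read_count"), class = "phagedyn_schema_error")
  # negative value
  writeLines(c("taxon_id\ts1\ts2", "t1\t1\t-2"), path)
  expect_error(read_abundance(path, "read_count"), class = "phagedyn_schema_error")
  # ragged row
  writeLines(c("taxon_id\ts1\ts2", "t1\t1"), path)
  expect_error(read_abundance(path, "read_count"), class = "phagedyn_parse_error")
  # unknown unit
  writeLines(c("taxon_id\ts1", "t1\t1"), path)
  expect_error(read_abundance(path, "parts_per_million"),
               class = "phagedyn_unit_error")
})

test_that("unit invariants are enforced on construction", {
  expect_error(make_abund(matrix(c(0.9, 0.9), 2, 1), "relative_fraction"),
               class = "phagedyn_schema_error")
  expect_silent(make_abund(matrix(c(0.5, 0.5), 2, 1), "relative_fraction"))
  expect_error(make_abund(matrix(c(60, 60), 2, 1), "relative_percent"),
               class = "phagedyn_schema_error")
  expect_error(make_abund(matrix(NA_real_, 1, 1)), class = "phagedyn_schema_error")
})

test_that("taxon retention filter matches the per-taxon disjunction oracle", {
  # forced first disjunct: max 0.3 > 0.2, prevalence 1/200 < 1%
  v <- matrix(0, 1, 200); v[1, 1] <- 0.3
  m <- make_abund(v, "relative_fraction")
  expect_equal(rownames(filter_taxa(m, 0.2, 0.01)), "t1")
  # all-zero taxon removed
  v2 <- rbind(v, 0)
  expect_equal(nrow(filter_taxa(make_abund(v2, "relative_fraction"), 0.2, 0.01)), 1L)
  # count input rejected
  expect_error(filter_taxa(rand_abund(2, 2)), class = "phagedyn_unit_error")

  # random 50-taxon table vs brute-force evaluation of the rule
  set.seed(42)
  vals <- matrix(runif(50 * 30) * rbinom(50 * 30, 1, 0.4), 50, 30) / 30
  m3 <- make_abund(vals, "relative_fraction")
  got <- rownames(filter_taxa(m3, relab_threshold = 0.02,
                              prevalence_fraction = 0.3))
  want <- rownames(m3)[vapply(seq_len(50), function(i) {
    max(vals[i, ]) > 0.02 || mean(vals[i, ] > 0) >= 0.3
  }, logical(1))]
  expect_identical(got, want)
})

test_that("alignment hits parse the 12-column convention and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene1\tctg1\t95.5\t300\t10\t1\t1\t300\t5\t304\t1e-07\t250.3", path)
  h <- read_alignment_hits(path)
  expect_equal(h$e_value, 1e-7)
  expect_equal(h$identity, 95.5)

  writeLines("gene1\tctg1\t95.5\t300\t10\t1\t1\t300\t5\t304\t1e-07", path)
  expect_error(read_alignment_hits(path), class = "phagedyn_parse_error")

  hits <- rand_hits(100, seed = 3)
  write_alignment_hits(hits, path)
  back <- read_alignment_hits(path)
  expect_equal(back, hits, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sample metadata and annotation validators reject invariant violations", {
  s <- tiny_samples()
  expect_silent(validate_sample_info(s))
  s2 <- s; s2$sample_id[2] <- s2$sample_id[1]
  expect_error(validate_sample_info(s2), class = "phagedyn_schema_error")
  s3 <- s; s3$subject_id <- s3$subject_id[1]; s3$day <- s3$day[1]
  expect_error(validate_sample_info(s3), class = "phagedyn_schema_error")

  ann <- data.frame(taxon_id = c("P1", "B1"),
                    species_name = c("s__Bacteroides_phage", "s__Bacteroides_sp1"),
                    kingdom = c("virus", "bacterium"),
                    lifestyle = c("virulent", ""),
                    host_genus = c("Bacteroides", ""),
                    host_phylum = c("Bacteroidetes", ""),
                    host_link_method = c("nomenclature", "none"),
                    stringsAsFactors = FALSE)
  expect_silent(validate_taxon_annotation(ann))
  bad <- ann; bad$lifestyle[2] <- "unknown"   # unknown reserved for viruses
  expect_error(validate_taxon_annotation(bad), class = "phagedyn_schema_error")
  bad2 <- ann; bad2$host_genus[1] <- ""       # host iff linked
  expect_error(validate_taxon_annotation(bad2), class = "phagedyn_schema_error")
})

test_that("HGT validator ties the phage-mediated flag to passing evidence", {
  ev <- data.frame(event_id = "e1", donor_taxon = "B1", recipient_taxon = "B2",
                   donor_genus = "Bacteroides", recipient_genus = "Akkermansia",
                   gene_id = "g1", amino_acid_identity = 90,
                   gene_cluster_coverage = 80, alignment_length_bp = 500,
                   group = "HFD", phage_contig_id = "c1",
                   phage_identity = 95, phage_evalue = 1e-10,
                   phage_mediated = TRUE, stringsAsFactors = FALSE)
  expect_silent(validate_hgt_events(ev))
  bad <- ev; bad$phage_identity <- 90  # boundary fails the strict screen
  expect_error(validate_hgt_events(bad), class = "phagedyn_schema_error")
})
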