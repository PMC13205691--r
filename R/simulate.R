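# Synthetic diet-intervention study generator. Emulates the three-group
# mouse design (CON / HFD / FUC, 6 subjects per group, fecal sampling on
# days 0/10/14/18) with planted, recorded ground truth: phage-bacterium
# pair correlations, lifestyle-composition shifts, HGT-enzyme trends,
# phage-mediated HGT labels and KO reversal patterns.

linked_genus_pool <- c("Bacteroides", "Prevotella", "Lactobacillus", "Roseburia",
                       "Blautia", "Alistipes", "Clostridium", "Enterococcus",
                       "Eubacterium", "Ruminococcus", "Oscillibacter", "Dorea",
                       "Coprococcus", "Butyrivibrio", "Marvinbryantia")
dab_genus_pool <- c("Parabacteroides", "Akkermansia", "Faecalibaculum",
                    "Anaerotignum", "Amedibacterium", "Acutalibacter")
filler_genus_pool <- c("Streptococcus", "Bifidobacterium", "Lactococcus",
                       "Klebsiella", "Escherichia", "Enterobacter", "Collinsella",
                       "Odoribacter", "Phocaeicola", "Paraprevotella",
                       "Mucispirillum", "Turicibacter", "Romboutsia",
                       "Sutterella", "Desulfovibrio", "Muribaculum")

sim_taxonomy <- function() {
  data.frame(
    genus = c("Bacteroides", "Prevotella", "Alistipes", "Parabacteroides",
              "Odoribacter", "Phocaeicola", "Paraprevotella", "Muribaculum",
              "Akkermansia",
              "Lactobacillus", "Roseburia", "Blautia", "Clostridium",
              "Enterococcus", "Eubacterium", "Ruminococcus", "Oscillibacter",
              "Dorea", "Coprococcus", "Butyrivibrio", "Marvinbryantia",
              "Faecalibaculum", "Anaerotignum", "Amedibacterium",
              "Acutalibacter", "Streptococcus", "Lactococcus", "Turicibacter",
              "Romboutsia",
              "Bifidobacterium", "Collinsella",
              "Klebsiella", "Escherichia", "Enterobacter", "Sutterella",
              "Desulfovibrio", "Mucispirillum"),
    phylum = c(rep("Bacteroidetes", 8), "Verrucomicrobia",
               rep("Firmicutes", 20),
               rep("Actinobacteria", 2),
               rep("Proteobacteria", 5), "Deferribacteres"),
    stringsAsFactors = FALSE)
}

#' Configuration of a synthetic diet-intervention study
#'
#' Defaults encode the emulated study conditions: 3 diet groups
#' (CON / HFD / FUC) x 6 subjects x days 0/10/14/18; planted pair
#' correlation 0.8; community virulent fraction 0.7 at baseline, dropping
#' to 0.5 under HFD and 0.65 under FUC after baseline; HGT-enzyme
#' trajectories flat under CON, decreasing under HFD, increasing under
#' FUC; phage-mediated HGT counts of 20/4/4/34 across the
#' HFD-baseline/HFD/FUC-baseline/FUC strata (an 80% reduction under HFD
#' and an 8.5-fold increase under FUC, each against its own baseline); and
#' five amino-acid-metabolism KOs with HFD-up / FUC-down reversal effects
#' next to three null KOs.
#'
#' @param seed integer seed driving every random stream (required).
#' @param groups diet group labels; the second is treated as the high-fat
#'   arm and the third as the supplemented arm.
#' @param n_subjects_per_group subjects (mice) per group.
#' @param days sampling days; the first is the baseline.
#' @param n_phage,n_bacteria numbers of taxa.
#' @param n_linked_pairs phage-bacterium pairs sharing a planted latent
#'   factor (each pair gets a private host genus; one pair is a crAssphage
#'   paired with a `Bacteroides` bacterium).
#' @param rho_planted target Spearman correlation of linked pairs.
#' @param virulent_fraction groups x days matrix of the planted community
#'   virulent relative-abundance fraction (dimnames = groups, days).
#' @param hgt_gene_trend named list per enzyme class of per-group trend
#'   labels (`increasing` / `flat` / `decreasing`).
#' @param n_hgt_events total HGT events.
#' @param phage_mediated_fraction fraction of events planted as
#'   phage-mediated.
#' @param hgt_group_weights named weights distributing the phage-mediated
#'   events over the group strata.
#' @param ko_effects data.frame `ko`, `pathway`, `hfd_fold`, `fuc_fold`;
#'   post-baseline multipliers per group (1 = null).
#' @param n_dab bacteria planted with a diet effect (the DAB truth set).
#' @param dab_fold multiplicative abundance effect of HFD on DAB taxa.
#' @param noise_sigma log-scale noise s.d. of taxon abundances.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       groups = c("CON", "HFD", "FUC"),
                       n_subjects_per_group = 6L,
                       days = c(0L, 10L, 14L, 18L),
                       n_phage = 80L,
                       n_bacteria = 40L,
                       n_linked_pairs = 10L,
                       rho_planted = 0.8,
                       virulent_fraction = NULL,
                       hgt_gene_trend = NULL,
                       n_hgt_events = 124L,
                       phage_mediated_fraction = 0.5,
                       hgt_group_weights = c(HFD_baseline = 20, HFD = 4,
                                             FUC_baseline = 4, FUC = 34),
                       ko_effects = NULL,
                       n_dab = 4L,
                       dab_fold = 10,
                       noise_sigma = 0.5) {
  if (missing(seed)) pd_stop("sim_config requires a seed", "config_error")
  if (n_phage < n_linked_pairs + 4L)
    pd_stop("n_phage must exceed n_linked_pairs + 4", "config_error")
  if (n_linked_pairs > length(linked_genus_pool))
    pd_stop(sprintf("at most %d linked pairs supported",
                    length(linked_genus_pool)), "config_error")
  if (n_bacteria < n_linked_pairs + n_dab)
    pd_stop("n_bacteria must cover linked partners and DAB taxa", "config_error")
  if (abs(rho_planted) > 0.99)
    pd_stop("planted |rho| > 0.99 is not achievable under noise", "config_error")
  if (is.null(virulent_fraction)) {
    virulent_fraction <- matrix(0.7, length(groups), length(days),
                                dimnames = list(groups, as.character(days)))
    virulent_fraction[2L, -1L] <- 0.5
    virulent_fraction[3L, -1L] <- 0.65
  }
  if (any(virulent_fraction <= 0 | virulent_fraction >= 1))
    pd_stop("virulent fractions must lie strictly inside (0, 1)", "config_error")
  if (is.null(hgt_gene_trend)) {
    tr <- stats::setNames(c("flat", "decreasing", "increasing"), groups)
    hgt_gene_trend <- list(integrase = tr, recombinase = tr, transposase = tr)
  }
  if (is.null(ko_effects)) {
    ko_effects <- data.frame(
      ko = c("K14157", "K01582", "K01953", "K12960", "K17103",
             "K00001", "K00002", "K03737"),
      pathway = c("Lysine degradation", "Lysine degradation",
                  "Alanine, aspartate and glutamate metabolism",
                  "Cysteine and methionine metabolism",
                  "Glycerophospholipid metabolism",
                  "Glycolysis / Gluconeogenesis",
                  "Glycolysis / Gluconeogenesis",
                  "Pyruvate metabolism"),
      hfd_fold = c(8, 6, 5, 4, 5, 1, 1, 1),
      fuc_fold = c(0.4, 0.5, 0.4, 0.5, 0.4, 1, 1, 1),
      stringsAsFactors = FALSE)
  }
  if (phage_mediated_fraction < 0 || phage_mediated_fraction > 1)
    pd_stop("phage_mediated_fraction must lie in [0, 1]", "config_error")
  cfg <- list(seed = as.integer(seed), groups = groups,
              n_subjects_per_group = as.integer(n_subjects_per_group),
              days = as.integer(days), n_phage = as.integer(n_phage),
              n_bacteria = as.integer(n_bacteria),
              n_linked_pairs = as.integer(n_linked_pairs),
              rho_planted = rho_planted,
              virulent_fraction = virulent_fraction,
              hgt_gene_trend = hgt_gene_trend,
              n_hgt_events = as.integer(n_hgt_events),
              phage_mediated_fraction = phage_mediated_fraction,
              hgt_group_weights = hgt_group_weights,
              ko_effects = ko_effects, n_dab = as.integer(n_dab),
              dab_fold = dab_fold, noise_sigma = noise_sigma)
  class(cfg) <- "sim_config"
  cfg
}

# Largest-remainder apportionment of `total` over `weights`.
apportion <- function(total, weights) {
  q <- total * weights / sum(weights)
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate a complete synthetic study with recorded ground truth
#'
#' Abundances are drawn log-normally around per-taxon baselines. Each
#' linked phage-bacterium pair shares a latent standard-normal factor on
#' the log scale with mixing weight `w = sqrt(r)` where
#' `r = 2 sin(pi rho / 6)` is the latent Pearson correlation that the
#' Gaussian copula maps to the target Spearman `rho` (the inverse of the
#' latent-model correlation map). Temperate phage abundance is rescaled
#' per sample so the community virulent fraction matches the planted
#' (group, day) value. HGT events carry planted phage-mediated labels with
#' alignment evidence that passes (or fails) the phage screen by
#' construction; enzyme and KO tables realize the configured trends. A
#' fixed seed yields a byte-identical bundle; every table passes the
#' package's validators.
#'
#' @param cfg a [sim_config()].
#' @return object of class `phage_sim`: list with `phage` and `bacteria`
#'   abundance matrices (`read_count`), `samples`, `annotation`,
#'   `taxonomy`, `hgt_events`, `phage_hits`, `enzyme_genes`, `ko_genes`
#'   and `truth` (the planted parameters for recovery scoring).
#' @export
simulate_study <- function(cfg) {
  if (!inherits(cfg, "sim_config")) pd_stop("cfg must be a sim_config", "config_error")
  groups <- cfg$groups; days <- cfg$days
  nsub <- cfg$n_subjects_per_group
  hfd <- groups[2L]; fuc <- groups[3L]

  samples <- do.call(rbind, lapply(groups, function(g)
    do.call(rbind, lapply(seq_len(nsub), function(m)
      data.frame(sample_id = sprintf("%s_m%d_d%d", g, m, days),
                 subject_id = sprintf("%s_m%d", g, m),
                 group = g, day = days, project_id = "sim_mouse_diet",
                 stringsAsFactors = FALSE)))))
  rownames(samples) <- NULL
  ns <- nrow(samples)

  # ---- taxa and annotation ----
  npair <- cfg$n_linked_pairs
  linked_genera <- linked_genus_pool[seq_len(npair)]
  bact_ids <- sprintf("B%03d", seq_len(cfg$n_bacteria))
  dab_genera <- rep_len(dab_genus_pool, cfg$n_dab)
  n_fill <- cfg$n_bacteria - npair - cfg$n_dab
  fill_genera <- rep_len(filler_genus_pool, max(n_fill, 0L))
  bact_genera <- c(linked_genera, dab_genera, fill_genera)
  bact_species <- sprintf("s__%s_sp%d", bact_genera, seq_len(cfg$n_bacteria))

  phage_ids <- sprintf("P%03d", seq_len(cfg$n_phage))
  crass_idx <- match("Bacteroides", linked_genera)
  linked_species <- sprintf("s__%s_phage", linked_genera)
  if (!is.na(crass_idx)) linked_species[crass_idx] <- "s__crAssphage_sp1"
  n_other <- cfg$n_phage - npair
  other_vir <- ceiling(n_other / 2)
  other_species <- sprintf("s__uncultured_virus_%d", seq_len(n_other))
  phage_species <- c(linked_species, other_species)
  phage_lifestyle <- c(rep("virulent", npair),
                       rep("virulent", other_vir),
                       rep("temperate", n_other - other_vir))

  taxonomy <- sim_taxonomy()
  parsed <- parse_host_genus(phage_species)
  phage_ann <- data.frame(
    taxon_id = phage_ids, species_name = phage_species, kingdom = "virus",
    lifestyle = phage_lifestyle,
    host_genus = parsed$host_genus,
    host_phylum = ifelse(parsed$method == "crassphage_override", "Bacteroidetes",
                         rollup_phylum(parsed$host_genus, taxonomy)),
    host_link_method = parsed$method, stringsAsFactors = FALSE)
  bact_ann <- data.frame(
    taxon_id = bact_ids, species_name = bact_species, kingdom = "bacterium",
    lifestyle = "", host_genus = "", host_phylum = "",
    host_link_method = "none", stringsAsFactors = FALSE)
  annotation <- validate_taxon_annotation(rbind(phage_ann, bact_ann))

  sigma <- cfg$noise_sigma
  r_latent <- 2 * sin(pi * cfg$rho_planted / 6)
  w <- sqrt(abs(r_latent))

  # ---- abundance matrices with planted pair correlations ----
  ab <- with_seed(stream_seed(cfg$seed, "abundance"), {
    mu_p <- stats::rnorm(cfg$n_phage, log(300), 0.6)
    mu_b <- stats::rnorm(cfg$n_bacteria, log(400), 0.6)
    z <- matrix(stats::rnorm(npair * ns), npair, ns)
    e_p <- matrix(stats::rnorm(cfg$n_phage * ns), cfg$n_phage, ns)
    e_b <- matrix(stats::rnorm(cfg$n_bacteria * ns), cfg$n_bacteria, ns)
    lp <- mu_p + sigma * e_p
    lb <- mu_b + sigma * e_b
    for (k in seq_len(npair)) {
      lat_p <- w * z[k, ] + sqrt(1 - w^2) * e_p[k, ]
      lat_b <- sign(r_latent) * w * z[k, ] + sqrt(1 - w^2) * e_b[k, ]
      lp[k, ] <- mu_p[k] + sigma * lat_p
      lb[k, ] <- mu_b[k] + sigma * lat_b
    }
    # DAB effect: HFD raises the planted taxa after baseline (FUC halves it)
    dab_rows <- npair + seq_len(cfg$n_dab)
    post <- samples$day > days[1L]
    eff <- log(cfg$dab_fold)
    for (i in dab_rows) {
      lb[i, samples$group == hfd & post] <- lb[i, samples$group == hfd & post] + eff
      lb[i, samples$group == fuc & post] <- lb[i, samples$group == fuc & post] + eff / 4
    }
    list(lp = lp, lb = lb)
  })

  # rescale temperate phages so each sample hits its planted virulent fraction
  vir_rows <- which(phage_lifestyle == "virulent")
  tem_rows <- which(phage_lifestyle == "temperate")
  pv <- exp(ab$lp)
  for (s in seq_len(ns)) {
    f <- cfg$virulent_fraction[samples$group[s], as.character(samples$day[s])]
    V <- sum(pv[vir_rows, s]); Tt <- sum(pv[tem_rows, s])
    pv[tem_rows, s] <- pv[tem_rows, s] * V * (1 - f) / (f * Tt)
  }
  phage_counts <- round(pv)
  phage_counts[phage_counts < 0] <- 0
  dimnames(phage_counts) <- list(phage_ids, samples$sample_id)
  bact_counts <- round(exp(ab$lb))
  dimnames(bact_counts) <- list(bact_ids, samples$sample_id)
  phage_m <- abundance_matrix(phage_counts, "read_count")
  bact_m <- abundance_matrix(bact_counts, "read_count")

  # ---- HGT events and phage alignment evidence ----
  strata <- names(cfg$hgt_group_weights)
  med_counts <- apportion(round(cfg$n_hgt_events * cfg$phage_mediated_fraction),
                          cfg$hgt_group_weights)
  n_med <- sum(med_counts)
  n_non <- cfg$n_hgt_events - n_med
  hgt <- with_seed(stream_seed(cfg$seed, "hgt"), {
    ev_group <- c(rep(strata, med_counts),
                  rep_len(strata, n_non))
    mediated <- c(rep(TRUE, n_med), rep(FALSE, n_non))
    n <- length(ev_group)
    donor <- sample(bact_ids, n, replace = TRUE)
    recipient <- vapply(donor, function(d)
      sample(setdiff(bact_ids, d), 1L), character(1))
    events <- data.frame(
      event_id = sprintf("hgt%04d", seq_len(n)),
      donor_taxon = donor, recipient_taxon = recipient,
      donor_genus = bact_genera[match(donor, bact_ids)],
      recipient_genus = bact_genera[match(recipient, bact_ids)],
      gene_id = sprintf("gene%04d", seq_len(n)),
      amino_acid_identity = round(stats::runif(n, 80, 100), 2),
      gene_cluster_coverage = round(stats::runif(n, 75, 100), 2),
      alignment_length_bp = sample(200:1500, n, replace = TRUE),
      group = ev_group, phage_contig_id = NA_character_,
      phage_identity = NA_real_, phage_evalue = NA_real_,
      phage_mediated = mediated, stringsAsFactors = FALSE)
    hit_rows <- list()
    for (i in seq_len(n)) {
      if (mediated[i]) {
        ident <- round(stats::runif(1, 92, 99.5), 2)
        ev <- 10^-stats::runif(1, 6, 40)
        contig <- sprintf("phagectg%03d", sample.int(60, 1))
        alen <- sample(300:2000, 1)
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          query_id = events$gene_id[i], subject_id = contig,
          identity = ident, alignment_length = alen,
          mismatches = round(alen * (100 - ident) / 100),
          gap_opens = sample(0:3, 1), q_start = 1L, q_end = alen,
          s_start = 1L, s_end = alen, e_value = signif(ev, 3),
          bit_score = round(stats::runif(1, 120, 900), 1),
          stringsAsFactors = FALSE)
        events$phage_contig_id[i] <- contig
        events$phage_identity[i] <- ident
        events$phage_evalue[i] <- signif(ev, 3)
      } else if (stats::runif(1) < 0.4) {
        # decoy hit failing the screen on identity or E-value
        fail_on_identity <- stats::runif(1) < 0.5
        ident <- if (fail_on_identity) round(stats::runif(1, 60, 88), 2)
                 else round(stats::runif(1, 92, 99), 2)
        ev <- if (fail_on_identity) 10^-stats::runif(1, 6, 20)
              else 10^-stats::runif(1, 0, 4)
        alen <- sample(150:800, 1)
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          query_id = events$gene_id[i],
          subject_id = sprintf("phagectg%03d", sample.int(60, 1)),
          identity = ident, alignment_length = alen,
          mismatches = round(alen * (100 - ident) / 100),
          gap_opens = sample(0:3, 1), q_start = 1L, q_end = alen,
          s_start = 1L, s_end = alen, e_value = signif(ev, 3),
          bit_score = round(stats::runif(1, 40, 200), 1),
          stringsAsFactors = FALSE)
      }
    }
    hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
      utils::read.table(text = "", col.names = alignment_cols())
    list(events = validate_hgt_events(events),
         hits = validate_alignment_hits(hits))
  })

  # ---- HGT-enzyme gene table ----
  trend_mult <- function(trend, di) switch(trend,
    increasing = 1.5^(di - 1),
    decreasing = 1.5^(1 - di),
    flat = 1,
    pd_stop(sprintf("unknown trend label: %s", trend), "config_error"))
  enzyme_base <- c(integrase = 50, recombinase = 30, transposase = 40)
  enzyme_genes <- with_seed(stream_seed(cfg$seed, "enzymes"), {
    rows <- lapply(names(cfg$hgt_gene_trend), function(cl) {
      tr <- cfg$hgt_gene_trend[[cl]]
      di <- match(samples$day, days)
      mult <- vapply(seq_len(ns), function(s)
        trend_mult(tr[[samples$group[s]]], di[s]), numeric(1))
      data.frame(gene_key = cl, pathway = "HGT enzymes",
                 sample_id = samples$sample_id,
                 value = enzyme_base[[cl]] * mult *
                   exp(stats::rnorm(ns, 0, 0.25)),
                 stringsAsFactors = FALSE)
    })
    validate_gene_abundance(do.call(rbind, rows))
  })

  # ---- KO table ----
  ko_genes <- with_seed(stream_seed(cfg$seed, "ko"), {
    post <- samples$day > days[1L]
    rows <- lapply(seq_len(nrow(cfg$ko_effects)), function(k) {
      eff <- cfg$ko_effects[k, ]
      mult <- rep(1, ns)
      mult[samples$group == hfd & post] <- eff$hfd_fold
      mult[samples$group == fuc & post] <- eff$fuc_fold
      data.frame(gene_key = eff$ko, pathway = eff$pathway,
                 sample_id = samples$sample_id,
                 value = 20 * mult * exp(stats::rnorm(ns, 0, 0.3)),
                 stringsAsFactors = FALSE)
    })
    validate_gene_abundance(do.call(rbind, rows))
  })

  f <- cfg$virulent_fraction
  truth <- list(
    pairs = data.frame(phage_id = phage_ids[seq_len(npair)],
                       bacterium_id = bact_ids[seq_len(npair)],
                       rho = cfg$rho_planted, stringsAsFactors = FALSE),
    virulent_fraction = f,
    lli_planted = f / (1 - f),
    dab_taxa = bact_ids[npair + seq_len(cfg$n_dab)],
    phage_mediated_ids = hgt$events$event_id[hgt$events$phage_mediated],
    hgt_mediated_counts = med_counts,
    ko_selected = cfg$ko_effects$ko[cfg$ko_effects$hfd_fold > 1 &
                                      cfg$ko_effects$fuc_fold < 1],
    seed = cfg$seed)

  structure(list(phage = phage_m, bacteria = bact_m, samples = samples,
                 annotation = annotation, taxonomy = taxonomy,
                 hgt_events = hgt$events, phage_hits = hgt$hits,
                 enzyme_genes = enzyme_genes, ko_genes = ko_genes,
                 truth = truth, config = cfg),
            class = "phage_sim")
}

#' Write a simulated bundle as the package's TSV set plus truth.json
#'
#' @param sim a `phage_sim` bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance(sim$phage, file.path(dir, "phage_abundance.tsv"))
  write_abundance(sim$bacteria, file.path(dir, "bacteria_abundance.tsv"))
  write_sample_info(sim$samples, file.path(dir, "samples.tsv"))
  write_taxon_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_hgt_events(sim$hgt_events, file.path(dir, "hgt_events.tsv"))
  write_alignment_hits(sim$phage_hits, file.path(dir, "phage_hits.tsv"))
  write_gene_abundance(sim$enzyme_genes, file.path(dir, "enzyme_genes.tsv"))
  write_gene_abundance(sim$ko_genes, file.path(dir, "ko_genes.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Score pipeline outputs against the planted ground truth
#'
#' Runs the analysis stages on a simulated bundle and reports recovery
#' metrics per stage.
#'
#' @param sim a `phage_sim` bundle.
#' @return list of metrics: `rho_recovered` (the study's point estimate of
#'   the planted correlation: median Spearman over all planted pair x
#'   stratum records), `rho_mean_abs_error` and `rho_within_0.15`
#'   (planted pair correlations, per group stratum),
#'   `lli_sign_agreement` (fraction of groups whose recovered community
#'   LLI day0 -> day10 change sign matches the planted sign),
#'   `dab_recall` / `dab_precision`, `phage_flag_match_rate`,
#'   `ko_recall`.
#' @export
truth_report <- function(sim) {
  cfg <- sim$config
  truth <- sim$truth
  days <- cfg$days

  # planted correlations, evaluated within each group stratum
  corr <- suppressWarnings(correlate_pairs(sim$phage, sim$bacteria, truth$pairs,
                                           sim$samples))
  err <- abs(corr$rho - truth$pairs$rho[match(corr$phage_id, truth$pairs$phage_id)])
  err <- err[!is.na(err)]

  # community LLI change per group, day0 -> day10
  lli <- lli_by_sample(sim$phage, sim$annotation)
  lli$group <- sim$samples$group[match(lli$sample_id, sim$samples$sample_id)]
  lli$day <- sim$samples$day[match(lli$sample_id, sim$samples$sample_id)]
  d0 <- days[1L]; d1 <- days[2L]
  signs_ok <- vapply(cfg$groups, function(g) {
    obs <- mean(lli$lli[lli$group == g & lli$day == d1]) -
      mean(lli$lli[lli$group == g & lli$day == d0])
    planted <- truth$lli_planted[g, as.character(d1)] -
      truth$lli_planted[g, as.character(d0)]
    if (planted == 0) TRUE else sign(obs) == sign(planted)
  }, logical(1))

  # DAB surrogate screen on the bacterial matrix
  scr <- screen_differential(sim$bacteria,
                             sim$samples$group[match(colnames(sim$bacteria),
                                                     sim$samples$sample_id)])
  hits <- scr$taxon_id[scr$selected]
  recall <- mean(truth$dab_taxa %in% hits)
  precision <- if (length(hits)) mean(hits %in% truth$dab_taxa) else NA_real_

  # phage-mediated flags recovered from the alignment evidence
  blank <- sim$hgt_events
  blank$phage_mediated <- FALSE
  flags <- classify_phage_mediated(blank, sim$phage_hits)
  flag_match <- mean(flags$phage_mediated == sim$hgt_events$phage_mediated)

  # KO reversal recovery
  amg <- suppressWarnings(amg_reversal_filter(sim$ko_genes, sim$samples,
    groups = c(hfd = cfg$groups[2L], fuc = cfg$groups[3L]),
    baseline_day = days[1L], test_day = days[2L], eval_days = days[-1L]))
  sel <- unique(amg$ko[amg$selected])
  ko_recall <- if (length(truth$ko_selected)) mean(truth$ko_selected %in% sel)
               else NA_real_

  list(rho_recovered = stats::median(corr$rho, na.rm = TRUE),
       rho_mean_abs_error = mean(err),
       rho_within_0.15 = mean(err <= 0.15),
       lli_sign_agreement = mean(signs_ok),
       dab_recall = recall, dab_precision = precision,
       phage_flag_match_rate = flag_match,
       ko_recall = ko_recall)
}
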