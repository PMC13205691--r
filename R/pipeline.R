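# End-to-end orchestration: data_io -> abundance -> host_link ->
# lifestyle -> interactions -> mobilome, each stage writing its outputs
# before the next starts, with a machine-readable run report.

#' Run the full diet-virome analysis pipeline
#'
#' Executes the analysis stages in order on either a simulated study
#' (`config$simulate`, passed to [sim_config()]) or a set of input tables
#' (`config$inputs`, a list of file paths: `phage_abundance`,
#' `bacteria_abundance`, `samples`, `annotation`, `taxonomy`,
#' `hgt_events`, `phage_hits`, `enzyme_genes`, `ko_genes`). All
#' randomness (simulation, Bray-Curtis subsampling) is funneled through
#' `config$seed`, so an identical config yields byte-identical numeric
#' outputs. Stage toggles live in `config$stages` (named logicals
#' `abundance`, `host_link`, `lifestyle`, `interactions`, `mobilome`).
#'
#' @param config configuration list, or path to a YAML file holding one.
#' @param output_dir directory for output TSVs and `report.json`
#'   (defaults to `config$output_dir`).
#' @return the run report (list), invisibly; written as
#'   `report.json` alongside the stage TSVs (`lli.tsv`,
#'   `correlations.tsv`, `changes.tsv`, `votes.tsv`, `concordance.tsv`,
#'   `hgt_flags.tsv`, `amg_selection.tsv`, ...).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      pd_stop("reading YAML configs requires the yaml package", "config_error")
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) pd_stop("config$seed is required", "config_error")
  seed <- as.integer(config$seed)
  output_dir <- output_dir %||% config$output_dir %||%
    pd_stop("an output directory is required", "config_error")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- utils::modifyList(list(abundance = TRUE, host_link = TRUE,
                                   lifestyle = TRUE, interactions = TRUE,
                                   mobilome = TRUE), config$stages %||% list())
  alpha <- config$alpha %||% 0.05
  report <- list(seed = seed, parameters = list(alpha = alpha),
                 stages = list(), headline = list(), warnings = character())
  note <- function(msg) report$warnings <<- c(report$warnings, msg)

  # ---- data_io ----
  if (!is.null(config$simulate)) {
    sim <- simulate_study(do.call(sim_config,
                                  c(list(seed = seed), config$simulate)))
    dat <- sim[c("phage", "bacteria", "samples", "annotation", "taxonomy",
                 "hgt_events", "phage_hits", "enzyme_genes", "ko_genes")]
  } else if (!is.null(config$inputs)) {
    ip <- config$inputs
    dat <- list(
      phage = read_abundance(ip$phage_abundance, ip$phage_unit %||% "read_count"),
      bacteria = read_abundance(ip$bacteria_abundance,
                                ip$bacteria_unit %||% "read_count"),
      samples = read_sample_info(ip$samples),
      annotation = read_taxon_annotation(ip$annotation),
      taxonomy = if (!is.null(ip$taxonomy)) read_tsv(ip$taxonomy,
                                                     c("genus", "phylum")),
      hgt_events = if (!is.null(ip$hgt_events)) read_hgt_events(ip$hgt_events),
      phage_hits = if (!is.null(ip$phage_hits)) read_alignment_hits(ip$phage_hits),
      enzyme_genes = if (!is.null(ip$enzyme_genes)) read_gene_abundance(ip$enzyme_genes),
      ko_genes = if (!is.null(ip$ko_genes)) read_gene_abundance(ip$ko_genes))
  } else pd_stop("config needs either a simulate block or inputs", "config_error")
  report$stages$data_io <- list(
    n_phage = nrow(dat$phage), n_bacteria = nrow(dat$bacteria),
    n_samples = nrow(dat$samples))
  samples <- dat$samples
  days <- sort(unique(samples$day))
  groups <- unique(samples$group)

  # ---- abundance ----
  phage_rel <- if (abundance_unit(dat$phage) == "read_count")
    to_relative(dat$phage) else dat$phage
  if (isTRUE(stages$abundance)) {
    bc <- list()
    for (g in groups) {
      pre_ids <- samples$sample_id[samples$group == g & samples$day == days[1L]]
      post_ids <- samples$sample_id[samples$group == g & samples$day == days[2L]]
      if (length(pre_ids) >= 2L && length(post_ids) >= 2L) {
        r <- subsampled_bc_shift(unclass(dat$bacteria)[, pre_ids, drop = FALSE],
                                 unclass(dat$bacteria)[, post_ids, drop = FALSE],
                                 n_iter = config$bc_iterations %||% 100L,
                                 seed = stream_seed(seed, paste0("bc_", g)))
        r$group <- g
        bc[[g]] <- r
      }
    }
    bc <- do.call(rbind, bc)
    write_tsv(bc, file.path(output_dir, "bc_shift.tsv"))
    report$stages$abundance <- list(
      bc_iterations = length(unique(bc$iteration)),
      median_bc_by_group = lapply(split(bc$median_bc, bc$group), stats::median))
  }

  # ---- host_link ----
  pairs <- NULL
  if (isTRUE(stages$host_link)) {
    ann <- dat$annotation
    pairs <- link_pairs(ann[ann$kingdom == "virus", ],
                        ann[ann$kingdom == "bacterium", ],
                        taxonomy = dat$taxonomy)
    write_tsv(pairs, file.path(output_dir, "host_links.tsv"))
    report$stages$host_link <- list(n_pairs = nrow(pairs))
  }

  # ---- lifestyle ----
  if (isTRUE(stages$lifestyle)) {
    lli <- lli_by_sample(dat$phage, dat$annotation)
    lli$group <- samples$group[match(lli$sample_id, samples$sample_id)]
    lli$day <- samples$day[match(lli$sample_id, samples$sample_id)]
    write_tsv(lli, file.path(output_dir, "lli.tsv"))
    chg <- vapply(groups, function(g)
      lli_percent_change(lli$lli[lli$group == g & lli$day == days[1L]],
                         lli$lli[lli$group == g & lli$day == days[2L]]),
      numeric(1))
    cmp <- tryCatch(
      compare_groups(lli$lli[lli$day == days[2L]],
                     lli$group[lli$day == days[2L]], min_n = 5L, alpha = alpha),
      phagedyn_error = function(e) { note(conditionMessage(e)); NULL })
    if (!is.null(cmp))
      write_tsv(cmp$summary, file.path(output_dir, "lli_group_comparison.tsv"))
    report$stages$lifestyle <- list(n_samples_scored = nrow(lli))
    report$headline$community_lli_percent_change <- as.list(chg)
    if (!is.null(cmp)) report$headline$lli_kruskal_p <- cmp$kruskal_p
  }

  # ---- interactions ----
  if (isTRUE(stages$interactions) && !is.null(pairs) && nrow(pairs)) {
    corr <- suppressWarnings(
      correlate_pairs(phage_rel, dat$bacteria, pairs, samples,
                      bh_scope = config$bh_scope %||% "stratum", alpha = alpha))
    write_tsv(corr, file.path(output_dir, "correlations.tsv"))
    ctrl <- groups[1L]
    changes <- do.call(rbind, lapply(setdiff(groups, ctrl), function(g) {
      cc <- classify_change(abs(corr$rho[corr$stratum == ctrl]),
                            abs(corr$rho[corr$stratum == g]), alpha = alpha)
      data.frame(stratum = g, control = ctrl,
                 median_abs_rho_control = cc$median_control,
                 median_abs_rho_intervention = cc$median_intervention,
                 p = cc$p, direction = cc$direction, stringsAsFactors = FALSE)
    }))
    write_tsv(changes, file.path(output_dir, "changes.tsv"))
    # one-project trend vote + phage-host concordance vs the control arm
    post <- samples$day > days[1L]
    proj <- samples$project_id[1L]
    votes <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      pdir <- project_direction(
        unclass(phage_rel)[pairs$phage_id[k], samples$group == ctrl & post],
        unclass(phage_rel)[pairs$phage_id[k], samples$group == groups[2L] & post])
      hdir <- project_direction(
        unclass(dat$bacteria)[pairs$bacterium_id[k], samples$group == ctrl & post],
        unclass(dat$bacteria)[pairs$bacterium_id[k], samples$group == groups[2L] & post])
      v <- vote_trend(pdir)
      cs <- suppressWarnings(concordance(stats::setNames(pdir, proj),
                                         stats::setNames(hdir, proj)))
      data.frame(phage_id = pairs$phage_id[k], bacterium_id = pairs$bacterium_id[k],
                 n_increase = v$n_increase, n_decrease = v$n_decrease,
                 trend = v$trend, n_concordant = cs$n_concordant,
                 n_discordant = cs$n_discordant,
                 proportion_concordant = cs$proportion_concordant,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(votes[, c("phage_id", "bacterium_id", "n_increase", "n_decrease",
                        "trend")], file.path(output_dir, "votes.tsv"))
    write_tsv(votes[, c("phage_id", "bacterium_id", "n_concordant",
                        "n_discordant", "proportion_concordant")],
              file.path(output_dir, "concordance.tsv"))
    report$stages$interactions <- list(
      n_correlations = nrow(corr),
      n_significant = sum(corr$significant, na.rm = TRUE))
    report$headline$interaction_change_direction <-
      stats::setNames(as.list(changes$direction), changes$stratum)
  }

  # ---- mobilome ----
  if (isTRUE(stages$mobilome) && !is.null(dat$hgt_events)) {
    flags <- classify_phage_mediated(dat$hgt_events, dat$phage_hits)
    write_tsv(flags, file.path(output_dir, "hgt_flags.tsv"))
    counts <- table(flags$group[flags$phage_mediated])
    freq <- list()
    for (g in names(counts)) {
      b <- paste0(g, "_baseline")
      if (b %in% names(counts) && counts[[b]] > 0)
        freq[[g]] <- hgt_frequency_change(counts[[b]], counts[[g]])
    }
    roles <- donor_recipient_roles(flags[flags$phage_mediated, , drop = FALSE])
    write_tsv(roles, file.path(output_dir, "hgt_roles.tsv"))
    if (!is.null(dat$enzyme_genes)) {
      traj <- enzyme_trajectory(dat$enzyme_genes, samples)
      write_tsv(traj$medians, file.path(output_dir, "enzyme_trajectory.tsv"))
      write_tsv(traj$trend, file.path(output_dir, "enzyme_trend.tsv"))
    }
    if (!is.null(dat$ko_genes)) {
      amg <- suppressWarnings(amg_reversal_filter(
        dat$ko_genes, samples,
        groups = c(hfd = groups[2L], fuc = groups[3L]),
        baseline_day = days[1L], test_day = days[2L],
        eval_days = days[-1L], alpha = alpha))
      write_tsv(amg, file.path(output_dir, "amg_selection.tsv"))
      report$stages$mobilome <- list(
        n_events = nrow(flags), n_phage_mediated = sum(flags$phage_mediated),
        n_ko_selected = length(unique(amg$ko[amg$selected])))
    }
    report$headline$hgt_frequency_change <- lapply(freq, function(f)
      list(fold = f$fold, percent_change = f$percent_change))
  }

  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
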