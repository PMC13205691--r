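# Phage-mediated HGT classification, HGT-enzyme trajectories, the signed
# log10 difference convention, and the two-step AMG reversal filter.

#' Flag phage-mediated HGT events
#'
#' An event is phage-mediated when some alignment hit of its transferred
#' gene against a phage contig has identity strictly greater than
#' `min_identity` and E-value strictly below `max_evalue`. The best passing
#' hit (highest bit score) is recorded on the event.
#'
#' @param events HGT event table ([validate_hgt_events()] columns; the
#'   `phage_*` and `phage_mediated` columns are overwritten).
#' @param hits alignment hits keyed by transferred-gene id in `query_id`.
#' @param min_identity percent identity threshold (default 90, strict >).
#' @param max_evalue E-value threshold (default 1e-5, strict <).
#' @return the events with `phage_mediated`, `phage_contig_id`,
#'   `phage_identity`, `phage_evalue` filled in.
#' @export
classify_phage_mediated <- function(events, hits, min_identity = 90,
                                    max_evalue = 1e-5) {
  pass <- hits[hits$identity > min_identity & hits$e_value < max_evalue, ,
               drop = FALSE]
  events$phage_mediated <- FALSE
  events$phage_contig_id <- NA_character_
  events$phage_identity <- NA_real_
  events$phage_evalue <- NA_real_
  if (nrow(pass)) {
    split_hits <- split(pass, pass$query_id)
    idx <- match(events$gene_id, names(split_hits))
    for (i in which(!is.na(idx))) {
      h <- split_hits[[idx[i]]]
      best <- h[which.max(h$bit_score), ]
      events$phage_mediated[i] <- TRUE
      events$phage_contig_id[i] <- best$subject_id
      events$phage_identity[i] <- best$identity
      events$phage_evalue[i] <- best$e_value
    }
  }
  events
}

#' Fold and percent change of HGT event frequency
#'
#' @param count_baseline event count at baseline, > 0.
#' @param count_condition event count under the condition.
#' @return list: `fold` (condition / baseline) and `percent_change`
#'   (`(condition - baseline) / baseline x 100`).
#' @export
hgt_frequency_change <- function(count_baseline, count_condition) {
  if (count_baseline <= 0)
    pd_stop("baseline count must be positive for a fold change", "domain_error")
  list(fold = count_condition / count_baseline,
       percent_change = (count_condition - count_baseline) / count_baseline * 100)
}

#' Donor/recipient role bias per bacterial genus
#'
#' Tallies how often each genus appears as HGT donor vs recipient and
#' labels the role by strict majority: `donor-biased`, `recipient-biased`
#' or `balanced`.
#'
#' @param events HGT event table with `donor_genus` and `recipient_genus`.
#' @return data.frame: `genus`, `n_donor`, `n_recipient`, `role`.
#' @export
donor_recipient_roles <- function(events) {
  genera <- sort(unique(c(events$donor_genus, events$recipient_genus)))
  nd <- vapply(genera, function(g) sum(events$donor_genus == g), integer(1))
  nr <- vapply(genera, function(g) sum(events$recipient_genus == g), integer(1))
  role <- ifelse(nd > nr, "donor-biased",
                 ifelse(nr > nd, "recipient-biased", "balanced"))
  data.frame(genus = genera, n_donor = nd, n_recipient = nr, role = role,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signed log10 change between two abundances
#'
#' The verbatim plotting convention for day-pair changes:
#' `+log10(b - a)` when `b > a`, `-log10(|b - a|)` when `b < a`, 0 when
#' equal. Because the log of a small absolute difference is negative, this
#' convention is sign-unstable for `|b - a| < 1`; the `stabilized`
#' alternative `sign(b - a) * log10(|b - a| + 1)` is monotone in the
#' difference and shares its sign with `b - a` everywhere.
#'
#' @param value_a abundance at the first day (baseline).
#' @param value_b abundance at the second day.
#' @param convention `"verbatim_difference"` (default) or `"stabilized"`.
#' @return signed change value(s).
#' @export
signed_log10_change <- function(value_a, value_b,
                                convention = c("verbatim_difference", "stabilized")) {
  convention <- match.arg(convention)
  if (any(value_a < 0) || any(value_b < 0))
    pd_stop("abundances must be nonnegative", "domain_error")
  d <- value_b - value_a
  out <- if (convention == "verbatim_difference")
    ifelse(d == 0, 0, sign(d) * log10(abs(d)))
  else
    sign(d) * log10(abs(d) + 1)
  out
}

#' Median trajectories of HGT-enzyme gene abundance
#'
#' Median normalized abundance per (enzyme class, group, day) and a
#' strict-monotone trend flag: a (class, group) series is
#' `continuously_increasing` iff its medians strictly increase across the
#' ordered days.
#'
#' @param gene_table gene-level abundance ([validate_gene_abundance()])
#'   with `gene_key` in `classes`.
#' @param sample_info sample metadata providing `group` and `day`.
#' @param classes enzyme classes to summarize (default integrase,
#'   recombinase, transposase).
#' @return list: `medians` (data.frame class/group/day/median) and
#'   `trend` (data.frame class/group/continuously_increasing; NA when a
#'   group misses a day).
#' @export
enzyme_trajectory <- function(gene_table, sample_info,
                              classes = c("integrase", "recombinase", "transposase")) {
  tab <- gene_table[gene_table$gene_key %in% classes, , drop = FALSE]
  idx <- match(tab$sample_id, sample_info$sample_id)
  if (anyNA(idx))
    pd_stop("gene table contains samples absent from metadata", "schema_error")
  tab$group <- sample_info$group[idx]
  tab$day <- sample_info$day[idx]
  days <- sort(unique(sample_info$day))
  if (length(days) < 2L)
    pd_stop("need >= 2 time points", "domain_error")
  med <- stats::aggregate(value ~ gene_key + group + day, data = tab,
                          FUN = stats::median)
  names(med)[names(med) == "value"] <- "median"
  med <- med[order(med$gene_key, med$group, med$day), ]
  rownames(med) <- NULL
  combos <- unique(med[, c("gene_key", "group")])
  inc <- vapply(seq_len(nrow(combos)), function(k) {
    sub <- med[med$gene_key == combos$gene_key[k] & med$group == combos$group[k], ]
    if (!all(days %in% sub$day)) return(NA)
    m <- sub$median[match(days, sub$day)]
    all(diff(m) > 0)
  }, logical(1))
  trend <- data.frame(combos, continuously_increasing = inc,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(medians = med, trend = trend)
}

#' Two-step AMG reversal filter
#'
#' Pinpoints KEGG Orthology groups (KOs) up-regulated by the high-fat diet
#' and reversed by the polysaccharide supplement. Step 1 (retention): the
#' KO changes significantly in normalized abundance between the baseline
#' day and day 10 in *both* the HFD and FUC groups (two-sided Wilcoxon,
#' p < `alpha`). Step 2, evaluated independently at each post-baseline day:
#' (1) the HFD group is elevated over its own baseline (positive percent
#' change of the group median), and (2) at that same day the FUC median is
#' lower than the HFD median. Output is sorted by pathway, then descending
#' day-10 HFD percent change, then KO id.
#'
#' @param ko_table gene-level abundance ([validate_gene_abundance()]) with
#'   KO identifiers in `gene_key`.
#' @param sample_info sample metadata providing `group` and `day`.
#' @param groups length-2 named character vector mapping the roles to
#'   group labels, default `c(hfd = "HFD", fuc = "FUC")`.
#' @param baseline_day baseline day (default 0).
#' @param test_day day of the retention test (default 10).
#' @param eval_days days at which criterion 2 is evaluated (default
#'   10, 14, 18).
#' @param alpha retention significance level (default 0.05).
#' @return data.frame with one row per (KO, eval day): `ko`, `pathway`,
#'   `day`, `hfd_median_baseline`, `hfd_median`, `fuc_median`,
#'   `p_hfd`, `p_fuc`, `retained`, `hfd_percent_change`, `selected`.
#'   KOs missing a required group/day are excluded with a warning.
#' @export
amg_reversal_filter <- function(ko_table, sample_info,
                                groups = c(hfd = "HFD", fuc = "FUC"),
                                baseline_day = 0L, test_day = 10L,
                                eval_days = c(10L, 14L, 18L), alpha = 0.05) {
  idx <- match(ko_table$sample_id, sample_info$sample_id)
  if (anyNA(idx))
    pd_stop("KO table contains samples absent from metadata", "schema_error")
  ko_table$group <- sample_info$group[idx]
  ko_table$day <- sample_info$day[idx]
  kos <- unique(ko_table$gene_key)
  rows <- list(); dropped <- character()
  for (ko in kos) {
    sub <- ko_table[ko_table$gene_key == ko, ]
    pick <- function(g, d) sub$value[sub$group == g & sub$day == d]
    need <- list(c(groups[["hfd"]], baseline_day), c(groups[["hfd"]], test_day),
                 c(groups[["fuc"]], baseline_day), c(groups[["fuc"]], test_day))
    if (any(vapply(need, function(nd) length(pick(nd[1], as.integer(nd[2]))) == 0,
                   logical(1)))) {
      dropped <- c(dropped, ko)
      next
    }
    p_hfd <- rank_sum_p(pick(groups[["hfd"]], baseline_day),
                        pick(groups[["hfd"]], test_day))
    p_fuc <- rank_sum_p(pick(groups[["fuc"]], baseline_day),
                        pick(groups[["fuc"]], test_day))
    retained <- is.finite(p_hfd) && is.finite(p_fuc) &&
      p_hfd < alpha && p_fuc < alpha
    base_med <- stats::median(pick(groups[["hfd"]], baseline_day))
    pathway <- sub$pathway[1L]
    for (d in eval_days) {
      hm <- stats::median(pick(groups[["hfd"]], d))
      fm <- stats::median(pick(groups[["fuc"]], d))
      if (!length(hm) || !length(fm) || is.na(hm) || is.na(fm)) next
      pct <- if (base_med > 0) (hm - base_med) / base_med * 100 else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        ko = ko, pathway = pathway, day = d,
        hfd_median_baseline = base_med, hfd_median = hm, fuc_median = fm,
        p_hfd = p_hfd, p_fuc = p_fuc, retained = retained,
        hfd_percent_change = pct,
        selected = retained && !is.na(pct) && pct > 0 && fm < hm,
        stringsAsFactors = FALSE)
    }
  }
  if (length(dropped))
    pd_warn(paste("KO(s) missing a required group/day excluded:",
                  paste(dropped, collapse = ", ")))
  if (!length(rows))
    return(data.frame(ko = character(), pathway = character(), day = integer(),
                      hfd_median_baseline = numeric(), hfd_median = numeric(),
                      fuc_median = numeric(), p_hfd = numeric(),
                      p_fuc = numeric(), retained = logical(),
                      hfd_percent_change = numeric(), selected = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  # deterministic ordering: pathway, descending day-10 HFD up-regulation, KO
  d10 <- out$hfd_percent_change[match(paste(out$ko, test_day),
                                      paste(out$ko, out$day))]
  out <- out[order(out$pathway, -ifelse(is.na(d10), -Inf, d10), out$ko, out$day), ]
  rownames(out) <- NULL
  out
}

#' Cross-kingdom homolog filter with first-record deduplication
#'
#' Keeps alignment hits with E-value strictly below `max_evalue` and bit
#' score strictly above `min_bitscore`, then retains only the first
#' surviving record per query id, preserving input order.
#'
#' @param hits alignment hits in input order.
#' @param max_evalue E-value threshold (default 1e-5, strict <).
#' @param min_bitscore bit-score threshold (default 90, strict >).
#' @return the nonredundant filtered hits.
#' @export
crosskingdom_homolog_filter <- function(hits, max_evalue = 1e-5, min_bitscore = 90) {
  keep <- hits$e_value < max_evalue & hits$bit_score > min_bitscore
  out <- hits[keep, , drop = FALSE]
  out <- out[!duplicated(out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
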