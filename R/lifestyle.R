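# Lytic-lysogenic index (LLI) formulations and their group-comparison
# statistics. Three scopes:
#   community  — ratio of virulent to temperate total relative abundance;
#   vOTU       — |log2((v + 0.1) / (t + 0.1))| per viral OTU;
#   host genus — median of (v + 1) / (t + 1) across the phages of a host.

#' Community-level lytic-lysogenic index
#'
#' Ratio of virulent to temperate total relative abundance in one sample,
#' with relative abundance obtained by normalizing contig counts to total
#' viral contigs per sample.
#'
#' @param virulent_total total relative abundance of virulent phages.
#' @param temperate_total total relative abundance of temperate phages.
#' @param pseudocount added to both totals before the ratio (default 0;
#'   with 0 and a zero temperate total the ratio is undefined and a domain
#'   error is raised).
#' @return LLI ratio, > 1 meaning lytic dominance.
#' @export
lli_community <- function(virulent_total, temperate_total, pseudocount = 0) {
  if (any(virulent_total < 0) || any(temperate_total < 0))
    pd_stop("abundance totals must be nonnegative", "domain_error")
  denom <- temperate_total + pseudocount
  if (any(denom == 0))
    pd_stop("temperate total is 0 with pseudocount 0: LLI undefined", "domain_error")
  (virulent_total + pseudocount) / denom
}

#' Per-vOTU lytic-lysogenic index
#'
#' `|log2((v + 0.1) / (t + 0.1))|` with the fixed 0.1 pseudocount; symmetric
#' in its arguments by the absolute value.
#'
#' @param v virulent-state abundance of the vOTU.
#' @param t temperate-state abundance of the vOTU.
#' @return nonnegative absolute log2 ratio.
#' @export
lli_votu <- function(v, t) {
  if (any(v < 0) || any(t < 0))
    pd_stop("vOTU abundances must be nonnegative", "domain_error")
  abs(log2((v + 0.1) / (t + 0.1)))
}

#' Relative change of a per-vOTU LLI between two days
#'
#' `log10(LLI_day10 / LLI_day0 + 1)`. Note the no-change baseline of this
#' convention is `log10(2)`, not 0; see `convention = "ratio"` for a plain
#' signed log-ratio alternative. A zero day-0 LLI cannot be scored: the
#' record is skipped (NA) with a warning.
#'
#' @param lli_d0 LLI at day 0 (baseline), > 0.
#' @param lli_d10 LLI at day 10.
#' @param convention `"plus_one"` (default, verbatim formulation) or
#'   `"ratio"` (`log10(lli_d10 / lli_d0)`, no-change baseline 0).
#' @return real change score (NA where the baseline LLI is 0).
#' @export
lli_votu_change <- function(lli_d0, lli_d10, convention = c("plus_one", "ratio")) {
  convention <- match.arg(convention)
  if (any(lli_d0 < 0) || any(lli_d10 < 0))
    pd_stop("LLI values must be nonnegative", "domain_error")
  zero <- lli_d0 == 0
  if (any(zero))
    pd_warn(sprintf("%d record(s) with LLI_day0 = 0 skipped", sum(zero)))
  out <- if (convention == "plus_one") log10(lli_d10 / lli_d0 + 1)
         else log10(lli_d10 / lli_d0)
  out[zero] <- NA_real_
  out
}

#' Host-genus-level lytic-lysogenic index
#'
#' Median of `(v + 1) / (t + 1)` across all phages infecting one host
#' genus; even-length sets take the midpoint mean.
#'
#' @param v virulent phage abundances for the genus (one entry per phage).
#' @param t temperate phage abundances, aligned with `v`.
#' @return median ratio.
#' @export
lli_host_genus <- function(v, t) {
  if (length(v) == 0L || length(v) != length(t))
    pd_stop("need a nonempty, aligned (v, t) set", "domain_error")
  if (any(v < 0) || any(t < 0))
    pd_stop("abundances must be nonnegative", "domain_error")
  stats::median((v + 1) / (t + 1))
}

#' Signed log10 fold change of a host-genus LLI
#'
#' `log10(lli_d10 / lli_d0)`; positive values indicate a shift toward lytic
#' dominance, negative toward lysogenic dominance.
#'
#' @param lli_d0,lli_d10 genus-level LLI at the two days, both > 0.
#' @return signed log10 fold change.
#' @export
lli_shift <- function(lli_d0, lli_d10) {
  if (any(lli_d0 <= 0) || any(lli_d10 <= 0))
    pd_stop("lli_shift needs positive LLI values", "domain_error")
  log10(lli_d10 / lli_d0)
}

#' Per-sample community LLI from a phage abundance matrix
#'
#' Converts counts to per-sample relative fractions, sums virulent and
#' temperate phage abundance per sample (taxa with `unknown` lifestyle are
#' excluded) and forms the community LLI.
#'
#' @param m phage `abundance_matrix` (`read_count` matrices are converted
#'   with [to_relative()]; relative matrices are used as-is).
#' @param annotation taxon annotation with `taxon_id` and `lifestyle`.
#' @param pseudocount passed to [lli_community()] (default 0.01 so samples
#'   lacking temperate signal remain scoreable).
#' @return data.frame with columns `sample_id`, `virulent`, `temperate`,
#'   `lli`.
#' @export
lli_by_sample <- function(m, annotation, pseudocount = 0.01) {
  if (abundance_unit(m) == "read_count") m <- to_relative(m)
  v <- unclass(m)
  ls <- annotation$lifestyle[match(rownames(v), annotation$taxon_id)]
  if (anyNA(ls))
    pd_stop("every phage taxon must be annotated with a lifestyle", "schema_error")
  vir <- colSums(v[ls == "virulent", , drop = FALSE])
  tem <- colSums(v[ls == "temperate", , drop = FALSE])
  data.frame(sample_id = colnames(v), virulent = vir, temperate = tem,
             lli = lli_community(vir, tem, pseudocount = pseudocount),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percent change of the average LLI between two sets of samples
#'
#' `(mean(after) - mean(before)) / mean(before) x 100`; the community-level
#' decrease/increase summaries use the mean.
#'
#' @param before,after LLI values for the two time points.
#' @return percent change (negative = decrease).
#' @export
lli_percent_change <- function(before, after) {
  mb <- mean(before)
  if (!is.finite(mb) || mb <= 0)
    pd_stop("baseline mean LLI must be positive", "domain_error")
  (mean(after) - mb) / mb * 100
}

# ---- Kruskal-Wallis + Dunn + BH group comparison --------------------------

# Dunn's z statistics on pooled average ranks with the tie correction.
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  mean_rank <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  gl <- levels(groups)
  pairs <- utils::combn(gl, 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term / (12 * (N - 1))) *
               (1 / n[[a]] + 1 / n[[b]]))
    z[k] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z,
             p_raw = p, stringsAsFactors = FALSE)
}

# Insert-and-absorb compact letter display. `signif` is a symmetric logical
# matrix (TRUE = significantly different) with group names on the dimnames.
compact_letters <- function(signif) {
  gl <- rownames(signif)
  sets <- list(gl)
  pairs <- which(signif & upper.tri(signif), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    a <- gl[pairs[k, 1L]]; b <- gl[pairs[k, 2L]]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb sets fully contained in another
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) for (j in seq_along(new_sets)) {
      if (i != j && keep[i] && keep[j] &&
          all(new_sets[[i]] %in% new_sets[[j]]) &&
          !(all(new_sets[[j]] %in% new_sets[[i]]) && i < j))
        keep[i] <- FALSE
    }
    sets <- new_sets[keep]
  }
  letters_out <- stats::setNames(rep("", length(gl)), gl)
  for (i in seq_along(sets))
    for (g in sets[[i]])
      letters_out[g] <- paste0(letters_out[g], letters[i])
  letters_out
}

#' Compare a statistic across diet groups
#'
#' Kruskal-Wallis test (with the standard tie correction), Dunn's post-hoc
#' pairwise z tests, Benjamini-Hochberg adjustment within the pairwise
#' family, and a compact-letter display at adjusted p < `alpha`: groups
#' sharing a letter are not significantly different.
#'
#' @param values numeric vector of the per-observation statistic.
#' @param groups group label per observation.
#' @param min_n minimum observations per group (default 5); groups below it
#'   are dropped with a warning, and fewer than two surviving groups is an
#'   error.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list with `summary` (per-group n / median / mean / letter),
#'   `kruskal_p`, `dunn` (pairwise z, raw and BH-adjusted p), `letters`.
#' @export
compare_groups <- function(values, groups, min_n = 5L, alpha = 0.05) {
  keep <- !is.na(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  n <- table(groups)
  small <- names(n)[n < min_n]
  if (length(small)) {
    pd_warn(sprintf("group(s) below min_n = %d dropped: %s", min_n,
                    paste(small, collapse = ", ")))
    sel <- !groups %in% small
    values <- values[sel]; groups <- groups[sel]
  }
  if (length(unique(groups)) < 2L)
    pd_stop("need >= 2 groups with at least min_n observations", "domain_error")
  groups <- factor(groups)
  kw <- stats::kruskal.test(values, groups)
  dn <- dunn_test(values, groups)
  dn$p_adj <- bh_adjust(dn$p_raw)
  gl <- levels(groups)
  sig <- matrix(FALSE, length(gl), length(gl), dimnames = list(gl, gl))
  for (k in seq_len(nrow(dn))) {
    s <- dn$p_adj[k] < alpha
    sig[dn$group1[k], dn$group2[k]] <- s
    sig[dn$group2[k], dn$group1[k]] <- s
  }
  # post-hoc letters only meaningful when the omnibus test fires
  lt <- if (is.finite(kw$p.value) && kw$p.value < alpha) compact_letters(sig)
        else stats::setNames(rep("a", length(gl)), gl)
  summ <- data.frame(group = gl,
                     n = as.integer(table(groups)[gl]),
                     median = as.numeric(tapply(values, groups, stats::median)[gl]),
                     mean = as.numeric(tapply(values, groups, mean)[gl]),
                     letter = as.character(lt[gl]),
                     stringsAsFactors = FALSE)
  list(summary = summ, kruskal_p = kw$p.value, dunn = dn, letters = lt)
}
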