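# Nomenclature-based phage-host linking: a phage is paired with a
# bacterium when the first genus-level token of its species name exactly
# matches the bacterial genus, with a manual override sending crAssphages
# to Bacteroides (genus) / Bacteroidetes (phylum).

phage_designators <- c("phage", "virus", "siphovirus", "myovirus",
                       "podovirus", "inovirus", "microvirus", "crassphage")

strip_rank_prefix <- function(x) sub("^s_{1,2}", "", x)

#' Parse the candidate host genus from a phage species name
#'
#' Strips the species rank prefix (`s__` or `s_`), splits the name on
#' underscores, and returns the first capitalized genus-like token that
#' precedes a phage designator token (`phage`, `virus`, `siphovirus`, ...).
#' Names containing "crass" (case-insensitive) take the crAssphage
#' override: host genus `Bacteroides`, method `crassphage_override`.
#' Unparseable names yield `NA` with method `none`.
#'
#' @param species_name character vector of phage species names
#'   (e.g. `"s__Bacteroides_phage"`).
#' @return data.frame with columns `species_name`, `host_genus`, `method`
#'   (`nomenclature` / `crassphage_override` / `none`) and `ambiguous`
#'   (TRUE when the name held more than one capitalized candidate token,
#'   in which case the first wins).
#' @examples
#' parse_host_genus(c("s__Bacteroides_phage", "s__crAssphage_sp",
#'                    "s__uncultured_virus"))
#' @export
parse_host_genus <- function(species_name) {
  one <- function(nm) {
    if (is.na(nm) || !nzchar(nm))
      return(list(genus = NA_character_, method = "none", ambiguous = FALSE))
    if (grepl("crass", nm, ignore.case = TRUE))
      return(list(genus = "Bacteroides", method = "crassphage_override",
                  ambiguous = FALSE))
    tokens <- strsplit(strip_rank_prefix(nm), "_", fixed = TRUE)[[1L]]
    tokens <- tokens[nzchar(tokens)]
    cap <- grepl("^[A-Z][a-z]+$", tokens)
    desig <- tolower(tokens) %in% phage_designators
    hit <- which(cap & !desig)
    hit <- hit[vapply(hit, function(i) any(desig[seq_along(tokens) > i]), logical(1))]
    if (!length(hit))
      return(list(genus = NA_character_, method = "none", ambiguous = FALSE))
    list(genus = tokens[hit[1L]], method = "nomenclature",
         ambiguous = length(hit) > 1L)
  }
  parsed <- lapply(species_name, one)
  data.frame(species_name = species_name,
             host_genus = vapply(parsed, `[[`, character(1), "genus"),
             method = vapply(parsed, `[[`, character(1), "method"),
             ambiguous = vapply(parsed, `[[`, logical(1), "ambiguous"),
             stringsAsFactors = FALSE)
}

#' Genus token of a bacterial species name
#'
#' First token after the rank prefix, e.g. `"s__Bacteroides_plebeius"` ->
#' `"Bacteroides"`.
#'
#' @param species_name character vector of bacterial species names.
#' @return character vector of genus tokens (`NA` when not genus-like).
#' @export
bacterial_genus <- function(species_name) {
  tok <- vapply(strsplit(strip_rank_prefix(species_name), "_", fixed = TRUE),
                function(t) if (length(t)) t[[1L]] else NA_character_,
                character(1))
  ifelse(grepl("^[A-Z][a-z]+$", tok), tok, NA_character_)
}

#' Enumerate candidate phage-bacterium pairs by nomenclature matching
#'
#' Emits every (phage, bacterium) pair whose parsed phage host genus
#' exactly equals the bacterial genus (case-sensitive by default);
#' crAssphages are paired with every `Bacteroides` bacterium. Output is
#' canonically sorted and duplicate-free, so it does not depend on input
#' ordering.
#'
#' @param phages annotation data.frame for viral taxa (`taxon_id`,
#'   `species_name`; a populated `host_genus`+`host_link_method = provided`
#'   is honored as-is).
#' @param bacteria annotation data.frame for bacterial taxa (`taxon_id`,
#'   `species_name`).
#' @param taxonomy optional genus -> phylum lookup (see [rollup_phylum()])
#'   used to annotate each link.
#' @param case_insensitive match genera ignoring case (default FALSE,
#'   mirroring exact matching).
#' @return data.frame with columns `phage_id`, `bacterium_id`,
#'   `host_genus`, `host_phylum`, `method`.
#' @export
link_pairs <- function(phages, bacteria, taxonomy = NULL, case_insensitive = FALSE) {
  parsed <- parse_host_genus(phages$species_name)
  genus <- parsed$host_genus
  method <- parsed$method
  if (!is.null(phages$host_link_method)) {
    prov <- which(phages$host_link_method == "provided")
    genus[prov] <- phages$host_genus[prov]
    method[prov] <- "provided"
  }
  bgen <- bacterial_genus(bacteria$species_name)
  norm <- function(x) if (case_insensitive) tolower(x) else x
  rows <- list()
  for (i in seq_along(genus)) {
    g <- genus[i]
    if (is.na(g)) next
    j <- which(!is.na(bgen) & norm(bgen) == norm(g))
    if (!length(j)) next
    rows[[length(rows) + 1L]] <- data.frame(
      phage_id = phages$taxon_id[i],
      bacterium_id = bacteria$taxon_id[j],
      host_genus = g,
      method = method[i],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phage_id = character(), bacterium_id = character(),
               host_genus = character(), method = character(),
               stringsAsFactors = FALSE)
  out <- unique(out)
  out$host_phylum <- ifelse(out$method == "crassphage_override", "Bacteroidetes",
                            rollup_phylum(out$host_genus, taxonomy))
  out <- out[order(out$phage_id, out$bacterium_id),
             c("phage_id", "bacterium_id", "host_genus", "host_phylum", "method")]
  rownames(out) <- NULL
  out
}

#' Roll a host genus up to its phylum
#'
#' @param genus character vector of genus names.
#' @param taxonomy data.frame with columns `genus`, `phylum`; `NULL` yields
#'   all-`NA`.
#' @return character vector of phyla (`NA` when the genus is absent).
#' @export
rollup_phylum <- function(genus, taxonomy = NULL) {
  if (is.null(taxonomy)) return(rep(NA_character_, length(genus)))
  if (!all(c("genus", "phylum") %in% names(taxonomy)))
    pd_stop("taxonomy table needs columns genus, phylum", "schema_error")
  taxonomy$phylum[match(genus, taxonomy$genus)]
}
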