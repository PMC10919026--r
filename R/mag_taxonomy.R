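#' Tier MAGs by completeness and contamination
#'
#' Quality tiers follow the standard thresholds used for retaining MAGs:
#' *high* requires completeness strictly greater than 90% and
#' contamination below 5%; *medium* (among the rest) requires
#' completeness of at least 50% and contamination below 10%; everything
#' else is *discarded*. The inequalities are deliberately asymmetric
#' (strict > 90 for high, >= 50 for medium) and boundary cases are
#' unit-tested.
#'
#' @param mags MAG metadata data.frame (see [read_mag_metadata()]).
#' @return List with `tiers` (data.frame `mag_id`, `host_sample`,
#'   `completeness_pct`, `contamination_pct`, `tier`) and `summary`
#'   (counts per `host_sample` x `tier`).
#' @export
#' @examples
#' m <- data.frame(mag_id = "m1", host_sample = "Sc", size_bp = 3e6,
#'                 completeness_pct = 92, contamination_pct = 3,
#'                 gtdb_classification = "unclassified")
#' tier_mags(m)$tiers$tier
tier_mags <- function(mags) {
  validate_mag_metadata(mags)
  tier <- quality_tier(mags$completeness_pct, mags$contamination_pct)
  tiers <- data.frame(mag_id = mags$mag_id,
                      host_sample = mags$host_sample,
                      completeness_pct = mags$completeness_pct,
                      contamination_pct = mags$contamination_pct,
                      tier = tier,
                      stringsAsFactors = FALSE)
  summary <- as.data.frame(table(host_sample = tiers$host_sample,
                                 tier = factor(tiers$tier,
                                               levels = c("high", "medium",
                                                          "discarded"))),
                           responseName = "n", stringsAsFactors = FALSE)
  list(tiers = tiers, summary = summary)
}

#' Vectorized quality-tier rule
#'
#' @param completeness_pct,contamination_pct Numeric vectors (percent).
#' @return Character vector: `"high"`, `"medium"` or `"discarded"`.
#' @export
quality_tier <- function(completeness_pct, contamination_pct) {
  ifelse(completeness_pct > 90 & contamination_pct < 5, "high",
         ifelse(completeness_pct >= 50 & contamination_pct < 10, "medium",
                "discarded"))
}

gtdb_rank_names <- c("domain", "phylum", "class", "order", "family",
                     "genus", "species")

#' Call taxonomic novelty from GTDB classification strings
#'
#' A MAG whose GTDB string stops above the species rank represents a
#' candidate novel taxon. The call is a pure function of the rank string:
#' \itemize{
#'   \item species assigned: `known_species`;
#'   \item genus assigned, species empty: `novel_species`;
#'   \item family assigned, genus empty: `novel_genus`;
#'   \item order assigned, family empty: `novel_family`;
#'   \item lowest assigned rank above family (order empty): `novel_higher`;
#'   \item literal `"unclassified"` or empty domain: `unclassified`.
#' }
#' `novel_family` deliberately requires an assigned order; less resolved
#' placements fall into the explicit `novel_higher` residual instead of
#' being guessed downward.
#'
#' @param mags MAG metadata data.frame.
#' @return data.frame `mag_id`, `lowest_assigned_rank` (one of the seven
#'   ranks or `"none"`), `novelty`.
#' @export
call_novelty <- function(mags) {
  ranks <- parse_gtdb(mags$gtdb_classification)
  out <- data.frame(mag_id = mags$mag_id,
                    lowest_assigned_rank = NA_character_,
                    novelty = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mags))) {
    r <- as.character(ranks[i, ])
    assigned <- !is.na(r) & nzchar(r)
    out$lowest_assigned_rank[i] <- if (any(assigned)) {
      gtdb_rank_names[max(which(assigned))]
    } else "none"
    out$novelty[i] <- novelty_rule(assigned)
  }
  out
}

novelty_rule <- function(assigned) {
  names(assigned) <- gtdb_rank_names
  if (!assigned[["domain"]]) return("unclassified")
  if (assigned[["species"]]) return("known_species")
  if (assigned[["genus"]]) return("novel_species")
  if (assigned[["family"]]) return("novel_genus")
  if (assigned[["order"]]) return("novel_family")
  "novel_higher"
}

#' Aggregate per-MAG densities by taxon
#'
#' Groups per-MAG density records (from [function_density()] or
#' [cluster_density()], `sample_id` = MAG id) by the taxon assigned at
#' one GTDB rank and summarizes each (taxon, key): number of
#' contributing MAGs, mean and max density. MAGs with an empty rank are
#' grouped under the sentinel `"(unassigned at rank)"`.
#'
#' @param density_records data.frame of density records over MAGs.
#' @param mags MAG metadata data.frame covering every profiled MAG.
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return List with `summary` (data.frame `taxon`, `key`, `level`,
#'   `n_mags`, `mean_density`, `max_density`), `per_mag` (the input
#'   records with a `taxon` column), and `mag_counts` (data.frame
#'   `taxon`, `n_mags` over all profiled MAGs).
#' @export
aggregate_by_taxon <- function(density_records, mags,
                               rank = c("phylum", "class", "order",
                                        "family", "genus")) {
  rank <- match.arg(rank)
  unknown <- setdiff(unique(density_records$sample_id), mags$mag_id)
  if (length(unknown)) {
    stop("density records reference MAG(s) absent from metadata: ",
         paste(unknown, collapse = ", "))
  }
  ranks <- parse_gtdb(mags$gtdb_classification)
  label <- ranks[[rank]]
  label[is.na(label) | !nzchar(label)] <- "(unassigned at rank)"
  taxon_of <- stats::setNames(label, mags$mag_id)

  per_mag <- density_records
  per_mag$taxon <- unname(taxon_of[per_mag$sample_id])

  grp <- interaction(per_mag$taxon, per_mag$key, drop = TRUE, sep = "\r")
  pieces <- split(per_mag, grp)
  summary <- do.call(rbind, lapply(pieces, function(p) {
    data.frame(taxon = p$taxon[1], key = p$key[1], level = p$level[1],
               n_mags = length(unique(p$sample_id)),
               mean_density = mean(p$density),
               max_density = max(p$density),
               stringsAsFactors = FALSE)
  }))
  if (is.null(summary)) {
    summary <- data.frame(taxon = character(0), key = character(0),
                          level = character(0), n_mags = integer(0),
                          mean_density = numeric(0),
                          max_density = numeric(0),
                          stringsAsFactors = FALSE)
  }
  summary <- summary[order(summary$taxon, summary$key), , drop = FALSE]
  rownames(summary) <- NULL

  profiled <- unique(density_records$sample_id)
  mag_counts <- as.data.frame(table(taxon = taxon_of[profiled]),
                              responseName = "n_mags",
                              stringsAsFactors = FALSE)
  list(summary = summary, per_mag = per_mag, mag_counts = mag_counts)
}
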