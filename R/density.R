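density_record_frame <- function(sample_id, key, level, n_genes, size_mbp,
                                 decimals) {
  density <- n_genes / size_mbp
  data.frame(sample_id = rep(sample_id, length(key)),
             key = key, level = rep(level, length(key)),
             n_genes = as.integer(n_genes),
             density = density,
             density_display = round(density, decimals),
             stringsAsFactors = FALSE)
}

#' Per-function gene densities for one sample
#'
#' The gene density of a function is the number of annotated genes
#' carrying its EC divided by the sample's assembled size in Mbp
#' (genes/Mbp). By default only functions observed at least once are
#' emitted; with `dense = TRUE` every catalog EC appears, zeros included.
#'
#' @param profile A `sample_profile`.
#' @param catalog The matching `halogen_catalog`; required when
#'   `dense = TRUE`.
#' @param decimals Decimals for the display-rounded column (default 2,
#'   the precision of published density values).
#' @param dense Emit zero-count ECs too.
#' @return data.frame of density records: `sample_id`, `key` (EC),
#'   `level` (`"function"`), `n_genes`, `density` (full precision),
#'   `density_display`.
#' @export
#' @examples
#' prof <- screen_sample(example_annotation_table(), load_catalog())
#' function_density(prof)
function_density <- function(profile, catalog = NULL, decimals = 2,
                             dense = FALSE) {
  stopifnot(inherits(profile, "sample_profile"))
  if (!is.finite(profile$size_mbp) || profile$size_mbp <= 0) {
    stop("sample ", profile$sample_id, " has non-positive size_mbp")
  }
  counts <- profile$counts
  if (dense) {
    if (is.null(catalog)) stop("dense export requires the catalog")
    all_ecs <- sort(catalog$functions$ec)
    n <- stats::setNames(rep(0L, length(all_ecs)), all_ecs)
    n[counts$ec] <- counts$n_genes
    density_record_frame(profile$sample_id, all_ecs, "function",
                         unname(n), profile$size_mbp, decimals)
  } else {
    density_record_frame(profile$sample_id, counts$ec, "function",
                         counts$n_genes, profile$size_mbp, decimals)
  }
}

#' Per-cluster gene densities for one sample
#'
#' A cluster's gene count is the sum of its member ECs' counts; an EC
#' belonging to k clusters contributes its full count to each of the k
#' clusters (within one cluster each (feature, EC) pair counts once).
#' All clusters of the catalog are emitted, zeros included, so cluster
#' profiles are directly comparable across samples.
#'
#' @inheritParams function_density
#' @return data.frame of density records with `level = "cluster"` and
#'   `key` = cluster id, in catalog cluster order.
#' @export
cluster_density <- function(profile, catalog, decimals = 2) {
  stopifnot(inherits(profile, "sample_profile"),
            inherits(catalog, "halogen_catalog"))
  if (!identical(profile$catalog_version, catalog$version)) {
    stop("profile for sample ", profile$sample_id,
         " was screened against a different catalog version")
  }
  if (!is.finite(profile$size_mbp) || profile$size_mbp <= 0) {
    stop("sample ", profile$sample_id, " has non-positive size_mbp")
  }
  count_of <- stats::setNames(profile$counts$n_genes, profile$counts$ec)
  n <- vapply(catalog$clusters$member_ecs, function(members) {
    hit <- count_of[members]
    sum(hit[!is.na(hit)])
  }, numeric(1))
  density_record_frame(profile$sample_id, catalog$clusters$cluster_id,
                       "cluster", n, profile$size_mbp, decimals)
}

presence_sets <- function(profiles, catalog, level) {
  lapply(profiles, function(p) {
    if (level == "function") {
      p$counts$ec[p$counts$n_genes >= 1L]
    } else {
      cd <- cluster_density(p, catalog)
      cd$key[cd$n_genes >= 1L]
    }
  })
}

make_comparison_report <- function(sets) {
  sample_ids <- names(sets)
  inter <- Reduce(intersect, sets)
  uni <- sort(unique(unlist(sets, use.names = FALSE)))
  pairs <- if (length(sets) >= 2) {
    combos <- utils::combn(sample_ids, 2)
    data.frame(
      sample_a = combos[1, ], sample_b = combos[2, ],
      n_shared = apply(combos, 2, function(p) {
        length(intersect(sets[[p[1]]], sets[[p[2]]]))
      }),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(sample_a = character(0), sample_b = character(0),
               n_shared = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(
    sample_ids = sample_ids,
    sets = sets,
    intersection = sort(inter),
    union = uni,
    pairwise = pairs,
    shared_fraction = if (length(uni)) length(inter) / length(uni)
                      else NA_real_
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", length(x$sample_ids), " samples: |intersection| = ",
      length(x$intersection), ", |union| = ", length(x$union),
      ", shared fraction = ",
      ifelse(is.na(x$shared_fraction), "NA",
             format(x$shared_fraction, digits = 4)), "\n", sep = "")
  invisible(x)
}

#' Shared-function comparison across samples
#'
#' Presence is binary (`n_genes >= 1`). Reports per-sample presence sets,
#' their intersection and union, pairwise shared counts, and the shared
#' fraction |intersection| / |union| (NA when the union is empty).
#'
#' @param profiles List of `sample_profile`s (length >= 2), all screened
#'   against the same catalog.
#' @param catalog The common `halogen_catalog`.
#' @param level `"function"` (presence of ECs) or `"cluster"`.
#' @return A `comparison_report`.
#' @export
compare_samples <- function(profiles, catalog, level = c("function", "cluster")) {
  level <- match.arg(level)
  if (length(profiles) < 2) stop("need at least 2 profiles to compare")
  versions <- unique(vapply(profiles, `[[`, "", "catalog_version"))
  if (length(versions) != 1 || !identical(versions, catalog$version)) {
    stop("profiles were screened against mixed or mismatching catalogs")
  }
  sets <- presence_sets(profiles, catalog, level)
  names(sets) <- vapply(profiles, `[[`, "", "sample_id")
  make_comparison_report(sets)
}

#' Shared-taxon comparison across samples
#'
#' Applies the same set algebra as [compare_samples()] to per-sample taxon
#' label lists at one rank (labels are case-folded and
#' whitespace-normalized first). Also emits a long-format table suitable
#' for chord-diagram rendering: one row per (sample, taxon) with a mask
#' naming every sample sharing that taxon.
#'
#' @param taxon_tables Named list (one element per sample) of character
#'   vectors of taxon labels.
#' @return List with `report` (a `comparison_report`) and `long`
#'   (data.frame `sample`, `taxon`, `shared_with_mask`, `n_samples`).
#' @export
shared_taxa <- function(taxon_tables) {
  if (is.null(names(taxon_tables)) || any(!nzchar(names(taxon_tables)))) {
    stop("taxon_tables must be a named list (one element per sample)")
  }
  norm <- lapply(names(taxon_tables), function(s) {
    labels <- taxon_tables[[s]]
    if (!length(labels)) {
      warning("sample ", s, " has an empty taxon table; treated as empty set")
      return(character(0))
    }
    unique(tolower(gsub("[[:space:]]+", " ", trimws(labels))))
  })
  names(norm) <- names(taxon_tables)
  report <- make_comparison_report(norm)
  long_rows <- lapply(names(norm), function(s) {
    taxa <- norm[[s]]
    if (!length(taxa)) return(NULL)
    with_whom <- vapply(taxa, function(t) {
      holders <- names(norm)[vapply(norm, function(set) t %in% set,
                                    logical(1))]
      paste(holders, collapse = "|")
    }, character(1))
    data.frame(sample = s, taxon = taxa, shared_with_mask = with_whom,
               n_samples = lengths(strsplit(with_whom, "|", fixed = TRUE)),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, c(long_rows,
                           list(data.frame(sample = character(0),
                                           taxon = character(0),
                                           shared_with_mask = character(0),
                                           n_samples = integer(0),
                                           stringsAsFactors = FALSE))))
  rownames(long) <- NULL
  list(report = report, long = long)
}

#' Wide density matrix across samples
#'
#' Rows are keys (ECs or cluster ids), columns are samples; values are
#' full-precision densities.
#'
#' @param density_tables List of density record data.frames (all the same
#'   `level`), e.g. from [function_density()] per sample.
#' @return data.frame with a `key` column followed by one numeric column
#'   per sample; missing (sample, key) combinations are 0.
#' @export
density_matrix <- function(density_tables) {
  all <- do.call(rbind, density_tables)
  if (!nrow(all)) {
    return(data.frame(key = character(0), stringsAsFactors = FALSE))
  }
  keys <- sort(unique(all$key))
  samples <- unique(all$sample_id)
  out <- data.frame(key = keys, stringsAsFactors = FALSE)
  for (s in samples) {
    sub <- all[all$sample_id == s, , drop = FALSE]
    v <- stats::setNames(rep(0, length(keys)), keys)
    v[sub$key] <- sub$density
    out[[s]] <- unname(v)
  }
  out
}
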