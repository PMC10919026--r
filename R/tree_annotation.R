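#' Build per-MAG annotation tracks for tree overlays
#'
#' For each screened MAG, computes summary gene densities suitable as
#' tree-annotation tracks: `total` (all catalog functions), `halogenase`,
#' `dehalogenase`, `hydrolytic`, `non_hydrolytic` (direct subset splits)
#' and one track per cluster id.
#'
#' @param profiles List of per-MAG `sample_profile`s.
#' @param catalog The matching `halogen_catalog`.
#' @return Long data.frame `mag_id`, `track`, `density`.
#' @export
build_mag_tracks <- function(profiles, catalog) {
  rows <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "sample_profile"))
    splits <- split_ec42(p, catalog)
    cd <- cluster_density(p, catalog)
    data.frame(
      mag_id = p$sample_id,
      track = c("total", "halogenase", "dehalogenase", "hydrolytic",
                "non_hydrolytic", cd$key),
      density = c(p$n_target_genes / p$size_mbp,
                  vapply(splits, function(s) sum(s$n_genes),
                         numeric(1)) / p$size_mbp,
                  cd$density),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Join per-MAG tracks and taxonomy onto a phylogenetic tree
#'
#' Produces, for each requested track, a per-leaf value table in the
#' tree's own leaf-label order (leaf order is never rearranged), plus a
#' taxonomic color-strip table at the order rank. Leaves whose label
#' starts with the reference prefix are passed through untouched and
#' flagged as reference genomes; MAG leaves without a computed track
#' value get 0 with a missing flag.
#'
#' @param tree An ape `phylo` object, or the list returned by
#'   [read_tree()].
#' @param tracks_df Long track table from [build_mag_tracks()].
#' @param mags MAG metadata data.frame.
#' @param tracks Character vector of track names to emit; must exist in
#'   `tracks_df`.
#' @param ref_prefix Leaf-label prefix marking external reference genomes
#'   (default `"Ref"`).
#' @return An `itol_bundle`: list with `leaves`, per-track data.frames
#'   (`leaf`, `value`, `missing`, `reference`) under `tracks`, and
#'   `color_strip` (`leaf`, `order`, `reference`).
#' @export
annotate_tree <- function(tree, tracks_df, mags, tracks,
                          ref_prefix = "Ref") {
  if (is.list(tree) && !inherits(tree, "phylo") && !is.null(tree$tree)) {
    tree <- tree$tree
  }
  stopifnot(inherits(tree, "phylo"))
  available <- unique(tracks_df$track)
  unknown <- setdiff(tracks, available)
  if (length(unknown)) {
    stop("requested track(s) not computed: ",
         paste(unknown, collapse = ", "),
         "; available tracks: ", paste(sort(available), collapse = ", "))
  }
  leaves <- tree$tip.label
  is_ref <- startsWith(leaves, ref_prefix)
  stray <- setdiff(leaves[!is_ref], mags$mag_id)
  if (length(stray)) {
    stop("tree leaves neither MAGs nor '", ref_prefix,
         "'-prefixed references: ", paste(stray, collapse = ", "))
  }

  track_tables <- lapply(tracks, function(tr) {
    sub <- tracks_df[tracks_df$track == tr, , drop = FALSE]
    val <- stats::setNames(sub$density, sub$mag_id)
    value <- unname(val[leaves])
    missing <- is.na(value) & !is_ref
    value[is.na(value)] <- 0
    data.frame(leaf = leaves, value = value, missing = missing,
               reference = is_ref, stringsAsFactors = FALSE)
  })
  names(track_tables) <- tracks

  ranks <- parse_gtdb(mags$gtdb_classification)
  order_of <- stats::setNames(ranks$order, mags$mag_id)
  order_label <- unname(order_of[leaves])
  order_label[is_ref] <- "(reference)"
  order_label[is.na(order_label) | !nzchar(order_label)] <-
    ifelse(is_ref[is.na(order_label) | !nzchar(order_label)],
           "(reference)", "(unassigned)")
  color_strip <- data.frame(leaf = leaves, order = order_label,
                            reference = is_ref, stringsAsFactors = FALSE)

  structure(list(leaves = leaves, tracks = track_tables,
                 color_strip = color_strip),
            class = "itol_bundle")
}

itol_palette <- function(n) {
  base <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
            "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf")
  rep(base, length.out = n)
}

#' Write an annotation bundle as iTOL datasets plus plain TSV twins
#'
#' Each track becomes a `DATASET_SIMPLEBAR` text file in the iTOL dataset
#' dialect (header block + tab-separated rows), the taxonomic orders a
#' `DATASET_COLORSTRIP`, and every dataset is mirrored by a renderer-
#' independent long-format TSV. Output is deterministic: identical inputs
#' produce byte-identical files.
#'
#' @param bundle An `itol_bundle` from [annotate_tree()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_itol_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "itol_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)

  for (tr in names(bundle$tracks)) {
    tab <- bundle$tracks[[tr]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", tr)
    itol_path <- file.path(dir, paste0("itol_simplebar_", safe, ".txt"))
    header <- c(
      "DATASET_SIMPLEBAR",
      "SEPARATOR TAB",
      paste0("DATASET_LABEL\t", tr, " gene density (genes/Mbp)"),
      "COLOR\t#1f77b4",
      "DATA"
    )
    rows <- paste(tab$leaf, sprintf("%.17g", tab$value), sep = "\t")
    writeLines(c(header, rows), itol_path)
    tsv_path <- file.path(dir, paste0("track_", safe, ".tsv"))
    write_result_tsv(
      data.frame(leaf = tab$leaf, track = tr, density = tab$value,
                 missing = tab$missing, reference = tab$reference,
                 stringsAsFactors = FALSE),
      tsv_path)
    written <- c(written, itol_path, tsv_path)
  }

  strip <- bundle$color_strip
  orders <- sort(unique(strip$order))
  colors <- stats::setNames(itol_palette(length(orders)), orders)
  strip_path <- file.path(dir, "itol_colorstrip_order.txt")
  header <- c(
    "DATASET_COLORSTRIP",
    "SEPARATOR TAB",
    "DATASET_LABEL\ttaxonomic order",
    "COLOR\t#7f7f7f",
    "DATA"
  )
  rows <- paste(strip$leaf, unname(colors[strip$order]), strip$order,
                sep = "\t")
  writeLines(c(header, rows), strip_path)
  strip_tsv <- file.path(dir, "track_order_strip.tsv")
  write_result_tsv(strip, strip_tsv)

  invisible(c(written, strip_path, strip_tsv))
}
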