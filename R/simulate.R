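#' Packaged GTDB taxon pool for simulation
#'
#' GTDB-style classification strings spanning the bacterial orders most
#' relevant to macroalgal halogen metabolism (Rhodobacterales,
#' Rhizobiales, Caulobacterales, Geminicoccales, Sphingomonadales,
#' Granulosicoccales, Microtrichales, Pseudomonadales, Flavobacteriales,
#' UBA10353, UBA9160), at varying taxonomic resolution so simulated MAG
#' sets exercise every novelty category.
#'
#' @return Named list of character vectors of GTDB strings, one vector
#'   per novelty category (`known_species`, `novel_species`,
#'   `novel_genus`, `novel_family`, `novel_higher`, `unclassified`).
#' @export
default_taxon_pool <- function() {
  g <- function(p, c, o, f = "", g = "", s = "") {
    sprintf("d__Bacteria;p__%s;c__%s;o__%s;f__%s;g__%s;s__%s",
            p, c, o, f, g, s)
  }
  list(
    known_species = c(
      g("Proteobacteria", "Alphaproteobacteria", "Rhodobacterales",
        "Rhodobacteraceae", "Sulfitobacter", "Sulfitobacter pontiacus"),
      g("Proteobacteria", "Gammaproteobacteria", "Pseudomonadales",
        "Pseudomonadaceae", "Pseudomonas", "Pseudomonas stutzeri"),
      g("Bacteroidota", "Bacteroidia", "Flavobacteriales",
        "Flavobacteriaceae", "Maribacter", "Maribacter dokdonensis")
    ),
    novel_species = c(
      g("Proteobacteria", "Alphaproteobacteria", "Rhodobacterales",
        "Rhodobacteraceae", "Sulfitobacter"),
      g("Proteobacteria", "Alphaproteobacteria", "Rhizobiales",
        "Stappiaceae", "Labrenzia"),
      g("Proteobacteria", "Alphaproteobacteria", "Caulobacterales",
        "Hyphomonadaceae", "Hyphomonas"),
      g("Proteobacteria", "Alphaproteobacteria", "Sphingomonadales",
        "Sphingomonadaceae", "Sphingomonas"),
      g("Proteobacteria", "Gammaproteobacteria", "Granulosicoccales",
        "Granulosicoccaceae", "Granulosicoccus"),
      g("Actinobacteriota", "Acidimicrobiia", "Microtrichales",
        "Microtrichaceae", "Sva0996"),
      g("Bacteroidota", "Bacteroidia", "Flavobacteriales",
        "Flavobacteriaceae", "Winogradskyella")
    ),
    novel_genus = c(
      g("Proteobacteria", "Alphaproteobacteria", "Geminicoccales",
        "Geminicoccaceae"),
      g("Proteobacteria", "Gammaproteobacteria", "Pseudomonadales",
        "Porticoccaceae"),
      g("Proteobacteria", "Gammaproteobacteria", "UBA10353",
        "UBA10353"),
      g("Myxococcota", "UBA9160", "UBA9160", "UBA9160"),
      g("Bacteroidota", "Bacteroidia", "Flavobacteriales",
        "Schleiferiaceae")
    ),
    novel_family = c(
      g("Proteobacteria", "Alphaproteobacteria", "Rhodobacterales"),
      g("Actinobacteriota", "Acidimicrobiia", "Microtrichales"),
      g("Proteobacteria", "Gammaproteobacteria", "Granulosicoccales")
    ),
    novel_higher = c(
      g("Proteobacteria", "Gammaproteobacteria", ""),
      g("Verrucomicrobiota", "Verrucomicrobiae", "")
    ),
    unclassified = "unclassified"
  )
}

#' Construct and validate a simulation specification
#'
#' @param seed Integer RNG seed; with a fixed seed the simulated bundle
#'   is byte-reproducible.
#' @param samples data.frame `sample_id`, `kind`
#'   (`"metagenome"`/`"mag"`), `size_bp`.
#' @param planted data.frame `sample_id`, `ec`, `density` (genes/Mbp);
#'   every EC must exist in the catalog used at simulation time, and
#'   (sample_id, ec) must be unique.
#' @param count_model `"exact"` (each planted cell receives exactly
#'   `round(density * size_mbp)` features) or `"poisson"` (a Poisson
#'   draw with that mean).
#' @param background List: `n_decoys` features per sample carrying
#'   non-catalog ECs or no EC, `decoy_ecs` alphabet, `no_ec_fraction`.
#' @param mag_block `NULL`, or a list describing a MAG cohort to
#'   simulate: `hosts` (named list, host sample id -> named counts
#'   `c(high=, medium=, discarded=)`), `taxon_pool` (as
#'   [default_taxon_pool()]), `novelty_weights` (named numeric over the
#'   pool categories), `ecs_per_mag` (length-2 range), `genes_per_ec`
#'   (length-2 range), `mag_size_range_bp` (length-2 range),
#'   `include_boundary` (add one completeness-90.0 and one
#'   completeness-50.0 MAG per cohort).
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(seed,
                            samples,
                            planted,
                            count_model = c("exact", "poisson"),
                            background = list(n_decoys = 25L,
                                              decoy_ecs = sprintf("9.9.9.%d", 1:10),
                                              no_ec_fraction = 0.5),
                            mag_block = NULL) {
  count_model <- match.arg(count_model)
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "kind", "size_bp") %in% names(samples)))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in spec")
  if (any(samples$size_bp <= 0)) stop("sample size_bp must be positive")
  if (!all(samples$kind %in% c("metagenome", "mag"))) {
    stop("sample kind must be 'metagenome' or 'mag'")
  }
  stopifnot(is.data.frame(planted),
            all(c("sample_id", "ec", "density") %in% names(planted)))
  if (any(planted$density < 0)) stop("planted densities must be >= 0")
  if (anyDuplicated(paste(planted$sample_id, planted$ec))) {
    stop("planted (sample_id, ec) pairs must be unique")
  }
  if (!all(planted$sample_id %in% samples$sample_id)) {
    stop("planted sample_id(s) not in the sample list")
  }
  structure(list(seed = seed, samples = samples, planted = planted,
                 count_model = count_model, background = background,
                 mag_block = mag_block),
            class = "simulation_spec")
}

rand_completeness <- function(tier, boundary = NA_real_) {
  if (!is.na(boundary)) return(boundary)
  switch(tier,
         high = stats::runif(1, 90.5, 99.5),
         medium = stats::runif(1, 50, 90),
         discarded = stats::runif(1, 5, 49))
}

rand_contamination <- function(tier) {
  switch(tier,
         high = stats::runif(1, 0, 4.5),
         medium = stats::runif(1, 0, 9.5),
         discarded = stats::runif(1, 10.5, 30))
}

simulate_mag_metadata <- function(mag_block) {
  rows <- list()
  pool <- mag_block$taxon_pool
  weights <- mag_block$novelty_weights
  if (is.null(weights)) {
    weights <- c(known_species = 0.07, novel_species = 0.54,
                 novel_genus = 0.32, novel_family = 0.06,
                 novel_higher = 0.005, unclassified = 0.005)
  }
  size_range <- mag_block$mag_size_range_bp %||% c(2e6, 8e6)
  for (host in names(mag_block$hosts)) {
    counts <- mag_block$hosts[[host]]
    idx <- 0L
    for (tier in names(counts)) {
      n <- counts[[tier]]
      if (!n) next
      for (k in seq_len(n)) {
        idx <- idx + 1L
        boundary <- NA_real_
        if (isTRUE(mag_block$include_boundary) && k == 1L) {
          # plant the documented boundary cases: completeness exactly at
          # the high (90.0, still medium) and medium (50.0) thresholds
          if (tier == "medium") boundary <- 90.0
          if (tier == "discarded") boundary <- 49.0
        }
        category <- sample(names(weights), 1L, prob = weights)
        gtdb <- sample(pool[[category]], 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          mag_id = sprintf("%sMAG%02d", host, idx),
          host_sample = host,
          size_bp = round(stats::runif(1, size_range[1], size_range[2])),
          completeness_pct = round(rand_completeness(tier, boundary), 2),
          contamination_pct = round(rand_contamination(tier), 2),
          gtdb_classification = gtdb,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

simulate_features <- function(sample_id, size_mbp, planted_sub, count_model,
                              background, catalog) {
  name_of <- stats::setNames(catalog$functions$name, catalog$functions$ec)
  rows <- list()
  realized <- integer(nrow(planted_sub))
  for (i in seq_len(nrow(planted_sub))) {
    mu <- planted_sub$density[i] * size_mbp
    n <- if (count_model == "exact") as.integer(round(mu))
         else stats::rpois(1L, mu)
    realized[i] <- n
    if (n > 0) {
      ec <- planted_sub$ec[i]
      rows[[length(rows) + 1L]] <- data.frame(
        ftype = "CDS",
        ec = ec,
        product = unname(name_of[ec]),
        stringsAsFactors = FALSE
      )[rep(1L, n), , drop = FALSE]
    }
  }
  n_decoys <- background$n_decoys %||% 0L
  if (n_decoys > 0) {
    decoy_ecs <- background$decoy_ecs %||% sprintf("9.9.9.%d", 1:10)
    bad <- intersect(decoy_ecs, catalog$functions$ec)
    if (length(bad)) {
      stop("decoy EC(s) collide with the catalog: ",
           paste(bad, collapse = ", "))
    }
    no_ec <- stats::runif(n_decoys) < (background$no_ec_fraction %||% 0.5)
    rows[[length(rows) + 1L]] <- data.frame(
      ftype = "CDS",
      ec = ifelse(no_ec, "", sample(decoy_ecs, n_decoys, replace = TRUE)),
      product = "hypothetical protein",
      stringsAsFactors = FALSE
    )
  }
  features <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(ftype = character(0), ec = character(0),
               product = character(0), stringsAsFactors = FALSE)
  }
  n <- nrow(features)
  if (n > 1) features <- features[sample.int(n), , drop = FALSE]
  out <- data.frame(
    locus_tag = sprintf("%s_%05d", sample_id, seq_len(max(n, 0L))),
    ftype = features$ftype,
    length_bp = if (n) sample(300:3000, n, replace = TRUE) else numeric(0),
    product = features$product,
    stringsAsFactors = FALSE
  )
  out$ec_numbers <- lapply(features$ec,
                           function(e) if (nzchar(e)) e else character(0))
  rownames(out) <- NULL
  list(features = out, realized = realized)
}

#' Simulate an annotation bundle with planted gene densities
#'
#' Generates, deterministically under the spec's seed, per-sample
#' annotation tables with planted per-EC gene counts (exact or Poisson
#' around `density * size_mbp`), decoy features guaranteed not to match
#' the catalog, an optional MAG cohort (metadata with controlled quality
#' and taxonomy plus one annotation table per MAG), a random bifurcating
#' tree over the MAG ids, and a ground-truth record of every planted and
#' realized quantity.
#'
#' @param spec A `simulation_spec`.
#' @param catalog The `halogen_catalog` the planted ECs refer to.
#' @return A `sim_bundle`: list with `spec`, `tables` (named list of
#'   `annotation_table`s), `mags` (metadata data.frame or `NULL`),
#'   `tree` (ape `phylo` or `NULL`) and `ground_truth` (list with
#'   `counts`, `tiers`, `novelty`, `samples`, `catalog_version`).
#' @export
simulate_bundle <- function(spec, catalog) {
  stopifnot(inherits(spec, "simulation_spec"),
            inherits(catalog, "halogen_catalog"))
  missing_ecs <- setdiff(spec$planted$ec, catalog$functions$ec)
  if (length(missing_ecs)) {
    stop("planted EC(s) not in catalog: ",
         paste(missing_ecs, collapse = ", "))
  }
  set.seed(spec$seed)

  samples <- spec$samples
  mags <- NULL
  if (!is.null(spec$mag_block)) {
    mags <- simulate_mag_metadata(spec$mag_block)
    validate_mag_metadata(mags)
    retained <- mags[quality_tier(mags$completeness_pct,
                                  mags$contamination_pct) != "discarded", ,
                     drop = FALSE]
    mag_samples <- data.frame(sample_id = retained$mag_id, kind = "mag",
                              size_bp = retained$size_bp,
                              stringsAsFactors = FALSE)
    samples <- rbind(samples, mag_samples)
    # plant per-MAG densities: an integer gene count per chosen EC so the
    # planted density is exactly representable as count / size_mbp
    ec_range <- spec$mag_block$ecs_per_mag %||% c(3L, 15L)
    gene_range <- spec$mag_block$genes_per_ec %||% c(1L, 10L)
    extra <- lapply(seq_len(nrow(retained)), function(i) {
      n_ec <- sample(ec_range[1]:ec_range[2], 1L)
      ecs <- sample(catalog$functions$ec, n_ec)
      counts <- sample(gene_range[1]:gene_range[2], n_ec, replace = TRUE)
      data.frame(sample_id = retained$mag_id[i], ec = ecs,
                 density = counts / (retained$size_bp[i] / 1e6),
                 stringsAsFactors = FALSE)
    })
    spec$planted <- rbind(spec$planted, do.call(rbind, extra))
  }

  tables <- list()
  gt_counts <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    size_bp <- samples$size_bp[i]
    planted_sub <- spec$planted[spec$planted$sample_id == sid, ,
                                drop = FALSE]
    sim <- simulate_features(sid, size_bp / 1e6, planted_sub,
                             spec$count_model, spec$background, catalog)
    tables[[sid]] <- new_annotation_table(sid, samples$kind[i], size_bp,
                                          sim$features)
    if (nrow(planted_sub)) {
      gt_counts[[length(gt_counts) + 1L]] <- data.frame(
        sample_id = sid, ec = planted_sub$ec,
        planted_density = planted_sub$density,
        n_genes = sim$realized,
        realized_density = sim$realized / (size_bp / 1e6),
        stringsAsFactors = FALSE
      )
    }
  }
  counts <- if (length(gt_counts)) do.call(rbind, gt_counts) else
    data.frame(sample_id = character(0), ec = character(0),
               planted_density = numeric(0), n_genes = integer(0),
               realized_density = numeric(0), stringsAsFactors = FALSE)
  rownames(counts) <- NULL

  tree <- NULL
  tiers <- NULL
  novelty <- NULL
  if (!is.null(mags)) {
    tiers <- tier_mags(mags)$tiers[, c("mag_id", "tier")]
    novelty <- call_novelty(mags)
    if (nrow(mags) >= 2) {
      tree <- ape::rtree(nrow(mags), tip.label = sample(mags$mag_id))
    }
  }

  structure(list(
    spec = spec, tables = tables, mags = mags, tree = tree,
    ground_truth = list(counts = counts, tiers = tiers, novelty = novelty,
                        samples = samples,
                        catalog_version = catalog$version)
  ), class = "sim_bundle")
}

encode_gff_value <- function(x) {
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}

write_annotation_tsv <- function(table, path) {
  f <- table$features
  out <- data.frame(
    locus_tag = f$locus_tag,
    ftype = f$ftype,
    length_bp = f$length_bp,
    gene = "",
    EC_number = vapply(f$ec_numbers, paste, character(1), collapse = ","),
    COG = "",
    product = f$product,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_annotation_gff3 <- function(table, path) {
  f <- table$features
  lines <- "##gff-version 3"
  if (nrow(f)) {
    start <- cumsum(c(1, utils::head(f$length_bp + 100, -1)))
    end <- start + f$length_bp - 1
    attrs <- vapply(seq_len(nrow(f)), function(i) {
      a <- c(paste0("ID=", encode_gff_value(f$locus_tag[i])),
             paste0("locus_tag=", encode_gff_value(f$locus_tag[i])))
      ecs <- f$ec_numbers[[i]]
      if (length(ecs)) a <- c(a, paste0("eC_number=", paste(ecs, collapse = ",")))
      if (nzchar(f$product[i])) {
        a <- c(a, paste0("product=", encode_gff_value(f$product[i])))
      }
      paste(a, collapse = ";")
    }, character(1))
    lines <- c(lines, paste("contig_1", "haloscreen_sim", f$ftype,
                            format(start, scientific = FALSE, trim = TRUE),
                            format(end, scientific = FALSE, trim = TRUE),
                            ".", "+",
                            ifelse(f$ftype == "CDS", "0", "."),
                            attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated bundle to disk
#'
#' Emits, under `dir`: `annotations/<sample>.tsv` and
#' `annotations/<sample>.gff` (paired exports of the same annotation),
#' `samples.tsv` (sample id, kind, size_bp), `mag_metadata.tsv`,
#' `tree.nwk` and `ground_truth.json`. Output is byte-deterministic for
#' a given bundle.
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  ann_dir <- file.path(dir, "annotations")
  dir.create(ann_dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(bundle$tables)) {
    write_annotation_tsv(bundle$tables[[sid]],
                         file.path(ann_dir, paste0(sid, ".tsv")))
    write_annotation_gff3(bundle$tables[[sid]],
                          file.path(ann_dir, paste0(sid, ".gff")))
  }
  utils::write.table(bundle$ground_truth$samples,
                     file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$mags)) {
    utils::write.table(bundle$mags, file.path(dir, "mag_metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$tree)) {
    ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  }
  gt <- bundle$ground_truth
  jsonlite::write_json(
    list(counts = gt$counts, tiers = gt$tiers, novelty = gt$novelty,
         samples = gt$samples, catalog_version = gt$catalog_version,
         seed = bundle$spec$seed, count_model = bundle$spec$count_model),
    file.path(dir, "ground_truth.json"),
    dataframe = "columns", digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Check pipeline recovery of simulated ground truth
#'
#' Re-runs the screening and density stages on the bundle's annotation
#' tables (and tiering/novelty on its MAG metadata) and compares every
#' recovered quantity with the planted ground truth. Under the exact
#' count model, counts and densities must agree exactly; under the
#' Poisson model the per-sample relative density error is reported, not
#' asserted.
#'
#' @param bundle A `sim_bundle`.
#' @param catalog The catalog used at simulation time.
#' @return List: `count_agreement` (fraction of ground-truth cells whose
#'   recovered count matches exactly, spurious counts included in the
#'   denominator), `max_abs_count_error`, `max_abs_density_error`,
#'   `tier_agreement`, `novelty_agreement` (fractions, `NA` without a
#'   MAG block), and `per_sample` (data.frame with per-sample totals and
#'   relative errors).
#' @export
recovery_check <- function(bundle, catalog) {
  stopifnot(inherits(bundle, "sim_bundle"))
  gt <- bundle$ground_truth
  if (!identical(gt$catalog_version, catalog$version)) {
    stop("bundle was simulated against a different catalog version")
  }
  recovered <- lapply(bundle$tables, screen_sample, catalog = catalog)

  rec_rows <- do.call(rbind, lapply(recovered, function(p) {
    if (!nrow(p$counts)) {
      return(data.frame(sample_id = character(0), ec = character(0),
                        rec = integer(0), stringsAsFactors = FALSE))
    }
    data.frame(sample_id = p$sample_id, ec = p$counts$ec,
               rec = p$counts$n_genes, stringsAsFactors = FALSE)
  }))
  gt_nonzero <- gt$counts[gt$counts$n_genes > 0, , drop = FALSE]
  key_gt <- paste(gt_nonzero$sample_id, gt_nonzero$ec)
  key_rec <- paste(rec_rows$sample_id, rec_rows$ec)
  rec_of <- stats::setNames(rec_rows$rec, key_rec)
  matched <- !is.na(rec_of[key_gt]) & rec_of[key_gt] == gt_nonzero$n_genes
  spurious <- setdiff(key_rec, key_gt)
  denom <- length(key_gt) + length(spurious)
  count_agreement <- if (denom) sum(matched) / denom else 1
  count_err <- abs(ifelse(is.na(rec_of[key_gt]), 0, rec_of[key_gt]) -
                     gt_nonzero$n_genes)

  size_of <- stats::setNames(gt$samples$size_bp / 1e6,
                             gt$samples$sample_id)
  rec_density <- ifelse(is.na(rec_of[key_gt]), 0, rec_of[key_gt]) /
    size_of[gt_nonzero$sample_id]
  density_err <- abs(rec_density - gt_nonzero$realized_density)

  per_sample <- do.call(rbind, lapply(names(bundle$tables), function(sid) {
    gts <- gt$counts[gt$counts$sample_id == sid, , drop = FALSE]
    p <- recovered[[sid]]
    planted_total <- sum(gts$planted_density) * size_of[sid]
    data.frame(sample_id = sid,
               n_planted_cells = nrow(gts),
               recovered_genes = p$n_target_genes,
               realized_genes = sum(gts$n_genes),
               rel_density_error = if (planted_total > 0) {
                 abs(p$n_target_genes - planted_total) / planted_total
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL

  tier_agreement <- NA_real_
  novelty_agreement <- NA_real_
  if (!is.null(bundle$mags)) {
    rec_tiers <- tier_mags(bundle$mags)$tiers
    tier_agreement <- mean(rec_tiers$tier[match(gt$tiers$mag_id,
                                                rec_tiers$mag_id)] ==
                             gt$tiers$tier)
    rec_nov <- call_novelty(bundle$mags)
    novelty_agreement <- mean(rec_nov$novelty[match(gt$novelty$mag_id,
                                                    rec_nov$mag_id)] ==
                                gt$novelty$novelty)
  }

  list(count_agreement = count_agreement,
       max_abs_count_error = if (length(count_err)) max(count_err) else 0,
       max_abs_density_error = if (length(density_err)) max(density_err)
                               else 0,
       tier_agreement = tier_agreement,
       novelty_agreement = novelty_agreement,
       per_sample = per_sample)
}

#' Study-scale default simulation specification
#'
#' Emulates the structure of a three-macroalga epiphytic microbiome
#' screen: three metagenomes (`Sc`, `At`, `Hs`) at the published
#' assembled sizes (784,246,579 / 525,823,578 / 435,330,334 bp), 81
#' catalog functions planted overall of which 63 are common to all three
#' samples, anchor enzymes planted at the published densities (haloalkane
#' dehalogenase EC 3.8.1.5 at 0.41/0.34/0.27 genes/Mbp and tryptophan
#' 7-halogenase EC 1.14.19.9 at 0.04/0.22/0.14 in Sc/At/Hs), and a
#' 98-MAG cohort (49 Sc = 7 high + 42 medium, 31 At = 10 + 21, 18 Hs =
#' 3 + 15) drawn from the packaged taxon pool.
#'
#' @param seed Integer seed.
#' @param catalog The catalog to plant against.
#' @return A `simulation_spec`.
#' @export
study_simulation_spec <- function(seed, catalog = load_catalog()) {
  set.seed(as.integer(seed))
  samples <- data.frame(
    sample_id = c("Sc", "At", "Hs"),
    kind = "metagenome",
    size_bp = c(784246579, 525823578, 435330334),
    stringsAsFactors = FALSE
  )
  anchors <- data.frame(
    sample_id = rep(c("Sc", "At", "Hs"), 2),
    ec = rep(c("3.8.1.5", "1.14.19.9"), each = 3),
    density = c(0.41, 0.34, 0.27, 0.04, 0.22, 0.14),
    stringsAsFactors = FALSE
  )
  other <- setdiff(sample(catalog$functions$ec, 81L), anchors$ec)[1:79]
  shared <- other[1:61]           # + 2 anchors = 63 functions in all three
  partial <- other[62:79]         # 18 functions in one or two samples
  rows <- list(anchors)
  for (ecv in shared) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = samples$sample_id, ec = ecv,
      density = round(stats::runif(3, 0.01, 0.4), 2),
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(partial)) {
    present <- sample(samples$sample_id,
                      sample(1:2, 1L, prob = c(0.6, 0.4)))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = present, ec = partial[i],
      density = round(stats::runif(length(present), 0.01, 0.3), 2),
      stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, rows)
  mag_block <- list(
    hosts = list(Sc = c(high = 7, medium = 42, discarded = 0),
                 At = c(high = 10, medium = 21, discarded = 0),
                 Hs = c(high = 3, medium = 15, discarded = 0)),
    taxon_pool = default_taxon_pool(),
    ecs_per_mag = c(3L, 20L),
    genes_per_ec = c(1L, 10L),
    mag_size_range_bp = c(2e6, 8e6),
    include_boundary = TRUE
  )
  simulation_spec(seed = seed, samples = samples, planted = planted,
                  count_model = "exact", mag_block = mag_block)
}
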