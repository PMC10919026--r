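# Fixture builders and independent brute-force oracles shared across the
# suite. Oracles are deliberately naive (explicit loops, rule tables) and
# never call the code paths they check.

the_catalog <- load_catalog()

# --- small hand-built catalog -------------------------------------------

mini_catalog_list <- function() {
  list(
    version = "mini 1.0",
    functions = list(
      list(ec = "3.8.1.5", name = "haloalkane dehalogenase",
           role = "dehalogenase", mechanism = "hydrolytic",
           direction = "dehalogenation", cluster_ids = list("D1")),
      list(ec = "3.8.1.2", name = "(S)-2-haloacid dehalogenase",
           role = "dehalogenase", mechanism = "hydrolytic",
           direction = "dehalogenation", cluster_ids = list("D1", "D2")),
      list(ec = "4.5.1.1", name = "DDT-dehydrochlorinase",
           role = "dehalogenase", mechanism = "non_hydrolytic",
           direction = "dehalogenation", cluster_ids = list("D2")),
      list(ec = "1.14.19.9", name = "tryptophan 7-halogenase",
           role = "halogenase", mechanism = "not_applicable",
           direction = "halogenation", cluster_ids = list("B1")),
      list(ec = "2.5.1.18", name = "glutathione transferase",
           role = "auxiliary", mechanism = "not_applicable",
           direction = "dehalogenation", cluster_ids = list("D1")),
      list(ec = "2.7.8.99", name = "auxiliary biosynthesis enzyme",
           role = "auxiliary", mechanism = "not_applicable",
           direction = "halogenation", cluster_ids = list("B1"))
    ),
    clusters = list(
      list(cluster_id = "D1", name = "haloalkane degradation",
           direction = "degradative",
           member_ecs = list("3.8.1.5", "3.8.1.2", "2.5.1.18")),
      list(cluster_id = "D2", name = "chloroacrylate degradation",
           direction = "degradative",
           member_ecs = list("3.8.1.2", "4.5.1.1")),
      list(cluster_id = "B1", name = "tryptophan halogenation",
           direction = "biosynthetic",
           member_ecs = list("1.14.19.9", "2.7.8.99"))
    )
  )
}

write_catalog_json <- function(lst, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(lst, path, auto_unbox = TRUE)
  path
}

mini_catalog <- function() load_catalog(write_catalog_json(mini_catalog_list()))

# --- annotation-table builders ------------------------------------------

make_table <- function(ec_sets, sample_id = "s1", kind = "metagenome",
                       size_bp = 5e6, ftype = "CDS") {
  n <- length(ec_sets)
  features <- data.frame(
    locus_tag = sprintf("%s_%05d", sample_id, seq_len(n)),
    ftype = rep(ftype, length.out = n),
    length_bp = rep(900, n),
    product = rep("protein", n),
    stringsAsFactors = FALSE
  )
  features$ec_numbers <- lapply(ec_sets, as.character)
  haloscreen:::new_annotation_table(sample_id, kind, size_bp, features)
}

random_table <- function(catalog, sample_id = "r1", size_bp = 4e6,
                         n_features = 50, p_hit = 0.5) {
  ecs <- catalog$functions$ec
  sets <- lapply(seq_len(n_features), function(i) {
    if (stats::runif(1) < p_hit) {
      sample(ecs, sample(1:2, 1))
    } else if (stats::runif(1) < 0.5) {
      "9.9.9.9"
    } else {
      character(0)
    }
  })
  make_table(sets, sample_id = sample_id, size_bp = size_bp)
}

write_prokka_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- "locus_tag\tftype\tlength_bp\tgene\tEC_number\tCOG\tproduct"
  writeLines(c(header, rows), path)
  path
}

# --- oracles -------------------------------------------------------------

# brute-force per-(feature, EC) recount
count_oracle <- function(table, catalog) {
  tally <- list()
  for (i in seq_len(nrow(table$features))) {
    seen <- character(0)
    for (ec in table$features$ec_numbers[[i]]) {
      if (ec %in% catalog$functions$ec && !(ec %in% seen)) {
        seen <- c(seen, ec)
        tally[[ec]] <- (tally[[ec]] %||% 0L) + 1L
      }
    }
  }
  if (!length(tally)) {
    return(data.frame(ec = character(0), n_genes = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(ec = names(tally),
                    n_genes = as.integer(unlist(tally)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$ec), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force set algebra over presence sets
set_algebra_oracle <- function(sets) {
  uni <- character(0)
  for (s in sets) for (x in s) if (!(x %in% uni)) uni <- c(uni, x)
  inter <- character(0)
  for (x in uni) {
    in_all <- TRUE
    for (s in sets) if (!(x %in% s)) in_all <- FALSE
    if (in_all) inter <- c(inter, x)
  }
  list(intersection = sort(inter), union = sort(uni),
       shared_fraction = if (length(uni)) length(inter) / length(uni)
                         else NA_real_)
}

# explicit quality-tier rule table
tier_oracle <- function(completeness, contamination) {
  if (completeness > 90) {
    if (contamination < 5) return("high")
    if (completeness >= 50 && contamination < 10) return("medium")
    return("discarded")
  }
  if (completeness >= 50 && contamination < 10) return("medium")
  "discarded"
}

# explicit novelty rule table over a 7-logical assignment vector
novelty_oracle <- function(assigned) {
  # assigned: domain, phylum, class, order, family, genus, species
  if (!assigned[1]) return("unclassified")
  if (assigned[7]) return("known_species")
  if (assigned[6]) return("novel_species")
  if (assigned[5]) return("novel_genus")
  if (assigned[4]) return("novel_family")
  "novel_higher"
}

gtdb_from_assigned <- function(assigned) {
  ranks <- c("Bacteria", "Proteobacteria", "Alphaproteobacteria",
             "Rhodobacterales", "Rhodobacteraceae", "Sulfitobacter",
             "Sulfitobacter sp001")
  parts <- ifelse(assigned, ranks, "")
  paste(paste0(c("d__", "p__", "c__", "o__", "f__", "g__", "s__"), parts),
        collapse = ";")
}

mag_row <- function(mag_id = "m1", host = "Sc", size_bp = 3e6,
                    completeness = 95, contamination = 2,
                    gtdb = "unclassified") {
  data.frame(mag_id = mag_id, host_sample = host, size_bp = size_bp,
             completeness_pct = completeness,
             contamination_pct = contamination,
             gtdb_classification = gtdb, stringsAsFactors = FALSE)
}

# small exact-model spec over the packaged catalog; densities are
# integer counts divided by size so they are exactly recoverable
random_exact_spec <- function(seed, catalog) {
  set.seed(seed)
  n_samples <- sample(2:3, 1)
  samples <- data.frame(
    sample_id = sprintf("sim%d_%d", seed, seq_len(n_samples)),
    kind = "metagenome",
    size_bp = sample(c(2e6, 4e6, 5e6, 8e6), n_samples, replace = TRUE),
    stringsAsFactors = FALSE
  )
  planted <- do.call(rbind, lapply(seq_len(n_samples), function(i) {
    ecs <- sample(catalog$functions$ec, sample(3:10, 1))
    counts <- sample(1:20, length(ecs), replace = TRUE)
    data.frame(sample_id = samples$sample_id[i], ec = ecs,
               density = counts / (samples$size_bp[i] / 1e6),
               stringsAsFactors = FALSE)
  }))
  simulation_spec(seed = seed, samples = samples, planted = planted,
                  count_model = "exact")
}
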