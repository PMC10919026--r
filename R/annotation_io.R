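new_annotation_table <- function(sample_id, sample_kind, size_bp, features) {
  if (!nzchar(sample_id)) stop("sample_id must be non-empty")
  if (!sample_kind %in% c("metagenome", "mag")) {
    stop("sample_kind must be 'metagenome' or 'mag', got '", sample_kind, "'")
  }
  size_bp <- as.numeric(size_bp)
  if (!is.finite(size_bp) || size_bp <= 0) {
    stop("size_bp must be a positive number for sample ", sample_id)
  }
  structure(list(sample_id = sample_id, sample_kind = sample_kind,
                 size_bp = size_bp, features = features),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("<annotation_table> sample ", x$sample_id, " (", x$sample_kind,
      "), ", format(x$size_bp, big.mark = ","), " bp, ",
      nrow(x$features), " features\n", sep = "")
  invisible(x)
}

split_ec_cell <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
  unique(strsplit(trimws(cell), "[,;[:space:]]+")[[1]])
}

validate_features <- function(features, path) {
  dup <- unique(features$locus_tag[duplicated(features$locus_tag)])
  if (length(dup)) {
    stop("duplicate locus_tag value(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  bad <- which(!is.finite(features$length_bp) | features$length_bp <= 0)
  if (length(bad)) {
    stop("non-positive or missing length_bp in ", path, " at data row(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a Prokka-dialect feature table (TSV)
#'
#' Parses the tab-separated feature table emitted by Prokka-style
#' annotation runs. The header must carry at least `locus_tag`, `ftype`,
#' `length_bp` and `EC_number`; a `product` column is kept when present.
#' The `EC_number` cell may hold several ECs separated by commas,
#' semicolons or whitespace; an empty cell yields an empty EC set.
#' Row order is preserved.
#'
#' The assembled size is supplied out-of-band (`size_bp`), not summed from
#' gene spans, because gene densities are normalized by total assembled
#' contig size.
#'
#' @param path TSV file path.
#' @param sample_id Sample identifier.
#' @param sample_kind `"metagenome"` or `"mag"`.
#' @param size_bp Total assembled size of the sample in bp.
#' @return An `annotation_table`: list with `sample_id`, `sample_kind`,
#'   `size_bp` and a `features` data.frame (`locus_tag`, `ftype`,
#'   `length_bp`, `product`, list-column `ec_numbers`).
#' @export
read_prokka_tsv <- function(path, sample_id, sample_kind, size_bp) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  required <- c("locus_tag", "ftype", "length_bp", "EC_number")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("annotation table ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  features <- data.frame(
    locus_tag = raw$locus_tag,
    ftype = raw$ftype,
    length_bp = suppressWarnings(as.numeric(raw$length_bp)),
    product = if ("product" %in% names(raw)) raw$product
              else rep("", nrow(raw)),
    stringsAsFactors = FALSE
  )
  features$ec_numbers <- lapply(raw$EC_number, split_ec_cell)
  validate_features(features, path)
  new_annotation_table(sample_id, sample_kind, size_bp, features)
}

decode_gff_value <- function(x) {
  x <- gsub("%2C", ",", x, fixed = TRUE)
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  gsub("%09", "\t", x, fixed = TRUE)
}

gff_attr <- function(attributes, key) {
  pattern <- paste0("(^|;)", key, "=([^;]*)")
  m <- regexec(pattern, attributes)
  vapply(regmatches(attributes, m), function(hit) {
    if (length(hit)) decode_gff_value(hit[3]) else NA_character_
  }, character(1))
}

#' Read a GFF3 annotation file
#'
#' Alternate reader for the same annotation run as [read_prokka_tsv()];
#' the two readers yield identical `annotation_table`s for paired exports.
#' Feature identifiers come from the `locus_tag` attribute (falling back
#' to `ID`), EC assignments from the `eC_number` attribute (Prokka's GFF
#' spelling), products from `product`. Coordinates are 1-based inclusive
#' and are used only to derive `length_bp` (`end - start + 1`). Any
#' trailing `##FASTA` section is ignored.
#'
#' @inheritParams read_prokka_tsv
#' @return An `annotation_table`.
#' @export
read_gff3 <- function(path, sample_id, sample_kind, size_bp) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  fasta_at <- which(lines == "##FASTA")
  if (length(fasta_at)) lines <- lines[seq_len(fasta_at[1] - 1L)]
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))

  if (length(body_idx)) {
    nfield <- vapply(strsplit(lines[body_idx], "\t", fixed = TRUE),
                     length, integer(1))
    bad <- body_idx[nfield != 9L]
    if (length(bad)) {
      stop("GFF3 ", path, ": line ", bad[1],
           " does not have 9 tab-separated columns")
    }
  }

  tmp <- tempfile(fileext = ".gff")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(c("##gff-version 3", lines[body_idx]), tmp)
  gff <- ape::read.gff(tmp, GFF3 = TRUE)

  if (nrow(gff)) {
    bad_iv <- which(gff$start > gff$end)
    if (length(bad_iv)) {
      stop("GFF3 ", path, ": line ", body_idx[bad_iv[1]],
           " has start > end")
    }
    locus <- gff_attr(gff$attributes, "locus_tag")
    ids <- gff_attr(gff$attributes, "ID")
    locus[is.na(locus)] <- ids[is.na(locus)]
    if (anyNA(locus)) {
      stop("GFF3 ", path, ": line ", body_idx[which(is.na(locus))[1]],
           " has neither a locus_tag nor an ID attribute")
    }
    ecs <- gff_attr(gff$attributes, "eC_number")
    product <- gff_attr(gff$attributes, "product")
    product[is.na(product)] <- ""
    features <- data.frame(
      locus_tag = locus,
      ftype = as.character(gff$type),
      length_bp = as.numeric(gff$end - gff$start + 1L),
      product = product,
      stringsAsFactors = FALSE
    )
    features$ec_numbers <- lapply(ecs, function(x) {
      if (is.na(x)) character(0) else split_ec_cell(x)
    })
  } else {
    features <- data.frame(locus_tag = character(0), ftype = character(0),
                           length_bp = numeric(0), product = character(0),
                           stringsAsFactors = FALSE)
    features$ec_numbers <- list()
  }
  validate_features(features, path)
  new_annotation_table(sample_id, sample_kind, size_bp, features)
}

gtdb_rank_prefixes <- c(domain = "d__", phylum = "p__", class = "c__",
                        order = "o__", family = "f__", genus = "g__",
                        species = "s__")

#' Parse GTDB classification strings into seven ranks
#'
#' A GTDB string is either the literal `"unclassified"` or seven
#' semicolon-delimited fields prefixed `d__;p__;c__;o__;f__;g__;s__`
#' (fields may be empty after the prefix, indicating taxonomic novelty at
#' that rank). Unclassified strings parse to seven `NA` ranks.
#'
#' @param gtdb_string Character vector of classification strings.
#' @return data.frame with columns `domain`, `phylum`, `class`, `order`,
#'   `family`, `genus`, `species` (empty string = rank unassigned,
#'   `NA` = unclassified).
#' @export
parse_gtdb <- function(gtdb_string) {
  out <- matrix(NA_character_, nrow = length(gtdb_string), ncol = 7L,
                dimnames = list(NULL, names(gtdb_rank_prefixes)))
  for (i in seq_along(gtdb_string)) {
    s <- gtdb_string[i]
    if (is.na(s) || s == "unclassified") next
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    if (length(parts) != 7L ||
        !all(startsWith(trimws(parts), unname(gtdb_rank_prefixes)))) {
      stop("malformed GTDB classification string: '", s,
           "' (expect 7 prefixed ranks or the literal 'unclassified')")
    }
    out[i, ] <- substring(trimws(parts), 4L)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read a MAG metadata table
#'
#' TSV with header `mag_id`, `host_sample`, `size_bp`,
#' `completeness_pct`, `contamination_pct`, `gtdb_classification`.
#' Enforces 0 <= completeness <= 100, contamination >= 0, positive size
#' and well-formed GTDB strings.
#'
#' @param path TSV path.
#' @return data.frame of MAG records (one per row) with the columns above.
#' @export
read_mag_metadata <- function(path) {
  if (!file.exists(path)) stop("MAG metadata file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("mag_id", "host_sample", "size_bp", "completeness_pct",
                "contamination_pct", "gtdb_classification")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("MAG metadata ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  mags <- data.frame(
    mag_id = raw$mag_id,
    host_sample = raw$host_sample,
    size_bp = suppressWarnings(as.numeric(raw$size_bp)),
    completeness_pct = suppressWarnings(as.numeric(raw$completeness_pct)),
    contamination_pct = suppressWarnings(as.numeric(raw$contamination_pct)),
    gtdb_classification = raw$gtdb_classification,
    stringsAsFactors = FALSE
  )
  validate_mag_metadata(mags)
  mags
}

validate_mag_metadata <- function(mags) {
  dup <- unique(mags$mag_id[duplicated(mags$mag_id)])
  if (length(dup)) stop("duplicate mag_id(s): ", paste(dup, collapse = ", "))
  bad <- mags$mag_id[!is.finite(mags$size_bp) | mags$size_bp <= 0]
  if (length(bad)) stop("non-positive size_bp for MAG(s): ",
                        paste(bad, collapse = ", "))
  bad <- mags$mag_id[!is.finite(mags$completeness_pct) |
                       mags$completeness_pct < 0 |
                       mags$completeness_pct > 100]
  if (length(bad)) {
    stop("completeness_pct outside [0, 100] for MAG(s): ",
         paste(bad, collapse = ", "))
  }
  bad <- mags$mag_id[!is.finite(mags$contamination_pct) |
                       mags$contamination_pct < 0]
  if (length(bad)) stop("negative contamination_pct for MAG(s): ",
                        paste(bad, collapse = ", "))
  for (i in seq_len(nrow(mags))) {
    tryCatch(parse_gtdb(mags$gtdb_classification[i]),
             error = function(e) {
               stop("MAG ", mags$mag_id[i], ": ", conditionMessage(e),
                    call. = FALSE)
             })
  }
  invisible(TRUE)
}

#' Read a Newick tree over MAG identifiers
#'
#' Wraps [ape::read.tree()] and cross-references the leaf set against a
#' MAG metadata table: leaves absent from the metadata and MAGs absent
#' from the tree are reported (not errors), so reference genomes and
#' unprofiled MAGs can coexist with the screen.
#'
#' @param path Newick file.
#' @param mags Optional MAG metadata data.frame (from
#'   [read_mag_metadata()]).
#' @return List with `tree` (an ape `phylo`), `leaves`,
#'   `unmatched_leaves` (in tree, not in metadata) and `missing_mags`
#'   (in metadata, not in tree).
#' @export
read_tree <- function(path, mags = NULL) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("could not parse Newick tree from ", path,
         " (malformed or truncated tree text)")
  }
  leaves <- tree$tip.label
  mag_ids <- if (is.null(mags)) character(0) else mags$mag_id
  list(tree = tree,
       leaves = leaves,
       unmatched_leaves = setdiff(leaves, mag_ids),
       missing_mags = setdiff(mag_ids, leaves))
}

#' Strip European-style digit grouping from integer text
#'
#' Published assembly sizes are sometimes printed with dot or comma
#' grouping (e.g. `"784.246.579"`). Inputs to this package accept plain
#' integers only; this utility normalizes grouped text when explicitly
#' invoked.
#'
#' @param x Character vector such as `"784.246.579"` or `"784,246,579"`.
#' @return Numeric vector.
#' @export
#' @examples
#' strip_digit_grouping("784.246.579")
strip_digit_grouping <- function(x) {
  cleaned <- gsub("[.,]", "", x)
  if (any(!grepl("^[0-9]+$", cleaned))) {
    stop("not an integer with digit grouping: ",
         paste(x[!grepl("^[0-9]+$", cleaned)], collapse = ", "))
  }
  as.numeric(cleaned)
}

#' Write a result table as TSV
#'
#' All result writers funnel through this helper so numeric columns named
#' `density` are serialized at full precision (17 significant digits,
#' lossless for doubles) next to any display-rounded column.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_result_tsv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && grepl("density$", col)) {
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
    if (is.list(out[[col]])) {
      out[[col]] <- vapply(out[[col]], paste, character(1), collapse = ";")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_result_tsv()]
#'
#' @param path TSV path.
#' @return data.frame; columns named `density` are numeric.
#' @export
read_result_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in names(df)) {
    if (grepl("density$", col)) df[[col]] <- as.numeric(df[[col]])
  }
  df
}
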