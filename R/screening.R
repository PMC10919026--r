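#' Screen an annotation table against the halogen-function catalog
#'
#' Counting is per (feature, EC): a feature contributes 1 to the count of
#' every *distinct* catalog EC it carries, so a bifunctional annotation is
#' visible under both functions; duplicate identical ECs on one feature
#' count once; features whose ECs are all outside the catalog contribute
#' nothing. All feature types are admitted — EC presence alone gates
#' counting.
#'
#' @param table An `annotation_table` (see [read_prokka_tsv()]).
#' @param catalog A `halogen_catalog`.
#' @return A `sample_profile`: list with `sample_id`, `sample_kind`,
#'   `size_mbp` (= `size_bp` / 1e6), `counts` (data.frame `ec`,
#'   `n_genes`, sorted by EC), `n_functions` (distinct catalog ECs
#'   observed), `n_target_genes` (total count) and `catalog_version`.
#' @export
#' @examples
#' cat <- load_catalog()
#' tab <- example_annotation_table()
#' screen_sample(tab, cat)
screen_sample <- function(table, catalog) {
  stopifnot(inherits(table, "annotation_table"),
            inherits(catalog, "halogen_catalog"))
  catalog_ecs <- catalog$functions$ec
  hits <- unlist(lapply(table$features$ec_numbers, function(ecs) {
    intersect(unique(ecs), catalog_ecs)
  }), use.names = FALSE)
  if (length(hits)) {
    tab <- table(hits)
    counts <- data.frame(ec = names(tab), n_genes = as.integer(tab),
                         stringsAsFactors = FALSE)
    counts <- counts[order(counts$ec), , drop = FALSE]
    rownames(counts) <- NULL
  } else {
    counts <- data.frame(ec = character(0), n_genes = integer(0),
                         stringsAsFactors = FALSE)
  }
  structure(list(sample_id = table$sample_id,
                 sample_kind = table$sample_kind,
                 size_mbp = table$size_bp / 1e6,
                 counts = counts,
                 n_functions = nrow(counts),
                 n_target_genes = sum(counts$n_genes),
                 catalog_version = catalog$version),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat("<sample_profile> ", x$sample_id, " (", x$sample_kind, "), ",
      format(x$size_mbp, digits = 6), " Mbp: ", x$n_functions,
      " catalog functions, ", x$n_target_genes, " target genes\n", sep = "")
  invisible(x)
}

#' Split a profile's counts along the direct-enzyme axes
#'
#' Partitions the gene counts of the 42-member direct subset by role
#' (halogenase vs dehalogenase) and, within dehalogenases, by mechanism
#' (hydrolytic EC 3.8.1.x vs non-hydrolytic). Auxiliary ECs are excluded
#' from all four outputs; hydrolytic + non-hydrolytic equals the
#' dehalogenase counts by construction.
#'
#' @param profile A `sample_profile`.
#' @param catalog The `halogen_catalog` the profile was screened against.
#' @return Named list of four count data.frames (`ec`, `n_genes`):
#'   `halogenase`, `dehalogenase`, `hydrolytic`, `non_hydrolytic`.
#' @export
split_ec42 <- function(profile, catalog) {
  stopifnot(inherits(profile, "sample_profile"),
            inherits(catalog, "halogen_catalog"))
  if (!identical(profile$catalog_version, catalog$version)) {
    stop("profile for sample ", profile$sample_id,
         " was screened against a different catalog version")
  }
  unknown <- setdiff(profile$counts$ec, catalog$functions$ec)
  if (length(unknown)) {
    stop("profile contains EC(s) unknown to the catalog: ",
         paste(unknown, collapse = ", "))
  }
  f <- catalog$functions
  role <- stats::setNames(f$role, f$ec)
  mech <- stats::setNames(f$mechanism, f$ec)
  counts <- profile$counts
  pick <- function(keep) {
    out <- counts[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(
    halogenase = pick(role[counts$ec] == "halogenase"),
    dehalogenase = pick(role[counts$ec] == "dehalogenase"),
    hydrolytic = pick(mech[counts$ec] == "hydrolytic"),
    non_hydrolytic = pick(role[counts$ec] == "dehalogenase" &
                            mech[counts$ec] == "non_hydrolytic")
  )
}

#' Write a per-sample function-count table
#'
#' One row per observed catalog EC: `sample_id`, `ec`, `enzyme_name`,
#' `role`, `mechanism`, `n_genes`.
#'
#' @param profile A `sample_profile`.
#' @param catalog The matching `halogen_catalog`.
#' @param path Output TSV path.
#' @return Invisibly, the table written.
#' @export
write_function_counts <- function(profile, catalog, path) {
  f <- catalog$functions
  idx <- match(profile$counts$ec, f$ec)
  out <- data.frame(sample_id = profile$sample_id,
                    ec = profile$counts$ec,
                    enzyme_name = f$name[idx],
                    role = f$role[idx],
                    mechanism = f$mechanism[idx],
                    n_genes = profile$counts$n_genes,
                    stringsAsFactors = FALSE)
  write_result_tsv(out, path)
  invisible(out)
}

#' A small worked annotation table
#'
#' Five features, two of which carry catalog ECs (the haloalkane
#' dehalogenase EC 3.8.1.5 and the tryptophan 7-halogenase EC 1.14.19.9),
#' used in documentation examples.
#'
#' @return An `annotation_table` of a 5 Mbp toy metagenome.
#' @export
example_annotation_table <- function() {
  features <- data.frame(
    locus_tag = sprintf("EX_%05d", 1:5),
    ftype = "CDS",
    length_bp = c(900, 1200, 750, 1500, 600),
    product = c("haloalkane dehalogenase", "tryptophan 7-halogenase",
                "hypothetical protein", "haloalkane dehalogenase",
                "hypothetical protein"),
    stringsAsFactors = FALSE
  )
  features$ec_numbers <- list("3.8.1.5", "1.14.19.9", character(0),
                              "3.8.1.5", character(0))
  new_annotation_table("example", "metagenome", 5e6, features)
}
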