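#' @keywords internal
"_PACKAGE"

#' Test whether a string is a complete EC number
#'
#' A complete Enzyme Commission number has four numeric fields
#' (`"a.b.c.d"`). Entries with missing or non-numeric fields (e.g.
#' `"3.8.1.-"`, `"3.8.1"`) are *partial* and are rejected throughout the
#' package: only fully characterized enzymes are matchable.
#'
#' @param ec Character vector of candidate EC strings.
#' @return Logical vector.
#' @export
#' @examples
#' is_complete_ec(c("3.8.1.5", "3.8.1.-", "3.8.1"))
is_complete_ec <- function(ec) {
  !is.na(ec) & grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", ec)
}

#' Path to the packaged halogen-metabolism catalog
#'
#' @return File path of the catalog JSON shipped with the package.
#' @export
packaged_catalog_path <- function() {
  system.file("extdata", "halogen_catalog.json", package = "haloscreen",
              mustWork = TRUE)
}

new_halogen_catalog <- function(functions, clusters, version) {
  structure(list(version = version, functions = functions,
                 clusters = clusters),
            class = "halogen_catalog")
}

#' Load and validate a halogen-function catalog
#'
#' Reads a catalog JSON file (top-level keys `version`, `functions`,
#' `clusters`) and enforces its structural invariants:
#' \itemize{
#'   \item every `ec` is a complete four-field EC number, unique in the
#'     catalog;
#'   \item `role` is one of `halogenase`, `dehalogenase`, `auxiliary`;
#'     halogenases and dehalogenases form the *direct* subset (enzymes
#'     forming or breaking carbon--halogen bonds);
#'   \item `mechanism` is `hydrolytic` exactly for dehalogenases of the
#'     EC 3.8.1.x family, `non_hydrolytic` for other dehalogenases, and
#'     `not_applicable` otherwise;
#'   \item every cluster has a non-empty `member_ecs` set resolved against
#'     the functions, direction `degradative` or `biosynthetic`, and its
#'     members' pathway `direction` is consistent (no halogenation-side
#'     enzyme inside a degradative cluster and vice versa);
#'   \item per-function `cluster_ids` mirror the cluster rosters.
#' }
#'
#' @param path Path to a catalog JSON file; defaults to the packaged
#'   catalog.
#' @return A `halogen_catalog` object: a list with `version` (character),
#'   `functions` (data.frame with columns `ec`, `name`, `role`,
#'   `mechanism`, `direction` and list-column `cluster_ids`) and
#'   `clusters` (data.frame with columns `cluster_id`, `name`,
#'   `direction` and list-column `member_ecs`).
#' @export
#' @examples
#' cat <- load_catalog()
#' nrow(cat$functions)
load_catalog <- function(path = packaged_catalog_path()) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("version", "functions", "clusters")) {
    if (is.null(raw[[key]])) stop("catalog file lacks top-level key '", key, "'")
  }

  pluck_chr <- function(lst, key, what) {
    vapply(lst, function(x) {
      v <- x[[key]]
      if (is.null(v)) stop("catalog ", what, " entry missing field '", key, "'")
      as.character(v)
    }, character(1))
  }
  pluck_set <- function(lst, key) {
    lapply(lst, function(x) {
      v <- x[[key]]
      if (is.null(v)) character(0) else unique(as.character(unlist(v)))
    })
  }

  functions <- data.frame(
    ec = if (length(raw$functions)) pluck_chr(raw$functions, "ec", "function") else character(0),
    name = if (length(raw$functions)) pluck_chr(raw$functions, "name", "function") else character(0),
    role = if (length(raw$functions)) pluck_chr(raw$functions, "role", "function") else character(0),
    mechanism = if (length(raw$functions)) pluck_chr(raw$functions, "mechanism", "function") else character(0),
    direction = if (length(raw$functions)) pluck_chr(raw$functions, "direction", "function") else character(0),
    stringsAsFactors = FALSE
  )
  functions$cluster_ids <- pluck_set(raw$functions, "cluster_ids")

  clusters <- data.frame(
    cluster_id = if (length(raw$clusters)) pluck_chr(raw$clusters, "cluster_id", "cluster") else character(0),
    name = if (length(raw$clusters)) pluck_chr(raw$clusters, "name", "cluster") else character(0),
    direction = if (length(raw$clusters)) pluck_chr(raw$clusters, "direction", "cluster") else character(0),
    stringsAsFactors = FALSE
  )
  clusters$member_ecs <- pluck_set(raw$clusters, "member_ecs")

  validate_catalog_structure(functions, clusters)
  new_halogen_catalog(functions, clusters, as.character(raw$version))
}

validate_catalog_structure <- function(functions, clusters) {
  bad <- functions$ec[!is_complete_ec(functions$ec)]
  if (length(bad)) {
    stop("catalog contains partial or malformed EC number(s): ",
         paste(bad, collapse = ", "),
         " (only complete four-field EC numbers are admitted)")
  }
  dup <- unique(functions$ec[duplicated(functions$ec)])
  if (length(dup)) stop("duplicate EC number(s) in catalog: ",
                        paste(dup, collapse = ", "))
  bad_role <- functions$ec[!functions$role %in%
                             c("halogenase", "dehalogenase", "auxiliary")]
  if (length(bad_role)) stop("invalid role for EC(s): ",
                             paste(bad_role, collapse = ", "))
  bad_dir <- functions$ec[!functions$direction %in%
                            c("halogenation", "dehalogenation")]
  if (length(bad_dir)) stop("invalid direction for EC(s): ",
                            paste(bad_dir, collapse = ", "))

  expected_mech <- ifelse(
    functions$role == "dehalogenase",
    ifelse(startsWith(functions$ec, "3.8.1."), "hydrolytic", "non_hydrolytic"),
    "not_applicable")
  bad_mech <- functions$ec[functions$mechanism != expected_mech]
  if (length(bad_mech)) {
    stop("mechanism inconsistent with role/EC for: ",
         paste(bad_mech, collapse = ", "),
         " (hydrolytic is reserved for EC 3.8.1.x dehalogenases)")
  }

  dupc <- unique(clusters$cluster_id[duplicated(clusters$cluster_id)])
  if (length(dupc)) stop("duplicate cluster id(s): ",
                         paste(dupc, collapse = ", "))
  bad_cdir <- clusters$cluster_id[!clusters$direction %in%
                                    c("degradative", "biosynthetic")]
  if (length(bad_cdir)) stop("invalid cluster direction for: ",
                             paste(bad_cdir, collapse = ", "))
  fn_dir <- stats::setNames(functions$direction, functions$ec)
  for (i in seq_len(nrow(clusters))) {
    members <- clusters$member_ecs[[i]]
    cid <- clusters$cluster_id[i]
    if (!length(members)) stop("cluster ", cid, " has no member ECs")
    unknown <- setdiff(members, functions$ec)
    if (length(unknown)) {
      stop("cluster ", cid, " references EC(s) absent from the catalog: ",
           paste(unknown, collapse = ", "))
    }
    want <- if (clusters$direction[i] == "degradative") "dehalogenation"
            else "halogenation"
    off <- members[fn_dir[members] != want]
    if (length(off)) {
      stop("cluster ", cid, " (", clusters$direction[i],
           ") contains EC(s) of the opposite pathway direction: ",
           paste(off, collapse = ", "))
    }
  }

  # cluster_ids on functions must mirror cluster rosters
  mirror <- stats::setNames(vector("list", nrow(functions)), functions$ec)
  for (i in seq_len(nrow(clusters))) {
    for (e in clusters$member_ecs[[i]]) {
      mirror[[e]] <- c(mirror[[e]], clusters$cluster_id[i])
    }
  }
  for (i in seq_len(nrow(functions))) {
    got <- sort(functions$cluster_ids[[i]])
    want <- sort(unlist(mirror[[functions$ec[i]]], use.names = FALSE))
    if (!identical(got, as.character(want))) {
      stop("cluster_ids of EC ", functions$ec[i],
           " do not mirror the cluster rosters (function lists [",
           paste(got, collapse = ";"), "], clusters list [",
           paste(want, collapse = ";"), "])")
    }
  }
  invisible(TRUE)
}

#' @export
print.halogen_catalog <- function(x, ...) {
  cat("<halogen_catalog> ", x$version, "\n", sep = "")
  cat("  functions: ", nrow(x$functions),
      " (", sum(x$functions$role == "halogenase"), " halogenase, ",
      sum(x$functions$role == "dehalogenase"), " dehalogenase, ",
      sum(x$functions$role == "auxiliary"), " auxiliary)\n", sep = "")
  cat("  clusters:  ", nrow(x$clusters),
      " (", sum(x$clusters$direction == "degradative"), " degradative, ",
      sum(x$clusters$direction == "biosynthetic"), " biosynthetic)\n", sep = "")
  invisible(x)
}

#' Direct (halogenase + dehalogenase) EC subset of a catalog
#'
#' @param catalog A `halogen_catalog`.
#' @return Character vector of ECs directly forming or breaking
#'   carbon--halogen bonds.
#' @export
direct_ecs <- function(catalog) {
  stopifnot(inherits(catalog, "halogen_catalog"))
  catalog$functions$ec[catalog$functions$role %in%
                         c("halogenase", "dehalogenase")]
}

#' Check a catalog against the published structural counts
#'
#' Compares a loaded catalog with the reference structure of the published
#' halogen-metabolism dataset: 161 functions in total, 42 direct (16
#' halogenases + 26 dehalogenases), 119 auxiliary enzymes, and 32 clusters
#' (23 degradative + 9 biosynthetic).
#'
#' @param catalog A `halogen_catalog`.
#' @return A data.frame of class `catalog_validation` with columns
#'   `check`, `expected`, `observed`, `pass` (seven rows).
#' @export
#' @examples
#' rep <- validate_reference(load_catalog())
#' all(rep$pass)
validate_reference <- function(catalog) {
  stopifnot(inherits(catalog, "halogen_catalog"))
  f <- catalog$functions
  cl <- catalog$clusters
  observed <- c(
    n_functions = nrow(f),
    n_direct = sum(f$role %in% c("halogenase", "dehalogenase")),
    n_halogenase = sum(f$role == "halogenase"),
    n_dehalogenase = sum(f$role == "dehalogenase"),
    n_auxiliary = sum(f$role == "auxiliary"),
    n_clusters_degradative = sum(cl$direction == "degradative"),
    n_clusters_biosynthetic = sum(cl$direction == "biosynthetic")
  )
  expected <- c(n_functions = 161L, n_direct = 42L, n_halogenase = 16L,
                n_dehalogenase = 26L, n_auxiliary = 119L,
                n_clusters_degradative = 23L, n_clusters_biosynthetic = 9L)
  out <- data.frame(check = names(expected),
                    expected = as.integer(expected),
                    observed = as.integer(observed[names(expected)]),
                    stringsAsFactors = FALSE)
  out$pass <- out$expected == out$observed
  class(out) <- c("catalog_validation", class(out))
  out
}

#' @export
print.catalog_validation <- function(x, ...) {
  cat("Reference-catalog structural checks:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-24s expected %4d  observed %4d  [%s]\n",
                x$check[i], x$expected[i], x$observed[i],
                if (x$pass[i]) "PASS" else "FAIL"))
  }
  cat(if (all(x$pass)) "All checks passed.\n" else "Some checks FAILED.\n")
  invisible(x)
}

#' Look up one catalog function by complete EC number
#'
#' Matching is exact string equality on the full four-field EC; prefix or
#' wildcard forms are rejected, since the catalog excludes partially
#' assigned enzymes.
#'
#' @param catalog A `halogen_catalog`.
#' @param ec A single complete EC string.
#' @return One-row data.frame for the function, or `NULL` when the EC is
#'   not in the catalog.
#' @export
#' @examples
#' lookup_function(load_catalog(), "3.8.1.5")$role
lookup_function <- function(catalog, ec) {
  stopifnot(inherits(catalog, "halogen_catalog"))
  if (length(ec) != 1L || !is_complete_ec(ec)) {
    stop("'", paste(ec, collapse = ","),
         "' is not a complete four-field EC number; partial ECs cannot be ",
         "looked up")
  }
  hit <- which(catalog$functions$ec == ec)
  if (!length(hit)) return(NULL)
  catalog$functions[hit, , drop = FALSE]
}

#' Export a catalog to TSV for curation round-trips
#'
#' Writes two tab-separated files: one function per row
#' (`cluster_ids` semicolon-delimited) and one cluster per row
#' (`member_ecs` semicolon-delimited).
#'
#' @param catalog A `halogen_catalog`.
#' @param functions_path,clusters_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_catalog_tsv <- function(catalog, functions_path, clusters_path) {
  stopifnot(inherits(catalog, "halogen_catalog"))
  f <- catalog$functions
  f_out <- data.frame(ec = f$ec, name = f$name, role = f$role,
                      mechanism = f$mechanism, direction = f$direction,
                      cluster_ids = vapply(f$cluster_ids, paste,
                                           character(1), collapse = ";"),
                      stringsAsFactors = FALSE)
  cl <- catalog$clusters
  c_out <- data.frame(cluster_id = cl$cluster_id, name = cl$name,
                      direction = cl$direction,
                      member_ecs = vapply(cl$member_ecs, paste,
                                          character(1), collapse = ";"),
                      stringsAsFactors = FALSE)
  utils::write.table(f_out, functions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(c_out, clusters_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(functions_path, clusters_path))
}

#' Import a catalog from its TSV curation form
#'
#' @param functions_path,clusters_path Paths written by
#'   [write_catalog_tsv()].
#' @param version Version string to attach.
#' @return A validated `halogen_catalog`.
#' @export
read_catalog_tsv <- function(functions_path, clusters_path,
                             version = "tsv import") {
  f <- utils::read.delim(functions_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  cl <- utils::read.delim(clusters_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  split_semi <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || !nzchar(s)) character(0)
      else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  }
  functions <- f[c("ec", "name", "role", "mechanism", "direction")]
  functions$cluster_ids <- split_semi(f$cluster_ids)
  clusters <- cl[c("cluster_id", "name", "direction")]
  clusters$member_ecs <- split_semi(cl$member_ecs)
  validate_catalog_structure(functions, clusters)
  new_halogen_catalog(functions, clusters, version)
}
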