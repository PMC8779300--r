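#' @import ChemmineR
#' @importFrom stats cor dist median prcomp rbinom rgamma rlnorm rnorm rpois sd
#' @importFrom utils read.csv write.csv
NULL

# ---- molecule sets ---------------------------------------------------------

#' Construct a molecule set
#'
#' A molecule set is the package's container for compound records: one row
#' per compound with a unique `id`, a `category` label (`drug`, `np` or
#' `toxin`), an optional `name`, and the structure as a SMILES string.
#' Structures may be absent (`NA`) for compounds that only exist as
#' descriptor rows.
#'
#' @param ids character vector of unique compound identifiers. MarinLit-style
#'   codes (e.g. `"L22017"`) pass through verbatim.
#' @param smiles character vector of SMILES strings (or `NA`).
#' @param category a single label, or one per compound: `drug`, `np`, `toxin`.
#' @param names optional compound names.
#' @return An object of class `molecule_set`: a data frame with columns
#'   `id`, `category`, `name`, `smiles`.
#' @export
molecule_set <- function(ids, smiles, category, names = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate molecule ids: ", paste(dup, collapse = ", "))
  }
  category <- rep_len(as.character(category), length(ids))
  bad <- setdiff(unique(category), c("drug", "np", "toxin"))
  if (length(bad)) {
    stop("unknown category label(s): ", paste(bad, collapse = ", "),
         " (must be drug, np or toxin)")
  }
  if (is.null(names)) names <- rep(NA_character_, length(ids))
  x <- data.frame(id = ids, category = category,
                  name = as.character(names),
                  smiles = as.character(rep_len(smiles, length(ids))),
                  stringsAsFactors = FALSE)
  class(x) <- c("molecule_set", "data.frame")
  x
}

#' @export
`[.molecule_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- c("molecule_set", "data.frame")
  out
}

#' @export
print.molecule_set <- function(x, ...) {
  cat("<molecule_set> ", nrow(x), " compounds (",
      paste(sprintf("%s: %d", names(table(x$category)), table(x$category)),
            collapse = ", "), ")\n", sep = "")
  n_failed <- attr(x, "n_failed")
  if (!is.null(n_failed) && n_failed > 0)
    cat("  ", n_failed, " input entries failed to parse\n", sep = "")
  invisible(x)
}

# Parse one SMILES through OpenBabel; returns canonical SMILES or NA.
ob_parse_smiles <- function(smi) {
  out <- tryCatch(
    suppressWarnings(suppressMessages(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(smi, "\n"))
    )),
    error = function(e) ""
  )
  out <- trimws(strsplit(out, "[\t\n ]")[[1]][1])
  if (is.na(out) || !nzchar(out)) NA_character_ else out
}

#' Read molecules from a SMILES or SDF file
#'
#' SMILES files hold one molecule per line, with an optional second
#' whitespace-separated token used as the id. Entries that fail to parse are
#' counted and reported via the `n_failed`/`failed` attributes (and a
#' message), never silently dropped; `strict = TRUE` aborts on the first
#' failure instead.
#'
#' @param path file path.
#' @param format `"smiles"` or `"sdf"`.
#' @param category category label applied to all records.
#' @param strict abort on the first unparseable entry?
#' @return A [molecule_set()] with attributes `n_failed` (count) and
#'   `failed` (ids/line numbers of rejected entries).
#' @export
read_molecules <- function(path, format = c("smiles", "sdf"),
                           category = "np", strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    if (!length(lines)) stop("empty molecule file: ", path)
    tok <- strsplit(trimws(lines), "\\s+")
    smi <- vapply(tok, `[`, "", 1L)
    ids <- vapply(tok, function(t) if (length(t) >= 2) t[2] else NA, "")
    ids[is.na(ids)] <- paste0("mol", which(is.na(ids)))
    parsed <- vapply(smi, ob_parse_smiles, "", USE.NAMES = FALSE)
    ok <- !is.na(parsed)
    if (!all(ok)) {
      msg <- paste0(sum(!ok), " of ", length(ok),
                    " entries failed to parse: ",
                    paste(ids[!ok], collapse = ", "))
      if (strict) stop(msg)
      message(msg)
    }
    if (anyDuplicated(ids[ok])) {
      stop("duplicate molecule ids: ",
           paste(unique(ids[ok][duplicated(ids[ok])]), collapse = ", "))
    }
    ms <- molecule_set(ids[ok], smi[ok], category)
    attr(ms, "n_failed") <- sum(!ok)
    attr(ms, "failed") <- ids[!ok]
    ms
  } else {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
    if (!length(sdf)) stop("empty SDF file: ", path)
    valid <- ChemmineR::validSDF(sdf)
    ids <- ChemmineR::sdfid(sdf)
    ids[!nzchar(ids) | is.na(ids)] <-
      paste0("mol", which(!nzchar(ids) | is.na(ids)))
    if (any(!valid)) {
      msg <- paste0(sum(!valid), " of ", length(valid),
                    " SDF entries failed to parse: ",
                    paste(ids[!valid], collapse = ", "))
      if (strict) stop(msg)
      message(msg)
    }
    sdf <- sdf[valid]
    ids <- ids[valid]
    if (anyDuplicated(ids)) {
      stop("duplicate molecule ids: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    smi <- as.character(suppressWarnings(ChemmineR::sdf2smiles(sdf)))
    ms <- molecule_set(ids, smi, category)
    attr(ms, "n_failed") <- sum(!valid)
    attr(ms, "failed") <- which(!valid)
    ms
  }
}

# SDFset for the multi-atom structures of a molecule set (used for ring
# perception and fingerprints). Single-atom molecules cannot be represented
# as valid V2000 blocks by ChemmineR and are returned in `skipped`.
mol_sdfset <- function(ms) {
  stopifnot(inherits(ms, "molecule_set"))
  if (any(is.na(ms$smiles))) stop("molecule set has structure-less records")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(ms$smiles, ms$id)))
  valid <- ChemmineR::validSDF(sdf)
  list(sdf = sdf[valid], ids = ms$id[valid], skipped = ms$id[!valid])
}

# ---- descriptor tables -----------------------------------------------------

#' Construct a descriptor table
#'
#' Molecules-by-variables matrix of continuous descriptors with a category
#' label per molecule (the stand-in for a QikProp-style property table).
#'
#' @param values numeric matrix, rownames = molecule ids, colnames =
#'   descriptor names.
#' @param categories category label per row.
#' @return Object of class `descriptor_table` with fields `ids`, `variables`,
#'   `values`, `categories`.
#' @export
descriptor_table <- function(values, categories) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have molecule ids as rownames")
  if (is.null(colnames(values))) stop("values must have variable names as colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate variable names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyDuplicated(rownames(values)))
    stop("duplicate molecule ids in descriptor table")
  if (!is.numeric(values)) stop("descriptor values must be numeric")
  if (any(!is.finite(values)))
    stop("descriptor table contains missing or non-finite values")
  categories <- rep_len(as.character(categories), nrow(values))
  x <- list(ids = rownames(values), variables = colnames(values),
            values = values, categories = categories)
  class(x) <- "descriptor_table"
  x
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("<descriptor_table> ", length(x$ids), " molecules x ",
      length(x$variables), " variables\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.descriptor_table <- function(x, ...) {
  data.frame(id = x$ids, category = x$categories, x$values,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a descriptor table from CSV
#'
#' Expects the first column to hold molecule ids, a `category` column, and
#' one numeric column per descriptor. Coercion is strict: any cell that is
#' missing or not interpretable as a number aborts the load, naming the
#' offending row and column.
#'
#' @param path CSV file path (comma-separated, UTF-8, `.` decimal).
#' @return A [descriptor_table()].
#' @export
read_descriptor_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = "character")
  if (!nrow(df)) stop("empty descriptor CSV: ", path)
  if (!("category" %in% names(df)))
    stop("descriptor CSV has no 'category' column: ", path)
  ids <- df[[1]]
  cat_col <- df$category
  varcols <- setdiff(names(df)[-1], "category")
  if (!length(varcols)) stop("descriptor CSV has no descriptor columns")
  vals <- matrix(NA_real_, nrow(df), length(varcols),
                 dimnames = list(ids, varcols))
  for (v in varcols) {
    raw <- df[[v]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric cell in descriptor CSV: row %d (id %s), column '%s', value '%s'",
        bad[1], ids[bad[1]], v, raw[bad[1]]))
    }
    vals[, v] <- num
  }
  descriptor_table(vals, cat_col)
}

#' Write a descriptor table to CSV
#' @param x a [descriptor_table()].
#' @param path output file path.
#' @export
write_descriptor_csv <- function(x, path) {
  stopifnot(inherits(x, "descriptor_table"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# ---- endpoint tables -------------------------------------------------------

#' Construct an ADMET endpoint table
#'
#' Binary molecules-by-endpoints matrix, coded 1 = predicted
#' positive/beneficial and 0 = negative/harmful (admetSAR-style output).
#'
#' @param values 0/1 matrix with molecule ids as rownames and endpoint names
#'   as colnames.
#' @return Object of class `endpoint_table`.
#' @export
endpoint_table <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("endpoint values need molecule id rownames")
  if (is.null(colnames(values))) stop("endpoint values need endpoint name colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate endpoint names")
  if (!all(values %in% c(0, 1)))
    stop("endpoint values must be binary (1 = beneficial, 0 = harmful)")
  storage.mode(values) <- "integer"
  x <- list(ids = rownames(values), endpoints = colnames(values),
            values = values)
  class(x) <- "endpoint_table"
  x
}

#' @export
print.endpoint_table <- function(x, ...) {
  cat("<endpoint_table> ", length(x$ids), " molecules x ",
      length(x$endpoints), " endpoints\n", sep = "")
  invisible(x)
}

#' Read an ADMET endpoint table from CSV
#'
#' First column = molecule ids, remaining columns = binary endpoints.
#' @param path CSV file path.
#' @return An [endpoint_table()].
#' @export
read_endpoint_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty endpoint CSV: ", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  if (any(is.na(vals)))
    stop("missing cells in endpoint CSV: ", path)
  endpoint_table(vals)
}

#' Write an endpoint table to CSV
#' @param x an [endpoint_table()].
#' @param path output file path.
#' @export
write_endpoint_csv <- function(x, path) {
  stopifnot(inherits(x, "endpoint_table"))
  write.csv(data.frame(id = x$ids, x$values, check.names = FALSE),
            path, row.names = FALSE)
  invisible(path)
}

# ---- score tables ----------------------------------------------------------

#' Write a score table (likeness profiles or composite scores) to CSV
#'
#' Column order is taken from the input and is stable: `id` first, then the
#' score columns in their given order.
#'
#' @param profiles data frame of per-molecule scores with an `id` column.
#' @param path output file path.
#' @export
write_scores_csv <- function(profiles, path) {
  profiles <- as.data.frame(profiles)
  if (!nrow(profiles)) stop("no profiles to write")
  if (!("id" %in% names(profiles))) stop("profiles must have an 'id' column")
  profiles <- profiles[, c("id", setdiff(names(profiles), "id")), drop = FALSE]
  ok <- tryCatch({ write.csv(profiles, path, row.names = FALSE); TRUE },
                 error = function(e) stop("cannot write scores to ", path,
                                          ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a score table written by [write_scores_csv()]
#' @param path CSV file path.
#' @return data frame with `id` column.
#' @export
read_scores_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  df
}
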