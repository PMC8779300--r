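# Eight QED/RDL molecular properties and structural alerts.
#
# Backend: OpenBabel via ChemmineOB for MW, ALOGP (atomic-contribution log P),
# HBD/HBA, TPSA and SMARTS matching; ChemmineR ring perception (SSSR) for
# aromatic ring counts. PSA is topological (TPSA) since inputs are 2D.

# Rotatable bond SMARTS: non-ring single bond between two non-terminal heavy
# atoms, triple-bond termini and amide C-N excluded (common convention).
ROTB_SMARTS <- paste0(
  "[!$(*#*)&!D1&!$([CX3](=[OX1])[NX3])]-&!@",
  "[!$(*#*)&!D1&!$([NX3][CX3]=[OX1])]")

ob_mols <- function(ms) {
  stopifnot(inherits(ms, "molecule_set"))
  if (any(is.na(ms$smiles)))
    stop("structures absent for: ",
         paste(ms$id[is.na(ms$smiles)], collapse = ", "))
  input <- paste0(ms$smiles, " ", ms$id, collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", input, identity)
  if (length(mols) != nrow(ms))
    stop("unsanitizable structure(s); parsed ", length(mols), " of ",
         nrow(ms), " molecules")
  mols
}

#' The eight QED/RDL molecular properties
#'
#' Computes, per molecule: molecular weight (`MW`, Da), octanol:water
#' log-partition estimate (`ALOGP`), hydrogen-bond donor and acceptor counts
#' (`HBD`, `HBA`), topological polar surface area (`PSA`, A^2), rotatable
#' bond count (`ROTB`), aromatic ring count (`AROM`, SSSR rings whose bonds
#' are all aromatic), and structural alert count (`ALERTS`, number of
#' distinct alert patterns matched).
#'
#' @param ms a [molecule_set()] with structures for every record.
#' @param alert_patterns alert pattern table from [load_alert_patterns()];
#'   default is the shipped curated Brenk-style set.
#' @return data frame: `id`, `category`, then the eight property columns.
#' @export
eight_properties <- function(ms, alert_patterns = load_alert_patterns()) {
  mols <- ob_mols(ms)
  props <- lapply(mols, ChemmineOB::prop_OB)
  getnum <- function(field) vapply(props, function(p) as.numeric(p[[field]]), 0)
  mw <- getnum("MW")
  if (any(mw <= 0)) stop("non-positive MW for: ",
                         paste(ms$id[mw <= 0], collapse = ", "))
  rotb <- as.integer(round(
    ChemmineOB::smartsSearch_OB(mols, ROTB_SMARTS, uniqueMatches = TRUE)))
  arom <- aromatic_ring_count(ms)
  alerts <- count_structural_alerts(ms, alert_patterns, .mols = mols)
  out <- data.frame(
    id = ms$id, category = ms$category,
    MW = mw, ALOGP = getnum("logP"),
    HBD = as.integer(getnum("HBD")), HBA = as.integer(getnum("HBA1")),
    PSA = getnum("TPSA"), ROTB = rotb, AROM = arom,
    ALERTS = alerts, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# SSSR rings whose bonds are all aromatic; 0 for molecules too small for
# ring perception (single heavy atom).
aromatic_ring_count <- function(ms) {
  conv <- mol_sdfset(ms)
  arom <- stats::setNames(integer(nrow(ms)), ms$id)
  if (length(conv$ids)) {
    r <- ChemmineR::rings(conv$sdf, type = "count", arom = TRUE, inner = TRUE)
    counts <- if (is.matrix(r)) r[, "AROMATIC"] else r[["AROMATIC"]]
    arom[conv$ids] <- as.integer(counts)
  }
  unname(arom)
}

#' Load a structural-alert pattern file
#'
#' One pattern per line: `SMARTS<whitespace>name`; `#` starts a comment.
#' Every pattern is compiled against a probe molecule so invalid SMARTS fail
#' at load, naming the pattern.
#'
#' @param path pattern file; default is the curated alert set shipped with
#'   the package (a hand-written subset of the published Brenk alerts).
#' @return data frame with columns `smarts`, `name`.
#' @export
load_alert_patterns <- function(path = system.file("extdata",
                                                   "structural_alerts.smarts",
                                                   package = "npdrugspace")) {
  if (!file.exists(path)) stop("alert pattern file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("(^|\\s)#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  tok <- regmatches(lines, regexpr("\\s+", lines), invert = TRUE)
  smarts <- vapply(tok, `[`, "", 1L)
  nm <- vapply(tok, function(t) if (length(t) >= 2) t[2] else t[1], "")
  probe <- ChemmineOB::forEachMol("SMILES", "CCO probe", identity)
  for (i in seq_along(smarts)) {
    ok <- tryCatch({
      suppressWarnings(ChemmineOB::smartsSearch_OB(probe, smarts[i]))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("invalid SMARTS pattern '", nm[i], "': ", smarts[i])
  }
  data.frame(smarts = smarts, name = nm, stringsAsFactors = FALSE)
}

#' Count structural alerts per molecule
#'
#' The count is the number of *distinct* alert patterns with at least one
#' match in the molecule, not the total number of matches.
#'
#' @param ms a [molecule_set()].
#' @param patterns data frame with `smarts` and `name` columns (see
#'   [load_alert_patterns()]); an empty table gives 0 for every molecule.
#' @param .mols internal: pre-parsed OpenBabel molecules.
#' @return integer vector, one count per molecule.
#' @export
count_structural_alerts <- function(ms, patterns = load_alert_patterns(),
                                    .mols = NULL) {
  if (is.null(.mols)) .mols <- ob_mols(ms)
  n <- length(.mols)
  if (!nrow(patterns)) return(integer(n))
  hits <- matrix(0L, n, nrow(patterns))
  for (j in seq_len(nrow(patterns))) {
    cnt <- tryCatch(
      suppressWarnings(ChemmineOB::smartsSearch_OB(
        .mols, patterns$smarts[j], uniqueMatches = TRUE)),
      error = function(e) stop("alert pattern failed to compile: '",
                               patterns$name[j], "' (", patterns$smarts[j], ")"))
    hits[, j] <- as.integer(cnt > 0)
  }
  as.integer(rowSums(hits))
}

#' Assemble a descriptor table for chemical-space analysis
#'
#' With `backend = "computed"` the table holds the eight computed property
#' columns. With a CSV backend the table is read from file and checked
#' against the molecule set ids.
#'
#' @param ms a [molecule_set()].
#' @param backend `"computed"`, or a path to a descriptor CSV
#'   (see [read_descriptor_csv()]).
#' @param alert_patterns passed to [eight_properties()].
#' @return A [descriptor_table()], ids aligned with `ms`.
#' @export
build_descriptor_table <- function(ms, backend = "computed",
                                   alert_patterns = load_alert_patterns()) {
  stopifnot(inherits(ms, "molecule_set"))
  if (identical(backend, "computed")) {
    pr <- eight_properties(ms, alert_patterns)
    vals <- as.matrix(pr[, c("MW", "ALOGP", "HBD", "HBA",
                             "PSA", "ROTB", "AROM", "ALERTS")])
    rownames(vals) <- pr$id
    descriptor_table(vals, ms$category)
  } else {
    tab <- read_descriptor_csv(backend)
    extra <- setdiff(tab$ids, ms$id)
    missing <- setdiff(ms$id, tab$ids)
    if (length(extra) || length(missing)) {
      stop("descriptor CSV / molecule set id mismatch; ",
           if (length(extra)) paste0("unknown in CSV: ",
                                     paste(extra, collapse = ", "), "; "),
           if (length(missing)) paste0("absent from CSV: ",
                                       paste(missing, collapse = ", ")))
    }
    idx <- match(ms$id, tab$ids)
    descriptor_table(tab$values[idx, , drop = FALSE], ms$category)
  }
}
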