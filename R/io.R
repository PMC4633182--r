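# CSV dialect: one row per worker, 22 trait columns (spelling variants
# tolerated), a nest/sample-code column, optional species and bookkeeping
# columns which are passed through untouched.

.meta_cols <- c("specimen_id", "nest_id", "species", "country", "region",
                "antennomere_count", "spine_angle_deg")

#' Read a worker morphometric dataset
#'
#' Reads a per-specimen CSV of the 22 linear measurements (micrometres).
#' Trait column names are matched case-insensitively and the spelling
#' variants `PoOc`/`POC` and `NodL` are accepted. Rows with non-numeric or
#' invalid trait cells are rejected (not fatal) and listed in the attached
#' parse report; a missing trait column is fatal. Unknown columns are kept.
#'
#' @param path CSV file path.
#' @param nest_col name of the nest/sample-code column; auto-detected among
#'   `nest_id`/`sample`/`sample_code` when `NULL`.
#' @param window plausibility window passed to [validate_traits()];
#'   `NULL` disables it.
#' @return data frame of accepted specimen records with canonical trait
#'   names, a `specimen_id` and `nest_id` column, and attribute
#'   `parse_report` (list: `rows_read`, `rows_rejected`, `reasons`).
#' @seealso [write_morph_csv()], [parse_report()]
#' @export
read_morph_csv <- function(path, nest_col = NULL, window = c(40, 2000)) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  names(raw) <- ifelse(canonical_trait(names(raw)) %in% trait_names(),
                       canonical_trait(names(raw)), names(raw))
  miss <- setdiff(trait_names(), names(raw))
  if (length(miss))
    stop("missing trait column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(nest_col)) {
    cand <- intersect(c("nest_id", "sample", "sample_code"), names(raw))
    if (!length(cand)) stop("no nest/sample-code column found", call. = FALSE)
    nest_col <- cand[1]
  }
  if (!nest_col %in% names(raw)) stop("nest column '", nest_col, "' absent", call. = FALSE)
  names(raw)[names(raw) == nest_col] <- "nest_id"

  n <- nrow(raw)
  reasons <- character(0)
  keep <- rep(TRUE, n)
  num <- raw
  for (tn in trait_names()) {
    v <- suppressWarnings(as.numeric(raw[[tn]]))
    bad <- is.na(v) & keep
    if (any(bad)) {
      reasons <- c(reasons, paste0("row ", which(bad), ": non-numeric ", tn,
                                   " ('", raw[[tn]][bad], "')"))
      keep[bad] <- FALSE
    }
    num[[tn]] <- v
  }
  for (i in which(keep)) {
    msg <- validate_traits(num[i, trait_names()], window = window, strict = FALSE)
    if (length(msg)) {
      reasons <- c(reasons, paste0("row ", i, ": ", paste(msg, collapse = "; ")))
      keep[i] <- FALSE
    }
  }
  out <- num[keep, , drop = FALSE]
  if (!"specimen_id" %in% names(out))
    out$specimen_id <- paste0("row", seq_len(n))[keep]
  if ("antennomere_count" %in% names(out))
    out$antennomere_count <- suppressWarnings(as.integer(out$antennomere_count))
  if ("spine_angle_deg" %in% names(out))
    out$spine_angle_deg <- suppressWarnings(as.numeric(out$spine_angle_deg))
  rownames(out) <- NULL
  attr(out, "parse_report") <- list(rows_read = n,
                                    rows_accepted = sum(keep),
                                    rows_rejected = n - sum(keep),
                                    reasons = reasons)
  out
}

#' Parse report of a read dataset
#'
#' @param records result of [read_morph_csv()].
#' @param json_path optional path; when given the report is also written
#'   as JSON.
#' @return the report list (rows read / accepted / rejected, reasons).
#' @export
parse_report <- function(records, json_path = NULL) {
  rep <- attr(records, "parse_report")
  if (is.null(rep)) stop("no parse report attached", call. = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, pretty = TRUE)
  rep
}

#' Write a worker morphometric dataset
#'
#' Inverse of [read_morph_csv()]. Numeric cells are serialized with 17
#' significant digits so that a write/read round trip reproduces every
#' value bit-identically.
#'
#' @param records specimen data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_morph_csv <- function(records, path) {
  out <- records
  for (cn in names(out)) {
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]]))
      out[[cn]] <- sub("^\\s+", "", sprintf("%.17g", out[[cn]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Parse a nest sample code
#'
#' Sample codes follow the convention
#' `COUNTRY:Locality-DistanceDirection-YYYYMMDD-sampleid`, e.g.
#' `"GRE:Levidi-10S-20000427-123"`.
#'
#' @param nest_id character vector of sample codes.
#' @return data frame with columns `country`, `locality`, `date`,
#'   `sample`; unparseable fields are `NA`.
#' @export
parse_nest_id <- function(nest_id) {
  m <- regmatches(nest_id, regexec("^([A-Z]{3}):(.+)-([0-9]{8})-([^-]+)$", nest_id))
  get <- function(i) vapply(m, function(x) if (length(x) == 5) x[i + 1] else NA_character_, "")
  data.frame(nest_id = nest_id, country = get(1), locality = get(2),
             date = get(3), sample = get(4), stringsAsFactors = FALSE)
}

#' Aggregate workers into nest samples
#'
#' Nest samples (all workers from one colony) are the unit of clustering
#' and of the identification key; their per-trait values are arithmetic
#' means of the member workers. Nests whose workers carry conflicting
#' species labels are kept but flagged ambiguous (and should be excluded
#' from supervised fitting).
#'
#' @param records specimen data frame with `nest_id` and trait columns.
#' @return data frame with one row per nest: `nest_id`, `n_workers`,
#'   trait means, plus `species` (NA + warning when members conflict) and
#'   any metadata columns constant within the nest.
#' @export
aggregate_nests <- function(records) {
  if (!"nest_id" %in% names(records)) stop("records lack nest_id", call. = FALSE)
  ids <- sort(unique(records$nest_id))
  tn <- intersect(trait_names(), names(records))
  rows <- lapply(ids, function(id) {
    sub <- records[records$nest_id == id, , drop = FALSE]
    out <- data.frame(nest_id = id, n_workers = nrow(sub), stringsAsFactors = FALSE)
    for (t in tn) out[[t]] <- mean(sub[[t]])
    for (mc in setdiff(.meta_cols, c("specimen_id", "nest_id", "species"))) {
      if (mc %in% names(sub)) {
        u <- unique(sub[[mc]])
        out[[mc]] <- if (length(u) == 1) u else u[1]
      }
    }
    if ("species" %in% names(sub)) {
      u <- unique(sub$species[!is.na(sub$species)])
      if (length(u) > 1) {
        warning("nest ", id, " has conflicting species labels (",
                paste(u, collapse = ", "), "); labeled ambiguous", call. = FALSE)
        out$species <- NA_character_
        out$ambiguous <- TRUE
      } else {
        out$species <- if (length(u)) u else NA_character_
        out$ambiguous <- FALSE
      }
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
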