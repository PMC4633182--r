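# Dichotomous identification keys: a machine-readable couplet structure,
# a traversal engine, JSON serialization, and the built-in 19-couplet
# worker key of the species group.

.couplet <- function(id, type, feature, op = NULL, threshold = NULL,
                     yes, no, threshold2 = NULL, yes_set = NULL, no_set = NULL,
                     range_yes = NULL, range_no = NULL, note = NULL,
                     range_no_unreliable = FALSE) {
  list(id = id, type = type, feature = feature, op = op,
       threshold = threshold, threshold2 = threshold2,
       yes_set = yes_set, no_set = no_set,
       yes = yes, no = no, range_yes = range_yes, range_no = range_no,
       note = note, range_no_unreliable = range_no_unreliable)
}

#' Assemble a dichotomous key
#'
#' @param couplets list of couplet nodes (see [nylanderi_key()] for the
#'   layout); branch targets are `"#<id>"` for another couplet or a taxon
#'   label for a leaf.
#' @param nest_mean_key logical: key calibrated for nest sample means.
#' @return object of class `morpho_key`.
#' @export
morpho_key <- function(couplets, nest_mean_key = TRUE) {
  ids <- vapply(couplets, `[[`, 0, "id")
  stopifnot(!anyDuplicated(ids))
  structure(list(couplets = stats::setNames(couplets, paste0("#", ids)),
                 nest_mean_key = nest_mean_key),
            class = "morpho_key")
}

#' The published 19-couplet worker key
#'
#' Machine-readable form of the dichotomous identification key for the
#' worker caste of the species group, generated in the original revision
#' by a cross-validated decision tree with two nodes manually replaced by
#' geographic distribution. Tests are strict as printed ("<"/">"); the
#' second lobe of each couplet is the complement of the first, and each
#' lobe carries the printed branch `[min, max]` of its nest-mean feature.
#' Couplet thresholds operate on nest sample means (2-3 workers per
#' nest); applying the key to a single worker is possible but carries the
#' published >95% caveat.
#'
#' Print-inherited quirks are preserved and flagged rather than repaired:
#' the bracketed range of couplet 11's second lobe is inconsistent with a
#' CL/CWb ratio and is marked unreliable; couplet 6's lobes carry branch
#' ranges that straddle the printed threshold (see note).
#'
#' @return `morpho_key` with 19 couplets.
#' @export
nylanderi_key <- function() {
  mainland <- c("EUROPE_MAINLAND", "CENTRAL_WEST_EUROPE",
                "EAST_EUROPE_BALKANS_CAUCASUS")
  morpho_key(list(
    .couplet(1, "categorical", "antennomere_count", yes = "flavicornis", no = "#2",
             yes_set = 11, no_set = 12,
             note = "11 antennomeres: yellow species of South Europe and the Central/East Mediterranean"),
    .couplet(2, "angle", "spine_angle_deg", op = "<", threshold = 28.5,
             threshold2 = 30, yes = "#3", no = "#4",
             range_yes = c(20, 25),
             note = "propodeal spine deviation from the mesosomal axis, lateral view"),
    .couplet(3, "ratio", "SPST/CS", op = ">", threshold = 0.384,
             yes = "laconicus", no = "lichtensteini",
             range_yes = c(0.391, 0.429), range_no = c(0.324, 0.377)),
    .couplet(4, "ratio", "SPST/CS", op = "<", threshold = 0.219,
             yes = "subtilis", no = "#5",
             range_yes = c(0.159, 0.230), range_no = c(0.190, 0.368)),
    .couplet(5, "ratio", "PoOC/NOH", op = ">", threshold = 2.678,
             yes = "#6", no = "#9",
             range_yes = c(2.526, 3.214), range_no = c(2.001, 2.733)),
    .couplet(6, "ratio", "SPST/CS", op = "<", threshold = 0.283,
             yes = "#7", no = "parvulus",
             range_yes = c(0.200, 0.298), range_no = c(0.278, 0.331),
             note = paste("printed lobes transposed relative to their own branch",
                          "ranges and the species' spine ratios; encoded with the",
                          "long-spined lobe leading to parvulus")),
    .couplet(7, "ratio", "FRS/CS", op = "<", threshold = 0.334,
             yes = "angustifrons", no = "#8",
             range_yes = c(0.320, 0.349), range_no = c(0.335, 0.397)),
    .couplet(8, "ratio", "ML/CS", op = ">", threshold = 1.228,
             yes = "similis", no = "helenae",
             range_yes = c(1.227, 1.272), range_no = c(1.155, 1.229),
             note = "see the differential diagnosis of ariadnae for helenae/ariadnae"),
    .couplet(9, "ratio", "SPST/CL", op = ">", threshold = 0.294,
             yes = "#10", no = "#11",
             range_yes = c(0.280, 0.338), range_no = c(0.178, 0.307)),
    .couplet(10, "ratio", "PEH/CS", op = ">", threshold = 0.402,
             threshold2 = 0.380, yes = "angulinodis", no = "crassispinus",
             range_yes = c(0.397, 0.413), range_no = c(0.366, 0.407),
             note = "see the differential diagnosis of crassispinus for crassispinus/crasecundus"),
    .couplet(11, "ratio", "CL/CWb", op = ">", threshold = 1.179,
             yes = "#12", no = "#16",
             range_yes = c(1.168, 1.278), range_no = c(0.178, 0.307),
             range_no_unreliable = TRUE,
             note = "second-lobe range as printed is inconsistent with CL/CWb; unreliable"),
    .couplet(12, "region", "region", yes = "#13", no = "#14",
             yes_set = mainland, no_set = "ANATOLIA_OR_CRETE"),
    .couplet(13, "ratio", "PL/CS", op = ">", threshold = 0.422,
             yes = "sordidulus", no = "tergestinus",
             range_yes = c(0.411, 0.434), range_no = c(0.390, 0.422),
             note = "see note under tergestinus"),
    .couplet(14, "ratio", "SPBA/CWb", op = "<", threshold = 0.30,
             yes = "lucidus", no = "#15",
             range_yes = c(0.266, 0.300), range_no = c(0.276, 0.341)),
    .couplet(15, "ratio", "NOL/CS", op = ">", threshold = 0.251,
             yes = "artvinensis", no = "ariadnae",
             range_yes = c(0.250, 0.288), range_no = c(0.228, 0.248),
             note = "see note under helenae"),
    .couplet(16, "ratio", "SPBA/CS", op = "<", threshold = 0.283,
             yes = "#17", no = "#18",
             range_yes = c(0.242, 0.282), range_no = c(0.243, 0.321)),
    .couplet(17, "ratio", "SPST/CS", op = ">", threshold = 0.262,
             yes = "nylanderi", no = "lucidus",
             range_yes = c(0.265, 0.297), range_no = c(0.190, 0.259)),
    .couplet(18, "ratio", "PoOC/CL", op = "<", threshold = 0.375,
             yes = "schoedli", no = "#19",
             range_yes = c(0.360, 0.385), range_no = c(0.378, 0.405)),
    .couplet(19, "region", "region", yes = "crasecundus", no = "nylanderi",
             yes_set = "EAST_EUROPE_BALKANS_CAUCASUS",
             no_set = "CENTRAL_WEST_EUROPE")
  ))
}

.key_feature_value <- function(cpl, ratios, antennomere_count, spine_angle_deg,
                               region) {
  switch(cpl$type,
         categorical = antennomere_count,
         angle = spine_angle_deg,
         region = region,
         ratio = {
           v <- ratios[[cpl$feature]]
           if (is.null(v)) NA_real_ else v
         })
}

#' Identify a specimen or nest mean through a key
#'
#' Traverses a [morpho_key()] from couplet 1 and returns the leaf taxon
#' together with the ordered couplet path. Thresholds are strict as
#' printed: a value exactly at a threshold (or inside a couplet's printed
#' dead zone, e.g. a spine angle between 28.5 and 30 degrees) is a tie —
#' flagged, not silently assigned. A feature missing at a traversed
#' couplet is an error naming the couplet and the feature.
#'
#' @param traits named vector or one-row data frame of raw measurements
#'   (micrometres; ratios are derived), or of pre-computed ratio values.
#' @param key a `morpho_key`; default the built-in [nylanderi_key()].
#' @param antennomere_count antennal segment count; default 12 (all but
#'   one species).
#' @param spine_angle_deg propodeal spine deviation from the mesosomal
#'   axis, degrees.
#' @param region geographic region code (`"EUROPE_MAINLAND"`,
#'   `"ANATOLIA_OR_CRETE"`, `"CENTRAL_WEST_EUROPE"`,
#'   `"EAST_EUROPE_BALKANS_CAUCASUS"`).
#' @param single_specimen set `TRUE` when keying a single worker instead
#'   of a nest mean; the result then carries the >95% reliability caveat.
#' @return object of class `key_result`: list with `taxon` (NA on tie),
#'   `path` (couplet ids), `decisions` (data frame of couplet, feature,
#'   value, lobe), `notes`, `tie`, `caveat`.
#' @export
#' @examples
#' classify_key(c(antennomere_count = 11))$taxon   # the 11-segment species
classify_key <- function(traits = NULL, key = nylanderi_key(),
                         antennomere_count = 12, spine_angle_deg = NULL,
                         region = NULL, single_specimen = FALSE) {
  ratios <- NULL
  if (!is.null(traits)) {
    if (is.numeric(traits)) traits <- as.data.frame(as.list(traits), check.names = FALSE)
    names(traits) <- ifelse(canonical_trait(names(traits)) %in% trait_names(),
                            canonical_trait(names(traits)), names(traits))
    if (all(c("CL", "CWb") %in% names(traits))) {
      have <- intersect(trait_names(), names(traits))
      ok_ratios <- Filter(function(r) {
        p <- strsplit(r, "/", fixed = TRUE)[[1]]
        all(p %in% c(have, "CS"))
      }, known_ratios())
      ratios <- as.list(compute_ratios(traits, ok_ratios))
    } else ratios <- as.list(traits)
    if ("antennomere_count" %in% names(traits) &&
        !is.na(traits[["antennomere_count"]][1]))
      antennomere_count <- traits[["antennomere_count"]][1]
    if ("spine_angle_deg" %in% names(traits) && is.null(spine_angle_deg))
      spine_angle_deg <- traits[["spine_angle_deg"]][1]
    if ("region" %in% names(traits) && is.null(region))
      region <- as.character(traits[["region"]][1])
  }
  path <- integer(0)
  decisions <- list()
  notes <- character(0)
  at <- "#1"
  taxon <- NA_character_
  tie <- FALSE
  repeat {
    cpl <- key$couplets[[at]]
    if (is.null(cpl)) stop("dangling branch target ", at, call. = FALSE)
    v <- .key_feature_value(cpl, ratios, antennomere_count, spine_angle_deg, region)
    if (is.null(v) || (length(v) == 1 && is.na(v)))
      stop("couplet ", cpl$id, " requires feature '", cpl$feature,
           "', which is missing", call. = FALSE)
    path <- c(path, cpl$id)
    if (!is.null(cpl$note)) notes <- c(notes, paste0("couplet ", cpl$id, ": ", cpl$note))
    lobe <- if (cpl$type %in% c("categorical", "region")) {
      if (v %in% cpl$yes_set) "yes" else if (v %in% cpl$no_set) "no" else {
        stop("couplet ", cpl$id, ": feature '", cpl$feature, "' value '", v,
             "' matches neither lobe", call. = FALSE)
      }
    } else {
      lo_thr <- cpl$threshold
      hi_thr <- cpl$threshold2 %||% cpl$threshold
      if (cpl$op == "<") {
        if (v < lo_thr) "yes" else if (v > hi_thr) "no" else "tie"
      } else {
        if (v > lo_thr) "yes" else if (v < hi_thr) "no" else "tie"
      }
    }
    decisions[[length(decisions) + 1L]] <-
      data.frame(couplet = cpl$id, feature = cpl$feature,
                 value = as.character(v), lobe = lobe, stringsAsFactors = FALSE)
    if (lobe == "tie") { tie <- TRUE; break }
    nxt <- if (lobe == "yes") cpl$yes else cpl$no
    if (startsWith(nxt, "#")) { at <- nxt } else { taxon <- nxt; break }
  }
  structure(list(taxon = taxon, path = path,
                 decisions = do.call(rbind, decisions), notes = notes,
                 tie = tie,
                 caveat = if (single_specimen)
                   "single-specimen identification: expected reliability > 95%, not certainty"
                 else NULL),
            class = "key_result")
}

#' @export
print.key_result <- function(x, ...) {
  cat("Key identification: ",
      if (x$tie) "tie at a threshold (no class)" else x$taxon,
      "\n  path: ", paste(x$path, collapse = " -> "), "\n", sep = "")
  if (!is.null(x$caveat)) cat("  note: ", x$caveat, "\n", sep = "")
  invisible(x)
}

#' Identify every nest of a dataset
#'
#' Applies [classify_key()] to each row of a nest table (e.g. from
#' [aggregate_nests()]).
#'
#' @param nests nest data frame with trait-mean columns.
#' @param key `morpho_key`.
#' @return data frame `nest_id`, `taxon`, `path`, `tie`, `error`.
#' @export
identify_nests <- function(nests, key = nylanderi_key()) {
  rows <- lapply(seq_len(nrow(nests)), function(i) {
    res <- tryCatch(classify_key(nests[i, , drop = FALSE], key = key),
                    error = function(e) e)
    if (inherits(res, "error"))
      data.frame(nest_id = nests$nest_id[i], taxon = NA_character_,
                 path = NA_character_, tie = NA,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    else
      data.frame(nest_id = nests$nest_id[i], taxon = res$taxon,
                 path = paste(res$path, collapse = ">"), tie = res$tie,
                 error = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.morpho_key <- function(x, ...) {
  cat(format_key(x), sep = "\n")
  invisible(x)
}

#' Render a key as numbered couplets
#'
#' Text rendering in the conventional couplet format: each couplet's two
#' lobes with feature, threshold and branch `[min, max]`, leading to a
#' taxon or a further couplet number.
#'
#' @param key `morpho_key`.
#' @return character vector, one element per line.
#' @export
format_key <- function(key) {
  fmt_rng <- function(r, bad) if (is.null(r)) "" else
    sprintf(" [%g, %g]%s", r[1], r[2], if (isTRUE(bad)) " (range unreliable)" else "")
  fmt_tgt <- function(t) if (startsWith(t, "#")) sub("#", "...", t) else paste0("...", t)
  out <- character(0)
  for (cpl in key$couplets) {
    if (cpl$type %in% c("categorical", "region")) {
      l1 <- paste0(cpl$id, ". ", cpl$feature, ": ",
                   paste(cpl$yes_set, collapse = "/"), " ", fmt_tgt(cpl$yes))
      l2 <- paste0("-  ", cpl$feature, ": ",
                   paste(cpl$no_set, collapse = "/"), " ", fmt_tgt(cpl$no))
    } else {
      op2 <- if (cpl$op == "<") ">" else "<"
      thr2 <- cpl$threshold2 %||% cpl$threshold
      l1 <- paste0(cpl$id, ". ", cpl$feature, " ", cpl$op, " ", cpl$threshold,
                   fmt_rng(cpl$range_yes, FALSE), " ", fmt_tgt(cpl$yes))
      l2 <- paste0("-  ", cpl$feature, " ", op2, " ", thr2,
                   fmt_rng(cpl$range_no, cpl$range_no_unreliable), " ",
                   fmt_tgt(cpl$no))
    }
    if (!is.null(cpl$note)) l2 <- paste0(l2, "  (", cpl$note, ")")
    out <- c(out, l1, l2)
  }
  out
}

#' Serialize / restore a key as JSON
#'
#' @param key `morpho_key`.
#' @param path JSON file path.
#' @return `read_key` returns the restored `morpho_key`.
#' @export
write_key <- function(key, path) {
  jsonlite::write_json(list(nest_mean_key = key$nest_mean_key,
                            couplets = unname(key$couplets)),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_key
#' @export
read_key <- function(path) {
  raw <- jsonlite::read_json(path)
  cpls <- lapply(raw$couplets, function(cp) {
    for (f in c("range_yes", "range_no", "yes_set", "no_set"))
      if (!is.null(cp[[f]])) cp[[f]] <- unlist(cp[[f]])
    for (f in c("threshold", "threshold2")) if (!is.null(cp[[f]]))
      cp[[f]] <- as.numeric(cp[[f]])
    cp$id <- as.numeric(cp$id)
    cp$range_no_unreliable <- isTRUE(cp$range_no_unreliable)
    cp
  })
  morpho_key(cpls, nest_mean_key = isTRUE(raw$nest_mean_key))
}
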