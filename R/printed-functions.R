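# Registry of the published discriminant diagnostics: the linear functions
# D2-D7 printed in the differential diagnoses (coefficients per um of raw
# measurement) and the FRS/SL quick ratio. Coefficients, intercepts and
# reference score statistics are encoded verbatim from the printed values.

.df_stats <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(class = r[[1]], mean = r[[2]], min = r[[3]], max = r[[4]],
               p5 = r[[5]], p95 = r[[6]],
               level = if (length(r) > 6) r[[7]] else "individual",
               stringsAsFactors = FALSE)))
}

.printed_registry <- function() {
  list(
    discriminant_function(
      "D3_helenae_lucidus",
      c(PoOC = -0.0807, SL = 0.0896, SPTI = -0.0578), -11.284,
      negative_classes = "helenae", positive_classes = "lucidus",
      stats = .df_stats(
        list("helenae", -1.982, -4.509, 0.876, -3.433, -0.296),
        list("lucidus",  1.982, -0.101, 3.944,  0.564,  3.559)),
      success = c(individual = 97.9)),
    discriminant_function(
      "D4_similis_pool",
      c(SPST = 0.0492, PEH = -0.1037, ML = 0.0547, CL = -0.0417), 2.2655,
      negative_classes = c("angustifrons", "lucidus", "subtilis"),
      positive_classes = "similis",
      stats = .df_stats(
        list("angustifrons", -0.732, -2.383, 1.128, -2.013, 0.587),
        list("lucidus",      -1.442, -4.654, 0.492, -3.701, 0.117),
        list("subtilis",     -1.658, -5.202, 0.278, -3.463, -0.105),
        list("similis",       1.597, -0.198, 2.966,  0.240,  2.600)),
      success = c(individual = 98.6)),
    discriminant_function(
      "D4_subtilis_lucidus",
      c(EL = 0.0717, NOH = 0.0778, SPST = 0.0404, SPBA = -0.0824), -10.321,
      negative_classes = "subtilis", positive_classes = "lucidus",
      stats = .df_stats(
        list("subtilis", -2.056, -4.256, 0.259, -3.620, -0.403),
        list("lucidus",   2.098, -0.146, 6.298,  0.576,  3.700)),
      success = c(individual = 98.6)),
    discriminant_function(
      "D2_subtilis_helenae",
      c(SPST = -0.0928, ML = 0.0215), -2.811,
      negative_classes = "helenae", positive_classes = "subtilis",
      stats = .df_stats(
        list("helenae", -1.760, -4.946, 2.088, -3.664, -0.038),
        list("subtilis", 1.690, -0.628, 4.455,  0.044,  3.148))),
    discriminant_function(
      "D3_lichtensteini_laconicus",
      c(PoOC = -0.0498, FRS = -0.0541, SPST = 0.0975), 3.3108,
      negative_classes = "lichtensteini", positive_classes = "laconicus",
      stats = .df_stats(
        list("lichtensteini", -0.656, -4.078, 1.928, -2.413, 1.121),
        list("laconicus",      3.085,  0.866, 4.950,  1.676, 4.471)),
      success = c(individual = 98.6)),
    discriminant_function(
      "D4_crassispinus_crasecundus",
      c(SL = 0.0392, SPST = -0.0746, SPL = 0.0933, SPWI = -0.0295), -7.2179,
      negative_classes = "crassispinus", positive_classes = "crasecundus",
      stats = .df_stats(
        list("crassispinus", -1.458, -4.225, 0.521, -3.064, -0.075),
        list("crasecundus",   1.458, -2.386, 3.947, -0.055,  3.387),
        list("crassispinus", -1.440, -2.789, -0.166, -2.511, -0.353, "nest"),
        list("crasecundus",   1.479, -0.381,  3.360, -0.035,  2.849, "nest")),
      success = c(individual = 95, nest = 97)),
    discriminant_function(
      "D4_ariadnae_helenae",
      c(PPL = -0.0932, PoOC = -0.0767, PL = 0.1203, SPWI = -0.0384), 9.827,
      negative_classes = "helenae", positive_classes = "ariadnae",
      stats = .df_stats(
        list("ariadnae",  1.607,  0.042, 2.571,  0.042,  2.571),
        list("helenae",  -1.607, -4.748, 0.746, -3.333, -0.061)),
      success = c(individual = 99.4, nest = 100)),
    discriminant_function(
      "D5_helenae_lucidus_subtilis",
      c(SPST = -0.0730, SL = 0.0255, PoOC = -0.0634, ML = 0.0405,
        SPBA = -0.0613), -4.8074,
      negative_classes = "helenae", positive_classes = c("lucidus", "subtilis"),
      stats = .df_stats(
        list("helenae", -2.209, -4.220, -0.234, NA, NA, "nest"),
        list("lucidus",  1.410,  0.190,  2.314, NA, NA, "nest"),
        list("subtilis", 1.579,  0.218,  3.155, NA, NA, "nest")),
      success = c(individual = 97, nest = 100)),
    discriminant_function(
      "D5_parvulus_helenae",
      c(CL = 0.0393, SPST = -0.0616, PEW = 0.0892, PPW = -0.0580,
        SPWI = -0.0338), -8.7356,
      negative_classes = "parvulus", positive_classes = "helenae",
      stats = .df_stats(
        list("parvulus", -1.624, -3.809, 0.811, NA, NA),
        list("helenae",   1.647, -0.950, 5.013, NA, NA),
        list("parvulus", -1.723, -2.921, -0.104, NA, NA, "nest"),
        list("helenae",   1.684,  0.018,  3.937, NA, NA, "nest")),
      success = c(individual = 97.1, nest = 100)),
    discriminant_function(
      "D4_artvinensis_pool",
      c(EL = 0.114, PEW = -0.124, NOH = 0.098, PPL = -0.068), 3.69209,
      negative_classes = "artvinensis",
      positive_classes = c("schoedli", "tergestinus", "sordidulus"),
      stats = .df_stats(
        list("artvinensis", -1.620, -2.633, -0.877, NA, NA, "nest"),
        list("schoedli",     2.044,  1.296,  3.555, NA, NA, "nest"),
        list("tergestinus",  1.575, -0.377,  3.208, NA, NA, "nest"),
        list("sordidulus",   2.218,  0.620,  3.336, NA, NA, "nest")),
      success = c(individual = 97.9)),
    discriminant_function(
      "D7_sordidulus_tergestinus",
      c(SPTI = 0.0323, NOL = -0.0594, SL = 0.0859, ML = -0.0490,
        CWb = 0.0867, EL = -0.1167, CL = -0.0414), -1.2164,
      negative_classes = "sordidulus", positive_classes = "tergestinus",
      stats = .df_stats(
        list("sordidulus",  -1.872, -5.013, -0.191, -4.301, -0.500),
        list("tergestinus",  1.872, -0.481,  4.314,  0.254,  3.275)),
      success = c(individual = 99, nest = 100))
  )
}

#' Published discriminant functions
#'
#' The registry of the linear discriminant diagnostics printed in the
#' group's revision, keyed by id. Each entry is a
#' [discriminant_function()] whose coefficients (per micrometre),
#' intercept, sign rule and reference score statistics (group means,
#' ranges and 5-95% percentiles, individual and/or nest level) are the
#' printed values. The class with the negative printed group mean is the
#' negative-score class.
#'
#' Also included (as class `ratio_diagnostic`) is the FRS/SL quick ratio
#' separating *angustifrons* (narrow frons, long scape) from the pool of
#' its complex.
#'
#' @return named list of function objects.
#' @export
#' @examples
#' names(printed_functions())
printed_functions <- function() {
  fns <- .printed_registry()
  out <- stats::setNames(fns, vapply(fns, function(f) f$id, ""))
  out$FRS_SL_angustifrons <- structure(list(
    id = "FRS_SL_angustifrons", ratio = "FRS/SL",
    classes = data.frame(
      class = c("angustifrons", "lucidus/similis/subtilis"),
      mean = c(0.398, 0.461), min = c(0.374, 0.400), max = c(0.439, 0.512),
      p5 = c(0.381, 0.432), p95 = c(0.422, 0.489), stringsAsFactors = FALSE)),
    class = "ratio_diagnostic")
  out
}

.resolve_printed <- function(id) {
  reg <- printed_functions()
  if (!id %in% names(reg))
    stop("unknown printed function id '", id, "'; known: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  reg[[id]]
}

#' @export
print.ratio_diagnostic <- function(x, ...) {
  cat("Quick-ratio diagnostic ", x$id, " on ", x$ratio, "\n", sep = "")
  print(x$classes)
  invisible(x)
}

#' Classify by a quick-ratio diagnostic
#'
#' Assigns to the class whose reference mean is nearer to the observed
#' ratio and reports the 5-95% band position.
#'
#' @param diag `ratio_diagnostic` (e.g.
#'   `printed_functions()$FRS_SL_angustifrons`).
#' @param value the observed ratio, or a trait vector from which it is
#'   computed.
#' @return data frame `value`, `taxon`, `band`.
#' @export
classify_by_ratio <- function(diag, value) {
  if (!is.numeric(value) || !is.null(names(value))) {
    tv <- if (is.numeric(value)) as.list(value) else value
    names(tv) <- canonical_trait(names(tv))
    parts <- strsplit(diag$ratio, "/", fixed = TRUE)[[1]]
    if (!all(parts %in% names(tv)))
      stop("traits ", paste(setdiff(parts, names(tv)), collapse = ", "),
           " required for ", diag$ratio, call. = FALSE)
    value <- unname(unlist(tv[[parts[1]]]) / unlist(tv[[parts[2]]]))
  }
  cl <- diag$classes
  out <- data.frame(value = value, taxon = NA_character_, band = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(value)) {
    j <- which.min(abs(cl$mean - value[i]))
    out$taxon[i] <- cl$class[j]
    out$band[i] <- if (value[i] >= cl$p5[j] && value[i] <= cl$p95[j]) "inside"
      else if (any(value[i] >= cl$p5 & value[i] <= cl$p95)) "outside"
      else "ambiguous/atypical"
  }
  out
}
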