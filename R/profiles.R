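# Species profiles: generator calibration for the 18-species worker fauna.

# ratio columns of a profile row that are trait/CS ratios (trait name = column)
.cs_ratio_traits <- c("EL", "FRS", "SL", "MW", "SPST", "SPBA", "SPWI", "SPTI",
                      "ML", "PEH", "PEW", "NOH", "NOL", "NOdL", "PL", "PPH",
                      "PPL", "PPW", "SPL")

# default individual-level sd for ratios whose range is not printed
.default_ratio_sd <- c(ML = 0.014, PEH = 0.010, PEW = 0.008, NOH = 0.006,
                       NOL = 0.008, NOdL = 0.008, PL = 0.009, PPH = 0.008,
                       PPL = 0.009, PPW = 0.010, SPL = 0.006)

#' Built-in species profiles of the study group
#'
#' One row per species: cephalic-size mean and sd, the `CL/CWb` and
#' `PoOC/CL` ratios, the eight printed trait/CS ratios (sd taken as
#' (max - min)/4 of the printed individual range), eleven further trait/CS
#' ratios calibrated against the printed discriminant-score means and the
#' key's branch statistics, plus antennomere count, geographic region and
#' the propodeal spine angle range (degrees). These profiles are a
#' synthetic calibration consistent with the printed per-species summary
#' statistics, not a copy of any unpublished data table.
#'
#' @return data frame of class `species_profiles`, 18 rows.
#' @seealso [generate_morph_data()], [profile_from_summary()]
#' @export
species_profiles <- function() {
  df <- do.call(rbind, lapply(.profile_rows, function(r)
    as.data.frame(r, col.names = .profile_cols, check.names = FALSE)))
  for (t in names(.default_ratio_sd))
    df[[paste0(t, "_sd")]] <- .default_ratio_sd[[t]]
  class(df) <- c("species_profiles", "data.frame")
  df
}

#' Build a species profile from printed summary rows
#'
#' Converts per-ratio summary statistics (mean plus either sd or an
#' observed range) into a generator-ready profile row. When only a range
#' is available the sd is imputed by the range rule `sd = (max - min)/4`
#' (an approximation: the central ~95% of a normal spans about 4 sd).
#' A mean-only row gets sd 0 with a warning.
#'
#' @param species taxon label.
#' @param cs list/row with `mean` and either `sd` or `min`,`max` for
#'   cephalic size (micrometres). Required.
#' @param ratios named list; each element a list with `mean` and either
#'   `sd` or `min`,`max`. Names as in [species_profiles()] columns, e.g.
#'   `"SPST"` for SPST/CS, `"CL.CWb"`, `"PoOC.CL"`.
#' @param antennomere_count,region,spine_angle optional metadata
#'   (spine_angle a length-2 range in degrees).
#' @return single-row data frame in the [species_profiles()] layout.
#' @export
#' @examples
#' profile_from_summary("angulinodis",
#'   cs = list(mean = 626, min = 594, max = 657),
#'   ratios = list(SPST = list(mean = 0.355, min = 0.332, max = 0.369)))
profile_from_summary <- function(species, cs, ratios = list(),
                                 antennomere_count = 12L,
                                 region = "EUROPE_MAINLAND",
                                 spine_angle = c(40, 45)) {
  get_sd <- function(x, what) {
    if (!is.null(x$sd)) return(x$sd)
    if (!is.null(x$min) && !is.null(x$max)) return((x$max - x$min) / 4)
    warning("no sd or range for ", what, "; sd set to 0", call. = FALSE)
    0
  }
  if (is.null(cs$mean)) stop("cephalic size information is required", call. = FALSE)
  out <- data.frame(species = species, complex = NA_character_,
                    region = region, antennomere_count = antennomere_count,
                    spine_angle_lo = spine_angle[1], spine_angle_hi = spine_angle[2],
                    cs_mean = cs$mean, cs_sd = get_sd(cs, "CS"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in names(ratios)) {
    r <- ratios[[nm]]
    if (is.null(r$mean) || r$mean <= 0) stop("ratio ", nm, ": positive mean required",
                                             call. = FALSE)
    out[[paste0(nm, "_mean")]] <- r$mean
    out[[paste0(nm, "_sd")]] <- get_sd(r, nm)
  }
  out
}

#' Construct uniformly well-separated validation profiles
#'
#' Builds a set of synthetic species profiles whose ratio means are
#' displaced from the group-average profile along a few randomly chosen
#' ratio axes per species — the axis-sparse divergence pattern real
#' congeners show, where species differ in a handful of characters — and
#' scaled so that every species pair is at least `separation` pooled sds
#' apart in ratio space (uniformly, unlike the realistic built-in
#' profiles whose closest pairs are deliberately cryptic). Used to
#' validate cluster and tree recovery under the stated separation
#' condition.
#'
#' @param separation minimum pairwise distance between ratio-mean
#'   vectors, in pooled-sd units.
#' @param seed seed for the random axis choices.
#' @param cs_sd within-species cephalic-size sd (micrometres); species CS
#'   means are spread evenly over 500-660.
#' @param n_axes how many ratio axes each species is displaced along.
#' @return data frame in the [species_profiles()] layout (18 species).
#' @export
well_separated_profiles <- function(separation = 7, seed = 1, cs_sd = 20,
                                    n_axes = 4) {
  p <- species_profiles()
  rc <- c("CL.CWb", "PoOC.CL", .cs_ratio_traits)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  base <- colMeans(as.matrix(p[, paste0(rc, "_mean")]))
  sds <- colMeans(as.matrix(p[, paste0(rc, "_sd")]))
  draw_axes <- function() {
    u <- numeric(length(rc))
    ax <- sample(length(rc), n_axes)
    u[ax] <- sample(c(-1, 1), n_axes, replace = TRUE)
    u
  }
  # profile means must keep the worker-level ordering invariants
  # (SPBA < SPWI, NOH <= PEH) attainable with comfortable noise margin
  ok_profile <- function(o) {
    mean_of <- function(t) base[[match(t, rc)]] + o[match(t, rc)] * sds[[match(t, rc)]]
    margin <- function(a, b) mean_of(b) - mean_of(a) >=
      4 * max(sds[[match(a, rc)]], sds[[match(b, rc)]])
    margin("SPBA", "SPWI") && margin("NOH", "PEH")
  }
  U <- t(vapply(seq_len(nrow(p)), function(i) draw_axes(), numeric(length(rc))))
  for (sweep in seq_len(200L)) {
    alpha <- separation / min(stats::dist(U))
    bad <- which(!vapply(seq_len(nrow(p)),
                         function(i) ok_profile(U[i, ] * alpha), TRUE))
    if (!length(bad)) break
    if (sweep == 200L) stop("could not place valid well-separated profiles",
                            call. = FALSE)
    for (i in bad) U[i, ] <- draw_axes()
  }
  O <- U * alpha                                # offsets in sd units
  for (i in seq_len(nrow(p))) for (j in seq_along(rc)) {
    p[[paste0(rc[j], "_mean")]][i] <- base[j] + O[i, j] * sds[j]
    p[[paste0(rc[j], "_sd")]][i] <- sds[j]
  }
  p$species <- sprintf("sp%02d", seq_len(nrow(p)))
  p$cs_mean <- seq(500, 660, length.out = nrow(p))
  p$cs_sd <- cs_sd
  p
}
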