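# Hierarchical synthetic worker generator: species -> nest -> worker.

#' Generate a synthetic worker morphometric dataset
#'
#' Draws workers under the hierarchical model the downstream analyses
#' assume. For species *s*, nest *j*, worker *i*:
#' \deqn{CS_{sji} = \mu_s + u_j + e_i}
#' with normal nest effect \eqn{u_j} and residual \eqn{e_i} splitting the
#' species' CS variance by `nest_effect_sd_fraction`, and every shape
#' ratio \eqn{r}:
#' \deqn{r_{sji} = \bar r_s + \beta_r (CS_{sji} - \mu_s) + v_{rj} + \epsilon_{ri}}
#' (allometric slope \eqn{\beta_r} on centred CS, nest and worker noise
#' with the same variance split). Raw traits are reconstructed as
#' ratio x CS; CL and CWb are solved from CS and the CL/CWb ratio, and
#' PoOC from the PoOC/CL ratio. Output is deterministic given `seed`.
#'
#' Defaults reproduce the study conditions: the 18 built-in profiles, 29
#' nests per species and 3 workers per nest (522 nests, 1566 workers,
#' matching the scale of the revision's 526 nests / 1693 workers).
#'
#' @param profiles data frame in the [species_profiles()] layout.
#' @param nests_per_species,workers_per_nest integers (scalar or one per
#'   species / a function(n_nests) returning per-nest counts).
#' @param nest_effect_sd_fraction share of each trait's variance placed at
#'   the nest level, in `[0, 1]`.
#' @param sd_scale multiplier on every sd (0 gives noise-free profile
#'   means; values < 1 give well-separated clouds for validation studies).
#' @param allometry named numeric vector of per-ratio slopes per
#'   micrometre of centred CS (names as profile ratio columns, e.g.
#'   `"SPST"`); default none.
#' @param round_um round traits to whole micrometres (off by default).
#' @param seed integer seed; every random draw depends only on it.
#' @return specimen data frame (one row per worker) in the layout read by
#'   [read_morph_csv()], with `species`, `nest_id`, `region`,
#'   `antennomere_count` and `spine_angle_deg` filled in.
#' @export
#' @examples
#' d <- generate_morph_data(nests_per_species = 2, workers_per_nest = 2, seed = 1)
#' nrow(d)  # 18 species x 2 nests x 2 workers = 72
generate_morph_data <- function(profiles = species_profiles(),
                                nests_per_species = 29,
                                workers_per_nest = 3,
                                nest_effect_sd_fraction = 0.3,
                                sd_scale = 1,
                                allometry = NULL,
                                round_um = FALSE,
                                seed = 1) {
  stopifnot(nests_per_species >= 1, nest_effect_sd_fraction >= 0,
            nest_effect_sd_fraction <= 1, sd_scale >= 0)
  ratio_cols <- c("CL.CWb", "PoOC.CL", .cs_ratio_traits)
  miss <- setdiff(paste0(ratio_cols, "_mean"), names(profiles))
  if (length(miss))
    stop("profiles lack ratio column(s): ", paste(miss, collapse = ", "), call. = FALSE)

  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)

  f <- nest_effect_sd_fraction
  sd_nest <- function(s) sqrt(f) * s * sd_scale
  sd_work <- function(s) sqrt(1 - f) * s * sd_scale
  nps <- rep(nests_per_species, length.out = nrow(profiles))

  all_rows <- vector("list", nrow(profiles))
  for (si in seq_len(nrow(profiles))) {
    p <- profiles[si, ]
    slopes <- structure(rep(0, length(ratio_cols)), names = ratio_cols)
    if (!is.null(allometry)) slopes[names(allometry)] <- allometry
    sds <- vapply(ratio_cols, function(rc) {
      s <- p[[paste0(rc, "_sd")]]
      if (is.null(s) || is.na(s)) 0 else s
    }, 0)
    means <- vapply(ratio_cols, function(rc) p[[paste0(rc, "_mean")]], 0)

    sp_rows <- vector("list", nps[si])
    for (j in seq_len(nps[si])) {
      nw <- if (is.function(workers_per_nest)) workers_per_nest(1) else workers_per_nest
      u_cs <- stats::rnorm(1, 0, sd_nest(p$cs_sd))
      v <- stats::rnorm(length(ratio_cols), 0, sd_nest(sds))
      nest_id <- sprintf("SYN:%s-1N-20200101-%03d",
                         paste0(toupper(substr(p$species, 1, 1)),
                                substr(p$species, 2, nchar(p$species))), j)
      workers <- vector("list", nw)
      for (i in seq_len(nw)) {
        for (try in seq_len(100L)) {
          cs <- p$cs_mean + u_cs + stats::rnorm(1, 0, sd_work(p$cs_sd))
          r <- means + slopes * (cs - p$cs_mean) + v +
            stats::rnorm(length(ratio_cols), 0, sd_work(sds))
          names(r) <- ratio_cols
          q <- r[["CL.CWb"]]
          tr <- c(CL = 2 * cs * q / (1 + q), CWb = 2 * cs / (1 + q))
          tr["PoOC"] <- r[["PoOC.CL"]] * tr[["CL"]]
          for (t in .cs_ratio_traits) tr[t] <- r[[t]] * cs
          if (round_um) tr <- round(tr)
          ok <- all(tr > 0) && tr[["PoOC"]] < tr[["CL"]] &&
            tr[["NOH"]] <= tr[["PEH"]] && tr[["SPBA"]] < tr[["SPWI"]]
          if (ok) break
          if (try == 100L) stop("could not draw a valid worker for species ",
                                p$species, call. = FALSE)
        }
        row <- data.frame(specimen_id = sprintf("%s-w%d", nest_id, i),
                          nest_id = nest_id, species = p$species,
                          country = "SYN", region = p$region,
                          antennomere_count = as.integer(p$antennomere_count),
                          spine_angle_deg = stats::runif(1, p$spine_angle_lo,
                                                         p$spine_angle_hi),
                          stringsAsFactors = FALSE)
        for (t in trait_names()) row[[t]] <- unname(tr[[t]])
        workers[[i]] <- row
      }
      sp_rows[[j]] <- do.call(rbind, workers)
    }
    all_rows[[si]] <- do.call(rbind, sp_rows)
  }
  out <- do.call(rbind, all_rows)
  rownames(out) <- NULL
  out
}
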